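test_that("simulation is bitwise deterministic in the seed", {
    s1 <- simulatePair(devSimConfig(77))
    s2 <- simulatePair(devSimConfig(77))
    expect_identical(residues(s1$x), residues(s2$x))
    expect_identical(residues(s1$y), residues(s2$y))
    expect_identical(blockRecords(s1$csb), blockRecords(s2$csb))
    expect_identical(s1$truth$junctions, s2$truth$junctions)
    s3 <- simulatePair(devSimConfig(78))
    expect_false(identical(residues(s1$x), residues(s3$x)))
})

test_that("the implanted inversion is the reverse complement across genomes",
{
    sim <- simulatePair(devSimConfig(5, substitutionRate = 0, jitter = 0))
    tr <- sim$truth$junctions
    bx <- tr$coord[tr$axis == "x" & tr$junction == "1b"] + 1L
    ex <- tr$coord[tr$axis == "x" & tr$junction == "2a"]
    xs <- substring(residues(sim$x), bx, ex)
    ys <- substring(residues(sim$y), bx, ex)
    expect_identical(ys, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(xs))))
    # the flanks are identical (no divergence applied)
    expect_identical(substring(residues(sim$x), 1, 1000),
                     substring(residues(sim$y), 1, 1000))
})

test_that("emitted tables describe the construction", {
    sim <- simulatePair(devSimConfig(6, substitutionRate = 0, jitter = 0))
    csb <- blockRecords(sim$csbTrue)
    expect_identical(nrow(csb), 3L)
    expect_identical(csb$strand, c("f", "r", "f"))
    reps <- blockRecords(sim$repeatsTrue)
    # per junction: one merged diagonal record plus two off-diagonal ones
    expect_identical(nrow(reps), 6L)
    tr <- sim$truth$junctions
    expect_identical(csb$x_end[1L], tr$coord[tr$axis == "x" &
                                             tr$junction == "1a"])
    expect_identical(csb$x_start[2L], tr$coord[tr$axis == "x" &
                                               tr$junction == "1b"] + 1L)
})

test_that("border jitter is bounded, clamped and reproducible", {
    sim <- simulatePair(devSimConfig(9, jitter = 30))
    before <- blockRecords(sim$csbTrue)
    after <- blockRecords(sim$csb)
    for (cc in c("x_start", "x_end", "y_start", "y_end"))
        expect_true(all(abs(after[[cc]] - before[[cc]]) <= 31L))
    expect_true(all(after$x_start <= after$x_end))
    expect_true(all(after$y_start <= after$y_end))
    ord <- order(after$x_start)
    expect_true(all(diff(after$x_start[ord]) > 0))

    bs <- blockSet(data.frame(x_start = c(10, 500), x_end = c(200, 900),
                              y_start = c(10, 500), y_end = c(200, 900),
                              strand = "f"), "csb")
    p1 <- perturbBorders(bs, 20, seed = 4)
    p2 <- perturbBorders(bs, 20, seed = 4)
    expect_identical(blockRecords(p1), blockRecords(p2))
    expect_identical(blockRecords(perturbBorders(bs, 0)), blockRecords(bs))
})

test_that("true junctions always fall inside the perturbed-table ROI", {
    for (s in 1:3) {
        sim <- simulatePair(devSimConfig(s))
        csb <- blockRecords(sim$csb)
        reps <- blockRecords(sim$repeats)
        tr <- sim$truth$junctions
        for (i in 1:2) {
            a <- as.list(csb[i, ]); b <- as.list(csb[i + 1L, ])
            rj <- reps[reps$x_end >= a$x_end & reps$x_start <= b$x_start, ]
            roi <- computeROI(a, b, rj, 100L, "x", length(sim$x))
            jx <- tr$coord[tr$axis == "x" &
                           tr$junction %in% paste0(i, c("a", "b"))]
            expect_true(all(jx > roi$start & jx < roi$end))
        }
    }
})

test_that("emitted blocks carry the expected identity level", {
    # identity of a collinear block should be about 1 - 2p for per-genome
    # substitution rate p (checked with a +-5 point band)
    sim <- simulatePair(devSimConfig(13, substitutionRate = 0.02))
    csb <- blockRecords(sim$csbTrue)
    p <- refineParams()
    m <- computeMetrics(csb[1, ], csb[1, ], sim$x, sim$y, p)
    expect_gte(m$identity_pct, (1 - 2 * 0.02) * 100 - 5)
    expect_lte(m$identity_pct, 100)
})

test_that("impossible configurations are rejected", {
    expect_error(simulationConfig(inversion = c(100, 90)),
                 "inside the backbone")
    expect_error(simulatePair(simulationConfig(
        backboneLength = 10000, inversion = c(4001, 4500),
        repeatLength = 400, repeatCopies = 2)), "too short")
})

test_that("indel events shift coordinates through the truth map", {
    cfg <- devSimConfig(21, indelRate = 5e-4)
    sim <- simulatePair(cfg)
    # sequences should differ in length from the indel-free construction
    expect_false(length(sim$x) == 12000L + 4L * 400L &&
                 length(sim$y) == 12000L + 4L * 400L)
    tr <- sim$truth$junctions
    expect_true(all(diff(tr$coord[tr$axis == "x"]) > 0))
    expect_true(all(tr$coord > 0))
})
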