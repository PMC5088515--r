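test_that("difference vectors are bounded absolute differences", {
    expect_equal(differenceVector(c(1, 2, 3), c(1, 2, 3)), rep(0, 3))
    expect_equal(differenceVector(rep(100, 4), rep(0, 4)), rep(100, 4))
    down <- seq(100, 0, length.out = 101)
    up <- seq(0, 100, length.out = 101)
    v <- differenceVector(down, up, label = "ramps")
    expect_equal(min(v), 0)
    expect_equal(which.min(v), 51L)
    expect_identical(attr(v, "pair_label"), "ramps")
    expect_error(differenceVector(1:3, 1:4), "length")
})

test_that("the six-state scan reproduces the hand-traced transition", {
    sig <- c(100, 100, 90, 80, 60, 40, 20, 10, 20, 40, 60, 80, 100)
    pairs <- detectTransitions(sig, 80, 20)
    # last index still at 80 before the dip is position 4 (1-based),
    # first index back at 80 is position 12
    expect_identical(nrow(pairs), 1L)
    expect_identical(unname(pairs[1L, "start"]), 4L)
    expect_identical(unname(pairs[1L, "end"]), 12L)
    expect_identical(sig[pairs[1L, "start"]], 80)
    expect_identical(sig[pairs[1L, "end"]], 80)
})

test_that("signals without a full excursion yield no pairs", {
    expect_identical(nrow(detectTransitions(c(100, 90, 85, 95, 100), 80, 20)),
                     0L)
    expect_identical(nrow(detectTransitions(seq(0, 60, by = 5), 80, 20)), 0L)
    # a dip still open at scan end is discarded with a warning
    expect_warning(
        pairs <- detectTransitions(c(100, 100, 10, 10, 10), 80, 20),
        "open at scan end")
    expect_identical(nrow(pairs), 0L)
})

test_that("multiple dips yield multiple pairs in scan order", {
    sig <- c(100, 10, 100, 10, 100)
    pairs <- detectTransitions(sig, 80, 20)
    expect_identical(nrow(pairs), 2L)
    expect_identical(pairs[, "start"], c(1L, 3L))
    expect_identical(pairs[, "end"], c(3L, 5L))
})

test_that("the scan agrees with an independent transition finder", {
    set.seed(19)
    for (k in seq_len(300)) {
        L <- sample(20:1000, 1)
        # piecewise-smooth random signal in [0, 100]
        knots <- pmax(0, pmin(100, cumsum(c(runif(1, 0, 100),
                                            rnorm(9, 0, 45)))))
        sig <- approx(seq(0, 1, length.out = 10), knots,
                      xout = seq(0, 1, length.out = L))$y
        got <- suppressWarnings(detectTransitions(sig, 80, 20))
        ref <- refTransitions(sig, 80, 20)
        expect_identical(unname(got[, "start"]), unname(ref[, "start"]),
                         info = paste("seed case", k))
        expect_identical(unname(got[, "end"]), unname(ref[, "end"]))
        # emitted-pair property: endpoints high, a low point in between,
        # and nothing in between reaches u1
        for (r in seq_len(nrow(got))) {
            s <- got[r, "start"]; e <- got[r, "end"]
            expect_gte(sig[s], 80); expect_gte(sig[e], 80)
            inner <- sig[seq(s + 1L, e - 1L)]
            expect_true(any(inner <= 20))
            expect_true(all(inner < 80))
        }
    }
})

test_that("widening the threshold band never shortens a transition", {
    set.seed(23)
    for (k in 1:20) {
        # one smooth dip from a high plateau
        L <- 200
        centre <- runif(1, 60, 140)
        width <- runif(1, 10, 40)
        sig <- 100 - 95 * exp(-((seq_len(L) - centre) / width)^2)
        p1 <- detectTransitions(sig, 80, 20)
        p2 <- detectTransitions(sig, 90, 10)
        if (nrow(p1) == 1L && nrow(p2) == 1L) {
            expect_lte(p2[1, "start"], p1[1, "start"])
            expect_gte(p2[1, "end"], p1[1, "end"])
        }
    }
})

test_that("index pairs map to genomic breakpoints with the size cap", {
    roi <- list(start = 747865L, end = 749673L, length = 1809L,
                offset = 100L, branch = "x", clamped = FALSE)
    pairs <- cbind(start = 137L, end = 148L)
    bp <- indicesToBreakpoints(pairs, roi, "NC-014448.1", 5000L, "a_side")
    expect_identical(bp$start, 748001L)
    expect_identical(bp$end, 748012L)
    expect_identical(bp$length, 11L)

    long <- cbind(start = 10L, end = 6500L)
    expect_warning(bp2 <- indicesToBreakpoints(long, roi, "s", 5000L),
                   "discarded as spurious")
    expect_identical(nrow(bp2), 0L)
    expect_identical(nrow(indicesToBreakpoints(cbind(start = integer(0),
                                                     end = integer(0)),
                                               roi, "s")), 0L)
})
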