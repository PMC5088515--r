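test_that("projection drops branch-gap columns only", {
    expect_identical(projectToBranch(c(1L, 0L, 1L), "A-C"), c(1L, 1L))
    expect_identical(projectToBranch(c(1L, 0L, 1L), "ATC"), c(1L, 0L, 1L))
    expect_error(projectToBranch(c(1L, 0L), "A-C"), "length")
    expect_error(projectToBranch(c(0L, 0L), "--"), "all gaps")
})

test_that("single-scale sliding identity matches hand-computed means", {
    expect_equal(slidingIdentity(rep(1, 10), 3), rep(1, 10))
    expect_equal(slidingIdentity(rep(0, 10), 2), rep(0, 10))
    # clamped edge windows use the actual window size as divisor
    expect_equal(slidingIdentity(c(0, 1, 0, 1, 0), 1),
                 c(1/2, 1/3, 2/3, 1/3, 1/2))
    expect_error(slidingIdentity(c(0, 1, 0), 2), "too short")
    expect_error(slidingIdentity(c(0, 1, 0), 0), ">= 1")
})

test_that("multi-scale identity is a weighted bank of box filters", {
    # all-ones input maps to all-100 for any weight table summing to 1
    set.seed(1)
    for (k in 1:5) {
        w <- runif(10); w <- w / sum(w)
        p <- refineParams(N = 10, weights = w, offset = 20)
        expect_equal(as.numeric(identityVector(rep(1L, 60), p)), rep(100, 60))
    }
    # a single-scale weight table degenerates to slidingIdentity * 100
    w <- rep(0, 10); w[7] <- 1
    p <- refineParams(N = 10, weights = w, offset = 20)
    v <- as.integer(runif(80) < 0.5)
    expect_equal(as.numeric(identityVector(v, p)),
                 100 * slidingIdentity(v, 7))
    expect_error(refineParams(N = 5, weights = rep(0.3, 5)), "sum to 1")
})

test_that("prefix-sum identity equals the naive double loop", {
    set.seed(11)
    for (N in c(1L, 5L, 50L)) {
        for (k in 1:4) {
            L <- sample(150:300, 1)
            v <- as.integer(runif(L) < runif(1))
            p <- refineParams(N = N, weights = rep(1 / N, N),
                              offset = 2L * N + 1L)
            expect_equal(as.numeric(identityVector(v, p)),
                         naiveIdentityVector(v, N, p$weights))
        }
    }
})

test_that("identity vectors are monotone in the match vector", {
    set.seed(3)
    p <- refineParams(N = 10, weights = rep(0.1, 10), offset = 20)
    v <- as.integer(runif(100) < 0.4)
    base <- as.numeric(identityVector(v, p))
    for (k in 1:10) {
        v2 <- v
        zero <- which(v2 == 0L)
        if (!length(zero)) break
        v2[sample(zero, 1)] <- 1L
        expect_true(all(as.numeric(identityVector(v2, p)) >= base - 1e-12))
    }
})

test_that("normalization maps profiles onto a common 0-100 scale", {
    expect_equal(normalizeIdentity(c(20, 60, 100), "minmax"), c(0, 50, 100))
    expect_equal(normalizeIdentity(c(0, 50, 100), "minmax"), c(0, 50, 100))
    expect_identical(normalizeIdentity(c(5, 7, 9), "none"), c(5, 7, 9))
    expect_warning(out <- normalizeIdentity(rep(42, 5), "minmax"),
                   "normalized to all zeros")
    expect_equal(out, rep(0, 5))

    # structural anchoring: plateau zone -> 100, background zone -> 0, clamped
    vals <- c(rep(95, 20), seq(95, 30, length.out = 20), rep(30, 20))
    out <- normalizeIdentity(vals, "quantile", plateau = 1:10,
                             background = 51:60)
    expect_equal(out[1:10], rep(100, 10))
    expect_equal(out[51:60], rep(0, 10))
    expect_true(all(out >= 0 & out <= 100))
    expect_warning(normalizeIdentity(rep(10, 30), "quantile",
                                     plateau = 1:5, background = 21:30),
                   "flat identity")
})
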