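test_that("the ROI spans the junction elements plus the offset padding", {
    # coordinates of the inversion junction between the first two blocks of
    # the M. hyorhinis worked example, with its junction transposase
    a <- list(x_start = 711591, x_end = 747965,
              y_start = 710528, y_end = 746902)
    b <- list(x_start = 749573, x_end = 762895,
              y_start = 748534, y_end = 761860)
    reps <- data.frame(x_start = 748012, x_end = 749513,
                       y_start = 746988, y_end = 748493)
    roi <- computeROI(a, b, reps, offset = 100, branch = "x",
                      seqLength = 839615)
    expect_identical(roi$start, 747865L)   # min(747965, 749573, 748012) - 100
    expect_identical(roi$end, 749673L)     # max(747965, 749573, 749513) + 100
    expect_identical(roi$length, roi$end - roi$start + 1L)

    # without repeats the repeat terms drop out of the min/max
    roi2 <- computeROI(list(x_end = 1000, x_start = 1),
                       list(x_start = 1200, x_end = 2000),
                       NULL, offset = 100, branch = "x", seqLength = 5000)
    expect_identical(c(roi2$start, roi2$end), c(900L, 1300L))
    expect_gte(roi2$length, (1200 - 1000) + 2 * 100)
})

test_that("the ROI is clamped to the sequence and misordered blocks error", {
    expect_warning(
        roi <- computeROI(list(x_end = 40, x_start = 1),
                          list(x_start = 120, x_end = 300),
                          NULL, offset = 100, branch = "x", seqLength = 350),
        "clamped")
    expect_identical(roi$start, 1L)
    expect_true(roi$clamped)
    expect_error(computeROI(list(x_end = 500, x_start = 1),
                            list(x_start = 200, x_end = 800),
                            NULL, 100, "x", 1000),
                 "must precede")
})

test_that("virtualization stretches blocks onto the ROI with alpha shifts", {
    roi <- list(start = 50L, end = 260L, length = 211L, offset = 10L,
                branch = "x", clamped = FALSE)
    fwd <- list(x_start = 100, x_end = 200, y_start = 500, y_end = 600,
                strand = "f")
    v <- makeVirtual(fwd, roi, "x")
    expect_identical(c(v$alpha_l, v$alpha_r), c(50L, 60L))
    expect_identical(c(v$p_start, v$p_end), c(450L, 660L))
    expect_identical(c(v$v_start, v$v_end), c(roi$start, roi$end))

    # identity case: roi equal to the block's own interval
    roiEq <- list(start = 100L, end = 200L, length = 101L, offset = 10L,
                  branch = "x", clamped = FALSE)
    v0 <- makeVirtual(fwd, roiEq, "x")
    expect_identical(c(v0$alpha_l, v0$alpha_r), c(0L, 0L))
    expect_identical(c(v0$p_start, v0$p_end), c(500L, 600L))

    # reverse strand: left extension on x maps to the right end of y
    rev <- modifyList(fwd, list(strand = "r"))
    vr <- makeVirtual(rev, roi, "x")
    expect_identical(c(vr$p_start, vr$p_end), c(440L, 650L))
})

test_that("all virtual blocks of one run share the branch interval", {
    a <- list(x_start = 200, x_end = 1000, y_start = 210, y_end = 1010,
              strand = "f")
    b <- list(x_start = 1400, x_end = 2600, y_start = 1420, y_end = 2630,
              strand = "r")
    roi <- computeROI(a, b, NULL, 100, "x", 5000)
    va <- makeVirtual(a, roi, "x"); vb <- makeVirtual(b, roi, "x")
    expect_identical(c(va$v_start, va$v_end), c(vb$v_start, vb$v_end))
})

test_that("partner slack widens the window and clamping stays in bounds", {
    roi <- list(start = 50L, end = 260L, length = 211L, offset = 10L,
                branch = "x", clamped = FALSE)
    blk <- list(x_start = 100, x_end = 200, y_start = 500, y_end = 600,
                strand = "f")
    v0 <- makeVirtual(blk, roi, "x")
    v1 <- makeVirtual(blk, roi, "x", slack = 30L)
    expect_identical(v1$p_start, v0$p_start - 30L)
    expect_identical(v1$p_end, v0$p_end + 30L)
    vc <- makeVirtual(blk, roi, "x", partnerLength = 620L, slack = 30L)
    expect_identical(vc$p_end, 620L)
})
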