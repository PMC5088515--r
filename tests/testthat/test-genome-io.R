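test_that("readGenome reads, uppercases and sanitizes FASTA records", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">s some description", "ACGT"), fa)
    g <- readGenome(fa)
    expect_s4_class(g, "GenomeSequence")
    expect_identical(seqId(g), "s")
    expect_identical(length(g), 4L)
    expect_identical(residues(g), "ACGT")
    expect_identical(nReplaced(g), 0L)

    writeLines(c(">s", "acgn"), fa)
    expect_identical(residues(readGenome(fa)), "ACGN")

    writeLines(c(">s", "ACXT"), fa)
    expect_message(g <- readGenome(fa), "1 non-ACGTN")
    expect_identical(residues(g), "ACNT")
    expect_identical(nReplaced(g), 1L)
})

test_that("readGenome rejects bad input and resolves multi-record files", {
    expect_error(readGenome(file.path(tempdir(), "nope.fa")), "not found")
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT", ">b", "GGCC"), fa)
    expect_error(readGenome(fa), "multi-record")
    expect_identical(residues(readGenome(fa, id = "b")), "GGCC")
    expect_error(readGenome(fa, id = "zz"), "not found")
    writeLines(c(">empty", ""), fa)
    expect_error(readGenome(fa), "empty")
})

test_that("block tables accept both reverse-strand dialects", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("x_start\tx_end\ty_start\ty_end\tstrand",
                 "749573\t762895\t761860\t748534\tr",
                 "711591\t747965\t710528\t746902\tf"), tsv)
    bs <- readBlockTable(tsv, kind = "csb")
    df <- blockRecords(bs)
    # swapped-Y dialect normalized internally, dialect remembered
    expect_identical(df$y_start[1L], 748534L)
    expect_identical(df$y_end[1L], 761860L)
    expect_identical(df$strand[1L], "r")
    expect_true(df$y_swapped[1L])
    # forward record stored unchanged
    expect_identical(df$y_start[2L], 710528L)
    expect_false(df$y_swapped[2L])

    # strand may be implied by the swap alone
    writeLines(c("x_start\tx_end\ty_start\ty_end",
                 "100\t200\t600\t500"), tsv)
    expect_identical(blockRecords(readBlockTable(tsv, "csb"))$strand, "r")
})

test_that("invalid block records are rejected", {
    expect_error(blockSet(data.frame(x_start = 5, x_end = 2,
                                     y_start = 1, y_end = 2), "csb"),
                 "x_start > x_end")
    expect_error(blockSet(data.frame(x_start = 0, x_end = 2,
                                     y_start = 1, y_end = 2), "csb"),
                 "coordinates < 1")
    expect_error(blockSet(data.frame(x_start = 1, x_end = 2,
                                     y_start = 9, y_end = 2,
                                     strand = "f"), "csb"),
                 "forward-strand")
})

test_that("block tables round-trip bit-exactly through write/read", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    lines <- c("x_start\tx_end\ty_start\ty_end\tstrand",
               "749573\t762895\t761860\t748534\tr",
               "711591\t747965\t710528\t746902\tf",
               "764581\t780474\t763521\t779414\tf")
    writeLines(lines, tsv)
    bs <- readBlockTable(tsv, "csb")
    out <- withr::local_tempfile(fileext = ".tsv")
    writeBlockTable(bs, out)
    orig <- utils::read.table(tsv, header = TRUE, sep = "\t")
    rt <- utils::read.table(out, header = TRUE, sep = "\t")
    expect_identical(rt[names(orig)], orig)
    # and reading the written file gives the same normalized records
    expect_identical(blockRecords(readBlockTable(out, "csb")),
                     blockRecords(bs))
})

test_that("writeResults emits consistent TSV and BED coordinates", {
    bp <- GenomicRanges::GRanges("chrX", IRanges::IRanges(748001, 748012))
    S4Vectors::mcols(bp)$bp_id <- "1.1x"
    S4Vectors::mcols(bp)$bp_length <- 11L
    S4Vectors::mcols(bp)$junction <- "a_side"
    S4Vectors::mcols(bp)$axis <- "x"
    S4Vectors::mcols(bp)$pair_id <- 1L
    S4Vectors::mcols(bp)$far_left <- NA_integer_
    S4Vectors::mcols(bp)$far_right <- NA_integer_
    res <- new("RefinementResult",
               blocks = data.frame(block = 1L, flag = "resolved"),
               repeats = data.frame(),
               breakpoints = bp,
               prasb = GenomicRanges::GRanges(),
               gaps = GenomicRanges::GRanges(),
               params = list(offset = 100), diagnostics = list())
    outDir <- withr::local_tempdir()
    files <- writeResults(res, outDir)
    expect_true(file.exists(file.path(outDir, "breakpoints.tsv")))
    tsv <- utils::read.table(file.path(outDir, "breakpoints.tsv"),
                             header = TRUE, sep = "\t")
    expect_identical(tsv$start, 748001L)
    expect_identical(tsv$end, 748012L)
    bed <- utils::read.table(file.path(outDir, "breakpoints.bed"), sep = "\t")
    # BED is 0-based half-open: start_BED = start_TSV - 1, end_BED = end_TSV
    expect_identical(bed$V2, tsv$start - 1L)
    expect_identical(bed$V3, tsv$end)
    expect_true(file.exists(file.path(outDir, "run_log.txt")))
    # empty interval sets still produce a commented BED file
    first <- readLines(file.path(outDir, "prasb.bed"), n = 1L)
    expect_match(first, "^#")
})
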