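#' Read one genome sequence from a FASTA file
#'
#' Reads a FASTA file, uppercases the residues and replaces every character
#' outside \{A,C,G,T,N\} by \code{N}, reporting the number of replacements as
#' a message. Multi-record files are rejected unless \code{id} selects one
#' record.
#'
#' @param path path to a FASTA file.
#' @param id optional record identifier to select from a multi-record file
#'   (matched against the first whitespace-delimited token of the header).
#' @return a [GenomeSequence-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "acgn"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path, id = NULL) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    recs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) stop("invalid FASTA: ", conditionMessage(e)))
    if (length(recs) == 0L) stop("empty FASTA: ", path)
    ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
    if (length(recs) > 1L) {
        if (is.null(id))
            stop("multi-record FASTA; pass 'id' to select one of: ",
                 paste(utils::head(ids, 5L), collapse = ", "))
        k <- match(id, ids)
        if (is.na(k)) stop("record id ", sQuote(id), " not found in ", path)
    } else {
        k <- 1L
        if (!is.null(id) && id != ids[1L])
            stop("record id ", sQuote(id), " not found in ", path)
    }
    chars <- toupper(as.character(recs[[k]]))
    if (nchar(chars) == 0L) stop("empty sequence for record ", sQuote(ids[k]))
    cleaned <- gsub("[^ACGTN]", "N", chars)
    nrep <- sum(utf8ToInt(chars) != utf8ToInt(cleaned))
    if (nrep > 0L)
        message(nrep, " non-ACGTN residue(s) replaced by N in record ",
                sQuote(ids[k]))
    new("GenomeSequence", id = ids[k], seq = Biostrings::DNAString(cleaned),
        nReplaced = as.integer(nrep))
}

#' Read a CSB or repeat block table
#'
#' Reads a tab-separated table with a header carrying at least
#' \code{x_start}, \code{x_end}, \code{y_start}, \code{y_end} and optionally
#' \code{strand}, \code{length}, \code{identity_pct}. Two reverse-strand
#' dialects are accepted: an explicit strand column ("f"/"r", "+"/"-",
#' "forward"/"reverse") or the swapped-Y dialect in which reverse records
#' carry \code{y_start > y_end}. Internally y intervals are always stored
#' with \code{y_start <= y_end} plus a strand flag; the input dialect is
#' remembered per record so [writeBlockTable()] round-trips coordinates
#' bit-exactly.
#'
#' @param path path to the TSV file.
#' @param kind "csb" or "repeat".
#' @param sep field separator, default tab.
#' @return a [BlockSet-class].
#' @export
readBlockTable <- function(path, kind = c("csb", "repeat"), sep = "\t") {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("block table not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "#")
    blockSet(df, kind = kind)
}

#' Write a block table preserving the input dialect
#'
#' Writes records back as TSV; records read from the swapped-Y dialect are
#' written with their y coordinates swapped again, so a read/write cycle
#' preserves every coordinate and strand bit-exactly.
#'
#' @param x a [BlockSet-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeBlockTable <- function(x, path) {
    stopifnot(is(x, "BlockSet"))
    df <- x@records
    out <- df
    swap <- df$y_swapped
    out$y_start[swap] <- df$y_end[swap]
    out$y_end[swap] <- df$y_start[swap]
    out$y_swapped <- NULL
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write all refinement outputs to a directory
#'
#' Writes (a) the refined-CSB TSV with before/after coordinates, strand,
#' alignment length, percent extension in X and Y and percent identity;
#' (b) breakpoints both as a 1-based inclusive TSV and as 0-based half-open
#' BED; (c) PRASB and gap intervals as BED; (d) optionally the underlying
#' interval sequences as FASTA; and (e) a plain-text run log with every
#' parameter and warning.
#'
#' @param result a [RefinementResult-class].
#' @param outDir output directory (created if missing).
#' @param xSeq,ySeq optional [GenomeSequence-class] objects; when given,
#'   breakpoint/PRASB/gap sequences are exported as FASTA.
#' @return invisibly, a character vector of the files written.
#' @export
writeResults <- function(result, outDir, xSeq = NULL, ySeq = NULL) {
    stopifnot(is(result, "RefinementResult"))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    written <- character(0)

    f <- file.path(outDir, "refined_blocks.tsv")
    utils::write.table(result@blocks, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)

    if (nrow(result@repeats) > 0L) {
        f <- file.path(outDir, "refined_repeats.tsv")
        utils::write.table(result@repeats, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, f)
    }

    bp <- result@breakpoints
    f <- file.path(outDir, "breakpoints.tsv")
    bpdf <- data.frame(id = if (length(bp)) mcols(bp)$bp_id else character(0),
                       sequence = as.character(seqnames(bp)),
                       start = start(bp), end = end(bp),
                       length = if (length(bp)) mcols(bp)$bp_length else integer(0),
                       junction = if (length(bp)) mcols(bp)$junction else character(0))
    utils::write.table(bpdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)

    written <- c(written,
                 .writeBed(bp, file.path(outDir, "breakpoints.bed")),
                 .writeBed(result@prasb, file.path(outDir, "prasb.bed")),
                 .writeBed(result@gaps, file.path(outDir, "gaps.bed")))

    if (!is.null(xSeq) && !is.null(ySeq)) {
        seqs <- list(xSeq, ySeq)
        names(seqs) <- c(seqId(xSeq), seqId(ySeq))
        for (what in c("breakpoints", "prasb", "gaps")) {
            gr <- slot(result, c(breakpoints = "breakpoints",
                                 prasb = "prasb", gaps = "gaps")[[what]])
            gr <- gr[width(gr) > 0L]
            if (length(gr) == 0L) next
            dna <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
                sid <- as.character(seqnames(gr))[i]
                s <- seqs[[sid]]
                if (is.null(s)) return(NA_character_)
                as.character(Biostrings::subseq(s@seq, start(gr)[i], end(gr)[i]))
            }, character(1)))
            names(dna) <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                                  start(gr), end(gr))
            f <- file.path(outDir, paste0(what, ".fasta"))
            Biostrings::writeXStringSet(dna, f)
            written <- c(written, f)
        }
    }

    f <- file.path(outDir, "run_log.txt")
    con <- file(f, "w")
    on.exit(close(con))
    writeLines(c("csbRefine run log", format(Sys.time()), "", "parameters:"), con)
    p <- result@params
    for (nm in names(p))
        writeLines(sprintf("  %s = %s", nm,
                           paste(format(p[[nm]], digits = 6), collapse = ",")), con)
    warns <- result@diagnostics$warnings
    writeLines(c("", "notes:"), con)
    if (length(warns)) writeLines(paste0("  ", warns), con)
    written <- c(written, f)
    invisible(written)
}

# BED is 0-based half-open; rtracklayer does the conversion from the 1-based
# GRanges. Zero-length intervals (abutting breakpoints) are dropped from BED
# but kept in the TSV.
.writeBed <- function(gr, path) {
    header <- sprintf("# %s: 0-based half-open intervals", basename(path))
    if (length(gr) == 0L || all(width(gr) <= 0L)) {
        writeLines(header, path)
        return(path)
    }
    gr <- gr[width(gr) > 0L]
    names(gr) <- NULL
    export <- gr
    mcols(export) <- NULL
    if (!is.null(mcols(gr)$bp_id)) export$name <- mcols(gr)$bp_id
    rtracklayer::export.bed(export, path)
    path
}

#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#' @importFrom S4Vectors mcols<-
#' @importFrom IRanges IRanges
NULL
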