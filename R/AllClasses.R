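#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom GenomicRanges GRanges
NULL

#' GenomeSequence: a single DNA sequence with ingest bookkeeping
#'
#' Thin S4 container around a [Biostrings::DNAString] holding one genome (or
#' contig). On ingest through [readGenome()] residues are uppercased and any
#' character outside \{A,C,G,T,N\} is replaced by \code{N}; the number of
#' replacements is kept so the caller can audit dirty assemblies. An \code{N}
#' never counts as a match during alignment scoring.
#'
#' @slot id character(1), the record identifier.
#' @slot seq a \code{DNAString} over \{A,C,G,T,N\}.
#' @slot nReplaced integer(1), characters replaced by N on ingest.
#'
#' @seealso [readGenome()]
#' @export
setClass("GenomeSequence",
    slots = c(id = "character", seq = "DNAString", nReplaced = "integer"))

setValidity("GenomeSequence", function(object) {
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("'id' must be a single non-empty string")
    if (length(object@seq) == 0L)
        return("empty sequence")
    letters <- Biostrings::uniqueLetters(object@seq)
    if (!all(letters %in% c("A", "C", "G", "T", "N")))
        return("sequence contains letters outside {A,C,G,T,N}")
    TRUE
})

#' BlockSet: a table of paired-interval block records
#'
#' Holds CSB or repeat records as paired intervals on sequences X and Y with a
#' strand. Coordinates are stored 1-based inclusive with
#' \code{x_start <= x_end} and \code{y_start <= y_end} always; reverse-strand
#' records read from the swapped-Y table dialect (y_start > y_end) are
#' normalized on ingest and the original dialect is remembered per record
#' (column \code{y_swapped}) so output round-trips bit-exactly.
#'
#' @slot records data.frame with columns \code{x_start}, \code{x_end},
#'   \code{y_start}, \code{y_end}, \code{strand} ("f"/"r"), \code{y_swapped}
#'   (logical) and optionally \code{length}, \code{identity_pct}.
#' @slot kind character(1), "csb" or "repeat".
#'
#' @seealso [readBlockTable()], [blockSet()]
#' @export
setClass("BlockSet", slots = c(records = "data.frame", kind = "character"))

setValidity("BlockSet", function(object) {
    df <- object@records
    need <- c("x_start", "x_end", "y_start", "y_end", "strand", "y_swapped")
    if (!all(need %in% names(df)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (!object@kind %in% c("csb", "repeat"))
        return("kind must be 'csb' or 'repeat'")
    if (nrow(df) == 0L) return(TRUE)
    if (any(df$x_start < 1L) || any(df$y_start < 1L))
        return("coordinates must be >= 1")
    if (any(df$x_start > df$x_end))
        return("x_start > x_end")
    if (any(df$y_start > df$y_end))
        return("y_start > y_end after normalization")
    if (!all(df$strand %in% c("f", "r")))
        return("strand must be 'f' or 'r'")
    TRUE
})

#' RefinementResult: refined blocks, breakpoints and derived intervals
#'
#' The combined outcome of refining one or more adjacent CSB pairs: the
#' before/after coordinate table with extension metrics, all emitted
#' breakpoints, the PRASB control intervals (a stretch of the adjacent
#' refined block with exactly the paired breakpoint's length) and the gap
#' intervals (the region strictly between the two breakpoints of one junction
#' on the same sequence), plus the complete parameter snapshot and per-signal
#' diagnostics.
#'
#' @slot blocks data.frame, one row per CSB: before/after coordinates,
#'   strand, alignment length, delta_x_pct, delta_y_pct, identity_pct, flags.
#' @slot repeats data.frame, repeat records with refined borders where a
#'   breakpoint bounded them.
#' @slot breakpoints [GenomicRanges::GRanges] on the two input sequences,
#'   with junction labels.
#' @slot prasb [GenomicRanges::GRanges], PRASB control intervals.
#' @slot gaps [GenomicRanges::GRanges], inter-breakpoint gap intervals.
#' @slot params list, the full configuration used.
#' @slot diagnostics list, per-junction difference signals and FSM traces.
#'
#' @seealso [refineChain()], [refineCSBPair()], [writeResults()]
#' @export
setClass("RefinementResult",
    slots = c(blocks = "data.frame", repeats = "data.frame",
              breakpoints = "GRanges", prasb = "GRanges", gaps = "GRanges",
              params = "list", diagnostics = "list"))

setMethod("show", "GenomeSequence", function(object) {
    cat("GenomeSequence", sQuote(object@id), "-", length(object@seq), "bp")
    if (object@nReplaced > 0L)
        cat(";", object@nReplaced, "residue(s) replaced by N on ingest")
    cat("\n")
})

setMethod("show", "BlockSet", function(object) {
    cat("BlockSet of kind", sQuote(object@kind), "with",
        nrow(object@records), "record(s)\n")
    if (nrow(object@records) > 0L)
        print(utils::head(object@records, 6L))
})

setMethod("show", "RefinementResult", function(object) {
    cat("RefinementResult:", nrow(object@blocks), "block(s),",
        length(object@breakpoints), "breakpoint(s),",
        length(object@prasb), "PRASB interval(s),",
        length(object@gaps), "gap interval(s)\n")
    unres <- sum(object@blocks$flag != "resolved")
    if (unres > 0L) cat(" ", unres, "block(s) partially unresolved\n")
})

#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' Accessors for GenomeSequence
#'
#' \code{seqId} returns the record identifier, \code{residues} the sequence
#' as a character string, \code{nReplaced} the count of residues replaced by
#' N on ingest.
#' @param x a \code{GenomeSequence}.
#' @return \code{seqId}: character(1); \code{residues}: character(1);
#'   \code{nReplaced}: integer(1); \code{length}: integer(1) sequence length.
#' @aliases seqId residues nReplaced
#' @export
setMethod("seqId", "GenomeSequence", function(x) x@id)

#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname seqId
#' @export
setMethod("residues", "GenomeSequence", function(x) as.character(x@seq))

#' @export
setGeneric("nReplaced", function(x) standardGeneric("nReplaced"))
#' @rdname seqId
#' @export
setMethod("nReplaced", "GenomeSequence", function(x) x@nReplaced)

#' @rdname seqId
#' @export
setMethod("length", "GenomeSequence", function(x) length(x@seq))

#' Accessors for BlockSet and RefinementResult
#'
#' \code{blockRecords} returns the normalized record table of a
#' \code{BlockSet}; \code{blockKind} its kind. \code{refinedBlocks},
#' \code{refinedRepeats}, \code{breakpoints}, \code{prasbIntervals},
#' \code{gapIntervals} and \code{runParams} extract the corresponding parts
#' of a \code{RefinementResult}.
#'
#' @param x a \code{BlockSet} or \code{RefinementResult}.
#' @return the extracted component (data.frame, GRanges or list).
#' @aliases blockRecords blockKind refinedBlocks refinedRepeats breakpoints
#'   prasbIntervals gapIntervals runParams
#' @export
setGeneric("blockRecords", function(x) standardGeneric("blockRecords"))
#' @rdname blockRecords
#' @export
setMethod("blockRecords", "BlockSet", function(x) x@records)

#' @export
setGeneric("blockKind", function(x) standardGeneric("blockKind"))
#' @rdname blockRecords
#' @export
setMethod("blockKind", "BlockSet", function(x) x@kind)

#' @rdname blockRecords
#' @export
setMethod("length", "BlockSet", function(x) nrow(x@records))

#' @export
setGeneric("refinedBlocks", function(x) standardGeneric("refinedBlocks"))
#' @rdname blockRecords
#' @export
setMethod("refinedBlocks", "RefinementResult", function(x) x@blocks)

#' @export
setGeneric("refinedRepeats", function(x) standardGeneric("refinedRepeats"))
#' @rdname blockRecords
#' @export
setMethod("refinedRepeats", "RefinementResult", function(x) x@repeats)

#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname blockRecords
#' @export
setMethod("breakpoints", "RefinementResult", function(x) x@breakpoints)

#' @export
setGeneric("prasbIntervals", function(x) standardGeneric("prasbIntervals"))
#' @rdname blockRecords
#' @export
setMethod("prasbIntervals", "RefinementResult", function(x) x@prasb)

#' @export
setGeneric("gapIntervals", function(x) standardGeneric("gapIntervals"))
#' @rdname blockRecords
#' @export
setMethod("gapIntervals", "RefinementResult", function(x) x@gaps)

#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))
#' @rdname blockRecords
#' @export
setMethod("runParams", "RefinementResult", function(x) x@params)

#' Construct a BlockSet from a data.frame
#'
#' Normalizes strand spellings ("f"/"forward"/"+" and "r"/"reverse"/"-") and
#' the swapped-Y reverse dialect (y_start > y_end implies reverse strand),
#' then validates.
#'
#' @param df data.frame with columns x_start, x_end, y_start, y_end and
#'   optionally strand, length, identity_pct.
#' @param kind "csb" or "repeat".
#' @return a \code{BlockSet}.
#' @export
blockSet <- function(df, kind = c("csb", "repeat")) {
    kind <- match.arg(kind)
    df <- as.data.frame(df)
    need <- c("x_start", "x_end", "y_start", "y_end")
    if (!all(need %in% names(df)))
        stop("block table must have columns: ", paste(need, collapse = ", "))
    for (cc in need) df[[cc]] <- as.integer(df[[cc]])
    if (any(is.na(df$x_start)) || any(is.na(df$y_start)) ||
        any(is.na(df$x_end)) || any(is.na(df$y_end)))
        stop("malformed block table: non-numeric coordinates")
    if (any(df$x_start > df$x_end))
        stop("invalid record: x_start > x_end")
    if (any(df$x_start < 1L) || any(pmin(df$y_start, df$y_end) < 1L))
        stop("invalid record: coordinates < 1")
    if (is.null(df$strand)) df$strand <- NA_character_
    df$strand <- .normalizeStrand(df$strand, df$y_start, df$y_end)
    df$y_swapped <- df$y_start > df$y_end
    swap <- df$y_swapped
    if (any(swap)) {
        tmp <- df$y_start[swap]
        df$y_start[swap] <- df$y_end[swap]
        df$y_end[swap] <- tmp
    }
    if (any(df$y_swapped & df$strand == "f"))
        stop("invalid record: y_start > y_end on a forward-strand record")
    keep <- intersect(c("x_start", "x_end", "y_start", "y_end", "strand",
                        "y_swapped", "length", "identity_pct"), names(df))
    new("BlockSet", records = df[, keep, drop = FALSE], kind = kind)
}

.normalizeStrand <- function(strand, y_start, y_end) {
    s <- tolower(as.character(strand))
    s[s %in% c("f", "forward", "+", "1")] <- "f"
    s[s %in% c("r", "reverse", "-", "-1")] <- "r"
    miss <- is.na(s) | !(s %in% c("f", "r"))
    # swapped-Y dialect carries strand implicitly
    s[miss] <- ifelse(y_start[miss] > y_end[miss], "r", "f")
    s
}
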