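#' Sum match vector over projected repeat alignments
#'
#' Elementwise sum of the repeats' projected binary match vectors. All
#' inputs must already live on ROI branch coordinates (see
#' [projectToBranch()]), so gap columns never contribute. Each repeat's
#' vector may additionally be masked to its own branch-axis span before
#' summation (see [consensusVectors()]): outside its span a virtual
#' repeat's matches are alignment background, not repeat coverage.
#'
#' @param projected list of equal-length integer 0/1 vectors, one per
#'   repeat; must be non-empty (a consensus is undefined without repeats).
#' @return integer vector, per-position count of repeats matching there.
#' @examples
#' sumMatchVector(list(c(1L, 0L, 1L), c(1L, 1L, 0L)))
#' @export
sumMatchVector <- function(projected) {
    if (length(projected) == 0L)
        stop("consensus undefined without repeats")
    L <- unique(lengths(projected))
    if (length(L) != 1L)
        stop("projected match vectors differ in length")
    as.integer(Reduce(`+`, lapply(projected, as.integer)))
}

#' Threshold the sum match vector into a consensus binary vector
#'
#' Position x is 1 iff at least \code{threshold} of the repeats match there
#' (inclusive comparison, so with four repeats one match reaches the default
#' 25\% exactly).
#'
#' @param vSM integer sum match vector.
#' @param nRepeats number of repeats summed, >= 1.
#' @param threshold coverage fraction in (0, 1], default 0.25.
#' @return integer 0/1 vector.
#' @export
consensusBinary <- function(vSM, nRepeats, threshold = 0.25) {
    if (nRepeats < 1L) stop("nRepeats must be >= 1")
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    as.integer(vSM / nRepeats >= threshold)
}

#' Consensus identity vector from projected repeat alignments
#'
#' Full consensus construction: mask each projected repeat match vector to
#' the repeat's own branch-axis span, sum ([sumMatchVector()]), threshold
#' ([consensusBinary()]) and smooth/normalize the resulting consensus
#' binary vector exactly as a block identity profile
#' ([identityVector()] + [normalizeIdentity()]).
#'
#' @param projected list of projected 0/1 match vectors, one per repeat.
#' @param spans optional list of integer index ranges \code{c(from, to)}
#'   (ROI-relative) giving each repeat's own span; positions outside are
#'   zeroed before summation. \code{NULL} keeps whole vectors.
#' @param params a [refineParams()] list (fields consensusThreshold, N,
#'   weights, normalize).
#' @param tolerance half-width in nt of a binary dilation applied to each
#'   projected match vector before summation (default 1). Every record
#'   covering a position reuses the same branch residue, so a single
#'   substitution in the branch copy knocks the position out of every
#'   record at once; tolerating isolated single-site mismatches keeps such
#'   correlated holes out of the consensus plateau.
#' @return list with \code{v_sm}, \code{consensus_binary} and \code{v_ci}
#'   (the normalized consensus identity vector).
#' @export
consensusVectors <- function(projected, spans = NULL,
                             params = refineParams(), tolerance = 1L) {
    if (tolerance > 0L) {
        projected <- lapply(projected, function(v) {
            v <- as.integer(v)
            out <- v
            for (d in seq_len(tolerance)) {
                L <- length(v)
                out <- pmax(out, c(v[-seq_len(d)], rep(0L, d)),
                            c(rep(0L, d), v[seq_len(L - d)]))
            }
            out
        })
    }
    if (!is.null(spans)) {
        stopifnot(length(spans) == length(projected))
        projected <- lapply(seq_along(projected), function(k) {
            v <- as.integer(projected[[k]])
            sp <- spans[[k]]
            lo <- max(1L, sp[1L]); hi <- min(length(v), sp[2L])
            keep <- logical(length(v))
            if (lo <= hi) keep[lo:hi] <- TRUE
            v[!keep] <- 0L
            v
        })
    }
    vSM <- sumMatchVector(projected)
    cb <- consensusBinary(vSM, length(projected), params$consensusThreshold)
    plateau <- NULL; background <- NULL
    if (!is.null(spans)) {
        lo <- max(1L, min(vapply(spans, `[`, integer(1), 1L)))
        hi <- min(length(vSM), max(vapply(spans, `[`, integer(1), 2L)))
        if (lo < hi) {
            plateau <- lo:hi
            background <- setdiff(seq_along(vSM), plateau)
            if (length(background) == 0L) background <- NULL
        }
    }
    vCI <- normalizeIdentity(identityVector(cb, params), params$normalize,
                             plateau = plateau, background = background)
    list(v_sm = vSM, consensus_binary = cb, v_ci = vCI)
}
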