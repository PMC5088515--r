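#' Global alignment of two virtual-block subsequences
#'
#' End-to-end (Needleman–Wunsch) global alignment through
#' [Biostrings::pairwiseAlignment] with a symmetric ACGTN substitution
#' matrix and affine gaps. An \code{N} scores as a mismatch against every
#' residue, including another \code{N}, so ambiguous positions can never
#' create spurious identity. A gap of length L costs
#' \code{gapOpen + L * gapExtend}. Reverse-strand partners must be
#' reverse-complemented by the caller before alignment.
#'
#' @param x,y character strings or \code{DNAString}s over \{A,C,G,T,N\};
#'   both non-empty.
#' @param params a [refineParams()] list (scoring fields used:
#'   match, mismatch, gapOpen, gapExtend, dpGuard).
#' @param type "global" (default) is strict end-to-end alignment.
#'   "local" reports the maximal-scoring contiguous segment
#'   (Smith-Waterman): the mode used for virtual blocks, whose oversized
#'   approximate windows deliberately contain non-homologous margins;
#'   forcing those margins into a global alignment would only manufacture
#'   noise, while the local mode leaves them uncovered.
#' @return a list with \code{aligned_x}, \code{aligned_y} (equal-length
#'   gapped strings), \code{score}, \code{match_vector} (integer 0/1 per
#'   alignment column; see [matchVector()]), and \code{x_range},
#'   \code{y_range} (1-based positions of each input covered by the
#'   alignment; the full sequences for "global").
#' @examples
#' aln <- nwAlign("ACGT", "AGGT", refineParams())
#' aln$match_vector
#' @export
nwAlign <- function(x, y, params = refineParams(),
                    type = c("global", "local")) {
    type <- match.arg(type)
    x <- as.character(x); y <- as.character(y)
    nx <- nchar(x); ny <- nchar(y)
    if (nx == 0L || ny == 0L) stop("cannot align an empty sequence")
    if (as.numeric(nx) * ny > params$dpGuard)
        stop("alignment of ", nx, " x ", ny, " exceeds the DP guard (",
             format(params$dpGuard, scientific = TRUE),
             " cells); shorten the ROI or raise 'dpGuard'")
    mat <- .nwMatrix(params$match, params$mismatch)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(x), Biostrings::DNAString(y), type = type,
        substitutionMatrix = mat,
        gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    ax <- as.character(Biostrings::alignedPattern(aln))
    ay <- as.character(Biostrings::alignedSubject(aln))
    if (type == "local") {
        xr <- c(Biostrings::start(Biostrings::pattern(aln)),
                Biostrings::end(Biostrings::pattern(aln)))
        yr <- c(Biostrings::start(Biostrings::subject(aln)),
                Biostrings::end(Biostrings::subject(aln)))
    } else {
        xr <- c(1L, nx); yr <- c(1L, ny)
    }
    out <- list(aligned_x = ax, aligned_y = ay,
                score = Biostrings::score(aln),
                x_range = xr, y_range = yr)
    out$match_vector <- matchVector(out)
    # ungapping must recover the covered input stretch exactly
    stopifnot(gsub("-", "", ax, fixed = TRUE) == substr(x, xr[1L], xr[2L]),
              gsub("-", "", ay, fixed = TRUE) == substr(y, yr[1L], yr[2L]))
    out
}

.nwMatrix <- function(match, mismatch) {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
    diag(m) <- match
    m["N", "N"] <- mismatch
    m
}

#' Binary match vector of a pairwise alignment
#'
#' Column j is 1 iff the two aligned residues are identical, neither is a
#' gap, and neither is \code{N}. The vector has the length of the alignment
#' (gap columns included, as zeros).
#'
#' @param aln a list with \code{aligned_x} and \code{aligned_y} as produced
#'   by [nwAlign()].
#' @return integer vector of 0/1 of the alignment length.
#' @export
matchVector <- function(aln) {
    cx <- strsplit(aln$aligned_x, "", fixed = TRUE)[[1L]]
    cy <- strsplit(aln$aligned_y, "", fixed = TRUE)[[1L]]
    if (length(cx) != length(cy))
        stop("aligned strings differ in length")
    as.integer(cx == cy & cx != "-" & cx != "N")
}

#' Reverse complement of a character DNA string
#'
#' @param s character(1) over \{A,C,G,T,N\}.
#' @return character(1), the reverse complement.
#' @keywords internal
revComp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
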