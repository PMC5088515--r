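#' Refinement parameters
#'
#' Assembles and validates the full parameter set of the border-refinement
#' pipeline. Defaults are the method's standard operating point (identity half-window bound N = 50, FSM thresholds
#' 80/20, repeat-consensus coverage threshold 25\%, breakpoint size cap
#' 5000 nt); the remaining knobs (offset, alignment scoring, normalization)
#' are documented package choices.
#'
#' @param offset padding in nt added on both sides of the region of interest
#'   so each difference signal starts and ends on a high-identity plateau.
#'   Must be strictly greater than \code{N}. Default 100.
#' @param N maximum half-window of the identity profile; scales i = 1..N
#'   with window width 2i+1 are averaged. Default 50.
#' @param weights numeric vector of length \code{N} of per-scale weights,
#'   must sum to 1. Default uniform \code{1/N}.
#' @param normalize identity-vector normalization mode: \code{"quantile"}
#'   (robust 5th/95th-percentile anchoring to [0,100], the default),
#'   \code{"minmax"} (plain affine map) or \code{"none"}; see
#'   [normalizeIdentity()].
#' @param u1,u2 high/low FSM thresholds on the 0-100 difference signal;
#'   \code{0 <= u2 < u1 <= 100}. Defaults 80 and 20.
#' @param maxBpLength breakpoints longer than this are discarded as spurious
#'   (not truncated). Default 5000 nt.
#' @param consensusThreshold minimum fraction of repeats that must match at
#'   a position for the consensus binary vector to be 1 (inclusive).
#'   Default 0.25.
#' @param match,mismatch alignment scores for identical / differing residues.
#'   Defaults +4 / -4. An N scores as a mismatch against everything,
#'   including N.
#' @param gapOpen,gapExtend affine gap penalty magnitudes: a gap of length L
#'   costs \code{gapOpen + L * gapExtend}. Defaults 8 and 5: the extension
#'   cost is set so a gap-gap column pair (2*gapExtend) costs more than a
#'   mismatch, which keeps alignment of non-homologous sequence
#'   net-negative — the property the local virtual-block alignments rely
#'   on to leave non-homologous margins uncovered.
#' @param partnerSlack extra nucleotides added to both ends of every
#'   virtual block's partner interval before alignment. The stretched
#'   partner window is anchored through the far block border, so
#'   coordinate error in the input tables displaces it off the true
#'   alignment diagonal; the slack absorbs that uncertainty. Default 100.
#' @param dpGuard maximum allowed DP matrix size (cells) for one global
#'   alignment. Default 1e8.
#'
#' @return a named list of validated parameters (class "refineParams").
#' @examples
#' p <- refineParams()
#' p$u1; p$offset
#' @export
refineParams <- function(offset = 100L, N = 50L, weights = NULL,
                         normalize = c("quantile", "minmax", "none"),
                         u1 = 80, u2 = 20, maxBpLength = 5000L,
                         consensusThreshold = 0.25,
                         match = 4, mismatch = -4,
                         gapOpen = 8, gapExtend = 5,
                         partnerSlack = 100L, dpGuard = 1e8) {
    normalize <- match.arg(normalize)
    N <- as.integer(N)
    offset <- as.integer(offset)
    if (N < 1L) stop("N must be >= 1")
    if (offset <= N)
        stop("offset (", offset, ") must be strictly greater than N (", N, ")")
    if (is.null(weights)) weights <- rep(1 / N, N)
    if (length(weights) != N || any(weights < 0))
        stop("weights must be a non-negative vector of length N")
    if (abs(sum(weights) - 1) > 1e-9)
        stop("weights must sum to 1 (got ", format(sum(weights)), ")")
    if (!(u2 >= 0 && u2 < u1 && u1 <= 100))
        stop("thresholds must satisfy 0 <= u2 < u1 <= 100")
    if (maxBpLength < 1) stop("maxBpLength must be positive")
    if (consensusThreshold <= 0 || consensusThreshold > 1)
        stop("consensusThreshold must be in (0, 1]")
    if (match <= 0 || mismatch >= 0)
        stop("expect match > 0 and mismatch < 0")
    if (gapOpen < 0 || gapExtend < 0)
        stop("gap penalties are magnitudes and must be >= 0")
    if (partnerSlack < 0) stop("partnerSlack must be >= 0")
    structure(list(offset = offset, N = N, weights = weights,
                   normalize = normalize, u1 = u1, u2 = u2,
                   maxBpLength = as.integer(maxBpLength),
                   consensusThreshold = consensusThreshold,
                   match = match, mismatch = mismatch,
                   gapOpen = gapOpen, gapExtend = gapExtend,
                   partnerSlack = as.integer(partnerSlack),
                   dpGuard = dpGuard),
              class = "refineParams")
}
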