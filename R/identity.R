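#' Project a match vector onto branch coordinates
#'
#' Alignment columns that are gaps in the branch sequence have no coordinate
#' on the branch axis; dropping them makes every projected vector of one run
#' exactly \code{roi_length} long, so profiles from different virtual blocks
#' are directly comparable position by position.
#'
#' @param matchVec integer 0/1 vector over alignment columns.
#' @param alignedBranch the gapped branch-sequence string of the same
#'   alignment.
#' @return integer 0/1 vector of the ungapped branch length.
#' @examples
#' projectToBranch(c(1L, 0L, 1L), "A-C")
#' @export
projectToBranch <- function(matchVec, alignedBranch) {
    chars <- strsplit(alignedBranch, "", fixed = TRUE)[[1L]]
    if (length(chars) != length(matchVec))
        stop("match vector and aligned branch string differ in length")
    keep <- chars != "-"
    if (!any(keep)) stop("branch sequence is all gaps")
    matchVec[keep]
}

#' Single-scale sliding identity
#'
#' Sliding mean of a binary match vector with half-window \code{i} (window
#' width 2i+1), computed in linear time via prefix sums. At the edges the
#' window is clamped to the vector and the divisor is the actual window
#' size, so the output always has the input's full length.
#'
#' @param v integer/numeric 0/1 vector.
#' @param i half-window, >= 1; the vector must be longer than 2i.
#' @return numeric vector in [0,1] of the same length as \code{v}.
#' @examples
#' slidingIdentity(c(0, 1, 0, 1, 0), 1)
#' @export
slidingIdentity <- function(v, i) {
    i <- as.integer(i)
    L <- length(v)
    if (i < 1L) stop("half-window must be >= 1")
    if (L <= 2L * i) stop("vector of length ", L,
                          " too short for half-window ", i)
    cs <- c(0, cumsum(as.numeric(v)))
    x <- seq_len(L)
    lo <- pmax(1L, x - i)
    hi <- pmin(L, x + i)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Multi-scale identity vector
#'
#' Weighted bank of box filters over a projected match vector: scales
#' i = 1..N (window width 2i+1) are each averaged by [slidingIdentity()] and
#' combined with weights summing to 1, then rescaled to a 0-100 identity
#' percentage. Small scales capture high-frequency identity changes, large
#' scales the smooth trend; the mixture responds to transitions at every
#' frequency at once. Positions closer than 2N+1 to either edge carry
#' incomplete largest windows (\code{edge_valid} attribute); the ROI offset
#' guarantees the informative region lies inside them.
#'
#' @param v integer/numeric 0/1 vector of length > 2N.
#' @param params a [refineParams()] list (fields N, weights).
#' @return numeric vector in [0,100] with attribute \code{edge_valid} =
#'   c(first, last) fully-supported index.
#' @export
identityVector <- function(v, params = refineParams()) {
    N <- params$N
    w <- params$weights
    if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
    L <- length(v)
    out <- numeric(L)
    for (i in seq_len(N)) {
        if (w[i] == 0) next
        out <- out + w[i] * slidingIdentity(v, i)
    }
    out <- 100 * out
    attr(out, "edge_valid") <- c(min(2L * N + 1L, L), max(L - 2L * N, 1L))
    out
}

#' Normalize an identity vector
#'
#' Profiles are compared by difference, so each must span the same dynamic
#' range regardless of its absolute identity level. \code{"quantile"} (the
#' default) anchors the profile on robust reference levels and clamps to
#' [0,100]. The construction of the ROI fixes where each profile must be
#' high and where it must be low: the offset padding puts block A's plateau
#' at the ROI start and block B's at the ROI end (each block's opposite end
#' is then guaranteed background), and the consensus profile is high over
#' the repeat span and background outside it. The high anchor is the
#' median over the supplied plateau zone (95th percentile if none), the
#' low anchor the median over the supplied background zone (10th
#' percentile if none); global quantiles alone are fragile because the
#' plateau/background fractions of the ROI vary freely with junction
#' geometry. Plain min-max anchoring is kept as \code{"minmax"}; because
#' the profiles are sliding means, their extremes are single fluctuation
#' points, so min-max leaves the background floor well above zero.
#' \code{"none"} leaves values untouched. A profile whose anchors
#' coincide carries no transition information and maps to all zeros with a
#' warning.
#'
#' @param values numeric identity vector.
#' @param mode "quantile", "minmax" or "none".
#' @param plateau optional integer indices of the zone known to lie inside
#'   the profile's own high-identity element (used only by "quantile").
#' @param background optional integer indices of the zone known to lie
#'   outside it (used only by "quantile").
#' @return numeric vector in [0,100] (attributes preserved).
#' @export
normalizeIdentity <- function(values, mode = c("quantile", "minmax", "none"),
                              plateau = NULL, background = NULL) {
    mode <- match.arg(mode)
    if (length(values) == 0L) stop("empty identity vector")
    if (mode == "none") return(values)
    a <- attributes(values)
    if (mode == "minmax") {
        anchors <- range(values)
    } else {
        hi <- if (is.null(plateau)) stats::quantile(values, 0.95, names = FALSE)
              else stats::median(values[plateau])
        lo <- if (is.null(background))
                  stats::quantile(values, 0.10, names = FALSE)
              else stats::median(values[background])
        anchors <- c(lo, hi)
    }
    if (anchors[2] <= anchors[1]) {
        warning("flat identity vector (no plateau above background); ",
                "normalized to all zeros")
        out <- rep(0, length(values))
    } else {
        out <- 100 * (values - anchors[1]) / (anchors[2] - anchors[1])
        out <- pmin(100, pmax(0, out))
    }
    attributes(out) <- a
    out
}
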