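#' Absolute difference of two identity profiles
#'
#' The finite-state machine's input signal: the elementwise absolute
#' difference of two normalized identity vectors. High values mean the two
#' profiles disagree (exactly one element is locally similar to its
#' partner); the low dips between high plateaus are the candidate
#' breakpoint transitions.
#'
#' @param left,right equal-length numeric vectors in [0,100] (already
#'   normalized).
#' @param label optional label naming the pair (e.g. "A|consensus").
#' @return numeric vector in [0,100] with attribute \code{pair_label}.
#' @export
differenceVector <- function(left, right, label = NULL) {
    if (length(left) != length(right))
        stop("identity vectors differ in length")
    out <- abs(as.numeric(left) - as.numeric(right))
    attr(out, "pair_label") <- label
    out
}

#' Detect breakpoint transitions with the six-state FSM
#'
#' Left-to-right scan of the difference signal with two thresholds
#' \code{u1} (high) and \code{u2} (low), both inclusive. States 1-3 locate
#' the breakpoint start: seek the first value >= u1, track the last index
#' still >= u1 while the signal stays in the descending band, and when the
#' signal reaches <= u2 record that last-high index as the start. States
#' 4-6 mirror them for the end: stay through the low region and ascending
#' band, and the first index back at >= u1 closes the pair. The scan then
#' resumes in the high-plateau state, so several dips yield several pairs
#' in scan order. A dip still open when the signal ends (never regaining
#' u1) is discarded with a warning.
#'
#' @param values numeric signal in [0,100].
#' @param u1,u2 thresholds, \code{0 <= u2 < u1 <= 100}.
#' @return integer matrix with columns \code{start}, \code{end} (1-based
#'   indices into \code{values}); zero rows if no complete transition.
#' @examples
#' sig <- c(100, 100, 90, 80, 60, 40, 20, 10, 20, 40, 60, 80, 100)
#' detectTransitions(sig, 80, 20)   # one pair: indices 4 and 12
#' @export
detectTransitions <- function(values, u1 = 80, u2 = 20) {
    if (!(u2 >= 0 && u2 < u1 && u1 <= 100))
        stop("thresholds must satisfy 0 <= u2 < u1 <= 100")
    v <- as.numeric(values)
    starts <- integer(0); ends <- integer(0)
    state <- 1L       # 1 seek-high, 2 plateau/descend, 3 in-dip/ascend
    lastHigh <- NA_integer_
    pendingStart <- NA_integer_
    for (k in seq_along(v)) {
        x <- v[k]
        if (state == 1L) {
            if (x >= u1) { state <- 2L; lastHigh <- k }
        } else if (state == 2L) {
            if (x >= u1) {
                lastHigh <- k
            } else if (x <= u2) {
                pendingStart <- lastHigh
                state <- 3L
            }
            # u2 < x < u1: descending band, keep lastHigh
        } else {
            if (x >= u1) {
                starts <- c(starts, pendingStart)
                ends <- c(ends, k)
                pendingStart <- NA_integer_
                state <- 2L
                lastHigh <- k
            }
            # x <= u2 or in the ascending band: stay
        }
    }
    if (state == 3L)
        warning("dip open at scan end (signal never regained u1); discarded")
    cbind(start = starts, end = ends)
}

#' Map FSM index pairs to genomic breakpoints
#'
#' Adds the ROI branch start to the (1-based) signal indices, drops any
#' breakpoint longer than \code{maxBpLength} with a warning (a transition
#' that wide is treated as a failed detection, not truncated to an
#' unobserved boundary), and labels each breakpoint with its junction. The
#' breakpoint length convention is \code{end - start}: start is the last
#' coordinate still belonging to the left element and end the first
#' belonging to the right, so a sharp transition gives length 0 or 1 (a
#' breakpoint may be a point or a region).
#'
#' @param pairs integer matrix from [detectTransitions()].
#' @param roi ROI list from [computeROI()].
#' @param seqName sequence identifier for the emitted intervals.
#' @param maxBpLength drop threshold in nt.
#' @param junction optional junction label(s).
#' @return data.frame with columns sequence, start, end, length, junction.
#' @export
indicesToBreakpoints <- function(pairs, roi, seqName,
                                 maxBpLength = 5000L, junction = NA) {
    if (is.null(pairs) || nrow(pairs) == 0L)
        return(data.frame(sequence = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          junction = character(0)))
    start <- roi$start + pairs[, "start"] - 1L
    end <- roi$start + pairs[, "end"] - 1L
    len <- end - start
    keep <- len <= maxBpLength
    if (any(!keep))
        warning(sum(!keep), " breakpoint(s) longer than ", maxBpLength,
                " nt discarded as spurious")
    data.frame(sequence = rep_len(seqName, sum(keep)),
               start = unname(start[keep]), end = unname(end[keep]),
               length = unname(len[keep]),
               junction = rep_len(as.character(junction),
                                  nrow(pairs))[keep])
}
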