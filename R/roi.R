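#' Compute the region of interest spanning a junction
#'
#' The region of interest (ROI) on one branch axis runs from just before the
#' first border involved in the junction to just after the last, padded by
#' \code{offset} nucleotides on each side:
#' \deqn{ROI_{start} = \min(A_{end}, B_{start}, repeat\ starts) - offset}
#' \deqn{ROI_{end}   = \max(A_{end}, B_{start}, repeat\ ends) + offset}
#' With no repeats the repeat terms are omitted. The padding guarantees that
#' every virtual block begins and ends inside genuinely homologous sequence,
#' so every difference signal starts and ends on a high plateau. The ROI is
#' clamped to the sequence bounds; clamping is recorded.
#'
#' @param a,b single-row block records (lists or 1-row data.frames with
#'   x_start/x_end/y_start/y_end); \code{a} must precede \code{b} on the
#'   branch axis.
#' @param repeats data.frame of repeat records between \code{a} and \code{b}
#'   (may have zero rows).
#' @param offset padding in nt; must exceed the identity half-window N.
#' @param branch "x" or "y": which axis the ROI lives on.
#' @param seqLength length of the branch sequence, used for clamping.
#' @return a list with \code{start}, \code{end}, \code{length},
#'   \code{offset}, \code{branch} and \code{clamped} (logical).
#' @examples
#' a <- list(x_start = 500, x_end = 1000, y_start = 500, y_end = 1000)
#' b <- list(x_start = 1200, x_end = 2000, y_start = 1200, y_end = 2000)
#' computeROI(a, b, offset = 100, branch = "x", seqLength = 5000)
#' @export
computeROI <- function(a, b, repeats = NULL, offset = 100L,
                       branch = c("x", "y"), seqLength = Inf) {
    branch <- match.arg(branch)
    sc <- paste0(branch, "_start"); ec <- paste0(branch, "_end")
    aEnd <- as.integer(a[[ec]]); bStart <- as.integer(b[[sc]])
    if (aEnd > bStart)
        stop("block 'a' must precede block 'b' on the ", branch,
             " axis (a ", ec, " = ", aEnd, " > b ", sc, " = ", bStart, ")")
    lo <- c(aEnd, bStart); hi <- c(aEnd, bStart)
    if (!is.null(repeats) && nrow(as.data.frame(repeats)) > 0L) {
        repeats <- as.data.frame(repeats)
        lo <- c(lo, repeats[[sc]])
        hi <- c(hi, repeats[[ec]])
    }
    start <- min(lo) - offset
    end <- max(hi) + offset
    clamped <- FALSE
    if (start < 1L) { start <- 1L; clamped <- TRUE }
    if (end > seqLength) { end <- as.integer(seqLength); clamped <- TRUE }
    if (clamped)
        warning("ROI clamped to [1, ", seqLength, "] on branch ", branch,
                "; the boundary plateau may be shortened")
    if (start >= end) stop("degenerate ROI on branch ", branch)
    list(start = as.integer(start), end = as.integer(end),
         length = as.integer(end - start + 1L),
         offset = as.integer(offset), branch = branch, clamped = clamped)
}

#' Stretch or trim a block into a virtual block covering the ROI
#'
#' A virtual block takes the ROI bounds on the branch axis and shifts its
#' partner-axis interval by the same signed extension amounts:
#' \deqn{\alpha_L = block_{start} - ROI_{start}, \quad
#'       \alpha_R = ROI_{end} - block_{end}}
#' (positive when extending, negative when trimming). For a forward-strand
#' block the partner interval becomes
#' \code{[y_start - alpha_L, y_end + alpha_R]}. For a reverse-strand block
#' the alignment runs antidiagonally, so a left extension on the branch axis
#' extends the partner interval on the right and vice versa:
#' \code{[y_start - alpha_R, y_end + alpha_L]}. Partner coordinates are
#' clamped to the partner sequence bounds.
#'
#' @param block single-row record (list or 1-row data.frame) with
#'   x_start/x_end/y_start/y_end and strand ("f"/"r").
#' @param roi an ROI as returned by [computeROI()].
#' @param branch "x" or "y": the ROI's axis.
#' @param partnerLength length of the partner sequence, for clamping.
#' @param slack extra nucleotides added on both ends of the partner
#'   interval. The alpha shifts anchor the partner window on the block's
#'   far border, so any error in the input borders displaces the window
#'   off the true alignment diagonal by the same amount; the slack keeps
#'   the diagonal inside the window when borders are only approximate.
#'   Default 0 (the exact stretched interval).
#' @return a list with the virtual branch interval (\code{v_start},
#'   \code{v_end} — identical to the ROI for every block of one run), the
#'   shifted partner interval (\code{p_start}, \code{p_end}),
#'   \code{alpha_l}, \code{alpha_r} and \code{strand}.
#' @export
makeVirtual <- function(block, roi, branch = c("x", "y"),
                        partnerLength = Inf, slack = 0L) {
    branch <- match.arg(branch)
    stopifnot(roi$branch == branch)
    sc <- paste0(branch, "_start"); ec <- paste0(branch, "_end")
    partner <- if (branch == "x") "y" else "x"
    psc <- paste0(partner, "_start"); pec <- paste0(partner, "_end")
    alphaL <- as.integer(block[[sc]]) - roi$start
    alphaR <- roi$end - as.integer(block[[ec]])
    strand <- as.character(block[["strand"]])
    if (!strand %in% c("f", "r")) stop("strand must be 'f' or 'r'")
    if (strand == "f") {
        pStart <- as.integer(block[[psc]]) - alphaL
        pEnd <- as.integer(block[[pec]]) + alphaR
    } else {
        pStart <- as.integer(block[[psc]]) - alphaR
        pEnd <- as.integer(block[[pec]]) + alphaL
    }
    pStart <- max(1L, pStart - as.integer(slack))
    pEnd <- min(as.integer(min(partnerLength, .Machine$integer.max)),
                pEnd + as.integer(slack))
    if (pStart > pEnd)
        stop("virtual block empty on the partner axis after clamping")
    list(v_start = roi$start, v_end = roi$end,
         p_start = pStart, p_end = pEnd,
         alpha_l = alphaL, alpha_r = alphaR, strand = strand)
}
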