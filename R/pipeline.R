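#' Refine one junction on one branch axis
#'
#' Runs the complete single-branch chain for the junction between two
#' adjacent blocks: ROI construction, virtualization of both blocks and any
#' intervening repeats, local-mode alignment of each virtual block
#' (reverse-strand partners are reverse-complemented; see [nwAlign()] for
#' why virtual windows are aligned locally), projection onto
#' branch coordinates, multi-scale identity profiles, the repeat consensus
#' profile when repeats are present, difference signal(s) and the FSM scan.
#' With repeats two signals are scanned independently (block A vs
#' consensus for the left junction side, consensus vs block B for the
#' right); without repeats a single A-vs-B signal is scanned.
#'
#' Refined coordinates follow the shared-endpoint convention: the left
#' block's refined end is the breakpoint start, the next element's refined
#' start is the breakpoint end. A junction side whose signal yields no
#' complete transition (or only transitions over the size cap) is flagged
#' unresolved and its border left untouched; this is a reported condition,
#' not an error.
#'
#' @param branchSeq,partnerSeq [GenomeSequence-class] objects: the branch
#'   axis sequence and its partner.
#' @param a,b single-row block records (lists/1-row data.frames);
#'   \code{a} must precede \code{b} on the branch axis.
#' @param repeats data.frame of repeat records lying in the junction (zero
#'   rows or NULL for none).
#' @param branch "x" or "y".
#' @param params a [refineParams()] list.
#' @return a list with elements \code{roi}, \code{bps} (data.frame of kept
#'   breakpoints with side labels), \code{refined} (a_end, rep_start,
#'   rep_end, b_start; NA where unresolved), \code{resolved} (logical for
#'   the a and b side), \code{signals}, \code{identity} and
#'   \code{nRepeats}.
#' @export
refineBranch <- function(branchSeq, partnerSeq, a, b, repeats = NULL,
                         branch = c("x", "y"), params = refineParams()) {
    branch <- match.arg(branch)
    a <- as.list(a); b <- as.list(b)
    repDf <- if (is.null(repeats)) NULL else as.data.frame(repeats)
    nRep <- if (is.null(repDf)) 0L else nrow(repDf)
    roi <- computeROI(a, b, repDf, params$offset, branch,
                      seqLength = length(branchSeq))
    branchStr <- residues(branchSeq)
    partnerStr <- residues(partnerSeq)

    # local alignment: the virtual windows are oversized approximations, so
    # their non-homologous margins are left uncovered rather than forced
    # into the alignment; uncovered branch positions contribute zeros.
    profileOf <- function(rec) {
        v <- makeVirtual(rec, roi, branch, partnerLength = length(partnerSeq),
                         slack = params$partnerSlack)
        bs <- substring(branchStr, v$v_start, v$v_end)
        ps <- substring(partnerStr, v$p_start, v$p_end)
        if (v$strand == "r") ps <- revComp(ps)
        aln <- nwAlign(bs, ps, params, type = "local")
        proj <- integer(roi$length)
        if (grepl("[^-]", aln$aligned_x)) {
            core <- projectToBranch(aln$match_vector, aln$aligned_x)
            proj[seq(aln$x_range[1L], aln$x_range[2L])] <- core
        }
        list(virtual = v, proj = proj)
    }

    pA <- profileOf(a)
    pB <- profileOf(b)
    # the offset guarantees each block profile a plateau at its own ROI end
    # and background at the opposite end
    headZone <- seq_len(params$offset)
    tailZone <- seq(roi$length - params$offset + 1L, roi$length)
    iA <- normalizeIdentity(identityVector(pA$proj, params), params$normalize,
                            plateau = headZone, background = tailZone)
    iB <- normalizeIdentity(identityVector(pB$proj, params), params$normalize,
                            plateau = tailZone, background = headZone)

    sc <- paste0(branch, "_start"); ec <- paste0(branch, "_end")
    signals <- list()
    cons <- NULL
    if (nRep > 0L) {
        projReps <- vector("list", nRep)
        spans <- vector("list", nRep)
        for (k in seq_len(nRep)) {
            pr <- profileOf(as.list(repDf[k, , drop = FALSE]))
            projReps[[k]] <- pr$proj
            spans[[k]] <- c(repDf[[sc]][k] - roi$start + 1L,
                            repDf[[ec]][k] - roi$start + 1L)
        }
        cons <- consensusVectors(projReps, spans, params)
        signals$a_side <- differenceVector(iA, cons$v_ci, "A|consensus")
        signals$b_side <- differenceVector(cons$v_ci, iB, "consensus|B")
    } else {
        signals$ab <- differenceVector(iA, iB, "A|B")
    }

    bps <- do.call(rbind, lapply(names(signals), function(nm) {
        pairs <- detectTransitions(signals[[nm]], params$u1, params$u2)
        out <- indicesToBreakpoints(pairs, roi, seqId(branchSeq),
                                    params$maxBpLength, junction = nm)
        out
    }))
    if (is.null(bps))
        bps <- data.frame(sequence = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          junction = character(0))

    refined <- list(a_end = NA_integer_, rep_start = NA_integer_,
                    rep_end = NA_integer_, b_start = NA_integer_)
    resolved <- c(a = FALSE, b = FALSE)
    if (nRep > 0L) {
        aside <- bps[bps$junction == "a_side", , drop = FALSE]
        bside <- bps[bps$junction == "b_side", , drop = FALSE]
        if (nrow(aside) > 0L) {
            refined$a_end <- aside$start[1L]
            refined$rep_start <- aside$end[1L]
            resolved["a"] <- TRUE
        }
        if (nrow(bside) > 0L) {
            refined$rep_end <- bside$start[nrow(bside)]
            refined$b_start <- bside$end[nrow(bside)]
            resolved["b"] <- TRUE
        }
    } else if (nrow(bps) > 0L) {
        refined$a_end <- bps$start[1L]
        refined$b_start <- bps$end[nrow(bps)]
        resolved[c("a", "b")] <- TRUE
    }

    list(branch = branch, roi = roi, bps = bps, refined = refined,
         resolved = resolved, signals = signals,
         identity = list(a = iA, b = iB,
                         consensus = if (!is.null(cons)) cons$v_ci),
         nRepeats = nRep)
}

# repeats overlapping the closed junction interval [aEnd, bStart] on an axis
.junctionRepeats <- function(repDf, a, b, branch) {
    if (is.null(repDf) || nrow(repDf) == 0L) return(NULL)
    sc <- paste0(branch, "_start"); ec <- paste0(branch, "_end")
    aEnd <- as.integer(a[[ec]]); bStart <- as.integer(b[[sc]])
    keep <- repDf[[ec]] >= aEnd & repDf[[sc]] <= bStart
    if (!any(keep)) return(NULL)
    repDf[keep, , drop = FALSE]
}

#' Combine the X- and Y-branch results of one junction
#'
#' The two branch refinements are independent; the combined record takes
#' its x coordinates from the X branch and its y coordinates from the Y
#' branch. An unresolved branch coordinate keeps its "before" value and
#' flags the record "partial"; if neither branch resolved, "unresolved".
#'
#' @param xRes,yRes branch results from [refineBranch()].
#' @param a,b the single-row block records, ordered by x (a precedes b).
#' @param aIsAy logical: is \code{a} also the preceding block on the Y axis?
#' @return list with \code{a_after}, \code{b_after} (named coordinate
#'   lists with flags) and \code{rep_after} (refined repeat-cluster borders
#'   per axis).
#' @export
combineBranches <- function(xRes, yRes, a, b, aIsAy = TRUE) {
    a <- as.list(a); b <- as.list(b)
    aAfter <- list(x_end = if (xRes$resolved[["a"]]) xRes$refined$a_end
                            else as.integer(a$x_end))
    bAfter <- list(x_start = if (xRes$resolved[["b"]]) xRes$refined$b_start
                             else as.integer(b$x_start))
    if (aIsAy) {
        aAfter$y_end <- if (yRes$resolved[["a"]]) yRes$refined$a_end
                        else as.integer(a$y_end)
        bAfter$y_start <- if (yRes$resolved[["b"]]) yRes$refined$b_start
                          else as.integer(b$y_start)
        aResolved <- c(xRes$resolved[["a"]], yRes$resolved[["a"]])
        bResolved <- c(xRes$resolved[["b"]], yRes$resolved[["b"]])
    } else {
        # b precedes a on the Y axis: the Y junction refines b's y_end and
        # a's y_start
        bAfter$y_end <- if (yRes$resolved[["a"]]) yRes$refined$a_end
                        else as.integer(b$y_end)
        aAfter$y_start <- if (yRes$resolved[["b"]]) yRes$refined$b_start
                          else as.integer(a$y_start)
        aResolved <- c(xRes$resolved[["a"]], yRes$resolved[["b"]])
        bResolved <- c(xRes$resolved[["b"]], yRes$resolved[["a"]])
    }
    flagOf <- function(r) if (all(r)) "resolved"
                          else if (any(r)) "partial" else "unresolved"
    aAfter$flag <- flagOf(aResolved)
    bAfter$flag <- flagOf(bResolved)
    list(a_after = aAfter, b_after = bAfter,
         rep_after = list(
             x_start = xRes$refined$rep_start, x_end = xRes$refined$rep_end,
             y_start = yRes$refined$rep_start, y_end = yRes$refined$rep_end))
}

#' Extension and identity metrics of a refined block
#'
#' Percent change of span on each axis
#' (\code{100 * |span_after - span_before| / span_before}) and the percent
#' identity of a fresh end-to-end alignment of the refined block
#' (matches / alignment length * 100; the reported \code{length} is the
#' alignment length, which can exceed the coordinate span when the
#' alignment carries gaps). Blocks whose DP matrix would exceed the guard
#' are aligned in successive proportional windows of 5 kb and the match
#' counts aggregated.
#'
#' @param before,after single-row records with x/y coordinates (and strand
#'   in \code{before}).
#' @param xSeq,ySeq [GenomeSequence-class] objects.
#' @param params a [refineParams()] list.
#' @return list with delta_x_pct, delta_y_pct, identity_pct, length.
#' @export
computeMetrics <- function(before, after, xSeq, ySeq,
                           params = refineParams()) {
    before <- as.list(before); after <- as.list(after)
    spanB <- function(p, rec) as.integer(rec[[paste0(p, "_end")]]) -
        as.integer(rec[[paste0(p, "_start")]]) + 1L
    dxy <- vapply(c("x", "y"), function(p)
        100 * abs(spanB(p, after) - spanB(p, before)) / spanB(p, before),
        numeric(1))
    xs <- substring(residues(xSeq), after$x_start, after$x_end)
    ys <- substring(residues(ySeq), after$y_start, after$y_end)
    if (as.character(before$strand) == "r") ys <- revComp(ys)
    stats <- .alignmentIdentity(xs, ys, params)
    list(delta_x_pct = unname(dxy["x"]), delta_y_pct = unname(dxy["y"]),
         identity_pct = stats$identity_pct, length = stats$length)
}

.alignmentIdentity <- function(xs, ys, params, chunk = 5000L) {
    nx <- nchar(xs); ny <- nchar(ys)
    if (as.numeric(nx) * ny <= params$dpGuard) {
        aln <- nwAlign(xs, ys, params)
        L <- length(aln$match_vector)
        return(list(identity_pct = 100 * sum(aln$match_vector) / L,
                    length = L))
    }
    nChunks <- ceiling(max(nx, ny) / chunk)
    bx <- round(seq(0L, nx, length.out = nChunks + 1L))
    by <- round(seq(0L, ny, length.out = nChunks + 1L))
    matches <- 0; alen <- 0
    for (k in seq_len(nChunks)) {
        cx <- substring(xs, bx[k] + 1L, bx[k + 1L])
        cy <- substring(ys, by[k] + 1L, by[k + 1L])
        if (nchar(cx) == 0L || nchar(cy) == 0L) next
        aln <- nwAlign(cx, cy, params)
        matches <- matches + sum(aln$match_vector)
        alen <- alen + length(aln$match_vector)
    }
    list(identity_pct = 100 * matches / alen, length = alen)
}

#' Refine every junction of an ordered chain of CSBs
#'
#' Orders the blocks along the X axis and refines each adjacent pair's
#' junction on both branch axes, producing a combined
#' [RefinementResult-class]: refined coordinates with extension/identity
#' metrics, all breakpoints, PRASB control intervals and inter-breakpoint
#' gaps. Borders not adjacent to a processed junction are never touched.
#'
#' @param xSeq,ySeq [GenomeSequence-class] objects for sequences X and Y.
#' @param csbs a [BlockSet-class] of kind "csb" with at least two records.
#' @param repeats optional [BlockSet-class] of kind "repeat"; each junction
#'   uses only the repeats lying in it.
#' @param params a [refineParams()] list.
#' @param metrics logical: compute per-block identity metrics (requires
#'   aligning every refined block; disable for speed).
#' @return a [RefinementResult-class].
#' @export
refineChain <- function(xSeq, ySeq, csbs, repeats = NULL,
                        params = refineParams(), metrics = TRUE) {
    stopifnot(is(csbs, "BlockSet"), blockKind(csbs) == "csb")
    df <- blockRecords(csbs)
    if (nrow(df) < 2L) stop("need at least two CSB records")
    ord <- order(df$x_start)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    repDf <- if (is.null(repeats)) NULL else blockRecords(repeats)

    warnings <- character(0)
    collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    })

    after <- df[, c("x_start", "x_end", "y_start", "y_end")]
    flags <- rep("untouched", nrow(df))
    bpAll <- list(); repAfter <- list(); diagnostics <- list()

    for (i in seq_len(nrow(df) - 1L)) {
        a <- as.list(df[i, , drop = FALSE])
        b <- as.list(df[i + 1L, , drop = FALSE])
        aIsAy <- a$y_start <= b$y_start
        aY <- if (aIsAy) a else b
        bY <- if (aIsAy) b else a
        repsX <- .junctionRepeats(repDf, a, b, "x")
        repsY <- .junctionRepeats(repDf, aY, bY, "y")
        xRes <- collect(refineBranch(xSeq, ySeq, a, b, repsX, "x", params))
        yRes <- collect(refineBranch(ySeq, xSeq, aY, bY, repsY, "y", params))
        comb <- combineBranches(xRes, yRes, a, b, aIsAy)

        after$x_end[i] <- comb$a_after$x_end
        after$x_start[i + 1L] <- comb$b_after$x_start
        if (!is.null(comb$a_after$y_end)) after$y_end[i] <- comb$a_after$y_end
        if (!is.null(comb$a_after$y_start))
            after$y_start[i] <- comb$a_after$y_start
        if (!is.null(comb$b_after$y_start))
            after$y_start[i + 1L] <- comb$b_after$y_start
        if (!is.null(comb$b_after$y_end))
            after$y_end[i + 1L] <- comb$b_after$y_end
        flags[i] <- .mergeFlag(flags[i], comb$a_after$flag)
        flags[i + 1L] <- .mergeFlag(flags[i + 1L], comb$b_after$flag)

        addAxis <- function(d, ax) { d$axis <- rep_len(ax, nrow(d)); d }
        bp <- rbind(addAxis(xRes$bps, "x"), addAxis(yRes$bps, "y"))
        if (nrow(bp) > 0L) {
            bp$pair_id <- i
            # far borders of the adjacent blocks, for PRASB truncation
            yFarLeft <- if (aIsAy) after$y_start[i] else after$y_start[i + 1L]
            yFarRight <- if (aIsAy) after$y_end[i + 1L] else after$y_end[i]
            bp$far_left <- ifelse(bp$axis == "x", after$x_start[i], yFarLeft)
            bp$far_right <- ifelse(bp$axis == "x", after$x_end[i + 1L],
                                   yFarRight)
            bpAll[[length(bpAll) + 1L]] <- bp
        }
        repAfter[[i]] <- comb$rep_after
        diagnostics[[paste0("junction_", i)]] <-
            list(x = xRes[c("roi", "signals", "identity", "nRepeats")],
                 y = yRes[c("roi", "signals", "identity", "nRepeats")])
    }

    bpDf <- if (length(bpAll)) do.call(rbind, bpAll) else
        data.frame(sequence = character(0), start = integer(0),
                   end = integer(0), length = integer(0),
                   junction = character(0), axis = character(0),
                   pair_id = integer(0), far_left = integer(0),
                   far_right = integer(0))

    blocks <- data.frame(
        block = seq_len(nrow(df)),
        strand = df$strand,
        x_start_before = df$x_start, x_end_before = df$x_end,
        y_start_before = df$y_start, y_end_before = df$y_end,
        x_start_after = after$x_start, x_end_after = after$x_end,
        y_start_after = after$y_start, y_end_after = after$y_end,
        flag = ifelse(flags == "untouched", "resolved", flags))

    blocks$delta_x_pct <- blocks$delta_y_pct <- blocks$identity_pct <-
        blocks$length <- NA_real_
    if (metrics) {
        for (i in seq_len(nrow(df))) {
            m <- collect(computeMetrics(
                df[i, ], list(x_start = after$x_start[i],
                              x_end = after$x_end[i],
                              y_start = after$y_start[i],
                              y_end = after$y_end[i]),
                xSeq, ySeq, params))
            blocks$delta_x_pct[i] <- m$delta_x_pct
            blocks$delta_y_pct[i] <- m$delta_y_pct
            blocks$identity_pct[i] <- m$identity_pct
            blocks$length[i] <- m$length
        }
    }

    repOut <- .refineRepeatTable(repDf, bpDf, repAfter)

    result <- new("RefinementResult",
        blocks = blocks, repeats = repOut,
        breakpoints = .bpGRanges(bpDf), prasb = GRanges(), gaps = GRanges(),
        params = c(unclass(params), list(metrics = metrics)),
        diagnostics = list(junctions = diagnostics, warnings = warnings))
    extractPrasbGap(result)
}

.mergeFlag <- function(old, new) {
    rank <- c(untouched = 0, resolved = 1, partial = 2, unresolved = 3)
    if (rank[new] >= rank[old]) new else old
}

.refineRepeatTable <- function(repDf, bpDf, repAfter) {
    if (is.null(repDf) || nrow(repDf) == 0L)
        return(data.frame())
    out <- repDf
    out$x_start_after <- out$x_start; out$x_end_after <- out$x_end
    out$y_start_after <- out$y_start; out$y_end_after <- out$y_end
    for (ra in repAfter) {
        if (!is.na(ra$x_start)) {
            k <- which.min(abs(out$x_start - ra$x_start))
            out$x_start_after[k] <- ra$x_start
        }
        if (!is.na(ra$x_end)) {
            k <- which.min(abs(out$x_end - ra$x_end))
            out$x_end_after[k] <- ra$x_end
        }
        if (!is.na(ra$y_start)) {
            k <- which.min(abs(out$y_start - ra$y_start))
            out$y_start_after[k] <- ra$y_start
        }
        if (!is.na(ra$y_end)) {
            k <- which.min(abs(out$y_end - ra$y_end))
            out$y_end_after[k] <- ra$y_end
        }
    }
    out
}

.bpGRanges <- function(bpDf) {
    if (nrow(bpDf) == 0L) return(GRanges())
    gr <- GRanges(seqnames = bpDf$sequence,
                  ranges = IRanges(start = bpDf$start, end = bpDf$end))
    mcols(gr)$bp_id <- sprintf("%d.%s%s", bpDf$pair_id,
                               ave(bpDf$start, bpDf$pair_id, bpDf$axis,
                                   FUN = seq_along),
                               bpDf$axis)
    mcols(gr)$bp_length <- bpDf$length
    mcols(gr)$junction <- bpDf$junction
    mcols(gr)$axis <- bpDf$axis
    mcols(gr)$pair_id <- bpDf$pair_id
    mcols(gr)$far_left <- bpDf$far_left
    mcols(gr)$far_right <- bpDf$far_right
    gr
}

#' Derive PRASB and gap intervals from a result's breakpoints
#'
#' For each breakpoint the PRASB (proportional region of the adjacent
#' synteny block) is the equally-long stretch of the adjacent refined block
#' immediately inside its refined border: left of the breakpoint start for
#' a block|repeat (or lone block|block) transition, right of the breakpoint
#' end for a repeat|block transition. A PRASB that would run past the
#' block's other border is truncated and flagged. The gap is the region
#' strictly between the two breakpoints of one junction on the same
#' sequence (length 0 when they abut). All intervals use the
#' shared-endpoint convention (length = end - start).
#'
#' @param result a [RefinementResult-class] with breakpoints.
#' @return the result with the \code{prasb} and \code{gaps} slots filled.
#' @export
extractPrasbGap <- function(result) {
    bp <- result@breakpoints
    if (length(bp) == 0L) {
        result@prasb <- GRanges(); result@gaps <- GRanges()
        return(result)
    }
    m <- mcols(bp)
    seqn <- as.character(seqnames(bp))
    pr <- list()
    for (i in seq_along(bp)) {
        len <- m$bp_length[i]
        if (len <= 0L) next
        side <- m$junction[i]
        mk <- function(s, e, far, dirLeft) {
            trunc <- FALSE
            if (dirLeft && !is.na(far) && s < far) { s <- far; trunc <- TRUE }
            if (!dirLeft && !is.na(far) && e > far) { e <- far; trunc <- TRUE }
            if (s > e) return(NULL)
            data.frame(seqn = seqn[i], start = s, end = e,
                       bp_id = m$bp_id[i], prasb_length = e - s,
                       truncated = trunc)
        }
        if (side %in% c("a_side", "ab"))
            pr[[length(pr) + 1L]] <- mk(start(bp)[i] - len, start(bp)[i],
                                        m$far_left[i], TRUE)
        if (side %in% c("b_side", "ab"))
            pr[[length(pr) + 1L]] <- mk(end(bp)[i], end(bp)[i] + len,
                                        m$far_right[i], FALSE)
    }
    result@prasb <- .intervalGRanges(do.call(rbind, pr))

    gp <- list()
    key <- paste(seqn, m$pair_id)
    for (k in unique(key)) {
        idx <- which(key == k)
        if (length(idx) != 2L) next
        idx <- idx[order(start(bp)[idx])]
        g1 <- end(bp)[idx[1L]]; g2 <- start(bp)[idx[2L]]
        if (g2 < g1) next
        gp[[length(gp) + 1L]] <- data.frame(seqn = seqn[idx[1L]], start = g1,
                                            end = g2,
                                            pair_id = m$pair_id[idx[1L]],
                                            gap_length = g2 - g1)
    }
    result@gaps <- .intervalGRanges(do.call(rbind, gp))
    result
}

.intervalGRanges <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(GRanges())
    gr <- GRanges(df$seqn, IRanges(df$start, df$end))
    mcols(gr) <- df[, setdiff(names(df), c("seqn", "start", "end")),
                    drop = FALSE]
    gr
}

#' Refine a single adjacent CSB pair
#'
#' Convenience wrapper around [refineChain()] for exactly two blocks.
#'
#' @inheritParams refineChain
#' @param a,b single-row block records (lists or 1-row data.frames) with
#'   x/y coordinates and strand.
#' @return a [RefinementResult-class].
#' @export
refineCSBPair <- function(xSeq, ySeq, a, b, repeats = NULL,
                          params = refineParams(), metrics = TRUE) {
    df <- rbind(as.data.frame(as.list(a)[c("x_start", "x_end", "y_start",
                                           "y_end", "strand")]),
                as.data.frame(as.list(b)[c("x_start", "x_end", "y_start",
                                           "y_end", "strand")]))
    refineChain(xSeq, ySeq, blockSet(df, "csb"), repeats, params, metrics)
}

#' Check the junction partition property of a result
#'
#' For every junction and axis with both sides resolved, verifies the
#' ordering \code{block end <= BP1 start <= BP1 end <= repeat span <= BP2
#' start <= BP2 end <= next block start} with equality exactly at shared
#' borders (block end == BP start, BP end == next element start).
#'
#' @param result a [RefinementResult-class].
#' @return TRUE if the partition holds, otherwise a character vector of
#'   violations.
#' @export
validatePartition <- function(result) {
    bp <- result@breakpoints
    if (length(bp) == 0L) return(TRUE)
    m <- mcols(bp)
    blocks <- result@blocks
    bad <- character(0)
    for (i in seq_along(bp)) {
        pid <- m$pair_id[i]; axis <- m$axis[i]
        lb <- blocks[pid, ]; rb <- blocks[pid + 1L, ]
        # identify the ordered borders on this axis
        if (axis == "x") {
            lEnd <- lb$x_end_after; rStart <- rb$x_start_after
        } else {
            ys <- sort(c(a = lb$y_end_after, b = rb$y_end_after,
                         a2 = lb$y_start_after, b2 = rb$y_start_after))
            lEnd <- ys[2L]; rStart <- ys[3L]   # junction-facing borders
        }
        s <- start(bp)[i]; e <- end(bp)[i]
        if (s > e) bad <- c(bad, sprintf("bp %s: start > end", m$bp_id[i]))
        if (m$junction[i] %in% c("a_side", "ab") && s != lEnd)
            bad <- c(bad, sprintf(
                "bp %s: start %d != refined left block end %d",
                m$bp_id[i], s, lEnd))
        if (m$junction[i] %in% c("b_side", "ab") && e != rStart)
            bad <- c(bad, sprintf(
                "bp %s: end %d != refined right block start %d",
                m$bp_id[i], e, rStart))
    }
    rp <- result@repeats
    if (nrow(rp) > 0L) {
        for (i in seq_along(bp)) {
            if (m$junction[i] == "a_side") {
                # BP end must be a refined repeat start on this axis
                col <- if (m$axis[i] == "x") "x_start_after" else "y_start_after"
                if (!end(bp)[i] %in% rp[[col]])
                    bad <- c(bad, sprintf(
                        "bp %s: end %d is not a refined repeat start",
                        m$bp_id[i], end(bp)[i]))
            } else if (m$junction[i] == "b_side") {
                col <- if (m$axis[i] == "x") "x_end_after" else "y_end_after"
                if (!start(bp)[i] %in% rp[[col]])
                    bad <- c(bad, sprintf(
                        "bp %s: start %d is not a refined repeat end",
                        m$bp_id[i], start(bp)[i]))
            }
        }
    }
    if (length(bad)) bad else TRUE
}

#' @importFrom stats ave
NULL
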