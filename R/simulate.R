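#' Simulation configuration for synthetic rearranged genome pairs
#'
#' Describes a pair of bacterial-sized genome fragments sharing a conserved
#' backbone, with one implanted inversion whose junctions carry
#' transposon-like repeat clusters, point-mutation divergence and optional
#' short indels. The two genomes carry *different* repeat elements at the
#' same junction (templates are swapped between genomes across the two
#' junctions), mirroring real rearrangement junctions where each genome
#' hosts its own mobile element; each element still has homologous copies
#' in the partner genome, so cross-genome repeat records exist for the
#' consensus step.
#'
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   output.
#' @param backboneLength ancestor length in nt (default 50000).
#' @param gcContent GC fraction (default 0.30, AT-rich as in mycoplasmas).
#' @param inversion c(start, end) of the inverted interval on the ancestor.
#' @param repeatLength repeat template length in nt (default 1500).
#' @param repeatCopies copies per genome per junction (default 2, so each
#'   junction is described by four cross-genome repeat records).
#' @param substitutionRate per-site substitution probability applied
#'   independently to each genome and to each repeat copy (default 0.02).
#' @param indelRate per-site indel event probability (default 0).
#' @param indelGeomP geometric length parameter for indel sizes
#'   (mean 1/p; default 0.5).
#' @param jitter half-width in nt of the uniform perturbation applied to
#'   every emitted block border, so refinement has work to do (default 30).
#' @return a validated list of class "simulationConfig".
#' @export
simulationConfig <- function(seed = 1L, backboneLength = 50000L,
                             gcContent = 0.30,
                             inversion = c(20001L, 30000L),
                             repeatLength = 1500L, repeatCopies = 2L,
                             substitutionRate = 0.02, indelRate = 0,
                             indelGeomP = 0.5, jitter = 30L) {
    stopifnot(backboneLength > 0, gcContent >= 0, gcContent <= 1,
              length(inversion) == 2L,
              substitutionRate >= 0, substitutionRate <= 1,
              indelRate >= 0, indelRate <= 1,
              repeatLength > 0, repeatCopies >= 1, jitter >= 0)
    inversion <- as.integer(inversion)
    if (inversion[1L] <= 1L || inversion[2L] >= backboneLength ||
        inversion[1L] >= inversion[2L])
        stop("inversion interval must lie strictly inside the backbone")
    structure(list(seed = as.integer(seed),
                   backboneLength = as.integer(backboneLength),
                   gcContent = gcContent, inversion = inversion,
                   repeatLength = as.integer(repeatLength),
                   repeatCopies = as.integer(repeatCopies),
                   substitutionRate = substitutionRate,
                   indelRate = indelRate, indelGeomP = indelGeomP,
                   jitter = as.integer(jitter)),
              class = "simulationConfig")
}

.randomBases <- function(n, gc) {
    sample(c("A", "T", "G", "C"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.substitute <- function(ch, rate) {
    if (rate <= 0) return(ch)
    idx <- which(stats::runif(length(ch)) < rate)
    if (length(idx)) {
        alt <- c("A", "C", "G", "T")
        ch[idx] <- vapply(ch[idx], function(b)
            sample(setdiff(alt, b), 1L), character(1))
    }
    ch
}

# Applies substitutions then indel events to a character vector; returns the
# mutated vector plus a coordinate map from original to mutated positions
# (positions inside a deletion map to the last surviving position before it).
.mutateSeq <- function(ch, subRate, indelRate, geomP) {
    ch <- .substitute(ch, subRate)
    L <- length(ch)
    if (indelRate <= 0)
        return(list(ch = ch, map = identity,
                    events = data.frame(pos = integer(0), type = character(0),
                                        len = integer(0))))
    pos <- which(stats::runif(L) < indelRate)
    ev <- data.frame(pos = pos,
                     type = sample(c("ins", "del"), length(pos), TRUE),
                     len = stats::rgeom(length(pos), geomP) + 1L)
    ev <- ev[order(ev$pos), , drop = FALSE]
    # drop deletions overlapping a previous deletion
    lastDelEnd <- 0L; keep <- rep(TRUE, nrow(ev))
    for (k in seq_len(nrow(ev))) {
        if (ev$pos[k] <= lastDelEnd) { keep[k] <- FALSE; next }
        if (ev$type[k] == "del")
            lastDelEnd <- min(L, ev$pos[k] + ev$len[k] - 1L)
    }
    ev <- ev[keep, , drop = FALSE]
    pieces <- list(); prev <- 1L
    for (k in seq_len(nrow(ev))) {
        p <- ev$pos[k]
        if (ev$type[k] == "ins") {
            pieces[[length(pieces) + 1L]] <- ch[prev:p]
            pieces[[length(pieces) + 1L]] <- .randomBases(ev$len[k], 0.5)
            prev <- p + 1L
        } else {
            dEnd <- min(L, p + ev$len[k] - 1L)
            if (p > prev) pieces[[length(pieces) + 1L]] <- ch[prev:(p - 1L)]
            prev <- dEnd + 1L
        }
    }
    if (prev <= L) pieces[[length(pieces) + 1L]] <- ch[prev:L]
    out <- unlist(pieces, use.names = FALSE)
    map <- function(coords) {
        vapply(coords, function(o) {
            shift <- 0L
            for (k in seq_len(nrow(ev))) {
                p <- ev$pos[k]
                if (ev$type[k] == "ins") {
                    if (p < o) shift <- shift + ev$len[k]
                } else {
                    dEnd <- min(L, p + ev$len[k] - 1L)
                    if (dEnd < o) shift <- shift - (dEnd - p + 1L)
                    else if (p <= o) { shift <- shift - (o - p + 1L) }
                }
            }
            as.integer(o + shift)
        }, integer(1))
    }
    list(ch = out, map = map, events = ev)
}

#' Simulate a genome pair with a known inversion and junction repeats
#'
#' Builds a random ancestor backbone, implants one inversion, inserts
#' independently mutated repeat copies at both junctions of both genomes
#' (different templates per genome at the same junction; see
#' [simulationConfig()]), applies genome-wide substitutions and optional
#' indels, and emits the implied CSB and repeat tables; every CSB border is
#' perturbed by the configured uniform jitter (repeat records are
#' alignment-derived intervals with exact extents in real pipelines, so
#' they are emitted unperturbed). The unperturbed truth
#' (junction coordinates, repeat spans, applied jitter) is returned
#' alongside, so border-refinement accuracy can be scored exactly.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements \code{x}, \code{y}
#'   ([GenomeSequence-class]), \code{csb} and \code{repeats}
#'   (perturbed [BlockSet-class] tables), \code{csbTrue},
#'   \code{repeatsTrue} (unperturbed), and \code{truth} (list with
#'   \code{junctions} data.frame (axis, junction, coord), repeat cluster
#'   spans and jitter log).
#' @examples
#' sim <- simulatePair(simulationConfig(seed = 7, backboneLength = 9000,
#'     inversion = c(3001, 6000), repeatLength = 300,
#'     substitutionRate = 0))
#' sim$truth$junctions
#' @export
simulatePair <- function(cfg = simulationConfig()) {
    stopifnot(inherits(cfg, "simulationConfig"))
    set.seed(cfg$seed)
    L <- cfg$backboneLength
    s <- cfg$inversion[1L] - 1L     # last base of block A
    e <- cfg$inversion[2L]          # last base of the inverted interval
    r <- cfg$repeatLength
    cN <- cfg$repeatCopies
    R <- cN * r
    if ((e - s) < 2L * R)
        stop("inversion too short to host the junction repeat clusters")

    backbone <- .randomBases(L, cfg$gcContent)
    t1 <- .randomBases(r, cfg$gcContent)
    t2 <- .randomBases(r, cfg$gcContent)
    copies <- function(tpl) lapply(seq_len(cN), function(i)
        .substitute(tpl, cfg$substitutionRate))
    xJ1 <- copies(t1); xJ2 <- copies(t2)   # genome X elements
    yJ1 <- copies(t2); yJ2 <- copies(t1)   # genome Y elements (swapped)

    inv <- rev(chartr("ACGT", "TGCA", backbone[(s + 1L):e]))
    x0 <- c(backbone[seq_len(s)], unlist(xJ1), backbone[(s + 1L):e],
            unlist(xJ2), backbone[(e + 1L):L])
    y0 <- c(backbone[seq_len(s)], unlist(yJ1), inv,
            unlist(yJ2), backbone[(e + 1L):L])

    mx <- .mutateSeq(x0, cfg$substitutionRate, cfg$indelRate, cfg$indelGeomP)
    my <- .mutateSeq(y0, cfg$substitutionRate, cfg$indelRate, cfg$indelGeomP)

    # junction coordinates in post-insertion space, then through the maps
    jx <- c(`1a` = s, `1b` = s + R, `2a` = e + R, `2b` = e + 2L * R)
    junctions <- rbind(
        data.frame(axis = "x", junction = names(jx), coord = mx$map(jx)),
        data.frame(axis = "y", junction = names(jx), coord = my$map(jx)))

    csbTrue <- data.frame(
        x_start = mx$map(c(1L, s + R + 1L, e + 2L * R + 1L)),
        x_end   = mx$map(c(s, e + R, L + 2L * R)),
        y_start = my$map(c(1L, s + R + 1L, e + 2L * R + 1L)),
        y_end   = my$map(c(s, e + R, L + 2L * R)),
        strand = c("f", "r", "f"))

    # Repeat records as a dotplot of two tandem arrays would yield them:
    # one merged full-length diagonal HSP plus the off-diagonal single-copy
    # HSPs (for cN copies: 1 long + 2*(cN-1) short records per template).
    span <- function(j, i1, i2) c((j + (i1 - 1L) * r + 1L), (j + i2 * r))
    arrayHSPs <- function(jx, jy) {
        rows <- list(data.frame(xs = span(jx, 1L, cN), ys = span(jy, 1L, cN)))
        for (d in seq_len(cN - 1L)) {
            rows[[length(rows) + 1L]] <- data.frame(
                xs = span(jx, 1L + d, cN), ys = span(jy, 1L, cN - d))
            rows[[length(rows) + 1L]] <- data.frame(
                xs = span(jx, 1L, cN - d), ys = span(jy, 1L + d, cN))
        }
        rows
    }
    hspRow <- function(h) data.frame(
        x_start = mx$map(h$xs[1L]), x_end = mx$map(h$xs[2L]),
        y_start = my$map(h$ys[1L]), y_end = my$map(h$ys[2L]), strand = "f")
    repRows <- c(lapply(arrayHSPs(s, e + R), hspRow),        # template 1
                 lapply(arrayHSPs(e + R, s), hspRow))        # template 2
    repTrue <- do.call(rbind, repRows)

    csbPerturbed <- perturbBorders(blockSet(csbTrue, "csb"), cfg$jitter)
    repSet <- blockSet(repTrue, "repeat")

    list(x = new("GenomeSequence", id = "simX",
                 seq = Biostrings::DNAString(paste(mx$ch, collapse = "")),
                 nReplaced = 0L),
         y = new("GenomeSequence", id = "simY",
                 seq = Biostrings::DNAString(paste(my$ch, collapse = "")),
                 nReplaced = 0L),
         csb = csbPerturbed, repeats = repSet,
         csbTrue = blockSet(csbTrue, "csb"),
         repeatsTrue = repSet,
         truth = list(junctions = junctions,
                      repeat_cluster_x = mx$map(c(s + 1L, s + R,
                                                  e + R + 1L, e + 2L * R)),
                      repeat_cluster_y = my$map(c(s + 1L, s + R,
                                                  e + R + 1L, e + 2L * R)),
                      jitter = attr(csbPerturbed, "shifts"),
                      indels_x = mx$events, indels_y = my$events))
}

#' Perturb block borders by a uniform jitter
#'
#' Shifts every border of every record by an independent uniform integer in
#' \code{[-jitter, +jitter]}, then clamps so each interval stays non-empty,
#' coordinates stay >= 1, and records stay non-overlapping in x order. The
#' applied shifts are attached as attribute \code{"shifts"}.
#'
#' @param blocks a [BlockSet-class].
#' @param jitter non-negative half-width in nt; 0 is the identity.
#' @param seed optional seed applied just for this perturbation (when NULL
#'   the current RNG stream is used, as inside [simulatePair()]).
#' @return the perturbed [BlockSet-class] with a \code{"shifts"} attribute.
#' @export
perturbBorders <- function(blocks, jitter, seed = NULL) {
    stopifnot(is(blocks, "BlockSet"), jitter >= 0)
    if (!is.null(seed)) set.seed(seed)
    df <- blockRecords(blocks)
    n <- nrow(df)
    cols <- c("x_start", "x_end", "y_start", "y_end")
    shifts <- matrix(0L, n, 4L, dimnames = list(NULL, cols))
    if (jitter > 0 && n > 0L) {
        shifts[] <- as.integer(sample(seq(-jitter, jitter),
                                      n * 4L, replace = TRUE))
        for (cc in cols) df[[cc]] <- df[[cc]] + shifts[, cc]
        # keep intervals valid
        for (p in c("x", "y")) {
            sc <- paste0(p, "_start"); ec <- paste0(p, "_end")
            df[[sc]] <- pmax(1L, df[[sc]])
            bad <- df[[sc]] > df[[ec]]
            df[[ec]][bad] <- df[[sc]][bad]
            if (blockKind(blocks) == "csb") {
                # no overlap between consecutive blocks in axis order
                # (repeat records may legitimately share spans)
                ordp <- order(df[[sc]])
                for (k in seq_len(n - 1L)) {
                    i <- ordp[k]; j <- ordp[k + 1L]
                    if (df[[ec]][i] >= df[[sc]][j])
                        df[[ec]][i] <- df[[sc]][j] - 1L
                }
            }
        }
    }
    out <- blockSet(df[, setdiff(names(df), "y_swapped")], blockKind(blocks))
    attr(out, "shifts") <- shifts
    out
}
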