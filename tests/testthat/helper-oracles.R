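# Independent reference implementations used as oracles.

# Affine-gap global alignment score by three-state dynamic programming,
# written independently of the package's alignment backend. Gap of length L
# costs go + L * ge.
refAlignScore <- function(x, y, match = 4, mismatch = -4, go = 8, ge = 5) {
    cx <- strsplit(x, "")[[1L]]; cy <- strsplit(y, "")[[1L]]
    nx <- length(cx); ny <- length(cy)
    NEG <- -1e9
    M <- matrix(NEG, nx + 1L, ny + 1L)   # last move diagonal
    X <- matrix(NEG, nx + 1L, ny + 1L)   # last move consumed x (gap in y)
    Y <- matrix(NEG, nx + 1L, ny + 1L)   # last move consumed y (gap in x)
    M[1L, 1L] <- 0
    for (i in seq_len(nx)) X[i + 1L, 1L] <- -(go + ge * i)
    for (j in seq_len(ny)) Y[1L, j + 1L] <- -(go + ge * j)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
        s <- if (cx[i] == cy[j] && cx[i] != "N") match else mismatch
        M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
        X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge, X[i, j + 1L] - ge,
                                 Y[i, j + 1L] - go - ge)
        Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge, X[i + 1L, j] - go - ge,
                                 Y[i + 1L, j] - ge)
    }
    max(M[nx + 1L, ny + 1L], X[nx + 1L, ny + 1L], Y[nx + 1L, ny + 1L])
}

# Brute-force enumeration of every global alignment (for tiny strings),
# cross-validating refAlignScore itself.
enumAlignScore <- function(x, y, match = 4, mismatch = -4, go = 8, ge = 5) {
    cx <- strsplit(x, "")[[1L]]; cy <- strsplit(y, "")[[1L]]
    rec <- function(i, j, last) {
        if (i > length(cx) && j > length(cy)) return(0)
        best <- -Inf
        if (i <= length(cx) && j <= length(cy)) {
            s <- if (cx[i] == cy[j] && cx[i] != "N") match else mismatch
            best <- max(best, s + rec(i + 1L, j + 1L, "m"))
        }
        if (i <= length(cx)) {
            open <- if (last == "x") 0 else go
            best <- max(best, -(open + ge) + rec(i + 1L, j, "x"))
        }
        if (j <= length(cy)) {
            open <- if (last == "y") 0 else go
            best <- max(best, -(open + ge) + rec(i, j + 1L, "y"))
        }
        best
    }
    rec(1L, 1L, "m")
}

# Naive O(L * N) multi-scale identity, the oracle for the prefix-sum path.
naiveIdentityVector <- function(v, N, weights) {
    L <- length(v)
    out <- numeric(L)
    for (x in seq_len(L)) {
        acc <- 0
        for (i in seq_len(N)) {
            lo <- max(1L, x - i); hi <- min(L, x + i)
            acc <- acc + weights[i] * mean(v[lo:hi])
        }
        out[x] <- 100 * acc
    }
    out
}

# Independent transition finder: for every position at or below u2, take the
# last index at or above u1 before it and the first at or above u1 after it;
# complete unique pairs, in scan order.
refTransitions <- function(v, u1, u2) {
    n <- length(v)
    high <- which(v >= u1)
    low <- which(v <= u2)
    if (length(high) == 0L || length(low) == 0L)
        return(cbind(start = integer(0), end = integer(0)))
    prevHigh <- vapply(low, function(i) {
        h <- high[high < i]
        if (length(h)) max(h) else NA_integer_
    }, integer(1))
    nextHigh <- vapply(low, function(i) {
        h <- high[high > i]
        if (length(h)) min(h) else NA_integer_
    }, integer(1))
    keep <- !is.na(prevHigh) & !is.na(nextHigh)
    pairs <- unique(cbind(start = prevHigh[keep], end = nextHigh[keep]))
    pairs[order(pairs[, 1L]), , drop = FALSE]
}

randomDNA <- function(n, gc = 0.4) {
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

# small simulation used across pipeline tests (fast, ~1.5 s to refine)
devSimConfig <- function(seed, ...) {
    simulationConfig(seed = seed, backboneLength = 12000,
                     inversion = c(4001, 9000), repeatLength = 400,
                     repeatCopies = 2, ...)
}

midpointErrors <- function(result, truth) {
    bp <- as.data.frame(breakpoints(result))
    if (nrow(bp) == 0L) return(numeric(0))
    tr <- truth$junctions
    key <- paste(bp$pair_id, substr(bp$junction, 1, 1), bp$axis)
    tkey <- paste(ifelse(tr$junction %in% c("1a", "1b"), 1, 2),
                  ifelse(tr$junction %in% c("1a", "2a"), "a", "b"), tr$axis)
    (bp$start + bp$end) / 2 - tr$coord[match(key, tkey)]
}
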