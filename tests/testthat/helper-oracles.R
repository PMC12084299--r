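# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles share no code with the implementation paths they
# check.

# minimal cell experiment from coordinates and types
makeCellsSCE <- function(x, y, types, roi = "r1", sample = "s1",
                         group = "control", markers = NULL) {
    n <- length(x)
    ids <- sprintf("%s_c%04d", roi, seq_len(n))
    cd <- S4Vectors::DataFrame(
        cell_id = ids, roi_id = rep(roi, n), sample_id = rep(sample, n),
        condition = rep(group, n), x = x, y = y,
        cell_type = types, row.names = ids)
    assay <- if (is.null(markers))
        matrix(0, 1, n, dimnames = list("m1", ids))
    else markers
    SingleCellExperiment::SingleCellExperiment(
        assays = list(raw = assay), colData = cd)
}

# brute-force kNN: per cell, all-pairs distances sorted with explicit
# (distance, index) tie-break
oracleKnn <- function(x, y, k) {
    n <- length(x)
    lapply(seq_len(n), function(i) {
        d <- sqrt((x - x[i])^2 + (y - y[i])^2)
        cand <- setdiff(seq_len(n), i)
        cand[order(d[cand], cand)][seq_len(min(k, n - 1))]
    })
}

# brute-force neighbourhood profile recount from oracle neighbour sets
oracleProfiles <- function(x, y, types, k, includeCenter = TRUE) {
    nb <- oracleKnn(x, y, k)
    levs <- sort(unique(types))
    t(vapply(seq_along(x), function(i) {
        w <- if (includeCenter) c(i, nb[[i]]) else nb[[i]]
        as.numeric(table(factor(types[w], levs))) / length(w)
    }, numeric(length(levs))))
}

# brute-force interaction count table: double loop over cells and
# neighbour windows
oracleCounts <- function(x, y, types, k, includeCenter = TRUE) {
    nb <- oracleKnn(x, y, k)
    levs <- sort(unique(types))
    out <- matrix(NA_real_, length(levs), length(levs),
                  dimnames = list(levs, levs))
    for (f in levs) {
        cells <- which(types == f)
        if (!length(cells)) next
        for (t in levs) {
            tot <- 0
            for (i in cells) {
                w <- if (includeCenter) c(i, nb[[i]]) else nb[[i]]
                tot <- tot + sum(types[w] == t)
            }
            out[f, t] <- tot / length(cells)
        }
    }
    out
}

# brute-force per-label region properties from a mask + stack
oracleRegionProps <- function(mask, stack) {
    labs <- sort(unique(mask[mask > 0]))
    C <- dim(stack)[3]
    res <- lapply(labs, function(l) {
        px <- which(mask == l, arr.ind = TRUE)
        means <- vapply(seq_len(C), function(c) {
            v <- numeric(nrow(px))
            for (r in seq_len(nrow(px)))
                v[r] <- stack[px[r, 1], px[r, 2], c]
            mean(v)
        }, numeric(1))
        list(label = l, area = nrow(px),
             x = mean(px[, 2] - 1), y = mean(px[, 1] - 1),
             means = means)
    })
    res
}

# brute-force linear-interpolation percentile (type 7)
oraclePercentile <- function(v, p) {
    s <- sort(v)
    h <- (length(s) - 1) * p / 100 + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force median filter with repeat-edge mirror reflection
oracleMedianFilter <- function(img, window) {
    h <- window %/% 2
    H <- nrow(img); W <- ncol(img)
    refl <- function(i, n) {
        while (i < 1 || i > n) {
            if (i < 1) i <- 1 - i
            if (i > n) i <- 2 * n - i + 1
        }
        i
    }
    out <- img
    for (i in seq_len(H)) for (j in seq_len(W)) {
        vals <- numeric(0)
        for (di in -h:h) for (dj in -h:h)
            vals <- c(vals, img[refl(i + di, H), refl(j + dj, W)])
        out[i, j] <- stats::median(vals)
    }
    out
}

# bivariate pair-correlation ratio at range r: observed A-B pairs within
# r over the CSR expectation (edge effects ignored; used only to show
# enrichment > 1)
oraclePairRatio <- function(ax, ay, bx, by, r, area) {
    d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
    obs <- sum(d2 <= r^2)
    expd <- length(ax) * length(bx) * pi * r^2 / area
    obs / expd
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
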