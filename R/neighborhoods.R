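# Spatial k-nearest-neighbour structure, cellular-neighbourhood (CN)
# composition profiles, CN discovery by k-means and CN-level group
# comparisons.

#' Build the per-ROI spatial k-nearest-neighbour graph
#'
#' Exact kNN on cell centroids, computed independently within each ROI
#' (neighbour lists never cross ROI boundaries). Ties at the k-th
#' distance are broken by ascending cell index, making the graph
#' deterministic. A single-cell ROI gets an empty neighbour list with a
#' warning.
#'
#' @param cells \code{SingleCellExperiment} with colData x, y, roi_id.
#' @param k neighbours per cell (default 20, the CN window minus its
#'   center).
#' @return a [SpatialGraph-class].
#' @export
spatialKnn <- function(cells, k = 20L) {
    cd <- cellData(cells)
    stopifnot(all(is.finite(cd$x)), all(is.finite(cd$y)))
    k <- as.integer(k)
    rois <- split(seq_len(nrow(cd)), cd$roi_id)
    out <- list()
    for (rid in names(rois)) {
        idx <- rois[[rid]]
        n <- length(idx)
        if (n < 2) {
            warning("ROI ", rid, " has a single cell; empty neighbour list")
            out[[rid]] <- list(cells = idx,
                               nn = matrix(NA_integer_, n, 0),
                               dist = matrix(NA_real_, n, 0))
            next
        }
        kk <- min(k, n - 1L)
        D <- as.matrix(stats::dist(cbind(cd$x[idx], cd$y[idx])))
        nn <- matrix(NA_integer_, n, kk)
        dd <- matrix(NA_real_, n, kk)
        for (i in seq_len(n)) {
            others <- seq_len(n)[-i]
            o <- others[order(D[i, others], others)][seq_len(kk)]
            nn[i, ] <- idx[o]
            dd[i, ] <- D[i, o]
        }
        out[[rid]] <- list(cells = idx, nn = nn, dist = dd)
    }
    new("SpatialGraph", k = k, cellIds = cd$cell_id,
        roiIds = cd$roi_id, rois = out)
}

# window membership matrix per ROI: n x (1 + k') of global indices,
# first column the center cell itself (or neighbours only if center
# exclusion is requested)
windowMatrix <- function(graph, includeCenter = TRUE) {
    lapply(graph@rois, function(ro) {
        if (includeCenter) cbind(ro$cells, ro$nn) else ro$nn
    })
}

#' Neighbourhood composition profiles
#'
#' For every cell, the fraction of each annotated cell type within its
#' CN window: the center cell plus its k nearest neighbours (the window
#' is the center plus neighbours by default; set
#' \code{includeCenter = FALSE} to use neighbours only). Cells without a
#' type are counted under "unassigned".
#'
#' @param graph a [SpatialGraph-class] built from the same experiment.
#' @param cells the cell experiment, with colData \code{cell_type} (or
#'   \code{typeCol}).
#' @param typeCol colData column holding the type.
#' @param includeCenter include the center cell in its own window.
#' @return numeric matrix cells x types; rows sum to 1. Row order is the
#'   experiment's column order; attribute "window_size" records per-cell
#'   window sizes.
#' @export
neighborhoodProfiles <- function(graph, cells, typeCol = "cell_type",
                                 includeCenter = TRUE) {
    cd <- cellData(cells)
    ty <- cd[[typeCol]]
    if (is.null(ty)) stop("missing type column ", typeCol)
    ty[is.na(ty)] <- "unassigned"
    types <- sort(unique(ty))
    tyi <- match(ty, types)
    n <- nrow(cd)
    P <- matrix(0, n, length(types), dimnames = list(cd$cell_id, types))
    wsize <- integer(n)
    for (ro in graph@rois) {
        for (j in seq_along(ro$cells)) {
            center <- ro$cells[j]
            nbrs <- ro$nn[j, ]
            nbrs <- nbrs[!is.na(nbrs)]
            w <- if (includeCenter) c(center, nbrs) else nbrs
            if (!length(w)) next
            cnt <- tabulate(tyi[w], length(types))
            P[center, ] <- cnt / length(w)
            wsize[center] <- length(w)
        }
    }
    attr(P, "window_size") <- wsize
    P
}

# k-means++ initial centres (Arthur & Vassilvitskii); deterministic given
# the RNG state
kmeansppInit <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(0, k, ncol(X))
    i <- sample.int(n, 1)
    centers[1, ] <- X[i, ]
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in seq_len(k - 1) + 1) {
        if (sum(d2) <= 0) i <- sample.int(n, 1)
        else i <- sample.int(n, 1, prob = d2)
        centers[j, ] <- X[i, ]
        d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
    centers
}

#' Cluster neighbourhood profiles into cellular neighbourhoods
#'
#' Standard k-means (Euclidean distance) on the composition profiles,
#' k-means++ seeding, best of \code{nInit} restarts by within-cluster
#' sum of squares, deterministic under \code{seed}. CN ids are
#' contiguous integers ordered by descending cluster size. If fewer
#' than \code{kCn} distinct profiles exist, kCn is reduced with a
#' warning; all-identical profiles give a single CN.
#'
#' @param profiles cells x types matrix from [neighborhoodProfiles()].
#' @param kCn number of CNs (default 10).
#' @param seed RNG seed.
#' @param nInit restarts (default 10).
#' @param maxIter,tol k-means iteration cap and convergence tolerance.
#' @return a [CNModel-class].
#' @export
clusterNeighborhoods <- function(profiles, kCn = 10L, seed = 1L,
                                 nInit = 10L, maxIter = 300L, tol = 1e-6) {
    X <- as.matrix(profiles)
    nDistinct <- nrow(unique(X))
    if (nDistinct < kCn) {
        warning("only ", nDistinct,
                " distinct profiles; reducing kCn from ", kCn)
        kCn <- nDistinct
    }
    kCn <- as.integer(kCn)
    fit <- withSeed(seed, {
        best <- NULL
        for (r in seq_len(nInit)) {
            cen <- kmeansppInit(X, kCn)
            km <- suppressWarnings(
                stats::kmeans(X, centers = cen, iter.max = maxIter,
                              algorithm = "Lloyd"))
            if (is.null(best) ||
                km$tot.withinss < best$tot.withinss * (1 - tol))
                best <- km
        }
        best
    })
    ids <- sizeOrderedIds(fit$cluster)
    ord <- vapply(seq_len(kCn), function(j)
        fit$cluster[match(j, ids)], integer(1))
    centroids <- fit$centers[ord, , drop = FALSE]
    rownames(centroids) <- paste0("CN", seq_len(kCn))
    glob <- colMeans(X)
    enr <- sweep(centroids, 2, ifelse(glob > 0, glob, NA), "/")
    new("CNModel", kCn = kCn, centroids = centroids,
        assignments = as.integer(ids), types = colnames(X),
        globalFractions = glob, enrichment = enr,
        labels = character(0), totWithinSS = fit$tot.withinss)
}

#' Attach CN assignments to the cell experiment
#'
#' @param cells the experiment the profiles were computed from.
#' @param model fitted [CNModel-class].
#' @return the experiment with colData column \code{cn_id}.
#' @export
addCN <- function(cells, model) {
    stopifnot(length(model@assignments) == ncol(cells))
    cells$cn_id <- model@assignments
    cells
}

#' Annotate CNs by enriched cell types
#'
#' Each CN is labelled by the types whose centroid fraction exceeds the
#' global fraction by at least \code{factor} (default 1.5), e.g.
#' "CD8+ T, B enriched"; a CN with no enriched type is "unenriched".
#' Labels are deterministic strings; they are also stored in the
#' returned model.
#'
#' @param model fitted [CNModel-class].
#' @param factor enrichment factor threshold.
#' @return the model with its \code{labels} slot filled.
#' @export
annotateCNs <- function(model, factor = 1.5) {
    labs <- apply(model@enrichment, 1, function(e) {
        hit <- names(e)[!is.na(e) & e >= factor]
        if (!length(hit)) "unenriched"
        else paste0(paste(hit, collapse = ", "), " enriched")
    })
    model@labels <- unname(labs)
    model
}

#' Per-sample CN abundance and two-group comparison
#'
#' Per-sample CN fraction table plus a Wilcoxon rank-sum test per CN
#' between two groups. P-values are reported unadjusted by default;
#' Benjamini-Hochberg adjusted values are added when \code{adjust} is
#' TRUE. A group with fewer than two samples skips the test (fractions
#' are still reported).
#'
#' @param cells experiment with colData \code{cn_id}.
#' @param by unit column (default "sample_id").
#' @param group two-level grouping column.
#' @param adjust add BH-adjusted p-values.
#' @return list(fractions, tests).
#' @export
cnAbundanceCompare <- function(cells, by = "sample_id",
                               group = "condition", adjust = FALSE) {
    cd <- cellData(cells)
    if (is.null(cd$cn_id)) stop("run addCN() first")
    cns <- sort(unique(cd$cn_id))
    units <- sort(unique(cd[[by]]))
    tab <- table(factor(cd[[by]], units), factor(cd$cn_id, cns))
    frac <- tab / rowSums(tab)
    grp <- if (!is.null(group) && group %in% names(cd))
        cd[[group]][match(units, cd[[by]])] else rep(NA, length(units))
    fractions <- data.frame(
        unit = rep(units, times = length(cns)),
        group = rep(grp, times = length(cns)),
        cn = rep(paste0("CN", cns), each = length(units)),
        fraction = as.vector(frac), stringsAsFactors = FALSE)
    tests <- NULL
    lv <- unique(stats::na.omit(grp))
    if (length(lv) == 2 && all(table(grp)[lv] >= 2)) {
        tests <- do.call(rbind, lapply(seq_along(cns), function(j) {
            f1 <- frac[grp == lv[1], j]
            f2 <- frac[grp == lv[2], j]
            wt <- suppressWarnings(stats::wilcox.test(f1, f2))
            data.frame(cn = paste0("CN", cns[j]),
                       W = unname(wt$statistic), p.value = wt$p.value,
                       direction = sprintf("%s %s %s", lv[1],
                           ifelse(mean(f1) >= mean(f2), ">=", "<"), lv[2]),
                       stringsAsFactors = FALSE)
        }))
        if (adjust && !is.null(tests))
            tests$p.adj <- stats::p.adjust(tests$p.value, "BH")
    }
    list(fractions = fractions, tests = tests)
}
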