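# Cell-cell spatial interaction statistics: directed interaction
# counting over CN windows, within-ROI label-permutation tests for
# interaction/avoidance, group comparisons of interaction counts,
# density-quartile association and composition correlations.

#' Observed cell-cell interaction counts
#'
#' For each ROI and ordered type pair (from, to): the mean, over cells
#' of the from type, of the number of to-type cells within their CN
#' window (center cell included by default, consistent with
#' [neighborhoodProfiles()]). Pairs whose from type is absent from an
#' ROI are reported with NA ("absent", not zero).
#'
#' @param graph a [SpatialGraph-class].
#' @param cells the matching cell experiment with a type column.
#' @param typeCol colData column holding the type.
#' @param includeCenter include the center cell in its window.
#' @return data.frame: roi_id, from_type, to_type, observed.
#' @export
countInteractions <- function(graph, cells, typeCol = "cell_type",
                              includeCenter = TRUE) {
    cd <- cellData(cells)
    ty <- cd[[typeCol]]
    if (is.null(ty)) stop("missing type column ", typeCol)
    types <- sort(unique(ty))
    tyi <- match(ty, types)
    out <- list()
    for (rid in names(graph@rois)) {
        ro <- graph@rois[[rid]]
        W <- if (includeCenter) cbind(ro$cells, ro$nn) else ro$nn
        if (!nrow(W)) next
        Wl <- matrix(match(W, ro$cells), nrow = nrow(W))
        cnt <- localPairCounts(tyi[ro$cells], Wl, length(types))
        out[[rid]] <- data.frame(
            roi_id = rid,
            from_type = rep(types, times = length(types)),
            to_type = rep(types, each = length(types)),
            observed = as.vector(cnt),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, unname(out))
}

#' Permutation test for spatial interaction and avoidance
#'
#' Within each ROI, cell labels are permuted uniformly (positions and
#' graph fixed, label multiset preserved) \code{nPerm} times. For each
#' ordered type pair the enrichment p-value uses the add-one estimator
#' p_enrich = (1 + #\{perm stat >= observed\}) / (nPerm + 1), and
#' p_avoid analogously with <=. A pair is classified "interaction" when
#' p_enrich < alpha, "avoidance" when p_avoid < alpha, else "ns". A
#' permutation in which the from type is absent (impossible under
#' within-ROI shuffling when the type is present in the ROI) contributes
#' a defined statistic of 0. Deterministic under \code{seed}.
#'
#' @param graph a [SpatialGraph-class].
#' @param cells the matching cell experiment.
#' @param nPerm permutations per ROI (default 1000).
#' @param seed RNG seed.
#' @param alpha classification level (default 0.05).
#' @param typeCol,includeCenter see [countInteractions()].
#' @return data.frame: roi_id, from_type, to_type, observed, null_mean,
#'   null_sd, p_enrich, p_avoid, n_perm, classification.
#' @export
testInteractions <- function(graph, cells, nPerm = 1000L, seed = 1L,
                             alpha = 0.05, typeCol = "cell_type",
                             includeCenter = TRUE) {
    cd <- cellData(cells)
    ty <- cd[[typeCol]]
    if (is.null(ty)) stop("missing type column ", typeCol)
    types <- sort(unique(ty))
    nT <- length(types)
    tyi <- match(ty, types)
    out <- list()
    for (rid in names(graph@rois)) {
        ro <- graph@rois[[rid]]
        n <- length(ro$cells)
        if (!n) next
        Wg <- if (includeCenter) cbind(ro$cells, ro$nn) else ro$nn
        Wl <- matrix(match(Wg, ro$cells), nrow = n)  # local indices
        labLoc <- tyi[ro$cells]
        obs <- localPairCounts(labLoc, Wl, nT)
        geCount <- matrix(0L, nT, nT)
        leCount <- matrix(0L, nT, nT)
        sumStat <- matrix(0, nT, nT)
        sumStat2 <- matrix(0, nT, nT)
        withSeed(deriveSeed(seed, rid, "perm"), {
            for (b in seq_len(nPerm)) {
                permStat <- localPairCounts(sample(labLoc), Wl, nT)
                permStat[is.na(permStat)] <- 0
                obs0 <- obs
                obs0[is.na(obs0)] <- 0
                geCount <- geCount + (permStat >= obs0)
                leCount <- leCount + (permStat <= obs0)
                sumStat <- sumStat + permStat
                sumStat2 <- sumStat2 + permStat^2
            }
        })
        pEnrich <- (1 + geCount) / (nPerm + 1)
        pAvoid <- (1 + leCount) / (nPerm + 1)
        nullMean <- sumStat / nPerm
        nullSd <- sqrt(pmax(sumStat2 / nPerm - nullMean^2, 0))
        cls <- matrix("ns", nT, nT)
        cls[pEnrich < alpha] <- "interaction"
        cls[pAvoid < alpha] <- "avoidance"
        absent <- is.na(obs)
        df <- data.frame(
            roi_id = rid,
            from_type = rep(types, times = nT),
            to_type = rep(types, each = nT),
            observed = as.vector(obs),
            null_mean = as.vector(nullMean),
            null_sd = as.vector(nullSd),
            p_enrich = as.vector(pEnrich),
            p_avoid = as.vector(pAvoid),
            n_perm = nPerm,
            classification = as.vector(cls),
            stringsAsFactors = FALSE)
        df$classification[as.vector(absent)] <- NA
        out[[rid]] <- df
    }
    do.call(rbind, unname(out))
}

# fast T x T mean-count statistic from local labels and a local window
# matrix (rows = cells, first column may be the center)
localPairCounts <- function(labLoc, Wl, nT) {
    nf <- tabulate(labLoc, nT)
    from <- rep(labLoc, ncol(Wl))
    toLab <- labLoc[as.vector(Wl)]
    ok <- !is.na(toLab)
    idx <- (from[ok] - 1L) * nT + toLab[ok]
    tot <- tabulate(idx, nT * nT)
    cnt <- matrix(tot, nT, nT, byrow = TRUE)
    sweep(cnt, 1, ifelse(nf > 0, nf, NA), "/")
}

#' Compare interaction counts between groups
#'
#' Per ordered type pair, a two-sample t test (Welch by default) on the
#' per-ROI observed mean counts between two groups. Degenerate
#' zero-variance pairs get p = 1 with a flag.
#'
#' @param counts data.frame from [countInteractions()] (or the observed
#'   columns of [testInteractions()]).
#' @param roiGroups named character vector mapping roi_id to group.
#' @param welch use the Welch correction (default TRUE).
#' @return data.frame: from_type, to_type, mean per group, t, p.value,
#'   direction, degenerate flag.
#' @export
compareInteractionsGroups <- function(counts, roiGroups, welch = TRUE) {
    counts$group <- roiGroups[counts$roi_id]
    lv <- sort(unique(stats::na.omit(counts$group)))
    if (length(lv) != 2)
        stop("need exactly two groups, got ", length(lv))
    pairs <- unique(counts[, c("from_type", "to_type")])
    out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        sub <- counts[counts$from_type == pairs$from_type[i] &
                      counts$to_type == pairs$to_type[i] &
                      !is.na(counts$observed), ]
        x1 <- sub$observed[sub$group == lv[1]]
        x2 <- sub$observed[sub$group == lv[2]]
        if (length(x1) < 2 || length(x2) < 2) return(NULL)
        degenerate <- stats::var(x1) == 0 && stats::var(x2) == 0
        if (degenerate) {
            tstat <- 0; p <- 1
        } else {
            tt <- stats::t.test(x1, x2, var.equal = !welch)
            tstat <- unname(tt$statistic); p <- tt$p.value
        }
        data.frame(from_type = pairs$from_type[i],
                   to_type = pairs$to_type[i],
                   mean1 = mean(x1), mean2 = mean(x2),
                   group1 = lv[1], group2 = lv[2],
                   t = tstat, p.value = p,
                   direction = ifelse(mean(x1) >= mean(x2), ">=", "<"),
                   degenerate = degenerate,
                   stringsAsFactors = FALSE)
    }))
    out
}

#' Density-quartile association of functional markers
#'
#' Ranks images (ROIs) by the density of a target cell type and splits
#' them into four equally sized rank bins (remainders go to the lower
#' bins), labelled absent / low / medium / high; the lowest bin is
#' labelled "absent" if and only if it contains zero-density images
#' (else "low-"). Within each bin and functional marker, the fraction
#' of all cells whose normalized marker value exceeds the positivity
#' threshold is reported, together with the Spearman rank correlation
#' of fraction against bin rank (exact p for the four bins). Density
#' ties at bin boundaries break by image id.
#'
#' @param cells experiment with assay "norm" and colData roi_id, plus a
#'   type column.
#' @param targetType the infiltrating type whose density defines bins.
#' @param functionalMarkers markers to score (default: all markers).
#' @param threshold positivity threshold on the normalized scale.
#' @param typeCol colData column holding the type.
#' @param roiAreas optional named vector of ROI areas (mm^2); densities
#'   become cells/mm^2, otherwise cells per image.
#' @return list with \code{bins} (roi_id, density, bin, bin_label) and
#'   \code{trend} (marker, fractions per bin, rho, p.value).
#' @export
densityQuartileAssociation <- function(cells, targetType,
                                       functionalMarkers = NULL,
                                       threshold = 0.5,
                                       typeCol = "cell_type",
                                       roiAreas = NULL) {
    cd <- cellData(cells)
    ty <- cd[[typeCol]]
    rois <- sort(unique(cd$roi_id))
    if (length(rois) < 4) stop("need at least 4 images")
    if (!targetType %in% ty)
        warning("target type ", targetType, " absent from all images")
    dens <- vapply(rois, function(r)
        sum(ty == targetType & cd$roi_id == r), numeric(1))
    if (!is.null(roiAreas)) dens <- dens / roiAreas[rois]
    ord <- order(dens, rois)  # ties break by image id
    nR <- length(rois)
    base <- nR %/% 4L; rem <- nR %% 4L
    sizes <- rep(base, 4) + as.integer(seq_len(4) <= rem)
    bin <- integer(nR)
    bin[ord] <- rep(1:4, times = sizes)
    labels <- c(if (any(dens[bin == 1] == 0)) "absent" else "low-",
                "low", "medium", "high")
    bins <- data.frame(roi_id = rois, density = dens, bin = bin,
                       bin_label = labels[bin], stringsAsFactors = FALSE)
    norm <- SummarizedExperiment::assay(cells, "norm")
    if (is.null(functionalMarkers)) functionalMarkers <- rownames(norm)
    cellBin <- bin[match(cd$roi_id, rois)]
    trend <- do.call(rbind, lapply(functionalMarkers, function(m) {
        posFrac <- vapply(1:4, function(b) {
            v <- norm[m, cellBin == b]
            if (!length(v)) return(NA_real_)
            mean(v > threshold)
        }, numeric(1))
        ok <- !is.na(posFrac)
        ct <- suppressWarnings(stats::cor.test(
            seq_len(4)[ok], posFrac[ok], method = "spearman",
            exact = TRUE))
        data.frame(marker = m,
                   frac_bin1 = posFrac[1], frac_bin2 = posFrac[2],
                   frac_bin3 = posFrac[3], frac_bin4 = posFrac[4],
                   rho = unname(ct$estimate), p.value = ct$p.value,
                   stringsAsFactors = FALSE)
    }))
    list(bins = bins, trend = trend)
}

#' Correlation of an anchor type's proportion with the other types
#'
#' Across ROIs, correlates the per-ROI fraction of the anchor type with
#' each other type's fraction (each observation is one ROI). A constant
#' fraction vector yields NA.
#'
#' @param cells experiment with a type column and colData roi_id.
#' @param anchorType anchor (default "epithelial").
#' @param method "pearson" (default) or "spearman".
#' @param typeCol colData column holding the type.
#' @return data.frame: cell_type, r, p.value, n_roi.
#' @export
compositionCorrelation <- function(cells, anchorType = "epithelial",
                                   method = c("pearson", "spearman"),
                                   typeCol = "cell_type") {
    method <- match.arg(method)
    cd <- cellData(cells)
    ty <- cd[[typeCol]]
    rois <- sort(unique(cd$roi_id))
    if (length(rois) < 3) stop("need at least 3 ROIs")
    types <- sort(unique(ty))
    tab <- table(factor(cd$roi_id, rois), factor(ty, types))
    frac <- tab / rowSums(tab)
    a <- frac[, anchorType]
    do.call(rbind, lapply(setdiff(types, anchorType), function(tt) {
        b <- frac[, tt]
        if (stats::sd(a) == 0 || stats::sd(b) == 0)
            return(data.frame(cell_type = tt, r = NA_real_,
                              p.value = NA_real_, n_roi = length(rois),
                              stringsAsFactors = FALSE))
        ct <- suppressWarnings(stats::cor.test(a, b, method = method))
        data.frame(cell_type = tt, r = unname(ct$estimate),
                   p.value = ct$p.value, n_roi = length(rois),
                   stringsAsFactors = FALSE)
    }))
}
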