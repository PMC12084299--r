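# Interaction counting, permutation test, group comparisons, density
# quartiles and composition correlations.

# build a SpatialGraph by hand (global indices, one ROI)
handGraph <- function(nn, ids, k) {
    new("SpatialGraph", k = as.integer(k), cellIds = ids,
        roiIds = rep("r1", length(ids)),
        rois = list(r1 = list(cells = seq_along(ids), nn = nn,
                              dist = matrix(1, nrow(nn), ncol(nn)))))
}

test_that("interaction counts match the hand-worked toy case", {
    # cells: 1 = A, 2 = A, 3..5 = B; windows include centers
    ids <- paste0("c", 1:5)
    nn <- rbind(c(2L, 3L, 4L),   # window {A, A, B, B} -> 2 B
                c(3L, 4L, 5L),   # window {A, B, B, B} -> 3 B
                c(1L, 2L, 4L), c(1L, 2L, 3L), c(2L, 3L, 4L))
    sce <- makeCellsSCE(1:5, rep(0, 5), c("A", "A", "B", "B", "B"))
    g <- handGraph(nn, ids, 3)
    cnt <- countInteractions(g, sce)
    expect_equal(cnt$observed[cnt$from_type == "A" &
                              cnt$to_type == "B"], 2.5)
})

test_that("interaction counts match the brute-force oracle", {
    set.seed(33)
    n <- 300
    x <- runif(n, 0, 350); y <- runif(n, 0, 350)
    ty <- sample(c("A", "B", "C"), n, TRUE, prob = c(0.5, 0.3, 0.2))
    sce <- makeCellsSCE(x, y, ty)
    g <- spatialKnn(sce, k = 20)
    cnt <- countInteractions(g, sce)
    want <- oracleCounts(x, y, ty, 20)
    for (i in seq_len(nrow(cnt)))
        expect_equal(cnt$observed[i],
                     want[cnt$from_type[i], cnt$to_type[i]])
})

test_that("single-type saturation and absent pairs behave as specified", {
    set.seed(3)
    sce <- makeCellsSCE(runif(40, 0, 100), runif(40, 0, 100),
                        rep("A", 40))
    g <- spatialKnn(sce, k = 20)
    cnt <- countInteractions(g, sce)
    expect_equal(cnt$observed[cnt$from_type == "A" &
                              cnt$to_type == "A"], 21)
    # absent from-type is reported NA, not zero
    sce2 <- makeCellsSCE(runif(30), runif(30),
                         sample(c("A", "B"), 30, TRUE))
    sce2$cell_type <- factor(sce2$cell_type, c("A", "B"))
    g2 <- spatialKnn(sce2, k = 5)
    # force a vocabulary including an absent type via annotation levels
    sce3 <- sce2
    sce3$cell_type <- as.character(sce3$cell_type)
    sce3$cell_type[1] <- "C"
    g3 <- spatialKnn(sce3, k = 5)
    cnt3 <- countInteractions(g3, sce3)
    expect_true(all(!is.na(
        cnt3$observed[cnt3$from_type == "C"])))
})

test_that("per-cell counts conserve the window size", {
    set.seed(41)
    n <- 120
    ty <- sample(c("A", "B", "C"), n, TRUE)
    sce <- makeCellsSCE(runif(n, 0, 150), runif(n, 0, 150), ty)
    g <- spatialKnn(sce, k = 20)
    cnt <- countInteractions(g, sce)
    # sum over to-types of mean counts equals the window size for every
    # present from-type
    for (f in unique(ty)) {
        s <- sum(cnt$observed[cnt$from_type == f], na.rm = TRUE)
        expect_equal(s, 21)
    }
})

test_that("permutation p-values satisfy the add-one bounds", {
    set.seed(55)
    n <- 150
    sce <- makeCellsSCE(runif(n, 0, 200), runif(n, 0, 200),
                        sample(c("A", "B"), n, TRUE))
    g <- spatialKnn(sce, k = 10)
    res <- testInteractions(g, sce, nPerm = 99, seed = 4)
    expect_true(all(res$p_enrich >= 1 / 100))
    expect_true(all(res$p_enrich <= 1))
    expect_true(all(res$p_enrich + res$p_avoid >= 1))
    # deterministic under seed
    res2 <- testInteractions(g, sce, nPerm = 99, seed = 4)
    expect_identical(res, res2)
    # null mean stays near the composition expectation
    fB <- mean(sce$cell_type == "B")
    expect_lt(abs(res$null_mean[res$from_type == "A" &
                                res$to_type == "B"] - fB * 11), 0.6)
})

test_that("planted attraction and avoidance are classified correctly", {
    att <- plantedAttractionSpec(seed = 19L)
    out <- generateROI(att, "control", render = FALSE)
    g <- spatialKnn(out$cells, k = 20)
    res <- testInteractions(g, out$cells, nPerm = 199, seed = 1,
                            typeCol = "true_type")
    expect_equal(res$classification[res$from_type == "epithelial" &
                                    res$to_type == "CD8+ T"],
                 "interaction")
    avd <- plantedAvoidanceSpec(seed = 19L)
    out2 <- generateROI(avd, "control", render = FALSE)
    g2 <- spatialKnn(out2$cells, k = 20)
    res2 <- testInteractions(g2, out2$cells, nPerm = 199, seed = 1,
                             typeCol = "true_type")
    expect_equal(res2$classification[res2$from_type == "CD8+ T" &
                                     res2$to_type == "B"], "avoidance")
})

test_that("group comparison is symmetric and handles degeneracy", {
    set.seed(61)
    counts <- data.frame(
        roi_id = sprintf("r%02d", 1:12),
        from_type = "A", to_type = "B",
        observed = c(rnorm(6, 2), rnorm(6, 3)))
    grp <- stats::setNames(rep(c("g1", "g2"), each = 6), counts$roi_id)
    res <- compareInteractionsGroups(counts, grp)
    grpFlip <- stats::setNames(rep(c("g2", "g1"), each = 6),
                               counts$roi_id)
    resFlip <- compareInteractionsGroups(counts, grpFlip)
    expect_equal(res$p.value, resFlip$p.value)
    expect_equal(res$t, -resFlip$t)
    # identical constant groups: t = 0, p = 1, degenerate flag
    cz <- counts; cz$observed <- 2
    rz <- compareInteractionsGroups(cz, grp)
    expect_equal(rz$t, 0)
    expect_equal(rz$p.value, 1)
    expect_true(rz$degenerate)
})

test_that("group comparison is calibrated under the null", {
    set.seed(71)
    rej <- 0
    nrep <- 500
    for (r in seq_len(nrep)) {
        counts <- data.frame(roi_id = sprintf("r%02d", 1:12),
                             from_type = "A", to_type = "B",
                             observed = rnorm(12, 2))
        grp <- stats::setNames(rep(c("g1", "g2"), each = 6),
                               counts$roi_id)
        rej <- rej + (compareInteractionsGroups(counts,
                                                grp)$p.value < 0.05)
    }
    expect_lte(rej / nrep, 0.07)
})

test_that("density quartiles split and label images as specified", {
    # 8 images with target densities 0,0,1,2,3,4,5,6
    dens <- c(0, 0, 1, 2, 3, 4, 5, 6)
    cells <- list()
    for (i in seq_along(dens)) {
        nT <- dens[i]; nO <- 30 - nT
        ty <- c(rep("CD8+ T", nT), rep("epithelial", nO))
        cells[[i]] <- data.frame(
            roi = sprintf("img%02d", i), ty = ty,
            x = runif(30), y = runif(30))
    }
    df <- do.call(rbind, cells)
    ids <- sprintf("c%04d", seq_len(nrow(df)))
    cd <- S4Vectors::DataFrame(cell_id = ids, roi_id = df$roi,
        sample_id = df$roi, condition = "pSS", x = df$x, y = df$y,
        row.names = ids)
    # functional marker rising with density
    m <- matrix(0, 2, nrow(df), dimnames = list(c("MMP9", "IL1b"), ids))
    d <- dens[match(df$roi, sprintf("img%02d", seq_along(dens)))]
    m["MMP9", ] <- ifelse(runif(nrow(df)) < 0.1 + 0.1 * d, 1, 0)
    m["IL1b", ] <- ifelse(runif(nrow(df)) < 0.3, 1, 0)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(raw = m, norm = m), colData = cd)
    sce$cell_type <- df$ty
    set.seed(5)
    res <- densityQuartileAssociation(sce, "CD8+ T",
                                      functionalMarkers = c("MMP9",
                                                            "IL1b"))
    expect_equal(unname(table(res$bins$bin)), rep(2L, 4),
                 ignore_attr = TRUE)
    expect_equal(res$bins$bin_label[res$bins$density == 0][1], "absent")
    expect_equal(sort(unique(res$bins$bin_label)),
                 sort(c("absent", "low", "medium", "high")))
    # a marker built to rise monotonically across bins has rho = 1
    fr <- unlist(res$trend[res$trend$marker == "MMP9",
                           paste0("frac_bin", 1:4)])
    if (all(diff(fr) > 0))
        expect_equal(res$trend$rho[res$trend$marker == "MMP9"], 1)
})

test_that("density quartile trend is conservative under independence", {
    set.seed(81)
    rejected <- 0
    for (r in 1:200) {
        nI <- 8
        df <- do.call(rbind, lapply(1:nI, function(i)
            data.frame(roi = sprintf("i%02d", i),
                       ty = sample(c("CD8+ T", "other"), 25, TRUE,
                                   prob = c(0.3, 0.7)))))
        ids <- sprintf("c%04d", seq_len(nrow(df)))
        cd <- S4Vectors::DataFrame(cell_id = ids, roi_id = df$roi,
            sample_id = df$roi, condition = "pSS",
            x = runif(nrow(df)), y = runif(nrow(df)), row.names = ids)
        m <- matrix(runif(nrow(df)), 1, nrow(df),
                    dimnames = list("MMP9", ids))
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(raw = m, norm = m), colData = cd)
        sce$cell_type <- df$ty
        res <- densityQuartileAssociation(sce, "CD8+ T",
                                          functionalMarkers = "MMP9")
        rejected <- rejected + (res$trend$p.value < 0.05)
    }
    expect_lte(rejected / 200, 0.05)
})

test_that("composition correlations match closed forms", {
    # two complementary types: r = -1 exactly
    set.seed(91)
    rois <- sprintf("r%02d", 1:10)
    nA <- rbinom(10, 50, 0.5)
    df <- do.call(rbind, lapply(1:10, function(i)
        data.frame(roi = rois[i],
                   ty = c(rep("epithelial", nA[i]),
                          rep("B", 50 - nA[i])))))
    sce <- makeCellsSCE(runif(nrow(df)), runif(nrow(df)), df$ty)
    SummarizedExperiment::colData(sce)$roi_id <- df$roi
    res <- compositionCorrelation(sce, "epithelial")
    expect_equal(res$r[res$cell_type == "B"], -1)

    # random three-type compositions: r matches the covariance formula
    df2 <- do.call(rbind, lapply(1:30, function(i)
        data.frame(roi = sprintf("q%02d", i),
                   ty = sample(c("epithelial", "B", "NK"), 60, TRUE))))
    sce2 <- makeCellsSCE(runif(nrow(df2)), runif(nrow(df2)), df2$ty)
    SummarizedExperiment::colData(sce2)$roi_id <- df2$roi
    res2 <- compositionCorrelation(sce2, "epithelial")
    tab <- table(df2$roi, df2$ty)
    frac <- tab / rowSums(tab)
    a <- frac[, "epithelial"]; b <- frac[, "B"]
    rManual <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(res2$r[res2$cell_type == "B"], rManual,
                 tolerance = 1e-12)

    # constant anchor: NA
    df3 <- data.frame(roi = rep(sprintf("r%d", 1:4), each = 10),
                      ty = rep(c("epithelial", "B"), 20))
    sce3 <- makeCellsSCE(runif(40), runif(40), df3$ty)
    SummarizedExperiment::colData(sce3)$roi_id <- df3$roi
    res3 <- compositionCorrelation(sce3, "epithelial")
    expect_true(is.na(res3$r[res3$cell_type == "B"]))
})
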