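# Spatial kNN graph, neighbourhood profiles and CN discovery.

test_that("kNN on collinear points matches hand geometry", {
    sce <- makeCellsSCE(c(0, 1, 10), c(0, 0, 0), rep("A", 3))
    g <- spatialKnn(sce, k = 1)
    nn <- g@rois[[1]]$nn
    expect_equal(as.vector(nn), c(2L, 1L, 2L))
    expect_true(all(diff(t(g@rois[[1]]$dist)) >= 0 |
                    ncol(g@rois[[1]]$dist) < 2))
})

test_that("kNN equals the brute-force oracle on random cells", {
    set.seed(14)
    n <- 200
    x <- runif(n, 0, 300); y <- runif(n, 0, 300)
    sce <- makeCellsSCE(x, y, sample(c("A", "B"), n, TRUE))
    g <- spatialKnn(sce, k = 20)
    want <- oracleKnn(x, y, 20)
    nn <- g@rois[[1]]$nn
    for (i in seq_len(n))
        expect_equal(unname(nn[i, ]), want[[i]])
    # distances are nondecreasing within each list
    expect_true(all(apply(g@rois[[1]]$dist, 1,
                          function(d) all(diff(d) >= -1e-12))))
})

test_that("k saturates at n - 1 and singletons warn", {
    sce <- makeCellsSCE(runif(5), runif(5), rep("A", 5))
    g <- spatialKnn(sce, k = 50)
    expect_equal(ncol(g@rois[[1]]$nn), 4L)
    expect_true(all(apply(g@rois[[1]]$nn, 1, function(r)
        length(unique(r)) == 4)))
    solo <- makeCellsSCE(0.5, 0.5, "A")
    expect_warning(g1 <- spatialKnn(solo, k = 3), "single cell")
    expect_equal(ncol(g1@rois[[1]]$nn), 0L)
})

test_that("kNN never crosses ROI boundaries", {
    x <- c(0, 1, 0, 1); y <- c(0, 0, 0, 0)
    cd <- S4Vectors::DataFrame(
        cell_id = paste0("c", 1:4), roi_id = c("r1", "r1", "r2", "r2"),
        sample_id = "s1", condition = "control", x = x, y = y,
        cell_type = "A", row.names = paste0("c", 1:4))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(raw = matrix(0, 1, 4,
            dimnames = list("m", paste0("c", 1:4)))), colData = cd)
    g <- spatialKnn(sce, k = 3)
    expect_equal(as.vector(g@rois[["r1"]]$nn), c(2L, 1L))
    expect_equal(as.vector(g@rois[["r2"]]$nn), c(4L, 3L))
})

test_that("profiles count the CN window exactly", {
    # homogeneous tissue: every profile is a unit vector
    set.seed(2)
    sce <- makeCellsSCE(runif(30), runif(30), rep("A", 30))
    g <- spatialKnn(sce, k = 5)
    P <- neighborhoodProfiles(g, sce)
    expect_true(all(P[, "A"] == 1))
    expect_true(all(attr(P, "window_size") == 6))

    # center CD8+ T surrounded by 20 epithelial
    ang <- seq(0, 2 * pi, length.out = 21)[-21]
    x <- c(0, cos(ang)); y <- c(0, sin(ang))
    sce2 <- makeCellsSCE(x, y, c("CD8+ T", rep("epithelial", 20)))
    g2 <- spatialKnn(sce2, k = 20)
    P2 <- neighborhoodProfiles(g2, sce2)
    expect_equal(unname(P2[1, "CD8+ T"]), 1 / 21)
    expect_equal(unname(P2[1, "epithelial"]), 20 / 21)

    # random ROI against the brute-force recount
    set.seed(23)
    n <- 150
    x <- runif(n, 0, 200); y <- runif(n, 0, 200)
    ty <- sample(c("A", "B", "C"), n, TRUE)
    sce3 <- makeCellsSCE(x, y, ty)
    g3 <- spatialKnn(sce3, k = 20)
    P3 <- neighborhoodProfiles(g3, sce3)
    expect_equal(unname(P3), unname(oracleProfiles(x, y, ty, 20)),
                 ignore_attr = TRUE)
    expect_true(all(abs(rowSums(P3) - 1) < 1e-9))
})

test_that("window conservation holds at every ROI size", {
    for (n in c(5, 21, 60)) {
        sce <- makeCellsSCE(runif(n), runif(n),
                            sample(c("A", "B"), n, TRUE))
        g <- spatialKnn(sce, k = 20)
        P <- neighborhoodProfiles(g, sce)
        expect_true(all(attr(P, "window_size") == 1 + min(20, n - 1)))
    }
})

test_that("k-means closed forms and determinism hold", {
    set.seed(8)
    P <- matrix(runif(300), 100, 3)
    P <- P / rowSums(P)
    colnames(P) <- c("A", "B", "C")
    m1 <- clusterNeighborhoods(P, kCn = 1, seed = 1)
    expect_equal(as.vector(cnCentroids(m1)), colMeans(P),
                 tolerance = 1e-12, ignore_attr = TRUE)
    m2a <- clusterNeighborhoods(P, kCn = 4, seed = 9)
    m2b <- clusterNeighborhoods(P, kCn = 4, seed = 9)
    expect_identical(cnIds(m2a), cnIds(m2b))
    # cn ids are size-ordered
    sz <- tabulate(cnIds(m2a))
    expect_true(all(diff(sz) <= 0))
    # identical profiles collapse with a warning
    flat <- matrix(1 / 3, 50, 3, dimnames = list(NULL, c("A", "B", "C")))
    expect_warning(mf <- clusterNeighborhoods(flat, kCn = 3, seed = 1),
                   "distinct")
    expect_equal(mf@kCn, 1L)
})

test_that("planted niches are recovered by CN clustering", {
    spec <- plantedNicheSpec(2, seed = 6L)
    out <- generateROI(spec, "control", render = FALSE)
    cells <- out$cells
    g <- spatialKnn(cells, k = 20)
    P <- neighborhoodProfiles(g, cells, typeCol = "true_type")
    m <- clusterNeighborhoods(P, kCn = 2, seed = 2)
    cd <- cellData(cells)
    interior <- abs(cd$x / spec@roiWidth - 0.5) > 0.08
    expect_gte(ari(cnIds(m)[interior], cd$true_niche[interior]), 0.8)
})

test_that("CN annotation reflects enrichment over the global mix", {
    # single CN: centroid equals the global composition -> unenriched
    P <- matrix(runif(150), 50, 3)
    P <- P / rowSums(P)
    colnames(P) <- c("A", "B", "C")
    m <- clusterNeighborhoods(P, kCn = 1, seed = 1)
    m <- annotateCNs(m)
    expect_equal(m@labels, "unenriched")
    # a centroid at twice the global fraction is labelled
    m2 <- m
    m2@enrichment <- matrix(c(2.1, 0.5, 0.7), 1, 3,
                            dimnames = list("CN1", c("A", "B", "C")))
    m2 <- annotateCNs(m2)
    expect_equal(m2@labels, "A enriched")
})

test_that("CN abundance fractions sum to one and detect planted shifts", {
    # per-sample fractions sum to 1
    set.seed(12)
    sce <- makeCellsSCE(runif(200), runif(200),
                        sample(c("A", "B"), 200, TRUE))
    sce$cn_id <- sample(1:3, 200, TRUE)
    out <- cnAbundanceCompare(sce, group = NULL)
    agg <- tapply(out$fractions$fraction, out$fractions$unit, sum)
    expect_true(all(abs(agg - 1) < 1e-12))

    # power: CN1 at 0.3 vs 0.1, 10 samples per group, 200 cells each
    detect <- logical(100)
    nullRej <- logical(100)
    set.seed(77)
    for (r in 1:100) {
        mk <- function(p1, grp, off) {
            n <- 10 * 200
            sid <- rep(sprintf("%s%02d", grp, 1:10), each = 200)
            cn <- sample(1:3, n, TRUE, prob = c(p1, (1 - p1) / 2,
                                                (1 - p1) / 2))
            data.frame(sid, grp = grp, cn)
        }
        df <- rbind(mk(0.3, "case"), mk(0.1, "ctrl"))
        ids <- sprintf("c%05d", seq_len(nrow(df)))
        cd <- S4Vectors::DataFrame(cell_id = ids, roi_id = df$sid,
            sample_id = df$sid, condition = df$grp, row.names = ids)
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(raw = matrix(0, 1, nrow(df),
                dimnames = list("m", ids))), colData = cd)
        sce$cn_id <- df$cn
        res <- cnAbundanceCompare(sce)
        detect[r] <- res$tests$p.value[res$tests$cn == "CN1"] < 0.05
        # null: compare two halves of the control group
        sub <- sce[, sce$condition == "ctrl"]
        sub$condition <- rep(c("h1", "h2"),
                             times = c(sum(sub$sample_id <= "ctrl05"),
                                       sum(sub$sample_id > "ctrl05")))
        resN <- cnAbundanceCompare(sub)
        nullRej[r] <- resN$tests$p.value[resN$tests$cn == "CN1"] < 0.05
    }
    expect_gte(mean(detect), 0.8)
    expect_lte(mean(nullRej), 0.1)
})
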