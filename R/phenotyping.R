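# Expression normalization, graph-based phenotype clustering and
# rule-based cluster annotation.

#' Percentile range normalization
#'
#' For each marker, divides the raw intensity by the q-th percentile of
#' that marker over ALL cells of the cohort (pooled across ROIs,
#' linear-interpolation percentile) and clips to [0, 1]. A marker whose
#' percentile is 0 gets all-zero normalized values with a warning.
#'
#' @param cells \code{SingleCellExperiment} with assay "raw".
#' @param q percentile in (0, 100]; default 99.
#' @return the experiment with an added assay "norm".
#' @export
normalizePercentile <- function(cells, q = 99) {
    stopifnot(q > 0, q <= 100)
    raw <- SummarizedExperiment::assay(cells, "raw")
    div <- apply(raw, 1, stats::quantile, probs = q / 100,
                 names = FALSE, type = 7)
    zero <- div <= 0
    if (any(zero)) {
        warning("markers with zero ", q, "th percentile set to 0: ",
                paste(rownames(raw)[zero], collapse = ", "))
        div[zero] <- Inf
    }
    norm <- pmin(raw / div, 1)
    SummarizedExperiment::assay(cells, "norm") <- norm
    cells
}

# k-nearest-neighbour index matrix in feature space (rows = cells),
# Euclidean, ties broken by ascending index
exprKnn <- function(X, k) {
    n <- nrow(X)
    D <- as.matrix(stats::dist(X))
    idx <- matrix(0L, n, k)
    for (i in seq_len(n)) {
        o <- order(D[i, -i], seq_len(n)[-i])[seq_len(k)]
        idx[i, ] <- (seq_len(n)[-i])[o]
    }
    idx
}

#' PhenoGraph-style expression clustering
#'
#' Builds the k-nearest-neighbour graph of cells in normalized
#' expression space (Euclidean), reweights each kNN edge by the Jaccard
#' overlap of the two cells' neighbour sets, and partitions the graph by
#' Louvain modularity optimization under a fixed seed. Cluster ids are
#' contiguous integers ordered by descending cluster size.
#'
#' @param cells experiment with assay "norm" (run
#'   [normalizePercentile()] first).
#' @param k neighbours in expression space (default 30). Lowered to
#'   n - 1 with a warning when fewer than k + 1 cells are present.
#' @param seed RNG seed for the community detection.
#' @param markers which markers span the distance space; default all
#'   markers whose panel category is "lineage" if a panel is supplied,
#'   else all markers.
#' @param panel optional panel table used to select lineage markers.
#' @param resolution Louvain resolution parameter. The default 0.05
#'   favours population-scale communities: disjoint populations occupy
#'   (near-)disconnected components of the kNN graph, which modularity
#'   optimization never merges, while a low resolution keeps single
#'   populations from fragmenting into micro-clusters.
#' @return the experiment with colData column \code{cluster_id}.
#' @export
clusterExpression <- function(cells, k = 30L, seed = 1L, markers = NULL,
                              panel = NULL, resolution = 0.05) {
    norm <- SummarizedExperiment::assay(cells, "norm")
    if (is.null(markers)) {
        markers <- if (!is.null(panel))
            intersect(rownames(norm),
                      panel$marker[panel$category == "lineage"])
        else rownames(norm)
    }
    X <- t(norm[markers, , drop = FALSE])
    n <- nrow(X)
    if (n < 2) {
        cells$cluster_id <- rep(1L, n)
        return(cells)
    }
    if (k >= n) {
        warning("k = ", k, " >= number of cells; lowered to ", n - 1)
        k <- n - 1L
    }
    if (sum(abs(sweep(X, 2, X[1, ]))) == 0) {
        cells$cluster_id <- rep(1L, n)
        return(cells)
    }
    nn <- exprKnn(X, k)
    # Jaccard weight of every kNN edge from shared-neighbour counts
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(A)
    ei <- rep(seq_len(n), k)
    ej <- as.vector(nn)
    und <- unique(data.frame(i = pmin(ei, ej), j = pmax(ei, ej)))
    sh <- shared[cbind(und$i, und$j)]
    w <- sh / (2 * k - sh)
    pos <- w > 0
    g <- igraph::graph_from_data_frame(
        data.frame(from = und$i[pos], to = und$j[pos]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
    igraph::E(g)$weight <- w[pos]
    comm <- withSeed(seed,
        igraph::cluster_louvain(g, resolution = resolution))
    memb <- igraph::membership(comm)[as.character(seq_len(n))]
    cells$cluster_id <- as.integer(sizeOrderedIds(as.integer(memb)))
    cells
}

#' Default annotation rule set
#'
#' Ordered marker-gating rules matched against cluster mean normalized
#' expression. Structural rules precede immune rules; an immune cluster
#' matching more than one immune rule is labelled by the fallback
#' "mixed immune"; a cluster matching nothing is "unassigned".
#'
#' @param threshold positivity threshold on the normalized [0, 1] scale.
#' @return list with fields \code{rules} (ordered list of
#'   \code{list(cell_type, positive, negative, threshold, immune)}) and
#'   \code{fallback}.
#' @export
defaultAnnotationRules <- function(threshold = 0.5) {
    r <- function(type, pos, neg = character(0), immune = FALSE)
        list(cell_type = type, positive = pos, negative = neg,
             threshold = threshold, immune = immune)
    list(rules = list(
        r("epithelial", "panCK", "CD45"),
        r("mesenchymal", "vimentin", c("panCK", "CD45")),
        r("endothelial", "CD31", "CD45"),
        r("aSMA+ fibroblast", "aSMA", "CD45"),
        r("CD8+ T", c("CD45", "CD8a"), immune = TRUE),
        r("CD4+ T", c("CD45", "CD4"), "FOXP3", immune = TRUE),
        r("Treg", c("CD45", "FOXP3"), immune = TRUE),
        r("B", c("CD45", "CD20"), immune = TRUE),
        r("NK", c("CD45", "CD56"), immune = TRUE),
        r("neutrophil", c("CD45", "CD15"), immune = TRUE),
        r("resident macrophage", c("CD45", "CD68"), immune = TRUE)),
        fallback = "mixed immune")
}

#' Read annotation rules from YAML
#'
#' Expected structure: a top-level \code{fallback} string and a
#' \code{rules} list whose elements carry \code{cell_type},
#' \code{positive}, optional \code{negative}, optional \code{threshold}
#' (default 0.5) and optional \code{immune} flag.
#'
#' @param path YAML file.
#' @param markers optional marker vocabulary; referencing an unknown
#'   marker is an error at load time.
#' @return rule set in the format of [defaultAnnotationRules()].
#' @export
readAnnotationRules <- function(path, markers = NULL) {
    y <- yaml::read_yaml(path)
    if (is.null(y$fallback)) stop("rules file must declare a fallback")
    rules <- lapply(y$rules, function(r) {
        list(cell_type = r$cell_type,
             positive = as.character(unlist(r$positive)),
             negative = as.character(unlist(r$negative)),
             threshold = if (is.null(r$threshold)) 0.5 else r$threshold,
             immune = isTRUE(r$immune))
    })
    if (!is.null(markers)) {
        used <- unique(unlist(lapply(rules,
            function(r) c(r$positive, r$negative))))
        bad <- setdiff(used, markers)
        if (length(bad))
            stop("annotation rules reference unknown markers: ",
                 paste(bad, collapse = ", "))
    }
    list(rules = rules, fallback = y$fallback)
}

#' Annotate clusters by marker rules
#'
#' Computes per-cluster mean normalized expression; the first rule whose
#' positive markers all exceed and negative markers all fall below its
#' threshold wins. An immune cluster satisfying more than one immune
#' rule is labelled with the fallback ("mixed immune"); a cluster
#' matching no rule is labelled "unassigned" (kept, never dropped).
#' Annotation is a deterministic function of cluster means and rules.
#'
#' @param cells experiment with colData \code{cluster_id} and assay
#'   "norm".
#' @param rules rule set (see [defaultAnnotationRules()]).
#' @return the experiment with colData column \code{cell_type}.
#' @export
annotateClusters <- function(cells, rules = defaultAnnotationRules()) {
    norm <- SummarizedExperiment::assay(cells, "norm")
    used <- unique(unlist(lapply(rules$rules,
        function(r) c(r$positive, r$negative))))
    bad <- setdiff(used, rownames(norm))
    if (length(bad))
        stop("annotation rules reference unknown markers: ",
             paste(bad, collapse = ", "))
    cl <- cells$cluster_id
    if (is.null(cl)) stop("run clusterExpression() first")
    labels <- vapply(sort(unique(cl)), function(cid) {
        mu <- rowMeans(norm[, cl == cid, drop = FALSE])
        matches <- vapply(rules$rules, function(r) {
            all(mu[r$positive] > r$threshold) &&
                all(mu[r$negative] < r$threshold)
        }, logical(1))
        hit <- which(matches)
        if (!length(hit)) return("unassigned")
        immuneHits <- hit[vapply(rules$rules[hit],
                                 function(r) r$immune, logical(1))]
        if (length(immuneHits) > 1) return(rules$fallback)
        rules$rules[[hit[1]]]$cell_type
    }, character(1))
    cells$cell_type <- labels[match(cl, sort(unique(cl)))]
    cells
}

#' Composition summary and two-group tests
#'
#' Per-unit (default per-sample) cell-type fractions, plus a Wilcoxon
#' rank-sum test per cell type comparing per-sample fractions between
#' two groups.
#'
#' @param cells experiment with colData \code{cell_type}.
#' @param by colData column defining the summary unit (default
#'   "sample_id").
#' @param group colData column with exactly two levels for testing, or
#'   NULL to skip tests.
#' @param typeCol which colData column holds the type (default
#'   "cell_type"; "true_type" is useful on synthetic data).
#' @return list with \code{fractions} (long data.frame: unit, group,
#'   cell_type, n, fraction) and \code{tests} (cell_type, W, p.value,
#'   direction) or NULL.
#' @export
compositionSummary <- function(cells, by = "sample_id", group = "condition",
                               typeCol = "cell_type") {
    cd <- cellData(cells)
    if (!typeCol %in% names(cd)) stop("missing column ", typeCol)
    types <- sort(unique(cd[[typeCol]]))
    units <- sort(unique(cd[[by]]))
    tab <- table(factor(cd[[by]], units), factor(cd[[typeCol]], types))
    frac <- tab / rowSums(tab)
    grp <- if (!is.null(group) && group %in% names(cd))
        cd[[group]][match(units, cd[[by]])] else rep(NA, length(units))
    fractions <- data.frame(
        unit = rep(units, times = length(types)),
        group = rep(grp, times = length(types)),
        cell_type = rep(types, each = length(units)),
        n = as.vector(tab), fraction = as.vector(frac),
        stringsAsFactors = FALSE)
    tests <- NULL
    lv <- unique(stats::na.omit(grp))
    if (length(lv) == 2) {
        tests <- do.call(rbind, lapply(types, function(ty) {
            f1 <- frac[grp == lv[1], ty]
            f2 <- frac[grp == lv[2], ty]
            if (length(f1) < 1 || length(f2) < 1) return(NULL)
            wt <- suppressWarnings(stats::wilcox.test(f1, f2))
            data.frame(cell_type = ty, W = unname(wt$statistic),
                       p.value = wt$p.value,
                       direction = sprintf("%s %s %s", lv[1],
                           ifelse(mean(f1) >= mean(f2), ">=", "<"), lv[2]),
                       stringsAsFactors = FALSE)
        }))
    }
    list(fractions = fractions, tests = tests)
}
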