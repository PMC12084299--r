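# Pipeline orchestration and figure rendering.
#
# Every stage writes its table to the output directory; a manifest
# records parameters, seed and per-table checksums so a re-run with the
# same configuration is verifiably identical. Figures are pure
# functions of the on-disk CSVs.

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level fields \code{output_dir}, \code{seed},
#' \code{params} (median_window, adjust, q, k_expr, k_spatial, k_cn,
#' n_perm, alpha, threshold, enrichment_factor), and either
#' \code{images_dir} (+ optional \code{panel}, \code{spillover},
#' \code{rules}) or \code{simulate} (arguments of [CohortSpec()]).
#' Referenced files must exist at load time.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
    if (is.null(cfg$output_dir)) stop("config must set output_dir")
    if (is.null(cfg$seed)) cfg$seed <- 1L
    p <- cfg$params
    defaults <- list(median_window = 3L, adjust = c(1, 99), q = 99,
                     k_expr = 30L, k_spatial = 20L, k_cn = 10L,
                     n_perm = 1000L, alpha = 0.05, threshold = 0.5,
                     enrichment_factor = 1.5)
    for (nm in names(defaults))
        if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
    stopifnot(p$median_window %% 2 == 1, p$q > 0, p$q <= 100,
              p$alpha > 0, p$alpha < 1)
    cfg$params <- p
    if (is.null(cfg$simulate)) {
        if (is.null(cfg$images_dir))
            stop("config needs either images_dir or simulate")
        for (f in c(cfg$images_dir, cfg$panel, cfg$spillover, cfg$rules))
            if (!is.null(f) && !file.exists(f))
                stop("configured path does not exist: ", f)
    }
    cfg
}

writeStage <- function(df, dir, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> normalize -> cluster -> annotate ->
#' neighbourhoods -> interactions -> reports. Input ROIs either come
#' from \code{config$images_dir} (TIFF stacks + masks + JSON sidecars
#' as written by [writeROI()]) or are simulated from
#' \code{config$simulate}. Each stage writes its table into
#' \code{config$output_dir}; a manifest records the package version,
#' seed, parameters and an md5 checksum per table. Re-running the same
#' config reproduces byte-identical tables.
#'
#' @param config a config list (see [readRunConfig()]) or path to YAML.
#' @param figures also render summary figures (default TRUE).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, figures = TRUE) {
    if (is.character(config)) config <- readRunConfig(config)
    else config <- validateRunConfig(config)
    p <- config$params
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stageFail <- function(stage, e)
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE)

    # ---- acquire ROIs
    rois <- tryCatch({
        if (!is.null(config$simulate)) {
            spec <- do.call(CohortSpec,
                            c(config$simulate, list(seed = config$seed)))
            sim <- generateCohort(spec, render = TRUE)
            sim$rois
        } else {
            metas <- list.files(config$images_dir,
                                pattern = "_meta\\.json$",
                                full.names = FALSE)
            if (!length(metas))
                stop("no ROIs found under ", config$images_dir)
            ids <- sub("_meta\\.json$", "", metas)
            stats::setNames(
                lapply(ids, function(i) readROI(config$images_dir, i)),
                ids)
        }
    }, error = function(e) stageFail("load", e))

    S <- if (!is.null(config$spillover)) readSpillover(config$spillover)
         else NULL

    # ---- quantify
    cells <- tryCatch({
        quantified <- lapply(names(rois), function(rid)
            tryCatch(preprocessROI(rois[[rid]], S = S,
                                   window = p$median_window,
                                   adjust = p$adjust),
                     error = function(e)
                         stop("ROI ", rid, ": ", conditionMessage(e))))
        do.call(BiocGenerics::cbind, quantified)
    }, error = function(e) stageFail("quantify", e))

    # ---- normalize, cluster, annotate
    cells <- tryCatch(normalizePercentile(cells, q = p$q),
                      error = function(e) stageFail("normalize", e))
    panel <- if (!is.null(config$panel)) readPanel(config$panel)
             else defaultPanel()
    cells <- tryCatch(
        clusterExpression(cells, k = p$k_expr, seed = config$seed,
                          panel = panel),
        error = function(e) stageFail("cluster", e))
    rules <- if (!is.null(config$rules))
        readAnnotationRules(config$rules, rownames(cells))
        else defaultAnnotationRules(p$threshold)
    cells <- tryCatch(annotateClusters(cells, rules),
                      error = function(e) stageFail("annotate", e))

    # ---- neighbourhoods
    nb <- tryCatch({
        graph <- spatialKnn(cells, k = p$k_spatial)
        prof <- neighborhoodProfiles(graph, cells)
        model <- clusterNeighborhoods(prof, kCn = p$k_cn,
                                      seed = config$seed)
        model <- annotateCNs(model, factor = p$enrichment_factor)
        list(graph = graph, model = model)
    }, error = function(e) stageFail("neighborhoods", e))
    cells <- addCN(cells, nb$model)

    # ---- interactions
    inter <- tryCatch(
        testInteractions(nb$graph, cells, nPerm = p$n_perm,
                         seed = config$seed, alpha = p$alpha),
        error = function(e) stageFail("interactions", e))

    # ---- stage tables
    cd <- cellData(cells)
    paths <- character(0)
    paths["cells"] <- writeStage(cd, out, "cells")
    norm <- SummarizedExperiment::assay(cells, "norm")
    clMeans <- t(vapply(sort(unique(cd$cluster_id)), function(cid)
        rowMeans(norm[, cd$cluster_id == cid, drop = FALSE]),
        numeric(nrow(norm))))
    clTab <- data.frame(cluster_id = sort(unique(cd$cluster_id)),
                        cell_type = cd$cell_type[
                            match(sort(unique(cd$cluster_id)),
                                  cd$cluster_id)],
                        clMeans, check.names = FALSE)
    paths["cluster_mean_expression"] <-
        writeStage(clTab, out, "cluster_mean_expression")
    comp <- compositionSummary(cells)
    paths["composition_fractions"] <-
        writeStage(comp$fractions, out, "composition_fractions")
    if (!is.null(comp$tests))
        paths["composition_tests"] <-
            writeStage(comp$tests, out, "composition_tests")
    cen <- data.frame(cn = rownames(cnCentroids(nb$model)),
                      label = nb$model@labels,
                      cnCentroids(nb$model), check.names = FALSE)
    paths["cn_centroids"] <- writeStage(cen, out, "cn_centroids")
    cnab <- cnAbundanceCompare(cells)
    paths["cn_fractions"] <- writeStage(cnab$fractions, out,
                                        "cn_fractions")
    if (!is.null(cnab$tests))
        paths["cn_tests"] <- writeStage(cnab$tests, out, "cn_tests")
    paths["interactions"] <- writeStage(inter, out, "interactions")
    roiGroups <- vapply(rois, function(r) r@groups[["condition"]],
                        character(1))
    if (length(unique(roiGroups)) == 2) {
        gc <- compareInteractionsGroups(
            inter[, c("roi_id", "from_type", "to_type", "observed")],
            roiGroups)
        if (!is.null(gc))
            paths["interactions_group_comparison"] <-
                writeStage(gc, out, "interactions_group_comparison")
    }

    # ---- manifest
    manifest <- list(
        package = "imcniche",
        version = as.character(utils::packageVersion("imcniche")),
        seed = config$seed,
        params = p,
        n_rois = length(rois),
        n_cells = ncol(cells),
        checksums = as.list(tools::md5sum(unname(paths))))
    names(manifest$checksums) <- basename(unname(paths))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    yaml::write_yaml(config, file.path(out, "config.yaml"))

    if (figures)
        renderSummaryFigures(out, cells = cells)
    invisible(out)
}

#' Render summary figures from stage tables
#'
#' Reads the CSV tables written by [runPipeline()] and renders the
#' figure analogs: cluster x marker expression heatmap, stacked
#' per-sample composition bars, CN abundance heatmap and the directed
#' interaction classification heatmap. A missing table skips its figure
#' with a warning; every figure is re-derivable from its CSV.
#'
#' @param dir pipeline output directory.
#' @param cells optional cell experiment; when given, a Voronoi map of
#'   the first ROI is also rendered.
#' @return invisibly, the figure paths written.
#' @export
renderSummaryFigures <- function(dir, cells = NULL) {
    done <- character(0)
    save <- function(plot, name, w = 7, h = 5) {
        path <- file.path(dir, paste0(name, ".png"))
        ggplot2::ggsave(path, plot, width = w, height = h, dpi = 150)
        done[[name]] <<- path
    }
    tab <- function(name) {
        path <- file.path(dir, paste0(name, ".csv"))
        if (!file.exists(path)) {
            warning("table ", name, ".csv missing; figure skipped")
            return(NULL)
        }
        utils::read.csv(path, check.names = FALSE)
    }
    cl <- tab("cluster_mean_expression")
    if (!is.null(cl) && nrow(cl)) {
        long <- do.call(rbind, lapply(names(cl)[-(1:2)], function(m)
            data.frame(cluster = paste0(cl$cluster_id, ": ",
                                        cl$cell_type),
                       marker = m, mean = cl[[m]])))
        save(ggplot2::ggplot(long, ggplot2::aes(marker,
                cluster, fill = mean)) +
            ggplot2::geom_tile() +
            ggplot2::scale_fill_viridis_c() +
            ggplot2::theme_minimal() +
            ggplot2::theme(axis.text.x =
                ggplot2::element_text(angle = 90, vjust = 0.5)),
            "fig_cluster_heatmap", w = 9)
    }
    comp <- tab("composition_fractions")
    if (!is.null(comp) && nrow(comp)) {
        save(ggplot2::ggplot(comp, ggplot2::aes(unit,
                100 * fraction, fill = cell_type)) +
            ggplot2::geom_col() +
            ggplot2::facet_grid(~group, scales = "free_x",
                                space = "free_x") +
            ggplot2::labs(y = "% of cells", x = NULL) +
            ggplot2::theme_minimal() +
            ggplot2::theme(axis.text.x =
                ggplot2::element_text(angle = 90, vjust = 0.5)),
            "fig_composition_bars", w = 9)
    }
    cn <- tab("cn_fractions")
    if (!is.null(cn) && nrow(cn)) {
        save(ggplot2::ggplot(cn, ggplot2::aes(cn, unit,
                fill = fraction)) +
            ggplot2::geom_tile() +
            ggplot2::scale_fill_viridis_c() +
            ggplot2::theme_minimal(),
            "fig_cn_abundance")
    }
    inter <- tab("interactions")
    if (!is.null(inter)) {
        if (!nrow(inter)) {
            warning("interaction table empty; heatmap skipped")
        } else {
            agg <- stats::aggregate(
                cbind(enrich = inter$classification == "interaction",
                      avoid = inter$classification == "avoidance"),
                by = list(from_type = inter$from_type,
                          to_type = inter$to_type),
                FUN = mean, na.rm = TRUE)
            agg$score <- agg$enrich - agg$avoid
            save(ggplot2::ggplot(agg, ggplot2::aes(to_type,
                    from_type, fill = score)) +
                ggplot2::geom_tile() +
                ggplot2::scale_fill_gradient2(low = "blue",
                    high = "orange", limits = c(-1, 1)) +
                ggplot2::labs(fill = "interaction - avoidance\n(fraction of ROIs)") +
                ggplot2::theme_minimal() +
                ggplot2::theme(axis.text.x =
                    ggplot2::element_text(angle = 90, vjust = 0.5)),
                "fig_interactions", w = 8, h = 6)
        }
    }
    if (!is.null(cells) && "cell_type" %in%
        names(SummarizedExperiment::colData(cells))) {
        v <- tryCatch(renderVoronoi(cells), warning = function(w) NULL,
                      error = function(e) NULL)
        if (!is.null(v)) save(v, "fig_voronoi", w = 7, h = 7)
    }
    invisible(done)
}
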