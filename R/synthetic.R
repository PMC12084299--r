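# Synthetic-tissue cohort generator.
#
# Emulates a multi-ROI imaging-mass-cytometry cohort with known ground
# truth: typed cells placed by homogeneous Poisson / Neyman-Scott
# processes with optional hard-core cross-type avoidance and planted
# niches, hard-disc rendering into a label mask, lognormal marker
# expression plus background, channel spillover and Poisson counting
# noise. Every downstream stage of the package is validated against the
# truth this module records.

#' The twelve salivary-gland cell populations
#'
#' Default cell-type vocabulary of the simulator: four structural
#' populations (epithelial, mesenchymal, endothelial, aSMA+ fibroblast)
#' and eight immune populations (CD8+ T, CD4+ T, Treg, B, NK,
#' neutrophil, resident macrophage, mixed immune), as typically resolved
#' in labial-salivary-gland IMC panels.
#'
#' @return character vector of length 12.
#' @export
lsgCellTypes <- function() {
    c("epithelial", "mesenchymal", "endothelial", "aSMA+ fibroblast",
      "CD8+ T", "CD4+ T", "Treg", "B", "NK", "neutrophil",
      "resident macrophage", "mixed immune")
}

#' Default antibody panel
#'
#' A compact synthetic stand-in for a full IMC panel: one defining
#' lineage marker per structural population, canonical immune lineage
#' markers, a handful of functional/inflammatory markers, two
#' disease-associated (pSS) markers and a DNA channel.
#'
#' @return data.frame with columns channel, metal, marker, category
#'   (category in lineage / functional / pSS_marker / dna).
#' @export
defaultPanel <- function() {
    marker <- c("panCK", "vimentin", "CD31", "aSMA", "CD45", "CD8a",
                "CD4", "FOXP3", "CD20", "CD56", "CD15", "CD68",
                "IL1b", "S100A9", "CCR7", "CXCL13", "MMP9", "Ki67",
                "SSA", "SSB", "DNA1")
    category <- c(rep("lineage", 12), rep("functional", 6),
                  rep("pSS_marker", 2), "dna")
    data.frame(
        channel = seq_along(marker),
        metal = sprintf("M%03d", 140 + seq_along(marker)),
        marker = marker,
        category = category,
        stringsAsFactors = FALSE
    )
}

#' Default lognormal expression model
#'
#' Per (cell type, marker) lognormal location/scale parameters. Each
#' population expresses its defining lineage marker(s) at a high level
#' (meanlog log(10)) over a low base (meanlog log(0.3)); all immune
#' populations share CD45; the "mixed immune" population carries two
#' immune lineage signals (CD8a and CD20) so that rule-based annotation
#' resolves it through the mixed-immune fallback. These values are
#' synthetic defaults, not estimates from any measured tissue.
#'
#' @param cellTypes type vocabulary (default [lsgCellTypes()]).
#' @param panel panel table (default [defaultPanel()]).
#' @param high,low meanlog of expressed / unexpressed markers.
#' @param sdlogHigh,sdlogLow lognormal scale for expressed / unexpressed.
#' @return list(meanlog, sdlog, markers) with types x markers matrices.
#' @export
defaultExpressionModel <- function(cellTypes = lsgCellTypes(),
                                   panel = defaultPanel(),
                                   high = log(10), low = log(0.3),
                                   sdlogHigh = 0.2, sdlogLow = 0.25) {
    markers <- panel$marker
    T <- length(cellTypes)
    M <- length(markers)
    meanlog <- matrix(low, T, M, dimnames = list(cellTypes, markers))
    sdlog <- matrix(sdlogLow, T, M, dimnames = list(cellTypes, markers))
    setHigh <- function(type, ms, value = high) {
        type <- intersect(type, cellTypes)
        ms <- intersect(ms, markers)
        if (!length(type) || !length(ms)) return(invisible())
        meanlog[type, ms] <<- value
        sdlog[type, ms] <<- sdlogHigh
    }
    setHigh("epithelial", "panCK")
    setHigh("mesenchymal", "vimentin")
    setHigh("endothelial", "CD31")
    setHigh("aSMA+ fibroblast", "aSMA")
    immune <- c("CD8+ T", "CD4+ T", "Treg", "B", "NK", "neutrophil",
                "resident macrophage", "mixed immune")
    for (ty in immune) setHigh(ty, "CD45")
    setHigh("CD8+ T", "CD8a")
    setHigh("CD4+ T", "CD4")
    setHigh("Treg", "FOXP3")
    if ("Treg" %in% cellTypes)
        meanlog["Treg", "CD4"] <- log(3)  # physiologic CD4-dim Treg
    setHigh("B", "CD20")
    setHigh("NK", "CD56")
    setHigh("neutrophil", "CD15")
    setHigh("resident macrophage", "CD68")
    setHigh("mixed immune", c("CD8a", "CD20"))
    # DNA present in every nucleus; functional markers at a broad low base
    setHigh(cellTypes, "DNA1", log(8))
    fm <- panel$marker[panel$category %in% c("functional", "pSS_marker")]
    meanlog[, fm] <- log(0.5)
    sdlog[, fm] <- 0.6
    list(meanlog = meanlog, sdlog = sdlog, markers = markers)
}

#' Default per-group composition
#'
#' Two clinical groups. The control composition carries ~14.5% immune
#' cells, the case composition ~27.6%, the range reported for
#' low- versus high-infiltration labial salivary glands; the per-type
#' split within those totals is a synthetic choice.
#'
#' @return named list of simplex vectors over [lsgCellTypes()].
#' @export
defaultProportions <- function() {
    types <- lsgCellTypes()
    control <- c(0.520, 0.140, 0.100, 0.095,
                 0.030, 0.015, 0.010, 0.020, 0.010, 0.010, 0.025, 0.025)
    case <- c(0.400, 0.130, 0.100, 0.094,
              0.070, 0.030, 0.015, 0.040, 0.012, 0.014, 0.035, 0.060)
    names(control) <- names(case) <- types
    list(control = control, case = case)
}

#' Construct a synthetic-cohort specification
#'
#' @param nSamplesPerGroup samples per clinical group.
#' @param roisPerSample ROIs acquired per sample.
#' @param roiWidth,roiHeight ROI size in px.
#' @param meanCellsPerRoi expected cell count per ROI (Poisson).
#' @param cellTypes type vocabulary.
#' @param proportions named list of per-group simplex vectors.
#' @param attractionPairs list of attraction specs, each
#'   \code{list(typeA=, typeB=, clusterRadius=, offspringPerParent=)}:
#'   typeB cells are placed as Neyman-Scott offspring around typeA
#'   parents within clusterRadius px.
#' @param avoidancePairs list of \code{list(typeA=, typeB=,
#'   exclusionRadius=)}: no A-B pair closer than exclusionRadius px.
#' @param nicheLayout NULL or list of regions \code{list(name=, xmin=,
#'   xmax=, ymin=, ymax=, proportions=)}, coordinates relative in [0,1];
#'   regions should partition the ROI.
#' @param expressionModel see [defaultExpressionModel()].
#' @param backgroundRate constant background intensity per pixel.
#' @param spillover square spillover matrix over panel markers or NULL.
#' @param cellRadius rendered disc radius, px.
#' @param noise "poisson" (counting noise on every pixel) or "none".
#' @param seed master seed; per-ROI seeds are derived from it.
#' @return validated [CohortSpec-class].
#' @export
CohortSpec <- function(nSamplesPerGroup = 3L, roisPerSample = 2L,
                       roiWidth = 400L, roiHeight = 400L,
                       meanCellsPerRoi = 500,
                       cellTypes = lsgCellTypes(),
                       proportions = defaultProportions(),
                       attractionPairs = list(),
                       avoidancePairs = list(),
                       nicheLayout = NULL,
                       expressionModel = defaultExpressionModel(cellTypes),
                       backgroundRate = 0.05,
                       spillover = NULL,
                       cellRadius = 3,
                       noise = "poisson",
                       seed = 1L) {
    new("CohortSpec",
        nSamplesPerGroup = as.integer(nSamplesPerGroup),
        roisPerSample = as.integer(roisPerSample),
        roiWidth = as.integer(roiWidth), roiHeight = as.integer(roiHeight),
        meanCellsPerRoi = meanCellsPerRoi,
        cellTypes = cellTypes, proportions = proportions,
        attractionPairs = attractionPairs, avoidancePairs = avoidancePairs,
        nicheLayout = nicheLayout, expressionModel = expressionModel,
        backgroundRate = backgroundRate, spillover = spillover,
        cellRadius = cellRadius, noise = noise, seed = as.integer(seed))
}

# ---- point placement -------------------------------------------------------

# Sequential hard-core placement. Returns data.frame(x, y, type, niche).
# Proposals come from each cell's generative mechanism (uniform within the
# ROI or niche region, or Neyman-Scott around an attraction parent) and are
# rejected while they violate the hard-core 2*cellRadius overlap rule or an
# avoidance exclusion; after `maxTry` rejections the ROI is declared
# unpackable.
placeCells <- function(spec, group, n, roiName, maxTry = 100L) {
    W <- spec@roiWidth; H <- spec@roiHeight
    r <- spec@cellRadius
    types <- spec@cellTypes
    niche <- spec@nicheLayout

    if (n == 0L)
        return(data.frame(x = numeric(0), y = numeric(0),
                          type = character(0), niche = integer(0)))

    # draw the type (and niche) of every cell
    if (is.null(niche)) {
        p <- spec@proportions[[group]]
        cellType <- sample(types, n, replace = TRUE, prob = p)
        cellNiche <- rep(NA_integer_, n)
    } else {
        areas <- vapply(niche, function(nl)
            (nl$xmax - nl$xmin) * (nl$ymax - nl$ymin), numeric(1))
        cellNiche <- sample(seq_along(niche), n, replace = TRUE,
                            prob = areas)
        cellType <- vapply(seq_len(n), function(i)
            sample(types, 1, prob = niche[[cellNiche[i]]]$proportions),
            character(1))
    }

    offspringOf <- rep(NA_character_, n)  # parent type for attraction pairs
    attr <- spec@attractionPairs
    for (ap in attr)
        offspringOf[cellType == ap$typeB] <- ap$typeA

    # avoidance partners per type
    avoidPartners <- function(ty) {
        out <- list()
        for (av in spec@avoidancePairs) {
            if (ty == av$typeA) out[[length(out) + 1]] <-
                list(other = av$typeB, d = av$exclusionRadius)
            if (ty == av$typeB) out[[length(out) + 1]] <-
                list(other = av$typeA, d = av$exclusionRadius)
        }
        out
    }

    # parents (non-offspring) first so attraction offspring can anchor
    ord <- order(!is.na(offspringOf), seq_len(n))
    x <- numeric(n); y <- numeric(n)
    placed <- logical(n)
    hard2 <- (2 * r)^2

    uniformIn <- function(i) {
        if (!is.null(niche) && !is.na(cellNiche[i])) {
            nl <- niche[[cellNiche[i]]]
            lo <- c(max(r, nl$xmin * W), max(r, nl$ymin * H))
            hi <- c(min(W - r, nl$xmax * W), min(H - r, nl$ymax * H))
        } else {
            lo <- c(r, r); hi <- c(W - r, H - r)
        }
        c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    }

    for (i in ord) {
        ty <- cellType[i]
        av <- avoidPartners(ty)
        # attraction anchors: placed cells of the parent type
        parents <- NULL
        if (!is.na(offspringOf[i])) {
            pidx <- which(placed & cellType == offspringOf[i])
            if (length(pidx)) {
                ap <- Filter(function(a) a$typeB == ty, attr)[[1]]
                nPar <- max(1L, ceiling(sum(cellType == ty) /
                                        ap$offspringPerParent))
                # deterministic parent pool per ROI: first nPar placed parents
                parents <- pidx[seq_len(min(nPar, length(pidx)))]
                clusterR <- ap$clusterRadius
            }
        }
        ok <- FALSE
        for (tr in seq_len(maxTry)) {
            if (!is.null(parents)) {
                pj <- parents[sample.int(length(parents), 1)]
                ang <- stats::runif(1, 0, 2 * pi)
                rad <- clusterR * sqrt(stats::runif(1))
                pos <- c(x[pj] + rad * cos(ang), y[pj] + rad * sin(ang))
                if (pos[1] < r || pos[1] > W - r ||
                    pos[2] < r || pos[2] > H - r) next
            } else {
                pos <- uniformIn(i)
            }
            idx <- which(placed)
            if (length(idx) &&
                any((x[idx] - pos[1])^2 + (y[idx] - pos[2])^2 < hard2))
                next
            bad <- FALSE
            for (a in av) {
                oidx <- idx[cellType[idx] == a$other]
                if (length(oidx) &&
                    any((x[oidx] - pos[1])^2 + (y[oidx] - pos[2])^2 <
                        a$d^2)) { bad <- TRUE; break }
            }
            if (bad) next
            x[i] <- pos[1]; y[i] <- pos[2]; placed[i] <- TRUE
            ok <- TRUE
            break
        }
        if (!ok)
            stop(sprintf(
                "packing failure in ROI %s: could not place cell %d (%s) after %d attempts",
                roiName, i, ty, maxTry))
    }
    data.frame(x = x, y = y, type = cellType, niche = cellNiche,
               stringsAsFactors = FALSE)
}

# ---- rendering -------------------------------------------------------------

# Render hard discs into a label mask and build the noisy intensity stack.
# Returns list(mask, intensities, area, centroidObs).
renderROI <- function(spec, pts, trueExpr) {
    W <- spec@roiWidth; H <- spec@roiHeight
    r <- spec@cellRadius
    markers <- spec@expressionModel$markers
    C <- length(markers)
    n <- nrow(pts)
    mask <- matrix(0L, H, W)
    # pixel (row i, col j) has centre (x = j - 1, y = i - 1)
    for (i in seq_len(n)) {
        cx <- pts$x[i]; cy <- pts$y[i]
        js <- max(1L, floor(cx + 1 - r)):min(W, ceiling(cx + 1 + r))
        is <- max(1L, floor(cy + 1 - r)):min(H, ceiling(cy + 1 + r))
        px <- expand.grid(i = is, j = js)
        keep <- (px$j - 1 - cx)^2 + (px$i - 1 - cy)^2 <= r^2
        mask[cbind(px$i[keep], px$j[keep])] <- i
    }
    stack <- array(spec@backgroundRate, dim = c(H, W, C))
    if (n > 0) {
        inCell <- which(mask > 0)
        lab <- mask[inCell]
        for (c in seq_len(C)) {
            ch <- stack[, , c]
            ch[inCell] <- ch[inCell] + trueExpr[lab, c]
            stack[, , c] <- ch
        }
    }
    if (!is.null(spec@spillover)) {
        S <- spec@spillover
        mixed <- array(0, dim = dim(stack))
        for (cOut in seq_len(C))
            for (cIn in seq_len(C))
                if (S[cIn, cOut] != 0)
                    mixed[, , cOut] <- mixed[, , cOut] +
                        S[cIn, cOut] * stack[, , cIn]
        stack <- mixed
    }
    if (spec@noise == "poisson")
        stack[] <- stats::rpois(length(stack), stack)
    area <- tabulate(mask[mask > 0], n)
    list(mask = mask, intensities = stack, area = area)
}

# ---- public generators -----------------------------------------------------

#' Generate one synthetic ROI
#'
#' Places typed cells by the processes declared in the spec (homogeneous
#' Poisson for unstructured types, Neyman-Scott offspring for attraction
#' pairs, hard-core thinning for avoidance pairs), optionally renders
#' non-overlapping discs into a label mask with a noisy multichannel
#' intensity stack, and returns the cells with their ground truth.
#'
#' @param spec a [CohortSpec-class].
#' @param group which group's composition to use (name in
#'   \code{spec@proportions}).
#' @param sampleId,roiId identifiers recorded on every cell.
#' @param seed integer stream seed; if NULL derived from the spec's
#'   master seed and the (sampleId, roiId) pair.
#' @param render if FALSE, skip mask/image rendering (fast path for
#'   point-pattern simulations); the returned \code{roi} is NULL and
#'   per-cell areas are NA.
#' @return list with elements \code{roi} ([SegmentedROI-class] or NULL),
#'   \code{cells} (a \code{SingleCellExperiment}: assay "raw" holds the
#'   true per-cell mean marker intensities, colData holds identifiers,
#'   centroids, area and ground-truth type/niche) and \code{truth}
#'   (list: perCell data.frame, plantedPairs).
#' @export
generateROI <- function(spec, group, sampleId = "s1", roiId = "r1",
                        seed = NULL, render = TRUE) {
    validObject(spec)
    if (!group %in% names(spec@proportions))
        stop("unknown group: ", group)
    if (is.null(seed))
        seed <- deriveSeed(spec@seed, sampleId, roiId)
    withSeed(seed, {
        n <- stats::rpois(1, spec@meanCellsPerRoi)
        roiName <- paste0(sampleId, "/", roiId)
        pts <- placeCells(spec, group, n, roiName)
        em <- spec@expressionModel
        C <- length(em$markers)
        trueExpr <- matrix(0, n, C, dimnames = list(NULL, em$markers))
        if (n > 0) {
            ti <- match(pts$type, spec@cellTypes)
            for (c in seq_len(C))
                trueExpr[, c] <- stats::rlnorm(n, em$meanlog[ti, c],
                                               em$sdlog[ti, c])
        }
        rend <- NULL
        if (render)
            rend <- renderROI(spec, pts, trueExpr)
    })
    cellIds <- if (n > 0) sprintf("%s_%s_c%04d", sampleId, roiId,
                                  seq_len(n)) else character(0)
    cd <- S4Vectors::DataFrame(
        cell_id = cellIds,
        roi_id = rep(paste0(sampleId, "_", roiId), n),
        sample_id = rep(sampleId, n),
        condition = rep(group, n),
        x = pts$x, y = pts$y,
        area = if (render && n > 0) rend$area else rep(NA_real_, n),
        true_type = pts$type,
        true_niche = pts$niche,
        row.names = cellIds)
    cells <- SingleCellExperiment::SingleCellExperiment(
        assays = list(raw = t(trueExpr)), colData = cd)
    roi <- NULL
    if (render)
        roi <- SegmentedROI(rend$intensities, rend$mask,
                            spec@expressionModel$markers,
                            pixelSize = 1,
                            roiId = paste0(sampleId, "_", roiId),
                            sampleId = sampleId,
                            groups = c(condition = group))
    truth <- list(
        perCell = data.frame(cell_id = cellIds, roi_id = cd$roi_id,
                             true_type = pts$type, true_niche = pts$niche,
                             stringsAsFactors = FALSE),
        plantedPairs = list(attraction = spec@attractionPairs,
                            avoidance = spec@avoidancePairs))
    list(roi = roi, cells = cells, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Iterates groups x samples x ROIs, deriving an independent seed per ROI
#' from the master seed, and concatenates the per-ROI cell tables. The
#' output is byte-identical across runs with the same spec.
#'
#' @param spec a [CohortSpec-class].
#' @param render render masks/images per ROI (default FALSE: cell-level
#'   simulation only, much faster).
#' @param sampleMetadata optional data.frame keyed by \code{sample_id}
#'   whose remaining columns (e.g. HE, SSA, response) are joined onto
#'   every cell of that sample.
#' @return list with \code{rois} (named list of [SegmentedROI-class],
#'   empty when render = FALSE), \code{cells} (one
#'   \code{SingleCellExperiment} of all cells) and \code{truth}.
#' @export
generateCohort <- function(spec, render = FALSE, sampleMetadata = NULL) {
    validObject(spec)
    groups <- names(spec@proportions)
    rois <- list()
    cellList <- list()
    truthList <- list()
    sampleIds <- character(0)
    for (g in groups) {
        for (s in seq_len(spec@nSamplesPerGroup)) {
            sid <- sprintf("%s_s%02d", g, s)
            if (sid %in% sampleIds)
                stop("duplicate sample identifier: ", sid)
            sampleIds <- c(sampleIds, sid)
            for (rr in seq_len(spec@roisPerSample)) {
                rid <- sprintf("r%02d", rr)
                out <- generateROI(spec, g, sid, rid, render = render)
                if (render)
                    rois[[paste0(sid, "_", rid)]] <- out$roi
                cellList[[paste0(sid, "_", rid)]] <- out$cells
                truthList[[paste0(sid, "_", rid)]] <- out$truth$perCell
            }
        }
    }
    cells <- do.call(BiocGenerics::cbind, unname(cellList))
    if (!is.null(sampleMetadata)) {
        stopifnot("sample_id" %in% names(sampleMetadata))
        m <- match(cells$sample_id, sampleMetadata$sample_id)
        for (col in setdiff(names(sampleMetadata), "sample_id"))
            SummarizedExperiment::colData(cells)[[col]] <-
                sampleMetadata[[col]][m]
    }
    truth <- list(perCell = do.call(rbind, unname(truthList)),
                  plantedPairs = list(attraction = spec@attractionPairs,
                                      avoidance = spec@avoidancePairs))
    list(rois = rois, cells = cells, truth = truth)
}

# ---- planted-structure study scenarios -------------------------------------

#' Planted-structure validation scenarios
#'
#' Ready-made cohort specifications with known spatial structure, used
#' to validate the interaction/avoidance test and CN discovery.
#'
#' \code{plantedAttractionSpec()}: Neyman-Scott attraction of CD8+ T
#' offspring around epithelial parents (cluster radius 15 px, 2
#' offspring per parent) in a co-dominant two-type composition
#' (epithelial and CD8+ T at 0.35 each) on a 600 x 600 px ROI at the
#' simulator's default cell density. The co-dominant composition and the
#' larger ROI give the CN-window statistic adequate sensitivity to
#' clustering at a scale (15 px) well below the window radius.
#'
#' \code{plantedAvoidanceSpec()}: hard-core avoidance (exclusion 40 px)
#' between CD8+ T and B cells, both at 0.12, on the default ROI.
#'
#' \code{plantedNicheSpec(n)}: 2 or 4 contiguous niches with disjoint
#' dominant compositions (vertical halves, or quadrants), for CN
#' recovery checks.
#'
#' @param seed master seed.
#' @param n number of niches (2 or 4).
#' @return a [CohortSpec-class].
#' @export
plantedAttractionSpec <- function(seed = 1L) {
    types <- lsgCellTypes()
    p <- stats::setNames(rep(0.30 / 10, length(types)), types)
    p["epithelial"] <- 0.35
    p["CD8+ T"] <- 0.35
    p <- p / sum(p)
    CohortSpec(roiWidth = 600L, roiHeight = 600L, meanCellsPerRoi = 1125,
               proportions = list(control = p, case = p),
               attractionPairs = list(list(typeA = "epithelial",
                   typeB = "CD8+ T", clusterRadius = 15,
                   offspringPerParent = 2)),
               seed = seed)
}

#' @rdname plantedAttractionSpec
#' @export
plantedAvoidanceSpec <- function(seed = 1L) {
    types <- lsgCellTypes()
    p <- stats::setNames(rep(0.76 / 10, length(types)), types)
    p["CD8+ T"] <- 0.12
    p["B"] <- 0.12
    p <- p / sum(p)
    CohortSpec(proportions = list(control = p, case = p),
               avoidancePairs = list(list(typeA = "CD8+ T", typeB = "B",
                   exclusionRadius = 40)),
               seed = seed)
}

#' @rdname plantedAttractionSpec
#' @export
plantedNicheSpec <- function(n = 2, seed = 1L) {
    types <- lsgCellTypes()
    dominant <- function(dom) {
        p <- stats::setNames(rep(0.10 / (length(types) - length(dom)),
                                 length(types)), types)
        p[dom] <- 0.90 / length(dom)
        p / sum(p)
    }
    if (n == 2) {
        layout <- list(
            list(name = "epithelial", xmin = 0, xmax = 0.5, ymin = 0,
                 ymax = 1, proportions = dominant("epithelial")),
            list(name = "immune", xmin = 0.5, xmax = 1, ymin = 0,
                 ymax = 1, proportions = dominant(c("CD8+ T", "B"))))
    } else if (n == 4) {
        doms <- list(c("epithelial", "mesenchymal"),
                     c("CD8+ T", "B"),
                     c("endothelial", "aSMA+ fibroblast"),
                     c("resident macrophage", "NK"))
        rects <- list(c(0, 0.5, 0, 0.5), c(0.5, 1, 0, 0.5),
                      c(0, 0.5, 0.5, 1), c(0.5, 1, 0.5, 1))
        layout <- lapply(1:4, function(i)
            list(name = paste(doms[[i]], collapse = "+"),
                 xmin = rects[[i]][1], xmax = rects[[i]][2],
                 ymin = rects[[i]][3], ymax = rects[[i]][4],
                 proportions = dominant(doms[[i]])))
    } else stop("n must be 2 or 4")
    CohortSpec(meanCellsPerRoi = 800, nicheLayout = layout, seed = seed)
}
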