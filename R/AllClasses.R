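#' @import methods
NULL

# intensities are stored H x W x C (row = y, col = x, 0-based pixel centers
# at integer coordinates); mask is H x W with 0 = background.

#' SegmentedROI: one acquisition window with its segmentation
#'
#' Container for a single region of interest (ROI): the multichannel
#' intensity stack, the integer cell label mask produced by segmentation,
#' channel names matching the antibody panel, and acquisition metadata.
#'
#' @slot intensities numeric array, H x W x C, finite and nonnegative.
#' @slot mask integer matrix H x W; 0 is background, positive labels are cells.
#' @slot channelNames character vector of length C.
#' @slot pixelSize physical pixel edge length in micrometres.
#' @slot roiId,sampleId identifiers.
#' @slot groups named character vector of group labels (e.g. condition).
#'
#' @exportClass SegmentedROI
setClass("SegmentedROI",
    representation(
        intensities = "array",
        mask = "matrix",
        channelNames = "character",
        pixelSize = "numeric",
        roiId = "character",
        sampleId = "character",
        groups = "character"
    )
)

setValidity("SegmentedROI", function(object) {
    msg <- NULL
    d <- dim(object@intensities)
    if (length(d) != 3L)
        msg <- c(msg, "intensities must be a 3-d array (H x W x C)")
    else {
        if (d[3] != length(object@channelNames))
            msg <- c(msg, "channel count must equal length(channelNames)")
        if (!all(dim(object@mask) == d[1:2]))
            msg <- c(msg, "mask dimensions must match intensities H x W")
    }
    if (any(!is.finite(object@intensities)) || any(object@intensities < 0))
        msg <- c(msg, "intensities must be finite and >= 0")
    if (any(object@mask < 0))
        msg <- c(msg, "mask labels must be nonnegative")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SegmentedROI
#'
#' @param intensities H x W x C numeric array of channel intensities.
#' @param mask H x W integer label mask (0 = background).
#' @param channelNames character vector naming the C channels.
#' @param pixelSize pixel edge length in micrometres (default 1).
#' @param roiId,sampleId identifiers.
#' @param groups named character vector of group labels.
#' @return A [SegmentedROI-class] object.
#' @export
SegmentedROI <- function(intensities, mask, channelNames,
                         pixelSize = 1, roiId = "roi1", sampleId = "s1",
                         groups = c(condition = "unknown")) {
    storage.mode(mask) <- "integer"
    new("SegmentedROI", intensities = intensities, mask = mask,
        channelNames = channelNames, pixelSize = pixelSize,
        roiId = roiId, sampleId = sampleId, groups = groups)
}

#' @describeIn SegmentedROI channel intensity stack (H x W x C)
#' @param object,x a SegmentedROI
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @export
setMethod("intensities", "SegmentedROI", function(x) x@intensities)

#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @describeIn SegmentedROI integer label mask
#' @export
setMethod("cellMask", "SegmentedROI", function(x) x@mask)

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @describeIn SegmentedROI channel names
#' @export
setMethod("channelNames", "SegmentedROI", function(x) x@channelNames)

#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))
#' @export
setMethod("roiId", "SegmentedROI", function(x) x@roiId)

setMethod("show", "SegmentedROI", function(object) {
    d <- dim(object@intensities)
    cat("SegmentedROI", object@roiId, "(sample", object@sampleId, ")\n")
    cat(" ", d[1], "x", d[2], "px,", d[3], "channels,",
        max(object@mask), "cells\n")
    if (length(object@groups))
        cat("  groups:", paste(names(object@groups), object@groups,
            sep = "=", collapse = ", "), "\n")
})

#' CohortSpec: generative description of a synthetic IMC cohort
#'
#' Full specification of a simulated multi-ROI cohort: design (groups,
#' samples, ROIs), geometry (ROI size, cell radius), composition per
#' group, planted spatial structure (attraction pairs via a Neyman-Scott
#' scheme, hard-core avoidance pairs, optional niche layout), the
#' lognormal marker-expression model, and the noise model (background,
#' spillover, Poisson counting noise).
#'
#' @slot nSamplesPerGroup,roisPerSample,meanCellsPerRoi design counts.
#' @slot roiWidth,roiHeight ROI dimensions in pixels.
#' @slot cellTypes character vector of type names.
#' @slot proportions named list (one per group) of per-type simplex vectors.
#' @slot attractionPairs list of lists with fields typeA, typeB,
#'   clusterRadius (px), offspringPerParent.
#' @slot avoidancePairs list of lists with fields typeA, typeB,
#'   exclusionRadius (px).
#' @slot nicheLayout NULL, or a list of regions, each a list with fields
#'   name, xmin, xmax, ymin, ymax (relative coordinates in [0,1]) and
#'   proportions (simplex over cellTypes).
#' @slot expressionModel list with matrices meanlog and sdlog
#'   (types x markers) and character vector markers.
#' @slot backgroundRate mean background intensity added to every pixel.
#' @slot spillover square spillover matrix over markers, or NULL for none.
#' @slot cellRadius disc radius of a rendered cell, px.
#' @slot seed master seed; per-ROI streams are derived from it.
#'
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(
        nSamplesPerGroup = "integer",
        roisPerSample = "integer",
        roiWidth = "integer",
        roiHeight = "integer",
        meanCellsPerRoi = "numeric",
        cellTypes = "character",
        proportions = "list",
        attractionPairs = "list",
        avoidancePairs = "list",
        nicheLayout = "ANY",
        expressionModel = "list",
        backgroundRate = "numeric",
        spillover = "ANY",
        cellRadius = "numeric",
        noise = "character",
        seed = "integer"
    )
)

setValidity("CohortSpec", function(object) {
    msg <- NULL
    if (object@nSamplesPerGroup < 0L || object@roisPerSample < 0L ||
        object@meanCellsPerRoi < 0)
        msg <- c(msg, "design counts must be >= 0")
    if (object@roiWidth <= 2 * object@cellRadius ||
        object@roiHeight <= 2 * object@cellRadius)
        msg <- c(msg, "ROI dimensions must exceed 2 * cellRadius")
    for (g in names(object@proportions)) {
        p <- object@proportions[[g]]
        if (length(p) != length(object@cellTypes))
            msg <- c(msg, sprintf("proportions[%s] length != cellTypes", g))
        if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, sprintf("proportions[%s] must sum to 1", g))
        if (any(p < 0))
            msg <- c(msg, sprintf("proportions[%s] must be >= 0", g))
    }
    for (ap in object@attractionPairs)
        if (ap$clusterRadius <= 0)
            msg <- c(msg, "clusterRadius must be > 0")
    for (av in object@avoidancePairs)
        if (av$exclusionRadius < 0)
            msg <- c(msg, "exclusionRadius must be >= 0")
    if (!is.null(object@nicheLayout)) {
        for (nl in object@nicheLayout) {
            if (abs(sum(nl$proportions) - 1) > 1e-9)
                msg <- c(msg, "niche proportions must sum to 1")
        }
    }
    if (!object@noise %in% c("poisson", "none"))
        msg <- c(msg, "noise must be 'poisson' or 'none'")
    em <- object@expressionModel
    if (!all(c("meanlog", "sdlog", "markers") %in% names(em)))
        msg <- c(msg, "expressionModel needs meanlog, sdlog, markers")
    else if (!all(dim(em$meanlog) == c(length(object@cellTypes),
                                       length(em$markers))))
        msg <- c(msg, "expressionModel meanlog must be types x markers")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortSpec", function(object) {
    cat("CohortSpec:", length(names(object@proportions)), "groups x",
        object@nSamplesPerGroup, "samples x", object@roisPerSample,
        "ROIs\n")
    cat(" ", object@roiWidth, "x", object@roiHeight, "px, ~",
        object@meanCellsPerRoi, "cells/ROI,",
        length(object@cellTypes), "cell types,",
        length(object@expressionModel$markers), "markers\n")
    if (length(object@attractionPairs))
        cat("  attraction pairs:", length(object@attractionPairs), "\n")
    if (length(object@avoidancePairs))
        cat("  avoidance pairs:", length(object@avoidancePairs), "\n")
    if (!is.null(object@nicheLayout))
        cat("  niches:", length(object@nicheLayout), "\n")
})

#' SpatialGraph: per-ROI k-nearest-neighbour structure over cell centroids
#'
#' For every cell the ordered ids of its k nearest neighbours within the
#' same ROI (Euclidean distance on centroids; ties at the k-th distance
#' broken by ascending cell index). Neighbour lists never cross ROI
#' boundaries. Indices refer to columns of the cell experiment the graph
#' was built from.
#'
#' @slot k requested neighbour count.
#' @slot cellIds cell identifiers in experiment column order.
#' @slot roiIds per-cell ROI id, same order.
#' @slot rois named list; each element has fields \code{cells} (global
#'   column indices of the ROI's cells), \code{nn} (n x k' matrix of
#'   global neighbour indices, NA-padded when n - 1 < k) and \code{dist}
#'   (matching distances).
#'
#' @exportClass SpatialGraph
setClass("SpatialGraph",
    representation(
        k = "integer",
        cellIds = "character",
        roiIds = "character",
        rois = "list"
    )
)

setMethod("show", "SpatialGraph", function(object) {
    cat("SpatialGraph: k =", object@k, ",", length(object@cellIds),
        "cells in", length(object@rois), "ROI(s)\n")
})

#' CNModel: k-means model of cellular-neighbourhood composition profiles
#'
#' @slot kCn number of cellular neighbourhoods (CNs).
#' @slot centroids kCn x T matrix of mean composition profiles (rows on
#'   the simplex); row order is descending cluster size.
#' @slot assignments integer CN id per cell (1-based, size-ordered).
#' @slot types the T cell-type vocabulary (column names of centroids).
#' @slot globalFractions global type fractions used for enrichment.
#' @slot enrichment kCn x T matrix centroid / global fraction.
#' @slot labels per-CN annotation strings (after [annotateCNs()]).
#' @slot totWithinSS within-cluster sum of squares of the fitted model.
#'
#' @exportClass CNModel
setClass("CNModel",
    representation(
        kCn = "integer",
        centroids = "matrix",
        assignments = "integer",
        types = "character",
        globalFractions = "numeric",
        enrichment = "matrix",
        labels = "character",
        totWithinSS = "numeric"
    )
)

setMethod("show", "CNModel", function(object) {
    cat("CNModel:", object@kCn, "cellular neighbourhoods over",
        length(object@assignments), "cells\n")
    sz <- tabulate(object@assignments, object@kCn)
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
    if (length(object@labels))
        cat("  labels:", paste(sprintf("CN%d=%s", seq_along(object@labels),
            object@labels), collapse = "; "), "\n")
})

#' @export
setGeneric("cnIds", function(x) standardGeneric("cnIds"))
#' @describeIn CNModel per-cell CN assignment (integer vector)
#' @param x a CNModel
#' @export
setMethod("cnIds", "CNModel", function(x) x@assignments)

#' @export
setGeneric("cnCentroids", function(x) standardGeneric("cnCentroids"))
#' @describeIn CNModel centroid composition matrix (kCn x types)
#' @export
setMethod("cnCentroids", "CNModel", function(x) x@centroids)

#' @export
setGeneric("cnEnrichment", function(x) standardGeneric("cnEnrichment"))
#' @describeIn CNModel per-CN type enrichment over the global composition
#' @export
setMethod("cnEnrichment", "CNModel", function(x) x@enrichment)
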