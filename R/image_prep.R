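# Image preprocessing and per-cell quantification.
#
# Fixed pipeline order (as applied to the acquisitions this package
# models): spillover compensation -> median denoise -> linear intensity
# adjustment -> per-cell quantification from the label mask.

#' Validate a spillover matrix
#'
#' A spillover matrix S is square over channels with S[i, i] = 1 and
#' S[i, j] in [0, 1] the fraction of channel i signal observed in
#' channel j (rows index the source channel).
#'
#' @param S numeric matrix.
#' @return S (invisibly validated).
#' @export
validateSpillover <- function(S) {
    if (!is.matrix(S) || nrow(S) != ncol(S))
        stop("spillover matrix must be square")
    if (any(abs(diag(S) - 1) > 0))
        stop("spillover diagonal must be exactly 1")
    if (any(S < 0) || any(S > 1))
        stop("spillover entries must lie in [0, 1]")
    S
}

#' Synthetic adjacent-channel spillover matrix
#'
#' Convenience constructor of a plausible spillover pattern: each channel
#' bleeds \code{magnitude} of its signal into the next channel (the +1
#' mass neighbour), as dominant in mass cytometry.
#'
#' @param n number of channels.
#' @param magnitude off-diagonal bleed fraction.
#' @return n x n spillover matrix.
#' @export
syntheticSpillover <- function(n, magnitude = 0.03) {
    S <- diag(n)
    if (n > 1)
        S[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- magnitude
    S
}

#' Compensate channel spillover by non-negative unmixing
#'
#' Per pixel the observed channel vector o is unmixed by solving
#' min || t(S) x - o ||^2 subject to x >= 0. Pixels whose unconstrained
#' solution is already nonnegative take it directly; the remainder are
#' refined by active-set NNLS. If S is ill-conditioned (condition number
#' above \code{condMax}) a warning is emitted and every pixel goes
#' through NNLS, which is defined for any S.
#'
#' @param roi a [SegmentedROI-class].
#' @param S spillover matrix matching the ROI's channel count.
#' @param condMax condition-number threshold for the fast solve path.
#' @return the ROI with compensated intensities (mask unchanged).
#' @export
compensateSpillover <- function(roi, S, condMax = 1e8) {
    S <- validateSpillover(S)
    d <- dim(roi@intensities)
    C <- d[3]
    if (nrow(S) != C)
        stop("spillover dimension (", nrow(S),
             ") does not match channel count (", C, ")")
    O <- matrix(aperm(roi@intensities, c(3, 1, 2)), nrow = C)  # C x P
    A <- t(S)
    illCond <- kappa(A, exact = FALSE) > condMax
    if (illCond) {
        warning("spillover matrix is ill-conditioned; ",
                "falling back to per-pixel NNLS for every pixel")
        X <- matrix(NA_real_, C, ncol(O))
        neg <- rep(TRUE, ncol(O))
    } else {
        X <- solve(A, O)
        neg <- colSums(X < -1e-12) > 0
    }
    if (any(neg)) {
        idx <- which(neg)
        for (p in idx)
            X[, p] <- pracma::lsqnonneg(A, O[, p])$x
    }
    X[X < 0] <- 0
    out <- roi
    out@intensities <- aperm(array(X, dim = c(C, d[1], d[2])), c(2, 3, 1))
    out
}

#' Median-filter denoising
#'
#' Replaces each channel by its 2-D median filter with reflection edge
#' handling.
#'
#' @param roi a [SegmentedROI-class].
#' @param window odd window edge length (default 3).
#' @return the denoised ROI.
#' @export
denoiseMedian <- function(roi, window = 3L) {
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        stop("window must be an odd integer >= 1")
    out <- roi
    for (c in seq_len(dim(roi@intensities)[3]))
        out@intensities[, , c] <-
            cppMedianFilter(roi@intensities[, , c], window)
    out
}

#' Linear intensity adjustment
#'
#' Per channel, rescales so the \code{lowPct} percentile maps to 0 and
#' the \code{highPct} percentile maps to its own (pre-adjustment) value;
#' values outside the window are clipped. Percentiles are computed over
#' the whole channel (background included) by linear interpolation.
#' Pixel-value order within a channel is preserved (non-strictly, due to
#' clipping). A degenerate all-equal channel is returned unchanged with
#' a warning.
#'
#' @param roi a [SegmentedROI-class].
#' @param lowPct,highPct percentiles, 0 <= lowPct < highPct <= 100.
#' @return the contrast-adjusted ROI.
#' @export
adjustIntensityLinear <- function(roi, lowPct = 1, highPct = 99) {
    if (!(lowPct >= 0 && lowPct < highPct && highPct <= 100))
        stop("need 0 <= lowPct < highPct <= 100")
    out <- roi
    for (c in seq_len(dim(roi@intensities)[3])) {
        v <- roi@intensities[, , c]
        qs <- stats::quantile(v, c(lowPct, highPct) / 100,
                              names = FALSE, type = 7)
        lo <- qs[1]; hi <- qs[2]
        if (hi <= lo) {
            warning("channel ", roi@channelNames[c],
                    " is degenerate (constant); returned unchanged")
            next
        }
        w <- (v - lo) * hi / (hi - lo)
        w[w < 0] <- 0
        w[w > hi] <- hi
        out@intensities[, , c] <- w
    }
    out
}

#' Quantify cells from the label mask
#'
#' One row (column of the experiment) per mask label: mean intensity per
#' channel over the label's pixels, the intensity-unweighted centroid
#' and the pixel area, ordered by label. An empty mask yields an empty
#' table.
#'
#' @param roi a [SegmentedROI-class].
#' @param statistic summary per cell and channel: "mean" (default) or
#'   "median".
#' @return \code{SingleCellExperiment} with assay "raw" (channels x
#'   cells) and colData cell_id, roi_id, sample_id, group labels, x, y,
#'   area.
#' @export
quantifyCells <- function(roi, statistic = c("mean", "median")) {
    statistic <- match.arg(statistic)
    mask <- roi@mask
    d <- dim(roi@intensities)
    labs <- sort(unique(mask[mask > 0]))
    n <- length(labs)
    C <- d[3]
    if (n == 0) {
        expr <- matrix(numeric(0), C, 0,
                       dimnames = list(roi@channelNames, NULL))
        cd <- S4Vectors::DataFrame(cell_id = character(0),
            roi_id = character(0), sample_id = character(0),
            x = numeric(0), y = numeric(0), area = numeric(0))
        return(SingleCellExperiment::SingleCellExperiment(
            assays = list(raw = expr), colData = cd))
    }
    inCell <- which(mask > 0)
    lab <- match(mask[inCell], labs)
    area <- tabulate(lab, n)
    # 0-based pixel-centre coordinates: x = col - 1, y = row - 1
    rows <- (inCell - 1L) %% d[1] + 1L
    cols <- (inCell - 1L) %/% d[1] + 1L
    cx <- rowsum(as.numeric(cols - 1L), lab)[, 1] / area
    cy <- rowsum(as.numeric(rows - 1L), lab)[, 1] / area
    expr <- matrix(0, C, n, dimnames = list(roi@channelNames, NULL))
    for (c in seq_len(C)) {
        ch <- roi@intensities[, , c]
        if (statistic == "mean")
            expr[c, ] <- rowsum(ch[inCell], lab)[, 1] / area
        else
            expr[c, ] <- vapply(split(ch[inCell], lab), stats::median,
                                numeric(1))
    }
    ids <- sprintf("%s_c%04d", roi@roiId, labs)
    cd <- S4Vectors::DataFrame(
        cell_id = ids, roi_id = rep(roi@roiId, n),
        sample_id = rep(roi@sampleId, n),
        x = cx, y = cy, area = as.numeric(area), row.names = ids)
    for (g in names(roi@groups)) cd[[g]] <- rep(roi@groups[[g]], n)
    colnames(expr) <- ids
    SingleCellExperiment::SingleCellExperiment(
        assays = list(raw = expr), colData = cd)
}

#' Preprocess and quantify one ROI
#'
#' Applies the fixed pipeline order: spillover compensation (identity
#' matrix, i.e. a no-op, when S is NULL), median denoise, linear
#' intensity adjustment, then per-cell quantification.
#'
#' @param roi a [SegmentedROI-class].
#' @param S optional spillover matrix (NULL = no compensation).
#' @param window median window (NULL skips denoising).
#' @param adjust length-2 percentile vector (NULL skips adjustment).
#' @return quantified \code{SingleCellExperiment} (see [quantifyCells()]).
#' @export
preprocessROI <- function(roi, S = NULL, window = 3L, adjust = c(1, 99)) {
    if (!is.null(S)) roi <- compensateSpillover(roi, S)
    if (!is.null(window)) roi <- denoiseMedian(roi, window)
    if (!is.null(adjust)) roi <- adjustIntensityLinear(roi, adjust[1],
                                                       adjust[2])
    quantifyCells(roi)
}

# ---- file IO ---------------------------------------------------------------

#' Read an antibody panel table
#'
#' @param path CSV with columns channel, metal, marker, category
#'   (category in lineage / functional / pSS_marker / dna).
#' @return validated data.frame.
#' @export
readPanel <- function(path) {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("channel", "metal", "marker", "category")
    if (!all(need %in% names(p)))
        stop("panel must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(p$marker))
        stop("panel marker names must be unique")
    if (!any(p$category == "lineage"))
        stop("panel must contain at least one lineage marker")
    p
}

#' Read a spillover matrix CSV
#'
#' @param path CSV with channel names as header and row names.
#' @return validated spillover matrix.
#' @export
readSpillover <- function(path) {
    m <- as.matrix(utils::read.csv(path, row.names = 1,
                                   check.names = FALSE))
    validateSpillover(m)
}

#' Write / read a SegmentedROI as TIFF files
#'
#' The intensity stack is written as a multi-page 32-bit float TIFF (one
#' page per channel, in panel order) and the mask as a single-page
#' 16-bit TIFF; channel names and metadata go into a JSON sidecar.
#'
#' @param roi a [SegmentedROI-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeROI <- function(roi, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(dir, roi@roiId)
    pages <- lapply(seq_len(dim(roi@intensities)[3]),
                    function(c) roi@intensities[, , c])
    # store per-channel [0,1]-scaled floats; scales go into the sidecar
    scale <- vapply(pages, max, numeric(1))
    scale[scale <= 0] <- 1
    pages <- mapply(function(p, s) p / s, pages, scale, SIMPLIFY = FALSE)
    tiff::writeTIFF(pages, paste0(base, "_intensities.tiff"),
                    bits.per.sample = 32L, reduce = FALSE)
    if (max(roi@mask) > 65535L) stop("mask labels exceed uint16 range")
    tiff::writeTIFF(roi@mask / 65535, paste0(base, "_mask.tiff"),
                    bits.per.sample = 16L)
    meta <- list(roi_id = roi@roiId, sample_id = roi@sampleId,
                 groups = as.list(roi@groups), pixel_size = roi@pixelSize,
                 channels = roi@channelNames, channel_scale = scale)
    jsonlite::write_json(meta, paste0(base, "_meta.json"),
                         auto_unbox = TRUE)
    invisible(paste0(base, c("_intensities.tiff", "_mask.tiff",
                             "_meta.json")))
}

#' @rdname writeROI
#' @param roiId ROI identifier (file stem) to read back.
#' @export
readROI <- function(dir, roiId) {
    base <- file.path(dir, roiId)
    pages <- tiff::readTIFF(paste0(base, "_intensities.tiff"), all = TRUE)
    meta0 <- jsonlite::read_json(paste0(base, "_meta.json"),
                                 simplifyVector = TRUE)
    pages <- mapply(function(p, s) p * s, pages, meta0$channel_scale,
                    SIMPLIFY = FALSE)
    stack <- array(unlist(pages),
                   dim = c(dim(pages[[1]]), length(pages)))
    mask <- round(tiff::readTIFF(paste0(base, "_mask.tiff")) * 65535)
    meta <- meta0
    SegmentedROI(stack, mask, meta$channels, pixelSize = meta$pixel_size,
                 roiId = meta$roi_id, sampleId = meta$sample_id,
                 groups = unlist(meta$groups))
}
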