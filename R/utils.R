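# shared internal helpers

# Deterministic 31-bit stream seed derived from a master seed plus string
# tags (sample id, roi id, stage name), so each ROI is independently
# reproducible regardless of generation order.
deriveSeed <- function(master, ...) {
    tags <- paste(c(...), collapse = "/")
    p <- 2147483629  # large prime < 2^31
    h <- as.numeric(master) %% p
    for (ch in utf8ToInt(tags))
        h <- (h * 131 + ch) %% p
    as.integer(h)
}

# run expr under a local RNG state; restores the caller's state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Cell metadata as a data.frame
#'
#' Convenience accessor returning the per-cell metadata (colData) of a
#' cell-level [SingleCellExperiment::SingleCellExperiment] as a plain
#' data.frame, for use with base statistics.
#'
#' @param cells a SingleCellExperiment of cells (markers x cells).
#' @return data.frame with one row per cell.
#' @export
cellData <- function(cells) {
    as.data.frame(SummarizedExperiment::colData(cells))
}

# relabel integer cluster ids to contiguous 1..K ordered by descending size;
# ties broken by original id for determinism
sizeOrderedIds <- function(ids) {
    tab <- table(ids)
    ord <- names(tab)[order(-as.integer(tab), names(tab))]
    match(as.character(ids), ord)
}

# simplex check used across profile code
stopifnotSimplex <- function(p, tol = 1e-9) {
    stopifnot(all(p >= -tol), abs(sum(p) - 1) <= tol)
}
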