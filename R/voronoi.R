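# Rectangle-clipped Voronoi tessellation by half-plane intersection.
# For each site the cell polygon starts from the bounding rectangle and
# is clipped against the perpendicular bisector of every other site
# (O(n^2), adequate for per-ROI rendering).

# clip convex polygon (matrix with columns x, y) against half-plane
# a*x + b*y <= c (Sutherland-Hodgman step)
clipHalfPlane <- function(poly, a, b, cc) {
    n <- nrow(poly)
    if (n == 0) return(poly)
    out <- matrix(numeric(0), ncol = 2)
    val <- a * poly[, 1] + b * poly[, 2] - cc
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        pi <- poly[i, ]; pj <- poly[j, ]
        vi <- val[i]; vj <- val[j]
        if (vi <= 0) out <- rbind(out, pi)
        if ((vi < 0) != (vj < 0) && vi != vj) {
            t <- vi / (vi - vj)
            out <- rbind(out, pi + t * (pj - pi))
        }
    }
    out
}

#' Voronoi polygons clipped to a rectangle
#'
#' @param x,y site coordinates.
#' @param bbox c(xmin, xmax, ymin, ymax) clipping rectangle.
#' @return list of polygons (two-column matrices, one per site; vertices
#'   in order, not closed).
#' @export
voronoiPolygons <- function(x, y, bbox) {
    n <- length(x)
    rect <- cbind(c(bbox[1], bbox[2], bbox[2], bbox[1]),
                  c(bbox[3], bbox[3], bbox[4], bbox[4]))
    lapply(seq_len(n), function(i) {
        poly <- rect
        for (j in seq_len(n)) {
            if (j == i || nrow(poly) == 0) next
            # keep side closer to i: bisector of (i, j)
            a <- x[j] - x[i]; b <- y[j] - y[i]
            cc <- (x[j]^2 - x[i]^2 + y[j]^2 - y[i]^2) / 2
            poly <- clipHalfPlane(poly, a, b, cc)
        }
        poly
    })
}

# shoelace area of a polygon matrix
polygonArea <- function(p) {
    n <- nrow(p)
    if (n < 3) return(0)
    j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# even-odd point-in-polygon test
pointInPolygon <- function(px, py, poly) {
    n <- nrow(poly)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1]; yi <- poly[i, 2]
        xj <- poly[j, 1]; yj <- poly[j, 2]
        if ((yi > py) != (yj > py) &&
            px < (xj - xi) * (py - yi) / (yj - yi) + xi)
            inside <- !inside
        j <- i
    }
    inside
}

#' Voronoi map of one ROI
#'
#' Voronoi tessellation of the ROI's cell centroids clipped to the ROI
#' rectangle, one polygon per cell coloured by cell type or CN id. With
#' fewer than three (or collinear) cells a point plot is drawn instead,
#' with a warning.
#'
#' @param cells experiment restricted to (or filtered by) one ROI.
#' @param roi_id which ROI to draw (default: the first).
#' @param colorBy colData column to colour polygons by ("cell_type" or
#'   "cn_id").
#' @param bbox c(xmin, xmax, ymin, ymax); default the centroid bounding
#'   box padded by 1 px.
#' @return a ggplot object.
#' @export
renderVoronoi <- function(cells, roi_id = NULL, colorBy = "cell_type",
                          bbox = NULL) {
    cd <- cellData(cells)
    if (is.null(roi_id)) roi_id <- cd$roi_id[1]
    cd <- cd[cd$roi_id == roi_id, ]
    if (is.null(cd[[colorBy]])) stop("missing colour column ", colorBy)
    fill <- factor(cd[[colorBy]])
    if (nrow(cd) < 3 ||
        abs(stats::cor(cd$x, cd$y)) > 1 - 1e-12 ||
        stats::sd(cd$x) == 0 || stats::sd(cd$y) == 0) {
        warning("fewer than 3 non-collinear cells; falling back to scatter")
        return(ggplot2::ggplot(data.frame(x = cd$x, y = cd$y,
                                          fill = fill),
                ggplot2::aes(x = x, y = y,
                             colour = fill)) +
            ggplot2::geom_point() + ggplot2::scale_y_reverse() +
            ggplot2::labs(colour = colorBy, title = roi_id))
    }
    if (is.null(bbox))
        bbox <- c(min(cd$x) - 1, max(cd$x) + 1,
                  min(cd$y) - 1, max(cd$y) + 1)
    polys <- voronoiPolygons(cd$x, cd$y, bbox)
    df <- do.call(rbind, lapply(seq_along(polys), function(i) {
        p <- polys[[i]]
        if (nrow(p) < 3) return(NULL)
        data.frame(x = p[, 1], y = p[, 2], id = i,
                   fill = fill[i], stringsAsFactors = FALSE)
    }))
    ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                     group = id,
                                     fill = fill)) +
        ggplot2::geom_polygon(colour = "white", linewidth = 0.1) +
        ggplot2::scale_y_reverse() +
        ggplot2::coord_equal() +
        ggplot2::labs(fill = colorBy, title = roi_id) +
        ggplot2::theme_void()
}
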