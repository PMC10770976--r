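#' Closed planar contour
#'
#' A contour is an ordered sequence of (x, y) pixel coordinates describing a
#' closed polygon (the last vertex connects back to the first). Coordinates
#' are 0-based with x = column index and y = row index, origin at the top
#' left. Consecutive duplicate vertices are removed on construction.
#'
#' @param points numeric matrix with two columns (x, y) and at least 3 rows
#'   after duplicate removal.
#' @return An object of class `efd_contour`: a list with `points` (n x 2
#'   matrix) and `orientation` (+1 for positive shoelace signed area, -1
#'   otherwise, 0 for degenerate).
#' @export
contour <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour points must be an n x 2 matrix")
  if (!all(is.finite(points))) stop("contour coordinates must be finite")
  n <- nrow(points)
  if (n > 1L) {
    dup <- c(FALSE, rowSums(abs(points[-1L, , drop = FALSE] -
                                points[-n, , drop = FALSE])) == 0)
    points <- points[!dup, , drop = FALSE]
    n <- nrow(points)
    if (n > 1L && all(points[1L, ] == points[n, ])) {
      points <- points[-n, , drop = FALSE]
      n <- n - 1L
    }
  }
  if (n < 3L) stop("a contour needs at least 3 distinct vertices")
  colnames(points) <- c("x", "y")
  structure(list(points = points, orientation = sign(signed_area(points))),
            class = "efd_contour")
}

#' @export
print.efd_contour <- function(x, ...) {
  cat(sprintf("<efd_contour: %d vertices, orientation %+d>\n",
              nrow(x$points), x$orientation))
  invisible(x)
}

# Shoelace signed area of a closed polygon given as an n x 2 matrix.
signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Re-orient a contour so its signed area is positive (counterclockwise in
# the shoelace sense). The first vertex is kept as the start point.
orient_positive <- function(ct) {
  if (ct$orientation >= 0) return(ct)
  pts <- ct$points
  n <- nrow(pts)
  contour(pts[c(1L, n:2L), , drop = FALSE])
}

# Reverse traversal direction, keeping the start vertex.
reverse_contour <- function(ct) {
  pts <- ct$points
  n <- nrow(pts)
  contour(pts[c(1L, n:2L), , drop = FALSE])
}

#' Trace cell contours from an instance-labeled mask
#'
#' Extracts one closed boundary contour per positive label of an instance
#' mask. The boundary is the crack polygon along pixel edges (vertices at
#' half-integer pixel-corner coordinates), traced from the top-left corner
#' of the topmost-then-leftmost pixel of the region, and re-oriented to
#' positive signed area so that coefficient signs downstream are
#' deterministic. Tracing along cracks keeps the mask -> contour -> mask
#' roundtrip exact for rectangles and symmetric under Fourier smoothing.
#' If a label is fragmented into several connected components only the
#' largest (by pixel count) is kept, with a warning.
#'
#' @param mask integer matrix; 0 = background, k = pixels of cell k.
#' @return A list with one element per label (in ascending label order), each
#'   a list with `label` and `contour` (an [contour()] object).
#' @export
trace_contours <- function(mask) {
  mask <- validate_mask(mask)
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0L) {
    warning("mask contains no labeled pixels")
    return(list())
  }
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lab <- labs[i]
    bin <- mask == lab
    comp <- .cpp_label_components(bin)
    ncomp <- max(comp)
    if (ncomp > 1L) {
      warning(sprintf("label %d has %d connected components; keeping the largest",
                      lab, ncomp))
      sizes <- tabulate(comp[comp > 0], nbins = ncomp)
      bin <- comp == which.max(sizes)
    }
    bd <- .cpp_trace_boundary(bin)
    out[[i]] <- list(label = lab, contour = boundary_to_contour(bd))
  }
  out
}

# Turn a traced crack boundary into a contour with positive orientation.
# A crack boundary always has >= 4 vertices (a single pixel gives its unit
# square).
boundary_to_contour <- function(bd) {
  ct <- contour(bd)
  if (ct$orientation < 0) ct <- orient_positive(ct)
  ct
}

validate_mask <- function(mask) {
  if (!is.matrix(mask)) stop("instance mask must be a 2-D matrix")
  if (is.double(mask)) {
    if (any(mask != round(mask))) stop("instance mask must contain integers")
    storage.mode(mask) <- "integer"
  }
  if (!is.integer(mask)) stop("instance mask must be integer-valued")
  if (any(mask < 0L)) stop("instance mask labels must be non-negative")
  mask
}

#' Rasterize a contour to pixel coordinates
#'
#' A pixel (x, y) with integer center coordinates belongs to the contour's
#' region iff the center lies inside the polygon under the even-odd rule;
#' points exactly on the boundary count as inside. This convention makes the
#' roundtrip mask -> traced contour -> rasterized mask exact for rectangular
#' regions.
#'
#' @param ct an [contour()] object (or an n x 2 vertex matrix).
#' @param dim optional image dimensions c(nrow, ncol); pixels outside are
#'   clipped.
#' @return Integer matrix with columns (x, y): the pixels inside the contour.
#' @export
rasterize_contour <- function(ct, dim = NULL) {
  pts <- if (inherits(ct, "efd_contour")) ct$points else as.matrix(ct)
  x0 <- floor(min(pts[, 1L])); x1 <- ceiling(max(pts[, 1L]))
  y0 <- floor(min(pts[, 2L])); y1 <- ceiling(max(pts[, 2L]))
  if (!is.null(dim)) {
    x0 <- max(x0, 0L); x1 <- min(x1, dim[2L] - 1L)
    y0 <- max(y0, 0L); y1 <- min(y1, dim[1L] - 1L)
  }
  if (x1 < x0 || y1 < y0) return(matrix(integer(), 0L, 2L,
                                        dimnames = list(NULL, c("x", "y"))))
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep(y0:y1, times = x1 - x0 + 1L)
  keep <- .cpp_points_in_polygon(as.numeric(gx), as.numeric(gy),
                                 pts[, 1L], pts[, 2L])
  out <- cbind(x = gx[keep], y = gy[keep])
  storage.mode(out) <- "integer"
  out
}

# Pixel (x, y) matrix -> logical mask of given dim.
pixels_to_mask <- function(pix, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (nrow(pix)) m[cbind(pix[, 2L] + 1L, pix[, 1L] + 1L)] <- TRUE
  m
}

# Linear indices of pixels for fast set operations (requires pixels in
# bounds).
pixel_index <- function(pix, dim) {
  pix[, 2L] + 1L + dim[1L] * pix[, 1L]
}
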