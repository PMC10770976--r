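#' Convert a probe-channel RGB image to grayscale FL intensity
#'
#' The grayscale value of each pixel represents the fluorescence intensity.
#' The default "mean" mode averages the three channels; "max" takes the
#' per-pixel channel maximum; "luma" uses Rec.601 weights (0.299, 0.587,
#' 0.114) — note the probe fluorescence is red-dominant, so luma reads
#' systematically low.
#'
#' @param rgb H x W x 3 array, native counts (uint8 scale).
#' @param mode "mean", "max" or "luma".
#' @return H x W intensity matrix.
#' @export
probe_to_gray <- function(rgb, mode = c("mean", "max", "luma")) {
  mode <- match.arg(mode)
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("probe image must be H x W x 3")
  switch(mode,
         mean = (rgb[, , 1L] + rgb[, , 2L] + rgb[, , 3L]) / 3,
         max = pmax(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L]),
         luma = 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] +
                0.114 * rgb[, , 3L])
}

#' Mean FL intensity over a cell mask
#'
#' @param cell `cell_instance`, logical matrix, or m x 2 pixel matrix.
#' @param gray intensity image from [probe_to_gray()].
#' @return Arithmetic mean of the gray values over the mask pixels.
#' @export
cell_mean_intensity <- function(cell, gray) {
  idx <- mask_to_index(cell, dim(gray))
  if (length(idx) == 0L) stop("cell mask is empty")
  mean(gray[idx])
}

#' Classify detected cells by mean FL intensity
#'
#' Computes each cell's mean probe intensity and flags it suspicious iff
#' the mean exceeds the threshold theta (a cell at exactly theta falls in
#' the normal bin: the two classes are "greater than theta" and "less than
#' or equal to theta"). Pixels claimed by several overlapping detections
#' are assigned to the higher-scoring cell for averaging; a cell left with
#' no unclaimed pixels falls back to its full mask.
#'
#' @param instances list of `cell_instance` objects.
#' @param gray probe intensity image.
#' @param theta classification threshold (native gray counts), default 10.
#' @return `intensity_report`: list(per_cell data.frame, per_image list,
#'   theta). The input instances are returned in `instances` with `mean_fl`
#'   and `suspicious` filled in.
#' @export
classify_cells <- function(instances, gray, theta = 10) {
  stopifnot(theta >= 0)
  n <- length(instances)
  if (n > 0L) {
    ord <- order(vapply(instances, function(i) i$score, numeric(1)),
                 decreasing = TRUE)
  } else ord <- integer()
  claimed <- rep(FALSE, length(gray))
  mean_fl <- numeric(n)
  for (i in ord) {
    idx <- pixel_index(instances[[i]]$pixels, dim(gray))
    own <- idx[!claimed[idx]]
    use <- if (length(own) > 0L) own else idx
    mean_fl[i] <- mean(gray[use])
    claimed[idx] <- TRUE
  }
  suspicious <- mean_fl > theta
  for (i in seq_len(n)) {
    instances[[i]]$mean_fl <- mean_fl[i]
    instances[[i]]$suspicious <- suspicious[i]
  }
  per_cell <- data.frame(
    cell = seq_len(n),
    x = vapply(instances, function(i) i$center[1L], numeric(1)),
    y = vapply(instances, function(i) i$center[2L], numeric(1)),
    area = vapply(instances, function(i) nrow(i$pixels), integer(1)),
    mean_fl = mean_fl,
    suspicious = suspicious)
  per_image <- list(total = n,
                    n_above_threshold = sum(suspicious),
                    n_at_or_below_threshold = sum(!suspicious),
                    mean_intensity = if (n > 0L) mean(mean_fl) else NA_real_,
                    theta = theta)
  structure(list(per_cell = per_cell, per_image = per_image, theta = theta,
                 instances = instances),
            class = "intensity_report")
}

#' @export
print.intensity_report <- function(x, ...) {
  cat(sprintf("<intensity_report: %d cells, %d suspicious (theta = %g)>\n",
              x$per_image$total, x$per_image$n_above_threshold, x$theta))
  invisible(x)
}

#' Crop and enlarge a single cell from each channel
#'
#' Takes the axis-aligned bounding box of the cell's mask, expands it by
#' `margin` pixels, clips to the image, and upscales by an integer `zoom`
#' factor with nearest-neighbor interpolation — one crop per channel.
#'
#' @param images named list of channel images (matrices or H x W x C
#'   arrays sharing spatial dimensions).
#' @param instance a `cell_instance`.
#' @param margin border in pixels around the bounding box.
#' @param zoom integer upscaling factor >= 1.
#' @return Named list of cropped (and zoomed) channel images.
#' @export
crop_cell <- function(images, instance, margin = 2L, zoom = 1L) {
  zoom <- as.integer(zoom)
  if (zoom < 1L) stop("zoom must be >= 1")
  pix <- instance$pixels
  if (nrow(pix) == 0L) stop("cell mask is empty")
  lapply(images, function(img) {
    H <- dim(img)[1L]; W <- dim(img)[2L]
    x0 <- max(0L, min(pix[, 1L]) - margin); x1 <- min(W - 1L, max(pix[, 1L]) + margin)
    y0 <- max(0L, min(pix[, 2L]) - margin); y1 <- min(H - 1L, max(pix[, 2L]) + margin)
    rows <- (y0 + 1L):(y1 + 1L); cols <- (x0 + 1L):(x1 + 1L)
    cr <- if (length(dim(img)) == 3L) img[rows, cols, , drop = FALSE]
          else img[rows, cols, drop = FALSE]
    if (zoom > 1L) {
      ri <- rep(seq_len(dim(cr)[1L]), each = zoom)
      ci <- rep(seq_len(dim(cr)[2L]), each = zoom)
      cr <- if (length(dim(cr)) == 3L) cr[ri, ci, , drop = FALSE]
            else cr[ri, ci, drop = FALSE]
    }
    cr
  })
}
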