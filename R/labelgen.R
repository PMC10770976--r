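#' Build network training targets from an instance mask
#'
#' Converts a ground-truth instance mask into the supervision consumed by
#' the detector: a center heatmap with one Gaussian bump per cell (peak
#' value exactly 1 at the rounded center pixel), a per-pixel regression map
#' of length 2 + 4N holding the sub-pixel center offset (dx, dy) and the N
#' elliptic Fourier harmonic quadruples, and a valid mask marking the center
#' pixels where the regression loss applies.
#'
#' Harmonic coefficients are divided by `scale` so regression targets are
#' O(1); the constant is stored in the target (and in checkpoints) for exact
#' de-normalization. Offsets are already sub-pixel and are stored raw.
#'
#' @param mask integer instance mask (0 = background).
#' @param n_harmonics harmonic order N of the regression targets.
#' @param sigma Gaussian bump standard deviation in pixels; default
#'   0.1 x mean cell equivalent diameter (floored at 1).
#' @param scale normalization constant for harmonic coefficients.
#' @return Object of class `training_target`: list with `heatmap` (H x W,
#'   values in [0, 1]), `reg` (H x W x (2+4N) array), `valid` (H x W
#'   logical), `centers` (data.frame: label, cx, cy, px, py), plus
#'   `n_harmonics`, `scale`, `sigma`.
#' @export
make_targets <- function(mask, n_harmonics = 6L, sigma = NULL, scale = 256) {
  mask <- validate_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  nch <- 2L + 4L * n_harmonics
  heat <- matrix(0, H, W)
  reg <- array(0, c(H, W, nch))
  valid <- matrix(FALSE, H, W)
  traced <- withCallingHandlers(
    if (any(mask > 0L)) trace_contours(mask) else list(),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(traced) == 0L) {
    return(new_training_target(heat, reg, valid,
                               data.frame(label = integer(), cx = numeric(),
                                          cy = numeric(), px = integer(),
                                          py = integer()),
                               n_harmonics, scale, sigma %||% 1))
  }
  areas <- tabulate(mask[mask > 0L])
  areas <- areas[areas > 0L]
  if (is.null(sigma)) {
    eqd <- mean(2 * sqrt(areas / pi))
    sigma <- max(1, 0.1 * eqd)
  }
  centers <- data.frame(label = integer(), cx = numeric(), cy = numeric(),
                        px = integer(), py = integer())
  for (tc in traced) {
    ct <- rotate_start_to_ray(tc$contour)
    K <- nrow(ct$points)
    N_eff <- min(n_harmonics, K %/% 2L)
    e <- efd_encode(ct, N_eff)
    cx <- e$A0; cy <- e$C0
    px <- min(max(round(cx), 0L), W - 1L)
    py <- min(max(round(cy), 0L), H - 1L)
    heat <- splat_gaussian(heat, px, py, sigma)
    h <- matrix(0, n_harmonics, 4L)
    h[seq_len(N_eff), ] <- e$harmonics
    reg[py + 1L, px + 1L, ] <- c(cx - px, cy - py, as.numeric(t(h)) / scale)
    valid[py + 1L, px + 1L] <- TRUE
    centers <- rbind(centers, data.frame(label = tc$label, cx = cx, cy = cy,
                                         px = px, py = py))
  }
  new_training_target(heat, reg, valid, centers, n_harmonics, scale, sigma)
}

new_training_target <- function(heatmap, reg, valid, centers, n_harmonics,
                                scale, sigma) {
  structure(list(heatmap = heatmap, reg = reg, valid = valid,
                 centers = centers, n_harmonics = as.integer(n_harmonics),
                 scale = scale, sigma = sigma),
            class = "training_target")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotate a contour's vertex order so traversal starts at the vertex nearest
# the +x ray from the vertex centroid. Unlike the topmost-pixel start (which
# can slide several pixels along a flat top under sub-pixel shape changes,
# rotating the Fourier phase of the regression labels discontinuously), this
# start point varies smoothly with shape for convex cells, which makes the
# coefficient labels learnable.
rotate_start_to_ray <- function(ct) {
  pts <- ct$points
  cx <- mean(pts[, 1L]); cy <- mean(pts[, 2L])
  ang <- atan2(pts[, 2L] - cy, pts[, 1L] - cx)
  i <- which.min(abs(ang))
  if (i > 1L) {
    n <- nrow(pts)
    ct <- contour(pts[c(i:n, 1L:(i - 1L)), , drop = FALSE])
  }
  ct
}

# Pixelwise-max a unit-peak Gaussian bump centered at (px, py) into `heat`.
splat_gaussian <- function(heat, px, py, sigma) {
  H <- nrow(heat); W <- ncol(heat)
  r <- ceiling(3 * sigma)
  xs <- max(0L, px - r):min(W - 1L, px + r)
  ys <- max(0L, py - r):min(H - 1L, py + r)
  g <- exp(-(outer((ys - py)^2, (xs - px)^2, `+`)) / (2 * sigma^2))
  block <- heat[ys + 1L, xs + 1L, drop = FALSE]
  heat[ys + 1L, xs + 1L] <- pmax(block, g)
  heat
}

# Per-channel sign flips of the regression vector under mirror flips,
# derived so the flipped labels stay in the CANONICAL parametrization
# (positive orientation, traversal starting at the +x ray) that
# make_targets produces — a naive coordinate mirror leaves reversed
# orientation and a phase shift, and under random flip augmentation such
# labels average to zero and destroy shape learning.
#
# Vertical (y -> H-1-y): mirror (c,d -> -c,-d), then orientation reversal
# (negate sines b,d); the +x start point is preserved. Net: (a,-b,-c,d),
# dy -> -dy.
# Horizontal (x -> W-1-x): mirror (a,b -> -a,-b), reversal, then a phase
# shift of half a period to return the start to the +x ray (multiplies
# harmonic n by (-1)^n). Net: n odd (a,-b,-c,d), n even (-a,b,c,-d);
# dx -> -dx.
flip_signs <- function(n_harmonics, horizontal, vertical) {
  s <- rep(1, 2L + 4L * n_harmonics)
  n <- seq_len(n_harmonics)
  base <- function(per_harm) { # per_harm: 4 x N sign matrix -> channels
    c(1, 1, as.vector(per_harm))
  }
  if (vertical) {
    ph <- matrix(rep(c(1, -1, -1, 1), n_harmonics), 4L)
    s <- s * base(ph); s[2L] <- s[2L] * -1
  }
  if (horizontal) {
    odd <- n %% 2L == 1L
    ph <- vapply(seq_len(n_harmonics), function(j)
      if (odd[j]) c(1, -1, -1, 1) else c(-1, 1, 1, -1), numeric(4L))
    s <- s * base(ph); s[1L] <- s[1L] * -1
  }
  s
}

# Mirror a training target horizontally and/or vertically (involution).
flip_target <- function(tg, horizontal = FALSE, vertical = FALSE) {
  if (!horizontal && !vertical) return(tg)
  H <- nrow(tg$heatmap); W <- ncol(tg$heatmap)
  ri <- if (vertical) H:1 else 1:H
  ci <- if (horizontal) W:1 else 1:W
  heat <- tg$heatmap[ri, ci, drop = FALSE]
  valid <- tg$valid[ri, ci, drop = FALSE]
  reg <- tg$reg[ri, ci, , drop = FALSE]
  s <- flip_signs(tg$n_harmonics, horizontal, vertical)
  reg <- sweep(reg, 3L, s, `*`)
  centers <- tg$centers
  if (nrow(centers)) {
    if (horizontal) { centers$cx <- (W - 1) - centers$cx
                      centers$px <- (W - 1L) - centers$px }
    if (vertical)   { centers$cy <- (H - 1) - centers$cy
                      centers$py <- (H - 1L) - centers$py }
  }
  new_training_target(heat, reg, valid, centers, tg$n_harmonics, tg$scale,
                      tg$sigma)
}

# Crop a training target to rows y0..y0+h-1, cols x0..x0+w-1 (0-based),
# zero-padding if the window exceeds the target extent.
crop_target <- function(tg, x0, y0, w, h) {
  H <- nrow(tg$heatmap); W <- ncol(tg$heatmap)
  heat <- matrix(0, h, w)
  valid <- matrix(FALSE, h, w)
  reg <- array(0, c(h, w, dim(tg$reg)[3L]))
  sx <- max(0L, x0); ex <- min(W - 1L, x0 + w - 1L)
  sy <- max(0L, y0); ey <- min(H - 1L, y0 + h - 1L)
  if (sx <= ex && sy <= ey) {
    dr <- (sy - y0 + 1L):(ey - y0 + 1L)
    dc <- (sx - x0 + 1L):(ex - x0 + 1L)
    heat[dr, dc] <- tg$heatmap[(sy + 1L):(ey + 1L), (sx + 1L):(ex + 1L)]
    valid[dr, dc] <- tg$valid[(sy + 1L):(ey + 1L), (sx + 1L):(ex + 1L)]
    reg[dr, dc, ] <- tg$reg[(sy + 1L):(ey + 1L), (sx + 1L):(ex + 1L), ,
                            drop = FALSE]
  }
  centers <- tg$centers
  if (nrow(centers)) {
    keep <- centers$px >= sx & centers$px <= ex &
            centers$py >= sy & centers$py <= ey
    centers <- centers[keep, , drop = FALSE]
    centers$cx <- centers$cx - x0; centers$px <- centers$px - x0
    centers$cy <- centers$cy - y0; centers$py <- centers$py - y0
  }
  new_training_target(heat, reg, valid, centers, tg$n_harmonics, tg$scale,
                      tg$sigma)
}
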