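# Independent oracles used by the tests. Each reimplements the quantity it
# checks by a different route than the package code (dense numerical
# integration, flood fill, exhaustive enumeration, pure-R geometry).

# Fourier coefficients of a closed piecewise-linear curve by direct
# trapezoidal integration over a dense arc-length resampling (frequency
# domain route, independent of the closed-form chain sums in efd_encode).
oracle_efd <- function(pts, n_harmonics, oversample = 400L) {
  K <- nrow(pts)
  nxt <- c(2:K, 1L)
  dense_x <- c(); dense_y <- c(); dense_t <- c()
  tacc <- 0
  for (i in seq_len(K)) {
    p0 <- pts[i, ]; p1 <- pts[nxt[i], ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    u <- seq(0, 1, length.out = oversample + 1L)[-(oversample + 1L)]
    dense_x <- c(dense_x, p0[1] + u * (p1[1] - p0[1]))
    dense_y <- c(dense_y, p0[2] + u * (p1[2] - p0[2]))
    dense_t <- c(dense_t, tacc + u * len)
    tacc <- tacc + len
  }
  L <- tacc
  # closed curve: append the first point at t = L for trapezoid closure
  x <- c(dense_x, dense_x[1]); y <- c(dense_y, dense_y[1])
  tt <- c(dense_t, L)
  trapz <- function(f) sum(diff(tt) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  A0 <- trapz(x) / L
  C0 <- trapz(y) / L
  harm <- t(vapply(seq_len(n_harmonics), function(n) {
    cn <- cos(2 * pi * n * tt / L); sn <- sin(2 * pi * n * tt / L)
    c(a = 2 / L * trapz(x * cn), b = 2 / L * trapz(x * sn),
      c = 2 / L * trapz(y * cn), d = 2 / L * trapz(y * sn))
  }, numeric(4)))
  list(A0 = A0, C0 = C0, harmonics = harm)
}

# Arc-length-weighted boundary centroid by dense resampling (plain average
# of uniformly spaced points along the polygon).
oracle_boundary_centroid <- function(pts, n_dense = 2e5) {
  K <- nrow(pts)
  nxt <- c(2:K, 1L)
  seg <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
  L <- sum(seg)
  s <- (seq_len(n_dense) - 0.5) / n_dense * L
  cum <- cumsum(seg)
  i <- findInterval(s, c(0, cum), rightmost.closed = TRUE)
  u <- (s - c(0, cum)[i]) / seg[i]
  c(mean(pts[i, 1] + u * (pts[nxt[i], 1] - pts[i, 1])),
    mean(pts[i, 2] + u * (pts[nxt[i], 2] - pts[i, 2])))
}

# Pure-R even-odd point-in-polygon (crossing test), independent of the C++
# rasterizer.
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- vx[j] + (py - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j])
    upd <- cross & (px < xint)
    inside[which(upd)] <- !inside[which(upd)]
    j <- i
  }
  inside
}

oracle_rasterize <- function(pts, dim) {
  gx <- rep(0:(dim[2] - 1), each = dim[1])
  gy <- rep(0:(dim[1] - 1), times = dim[2])
  keep <- oracle_in_polygon(gx, gy, pts[, 1], pts[, 2])
  cbind(x = gx[keep], y = gy[keep])
}

oracle_pixel_iou <- function(pixa, pixb, dim) {
  ia <- pixa[, 2] + 1 + dim[1] * pixa[, 1]
  ib <- pixb[, 2] + 1 + dim[1] * pixb[, 1]
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# 4-connected flood fill from a seed pixel (row, col), pure R.
oracle_flood_fill <- function(bin, seed_rc) {
  H <- nrow(bin); W <- ncol(bin)
  seen <- matrix(FALSE, H, W)
  stack <- list(seed_rc)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (r < 1 || r > H || c < 1 || c > W || seen[r, c] || !bin[r, c]) next
    seen[r, c] <- TRUE
    stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
  }
  which(seen)
}

# Exhaustive maximum one-to-one matching over an admissibility matrix
# (rows = predictions, cols = ground truths); feasible for <= ~8 x 8.
oracle_max_matching <- function(adj) {
  n <- nrow(adj); m <- ncol(adj)
  if (n == 0 || m == 0) return(0L)
  best <- 0L
  rec <- function(r, used, count) {
    if (count + (n - r + 1) <= best) return() # bound
    if (r > n) { best <<- max(best, count); return() }
    rec(r + 1, used, count) # leave prediction r unmatched
    for (c in which(adj[r, ])) {
      if (!used[c]) {
        used[c] <- TRUE
        rec(r + 1, used, count + 1L)
        used[c] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0L)
  best
}

# F1avg by exhaustive matching, mirroring the published definition.
oracle_f1avg <- function(iou, taus = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  n_pred <- nrow(iou); n_gt <- ncol(iou)
  f1s <- vapply(taus, function(tau) {
    if (n_pred == 0 && n_gt == 0) return(1)
    tp <- oracle_max_matching(iou >= tau)
    if (tp == 0) return(0)
    P <- tp / n_pred; R <- tp / n_gt
    2 * P * R / (P + R)
  }, numeric(1))
  mean(f1s)
}

# Random smooth star-convex polygon (guaranteed simple) around a center.
random_simple_polygon <- function(n_vertices = 60L, center = c(40, 40),
                                  r0 = 20, wobble = 0.35) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  k <- sample(2:6, 3)
  amp <- runif(3, 0, wobble) * r0 / seq_along(k)
  ph <- runif(3, 0, 2 * pi)
  r <- r0 + rowSums(vapply(1:3, function(i) amp[i] * sin(k[i] * th + ph[i]),
                           numeric(n_vertices)))
  r <- pmax(r, 3)
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# Random cluster of small disjoint pixel blobs as cell_instance stand-ins.
random_instances <- function(n, dim = c(48, 48), jitter = 0) {
  out <- list()
  centers <- cbind(runif(n, 8, dim[2] - 8), runif(n, 8, dim[1] - 8))
  for (i in seq_len(n)) {
    r <- runif(1, 2, 5)
    th <- 2 * pi * (0:23) / 24
    ct <- contour(cbind(centers[i, 1] + jitter * rnorm(1) + r * cos(th),
                        centers[i, 2] + jitter * rnorm(1) + r * sin(th)))
    pix <- rasterize_contour(ct, dim = dim)
    if (nrow(pix) == 0) next
    out[[length(out) + 1]] <- structure(
      list(center = centers[i, ], efd = NULL, score = runif(1),
           pixels = pix, dim = dim, mean_fl = NA_real_, suspicious = NA),
      class = "cell_instance")
  }
  out
}
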