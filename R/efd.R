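#' Elliptic Fourier descriptor of a closed contour
#'
#' Encodes a closed polygon as a truncated elliptic Fourier series in the
#' chain/arc-length parametrization (Kuhl-Giardina form). The traversal
#' parameter t runs over cumulative perimeter length; harmonic n contributes
#' four coefficients:
#' \deqn{x(t) = A_0 + \sum_n a_n \cos(2\pi n t/T) + b_n \sin(2\pi n t/T)}
#' \deqn{y(t) = C_0 + \sum_n c_n \cos(2\pi n t/T) + d_n \sin(2\pi n t/T)}
#' The DC terms (A0, C0) are the arc-length-averaged centroid of the
#' boundary. Coefficients are stored un-normalized for phase and
#' orientation: the encoding reflects the traversal it was given.
#'
#' @param ct an [contour()] object.
#' @param n_harmonics number of harmonics N; must satisfy
#'   1 <= N <= floor(n_vertices / 2).
#' @return An object of class `efd`: list with `A0`, `C0`, `harmonics`
#'   (N x 4 matrix with columns a, b, c, d) and `n_harmonics`.
#' @export
efd_encode <- function(ct, n_harmonics) {
  if (!inherits(ct, "efd_contour")) ct <- contour(ct)
  pts <- ct$points
  K <- nrow(pts)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics > K %/% 2L)
    stop(sprintf("n_harmonics (%d) exceeds floor(n_vertices/2) = %d",
                 n_harmonics, K %/% 2L))
  # segment i runs from vertex i to vertex i+1 (closing back to vertex 1),
  # so the traversal parameter t starts at the first vertex
  nxt <- c(seq_len(K - 1L) + 1L, 1L)
  dx <- pts[nxt, 1L] - pts[, 1L]
  dy <- pts[nxt, 2L] - pts[, 2L]
  dt <- sqrt(dx^2 + dy^2)
  Tt <- sum(dt)
  if (Tt <= 0) stop("degenerate contour: zero total perimeter")
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-K])
  # DC terms: arc-length average over the piecewise-linear boundary
  A0 <- sum(dt * (pts[, 1L] + pts[nxt, 1L]) / 2) / Tt
  C0 <- sum(dt * (pts[, 2L] + pts[nxt, 2L]) / 2) / Tt
  n <- seq_len(n_harmonics)
  w <- 2 * pi / Tt
  # outer products: rows = segments, cols = harmonics
  c1 <- cos(outer(t1, n * w)); c0 <- cos(outer(t0, n * w))
  s1 <- sin(outer(t1, n * w)); s0 <- sin(outer(t0, n * w))
  fac <- Tt / (2 * n^2 * pi^2)
  gx <- dx / dt; gy <- dy / dt
  harm <- cbind(a = fac * colSums(gx * (c1 - c0)),
                b = fac * colSums(gx * (s1 - s0)),
                c = fac * colSums(gy * (c1 - c0)),
                d = fac * colSums(gy * (s1 - s0)))
  new_efd(A0, C0, harm)
}

new_efd <- function(A0, C0, harmonics) {
  harmonics <- matrix(as.numeric(harmonics), ncol = 4L,
                      dimnames = list(NULL, c("a", "b", "c", "d")))
  if (!all(is.finite(harmonics)) || !is.finite(A0) || !is.finite(C0))
    stop("EFD coefficients must be finite")
  structure(list(A0 = as.numeric(A0), C0 = as.numeric(C0),
                 harmonics = harmonics, n_harmonics = nrow(harmonics)),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("<efd: center (%.2f, %.2f), %d harmonics>\n",
              x$A0, x$C0, x$n_harmonics))
  invisible(x)
}

#' Evaluate an elliptic Fourier descriptor into a polygon
#'
#' Samples the truncated Fourier series at `n_points` uniform parameter
#' steps. As the harmonic order grows, `efd_decode(efd_encode(C, N))`
#' converges to the source contour C.
#'
#' @param efd an [efd_encode()] descriptor.
#' @param n_points number of polygon vertices to evaluate (>= 3).
#' @return An [contour()] object.
#' @export
efd_decode <- function(efd, n_points = 120L) {
  stopifnot(inherits(efd, "efd"))
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be >= 3")
  s <- (seq_len(n_points) - 1L) / n_points
  n <- seq_len(efd$n_harmonics)
  cs <- cos(2 * pi * outer(s, n)); sn <- sin(2 * pi * outer(s, n))
  h <- efd$harmonics
  x <- efd$A0 + cs %*% h[, "a"] + sn %*% h[, "b"]
  y <- efd$C0 + cs %*% h[, "c"] + sn %*% h[, "d"]
  contour(cbind(x, y))
}

#' Contour center from a descriptor
#'
#' Returns the DC terms (A0, C0): the arc-length-weighted centroid of the
#' encoded boundary.
#'
#' @param efd an `efd` object.
#' @return Numeric length-2 vector (x, y).
#' @export
contour_center <- function(efd) {
  stopifnot(inherits(efd, "efd"))
  c(x = efd$A0, y = efd$C0)
}

#' Tabulate descriptors for CSV serialization
#'
#' One row per cell: label, A0, C0, a1, b1, c1, d1, ..., aN, bN, cN, dN.
#'
#' @param efds list of `efd` objects.
#' @param labels integer labels, one per descriptor.
#' @return data.frame.
#' @export
efd_to_table <- function(efds, labels = seq_along(efds)) {
  if (length(efds) == 0L) {
    return(data.frame(label = integer(), A0 = numeric(), C0 = numeric()))
  }
  N <- max(vapply(efds, function(e) e$n_harmonics, integer(1)))
  rows <- lapply(seq_along(efds), function(i) {
    e <- efds[[i]]
    h <- matrix(0, N, 4L)
    h[seq_len(e$n_harmonics), ] <- e$harmonics
    c(label = labels[i], A0 = e$A0, C0 = e$C0, as.numeric(t(h)))
  })
  df <- as.data.frame(do.call(rbind, rows))
  coefnames <- as.vector(t(outer(seq_len(N), c("a", "b", "c", "d"),
                                 function(n, l) paste0(l, n))))
  names(df) <- c("label", "A0", "C0", coefnames)
  df
}

#' Rebuild descriptors from a serialized table
#'
#' Inverse of [efd_to_table()].
#'
#' @param df data.frame as produced by [efd_to_table()].
#' @return Named list of `efd` objects (names = labels).
#' @export
efd_from_table <- function(df) {
  N <- (ncol(df) - 3L) %/% 4L
  out <- lapply(seq_len(nrow(df)), function(i) {
    h <- matrix(as.numeric(df[i, -(1:3)]), ncol = 4L, byrow = TRUE)
    new_efd(df$A0[i], df$C0[i], h)
  })
  names(out) <- df$label
  out
}
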