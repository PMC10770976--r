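#' Intersection-over-union of two pixel masks
#'
#' @param a,b `cell_instance` objects, logical matrices of equal dimension,
#'   or m x 2 pixel-coordinate matrices (with `dim` supplied).
#' @param dim image dimensions, required when passing pixel matrices.
#' @return IoU in [0, 1]. Two empty masks are an error (undefined union).
#' @export
mask_iou <- function(a, b, dim = NULL) {
  ia <- mask_to_index(a, dim)
  ib <- mask_to_index(b, dim)
  ninter <- length(intersect(ia, ib))
  nunion <- length(ia) + length(ib) - ninter
  if (nunion == 0L) stop("IoU of two empty masks is undefined")
  ninter / nunion
}

mask_to_index <- function(m, dim = NULL) {
  if (inherits(m, "cell_instance")) return(pixel_index(m$pixels, m$dim))
  if (is.logical(m) && is.matrix(m)) return(which(m))
  if (is.matrix(m) && ncol(m) == 2L) {
    if (is.null(dim)) stop("dim required for pixel-coordinate masks")
    return(pixel_index(m, dim))
  }
  stop("unsupported mask representation")
}

# Pairwise IoU matrix between two lists of instances.
iou_matrix <- function(pred, gt) {
  M <- matrix(0, length(pred), length(gt))
  if (length(pred) == 0L || length(gt) == 0L) return(M)
  pidx <- lapply(pred, function(p) pixel_index(p$pixels, p$dim))
  gidx <- lapply(gt, function(g) pixel_index(g$pixels, g$dim))
  for (i in seq_along(pidx)) for (j in seq_along(gidx)) {
    ninter <- length(intersect(pidx[[i]], gidx[[j]]))
    nunion <- length(pidx[[i]]) + length(gidx[[j]]) - ninter
    M[i, j] <- if (nunion > 0L) ninter / nunion else 0
  }
  M
}

#' Match predictions to ground truth at an IoU threshold
#'
#' One-to-one matching that maximizes the number of matched pairs among all
#' (prediction, ground truth) pairs with IoU >= tau — a maximum bipartite
#' matching (Kuhn's augmenting-path algorithm), so the TP count is never
#' understated by greedy ordering.
#'
#' @param pred,gt lists of `cell_instance` objects (or anything carrying
#'   `pixels`/`dim`).
#' @param tau IoU threshold in (0, 1).
#' @param iou optional precomputed IoU matrix (predictions x ground truths).
#' @return list(TP, FP, FN).
#' @export
match_at_tau <- function(pred, gt, tau, iou = NULL) {
  stopifnot(tau > 0, tau < 1)
  if (is.null(iou)) iou <- iou_matrix(pred, gt)
  adj <- iou >= tau
  tp <- max_bipartite_matching(adj)
  list(TP = tp, FP = nrow(adj) - tp, FN = ncol(adj) - tp)
}

# Kuhn's algorithm: maximum cardinality matching of a bipartite adjacency
# matrix (rows = predictions, cols = ground truths).
max_bipartite_matching <- function(adj) {
  n <- nrow(adj); m <- ncol(adj)
  if (n == 0L || m == 0L) return(0L)
  env <- new.env()
  env$match_col <- integer(m) # 0 = unmatched, else matched row index
  dfs <- function(r) {
    for (c in which(adj[r, ])) {
      if (env$seen[c]) next
      env$seen[c] <- TRUE
      if (env$match_col[c] == 0L || dfs(env$match_col[c])) {
        env$match_col[c] <- r
        return(TRUE)
      }
    }
    FALSE
  }
  total <- 0L
  for (r in seq_len(n)) {
    env$seen <- rep(FALSE, m)
    if (dfs(r)) total <- total + 1L
  }
  total
}

#' Detection F1 averaged over IoU thresholds
#'
#' For each threshold tau in T, predictions are matched one-to-one to
#' ground truths at IoU >= tau; precision P = TP/(TP+FP), recall
#' R = TP/(TP+FN), F1 = 2PR/(P+R) (0 when TP = 0). The summary score is
#' \deqn{F1_{avg} = \frac{1}{|T|} \sum_{\tau \in T} F1_\tau,\quad
#'       T = (0.5, 0.6, 0.7, 0.8, 0.9).}
#' When both the prediction and ground-truth sets are empty, F1 is defined
#' as 1 (vacuous perfect agreement).
#'
#' @param pred,gt lists of `cell_instance` objects.
#' @param taus threshold set T (values in (0,1)).
#' @return `eval_report`: list(per_tau data.frame with tau, TP, FP, FN,
#'   precision, recall, F1; f1avg; taus).
#' @export
f1avg_report <- function(pred, gt, taus = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  stopifnot(length(taus) > 0, all(taus > 0), all(taus < 1))
  iou <- iou_matrix(pred, gt)
  rows <- lapply(taus, function(tau) {
    if (length(pred) == 0L && length(gt) == 0L) {
      return(data.frame(tau = tau, TP = 0L, FP = 0L, FN = 0L,
                        precision = 1, recall = 1, F1 = 1))
    }
    m <- match_at_tau(pred, gt, tau, iou = iou)
    P <- if (m$TP + m$FP > 0L) m$TP / (m$TP + m$FP) else 0
    R <- if (m$TP + m$FN > 0L) m$TP / (m$TP + m$FN) else 0
    F1 <- if (m$TP > 0L) 2 * P * R / (P + R) else 0
    data.frame(tau = tau, TP = m$TP, FP = m$FP, FN = m$FN,
               precision = P, recall = R, F1 = F1)
  })
  per_tau <- do.call(rbind, rows)
  structure(list(per_tau = per_tau, f1avg = mean(per_tau$F1), taus = taus),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$per_tau, row.names = FALSE)
  cat(sprintf("F1avg = %.4f\n", x$f1avg))
  invisible(x)
}

#' Score a set of prediction/ground-truth pairs
#'
#' `mode = "macro"` (default) computes F1avg per image and averages the
#' scores over images ("average F1avg"); `mode = "micro"` pools TP/FP/FN
#' counts over all images at each threshold before computing F1.
#'
#' @param pairs list of `list(pred = ..., gt = ...)` instance-list pairs.
#' @param taus threshold set.
#' @param mode "macro" or "micro".
#' @return `eval_report` with an extra `per_image` component (macro mode).
#' @export
f1avg_dataset <- function(pairs, taus = c(0.5, 0.6, 0.7, 0.8, 0.9),
                          mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  reports <- lapply(pairs, function(p) f1avg_report(p$pred, p$gt, taus))
  if (mode == "macro") {
    scores <- vapply(reports, function(r) r$f1avg, numeric(1))
    agg <- Reduce(`+`, lapply(reports, function(r)
      as.matrix(r$per_tau[, c("TP", "FP", "FN")])))
    per_tau <- data.frame(tau = taus, agg,
                          F1 = rowMeans(vapply(reports,
                                               function(r) r$per_tau$F1,
                                               numeric(length(taus)))))
    return(structure(list(per_tau = per_tau, f1avg = mean(scores),
                          per_image = scores, taus = taus),
                     class = "eval_report"))
  }
  agg <- Reduce(`+`, lapply(reports, function(r)
    as.matrix(r$per_tau[, c("TP", "FP", "FN")])))
  rows <- lapply(seq_along(taus), function(i) {
    TP <- agg[i, "TP"]; FP <- agg[i, "FP"]; FN <- agg[i, "FN"]
    P <- if (TP + FP > 0) TP / (TP + FP) else 0
    R <- if (TP + FN > 0) TP / (TP + FN) else 0
    F1 <- if (TP > 0) 2 * P * R / (P + R) else
      if (TP + FP + FN == 0) 1 else 0
    data.frame(tau = taus[i], TP = TP, FP = FP, FN = FN,
               precision = P, recall = R, F1 = F1)
  })
  per_tau <- do.call(rbind, rows)
  structure(list(per_tau = per_tau, f1avg = mean(per_tau$F1), taus = taus),
            class = "eval_report")
}

# Wrap ground-truth mask labels as instances for scoring.
instances_from_mask <- function(mask) {
  mask <- validate_mask(mask)
  labs <- sort(unique(mask[mask > 0L]))
  lapply(labs, function(lab) {
    idx <- which(mask == lab, arr.ind = TRUE)
    pix <- cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
    storage.mode(pix) <- "integer"
    ctr <- c(mean(pix[, 1L]), mean(pix[, 2L]))
    structure(list(center = ctr, efd = NULL, score = 1, pixels = pix,
                   dim = dim(mask), mean_fl = NA_real_, suspicious = NA),
              class = "cell_instance")
  })
}
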