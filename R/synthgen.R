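#' Synthetic scene specification
#'
#' Parameters of the two-channel synthetic micrograph generator. Defaults
#' emulate the intensity separation observed between normal lung epithelial
#' cells (probe-channel mean FL near zero, default mean 3 counts) and
#' adenocarcinoma cells (mean FL above 40, default 45 counts) so the
#' threshold-10 rule separates the classes, and nuclear sizes/densities
#' typical of cultured-cell micrographs at ~0.5 um/px.
#'
#' @param size image dimensions c(nrow, ncol).
#' @param lambda Poisson mean of the per-image cell count.
#' @param axis_range ellipse semi-axis range in pixels (uniform draw).
#' @param irregularity relative amplitude of random perturbations on
#'   harmonics 2-4 (fraction of the mean semi-axis).
#' @param max_overlap_iou maximum allowed pairwise mask IoU between cells.
#' @param tumor_fraction probability a cell is tumor-like.
#' @param normal_mean,normal_sd probe FL model of normal-like cells, in
#'   MEASURED grayscale counts (the generator scales the red channel so the
#'   channel-mean gray equals the drawn value). Normal draws are truncated
#'   below the threshold-10 line, matching the reported distributions.
#' @param tumor_mean,tumor_sd probe FL model of tumor-like cells
#'   (measured grayscale counts; untruncated).
#' @param dapi_fg_mean,dapi_fg_sd per-cell nuclear-stain brightness model.
#' @param dapi_bg nuclear-channel background level.
#' @param noise_sd per-pixel Gaussian noise s.d. (both channels).
#' @param probe_bg probe-channel background level (red channel).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = c(256L, 256L), lambda = 20, axis_range = c(6, 12),
                       irregularity = 0.06, max_overlap_iou = 0.05,
                       tumor_fraction = 0.5,
                       normal_mean = 3, normal_sd = 2,
                       tumor_mean = 45, tumor_sd = 8,
                       dapi_fg_mean = 180, dapi_fg_sd = 25,
                       dapi_bg = 12, noise_sd = 4, probe_bg = 1) {
  spec <- list(size = as.integer(size), lambda = lambda,
               axis_range = axis_range, irregularity = irregularity,
               max_overlap_iou = max_overlap_iou,
               tumor_fraction = tumor_fraction,
               normal_mean = normal_mean, normal_sd = normal_sd,
               tumor_mean = tumor_mean, tumor_sd = tumor_sd,
               dapi_fg_mean = dapi_fg_mean, dapi_fg_sd = dapi_fg_sd,
               dapi_bg = dapi_bg, noise_sd = noise_sd, probe_bg = probe_bg)
  stopifnot(length(spec$size) == 2L, all(spec$size > 0L), spec$lambda >= 0,
            all(spec$axis_range > 0), diff(spec$axis_range) >= 0,
            spec$tumor_fraction >= 0, spec$tumor_fraction <= 1,
            spec$tumor_mean > spec$normal_mean)
  structure(spec, class = "scene_spec")
}

# Sample one cell shape directly in EFD space: rotated harmonic-1 ellipse
# plus small random harmonics 2-4, so every generated cell carries exact
# descriptor ground truth.
sample_cell_efd <- function(cx, cy, rx, ry, irregularity) {
  phi <- runif(1, 0, pi)
  h1 <- c(a = rx * cos(phi), b = -ry * sin(phi),
          c = rx * sin(phi), d = ry * cos(phi))
  rmean <- (rx + ry) / 2
  harm <- rbind(h1, t(vapply(2:4, function(n)
    rnorm(4L, sd = irregularity * rmean / n), numeric(4L))))
  new_efd(cx, cy, harm)
}

#' Generate one synthetic two-channel scene
#'
#' Synthesizes a DAPI-like nuclear channel, an RGB probe channel whose red
#' channel carries the fluorescence signal (faint autofluorescence in
#' green/blue), an instance-labeled mask, per-cell class labels, and exact
#' elliptic Fourier descriptor ground truth. Cells are placed by rejection
#' sampling so no pair exceeds the overlap cap; a cell that cannot be
#' placed within the retry budget is skipped with a warning. Intensities
#' are clipped to 8-bit and rounded. Fully determined by `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; if NULL the current RNG stream is used.
#' @param noiseless if TRUE, omit per-pixel noise (cells painted at their
#'   exact class draw; useful for exact count recovery checks).
#' @return list(dapi, probe, mask, cells, efds, spec, seed) where `cells`
#'   is a data.frame (label, tumor, probe_mean, dapi_mean, cx, cy) and
#'   `efds` the list of ground-truth descriptors.
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL,
                           noiseless = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  H <- spec$size[1L]; W <- spec$size[2L]
  n_want <- rpois(1L, spec$lambda)
  mask <- matrix(0L, H, W)
  cells <- data.frame(label = integer(), tumor = logical(),
                      probe_mean = numeric(), dapi_mean = numeric(),
                      cx = numeric(), cy = numeric())
  efds <- list()
  pixsets <- list()
  margin <- max(spec$axis_range) + 2
  lab <- 0L
  for (k in seq_len(n_want)) {
    placed <- FALSE
    for (try in seq_len(50L)) {
      rx <- runif(1, spec$axis_range[1L], spec$axis_range[2L])
      ry <- runif(1, spec$axis_range[1L], spec$axis_range[2L])
      cx <- runif(1, margin, W - 1 - margin)
      cy <- runif(1, margin, H - 1 - margin)
      e <- sample_cell_efd(cx, cy, rx, ry, spec$irregularity)
      pix <- rasterize_contour(efd_decode(e, 96L), dim = c(H, W))
      if (nrow(pix) < 5L) next
      idx <- pixel_index(pix, c(H, W))
      ok <- TRUE
      for (ps in pixsets) {
        ninter <- length(intersect(idx, ps))
        if (ninter > 0L &&
            ninter / (length(idx) + length(ps) - ninter) > spec$max_overlap_iou) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      lab <- lab + 1L
      free <- mask[idx] == 0L
      mask[idx[free]] <- lab
      pixsets[[lab]] <- idx
      tumor <- runif(1) < spec$tumor_fraction
      pm <- if (tumor) {
        max(0, rnorm(1, spec$tumor_mean, spec$tumor_sd))
      } else {
        # normal-like cells all sit below the threshold-10 line (matching
        # the reported intensity distributions); truncate the tail with a
        # margin for 8-bit rounding
        repeat {
          cand <- max(0, rnorm(1, spec$normal_mean, spec$normal_sd))
          if (cand <= 9.5) break
        }
        cand
      }
      dm <- max(40, rnorm(1, spec$dapi_fg_mean, spec$dapi_fg_sd))
      cells <- rbind(cells, data.frame(label = lab, tumor = tumor,
                                       probe_mean = pm, dapi_mean = dm,
                                       cx = e$A0, cy = e$C0))
      efds[[lab]] <- e
      placed <- TRUE
      break
    }
    if (!placed && n_want > 0L)
      warning(sprintf("could not place cell %d of %d within retry budget",
                      k, n_want))
  }
  noise <- function(n) if (noiseless) 0 else rnorm(n, 0, spec$noise_sd)
  # the planted per-cell mean is the MEASURED FL quantity: gray =
  # (R + G + B)/3 with G = B = 0.05 R, so R = 3 m / 1.1
  red_scale <- 3 / 1.1
  dapi <- matrix(spec$dapi_bg + noise(H * W), H, W)
  red <- matrix(spec$probe_bg + noise(H * W) / 2, H, W)
  for (i in seq_len(lab)) {
    idx <- which(mask == i)
    dapi[idx] <- cells$dapi_mean[i] + noise(length(idx))
    red[idx] <- red_scale * cells$probe_mean[i] + if (noiseless) 0 else
      rnorm(length(idx), 0, 1)
  }
  clip8 <- function(m) { m <- round(m); m[m < 0] <- 0; m[m > 255] <- 255; m }
  dapi <- clip8(dapi)
  red <- clip8(red)
  green <- clip8(0.05 * red + matrix(noise(H * W) / 2, H, W))
  blue <- clip8(0.05 * red + matrix(noise(H * W) / 2, H, W))
  probe <- array(c(red, green, blue), c(H, W, 3L))
  list(dapi = dapi, probe = probe, mask = mask, cells = cells, efds = efds,
       spec = spec, seed = seed)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes per-image nuclear-channel PGM, probe-channel PPM, 16-bit instance
#' mask PGM and ground-truth CSV (class labels + EFD coefficients), plus a
#' JSON manifest listing files, per-image seeds, cell counts and file
#' hashes. Regeneration with the same seed reproduces identical files.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes.
#' @param out_dir output directory.
#' @param seed base seed; image i uses seed + i.
#' @param force overwrite a non-empty existing directory.
#' @return The manifest (invisibly also written to manifest.json).
#' @export
generate_dataset <- function(spec = scene_spec(), n_images, out_dir,
                             seed = 1L, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)",
                 out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_len(n_images)) {
    si <- as.integer(seed) + i
    sc <- generate_scene(spec, seed = si)
    base <- sprintf("img_%03d", i)
    fd <- file.path(out_dir, paste0(base, "_dapi.pgm"))
    fp <- file.path(out_dir, paste0(base, "_probe.ppm"))
    fm <- file.path(out_dir, paste0(base, "_mask.pgm"))
    ft <- file.path(out_dir, paste0(base, "_truth.csv"))
    write_image(sc$dapi, fd)
    write_image(sc$probe, fp)
    write_mask(sc$mask, fm)
    truth <- cbind(sc$cells,
                   efd_to_table(sc$efds, sc$cells$label)[, -1, drop = FALSE])
    write.csv(truth, ft, row.names = FALSE)
    entries[[i]] <- list(id = base, seed = si,
                         n_cells = nrow(sc$cells),
                         n_tumor = sum(sc$cells$tumor),
                         dapi = basename(fd), probe = basename(fp),
                         mask = basename(fm), truth = basename(ft),
                         md5 = as.list(stats::setNames(
                           unname(tools::md5sum(c(fd, fp, fm, ft))),
                           c("dapi", "probe", "mask", "truth"))))
  }
  manifest <- list(n_images = n_images, seed = as.integer(seed),
                   spec = unclass(spec), images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
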