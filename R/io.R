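# Image input/output in binary netpbm formats: P5 (grayscale, 8- or 16-bit
# big-endian) and P6 (RGB). Lossless roundtrip for 8-bit images and 16-bit
# instance masks; no external imaging libraries required.

#' Read and write images (netpbm PGM/PPM)
#'
#' `write_image` stores a matrix as 8-bit PGM (P5) or an H x W x 3 array as
#' 8-bit PPM (P6). `read_image` returns a matrix or H x W x 3 array of
#' integer counts. `write_mask`/`read_mask` store integer instance masks as
#' 16-bit big-endian PGM, losslessly for labels up to 65535.
#'
#' @param image matrix (grayscale) or H x W x 3 array (RGB), values 0-255.
#' @param path file path.
#' @return `read_image`/`read_mask` return the image; writers return the
#'   path invisibly.
#' @export
write_image <- function(image, path) {
  v <- round(as.numeric(image))
  if (any(v < 0 | v > 255)) stop("8-bit image values must be in [0, 255]")
  if (length(dim(image)) == 3L) {
    if (dim(image)[3L] != 3L) stop("color images must be H x W x 3")
    H <- dim(image)[1L]; W <- dim(image)[2L]
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(W, H), "255"), con, sep = "\n")
    # channel fastest, then column, then row (netpbm raster order)
    writeBin(as.integer(round(aperm(image, c(3L, 2L, 1L)))), con, size = 1L)
  } else {
    H <- nrow(image); W <- ncol(image)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(W, H), "255"), con, sep = "\n")
    writeBin(as.integer(t(round(image))), con, size = 1L)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_pnm_header(con)
  npx <- hdr$W * hdr$H
  if (hdr$magic == "P5") {
    if (hdr$maxval <= 255L) {
      v <- readBin(con, "integer", npx, size = 1L, signed = FALSE)
      matrix(v, hdr$H, hdr$W, byrow = TRUE)
    } else {
      v <- readBin(con, "integer", npx, size = 2L, signed = FALSE,
                   endian = "big")
      matrix(v, hdr$H, hdr$W, byrow = TRUE)
    }
  } else if (hdr$magic == "P6") {
    v <- readBin(con, "integer", 3L * npx, size = 1L, signed = FALSE)
    arr <- array(v, c(3L, hdr$W, hdr$H))
    aperm(arr, c(3L, 2L, 1L))
  } else stop(sprintf("unsupported netpbm magic '%s'", hdr$magic))
}

#' @rdname write_image
#' @param mask integer instance mask, labels 0-65535.
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  if (any(mask > 65535L)) stop("mask labels exceed 16-bit range")
  H <- nrow(mask); W <- ncol(mask)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(W, H), "65535"), con, sep = "\n")
  v <- as.integer(t(mask))
  b <- as.raw(c(rbind(v %/% 256L, v %% 256L))) # big-endian
  writeBin(b, con)
  invisible(path)
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  validate_mask(m)
}

read_pnm_header <- function(con) {
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  list(magic = tok[1L], W = as.integer(tok[2L]), H = as.integer(tok[3L]),
       maxval = as.integer(tok[4L]))
}

#' Write a structured report as JSON
#'
#' Serializes evaluation and intensity reports with a fixed schema:
#' `eval_report` -> {type, taus, per_tau: [...], f1avg};
#' `intensity_report` -> {type, theta, per_cell: [...], per_image: {...}}.
#'
#' @param report an `eval_report` or `intensity_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  obj <- if (inherits(report, "eval_report")) {
    list(type = "eval_report", taus = report$taus,
         per_tau = report$per_tau, f1avg = report$f1avg)
  } else if (inherits(report, "intensity_report")) {
    list(type = "intensity_report", theta = report$theta,
         per_cell = report$per_cell, per_image = report$per_image)
  } else stop("unsupported report type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

default_config <- function() {
  list(detector = unclass(detector_config()),
       quantify = list(threshold = 10, gray_mode = "mean"),
       evaluate = list(taus = c(0.5, 0.6, 0.7, 0.8, 0.9), mode = "macro"),
       synthgen = unclass(scene_spec()),
       seed = 1L,
       verbosity = 1L)
}

#' Load and validate a run configuration
#'
#' Precedence: package defaults < JSON config file < explicit overrides.
#' Unknown keys anywhere in the tree are rejected with an error naming
#' them.
#'
#' @param path optional JSON config file.
#' @param overrides named list of overrides, nested like the defaults
#'   (e.g. `list(quantify = list(threshold = 12))`).
#' @return The merged configuration list (class `run_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, file_cfg, "")
  }
  cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, upd, prefix) {
  if (length(upd) == 0L) return(base)
  bad <- setdiff(names(upd), names(base))
  if (length(bad) > 0L)
    stop(sprintf("unknown config key(s): %s",
                 paste0(prefix, bad, collapse = ", ")))
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]],
                                 paste0(prefix, nm, "."))
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}
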