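#' CT slice container
#'
#' A `ct_slice` holds a rectangular grid of Hounsfield units (HU) together
#' with optional acquisition metadata. HU are dimensionless attenuation
#' values (water = 0, air = -1000); no range clamp is applied.
#'
#' @param pixel_hu numeric matrix of HU values (rows x cols), all finite.
#' @param pixel_spacing optional mm-per-pixel scalar or length-2 vector.
#' @param source_id opaque provenance string.
#' @return An object of class `ct_slice` with fields `pixel_hu`,
#'   `row_count`, `col_count`, `pixel_spacing`, `source_id`.
#' @export
#' @examples
#' s <- ct_slice(matrix(0, 4, 4))
#' dim(s$pixel_hu)
ct_slice <- function(pixel_hu, pixel_spacing = NULL, source_id = "") {
  if (!is.matrix(pixel_hu) || !is.numeric(pixel_hu) || length(pixel_hu) == 0L)
    ct2bmd_stop("ct2bmd_format_error", "pixel_hu must be a non-empty numeric matrix")
  if (!all(is.finite(pixel_hu)))
    ct2bmd_stop("ct2bmd_format_error", "pixel_hu contains non-finite values")
  structure(list(
    pixel_hu = pixel_hu,
    row_count = nrow(pixel_hu),
    col_count = ncol(pixel_hu),
    pixel_spacing = pixel_spacing,
    source_id = source_id
  ), class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, HU range [%.1f, %.1f]%s\n",
              x$row_count, x$col_count, min(x$pixel_hu), max(x$pixel_hu),
              if (nzchar(x$source_id)) paste0(", source ", x$source_id) else ""))
  invisible(x)
}

#' Load a CT slice from disk
#'
#' Reads a single-frame grayscale image and converts stored pixel values to
#' Hounsfield units as `HU = stored * rescale_slope + rescale_intercept`.
#' Two formats are supported:
#' \describe{
#'   \item{DICOM (`.dcm`/`.dicom`)}{single-frame, uncompressed, grayscale,
#'     little-endian; rescale slope/intercept taken from the standard tags
#'     when present, identity otherwise (with a message).}
#'   \item{PGM (`.pgm`)}{plain (P2) or raw 8/16-bit (P5) portable graymap,
#'     the package's lossless fixture format, with an optional JSON sidecar
#'     `<path>.json` holding `{"rescale_slope": s, "rescale_intercept": b}`.
#'     Without a sidecar the identity mapping is used (with a message).}
#' }
#'
#' @param path file path.
#' @param sidecar optional explicit sidecar path for PGM input; default is
#'   `<path>.json` if it exists.
#' @return A [ct_slice].
#' @export
load_slice <- function(path, sidecar = NULL) {
  if (!file.exists(path))
    ct2bmd_stop("ct2bmd_format_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) {
    return(read_dicom_slice(path))
  }
  if (ext == "pgm") {
    px <- read_pgm(path)
    if (is.null(sidecar)) {
      cand <- paste0(path, ".json")
      if (file.exists(cand)) sidecar <- cand
    }
    slope <- 1; intercept <- 0
    if (!is.null(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(sc$rescale_slope)) slope <- as.numeric(sc$rescale_slope)
      if (!is.null(sc$rescale_intercept)) intercept <- as.numeric(sc$rescale_intercept)
    } else {
      message("load_slice: no HU sidecar for ", basename(path),
              "; using identity HU mapping")
    }
    return(ct_slice(px * slope + intercept, source_id = basename(path)))
  }
  ct2bmd_stop("ct2bmd_format_error", "unsupported image format: .%s", ext)
}

#' Read a PGM image
#'
#' Supports plain ASCII (P2) and raw binary (P5, 8- or 16-bit big-endian)
#' portable graymaps. Comment lines (`#`) in the header are ignored.
#'
#' @param path file path.
#' @return Integer matrix of stored pixel values.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    ct2bmd_stop("ct2bmd_format_error", "not a P2/P5 PGM file: %s", path)
  # read header tokens (width, height, maxval), skipping comments
  toks <- integer(0)
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || !nzchar(ch))
      ct2bmd_stop("ct2bmd_format_error", "truncated PGM header: %s", path)
    if (ch == "#") { # skip to end of line
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (!nzchar(c2) || c2 == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (w < 1L || h < 1L)
    ct2bmd_stop("ct2bmd_format_error", "bad PGM dimensions in %s", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    size <- if (maxval > 255L) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                    endian = "big")
  }
  if (length(vals) < n)
    ct2bmd_stop("ct2bmd_format_error", "truncated PGM pixel data: %s", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a plain (P2) PGM image, optionally with an HU sidecar
#'
#' Stored values are `round((hu - rescale_intercept) / rescale_slope)`;
#' with the default 16-bit range and integer HU this round-trips losslessly
#' through [load_slice()].
#'
#' @param hu numeric HU matrix.
#' @param path output path (`.pgm`).
#' @param rescale_slope,rescale_intercept affine HU mapping stored in the
#'   JSON sidecar `<path>.json`.
#' @param maxval PGM maximum stored value (default 65535).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(hu, path, rescale_slope = 1, rescale_intercept = -1024,
                      maxval = 65535L) {
  stored <- round((hu - rescale_intercept) / rescale_slope)
  if (any(stored < 0) || any(stored > maxval))
    ct2bmd_stop("ct2bmd_parameter_error",
                "HU values out of storable range for the given rescale mapping")
  lines <- c("P2", sprintf("%d %d", ncol(hu), nrow(hu)), as.character(maxval),
             apply(stored, 1L, paste, collapse = " "))
  writeLines(lines, path)
  jsonlite::write_json(
    list(rescale_slope = rescale_slope, rescale_intercept = rescale_intercept),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Region-of-interest definitions
#'
#' ROIs use 0-based, row-major coordinates with half-open extents: a
#' rectangle at origin `(r, c)` with size `(h, w)` covers rows
#' `r .. r+h-1` and columns `c .. c+w-1`. The ellipse variant keeps the
#' pixels inside the ellipse inscribed in that bounding box.
#'
#' @param origin_row,origin_col 0-based integer origin.
#' @param height,width positive integer extents in pixels.
#' @return An object of class `roi_definition`.
#' @export
#' @examples
#' roi_rectangle(0, 0, 4, 4)
roi_rectangle <- function(origin_row, origin_col, height, width) {
  new_roi("rectangle", origin_row, origin_col, height, width)
}

#' @rdname roi_rectangle
#' @export
roi_ellipse <- function(origin_row, origin_col, height, width) {
  new_roi("ellipse", origin_row, origin_col, height, width)
}

new_roi <- function(shape, origin_row, origin_col, height, width) {
  if (height < 1L || width < 1L)
    ct2bmd_stop("ct2bmd_parameter_error", "ROI extents must be positive")
  if (origin_row < 0L || origin_col < 0L)
    ct2bmd_stop("ct2bmd_parameter_error", "ROI origin must be non-negative")
  structure(list(shape = shape,
                 origin_row = as.integer(origin_row),
                 origin_col = as.integer(origin_col),
                 height = as.integer(height),
                 width = as.integer(width)),
            class = "roi_definition")
}

#' Read an ROI definition from JSON
#'
#' Format: `{"shape": "rectangle"|"ellipse", "origin": [r, c], "size": [h, w]}`
#' with 0-based origin.
#'
#' @param path JSON file path.
#' @return A `roi_definition`.
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_roi(match.arg(x$shape, c("rectangle", "ellipse")),
          x$origin[1], x$origin[2], x$size[1], x$size[2])
}

#' Extract an ROI from a slice
#'
#' Returns the masked HU pixels plus their mean and standard deviation.
#' For an ellipse, pixels outside the inscribed ellipse are `NA` in the
#' returned grid and excluded from the statistics. The SD is the population
#' SD (divide by n) unless `sample_sd = TRUE`.
#'
#' @param slice a [ct_slice].
#' @param roi a `roi_definition` (see [roi_rectangle()]).
#' @param sample_sd use the n-1 denominator instead of n.
#' @return List with `hu` (matrix, `NA` outside an elliptical mask),
#'   `values` (vector of masked pixels), `mask` (logical matrix),
#'   `mean_hu`, `sd_hu`, `n_pixels`.
#' @export
#' @examples
#' s <- ct_slice(matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE))
#' extract_roi(s, roi_rectangle(0, 0, 2, 2))$mean_hu
extract_roi <- function(slice, roi, sample_sd = FALSE) {
  stopifnot(inherits(slice, "ct_slice"), inherits(roi, "roi_definition"))
  r0 <- roi$origin_row; c0 <- roi$origin_col
  h <- roi$height; w <- roi$width
  if (r0 + h > slice$row_count || c0 + w > slice$col_count)
    ct2bmd_stop("ct2bmd_bounds_error",
                "ROI [%d+%d, %d+%d] exceeds slice bounds %d x %d",
                r0, h, c0, w, slice$row_count, slice$col_count)
  grid <- slice$pixel_hu[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), drop = FALSE]
  if (roi$shape == "ellipse") {
    cr <- (h - 1) / 2; cc <- (w - 1) / 2
    rr <- matrix(0:(h - 1), h, w)
    cm <- matrix(0:(w - 1), h, w, byrow = TRUE)
    mask <- ((rr - cr) / (h / 2))^2 + ((cm - cc) / (w / 2))^2 <= 1
    if (sum(mask) < 4L)
      ct2bmd_stop("ct2bmd_degenerate_roi_error",
                  "elliptical mask contains %d < 4 pixels", sum(mask))
    grid[!mask] <- NA_real_
  } else {
    mask <- matrix(TRUE, h, w)
  }
  vals <- grid[mask]
  n <- length(vals)
  m <- mean(vals)
  ss <- sum((vals - m)^2)
  s <- sqrt(ss / if (sample_sd) max(n - 1L, 1L) else n)
  list(hu = grid, values = vals, mask = mask,
       mean_hu = m, sd_hu = s, n_pixels = n)
}

#' Quantize an HU grid to discrete gray levels
#'
#' Linear binning of `[hu_min, hu_max]` into `Ng` equal-width bins; values
#' at or below `hu_min` map to level 0, at or above `hu_max` to `Ng - 1`.
#' Default bounds are the grid's own (finite) min/max, the per-ROI
#' convention of common GLCM toolboxes. A constant grid maps entirely to
#' level 0. `NA` pixels (elliptical masks) stay `NA`.
#'
#' @param hu numeric matrix of HU values, possibly with `NA` outside a mask.
#' @param Ng number of gray levels, >= 2 (default 8).
#' @param bounds optional `c(hu_min, hu_max)` fixed binning bounds.
#' @return An object of class `quantized_roi`: `levels` (integer matrix in
#'   `0..Ng-1`), `Ng`, `hu_min`, `hu_max`, `mean_hu`, `sd_hu`.
#' @export
#' @examples
#' q <- quantize(matrix(c(0, 10, 20, 30), 2, 2), Ng = 2)
#' q$levels
quantize <- function(hu, Ng = 8L, bounds = NULL) {
  if (is.list(hu) && !is.null(hu$hu)) hu <- hu$hu  # accept extract_roi output
  if (!is.matrix(hu) || length(hu) == 0L)
    ct2bmd_stop("ct2bmd_parameter_error", "hu must be a non-empty matrix")
  Ng <- as.integer(Ng)
  if (is.na(Ng) || Ng < 2L)
    ct2bmd_stop("ct2bmd_parameter_error", "Ng must be an integer >= 2")
  vals <- hu[is.finite(hu)]
  if (length(vals) == 0L)
    ct2bmd_stop("ct2bmd_degenerate_roi_error", "no finite pixels to quantize")
  if (is.null(bounds)) bounds <- range(vals)
  hu_min <- bounds[1]; hu_max <- bounds[2]
  if (hu_min > hu_max)
    ct2bmd_stop("ct2bmd_parameter_error", "hu_min must be <= hu_max")
  lv <- matrix(NA_integer_, nrow(hu), ncol(hu))
  fin <- is.finite(hu)
  if (hu_max == hu_min) {
    lv[fin] <- 0L
  } else {
    z <- floor((hu[fin] - hu_min) / (hu_max - hu_min) * Ng)
    lv[fin] <- as.integer(pmin(pmax(z, 0), Ng - 1L))
  }
  m <- mean(vals)
  structure(list(levels = lv, Ng = Ng, hu_min = hu_min, hu_max = hu_max,
                 mean_hu = m, sd_hu = sqrt(mean((vals - m)^2))),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d x %d px, Ng = %d, HU [%.1f, %.1f], mean %.2f (SD %.2f)\n",
              nrow(x$levels), ncol(x$levels), x$Ng, x$hu_min, x$hu_max,
              x$mean_hu, x$sd_hu))
  invisible(x)
}
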