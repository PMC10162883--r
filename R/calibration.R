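#' Fit a QCT phantom calibration line
#'
#' Ordinary least squares of nominal insert density on measured HU:
#' `density = slope * HU + intercept`. This is the standard QCT convention
#' for converting attenuation to hydroxyapatite-equivalent density using a
#' tissue-characterization phantom scanned alongside the specimen.
#'
#' @param inserts data frame with columns `density` (mg/cm3, >= 0) and `hu`
#'   (mean HU over each rod's ROI); at least 2 rows with distinct HU.
#' @param unit unit label carried through to outputs (default `"mg/cm3"`).
#' @return Object of class `phantom_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n_inserts`, `unit`.
#' @export
#' @examples
#' cal <- fit_calibration(data.frame(density = c(0, 100, 200),
#'                                   hu = c(-50, 75, 200)))
#' cal$slope
fit_calibration <- function(inserts, unit = "mg/cm3") {
  if (!is.data.frame(inserts) || !all(c("density", "hu") %in% names(inserts)))
    ct2bmd_stop("ct2bmd_parameter_error",
                "inserts must be a data frame with columns density, hu")
  if (nrow(inserts) < 2L || length(unique(inserts$hu)) < 2L)
    ct2bmd_stop("ct2bmd_degenerate_calibration_error",
                "need >= 2 inserts with distinct HU (got %d distinct)",
                length(unique(inserts$hu)))
  if (any(inserts$density < 0))
    ct2bmd_stop("ct2bmd_parameter_error", "nominal densities must be >= 0")
  fit <- stats::lm(density ~ hu, data = inserts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((inserts$density - mean(inserts$density))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_inserts = nrow(inserts),
                 unit = unit),
            class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat(sprintf("<phantom_calibration> density = %.6g * HU + %.6g %s (r2 = %.4f, %d inserts)\n",
              x$slope, x$intercept, x$unit, x$r_squared, x$n_inserts))
  invisible(x)
}

#' Convert HU to bone-equivalent density
#'
#' Applies the fitted affine phantom calibration element-wise.
#'
#' @param hu HU value, vector, or matrix.
#' @param cal a [fit_calibration()] result.
#' @return Density in `cal$unit`, same shape as `hu`.
#' @export
hu_to_bmd <- function(hu, cal) {
  stopifnot(inherits(cal, "phantom_calibration"))
  cal$slope * hu + cal$intercept
}

#' Read/write phantom calibration files
#'
#' Insert files: `{"inserts": [{"density": x, "hu": y}, ...]}`.
#' Calibration files:
#' `{"slope": s, "intercept": b, "r_squared": r, "n_inserts": n, "unit": u}`.
#'
#' @param path JSON file path.
#' @return `read_inserts()`: a data frame; `read_calibration()`: a
#'   `phantom_calibration`; writers return `path` invisibly.
#' @export
read_inserts <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(x$inserts)
}

#' @rdname read_inserts
#' @param cal a `phantom_calibration`.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_inserts
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("slope", "intercept", "r_squared", "n_inserts", "unit")],
            class = "phantom_calibration")
}

#' Reference calibration used by the synthetic phantom world
#'
#' A fixed four-insert hydroxyapatite-style calibration (0, 100, 200 and
#' 400 mg/cm3 at 0, 125, 250 and 500 HU; slope 0.8 mg/cm3 per HU,
#' intercept 0). Ground-truth densities of synthetic phantoms are defined
#' through this line so the synthetic path exercises the calibration code.
#'
#' @return A `phantom_calibration`.
#' @export
reference_calibration <- function() {
  fit_calibration(data.frame(density = c(0, 100, 200, 400),
                             hu = c(0, 125, 250, 500)))
}
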