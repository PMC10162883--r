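#' Gray-level co-occurrence matrix (GLCM)
#'
#' Counts ordered pixel pairs `(p, q)` where `q` sits at displacement `d`
#' from `p` along orientation `theta`, then normalizes counts to a joint
#' probability matrix `P(i, j | d, theta)`. Offsets follow the usual image
#' convention (row down, column right):
#' 0 deg -> `(0, +d)`, 45 deg -> `(-d, +d)`, 90 deg -> `(-d, 0)`,
#' 135 deg -> `(-d, -d)`.
#'
#' By default accumulation is asymmetric (each pair counted once, in the
#' offset direction), matching the common MATLAB/IPT default; with
#' `symmetric = TRUE` every pair is also counted in reverse. `NA` levels
#' (pixels outside an elliptical mask) never contribute.
#'
#' @param roi a [quantize()]d ROI, or a bare integer level matrix (then `Ng`
#'   must be supplied).
#' @param d displacement in pixels, >= 1.
#' @param theta orientation in degrees: 0, 45, 90 or 135.
#' @param symmetric count each pair in both directions.
#' @param Ng gray-level count when `roi` is a bare matrix.
#' @return Object of class `glcm`: `P` (Ng x Ng probability matrix with
#'   `P[i+1, j+1] = P(i, j)`), `Ng`, `d`, `theta`, `symmetric`,
#'   `pair_count`.
#' @export
#' @examples
#' q <- quantize(matrix(c(0, 0, 30, 30), 2, 2), Ng = 2)
#' compute_glcm(q, d = 1, theta = 0)$P
compute_glcm <- function(roi, d = 1L, theta = 0, symmetric = FALSE, Ng = NULL) {
  if (inherits(roi, "quantized_roi")) {
    L <- roi$levels; Ng <- roi$Ng
  } else {
    L <- roi
    if (is.null(Ng)) Ng <- max(L, na.rm = TRUE) + 1L
  }
  d <- as.integer(d)
  if (d < 1L) ct2bmd_stop("ct2bmd_parameter_error", "d must be >= 1")
  off <- switch(as.character(theta),
                "0"   = c(0L, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0L),
                "135" = c(-d, -d),
                ct2bmd_stop("ct2bmd_parameter_error",
                            "theta must be one of 0, 45, 90, 135 (got %s)", theta))
  counts <- glcm_counts(L, Ng, off[1], off[2])
  if (symmetric) counts <- counts + t(counts)
  pair_count <- sum(counts)
  if (pair_count == 0)
    ct2bmd_stop("ct2bmd_degenerate_roi_error",
                "no valid pixel pairs at d = %d, theta = %s", d, theta)
  structure(list(P = counts / pair_count, Ng = as.integer(Ng), d = d,
                 theta = theta, symmetric = symmetric,
                 pair_count = pair_count),
            class = "glcm")
}

# Raw pair counts for a (dr, dc) offset; vectorized over shifted submatrices.
glcm_counts <- function(L, Ng, dr, dc) {
  nr <- nrow(L); nc <- ncol(L)
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(matrix(0, Ng, Ng))
  i <- L[rlo:rhi, clo:chi, drop = FALSE]
  j <- L[(rlo + dr):(rhi + dr), (clo + dc):(chi + dc), drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  idx <- i[ok] * Ng + j[ok] + 1L
  matrix(tabulate(idx, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> Ng = %d, d = %d, theta = %s, %s, %d pairs\n",
              x$Ng, x$d, as.character(x$theta),
              if (x$symmetric) "symmetric" else "asymmetric", x$pair_count))
  invisible(x)
}

#' Average a list of GLCMs
#'
#' Element-wise arithmetic mean, renormalized so entries sum to exactly 1
#' (guards accumulated rounding). All matrices must share `Ng`.
#'
#' @param mats non-empty list of [compute_glcm()] results.
#' @return A `glcm` with `theta = "averaged"`.
#' @export
average_glcms <- function(mats) {
  if (!length(mats))
    ct2bmd_stop("ct2bmd_parameter_error", "empty GLCM list")
  ngs <- vapply(mats, function(m) m$Ng, integer(1))
  if (length(unique(ngs)) != 1L)
    ct2bmd_stop("ct2bmd_shape_error", "GLCMs have mixed Ng: %s",
                paste(unique(ngs), collapse = ", "))
  P <- Reduce(`+`, lapply(mats, `[[`, "P")) / length(mats)
  P <- P / sum(P)
  structure(list(P = P, Ng = ngs[1], d = mats[[1]]$d, theta = "averaged",
                 symmetric = mats[[1]]$symmetric,
                 pair_count = sum(vapply(mats, `[[`, numeric(1), "pair_count"))),
            class = "glcm")
}

as_prob_matrix <- function(P) {
  if (inherits(P, "glcm")) P <- P$P
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  P
}

#' Haralick texture features of a GLCM
#'
#' Five second-order statistics of the joint probability matrix `P(i, j)`,
#' with gray-level indices `i, j` running from 0 to `Ng - 1`:
#' \describe{
#'   \item{energy}{angular second moment, `sum P(i,j)^2`; 1 iff all mass in
#'     one cell.}
#'   \item{entropy}{`-sum P log2 P` (bits; `0 log 0 = 0`); base switchable.}
#'   \item{contrast}{`sum (i-j)^2 P(i,j)`, local variation in level units^2.}
#'   \item{homogeneity}{inverse difference moment,
#'     `sum P(i,j) / (1 + (i-j)^2)`, in (0, 1].}
#'   \item{correlation}{`(sum i*j*P(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)`
#'     with marginal means/SDs; the degenerate case `sigma_x*sigma_y = 0`
#'     (e.g. a constant image) returns 1 with `correlation_degenerate` set.}
#' }
#'
#' @param P a `glcm` or a bare square probability matrix.
#' @param base logarithm base for the entropy (default 2, bits).
#' @return For `glcm_features()`, an object of class `texture_features`:
#'   the five features plus marginal statistics `mu_x`, `mu_y`, `sigma_x`,
#'   `sigma_y` and the `correlation_degenerate` flag. The single-feature
#'   functions return one numeric value.
#' @export
glcm_features <- function(P, base = 2) {
  P <- as_prob_matrix(P)
  Ng <- nrow(P)
  idx <- 0:(Ng - 1)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(idx * px); mu_y <- sum(idx * py)
  sigma_x <- sqrt(sum((idx - mu_x)^2 * px))
  sigma_y <- sqrt(sum((idx - mu_y)^2 * py))
  dd <- outer(idx, idx, `-`)^2
  degen <- sigma_x * sigma_y == 0
  corr <- if (degen) 1 else
    (sum(outer(idx, idx) * P) - mu_x * mu_y) / (sigma_x * sigma_y)
  structure(list(
    energy = sum(P^2),
    entropy = glcm_entropy(P, base),
    contrast = sum(dd * P),
    homogeneity = sum(P / (1 + dd)),
    correlation = corr,
    mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
    correlation_degenerate = degen
  ), class = "texture_features")
}

#' @rdname glcm_features
#' @export
glcm_energy <- function(P) sum(as_prob_matrix(P)^2)

#' @rdname glcm_features
#' @export
glcm_entropy <- function(P, base = 2) {
  P <- as_prob_matrix(P)
  p <- P[P > 0]
  -sum(p * log(p, base = base))
}

#' @rdname glcm_features
#' @export
glcm_contrast <- function(P) {
  P <- as_prob_matrix(P)
  idx <- 0:(nrow(P) - 1)
  sum(outer(idx, idx, `-`)^2 * P)
}

#' @rdname glcm_features
#' @export
glcm_homogeneity <- function(P) {
  P <- as_prob_matrix(P)
  idx <- 0:(nrow(P) - 1)
  sum(P / (1 + outer(idx, idx, `-`)^2))
}

#' @rdname glcm_features
#' @export
glcm_correlation <- function(P) glcm_features(P)$correlation

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf(paste0("<texture_features> contrast %.4f, correlation %.4f%s, ",
                     "energy %.4f, homogeneity %.4f, entropy %.4f\n"),
              x$contrast, x$correlation,
              if (x$correlation_degenerate) " (degenerate)" else "",
              x$energy, x$homogeneity, x$entropy))
  invisible(x)
}

#' Texture features of a quantized ROI
#'
#' Computes GLCMs at every requested orientation, averages them, and
#' evaluates the five Haralick features on the averaged matrix (the
#' "features of the average GLCM" convention). Defaults: displacement 1,
#' orientations 0/45/90 degrees, asymmetric accumulation. Set
#' `average = "features"` to instead average per-orientation feature values
#' (sensitivity-check alternative).
#'
#' @param roi a `quantized_roi` (or bare level matrix with `Ng` attr via
#'   [compute_glcm()] semantics).
#' @param d displacement in pixels.
#' @param thetas orientations in degrees.
#' @param symmetric symmetric pair accumulation.
#' @param average `"glcm"` (default) or `"features"`.
#' @param base entropy log base.
#' @return A `texture_features` object.
#' @export
#' @examples
#' set.seed(1)
#' q <- quantize(matrix(rnorm(256), 16, 16), Ng = 8)
#' features_from_roi(q)
features_from_roi <- function(roi, d = 1L, thetas = c(0, 45, 90),
                              symmetric = FALSE, average = c("glcm", "features"),
                              base = 2) {
  average <- match.arg(average)
  mats <- lapply(thetas, function(th) compute_glcm(roi, d, th, symmetric))
  if (average == "glcm") {
    glcm_features(average_glcms(mats), base = base)
  } else {
    fs <- lapply(mats, glcm_features, base = base)
    out <- fs[[1]]
    num <- c("energy", "entropy", "contrast", "homogeneity", "correlation",
             "mu_x", "mu_y", "sigma_x", "sigma_y")
    for (k in num) out[[k]] <- mean(vapply(fs, `[[`, numeric(1), k))
    out$correlation_degenerate <- any(vapply(fs, `[[`, logical(1),
                                             "correlation_degenerate"))
    out
  }
}

#' Convert texture features to a one-row data frame
#'
#' Column order follows the package's canonical feature table layout:
#' `contrast, correlation, energy, homogeneity, entropy`.
#'
#' @param x a `texture_features` object.
#' @param ... unused.
#' @return One-row data frame.
#' @export
as.data.frame.texture_features <- function(x, ...) {
  as.data.frame(x[FEATURE_NAMES])
}
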