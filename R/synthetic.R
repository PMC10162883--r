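#' Synthetic trabecular phantom specification
#'
#' Describes a two-phase (bone/marrow) trabecular-textured 2D phantom.
#' A seeded Gaussian random field is thresholded at the `1 - bvtv`
#' quantile, so the realized bone-pixel fraction tracks the target
#' bone-volume fraction (BV/TV) up to discreteness. Two renderings are
#' produced per phantom: a sharp "QCT" image (additive noise only) and a
#' degraded "clinical CT" image (Gaussian blur, then stronger noise).
#'
#' Defaults (documented in the methods vignette): 128 x 128 px, marrow at
#' -50 HU, bone at +700 HU, texture correlation length 3 px, QCT noise SD
#' 15 HU, clinical noise SD 30 HU, clinical blur sigma 1 px.
#'
#' @param size `c(rows, cols)` image size.
#' @param bvtv target bone-volume fraction in (0, 1).
#' @param correlation_length Gaussian-field smoothing scale, px.
#' @param bone_hu,marrow_hu phase HU values (`bone_hu > marrow_hu`).
#' @param noise_sd_qct,noise_sd_clinical additive HU noise SDs (>= 0).
#' @param blur_sigma_clinical clinical blur sigma, px (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(128L, 128L), bvtv = 0.35,
                         correlation_length = 3, bone_hu = 700,
                         marrow_hu = -50, noise_sd_qct = 15,
                         noise_sd_clinical = 30, blur_sigma_clinical = 1,
                         seed = NULL) {
  if (bvtv <= 0 || bvtv >= 1)
    ct2bmd_stop("ct2bmd_parameter_error", "bvtv must be in (0, 1)")
  if (bone_hu <= marrow_hu)
    ct2bmd_stop("ct2bmd_parameter_error", "bone_hu must exceed marrow_hu")
  if (noise_sd_qct < 0 || noise_sd_clinical < 0 || blur_sigma_clinical < 0)
    ct2bmd_stop("ct2bmd_parameter_error", "noise/blur parameters must be >= 0")
  if (min(size) < 4 * correlation_length)
    ct2bmd_stop("ct2bmd_parameter_error",
                "image size %d too small for correlation length %g",
                min(size), correlation_length)
  structure(list(size = as.integer(size), bvtv = bvtv,
                 correlation_length = correlation_length,
                 bone_hu = bone_hu, marrow_hu = marrow_hu,
                 noise_sd_qct = noise_sd_qct,
                 noise_sd_clinical = noise_sd_clinical,
                 blur_sigma_clinical = blur_sigma_clinical,
                 seed = seed),
            class = "phantom_spec")
}

# Periodic (FFT) Gaussian blur; sigma = 0 is the identity.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), sd = sigma)
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), sd = sigma)
  K <- outer(kr, kc)
  K <- K / sum(K)
  Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

#' Generate one synthetic trabecular phantom
#'
#' Construction: smooth seeded white noise with a Gaussian kernel of scale
#' `correlation_length`; threshold at the empirical `1 - bvtv` quantile to
#' obtain the bone mask; assign phase HU values. The QCT rendering adds
#' `noise_sd_qct` Gaussian noise; the clinical rendering blurs the
#' noise-free phase image by `blur_sigma_clinical` and then adds
#' `noise_sd_clinical` noise. Ground truth is defined through the
#' package's [reference_calibration()] applied to the noise-free phase
#' mixture: `true_bmd = cal(bvtv * bone_hu + (1 - bvtv) * marrow_hu)`.
#'
#' @param spec a [phantom_spec()].
#' @param cal calibration defining ground truth (default
#'   [reference_calibration()]).
#' @return Object of class `synthetic_sample`: `qct`, `clinical` (two
#'   [ct_slice] renderings), `true_bmd` (mg/cm3), `bone_fraction`
#'   (realized), `spec`.
#' @export
#' @examples
#' s <- generate_phantom(phantom_spec(size = c(32, 32), seed = 1))
#' s$true_bmd
generate_phantom <- function(spec, cal = reference_calibration()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nr <- spec$size[1]; nc <- spec$size[2]
  field <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc),
                         spec$correlation_length)
  thr <- stats::quantile(field, 1 - spec$bvtv, names = FALSE)
  bone <- field > thr
  phase <- matrix(spec$marrow_hu, nr, nc)
  phase[bone] <- spec$bone_hu
  qct <- phase + rnorm(nr * nc, sd = spec$noise_sd_qct)
  clinical <- gaussian_blur(phase, spec$blur_sigma_clinical) +
    rnorm(nr * nc, sd = spec$noise_sd_clinical)
  mean_hu <- spec$bvtv * spec$bone_hu + (1 - spec$bvtv) * spec$marrow_hu
  structure(list(
    qct = ct_slice(qct, source_id = "synthetic-qct"),
    clinical = ct_slice(clinical, source_id = "synthetic-clinical"),
    true_bmd = hu_to_bmd(mean_hu, cal),
    bone_fraction = mean(bone),
    spec = spec
  ), class = "synthetic_sample")
}

#' Generate a synthetic feature/target dataset
#'
#' Draws `n` bone-volume fractions uniformly from `bvtv_range`, renders
#' each phantom in QCT and clinical variants, and extracts the five
#' texture features from both renderings (full image as the ROI,
#' per-image min-max quantization). QCT features paired with `true_bmd`
#' form the training table; clinical features are kept for held-out
#' evaluation. Fully seeded and reproducible.
#'
#' @param n number of phantoms (>= 1).
#' @param bvtv_range `c(lo, hi)` bone-fraction range, `lo < hi`.
#' @param seed integer seed.
#' @param spec template [phantom_spec()] supplying every other parameter.
#' @param Ng,d,thetas,symmetric texture-extraction parameters.
#' @param out_dir optional directory; when given, images are written as
#'   PGM + HU sidecars along with `features.csv`, `features_clinical.csv`,
#'   `truth.csv` and the generating spec JSON.
#' @return List with data frames `features_qct`, `features_clinical`
#'   (columns `contrast, correlation, energy, homogeneity, entropy, bmd`)
#'   and `truth` (`sample, bvtv, bone_fraction, true_bmd`).
#' @export
generate_dataset <- function(n, bvtv_range = c(0.1, 0.6), seed = 1L,
                             spec = phantom_spec(), Ng = 8L, d = 1L,
                             thetas = c(0, 45, 90), symmetric = FALSE,
                             out_dir = NULL) {
  if (n < 1L) ct2bmd_stop("ct2bmd_parameter_error", "n must be >= 1")
  if (length(bvtv_range) != 2L || bvtv_range[1] >= bvtv_range[2])
    ct2bmd_stop("ct2bmd_parameter_error", "bvtv_range must be c(lo, hi) with lo < hi")
  set.seed(seed)
  bvtvs <- runif(n, bvtv_range[1], bvtv_range[2])
  cal <- reference_calibration()

  feat_row <- function(slice) {
    q <- quantize(slice$pixel_hu, Ng = Ng)
    as.data.frame(features_from_roi(q, d = d, thetas = thetas,
                                    symmetric = symmetric))
  }

  rows_q <- vector("list", n); rows_c <- vector("list", n)
  truth <- data.frame(sample = seq_len(n), bvtv = bvtvs,
                      bone_fraction = NA_real_, true_bmd = NA_real_)
  for (i in seq_len(n)) {
    sp <- spec; sp$bvtv <- bvtvs[i]; sp$seed <- NULL  # stays on the stream
    smp <- generate_phantom(sp, cal)
    rows_q[[i]] <- feat_row(smp$qct)
    rows_c[[i]] <- feat_row(smp$clinical)
    truth$bone_fraction[i] <- smp$bone_fraction
    truth$true_bmd[i] <- smp$true_bmd
    if (!is.null(out_dir)) {
      write_pgm(round(smp$qct$pixel_hu),
                file.path(out_dir, sprintf("qct_%03d.pgm", i)))
      write_pgm(round(smp$clinical$pixel_hu),
                file.path(out_dir, sprintf("clinical_%03d.pgm", i)))
    }
  }
  features_qct <- do.call(rbind, rows_q)
  features_clinical <- do.call(rbind, rows_c)
  features_qct$bmd <- truth$true_bmd
  features_clinical$bmd <- truth$true_bmd

  if (!is.null(out_dir)) {
    write.csv(features_qct, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(features_clinical, file.path(out_dir, "features_clinical.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(unclass(spec)[setdiff(names(spec), "seed")],
        list(n = n, bvtv_range = bvtv_range, seed = seed, Ng = Ng, d = d,
             thetas = thetas, symmetric = symmetric)),
      file.path(out_dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  }
  list(features_qct = features_qct, features_clinical = features_clinical,
       truth = truth)
}
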