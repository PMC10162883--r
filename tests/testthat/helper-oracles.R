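# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementation.

# GLCM by explicit pair enumeration over every pixel.
brute_glcm <- function(L, Ng, d, theta, symmetric = FALSE) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  C <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(L))) {
    for (c in seq_len(ncol(L))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(L) && c2 >= 1 && c2 <= ncol(L) &&
          !is.na(L[r, c]) && !is.na(L[r2, c2])) {
        C[L[r, c] + 1, L[r2, c2] + 1] <- C[L[r, c] + 1, L[r2, c2] + 1] + 1
        if (symmetric)
          C[L[r2, c2] + 1, L[r, c] + 1] <- C[L[r2, c2] + 1, L[r, c] + 1] + 1
      }
    }
  }
  C / sum(C)
}

# All five features by scalar double loops.
brute_features <- function(P, base = 2) {
  Ng <- nrow(P)
  en <- 0; et <- 0; co <- 0; ho <- 0; sij <- 0
  px <- rep(0, Ng); py <- rep(0, Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    en <- en + p^2
    if (p > 0) et <- et - p * log(p, base)
    co <- co + (i - j)^2 * p
    ho <- ho + p / (1 + (i - j)^2)
    sij <- sij + (i - 1) * (j - 1) * p
    px[i] <- px[i] + p
    py[j] <- py[j] + p
  }
  mx <- 0; my <- 0
  for (i in 1:Ng) { mx <- mx + (i - 1) * px[i]; my <- my + (i - 1) * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:Ng) { vx <- vx + (i - 1 - mx)^2 * px[i]; vy <- vy + (i - 1 - my)^2 * py[i] }
  sx <- sqrt(vx); sy <- sqrt(vy)
  list(energy = en, entropy = et, contrast = co, homogeneity = ho,
       correlation = if (sx * sy == 0) 1 else (sij - mx * my) / (sx * sy))
}

# Random normalized probability matrix.
random_prob_matrix <- function(Ng) {
  P <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  P / sum(P)
}

# Central finite-difference gradient of the scaled-space MSE w.r.t. one
# parameter of the network.
fd_gradient <- function(net, S, t_scaled, field, i, j = NULL, eps = 1e-6) {
  bump <- function(delta) {
    n2 <- net
    if (is.null(j)) n2[[field]][i] <- n2[[field]][i] + delta
    else n2[[field]][i, j] <- n2[[field]][i, j] + delta
    y <- ct2bmd::nn_gradient(n2, S, t_scaled)$mse
    y
  }
  (bump(eps) - bump(-eps)) / (2 * eps)
}

# Closed-form simple-OLS slope/intercept via normal equations.
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Minimal explicit-VR little-endian DICOM writer for reader tests.
write_minimal_dicom <- function(path, stored, slope = NULL, intercept = NULL,
                                frames = NULL, samples_per_pixel = 1L,
                                truncate_at = NULL) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_us <- function(g, e, val) { u16(g); u16(e); writeChar("US", con, eos = NULL); u16(2L); u16(val) }
  elem_str <- function(g, e, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(g); u16(e); writeChar(vr, con, eos = NULL); u16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  con <- file(path, "wb")
  writeBin(raw(128), con); writeChar("DICM", con, eos = NULL)
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  if (!is.null(frames)) elem_str(0x0028, 0x0008, "IS", as.character(frames))
  elem_us(0x0028, 0x0002, samples_per_pixel)
  elem_us(0x0028, 0x0010, nrow(stored))
  elem_us(0x0028, 0x0011, ncol(stored))
  elem_us(0x0028, 0x0100, 16L)  # BitsAllocated
  elem_us(0x0028, 0x0103, 0L)   # unsigned
  if (!is.null(intercept)) elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  if (!is.null(slope)) elem_str(0x0028, 0x1053, "DS", as.character(slope))
  n <- length(stored)
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0L); u32(2L * n)
  px <- as.integer(t(stored))  # row-major
  if (!is.null(truncate_at)) px <- px[seq_len(truncate_at)]
  writeBin(px, con, size = 2, endian = "little")
  close(con)
  path
}

# Deterministic quantized test ROI shared by several tests.
fixture_roi <- function(seed = 42, n = 16, Ng = 8) {
  set.seed(seed)
  structure(list(levels = matrix(sample(0:(Ng - 1), n * n, replace = TRUE), n, n),
                 Ng = as.integer(Ng), hu_min = 0, hu_max = Ng - 1,
                 mean_hu = NA_real_, sd_hu = NA_real_),
            class = "quantized_roi")
}
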