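# Minimal single-frame DICOM reader. Scope: uncompressed little-endian
# grayscale images (explicit or implicit VR), the only layout the package
# ingests; anything else raises an unsupported-input error. No pre-installed
# R DICOM reader exists in the target environment, hence this parser.

read_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

read_uint32 <- function(raw, pos) {
  as.double(raw[pos]) + 256 * as.double(raw[pos + 1L]) +
    65536 * as.double(raw[pos + 2L]) + 16777216 * as.double(raw[pos + 3L])
}

#' Read a single-frame grayscale DICOM slice
#'
#' Parses the data set sequentially and applies
#' `HU = stored * RescaleSlope + RescaleIntercept` when the rescale tags
#' (0028,1052/1053) are present; otherwise the identity mapping is used and
#' a message is emitted. Only uncompressed little-endian single-frame
#' grayscale images are supported.
#'
#' @param path DICOM file path.
#' @return A [ct_slice].
#' @export
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132L &&
      rawToChar(raw[129:132]) == "DICM") pos <- 133L
  if (length(raw) < pos + 8L)
    ct2bmd_stop("ct2bmd_format_error", "truncated DICOM file: %s", path)

  tags <- list()
  px_off <- NA_integer_; px_len <- NA_real_
  vr_codes <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
                "OB","OD","OF","OW","PN","SH","SL","SQ","SS","ST","TM","UI",
                "UL","UN","US","UT")
  long_vrs <- c("OB","OW","OF","OD","SQ","UT","UN")

  while (pos + 7L <= length(raw)) {
    group <- read_uint16(raw, pos); elem <- read_uint16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- vr %in% vr_codes
    if (explicit) {
      if (vr %in% long_vrs) {
        len <- read_uint32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- read_uint16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      len <- read_uint32(raw, pos + 4L); hdr <- 8L; vr <- NA_character_
    }
    if (len == 4294967295) # undefined length => encapsulated/sequence
      ct2bmd_stop("ct2bmd_unsupported_input_error",
                  "undefined-length element (compressed or sequence data) in %s", path)
    vstart <- pos + hdr
    if (vstart + len - 1L > length(raw))
      ct2bmd_stop("ct2bmd_format_error", "truncated DICOM element in %s", path)
    key <- sprintf("%04x%04x", group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      px_off <- vstart; px_len <- len
    } else if (group == 0x0028 || (group == 0x0002 && elem == 0x0010)) {
      tags[[key]] <- raw[vstart:(vstart + len - 1L)]
    }
    pos <- vstart + as.integer(len)
  }

  get_us <- function(key, default = NA_integer_) {
    v <- tags[[key]]
    if (is.null(v)) default else read_uint16(v, 1L)
  }
  get_str <- function(key, default = NA_character_) {
    v <- tags[[key]]
    if (is.null(v)) default else trimws(rawToChar(v))
  }

  ts <- get_str("00020010")
  if (!is.na(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    ct2bmd_stop("ct2bmd_unsupported_input_error",
                "unsupported transfer syntax %s in %s", ts, path)
  rows <- get_us("00280010"); cols <- get_us("00280011")
  if (is.na(rows) || is.na(cols) || is.na(px_off))
    ct2bmd_stop("ct2bmd_format_error", "missing image tags in %s", path)
  spp <- get_us("00280002", 1L)
  frames <- suppressWarnings(as.integer(get_str("00280008", "1")))
  if (spp != 1L)
    ct2bmd_stop("ct2bmd_unsupported_input_error",
                "color image (SamplesPerPixel = %d) not supported: %s", spp, path)
  if (!is.na(frames) && frames > 1L)
    ct2bmd_stop("ct2bmd_unsupported_input_error",
                "multi-frame image (%d frames) not supported: %s", frames, path)
  bits <- get_us("00280100", 16L)
  signed <- get_us("00280103", 0L) == 1L
  size <- bits %/% 8L
  n <- rows * cols
  if (px_len < n * size)
    ct2bmd_stop("ct2bmd_format_error", "pixel data shorter than Rows*Columns in %s", path)
  stored <- readBin(raw[px_off:(px_off + n * size - 1L)], "integer",
                    n = n, size = size, signed = signed || size > 2L,
                    endian = "little")
  if (!signed && size == 2L) stored <- ifelse(stored < 0L, stored + 65536L, stored)

  slope_s <- get_str("00281053"); inter_s <- get_str("00281052")
  if (is.na(slope_s) && is.na(inter_s)) {
    message("read_dicom_slice: no rescale tags in ", basename(path),
            "; using identity HU mapping")
    slope <- 1; intercept <- 0
  } else {
    slope <- if (is.na(slope_s)) 1 else as.numeric(slope_s)
    intercept <- if (is.na(inter_s)) 0 else as.numeric(inter_s)
  }
  spacing_s <- get_str("00280030")
  spacing <- if (is.na(spacing_s)) NULL else
    as.numeric(strsplit(spacing_s, "\\\\")[[1]])

  ct_slice(matrix(stored, rows, cols, byrow = TRUE) * slope + intercept,
           pixel_spacing = spacing, source_id = basename(path))
}
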