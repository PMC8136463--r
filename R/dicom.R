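#' Read PixelSpacing from a DICOM file
#'
#' Extracts the PixelSpacing attribute (group `0028`, element `0030`):
#' physical row spacing then column spacing, in mm.  Only the metadata is
#' read; pixel data are never decoded.  The parser walks explicit-VR
#' little-endian data elements (the encoding of the file meta group and
#' of ordinary exported files); implicit-VR datasets or undefined-length
#' sequences are refused rather than guessed at.
#'
#' @param path path to a DICOM file.
#' @return numeric `c(row_mm, col_mm)`, both positive.
#' @export
read_dicom_spacing <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM")
    .stopf("'%s' is not a DICOM file (missing DICM marker)", path)
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT",
                "UN")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  pos <- 133L
  while (pos + 7L <= length(raw)) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      .stopf("'%s': not explicit-VR little endian; cannot parse", path)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (len == 4294967295)
      .stopf("'%s': undefined-length element encountered; unsupported",
             path)
    if (group == 0x0028 && elem == 0x0030) {
      val <- rawToChar(raw[(pos + hdr):(pos + hdr + len - 1L)])
      parts <- strsplit(trimws(val), "\\\\")[[1]]
      sp <- suppressWarnings(as.numeric(trimws(parts)))
      if (length(sp) != 2L || anyNA(sp))
        .stopf("'%s': malformed PixelSpacing value '%s'", path, val)
      if (any(sp <= 0))
        .stopf("'%s': nonpositive PixelSpacing %s", path,
               paste(sp, collapse = ", "))
      return(c(row_mm = sp[1], col_mm = sp[2]))
    }
    pos <- pos + hdr + len
  }
  .stopf(paste0("'%s' has no PixelSpacing (0028,0030) attribute; ",
                "supply pixel spacing manually"), path)
}
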