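#' Write / read a profile image as TIFF plus JSON sidecar
#'
#' The intensity grid is stored as 32-bit float TIFF; pixel size, boundary
#' polylines (0-based pixel coordinates, x right / y down) and the truth
#' label go to a JSON sidecar next to it.
#'
#' @param profile a `profile_image`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile_image"))
  scale <- max(profile$intensity, 1)
  tiff::writeTIFF(profile$intensity / scale, path,
                  bits.per.sample = 32L, reduce = FALSE)
  p <- profile$pixel_size_nm
  bnd <- lapply(profile$boundaries, function(tr) {
    list(closed = isTRUE(attr(tr, "closed")),
         x_px = unname(tr[, 1]) / p, y_px = unname(tr[, 2]) / p)
  })
  jsonlite::write_json(
    list(pixel_size_nm = p, intensity_scale = scale,
         truth_label = profile$truth_label, boundaries = bnd),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @param path TIFF path written by [write_profile()] (sidecar expected at
#'   `<path>.json`).
#' @param invert invert the intensity contrast on reading (for data
#'   recorded membrane-dark); the membrane-HIGH convention is required by
#'   all measurements.
#' @export
read_profile <- function(path, invert = FALSE) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) abort(paste0("missing sidecar: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- tiff::readTIFF(path, as.is = FALSE) * meta$intensity_scale
  if (invert) img <- max(img) - img
  p <- meta$pixel_size_nm
  bnd <- lapply(meta$boundaries, function(b) {
    tr <- cbind(x = b$x_px * p, y = b$y_px * p)
    attr(tr, "closed") <- isTRUE(b$closed)
    tr
  })
  structure(list(intensity = img, pixel_size_nm = p,
                 boundaries = bnd,
                 truth_label = meta$truth_label, spec = NULL),
            class = "profile_image")
}

#' Read a 2D slice from an MRC file
#'
#' Minimal reader for single-section MRC maps (modes 0, 1, 2, 6), as
#' exported from tomogram slices. Returns a `profile_image` without
#' boundary annotations; the pixel size is taken from the header cell
#' dimensions.
#'
#' @param path MRC file.
#' @param invert invert contrast on reading (tomograms are usually
#'   membrane-dark; measurements require membrane-HIGH).
#' @return a `profile_image` (boundaries empty).
#' @export
read_mrc <- function(path, invert = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (nz != 1) abort("read_mrc reads single 2D sections (nz = 1)")
  seek(con, 40)
  cell <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    abort(paste0("unsupported MRC mode: ", mode)))
  if (length(data) < n) abort("truncated MRC data section")
  img <- matrix(as.numeric(data), nrow = ny, ncol = nx, byrow = TRUE)
  if (invert) img <- max(img) - img
  px_nm <- if (cell[1] > 0) cell[1] / nx / 10 else 1.228  # A -> nm
  structure(list(intensity = img, pixel_size_nm = px_nm,
                 boundaries = list(), truth_label = NA_character_,
                 spec = NULL),
            class = "profile_image")
}

#' Read / write analysis tables as CSV
#'
#' Thin wrappers around readr with the package's column conventions;
#' unknown columns are preserved.
#'
#' @param path CSV file.
#' @return tibble ([read_table_csv()]) or `path` invisibly.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_table_csv
#' @param x data frame to write.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
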