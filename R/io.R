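#' Write a T1 study to disk as 16-bit TIFF slices plus a JSON sidecar
#'
#' Pixel values (ms) are rounded to integers and stored in 16-bit
#' grayscale TIFFs, one per slice; a `study.json` sidecar records case id,
#' pixel spacing and the slice ordering and level tags.
#'
#' @param study a `t1_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_t1_study <- function(study, dir) {
  stopifnot(inherits(study, "t1_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(study$maps))
  for (i in seq_along(study$maps)) {
    files[i] <- sprintf("slice_%02d.tif", i)
    px <- round(study$maps[[i]]$pixels)
    if (min(px) < 0 || max(px) > 65535) stop("T1 values outside 16-bit range")
    tiff::writeTIFF(px / 65535, file.path(dir, files[i]),
                    bits.per.sample = 16L)
  }
  sidecar <- list(case_id = study$case_id,
                  pixel_spacing_mm = study$maps[[1]]$pixel_spacing,
                  slice_files = files,
                  slice_levels = vapply(study$maps, `[[`, "", "slice_level"),
                  units = "ms, integer-rounded")
  path <- file.path(dir, "study.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a T1 study written by [write_t1_study()]
#'
#' @param dir directory containing the TIFF slices and `study.json`.
#' @return A `t1_study` with integer-valued (ms) pixel matrices.
#' @export
read_t1_study <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "study.json"),
                                 simplifyVector = TRUE)
  maps <- vector("list", length(sidecar$slice_files))
  for (i in seq_along(maps)) {
    px <- tiff::readTIFF(file.path(dir, sidecar$slice_files[i]))
    maps[[i]] <- structure(
      list(pixels = round(px * 65535),
           pixel_spacing = sidecar$pixel_spacing_mm,
           slice_index = i, slice_level = sidecar$slice_levels[i]),
      class = "t1_map")
  }
  structure(list(maps = maps, case_id = sidecar$case_id), class = "t1_study")
}

#' Write a histology image (and optional ground-truth mask) as PNG
#'
#' @param img a `histology_image`.
#' @param path output PNG path.
#' @param mask optional logical matrix written as a single-channel PNG next
#'   to the image (suffix `_mask.png`).
#' @return Invisibly, `path`.
#' @export
write_histology <- function(img, path, mask = NULL) {
  stopifnot(inherits(img, "histology_image"))
  png::writePNG(img$rgb / 255, path)
  if (!is.null(mask)) {
    png::writePNG(mask * 1, sub("\\.png$", "_mask.png", path))
  }
  invisible(path)
}

#' Read an RGB histology image from PNG/TIFF
#'
#' @param path image file; an optional exclusion mask (single-channel,
#'   nonzero = excluded) can be supplied.
#' @param exclusion_path optional mask file.
#' @return A `histology_image` with 0..255 integer channels.
#' @export
read_histology <- function(path, exclusion_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    arr <- arr[, , 1:3]
  } else stop("expected an RGB image")
  excl <- NULL
  if (!is.null(exclusion_path)) {
    m <- if (tolower(tools::file_ext(exclusion_path)) %in% c("tif", "tiff")) {
      tiff::readTIFF(exclusion_path)
    } else png::readPNG(exclusion_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    excl <- m > 0
  }
  histology_image(round(arr * 255), exclusion_mask = excl)
}

#' Write / read the cohort table as CSV
#'
#' Column names are documented in [generate_cohort()]; values round-trip
#' exactly at 15 significant digits.
#'
#' @param table cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: invisibly, `path`; `read_cohort_csv`: the
#'   data frame.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
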