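# Reading and writing OCT volumes as multi-page TIFF stacks or
# directories of per-slice PNG/TIFF images.

read_slice_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stopf("unsupported slice format: %s", path))
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  as.matrix(img)
}

#' Load an OCT volume
#'
#' Reads a multi-page TIFF stack, or a directory of per-slice PNG/TIFF
#' images in lexicographic filename order, as a grayscale volume scaled to
#' `[0, 1]` (color slices are averaged across channels). The source bit
#' depth is recorded in the `bit_depth` attribute when available.
#'
#' @param path a TIFF file or a directory of slice images.
#' @return `H x W x S` numeric array in `[0, 1]`.
#' @export
load_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stopf("no PNG/TIFF slices found in %s", path)
    slices <- lapply(files, function(f) {
      img <- tryCatch(read_slice_file(f),
                      error = function(e) stopf("unreadable slice %s: %s",
                                                basename(f), conditionMessage(e)))
      img
    })
    d <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), d))
        stopf("slice %s has shape %s, expected %s", basename(files[i]),
              paste(dim(slices[[i]]), collapse = "x"),
              paste(d, collapse = "x"))
    vol <- array(0, dim = c(d, length(slices)))
    for (i in seq_along(slices)) vol[, , i] <- slices[[i]]
  } else {
    if (!file.exists(path)) stopf("no such file: %s", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    pages <- lapply(pages, to_gray)
    d <- dim(pages[[1]])
    for (i in seq_along(pages))
      if (!identical(dim(pages[[i]]), d))
        stopf("page %d has shape %s, expected %s", i,
              paste(dim(pages[[i]]), collapse = "x"),
              paste(d, collapse = "x"))
    vol <- array(0, dim = c(d, length(pages)))
    for (i in seq_along(pages)) vol[, , i] <- pages[[i]]
    attr(vol, "bit_depth") <- bits
  }
  vol
}

#' Write an OCT volume as a multi-page TIFF
#'
#' @param volume `H x W x S` numeric array in `[0, 1]`.
#' @param path output file.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = 16L) {
  stopifnot(length(dim(volume)) == 3L)
  slices <- lapply(seq_len(dim(volume)[3]),
                   function(i) pmin(pmax(volume[, , i], 0), 1))
  tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
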