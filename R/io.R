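#' Read an image stack
#'
#' Reads a multi-page TIFF file or a directory of PNG files (slices in
#' page order, respectively lexicographic filename order) as a list of
#' matrices. Interpretation depends on `kind`:
#' \describe{
#'   \item{binary}{values must be exactly two-valued \{0, max\} for the
#'     sample depth; mapped to \{0, 1\}. Any other value is an error.}
#'   \item{prob}{values scaled linearly to `[0, 1]` by the sample
#'     depth range.}
#'   \item{label}{integer values passed through unchanged.}
#' }
#'
#' @param path a `.tif`/`.tiff` file or a directory containing `.png`
#'   files.
#' @param kind one of `"binary"`, `"prob"`, `"label"`.
#' @param invert logical; flip polarity at read time (`x -> 1 - x` for
#'   binary/prob), for datasets that use 1 = membrane instead of the
#'   1 = interior convention of this package.
#' @return A list of matrices, all of identical dimension.
#' @export
read_stack <- function(path, kind = c("binary", "prob", "label"),
                       invert = FALSE) {
  kind <- match.arg(kind)
  if (invert && kind == "label")
    stop("`invert` does not apply to label stacks", call. = FALSE)
  pages <- read_pages(path, raw_integers = kind == "label")
  if (length(pages) == 0) stop("no images found at ", path, call. = FALSE)
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("mixed dimensions across slices", call. = FALSE)
  out <- lapply(pages, convert_page, kind = kind)
  if (invert) out <- lapply(out, function(m) 1 - m)
  out
}

# Read raw pages as matrices. Binary and probability kinds use the
# readers' normalized form (sample values scaled to [0, 1] by the
# sample depth); label kind reads TIFF integer samples as-is. PNG is
# always returned by libpng scaled to [0, 1].
read_pages <- function(path, raw_integers = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0)
      stop("no .png files in directory ", path, call. = FALSE)
    lapply(files, function(f) flatten_gray(png::readPNG(f), f))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = raw_integers)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, flatten_gray, path)
  } else {
    stop("unsupported input (expected .tif/.tiff file or PNG directory): ",
         path, call. = FALSE)
  }
}

flatten_gray <- function(x, src) {
  if (length(dim(x)) == 3) {
    # accept gray stored as identical channels; reject true color
    ch <- dim(x)[3]
    for (k in seq_len(ch)[-1])
      if (!identical(x[, , 1], x[, , k]))
        stop("expected grayscale image: ", src, call. = FALSE)
    x <- x[, , 1]
  }
  if (length(dim(x)) != 2)
    stop("expected a 2D image: ", src, call. = FALSE)
  x
}

convert_page <- function(m, kind) {
  if (kind == "label") {
    if (any(m != round(m)))
      stop("non-integer values in label stack", call. = FALSE)
    return(as_int_matrix(m))
  }
  # binary and prob arrive normalized to [0, 1] by the sample depth
  if (kind == "binary") {
    if (!all(m == 0 | m == 1))
      stop("non-binary input: values other than {0, max} in binary stack",
           call. = FALSE)
    m + 0
  } else {                              # prob
    if (any(m < 0) || any(m > 1))
      stop("probability values outside [0, 1]", call. = FALSE)
    m
  }
}

#' Write an image stack
#'
#' Inverse of [read_stack()]: writes a list of matrices as a multi-page
#' TIFF (path ending in `.tif`/`.tiff`) or as numbered PNG files in a
#' directory. Binary maps are stored at 8 bits, probability maps as
#' 32-bit TIFF samples (round trip accurate to 1 part in 2^32; PNG
#' probability output is quantized to 8 bits), label images as 16-bit
#' integer TIFF (labels above 65535 are an error; label stacks cannot
#' be written as PNG).
#'
#' @param maps list of matrices.
#' @param path output `.tif`/`.tiff` file or directory.
#' @inheritParams read_stack
#' @return `path`, invisibly.
#' @export
write_stack <- function(maps, path, kind = c("binary", "prob", "label")) {
  kind <- match.arg(kind)
  if (!is.list(maps) || length(maps) == 0)
    stop("`maps` must be a non-empty list of matrices", call. = FALSE)
  tiff_out <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (!tiff_out && kind == "label")
    stop("label stacks require 16-bit TIFF output", call. = FALSE)
  prep <- function(m) {
    switch(kind,
      binary = { assert_binary_map(m); m },
      prob = { assert_prob_map(m); m },
      label = {
        assert_label_image(m)
        if (max(m) > 65535) stop("labels above 65535 cannot be stored",
                                 call. = FALSE)
        m / 65535
      })
  }
  scaled <- lapply(maps, prep)
  scaled <- lapply(scaled, function(m) { storage.mode(m) <- "double"; m })
  if (tiff_out) {
    bits <- switch(kind, binary = 8L, prob = 32L, label = 16L)
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(scaled)) {
      f <- file.path(path, sprintf("slice_%04d.png", k))
      png::writePNG(scaled[[k]], f)
    }
  }
  invisible(path)
}
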