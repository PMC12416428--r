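#' Write a label or phase map as a multi-page TIFF stack
#'
#' One page per z-slice, 16-bit unsigned integers (labels up to 65535).
#'
#' @param labels integer 3D array (labels or binary phase values).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  check_vol(labels, "label volume")
  if (max(labels) > 65535L) stop("labels exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(labels)[1]),
                  function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label/phase TIFF stack written by \code{\link{write_label_tiff}}
#'
#' @param path input file.
#' @return integer 3D array with dim (nz, ny, nx).
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  out <- array(0L, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) out[z, , ] <- as.integer(round(pages[[z]] * 65535))
  out
}

#' Write a grayscale volume as a multi-page TIFF with a range sidecar
#'
#' Intensities are rescaled to [0, 1] for 16-bit storage; the original range
#' is kept in a JSON sidecar (\code{<path>.range.json}) so reading restores
#' the values (to 16-bit quantization).
#'
#' @param vol numeric 3D array.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gray_tiff <- function(vol, path) {
  check_vol(vol)
  rng <- range(vol)
  scaled <- if (diff(rng) > 0) (vol - rng[1]) / diff(rng) else vol * 0
  pages <- lapply(seq_len(dim(vol)[1]), function(z) scaled[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a grayscale volume written by \code{\link{write_gray_tiff}}
#'
#' @param path input file.
#' @return numeric 3D array.
#' @export
read_gray_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  out <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  side <- paste0(path, ".range.json")
  if (file.exists(side)) {
    rng <- jsonlite::read_json(side)
    out <- out * (rng$max - rng$min) + rng$min
  }
  out
}

#' Write a region/contact/track table as CSV
#'
#' @param tab data frame (list columns are flattened to comma-separated
#'   strings).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  tab <- as.data.frame(tab)
  for (k in seq_along(tab))
    if (is.list(tab[[k]]))
      tab[[k]] <- vapply(tab[[k]], function(v) paste(v, collapse = ","),
                         character(1))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
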