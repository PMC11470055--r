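#' Read a trajectory table
#'
#' Comma-separated with a header row; requires columns `track_id`,
#' `frame`, `x_um`, `y_um`; extra columns are kept.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) abort(sprintf("trajectory file not found: %s", path))
  out <- as_tibble(read.csv(path))
  check_columns(out, c("track_id", "frame", "x_um", "y_um"), path)
  out
}

#' Read an SMLM localization table
#'
#' Header-named CSV compatible with common localization-table exports:
#' coordinates are taken from `x_nm`/`y_nm` or, failing that, from
#' `x [nm]`/`y [nm]` or plain `x`/`y` columns; extra columns are ignored.
#' A `channel` column is kept when present, else set from `channel`.
#'
#' @param path CSV file path.
#' @param channel Channel tag used when the file has no channel column.
#' @return Tibble with `x_nm`, `y_nm`, `frame`, `channel`.
#' @export
read_localizations <- function(path, channel = NA_character_) {
  if (!file.exists(path)) abort(sprintf("localization file not found: %s", path))
  raw <- as_tibble(read.csv(path, check.names = FALSE))
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (length(hit) == 0) NULL else raw[[hit[1]]]
  }
  x <- pick(c("x_nm", "x [nm]", "x"))
  y <- pick(c("y_nm", "y [nm]", "y"))
  if (is.null(x) || is.null(y)) {
    abort(sprintf("%s: no recognizable coordinate columns (x_nm/y_nm)", path))
  }
  tibble(
    x_nm = as.numeric(x),
    y_nm = as.numeric(y),
    frame = as.integer(pick(c("frame", "frame_id")) %||% rep(1L, nrow(raw))),
    channel = as.character(pick("channel") %||% rep(channel, nrow(raw)))
  )
}

#' Read intensity traces (FRAP or pH protocols)
#'
#' @param path CSV file path.
#' @param required Character vector of required columns.
#' @return Tibble.
#' @export
read_traces <- function(path, required = c("region_id", "frame")) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  out <- as_tibble(read.csv(path))
  check_columns(out, required, path)
  out
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are scaled by `scale` and clipped into the 16-bit range.
#'
#' @param movie Numeric array `[row, column, frame]`.
#' @param path Output file.
#' @param scale Intensity units per grey level (default 1).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = 1) {
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  pages <- purrr::map(seq_len(dim(movie)[3]), function(f) {
    m <- movie[, , f] / scale
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535 # tiff package expects [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @param scale Intensity units per grey level used at write time.
#' @return Numeric array `[row, column, frame]`.
#' @export
read_movie_tiff <- function(path, scale = 1) {
  if (!file.exists(path)) abort(sprintf("movie file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535 * scale
  arr
}

#' Read a synapse mask raster from TIFF
#'
#' Nonzero pixels mark synaptic areas.
#'
#' @param path TIFF file (single page, 8- or 16-bit).
#' @param pixel_size_um Pixel size in micrometres.
#' @return A [synapse_mask()]-compatible object.
#' @export
read_mask_tiff <- function(path, pixel_size_um) {
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path))
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(
    list(mask = (img > 0) * 1L, pixel_size_um = pixel_size_um, centers = NULL),
    class = "synapse_mask"
  )
}

#' Write a synapse mask raster to TIFF
#'
#' @param masks A [synapse_mask()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  stopifnot(inherits(masks, "synapse_mask"))
  tiff::writeTIFF((masks$mask > 0) * 1.0, path, bits.per.sample = 8)
  invisible(path)
}
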