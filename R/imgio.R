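#' Calibrated multi-channel image set
#'
#' Container for a calibrated fluorescence image: one intensity array per
#' channel role. Roles follow the three-channel synapse assay: `cell_fill`
#' (volume marker delineating the dendrite), `puncta_A` and `puncta_B`
#' (pre-/post-synaptic marker channels). Arrays are 2D matrices
#' (row = y, col = x) or 3D arrays (row, col, z) for stacks; physical
#' coordinates are `index * pixel_size` micrometers with a 0-based origin at
#' the top-left pixel center.
#'
#' @param channels named list of numeric matrices/arrays; names are roles,
#'   any subset of `cell_fill`, `puncta_A`, `puncta_B`.
#' @param pixel_size isotropic pixel size in micrometers (> 0).
#' @param z_step slice spacing in micrometers for stacks, or `NULL`.
#' @param bit_depth 8 or 16.
#' @return an object of class `image_set`.
#' @export
image_set <- function(channels, pixel_size, z_step = NULL, bit_depth = 16) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    nq_data_error("'channels' must be a named list of arrays")
  bad <- setdiff(names(channels), c("cell_fill", "puncta_A", "puncta_B"))
  if (length(bad))
    nq_data_error(paste0("unknown channel role(s): ",
                         paste(bad, collapse = ", ")))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    nq_data_error("all channels must share the same shape")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    nq_data_error("'pixel_size' must be a positive scalar (micrometers)")
  if (!bit_depth %in% c(8L, 16L))
    nq_data_error("'bit_depth' must be 8 or 16")
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, bit_depth = as.integer(bit_depth)),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_set> ", paste(d, collapse = " x "), " px, ",
      x$pixel_size, " um/px, ", x$bit_depth, "-bit\n", sep = "")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

is_stack <- function(x) length(dim(x$channels[[1]])) == 3L

#' Read a calibrated multi-channel TIFF
#'
#' Reads a (multi-page) TIFF and assigns channel roles by page index.
#' A JSON sidecar written by [write_image_set()] (same path with `.json`
#' appended) supplies calibration and stack layout when present; the
#' `pixel_size` argument overrides any stored calibration.
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector, role -> 1-based channel index,
#'   e.g. `c(cell_fill = 1, puncta_A = 2, puncta_B = 3)`.
#' @param pixel_size pixel size in micrometers; required if no sidecar.
#' @return an [image_set()].
#' @export
read_image <- function(path, channel_map, pixel_size = NULL) {
  if (!file.exists(path))
    nq_data_error(paste0("file not found: ", path))
  if (anyDuplicated(channel_map))
    nq_data_error("channel_map assigns two roles to the same channel index")
  if (anyDuplicated(names(channel_map)))
    nq_data_error("channel_map assigns a role twice")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      nq_data_error(paste0("unreadable TIFF: ",
                                           conditionMessage(e))))
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_slices <- if (!is.null(meta$n_slices)) meta$n_slices else 1L
  n_channels <- length(pages) / n_slices
  if (n_channels != round(n_channels))
    nq_data_error("page count inconsistent with sidecar slice count")
  if (any(channel_map < 1L | channel_map > n_channels))
    nq_data_error("channel index out of range")
  z_step <- if (!is.null(meta$z_step)) meta$z_step else NULL
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size))
    nq_config_error("pixel_size missing: not in file metadata, not given")
  bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 16L
  # pages are channel-major: channel c occupies pages ((c-1)*n_slices+1) ...
  channels <- lapply(channel_map, function(ci) {
    sl <- pages[((ci - 1L) * n_slices + 1L):(ci * n_slices)]
    if (n_slices == 1L) sl[[1L]]
    else array(unlist(sl), dim = c(dim(sl[[1L]]), n_slices))
  })
  names(channels) <- names(channel_map)
  image_set(channels, pixel_size = pixel_size, z_step = z_step,
            bit_depth = bit_depth)
}

#' Write an image set as multi-page TIFF plus JSON sidecar
#'
#' Channels are written channel-major (all slices of channel 1, then
#' channel 2, ...) as 16- or 8-bit pages; a `<path>.json` sidecar records
#' pixel size, z-step, bit depth, slice count and the role order so that
#' [read_image()] round-trips bit-exactly.
#'
#' @param x an [image_set()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_set <- function(x, path) {
  stopifnot(inherits(x, "image_set"))
  maxval <- 2^x$bit_depth - 1
  pages <- list()
  for (ch in x$channels) {
    if (length(dim(ch)) == 3L)
      for (k in seq_len(dim(ch)[3])) pages <- c(pages, list(ch[, , k]))
    else pages <- c(pages, list(ch))
  }
  pages <- lapply(pages, function(p) pmin(pmax(round(p), 0), maxval) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = x$bit_depth)
  n_slices <- if (is_stack(x)) dim(x$channels[[1]])[3] else 1L
  meta <- list(pixel_size = x$pixel_size, z_step = x$z_step,
               bit_depth = x$bit_depth, n_slices = n_slices,
               channel_roles = names(x$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Maximum-intensity projection
#'
#' Collapses each channel of a z-stack to 2D by taking the per-pixel maximum
#' over slices, the standard projection used before mask-based puncta
#' analysis. Calibration is preserved. A 2D input is returned unchanged with
#' a warning.
#'
#' @param x an [image_set()] whose channels are 3D stacks.
#' @return an [image_set()] with 2D channels.
#' @export
max_project <- function(x) {
  stopifnot(inherits(x, "image_set"))
  if (!is_stack(x)) {
    warning("input is already 2D; returned unchanged")
    return(x)
  }
  channels <- lapply(x$channels, function(ch) {
    out <- ch[, , 1L]
    for (k in seq_len(dim(ch)[3])[-1L]) out <- pmax(out, ch[, , k])
    out
  })
  image_set(channels, pixel_size = x$pixel_size, z_step = NULL,
            bit_depth = x$bit_depth)
}
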