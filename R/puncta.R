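#' Threshold specification for mask-based puncta analysis
#'
#' The per-image adaptive thresholds of the synapse assay: each marker
#' (puncta) channel is binarized at the mean pixel intensity of the entire
#' image plus `k_puncta` standard deviations; the cell-fill channel at mean
#' plus `k_cell_fill` standard deviations.
#'
#' @param k_puncta SD multiplier for puncta channels (assay default 2).
#' @param k_cell_fill SD multiplier for the cell-fill channel (assay
#'   default 1).
#' @param sd_kind `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1); the assay description does not specify, population is the
#'   default and the choice is recorded in results.
#' @return a `threshold_spec` list.
#' @export
threshold_spec <- function(k_puncta = 2, k_cell_fill = 1,
                           sd_kind = c("population", "sample")) {
  if (k_puncta < 0 || k_cell_fill < 0)
    nq_config_error("SD multipliers must be >= 0")
  structure(list(k_puncta = k_puncta, k_cell_fill = k_cell_fill,
                 sd_kind = match.arg(sd_kind)),
            class = "threshold_spec")
}

#' Mean-plus-k-SD binary mask
#'
#' Binarizes a channel at its whole-image adaptive threshold: a pixel is
#' foreground iff its intensity is strictly greater than
#' `mean(image) + k * SD(image)`, both moments computed over all pixels of
#' that image. The mask is invariant under positive affine intensity maps.
#'
#' @param channel 2D numeric intensity matrix.
#' @param k SD multiplier (>= 0).
#' @param sd_kind `"population"` or `"sample"` standard deviation.
#' @return logical matrix of the same shape.
#' @export
threshold_mask <- function(channel, k, sd_kind = c("population", "sample")) {
  sd_kind <- match.arg(sd_kind)
  if (!is.matrix(channel) || length(channel) == 0L)
    nq_data_error("'channel' must be a non-empty 2D matrix")
  if (k < 0) nq_config_error("'k' must be >= 0")
  m <- mean(channel)
  s <- if (sd_kind == "population")
    sqrt(mean((channel - m)^2)) else sd(as.vector(channel))
  channel > m + k * s
}

#' Colocalization mask (pixelwise conjunction)
#'
#' Triple colocalization for the synapse assay is the pixelwise AND of the
#' two puncta masks and the cell-fill mask; the dual variant (marker/marker
#' colocalization, e.g. TRIM47/PSD95) omits `mask_cell`.
#'
#' @param mask_A,mask_B logical puncta-channel masks.
#' @param mask_cell optional logical cell-fill mask.
#' @return logical matrix.
#' @export
colocalize <- function(mask_A, mask_B, mask_cell = NULL) {
  if (!identical(dim(mask_A), dim(mask_B)))
    nq_data_error("mask shapes differ")
  out <- mask_A & mask_B
  if (!is.null(mask_cell)) {
    if (!identical(dim(out), dim(mask_cell)))
      nq_data_error("mask shapes differ")
    out <- out & mask_cell
  }
  out
}

#' Label connected components of a binary mask
#'
#' 8-connectivity by default (the standard for puncta); the pixel adjacency
#' graph is handed to igraph for component extraction.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    nq_config_error("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(idx)) return(out)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  # undirected neighbor offsets: E, S (+ SE, SW for 8-connectivity)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- id[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    edges[[length(edges) + 1L]] <-
      cbind(id[cbind(rr[ok], cc[ok])][keep], j[keep])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0L) {  # all pixels isolated
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

#' Detect puncta objects in a colocalization mask
#'
#' Labels connected components (8-connectivity) of the mask and applies the
#' assay's size rule: only components whose area-equivalent diameter is
#' strictly less than `size_limit` micrometers are retained as puncta;
#' components smaller than `min_area_px` pixels are dropped.
#'
#' @param coloc_mask logical matrix.
#' @param pixel_size micrometers per pixel.
#' @param size_limit upper size cutoff, micrometers (assay default 10).
#' @param min_area_px minimum component area in pixels.
#' @param connectivity 4 or 8.
#' @param size_measure `"equivalent_diameter"` (default: diameter of the
#'   disk with the component's area) or `"feret"` (maximal pixel-center
#'   distance within the component).
#' @return `data.frame` with one row per retained object: `label`, centroid
#'   `x`/`y` (micrometers), `area_um2`, `equivalent_diameter_um`.
#' @export
detect_puncta <- function(coloc_mask, pixel_size, size_limit = 10,
                          min_area_px = 1L, connectivity = 8L,
                          size_measure = c("equivalent_diameter", "feret")) {
  size_measure <- match.arg(size_measure)
  if (pixel_size <= 0) nq_config_error("pixel_size must be > 0")
  lab <- label_components(coloc_mask, connectivity)
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0))
  if (max(lab) == 0L) return(empty)
  idx <- which(lab > 0L)
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  f <- factor(lab[idx])
  area_px <- as.vector(table(f))
  x_um <- tapply((cc - 1) * pixel_size, f, mean)
  y_um <- tapply((rr - 1) * pixel_size, f, mean)
  area_um2 <- area_px * pixel_size^2
  eqd <- 2 * sqrt(area_um2 / pi)
  size_um <- if (size_measure == "equivalent_diameter") eqd else
    vapply(levels(f), function(l) {
      pts <- cbind(cc[f == l], rr[f == l]) * pixel_size
      if (nrow(pts) == 1L) return(0)
      max(dist(pts))
    }, numeric(1))
  keep <- size_um < size_limit & area_px >= min_area_px
  out <- data.frame(label = as.integer(levels(f)), x = as.numeric(x_um),
                    y = as.numeric(y_um), area_um2 = as.numeric(area_um2),
                    equivalent_diameter_um = as.numeric(eqd))[keep, ]
  rownames(out) <- NULL
  out
}

#' Package puncta counts as a density per micrometer of dendrite
#'
#' Synapse (or colocalized puncta) density = number of retained objects
#' divided by the traced dendrite length.
#'
#' @param objects object table from [detect_puncta()].
#' @param dendrite_length dendrite length in micrometers (> 0).
#' @param size_limit,threshold_spec,mode provenance to record alongside the
#'   result.
#' @return a `punctaresult` with fields `objects`, `count`,
#'   `dendrite_length`, `density`, `size_limit`, `threshold_spec`, `mode`.
#' @export
synapse_density <- function(objects, dendrite_length, size_limit = 10,
                            threshold_spec = NULL, mode = NA_character_) {
  if (!is.numeric(dendrite_length) || dendrite_length <= 0)
    nq_data_error("dendrite_length must be > 0")
  structure(list(objects = objects, count = nrow(objects),
                 dendrite_length = dendrite_length,
                 density = nrow(objects) / dendrite_length,
                 size_limit = size_limit, threshold_spec = threshold_spec,
                 mode = mode),
            class = "punctaresult")
}

#' @export
print.punctaresult <- function(x, ...) {
  cat("<punctaresult> ", x$count, " puncta on ",
      signif(x$dendrite_length, 5), " um of dendrite\n", sep = "")
  cat("  density: ", signif(x$density, 4), " per um",
      if (!is.na(x$mode)) paste0("  (", x$mode, " colocalization)"), "\n",
      sep = "")
  invisible(x)
}

#' Quantify colocalized puncta density for one image
#'
#' The full assay for a single image: maximum-intensity projection (if a
#' stack), per-channel mean + k*SD masks, mask conjunction (triple:
#' puncta_A & puncta_B & cell_fill; dual: puncta_A & puncta_B), connected
#' components with the size rule, and density per micrometer using the trace
#' length as the denominator. Deterministic.
#'
#' @param img an [image_set()].
#' @param trace a [dendrite_trace] supplying the length denominator.
#' @param spec a [threshold_spec()].
#' @param mode `"triple"` or `"dual"`.
#' @param size_limit,min_area_px passed to [detect_puncta()].
#' @return a `punctaresult`.
#' @export
quantify_image <- function(img, trace, spec = threshold_spec(),
                           mode = c("triple", "dual"), size_limit = 10,
                           min_area_px = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "image_set"), inherits(trace, "dendrite_trace"))
  if (is_stack(img)) img <- max_project(img)
  need <- c("puncta_A", "puncta_B", if (mode == "triple") "cell_fill")
  missing <- setdiff(need, names(img$channels))
  if (length(missing))
    nq_data_error(paste0("image lacks channel role(s): ",
                         paste(missing, collapse = ", ")))
  mA <- threshold_mask(img$channels$puncta_A, spec$k_puncta, spec$sd_kind)
  mB <- threshold_mask(img$channels$puncta_B, spec$k_puncta, spec$sd_kind)
  mC <- if (mode == "triple")
    threshold_mask(img$channels$cell_fill, spec$k_cell_fill, spec$sd_kind)
  coloc <- colocalize(mA, mB, mC)
  obj <- detect_puncta(coloc, img$pixel_size, size_limit = size_limit,
                       min_area_px = min_area_px)
  synapse_density(obj, trace$total_length, size_limit = size_limit,
                  threshold_spec = spec, mode = mode)
}
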