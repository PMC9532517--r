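#' Simulation configuration for synthetic neuron images
#'
#' Parameters of the confocal-like three-channel image simulator: a dendritic
#' tree (random binary tree of straight segments from a central soma) rendered
#' as a tube in the cell-fill channel, colocalized synaptic puncta pairs
#' placed on the skeleton and rendered as Gaussian spots in both puncta
#' channels, channel-specific distractor puncta, isotropic Gaussian PSF and
#' Poisson-plus-Gaussian noise. Defaults emulate the acquisition regime of a
#' 60x confocal field: 1024 x 1024 px at 0.1 um/px, 16-bit.
#'
#' @param image_shape integer (H, W) in pixels.
#' @param pixel_size isotropic pixel size, micrometers per pixel.
#' @param n_branches number of primary dendrites leaving the soma.
#' @param branch_length_range (min, max) segment length in micrometers.
#' @param true_density colocalized (synaptic) puncta per micrometer of
#'   skeleton.
#' @param distractor_density_A,distractor_density_B single-channel puncta per
#'   micrometer of skeleton.
#' @param punctum_sigma Gaussian spot SD, micrometers.
#' @param punctum_amplitude peak spot intensity above background.
#' @param colocalization_jitter maximal offset between the two channels'
#'   members of a colocalized pair, micrometers.
#' @param min_separation minimal center-to-center distance between rendered
#'   puncta, micrometers. Puncta are simulated as optically resolvable
#'   objects: truth positions keep this separation within a channel, and
#'   channel-specific distractors keep it across channels so that a
#'   zero-density image truly contains zero colocalized pairs. Densities
#'   requiring closer packing are rejected.
#' @param background constant background intensity.
#' @param read_noise_sd additive Gaussian noise SD.
#' @param shot_noise apply Poisson noise to the pre-noise intensity.
#' @param tube_radius dendrite tube radius in the cell-fill channel,
#'   micrometers.
#' @param soma_radius soma disk radius, micrometers.
#' @param cell_amplitude cell-fill tube intensity above background.
#' @param n_slices 1 for a 2D image, 3 for a small z-stack (0.75 um step)
#'   exercising maximum-intensity projection.
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(image_shape = c(1024L, 1024L),
                       pixel_size = 0.1,
                       n_branches = 8L,
                       branch_length_range = c(20, 45),
                       true_density = 0.25,
                       distractor_density_A = 0.3,
                       distractor_density_B = 0.3,
                       punctum_sigma = 0.2,
                       punctum_amplitude = 4000,
                       colocalization_jitter = 0.1,
                       min_separation = 1.0,
                       background = 200,
                       read_noise_sd = 20,
                       shot_noise = TRUE,
                       tube_radius = 0.5,
                       soma_radius = 4,
                       cell_amplitude = 2500,
                       n_slices = 1L,
                       seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              n_branches = as.integer(n_branches),
              branch_length_range = branch_length_range,
              true_density = true_density,
              distractor_density_A = distractor_density_A,
              distractor_density_B = distractor_density_B,
              punctum_sigma = punctum_sigma,
              punctum_amplitude = punctum_amplitude,
              colocalization_jitter = colocalization_jitter,
              min_separation = min_separation,
              background = background, read_noise_sd = read_noise_sd,
              shot_noise = isTRUE(shot_noise), tube_radius = tube_radius,
              soma_radius = soma_radius, cell_amplitude = cell_amplitude,
              n_slices = as.integer(n_slices), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$pixel_size <= 0) nq_config_error("pixel_size must be > 0")
  if (cfg$punctum_sigma <= 0) nq_config_error("punctum_sigma must be > 0")
  if (cfg$true_density < 0) nq_config_error("true_density must be >= 0")
  if (cfg$distractor_density_A < 0 || cfg$distractor_density_B < 0)
    nq_config_error("distractor densities must be >= 0")
  if (cfg$min_separation <= 0)
    nq_config_error("min_separation must be > 0")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 64L))
    nq_config_error("image_shape must be (H, W) with H, W >= 64")
  if (!cfg$n_slices %in% c(1L, 3L))
    nq_config_error("n_slices must be 1 or 3")
  invisible(cfg)
}

segment_lengths <- function(p) {
  d <- diff(p)
  sqrt(rowSums(d^2))
}

polyline_length <- function(p) sum(segment_lengths(p))

# Grow a random binary dendritic tree inside the field; returns list of
# polylines (n x 2 matrices, micrometer x/y columns) rooted at `soma`.
grow_tree <- function(cfg, soma) {
  field <- rev(cfg$image_shape) * cfg$pixel_size  # (x extent, y extent)
  margin <- 2
  clip_len <- function(p0, dir, len) {
    # largest step keeping p0 + t*dir inside [margin, field - margin]
    tmax <- len
    for (i in 1:2) {
      if (dir[i] > 0) tmax <- min(tmax, (field[i] - margin - p0[i]) / dir[i])
      if (dir[i] < 0) tmax <- min(tmax, (margin - p0[i]) / dir[i])
    }
    max(tmax, 0)
  }
  polylines <- list()
  angles <- seq(0, 2 * pi, length.out = cfg$n_branches + 1L)[-1L] +
    runif(cfg$n_branches, -0.2, 0.2)
  for (a in angles) {
    dir <- c(cos(a), sin(a))
    len <- runif(1, cfg$branch_length_range[1], cfg$branch_length_range[2])
    len <- clip_len(soma, dir, len)
    if (len < 5) next
    tip <- soma + len * dir
    polylines[[length(polylines) + 1L]] <- rbind(soma, tip)
    # one binary split per primary branch (random binary tree, depth 2)
    if (runif(1) < 0.7) {
      for (s in c(-1, 1)) {
        da <- s * runif(1, 20, 50) * pi / 180
        cdir <- c(cos(a + da), sin(a + da))
        clen <- runif(1, cfg$branch_length_range[1],
                      cfg$branch_length_range[2]) * 0.6
        clen <- clip_len(tip, cdir, clen)
        if (clen < 5) next
        polylines[[length(polylines) + 1L]] <- rbind(tip, tip + clen * cdir)
      }
    }
  }
  if (!length(polylines)) nq_config_error("tree generation produced no branches")
  polylines
}

# Sample up to `n` points uniformly by arc length, rejecting candidates
# closer than `min_sep` (euclidean) to accepted points or to `avoid`.
# Errors if placement fails (packing bound).
sample_separated <- function(polylines, n, min_sep, avoid = NULL,
                             self_sep = TRUE, what = "puncta") {
  if (n == 0L) return(matrix(0, 0, 2))
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  max_tries <- 400L * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample_on_polylines(polylines, 1L)
    ok <- TRUE
    if (self_sep && got > 0L)
      ok <- all((pts[seq_len(got), 1] - cand[1])^2 +
                (pts[seq_len(got), 2] - cand[2])^2 >= min_sep^2)
    if (ok && !is.null(avoid) && nrow(avoid) > 0L)
      ok <- all((avoid[, 1] - cand[1])^2 +
                (avoid[, 2] - cand[2])^2 >= min_sep^2)
    if (ok) {
      got <- got + 1L
      pts[got, ] <- cand
    }
  }
  if (got < n)
    nq_config_error(sprintf(
      "cannot place %d %s at min_separation %.2f um on this skeleton: requested density exceeds the packing bound",
      n, what, min_sep))
  pts
}

# Sample `n` points uniformly by arc length over a list of polylines.
sample_on_polylines <- function(polylines, n) {
  lens <- vapply(polylines, polyline_length, numeric(1))
  total <- sum(lens)
  s <- sort(runif(n, 0, total))
  cum <- cumsum(lens)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- which(s[i] <= cum)[1L]
    local <- s[i] - if (j > 1L) cum[j - 1L] else 0
    p <- polylines[[j]]
    segl <- segment_lengths(p)
    k <- which(local <= cumsum(segl))[1L]
    t0 <- local - if (k > 1L) sum(segl[1:(k - 1L)]) else 0
    frac <- if (segl[k] > 0) t0 / segl[k] else 0
    out[i, ] <- p[k, ] + frac * (p[k + 1L, ] - p[k, ])
  }
  out
}

# Add isotropic Gaussian spots (peak `amplitude`) to an intensity matrix.
render_spots <- function(img, centers_um, pixel_size, sigma_um, amplitude) {
  if (is.null(centers_um) || nrow(centers_um) == 0L) return(img)
  sg <- sigma_um / pixel_size
  w <- ceiling(4 * sg)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(centers_um))) {
    cx <- centers_um[i, 1] / pixel_size  # 0-based pixel coords
    cy <- centers_um[i, 2] / pixel_size
    r0 <- max(1L, floor(cy) - w + 1L); r1 <- min(nr, ceiling(cy) + w + 1L)
    c0 <- max(1L, floor(cx) - w + 1L); c1 <- min(nc, ceiling(cx) + w + 1L)
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    dy <- (rows - 1) - cy
    dx <- (cols - 1) - cx
    patch <- amplitude * outer(exp(-dy^2 / (2 * sg^2)),
                               exp(-dx^2 / (2 * sg^2)))
    img[rows, cols] <- img[rows, cols] + patch
  }
  img
}

# Rasterize polylines onto a logical matrix (pixel centers within half a
# pixel of the sampled path).
rasterize_polylines <- function(polylines, shape, pixel_size) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (p in polylines) {
    for (k in seq_len(nrow(p) - 1L)) {
      a <- p[k, ]; b <- p[k + 1L, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (pixel_size / 3)))
      t <- seq(0, 1, length.out = n)
      xs <- a[1] + t * (b[1] - a[1])
      ys <- a[2] + t * (b[2] - a[2])
      rr <- pmin(pmax(round(ys / pixel_size) + 1L, 1L), shape[1])
      cc <- pmin(pmax(round(xs / pixel_size) + 1L, 1L), shape[2])
      m[cbind(rr, cc)] <- TRUE
    }
  }
  m
}

# Euclidean distance (in pixels) of every pixel to the nearest TRUE pixel.
distance_to <- function(mask) {
  inv <- matrix(1, nrow(mask), ncol(mask))
  inv[mask] <- 0
  as.matrix(EBImage::imageData(EBImage::distmap(inv)))
}

apply_noise <- function(signal, cfg) {
  x <- signal
  if (cfg$shot_noise) x <- matrix(rpois(length(x), lambda = pmax(x, 0)),
                                  nrow(x), ncol(x))
  x <- x + matrix(rnorm(length(x), 0, cfg$read_noise_sd), nrow(x), ncol(x))
  pmin(pmax(round(x), 0), 65535)
}

#' Generate a synthetic three-channel neuron image with ground truth
#'
#' Renders a dendritic tree (tube plus soma disk) in the cell-fill channel and
#' Gaussian puncta in the two marker channels: every true synapse contributes
#' a spot to both puncta channels (offset by at most
#' `colocalization_jitter`), distractors to one channel each. Poisson shot
#' noise and Gaussian read noise are applied after rendering. The paired
#' ground truth records the skeleton polylines, skeleton length, true synapse
#' positions and the true density.
#'
#' @param config a [sim_config()].
#' @return list with elements `image` (an [image_set()]) and `truth` (a
#'   `ground_truth` list).
#' @export
generate_neuron_image <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    shape <- config$image_shape
    field <- rev(shape) * config$pixel_size
    soma <- field / 2 + runif(2, -2, 2)
    polylines <- grow_tree(config, soma)
    total_len <- sum(vapply(polylines, polyline_length, numeric(1)))

    n_syn <- round(config$true_density * total_len)
    max_fit <- floor(total_len / config$min_separation)
    if (n_syn > max_fit)
      nq_config_error(sprintf(
        "requested %d puncta exceed the packing bound (%d) for a %.1f um skeleton: lower true_density or min_separation",
        n_syn, max_fit, total_len))
    syn <- sample_separated(polylines, n_syn, config$min_separation,
                            what = "synaptic puncta")
    jitter_pair <- function(centers) {
      if (nrow(centers) == 0L) return(centers)
      ang <- runif(nrow(centers), 0, 2 * pi)
      mag <- runif(nrow(centers), 0, config$colocalization_jitter)
      centers + cbind(mag * cos(ang), mag * sin(ang))
    }
    n_da <- round(config$distractor_density_A * total_len)
    n_db <- round(config$distractor_density_B * total_len)
    # distractors are channel-specific by definition: the two channels'
    # distractors keep min_separation from each other so they can never
    # form a colocalized object (overlap with a true pair only merges into
    # that object and cannot change the colocalized count)
    da <- if (n_da > 0) sample_on_polylines(polylines, n_da)
          else matrix(0, 0, 2)
    db <- sample_separated(polylines, n_db, config$min_separation,
                           avoid = da, self_sep = FALSE,
                           what = "channel-B distractors")
    perp_jitter <- function(centers) {
      if (nrow(centers) == 0L) return(centers)
      centers + matrix(runif(2 * nrow(centers), -0.3, 0.3), ncol = 2)
    }
    da <- perp_jitter(da)
    db <- perp_jitter(db)

    # cell-fill: tube of tube_radius around skeleton + soma disk
    skel_raster <- rasterize_polylines(polylines, shape, config$pixel_size)
    dist_px <- distance_to(skel_raster)
    tube <- dist_px * config$pixel_size <= config$tube_radius
    xg <- ((seq_len(shape[2]) - 1) * config$pixel_size)
    yg <- ((seq_len(shape[1]) - 1) * config$pixel_size)
    soma_disk <- outer((yg - soma[2])^2, rep(1, shape[2])) +
      outer(rep(1, shape[1]), (xg - soma[1])^2) <= config$soma_radius^2
    cell_signal <- config$background +
      config$cell_amplitude * (tube | soma_disk)
    cell_signal <- as.matrix(EBImage::imageData(
      EBImage::gblur(cell_signal, sigma = 1)))

    base_A <- render_spots(matrix(config$background, shape[1], shape[2]),
                           rbind(jitter_pair(syn), da), config$pixel_size,
                           config$punctum_sigma, config$punctum_amplitude)
    base_B <- render_spots(matrix(config$background, shape[1], shape[2]),
                           rbind(jitter_pair(syn), db), config$pixel_size,
                           config$punctum_sigma, config$punctum_amplitude)

    make_channel <- function(signal) {
      if (config$n_slices == 1L) return(apply_noise(signal, config))
      wts <- c(0.6, 1, 0.6)  # out-of-focus attenuation
      arr <- array(0, dim = c(shape, config$n_slices))
      for (k in seq_len(config$n_slices)) {
        focal <- config$background + wts[k] * (signal - config$background)
        arr[, , k] <- apply_noise(focal, config)
      }
      arr
    }
    img <- image_set(list(cell_fill = make_channel(cell_signal),
                          puncta_A = make_channel(base_A),
                          puncta_B = make_channel(base_B)),
                     pixel_size = config$pixel_size,
                     z_step = if (config$n_slices > 1L) 0.75 else NULL,
                     bit_depth = 16L)
    truth <- structure(list(skeleton_polylines = polylines,
                            skeleton_length = total_len,
                            soma_center = soma,
                            synapse_centers = syn,
                            true_density = config$true_density,
                            distractor_centers_A = da,
                            distractor_centers_B = db,
                            config = config),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Write simulator ground truth as JSON
#'
#' @param truth a `ground_truth` object from [generate_neuron_image()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(skeleton_length = truth$skeleton_length,
              soma_center = truth$soma_center,
              true_density = truth$true_density,
              skeleton_polylines = lapply(truth$skeleton_polylines,
                                          function(p) unname(p)),
              synapse_centers = unname(truth$synapse_centers),
              distractor_centers_A = unname(truth$distractor_centers_A),
              distractor_centers_B = unname(truth$distractor_centers_B))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Generate a synthetic nose-point trajectory
#'
#' Produces a planned exploration session: during a dwell segment for an
#' object the nose stays strictly within the exploration radius of that
#' object's boundary; during a `"roam"` segment it stays strictly farther
#' than the radius from every object.
#'
#' @param arena_size arena side length(s) in cm, length 1 or 2.
#' @param objects named list of objects, each `list(center = c(x, y),
#'   radius = r)` in cm.
#' @param dwell_plan list of `list(where, duration)` with `where` an object
#'   name or `"roam"` and `duration` in seconds.
#' @param sample_rate samples per second.
#' @param exploration_radius scoring radius in cm (paper rule: nose closer
#'   than 2 cm to the object).
#' @param seed integer RNG seed.
#' @return a `trajectory` object (see [score_exploration()]).
#' @export
generate_trajectory <- function(arena_size, objects, dwell_plan,
                                sample_rate = 10, exploration_radius = 2,
                                seed = 1L) {
  if (length(arena_size) == 1L) arena_size <- rep(arena_size, 2L)
  centers <- do.call(rbind, lapply(objects, function(o) o$center))
  radii <- vapply(objects, function(o) o$radius, numeric(1))
  if (length(objects) >= 2L) {
    dd <- as.matrix(dist(centers))
    diag(dd) <- Inf
    if (any(dd < outer(radii, radii, `+`)))
      nq_config_error("objects overlap")
  }
  for (p in dwell_plan) {
    if (p[[2]] <= 0) nq_config_error("dwell durations must be > 0")
    if (!identical(p[[1]], "roam") && !p[[1]] %in% names(objects))
      nq_config_error(paste0("unknown object in dwell_plan: ", p[[1]]))
  }
  with_seed(seed, {
    xs <- ys <- numeric(0)
    for (p in dwell_plan) {
      n <- round(p[[2]] * sample_rate)
      if (identical(p[[1]], "roam")) {
        px <- py <- numeric(n)
        for (i in seq_len(n)) {
          repeat {
            cand <- c(runif(1, 1, arena_size[1] - 1),
                      runif(1, 1, arena_size[2] - 1))
            bd <- sqrt((cand[1] - centers[, 1])^2 +
                       (cand[2] - centers[, 2])^2) - radii
            if (all(bd > exploration_radius * 1.1)) break
          }
          px[i] <- cand[1]; py[i] <- cand[2]
        }
      } else {
        o <- objects[[p[[1]]]]
        ang <- runif(n, 0, 2 * pi)
        bd <- runif(n, 0.05 * exploration_radius, 0.9 * exploration_radius)
        px <- o$center[1] + (o$radius + bd) * cos(ang)
        py <- o$center[2] + (o$radius + bd) * sin(ang)
        px <- pmin(pmax(px, 0), arena_size[1])
        py <- pmin(pmax(py, 0), arena_size[2])
      }
      xs <- c(xs, px); ys <- c(ys, py)
    }
    trajectory(data.frame(t = (seq_along(xs) - 1) / sample_rate,
                          x = xs, y = ys),
               sample_rate = sample_rate, arena = arena_size)
  })
}

#' Generate a synthetic densitometry band table
#'
#' Lognormal target and loading-control band intensities whose
#' loading-normalized group means converge to `group_means` as `n_per_group`
#' grows; the fixture for testing densitometry normalization.
#'
#' @param group_means true normalized mean per group (first group is the
#'   control at mean 1 in typical use).
#' @param cv coefficient of variation of the multiplicative noise (0 gives
#'   exact means).
#' @param n_per_group samples per group (>= 2).
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `sample_id`, `group`,
#'   `target_intensity`, `loading_intensity`.
#' @export
generate_band_table <- function(group_means, cv = 0.2, n_per_group = 4L,
                                seed = 1L) {
  if (any(group_means <= 0)) nq_config_error("group means must be > 0")
  if (cv < 0) nq_config_error("cv must be >= 0")
  if (n_per_group < 2L) nq_config_error("n_per_group must be >= 2")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    rows <- list()
    groups <- if (is.null(names(group_means)))
      paste0("group", seq_along(group_means)) else names(group_means)
    for (g in seq_along(group_means)) {
      loading <- 1000 * rlnorm(n_per_group, -sdlog^2 / 2, sdlog)
      target <- group_means[g] * loading *
        rlnorm(n_per_group, -sdlog^2 / 2, sdlog)
      rows[[g]] <- data.frame(
        sample_id = paste0(groups[g], "_", seq_len(n_per_group)),
        group = groups[g], target_intensity = target,
        loading_intensity = loading)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
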