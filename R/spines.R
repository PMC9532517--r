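#' Spine classification rule set
#'
#' Geometric classification thresholds (Rodriguez-type heuristic). Applied
#' in order: protrusions longer than `filopodium_length` are filopodia; else
#' head/neck ratio above `mushroom_ratio` with head width above
#' `mushroom_head` makes a mushroom spine; else length/head-width above
#' `thin_ratio` makes a thin spine; everything else is stubby. Every
#' constant is configurable and recorded with results.
#'
#' @param filopodium_length micrometers (default 3).
#' @param mushroom_ratio head/neck width ratio (default 1.1).
#' @param mushroom_head minimal mushroom head width, micrometers
#'   (default 0.35).
#' @param thin_ratio length/head-width ratio (default 2.5).
#' @return a `spine_rules` list.
#' @export
spine_rules <- function(filopodium_length = 3, mushroom_ratio = 1.1,
                        mushroom_head = 0.35, thin_ratio = 2.5) {
  structure(list(filopodium_length = filopodium_length,
                 mushroom_ratio = mushroom_ratio,
                 mushroom_head = mushroom_head, thin_ratio = thin_ratio),
            class = "spine_rules")
}

#' Classify one spine from its geometry
#'
#' @param record list or one-row data.frame with `length`, `head_width`,
#'   `neck_width` (micrometers).
#' @param rules a [spine_rules()].
#' @return one of `"filopodium"`, `"mushroom"`, `"thin"`, `"stubby"`.
#' @export
classify_spine <- function(record, rules = spine_rules()) {
  len <- record$length; head <- record$head_width; neck <- record$neck_width
  if (is.null(len) || is.null(head) || is.null(neck) ||
      is.na(len) || is.na(head) || is.na(neck))
    nq_data_error("spine record lacks geometry fields")
  if (len > rules$filopodium_length) return("filopodium")
  if (neck > 0 && head / neck > rules$mushroom_ratio &&
      head > rules$mushroom_head) return("mushroom")
  if (head > 0 && len / head > rules$thin_ratio) return("thin")
  "stubby"
}

#' Classify a table of detected spines
#'
#' Adds a `class` column; rows with a non-missing `override` column value
#' keep that manual class instead (the supported route for manual
#' reclassification).
#'
#' @param records data.frame from [detect_spines()].
#' @param rules a [spine_rules()].
#' @return `records` with a `class` column.
#' @export
classify_spines <- function(records, rules = spine_rules()) {
  if (!nrow(records)) {
    records$class <- character(0)
    return(records)
  }
  records$class <- vapply(seq_len(nrow(records)), function(i)
    classify_spine(records[i, ], rules), character(1))
  if ("override" %in% names(records)) {
    manual <- !is.na(records$override) & nzchar(records$override)
    records$class[manual] <- records$override[manual]
  }
  records
}

#' Detect spines along a traced dendrite (stand-in morphometry)
#'
#' Protrusion-based spine detection in a high-magnification cell-fill mask:
#' the dendrite shaft is the trace dilated to the local shaft radius
#' (estimated from the distance transform along the trace); connected
#' components of mask-minus-shaft that touch the shaft are protrusion
#' candidates. Each yields a base point (nearest point to the trace), an
#' axis from base to tip, a length along that axis, a head width (maximal
#' width over the distal half of the axis) and a neck width (minimal width
#' between base and head). Protrusions longer than `max_length` are
#' discarded as non-spines.
#'
#' @param cell_fill_mask logical matrix.
#' @param trace a [dendrite_trace()] for the same image.
#' @param pixel_size micrometers per pixel.
#' @param max_length protrusion length cutoff, micrometers (default 5).
#' @return data.frame with one row per spine: `base_x`, `base_y`, `length`,
#'   `head_width`, `neck_width` (micrometers).
#' @export
detect_spines <- function(cell_fill_mask, trace, pixel_size, max_length = 5) {
  if (!length(trace$polylines)) nq_data_error("empty trace")
  shape <- dim(cell_fill_mask)
  skel <- rasterize_polylines(trace$polylines, shape, pixel_size)
  dist_to_tr <- distance_to(skel)
  radius_map <- as.matrix(EBImage::imageData(
    EBImage::distmap(cell_fill_mask * 1)))
  tr_idx <- which(skel)
  # stamp a disk of the local radius around every trace pixel
  shaft <- matrix(FALSE, shape[1], shape[2])
  nr <- shape[1]
  rr_t <- ((tr_idx - 1L) %% nr) + 1L
  cc_t <- ((tr_idx - 1L) %/% nr) + 1L
  rr <- rr_t
  cc <- cc_t
  for (i in seq_along(tr_idx)) {
    rad <- ceiling(radius_map[tr_idx[i]])
    if (rad < 1) rad <- 1
    r0 <- max(1, rr[i] - rad); r1 <- min(shape[1], rr[i] + rad)
    c0 <- max(1, cc[i] - rad); c1 <- min(shape[2], cc[i] + rad)
    sub_r <- r0:r1; sub_c <- c0:c1
    dd <- outer((sub_r - rr[i])^2, (sub_c - cc[i])^2, `+`)
    shaft[sub_r, sub_c] <- shaft[sub_r, sub_c] | (dd <= rad^2)
  }
  prot <- cell_fill_mask & !shaft
  lab <- label_components(prot, 8L)
  if (max(lab) == 0L)
    return(data.frame(base_x = numeric(0), base_y = numeric(0),
                      length = numeric(0), head_width = numeric(0),
                      neck_width = numeric(0)))
  # keep components adjacent to the shaft
  shaft_grown <- as.matrix(EBImage::imageData(EBImage::dilate(
    shaft * 1, EBImage::makeBrush(3, "box")))) > 0
  records <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (!any(shaft_grown[idx])) next
    pr <- ((idx - 1L) %% nr) + 1L
    pc <- ((idx - 1L) %/% nr) + 1L
    px <- (pc - 1) * pixel_size
    py <- (pr - 1) * pixel_size
    base_i <- which.min(dist_to_tr[idx])
    base <- c(px[base_i], py[base_i])
    # protrusion axis = outward normal from the dendrite: base minus its
    # nearest trace point (a base-to-tip axis tilts toward corner pixels
    # and corrupts the width profile)
    tx <- (cc_t - 1) * pixel_size
    ty <- (rr_t - 1) * pixel_size
    nt <- which.min((tx - base[1])^2 + (ty - base[2])^2)
    axis <- c(base[1] - tx[nt], base[2] - ty[nt])
    anorm <- sqrt(sum(axis^2))
    if (anorm == 0) {  # base on the trace: fall back to base-to-tip
      d2 <- (px - base[1])^2 + (py - base[2])^2
      tip_i <- which.max(d2)
      axis <- c(px[tip_i] - base[1], py[tip_i] - base[2])
      anorm <- sqrt(sum(axis^2))
      if (anorm == 0) next
    }
    axis <- axis / anorm
    u <- (px - base[1]) * axis[1] + (py - base[2]) * axis[2]
    v <- -(px - base[1]) * axis[2] + (py - base[2]) * axis[1]
    len <- max(u) + pixel_size  # pixel-center extent -> physical length
    if (len > max_length) next
    bins <- pmin(floor(u / pixel_size), floor(max(u) / pixel_size))
    widths <- tapply(v, bins, function(vv) diff(range(vv)) + pixel_size)
    # 3-bin running mean: single-bin extrema are +/- one pixel quantization
    # noise, which a 1.1 head/neck ratio rule cannot tolerate
    if (length(widths) >= 3L) {
      sm <- as.numeric(stats::filter(widths, rep(1 / 3, 3), sides = 2))
      widths[!is.na(sm)] <- sm[!is.na(sm)]
    }
    ub <- as.numeric(names(widths)) * pixel_size
    distal <- ub >= 0.5 * max(u)
    head_w <- if (any(distal)) max(widths[distal]) else max(widths)
    head_pos <- ub[distal][which.max(widths[distal])]
    # basal 20% excluded: the shaft-junction bite narrows those bins and
    # would fake a neck on uniform-width (stubby) protrusions
    between <- ub >= 0.2 * max(u) & ub < head_pos
    neck_w <- if (any(between)) min(widths[between]) else min(widths)
    records[[length(records) + 1L]] <-
      data.frame(base_x = base[1], base_y = base[2], length = len,
                 head_width = head_w, neck_width = neck_w)
  }
  if (!length(records))
    return(data.frame(base_x = numeric(0), base_y = numeric(0),
                      length = numeric(0), head_width = numeric(0),
                      neck_width = numeric(0)))
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Spine densities per micrometer of dendrite
#'
#' Total and per-class densities; filopodia are reported but excluded from
#' the total by default (they are not spines).
#'
#' @param records classified spine table ([classify_spines()]).
#' @param trace a [dendrite_trace()] (length denominator).
#' @param include_filopodia count filopodia in the total density.
#' @return a `spine_density_result` with `total_density`,
#'   `per_class_density`, `dendrite_length`, `n_spines`.
#' @export
spine_density <- function(records, trace, include_filopodia = FALSE) {
  if (trace$total_length <= 0) nq_data_error("dendrite length must be > 0")
  classes <- c("thin", "stubby", "mushroom", "filopodium")
  counts <- setNames(numeric(4), classes)
  if (nrow(records)) {
    tab <- table(factor(records$class, levels = classes))
    counts[] <- as.numeric(tab)
  }
  per_class <- counts / trace$total_length
  total_classes <- if (include_filopodia) classes else setdiff(classes,
                                                               "filopodium")
  structure(list(total_density = sum(per_class[total_classes]),
                 per_class_density = per_class,
                 dendrite_length = trace$total_length,
                 n_spines = sum(counts[total_classes])),
            class = "spine_density_result")
}

#' @export
print.spine_density_result <- function(x, ...) {
  cat("<spine_density_result> ", x$n_spines, " spines on ",
      signif(x$dendrite_length, 5), " um: ",
      signif(x$total_density, 4), " per um\n", sep = "")
  print(signif(x$per_class_density, 4))
  invisible(x)
}

#' Generate a synthetic spine-bearing dendrite segment with ground truth
#'
#' High-magnification fixture for the spine morphometry stand-in: a straight
#' horizontal dendrite shaft with protrusions of prescribed base position,
#' side, length, head width and neck width (stem rectangle of neck width
#' plus a head disk at the tip). Returns an intensity image, the matching
#' straight-shaft trace and the per-spine ground truth with the class each
#' geometry encodes under the given rules.
#'
#' @param spine_plan data.frame with columns `base_x` (micrometers along the
#'   shaft), `side` (+1/-1), `length`, `head_width`, `neck_width`
#'   (micrometers). If `NULL`, a plan of `n_spines` is drawn at random from
#'   typical class geometries.
#' @param n_spines number of spines when `spine_plan` is `NULL`.
#' @param segment_length shaft length, micrometers.
#' @param pixel_size micrometers per pixel (high-mag default 0.05).
#' @param shaft_radius micrometers.
#' @param background,amplitude,read_noise_sd intensity model.
#' @param rules a [spine_rules()] used to annotate the planned class.
#' @param seed integer RNG seed.
#' @return list with `image` (intensity matrix), `trace`
#'   ([dendrite_trace()]), `plan` (the realized spine plan with a
#'   `planned_class` column), and `pixel_size`.
#' @export
generate_spine_image <- function(spine_plan = NULL, n_spines = 12L,
                                 segment_length = 20, pixel_size = 0.05,
                                 shaft_radius = 0.4, background = 100,
                                 amplitude = 3000, read_noise_sd = 10,
                                 rules = spine_rules(), seed = 1L) {
  with_seed(seed, {
    if (is.null(spine_plan)) {
      archetypes <- data.frame(
        class = c("mushroom", "thin", "stubby"),
        length = c(1.2, 1.6, 0.6),
        head_width = c(0.6, 0.25, 0.4),
        neck_width = c(0.25, 0.18, 0.4))
      pick <- sample(seq_len(nrow(archetypes)), n_spines, replace = TRUE)
      # jittered regular grid: guarantees neighboring protrusions (which
      # alternate sides) can never merge
      margin <- 1.5
      usable <- segment_length - 2 * margin
      spacing <- usable / n_spines
      if (spacing < 1)
        nq_config_error("too many spines for this segment length")
      base_x <- margin + (seq_len(n_spines) - 0.5) * spacing +
        runif(n_spines, -0.2, 0.2) * spacing
      spine_plan <- data.frame(base_x = base_x,
                               side = rep_len(c(1, -1), n_spines),
                               length = archetypes$length[pick],
                               head_width = archetypes$head_width[pick],
                               neck_width = archetypes$neck_width[pick])
    }
    spine_plan$planned_class <- vapply(seq_len(nrow(spine_plan)), function(i)
      classify_spine(list(length = spine_plan$length[i],
                          head_width = spine_plan$head_width[i],
                          neck_width = spine_plan$neck_width[i]), rules),
      character(1))
    h_um <- 2 * (shaft_radius + max(c(spine_plan$length, 1)) + 1)
    shape <- c(ceiling(h_um / pixel_size), ceiling(segment_length / pixel_size))
    y0 <- h_um / 2
    xg <- (seq_len(shape[2]) - 1) * pixel_size
    yg <- (seq_len(shape[1]) - 1) * pixel_size
    mask <- outer(abs(yg - y0) <= shaft_radius, rep(TRUE, shape[2]))
    for (i in seq_len(nrow(spine_plan))) {
      s <- spine_plan[i, ]
      x_in <- abs(xg - s$base_x) <= s$neck_width / 2
      tip_y <- y0 + s$side * (shaft_radius + s$length)
      stem_lo <- min(y0, tip_y); stem_hi <- max(y0, tip_y)
      y_in <- yg >= stem_lo & yg <= stem_hi
      mask <- mask | outer(y_in, x_in)
      head_c <- c(s$base_x, y0 + s$side * (shaft_radius + s$length -
                                             s$head_width / 2))
      dd <- outer((yg - head_c[2])^2, (xg - head_c[1])^2, `+`)
      mask <- mask | (dd <= (s$head_width / 2)^2)
    }
    img <- background + amplitude * mask
    img <- img + matrix(rnorm(length(img), 0, read_noise_sd),
                        shape[1], shape[2])
    img <- pmin(pmax(round(img), 0), 65535)
    trace <- dendrite_trace(list(rbind(c(0, y0), c(segment_length - pixel_size,
                                                   y0))),
                            soma_center = c(0, y0), source = "imported")
    list(image = img, trace = trace, plan = spine_plan,
         pixel_size = pixel_size)
  })
}
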