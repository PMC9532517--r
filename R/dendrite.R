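#' Dendrite trace
#'
#' Polyline representation of a dendritic arbor in micrometer coordinates,
#' with total length and soma center. Produced by [trace_dendrites()]
#' (skeleton-based stand-in tracer) or [import_trace()] (SWC).
#'
#' @param polylines list of n x 2 matrices (columns x, y in micrometers).
#' @param soma_center length-2 numeric, micrometers.
#' @param source `"traced"` or `"imported"`.
#' @return a `dendrite_trace`.
#' @export
dendrite_trace <- function(polylines, soma_center, source = "traced") {
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    unname(p)
  })
  total <- sum(vapply(polylines, polyline_length, numeric(1)))
  structure(list(polylines = polylines, total_length = total,
                 soma_center = as.numeric(soma_center), source = source),
            class = "dendrite_trace")
}

#' @export
print.dendrite_trace <- function(x, ...) {
  cat("<dendrite_trace> ", length(x$polylines), " branches, total ",
      signif(x$total_length, 5), " um (", x$source, ")\n", sep = "")
  invisible(x)
}

# Zhang-Suen morphological thinning of a logical matrix (vectorized; the
# stand-in skeletonizer behind trace_dendrites).
skeletonize <- function(mask) {
  m <- mask * 1L
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors P2..P9 clockwise from north
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1L & b >= 2 & b <= 6 & a == 1
      if (phase == 1)
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_residue(m) == 1L
}

# Sequential simple-point pass removing the 2-pixel-thick staircase residue
# Zhang-Suen leaves: delete any non-endpoint 8-simple pixel (Yokoi
# connectivity number 1), preserving topology.
thin_residue <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # x1..x8 = E, NE, N, NW, W, SW, S, SE (Yokoi order)
  ring <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    changed <- FALSE
    for (i in which(m == 1L)) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      rs <- r + ring[, 1]; cs <- c + ring[, 2]
      nb <- integer(8)
      ok <- rs >= 1L & rs <= nr & cs >= 1L & cs <= nc
      nb[ok] <- m[cbind(rs[ok], cs[ok])]
      bsum <- sum(nb)
      bg <- 1L - nb
      cn <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        k2 <- if (k == 7L) 8L else k + 1L
        k3 <- if (k >= 7L) k - 6L else k + 2L
        cn <- cn + bg[k] - bg[k] * bg[k2] * bg[k3]
      }
      if (bsum >= 2L && bsum <= 7L && cn == 1L) {
        m[i] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Extract branch polylines (pixel coordinates, 1-based rows/cols) from an
# 8-connected skeleton. Branch points = pixels with degree != 2.
skeleton_paths <- function(skel) {
  nr <- nrow(skel)
  idx <- which(skel)
  if (!length(idx)) return(list())
  id <- matrix(0L, nr, ncol(skel))
  id[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nbrs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    r2 <- rr[i] + offs[, 1]; c2 <- cc[i] + offs[, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skel)
    nb <- id[cbind(r2[ok], c2[ok])]
    nbrs[[i]] <- nb[nb > 0L]
  }
  deg <- lengths(nbrs)
  visited_edge <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  paths <- list()
  walk <- function(from, to) {
    # walk from node `from` through degree-2 pixels starting toward `to`
    path <- c(from, to)
    assign(ekey(from, to), TRUE, envir = visited_edge)
    prev <- from; cur <- to
    while (deg[cur] == 2L) {
      nxt <- setdiff(nbrs[[cur]], prev)
      if (!length(nxt)) break
      nxt <- nxt[1L]
      if (exists(ekey(cur, nxt), envir = visited_edge)) break
      assign(ekey(cur, nxt), TRUE, envir = visited_edge)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  nodes <- which(deg != 2L)
  for (s in nodes)
    for (t in nbrs[[s]])
      if (!exists(ekey(s, t), envir = visited_edge))
        paths[[length(paths) + 1L]] <- walk(s, t)
  # pure cycles (every pixel degree 2) - rare; walk one loop each
  remaining <- which(deg == 2L)
  for (s in remaining) {
    t <- nbrs[[s]][1L]
    if (!exists(ekey(s, t), envir = visited_edge))
      paths[[length(paths) + 1L]] <- walk(s, t)
  }
  lapply(paths, function(p) cbind(col = cc[p], row = rr[p]))
}

#' Trace dendrites from a cell-fill mask (skeleton-based stand-in)
#'
#' Skeletonizes the largest connected component of the binary cell-fill mask
#' (Zhang-Suen thinning), extracts branches as polylines, measures length in
#' micrometers with diagonal pixel steps counted as sqrt(2) pixels, and
#' places the soma at the center of the maximal disk inscribed in the mask.
#' Terminal branches shorter than `prune_um` are discarded as
#' skeletonization spurs.
#'
#' @param cell_fill_mask logical matrix (e.g. from [threshold_mask()]).
#' @param pixel_size micrometers per pixel.
#' @param prune_um spur-pruning length, micrometers.
#' @return a [dendrite_trace()].
#' @export
trace_dendrites <- function(cell_fill_mask, pixel_size, prune_um = 2) {
  if (!any(cell_fill_mask)) nq_data_error("empty cell-fill mask")
  lab <- label_components(cell_fill_mask, 8L)
  biggest <- as.integer(names(which.max(table(lab[lab > 0L]))))
  mask <- lab == biggest
  dist_in <- as.matrix(EBImage::imageData(EBImage::distmap(mask * 1)))
  soma_idx <- which.max(dist_in)
  soma <- c(((soma_idx - 1L) %/% nrow(mask)),      # col - 1 -> x
            ((soma_idx - 1L) %% nrow(mask))) * pixel_size
  skel <- skeletonize(mask)
  paths <- skeleton_paths(skel)
  if (!length(paths)) nq_data_error("skeleton extraction failed")
  polylines <- lapply(paths, function(p)
    cbind((p[, 1] - 1) * pixel_size, (p[, 2] - 1) * pixel_size))
  lens <- vapply(polylines, polyline_length, numeric(1))
  # prune short terminal spurs; count endpoint occurrences to find terminals
  ends <- do.call(rbind, lapply(polylines, function(p)
    rbind(p[1, ], p[nrow(p), ])))
  key <- paste(round(ends[, 1], 6), round(ends[, 2], 6))
  occ <- table(key)
  is_terminal <- vapply(seq_along(polylines), function(i) {
    k1 <- key[2 * i - 1]; k2 <- key[2 * i]
    occ[[k1]] == 1L || occ[[k2]] == 1L
  }, logical(1))
  # junction clusters in the raw skeleton leave tiny internal fragments;
  # drop those below a few pixels as well
  keep <- !(is_terminal & lens < prune_um) &
    !(!is_terminal & lens < 3 * pixel_size)
  if (!any(keep)) keep <- lens == max(lens)
  dendrite_trace(polylines[keep], soma, source = "traced")
}

#' Import a dendrite trace from an SWC file
#'
#' Reconstructs branch polylines and total length from the parent-child
#' records of an SWC morphology file; the soma is the first type-1 node (or
#' the root if no type-1 node exists). Only x/y are used downstream but
#' length is measured in 3D.
#'
#' @param path SWC file path.
#' @return a [dendrite_trace()].
#' @export
import_trace <- function(path) {
  if (!file.exists(path)) nq_data_error(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) nq_data_error("empty SWC file")
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) != 7L)) nq_data_error("malformed SWC record")
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(tab)) nq_data_error("malformed SWC record")
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- tab[, "id"]
  if (anyDuplicated(ids)) nq_data_error("duplicate SWC node id")
  parent <- tab[, "parent"]
  orphan <- parent != -1 & !(parent %in% ids)
  if (any(orphan)) nq_data_error("SWC node references missing parent")
  row_of <- setNames(seq_along(ids), as.character(ids))
  soma_row <- which(tab[, "type"] == 1)[1]
  if (is.na(soma_row)) soma_row <- which(parent == -1)[1]
  soma <- tab[soma_row, c("x", "y")]
  # children map; branch nodes = roots, nodes with >1 child, leaves
  nchild <- table(factor(as.character(parent[parent != -1]),
                         levels = as.character(ids)))
  nchild <- as.integer(nchild)
  is_branch <- parent == -1 | nchild != 1L
  polylines <- list()
  for (i in which(parent != -1)) {
    # start a polyline at each child whose parent is a branch node
    p_row <- row_of[[as.character(parent[i])]]
    if (!is_branch[p_row]) next
    pts <- tab[p_row, c("x", "y", "z"), drop = FALSE]
    cur <- i
    repeat {
      pts <- rbind(pts, tab[cur, c("x", "y", "z")])
      if (is_branch[cur]) break
      ch <- which(parent == ids[cur])
      if (!length(ch)) break
      cur <- ch[1L]
    }
    polylines[[length(polylines) + 1L]] <- pts
  }
  if (!length(polylines))
    nq_data_error("SWC file contains no segments")
  tr <- dendrite_trace(lapply(polylines, function(p) p[, 1:2, drop = FALSE]),
                       soma, source = "imported")
  # recompute length in 3D over parent-child pairs (exact, path-independent)
  seg <- tab[parent != -1, , drop = FALSE]
  pr <- row_of[as.character(seg[, "parent"])]
  tr$total_length <- sum(sqrt(rowSums(
    (seg[, c("x", "y", "z"), drop = FALSE] -
       tab[pr, c("x", "y", "z"), drop = FALSE])^2)))
  tr
}

#' Export a dendrite trace to SWC
#'
#' @param trace a [dendrite_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  rows <- list()
  id <- 1L
  rows[[1]] <- c(1, 1, trace$soma_center[1], trace$soma_center[2], 0, 1, -1)
  for (p in trace$polylines) {
    prev <- -1L
    for (k in seq_len(nrow(p))) {
      id <- id + 1L
      rows[[length(rows) + 1L]] <- c(id, 3, p[k, 1], p[k, 2], 0, 0.5, prev)
      prev <- id
    }
  }
  tab <- do.call(rbind, rows)
  writeLines(c("# SWC export", apply(tab, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))),
    path)
  invisible(path)
}

#' Sholl intersection profile
#'
#' Counts dendrite crossings of concentric circles of radius `step`,
#' `2*step`, ... centered on the soma. A polyline segment whose endpoint
#' distances to the soma straddle a radius contributes one crossing per
#' straddle event; a vertex lying exactly on a circle (tangential touch)
#' counts once. Radii extend to the first multiple of `step` beyond the
#' maximal branch extent, so the final count is 0.
#'
#' @param trace a [dendrite_trace()].
#' @param step ring spacing in micrometers (assay default 10).
#' @return a `sholl_profile`: list with `radii` and `intersections`.
#' @export
sholl <- function(trace, step = 10) {
  if (step <= 0) nq_config_error("step must be > 0")
  sc <- trace$soma_center
  dists <- lapply(trace$polylines, function(p)
    sqrt((p[, 1] - sc[1])^2 + (p[, 2] - sc[2])^2))
  max_d <- max(unlist(dists))
  radii <- step * seq_len(floor(max_d / step) + 1L)
  counts <- integer(length(radii))
  for (d in dists) {
    for (j in seq_along(radii)) {
      s <- d - radii[j]
      crossings <- sum(s[-length(s)] * s[-1] < 0)
      touches <- sum(s == 0)
      counts[j] <- counts[j] + crossings + touches
    }
  }
  structure(list(radii = radii, intersections = counts, step = step),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("<sholl_profile> step", x$step, "um\n")
  print(setNames(x$intersections, x$radii))
  invisible(x)
}

#' Compare two groups of Sholl profiles (K-S test)
#'
#' Pools the per-ring intersection counts of each group and compares the two
#' count distributions with the two-sample Kolmogorov-Smirnov test, the
#' test used for Sholl comparisons in this assay; also returns per-radius
#' group means and SEM on the common radius grid for plotting.
#'
#' @param profiles_a,profiles_b lists of `sholl_profile` objects (one per
#'   cell).
#' @return a [stat_report] with fields `per_radius` (radius, mean and SEM
#'   per group) and the K-S `statistic`/`p.value`.
#' @export
compare_sholl <- function(profiles_a, profiles_b) {
  if (!length(profiles_a) || !length(profiles_b))
    nq_data_error("each group needs at least one profile")
  grid <- function(ps) max(vapply(ps, function(p) max(p$radii), numeric(1)))
  step <- profiles_a[[1]]$step
  radii <- seq(step, max(grid(profiles_a), grid(profiles_b)), by = step)
  counts_on <- function(p) {
    out <- integer(length(radii))
    out[match(p$radii, radii)] <- p$intersections
    out
  }
  ma <- vapply(profiles_a, counts_on, integer(length(radii)))
  mb <- vapply(profiles_b, counts_on, integer(length(radii)))
  ma <- matrix(ma, nrow = length(radii))
  mb <- matrix(mb, nrow = length(radii))
  pooled_a <- as.vector(ma); pooled_b <- as.vector(mb)
  ks <- suppressWarnings(ks.test(pooled_a, pooled_b, exact = FALSE))
  D <- if (identical(pooled_a, pooled_b)) 0 else unname(ks$statistic)
  sem <- function(x) sd(x) / sqrt(length(x))
  per_radius <- data.frame(
    radius = radii,
    mean_a = rowMeans(ma), sem_a = apply(ma, 1, sem),
    mean_b = rowMeans(mb), sem_b = apply(mb, 1, sem))
  stat_report(test = "two-sample Kolmogorov-Smirnov",
              statistic = D,
              p.value = if (D == 0) 1 else unname(ks$p.value),
              estimates = data.frame(
                group = c("A", "B"),
                mean = c(mean(pooled_a), mean(pooled_b)),
                sem = c(sem(pooled_a), sem(pooled_b)),
                n = c(length(pooled_a), length(pooled_b))),
              extra = list(per_radius = per_radius))
}
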