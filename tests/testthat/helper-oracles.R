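# Independent brute-force oracles used to validate the implementation paths.

# Flood-fill connected-component labeling (explicit stack, no igraph).
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# Per-pixel loop conjunction of three masks.
oracle_conjunction <- function(a, b, cell) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a)))
    out[r, c] <- a[r, c] && b[r, c] && cell[r, c]
  out
}

# Dense-sampling Sholl oracle: sample each polyline every 0.01 um and count
# sign changes of (distance to soma - r).
oracle_sholl <- function(trace, radii) {
  counts <- integer(length(radii))
  for (p in trace$polylines) {
    pts <- list()
    for (k in seq_len(nrow(p) - 1L)) {
      seg <- sqrt(sum((p[k + 1L, ] - p[k, ])^2))
      n <- max(2L, ceiling(seg / 0.01))
      t <- seq(0, 1, length.out = n)
      pts[[k]] <- cbind(p[k, 1] + t * (p[k + 1L, 1] - p[k, 1]),
                        p[k, 2] + t * (p[k + 1L, 2] - p[k, 2]))
    }
    pts <- do.call(rbind, pts)
    d <- sqrt((pts[, 1] - trace$soma_center[1])^2 +
              (pts[, 2] - trace$soma_center[2])^2)
    for (j in seq_along(radii)) {
      s <- sign(d - radii[j])
      s <- s[s != 0]
      counts[j] <- counts[j] + sum(s[-1] != s[-length(s)])
    }
  }
  counts
}

# Direct Welch t formula.
oracle_welch <- function(a, b) {
  se2 <- var(a) / length(a) + var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                 (var(b) / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Max ECDF gap scanned over the pooled sample points.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g)
    mean(a <= g) - mean(b <= g), numeric(1))))
}

# Small random tree of straight branches from a soma, for Sholl testing.
random_tree_trace <- function(n_branches = 5L, max_len = 40) {
  polys <- lapply(seq_len(n_branches), function(i) {
    a <- runif(1, 0, 2 * pi)
    l1 <- runif(1, 5, max_len)
    p1 <- l1 * c(cos(a), sin(a))
    if (runif(1) < 0.5) {
      a2 <- a + runif(1, -1, 1)
      p2 <- p1 + runif(1, 5, max_len / 2) * c(cos(a2), sin(a2))
      rbind(c(0, 0), p1, p2)
    } else rbind(c(0, 0), p1)
  })
  dendrite_trace(polys, c(0, 0))
}

# Quantify a freshly generated synthetic image end to end with the traced
# dendrite supplying the length denominator.
quantify_synthetic <- function(true_density, seed,
                               image_shape = c(512L, 512L)) {
  cfg <- sim_config(image_shape = image_shape, true_density = true_density,
                    seed = seed)
  sim <- generate_neuron_image(cfg)
  cm <- threshold_mask(sim$image$channels$cell_fill, 1)
  tr <- trace_dendrites(cm, sim$image$pixel_size)
  list(result = quantify_image(sim$image, tr), truth = sim$truth,
       trace = tr)
}
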