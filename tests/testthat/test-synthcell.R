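test_that("ground truth is internally consistent and deterministic", {
  cfg <- sim_config(image_shape = c(256L, 256L), true_density = 0.4,
                    seed = 11L)
  sim1 <- generate_neuron_image(cfg)
  sim2 <- generate_neuron_image(cfg)
  # bit-identical repeat under the same config
  expect_identical(sim1$image$channels, sim2$image$channels)
  expect_identical(sim1$truth$synapse_centers, sim2$truth$synapse_centers)

  tr <- sim1$truth
  # count = round(density * length)
  expect_identical(nrow(tr$synapse_centers),
                   as.integer(round(cfg$true_density * tr$skeleton_length)))
  # stored length agrees with re-measuring the polylines
  remeasured <- sum(vapply(tr$skeleton_polylines, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1)))
  expect_equal(remeasured, tr$skeleton_length, tolerance = 1e-10)
  # every synapse center lies on (within 1 um of) the skeleton; sample the
  # polylines densely so segment interiors count
  dense <- do.call(rbind, lapply(tr$skeleton_polylines, function(p) {
    do.call(rbind, lapply(seq_len(nrow(p) - 1L), function(k) {
      t <- seq(0, 1, length.out = max(
        2L, ceiling(sqrt(sum((p[k + 1L, ] - p[k, ])^2)) / 0.1)))
      cbind(p[k, 1] + t * (p[k + 1L, 1] - p[k, 1]),
            p[k, 2] + t * (p[k + 1L, 2] - p[k, 2]))
    }))
  }))
  for (i in seq_len(nrow(tr$synapse_centers))) {
    d <- min(sqrt((dense[, 1] - tr$synapse_centers[i, 1])^2 +
                  (dense[, 2] - tr$synapse_centers[i, 2])^2))
    expect_lt(d, 1)
  }
})

test_that("zero densities give puncta channels of pure background noise", {
  cfg <- sim_config(image_shape = c(256L, 256L), true_density = 0,
                    distractor_density_A = 0, distractor_density_B = 0,
                    shot_noise = FALSE, read_noise_sd = 5, seed = 3L)
  sim <- generate_neuron_image(cfg)
  for (ch in c("puncta_A", "puncta_B")) {
    x <- sim$image$channels[[ch]]
    expect_equal(mean(x), cfg$background, tolerance = 0.01)
    expect_lt(max(x), cfg$background + 6 * cfg$read_noise_sd)
  }
})

test_that("infeasible packing is rejected with a clear message", {
  cfg <- sim_config(image_shape = c(256L, 256L), true_density = 3,
                    seed = 1L)
  expect_error(generate_neuron_image(cfg), "packing bound")
})

test_that("rendered colocalized spot count increases with true density", {
  counts <- vapply(c(0.1, 0.25, 0.5), function(d) {
    cfg <- sim_config(image_shape = c(256L, 256L), true_density = d,
                      seed = 21L)
    nrow(generate_neuron_image(cfg)$truth$synapse_centers)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("trajectory generator honors the dwell plan", {
  layout <- list(A = list(center = c(25, 40), radius = 3),
                 B = list(center = c(55, 40), radius = 3))
  near <- function(traj, o)
    sqrt((traj$samples$x - o$center[1])^2 +
         (traj$samples$y - o$center[2])^2) - o$radius
  t1 <- generate_trajectory(80, layout, list(list("A", 600)), seed = 5L)
  expect_true(all(near(t1, layout$A) < 2))
  t2 <- generate_trajectory(80, layout, list(list("roam", 600)), seed = 5L)
  expect_true(all(near(t2, layout$A) >= 2))
  expect_true(all(near(t2, layout$B) >= 2))
  t3 <- generate_trajectory(80, layout,
                            list(list("A", 300), list("B", 300)),
                            sample_rate = 10, seed = 5L)
  expect_identical(nrow(t3$samples), 6000L)
  expect_error(
    generate_trajectory(80, list(A = list(center = c(10, 10), radius = 3),
                                 B = list(center = c(12, 10), radius = 3)),
                        list(list("A", 10))),
    "overlap")
})

test_that("band-table fixture converges to its prescribed group means", {
  # cv = 0: exact
  b0 <- generate_band_table(c(control = 1, treated = 2), cv = 0,
                            n_per_group = 3L, seed = 1L)
  n0 <- normalize_bands(b0, "control")
  expect_equal(as.numeric(tapply(n0$fold_change, n0$group,
                                 mean)[c("control", "treated")]),
               c(1, 2), tolerance = 1e-12)
  # null case
  bn <- generate_band_table(c(a = 1, b = 1), cv = 0.2, n_per_group = 2000L,
                            seed = 2L)
  nn <- normalize_bands(bn, "a")
  expect_equal(mean(nn$fold_change[nn$group == "b"]), 1, tolerance = 0.05)
  # law of large numbers at mean 3
  b3 <- generate_band_table(c(ctl = 1, glut = 3), cv = 0.2,
                            n_per_group = 10000L, seed = 3L)
  n3 <- normalize_bands(b3, "ctl")
  expect_equal(mean(n3$fold_change[n3$group == "glut"]), 3,
               tolerance = 0.05 * 3)
})
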