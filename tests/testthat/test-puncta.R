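test_that("adaptive threshold reproduces the hand-computed example", {
  # nine pixels at 10 and one at 110: mean 20, population SD 30, cutoff 80
  img <- matrix(c(rep(10, 9), 110), nrow = 2)
  mask <- threshold_mask(img, 2, "population")
  expect_identical(sum(mask), 1L)
  expect_true(mask[img == 110])
})

test_that("threshold masks are affine-invariant and empty on flat images", {
  set.seed(1)
  img <- matrix(rpois(400, 50), 20, 20)
  m0 <- threshold_mask(img, 2)
  expect_identical(threshold_mask(3.7 * img + 12, 2), m0)
  expect_identical(threshold_mask(0.01 * img, 2), m0)
  for (k in c(0, 1, 2))
    expect_false(any(threshold_mask(matrix(7, 5, 5), k)))
})

test_that("colocalization equals the per-pixel conjunction oracle", {
  a <- matrix(TRUE, 4, 4)
  expect_identical(colocalize(a, a, a), a)
  d1 <- matrix(c(TRUE, FALSE), 4, 4)
  expect_false(any(colocalize(d1, !d1)))
  expect_error(colocalize(a, matrix(TRUE, 3, 3)), "shape")
  set.seed(2)
  for (i in 1:20) {
    ma <- matrix(runif(64 * 64) < 0.4, 64, 64)
    mb <- matrix(runif(64 * 64) < 0.4, 64, 64)
    mc <- matrix(runif(64 * 64) < 0.6, 64, 64)
    expect_identical(colocalize(ma, mb, mc), oracle_conjunction(ma, mb, mc))
  }
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(3)
  for (i in 1:25) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    lab <- label_components(mask, 8L)
    ref <- oracle_label(mask, 8L)
    expect_identical(max(lab), max(ref))
    # same partition: each label maps to exactly one oracle label
    expect_true(all(tapply(ref[mask], lab[mask],
                           function(v) length(unique(v))) == 1L))
    lab4 <- label_components(mask, 4L)
    expect_identical(max(lab4), max(oracle_label(mask, 4L)))
  }
})

test_that("size rule retains only objects strictly below the limit", {
  px <- 0.5
  disk <- function(d_um, shape = 64L) {
    r <- d_um / 2 / px
    ctr <- shape / 2
    outer(seq_len(shape), seq_len(shape), function(i, j)
      (i - ctr)^2 + (j - ctr)^2 < r^2)
  }
  expect_identical(nrow(detect_puncta(disk(5), px)), 1L)
  expect_identical(nrow(detect_puncta(disk(12), px)), 0L)
  # boundary: a component with equivalent diameter exactly 10 um is removed
  area_px <- round(pi * (10 / 2)^2 / px^2)
  strip <- matrix(FALSE, 40, 400)
  strip[10, seq_len(area_px)] <- TRUE
  eqd <- 2 * sqrt(area_px * px^2 / pi)
  expect_equal(eqd, 10, tolerance = 1e-3)
  hits <- detect_puncta(strip, px, size_limit = eqd)
  expect_identical(nrow(hits), 0L)
})

test_that("puncta counts match brute-force labeling on random masks", {
  set.seed(5)
  for (i in 1:10) {
    mask <- matrix(runif(64 * 64) < 0.2, 64, 64)
    got <- detect_puncta(mask, 0.1, size_limit = Inf)
    expect_identical(nrow(got), max(oracle_label(mask, 8L)))
  }
})

test_that("density is count over length with provenance attached", {
  obj <- data.frame(label = 1:12, x = 0, y = 0, area_um2 = 1,
                    equivalent_diameter_um = 1)
  res <- synapse_density(obj, 50)
  expect_equal(res$density, 0.24)
  expect_equal(res$count / res$dendrite_length, res$density)
  res0 <- synapse_density(obj[0, ], 50)
  expect_equal(res0$density, 0)
  expect_error(synapse_density(obj, 0), "> 0")
})

test_that("full quantification is deterministic and affine-invariant", {
  cfg <- sim_config(image_shape = c(256L, 256L), true_density = 0.4,
                    seed = 17L)
  sim <- generate_neuron_image(cfg)
  cm <- threshold_mask(sim$image$channels$cell_fill, 1)
  tr <- trace_dendrites(cm, sim$image$pixel_size)
  r1 <- quantify_image(sim$image, tr)
  r2 <- quantify_image(sim$image, tr)
  expect_identical(r1$objects, r2$objects)
  expect_identical(r1$density, r2$density)
  # rescaled intensities give the same density
  img2 <- sim$image
  img2$channels <- lapply(img2$channels, function(ch) 2.5 * ch + 40)
  r3 <- quantify_image(img2, tr)
  expect_identical(r3$count, r1$count)
  # dual mode counts at least as many objects as triple
  r4 <- quantify_image(sim$image, tr, mode = "dual")
  expect_gte(r4$count, r1$count)
})
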