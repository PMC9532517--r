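test_that("classification rules reproduce the published heuristics", {
  expect_identical(classify_spine(list(length = 2.0, head_width = 0.5,
                                       neck_width = 0.2)), "mushroom")
  expect_identical(classify_spine(list(length = 0.5, head_width = 0.3,
                                       neck_width = 0.3)), "stubby")
  expect_identical(classify_spine(list(length = 3.5, head_width = 0.2,
                                       neck_width = 0.2)), "filopodium")
  expect_identical(classify_spine(list(length = 1.5, head_width = 0.25,
                                       neck_width = 0.2)), "thin")
  expect_error(classify_spine(list(length = 1)), "geometry")
})

test_that("every detected spine receives exactly one class", {
  for (s in 1:3) {
    fix <- generate_spine_image(n_spines = 10L, seed = s)
    rec <- classify_spines(detect_spines(threshold_mask(fix$image, 1),
                                         fix$trace, fix$pixel_size))
    expect_true(all(rec$class %in% c("thin", "stubby", "mushroom",
                                     "filopodium")))
    expect_identical(length(rec$class), nrow(rec))
  }
})

test_that("fixture spines are recovered with their planned classes", {
  fix <- generate_spine_image(n_spines = 12L, seed = 5L)
  rec <- classify_spines(detect_spines(threshold_mask(fix$image, 1),
                                       fix$trace, fix$pixel_size))
  expect_identical(nrow(rec), nrow(fix$plan))
  expect_identical(table(factor(rec$class, levels = unique(sort(
    c(rec$class, fix$plan$planned_class))))),
    table(factor(fix$plan$planned_class, levels = unique(sort(
      c(rec$class, fix$plan$planned_class))))))
  # smooth tube with no protrusions yields none
  smooth <- generate_spine_image(
    spine_plan = data.frame(base_x = numeric(0), side = numeric(0),
                            length = numeric(0), head_width = numeric(0),
                            neck_width = numeric(0)), seed = 1L)
  rec0 <- detect_spines(threshold_mask(smooth$image, 1), smooth$trace,
                        smooth$pixel_size)
  expect_identical(nrow(rec0), 0L)
})

test_that("over-long protrusions are excluded as non-spines", {
  fix <- generate_spine_image(
    spine_plan = data.frame(base_x = c(6, 14), side = c(1, -1),
                            length = c(8, 1.2), head_width = c(0.4, 0.6),
                            neck_width = c(0.3, 0.25)), seed = 2L)
  rec <- detect_spines(threshold_mask(fix$image, 1), fix$trace,
                       fix$pixel_size)
  expect_identical(nrow(rec), 1L)
  expect_lt(rec$length, 5)
})

test_that("densities per class follow a known fixture mix", {
  plan <- data.frame(
    base_x = seq(1.5, 18.5, length.out = 20),
    side = rep_len(c(1, -1), 20),
    length = rep(c(1.2, 1.6, 0.6, 1.2), 5),
    head_width = rep(c(0.6, 0.25, 0.4, 0.6), 5),
    neck_width = rep(c(0.25, 0.18, 0.4, 0.25), 5))
  fix <- generate_spine_image(spine_plan = plan, segment_length = 20,
                              seed = 7L)
  rec <- classify_spines(detect_spines(threshold_mask(fix$image, 1),
                                       fix$trace, fix$pixel_size))
  dens <- spine_density(rec, fix$trace)
  # 10 mushroom, 5 thin, 5 stubby on ~20 um
  expect_equal(dens$total_density, 1.0, tolerance = 0.15)
  expect_equal(unname(dens$per_class_density["mushroom"]), 0.5,
               tolerance = 0.15 * 0.5 + 0.05)
  expect_equal(unname(dens$per_class_density["thin"]), 0.25,
               tolerance = 0.15 * 0.25 + 0.05)
  expect_equal(unname(dens$per_class_density["stubby"]), 0.25,
               tolerance = 0.15 * 0.25 + 0.05)
  # empty record list gives all-zero densities
  z <- spine_density(rec[0, ], fix$trace)
  expect_identical(z$total_density, 0)
})

test_that("manual overrides replace the automatic class", {
  fix <- generate_spine_image(n_spines = 6L, seed = 9L)
  rec <- detect_spines(threshold_mask(fix$image, 1), fix$trace,
                       fix$pixel_size)
  rec$override <- NA_character_
  rec$override[1] <- "filopodium"
  out <- classify_spines(rec)
  expect_identical(out$class[1], "filopodium")
})
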