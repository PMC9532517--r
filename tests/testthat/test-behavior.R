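std_layout <- function()
  list(A = list(center = c(25, 40), radius = 3),
       B = list(center = c(55, 40), radius = 3))

test_that("exploration scoring handles the canonical cases exactly", {
  layout <- std_layout()
  tA <- generate_trajectory(80, layout, list(list("A", 600)), seed = 1L)
  rA <- score_exploration(tA, layout)
  expect_equal(unname(rA$percent_per_object), c(100, 0))
  expect_equal(rA$exploring_total, 600)

  tR <- generate_trajectory(80, layout, list(list("roam", 120)), seed = 1L)
  rR <- score_exploration(tR, layout)
  expect_true(all(rR$time_per_object == 0))
  expect_true(rR$undefined)
  expect_true(all(is.na(rR$percent_per_object)))

  tAB <- generate_trajectory(80, layout,
                             list(list("A", 300), list("B", 300)), seed = 2L)
  rAB <- score_exploration(tAB, layout)
  expect_equal(unname(rAB$percent_per_object), c(50, 50))
  expect_equal(sum(rAB$percent_per_object), 100)
})

test_that("the 2 cm rule is strict and measured to the object boundary", {
  layout <- list(A = list(center = c(40, 40), radius = 3))
  mk <- function(d_boundary) trajectory(
    data.frame(t = 0, x = 40 + 3 + d_boundary, y = 40),
    sample_rate = 1, arena = c(80, 80))
  expect_equal(score_exploration(mk(1.99), layout)$exploring_total, 1)
  expect_equal(score_exploration(mk(2.00), layout)$exploring_total, 0)
  expect_equal(score_exploration(mk(2.01), layout)$exploring_total, 0)
  expect_error(score_exploration(trajectory(
    data.frame(t = numeric(0), x = numeric(0), y = numeric(0)), 1,
    c(80, 80)), layout), "empty")
})

test_that("planned dwell durations are recovered within two sample periods", {
  layout <- std_layout()
  plan <- list(list("A", 137), list("roam", 60), list("B", 403))
  traj <- generate_trajectory(80, layout, plan, sample_rate = 10, seed = 3L)
  res <- score_exploration(traj, layout)
  expect_equal(unname(res$time_per_object["A"]), 137, tolerance = 0.2 / 137)
  expect_equal(unname(res$time_per_object["B"]), 403, tolerance = 0.2 / 403)
  expect_lte(res$exploring_total, max(traj$samples$t) + 0.1)
})

test_that("scoring is stable under resampling at a higher rate", {
  layout <- std_layout()
  traj <- generate_trajectory(80, layout,
                              list(list("A", 60), list("B", 30)),
                              sample_rate = 10, seed = 4L)
  # linear interpolation to 50 Hz
  t2 <- seq(0, max(traj$samples$t), by = 0.02)
  up <- trajectory(data.frame(
    t = t2,
    x = approx(traj$samples$t, traj$samples$x, t2)$y,
    y = approx(traj$samples$t, traj$samples$y, t2)$y),
    sample_rate = 50, arena = traj$arena)
  r1 <- score_exploration(traj, layout)
  r2 <- score_exploration(up, layout)
  expect_equal(unname(r1$time_per_object), unname(r2$time_per_object),
               tolerance = 0.2 / 30)
})

test_that("trajectory CSV round trips", {
  layout <- std_layout()
  traj <- generate_trajectory(80, layout, list(list("A", 30)), seed = 5L)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f, arena = 80)
  expect_equal(back$samples, traj$samples, tolerance = 1e-12)
  expect_equal(back$sample_rate, traj$sample_rate, tolerance = 1e-6)
})

test_that("preference test flags displaced-object preference", {
  layout <- std_layout()
  mk_animal <- function(pctA, seed) {
    dur <- 600
    tA <- max(1, round(dur * pctA / 100))
    traj <- generate_trajectory(80, layout,
                                list(list("A", tA), list("B", dur - tA)),
                                seed = seed)
    score_exploration(traj, layout)
  }
  set.seed(6)
  trained <- lapply(1:8, function(i) mk_animal(rnorm(1, 50, 5), i))
  test_s <- lapply(1:8, function(i) mk_animal(rnorm(1, 65, 5), 100 + i))
  rep <- preference_test(trained, test_s, displaced = "A")
  expect_lt(rep$p.value, 0.05)
  key <- grepl("test:A", rep$comparisons$comparison) &
    grepl("training:A", rep$comparisons$comparison)
  expect_true(any(rep$comparisons$p.value[key] < 0.05))
  expect_equal(rep$extra$displaced_test_mean, 65, tolerance = 0.1)

  # null case: all animals at exactly 50 percent
  flat <- lapply(1:4, function(i) mk_animal(50, 200 + i))
  rep0 <- preference_test(flat, flat, displaced = "A")
  expect_gt(min(rep0$comparisons$p.value), 0.99)
  expect_error(preference_test(flat[1], flat, "A"), ">= 2")
})
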