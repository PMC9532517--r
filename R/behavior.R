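#' Nose-point trajectory
#'
#' @param samples data.frame with columns `t` (s, strictly increasing),
#'   `x`, `y` (cm).
#' @param sample_rate samples per second.
#' @param arena arena (width, height) in cm.
#' @return a `trajectory`.
#' @export
trajectory <- function(samples, sample_rate, arena) {
  need <- c("t", "x", "y")
  if (!all(need %in% names(samples)))
    nq_data_error("trajectory needs columns t, x, y")
  if (nrow(samples) && any(diff(samples$t) <= 0))
    nq_data_error("timestamps must be strictly increasing")
  if (length(arena) == 1L) arena <- rep(arena, 2L)
  if (nrow(samples) &&
      (any(samples$x < 0 | samples$x > arena[1]) ||
       any(samples$y < 0 | samples$y > arena[2])))
    nq_data_error("trajectory points fall outside the arena")
  structure(list(samples = samples[, need], sample_rate = sample_rate,
                 arena = arena),
            class = "trajectory")
}

#' Read a trajectory from CSV
#'
#' Expects a `t,x,y` header (seconds, cm).
#'
#' @param path CSV file.
#' @param sample_rate samples per second; inferred from median time step if
#'   `NULL`.
#' @param arena arena size in cm.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, sample_rate = NULL, arena) {
  if (!file.exists(path)) nq_data_error(paste0("file not found: ", path))
  tab <- read.csv(path)
  if (is.null(sample_rate)) {
    if (nrow(tab) < 2L) nq_data_error("cannot infer sample rate")
    sample_rate <- 1 / median(diff(tab$t))
  }
  trajectory(tab, sample_rate, arena)
}

#' Write a trajectory to CSV
#'
#' @param traj a [trajectory()].
#' @param path output CSV path (`t,x,y` header).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj$samples, path, row.names = FALSE)
  invisible(path)
}

#' Score object exploration from a nose-point trajectory
#'
#' A sample counts as exploring an object iff the nose is strictly closer
#' than `radius_cm` to the object's boundary (center distance minus object
#' radius); a sample within the radius of two objects is assigned to the
#' nearer one. Exploration time is sample count over sample rate; the
#' recognition readout is each object's percentage of total exploring time.
#'
#' @param traj a [trajectory()].
#' @param layout named list of objects `list(center = c(x, y), radius = r)`
#'   (cm).
#' @param radius_cm exploration radius (assay rule: 2 cm, strict).
#' @return an `exploration_result`: `time_per_object` (s),
#'   `percent_per_object`, `exploring_total` (s), `undefined` flag (TRUE
#'   when no exploration occurred and percentages are undefined).
#' @export
score_exploration <- function(traj, layout, radius_cm = 2) {
  if (!nrow(traj$samples)) nq_data_error("empty trajectory")
  centers <- do.call(rbind, lapply(layout, function(o) o$center))
  radii <- vapply(layout, function(o) o$radius, numeric(1))
  if (length(layout) >= 2L) {
    dd <- as.matrix(dist(centers)); diag(dd) <- Inf
    if (any(dd < outer(radii, radii, `+`))) nq_data_error("objects overlap")
  }
  bd <- vapply(seq_along(layout), function(i)
    sqrt((traj$samples$x - centers[i, 1])^2 +
         (traj$samples$y - centers[i, 2])^2) - radii[i],
    numeric(nrow(traj$samples)))
  bd <- matrix(bd, nrow = nrow(traj$samples))
  exploring <- bd < radius_cm            # strict: exactly radius_cm excluded
  nearest <- apply(bd, 1, which.min)
  assigned <- ifelse(rowSums(exploring) > 0, nearest, NA_integer_)
  counts <- vapply(seq_along(layout), function(i)
    sum(assigned == i, na.rm = TRUE), numeric(1))
  times <- counts / traj$sample_rate
  total <- sum(times)
  pct <- if (total > 0) 100 * times / total else rep(NA_real_, length(times))
  structure(list(time_per_object = setNames(times, names(layout)),
                 percent_per_object = setNames(pct, names(layout)),
                 exploring_total = total, undefined = total == 0),
            class = "exploration_result")
}

#' @export
print.exploration_result <- function(x, ...) {
  cat("<exploration_result> total exploring ", signif(x$exploring_total, 5),
      " s\n", sep = "")
  tab <- rbind(`time (s)` = x$time_per_object,
               `percent` = x$percent_per_object)
  print(signif(tab, 4))
  if (x$undefined) cat("  (no exploration: percentages undefined)\n")
  invisible(x)
}

#' Compare object preference across training and test sessions
#'
#' Builds the session-by-object percentage table (one row per animal and
#' object within each session type), reports group means +/- SEM of the
#' displaced-object percentage, and tests across the session/object cells
#' with a one-way ANOVA followed by Fisher's LSD (all pairwise t-tests on
#' the pooled residual variance, unadjusted).
#'
#' @param results_trained,results_test lists of `exploration_result` (one
#'   per animal, >= 2 each).
#' @param displaced name of the displaced object.
#' @return a [stat_report()]; `comparisons` holds the LSD pairwise tests
#'   between cells (`training:obj`, `test:obj`).
#' @export
preference_test <- function(results_trained, results_test, displaced) {
  if (length(results_trained) < 2L || length(results_test) < 2L)
    nq_data_error("need >= 2 animals per condition")
  objs <- names(results_trained[[1]]$percent_per_object)
  if (!displaced %in% objs)
    nq_data_error(paste0("unknown displaced object: ", displaced))
  cells <- function(results, session) {
    do.call(rbind, lapply(seq_along(results), function(a)
      data.frame(animal = a, session = session, object = objs,
                 percent = as.numeric(
                   results[[a]]$percent_per_object[objs]))))
  }
  long <- rbind(cells(results_trained, "training"),
                cells(results_test, "test"))
  long <- long[complete.cases(long), ]
  long$cell <- factor(paste(long$session, long$object, sep = ":"))
  fit <- aov(percent ~ cell, data = long)
  atab <- anova(fit)
  mse <- atab$`Mean Sq`[2]; dfr <- atab$Df[2]
  flags <- character(0)
  if (mse == 0) flags <- "degenerate: zero within-cell variance"
  lev <- levels(long$cell)
  means <- tapply(long$percent, long$cell, mean)
  ns <- tapply(long$percent, long$cell, length)
  pairs <- utils::combn(lev, 2)
  comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    diffab <- means[[a]] - means[[b]]
    tstat <- if (se > 0) diffab / se else if (diffab == 0) 0 else Inf
    data.frame(comparison = paste(a, "vs", b),
               estimate = diffab, t = tstat, df = dfr,
               p.value = if (is.finite(tstat)) 2 * pt(-abs(tstat), dfr)
                         else 0)
  }))
  groups <- split(long$percent, long$cell)
  est <- group_estimates(groups)
  disp_pct <- vapply(results_test, function(r)
    as.numeric(r$percent_per_object[displaced]), numeric(1))
  Fv <- atab$`F value`[1]
  pv <- atab$`Pr(>F)`[1]
  if (mse == 0) {
    between_zero <- atab$`Sum Sq`[1] < 1e-12
    Fv <- if (between_zero) 0 else Inf
    pv <- if (between_zero) 1 else 0
  }
  stat_report("one-way ANOVA with Fisher's LSD",
              statistic = Fv, p.value = pv,
              estimates = est, df = c(atab$Df[1], dfr), comparisons = comp,
              flags = flags,
              extra = list(displaced = displaced,
                           displaced_test_mean = mean(disp_pct),
                           displaced_test_sem = sd(disp_pct) /
                             sqrt(length(disp_pct))))
}
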