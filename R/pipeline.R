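#' Default run configuration
#'
#' Fills a pipeline configuration with the assay defaults: puncta threshold
#' mean + 2 SD, cell-fill threshold mean + 1 SD, 10 um colocalization size
#' limit, 10 um Sholl step, 2 cm exploration radius, alpha 0.05.
#'
#' @param ... named overrides (nested lists merge shallowly per stage).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    output_dir = "neuroquant_results",
    seed = 1L,
    simulate = list(n_images = 3L, conditions = list(control = 0.25),
                    image_shape = c(512L, 512L), pixel_size = 0.1,
                    n_slices = 1L),
    quantify = list(k_puncta = 2, k_cell_fill = 1, sd_kind = "population",
                    mode = "triple", size_limit = 10, min_area_px = 1L),
    sholl = list(step = 10),
    spines = list(n_segments = 5L, n_spines = 12L, segment_length = 20),
    behavior = list(arena = 80, radius_cm = 2),
    alpha = 0.05)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      nq_config_error(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) nq_config_error("config must be a list or YAML path")
  do.call(run_config, config)
}

write_result_csv <- function(df, path, hash) {
  df$config_hash <- hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run pipeline stages from a configuration
#'
#' Executes the requested stage(s) -- `simulate`, `quantify`, `sholl`,
#' `spines`, `behavior`, `stats`, `report` -- writing result tables under
#' `config$output_dir`. Every output table carries the configuration hash;
#' identical configuration and seed give byte-identical outputs.
#'
#' @param config a [run_config()], plain list, or YAML file path.
#' @param stages character vector of stages to run (default: simulate,
#'   quantify, stats).
#' @return named list of per-stage outputs, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "quantify", "stats")) {
  cfg <- load_run_config(config)
  known <- c("simulate", "quantify", "sholl", "spines", "behavior",
             "stats", "report")
  bad <- setdiff(stages, known)
  if (length(bad))
    nq_config_error(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a(unclass(cfg))
  out <- list()

  if ("simulate" %in% stages) {
    rows <- list()
    img_dir <- file.path(cfg$output_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (cond in names(cfg$simulate$conditions)) {
      dens <- cfg$simulate$conditions[[cond]]
      for (i in seq_len(cfg$simulate$n_images)) {
        seed_i <- cfg$seed * 10000L + length(rows)
        sc <- sim_config(image_shape = cfg$simulate$image_shape,
                         pixel_size = cfg$simulate$pixel_size,
                         true_density = dens,
                         n_slices = cfg$simulate$n_slices, seed = seed_i)
        sim <- generate_neuron_image(sc)
        stem <- file.path(img_dir, sprintf("%s_%02d", cond, i))
        write_image_set(sim$image, paste0(stem, ".tif"))
        write_ground_truth(sim$truth, paste0(stem, "_truth.json"))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, image = paste0(stem, ".tif"),
          truth = paste0(stem, "_truth.json"),
          true_density = dens, seed = seed_i)
      }
    }
    manifest <- do.call(rbind, rows)
    write_result_csv(manifest, file.path(cfg$output_dir, "manifest.csv"),
                     hash)
    out$simulate <- manifest
  }

  manifest_path <- file.path(cfg$output_dir, "manifest.csv")
  if (any(c("quantify", "sholl") %in% stages) && !file.exists(manifest_path))
    nq_data_error("missing manifest.csv: run the simulate stage first")

  if ("quantify" %in% stages) {
    manifest <- read.csv(manifest_path)
    q <- cfg$quantify
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      img <- read_image(manifest$image[i],
                        c(cell_fill = 1, puncta_A = 2, puncta_B = 3))
      if (is_stack(img)) img <- max_project(img)
      cm <- threshold_mask(img$channels$cell_fill, q$k_cell_fill, q$sd_kind)
      trace <- trace_dendrites(cm, img$pixel_size)
      res <- quantify_image(img, trace,
                            threshold_spec(q$k_puncta, q$k_cell_fill,
                                           q$sd_kind),
                            mode = q$mode, size_limit = q$size_limit,
                            min_area_px = q$min_area_px)
      data.frame(condition = manifest$condition[i],
                 image = manifest$image[i], count = res$count,
                 dendrite_length_um = res$dendrite_length,
                 density_per_um = res$density,
                 k_puncta = q$k_puncta, k_cell_fill = q$k_cell_fill,
                 size_limit_um = q$size_limit)
    })
    qtab <- do.call(rbind, rows)
    write_result_csv(qtab, file.path(cfg$output_dir, "puncta_density.csv"),
                     hash)
    out$quantify <- qtab
  }

  if ("sholl" %in% stages) {
    manifest <- read.csv(manifest_path)
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      img <- read_image(manifest$image[i],
                        c(cell_fill = 1, puncta_A = 2, puncta_B = 3))
      if (is_stack(img)) img <- max_project(img)
      cm <- threshold_mask(img$channels$cell_fill,
                           cfg$quantify$k_cell_fill, cfg$quantify$sd_kind)
      pr <- sholl(trace_dendrites(cm, img$pixel_size), cfg$sholl$step)
      data.frame(condition = manifest$condition[i],
                 image = manifest$image[i], radius_um = pr$radii,
                 intersections = pr$intersections)
    })
    stab <- do.call(rbind, rows)
    write_result_csv(stab, file.path(cfg$output_dir, "sholl.csv"), hash)
    out$sholl <- stab
  }

  if ("spines" %in% stages) {
    sp <- cfg$spines
    rows <- list()
    for (j in seq_len(sp$n_segments)) {
      fix <- generate_spine_image(n_spines = sp$n_spines,
                                  segment_length = sp$segment_length,
                                  seed = cfg$seed * 1000L + j)
      mask <- threshold_mask(fix$image, 1)
      rec <- classify_spines(detect_spines(mask, fix$trace, fix$pixel_size))
      dens <- spine_density(rec, fix$trace)
      rows[[j]] <- data.frame(
        segment = j, n_spines = dens$n_spines,
        dendrite_length_um = dens$dendrite_length,
        total_density = dens$total_density,
        thin = dens$per_class_density[["thin"]],
        stubby = dens$per_class_density[["stubby"]],
        mushroom = dens$per_class_density[["mushroom"]],
        filopodium = dens$per_class_density[["filopodium"]])
    }
    sptab <- do.call(rbind, rows)
    write_result_csv(sptab, file.path(cfg$output_dir, "spine_density.csv"),
                     hash)
    out$spines <- sptab
  }

  if ("behavior" %in% stages) {
    b <- cfg$behavior
    layout <- list(A = list(center = c(25, 40), radius = 3),
                   B = list(center = c(55, 40), radius = 3))
    traj <- generate_trajectory(b$arena, layout,
                                list(list("A", 300), list("B", 300)),
                                seed = cfg$seed)
    res <- score_exploration(traj, layout, b$radius_cm)
    btab <- data.frame(object = names(res$time_per_object),
                       time_s = as.numeric(res$time_per_object),
                       percent = as.numeric(res$percent_per_object))
    write_result_csv(btab, file.path(cfg$output_dir, "behavior.csv"), hash)
    out$behavior <- btab
  }

  if ("stats" %in% stages) {
    qpath <- file.path(cfg$output_dir, "puncta_density.csv")
    if (!file.exists(qpath))
      nq_data_error("missing puncta_density.csv: run the quantify stage first")
    qtab <- read.csv(qpath)
    groups <- split(qtab$density_per_um, qtab$condition)
    enough <- all(lengths(groups) >= 2L)
    rep_out <- if (!enough) NULL
      else if (length(groups) >= 3L) anova_dunnett_t3(groups)
      else if (length(groups) == 2L) welch_t(groups[[1]], groups[[2]])
      else NULL
    summ <- data.frame(condition = names(groups),
                       mean_density = vapply(groups, mean, numeric(1)),
                       sem = vapply(groups, function(g)
                         sd(g) / sqrt(length(g)), numeric(1)),
                       n = lengths(groups))
    write_result_csv(summ, file.path(cfg$output_dir, "stats_summary.csv"),
                     hash)
    if (!is.null(rep_out)) {
      srl <- list(test = rep_out$test, statistic = rep_out$statistic,
                  df = rep_out$df, p.value = rep_out$p.value,
                  estimates = rep_out$estimates,
                  comparisons = rep_out$comparisons,
                  config_hash = hash,
                  package_version = as.character(packageVersion("neuroquant")))
      jsonlite::write_json(srl, file.path(cfg$output_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    out$stats <- rep_out
  }

  if ("report" %in% stages) out$report <- make_report(cfg$output_dir)
  invisible(out)
}

#' Collate run artifacts into a Markdown report
#'
#' @param result_dir directory written by [run_pipeline()].
#' @param path output Markdown path (default `report.md` inside
#'   `result_dir`).
#' @return `path`, invisibly.
#' @export
make_report <- function(result_dir, path = file.path(result_dir,
                                                     "report.md")) {
  if (!dir.exists(result_dir))
    nq_data_error(paste0("result directory not found: ", result_dir))
  expected <- c("puncta_density.csv", "stats_summary.csv")
  present <- file.exists(file.path(result_dir, expected))
  if (!any(present))
    nq_data_error(paste0("no run artifacts in ", result_dir,
                         "; expected at least one of: ",
                         paste(expected, collapse = ", ")))
  lines <- c("# neuroquant run report", "")
  fmt_table <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r)
      paste0("| ", paste(trimws(format(r)), collapse = " | "), " |"))
    c(hdr, sep, body)
  }
  for (f in c("stats_summary.csv", "puncta_density.csv", "sholl.csv",
              "spine_density.csv", "behavior.csv")) {
    p <- file.path(result_dir, f)
    if (!file.exists(p)) next
    tab <- read.csv(p)
    lines <- c(lines, paste0("## ", f), "", fmt_table(head(tab, 50)), "")
  }
  sj <- file.path(result_dir, "stats.json")
  if (file.exists(sj)) {
    s <- jsonlite::read_json(sj, simplifyVector = TRUE)
    lines <- c(lines, "## Group comparison", "",
               paste0("- test: ", s$test),
               paste0("- statistic: ", signif(s$statistic, 5)),
               paste0("- p-value: ", format.pval(s$p.value, digits = 4)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
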