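#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run.  Defaults mirror the study
#' design this package models: searchlight radius 3 voxels, step 2, minimum 15
#' voxels, 70% activity and 0.2 grey-matter thresholds, a 5-s hemodynamic
#' shift with a 1-s tolerance window, TR 2.47 s, 34 groups of 17, FDR level
#' 0.05, and noise levels of 5/50/100% of the signal SD with 100 repetitions.
#'
#' @param mode `"synthetic"` (default) or `"real"`.
#' @param cohort a [cohort_spec()] (synthetic mode).
#' @param paths list for real mode: `subjects_tsv` (character vector of
#'   per-subject TSVs), `ages_tsv` (TSV with columns `subject`, `age`),
#'   `events_tsv` (one column of onset seconds, no header).
#' @param searchlight list: `radius`, `step`, `min_size`, `activity_frac`,
#'   `gm_thresh`.
#' @param gsbs list: `k_max` (NULL = T/2), `finetune_window`, `criterion`,
#'   `var.equal`.
#' @param events list: `hrf_shift_s`, `window_s`, `cluster_window_s`,
#'   `min_agree`.
#' @param stats list: `n_groups`, `group_size`, `q`.
#' @param sims list: `enabled`, `levels`, `shifts`, `reps`, `trim`.
#' @param hyperalign align subjects within each group before averaging.
#' @param seed master seed; all stage seeds are derived from it.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "real"), cohort = cohort_spec(),
                       paths = list(),
                       searchlight = list(radius = 3, step = 2L, min_size = 15L,
                                          activity_frac = 0.70, gm_thresh = 0.2),
                       gsbs = list(k_max = NULL, finetune_window = 1L,
                                   criterion = "fit", var.equal = TRUE),
                       events = list(hrf_shift_s = 5, window_s = 1,
                                     cluster_window_s = 2.47, min_agree = 5L),
                       stats = list(n_groups = 34L, group_size = 17L, q = 0.05),
                       sims = list(enabled = FALSE, levels = c(0.05, 0.5, 1),
                                   shifts = c(1L, 2L), reps = 100L, trim = 2L),
                       hyperalign = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "real") {
    need <- c("subjects_tsv", "ages_tsv", "events_tsv")
    if (!all(need %in% names(paths))) {
      abort("Real mode requires paths$subjects_tsv, paths$ages_tsv, paths$events_tsv.")
    }
    missing_files <- setdiff(c(paths$subjects_tsv, paths$ages_tsv, paths$events_tsv),
                             character(0))
    missing_files <- missing_files[!file.exists(missing_files)]
    if (length(missing_files) > 0L) {
      abort(sprintf("Missing input file(s): %s",
                    paste(missing_files, collapse = ", ")))
    }
  }
  structure(list(mode = mode, cohort = cohort, paths = paths,
                 searchlight = searchlight, gsbs = gsbs, events = events,
                 stats = stats, sims = sims, hyperalign = hyperalign,
                 seed = assert_count(seed, min = 0L)),
            class = "run_config")
}

#' Stable hash of a run configuration
#'
#' Functions (the cohort's `duration_map`) enter the hash by their deparsed
#' body, so any parameter change — including the duration map — changes the
#' hash.
#'
#' @param config a [run_config()].
#' @return a hash string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$duration_map <- paste(deparse(x$cohort$duration_map), collapse = "\n")
  rlang::hash(x)
}

#' Read a run configuration from JSON or YAML
#'
#' Scalar fields override [run_config()] defaults; the cohort `duration_map`
#' may be given as a string of R code for a function.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("YAML configs require the yaml package.")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$duration_map) && is.character(cohort_args$duration_map)) {
    cohort_args$duration_map <- eval(parse(text = cohort_args$duration_map))
  }
  defaults <- run_config()
  merge_list <- function(base, new) {
    for (nm in names(new)) base[[nm]] <- new[[nm]]
    base
  }
  run_config(
    mode = raw$mode %||% "synthetic",
    cohort = do.call(cohort_spec, cohort_args),
    paths = raw$paths %||% list(),
    searchlight = merge_list(defaults$searchlight, raw$searchlight %||% list()),
    gsbs = merge_list(defaults$gsbs, raw$gsbs %||% list()),
    events = merge_list(defaults$events, raw$events %||% list()),
    stats = merge_list(defaults$stats, raw$stats %||% list()),
    sims = merge_list(defaults$sims, raw$sims %||% list()),
    hyperalign = raw$hyperalign %||% TRUE,
    seed = raw$seed %||% 1L
  )
}

write_stamped_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
}

read_stamped_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Serialise a GSBS fit to TSV + JSON
#'
#' The TSV has one row per TR (`tr_index`, `is_start`, `k_at_detection`: the
#' smallest k at which that TR was a boundary); the JSON carries the
#' t-distance curve and the selected k.
#'
#' @param fit a `"gsbs"` object.
#' @param stem output path stem (writes `<stem>.tsv` and `<stem>.json`).
#' @param hash config hash stamped into the TSV.
#' @return `stem`, invisibly.
#' @export
write_segmentation <- function(fit, stem, hash = "") {
  stopifnot(inherits(fit, "gsbs"))
  k_at <- rep(NA_integer_, fit$n_tr)
  for (k in 2:fit$k_max) {
    b <- fit$boundaries_per_k[[k]]
    newly <- setdiff(b, which(!is.na(k_at)))
    k_at[newly[is.na(k_at[newly])]] <- k
  }
  df <- tibble(tr_index = seq_len(fit$n_tr),
               is_start = as.integer(seq_len(fit$n_tr) %in% fit$optimal),
               k_at_detection = k_at)
  write_stamped_tsv(df, paste0(stem, ".tsv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, optimal_k = fit$optimal_k,
         tdistance_per_k = fit$tdistance_per_k,
         optimal_starts = fit$optimal),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(stem)
}

run_stage <- function(name, log_con, code) {
  writeLines(sprintf("stage %s: start", name), log_con)
  res <- tryCatch(force(code), error = function(e) {
    writeLines(sprintf("stage %s: FAILED (%s)", name, conditionMessage(e)), log_con)
    close(log_con)
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  })
  writeLines(sprintf("stage %s: done", name), log_con)
  res
}

#' Run the end-to-end neural-state pipeline
#'
#' Executes the stages in dependency order — simulate/load, group preparation
#' (hyperalignment and averaging), segmentation, boundary metrics, age
#' inference, and optional perturbation simulations — writing TSV/JSON outputs
#' plus a stage log into `out_dir`.  Every table carries the configuration
#' hash; a rerun with the same configuration and seed reproduces the TSV/JSON
#' outputs byte-for-byte.  In synthetic mode the cohort is one region; the
#' searchlight utilities ([define_searchlights()] and friends) serve
#' volumetric analyses outside this driver.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @return invisibly, a list with the per-group metrics tibble, the stats
#'   tibble, and the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_con <- file(file.path(out_dir, "pipeline.log"), "w")
  writeLines(c(sprintf("config_hash: %s", hash),
               sprintf("mode: %s", config$mode),
               sprintf("seed: %d", config$seed)), log_con)

  # --- stage: simulate / load -------------------------------------------
  inputs <- run_stage("simulate", log_con, {
    if (config$mode == "synthetic") {
      sp <- config$cohort
      sp$seed <- derive_seed(config$seed, 10L)
      coh <- make_cohort(sp)
      list(
        groups = lapply(coh$groups, function(g) list(age = g$age, subjects = g$subjects)),
        onsets_s = coh$truth$event_times_s,
        TR = sp$TR, n_tr = sp$n_tr, cohort = coh
      )
    } else {
      ages_tbl <- readr::read_tsv(config$paths$ages_tsv, show_col_types = FALSE,
                                  progress = FALSE)
      mats <- lapply(config$paths$subjects_tsv, read_subject_tsv)
      TR <- attr(mats[[1]], "TR") %||% config$cohort$TR
      asg <- assign_age_groups(ages_tbl$age, config$stats$n_groups,
                               config$stats$group_size)
      groups <- lapply(sort(unique(asg$group)), function(g) {
        idx <- asg$subject[asg$group == g]
        list(age = asg$median_age[asg$group == g][1], subjects = mats[idx])
      })
      onsets <- readr::read_tsv(config$paths$events_tsv, col_names = "onset_s",
                                show_col_types = FALSE, progress = FALSE)$onset_s
      list(groups = groups, onsets_s = onsets, TR = TR, n_tr = nrow(mats[[1]]))
    }
  })
  writeLines(sprintf("groups: %d; TR: %g s; T: %d TRs; events: %d",
                     length(inputs$groups), inputs$TR, inputs$n_tr,
                     length(inputs$onsets_s)), log_con)

  # --- stage: group preparation -----------------------------------------
  prep <- run_stage("group_prep", log_con, {
    lapply(inputs$groups, function(g) {
      subs <- g$subjects
      if (config$hyperalign && length(subs) >= 2L) subs <- hyperalign_group(subs)
      list(age = g$age, avg = group_average(subs),
           iss = if (length(g$subjects) >= 2L) group_iss(g$subjects) else NA_real_)
    })
  })

  # --- stage: segmentation ----------------------------------------------
  fits <- run_stage("segment", log_con, {
    lapply(seq_along(prep), function(g) {
      fit <- gsbs(prep[[g]]$avg, k_max = config$gsbs$k_max,
                  finetune_window = config$gsbs$finetune_window,
                  criterion = config$gsbs$criterion,
                  var.equal = config$gsbs$var.equal, TR = inputs$TR)
      write_segmentation(fit, file.path(out_dir, sprintf("segmentation_group%02d", g)),
                         hash = hash)
      fit
    })
  })

  # --- stage: metrics ----------------------------------------------------
  metrics <- run_stage("metrics", log_con, {
    tl <- event_timeline(inputs$onsets_s, TR = inputs$TR,
                         hrf_shift_s = config$events$hrf_shift_s,
                         window_s = config$events$window_s)
    ev_trs <- event_tr_set(tl, inputs$n_tr)
    occ <- boundary_occurrence_split(lapply(fits, `[[`, "optimal"), ev_trs,
                                     inputs$n_tr)
    tab <- purrr::map_dfr(seq_along(fits), function(g) {
      b <- fits[[g]]$optimal
      ov <- absolute_overlap(b, ev_trs, inputs$n_tr)
      tibble(group = g, age = prep[[g]]$age,
             optimal_k = fits[[g]]$optimal_k,
             median_duration_s = median_duration_s(b, inputs$n_tr, inputs$TR),
             duration_cv = duration_cv(b, inputs$n_tr),
             absolute_overlap = ov$absolute,
             observed_overlap = ov$observed,
             expected_overlap = ov$expected,
             iss = prep[[g]]$iss,
             on_event_occurrence = occ$on_event[g],
             off_event_occurrence = occ$off_event[g])
    })
    write_stamped_tsv(tab, file.path(out_dir, "group_metrics.tsv"), hash)
    jsonlite::write_json(list(config_hash = hash, event_trs = ev_trs),
                         file.path(out_dir, "event_trs.json"),
                         auto_unbox = TRUE, digits = NA)
    tab
  })

  # --- stage: inference ---------------------------------------------------
  stats_tab <- run_stage("infer", log_con, {
    # analyses whose preconditions fail on a given cohort (too few groups,
    # missing ISS) are skipped with a log note rather than aborting the run
    try_row <- function(analysis, expr) {
      tryCatch(dplyr::bind_cols(tibble(analysis = analysis), expr),
               error = function(e) {
                 writeLines(sprintf("infer: skipped %s (%s)", analysis,
                                    conditionMessage(e)), log_con)
                 NULL
               })
    }
    rows <- list(
      try_row("age_vs_median_duration",
              spearman_cor(metrics$age, metrics$median_duration_s)),
      try_row("age_vs_duration_cv",
              spearman_cor(metrics$age, metrics$duration_cv)),
      try_row("age_vs_absolute_overlap",
              spearman_cor(metrics$age, metrics$absolute_overlap)),
      try_row("age_vs_on_event_occurrence",
              spearman_cor(metrics$age, metrics$on_event_occurrence)),
      try_row("age_vs_off_event_occurrence",
              spearman_cor(metrics$age, metrics$off_event_occurrence))
    )
    if (!anyNA(metrics$iss)) {
      rows <- c(rows, list(
        try_row("age_vs_median_duration_given_iss",
                partial_spearman_cor(metrics$age, metrics$median_duration_s,
                                     metrics$iss)),
        try_row("age_vs_iss", spearman_cor(metrics$age, metrics$iss))
      ))
    }
    rows <- c(rows, list(try_row(
      "overlap_vs_zero",
      tibble(estimate = median(metrics$absolute_overlap), statistic = NA_real_,
             p.value = overlap_vs_zero_test(metrics$absolute_overlap),
             n = nrow(metrics), method = "wilcoxon signed-rank vs 0")
    )))
    tab <- dplyr::bind_rows(rows)
    write_stamped_tsv(tab, file.path(out_dir, "stats.tsv"), hash)
    tab
  })

  # --- stage: perturbation simulations ------------------------------------
  if (isTRUE(config$sims$enabled)) {
    run_stage("perturb", log_con, {
      young <- prep[[1]]$avg
      ns <- run_noise_sim(young, levels = config$sims$levels,
                          reps = config$sims$reps, k_max = config$gsbs$k_max,
                          seed = derive_seed(config$seed, 20L))
      write_sim_report(ns, out_dir)
      ss <- run_shift_sim(young, shifts = config$sims$shifts,
                          trim = config$sims$trim, k_max = config$gsbs$k_max)
      write_sim_report(ss, out_dir)
      NULL
    })
  }

  writeLines("pipeline: complete", log_con)
  close(log_con)
  jsonlite::write_json(list(config_hash = hash, complete = TRUE,
                            mode = config$mode, seed = config$seed),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, stats = stats_tab, out_dir = out_dir))
}

#' Render a human-readable markdown report of a completed run
#'
#' Tabulates the per-group metrics and statistical tests, summarises any
#' simulation reports, and prints a built-in self-check line recomputing the
#' absolute-overlap worked example (20 state boundaries, 10 event TRs, 100
#' timepoints, 8 observed).  For an incomplete run the missing stages are
#' listed instead.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path output markdown path (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
pipeline_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  needed <- c(metrics = "group_metrics.tsv", stats = "stats.tsv",
              run = "run.json")
  present <- file.exists(file.path(run_dir, needed))
  lines <- c("# Neural-state pipeline report", "")
  if (!all(present)) {
    lines <- c(lines, "**Run incomplete.** Missing stages/outputs:",
               paste0("- ", needed[!present]))
    writeLines(lines, path)
    return(invisible(path))
  }
  run <- jsonlite::read_json(file.path(run_dir, "run.json"))
  lines <- c(lines, sprintf("- config hash: `%s`", run$config_hash),
             sprintf("- mode: %s, seed: %s", run$mode, run$seed), "")

  md_table <- function(df, digits = 4) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, digits)))
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, body)
  }

  metrics <- read_stamped_tsv(file.path(run_dir, "group_metrics.tsv"))
  stats <- read_stamped_tsv(file.path(run_dir, "stats.tsv"))
  lines <- c(lines, "## Per-group metrics", "", md_table(metrics), "",
             "## Statistical tests", "", md_table(stats), "")

  for (sim in c("noise_sim", "shift_sim")) {
    fp <- file.path(run_dir, paste0(sim, ".json"))
    if (file.exists(fp)) {
      js <- jsonlite::read_json(fp, simplifyVector = TRUE)
      lines <- c(lines, sprintf("## %s", gsub("_", " ", sim)), "",
                 sprintf("baseline k = %s", js$baseline_k), "",
                 md_table(as_tibble(js$summary)), "")
    }
  }

  chk <- overlap_stat(20, 10, 100, 8)
  lines <- c(lines, "## Self-check", "",
             sprintf("Absolute overlap for (20 state boundaries, 10 event TRs, 100 TRs, 8 observed): expected = %.4f, absolute = %.4f.",
                     chk$expected, chk$absolute))
  writeLines(lines, path)
  invisible(path)
}
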