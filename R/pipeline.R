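#' Run the full simulation-to-report pipeline
#'
#' Orchestrates the four stages — simulate shaker trials, compare devices on
#' the shaker, simulate the paired-wear activity study and extract TD/FD
#' feature tables, evaluate the transfer grid — and writes every stage output
#' as plain CSV plus a run manifest and a human-readable summary. The whole
#' run is a deterministic function of the configuration and `master_seed`.
#'
#' With a single device model the shaker oracle check still runs and the
#' transfer stage is skipped with a logged notice.
#'
#' @param out_dir output directory; refuses to overwrite a non-empty
#'   directory unless `force = TRUE`.
#' @param master_seed master seed for all randomness.
#' @param devices named list of `device_model`s (1 or 2).
#' @param subjects character vector of subject ids.
#' @param models named list of `activity_model`s.
#' @param rpms shaker platform speeds.
#' @param n_trials shaker trials per speed.
#' @param window_s,use_last_s windowing parameters (see [make_windows()]).
#' @param n_trees random-forest size.
#' @param n_perm shaker permutation-test resamples.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return Invisibly, a list with `shaker` (comparison table or `NULL`),
#'   `grid`, `ztests`, and the output paths.
#' @export
run_pipeline <- function(out_dir, master_seed = 1,
                         devices = default_device_models(),
                         subjects = sprintf("S%02d", 1:8),
                         models = default_activity_models(),
                         rpms = c(40, 80, 140, 200, 240), n_trials = 10,
                         window_s = 20, use_last_s = 60,
                         n_trees = 500, n_perm = 2000, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " already contains files; use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dev_ids <- vapply(devices, function(d) d$device_id, character(1))

  message("[shaker] simulating ", length(rpms), " speeds x ", n_trials,
          " trials x ", length(devices), " devices")
  trials <- simulate_shaker_study(devices, rpms = rpms, n_trials = n_trials,
                                  master_seed = child_seed(master_seed,
                                                           "shaker"))
  shaker_tab <- NULL
  if (length(devices) >= 2) {
    shaker_tab <- shaker_comparison_table(trials, dev_ids[1], dev_ids[2],
                                          n_perm = n_perm,
                                          seed = child_seed(master_seed,
                                                            "shakerperm"))
    write.csv(shaker_tab, file.path(out_dir, "shaker_comparison.csv"),
              row.names = FALSE)
  } else {
    oracle <- data.frame(rpm = rpms, nominal_hz = nominal_hz(rpms),
                         oracle_g = centripetal_acceleration(rpms))
    write.csv(oracle, file.path(out_dir, "shaker_oracle.csv"),
              row.names = FALSE)
  }

  message("[activity] simulating ", length(subjects), " subjects x ",
          length(models), " activities x ", length(devices), " devices")
  study <- build_study(subjects = subjects, models = models,
                       devices = devices,
                       master_seed = child_seed(master_seed, "study"))
  wins <- study_windows(study, window_s = window_s, use_last_s = use_last_s)
  message("[features] ", sum(lengths(wins)), " windows")
  tables <- lapply(wins, function(w)
    list(TD = extract_table(w, "TD"), FD = extract_table(w, "FD")))
  for (d in names(tables)) {
    for (fset in c("TD", "FD")) {
      write.csv(tables[[d]][[fset]],
                file.path(out_dir, sprintf("features_%s_%s.csv", d, fset)),
                row.names = FALSE)
    }
  }

  grid <- NULL; zt <- NULL
  if (length(devices) >= 2) {
    message("[transfer] evaluating 8-cell grid")
    spec <- model_spec(n_trees = n_trees,
                       seed = child_seed(master_seed, "transfer"))
    grid <- transfer_grid(tables, spec)
    write.csv(grid$table, file.path(out_dir, "transfer_grid.csv"),
              row.names = FALSE)
    for (key in names(grid$results)) {
      cm <- grid$results[[key]]$confusion
      fname <- sprintf("confusion_%s.csv",
                       gsub("[^A-Za-z0-9]+", "_", key))
      write.csv(as.data.frame(cm$counts),
                file.path(out_dir, fname), row.names = TRUE)
    }
    zt <- transfer_ztests(grid)
    write.csv(zt, file.path(out_dir, "transfer_ztests.csv"),
              row.names = FALSE)
  } else {
    message("[transfer] skipped: only one device configured")
  }

  manifest <- c(
    sprintf("accelequiv %s", as.character(utils::packageVersion("accelequiv"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("master_seed: %d", master_seed),
    sprintf("devices: %s", paste(dev_ids, collapse = ", ")),
    sprintf("subjects: %s", paste(subjects, collapse = ", ")),
    sprintf("activities: %s",
            paste(vapply(models, function(m) m$label, character(1)),
                  collapse = ", ")),
    sprintf("rpms: %s", paste(rpms, collapse = ", ")),
    sprintf("n_trials: %d  window_s: %g  use_last_s: %g  n_trees: %d  n_perm: %d",
            n_trials, window_s, use_last_s, n_trees, n_perm))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  summary_lines <- manifest
  if (!is.null(shaker_tab)) {
    summary_lines <- c(summary_lines, "", "shaker comparison (% diff B vs A):",
      sprintf("  rpm %3d (%.1f Hz): oracle %.3f g, VM %s=%.3f %s=%.3f, diff %+.2f%%, p=%.4f",
              shaker_tab$rpm, shaker_tab$nominal_hz, shaker_tab$oracle_g,
              dev_ids[1], shaker_tab$mean_vm_a, dev_ids[2],
              shaker_tab$mean_vm_b, shaker_tab$pct_difference,
              shaker_tab$p_value))
  }
  if (!is.null(grid)) {
    summary_lines <- c(summary_lines, "", "transfer grid:",
      sprintf("  %s train %s -> test %s: %.1f%%", grid$table$feature_set,
              grid$table$train_device, grid$table$test_device,
              grid$table$accuracy))
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(shaker = shaker_tab, grid = grid, ztests = zt,
                 out_dir = out_dir))
}
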