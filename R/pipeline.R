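#' Pipeline configuration
#'
#' Everything needed to reproduce a full synthetic study: design seed,
#' cohort specification, fit options and analysis settings. Any run is
#' reproducible from the config alone; every output file records the
#' config's MD5 hash.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; stage seeds are derived from it.
#' @param cohort_spec A `cohort_spec` data frame
#'   ([dementia_cohort_spec()] by default).
#' @param fit_opts Options from [fit_options()].
#' @param control_group Label of the reference group for ROC contrasts.
#' @param roc_method `"empirical"` or `"binormal"`.
#' @param outlier_q Quantile for threshold outlier flagging.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cohort_spec = dementia_cohort_spec(),
                            fit_opts = fit_options(),
                            control_group = "Controls",
                            roc_method = c("empirical", "binormal"),
                            outlier_q = 0.975) {
  roc_method <- match.arg(roc_method)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_spec = cohort_spec, fit_opts = fit_opts,
                 control_group = control_group, roc_method = roc_method,
                 outlier_q = outlier_q, schema = "vocometrics-report-1"),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config[setdiff(names(config), "out_dir")]), tf,
                       auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Fit every listener in a trial table
#'
#' Aggregates and fits each participant's psychometric function and
#' collects the reporting-scale parameters into one table.
#'
#' @param trials A multi-participant `trial_table`.
#' @param fit_opts Options from [fit_options()].
#' @return A data frame: `participant_id`, `group`, `threshold`, `slope`,
#'   `gamma`, `lam`, `eta`, `nll`, `converged`, `threshold_defined`,
#'   `clear_prop` (proportion of clear-speech digits correct).
#' @export
fit_all_listeners <- function(trials, fit_opts = fit_options()) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    pd <- aggregate_trials(trials, id)
    fit <- fit_psychometric(pd, fit_opts)
    data.frame(participant_id = id,
               group = trials$group[match(id, trials$participant_id)],
               threshold = fit$threshold, slope = fit$slope,
               gamma = fit$gamma, lam = fit$lam, eta = fit$eta,
               nll = fit$nll, converged = fit$converged,
               threshold_defined = fit$threshold_defined,
               clear_prop = if (pd$clear_n > 0) pd$clear_k / pd$clear_n
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic study pipeline
#'
#' Builds the 100-item stimulus design, simulates the cohort's trial
#' responses, scores and fits every listener, runs the group statistics,
#' and computes ROC contrasts of each non-control group against the
#' control group on the fitted threshold. Writes `stimuli.csv`,
#' `trials.csv`, `truth.csv`, `fits.csv`, `stats.json`, `roc.json` and a
#' human-readable `summary.txt` under `config$out_dir`; each JSON report
#' carries the config hash and stage seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`design`, `sim`,
#'   `fits`, `stats`, `roc`, `paths`, `config_hash`, `n_not_converged`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  pth <- function(f) file.path(config$out_dir, f)
  seeds <- list(design = derive_seed(config$seed, "design"),
                cohort = derive_seed(config$seed, "cohort"))

  design <- build_stimulus_list(seeds$design)
  utils::write.csv(cbind(design, config_hash = hash), pth("stimuli.csv"),
                   row.names = FALSE)

  sim <- simulate_cohort(config$cohort_spec, design, seeds$cohort)
  utils::write.csv(sim$trials, pth("trials.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, pth("truth.csv"), row.names = FALSE)

  fits <- fit_all_listeners(sim$trials, config$fit_opts)
  utils::write.csv(fits, pth("fits.csv"), row.names = FALSE)
  n_nc <- sum(!fits$converged)
  if (n_nc > 0)
    warning(n_nc, " listener fit(s) flagged non-converged", call. = FALSE)

  stats_rep <- group_stats_report(fits, outlier_q = config$outlier_q)
  stats_json <- list(
    schema = config$schema, config_hash = hash, seeds = seeds,
    parameters = lapply(
      stats_rep[intersect(c("threshold", "slope", "lam", "gamma", "eta"),
                          names(stats_rep))],
      function(s) list(omnibus = unclass(s$omnibus),
                       pairwise = as.data.frame(s$pairwise))),
    threshold_outliers = stats_rep$threshold_outliers,
    underpowered = stats_rep$underpowered)
  jsonlite::write_json(stats_json, pth("stats.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)

  ctrl <- fits$threshold[fits$group == config$control_group &
                           is.finite(fits$threshold)]
  roc_list <- list()
  for (g in setdiff(unique(fits$group), config$control_group)) {
    cas <- fits$threshold[fits$group == g & is.finite(fits$threshold)]
    roc_list[[g]] <- if (length(cas) >= 2 && length(ctrl) >= 2) {
      r <- suppressWarnings(
        if (config$roc_method == "empirical") empirical_auc(cas, ctrl)
        else binormal_auc(cas, ctrl, seed = derive_seed(config$seed, "boot", g)))
      list(auc = r$auc, ci_lo = r$ci_lo, ci_hi = r$ci_hi, method = r$method,
           ci_method = r$ci_method, n_case = length(cas),
           n_control = length(ctrl))
    } else list(auc = NA, note = "group too small for ROC")
  }
  jsonlite::write_json(list(schema = config$schema, config_hash = hash,
                            classifier = "threshold", contrasts = roc_list),
                       pth("roc.json"), auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)

  writeLines(pipeline_summary(fits, stats_rep, roc_list, hash,
                              config$control_group),
             pth("summary.txt"))

  invisible(list(design = design, sim = sim, fits = fits, stats = stats_rep,
                 roc = roc_list, config_hash = hash,
                 n_not_converged = n_nc,
                 paths = vapply(c("stimuli.csv", "trials.csv", "truth.csv",
                                  "fits.csv", "stats.json", "roc.json",
                                  "summary.txt"), pth, character(1))))
}

pipeline_summary <- function(fits, stats_rep, roc_list, hash, control_group) {
  lines <- c(sprintf("Synthetic noise-vocoded speech study  [config %s]", hash),
             "", "Group-level psychometric parameters, mean (SD):",
             sprintf("  %-10s %-4s %-12s %-12s %-12s %-12s %-12s",
                     "group", "n", "threshold", "slope", "lam", "gamma", "eta"))
  msd <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                             stats::sd(v, na.rm = TRUE))
  for (g in unique(fits$group)) {
    f <- fits[fits$group == g, ]
    lines <- c(lines, sprintf("  %-10s %-4d %-12s %-12s %-12s %-12s %-12s",
                              g, nrow(f), msd(f$threshold), msd(f$slope),
                              msd(f$lam), msd(f$gamma), msd(f$eta)))
  }
  lines <- c(lines, "", "Omnibus tests (Kruskal-Wallis):")
  for (p in intersect(c("threshold", "slope", "lam", "gamma", "eta"),
                      names(stats_rep))) {
    o <- stats_rep[[p]]$omnibus
    lines <- c(lines, sprintf("  %-10s H(%d) = %6.2f, p = %.4g, eta2_H = %.3f",
                              p, o$df, o$H, o$p, o$eta2_H))
  }
  if (isTRUE(stats_rep$underpowered))
    lines <- c(lines, "", "WARNING: some groups have < 2 listeners;",
               "         statistics above are underpowered.")
  lines <- c(lines, "",
             sprintf("ROC (threshold, each group vs %s):", control_group))
  for (g in names(roc_list)) {
    r <- roc_list[[g]]
    lines <- c(lines, if (is.na(r$auc[1]))
      sprintf("  %-10s %s", g, r$note)
      else sprintf("  %-10s AUC = %.3f, 95%% CI (%.3f, %.3f)", g, r$auc,
                   r$ci_lo, r$ci_hi))
  }
  nonc <- sum(!fits$converged)
  if (nonc > 0) lines <- c(lines, "",
                           sprintf("WARNING: %d fit(s) not converged.", nonc))
  lines
}
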