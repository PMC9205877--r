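#' Run the full analysis pipeline
#'
#' End-to-end orchestration: generate the synthetic study, write its tables,
#' clean trials, run the 2x2 repeated-measures ANOVAs (cooperation, RT, and
#' the likability / total-points control analyses), the mixed-effects
#' logistic regression, the diffusion-model subject fits with group tests
#' and the cohort nested-model scan, the post-hoc and clinical correlations,
#' the affect t-tests and the paired power computation; then write a
#' markdown report and a run manifest (config hash, seed, stage timings,
#' file checksums). Any stage failure aborts with the stage name.
#'
#' @param cfg a [study_config()] configuration.
#' @param out_dir output directory (created if absent).
#' @param seed root seed.
#' @param ddm_params which diffusion parameters the cohort scan frees
#'   (default `c("z", "v")`, the two targeted by the study hypotheses; pass
#'   all seven for the complete scan).
#' @return the run manifest (list), invisibly.
#' @export
run_all <- function(cfg = study_config(), out_dir = "pddm_results", seed = 1L,
                    ddm_params = c("z", "v")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = list())
  t_all <- Sys.time()
  res <- new.env()

  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  study <- stage("simulate", function() generate_study(cfg = cfg, seed = seed))
  stage("write_tables", function() {
    write_trials(study$trials, file.path(out_dir, "trials.csv"))
    write_profiles(study$profiles, file.path(out_dir, "profiles.csv"))
    write_likability(study$likability, file.path(out_dir, "likability.csv"))
  })

  cleaned <- stage("clean", function() clean_trials(study$trials))
  utils::write.csv(cleaned$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)

  anovas <- stage("anova", function() {
    coop <- cooperation_table(cleaned$trials, "cooperation")
    rt <- cooperation_table(cleaned$trials, "rt")
    pts <- cooperation_table(cleaned$trials, "points")
    likab <- merge(study$likability,
                   unique(study$trials[, c("subject_id", "session_index",
                                           "stim_condition")]))
    lik_tab <- stats::aggregate(
      list(value = likab$sam_likability),
      by = list(subject_id = likab$subject_id,
                stim_condition = likab$stim_condition,
                opponent_class = likab$opponent_class), FUN = mean)
    out <- rbind(
      cbind(outcome = "cooperation_pct", rm_anova_2x2(coop)),
      cbind(outcome = "rt_s", rm_anova_2x2(rt)),
      cbind(outcome = "points", rm_anova_2x2(pts)),
      cbind(outcome = "likability", rm_anova_2x2(lik_tab)))
    res$coop_table <- coop
    out
  })
  utils::write.csv(anovas, file.path(out_dir, "anova.csv"), row.names = FALSE)

  mixed <- stage("mixed_model", function()
    mixed_logit_cooperation(cleaned$trials, study$profiles, study$likability,
                            r2_threshold = cfg$stats$screen_r2))
  utils::write.csv(mixed$coefficients, file.path(out_dir, "mixed_model.csv"),
                   row.names = FALSE)

  ddm <- stage("ddm", function() {
    ctrl <- fit_control(restarts = cfg$fit$restarts, reltol = cfg$fit$reltol,
                        rt_floor = cfg$fit$rt_floor_s,
                        quad_points = cfg$fit$quad_points)
    sp <- ddm_subject_params(cleaned$trials, group_col = cfg$fit$grouping,
                             control = ctrl)
    list(subject_params = sp,
         group_tests = ddm_group_tests(sp),
         scan = ddm_scan_cohort(cleaned$trials, params = ddm_params,
                                group_col = cfg$fit$grouping, control = ctrl))
  })
  utils::write.csv(ddm$subject_params, file.path(out_dir, "ddm_subject_params.csv"),
                   row.names = FALSE)
  utils::write.csv(ddm$group_tests, file.path(out_dir, "ddm_group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ddm$scan), file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)

  cors <- stage("correlations", function() {
    eff <- stimulation_effect(res$coop_table)
    pr <- study$profiles[match(eff$subject_id, study$profiles$subject_id), ]
    # a clinical covariate can be constant in a small cohort; report NA then
    safe_cor <- function(target, y, method) {
      out <- tryCatch(correlate(eff$effect, y, method),
                      error = function(e) data.frame(
                        method = method, coefficient = NA_real_, p = NA_real_,
                        n = length(y)))
      cbind(target = target, out)
    }
    rbind(
      safe_cor("neuroticism", pr$neo_neuroticism, "spearman"),
      safe_cor("extraversion", pr$neo_extraversion, "spearman"),
      safe_cor("disease_duration", pr$disease_duration, "pearson"),
      safe_cor("time_since_last_seizure", pr$time_since_last_seizure, "pearson"),
      safe_cor("affected_hemisphere",
               as.numeric(pr$affected_hemisphere == "left"), "pearson"),
      safe_cor("medicated", as.numeric(pr$medicated), "pearson"))
  })
  utils::write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)

  affect <- stage("affect", function() affect_ttests(study$profiles))
  power <- stage("power", function()
    sample_size_cooperation(cfg$stats$pilot_mean_diff, cfg$stats$pilot_sd,
                            alpha = cfg$stats$alpha, power = cfg$stats$power))
  writeLines(c(sprintf("Paired power analysis: alpha = %g, power = %g", power$alpha, power$power),
               sprintf("Pilot mean difference = %g, SD = %g", power$pilot_mean_diff, power$pilot_sd),
               sprintf("Minimum n = %d (power %.4f at n, %.4f at n-1)",
                       power$n, power$power_at_n, power$power_at_n_minus_1)),
             file.path(out_dir, "power.txt"))

  stage("report", function()
    write_report(out_dir, study, cleaned, anovas, mixed, ddm, cors, affect, power))

  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  files <- list.files(out_dir, full.names = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  manifest$files <- as.list(tools::md5sum(files[!grepl("manifest", files)]))
  names(manifest$files) <- basename(names(manifest$files))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

write_report <- function(out_dir, study, cleaned, anovas, mixed, ddm, cors,
                         affect, power) {
  fm <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  coop <- cooperation_table(cleaned$trials)
  by_cond <- tapply(coop$value, coop$stim_condition, mean)
  lines <- c(
    "# Study analysis report", "",
    sprintf("Subjects: %d; trials: %d (%d excluded as invalid); seed: %d.",
            nrow(study$profiles), nrow(study$trials),
            sum(cleaned$exclusions$n_excluded), study$seed), "",
    sprintf("Mean cooperation: tVNS %.2f%%, sham %.2f%%.",
            by_cond[["tvns"]], by_cond[["sham"]]), "",
    "## Repeated-measures ANOVAs", "",
    paste(utils::capture.output(print(anovas, row.names = FALSE)), collapse = "\n"), "",
    "## Mixed-effects logistic regression (trial-level cooperation)", "",
    sprintf("%d trials, residual df %d, subject variance %.3f; dropped predictors: %s",
            mixed$n_trials, mixed$df, mixed$subject_variance,
            if (length(mixed$screen$dropped)) paste(mixed$screen$dropped, collapse = ", ") else "none"), "",
    paste(utils::capture.output(print(mixed$coefficients, row.names = FALSE)), collapse = "\n"), "",
    "## Diffusion-model group tests", "",
    paste(utils::capture.output(print(ddm$group_tests, row.names = FALSE)), collapse = "\n"), "",
    "## Cohort nested-model comparison", "",
    paste(utils::capture.output(print(as.data.frame(ddm$scan), row.names = FALSE)), collapse = "\n"), "",
    "## Correlations of the stimulation effect", "",
    paste(utils::capture.output(print(cors, row.names = FALSE)), collapse = "\n"), "",
    "## Affect (paired t-tests)", "",
    paste(utils::capture.output(print(affect, row.names = FALSE)), collapse = "\n"), "",
    "## Power", "",
    sprintf("Minimum n for a paired test at alpha %.3g, power %.3g with pilot effect %.3g/%.3g: **%d**.",
            power$alpha, power$power, power$pilot_mean_diff, power$pilot_sd, power$n))
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(NULL)
}
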