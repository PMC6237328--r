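#' Write / read a scenario bundle
#'
#' A scenario bundle is a directory with a structured `manifest.json` (risk
#' states, diseases, kinds, causal edges, relative paths) and one long-format
#' rate CSV (`sex,age,value`) per quantity.  Values round-trip bit-identically
#' through [read_scenario_bundle()].
#'
#' @param s a valid [scenario].
#' @param dir bundle directory (created if needed).
#' @return `write_scenario_bundle`: `dir`, invisibly; `read_scenario_bundle`:
#'   a [scenario].
#' @export
write_scenario_bundle <- function(s, dir) {
  v <- validate_scenario(s)
  if (length(v)) stop("invalid scenario: ", v[1])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(t, name) {
    f <- paste0(name, ".csv")
    write_rate_table(t, file.path(dir, f))
    f
  }
  rf <- s$risk_factor
  manifest <- list(
    format = "chronicsim-scenario",
    version = as.character(utils::packageVersion("chronicsim")),
    a_max = s$a_max, cap_age = s$cap_age,
    risk_factor = list(
      states = as.list(rf$states),
      prevalence = lapply(stats::setNames(rf$states, rf$states), function(st)
        wt(rf$prevalence[[st]], paste0("risk_prevalence_", st))),
      rr_other_cause = if (!is.null(rf$rr_other_cause)) {
        lapply(stats::setNames(rf$states, rf$states), function(st)
          wt(rf$rr_other_cause[[st]], paste0("rr_other_cause_", st)))
      }
    ),
    other_cause_mortality = wt(s$other_cause_mortality, "other_cause_mortality"),
    diseases = lapply(s$diseases, function(d) {
      base <- list(
        name = d$name, kind = d$kind,
        prevalence = wt(d$prevalence, paste0(d$name, "_prevalence")),
        incidence = wt(d$incidence, paste0(d$name, "_incidence")),
        attributable_mortality = wt(d$attributable_mortality,
                                    paste0(d$name, "_attributable_mortality")),
        rr_from_risk = lapply(stats::setNames(rf$states, rf$states), function(st)
          wt(d$rr_from_risk[[st]], paste0(d$name, "_rr_risk_", st))),
        rr_from_causes = lapply(d$rr_from_causes, function(t) NULL)
      )
      if (length(d$rr_from_causes)) {
        base$rr_from_causes <- lapply(
          stats::setNames(names(d$rr_from_causes), names(d$rr_from_causes)),
          function(p) wt(d$rr_from_causes[[p]], paste0(d$name, "_rr_cause_", p)))
      } else base$rr_from_causes <- NULL
      if (d$kind == "acute") {
        base$acute_fatality <- wt(d$acute_fatality, paste0(d$name, "_acute_fatality"))
      }
      if (d$kind == "cured") {
        base$cured_fraction <- wt(d$cured_fraction, paste0(d$name, "_cured_fraction"))
      }
      base
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_scenario_bundle
#' @export
read_scenario_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  rd <- function(f, q) read_rate_table(file.path(dir, f), quantity = q)
  states <- unlist(manifest$risk_factor$states)
  prev <- lapply(stats::setNames(states, states), function(st)
    rd(manifest$risk_factor$prevalence[[st]], "risk_prevalence"))
  rr_oc <- if (!is.null(manifest$risk_factor$rr_other_cause)) {
    lapply(stats::setNames(states, states), function(st)
      rd(manifest$risk_factor$rr_other_cause[[st]], "rr_other_cause"))
  }
  diseases <- lapply(manifest$diseases, function(md) {
    args <- list(
      name = md$name, kind = md$kind,
      prevalence = rd(md$prevalence, "prevalence"),
      incidence = rd(md$incidence, "incidence"),
      attributable_mortality = rd(md$attributable_mortality, "attributable_mortality"),
      rr_from_risk = lapply(stats::setNames(states, states), function(st)
        rd(md$rr_from_risk[[st]], "rr")),
      rr_from_causes = if (length(md$rr_from_causes)) {
        lapply(md$rr_from_causes, rd, q = "rr")
      } else list()
    )
    if (md$kind == "acute") args$acute_fatality <- rd(md$acute_fatality, "acute_fatality")
    if (md$kind == "cured") args$cured_fraction <- rd(md$cured_fraction, "cured_fraction")
    do.call(disease, args)
  })
  s <- scenario(risk_factor(states, prev, rr_oc), diseases,
                rd(manifest$other_cause_mortality, "other_cause_mortality"),
                a_max = manifest$a_max, cap_age = manifest$cap_age)
  v <- validate_scenario(s)
  if (length(v)) stop("bundle in ", dir, " failed validation: ", v[1])
  s
}

#' Derive replicate seeds from a master seed
#'
#' Replicate `k` of a multi-replicate run uses the `k`-th element of the
#' stream drawn here, so any single replicate is reproducible from
#' `(master_seed, k)` alone.
#'
#' @param master_seed integer master seed.
#' @param k number of replicates.
#' @return integer vector of `k` seeds.
#' @export
replicate_seeds <- function(master_seed, k) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(2147483645L, k)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full internal-consistency validation
#'
#' End-to-end pipeline: build the exact joint initial-population distribution,
#' calibrate the baseline incidences against it, estimate the net transition
#' schedule, run `replicates` Monte-Carlo newborn cohorts with derived seeds,
#' compare each to the initial population at the report ages, and summarise
#' over replicates with confidence intervals.  The initial side of every
#' comparison is the exact joint distribution (never a sampled population),
#' so all Monte-Carlo error is attributable to the newborn cohorts.
#'
#' @param s a valid [scenario].
#' @param n_per_sex individuals per sex per cohort replicate (default 2000;
#'   500 is customary for comorbidity-focused runs).
#' @param replicates number of Monte-Carlo replicates (default 100).
#' @param report_ages ages tabulated (default 50, 65, 75, 85).
#' @param seed master seed; replicate seeds are derived via
#'   [replicate_seeds()].
#' @param out_dir optional output directory: difference tables as CSV, a
#'   machine-readable `summary.json` (max |difference| per block) and a run
#'   log with seeds, version and durations.
#' @param keep_cohorts keep the first replicate's `cohort_result` in the
#'   return value (for plotting).
#' @return a `difference_report` (see [replicate_summary()]) with extra
#'   metadata: `seeds`, `master_seed`, `n_per_sex`, `max_abs` summary, and
#'   optionally `cohort` / `joint`.
#' @export
validate_consistency <- function(s, n_per_sex = 2000, replicates = 100,
                                 report_ages = c(50, 65, 75, 85), seed = 1,
                                 out_dir = NULL, keep_cohorts = FALSE) {
  t0 <- Sys.time()
  with_stage("validate_scenario", {
    v <- validate_scenario(s)
    if (length(v)) stop(v[1])
  })
  j <- with_stage("build_joint_distribution", build_joint_distribution(s))
  cp <- with_stage("calibrate_baseline_incidence", calibrate_baseline_incidence(s, j))
  Tarr <- with_stage("estimate_net_transitions", estimate_net_transitions(s))
  kernels <- with_stage("year_kernels", year_kernels(cp))
  seeds <- replicate_seeds(seed, replicates)
  diffs <- vector("list", replicates)
  first_cohort <- NULL
  for (k in seq_len(replicates)) {
    cohort <- with_stage(sprintf("simulate_newborn_cohort[%d]", k),
                         simulate_newborn_cohort(s, cp, Tarr, n_per_sex,
                                                 seed = seeds[k], kernels = kernels))
    if (k == 1L && keep_cohorts) first_cohort <- cohort
    diffs[[k]] <- with_stage(sprintf("compare_populations[%d]", k),
                             compare_populations(j, cohort, report_ages))
  }
  report <- with_stage("replicate_summary", replicate_summary(diffs))
  report$master_seed <- seed
  report$seeds <- seeds
  report$n_per_sex <- n_per_sex
  report$report_ages <- report_ages
  report$max_abs <- list(
    risk_within_pp = max(abs(report$risk_within$mean), na.rm = TRUE),
    comorbidity = if (!is.null(report$comorbidity))
      max(abs(report$comorbidity$mean), na.rm = TRUE))
  if (keep_cohorts) {
    report$cohort <- first_cohort
    report$joint <- j
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$risk_within,
                     file.path(out_dir, "risk_within_differences.csv"),
                     row.names = FALSE)
    if (!is.null(report$comorbidity)) {
      utils::write.csv(report$comorbidity,
                       file.path(out_dir, "comorbidity_differences.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report$max_abs, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log <- c(
      sprintf("chronicsim %s", as.character(utils::packageVersion("chronicsim"))),
      sprintf("started: %s", format(t0)),
      sprintf("master seed: %d; replicates: %d; n_per_sex: %d",
              seed, replicates, n_per_sex),
      sprintf("replicate seeds: %s", paste(seeds, collapse = ", ")),
      sprintf("report ages: %s", paste(report_ages, collapse = ", ")),
      sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  report
}
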