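#' Standardised prevalence tables
#'
#' Internal accessor giving a common view of an initial population (a
#' `joint_distribution`) and a simulated newborn cohort (a `cohort_result`):
#' per (sex, age) the per-disease prevalence, the joint risk-by-disease
#' prevalence, the pairwise disease prevalence and the risk-state marginal.
#'
#' @param x a `joint_distribution` or `cohort_result`.
#' @return list of arrays.
#' @keywords internal
prevalence_tables <- function(x) UseMethod("prevalence_tables")

#' @export
prevalence_tables.cohort_result <- function(x) {
  list(risk_prev = x$risk_prev, disease_prev = x$disease_prev,
       joint_risk_disease = x$joint_risk_disease, pair_prev = x$pair_prev,
       risk_states = x$risk_states, disease_names = x$disease_names,
       a_max = x$a_max)
}

#' @export
prevalence_tables.joint_distribution <- function(x) {
  dn <- x$disease_names
  nd <- length(dn)
  states <- x$risk_states
  nr <- length(states)
  amax <- x$a_max
  ridx <- match(x$cells$risk_state, states)
  pres <- sapply(dn, function(d) x$cells[[d]] >= 1)
  if (is.null(dim(pres))) pres <- matrix(pres, ncol = nd, dimnames = list(NULL, dn))
  jr <- array(0, c(nr, nd, amax + 1L, 2L), dimnames = list(states, dn, 0:amax, SEXES))
  pair <- array(0, c(nd, nd, amax + 1L, 2L), dimnames = list(dn, dn, 0:amax, SEXES))
  risk <- array(0, c(nr, amax + 1L, 2L), dimnames = list(states, 0:amax, SEXES))
  for (sex in SEXES) {
    for (age in 0:amax) {
      m <- x$mass[, age + 1L, sex]
      risk[, age + 1L, sex] <- rowsum(m, ridx)[, 1L]
      jr[, , age + 1L, sex] <- rowsum(m * pres, ridx)
      pair[, , age + 1L, sex] <- crossprod(pres, m * pres)
    }
  }
  dis <- apply(jr, c(2, 3, 4), sum)
  list(risk_prev = risk, disease_prev = dis, joint_risk_disease = jr,
       pair_prev = pair, risk_states = states, disease_names = dn, a_max = amax)
}

#' Within-disease risk-factor distribution
#'
#' For each (sex, age, disease), the distribution of the risk-factor states
#' among those who have the disease:
#' `proportion_r = P(disease & risk state r) / P(disease)`.  Rows sum to 1
#' where the disease prevalence is positive; cells with zero prevalence are
#' reported as `NA` (undefined), never as 0.
#'
#' @param x a `joint_distribution` or `cohort_result`.
#' @param ages ages to report (default all).
#' @return data frame with columns `sex`, `age`, `disease`, `risk_state`,
#'   `proportion`.
#' @export
risk_within_disease <- function(x, ages = NULL) {
  tb <- prevalence_tables(x)
  if (is.null(ages)) ages <- 0:tb$a_max
  out <- expand.grid(risk_state = tb$risk_states, disease = tb$disease_names,
                     age = ages, sex = SEXES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prop <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    p <- tb$disease_prev[out$disease[i], as.character(out$age[i]), out$sex[i]]
    prop[i] <- if (p > 0) {
      tb$joint_risk_disease[out$risk_state[i], out$disease[i],
                            as.character(out$age[i]), out$sex[i]] / p
    } else NA_real_
  }
  out$proportion <- prop
  out[, c("sex", "age", "disease", "risk_state", "proportion")]
}

#' Comorbidity ratios
#'
#' For each (sex, age) and unordered disease pair (A, B), the ratio
#' `P_AB / (P_A * P_B)`: 1 under independence, above 1 for positive
#' association.  Undefined (NA) where `P_A * P_B = 0`.
#'
#' @param x a `joint_distribution` or `cohort_result`.
#' @param ages ages to report (default all).
#' @return data frame with columns `sex`, `age`, `disease_a`, `disease_b`,
#'   `ratio`.
#' @export
comorbidity_ratios <- function(x, ages = NULL) {
  tb <- prevalence_tables(x)
  if (is.null(ages)) ages <- 0:tb$a_max
  dn <- tb$disease_names
  if (length(dn) < 2) stop("comorbidity ratios need at least two diseases")
  pairs <- t(utils::combn(dn, 2))
  out <- expand.grid(pair = seq_len(nrow(pairs)), age = ages, sex = SEXES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$disease_a <- pairs[out$pair, 1]
  out$disease_b <- pairs[out$pair, 2]
  ratio <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    ac <- as.character(out$age[i]); sx <- out$sex[i]
    pa <- tb$disease_prev[out$disease_a[i], ac, sx]
    pb <- tb$disease_prev[out$disease_b[i], ac, sx]
    ratio[i] <- if (pa * pb > 0) {
      tb$pair_prev[out$disease_a[i], out$disease_b[i], ac, sx] / (pa * pb)
    } else NA_real_
  }
  out$ratio <- ratio
  out[, c("sex", "age", "disease_a", "disease_b", "ratio")]
}

#' Compare an initial population with a newborn cohort
#'
#' Computes the standard single-replicate difference tables: per cell the
#' within-disease risk-state proportion difference (initial minus newborn) in
#' percent points, and the plain comorbidity-ratio difference, at the report
#' ages.
#'
#' @param init the initial population (`joint_distribution`).
#' @param cohort the newborn cohort (`cohort_result`, or another
#'   `joint_distribution` for deterministic comparisons).
#' @param report_ages ages to tabulate (default 50, 65, 75, 85).
#' @param comorbidity include the comorbidity block (default: yes when there
#'   are >= 2 diseases).
#' @return list with data frames `risk_within` (columns `initial`, `newborn`,
#'   `diff_pp`) and `comorbidity` (columns `initial`, `newborn`, `diff`).
#' @export
compare_populations <- function(init, cohort, report_ages = c(50, 65, 75, 85),
                                comorbidity = NULL) {
  ti <- prevalence_tables(init)
  tc <- prevalence_tables(cohort)
  if (!identical(ti$risk_states, tc$risk_states) ||
      !identical(ti$disease_names, tc$disease_names) ||
      ti$a_max != tc$a_max) {
    stop("mismatched strata: initial population and cohort disagree on states, diseases or age range")
  }
  if (any(report_ages < 0 | report_ages > ti$a_max)) {
    stop("report_ages outside 0..a_max")
  }
  if (is.null(comorbidity)) comorbidity <- length(ti$disease_names) >= 2
  rw_i <- risk_within_disease(init, ages = report_ages)
  rw_c <- risk_within_disease(cohort, ages = report_ages)
  rw <- rw_i
  names(rw)[names(rw) == "proportion"] <- "initial"
  rw$newborn <- rw_c$proportion
  rw$diff_pp <- (rw$initial - rw$newborn) * 100
  out <- list(risk_within = rw)
  if (comorbidity) {
    cm_i <- comorbidity_ratios(init, ages = report_ages)
    cm_c <- comorbidity_ratios(cohort, ages = report_ages)
    cm <- cm_i
    names(cm)[names(cm) == "ratio"] <- "initial"
    cm$newborn <- cm_c$ratio
    cm$diff <- cm$initial - cm$newborn
    out$comorbidity <- cm
  }
  out
}

#' Replicate summary with confidence intervals
#'
#' Averages single-replicate difference tables over Monte-Carlo replicates
#' and attaches normal-approximation confidence intervals of the mean
#' (`mean +/- z * sd / sqrt(k)`), the convention for reporting
#' simulation-error uncertainty over repeated runs (default protocol: 100
#' replicates, 95% intervals).
#'
#' @param diffs list of [compare_populations()] outputs (length >= 2).
#' @param level confidence level (default 0.95).
#' @return a `difference_report`: data frames `risk_within` and (if present)
#'   `comorbidity` with columns `mean`, `lo`, `hi`, plus metadata.
#' @export
replicate_summary <- function(diffs, level = 0.95) {
  k <- length(diffs)
  if (k < 2) stop("replicate_summary needs >= 2 replicates")
  z <- stats::qnorm(1 - (1 - level) / 2)
  summarise_block <- function(block, value_col) {
    key <- diffs[[1]][[block]][setdiff(names(diffs[[1]][[block]]),
                                       c("initial", "newborn", value_col))]
    vals <- vapply(diffs, function(d) d[[block]][[value_col]],
                   numeric(nrow(key)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(key))
    m <- rowMeans(vals)
    sd <- apply(vals, 1, stats::sd)
    cbind(key, data.frame(mean = m, lo = m - z * sd / sqrt(k),
                          hi = m + z * sd / sqrt(k)))
  }
  out <- list(risk_within = summarise_block("risk_within", "diff_pp"),
              n_replicates = k, level = level)
  if (!is.null(diffs[[1]]$comorbidity)) {
    out$comorbidity <- summarise_block("comorbidity", "diff")
  }
  structure(out, class = "difference_report")
}

#' @export
print.difference_report <- function(x, ...) {
  cat(sprintf("<difference_report> %d replicates, %.0f%% CIs\n",
              x$n_replicates, 100 * x$level))
  cat(sprintf("  max |risk-within difference|: %.3f pp\n",
              max(abs(x$risk_within$mean), na.rm = TRUE)))
  if (!is.null(x$comorbidity)) {
    cat(sprintf("  max |comorbidity difference|: %.4f\n",
                max(abs(x$comorbidity$mean), na.rm = TRUE)))
  }
  invisible(x)
}

#' Plot within-disease risk distributions or comorbidity ratios by age
#'
#' Convenience figures contrasting the constructed initial population with
#' the newborn-cohort equilibrium, one panel per risk state (or disease
#' pair), colours by population, shapes by sex.  Requires ggplot2.
#'
#' @param init a `joint_distribution`.
#' @param cohort a `cohort_result`.
#' @param disease disease to plot.
#' @return a ggplot object.
#' @export
plot_risk_within_disease <- function(init, cohort, disease) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_risk_within_disease requires ggplot2")
  }
  a <- risk_within_disease(init)
  a$population <- "initial"
  b <- risk_within_disease(cohort)
  b$population <- "newborns"
  df <- rbind(a, b)
  df <- df[df$disease == disease & !is.na(df$proportion), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$proportion,
                                   colour = .data$population,
                                   linetype = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~risk_state) +
    ggplot2::labs(title = sprintf("Risk-factor distribution within %s", disease),
                  y = "proportion of diseased") +
    ggplot2::theme_minimal()
}

#' @rdname plot_risk_within_disease
#' @export
plot_comorbidity_ratios <- function(init, cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comorbidity_ratios requires ggplot2")
  }
  a <- comorbidity_ratios(init)
  a$population <- "initial"
  b <- comorbidity_ratios(cohort)
  b$population <- "newborns"
  df <- rbind(a, b)
  df <- df[!is.na(df$ratio), ]
  df$pair <- paste(df$disease_a, df$disease_b, sep = " & ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$ratio,
                                   colour = .data$population,
                                   linetype = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(y = "comorbidity ratio") +
    ggplot2::theme_minimal()
}
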