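#' Model scenarios: risk factor, diseases, mortality
#'
#' A scenario is the complete specification of one simulation setting: a
#' single categorical risk factor (e.g. never/current/former smoker), a set
#' of diseases with their hazard parameters, an at-most-one-layer causal
#' dependency graph between diseases (e.g. diabetes raising the incidence of
#' cardiovascular diseases), and a baseline other-cause mortality rate.  All
#' rate inputs are [rate_table]s on the age grid `0..a_max`.
#'
#' The first risk-factor state is the reference state: all relative risks are
#' expressed relative to it and its RR tables must be identically 1.
#'
#' @name scenario
NULL

SEXES <- c("male", "female")

#' Construct a risk factor
#'
#' @param states ordered character vector of state names (>= 1); the first is
#'   the reference state.
#' @param prevalence named list of [rate_table]s, one per state, summing to 1
#'   over states at every (sex, age).
#' @param rr_other_cause optional named list of [rate_table]s with the
#'   relative risk of each state on other-cause (non-modelled) mortality;
#'   `NULL` means no risk-factor effect on other-cause mortality (all 1).
#' @return an object of class `risk_factor`.
#' @export
risk_factor <- function(states, prevalence, rr_other_cause = NULL) {
  structure(list(states = as.character(states),
                 prevalence = prevalence[states],
                 rr_other_cause = if (!is.null(rr_other_cause)) rr_other_cause[states]),
            class = "risk_factor")
}

#' Construct a disease
#'
#' Three mortality processes are supported: `"chronic"` (a constant
#' attributable mortality rate while diseased), `"acute"` (additionally an
#' acutely-fatal incidence channel with baseline fatality rate
#' `acute_fatality`), and `"cured"` (incident cases split at diagnosis into a
#' not-cured state with attributable mortality and a cured state with none).
#'
#' @param name disease name (unique within a scenario).
#' @param kind one of `"chronic"`, `"acute"`, `"cured"`.
#' @param prevalence,incidence [rate_table]s: marginal prevalence (input to
#'   the initial-population construction) and population incidence per
#'   person-year (input to baseline-incidence calibration).
#' @param attributable_mortality [rate_table]: excess death rate while
#'   diseased (for `"cured"`, applies to the not-cured state only).
#' @param acute_fatality [rate_table], `"acute"` kind only: baseline hazard of
#'   dying acutely at incidence.
#' @param cured_fraction [rate_table] in `[0, 1]`, `"cured"` kind only:
#'   fraction of incident cases entering the cured state.
#' @param rr_from_risk named list of [rate_table]s (one per risk-factor
#'   state): relative risk of each state on this disease's incidence.
#' @param rr_from_causes named list of [rate_table]s keyed by causal-disease
#'   name: relative risk of each causal disease on this disease's incidence.
#'   Empty list for independent diseases.
#' @return an object of class `disease`.
#' @export
disease <- function(name, kind = c("chronic", "acute", "cured"),
                    prevalence, incidence, attributable_mortality,
                    acute_fatality = NULL, cured_fraction = NULL,
                    rr_from_risk, rr_from_causes = list()) {
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind,
                 prevalence = prevalence, incidence = incidence,
                 attributable_mortality = attributable_mortality,
                 acute_fatality = acute_fatality,
                 cured_fraction = cured_fraction,
                 rr_from_risk = rr_from_risk,
                 rr_from_causes = rr_from_causes),
            class = "disease")
}

#' Construct a scenario
#'
#' @param risk_factor a [risk_factor].
#' @param diseases list of [disease] objects.
#' @param other_cause_mortality [rate_table]: baseline other-cause death rate.
#' @param a_max highest simulated age (default 95).
#' @param cap_age age above which disease rate inputs are held constant
#'   (default 87); applied by the scenario generator, not re-applied here.
#' @return an object of class `scenario`.
#' @export
scenario <- function(risk_factor, diseases, other_cause_mortality,
                     a_max = 95L, cap_age = 87L) {
  names(diseases) <- vapply(diseases, `[[`, character(1), "name")
  structure(list(risk_factor = risk_factor, diseases = diseases,
                 other_cause_mortality = other_cause_mortality,
                 a_max = as.integer(a_max), cap_age = as.integer(cap_age)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d risk states (%s), %d diseases, ages 0..%d\n",
              length(x$risk_factor$states),
              paste(x$risk_factor$states, collapse = "/"),
              length(x$diseases), x$a_max))
  for (d in x$diseases) {
    dep <- names(d$rr_from_causes)
    cat(sprintf("  - %s [%s]%s\n", d$name, d$kind,
                if (length(dep)) paste0(" <- ", paste(dep, collapse = ", ")) else ""))
  }
  invisible(x)
}

## Causal-graph helpers ------------------------------------------------------

#' Causal structure of a scenario
#'
#' `causal_parents` lists, per disease, the names of its causal diseases;
#' `independent_diseases`/`dependent_diseases` partition diseases by whether
#' they have incoming causal edges; `disease_clusters` returns the connected
#' components of the (undirected) causal graph, the unit over which the
#' engine evolves joint disease states.
#'
#' @param s a [scenario].
#' @return `disease_clusters`: a list of character vectors of disease names.
#' @export
disease_clusters <- function(s) {
  nm <- names(s$diseases)
  comp <- seq_along(nm)
  names(comp) <- nm
  for (d in s$diseases) {
    for (p in names(d$rr_from_causes)) {
      a <- comp[d$name]; b <- comp[p]
      comp[comp == max(a, b)] <- min(a, b)
    }
  }
  unname(lapply(split(nm, comp), identity))
}

#' @rdname disease_clusters
#' @export
causal_parents <- function(s) {
  lapply(s$diseases, function(d) names(d$rr_from_causes))
}

#' @rdname disease_clusters
#' @export
independent_diseases <- function(s) {
  names(s$diseases)[vapply(s$diseases, function(d) length(d$rr_from_causes) == 0L, logical(1))]
}

#' @rdname disease_clusters
#' @export
dependent_diseases <- function(s) {
  setdiff(names(s$diseases), independent_diseases(s))
}

## Validation ----------------------------------------------------------------

check_table <- function(t, s, field, probab = FALSE, violations) {
  if (is.null(t)) {
    return(c(violations, sprintf("%s: missing rate table", field)))
  }
  if (a_max_of(t) != s$a_max) {
    return(c(violations, sprintf("%s: age grid 0..%d does not match a_max %d",
                                 field, a_max_of(t), s$a_max)))
  }
  m <- unclass(t)
  bad <- which(m < 0 | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    violations <- c(violations, sprintf(
      "%s: negative or non-finite value at (%s, age %d)",
      field, rownames(m)[bad[1, 1]], bad[1, 2] - 1L))
  }
  if (probab) {
    bad <- which(m > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      violations <- c(violations, sprintf(
        "%s: probability > 1 at (%s, age %d)",
        field, rownames(m)[bad[1, 1]], bad[1, 2] - 1L))
    }
  }
  violations
}

#' Validate a scenario
#'
#' Checks every structural invariant: rate tables defined on the full age
#' grid and non-negative, probabilities in `[0, 1]`, risk-state prevalences
#' summing to 1 at every (sex, age), reference-state relative risks equal to
#' 1, disease prevalence < 1, kind-specific fields present, unique disease
#' names, and the causal graph restricted to a single layer (no disease with
#' incoming causal edges has outgoing ones).
#'
#' @param s a [scenario].
#' @return character vector of human-readable violations; empty when valid.
#'   Callers should treat a non-empty result as fatal.
#' @export
validate_scenario <- function(s) {
  v <- character(0)
  rf <- s$risk_factor
  if (length(rf$states) < 1L) v <- c(v, "risk factor: needs >= 1 state")
  if (anyDuplicated(rf$states)) v <- c(v, "risk factor: duplicate state names")
  for (st in rf$states) {
    v <- check_table(rf$prevalence[[st]], s, sprintf("risk prevalence[%s]", st),
                     probab = TRUE, v)
  }
  if (all(rf$states %in% names(rf$prevalence))) {
    tot <- Reduce(`+`, lapply(rf$prevalence, unclass))
    bad <- which(abs(tot - 1) > 1e-9, arr.ind = TRUE)
    if (length(bad) && nrow(bad)) {
      v <- c(v, sprintf("risk prevalence: states sum to %.6f, not 1, at (%s, age %d)",
                        tot[bad[1, 1], bad[1, 2]], SEXES[bad[1, 1]], bad[1, 2] - 1L))
    }
  }
  if (!is.null(rf$rr_other_cause)) {
    for (st in rf$states) {
      v <- check_table(rf$rr_other_cause[[st]], s,
                       sprintf("rr_other_cause[%s]", st), probab = FALSE, v)
    }
    ref <- rf$rr_other_cause[[rf$states[1]]]
    if (!is.null(ref) && any(abs(unclass(ref) - 1) > 1e-12)) {
      v <- c(v, "rr_other_cause: reference state must have RR 1 at all ages")
    }
  }
  if (anyDuplicated(names(s$diseases))) v <- c(v, "diseases: duplicate names")
  for (d in s$diseases) {
    pfx <- sprintf("disease %s", d$name)
    v <- check_table(d$prevalence, s, paste0(pfx, ": prevalence"), TRUE, v)
    if (!is.null(d$prevalence) && any(unclass(d$prevalence) >= 1)) {
      v <- c(v, paste0(pfx, ": prevalence must be < 1 at every age"))
    }
    v <- check_table(d$incidence, s, paste0(pfx, ": incidence"), FALSE, v)
    v <- check_table(d$attributable_mortality, s,
                     paste0(pfx, ": attributable mortality"), FALSE, v)
    if (d$kind == "acute") {
      v <- check_table(d$acute_fatality, s, paste0(pfx, ": acute fatality"), FALSE, v)
    } else if (!is.null(d$acute_fatality)) {
      v <- c(v, paste0(pfx, ": acute_fatality defined for non-acute kind"))
    }
    if (d$kind == "cured") {
      v <- check_table(d$cured_fraction, s, paste0(pfx, ": cured fraction"), TRUE, v)
    } else if (!is.null(d$cured_fraction)) {
      v <- c(v, paste0(pfx, ": cured_fraction defined for non-cured kind"))
    }
    for (st in rf$states) {
      v <- check_table(d$rr_from_risk[[st]], s,
                       sprintf("%s: rr_from_risk[%s]", pfx, st), FALSE, v)
    }
    ref <- d$rr_from_risk[[rf$states[1]]]
    if (!is.null(ref) && any(abs(unclass(ref) - 1) > 1e-12)) {
      v <- c(v, paste0(pfx, ": reference risk state must have RR 1"))
    }
    for (p in names(d$rr_from_causes)) {
      if (!p %in% names(s$diseases)) {
        v <- c(v, sprintf("%s: causal disease '%s' not in scenario", pfx, p))
      } else {
        v <- check_table(d$rr_from_causes[[p]], s,
                         sprintf("%s: rr_from_causes[%s]", pfx, p), FALSE, v)
      }
    }
  }
  ## one-layer dependency: a disease with incoming edges must have no outgoing
  has_in <- names(s$diseases)[vapply(s$diseases, function(d)
    length(d$rr_from_causes) > 0L, logical(1))]
  parents <- unique(unlist(lapply(s$diseases, function(d) names(d$rr_from_causes))))
  deep <- intersect(has_in, parents)
  if (length(deep)) {
    v <- c(v, sprintf("dependency depth > 1: disease '%s' both depends on and causes other diseases",
                      deep[1]))
  }
  v
}
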