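# Hand-built toy scenarios and a small cache of expensive fixtures.
# Toys are constructed directly from the constructors (not via the synthetic
# generator) so that generator and construction bugs cannot mask each other.

toy_rt <- function(x, a_max, q = "rate") rate_table_constant(x, a_max, q)

# one categorical risk factor with constant prevalence, chronic diseases with
# constant rates; RRs per disease given as named list of per-state constants
toy_scenario <- function(a_max = 10, w = c(ref = 0.5, alt = 0.5),
                         diseases = list(d1 = list(prev = 0.1, inc = 0.02,
                                                   am = 0, rr = c(1, 1))),
                         causal = list(), oc = 0.01, kinds = NULL) {
  states <- names(w)
  prev <- lapply(w, toy_rt, a_max = a_max, q = "risk_prevalence")
  rf <- risk_factor(states, prev)
  ds <- lapply(names(diseases), function(nm) {
    d <- diseases[[nm]]
    kind <- if (!is.null(kinds[[nm]])) kinds[[nm]] else "chronic"
    rrl <- lapply(seq_along(states), function(i) toy_rt(d$rr[i], a_max, "rr"))
    names(rrl) <- states
    causes <- list()
    if (!is.null(causal[[nm]])) {
      causes <- lapply(causal[[nm]], toy_rt, a_max = a_max, q = "rr")
    }
    args <- list(name = nm, kind = kind,
                 prevalence = toy_rt(d$prev, a_max, "prevalence"),
                 incidence = toy_rt(d$inc, a_max, "incidence"),
                 attributable_mortality = toy_rt(d$am, a_max, "am"),
                 rr_from_risk = rrl, rr_from_causes = causes)
    if (kind == "acute") args$acute_fatality <- toy_rt(d$cf %||% 0.005, a_max, "cf")
    if (kind == "cured") args$cured_fraction <- toy_rt(d$cured %||% 0.4, a_max, "cured")
    do.call(disease, args)
  })
  scenario(rf, ds, toy_rt(oc, a_max, "oc"), a_max = a_max, cap_age = a_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# session-level cache for expensive shared fixtures (smoking-like pipeline)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

smoking_fixture <- function() {
  cached("smoking", {
    s <- synthetic_scenario("smoking_like", seed = 1)
    j <- build_joint_distribution(s)
    cp <- calibrate_baseline_incidence(s, j)
    Tarr <- estimate_net_transitions(s)
    kernels <- chronicsim:::year_kernels(cp)
    fw <- forward_expectation(s, cp, Tarr, kernels = kernels)
    list(s = s, j = j, cp = cp, Tarr = Tarr, kernels = kernels, fw = fw)
  })
}

causal_fixture <- function() {
  cached("causal", {
    s <- synthetic_scenario("causal_pair", seed = 1)
    j <- build_joint_distribution(s)
    cp <- calibrate_baseline_incidence(s, j)
    Tarr <- estimate_net_transitions(s)
    kernels <- chronicsim:::year_kernels(cp)
    fw <- forward_expectation(s, cp, Tarr, kernels = kernels)
    list(s = s, j = j, cp = cp, Tarr = Tarr, kernels = kernels, fw = fw)
  })
}

# minimal hand-filled cohort_result for metric formula tests
fake_cohort_result <- function(disease_prev, pair_prev, joint_risk_disease,
                               risk_states = "all", a_max = 0) {
  dn <- dimnames(disease_prev)[[1]]
  res <- list(
    alive = matrix(1, 2, a_max + 1, dimnames = list(c("male", "female"), 0:a_max)),
    risk_prev = array(1, c(length(risk_states), a_max + 1, 2),
                      dimnames = list(risk_states, 0:a_max, c("male", "female"))),
    disease_prev = disease_prev, pair_prev = pair_prev,
    joint_risk_disease = joint_risk_disease,
    disease_prev_se = disease_prev * 0,
    risk_states = risk_states, disease_names = dn, a_max = a_max,
    kind = "montecarlo", n_per_sex = 1L, seed = 1L)
  class(res) <- "cohort_result"
  res
}
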