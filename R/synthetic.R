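#' Synthetic scenario generator
#'
#' Builds fully specified, self-contained [scenario]s emulating the settings
#' used to study initial-population construction: a smoking-like risk factor
#' with strong generational prevalence patterns and high, age-varying
#' relative risks; an adiposity-like (BMI) risk factor whose development is
#' driven by physiological aging; and three reduced settings used for
#' property testing (an idealised steady-state setting, a causal disease
#' pair, and an independent disease pair).
#'
#' All rates are invented but shaped and scaled to be epidemiologically
#' plausible for a high-income population: Gompertz-like other-cause
#' mortality, near-zero chronic-disease incidence before age 20, cancer
#' relative risks of smoking that rise and then fall with age, and
#' cardiovascular relative risks that decline with age.  Disease prevalence
#' inputs are derived from the incidence and excess-mortality curves by a
#' crude alive-mass recursion, so that the marginal inputs are broadly
#' consistent with the dynamic rates.  Disease rate inputs are capped at
#' `cap_age` (default 87), emulating the sparse-data treatment of high ages.
#'
#' @param preset one of `"pearce_ideal"`, `"smoking_like"`, `"bmi_like"`,
#'   `"causal_pair"`, `"independent_pair"`.
#' @param n_diseases number of diseases (only for `smoking_like`, 1..8;
#'   default 8; the diseases are drawn in a fixed order that keeps the
#'   diabetes-like causal disease first).
#' @param seed integer; scenario parameters are mildly jittered (scales,
#'   relative-risk magnitudes) by a private RNG stream so that different
#'   seeds give different valid scenarios, identical seeds identical ones.
#' @param rr_scale,incidence_scale,excess_mortality_scale multiplicative
#'   knobs on the RR excess (RR - 1), incidence and attributable mortality.
#' @param rr_exposed constant RR of the exposed state (`pearce_ideal`).
#' @param rr_causal constant causal RR of disease A on disease B
#'   (`causal_pair`).
#' @param min_incidence_age age below which disease incidence is zero
#'   (default 20; 0 for `pearce_ideal`, whose steady state starts at birth).
#' @param a_max highest age (default 95).
#' @param cap_age cap age for disease rate inputs (default 87).
#' @param include_oc_effect if `TRUE`, the risk factor also multiplies
#'   other-cause mortality (off by default; the risk factor then acts on
#'   mortality only through the diseases).
#' @return a validated [scenario].
#' @examples
#' s <- synthetic_scenario("causal_pair", seed = 1)
#' validate_scenario(s)  # character(0)
#' @export
synthetic_scenario <- function(preset = c("pearce_ideal", "smoking_like", "bmi_like",
                                          "causal_pair", "independent_pair"),
                               n_diseases = NULL, seed = 1L,
                               rr_scale = 1, incidence_scale = 1,
                               excess_mortality_scale = 1,
                               rr_exposed = 3, rr_causal = 4,
                               min_incidence_age = NULL,
                               a_max = 95L, cap_age = 87L,
                               include_oc_effect = FALSE) {
  preset <- match.arg(preset)
  jit <- local_jitter(seed)
  s <- switch(preset,
    pearce_ideal = gen_pearce(n_diseases %||% 1L, jit, rr_exposed, rr_scale,
                              incidence_scale, min_incidence_age %||% 0L, a_max),
    smoking_like = gen_smoking(n_diseases %||% 8L, jit, rr_scale, incidence_scale,
                               excess_mortality_scale, min_incidence_age %||% 20L,
                               a_max, cap_age, include_oc_effect),
    bmi_like = gen_bmi(jit, rr_scale, incidence_scale, excess_mortality_scale,
                       min_incidence_age %||% 20L, a_max, cap_age, include_oc_effect),
    causal_pair = gen_causal_pair(jit, rr_causal, incidence_scale,
                                  excess_mortality_scale,
                                  min_incidence_age %||% 20L, a_max, cap_age),
    independent_pair = gen_independent_pair(jit, incidence_scale,
                                            excess_mortality_scale,
                                            min_incidence_age %||% 20L, a_max, cap_age)
  )
  v <- validate_scenario(s)
  if (length(v)) stop("generated scenario failed validation: ", v[1])
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## private jitter stream: does not disturb the caller's RNG state
local_jitter <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483562L) + 1L)
  function(lo = 0.9, hi = 1.1) {
    # Lehmer / Park-Miller minimal standard generator
    state <<- (state * 48271) %% 2147483647
    lo + (hi - lo) * (state / 2147483647)
  }
}

plg <- function(x) stats::plogis(x)

## smooth incidence ramp: zero strictly below min_age, full weight ~10y later
age_ramp <- function(ages, min_age) {
  if (min_age <= 0L) return(rep(1, length(ages)))
  pmin(1, pmax(0, (ages - min_age) / 10))
}

## crude alive-mass recursion giving a prevalence input consistent with the
## incidence / excess-mortality curves (other-cause mortality cancels)
derive_prevalence <- function(inc, am, a_max, acute_frac = 0) {
  prev <- matrix(0, 2, a_max + 1L)
  for (i in 1:2) {
    D <- 0; H <- 1
    for (a in 0:(a_max - 1L)) {
      prev[i, a + 1L] <- D / (D + H)
      pI <- 1 - exp(-inc[i, a + 1L])
      D2 <- D * exp(-am[i, a + 1L]) + H * pI * (1 - acute_frac)
      H2 <- H * (1 - pI)
      D <- D2; H <- H2
    }
    prev[i, a_max + 1L] <- D / (D + H)
  }
  rate_table(pmin(prev, 0.95), quantity = "prevalence")
}

rr_const_list <- function(states, values, a_max, quantity = "rr") {
  out <- lapply(seq_along(states), function(i)
    rate_table_constant(values[i], a_max, quantity))
  names(out) <- states
  out
}

gompertz_oc <- function(a_max, base = 1.5e-4, slope = 2e-5, rate = 0.088) {
  rate_table_from_fn(function(a) base + slope * exp(rate * a), a_max,
                     quantity = "other_cause_mortality")
}

## ---------------------------------------------------------------------------

gen_pearce <- function(n_diseases, jit, rr_exposed, rr_scale, incidence_scale,
                       min_age, a_max) {
  states <- c("unexposed", "exposed")
  w_exp <- 0.4 + 0.2 * (jit() - 1) # age-constant exposure near 0.4
  prev <- list(unexposed = rate_table_constant(1 - w_exp, a_max, "risk_prevalence"),
               exposed = rate_table_constant(w_exp, a_max, "risk_prevalence"))
  rf <- risk_factor(states, prev)
  diseases <- lapply(seq_len(n_diseases), function(k) {
    # cumulative population incidence held at <= 2% so the disease stays rare
    inc_scale <- min(incidence_scale, 1) * 0.02 / (a_max + 1) * (0.5 + 0.5 * k / n_diseases)
    inc <- rate_table(rbind(inc_scale * (0:a_max >= min_age),
                            inc_scale * (0:a_max >= min_age)), "incidence")
    am <- rate_table_constant(0, a_max, "attributable_mortality")
    rr <- 1 + (rr_exposed - 1) * rr_scale
    disease(sprintf("disease_%d", k), "chronic",
            prevalence = derive_prevalence(unclass(inc), unclass(am), a_max),
            incidence = inc, attributable_mortality = am,
            rr_from_risk = rr_const_list(states, c(1, rr), a_max))
  })
  scenario(rf, diseases, rate_table_constant(0.004, a_max, "other_cause_mortality"),
           a_max = a_max, cap_age = a_max)
}

## smoking-like prevalence: uptake in adolescence, generational never-share
smoking_prevalence <- function(a_max) {
  a <- 0:a_max
  ever_f <- plg((a - 17) / 2.5) * (0.68 - 0.42 * plg((a - 60) / 10))
  frac_cur_f <- 0.25 + 0.60 * plg((55 - a) / 14)
  ever_m <- plg((a - 17) / 2.5) * (0.60 + 0.14 * plg((a - 50) / 10))
  frac_cur_m <- 0.30 + 0.55 * plg((52 - a) / 13)
  never <- rbind(male = 1 - ever_m, female = 1 - ever_f)
  current <- rbind(male = ever_m * frac_cur_m, female = ever_f * frac_cur_f)
  former <- 1 - never - current
  list(never = rate_table(never, "risk_prevalence"),
       current = rate_table(current, "risk_prevalence"),
       former = rate_table(former, "risk_prevalence"))
}

## RR age-shapes; former-smoker excess is a fixed fraction of current excess
rr_declining <- function(r0, a_max, rr_scale, r_inf = 1.2) {
  rate_table_from_fn(function(a)
    1 + rr_scale * ((r_inf - 1) + (r0 - r_inf) * plg((55 - a) / 12)), a_max, "rr")
}
rr_peaked <- function(rmax, peak, width, a_max, rr_scale) {
  rate_table_from_fn(function(a)
    1 + rr_scale * (rmax - 1) * exp(-((a - peak) / width)^2), a_max, "rr")
}
rr_former_of <- function(current_rr, share = 0.45) {
  rate_table(1 + share * (unclass(current_rr) - 1), quantity = "rr")
}

shaped_incidence <- function(scale, mid, slope, a_max, min_age, cap_age) {
  a <- 0:a_max
  v <- scale * plg((a - mid) / slope) * age_ramp(a, min_age)
  v[a < min_age] <- 0
  cap_rates_above_age(rate_table(rbind(v, v), "incidence"), cap_age)
}

smoking_disease_defs <- function(jit, rr_scale, incidence_scale, am_scale,
                                 a_max, min_age, cap_age, states) {
  j <- function() jit(0.85, 1.15)
  rr1 <- rr_const_list(states, c(1, 1, 1), a_max)
  mk_rr <- function(cur) {
    list(never = rate_table_constant(1, a_max, "rr"),
         current = cur, former = rr_former_of(cur))
  }
  defs <- list(
    diabetes = list(kind = "chronic", inc = c(8e-3, 55, 12), am = 8e-3,
                    rr = NULL), # no smoking effect on the diabetes-like disease
    chd = list(kind = "acute", inc = c(1.2e-2, 60, 10), am = 2e-2,
               rr = rr_declining(3.2 * j(), a_max, rr_scale), cf = 0.25,
               causal = 2.2),
    stroke = list(kind = "acute", inc = c(9e-3, 65, 9), am = 5e-2,
                  rr = rr_declining(3.0 * j(), a_max, rr_scale), cf = 0.30,
                  causal = 2.6),
    heart_failure = list(kind = "chronic", inc = c(1.1e-2, 70, 8), am = 8e-2,
                         rr = rr_declining(2.4 * j(), a_max, rr_scale),
                         causal = 3.4),
    copd = list(kind = "chronic", inc = c(3e-3, 58, 10), am = 2e-2,
                rr = rr_peaked(11 * j(), 60, 24, a_max, rr_scale)),
    lung_cancer = list(kind = "cured", inc = c(3.2e-3, 62, 9), am = 0.25,
                       rr = rr_peaked(14 * j(), 62, 22, a_max, rr_scale),
                       cured = 0.15),
    oral_cancer = list(kind = "cured", inc = c(6e-4, 60, 11), am = 0.12,
                       rr = rr_peaked(7 * j(), 60, 25, a_max, rr_scale),
                       cured = 0.50),
    larynx_cancer = list(kind = "cured", inc = c(5e-4, 62, 11), am = 0.10,
                         rr = rr_peaked(9 * j(), 62, 24, a_max, rr_scale),
                         cured = 0.60)
  )
  lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    inc <- shaped_incidence(d$inc[1] * incidence_scale, d$inc[2], d$inc[3],
                            a_max, min_age, cap_age)
    am <- cap_rates_above_age(
      rate_table_constant(d$am * am_scale, a_max, "attributable_mortality"), cap_age)
    rr_risk <- if (is.null(d$rr)) rr1 else mk_rr(d$rr)
    causes <- if (!is.null(d$causal)) {
      list(diabetes = rate_table_from_fn(
        function(a) 1 + (d$causal - 1) * (0.7 + 0.3 * plg((70 - a) / 18)),
        a_max, "rr"))
    } else list()
    acute_frac <- if (identical(d$kind, "acute")) d$cf / (1 + d$cf) else 0
    args <- list(name = nm, kind = d$kind,
                 prevalence = cap_rates_above_age(
                   derive_prevalence(unclass(inc), unclass(am), a_max, acute_frac),
                   cap_age),
                 incidence = inc, attributable_mortality = am,
                 rr_from_risk = rr_risk, rr_from_causes = causes)
    if (identical(d$kind, "acute")) {
      args$acute_fatality <- rate_table(unclass(inc) * d$cf, "acute_fatality")
    }
    if (identical(d$kind, "cured")) {
      args$cured_fraction <- rate_table_constant(d$cured, a_max, "cured_fraction")
    }
    do.call(disease, args)
  })
}

gen_smoking <- function(n_diseases, jit, rr_scale, incidence_scale, am_scale,
                        min_age, a_max, cap_age, include_oc_effect) {
  states <- c("never", "current", "former")
  rf_prev <- smoking_prevalence(a_max)
  rr_oc <- if (include_oc_effect) {
    rr_const_list(states, c(1, 1.8, 1.3), a_max, "rr_other_cause")
  } else NULL
  rf <- risk_factor(states, rf_prev, rr_other_cause = rr_oc)
  diseases <- smoking_disease_defs(jit, rr_scale, incidence_scale, am_scale,
                                   a_max, min_age, cap_age, states)
  stopifnot(n_diseases >= 1L, n_diseases <= length(diseases))
  diseases <- diseases[seq_len(n_diseases)]
  ## drop causal edges whose parent is not retained
  kept <- vapply(diseases, `[[`, character(1), "name")
  diseases <- lapply(diseases, function(d) {
    d$rr_from_causes <- d$rr_from_causes[intersect(names(d$rr_from_causes), kept)]
    d
  })
  scenario(rf, diseases, gompertz_oc(a_max), a_max = a_max, cap_age = cap_age)
}

gen_bmi <- function(jit, rr_scale, incidence_scale, am_scale, min_age, a_max,
                    cap_age, include_oc_effect) {
  states <- c("bmi_normal", "bmi_over", "bmi_obese")
  a <- 0:a_max
  ## physiological weight gain with age, mild generational component
  normal_m <- 0.30 + 0.55 * plg((28 - a) / 12)
  normal_f <- 0.34 + 0.52 * plg((32 - a) / 13)
  obese_m <- 0.08 + 0.12 * plg((a - 50) / 15)
  obese_f <- 0.09 + 0.14 * plg((a - 52) / 15)
  prev <- list(
    bmi_normal = rate_table(rbind(normal_m, normal_f), "risk_prevalence"),
    bmi_over = rate_table(rbind(1 - normal_m - obese_m, 1 - normal_f - obese_f),
                          "risk_prevalence"),
    bmi_obese = rate_table(rbind(obese_m, obese_f), "risk_prevalence"))
  rf <- risk_factor(states, prev,
                    rr_other_cause = if (include_oc_effect)
                      rr_const_list(states, c(1, 1.1, 1.4), a_max, "rr_other_cause"))
  j <- function() jit(0.85, 1.15)
  mk_rr <- function(r_over, r_obese) {
    list(bmi_normal = rate_table_constant(1, a_max, "rr"),
         bmi_over = rate_table_from_fn(function(x)
           1 + rr_scale * (r_over - 1) * (0.55 + 0.45 * plg((60 - x) / 15)), a_max, "rr"),
         bmi_obese = rate_table_from_fn(function(x)
           1 + rr_scale * (r_obese - 1) * (0.55 + 0.45 * plg((60 - x) / 15)), a_max, "rr"))
  }
  sex_only <- function(t, sex) { # zero the other sex's rates
    m <- unclass(t); m[setdiff(SEXES, sex), ] <- 0
    rate_table(m, attr(t, "quantity"))
  }
  def <- list(
    diabetes = list(kind = "chronic", inc = c(8e-3, 55, 12), am = 8e-3,
                    rr = c(2.2, 6.0 * j())),
    chd = list(kind = "acute", inc = c(1.2e-2, 60, 10), am = 2e-2,
               rr = c(1.3, 1.8), cf = 0.25, causal = 2.2),
    stroke = list(kind = "acute", inc = c(9e-3, 65, 9), am = 5e-2,
                  rr = c(1.2, 1.6), cf = 0.30, causal = 2.6),
    heart_failure = list(kind = "chronic", inc = c(1.1e-2, 70, 8), am = 8e-2,
                         rr = c(1.4, 2.0), causal = 3.4),
    colorectal_cancer = list(kind = "cured", inc = c(2.5e-3, 62, 9), am = 0.12,
                             rr = c(1.15, 1.4), cured = 0.55),
    breast_cancer = list(kind = "cured", inc = c(3.5e-3, 55, 12), am = 0.08,
                         rr = c(1.1, 1.3), cured = 0.75, sex = "female"),
    prostate_cancer = list(kind = "cured", inc = c(3.0e-3, 66, 8), am = 0.07,
                           rr = c(1.05, 1.1), cured = 0.80, sex = "male"),
    kidney_cancer = list(kind = "cured", inc = c(7e-4, 63, 10), am = 0.15,
                         rr = c(1.3, 1.8), cured = 0.60),
    endometrial_cancer = list(kind = "cured", inc = c(8e-4, 62, 9), am = 0.08,
                              rr = c(1.5, 2.6), cured = 0.80, sex = "female"))
  diseases <- lapply(names(def), function(nm) {
    d <- def[[nm]]
    inc <- shaped_incidence(d$inc[1] * incidence_scale, d$inc[2], d$inc[3],
                            a_max, min_age, cap_age)
    if (!is.null(d$sex)) inc <- sex_only(inc, d$sex)
    am <- cap_rates_above_age(
      rate_table_constant(d$am * am_scale, a_max, "attributable_mortality"), cap_age)
    causes <- if (!is.null(d$causal)) {
      list(diabetes = rate_table_from_fn(
        function(x) 1 + (d$causal - 1) * (0.7 + 0.3 * plg((70 - x) / 18)),
        a_max, "rr"))
    } else list()
    acute_frac <- if (identical(d$kind, "acute")) d$cf / (1 + d$cf) else 0
    args <- list(name = nm, kind = d$kind,
                 prevalence = cap_rates_above_age(
                   derive_prevalence(unclass(inc), unclass(am), a_max, acute_frac),
                   cap_age),
                 incidence = inc, attributable_mortality = am,
                 rr_from_risk = mk_rr(d$rr[1], d$rr[2]),
                 rr_from_causes = causes)
    if (identical(d$kind, "acute")) {
      args$acute_fatality <- rate_table(unclass(inc) * d$cf, "acute_fatality")
    }
    if (identical(d$kind, "cured")) {
      args$cured_fraction <- rate_table_constant(d$cured, a_max, "cured_fraction")
    }
    do.call(disease, args)
  })
  scenario(rf, diseases, gompertz_oc(a_max), a_max = a_max, cap_age = cap_age)
}

gen_causal_pair <- function(jit, rr_causal, incidence_scale, am_scale,
                            min_age, a_max, cap_age) {
  states <- c("ref", "alt")
  prev <- list(ref = rate_table_constant(0.5, a_max, "risk_prevalence"),
               alt = rate_table_constant(0.5, a_max, "risk_prevalence"))
  rf <- risk_factor(states, prev)
  rr1 <- rr_const_list(states, c(1, 1), a_max)
  mk <- function(nm, scale, mid, am, causes = list()) {
    inc <- shaped_incidence(scale * incidence_scale, mid, 10, a_max, min_age, cap_age)
    amt <- rate_table_constant(am * am_scale, a_max, "attributable_mortality")
    disease(nm, "chronic",
            prevalence = derive_prevalence(unclass(inc), unclass(amt), a_max),
            incidence = inc, attributable_mortality = amt,
            rr_from_risk = rr1, rr_from_causes = causes)
  }
  a <- mk("disease_a", 7e-3, 50, 0.010)
  b <- mk("disease_b", 6e-3, 55, 0.015,
          causes = list(disease_a = rate_table_constant(rr_causal, a_max, "rr")))
  scenario(rf, list(a, b), gompertz_oc(a_max), a_max = a_max, cap_age = cap_age)
}

gen_independent_pair <- function(jit, incidence_scale, am_scale, min_age,
                                 a_max, cap_age) {
  states <- c("ref", "alt")
  prev <- list(ref = rate_table_constant(0.6, a_max, "risk_prevalence"),
               alt = rate_table_constant(0.4, a_max, "risk_prevalence"))
  rf <- risk_factor(states, prev)
  rr1 <- rr_const_list(states, c(1, 1), a_max)
  mk <- function(nm, scale, mid, am) {
    inc <- shaped_incidence(scale * incidence_scale, mid, 10, a_max, min_age, cap_age)
    amt <- rate_table_constant(am * am_scale, a_max, "attributable_mortality")
    disease(nm, "chronic",
            prevalence = derive_prevalence(unclass(inc), unclass(amt), a_max),
            incidence = inc, attributable_mortality = amt,
            rr_from_risk = rr1, rr_from_causes = list())
  }
  scenario(rf, list(mk("disease_a", 9e-3, 45, 0.010), mk("disease_b", 8e-3, 50, 0.015)),
           gompertz_oc(a_max), a_max = a_max, cap_age = cap_age)
}
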