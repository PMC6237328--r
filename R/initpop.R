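#' Solve the baseline odds of a disease from its marginal prevalence
#'
#' The initial-population construction equates the prevalence odds ratio
#' (POR) between strata to the incidence rate ratio (RR).  Given the marginal
#' prevalence `p`, stratum probabilities `w` and per-stratum RRs `rr`, the
#' baseline odds `b` (the odds of disease in the reference stratum, where all
#' RRs are 1) solves
#'
#'   sum_r  w_r * rr_r * b / (rr_r * b + 1)  =  p .
#'
#' The left-hand side is strictly increasing in `b` wherever some
#' `w_r * rr_r > 0`, so the root is unique; it is found by bracketed
#' bisection polished with Newton steps, to a residual below `tol`.
#'
#' @param p marginal prevalence, `0 <= p < 1`.
#' @param w stratum probabilities (non-negative, summing to 1).
#' @param rr per-stratum relative risks (non-negative; reference stratum 1).
#' @param tol residual tolerance (default 1e-12).
#' @return baseline odds `b >= 0`.
#' @examples
#' solve_baseline_odds(0.2, c(0.5, 0.5), c(1, 1))  # p/(1-p) = 0.25
#' @export
solve_baseline_odds <- function(p, w, rr, tol = 1e-12) {
  if (p >= 1) stop("prevalence must be < 1")
  if (p < 0) stop("prevalence must be >= 0")
  if (p == 0) return(0)
  active <- w * rr > 0
  if (!any(active)) stop("unattainable prevalence: all strata have w * rr = 0")
  if (sum(w[active]) <= p) {
    stop("unattainable prevalence: attainable mass ", sum(w[active]),
         " <= target ", p)
  }
  f <- function(b) sum(w * rr * b / (rr * b + 1))
  fp <- function(b) sum(w * rr / (rr * b + 1)^2)
  lo <- 0
  hi <- p / (1 - p)
  while (f(hi) < p) hi <- hi * 2
  b <- hi
  for (it in 1:200) {
    res <- f(b) - p
    if (abs(res) <= tol) return(b)
    if (res > 0) hi <- b else lo <- b
    step <- res / fp(b)
    b2 <- b - step
    if (!is.finite(b2) || b2 <= lo || b2 >= hi) b2 <- (lo + hi) / 2
    b <- b2
  }
  b
}

#' Conditional disease probability from baseline odds and stratum RR
#'
#' Returns `rr * b / (rr * b + 1)`, the prevalence probability of the disease
#' in a stratum with relative risk `rr` when the reference-stratum odds are
#' `b`; vectorised over `rr`.
#'
#' @param b baseline odds (`>= 0`).
#' @param rr stratum relative risk(s) (`>= 0`).
#' @return probability in `[0, 1)`.
#' @export
conditional_disease_probability <- function(b, rr) {
  rr * b / (rr * b + 1)
}

## Cell table: one row per joint (risk state x disease levels) state.
## Levels: 0 = absent; 1 = present (not-cured for "cured" kind); 2 = cured.
joint_cell_states <- function(s) {
  lv <- lapply(s$diseases, function(d) if (d$kind == "cured") 0:2 else 0:1)
  grid <- expand.grid(c(list(risk_state = s$risk_factor$states), lv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- c("risk_state", names(s$diseases))
  grid
}

#' Construct the joint risk-factor / disease distribution (POR = RR method)
#'
#' Builds, for every sex and age, the exact joint probability distribution
#' over (risk-factor state x joint disease-state vector) implied by the
#' marginal inputs and the assumption that prevalence odds ratios equal the
#' input relative risks.  Two stages:
#'
#' 1. For each independent disease (no incoming causal edge), the baseline
#'    odds are solved against the risk-state strata via
#'    [solve_baseline_odds()]; within each risk state, independent diseases
#'    are combined by conditional independence.
#' 2. Composite strata `r* = (risk state x joint state of the causal
#'    diseases)` are formed with the stage-1 masses; each dependent disease's
#'    baseline odds are re-solved against `r*`, with stratum RR equal to the
#'    risk-state RR times the product of the RRs of its causal diseases that
#'    are present.
#'
#' Diseases with a cured fraction have their "present" mass split into
#' not-cured and cured parts by the age-specific cured fraction.
#'
#' By construction, risk-state marginals are recovered exactly, disease
#' marginals to solver tolerance, and every within-stratum prevalence odds
#' ratio equals the input RR product exactly.
#'
#' @param s a valid [scenario] (checked with [validate_scenario()]).
#' @param sexes,ages strata to build (defaults: both sexes, all ages).
#' @return an object of class `joint_distribution` with elements `cells`
#'   (data frame: `risk_state` plus one level column per disease), `mass`
#'   (array cells x ages x sexes), and scenario metadata.
#' @export
build_joint_distribution <- function(s, sexes = SEXES, ages = 0:s$a_max) {
  v <- validate_scenario(s)
  if (length(v)) stop("invalid scenario: ", v[1])
  cells <- joint_cell_states(s)
  mass <- array(NA_real_, dim = c(nrow(cells), s$a_max + 1L, 2L),
                dimnames = list(NULL, 0:s$a_max, SEXES))
  for (sex in sexes) {
    for (age in ages) {
      mass[, age + 1L, sex] <- joint_mass_age(s, cells, sex, age)
    }
  }
  new_joint(s, cells, mass)
}

new_joint <- function(s, cells, mass) {
  structure(list(cells = cells, mass = mass,
                 risk_states = s$risk_factor$states,
                 disease_names = names(s$diseases),
                 disease_kinds = vapply(s$diseases, `[[`, character(1), "kind"),
                 a_max = s$a_max),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("<joint_distribution> %d cells (%d risk states x %d diseases), ages 0..%d\n",
              nrow(x$cells), length(x$risk_states), length(x$disease_names), x$a_max))
  invisible(x)
}

## per-(sex, age) cell masses; the workhorse of the two-stage construction
joint_mass_age <- function(s, cells, sex, age) {
  rf <- s$risk_factor
  states <- rf$states
  nr <- length(states)
  w <- vapply(rf$prevalence, rt_value, numeric(1), sex = sex, age = age)
  dn <- names(s$diseases)
  indep <- independent_diseases(s)
  dep <- setdiff(dn, indep)
  causal <- unique(unlist(lapply(s$diseases, function(d) names(d$rr_from_causes))))

  ## stage 1: P(disease | risk state) for independent diseases
  pc <- matrix(0, length(indep), nr, dimnames = list(indep, states))
  for (i in indep) {
    d <- s$diseases[[i]]
    rr <- vapply(d$rr_from_risk, rt_value, numeric(1), sex = sex, age = age)
    p <- rt_value(d$prevalence, sex, age)
    b <- tryCatch(solve_baseline_odds(p, w, rr),
                  error = function(e) stop(sprintf(
                    "disease %s at (%s, age %d): %s", i, sex, age, conditionMessage(e)),
                    call. = FALSE))
    pc[i, ] <- conditional_disease_probability(b, rr)
  }

  ## stage 2: P(dependent disease | r, causal states) on composite strata r*
  pdep <- list()
  if (length(dep)) {
    cgrid <- as.matrix(expand.grid(rep(list(0:1), length(causal))))
    colnames(cgrid) <- causal
    ## stratum weights w*(r, c) from stage-1 conditionals
    wstar <- matrix(0, nr, nrow(cgrid))
    for (r in seq_len(nr)) {
      pr <- pc[causal, r]
      wstar[r, ] <- w[r] * apply(cgrid, 1, function(cv)
        prod(ifelse(cv == 1, pr, 1 - pr)))
    }
    for (k in dep) {
      d <- s$diseases[[k]]
      rr_r <- vapply(d$rr_from_risk, rt_value, numeric(1), sex = sex, age = age)
      rr_c <- vapply(d$rr_from_causes, rt_value, numeric(1), sex = sex, age = age)
      ## RR per (r, c) stratum: risk RR times product over present parents
      rrmat <- outer(rr_r, apply(cgrid, 1, function(cv) {
        pr <- rr_c[intersect(names(rr_c), causal[cv == 1])]
        prod(pr)
      }))
      p <- rt_value(d$prevalence, sex, age)
      b <- tryCatch(solve_baseline_odds(p, as.vector(wstar), as.vector(rrmat)),
                    error = function(e) stop(sprintf(
                      "disease %s at (%s, age %d): %s", k, sex, age,
                      conditionMessage(e)), call. = FALSE))
      pdep[[k]] <- conditional_disease_probability(b, rrmat) # nr x ncgrid
    }
  }

  ## assemble cell masses
  ridx <- match(cells$risk_state, states)
  m <- w[ridx]
  for (i in indep) {
    d <- s$diseases[[i]]
    lev <- cells[[i]]
    p <- pc[i, ridx]
    if (d$kind == "cured") {
      f <- rt_value(d$cured_fraction, sex, age)
      m <- m * ifelse(lev == 0, 1 - p, ifelse(lev == 1, p * (1 - f), p * f))
    } else {
      m <- m * ifelse(lev == 1, p, 1 - p)
    }
  }
  if (length(dep)) {
    ## stratum column index per cell from the causal diseases' presence
    cpow <- 2^(seq_along(causal) - 1L)
    cidx <- 1L
    if (length(causal)) {
      pres <- sapply(causal, function(j) as.integer(cells[[j]] >= 1))
      if (is.null(dim(pres))) pres <- matrix(pres, ncol = length(causal))
      cidx <- as.integer(pres %*% cpow) + 1L
    }
    for (k in dep) {
      d <- s$diseases[[k]]
      lev <- cells[[k]]
      p <- pdep[[k]][cbind(ridx, cidx)]
      if (d$kind == "cured") {
        f <- rt_value(d$cured_fraction, sex, age)
        m <- m * ifelse(lev == 0, 1 - p, ifelse(lev == 1, p * (1 - f), p * f))
      } else {
        m <- m * ifelse(lev == 1, p, 1 - p)
      }
    }
  }
  m
}

#' Independence-baseline joint distribution
#'
#' The comparator construction: the plain product of all marginals, removing
#' every association between the risk factor and the diseases and between
#' diseases.
#'
#' @param s a valid [scenario].
#' @return a `joint_distribution`.
#' @export
independence_baseline <- function(s) {
  v <- validate_scenario(s)
  if (length(v)) stop("invalid scenario: ", v[1])
  cells <- joint_cell_states(s)
  mass <- array(NA_real_, dim = c(nrow(cells), s$a_max + 1L, 2L),
                dimnames = list(NULL, 0:s$a_max, SEXES))
  ridx <- match(cells$risk_state, s$risk_factor$states)
  for (sex in SEXES) {
    for (age in 0:s$a_max) {
      w <- vapply(s$risk_factor$prevalence, rt_value, numeric(1),
                  sex = sex, age = age)
      m <- w[ridx]
      for (i in names(s$diseases)) {
        d <- s$diseases[[i]]
        lev <- cells[[i]]
        p <- rt_value(d$prevalence, sex, age)
        if (d$kind == "cured") {
          f <- rt_value(d$cured_fraction, sex, age)
          m <- m * ifelse(lev == 0, 1 - p, ifelse(lev == 1, p * (1 - f), p * f))
        } else {
          m <- m * ifelse(lev == 1, p, 1 - p)
        }
      }
      mass[, age + 1L, sex] <- m
    }
  }
  new_joint(s, cells, mass)
}

#' Marginals of a joint distribution
#'
#' `joint_risk_marginals` returns the risk-state marginal per (sex, age);
#' `joint_disease_marginals` the marginal prevalence of each disease (a
#' cured-kind disease counts as present in both its not-cured and cured
#' states).
#'
#' @param j a `joint_distribution`.
#' @return a 3-d array (state or disease) x age x sex.
#' @export
joint_risk_marginals <- function(j) {
  ridx <- match(j$cells$risk_state, j$risk_states)
  out <- array(0, dim = c(length(j$risk_states), j$a_max + 1L, 2L),
               dimnames = list(j$risk_states, 0:j$a_max, SEXES))
  for (sex in SEXES) {
    out[, , sex] <- rowsum(j$mass[, , sex], ridx)
  }
  out
}

#' @rdname joint_risk_marginals
#' @export
joint_disease_marginals <- function(j) {
  out <- array(0, dim = c(length(j$disease_names), j$a_max + 1L, 2L),
               dimnames = list(j$disease_names, 0:j$a_max, SEXES))
  for (d in j$disease_names) {
    pres <- j$cells[[d]] >= 1
    for (sex in SEXES) {
      out[d, , sex] <- colSums(j$mass[pres, , sex, drop = FALSE])
    }
  }
  out
}

#' Prevalence odds ratios implied by a joint distribution
#'
#' For one disease at one (sex, age), the POR of each risk stratum versus the
#' reference stratum, computed from the cell masses.  Under the POR = RR
#' construction these equal the input RRs exactly.
#'
#' @param j a `joint_distribution`.
#' @param disease disease name.
#' @param sex,age stratum.
#' @return named vector of PORs (reference state first, = 1).
#' @export
joint_por <- function(j, disease, sex, age) {
  m <- j$mass[, age + 1L, sex]
  pres <- j$cells[[disease]] >= 1
  ridx <- j$cells$risk_state
  odds <- vapply(j$risk_states, function(r) {
    p1 <- sum(m[pres & ridx == r])
    p0 <- sum(m[!pres & ridx == r])
    p1 / p0
  }, numeric(1))
  odds / odds[1]
}

#' Sample a discrete initial population from a joint distribution
#'
#' Risk states are assigned by quota: `floor(n * mass)` individuals per risk
#' state, the remainder drawn from the residual distribution.  Disease states
#' are then drawn per individual from the conditional cell distribution given
#' the assigned risk state.  Deterministic given `seed`.
#'
#' @param j a `joint_distribution`.
#' @param n_per_stratum individuals per (sex, age) stratum.
#' @param seed integer RNG seed.
#' @param sexes,ages strata to sample.
#' @return a data frame (class `population`) with columns `sex`, `age`,
#'   `risk_state`, one level column per disease, and `alive`.
#' @export
sample_initial_population <- function(j, n_per_stratum, seed,
                                      sexes = SEXES, ages = 0:j$a_max) {
  stopifnot(n_per_stratum >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ridx <- match(j$cells$risk_state, j$risk_states)
  out <- vector("list", length(sexes) * length(ages))
  k <- 0L
  for (sex in sexes) {
    for (age in ages) {
      m <- j$mass[, age + 1L, sex]
      if (anyNA(m)) {
        stop(sprintf("joint distribution not built for (%s, age %d)", sex, age))
      }
      wr <- rowsum(m, ridx)[, 1]
      quota <- floor(n_per_stratum * wr)
      resid <- n_per_stratum * wr - quota
      extra <- n_per_stratum - sum(quota)
      counts <- quota
      if (extra > 0) {
        pick <- sample.int(length(wr), extra, replace = TRUE,
                           prob = if (sum(resid) > 0) resid else wr)
        counts <- quota + tabulate(pick, nbins = length(wr))
      }
      rows <- integer(0)
      for (r in seq_along(j$risk_states)) {
        if (counts[r] == 0) next
        in_r <- which(ridx == r)
        rows <- c(rows, sample(in_r, counts[r], replace = TRUE, prob = m[in_r]))
      }
      df <- j$cells[rows, , drop = FALSE]
      df <- cbind(sex = sex, age = age, df, alive = TRUE)
      k <- k + 1L
      out[[k]] <- df
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  class(res) <- c("population", "data.frame")
  res
}

#' Write a joint distribution as a long CSV
#'
#' Columns: `sex`, `age`, `risk_state`, one level column per disease, `mass`.
#'
#' @param j a `joint_distribution`.
#' @param path output file.
#' @export
write_joint_distribution <- function(j, path) {
  parts <- list()
  for (sex in SEXES) {
    for (age in 0:j$a_max) {
      df <- j$cells
      df <- cbind(sex = sex, age = age, df, mass = j$mass[, age + 1L, sex])
      parts[[length(parts) + 1L]] <- df
    }
  }
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
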