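#' Baseline-incidence calibration
#'
#' The population incidence input is the incidence rate observed in the
#' at-risk (disease-free) population.  The per-year hazard model multiplies a
#' baseline incidence by the relative risks of the risk-factor state and of
#' any causal diseases present, so the baseline must be calibrated against
#' the composition of the initial population: for disease `i` at each
#' (sex, age),
#'
#'   I_0,i = I_pop,i / sum_s w'_s * RRprod_s ,
#'
#' where `s` runs over the joint (risk state x causal-disease state) strata
#' and `w'` is the joint-distribution mass renormalised among those currently
#' without disease `i`.  Applying the hazard model with this baseline to the
#' initial population reproduces the input population incidence in the first
#' simulated year.
#'
#' @param s a valid [scenario].
#' @param j the `joint_distribution` built from `s` (the initial population
#'   in exact form).
#' @return an object of class `calibrated_parameters`: the scenario plus a
#'   per-disease baseline-incidence table.
#' @export
calibrate_baseline_incidence <- function(s, j) {
  amax <- s$a_max
  cells <- j$cells
  ridx <- match(cells$risk_state, s$risk_factor$states)
  out <- list()
  for (i in names(s$diseases)) {
    d <- s$diseases[[i]]
    free <- cells[[i]] == 0
    parents <- names(d$rr_from_causes)
    I0 <- matrix(0, 2L, amax + 1L, dimnames = list(SEXES, 0:amax))
    for (sex in SEXES) {
      for (age in 0:amax) {
        ipop <- rt_value(d$incidence, sex, age)
        if (ipop == 0) next
        rr_r <- vapply(d$rr_from_risk, rt_value, numeric(1), sex = sex, age = age)
        rrv <- rr_r[ridx[free]]
        for (p in parents) {
          rp <- rt_value(d$rr_from_causes[[p]], sex, age)
          rrv <- rrv * ifelse(cells[[p]][free] >= 1, rp, 1)
        }
        m <- j$mass[free, age + 1L, sex]
        denom <- sum(m * rrv)
        if (denom <= 0) {
          stop(sprintf("incidence unattainable for disease %s at (%s, age %d)",
                       i, sex, age))
        }
        I0[sex, age + 1L] <- ipop * sum(m) / denom
      }
    }
    out[[i]] <- I0
  }
  structure(list(scenario = s, baseline_incidence = out),
            class = "calibrated_parameters")
}

#' Hazard model: incidence and mortality rates
#'
#' `incidence_rate` returns the incidence hazard of one disease given the
#' risk-factor state and the states of its causal diseases:
#' `I_0 * RR_risk * prod(RR_causal[present])`.  `mortality_rate` returns the
#' total death hazard given the full disease-state vector: baseline
#' other-cause mortality times the risk-state RR, plus the attributable
#' mortality of each disease present (zero for cured copies), plus, for each
#' acutely-fatal disease not currently present, its acute-fatality hazard
#' `M_0,CF * RR_risk * prod(RR_causal[present])` (acute fatality models
#' instantly fatal incident cases, so it applies to the still-disease-free).
#'
#' @param cp [calibrate_baseline_incidence()] output.
#' @param disease disease name.
#' @param r risk-state name.
#' @param C named logical/0-1 vector over causal diseases (presence); may be
#'   empty or cover any superset of the disease's parents.
#' @param D named integer vector of disease levels (0 absent, 1 present /
#'   not-cured, 2 cured) over all diseases of the scenario.
#' @param sex,age stratum.
#' @return hazard (per person-year).
#' @export
incidence_rate <- function(cp, disease, r, C, sex, age) {
  s <- cp$scenario
  d <- s$diseases[[disease]]
  rate <- cp$baseline_incidence[[disease]][sex, age + 1L] *
    rt_value(d$rr_from_risk[[r]], sex, age)
  for (p in names(d$rr_from_causes)) {
    if (isTRUE(C[[p]] >= 1)) rate <- rate * rt_value(d$rr_from_causes[[p]], sex, age)
  }
  rate
}

#' @rdname incidence_rate
#' @export
mortality_rate <- function(cp, r, D, sex, age) {
  s <- cp$scenario
  oc <- rt_value(s$other_cause_mortality, sex, age)
  if (!is.null(s$risk_factor$rr_other_cause)) {
    oc <- oc * rt_value(s$risk_factor$rr_other_cause[[r]], sex, age)
  }
  rate <- oc
  for (i in names(s$diseases)) {
    d <- s$diseases[[i]]
    li <- D[[i]]
    if (li == 1) rate <- rate + rt_value(d$attributable_mortality, sex, age)
    if (d$kind == "acute" && li == 0) {
      cf <- rt_value(d$acute_fatality, sex, age) *
        rt_value(d$rr_from_risk[[r]], sex, age)
      for (p in names(d$rr_from_causes)) {
        if (isTRUE(D[[p]] >= 1)) cf <- cf * rt_value(d$rr_from_causes[[p]], sex, age)
      }
      rate <- rate + cf
    }
  }
  rate
}

## ---------------------------------------------------------------------------
## Cluster machinery: diseases evolve jointly within each connected component
## of the causal graph; across clusters the hazards are additive, so the
## within-year exponential factorises exactly over clusters.

#' Joint state table of a disease cluster
#'
#' @param s a [scenario].
#' @param members character vector of disease names forming one cluster.
#' @return data frame with one level column per member (0 absent, 1 present /
#'   not-cured, 2 cured); the first row is the all-absent state.
#' @export
cluster_state_table <- function(s, members) {
  lv <- lapply(s$diseases[members], function(d) if (d$kind == "cured") 0:2 else 0:1)
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- members
  grid
}

## Continuous-time generator over the cluster's joint alive states + dead.
cluster_generator <- function(cp, members, cst, r, sex, age, oc_rate = 0) {
  s <- cp$scenario
  n <- nrow(cst)
  sizes <- vapply(members, function(i)
    if (s$diseases[[i]]$kind == "cured") 3L else 2L, integer(1))
  stride <- c(1L, cumprod(sizes))[seq_along(members)]
  idx_of <- function(lev) 1L + as.integer(sum(lev * stride))
  Q <- matrix(0, n + 1L, n + 1L)
  for (si in seq_len(n)) {
    lev <- as.integer(cst[si, ])
    names(lev) <- members
    death <- oc_rate
    for (i in members) {
      d <- s$diseases[[i]]
      li <- lev[[i]]
      if (li == 1L) death <- death + rt_value(d$attributable_mortality, sex, age)
      if (li == 0L) {
        rr <- rt_value(d$rr_from_risk[[r]], sex, age)
        for (p in names(d$rr_from_causes)) {
          if (lev[[p]] >= 1L) rr <- rr * rt_value(d$rr_from_causes[[p]], sex, age)
        }
        lam <- cp$baseline_incidence[[i]][sex, age + 1L] * rr
        if (lam < 0) stop("negative incidence rate")
        if (d$kind == "cured") {
          f <- rt_value(d$cured_fraction, sex, age)
          lev1 <- lev; lev1[[i]] <- 1L
          lev2 <- lev; lev2[[i]] <- 2L
          Q[si, idx_of(lev1)] <- Q[si, idx_of(lev1)] + lam * (1 - f)
          Q[si, idx_of(lev2)] <- Q[si, idx_of(lev2)] + lam * f
        } else {
          lev1 <- lev; lev1[[i]] <- 1L
          Q[si, idx_of(lev1)] <- Q[si, idx_of(lev1)] + lam
          if (d$kind == "acute") {
            death <- death + rt_value(d$acute_fatality, sex, age) * rr
          }
        }
      }
    }
    if (death < 0) stop("negative mortality rate")
    Q[si, n + 1L] <- death
    Q[si, si] <- -(sum(Q[si, ]) - Q[si, si])
  }
  Q
}

## one-year transition matrix (alive states + dead) by exact exponential
cluster_year_matrix <- function(cp, members, cst, r, sex, age, oc_rate = 0) {
  Q <- cluster_generator(cp, members, cst, r, sex, age, oc_rate)
  as.matrix(Matrix::expm(Matrix::Matrix(Q)))
}

#' Evolve a disease-cluster state by one year
#'
#' Advances a probability mass over the joint states of one disease cluster
#' (plus an absorbed dead channel) through one year of age, using the exact
#' exponential of the piecewise-constant competing-risk generator: incidence
#' transitions (with the acute-fatal split into an instantly-fatal hazard and
#' the cured-fraction split at diagnosis) and additive death hazards.  The
#' risk-factor state is held at its start-of-year value.
#'
#' @param cp [calibrate_baseline_incidence()] output.
#' @param members disease names of the cluster.
#' @param state numeric vector of masses over `nrow(cluster_state_table())`
#'   alive states followed by one dead state; conserved within 1e-10.
#' @param r risk-state name; @param sex,age stratum.
#' @param oc_rate additional uniform death hazard (other-cause mortality) to
#'   include in this cluster's generator; the cohort simulators keep it at 0
#'   and account for the shared other-cause hazard exactly once globally.
#' @return evolved state vector.
#' @export
evolve_cluster_year <- function(cp, members, state, r, sex, age, oc_rate = 0) {
  cst <- cluster_state_table(cp$scenario, members)
  if (length(state) != nrow(cst) + 1L) {
    stop("state must have length #cluster-states + 1 (dead)")
  }
  P <- cluster_year_matrix(cp, members, cst, r, sex, age, oc_rate)
  as.vector(state %*% P)
}

## Precompute all per-year kernels: for each (sex, age, risk state, cluster)
## the alive-to-alive one-year matrix (without other-cause mortality), and
## the scalar other-cause survival factor.
year_kernels <- function(cp) {
  s <- cp$scenario
  clusters <- disease_clusters(s)
  csts <- lapply(clusters, cluster_state_table, s = s)
  sizes <- vapply(csts, nrow, integer(1))
  states <- s$risk_factor$states
  amax <- s$a_max
  P <- vector("list", 2L); names(P) <- SEXES
  ocfac <- array(1, dim = c(2L, amax + 1L, length(states)),
                 dimnames = list(SEXES, 0:amax, states))
  for (sex in SEXES) {
    P[[sex]] <- vector("list", amax + 1L)
    for (age in 0:amax) {
      byr <- vector("list", length(states))
      for (r in seq_along(states)) {
        byr[[r]] <- lapply(seq_along(clusters), function(c)
          cluster_year_matrix(cp, clusters[[c]], csts[[c]], states[r], sex, age))
        oc <- rt_value(s$other_cause_mortality, sex, age)
        if (!is.null(s$risk_factor$rr_other_cause)) {
          oc <- oc * rt_value(s$risk_factor$rr_other_cause[[states[r]]], sex, age)
        }
        ocfac[sex, age + 1L, r] <- exp(-oc)
      }
      P[[sex]][[age + 1L]] <- byr
    }
  }
  structure(list(clusters = clusters, csts = csts, sizes = sizes,
                 P = P, ocfac = ocfac), class = "year_kernels")
}

## presence bookkeeping shared by both engines
presence_info <- function(s, kernels) {
  clusters <- kernels$clusters
  csts <- kernels$csts
  dn <- names(s$diseases)
  cl_of <- integer(length(dn)); names(cl_of) <- dn
  pres_cols <- vector("list", length(dn)); names(pres_cols) <- dn
  for (c in seq_along(clusters)) {
    for (d in clusters[[c]]) {
      cl_of[d] <- c
      pres_cols[[d]] <- which(csts[[c]][[d]] >= 1)
    }
  }
  list(cl_of = cl_of, pres_cols = pres_cols)
}

#' Deterministic forward recursion of a newborn cohort
#'
#' Evolves the full joint distribution over (risk state x all-disease joint
#' state, plus dead) per sex from a disease-free birth cohort, composing the
#' net-transition matrices with the exact within-year disease/mortality
#' evolution.  No randomness: this is the deterministic twin of
#' [simulate_newborn_cohort()], exact because all hazards depend only on the
#' current (risk state, disease state); it serves as the Monte-Carlo oracle.
#'
#' @param s a valid [scenario].
#' @param cp calibrated parameters for `s`.
#' @param Tarr a `transition_schedule` from [estimate_net_transitions()].
#' @param kernels optional precomputed kernels (reused across runs).
#' @param max_states guard on the tracked joint state-space size
#'   (risk states x product of cluster sizes); exceeding it errors with
#'   advice to factorise clusters further.
#' @return a `cohort_result` with per-(sex, age) alive mass, risk-state and
#'   disease prevalences, joint risk-by-disease prevalences and pairwise
#'   disease prevalences among the alive.
#' @export
forward_expectation <- function(s, cp, Tarr, kernels = NULL, max_states = 50000) {
  if (is.null(kernels)) kernels <- year_kernels(cp)
  states <- s$risk_factor$states
  nr <- length(states)
  sizes <- kernels$sizes
  nD <- prod(sizes)
  if (nr * nD > max_states) {
    stop(sprintf("joint state space %d exceeds max_states=%d; factorise disease clusters",
                 nr * nD, max_states))
  }
  info <- presence_info(s, kernels)
  dn <- names(s$diseases)
  nd <- length(dn)
  amax <- s$a_max
  ## presence indicator over joint disease combos
  pres <- matrix(FALSE, nD, nd, dimnames = list(NULL, dn))
  for (d in dn) {
    c <- info$cl_of[d]
    in_cols <- info$pres_cols[[d]]
    before <- if (c > 1) prod(sizes[seq_len(c - 1L)]) else 1L
    within <- rep(seq_len(sizes[c]) %in% in_cols, each = before)
    pres[, d] <- rep(within, length.out = nD)
  }
  res <- empty_cohort_result(s, kind = "deterministic")
  for (sex in SEXES) {
    mu <- matrix(0, nr, nD)
    w0 <- vapply(s$risk_factor$prevalence, rt_value, numeric(1), sex = sex, age = 0)
    mu[, 1L] <- w0
    dead <- 0
    for (age in 0:amax) {
      res <- record_expectation(res, mu, dead, pres, sex, age)
      if (age == amax) break
      for (r in seq_len(nr)) {
        v <- mu[r, ]
        for (c in seq_along(sizes)) {
          P <- kernels$P[[sex]][[age + 1L]][[r]][[c]]
          v <- apply_along_dim(v, sizes, c, P[seq_len(sizes[c]), seq_len(sizes[c]), drop = FALSE])
        }
        mu[r, ] <- v * kernels$ocfac[sex, age + 1L, r]
      }
      dead <- 1 - sum(mu)
      mu <- crossprod(Tarr[, , age + 1L, sex], mu)
    }
  }
  res
}

## apply cluster transition P along dimension k of a joint vector
apply_along_dim <- function(v, sizes, k, P) {
  K <- length(sizes)
  if (K == 1L) return(as.vector(crossprod(P, v)))
  perm <- c(k, setdiff(seq_len(K), k))
  arr <- array(v, sizes)
  m <- matrix(aperm(arr, perm), nrow = sizes[k])
  m2 <- crossprod(P, m)
  as.vector(aperm(array(m2, dim = sizes[perm]), order(perm)))
}

empty_cohort_result <- function(s, kind, n_per_sex = NA_integer_, seed = NA_integer_) {
  dn <- names(s$diseases)
  states <- s$risk_factor$states
  amax <- s$a_max
  structure(list(
    alive = matrix(NA_real_, 2L, amax + 1L, dimnames = list(SEXES, 0:amax)),
    risk_prev = array(NA_real_, c(length(states), amax + 1L, 2L),
                      dimnames = list(states, 0:amax, SEXES)),
    disease_prev = array(NA_real_, c(length(dn), amax + 1L, 2L),
                         dimnames = list(dn, 0:amax, SEXES)),
    joint_risk_disease = array(NA_real_, c(length(states), length(dn), amax + 1L, 2L),
                               dimnames = list(states, dn, 0:amax, SEXES)),
    pair_prev = array(NA_real_, c(length(dn), length(dn), amax + 1L, 2L),
                      dimnames = list(dn, dn, 0:amax, SEXES)),
    disease_prev_se = array(0, c(length(dn), amax + 1L, 2L),
                            dimnames = list(dn, 0:amax, SEXES)),
    risk_states = states, disease_names = dn, a_max = amax,
    kind = kind, n_per_sex = n_per_sex, seed = seed),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s, %d diseases, ages 0..%d%s\n", x$kind,
              length(x$disease_names), x$a_max,
              if (!is.na(x$n_per_sex)) sprintf(", n/sex = %d", x$n_per_sex) else ""))
  invisible(x)
}

record_expectation <- function(res, mu, dead, pres, sex, age) {
  alive <- sum(mu)
  res$alive[sex, age + 1L] <- alive
  res$risk_prev[, age + 1L, sex] <- rowSums(mu) / alive
  jr <- mu %*% pres
  res$joint_risk_disease[, , age + 1L, sex] <- jr / alive
  res$disease_prev[, age + 1L, sex] <- colSums(jr) / alive
  mtot <- colSums(mu)
  res$pair_prev[, , age + 1L, sex] <- crossprod(pres, mtot * pres) / alive
  res
}

#' Simulate risk-factor biographies
#'
#' Draws risk-state paths from the age-0 prevalence and a transition
#' schedule: `r(0)` from the age-0 risk-factor prevalence, then
#' `r(a+1) ~ T(a)[r(a), ]`.  Deterministic given the RNG state.
#'
#' @param Tarr a `transition_schedule`.
#' @param rf the [risk_factor] (or [scenario]) providing age-0 prevalence.
#' @param sex `"male"` or `"female"`.
#' @param n number of paths.
#' @return integer matrix `n x (a_max + 1)` of 1-based risk-state indices.
#' @export
simulate_risk_paths <- function(Tarr, rf, sex, n) {
  if (inherits(rf, "scenario")) rf <- rf$risk_factor
  ns <- dim(Tarr)[1]
  amax <- dim(Tarr)[3] - 1L
  paths <- matrix(0L, n, amax + 1L)
  w0 <- vapply(rf$prevalence, rt_value, numeric(1), sex = sex, age = 0)
  paths[, 1L] <- sample.int(ns, n, replace = TRUE, prob = w0)
  for (a in 0:(amax - 1L)) {
    cur <- paths[, a + 1L]
    nxt <- integer(n)
    for (r in seq_len(ns)) {
      idx <- which(cur == r)
      if (!length(idx)) next
      row <- Tarr[r, , a + 1L, sex]
      if (max(row) >= 1 - 1e-15) {
        nxt[idx] <- which.max(row)
      } else {
        nxt[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = row)
      }
    }
    paths[, a + 2L] <- nxt
  }
  paths
}

#' Partial micro-simulation of a newborn cohort
#'
#' Simulates `n_per_sex` disease-free newborns per sex to the top age:
#' each individual receives a stochastic risk-factor biography
#' ([simulate_risk_paths()]), while disease states and survival are carried
#' as exact probabilities conditional on the biography (deterministic cluster
#' evolution by the year kernels; overall survival is the product of the
#' cluster alive-masses times the shared other-cause survival, counted
#' exactly once).  Aggregates alive-weighted prevalences per (sex, age);
#' Monte-Carlo standard errors of the disease prevalences are estimated from
#' the between-individual variation.  Deterministic given `seed`.
#'
#' @inheritParams forward_expectation
#' @param n_per_sex simulated individuals per sex (customary defaults: 2000
#'   for risk-factor analyses, 500 for comorbidity analyses).
#' @param seed integer RNG seed.
#' @return a `cohort_result` (kind `"montecarlo"`).
#' @export
simulate_newborn_cohort <- function(s, cp, Tarr, n_per_sex, seed, kernels = NULL) {
  stopifnot(n_per_sex >= 1)
  if (is.null(kernels)) kernels <- year_kernels(cp)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  states <- s$risk_factor$states
  nr <- length(states)
  sizes <- kernels$sizes
  ncl <- length(sizes)
  info <- presence_info(s, kernels)
  dn <- names(s$diseases)
  nd <- length(dn)
  amax <- s$a_max
  n <- n_per_sex
  res <- empty_cohort_result(s, kind = "montecarlo", n_per_sex = n, seed = seed)
  for (sex in SEXES) {
    paths <- simulate_risk_paths(Tarr, s$risk_factor, sex, n)
    M <- lapply(sizes, function(k) {
      m <- matrix(0, n, k); m[, 1L] <- 1; m
    })
    ocS <- rep(1, n)
    for (age in 0:amax) {
      ## aggregate at the start of age-year `age`
      AC <- vapply(M, rowSums, numeric(n)) # n x ncl cluster alive masses
      L <- ocS * apply_rowprod(AC)
      sumL <- sum(L)
      res$alive[sex, age + 1L] <- sumL / n
      r_now <- paths[, age + 1L]
      res$risk_prev[, age + 1L, sex] <-
        rowsum_safe(L, r_now, nr) / sumL
      prod_other <- lapply(seq_len(ncl), function(c)
        ocS * apply_rowprod(AC[, -c, drop = FALSE]))
      xd <- matrix(0, n, nd, dimnames = list(NULL, dn))
      for (d in dn) {
        c <- info$cl_of[d]
        pd <- rowSums(M[[c]][, info$pres_cols[[d]], drop = FALSE])
        xd[, d] <- pd * prod_other[[c]]
      }
      res$disease_prev[, age + 1L, sex] <- colSums(xd) / sumL
      phat <- colSums(xd) / sumL
      dev <- xd - outer(L, phat)
      res$disease_prev_se[, age + 1L, sex] <- sqrt(colSums(dev^2)) / sumL
      for (r in seq_len(nr)) {
        idx <- r_now == r
        res$joint_risk_disease[r, , age + 1L, sex] <-
          colSums(xd[idx, , drop = FALSE]) / sumL
      }
      pair <- matrix(0, nd, nd, dimnames = list(dn, dn))
      for (a_i in seq_len(nd)) {
        for (b_i in seq_len(a_i)) {
          da <- dn[a_i]; db <- dn[b_i]
          ca <- info$cl_of[da]; cb <- info$cl_of[db]
          if (a_i == b_i) {
            pair[a_i, b_i] <- sum(xd[, da]) / sumL
          } else if (ca == cb) {
            both <- intersect(info$pres_cols[[da]], info$pres_cols[[db]])
            pab <- rowSums(M[[ca]][, both, drop = FALSE])
            pair[a_i, b_i] <- sum(pab * prod_other[[ca]]) / sumL
          } else {
            pa <- rowSums(M[[ca]][, info$pres_cols[[da]], drop = FALSE])
            pb <- rowSums(M[[cb]][, info$pres_cols[[db]], drop = FALSE])
            po <- ocS * apply_rowprod(AC[, -c(ca, cb), drop = FALSE])
            pair[a_i, b_i] <- sum(pa * pb * po) / sumL
          }
          pair[b_i, a_i] <- pair[a_i, b_i]
        }
      }
      res$pair_prev[, , age + 1L, sex] <- pair
      if (age == amax) break
      ## evolve the year with the risk state frozen at its start value
      for (r in seq_len(nr)) {
        idx <- which(r_now == r)
        if (!length(idx)) next
        for (c in seq_len(ncl)) {
          P <- kernels$P[[sex]][[age + 1L]][[r]][[c]]
          M[[c]][idx, ] <- M[[c]][idx, , drop = FALSE] %*%
            P[seq_len(sizes[c]), seq_len(sizes[c]), drop = FALSE]
        }
        ocS[idx] <- ocS[idx] * kernels$ocfac[sex, age + 1L, r]
      }
    }
  }
  res
}

apply_rowprod <- function(m) {
  if (is.null(dim(m)) || ncol(m) == 0L) return(rep(1, NROW(m)))
  out <- m[, 1L]
  for (c in seq_len(ncol(m))[-1L]) out <- out * m[, c]
  out
}

rowsum_safe <- function(x, g, nlev) {
  out <- numeric(nlev)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Write a cohort result as CSV
#'
#' One row per (sex, age) with alive mass, per-disease prevalences and
#' pairwise `prev_<A>_<B>` columns.
#'
#' @param res a `cohort_result`.
#' @param path output file.
#' @export
write_cohort_result <- function(res, path) {
  dn <- res$disease_names
  rows <- list()
  for (sex in SEXES) {
    df <- data.frame(sex = sex, age = 0:res$a_max,
                     alive_mass = res$alive[sex, ])
    for (d in dn) df[[paste0("prev_", d)]] <- res$disease_prev[d, , sex]
    if (length(dn) > 1) {
      for (a_i in seq_along(dn)) for (b_i in seq_len(a_i - 1L)) {
        df[[paste0("prev_", dn[a_i], "_", dn[b_i])]] <-
          res$pair_prev[a_i, b_i, , sex]
      }
    }
    rows[[sex]] <- df
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
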