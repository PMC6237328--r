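#' Net risk-factor transition probabilities
#'
#' Estimates, per sex and age, the row-stochastic transition matrix over the
#' ordered risk-factor states that keeps the age- and sex-specific
#' risk-factor prevalence constant over calendar time ("net transitions").
#' Flows cross only adjacent boundaries in the declared state order and in at
#' most one direction per boundary per age: the signed net flow across
#' boundary `k` between ages `a` and `a+1` is
#'
#'   F_k(a) - F_k(a+1),   F_k = cumulative prevalence of states 1..k,
#'
#' moving mass from state `k` to `k+1` when positive and from `k+1` to `k`
#' when negative.  A rising never-smoker share therefore yields
#' current-to-never flows: a demographically unreal but prevalence-preserving
#' repair that is a known artifact of the net-transition mode, and is
#' deliberately not corrected here.  Probabilities are flows divided by the
#' source-state prevalence at age `a`, so `prev(a) %*% T(a) = prev(a+1)`
#' holds exactly; the matrix at the top age is the identity.
#'
#' No mortality adjustment is applied: with risk-dependent mortality the
#' simulated among-the-living risk distribution may drift from the schedule
#' at high ages, which is part of the behaviour under study.
#'
#' @param rf a [risk_factor] (its `prevalence` tables and state order are
#'   used), or a [scenario] (its risk factor is taken).
#' @return a `transition_schedule`: array states x states x ages x sexes.
#' @export
estimate_net_transitions <- function(rf) {
  if (inherits(rf, "scenario")) rf <- rf$risk_factor
  states <- rf$states
  ns <- length(states)
  amax <- a_max_of(rf$prevalence[[1]])
  Tarr <- array(0, dim = c(ns, ns, amax + 1L, 2L),
                dimnames = list(states, states, 0:amax, SEXES))
  for (sex in SEXES) {
    prev <- vapply(rf$prevalence, function(t) unclass(t)[sex, ], numeric(amax + 1L))
    # prev: (amax+1) x ns
    for (a in 0:(amax - 1L)) {
      p0 <- prev[a + 1L, ]
      p1 <- prev[a + 2L, ]
      Fk0 <- cumsum(p0)[-ns]
      Fk1 <- cumsum(p1)[-ns]
      flow <- Fk0 - Fk1 # positive: k -> k+1
      M <- diag(ns)
      out_mass <- numeric(ns)
      for (k in seq_len(ns - 1L)) {
        if (flow[k] > 0) {
          src <- k; dst <- k + 1L; f <- flow[k]
        } else if (flow[k] < 0) {
          src <- k + 1L; dst <- k; f <- -flow[k]
        } else next
        if (p0[src] <= 0 || f > p0[src] + 1e-12) {
          stop(sprintf(
            "infeasible net flow at (%s, age %d, boundary %s|%s): flow %.6g exceeds source mass %.6g",
            sex, a, states[k], states[k + 1L], f, p0[src]))
        }
        M[src, dst] <- M[src, dst] + f / p0[src]
        out_mass[src] <- out_mass[src] + f / p0[src]
      }
      diag(M) <- diag(M) - out_mass
      if (any(diag(M) < -1e-12)) {
        stop(sprintf("infeasible net flow at (%s, age %d): outflows exceed source state",
                     sex, a))
      }
      Tarr[, , a + 1L, sex] <- M
    }
    Tarr[, , amax + 1L, sex] <- diag(ns)
  }
  structure(Tarr, class = "transition_schedule")
}

#' Stationarity residual of a transition schedule
#'
#' Maximum over (sex, age) of the L1 distance between
#' `prev(a) %*% T(a)` and `prev(a + 1)`; a schedule from
#' [estimate_net_transitions()] has residual at machine precision.
#'
#' @param Tarr a `transition_schedule`.
#' @param rf the [risk_factor] (or [scenario]) providing the prevalence.
#' @return maximum L1 residual (numeric scalar).
#' @export
stationarity_residual <- function(Tarr, rf) {
  if (inherits(rf, "scenario")) rf <- rf$risk_factor
  amax <- dim(Tarr)[3] - 1L
  worst <- 0
  for (sex in SEXES) {
    prev <- vapply(rf$prevalence, function(t) unclass(t)[sex, ], numeric(amax + 1L))
    for (a in 0:(amax - 1L)) {
      res <- sum(abs(prev[a + 1L, ] %*% Tarr[, , a + 1L, sex] - prev[a + 2L, ]))
      worst <- max(worst, res)
    }
  }
  worst
}

#' Write a transition schedule as a long CSV
#'
#' Columns: `sex,age,from_state,to_state,probability`.
#'
#' @param Tarr a `transition_schedule`.
#' @param path output file.
#' @export
write_transition_schedule <- function(Tarr, path) {
  dn <- dimnames(Tarr)
  df <- expand.grid(from_state = dn[[1]], to_state = dn[[2]],
                    age = as.integer(dn[[3]]), sex = dn[[4]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$probability <- as.vector(Tarr)
  df <- df[, c("sex", "age", "from_state", "to_state", "probability")]
  df <- df[order(df$sex, df$age, df$from_state), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
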