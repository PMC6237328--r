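test_that("baseline incidence calibration matches closed forms", {
  # all RRs 1: baseline equals population incidence
  s <- toy_scenario(diseases = list(d1 = list(prev = 0.1, inc = 0.02, am = 0,
                                              rr = c(1, 1))))
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  expect_equal(unique(as.vector(cp$baseline_incidence$d1)), 0.02,
               tolerance = 1e-12)
  # two equal-mass disease-free strata with RR {1, 2}: I0 = Ipop / 1.5
  s2 <- toy_scenario(diseases = list(d1 = list(prev = 0, inc = 0.03, am = 0,
                                               rr = c(1, 2))))
  j2 <- build_joint_distribution(s2)
  cp2 <- calibrate_baseline_incidence(s2, j2)
  expect_equal(unique(as.vector(cp2$baseline_incidence$d1)), 0.03 / 1.5,
               tolerance = 1e-12)
})

test_that("calibration reproduces the input incidence in the first year", {
  fx <- causal_fixture()
  s <- fx$s; j <- fx$j; cp <- fx$cp
  cells <- j$cells
  for (dn in names(s$diseases)) {
    d <- s$diseases[[dn]]
    free <- cells[[dn]] == 0
    for (age in c(30, 60, 85)) {
      m <- j$mass[free, age + 1, "female"]
      rr <- vapply(d$rr_from_risk[cells$risk_state[free]], rt_value, numeric(1),
                   sex = "female", age = age)
      for (p in names(d$rr_from_causes)) {
        rr <- rr * ifelse(cells[[p]][free] >= 1,
                          rt_value(d$rr_from_causes[[p]], "female", age), 1)
      }
      i0 <- cp$baseline_incidence[[dn]]["female", age + 1]
      realised <- sum(m * i0 * rr) / sum(m)
      expect_equal(realised, rt_value(d$incidence, "female", age),
                   tolerance = 1e-10)
    }
  }
})

test_that("hazard rates follow the multiplicative / additive model", {
  s <- toy_scenario(
    diseases = list(diab = list(prev = 0.1, inc = 0.001, am = 0.05, rr = c(1, 1)),
                    chd = list(prev = 0.05, inc = 0.001, am = 0.02, rr = c(1, 3)),
                    ca = list(prev = 0.02, inc = 0.001, am = 0.1, rr = c(1, 1),
                              cured = 0.5)),
    causal = list(chd = list(diab = 4)), oc = 0.02,
    kinds = list(ca = "cured"))
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  i0 <- cp$baseline_incidence$chd["male", 6]
  # product form: baseline x risk RR x causal RR for each causal disease present
  expect_equal(incidence_rate(cp, "chd", "alt", c(diab = 1), "male", 5), i0 * 3 * 4)
  expect_equal(incidence_rate(cp, "chd", "alt", c(diab = 0), "male", 5), i0 * 3)
  expect_equal(incidence_rate(cp, "chd", "ref", c(), "male", 5), i0)
  # mortality: other-cause plus attributable terms; cured copies contribute 0
  expect_equal(mortality_rate(cp, "ref", c(diab = 0, chd = 0, ca = 0), "male", 5),
               0.02)
  expect_equal(mortality_rate(cp, "ref", c(diab = 1, chd = 1, ca = 0), "male", 5),
               0.02 + 0.05 + 0.02)
  expect_equal(mortality_rate(cp, "ref", c(diab = 0, chd = 0, ca = 2), "male", 5),
               mortality_rate(cp, "ref", c(diab = 0, chd = 0, ca = 0), "male", 5))
  expect_equal(mortality_rate(cp, "ref", c(diab = 0, chd = 0, ca = 1), "male", 5),
               0.02 + 0.1)
})

test_that("acute fatality applies only to those still free of the disease", {
  s <- toy_scenario(
    diseases = list(chd = list(prev = 0.05, inc = 0.01, am = 0.02,
                               rr = c(1, 2), cf = 0.004)),
    oc = 0.01, kinds = list(chd = "acute"))
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  without <- mortality_rate(cp, "alt", c(chd = 0), "male", 3)
  with_d <- mortality_rate(cp, "alt", c(chd = 1), "male", 3)
  expect_equal(without, 0.01 + 0.004 * 2)
  expect_equal(with_d, 0.01 + 0.02)
})

test_that("one-year cluster evolution matches closed forms", {
  # all rates zero: state unchanged
  s0 <- toy_scenario(diseases = list(d1 = list(prev = 0, inc = 0, am = 0,
                                               rr = c(1, 1))), oc = 0)
  cp0 <- calibrate_baseline_incidence(s0, build_joint_distribution(s0))
  st <- c(0.7, 0.3, 0)
  expect_equal(evolve_cluster_year(cp0, "d1", st, "ref", "male", 2), st,
               tolerance = 1e-12)
  # single chronic disease, I = 0.1, no mortality: 1 - exp(-0.1)
  s1 <- toy_scenario(diseases = list(d1 = list(prev = 0, inc = 0.1, am = 0,
                                               rr = c(1, 1))), oc = 0)
  cp1 <- calibrate_baseline_incidence(s1, build_joint_distribution(s1))
  out <- evolve_cluster_year(cp1, "d1", c(1, 0, 0), "ref", "male", 2)
  expect_equal(out[2], 1 - exp(-0.1), tolerance = 1e-10)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("factorised clusters match the dense full-joint generator", {
  # diabetes-like causal disease, a dependent disease, and an unrelated
  # cured-fraction disease: evolve 3 years both ways
  s <- toy_scenario(
    a_max = 10,
    diseases = list(diab = list(prev = 0.05, inc = 0.008, am = 0.01, rr = c(1, 1.5)),
                    chd = list(prev = 0.04, inc = 0.01, am = 0.03, rr = c(1, 2),
                               cf = 0.003),
                    ca = list(prev = 0.02, inc = 0.004, am = 0.08, rr = c(1, 3),
                              cured = 0.4)),
    causal = list(chd = list(diab = 4)), oc = 0.015,
    kinds = list(chd = "acute", ca = "cured"))
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  oc <- 0.015
  ## dense: all three diseases as one joint space (12 states + dead), with OC
  members_all <- c("diab", "chd", "ca")
  cst_all <- cluster_state_table(s, members_all)
  dense <- c(1, rep(0, nrow(cst_all)))
  for (age in 0:2) {
    dense <- evolve_cluster_year(cp, members_all, dense, "alt", "male", age,
                                 oc_rate = oc)
  }
  ## factorised: clusters {diab, chd} and {ca}, OC as a scalar factor
  cl1 <- c("diab", "chd"); cl2 <- "ca"
  m1 <- c(1, rep(0, nrow(cluster_state_table(s, cl1))))
  m2 <- c(1, rep(0, nrow(cluster_state_table(s, cl2))))
  ocS <- 1
  for (age in 0:2) {
    m1 <- evolve_cluster_year(cp, cl1, m1, "alt", "male", age)
    m2 <- evolve_cluster_year(cp, cl2, m2, "alt", "male", age)
    ocS <- ocS * exp(-oc)
  }
  a1 <- m1[-length(m1)]; a2 <- m2[-length(m2)]
  prod_alive <- ocS * outer(a1, a2) # (diab, chd) x ca
  ## map the dense layout (diab fastest, then chd, then ca) onto the product
  dense_alive <- dense[-length(dense)]
  dense_arr <- array(dense_alive, dim = c(2, 2, 3))
  expect_equal(as.vector(dense_arr), as.vector(array(prod_alive, c(4, 3))),
               tolerance = 1e-10)
  expect_equal(sum(dense), 1, tolerance = 1e-10)
})

test_that("risk paths follow the schedule", {
  s <- toy_scenario(a_max = 5)
  Tarr <- estimate_net_transitions(s)
  set.seed(1)
  paths <- simulate_risk_paths(Tarr, s$risk_factor, "male", 50)
  # constant prevalence: identity schedule, constant paths
  expect_true(all(paths == paths[, 1]))
  # forced alternation
  ns <- 2
  Talt <- Tarr
  for (a in 0:4) Talt[, , a + 1, ] <- matrix(c(0, 1, 1, 0), 2, 2)
  p2 <- simulate_risk_paths(Talt, s$risk_factor, "male", 10)
  expect_true(all(p2[, 2] != p2[, 1] & p2[, 3] == p2[, 1]))
})

test_that("with no disease burden, survival is the other-cause exponential", {
  s <- toy_scenario(a_max = 20,
                    diseases = list(d1 = list(prev = 0, inc = 0, am = 0.5,
                                              rr = c(1, 1))), oc = 0.03)
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  Tarr <- estimate_net_transitions(s)
  mc <- simulate_newborn_cohort(s, cp, Tarr, 50, seed = 3)
  expect_equal(mc$alive["male", ], exp(-0.03 * (0:20)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the deterministic recursion matches single-disease closed forms", {
  s <- toy_scenario(a_max = 30, w = c(only = 1),
                    diseases = list(d1 = list(prev = 0, inc = 0.05, am = 0,
                                              rr = 1)), oc = 0)
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  Tarr <- estimate_net_transitions(s)
  fw <- forward_expectation(s, cp, Tarr)
  expect_equal(fw$disease_prev["d1", , "female"], 1 - exp(-0.05 * (0:30)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fw$alive["female", ], rep(1, 31), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the forward recursion equals exhaustive risk-path enumeration", {
  # 3 ages, 2 risk states with genuine transitions: 8 possible paths
  prev <- rbind(c(0.5, 0.5), c(0.4, 0.6), c(0.55, 0.45))
  s <- toy_scenario(a_max = 2,
                    diseases = list(d1 = list(prev = 0.05, inc = 0.04, am = 0.3,
                                              rr = c(1, 4))), oc = 0.05)
  for (k in 1:2) {
    s$risk_factor$prevalence[[k]] <- rate_table(rbind(prev[, k], prev[, k]),
                                                "risk_prevalence")
  }
  j <- build_joint_distribution(s)
  cp <- calibrate_baseline_incidence(s, j)
  Tarr <- estimate_net_transitions(s)
  fw <- forward_expectation(s, cp, Tarr)

  states <- c("ref", "alt")
  paths <- expand.grid(r0 = 1:2, r1 = 1:2, r2 = 1:2)
  agg_alive <- numeric(3); agg_dis <- numeric(3)
  for (i in seq_len(nrow(paths))) {
    pr <- prev[1, paths$r0[i]] *
      Tarr[paths$r0[i], paths$r1[i], 1, "male"] *
      Tarr[paths$r1[i], paths$r2[i], 2, "male"]
    if (pr == 0) next
    m <- c(1, 0, 0) # healthy, diseased, dead
    for (a in 0:2) {
      r <- states[paths[[paste0("r", a)]][i]]
      alive <- sum(m[1:2]) * exp(-0.05 * a)
      agg_alive[a + 1] <- agg_alive[a + 1] + pr * alive
      agg_dis[a + 1] <- agg_dis[a + 1] + pr * m[2] * exp(-0.05 * a)
      if (a < 2) m <- evolve_cluster_year(cp, "d1", m, r, "male", a)
    }
  }
  expect_equal(fw$alive["male", ], agg_alive, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fw$disease_prev["d1", , "male"], agg_dis / agg_alive,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cohort simulation is reproducible and converges to the oracle", {
  fx <- causal_fixture()
  a <- simulate_newborn_cohort(fx$s, fx$cp, fx$Tarr, 300, seed = 11,
                               kernels = fx$kernels)
  b <- simulate_newborn_cohort(fx$s, fx$cp, fx$Tarr, 300, seed = 11,
                               kernels = fx$kernels)
  expect_identical(a, b)
  # Monte-Carlo error shrinks roughly as 1/sqrt(n); needs a scenario where
  # the risk factor actually modifies disease risk, so paths carry variance
  sp <- synthetic_scenario("pearce_ideal", seed = 1)
  jp <- build_joint_distribution(sp)
  cpp <- calibrate_baseline_incidence(sp, jp)
  Tp <- estimate_net_transitions(sp)
  fwp <- forward_expectation(sp, cpp, Tp)
  errs <- vapply(c(500, 8000), function(n) {
    mc <- simulate_newborn_cohort(sp, cpp, Tp, n, seed = 21)
    max(abs(mc$disease_prev - fwp$disease_prev))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("survival is non-increasing and mass is conserved", {
  fx <- smoking_fixture()
  expect_true(all(diff(fx$fw$alive["male", ]) <= 1e-12))
  expect_true(all(diff(fx$fw$alive["female", ]) <= 1e-12))
  expect_true(all(fx$fw$disease_prev >= -1e-12 & fx$fw$disease_prev <= 1))
  # pairwise prevalence bounded by the marginals
  for (sex in c("male", "female")) {
    for (age in c(40, 70, 90)) {
      pp <- fx$fw$pair_prev[, , age + 1, sex]
      dp <- fx$fw$disease_prev[, age + 1, sex]
      expect_true(all(pp <= outer(dp, dp, pmin) + 1e-12))
    }
  }
  # year kernels are stochastic over (alive states + dead)
  K <- fx$kernels
  for (pick in list(c(1, 30, 1, 1), c(2, 70, 3, 2))) {
    P <- K$P[[pick[1]]][[pick[2]]][[pick[3]]][[pick[4]]]
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
    expect_true(all(P >= -1e-12))
  }
})
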