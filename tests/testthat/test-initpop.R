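# independent oracle: plain bisection on the defining marginal equation
bisect_baseline_odds <- function(p, w, rr, tol = 1e-12) {
  f <- function(b) sum(w * rr * b / (rr * b + 1)) - p
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, lo)) break
  }
  (lo + hi) / 2
}

test_that("baseline-odds solver matches closed forms and a bisection oracle", {
  # all RRs 1: reduces to the plain odds p / (1 - p)
  expect_equal(solve_baseline_odds(0.2, c(0.3, 0.7), c(1, 1)), 0.25,
               tolerance = 1e-10)
  expect_identical(solve_baseline_odds(0, c(0.5, 0.5), c(1, 2)), 0)
  b <- solve_baseline_odds(0.1, c(0.5, 0.5), c(1, 2))
  expect_equal(b, bisect_baseline_odds(0.1, c(0.5, 0.5), c(1, 2)),
               tolerance = 1e-9)
  expect_equal(b, 0.0749, tolerance = 1e-3)
  # residual of the defining equation below 1e-10
  expect_lt(abs(sum(0.5 * c(1, 2) * b / (c(1, 2) * b + 1)) - 0.1), 1e-10)
  # randomised agreement with the oracle
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    w <- as.vector(stats::rmultinom(1, 1000, runif(k))) / 1000
    rr <- c(1, runif(k - 1, 0.2, 8))
    p <- runif(1, 0, 0.6)
    expect_equal(solve_baseline_odds(p, w, rr), bisect_baseline_odds(p, w, rr),
                 tolerance = 1e-8)
  }
  expect_error(solve_baseline_odds(1, c(1), c(1)), "< 1")
  expect_error(solve_baseline_odds(0.1, c(0.5, 0.5), c(0, 0)), "unattainable")
  expect_error(solve_baseline_odds(0.6, c(0.5, 0.5), c(0, 1)), "unattainable")
})

test_that("conditional disease probability recovers the marginal", {
  expect_equal(conditional_disease_probability(1, 1), 0.5)
  expect_equal(conditional_disease_probability(0.25, 4), 0.5)
  w <- c(0.5, 0.5); rr <- c(1, 2)
  b <- solve_baseline_odds(0.1, w, rr)
  expect_equal(sum(w * conditional_disease_probability(b, rr)), 0.1,
               tolerance = 1e-10)
})

test_that("with all RRs at 1 the joint factorises into its marginals", {
  s <- toy_scenario(diseases = list(
    d1 = list(prev = 0.1, inc = 0.01, am = 0, rr = c(1, 1)),
    d2 = list(prev = 0.3, inc = 0.02, am = 0, rr = c(1, 1))))
  j <- build_joint_distribution(s, ages = 5)
  m <- j$mass[, 6, "male"]
  # every pairwise log-odds-ratio among binary margins is zero
  vars <- list(r = j$cells$risk_state == "alt", d1 = j$cells$d1 >= 1,
               d2 = j$cells$d2 >= 1)
  for (a in 1:2) for (b in (a + 1):3) {
    x <- vars[[a]]; y <- vars[[b]]
    lor <- log(sum(m[x & y]) * sum(m[!x & !y]) /
                 (sum(m[x & !y]) * sum(m[!x & y])))
    expect_lt(abs(lor), 1e-10)
  }
})

test_that("the construction makes every stratum POR equal the input RR exactly", {
  s <- toy_scenario(w = c(ref = 0.4, mid = 0.35, top = 0.25),
                    diseases = list(d1 = list(prev = 0.12, inc = 0.01, am = 0,
                                              rr = c(1, 3, 5))))
  j <- build_joint_distribution(s, ages = 4)
  expect_equal(unname(joint_por(j, "d1", "female", 4)), c(1, 3, 5),
               tolerance = 1e-8)
})

test_that("dependent diseases match a brute-force enumeration oracle", {
  # two risk states; A causal (RR_r->A = 2), B dependent (RR_A->B = 4)
  s <- toy_scenario(w = c(ref = 0.6, alt = 0.4),
                    diseases = list(A = list(prev = 0.15, inc = 0.01, am = 0,
                                             rr = c(1, 2)),
                                    B = list(prev = 0.08, inc = 0.01, am = 0,
                                             rr = c(1, 1.5))),
                    causal = list(B = list(A = 4)))
  j <- build_joint_distribution(s, ages = 3)
  m <- j$mass[, 4, "male"]

  # oracle: solve the defining equations directly on the 8-cell grid
  w <- c(0.6, 0.4)
  bA <- bisect_baseline_odds(0.15, w, c(1, 2))
  pA <- c(1, 2) * bA / (c(1, 2) * bA + 1)            # P(A | r)
  wstar <- c(w * (1 - pA), w * pA)                   # strata (r, A=0), (r, A=1)
  rrB <- c(1, 1.5, 1 * 4, 1.5 * 4)
  bB <- bisect_baseline_odds(0.08, wstar, rrB)
  pB <- rrB * bB / (rrB * bB + 1)
  oracle <- numeric(nrow(j$cells))
  for (i in seq_len(nrow(j$cells))) {
    r <- match(j$cells$risk_state[i], c("ref", "alt"))
    a <- j$cells$A[i]; b <- j$cells$B[i]
    st <- r + 2 * a
    oracle[i] <- w[r] * (if (a == 1) pA[r] else 1 - pA[r]) *
      (if (b == 1) pB[st] else 1 - pB[st])
  }
  expect_equal(m, oracle, tolerance = 1e-9)
  # all marginals and PORs recovered
  expect_equal(unname(joint_disease_marginals(j)[, 4, "male"]), c(0.15, 0.08),
               tolerance = 1e-8)
  expect_equal(unname(joint_por(j, "A", "male", 3)), c(1, 2), tolerance = 1e-8)
  # POR of B given A within each risk state equals the causal RR
  for (r in c("ref", "alt")) {
    sel <- j$cells$risk_state == r
    odds <- function(a) sum(m[sel & j$cells$A == a & j$cells$B == 1]) /
      sum(m[sel & j$cells$A == a & j$cells$B == 0])
    expect_equal(odds(1) / odds(0), 4, tolerance = 1e-8)
  }
})

test_that("marginal recovery holds across presets and seeds", {
  for (preset in c("smoking_like", "bmi_like", "independent_pair")) {
    s <- synthetic_scenario(preset, seed = 17)
    j <- build_joint_distribution(s)
    rm_ <- joint_risk_marginals(j)
    dm <- joint_disease_marginals(j)
    for (sex in c("male", "female")) {
      wm <- sapply(s$risk_factor$prevalence, function(t) unclass(t)[sex, ])
      expect_lt(max(abs(t(rm_[, , sex]) - wm)), 1e-12)
      pm <- sapply(s$diseases, function(d) unclass(d$prevalence)[sex, ])
      expect_lt(max(abs(t(dm[, , sex]) - pm)), 1e-8)
    }
  }
})

test_that("raising one RR raises the conditional probability in that stratum", {
  w <- c(0.5, 0.3, 0.2)
  p <- 0.1
  base_rr <- c(1, 2, 3)
  b0 <- solve_baseline_odds(p, w, base_rr)
  p0 <- conditional_disease_probability(b0, base_rr[3])
  for (mult in c(1.2, 2, 5)) {
    rr <- base_rr; rr[3] <- rr[3] * mult
    b1 <- solve_baseline_odds(p, w, rr)
    expect_gte(conditional_disease_probability(b1, rr[3]), p0 - 1e-12)
  }
})

test_that("cured-fraction mass splits by the age-specific fraction", {
  s <- toy_scenario(diseases = list(ca = list(prev = 0.2, inc = 0.01, am = 0.1,
                                              rr = c(1, 2), cured = 0.4)),
                    kinds = list(ca = "cured"))
  j <- build_joint_distribution(s, ages = 2)
  m <- j$mass[, 3, "male"]
  notc <- sum(m[j$cells$ca == 1])
  cur <- sum(m[j$cells$ca == 2])
  expect_equal(cur / (notc + cur), 0.4, tolerance = 1e-10)
  expect_equal(notc + cur, 0.2, tolerance = 1e-8)
})

test_that("quota sampling assigns floor(n * mass) before random residuals", {
  s <- toy_scenario()
  j <- build_joint_distribution(s, ages = 0)
  pop <- sample_initial_population(j, 4, seed = 1, ages = 0)
  expect_equal(unname(table(pop$risk_state[pop$sex == "male"])), c(2L, 2L),
               ignore_attr = TRUE)
  # degenerate distribution: all individuals identical
  s1 <- toy_scenario(w = c(only = 1),
                     diseases = list(d1 = list(prev = 0, inc = 0, am = 0, rr = 1)))
  j1 <- build_joint_distribution(s1, ages = 0)
  pop1 <- sample_initial_population(j1, 8, seed = 2, ages = 0)
  expect_equal(nrow(unique(pop1[, c("risk_state", "d1")])), 1L)
  # determinism
  expect_identical(sample_initial_population(j, 100, seed = 9, ages = 0),
                   sample_initial_population(j, 100, seed = 9, ages = 0))
})

test_that("residual assignment is consistent with the residual distribution", {
  # 3 states with masses that leave residuals 0.5/0.3/0.2 after the quota
  s <- toy_scenario(w = c(a = 0.25, b = 0.23, c = 0.52),
                    diseases = list(d1 = list(prev = 0.1, inc = 0.02, am = 0,
                                              rr = c(1, 1, 1))))
  j <- build_joint_distribution(s, ages = 0)
  n <- 25 # quotas 6/5/13, one residual slot with probs 0.25/0.75/0
  extra <- matrix(0L, 50, 3)
  for (k in 1:50) {
    pop <- sample_initial_population(j, n, seed = k, ages = 0, sexes = "male")
    cnt <- table(factor(pop$risk_state, levels = c("a", "b", "c")))
    extra[k, ] <- as.integer(cnt) - floor(n * c(0.25, 0.23, 0.52))
  }
  expect_true(all(rowSums(extra) == 1L))
  # across seeds the residual slot follows the residual probabilities
  obs <- colSums(extra)
  expected <- 50 * c(0.25, 0.75, 0) / 1
  chi <- sum((obs[1:2] - expected[1:2])^2 / expected[1:2])
  expect_gt(stats::pchisq(chi, df = 1, lower.tail = FALSE), 0.001)
})
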