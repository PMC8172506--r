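test_that("cumulative ICF matches the logistic form", {
  it <- toy_item()
  expect_equal(prob_at_or_above(it, psi = 0, k = 2), 0.5)   # psi = b_2
  expect_equal(prob_at_or_above(it, psi = log(3), k = 2), 0.75)
  expect_equal(prob_at_or_above(it, psi = 50, k = 3), 1, tolerance = 1e-10)
  expect_equal(prob_at_or_above(it, psi = -50, k = 1), 0, tolerance = 1e-10)
  expect_equal(prob_at_or_above(it, psi = 1.3, k = 0), 1)
  expect_error(prob_at_or_above(it, 0, k = 4), "k must be")
  ## strictly increasing in psi, strictly decreasing in k
  psis <- seq(-3, 3, 0.5)
  for (k in 1:3) expect_true(all(diff(prob_at_or_above(it, psis, k)) > 0))
  for (p in psis)
    expect_true(all(diff(vapply(1:3, function(k)
      prob_at_or_above(it, p, k), numeric(1))) < 0))
})

test_that("category probabilities telescope, sum to 1 and hit the hand value", {
  it <- toy_item()
  ## hand computation at psi = 0, a = 1, b = (-1, 0, 1)
  e <- exp(1)
  expect_equal(unname(category_probabilities(it, 0)),
               c(1 - e / (1 + e), e / (1 + e) - 0.5,
                 0.5 - exp(-1) / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  set.seed(42)
  for (psi in stats::rnorm(25, 0, 3)) {
    for (bank_seed in 1:2) {
      it2 <- bank_item(default_item_bank(bank_seed), sample(1:14, 1))
      p <- category_probabilities(it2, psi)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  expect_equal(unname(category_probabilities(it, -40)), c(1, 0, 0, 0),
               tolerance = 1e-12)
})

test_that("all trajectory models reduce to baseline at t = 0", {
  eff <- list(psi0 = 0.37)
  models <- list(
    trajectory_parameters("linear", list(slope = 0.01), list(slope = 0)),
    trajectory_parameters("power", list(slope = 0.01, gamma = 0.7),
                          list(slope = 0, gamma = 0.7)),
    trajectory_parameters("asymptotic", list(r_max = -1, t_prog = 30),
                          list(r_max = 1, t_prog = 30)),
    trajectory_parameters("weibull", list(r_max = -1, t_prog = 30,
                                          gamma = 1.4),
                          list(r_max = 1, t_prog = 30, gamma = 1.4)),
    trajectory_parameters("step", list(r_max = -1, t_r = 10),
                          list(r_max = 1, t_r = 10)))
  for (m in models)
    for (arm in c("drug", "placebo"))
      expect_equal(trajectory_value(m, eff, 0, arm), 0.37)
})

test_that("step trajectory switches strictly after the response time", {
  tr <- trajectory_parameters("step",
                              drug = list(r_max = -0.16, t_r = 54.8),
                              placebo = list(r_max = 0.18, t_r = 51.1))
  expect_equal(trajectory_value(tr, list(), c(0, 54.8, 55), "drug"),
               c(0, 0, -0.16))
  expect_equal(trajectory_value(tr, list(), c(51.1, 52), "placebo"),
               c(0, 0.18))
})

test_that("asymptotic model reaches its half-life midpoint at t_prog", {
  m <- trajectory_parameters("asymptotic", list(r_max = -1, t_prog = 40),
                             list(r_max = -1, t_prog = 40))
  psi0 <- 0.4
  expect_equal(trajectory_value(m, list(psi0 = psi0), 40, "drug"),
               (psi0 + -1) / 2)
})

test_that("weibull with gamma = 1 equals the asymptotic shape in amplitude form", {
  wb <- trajectory_parameters("weibull",
                              list(r_max = -0.8, t_prog = 25, gamma = 1),
                              list(r_max = -0.8, t_prog = 25, gamma = 1))
  ## amplitude form: psi0 + r_max * (1 - exp(-ln2 t / t_prog))
  ts <- seq(0, 120, 7.5)
  expect_equal(trajectory_value(wb, list(psi0 = 0.2), ts, "drug"),
               0.2 - 0.8 * (1 - exp(-log(2) / 25 * ts)), tolerance = 1e-12)
})

test_that("missing required fixed effects are reported by name", {
  expect_error(trajectory_parameters("step", drug = list(r_max = -1),
                                     placebo = list(r_max = 1, t_r = 5)),
               "t_r")
  expect_error(trajectory_parameters("weibull",
                                     drug = list(r_max = -1, t_prog = 10),
                                     placebo = list(r_max = -1,
                                                    t_prog = 10)),
               "gamma")
})

test_that("transition matrix satisfies its stationarity and limit contracts", {
  set.seed(7)
  bank <- default_item_bank(3)
  for (j in c(1, 8, 13)) {
    it <- bank_item(bank, j)
    for (psi in c(-1, 0.4)) {
      pi_ <- as.numeric(category_probabilities(it, psi))
      for (dt in c(0.3, 1, 5)) {
        P <- transition_matrix(it, psi, dt, met = 2)
        expect_equal(unname(rowSums(P)), rep(1, it$K + 1),
                     tolerance = 1e-12)
        ## stationarity to 1e-10
        expect_lt(max(abs(as.numeric(pi_ %*% P) - pi_)), 1e-10)
        ## Chapman-Kolmogorov within a constant-MET window
        P2 <- transition_matrix(it, psi, 2 * dt, met = 2)
        expect_lt(max(abs(P %*% P - P2)), 1e-10)
      }
      ## dt limits
      expect_equal(transition_matrix(it, psi, 1e-9, 2), diag(it$K + 1),
                   tolerance = 1e-6, ignore_attr = TRUE)
      Pinf <- transition_matrix(it, psi, 1e6, 2)
      expect_equal(Pinf, matrix(pi_, it$K + 1, it$K + 1, byrow = TRUE),
                   tolerance = 1e-10, ignore_attr = TRUE)
      ## half-deviation closed form at dt = MET * ln 2
      Ph <- transition_matrix(it, psi, 2 * log(2), met = 2)
      expect_equal(Ph, 0.5 * diag(it$K + 1) +
                     0.5 * matrix(pi_, it$K + 1, it$K + 1, byrow = TRUE),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  expect_error(transition_matrix(toy_item(), 0, dt = 0, met = 1),
               "out of range")
  expect_error(transition_matrix(toy_item(), 0, dt = 1, met = 0),
               "out of range")
})

test_that("simulated marginals match the ICF distribution (chi-square GOF)", {
  ## zero IIV and zero effect: psi = 0 for everyone, and without a Markov
  ## layer every present day is an independent marginal ICF draw, so
  ## 200 subjects x 100 days give 20,000 draws
  bank <- default_item_bank(5)
  tr <- trajectory_parameters("step", drug = list(r_max = 0, t_r = 1),
                              placebo = list(r_max = 0, t_r = 1))
  sim <- simulate_trial(list(n_drug = 200, n_placebo = 0, days = 0:99),
                        bank, tr, markov = NULL, seed = 31L)
  w <- sim$data
  for (j in c(2, 8, 13)) {
    it <- bank_item(bank, j)
    obs <- tabulate(w[[paste0("i", j)]] + 1L, nbins = it$K + 1)
    p <- as.numeric(category_probabilities(it, 0))
    gof <- suppressWarnings(stats::chisq.test(obs, p = p))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("diary simulation is seed-reproducible and respects missingness", {
  bank <- default_item_bank(2)
  tr <- trajectory_parameters("step", drug = list(r_max = -0.3, t_r = 5),
                              placebo = list(r_max = 0, t_r = 5),
                              iiv = list(psi0 = 1))
  mk <- markov_parameters(2, 0, 0, horizon = 20)
  d1 <- simulate_subject_diary(bank, tr, mk, list(psi0 = 0.3), "drug",
                               days = 0:20, missing_days = c(3, 7),
                               seed = 99L)
  d2 <- simulate_subject_diary(bank, tr, mk, list(psi0 = 0.3), "drug",
                               days = 0:20, missing_days = c(3, 7),
                               seed = 99L)
  expect_identical(d1, d2)
  expect_false(any(c(3, 7) %in% d1$day))
  expect_equal(nrow(d1), 19)
})

test_that("large MET raises lag-1 concordance above independent draws", {
  bank <- default_item_bank(2)
  tr <- trajectory_parameters("step", drug = list(r_max = 0, t_r = 1),
                              placebo = list(r_max = 0, t_r = 1))
  mk <- markov_parameters(10, 0, 0, horizon = 60)
  conc <- function(markov, seed) {
    agree <- total <- 0
    for (i in 1:30) {
      d <- simulate_subject_diary(bank, tr, markov, list(), "drug", 0:60,
                                  seed = derive_seed(seed, i))
      Y <- as.matrix(d[, paste0("i", 1:14)])
      agree <- agree + sum(Y[-1, ] == Y[-nrow(Y), ])
      total <- total + length(Y[-1, ])
    }
    agree / total
  }
  expect_gt(conc(mk, 1L), conc(NULL, 2L) + 0.1)
})

test_that("simulate_trial propagates arm effects with the right sign", {
  bank <- default_item_bank(8)
  ## zero IIV, zero effect: arms coincide in expectation
  tr0 <- trajectory_parameters("step", drug = list(r_max = 0, t_r = 10),
                               placebo = list(r_max = 0, t_r = 10))
  s0 <- simulate_trial(list(n_drug = 400, n_placebo = 400, days = c(0, 30)),
                       bank, tr0, markov = NULL, seed = 5L)
  sc0 <- score_diary(s0)
  m0 <- tapply(sc0$rs_total[sc0$day == 30], sc0$arm[sc0$day == 30], mean)
  expect_lt(abs(m0[["drug"]] - m0[["placebo"]]), 1)

  ## negative drug r_max, positive placebo: drug scores lower after max(T_R)
  tr1 <- trajectory_parameters("step", drug = list(r_max = -0.5, t_r = 10),
                               placebo = list(r_max = 0.5, t_r = 10))
  s1 <- simulate_trial(list(n_drug = 500, n_placebo = 500, days = c(0, 30)),
                       bank, tr1, markov = NULL, seed = 6L)
  sc1 <- score_diary(s1)
  m1 <- tapply(sc1$rs_total[sc1$day == 30], sc1$arm[sc1$day == 30], mean)
  expect_lt(m1[["drug"]], m1[["placebo"]] - 1)

  ## empty design
  s2 <- simulate_trial(list(n_drug = 0, n_placebo = 0, horizon = 3),
                       default_item_bank(1),
                       tr0, markov = NULL, seed = 1L)
  expect_equal(nrow(s2$data), 0)
})
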