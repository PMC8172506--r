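test_that("sample-size ratio reproduces the published comparison", {
  ## printed 95% CIs: reference (-4.77, 2.04), item-based (-3.16, 0.48)
  expect_equal(ci_width(-4.77, 2.04), 6.81)
  expect_equal(ci_width(-3.16, 0.48), 3.64)
  expect_equal(round(sample_size_ratio(6.81, 3.64), 1), 3.5)
  expect_equal(sample_size_ratio(2, 2), 1)
  expect_equal(sample_size_ratio(2, 1), 4)
  expect_error(sample_size_ratio(0, 1), "out of range")
  expect_error(ci_width(1, 1), "exceed")
})

test_that("sd_from_ci inverts an equal-tailed normal interval", {
  expect_equal(sd_from_ci(-3.16, 0.48), 3.64 / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(sd_from_ci(-1, 1), 2 / 3.91993, tolerance = 1e-4)
  ## round trip: a N(0, s) 95% CI maps back to s
  s <- 1.7
  expect_equal(sd_from_ci(-1.96 * s, 1.96 * s), s, tolerance = 1e-3)
})

test_that("go probability reproduces the published power values", {
  ## true effect -5, TV -2: published 87% / 96%
  expect_equal(round(100 * p_go(-5, 2.70, -2)), 87)
  expect_equal(round(100 * p_go(-5, 1.74, -2)), 96)
  expect_equal(p_go(-2, 1.74, -2), 0.5)
  expect_equal(p_go(-3, 2, -2) + p_stop(-3, 2, -2), 1)
})

test_that("analytic decision table reproduces the published MMRM cells", {
  ## sigma 2.70 (EXACT): printed stop/go cells 0.68/0.22 and 0.04/0.06
  t1 <- decision_table_analytic(decision_inputs(tv = -2,
                                                sigma_delta = 2.70))
  expect_close(t1$p_correct_stop, 0.68, 0.015)
  expect_close(t1$p_incorrect_go, 0.22, 0.015)
  expect_close(t1$p_incorrect_stop, 0.04, 0.015)
  expect_close(t1$p_correct_go, 0.06, 0.015)
  expect_close(ppv(t1), 0.22, 0.015)
  expect_close(npv(t1), 0.95, 0.015)

  ## sigma 1.74 (E-RS): printed correct-go 0.07, PPV 0.34, NPV 0.96
  t2 <- decision_table_analytic(decision_inputs(tv = -2,
                                                sigma_delta = 1.74))
  expect_close(t2$p_correct_go, 0.07, 0.015)
  expect_close(ppv(t2), 0.34, 0.015)
  expect_close(npv(t2), 0.96, 0.015)

  ## item-based E-RS column: sigma back-derived from the printed interval
  t3 <- decision_table_analytic(
    decision_inputs(tv = -2, sigma_delta = sd_from_ci(-3.16, 0.48)))
  expect_close(t3$p_correct_stop, 0.87, 0.015)
  expect_close(ppv(t3), 0.67, 0.02)
  expect_close(npv(t3), 0.97, 0.015)
})

test_that("decision table cells are coherent and margins match the prior", {
  for (s in c(0.5, 1.74, 2.7)) {
    tab <- decision_table_analytic(decision_inputs(tv = -2,
                                                   sigma_delta = s))
    cells <- c(tab$p_correct_go, tab$p_incorrect_go, tab$p_correct_stop,
               tab$p_incorrect_stop)
    expect_equal(sum(cells), 1, tolerance = 1e-9)
    expect_equal(tab$p_go, tab$p_correct_go + tab$p_incorrect_go,
                 tolerance = 1e-12)
    ## P(true effect at/beyond TV) = w1/2 = 0.1 under the default mixture
    expect_equal(tab$p_correct_go + tab$p_incorrect_stop, 0.1,
                 tolerance = 1e-9)
    expect_equal(tab$p_incorrect_go + tab$p_correct_stop, 0.9,
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo tables converge to the analytic oracle", {
  set.seed(123)
  for (r in 1:5) {
    tv <- -runif(1, 0.5, 3)
    sg <- runif(1, 0.5, 3)
    w0 <- runif(1, 0.5, 0.95)
    n <- 40000
    inp <- decision_inputs(tv, sg, w0 = w0, n_samples = n,
                           seed = 100L + r)
    mc <- decision_table_mc(inp)
    an <- decision_table_analytic(inp)
    for (cell in c("p_correct_go", "p_incorrect_go", "p_correct_stop",
                   "p_incorrect_stop")) {
      se <- sqrt(an[[cell]] * (1 - an[[cell]]) / n)
      expect_lt(abs(mc[[cell]] - an[[cell]]), 3 * se + 1e-9)
    }
  }
  ## determinism
  inp <- decision_inputs(-2, 1.5, seed = 9L)
  expect_identical(decision_table_mc(inp)$p_go,
                   decision_table_mc(inp)$p_go)
})

test_that("noiseless decisions classify perfectly", {
  inp <- decision_inputs(tv = -2, sigma_delta = 1e-9, n_samples = 5000,
                         seed = 2L)
  mc <- decision_table_mc(inp)
  expect_equal(mc$p_incorrect_go, 0)
  expect_equal(mc$p_incorrect_stop, 0)
  expect_equal(ppv(mc), 1)
  expect_equal(npv(mc), 1)
})

test_that("degenerate denominators yield NA with a warning", {
  ## huge positive TV-distance: go never happens in a small MC sample
  inp <- decision_inputs(tv = -30, sigma_delta = 0.1, w0 = 1,
                         n_samples = 100, seed = 3L)
  expect_warning(tab <- decision_table_mc(inp), "PPV")
  expect_true(is.na(ppv(tab)))
})

test_that("power curve is monotone and the threshold inverts it", {
  cv <- power_curve(1.74, -2, seq(-6, 2, 0.1))
  expect_true(all(diff(cv$p_go) <= 0))
  expect_equal(cv$p_go + cv$p_stop, rep(1, nrow(cv)))
  expect_equal(power_threshold(1.74, -2, 0.5), -2)
  d80 <- power_threshold(1.74, -2, 0.8)
  expect_equal(p_go(d80, 1.74, -2), 0.8, tolerance = 1e-12)
  ## closed form: tv - 0.8416 * sigma
  expect_equal(d80, -2 - 1.74 * qnorm(0.8), tolerance = 1e-12)
  ## published 80%-power efforts are soft cross-checks (~1-2%)
  expect_equal(power_threshold(2.70, -2, 0.8), -4.22, tolerance = 0.02 * 4.22)
  expect_equal(power_threshold(1.74, -2, 0.8), -3.43, tolerance = 0.02 * 3.43)
  expect_error(power_threshold(1, -2, 1.2), "target_power")
  expect_error(power_curve(1, -2, seq(-1, 0, 0.1)), "cover")
})

test_that("ROC/AUC agrees with the closed-form oracle", {
  ## identical arms: no discrimination
  r0 <- roc_and_auc(method_summary(-1, 1), method_summary(-1, 1),
                    n_draws = 4000, seed = 4L, n_boot = 200)
  expect_equal(r0$auc, 0.5, tolerance = 0.03)
  expect_equal(r0$auc_closed_form, 0.5)

  set.seed(11)
  for (r in 1:4) {
    md <- -runif(1, 0, 3)
    sep <- runif(1, 0.3, 2)
    drug <- method_summary(md, sep)
    plac <- method_summary(0, runif(1, 0.3, 2))
    rr <- roc_and_auc(drug, plac, n_draws = 4000, seed = 20L + r,
                      n_boot = 200)
    mc_se <- sqrt(rr$auc_closed_form * (1 - rr$auc_closed_form) / 4000)
    expect_lt(abs(rr$auc - rr$auc_closed_form), 4 * mc_se + 0.01)
    expect_true(rr$auc_ci[1] <= rr$auc && rr$auc <= rr$auc_ci[2])
  }

  ## separation limit
  rbig <- roc_and_auc(method_summary(-50, 0.5), method_summary(0, 0.5),
                      n_draws = 2000, seed = 5L, n_boot = 100)
  expect_equal(rbig$auc, 1)
  expect_error(roc_and_auc(method_summary(0, 0), method_summary(0, 1)),
               "out of range")
})
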