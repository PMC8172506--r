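## a small fitted-model stand-in built from ground truth: VPC and smooth
## checks only need bank/trajectory/markov components
truth_fit <- function(fx_bank, traj, markov) {
  structure(list(type = "longitudinal", bank = fx_bank, trajectory = traj,
                 markov = markov), class = "irm_fit")
}

vpc_world <- function() {
  cached("vpc_world", {
    cfg <- trial_config(n_drug = 25, n_placebo = 25, horizon_days = 60,
                        trajectory = trajectory_parameters(
                          "step", drug = list(r_max = -0.3, t_r = 20),
                          placebo = list(r_max = 0.3, t_r = 20),
                          iiv = list(psi0 = 1, r_max = 0.05, t_r = 0.05)),
                        markov = markov_parameters(2, 0.003, 0.05,
                                                   horizon = 60),
                        miss_rate = 0.02, dropout_frac = 0, seed = 2025L)
    g <- generate_trial(cfg)
    list(data = g$data,
         fit = truth_fit(default_item_bank(derive_seed(2025L, 4L)),
                         cfg$trajectory, cfg$markov))
  })
}

test_that("total-score VPC is self-consistent on model-simulated data", {
  vw <- vpc_world()
  v <- vpc_total_score(vw$fit, vw$data, n_sim = 200, bins = 8, seed = 55L)
  st <- v$stats
  expect_true(all(st$band_lo <= st$band_hi, na.rm = TRUE))
  inside <- st$observed >= st$band_lo - 1e-9 &
    st$observed <= st$band_hi + 1e-9
  expect_gte(mean(inside, na.rm = TRUE), 0.9)
  ## both arms and all three percentiles present
  expect_setequal(unique(st$arm), c("drug", "placebo"))
  expect_setequal(unique(st$stat), c("p2.5", "p50", "p97.5"))
})

test_that("degenerate VPCs still behave", {
  vw <- vpc_world()
  ## n_sim = 2 is allowed (bands are degenerate but ordered)
  v2 <- vpc_total_score(vw$fit, vw$data, n_sim = 2, bins = 4, seed = 7L)
  expect_true(all(v2$stats$band_lo <= v2$stats$band_hi, na.rm = TRUE))
  expect_error(vpc_total_score(vw$fit, vw$data, n_sim = 1), "n_sim")
  ## unfitted model
  expect_error(vpc_total_score(structure(list(), class = "irm_fit"),
                               vw$data, n_sim = 2),
               "trajectory")
})

test_that("near-deterministic responses collapse the bands onto the median", {
  ## huge discriminations, thresholds far from psi = 0, zero IIV:
  ## everyone answers identically
  K <- exact_items()$max_score
  bank <- item_bank(data.frame(
    item_id = 1:14, a = 30,
    b1 = -2, b2 = -1, b3 = 1, b4 = ifelse(K == 4, 2, NA)))
  traj <- trajectory_parameters("step", drug = list(r_max = 0, t_r = 5),
                                placebo = list(r_max = 0, t_r = 5))
  cfg_fit <- truth_fit(bank, traj, NULL)
  sim <- simulate_trial(list(n_drug = 10, n_placebo = 10, days = 0:10),
                        bank, traj, NULL, seed = 3L)
  v <- vpc_total_score(cfg_fit, sim, n_sim = 20, bins = 3, seed = 4L)
  expect_lt(max(v$stats$band_hi - v$stats$band_lo, na.rm = TRUE), 1e-9)
  expect_equal(v$stats$observed, v$stats$band_lo, tolerance = 1e-9)
})

test_that("item VPC proportions sum to one within each stratum-bin", {
  vw <- vpc_world()
  v <- vpc_items(vw$fit, vw$data, n_sim = 150, bins = 5, seed = 9L)
  st <- v$stats
  sums <- tapply(st$observed, interaction(st$arm, st$bin), sum,
                 na.rm = TRUE)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
               tolerance = 1e-9)
  ## category-bin cells within an arm share subjects, so misses cluster;
  ## 80% inside the 95% bands is the practical self-consistency floor
  inside <- st$observed >= st$band_lo - 1e-9 &
    st$observed <= st$band_hi + 1e-9
  expect_gte(mean(inside, na.rm = TRUE), 0.8)
})

test_that("transition VPC detects a missing Markov layer", {
  fx <- markov_fixture()          # strong persistence world (MET = 8)
  bank <- default_item_bank(derive_seed(707L, 4L))
  traj <- trajectory_parameters("step",
                                drug = list(r_max = -0.16, t_r = 54.8),
                                placebo = list(r_max = 0.18, t_r = 51.1),
                                iiv = list(psi0 = 1, r_max = 0.05,
                                           t_r = 0.1))
  good <- truth_fit(bank, traj, markov_parameters(8, 0, 0.05,
                                                  horizon = 60))
  bad <- truth_fit(bank, traj, NULL)   # independence model

  vg <- vpc_transitions(good, fx$data, n_sim = 60, bins = 4, seed = 12L)
  same_g <- vg$stats[vg$stats$direction == "same", ]
  expect_gte(mean(same_g$observed >= same_g$band_lo - 1e-9 &
                    same_g$observed <= same_g$band_hi + 1e-9,
                  na.rm = TRUE), 0.7)

  vb <- vpc_transitions(bad, fx$data, n_sim = 60, bins = 4, seed = 13L)
  same_b <- vb$stats[vb$stats$direction == "same", ]
  ## the observed persistence escapes the independence bands everywhere
  expect_gte(mean(same_b$observed > same_b$band_hi, na.rm = TRUE), 0.9)
})

test_that("transition VPC requires consecutive-day pairs", {
  fx <- tiny_fixture()
  w <- fx$data$data
  w <- w[w$day != 1, ]           # remove the middle day: gaps of 2 only
  vwf <- vpc_world()
  expect_error(vpc_transitions(vwf$fit, diary_dataset(w), n_sim = 2),
               "consecutive")
})

test_that("ICF smooth check agrees with the model on simulated data", {
  bank <- default_item_bank(9)
  d <- independent_occasions(bank, 1000, 1000, mu = 0, omega2 = 1,
                             seed = 71)
  sm <- icf_smooth_check(bank, d, seed = 72L)
  expect_length(sm, 14)
  ## compare where the smooth has real support: the central 80% of the
  ## latent range (at n = 2000 the outermost 10% carries too few
  ## occasions for a max-gap statistic to be meaningful)
  gaps <- vapply(sm, function(s) {
    ctr <- s$psi >= stats::quantile(attr(sm, "psi_hat"), 0.10) &
      s$psi <= stats::quantile(attr(sm, "psi_hat"), 0.90)
    max(abs(s$observed[ctr] - s$simulated[ctr]))
  }, numeric(1))
  expect_lt(max(gaps), 0.15)
  ## expected-score curves are monotone in psi
  for (s in sm) expect_true(all(diff(s$expected) > 0))
  ## too few occasions
  few <- diary_dataset(d$data[1:10, ])
  expect_error(icf_smooth_check(bank, few), "20 occasions")
})
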