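## step-1 fits here run on reduced data so the unit suite stays fast; the
## full-scale parameter recovery lives in test-acceptance.R

test_that("step-1 marginal likelihood matches a dense-grid oracle", {
  ## one item, a handful of occasions: integrate the likelihood on a dense
  ## trapezoid grid, fully independent of the quadrature code path
  bank <- default_item_bank(1)
  fx <- tiny_fixture()
  ofv <- icf_ofv(bank, fx$data, mu = -0.4, omega2 = 1.3, nodes = 61,
                 item_ids = 3L)
  grid <- seq(-10, 10, length.out = 20001)
  w <- fx$data$data
  it <- bank_item(bank, 3)
  ll <- 0
  for (r in seq_len(nrow(w))) {
    dens <- if (w$day[r] == 0) stats::dnorm(grid) else
      stats::dnorm(grid, -0.4, sqrt(1.3))
    lik <- category_probabilities(it, grid)[, w$i3[r] + 1L]
    ll <- ll + log(sum((lik * dens)[-1] + (lik * dens)[-length(grid)]) / 2 *
                     diff(grid[1:2]))
  }
  expect_equal(ofv, -2 * ll, tolerance = 1e-6)
})

test_that("doubling quadrature nodes leaves the objective unchanged", {
  bank <- default_item_bank(1)
  d <- independent_occasions(bank, 150, 300, mu = -0.3, omega2 = 1.4,
                             seed = 21)
  o1 <- icf_ofv(bank, d, -0.3, 1.4)            # default node count
  o2 <- icf_ofv(bank, d, -0.3, 1.4, nodes = 122)
  expect_lt(abs(o1 - o2), 0.01)
})

test_that("duplicating every occasion doubles the OFV and keeps estimates", {
  bank <- default_item_bank(4)
  d <- independent_occasions(bank, 150, 350, mu = 0.2, omega2 = 0.8,
                             seed = 31)
  f1 <- fit_icfs(d, nodes = 15, se = FALSE, max_restarts = 0)
  w2 <- d$data
  w2b <- w2
  w2b$subject_id <- paste0(w2b$subject_id, "_dup")
  d2 <- diary_dataset(rbind(w2, w2b))
  f2 <- fit_icfs(d2, nodes = 15, se = FALSE, max_restarts = 0)
  expect_equal(f2$ofv, 2 * f1$ofv, tolerance = 1e-4)
  expect_equal(f2$bank$a, f1$bank$a, tolerance = 1e-3)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-4)
})

test_that("a balanced binary-like item centres its threshold at zero", {
  ## single 0-3 item (id 3) whose responses are symmetric around the
  ## middle threshold: b_2 should be ~0 by symmetry
  set.seed(41)
  n <- 3000
  psi <- stats::rnorm(n)
  it <- list(a = 1.2, b = c(-1.5, 0, 1.5))
  pr <- category_probabilities(it, psi)
  cum <- pr %*% upper.tri(diag(4), diag = TRUE)
  y <- as.integer(rowSums(stats::runif(n) > cum[, 1:3]))
  w <- data.frame(subject_id = sprintf("O%04d", 1:n), arm = "drug",
                  day = 0L)
  for (j in 1:14) w[[paste0("i", j)]] <- 0L
  w$i3 <- y
  f <- fit_icfs(diary_dataset(w), item_ids = 3L, nodes = 21, se = TRUE,
                max_restarts = 0)
  b2 <- f$bank[f$bank$item_id == 3, "b2"]
  expect_lt(abs(b2), 3 * f$se[["b_3_2"]])
  expect_lt(abs(b2), 0.15)
})

test_that("unobserved categories collapse with a report", {
  bank <- default_item_bank(4)
  d <- independent_occasions(bank, 120, 240, mu = 0, omega2 = 1, seed = 51)
  ## censor the top category of item 1 so it is never observed
  w <- d$data
  w$i1[w$i1 == 4] <- 3L
  d2 <- diary_dataset(w)
  f <- fit_icfs(d2, nodes = 15, se = FALSE, max_restarts = 0)
  expect_match(f$convergence$collapsed, "item 1", all = FALSE)
  expect_true(is.na(f$bank_table$b4[1]))      # raw estimate absent
  expect_false(anyNA(f$bank_table$b3[1]))
  ## the returned bank is completed so downstream stages stay usable
  expect_s3_class(f$bank, "item_bank")
  expect_gt(f$bank$b4[1], f$bank$b3[1])
})

test_that("step-1 SEs shrink like 1/sqrt(n)", {
  bank <- default_item_bank(6)
  d1 <- independent_occasions(bank, 150, 300, mu = 0, omega2 = 1, seed = 61)
  d4 <- independent_occasions(bank, 600, 1200, mu = 0, omega2 = 1, seed = 62)
  f1 <- fit_icfs(d1, nodes = 15, max_restarts = 0)
  f4 <- fit_icfs(d4, nodes = 15, max_restarts = 0)
  shared <- intersect(names(f1$se), names(f4$se))
  ratio <- stats::median(f4$se[shared] / f1$se[shared])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("step-2 objective equals the independent-day oracle at zero IIV", {
  fx <- tiny_fixture()
  bank <- default_item_bank(derive_seed(101L, 4L))
  pars <- list(r_max_drug = -0.16, r_max_placebo = 0.18, t_r_drug = 54.8,
               t_r_placebo = 51.1, omega2_psi0 = 0, omega2_r_max = 0,
               omega2_t_r = 0)
  ofv <- longitudinal_ofv(fx$data, bank, model = "step", markov = FALSE,
                          params = pars)
  ## brute force: product of marginal ICF probabilities
  traj <- trajectory_parameters("step",
                                drug = list(r_max = -0.16, t_r = 54.8),
                                placebo = list(r_max = 0.18, t_r = 51.1))
  w <- fx$data$data
  oracle <- 0
  for (r in seq_len(nrow(w))) {
    psi <- trajectory_value(traj, list(), w$day[r], w$arm[r])
    for (j in 1:14) {
      it <- bank_item(bank, j)
      oracle <- oracle +
        log(category_probabilities(it, psi)[[w[[paste0("i", j)]][r] + 1L]])
    }
  }
  expect_equal(ofv, -2 * oracle, tolerance = 1e-8)
})

test_that("step-2 Markov objective matches a transition-probability oracle", {
  ## zero IIV so no integration: the likelihood is the first-day marginal
  ## times one-step transition probabilities over the day gaps
  fx <- markov_fixture()
  bank <- default_item_bank(derive_seed(707L, 4L))
  pars <- list(r_max_drug = -0.16, r_max_placebo = 0.18, t_r_drug = 54.8,
               t_r_placebo = 51.1, omega2_psi0 = 0, omega2_r_max = 0,
               omega2_t_r = 0, met0 = 8, met_slope = 0, omega2_met = 0)
  ofv <- longitudinal_ofv(fx$data, bank, model = "step", markov = TRUE,
                          params = pars)
  traj <- trajectory_parameters("step",
                                drug = list(r_max = -0.16, t_r = 54.8),
                                placebo = list(r_max = 0.18, t_r = 51.1))
  met_const <- 8                      # met0 = 8, zero slope
  w <- fx$data$data
  oracle <- 0
  for (id in unique(w$subject_id)) {
    di <- w[w$subject_id == id, ]
    di <- di[order(di$day), ]
    for (m in seq_len(nrow(di))) {
      psi <- trajectory_value(traj, list(), di$day[m], di$arm[1])
      for (j in 1:14) {
        it <- bank_item(bank, j)
        y <- di[[paste0("i", j)]][m]
        if (m == 1) {
          oracle <- oracle +
            log(category_probabilities(it, psi)[[y + 1L]])
        } else {
          P <- transition_matrix(it, psi, di$day[m] - di$day[m - 1],
                                 met_const)
          oracle <- oracle +
            log(P[di[[paste0("i", j)]][m - 1] + 1L, y + 1L])
        }
      }
    }
  }
  expect_equal(ofv, -2 * oracle, tolerance = 1e-8)
})

test_that("step-2 objective is invariant to subject relabeling and to the
           arm-swap symmetry", {
  fx <- markov_fixture()
  bank <- default_item_bank(derive_seed(707L, 4L))
  pars <- list(r_max_drug = -0.2, r_max_placebo = 0.1, t_r_drug = 30,
               t_r_placebo = 25, omega2_psi0 = 1, omega2_r_max = 0.05,
               omega2_t_r = 0.1, met0 = 8, met_slope = 0,
               omega2_met = 0.05)
  o1 <- longitudinal_ofv(fx$data, bank, "step", TRUE, pars)

  ## permute subject labels
  w <- fx$data$data
  ids <- unique(w$subject_id)
  perm <- setNames(sample(ids), ids)
  w2 <- w
  w2$subject_id <- unname(perm[w$subject_id])
  o2 <- longitudinal_ofv(diary_dataset(w2), bank, "step", TRUE, pars)
  expect_equal(o2, o1, tolerance = 1e-9)

  ## swap arm labels and the arm parameter blocks together
  w3 <- w
  w3$arm <- ifelse(w$arm == "drug", "placebo", "drug")
  pars_swap <- pars
  pars_swap[c("r_max_drug", "r_max_placebo")] <-
    pars[c("r_max_placebo", "r_max_drug")]
  pars_swap[c("t_r_drug", "t_r_placebo")] <-
    pars[c("t_r_placebo", "t_r_drug")]
  o3 <- longitudinal_ofv(diary_dataset(w3), bank, "step", TRUE, pars_swap)
  expect_equal(o3, o1, tolerance = 1e-9)
})

test_that("model comparison applies the LRT and AIC rules", {
  mkfit <- function(ofv, np, label) {
    structure(list(type = "longitudinal", model = label, markov_on = FALSE,
                   ofv = ofv, n_params = np, data_fingerprint = "abc"),
              class = "irm_fit")
  }
  ## boundary: delta OFV exactly the 5% chi-square(1) quantile -> simpler
  cmp <- compare_models(list(mkfit(100, 3, "simple"),
                             mkfit(100 - qchisq(0.95, 1), 4, "complex")),
                        nested = TRUE)
  expect_equal(cmp$selected, 1)
  ## delta OFV 10 on 2 df: p ~ 0.0067 -> complex wins
  cmp2 <- compare_models(list(mkfit(100, 3, "simple"),
                              mkfit(90, 5, "complex")), nested = TRUE)
  expect_equal(cmp2$selected, 2)
  expect_equal(cmp2$table$p_value[2], pchisq(10, 2, lower.tail = FALSE))
  ## identical OFV, fewer parameters wins on AIC
  cmp3 <- compare_models(list(mkfit(100, 3, "lean"), mkfit(100, 6, "fat")))
  expect_equal(cmp3$selected, 1)
  ## refuses different datasets
  f2 <- mkfit(1, 1, "other")
  f2$data_fingerprint <- "zzz"
  expect_error(compare_models(list(mkfit(1, 1, "a"), f2)), "different")
})

test_that("small-scale longitudinal recovery stays within its intervals", {
  ## scaled-down replicate study (full-size recovery is in acceptance):
  ## 12 subjects/arm, 40 days, no Markov layer, paper-magnitude effects
  ## scaled up so the small sample still identifies them
  reps <- 3
  hits <- misses <- 0
  for (r in seq_len(reps)) {
    cfg <- trial_config(
      n_drug = 12, n_placebo = 12, horizon_days = 40,
      trajectory = trajectory_parameters(
        "step", drug = list(r_max = -0.8, t_r = 15),
        placebo = list(r_max = 0.6, t_r = 12),
        iiv = list(psi0 = 1, r_max = 0.05, t_r = 0.05)),
      markov = markov_parameters(1e-3, 0, 0, horizon = 40),
      miss_rate = 0, dropout_frac = 0, seed = 800L + r)
    g <- generate_trial(cfg)
    bank <- default_item_bank(derive_seed(800L + r, 4L))
    f <- fit_longitudinal(g$data, bank, model = "step", markov = FALSE,
                          se = TRUE)
    truth <- c(r_max_drug = -0.8, r_max_placebo = 0.6, t_r_drug = 15,
               t_r_placebo = 12)
    z <- abs(f$estimates[names(truth)] - truth) / f$se[names(truth)]
    hits <- hits + sum(z <= 3)
    misses <- misses + sum(z > 3)
  }
  expect_gte(hits / (hits + misses), 0.8)
})
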