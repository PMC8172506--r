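## Shared fixtures, memoised so expensive generation happens once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_fixture <- function() cached("tiny", make_fixture("tiny-2x3"))

## absolute-tolerance comparison (testthat's default tolerance is relative,
## which is too strict for printed two-decimal probabilities)
expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol)
}

markov_fixture <- function() cached("markov", make_fixture("markov-strong"))

## a small, fast item bank used in hand-computed checks
toy_item <- function(a = 1, b = c(-1, 0, 1)) list(a = a, b = b, K = length(b))

## complete wide responses helper: all items at a given value (clipped to
## each item's maximum)
flat_responses <- function(value) {
  pmin(rep(value, 14), exact_items()$max_score)
}

## data generated under the step-1 world itself: independent occasions,
## baseline psi ~ N(0,1), later psi ~ N(mu, omega2)
independent_occasions <- function(bank, n_base, n_later, mu, omega2, seed) {
  set.seed(seed)
  n <- n_base + n_later
  psi <- c(stats::rnorm(n_base), mu + sqrt(omega2) * stats::rnorm(n_later))
  day <- c(rep(0L, n_base), rep(1L, n_later))
  w <- data.frame(subject_id = sprintf("O%05d", seq_len(n)),
                  arm = "drug", day = day, stringsAsFactors = FALSE)
  for (j in 1:14) {
    it <- bank_item(bank, j)
    pr <- category_probabilities(it, psi)
    cum <- pr %*% upper.tri(diag(it$K + 1), diag = TRUE)
    w[[paste0("i", j)]] <-
      as.integer(rowSums(stats::runif(n) > cum[, seq_len(it$K),
                                              drop = FALSE]))
  }
  diary_dataset(w)
}

## ground-truth parameters of the recovery fixture, as named vectors
recovery_truth <- function() {
  c(r_max_drug = -0.16, r_max_placebo = 0.18,
    t_r_drug = 54.8, t_r_placebo = 51.1,
    omega2_psi0 = 1, omega2_r_max = 0.05, omega2_t_r = 0.1,
    met0 = 1.23, met_slope = (3.09 - 1.23) / 365, omega2_met = 0.1)
}

recovery_bank <- function() default_item_bank(derive_seed(404L, 4L))
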