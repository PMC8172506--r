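## The decision-confidence layer: sample-size ratio, go/stop probability
## tables under a mixture prior on the true effect, PPV/NPV, power
## functions and ROC/AUC - with closed-form counterparts for everything
## the Monte-Carlo routines compute.
##
## Sign conventions: benefit is negative (scores fall when symptoms
## improve); the go rule declares efficacy when the estimated arm
## difference is at or below the target value TV, so
## P(Go | Delta) = pnorm((TV - Delta) / sigma) - more-negative true
## effects increase the go probability.

#' Squared-ratio sample-size comparison
#'
#' The sample-size multiplier for a reference method to match an
#' alternative method's precision, treating each 95% CI width as the
#' desired margin of error: `N = (width_ref / width_alt)^2`.
#'
#' @param ci_width_reference,ci_width_alternative CI widths (> 0).
#' @return the fold-change in required sample size.
#' @export
sample_size_ratio <- function(ci_width_reference, ci_width_alternative) {
  check_scalar(ci_width_reference, "ci_width_reference", 0,
               strict_lower = TRUE)
  check_scalar(ci_width_alternative, "ci_width_alternative", 0,
               strict_lower = TRUE)
  (ci_width_reference / ci_width_alternative)^2
}

#' CI width and the SD it implies
#'
#' `ci_width` is `upper - lower`; `sd_from_ci` assumes an equal-tailed
#' normal 95% interval, `sigma = width / (2 * qnorm(0.975))`.
#'
#' @param lower,upper interval bounds (`upper > lower`).
#' @return width, respectively sigma.
#' @export
ci_width <- function(lower, upper) {
  if (upper <= lower) stop("upper must exceed lower", call. = FALSE)
  upper - lower
}

#' @rdname ci_width
#' @export
sd_from_ci <- function(lower, upper) {
  ci_width(lower, upper) / (2 * stats::qnorm(0.975))
}

#' Go / stop probability at a given true effect
#'
#' `p_go(delta) = pnorm((tv - delta) / sigma_delta)`: the probability that
#' the estimated arm difference lands at or below the target value when
#' the true effect is `delta`.  `p_stop` is its complement.
#'
#' @param delta true arm difference (score units; negative = benefit).
#' @param sigma_delta SD of the estimated arm difference (> 0).
#' @param tv target value (score units).
#' @return probability (vectorised over `delta`).
#' @export
p_go <- function(delta, sigma_delta, tv) {
  check_scalar(sigma_delta, "sigma_delta", 0, strict_lower = TRUE)
  stats::pnorm((tv - delta) / sigma_delta)
}

#' @rdname p_go
#' @export
p_stop <- function(delta, sigma_delta, tv) 1 - p_go(delta, sigma_delta, tv)

#' Decision inputs
#'
#' Bundles the target value, the decision SD and the mixture prior for the
#' true effect: probability `w0` of no effect (point mass at zero) and
#' `1 - w0` of a normally distributed effect centred at the target value.
#'
#' @param tv target value (negative = benefit threshold).
#' @param sigma_delta SD of the estimated arm difference for the method.
#' @param w0 mixture weight of the no-effect point mass.
#' @param prior_sd SD of the effective-compound component.
#' @param n_samples Monte-Carlo sample count for [decision_table_mc()].
#' @param seed integer seed.
#' @return a list of class `decision_inputs`.
#' @export
decision_inputs <- function(tv, sigma_delta, w0 = 0.8, prior_sd = 1,
                            n_samples = 10000, seed = 1L) {
  check_scalar(tv, "tv")
  check_scalar(sigma_delta, "sigma_delta", 0, strict_lower = TRUE)
  check_scalar(w0, "w0", 0, 1)
  check_scalar(prior_sd, "prior_sd", 0, strict_lower = TRUE)
  check_scalar(n_samples, "n_samples", 1)
  structure(list(tv = tv, sigma_delta = sigma_delta, w0 = w0,
                 w1 = 1 - w0, prior_sd = prior_sd,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)), class = "decision_inputs")
}

.decision_table <- function(cg, ig, cs, is, inputs, method) {
  pgo <- cg + ig
  pstop <- cs + is
  tab <- list(p_correct_go = cg, p_incorrect_go = ig,
              p_correct_stop = cs, p_incorrect_stop = is,
              p_go = pgo, p_stop = pstop,
              ppv = if (pgo > 0) cg / pgo else {
                warning("p_go = 0: PPV undefined")
                NA_real_
              },
              npv = if (pstop > 0) cs / pstop else {
                warning("p_stop = 0: NPV undefined")
                NA_real_
              },
              inputs = inputs, method = method)
  class(tab) <- "decision_table"
  tab
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("decision_table (%s): TV = %g, sigma = %g\n", x$method,
              x$inputs$tv, x$inputs$sigma_delta))
  m <- matrix(c(x$p_correct_stop, x$p_incorrect_stop,
                x$p_incorrect_go, x$p_correct_go), 2, 2,
              dimnames = list(c("true > TV", "true <= TV"),
                              c("stop", "go")))
  print(round(m, 3))
  cat(sprintf("P(Go) = %.3f, P(Stop) = %.3f, PPV = %.3f, NPV = %.3f\n",
              x$p_go, x$p_stop, x$ppv, x$npv))
  invisible(x)
}

#' Monte-Carlo decision probability table
#'
#' Draws the true effect from the mixture prior, an estimated effect from
#' `Normal(true, sigma_delta)`, applies the inclusive go rule
#' (estimate <= TV), and classifies the four outcomes by whether the true
#' effect is at or beyond TV.
#'
#' @param inputs a [decision_inputs()].
#' @return a `decision_table` with the four joint probabilities, the go and
#'   stop margins and PPV/NPV.
#' @export
decision_table_mc <- function(inputs) {
  stopifnot(inherits(inputs, "decision_inputs"))
  set.seed(derive_seed(inputs$seed, 11L))
  n <- inputs$n_samples
  effective <- stats::runif(n) >= inputs$w0
  delta_t <- numeric(n)
  delta_t[effective] <- stats::rnorm(sum(effective), inputs$tv,
                                     inputs$prior_sd)
  est <- stats::rnorm(n, delta_t, inputs$sigma_delta)
  go <- est <= inputs$tv
  pos <- delta_t <= inputs$tv
  .decision_table(mean(go & pos), mean(go & !pos),
                  mean(!go & !pos), mean(!go & pos),
                  inputs, "mc")
}

#' Closed-form decision probability table
#'
#' Exact cells by integrating the go probability over each mixture
#' component: the point-mass component contributes
#' `w0 * pnorm((tv - 0) / sigma)` to go, and the normal component is
#' integrated numerically over the regions above/below TV.  Serves as the
#' deterministic oracle for [decision_table_mc()].
#'
#' @param inputs a [decision_inputs()].
#' @return a `decision_table`.
#' @export
decision_table_analytic <- function(inputs) {
  stopifnot(inherits(inputs, "decision_inputs"))
  tv <- inputs$tv
  s <- inputs$sigma_delta
  go_at <- function(u) stats::pnorm((tv - u) / s)
  dens <- function(u) stats::dnorm(u, tv, inputs$prior_sd)
  int <- function(f, lower, upper)
    stats::integrate(f, lower, upper, rel.tol = 1e-10,
                     abs.tol = 1e-12)$value
  ## normal component split at TV
  go_below <- int(function(u) dens(u) * go_at(u), -Inf, tv)
  go_above <- int(function(u) dens(u) * go_at(u), tv, Inf)
  mass_below <- int(dens, -Inf, tv)        # = 1/2 when centred at TV
  mass_above <- 1 - mass_below
  point_pos <- 0 <= tv                     # is "no effect" at/beyond TV?
  cg <- inputs$w1 * go_below + inputs$w0 * point_pos * go_at(0)
  ig <- inputs$w1 * go_above + inputs$w0 * (!point_pos) * go_at(0)
  cs <- inputs$w1 * (mass_above - go_above) +
    inputs$w0 * (!point_pos) * (1 - go_at(0))
  is <- inputs$w1 * (mass_below - go_below) +
    inputs$w0 * point_pos * (1 - go_at(0))
  .decision_table(cg, ig, cs, is, inputs, "analytic")
}

#' Positive / negative predictive value of a decision table
#'
#' `ppv = P(correct go) / P(go)`; `npv = P(correct stop) / P(stop)`.
#'
#' @param table a `decision_table`.
#' @return probability in `[0, 1]` (or `NA` with a warning when the
#'   denominator is zero).
#' @export
ppv <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  table$ppv
}

#' @rdname ppv
#' @export
npv <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  table$npv
}

#' Power curve and the effect needed for a target power
#'
#' `power_curve` evaluates the go probability over a grid of true effects.
#' `power_threshold` inverts it in closed form:
#' `delta = tv - sigma * qnorm(target_power)`.
#'
#' @param sigma_delta decision SD (> 0).
#' @param tv target value.
#' @param delta grid of true effects (must straddle `tv`).
#' @param target_power desired go probability, in (0, 1).
#' @return `power_curve`: data.frame `delta`, `p_go`, `p_stop`;
#'   `power_threshold`: the true effect giving the target go probability.
#' @export
power_curve <- function(sigma_delta, tv, delta) {
  if (min(delta) > tv || max(delta) < tv)
    stop("delta grid must cover the target value", call. = FALSE)
  pg <- p_go(delta, sigma_delta, tv)
  data.frame(delta = delta, p_go = pg, p_stop = 1 - pg)
}

#' @rdname power_curve
#' @export
power_threshold <- function(sigma_delta, tv, target_power) {
  check_scalar(sigma_delta, "sigma_delta", 0, strict_lower = TRUE)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must be in (0, 1)", call. = FALSE)
  tv - sigma_delta * stats::qnorm(target_power)
}

#' Per-method endpoint summary for ROC construction
#'
#' @param mean endpoint mean (score units).
#' @param se its standard error (> 0).
#' @return a `method_summary`.
#' @export
method_summary <- function(mean, se) {
  check_scalar(mean, "mean")
  check_scalar(se, "se", 0, strict_lower = TRUE)
  structure(list(mean = mean, se = se), class = "method_summary")
}

#' ROC curve and AUC for discriminating the treatment arms
#'
#' Treats each arm's endpoint estimate as `Normal(mean, se)`, classifies
#' "drug" when the value is at or below a sweeping threshold (lower scores
#' = benefit), and reports the empirical ROC and AUC from paired samples
#' with a percentile-bootstrap 95% CI.  The closed-form AUC
#' `pnorm(|mean_drug - mean_placebo| / sqrt(se_d^2 + se_p^2))` is included
#' as `auc_closed_form`.
#'
#' @param drug,placebo [method_summary()] objects.
#' @param n_draws Monte-Carlo draws per arm.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param n_thresholds grid size of the reported ROC curve.
#' @return list of class `roc_result`: `curve` (data.frame `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_ci`, `auc_closed_form`.
#' @export
roc_and_auc <- function(drug, placebo, n_draws = 10000, seed = 1L,
                        n_boot = 2000, n_thresholds = 201) {
  stopifnot(inherits(drug, "method_summary"),
            inherits(placebo, "method_summary"))
  set.seed(derive_seed(seed, 12L))
  xd <- stats::rnorm(n_draws, drug$mean, drug$se)
  xp <- stats::rnorm(n_draws, placebo$mean, placebo$se)
  ## orient so the drug arm is the lower-scoring (positive) class
  flip <- drug$mean > placebo$mean
  if (flip) {
    tmp <- xd
    xd <- xp
    xp <- tmp
  }
  thr <- stats::quantile(c(xd, xp),
                         probs = seq(0, 1, length.out = n_thresholds),
                         names = FALSE)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(cc) mean(xd <= cc), numeric(1)),
    specificity = vapply(thr, function(cc) mean(xp > cc), numeric(1)))
  auc_emp <- function(a, b) {
    r <- rank(c(a, b))
    (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
      (length(a) * length(b))
  }
  ## P(drug draw below placebo draw): rank-sum on the placebo side
  auc <- auc_emp(xp, xd)
  boot <- vapply(seq_len(n_boot), function(b) {
    auc_emp(sample(xp, replace = TRUE), sample(xd, replace = TRUE))
  }, numeric(1))
  closed <- stats::pnorm(abs(drug$mean - placebo$mean) /
                           sqrt(drug$se^2 + placebo$se^2))
  structure(list(curve = curve, auc = auc,
                 auc_ci = unname(stats::quantile(boot, c(0.025, 0.975))),
                 auc_closed_form = closed, n_draws = n_draws,
                 flipped = flip), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (95%% CI %.3f-%.3f), closed form %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$auc_closed_form))
  invisible(x)
}
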