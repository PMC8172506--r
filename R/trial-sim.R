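## Propagation of parameter uncertainty into the end-of-trial endpoint:
## sample parameter vectors from their estimation-uncertainty distribution,
## simulate large virtual trials at the evaluation window, and summarise
## the distribution of arm differences in mean total score.

#' Degrees of freedom for a scalar inverse-Wishart from a standard error
#'
#' The standard SE-matching rule for the scalar (inverse-chi-square) case:
#' `df = 2 * (omega2 / se)^2 + 1`.
#'
#' @param omega2 variance estimate (> 0).
#' @param se its standard error (> 0).
#' @param cap upper bound returned (with a warning) when `se` is so small
#'   that the prior degenerates to a point mass.
#' @return degrees of freedom (> 1).
#' @export
df_from_se <- function(omega2, se, cap = 1e6) {
  check_scalar(omega2, "omega2", 0, strict_lower = TRUE)
  check_scalar(se, "se", 0)
  if (se == 0) {
    warning("se = 0: degrees of freedom capped at ", cap)
    return(cap)
  }
  df <- 2 * (omega2 / se)^2 + 1
  if (df > cap) {
    warning("degrees of freedom capped at ", cap)
    df <- cap
  }
  df
}

#' Build an uncertainty specification from a step-2 fit
#'
#' Fixed effects get a multivariate-normal uncertainty distribution with
#' the fit's asymptotic covariance; each random-effect variance gets a
#' scaled inverse-chi-square with degrees of freedom matched to its
#' standard error ([df_from_se()]).  Item parameters are carried at their
#' point estimates (they were fixed in step 2).
#'
#' @param fit a longitudinal `irm_fit` with standard errors.
#' @param fixed_cov optional replacement covariance for the fixed effects.
#' @return object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(fit, fixed_cov = NULL) {
  stopifnot(inherits(fit, "irm_fit"), identical(fit$type, "longitudinal"))
  if (is.null(fit$covariance) && is.null(fixed_cov))
    stop("fit carries no covariance; rerun fit_longitudinal(se = TRUE)",
         call. = FALSE)
  est <- fit$estimates[fit$free]
  is_var <- grepl("^omega2_", names(est))
  fixed <- est[!is_var]
  vars <- est[is_var]
  cov_f <- if (!is.null(fixed_cov)) fixed_cov else
    fit$covariance[names(fixed), names(fixed), drop = FALSE]
  if (any(eigen(make_psd(cov_f), symmetric = TRUE,
                only.values = TRUE)$values < -1e-8))
    stop("fixed-effect covariance is not positive semi-definite",
         call. = FALSE)
  dfs <- vapply(names(vars), function(nm) {
    se <- if (!is.null(fit$se)) fit$se[[nm]] else NA_real_
    if (is.na(se) || se <= 0) Inf else df_from_se(vars[[nm]], se)
  }, numeric(1))
  structure(list(fixed = fixed, fixed_cov = make_psd(cov_f),
                 variances = vars, df = dfs,
                 model = fit$model, markov_on = fit$markov_on,
                 fix = fit$fix, bank = fit$bank,
                 source_ofv = fit$ofv), class = "uncertainty_spec")
}

#' Manually assembled uncertainty specification
#'
#' Same shape as [uncertainty_spec()] but with every component supplied
#' explicitly - used for synthetic ground-truth parameters or scaled-down
#' tests.
#'
#' @param fixed named vector of fixed-effect estimates.
#' @param fixed_cov their covariance matrix (PSD, matching order).
#' @param variances named vector of variance components (`omega2_*`).
#' @param df degrees of freedom per variance (same length; `Inf` = fixed).
#' @param model,markov_on,bank,fix model template (see
#'   [fit_longitudinal()]).
#' @return an `uncertainty_spec`.
#' @export
manual_uncertainty_spec <- function(fixed, fixed_cov, variances, df,
                                    model, markov_on, bank, fix = list()) {
  stopifnot(length(df) == length(variances),
            nrow(fixed_cov) == length(fixed))
  structure(list(fixed = fixed, fixed_cov = make_psd(fixed_cov),
                 variances = variances, df = df, model = model,
                 markov_on = markov_on, fix = fix,
                 bank = .check_bank(bank), source_ofv = NA_real_),
            class = "uncertainty_spec")
}

#' Draw one parameter set from its uncertainty distribution
#'
#' Fixed effects are multivariate normal around the estimates; each
#' variance is scaled inverse-chi-square (`v_hat * df / chisq(df)`).
#' Draws violating the parameter domain (non-positive response times,
#' MET, gamma) are rejected and redrawn.
#'
#' @param spec an [uncertainty_spec()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return named vector of natural-scale parameters (fixed effects and
#'   variances combined).
#' @export
sample_parameters <- function(spec, seed, max_tries = 200) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  set.seed(derive_seed(seed, 8L))
  p <- length(spec$fixed)
  degenerate <- max(abs(spec$fixed_cov)) == 0   # point mass: exact values
  R <- if (degenerate) NULL else chol(spec$fixed_cov + diag(1e-12, p))
  positive <- grepl("^(t_r|t_prog|met0|gamma)", names(spec$fixed))
  for (try in seq_len(max_tries)) {
    fx <- if (degenerate) spec$fixed else
      spec$fixed + as.numeric(stats::rnorm(p) %*% R)
    if (all(fx[positive] > 0)) break
    if (try == max_tries)
      stop("could not draw a valid fixed-effect vector", call. = FALSE)
  }
  names(fx) <- names(spec$fixed)
  vs <- mapply(function(v, d) {
    if (!is.finite(d)) return(v)
    v * d / stats::rchisq(1, df = d)
  }, spec$variances, spec$df)
  names(vs) <- names(spec$variances)
  c(fx, vs)
}

## rebuild trajectory/markov objects from a named natural parameter vector
.components_from_estimates <- function(model, markov_on, est, fix,
                                       horizon) {
  for (nm in names(fix)) est[[nm]] <- fix[[nm]]
  layout <- .step2_layout(model, markov_on)
  p1 <- layout$p1
  p2 <- layout$p2
  fxarm <- function(arm) {
    out <- list()
    out[[p1]] <- est[[paste0(p1, "_", arm)]]
    if (layout$has_p2) out[[p2]] <- est[[paste0(p2, "_", arm)]]
    if (model %in% c("power", "weibull")) out$gamma <- est[["gamma"]]
    out
  }
  iiv <- list(psi0 = est[["omega2_psi0"]])
  iiv[[p1]] <- est[[paste0("omega2_", p1)]]
  if (layout$has_p2) iiv[[p2]] <- est[[paste0("omega2_", p2)]]
  iiv <- iiv[vapply(iiv, function(v) !is.null(v) && v > 0, logical(1))]
  traj <- trajectory_parameters(model, drug = fxarm("drug"),
                                placebo = fxarm("placebo"), iiv = iiv)
  mk <- if (markov_on)
    markov_parameters(est[["met0"]], est[["met_slope"]],
                      est[["omega2_met"]] %||% 0, horizon = horizon)
  else NULL
  list(trajectory = traj, markov = mk)
}

## latent status for many subjects at a shared day grid (n x D matrix)
.psi_matrix <- function(traj, effects, arms, days) {
  n <- length(arms)
  D <- length(days)
  eff <- function(nm) if (!is.null(effects[[nm]])) effects[[nm]] else
    rep(0, n)
  psi <- matrix(0, n, D)
  for (arm in c("drug", "placebo")) {
    sel <- arms == arm
    if (!any(sel)) next
    fx <- traj$fixed[[arm]]
    psi0 <- eff("psi0")[sel]
    psi[sel, ] <- switch(traj$model,
      linear = psi0 + outer(fx$slope + eff("slope")[sel], days),
      power = psi0 + outer(fx$slope + eff("slope")[sel], days^fx$gamma),
      asymptotic = {
        tp <- fx$t_prog * exp(eff("t_prog")[sel])
        rm_ <- fx$r_max + eff("r_max")[sel]
        frac <- 1 - exp(-outer(log(2) / tp, days))
        psi0 + (rm_ - psi0) * frac
      },
      weibull = {
        tp <- fx$t_prog * exp(eff("t_prog")[sel])
        rm_ <- fx$r_max + eff("r_max")[sel]
        psi0 + rm_ * (1 - exp(-outer(log(2) / tp, days)^fx$gamma))
      },
      step = {
        tr <- fx$t_r * exp(eff("t_r")[sel])
        rm_ <- fx$r_max + eff("r_max")[sel]
        psi0 + rm_ * outer(tr, days, function(a, t) t > a)
      })
  }
  psi
}

## batch diary simulation on a short shared day grid; returns per-scale
## per-subject window means (n x n_scales)
.simulate_window_scores <- function(bank, traj, markov, effects, arms,
                                    days, seed, score_map = NULL) {
  set.seed(derive_seed(seed, 9L))
  n <- length(arms)
  D <- length(days)
  psi <- .psi_matrix(traj, effects, arms, days)
  eta_met <- if (!is.null(effects$eta_met)) effects$eta_met else rep(0, n)
  rs <- matrix(0, n, D)
  sub <- list(breathlessness = matrix(0, n, D),
              cough_sputum = matrix(0, n, D),
              chest_symptoms = matrix(0, n, D))
  raw <- matrix(0, n, D)
  members <- .subscale_members
  for (j in 1:14) {
    it <- bank_item(bank, j)
    ## elementwise category draw: u against cumulative curves
    cum_lt <- matrix(1, n, D)           # P(y <= K) = 1 built downward
    u <- matrix(stats::runif(n * D), n, D)
    yfresh <- matrix(0L, n, D)
    for (k in seq_len(it$K)) {
      ## P(y <= k - 1) = 1 - P(y >= k)
      ple <- 1 - stats::plogis(it$a * (psi - it$b[k]))
      yfresh <- yfresh + (u > ple)
    }
    if (!is.null(markov) && D > 1) {
      keep <- matrix(FALSE, n, D)
      dts <- diff(days)
      for (m in 2:D) {
        met_i <- met_at(markov, days[m]) * exp(eta_met)
        keep[, m] <- stats::runif(n) < exp(-dts[m - 1] / met_i)
      }
      idx <- matrix(1L, n, D)
      for (m in 2:D) idx[, m] <- ifelse(keep[, m], idx[, m - 1], m)
      y <- matrix(yfresh[cbind(rep(seq_len(n), D), as.integer(idx))], n, D)
    } else {
      y <- yfresh
    }
    raw <- raw + y
    if (j <= 11) rs <- rs + y
    for (s in names(members)) if (j %in% members[[s]])
      sub[[s]] <- sub[[s]] + y
  }
  out <- data.frame(rs_total = rowMeans(rs),
                    breathlessness = rowMeans(sub$breathlessness),
                    cough_sputum = rowMeans(sub$cough_sputum),
                    chest_symptoms = rowMeans(sub$chest_symptoms))
  if (!is.null(score_map)) {
    m <- .check_score_map(score_map)
    ex <- matrix(m$measure[raw + 1L], n, D)
    out$exact_total <- rowMeans(ex)
  }
  out
}

#' Simulate the end-of-trial endpoint distribution under uncertainty
#'
#' For each replicate: draw a parameter vector from the uncertainty
#' distribution, simulate `n_subj` subjects per arm over the evaluation
#' window, and record the arm difference (drug minus placebo) in mean
#' total score per scale.  The 95% CI is the 2.5th-97.5th percentile range
#' of the replicate differences and `sd_delta` their standard deviation -
#' the sigma_Delta consumed by the decision layer.
#'
#' @param spec an [uncertainty_spec()] (or [manual_uncertainty_spec()]).
#' @param n_subj subjects per arm per replicate.
#' @param n_rep number of replicates.
#' @param eval_window days over which each subject's score is averaged.
#' @param score_map optional map to also report the EXACT-Total scale.
#' @param seed integer seed.
#' @return object of class `endpoint_distribution`: matrix `differences`
#'   (`n_rep` x scales), `summary` (mean, CI bounds, ci_width, sd_delta
#'   per scale), and the design metadata.
#' @export
simulate_endpoint_distribution <- function(spec, n_subj = 5000,
                                           n_rep = 2000,
                                           eval_window = 351:365,
                                           score_map = NULL, seed = 1L) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  scales <- c("rs_total", "breathlessness", "cough_sputum",
              "chest_symptoms", if (!is.null(score_map)) "exact_total")
  diffs <- matrix(NA_real_, n_rep, length(scales),
                  dimnames = list(NULL, scales))
  horizon <- max(eval_window)
  arms <- rep(c("drug", "placebo"), each = n_subj)
  for (r in seq_len(n_rep)) {
    pars <- sample_parameters(spec, derive_seed(seed, 5000L + r))
    comp <- .components_from_estimates(spec$model, spec$markov_on,
                                       as.list(pars), spec$fix, horizon)
    effects <- draw_subject_effects(comp$trajectory, comp$markov,
                                    2L * n_subj,
                                    derive_seed(seed, 6000L + r))
    sc <- .simulate_window_scores(spec$bank, comp$trajectory, comp$markov,
                                  effects, arms, eval_window,
                                  derive_seed(seed, 7000L + r), score_map)
    for (s in scales)
      diffs[r, s] <- mean(sc[[s]][arms == "drug"]) -
        mean(sc[[s]][arms == "placebo"])
  }
  qs <- apply(diffs, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(scale = scales,
                        mean = colMeans(diffs),
                        median = qs[2, ],
                        ci_lo = qs[1, ], ci_hi = qs[3, ],
                        ci_width = qs[3, ] - qs[1, ],
                        sd_delta = apply(diffs, 2, stats::sd),
                        row.names = NULL)
  structure(list(differences = diffs, summary = summary, n_rep = n_rep,
                 n_subj = n_subj, eval_window = eval_window),
            class = "endpoint_distribution")
}

#' @export
print.endpoint_distribution <- function(x, ...) {
  cat(sprintf("endpoint_distribution: %d replicates, %d subjects/arm, days %d-%d\n",
              x$n_rep, x$n_subj, min(x$eval_window), max(x$eval_window)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Persist an endpoint distribution
#'
#' Replicate differences as tidy CSV and the summary as JSON.
#' @param x an `endpoint_distribution`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_endpoint_distribution <- function(x, csv_path = NULL,
                                        json_path = NULL) {
  stopifnot(inherits(x, "endpoint_distribution"))
  if (!is.null(csv_path)) {
    df <- data.frame(replicate = rep(seq_len(x$n_rep),
                                     ncol(x$differences)),
                     scale = rep(colnames(x$differences),
                                 each = x$n_rep),
                     difference = as.numeric(x$differences))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(x$summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(x)
}
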