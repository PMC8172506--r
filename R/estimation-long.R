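## Step 2 of the two-step fit: the longitudinal latent-variable model with
## item characteristic functions fixed from step 1, plus likelihood-based
## model comparison.

## assemble the per-subject data structures handed to the compiled likelihood
.step2_subjects <- function(data) {
  w <- data$data
  ids <- data$subjects$subject_id
  lapply(seq_along(ids), function(i) {
    di <- w[w$subject_id == ids[i], , drop = FALSE]
    list(days = as.numeric(di$day),
         Y = as.matrix(di[, paste0("i", 1:14)]),
         arm = if (data$subjects$arm[i] == "drug") 0L else 1L)
  })
}

.bank_cpp <- function(bank) {
  bank <- .check_bank(bank)
  b <- as.matrix(bank[, paste0("b", 1:4)])
  b[is.na(b)] <- 0
  list(a = bank$a, b = b, K = as.integer(bank$K))
}

## free-parameter bookkeeping: names, transforms, defaults
.step2_layout <- function(model, markov) {
  has_p2 <- model %in% c("asymptotic", "weibull", "step")
  p1 <- if (model %in% c("linear", "power")) "slope" else "r_max"
  p2 <- switch(model, asymptotic = "t_prog", weibull = "t_prog",
               step = "t_r", NULL)
  nm <- c(paste0(p1, "_drug"), paste0(p1, "_placebo"))
  tr <- c("id", "id")
  if (has_p2) {
    nm <- c(nm, paste0(p2, "_drug"), paste0(p2, "_placebo"))
    tr <- c(tr, "log", "log")
  }
  if (model %in% c("power", "weibull")) {
    nm <- c(nm, "gamma")
    tr <- c(tr, "log")
  }
  nm <- c(nm, "omega2_psi0", paste0("omega2_", p1))
  tr <- c(tr, "log", "log")
  if (has_p2) {
    nm <- c(nm, paste0("omega2_", p2))
    tr <- c(tr, "log")
  }
  if (markov) {
    nm <- c(nm, "met0", "met_slope", "omega2_met")
    tr <- c(tr, "log", "id", "log")
  }
  list(names = nm, transform = tr, p1 = p1, p2 = p2, has_p2 = has_p2)
}

## map a named natural-parameter vector onto the fixed-size theta the C++
## likelihood expects
.step2_theta <- function(nat, layout, model) {
  th <- numeric(11)
  p1 <- layout$p1
  p2 <- layout$p2
  th[1] <- nat[[paste0(p1, "_drug")]]
  th[2] <- nat[[paste0(p1, "_placebo")]]
  if (layout$has_p2) {
    th[3] <- nat[[paste0(p2, "_drug")]]
    th[4] <- nat[[paste0(p2, "_placebo")]]
  }
  th[5] <- if (!is.null(nat[["gamma"]])) nat[["gamma"]] else 1
  th[6] <- nat[["omega2_psi0"]]
  th[7] <- nat[[paste0("omega2_", p1)]]
  th[8] <- if (layout$has_p2) nat[[paste0("omega2_", p2)]] else 0
  if (!is.null(nat[["met0"]])) {
    th[9] <- nat[["met0"]]
    th[10] <- nat[["met_slope"]]
    th[11] <- nat[["omega2_met"]]
  }
  th
}

.to_nat <- function(x, tr) ifelse(tr == "log", exp(x), x)
.to_trans <- function(x, tr) ifelse(tr == "log", log(pmax(x, 1e-12)), x)

## crude derivative of the expected RS-Total wrt psi, used for start values
.dscore_dpsi <- function(bank, psi = 0, items = 1:11) {
  E <- function(p) sum(vapply(items, function(j) {
    it <- bank_item(bank, j)
    sum(stats::plogis(it$a * (p - it$b)))
  }, numeric(1)))
  (E(psi + 0.1) - E(psi - 0.1)) / 0.2
}

#' Fit the longitudinal latent-variable model (step 2)
#'
#' With the item characteristic functions fixed, maximises the marginal
#' likelihood over the subject-level random effects (per-subject Laplace
#' approximation; for the step model the response-time effect is integrated
#' by Gauss-Hermite quadrature on its lognormal prior because the
#' likelihood is piecewise constant in it).  Arm-specific fixed effects are
#' estimated for everything except the baseline mean, which is fixed at 0.
#' When the Markov layer is on, the likelihood of each present day after a
#' subject's first uses the transition probability over the gap since the
#' previous present day; the first day uses the marginal ICF probability
#' (single-day subjects therefore contribute a marginal term only).
#'
#' @param data a [diary_dataset].
#' @param fixed_icfs an [item_bank] of fixed item parameters (typically the
#'   `bank` of a step-1 [fit_icfs()] result).
#' @param model trajectory kind: `"linear"`, `"power"`, `"asymptotic"`,
#'   `"weibull"` or `"step"`.
#' @param markov include the continuous-time Markov dependence layer?
#' @param fix named list of parameters to hold fixed at given values (a
#'   variance fixed at 0 removes the corresponding random effect), e.g.
#'   `list(omega2_met = 0)`.
#' @param start optional named list of natural-scale starting values.
#' @param quad_nodes Gauss-Hermite nodes for the step-model response-time
#'   effect.
#' @param se compute standard errors (numeric Hessian of the objective on
#'   the transformed scale; adds runtime).
#' @param control passed to [stats::optim()] (method BFGS).
#' @return an `irm_fit` with `estimates` (named natural-scale vector),
#'   `se`, `covariance`, `ofv`, `trajectory` / `markov` objects rebuilt at
#'   the estimates, and convergence diagnostics.
#' @export
fit_longitudinal <- function(data, fixed_icfs, model = "step",
                             markov = TRUE, fix = list(), start = list(),
                             quad_nodes = 9, se = TRUE, control = list()) {
  stopifnot(inherits(data, "diary_dataset"))
  model <- match.arg(model, .traj_models)
  bank <- .check_bank(fixed_icfs)
  layout <- .step2_layout(model, markov)
  subjects <- .step2_subjects(data)
  if (!length(subjects)) stop("no subjects to fit", call. = FALSE)
  bank_cpp <- .bank_cpp(bank)
  gh <- gauss_hermite_normal(quad_nodes)
  model_id <- match(model, .traj_models)

  ## default starting values from the arm-mean score time course
  sc <- score_diary(data)
  horizon <- max(sc$day)
  d1 <- .dscore_dpsi(bank)
  arm_shift <- vapply(c("drug", "placebo"), function(a) {
    s <- sc[sc$arm == a, ]
    if (!nrow(s)) return(0.05)
    pre <- mean(s$rs_total[s$day <= stats::quantile(s$day, 0.2)])
    post <- mean(s$rs_total[s$day >= stats::quantile(s$day, 0.8)])
    (post - pre) / max(d1, 1e-6)
  }, numeric(1))
  arm_shift[abs(arm_shift) < 0.02] <- sign(arm_shift[abs(arm_shift) < 0.02] +
                                             1e-9) * 0.05
  defaults <- list(omega2_psi0 = 1)
  defaults[[paste0(layout$p1, "_drug")]] <-
    if (layout$p1 == "slope") arm_shift[1] / max(horizon, 1) else arm_shift[1]
  defaults[[paste0(layout$p1, "_placebo")]] <-
    if (layout$p1 == "slope") arm_shift[2] / max(horizon, 1) else arm_shift[2]
  defaults[[paste0("omega2_", layout$p1)]] <-
    if (layout$p1 == "slope") (0.3 / max(horizon, 1))^2 else 0.05
  if (layout$has_p2) {
    defaults[[paste0(layout$p2, "_drug")]] <- horizon / 3
    defaults[[paste0(layout$p2, "_placebo")]] <- horizon / 3
    defaults[[paste0("omega2_", layout$p2)]] <- 0.1
  }
  if (model %in% c("power", "weibull")) defaults$gamma <- 1
  if (markov) {
    defaults$met0 <- 1.5
    defaults$met_slope <- 0.002
    defaults$omega2_met <- 0.1
  }
  for (nm in names(start)) defaults[[nm]] <- start[[nm]]

  free <- setdiff(layout$names, names(fix))
  tr_free <- layout$transform[match(free, layout$names)]
  par0 <- .to_trans(unlist(defaults[free]), tr_free)
  names(par0) <- free

  nat_full <- function(par) {
    nat <- as.list(.to_nat(par, tr_free))
    names(nat) <- free
    for (nm in names(fix)) nat[[nm]] <- fix[[nm]]
    nat
  }

  warm_env <- new.env(parent = emptyenv())
  warm_env$modes <- NULL
  ofv_fun <- function(par) {
    nat <- nat_full(par)
    th <- .step2_theta(nat, layout, model)
    if (th[9] < 0 || (markov && th[9] + th[10] * horizon <= 0)) return(1e10)
    res <- cpp_step2_loglik(th, subjects, bank_cpp, model_id, markov,
                            gh$nodes, gh$weights, warm_env$modes)
    warm_env$modes <- res$modes
    -2 * res$loglik
  }

  ctrl <- utils::modifyList(list(maxit = 300, reltol = 1e-10,
                                 ndeps = rep(1e-4, length(par0))), control)
  opt <- stats::optim(par0, ofv_fun, method = "BFGS", control = ctrl)
  est_nat <- unlist(nat_full(opt$par))[layout$names]

  se_vec <- covariance <- NULL
  if (se && length(free)) {
    H <- numeric_hessian(ofv_fun, opt$par, h = 1e-3)
    cov_t <- tryCatch(2 * solve(make_psd(H)), error = function(e) NULL)
    if (!is.null(cov_t)) {
      jac <- diag(ifelse(tr_free == "log", .to_nat(opt$par, tr_free), 1),
                  length(free))
      covariance <- jac %*% cov_t %*% t(jac)
      dimnames(covariance) <- list(free, free)
      se_vec <- sqrt(pmax(diag(covariance), 0))
      names(se_vec) <- free
    }
  }

  ## rebuild model objects at the estimates
  p1 <- layout$p1
  p2 <- layout$p2
  fx <- function(arm) {
    out <- list()
    out[[p1]] <- est_nat[[paste0(p1, "_", arm)]]
    if (layout$has_p2) out[[p2]] <- est_nat[[paste0(p2, "_", arm)]]
    if (model %in% c("power", "weibull")) out$gamma <- est_nat[["gamma"]]
    out
  }
  iiv <- list(psi0 = est_nat[["omega2_psi0"]])
  iiv[[p1]] <- est_nat[[paste0("omega2_", p1)]]
  if (layout$has_p2) iiv[[p2]] <- est_nat[[paste0("omega2_", p2)]]
  iiv <- iiv[vapply(iiv, function(v) v > 0, logical(1))]
  traj <- trajectory_parameters(model, drug = fx("drug"),
                                placebo = fx("placebo"), iiv = iiv)
  mk <- if (markov)
    markov_parameters(est_nat[["met0"]], est_nat[["met_slope"]],
                      est_nat[["omega2_met"]], horizon = max(horizon, 1))
  else NULL

  structure(list(
    type = "longitudinal", model = model, markov_on = markov,
    estimates = est_nat, se = se_vec, covariance = covariance,
    ofv = opt$value, n_params = length(free), free = free, fix = fix,
    trajectory = traj, markov = mk, bank = bank,
    convergence = list(converged = opt$convergence == 0,
                       code = opt$convergence),
    n_subjects = length(subjects),
    data_fingerprint = .data_fingerprint(data),
    quad_nodes = quad_nodes), class = "irm_fit")
}

#' Step-2 objective at given parameters
#'
#' Evaluates the longitudinal marginal-likelihood objective (-2 log L) at a
#' fixed parameter set, without optimisation.  `params` uses the same
#' natural-scale names as [fit_longitudinal()]'s `estimates`.
#'
#' @inheritParams fit_longitudinal
#' @param params named list/vector of all model parameters.
#' @return the objective function value (scalar).
#' @export
longitudinal_ofv <- function(data, fixed_icfs, model = "step",
                             markov = TRUE, params, quad_nodes = 9) {
  stopifnot(inherits(data, "diary_dataset"))
  model <- match.arg(model, .traj_models)
  layout <- .step2_layout(model, markov)
  th <- .step2_theta(as.list(params), layout, model)
  gh <- gauss_hermite_normal(quad_nodes)
  res <- cpp_step2_loglik(th, .step2_subjects(data),
                          .bank_cpp(fixed_icfs),
                          match(model, .traj_models), markov,
                          gh$nodes, gh$weights, NULL)
  -2 * res$loglik
}

#' Compare fitted models
#'
#' Nested pairs are compared with the likelihood-ratio test on the change
#' in objective function value (chi-square with degrees of freedom equal to
#' the parameter difference, 5% level for selecting the more complex
#' model); non-nested models are ranked by AIC = OFV + 2 * n_params.
#'
#' @param fits list of two or more `irm_fit` objects on the same data.
#' @param nested `TRUE` when the fits form a nested sequence ordered simple
#'   to complex.
#' @param alpha significance level of the likelihood-ratio test.
#' @return a `model_comparison`: table of OFV/AIC (and LRT p-values when
#'   nested) plus the index of the selected model.
#' @export
compare_models <- function(fits, nested = FALSE, alpha = 0.05) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, logical(1),
                                          "irm_fit")))
  fp <- vapply(fits, function(f) f$data_fingerprint %||% NA_character_,
               character(1))
  if (length(unique(stats::na.omit(fp))) > 1)
    stop("fits were obtained on different datasets", call. = FALSE)
  ofv <- vapply(fits, function(f) f$ofv, numeric(1))
  np <- vapply(fits, function(f) f$n_params, numeric(1))
  labels <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (!is.null(f$model)) paste0(f$model, if (f$markov_on) "+markov" else "")
    else paste0("fit", i)
  }, character(1))
  tab <- data.frame(model = labels, ofv = ofv, n_params = np,
                    aic = ofv + 2 * np)
  if (nested) {
    if (is.unsorted(np))
      stop("nested fits must be ordered simple to complex", call. = FALSE)
    tab$delta_ofv <- c(NA, -diff(ofv))
    tab$df <- c(NA, diff(np))
    tab$p_value <- c(NA, stats::pchisq(pmax(tab$delta_ofv[-1], 0),
                                       df = tab$df[-1],
                                       lower.tail = FALSE))
    ## adopt the more complex model only when the OFV drop strictly
    ## exceeds the chi-square critical value (exact-boundary drops keep
    ## the simpler model)
    sel <- 1L
    for (i in 2:nrow(tab)) {
      crit <- stats::qchisq(1 - alpha, df = tab$df[i])
      ## small slack so a drop exactly at the critical value (p = alpha)
      ## keeps the simpler model despite floating-point rounding
      if (!is.na(tab$delta_ofv[i]) && tab$delta_ofv[i] > crit + 1e-8)
        sel <- i
    }
    selected <- sel
  } else {
    selected <- which.min(tab$aic)
  }
  structure(list(table = tab, selected = selected, nested = nested,
                 alpha = alpha), class = "model_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected:", x$table$model[x$selected], "\n")
  invisible(x)
}
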