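## The probabilistic model: graded-response item characteristic functions,
## latent disease-status trajectories with inter-individual variability, the
## continuous-time Markov dependence layer, and forward simulation.

## ---------------------------------------------------------------------------
## item parameters

#' Item parameter bank
#'
#' A bank holds the graded-response parameters of all 14 items: one
#' discrimination `a > 0` per item and strictly increasing difficulties
#' `b_1 < ... < b_K` where `K` is the item's maximum score (3 or 4).
#'
#' @param df data.frame with columns `item_id`, `a`, `b1`..`b4` (`b4 = NA`
#'   for the 0-3 items).
#' @return object of class `item_bank` (a validated data.frame with an
#'   extra `K` column).
#' @export
item_bank <- function(df) {
  .check_bank(df)
}

.check_bank <- function(df) {
  if (inherits(df, "item_bank")) return(df)
  need <- c("item_id", "a", paste0("b", 1:4))
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("item bank needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  items <- exact_items()
  df <- as.data.frame(df)[, need]
  df <- df[order(df$item_id), ]
  if (!identical(as.integer(df$item_id), 1:14))
    stop("item bank must contain items 1..14 exactly once", call. = FALSE)
  df$K <- items$max_score
  for (j in 1:14) {
    b <- as.numeric(df[j, paste0("b", seq_len(df$K[j]))])
    if (df$a[j] <= 0) stop("discrimination a must be > 0 (item ", j, ")",
                           call. = FALSE)
    if (anyNA(b) || is.unsorted(b, strictly = TRUE))
      stop("difficulties must be strictly increasing (item ", j, ")",
           call. = FALSE)
    if (df$K[j] < 4 && !is.na(df$b4[j]))
      stop("item ", j, " has max score 3; b4 must be NA", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("item_bank", "data.frame")
  df
}

#' Extract one item's parameters from a bank
#'
#' @param bank an [item_bank].
#' @param j item id (1-14).
#' @return list with `item_id`, `a`, `b` (difficulty vector), `K`.
#' @export
bank_item <- function(bank, j) {
  bank <- .check_bank(bank)
  stopifnot(j %in% 1:14)
  K <- bank$K[j]
  list(item_id = j, a = bank$a[j],
       b = as.numeric(bank[j, paste0("b", seq_len(K))]), K = K)
}

.as_item <- function(item) {
  if (is.list(item) && all(c("a", "b") %in% names(item))) {
    if (is.null(item$K)) item$K <- length(item$b)
    stopifnot(item$a > 0, !is.unsorted(item$b, strictly = TRUE))
    return(item)
  }
  stop("item must be a list with fields a and b (see bank_item())",
       call. = FALSE)
}

#' Read / write an item bank as CSV
#'
#' Columns `item_id`, `a`, `b1`..`b4`.
#' @param path CSV path.
#' @param bank an [item_bank].
#' @export
read_item_bank <- function(path) {
  df <- utils::read.csv(path)
  .check_bank(df)
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  bank <- .check_bank(bank)
  utils::write.csv(bank[, c("item_id", "a", paste0("b", 1:4))], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

## ---------------------------------------------------------------------------
## item characteristic functions

#' Cumulative item characteristic function
#'
#' Probability that the response is at or above category `k` given the
#' latent disease status `psi`:
#' `P(y >= k) = plogis(a * (psi - b_k))`, with `P(y >= 0) = 1`.
#'
#' @param item item parameters (list with `a`, `b`; see [bank_item()]).
#' @param psi latent disease status (numeric vector allowed).
#' @param k category index, `0 <= k <= K`.
#' @return probability (vectorised over `psi`).
#' @export
prob_at_or_above <- function(item, psi, k) {
  item <- .as_item(item)
  if (length(k) != 1L || k < 0 || k > item$K || k != round(k))
    stop("k must be an integer in 0..", item$K, call. = FALSE)
  if (k == 0) return(rep(1, length(psi)))
  stats::plogis(item$a * (psi - item$b[k]))
}

#' Category probabilities of an item
#'
#' `P(y = k) = P(y >= k) - P(y >= k + 1)` for `k = 0..K`.
#'
#' @inheritParams prob_at_or_above
#' @return for scalar `psi` a probability vector of length `K + 1`
#'   (categories `0..K`); for vector `psi` a matrix with one row per value.
#' @export
category_probabilities <- function(item, psi) {
  item <- .as_item(item)
  cum <- cbind(1, stats::plogis(outer(psi, item$b, function(p, b)
    item$a * (p - b))), 0)
  pr <- cum[, seq_len(item$K + 1), drop = FALSE] -
    cum[, 1 + seq_len(item$K + 1), drop = FALSE]
  colnames(pr) <- as.character(0:item$K)
  if (length(psi) == 1L) drop(pr) else pr
}

## ---------------------------------------------------------------------------
## latent trajectories

.traj_models <- c("linear", "power", "asymptotic", "weibull", "step")
## fixed effects each model uses (psi0 mean is always fixed at 0)
.traj_fixed <- list(
  linear     = "slope",
  power      = c("slope", "gamma"),
  asymptotic = c("r_max", "t_prog"),
  weibull    = c("r_max", "t_prog", "gamma"),
  step       = c("r_max", "t_r"))
## parameters that may carry inter-individual variability, and its style
.traj_iiv <- list(
  linear     = c(psi0 = "additive", slope = "additive"),
  power      = c(psi0 = "additive", slope = "additive"),
  asymptotic = c(psi0 = "additive", r_max = "additive", t_prog = "exponential"),
  weibull    = c(psi0 = "additive", r_max = "additive", t_prog = "exponential"),
  step       = c(psi0 = "additive", r_max = "additive", t_r = "exponential"))

#' Latent-trajectory parameter set
#'
#' Describes the population time course of the latent disease status
#' `psi_i(t)`.  Five functional forms are supported: `linear`
#' (`psi0 + slope * t`), `power` (`psi0 + slope * t^gamma`), `asymptotic`
#' (`psi0 + (r_max - psi0) * (1 - exp(-log(2)/t_prog * t))`), `weibull`
#' (`psi0 + r_max * (1 - exp(-(log(2)/t_prog * t)^gamma))`) and `step`
#' (`psi0` up to `t_r`, `psi0 + r_max` after).  Fixed effects are
#' arm-specific except the baseline mean, which is fixed at 0.  `t_prog`,
#' `t_r` and MET carry exponential (lognormal) inter-individual
#' variability; `psi0`, `slope` and `r_max` additive-normal variability.
#'
#' @param model one of `"linear"`, `"power"`, `"asymptotic"`, `"weibull"`,
#'   `"step"`.
#' @param drug,placebo named lists of arm-specific fixed effects, e.g.
#'   `list(r_max = -0.16, t_r = 54.8)` for the step model.
#' @param iiv named list of inter-individual variance components (omega^2),
#'   e.g. `list(psi0 = 1, r_max = 0.05, t_r = 0.1)`.  Missing entries mean
#'   no variability on that parameter.
#' @return object of class `trajectory_parameters`.
#' @export
trajectory_parameters <- function(model, drug, placebo, iiv = list()) {
  model <- match.arg(model, .traj_models)
  need <- .traj_fixed[[model]]
  for (arm in list(drug = drug, placebo = placebo)) {
    miss <- setdiff(need, names(arm))
    if (length(miss))
      stop(sprintf("model '%s' requires fixed effect(s): %s",
                   model, paste(miss, collapse = ", ")), call. = FALSE)
  }
  allowed <- names(.traj_iiv[[model]])
  extra <- setdiff(names(iiv), allowed)
  if (length(extra))
    stop("iiv not supported for: ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (nm in names(iiv)) check_scalar(iiv[[nm]], paste0("iiv$", nm), lower = 0)
  for (arm in list(drug, placebo)) {
    if ("t_prog" %in% need) check_scalar(arm$t_prog, "t_prog", 0, strict_lower = TRUE)
    if ("t_r" %in% need) check_scalar(arm$t_r, "t_r", 0)
    if ("gamma" %in% need) check_scalar(arm$gamma, "gamma", 0, strict_lower = TRUE)
  }
  structure(list(model = model,
                 fixed = list(drug = drug[need], placebo = placebo[need]),
                 iiv = iiv),
            class = "trajectory_parameters")
}

#' Markov dependence parameters
#'
#' Day-to-day correlation of item responses is governed by the mean
#' equilibrium time (MET): the time scale on which an item's response
#' re-equilibrates to its marginal (ICF) distribution.  MET changes
#' linearly with study day, `MET(t) = met0 + met_slope * t`, and carries
#' lognormal inter-individual variability (`MET_i = MET * exp(eta_i)`).
#'
#' @param met0 MET at day 0 (days, > 0).
#' @param met_slope change in MET per day.
#' @param omega2_met variance of the subject-level log-MET deviation.
#' @param horizon study horizon (days) over which `MET(t) > 0` is enforced.
#' @return object of class `markov_parameters`.
#' @export
markov_parameters <- function(met0, met_slope = 0, omega2_met = 0,
                              horizon = 365) {
  check_scalar(met0, "met0", 0, strict_lower = TRUE)
  check_scalar(met_slope, "met_slope")
  check_scalar(omega2_met, "omega2_met", 0)
  if (met0 + met_slope * horizon <= 0)
    stop("MET(t) must stay positive over the study horizon", call. = FALSE)
  structure(list(met0 = met0, met_slope = met_slope,
                 omega2_met = omega2_met, horizon = horizon),
            class = "markov_parameters")
}

met_at <- function(markov, t) markov$met0 + markov$met_slope * t

#' Evaluate the latent trajectory for one subject
#'
#' @param params a [trajectory_parameters] object.
#' @param effects named list of subject-level realizations: `psi0` plus the
#'   model's random effects (`slope`, `r_max` as additive deviations;
#'   `t_prog`, `t_r` as log-scale deviations `eta`, i.e. the subject value
#'   is `fixed * exp(eta)`).  Missing entries default to 0.
#' @param t day (vector allowed), `t >= 0`.
#' @param arm `"drug"` or `"placebo"`.
#' @return psi value(s).
#' @export
trajectory_value <- function(params, effects, t, arm) {
  stopifnot(inherits(params, "trajectory_parameters"))
  arm <- match.arg(arm, c("drug", "placebo"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  fx <- params$fixed[[arm]]
  eff <- function(nm) if (!is.null(effects[[nm]])) effects[[nm]] else 0
  psi0 <- eff("psi0")
  switch(params$model,
    linear = psi0 + (fx$slope + eff("slope")) * t,
    power = psi0 + (fx$slope + eff("slope")) * t^fx$gamma,
    asymptotic = {
      t_prog <- fx$t_prog * exp(eff("t_prog"))
      r_max <- fx$r_max + eff("r_max")
      psi0 + (r_max - psi0) * (1 - exp(-log(2) / t_prog * t))
    },
    weibull = {
      t_prog <- fx$t_prog * exp(eff("t_prog"))
      r_max <- fx$r_max + eff("r_max")
      psi0 + r_max * (1 - exp(-(log(2) / t_prog * t)^fx$gamma))
    },
    step = {
      t_r <- fx$t_r * exp(eff("t_r"))
      r_max <- fx$r_max + eff("r_max")
      psi0 + r_max * (t > t_r)
    })
}

#' Draw subject-level random effects
#'
#' @param params a [trajectory_parameters] object.
#' @param markov a [markov_parameters] object or `NULL`.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data.frame with one row per subject: `psi0`, the model's random
#'   effects and `eta_met` (all additive / log-scale deviations).
#' @export
draw_subject_effects <- function(params, markov = NULL, n, seed) {
  stopifnot(inherits(params, "trajectory_parameters"))
  set.seed(derive_seed(seed, 0L))
  nm <- names(.traj_iiv[[params$model]])
  out <- data.frame(row.names = seq_len(max(n, 0)))
  for (p in nm) {
    v <- params$iiv[[p]]
    out[[p]] <- if (is.null(v) || v == 0) rep(0, n) else
      stats::rnorm(n, 0, sqrt(v))
  }
  vmet <- if (is.null(markov)) 0 else markov$omega2_met
  out$eta_met <- if (vmet == 0) rep(0, n) else stats::rnorm(n, 0, sqrt(vmet))
  out
}

## ---------------------------------------------------------------------------
## the continuous-time Markov layer

#' Single-item transition matrix over a time gap
#'
#' The default construction shrinks the identity toward the stationary
#' (marginal ICF) distribution: `P(dt) = e * I + (1 - e) * 1 pi'` with
#' `e = exp(-dt / MET)`, so MET is the mean of the exponentially
#' distributed re-equilibration time and the deviation from stationarity
#' halves every `MET * log(2)` days.  The matrix is row-stochastic, has the
#' ICF category probabilities as stationary distribution, tends to the
#' identity as `dt -> 0` and to the stationary matrix as `dt -> Inf`, and
#' satisfies Chapman-Kolmogorov within a constant-MET window.
#'
#' @param item item parameters (see [bank_item()]).
#' @param psi latent disease status (scalar).
#' @param dt time gap in days, `> 0`.
#' @param met subject-specific mean equilibrium time at the current day
#'   (days, `> 0`).
#' @return a `(K+1) x (K+1)` row-stochastic matrix over categories `0..K`.
#' @export
transition_matrix <- function(item, psi, dt, met) {
  item <- .as_item(item)
  check_scalar(dt, "dt", 0, strict_lower = TRUE)
  check_scalar(met, "met", 0, strict_lower = TRUE)
  check_scalar(psi, "psi")
  pi_ <- as.numeric(category_probabilities(item, psi))
  e <- exp(-dt / met)
  P <- e * diag(item$K + 1) + (1 - e) * matrix(pi_, item$K + 1,
                                               item$K + 1, byrow = TRUE)
  dimnames(P) <- list(as.character(0:item$K), as.character(0:item$K))
  P
}

## ---------------------------------------------------------------------------
## forward simulation

#' Simulate one subject's diary
#'
#' Day-0 (more generally first-present-day) responses are drawn from the
#' marginal ICF distribution at `psi(t)`; each later present day is drawn
#' item-wise from the Markov transition matrix with `dt` the gap since the
#' previous present day and MET evaluated at the current day times
#' `exp(eta_met)`.  Days listed in `missing_days` are omitted entirely
#' (the diary never contains partial days).
#'
#' @param bank an [item_bank].
#' @param traj a [trajectory_parameters] object.
#' @param markov a [markov_parameters] object, or `NULL` to draw every day
#'   independently from the marginal ICF distribution.
#' @param effects one row of [draw_subject_effects()] (or a named list).
#' @param arm `"drug"` or `"placebo"`.
#' @param days sorted vector of scheduled days.
#' @param missing_days days to drop from the schedule.
#' @param seed integer seed.
#' @return data.frame with columns `day`, `i1`..`i14` for present days.
#' @export
simulate_subject_diary <- function(bank, traj, markov, effects, arm, days,
                                   missing_days = integer(), seed) {
  bank <- .check_bank(bank)
  days <- sort(unique(as.integer(days)))
  present <- setdiff(days, as.integer(missing_days))
  if (!length(present))
    return(data.frame(day = integer())[, FALSE])
  set.seed(derive_seed(seed, 1L))
  psi <- trajectory_value(traj, effects, present, arm)
  M <- length(present)
  Y <- matrix(NA_integer_, M, 14)
  eta_met <- if (!is.null(effects$eta_met)) effects$eta_met else 0
  ## per item the chain either copies the previous present day's value
  ## (prob exp(-dt/MET_i)) or redraws from the day's marginal; a value thus
  ## equals the fresh draw made at its most recent "refresh" day, which
  ## vectorises via cummax over refresh indices.
  e_gap <- numeric(0)
  if (M > 1 && !is.null(markov)) {
    dt <- diff(present)
    met_i <- met_at(markov, present[-1]) * exp(eta_met)
    e_gap <- exp(-dt / met_i)
  }
  for (j in 1:14) {
    it <- bank_item(bank, j)
    pr <- category_probabilities(it, psi)
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    keep <- rep(FALSE, M)
    if (length(e_gap)) keep[-1] <- stats::runif(M - 1) < e_gap
    refresh_idx <- cummax(seq_len(M) * (!keep))
    cum <- pr %*% upper.tri(diag(it$K + 1), diag = TRUE)
    fresh <- rowSums(stats::runif(M) > cum[, seq_len(it$K), drop = FALSE])
    Y[, j] <- as.integer(fresh[refresh_idx])
  }
  out <- data.frame(day = present)
  for (j in 1:14) out[[paste0("i", j)]] <- Y[, j]
  out
}

#' Simulate a two-arm trial at the item level
#'
#' Per-subject random effects are drawn from the stated inter-individual
#' distributions; each arm uses its own fixed effects.  No missingness or
#' drop-out is applied here (see [generate_trial()] for the full synthetic
#' trial generator).
#'
#' @param design list with `n_drug`, `n_placebo` and either `days` (vector
#'   of scheduled days) or `horizon` (days 0..horizon).
#' @param bank an [item_bank].
#' @param traj a [trajectory_parameters] object.
#' @param markov a [markov_parameters] object or `NULL`.
#' @param seed integer seed.
#' @param effects optional pre-drawn effects data.frame
#'   (`n_drug + n_placebo` rows, drug block first); drawn if `NULL`.
#' @return a [diary_dataset] (plus the effects as attribute `"effects"`).
#' @export
simulate_trial <- function(design, bank, traj, markov = NULL, seed,
                           effects = NULL) {
  bank <- .check_bank(bank)
  n_d <- design$n_drug
  n_p <- design$n_placebo
  stopifnot(n_d >= 0, n_p >= 0)
  days <- if (!is.null(design$days)) design$days else 0:design$horizon
  n <- n_d + n_p
  if (n == 0) {
    empty <- data.frame(subject_id = character(), arm = character(),
                        day = integer())
    for (j in 1:14) empty[[paste0("i", j)]] <- integer()
    return(diary_dataset(empty))
  }
  if (is.null(effects))
    effects <- draw_subject_effects(traj, markov, n, derive_seed(seed, 2L))
  arms <- c(rep("drug", n_d), rep("placebo", n_p))
  ids <- sprintf("S%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- simulate_subject_diary(bank, traj, markov,
                                as.list(effects[i, , drop = FALSE]),
                                arms[i], days,
                                seed = derive_seed(seed, 10L + i))
    d <- cbind(data.frame(subject_id = ids[i], arm = arms[i],
                          stringsAsFactors = FALSE), d)
    rows[[i]] <- d
  }
  out <- diary_dataset(do.call(rbind, rows))
  attr(out, "effects") <- cbind(data.frame(subject_id = ids, arm = arms,
                                           stringsAsFactors = FALSE), effects)
  out
}
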