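## Simulation-based model checking: visual predictive checks on the
## total-score, item and transition level, and non-parametric ICF smooths.

#' Simulate a replicate dataset under a fitted model, keeping the design
#'
#' Every replicate uses exactly the observed design - same subjects, arms
#' and present days (hence the same whole-day missingness pattern) - with
#' fresh subject-level random effects and responses.
#'
#' @param fit a longitudinal `irm_fit` (from [fit_longitudinal()]), or any
#'   list with `bank`, `trajectory` and `markov` elements.
#' @param data the observed [diary_dataset] providing the design.
#' @param seed integer seed.
#' @return a [diary_dataset].
#' @export
simulate_from_fit <- function(fit, data, seed) {
  if (is.null(fit$trajectory) || is.null(fit$bank))
    stop("fit must carry a trajectory and an item bank (run fit_longitudinal first)",
         call. = FALSE)
  stopifnot(inherits(data, "diary_dataset"))
  w <- data$data
  ids <- data$subjects$subject_id
  effects <- draw_subject_effects(fit$trajectory, fit$markov, length(ids),
                                  derive_seed(seed, 20L))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    days_i <- w$day[w$subject_id == ids[i]]
    d <- simulate_subject_diary(fit$bank, fit$trajectory, fit$markov,
                                as.list(effects[i, , drop = FALSE]),
                                data$subjects$arm[i], days_i,
                                seed = derive_seed(seed, 300L + i))
    rows[[i]] <- cbind(data.frame(subject_id = ids[i],
                                  arm = data$subjects$arm[i],
                                  stringsAsFactors = FALSE), d)
  }
  diary_dataset(do.call(rbind, rows))
}

## equal-count day bins shared by observed data and replicates
.day_bins <- function(days, bins) {
  qs <- unique(stats::quantile(days, probs = seq(0, 1, length.out = bins + 1),
                               type = 1))
  if (length(qs) < 2) qs <- c(min(days), max(days) + 1)
  qs[length(qs)] <- qs[length(qs)] + 1           # right-open last bin
  qs
}

.bin_of <- function(days, edges) {
  cut(days, breaks = edges, right = FALSE, labels = FALSE,
      include.lowest = TRUE)
}

.vpc_result <- function(stats_df, n_sim, kind) {
  structure(list(stats = stats_df, n_sim = n_sim, kind = kind),
            class = "irm_vpc")
}

#' @export
print.irm_vpc <- function(x, ...) {
  cat(sprintf("irm_vpc (%s): %d statistics, %d simulations\n",
              x$kind, nrow(x$stats), x$n_sim))
  invisible(x)
}

#' Write VPC statistics as tidy CSV
#' @param vpc an `irm_vpc`.
#' @param path output path.
#' @export
write_vpc_csv <- function(vpc, path) {
  stopifnot(inherits(vpc, "irm_vpc"))
  utils::write.csv(vpc$stats, path, row.names = FALSE)
  invisible(path)
}

## generic VPC engine: stat_fun maps a scored/summarised dataset to a
## data.frame of statistics keyed by (stratum, bin, stat)
.vpc_engine <- function(fit, data, n_sim, seed, stat_fun, kind) {
  if (n_sim < 2) stop("n_sim must be >= 2", call. = FALSE)
  obs <- stat_fun(data)
  sims <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    rep_data <- simulate_from_fit(fit, data, derive_seed(seed, 4000L + r))
    s <- stat_fun(rep_data)
    sims[[r]] <- s$value
    ## structural contract: replicates share the observed design exactly
    stopifnot(identical(s[, setdiff(names(s), "value")],
                        obs[, setdiff(names(obs), "value")]))
  }
  S <- do.call(cbind, sims)
  obs$band_lo <- apply(S, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
  obs$band_hi <- apply(S, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  names(obs)[names(obs) == "value"] <- "observed"
  .vpc_result(obs, n_sim, kind)
}

#' Visual predictive check for the total score
#'
#' Compares the 2.5th, 50th and 97.5th percentiles of the observed
#' total-score distribution over time bins with the 95% band of the same
#' percentiles across model-simulated replicate datasets (original design,
#' fresh random effects).
#'
#' @param fit a longitudinal `irm_fit`.
#' @param data observed [diary_dataset].
#' @param n_sim number of simulated replicates.
#' @param bins number of equal-count day bins.
#' @param stratify_by_arm stratify all statistics by treatment arm?
#' @param statistic `"rs_total"` (default) or `"exact_total"`.
#' @param score_map required when `statistic = "exact_total"`.
#' @param seed integer seed.
#' @return an `irm_vpc` whose `stats` hold one row per
#'   (arm, bin, percentile): columns `arm`, `bin`, `day_mid`, `stat`,
#'   `observed`, `band_lo`, `band_hi`.
#' @export
vpc_total_score <- function(fit, data, n_sim = 500, bins = 14,
                            stratify_by_arm = TRUE,
                            statistic = c("rs_total", "exact_total"),
                            score_map = NULL, seed = 1L) {
  statistic <- match.arg(statistic)
  if (statistic == "exact_total" && is.null(score_map))
    stop("exact_total VPC needs a score_map", call. = FALSE)
  edges <- .day_bins(data$data$day, bins)
  probs <- c(0.025, 0.5, 0.975)
  stat_fun <- function(d) {
    sc <- score_diary(d, score_map)
    y <- sc[[statistic]]
    arm <- if (stratify_by_arm) sc$arm else "all"
    bin <- .bin_of(sc$day, edges)
    keys <- expand.grid(stat = paste0("p", probs * 100),
                        bin = sort(unique(bin)),
                        arm = sort(unique(arm)),
                        stringsAsFactors = FALSE)[, 3:1]
    keys$day_mid <- tapply(sc$day, bin, stats::median)[as.character(keys$bin)]
    keys$value <- mapply(function(a, b, st) {
      sel <- arm == a & bin == b
      if (!any(sel)) return(NA_real_)
      stats::quantile(y[sel], probs[match(st, paste0("p", probs * 100))],
                      names = FALSE)
    }, keys$arm, keys$bin, keys$stat)
    keys[order(keys$arm, keys$bin, keys$stat), , drop = FALSE]
  }
  .vpc_engine(fit, data, n_sim, seed, stat_fun,
              kind = paste0("total-score:", statistic))
}

#' Visual predictive check on the item level
#'
#' Statistic: the proportion of responses at each category over time bins,
#' pooled over items (`per_item = FALSE`) or per item.
#'
#' @inheritParams vpc_total_score
#' @param per_item stratify by item?
#' @return an `irm_vpc`; `stats` has one row per
#'   (arm, item stratum, bin, category).
#' @export
vpc_items <- function(fit, data, n_sim = 500, bins = 14,
                      stratify_by_arm = TRUE, per_item = FALSE, seed = 1L) {
  edges <- .day_bins(data$data$day, bins)
  stat_fun <- function(d) {
    w <- d$data
    long <- do.call(rbind, lapply(1:14, function(j)
      data.frame(arm = if (stratify_by_arm) w$arm else "all",
                 item = if (per_item) j else 0L,
                 bin = .bin_of(w$day, edges),
                 y = w[[paste0("i", j)]], stringsAsFactors = FALSE)))
    keys <- expand.grid(category = 0:4, bin = sort(unique(long$bin)),
                        item = sort(unique(long$item)),
                        arm = sort(unique(long$arm)),
                        stringsAsFactors = FALSE)[, 4:1]
    grp <- interaction(long$arm, long$item, long$bin, drop = FALSE)
    keys$value <- mapply(function(a, it, b, cc) {
      sel <- long$arm == a & long$item == it & long$bin == b
      if (!any(sel)) return(NA_real_)
      mean(long$y[sel] == cc)
    }, keys$arm, keys$item, keys$bin, keys$category)
    keys[order(keys$arm, keys$item, keys$bin, keys$category), , drop = FALSE]
  }
  .vpc_engine(fit, data, n_sim, seed, stat_fun, kind = "items")
}

#' Visual predictive check for day-to-day transitions
#'
#' Extracts consecutive present-day pairs per subject and compares the
#' observed proportions of score changes (down / same / up, pooled over
#' items) with the simulated 95% bands.  This targets the Markov layer:
#' an independence model understates the "same" proportion.
#'
#' @inheritParams vpc_total_score
#' @return an `irm_vpc`; `stats` has one row per (arm, bin, direction).
#' @export
vpc_transitions <- function(fit, data, n_sim = 500, bins = 7,
                            stratify_by_arm = TRUE, seed = 1L) {
  pair_frame <- function(d) {
    w <- d$data
    out <- lapply(split(w, w$subject_id), function(di) {
      di <- di[order(di$day), ]
      if (nrow(di) < 2) return(NULL)
      gap1 <- which(diff(di$day) == 1)
      if (!length(gap1)) return(NULL)
      Y <- as.matrix(di[, paste0("i", 1:14)])
      ch <- Y[gap1 + 1, , drop = FALSE] - Y[gap1, , drop = FALSE]
      data.frame(arm = di$arm[1], day = di$day[gap1 + 1],
                 down = rowSums(ch < 0), same = rowSums(ch == 0),
                 up = rowSums(ch > 0), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  pf0 <- pair_frame(data)
  if (is.null(pf0) || !nrow(pf0))
    stop("no consecutive-day pairs in the data", call. = FALSE)
  edges <- .day_bins(pf0$day, bins)
  stat_fun <- function(d) {
    pf <- pair_frame(d)
    arm <- if (stratify_by_arm) pf$arm else "all"
    bin <- .bin_of(pf$day, edges)
    keys <- expand.grid(direction = c("down", "same", "up"),
                        bin = sort(unique(bin)),
                        arm = sort(unique(arm)),
                        stringsAsFactors = FALSE)[, 3:1]
    keys$value <- mapply(function(a, b, dir) {
      sel <- arm == a & bin == b
      if (!any(sel)) return(NA_real_)
      sum(pf[[dir]][sel]) / (14 * sum(sel))
    }, keys$arm, keys$bin, keys$direction)
    keys[order(keys$arm, keys$bin, keys$direction), , drop = FALSE]
  }
  .vpc_engine(fit, data, n_sim, seed, stat_fun, kind = "transitions")
}

## posterior-mean latent value per occasion under an item bank and a
## normal latent distribution
.occasion_eap <- function(bank, w, mu, omega2, nodes) {
  gh <- gauss_hermite_normal(nodes)
  psi_q <- mu + sqrt(omega2) * gh$nodes
  S <- matrix(rep(log(gh$weights), nrow(w)), length(psi_q), nrow(w))
  for (j in 1:14) {
    it <- bank_item(bank, j)
    lp <- log(pmax(category_probabilities(it, psi_q), 1e-300))
    S <- S + lp[, w[[paste0("i", j)]] + 1L, drop = FALSE]
  }
  smax <- apply(S, 2, max)
  post <- exp(sweep(S, 2, smax))
  post <- sweep(post, 2, colSums(post), "/")
  colSums(post * psi_q)
}

.kernel_smooth <- function(x, y, grid, bw) {
  vapply(grid, function(g) {
    k <- stats::dnorm((x - g) / bw)
    sum(k * y) / sum(k)
  }, numeric(1))
}

#' Non-parametric ICF smooth check
#'
#' For step-1 style pseudo-occasion data, computes each occasion's
#' posterior-mean latent value under the supplied item parameters and
#' kernel-smooths the observed mean item score against it.  The reference
#' curve is the *same smooth computed on model-simulated pseudo-occasions*
#' (same size, same latent distribution, averaged over `n_sim` replicate
#' simulations): since posterior means are shrunken towards the prior,
#' comparing two smooths built the same way is the like-for-like check -
#' agreement indicates acceptable ICF fit.  The pure model expected-score
#' curve `E[y | psi]` is returned as well for display; it is systematically
#' shallower than either smooth at the extremes and is not the acceptance
#' reference.
#'
#' @param item_params an [item_bank].
#' @param data a [diary_dataset] of pseudo-occasions.
#' @param mu,omega2 latent distribution of the occasions used for the
#'   posterior means and the simulation (defaults to the standard-normal
#'   anchor).
#' @param grid_n number of psi grid points.
#' @param nodes quadrature nodes for the posterior means.
#' @param n_sim simulated replicates averaged into the reference smooth.
#' @param seed integer seed for the reference simulation.
#' @return list of class `icf_smooth` with one element per item:
#'   data.frame `psi`, `observed` (kernel smooth of the data),
#'   `simulated` (reference smooth under the model) and `expected`
#'   (pure `E[y | psi]`); the occasion posterior means are attached as
#'   attribute `psi_hat`.
#' @export
icf_smooth_check <- function(item_params, data, mu = 0, omega2 = 1,
                             grid_n = 41, nodes = 41, n_sim = 5,
                             seed = 1L) {
  bank <- .check_bank(item_params)
  stopifnot(inherits(data, "diary_dataset"))
  w <- data$data
  if (nrow(w) < 20)
    stop("at least 20 occasions are required for a reliable smooth",
         call. = FALSE)
  psi_hat <- .occasion_eap(bank, w, mu, omega2, nodes)
  grid <- seq(stats::quantile(psi_hat, 0.02),
              stats::quantile(psi_hat, 0.98), length.out = grid_n)
  bw <- stats::bw.nrd0(psi_hat)

  ## reference: identical pipeline on data simulated from the ICFs
  sim_curves <- array(0, c(grid_n, 14, n_sim))
  n <- nrow(w)
  for (r in seq_len(n_sim)) {
    set.seed(derive_seed(seed, 40L + r))
    psi_sim <- mu + sqrt(omega2) * stats::rnorm(n)
    ws <- w
    for (j in 1:14) {
      it <- bank_item(bank, j)
      pr <- category_probabilities(it, psi_sim)
      cum <- pr %*% upper.tri(diag(it$K + 1), diag = TRUE)
      ws[[paste0("i", j)]] <-
        as.integer(rowSums(stats::runif(n) > cum[, seq_len(it$K),
                                                 drop = FALSE]))
    }
    eap_sim <- .occasion_eap(bank, ws, mu, omega2, nodes)
    for (j in 1:14)
      sim_curves[, j, r] <- .kernel_smooth(eap_sim,
                                           ws[[paste0("i", j)]], grid, bw)
  }

  out <- vector("list", 14)
  for (j in 1:14) {
    it <- bank_item(bank, j)
    obs <- .kernel_smooth(psi_hat, w[[paste0("i", j)]], grid, bw)
    expct <- as.numeric(category_probabilities(it, grid) %*% (0:it$K))
    out[[j]] <- data.frame(psi = grid, observed = obs,
                           simulated = rowMeans(sim_curves[, j, ,
                                                           drop = FALSE]),
                           expected = expct)
  }
  names(out) <- paste0("item_", 1:14)
  attr(out, "psi_hat") <- psi_hat
  class(out) <- "icf_smooth"
  out
}

#' Plot a VPC
#'
#' Simple base-graphics rendering: observed statistics as lines, simulated
#' bands as shaded polygons, one panel per stratum.
#'
#' @param x an `irm_vpc`.
#' @param ... unused.
#' @export
plot.irm_vpc <- function(x, ...) {
  st <- x$stats
  strata <- unique(st$arm)
  statcol <- intersect(c("stat", "direction", "category"), names(st))[1]
  op <- graphics::par(mfrow = c(1, length(strata)))
  on.exit(graphics::par(op))
  xcol <- if ("day_mid" %in% names(st)) "day_mid" else "bin"
  for (a in strata) {
    s <- st[st$arm == a, ]
    ylim <- range(c(s$observed, s$band_lo, s$band_hi), na.rm = TRUE)
    graphics::plot(NA, xlim = range(s[[xcol]], na.rm = TRUE), ylim = ylim,
                   xlab = "day", ylab = "statistic",
                   main = paste(x$kind, a))
    for (g in unique(s[[statcol]])) {
      sg <- s[s[[statcol]] == g, ]
      sg <- sg[order(sg[[xcol]]), ]
      graphics::polygon(c(sg[[xcol]], rev(sg[[xcol]])),
                        c(sg$band_lo, rev(sg$band_hi)),
                        col = grDevices::adjustcolor("grey", 0.5),
                        border = NA)
      graphics::lines(sg[[xcol]], sg$observed)
    }
  }
  invisible(x)
}
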