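## Configuration-driven pipeline tying the stages together: generate ->
## fit step 1 -> fit step 2 -> VPC -> endpoint simulation -> decision.
## Configurations are plain lists (or JSON files); every artifact written
## carries the configuration hash and the seed that produced it.

.pipeline_stages <- c("generate", "fit_step1", "fit_step2", "vpc",
                      "simulate", "decide")

#' Validate a pipeline configuration
#'
#' @param config list or path to a JSON file.  Recognised fields:
#'   `seed` (integer), `out_dir`, `stages` (character subset of
#'   generate / fit_step1 / fit_step2 / vpc / simulate / decide),
#'   `generate` (either `fixture = "<name>"` or [trial_config()]
#'   arguments), `fit` (`model`, `markov`, `nodes`, `se`), `vpc`
#'   (`n_sim`, `bins`), `simulate` (`n_subj`, `n_rep`, `eval_window`),
#'   `decide` (`tv`, `sigma`, `w0`, `prior_sd`, `n_samples`, `analytic`).
#' @return the normalised configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file does not exist: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% .pipeline_stages
  bad <- setdiff(config$stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$out_dir))
    stop("config needs an out_dir", call. = FALSE)
  ## stage dependency checks happen before any computation
  st <- config$stages
  needs <- function(stage, dep, alt = NULL) {
    if (stage %in% st && !dep %in% st && (is.null(alt) || is.null(alt())))
      stop(sprintf("stage '%s' requires stage '%s' (or the corresponding input in the config)",
                   stage, dep), call. = FALSE)
  }
  needs("fit_step1", "generate",
        function() config$data_csv)
  needs("fit_step2", "fit_step1",
        function() config$fit$item_bank_csv)
  needs("vpc", "fit_step2")
  needs("simulate", "fit_step2")
  if ("decide" %in% st && !"simulate" %in% st &&
      is.null(config$decide$sigma))
    stop("stage 'decide' requires stage 'simulate' or an explicit decide$sigma",
         call. = FALSE)
  config$hash <- fnv1a_hash(jsonlite::toJSON(
    config[setdiff(names(config), "hash")], auto_unbox = TRUE,
    force = TRUE, digits = NA))
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in their natural order and writes all
#' artifacts (CSV/JSON) into `out_dir`.  Outputs are deterministic given
#' the configuration: rerunning with the same config reproduces them.
#'
#' @param config a [pipeline_config()] (list or JSON path accepted).
#' @return invisibly, a list with the stage results and a `log` data.frame
#'   of stage timings; artifacts live in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stamp <- list(config_hash = config$hash, seed = seed)
  log <- list()
  res <- list(config = config)
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    log[[stage]] <<- data.frame(stage = stage,
                                seconds = proc.time()[["elapsed"]] - t0)
    out
  }
  st <- config$stages

  if ("generate" %in% st) {
    res$generated <- tic("generate", {
      g <- config$generate %||% list()
      gen <- if (!is.null(g$fixture)) make_fixture(g$fixture) else {
        g$seed <- g$seed %||% seed
        generate_trial(do.call(trial_config, g))
      }
      write_diary_csv(gen$data, file.path(config$out_dir, "diary.csv"))
      man <- gen$manifest
      man$config <- unclass(man$config)
      man$config$trajectory <- unclass(man$config$trajectory)
      man$config$markov <- unclass(man$config$markov)
      jsonlite::write_json(c(stamp, man), digits = NA,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, force = TRUE)
      gen
    })
  }
  data <- if (!is.null(res$generated)) res$generated$data else
    if (!is.null(config$data_csv)) read_diary_csv(config$data_csv) else NULL

  fitcfg <- config$fit %||% list()
  if ("fit_step1" %in% st) {
    res$step1 <- tic("fit_step1", {
      f1 <- fit_icfs(data, nodes = fitcfg$nodes %||% 21,
                     se = fitcfg$se %||% TRUE)
      write_item_bank(f1$bank, file.path(config$out_dir, "icf_bank.csv"))
      jsonlite::write_json(
        c(stamp, list(ofv = f1$ofv, mu = f1$mu, omega2 = f1$omega2,
                      converged = f1$convergence$converged,
                      se = as.list(f1$se))),
        file.path(config$out_dir, "step1.json"), auto_unbox = TRUE,
        digits = NA)
      f1
    })
  }
  bank <- if (!is.null(res$step1)) res$step1$bank else
    if (!is.null(fitcfg$item_bank_csv)) read_item_bank(fitcfg$item_bank_csv)
    else NULL

  if ("fit_step2" %in% st) {
    res$step2 <- tic("fit_step2", {
      f2 <- fit_longitudinal(data, bank,
                             model = fitcfg$model %||% "step",
                             markov = fitcfg$markov %||% TRUE,
                             se = fitcfg$se %||% TRUE)
      jsonlite::write_json(
        c(stamp, list(model = f2$model, markov = f2$markov_on,
                      ofv = f2$ofv, estimates = as.list(f2$estimates),
                      se = as.list(f2$se),
                      converged = f2$convergence$converged)),
        file.path(config$out_dir, "step2.json"), auto_unbox = TRUE,
        digits = NA)
      f2
    })
  }

  if ("vpc" %in% st) {
    res$vpc <- tic("vpc", {
      v <- config$vpc %||% list()
      vt <- vpc_total_score(res$step2, data, n_sim = v$n_sim %||% 500,
                            bins = v$bins %||% 14,
                            seed = derive_seed(seed, 30L))
      write_vpc_csv(vt, file.path(config$out_dir, "vpc_total.csv"))
      vtr <- vpc_transitions(res$step2, data, n_sim = v$n_sim %||% 500,
                             seed = derive_seed(seed, 31L))
      write_vpc_csv(vtr, file.path(config$out_dir, "vpc_transitions.csv"))
      list(total = vt, transitions = vtr)
    })
  }

  if ("simulate" %in% st) {
    res$endpoints <- tic("simulate", {
      s <- config$simulate %||% list()
      spec <- uncertainty_spec(res$step2)
      ew <- s$eval_window %||% c(351, 365)
      ep <- simulate_endpoint_distribution(
        spec, n_subj = s$n_subj %||% 5000, n_rep = s$n_rep %||% 2000,
        eval_window = ew[1]:ew[2], seed = derive_seed(seed, 32L))
      write_endpoint_distribution(
        ep, csv_path = file.path(config$out_dir, "endpoints.csv"),
        json_path = file.path(config$out_dir, "endpoints_summary.json"))
      ep
    })
  }

  if ("decide" %in% st) {
    res$decision <- tic("decide", {
      d <- config$decide %||% list()
      sigma <- d$sigma %||% {
        sm <- res$endpoints$summary
        sm$sd_delta[sm$scale == (d$scale %||% "rs_total")]
      }
      inp <- decision_inputs(tv = d$tv %||% -2, sigma_delta = sigma,
                             w0 = d$w0 %||% 0.8,
                             prior_sd = d$prior_sd %||% 1,
                             n_samples = d$n_samples %||% 10000,
                             seed = derive_seed(seed, 33L))
      tab <- if (isTRUE(d$analytic) || is.null(d$analytic))
        decision_table_analytic(inp) else decision_table_mc(inp)
      jsonlite::write_json(
        c(stamp, list(method = tab$method, tv = inp$tv,
                      sigma_delta = inp$sigma_delta,
                      p_correct_go = tab$p_correct_go,
                      p_incorrect_go = tab$p_incorrect_go,
                      p_correct_stop = tab$p_correct_stop,
                      p_incorrect_stop = tab$p_incorrect_stop,
                      p_go = tab$p_go, p_stop = tab$p_stop,
                      ppv = tab$ppv, npv = tab$npv)),
        file.path(config$out_dir, "decision.json"), auto_unbox = TRUE,
        digits = NA)
      tab
    })
  }

  res$log <- do.call(rbind, log)
  jsonlite::write_json(c(stamp, list(stages = st,
                                     log = res$log)),
                       file.path(config$out_dir, "pipeline_log.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(res)
}
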