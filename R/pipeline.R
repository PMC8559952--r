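#' Configuration of a full pipeline run
#'
#' Bundles everything a run needs so that it is reproducible from the config
#' alone: the population settings, which cognitive models to fit, MCMC and
#' prior settings, the compliance threshold, output directory and master
#' seed.
#'
#' @param population a [population_config()].
#' @param models character vector of `"family/scheme"` strings (e.g.
#'   `"variable/full"`); `"all"` expands to all six.
#' @param priors a [default_priors()].
#' @param mcmc an [mcmc_control()].
#' @param compliance_threshold percent threshold for the compliance flag.
#' @param out_dir output directory for run artefacts.
#' @param seed master seed, overriding the population and MCMC seeds.
#' @param verbose log progress to the console as well as the log file.
#' @export
run_config <- function(population = population_config(),
                       models = "variable/full",
                       priors = default_priors(),
                       mcmc = mcmc_control(),
                       compliance_threshold = 25,
                       out_dir = tempfile("svo_run_"),
                       seed = 1L, verbose = TRUE) {
  if (identical(models, "all"))
    models <- vapply(all_model_specs(), function(s)
      paste(s$family, s$scheme, sep = "/"), "")
  cfg <- list(population = population, models = models, priors = priors,
              mcmc = mcmc, compliance_threshold = compliance_threshold,
              out_dir = out_dir, seed = as.integer(seed), verbose = verbose)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg$population, "population_config"),
            inherits(cfg$mcmc, "mcmc_control"),
            inherits(cfg$priors, "svo_priors"))
  if (sum(cfg$population$n_per_condition) < 1)
    stop("invalid config: n_per_condition sums to 0, nothing to simulate")
  ok <- grepl("^(variable|stable)/(full|shared_attitude|shared_variability)$",
              cfg$models)
  if (length(cfg$models) < 1 || !all(ok))
    stop("invalid config: models must be family/scheme strings, got ",
         paste(cfg$models[!ok], collapse = ", "))
  if (cfg$compliance_threshold < 0 || cfg$compliance_threshold > 100)
    stop("invalid config: compliance_threshold must be in [0, 100]")
  invisible(cfg)
}

parse_spec <- function(s) {
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  model_spec(parts[1], parts[2])
}

# recursively strip classes so yaml serialisation round-trips
as_plain <- function(x) {
  if (is.list(x)) lapply(unclass(x), as_plain)
  else if (is.numeric(x) && !is.null(names(x))) as.list(x)
  else x
}

#' Read a pipeline config from YAML
#'
#' Fields mirror the arguments of [run_config()], [population_config()] and
#' [mcmc_control()]; missing fields take their defaults, and the config is
#' validated before anything runs.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(src, fn) {
    fml <- names(formals(fn))
    args <- src[intersect(names(src), fml)]
    args <- lapply(args, function(a)
      if (is.list(a) && all(vapply(a, is.numeric, TRUE))) unlist(a) else a)
    do.call(fn, args)
  }
  pop <- if (is.null(y$population)) population_config()
         else take(y$population, population_config)
  mcmc <- if (is.null(y$mcmc)) mcmc_control() else take(y$mcmc, mcmc_control)
  priors <- if (is.null(y$priors)) default_priors()
            else take(lapply(y$priors, function(p) lapply(p, as.numeric)),
                      default_priors)
  top <- y[intersect(names(y), c("models", "compliance_threshold",
                                 "out_dir", "seed", "verbose"))]
  do.call(run_config, c(list(population = pop, priors = priors,
                             mcmc = mcmc), top))
}

test_to_list <- function(tr) {
  out <- list(statistic = unname(tr$statistic[1]),
              statistic_name = names(tr$statistic)[1],
              p_value = tr$p_value, alternative = tr$alternative, n = tr$n)
  if (!is.null(tr$effect))
    out <- c(out, list(effect_name = tr$effect_name, effect = tr$effect,
                       effect_ci = tr$effect_ci))
  if (!is.null(tr$bf)) out$bf10 <- tr$bf
  if (!is.null(tr$log_V)) out$log_V <- tr$log_V
  out
}

#' Run the full analysis pipeline
#'
#' Stages: design generation, population simulation, model fitting and DIC
#' comparison, per-participant measures from the winning model's MAP
#' estimates, and the statistical battery. Artefacts are written to the
#' config's output directory as they are produced (design.csv, choices.csv,
#' truth.csv, fit directories, measures.csv, analysis_report.json, run.log
#' and the resolved config as config.yaml), so a failing stage leaves the
#' earlier outputs in place and reports the stage name.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return the output directory, invisibly; the measures table and report
#'   are attached as attributes.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (config$verbose) message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " start (seed ", config$seed, ")")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  yaml::write_yaml(as_plain(config[setdiff(names(config), "verbose")]),
                   file.path(config$out_dir, "config.yaml"))

  design <- stage("design", {
    d <- partition_subsets(generate_allocation_set())
    write_allocations(d, file.path(config$out_dir, "design.csv"))
    d
  })

  pop <- stage("simulate", {
    popcfg <- config$population
    popcfg$seed <- config$seed
    p <- sample_population(popcfg)
    write_population(p, config$out_dir)
    p
  })
  records <- population_records(pop)
  truth <- population_truth(pop)

  fits <- stage("fit", {
    mcmc <- config$mcmc
    mcmc$seed <- config$seed
    fl <- lapply(config$models, function(m) {
      log_line("  fitting ", m)
      f <- suppressWarnings(
        fit_attitude_model(records, parse_spec(m), config$priors, mcmc))
      write_fit(f, file.path(config$out_dir,
                             paste0("fit_", gsub("/", "_", m))))
      f
    })
    names(fl) <- config$models
    fl
  })
  dics <- vapply(fits, function(f) f$dic$dic, 0)
  winner <- fits[[which.min(dics)]]
  log_line("winner by DIC: ", names(fits)[which.min(dics)])

  measures <- stage("measure", {
    cf <- coef(winner)
    att_a <- if ("attitude_after" %in% colnames(cf)) cf[, "attitude_after"]
             else cf[, "attitude_before"]
    var_a <- if ("variability_after" %in% colnames(cf))
               cf[, "variability_after"] else cf[, "variability_before"]
    params <- data.frame(
      participant_id = winner$participants,
      condition = truth$condition[match(winner$participants,
                                        truth$participant_id)],
      alpha_before = cf[, "attitude_before"], alpha_after = att_a,
      sigma_before = cf[, "variability_before"], sigma_after = var_a,
      kappa_before = cf[, "kappa_before"],
      alpha_obs = truth$alpha_obs[match(winner$participants,
                                        truth$participant_id)])
    m <- measures_table(params, records[records$phase == "before", ],
                        config$compliance_threshold)
    write_measures(m, file.path(config$out_dir, "measures.csv"))
    m
  })

  report <- stage("analyze", {
    rep <- list(dic = as.list(dics),
                winner = names(fits)[which.min(dics)])
    for (cond in unique(measures$condition)) {
      v <- measures$delta_diff[measures$condition == cond]
      if (sum(v != 0) >= 5)
        rep[[paste0("convergence_", cond)]] <-
          test_to_list(wilcoxon_signed(v, alternative = "greater",
                                       seed = config$seed))
    }
    if (length(unique(measures$condition)) >= 2 &&
        all(table(measures$condition) >= 3))
      rep$convergence_by_condition <- test_to_list(
        kruskal_with_posthoc(measures$delta_diff, measures$condition,
                             seed = config$seed))
    ok <- !is.na(measures$compliance_index)
    if (sum(ok) >= 5)
      rep$kappa_compliance_spearman <- test_to_list(
        spearman_assoc(measures$compliance_index[ok],
                       measures$kappa_before[ok], seed = config$seed))
    if (length(unique(measures$condition)) >= 2 && sum(ok) >= 10) {
      m2 <- measures[ok, ]
      m2$compliance <- m2$compliance_index / 100
      # singular at very small n (e.g. a condition with constant compliance)
      rr <- tryCatch(
        robust_linreg(delta_diff ~ 0 + condition + condition:compliance,
                      m2, delta_diff ~ 0 + condition),
        error = function(e) {
          log_line("  compliance regression skipped: ",
                   conditionMessage(e))
          NULL
        })
      if (!is.null(rr)) {
        rep$compliance_regression <- list(
          coefficients = as.list(round(rr$coefficients$estimate, 4)),
          adj_r_squared = rr$adj_r_squared,
          deviance_test = test_to_list(rr$deviance_test))
        names(rep$compliance_regression$coefficients) <-
          rownames(rr$coefficients)
      }
    }
    cc <- measures$consistency_change
    if (sum(cc != 0) >= 5)
      rep$consistency_increase <- test_to_list(
        wilcoxon_signed(cc, alternative = "greater", seed = config$seed))
    # norm battery: prosocial vs antisocial, computer condition
    comp <- pop[vapply(pop, `[[`, "", "condition") == "computer"]
    if (length(comp) >= 10) {
      cls <- vapply(comp, function(p)
        classify_attitude(p$records[p$records$phase == "before", ])$class, "")
      if (length(unique(cls)) == 2) {
        nr <- length(comp[[1]]$norm_ratings)
        bat <- norm_rating_battery(
          unlist(lapply(comp, `[[`, "norm_ratings")),
          rep(cls, each = nr), rep(seq_len(nr), length(comp)))
        rep$norm_battery <- list(
          n_significant_adj = attr(bat, "n_significant_adj"),
          n_favour_null = attr(bat, "n_favour_null"),
          n_favour_alt = attr(bat, "n_favour_alt"))
      }
    }
    jsonlite::write_json(rep,
                         file.path(config$out_dir, "analysis_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })
  log_line("run complete")
  out <- config$out_dir
  attr(out, "measures") <- measures
  attr(out, "report") <- report
  invisible(out)
}
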