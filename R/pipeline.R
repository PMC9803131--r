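#' Default run configuration
#'
#' @param ... overrides of the defaults.
#' @return a named list understood by [run_pipeline()].
#' @export
run_config <- function(...) {
  cfg <- list(
    population = NULL, life_table = NULL, cross_sections = NULL,
    panel = NULL, fixed_transitions = NULL,
    window = NULL, estimation_year = NULL,
    cohort_size = 200000L, rule = "max",
    bootstrap_B = 0L, backend = "mc", seed = 1L,
    out_dir = ".")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config needs the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- do.call(run_config, config)
  if (is.null(cfg$window) || length(cfg$window) != 2L || cfg$window[1L] >= cfg$window[2L])
    stop("config: window must be two ordered years", call. = FALSE)
  if (is.null(cfg$estimation_year)) cfg$estimation_year <- cfg$window[2L]
  if (cfg$estimation_year < cfg$window[2L])
    stop("config: estimation_year must not precede the window end", call. = FALSE)
  if (cfg$cohort_size < 1) stop("config: cohort_size must be >= 1", call. = FALSE)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full estimation pipeline
#'
#' Executes the three-model chain end to end: fits the prevalence trend model
#' to cross-sectional survey data (Model 1), fits transition models to
#' matched panel pairs or loads a fixed transition table (Model 2), runs the
#' cohort microsimulation with life-table censoring (Model 3), computes
#' period prevalence and occupational-turnover ratios, optionally propagates
#' input uncertainty by bootstrap, and writes the result CSVs plus a manifest
#' that suffices to repeat the run.
#'
#' @param config a list from [run_config()] or the path of a YAML file with
#'   the same keys. Required: `population`, `life_table`, `cross_sections`,
#'   either `panel` or `fixed_transitions`, and `window`.
#' @return invisibly, a named list of output file paths plus the in-memory
#'   results.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  year_t <- cfg$window[1L]; year_end <- cfg$window[2L]
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  population <- stage("read population", read_population(cfg$population))
  life <- stage("read life table", read_life_table(cfg$life_table))

  ## Model 1
  prevfit <- stage("prevalence model", {
    cs <- read_cross_sections(cfg$cross_sections)
    prevalence_trend(aggregate_proportions(cs), year0 = year_t)
  })
  prevtab <- stage("prevalence at window start",
                   prevalence_table(prevfit, year_t, interval = "ur"))
  prev_est <- stage("prevalence at estimation year", suppressWarnings(
    prevalence_table(prevfit, cfg$estimation_year, interval = "ur")))

  ## Model 2
  trans <- stage("transition model", {
    if (!is.null(cfg$fixed_transitions)) {
      tt <- read_transition_table(cfg$fixed_transitions)
      sexes <- unique(population$sex)
      # use per-sex blocks when present, else the first block for everyone
      stats::setNames(lapply(sexes, function(s)
        (tt[[s]] %||% tt[[1L]])$matrix), sexes)
    } else {
      panel <- read_panel(cfg$panel)
      yrs <- sort(unique(panel$year))
      pairs <- match_pseudo_panel(panel[panel$year == yrs[1L], ],
                                  panel[panel$year == yrs[2L], ])
      transition_model(pairs)
    }
  })

  ## Model 3
  cohort <- stage("microsimulation", {
    co <- initialize_cohort(population, prevtab, cfg$cohort_size, year_t,
                            seed = cfg$seed)
    co <- simulate_window(co, trans, life, year_end, seed = cfg$seed + 1L)
    censor_to_estimation_year(co, life, cfg$estimation_year, seed = cfg$seed + 2L)
  })
  period <- stage("period prevalence", {
    pp <- period_prevalence(cohort, rule = cfg$rule)
    pe <- prev_est[, c("sex", "age_group", "category", "proportion")]
    # population-weighted overall point prevalence for the "all" stratum
    wt <- population$count[match(paste(pe$sex, pe$age_group),
                                 paste(population$sex, population$age_group))]
    ov <- stats::aggregate(list(proportion = pe$proportion * wt),
                           by = list(category = pe$category), FUN = sum)
    ov$proportion <- ov$proportion / sum(population$count)
    pe <- rbind(pe, data.frame(sex = "all", age_group = "all",
                               category = ov$category, proportion = ov$proportion))
    occupational_turnover(pp, pe)
  })

  paths <- list(prevalence = file.path(cfg$out_dir, "prevalence.csv"),
                period = file.path(cfg$out_dir, "period_prevalence.csv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_prevalence(prevtab, paths$prevalence)

  boot <- NULL
  if (cfg$bootstrap_B >= 2) {
    boot <- stage("bootstrap", {
      prob <- pipeline_problem(population, prevtab, trans, life,
                               year_t, year_end, cfg$estimation_year, cfg$rule)
      bootstrap_period_prevalence(prob, B = cfg$bootstrap_B, seed = cfg$seed + 3L,
                                  backend = cfg$backend,
                                  n = min(cfg$cohort_size, 20000L))
    })
    paths$bootstrap <- file.path(cfg$out_dir, "period_prevalence_ur.csv")
    bs <- boot; attr(bs, "replicates") <- NULL
    utils::write.csv(bs, paths$bootstrap, row.names = FALSE)
  }

  utils::write.csv(period, paths$period, row.names = FALSE)
  manifest <- list(
    package = "expowin",
    version = as.character(utils::packageVersion("expowin")),
    config = cfg,
    rows = list(population = nrow(population), prevalence = nrow(prevtab),
                period = nrow(period)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, period = period, prevalence = prevtab,
                 bootstrap = boot))
}

# reduce the pipeline's fitted objects to a sim_problem: one representative
# age per stratum (band midpoint), per-sex matrices at the share-weighted
# mean age, prevalence sds from the Model 1 uncertainty ranges
pipeline_problem <- function(population, prevtab, trans, life,
                             year_t, year_end, year_a, rule) {
  strata <- population
  strata$share <- strata$count / sum(strata$count)
  rng <- age_band_range(strata$age_group)
  strata$age <- floor((rng[, 1L] + rng[, 2L] - 1) / 2)
  K <- max(prevtab$category) + 1L
  S <- nrow(strata)
  prev <- prev_sd <- matrix(0, S, K)
  for (i in seq_len(S)) {
    sel <- prevtab$sex == strata$sex[i] & prevtab$age_group == strata$age_group[i]
    block <- prevtab[sel, ]
    block <- block[order(block$category), ]
    prev[i, ] <- block$proportion
    prev_sd[i, ] <- if (all(c("lower", "upper") %in% names(block)))
      sd_from_ur(block$proportion, pmin(block$lower, block$proportion),
                 pmax(block$upper, block$proportion)) else 0
  }
  sexes <- unique(strata$sex)
  mean_age <- stats::weighted.mean(strata$age, strata$share)
  tmats <- list(); tsd <- list()
  for (s in sexes) {
    if (inherits(trans, "transfit")) {
      pr <- predict(trans, s, mean_age, se = TRUE)
      tmats[[s]] <- unclass(pr$matrix)
      tsd[[s]] <- pr$se
    } else {
      tmats[[s]] <- unclass(trans[[s]] %||% trans[[1L]])
      tsd[[s]] <- matrix(0, K, K)
    }
  }
  steps <- year_end - year_t
  censor <- year_a - year_end
  qm <- matrix(0, S, steps + censor)
  for (i in seq_len(S)) {
    yrs <- seq(year_t + 1L, year_a)
    qm[i, ] <- q_lookup(life, strata$sex[i], floor(strata$age[i] + seq_along(yrs)),
                        yrs, clamp = TRUE)
  }
  sim_problem(strata, prev, tmats, steps, censor_steps = censor, q = qm,
              prev_sd = prev_sd, trans_sd = tsd, q_sd = 0, rule = rule)
}
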