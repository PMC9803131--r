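#' Generate a fully specified synthetic "truth" world
#'
#' Builds a self-contained generative world for testing and calibration:
#' linear-in-year prevalence coefficients per (country, sex, age group,
#' category), a smooth age-dependent transition structure per sex
#' (multinomial-logit in age and age squared, additive sex effect on the
#' log-odds), a Gompertz-like life table, and a population structure at the
#' window's first year. All downstream estimators can be validated against
#' this world because every quantity they target is known exactly.
#'
#' @param K number of exposure categories (>= 2). The default 6 uses the
#'   working-hours bands (inactive, 0-34, 35-40, 41-48, 49-54, >= 55 h/week).
#' @param countries character vector of country codes (>= 1).
#' @param sexes character vector, default `c("female", "male")`.
#' @param age_groups character vector of 5-year band labels.
#' @param years integer vector of calendar years covered by the world.
#' @param seed integer seed; the world is bit-reproducible given the seed.
#' @param slope_scale typical magnitude of the per-year prevalence drift.
#'   Default 0.003 (0.3 percentage points/year), a realistic labour-market
#'   trend magnitude.
#' @param persistence additive log-odds bonus for staying in the current
#'   category; larger values give more diagonal-dominant transition matrices.
#' @param gompertz list with elements `a` (named per sex) and `b`: annual
#'   death probability q(age) = min(1, a * exp(b * age)); `year_factor`
#'   multiplies q per calendar year after the first (1 = constant mortality).
#' @param population_total total population count at the first year.
#' @return an object of class `truth_world`.
#' @export
make_truth <- function(K = 6L,
                       countries = "ITA",
                       sexes = c("female", "male"),
                       age_groups = age_groups_5y(),
                       years = 2002:2011,
                       seed = 1L,
                       slope_scale = 0.003,
                       persistence = 2.8,
                       gompertz = list(a = c(female = 1.6e-5, male = 3.2e-5),
                                       b = 0.095, year_factor = 1),
                       population_total = 1e6) {
  if (!is.numeric(K) || K < 2) stop("configuration error: K must be >= 2", call. = FALSE)
  K <- as.integer(K)
  if (length(countries) < 1L) stop("configuration error: at least one country required", call. = FALSE)
  if (length(years) < 1L) stop("configuration error: empty year range", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("configuration error: seed required", call. = FALSE)
  if (length(sexes) < 1L) stop("configuration error: at least one sex required", call. = FALSE)

  categories <- default_category_labels(K)
  span <- max(years) - min(years)
  cells <- expand.grid(country = countries, sex = sexes, age_group = age_groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  world <- with_seed(seed, {
    ## prevalence truth: Dirichlet intercepts, zero-sum slopes kept inside [eps, 1-eps]
    eps <- 0.005
    nc <- nrow(cells)
    A <- matrix(stats::rgamma(nc * K, shape = 2), nc, K)
    A <- A / rowSums(A)
    A <- A * (1 - 2 * eps * K) + 2 * eps   # floor each entry at 2*eps, rows still sum to 1
    B <- matrix(stats::rnorm(nc * K, sd = slope_scale), nc, K)
    B <- B - rowMeans(B)                               # slopes sum to 0 per cell
    if (span > 0) {
      # shrink slopes per cell so A + B*t stays within [eps, 1-eps] for t in [0, span]
      for (i in seq_len(nc)) {
        s <- 1
        for (k in seq_len(K)) {
          if (B[i, k] < 0) s <- min(s, (A[i, k] - eps) / (-B[i, k] * span))
          if (B[i, k] > 0) s <- min(s, (1 - eps - A[i, k]) / (B[i, k] * span))
        }
        B[i, ] <- B[i, ] * max(0, s)
      }
    }

    ## transition truth: per origin, destination log-odds vs pivot 0 are
    ## intercept + sexM + b1*(age/50) + b2*(age/50)^2
    trans <- array(0, dim = c(K, K, 4L),
                   dimnames = list(origin = NULL, dest = NULL,
                                   coef = c("intercept", "sexM", "a1", "a2")))
    for (o in seq_len(K)) {
      for (d in 2:K) {  # destination index 1 (category 0) is the pivot: all zeros
        trans[o, d, ] <- c(stats::rnorm(1, sd = 0.5) +
                             if (d == o) persistence else if (o == 1L) -persistence else 0,
                           stats::rnorm(1, sd = 0.2),
                           stats::rnorm(1, sd = 0.25),
                           stats::rnorm(1, sd = 0.15))
      }
    }
    # origin 0 keeps its pivot at zero; its other destinations are shifted down
    # by `persistence`, which is equivalent to a stay-put bonus on the pivot

    ## population: smooth, vaguely Italy-like age pyramid
    base <- c(2.9, 3.0, 3.7, 4.4, 4.6, 4.5, 4.2, 4.0, 3.7, 3.5,
              3.0, 2.8, 2.6, 2.2, 1.6, 0.9, 0.3)
    gshape <- if (length(age_groups) == 17L) base else
      stats::dnorm(seq_along(age_groups), mean = length(age_groups) / 3,
                   sd = length(age_groups) / 2.2)
    fshare <- seq(0.49, 0.62, length.out = length(age_groups))
    pop <- expand.grid(sex = sexes, age_group = age_groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sh <- gshape[match(pop$age_group, age_groups)]
    if (setequal(sexes, c("female", "male")))
      sh <- sh * ifelse(pop$sex == "female",
                        fshare[match(pop$age_group, age_groups)],
                        1 - fshare[match(pop$age_group, age_groups)])
    else sh <- sh / length(sexes)
    pop$count <- round(population_total * sh / sum(sh))

    list(A = A, B = B, trans = trans, pop = pop)
  })

  structure(list(
    K = K, categories = categories, countries = countries, sexes = sexes,
    age_groups = age_groups, years = years, seed = as.integer(seed),
    cells = cells, prev_A = world$A, prev_B = world$B,
    trans_coef = world$trans, gompertz = gompertz,
    population = world$pop
  ), class = "truth_world")
}

#' @export
print.truth_world <- function(x, ...) {
  cat("Synthetic truth world\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  cat("  countries: ", paste(x$countries, collapse = ", "),
      " | sexes: ", paste(x$sexes, collapse = ", "), "\n", sep = "")
  cat("  age groups:", length(x$age_groups), "| years:",
      min(x$years), "-", max(x$years), "| seed:", x$seed, "\n")
  invisible(x)
}

cell_index <- function(truth, country, sex, age_group) {
  i <- which(truth$cells$country == country & truth$cells$sex == sex &
             truth$cells$age_group == age_group)
  if (length(i) != 1L)
    stop("unknown cell (", country, ", ", sex, ", ", age_group, ")", call. = FALSE)
  i
}

#' True prevalence vector of a cell at a year
#'
#' @param truth a `truth_world`.
#' @param country,sex,age_group cell identifiers.
#' @param year calendar year within the world's range.
#' @return numeric vector of K proportions summing to 1.
#' @export
truth_prevalence <- function(truth, country, sex, age_group, year) {
  if (year < min(truth$years) || year > max(truth$years))
    stop("year ", year, " outside the truth range", call. = FALSE)
  i <- cell_index(truth, country, sex, age_group)
  p <- truth$prev_A[i, ] + truth$prev_B[i, ] * (year - min(truth$years))
  check_prob_vector(p, tol = 1e-9, what = "truth prevalence")
  p
}

#' True annual transition matrix for a sex at an exact age
#'
#' @param truth a `truth_world`.
#' @param sex one of the world's sexes.
#' @param age age in years (> 0).
#' @return K x K row-stochastic matrix of class `transition_matrix`.
#' @export
truth_transition_matrix <- function(truth, sex, age) {
  sexM <- as.numeric(sex == "male")
  x <- c(1, sexM, age / 50, (age / 50)^2)
  eta <- apply(truth$trans_coef, c(1, 2), function(b) sum(b * x))
  M <- softmax_rows(eta)
  new_transition_matrix(M, labels = truth$categories, sex = sex, age = age)
}

#' True annual death probability
#'
#' @param truth a `truth_world`.
#' @param sex,age,year vectors (recycled) identifying the life-table cell.
#' @return numeric vector of probabilities in [0, 1].
#' @export
truth_qx <- function(truth, sex, age, year) {
  g <- truth$gompertz
  a <- g$a[sex]
  yf <- if (is.null(g$year_factor)) 1 else g$year_factor
  pmin(1, a * exp(g$b * age) * yf^(year - min(truth$years)))
}

#' Sample cross-sectional survey records from a truth world
#'
#' Draws `n_per_cell` weighted records per (year, country, sex, age group)
#' cell, with categories drawn multinomially from the truth prevalence.
#'
#' @param truth a `truth_world`.
#' @param n_per_cell records per cell (>= 1).
#' @param years years to survey (within the truth range).
#' @param seed integer seed for the draws.
#' @return data.frame with columns year, country, sex, age_group, category
#'   (0-based), weight.
#' @export
sample_cross_sections <- function(truth, n_per_cell, years = truth$years, seed = truth$seed) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1", call. = FALSE)
  if (any(years < min(truth$years) | years > max(truth$years)))
    stop("survey years outside the truth range", call. = FALSE)
  grid <- expand.grid(year = years, i = seq_len(nrow(truth$cells)),
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    out <- vector("list", nrow(grid))
    for (r in seq_len(nrow(grid))) {
      i <- grid$i[r]
      cell <- truth$cells[i, ]
      p <- truth$prev_A[i, ] + truth$prev_B[i, ] * (grid$year[r] - min(truth$years))
      out[[r]] <- data.frame(
        year = grid$year[r], country = cell$country, sex = cell$sex,
        age_group = cell$age_group,
        category = sample.int(truth$K, n_per_cell, replace = TRUE, prob = p) - 1L,
        weight = stats::runif(n_per_cell, 0.5, 1.5))
    }
    do.call(rbind, out)
  })
}

#' Sample raw two-wave rotating-panel records from a truth world
#'
#' Emulates a rotating-panel labour-force survey: individuals observed in two
#' consecutive annual waves, identified only by the quasi-identifier tuple
#' (household number, household sequence number, sex, year of birth). The
#' second-wave category is drawn from the truth transition matrix at the
#' individual's age. A configurable fraction of individuals is lost to
#' attrition (absent from wave two), and a configurable fraction gets a
#' duplicated key (a "collision") so the matcher's discard rule is exercised.
#'
#' @param truth a `truth_world`.
#' @param n_households number of households (>= 1); each holds 1-3 members.
#' @param years length-2 vector of consecutive years (t, t+1).
#' @param seed integer seed.
#' @param attrition fraction of individuals missing from the second wave.
#' @param collision fraction of individuals whose key is duplicated in wave 1.
#' @param age_range inclusive integer range of ages at wave 1.
#' @param country country code stamped on the records (first truth country).
#' @return data.frame with columns hh_id, seq, sex, birth_year, year,
#'   category, weight; attribute `panel_truth` records the bookkeeping counts.
#' @export
sample_rotating_panel <- function(truth, n_households, years, seed = truth$seed,
                                  attrition = 0.1, collision = 0,
                                  age_range = c(15, 79),
                                  country = truth$countries[1L]) {
  if (n_households < 1) stop("n_households must be >= 1", call. = FALSE)
  if (length(years) != 2L || years[2L] != years[1L] + 1L)
    stop("panel years must be a consecutive pair (t, t+1)", call. = FALSE)
  with_seed(seed, {
    members <- sample(1:3, n_households, replace = TRUE)
    n <- sum(members)
    hh <- rep(seq_len(n_households), members)
    sq <- sequence(members)
    sex <- sample(truth$sexes, n, replace = TRUE)
    age <- sample(seq(age_range[1L], age_range[2L]), n, replace = TRUE)
    by <- years[1L] - age
    grp <- age_to_group(age, truth$age_groups)
    w <- stats::runif(n, 0.5, 1.5)

    yr <- min(max(years[1L], min(truth$years)), max(truth$years)) - min(truth$years)
    cat_t <- integer(n)
    for (s in unique(sex)) for (g in unique(grp)) {
      idx <- which(sex == s & grp == g)
      if (!length(idx)) next
      i <- cell_index(truth, country, s, g)
      p <- truth$prev_A[i, ] + truth$prev_B[i, ] * yr
      cat_t[idx] <- sample.int(truth$K, length(idx), replace = TRUE, prob = p) - 1L
    }
    cat_t1 <- integer(n)
    for (s in truth$sexes) for (a in unique(age)) {
      idx <- which(sex == s & age == a)
      if (!length(idx)) next
      M <- truth_transition_matrix(truth, s, a)
      for (o in unique(cat_t[idx])) {
        ii <- idx[cat_t[idx] == o]
        cat_t1[ii] <- sample.int(truth$K, length(ii), replace = TRUE, prob = M[o + 1L, ]) - 1L
      }
    }

    attrited <- stats::runif(n) < attrition
    collided <- stats::runif(n) < collision

    w1 <- data.frame(hh_id = hh, seq = sq, sex = sex, birth_year = by,
                     year = years[1L], category = cat_t, weight = w)
    # collisions: a second wave-1 record with the same key but its own category
    if (any(collided)) {
      dup <- w1[collided, ]
      dup$category <- sample.int(truth$K, nrow(dup), replace = TRUE) - 1L
      w1 <- rbind(w1, dup)
    }
    w2 <- data.frame(hh_id = hh, seq = sq, sex = sex, birth_year = by,
                     year = years[2L], category = cat_t1, weight = w)[!attrited, ]
    out <- rbind(w1, w2)
    rownames(out) <- NULL
    attr(out, "panel_truth") <- list(
      n_individuals = n, n_attrited = sum(attrited), n_collided = sum(collided),
      n_matchable = sum(!attrited & !collided))
    out
  })
}

#' Materialise a truth world's life table as a data frame
#'
#' @param truth a `truth_world`.
#' @param ages integer ages to tabulate.
#' @param years calendar years to tabulate.
#' @return data.frame with columns sex, age, year, qx.
#' @export
truth_life_table <- function(truth, ages = 15:110, years = truth$years) {
  g <- expand.grid(sex = truth$sexes, age = ages, year = years,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$qx <- truth_qx(truth, g$sex, g$age, g$year)
  g
}

#' Export a truth world's input tables as CSV fixtures
#'
#' Writes the population, life-table, cross-section and panel tables in the
#' formats the package's readers consume, so a full pipeline run can start
#' from files on disk.
#'
#' @param truth a `truth_world`.
#' @param out_dir writable directory.
#' @param n_per_cell cross-section records per cell.
#' @param panel_households households in the rotating panel.
#' @param panel_years consecutive year pair for the panel.
#' @param ... passed on to [sample_rotating_panel()].
#' @return invisibly, a named list of the file paths written.
#' @export
export_fixtures <- function(truth, out_dir, n_per_cell = 50,
                            panel_households = 2000,
                            panel_years = truth$years[1:2], ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir, call. = FALSE)
  paths <- list(
    population = file.path(out_dir, "population.csv"),
    life_table = file.path(out_dir, "life_table.csv"),
    cross_sections = file.path(out_dir, "cross_sections.csv"),
    panel = file.path(out_dir, "panel.csv"))
  ya <- max(truth$years) + 15L
  write_population(truth$population, paths$population)
  write_life_table(truth_life_table(truth, years = min(truth$years):ya), paths$life_table)
  write_cross_sections(sample_cross_sections(truth, n_per_cell), paths$cross_sections)
  write_panel(sample_rotating_panel(truth, panel_households, panel_years, ...), paths$panel)
  invisible(paths)
}
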