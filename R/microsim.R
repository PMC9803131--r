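#' Initialize a representative synthetic cohort (Step A)
#'
#' Allocates `n` individuals across sex x age-group strata by largest-remainder
#' rounding of the population shares, draws exact ages uniformly within each
#' 5-year band (95+ spans ages 95-99), and assigns initial exposure categories
#' by a seeded multinomial draw from the first-year prevalence of the stratum.
#'
#' @param population data.frame with columns sex, age_group, count.
#' @param prevalence data.frame with columns sex, age_group, category,
#'   proportion — the point prevalence at the window's first year.
#' @param n cohort size (the reference application uses 200,000).
#' @param year_t first year of the time window.
#' @param seed integer seed.
#' @param K number of categories; inferred from `prevalence` if missing.
#' @return an object of class `cohort`.
#' @export
initialize_cohort <- function(population, prevalence, n, year_t, seed,
                              K = max(prevalence$category) + 1L) {
  if (sum(population$count) <= 0) stop("population counts are all zero", call. = FALSE)
  if (any(population$count < 0)) stop("population counts must be >= 0", call. = FALSE)
  sizes <- largest_remainder(population$count, n)
  with_seed(seed, {
    sex <- rep(population$sex, sizes)
    grp <- rep(population$age_group, sizes)
    rng <- age_band_range(grp)
    age0 <- stats::runif(length(sex), rng[, 1L], rng[, 2L])
    cat0 <- integer(length(sex))
    pos <- cumsum(sizes)
    start <- c(1L, utils::head(pos, -1L) + 1L)
    for (i in seq_len(nrow(population))) {
      if (sizes[i] == 0L) next
      p <- prevalence$proportion[prevalence$sex == population$sex[i] &
                                 prevalence$age_group == population$age_group[i]]
      ord <- order(prevalence$category[prevalence$sex == population$sex[i] &
                                       prevalence$age_group == population$age_group[i]])
      p <- p[ord]
      if (length(p) != K) stop("prevalence vector missing for stratum (",
                               population$sex[i], ", ", population$age_group[i], ")",
                               call. = FALSE)
      check_prob_vector(p, tol = 1e-6, what = "initial prevalence")
      cat0[start[i]:pos[i]] <- sample.int(K, sizes[i], replace = TRUE, prob = p) - 1L
    }
    structure(list(
      data = data.frame(id = seq_along(sex), sex = sex, age_group = grp, age0 = age0),
      seq = matrix(cat0, ncol = 1L),
      alive = rep(TRUE, length(sex)),
      age = age0, years = year_t, K = K, year_a = NULL,
      alive_at_est = NULL), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$data), "| categories:", x$K, "\n")
  cat("  window years recorded:", min(x$years), "-", max(x$years),
      "| alive:", sum(x$alive), "\n")
  if (!is.null(x$year_a))
    cat("  censored to estimation year", x$year_a, "| alive then:",
        sum(x$alive_at_est), "\n")
  invisible(x)
}

#' Inverse-CDF assignment of the next exposure category (Step B)
#'
#' Splits the (0,1) interval by the cumulative transition probabilities of the
#' current category's row and returns the smallest category k whose cumulative
#' sum exceeds the uniform draw.
#'
#' @param category current category (0-based; used only for validation).
#' @param row probability vector over destination categories.
#' @param u uniform(0,1) draw.
#' @return next category, 0-based.
#' @examples
#' step_transition(0, c(0.2, 0.3, 0.5), 0.6)  # 2
#' @export
step_transition <- function(category, row, u) {
  check_prob_vector(row, tol = 1e-9, what = "transition row")
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)", call. = FALSE)
  min(findInterval(u, cumsum(row)), length(row) - 1L)
}

#' Annual mortality draw (Step C)
#'
#' An individual dies in the year iff the uniform draw falls below the
#' life-table death probability for their sex, exact (integer) age and year.
#'
#' @param life_table a `lifetable` object (see [make_life_table()]).
#' @param sex,age,year life-table cell.
#' @param u uniform(0,1) draw.
#' @return logical: TRUE if still alive.
#' @export
step_mortality <- function(life_table, sex, age, year, u) {
  q <- q_lookup(life_table, sex, floor(age), year, clamp = FALSE)
  u >= q
}

resolve_transitions <- function(transitions, sexes, K) {
  if (inherits(transitions, "transfit")) {
    lk <- transition_lookup(transitions, sexes)
    ages <- attr(lk, "ages")
    return(function(sex, age) {
      i <- pmin(length(ages), pmax(1L, floor(age) - ages[1L] + 1L))
      lk[[sex]][i, , , drop = FALSE]
    })
  }
  if (is.function(transitions)) {
    return(function(sex, age) {
      out <- array(0, dim = c(length(age), K, K))
      for (i in seq_along(age)) out[i, , ] <- unclass(transitions(sex, age[i]))
      out
    })
  }
  if (is.list(transitions) && !is.matrix(transitions)) {
    for (M in transitions) check_row_stochastic(unclass(M), tol = 1e-9)
    return(function(sex, age) {
      M <- unclass(transitions[[sex]])
      array(rep(M, each = length(age)), dim = c(length(age), nrow(M), ncol(M)))
    })
  }
  M <- unclass(as.matrix(transitions))
  check_row_stochastic(M, tol = 1e-9)
  function(sex, age) array(rep(M, each = length(age)),
                           dim = c(length(age), nrow(M), ncol(M)))
}

# vectorised inverse-CDF draw: rows of `P` (n x K) are the applicable
# transition rows, already matched to individuals
draw_next <- function(P, u) {
  K <- ncol(P)
  U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1   # cum = P %*% U, row-wise cumsum
  cum <- P %*% U
  k <- rowSums(cum <= u)          # counts cum_j <= u  ==> smallest k with u < cum_k
  pmin(k, K - 1L)
}

#' Evolve the cohort over the time window (Step B + within-window censoring)
#'
#' For each year after the window's first: ages increase by one, a mortality
#' draw censors individuals (death is absorbing), and survivors transition
#' between exposure categories by the inverse-CDF rule applied to the
#' transition row for their sex and exact integer age. Sequences are recorded
#' per year; entries after death are NA.
#'
#' @param cohort a `cohort` from [initialize_cohort()].
#' @param transitions a `transition_matrix` (applied to everyone), a named
#'   per-sex list of matrices, a `transfit`, or a function(sex, age) returning
#'   a matrix.
#' @param life_table a `lifetable`, or NULL for zero mortality.
#' @param year_end last year of the window.
#' @param seed integer seed for the simulation draws.
#' @return the evolved `cohort`.
#' @export
simulate_window <- function(cohort, transitions, life_table = NULL, year_end, seed) {
  year_t <- cohort$years[1L]
  if (year_end < year_t) stop("year_end before the window start", call. = FALSE)
  n <- nrow(cohort$data)
  K <- cohort$K
  getP <- resolve_transitions(transitions, unique(cohort$data$sex), K)
  with_seed(seed, {
    for (year in seq.int(year_t + 1L, length.out = year_end - year_t)) {
      cohort$age <- cohort$age + 1
      if (!is.null(life_table)) {
        u <- stats::runif(n)
        die <- cohort$alive &
          u < q_lookup(life_table, cohort$data$sex, floor(cohort$age), year, clamp = TRUE)
        cohort$alive[die] <- FALSE
      }
      cur <- cohort$seq[, ncol(cohort$seq)]
      nxt <- rep(NA_integer_, n)
      u <- stats::runif(n)
      for (s in unique(cohort$data$sex)) {
        idx <- which(cohort$alive & cohort$data$sex == s)
        if (!length(idx)) next
        P <- getP(s, cohort$age[idx])   # length(idx) x K x K
        rows <- P[cbind(rep(seq_along(idx), K), rep(cur[idx] + 1L, K),
                        rep(seq_len(K), each = length(idx)))]
        rows <- matrix(rows, nrow = length(idx))
        nxt[idx] <- draw_next(rows, u[idx])
      }
      cohort$seq <- cbind(cohort$seq, nxt)
      cohort$years <- c(cohort$years, year)
    }
  })
  dimnames(cohort$seq) <- NULL
  cohort
}

#' Censor the cohort for deaths after the time window (Step C)
#'
#' Applies mortality-only annual steps from the end of the window to the
#' estimation year; exposure sequences stay frozen. Individuals alive at the
#' estimation year form the analysis cohort.
#'
#' @param cohort an evolved `cohort`.
#' @param life_table a `lifetable`, or NULL for zero post-window mortality.
#' @param year_a estimation year (>= last window year).
#' @param seed integer seed.
#' @return the `cohort` with `alive_at_est` flags and `year_a` set.
#' @export
censor_to_estimation_year <- function(cohort, life_table, year_a, seed) {
  year_end <- max(cohort$years)
  if (year_a < year_end) stop("estimation year before the window end", call. = FALSE)
  alive <- cohort$alive
  with_seed(seed, {
    for (year in seq.int(year_end + 1L, length.out = year_a - year_end)) {
      cohort$age <- cohort$age + 1
      if (!is.null(life_table)) {
        u <- stats::runif(length(alive))
        die <- alive & u < q_lookup(life_table, cohort$data$sex,
                                    floor(cohort$age), year, clamp = TRUE)
        alive[die] <- FALSE
      }
    }
  })
  cohort$alive_at_est <- alive
  cohort$year_a <- year_a
  cohort
}

# assign one category per individual from its window sequence
assign_category <- function(m, rule = c("max", "max2", "most")) {
  rule <- match.arg(rule)
  if (rule == "max") return(do.call(pmax, as.data.frame(m)))
  if (rule == "max2") {
    if (ncol(m) < 2L) return(do.call(pmax, as.data.frame(m)))
    eq <- m[, -1L, drop = FALSE] == m[, -ncol(m), drop = FALSE]
    cand <- m[, -1L, drop = FALSE]
    cand[!eq] <- -1L
    best2 <- do.call(pmax, as.data.frame(cand))
    fallback <- do.call(pmax, as.data.frame(m))
    return(ifelse(best2 >= 0, best2, fallback))
  }
  K <- max(m) + 1L
  counts <- vapply(0:(K - 1L), function(k) rowSums(m == k), numeric(nrow(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  max.col(counts, ties.method = "last") - 1L   # ties go to the higher category
}

#' Period prevalence over the time window
#'
#' Among individuals alive at the estimation year, assigns each to one
#' category over the window — `"max"`: the highest category in the sequence;
#' `"max2"`: the highest category held for at least two consecutive years
#' (falling back to the sequence maximum when none is); `"most"`: the modal
#' category, ties resolved toward the higher category — and tabulates
#' proportions per sex x age-group stratum and overall.
#'
#' @param cohort a simulated (and typically censored) `cohort`.
#' @param rule `"max"` (default), `"max2"`, or `"most"`.
#' @param by `"stratum"` for per-(sex, age-group) results plus an overall
#'   row set, or `"overall"` only.
#' @return data.frame of class `period_prevalence`: sex, age_group, category,
#'   proportion, alive_n. Strata with zero alive individuals have NA
#'   proportions.
#' @export
period_prevalence <- function(cohort, rule = c("max", "max2", "most"),
                              by = c("stratum", "overall")) {
  rule <- match.arg(rule)
  by <- match.arg(by)
  alive <- if (!is.null(cohort$alive_at_est)) cohort$alive_at_est else cohort$alive
  K <- cohort$K
  res <- list()
  tab_one <- function(sel, sex, grp) {
    n_alive <- sum(sel)
    p <- if (n_alive == 0L) rep(NA_real_, K) else {
      a <- assign_category(cohort$seq[sel, , drop = FALSE], rule)
      tabulate(a + 1L, nbins = K) / n_alive
    }
    data.frame(sex = sex, age_group = grp, category = 0:(K - 1L),
               proportion = p, alive_n = n_alive)
  }
  if (by == "stratum") {
    strata <- unique(cohort$data[, c("sex", "age_group")])
    for (r in seq_len(nrow(strata))) {
      sel <- alive & cohort$data$sex == strata$sex[r] &
        cohort$data$age_group == strata$age_group[r]
      res[[length(res) + 1L]] <- tab_one(sel, strata$sex[r], strata$age_group[r])
    }
  }
  res[[length(res) + 1L]] <- tab_one(alive, "all", "all")
  out <- do.call(rbind, res)
  attr(out, "rule") <- rule
  class(out) <- c("period_prevalence", class(out))
  out
}

#' Occupational turnover ratios
#'
#' The ratio of period prevalence over the window to point prevalence in a
#' chosen year, per category: point prevalence x OT = period prevalence. A
#' constant OT of 4 has been used by earlier burden-of-disease studies; this
#' function returns the category- and cohort-specific values.
#'
#' @param period numeric vector of period-prevalence proportions, or a
#'   `period_prevalence` data.frame.
#' @param point numeric vector of point-prevalence proportions (same category
#'   order), or a data.frame with columns sex, age_group, category,
#'   proportion matching the strata of `period`.
#' @return numeric vector (or the data.frame with an `ot` column); NA where
#'   point prevalence is zero.
#' @export
occupational_turnover <- function(period, point) {
  if (is.data.frame(period)) {
    if (is.data.frame(point)) {
      key <- function(d) paste(d$sex, d$age_group, d$category, sep = "\r")
      pp <- point$proportion[match(key(period), key(point))]
    } else pp <- rep(point, length.out = nrow(period))
    period$ot <- ifelse(pp > 0, period$proportion / pp, NA_real_)
    return(period)
  }
  ifelse(point > 0, period / point, NA_real_)
}

#' Exact period-prevalence distribution (dynamic-programming oracle)
#'
#' Computes the exact distribution of the assigned over-window category for a
#' single cohort profile, by dynamic programming over the joint state
#' (current category, maximum category so far), with an annual survival
#' factor applied before each transition. Because mortality does not depend
#' on the exposure category, conditioning on survival leaves the distribution
#' unchanged; the survival probability is still tracked and returned. For
#' rules other than `"max"` the distribution is computed by full path
#' enumeration, feasible only for tiny systems.
#'
#' @param init initial category distribution (length K).
#' @param matrices a single K x K matrix, or a list of length `steps` (one
#'   per transition year).
#' @param steps number of annual transitions in the window.
#' @param q annual death probabilities, scalar or length `steps` (+ optional
#'   further censoring years appended via `q_censor`).
#' @param q_censor death probabilities for the years between the window end
#'   and the estimation year (affects survival only).
#' @param rule `"max"` (DP; K <= 8, steps <= 15), `"max2"` or `"most"`
#'   (path enumeration; K <= 3, steps <= 6).
#' @return list with `proportion` (length-K exact distribution conditional on
#'   being alive at the estimation year) and `alive_prob`.
#' @export
exact_period_prevalence <- function(init, matrices, steps, q = 0, q_censor = numeric(),
                                    rule = c("max", "max2", "most")) {
  rule <- match.arg(rule)
  K <- length(init)
  check_prob_vector(init, tol = 1e-9, what = "initial distribution")
  Ms <- if (is.matrix(matrices) || inherits(matrices, "transition_matrix"))
    rep(list(unclass(as.matrix(matrices))), steps) else matrices
  if (length(Ms) != steps) stop("need one matrix per transition step", call. = FALSE)
  for (M in Ms) check_row_stochastic(unclass(as.matrix(M)), tol = 1e-9)
  qv <- rep(q, length.out = steps)
  surv <- prod(1 - qv) * prod(1 - q_censor)

  if (rule != "max") {
    if (K > 3 || steps > 6)
      stop("path enumeration limited to K <= 3 and steps <= 6", call. = FALSE)
    paths <- as.matrix(expand.grid(rep(list(0:(K - 1L)), steps + 1L)))
    pr <- init[paths[, 1L] + 1L]
    for (t in seq_len(steps))
      pr <- pr * unclass(as.matrix(Ms[[t]]))[cbind(paths[, t] + 1L, paths[, t + 1L] + 1L)]
    assigned <- assign_category(paths, rule)
    p <- as.numeric(tapply(pr, factor(assigned, levels = 0:(K - 1L)), sum, default = 0))
    return(list(proportion = p / sum(p), alive_prob = surv))
  }
  if (K > 8 || steps > 15)
    stop("DP oracle limited to K <= 8 and steps <= 15", call. = FALSE)
  T <- matrix(0, K, K)            # T[cur, max-so-far]
  T[cbind(seq_len(K), seq_len(K))] <- init
  for (t in seq_len(steps)) {
    M <- unclass(as.matrix(Ms[[t]]))
    T2 <- matrix(0, K, K)
    for (c1 in seq_len(K)) for (m in seq_len(K)) {
      mass <- T[c1, m]
      if (mass == 0) next
      for (c2 in seq_len(K)) {
        m2 <- max(m, c2)
        T2[c2, m2] <- T2[c2, m2] + mass * M[c1, c2]
      }
    }
    T <- T2
  }
  p <- colSums(T)
  list(proportion = p / sum(p), alive_prob = surv)
}

#' Monte Carlo period prevalence for a single cohort profile
#'
#' The stochastic counterpart of [exact_period_prevalence()]: simulates `n`
#' individuals from an initial distribution through `steps` annual
#' transitions with optional mortality, and tabulates the assigned
#' over-window categories among survivors.
#'
#' @inheritParams exact_period_prevalence
#' @param n cohort size.
#' @param seed integer seed.
#' @return list with `proportion` (length K), `alive_n`, and `n`.
#' @export
mc_period_prevalence <- function(init, matrices, steps, n, seed, q = 0,
                                 q_censor = numeric(),
                                 rule = c("max", "max2", "most")) {
  rule <- match.arg(rule)
  K <- length(init)
  check_prob_vector(init, tol = 1e-9, what = "initial distribution")
  Ms <- if (is.matrix(matrices) || inherits(matrices, "transition_matrix"))
    rep(list(unclass(as.matrix(matrices))), steps) else lapply(matrices, function(M) unclass(as.matrix(M)))
  qv <- rep(q, length.out = steps)
  with_seed(seed, {
    cur <- sample.int(K, n, replace = TRUE, prob = init) - 1L
    seqm <- matrix(cur, ncol = 1L)
    alive <- rep(TRUE, n)
    for (t in seq_len(steps)) {
      if (qv[t] > 0) alive <- alive & (stats::runif(n) >= qv[t])
      u <- stats::runif(n)
      nxt <- rep(NA_integer_, n)
      idx <- which(alive)
      if (length(idx)) {
        rows <- Ms[[t]][cur[idx] + 1L, , drop = FALSE]
        nxt[idx] <- draw_next(rows, u[idx])
      }
      cur <- nxt
      seqm <- cbind(seqm, nxt)
    }
    for (qc in q_censor) if (qc > 0) alive <- alive & (stats::runif(n) >= qc)
    alive_n <- sum(alive)
    p <- if (alive_n == 0L) rep(NA_real_, K) else {
      a <- assign_category(seqm[alive, , drop = FALSE], rule)
      tabulate(a + 1L, nbins = K) / alive_n
    }
    list(proportion = p, alive_n = alive_n, n = n)
  })
}
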