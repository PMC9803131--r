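#' Construct a validated annual transition matrix
#'
#' @param M K x K numeric matrix, rows indexed by origin category, columns by
#'   destination; rows must be valid probability distributions.
#' @param labels optional category labels.
#' @param sex,age optional tags recording which cohort the matrix applies to.
#' @param tol row-sum tolerance.
#' @return `M` with class `transition_matrix`.
#' @export
new_transition_matrix <- function(M, labels = NULL, sex = NULL, age = NULL, tol = 1e-9) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("transition matrix must be square", call. = FALSE)
  check_row_stochastic(M, tol = tol)
  if (!is.null(labels)) dimnames(M) <- list(origin = labels, dest = labels)
  structure(M, class = c("transition_matrix", class(M)),
            sex = sex, age = age)
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Annual transition matrix (", nrow(x), " categories",
      if (!is.null(attr(x, "sex"))) paste0("; sex = ", attr(x, "sex")),
      if (!is.null(attr(x, "age"))) paste0("; age = ", attr(x, "age")),
      ")\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Load a fixed transition matrix given in percent
#'
#' Converts a K x K table of percentages (e.g. a published transition table)
#' to proportions, optionally renormalising each row to sum exactly to 1 —
#' published rows often sum to slightly off 100% due to rounding.
#'
#' @param tab numeric K x K matrix or data.frame of percentages.
#' @param renormalize divide each row by its sum (default TRUE).
#' @param labels optional category labels.
#' @return a `transition_matrix`.
#' @export
load_fixed_matrix <- function(tab, renormalize = TRUE, labels = NULL) {
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M)) stop("fixed matrix must be square", call. = FALSE)
  if (any(M < 0)) stop("fixed matrix has negative entries", call. = FALSE)
  rs <- rowSums(M)
  if (any(abs(rs - 100) > 20))
    stop("row sum deviates from 100% by more than 20% (row ",
         which.max(abs(rs - 100)), ": ", format(max(rs)), ")", call. = FALSE)
  M <- M / 100
  if (renormalize) M <- M / rowSums(M)
  new_transition_matrix(M, labels = labels, tol = if (renormalize) 1e-12 else 0.21)
}

#' Match rotating-panel waves into pseudo-longitudinal pairs
#'
#' Joins two consecutive survey waves on the quasi-identifier tuple
#' (household number, household sequence number, sex, year of birth). Key
#' tuples matching more than one record in either wave are ambiguous and are
#' discarded.
#'
#' @param wave_t,wave_t1 data.frames with columns hh_id, seq, sex,
#'   birth_year, year, category, weight.
#' @return data.frame of panel pairs: sex, age (at the first wave), from, to,
#'   weight (the first-wave weight). Attribute `match_rate` records matched
#'   pairs / wave-1 records.
#' @export
match_pseudo_panel <- function(wave_t, wave_t1) {
  need <- c("hh_id", "seq", "sex", "birth_year", "category", "weight")
  for (w in list(wave_t, wave_t1)) {
    miss <- setdiff(need, names(w))
    if (length(miss)) stop("panel wave missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- function(d) paste(d$hh_id, d$seq, d$sex, d$birth_year, sep = "\r")
  k1 <- key(wave_t); k2 <- key(wave_t1)
  amb <- union(k1[duplicated(k1)], k2[duplicated(k2)])
  a <- wave_t[!(k1 %in% amb), ]; ka <- k1[!(k1 %in% amb)]
  b <- wave_t1[!(k2 %in% amb), ]; kb <- k2[!(k2 %in% amb)]
  i <- match(ka, kb)
  hit <- !is.na(i)
  year_t <- if ("year" %in% names(wave_t)) wave_t$year[1L] else NA_integer_
  out <- data.frame(sex = a$sex[hit],
                    age = if (is.na(year_t)) NA_real_ else year_t - a$birth_year[hit],
                    from = a$category[hit], to = b$category[i[hit]],
                    weight = a$weight[hit])
  attr(out, "match_rate") <- nrow(out) / max(1L, nrow(wave_t))
  message("matched ", nrow(out), " pairs (",
          round(100 * attr(out, "match_rate"), 1), "% of wave-1 records; ",
          length(amb), " ambiguous key(s) discarded)")
  out
}

#' Post-stratify panel pairs to cross-sectional margins
#'
#' Rescales longitudinal weights so that weighted totals by labour status
#' (origin category), sex and 10-year age group match target margins from
#' the cross-sectional survey.
#'
#' @param pairs panel-pair table from [match_pseudo_panel()].
#' @param targets data.frame with columns from, sex, age10, target (cell
#'   totals to match). See [panel_margins()] for the current margins.
#' @return `pairs` with adjusted weights; weighted margins equal targets to
#'   1e-9 relative for every matched cell.
#' @export
reweight_panel <- function(pairs, targets) {
  pairs$age10 <- age_to_group10(pairs$age)
  pk <- paste(pairs$from, pairs$sex, pairs$age10, sep = "\r")
  tk <- paste(targets$from, targets$sex, targets$age10, sep = "\r")
  cur <- tapply(pairs$weight, pk, sum)
  miss <- setdiff(names(cur), tk)
  if (length(miss))
    stop("no target margin for ", length(miss), " populated cell(s), e.g. ",
         gsub("\r", "/", miss[1L]), call. = FALSE)
  dead <- !(tk %in% names(cur))
  if (any(dead)) warning(sum(dead), " target cell(s) with zero panel mass skipped")
  f <- targets$target[match(names(cur), tk)] / as.numeric(cur)
  pairs$weight <- pairs$weight * f[match(pk, names(cur))]
  pairs$age10 <- NULL
  pairs
}

#' Current weighted panel margins by status, sex and 10-year age group
#'
#' @param pairs panel-pair table.
#' @return data.frame with columns from, sex, age10, target — suitable as
#'   the `targets` argument of [reweight_panel()].
#' @export
panel_margins <- function(pairs) {
  a10 <- age_to_group10(pairs$age)
  agg <- stats::aggregate(pairs$weight,
                          by = list(from = pairs$from, sex = pairs$sex, age10 = a10),
                          FUN = sum)
  names(agg)[4L] <- "target"
  agg
}

sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(tolower(as.character(sex)) %in% c("male", "m", "1"))
}

# aggregate identical (sexM, age, to) rows: the weighted multinomial
# log-likelihood is unchanged and the fits get much faster
collapse_pairs <- function(d) {
  key <- paste(d$sexM, d$age, d$to, sep = "\r")
  w <- tapply(d$weight, key, sum)
  u <- d[!duplicated(key), c("sexM", "age", "to")]
  u$weight <- as.numeric(w[match(paste(u$sexM, u$age, u$to, sep = "\r"), names(w))])
  u
}

fit_origin_multinom <- function(d, powers, K, pivot, decay = 0) {
  X <- fp_transform(d$age, powers)
  # rescale FP columns to unit max-magnitude for optimisation (x^3 and x^-2
  # differ by ~8 orders at adult ages); a pure linear reparametrisation, so
  # the model space, fitted probabilities and deviance are unchanged, and the
  # coefficients and covariance are mapped back to the original scale below
  scale <- apply(abs(X), 2L, max)
  Xs <- sweep(X, 2L, scale, "/")
  dat <- data.frame(to = d$to, sexM = d$sexM, Xs, weight = d$weight)
  lev <- sort(unique(d$to))
  if (pivot %in% lev) lev <- c(pivot, setdiff(lev, pivot))
  dat$to <- factor(dat$to, levels = lev)
  form <- stats::as.formula(paste("to ~ sexM +", paste(colnames(X), collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, weights = dat$weight, trace = FALSE,
                        maxit = 1000, reltol = 1e-12, abstol = 1e-10,
                        decay = decay, Hess = FALSE)
  list(fit = fit, levels = as.integer(lev), powers = powers, scale = scale,
       deviance = fit$deviance, converged = fit$convergence == 0)
}

# map coefficients (and covariance) fitted on rescaled FP columns back to the
# original covariate scale; theta layout is destination-major
unscale_coef <- function(cf, V, scale) {
  s_all <- c(1, 1, scale)            # intercept, sexM, fp terms
  cf <- sweep(cf, 2L, s_all, "/")
  if (!is.null(V)) {
    d <- rep(1 / s_all, times = nrow(cf))
    V <- V * tcrossprod(d)
  }
  list(coef = cf, vcov = V)
}

#' Select the fractional-polynomial age specification for one origin
#'
#' Exhaustively fits the weighted multinomial logit of destination on sex and
#' FP(age) for all 44 candidate power specifications (8 of degree 1, 36 of
#' degree 2 with repetition) and returns the one with the lowest deviance
#' (-2 x maximised weighted log-likelihood). Ties break toward lower degree,
#' then lexicographically smaller powers. Candidates that fail to converge
#' are skipped with a warning.
#'
#' @param pairs panel pairs for a single origin category (columns sex, age,
#'   to, weight).
#' @param K number of categories.
#' @param pivot pivot destination (coefficients fixed at zero), default 0.
#' @return numeric power vector with attributes `deviance` and `search`
#'   (a data.frame logging every candidate's deviance).
#' @export
select_fp <- function(pairs, K, pivot = 0L) {
  if (length(unique(pairs$to)) < 2L)
    stop("need >= 2 observed destination categories to select an FP", call. = FALSE)
  d <- data.frame(sexM = sex_indicator(pairs$sex), age = pairs$age,
                  to = pairs$to, weight = pairs$weight)
  d <- collapse_pairs(d)
  cands <- fp_candidates()
  log <- data.frame(degree = vapply(cands, length, 1L),
                    p1 = vapply(cands, `[`, 0, 1L),
                    p2 = vapply(cands, function(p) if (length(p) > 1L) p[2L] else NA_real_, 0),
                    deviance = NA_real_, converged = NA)
  best <- NULL; best_dev <- Inf
  for (i in seq_along(cands)) {
    res <- tryCatch(fit_origin_multinom(d, cands[[i]], K, pivot),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      warning("FP candidate (", paste(cands[[i]], collapse = ", "),
              ") failed to converge; skipped")
      log$converged[i] <- FALSE
      next
    }
    log$deviance[i] <- res$deviance
    log$converged[i] <- TRUE
    if (res$deviance < best_dev) { best_dev <- res$deviance; best <- cands[[i]] }
  }
  if (is.null(best)) stop("every FP candidate failed to fit", call. = FALSE)
  structure(best, deviance = best_dev, search = log)
}

#' Fit per-origin transition models (Model 2)
#'
#' For each origin category, fits a weighted multinomial logit of the
#' destination category on a sex indicator and fractional-polynomial age
#' terms, with one destination as the pivot outcome (coefficients fixed at
#' zero). FP powers are selected per origin by lowest deviance unless
#' supplied. Weights are treated as probability weights: they scale the
#' log-likelihood, so point estimates are exact and model-based standard
#' errors are approximate.
#'
#' @param pairs panel-pair table: sex, age, from, to, weight.
#' @param K number of exposure categories.
#' @param pivot pivot destination category, default 0.
#' @param fp NULL to select per origin, or a list (indexed by origin label
#'   `"0"`.. `"K-1"`) of power vectors.
#' @param floor probability floor for destinations never observed from an
#'   origin (default 0: such transitions get probability 0).
#' @return an object of class `transfit`.
#' @export
transition_model <- function(pairs, K = max(c(pairs$from, pairs$to)) + 1L,
                             pivot = 0L, fp = NULL, floor = 0) {
  if (any(pairs$weight <= 0)) stop("pair weights must be positive", call. = FALSE)
  if (any(pairs$age < 15, na.rm = TRUE)) warning("panel pairs with age < 15 present")
  origins <- sort(unique(pairs$from))
  models <- vector("list", K)
  names(models) <- as.character(0:(K - 1L))
  for (o in origins) {
    sub <- pairs[pairs$from == o, ]
    d <- data.frame(sexM = sex_indicator(sub$sex), age = sub$age,
                    to = sub$to, weight = sub$weight)
    d <- collapse_pairs(d)
    if (length(unique(d$to)) < 2L) {
      # degenerate origin: single destination observed
      models[[as.character(o)]] <- list(degenerate = TRUE, dest = unique(d$to),
                                        n = nrow(sub))
      next
    }
    powers <- if (is.null(fp)) {
      tryCatch(as.numeric(select_fp(sub, K, pivot)), error = function(e) NULL)
    } else fp[[as.character(o)]]
    if (is.null(powers)) {
      # too little data for any age model: constant weighted empirical row
      warning("origin ", o, ": no FP candidate fitted; ",
              "using the age-constant empirical distribution")
      pr <- vapply(0:(K - 1L), function(k) sum(d$weight[d$to == k]), 0)
      models[[as.character(o)]] <- list(empirical = TRUE, probs = pr / sum(pr),
                                        n = nrow(sub))
      next
    }
    res <- tryCatch(fit_origin_multinom(d, powers, K, pivot),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      warning("origin ", o, ": unpenalised fit failed; ridge fallback (decay = 1e-4)")
      res <- fit_origin_multinom(d, powers, K, pivot, decay = 1e-4)
    }
    cf <- stats::coef(res$fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                       dimnames = list(as.character(res$levels[2L]),
                                                       names(stats::coef(res$fit))))
    V <- tryCatch(stats::vcov(res$fit), error = function(e) NULL)
    us <- unscale_coef(cf, V, res$scale)
    cf <- us$coef; V <- us$vcov
    models[[as.character(o)]] <- list(
      degenerate = FALSE, powers = powers, coef = cf, vcov = V,
      levels = res$levels, pivot = res$levels[1L],
      deviance = res$deviance, n = nrow(sub))
  }
  structure(list(models = models, K = K, pivot = pivot, floor = floor,
                 origins = origins, categories = default_category_labels(K)),
            class = "transfit")
}

#' @export
print.transfit <- function(x, ...) {
  cat("Transition model:", x$K, "categories,",
      length(x$origins), "fitted origins, pivot destination", x$pivot, "\n")
  for (o in x$origins) {
    m <- x$models[[as.character(o)]]
    if (isTRUE(m$degenerate)) {
      cat(sprintf("  origin %d: degenerate (single destination %d)\n", o, m$dest))
    } else if (isTRUE(m$empirical)) {
      cat(sprintf("  origin %d: age-constant empirical distribution, n = %d\n",
                  o, m$n))
    } else {
      cat(sprintf("  origin %d: FP powers (%s), deviance %.2f, n = %d\n",
                  o, paste(m$powers, collapse = ", "), m$deviance, m$n))
    }
  }
  invisible(x)
}

#' @export
coef.transfit <- function(object, ...) {
  lapply(object$models[as.character(object$origins)],
         function(m) if (isTRUE(m$degenerate) || isTRUE(m$empirical)) NULL else m$coef)
}

origin_row <- function(object, m, o, sexM, age) {
  K <- object$K
  p <- numeric(K)
  if (is.null(m)) {           # origin never observed: stay put
    p[o + 1L] <- 1
    return(p)
  }
  if (isTRUE(m$degenerate)) {
    p[m$dest + 1L] <- 1
    return(p)
  }
  if (isTRUE(m$empirical)) return(m$probs)
  X <- c(1, sexM, fp_transform(age, m$powers))
  eta <- c(0, as.vector(m$coef %*% X))   # pivot first
  pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
  p[m$levels + 1L] <- pr
  if (object$floor > 0) {
    p[p == 0] <- object$floor
    p <- p / sum(p)
  }
  p
}

#' Predict the annual transition matrix at a sex and exact age
#'
#' @param object a `transfit`.
#' @param sex `"female"`/`"male"` (or 0/1 indicator).
#' @param age age in years; clamped to [15, 110] with a warning.
#' @param se if TRUE, also return delta-method standard errors and 95%
#'   uncertainty ranges per cell (from the multinomial fit's covariance).
#' @param ... unused.
#' @return a `transition_matrix`, or (with `se = TRUE`) a list with elements
#'   `matrix`, `se`, `lower`, `upper`.
#' @export
predict.transfit <- function(object, sex, age, se = FALSE, ...) {
  if (age < 15 || age > 110) {
    warning("age ", age, " outside [15, 110]; clamped")
    age <- min(110, max(15, age))
  }
  sexM <- sex_indicator(sex)
  K <- object$K
  M <- matrix(0, K, K)
  SE <- matrix(0, K, K)
  for (o in 0:(K - 1L)) {
    m <- object$models[[as.character(o)]]
    M[o + 1L, ] <- origin_row(object, m, o, sexM, age)
    if (se && !is.null(m) && !isTRUE(m$degenerate) && !is.null(m$vcov)) {
      SE[o + 1L, m$levels + 1L] <- row_delta_se(m, sexM, age)
    }
  }
  M <- new_transition_matrix(M, labels = object$categories, sex = sex, age = age)
  if (!se) return(M)
  list(matrix = M, se = SE,
       lower = pmax(0, unclass(M) - 1.959964 * SE),
       upper = pmin(1, unclass(M) + 1.959964 * SE))
}

# delta-method se of the predicted probabilities of one origin's fit;
# theta is laid out as in nnet::multinom vcov (destination-major)
row_delta_se <- function(m, sexM, age) {
  X <- c(1, sexM, fp_transform(age, m$powers))
  eta <- c(0, as.vector(m$coef %*% X))
  p <- exp(eta - max(eta)); p <- p / sum(p)
  nd <- length(eta)                       # destinations incl. pivot
  np <- length(X)
  G <- matrix(0, nd, (nd - 1L) * np)      # d p_k / d theta_(j,c)
  for (k in seq_len(nd))
    for (j in 2:nd)
      G[k, ((j - 2L) * np + 1L):((j - 1L) * np)] <-
        p[k] * ((k == j) - p[j]) * X
  V <- m$vcov
  sqrt(pmax(0, diag(G %*% V %*% t(G))))
}

# per-sex lookup table of transition matrices at integer ages (internal;
# used by the simulator so each year's draws are a single array lookup)
transition_lookup <- function(object, sexes, ages = 15:110) {
  out <- list()
  for (s in sexes) {
    arr <- array(0, dim = c(length(ages), object$K, object$K))
    for (i in seq_along(ages))
      arr[i, , ] <- suppressWarnings(unclass(predict(object, s, ages[i])))
    out[[s]] <- arr
  }
  attr(out, "ages") <- ages
  out
}
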