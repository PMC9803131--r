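#' Aggregate survey records into weighted cell proportions
#'
#' Collapses record-level survey data to weighted category proportions per
#' (country, sex, age group, year) cell — the response for the prevalence
#' trend model. Cells with zero total weight are dropped with a warning.
#'
#' @param records data.frame with columns year, country, sex, age_group,
#'   category (0-based integer), weight (non-negative).
#' @param K number of categories; inferred as max(category) + 1 if missing.
#' @return data.frame with one row per cell x category: country, sex,
#'   age_group, year, category, proportion, cell_weight. Per-cell proportions
#'   sum to 1 within 1e-12.
#' @export
aggregate_proportions <- function(records, K = NULL) {
  need <- c("year", "country", "sex", "age_group", "category", "weight")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$weight < 0)) stop("weights must be non-negative", call. = FALSE)
  if (is.null(K)) K <- max(records$category) + 1L
  cellkey <- interaction(records$country, records$sex, records$age_group,
                         records$year, drop = TRUE, lex.order = TRUE)
  tot <- tapply(records$weight, cellkey, sum)
  empty <- names(tot)[tot <= 0]
  if (length(empty)) {
    warning(length(empty), " cell(s) with zero total weight excluded")
    keep <- !(as.character(cellkey) %in% empty)
    records <- records[keep, ]
    cellkey <- droplevels(cellkey[keep])
  }
  wsum <- tapply(records$weight,
                 list(cell = cellkey, category = factor(records$category, levels = 0:(K - 1L))),
                 sum, default = 0)
  props <- wsum / rowSums(wsum)
  first <- records[!duplicated(cellkey), c("country", "sex", "age_group", "year")]
  first <- first[order(cellkey[!duplicated(cellkey)]), ]
  out <- first[rep(seq_len(nrow(first)), each = K), ]
  out$category <- rep(0:(K - 1L), nrow(first))
  out$proportion <- as.vector(t(props))
  out$cell_weight <- rep(rowSums(wsum), each = K)
  rownames(out) <- NULL
  out
}

#' Fit the prevalence trend model (Model 1)
#'
#' Fits, per exposure category, a linear model of cell proportions on
#' calendar year, yielding an intercept A and slope B for every
#' (country, sex, age group) cell. Year is centred at `year0` (the window's
#' first year), so A is the fitted prevalence at `year0`. Residuals are
#' treated as normal on the proportion scale; predictions are clamped to
#' [0, 1] and renormalised across categories.
#'
#' With a single country (the default `engine = "cell"`) the model reduces to
#' the fixed-effects regression of proportion on year within each
#' sex x age-group cell, each cell weighted by its survey-weight total. With
#' several countries, `engine = "lmm"` fits a multilevel model per category
#' (sex and age group as fixed effects; random intercept and year slope per
#' sex x age group nested in country, via lme4) and recovers per-cell A and B
#' as fixed + random effect sums.
#'
#' @param props proportion table from [aggregate_proportions()].
#' @param year0 centring year (default: earliest year in the data).
#' @param engine `"auto"` (cell-wise for one country, multilevel otherwise),
#'   `"cell"`, or `"lmm"`.
#' @param weighted if TRUE (default) cells are weighted by their survey
#'   weight totals.
#' @return an object of class `prevfit` with `coef`, `predict`, `print`
#'   methods.
#' @export
prevalence_trend <- function(props, year0 = min(props$year),
                             engine = c("auto", "cell", "lmm"),
                             weighted = TRUE) {
  engine <- match.arg(engine)
  K <- max(props$category) + 1L
  n_country <- length(unique(props$country))
  if (length(unique(props$year)) < 2L)
    stop("only one survey year: the year slope is unidentifiable; supply >= 2 years",
         call. = FALSE)
  if (engine == "auto") engine <- if (n_country > 1L) "lmm" else "cell"
  if (engine == "lmm" && n_country == 1L) {
    message("single country: multilevel random effects collapse to fixed effects; using cell-wise fits")
    engine <- "cell"
  }
  props$yc <- props$year - year0
  w <- if (weighted) props$cell_weight else rep(1, nrow(props))

  coefs <- if (engine == "cell") fit_prev_cell(props, w, K) else fit_prev_lmm(props, w, K)
  structure(list(coef = coefs, year0 = year0, K = K,
                 categories = default_category_labels(K), engine = engine,
                 year_range = range(props$year), weighted = weighted),
            class = "prevfit")
}

fit_prev_cell <- function(props, w, K) {
  key <- interaction(props$country, props$sex, props$age_group, drop = TRUE, lex.order = TRUE)
  out <- list()
  for (cell in levels(key)) {
    sel0 <- key == cell
    info <- props[sel0, c("country", "sex", "age_group")][1L, ]
    for (k in 0:(K - 1L)) {
      sel <- sel0 & props$category == k
      d <- props[sel, ]
      wi <- w[sel]
      if (length(unique(d$yc)) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          info, category = k, A = stats::weighted.mean(d$proportion, wi), B = 0,
          se_A = NA_real_, se_B = NA_real_, cov_AB = NA_real_,
          sigma = NA_real_, df = 0L)
        next
      }
      fit <- stats::lm(proportion ~ yc, data = d, weights = wi)
      # noise-free cells interpolate exactly; the "essentially perfect fit"
      # note from summary.lm is expected there, not a problem
      V <- suppressWarnings(stats::vcov(fit))
      out[[length(out) + 1L]] <- data.frame(
        info, category = k,
        A = unname(stats::coef(fit)[1L]), B = unname(stats::coef(fit)[2L]),
        se_A = sqrt(V[1L, 1L]), se_B = sqrt(V[2L, 2L]), cov_AB = V[1L, 2L],
        sigma = suppressWarnings(summary(fit)$sigma), df = fit$df.residual)
    }
  }
  do.call(rbind, out)
}

fit_prev_lmm <- function(props, w, K) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("the multilevel engine needs the lme4 package", call. = FALSE)
  props$sa <- interaction(props$sex, props$age_group, drop = TRUE)
  out <- list()
  cells <- unique(props[, c("country", "sex", "age_group")])
  for (k in 0:(K - 1L)) {
    d <- props[props$category == k, ]
    wi <- w[props$category == k]
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(proportion ~ sex + age_group + yc + (1 + yc | country) +
                   (1 + yc | country:sa),
                 data = d, weights = wi, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    for (r in seq_len(nrow(cells))) {
      nd <- cells[r, ]
      nd$yc <- 0
      nd$sa <- interaction(nd$sex, nd$age_group)
      A <- predict_lmm_cell(fit, nd, 0)
      B <- predict_lmm_cell(fit, nd, 1) - A
      out[[length(out) + 1L]] <- data.frame(
        nd[, c("country", "sex", "age_group")], category = k, A = A, B = B,
        se_A = NA_real_, se_B = NA_real_, cov_AB = NA_real_,
        sigma = stats::sigma(fit), df = NA_integer_)
    }
  }
  do.call(rbind, out)
}

predict_lmm_cell <- function(fit, nd, yc) {
  nd$yc <- yc
  as.numeric(stats::predict(fit, newdata = nd, allow.new.levels = TRUE))
}

#' @export
print.prevfit <- function(x, ...) {
  cat("Prevalence trend model (", x$engine, " engine)\n", sep = "")
  cat("  categories:", x$K, "| cells:",
      nrow(unique(x$coef[, c("country", "sex", "age_group")])), "\n")
  cat("  years:", x$year_range[1L], "-", x$year_range[2L],
      "(centred at", x$year0, ")\n")
  invisible(x)
}

#' @export
coef.prevfit <- function(object, ...) object$coef

#' Predict category prevalence for a cohort and year
#'
#' Evaluates A + B * (year - year0) per category, clamps the raw linear
#' predictions to [0, 1], and renormalises so proportions sum to 1. When
#' `interval = "ur"`, symmetric normal 95% ranges from the per-cell
#' regression are carried through the same scaling.
#'
#' @param object a `prevfit`.
#' @param country,sex,age_group cell identifiers seen in training.
#' @param year prediction year.
#' @param interval `"none"` or `"ur"` for 95% uncertainty ranges.
#' @param horizon warn when `year` lies more than this many years outside the
#'   training range (default 10).
#' @param ... unused.
#' @return data.frame with columns category, label, raw, proportion, and
#'   (with `interval = "ur"`) lower, upper.
#' @export
predict.prevfit <- function(object, country, sex, age_group, year,
                            interval = c("none", "ur"), horizon = 10, ...) {
  interval <- match.arg(interval)
  sel <- object$coef$country == country & object$coef$sex == sex &
    object$coef$age_group == age_group
  if (!any(sel)) stop("cell (", country, ", ", sex, ", ", age_group,
                      ") not seen in training", call. = FALSE)
  co <- object$coef[sel, ]
  co <- co[order(co$category), ]
  yc <- year - object$year0
  gap <- max(object$year_range[1L] - year, year - object$year_range[2L], 0)
  if (gap > horizon)
    warning("prediction year ", year, " is ", gap,
            " years outside the training range; extrapolation is unreliable")
  raw <- co$A + co$B * yc
  clamped <- pmin(1, pmax(0, raw))
  s <- sum(clamped)
  if (s <= 0) {
    warning("all clamped predictions are zero; returning uniform proportions")
    prop <- rep(1 / object$K, object$K)
    s <- 1
  } else prop <- clamped / s
  out <- data.frame(category = co$category,
                    label = object$categories[co$category + 1L],
                    raw = raw, proportion = prop)
  if (interval == "ur") {
    se <- sqrt(pmax(0, co$se_A^2 + yc^2 * co$se_B^2 + 2 * yc * co$cov_AB))
    lo <- pmin(1, pmax(0, raw - 1.959964 * se)) / s
    hi <- pmin(1, pmax(0, raw + 1.959964 * se)) / s
    out$lower <- pmin(lo, out$proportion)
    out$upper <- pmax(pmin(hi, 1), out$proportion)
  }
  out
}

#' Tabulate predicted prevalence for every training cell at one year
#'
#' @param object a `prevfit`.
#' @param year prediction year.
#' @param interval passed to [predict.prevfit()].
#' @return data.frame in long format: country, sex, age_group, year,
#'   category, proportion (and lower/upper when requested).
#' @export
prevalence_table <- function(object, year, interval = c("none", "ur")) {
  interval <- match.arg(interval)
  cells <- unique(object$coef[, c("country", "sex", "age_group")])
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    p <- predict(object, cells$country[r], cells$sex[r], cells$age_group[r],
                 year, interval = interval)
    out[[r]] <- cbind(cells[r, ], year = year,
                      p[, setdiff(names(p), c("raw", "label"))], row.names = NULL)
  }
  do.call(rbind, out)
}
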