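#' @keywords internal
#' @importFrom nnet multinom
#' @importFrom stats coef predict
"_PACKAGE"

# run code with a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards so library functions never disturb user-level reproducibility
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Largest-remainder rounding of shares to integer counts
#'
#' Allocates `n` units across strata proportionally to `shares`, rounding by
#' the largest-remainder (Hamilton) method so the counts sum exactly to `n`.
#'
#' @param shares non-negative numeric vector (need not sum to 1).
#' @param n total count to allocate.
#' @return integer vector of the same length as `shares`, summing to `n`.
#' @examples
#' largest_remainder(c(0.5, 0.3, 0.2), 10)  # 5 3 2
#' @export
largest_remainder <- function(shares, n) {
  if (any(shares < 0) || sum(shares) <= 0) stop("shares must be non-negative with positive sum", call. = FALSE)
  p <- shares / sum(shares)
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

check_prob_vector <- function(p, tol = 1e-9, what = "probability vector") {
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol))
    stop(what, " has entries outside [0,1]", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(what, " does not sum to 1 (sum = ", format(sum(p)), ")", call. = FALSE)
  invisible(TRUE)
}

check_row_stochastic <- function(M, tol = 1e-9) {
  if (any(!is.finite(M)) || any(M < -tol) || any(M > 1 + tol))
    stop("transition matrix has entries outside [0,1]", call. = FALSE)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > tol))
    stop("transition matrix rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  invisible(TRUE)
}

#' Exposure category labels for the working-hours application
#'
#' The six ordered categories used for long working hours: labour-force
#' inactive and five weekly-hours bands.
#'
#' @return character vector of length 6 (index 0..5 in model notation).
#' @export
working_hours_bands <- function() {
  c("inactive", "0-34h", "35-40h", "41-48h", "49-54h", "55+h")
}

#' Five-year age-group labels from 15-19 to 95+
#'
#' @return character vector of 17 labels.
#' @export
age_groups_5y <- function() {
  c(paste(seq(15, 90, 5), seq(19, 94, 5), sep = "-"), "95+")
}

# [lo, hi) continuous age range of a band label like "15-19" or "95+"
age_band_range <- function(label) {
  out <- matrix(NA_real_, length(label), 2L)
  open <- grepl("\\+$", label)
  out[open, 1L] <- as.numeric(sub("\\+$", "", label[open]))
  out[open, 2L] <- out[open, 1L] + 5
  m <- regmatches(label[!open], regexec("^([0-9]+)-([0-9]+)$", label[!open]))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable age-group label: ", label[!open][bad][1L], call. = FALSE)
  out[!open, 1L] <- as.numeric(vapply(m, `[`, "", 2L))
  out[!open, 2L] <- as.numeric(vapply(m, `[`, "", 3L)) + 1
  out
}

# map an exact age to a 5-year band label (clamped to the provided set)
age_to_group <- function(age, groups = age_groups_5y()) {
  rng <- age_band_range(groups)
  idx <- findInterval(age, rng[, 1L])
  idx[idx < 1L] <- 1L
  idx[idx > length(groups)] <- length(groups)
  groups[idx]
}

# 10-year reweighting bands: 15-24, 25-34, ..., 75+
age_to_group10 <- function(age) {
  lo <- pmin(75, 15 + 10 * pmax(0, floor((age - 15) / 10)))
  ifelse(lo >= 75, "75+", paste(lo, lo + 9, sep = "-"))
}

default_category_labels <- function(K) {
  if (K == 6L) working_hours_bands() else paste0("cat", seq_len(K) - 1L)
}
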