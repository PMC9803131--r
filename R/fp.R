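#' Fractional-polynomial transforms of a positive covariate
#'
#' Transforms age (or any positive covariate) by a fractional-polynomial
#' specification. Powers are drawn from the conventional set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where power 0 denotes ln(x). A repeated
#' power at degree 2 multiplies the second term by an additional ln(x):
#' powers (3, 3) give (x^3, x^3 ln x), and powers (0, 0) give (ln x, (ln x)^2).
#'
#' @param x positive numeric vector (age in years).
#' @param powers numeric vector of length 1 or 2 from the FP power set.
#' @return numeric matrix with one column per FP term.
#' @examples
#' fp_transform(40, c(3, 3))   # (40^3, 40^3 * log(40))
#' fp_transform(40, c(0, -1))  # (log(40), 1/40)
#' fp_transform(1, 0)          # ln 1 = 0
#' @export
fp_transform <- function(x, powers) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("fractional polynomials need x > 0", call. = FALSE)
  powers <- fp_check_powers(powers)
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1L) {
    out <- cbind(one(powers))
  } else if (powers[1L] != powers[2L]) {
    out <- cbind(one(powers[1L]), one(powers[2L]))
  } else {
    t1 <- one(powers[1L])
    out <- cbind(t1, t1 * log(x))
  }
  colnames(out) <- paste0("fp", seq_len(ncol(out)))
  out
}

fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_check_powers <- function(powers) {
  if (!length(powers) %in% 1:2) stop("FP degree must be 1 or 2", call. = FALSE)
  if (!all(powers %in% fp_power_set()))
    stop("FP powers must come from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}", call. = FALSE)
  powers
}

#' Enumerate the fractional-polynomial candidate set
#'
#' All degree-1 specifications (8) and degree-2 specifications with repetition
#' allowed (36), in tie-break order: lower degree first, then lexicographically
#' increasing powers.
#'
#' @return list of numeric power vectors, length 44.
#' @export
fp_candidates <- function() {
  ps <- fp_power_set()
  out <- lapply(ps, function(p) p)
  for (i in seq_along(ps))
    for (j in i:length(ps))
      out[[length(out) + 1L]] <- c(ps[i], ps[j])
  out
}
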