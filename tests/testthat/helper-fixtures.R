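# shared fixtures; everything is generated in code at test time

rand_stoch_matrix <- function(K, seed, shape = 1.5) {
  set.seed(seed)
  M <- matrix(rgamma(K * K, shape), K)
  M / rowSums(M)
}

rand_simplex <- function(K, seed, shape = 2) {
  set.seed(seed)
  p <- rgamma(K, shape)
  p / sum(p)
}

# small truth world used across tests (5 age bands for speed)
small_truth <- function(seed = 5) {
  make_truth(seed = seed,
             age_groups = c("20-24", "30-34", "40-44", "50-54", "60-64"))
}

# force a truth world's transition structure to the identity at every age
make_identity_transitions <- function(truth) {
  K <- truth$K
  truth$trans_coef[] <- 0
  for (o in seq_len(K))
    if (o > 1L) truth$trans_coef[o, o, 1L] <- 50   # softmax ~ 1 on the diagonal
  # origin 0: pivot already dominant once every other destination is pushed down
  for (d in 2:K) truth$trans_coef[1L, d, 1L] <- -50
  truth
}

# hand-built transition model with all coefficients zero (uniform predictions)
zero_coef_transfit <- function(K = 6L) {
  models <- lapply(0:(K - 1L), function(o) {
    cf <- matrix(0, K - 1L, 3L,
                 dimnames = list(as.character(1:(K - 1L)),
                                 c("(Intercept)", "sexM", "fp1")))
    list(degenerate = FALSE, powers = 1, coef = cf, vcov = NULL,
         levels = 0:(K - 1L), pivot = 0L, deviance = NA_real_, n = 0L)
  })
  names(models) <- as.character(0:(K - 1L))
  structure(list(models = models, K = K, pivot = 0L, floor = 0,
                 origins = 0:(K - 1L),
                 categories = expowin::working_hours_bands()),
            class = "transfit")
}

# constant life table: one q for all sexes/ages/years
flat_life_table <- function(q, sexes = c("female", "male"),
                            ages = 15:110, years = 2000:2030) {
  make_life_table(expand.grid(sex = sexes, age = ages, year = years,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE) |>
                    transform(qx = q))
}

# exact proportion table from a truth world (zero residual noise)
truth_proportions <- function(truth, years = truth$years) {
  out <- list()
  for (i in seq_len(nrow(truth$cells))) for (y in years) {
    p <- truth$prev_A[i, ] + truth$prev_B[i, ] * (y - min(truth$years))
    out[[length(out) + 1L]] <- data.frame(
      truth$cells[i, ], year = y, category = 0:(truth$K - 1L),
      proportion = p, cell_weight = 1, row.names = NULL)
  }
  do.call(rbind, out)
}

# independent brute-force evaluation of the weighted multinomial logit
# log-likelihood (pivot level first); used to cross-check fitted coefficients
manual_mlogit_loglik <- function(beta_mat, X, y, w, levels) {
  eta <- cbind(0, X %*% t(beta_mat))   # n x ndest, pivot first
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  sum(w * log(p[cbind(seq_along(y), match(y, levels))]))
}
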