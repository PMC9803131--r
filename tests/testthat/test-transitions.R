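test_that("fractional-polynomial transforms follow the power conventions", {
  x <- 40
  expect_equal(fp_transform(x, c(3, 3)), cbind(x^3, x^3 * log(x)),
               ignore_attr = TRUE)
  expect_equal(fp_transform(x, c(0, -1)), cbind(log(x), 1 / x),
               ignore_attr = TRUE)
  expect_equal(fp_transform(1, 0), cbind(0), ignore_attr = TRUE)
  expect_equal(fp_transform(x, c(0, 0)), cbind(log(x), log(x)^2),
               ignore_attr = TRUE)
  expect_error(fp_transform(0, 1), "x > 0")
  expect_error(fp_transform(40, 1.5), "powers")
  cands <- fp_candidates()
  expect_length(cands, 44L)
  expect_true(all(vapply(cands[1:8], length, 1L) == 1L))
  expect_true(all(vapply(cands[9:44], length, 1L) == 2L))
})

test_that("pseudo-panel matching keeps unique keys only", {
  w1 <- data.frame(hh_id = 1:3, seq = 1, sex = "male", birth_year = 1970,
                   year = 2002, category = c(0, 1, 2), weight = 1)
  w2 <- transform(w1, year = 2003, category = c(2, 1, 0))
  # disjoint households: no matches
  w2b <- transform(w2, hh_id = hh_id + 10L)
  expect_identical(nrow(suppressMessages(match_pseudo_panel(w1, w2b))), 0L)
  # unique match carries both categories and the first-wave age
  p <- suppressMessages(match_pseudo_panel(w1[1, ], w2[1, ]))
  expect_identical(nrow(p), 1L)
  expect_identical(p$from, 0); expect_identical(p$to, 2)
  expect_identical(p$age, 32)
  # duplicated key in one wave discards all its records
  w1dup <- rbind(w1, w1[1, ])
  pd <- suppressMessages(match_pseudo_panel(w1dup, w2))
  expect_identical(nrow(pd), 2L)
  expect_error(match_pseudo_panel(w1[, -1], w2), "hh_id")
})

test_that("post-stratification reproduces target margins exactly", {
  set.seed(42)
  pairs <- data.frame(sex = sample(c("female", "male"), 400, TRUE),
                      age = sample(15:79, 400, TRUE),
                      from = sample(0:5, 400, TRUE),
                      to = sample(0:5, 400, TRUE),
                      weight = runif(400, 0.5, 2))
  m <- panel_margins(pairs)
  # identity targets: weights unchanged
  rw <- reweight_panel(pairs, m)
  expect_equal(rw$weight, pairs$weight, tolerance = 1e-12)
  # doubling one cell's target doubles exactly its weights
  m2 <- m; m2$target[1] <- 2 * m2$target[1]
  rw2 <- reweight_panel(pairs, m2)
  in_cell <- pairs$from == m$from[1] & pairs$sex == m$sex[1] &
    expowin:::age_to_group10(pairs$age) == m$age10[1]
  expect_equal(rw2$weight[in_cell], 2 * pairs$weight[in_cell], tolerance = 1e-12)
  expect_equal(rw2$weight[!in_cell], pairs$weight[!in_cell], tolerance = 1e-12)
  # arbitrary positive targets are matched to 1e-9 relative
  m3 <- m; m3$target <- m3$target * runif(nrow(m3), 0.2, 5)
  rw3 <- reweight_panel(pairs, m3)
  got <- panel_margins(rw3)
  i <- match(paste(m3$from, m3$sex, m3$age10), paste(got$from, got$sex, got$age10))
  expect_lt(max(abs(got$target[i] / m3$target - 1)), 1e-9)
  # missing target for a populated cell is an error
  expect_error(reweight_panel(pairs, m[-1, ]), "target")
})

test_that("reweighting to truthful margins reduces attrition bias", {
  tw <- small_truth(seed = 6)
  panel <- sample_rotating_panel(tw, 6000, c(2002, 2003), seed = 61,
                                 attrition = 0, collision = 0)
  w1 <- panel[panel$year == 2002, ]; w2 <- panel[panel$year == 2003, ]
  pairs_full <- suppressMessages(match_pseudo_panel(w1, w2))
  full_m <- panel_margins(pairs_full)
  # status-dependent attrition: drop 60% of pairs with origin 0
  set.seed(62)
  drop <- pairs_full$from == 0 & runif(nrow(pairs_full)) < 0.6
  pairs_att <- pairs_full[!drop, ]
  est_mat <- function(p) {
    n <- stats::aggregate(p$weight, list(from = p$from, to = p$to), sum)
    M <- matrix(0, 6, 6)
    M[cbind(n$from + 1, n$to + 1)] <- n$x
    M / rowSums(M)
  }
  truthM <- matrix(0, 6, 6)
  # empirical truth: the full-sample matrix
  truthM <- est_mat(pairs_full)
  biased <- est_mat(pairs_att)
  fixed <- est_mat(suppressWarnings(reweight_panel(pairs_att, full_m)))
  # reweighting restores origin-0 mass in aggregate margins
  w_b <- sum(pairs_att$weight[pairs_att$from == 0]) / sum(pairs_att$weight)
  rw <- suppressWarnings(reweight_panel(pairs_att, full_m))
  w_f <- sum(rw$weight[rw$from == 0]) / sum(rw$weight)
  w_t <- sum(pairs_full$weight[pairs_full$from == 0]) / sum(pairs_full$weight)
  expect_lt(abs(w_f - w_t), abs(w_b - w_t))
})

test_that("zero coefficients predict uniform transition rows", {
  tm <- zero_coef_transfit(6)
  M <- predict(tm, "male", 40)
  expect_equal(unclass(M), matrix(1/6, 6, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_warning(M2 <- predict(tm, "female", 130), "clamped")
  expect_equal(rowSums(unclass(M2)), rep(1, 6), ignore_attr = TRUE)
})

test_that("fitted coefficients agree with a brute-force likelihood oracle", {
  # tiny weighted dataset, 3 destinations, intercept + sexM + age
  set.seed(7)
  pairs <- data.frame(sex = rep(c("male", "female"), 5),
                      age = c(22, 35, 41, 57, 63, 28, 46, 52, 38, 60),
                      from = 0,
                      to = c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1),
                      weight = runif(10, 0.5, 2))
  fit <- suppressWarnings(
    transition_model(pairs, K = 3, fp = list(`0` = 1)))
  cf <- coef(fit)[["0"]]
  # independent maximisation of the hand-written weighted log-likelihood,
  # with its analytic score for tight convergence
  X <- cbind(1, as.numeric(pairs$sex == "male"), pairs$age)
  nll <- function(th) -manual_mlogit_loglik(matrix(th, nrow = 2, byrow = TRUE),
                                            X, pairs$to, pairs$weight, 0:2)
  grad <- function(th) {
    beta <- matrix(th, nrow = 2, byrow = TRUE)
    eta <- cbind(0, X %*% t(beta))
    p <- exp(eta - apply(eta, 1, max)); p <- p / rowSums(p)
    g <- matrix(0, 2, ncol(X))
    for (j in 1:2)
      g[j, ] <- -colSums(pairs$weight * ((pairs$to == j) - p[, j + 1]) * X)
    as.vector(t(g))
  }
  opt <- optim(rep(0, 6), nll, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(as.vector(t(cf)) - opt$par)), 1e-4)
})

test_that("predicted probabilities are invariant to the pivot choice", {
  set.seed(15)
  pairs <- data.frame(sex = sample(c("female", "male"), 300, TRUE),
                      age = sample(20:70, 300, TRUE), from = 0,
                      to = sample(0:2, 300, TRUE, prob = c(0.5, 0.3, 0.2)),
                      weight = 1)
  f0 <- suppressWarnings(transition_model(pairs, K = 3, pivot = 0, fp = list(`0` = 1)))
  f2 <- suppressWarnings(transition_model(pairs, K = 3, pivot = 2, fp = list(`0` = 1)))
  expect_equal(unclass(predict(f0, "male", 45))[1, ],
               unclass(predict(f2, "male", 45))[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("FP selection returns the deviance minimiser over all 44 candidates", {
  tw <- small_truth(seed = 10)
  panel <- sample_rotating_panel(tw, 2500, c(2002, 2003), seed = 71, attrition = 0)
  pairs <- suppressMessages(
    match_pseudo_panel(panel[panel$year == 2002, ], panel[panel$year == 2003, ]))
  sub <- pairs[pairs$from == 2, ]
  spec <- suppressWarnings(select_fp(sub, K = 6))
  log <- attr(spec, "search")
  expect_identical(nrow(log), 44L)
  expect_equal(attr(spec, "deviance"), min(log$deviance, na.rm = TRUE))
  expect_true(all(attr(spec, "deviance") <= log$deviance + 1e-9, na.rm = TRUE))
})

test_that("transition model predicts valid rows everywhere", {
  tw <- small_truth(seed = 12)
  panel <- sample_rotating_panel(tw, 4000, c(2002, 2003), seed = 81, attrition = 0.1)
  pairs <- suppressMessages(
    match_pseudo_panel(panel[panel$year == 2002, ], panel[panel$year == 2003, ]))
  fp <- setNames(rep(list(c(1, 2)), 6), as.character(0:5))
  tm <- suppressWarnings(transition_model(pairs, fp = fp))
  for (a in c(15, 30, 55, 80, 110)) {
    M <- predict(tm, "female", a)
    expect_equal(rowSums(unclass(M)), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # delta-method uncertainty ranges bracket the point estimates
  pr <- predict(tm, "male", 45, se = TRUE)
  expect_true(all(pr$lower <= unclass(pr$matrix) + 1e-12))
  expect_true(all(pr$upper >= unclass(pr$matrix) - 1e-12))
  expect_true(all(pr$se >= 0))
})

test_that("origins too sparse for any age model fall back to empirical rows", {
  set.seed(88)
  pairs <- data.frame(sex = "male", age = sample(30:40, 8, TRUE), from = 0,
                      to = c(0, 0, 1, 1, 2, 2, 3, 4), weight = 1)
  tm <- suppressWarnings(transition_model(pairs, K = 6))
  M <- suppressWarnings(predict(tm, "male", 35))
  expect_equal(rowSums(unclass(M)), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the empirical branch itself returns the weighted destination distribution
  tm$models[["0"]] <- list(empirical = TRUE,
                           probs = c(0.25, 0.25, 0.125, 0.125, 0.125, 0.125),
                           n = 8L)
  M2 <- predict(tm, "male", 35)
  expect_equal(unclass(M2)[1, ], c(0.25, 0.25, 0.125, 0.125, 0.125, 0.125),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fixed matrices in percent are validated and renormalised", {
  h5 <- c(24.3, 8.5, 15.7, 13.0, 10.1, 36.9)
  tab <- matrix(h5, 6, 6, byrow = TRUE)
  M <- load_fixed_matrix(tab)
  expect_equal(rowSums(unclass(M)), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identity in percent is unchanged
  I6 <- diag(6) * 100
  expect_equal(unclass(load_fixed_matrix(I6)), diag(6), ignore_attr = TRUE)
  # a row printed as 101.7% is divided by 1.017
  h0 <- c(65.8, 8.9, 11.1, 7.6, 3.2, 5.1)
  expect_equal(sum(h0), 101.7, tolerance = 1e-9)
  M0 <- load_fixed_matrix(matrix(h0, 6, 6, byrow = TRUE))
  expect_equal(unclass(M0)[1, 1], 0.658 / 1.017, tolerance = 1e-12)
  expect_error(load_fixed_matrix(matrix(-1, 6, 6)), "negative")
  expect_error(load_fixed_matrix(matrix(10, 6, 6)), "20%")
})
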