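test_that("largest-remainder allocation matches hand results", {
  expect_identical(largest_remainder(c(0.5, 0.3, 0.2), 10), c(5L, 3L, 2L))
  expect_identical(sum(largest_remainder(runif(7), 1234)), 1234L)
})

test_that("cohort initialisation is representative and seeded", {
  pop <- data.frame(sex = c("female", "male"), age_group = "40-44",
                    count = c(300, 200))
  prev <- expand.grid(sex = c("female", "male"), category = 0:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prev$age_group <- "40-44"
  prev$proportion <- rep(c(1, 0, 0), each = 2)
  co <- initialize_cohort(pop, prev, 10, 2002, seed = 1, K = 3)
  expect_identical(table(co$data$sex)[["female"]], 6L)  # 0.6 * 10
  expect_true(all(co$seq[, 1] == 0L))
  expect_true(all(co$age >= 40 & co$age < 45))
  co2 <- initialize_cohort(pop, prev, 10, 2002, seed = 1, K = 3)
  expect_identical(co, co2)
  expect_error(initialize_cohort(transform(pop, count = 0), prev, 10, 2002, 1),
               "zero")
})

test_that("inverse-CDF transition step picks the first exceeding category", {
  row <- c(0.2, 0.3, 0.5)
  expect_identical(step_transition(0, row, 0.6), 2L)
  expect_identical(step_transition(0, row, 0.0), 0L)
  expect_identical(step_transition(0, row, 0.19), 0L)
  expect_identical(step_transition(0, row, 0.5), 2L)
  expect_identical(step_transition(3, c(0, 0, 0, 1), 0.99), 3L)
  expect_error(step_transition(0, c(0.5, 0.4), 0.1), "sum")
})

test_that("mortality step kills iff the draw falls below q", {
  lt1 <- flat_life_table(1)
  lt0 <- flat_life_table(0)
  expect_false(step_mortality(lt1, "male", 40, 2005, 0.99))
  expect_true(step_mortality(lt0, "male", 40, 2005, 1e-9))
  # death fraction matches q at binomial tolerance
  lt <- flat_life_table(0.5)
  set.seed(3)
  u <- runif(1e5)
  frac <- mean(u < q_lookup(lt, "male", 40, 2005))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(q_lookup(lt, "male", 300, 2005, clamp = FALSE), "300")
})

test_that("identity transitions and zero mortality freeze the cohort", {
  pop <- data.frame(sex = "male", age_group = "30-34", count = 1)
  prev <- data.frame(sex = "male", age_group = "30-34", category = 0:2,
                     proportion = c(0.2, 0.3, 0.5))
  co <- initialize_cohort(pop, prev, 500, 2002, seed = 4, K = 3)
  co <- simulate_window(co, diag(3), NULL, 2008, seed = 5)
  expect_true(all(co$seq == co$seq[, 1]))
  expect_identical(sum(co$alive), 500L)
  pp <- period_prevalence(co, by = "overall")
  expect_equal(pp$proportion, tabulate(co$seq[, 1] + 1, 3) / 500,
               tolerance = 1e-12)
})

test_that("certain death leaves no survivors; zero mortality keeps all", {
  pop <- data.frame(sex = "female", age_group = "50-54", count = 1)
  prev <- data.frame(sex = "female", age_group = "50-54", category = 0:1,
                     proportion = c(0.5, 0.5))
  co <- initialize_cohort(pop, prev, 200, 2002, seed = 6, K = 2)
  dead <- simulate_window(co, diag(2), flat_life_table(1), 2005, seed = 7)
  expect_identical(sum(dead$alive), 0L)
  dead <- censor_to_estimation_year(dead, flat_life_table(1), 2008, seed = 8)
  expect_identical(sum(dead$alive_at_est), 0L)
  live <- simulate_window(co, diag(2), flat_life_table(0), 2005, seed = 7)
  live <- censor_to_estimation_year(live, flat_life_table(0), 2008, seed = 8)
  expect_identical(sum(live$alive_at_est), 200L)
})

test_that("post-window censoring matches closed-form survival", {
  pop <- data.frame(sex = "male", age_group = "60-64", count = 1)
  prev <- data.frame(sex = "male", age_group = "60-64", category = 0:1,
                     proportion = c(1, 0))
  n <- 20000
  co <- initialize_cohort(pop, prev, n, 2002, seed = 9, K = 2)
  q <- 0.03
  lt <- flat_life_table(q)
  co <- simulate_window(co, diag(2), NULL, 2006, seed = 10)   # no window deaths
  co <- censor_to_estimation_year(co, lt, 2011, seed = 11)    # 5 mortality years
  s_true <- (1 - q)^5
  expect_lt(abs(mean(co$alive_at_est) - s_true),
            3 * sqrt(s_true * (1 - s_true) / n))
  # estimation year == window end leaves flags untouched
  co2 <- simulate_window(initialize_cohort(pop, prev, 100, 2002, seed = 1, K = 2),
                         diag(2), NULL, 2006, seed = 2)
  co2 <- censor_to_estimation_year(co2, lt, 2006, seed = 3)
  expect_identical(co2$alive_at_est, co2$alive)
})

test_that("assignment rules follow their definitions on hand-checked sequences", {
  m <- rbind(c(1, 3, 2))
  expect_identical(expowin:::assign_category(m, "max"), 3)
  # constant sequences agree under every rule
  mc <- rbind(c(2, 2, 2, 2))
  for (r in c("max", "max2", "most"))
    expect_identical(as.integer(expowin:::assign_category(mc, r)), 2L)
  # (5,1,5,1): no category held 2 consecutive years -> fallback to max
  expect_identical(as.integer(expowin:::assign_category(rbind(c(5, 1, 5, 1)), "max2")), 5L)
  # most-time tie goes to the higher category
  expect_identical(as.integer(expowin:::assign_category(rbind(c(1, 1, 2, 2)), "most")), 2L)
})

test_that("rules agree with exhaustive hand evaluation on all length-4 binary sequences", {
  seqs <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  dimnames(seqs) <- NULL
  hand_max2 <- apply(seqs, 1, function(s) {
    runs <- rle(s)
    held <- runs$values[runs$lengths >= 2]
    if (length(held)) max(held) else max(s)
  })
  hand_most <- apply(seqs, 1, function(s) {
    tab <- tabulate(s + 1, 2)
    max(which(tab == max(tab))) - 1   # tie -> higher category
  })
  expect_identical(as.integer(expowin:::assign_category(seqs, "max2")),
                   as.integer(hand_max2))
  expect_identical(as.integer(expowin:::assign_category(seqs, "most")),
                   as.integer(hand_most))
  expect_identical(as.integer(expowin:::assign_category(seqs, "max")),
                   as.integer(apply(seqs, 1, max)))
})

test_that("DP oracle matches hand enumeration and trivial limits", {
  # identity transitions return the initial distribution exactly
  init <- c(0.2, 0.5, 0.3)
  r <- exact_period_prevalence(init, diag(3), steps = 4)
  expect_identical(r$proportion, init)
  # 2 states, uniform rows, 2 transitions from state 0: P(max=1) = 3/4
  r2 <- exact_period_prevalence(c(1, 0), matrix(0.5, 2, 2), steps = 2)
  expect_equal(r2$proportion, c(0.25, 0.75), tolerance = 1e-12)
  # DP equals full path enumeration on random tiny systems
  for (s in 1:5) {
    K <- 3; steps <- 4
    M <- rand_stoch_matrix(K, 100 + s)
    init <- rand_simplex(K, 200 + s)
    dp <- exact_period_prevalence(init, M, steps = steps)$proportion
    paths <- as.matrix(expand.grid(rep(list(0:(K - 1)), steps + 1)))
    pr <- init[paths[, 1] + 1]
    for (t in 1:steps) pr <- pr * M[cbind(paths[, t] + 1, paths[, t + 1] + 1)]
    brute <- vapply(0:(K - 1), function(k)
      sum(pr[apply(paths, 1, max) == k]), 0)
    expect_equal(dp, brute, tolerance = 1e-12)
  }
  expect_error(exact_period_prevalence(rand_simplex(9, 1), diag(9), steps = 2),
               "K <= 8")
})

test_that("enumeration backend supports the alternative rules on tiny systems", {
  K <- 2; steps <- 3
  M <- rand_stoch_matrix(K, 9)
  init <- c(0.6, 0.4)
  for (rule in c("max2", "most")) {
    r <- exact_period_prevalence(init, M, steps = steps, rule = rule)
    paths <- as.matrix(expand.grid(rep(list(0:1), steps + 1)))
    pr <- init[paths[, 1] + 1]
    for (t in 1:steps) pr <- pr * M[cbind(paths[, t] + 1, paths[, t + 1] + 1)]
    assigned <- expowin:::assign_category(paths, rule)
    brute <- vapply(0:1, function(k) sum(pr[assigned == k]), 0)
    expect_equal(r$proportion, brute, tolerance = 1e-12)
  }
  expect_error(exact_period_prevalence(init, M, steps = 7, rule = "most"),
               "enumeration")
})

test_that("P(max >= k) is non-decreasing in window length", {
  M <- rand_stoch_matrix(4, 33)
  init <- rand_simplex(4, 34)
  prev_tail <- rep(0, 4)
  for (steps in 1:6) {
    p <- exact_period_prevalence(init, M, steps = steps)$proportion
    tail_p <- rev(cumsum(rev(p)))   # P(max >= k)
    expect_true(all(tail_p >= prev_tail - 1e-12))
    prev_tail <- tail_p
  }
})

test_that("Monte Carlo estimates converge to the DP oracle", {
  for (s in 1:3) {
    K <- 6
    M <- rand_stoch_matrix(K, 300 + s)
    init <- rand_simplex(K, 400 + s)
    dp <- exact_period_prevalence(init, M, steps = 9)$proportion
    mc <- mc_period_prevalence(init, M, steps = 9, n = 40000, seed = 500 + s)
    tol <- 3 * sqrt(dp * (1 - dp) / 40000)
    expect_true(all(abs(mc$proportion - dp) <= pmax(tol, 5e-4)))
  }
})

test_that("occupational turnover relates period to point prevalence", {
  expect_equal(occupational_turnover(0.4, 0.1), 4)
  expect_true(is.na(occupational_turnover(0.4, 0)))
  # identity transitions, no mortality: OT = 1 for every category
  init <- c(0.3, 0.3, 0.4)
  dp <- exact_period_prevalence(init, diag(3), steps = 5)$proportion
  expect_equal(occupational_turnover(dp, init), rep(1, 3), tolerance = 1e-12)
  # data.frame method joins on stratum and category
  pp <- data.frame(sex = "all", age_group = "all", category = 0:1,
                   proportion = c(0.6, 0.4), alive_n = 10)
  pt <- data.frame(sex = "all", age_group = "all", category = 0:1,
                   proportion = c(0.3, 0.7))
  got <- occupational_turnover(pp, pt)
  expect_equal(got$ot, c(2, 4/7), tolerance = 1e-12)
})

test_that("simulation conserves counts and is reproducible under a fixed seed", {
  tw <- small_truth(seed = 20)
  prev <- do.call(rbind, lapply(seq_len(nrow(tw$cells)), function(i)
    data.frame(sex = tw$cells$sex[i], age_group = tw$cells$age_group[i],
               category = 0:5,
               proportion = truth_prevalence(tw, "ITA", tw$cells$sex[i],
                                             tw$cells$age_group[i], 2002))))
  lt <- make_life_table(truth_life_table(tw, years = 2002:2016))
  run <- function() {
    co <- initialize_cohort(tw$population, prev, 3000, 2002, seed = 21)
    co <- simulate_window(co, function(s, a) truth_transition_matrix(tw, s, a),
                          lt, 2007, seed = 22)
    censor_to_estimation_year(co, lt, 2010, seed = 23)
  }
  co1 <- run(); co2 <- run()
  expect_identical(co1, co2)
  expect_identical(nrow(co1$data), 3000L)
  expect_identical(sum(co1$alive) + sum(!co1$alive), 3000L)
  # dead individuals record no further transitions
  expect_true(all(is.na(co1$seq[!co1$alive, ncol(co1$seq)])))
  pp <- period_prevalence(co1)
  all_rows <- pp[pp$sex == "all", ]
  expect_equal(sum(all_rows$proportion), 1, tolerance = 1e-12)
})
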