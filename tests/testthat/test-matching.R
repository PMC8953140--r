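# Propensity model, greedy matching, stability aggregation

mk_cases <- function(n_case, n_ctrl, seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  data.table::data.table(
    case_id = sprintf("c%05d", 1:n),
    jaundice = rep(c(TRUE, FALSE), c(n_case, n_ctrl)),
    age_band = sample(c("15-24", "25-34", "35-49"), n, TRUE,
                      prob = c(.05, .79, .16)),
    income_group = sample(1:5, n, TRUE),
    mode = sample(c("vaginal", "cesarean"), n, TRUE),
    preterm = runif(n) < .02, multiple_gestation = runif(n) < .015,
    anc_duration = as.integer(round(rnorm(n, 222, 36))))
}

test_that("propensity model recovers structure and rejects degeneracy", {
  # no covariate effect: all scores near the prevalence
  cs <- mk_cases(60, 600)
  ps <- estimate_propensity(cs)
  expect_true(all(abs(ps$scores - 60 / 660) < 0.1))
  # planted income gradient: scores monotone in income group
  set.seed(5)
  cs2 <- mk_cases(0, 4000)
  cs2$jaundice <- runif(nrow(cs2)) < plogis(-3 + 0.5 * (cs2$income_group - 3))
  ps2 <- estimate_propensity(cs2)
  by_inc <- tapply(ps2$scores, cs2$income_group, mean)
  expect_true(all(diff(by_inc) > 0))
  # oracle: direct likelihood maximization over the 15-cell table gives the
  # same cell probabilities as the glm fit
  cells <- expand.grid(age_band = sort(unique(cs2$age_band)),
                       income_group = 1:5)
  glm_cell <- sapply(seq_len(nrow(cells)), function(i) {
    sel <- cs2$age_band == cells$age_band[i] &
      cs2$income_group == cells$income_group[i]
    ps2$scores[which(sel)[1]]
  })
  # direct maximization: since the model is saturated in neither factor the
  # oracle optimizes the 7-parameter likelihood numerically
  ll <- function(beta) {
    X <- model.matrix(~ factor(age_band) + factor(income_group), cs2)
    eta <- X %*% beta
    -sum(cs2$jaundice * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 7), ll, method = "BFGS")
  X1 <- model.matrix(~ factor(age_band) + factor(income_group),
                     cbind(cells, jaundice = FALSE))
  oracle_cell <- plogis(X1 %*% opt$par)
  expect_equal(unname(glm_cell[!is.na(glm_cell)]),
               unname(oracle_cell[!is.na(glm_cell)]), tolerance = 1e-4)
  # single outcome class
  cs3 <- mk_cases(0, 50)
  expect_error(estimate_propensity(cs3), "outcome")
  # single-level covariates collapse to the intercept
  cs4 <- mk_cases(20, 200)
  cs4$age_band <- "25-34"; cs4$income_group <- 3L
  ps4 <- estimate_propensity(cs4)
  expect_true(all(abs(ps4$scores - ps4$scores[1]) < 1e-12))
})

test_that("greedy matcher equals the exhaustive oracle, ties and all", {
  set.seed(77)
  for (i in 1:20) {
    n_case <- sample(2:6, 1); ratio <- sample(2:4, 1)
    n_ctrl <- n_case * ratio + sample(0:8, 1)
    # coarse scores force plenty of exact ties
    ca <- sample(seq(0.1, 0.9, by = 0.1), n_case, TRUE)
    co <- sample(seq(0.1, 0.9, by = 0.1), n_ctrl, TRUE)
    rk <- sample.int(n_ctrl)
    got <- jaundiceclaims:::greedy_match_cpp(ca, co, rk, ratio)
    want <- greedy_match_oracle(ca, co, rk, ratio)
    expect_identical(unname(got), unname(want))
  }
})

test_that("matched samples: shuffle semantics, disjointness, reproducibility", {
  cs <- mk_cases(5, 80, seed = 3)
  scores <- rep(0.5, nrow(cs)) # all tied
  ms <- nearest_neighbor_match(scores, cs, ratio = 10, order_seed = 42)
  # with identical scores, matching follows the shuffled record order
  perm <- jaundiceclaims:::with_seed(42, sample.int(nrow(cs)))
  shuffle_pos <- integer(nrow(cs)); shuffle_pos[perm] <- seq_len(nrow(cs))
  ctrl_ids <- cs$case_id[!cs$jaundice]
  ctrl_pos <- shuffle_pos[!cs$jaundice]
  expect_identical(ms$control_ids[1:10], ctrl_ids[order(ctrl_pos)][1:10])
  # different seed, different strata
  ms2 <- nearest_neighbor_match(scores, cs, 10, order_seed = 43)
  expect_false(identical(ms$control_ids, ms2$control_ids))
  # same seed bit-identical
  ms3 <- nearest_neighbor_match(scores, cs, 10, order_seed = 42)
  expect_identical(ms$strata, ms3$strata)
  # without replacement: all matched controls distinct
  expect_equal(anyDuplicated(ms$control_ids), 0L)
  # 1 case, 10 controls: everything matched
  cs1 <- mk_cases(1, 10)
  m1 <- nearest_neighbor_match(runif(11), cs1, 10, 1)
  expect_setequal(m1$control_ids, cs1$case_id[!cs1$jaundice])
  # pool exhaustion
  expect_error(nearest_neighbor_match(runif(11), mk_cases(2, 9), 10, 1),
               "exhausted")
})

test_that("matching balances confounded covariates", {
  cfg <- sim_config(n_women = 8000L, p_second_episode = 0)
  sim <- generate_dataset(cfg, seed = 12, emit_claims = FALSE)
  cs <- cases_from_truth(sim$truth)
  ps <- estimate_propensity(cs)
  std_diff <- function(x_case, x_ctrl) {
    (mean(x_case) - mean(x_ctrl)) /
      sqrt((var(x_case) + var(x_ctrl)) / 2)
  }
  inc_case <- cs$income_group[cs$jaundice]
  d_unmatched <- abs(std_diff(inc_case, cs$income_group[!cs$jaundice]))
  d_matched <- sapply(1:10, function(r) {
    ms <- nearest_neighbor_match(ps$scores, cs, 10, order_seed = 100 + r)
    abs(std_diff(inc_case,
                 cs$income_group[match(ms$control_ids, cs$case_id)]))
  })
  expect_lt(mean(d_matched), d_unmatched)
})

test_that("per-rep significance and classification follow the stated rules", {
  expect_identical(classify_factor(901, 1000, 3.2, 0.003), "risk")
  expect_identical(classify_factor(900, 1000, 3.2, 0.003), "none") # strict >
  expect_identical(classify_factor(950, 1000, 0.4, 0.01), "protective")
  expect_identical(classify_factor(950, 1000, 1.5, 0.2), "none") # mean p
  expect_identical(classify_factor(181, 200, 2.0, 0.01), "risk") # scaled
  expect_identical(classify_factor(180, 200, 2.0, 0.01), "none")
})

test_that("run_stability: n_reps = 1 equals a single evaluation; seeds fix all", {
  sim <- generate_dataset(sim_config(n_women = 4000L, p_second_episode = 0),
                          seed = 14, emit_claims = FALSE)
  cs <- cases_from_truth(sim$truth)
  pf <- profiles_from_truth(sim$truth, "A")
  st1 <- run_stability(cs, pf, codes = c("D25", "J00"), n_reps = 1,
                       master_seed = 7)
  ps <- estimate_propensity(cs)
  seed1 <- jaundiceclaims:::derive_seeds(7, 1)
  ms <- nearest_neighbor_match(ps$scores, cs, 10, seed1)
  ev <- evaluate_matched_sample(ms, pf, c("D25", "J00"))
  expect_equal(st1$n_significant, as.integer(ev$significant))
  expect_equal(st1$mean_case_count, as.numeric(ev$a))
  # bit-for-bit reproducibility of aggregates
  st_a <- run_stability(cs, pf, codes = c("D25", "J00"), n_reps = 8,
                        master_seed = 99)
  st_b <- run_stability(cs, pf, codes = c("D25", "J00"), n_reps = 8,
                        master_seed = 99)
  expect_identical(as.data.frame(st_a), as.data.frame(st_b))
})

test_that("infinite odds ratios count for significance but not the mean", {
  # build a matched sample where one code has 0 exposed controls
  cs <- mk_cases(30, 300, seed = 9)
  pf <- data.table::data.table(
    case_id = cs$case_id[cs$jaundice][1:12], study = "A", code3 = "Q10")
  ms <- nearest_neighbor_match(rep(0.5, nrow(cs)), cs, 10, 1)
  ev <- evaluate_matched_sample(ms, pf, "Q10")
  expect_identical(ev$or_cmle, Inf)
  expect_true(ev$significant) # ci_low > 1
  agg <- run_stability(cs, pf, codes = "Q10", n_reps = 3, master_seed = 2)
  expect_equal(agg$n_significant, 3L)
  expect_equal(agg$n_infinite_or, 3L)
  expect_true(is.nan(agg$mean_or)) # no finite significant OR to average
})
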