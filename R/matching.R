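#' Repeated propensity-score matching and stability selection
#'
#' @description
#' The propensity score is the fitted probability of jaundice-group
#' membership from a logistic regression on the two design covariates:
#' maternal age band at delivery (3 levels) and income group at pregnancy
#' diagnosis (5 levels). Each case is matched to `ratio` (default 10)
#' controls by greedy nearest-neighbour matching without replacement on the
#' raw score; the record order is shuffled before every repetition, which
#' sets both the case processing order and the tie-break among equidistant
#' controls. Matching is repeated `n_reps` (default 1000) times; a code is
#' called a risk (protective) factor when it is significant in more than a
#' fraction (default 0.9) of the repetitions with mean odds ratio above
#' (below) 1 and mean p below 0.05, means taken over the significant
#' repetitions only and infinite odds ratios dropped from the mean.
#'
#' @name matching
NULL

#' Fit the propensity model
#'
#' @param cases delivery-cases table (needs `jaundice`, `age_band`,
#'   `income_group`).
#' @return list of class `propensity_model` with `coefficients`, `scores`
#'   (per-case fitted probabilities, aligned with `cases` rows), and `model`
#'   (the underlying `glm`).
#' @export
estimate_propensity <- function(cases) {
  cases <- as.data.table(cases)
  if (length(unique(cases$jaundice)) < 2L)
    stop("both outcome classes must be present to fit a propensity model")
  df <- data.frame(y = as.integer(cases$jaundice),
                   age = factor(cases$age_band),
                   income = factor(cases$income_group))
  # single-level factors collapse to the intercept
  terms <- c(if (nlevels(df$age) > 1L) "age",
             if (nlevels(df$income) > 1L) "income")
  form <- stats::reformulate(if (length(terms)) terms else "1", response = "y")
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = df))
  # a covariate cell holding only cases makes its score 1 and matching
  # meaningless; cells with no cases merely get score ~0 and are harmless
  if (!fit$converged || any(stats::fitted(fit) >= 1 - 1e-10))
    stop("propensity model did not converge (complete separation: some ",
         "covariate cell is predicted case with certainty)")
  structure(list(coefficients = stats::coef(fit),
                 scores = as.numeric(stats::fitted(fit)), model = fit),
            class = "propensity_model")
}

#' One greedy 1:ratio nearest-neighbour matched sample
#'
#' @param scores propensity scores aligned with `cases` rows.
#' @param cases delivery-cases table (needs `case_id`, `jaundice`).
#' @param ratio controls per case (default 10).
#' @param order_seed integer seed for the record shuffle.
#' @return list of class `matched_sample`: `strata` (data.table `stratum,
#'   case_id, role`), `case_ids`, `control_ids`, `ratio`, `order_seed`.
#' @export
nearest_neighbor_match <- function(scores, cases, ratio = 10L, order_seed = 1L) {
  cases <- as.data.table(cases)
  stopifnot(length(scores) == nrow(cases))
  is_case <- cases$jaundice
  n <- nrow(cases)
  if (sum(!is_case) < ratio * sum(is_case))
    stop("control pool exhausted: need ", ratio * sum(is_case),
         " controls, have ", sum(!is_case))

  perm <- with_seed(order_seed, sample.int(n)) # shuffled record order
  shuffle_pos <- integer(n); shuffle_pos[perm] <- seq_len(n)

  ca_idx <- which(is_case); co_idx <- which(!is_case)
  ca_idx <- ca_idx[order(shuffle_pos[ca_idx])] # process cases in shuffle order
  m <- greedy_match_cpp(scores[ca_idx], scores[co_idx],
                        shuffle_pos[co_idx], as.integer(ratio))

  rows <- as.vector(t(cbind(ca_idx, matrix(co_idx[m], nrow(m)))))
  strata <- data.table(
    stratum = rep(seq_along(ca_idx), each = ratio + 1L),
    case_id = cases$case_id[rows],
    role = rep(c("case", rep("control", ratio)), length(ca_idx)))
  structure(list(strata = strata,
                 case_ids = cases$case_id[ca_idx],
                 control_ids = cases$case_id[co_idx[as.vector(t(m))]],
                 ratio = as.integer(ratio), order_seed = order_seed),
            class = "matched_sample")
}

#' Evaluate per-code 2x2 tables on one matched sample
#'
#' Significance per repetition: the exact 95% CI excludes 1 (lower bound > 1
#' or upper bound < 1) and p < 0.05.
#'
#' @param sample a `matched_sample`.
#' @param profiles profile table (`case_id`, `code3`).
#' @param codes codes to evaluate.
#' @param alpha significance level (default 0.05).
#' @return data.table `code3, a, b, c, d, or_cmle, ci_low, ci_high, p,
#'   significant`.
#' @export
evaluate_matched_sample <- function(sample, profiles, codes, alpha = 0.05) {
  profiles <- as.data.table(profiles)
  nJ <- length(sample$case_ids); nC <- length(sample$control_ids)
  pj <- profiles[case_id %in% sample$case_ids & code3 %in% codes]
  pc <- profiles[case_id %in% sample$control_ids & code3 %in% codes]
  aj <- pj[, .(a = .N), by = code3]
  ac <- pc[, .(cc = .N), by = code3]
  out <- data.table(code3 = codes)
  out <- aj[out, on = "code3"]; out <- ac[out, on = "code3"]
  out[is.na(a), a := 0L][is.na(cc), cc := 0L]
  out[, `:=`(b = nJ - a, d = nC - cc)]
  res <- lapply(seq_len(nrow(out)), function(i)
    fisher_2x2(out$a[i], out$b[i], out$cc[i], out$d[i]))
  out[, `:=`(or_cmle = vapply(res, `[[`, 0, "or_cmle"),
             ci_low = vapply(res, `[[`, 0, "ci_low"),
             ci_high = vapply(res, `[[`, 0, "ci_high"),
             p = vapply(res, `[[`, 0, "p"))]
  out[, significant := (ci_low > 1 | ci_high < 1) & p < alpha]
  setnames(out, "cc", "c")
  out[, .(code3, a, b, c, d, or_cmle, ci_low, ci_high, p, significant)]
}

#' Repeat matching and aggregate per-code stability
#'
#' Deterministic given `master_seed`: per-repetition shuffle seeds are drawn
#' once from the master seed.
#'
#' @param cases delivery-cases table.
#' @param profiles profile table for the study window.
#' @param codes codes to track (default: all codes in `profiles` with at
#'   least one exposed case).
#' @param n_reps number of matched samples (default 1000).
#' @param master_seed integer master seed.
#' @param ratio controls per case.
#' @param alpha per-repetition significance level.
#' @param fraction stability fraction (default 0.9: "more than 900 of
#'   1,000").
#' @return data.table of class `stability_aggregate`: `code3, n_reps,
#'   n_significant, mean_or, mean_p, mean_case_count, mean_control_count,
#'   n_infinite_or, label`.
#' @export
run_stability <- function(cases, profiles, codes = NULL, n_reps = 1000L,
                          master_seed = 1L, ratio = 10L, alpha = 0.05,
                          fraction = 0.9) {
  stopifnot(n_reps >= 1L)
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)
  if (is.null(codes))
    codes <- sort(unique(profiles[case_id %in% cases$case_id, code3]))
  ps <- estimate_propensity(cases)
  seeds <- derive_seeds(master_seed, n_reps)

  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ms <- nearest_neighbor_match(ps$scores, cases, ratio, seeds[r])
    ev <- evaluate_matched_sample(ms, profiles, codes, alpha)
    ev[, rep_index := r]
    per_rep[[r]] <- ev
  }
  all <- rbindlist(per_rep)
  agg <- all[, .(
    n_reps = as.integer(n_reps),
    n_significant = sum(significant),
    mean_or = mean(or_cmle[significant & is.finite(or_cmle)]),
    mean_p = mean(p[significant]),
    mean_case_count = mean(a),
    mean_control_count = mean(c),
    n_infinite_or = sum(significant & !is.finite(or_cmle))
  ), by = code3]
  agg[, label := classify_factor(n_significant, n_reps, mean_or, mean_p,
                                 fraction = fraction)]
  setorder(agg, code3)
  data.table::setattr(agg, "class",
                      c("stability_aggregate", class(agg)))
  agg
}

#' Classify a code as risk, protective, or none
#'
#' Risk: significant in strictly more than `fraction * n_reps` repetitions
#' with mean OR > 1 and mean p < 0.05; protective: the same with mean OR < 1;
#' otherwise none. With `n_reps = 1000` and `fraction = 0.9` this is the
#' "more than 900 of 1,000" rule; the same fraction scales to reduced runs.
#'
#' @param n_significant,n_reps,mean_or,mean_p vectors (recycled as usual).
#' @param alpha mean-p threshold (default 0.05).
#' @param fraction stability fraction (default 0.9).
#' @return character vector in `{"risk", "protective", "none"}`.
#' @export
classify_factor <- function(n_significant, n_reps, mean_or, mean_p,
                            alpha = 0.05, fraction = 0.9) {
  stable <- n_significant > fraction * n_reps & !is.na(mean_p) & mean_p < alpha
  fifelse(stable & !is.na(mean_or) & mean_or > 1, "risk",
          fifelse(stable & !is.na(mean_or) & mean_or < 1, "protective",
                  "none"))
}
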