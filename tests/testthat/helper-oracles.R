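# Independent oracles used across the suite. None of these share code with
# the package paths they check.

# two-sided minimum-likelihood Fisher p by direct enumeration with lchoose
# (no dhyper): m exposed total, n unexposed total, k cases
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  supp <- max(0, k - n):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  pr <- exp(lp)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}

# O(n_case * n_ctrl) greedy nearest-neighbour replay: cases in given order,
# each takes `ratio` nearest available controls, ties by smaller rank
greedy_match_oracle <- function(case_scores, ctrl_scores, ctrl_rank, ratio) {
  avail <- rep(TRUE, length(ctrl_scores))
  out <- matrix(NA_integer_, length(case_scores), ratio)
  for (i in seq_along(case_scores)) {
    for (r in seq_len(ratio)) {
      d <- abs(ctrl_scores - case_scores[i])
      d[!avail] <- Inf
      best <- which(d == min(d))
      pick <- best[which.min(ctrl_rank[best])]
      out[i, r] <- pick
      avail[pick] <- FALSE
    }
  }
  out
}

# conditional log-likelihood for 1-case strata, written independently
clogit_ll_oracle <- function(beta, X, y, stratum) {
  eta <- as.vector(as.matrix(X) %*% beta)
  sum(vapply(split(seq_along(eta), stratum), function(idx) {
    eta[idx][y[idx] == 1] - log(sum(exp(eta[idx] - max(eta[idx])))) -
      max(eta[idx])
  }, 0))
}

# dense grid search over beta in [-4, 4]^k maximizing the conditional
# likelihood (coarse-to-fine refinement)
clogit_grid_oracle <- function(X, y, stratum, k = ncol(as.matrix(X))) {
  ctr <- rep(0, k); width <- 4
  for (pass in 1:8) {
    axes <- lapply(seq_len(k), function(j)
      seq(ctr[j] - width, ctr[j] + width, length.out = 9))
    grid <- as.matrix(do.call(expand.grid, axes))
    ll <- apply(grid, 1, function(b) clogit_ll_oracle(b, X, y, stratum))
    ctr <- grid[which.max(ll), ]
    width <- width / 3
  }
  ctr
}

# shorthand bundle constructor for hand-built fixtures
make_bundle <- function(qual, claims) {
  qual <- data.table::as.data.table(qual)
  claims <- data.table::as.data.table(claims)
  if (!"claim_no" %in% names(claims))
    claims[, claim_no := sprintf("C%04d", .I)]
  if (!"source" %in% names(claims)) claims[, source := "principal"]
  claims[, visit_date := as.Date(visit_date)]
  jaundiceclaims:::new_claims_bundle(qual, claims)
}

# qualification rows for one woman over a span of years
qual_rows <- function(pid, years, age_group = 6L, income_rank = 5L,
                      sex = "female") {
  data.table::data.table(person_id = pid, sex = sex, year = years,
                         age_group = age_group, income_rank = income_rank)
}

claim_rows <- function(pid, dates, codes) {
  data.table::data.table(person_id = pid, visit_date = as.Date(dates),
                         code = codes)
}
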