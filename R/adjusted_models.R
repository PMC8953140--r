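#' Stratified conditional logistic regression for matched sets
#'
#' @description
#' For matched strata (here 1 case : 10 controls) the per-stratum intercepts
#' are conditioned out, leaving the conditional likelihood
#' `prod_s exp(x_case' b) / sum_{j in s} exp(x_j' b)` (each stratum has one
#' case). The score and observed information have closed forms (per-stratum
#' softmax mean and covariance), so the likelihood is maximized by damped
#' Newton iterations; confidence intervals are Wald intervals from the
#' inverse observed information. Strata with no covariate variation
#' contribute a constant and carry no information.
#'
#' @name adjusted_models
NULL

# log conditional likelihood, gradient and information for 1-case strata
# X: n x p matrix; y: 1 for the stratum's case; stratum: integer vector
.clogit_parts <- function(beta, X, y, stratum) {
  eta <- as.vector(X %*% beta)
  sp <- split(seq_along(eta), stratum)
  ll <- 0; grad <- numeric(ncol(X)); info <- matrix(0, ncol(X), ncol(X))
  for (idx in sp) {
    e <- eta[idx]; w <- exp(e - max(e)); w <- w / sum(w)
    xs <- X[idx, , drop = FALSE]
    xbar <- colSums(xs * w)
    ci <- which(y[idx] == 1L)
    ll <- ll + e[ci] - (log(sum(exp(e - max(e)))) + max(e))
    grad <- grad + xs[ci, ] - xbar
    info <- info + crossprod(xs * sqrt(w)) - tcrossprod(xbar)
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a conditional logistic regression on matched strata
#'
#' @param X numeric covariate matrix (one row per record); columns are the
#'   model terms.
#' @param y 0/1 outcome (exactly one 1 per stratum).
#' @param stratum stratum identifier per record.
#' @param max_iter Newton iteration cap (default 100).
#' @param tol convergence tolerance on the gradient max-norm.
#' @return list of class `clogit_fit`: `beta`, `se`, `or` (= exp(beta)),
#'   `ci_low`, `ci_high` (Wald 95%), `p` (Wald), `loglik`, `converged`,
#'   `n_strata`, `uninformative_strata` (no within-stratum variation in any
#'   covariate).
#' @export
conditional_logit_fit <- function(X, y, stratum, max_iter = 100L,
                                  tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), length(stratum) == nrow(X))
  tab <- tapply(y, stratum, sum)
  if (any(tab != 1L)) stop("each stratum must contain exactly one case")

  uninf <- vapply(split(seq_along(y), stratum), function(idx) {
    all(apply(X[idx, , drop = FALSE], 2, function(col) all(col == col[1])))
  }, TRUE)

  # center columns for numerical stability (conditional likelihood is
  # invariant to per-column shifts)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    parts <- .clogit_parts(beta, Xc, y, stratum)
    if (max(abs(parts$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) NULL)
    if (is.null(step)) break # singular information: non-estimable direction
    # step-halving on the log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (.clogit_parts(cand, Xc, y, stratum)$ll >= parts$ll - 1e-12 ||
          lam < 1e-4) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
  }
  parts <- .clogit_parts(beta, Xc, y, stratum)
  vcov <- tryCatch(solve(parts$info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vcov))
  # separation / non-estimability: runaway coefficients flagged non-finite
  beta[abs(beta) > 15] <- sign(beta[abs(beta) > 15]) * Inf
  z <- beta / se
  structure(list(
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    loglik = parts$ll,
    converged = converged,
    n_strata = length(unique(stratum)),
    uninformative_strata = sum(uninf)
  ), class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("conditional logit: %d strata (%d uninformative), %s\n",
              x$n_strata, x$uninformative_strata,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(beta = x$beta, se = x$se, or = x$or,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$p))
  invisible(x)
}

# covariate matrix for the adjusted model of one exposure code
.adjusted_design <- function(sample, cases, profiles, code) {
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)
  st <- copy(sample$strata)
  st <- cases[st, on = "case_id"]
  exposed_ids <- unique(profiles[code3 == code, case_id])
  X <- cbind(exposure = as.numeric(st$case_id %in% exposed_ids),
             preterm = as.numeric(st$preterm),
             cesarean = as.numeric(st$mode == "cesarean"),
             multiple_gestation = as.numeric(st$multiple_gestation),
             anc_duration = as.numeric(st$anc_duration))
  list(X = X, y = as.integer(st$role == "case"), stratum = st$stratum)
}

#' Adjusted model for one code on one matched sample
#'
#' Conditional logistic regression of case status on exposure to `code`,
#' adjusted for preterm delivery, delivery mode (cesarean), multiple
#' gestation, and antenatal-care duration (per day).
#'
#' @param sample a `matched_sample`.
#' @param cases delivery-cases table (covariate source).
#' @param profiles profile table for the study window.
#' @param code the 3-character exposure code.
#' @return a `clogit_fit` with coefficient order `exposure, preterm,
#'   cesarean, multiple_gestation, anc_duration`.
#' @export
fit_adjusted_code <- function(sample, cases, profiles, code) {
  d <- .adjusted_design(sample, cases, profiles, code)
  keep <- apply(d$X, 2, function(col) stats::var(col) > 0)
  fit <- conditional_logit_fit(d$X[, keep, drop = FALSE], d$y, d$stratum)
  # report dropped (constant) covariates as non-estimable
  full <- colnames(d$X)
  pad <- function(v, fill) stats::setNames(
    replace(rep(fill, length(full)), match(names(v), full), v), full)
  for (f in c("beta", "se", "or", "ci_low", "ci_high", "p"))
    fit[[f]] <- pad(fit[[f]], NA_real_)
  fit
}

#' Aggregate adjusted models over matched repetitions
#'
#' For each code passing the stability rule, the adjusted model is refitted
#' on every matched repetition; means of the adjusted OR, Wald CI bounds and
#' p-value are taken over the repetitions where the *univariable* test was
#' significant, dropping non-finite estimates (counted separately).
#'
#' @param per_rep list of `clogit_fit` objects (one per repetition).
#' @param significant logical vector: univariable significance per
#'   repetition.
#' @return data.table `term, mean_or, mean_ci_low, mean_ci_high, mean_p,
#'   n_used, n_nonfinite`; zero rows when no repetition was significant.
#' @export
aggregate_adjusted <- function(per_rep, significant) {
  stopifnot(length(per_rep) == length(significant))
  used <- per_rep[significant]
  if (!length(used))
    return(data.table(term = character(), mean_or = numeric(),
                      mean_ci_low = numeric(), mean_ci_high = numeric(),
                      mean_p = numeric(), n_used = integer(),
                      n_nonfinite = integer()))
  terms <- names(used[[1]]$beta)
  rbindlist(lapply(terms, function(tm) {
    or <- vapply(used, function(f) f$or[[tm]], 0)
    lo <- vapply(used, function(f) f$ci_low[[tm]], 0)
    hi <- vapply(used, function(f) f$ci_high[[tm]], 0)
    p <- vapply(used, function(f) f$p[[tm]], 0)
    ok <- is.finite(or) & is.finite(lo) & is.finite(hi)
    data.table(term = tm, mean_or = mean(or[ok]), mean_ci_low = mean(lo[ok]),
               mean_ci_high = mean(hi[ok]), mean_p = mean(p[ok]),
               n_used = sum(ok), n_nonfinite = sum(!ok))
  }))
}
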