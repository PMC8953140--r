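# matched-set fixture: n_strata strata of 1 case : `ratio` controls with a
# binary covariate design drawn from the conditional model itself
mk_strata <- function(n_strata, ratio = 10, k = 2, seed = 1,
                      beta = c(1, -0.5, 0.3)) {
  set.seed(seed)
  rows <- lapply(seq_len(n_strata), function(s) {
    X <- matrix(rbinom((ratio + 1) * k, 1, 0.3), ratio + 1, k)
    eta <- X %*% beta[seq_len(k)]
    pick <- sample(ratio + 1, 1, prob = exp(eta))
    y <- integer(ratio + 1); y[pick] <- 1L
    list(X = X, y = y, stratum = rep(s, ratio + 1))
  })
  list(X = do.call(rbind, lapply(rows, `[[`, "X")),
       y = unlist(lapply(rows, `[[`, "y")),
       stratum = unlist(lapply(rows, `[[`, "stratum")))
}
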