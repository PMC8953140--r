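#' @importFrom data.table := .N .SD data.table as.data.table setkey setorder
#'   fread fwrite rbindlist setnames copy fifelse
#' @importFrom Rcpp sourceCpp
#' @useDynLib jaundiceclaims, .registration = TRUE
NULL

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# derive `n` independent 31-bit sub-seeds from one master seed
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

# dots are presentation only in KCD/ICD code strings; normalize them away so
# "O84.2" and "O842" match the same prefixes
strip_dot <- function(code) gsub(".", "", code, fixed = TRUE)

# TRUE for each code that starts with at least one prefix in `prefixes`
# (matching on the dot-normalized, uppercased strings)
code_has_prefix <- function(codes, prefixes) {
  codes <- toupper(strip_dot(codes))
  prefixes <- toupper(strip_dot(prefixes))
  out <- logical(length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
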