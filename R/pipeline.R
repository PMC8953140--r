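#' End-to-end pipeline and report export
#'
#' [run_pipeline()] composes the whole analysis: read (or accept) a claims
#' bundle, build delivery cases, extract study windows, apply eligibility,
#' tabulate unmatched per-code odds ratios, run repeated propensity-score
#' matching with stability selection, fit adjusted conditional-logit models
#' for the stability-selected codes, and write one TSV per report surface
#' plus the factor-network edge list. All randomness flows from one master
#' seed through per-stage derived seeds.
#'
#' @name cli_report
NULL

#' Pipeline configuration
#'
#' @param study `"A"`, `"B"`, or `"both"`.
#' @param match_ratio controls per case (default 10).
#' @param n_reps matched repetitions (default 1000).
#' @param master_seed integer master seed.
#' @param alpha per-repetition significance level (default 0.05).
#' @param fraction stability fraction (default 0.9).
#' @param code_sets a `code_sets` list.
#' @param windows window list.
#' @param min_codes_for_stability minimum exposed cases overall for a code to
#'   enter the stability stage (default 1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = "both", match_ratio = 10L,
                            n_reps = 1000L, master_seed = 1L, alpha = 0.05,
                            fraction = 0.9,
                            code_sets = default_code_sets(),
                            windows = default_windows(),
                            min_codes_for_stability = 1L) {
  stopifnot(n_reps >= 1L, match_ratio >= 1L, fraction > 0, fraction < 1,
            study %in% c("A", "B", "both"))
  structure(as.list(environment()), class = "pipeline_config")
}

.fmt_or <- function(x) ifelse(is.finite(x), sprintf("%.2f", x),
                              ifelse(x > 0, "Inf", "0"))

# demographics table (counts, percentages, exact / t / trend p-values)
.demographics <- function(cases, seed) {
  cases <- as.data.table(cases)
  g <- cases$jaundice
  nJ <- sum(g); nC <- sum(!g)
  rows <- list()
  cat_block <- function(var, label) {
    lv <- sort(unique(var))
    cj <- vapply(lv, function(l) sum(var == l & g), 0L)
    cc <- vapply(lv, function(l) sum(var == l & !g), 0L)
    p <- if (length(lv) >= 2 && all(cj + cc > 0))
      fisher_rxc_mc(rbind(cj, cc), seed = seed)$p else NA_real_
    data.table(characteristic = label, level = as.character(lv),
               jaundice_n = cj, jaundice_pct = round(100 * cj / nJ, 1),
               control_n = cc, control_pct = round(100 * cc / nC, 1),
               p = c(p, rep(NA_real_, length(lv) - 1L)))
  }
  rows$age <- cat_block(cases$age_band, "age_band")
  rows$income <- cat_block(cases$income_group, "income_group")
  flag_block <- function(var, label) {
    ft <- fisher_2x2(sum(var & g), sum(!var & g), sum(var & !g),
                     sum(!var & !g))
    data.table(characteristic = label, level = "yes",
               jaundice_n = sum(var & g),
               jaundice_pct = round(100 * mean(var[g]), 1),
               control_n = sum(var & !g),
               control_pct = round(100 * mean(var[!g]), 1), p = ft$p)
  }
  rows$preterm <- flag_block(cases$preterm, "preterm")
  rows$cesarean <- flag_block(cases$mode == "cesarean", "cesarean")
  rows$multi <- flag_block(cases$multiple_gestation, "multiple_gestation")
  wt <- welch_t(nJ, mean(cases$anc_duration[g]), stats::sd(cases$anc_duration[g]),
                nC, mean(cases$anc_duration[!g]),
                stats::sd(cases$anc_duration[!g]))
  rows$anc <- data.table(
    characteristic = "anc_duration", level = "mean_sd",
    jaundice_n = nJ, jaundice_pct = round(mean(cases$anc_duration[g]), 1),
    control_n = nC, control_pct = round(mean(cases$anc_duration[!g]), 1),
    p = wt$p)
  tots <- vapply(1:5, function(l) sum(cases$income_group == l), 0L)
  trend_p <- if (all(tots > 0))
    cochran_armitage(vapply(1:5, function(l)
      sum(cases$income_group == l & g), 0L), tots)$p else NA_real_
  rows$trend <- data.table(characteristic = "income_trend", level = "",
                           jaundice_n = NA_integer_, jaundice_pct = NA_real_,
                           control_n = NA_integer_, control_pct = NA_real_,
                           p = trend_p)
  rbindlist(rows)
}

#' Replay matched repetitions and aggregate adjusted models
#'
#' Reproduces the matched samples of [run_stability()] (same master seed,
#' same seed derivation) and fits the adjusted conditional-logit model for
#' each requested code on every repetition, aggregating over the repetitions
#' where the code's univariable test was significant.
#'
#' @param cases,profiles as in [run_stability()].
#' @param codes codes to model (typically the stability-selected ones).
#' @param n_reps,master_seed,ratio,alpha as in [run_stability()].
#' @return data.table `code3, term, mean_or, mean_ci_low, mean_ci_high,
#'   mean_p, n_used, n_nonfinite`.
#' @export
run_adjusted <- function(cases, profiles, codes, n_reps = 1000L,
                         master_seed = 1L, ratio = 10L, alpha = 0.05) {
  if (!length(codes))
    return(data.table(code3 = character(), term = character(),
                      mean_or = numeric(), mean_ci_low = numeric(),
                      mean_ci_high = numeric(), mean_p = numeric(),
                      n_used = integer(), n_nonfinite = integer()))
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)
  ps <- estimate_propensity(cases)
  seeds <- derive_seeds(master_seed, n_reps)
  fits <- lapply(codes, function(cd) vector("list", n_reps))
  names(fits) <- codes
  sig <- matrix(FALSE, n_reps, length(codes),
                dimnames = list(NULL, codes))
  for (r in seq_len(n_reps)) {
    ms <- nearest_neighbor_match(ps$scores, cases, ratio, seeds[r])
    ev <- evaluate_matched_sample(ms, profiles, codes, alpha)
    sig[r, ev$code3] <- ev$significant
    for (cd in codes)
      fits[[cd]][[r]] <- fit_adjusted_code(ms, cases, profiles, cd)
  }
  rbindlist(lapply(codes, function(cd) {
    agg <- aggregate_adjusted(fits[[cd]], sig[, cd])
    if (nrow(agg)) agg[, code3 := cd]
    agg
  }), fill = TRUE)
}

#' Export the risk/protective factor network edge list
#'
#' Nodes are the outcome plus every code labeled risk or protective; each
#' edge carries the study, label, mean OR over significant repetitions, and
#' mean exposed-case count.
#'
#' @param agg_a,agg_b stability aggregates for studies A and B (either may be
#'   `NULL`).
#' @return data.table `source, target, study, label, mean_or, mean_cases`.
#' @export
export_network <- function(agg_a = NULL, agg_b = NULL) {
  one <- function(agg, study) {
    if (is.null(agg)) return(NULL)
    sel <- as.data.table(agg)[label != "none"]
    if (!nrow(sel)) return(NULL)
    sel[, .(source = code3, target = "neonatal_jaundice", study = study,
            label, mean_or, mean_cases = mean_case_count)]
  }
  out <- rbindlist(list(one(agg_a, "A"), one(agg_b, "B")))
  if (is.null(out) || !nrow(out))
    out <- data.table(source = character(), target = character(),
                      study = character(), label = character(),
                      mean_or = numeric(), mean_cases = numeric())
  out
}

.study_report <- function(cases0, claims, cfg, study, seeds) {
  profiles <- extract_window_profiles(cases0, claims, study, cfg$windows)
  elig <- apply_eligibility(cases0, profiles, cfg$code_sets)
  cases <- elig$cases
  profiles <- elig$profiles
  exclude <- if (study == "A") cfg$code_sets$pregnancy_related_exclusion
             else character()
  tabs <- tabulate_all_codes(cases, profiles, exclude)
  tabs <- tabs[a >= 1L] # unmatched table: codes with >= 1 exposed case
  un <- lapply(seq_len(nrow(tabs)), function(i)
    fisher_2x2(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]))
  unmatched <- copy(tabs)
  unmatched[, `:=`(or_cmle = vapply(un, `[[`, 0, "or_cmle"),
                   ci_low = vapply(un, `[[`, 0, "ci_low"),
                   ci_high = vapply(un, `[[`, 0, "ci_high"),
                   p = vapply(un, `[[`, 0, "p"))]
  setorder(unmatched, -or_cmle, code3)

  stab_codes <- tabs[a >= cfg$min_codes_for_stability, code3]
  stab <- run_stability(cases, profiles, stab_codes, cfg$n_reps,
                        seeds["stability"], cfg$match_ratio, cfg$alpha,
                        cfg$fraction)
  pass <- stab[label != "none", code3]
  adj <- run_adjusted(cases, profiles, pass, cfg$n_reps, seeds["stability"],
                      cfg$match_ratio, cfg$alpha)
  demo <- .demographics(cases, seeds["demographics"])
  list(cases = cases, profiles = profiles,
       n_ineligible = elig$n_excluded, demographics = demo,
       unmatched = unmatched, stability = stab, adjusted = adj)
}

#' Run the full pipeline and write a report directory
#'
#' @param bundle a `claims_bundle` (or a list of the three table paths:
#'   `qual`, `statement`, `disease`, read with [read_claims_tables()]).
#' @param out_dir report directory (created).
#' @param config a [pipeline_config()].
#' @param dialect used only when `bundle` is a path list.
#' @return invisibly, a list with the per-study results and the ledger;
#'   writes `delivery_cases.tsv`, `exclusion_ledger.tsv`, and per study S:
#'   `demographics_S.tsv`, `unmatched_or_S.tsv`, `stability_S.tsv`,
#'   `adjusted_S.tsv`, plus `network.tsv` and `run_config.yaml`.
#' @export
run_pipeline <- function(bundle, out_dir, config = pipeline_config(),
                         dialect = default_dialect()) {
  if (!inherits(bundle, "claims_bundle"))
    bundle <- read_claims_tables(bundle$qual, bundle$statement,
                                 bundle$disease, dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stats::setNames(derive_seeds(config$master_seed, 3L),
                           c("stability", "demographics", "spare"))

  built <- build_delivery_cases(bundle, config$code_sets, config$windows)
  fwrite(built$cases, file.path(out_dir, "delivery_cases.tsv"), sep = "\t")

  studies <- if (config$study == "both") c("A", "B") else config$study
  res <- list()
  for (s in studies) {
    r <- .study_report(built$cases, bundle$claims, config, s, seeds)
    res[[s]] <- r
    fwrite(r$demographics, file.path(out_dir, sprintf("demographics_%s.tsv", s)),
           sep = "\t")
    fwrite(r$unmatched, file.path(out_dir, sprintf("unmatched_or_%s.tsv", s)),
           sep = "\t")
    fwrite(r$stability, file.path(out_dir, sprintf("stability_%s.tsv", s)),
           sep = "\t")
    fwrite(r$adjusted, file.path(out_dir, sprintf("adjusted_%s.tsv", s)),
           sep = "\t")
  }
  ledger <- copy(built$ledger)
  for (s in studies)
    ledger <- rbindlist(list(ledger, data.table(
      stage = sprintf("no_nonpregnancy_dx_in_window_%s", s),
      n_excluded = res[[s]]$n_ineligible)))
  fwrite(ledger, file.path(out_dir, "exclusion_ledger.tsv"), sep = "\t")

  net <- export_network(res[["A"]]$stability, res[["B"]]$stability)
  fwrite(net, file.path(out_dir, "network.tsv"), sep = "\t")

  yaml::write_yaml(list(master_seed = config$master_seed,
                        n_reps = config$n_reps,
                        match_ratio = config$match_ratio,
                        alpha = config$alpha, fraction = config$fraction,
                        study = config$study),
                   file.path(out_dir, "run_config.yaml"))
  invisible(c(res, list(ledger = ledger, network = net)))
}
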