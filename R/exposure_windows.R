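#' Exposure windows: per-case diagnosis profiles and 2x2 tables
#'
#' Study A looks at diagnoses during antenatal care, from the pregnancy
#' diagnosis date up to the day before delivery; study B looks at the year
#' before the pregnancy diagnosis, `[pregnancy_dx - 365, pregnancy_dx - 1]`.
#' Codes are truncated to their 3-character category and deduplicated per
#' case (a repeated diagnosis counts once). The two windows of a case are
#' disjoint by construction.
#'
#' @name exposure_windows
NULL

.study_window <- function(cases, study, windows) {
  cases <- as.data.table(cases)
  if (study == "A") {
    cases[, .(case_id, person_id, lo = pregnancy_dx_date,
              hi = delivery_date - 1L)]
  } else if (study == "B") {
    cases[, .(case_id, person_id,
              lo = pregnancy_dx_date - windows$preconception_days,
              hi = pregnancy_dx_date - 1L)]
  } else stop("study must be 'A' or 'B'")
}

#' Extract per-case 3-character code profiles for a study window
#'
#' @param cases delivery-cases table from [build_delivery_cases()].
#' @param claims claim stream.
#' @param study `"A"` (antenatal) or `"B"` (pre-conception year).
#' @param windows window list (see [default_windows()]).
#' @return data.table `case_id, study, code3`, deduplicated.
#' @export
extract_window_profiles <- function(cases, claims, study,
                                    windows = default_windows()) {
  win <- .study_window(cases, study, windows)
  cl <- as.data.table(claims)[, .(person_id, visit_date, code)]
  hit <- cl[win, on = .(person_id, visit_date >= lo, visit_date <= hi),
            nomatch = NULL, .(case_id = i.case_id, code = x.code)]
  if (nrow(hit) == 0L)
    return(data.table(case_id = character(), study = character(),
                      code3 = character()))
  hit[, code3 := truncate_code(code)]
  st <- study
  out <- unique(hit[, .(case_id, code3)])[, study := st]
  setorder(out, case_id, code3)
  out[, .(case_id, study, code3)]
}

#' Apply window eligibility: at least one non-pregnancy-related diagnosis
#'
#' A case is eligible iff its window profile contains at least one code whose
#' prefix is not in `code_sets$pregnancy_related_exclusion` — cases insured
#' only for pregnancy/delivery care in the window carry no exposure
#' information.
#'
#' @param cases delivery-cases table.
#' @param profiles output of [extract_window_profiles()] for the same study.
#' @param code_sets a `code_sets` list.
#' @return list with `cases` (eligible subset), `profiles` (restricted to
#'   eligible cases), and `n_excluded`.
#' @export
apply_eligibility <- function(cases, profiles, code_sets = default_code_sets()) {
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)
  informative <- profiles[
    !code_has_prefix(code3, code_sets$pregnancy_related_exclusion),
    unique(case_id)]
  keep <- cases$case_id %in% informative
  list(cases = cases[keep],
       profiles = profiles[case_id %in% cases$case_id[keep]],
       n_excluded = sum(!keep))
}

#' Build the 2x2 exposure table for one code
#'
#' @param cases eligible cases (must carry `case_id`, `jaundice`).
#' @param profiles profile table for the study.
#' @param code3 one 3-character code.
#' @return named integer vector `c(a, b, c, d)`: exposed jaundice cases,
#'   unexposed jaundice cases, exposed controls, unexposed controls.
#' @export
tabulate_code <- function(cases, profiles, code3) {
  stopifnot(nchar(code3) == 3L)
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)
  exposed <- unique(profiles$case_id[profiles$code3 == code3])
  ex <- cases$case_id %in% exposed
  a <- sum(ex & cases$jaundice); b <- sum(cases$jaundice) - a
  cc <- sum(ex & !cases$jaundice); d <- sum(!cases$jaundice) - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Tabulate every code with at least one exposed case
#'
#' Codes whose prefix is in `exclude_prefixes` (study A: the
#' pregnancy-related set) are never tabulated as exposures.
#'
#' @param cases eligible cases.
#' @param profiles profile table.
#' @param exclude_prefixes prefixes to skip (default none).
#' @return data.table `code3, a, b, c, d` (one row per code, any code
#'   observed in at least one case).
#' @export
tabulate_all_codes <- function(cases, profiles, exclude_prefixes = character()) {
  cases <- as.data.table(cases)
  profiles <- as.data.table(profiles)[case_id %in% cases$case_id]
  if (length(exclude_prefixes))
    profiles <- profiles[!code_has_prefix(code3, exclude_prefixes)]
  nJ <- sum(cases$jaundice); nC <- sum(!cases$jaundice)
  jset <- cases[jaundice == TRUE, case_id]
  tab <- profiles[, .(a = sum(case_id %in% jset), exposed = .N), by = code3]
  tab[, `:=`(b = nJ - a, c = exposed - a)]
  tab[, d := nC - c]
  setorder(tab, code3)
  tab[, .(code3, a, b, c, d)]
}
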