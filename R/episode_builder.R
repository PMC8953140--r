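#' Episode builder: from a claim stream to analyzable delivery cases
#'
#' @description
#' Delivery-coded claim dates are grouped greedily into delivery events (a
#' date starts a new event iff it falls at least 24 weeks = 168 days after
#' the current event's anchor date). Each event is paired with the earliest
#' pregnancy-coded visit no more than 44 weeks = 308 days before delivery and
#' at least 4 weeks = 28 days after the woman's previous delivery. Events
#' then pass an ordered exclusion cascade (age range, pregnancy pairing,
#' delivery-mode identification, abortion/stillbirth codes, qualification
#' completeness) tracked in an exclusion ledger, and each retained event
#' becomes one independent delivery case with delivery-adjacent flags
#' (preterm, multiple gestation, neonatal jaundice) and covariates (3-band
#' maternal age at delivery, 5-group income at pregnancy diagnosis).
#'
#' @name episode_builder
NULL

# analysis age bands from the 5-year qualification band index:
# bands 4..10 cover ages 15-49; midpoints map 4,5 -> 15-24; 6,7 -> 25-34;
# 8,9,10 -> 35-49
.age_band3 <- function(age_group) {
  fifelse(age_group %in% 4:5, "15-24",
          fifelse(age_group %in% 6:7, "25-34",
                  fifelse(age_group %in% 8:10, "35-49", NA_character_)))
}

#' Regroup the 11-level income rank into 5 groups
#'
#' Deciles fold in pairs into 20% groups; medical-aid beneficiaries (rank 0)
#' join the lowest group by default.
#' @param income_rank integer vector in 0..10.
#' @param fold a length-11 integer vector mapping ranks 0..10 to groups.
#' @return integer group 1 (lowest) .. 5 (highest).
#' @export
income_group5 <- function(income_rank,
                          fold = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L)) {
  stopifnot(all(income_rank %in% 0:10))
  fold[income_rank + 1L]
}

#' Group delivery-coded claim dates into delivery events
#'
#' @param claims claim stream (`person_id`, `visit_date`, `code`).
#' @param code_sets a `code_sets` list.
#' @param min_gap minimum inter-delivery gap in days (default 168).
#' @return data.table `person_id, event_id, delivery_date, n_dates` with one
#'   row per event; `delivery_date` is the event's earliest (anchor) date.
#'   Grouping is greedy and anchored: a date joins the current event iff it is
#'   `< min_gap` days after the anchor.
#' @export
group_delivery_events <- function(claims, code_sets = default_code_sets(),
                                  min_gap = 168L) {
  claims <- as.data.table(claims)
  dcodes <- c(code_sets$delivery_vaginal, code_sets$delivery_cesarean)
  dd <- unique(claims[code_has_prefix(code, dcodes),
                      .(person_id, visit_date)])
  if (nrow(dd) == 0L)
    return(data.table(person_id = character(), event_id = integer(),
                      delivery_date = as.Date(character()),
                      n_dates = integer()))
  setorder(dd, person_id, visit_date)
  dd[, event_id := {
    anchor <- visit_date[1L]; id <- 1L; ids <- integer(.N); ids[1L] <- 1L
    if (.N > 1L) for (i in 2:.N) {
      if (as.integer(visit_date[i] - anchor) >= min_gap) {
        id <- id + 1L; anchor <- visit_date[i]
      }
      ids[i] <- id
    }
    ids
  }, by = person_id]
  dd[, .(delivery_date = min(visit_date), n_dates = .N),
     by = .(person_id, event_id)]
}

#' Pair each delivery event with its first pregnancy diagnosis
#'
#' @param events output of [group_delivery_events()].
#' @param claims claim stream.
#' @param code_sets a `code_sets` list.
#' @param windows window list (see [default_windows()]).
#' @return `events` with a `pregnancy_dx_date` column: the earliest
#'   pregnancy-coded date `D` with
#'   `delivery_date - max_gestation <= D <= delivery_date - 1` and, when the
#'   woman has an earlier event, `D >= previous delivery_date + flag_days`.
#'   Unpairable events get `NA`.
#' @export
pair_pregnancy <- function(events, claims, code_sets = default_code_sets(),
                           windows = default_windows()) {
  events <- copy(as.data.table(events))
  setorder(events, person_id, delivery_date)
  events[, prev_delivery := data.table::shift(delivery_date), by = person_id]
  preg <- unique(as.data.table(claims)[
    code_has_prefix(code, code_sets$pregnancy), .(person_id, visit_date)])
  events[, lb := delivery_date - windows$max_gestation]
  events[, ub := delivery_date - 1L]
  events[!is.na(prev_delivery),
         lb := pmax(lb, prev_delivery + windows$flag_days)]
  hit <- preg[events, on = .(person_id, visit_date >= lb, visit_date <= ub),
              .(person_id, event_id = i.event_id,
                pregnancy_dx_date = x.visit_date)]
  hit <- hit[!is.na(pregnancy_dx_date)]
  first_hit <- if (nrow(hit)) {
    hit[, .(pregnancy_dx_date = min(pregnancy_dx_date)),
        by = .(person_id, event_id)]
  } else {
    data.table(person_id = character(), event_id = integer(),
               pregnancy_dx_date = as.Date(character()))
  }
  out <- first_hit[events, on = .(person_id, event_id)]
  out[, c("lb", "ub") := NULL]
  setorder(out, person_id, delivery_date)
  out[]
}

#' Assign the delivery mode of an event
#'
#' Scans codes dated within `flag_days` of the delivery date; any cesarean
#' code wins over vaginal codes (cesarean priority); neither present gives
#' `"unidentified"`.
#'
#' @param events events table with `person_id`, `event_id`, `delivery_date`.
#' @param claims claim stream.
#' @param code_sets a `code_sets` list.
#' @param flag_days half-width of the search window (default 28).
#' @return `events` with a `mode` column in
#'   `{"cesarean", "vaginal", "unidentified"}`.
#' @export
assign_delivery_mode <- function(events, claims,
                                 code_sets = default_code_sets(),
                                 flag_days = 28L) {
  events <- copy(as.data.table(events))
  events[, mode := fifelse(
    flag_window_codes(events, claims, code_sets$delivery_cesarean,
                      c(-flag_days, flag_days)), "cesarean",
    fifelse(flag_window_codes(events, claims, code_sets$delivery_vaginal,
                              c(-flag_days, flag_days)),
            "vaginal", "unidentified"))]
  events[]
}

#' Flag events having a code from a prefix set in a delivery-relative window
#'
#' @param events events table (`person_id`, `delivery_date`).
#' @param claims claim stream.
#' @param prefixes character vector of code prefixes.
#' @param window closed day offsets relative to delivery, e.g. `c(-28, 28)`
#'   or `c(0, 28)`.
#' @return logical vector along `events` rows.
#' @export
flag_window_codes <- function(events, claims, prefixes, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  events <- as.data.table(events)
  ev <- events[, .(person_id, delivery_date,
                   lo = delivery_date + window[1], hi = delivery_date + window[2],
                   row = .I)]
  sub <- as.data.table(claims)[code_has_prefix(code, prefixes),
                               .(person_id, visit_date)]
  hit <- sub[ev, on = .(person_id, visit_date >= lo, visit_date <= hi),
             nomatch = NULL, .(row = i.row)]
  out <- logical(nrow(events))
  out[unique(hit$row)] <- TRUE
  out
}

.ledger_stages <- c("no_delivery", "age_out_of_range", "no_pregnancy_pairing",
                    "mode_unidentified", "abortion_or_stillbirth",
                    "qualification_incomplete", "no_nonpregnancy_dx_in_window")

new_exclusion_ledger <- function() {
  data.table(stage = .ledger_stages, n_excluded = 0L)
}

ledger_add <- function(ledger, stg, n) {
  i <- which(ledger$stage == stg)
  data.table::set(ledger, i, "n_excluded", ledger$n_excluded[i] + as.integer(n))
  ledger
}

#' Build delivery cases from a claims bundle
#'
#' Applies the ordered inclusion/exclusion cascade and returns one row per
#' retained delivery case together with the exclusion ledger. Stages, in
#' order: restrict to female persons with claims; group delivery events;
#' maternal age 15-49 at the delivery year; pregnancy pairing; delivery-mode
#' identification; abortion/stillbirth codes dated between the pregnancy
#' diagnosis and 4 weeks post-delivery; qualification rows present for both
#' the pregnancy-diagnosis year and the delivery year. Flags (preterm,
#' multiple gestation in a +/-4-week window; jaundice in \[delivery,
#' delivery+4wk\]) and covariates are then attached.
#'
#' @param bundle a `claims_bundle`.
#' @param code_sets a `code_sets` list.
#' @param windows window list (see [default_windows()]).
#' @return list with `cases` (data.table, one row per case: `case_id,
#'   person_id, event_id, delivery_date, pregnancy_dx_date, anc_duration,
#'   mode, preterm, multiple_gestation, jaundice, age_band, income_group`)
#'   and `ledger` (stage, n_excluded).
#' @export
build_delivery_cases <- function(bundle, code_sets = default_code_sets(),
                                 windows = default_windows()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  ledger <- new_exclusion_ledger()
  qual <- as.data.table(bundle$qualifications)
  females <- unique(qual[sex == "female", person_id])
  claims <- as.data.table(bundle$claims)[person_id %in% females]

  events <- group_delivery_events(claims, code_sets, windows$min_delivery_gap)
  n_women_claims <- length(unique(claims$person_id))
  ledger <- ledger_add(ledger, "no_delivery",
                       n_women_claims - length(unique(events$person_id)))
  if (nrow(events) == 0L)
    return(list(cases = .empty_cases(), ledger = ledger))

  # age at delivery year (from that year's qualification band, if present)
  events[, delivery_year := as.integer(format(delivery_date, "%Y"))]
  events <- qual[, .(person_id, year, age_group)][
    events, on = .(person_id, year = delivery_year)]
  setnames(events, "year", "delivery_year")
  events[, age_band := .age_band3(age_group)]
  drop <- !is.na(events$age_group) & is.na(events$age_band)
  ledger <- ledger_add(ledger, "age_out_of_range", sum(drop))
  events <- events[!drop]

  events <- pair_pregnancy(events, claims, code_sets, windows)
  drop <- is.na(events$pregnancy_dx_date)
  ledger <- ledger_add(ledger, "no_pregnancy_pairing", sum(drop))
  events <- events[!drop]

  if (nrow(events)) {
    events <- assign_delivery_mode(events, claims, code_sets,
                                   windows$flag_days)
    drop <- events$mode == "unidentified"
    ledger <- ledger_add(ledger, "mode_unidentified", sum(drop))
    events <- events[!drop]
  }

  if (nrow(events)) {
    # abortion/stillbirth codes inside the episode disqualify it; the window
    # opens at the pregnancy diagnosis so unrelated earlier pregnancies with
    # abortive outcomes do not taint this one
    ab <- as.data.table(claims)[
      code_has_prefix(code, c(code_sets$abortion, code_sets$stillbirth)),
      .(person_id, visit_date)]
    ev <- events[, .(person_id, lo = pregnancy_dx_date,
                     hi = delivery_date + windows$flag_days, row = .I)]
    hit <- ab[ev, on = .(person_id, visit_date >= lo, visit_date <= hi),
              nomatch = NULL, .(row = i.row)]
    drop <- logical(nrow(events)); drop[unique(hit$row)] <- TRUE
    ledger <- ledger_add(ledger, "abortion_or_stillbirth", sum(drop))
    events <- events[!drop]
  }

  if (nrow(events)) {
    events[, preg_year := as.integer(format(pregnancy_dx_date, "%Y"))]
    have_year <- unique(qual[, .(person_id, year)])[, have := TRUE][]
    events <- have_year[events, on = .(person_id, year = preg_year)]
    setnames(events, "year", "preg_year")
    drop <- is.na(events$have) | is.na(events$age_group)
    ledger <- ledger_add(ledger, "qualification_incomplete", sum(drop))
    events <- events[!drop][, have := NULL]
  }

  if (nrow(events) == 0L)
    return(list(cases = .empty_cases(), ledger = ledger))

  fd <- windows$flag_days
  events[, preterm := flag_window_codes(events, claims, code_sets$preterm,
                                        c(-fd, fd))]
  events[, multiple_gestation := flag_window_codes(
    events, claims, code_sets$multiple_gestation, c(-fd, fd))]
  events[, jaundice := flag_window_codes(events, claims, code_sets$jaundice,
                                         c(0L, fd))]

  inc <- qual[, .(person_id, year, income_rank)]
  events <- inc[events, on = .(person_id, year = preg_year)]
  setnames(events, "year", "preg_year")
  events[, income_group := income_group5(income_rank)]
  events[, anc_duration := as.integer(delivery_date - pregnancy_dx_date)]
  setorder(events, person_id, delivery_date)
  events[, case_id := sprintf("%s#%d", person_id, event_id)]
  cases <- events[, .(case_id, person_id, event_id, delivery_date,
                      pregnancy_dx_date, anc_duration, mode, preterm,
                      multiple_gestation, jaundice, age_band, income_group)]
  list(cases = cases, ledger = ledger)
}

.empty_cases <- function() {
  data.table(case_id = character(), person_id = character(),
             event_id = integer(), delivery_date = as.Date(character()),
             pregnancy_dx_date = as.Date(character()),
             anc_duration = integer(), mode = character(),
             preterm = logical(), multiple_gestation = logical(),
             jaundice = logical(), age_band = character(),
             income_group = integer())
}
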