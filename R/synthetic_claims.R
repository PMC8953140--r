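#' Synthetic national-sample-cohort claims generator
#'
#' @description
#' Generates the three claims tables (qualification / statement / disease)
#' with planted pregnancy-delivery episodes and a known exposure-outcome
#' structure, so the full pipeline is testable without the non-public source
#' data. The generative direction is exposure-to-jaundice: per episode,
#' exposure indicators are drawn first (optionally income-confounded), then
#' the jaundice label from a logistic model whose exposure coefficients are
#' the configured log odds ratios, with the intercept calibrated so the
#' realized jaundice fraction matches the configured base rate. Conception
#' is latent; only the first pregnancy claim (4-12 weeks after conception)
#' is observable, exactly as in the real data.
#'
#' @name synthetic_claims
NULL

#' Simulation configuration
#'
#' Defaults state a cohort of roughly 30,000 delivery episodes with a
#' realistic claims shape: gestation Normal(280, 10) days truncated to
#' \[200, 308\]; first pregnancy claim Uniform(28, 84) days after conception;
#' cesarean fraction 0.38; jaundice base rate 1.3% (mother-attached coding
#' captures only a fraction of clinical jaundice); one income-confounded
#' antenatal exposure with true OR 3 at 3% prevalence and one null exposure
#' at 10% prevalence; background noise diagnoses at 0.6 visits / 30 days.
#'
#' @param n_women number of women with episodes.
#' @param year_range observation years (claims and qualification coverage).
#' @param p_second_episode probability of a second pregnancy episode.
#' @param gestation_mean,gestation_sd,gestation_range gestation length model
#'   (days).
#' @param preg_claim_delay range (days) from conception to the first
#'   pregnancy claim.
#' @param p_cesarean,p_preterm,p_multiple delivery-mode and flag
#'   probabilities.
#' @param exposures data.frame with columns `code3, prevalence, window`
#'   (`"ANC"`, `"preB"`, or `"both"`), `true_or`, `confounded_by_income`.
#' @param jaundice_base_rate target marginal jaundice fraction.
#' @param jaundice_delay range (days) from delivery to the jaundice claim.
#' @param beta_cesarean,beta_income jaundice-model nuisance coefficients
#'   (income enters per group, centered at group 3).
#' @param income_exposure_beta logit shift per income group for confounded
#'   exposures.
#' @param noise_rate_per_30d background diagnosis rate.
#' @param n_noise_codes size of the noise code pool.
#' @param frac_male fraction of extra male persons (exercise the sex filter).
#' @param p_stillbirth_code,p_missing_qual,p_pregnancy_only
#'   exclusion-injection rates (all 0 by default: a clean world).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_women = 25000L,
                       year_range = c(2002L, 2013L),
                       p_second_episode = 0.2,
                       gestation_mean = 280, gestation_sd = 10,
                       gestation_range = c(200, 308),
                       preg_claim_delay = c(28, 84),
                       p_cesarean = 0.38, p_preterm = 0.018,
                       p_multiple = 0.015,
                       exposures = data.frame(
                         code3 = c("D25", "J00"),
                         prevalence = c(0.03, 0.10),
                         window = c("ANC", "ANC"),
                         true_or = c(3, 1),
                         confounded_by_income = c(TRUE, FALSE)),
                       jaundice_base_rate = 0.013,
                       jaundice_delay = c(0, 14),
                       beta_cesarean = log(1.6),
                       beta_income = 0.25,
                       income_exposure_beta = 0.4,
                       noise_rate_per_30d = 0.6,
                       n_noise_codes = 30L,
                       frac_male = 0.02,
                       p_stillbirth_code = 0,
                       p_missing_qual = 0,
                       p_pregnancy_only = 0) {
  cfg <- as.list(environment())
  cfg$exposures <- as.data.table(exposures)
  probs <- c(p_second_episode, p_cesarean, p_preterm, p_multiple,
             jaundice_base_rate, p_stillbirth_code, p_missing_qual,
             p_pregnancy_only, cfg$exposures$prevalence)
  stopifnot(all(probs >= 0 & probs <= 1), all(cfg$exposures$true_or > 0),
            gestation_range[2] <= 308)
  structure(cfg, class = "sim_config")
}

.band_from_age <- function(age) {
  fifelse(age == 0L, 0L, fifelse(age < 5L, 1L, age %/% 5L + 1L))
}

# calibrate the jaundice-model intercept so mean(plogis(a + eta)) = target
.calibrate_alpha <- function(eta, target) {
  if (target <= 0 || target >= 1)
    stop("infeasible jaundice_base_rate: must be in (0, 1)")
  f <- function(a) mean(stats::plogis(a + eta)) - target
  if (f(-30) > 0 || f(10) < 0)
    stop("cannot calibrate intercept for jaundice_base_rate ", target)
  stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' Generate a synthetic claims dataset with known truth
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @param emit_claims when `FALSE`, skip claim/qualification emission and
#'   return only the truth table (`bundle = NULL`). All truth fields are
#'   drawn before any claim-level randomness, so the truth is identical to an
#'   `emit_claims = TRUE` run at the same seed; used by repeated-seed
#'   simulation studies that work from [cases_from_truth()].
#' @return list with `bundle` (a `claims_bundle`) and `truth` (data.table,
#'   one row per planted episode, with planted dates, mode, flags, label,
#'   covariates, one `exp_<code>` column per configured exposure, and the
#'   injection flags; exposure configuration with realized prevalences in
#'   `attr(truth, "exposures")`).
#' @export
generate_dataset <- function(config = sim_config(), seed = 1L,
                             emit_claims = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, .generate_dataset_impl(config, emit_claims))
}

.generate_dataset_impl <- function(cfg, emit_claims = TRUE) {
  y0 <- cfg$year_range[1]; y1 <- cfg$year_range[2]
  nw <- cfg$n_women

  # --- women, covariates ---------------------------------------------------
  person_id <- sprintf("W%06d", seq_len(nw))
  income_rank <- sample(0:10, nw, replace = TRUE,
                        prob = c(0.04, rep(0.096, 10)))
  income_group <- income_group5(income_rank)
  # age at first conception: 18-42, centered on the late twenties
  age1 <- pmin(42L, pmax(18L, as.integer(round(stats::rnorm(nw, 29, 5)))))

  # --- episodes ------------------------------------------------------------
  d0 <- as.Date(sprintf("%d-01-01", y0 + 1L))
  d1 <- as.Date(sprintf("%d-12-01", y1 - 1L))
  conception1 <- d0 + sample.int(as.integer(d1 - d0), nw, replace = TRUE)
  two <- stats::runif(nw) < cfg$p_second_episode

  ep <- rbindlist(list(
    data.table(person_id, episode = 1L, conception = conception1,
               income_rank, income_group, age1),
    data.table(person_id = person_id[two], episode = 2L,
               conception = as.Date(NA), income_rank = income_rank[two],
               income_group = income_group[two], age1 = age1[two])
  ))
  n1 <- nw
  gest <- function(n) pmin(cfg$gestation_range[2],
                           pmax(cfg$gestation_range[1],
                                round(stats::rnorm(n, cfg$gestation_mean,
                                                   cfg$gestation_sd))))
  ep[episode == 1L, gestation := gest(.N)]
  ep[episode == 1L, delivery_date := conception + gestation]
  # second conception: 60-700 days after the first delivery
  first <- ep[episode == 1L, .(person_id, d1st = delivery_date)]
  ep <- first[ep, on = "person_id"]
  ep[episode == 2L, conception := d1st + sample(60:700, .N, replace = TRUE)]
  ep[episode == 2L, gestation := gest(.N)]
  ep[episode == 2L, delivery_date := conception + gestation]
  ep <- ep[delivery_date <= as.Date(sprintf("%d-12-31", y1)) -
             max(cfg$jaundice_delay)]
  ep[, d1st := NULL]

  ep[, preg_delay := sample(cfg$preg_claim_delay[1]:cfg$preg_claim_delay[2],
                            .N, replace = TRUE)]
  ep[, pregnancy_dx_date := conception + preg_delay]
  ep[, delivery_year := as.integer(format(delivery_date, "%Y"))]
  ep[, preg_year := as.integer(format(pregnancy_dx_date, "%Y"))]
  byear <- data.table(person_id,
                      birth_year = as.integer(format(conception1, "%Y")) - age1)
  ep <- byear[ep, on = "person_id"]
  ep[, age_at_delivery := delivery_year - birth_year]
  ep[, age_band5 := .band_from_age(age_at_delivery)]
  ep[, age_band := .age_band3(age_band5)]
  ep[, mode := fifelse(stats::runif(.N) < cfg$p_cesarean,
                       "cesarean", "vaginal")]
  ep[, preterm := stats::runif(.N) < cfg$p_preterm]
  ep[, multiple_gestation := stats::runif(.N) < cfg$p_multiple]
  ep[, anc_duration := as.integer(delivery_date - pregnancy_dx_date)]

  # --- exposures and jaundice label ---------------------------------------
  expo <- copy(cfg$exposures)
  eta <- numeric(nrow(ep))
  for (i in seq_len(nrow(expo))) {
    pv <- expo$prevalence[i]
    lp <- stats::qlogis(pv) +
      if (expo$confounded_by_income[i])
        cfg$income_exposure_beta * (ep$income_group - 3) else 0
    x <- stats::runif(nrow(ep)) < stats::plogis(lp)
    ep[, (paste0("exp_", expo$code3[i])) := x]
    eta <- eta + log(expo$true_or[i]) * x
    expo[i, realized_prevalence := mean(x)]
  }
  eta <- eta + cfg$beta_cesarean * (ep$mode == "cesarean") +
    cfg$beta_income * (ep$income_group - 3)
  alpha <- .calibrate_alpha(eta, cfg$jaundice_base_rate)
  ep[, jaundice := stats::runif(.N) < stats::plogis(alpha + eta)]

  # --- exclusion injections ------------------------------------------------
  ep[, injected_stillbirth := stats::runif(.N) < cfg$p_stillbirth_code]
  ep[, injected_pregnancy_only := stats::runif(.N) < cfg$p_pregnancy_only]
  ep[, injected_missing_qual := stats::runif(.N) < cfg$p_missing_qual]

  # --- truth table (complete before any claim-level randomness) -----------
  setorder(ep, person_id, episode)
  truth <- ep[, c(list(person_id = person_id, episode = episode,
                       case_id = sprintf("%s#%d", person_id, episode),
                       conception = conception,
                       pregnancy_dx_date = pregnancy_dx_date,
                       delivery_date = delivery_date,
                       anc_duration = anc_duration, mode = mode,
                       preterm = preterm,
                       multiple_gestation = multiple_gestation,
                       jaundice = jaundice, age_band = age_band,
                       income_rank = income_rank,
                       income_group = income_group,
                       injected_stillbirth = injected_stillbirth,
                       injected_pregnancy_only = injected_pregnancy_only,
                       injected_missing_qual = injected_missing_qual),
                  .SD),
              .SDcols = grep("^exp_", names(ep), value = TRUE)]
  data.table::setattr(truth, "exposures", expo[])
  data.table::setattr(truth, "alpha", alpha)
  if (!emit_claims) return(list(bundle = NULL, truth = truth))

  # --- claim emission ------------------------------------------------------
  emit <- list()
  say <- function(pid, date, code) data.table(person_id = pid,
                                              visit_date = date, code = code)
  emit$preg <- ep[, say(person_id, pregnancy_dx_date, "Z34")]
  anc_mid <- ep[anc_duration > 60]
  emit$preg2 <- anc_mid[, say(person_id, pregnancy_dx_date + 30L, "Z34")]
  emit$delivery <- ep[, say(person_id, delivery_date,
                            fifelse(mode == "cesarean", "O82", "O80"))]
  extra <- ep[stats::runif(.N) < 0.3]
  emit$delivery2 <- extra[, say(person_id, delivery_date + 1L,
                                fifelse(mode == "cesarean", "O82", "O80"))]
  emit$preterm <- ep[preterm == TRUE,
                     say(person_id, delivery_date - sample(0:14, .N, TRUE),
                         "O60")]
  emit$multi <- ep[multiple_gestation == TRUE,
                   say(person_id, delivery_date - sample(0:14, .N, TRUE),
                       "O30")]
  emit$jaundice <- ep[jaundice == TRUE,
                      say(person_id,
                          delivery_date + sample(
                            cfg$jaundice_delay[1]:cfg$jaundice_delay[2],
                            .N, TRUE),
                          "P59")]
  emit$stillbirth <- ep[injected_stillbirth == TRUE,
                        say(person_id, delivery_date + sample(0:28, .N, TRUE),
                            "Z37.1")]

  for (i in seq_len(nrow(expo))) {
    code <- expo$code3[i]; w <- expo$window[i]
    sub <- ep[get(paste0("exp_", code)) == TRUE &
                injected_pregnancy_only == FALSE]
    if (nrow(sub) == 0L) next
    if (w %in% c("ANC", "both"))
      emit[[paste0("expA", i)]] <- sub[, say(
        person_id,
        pregnancy_dx_date + sample.int(max(anc_duration), .N, TRUE) %%
          pmax(anc_duration, 1L),
        code)]
    if (w %in% c("preB", "both"))
      emit[[paste0("expB", i)]] <- sub[, say(
        person_id, pregnancy_dx_date - sample(1:365, .N, TRUE), code)]
  }

  # background noise over [pregnancy_dx - 365, delivery - 1]
  noise_pool <- sprintf("X%02d", seq_len(cfg$n_noise_codes) - 1L)
  span <- ep[, as.integer(delivery_date - (pregnancy_dx_date - 365L))]
  n_noise <- stats::rpois(nrow(ep),
                          cfg$noise_rate_per_30d * span / 30)
  idx <- rep(seq_len(nrow(ep)), n_noise)
  if (length(idx)) {
    off <- floor(stats::runif(length(idx)) * span[idx])
    noise <- data.table(
      person_id = ep$person_id[idx],
      visit_date = ep$pregnancy_dx_date[idx] - 365L + off,
      code = sample(noise_pool, length(idx), TRUE),
      keep = !(ep$injected_pregnancy_only[idx] &
                 ep$pregnancy_dx_date[idx] - 365L + off >=
                 ep$pregnancy_dx_date[idx]))
    emit$noise <- noise[keep == TRUE, .(person_id, visit_date, code)]
  }

  claims_raw <- rbindlist(emit)

  # --- extra male persons --------------------------------------------------
  nm <- round(cfg$frac_male * nw)
  male_qual <- male_claims <- NULL
  if (nm > 0) {
    mid <- sprintf("M%06d", seq_len(nm))
    male_claims <- data.table(
      person_id = mid,
      visit_date = d0 + sample.int(as.integer(d1 - d0), nm, TRUE),
      code = sample(noise_pool, nm, TRUE))
    male_age <- pmin(80L, pmax(20L, as.integer(round(stats::rnorm(nm, 40, 12)))))
    male_qual <- data.table(person_id = rep(mid, each = y1 - y0 + 1L),
                            sex = "male", year = rep(y0:y1, nm))
    male_qual[, age_group := pmin(18L, .band_from_age(
      rep(male_age, each = y1 - y0 + 1L) + year - y0))]
    male_qual[, income_rank := sample(0:10, .N, TRUE)]
    claims_raw <- rbindlist(list(claims_raw, male_claims))
  }

  # --- pack codes into statement + disease rows ---------------------------
  setorder(claims_raw, person_id, visit_date, code)
  claims_raw <- unique(claims_raw)
  claims_raw[, claim_no := sprintf("C%08d", .GRP),
             by = .(person_id, visit_date)]
  claims_raw[, slot := seq_len(.N), by = claim_no]
  claims_raw[, source := c("principal", "additional",
                           rep("disease_table", max(0L, .N - 2L)))[seq_len(.N)],
             by = claim_no]
  claims <- claims_raw[, .(person_id, claim_no, visit_date, code, source)]

  # --- qualification rows --------------------------------------------------
  qual <- data.table(person_id = rep(person_id, each = y1 - y0 + 1L),
                     sex = "female", year = rep(y0:y1, nw))
  birth_year <- as.integer(format(conception1, "%Y")) - age1
  qual[, age_group := .band_from_age(
    pmax(0L, rep(-birth_year, each = y1 - y0 + 1L) + year))]
  qual[, income_rank := rep(income_rank, each = y1 - y0 + 1L)]
  if (any(ep$injected_missing_qual)) {
    gone <- ep[injected_missing_qual == TRUE,
               .(person_id, year = delivery_year)]
    qual <- qual[!gone, on = .(person_id, year)]
  }
  if (!is.null(male_qual)) qual <- rbindlist(list(qual, male_qual))

  list(bundle = new_claims_bundle(qual, claims), truth = truth)
}

#' Reconstruct the delivery-cases table from generator truth
#'
#' Convenience for tests and pilots that exercise matching and stability
#' selection directly, without the claims round trip.
#' @param truth truth table from [generate_dataset()].
#' @return data.table shaped like [build_delivery_cases()]'s `cases`.
#' @export
cases_from_truth <- function(truth) {
  truth <- as.data.table(truth)
  truth[, .(case_id, person_id, event_id = episode, delivery_date,
            pregnancy_dx_date, anc_duration, mode, preterm,
            multiple_gestation, jaundice, age_band, income_group)]
}

#' Planted exposure profiles from generator truth
#'
#' @param truth truth table from [generate_dataset()].
#' @param study study label to stamp on the profile rows.
#' @return data.table `case_id, study, code3` restricted to the planted
#'   exposure indicators (noise and pregnancy codes are not included).
#' @export
profiles_from_truth <- function(truth, study = "A") {
  truth <- as.data.table(truth)
  cols <- grep("^exp_", names(truth), value = TRUE)
  rbindlist(lapply(cols, function(cl)
    truth[get(cl) == TRUE,
          .(case_id, study = study, code3 = sub("^exp_", "", cl))]))
}

#' Write / read the generator truth table
#'
#' TSV round trip is lossless for all columns (dates in ISO-8601).
#' @param truth truth table.
#' @param path output path.
#' @return `write_truth`: the path, invisibly; `read_truth`: the table.
#' @export
write_truth <- function(truth, path) {
  if (!nrow(truth)) stop("refusing to write an empty truth table")
  fwrite(truth, path, sep = "\t", dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- fread(path, sep = "\t", colClasses = list(character = "person_id"))
  for (col in c("conception", "pregnancy_dx_date", "delivery_date"))
    tr[, (col) := as.Date(get(col))]
  tr[]
}
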