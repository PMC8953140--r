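# Episode construction: grouping, pairing, mode, flags, cascade

cs <- default_code_sets()

test_that("delivery-event grouping is greedy, anchored, with a 168-day gap", {
  mk <- function(offsets) {
    claim_rows("P1", as.Date("2005-01-01") + offsets, rep("O80", length(offsets)))
  }
  ev <- group_delivery_events(mk(c(0, 3)), cs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$delivery_date, as.Date("2005-01-01"))
  # boundary: exactly 168 days starts a new event
  ev2 <- group_delivery_events(mk(c(0, 168)), cs)
  expect_equal(nrow(ev2), 2L)
  ev3 <- group_delivery_events(mk(c(0, 167)), cs)
  expect_equal(nrow(ev3), 1L)
  # anchored greediness: d+100 joins event(d); d+200 is >= 168 from anchor
  ev4 <- group_delivery_events(mk(c(0, 100, 200)), cs)
  expect_equal(nrow(ev4), 2L)
  expect_equal(as.integer(ev4$delivery_date - as.Date("2005-01-01")), c(0L, 200L))
  # brute-force greedy partition oracle on random date sets
  greedy_oracle <- function(offs) {
    offs <- sort(offs); anchors <- offs[1]
    for (o in offs[-1]) if (o - anchors[length(anchors)] >= 168)
      anchors <- c(anchors, o)
    anchors
  }
  set.seed(20)
  for (i in 1:25) {
    offs <- sort(sample(0:2000, sample(2:12, 1)))
    ev <- group_delivery_events(mk(offs), cs)
    expect_equal(as.integer(ev$delivery_date - as.Date("2005-01-01")),
                 greedy_oracle(offs))
  }
})

test_that("pregnancy pairing takes the earliest date inside the 308/28 rules", {
  dd <- as.Date("2005-10-01")
  mk <- function(preg_offsets, extra_delivery = NULL) {
    cl <- rbind(
      claim_rows("P1", dd, "O80"),
      claim_rows("P1", dd + preg_offsets, rep("Z34", length(preg_offsets))))
    if (!is.null(extra_delivery))
      cl <- rbind(cl, claim_rows("P1", extra_delivery, "O80"))
    ev <- group_delivery_events(cl, cs)
    pair_pregnancy(ev, cl, cs)
  }
  # simple: claim at delivery - 280
  p <- mk(-280)
  expect_equal(as.integer(dd - p$pregnancy_dx_date[1]), 280L)
  # window boundaries: -308 pairs, -309 does not; -1 pairs, 0 does not
  expect_equal(as.integer(dd - mk(-308)$pregnancy_dx_date[1]), 308L)
  expect_true(is.na(mk(-309)$pregnancy_dx_date[1]))
  expect_equal(as.integer(dd - mk(-1)$pregnancy_dx_date[1]), 1L)
  expect_true(is.na(mk(0)$pregnancy_dx_date[1]))
  # earliest valid among candidates: -310 invalid, -200 valid
  expect_equal(as.integer(dd - mk(c(-310, -200))$pregnancy_dx_date[1]), 200L)
  # inter-episode rule: pregnancy claims within 28 d of the previous
  # delivery cannot start the next episode
  prev <- dd - 250
  cl <- rbind(claim_rows("P1", c(prev, dd), c("O80", "O80")),
              claim_rows("P1", c(prev + 10, prev + 28, prev + 40),
                         rep("Z34", 3)))
  ev <- group_delivery_events(cl, cs)
  p2 <- pair_pregnancy(ev, cl, cs)
  expect_equal(p2$pregnancy_dx_date[p2$delivery_date == dd], prev + 28)
})

test_that("delivery mode: cesarean priority, O84.1 vaginal, none excluded", {
  dd <- as.Date("2006-06-01")
  mode_of <- function(codes, offs = rep(0L, length(codes))) {
    cl <- claim_rows("P1", dd + offs, codes)
    ev <- group_delivery_events(cl, cs)
    if (nrow(ev) == 0) { # no delivery codes at all: seed one far away
      cl2 <- rbind(cl, claim_rows("P1", dd, "O80"))
      ev <- group_delivery_events(cl2, cs)
    }
    assign_delivery_mode(ev, cl, cs)$mode[1]
  }
  expect_identical(mode_of(c("O80", "O82")), "cesarean")
  expect_identical(mode_of("O84.1"), "vaginal")
  expect_identical(mode_of("O84.2"), "cesarean")
  expect_identical(mode_of("O842"), "cesarean") # dotless dialect
  # codes outside +/- 28 days do not count
  cl <- rbind(claim_rows("P1", dd, "O80"), claim_rows("P1", dd + 29, "O82"))
  ev <- group_delivery_events(cl, cs)
  expect_identical(assign_delivery_mode(ev, cl, cs)$mode[1], "vaginal")
  cl2 <- rbind(claim_rows("P1", dd, "O80"), claim_rows("P1", dd + 28, "O82"))
  expect_identical(assign_delivery_mode(ev, cl2, cs)$mode[1], "cesarean")
})

test_that("window flags use closed boundaries", {
  dd <- as.Date("2006-06-01")
  ev <- data.table::data.table(person_id = "P1", event_id = 1L,
                               delivery_date = dd)
  f <- function(off, win) flag_window_codes(
    ev, claim_rows("P1", dd + off, "P59"), cs$jaundice, win)
  expect_true(f(28, c(0, 28)))
  expect_false(f(29, c(0, 28)))
  expect_false(f(-1, c(0, 28)))
  expect_true(f(-28, c(-28, 28)))
  expect_false(f(-29, c(-28, 28)))
})

test_that("the exclusion cascade is ordered, conserving, and exact", {
  qual <- rbind(qual_rows("P1", 2004:2007), qual_rows("P2", 2004:2007),
                qual_rows("P3", 2004:2007), qual_rows("P4", 2004:2007),
                qual_rows("P5", 2005), # missing pregnancy-dx year 2004
                qual_rows("P6", 2004:2007, age_group = 12L)) # age 55-59
  mk_episode <- function(pid, dd, extra = NULL) {
    cl <- rbind(claim_rows(pid, dd - 250, "Z34"),
                claim_rows(pid, dd, "O80"),
                claim_rows(pid, dd - 100, "X01"))
    if (!is.null(extra)) cl <- rbind(cl, extra)
    cl
  }
  dd <- as.Date("2005-09-01")
  claims <- rbind(
    mk_episode("P1", dd),                                   # clean, control
    mk_episode("P2", dd, claim_rows("P2", dd + 10, "P59")), # clean, jaundice
    mk_episode("P3", dd, claim_rows("P3", dd + 10, "Z37.1")), # stillbirth
    claim_rows("P4", dd, "O80"),                            # no pregnancy claim
    mk_episode("P5", dd),                                   # qual incomplete
    mk_episode("P6", dd))                                   # age out of range
  b <- make_bundle(qual, claims)
  built <- build_delivery_cases(b)
  lg <- built$ledger
  g <- function(s) lg$n_excluded[lg$stage == s]
  expect_equal(g("age_out_of_range"), 1L)
  expect_equal(g("no_pregnancy_pairing"), 1L)
  expect_equal(g("abortion_or_stillbirth"), 1L)
  expect_equal(g("qualification_incomplete"), 1L)
  expect_equal(g("mode_unidentified"), 0L)
  expect_equal(nrow(built$cases), 2L)
  expect_setequal(built$cases$case_id, c("P1#1", "P2#1"))
  expect_identical(built$cases$jaundice[built$cases$person_id == "P2"], TRUE)
  # conservation: candidate events = retained + sum(episode-level exclusions)
  n_events <- 6L
  expect_equal(nrow(built$cases) +
                 sum(lg$n_excluded[lg$stage != "no_delivery"]), n_events)
})

test_that("output is independent of claim row order", {
  sim <- generate_dataset(sim_config(n_women = 250L, p_stillbirth_code = 0.02),
                          seed = 8)
  b <- sim$bundle
  shuf <- data.table::copy(b$claims)
  set.seed(99)
  shuf <- shuf[sample(nrow(shuf))]
  b2 <- jaundiceclaims:::new_claims_bundle(b$qualifications, shuf)
  r1 <- build_delivery_cases(b)
  r2 <- build_delivery_cases(b2)
  data.table::setorder(r1$cases, case_id)
  data.table::setorder(r2$cases, case_id)
  expect_equal(as.data.frame(r1$cases), as.data.frame(r2$cases))
  expect_equal(as.data.frame(r1$ledger), as.data.frame(r2$ledger))
})

test_that("generator truth is recovered exactly when injection is off", {
  sim <- generate_dataset(sim_config(n_women = 600L), seed = 21)
  built <- build_delivery_cases(sim$bundle)
  expect_setequal(built$cases$case_id, sim$truth$case_id)
  m <- merge(built$cases, sim$truth, by = "case_id")
  for (f in c("delivery_date", "pregnancy_dx_date", "mode", "jaundice",
              "age_band", "income_group", "anc_duration", "preterm",
              "multiple_gestation"))
    expect_equal(m[[paste0(f, ".x")]], m[[paste0(f, ".y")]],
                 label = f, ignore_attr = TRUE)
  # retained case constraints
  expect_true(all(built$cases$anc_duration >= 1 &
                    built$cases$anc_duration <= 308))
})

test_that("injected stillbirth episodes are excluded and counted exactly", {
  cfg <- sim_config(n_women = 400L, p_second_episode = 0,
                    p_stillbirth_code = 0.1)
  sim <- generate_dataset(cfg, seed = 31)
  built <- build_delivery_cases(sim$bundle)
  n_sb <- sum(sim$truth$injected_stillbirth)
  lg <- built$ledger
  expect_equal(lg$n_excluded[lg$stage == "abortion_or_stillbirth"], n_sb)
  expect_equal(nrow(built$cases), nrow(sim$truth) - n_sb)
})
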