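test_that("conception date is exactly 228 days before birth, leap years respected", {
  expect_equal(conception_date(as.Date("2010-08-17")), as.Date("2010-01-01"))

  # round-trip identity over a spread of dates
  set.seed(1)
  dates <- as.Date("1990-01-01") + sample.int(15000, 50)
  expect_equal(conception_date(dates) + 228L, dates)

  # independent day-count oracle across the 2012 leap year
  d <- as.Date("2012-03-01")
  oracle <- d
  for (i in 1:228) oracle <- oracle - 1L
  expect_equal(conception_date(d), oracle)
  expect_equal(as.integer(d - conception_date(d)), 228L)

  expect_error(conception_date("not-a-date"))
})

test_that("ages use 365.25-day years and reject dates before birth", {
  rec <- make_record("A", birth = "2000-01-01")
  expect_equal(age_at(rec, as.Date("2010-01-01")), 3653 / 365.25)
  expect_equal(round(age_at(rec, as.Date("2010-01-01")), 1), 10.0)
  expect_equal(age_at(rec, as.Date("2000-01-01")), 0)
  expect_error(age_at(rec, as.Date("1999-12-31")), "precedes birth")
})

test_that("immigrant birth dates are imputed as arrival minus 13 years", {
  rec <- make_records(make_record("IMM", natality = "immigrant",
                                  birth = "1990-01-01", birth_known = FALSE,
                                  immigration = "2015-06-01",
                                  residency = res1("2015-06-01")))
  expect_equal(rec$birth_date, as.Date("2002-06-01"))
  # age at arrival is 13 to within leap-day granularity of 365.25-day years
  expect_equal(age_at(rec[1, ], as.Date("2015-06-01")), 13, tolerance = 2e-3)

  # known birth dates are never overwritten
  rec2 <- make_records(make_record("IMM2", natality = "immigrant",
                                   birth = "2001-03-15", birth_known = TRUE,
                                   immigration = "2015-06-01",
                                   residency = res1("2015-06-01")))
  expect_equal(rec2$birth_date, as.Date("2001-03-15"))
})

test_that("reproductive-age threshold is 10.5 years, boundary inclusive", {
  birth <- as.Date("2000-01-01")
  rec <- make_record("A", birth = birth)
  at_age <- function(yrs) birth + round(yrs * 365.25)
  expect_false(is_reproductively_aged(rec, at_age(10.4)))
  expect_true(is_reproductively_aged(rec, birth + ceiling(10.5 * 365.25)))
  expect_true(is_reproductively_aged(rec, at_age(45)))
})

test_that("record validation enforces residency and date invariants", {
  expect_error(make_records(make_record("A", death = "1999-01-01")),
               "death before birth")
  expect_error(make_records(
    make_record("A", residency = data.frame(start = as.Date(c("2000-01-01", "2001-06-01")),
                                            end = as.Date(c("2002-01-01", NA))))),
    "overlapping")
  expect_error(make_records(make_record("A", natality = "immigrant")),
               "immigration_date")
  expect_error(make_records(make_record("A"), make_record("A")), "duplicated")
})

test_that("philopatry rate matches the worked example and handles edge cases", {
  rec <- philopatry_fixture(36, 18)
  out <- philopatry_rate(rec, as.Date("2004-01-01"), as.Date("2018-08-01"))
  expect_equal(out$denominator, 36)
  expect_equal(out$numerator, 18)
  expect_equal(out$rate, 50)

  all_gone <- philopatry_fixture(10, 0)
  expect_equal(philopatry_rate(all_gone, as.Date("2004-01-01"),
                               as.Date("2018-08-01"))$rate, 0)

  # no eligible females: explicit undefined-rate error, not a silent zero
  none <- philopatry_fixture(5, 5)
  expect_error(philopatry_rate(none, as.Date("1990-01-01"), as.Date("1991-01-01")),
               "undefined")
})

test_that("philopatry eligibility matches a day-level brute-force scan", {
  # staggered 13th birthdays straddling the study start
  set.seed(42)
  births <- as.Date("1990-06-01") + sample.int(2500, 30)
  rows <- lapply(seq_along(births), function(i) {
    stays <- i %% 3 != 0
    emi <- if (stays) NA else add_years(births[i], 13) + 10
    make_record(sprintf("S%02d", i), birth = births[i], emigration = emi,
                residency = res1(births[i], emi))
  })
  rec <- do.call(make_records, rows)
  start <- as.Date("2004-05-15"); end <- as.Date("2006-02-10")

  # oracle: per-individual scan over every day of the window
  days <- seq(start, end, by = "day")
  eligible_oracle <- vapply(seq_len(nrow(rec)), function(i) {
    any(days == add_years(rec$birth_date[i], 13))
  }, logical(1))
  stay_oracle <- is.na(rec$emigration_date)

  got <- tryCatch(philopatry_rate(rec, start, end), error = function(e) NULL)
  if (sum(eligible_oracle) == 0) {
    expect_null(got)
  } else {
    expect_equal(got$denominator, sum(eligible_oracle))
    expect_equal(got$numerator, sum(eligible_oracle & stay_oracle))
    expect_lte(got$numerator, got$denominator)
  }
})

# six-male roster used by the potential-sire tests: conception 2010-06-01
psire_fixture <- function() {
  conc <- as.Date("2010-06-01")
  make_records(
    make_record("MOM", residency = res1("1995-01-01"), birth = "1990-01-01"),
    # resident, adult: included
    make_record("M1", sex = "male", birth = "1995-01-01",
                residency = res1("1995-01-01")),
    # residency ended 20 days before conception: excluded
    make_record("M2", sex = "male", birth = "1995-01-01",
                emigration = conc - 20, residency = res1("1995-01-01", conc - 20)),
    # residency ends 10 days before conception: inside the window, included
    make_record("M3", sex = "male", birth = "1995-01-01",
                emigration = conc - 10, residency = res1("1995-01-01", conc - 10)),
    # aged 10.4 at conception: excluded
    make_record("M4", sex = "male", birth = conc - round(10.4 * 365.25),
                residency = res1("2001-01-01")),
    # aged 10.6 at conception: included
    make_record("M5", sex = "male", birth = conc - round(10.6 * 365.25),
                residency = res1("2000-06-01")),
    # not genotyped: excluded
    make_record("M6", sex = "male", birth = "1995-01-01",
                residency = res1("1995-01-01"), genotyped = FALSE)
  )
}

test_that("potential sires respect the window, age, genotyping and actual-sire rules", {
  rec <- psire_fixture()
  conc <- as.Date("2010-06-01")
  got <- potential_sires("MOM", conc, actual_sire = "M1", rec)
  expect_equal(got, c("M3", "M5"))

  # the actual sire is excluded, never in the potential set (disjointness)
  got2 <- potential_sires("MOM", conc, actual_sire = NA, rec)
  expect_true("M1" %in% got2)
  expect_false("M1" %in% potential_sires("MOM", conc, "M1", rec))

  # mother outside the window is an inconsistent record
  expect_error(potential_sires("MOM", as.Date("1993-01-01"), NA, rec),
               "no residency inside the window")
})

test_that("potential-sire sets match a brute-force day-by-day roster oracle", {
  rec <- psire_fixture()
  conc <- as.Date("2010-06-01")
  for (w in c(0L, 5L, 15L, 40L)) {
    days <- seq(conc - w, conc + w, by = "day")
    resident_on <- function(id, d) {
      res <- rec$residency[[match(id, rec$id)]]
      any(res$start <= d & (is.na(res$end) | res$end >= d))
    }
    oracle <- sort(Filter(function(m) {
      row <- rec[rec$id == m, ]
      row$sex == "male" && row$in_genetic_dataset && m != "M1" &&
        is_reproductively_aged(row, conc) &&
        any(vapply(days, function(d) resident_on(m, d) && resident_on("MOM", d),
                   logical(1)))
    }, rec$id))
    expect_equal(potential_sires("MOM", conc, "M1", rec, window_days = w), oracle,
                 info = paste("window", w))
  }
})

test_that("shrinking the window never adds potential sires", {
  rec <- psire_fixture()
  conc <- as.Date("2010-06-01")
  prev <- NULL
  for (w in c(40L, 15L, 5L, 0L)) {
    cur <- potential_sires("MOM", conc, "M1", rec, window_days = w)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pair table has one actual row per offspring plus enumerated potential rows", {
  conc_base <- as.Date("2010-06-01")
  males <- lapply(1:5, function(i) {
    make_record(sprintf("PM%d", i), sex = "male", birth = "1995-01-01",
                residency = res1("1995-01-01"))
  })
  moms <- list(
    make_record("A1", birth = "1992-01-01", residency = res1("1992-01-01")),
    make_record("A2", birth = "1992-01-01", natality = "immigrant",
                immigration = "2006-01-01", residency = res1("2006-01-01")),
    make_record("A3", birth = "1992-01-01", natality = "unknown",
                residency = res1("1992-01-01"))
  )
  rec <- do.call(make_records, c(moms, males))
  par <- parentage_records(data.frame(
    offspring_id = c("K1", "K2", "K3"),
    mother_id = c("A1", "A2", "A3"),
    sire_id = c("PM1", "PM2", NA),
    birth_date = conc_base + 228, stringsAsFactors = FALSE
  ), rec)
  lk <- function(a, b) 0.01

  tab <- build_pair_table(par, rec, lk)
  # K3 has no known sire: contributes no rows at all
  expect_false("K3" %in% tab$offspring_id)
  # per offspring: 1 actual + brute-force enumerated potential set
  for (off in c("K1", "K2")) {
    sub <- tab[tab$offspring_id == off, ]
    sire <- par$sire_id[par$offspring_id == off]
    pot <- potential_sires(par$mother_id[par$offspring_id == off],
                           conc_base, sire, rec)
    expect_equal(nrow(sub), 1L + length(pot))
    expect_equal(sum(sub$pair_kind == "actual"), 1L)
    expect_false(sire %in% sub$male_id[sub$pair_kind == "potential"])
  }
  # natality is copied from the mother
  expect_equal(unique(tab$natality[tab$offspring_id == "K2"]), "immigrant")

  # row counts invariant under permutation of record and parentage order
  set.seed(9)
  rec_perm <- individual_records(rec[sample.int(nrow(rec)), ])
  par_perm <- par[sample.int(nrow(par)), ]
  tab2 <- build_pair_table(par_perm, rec_perm, lk)
  expect_equal(nrow(tab2), nrow(tab))
  expect_equal(sort(paste(tab2$offspring_id, tab2$male_id)),
               sort(paste(tab$offspring_id, tab$male_id)))

  # missing relatedness for a retained pair is a hard error naming the pair
  lk_na <- function(a, b) if (b == "PM3") NA else 0.01
  expect_error(build_pair_table(par, rec, lk_na), "PM3")

  # ungenotyped sire: offspring contributes no rows
  rec3 <- do.call(make_records, c(moms, males[-1], list(
    make_record("PM1", sex = "male", birth = "1995-01-01",
                residency = res1("1995-01-01"), genotyped = FALSE))))
  tab3 <- build_pair_table(par, rec3, lk)
  expect_false("K1" %in% tab3$offspring_id)
})

test_that("an offspring with an empty potential pool keeps its actual row with a warning", {
  rec <- make_records(
    make_record("MOM", residency = res1("1995-01-01"), birth = "1990-01-01"),
    make_record("DAD", sex = "male", birth = "1990-01-01",
                residency = res1("1995-01-01"))
  )
  par <- parentage_records(data.frame(
    offspring_id = "K", mother_id = "MOM", sire_id = "DAD",
    birth_date = as.Date("2011-01-15"), stringsAsFactors = FALSE
  ), rec)
  expect_warning(tab <- build_pair_table(par, rec, function(a, b) 0.25),
                 "no potential sires")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$pair_kind, "actual")
})
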