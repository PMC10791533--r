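#' Conception date from a birth date
#'
#' Gestation is taken as a fixed 228-day offset, so the conception date is
#' the estimated birth date minus 228 days (ordinary calendar arithmetic,
#' leap years respected).
#'
#' @param birth_date `Date` vector.
#' @return `Date` vector, `birth_date - 228` days.
#' @export
#' @examples
#' conception_date(as.Date("2010-08-17"))
conception_date <- function(birth_date) {
  birth_date <- as.Date(birth_date)
  if (anyNA(birth_date)) stop("conception_date: birth_date contains NA or unparseable dates")
  birth_date - 228L
}

#' Age in fractional years at a date
#'
#' Ages use 365.25-day years throughout: `age = days / 365.25`.
#'
#' @param individual a one-row individual record (see [individual_records()])
#'   or a `Date` birth date.
#' @param date `Date` at which to evaluate the age.
#' @return age in years (numeric).
#' @export
age_at <- function(individual, date) {
  birth <- if (inherits(individual, "data.frame")) {
    stopifnot(nrow(individual) == 1L)
    individual$birth_date
  } else {
    as.Date(individual)
  }
  date <- as.Date(date)
  if (anyNA(birth) || anyNA(date)) stop("age_at: missing birth date or evaluation date")
  if (any(date < birth)) {
    stop("age_at: date precedes birth date (inconsistent records): ",
         paste(format(date[date < birth]), collapse = ", "))
  }
  as.numeric(date - birth) / 365.25
}

#' Reproductive-age test
#'
#' An individual counts as reproductively aged from 10.5 years
#' (inclusive boundary), the minimum threshold derived from the earliest
#' observed ages at first conception in the study community.
#'
#' @inheritParams age_at
#' @param threshold minimum age in years (default 10.5).
#' @return logical.
#' @export
is_reproductively_aged <- function(individual, date, threshold = 10.5) {
  age_at(individual, date) >= threshold
}

#' Add whole calendar years to a date
#'
#' Feb 29 anniversaries fall on Mar 1 in non-leap years.
#' @param date `Date` vector.
#' @param years integer number of years.
#' @return `Date` vector.
#' @export
add_years <- function(date, years) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  as.Date(lt)
}

# ---- individual records ------------------------------------------------------

#' Build and validate a table of individual records
#'
#' One row per community member. `residency` is a list column; each element a
#' data.frame with `start` and `end` Date columns (`end = NA` means the
#' interval is open, i.e. the individual is still resident at the end of the
#' records). Invariants checked: intervals ordered and non-overlapping;
#' immigrants carry an immigration date equal to the start of a residency
#' interval; death never precedes birth. For immigrants whose birth date is
#' not known, the birth date is imputed as the immigration date minus 13
#' calendar years (the assumed age of immigrant females on arrival).
#'
#' @param df data.frame with columns `id`, `sex` ("female"/"male"),
#'   `birth_date`, `birth_date_known` (logical), `death_date`, `natality`
#'   ("natal"/"immigrant"/"unknown"), `immigration_date`, `emigration_date`,
#'   `residency` (list column as above), `in_genetic_dataset` (logical).
#' @return the validated data.frame, classed `individual_records`.
#' @export
individual_records <- function(df) {
  req <- c("id", "sex", "birth_date", "birth_date_known", "death_date",
           "natality", "immigration_date", "emigration_date", "residency",
           "in_genetic_dataset")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("individual_records: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("individual_records: duplicated ids")
  if (!all(df$sex %in% c("female", "male"))) stop("individual_records: sex must be female/male")
  if (!all(df$natality %in% c("natal", "immigrant", "unknown"))) {
    stop("individual_records: natality must be natal/immigrant/unknown")
  }
  for (col in c("birth_date", "death_date", "immigration_date", "emigration_date")) {
    df[[col]] <- as.Date(df[[col]])
  }

  # impute immigrant birth dates: arrival minus 13 calendar years
  imp <- df$natality == "immigrant" & !df$birth_date_known & !is.na(df$immigration_date)
  df$birth_date[imp] <- add_years(df$immigration_date[imp], -13L)

  if (any(df$natality == "immigrant" & is.na(df$immigration_date))) {
    stop("individual_records: immigrant without immigration_date: ",
         paste(df$id[df$natality == "immigrant" & is.na(df$immigration_date)], collapse = ", "))
  }
  bad_death <- !is.na(df$death_date) & df$death_date < df$birth_date
  if (any(bad_death)) {
    stop("individual_records: death before birth: ", paste(df$id[bad_death], collapse = ", "))
  }

  for (i in seq_len(nrow(df))) {
    res <- df$residency[[i]]
    if (is.null(res) || nrow(res) == 0L) {
      stop("individual_records: no residency intervals for ", df$id[i])
    }
    res$start <- as.Date(res$start)
    res$end <- as.Date(res$end)
    if (anyNA(res$start)) stop("individual_records: NA residency start for ", df$id[i])
    if (any(is.na(res$end[-nrow(res)]))) {
      stop("individual_records: only the final residency interval may be open (", df$id[i], ")")
    }
    closed <- !is.na(res$end)
    if (any(res$end[closed] < res$start[closed])) {
      stop("individual_records: residency end before start for ", df$id[i])
    }
    if (nrow(res) > 1L) {
      if (is.unsorted(res$start)) stop("individual_records: residency intervals unordered for ", df$id[i])
      if (any(res$start[-1L] <= res$end[-nrow(res)])) {
        stop("individual_records: overlapping residency intervals for ", df$id[i])
      }
    }
    if (df$natality[i] == "immigrant" && !df$immigration_date[i] %in% res$start) {
      stop("individual_records: immigration_date is not a residency start for ", df$id[i])
    }
    df$residency[[i]] <- res
  }
  class(df) <- c("individual_records", class(df))
  df
}

# days of `intervals` (data.frame start/end, NA end = open) falling inside
# [lo, hi]; returns integer vector of Dates (as integers) for set operations
.interval_days <- function(intervals, lo, hi) {
  out <- integer(0)
  for (k in seq_len(nrow(intervals))) {
    s <- max(as.integer(intervals$start[k]), as.integer(lo))
    e <- min(if (is.na(intervals$end[k])) as.integer(hi) else as.integer(intervals$end[k]),
             as.integer(hi))
    if (s <= e) out <- c(out, s:e)
  }
  unique(out)
}

.record_row <- function(records, id) {
  i <- match(id, records$id)
  if (is.na(i)) stop("unknown individual id: ", id)
  records[i, , drop = FALSE]
}

#' Female philopatry rate over a study period
#'
#' Denominator: natal females who reach their 13th birthday (the typical
#' female dispersal age) within `[study_start, study_end]`, both endpoints
#' inclusive — i.e. the birthday falls in the window and the female is alive
#' on it. Numerator: those that never emigrated — no emigration date, and any
#' terminated residency is explained by death (emigration is inferred from a
#' terminated residency without a death date). Rate is reported in percent.
#'
#' @param records an `individual_records` table.
#' @param study_start,study_end `Date` study period bounds.
#' @param dispersal_age age in calendar years defining eligibility (default 13).
#' @return list with `numerator`, `denominator`, `rate` (percent).
#' @export
philopatry_rate <- function(records, study_start, study_end, dispersal_age = 13L) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  f <- records[records$sex == "female" & records$natality == "natal", , drop = FALSE]
  bday13 <- add_years(f$birth_date, dispersal_age)
  reached <- bday13 >= study_start & bday13 <= study_end &
    (is.na(f$death_date) | f$death_date >= bday13)
  eligible <- f[reached, , drop = FALSE]
  den <- nrow(eligible)
  if (den == 0L) {
    stop("philopatry_rate: no natal females reach dispersal age in the study period; ",
         "rate is undefined")
  }
  stayed <- vapply(seq_len(den), function(i) {
    res <- eligible$residency[[i]]
    last_end <- res$end[nrow(res)]
    is.na(eligible$emigration_date[i]) &&
      (is.na(last_end) || (!is.na(eligible$death_date[i]) &&
                           last_end == eligible$death_date[i]))
  }, logical(1))
  num <- sum(stayed)
  list(numerator = num, denominator = den, rate = 100 * num / den)
}

#' Potential sires of an offspring under the random-mating null
#'
#' The potential sires for a conception are all males, other than the actual
#' sire, that (i) are in the genetic dataset, (ii) are reproductively aged
#' (>= 10.5 years) on the conception date, and (iii) co-resided with the
#' mother on at least one calendar day inside the closed window
#' `[conception - window_days, conception + window_days]`.
#'
#' @param mother_id id of the mother.
#' @param conception `Date` conception date.
#' @param actual_sire id of the known sire, or `NA`.
#' @param records an `individual_records` table.
#' @param window_days half-width of the co-residency window (default 15).
#' @return character vector of male ids (possibly empty), sorted.
#' @export
potential_sires <- function(mother_id, conception, actual_sire, records,
                            window_days = 15L) {
  conception <- as.Date(conception)
  lo <- conception - window_days
  hi <- conception + window_days
  mother <- .record_row(records, mother_id)
  mdays <- .interval_days(mother$residency[[1L]], lo, hi)
  if (length(mdays) == 0L) {
    stop("potential_sires: mother ", mother_id,
         " has no residency inside the window around ", format(conception),
         " (inconsistent parentage record)")
  }
  males <- records[records$sex == "male" & records$in_genetic_dataset, , drop = FALSE]
  if (!is.na(actual_sire)) males <- males[males$id != actual_sire, , drop = FALSE]
  keep <- vapply(seq_len(nrow(males)), function(i) {
    if (males$birth_date[i] > conception) return(FALSE)
    if (!is_reproductively_aged(males[i, ], conception)) return(FALSE)
    length(intersect(.interval_days(males$residency[[i]], lo, hi), mdays)) > 0L
  }, logical(1))
  sort(males$id[keep])
}

#' Parentage records with derived conception dates
#'
#' @param df data.frame with `offspring_id`, `mother_id`, `sire_id`
#'   (`NA` if unknown), `birth_date`.
#' @param records optional `individual_records` table for sex checks.
#' @return data.frame with an added `conception_date` column.
#' @export
parentage_records <- function(df, records = NULL) {
  req <- c("offspring_id", "mother_id", "sire_id", "birth_date")
  if (!all(req %in% names(df))) {
    stop("parentage_records: need columns ", paste(req, collapse = ", "))
  }
  df$birth_date <- as.Date(df$birth_date)
  df$conception_date <- conception_date(df$birth_date)
  if (!is.null(records)) {
    msex <- records$sex[match(df$mother_id, records$id)]
    if (any(!is.na(msex) & msex != "female")) stop("parentage_records: mother is not female")
    ssex <- records$sex[match(df$sire_id, records$id)]
    if (any(!is.na(ssex) & ssex != "male")) stop("parentage_records: sire is not male")
  }
  df
}

#' Actual and potential parent-pair table
#'
#' One *actual* row per offspring whose mother and sire are both known and in
#' the genetic dataset, plus one *potential* row for each potential sire of
#' that offspring (see [potential_sires()]). Offspring with an unknown or
#' ungenotyped parent contribute no rows at all, keeping actual and potential
#' sets balanced per offspring. The `natality` column is the mother's.
#'
#' @param parentage output of [parentage_records()].
#' @param records an `individual_records` table.
#' @param relatedness_lookup function `(id_a, id_b) -> numeric` returning the
#'   pairwise genetic relatedness, or `NA` when unavailable (which is an error
#'   for retained pairs).
#' @param window_days co-residency window half-width passed to
#'   [potential_sires()].
#' @return data.frame with columns `offspring_id`, `mother_id`, `male_id`,
#'   `pair_kind` ("actual"/"potential"), `natality`, `relatedness`.
#' @export
build_pair_table <- function(parentage, records, relatedness_lookup,
                             window_days = 15L) {
  rows <- list()
  for (i in seq_len(nrow(parentage))) {
    off <- parentage$offspring_id[i]
    mom <- parentage$mother_id[i]
    sire <- parentage$sire_id[i]
    if (is.na(sire)) next
    mrec <- .record_row(records, mom)
    srec <- .record_row(records, sire)
    if (!mrec$in_genetic_dataset || !srec$in_genetic_dataset) next
    conc <- parentage$conception_date[i]
    pot <- potential_sires(mom, conc, sire, records, window_days)
    if (length(pot) == 0L) {
      warning("build_pair_table: no potential sires for offspring ", off)
    }
    males <- c(sire, pot)
    r <- vapply(males, function(m) as.numeric(relatedness_lookup(mom, m)), numeric(1))
    if (anyNA(r)) {
      stop("build_pair_table: missing relatedness for pair(s): ",
           paste(sprintf("(%s,%s)", mom, males[is.na(r)]), collapse = ", "))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      offspring_id = off, mother_id = mom, male_id = males,
      pair_kind = c("actual", rep("potential", length(pot))),
      natality = mrec$natality, relatedness = r,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(offspring_id = character(), mother_id = character(),
                      male_id = character(), pair_kind = character(),
                      natality = character(), relatedness = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
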