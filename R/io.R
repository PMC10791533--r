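# One TSV dialect everywhere: tab-separated, '#' comments, header row,
# ISO-8601 dates, empty field = unknown/NA.

.open_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  path
}

.read_tsv <- function(path, what) {
  out <- tryCatch(
    utils::read.table(.open_read(path), sep = "\t", header = TRUE,
                      comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = "",
                      check.names = FALSE, quote = ""),
    error = function(e) stop("failed to read ", what, " file '", path, "': ",
                             conditionMessage(e)),
    warning = function(w) stop("failed to read ", what, " file '", path, "': ",
                               conditionMessage(w))
  )
  out
}

.write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.require_cols <- function(df, cols, path, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
}

.fmt_date <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))

.parse_date <- function(x, path, field) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad)) {
    stop("file '", path, "', line ", bad[1] + 1L, ", field '", field,
         "': unparseable date '", x[bad[1]], "'")
  }
  d
}

# ---- residency / demography --------------------------------------------------

#' Read and write residency/demography records
#'
#' One row per individual; residency intervals are encoded as a
#' semicolon-separated list of `start..end` items, with an open interval
#' written as `start..`.
#'
#' @param path file path (a `.gz` suffix is handled transparently).
#' @param records an [individual_records()] table (writer).
#' @return reader: an [individual_records()] table.
#' @export
read_residency <- function(path) {
  df <- .read_tsv(path, "residency")
  cols <- c("id", "sex", "birth_date", "birth_date_known", "death_date",
            "natality", "immigration_date", "emigration_date", "residency",
            "in_genetic_dataset")
  .require_cols(df, cols, path, "residency")
  res <- lapply(seq_along(df$residency), function(i) {
    s <- df$residency[i]
    if (is.na(s) || s == "") {
      stop("file '", path, "', line ", i + 1L, ": empty residency field")
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "..", fixed = TRUE)
    data.frame(
      start = .parse_date(vapply(parts, `[`, character(1), 1L), path, "residency"),
      end = .parse_date(vapply(parts, function(p)
        if (length(p) > 1L && nzchar(p[2])) p[2] else NA_character_,
        character(1)), path, "residency")
    )
  })
  individual_records(data.frame(
    id = df$id, sex = df$sex,
    birth_date = .parse_date(df$birth_date, path, "birth_date"),
    birth_date_known = as.logical(df$birth_date_known),
    death_date = .parse_date(df$death_date, path, "death_date"),
    natality = df$natality,
    immigration_date = .parse_date(df$immigration_date, path, "immigration_date"),
    emigration_date = .parse_date(df$emigration_date, path, "emigration_date"),
    residency = I(res),
    in_genetic_dataset = as.logical(df$in_genetic_dataset),
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_residency
#' @export
write_residency <- function(records, path) {
  enc <- vapply(records$residency, function(r) {
    paste(sprintf("%s..%s", format(r$start, "%Y-%m-%d"),
                  ifelse(is.na(r$end), "", format(r$end, "%Y-%m-%d"))),
          collapse = ";")
  }, character(1))
  out <- data.frame(
    id = records$id, sex = records$sex,
    birth_date = .fmt_date(records$birth_date),
    birth_date_known = records$birth_date_known,
    death_date = .fmt_date(records$death_date),
    natality = records$natality,
    immigration_date = .fmt_date(records$immigration_date),
    emigration_date = .fmt_date(records$emigration_date),
    residency = enc,
    in_genetic_dataset = records$in_genetic_dataset,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

# ---- parentage ---------------------------------------------------------------

#' Read and write parentage records
#' @param path file path.
#' @param parentage a [parentage_records()] table (writer; the derived
#'   conception date is not stored).
#' @param records optional [individual_records()] for sex validation.
#' @return reader: a [parentage_records()] table.
#' @export
read_parentage <- function(path, records = NULL) {
  df <- .read_tsv(path, "parentage")
  .require_cols(df, c("offspring_id", "mother_id", "sire_id", "birth_date"),
                path, "parentage")
  parentage_records(data.frame(
    offspring_id = df$offspring_id, mother_id = df$mother_id,
    sire_id = df$sire_id,
    birth_date = .parse_date(df$birth_date, path, "birth_date"),
    stringsAsFactors = FALSE
  ), records)
}

#' @rdname read_parentage
#' @export
write_parentage <- function(parentage, path) {
  out <- parentage[, c("offspring_id", "mother_id", "sire_id", "birth_date")]
  out$birth_date <- .fmt_date(out$birth_date)
  .write_tsv(out, path)
}

# ---- pedigree ----------------------------------------------------------------

#' Read and write a pedigree trio table
#'
#' Columns `id`, `sire`, `dam`; `0` or an empty field marks an unknown parent.
#' @param path file path.
#' @param ped a [pedigree()] (writer).
#' @return reader: a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- .read_tsv(path, "pedigree")
  .require_cols(df, c("id", "sire", "dam"), path, "pedigree")
  pedigree(df)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  tab <- ped$tab
  tab$sire[is.na(tab$sire)] <- "0"
  tab$dam[is.na(tab$dam)] <- "0"
  .write_tsv(tab, path)
}

# ---- beagle genotype likelihoods ---------------------------------------------

#' Read and write genotype likelihoods in beagle format
#'
#' Text layout: `marker`, `allele1`, `allele2`, then three likelihood columns
#' per individual (the header repeats each individual id three times). In this
#' dialect a missing site is three empty fields; triples that do not sum to
#' one are renormalized with a warning. A `.gz` suffix is handled
#' transparently.
#'
#' @param path file path.
#' @param gl a [gl_matrix()] (writer).
#' @return reader: a [gl_matrix()].
#' @export
read_beagle <- function(path) {
  df <- .read_tsv(path, "beagle genotype-likelihood")
  if (ncol(df) < 6L || (ncol(df) - 3L) %% 3L != 0L) {
    stop("beagle file '", path, "': expected 3 site columns plus 3 columns per individual")
  }
  hdr <- names(df)[-(1:3)]
  ids <- hdr[seq(1L, length(hdr), by = 3L)]
  trip <- matrix(hdr, nrow = 3L)
  if (!all(trip[1, ] == trip[2, ] & trip[2, ] == trip[3, ])) {
    stop("beagle file '", path, "': header must repeat each individual id three times")
  }
  sites <- df[[1]]
  n <- length(ids); m <- length(sites)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -(1:3), drop = FALSE])), nrow = m))
  gl <- array(NA_real_, c(n, m, 3L))
  for (i in seq_len(n)) for (g in 1:3) gl[i, , g] <- vals[, 3L * (i - 1L) + g]
  part <- matrix(is.na(gl[, , 1]), n, m) + matrix(is.na(gl[, , 2]), n, m) +
    matrix(is.na(gl[, , 3]), n, m)
  if (any(part %in% 1:2)) {
    stop("beagle file '", path, "': partially missing likelihood triple (site index ",
         which(apply(part, 2, function(x) any(x %in% 1:2)))[1], ")")
  }
  gl_matrix(ids, sites, gl, normalize = TRUE)
}

#' @rdname read_beagle
#' @export
write_beagle <- function(gl, path) {
  m <- length(gl$sites); n <- length(gl$ids)
  out <- matrix("", m, 3L * n)
  for (i in seq_len(n)) {
    for (g in 1:3) {
      v <- gl$gl[i, , g]
      out[, 3L * (i - 1L) + g] <- ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE))
    }
  }
  df <- data.frame(marker = gl$sites, allele1 = "A", allele2 = "C", out,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("marker", "allele1", "allele2", rep(gl$ids, each = 3L))
  .write_tsv(df, path)
}

# ---- allele frequencies ------------------------------------------------------

#' Read and write a two-column site/frequency table
#' @param path file path.
#' @param freqs named numeric vector (writer).
#' @return reader: named numeric vector of minor-allele frequencies.
#' @export
read_freqs <- function(path) {
  df <- .read_tsv(path, "allele-frequency")
  .require_cols(df, c("site", "maf"), path, "allele-frequency")
  maf <- suppressWarnings(as.numeric(df$maf))
  if (anyNA(maf)) {
    stop("allele-frequency file '", path, "', line ", which(is.na(maf))[1] + 1L,
         ": non-numeric maf")
  }
  stats::setNames(maf, df$site)
}

#' @rdname read_freqs
#' @export
write_freqs <- function(freqs, path) {
  .write_tsv(data.frame(site = names(freqs), maf = format(unname(freqs), digits = 10),
                        stringsAsFactors = FALSE), path)
}

# ---- pair table and relatedness table ----------------------------------------

#' Read and write the actual/potential pair table
#' @param path file path.
#' @param pairs pair table from [build_pair_table()] (writer).
#' @return reader: pair table data.frame.
#' @export
read_pairs <- function(path) {
  df <- .read_tsv(path, "pair")
  cols <- c("offspring_id", "mother_id", "male_id", "pair_kind", "natality",
            "relatedness")
  .require_cols(df, cols, path, "pair")
  df$relatedness <- as.numeric(df$relatedness)
  df
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) .write_tsv(pairs, path)

#' Read and write a relatedness table
#' @param path file path.
#' @param tab output of [relatedness_table()] (writer).
#' @return reader: relatedness table data.frame.
#' @export
read_relatedness <- function(path) {
  df <- .read_tsv(path, "relatedness")
  .require_cols(df, c("a", "b", "r"), path, "relatedness")
  for (col in setdiff(names(df), c("a", "b"))) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_relatedness
#' @export
write_relatedness <- function(tab, path) {
  out <- tab
  for (col in setdiff(names(out), c("a", "b"))) {
    out[[col]] <- format(out[[col]], digits = 10, trim = TRUE)
  }
  .write_tsv(out, path)
}
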