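#' Pipeline run configuration
#'
#' Bundles and validates every stage parameter. Unknown arguments are
#' rejected.
#'
#' @param sim a [sim_config()] describing the synthetic study (or `NULL` to
#'   read inputs from files in `outdir`; files written by a previous
#'   `simulate` stage are reused).
#' @param window_days co-residency window half-width for potential sires.
#' @param cryptic_band length-2 genetic-relatedness band flagged as cryptic
#'   relatives.
#' @param min_ind_frac,hwe_alpha,maf_min site-filter thresholds (see
#'   [site_filters()]).
#' @param priors GLMM priors, see [default_priors()].
#' @param chains,adapt,iter MCMC settings for [fit_avoidance_glmm()].
#' @param seed master seed for every stochastic stage.
#' @param outdir output directory.
#' @param ... unknown keys raise an error.
#' @return named list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), window_days = 15L,
                       cryptic_band = c(0.1, 0.35), min_ind_frac = 0.9,
                       hwe_alpha = 0.001, maf_min = 0.05,
                       priors = default_priors(), chains = 2L, adapt = 500L,
                       iter = 1500L, seed = 1L, outdir = tempfile("run"), ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("run_config: unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(length(cryptic_band) == 2L, cryptic_band[1] <= cryptic_band[2],
            min_ind_frac >= 0, min_ind_frac <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            maf_min >= 0, maf_min < 0.5, window_days >= 0)
  structure(list(sim = sim, window_days = window_days,
                 cryptic_band = cryptic_band, min_ind_frac = min_ind_frac,
                 hwe_alpha = hwe_alpha, maf_min = maf_min, priors = priors,
                 chains = chains, adapt = adapt, iter = iter, seed = seed,
                 outdir = outdir), class = "run_config")
}

#' Mother-male pairs required by the parent-pair analysis
#'
#' The unique (mother, male) pairs whose relatedness the pair table needs:
#' for each offspring with a genotyped known sire and genotyped mother, the
#' mother against the sire and against every potential sire.
#'
#' @param parentage output of [parentage_records()].
#' @param records an [individual_records()] table.
#' @param window_days co-residency window half-width (default 15).
#' @return 2-column character matrix of pairs.
#' @export
required_pairs <- function(parentage, records, window_days = 15L) {
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(parentage))) {
    mom <- parentage$mother_id[i]; sire <- parentage$sire_id[i]
    if (is.na(sire)) next
    mrec <- .record_row(records, mom); srec <- .record_row(records, sire)
    if (!mrec$in_genetic_dataset || !srec$in_genetic_dataset) next
    males <- c(sire, potential_sires(mom, parentage$conception_date[i], sire,
                                     records, window_days))
    for (m in males) {
      key <- paste0(mom, "|", m)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- c(mom, m)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (when `config$sim` is set) -> site filters (on the
#' reference panel) -> pairwise relatedness by EM -> actual/potential pair
#' table -> beta GLMM -> report. All intermediate files, the posterior draw
#' table, a table-shaped JSON report (per-natality medians, 89% intervals,
#' percent differences) and a manifest (package version, seed, input hashes)
#' are written under `config$outdir`. Any stage failure halts the run with
#' that stage's diagnostic.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the pair table, relatedness table, GLMM
#'   fit, report data.frame and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outdir, f)

  if (!is.null(config$sim)) {
    study <- simulate_study(config$sim)
    write_residency(study$records, path("residency.tsv"))
    write_parentage(study$parentage, path("parentage.tsv"))
    write_pedigree(pedigree(study$pedigree_observed), path("pedigree.tsv"))
    write_beagle(study$gl, path("gl.beagle.gz"))
    write_beagle(study$panel_gl, path("panel.beagle.gz"))
    write_freqs(study$freqs, path("freqs.tsv"))
  }
  records <- read_residency(path("residency.tsv"))
  parentage <- read_parentage(path("parentage.tsv"), records)
  gl <- read_beagle(path("gl.beagle.gz"))
  panel_gl <- read_beagle(path("panel.beagle.gz"))
  freqs <- read_freqs(path("freqs.tsv"))

  keep_sites <- site_filters(panel_gl, freqs, min_ind_frac = config$min_ind_frac,
                             hwe_alpha = config$hwe_alpha, maf_min = config$maf_min)
  if (length(keep_sites) == 0L) stop("run_pipeline: no sites pass the filters")
  gl_f <- gl_subset(gl, sites = keep_sites)
  freqs_f <- freqs[keep_sites]

  pairs_needed <- required_pairs(parentage, records, config$window_days)
  if (is.null(pairs_needed)) stop("run_pipeline: no offspring with genotyped parents")
  rel <- relatedness_table(gl_f, freqs_f, pairs = pairs_needed, seed = config$seed)
  write_relatedness(rel, path("relatedness.tsv"))

  pairs <- build_pair_table(parentage, records, relatedness_lookup(rel),
                            window_days = config$window_days)
  write_pairs(pairs, path("pairs.tsv"))

  fit <- fit_avoidance_glmm(glmm_data(pairs), priors = config$priors,
                            chains = config$chains, adapt = config$adapt,
                            iter = config$iter, seed = config$seed)
  utils::write.csv(fit$draws, path("draws.csv"), row.names = FALSE)
  report <- avoidance_report(fit)

  report_json <- list(
    interval = "89% percentile",
    predictions = report,
    diagnostics = list(rhat = as.list(fit$rhat), ess = as.list(fit$ess)),
    n_rows = nrow(pairs),
    n_actual = sum(pairs$pair_kind == "actual"),
    n_potential = sum(pairs$pair_kind == "potential")
  )
  jsonlite::write_json(report_json, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  inputs <- c("residency.tsv", "parentage.tsv", "pedigree.tsv", "gl.beagle.gz",
              "panel.beagle.gz", "freqs.tsv")
  manifest <- list(
    package = "kinavoid",
    version = as.character(utils::packageVersion("kinavoid")),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(vapply(inputs, path, character(1))))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(pairs = pairs, relatedness = rel, fit = fit, report = report,
                 outdir = config$outdir))
}
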