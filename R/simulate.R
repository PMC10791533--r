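#' Simulation configuration
#'
#' Parameters of the synthetic community generator. Defaults emulate the
#' study system: overlapping generations, female-biased but incomplete
#' dispersal (half of natal females emigrate at the typical dispersal age of
#' 13), steady immigration of 13-year-old females carrying unrecorded outside
#' ancestry, unlinked biallelic SNPs with reference-panel allele frequencies,
#' and low-coverage sequencing noise.
#'
#' @param n_founders founding community size (default 30, even sex ratio).
#' @param years simulated years (default 35).
#' @param start_date calendar start (default "1980-01-01").
#' @param p_birth annual birth probability per fertile female (default 0.25).
#' @param min_mother_age,max_mother_age female fertile ages (12 and 45).
#' @param p_female_emigration probability a natal female emigrates on
#'   reaching `dispersal_age` (default 0.5).
#' @param dispersal_age typical female dispersal age in years (default 13).
#' @param immigration_rate Poisson mean of female immigrants per year
#'   (default 1).
#' @param p_share_immigrant_parent probability a new immigrant's hidden
#'   parents are reused from an earlier immigrant, planting cryptic relatives
#'   (default 0.3).
#' @param mortality named vector of annual death probabilities for ages
#'   `<1`, `1-34`, and `>= 35`.
#' @param gamma mate-choice avoidance strength; sires are drawn with
#'   probability proportional to `exp(-gamma * pedigree relatedness)` and
#'   `gamma = 0` is uniform random mating.
#' @param n_sites number of unlinked biallelic sites (default 10000).
#' @param maf_range allele frequencies drawn Uniform over this range
#'   (default `c(0.05, 0.5)`).
#' @param depth mean sequencing depth (Poisson; default 8).
#' @param err per-base error rate (default 0.01).
#' @param panel_size reference-panel individuals for allele-frequency
#'   estimation (default 60).
#' @param panel_depth mean depth of the panel (default 12).
#' @param seed integer master seed.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 30L, years = 35L, start_date = "1980-01-01",
                       p_birth = 0.25, min_mother_age = 12, max_mother_age = 45,
                       p_female_emigration = 0.5, dispersal_age = 13L,
                       immigration_rate = 1, p_share_immigrant_parent = 0.3,
                       mortality = c(infant = 0.08, adult = 0.02, old = 0.12),
                       gamma = 0, n_sites = 10000L, maf_range = c(0.05, 0.5),
                       depth = 8, err = 0.01, panel_size = 60L,
                       panel_depth = 12, seed = 1L) {
  cfg <- list(n_founders = n_founders, years = years,
              start_date = as.Date(start_date), p_birth = p_birth,
              min_mother_age = min_mother_age, max_mother_age = max_mother_age,
              p_female_emigration = p_female_emigration,
              dispersal_age = dispersal_age, immigration_rate = immigration_rate,
              p_share_immigrant_parent = p_share_immigrant_parent,
              mortality = mortality, gamma = gamma, n_sites = n_sites,
              maf_range = maf_range, depth = depth, err = err,
              panel_size = panel_size, panel_depth = panel_depth, seed = seed)
  probs <- c(p_birth, p_female_emigration, immigration_rate = NULL,
             p_share_immigrant_parent, mortality)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must lie in [0, 1]")
  if (gamma < 0) stop("sim_config: gamma must be >= 0")
  if (n_sites < 1L) stop("sim_config: n_sites must be >= 1")
  if (err < 0 || err >= 0.5) stop("sim_config: err must lie in [0, 0.5)")
  class(cfg) <- "sim_config"
  cfg
}

#' Mate choice with inbreeding avoidance
#'
#' Draws a sire from the reproductively aged candidates with probability
#' proportional to `exp(-gamma * r)` where r is the pedigree expected
#' relatedness between the mother and each candidate. `gamma = 0` gives
#' uniform random mating; large `gamma` makes related matings vanishingly
#' rare.
#'
#' @param mother_id the mother's id.
#' @param candidate_males character vector of candidate male ids.
#' @param gamma avoidance strength, >= 0.
#' @param ped a [pedigree()] containing mother and candidates (the
#'   simulator's hidden pedigree).
#' @return the chosen sire id, or `NA_character_` if there are no candidates
#'   (no conception that cycle).
#' @export
mate_choice <- function(mother_id, candidate_males, gamma, ped) {
  if (length(candidate_males) == 0L) return(NA_character_)
  r <- vapply(candidate_males, function(m) expected_relatedness(ped, mother_id, m),
              numeric(1))
  w <- exp(-gamma * r)
  if (all(w == 0)) w <- rep(1, length(w))  # gamma effectively infinite everywhere
  candidate_males[sample.int(length(candidate_males), 1L, prob = w)]
}

#' Simulate a multi-generation community
#'
#' Annual event loop: female immigration (arrivals aged 13 carrying hidden
#' two-generation outside pedigrees, some sharing outside parents),
#' dispersal-age emigration of natal females, births with sires drawn by
#' [mate_choice()], and age-dependent mortality. Emitted records mask
#' immigrant ancestry (immigrants are pedigree founders in the observable
#' trio table) and label founding-era females as natality `unknown`.
#'
#' @param config a [sim_config()].
#' @return list with `records` ([individual_records()]), `parentage`
#'   ([parentage_records()]), `pedigree_observed` (trio data.frame with
#'   outside ancestry masked), and `truth` (hidden full pedigree including
#'   outside ancestors, true sires, natality labels, `gamma`).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_community_impl(config))
}

.simulate_community_impl <- function(cfg) {
  ind <- list()    # per-id list: sex, birth, birth_known, death, natality,
                   # imm_date, emi_date, res_start, res_end
  links <- list()  # full hidden pedigree: id -> c(sire, dam)
  n_ext <- 0L
  counter <- 0L
  new_id <- function(prefix) {
    counter <<- counter + 1L
    sprintf("%s%04d", prefix, counter)
  }

  add_ind <- function(id, sex, birth, birth_known, natality, res_start,
                      imm_date = as.Date(NA)) {
    ind[[id]] <<- list(sex = sex, birth = birth, birth_known = birth_known,
                       death = as.Date(NA), natality = natality,
                       imm_date = imm_date, emi_date = as.Date(NA),
                       res_start = res_start, res_end = as.Date(NA))
  }

  # hidden outside ancestry: an external parent pair, two generations deep
  new_external_pair <- function() {
    gp <- replicate(4, { n_ext <<- n_ext + 1L; sprintf("EXT%04d", n_ext) })
    pa <- { n_ext <<- n_ext + 1L; sprintf("EXT%04d", n_ext) }
    ma <- { n_ext <<- n_ext + 1L; sprintf("EXT%04d", n_ext) }
    for (g in gp) links[[g]] <<- c(NA_character_, NA_character_)
    links[[pa]] <<- c(gp[1], gp[2])
    links[[ma]] <<- c(gp[3], gp[4])
    c(pa, ma)
  }
  ext_pairs <- list()

  start <- cfg$start_date
  # founders: ages 5-30 at start, alternating sex
  for (k in seq_len(cfg$n_founders)) {
    id <- new_id("I")
    sex <- if (k %% 2L == 0L) "female" else "male"
    age0 <- stats::runif(1, 5, 30)
    birth <- start - round(age0 * 365.25)
    add_ind(id, sex, birth, TRUE, "unknown", start)
    links[[id]] <- c(NA_character_, NA_character_)
  }

  resident_ids <- function() names(ind)[vapply(ind, function(x) is.na(x$res_end), logical(1))]
  age_of <- function(id, date) as.numeric(date - ind[[id]]$birth) / 365.25

  for (y in seq_len(cfg$years) - 1L) {
    ystart <- add_years(start, y)
    yend <- add_years(start, y + 1L) - 1L

    # 1. immigration: females arriving at the dispersal age
    n_imm <- stats::rpois(1L, cfg$immigration_rate)
    for (k in seq_len(n_imm)) {
      id <- new_id("I")
      arrive <- ystart + sample.int(as.integer(yend - ystart) + 1L, 1L) - 1L
      birth <- add_years(arrive, -cfg$dispersal_age)
      add_ind(id, "female", birth, FALSE, "immigrant", arrive, imm_date = arrive)
      if (length(ext_pairs) > 0L &&
          stats::runif(1) < cfg$p_share_immigrant_parent) {
        parents <- ext_pairs[[sample.int(length(ext_pairs), 1L)]]
      } else {
        parents <- new_external_pair()
        ext_pairs[[length(ext_pairs) + 1L]] <- parents
      }
      links[[id]] <- parents
    }

    # 2. dispersal-age emigration of natal females
    for (id in resident_ids()) {
      x <- ind[[id]]
      if (x$sex != "female" || x$natality != "natal") next
      bday <- add_years(x$birth, cfg$dispersal_age)
      if (bday >= ystart && bday <= yend &&
          stats::runif(1) < cfg$p_female_emigration) {
        emi <- min(bday + sample.int(60L, 1L), yend)
        ind[[id]]$emi_date <- emi
        ind[[id]]$res_end <- emi
      }
    }

    # 3. births (pedigree snapshot includes this year's arrivals; newborns
    # are never mates or mothers within the year)
    ped_now <- pedigree(data.frame(
      id = names(links),
      sire = vapply(links, `[`, character(1), 1L),
      dam = vapply(links, `[`, character(1), 2L),
      stringsAsFactors = FALSE))
    for (mom in resident_ids()) {
      x <- ind[[mom]]
      if (x$sex != "female") next
      age_mid <- age_of(mom, ystart + 182L)
      if (age_mid < cfg$min_mother_age || age_mid > cfg$max_mother_age) next
      if (stats::runif(1) >= cfg$p_birth) next
      bdate <- ystart + sample.int(as.integer(yend - ystart) + 1L, 1L) - 1L
      conc <- conception_date(bdate)
      if (x$res_start > conc) next  # mother not yet resident at conception
      cand <- Filter(function(m) {
        mm <- ind[[m]]
        mm$sex == "male" && mm$res_start <= conc &&
          (is.na(mm$res_end) || mm$res_end >= conc) &&
          age_of(m, conc) >= 10.5
      }, names(ind))
      sire <- mate_choice(mom, unlist(cand), cfg$gamma, ped_now)
      if (is.na(sire)) next
      id <- new_id("I")
      sex <- if (stats::runif(1) < 0.5) "female" else "male"
      add_ind(id, sex, bdate, TRUE, "natal", bdate)
      links[[id]] <- c(sire, mom)
    }

    # 4. mortality
    for (id in resident_ids()) {
      age <- age_of(id, yend)
      p_die <- if (age < 1) cfg$mortality[["infant"]]
               else if (age < 35) cfg$mortality[["adult"]]
               else cfg$mortality[["old"]]
      if (stats::runif(1) < p_die) {
        # keep the record consistent with any birth this individual produced
        own_births <- vapply(names(links), function(c2) {
          !is.na(links[[c2]][1]) && (links[[c2]][1] == id || links[[c2]][2] == id) &&
            ind[[c2]]$birth >= ystart
        }, logical(1))
        floor_date <- max(ystart, ind[[id]]$res_start)
        if (any(own_births)) {
          floor_date <- max(floor_date,
                            max(do.call(c, lapply(names(links)[own_births],
                                                  function(c2) ind[[c2]]$birth))))
        }
        span <- as.integer(yend - floor_date)
        death <- floor_date + if (span > 0L) sample.int(span, 1L) else 0L
        ind[[id]]$death <- death
        ind[[id]]$res_end <- death
      }
    }

    if (length(resident_ids()) == 0L) {
      stop("simulate_community: population went extinct in year ", y + 1L,
           "; increase n_founders or p_birth, or reduce mortality")
    }
  }

  ids <- names(ind)
  records <- individual_records(data.frame(
    id = ids,
    sex = vapply(ind, `[[`, character(1), "sex"),
    birth_date = do.call(c, lapply(ind, `[[`, "birth")),
    birth_date_known = vapply(ind, `[[`, logical(1), "birth_known"),
    death_date = do.call(c, lapply(ind, `[[`, "death")),
    natality = vapply(ind, `[[`, character(1), "natality"),
    immigration_date = do.call(c, lapply(ind, `[[`, "imm_date")),
    emigration_date = do.call(c, lapply(ind, `[[`, "emi_date")),
    residency = I(lapply(ind, function(x) {
      data.frame(start = x$res_start, end = x$res_end)
    })),
    in_genetic_dataset = TRUE,
    stringsAsFactors = FALSE, row.names = NULL
  ))

  born <- ids[vapply(ind, function(x) x$natality == "natal", logical(1))]
  parentage <- parentage_records(data.frame(
    offspring_id = born,
    mother_id = vapply(born, function(id) links[[id]][2], character(1)),
    sire_id = vapply(born, function(id) links[[id]][1], character(1)),
    birth_date = do.call(c, lapply(born, function(id) ind[[id]]$birth)),
    stringsAsFactors = FALSE, row.names = NULL
  ), records)

  full_ped <- data.frame(id = names(links),
                         sire = vapply(links, `[`, character(1), 1L),
                         dam = vapply(links, `[`, character(1), 2L),
                         stringsAsFactors = FALSE, row.names = NULL)
  observed <- full_ped[full_ped$id %in% ids, , drop = FALSE]
  mask <- !(observed$sire %in% ids) | vapply(ind[observed$id], function(x)
    x$natality != "natal", logical(1))
  observed$sire[mask] <- NA_character_
  observed$dam[mask] <- NA_character_

  list(records = records, parentage = parentage,
       pedigree_observed = observed,
       truth = list(pedigree_full = full_ped, gamma = cfg$gamma,
                    natality = stats::setNames(
                      vapply(ind, `[[`, character(1), "natality"), ids),
                    config = cfg))
}

#' Gene dropping down a pedigree
#'
#' Founders draw genotypes Binomial(2, p) per site; each non-founder inherits
#' one allele per parent, chosen uniformly and independently across sites
#' (unlinked loci). Genotypes count copies of the minor allele.
#'
#' @param ped a [pedigree()].
#' @param freqs numeric vector of per-site minor-allele frequencies.
#' @param seed optional integer seed.
#' @return integer matrix individuals x sites (rownames = ids).
#' @export
gene_drop <- function(ped, freqs, seed = NULL) {
  .with_seed(seed, {
    n <- nrow(ped$tab)
    m <- length(freqs)
    geno <- matrix(NA_integer_, n, m, dimnames = list(ped$tab$id, NULL))
    for (i in order(ped$gen)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      geno[i, ] <- if (is.na(s) || is.na(d)) {
        stats::rbinom(m, 2L, freqs)
      } else {
        stats::rbinom(m, 1L, geno[s, ] / 2) + stats::rbinom(m, 1L, geno[d, ] / 2)
      }
    }
    geno
  })
}

#' Simulate genotype likelihoods from true genotypes
#'
#' Per individual and site: sequencing depth is Poisson(`depth`) (a depth of
#' zero marks the site missing); the minor-allele read count is
#' Binomial(depth, q) with q = `err`, 1/2, `1 - err` for genotypes 0, 1, 2;
#' the three genotype likelihoods are the binomial probabilities of the
#' observed read count, normalized to sum to one.
#'
#' @param geno integer matrix individuals x sites (0/1/2).
#' @param depth mean depth, > 0.
#' @param err per-base error rate in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @param site_ids site names (default `s1..sm`).
#' @return a [gl_matrix()].
#' @export
simulate_gls <- function(geno, depth = 8, err = 0.01, seed = NULL,
                         site_ids = NULL) {
  stopifnot(depth > 0, err >= 0, err < 0.5)
  .with_seed(seed, {
    n <- nrow(geno); m <- ncol(geno)
    ids <- rownames(geno)
    if (is.null(ids)) ids <- sprintf("i%d", seq_len(n))
    if (is.null(site_ids)) site_ids <- sprintf("s%d", seq_len(m))
    dp <- matrix(stats::rpois(n * m, depth), n, m)
    q <- c(err, 0.5, 1 - err)[geno + 1L]
    reads <- stats::rbinom(n * m, as.vector(dp), q)
    gl <- array(NA_real_, c(n, m, 3L))
    for (g in 0:2) {
      qq <- c(err, 0.5, 1 - err)[g + 1L]
      gl[, , g + 1L] <- matrix(stats::dbinom(reads, as.vector(dp), qq), n, m)
    }
    tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    for (g in 1:3) gl[, , g] <- gl[, , g] / tot
    miss <- dp == 0L
    for (g in 1:3) { slice <- gl[, , g]; slice[miss] <- NA_real_; gl[, , g] <- slice }
    gl_matrix(ids, site_ids, gl)
  })
}

#' Allele frequencies from a reference panel
#'
#' Hard-calls the maximum-likelihood genotype per panel individual and site
#' and returns the empirical minor-allele frequency, clamped strictly inside
#' (0, 1) (monomorphic-looking sites are later removed by [site_filters()]).
#'
#' @param gl [gl_matrix()] of the panel.
#' @return named numeric vector of frequencies per site.
#' @export
panel_allele_freqs <- function(gl) {
  n_site <- length(gl$sites)
  p <- vapply(seq_len(n_site), function(s) {
    m <- matrix(gl$gl[, s, ], ncol = 3L)
    ok <- !is.na(m[, 1])
    if (!any(ok)) return(NA_real_)
    g <- max.col(m[ok, , drop = FALSE], ties.method = "first") - 1L
    sum(g) / (2 * length(g))
  }, numeric(1))
  n2 <- 2 * length(gl$ids)
  p <- pmin(pmax(p, 1 / (2 * n2)), 1 - 1 / (2 * n2))
  stats::setNames(p, gl$sites)
}

#' Simulate a full study: community, genotypes, likelihoods, panel
#'
#' Orchestrates [simulate_community()], [gene_drop()] over the hidden full
#' pedigree (so unrecorded immigrant ancestry segregates in the data),
#' [simulate_gls()] for the community, and an independent unrelated reference
#' panel from the same site frequencies, whose estimated frequencies are
#' returned for downstream relatedness estimation.
#'
#' @param config a [sim_config()].
#' @return list: `records`, `parentage`, `pedigree_observed`, `gl`
#'   (community genotype likelihoods), `panel_gl`, `freqs` (panel-estimated,
#'   named), `freqs_true`, `geno` (true community genotypes), `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    com <- .simulate_community_impl(config)
    freqs_true <- stats::runif(config$n_sites, config$maf_range[1], config$maf_range[2])
    site_ids <- sprintf("s%d", seq_len(config$n_sites))
    ped_full <- pedigree(com$truth$pedigree_full)
    geno_all <- gene_drop(ped_full, freqs_true)
    ids <- com$records$id
    geno <- geno_all[ids, , drop = FALSE]
    gl <- simulate_gls(geno, depth = config$depth, err = config$err,
                       site_ids = site_ids)
    panel_geno <- matrix(stats::rbinom(config$panel_size * config$n_sites, 2L,
                                       rep(freqs_true, each = config$panel_size)),
                         config$panel_size, config$n_sites,
                         dimnames = list(sprintf("P%03d", seq_len(config$panel_size)), NULL))
    panel_gl <- simulate_gls(panel_geno, depth = config$panel_depth,
                             err = config$err, site_ids = site_ids)
    freqs <- panel_allele_freqs(panel_gl)
    c(com, list(gl = gl, panel_gl = panel_gl, freqs = freqs,
                freqs_true = stats::setNames(freqs_true, site_ids), geno = geno))
  })
}

#' Sample pedigree-labelled pairs by expected-relatedness class
#'
#' Scans all pairs of the given ids, buckets them by pedigree expected
#' relatedness, and samples up to `per_class` pairs from each requested
#' class — the labelled validation set for comparing genetic and pedigree
#' relatedness.
#'
#' @param ped a [pedigree()].
#' @param ids candidate individual ids.
#' @param classes expected-relatedness values to sample (default 0, 1/16,
#'   1/8, 1/4, 1/2).
#' @param per_class maximum pairs per class (default 60).
#' @param seed optional integer seed.
#' @param tol matching tolerance on the class value.
#' @return data.frame `a`, `b`, `expected_r`.
#' @export
sample_labelled_pairs <- function(ped, ids, classes = c(0, 0.0625, 0.125, 0.25, 0.5),
                                  per_class = 60L, seed = NULL, tol = 1e-9) {
  .with_seed(seed, {
    prs <- t(utils::combn(ids, 2L))
    er <- vapply(seq_len(nrow(prs)), function(i) {
      expected_relatedness(ped, prs[i, 1], prs[i, 2])
    }, numeric(1))
    out <- lapply(classes, function(cl) {
      hit <- which(abs(er - cl) < tol)
      if (length(hit) > per_class) hit <- sample(hit, per_class)
      if (length(hit) == 0L) return(NULL)
      data.frame(a = prs[hit, 1], b = prs[hit, 2], expected_r = er[hit],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
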