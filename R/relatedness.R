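#' Genotype-likelihood matrix
#'
#' Container for per-individual, per-site genotype likelihoods at biallelic
#' autosomal sites: three non-negative likelihoods L(data | g) for g in
#' {0, 1, 2} copies of the minor allele, normalized to sum to one. A site
#' missing in an individual (e.g. sequencing depth zero) is an all-`NA`
#' triple.
#'
#' @param ids character vector of individual ids.
#' @param sites character vector of site ids.
#' @param gl numeric array `length(ids) x length(sites) x 3`.
#' @param normalize renormalize non-missing triples (with a warning if any
#'   deviate by more than 1e-9 from unit sum).
#' @return object of class `gl_matrix`.
#' @export
gl_matrix <- function(ids, sites, gl, normalize = FALSE) {
  stopifnot(length(dim(gl)) == 3L, dim(gl)[3] == 3L,
            dim(gl)[1] == length(ids), dim(gl)[2] == length(sites))
  if (anyDuplicated(ids)) stop("gl_matrix: duplicated individual ids")
  if (anyDuplicated(sites)) stop("gl_matrix: duplicated site ids")
  miss <- is.na(gl[, , 1, drop = FALSE])[, , 1, drop = FALSE]
  if (any(gl < 0, na.rm = TRUE)) stop("gl_matrix: negative likelihood")
  sums <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  off <- abs(sums - 1) > 1e-9
  if (any(off, na.rm = TRUE)) {
    if (!normalize) {
      stop("gl_matrix: ", sum(off, na.rm = TRUE),
           " likelihood triples do not sum to 1 (tolerance 1e-9); ",
           "set normalize = TRUE to renormalize")
    }
    warning("gl_matrix: renormalized ", sum(off, na.rm = TRUE),
            " likelihood triples that did not sum to 1")
  }
  if (normalize) for (g in 1:3) gl[, , g] <- gl[, , g] / sums
  dimnames(gl) <- list(ids, sites, c("g0", "g1", "g2"))
  structure(list(ids = ids, sites = sites, gl = gl), class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("gl_matrix:", length(x$ids), "individuals x", length(x$sites), "sites;",
      round(100 * mean(is.na(x$gl[, , 1])), 1), "% missing\n")
  invisible(x)
}

#' Extract one individual's site-by-genotype likelihood matrix
#' @param gl a [gl_matrix()].
#' @param id individual id.
#' @return `n_sites x 3` matrix (rows of `NA` mark missing sites).
#' @export
gl_individual <- function(gl, id) {
  i <- match(id, gl$ids)
  if (is.na(i)) stop("gl_individual: unknown id: ", id)
  m <- gl$gl[i, , , drop = TRUE]
  dim(m) <- c(length(gl$sites), 3L)
  rownames(m) <- gl$sites
  m
}

# Per-state genotype-pair probability tables.
#
# The nine condensed identity states of the four alleles carried by a pair at
# a biallelic locus, with minor-allele frequency p (genotypes count copies of
# the minor allele). Each entry names a (g1, g2) pair and gives its
# probability under that state, obtained by drawing each distinct founder
# lineage independently from the allele frequency. Entries absent from a
# state's list have probability zero.
.jacquard_tables <- function(p) {
  q <- 1 - p
  hw <- list(q * q, 2 * p * q, p * p)
  k9 <- list()
  for (g1 in 0:2) for (g2 in 0:2) {
    k9[[paste0(g1, g2)]] <- hw[[g1 + 1]] * hw[[g2 + 1]]
  }
  list(
    # 1: all four alleles IBD
    list(`00` = q, `22` = p),
    # 2: each individual inbred, the two lineages independent
    list(`00` = q * q, `02` = p * q, `20` = p * q, `22` = p * p),
    # 3: A inbred and IBD to one of B's alleles; B's other allele free
    list(`00` = q * q, `01` = p * q, `21` = p * q, `22` = p * p),
    # 4: A inbred; B's two alleles free
    list(`00` = q * hw[[1]], `01` = q * hw[[2]], `02` = q * hw[[3]],
         `20` = p * hw[[1]], `21` = p * hw[[2]], `22` = p * hw[[3]]),
    # 5: B inbred and IBD to one of A's alleles
    list(`00` = q * q, `10` = p * q, `12` = p * q, `22` = p * p),
    # 6: B inbred; A's two alleles free
    list(`00` = hw[[1]] * q, `10` = hw[[2]] * q, `20` = hw[[3]] * q,
         `02` = hw[[1]] * p, `12` = hw[[2]] * p, `22` = hw[[3]] * p),
    # 7: two cross-pair IBD lines (A and B share both alleles)
    list(`00` = q * q, `11` = 2 * p * q, `22` = p * p),
    # 8: one cross-pair IBD line, two free alleles
    list(`00` = q^3, `01` = p * q * q, `10` = p * q * q, `11` = p * q,
         `12` = p * p * q, `21` = p * p * q, `22` = p^3),
    # 9: no IBD
    k9
  )
}

#' Genotype-pair probability under one condensed identity state
#'
#' P(g1, g2 | state k, p) for a biallelic site with minor-allele frequency p,
#' under random union of non-IBD alleles. States follow the condensed
#' Jacquard ordering: 1 = all four alleles IBD, ..., 9 = no IBD.
#'
#' @param g1,g2 genotypes, 0/1/2 copies of the minor allele.
#' @param k state, 1..9.
#' @param p minor-allele frequency in (0, 1).
#' @return probability.
#' @export
pair_genotype_prob <- function(g1, g2, k, p) {
  if (!g1 %in% 0:2 || !g2 %in% 0:2) stop("pair_genotype_prob: genotypes must be 0, 1 or 2")
  if (!k %in% 1:9) stop("pair_genotype_prob: state must be in 1..9")
  if (any(p <= 0 | p >= 1)) stop("pair_genotype_prob: p must lie strictly in (0, 1)")
  tab <- .jacquard_tables(p)[[k]]
  val <- tab[[paste0(g1, g2)]]
  if (is.null(val)) rep(0, length(p)) else val
}

# site x 9 matrix of state evidence: W[s, k] =
#   sum_{g1,g2} L_A(g1) L_B(g2) P(g1, g2 | k, p_s)
.state_weights <- function(glA, glB, p) {
  tabs <- .jacquard_tables(p)
  W <- matrix(0, nrow = length(p), ncol = 9L)
  for (k in 1:9) {
    tab <- tabs[[k]]
    for (nm in names(tab)) {
      g1 <- as.integer(substr(nm, 1, 1)); g2 <- as.integer(substr(nm, 2, 2))
      W[, k] <- W[, k] + glA[, g1 + 1L] * glB[, g2 + 1L] * tab[[nm]]
    }
  }
  W
}

.shared_sites <- function(glA, glB, p) {
  ok <- !is.na(glA[, 1]) & !is.na(glB[, 1]) & !is.na(p)
  which(ok)
}

#' Pair log-likelihood given Jacquard coefficients
#'
#' Sum over shared non-missing sites of
#' log sum_{g1,g2} L_A(g1) L_B(g2) sum_k Delta_k P(g1, g2 | k, p).
#' Sites missing in either member are skipped.
#'
#' @param glA,glB `n_sites x 3` genotype-likelihood matrices (rows of `NA`
#'   mark missing sites), e.g. from [gl_individual()].
#' @param freqs numeric vector of minor-allele frequencies per site.
#' @param delta numeric length-9 simplex of Jacquard coefficients.
#' @return log-likelihood (scalar).
#' @export
pair_loglik <- function(glA, glB, freqs, delta) {
  stopifnot(length(delta) == 9L)
  if (any(delta < -1e-12) || abs(sum(delta) - 1) > 1e-8) {
    stop("pair_loglik: delta must be a length-9 probability simplex")
  }
  keep <- .shared_sites(glA, glB, freqs)
  if (length(keep) == 0L) stop("pair_loglik: zero shared non-missing sites")
  W <- .state_weights(glA[keep, , drop = FALSE], glB[keep, , drop = FALSE], freqs[keep])
  lik <- as.numeric(W %*% delta)
  if (any(!is.finite(log(lik)))) {
    bad <- keep[!is.finite(log(lik))][1]
    stop("pair_loglik: non-finite likelihood at site index ", bad)
  }
  sum(log(lik))
}

#' Relatedness and kinship summaries of a Jacquard vector
#'
#' Kinship theta = D1 + (D3 + D5 + D7)/2 + D8/4; inbreeding
#' F_a = D1 + D2 + D3 + D4 and F_b = D1 + D2 + D5 + D6. The Hedrick-Lacy
#' relatedness normalizes kinship by the pair's mean self-kinship:
#' r = 4 theta / (2 + F_a + F_b), which stays calibrated when either
#' individual is inbred and reduces to 2 theta for outbred pairs.
#'
#' @param delta length-9 Jacquard simplex.
#' @return for `hedrick_lacy_r`, the relatedness r in `[0, 1]`; for
#'   `jacquard_summaries`, a list with `theta`, `F_a`, `F_b`, `r`.
#' @export
hedrick_lacy_r <- function(delta) {
  jacquard_summaries(delta)$r
}

#' @rdname hedrick_lacy_r
#' @export
jacquard_summaries <- function(delta) {
  stopifnot(length(delta) == 9L)
  theta <- delta[1] + 0.5 * (delta[3] + delta[5] + delta[7]) + 0.25 * delta[8]
  F_a <- delta[1] + delta[2] + delta[3] + delta[4]
  F_b <- delta[1] + delta[2] + delta[5] + delta[6]
  list(theta = theta, F_a = F_a, F_b = F_b, r = 4 * theta / (2 + F_a + F_b))
}

# index permutation swapping the roles of the two individuals (D3<->D5, D4<->D6)
.delta_swap <- c(1L, 2L, 5L, 6L, 3L, 4L, 7L, 8L, 9L)

# run expr with a temporary RNG state seeded by `seed` (NULL = use current RNG)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Maximum-likelihood Jacquard coefficients by EM
#'
#' Fits the nine-component mixture over condensed identity states to a pair's
#' genotype likelihoods. E-step: per-site posterior over states; M-step:
#' average of the posteriors. The log-likelihood is non-decreasing every
#' iteration; iteration stops when its change drops below `tol` or after
#' `max_iter` iterations. The per-site likelihood is linear in the simplex,
#' so the log-likelihood is concave and EM converges to the global optimum
#' from any interior start; by default it runs once from the simplex
#' barycentre. `n_restarts` extra random interior starts (each symmetrized
#' over the pair-swap permutation so estimates for (A, B) and (B, A) stay
#' mirror images) are available as a numerical cross-check.
#'
#' @inheritParams pair_loglik
#' @param tol convergence tolerance on the log-likelihood change (default 1e-6).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param seed integer seed for the random restarts (`NULL` = current RNG).
#' @param n_restarts extra random starts beyond the barycentre (default 0;
#'   the objective is concave, so restarts only re-verify the optimum).
#' @param ids length-2 character vector naming the pair.
#' @return object of class `relatedness_estimate`: `ids`, `delta` (named
#'   D1..D9), `theta`, `F_a`, `F_b`, `r`, `n_sites`, `loglik`, `trace`
#'   (per-iteration log-likelihoods of the winning start), `converged`.
#' @export
em_estimate <- function(glA, glB, freqs, tol = 1e-6, max_iter = 500L,
                        seed = NULL, n_restarts = 0L, ids = c("A", "B")) {
  keep <- .shared_sites(glA, glB, freqs)
  if (length(keep) == 0L) stop("em_estimate: zero shared non-missing sites")
  if (length(keep) < 100L) {
    warning("em_estimate: only ", length(keep),
            " shared sites; estimates may be unstable (>= 100 recommended)")
  }
  W <- .state_weights(glA[keep, , drop = FALSE], glB[keep, , drop = FALSE], freqs[keep])
  if (any(rowSums(W) <= 0) || any(!is.finite(W))) {
    stop("em_estimate: non-finite or zero likelihood at site index ",
         keep[which(rowSums(W) <= 0 | !is.finite(rowSums(W)))[1]])
  }

  starts <- list(rep(1 / 9, 9))
  if (n_restarts > 0L) {
    extra <- .with_seed(seed, lapply(seq_len(n_restarts), function(i) {
      d <- stats::rexp(9); d <- d / sum(d)
      (d + d[.delta_swap]) / 2  # pair-swap symmetric start
    }))
    starts <- c(starts, extra)
  }

  # E-step responsibilities never need materializing: with lik = W delta,
  # the M-step average of per-site posteriors is delta * t(W) (1/lik) / n
  n_sites_kept <- nrow(W)
  run_em <- function(delta) {
    trace <- numeric(max_iter)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lik <- as.numeric(W %*% delta)
      ll <- sum(log(lik))
      trace[it] <- ll
      if (!is.finite(ll)) stop("em_estimate: non-finite log-likelihood during EM")
      if (it > 1L && abs(ll - ll_old) < tol) {
        return(list(delta = delta, loglik = ll, trace = trace[seq_len(it)],
                    converged = TRUE))
      }
      ll_old <- ll
      delta <- delta * as.numeric(crossprod(W, 1 / lik)) / n_sites_kept
    }
    list(delta = delta, loglik = ll_old, trace = trace, converged = FALSE)
  }

  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  s <- jacquard_summaries(best$delta)
  structure(list(ids = ids,
                 delta = stats::setNames(best$delta, paste0("D", 1:9)),
                 theta = s$theta, F_a = s$F_a, F_b = s$F_b, r = s$r,
                 n_sites = length(keep), loglik = best$loglik,
                 trace = best$trace, converged = best$converged),
            class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat(sprintf("pair (%s, %s): r = %.4f, theta = %.4f, F = (%.3f, %.3f), %d sites, loglik %.2f\n",
              x$ids[1], x$ids[2], x$r, x$theta, x$F_a, x$F_b, x$n_sites, x$loglik))
  invisible(x)
}

#' Pairwise relatedness table for many pairs
#'
#' Runs [em_estimate()] for each requested pair of individuals in a
#' [gl_matrix()] and collects the results.
#'
#' @param gl a [gl_matrix()].
#' @param freqs named numeric vector of minor-allele frequencies (names =
#'   site ids) or a data.frame with columns `site`, `maf`.
#' @param pairs 2-column character matrix/data.frame of pairs, or `NULL` for
#'   all unordered pairs of `gl$ids`.
#' @param ... passed to [em_estimate()].
#' @return data.frame with columns `a`, `b`, `n_sites`, `D1`..`D9`, `theta`,
#'   `F_a`, `F_b`, `r`, `loglik`.
#' @export
relatedness_table <- function(gl, freqs, pairs = NULL, ...) {
  if (is.data.frame(freqs)) freqs <- stats::setNames(freqs$maf, freqs$site)
  p <- unname(freqs[gl$sites])
  if (anyNA(p)) stop("relatedness_table: allele frequencies missing for some sites")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(gl$ids, 2L))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  ind_gl <- lapply(gl$ids, function(id) gl_individual(gl, id))
  names(ind_gl) <- gl$ids
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    est <- em_estimate(ind_gl[[a]], ind_gl[[b]], p, ids = c(a, b), ...)
    data.frame(a = a, b = b, n_sites = est$n_sites,
               as.list(est$delta), theta = est$theta,
               F_a = est$F_a, F_b = est$F_b, r = est$r, loglik = est$loglik,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relatedness lookup closure from a relatedness table
#'
#' @param tab output of [relatedness_table()] (or any data.frame with
#'   columns `a`, `b`, `r`).
#' @return function `(id_a, id_b) -> r` (symmetric; `NA` if the pair is absent).
#' @export
relatedness_lookup <- function(tab) {
  key <- function(a, b) ifelse(a <= b, paste0(a, "|", b), paste0(b, "|", a))
  map <- stats::setNames(tab$r, key(tab$a, tab$b))
  function(id_a, id_b) {
    v <- map[key(id_a, id_b)]
    unname(v)
  }
}

#' Site filters: missingness, Hardy-Weinberg, minor-allele frequency
#'
#' Applied to the reference-panel individuals only. A site is retained when
#' (i) the fraction of panel individuals with data is at least
#' `min_ind_frac`, (ii) a 1-df likelihood-ratio test of Hardy-Weinberg
#' equilibrium on hard-called genotype counts does not reject at
#' `hwe_alpha` (retain p >= `hwe_alpha`), and (iii) the minor-allele
#' frequency is at least `maf_min` (monomorphic sites are removed).
#'
#' @param gl [gl_matrix()] of the reference panel.
#' @param freqs named frequency vector or `site`/`maf` data.frame.
#' @param min_ind_frac minimum non-missing fraction (default 0.9).
#' @param hwe_alpha HWE rejection threshold (default 0.001).
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @return character vector of retained site ids.
#' @export
site_filters <- function(gl, freqs, min_ind_frac = 0.9, hwe_alpha = 0.001,
                         maf_min = 0.05) {
  if (is.data.frame(freqs)) freqs <- stats::setNames(freqs$maf, freqs$site)
  p <- unname(freqs[gl$sites])
  n_ind <- length(gl$ids)
  miss <- is.na(gl$gl[, , 1, drop = FALSE])[, , 1]
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = n_ind)
  nonmiss_frac <- 1 - colSums(miss) / n_ind

  maf <- pmin(p, 1 - p)
  keep <- nonmiss_frac >= min_ind_frac & !is.na(maf) & maf >= maf_min

  hwe_p <- rep(NA_real_, length(gl$sites))
  for (s in which(keep)) {
    g <- max.col(matrix(gl$gl[, s, ], ncol = 3L), ties.method = "first") - 1L
    g <- g[!miss[, s]]
    n <- length(g)
    if (n == 0L) { keep[s] <- FALSE; next }
    counts <- tabulate(g + 1L, 3L)
    phat <- (2 * counts[3] + counts[2]) / (2 * n)
    exp_p <- c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    l_hwe <- sum(counts[counts > 0] * log(exp_p[counts > 0]))
    l_sat <- sum(counts[counts > 0] * log(counts[counts > 0] / n))
    lrt <- max(0, 2 * (l_sat - l_hwe))
    hwe_p[s] <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  }
  keep <- keep & !is.na(hwe_p) & hwe_p >= hwe_alpha
  gl$sites[keep]
}

#' Validate genetic relatedness against the pedigree
#'
#' Ordinary least squares of genetic relatedness estimates on pedigree
#' expected relatedness over pairs present in the pedigree, as used to check
#' estimator calibration against known relatives.
#'
#' @param estimates data.frame with columns `a`, `b`, `r` (e.g. from
#'   [relatedness_table()]).
#' @param ped a [pedigree()] containing the pair members.
#' @return list with `r_squared`, `slope`, `intercept`, `n_pairs`, and the
#'   per-pair `data` (genetic and expected relatedness).
#' @export
validate_against_pedigree <- function(estimates, ped) {
  keep <- estimates$a %in% ped$tab$id & estimates$b %in% ped$tab$id
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) < 3L) stop("validate_against_pedigree: need >= 3 pairs with pedigree records")
  expected <- vapply(seq_len(nrow(est)), function(i) {
    expected_relatedness(ped, est$a[i], est$b[i])
  }, numeric(1))
  fit <- stats::lm(est$r ~ expected)
  sst <- sum((est$r - mean(est$r))^2)
  # summary.lm warns on exact fits; R^2 is still well-defined there
  r2 <- if (sst == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  list(r_squared = r2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_pairs = nrow(est),
       data = data.frame(a = est$a, b = est$b, genetic_r = est$r,
                         pedigree_r = expected, stringsAsFactors = FALSE))
}

#' Subset a genotype-likelihood matrix
#'
#' @param gl a [gl_matrix()].
#' @param sites site ids to keep (default all).
#' @param ids individual ids to keep (default all).
#' @return a [gl_matrix()] restricted to the requested sites/individuals.
#' @export
gl_subset <- function(gl, sites = NULL, ids = NULL) {
  if (is.null(sites)) sites <- gl$sites
  if (is.null(ids)) ids <- gl$ids
  si <- match(sites, gl$sites)
  ii <- match(ids, gl$ids)
  if (anyNA(si)) stop("gl_subset: unknown site id(s)")
  if (anyNA(ii)) stop("gl_subset: unknown individual id(s)")
  gl_matrix(ids, sites, gl$gl[ii, si, , drop = FALSE])
}
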