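test_that("gl_matrix validates shape, normalization and missingness", {
  gl <- array(rep(c(0.9, 0.08, 0.02), each = 4), c(2, 2, 3))
  m <- gl_matrix(c("a", "b"), c("s1", "s2"), gl)
  expect_s3_class(m, "gl_matrix")
  expect_equal(dim(gl_individual(m, "a")), c(2L, 3L))

  bad <- gl; bad[1, 1, ] <- c(0.5, 0.4, 0.2)
  expect_error(gl_matrix(c("a", "b"), c("s1", "s2"), bad), "sum to 1")
  expect_warning(gl_matrix(c("a", "b"), c("s1", "s2"), bad, normalize = TRUE),
                 "renormalized")
  neg <- gl; neg[1, 1, 1] <- -0.1
  expect_error(gl_matrix(c("a", "b"), c("s1", "s2"), neg), "negative")
})

test_that("state genotype-pair probabilities are proper and match closed forms", {
  for (p in c(0.1, 0.3, 0.5)) {
    for (k in 1:9) {
      tot <- sum(vapply(0:2, function(g1) sum(vapply(0:2, function(g2)
        pair_genotype_prob(g1, g2, k, p), numeric(1))), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12, info = paste("state", k, "p", p))
    }
    q <- 1 - p
    # no IBD factorizes into Hardy-Weinberg margins
    expect_equal(pair_genotype_prob(1, 1, 9, p), (2 * p * q)^2)
    # all four alleles IBD: one founder lineage, discordant pairs impossible
    expect_equal(pair_genotype_prob(2, 2, 1, p), p)
    expect_equal(pair_genotype_prob(0, 0, 1, p), q)
    expect_equal(pair_genotype_prob(2, 0, 1, p), 0)
    expect_equal(pair_genotype_prob(1, 1, 1, p), 0)
  }
  expect_error(pair_genotype_prob(3, 0, 1, 0.5), "genotypes")
  expect_error(pair_genotype_prob(0, 0, 10, 0.5), "state")
  expect_error(pair_genotype_prob(0, 0, 1, 0), "strictly")
})

test_that("every state's table matches the lineage-enumeration oracle exactly", {
  for (k in 1:9) for (g1 in 0:2) for (g2 in 0:2) for (p in c(0.15, 0.3, 0.45)) {
    expect_equal(pair_genotype_prob(g1, g2, k, p), oracle_state_prob(g1, g2, k, p),
                 tolerance = 1e-12, info = paste(k, g1, g2, p))
  }
})

test_that("state tables agree with a Monte-Carlo allele-drawing oracle", {
  set.seed(99)
  p <- 0.3
  n_draws <- 1e6
  for (k in c(1, 3, 7, 8, 9)) {
    emp <- oracle_state_mc(k, p, n_draws)
    for (g1 in 0:2) for (g2 in 0:2) {
      theo <- pair_genotype_prob(g1, g2, k, p)
      se <- sqrt(theo * (1 - theo) / n_draws)
      expect_lt(abs(emp[g1 + 1, g2 + 1] - theo), max(3 * se, 1e-5))
    }
  }
})

test_that("pair log-likelihood reduces to independence and matches brute force", {
  set.seed(11)
  p <- runif(100, 0.1, 0.45)
  gA <- rbinom(100, 2, p); gB <- rbinom(100, 2, p)
  glA <- hard_gl(gA); glB <- hard_gl(gB)

  # no-IBD coefficients: product of Hardy-Weinberg margins
  d9 <- c(rep(0, 8), 1)
  hwe <- function(g, p) ifelse(g == 0, (1 - p)^2, ifelse(g == 1, 2 * p * (1 - p), p^2))
  expect_equal(pair_loglik(glA, glB, p, d9),
               sum(log(hwe(gA, p)) + log(hwe(gB, p))), tolerance = 1e-10)

  # uniform likelihoods carry no identity information
  u <- matrix(1 / 3, 1, 3)
  d_po <- c(0, 0, 0, 0, 0, 0, 0, 1, 0)
  expect_equal(pair_loglik(u, u, 0.3, d9), pair_loglik(u, u, 0.3, d_po),
               tolerance = 1e-12)

  # brute-force nested-loop oracle on noisy likelihoods
  set.seed(12)
  glA2 <- matrix(runif(300), 100, 3); glA2 <- glA2 / rowSums(glA2)
  glB2 <- matrix(runif(300), 100, 3); glB2 <- glB2 / rowSums(glB2)
  delta <- c(0.05, 0.05, 0.1, 0.1, 0.1, 0.1, 0.2, 0.2, 0.1)
  oracle <- 0
  for (s in 1:100) {
    site <- 0
    for (g1 in 0:2) for (g2 in 0:2) for (k in 1:9) {
      site <- site + glA2[s, g1 + 1] * glB2[s, g2 + 1] * delta[k] *
        oracle_state_prob(g1, g2, k, p[s])
    }
    oracle <- oracle + log(site)
  }
  expect_equal(pair_loglik(glA2, glB2, p, delta), oracle, tolerance = 1e-10)

  expect_error(pair_loglik(glA, glB, p, rep(0.2, 9)), "simplex")
  miss <- glA; miss[, ] <- NA
  expect_error(pair_loglik(miss, glB, p, d9), "zero shared")
})

test_that("Hedrick-Lacy relatedness matches closed forms including inbred limits", {
  d <- function(...) { v <- rep(0, 9); args <- list(...)
    for (nm in names(args)) v[as.integer(sub("D", "", nm))] <- args[[nm]]; v }
  expect_equal(hedrick_lacy_r(d(D8 = 1)), 0.5)                  # parent-offspring
  expect_equal(hedrick_lacy_r(d(D7 = 0.25, D8 = 0.5, D9 = 0.25)), 0.5)  # full sibs
  expect_equal(hedrick_lacy_r(d(D9 = 1)), 0)                    # unrelated
  expect_equal(hedrick_lacy_r(d(D1 = 1)), 1)                    # identical inbred lineage
  s <- jacquard_summaries(d(D1 = 1))
  expect_equal(s$theta, 1); expect_equal(s$F_a, 1); expect_equal(s$F_b, 1)
})

test_that("EM on certain genotypes matches the independent hard-call oracle to 1e-6", {
  set.seed(31)
  for (rep in 1:3) {
    p <- runif(400, 0.1, 0.45)
    # related pair: share one parental draw at ~half the sites
    shared <- rbinom(400, 1, p)
    gA <- shared + rbinom(400, 1, p)
    gB <- shared + rbinom(400, 1, p)
    # same start and stopping rule on both sides so the comparison isolates
    # the likelihood computation, which the oracle builds by lineage
    # enumeration and plain loops
    est <- em_estimate(hard_gl(gA), hard_gl(gB), p, n_restarts = 0,
                       tol = 1e-9, max_iter = 3000)
    oracle <- oracle_hard_em(gA, gB, p, tol = 1e-9, max_iter = 3000)
    expect_equal(est$r, oracle$r, tolerance = 1e-6)
    expect_equal(unname(est$delta), oracle$delta, tolerance = 1e-6)
    expect_equal(est$loglik, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is monotone non-decreasing at every iteration", {
  set.seed(41)
  p <- runif(500, 0.1, 0.45)
  shared <- rbinom(500, 1, p)
  gA <- shared + rbinom(500, 1, p); gB <- shared + rbinom(500, 1, p)
  gls <- simulate_gls(rbind(A = gA, B = gB), depth = 6, err = 0.02, seed = 42)
  est <- em_estimate(gl_individual(gls, "A"), gl_individual(gls, "B"), p, seed = 43)
  expect_true(all(diff(est$trace) >= -1e-8))
  expect_gt(length(est$trace), 3)
})

test_that("estimates are symmetric in pair order, with D3/D5 and D4/D6 swapped", {
  set.seed(51)
  p <- runif(600, 0.1, 0.45)
  shared <- rbinom(600, 1, p)
  gA <- shared + rbinom(600, 1, p); gB <- shared + rbinom(600, 1, p)
  gls <- simulate_gls(rbind(A = gA, B = gB), depth = 8, err = 0.01, seed = 52)
  mA <- gl_individual(gls, "A"); mB <- gl_individual(gls, "B")
  ab <- em_estimate(mA, mB, p, seed = 7)
  ba <- em_estimate(mB, mA, p, seed = 7)
  expect_equal(ab$r, ba$r, tolerance = 1e-8)
  swap <- c(1, 2, 5, 6, 3, 4, 7, 8, 9)
  expect_equal(unname(ab$delta), unname(ba$delta[swap]), tolerance = 1e-8)
  expect_equal(ab$F_a, ba$F_b, tolerance = 1e-8)
})

test_that("estimates are invariant to relabelling the minor allele", {
  set.seed(61)
  p <- runif(500, 0.1, 0.45)
  shared <- rbinom(500, 1, p)
  gA <- shared + rbinom(500, 1, p); gB <- shared + rbinom(500, 1, p)
  gls <- simulate_gls(rbind(A = gA, B = gB), depth = 8, err = 0.01, seed = 62)
  mA <- gl_individual(gls, "A"); mB <- gl_individual(gls, "B")
  est <- em_estimate(mA, mB, p, seed = 7)
  est_flip <- em_estimate(mA[, 3:1], mB[, 3:1], 1 - p, seed = 7)
  expect_equal(est$r, est_flip$r, tolerance = 1e-8)
  expect_equal(unname(est$delta), unname(est_flip$delta), tolerance = 1e-7)
})

test_that("genotype-likelihood estimates converge to hard-call estimates as noise vanishes", {
  set.seed(71)
  p <- runif(800, 0.1, 0.45)
  shared <- rbinom(800, 1, p)
  gA <- shared + rbinom(800, 1, p); gB <- shared + rbinom(800, 1, p)
  hard <- em_estimate(hard_gl(gA), hard_gl(gB), p, n_restarts = 0)
  gls <- simulate_gls(rbind(A = gA, B = gB), depth = 60, err = 1e-4, seed = 72)
  soft <- em_estimate(gl_individual(gls, "A"), gl_individual(gls, "B"), p,
                      n_restarts = 0)
  expect_equal(soft$r, hard$r, tolerance = 5e-3)
})

test_that("parent-offspring and unrelated pairs are recovered from noisy likelihoods", {
  set.seed(81)
  n_rep <- 12
  r_po <- numeric(n_rep); r_un <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    p <- runif(5000, 0.05, 0.5)
    ped <- pedigree(data.frame(id = c("M", "D", "O"), sire = c(NA, NA, "D"),
                               dam = c(NA, NA, "M")))
    g <- gene_drop(ped, p, seed = 100 + i)
    gls <- simulate_gls(g, depth = 10, err = 0.01, seed = 200 + i)
    po <- em_estimate(gl_individual(gls, "M"), gl_individual(gls, "O"), p,
                      seed = 300 + i)
    un <- em_estimate(gl_individual(gls, "M"), gl_individual(gls, "D"), p,
                      seed = 400 + i)
    r_po[i] <- po$r; r_un[i] <- un$r
    expect_gt(po$delta["D8"], 0.8)  # parent-offspring: one shared allele everywhere
  }
  expect_lt(abs(mean(r_po) - 0.5), 0.05)
  expect_lt(mean(r_un), 0.05)
})

test_that("estimator bias on unrelated pairs is small at high site counts", {
  # 50 unrelated pairs at 20k sites, depth 8: the mean estimate (the noise
  # floor from the boundary at r = 0) stays below 0.02
  set.seed(121)
  n_pairs <- 50L
  p <- runif(20000, 0.05, 0.5)
  geno <- matrix(rbinom(2L * n_pairs * length(p), 2L, rep(p, each = 2L * n_pairs)),
                 2L * n_pairs, length(p))
  gls <- simulate_gls(geno, depth = 8, err = 0.01, seed = 122)
  r_un <- vapply(seq_len(n_pairs), function(i) {
    em_estimate(gl_individual(gls, sprintf("i%d", 2L * i - 1L)),
                gl_individual(gls, sprintf("i%d", 2L * i)), p)$r
  }, numeric(1))
  expect_lt(mean(r_un), 0.02)
})

test_that("few shared sites warn and zero shared sites error", {
  p <- runif(50, 0.1, 0.4)
  g <- rbinom(50, 2, p)
  expect_warning(em_estimate(hard_gl(g), hard_gl(g), p, n_restarts = 0),
                 "shared sites")
  empty <- matrix(NA_real_, 50, 3)
  expect_error(em_estimate(empty, hard_gl(g), p), "zero shared")
})

test_that("site filters enforce missingness, Hardy-Weinberg and MAF thresholds", {
  set.seed(91)
  n_ind <- 40; n_site <- 200
  p <- runif(n_site, 0.02, 0.5)
  geno <- matrix(rbinom(n_ind * n_site, 2, rep(p, each = n_ind)), n_ind, n_site,
                 dimnames = list(sprintf("P%02d", 1:n_ind), NULL))
  # plant violations: HWE-violating sites (all hets), a monomorphic site,
  # and a high-missingness site
  geno[, 5] <- 1L                      # extreme heterozygote excess
  geno[, 6] <- ifelse(seq_len(n_ind) %% 2 == 0, 0L, 2L)  # het deficit
  geno[, 7] <- 0L                      # monomorphic
  p[7] <- 1e-6
  gls <- simulate_gls(geno, depth = 30, err = 0.001, seed = 92)
  # site 8: force missing in 30% of individuals
  gls$gl[1:12, 8, ] <- NA_real_
  freqs <- stats::setNames(p, gls$sites)

  kept <- site_filters(gls, freqs, min_ind_frac = 0.9, hwe_alpha = 0.001,
                       maf_min = 0.05)
  expect_false(any(c("s5", "s6", "s7", "s8") %in% kept))

  # per-site oracle recomputation (hard calls are exact at depth 30, err 1e-3)
  hwe_oracle <- function(g) {
    n <- length(g); counts <- tabulate(g + 1L, 3L)
    ph <- (2 * counts[3] + counts[2]) / (2 * n)
    if (ph <= 0 || ph >= 1) return(1)  # boundary: saturated = HWE, LRT 0
    e <- c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
    lrt <- 2 * (sum(counts[counts > 0] * log(counts[counts > 0] / n)) -
                sum(counts[counts > 0] * log(e[counts > 0])))
    pchisq(max(0, lrt), 1, lower.tail = FALSE)
  }
  # the oracle recomputes from the same hard calls the filter sees
  hard_calls <- function(s) {
    m <- matrix(gls$gl[, s, ], ncol = 3)
    ok <- !is.na(m[, 1])
    max.col(m[ok, , drop = FALSE], ties.method = "first") - 1L
  }
  oracle_keep <- vapply(seq_len(n_site), function(s) {
    nonmiss <- mean(!is.na(gls$gl[, s, 1]))
    nonmiss >= 0.9 && min(p[s], 1 - p[s]) >= 0.05 &&
      hwe_oracle(hard_calls(s)) >= 0.001
  }, logical(1))
  expect_setequal(kept, gls$sites[oracle_keep])

  # a site with counts exactly at HWE proportions is retained (LRT = 0)
  g_hwe <- rep(c(0L, 1L, 2L), times = c(16, 16, 4))  # p = 0.3, 36 = n(q^2,2pq,p^2)?
  counts <- tabulate(g_hwe + 1L, 3L)
  ph <- (2 * counts[3] + counts[2]) / (2 * length(g_hwe))
  exp_counts <- length(g_hwe) * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
  if (all(abs(exp_counts - counts) < 1e-9)) {
    gls2 <- simulate_gls(matrix(g_hwe, ncol = 1,
                                dimnames = list(sprintf("Q%02d", seq_along(g_hwe)), NULL)),
                         depth = 50, err = 1e-4, seed = 93)
    expect_equal(site_filters(gls2, stats::setNames(ph, "s1"), maf_min = 0.01), "s1")
  }
})

test_that("pedigree validation regression recovers calibration and degenerate cases", {
  ped <- pedigree(data.frame(
    id = c("F1", "F2", "A", "B", "C"),
    sire = c(NA, NA, "F1", "F1", "F1"),
    dam = c(NA, NA, "F2", "F2", NA), stringsAsFactors = FALSE))
  pairs <- data.frame(a = c("A", "A", "F1", "F1"), b = c("B", "C", "F2", "A"),
                      stringsAsFactors = FALSE)
  expected <- c(0.5, 0.25, 0, 0.5)

  # genetic exactly equal to pedigree: perfect fit
  est <- cbind(pairs, r = expected)
  v <- validate_against_pedigree(est, ped)
  expect_equal(v$r_squared, 1)
  expect_equal(v$slope, 1)
  expect_equal(v$intercept, 0, tolerance = 1e-12)
  expect_equal(v$n_pairs, 4)

  # constant estimates carry no signal
  v0 <- validate_against_pedigree(cbind(pairs, r = 0.2), ped)
  expect_equal(v0$r_squared, 0)

  expect_error(validate_against_pedigree(est[1:2, ], ped), ">= 3 pairs")
})

test_that("relatedness tables cover requested pairs and power the lookup closure", {
  set.seed(101)
  p <- runif(300, 0.1, 0.45)
  geno <- rbind(A = rbinom(300, 2, p), B = rbinom(300, 2, p), C = rbinom(300, 2, p))
  gls <- simulate_gls(geno, depth = 12, err = 0.01, seed = 102)
  tab <- relatedness_table(gls, stats::setNames(p, gls$sites), seed = 103)
  expect_equal(nrow(tab), 3L)  # all unordered pairs
  expect_true(all(c("D1", "D9", "theta", "F_a", "F_b", "r", "loglik") %in% names(tab)))
  lk <- relatedness_lookup(tab)
  expect_equal(lk("A", "B"), lk("B", "A"))
  expect_equal(lk("A", "B"), tab$r[tab$a == "A" & tab$b == "B"])
  expect_true(is.na(lk("A", "Z")))
})
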