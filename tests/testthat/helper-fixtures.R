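# Fixture builders and independent oracles shared across test files.

# -- individual-record fixtures -------------------------------------------------

# one-interval residency helper
res1 <- function(start, end = NA) {
  data.frame(start = as.Date(start), end = as.Date(end))
}

# minimal valid record row; override fields as needed
make_record <- function(id, sex = "female", birth = "2000-01-01",
                        birth_known = TRUE, death = NA, natality = "natal",
                        immigration = NA, emigration = NA,
                        residency = NULL, genotyped = TRUE) {
  if (is.null(residency)) residency <- res1(birth)
  data.frame(id = id, sex = sex, birth_date = as.Date(birth),
             birth_date_known = birth_known, death_date = as.Date(death),
             natality = natality, immigration_date = as.Date(immigration),
             emigration_date = as.Date(emigration),
             residency = I(list(residency)), in_genetic_dataset = genotyped,
             stringsAsFactors = FALSE)
}

make_records <- function(...) individual_records(do.call(rbind, list(...)))

# philopatry fixture: n_eligible natal females whose 13th birthdays fall in
# 2005..2015, of whom n_stay never emigrate (the rest emigrate at 13)
philopatry_fixture <- function(n_eligible, n_stay,
                               study_start = as.Date("2004-01-01"),
                               study_end = as.Date("2018-08-01")) {
  rows <- lapply(seq_len(n_eligible), function(i) {
    birth <- as.Date("1992-06-15") + ((i - 1) %% 10) * 330
    stays <- i <= n_stay
    bday13 <- add_years(birth, 13)
    make_record(sprintf("F%03d", i), birth = birth,
                emigration = if (stays) NA else bday13 + 30,
                residency = res1(birth, if (stays) NA else bday13 + 30))
  })
  do.call(make_records, rows)
}

# -- pedigree oracles -----------------------------------------------------------

# All ancestor paths from id up the trio table `tab` (id/sire/dam data.frame,
# NA = unknown). Each path is the vector (id, parent, ..., ancestor); the
# trivial path (id) is included.
all_paths_up <- function(tab, id) {
  row <- tab[tab$id == id, ]
  out <- list(id)
  for (par in c(row$sire, row$dam)) {
    if (!is.na(par) && par %in% tab$id) {
      for (p in all_paths_up(tab, par)) out <- c(out, list(c(id, p)))
    }
  }
  out
}

# Independent kinship oracle by Wright path counting:
# theta(a,b) = sum over common ancestors C and pairs of paths meeting only
# at C of (1/2)^(n1+n2+1) (1+F_C), with F_C computed by the same oracle.
path_kinship <- function(tab, a, b) {
  if (a == b) {
    row <- tab[tab$id == a, ]
    f <- if (is.na(row$sire) || is.na(row$dam)) 0 else path_kinship(tab, row$sire, row$dam)
    return(0.5 * (1 + f))
  }
  pa <- all_paths_up(tab, a)
  pb <- all_paths_up(tab, b)
  theta <- 0
  for (p1 in pa) for (p2 in pb) {
    C <- p1[length(p1)]
    if (C != p2[length(p2)]) next
    if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
    row <- tab[tab$id == C, ]
    fC <- if (is.na(row$sire) || is.na(row$dam)) 0 else path_kinship(tab, row$sire, row$dam)
    theta <- theta + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + fC)
  }
  theta
}

path_relatedness <- function(tab, a, b) {
  fa <- path_kinship(tab, a, a) * 2 - 1
  fb <- path_kinship(tab, b, b) * 2 - 1
  2 * path_kinship(tab, a, b) / sqrt((1 + fa) * (1 + fb))
}

# random multi-generation pedigree avoiding self-matings
random_pedigree_tab <- function(n_founders = 6, n_gen = 4, per_gen = 5, seed = 1) {
  set.seed(seed)
  tab <- data.frame(id = sprintf("G0_%d", seq_len(n_founders)),
                    sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  prev <- tab$id
  for (g in seq_len(n_gen)) {
    ids <- sprintf("G%d_%d", g, seq_len(per_gen))
    pool <- tab$id
    sires <- sample(pool, per_gen, replace = TRUE)
    dams <- vapply(sires, function(s) sample(setdiff(pool, s), 1), character(1))
    tab <- rbind(tab, data.frame(id = ids, sire = sires, dam = dams,
                                 stringsAsFactors = FALSE))
    prev <- ids
  }
  tab
}

# -- genotype-likelihood fixtures ----------------------------------------------

# certain-genotype likelihood matrix (1 on the true genotype)
hard_gl <- function(geno_vec) {
  m <- matrix(0, length(geno_vec), 3)
  m[cbind(seq_along(geno_vec), geno_vec + 1L)] <- 1
  m
}

# Lineage layout of each condensed identity state: which independent founder
# lineage each of the four alleles (two per individual) descends from.
oracle_state_lineages <- list(
  list(i1 = c(1, 1), i2 = c(1, 1)),  # 1: all four IBD
  list(i1 = c(1, 1), i2 = c(2, 2)),  # 2: both inbred, lineages separate
  list(i1 = c(1, 1), i2 = c(1, 2)),  # 3: A inbred, shares with B
  list(i1 = c(1, 1), i2 = c(2, 3)),  # 4: A inbred only
  list(i1 = c(1, 2), i2 = c(1, 1)),  # 5: B inbred, shares with A
  list(i1 = c(2, 3), i2 = c(1, 1)),  # 6: B inbred only
  list(i1 = c(1, 2), i2 = c(1, 2)),  # 7: share both alleles
  list(i1 = c(1, 2), i2 = c(1, 3)),  # 8: share one allele
  list(i1 = c(1, 2), i2 = c(3, 4))   # 9: no IBD
)

# independent genotype-pair probability oracle: enumerate every assignment of
# minor/major alleles to the state's founder lineages
oracle_state_prob <- function(g1, g2, k, p) {
  lay <- oracle_state_lineages[[k]]
  n <- max(lay$i1, lay$i2)
  tot <- 0
  for (code in 0:(2^n - 1)) {
    v <- as.integer(intToBits(code))[seq_len(n)]
    if (sum(v[lay$i1]) == g1 && sum(v[lay$i2]) == g2) {
      tot <- tot + prod(ifelse(v == 1, p, 1 - p))
    }
  }
  tot
}

# Monte-Carlo allele-drawing oracle for one state
oracle_state_mc <- function(k, p, n_draws = 1e6) {
  lay <- oracle_state_lineages[[k]]
  n <- max(lay$i1, lay$i2)
  v <- matrix(stats::rbinom(n_draws * n, 1, p), n_draws, n)
  g1 <- rowSums(v[, lay$i1, drop = FALSE])
  g2 <- rowSums(v[, lay$i2, drop = FALSE])
  table(factor(g1, 0:2), factor(g2, 0:2)) / n_draws
}

oracle_hard_em <- function(g1, g2, p, tol = 1e-10, max_iter = 2000) {
  n <- length(g1)
  W <- matrix(0, n, 9)
  for (s in seq_len(n)) for (k in 1:9) {
    W[s, k] <- oracle_state_prob(g1[s], g2[s], k, p[s])
  }
  delta <- rep(1 / 9, 9)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- sweep(W, 2, delta, `*`)
    lik <- rowSums(num)
    ll <- sum(log(lik))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    delta <- colMeans(num / lik)
  }
  th <- delta[1] + 0.5 * (delta[3] + delta[5] + delta[7]) + 0.25 * delta[8]
  Fa <- sum(delta[1:4]); Fb <- sum(delta[c(1, 2, 5, 6)])
  list(delta = delta, r = 4 * th / (2 + Fa + Fb), loglik = ll_old)
}
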