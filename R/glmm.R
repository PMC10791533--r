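#' Shift a relatedness outcome into the open unit interval
#'
#' Logit-link beta regression is undefined at the boundaries, and observed
#' relatedness includes exact zeroes, so 0.0001 is added to every value (and
#' the result clamped strictly below one).
#'
#' @param r numeric vector of relatedness values in `[0, 1]`.
#' @return values in `(0, 1)`.
#' @export
shift_outcome <- function(r) {
  if (any(r < 0 | r > 1, na.rm = TRUE) || anyNA(r)) {
    stop("shift_outcome: relatedness must lie in [0, 1]")
  }
  pmin(r + 1e-4, 1 - 1e-9)
}

.natality_levels <- c("natal", "immigrant", "unknown")

#' Model data for the inbreeding-avoidance GLMM
#'
#' Maps a pair table to the regression layout: shifted outcome, actual
#' indicator, natality index (natal = reference), offspring index, and a
#' single joint individual index covering mothers and males so both members
#' of a dyad contribute the same type of individual-level varying effect
#' (multi-membership).
#'
#' @param pairs pair table from [build_pair_table()] (columns `offspring_id`,
#'   `mother_id`, `male_id`, `pair_kind`, `natality`, `relatedness`).
#' @return object of class `avoidance_data`: list with `y`, `A`, `nat`,
#'   `off`, `i1`, `i2`, `n_off`, `n_ind`, plus the level tables.
#' @export
glmm_data <- function(pairs) {
  req <- c("offspring_id", "mother_id", "male_id", "pair_kind", "natality", "relatedness")
  if (!all(req %in% names(pairs))) stop("glmm_data: pair table is missing columns")
  if (!all(pairs$pair_kind %in% c("actual", "potential"))) {
    stop("glmm_data: pair_kind must be actual/potential")
  }
  if (!all(pairs$natality %in% .natality_levels)) {
    stop("glmm_data: natality must be natal/immigrant/unknown")
  }
  offspring <- sort(unique(pairs$offspring_id))
  individuals <- sort(unique(c(pairs$mother_id, pairs$male_id)))
  structure(list(
    y = shift_outcome(pairs$relatedness),
    A = as.integer(pairs$pair_kind == "actual"),
    nat = match(pairs$natality, .natality_levels),
    off = match(pairs$offspring_id, offspring),
    i1 = match(pairs$mother_id, individuals),
    i2 = match(pairs$male_id, individuals),
    n_off = length(offspring), n_ind = length(individuals),
    offspring = offspring, individuals = individuals
  ), class = "avoidance_data")
}

#' Default weakly regularizing priors
#'
#' Intercept centred near logit of the typical mean relatedness (~0.02);
#' unit-normal coefficient priors; exponential(1) on the varying-effect
#' standard deviations; wide normal on log precision.
#'
#' @return named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(alpha_mean = -4, alpha_sd = 1.5, beta_sd = 1,
       sigma_rate = 1, logphi_mean = 3, logphi_sd = 2)
}

#' Joint log-posterior of the avoidance GLMM
#'
#' Beta likelihood with logit link,
#' logit(mu) = alpha + bA A + bnat\[nat\] + bint\[nat\] A + u\[off\] + v\[i\] + v\[j\],
#' plus prior densities. Supports the centred parametrization (`u`, `v`
#' supplied directly) and the non-centred one (`zu`, `zv` standard-normal,
#' u = sigma_u zu, v = sigma_v zv); the two differ by the fixed Jacobian
#' term `n_u log sigma_u + n_v log sigma_v` of the change of variables.
#'
#' @param params list with `alpha`, `bA`, `bnat` (length 3, first element 0),
#'   `bint` (length 3, first element 0), `sigma_u`, `sigma_v`, `logphi`, and
#'   either `u`,`v` (centred) or `zu`,`zv` (non-centred).
#' @param data an [glmm_data()] object.
#' @param priors list as [default_priors()].
#' @param noncentred interpret varying effects as standard-normal `zu`, `zv`.
#' @return log posterior density (scalar).
#' @export
log_posterior <- function(params, data, priors = default_priors(),
                          noncentred = FALSE) {
  if (params$sigma_u <= 0 || params$sigma_v <= 0) return(-Inf)
  phi <- exp(params$logphi)
  if (noncentred) {
    u <- params$sigma_u * params$zu
    v <- params$sigma_v * params$zv
  } else {
    u <- params$u
    v <- params$v
  }
  eta <- params$alpha + params$bA * data$A + params$bnat[data$nat] +
    params$bint[data$nat] * data$A + u[data$off] + v[data$i1] + v[data$i2]
  mu <- stats::plogis(eta)
  ll <- stats::dbeta(data$y, mu * phi, (1 - mu) * phi, log = TRUE)
  if (any(!is.finite(ll))) {
    stop("log_posterior: non-finite likelihood at row ", which(!is.finite(ll))[1])
  }
  lp <- sum(ll) +
    stats::dnorm(params$alpha, priors$alpha_mean, priors$alpha_sd, log = TRUE) +
    stats::dnorm(params$bA, 0, priors$beta_sd, log = TRUE) +
    sum(stats::dnorm(params$bnat[2:3], 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(params$bint[2:3], 0, priors$beta_sd, log = TRUE)) +
    stats::dexp(params$sigma_u, priors$sigma_rate, log = TRUE) +
    stats::dexp(params$sigma_v, priors$sigma_rate, log = TRUE) +
    stats::dnorm(params$logphi, priors$logphi_mean, priors$logphi_sd, log = TRUE)
  lp + if (noncentred) {
    sum(stats::dnorm(params$zu, 0, 1, log = TRUE)) +
      sum(stats::dnorm(params$zv, 0, 1, log = TRUE))
  } else {
    sum(stats::dnorm(u, 0, params$sigma_u, log = TRUE)) +
      sum(stats::dnorm(v, 0, params$sigma_v, log = TRUE))
  }
}

# The linear predictor is sampled through per-natality intercepts
# anat[k] = alpha + bnat[k] and per-natality actual effects
# bact[k] = bA + bint[k] (hierarchical centring): with bnat[k], bint[k]
# ~ Normal(0, beta_sd) this is the identical joint prior, but each group
# intercept is informed directly by its own rows, which mixes far better
# than sampling the contrasts one at a time. The contrasts are recovered
# deterministically. Varying effects use the non-centred parametrization.
.jags_model_string <- function(priors) {
  sprintf("
model {
  for (r in 1:N) {
    y[r] ~ dbeta(mu[r] * phi, (1 - mu[r]) * phi)
    logit(mu[r]) <- anat[nat[r]] + bact[nat[r]] * A[r] +
                    sigma_u * zu[off[r]] + sigma_v * (zv[i1[r]] + zv[i2[r]])
  }
  anat[1] <- alpha
  bact[1] <- bA
  bnat[1] <- 0
  bint[1] <- 0
  for (k in 2:3) {
    anat[k] ~ dnorm(alpha, %.10g)
    bact[k] ~ dnorm(bA, %.10g)
    bnat[k] <- anat[k] - alpha
    bint[k] <- bact[k] - bA
  }
  alpha ~ dnorm(%.10g, %.10g)
  bA ~ dnorm(0, %.10g)
  for (k in 1:Noff) { zu[k] ~ dnorm(0, 1) }
  for (k in 1:Nind) { zv[k] ~ dnorm(0, 1) }
  sigma_u ~ dexp(%.10g)
  sigma_v ~ dexp(%.10g)
  logphi ~ dnorm(%.10g, %.10g)
  phi <- exp(logphi)
}",
    priors$beta_sd^-2, priors$beta_sd^-2,
    priors$alpha_mean, priors$alpha_sd^-2, priors$beta_sd^-2,
    priors$sigma_rate, priors$sigma_rate,
    priors$logphi_mean, priors$logphi_sd^-2)
}

.fixed_params <- c("alpha", "bA", "bnat[2]", "bnat[3]", "bint[2]", "bint[3]")
.monitor_params <- c("alpha", "bA", "bnat", "bint", "sigma_u", "sigma_v", "phi")

#' Fit the inbreeding-avoidance beta GLMM by MCMC
#'
#' Samples the model of [log_posterior()] in its non-centred parametrization
#' with JAGS. Runs `chains` independent chains with per-chain seeded RNG
#' streams derived from `seed`, so a fixed seed reproduces draws exactly.
#' Convergence is checked on the monitored parameters via split-free
#' Gelman-Rubin R-hat and effective sample size; R-hat above `rhat_limit`
#' raises a diagnostic error by default.
#'
#' @param data an [glmm_data()] object.
#' @param priors list as [default_priors()].
#' @param chains number of chains (>= 2, for R-hat).
#' @param adapt adaptation iterations (default 500).
#' @param iter retained sampling iterations per chain (default 1500).
#' @param seed integer master seed.
#' @param rhat_limit convergence threshold (default 1.05).
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @param quiet suppress JAGS progress output.
#' @return object of class `avoidance_fit`: `samples` (coda `mcmc.list`),
#'   `draws` (pooled matrix), `rhat`, `ess`, `data`, `priors`, `seed`.
#' @export
fit_avoidance_glmm <- function(data, priors = default_priors(), chains = 2L,
                               adapt = 500L, iter = 1500L, seed = 1L,
                               rhat_limit = 1.05,
                               on_nonconvergence = c("error", "warn"),
                               quiet = TRUE) {
  stopifnot(inherits(data, "avoidance_data"))
  if (length(data$y) == 0L) stop("fit_avoidance_glmm: empty model data")
  if (chains < 2L) stop("fit_avoidance_glmm: need >= 2 chains for R-hat")
  on_nonconvergence <- match.arg(on_nonconvergence)

  jdata <- list(y = data$y, A = data$A, nat = data$nat, off = data$off,
                i1 = data$i1, i2 = data$i2, N = length(data$y),
                Noff = data$n_off, Nind = data$n_ind)
  inits <- lapply(seq_len(chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 101L + c) %% .Machine$integer.max)
  })
  model <- rjags::jags.model(textConnection(.jags_model_string(priors)),
                             data = jdata, inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = quiet)
  samples <- rjags::coda.samples(model, .monitor_params, n.iter = iter,
                                 progress.bar = if (quiet) "none" else "text")
  # drop the structurally-zero reference-level columns
  keep_cols <- setdiff(colnames(samples[[1]]), c("bnat[1]", "bint[1]"))
  samples <- coda::as.mcmc.list(lapply(samples, function(ch) {
    coda::as.mcmc(ch[, keep_cols, drop = FALSE])
  }))
  rhat <- coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  ess <- coda::effectiveSize(samples)
  if (any(rhat > rhat_limit)) {
    msg <- paste0("fit_avoidance_glmm: chains have not converged; R-hat > ",
                  rhat_limit, " for ",
                  paste(sprintf("%s (%.3f)", names(rhat)[rhat > rhat_limit],
                                rhat[rhat > rhat_limit]), collapse = ", "),
                  "; increase iterations")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  structure(list(samples = samples, draws = as.matrix(samples),
                 rhat = rhat, ess = ess, data = data, priors = priors,
                 chains = chains, iter = iter, seed = seed),
            class = "avoidance_fit")
}

#' @export
print.avoidance_fit <- function(x, ...) {
  cat("avoidance_fit:", nrow(x$draws), "pooled draws over", x$chains, "chains\n")
  q <- t(apply(x$draws[, c(.fixed_params, "sigma_u", "sigma_v", "phi")], 2,
               stats::quantile, probs = c(0.055, 0.5, 0.945)))
  colnames(q) <- c("5.5%", "median", "94.5%")
  print(round(cbind(q, rhat = x$rhat[rownames(q)], ess = round(x$ess[rownames(q)])), 3))
  invisible(x)
}

#' Posterior predictions per predictor combination
#'
#' For `n_draws` evenly thinned posterior draws, computes the
#' population-average predicted relatedness (varying effects at zero) on the
#' response scale for every actual/potential x natality combination, and
#' summarizes as the median with an 89% percentile interval.
#'
#' @param fit an [fit_avoidance_glmm()] result.
#' @param n_draws number of retained draws (default 1000; error if fewer are
#'   available).
#' @param level interval mass (default 0.89).
#' @param predictive if `TRUE`, return intervals for a new observation
#'   (a Beta draw around each posterior mean, so lower precision phi widens
#'   the interval) instead of for the population-average mean.
#' @return data.frame with `pair_kind`, `natality`, `median`, `lower`,
#'   `upper`; the draw matrix is attached as attribute `"draws"` and the
#'   interval type (`"percentile"`) as `"interval"`.
#' @export
posterior_predict <- function(fit, n_draws = 1000L, level = 0.89,
                              predictive = FALSE) {
  d <- fit$draws
  if (nrow(d) < n_draws) {
    stop("posterior_predict: only ", nrow(d), " draws available; need ", n_draws)
  }
  idx <- unique(round(seq(1L, nrow(d), length.out = n_draws)))
  if (length(idx) < n_draws) idx <- seq_len(n_draws)
  d <- d[idx, , drop = FALSE]
  grid <- expand.grid(pair_kind = c("actual", "potential"),
                      natality = .natality_levels,
                      stringsAsFactors = FALSE)
  bnat <- cbind(0, d[, "bnat[2]"], d[, "bnat[3]"])
  bint <- cbind(0, d[, "bint[2]"], d[, "bint[3]"])
  lo <- (1 - level) / 2
  pred <- matrix(NA_real_, n_draws, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    A <- as.integer(grid$pair_kind[g] == "actual")
    n <- match(grid$natality[g], .natality_levels)
    mu <- stats::plogis(d[, "alpha"] + d[, "bA"] * A + bnat[, n] + bint[, n] * A)
    pred[, g] <- if (predictive) {
      stats::rbeta(n_draws, mu * d[, "phi"], (1 - mu) * d[, "phi"])
    } else mu
  }
  out <- cbind(grid,
               median = apply(pred, 2, stats::median),
               lower = apply(pred, 2, stats::quantile, probs = lo),
               upper = apply(pred, 2, stats::quantile, probs = 1 - lo))
  colnames(pred) <- paste(grid$pair_kind, grid$natality, sep = ".")
  attr(out, "draws") <- pred
  attr(out, "interval") <- "percentile"
  out
}

#' Percent difference between actual and potential predictions
#'
#' `100 * (pred_actual - pred_potential) / pred_potential`, reported to two
#' decimals.
#'
#' @param pred_actual,pred_potential predicted relatedness values;
#'   `pred_potential` must be positive.
#' @return percent difference, rounded to 2 decimals.
#' @export
percent_difference <- function(pred_actual, pred_potential) {
  if (any(pred_potential <= 0)) stop("percent_difference: pred_potential must be > 0")
  round(100 * (pred_actual - pred_potential) / pred_potential, 2L)
}

#' Posterior-prediction report by natality
#'
#' Medians and 89% intervals for actual and potential pairs within each
#' natality class, with the percent difference of the medians — the layout of
#' the study's headline table.
#'
#' @inheritParams posterior_predict
#' @return data.frame with one actual and one potential row per natality and
#'   a `percent_difference` column on the actual rows.
#' @export
avoidance_report <- function(fit, n_draws = 1000L) {
  pp <- posterior_predict(fit, n_draws = n_draws)
  pp$percent_difference <- NA_real_
  for (nat in .natality_levels) {
    a <- pp$pair_kind == "actual" & pp$natality == nat
    p <- pp$pair_kind == "potential" & pp$natality == nat
    pp$percent_difference[a] <- percent_difference(pp$median[a], pp$median[p])
  }
  pp[order(match(pp$natality, .natality_levels), pp$pair_kind), ]
}

#' Simulate pair-table rows from the GLMM itself
#'
#' Draws a dataset from the avoidance model's own generative process (for
#' parameter-recovery checks): offspring are assigned mothers, an actual male
#' and a pool of potential males; relatedness outcomes are Beta draws around
#' the linear predictor with the supplied coefficients.
#'
#' @param n_offspring number of offspring (default 80).
#' @param n_females,n_males pool sizes (defaults 30 and 40).
#' @param males_per_offspring potential-pool size per offspring (default 25).
#' @param params true parameter list: `alpha`, `bA`, `bnat`, `bint` (length-3,
#'   first element 0), `sigma_u`, `sigma_v`, `phi`.
#' @param seed integer seed.
#' @return list with `pairs` (a pair table whose `relatedness` is the shifted
#'   outcome minus 0.0001, clamped at 0) and `truth` (the parameters and the
#'   realized varying effects).
#' @export
simulate_model_rows <- function(n_offspring = 80L, n_females = 30L,
                                n_males = 40L, males_per_offspring = 25L,
                                params, seed = 1L) {
  .with_seed(seed, {
    females <- sprintf("F%02d", seq_len(n_females))
    males <- sprintf("M%02d", seq_len(n_males))
    nat_f <- stats::setNames(sample(.natality_levels, n_females, replace = TRUE,
                                    prob = c(0.4, 0.4, 0.2)), females)
    u <- stats::rnorm(n_offspring, 0, params$sigma_u)
    inds <- c(females, males)
    v <- stats::setNames(stats::rnorm(length(inds), 0, params$sigma_v), inds)
    rows <- lapply(seq_len(n_offspring), function(o) {
      mom <- sample(females, 1L)
      pool <- sample(males, males_per_offspring)
      data.frame(offspring_id = sprintf("O%03d", o), mother_id = mom,
                 male_id = pool,
                 pair_kind = c("actual", rep("potential", males_per_offspring - 1L)),
                 natality = nat_f[[mom]], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, rows)
    nat_i <- match(pairs$natality, .natality_levels)
    A <- as.integer(pairs$pair_kind == "actual")
    off_i <- match(pairs$offspring_id, unique(pairs$offspring_id))
    eta <- params$alpha + params$bA * A + params$bnat[nat_i] +
      params$bint[nat_i] * A + u[off_i] + v[pairs$mother_id] + v[pairs$male_id]
    mu <- stats::plogis(eta)
    y <- stats::rbeta(length(mu), mu * params$phi, (1 - mu) * params$phi)
    pairs$relatedness <- pmax(y - 1e-4, 0)
    list(pairs = pairs, truth = list(params = params, u = u, v = v))
  })
}
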