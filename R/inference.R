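# Poisson composite-likelihood fitting of demographic models to an observed
# folded 2D-JSFS, with theta profiled analytically at every evaluation.

#' Profile the scaled mutation rate theta
#'
#' Under the Poisson composite likelihood the maximising theta is the ratio
#' of total unmasked observed mass to total unmasked model mass.
#'
#' @param obs observed [joint_sfs()]
#' @param model_sfs expected [joint_sfs()] at theta = 1 scale, same shape,
#'   fold state and mask
#' @return theta-hat (positive scalar)
#' @export
profile_theta <- function(obs, model_sfs) {
  check_same_shape(obs, model_sfs)
  denom <- sfs_total(model_sfs)
  if (denom <= 0) stop("degenerate model spectrum: total expected mass is 0")
  sfs_total(obs) / denom
}

check_same_shape <- function(a, b) {
  if (a$n1 != b$n1 || a$n2 != b$n2)
    stop("spectra have different dimensions")
  if (!identical(a$folded, b$folded))
    stop("spectra have different fold states")
  invisible(TRUE)
}

#' Poisson composite log-likelihood of a spectrum
#'
#' Sum over unmasked cells of `obs * log(mu) - mu - lgamma(obs + 1)` with
#' `mu = theta * model`. Cells where both `mu` and `obs` are 0 contribute 0;
#' `mu` is floored at 1e-300 so an observed count in an empty model cell
#' yields a very small (finite) likelihood rather than `-Inf`.
#'
#' @inheritParams profile_theta
#' @param theta positive scaling of the model spectrum
#' @return log-likelihood (scalar)
#' @export
poisson_loglik <- function(obs, model_sfs, theta) {
  check_same_shape(obs, model_sfs)
  stopifnot(theta > 0)
  keep <- !obs$mask & !model_sfs$mask
  o <- obs$counts[keep]
  mu <- theta * model_sfs$counts[keep]
  zero <- mu == 0 & o == 0
  mu <- pmax(mu, 1e-300)
  sum(ifelse(zero, 0, o * log(mu) - mu - lgamma(o + 1)))
}

#' AIC, delta-AIC and Akaike weights
#'
#' `AIC = 2k - 2 loglik` with `k` the number of free demographic parameters
#' (theta, profiled analytically, is excluded by convention);
#' `delta_i = AIC_i - min(AIC)`; `w_i = exp(-delta_i/2) / sum exp(-delta_j/2)`.
#'
#' @param loglik log-likelihood at the optimum
#' @param k number of free parameters
#' @return `aic()`: scalar; `delta_aic()` and `akaike_weights()`: numeric
#'   vectors aligned with `aics`.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 1)
  2 * k - 2 * loglik
}

#' @rdname aic
#' @param aics numeric vector of AIC values
#' @export
delta_aic <- function(aics) {
  if (!length(aics)) stop("empty AIC list")
  aics - min(aics)
}

#' @rdname aic
#' @export
akaike_weights <- function(aics) {
  d <- delta_aic(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Multi-round optimizer schema
#'
#' Round 1 starts each replicate from an independent log-uniform draw within
#' the bounds; later rounds perturb the incumbent best by up to the stated
#' fold (log-uniform multiplicative). Each replicate is a Nelder-Mead local
#' search with theta profiled at every evaluation.
#'
#' @param replicates integer vector, replicates per round
#' @param fold numeric vector, perturbation fold per round
#' @param maxit integer vector, Nelder-Mead iteration cap per round
#' @param nreps_frac fraction of the engine replicate budget used per round;
#'   early rounds can screen the parameter space cheaply while the final
#'   round refines at full Monte Carlo resolution
#' @return list of class `optim_schema`
#' @export
optim_schema <- function(replicates = c(10L, 20L, 30L, 40L),
                         fold = c(3, 2, 2, 1),
                         maxit = c(30L, 40L, 50L, 60L),
                         nreps_frac = rep(1, length(replicates))) {
  stopifnot(length(replicates) == length(fold),
            length(fold) == length(maxit),
            length(nreps_frac) == length(replicates),
            all(nreps_frac > 0), all(nreps_frac <= 1))
  structure(list(replicates = as.integer(replicates), fold = fold,
                 maxit = as.integer(maxit), nreps_frac = nreps_frac,
                 rounds = length(fold)),
            class = "optim_schema")
}

# Bijection between bounded parameters and the unconstrained Nelder-Mead
# space: log-scale logistic, so sizes/times/migration spanning orders of
# magnitude move freely while bounds (notably s <= 0.5) can never be crossed.
search_space <- function(model) {
  lo <- vapply(model$free_params, function(b) max(b[1], 1e-5), numeric(1))
  hi <- vapply(model$free_params, `[`, numeric(1), 2)
  list(
    lo = lo, hi = hi,
    to_x = function(p) stats::qlogis(pmin(pmax(
      (log(p) - log(lo)) / (log(hi) - log(lo)), 1e-9), 1 - 1e-9)),
    to_p = function(x) exp(log(lo) + (log(hi) - log(lo)) * stats::plogis(x))
  )
}

#' Fit one demographic model to an observed folded spectrum
#'
#' Maximises the Poisson composite log-likelihood over the model's free
#' parameters by multi-round perturbed Nelder-Mead (see [optim_schema()]).
#' Expected spectra are computed with common random numbers (a single engine
#' seed reused at every evaluation) so the likelihood surface is
#' deterministic and the simplex search converges. Fully reproducible given
#' `seed`.
#'
#' @param model a `demographic_model`
#' @param obs observed folded [joint_sfs()]
#' @param schema an [optim_schema()]
#' @param seed integer seed (drives starting points, perturbations, and the
#'   engine stream)
#' @param nreps engine replicates per likelihood evaluation
#' @return An object of class `sfs_fit`: `model`, `params`, `loglik`, `k`,
#'   `aic`, `theta_hat`, `trajectory` (data.frame round/replicate/loglik),
#'   `seed`, `n1`, `n2`.
#' @export
optimize_model <- function(model, obs, schema = optim_schema(), seed = 1L,
                           nreps = 50000L) {
  if (!obs$folded) stop("the observed spectrum must be folded before fitting")
  sp <- search_space(model)
  engine_seed <- (as.numeric(seed) * 1000003) %% 2147483647
  round_nreps <- nreps  # rebound per round below
  # A Monte Carlo zero in an expected cell only means E[L] is below the
  # engine's resolution (~1/nreps), not that the class is impossible; cells
  # are floored at half a replicate unit so an observed count there is
  # penalised at the resolution scale instead of the hard 1e-300 floor.
  floor_counts <- function(ex, nr) {
    open <- !ex$mask
    ex$counts[open] <- pmax(ex$counts[open], 0.5 / nr)
    ex
  }
  neg_ll <- function(x) {
    p <- setNames(sp$to_p(x), names(model$free_params))
    exp_sfs <- floor_counts(
      expected_jsfs(model, p, obs$n1, obs$n2, nreps = round_nreps,
                    seed = engine_seed, fold = TRUE),
      round_nreps
    )
    tot <- sfs_total(exp_sfs)
    if (!is.finite(tot) || tot <= 0) return(1e10)
    th <- profile_theta(obs, exp_sfs)
    ll <- poisson_loglik(obs, exp_sfs, th)
    if (!is.finite(ll)) 1e10 else -ll
  }

  rng <- local({ set.seed(seed); NULL })  # draws below use R's stream
  best <- NULL
  traj <- list()
  for (r in seq_len(schema$rounds)) {
    round_nreps <- max(500L, as.integer(ceiling(nreps * schema$nreps_frac[r])))
    for (rep in seq_len(schema$replicates[r])) {
      x0 <- if (r == 1 || is.null(best)) {
        sp$to_x(exp(runif(length(sp$lo), log(pmax(sp$lo, 1e-5)), log(sp$hi))))
      } else {
        f <- schema$fold[r]
        sp$to_x(pmin(pmax(best$p * exp(runif(length(sp$lo), -log(f), log(f))),
                          sp$lo * 1.0000001), sp$hi * 0.9999999))
      }
      # maxit <= 1 marks a screening round: score the start point only
      fit <- tryCatch(
        if (schema$maxit[r] <= 1L) list(par = x0, value = neg_ll(x0))
        else optim(x0, neg_ll, method = "Nelder-Mead",
                   control = list(maxit = schema$maxit[r])),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      ll <- -fit$value
      traj[[length(traj) + 1]] <- data.frame(round = r, replicate = rep,
                                             loglik = ll)
      if (is.finite(ll) && ll > -1e9 &&
          (is.null(best) || ll > best$loglik)) {
        best <- list(p = setNames(sp$to_p(fit$par), names(model$free_params)),
                     loglik = ll)
      }
    }
  }
  if (is.null(best))
    stop("optimization failed for model ", model$name,
         ": no replicate reached a finite likelihood")
  # re-evaluate the winner at the full replicate budget so fits optimised
  # with screening rounds report comparable likelihoods
  exp_best <- floor_counts(
    expected_jsfs(model, best$p, obs$n1, obs$n2, nreps = nreps,
                  seed = engine_seed, fold = TRUE),
    nreps
  )
  theta_hat <- profile_theta(obs, exp_best)
  loglik <- poisson_loglik(obs, exp_best, theta_hat)
  structure(
    list(model = model, params = best$p, loglik = loglik, k = model$k,
         aic = aic(loglik, model$k), theta_hat = theta_hat,
         trajectory = do.call(rbind, traj), seed = seed,
         n1 = obs$n1, n2 = obs$n2),
    class = "sfs_fit"
  )
}

#' @export
#' @method print sfs_fit
print.sfs_fit <- function(x, ...) {
  cat(sprintf("<sfs_fit> %s: loglik = %.2f, k = %d, AIC = %.2f, theta = %.2f\n",
              x$model$name, x$loglik, x$k, x$aic, x$theta_hat))
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' Fit and rank a set of candidate models
#'
#' Fits every registry model (each with its own seeded substream), ranks by
#' AIC ascending (ties broken by smaller `k`, then name) and attaches
#' delta-AIC and Akaike weights over the full fitted set. A model whose
#' optimization fails is excluded with a warning, never silently.
#'
#' @param obs observed folded [joint_sfs()]
#' @param registry list of models from [model_registry()]
#' @param schema an [optim_schema()]
#' @param seed master integer seed
#' @param nreps engine replicates per likelihood evaluation
#' @return An object of class `sfs_model_comparison`: `fits` (list of
#'   [optimize_model()] results, ranked) and `table` (data.frame analogue of
#'   a model-comparison table). `as.data.frame()` returns the table.
#' @export
compare_models <- function(obs, registry, schema = optim_schema(), seed = 1L,
                           nreps = 50000L) {
  if (!length(registry)) stop("empty model registry")
  fits <- list()
  for (i in seq_along(registry)) {
    m <- registry[[i]]
    f <- tryCatch(
      optimize_model(m, obs, schema = schema, seed = seed + 97L * i,
                     nreps = nreps),
      error = function(e) {
        warning("model ", m$name, " excluded: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(f)) fits[[m$name]] <- f
  }
  if (!length(fits)) stop("all model optimizations failed")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(aics, ks, names(fits))
  fits <- fits[ord]
  aics <- aics[ord]
  d <- delta_aic(aics)
  w <- akaike_weights(aics)
  all_params <- unique(unlist(lapply(fits, function(f) names(f$params))))
  canonical <- c("nuA", "nu1", "nu2", "T", "T1", "T2", "s", "m12", "m21")
  all_params <- c(intersect(canonical, all_params),
                  setdiff(all_params, canonical))
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AIC = aics, deltaAIC = d, weight = w,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (pn in all_params)
    tab[[pn]] <- vapply(fits, function(f)
      if (pn %in% names(f$params)) f$params[[pn]] else NA_real_, numeric(1))
  structure(list(fits = fits, table = tab), class = "sfs_model_comparison")
}

#' @export
as.data.frame.sfs_model_comparison <- function(x, ...) x$table

#' @export
#' @method print sfs_model_comparison
print.sfs_model_comparison <- function(x, ...) {
  cat("<sfs_model_comparison>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 4)
  print(tab)
  invisible(x)
}

#' Build a ranked comparison from precomputed fits
#'
#' Utility for ranking externally supplied `(loglik, k)` pairs without
#' refitting (e.g. published log-likelihoods).
#'
#' @param models character vector of model names
#' @param logliks numeric log-likelihoods
#' @param ks integer parameter counts
#' @return data.frame with `AIC`, `deltaAIC` and `weight`, sorted by AIC.
#' @export
rank_models <- function(models, logliks, ks) {
  stopifnot(length(models) == length(logliks), length(logliks) == length(ks))
  aics <- mapply(aic, logliks, ks)
  ord <- order(aics, ks, models)
  data.frame(
    model = models[ord], loglik = logliks[ord], k = ks[ord],
    AIC = aics[ord], deltaAIC = delta_aic(aics[ord]),
    weight = akaike_weights(aics[ord]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pearson residual grid of a fitted spectrum
#'
#' `(obs - mu) / sqrt(mu)` per unmasked cell with `mu = theta_hat * model`;
#' masked cells are `NA`.
#'
#' @inheritParams profile_theta
#' @param theta_hat fitted theta
#' @return numeric matrix of the spectrum's shape.
#' @export
sfs_residuals <- function(obs, model_sfs, theta_hat) {
  check_same_shape(obs, model_sfs)
  mu <- theta_hat * model_sfs$counts
  res <- (obs$counts - mu) / sqrt(pmax(mu, 1e-300))
  res[obs$mask | model_sfs$mask] <- NA_real_
  res
}

#' Rescale fitted parameters to a reference mutation scale
#'
#' The Poisson composite likelihood with profiled theta identifies
#' demographic parameters only up to a joint rescaling: multiplying all
#' sizes and times by `c`, dividing migration rates by `c` and dividing
#' theta by `c` leaves every expected spectrum unchanged. When the true
#' (or externally known) theta is available — as for simulated data, where
#' `theta = 4 Nref mu L` is set by the generator — fitted parameters become
#' absolute after rescaling by `c = theta_hat / theta_ref`. Sizes and times
#' are multiplied by `c`, migration rates divided by `c`, and the founding
#' fraction `s` (a ratio) is left untouched.
#'
#' @param params named parameter vector (a fit's `params`)
#' @param theta_hat the fit's profiled theta
#' @param theta_ref the reference theta to rescale to
#' @return named numeric vector on the reference scale.
#' @export
canonical_params <- function(params, theta_hat, theta_ref) {
  stopifnot(theta_hat > 0, theta_ref > 0)
  p <- unlist(params)
  cc <- theta_hat / theta_ref
  for (nm in names(p)) {
    kind <- param_kind(nm)
    if (kind %in% c("size", "time")) p[[nm]] <- p[[nm]] * cc
    if (kind == "migration") p[[nm]] <- p[[nm]] / cc
  }
  p
}
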