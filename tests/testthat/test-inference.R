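# A tiny single-cell spectrum pair for likelihood arithmetic.
one_cell_pair <- function(obs_val, model_val) {
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)  # only cell (0,1) open
  list(
    obs = joint_sfs(matrix(c(0, 0, obs_val, 0), 2, 2), folded = TRUE,
                    mask = mask, mask_corners = FALSE),
    mod = joint_sfs(matrix(c(0, 0, model_val, 0), 2, 2), folded = TRUE,
                    mask = mask, mask_corners = FALSE)
  )
}

test_that("theta profiling is the observed/expected mass ratio and optimal", {
  a <- joint_sfs(matrix(c(0, 40, 60, 0), 2, 2), folded = TRUE)
  b <- joint_sfs(matrix(c(0, 10, 15, 0), 2, 2), folded = TRUE)
  expect_equal(profile_theta(a, b), 4)
  expect_equal(profile_theta(a, a), 1)
  expect_error(profile_theta(a, joint_sfs(matrix(0, 2, 2), folded = TRUE)),
               "degenerate")

  # local optimality of the profiled theta on a random fixture
  set.seed(8)
  mod <- joint_sfs(matrix(rexp(35), 5, 7))
  obs <- joint_sfs(matrix(rpois(35, 20 * mod$counts), 5, 7))
  th <- profile_theta(obs, mod)
  ll <- function(t) poisson_loglik(obs, mod, t)
  expect_gte(ll(th), ll(th * 1.01))
  expect_gte(ll(th), ll(th * 0.99))
  expect_gt(ll(th), ll(th * 2))     # unimodal decay away from the optimum
})

test_that("Poisson composite log-likelihood matches hand arithmetic", {
  pr <- one_cell_pair(2, 1)
  expect_equal(poisson_loglik(pr$obs, pr$mod, 1), 2 * log(1) - 1 - log(2))
  # obs == mu: the Poisson log-mass at its mean, cell-wise
  pr2 <- one_cell_pair(3, 3)
  expect_equal(poisson_loglik(pr2$obs, pr2$mod, 1), dpois(3, 3, log = TRUE))
  # empty model cell with zero observation contributes nothing
  pr3 <- one_cell_pair(0, 0)
  expect_equal(poisson_loglik(pr3$obs, pr3$mod, 1), 0)
  # empty model cell with a positive observation is finite but abysmal
  pr4 <- one_cell_pair(2, 0)
  expect_lt(poisson_loglik(pr4$obs, pr4$mod, 1), -1000)
  expect_true(is.finite(poisson_loglik(pr4$obs, pr4$mod, 1)))
})

test_that("AIC arithmetic, delta-AIC and Akaike weights", {
  expect_equal(aic(-177.32, 5), 364.64)
  expect_equal(aic(-175.33, 8), 366.66)
  expect_equal(aic(-175.33, 8) - aic(-177.32, 5), 2.02, tolerance = 1e-10)
  expect_equal(delta_aic(c(364.64, 366.66)), c(0, 2.02), tolerance = 1e-10)
  # direct evaluation of the weight formula at delta = {0, 2.02}
  w <- akaike_weights(c(0, 2.02))
  expect_equal(w, c(1, exp(-1.01)) / (1 + exp(-1.01)))
  expect_equal(round(w, 4), c(0.7330, 0.2670))
  expect_equal(akaike_weights(42), 1)
  expect_equal(delta_aic(42), 0)
  expect_error(delta_aic(numeric(0)), "empty")
  set.seed(3)
  for (k in 1:5) {
    ws <- akaike_weights(runif(7, 100, 120))
    expect_equal(sum(ws), 1, tolerance = 1e-12)
    # adding a constant to all AICs leaves weights and ranking unchanged
    expect_equal(akaike_weights(runif(1, 1, 9) + sort(ws)),
                 akaike_weights(sort(ws)), tolerance = 1e-12)
  }
})

test_that("default optimizer schema is four rounds of 10/20/30/40 replicates", {
  s <- optim_schema()
  expect_equal(s$rounds, 4)
  expect_equal(s$replicates, c(10L, 20L, 30L, 40L))
  expect_equal(s$fold, c(3, 2, 2, 1))
  expect_equal(s$maxit, c(30L, 40L, 50L, 60L))
})

test_that("precomputed ranking places the vicariance model first", {
  tab <- rank_models(
    c("founder_anc_asym_two_epoch", "vic_no_mig"),
    c(-175.33, -177.32), c(8L, 5L)
  )
  expect_equal(tab$model[1], "vic_no_mig")
  expect_equal(tab$deltaAIC, c(0, 2.02), tolerance = 1e-10)
  expect_equal(sum(tab$weight), 1)
})

test_that("model fitting respects the s bound and is reproducible", {
  m <- model_registry("full")$vic_no_mig
  p_true <- c(nuA = 1, nu1 = 1.2, nu2 = 0.6, T = 0.5, s = 0.3)
  e <- expected_jsfs(m, p_true, 8, 6, nreps = 20000, seed = 31, fold = TRUE)
  obs <- sample_obs_sfs(e, 200, seed = 77)
  schema <- optim_schema(replicates = c(10, 2), fold = c(3, 2),
                         maxit = c(1, 25), nreps_frac = c(0.5, 1))
  f1 <- optimize_model(m, obs, schema = schema, seed = 3, nreps = 2000)
  f2 <- optimize_model(m, obs, schema = schema, seed = 3, nreps = 2000)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_lte(f1$params[["s"]], 0.5)
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik)
  expect_gt(f1$theta_hat, 0)
  expect_equal(nrow(f1$trajectory), 12)
  unfolded <- expected_jsfs(m, p_true, 8, 6, nreps = 1000, seed = 31)
  expect_error(optimize_model(m, unfolded), "folded")
})

test_that("compare_models ranks fits with weights over the full set", {
  m <- model_registry("full")
  p_true <- c(nuA = 1, nu1 = 1.2, nu2 = 0.6, T = 0.5, s = 0.3)
  e <- expected_jsfs(m$vic_no_mig, p_true, 8, 6, nreps = 20000, seed = 31,
                     fold = TRUE)
  obs <- sample_obs_sfs(e, 200, seed = 78)
  schema <- optim_schema(replicates = c(8, 2), fold = c(3, 2),
                         maxit = c(1, 20), nreps_frac = c(0.5, 1))
  reg2 <- m[c("vic_no_mig", "founder_no_mig_exp")]
  cmp <- compare_models(obs, reg2, schema = schema, seed = 5, nreps = 2000)
  tab <- as.data.frame(cmp)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_equal(tab$deltaAIC[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true(all(c("nuA", "nu1", "nu2", "T", "s") %in% names(tab)))
  # identical observation and configuration -> identical comparison table
  cmp2 <- compare_models(obs, reg2, schema = schema, seed = 5, nreps = 2000)
  expect_identical(as.data.frame(cmp2), tab)
})

test_that("Pearson residuals are zero at the fit and follow (obs-mu)/sqrt(mu)", {
  a <- joint_sfs(matrix(c(0, 4, 9, 0), 2, 2), folded = TRUE)
  expect_equal(sfs_residuals(a, a, 1)[!a$mask], c(0, 0))
  pr <- one_cell_pair(4, 1)
  r <- sfs_residuals(pr$obs, pr$mod, 1)
  expect_equal(r[1, 2], 3)
  expect_equal(dim(r), c(2, 2))
  expect_true(all(is.na(r[pr$obs$mask])))
})

test_that("canonical rescaling inverts the likelihood's scale ridge", {
  p <- c(nuA = 0.1, nu1 = 0.2, nu2 = 1, T = 0.05, s = 0.3, m12 = 2, m21 = 4)
  pc <- canonical_params(p, theta_hat = 2000, theta_ref = 500)
  expect_equal(unname(pc[c("nuA", "nu1", "nu2", "T")]),
               c(0.4, 0.8, 4, 0.2))
  expect_equal(unname(pc[c("m12", "m21")]), c(0.5, 1))
  expect_equal(pc[["s"]], 0.3)   # ratios are scale-free
})
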