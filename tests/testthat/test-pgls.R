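# Phylogenetic GLS: estimator correctness, transform profiling, MCMC
# regression, mass threshold, Brownian ancestral states.

test_that("gls_fit reduces to OLS under identity covariance", {
  set.seed(1)
  n <- 25
  X <- cbind(intercept = 1, Orna = rbinom(n, 1, 0.4))
  y <- 1 + 2 * X[, 2] + rnorm(n)
  f <- gls_fit(y, X, diag(n))
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)
  # and lambda = 0 gives the same thing through the transform pathway
  tr <- shared_tree(25, seed = 21)
  C0 <- apply_transforms(tr, lambda = 0)
  f0 <- gls_fit(y, X, C0 / diag(C0)[1])  # equal depths not guaranteed;
  # instead check the property on an ultrametric tree
  tru <- sim_bd_tree(25, 0.1, 0, seed = 22)
  Cu <- apply_transforms(tru, lambda = 0)
  fu <- gls_fit(y, X, Cu)
  expect_equal(unname(fu$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("gls_fit handles perfect fits and singular designs", {
  n <- 10
  X <- cbind(intercept = 1, Orna = rep(c(0, 1), 5))
  y <- 3 + 2 * X[, 2]
  f <- gls_fit(y, X, diag(n))
  expect_equal(f$sigma2, 0)
  expect_equal(max(abs(f$residuals)), 0)

  Xs <- cbind(X, dup = X[, 2])
  expect_error(gls_fit(rnorm(n), Xs, diag(n)), "collinear")
})

test_that("gls_fit matches a brute-force MVN optimizer", {
  set.seed(23)
  tr <- sim_bd_tree(10, 0.1, 0.03, seed = 24)
  C <- phylo_vcv(tr)
  X <- cbind(intercept = 1, Orna = rbinom(10, 1, 0.5))
  y <- as.numeric(2 + 1.5 * X[, 2] + t(chol(0.3 * C)) %*% rnorm(10))
  f <- gls_fit(y, X, C)
  # independent oracle: numerically maximize the MVN log density over
  # (beta, log sigma2)
  nll <- function(p) {
    m <- X %*% p[1:2]
    -mvn_logdens(y, as.numeric(m), exp(p[3]) * C)
  }
  mvn_logdens <- function(v, m, S)
    -0.5 * (length(v) * log(2 * pi) + determinant(S)$modulus[1] +
              t(v - m) %*% solve(S) %*% (v - m))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(unname(f$coefficients), opt$par[1:2], tolerance = 1e-6)
  expect_equal(log(f$sigma2), opt$par[3], tolerance = 1e-5)
  expect_equal(f$logL, -opt$value, tolerance = 1e-8)
})

test_that("BM-GLS equivalence holds across random datasets", {
  # identity transforms reproduce untransformed BM covariance fits
  tr <- shared_tree(20, seed = 25)
  C <- phylo_vcv(tr)
  set.seed(26)
  for (i in 1:5) {
    X <- cbind(intercept = 1, Orna = rbinom(20, 1, 0.4))
    y <- as.numeric(1 + X[, 2] + t(chol(0.2 * C)) %*% rnorm(20))
    f1 <- gls_fit(y, X, C)
    f2 <- gls_fit(y, X, apply_transforms(tr, 1, 1, 1))
    expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
    expect_true(f1$r2 >= 0 && f1$r2 <= 1)
  }
})

test_that("pgls_ml profiles transforms and recovers generating values", {
  # near-noiseless regime means: coefficients recovered to 2 decimals
  tr <- shared_tree(60, seed = 27)
  orn <- sim_mk(tr, make_q_binary(0.01, 0.01), seed = 28)$states
  o01 <- setNames(as.integer(orn == "1"), names(orn))
  y <- sim_pgls(tr, o01, 1.98, 2.09, lambda = 1, sigma2 = 1e-6, seed = 29)
  tab <- data.frame(taxon = tr$tip.label, ornamented = o01[tr$tip.label],
                    log_mass = y[tr$tip.label], maniraptoriform = 0)
  f <- pgls_ml(tab, tr, transforms = c("lambda", "kappa"))
  expect_equal(unname(f$fit$coefficients), c(1.98, 2.09), tolerance = 5e-3)

  # lambda = 1 BM truth: profiled lambda near the upper boundary
  y2 <- sim_pgls(tr, o01, 1.98, 2.09, lambda = 1, sigma2 = 0.03, seed = 30)
  tab2 <- tab; tab2$log_mass <- y2[tr$tip.label]
  f2 <- pgls_ml(tab2, tr, transforms = "lambda")
  expect_gte(f2$fit$transforms$lambda, 0.8)

  # empty transform set on an ultrametric star-like comparison: plain GLS
  f3 <- pgls_ml(tab2, tr, transforms = character(0))
  expect_equal(f3$fit$transforms$lambda, 1)
  expect_equal(f3$score$K, 3)

  set <- pgls_model_set(tab2, tr, subsets = list(character(0), "lambda",
                                                 c("lambda", "kappa")))
  expect_equal(sum(set$table$weight), 1, tolerance = 1e-12)
})

test_that("pgls_mcmc detects a strong effect and is calibrated under the null", {
  tr <- shared_tree(100, seed = 210)
  orn <- sim_mk(tr, make_q_binary(0.01, 0.01), seed = 211)$states
  o01 <- setNames(as.integer(orn == "1"), names(orn))
  y1 <- sim_pgls(tr, o01, 2, 2, lambda = 0.9, sigma2 = 0.03, seed = 212)
  tab1 <- data.frame(taxon = tr$tip.label, ornamented = o01[tr$tip.label],
                     log_mass = y1[tr$tip.label], maniraptoriform = 0)
  p1 <- pgls_mcmc(tab1, tr, transforms = "lambda", iterations = 2500,
                  thin = 5, burnin = 500, seed = 213)
  orna1 <- p1$summary[p1$summary$parameter == "Orna", ]
  expect_gte(orna1$prop_gt0, 0.975)
  # draw bookkeeping: (iterations - burnin) / thin rows
  expect_equal(nrow(p1$draws), (2500 - 500) / 5)
  # single tree: constant index
  expect_equal(unique(p1$draws$tree_index), 1L)

  y0 <- sim_pgls(tr, o01, 2, 0, lambda = 0.9, sigma2 = 0.03, seed = 214)
  tab0 <- tab1; tab0$log_mass <- y0[tr$tip.label]
  p0 <- pgls_mcmc(tab0, tr, transforms = "lambda", iterations = 2500,
                  thin = 5, burnin = 500, seed = 215)
  orna0 <- p0$summary[p0$summary$parameter == "Orna", ]
  expect_lt(orna0$lo95, 0)       # 95% interval covers zero
  expect_gt(orna0$hi95, 0)
  expect_lt(abs(orna0$median), 0.75)

  # the zero-slope null used for Bayes factors really drops the term
  pn <- pgls_mcmc(tab1, tr, transforms = "lambda", iterations = 1000,
                  thin = 5, burnin = 200, seed = 216, drop_terms = "Orna")
  expect_false("Orna" %in% pn$summary$parameter)
})

test_that("posterior means agree with ML estimates on large samples", {
  tr <- sim_bd_tree(200, 0.065, 0.035, seed = 220)
  orn <- sim_mk(tr, make_q_binary(0.01, 0.01), seed = 221)$states
  o01 <- setNames(as.integer(orn == "1"), names(orn))
  y <- sim_pgls(tr, o01, 2, 1.8, lambda = 0.9, sigma2 = 0.05, seed = 222)
  tab <- data.frame(taxon = tr$tip.label, ornamented = o01[tr$tip.label],
                    log_mass = y[tr$tip.label], maniraptoriform = 0)
  ml <- pgls_ml(tab, tr, transforms = "lambda")
  pm <- pgls_mcmc(tab, tr, transforms = "lambda", iterations = 3000,
                  thin = 5, burnin = 600, seed = 223)
  expect_equal(mean(pm$draws$Orna), unname(ml$fit$coefficients["Orna"]),
               tolerance = 0.1)
})

test_that("ornamented-mass threshold back-transforms the coefficients", {
  f <- structure(list(coefficients = c(intercept = 0, Orna = 0)),
                 class = "gls_fit")
  expect_equal(unname(ornament_mass_threshold(f)["threshold_kg"]), 1)
  f$coefficients <- c(intercept = 1.98, Orna = 2.09)
  expect_equal(unname(ornament_mass_threshold(f)["threshold_kg"]),
               exp(4.07), tolerance = 1e-12)
  f$coefficients <- c(intercept = 1.97, Orna = 2.04)
  expect_equal(unname(ornament_mass_threshold(f)["threshold_kg"]), 55.2,
               tolerance = 0.002)   # 55.15 at printed precision
  f$coefficients <- c(intercept = 1)
  expect_error(ornament_mass_threshold(f), "Orna")
})

test_that("Brownian ancestral estimates match closed forms and the MVN oracle", {
  t2 <- parse_newick("(A:1,B:1);")
  est <- bm_ancestral_estimate(t2, c(A = 0, B = 4), 3)
  expect_equal(unname(est["mean"]), 2)

  # unequal branches: inverse-branch-length weighting
  t3 <- parse_newick("(A:1,B:3);")
  est3 <- bm_ancestral_estimate(t3, c(A = 0, B = 4), 3)
  expect_equal(unname(est3["mean"]), (0 / 1 + 4 / 3) / (1 + 1 / 3))

  expect_error(bm_ancestral_estimate(t3, c(A = 0, B = 4), 1), "internal")

  # 20-tip tree vs brute-force conditional MVN mean (plug-in GLS root)
  tr <- shared_tree(20, seed = 218)
  x <- sim_hansen(sim_mk(tr, make_q_binary(0, 0), seed = 1)$map,
                  list(alpha = 0, sigma2 = 1, x0 = 0), seed = 219)
  node <- 25L
  est20 <- bm_ancestral_estimate(tr, x, node)
  C <- phylo_vcv(tr)
  depth <- node_depths(tr)
  mu <- as.numeric(solve(t(rep(1, 20)) %*% solve(C) %*% rep(1, 20),
                         t(rep(1, 20)) %*% solve(C) %*% x[tr$tip.label]))
  # covariance of the node with each tip = depth of the common path
  paths <- ornamass:::.root_paths(tr)
  cn <- vapply(1:20, function(i)
    max(depth[intersect(paths[[node]], paths[[i]])]), numeric(1))
  cond_mean <- mu + as.numeric(cn %*% solve(C, x[tr$tip.label] - mu))
  expect_equal(unname(est20["mean"]), cond_mean, tolerance = 1e-8)

  # root estimate agrees with the independent ape implementation
  root_ml <- ape::ace(x[tr$tip.label], tr, method = "ML")$ace[1]
  est_root <- bm_ancestral_estimate(tr, x, 21L)
  expect_equal(unname(est_root["mean"]), unname(root_ml), tolerance = 1e-4)
})
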