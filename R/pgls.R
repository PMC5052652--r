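# Phylogenetic generalized least squares: Cholesky GLS core, ML profiling
# of the Pagel transform parameters, Metropolis-within-Gibbs regression over
# a set of time-scaled trees (the phylogenetic t-test / ANOVA), the
# ornamented-mass threshold back-transform, and Brownian ancestral states.

#' Build a design matrix from named terms
#'
#' Terms are drawn from \code{intercept} (column of ones), \code{Orna}
#' (ornamentation 0/1), \code{Phylo} (Maniraptoriformes membership 0/1)
#' and \code{Orna:Phylo} (interaction).
#'
#' @param tab a trait table in tree order (see [match_traits()]).
#' @param terms character vector of term names.
#' @return numeric matrix with one column per term.
#' @export
build_design <- function(tab, terms = c("intercept", "Orna")) {
  cols <- lapply(terms, function(tm) switch(tm,
    intercept    = rep(1, nrow(tab)),
    Orna         = tab$ornamented,
    Phylo        = tab$maniraptoriform,
    `Orna:Phylo` = tab$ornamented * tab$maniraptoriform,
    stop("unknown design term: ", tm)))
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Generalized least squares under a phylogenetic covariance
#'
#' Fits \eqn{y = X\beta + e}, \eqn{e \sim N(0, \sigma^2 C)} by whitening
#' with the Cholesky factor of \code{C} (no explicit inverse). \eqn{\sigma^2}
#' is the ML residual rate (RSS/n in the whitened space) and \code{logL}
#' the multivariate-normal log density at the optimum. \code{r2} is the
#' generalized \eqn{R^2 = 1 - RSS/TSS} computed in the whitened space, with
#' TSS from the GLS intercept-only model; \code{epsilon} is the whitened
#' residual standard deviation.
#'
#' @param y response vector (here log_e body mass).
#' @param X design matrix (see [build_design()]).
#' @param C phylogenetic covariance, positive definite, in \code{y} order.
#' @return an object of class \code{"gls_fit"}: coefficients, sigma2, logL,
#'   r2, epsilon, n, residuals (whitened).
#' @export
gls_fit <- function(y, X, C) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is not positive definite (",
         conditionMessage(e), ")", call. = FALSE))
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw))
    stop("singular design: column '",
         colnames(X)[qrX$pivot[qrX$rank + 1]], "' is collinear")
  beta <- qr.coef(qrX, yw)
  resw <- yw - Xw %*% beta
  rss <- sum(resw^2)
  sigma2 <- rss / n
  logdetC <- 2 * sum(log(diag(L)))
  logL <- if (sigma2 > 0)
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  else Inf  # perfect fit: density degenerates
  # generalized R^2 against the GLS intercept-only model
  onew <- backsolve(L, rep(1, n), transpose = TRUE)
  mu0 <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - onew * mu0)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2 <- min(max(r2, 0), 1)
  structure(list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
                 sigma2 = sigma2, logL = logL, r2 = r2,
                 epsilon = sqrt(rss / max(n - ncol(X), 1)),
                 n = n, residuals = as.numeric(resw)),
            class = "gls_fit")
}

# log-likelihood of the GLS model for given transform parameters
.pgls_objective <- function(par, tnames, y, X, tree) {
  tp <- list(lambda = 1, kappa = 1, delta = 1)
  tp[tnames] <- as.list(par)
  C <- apply_transforms(tree, tp$lambda, tp$kappa, tp$delta)
  f <- tryCatch(gls_fit(y, X, C), error = function(e) NULL)
  if (is.null(f) || !is.finite(f$logL)) return(1e10)
  -f$logL
}

#' Maximum-likelihood PGLS with profiled Pagel transforms
#'
#' Profiles any subset of (\eqn{\lambda}, \eqn{\kappa}, \eqn{\delta}) by
#' bounded numerical optimization (multi-start \code{optim(L-BFGS-B)}),
#' refitting the GLS at each evaluation, and attaches an information score
#' with \code{K = ncol(X) + 1 +} number of profiled transforms and
#' \code{n =} number of taxa.
#'
#' @param tab trait table; @param tree dated \code{"phylo"}.
#' @param formula character vector of design terms (see [build_design()]).
#' @param transforms subset of \code{c("lambda", "kappa", "delta")}
#'   (possibly empty: plain Brownian GLS).
#' @param response column of \code{tab} used as response.
#' @return list with elements \code{fit} (a \code{"gls_fit"} carrying a
#'   \code{transforms} element), \code{score} (one-row data frame with
#'   logL, K, AICc).
#' @export
pgls_ml <- function(tab, tree, formula = c("intercept", "Orna"),
                    transforms = c("lambda", "kappa"),
                    response = "log_mass") {
  tab <- match_traits(tab, tree)
  y <- tab[[response]]
  X <- build_design(tab, formula)
  bounds <- list(lambda = c(0, 1), kappa = c(1e-4, 3), delta = c(1e-4, 3))
  tnames <- transforms
  if (length(tnames) == 0) {
    C <- phylo_vcv(tree)
    fit <- gls_fit(y, X, C)
    fit$transforms <- list(lambda = 1, kappa = 1, delta = 1)
  } else {
    lo <- vapply(bounds[tnames], `[`, numeric(1), 1)
    hi <- vapply(bounds[tnames], `[`, numeric(1), 2)
    starts <- list(stats::setNames(rep(1, length(tnames)) * 0.9, tnames),
                   stats::setNames((lo + hi) / 2, tnames),
                   stats::setNames(lo + 0.9 * (hi - lo), tnames))
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(pmin(pmax(s, lo), hi), .pgls_objective,
                     tnames = tnames, y = y, X = X, tree = tree,
                     method = "L-BFGS-B", lower = lo, upper = hi),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best))
      stop("transform optimization failed to converge from any start")
    tp <- list(lambda = 1, kappa = 1, delta = 1)
    tp[tnames] <- as.list(best$par)
    fit <- gls_fit(y, X, apply_transforms(tree, tp$lambda, tp$kappa, tp$delta))
    fit$transforms <- tp
  }
  K <- ncol(X) + 1 + length(tnames)
  score <- information_scores(
    data.frame(model = paste(c("GLS", tnames), collapse = "+"),
               logL = fit$logL, K = K),
    n = length(y), corrected = TRUE)
  list(fit = fit, score = score)
}

#' Compare PGLS transform subsets by AICc weight
#'
#' Fits [pgls_ml()] for each requested transform subset and tabulates
#' AICc, delta and Akaike weights.
#'
#' @inheritParams pgls_ml
#' @param subsets list of character vectors, default all 8 subsets of
#'   \code{lambda, kappa, delta}.
#' @return list: \code{table} (data frame sorted by AICc), \code{fits}.
#' @export
pgls_model_set <- function(tab, tree, formula = c("intercept", "Orna"),
                           subsets = NULL, response = "log_mass") {
  if (is.null(subsets)) {
    base <- c("lambda", "kappa", "delta")
    subsets <- unlist(lapply(0:3, function(k)
      utils::combn(base, k, simplify = FALSE)), recursive = FALSE)
  }
  fits <- lapply(subsets, function(s)
    pgls_ml(tab, tree, formula, transforms = s, response = response))
  lab <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = "+") else "none", character(1))
  sc <- information_scores(
    data.frame(model = lab,
               logL = vapply(fits, function(f) f$fit$logL, numeric(1)),
               K = vapply(fits, function(f) f$score$K, numeric(1))),
    n = nrow(match_traits(tab, tree)), corrected = TRUE)
  names(fits) <- lab
  list(table = sc[order(sc$AICc), ], fits = fits)
}

#' Bayesian PGLS regression over a set of time-scaled trees
#'
#' Metropolis-within-Gibbs sampler for the PGLS model: block random-walk
#' updates of the coefficients, log \eqn{\sigma^2}, and two Pagel
#' transform parameters (\eqn{\lambda} with either \eqn{\kappa} or
#' \eqn{\delta}); a tree index is drawn uniformly at random each iteration
#' so calibration uncertainty propagates into the posterior. Coefficient
#' priors are uniform on \code{(-100, 100)}; \eqn{\log\sigma^2} uniform on
#' a wide bound; transform priors uniform on their ranges. Proposal scales
#' adapt during burn-in only.
#'
#' @inheritParams pgls_ml
#' @param trees a list of dated trees (or a single tree).
#' @param transforms \code{c("lambda","kappa")} or \code{c("lambda","delta")}
#'   (or fewer).
#' @param iterations,thin,burnin chain settings (iterations counts
#'   post-nothing total updates; samples retained every \code{thin} after
#'   \code{burnin}).
#' @param seed integer seed (mandatory for reproducibility).
#' @param drop_terms terms forced out of the model (e.g. \code{"Orna"} to
#'   run the slope-forced-to-zero null for a Bayes factor test).
#' @param coef_prior numeric length-2, uniform prior bounds on every
#'   coefficient.
#' @return an object of class \code{"posterior_sample"}: \code{draws}
#'   (data frame of coefficients, sigma2, transforms, tree index, logL),
#'   \code{summary} (median, 95\% interval, proportion > 0 per parameter),
#'   \code{logL_trace}, \code{accept}.
#' @export
pgls_mcmc <- function(tab, trees, formula = c("intercept", "Orna"),
                      transforms = c("lambda", "kappa"),
                      iterations = 11000, thin = 10, burnin = 1000,
                      seed = 1, drop_terms = character(0),
                      coef_prior = c(-100, 100),
                      response = "log_mass") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, iterations > burnin, thin >= 1)
  formula <- setdiff(formula, drop_terms)
  tab0 <- match_traits(tab, trees[[1]])
  y <- tab0[[response]]
  X <- build_design(tab0, formula)
  p <- ncol(X)
  set.seed(seed)

  bounds <- list(lambda = c(0, 1), kappa = c(1e-4, 3), delta = c(1e-4, 3))
  tnames <- transforms
  ls2_bounds <- c(log(1e-8), log(1e8))

  # cache covariances per (tree, transform-params) is impossible; instead
  # precompute per-tree edge data once via closure over apply_transforms
  loglik <- function(beta, ls2, tpar, ti) {
    tp <- list(lambda = 1, kappa = 1, delta = 1)
    tp[tnames] <- as.list(tpar)
    C <- apply_transforms(trees[[ti]], tp$lambda, tp$kappa, tp$delta)
    L <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
    yw <- backsolve(L, y - X %*% beta, transpose = TRUE)
    s2 <- exp(ls2)
    -0.5 * (length(y) * log(2 * pi) + length(y) * ls2 +
              2 * sum(log(diag(L))) + sum(yw^2) / s2)
  }

  # initial state from an OLS-ish fit
  beta <- as.numeric(qr.coef(qr(X), y))
  ls2 <- log(max(stats::var(y - X %*% beta), 1e-4))
  tpar <- stats::setNames(vapply(tnames, function(nm)
    mean(bounds[[nm]]), numeric(1)), tnames)
  ti <- sample.int(length(trees), 1)
  ll <- loglik(beta, ls2, tpar, ti)
  if (!is.finite(ll)) stop("non-finite likelihood at initial state")

  scales <- list(beta = rep(0.5, p), ls2 = 0.5,
                 tpar = rep(0.1, length(tnames)))
  acc <- c(beta = 0, ls2 = 0, tpar = 0); try_n <- c(beta = 0, ls2 = 0, tpar = 0)

  keep <- floor((iterations - burnin) / thin)
  draws <- matrix(NA_real_, keep, p + 2 + length(tnames))
  colnames(draws) <- c(colnames(X), "sigma2", tnames, "logL")
  tree_idx <- integer(keep)
  kept <- 0L

  for (it in seq_len(iterations)) {
    ti <- sample.int(length(trees), 1)
    ll <- loglik(beta, ls2, tpar, ti)
    # coefficients, elementwise RW
    for (j in seq_len(p)) {
      prop <- beta; prop[j] <- beta[j] + stats::rnorm(1, 0, scales$beta[j])
      try_n["beta"] <- try_n["beta"] + 1
      if (prop[j] > coef_prior[1] && prop[j] < coef_prior[2]) {
        llp <- loglik(prop, ls2, tpar, ti)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
          beta <- prop; ll <- llp; acc["beta"] <- acc["beta"] + 1
        }
      }
    }
    # log sigma2
    prop <- ls2 + stats::rnorm(1, 0, scales$ls2)
    try_n["ls2"] <- try_n["ls2"] + 1
    if (prop > ls2_bounds[1] && prop < ls2_bounds[2]) {
      llp <- loglik(beta, prop, tpar, ti)
      if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
        ls2 <- prop; ll <- llp; acc["ls2"] <- acc["ls2"] + 1
      }
    }
    # transforms
    for (j in seq_along(tnames)) {
      prop <- tpar
      prop[j] <- tpar[j] + stats::rnorm(1, 0, scales$tpar[j])
      try_n["tpar"] <- try_n["tpar"] + 1
      b <- bounds[[tnames[j]]]
      if (prop[j] > b[1] && prop[j] < b[2]) {
        llp <- loglik(beta, ls2, prop, ti)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
          tpar <- prop; ll <- llp; acc["tpar"] <- acc["tpar"] + 1
        }
      }
    }
    # adapt during burn-in only
    if (it <= burnin && it %% 100 == 0) {
      for (nm in names(scales)) {
        r <- acc[nm] / max(try_n[nm], 1)
        f <- if (r > 0.5) 1.3 else if (r < 0.2) 0.7 else 1
        scales[[nm]] <- scales[[nm]] * f
      }
      acc[] <- 0; try_n[] <- 0
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(beta, exp(ls2), tpar, ll)
      tree_idx[kept] <- ti
    }
  }
  draws <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  draws$tree_index <- tree_idx[seq_len(kept)]
  rate <- acc / pmax(try_n, 1)
  if (any(rate < 0.05 | rate > 0.7))
    warning("acceptance rate outside [0.05, 0.7] after adaptation: ",
            paste(sprintf("%s=%.2f", names(rate), rate), collapse = ", "))
  pars <- setdiff(colnames(draws), c("logL", "tree_index"))
  summ <- do.call(rbind, lapply(pars, function(nm) {
    v <- draws[[nm]]
    data.frame(parameter = nm, median = stats::median(v),
               lo95 = stats::quantile(v, 0.025), hi95 = stats::quantile(v, 0.975),
               prop_gt0 = mean(v > 0), row.names = NULL)
  }))
  structure(list(draws = draws, summary = summ,
                 logL_trace = draws$logL, accept = rate,
                 formula = formula, transforms = tnames),
            class = "posterior_sample")
}

#' Minimum ornamented body mass implied by a PGLS fit (kg)
#'
#' Back-transforms \code{exp(intercept + Orna coefficient)}: the model's
#' predicted mass for an ornamented taxon, interpreted as the body-mass
#' threshold below which ornaments are not expected. For a posterior
#' sample the median and a 95\% interval are returned. Prediction through
#' PGLS is a generalization of the fitted model, not a forecast; a warning
#' attribute says so.
#'
#' @param fit a \code{"gls_fit"} or \code{"posterior_sample"} containing
#'   \code{intercept} and \code{Orna} terms.
#' @return named numeric: \code{threshold_kg} (plus \code{lo95}/\code{hi95}
#'   for posteriors), with attribute \code{note}.
#' @export
ornament_mass_threshold <- function(fit) {
  note <- "PGLS prediction is approximate; treat as a generalization of the fitted model"
  if (inherits(fit, "gls_fit")) {
    b <- fit$coefficients
    if (!all(c("intercept", "Orna") %in% names(b)))
      stop("model must contain intercept and Orna terms")
    out <- c(threshold_kg = unname(exp(b["intercept"] + b["Orna"])))
  } else if (inherits(fit, "posterior_sample")) {
    d <- fit$draws
    if (!all(c("intercept", "Orna") %in% names(d)))
      stop("model must contain intercept and Orna terms")
    v <- exp(d$intercept + d$Orna)
    out <- c(threshold_kg = stats::median(v),
             lo95 = unname(stats::quantile(v, 0.025)),
             hi95 = unname(stats::quantile(v, 0.975)))
  } else stop("fit must be a gls_fit or posterior_sample")
  attr(out, "note") <- note
  out
}

#' Brownian-motion ancestral estimate at an internal node
#'
#' GLS reconstruction: the root state is estimated by GLS over the tips,
#' the trait rate \eqn{\sigma^2} by ML, and the node value by the
#' conditional multivariate-normal mean and variance given the tips.
#'
#' @param tree dated \code{"phylo"}.
#' @param x named tip values (names matching tip labels) or vector in tip
#'   order.
#' @param node internal node number (\code{ape} numbering,
#'   \code{Ntip+1} = root).
#' @return c(mean, variance).
#' @export
bm_ancestral_estimate <- function(tree, x, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) stop("node must be internal (tips are 1..", ntip, ")")
  if (!is.null(names(x))) x <- x[tree$tip.label]
  stopifnot(length(x) == ntip, !anyNA(x))
  C <- phylo_vcv(tree)
  depth <- node_depths(tree)
  # cov(node, tip) = depth of the deepest node on both root paths
  paths <- .root_paths(tree)
  cn <- vapply(seq_len(ntip), function(i) {
    shared <- intersect(paths[[node]], paths[[i]])
    max(depth[shared])
  }, numeric(1))
  L <- chol(C)
  one <- rep(1, ntip)
  Ci_x <- backsolve(L, backsolve(L, x, transpose = TRUE))
  Ci_1 <- backsolve(L, backsolve(L, one, transpose = TRUE))
  mu <- sum(Ci_x) / sum(Ci_1)              # GLS root estimate
  res <- x - mu
  Ci_r <- backsolve(L, backsolve(L, res, transpose = TRUE))
  sigma2 <- sum(res * Ci_r) / ntip         # ML rate
  m <- mu + sum(cn * Ci_r)
  Ci_c <- backsolve(L, backsolve(L, cn, transpose = TRUE))
  # conditional variance given the tips, plus root-estimate uncertainty
  g <- 1 - sum(cn * Ci_1)
  v <- sigma2 * (depth[node] - sum(cn * Ci_c) + g^2 / sum(Ci_1))
  c(mean = m, variance = max(v, 0))
}

# list of root-path node sets (including the node itself and the root)
.root_paths <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(ntip + tree$Nnode), function(n) {
    path <- n
    while (n != root) { n <- parent[n]; path <- c(path, n) }
    path
  })
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit\n  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma2 = %.4g, logL = %.3f, R2 = %.3f, epsilon = %.3f\n",
              x$sigma2, x$logL, x$r2, x$epsilon))
  if (!is.null(x$transforms))
    cat(sprintf("  transforms: lambda = %.3f, kappa = %.3f, delta = %.3f\n",
                x$transforms$lambda, x$transforms$kappa, x$transforms$delta))
  invisible(x)
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample (", nrow(x$draws), " draws)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
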