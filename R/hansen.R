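# Generalized Hansen models: Ornstein-Uhlenbeck trait evolution with
# regime-specific optima painted on the tree by a stochastic map. The mean
# vector accumulates exponentially-weighted optimum contributions along
# each root-to-tip path segment by segment; the covariance accumulates
# per-segment OU/BM variance, discounted tipward, which handles
# non-ultrametric (fossil-tip) trees naturally.

.hansen_models <- c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")

# regimes present in a simmap painting
simmap_regimes <- function(map) {
  sort(unique(unlist(lapply(map$maps, names))))
}

# regime at the rootward end of the tree (oldest segment's state)
.root_regime <- function(map) {
  root <- ape::Ntip(map) + 1L
  e <- which(map$edge[, 1] == root)[1]
  names(map$maps[[e]])[1]
}

# expand model parameters to per-regime named vectors; validates shape
.hansen_pars <- function(model, params, regimes, root_mode) {
  m <- length(regimes)
  expand <- function(v, what, per_regime) {
    if (per_regime) {
      if (length(v) == m && !is.null(names(v))) return(v[regimes])
      if (length(v) == m) return(stats::setNames(v, regimes))
      stop(what, " must have one value per regime (", m, ") for ", model)
    }
    if (length(v) != 1) stop(what, " must be scalar for ", model)
    stats::setNames(rep(v, m), regimes)
  }
  is_ou <- !model %in% c("BM1", "BMS")
  if (is_ou) {
    if (is.null(params$alpha) || any(params$alpha <= 0))
      stop("alpha must be > 0 for OU models; use the BM variants (BM1/BMS) ",
           "for alpha = 0")
  }
  alpha <- if (!is_ou) stats::setNames(rep(0, m), regimes)
           else expand(params$alpha, "alpha", model %in% c("OUMA", "OUMVA"))
  sigma2 <- expand(params$sigma2, "sigma2",
                   model %in% c("BMS", "OUMV", "OUMVA"))
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  theta <- if (!is_ou) NULL
           else expand(params$theta, "theta",
                       model %in% c("OUM", "OUMV", "OUMA", "OUMVA"))
  stationary <- is_ou && root_mode == "stationary"
  x0 <- if (stationary) NULL else params$x0
  if (!stationary && is.null(x0)) stop("x0 (root value) required")
  list(alpha = alpha, sigma2 = sigma2, theta = theta, x0 = x0,
       stationary = stationary)
}

# cacheable traversal structure of a simmap tree
.hansen_struct <- function(map) {
  eo <- ape::reorder.phylo(map, "postorder")
  key_orig <- paste(map$edge[, 1], map$edge[, 2])
  key_post <- paste(eo$edge[, 1], eo$edge[, 2])
  list(ntip = ape::Ntip(map), nnode = map$Nnode,
       edge_post = eo$edge,
       post2orig = match(key_post, key_orig),
       mrca = ape::mrca(map),
       root_regime = .root_regime(map))
}

# per-tip mean, per-node accumulated variance and discount factors
.hansen_moments <- function(map, alpha, sigma2, theta, x0, stationary,
                            str = NULL) {
  if (is.null(str)) str <- .hansen_struct(map)
  ntip <- str$ntip
  nnode <- str$nnode
  root <- ntip + 1L
  A <- numeric(ntip + nnode)       # cumulative alpha integral from root
  M <- numeric(ntip + nnode)       # mean value at node
  V <- numeric(ntip + nnode)       # accumulated variance at node
  rreg <- str$root_regime
  if (stationary) {
    M[root] <- theta[[rreg]]
    V[root] <- sigma2[[rreg]] / (2 * alpha[[rreg]])
  } else {
    M[root] <- x0
    V[root] <- 0
  }
  for (kk in rev(seq_len(nrow(str$edge_post)))) {    # preorder
    p <- str$edge_post[kk, 1]; ch <- str$edge_post[kk, 2]
    segs <- map$maps[[str$post2orig[kk]]]
    a <- A[p]; mval <- M[p]; v <- V[p]
    for (si in seq_along(segs)) {
      reg <- names(segs)[si]; tt <- segs[si]
      al <- alpha[[reg]]; s2 <- sigma2[[reg]]
      if (al > 0) {
        e1 <- exp(-al * tt)
        mval <- mval * e1 + theta[[reg]] * (1 - e1)
        v <- v * e1^2 + s2 * (1 - e1^2) / (2 * al)
        a <- a + al * tt
      } else {
        v <- v + s2 * tt
      }
    }
    A[ch] <- a; M[ch] <- mval; V[ch] <- v
  }
  list(A = A, M = M, V = V)
}

#' Log-likelihood of a generalized Hansen (multi-regime OU) model
#'
#' Computes the multivariate-normal log density of tip values under a
#' regime-painted OU/BM model. Mean: each root-to-tip path accumulates
#' \eqn{\theta} contributions weighted \eqn{(1 - e^{-\alpha t})} per
#' segment, discounted by the downstream attraction. Covariance:
#' per-segment variance \eqn{\sigma^2 (1 - e^{-2\alpha t})/(2\alpha)}
#' (or \eqn{\sigma^2 t} for BM segments) accumulated to the pairwise MRCA
#' and discounted by \eqn{e^{-\alpha}} integrals to each tip.
#' \code{root_mode = "stationary"} starts the root in the stationary
#' distribution of its regime (\eqn{\theta} mean, \eqn{\sigma^2/2\alpha}
#' variance, no free root value); \code{"estimated"} adds the root value
#' \code{x0} as a parameter.
#'
#' @param map a \code{"simmap"} tree (see [stochastic_maps()]).
#' @param x named tip values.
#' @param params list with elements among \code{alpha}, \code{sigma2},
#'   \code{theta} (scalar or per-regime named vectors as the model
#'   requires) and \code{x0}.
#' @param model one of BM1, BMS, OU1, OUM, OUMV, OUMA, OUMVA.
#' @param root_mode \code{"estimated"} or \code{"stationary"}.
#' @param str optional precomputed traversal structure (internal cache).
#' @return log-likelihood (nats).
#' @export
hansen_loglik <- function(map, x, params,
                          model = c("OUMV", "BM1", "BMS", "OU1", "OUM",
                                    "OUMA", "OUMVA"),
                          root_mode = c("estimated", "stationary"),
                          str = NULL) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  regimes <- simmap_regimes(map)
  pp <- .hansen_pars(model, params, regimes, root_mode)
  if (is.null(str)) str <- .hansen_struct(map)
  ntip <- str$ntip
  xv <- if (!is.null(names(x))) as.numeric(x[map$tip.label]) else as.numeric(x)
  stopifnot(length(xv) == ntip, !anyNA(xv))
  mo <- .hansen_moments(map, pp$alpha, pp$sigma2, pp$theta, pp$x0,
                        pp$stationary, str = str)
  D <- exp(-mo$A)
  mr <- str$mrca
  # V[mrca] * (D_i / D_mrca) * (D_j / D_mrca), vectorized over the matrix
  am <- mr[seq_len(ntip), seq_len(ntip)]
  Vm <- matrix(mo$V[am] / (D[am]^2), ntip, ntip) *
    tcrossprod(D[seq_len(ntip)])
  diag(Vm) <- mo$V[seq_len(ntip)]
  L <- tryCatch(chol(Vm), error = function(e)
    stop("non-positive-definite OU covariance (", conditionMessage(e), ")",
         call. = FALSE))
  z <- backsolve(L, xv - mo$M[seq_len(ntip)], transpose = TRUE)
  -0.5 * (ntip * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# free-parameter count by model and root mode
.hansen_K <- function(model, m, root_mode) {
  est <- if (model %in% c("BM1", "BMS")) 1L
         else if (root_mode == "estimated") 1L else 0L
  switch(model,
         BM1 = 1L + est, BMS = m + est,
         OU1 = 2L + 1L + est,
         OUM = 2L + m + est,
         OUMV = 1L + m + m + est,
         OUMA = m + 1L + m + est,
         OUMVA = m + m + m + est)
}

#' Fit a generalized Hansen model by multi-start ML
#'
#' Bounded optimization over log \eqn{\alpha}, log \eqn{\sigma^2} and the
#' free means, from several seeded starting points (the parameter surface
#' of multi-peak OU models is notoriously multimodal). Standard errors
#' come from the numerical Hessian at the optimum; when it is not
#' invertible, SEs are reported absent and a flag is raised. Diagnostics
#' from [sanity_flags()] are attached.
#'
#' @inheritParams hansen_loglik
#' @param nstarts number of optimization starts.
#' @param seed integer seed for start jitter.
#' @return object of class \code{"hansen_fit"}: model, root_mode, alpha,
#'   sigma2, theta, x0, se (named), logL, score, flags.
#' @export
fit_hansen <- function(map, x, model = "OUMV",
                       root_mode = c("estimated", "stationary"),
                       nstarts = 5, seed = 1) {
  root_mode <- match.arg(root_mode)
  if (model %in% c("BM1", "BMS")) root_mode <- "estimated"
  regimes <- simmap_regimes(map)
  m <- length(regimes)
  ntip <- ape::Ntip(map)
  xv <- if (!is.null(names(x))) as.numeric(x[map$tip.label]) else as.numeric(x)
  set.seed(seed)
  is_ou <- !model %in% c("BM1", "BMS")
  n_alpha <- if (!is_ou) 0L else if (model %in% c("OUMA", "OUMVA")) m else 1L
  n_sig <- if (model %in% c("BMS", "OUMV", "OUMVA")) m else 1L
  n_theta <- if (!is_ou) 0L else if (model == "OU1") 1L else m
  has_x0 <- !is_ou || root_mode == "estimated"

  unpack <- function(par) {
    i <- 0L
    alpha <- if (n_alpha) exp(par[i + seq_len(n_alpha)]) else NULL
    i <- i + n_alpha
    sigma2 <- exp(par[i + seq_len(n_sig)]); i <- i + n_sig
    theta <- if (n_theta) par[i + seq_len(n_theta)] else NULL
    i <- i + n_theta
    x0 <- if (has_x0) par[i + 1L] else NULL
    if (!is.null(alpha) && length(alpha) == m) names(alpha) <- regimes
    if (length(sigma2) == m) names(sigma2) <- regimes
    if (!is.null(theta) && length(theta) == m) names(theta) <- regimes
    list(alpha = alpha, sigma2 = sigma2, theta = theta, x0 = x0)
  }
  str <- .hansen_struct(map)
  obj <- function(par) {
    p <- unpack(par)
    ll <- tryCatch(hansen_loglik(map, xv, p, model, root_mode, str = str),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # moment-based starting values: regime means of x, tree-depth alpha
  depth <- max(node_depths(map))
  tipreg <- vapply(seq_len(ntip), function(i) {
    e <- which(map$edge[, 2] == i)
    names(map$maps[[e]])[length(map$maps[[e]])]
  }, character(1))
  regmean <- vapply(regimes, function(r) {
    v <- xv[tipreg == r]; if (length(v)) mean(v) else mean(xv)
  }, numeric(1))
  base <- c(rep(log(2 * log(2) / depth), n_alpha),
            rep(log(max(stats::var(xv) / depth, 1e-4)), n_sig),
            if (n_theta == 1) mean(regmean) else regmean,
            if (has_x0) mean(xv))
  lo <- c(rep(log(1e-7), n_alpha), rep(log(1e-8), n_sig),
          rep(-1e3, n_theta + has_x0))
  hi <- c(rep(log(50), n_alpha), rep(log(1e4), n_sig),
          rep(1e3, n_theta + has_x0))
  best <- NULL
  for (s in seq_len(nstarts)) {
    start <- base + if (s == 1) 0 else stats::rnorm(length(base), 0, 0.75)
    start <- pmin(pmax(start, lo), hi)
    opt <- tryCatch(stats::optim(start, obj, method = "L-BFGS-B",
                                 lower = lo, upper = hi),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e10)
    stop("Hansen optimization failed for model ", model)
  pars <- unpack(best$par)
  # delta-method SEs on the natural scale from the numerical Hessian
  se <- rep(NA_real_, length(best$par))
  H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  hess_ok <- FALSE
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi) && all(diag(Hi) > 0)) {
      se_t <- sqrt(diag(Hi))
      scale <- c(if (n_alpha) pars$alpha, pars$sigma2,
                 rep(1, n_theta + has_x0))
      se <- se_t * scale
      hess_ok <- TRUE
    }
  }
  nm <- c(if (n_alpha) paste0("alpha", if (n_alpha > 1) paste0(".", regimes) else ""),
          paste0("sigma2", if (n_sig > 1) paste0(".", regimes) else ""),
          if (n_theta) paste0("theta", if (n_theta > 1) paste0(".", regimes) else ""),
          if (has_x0) "x0")
  names(se) <- nm
  K <- .hansen_K(model, m, root_mode)
  score <- information_scores(
    data.frame(model = paste0(model, "_", substr(root_mode, 1, 3)),
               logL = -best$value, K = K), n = ntip, corrected = TRUE)
  fit <- structure(list(model = model, root_mode = root_mode,
                        alpha = pars$alpha, sigma2 = pars$sigma2,
                        theta = pars$theta, x0 = pars$x0, se = se,
                        logL = -best$value, score = score,
                        regimes = regimes, hessian_ok = hess_ok),
                   class = "hansen_fit")
  fit$flags <- sanity_flags(fit, xv)
  fit
}

#' Degenerate-fit diagnostics for Hansen fits
#'
#' Flags the failure modes of whole-tree multi-peak OU fits:
#' \code{alpha_degenerate} when any attraction is below \code{1e-6}/Ma,
#' \code{theta_outside} when an optimum lies far outside the data range
#' (beyond 2 ranges), \code{theta_unreliable} when SE(theta) exceeds
#' |theta|, and \code{no_se} when the Hessian was not invertible.
#'
#' @param fit a \code{"hansen_fit"}.
#' @param x tip values the model was fitted to.
#' @return character vector of flags (empty when clean).
#' @export
sanity_flags <- function(fit, x) {
  flags <- character(0)
  if (!is.null(fit$alpha) && any(fit$alpha < 1e-6))
    flags <- c(flags, "alpha_degenerate")
  if (!is.null(fit$theta)) {
    rg <- range(x); span <- diff(rg)
    if (any(fit$theta < rg[1] - 2 * span | fit$theta > rg[2] + 2 * span))
      flags <- c(flags, "theta_outside")
    se_t <- fit$se[grep("^theta", names(fit$se))]
    if (length(se_t) && any(is.finite(se_t) & se_t > abs(fit$theta)))
      flags <- c(flags, "theta_unreliable")
  }
  if (!isTRUE(fit$hessian_ok)) flags <- c(flags, "no_se")
  flags
}

#' Fit all Hansen models across a set of stochastic maps and average
#'
#' Fits every requested (model, root mode) pair on every map, computes
#' AICc weights within each map, and reports weight-averaged optima per
#' regime plus the across-map winner frequencies. Fits carrying
#' degeneracy flags (other than \code{no_se}) are excluded from the
#' averages and listed separately.
#'
#' @param maps list of \code{"simmap"} trees.
#' @param x named tip values.
#' @param models subset of the seven Hansen models.
#' @param root_modes subset of \code{c("estimated", "stationary")}.
#' @param nstarts,seed passed to [fit_hansen()].
#' @return object of class \code{"hansen_average"}: \code{table} (per
#'   map/model fit rows), \code{mean_weight} (per model), \code{winner_freq},
#'   \code{theta_avg} (model-averaged optimum per regime),
#'   \code{theta_dispersion} (across-map sd), \code{excluded}.
#' @export
hansen_model_set <- function(maps, x, models = .hansen_models,
                             root_modes = c("estimated", "stationary"),
                             nstarts = 3, seed = 1) {
  if (inherits(maps, "simmap")) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  regimes <- simmap_regimes(maps[[1]])
  rows <- list(); fits <- list()
  for (mi in seq_along(maps)) {
    for (mod in models) {
      rms <- if (mod %in% c("BM1", "BMS")) "estimated" else root_modes
      for (rm in rms) {
        f <- tryCatch(fit_hansen(maps[[mi]], x, mod, rm, nstarts = nstarts,
                                 seed = seed + mi),
                      error = function(e) NULL)
        if (is.null(f)) next
        id <- paste0(mod, "_", substr(rm, 1, 3))
        rows[[length(rows) + 1]] <- data.frame(
          map = mi, model = id, K = f$score$K, logL = f$logL,
          flags = paste(f$flags, collapse = ";"), stringsAsFactors = FALSE)
        fits[[paste(mi, id)]] <- f
      }
    }
  }
  tab <- do.call(rbind, rows)
  ntip <- ape::Ntip(maps[[1]])
  tab$admissible <- !grepl("alpha_degenerate|theta_outside|theta_unreliable",
                           tab$flags)
  out_tab <- list(); theta_by_map <- list(); winner <- character(0)
  for (mi in unique(tab$map)) {
    sub <- tab[tab$map == mi & tab$admissible, , drop = FALSE]
    if (!nrow(sub)) next
    sc <- information_scores(sub[, c("model", "logL", "K")], n = ntip)
    sc$map <- mi
    out_tab[[length(out_tab) + 1]] <- sc
    winner <- c(winner, sc$model[which.max(sc$weight)])
    th <- matrix(NA_real_, nrow(sc), length(regimes),
                 dimnames = list(sc$model, regimes))
    for (r in seq_len(nrow(sc))) {
      f <- fits[[paste(mi, sc$model[r])]]
      if (!is.null(f$theta)) {
        th[r, ] <- if (length(f$theta) == 1) rep(f$theta, length(regimes))
                   else f$theta[regimes]
      }
    }
    hasth <- !is.na(th[, 1])
    if (any(hasth)) {
      w <- sc$weight[hasth] / sum(sc$weight[hasth])
      theta_by_map[[length(theta_by_map) + 1]] <- colSums(th[hasth, , drop = FALSE] * w)
    }
  }
  if (!length(out_tab)) stop("no admissible model on any map")
  full <- do.call(rbind, out_tab)
  mean_weight <- tapply(full$weight, full$model, mean)
  th_mat <- do.call(rbind, theta_by_map)
  structure(list(table = full, fits = fits,
                 mean_weight = sort(mean_weight, decreasing = TRUE),
                 winner_freq = table(winner) / length(winner),
                 theta_avg = colMeans(th_mat),
                 theta_dispersion = apply(th_mat, 2, stats::sd),
                 excluded = tab[!tab$admissible, , drop = FALSE]),
            class = "hansen_average")
}

#' Phylogenetic half-life
#'
#' Time for a lineage to move halfway to its optimum: \eqn{\ln 2 / \alpha}.
#'
#' @param alpha attraction parameter, 1/Ma (must be > 0).
#' @param tree_depth optional total tree age (Ma); when given, the ratio
#'   half-life / depth is attached as attribute \code{"fraction_of_depth"}.
#' @return half-life in Ma.
#' @export
half_life <- function(alpha, tree_depth = NULL) {
  if (!is.numeric(alpha) || any(alpha <= 0)) stop("alpha must be > 0")
  hl <- log(2) / alpha
  if (!is.null(tree_depth)) attr(hl, "fraction_of_depth") <- hl / tree_depth
  hl
}

#' @export
print.hansen_fit <- function(x, ...) {
  cat(sprintf("Hansen fit: %s (root %s)  logL = %.3f\n",
              x$model, x$root_mode, x$logL))
  if (!is.null(x$alpha)) cat("  alpha: ", paste(signif(x$alpha, 4),
                                                collapse = ", "), "\n")
  cat("  sigma2:", paste(signif(x$sigma2, 4), collapse = ", "), "\n")
  if (!is.null(x$theta)) cat("  theta: ", paste(signif(x$theta, 4),
                                                collapse = ", "), "\n")
  if (!is.null(x$x0)) cat("  x0:    ", signif(x$x0, 4), "\n")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.hansen_average <- function(x, ...) {
  cat("Hansen model set across", length(unique(x$table$map)), "maps\n")
  cat("  mean AICc weights:\n")
  print(round(x$mean_weight, 3))
  cat("  model-averaged theta per regime:\n")
  print(round(x$theta_avg, 3))
  invisible(x)
}
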