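# Felsenstein's threshold model: a binary character is the sign of a
# latent "liability" evolving by Brownian motion jointly with an observed
# continuous trait; their correlation is estimated by MCMC over the tip
# liabilities. Identifiability: threshold fixed at 0, liability BM rate
# fixed at 1.

# truncated-normal draw by inverse CDF, numerically safe in the tails
.rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- stats::pnorm(lower, mean, sd)
  b <- stats::pnorm(upper, mean, sd)
  if (b - a > 1e-12)
    return(stats::qnorm(stats::runif(1, a, b), mean, sd))
  # deep tail: exponential-tilted rejection at the nearer bound
  if (is.finite(lower) && a > 0.5) {        # mass below lower: sample just above it
    z <- (lower - mean) / sd
    repeat {
      e <- stats::rexp(1, z) + z
      if (stats::runif(1) < exp(-(e^2 - z^2) / 2 + (e - z) * z)) break
    }
    x <- mean + sd * e
    return(if (is.finite(upper)) min(x, upper) else x)
  }
  if (is.finite(upper) && b < 0.5) {
    z <- (mean - upper) / sd
    repeat {
      e <- stats::rexp(1, z) + z
      if (stats::runif(1) < exp(-(e^2 - z^2) / 2 + (e - z) * z)) break
    }
    x <- mean - sd * e
    return(if (is.finite(lower)) max(x, lower) else x)
  }
  mean  # should not happen
}

#' Threshold-model MCMC for a binary and a continuous trait
#'
#' Gibbs/Metropolis alternation: (i) each tip liability is updated from
#' its conditional normal under the bivariate Brownian covariance
#' \eqn{R \otimes C}, truncated to the side of zero matching the observed
#' binary state; (ii) the continuous-trait rate \eqn{\sigma^2}, the
#' correlation \eqn{r} and the two root means are updated by random-walk
#' Metropolis (uniform priors: \eqn{r} on \code{[-1, 1]},
#' \eqn{\log\sigma^2} on a wide bound). The liability BM rate is fixed at
#' 1 and the threshold at 0.
#'
#' One generation is one full sweep (all liabilities + all parameters).
#'
#' @param tree dated \code{"phylo"}.
#' @param binary named 0/1 tip states.
#' @param continuous named tip values (log_e kg).
#' @param ngen generations; desk-scale values (a few thousand) suffice for
#'   the package's fixtures.
#' @param thin keep every \code{thin}-th generation after \code{burnin}
#'   (default 20\% of \code{ngen}).
#' @param burnin generations discarded.
#' @param seed integer seed.
#' @return object of class \code{"threshold_posterior"}: \code{draws}
#'   (r, sigma2, mu_liab, mu_cont, logL), \code{liabilities} (draws x tips),
#'   \code{mean_r}, \code{mean_r2}, \code{summary}.
#' @export
threshbayes <- function(tree, binary, continuous, ngen = 5000,
                        thin = 5, burnin = ceiling(0.2 * ngen), seed = 1) {
  stopifnot(ngen > burnin, thin >= 1)
  set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  y <- as.numeric(binary[tips])
  x <- as.numeric(continuous[tips])
  if (anyNA(y) || anyNA(x)) stop("binary/continuous must cover every tip")
  if (!all(y %in% 0:1)) stop("binary states must be 0/1")
  C <- phylo_vcv(tree)
  L <- chol(C)
  Cinv <- chol2inv(L)
  logdetC <- 2 * sum(log(diag(L)))

  # joint density of (l, x) under R kron C with root means (mu_l, mu_x):
  # R = [[1, r s],[r s, s2]] with s = sqrt(s2); liability rate fixed at 1
  joint_ll <- function(l, mu_l, mu_x, s2, r) {
    s <- sqrt(s2)
    R <- matrix(c(1, r * s, r * s, s2), 2, 2)
    detR <- s2 * (1 - r^2)
    if (detR <= 0) return(-Inf)
    Rinv <- matrix(c(s2, -r * s, -r * s, 1), 2, 2) / detR
    A <- cbind(l - mu_l, x - mu_x)
    W <- Cinv %*% A
    quad <- sum(Rinv * crossprod(A, W))
    -0.5 * (2 * n * log(2 * pi) + n * log(detR) + 2 * logdetC + quad)
  }

  # init: liabilities at +/-1 matching states
  l <- ifelse(y == 1, 1, -1)
  mu_x <- mean(x); mu_l <- 0
  s2 <- max(stats::var(x), 1e-3); r <- 0
  ll <- joint_ll(l, mu_l, mu_x, s2, r)
  keep <- floor((ngen - burnin) / thin)
  draws <- matrix(NA_real_, keep, 5,
                  dimnames = list(NULL, c("r", "sigma2", "mu_liab",
                                          "mu_cont", "logL")))
  liab <- matrix(NA_real_, keep, n, dimnames = list(NULL, tips))
  kept <- 0L
  scales <- c(r = 0.2, ls2 = 0.4, mu = 0.5)

  for (g in seq_len(ngen)) {
    # --- liability Gibbs sweep -------------------------------------------
    s <- sqrt(s2)
    detR <- s2 * (1 - r^2)
    Rinv11 <- s2 / detR
    Rinv12 <- -r * s / detR
    zx <- x - mu_x
    Cinv_zx <- Cinv %*% zx
    zl <- l - mu_l
    Cinv_zl <- Cinv %*% zl
    for (i in seq_len(n)) {
      pii <- Rinv11 * Cinv[i, i]
      # remove i's own contribution from the cached product
      rest <- Rinv11 * (Cinv_zl[i] - Cinv[i, i] * zl[i]) + Rinv12 * Cinv_zx[i]
      m_i <- mu_l - rest / pii
      sd_i <- sqrt(1 / pii)
      new_l <- if (y[i] == 1) .rtruncnorm1(m_i, sd_i, lower = 0)
               else .rtruncnorm1(m_i, sd_i, upper = 0)
      dl <- new_l - l[i]
      if (dl != 0) {
        l[i] <- new_l
        zl[i] <- zl[i] + dl
        Cinv_zl <- Cinv_zl + Cinv[, i] * dl
      }
    }
    ll <- joint_ll(l, mu_l, mu_x, s2, r)
    # --- parameter Metropolis updates ------------------------------------
    rp <- r + stats::rnorm(1, 0, scales["r"])
    if (rp > -1 && rp < 1) {
      llp <- joint_ll(l, mu_l, mu_x, s2, rp)
      if (is.finite(llp) && log(stats::runif(1)) < llp - ll) { r <- rp; ll <- llp }
    }
    s2p <- s2 * exp(stats::rnorm(1, 0, scales["ls2"]))
    if (s2p > 1e-8 && s2p < 1e8) {
      llp <- joint_ll(l, mu_l, mu_x, s2p, r)
      # log-scale proposal Jacobian with flat prior on log sigma2 cancels
      if (is.finite(llp) && log(stats::runif(1)) < llp - ll) { s2 <- s2p; ll <- llp }
    }
    for (mu_which in 1:2) {
      if (mu_which == 1) {
        mp <- mu_l + stats::rnorm(1, 0, scales["mu"])
        llp <- joint_ll(l, mp, mu_x, s2, r)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) { mu_l <- mp; ll <- llp }
      } else {
        mp <- mu_x + stats::rnorm(1, 0, scales["mu"])
        llp <- joint_ll(l, mu_l, mp, s2, r)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) { mu_x <- mp; ll <- llp }
      }
    }
    if (g > burnin && (g - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(r, s2, mu_l, mu_x, ll)
      liab[kept, ] <- l
    }
  }
  draws <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  liab <- liab[seq_len(kept), , drop = FALSE]
  # invariant: liability signs always match the observed states
  ok <- all(apply(liab, 1, function(lr) all((lr > 0) == (y == 1))))
  if (!ok) warning("liability-sign inconsistency detected in retained draws")
  summ <- data.frame(
    parameter = c("r", "sigma2"),
    median = c(stats::median(draws$r), stats::median(draws$sigma2)),
    lo95 = c(stats::quantile(draws$r, 0.025), stats::quantile(draws$sigma2, 0.025)),
    hi95 = c(stats::quantile(draws$r, 0.975), stats::quantile(draws$sigma2, 0.975)))
  structure(list(draws = draws, liabilities = liab,
                 mean_r = mean(draws$r), mean_r2 = mean(draws$r^2),
                 summary = summ, logL_trace = draws$logL,
                 sign_consistent = ok),
            class = "threshold_posterior")
}

#' @export
print.threshold_posterior <- function(x, ...) {
  cat("Threshold-model posterior (", nrow(x$draws), " draws)\n", sep = "")
  cat(sprintf("  mean r = %.3f   mean r^2 = %.3f\n", x$mean_r, x$mean_r2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
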