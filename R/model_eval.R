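# Information criteria, Akaike weights, harmonic-mean marginal likelihoods
# and Bayes factors shared by every fitting module. Natural-log convention
# throughout; Bayes factors on the 2 x log scale.

#' Information scores for a set of fitted models
#'
#' AIC = -2 logL + 2K; AICc adds the small-sample correction
#' 2K(K+1)/(n - K - 1). Delta is relative to the best (smallest) score and
#' Akaike weights are exp(-delta/2), renormalized.
#'
#' @param models a data frame (or list of lists) with components
#'   \code{logL} (nats) and \code{K} (free-parameter count); an optional
#'   \code{model} column names each row.
#' @param n sample size (required when \code{corrected = TRUE}).
#' @param corrected use AICc instead of AIC.
#' @return a data frame: model, K, logL, AIC (or AICc), delta, weight.
#' @export
#' @examples
#' information_scores(data.frame(model = c("a", "b"),
#'                               logL = c(-10, -12), K = c(2, 1)),
#'                    n = 10)
information_scores <- function(models, n = NULL, corrected = TRUE) {
  if (!is.data.frame(models)) {
    models <- data.frame(
      model = vapply(seq_along(models), function(i) {
        m <- models[[i]]; if (!is.null(m$model)) m$model else paste0("m", i)
      }, character(1)),
      logL = vapply(models, function(m) m$logL, numeric(1)),
      K    = vapply(models, function(m) m$K, numeric(1)))
  }
  if (is.null(models$model)) models$model <- paste0("m", seq_len(nrow(models)))
  stopifnot(all(c("logL", "K") %in% names(models)))
  aic <- -2 * models$logL + 2 * models$K
  if (corrected) {
    if (is.null(n)) stop("n required for AICc")
    if (any(n <= models$K + 1))
      stop("AICc undefined: n <= K + 1 for model(s) ",
           paste(models$model[n <= models$K + 1], collapse = ", "))
    aic <- aic + (2 * models$K * (models$K + 1)) / (n - models$K - 1)
  }
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = models$model, K = models$K, logL = models$logL,
                    IC = aic, delta = delta, weight = w,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "IC"] <- if (corrected) "AICc" else "AIC"
  out
}

#' Log marginal likelihood by the harmonic-mean estimator
#'
#' log(1 / mean(1 / L_i)) computed in log space via log-sum-exp, so traces
#' of very negative log-likelihoods do not underflow. A batch-means Monte
#' Carlo standard error is attached (attribute \code{"mc_se"}) because the
#' harmonic-mean estimator is notoriously unstable.
#'
#' @param logL_trace numeric vector of post-burn-in log-likelihood samples.
#' @param min_samples minimum trace length accepted.
#' @return scalar log marginal likelihood (nats), with attribute
#'   \code{mc_se}.
#' @export
harmonic_mean_logml <- function(logL_trace, min_samples = 2) {
  if (length(logL_trace) == 0) stop("empty log-likelihood trace")
  if (length(logL_trace) < min_samples)
    stop("trace too short: ", length(logL_trace), " < ", min_samples)
  if (anyNA(logL_trace)) stop("NA in log-likelihood trace")
  est <- .log_hm(logL_trace)
  nb <- max(2L, min(20L, length(logL_trace) %/% 10L))
  if (nb >= 2 && length(logL_trace) >= 2 * nb) {
    batches <- split(logL_trace,
                     cut(seq_along(logL_trace), nb, labels = FALSE))
    bests <- vapply(batches, .log_hm, numeric(1))
    attr(est, "mc_se") <- stats::sd(bests) / sqrt(nb)
  } else attr(est, "mc_se") <- NA_real_
  est
}

.log_hm <- function(x) {
  # log HM = -( logsumexp(-x) - log n )
  m <- max(-x)
  -(m + log(sum(exp(-x - m))) - log(length(x)))
}

#' Bayes factor between two MCMC runs (2 x log scale)
#'
#' BF = 2 (log HM_complex - log HM_simple) from the harmonic-mean marginal
#' likelihoods of the two traces. Values over 5 are conventionally "strong"
#' and over 10 "very strong" support for the complex model; negative values
#' support the simple model.
#'
#' @param complex_trace,simple_trace post-burn-in log-likelihood traces.
#' @return a list of class \code{"bayes_factor"}: \code{log_hm_complex},
#'   \code{log_hm_simple}, \code{bf}, \code{verdict} in
#'   \code{none/positive/strong/very strong}.
#' @export
bayes_factor <- function(complex_trace, simple_trace) {
  hc <- harmonic_mean_logml(complex_trace)
  hs <- harmonic_mean_logml(simple_trace)
  bf <- 2 * (as.numeric(hc) - as.numeric(hs))
  verdict <- if (abs(bf) >= 10) "very strong"
             else if (abs(bf) >= 5) "strong"
             else if (abs(bf) > 2) "positive"
             else "none"
  structure(list(log_hm_complex = as.numeric(hc),
                 log_hm_simple = as.numeric(hs),
                 bf = bf, verdict = verdict,
                 mc_se = sqrt(sum(c(attr(hc, "mc_se"), attr(hs, "mc_se"))^2,
                                  na.rm = TRUE)) * 2),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Bayes factor (2 x log): %.3f  [%s]\n", x$bf, x$verdict))
  cat(sprintf("  log HM complex: %.3f   log HM simple: %.3f\n",
              x$log_hm_complex, x$log_hm_simple))
  invisible(x)
}
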