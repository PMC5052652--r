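# Continuous-time Markov (Mk) machinery for binary characters: Felsenstein
# pruning, ML model fitting (ER/SYM/ARD), reversible-jump MCMC over rate
# models, the two-trait dependent model on 4 combined states, ancestral
# "fossilization" Bayes-factor tests, and stochastic character mapping.

#' Build a binary-trait rate matrix
#'
#' @param q01 instantaneous gain rate (state 0 to 1), per Ma.
#' @param q10 loss rate (1 to 0), per Ma.
#' @param states state labels.
#' @return 2x2 rate matrix with rows summing to zero.
#' @export
make_q_binary <- function(q01, q10, states = c("0", "1")) {
  stopifnot(q01 >= 0, q10 >= 0)
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE,
              dimnames = list(states, states))
  Q
}

# transition probability matrix exp(Q t); closed form for 2 states,
# ape's matrix exponential otherwise
.pmat <- function(Q, t) {
  k <- nrow(Q)
  if (k == 2L) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    if (s == 0) {
      P <- diag(2); dimnames(P) <- dimnames(Q)
      return(P)
    }
    e <- exp(-s * t)
    P <- matrix(c(b + a * e, a - a * e, b - b * e, a + b * e), 2, 2,
                byrow = TRUE) / s
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- ape::matexpo(Q * t)
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0
  P
}

# canonicalize tip states to a factor over Q's state labels
.match_states <- function(states, labels, tips) {
  s <- stats::setNames(as.character(states), names(states))
  if (!is.null(names(states))) s <- s[tips] else names(s) <- tips
  if (anyNA(s)) stop("unscored tip(s): ",
                     paste(tips[is.na(s)], collapse = ", "))
  bad <- setdiff(unique(s), labels)
  if (length(bad)) stop("tip states not among Q states: ",
                        paste(bad, collapse = ", "))
  s
}

# stationary distribution of Q (left null vector)
.stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- stats::setNames(as.numeric(qr.solve(A, b)), rownames(Q))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of discrete tip states under a
#' continuous-time Markov model, with per-branch transition matrices
#' \eqn{e^{Qt}} and partial likelihoods rescaled at every node so deep
#' trees do not underflow. Root partials are weighted by the observed
#' (empirical) state frequencies by default, matching the convention of
#' treating stationary frequencies as empirical; \code{"flat"} and
#' \code{"stationary"} weightings are also available. Internal nodes can
#' be "fossilized" to a fixed state via \code{fixed_nodes}, which zeroes
#' the partials of all other states at that node.
#'
#' @param tree binary \code{"phylo"} (polytomies are refused).
#' @param states tip states: named character/numeric vector over tip
#'   labels, values among \code{rownames(Q)} (0/1 coerced to "0"/"1").
#' @param Q rate matrix with dimnames.
#' @param root \code{"empirical"}, \code{"flat"} or \code{"stationary"}.
#' @param fixed_nodes optional named list/vector mapping internal node
#'   numbers to forced states.
#' @return log-likelihood in nats.
#' @export
mk_loglik <- function(tree, states, Q,
                      root = c("empirical", "flat", "stationary"),
                      fixed_nodes = NULL) {
  root <- match.arg(root)
  if (max(tabulate(tree$edge[, 1])) > 2L)
    stop("likelihood operations require a fully resolved (binary) tree")
  labels <- rownames(Q)
  ntip <- ape::Ntip(tree)
  s <- .match_states(states, labels, tree$tip.label)
  k <- length(labels)
  part <- matrix(0, ntip + tree$Nnode, k, dimnames = list(NULL, labels))
  part[cbind(seq_len(ntip), match(s, labels))] <- 1
  scaler <- 0
  eo <- ape::reorder.phylo(tree, "postorder")
  edges <- eo$edge; lens <- eo$edge.length
  done <- rep(FALSE, ntip + tree$Nnode)
  done[seq_len(ntip)] <- TRUE
  for (kk in seq_len(nrow(edges))) {
    p <- edges[kk, 1]; ch <- edges[kk, 2]
    P <- .pmat(Q, lens[kk])
    msg <- P %*% part[ch, ]
    if (!all(is.finite(msg))) stop("non-finite exp(Qt) on branch to node ", ch)
    if (!done[p]) { part[p, ] <- msg; done[p] <- TRUE }
    else part[p, ] <- part[p, ] * msg
    if (!is.null(fixed_nodes) && as.character(p) %in% names(fixed_nodes)) {
      keep <- as.character(fixed_nodes[[as.character(p)]])
      part[p, setdiff(labels, keep)] <- 0
    }
    m <- max(part[p, ])
    if (m <= 0) return(-Inf)
    part[p, ] <- part[p, ] / m
    scaler <- scaler + log(m)
  }
  w <- switch(root,
              empirical = {
                f <- table(factor(s, levels = labels)) / ntip
                as.numeric(f)
              },
              flat = rep(1 / k, k),
              stationary = as.numeric(.stationary(Q)))
  rootn <- ntip + 1L
  lik <- sum(w * part[rootn, ])
  if (lik <= 0) return(-Inf)
  log(lik) + scaler
}

#' Maximum-likelihood Mk fit (ER / SYM / ARD)
#'
#' Bounded ML optimization of the free transition rates of a binary
#' character. For two states the symmetric model coincides with the
#' equal-rates model (one free rate); the all-rates-different model has
#' two. An information score with \code{n} = number of tips is attached,
#' and a \code{boundary} flag is raised when a rate estimate is pinned at
#' the optimization bound (e.g. invariant characters).
#'
#' @inheritParams mk_loglik
#' @param model \code{"ER"}, \code{"SYM"} or \code{"ARD"}.
#' @param bounds log-rate optimization bounds (per Ma).
#' @return an object of class \code{"mk_fit"}: \code{Q}, \code{rates},
#'   \code{logL}, \code{score}, \code{boundary}.
#' @export
fit_mk_ml <- function(tree, states, model = c("ER", "SYM", "ARD"),
                      root = "empirical", bounds = c(1e-7, 100)) {
  model <- match.arg(model)
  nfree <- if (model == "ARD") 2L else 1L
  obj <- function(lq) {
    q <- exp(lq)
    Q <- if (nfree == 1L) make_q_binary(q[1], q[1]) else make_q_binary(q[1], q[2])
    -mk_loglik(tree, states, Q, root = root)
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  best <- NULL
  for (st in c(-4, -2, 0)) {
    opt <- tryCatch(
      stats::optim(rep(st, nfree), obj, method = "L-BFGS-B",
                   lower = lb, upper = ub),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("Mk optimization failed")
  q <- exp(best$par)
  Q <- if (nfree == 1L) make_q_binary(q[1], q[1]) else make_q_binary(q[1], q[2])
  boundary <- any(abs(best$par - lb) < 1e-6 | abs(best$par - ub) < 1e-6)
  score <- information_scores(
    data.frame(model = model, logL = -best$value, K = nfree),
    n = ape::Ntip(tree), corrected = TRUE)
  structure(list(model = model, Q = Q,
                 rates = stats::setNames(q, if (nfree == 1) "q" else c("q01", "q10")),
                 logL = -best$value, score = score, boundary = boundary),
            class = "mk_fit")
}

#' Compare ER/SYM/ARD Mk models by AICc weight
#'
#' @inheritParams fit_mk_ml
#' @return list: \code{table} (AICc comparison), \code{fits}.
#' @export
mk_model_set <- function(tree, states, root = "empirical") {
  fits <- lapply(c(ER = "ER", SYM = "SYM", ARD = "ARD"), function(m)
    fit_mk_ml(tree, states, model = m, root = root))
  sc <- information_scores(
    data.frame(model = names(fits),
               logL = vapply(fits, function(f) f$logL, numeric(1)),
               K = vapply(fits, function(f) f$score$K, numeric(1))),
    n = ape::Ntip(tree), corrected = TRUE)
  list(table = sc, fits = fits)
}

# log prior of rates under Exp(mean m)
.lprior_exp <- function(rates, m) sum(stats::dexp(rates, rate = 1 / m, log = TRUE))

# mean log-likelihood over a (sub)set of trees: one tree index drawn per
# iteration by the callers, so this evaluates a single tree
.mk_ll_tree <- function(trees, ti, states, Q, root, fixed_nodes = NULL) {
  mk_loglik(trees[[ti]], states, Q, root = root, fixed_nodes = fixed_nodes)
}

#' Reversible-jump MCMC over binary-trait rate models
#'
#' Samples jointly over rate models (one shared rate; two distinct rates;
#' either rate set to zero) and rate values, under an exponential rate
#' prior whose mean is itself uniform on \code{(0, 10)} (hyperprior).
#' Model jumps are independence proposals: a candidate model is drawn
#' uniformly and its free rates drawn fresh from the exponential prior, so
#' the prior and proposal densities cancel and acceptance reduces to the
#' likelihood ratio. Within-model updates are random-walk Metropolis on
#' log rates. A tree index is drawn uniformly per iteration when a tree
#' set is supplied. \code{fixed_model} disables jumps ("equal" or "free"),
#' giving the non-reversible-jump chains used for Bayes-factor tests.
#'
#' @param trees a tree or list of trees.
#' @param states binary tip states (see [mk_loglik()]).
#' @param iterations,thin,burnin chain settings.
#' @param hyper_range uniform range for the exponential-prior mean.
#' @param fixed_model \code{NULL} (reversible jump), \code{"equal"} or
#'   \code{"free"}.
#' @param root root frequency rule.
#' @param fixed_nodes optional fossilized-node constraint (see
#'   [mk_loglik()]).
#' @param seed integer seed.
#' @return an object of class \code{"rj_posterior"}: \code{draws} (model,
#'   q01, q10, hyper mean, logL), \code{model_freq}, \code{logL_trace}.
#' @export
rjmcmc_binary <- function(trees, states, iterations = 20000, thin = 10,
                          burnin = 2000, hyper_range = c(0, 10),
                          fixed_model = NULL, root = "empirical",
                          fixed_nodes = NULL, seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(iterations > burnin)
  set.seed(seed)
  # models: mapping from free rates to (q01, q10)
  models <- list(
    one  = function(r) c(r[1], r[1]),
    two  = function(r) c(r[1], r[2]),
    gain0 = function(r) c(0, r[1]),
    loss0 = function(r) c(r[1], 0))
  nfree <- c(one = 1L, two = 2L, gain0 = 1L, loss0 = 1L)
  if (!is.null(fixed_model)) {
    mod <- switch(fixed_model, equal = "one", free = "two",
                  stop("fixed_model must be 'equal' or 'free'"))
    model_set <- mod
  } else {
    mod <- "one"
    model_set <- names(models)
  }
  m_hyper <- stats::runif(1, max(hyper_range[1], 1e-3), hyper_range[2])
  r <- stats::rexp(nfree[mod], 1 / m_hyper)
  llfun <- function(mod, r, ti) {
    q <- models[[mod]](r)
    .mk_ll_tree(trees, ti, states, make_q_binary(q[1], q[2]), root,
                fixed_nodes)
  }
  ti <- sample.int(length(trees), 1)
  ll <- llfun(mod, r, ti)
  if (!is.finite(ll)) { mod <- "two"; r <- c(0.05, 0.05); ll <- llfun(mod, r, ti) }
  keep <- floor((iterations - burnin) / thin)
  out <- data.frame(model = character(keep), q01 = numeric(keep),
                    q10 = numeric(keep), hyper = numeric(keep),
                    logL = numeric(keep), stringsAsFactors = FALSE)
  kept <- 0L
  jump_acc <- 0L; jump_try <- 0L
  scale_r <- 0.5
  for (it in seq_len(iterations)) {
    ti <- sample.int(length(trees), 1)
    ll <- llfun(mod, r, ti)
    # model jump (independence proposal from the prior)
    if (length(model_set) > 1L) {
      jump_try <- jump_try + 1L
      mod2 <- sample(model_set, 1)
      r2 <- stats::rexp(nfree[mod2], 1 / m_hyper)
      ll2 <- llfun(mod2, r2, ti)
      if (is.finite(ll2) && log(stats::runif(1)) < ll2 - ll) {
        mod <- mod2; r <- r2; ll <- ll2; jump_acc <- jump_acc + 1L
      }
    }
    # within-model log-rate random walk
    for (j in seq_along(r)) {
      r2 <- r; r2[j] <- r[j] * exp(stats::rnorm(1, 0, scale_r))
      ll2 <- llfun(mod, r2, ti)
      lacc <- (ll2 - ll) + (.lprior_exp(r2, m_hyper) - .lprior_exp(r, m_hyper)) +
        (log(r2[j]) - log(r[j]))   # log-scale proposal Jacobian
      if (is.finite(ll2) && log(stats::runif(1)) < lacc) { r <- r2; ll <- ll2 }
    }
    # hyperprior mean update
    m2 <- m_hyper + stats::rnorm(1, 0, 0.5)
    if (m2 > max(hyper_range[1], 1e-3) && m2 < hyper_range[2]) {
      la <- .lprior_exp(r, m2) - .lprior_exp(r, m_hyper)
      if (log(stats::runif(1)) < la) m_hyper <- m2
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      q <- models[[mod]](r)
      out$model[kept] <- mod; out$q01[kept] <- q[1]; out$q10[kept] <- q[2]
      out$hyper[kept] <- m_hyper; out$logL[kept] <- ll
    }
  }
  out <- out[seq_len(kept), , drop = FALSE]
  if (length(model_set) > 1L && jump_acc == 0L)
    warning("no model jump accepted after burn-in: chain may be stuck")
  mf <- table(factor(out$model, levels = model_set)) / nrow(out)
  structure(list(draws = out, model_freq = mf, logL_trace = out$logL,
                 fixed_model = fixed_model),
            class = "rj_posterior")
}

#' @export
print.rj_posterior <- function(x, ...) {
  cat("Rate-model posterior (", nrow(x$draws), " draws)\n", sep = "")
  print(round(x$model_freq, 3))
  cat(sprintf("  q01: median %.4g   q10: median %.4g\n",
              stats::median(x$draws$q01), stats::median(x$draws$q10)))
  invisible(x)
}

# ---- two-trait dependent model -------------------------------------------

# 4-state space: "00","01","10","11"; first digit = trait A (ornament),
# second = trait B (giant). Double transitions structurally zero.
.dep_cells <- matrix(c(
  # from, to, trait changed, direction, conditioning state of other trait
  "00", "10", "A", "01", "0",
  "01", "11", "A", "01", "1",
  "10", "00", "A", "10", "0",
  "11", "01", "A", "10", "1",
  "00", "01", "B", "01", "0",
  "10", "11", "B", "01", "1",
  "01", "00", "B", "10", "0",
  "11", "10", "B", "10", "1"), ncol = 5, byrow = TRUE,
  dimnames = list(NULL, c("from", "to", "trait", "dir", "cond")))

#' Build the 4-state rate matrix of the two-trait model
#'
#' @param rates named vector. Independent mode: \code{qA01, qA10, qB01,
#'   qB10}. Dependent mode: \code{qA01.B0, qA01.B1, qA10.B0, qA10.B1,
#'   qB01.A0, qB01.A1, qB10.A0, qB10.A1}.
#' @param mode \code{"independent"} or \code{"dependent"}.
#' @return 4x4 rate matrix over states 00, 01, 10, 11 (A then B digit).
#' @export
make_q_dependent <- function(rates, mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  st <- c("00", "01", "10", "11")
  Q <- matrix(0, 4, 4, dimnames = list(st, st))
  for (i in seq_len(nrow(.dep_cells))) {
    cell <- .dep_cells[i, ]
    nm <- if (mode == "independent")
      paste0("q", cell["trait"], cell["dir"])
    else
      paste0("q", cell["trait"], cell["dir"], ".",
             if (cell["trait"] == "A") "B" else "A", cell["cond"])
    if (!nm %in% names(rates)) stop("missing rate: ", nm)
    Q[cell["from"], cell["to"]] <- rates[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Correlated evolution of two binary traits (dependent Mk model)
#'
#' MCMC over the 4-combined-state model of two binary traits (ornament
#' status and the discretized giant flag). In independent mode each
#' trait's gain/loss rate ignores the other trait (4 free rates); in
#' dependent mode each of the 8 single-change rates is free. Double
#' transitions are structurally zero. The sampler uses the same
#' exponential hyperprior scheme as [rjmcmc_binary()] (fixed model, no
#' jumps) and reports the giantism-rate contrast
#' \code{qB01.A1 / qB01.A0}: how much faster the mass threshold is crossed
#' in ornamented lineages.
#'
#' @param trees tree or list of trees.
#' @param traitA,traitB named binary vectors over the tips (ornament,
#'   giant).
#' @inheritParams rjmcmc_binary
#' @param mode \code{"independent"} or \code{"dependent"}.
#' @return \code{"rj_posterior"} whose draws hold the free rates, plus
#'   \code{contrast} draws in dependent mode.
#' @export
fit_dependent_discrete <- function(trees, traitA, traitB,
                                   mode = c("independent", "dependent"),
                                   iterations = 20000, thin = 10,
                                   burnin = 2000, hyper_range = c(0, 10),
                                   root = "empirical", seed = 1) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  set.seed(seed)
  tips <- trees[[1]]$tip.label
  a <- as.integer(traitA[tips]); b <- as.integer(traitB[tips])
  if (anyNA(a) || anyNA(b)) stop("traits must cover every tip")
  if (all(a == b) || all(a == 1 - b))
    warning("traits perfectly confounded: contrast unidentifiable")
  comb <- stats::setNames(paste0(a, b), tips)
  rnames <- if (mode == "independent") c("qA01", "qA10", "qB01", "qB10")
            else c("qA01.B0", "qA01.B1", "qA10.B0", "qA10.B1",
                   "qB01.A0", "qB01.A1", "qB10.A0", "qB10.A1")
  m_hyper <- stats::runif(1, max(hyper_range[1], 1e-3), hyper_range[2])
  r <- stats::setNames(rep(0.05, length(rnames)), rnames)
  llfun <- function(r, ti)
    mk_loglik(trees[[ti]], comb, make_q_dependent(r, mode), root = root)
  ti <- sample.int(length(trees), 1)
  ll <- llfun(r, ti)
  if (!is.finite(ll)) stop("non-finite likelihood at initial state")
  keep <- floor((iterations - burnin) / thin)
  draws <- matrix(NA_real_, keep, length(rnames) + 2,
                  dimnames = list(NULL, c(rnames, "hyper", "logL")))
  kept <- 0L
  for (it in seq_len(iterations)) {
    ti <- sample.int(length(trees), 1)
    ll <- llfun(r, ti)
    for (j in seq_along(r)) {
      r2 <- r; r2[j] <- r[j] * exp(stats::rnorm(1, 0, 0.5))
      ll2 <- llfun(r2, ti)
      lacc <- (ll2 - ll) + (.lprior_exp(r2, m_hyper) - .lprior_exp(r, m_hyper)) +
        (log(r2[j]) - log(r[j]))
      if (is.finite(ll2) && log(stats::runif(1)) < lacc) { r <- r2; ll <- ll2 }
    }
    m2 <- m_hyper + stats::rnorm(1, 0, 0.5)
    if (m2 > max(hyper_range[1], 1e-3) && m2 < hyper_range[2]) {
      if (log(stats::runif(1)) < .lprior_exp(r, m2) - .lprior_exp(r, m_hyper))
        m_hyper <- m2
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(r, m_hyper, ll)
    }
  }
  draws <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  res <- list(draws = draws, logL_trace = draws$logL, mode = mode,
              model_freq = stats::setNames(1, mode))
  if (mode == "dependent")
    res$contrast <- draws$qB01.A1 / pmax(draws$qB01.A0, 1e-12)
  class(res) <- "rj_posterior"
  res
}

#' Ancestral-state Bayes factor by node fossilization
#'
#' Runs two fixed-model MCMC chains with an internal node's state
#' constrained ("fossilized") to \code{forced_state} and to its opposite,
#' and returns the harmonic-mean Bayes factor. Positive values favor
#' \code{forced_state}.
#'
#' @inheritParams rjmcmc_binary
#' @param node internal node number.
#' @param forced_state the state whose support is being measured
#'   (\code{"0"} or \code{"1"}).
#' @param fixed_model rate model for both chains (default equal rates).
#' @return a \code{"bayes_factor"} object.
#' @export
fossilize_bf <- function(trees, states, node, forced_state = "1",
                         iterations = 20000, thin = 10, burnin = 2000,
                         fixed_model = "equal", root = "empirical",
                         seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ntip <- ape::Ntip(trees[[1]])
  if (node <= ntip) stop("node must be internal")
  other <- setdiff(c("0", "1"), as.character(forced_state))
  fx1 <- stats::setNames(list(as.character(forced_state)), as.character(node))
  fx0 <- stats::setNames(list(other), as.character(node))
  ch1 <- rjmcmc_binary(trees, states, iterations = iterations, thin = thin,
                       burnin = burnin, fixed_model = fixed_model,
                       root = root, fixed_nodes = fx1, seed = seed)
  ch0 <- rjmcmc_binary(trees, states, iterations = iterations, thin = thin,
                       burnin = burnin, fixed_model = fixed_model,
                       root = root, fixed_nodes = fx0, seed = seed + 1)
  bayes_factor(ch1$logL_trace, ch0$logL_trace)
}

# ---- stochastic character mapping ----------------------------------------

# pruning pass returning scaled partials for all nodes
.mk_partials <- function(tree, states, Q, fixed_nodes = NULL) {
  labels <- rownames(Q)
  ntip <- ape::Ntip(tree)
  s <- .match_states(states, labels, tree$tip.label)
  k <- length(labels)
  part <- matrix(0, ntip + tree$Nnode, k, dimnames = list(NULL, labels))
  part[cbind(seq_len(ntip), match(s, labels))] <- 1
  eo <- ape::reorder.phylo(tree, "postorder")
  done <- rep(FALSE, ntip + tree$Nnode); done[seq_len(ntip)] <- TRUE
  for (kk in seq_len(nrow(eo$edge))) {
    p <- eo$edge[kk, 1]; ch <- eo$edge[kk, 2]
    msg <- .pmat(Q, eo$edge.length[kk]) %*% part[ch, ]
    if (!done[p]) { part[p, ] <- msg; done[p] <- TRUE }
    else part[p, ] <- part[p, ] * msg
    if (!is.null(fixed_nodes) && as.character(p) %in% names(fixed_nodes))
      part[p, setdiff(labels, as.character(fixed_nodes[[as.character(p)]]))] <- 0
    m <- max(part[p, ])
    if (m <= 0) stop("zero partial likelihood at node ", p)
    part[p, ] <- part[p, ] / m
  }
  part
}

# sample a CTMC path on one branch conditional on endpoint states; returns
# named duration vector ordered rootward -> tipward
.sample_branch_history <- function(Q, t, s_from, s_to, max_reject = 1000) {
  for (att in seq_len(max_reject)) {
    path <- .gillespie_path(Q, t, s_from)
    if (names(path)[length(path)] == s_to) return(path)
  }
  .uniformization_path(Q, t, s_from, s_to)
}

# unconditional Gillespie simulation along a branch
.gillespie_path <- function(Q, t, s0) {
  labels <- rownames(Q)
  cur <- s0; left <- t
  segs <- numeric(0); seg_states <- character(0)
  repeat {
    rate <- -Q[cur, cur]
    dt <- if (rate <= 0) Inf else stats::rexp(1, rate)
    if (dt >= left) {
      segs <- c(segs, left); seg_states <- c(seg_states, cur)
      break
    }
    segs <- c(segs, dt); seg_states <- c(seg_states, cur)
    left <- left - dt
    pr <- Q[cur, ]; pr[cur] <- 0
    cur <- sample(labels, 1, prob = pr)
  }
  stats::setNames(segs, seg_states)
}

# endpoint-conditioned path by uniformization
.uniformization_path <- function(Q, t, s_from, s_to, nmax = 200) {
  labels <- rownames(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) return(stats::setNames(t, s_from))
  R <- diag(nrow(Q)) + Q / lam
  dimnames(R) <- dimnames(Q)
  Pt <- .pmat(Q, t)
  pn <- numeric(nmax + 1)
  Rn <- diag(nrow(Q)); dimnames(Rn) <- dimnames(Q)
  for (n in 0:nmax) {
    pn[n + 1] <- stats::dpois(n, lam * t) * Rn[s_from, s_to] / Pt[s_from, s_to]
    Rn <- Rn %*% R
  }
  pn[!is.finite(pn) | pn < 0] <- 0
  if (sum(pn) <= 0) stop("uniformization failed on branch (t = ", t, ")")
  N <- sample(0:nmax, 1, prob = pn)
  if (N == 0) return(stats::setNames(t, s_from))
  times <- sort(stats::runif(N, 0, t))
  # sample the virtual chain states by backward-forward products of R
  Rpow <- vector("list", N + 1)
  Rpow[[1]] <- diag(nrow(Q)); dimnames(Rpow[[1]]) <- dimnames(Q)
  for (n in seq_len(N)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  st <- character(N + 2)
  st[1] <- s_from; st[N + 2] <- s_to
  for (j in seq_len(N)) {
    pr <- vapply(labels, function(sv)
      R[st[j], sv] * Rpow[[N - j + 1]][sv, s_to], numeric(1))
    pr[pr < 0 | !is.finite(pr)] <- 0
    st[j + 1] <- if (sum(pr) > 0) sample(labels, 1, prob = pr) else st[j]
  }
  bounds <- c(0, times, t)
  segs <- diff(bounds)
  keepn <- st[-length(st)]
  # merge consecutive identical states (virtual jumps)
  out_s <- character(0); out_d <- numeric(0)
  for (j in seq_along(segs)) {
    if (length(out_s) && out_s[length(out_s)] == keepn[j])
      out_d[length(out_d)] <- out_d[length(out_d)] + segs[j]
    else { out_s <- c(out_s, keepn[j]); out_d <- c(out_d, segs[j]) }
  }
  stats::setNames(out_d, out_s)
}

#' Stochastic character maps conditional on tip data
#'
#' Samples full character histories ("paintings") of a discrete trait:
#' node states are drawn from their conditional distributions computed by
#' pruning (root first, then a preorder sweep), and branch histories are
#' sampled conditional on endpoint states by rejection sampling with a
#' uniformization fallback. Tip states are honored exactly on every map.
#'
#' @inheritParams mk_loglik
#' @param model \code{"ER"}, \code{"SYM"}, \code{"ARD"} (rates fitted by
#'   ML first) or a rate matrix \code{Q}.
#' @param nmaps number of maps (default 25).
#' @param seed integer seed.
#' @return list of \code{"simmap"} trees (each a \code{"phylo"} with a
#'   \code{$maps} element: per-edge named duration vectors ordered
#'   rootward to tipward, names = states, durations summing to the branch
#'   length, and a \code{$node.states} vector), with attribute
#'   \code{node_freq}: per-node posterior state frequencies across maps.
#' @export
stochastic_maps <- function(tree, states, model = "ER", nmaps = 25,
                            root = "empirical", seed = 1) {
  set.seed(seed)
  Q <- if (is.matrix(model)) model else fit_mk_ml(tree, states, model,
                                                 root = root)$Q
  labels <- rownames(Q)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  s <- .match_states(states, labels, tree$tip.label)
  part <- .mk_partials(tree, s, Q)
  w <- switch(root,
              empirical = as.numeric(table(factor(s, levels = labels)) / ntip),
              flat = rep(1 / length(labels), length(labels)),
              stationary = as.numeric(.stationary(Q)))
  pre <- rev(seq_len(nrow(tree$edge)))
  eo <- ape::reorder.phylo(tree, "postorder")
  maps <- vector("list", nmaps)
  freq <- matrix(0, ntip + nnode, length(labels),
                 dimnames = list(NULL, labels))
  for (m in seq_len(nmaps)) {
    node_state <- character(ntip + nnode)
    node_state[seq_len(ntip)] <- s
    pr_root <- w * part[ntip + 1L, ]
    node_state[ntip + 1L] <- sample(labels, 1, prob = pr_root)
    edge_maps <- vector("list", nrow(tree$edge))
    for (kk in pre) {
      p <- eo$edge[kk, 1]; ch <- eo$edge[kk, 2]
      tlen <- eo$edge.length[kk]
      P <- .pmat(Q, tlen)
      if (ch > ntip) {
        pr <- P[node_state[p], ] * part[ch, ]
        node_state[ch] <- sample(labels, 1, prob = pr)
      }
      e_orig <- which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
      edge_maps[[e_orig]] <- .sample_branch_history(
        Q, tlen, node_state[p], node_state[ch])
    }
    st <- tree
    st$maps <- edge_maps
    st$node.states <- node_state
    st$Q <- Q
    class(st) <- c("simmap", "phylo")
    maps[[m]] <- st
    freq[cbind(seq_len(ntip + nnode), match(node_state, labels))] <-
      freq[cbind(seq_len(ntip + nnode), match(node_state, labels))] + 1
  }
  attr(maps, "node_freq") <- freq / nmaps
  maps
}

#' Per-branch expected number of state changes across maps
#'
#' @param maps list of \code{"simmap"} trees.
#' @return numeric vector over edges: mean number of changes per map.
#' @export
map_change_counts <- function(maps) {
  nedge <- nrow(maps[[1]]$edge)
  counts <- vapply(maps, function(m)
    vapply(m$maps, function(seg) length(seg) - 1L, integer(1)),
    integer(nedge))
  rowMeans(matrix(counts, nrow = nedge))
}
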