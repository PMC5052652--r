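# Mk machinery: pruning likelihood, ML fits, reversible jump, dependent
# model, fossilization, stochastic maps.

test_that("pruning likelihood matches trivial and closed-form cases", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  # zero rates, all tips in the root state: probability 1
  Q0 <- make_q_binary(0, 0)
  st0 <- c(A = "0", B = "0", C = "0")
  expect_equal(mk_loglik(tr, st0, Q0), 0)

  # 2-tip tree, opposite states: closed-form two-branch expression
  t2 <- parse_newick("(A:1.5,B:2.5);")
  q <- 0.3
  Q <- make_q_binary(q, q)
  st <- c(A = "0", B = "1")
  P1 <- ornamass:::.pmat(Q, 1.5); P2 <- ornamass:::.pmat(Q, 2.5)
  hand <- 0.5 * (P1["0", "0"] * P2["0", "1"] + P1["1", "0"] * P2["1", "1"])
  expect_equal(mk_loglik(t2, st, Q, root = "flat"), log(hand),
               tolerance = 1e-12)

  expect_error(mk_loglik(tr, c(A = "0", B = "1"), Q), "unscored")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(mk_loglik(poly, st0, Q), "binary")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (seed in c(3, 5)) {
    tr <- sim_bd_tree(6, 0.1, 0.02, seed = seed)
    Q <- make_q_binary(0.05, 0.08)
    st <- sim_mk(tr, Q, seed = seed + 1)$states
    ll <- mk_loglik(tr, st, Q, root = "flat")
    combs <- expand.grid(rep(list(c("0", "1")), tr$Nnode),
                         stringsAsFactors = FALSE)
    tot <- 0
    for (r in seq_len(nrow(combs))) {
      asg <- c(st[tr$tip.label], unlist(combs[r, ]))
      p <- 0.5
      for (e in seq_len(nrow(tr$edge))) {
        P <- ornamass:::.pmat(Q, tr$edge.length[e])
        p <- p * P[asg[tr$edge[e, 1]], asg[tr$edge[e, 2]]]
      }
      tot <- tot + p
    }
    expect_equal(ll, log(tot), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to state relabeling with permuted Q", {
  tr <- shared_tree(20, seed = 31)
  st <- sim_mk(tr, make_q_binary(0.05, 0.02), seed = 32)$states
  Q <- make_q_binary(0.07, 0.03)
  l1 <- mk_loglik(tr, st, Q, root = "flat")
  # swap labels: "0" <-> "1" and permute Q accordingly
  st_swap <- setNames(ifelse(st == "0", "1", "0"), names(st))
  Q_swap <- make_q_binary(0.03, 0.07)
  l2 <- mk_loglik(tr, st_swap, Q_swap, root = "flat")
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("ML fits match the independent phytools implementation", {
  tr <- sim_bd_tree(30, 0.08, 0.03, seed = 61)
  st <- sim_mk(tr, make_q_binary(0.03, 0.05), seed = 62)$states
  ours <- fit_mk_ml(tr, st, "ARD")
  skip_if_not_installed("phytools")
  pi_emp <- as.numeric(table(factor(st, levels = c("0", "1"))) / 30)
  ref <- phytools::fitMk(tr, st, model = "ARD", pi = pi_emp)
  expect_equal(ours$logL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(sort(unname(ours$rates)), sort(unname(ref$rates)),
               tolerance = 1e-2)
})

test_that("ER and SYM coincide for binary traits; invariant traits flag", {
  tr <- shared_tree(30, seed = 33)
  st <- sim_mk(tr, make_q_binary(0.02, 0.02), seed = 34)$states
  ms <- mk_model_set(tr, st)
  er <- ms$fits$ER; sym <- ms$fits$SYM
  expect_equal(er$logL, sym$logL, tolerance = 1e-10)
  expect_equal(er$score$K, sym$score$K)

  inv <- setNames(rep("0", 30), tr$tip.label)
  f <- fit_mk_ml(tr, inv, "ER")
  expect_true(f$boundary)
  expect_lt(f$rates[1], 1e-5)
})

test_that("reversible jump prefers the generating rate model", {
  # equal-rates truth: one-parameter model should carry most mass
  tr <- shared_tree(80, seed = 35)
  st1 <- sim_mk(tr, make_q_binary(0.02, 0.02), seed = 36)$states
  rj1 <- rjmcmc_binary(tr, st1, iterations = 2000, thin = 5, burnin = 400,
                       seed = 37)
  expect_gt(rj1$model_freq[["one"]], 0.5)
  expect_equal(sum(rj1$model_freq), 1, tolerance = 1e-12)

  # strongly asymmetric truth: two-parameter model outweighs one-parameter
  st2 <- sim_mk(sim_bd_tree(100, 0.065, 0.035, seed = 230),
                make_q_binary(0.05, 0.005), seed = 231)$states
  rj2 <- rjmcmc_binary(sim_bd_tree(100, 0.065, 0.035, seed = 230), st2,
                       iterations = 2000, thin = 5, burnin = 400, seed = 38)
  expect_gt(rj2$model_freq[["two"]], rj2$model_freq[["one"]])

  # fixed-model chains are deterministic under seed and expose logL traces
  f1 <- rjmcmc_binary(tr, st1, iterations = 600, thin = 5, burnin = 100,
                      fixed_model = "equal", seed = 39)
  f2 <- rjmcmc_binary(tr, st1, iterations = 600, thin = 5, burnin = 100,
                      fixed_model = "equal", seed = 39)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$logL_trace)))
})

test_that("the dependent model nests the independent model", {
  # 8 dependent rates constrained pairwise equal = independent likelihood
  tr <- shared_tree(20, seed = 40)
  rates_i <- c(qA01 = 0.03, qA10 = 0.02, qB01 = 0.04, qB10 = 0.01)
  rates_d <- c(qA01.B0 = 0.03, qA01.B1 = 0.03, qA10.B0 = 0.02,
               qA10.B1 = 0.02, qB01.A0 = 0.04, qB01.A1 = 0.04,
               qB10.A0 = 0.01, qB10.A1 = 0.01)
  Qi <- make_q_dependent(rates_i, "independent")
  Qd <- make_q_dependent(rates_d, "dependent")
  expect_equal(Qi, Qd, tolerance = 1e-15)
  expect_equal(unname(rowSums(Qd)), rep(0, 4), tolerance = 1e-15)
  # double transitions structurally zero
  expect_equal(Qd["00", "11"], 0)
  expect_equal(Qd["01", "10"], 0)

  st <- sim_mk(tr, Qd, root_state = "00", seed = 41)$states
  l_i <- mk_loglik(tr, st, Qi, root = "flat")
  l_d <- mk_loglik(tr, st, Qd, root = "flat")
  expect_equal(l_i, l_d, tolerance = 1e-8)
})

test_that("dependent-model MCMC recovers the direction of the rate contrast", {
  tr <- shared_tree(80, seed = 51)
  rates <- c(qA01.B0 = 0.02, qA01.B1 = 0.02, qA10.B0 = 0.01,
             qA10.B1 = 0.01, qB01.A0 = 0.01, qB01.A1 = 0.2,
             qB10.A0 = 0.02, qB10.A1 = 0.02)
  sm <- sim_mk(tr, make_q_dependent(rates, "dependent"),
               root_state = "00", seed = 52)
  a <- setNames(as.integer(substr(sm$states, 1, 1) == "1"), names(sm$states))
  b <- setNames(as.integer(substr(sm$states, 2, 2) == "1"), names(sm$states))
  dep <- fit_dependent_discrete(tr, a, b, "dependent", iterations = 1200,
                                thin = 5, burnin = 300, seed = 53)
  expect_gt(median(dep$contrast), 1)
  expect_gt(mean(dep$draws$qB01.A1), mean(dep$draws$qB01.A0))

  expect_warning(fit_dependent_discrete(tr, a, a, "dependent",
                                        iterations = 60, thin = 2,
                                        burnin = 10, seed = 54),
                 "confounded")
})

test_that("node fossilization gives a Bayes factor favoring the true state", {
  tr <- shared_tree(80, seed = 55)
  orn <- sim_mk(tr, make_q_binary(0.008, 0.008), root_state = "0",
                seed = 56)$states
  bf <- fossilize_bf(tr, orn, node = 81L, forced_state = "0",
                     iterations = 1200, thin = 5, burnin = 300, seed = 57)
  expect_gt(bf$bf, 5)   # strong support for the generating root state
  expect_error(fossilize_bf(tr, orn, node = 3, forced_state = "0"),
               "internal")
})

test_that("stochastic maps honor tip states and endpoint constraints", {
  # zero rates: every map is single-regime
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  maps0 <- stochastic_maps(tr, c(A = "0", B = "0", C = "0"),
                           model = make_q_binary(0, 0), nmaps = 5, seed = 1)
  expect_true(all(vapply(maps0, function(m)
    all(vapply(m$maps, function(s) identical(names(s), "0"), logical(1))),
    logical(1))))

  # 2-tip opposite states: every branch history has at least one change
  t2 <- parse_newick("(A:2,B:3);")
  maps2 <- stochastic_maps(t2, c(A = "0", B = "1"),
                           model = make_q_binary(0.2, 0.2), nmaps = 40,
                           seed = 2)
  changes <- vapply(maps2, function(m) sum(lengths(m$maps) - 1L), numeric(1))
  expect_true(all(changes >= 1))

  # segment durations sum to branch lengths; tip segments match states
  tr3 <- shared_tree(30, seed = 58)
  st3 <- sim_mk(tr3, make_q_binary(0.03, 0.03), seed = 59)$states
  maps3 <- stochastic_maps(tr3, st3, model = "ER", nmaps = 10, seed = 3)
  for (m in maps3) {
    expect_equal(vapply(m$maps, sum, numeric(1)), m$edge.length,
                 tolerance = 1e-9)
    tipst <- vapply(seq_len(30), function(i) {
      e <- which(m$edge[, 2] == i)
      names(m$maps[[e]])[length(m$maps[[e]])]
    }, character(1))
    expect_equal(tipst, unname(as.character(st3[m$tip.label])))
  }
})

test_that("mapped change counts agree with the independent phytools sampler", {
  skip_if_not_installed("phytools")
  tr <- sim_bd_tree(40, 0.08, 0.03, seed = 260)
  Q <- make_q_binary(0.03, 0.02)
  st <- sim_mk(tr, Q, seed = 261)$states
  pi_emp <- as.numeric(table(factor(st, levels = c("0", "1"))) / 40)
  ours <- stochastic_maps(tr, st, model = Q, nmaps = 300, seed = 262)
  ref <- phytools::make.simmap(tr, st, Q = Q, pi = pi_emp, nsim = 300,
                               message = FALSE)
  ch_ours <- mean(vapply(ours, function(m) sum(lengths(m$maps) - 1L),
                         numeric(1)))
  ch_ref <- mean(vapply(ref, function(m) sum(lengths(m$maps) - 1L),
                        numeric(1)))
  # both estimate the same conditional expectation; allow Monte Carlo error
  expect_equal(ch_ours, ch_ref, tolerance = 0.15)
})
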