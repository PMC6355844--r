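test_that("tree-set reading validates branch lengths and tip coverage", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("(A:1,B:1);", "(A:2,B:2);"), tf)
  trees <- read_tree_set(tf)
  expect_length(trees, 2)
  expect_equal(trees[[1]]$edge.length, c(1, 1))
  states <- hetmap:::parse_state_spec(c(A = "ZW", B = "XY"))
  expect_silent(read_tree_set(tf, states))
  writeLines("(A:1,C:1);", tf)
  expect_error(read_tree_set(tf, states), "C")
  writeLines("(A,B);", tf)
  expect_error(read_tree_set(tf), "branch lengths")
})

test_that("transition matrices obey closed forms and limits", {
  Q <- hetmap:::q_from_rates(c(0.7, 0.2, 0.4, 0.1, 0.3, 0.6))
  expect_equal(transition_matrix(Q, 0), diag(3), ignore_attr = TRUE)
  P <- transition_matrix(Q, 1.3)
  expect_equal(rowSums(P), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(P >= 0))
  # embedded symmetric 2-state case: rates into/out of N zero
  q <- 0.9; t <- 0.7
  Q2 <- hetmap:::q_from_rates(c(q, 0, q, 0, 0, 0))
  P2 <- transition_matrix(Q2, t)
  expect_equal(P2["ZW", "ZW"], (1 + exp(-2 * q * t)) / 2, tolerance = 1e-12)
  # stationary limit with all rates equal
  Pinf <- transition_matrix(hetmap:::q_from_rates(rep(1, 6)), 50)
  expect_equal(as.numeric(Pinf), rep(1 / 3, 9), tolerance = 1e-8)
  expect_error(transition_matrix(Q, -1), ">= 0")
})

test_that("pruning equals exhaustive enumeration on random small instances", {
  set.seed(99)
  worst <- 0
  for (i in 1:300) {
    n <- sample(3:5, 1)
    tree <- ape::rtree(n)
    Q <- hetmap:::q_from_rates(runif(6, 0.05, 2))
    tips <- stats::setNames(
      sample(c("ZW", "XY", "N", "?", "ZW|XY"), n, TRUE), tree$tip.label)
    cons <- if (i %% 3 == 0) {
      list(list(tips = sample(tree$tip.label, 2),
                state = sample(c("ZW", "XY", "N"), 1)))
    } else NULL
    got <- pruning_likelihood(tree, tips, Q, constraints = cons)
    want <- brute_force_likelihood(tree, tips, Q, constraints = cons)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-10)
})

test_that("likelihoods normalise and decompose over constraint states", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.4):0.3,(C:0.1,D:0.5):0.2);")
  Q <- hetmap:::q_from_rates(c(0.5, 1.2, 0.3, 0.8, 0.2, 0.9))
  states <- c("ZW", "XY", "N")
  # sum over all 3^4 tip-state combinations = 1
  combos <- expand.grid(rep(list(states), 4), stringsAsFactors = FALSE)
  tot <- sum(vapply(seq_len(nrow(combos)), function(r) {
    pruning_likelihood(tree, stats::setNames(unlist(combos[r, ]),
                                             tree$tip.label), Q)
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-10)
  # law of total probability at every internal node
  tips <- c(A = "ZW", B = "XY", C = "N", D = "ZW")
  un <- pruning_likelihood(tree, tips, Q)
  for (clade in list(c("A", "B"), c("C", "D"), tree$tip.label)) {
    parts <- vapply(states, function(s) {
      pruning_likelihood(tree, tips, Q,
                         constraints = list(list(tips = clade, state = s)))
    }, 0)
    expect_equal(sum(parts), un, tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(
    pruning_likelihood(ape::read.tree(text = "(A:0,B:0);"),
                       c(A = "ZW", B = "?"), Q), 1 / 3, tolerance = 1e-12)
  expect_equal(
    pruning_likelihood(ape::read.tree(text = "(A:0,B:0);"),
                       c(A = "ZW", B = "XY"), Q), 0)
  expect_error(
    pruning_likelihood(tree, tips, Q,
                       constraints = list(list(tips = "Z", state = "ZW"))),
    "absent")
})

test_that("a zero proposal scale freezes the MCMC chain", {
  tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  post <- mcmc_posterior(tree, c(A = "ZW", B = "ZW"), n_iter = 200,
                         prop_scale = 0, seed = 4)
  expect_equal(nrow(unique(post$samples[, 1:8])), 1)
})

test_that("with a flat likelihood the sampler reproduces the hierarchical prior", {
  # both tips fully ambiguous: every character contributes likelihood 1
  tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  post <- mcmc_posterior(tree, c(A = "?", B = "?"), n_iter = 20000,
                         seed = 8)
  m <- post$samples$m
  # m ~ U(0, 10): mean, median and quartiles within MC bands computed
  # from a conservative effective-sample-size allowance for the chain's
  # autocorrelation (ESS ~ n/150)
  se_mean <- sqrt(100 / 12) / sqrt(20000 / 150)
  expect_lt(abs(mean(m) - 5), 4 * se_mean)
  expect_lt(abs(stats::median(m) - 5), 4 * se_mean)
  qs <- stats::quantile(m, c(0.25, 0.75))
  expect_lt(abs(qs[[1]] - 2.5), 5 * se_mean)
  expect_lt(abs(qs[[2]] - 7.5), 5 * se_mean)
  # E[rate] = E[m] = 5 under the hierarchy
  expect_lt(abs(mean(post$samples$mean_rate) - 5), 5 * se_mean)
})

test_that("posterior concentrates near the generating rate (parameter recovery)", {
  set.seed(17)
  tree <- ape::rcoal(8)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  Q <- hetmap:::q_from_rates(rep(1, 6))
  chars <- simulate_mk_characters(tree, Q, 200, seed = 5)
  post <- mcmc_posterior(tree, chars, n_iter = 3000, seed = 11)
  med <- stats::median(post$samples$mean_rate)
  expect_gt(med, 0.5)
  expect_lt(med, 2.0)
  expect_error(mcmc_posterior(list(), chars), "empty tree set")
})

test_that("stepping stones are exact for constant likelihoods and match the conjugate toy", {
  ln_prior <- function(th) if (th <= 0 || th >= 1) -Inf else 0
  init <- function() runif(1)
  propose <- function(th) list(state = th + 0.2 * rnorm(1), ln_hastings = 0)
  # constant likelihood c: ln mL = ln c for any ladder
  resc <- stepping_stone(ln_prior, function(th) log(3.7), init, propose,
                         K_stones = 4, iter_per_stone = 40, seed = 1)
  expect_equal(resc$lnml, log(3.7), tolerance = 1e-12)
  # Beta(1,1) prior, binomial likelihood y=3 of n=10 (without the
  # binomial coefficient): ln mL = ln B(4, 8)
  ln_lik <- function(th) 3 * log(th) + 7 * log(1 - th)
  res <- stepping_stone(ln_prior, ln_lik, init, propose,
                        K_stones = 16, iter_per_stone = 1000, seed = 7)
  expect_lt(abs(res$lnml - lbeta(4, 8)), 3 * max(res$se, 0.02))
  expect_error(stepping_stone(ln_prior, ln_lik, init, propose, K_stones = 1),
               ">= 2")
})

test_that("stepping-stone error shrinks as sampling effort grows", {
  ln_prior <- function(th) if (th <= 0 || th >= 1) -Inf else 0
  ln_lik <- function(th) 3 * log(th) + 7 * log(1 - th)
  init <- function() runif(1)
  propose <- function(th) list(state = th + 0.2 * rnorm(1), ln_hastings = 0)
  truth <- lbeta(4, 8)
  effort <- c(60, 300, 1500)
  mean_abs_err <- vapply(effort, function(it) {
    errs <- vapply(1:12, function(s) {
      abs(stepping_stone(ln_prior, ln_lik, init, propose, K_stones = 8,
                         iter_per_stone = it, seed = s)$lnml - truth)
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(mean_abs_err[3], mean_abs_err[1])
})

test_that("all-ZW tip data ranks the ZW/ZW scenario first with sane Bayes factors", {
  tree <- scenario_tree()
  tips <- stats::setNames(rep("ZW", 6), tree$tip.label)
  res <- evaluate_scenarios(list(tree), tips,
                            section_tips = c("A", "B", "C", "D"),
                            group_tips = c("A", "B"),
                            K_stones = 6, iter_per_stone = 250, seed = 5)
  expect_equal(res$section_state[1], "ZW")
  expect_equal(res$group_state[1], "ZW")
  expect_equal(res$BF[1], 1)
  expect_false(res$significant[1])
  expect_true(all(res$BF >= 1))
  # non-monophyletic focal clade: tree skipped with a warning
  tree2 <- ape::read.tree(text = "((A:1,E:1):1,((B:1,C:1):0.5,D:1.5):0.5);")
  expect_warning(
    expect_error(
      evaluate_scenarios(list(tree2), tips[tree2$tip.label],
                         section_tips = c("A", "B"), group_tips = c("A", "B"),
                         K_stones = 2, iter_per_stone = 10),
      "no usable trees"),
    "non-monophyletic")
})

test_that("Bayes-factor arithmetic and the significance threshold are exact", {
  lnml <- c(best = -10, next_best = -10 - log(5), third = -12.0, fourth = -11.9)
  bf <- bayes_factors(lnml)
  expect_equal(bf$BF[bf$scenario == "best"], 1)
  expect_equal(bf$BF[bf$scenario == "next_best"], 5, tolerance = 1e-12)
  expect_true(bf$significant[bf$scenario == "third"])     # delta = 2.0
  expect_false(bf$significant[bf$scenario == "fourth"])   # delta = 1.9
})
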