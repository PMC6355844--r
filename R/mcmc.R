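# Hierarchical prior on the six transition rates: rates iid Gamma with
# mean m and variance v (shape m^2/v, rate m/v); m ~ U(0,10), v ~ U(0,10).
ln_rate_prior <- function(rates, m, v) {
  if (m <= 0 || m > 10 || v <= 0 || v > 10) return(-Inf)
  if (any(rates <= 0)) return(-Inf)
  sum(stats::dgamma(rates, shape = m^2 / v, rate = m / v, log = TRUE))
}

# One Metropolis-Hastings sweep over (rates, m, v, tree index) targeting
# ln prior + beta * lnL.  `lnl_fun(rates, tree_idx)` returns the total
# log-likelihood.  Returns the updated state.
mk_mh_sweep <- function(state, lnl_fun, n_tree, beta = 1,
                        prop_scale = 0.5) {
  for (i in seq_along(state$rates)) {
    prop <- state$rates
    prop[i] <- prop[i] * exp(prop_scale * stats::rnorm(1))
    lp_new <- ln_rate_prior(prop, state$m, state$v)
    if (is.finite(lp_new)) {
      ll_new <- lnl_fun(prop, state$tree)
      lacc <- (lp_new + beta * ll_new) -
        (state$lp + beta * state$ll) +
        log(prop[i]) - log(state$rates[i])  # lognormal Hastings term
      if (log(stats::runif(1)) < lacc) {
        state$rates <- prop; state$lp <- lp_new; state$ll <- ll_new
      }
    } else stats::runif(1)  # keep the RNG stream aligned
  }
  for (h in c("m", "v")) {
    cand <- state
    cand[[h]] <- state[[h]] + 2 * prop_scale * stats::rnorm(1)
    lp_new <- ln_rate_prior(state$rates, cand$m, cand$v)
    if (log(stats::runif(1)) < lp_new - state$lp) {
      state$m <- cand$m; state$v <- cand$v; state$lp <- lp_new
    }
  }
  # Joint rescaling move: the hierarchical prior couples the rates to
  # their mean m (a funnel), so propose m' together with rates scaled by
  # m'/m; the deterministic map contributes a (m'/m)^6 Jacobian.
  m_new <- state$m + 4 * prop_scale * stats::rnorm(1)
  if (m_new > 0 && m_new <= 10 && state$m > 0) {
    fac <- m_new / state$m
    rates_new <- state$rates * fac
    lp_new <- ln_rate_prior(rates_new, m_new, state$v)
    if (is.finite(lp_new)) {
      ll_new <- lnl_fun(rates_new, state$tree)
      lacc <- (lp_new + beta * ll_new) - (state$lp + beta * state$ll) +
        6 * log(fac)
      if (log(stats::runif(1)) < lacc) {
        state$rates <- rates_new; state$m <- m_new
        state$lp <- lp_new; state$ll <- ll_new
      }
    } else stats::runif(1)
  } else stats::runif(1)
  if (n_tree > 1) {
    tr_new <- sample.int(n_tree, 1)
    ll_new <- lnl_fun(state$rates, tr_new)
    if (log(stats::runif(1)) < beta * (ll_new - state$ll)) {
      state$tree <- tr_new; state$ll <- ll_new
    }
  }
  state
}

mk_init_state <- function(lnl_fun) {
  m <- stats::runif(1, 0, 10); v <- stats::runif(1, 0, 10)
  rates <- stats::rgamma(6, shape = m^2 / v, rate = m / v)
  rates[rates <= 0] <- 1e-6
  list(rates = rates, m = m, v = v, tree = 1L,
       lp = ln_rate_prior(rates, m, v), ll = lnl_fun(rates, 1L))
}

# Total log-likelihood closure for a tree set + tip data + constraints.
mk_lnl_closure <- function(tree_set, tip_states, constraints) {
  force(tree_set); force(tip_states); force(constraints)
  function(rates, tree_idx) {
    Q <- q_from_rates(rates)
    ll <- pruning_likelihood(tree_set[[tree_idx]], tip_states, Q,
                             constraints = constraints, log = TRUE)
    sum(ll)
  }
}

#' Posterior sampling of heterogamety transition rates
#'
#' Metropolis-Hastings sampler for the three-state Markov model of
#' heterogamety over a set of species trees: the six off-diagonal rates
#' carry a hierarchical Gamma prior (mean and variance each uniform on
#' (0, 10)), a tree index is resampled uniformly each sweep, and optional
#' node constraints condition the likelihood.  Deterministic given
#' `seed`.
#'
#' @param tree_set List of `phylo` trees (non-empty).
#' @param tip_states Tip states (vector/list form of
#'   [pruning_likelihood()]), or a tips x characters matrix.
#' @param n_iter Number of sweeps (post burn-in samples are all sweeps
#'   past `burn`).
#' @param burn Burn-in sweeps discarded (default 20%).
#' @param prop_scale Proposal scale; 0 freezes the chain.
#' @param constraints Optional node constraints.
#' @param seed Integer seed.
#' @return Object of class `mk_mcmc`: data frame `samples` with the six
#'   rates, `m`, `v`, `mean_rate`, `tree`, `lnL`.
#' @export
mcmc_posterior <- function(tree_set, tip_states, n_iter = 2000,
                           burn = floor(n_iter / 5), prop_scale = 0.5,
                           constraints = NULL, seed = 1L) {
  if (!length(tree_set)) stop("empty tree set")
  if (inherits(tree_set, "phylo")) tree_set <- list(tree_set)
  lnl_fun <- mk_lnl_closure(tree_set, tip_states, constraints)
  with_seed(seed, {
    state <- mk_init_state(lnl_fun)
    keep <- matrix(NA_real_, n_iter, 10)
    for (it in seq_len(n_iter)) {
      state <- mk_mh_sweep(state, lnl_fun, length(tree_set),
                           beta = 1, prop_scale = prop_scale)
      keep[it, ] <- c(state$rates, state$m, state$v, state$tree, state$ll)
    }
    colnames(keep) <- c(sprintf("q%d", 1:6), "m", "v", "tree", "lnL")
    samples <- as.data.frame(keep[seq(burn + 1, n_iter), , drop = FALSE])
    samples$mean_rate <- rowMeans(samples[, sprintf("q%d", 1:6)])
    structure(list(samples = samples, n_iter = n_iter, burn = burn,
                   prop_scale = prop_scale),
              class = "mk_mcmc")
  })
}

#' @export
print.mk_mcmc <- function(x, ...) {
  cat("mk_mcmc:", nrow(x$samples), "samples\n")
  cat(sprintf("  posterior mean rate %.3f (median %.3f)\n",
              mean(x$samples$mean_rate), stats::median(x$samples$mean_rate)))
  invisible(x)
}

#' Generic stepping-stone marginal-likelihood estimator
#'
#' Estimates `ln` marginal likelihood via a ladder of power posteriors
#' `prior * L^beta` with `beta_k = (k/K)^(1/alpha)` (the skewed ladder
#' concentrates stones near the prior).  Each stone is sampled by
#' Metropolis-Hastings; the stone ratios are averaged in a numerically
#' stable log-sum-exp form and the standard error follows from the
#' per-stone delta method (treating draws as independent, so it is a
#' lower bound under autocorrelation).
#'
#' @param ln_prior,ln_lik Functions of the parameter state returning log
#'   prior density and log likelihood.
#' @param init Function returning an initial state drawn from the prior.
#' @param propose Function `(state) -> list(state, ln_hastings)` giving a
#'   proposal and its log Hastings correction.
#' @param K_stones Number of stones (>= 2).
#' @param iter_per_stone MH iterations per stone.
#' @param alpha Ladder skew (default 0.3, the usual Beta(alpha, 1)
#'   quantile spacing).
#' @param seed Integer seed.
#' @param burn_frac Fraction of each stone's iterations discarded.
#' @return List: `lnml`, `se`, `betas`, per-stone `ln_ratio`.
#' @export
stepping_stone <- function(ln_prior, ln_lik, init, propose,
                           K_stones = 8, iter_per_stone = 500,
                           alpha = 0.3, seed = 1L, burn_frac = 0.2) {
  if (K_stones < 2) stop("K_stones must be >= 2")
  betas <- (seq(0, K_stones) / K_stones)^(1 / alpha)
  with_seed(seed, {
    state <- init()
    lp <- ln_prior(state); ll <- ln_lik(state)
    ln_ratio <- numeric(K_stones)
    var_ratio <- numeric(K_stones)
    for (k in seq_len(K_stones)) {
      beta <- betas[k]
      dbeta <- betas[k + 1] - betas[k]
      nburn <- ceiling(burn_frac * iter_per_stone)
      lls <- numeric(iter_per_stone)
      for (it in seq_len(iter_per_stone + nburn)) {
        prop <- propose(state)
        lp_new <- ln_prior(prop$state)
        if (is.finite(lp_new)) {
          ll_new <- ln_lik(prop$state)
          lacc <- (lp_new + beta * ll_new) - (lp + beta * ll) +
            prop$ln_hastings
          if (log(stats::runif(1)) < lacc) {
            state <- prop$state; lp <- lp_new; ll <- ll_new
          }
        } else stats::runif(1)
        if (it > nburn) lls[it - nburn] <- ll
      }
      w <- dbeta * lls
      ln_ratio[k] <- log_sum_exp(w) - log(length(w))
      ww <- exp(w - max(w))
      var_ratio[k] <- stats::var(ww) / (length(ww) * mean(ww)^2)
    }
    list(lnml = sum(ln_ratio), se = sqrt(sum(var_ratio)),
         betas = betas, ln_ratio = ln_ratio)
  })
}

#' Stepping-stone marginal likelihood of the heterogamety Mk model
#'
#' Runs [stepping_stone()] with the hierarchical-prior Mk model over a
#' tree set, with optional ancestral-state constraints; the tree index is
#' part of the sampled state (uniform prior over the set).
#'
#' @inheritParams mcmc_posterior
#' @inheritParams stepping_stone
#' @return List: `lnml`, `se`, `betas`, `ln_ratio`.
#' @export
stepping_stone_lnML <- function(tree_set, tip_states, K_stones = 8,
                                iter_per_stone = 400, alpha = 0.3,
                                prop_scale = 0.5, constraints = NULL,
                                seed = 1L) {
  if (!length(tree_set)) stop("empty tree set")
  if (inherits(tree_set, "phylo")) tree_set <- list(tree_set)
  lnl_fun <- mk_lnl_closure(tree_set, tip_states, constraints)
  n_tree <- length(tree_set)
  ln_prior <- function(s) {
    lp <- ln_rate_prior(s$rates, s$m, s$v)
    if (!is.finite(lp)) return(-Inf)
    lp - log(n_tree)  # uniform tree prior
  }
  ln_lik <- function(s) lnl_fun(s$rates, s$tree)
  init <- function() {
    m <- stats::runif(1, 0, 10); v <- stats::runif(1, 0, 10)
    list(rates = stats::rgamma(6, shape = m^2 / v, rate = m / v) + 1e-9,
         m = m, v = v, tree = sample.int(n_tree, 1))
  }
  propose <- function(s) {
    pick <- sample.int(6L, 1)
    lh <- 0
    if (pick == 6L) {
      # joint funnel move: shift m and rescale the rates with it
      m_new <- s$m + 2 * prop_scale * stats::rnorm(1)
      if (m_new > 0 && s$m > 0) {
        fac <- m_new / s$m
        s$rates <- s$rates * fac
        s$m <- m_new
        lh <- 6 * log(fac)
      }
    } else if (pick == 1L) {
      i <- sample.int(6L, 1)
      fac <- exp(2 * prop_scale * stats::rnorm(1))
      s$rates[i] <- s$rates[i] * fac
      lh <- log(fac)
    } else if (pick == 2L) {
      # scale all rates together: moves quickly along the dominant
      # posterior direction (overall amount of change)
      fac <- exp(prop_scale * stats::rnorm(1))
      s$rates <- s$rates * fac
      lh <- 6 * log(fac)
    } else if (pick == 3L) {
      s$m <- s$m + 4 * prop_scale * stats::rnorm(1)
    } else if (pick == 4L) {
      s$v <- s$v + 4 * prop_scale * stats::rnorm(1)
    } else if (n_tree > 1) {
      s$tree <- sample.int(n_tree, 1)
    } else {
      i <- sample.int(6L, 1)
      fac <- exp(2 * prop_scale * stats::rnorm(1))
      s$rates[i] <- s$rates[i] * fac
      lh <- log(fac)
    }
    list(state = s, ln_hastings = lh)
  }
  stepping_stone(ln_prior, ln_lik, init, propose, K_stones,
                 iter_per_stone, alpha, seed)
}

#' Bayes factors and significance from scenario marginal likelihoods
#'
#' Given per-scenario `ln` marginal likelihoods, computes each scenario's
#' Bayes factor against the best (`BF = exp(lnML_best - lnML)`, so the
#' best scenario has BF 1) and flags differences of at least 2 `ln`
#' units as significant (the conventional "strong evidence" reading of
#' the Kass-Raftery scale).
#'
#' @param lnml Named numeric vector of `ln` marginal likelihoods.
#' @return Data frame: `scenario`, `lnML`, `delta_ln`, `BF`,
#'   `significant`, ordered best first.
#' @export
bayes_factors <- function(lnml) {
  stopifnot(is.numeric(lnml), length(lnml) >= 1)
  nm <- names(lnml) %||% paste0("scenario", seq_along(lnml))
  best <- max(lnml)
  out <- data.frame(scenario = nm, lnML = as.numeric(lnml),
                    delta_ln = best - as.numeric(lnml),
                    stringsAsFactors = FALSE)
  out$BF <- exp(out$delta_ln)
  out$significant <- out$delta_ln >= 2
  out[order(out$delta_ln), , drop = FALSE]
}

#' Rank ancestral-heterogamety scenarios by marginal likelihood
#'
#' Enumerates the nine combinations of ancestral state (ZW, XY or
#' non-dioecious) at two focal ancestors -- the MRCA of a section-level
#' tip set and the MRCA of a nested group-level tip set -- constrains
#' each in turn, estimates each scenario's `ln` marginal likelihood by
#' stepping-stone sampling, and ranks them with Bayes factors against the
#' best.  Trees in which either focal tip set is non-monophyletic are
#' skipped with a warning.
#'
#' @param tree_set List of trees.
#' @param tip_states Tip heterogamety states.
#' @param section_tips,group_tips Tip sets whose MRCAs are constrained.
#' @param states State space (default `c("ZW","XY","N")`).
#' @param ... Passed to [stepping_stone_lnML()] (`K_stones`,
#'   `iter_per_stone`, `alpha`, `prop_scale`).
#' @param seed Integer seed (one sub-stream per scenario).
#' @return Data frame of class `scenario_table`: `section_state`,
#'   `group_state`, `lnML`, `se`, `delta_ln`, `BF`, `significant`,
#'   ordered best first.
#' @export
evaluate_scenarios <- function(tree_set, tip_states, section_tips,
                               group_tips, states = c("ZW", "XY", "N"),
                               seed = 1L, ...) {
  if (inherits(tree_set, "phylo")) tree_set <- list(tree_set)
  ok <- vapply(tree_set, function(tr) {
    ape::is.monophyletic(tr, section_tips) &&
      ape::is.monophyletic(tr, group_tips)
  }, TRUE)
  if (!all(ok)) {
    warning(sum(!ok), " tree(s) skipped: focal clade non-monophyletic")
    tree_set <- tree_set[ok]
  }
  if (!length(tree_set)) stop("no usable trees: focal clades never monophyletic")
  grid <- expand.grid(group_state = states, section_state = states,
                      stringsAsFactors = FALSE)[, 2:1]
  # Common random numbers: every scenario reuses the same seed, so the
  # Monte-Carlo error of the *differences* in ln marginal likelihood is
  # much smaller than the per-scenario error.
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cs <- list(
      list(tips = section_tips, state = grid$section_state[i]),
      list(tips = group_tips, state = grid$group_state[i])
    )
    stepping_stone_lnML(tree_set, tip_states, constraints = cs,
                        seed = seed, ...)
  })
  out <- cbind(grid,
               lnML = vapply(res, `[[`, 0, "lnml"),
               se = vapply(res, `[[`, 0, "se"))
  out$delta_ln <- max(out$lnML) - out$lnML
  out$BF <- exp(out$delta_ln)
  out$significant <- out$delta_ln >= 2
  out <- out[order(out$delta_ln), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' @export
`[.scenario_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("Ancestral-heterogamety scenarios (best first):\n")
  df <- as.data.frame(x)
  df$lnML <- round(df$lnML, 3)
  df$se <- signif(df$se, 2)
  df$BF <- signif(df$BF, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
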