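#' Read a set of species trees
#'
#' Reads a newick tree-list file (one tree per line) and optionally
#' validates the tip labels against a tip-state table.  Every tree must
#' carry branch lengths.
#'
#' @param path Newick file, one tree per line.
#' @param tip_states Optional tip-state assignment (see
#'   [read_tip_states()]); every tip of every tree must appear in it.
#' @return A `multiPhylo` list of trees.
#' @export
read_tree_set <- function(path, tip_states = NULL) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!length(trees)) stop("no trees in ", path)
  for (tr in trees) {
    if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
      stop("every tree must have branch lengths")
    }
    if (!is.null(tip_states)) {
      missing_tip <- setdiff(tr$tip.label, names(tip_states))
      if (length(missing_tip)) {
        stop("tip(s) absent from the state table: ",
             paste(missing_tip, collapse = ", "))
      }
    }
  }
  trees
}

#' Read tip heterogamety states
#'
#' Parses a TSV with columns `taxon` and `state`; states are `ZW`, `XY`,
#' `N` (non-dioecious), `?` (fully ambiguous) or an alternation such as
#' `ZW|XY` (dioecious, heterogamety unknown).
#'
#' @param path TSV path.
#' @param states The full state space (default `c("ZW","XY","N")`).
#' @return A named list of allowed-state character vectors, one per taxon.
#' @export
read_tip_states <- function(path, states = c("ZW", "XY", "N")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(df))) {
    stop("tip-state table needs columns 'taxon' and 'state'")
  }
  parse_state_spec(stats::setNames(df$state, df$taxon), states)
}

# Normalise tip-state specifications to allowed-state sets.
parse_state_spec <- function(x, states = c("ZW", "XY", "N")) {
  lapply(stats::setNames(as.list(x), names(x)), function(s) {
    if (is.na(s) || s == "?") return(states)
    parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
    bad <- setdiff(parts, states)
    if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
    if (!length(parts)) stop("empty allowed-state set")
    parts
  })
}

# Validate a continuous-time rate matrix.
validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of Q must sum to 0")
  invisible(Q)
}

#' Transition probability matrix of a Markov rate matrix
#'
#' `P(t) = exp(Qt)`, with rows summing to 1 and non-negative entries.
#'
#' @param Q Valid rate matrix (off-diagonals `>= 0`, rows sum to 0).
#' @param t Elapsed time (`>= 0`).
#' @return The transition probability matrix.
#' @export
transition_matrix <- function(Q, t) {
  validate_q(Q)
  if (t < 0) stop("t must be >= 0")
  P <- ape::matexpo(Q * t)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Build a 3-state rate matrix from the 6 off-diagonal rates, ordered
# (q12, q13, q21, q23, q31, q32) over states c("ZW","XY","N").
q_from_rates <- function(rates, states = c("ZW", "XY", "N")) {
  k <- length(states)
  stopifnot(length(rates) == k * (k - 1))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) { Q[i, j] <- rates[idx]; idx <- idx + 1L }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Convert tip allowed-state sets (or a character matrix of states) into
# per-tip partial-likelihood matrices of dimension n_char x n_states.
tip_partials <- function(tree, tip_states, states) {
  ntip <- length(tree$tip.label)
  if (is.matrix(tip_states)) {      # tips x characters state matrix
    n_char <- ncol(tip_states)
    out <- lapply(tree$tip.label, function(tp) {
      m <- matrix(0, n_char, length(states))
      sts <- tip_states[tp, ]
      m[cbind(seq_len(n_char), match(sts, states))] <- 1
      m
    })
  } else {
    spec <- if (is.list(tip_states)) tip_states
            else parse_state_spec(tip_states, states)
    out <- lapply(tree$tip.label, function(tp) {
      allowed <- spec[[tp]]
      if (is.null(allowed)) stop("no state for tip '", tp, "'")
      matrix(as.numeric(states %in% allowed), 1, length(states), byrow = TRUE)
    })
  }
  out
}

#' Felsenstein pruning likelihood with optional node constraints
#'
#' Computes the likelihood of tip states under a continuous-time Markov
#' model by post-order pruning.  A constraint ("fossilisation") fixes an
#' internal node -- located as the MRCA of a tip set -- to one state by
#' zeroing the other partial likelihoods at that node, i.e. conditioning
#' rather than adding a pseudo-tip.  Ambiguous tips carry partial
#' likelihood 1 for each allowed state.
#'
#' @param tree An `ape` phylo with branch lengths (>= 2 tips).
#' @param tip_states Either a named character vector / list of allowed
#'   states per tip (`"ZW"`, `"ZW|XY"`, `"?"`, ...), or a tips x
#'   characters state matrix (rownames = tip labels) for many independent
#'   characters.
#' @param Q Rate matrix with `dimnames` naming the states (defaults to
#'   `ZW`/`XY`/`N` for 3 states).
#' @param root_prior Root state prior (default uniform).
#' @param constraints Optional list of `list(tips = c(...), state = "ZW")`
#'   node constraints.
#' @param log Return log-likelihood(s)?
#' @return Likelihood (or vector, one per character).
#' @export
pruning_likelihood <- function(tree, tip_states, Q, root_prior = NULL,
                               constraints = NULL, log = FALSE) {
  validate_q(Q)
  states <- rownames(Q) %||% (if (nrow(Q) == 3) c("ZW", "XY", "N")
                              else paste0("S", seq_len(nrow(Q))))
  dimnames(Q) <- list(states, states)
  tree <- ape::reorder.phylo(tree, "postorder")
  k <- length(states)
  ntip <- length(tree$tip.label)
  nvert <- ntip + tree$Nnode
  tp <- tip_partials(tree, tip_states, states)
  n_char <- nrow(tp[[1]])
  root_prior <- root_prior %||% rep(1 / k, k)

  mask <- matrix(1, k, nvert)
  for (cs in constraints %||% list()) {
    node <- locate_mrca(tree, cs$tips)
    st <- match(cs$state, states)
    if (is.na(st)) stop("unknown constraint state: ", cs$state)
    mask[, node] <- 0
    mask[st, node] <- 1
  }

  partial <- vector("list", nvert)
  for (i in seq_len(ntip)) partial[[i]] <- tp[[i]]
  for (i in ntip + seq_len(tree$Nnode)) {
    partial[[i]] <- matrix(1, n_char, k)
  }
  # Post-order: a node's partial is complete before its edge to the
  # parent is visited, so the constraint mask is applied exactly then.
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    P <- ape::matexpo(Q * tree$edge.length[e])
    P[P < 0] <- 0
    pc <- partial[[chd]] * rep(mask[, chd], each = n_char)
    partial[[par]] <- partial[[par]] * (pc %*% t(P))
  }
  root <- ntip + 1L
  rootp <- partial[[root]] * rep(mask[, root], each = n_char)
  lik <- as.numeric(rootp %*% root_prior)
  if (log) base::log(lik) else lik
}

# MRCA of a tip set; a single tip is its own "MRCA".
locate_mrca <- function(tree, tips) {
  missing_tip <- setdiff(tips, tree$tip.label)
  if (length(missing_tip)) {
    stop("constraint names tip(s) absent from tree: ",
         paste(missing_tip, collapse = ", "))
  }
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Simulate discrete characters along a tree
#'
#' Draws independent characters under a continuous-time Markov model by
#' simulating the embedded jump chain along each branch, starting from a
#' uniformly drawn root state.
#'
#' @param tree `ape` phylo with branch lengths.
#' @param Q Valid rate matrix (`dimnames` name the states).
#' @param n_chars Number of independent characters.
#' @param seed Integer seed.
#' @return Character matrix, tips x characters (rownames = tip labels).
#' @export
simulate_mk_characters <- function(tree, Q, n_chars, seed = 1L) {
  validate_q(Q)
  states <- rownames(Q) %||% (if (nrow(Q) == 3) c("ZW", "XY", "N")
                              else paste0("S", seq_len(nrow(Q))))
  k <- length(states)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nvert <- ntip + tree$Nnode
  with_seed(seed, {
    out <- matrix(NA_character_, ntip, n_chars,
                  dimnames = list(tree$tip.label, NULL))
    for (ch in seq_len(n_chars)) {
      state <- integer(nvert)
      state[ntip + 1L] <- sample.int(k, 1)
      for (e in seq_len(nrow(tree$edge))) {
        s <- state[tree$edge[e, 1]]
        t_left <- tree$edge.length[e]
        repeat {
          rate <- -Q[s, s]
          if (rate <= 0) break
          wait <- stats::rexp(1, rate)
          if (wait > t_left) break
          t_left <- t_left - wait
          probs <- Q[s, ]; probs[s] <- 0
          s <- sample.int(k, 1, prob = probs)
        }
        state[tree$edge[e, 2]] <- s
      }
      out[, ch] <- states[state[seq_len(ntip)]]
    }
    out
  })
}
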