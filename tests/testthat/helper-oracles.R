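# Independent oracles and fixture builders used across the suite.

# ---- Mendelian gamete enumeration ------------------------------------------
# Enumerate the possible offspring calls per sex for a planted site class
# by brute-force combination of parental gametes.  The heterogametic
# parent's gametes carry the sex chromosome ("L" = sex-limited W/Y,
# "S" = shared Z/X); offspring sex follows the inherited chromosome.
enumerate_offspring_calls <- function(class, system = "ZW") {
  # gametes: list of c(chr, allele); allele NA = no copy of the site
  het_gametes <- switch(class,
    SEXLIM = list(c("L", "B"), c("S", "A")),
    SHARED = list(c("L", NA), c("S", "A")),
    PAR    = list(c("L", "B"), c("L", "A"), c("S", "A"), c("S", "B")),
    AUTOSOMAL = list(c("-", "A"), c("-", "B"))
  )
  hom_gametes <- switch(class,
    SEXLIM = list(c("S", "A")),
    SHARED = list(c("S", "A"), c("S", "B")),
    PAR    = list(c("S", "A")),
    AUTOSOMAL = list(c("-", "A"), c("-", "B"))
  )
  het_sex <- if (system == "ZW") "F" else "M"
  out <- list(F = character(0), M = character(0))
  for (hg in het_gametes) for (og in hom_gametes) {
    alleles <- c(hg[2], og[2])
    call <- paste(sort(unique(alleles[!is.na(alleles)])), collapse = "")
    sex <- if (hg[1] == "-") c("F", "M")
           else if (hg[1] == "L") het_sex
           else setdiff(c("F", "M"), het_sex)
    for (s in sex) out[[s]] <- union(out[[s]], call)
  }
  out
}

# Map a truth label to the generic class used by the oracle.
generic_class <- function(label) {
  switch(label,
    W_LINKED = , Y_LINKED = "SEXLIM",
    Z_LINKED = , X_LINKED = "SHARED",
    PAR = "PAR", AUTOSOMAL = "AUTOSOMAL")
}

# ---- Exhaustive pruning oracle ---------------------------------------------
# Likelihood by explicit summation over all internal-node assignments,
# with per-tip ambiguity handled as a sum over allowed states.
brute_force_likelihood <- function(tree, tip_states, Q,
                                   root_prior = NULL, constraints = NULL) {
  states <- rownames(Q)
  k <- nrow(Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root_prior <- if (is.null(root_prior)) rep(1 / k, k) else root_prior
  spec <- lapply(tip_states[tree$tip.label], function(s) {
    if (is.na(s) || s == "?") states else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- ape::matexpo(Q * tree$edge.length[e]); p[p < 0] <- 0; p
  })
  cons <- rep(NA_integer_, ntip + nint)
  for (cs in if (is.null(constraints)) list() else constraints) {
    node <- if (length(cs$tips) == 1) match(cs$tips, tree$tip.label)
            else ape::getMRCA(tree, cs$tips)
    cons[node] <- match(cs$state, states)
  }
  tipmask <- lapply(seq_len(ntip), function(i) {
    v <- as.numeric(states %in% spec[[i]])
    if (!is.na(cons[i])) v <- v * as.numeric(seq_len(k) == cons[i])
    v
  })
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    st_int <- combos[r, ]
    ok <- TRUE
    for (nd in which(!is.na(cons))) {
      if (nd > ntip && st_int[nd - ntip] != cons[nd]) { ok <- FALSE; break }
    }
    if (!ok) next
    p <- root_prior[st_int[1]]  # root is node ntip+1 -> index 1
    for (e in seq_len(nrow(tree$edge))) {
      pa <- st_int[tree$edge[e, 1] - ntip]
      ch <- tree$edge[e, 2]
      p <- p * if (ch <= ntip) sum(P[[e]][pa, ] * tipmask[[ch]])
               else P[[e]][pa, st_int[ch - ntip]]
      if (p == 0) break
    }
    total <- total + p
  }
  total
}

# ---- Small genotype-table builder ------------------------------------------
# Build a one-site family table from explicit calls.
tiny_family <- function(mother, father, daughters, sons, site_id = "s1") {
  ids <- c("MOTHER", "FATHER",
           if (length(daughters)) sprintf("F%02d", seq_along(daughters)),
           if (length(sons)) sprintf("M%02d", seq_along(sons)))
  samples <- data.frame(
    sample_id = ids,
    sex = c("F", "M", rep("F", length(daughters)), rep("M", length(sons))),
    role = c("mother", "father",
             rep("offspring", length(daughters) + length(sons))),
    stringsAsFactors = FALSE)
  calls <- matrix(c(mother, father, daughters, sons), nrow = 1,
                  dimnames = list(site_id, ids))
  genotype_table(calls, samples = samples)
}

# Swap sexes and parental roles of a table (for mirror-symmetry tests).
mirror_family <- function(tab) {
  s <- tab$samples
  s$sex <- ifelse(s$sex == "F", "M", "F")
  s$role[s$role == "mother"] <- "tmp"
  s$role[s$role == "father"] <- "mother"
  s$role[s$role == "tmp"] <- "father"
  genotype_table(tab$calls, tab$depth, s, tab$sites)
}

mirror_class <- function(cl) {
  map <- c(W_LINKED = "Y_LINKED", Z_LINKED = "X_LINKED",
           Y_LINKED = "W_LINKED", X_LINKED = "Z_LINKED")
  ifelse(cl %in% names(map), map[cl], cl)
}

# A fixed 6-tip ultrametric-ish tree with short branches, used by the
# scenario tests (heights comparable to the rate prior scale so node
# constraints carry real information).
scenario_tree <- function() {
  ape::read.tree(text = paste0(
    "((((A:0.03,B:0.03):0.03,C:0.06):0.03,D:0.09):0.06,",
    "(E:0.12,F:0.12):0.03);"))
}
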