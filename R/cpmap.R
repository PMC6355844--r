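#' Haldane's mapping function
#'
#' Converts a recombination fraction into a map distance assuming no
#' crossover interference: `d = -50 * ln(1 - 2r)` centimorgans.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centimorgans.
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fractions must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cM
#' @param d Map distance(s) in centimorgans (`>= 0`).
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distances must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' LOD score for linkage versus independent assortment
#'
#' Two-point LOD score from `n` informative meioses with `R` recombinants:
#' `LOD = R log10(r) + (n - R) log10(1 - r) + n log10(2)` at the
#' maximum-likelihood `r = min(R/n, 0.5)`.  The `R = 0` limit is handled
#' exactly (`LOD = n log10 2`) and `R/n >= 0.5` gives exactly 0.
#'
#' @param n Number of informative meioses (> 0).
#' @param R Number of recombinants (`0 <= R <= n`).
#' @return The LOD score (always `>= 0`; 0 iff `r >= 0.5`).
#' @export
lod_independence <- function(n, R) {
  if (n <= 0) stop("n must be > 0")
  if (R < 0 || R > n) stop("R must lie in [0, n]")
  rhat <- R / n
  if (rhat >= 0.5) return(0)
  if (R == 0) return(n * log10(2))
  R * log10(rhat) + (n - R) * log10(1 - rhat) + n * log10(2)
}

#' Extract marker segregation data from a full-sib family
#'
#' Resolves, for every site, which parental meioses are informative and
#' which allele each parent transmitted to each offspring, in the three
#' outbred full-sib (CP) configurations: `maternal_testcross` (mother
#' heterozygous, father homozygous -- every offspring informative for the
#' maternal meiosis), `paternal_testcross` (mirror) and `both_het`
#' (both heterozygous; transmissions resolvable only for homozygous
#' offspring).  A `SEX` pseudo-marker is added: phenotypic sex scored as
#' a testcross marker heterozygous in the heterogametic parent.
#'
#' @param table A [genotype_table()].
#' @param mode `"ZW"` or `"XY"`: which parent is heterogametic.
#' @return A list of class `marker_segregation_set`; each element has
#'   `marker_id`, `configuration`, `maternal`/`paternal` transmitted
#'   allele vectors (NA where unresolved) and `n_informative`.
#' @export
marker_segregation <- function(table, mode = c("ZW", "XY")) {
  stopifnot(inherits(table, "genotype_table"))
  mode <- match.arg(mode)
  off <- offspring_ids(table)
  sexes <- offspring_sexes(table)
  m_id <- mother_id(table); f_id <- father_id(table)
  out <- list()
  for (s in rownames(table$calls)) {
    mc <- table$calls[s, m_id]; fc <- table$calls[s, f_id]
    oc <- table$calls[s, off]
    seg <- resolve_segregation(mc, fc, oc)
    if (!is.null(seg)) {
      seg$marker_id <- s
      out[[s]] <- seg
    }
  }
  # Phenotypic sex as a testcross locus in the heterogametic parent.
  het_sex <- if (mode == "ZW") "F" else "M"
  sex_code <- ifelse(sexes == het_sex, "S", "s")  # S = sex-limited chromosome
  sex_seg <- list(
    marker_id = "SEX",
    configuration = if (mode == "ZW") "maternal_testcross" else "paternal_testcross",
    maternal = if (mode == "ZW") sex_code else rep(NA_character_, length(off)),
    paternal = if (mode == "XY") sex_code else rep(NA_character_, length(off)),
    n_informative = length(off)
  )
  out[["SEX"]] <- sex_seg
  structure(out, class = "marker_segregation_set", offspring = off)
}

# Resolve transmitted parental alleles for one site; NULL if uninformative.
resolve_segregation <- function(mc, fc, oc) {
  n <- length(oc)
  mat <- rep(NA_character_, n); pat <- rep(NA_character_, n)
  if (is.na(mc) || is.na(fc)) return(NULL)
  # Only a heterozygous parent's meioses are informative: a homozygous
  # parent transmits the same allele to every offspring.
  if (is_het_call(mc) && is_single_call(fc)) {
    config <- "maternal_testcross"
    for (j in seq_len(n)) {
      cl <- oc[j]
      if (is.na(cl)) next
      if (cl == "AB") mat[j] <- other_allele(fc)
      else if (cl == fc) mat[j] <- fc
      # offspring homozygous for the non-paternal allele: miscall, leave NA
    }
  } else if (is_het_call(fc) && is_single_call(mc)) {
    config <- "paternal_testcross"
    for (j in seq_len(n)) {
      cl <- oc[j]
      if (is.na(cl)) next
      if (cl == "AB") pat[j] <- other_allele(mc)
      else if (cl == mc) pat[j] <- mc
    }
  } else if (is_het_call(mc) && is_het_call(fc)) {
    config <- "both_het"
    for (j in seq_len(n)) {
      cl <- oc[j]
      if (is.na(cl) || cl == "AB") next
      mat[j] <- cl; pat[j] <- cl
    }
  } else {
    return(NULL)  # neither parent heterozygous: no segregation
  }
  # Hemizygous-sex offspring of a paternal/maternal testcross (single-
  # allele offspring of the shared chromosome) are handled naturally:
  # their single allele is the transmitted one.
  list(configuration = config, maternal = mat, paternal = pat,
       genotypes = unname(oc),
       n_informative = sum(!is.na(mat)) + sum(!is.na(pat)))
}

#' Estimate the recombination fraction between two markers
#'
#' For two markers informative through the same parent, the estimate is
#' the direct recombinant count `R/n` under the maximum-likelihood phase
#' (the phase minimising the estimate).  For two fully heterozygous
#' (`both_het`) markers the estimate maximises the full multinomial
#' likelihood of the 3x3 offspring genotype classes over a bounded 1-D
#' search, with the phase pair chosen by maximum likelihood.  The result
#' is clipped to `[0, 0.5]`.
#'
#' @param m1,m2 Elements of a [marker_segregation()] set.
#' @return List: `rf`, `n_informative`, `phase` (`"coupling"`,
#'   `"repulsion"`, or a pair for `both_het`), `lod`.
#' @export
estimate_rf <- function(m1, m2) {
  if (identical(m1$marker_id, m2$marker_id)) {
    n <- m1$n_informative
    return(list(rf = 0, n_informative = n, phase = "coupling",
                lod = lod_independence(max(n, 1L), 0L)))
  }
  if (m1$configuration == "both_het" && m2$configuration == "both_het") {
    return(estimate_rf_bothhet(m1, m2))
  }
  best <- NULL
  for (par in c("maternal", "paternal")) {
    a <- m1[[par]]; b <- m2[[par]]
    use <- !is.na(a) & !is.na(b)
    n <- sum(use)
    if (n == 0) next
    # Each marker's transmitted alleles are binarised independently:
    # the labelling is arbitrary and phase minimisation absorbs it.
    xa <- a[use] == a[use][1]
    xb <- b[use] == b[use][1]
    mism <- sum(xa != xb)
    R <- min(mism, n - mism)
    phase <- if (mism <= n - mism) "coupling" else "repulsion"
    cand <- list(rf = R / n, n_informative = n, phase = phase,
                 lod = lod_independence(n, R))
    if (is.null(best) || cand$n_informative > best$n_informative) best <- cand
  }
  if (is.null(best)) {
    stop("no shared informative meioses between markers '",
         m1$marker_id, "' and '", m2$marker_id, "'")
  }
  best
}

# Multinomial ML for a both_het x both_het pair: offspring genotype-pair
# class counts, likelihood summed over parental haplotype transmissions,
# maximised over r for each of the four phase combinations.
estimate_rf_bothhet <- function(m1, m2) {
  g1 <- m1$genotypes; g2 <- m2$genotypes
  if (is.null(g1) || is.null(g2)) {
    stop("both_het rf estimation needs raw genotype vectors ",
         "(classify via marker_segregation on a genotype_table)")
  }
  use <- !is.na(g1) & !is.na(g2)
  n <- sum(use)
  if (n == 0) stop("no shared informative meioses")
  lev <- c("A", "AB", "B")
  counts <- table(factor(g1[use], lev), factor(g2[use], lev))
  phases <- expand.grid(pm = c("coupling", "repulsion"),
                        pf = c("coupling", "repulsion"),
                        stringsAsFactors = FALSE)
  best <- NULL
  for (i in seq_len(nrow(phases))) {
    negll <- function(r) {
      -sum(counts * log(bothhet_class_probs(r, phases$pm[i], phases$pf[i])))
    }
    opt <- stats::optimize(negll, c(1e-9, 0.5 - 1e-9))
    if (is.null(best) || opt$objective < best$objective) {
      best <- list(objective = opt$objective, rf = opt$minimum,
                   phase = paste(phases$pm[i], phases$pf[i], sep = "/"))
    }
  }
  rf <- min(max(best$rf, 0), 0.5)
  # LOD from the multinomial likelihood ratio against r = 0.5 (all
  # phases coincide at independence).
  ll_null <- sum(counts * log(bothhet_class_probs(0.5, "coupling", "coupling")))
  lod <- max(0, (-best$objective - ll_null) / log(10))
  list(rf = rf, n_informative = n, phase = best$phase, lod = lod)
}

# P(offspring genotype pair) for two both_het markers at recombination
# fraction r; phase "coupling" means A at marker 1 rides with A at 2.
bothhet_class_probs <- function(r, phase_m, phase_f) {
  hap_p <- function(phase) {
    # rows: allele at marker1, cols: allele at marker2
    if (phase == "coupling") {
      matrix(c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2), 2, 2, byrow = TRUE,
             dimnames = list(c("A", "B"), c("A", "B")))
    } else {
      matrix(c(r / 2, (1 - r) / 2, (1 - r) / 2, r / 2), 2, 2, byrow = TRUE,
             dimnames = list(c("A", "B"), c("A", "B")))
    }
  }
  hm <- hap_p(phase_m); hf <- hap_p(phase_f)
  lev <- c("A", "AB", "B")
  probs <- matrix(0, 3, 3, dimnames = list(lev, lev))
  for (ma in c("A", "B")) for (mb in c("A", "B")) {
    for (fa in c("A", "B")) for (fb in c("A", "B")) {
      gg1 <- normalize_call(c(ma, fa)); gg2 <- normalize_call(c(mb, fb))
      probs[gg1, gg2] <- probs[gg1, gg2] + hm[ma, mb] * hf[fa, fb]
    }
  }
  probs
}

#' Group markers into linkage groups by LOD threshold
#'
#' Single-linkage connected components of the graph whose edges join
#' marker pairs with LOD above the threshold.
#'
#' @param lod A symmetric matrix of pairwise LOD scores (dimnames are the
#'   marker ids); `NA` entries mean no shared information (no edge).
#' @param threshold LOD threshold for declaring linkage (default 4).
#' @return A list of character vectors, one per linkage group (singletons
#'   included), ordered by decreasing size.
#' @export
group_markers <- function(lod, threshold = 4) {
  stopifnot(is.matrix(lod), nrow(lod) == ncol(lod))
  ids <- rownames(lod) %||% as.character(seq_len(nrow(lod)))
  n <- nrow(lod)
  adj <- !is.na(lod) & lod > threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  groups <- split(ids, comp)
  groups[order(-vapply(groups, length, 1L))]
}

#' Order markers and assign Haldane map positions
#'
#' Marker order comes from greedy seriation (nearest-neighbour chain
#' growth from the tightest pair) minimising the sum of adjacent
#' recombination fractions, refined by adjacent-swap improvement until no
#' swap lowers the total.  Positions are cumulative Haldane distances
#' from the first marker; completely linked markers (rf 0) share a
#' position.  Orientation is arbitrary (a map and its reversal are
#' equivalent); the returned map is canonicalised so the first marker id
#' sorts before the last.
#'
#' @param group Character vector of marker ids.
#' @param rf Symmetric matrix of pairwise recombination fractions.
#' @param linkage_group_id Label for the output map.
#' @return A data frame of class `genetic_map`: `linkage_group`,
#'   `marker`, `position_cM`; attribute `length_cM`.
#' @export
order_and_position <- function(group, rf, linkage_group_id = "LG1") {
  stopifnot(all(group %in% rownames(rf)))
  m <- rf[group, group, drop = FALSE]
  m[is.na(m)] <- 0.5
  k <- length(group)
  ord <- if (k <= 2) seq_len(k) else seriate_greedy(m)
  ord <- improve_adjacent(ord, m)
  ids <- group[ord]
  if (k > 1 && ids[1] > ids[k]) ids <- rev(ids)
  adj <- if (k > 1) {
    vapply(seq_len(k - 1), function(i) m[ids[i], ids[i + 1]], 0)
  } else numeric(0)
  pos <- cumsum(c(0, haldane_cM(pmin(adj, 0.499))))
  out <- data.frame(linkage_group = linkage_group_id, marker = ids,
                    position_cM = pos, stringsAsFactors = FALSE)
  attr(out, "length_cM") <- if (k > 1) pos[k] else 0
  class(out) <- c("genetic_map", "data.frame")
  out
}

seriate_greedy <- function(m) {
  k <- nrow(m)
  d <- m; diag(d) <- Inf
  start <- which(d == min(d), arr.ind = TRUE)[1, ]
  chain <- as.integer(start)
  left <- setdiff(seq_len(k), chain)
  while (length(left)) {
    ends <- c(chain[1], chain[length(chain)])
    cand <- expand.grid(e = ends, v = left)
    dd <- mapply(function(e, v) d[e, v], cand$e, cand$v)
    b <- which.min(dd)
    if (cand$e[b] == chain[1]) chain <- c(cand$v[b], chain)
    else chain <- c(chain, cand$v[b])
    left <- setdiff(left, cand$v[b])
  }
  chain
}

improve_adjacent <- function(ord, m) {
  total <- function(o) {
    if (length(o) < 2) return(0)
    sum(m[cbind(o[-length(o)], o[-1])])
  }
  repeat {
    improved <- FALSE
    for (i in seq_len(length(ord) - 1)) {
      cand <- ord
      cand[c(i, i + 1)] <- cand[c(i + 1, i)]
      if (total(cand) < total(ord) - 1e-12) {
        ord <- cand; improved <- TRUE
      }
    }
    if (!improved) return(ord)
  }
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map %s: %d markers, %.1f cM\n",
              x$linkage_group[1] %||% "?", nrow(x),
              attr(x, "length_cM") %||% max(x$position_cM)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.genetic_map <- function(x, ...) {
  graphics::plot(x$position_cM, rep(0, nrow(x)), pch = 3, yaxt = "n",
                 ylab = "", xlab = "position (cM)",
                 main = x$linkage_group[1], ...)
  graphics::text(x$position_cM, 0.02, x$marker, srt = 90, adj = 0, cex = 0.7)
  invisible(x)
}

#' Map the sex-determining locus in a full-sib family
#'
#' End-to-end two-point mapping: extracts marker segregations (including
#' the `SEX` pseudo-marker), estimates all pairwise recombination
#' fractions and LOD scores through the shared parent, forms linkage
#' groups at the LOD threshold and builds the Haldane map of the group
#' containing `SEX`.  Markers with no shared informative meioses with a
#' pair member simply contribute no edge.
#'
#' @param table A [genotype_table()].
#' @param mode `"ZW"` or `"XY"`.
#' @param lod_threshold Linkage-group threshold (default 4).
#' @return List of class `sex_linkage_map`: `map` (a [order_and_position()]
#'   result for the SEX group), `groups`, `rf`, `lod`.
#' @export
sex_linkage_map <- function(table, mode = c("ZW", "XY"), lod_threshold = 4) {
  mode <- match.arg(mode)
  segs <- marker_segregation(table, mode)
  ids <- names(segs)
  if (length(ids) <= 1L) stop("no informative markers")
  k <- length(ids)
  rf <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  lod <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(rf) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    est <- tryCatch(estimate_rf(segs[[i]], segs[[j]]), error = function(e) NULL)
    if (!is.null(est)) {
      rf[i, j] <- rf[j, i] <- est$rf
      lod[i, j] <- lod[j, i] <- est$lod
    }
  }
  groups <- group_markers(lod, lod_threshold)
  sexg <- groups[vapply(groups, function(g) "SEX" %in% g, TRUE)][[1]]
  if (length(sexg) <= 1L) stop("no informative markers linked to SEX")
  map <- order_and_position(sexg, rf, linkage_group_id = "SEX_LG")
  structure(list(map = map, groups = groups, rf = rf, lod = lod),
            class = "sex_linkage_map")
}

#' @export
print.sex_linkage_map <- function(x, ...) {
  cat("sex_linkage_map:", length(x$groups), "linkage group(s)\n")
  sexpos <- x$map$position_cM[x$map$marker == "SEX"]
  cat(sprintf("  SEX locus at %.1f cM of %.1f cM total\n",
              sexpos, attr(x$map, "length_cM")))
  invisible(x)
}
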