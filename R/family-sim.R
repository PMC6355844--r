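#' Describe a synthetic full-sib family design
#'
#' Captures the layout of a simulated two-parent full-sib family: the
#' heterogamety system, the number of daughters and sons, and how many
#' fully sex-linked, pseudoautosomal (PAR) and autosomal biallelic sites
#' to plant.  The defaults mirror an RNA-seq mapping design of two
#' parents plus six progeny of each sex.
#'
#' Fully sex-linked sites alternate between the two observable SNP types:
#' sites where the variant allele rides on the sex-limited chromosome
#' (W in a ZW system, Y in XY; the heterogametic parent and the offspring
#' of its sex look heterozygous because the gametolog co-assembles), and
#' sites where the shared chromosome (Z or X) is heterozygous in the
#' homogametic parent, so offspring of the hemizygous sex carry exactly
#' one of its alleles and are never heterozygous.
#'
#' @param system `"ZW"` (female heterogamety) or `"XY"` (male).
#' @param n_daughters,n_sons Offspring counts (>= 0).
#' @param n_sexlinked Number of fully sex-linked sites.
#' @param par_rfs Numeric vector of recombination fractions in `[0, 0.5)`,
#'   one pseudoautosomal site each, measured against the sex-determining
#'   locus; crossovers along the PAR follow a no-interference (Haldane)
#'   model so the planted fractions are the marginal fractions.
#' @param n_autosomal Number of autosomal sites, planted in the intercross
#'   configuration (both parents heterozygous).
#' @param missing_rate Per-call probability that a genotype is dropped.
#' @param error_rate Per-allele-copy probability of a symmetric miscall
#'   (A flipped to B or vice versa).
#' @param seed Integer seed; the same design and seed reproduce the table
#'   byte for byte.
#' @return An object of class `family_design`.
#' @export
family_design <- function(system = c("ZW", "XY"),
                          n_daughters = 6L, n_sons = 6L,
                          n_sexlinked = 10L, par_rfs = 0.1,
                          n_autosomal = 20L,
                          missing_rate = 0.02, error_rate = 0.005,
                          seed = 1L) {
  system <- match.arg(system)
  counts <- c(n_daughters = n_daughters, n_sons = n_sons,
              n_sexlinked = n_sexlinked, n_autosomal = n_autosomal)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  probs <- c(missing_rate = missing_rate, error_rate = error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("missing_rate and error_rate must be probabilities in [0, 1]")
  }
  par_rfs <- as.numeric(par_rfs %||% numeric(0))
  if (length(par_rfs) && (any(par_rfs < 0) || any(par_rfs >= 0.5))) {
    stop("par_rfs entries must lie in [0, 0.5)")
  }
  structure(
    list(system = system,
         n_daughters = as.integer(n_daughters), n_sons = as.integer(n_sons),
         n_sexlinked = as.integer(n_sexlinked), par_rfs = par_rfs,
         n_autosomal = as.integer(n_autosomal),
         missing_rate = missing_rate, error_rate = error_rate,
         seed = as.integer(seed)),
    class = "family_design"
  )
}

#' @export
print.family_design <- function(x, ...) {
  cat(sprintf("family_design: %s system, %d daughters + %d sons\n",
              x$system, x$n_daughters, x$n_sons))
  cat(sprintf("  sites: %d sex-linked, %d PAR (rf: %s), %d autosomal\n",
              x$n_sexlinked, length(x$par_rfs),
              if (length(x$par_rfs)) paste(x$par_rfs, collapse = ", ") else "-",
              x$n_autosomal))
  cat(sprintf("  missing %.3f, error %.3f, seed %d\n",
              x$missing_rate, x$error_rate, x$seed))
  invisible(x)
}

#' Simulate a full-sib family genotype table with known truth
#'
#' Generates a [genotype_table()] for two parents plus the designed
#' offspring, planting fully sex-linked, pseudoautosomal and autosomal
#' biallelic sites with exact Mendelian (and hemizygous) transmission,
#' then applying genotyping error and missingness.  Sites are transmitted
#' independently given their truth labels; PAR sites recombine with the
#' sex-determining locus at their planted fractions via a no-interference
#' crossover chain along the heterogametic parent's meiosis.
#'
#' @param design A [family_design()].
#' @return A list with components `table` (a `genotype_table`) and
#'   `truth` (data frame: `site_id`, `class` in `W_LINKED`, `Z_LINKED`,
#'   `X_LINKED`, `Y_LINKED`, `PAR`, `AUTOSOMAL`, and `rf`, the planted
#'   recombination fraction, `NA` except for PAR sites).
#' @export
simulate_family <- function(design) {
  stopifnot(inherits(design, "family_design"))
  with_seed(design$seed, simulate_family_impl(design))
}

simulate_family_impl <- function(design) {
  zw <- design$system == "ZW"
  n_d <- design$n_daughters
  n_s <- design$n_sons
  ids <- c("MOTHER", "FATHER",
           if (n_d) sprintf("F%02d", seq_len(n_d)),
           if (n_s) sprintf("M%02d", seq_len(n_s)))
  samples <- data.frame(
    sample_id = ids,
    sex = c("F", "M", rep("F", n_d), rep("M", n_s)),
    role = c("mother", "father", rep("offspring", n_d + n_s)),
    stringsAsFactors = FALSE
  )
  n_ind <- nrow(samples)
  off_is_het_sex <- c(rep(zw, n_d), rep(!zw, n_s))  # offspring carrying the sex-limited chromosome
  n_off <- n_d + n_s

  rows <- list()
  truth <- list()
  add_site <- function(mother, father, off, class, rf = NA_real_) {
    k <- length(rows) + 1L
    rows[[k]] <<- c(mother, father, off)
    truth[[k]] <<- data.frame(class = class, rf = rf, stringsAsFactors = FALSE)
  }

  # In the generic frame the "het parent" carries the sex-limited
  # chromosome; translate to mother/father depending on the system.
  emit <- function(het_call, hom_call, off, class, rf = NA_real_) {
    if (zw) add_site(het_call, hom_call, off, class, rf)
    else add_site(hom_call, het_call, off, class, rf)
  }
  lab <- function(generic) {
    switch(generic,
           SEXLIM = if (zw) "W_LINKED" else "Y_LINKED",
           SHARED = if (zw) "Z_LINKED" else "X_LINKED",
           generic)
  }

  # Fully sex-linked sites, alternating the two SNP types.
  if (design$n_sexlinked > 0L) {
    for (i in seq_len(design$n_sexlinked)) {
      if (i %% 2L == 1L) {
        # Variant on the sex-limited chromosome (W or Y), gametolog
        # co-assembled: het parent AB, hom parent A; offspring of the
        # heterogametic sex AB, others A.  Deterministic.
        off <- ifelse(off_is_het_sex, "AB", "A")
        emit("AB", "A", off, lab("SEXLIM"))
      } else {
        # Variant between the two shared chromosomes (Z or X) of the
        # homogametic parent; het parent hemizygous A.  Offspring of the
        # heterogametic sex receive exactly one shared chromosome and are
        # hemizygous for it; the other sex pairs it with the A.
        trans <- sample(c("A", "B"), n_off, replace = TRUE)
        off <- ifelse(off_is_het_sex, trans,
                      ifelse(trans == "B", "AB", "A"))
        emit("A", "AB", off, lab("SHARED"))
      }
    }
  }

  # PAR sites: heterozygous in the heterogametic parent with the B allele
  # in coupling with the sex-limited chromosome; the other parent is AA.
  # One crossover chain per meiosis across the ordered PAR loci.
  if (length(design$par_rfs)) {
    ord <- order(design$par_rfs)
    d_pos <- -50 * log(1 - 2 * design$par_rfs[ord])  # Haldane cM from SEX
    gaps <- diff(c(0, d_pos))
    gap_rf <- (1 - exp(-gaps / 50)) / 2
    par_allele <- matrix("", n_off, length(ord))
    for (j in seq_len(n_off)) {
      coupled <- TRUE  # tracking linkage to the chromosome the offspring received
      for (k in seq_along(gap_rf)) {
        if (stats::runif(1) < gap_rf[k]) coupled <- !coupled
        on_sexlim <- if (off_is_het_sex[j]) coupled else !coupled
        par_allele[j, k] <- if (on_sexlim) "B" else "A"
      }
    }
    for (k in seq_along(ord)) {
      off <- ifelse(par_allele[, k] == "B", "AB", "A")
      emit("AB", "A", off, "PAR", rf = design$par_rfs[ord][k])
    }
  }

  # Autosomal sites: intercross AB x AB, offspring 1:2:1.
  if (design$n_autosomal > 0L) {
    for (i in seq_len(design$n_autosomal)) {
      mat <- sample(c("A", "B"), n_off, replace = TRUE)
      pat <- sample(c("A", "B"), n_off, replace = TRUE)
      off <- vapply(seq_len(n_off),
                    function(j) normalize_call(c(mat[j], pat[j])), "")
      add_site("AB", "AB", off, "AUTOSOMAL")
    }
  }

  n_site <- length(rows)
  calls <- if (n_site) do.call(rbind, rows) else
    matrix(character(0), 0, n_ind)
  truth <- if (n_site) do.call(rbind, truth) else
    data.frame(class = character(0), rf = numeric(0))

  # Genotyping error: each allele copy flips independently.
  if (n_site && design$error_rate > 0) {
    for (r in seq_len(n_site)) for (c in seq_len(n_ind)) {
      al <- call_alleles(calls[r, c])
      flip <- stats::runif(length(al)) < design$error_rate
      if (any(flip)) {
        al[flip] <- vapply(al[flip], other_allele, "")
        calls[r, c] <- normalize_call(al)
      }
    }
  }

  depth <- matrix(stats::rpois(n_site * n_ind, 30) + 2L, n_site, n_ind)
  storage.mode(depth) <- "integer"

  # Missingness, independent of genotype.
  if (n_site && design$missing_rate > 0) {
    drop <- matrix(stats::runif(n_site * n_ind) < design$missing_rate,
                   n_site, n_ind)
    calls[drop] <- NA_character_
    depth[drop] <- 0L
  }

  class_contig <- c(W_LINKED = "chrW", Z_LINKED = "chrZ",
                    X_LINKED = "chrX", Y_LINKED = "chrY",
                    PAR = "chrPAR", AUTOSOMAL = "chrAUT")
  contig <- unname(class_contig[truth$class])
  pos <- stats::ave(seq_len(n_site), contig, FUN = seq_along)
  site_id <- if (n_site) sprintf("%s_%03d", tolower(sub("chr", "", contig)), pos)
             else character(0)
  sites <- data.frame(site_id = site_id, contig = contig, pos = pos,
                      stringsAsFactors = FALSE)
  colnames(calls) <- ids
  tab <- genotype_table(calls, depth, samples, sites)
  list(table = tab,
       truth = data.frame(site_id = site_id, class = truth$class,
                          rf = truth$rf, stringsAsFactors = FALSE),
       design = design)
}
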