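#' Strict-clock age from synonymous divergence
#'
#' Converts a pairwise synonymous-site divergence into a divergence time
#' under a strict molecular clock.  Pairwise divergence accumulates along
#' the two lineages since the common ancestor, so
#' `age = dS / (2 * rate * generations_per_year)` years.
#'
#' @param ds Pairwise synonymous divergence (substitutions/site, `>= 0`).
#' @param rate Substitution rate in synonymous substitutions/site/year
#'   (`> 0`); e.g. the angiosperm average 5.35e-9.
#' @param gen_per_year Generations per year (default 1).
#' @return Age in years.
#' @export
age_from_dS <- function(ds, rate, gen_per_year = 1) {
  if (any(ds < 0)) stop("dS must be >= 0")
  if (rate <= 0) stop("substitution rate must be > 0")
  if (gen_per_year <= 0) stop("gen_per_year must be > 0")
  ds / (2 * rate * gen_per_year)
}

#' Mean age and standard error from per-gene divergences
#'
#' Applies the strict-clock conversion to the mean of a per-gene `dS`
#' distribution; the standard error of the mean `dS` propagates linearly:
#' `SE(age) = (sd(dS)/sqrt(n)) / (2 * rate * gen_per_year)`.
#'
#' @param ds_per_gene Numeric vector of per-gene synonymous divergences
#'   (length >= 2).
#' @inheritParams age_from_dS
#' @return Object of class `age_estimate`: list with `mean_age_years`,
#'   `se_years`, `n_genes`, `mean_ds`, `rate`, `gen_per_year`.
#' @export
age_summary <- function(ds_per_gene, rate, gen_per_year = 1) {
  if (length(ds_per_gene) < 2) stop("need dS for at least 2 genes")
  denom <- 2 * rate * gen_per_year
  structure(
    list(mean_age_years = mean(ds_per_gene) / denom,
         se_years = stats::sd(ds_per_gene) / sqrt(length(ds_per_gene)) / denom,
         n_genes = length(ds_per_gene),
         mean_ds = mean(ds_per_gene),
         rate = rate, gen_per_year = gen_per_year),
    class = "age_estimate"
  )
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("MRCA age: %.0f years (%.0f ky, %.2f MY), SE = %.0f years\n",
              x$mean_age_years, x$mean_age_years / 1e3,
              x$mean_age_years / 1e6, x$se_years))
  cat(sprintf("  from mean dS = %.4g over %d genes at %.3g subs/site/year\n",
              x$mean_ds, x$n_genes, x$rate))
  invisible(x)
}

#' Gene density of a genomic region
#'
#' Physical span per gene, e.g. a 180 kb non-recombining region carrying
#' 5 genes has one gene per 36 kb.
#'
#' @param region_kb Region length in kilobases (`> 0`).
#' @param n_genes Number of genes in the region (`> 0`).
#' @return Kilobases per gene.
#' @export
gene_density <- function(region_kb, n_genes) {
  if (region_kb <= 0 || n_genes <= 0) stop("region_kb and n_genes must be > 0")
  region_kb / n_genes
}
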