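#' Classify a site's sex-linkage pattern in a full-sib family
#'
#' Applies the idealised segregation rules for completely sex-linked SNPs
#' in a two-parent full-sib family, under a chosen heterogamety model.
#' In ZW mode (female heterogamety):
#'
#' * `W_LINKED`: an allele present in the mother and every daughter and
#'   absent from the father and every son (the sex-limited chromosome's
#'   allele, visible through gametolog co-assembly).
#' * `Z_LINKED`: father heterozygous, mother single-allele; no daughter
#'   is heterozygous (daughters are hemizygous for one paternal Z) and
#'   every son carries the maternal allele.
#' * `PAR_CANDIDATE`: one of the above parental configurations with a
#'   small number of inconsistent offspring (putative recombinants); a
#'   screening label only -- definitive pseudoautosomal status comes from
#'   linkage mapping.
#' * `AUTOSOMAL` / `UNCLASSIFIED`: everything else (uninformative
#'   configuration, too many violations, or missing parents).
#'
#' XY mode is the exact mirror (swap sexes and parents; `W -> Y`,
#' `Z -> X`).  Classification is invariant to offspring ordering and to a
#' consistent relabelling of the two alleles.
#'
#' A precedence gate protects against a cross-model ambiguity: a site
#' whose calls perfectly match the sex-limited presence pattern of the
#' *opposite* system (e.g., in ZW mode, a paternal allele carried by every
#' son and absent from the mother and every daughter) is Mendelian-
#' consistent with complete linkage under the mirrored model and is
#' therefore not called `Z_LINKED`/`X_LINKED`; it is left `UNCLASSIFIED`
#' in the non-matching mode.
#'
#' @param table A [genotype_table()].
#' @param site_id Site identifier (must exist in `table`).
#' @param mode `"ZW"` or `"XY"`.
#' @param max_inconsistent Maximum offspring violating the pattern for a
#'   *complete* call (default 0, i.e. no recombinants).
#' @param max_missing Maximum offspring with missing calls tolerated
#'   (default: 25% of the offspring).
#' @param par_max_inconsistent Upper bound on violations for the
#'   `PAR_CANDIDATE` screening label (default: 25% of the offspring,
#'   at least 1).
#' @return A one-row data frame of class `site_classification`:
#'   `site_id`, `mode`, `class`, `n_consistent`, `n_inconsistent`,
#'   `n_missing`.  The three counts always sum to the offspring count.
#' @export
classify_site <- function(table, site_id, mode = c("ZW", "XY"),
                          max_inconsistent = 0L, max_missing = NULL,
                          par_max_inconsistent = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  mode <- match.arg(mode)
  if (!site_id %in% rownames(table$calls)) {
    stop("site '", site_id, "' not present in the genotype table")
  }
  n_off <- length(offspring_ids(table))
  th <- classify_thresholds(n_off, max_inconsistent, max_missing,
                            par_max_inconsistent)
  res <- classify_one(table$calls[site_id, ], table$samples, mode, th)
  out <- data.frame(site_id = site_id, mode = mode, class = res$class,
                    n_consistent = res$n_consistent,
                    n_inconsistent = res$n_inconsistent,
                    n_missing = res$n_missing, stringsAsFactors = FALSE)
  class(out) <- c("site_classification", "data.frame")
  out
}

classify_thresholds <- function(n_off, max_inconsistent, max_missing,
                                par_max_inconsistent) {
  list(
    max_inconsistent = as.integer(max_inconsistent),
    max_missing = as.integer(max_missing %||% ceiling(0.25 * n_off)),
    par_max_inconsistent =
      as.integer(par_max_inconsistent %||% max(1, ceiling(0.25 * n_off)))
  )
}

# Core rule engine.  Works in a system-generic frame where `het` is the
# heterogametic parent's call and `hs`/`os` flag offspring of the
# heterogametic / other sex; XY mode is obtained by swapping roles.
classify_one <- function(calls, samples, mode, th) {
  zw <- mode == "ZW"
  het_call <- calls[samples$sample_id[samples$role ==
                                        if (zw) "mother" else "father"]]
  hom_call <- calls[samples$sample_id[samples$role ==
                                        if (zw) "father" else "mother"]]
  off <- samples$role == "offspring"
  off_calls <- calls[samples$sample_id[off]]
  het_sex <- samples$sex[off] == (if (zw) "F" else "M")
  n_off <- length(off_calls)
  n_na <- sum(is.na(off_calls))

  finish <- function(class, cons, inc, mis) {
    list(class = class, n_consistent = cons, n_inconsistent = inc,
         n_missing = mis)
  }
  uninformative <- function(class) finish(class, n_off - n_na, 0L, n_na)

  if (is.na(het_call) || is.na(hom_call)) return(uninformative("UNCLASSIFIED"))

  lab_sexlim <- if (zw) "W_LINKED" else "Y_LINKED"
  lab_shared <- if (zw) "Z_LINKED" else "X_LINKED"

  # Sex-limited-chromosome pattern: allele x in het parent, not in hom.
  x <- setdiff(call_alleles(het_call), call_alleles(hom_call))
  if (length(x) == 1L) {
    cons <- as.logical(mapply(function(cl, hs) {
      if (is.na(cl)) NA else if (hs) has_allele(cl, x) else !has_allele(cl, x)
    }, off_calls, het_sex))
    return(pattern_verdict(cons, lab_sexlim, th, n_off))
  }

  # Shared-chromosome pattern: hom parent heterozygous, het parent single.
  if (is_het_call(hom_call) && is_single_call(het_call)) {
    m <- het_call
    y <- other_allele(m)  # hom-parent allele absent from the het parent
    # Precedence gate: perfect opposite-system presence pattern.
    os_calls <- off_calls[!het_sex]
    hs_calls <- off_calls[het_sex]
    opp <- length(os_calls[!is.na(os_calls)]) > 0 &&
      all(vapply(os_calls[!is.na(os_calls)], has_allele, TRUE, x = y)) &&
      !any(vapply(hs_calls[!is.na(hs_calls)], has_allele, TRUE, x = y))
    if (opp) return(uninformative("UNCLASSIFIED"))
    cons <- as.logical(mapply(function(cl, hs) {
      if (is.na(cl)) NA else if (hs) is_single_call(cl) else has_allele(cl, m)
    }, off_calls, het_sex))
    return(pattern_verdict(cons, lab_shared, th, n_off))
  }

  uninformative("AUTOSOMAL")
}

pattern_verdict <- function(cons, label, th, n_off) {
  mis <- sum(is.na(cons))
  inc <- sum(!cons, na.rm = TRUE)
  con <- n_off - mis - inc
  class <-
    if (mis > th$max_missing) "UNCLASSIFIED"
    else if (inc <= th$max_inconsistent) label
    else if (inc <= th$par_max_inconsistent) "PAR_CANDIDATE"
    else "AUTOSOMAL"
  list(class = class, n_consistent = con, n_inconsistent = inc,
       n_missing = mis)
}

#' Classify every site of a genotype table
#'
#' Batch version of [classify_site()]; returns one row per site.
#'
#' @inheritParams classify_site
#' @param table A [genotype_table()].
#' @return A data frame of class `site_classification` with one row per
#'   site (empty for an empty table).  `summary()` tabulates the classes.
#' @export
classify_table <- function(table, mode = c("ZW", "XY"),
                           max_inconsistent = 0L, max_missing = NULL,
                           par_max_inconsistent = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  mode <- match.arg(mode)
  n_off <- length(offspring_ids(table))
  th <- classify_thresholds(n_off, max_inconsistent, max_missing,
                            par_max_inconsistent)
  ids <- rownames(table$calls)
  res <- lapply(ids, function(s) {
    classify_one(table$calls[s, ], table$samples, mode, th)
  })
  out <- data.frame(
    site_id = ids %||% character(0),
    mode = rep(mode, length(ids)),
    class = vapply(res, `[[`, "", "class"),
    n_consistent = vapply(res, `[[`, 0L, "n_consistent"),
    n_inconsistent = vapply(res, `[[`, 0L, "n_inconsistent"),
    n_missing = vapply(res, `[[`, 0L, "n_missing"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_classification", "data.frame")
  out
}

#' @export
summary.site_classification <- function(object, ...) {
  tab <- table(factor(object$class,
                      levels = c("W_LINKED", "Z_LINKED", "X_LINKED",
                                 "Y_LINKED", "PAR_CANDIDATE", "AUTOSOMAL",
                                 "UNCLASSIFIED")))
  tab[tab > 0 | names(tab) %in% c("AUTOSOMAL", "UNCLASSIFIED")]
}

#' Infer which sex is heterogametic
#'
#' Classifies the table under both the ZW and the XY model and compares
#' the numbers of completely sex-linked sites each model explains.  The
#' verdict is `ZW` if at least `min_count` sites are completely W- or
#' Z-linked and that count is at least `min_ratio` times the mirrored
#' count (symmetrically for `XY`); otherwise `AMBIGUOUS`.
#'
#' @param table A [genotype_table()].
#' @param min_count Minimum number of complete sex-linked sites (default 5).
#' @param min_ratio Minimum ratio over the competing model (default 3).
#' @param ... Passed to [classify_table()] (thresholds).
#' @return An object of class `heterogamety_call`: list with `verdict`
#'   (`"ZW"`, `"XY"` or `"AMBIGUOUS"`), `n_zw_complete`, `n_xy_complete`,
#'   `ratio`, `thresholds`, and the two classification tables.
#' @export
infer_heterogamety <- function(table, min_count = 5L, min_ratio = 3, ...) {
  stopifnot(inherits(table, "genotype_table"))
  zw <- classify_table(table, "ZW", ...)
  xy <- classify_table(table, "XY", ...)
  n_zw <- sum(zw$class %in% c("W_LINKED", "Z_LINKED"))
  n_xy <- sum(xy$class %in% c("X_LINKED", "Y_LINKED"))
  verdict <-
    if (n_zw >= min_count && n_zw >= min_ratio * n_xy) "ZW"
    else if (n_xy >= min_count && n_xy >= min_ratio * n_zw) "XY"
    else "AMBIGUOUS"
  structure(
    list(verdict = verdict, n_zw_complete = n_zw, n_xy_complete = n_xy,
         ratio = if (n_xy == 0 && n_zw == 0) NA_real_
                 else max(n_zw, n_xy) / max(1e-12, min(n_zw, n_xy)),
         thresholds = list(min_count = min_count, min_ratio = min_ratio),
         zw_classification = zw, xy_classification = xy),
    class = "heterogamety_call"
  )
}

#' @export
print.heterogamety_call <- function(x, ...) {
  cat("Heterogamety call:", x$verdict, "\n")
  cat(sprintf("  complete sex-linked sites: ZW model %d, XY model %d\n",
              x$n_zw_complete, x$n_xy_complete))
  cat(sprintf("  thresholds: min_count = %d, min_ratio = %s\n",
              x$thresholds$min_count, format(x$thresholds$min_ratio)))
  invisible(x)
}
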