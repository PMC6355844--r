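#' Construct a full-sib family genotype table
#'
#' A `genotype_table` holds per-site, per-individual genotype calls with
#' read depths for a two-parent full-sib family.  Calls are encoded as
#' `"A"` (single allele A: homozygous, or hemizygous in the sex carrying
#' one copy), `"B"`, `"AB"` (heterozygous) or `NA` (missing).  Diploid
#' variant callers report hemizygotes as homozygous-looking single-allele
#' calls, so hemizygosity is only visible through segregation patterns.
#'
#' @param calls Character matrix, sites x individuals, entries in
#'   `c("A","B","AB", NA)`.  Row names are site ids, column names sample ids.
#' @param depth Integer matrix of read depths, same dimensions as `calls`.
#'   If `NULL`, missing calls get depth 0 and observed calls a nominal
#'   depth of 30.
#' @param samples Data frame with columns `sample_id`, `sex` (`"F"`/`"M"`)
#'   and `role` (`"mother"`, `"father"`, `"offspring"`).  Exactly one
#'   mother and one father are required; every individual needs a sex.
#' @param sites Optional data frame with columns `site_id`, `contig`,
#'   `pos` (1-based).  Defaults to one synthetic contig.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, depth = NULL, samples, sites = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  bad <- !is.na(calls) & !(calls %in% c("A", "B", "AB"))
  if (any(bad)) {
    stop("invalid genotype call(s): ", paste(unique(calls[bad]), collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "role")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns sample_id, sex, role")
  }
  if (sum(samples$role == "mother") != 1L || sum(samples$role == "father") != 1L) {
    stop("exactly one mother and one father are required")
  }
  if (any(is.na(samples$sex)) || !all(samples$sex %in% c("F", "M"))) {
    stop("every individual must have sex 'F' or 'M'")
  }
  if (ncol(calls) != nrow(samples)) {
    stop("calls has ", ncol(calls), " columns but samples has ", nrow(samples), " rows")
  }
  if (is.null(colnames(calls))) colnames(calls) <- samples$sample_id
  if (!identical(colnames(calls), samples$sample_id)) {
    calls <- calls[, samples$sample_id, drop = FALSE]
  }
  if (is.null(depth)) {
    depth <- matrix(30L, nrow = nrow(calls), ncol = ncol(calls),
                    dimnames = dimnames(calls))
    depth[is.na(calls)] <- 0L
  }
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  dimnames(depth) <- dimnames(calls)
  if (any(depth < 0, na.rm = TRUE)) stop("read depths must be >= 0")
  if (is.null(sites)) {
    ids <- rownames(calls) %||% paste0("site", seq_len(nrow(calls)))
    sites <- data.frame(site_id = ids, contig = "contig1",
                        pos = seq_len(nrow(calls)), stringsAsFactors = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(calls) <- sites$site_id
  rownames(depth) <- sites$site_id
  structure(
    list(calls = calls, depth = depth, samples = samples, sites = sites),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  n_off <- sum(x$samples$role == "offspring")
  cat("genotype_table:", nrow(x$calls), "sites x", ncol(x$calls), "individuals\n")
  cat("  offspring:", sum(x$samples$sex == "F" & x$samples$role == "offspring"),
      "F /", sum(x$samples$sex == "M" & x$samples$role == "offspring"), "M",
      sprintf("(%d total)\n", n_off))
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

# Convenience accessors (internal).
mother_id <- function(tab) tab$samples$sample_id[tab$samples$role == "mother"]
father_id <- function(tab) tab$samples$sample_id[tab$samples$role == "father"]
offspring_ids <- function(tab) tab$samples$sample_id[tab$samples$role == "offspring"]
offspring_sexes <- function(tab) {
  s <- tab$samples
  stats::setNames(s$sex, s$sample_id)[offspring_ids(tab)]
}

#' Mask low-depth genotype calls
#'
#' Sets calls whose read depth falls below `min_depth` to missing,
#' mirroring the quality-control rule of masking sites with read depth
#' below 2 before downstream analysis.  Nothing else changes: site and
#' sample bookkeeping is preserved.
#'
#' @param table A [genotype_table()].
#' @param min_depth Minimum acceptable read depth (default 2).
#' @return A `genotype_table` with sub-threshold calls set to `NA`.
#' @export
mask_low_depth <- function(table, min_depth = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.numeric(min_depth) || length(min_depth) != 1L || min_depth < 0) {
    stop("min_depth must be a single count >= 0")
  }
  table$calls[table$depth < min_depth] <- NA_character_
  table
}
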