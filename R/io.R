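#' Write a simulated family to VCF 4.2 plus companion tables
#'
#' Writes the genotype table as a plain-text VCF 4.2 file (GT and DP per
#' sample, 1-based positions, one synthetic contig per planted site
#' class, alleles A/B as REF/ALT), the sample manifest TSV
#' (`sample_id`, `sex`, `role`), the truth-label TSV and, when present,
#' the expression matrix TSV.  Output headers record the seed and a
#' configuration hash so runs are traceable.
#'
#' @param sim Result of [simulate_family()] (optionally with an `expr`
#'   element from [simulate_expression()]).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, the named vector of written paths.
#' @export
write_family_vcf <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim$table, "genotype_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sim$table
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             manifest = file.path(dir, paste0(prefix, ".manifest.tsv")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  seed <- if (!is.null(sim$design)) sim$design$seed else NA
  hash <- config_hash(sim$design %||% list())

  gt <- c(A = "0/0", B = "1/1", AB = "0/1")
  n_site <- nrow(tab$calls)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=hetmap_", utils::packageVersion("hetmap")),
    paste0("##seed=", seed),
    paste0("##confighash=", hash),
    sprintf("##contig=<ID=%s>", unique(tab$sites$contig)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", tab$samples$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(n_site), function(i) {
    cells <- vapply(seq_len(ncol(tab$calls)), function(j) {
      g <- tab$calls[i, j]
      paste0(if (is.na(g)) "./." else gt[[g]], ":", tab$depth[i, j])
    }, "")
    paste(c(tab$sites$contig[i], tab$sites$pos[i], tab$sites$site_id[i],
            "A", "B", ".", "PASS", ".", "GT:DP", cells), collapse = "\t")
  }, "")
  writeLines(c(header, body), paths[["vcf"]])
  utils::write.table(tab$samples, paths[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth)) {
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$expr)) {
    paths[["expr"]] <- file.path(dir, paste0(prefix, ".expression.tsv"))
    utils::write.table(sim$expr, paths[["expr"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a family genotype table from VCF plus manifest
#'
#' Parses a VCF 4.2 file (via `vcfR`) together with a sample manifest and
#' returns a [genotype_table()].  Only biallelic SNP records are kept;
#' multiallelic or indel records are skipped and counted.  Genotypes map
#' as `0/0 -> A`, `1/1 -> B`, `0/1` (or `1/0`, phased variants included)
#' `-> AB`, `./. -> ` missing.
#'
#' @param vcf_path VCF file (plain text or bgzipped).
#' @param manifest_path TSV with `sample_id`, `sex`, `role` covering every
#'   VCF sample, with exactly one mother and one father.
#' @return A `genotype_table`; attribute `n_skipped` counts skipped
#'   records.
#' @export
read_vcf_family <- function(vcf_path, manifest_path) {
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex", "role") %in% names(manifest))) {
    stop("manifest needs columns sample_id, sex, role")
  }
  if (sum(manifest$role == "mother") != 1L ||
      sum(manifest$role == "father") != 1L) {
    stop("manifest must name exactly one mother and one father")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!keep)
  vcf_samples <- colnames(v@gt)[-1]
  missing_sample <- setdiff(vcf_samples, manifest$sample_id)
  if (length(missing_sample)) {
    stop("VCF sample(s) absent from manifest: ",
         paste(missing_sample, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_character_, nrow(gt_norm), ncol(gt_norm),
                  dimnames = dimnames(gt_norm))
  calls[gt_norm %in% "0/0"] <- "A"
  calls[gt_norm %in% "1/1"] <- "B"
  calls[gt_norm %in% c("0/1", "1/0")] <- "AB"
  dp[is.na(dp)] <- 0
  ids <- fix[keep, "ID"]
  if (anyNA(ids) || any(ids == ".")) {
    ids <- paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = "_")
  }
  sites <- data.frame(site_id = ids, contig = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      stringsAsFactors = FALSE)
  rownames(calls) <- ids
  manifest <- manifest[match(vcf_samples, manifest$sample_id), , drop = FALSE]
  tab <- genotype_table(calls, dp, manifest, sites)
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Write a site-classification table to TSV
#'
#' @param classification A [classify_table()] result.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(classification, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hetmap %s classification; seed=%s",
                     utils::packageVersion("hetmap"), seed), con)
  utils::write.table(as.data.frame(classification), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a heterogamety report as key-value text
#'
#' @param call An [infer_heterogamety()] result.
#' @param path Output path.
#' @param seed Optional seed recorded in the report.
#' @return Invisibly, `path`.
#' @export
write_heterogamety_report <- function(call, path, seed = NA) {
  lines <- c(
    sprintf("hetmap_version: %s", utils::packageVersion("hetmap")),
    sprintf("seed: %s", seed),
    sprintf("verdict: %s", call$verdict),
    sprintf("n_zw_complete: %d", call$n_zw_complete),
    sprintf("n_xy_complete: %d", call$n_xy_complete),
    sprintf("ratio: %s", format(call$ratio)),
    sprintf("min_count: %d", call$thresholds$min_count),
    sprintf("min_ratio: %s", format(call$thresholds$min_ratio))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a genetic map as marker-per-line TSV
#'
#' @param map A [order_and_position()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format expression matrix TSV
#'
#' @param path TSV with columns `transcript`, `sample`, `tissue`, `count`.
#' @return Data frame.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "sample", "tissue", "count")
  if (!all(need %in% names(df))) {
    stop("expression table needs columns ", paste(need, collapse = ", "))
  }
  df
}
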