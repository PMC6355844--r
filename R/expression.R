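#' Simulate a transcript expression matrix with planted sex-specificity
#'
#' Draws Poisson read counts for a set of transcripts across the samples
#' of a full-sib family, in one or more tissues.  Planted sex-specific
#' transcripts have exactly zero counts in every sample of the opposite
#' sex (in all tissues), emulating the mapping signal of transcripts
#' present only in one sex; all other transcripts draw counts in both
#' sexes.
#'
#' @param n_transcripts Total number of transcripts.
#' @param n_female_specific,n_male_specific Numbers of planted
#'   sex-specific transcripts (their sum must not exceed
#'   `n_transcripts`).
#' @param tissues Character vector of tissue names (e.g.
#'   `c("leaf", "bud")`).
#' @param depth_mean Mean read count per expressed transcript/sample.
#' @param samples Data frame with `sample_id` and `sex` columns; defaults
#'   to 2 parents plus six offspring of each sex.
#' @param seed Integer seed.
#' @return List with `expr` (long-format data frame: `transcript`,
#'   `sample`, `tissue`, `count`), `truth` (data frame: `transcript`,
#'   `sex_specific` in `"F"`, `"M"`, `"none"`) and `samples`.
#' @export
simulate_expression <- function(n_transcripts, n_female_specific = 0L,
                                n_male_specific = 0L,
                                tissues = c("leaf", "bud"),
                                depth_mean = 50, samples = NULL,
                                seed = 1L) {
  if (n_female_specific + n_male_specific > n_transcripts) {
    stop("n_female_specific + n_male_specific exceeds n_transcripts")
  }
  if (n_transcripts < 0 || n_female_specific < 0 || n_male_specific < 0) {
    stop("transcript counts must be non-negative")
  }
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = c("MOTHER", "FATHER", sprintf("F%02d", 1:6),
                    sprintf("M%02d", 1:6)),
      sex = c("F", "M", rep("F", 6), rep("M", 6)),
      stringsAsFactors = FALSE
    )
  }
  with_seed(seed, {
    tr <- sprintf("tr%04d", seq_len(n_transcripts))
    spec <- rep("none", n_transcripts)
    if (n_female_specific) spec[seq_len(n_female_specific)] <- "F"
    if (n_male_specific) {
      spec[n_female_specific + seq_len(n_male_specific)] <- "M"
    }
    grid <- expand.grid(transcript = tr, sample = samples$sample_id,
                        tissue = tissues, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    sex_of <- stats::setNames(samples$sex, samples$sample_id)
    sx <- sex_of[grid$sample]
    sp <- spec[match(grid$transcript, tr)]
    counts <- stats::rpois(nrow(grid), depth_mean)
    # Sex-specific transcripts: guaranteed expression in the focal sex,
    # hard zero in the other.
    focal <- sp != "none" & sx == sp
    counts[focal] <- counts[focal] + 1L
    counts[sp != "none" & sx != sp] <- 0L
    grid$count <- counts
    list(expr = grid,
         truth = data.frame(transcript = tr, sex_specific = spec,
                            stringsAsFactors = FALSE),
         samples = samples)
  })
}

#' Detect sex-specific transcripts
#'
#' Returns transcripts expressed in every sample of the focal sex and
#' (near-)absent from every sample of the opposite sex, in *every*
#' required tissue -- the two-tissue intersection rule that separates
#' constitutively sex-limited transcripts from tissue-specific ones.
#'
#' @param expr Long-format expression data frame with columns
#'   `transcript`, `sample`, `tissue`, `count`.
#' @param samples Data frame mapping `sample_id` to `sex`.
#' @param focal_sex `"F"` or `"M"`.
#' @param tissues_required Tissues in which the pattern must hold
#'   (must all be present in `expr`).
#' @param min_count Minimum count in every focal-sex sample (default 5).
#' @param max_leak Maximum tolerated count in any opposite-sex sample
#'   (default 0).
#' @return Character vector of transcript ids.
#' @export
detect_sex_specific_transcripts <- function(expr, samples,
                                            focal_sex = c("F", "M"),
                                            tissues_required = NULL,
                                            min_count = 5L, max_leak = 0L) {
  focal_sex <- match.arg(focal_sex)
  need <- c("transcript", "sample", "tissue", "count")
  if (!all(need %in% names(expr))) {
    stop("expr must have columns transcript, sample, tissue, count")
  }
  present <- unique(expr$tissue)
  tissues_required <- tissues_required %||% present
  unknown <- setdiff(tissues_required, present)
  if (length(unknown)) {
    stop("unknown tissue name(s): ", paste(unknown, collapse = ", "))
  }
  sex_of <- stats::setNames(samples$sex, samples$sample_id)
  if (anyNA(sex_of[unique(expr$sample)])) {
    stop("every expression sample must appear in the sample table")
  }
  keep <- expr$tissue %in% tissues_required
  e <- expr[keep, , drop = FALSE]
  is_focal <- sex_of[e$sample] == focal_sex
  ok_focal <- tapply(e$count[is_focal] >= min_count,
                     e$transcript[is_focal], all)
  ok_other <- tapply(e$count[!is_focal] <= max_leak,
                     e$transcript[!is_focal], all)
  ids <- intersect(names(ok_focal)[ok_focal], names(ok_other)[ok_other])
  ids[order(match(ids, unique(expr$transcript)))]
}

#' Test population concordance of a presence/absence marker
#'
#' A candidate fully sex-linked presence/absence marker (e.g. a PCR
#' product amplifying only from the sex-limited chromosome) is concordant
#' in a population sample when presence coincides exactly with the focal
#' sex in every individual.
#'
#' @param presence Logical vector, one entry per individual.
#' @param sexes Character vector (`"F"`/`"M"`), same length; no missing
#'   values allowed.
#' @param focal_sex The sex expected to carry the marker.
#' @return List: `concordant` (logical), `n_focal_with`, `n_other_with`.
#' @export
population_concordance <- function(presence, sexes, focal_sex = "F") {
  if (length(presence) != length(sexes)) {
    stop("presence and sexes must have equal length")
  }
  if (anyNA(sexes)) stop("every individual must have a sex")
  if (anyNA(presence)) stop("every individual must have a presence call")
  focal <- sexes == focal_sex
  list(concordant = all(presence == focal),
       n_focal_with = sum(presence & focal),
       n_other_with = sum(presence & !focal))
}
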