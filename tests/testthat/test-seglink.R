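test_that("low-depth masking follows the depth-below-threshold rule", {
  sim <- simulate_family(family_design("ZW", 3, 3, 2, numeric(0), 2, 0, 0,
                                       seed = 1))
  tab <- sim$table
  expect_identical(mask_low_depth(tab, 0), tab)   # identity at threshold 0
  tab$depth[1, 1] <- 1L
  masked <- mask_low_depth(tab, 2)
  expect_true(is.na(masked$calls[1, 1]))
  expect_identical(masked$calls[-1, ], tab$calls[-1, ])
  tab$depth[] <- 0L
  all_masked <- mask_low_depth(tab, 2)
  expect_true(all(is.na(all_masked$calls)))
  expect_equal(nrow(all_masked$calls), nrow(tab$calls))
  expect_error(mask_low_depth(tab, -1), "count")
})

test_that("defining complete-linkage patterns classify correctly", {
  # W-linked: maternal allele in every daughter, absent from all males
  w <- tiny_family("AB", "A", rep("AB", 6), rep("A", 6))
  cw <- classify_site(w, "s1", "ZW")
  expect_equal(cw$class, "W_LINKED")
  expect_equal(cw$n_inconsistent, 0)

  # Z-linked: father heterozygous, daughters hemizygous, sons carry the
  # maternal allele.  A {B}-only daughter is impossible for an autosomal
  # A/A x A/B cross (enumeration oracle below), so hemizygous paternal
  # transmission is the only consistent model.
  auto_testcross_offspring <- unique(vapply(
    expand.grid(m = "A", p = c("A", "B"))$p,
    function(p) paste(sort(unique(c("A", p))), collapse = ""), ""))
  expect_false("B" %in% auto_testcross_offspring)
  z <- tiny_family("A", "AB", c("A", "A", "A", "B", "B", "B"),
                   c("AB", "AB", "AB", "A", "A", "A"))
  expect_equal(classify_site(z, "s1", "ZW")$class, "Z_LINKED")

  # both parents heterozygous, mixed offspring: uninformative
  u <- tiny_family("AB", "AB", c("AB", "A", "B"), c("AB", "B", "A"))
  expect_equal(classify_site(u, "s1", "ZW")$class, "AUTOSOMAL")

  # Z pattern broken by exactly one heterozygous daughter -> PAR screen
  par <- tiny_family("A", "AB", c("A", "B", "A", "B", "A", "AB"),
                     c("AB", "AB", "A", "A", "AB", "A"))
  cp <- classify_site(par, "s1", "ZW")
  expect_equal(cp$class, "PAR_CANDIDATE")
  expect_equal(cp$n_inconsistent, 1)
})

test_that("count bookkeeping always sums to the offspring count", {
  fams <- list(
    tiny_family("AB", "A", c("AB", NA, "A"), c("A", "B", NA)),
    tiny_family("A", "AB", c("A", "B", "AB"), c("A", "AB", "B")),
    tiny_family(NA, "AB", c("A", "B"), c("A", "B")),
    tiny_family("AB", "AB", c("A", "B"), c("AB", NA))
  )
  for (f in fams) {
    for (mode in c("ZW", "XY")) {
      cl <- classify_site(f, "s1", mode)
      expect_equal(cl$n_consistent + cl$n_inconsistent + cl$n_missing,
                   sum(f$samples$role == "offspring"))
    }
  }
  expect_error(classify_site(fams[[1]], "nope", "ZW"), "not present")
})

test_that("classification is invariant to offspring order and allele relabelling", {
  sim <- simulate_family(family_design("ZW", 6, 6, 8, c(0.2), 10, 0.01, 0.02,
                                       seed = 9))
  tab <- sim$table
  base <- classify_table(tab, "ZW")

  # permute offspring columns
  perm <- tab
  off_idx <- which(perm$samples$role == "offspring")
  shuffle <- sample(off_idx)
  new_order <- seq_len(nrow(perm$samples))
  new_order[off_idx] <- shuffle
  perm$samples <- perm$samples[new_order, ]
  perm$calls <- perm$calls[, new_order, drop = FALSE]
  perm$depth <- perm$depth[, new_order, drop = FALSE]
  expect_equal(classify_table(perm, "ZW")$class, base$class)

  # swap A <-> B everywhere
  swapped <- tab
  swapped$calls[] <- chartr("AB", "BA", tab$calls)
  swapped$calls[swapped$calls == "BA"] <- "AB"
  expect_equal(classify_table(swapped, "ZW")$class, base$class)
})

test_that("mirror symmetry: sex+role swap with mode swap exchanges W<->Y and Z<->X", {
  set.seed(42)
  calls_pool <- c("A", "B", "AB", NA)
  for (rep in 1:60) {
    nd <- sample(3:6, 1); ns <- sample(3:6, 1)
    f <- tiny_family(sample(calls_pool, 1, prob = c(.3, .3, .3, .1)),
                     sample(calls_pool, 1, prob = c(.3, .3, .3, .1)),
                     sample(calls_pool, nd, replace = TRUE),
                     sample(calls_pool, ns, replace = TRUE))
    zw <- classify_site(f, "s1", "ZW")
    xy_mirrored <- classify_site(mirror_family(f), "s1", "XY")
    expect_equal(xy_mirrored$class, unname(mirror_class(zw$class)))
    expect_equal(xy_mirrored$n_inconsistent, zw$n_inconsistent)
  }
})

test_that("complete sex-linkage is recovered exactly on clean simulated families", {
  for (system in c("ZW", "XY")) {
    sim <- simulate_family(
      family_design(system, 6, 6, 10, numeric(0), 20, 0, 0, seed = 21))
    cls <- classify_table(sim$table, system)
    complete <- c("W_LINKED", "Z_LINKED", "X_LINKED", "Y_LINKED")
    truth_linked <- sim$truth$class %in% complete
    called_linked <- cls$class %in% complete
    expect_equal(called_linked, truth_linked)          # sens = spec = 1
    expect_equal(cls$class[truth_linked], sim$truth$class[truth_linked])
    # mirrored mode: no complete calls at all
    other <- if (system == "ZW") "XY" else "ZW"
    expect_equal(sum(classify_table(sim$table, other)$class %in% complete), 0)
  }
  # empty table -> empty classification
  empty <- simulate_family(family_design("ZW", 6, 6, 0, numeric(0), 0, 0, 0,
                                         seed = 1))
  expect_equal(nrow(classify_table(empty$table, "ZW")), 0)
})

test_that("heterogamety verdicts follow the count and ratio thresholds", {
  sim <- simulate_family(family_design("ZW", 6, 6, 20, numeric(0), 10, 0, 0,
                                       seed = 2))
  h <- infer_heterogamety(sim$table)
  expect_equal(h$verdict, "ZW")
  expect_gte(h$n_zw_complete, 5)

  empty <- simulate_family(family_design("ZW", 6, 6, 0, numeric(0), 0, 0, 0,
                                         seed = 1))
  he <- infer_heterogamety(empty$table)
  expect_equal(he$verdict, "AMBIGUOUS")
  expect_equal(c(he$n_zw_complete, he$n_xy_complete), c(0L, 0L))

  # equal complete counts in both modes cannot clear the ratio rule
  f1 <- tiny_family("AB", "A", rep("AB", 3), rep("A", 3))   # W-linked
  f2 <- tiny_family("A", "AB", rep("A", 3), rep("AB", 3))   # Y-linked
  calls <- rbind(s1 = f1$calls[1, ], s2 = f2$calls[1, ])
  tab <- genotype_table(calls, samples = f1$samples)
  ht <- infer_heterogamety(tab, min_count = 1)
  expect_equal(ht$n_zw_complete, ht$n_xy_complete)
  expect_equal(ht$verdict, "AMBIGUOUS")
})

test_that("sex-specific transcript detection applies count, leak and tissue rules", {
  expr <- expand.grid(transcript = c("t1", "t2", "t3"),
                      sample = c("F1", "F2", "M1", "M2"),
                      tissue = c("leaf", "bud"), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("F1", "F2", "M1", "M2"),
                        sex = c("F", "F", "M", "M"))
  expr$count <- 50
  expr$count[expr$transcript == "t1" & expr$sample %in% c("M1", "M2")] <- 0
  # t2: female-specific in buds only
  expr$count[expr$transcript == "t2" & expr$sample %in% c("M1", "M2") &
               expr$tissue == "bud"] <- 0
  hits <- detect_sex_specific_transcripts(expr, samples, "F",
                                          c("leaf", "bud"))
  expect_equal(hits, "t1")
  # leak threshold contract
  expr$count[expr$transcript == "t1" & expr$sample == "M1" &
               expr$tissue == "bud"] <- 3
  expect_length(detect_sex_specific_transcripts(expr, samples, "F",
                                                max_leak = 0), 0)
  expect_equal(detect_sex_specific_transcripts(expr, samples, "F",
                                               max_leak = 5), "t1")
  expect_error(detect_sex_specific_transcripts(expr, samples, "F", "root"),
               "unknown tissue")
})

test_that("population concordance matches the presence<->sex rule and combinatorics", {
  # two natural population samples: 15F+12F carriers, 17M+18M non-carriers
  sexes <- c(rep("F", 15 + 12), rep("M", 17 + 18))
  presence <- sexes == "F"
  res <- population_concordance(presence, sexes, "F")
  expect_true(res$concordant)
  expect_equal(res$n_focal_with, 27)
  expect_equal(res$n_other_with, 0)
  presence[28] <- TRUE  # one male with a product
  expect_false(population_concordance(presence, sexes, "F")$concordant)
  expect_error(population_concordance(c(TRUE, TRUE), c("F", NA)), "sex")

  # brute force over n = 5 confirms the 2^(1-n) spurious-concordance rate
  sx <- c("F", "F", "F", "M", "M")
  n_conc <- 0
  for (bits in 0:31) {
    pres <- as.logical(bitwAnd(bits, 2^(0:4)))
    conc <- population_concordance(pres, sx, "F")$concordant ||
      population_concordance(pres, sx, "M")$concordant
    n_conc <- n_conc + conc
  }
  expect_equal(n_conc / 32, 2^(1 - 5))
})
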