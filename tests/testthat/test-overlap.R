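# Builds an abundance table with one stool/saliva pair per subject and a
# given per-pair detection pattern for one species.
pattern_cohort <- function(stool_hits, oral_hits,
                           species = "Streptococcus_salivarius") {
  n <- length(stool_hits)
  subj <- sprintf("P%02d", seq_len(n))
  meta <- tibble::tibble(
    sample_id = c(paste0(subj, "_st"), paste0(subj, "_or")),
    subject_id = rep(subj, 2),
    body_site = rep(c("stool", "saliva"), each = n),
    study_id = "s", visit = 1L
  )
  ab <- tibble::tibble(
    sample_id = meta$sample_id,
    species = "Baseline_sp",
    relative_abundance = 50
  )
  hits <- c(
    paste0(subj, "_st")[stool_hits == 1],
    paste0(subj, "_or")[oral_hits == 1]
  )
  if (length(hits)) {
    ab <- rbind(ab, tibble::tibble(
      sample_id = hits, species = species, relative_abundance = 2
    ))
  }
  abundance_table(ab, meta)
}

test_that("prevalence filter applies the max(count, ceiling(fraction*N)) rule", {
  make <- function(n_samples, n_detected) {
    ids <- sprintf("S%03d", seq_len(n_samples))
    meta <- tibble::tibble(
      sample_id = ids, subject_id = ids, body_site = "stool",
      study_id = "s", visit = 1L
    )
    ab <- rbind(
      tibble::tibble(
        sample_id = ids, species = "Common_sp", relative_abundance = 50
      ),
      tibble::tibble(
        sample_id = ids[seq_len(n_detected)], species = "Rare_sp",
        relative_abundance = 1
      )
    )
    abundance_table(ab, meta)
  }
  # N = 20: threshold = max(3, ceiling(2)) = 3
  t20 <- make(20, 3)
  expect_true("Rare_sp" %in% prevalence_filter(t20, t20$metadata$sample_id))
  t20b <- make(20, 2)
  expect_false("Rare_sp" %in% prevalence_filter(t20b, t20b$metadata$sample_id))
  # N = 100: threshold = ceiling(0.10 * 100) = 10 (not 11 from float noise)
  t9 <- make(100, 9)
  expect_false("Rare_sp" %in% prevalence_filter(t9, t9$metadata$sample_id))
  t10 <- make(100, 10)
  expect_true("Rare_sp" %in% prevalence_filter(t10, t10$metadata$sample_id))
  expect_error(
    prevalence_filter(t10, character(0)),
    class = "oralgut_argument_error"
  )
})

test_that("overlap frequency counts pairs detected in both members", {
  tab <- pattern_cohort(c(1, 1, 0), c(1, 1, 1))
  pairs <- build_sample_pairs(tab, "saliva")
  ov <- pairwise_overlap_frequency(
    tab, pairs, "Streptococcus_salivarius"
  )
  expect_equal(ov$n_overlapping_pairs, 2)
  expect_equal(ov$overlap_frequency, 2 / 3)

  expect_equal(
    pairwise_overlap_frequency(tab, pairs, "Never_seen_sp")$overlap_frequency,
    0
  )
  # present in all stool but no oral samples: both-presence required
  asym <- pattern_cohort(c(1, 1, 1), c(0, 0, 0))
  expect_equal(
    pairwise_overlap_frequency(
      asym, build_sample_pairs(asym, "saliva"), "Streptococcus_salivarius"
    )$overlap_frequency,
    0
  )
})

test_that("overlap frequency is symmetric under swapping niche roles", {
  set.seed(21)
  for (i in 1:10) {
    n <- 12
    tab <- pattern_cohort(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    pairs <- build_sample_pairs(tab, "saliva")
    swapped <- pairs
    swapped$stool_sample_id <- pairs$oral_sample_id
    swapped$oral_sample_id <- pairs$stool_sample_id
    expect_equal(
      pairwise_overlap_frequency(
        tab, pairs, "Streptococcus_salivarius"
      )$overlap_frequency,
      pairwise_overlap_frequency(
        tab, swapped, "Streptococcus_salivarius"
      )$overlap_frequency
    )
  }
})

test_that("overlapping-species selection is inclusive at the 10% boundary", {
  tab <- pattern_cohort(
    c(1, rep(0, 9)), c(1, rep(1, 9))
  ) # overlap in exactly 1 of 10 pairs
  pairs <- build_sample_pairs(tab, "saliva")
  cfg <- analysis_config(prevalence_min_count = 1L)
  found <- find_overlapping_species(tab, pairs, cfg)
  expect_true("Streptococcus_salivarius" %in% found$species)

  none <- pattern_cohort(rep(1, 10), rep(0, 10))
  found0 <- find_overlapping_species(
    none, build_sample_pairs(none, "saliva"), cfg
  )
  expect_false("Streptococcus_salivarius" %in% found0$species)
})

test_that("equal overlap frequencies are ordered lexicographically", {
  n <- 10
  subj <- sprintf("P%02d", 1:n)
  meta <- tibble::tibble(
    sample_id = c(paste0(subj, "_st"), paste0(subj, "_or")),
    subject_id = rep(subj, 2),
    body_site = rep(c("stool", "saliva"), each = n),
    study_id = "s", visit = 1L
  )
  ab <- dplyr::bind_rows(lapply(c("Zeta_sp", "Alpha_sp"), function(sp) {
    tibble::tibble(
      sample_id = meta$sample_id[c(1:5, n + (1:5))],
      species = sp, relative_abundance = 3
    )
  }))
  tab <- abundance_table(ab, meta)
  found <- find_overlapping_species(
    tab, build_sample_pairs(tab, "saliva"),
    analysis_config(prevalence_min_count = 1L)
  )
  expect_equal(found$species, c("Alpha_sp", "Zeta_sp"))
})

test_that("raising detection or prevalence thresholds never enlarges results", {
  set.seed(33)
  for (i in 1:5) {
    n <- 15
    subj <- sprintf("P%02d", 1:n)
    meta <- tibble::tibble(
      sample_id = c(paste0(subj, "_st"), paste0(subj, "_or")),
      subject_id = rep(subj, 2),
      body_site = rep(c("stool", "saliva"), each = n),
      study_id = "s", visit = 1L
    )
    ab <- dplyr::bind_rows(lapply(sprintf("Sp_%02d", 1:8), function(sp) {
      keep <- runif(2 * n) < 0.6
      tibble::tibble(
        sample_id = meta$sample_id[keep], species = sp,
        relative_abundance = round(runif(sum(keep), 0, 8), 2)
      )
    }))
    tab <- abundance_table(ab, meta)
    pairs <- build_sample_pairs(tab, "saliva")
    lo <- analysis_config(presence_threshold = 0)
    hi <- analysis_config(presence_threshold = 2)
    for (sp in sprintf("Sp_%02d", 1:8)) {
      expect_lte(
        pairwise_overlap_frequency(tab, pairs, sp, hi)$overlap_frequency,
        pairwise_overlap_frequency(tab, pairs, sp, lo)$overlap_frequency
      )
    }
    ids <- meta$sample_id
    strict <- analysis_config(
      prevalence_min_fraction = 0.4, prevalence_min_count = 5L
    )
    expect_true(all(
      prevalence_filter(tab, ids, strict) %in% prevalence_filter(tab, ids, lo)
    ))
  }
})

test_that("signed-rank p matches hand-enumerated exact values", {
  # n = 5, all differences positive, no ties: 2 of 32 sign assignments
  expect_equal(paired_wilcoxon(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)), 0.0625)
  # a single nonzero pair: both sign assignments are equally extreme
  expect_equal(paired_wilcoxon(c(5), c(1)), 1.0)
  expect_error(
    paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)),
    class = "oralgut_degenerate_error"
  )
  expect_error(
    paired_wilcoxon(c(1, 2), c(1)),
    class = "oralgut_argument_error"
  )
})

test_that("signed-rank test agrees with wilcox.test where both are exact", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    fecal <- runif(n, 0, 5) # continuous: no ties, wilcox.test stays exact
    oral <- runif(n, 0, 5)
    expect_equal(
      paired_wilcoxon(fecal, oral),
      suppressWarnings(
        stats::wilcox.test(fecal, oral, paired = TRUE, exact = TRUE)$p.value
      ),
      tolerance = 1e-12
    )
  }
})

test_that("large-sample signed-rank approximation matches the standard one", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(40:70, 1)
    fecal <- sample(0:10, n, replace = TRUE) / 2 # ties and zeros likely
    oral <- sample(0:10, n, replace = TRUE) / 2
    if (sum(fecal != oral) <= 25) next # stay in the approximation regime
    expect_equal(
      paired_wilcoxon(fecal, oral),
      suppressWarnings(
        stats::wilcox.test(
          fecal, oral,
          paired = TRUE, exact = FALSE, correct = TRUE
        )$p.value
      ),
      tolerance = 1e-10
    )
  }
})

test_that("BH adjustment reproduces the worked step-up example", {
  expect_equal(
    bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
    c(0.02, 0.04, 0.04, 0.008)
  )
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "oralgut_argument_error")
  expect_error(bh_adjust(c(0.1, -0.1)), class = "oralgut_argument_error")
})

test_that("BH output dominates input elementwise and preserves order", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # sorting by p must also sort q: the adjustment preserves the ordering
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("Bray-Curtis matches direct formula and vegan on examples", {
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(3, 0, 1), c(3, 0, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1)
  expect_error(
    bray_curtis(c(0, 0), c(0, 0)),
    class = "oralgut_degenerate_error"
  )
  expect_error(bray_curtis(c(1, 2), c(1)), class = "oralgut_argument_error")
  expect_error(bray_curtis(c(-1, 2), c(1, 1)), class = "oralgut_argument_error")

  skip_if_not_installed("vegan")
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(runif(10, 0, 5), 2)
    expect_equal(
      bray_curtis(m[1, ], m[2, ]),
      as.numeric(vegan::vegdist(m, method = "bray"))
    )
  }
})

test_that("the fast distance matrix equals pairwise Bray-Curtis", {
  set.seed(12)
  m <- matrix(runif(40, 0, 3), 8, 5)
  d <- oralgut:::bray_curtis_matrix(m)
  for (i in 1:8) {
    for (j in 1:8) {
      if (i == j) {
        expect_equal(d[i, j], 0)
      } else {
        expect_equal(d[i, j], bray_curtis(m[i, ], m[j, ]))
      }
    }
  }
})

test_that("box summaries place whiskers at 1.5 IQR fences", {
  s <- oralgut:::box_summary(c(1, 2, 3, 4, 100))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whisker_high, 4) # 100 is beyond the 4 + 1.5*2 = 7 fence
  expect_equal(s$whisker_low, 1)
})

test_that("niche comparison infers origin from significance and medians", {
  n <- 20
  subj <- sprintf("P%02d", 1:n)
  meta <- tibble::tibble(
    sample_id = c(paste0(subj, "_st"), paste0(subj, "_or")),
    subject_id = rep(subj, 2),
    body_site = rep(c("stool", "saliva"), each = n),
    study_id = "s", visit = 1L
  )
  set.seed(14)
  ab <- dplyr::bind_rows(
    # oral-origin pattern: trace in stool, abundant orally
    tibble::tibble(
      sample_id = paste0(subj, "_st"), species = "Oral_origin_sp",
      relative_abundance = round(runif(n, 0.001, 0.02), 4)
    ),
    tibble::tibble(
      sample_id = paste0(subj, "_or"), species = "Oral_origin_sp",
      relative_abundance = round(runif(n, 1, 5), 3)
    ),
    # fecal-origin pattern: ~20% in stool, trace orally
    tibble::tibble(
      sample_id = paste0(subj, "_st"), species = "Fecal_origin_sp",
      relative_abundance = round(runif(n, 15, 25), 3)
    ),
    tibble::tibble(
      sample_id = paste0(subj, "_or"), species = "Fecal_origin_sp",
      relative_abundance = round(runif(n, 0.001, 0.05), 4)
    ),
    # no consistent direction: test should not reach significance
    tibble::tibble(
      sample_id = meta$sample_id, species = "Ambiguous_sp",
      relative_abundance = c(
        round(runif(n, 1, 1.2), 3), round(runif(n, 1, 1.2), 3)
      )
    )
  )
  tab <- abundance_table(ab, meta)
  pairs <- build_sample_pairs(tab, "saliva")
  res <- compare_niche_abundances(
    tab, pairs, c("Oral_origin_sp", "Fecal_origin_sp", "Ambiguous_sp")
  )
  res <- res[match(
    c("Oral_origin_sp", "Fecal_origin_sp", "Ambiguous_sp"), res$species
  ), ]
  expect_equal(res$inferred_origin, c("oral", "fecal", "indeterminate"))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_equal(res$significant, res$q_value < 0.05)
})

test_that("species with all-zero differences is flagged, not significant", {
  tab <- pattern_cohort(c(1, 1, 1), c(1, 1, 1))
  pairs <- build_sample_pairs(tab, "saliva")
  # same abundance (2) in every sample: every paired difference is zero
  expect_warning(
    res <- compare_niche_abundances(
      tab, pairs, "Streptococcus_salivarius"
    ),
    "undefined"
  )
  expect_false(res$test_defined)
  expect_false(res$significant)
  expect_equal(res$inferred_origin, "indeterminate")
})
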