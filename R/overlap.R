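#' Analysis configuration for overlap statistics
#'
#' @param presence_threshold Detection floor in percent; a species is
#'   detected in a sample when its relative abundance is strictly greater
#'   than this (default 0 — the upstream taxonomic profiler already applies
#'   its own presence floor).
#' @param prevalence_min_fraction,prevalence_min_count A species passes the
#'   prevalence filter when detected in at least
#'   `max(prevalence_min_count, ceiling(prevalence_min_fraction * N))` of
#'   the N samples under assessment (defaults 0.10 and 3: "occurred at
#'   least 3 times in at least 10 percent of the samples").
#' @param overlap_min_fraction Minimum pairwise overlap frequency for a
#'   species to count as overlapping (default 0.10, inclusive boundary).
#' @param q_threshold Significance level on BH-adjusted q values
#'   (default 0.05, strict `<`).
#' @param wilcoxon_variant `"paired"` (signed-rank over within-subject
#'   pairs, the default — samples are explicitly paired by subject) or
#'   `"unpaired"` (Mann-Whitney rank-sum fallback).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(presence_threshold = 0,
                            prevalence_min_fraction = 0.10,
                            prevalence_min_count = 3L,
                            overlap_min_fraction = 0.10,
                            q_threshold = 0.05,
                            wilcoxon_variant = c("paired", "unpaired")) {
  cfg <- list(
    presence_threshold = as.numeric(presence_threshold),
    prevalence_min_fraction = as.numeric(prevalence_min_fraction),
    prevalence_min_count = as.integer(prevalence_min_count),
    overlap_min_fraction = as.numeric(overlap_min_fraction),
    q_threshold = as.numeric(q_threshold),
    wilcoxon_variant = match.arg(wilcoxon_variant)
  )
  fracs <- c(cfg$prevalence_min_fraction, cfg$overlap_min_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort_argument("fractions must lie in [0, 1]")
  }
  if (cfg$presence_threshold < 0 || cfg$prevalence_min_count < 0 ||
      cfg$q_threshold < 0) {
    abort_argument("thresholds must be nonnegative")
  }
  class(cfg) <- "analysis_config"
  cfg
}

abundance_matrix_for <- function(table, sample_ids, species = NULL) {
  ab <- table$abundance
  if (!is.null(species)) {
    ab <- dplyr::filter(ab, .data$species %in% !!species)
  }
  ab <- dplyr::filter(ab, .data$sample_id %in% sample_ids)
  ab
}

lookup_abundance <- function(table, sample_ids, species_name) {
  ab <- table$abundance[table$abundance$species == species_name, ]
  out <- ab$relative_abundance[match(sample_ids, ab$sample_id)]
  out[is.na(out)] <- 0
  out
}

#' Prevalence-filter species across a sample set
#'
#' Retains species detected (relative abundance strictly above
#' `presence_threshold`) in at least
#' `max(prevalence_min_count, ceiling(prevalence_min_fraction * N))` of the
#' `N` listed samples.
#'
#' @param table An [abundance_table()].
#' @param sample_ids Samples under assessment (must exist in `table`).
#' @param config An [analysis_config()].
#' @return Lexicographically sorted character vector of retained species.
#' @export
prevalence_filter <- function(table, sample_ids, config = analysis_config()) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(sample_ids) == 0L) {
    abort_argument("sample_ids must be non-empty")
  }
  missing <- setdiff(sample_ids, table$metadata$sample_id)
  if (length(missing)) {
    abort_argument(paste0(
      "unknown sample_id(s): ", paste(missing, collapse = ", ")
    ))
  }
  n <- length(unique(sample_ids))
  need <- max(
    config$prevalence_min_count,
    ceiling(config$prevalence_min_fraction * n - .eps)
  )
  detected <- table$abundance |>
    dplyr::filter(
      .data$sample_id %in% sample_ids,
      .data$relative_abundance > config$presence_threshold
    ) |>
    dplyr::distinct(.data$sample_id, .data$species) |>
    dplyr::count(.data$species)
  sort(detected$species[detected$n >= need])
}

#' Pairwise overlap frequency of one species
#'
#' A stool/oral pair counts as overlapping when the species is detected
#' (abundance strictly above `presence_threshold`) in both members. A
#' species absent from the table has frequency 0.
#'
#' @param table An [abundance_table()].
#' @param pairs A [build_sample_pairs()] result.
#' @param species_name Species to assess.
#' @param config An [analysis_config()].
#' @return One-row tibble: `species`, `n_pairs`, `n_overlapping_pairs`,
#'   `overlap_frequency`.
#' @export
pairwise_overlap_frequency <- function(table, pairs, species_name,
                                       config = analysis_config()) {
  if (nrow(pairs) == 0L) abort_argument("pairs must be non-empty")
  a_stool <- lookup_abundance(table, pairs$stool_sample_id, species_name)
  a_oral <- lookup_abundance(table, pairs$oral_sample_id, species_name)
  both <- a_stool > config$presence_threshold &
    a_oral > config$presence_threshold
  tibble::tibble(
    species = species_name,
    n_pairs = nrow(pairs),
    n_overlapping_pairs = sum(both),
    overlap_frequency = sum(both) / nrow(pairs)
  )
}

#' Species overlapping between stool and an oral site
#'
#' Applies the prevalence filter over the pooled samples of the pair set,
#' then keeps species whose pairwise overlap frequency is at least
#' `overlap_min_fraction` (inclusive).
#'
#' @inheritParams pairwise_overlap_frequency
#' @return Tibble with one row per overlapping species (`species`,
#'   `n_pairs`, `n_overlapping_pairs`, `overlap_frequency`), sorted by
#'   descending frequency, ties broken lexicographically.
#' @export
find_overlapping_species <- function(table, pairs,
                                     config = analysis_config()) {
  if (nrow(pairs) == 0L) abort_argument("pairs must be non-empty")
  pooled <- unique(c(pairs$stool_sample_id, pairs$oral_sample_id))
  candidates <- prevalence_filter(table, pooled, config)
  freq <- purrr::map_dfr(
    candidates,
    function(sp) pairwise_overlap_frequency(table, pairs, sp, config)
  )
  if (nrow(freq) == 0L) {
    return(tibble::tibble(
      species = character(0), n_pairs = integer(0),
      n_overlapping_pairs = integer(0), overlap_frequency = numeric(0)
    ))
  }
  freq |>
    dplyr::filter(
      .data$overlap_frequency >= config$overlap_min_fraction - .eps
    ) |>
    dplyr::arrange(dplyr::desc(.data$overlap_frequency), .data$species)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction converting p values to q values,
#' clipped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted q values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_argument("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Tukey box summary: quartiles plus whiskers at the most extreme
# observations within 1.5 * IQR of the box.
box_summary <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
    whisker_high = max(x[x <= q[3] + 1.5 * iqr])
  )
}

#' Compare fecal versus oral abundances of overlapping species
#'
#' For each species, tests the within-subject fecal and oral abundances
#' over all pairs (paired Wilcoxon signed-rank by default), adjusts the p
#' values with Benjamini-Hochberg across the supplied species family (one
#' family per oral-site dataset), and infers the likely niche of origin:
#' `oral` when significantly more abundant orally, `fecal` when
#' significantly more abundant in stool, otherwise `indeterminate`. A
#' species with all paired differences zero cannot be tested; it is flagged
#' (`test_defined = FALSE`) and reported as non-significant.
#'
#' @inheritParams pairwise_overlap_frequency
#' @param species_list Species family to test, typically
#'   `find_overlapping_species(...)$species`.
#' @return Tibble with one row per species: overlap counts, box summaries
#'   (`fecal_*`, `oral_*`, percent), `p_value`, `q_value`, `significant`,
#'   `inferred_origin`, `test_defined`.
#' @export
compare_niche_abundances <- function(table, pairs, species_list,
                                     config = analysis_config()) {
  if (nrow(pairs) == 0L) abort_argument("pairs must be non-empty")
  if (length(species_list) == 0L) {
    return(tibble::tibble(
      species = character(0), oral_site = character(0)
    ))
  }
  rows <- purrr::map_dfr(species_list, function(sp) {
    fecal <- lookup_abundance(table, pairs$stool_sample_id, sp)
    oral <- lookup_abundance(table, pairs$oral_sample_id, sp)
    ov <- pairwise_overlap_frequency(table, pairs, sp, config)
    p <- tryCatch(
      if (config$wilcoxon_variant == "paired") {
        paired_wilcoxon(fecal, oral)
      } else {
        stats::wilcox.test(fecal, oral, exact = FALSE)$p.value
      },
      oralgut_degenerate_error = function(e) NA_real_
    )
    fs <- box_summary(fecal)
    os <- box_summary(oral)
    tibble::tibble(
      species = sp,
      oral_site = pairs$oral_site[1],
      n_pairs = ov$n_pairs,
      n_overlapping_pairs = ov$n_overlapping_pairs,
      overlap_frequency = ov$overlap_frequency,
      fecal_median = fs$median, fecal_q1 = fs$q1, fecal_q3 = fs$q3,
      fecal_whisker_low = fs$whisker_low,
      fecal_whisker_high = fs$whisker_high,
      oral_median = os$median, oral_q1 = os$q1, oral_q3 = os$q3,
      oral_whisker_low = os$whisker_low,
      oral_whisker_high = os$whisker_high,
      p_value = p,
      test_defined = !is.na(p)
    )
  })
  if (any(!rows$test_defined)) {
    warn(paste0(
      "signed-rank test undefined (all differences zero) for: ",
      paste(rows$species[!rows$test_defined], collapse = ", "),
      "; reported as non-significant"
    ))
  }
  rows$q_value <- NA_real_
  ok <- rows$test_defined
  rows$q_value[ok] <- bh_adjust(rows$p_value[ok])
  rows |>
    dplyr::mutate(
      significant = !is.na(.data$q_value) &
        .data$q_value < config$q_threshold,
      inferred_origin = dplyr::case_when(
        .data$significant & .data$oral_median > .data$fecal_median ~ "oral",
        .data$significant & .data$fecal_median > .data$oral_median ~ "fecal",
        TRUE ~ "indeterminate"
      )
    )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|a - b|) / sum(a + b)`: 0 for identical composition, 1 for disjoint
#' supports.
#'
#' @param a,b Equal-length nonnegative numeric vectors, not both all zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) {
    abort_argument("vectors must have equal length")
  }
  if (anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    abort_argument("vectors must be nonnegative with no NA")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    abort_degenerate("Bray-Curtis undefined for two all-zero vectors")
  }
  sum(abs(a - b)) / denom
}

# Full pairwise Bray-Curtis matrix via the manhattan-distance identity
# BC(a, b) = manhattan(a, b) / (sum(a) + sum(b)); rows of `m` are samples.
bray_curtis_matrix <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort_degenerate("Bray-Curtis undefined for all-zero samples")
  }
  manhattan <- as.matrix(stats::dist(m, method = "manhattan"))
  manhattan / outer(rs, rs, "+")
}

#' Abundance matrix over a sample set
#'
#' Wide samples-by-species matrix of relative abundances (absent entries are
#' exact zeros), in deterministic sorted order.
#'
#' @param table An [abundance_table()].
#' @param sample_ids Samples to include as rows.
#' @return Numeric matrix, samples x species.
#' @export
abundance_wide_matrix <- function(table, sample_ids) {
  ab <- abundance_matrix_for(table, sample_ids)
  if (nrow(ab) == 0L) abort_argument("no abundance entries for these samples")
  wide <- ab |>
    dplyr::arrange(.data$sample_id, .data$species) |>
    tidyr::pivot_wider(
      names_from = "species", values_from = "relative_abundance",
      values_fill = 0
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, sort(colnames(m)), drop = FALSE]
}

#' Log-transformed abundance matrix for heatmaps and ordination
#'
#' Returns `log10(x + pseudocount)` with the pseudocount set to the smallest
#' nonzero abundance in the table (so zeros map below every observed value),
#' over the requested samples.
#'
#' @inheritParams abundance_wide_matrix
#' @return Numeric matrix, samples x species.
#' @export
log_abundance_matrix <- function(table, sample_ids) {
  m <- abundance_wide_matrix(table, sample_ids)
  pseudo <- min(table$abundance$relative_abundance[
    table$abundance$relative_abundance > 0
  ])
  log10(m + pseudo)
}
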