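#' Binary marker presence/absence pattern of one sample for one species
#'
#' A marker counts as present when its value is strictly greater than
#' `marker_presence_threshold` (default 0; the upstream profiler has already
#' applied its own reads-per-kilobase presence floor). Markers of the
#' species with no entry for the sample are absent. Coverage is the
#' fraction of the species' full marker set that is present — low coverage
#' indicates insufficient sequencing depth rather than gene loss.
#'
#' @param markers A [marker_table()].
#' @param sample_id Sample to extract.
#' @param species_name Species whose marker set to use (must have mapped
#'   markers).
#' @param marker_presence_threshold Detection floor on marker values.
#' @return Object of class `marker_pattern`: list with `sample_id`,
#'   `species_name`, `presence` (named 0/1 vector over the species' markers
#'   in sorted marker_id order) and `coverage`.
#' @export
binarize_pattern <- function(markers, sample_id, species_name,
                             marker_presence_threshold = 0) {
  stopifnot(inherits(markers, "marker_table"))
  ids <- sort(markers$marker_map$marker_id[
    markers$marker_map$species == species_name
  ])
  if (length(ids) == 0L) {
    abort_argument(paste0(
      "species has no mapped markers: ", species_name
    ))
  }
  vals <- markers$values[markers$values$sample_id == sample_id, ]
  v <- vals$value[match(ids, vals$marker_id)]
  present <- as.integer(!is.na(v) & v > marker_presence_threshold)
  names(present) <- ids
  structure(
    list(
      sample_id = sample_id,
      species_name = species_name,
      presence = present,
      coverage = sum(present) / length(present)
    ),
    class = "marker_pattern"
  )
}

#' Marker patterns passing the coverage filter
#'
#' Binarizes the requested samples and retains those with at least
#' `coverage_min` of the species' markers present (inclusive boundary, so
#' exactly 90 percent passes the default filter). The filter excludes
#' samples whose missing markers likely reflect low sequencing depth rather
#' than true gene loss.
#'
#' @inheritParams binarize_pattern
#' @param sample_ids Samples to consider.
#' @param coverage_min Minimum coverage fraction in \[0, 1\] (default 0.9).
#' @return List of `marker_pattern` objects in `sort(sample_ids)` order.
#' @export
eligible_samples <- function(markers, sample_ids, species_name,
                             coverage_min = 0.9,
                             marker_presence_threshold = 0) {
  if (coverage_min < 0 || coverage_min > 1) {
    abort_argument("coverage_min must lie in [0, 1]")
  }
  pats <- lapply(
    sort(unique(sample_ids)),
    function(s) {
      binarize_pattern(markers, s, species_name, marker_presence_threshold)
    }
  )
  keep <- vapply(
    pats, function(p) p$coverage >= coverage_min - .eps, logical(1)
  )
  pats[keep]
}

#' Do two samples carry the same marker presence/absence pattern?
#'
#' Strict identity of the binary vectors over the species' full marker set.
#' Identity is necessary but not sufficient evidence of the same strain
#' (single-nucleotide differences within markers are invisible), so a match
#' is reported as "consistent with" same-strain colonization.
#'
#' @param stool,oral `marker_pattern` objects for the same species.
#' @return TRUE iff the patterns are identical at every marker.
#' @export
pattern_match <- function(stool, oral) {
  stopifnot(inherits(stool, "marker_pattern"), inherits(oral, "marker_pattern"))
  if (stool$species_name != oral$species_name) {
    abort_argument("patterns belong to different species")
  }
  if (length(stool$presence) != length(oral$presence)) {
    abort_argument("patterns have different marker-set lengths")
  }
  all(stool$presence == oral$presence)
}

#' Call individuals consistent with same-strain stool/oral colonization
#'
#' For each (subject, species) having at least one coverage-eligible stool
#' pattern and at least one coverage-eligible oral pattern, the subject is
#' consistent for that species iff some stool pattern is identical to some
#' oral pattern; `matched_oral_sites` lists every oral site with a matching
#' sample. Subjects lacking an eligible stool or oral pattern for a species
#' are omitted from the calls for that species.
#'
#' @param markers A [marker_table()].
#' @param metadata Sample metadata tibble (as in an
#'   [abundance_table()]`$metadata`).
#' @param species_list Species to assess; defaults to
#'   [default_species_list()].
#' @param coverage_min Minimum marker coverage (default 0.9).
#' @param marker_presence_threshold Detection floor on marker values.
#' @return Tibble with one row per assessed (subject, species):
#'   `subject_id`, `species`, `stool_sample_id` (first eligible, for
#'   reference), `matched_oral_sites` (list-column), `is_consistent`.
#' @export
call_shared_strains <- function(markers, metadata,
                                species_list = default_species_list(),
                                coverage_min = 0.9,
                                marker_presence_threshold = 0) {
  stopifnot(inherits(markers, "marker_table"))
  metadata <- tibble::as_tibble(metadata)
  species_list <- intersect(
    species_list, unique(markers$marker_map$species)
  )
  out <- list()
  for (sp in sort(species_list)) {
    # only samples with >= 1 detected marker of the species can be eligible
    sp_markers <- markers$marker_map$marker_id[
      markers$marker_map$species == sp
    ]
    carriers <- unique(markers$values$sample_id[
      markers$values$marker_id %in% sp_markers
    ])
    pats <- eligible_samples(
      markers, intersect(carriers, metadata$sample_id), sp,
      coverage_min, marker_presence_threshold
    )
    if (!length(pats)) next
    pat_ids <- vapply(pats, `[[`, character(1), "sample_id")
    info <- metadata[match(pat_ids, metadata$sample_id), ]
    for (subj in sort(unique(info$subject_id))) {
      stool_idx <- which(info$subject_id == subj & info$body_site == "stool")
      oral_idx <- which(info$subject_id == subj & info$body_site != "stool")
      if (!length(stool_idx) || !length(oral_idx)) next
      matched <- character(0)
      for (oi in oral_idx) {
        hit <- any(vapply(
          stool_idx,
          function(si) pattern_match(pats[[si]], pats[[oi]]),
          logical(1)
        ))
        if (hit) matched <- c(matched, info$body_site[oi])
      }
      matched <- sort(unique(matched))
      out[[length(out) + 1L]] <- tibble::tibble(
        subject_id = subj,
        species = sp,
        stool_sample_id = info$sample_id[stool_idx[1]],
        matched_oral_sites = list(matched),
        is_consistent = length(matched) > 0L
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      subject_id = character(0), species = character(0),
      stool_sample_id = character(0), matched_oral_sites = list(),
      is_consistent = logical(0)
    ))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$species, .data$subject_id)
}

#' Number of distinct individuals with a same-strain-consistent pattern
#'
#' A subject matching for several species or several oral sites still
#' counts once.
#'
#' @param calls Output of [call_shared_strains()].
#' @return Integer count of distinct consistent subjects.
#' @export
count_consistent_individuals <- function(calls) {
  length(unique(calls$subject_id[calls$is_consistent]))
}

#' Consistent (subject, species, oral_site) triples from strain calls
#'
#' Expands `matched_oral_sites` so the caller's output can be compared
#' directly with a synthetic cohort's planted ground truth.
#'
#' @param calls Output of [call_shared_strains()].
#' @return Tibble with columns `subject_id`, `species`, `oral_site`.
#' @export
consistent_triples <- function(calls) {
  calls <- calls[calls$is_consistent, , drop = FALSE]
  if (!nrow(calls)) {
    return(tibble::tibble(
      subject_id = character(0), species = character(0),
      oral_site = character(0)
    ))
  }
  calls |>
    dplyr::select("subject_id", "species", "matched_oral_sites") |>
    tidyr::unnest_longer("matched_oral_sites") |>
    dplyr::rename(oral_site = "matched_oral_sites") |>
    dplyr::arrange(.data$subject_id, .data$species, .data$oral_site)
}
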