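#' Controlled vocabulary of body sites
#'
#' The analysis pairs one stool sample with a sample from one of four oral
#' sites collected from the same subject.
#'
#' @return `oral_sites()` returns the four oral site labels;
#'   `body_sites()` additionally includes `"stool"`.
#' @export
oral_sites <- function() {
  c("saliva", "buccal_mucosa", "supragingival_plaque", "tongue_dorsum")
}

#' @rdname oral_sites
#' @export
body_sites <- function() {
  c("stool", oral_sites())
}

#' Default species for clade-specific marker-gene comparison
#'
#' The five members of the normal oral flora that most frequently overlap
#' between stool and oral samples, and for which strain consistency is
#' assessed by marker-gene presence/absence matching.
#'
#' @return Character vector of five species names.
#' @export
default_species_list <- function() {
  c(
    "Streptococcus_parasanguinis",
    "Haemophilus_parainfluenzae",
    "Streptococcus_salivarius",
    "Streptococcus_mitis",
    "Veillonella_parvula"
  )
}

#' Construct a validated abundance table
#'
#' An abundance table bundles long-format species relative abundances
#' (percent of the classified fraction, so per-sample totals are at most 100)
#' with per-sample metadata. Absent (sample, species) combinations are exact
#' zeros, matching taxonomic-profiler output semantics.
#'
#' @param abundance Data frame with columns `sample_id`, `species`,
#'   `relative_abundance` (percent, in \[0, 100\]).
#' @param metadata Data frame with columns `sample_id`, `subject_id`,
#'   `body_site` (one of [body_sites()]), `study_id`, `visit` (integer >= 1).
#' @return An object of class `abundance_table`: a list with tibbles
#'   `$abundance` and `$metadata`.
#' @export
abundance_table <- function(abundance, metadata) {
  abundance <- tibble::as_tibble(abundance)
  metadata <- tibble::as_tibble(metadata)

  need_meta <- c("sample_id", "subject_id", "body_site", "study_id", "visit")
  if (!all(need_meta %in% names(metadata))) {
    abort_validation(paste0(
      "metadata is missing column(s): ",
      paste(setdiff(need_meta, names(metadata)), collapse = ", ")
    ))
  }
  need_ab <- c("sample_id", "species", "relative_abundance")
  if (!all(need_ab %in% names(abundance))) {
    abort_validation(paste0(
      "abundance is missing column(s): ",
      paste(setdiff(need_ab, names(abundance)), collapse = ", ")
    ))
  }

  metadata <- dplyr::mutate(
    metadata,
    sample_id = as.character(.data$sample_id),
    subject_id = as.character(.data$subject_id),
    body_site = as.character(.data$body_site),
    study_id = as.character(.data$study_id),
    visit = as.integer(.data$visit)
  )
  abundance <- dplyr::mutate(
    abundance,
    sample_id = as.character(.data$sample_id),
    species = as.character(.data$species),
    relative_abundance = as.numeric(.data$relative_abundance)
  )

  if (anyDuplicated(metadata$sample_id)) {
    dups <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    abort_validation(paste0(
      "duplicate sample_id in metadata: ", paste(dups, collapse = ", ")
    ))
  }
  bad_site <- setdiff(unique(metadata$body_site), body_sites())
  if (length(bad_site)) {
    abort_validation(paste0(
      "unknown body_site value(s): ", paste(bad_site, collapse = ", "),
      " (allowed: ", paste(body_sites(), collapse = ", "), ")"
    ))
  }
  if (anyNA(metadata$subject_id) || any(metadata$subject_id == "")) {
    abort_validation("every sample must have a subject_id")
  }
  if (anyNA(metadata$visit) || any(metadata$visit < 1L)) {
    abort_validation("visit must be an integer >= 1 for every sample")
  }

  if (anyNA(abundance$relative_abundance)) {
    abort_validation("relative_abundance contains missing/non-numeric values")
  }
  out_of_range <- abundance$relative_abundance < 0 |
    abundance$relative_abundance > 100
  if (any(out_of_range)) {
    abort_validation(paste0(
      "relative_abundance outside [0, 100] for ",
      sum(out_of_range), " row(s), e.g. ",
      abundance$sample_id[which(out_of_range)[1]], " / ",
      abundance$species[which(out_of_range)[1]]
    ))
  }
  key <- paste(abundance$sample_id, abundance$species, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- abundance[duplicated(key), c("sample_id", "species")]
    dups <- unique(paste0("(", dups$sample_id, ", ", dups$species, ")"))
    abort_validation(paste0(
      "duplicate (sample_id, species) row(s): ", paste(dups, collapse = ", ")
    ))
  }
  orphan <- setdiff(unique(abundance$sample_id), metadata$sample_id)
  if (length(orphan)) {
    abort_validation(paste0(
      "abundance rows reference sample_id(s) absent from metadata: ",
      paste(orphan, collapse = ", ")
    ))
  }
  sums <- tapply(abundance$relative_abundance, abundance$sample_id, sum)
  if (any(sums > 100 + 1e-6)) {
    bad <- names(sums)[sums > 100 + 1e-6][1]
    abort_validation(paste0(
      "per-sample abundance sum exceeds 100 (+1e-6 tolerance) for sample ",
      bad, " (sum = ", format(sums[[bad]]), ")"
    ))
  }

  structure(
    list(abundance = abundance, metadata = metadata),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(
    "<abundance_table> ", nrow(x$metadata), " samples, ",
    length(unique(x$abundance$species)), " species, ",
    nrow(x$abundance), " non-zero entries\n",
    sep = ""
  )
  tab <- table(x$metadata$body_site)
  cat("  body sites:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a validated marker table
#'
#' Per-sample detection values for clade-specific marker genes, together with
#' the map assigning each marker to exactly one species. Markers with no
#' entry for a sample are undetected.
#'
#' @param values Data frame with columns `sample_id`, `marker_id`, `value`
#'   (nonnegative).
#' @param marker_map Data frame with columns `marker_id`, `species`; each
#'   marker maps to exactly one species.
#' @return An object of class `marker_table`: list with tibbles `$values`
#'   and `$marker_map`.
#' @export
marker_table <- function(values, marker_map) {
  values <- tibble::as_tibble(values)
  marker_map <- tibble::as_tibble(marker_map)

  if (!all(c("sample_id", "marker_id", "value") %in% names(values))) {
    abort_validation("values must have columns sample_id, marker_id, value")
  }
  if (!all(c("marker_id", "species") %in% names(marker_map))) {
    abort_validation("marker_map must have columns marker_id, species")
  }
  values <- dplyr::mutate(
    values,
    sample_id = as.character(.data$sample_id),
    marker_id = as.character(.data$marker_id),
    value = as.numeric(.data$value)
  )
  marker_map <- dplyr::mutate(
    marker_map,
    marker_id = as.character(.data$marker_id),
    species = as.character(.data$species)
  )

  if (anyDuplicated(marker_map$marker_id)) {
    dups <- unique(marker_map$marker_id[duplicated(marker_map$marker_id)])
    abort_validation(paste0(
      "marker_map assigns marker(s) to more than one species: ",
      paste(dups, collapse = ", ")
    ))
  }
  if (anyNA(values$value) || any(values$value < 0)) {
    abort_validation("marker values must be nonnegative numbers")
  }
  unmapped <- setdiff(unique(values$marker_id), marker_map$marker_id)
  if (length(unmapped)) {
    abort_validation(paste0(
      "marker(s) with no species mapping: ", paste(unmapped, collapse = ", ")
    ))
  }
  key <- paste(values$sample_id, values$marker_id, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- values[duplicated(key), c("sample_id", "marker_id")]
    dups <- unique(paste0("(", dups$sample_id, ", ", dups$marker_id, ")"))
    abort_validation(paste0(
      "duplicate (sample_id, marker_id) row(s): ", paste(dups, collapse = ", ")
    ))
  }
  if (nrow(values) == 0L) {
    warn("marker table has zero entries")
  }

  structure(
    list(values = values, marker_map = marker_map),
    class = "marker_table"
  )
}

#' @export
print.marker_table <- function(x, ...) {
  cat(
    "<marker_table> ", nrow(x$values), " entries, ",
    nrow(x$marker_map), " markers across ",
    length(unique(x$marker_map$species)), " species\n",
    sep = ""
  )
  invisible(x)
}

read_tsv_checked <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort_io(paste0(what, " file not found: ", path))
  }
  # parsing issues are escalated to errors below, so silence readr's warning
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort_parse(paste0(
      "malformed ", what, " file ", path, ": ",
      nrow(probs), " problem(s), first at line ", probs$row[1],
      " (expected ", probs$expected[1], ")"
    ))
  }
  missing_cols <- setdiff(names(attr(col_types, "cols")), names(x))
  if (length(missing_cols)) {
    abort_parse(paste0(
      what, " file ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x
}

#' Read an abundance table from interchange TSV files
#'
#' @param abundance_path TSV with columns `sample_id`, `species`,
#'   `relative_abundance`.
#' @param metadata_path TSV with columns `sample_id`, `subject_id`,
#'   `body_site`, `study_id`, `visit`.
#' @return A validated [abundance_table()].
#' @export
load_abundance_table <- function(abundance_path, metadata_path) {
  ab <- read_tsv_checked(
    abundance_path,
    readr::cols(
      sample_id = readr::col_character(),
      species = readr::col_character(),
      relative_abundance = readr::col_double()
    ),
    "abundance"
  )
  meta <- read_tsv_checked(
    metadata_path,
    readr::cols(
      sample_id = readr::col_character(),
      subject_id = readr::col_character(),
      body_site = readr::col_character(),
      study_id = readr::col_character(),
      visit = readr::col_integer()
    ),
    "metadata"
  )
  abundance_table(ab, meta)
}

#' Write an abundance table to interchange TSV files
#'
#' Rows are written in sorted order so that output is byte-identical across
#' runs on the same data.
#'
#' @param table An [abundance_table()].
#' @inheritParams load_abundance_table
#' @return `table`, invisibly.
#' @export
write_abundance_table <- function(table, abundance_path, metadata_path) {
  stopifnot(inherits(table, "abundance_table"))
  ab <- dplyr::arrange(table$abundance, .data$sample_id, .data$species)
  meta <- dplyr::arrange(table$metadata, .data$sample_id)
  readr::write_tsv(ab, abundance_path, progress = FALSE)
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  invisible(table)
}

#' Read a marker table from interchange TSV files
#'
#' @param marker_path TSV with columns `sample_id`, `marker_id`, `value`.
#' @param marker_map_path TSV with columns `marker_id`, `species`.
#' @return A validated [marker_table()].
#' @export
load_marker_table <- function(marker_path, marker_map_path) {
  vals <- read_tsv_checked(
    marker_path,
    readr::cols(
      sample_id = readr::col_character(),
      marker_id = readr::col_character(),
      value = readr::col_double()
    ),
    "marker"
  )
  map <- read_tsv_checked(
    marker_map_path,
    readr::cols(
      marker_id = readr::col_character(),
      species = readr::col_character()
    ),
    "marker map"
  )
  marker_table(vals, map)
}

#' Write a marker table to interchange TSV files
#'
#' @param markers A [marker_table()].
#' @inheritParams load_marker_table
#' @return `markers`, invisibly.
#' @export
write_marker_table <- function(markers, marker_path, marker_map_path) {
  stopifnot(inherits(markers, "marker_table"))
  vals <- dplyr::arrange(markers$values, .data$sample_id, .data$marker_id)
  map <- dplyr::arrange(markers$marker_map, .data$marker_id)
  readr::write_tsv(vals, marker_path, progress = FALSE)
  readr::write_tsv(map, marker_map_path, progress = FALSE)
  invisible(markers)
}

#' Build within-subject stool/oral sample pairs
#'
#' For every (subject, visit) having both a stool sample and a sample from
#' `oral_site`, emits exactly one pair. When a subject has several candidate
#' samples of one type at the same visit, the lexicographically smallest
#' sample_id is chosen, so pairing is deterministic and invariant to input
#' row order. Subjects lacking either member contribute nothing.
#'
#' @param table An [abundance_table()].
#' @param oral_site One of [oral_sites()].
#' @return A tibble of class `sample_pair_set` with columns `subject_id`,
#'   `visit`, `stool_sample_id`, `oral_sample_id`, `oral_site`, sorted by
#'   subject then visit.
#' @export
build_sample_pairs <- function(table, oral_site) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(oral_site) != 1L || !oral_site %in% oral_sites()) {
    abort_argument(paste0(
      "oral_site must be one of: ", paste(oral_sites(), collapse = ", ")
    ))
  }
  meta <- table$metadata
  pick_one <- function(site) {
    meta |>
      dplyr::filter(.data$body_site == site) |>
      dplyr::group_by(.data$subject_id, .data$visit) |>
      dplyr::summarise(sample_id = min(.data$sample_id), .groups = "drop")
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(pick_one("stool"), stool_sample_id = "sample_id"),
    dplyr::rename(pick_one(oral_site), oral_sample_id = "sample_id"),
    by = c("subject_id", "visit")
  ) |>
    dplyr::mutate(oral_site = oral_site) |>
    dplyr::arrange(.data$subject_id, .data$visit)
  class(pairs) <- c("sample_pair_set", class(pairs))
  pairs
}
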