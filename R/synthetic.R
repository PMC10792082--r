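#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the statistical structure of a simulated cohort: each subject
#' contributes one stool sample plus one sample per configured oral site.
#' Species belong to three niche pools. Oral-adapted species occur in oral
#' samples with probability `occupancy_oral_in_oral` and spill into stool
#' with probability `occupancy_oral_in_gut`; gut-adapted species occur in
#' stool with probability `occupancy_gut_in_gut` and never orally;
#' generalist species use the in-niche occupancies on both sides. The
#' shared (plantable) species sit at the head of the generalist pool, since
#' the strain-sharing question concerns oral-origin bacteria that frequently
#' reach the gut. Present species get log-normal magnitudes renormalized to
#' 100 percent per sample; non-gut-adapted species found in stool draw their
#' magnitudes with the log-mean shifted down by a fixed spillover penalty,
#' so oral-origin overlappers are frequent in stool but only at trace
#' relative abundance, far below their oral abundance.
#'
#' Strains of a species are marker-gene repertoires: binary vectors obtained
#' from the all-present reference by independent gene loss. Exactly
#' `n_shared_subjects` subjects are planted with an identical stool/oral
#' repertoire for one randomly chosen shared species and oral site; every
#' other within-subject sample carries its own distinct repertoire. Marker
#' detection fails independently per present marker with
#' `marker_dropout_prob` (depth-driven missingness; never false detection).
#'
#' @param n_subjects Number of subjects (125 by default, giving 500
#'   stool/oral pairs across the four sites — the scale of the multi-cohort
#'   datasets this generator emulates).
#' @param oral_sites Subset of [oral_sites()] sampled per subject.
#' @param n_oral_species,n_gut_species,n_generalist_species Niche pool sizes.
#' @param lognormal_mu,lognormal_sigma Log-scale abundance parameters.
#' @param occupancy_oral_in_oral,occupancy_gut_in_gut,occupancy_oral_in_gut
#'   Per-species presence probabilities by niche.
#' @param n_markers_per_species Markers per shared species (>= 10).
#' @param gene_loss_prob Per-marker loss probability when deriving a strain
#'   repertoire, in \[0, 0.1\].
#' @param marker_dropout_prob Per-marker detection failure probability.
#' @param n_shared_subjects Number of subjects planted with a shared strain.
#' @param shared_species Species eligible for strain planting; default the
#'   five frequently overlapping oral species of [default_species_list()].
#' @param seed Integer seed; equal configs give bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 125L,
                       oral_sites = c(
                         "saliva", "buccal_mucosa",
                         "supragingival_plaque", "tongue_dorsum"
                       ),
                       n_oral_species = 60L,
                       n_gut_species = 100L,
                       n_generalist_species = 8L,
                       lognormal_mu = 0,
                       lognormal_sigma = 2,
                       occupancy_oral_in_oral = 0.8,
                       occupancy_gut_in_gut = 0.8,
                       occupancy_oral_in_gut = 0.1,
                       n_markers_per_species = 100L,
                       gene_loss_prob = 0.02,
                       marker_dropout_prob = 0.01,
                       n_shared_subjects = 7L,
                       shared_species = default_species_list(),
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    oral_sites = as.character(oral_sites),
    n_oral_species = as.integer(n_oral_species),
    n_gut_species = as.integer(n_gut_species),
    n_generalist_species = as.integer(n_generalist_species),
    lognormal_mu = as.numeric(lognormal_mu),
    lognormal_sigma = as.numeric(lognormal_sigma),
    occupancy_oral_in_oral = as.numeric(occupancy_oral_in_oral),
    occupancy_gut_in_gut = as.numeric(occupancy_gut_in_gut),
    occupancy_oral_in_gut = as.numeric(occupancy_oral_in_gut),
    n_markers_per_species = as.integer(n_markers_per_species),
    gene_loss_prob = as.numeric(gene_loss_prob),
    marker_dropout_prob = as.numeric(marker_dropout_prob),
    n_shared_subjects = as.integer(n_shared_subjects),
    shared_species = as.character(shared_species),
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L) abort_argument("n_subjects must be >= 1")
  if (length(cfg$oral_sites) < 1L ||
      !all(cfg$oral_sites %in% oral_sites())) {
    abort_argument(paste0(
      "oral_sites must be a non-empty subset of: ",
      paste(oral_sites(), collapse = ", ")
    ))
  }
  probs <- c(
    cfg$occupancy_oral_in_oral, cfg$occupancy_gut_in_gut,
    cfg$occupancy_oral_in_gut, cfg$marker_dropout_prob, cfg$gene_loss_prob
  )
  if (any(probs < 0 | probs > 1)) {
    abort_argument("all probabilities must lie in [0, 1]")
  }
  if (cfg$gene_loss_prob > 0.1) {
    abort_argument("gene_loss_prob must lie in [0, 0.1]")
  }
  if (cfg$n_markers_per_species < 10L) {
    abort_argument("n_markers_per_species must be >= 10")
  }
  if (cfg$n_shared_subjects > cfg$n_subjects) {
    abort_argument("n_shared_subjects must not exceed n_subjects")
  }
  if (cfg$n_shared_subjects > 0L && length(cfg$shared_species) == 0L) {
    abort_argument("shared_species must be non-empty when planting subjects")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw distinct strain repertoires for one species
#'
#' Each repertoire starts from the all-present reference marker set and
#' independently loses markers with probability `gene_loss_prob`. Draws
#' losing more than 10 percent of markers are rejected, so a noise-free
#' strain always passes the 90 percent coverage filter; draws colliding with
#' an already accepted repertoire are redrawn (same strain means same
#' pattern, so distinct strains must differ in at least one marker).
#'
#' @param species_name Species the repertoires belong to.
#' @param n_strains Number of pairwise-distinct repertoires (>= 1).
#' @param gene_loss_prob Per-marker loss probability, in \[0, 0.1\].
#' @param n_markers Total marker count for the species.
#' @param max_attempts Attempt budget before giving up (degenerate configs
#'   such as `gene_loss_prob = 0` with `n_strains > 1` cannot succeed).
#' @return List of `strain_repertoire` objects, each a list with
#'   `species_name` and a 0/1 `presence` vector of length `n_markers`.
#' @export
draw_strain_repertoires <- function(species_name, n_strains, gene_loss_prob,
                                    n_markers, max_attempts = 1000L) {
  if (n_strains < 1L) abort_argument("n_strains must be >= 1")
  if (n_markers < 10L) abort_argument("n_markers must be >= 10")
  if (gene_loss_prob < 0 || gene_loss_prob > 0.1) {
    abort_argument("gene_loss_prob must lie in [0, 0.1]")
  }
  floor_present <- ceiling(0.9 * n_markers)
  reps <- vector("list", n_strains)
  seen <- character(0)
  attempts <- 0L
  i <- 1L
  while (i <= n_strains) {
    if (attempts >= max_attempts) {
      abort_generation(paste0(
        "could not draw ", n_strains, " distinct repertoires for ",
        species_name, " within ", max_attempts,
        " attempts (gene_loss_prob = ", gene_loss_prob, ")"
      ))
    }
    attempts <- attempts + 1L
    v <- as.integer(runif(n_markers) >= gene_loss_prob)
    if (sum(v) < floor_present) next
    key <- paste(v, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    reps[[i]] <- structure(
      list(species_name = species_name, presence = v),
      class = "strain_repertoire"
    )
    i <- i + 1L
  }
  reps
}

#' Simulate depth-dependent marker detection
#'
#' Each marker present in the strain repertoire is observed independently
#' with probability `1 - marker_dropout_prob`; absent markers are never
#' observed (clade-specific markers yield no false detections).
#'
#' @param repertoire A `strain_repertoire` from [draw_strain_repertoires()].
#' @param marker_dropout_prob Per-marker detection failure probability.
#' @return Integer 0/1 vector of observed markers.
#' @export
simulate_marker_detection <- function(repertoire, marker_dropout_prob) {
  stopifnot(inherits(repertoire, "strain_repertoire"))
  if (marker_dropout_prob < 0 || marker_dropout_prob > 1) {
    abort_argument("marker_dropout_prob must lie in [0, 1]")
  }
  p <- repertoire$presence
  as.integer(p == 1L & runif(length(p)) >= marker_dropout_prob)
}

# Model constant: log-scale magnitude shift for non-gut-adapted species
# observed in stool (spillover occurs at trace abundance, about e^-4 of the
# in-niche magnitude).
gut_spillover_log_penalty <- 4

species_pool <- function(config) {
  n_gen <- max(config$n_generalist_species, length(config$shared_species))
  extra_gen <- n_gen - length(config$shared_species)
  tibble::tibble(
    species = c(
      config$shared_species,
      if (extra_gen > 0) sprintf("Generalist_sp_%03d", seq_len(extra_gen)),
      if (config$n_oral_species > 0) {
        sprintf("Oral_sp_%03d", seq_len(config$n_oral_species))
      },
      if (config$n_gut_species > 0) {
        sprintf("Gut_sp_%03d", seq_len(config$n_gut_species))
      }
    ),
    niche = c(
      rep("generalist", n_gen),
      rep("oral", config$n_oral_species),
      rep("gut", config$n_gut_species)
    )
  ) |>
    dplyr::mutate(
      occ_oral = dplyr::case_when(
        .data$niche == "gut" ~ 0,
        TRUE ~ config$occupancy_oral_in_oral
      ),
      occ_gut = dplyr::case_when(
        .data$niche == "oral" ~ config$occupancy_oral_in_gut,
        TRUE ~ config$occupancy_gut_in_gut
      )
    )
}

#' Generate a seeded synthetic paired cohort
#'
#' Produces abundance and marker tables that pass the package's validation,
#' plus the ground truth needed to verify the strain caller: which
#' (subject, species, oral site) triples were planted with an identical
#' stool/oral strain repertoire, and which repertoire every sample carries.
#' See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort` with elements `abundance`
#'   ([abundance_table()]), `markers` ([marker_table()]), `truth` (list with
#'   tibbles `$shared` (`subject_id`, `species`, `oral_site`) and
#'   `$strain_assignment` (`sample_id`, `species`, list-column
#'   `repertoire`)), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  subjects <- sprintf("subj_%04d", seq_len(config$n_subjects))
  sites <- c("stool", sort(config$oral_sites))
  meta <- tidyr::expand_grid(subject_id = subjects, body_site = sites) |>
    dplyr::mutate(
      sample_id = paste(.data$subject_id, .data$body_site, sep = "__"),
      study_id = "synthetic",
      visit = 1L
    ) |>
    dplyr::select(
      "sample_id", "subject_id", "body_site", "study_id", "visit"
    )

  pool <- species_pool(config)
  n_samp <- nrow(meta)
  n_spec <- nrow(pool)
  is_oral_sample <- meta$body_site != "stool"

  # occupancy matrix: samples x species
  occ <- matrix(rep(pool$occ_gut, each = n_samp), n_samp, n_spec)
  occ[is_oral_sample, ] <- matrix(
    rep(pool$occ_oral, each = sum(is_oral_sample)),
    sum(is_oral_sample), n_spec
  )
  present <- matrix(runif(n_samp * n_spec) < occ, n_samp, n_spec)
  # Non-gut-adapted species reaching stool do so at trace levels: their
  # stool magnitudes are drawn with the log-mean shifted down by a fixed
  # spillover penalty, reproducing the hallmark of oral-origin overlappers
  # (frequent detection in stool, but at far lower relative abundance than
  # in the mouth).
  mu <- matrix(config$lognormal_mu, n_samp, n_spec)
  mu[!is_oral_sample, pool$niche != "gut"] <-
    config$lognormal_mu - gut_spillover_log_penalty
  magnitude <- matrix(
    rlnorm(n_samp * n_spec, as.vector(mu), config$lognormal_sigma),
    n_samp, n_spec
  )
  abund <- present * magnitude
  rownames(abund) <- meta$sample_id
  colnames(abund) <- pool$species

  # plant shared-strain subjects: force the chosen species present in both
  # members of the planted pair before renormalization
  shared <- tibble::tibble(
    subject_id = character(0), species = character(0), oral_site = character(0)
  )
  if (config$n_shared_subjects > 0L) {
    planted_subjects <- sort(sample(subjects, config$n_shared_subjects))
    shared <- tibble::tibble(
      subject_id = planted_subjects,
      species = sample(config$shared_species, config$n_shared_subjects,
        replace = TRUE
      ),
      oral_site = sample(config$oral_sites, config$n_shared_subjects,
        replace = TRUE
      )
    )
    for (k in seq_len(nrow(shared))) {
      for (site in c("stool", shared$oral_site[k])) {
        sid <- paste(shared$subject_id[k], site, sep = "__")
        if (abund[sid, shared$species[k]] == 0) {
          mu_k <- if (site == "stool") {
            config$lognormal_mu - gut_spillover_log_penalty
          } else {
            config$lognormal_mu
          }
          abund[sid, shared$species[k]] <-
            rlnorm(1, mu_k, config$lognormal_sigma)
        }
      }
    }
  }

  # a sample with no species drawn present gets one valid species forced,
  # so renormalization to 100 is defined (negligible probability at defaults)
  empty <- which(rowSums(abund) == 0)
  for (r in empty) {
    ok <- which(occ[r, ] > 0)
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    abund[r, j] <- rlnorm(1, mu[r, j], config$lognormal_sigma)
  }
  abund <- abund / rowSums(abund) * 100

  entries <- which(abund > 0, arr.ind = TRUE)
  abundance_long <- tibble::tibble(
    sample_id = rownames(abund)[entries[, 1]],
    species = colnames(abund)[entries[, 2]],
    relative_abundance = abund[entries]
  ) |>
    dplyr::arrange(.data$sample_id, .data$species)

  # strain repertoires for shared species: one per (sample, species) with the
  # species present; within a subject all repertoires are pairwise distinct
  # except the planted stool/oral pair, which shares one
  assignment <- list()
  for (sp in sort(unique(config$shared_species))) {
    carriers <- abundance_long |>
      dplyr::filter(.data$species == sp) |>
      dplyr::left_join(meta, by = "sample_id") |>
      dplyr::arrange(.data$subject_id, .data$sample_id)
    for (subj in unique(carriers$subject_id)) {
      ids <- carriers$sample_id[carriers$subject_id == subj]
      plant <- shared[shared$subject_id == subj & shared$species == sp, ]
      planted_ids <- character(0)
      if (nrow(plant) == 1L) {
        planted_ids <- paste(subj, c("stool", plant$oral_site), sep = "__")
      }
      solo_ids <- setdiff(ids, planted_ids)
      n_groups <- length(solo_ids) + (length(planted_ids) > 0)
      reps <- draw_strain_repertoires(
        sp, n_groups, config$gene_loss_prob, config$n_markers_per_species
      )
      grp <- c(
        if (length(planted_ids)) {
          setNames(rep(1L, length(planted_ids)), planted_ids)
        },
        setNames(
          seq_along(solo_ids) + (length(planted_ids) > 0),
          solo_ids
        )
      )
      assignment[[length(assignment) + 1L]] <- tibble::tibble(
        sample_id = names(grp),
        species = sp,
        repertoire = reps[unname(grp)]
      )
    }
  }
  assignment <- if (length(assignment)) {
    dplyr::bind_rows(assignment) |>
      dplyr::arrange(.data$species, .data$sample_id)
  } else {
    tibble::tibble(
      sample_id = character(0), species = character(0), repertoire = list()
    )
  }

  # observed marker entries: dropout applied per present marker; detected
  # markers get an RPK-like positive value
  marker_ids <- function(sp) {
    sprintf("%s__m%03d", sp, seq_len(config$n_markers_per_species))
  }
  marker_rows <- purrr::pmap(
    assignment,
    function(sample_id, species, repertoire) {
      obs <- simulate_marker_detection(repertoire, config$marker_dropout_prob)
      idx <- which(obs == 1L)
      tibble::tibble(
        sample_id = sample_id,
        marker_id = marker_ids(species)[idx],
        value = round(runif(length(idx), 1, 20), 3)
      )
    }
  )
  marker_values <- if (length(marker_rows)) {
    dplyr::bind_rows(marker_rows)
  } else {
    tibble::tibble(
      sample_id = character(0), marker_id = character(0), value = numeric(0)
    )
  }
  shared_sorted <- sort(unique(config$shared_species))
  marker_map <- tibble::tibble(
    marker_id = as.character(unlist(lapply(shared_sorted, marker_ids))),
    species = rep(shared_sorted, each = config$n_markers_per_species)
  )

  markers <- suppressWarnings(marker_table(marker_values, marker_map))

  structure(
    list(
      abundance = abundance_table(abundance_long, meta),
      markers = markers,
      truth = list(shared = shared, strain_assignment = assignment),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", x$config$n_subjects, " subjects, sites: stool + ",
    paste(x$config$oral_sites, collapse = ", "), "\n",
    "  planted shared-strain subjects: ", nrow(x$truth$shared), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic cohort as interchange TSV files
#'
#' Emits `metadata.tsv`, `abundance.tsv`, `markers.tsv`, `marker_map.tsv`
#' and `truth.tsv` (planted `subject_id`, `species`, `oral_site` triples)
#' into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metadata = file.path(dir, "metadata.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    markers = file.path(dir, "markers.tsv"),
    marker_map = file.path(dir, "marker_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_abundance_table(cohort$abundance, paths["abundance"], paths["metadata"])
  write_marker_table(cohort$markers, paths["markers"], paths["marker_map"])
  readr::write_tsv(
    dplyr::arrange(cohort$truth$shared, .data$subject_id, .data$species),
    paths["truth"],
    progress = FALSE
  )
  invisible(paths)
}
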