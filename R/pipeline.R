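#' Run the full oral-gut overlap pipeline from a YAML configuration
#'
#' Executes, for each configured oral site: within-subject pairing,
#' prevalence filtering, overlap-frequency computation, fecal-vs-oral
#' abundance comparison (paired Wilcoxon + Benjamini-Hochberg), and the
#' Bray-Curtis distance matrix on log-transformed abundances; then
#' clade-specific marker-gene strain-consistency calling across all sites.
#' All result tables are written as TSV, figures as PDF, and a JSON run
#' manifest (config hash, seed, input checksums, row counts) records
#' provenance. On failure, files created by the run are removed.
#'
#' The YAML config has either an `inputs:` section (paths `metadata`,
#' `abundance`, `markers`, `marker_map`) or a `simulate:` section
#' ([sim_config()] fields) for self-contained runs, plus optional
#' `oral_sites:`, `analysis:` ([analysis_config()] fields), `strain:`
#' (`species`, `coverage_min`, `marker_presence_threshold`), `seed:` and
#' `output_dir:`.
#'
#' @param config_path Path to the YAML configuration.
#' @param output_dir Overrides the config's `output_dir` if given.
#' @param render_figures Set FALSE to skip PDFs (tables always written).
#' @return A `report_bundle`: list with `overlap` (per-site tibbles),
#'   `strain_calls`, `consistent_individuals`, `distances` (per-site
#'   matrices), `manifest`, and `paths` of written files. Invisibly.
#' @export
run_pipeline <- function(config_path, output_dir = NULL,
                         render_figures = TRUE) {
  if (!file.exists(config_path)) {
    abort_io(paste0("config file not found: ", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  out_dir <- output_dir %||% cfg$output_dir %||% "oralgut_results"
  sites <- as.character(cfg$oral_sites %||% oral_sites())
  if (length(sites) == 0L) {
    abort_argument("config must request at least one oral site")
  }
  if (!all(sites %in% oral_sites())) {
    abort_argument(paste0(
      "unknown oral site(s) in config: ",
      paste(setdiff(sites, oral_sites()), collapse = ", ")
    ))
  }
  seed <- as.integer(cfg$seed %||% 1L)
  acfg <- do.call(analysis_config, cfg$analysis %||% list())
  strain_cfg <- cfg$strain %||% list()

  created <- character(0)
  note <- function(paths) created <<- c(created, paths)
  pre_existing <- dir.exists(out_dir)

  bundle <- tryCatch(
    {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      input_paths <- character(0)
      if (!is.null(cfg$simulate)) {
        sim_args <- cfg$simulate
        sim_args$seed <- as.integer(sim_args$seed %||% seed)
        sim <- do.call(sim_config, sim_args)
        if (is.null(cfg$simulate$oral_sites)) {
          sim$oral_sites <- sites
        }
        log_stage("simulate", paste0(
          "n_subjects=", sim$n_subjects,
          " planted=", sim$n_shared_subjects, " seed=", sim$seed
        ))
        cohort <- generate_cohort(sim)
        input_dir <- file.path(out_dir, "inputs")
        input_paths <- write_cohort(cohort, input_dir)
        note(input_paths)
        table <- cohort$abundance
        markers <- cohort$markers
      } else if (!is.null(cfg$inputs)) {
        need <- c("metadata", "abundance", "markers", "marker_map")
        miss <- setdiff(need, names(cfg$inputs))
        if (length(miss)) {
          abort_argument(paste0(
            "config inputs section lacks: ", paste(miss, collapse = ", ")
          ))
        }
        input_paths <- unlist(cfg$inputs[need])
        table <- load_abundance_table(
          cfg$inputs$abundance, cfg$inputs$metadata
        )
        markers <- load_marker_table(
          cfg$inputs$markers, cfg$inputs$marker_map
        )
      } else {
        abort_argument("config must contain either `inputs` or `simulate`")
      }

      overlap_results <- list()
      distances <- list()
      for (site in sites) {
        pairs <- build_sample_pairs(table, site)
        log_stage(site, paste0("pairs=", nrow(pairs)))
        if (nrow(pairs) == 0L) {
          warn(paste0("no stool/", site, " pairs; site skipped"))
          next
        }
        overlapping <- find_overlapping_species(table, pairs, acfg)
        log_stage(site, paste0(
          "overlapping_species=", nrow(overlapping)
        ))
        res <- compare_niche_abundances(
          table, pairs, overlapping$species, acfg
        )
        overlap_results[[site]] <- res
        f1 <- file.path(out_dir, paste0(site, "_overlapping_species.tsv"))
        readr::write_tsv(overlapping, f1, progress = FALSE)
        note(f1)
        pooled <- unique(c(pairs$stool_sample_id, pairs$oral_sample_id))
        d <- bray_curtis_matrix(abundance_wide_matrix(table, pooled))
        distances[[site]] <- d
        f2 <- file.path(out_dir, paste0(site, "_bray_curtis.tsv"))
        readr::write_tsv(
          tibble::as_tibble(d, rownames = "sample_id"), f2,
          progress = FALSE
        )
        note(f2)
        if (nrow(res) && render_figures) {
          note(render_overlap_report(res, out_dir, prefix = site))
        } else if (nrow(res)) {
          f3 <- file.path(
            out_dir, paste0(site, "_abundance_comparison.tsv")
          )
          readr::write_tsv(
            dplyr::arrange(res, .data$species), f3,
            progress = FALSE
          )
          note(f3)
        }
      }

      species_list <- as.character(
        strain_cfg$species %||% default_species_list()
      )
      coverage_min <- as.numeric(strain_cfg$coverage_min %||% 0.9)
      thr <- as.numeric(strain_cfg$marker_presence_threshold %||% 0)
      calls <- call_shared_strains(
        markers, table$metadata, species_list, coverage_min, thr
      )
      n_consistent <- count_consistent_individuals(calls)
      log_stage("strains", paste0(
        "calls=", nrow(calls), " consistent_individuals=", n_consistent
      ))
      calls_flat <- calls |>
        dplyr::mutate(
          matched_oral_sites = vapply(
            .data$matched_oral_sites, paste, character(1),
            collapse = ","
          )
        )
      f4 <- file.path(out_dir, "strain_calls.tsv")
      readr::write_tsv(calls_flat, f4, progress = FALSE)
      note(f4)

      if (render_figures && nrow(calls)) {
        pats <- unlist(
          lapply(intersect(species_list, markers$marker_map$species),
            function(sp) {
              eligible_samples(
                markers, unique(markers$values$sample_id), sp,
                coverage_min, thr
              )
            }
          ),
          recursive = FALSE
        )
        if (length(pats)) {
          note(render_marker_heatmap(
            pats, calls, out_dir, table$metadata
          ))
        }
      }

      manifest <- list(
        package_version = as.character(utils::packageVersion("oralgut")),
        timestamp = format(Sys.time(), tz = "UTC"),
        seed = seed,
        config_hash = rlang::hash(cfg),
        input_checksums = as.list(tools::md5sum(
          input_paths[file.exists(input_paths)]
        )),
        oral_sites = sites,
        n_consistent_individuals = n_consistent
      )
      f5 <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(
        manifest, f5,
        auto_unbox = TRUE, pretty = TRUE
      )
      note(f5)

      structure(
        list(
          overlap = overlap_results,
          strain_calls = calls,
          consistent_individuals = n_consistent,
          distances = distances,
          manifest = manifest,
          paths = unname(created)
        ),
        class = "report_bundle"
      )
    },
    error = function(e) {
      # remove partial outputs of this run, then re-raise with stage context
      unlink(created[file.exists(created)])
      if (!pre_existing) unlink(out_dir, recursive = TRUE)
      abort(
        paste0("pipeline failed: ", conditionMessage(e)),
        class = "oralgut_pipeline_error", parent = e
      )
    }
  )
  invisible(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (site in names(x$overlap)) {
    cat(
      "  ", site, ": ", nrow(x$overlap[[site]]),
      " overlapping species\n",
      sep = ""
    )
  }
  cat(
    "  consistent individuals (same-strain pattern): ",
    x$consistent_individuals, "\n",
    sep = ""
  )
  invisible(x)
}

log_stage <- function(stage, msg) {
  message(sprintf("[oralgut] %-22s %s", stage, msg))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
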