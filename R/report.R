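#' Render overlap-analysis figures and their backing tables
#'
#' Produces, for one oral-site dataset: a bar chart of pairwise overlap
#' frequencies, paired fecal/oral abundance boxplots built from the
#' precomputed Tukey summaries (whiskers at the most extreme points within
#' 1.5 IQR of the box), and a `-log10(q)` significance plot with the
#' q = 0.05 threshold line. Every rendered number is also written to a TSV:
#' the figures are views of the tables, never the sole output.
#'
#' @param results Tibble from [compare_niche_abundances()].
#' @param output_dir Directory for the figure PDFs and backing TSV.
#' @param prefix Filename prefix, typically the oral site.
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlap_report <- function(results, output_dir, prefix = "overlap") {
  if (is.null(results) || nrow(results) == 0L) {
    warn("no overlap results to render")
    return(invisible(character(0)))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(output_dir, paste0(prefix, "_abundance_comparison.tsv"))
  readr::write_tsv(
    dplyr::arrange(results, .data$species), tsv,
    progress = FALSE
  )

  ord <- results |>
    dplyr::arrange(dplyr::desc(.data$overlap_frequency), .data$species)
  ord$species <- factor(ord$species, levels = rev(ord$species))

  p_freq <- ggplot2::ggplot(
    ord,
    ggplot2::aes(x = .data$species, y = .data$overlap_frequency)
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "pairwise overlap frequency",
      title = paste0(prefix, ": species overlapping stool and oral samples")
    ) +
    ggplot2::theme_minimal(base_size = 9)
  f_freq <- file.path(output_dir, paste0(prefix, "_overlap_frequency.pdf"))
  ggplot2::ggsave(f_freq, p_freq, width = 6, height = 5)

  box_long <- dplyr::bind_rows(
    dplyr::transmute(
      ord,
      species = .data$species, niche = "fecal",
      median = .data$fecal_median, q1 = .data$fecal_q1, q3 = .data$fecal_q3,
      lo = .data$fecal_whisker_low, hi = .data$fecal_whisker_high
    ),
    dplyr::transmute(
      ord,
      species = .data$species, niche = "oral",
      median = .data$oral_median, q1 = .data$oral_q1, q3 = .data$oral_q3,
      lo = .data$oral_whisker_low, hi = .data$oral_whisker_high
    )
  )
  p_box <- ggplot2::ggplot(
    box_long,
    ggplot2::aes(x = .data$species, fill = .data$niche)
  ) +
    ggplot2::geom_boxplot(
      ggplot2::aes(
        ymin = .data$lo, lower = .data$q1, middle = .data$median,
        upper = .data$q3, ymax = .data$hi
      ),
      stat = "identity", position = ggplot2::position_dodge(width = 0.8),
      width = 0.6
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "relative abundance (%)",
      title = paste0(prefix, ": fecal vs. oral abundance of overlappers")
    ) +
    ggplot2::theme_minimal(base_size = 9)
  f_box <- file.path(output_dir, paste0(prefix, "_abundance_boxplots.pdf"))
  ggplot2::ggsave(f_box, p_box, width = 7, height = 5)

  sig <- dplyr::filter(ord, .data$test_defined)
  f_sig <- character(0)
  if (nrow(sig)) {
    p_sig <- ggplot2::ggplot(
      sig,
      ggplot2::aes(
        x = .data$species,
        y = -log10(pmax(.data$q_value, 1e-300))
      )
    ) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_hline(yintercept = -log10(0.05), colour = "red") +
      ggplot2::coord_flip() +
      ggplot2::labs(
        x = NULL, y = "-log10(q)",
        title = paste0(
          prefix,
          ": fecal vs. oral abundance test (points above the red line",
          " are significant, q < 0.05)"
        )
      ) +
      ggplot2::theme_minimal(base_size = 9)
    f_sig <- file.path(output_dir, paste0(prefix, "_significance.pdf"))
    ggplot2::ggsave(f_sig, p_sig, width = 6, height = 5)
  }
  invisible(c(tsv, f_freq, f_box, f_sig))
}

#' Render binary marker-gene heatmaps with same-strain annotations
#'
#' One heatmap per species: rows are marker genes, columns are samples
#' grouped by subject, cells are presence/absence; stool samples with at
#' least one matching oral sample from the same individual are marked with
#' an asterisk. The underlying binary matrix is also written as a TSV per
#' species.
#'
#' @param patterns List of `marker_pattern` objects (any mix of species).
#' @param calls Output of [call_shared_strains()] used for the asterisks.
#' @param output_dir Directory for the per-species PDF and TSV files.
#' @param metadata Sample metadata tibble used to group columns by subject.
#' @return Character vector of written file paths, invisibly.
#' @export
render_marker_heatmap <- function(patterns, calls, output_dir, metadata) {
  if (!length(patterns)) abort_argument("patterns must be non-empty")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  metadata <- tibble::as_tibble(metadata)
  species_of <- vapply(patterns, `[[`, character(1), "species_name")
  written <- character(0)
  consistent_stool <- unique(
    calls$stool_sample_id[calls$is_consistent]
  )
  for (sp in sort(unique(species_of))) {
    pats <- patterns[species_of == sp]
    ids <- vapply(pats, `[[`, character(1), "sample_id")
    mat <- do.call(cbind, lapply(pats, `[[`, "presence"))
    colnames(mat) <- ids
    info <- metadata[match(ids, metadata$sample_id), ]
    # columns grouped by subject, stool first within each subject
    col_order <- order(info$subject_id, info$body_site != "stool", ids)
    mat <- mat[, col_order, drop = FALSE]
    info <- info[col_order, ]

    tsv <- file.path(output_dir, paste0("marker_matrix_", sp, ".tsv"))
    readr::write_tsv(
      tibble::as_tibble(mat, rownames = "marker_id"), tsv,
      progress = FALSE
    )

    long <- tibble::as_tibble(mat, rownames = "marker_id") |>
      tidyr::pivot_longer(
        -"marker_id",
        names_to = "sample_id", values_to = "present"
      )
    long$sample_id <- factor(long$sample_id, levels = colnames(mat))
    star <- tibble::tibble(
      sample_id = factor(
        intersect(
          colnames(mat),
          calls$stool_sample_id[calls$is_consistent & calls$species == sp]
        ),
        levels = colnames(mat)
      )
    )
    p <- ggplot2::ggplot(
      long,
      ggplot2::aes(x = .data$sample_id, y = .data$marker_id)
    ) +
      ggplot2::geom_tile(
        ggplot2::aes(fill = factor(.data$present)),
        colour = NA
      ) +
      ggplot2::scale_fill_manual(
        values = c(`0` = "grey92", `1` = "grey15"),
        name = "marker", labels = c("absent", "present")
      ) +
      ggplot2::labs(
        x = "samples (grouped by individual; * = stool matching an oral",
        y = "marker gene",
        title = paste0(sp, ": clade-specific marker presence/absence")
      ) +
      ggplot2::theme_minimal(base_size = 7) +
      ggplot2::theme(
        axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
        axis.text.y = ggplot2::element_blank()
      )
    if (nrow(star)) {
      p <- p + ggplot2::geom_text(
        data = star,
        ggplot2::aes(x = .data$sample_id, y = Inf),
        label = "*", vjust = 1.1, size = 5, colour = "red"
      )
    }
    pdf_path <- file.path(output_dir, paste0("marker_heatmap_", sp, ".pdf"))
    ggplot2::ggsave(
      pdf_path, p,
      width = max(5, 0.25 * ncol(mat) + 2), height = 6, limitsize = FALSE
    )
    written <- c(written, tsv, pdf_path)
  }
  invisible(written)
}
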