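# In-code fixtures: small paired cohorts and marker tables built fresh per
# test, plus independent brute-force oracles for the statistics.

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    subject_id = c("A", "A", "B", "B", "C", "C"),
    body_site = rep(c("stool", "saliva"), 3),
    study_id = "study1",
    visit = 1L
  )
}

toy_abundance <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S3", "S4", "S5", "S6"),
    species = c(
      "Streptococcus_salivarius", "Gut_sp_A",
      "Streptococcus_salivarius",
      "Streptococcus_salivarius", "Streptococcus_salivarius",
      "Gut_sp_A", "Streptococcus_salivarius"
    ),
    relative_abundance = c(0.5, 80, 12, 1.5, 30, 95, 4)
  )
}

toy_table <- function() abundance_table(toy_abundance(), toy_metadata())

# Marker fixture: one species, `n` markers, chosen samples present at
# chosen markers.
toy_markers <- function(presence, species = "Streptococcus_salivarius") {
  n <- max(vapply(presence, length, integer(1)))
  map <- tibble::tibble(
    marker_id = sprintf("%s__m%03d", species, seq_len(n)),
    species = species
  )
  vals <- purrr::imap_dfr(presence, function(pres, sid) {
    idx <- which(pres == 1L)
    tibble::tibble(
      sample_id = sid,
      marker_id = map$marker_id[idx],
      value = 1
    )
  })
  suppressWarnings(marker_table(vals, map))
}

write_toy_tsvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ap <- file.path(dir, "abundance.tsv")
  mp <- file.path(dir, "metadata.tsv")
  readr::write_tsv(toy_abundance(), ap, progress = FALSE)
  readr::write_tsv(toy_metadata(), mp, progress = FALSE)
  list(abundance = ap, metadata = mp)
}

# Independent step-up BH oracle (sort, p * n / rank, enforce monotonicity
# from the largest rank, clip at 1, map back to input order).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive sign-flip oracle for the paired signed-rank test: enumerate all
# 2^n sign assignments of the nonzero differences and count assignments at
# least as extreme as the observed signed-rank sum.
wilcoxon_oracle <- function(fecal, oral) {
  d <- fecal - oral
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

random_paired_percent <- function(n, max_int = 4L) {
  # integer-valued to force ties and zero differences
  list(
    fecal = sample(0:max_int, n, replace = TRUE) / 2,
    oral = sample(0:max_int, n, replace = TRUE) / 2
  )
}
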