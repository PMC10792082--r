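# oralgut

Do oral bacteria colonize the healthy adult gut, or do the mouth and colon
host separate, niche-adapted pools of the same species? `oralgut` implements
the two-level analysis needed to ask this of paired shotgun metagenomic
profiles — one stool sample and one oral sample (saliva, buccal mucosa,
supragingival plaque, or tongue dorsum) per individual:

1. **Species-level overlap.** For each oral site, after prevalence
   filtering (species detected in at least `max(3, ⌈0.10·N⌉)` of the `N`
   samples), compute each species' *pairwise overlap frequency*

   `f_s = #{pairs with species s detected in both members} / #pairs`,

   keep species with `f_s ≥ 0.10`, and compare their fecal vs. oral
   relative abundances with a paired Wilcoxon signed-rank test,
   Benjamini–Hochberg corrected per site (`q < 0.05`). A significantly
   higher oral median implies an oral origin; a significantly higher fecal
   median implies a fecal origin.

2. **Strain-level consistency from clade-specific marker genes.** Strains
   of a species gain and lose marker genes, so the binary presence/absence
   pattern over a species' full marker set is a coarse strain fingerprint.
   Restricting to samples with ≥ 90% marker coverage (to exclude
   depth-driven missingness), an individual whose stool pattern is
   *identical* to an oral pattern for the same species is called
   **consistent with same-strain colonization** — necessary but not
   sufficient evidence, since SNP-level strain differences are invisible to
   presence/absence.

The package also ships a seeded synthetic paired-cohort generator
(niche-adapted species pools, sparse log-normal abundances, gene-gain/loss
strain repertoires, depth-dependent marker dropout, planted shared-strain
individuals with ground truth), so every stage is verifiable without any
external download. It is aimed at microbiome researchers analysing paired
body-site profiles from uniformly processed taxonomic/marker tables.

## Worked example

```r
library(oralgut)

cohort <- generate_cohort(sim_config(n_subjects = 40, n_shared_subjects = 4,
                                     marker_dropout_prob = 0, seed = 11))
pairs <- build_sample_pairs(cohort$abundance, "saliva")
overlapping <- find_overlapping_species(cohort$abundance, pairs)
head(overlapping, 5)
#> # A tibble: 5 × 4
#>   species                     n_pairs n_overlapping_pairs overlap_frequency
#>   <chr>                         <int>               <int>             <dbl>
#> 1 Generalist_sp_003                40                  31             0.775
#> 2 Streptococcus_parasanguinis      40                  30             0.75
#> 3 Generalist_sp_002                40                  28             0.7
#> 4 Streptococcus_salivarius         40                  28             0.7
#> 5 Haemophilus_parainfluenzae       40                  26             0.65
```

Members of the normal oral flora overlap with stool in well over half of the
within-subject pairs. Are they *resident* in the gut? Their fecal abundance
says otherwise:

```r
res <- compare_niche_abundances(cohort$abundance, pairs, overlapping$species)
head(dplyr::select(res, species, overlap_frequency, fecal_median, oral_median,
                   q_value, inferred_origin), 5)
#> # A tibble: 5 × 6
#>   species     overlap_frequency fecal_median oral_median q_value inferred_origin
#>   <chr>                   <dbl>        <dbl>       <dbl>   <dbl> <chr>
#> 1 Generalist…             0.775      0.00232       0.196 1.76e-6 oral
#> 2 Streptococ…             0.75       0.00148       0.134 1.76e-6 oral
#> 3 Generalist…             0.7        0.00172       0.273 1.86e-6 oral
#> 4 Streptococ…             0.7        0.00117       0.245 1.16e-6 oral
#> 5 Haemophilu…             0.65       0.00123       0.196 3.04e-6 oral
```

Fecal medians are trace (≪ 0.1%) while oral medians are ~100× higher, with
`q < 0.05` — the signature of oral-origin spillover rather than gut
residence. The decisive test is at the strain level: this cohort was
simulated with 4 individuals planted to carry an identical stool/oral strain
(and no marker dropout), and the caller recovers exactly those:

```r
calls <- call_shared_strains(cohort$markers, cohort$abundance$metadata)
count_consistent_individuals(calls)
#> [1] 4
consistent_triples(calls)
#> # A tibble: 4 × 3
#>   subject_id species                     oral_site
#>   <chr>      <chr>                       <chr>
#> 1 subj_0003  Streptococcus_parasanguinis saliva
#> 2 subj_0012  Streptococcus_parasanguinis supragingival_plaque
#> 3 subj_0026  Veillonella_parvula         saliva
#> 4 subj_0027  Streptococcus_mitis         tongue_dorsum
```

`run_pipeline("config.yaml")` composes all of the above for every configured
oral site from a YAML file (either TSV input paths or an embedded simulation
config), writing per-site overlap and comparison TSVs, Bray–Curtis distance
matrices, strain calls, figures (overlap bars, paired boxplots, −log10(q)
panels, marker heatmaps with asterisks on consistent stool samples), and a
JSON run manifest. A thin CLI wrapper with `simulate`, `overlap`, `strains`
and `run` subcommands lives at `inst/cli/oralgut.R`.

See the methods vignette (`vignettes/oral-gut-overlap-methods.Rmd`) for the
statistical model, filter semantics, the generator's assumptions, and known
limitations.

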