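# mamcross

Cross-species mammary tumor subtyping and homology analysis.

## The problem

Basal-like breast cancer (BLBC) is the human intrinsic subtype with the
worst prognosis; most cases are triple-negative and lack targeted
therapies, and a faithful spontaneous animal model is missing. Mammary
tumors in pet dogs are a candidate: they arise naturally in
immune-competent animals at rates comparable to human breast cancer. The
analytic question is two-sided — do canine mammary tumors contain
molecularly distinct subtypes, and is one of them homologous to human
BLBC?

`mamcross` implements the full analysis chain for that question, for
computational biologists working with bulk expression cohorts:

1. **Subtype discovery** — non-negative matrix factorization
   (multiplicative updates, generalized Kullback–Leibler objective) with
   cophenetic-coefficient rank selection, repeated over gene subsets (all
   expressed, top 5000/2000/1000/500 most variable); samples are assigned
   a subtype only when every subset run agrees. Cross-validated against
   k-means, resampled consensus clustering and bootstrap-supported
   hierarchical clustering.
2. **Panel classification** — a PAM50-style nearest-centroid classifier
   (Spearman correlation to per-subtype median centroids), tolerant of
   partial panels (e.g. 43 of 50 genes present in an annotation).
3. **Cross-species homology test** — repeatedly sample a human reference
   (60 tumors per intrinsic subtype + all normal-like), co-cluster it
   with the full canine cohort on the shared panel genes, cut the
   dendrogram at the minimum number of clusters that maximally separates
   human basal-like from luminal A anchors, and call a (canine, human)
   subtype pair *matched* when one cluster holds a strict majority of
   both. Match counts over repeats feed a Fisher exact test; per-repeat
   2-D MDS embeddings give Mahalanobis distances between subtype centers,
   compared by Wilcoxon rank-sum tests.
4. **Feature-gene selection** — pairwise differential-expression pools
   feeding an iterated Boruta (shadow-feature random forest) selector
   with a cross-repeat frequency cutoff.
5. **Expression statistics** — NB Wald differential expression with
   median-of-ratios normalization, single-sample gene-set enrichment
   (ssGSEA) scores, dual Pearson/Spearman correlation screens,
   ER/PR/HER2 status calls from FPKM thresholds (1 and 35), and subgroup
   crosstabs.

A seeded synthetic-cohort generator (`simulate_cohort`) produces
two-species negative-binomial cohorts with a planted homologous subtype
pair, species/batch location-scale effects, a discriminative gene panel
and receptor marker genes, so every stage is testable against ground
truth without downloading external cohorts.

## Worked example

Simulate a dog+human cohort pair with one homologous axis (canine
basal-like ~ human basal-like), discover the canine subtypes without
labels, and test the cross-species homology:

```r
library(mamcross)

cfg <- sim_config(
  n_genes = 1500, n_panel_genes = 50,
  subtypes = list(canine = c(BLMT = 69, NBLMT = 74),
                  human  = c(Basal = 100, LumA = 100, LumB = 100,
                             Her2 = 100, Normal = 27)),
  homologous_pair = c(canine = "BLMT", human = "Basal"),
  axis_weights = c("canine:NBLMT" = 5, shared = 2),
  repressed = list(NBLMT = "shared"),
  n_informative = 80, effect_size = 2,
  species_shift = 1, species_scale = 1.2, seed = 1)
cohort <- simulate_cohort(cfg)
cohort
#> Simulated expression cohort
#>   1500 genes x 570 samples
#>   canine: BLMT=69, NBLMT=74
#>   human: Basal=100, LumA=100, LumB=100, Her2=100, Normal=27
#>   homologous pair: canine:BLMT ~ human:Basal

## receptor status from FPKM thresholds (ER/PR: 1, HER2: 35)
fpkm <- counts_to_fpkm(cohort$counts, cohort$gene_lengths)
head(call_receptor_status(fpkm), 3)
#>       sample  ER  PR         HER2 subgroup
#> 1 canine_001 neg pos not_enriched   ER-PR+
#> 2 canine_002 pos neg not_enriched   ER+PR-
#> 3 canine_003 neg pos not_enriched   ER-PR+

## unsupervised two-subtype discovery on the canine cohort
lt <- cohort_log2tpm(cohort)
canine <- cohort$meta$sample[cohort$meta$species == "canine"]
sub <- consensus_subtypes(lt[, canine], rank = 2, n_runs = 6, seed = 2,
                          max_iter = 1500)
sub
#> Consensus subtyping over 3 gene subsets (rank 2)
#>   143 / 143 samples consistently assigned (100%)
#>   subtype sizes: 1=74, 2=69
#>   238 metagenes

## cross-species homology test (20 of the usual 100 repeats shown)
corrected <- combat_correct(lt, cohort$meta$species)
human <- setdiff(cohort$meta$sample, canine)
labs <- setNames(cohort$meta$subtype, cohort$meta$sample)
hom <- homology_experiment(
  corrected[, canine], labs[canine], corrected[, human], labs[human],
  panel = cohort$truth$panel_genes,
  scheme = sampling_scheme(n_repeats = 20, seed = 3),
  target_pair = c(canine = "BLMT", human = "Basal"), k_max = 45)
hom
#> Cross-species homology experiment (20 repeats)
#>   target pair BLMT ~ Basal matched in 20 / 20 repeats
#>   NBLMT matched any human subtype in 0 / 20 repeats
#>   Fisher exact p = 1.45e-11 (odds ratio Inf)
#>   reference coverage: 100% of tumors drawn at least once
```

Reading the output: the 143 canine tumors split cleanly into the two
planted subtypes (all samples agree across every gene-subset NMF run);
the basal-like canine subtype co-clusters with human basal-like tumors in
every reference resampling, while the other canine subtype matches no
human subtype — the planted homology structure, recovered end to end. On
real cohorts the same calls run unchanged on expression TSVs loaded with
`read_expr_tsv()`.

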