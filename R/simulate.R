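# Two-species expression cohort simulator with known ground truth.
#
# Generative model: each gene g has a log2 baseline b_g ~ N(3, 1.5),
# recentred so that typical FPKM values land on a realistic scale. Each
# subtype owns a slice of a discriminative gene panel plus a private set of
# informative genes; samples of that subtype have those genes shifted by
# `effect_size` on the log2 scale. A homologous subtype pair (one per
# species) shares a single profile, i.e. the same panel slice and
# informative genes — this is the planted cross-species axis. Species and
# batch effects are per-gene location shifts plus a multiplicative scale on
# the biological log-noise (the location-scale model ComBat assumes).
# Counts are negative binomial around length- and library-size-scaled means,
# so counts -> FPKM -> TPM conversions behave like real RNA-seq.

#' Receptor marker configuration for the simulator
#'
#' Controls the three hormone-receptor marker genes (ESR1-, PGR- and
#' ERBB2-like). Per subtype, samples are assigned an ER/PR subgroup with the
#' given proportions; marker counts are then generated so the expected FPKM
#' of each marker straddles the clinical thresholds (1 for ER/PR, 35 for
#' HER2) according to the intended status.
#'
#' @param markers named character vector naming the ER, PR and HER2 marker
#'   genes (these become the last three gene names of the matrix).
#' @param subgroup_props named list: per subtype, a named numeric vector of
#'   proportions over the four ER/PR subgroups (`ER-PR-`, `ER-PR+`,
#'   `ER+PR+`, `ER+PR-`). Subtypes not listed get uniform proportions.
#' @param fpkm_pos,fpkm_neg expected FPKM of ESR1/PGR when positive/negative.
#' @param her2_enriched_fpkm,her2_not_fpkm expected ERBB2 FPKM by HER2 status.
#' @param p_her2 probability a sample is HER2 enriched.
#' @return A list of class `receptor_config`.
#' @export
receptor_config <- function(markers = c(ER = "ESR1", PR = "PGR", HER2 = "ERBB2"),
                            subgroup_props = NULL,
                            fpkm_pos = 8, fpkm_neg = 0.2,
                            her2_enriched_fpkm = 80, her2_not_fpkm = 8,
                            p_her2 = 0.1) {
  .check(length(markers) == 3L && all(c("ER", "PR", "HER2") %in% names(markers)),
         "receptor_config: markers must name ER, PR and HER2 genes")
  .check(fpkm_pos > 1 && fpkm_neg <= 1,
         "receptor_config: fpkm_pos must exceed 1 and fpkm_neg must not")
  .check(her2_enriched_fpkm > 35 && her2_not_fpkm <= 35,
         "receptor_config: her2 FPKM levels must straddle the threshold of 35")
  structure(list(markers = markers, subgroup_props = subgroup_props,
                 fpkm_pos = fpkm_pos, fpkm_neg = fpkm_neg,
                 her2_enriched_fpkm = her2_enriched_fpkm,
                 her2_not_fpkm = her2_not_fpkm, p_her2 = p_her2),
            class = "receptor_config")
}

#' Simulation configuration
#'
#' Defines a one- or two-species cohort with latent subtypes. Each subtype
#' maps to an expression *profile*; the `homologous_pair` (one subtype per
#' species) shares a single profile, planting a cross-species homology. All
#' other subtypes get species-private profiles.
#'
#' @param n_genes number of genes (includes panel and marker genes).
#' @param n_panel_genes size of the discriminative gene panel (the panel is
#'   split into contiguous slices, one per profile).
#' @param subtypes named list: per species, a named integer vector of
#'   per-subtype sample counts.
#' @param homologous_pair `NULL`, or a named character vector giving one
#'   subtype per species (names = species) that share a profile.
#' @param n_informative number of non-panel informative genes per profile.
#' @param programs optional named list of subtype-name groups sharing an
#'   additional expression program (e.g. a "luminal" axis spanning LumA,
#'   LumB and Normal-like). Each program gets its own panel slice and
#'   informative genes, up-shifted in every sample of its member subtypes
#'   (in any species). Programs make member subtypes mutually closer than
#'   they are to outside subtypes, mirroring the correlation structure of
#'   intrinsic breast cancer subtypes.
#' @param repressed optional named list: subtype name -> axis names whose
#'   genes are *down*-shifted by `effect_size` in that subtype's samples
#'   (in any species carrying the subtype). Models lineage programs a
#'   subtype actively lacks — e.g. a multi-lineage subtype suppressing the
#'   luminal epithelial programs of every other group, making it distant
#'   from all of them.
#' @param axis_weights optional named numeric vector of relative panel-slice
#'   weights per expression axis. Axes are named `"shared"` (the homologous
#'   profile), `"species:subtype"` for private profiles, and program names.
#'   Unnamed axes get weight 1. A weight of 2 gives an axis roughly twice
#'   the panel genes, making that profile proportionally more divergent —
#'   e.g. a species-private subtype carrying a lineage program absent from
#'   the other species.
#' @param effect_size log2 shift applied to a profile's panel slice and
#'   informative genes in samples of that profile (>= 0).
#' @param species_shift,species_scale per-gene additive log2 shift (mean of
#'   a N(shift, 0.3) draw) and multiplicative scale on the biological
#'   log-noise for every species after the first. The first species is the
#'   reference (no shift, scale 1).
#' @param batches optional named list: per species, a named integer vector
#'   of per-batch sample counts (must sum to the species size). Default: one
#'   batch per species, named after the species.
#' @param batch_shift,batch_scale location/scale batch effects for every
#'   batch after the first within a species, applied like the species effect.
#' @param nb_dispersion negative binomial dispersion (Var = mu + disp*mu^2).
#' @param bio_sd standard deviation of the per-gene-per-sample biological
#'   log2 noise (default 1, the within-subtype heterogeneity typical of
#'   bulk tumor log2 expression).
#' @param panel_log2_mean,panel_log2_sd baseline log2 expression
#'   distribution of the panel genes (curated classifier panels are
#'   robustly expressed, so their default baseline sits above the
#'   genome-wide distribution).
#' @param gene_length_range range (bp) gene lengths are drawn from.
#' @param library_size_range range of per-sample total expected counts.
#' @param receptor a [receptor_config()], or `NULL` to disable marker genes.
#' @param seed RNG seed; identical configs with the same seed give
#'   byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_panel_genes = 50,
                       subtypes = list(canine = c(BLMT = 69L, NBLMT = 74L)),
                       homologous_pair = NULL,
                       n_informative = 100,
                       programs = NULL,
                       repressed = NULL,
                       axis_weights = NULL,
                       effect_size = 2,
                       species_shift = 0,
                       species_scale = 1,
                       batches = NULL,
                       batch_shift = 0,
                       batch_scale = 1,
                       nb_dispersion = 0.15,
                       bio_sd = 1.0,
                       panel_log2_mean = 4.5,
                       panel_log2_sd = 1,
                       gene_length_range = c(500, 5000),
                       library_size_range = c(1e6, 2e6),
                       receptor = receptor_config(),
                       seed = 1L) {
  .check(is.numeric(n_genes) && n_genes >= 10, "sim_config: n_genes must be >= 10")
  .check(n_panel_genes > 0 && n_panel_genes < n_genes,
         "sim_config: n_panel_genes must be positive and below n_genes")
  .check(is.list(subtypes) && length(subtypes) >= 1L && !is.null(names(subtypes)),
         "sim_config: subtypes must be a named list (one entry per species)")
  for (sp in names(subtypes)) {
    v <- subtypes[[sp]]
    .check(is.numeric(v) && all(v > 0) && !is.null(names(v)),
           "sim_config: subtypes[['", sp, "']] must be a named vector of positive counts")
  }
  .check(effect_size >= 0, "sim_config: effect_size must be >= 0")
  .check(nb_dispersion > 0, "sim_config: nb_dispersion must be > 0")
  .check(n_informative >= 0, "sim_config: n_informative must be >= 0")
  .check(length(gene_length_range) == 2L && all(gene_length_range > 0),
         "sim_config: gene_length_range must be two positive lengths")
  .check(length(library_size_range) == 2L && all(library_size_range > 0),
         "sim_config: library_size_range must be two positive totals")
  if (!is.null(homologous_pair)) {
    .check(length(homologous_pair) == 2L && length(subtypes) == 2L,
           "sim_config: homologous_pair needs one subtype in each of two species")
    .check(setequal(names(homologous_pair), names(subtypes)),
           "sim_config: homologous_pair names must be the species names")
    for (sp in names(homologous_pair))
      .check(homologous_pair[[sp]] %in% names(subtypes[[sp]]),
             "sim_config: homologous_pair subtype '", homologous_pair[[sp]],
             "' not a subtype of species '", sp, "'")
  }
  if (!is.null(batches)) {
    .check(setequal(names(batches), names(subtypes)),
           "sim_config: batches must name the same species as subtypes")
    for (sp in names(batches))
      .check(sum(batches[[sp]]) == sum(subtypes[[sp]]),
             "sim_config: batches[['", sp, "']] must sum to the species size")
  }
  if (!is.null(receptor))
    .check(inherits(receptor, "receptor_config"),
           "sim_config: receptor must be a receptor_config or NULL")
  if (!is.null(programs)) {
    .check(is.list(programs) && !is.null(names(programs)),
           "sim_config: programs must be a named list of subtype groups")
    all_st <- unlist(lapply(subtypes, names))
    for (pg in names(programs))
      .check(all(programs[[pg]] %in% all_st),
             "sim_config: program '", pg, "' names unknown subtype(s)")
  }
  n_marker <- if (is.null(receptor)) 0L else 3L
  n_axes <- length(unlist(lapply(subtypes, names))) -
    (!is.null(homologous_pair)) + length(programs)
  .check(n_panel_genes >= n_axes,
         "sim_config: n_panel_genes must be >= the number of profiles + programs")
  .check(n_genes > n_panel_genes + n_marker + n_informative * n_axes,
         "sim_config: n_genes too small for panel + informative + marker genes")
  structure(list(
    n_genes = as.integer(n_genes), n_panel_genes = as.integer(n_panel_genes),
    subtypes = subtypes, homologous_pair = homologous_pair,
    n_informative = as.integer(n_informative), programs = programs,
    repressed = repressed, axis_weights = axis_weights,
    effect_size = effect_size,
    species_shift = species_shift, species_scale = species_scale,
    batches = batches, batch_shift = batch_shift, batch_scale = batch_scale,
    nb_dispersion = nb_dispersion, bio_sd = bio_sd,
    panel_log2_mean = panel_log2_mean, panel_log2_sd = panel_log2_sd,
    gene_length_range = gene_length_range,
    library_size_range = library_size_range,
    receptor = receptor, seed = as.integer(seed)), class = "sim_config")
}

.subgroups <- c("ER-PR-", "ER-PR+", "ER+PR+", "ER+PR-")

#' Simulate a cohort of expression profiles with known subtype structure
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_cohort`: a list with
#'   \describe{
#'     \item{counts}{gene-by-sample integer matrix of NB counts,}
#'     \item{gene_lengths}{named per-gene lengths in bp,}
#'     \item{meta}{per-sample data frame (sample, species, subtype, batch,
#'       and — when receptor markers are simulated — subgroup, ER, PR, HER2),}
#'     \item{truth}{ground truth: per-sample subtype labels, per-profile
#'       informative gene sets, the homologous pair, panel gene names, and
#'       intended receptor status,}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sc <- simulate_cohort(sim_config(n_genes = 300, n_panel_genes = 20,
#'   subtypes = list(sp = c(A = 10, B = 10)), n_informative = 20, seed = 7))
#' dim(sc$counts)
#' @export
simulate_cohort <- function(config) {
  .check(inherits(config, "sim_config"),
         "simulate_cohort: config must come from sim_config()")
  set.seed(config$seed)
  cfg <- config
  n_marker <- if (is.null(cfg$receptor)) 0L else 3L

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  panel_idx <- seq_len(cfg$n_panel_genes)
  genes[panel_idx] <- sprintf("PNL%03d", panel_idx)
  if (n_marker > 0L) {
    mk <- cfg$receptor$markers[c("ER", "PR", "HER2")]
    genes[(cfg$n_genes - 2L):cfg$n_genes] <- unname(mk)
  }

  # Sample table ---------------------------------------------------------
  meta <- do.call(rbind, lapply(names(cfg$subtypes), function(sp) {
    st <- cfg$subtypes[[sp]]
    data.frame(species = sp,
               subtype = rep(names(st), times = st),
               stringsAsFactors = FALSE)
  }))
  meta$sample <- sprintf("%s_%03d", meta$species,
                         stats::ave(seq_len(nrow(meta)), meta$species,
                                    FUN = seq_along))
  meta <- meta[, c("sample", "species", "subtype")]
  n <- nrow(meta)

  # Batches: default one per species.
  meta$batch <- meta$species
  if (!is.null(cfg$batches)) {
    meta$batch <- unlist(lapply(names(cfg$subtypes), function(sp) {
      b <- cfg$batches[[sp]]
      rep(paste0(sp, ".", names(b)), times = b)
    }))
  }

  # Profiles: species-private except the shared homologous pair ----------
  profile_of <- character(0)
  for (sp in names(cfg$subtypes)) for (st in names(cfg$subtypes[[sp]])) {
    key <- if (!is.null(cfg$homologous_pair) &&
               identical(unname(cfg$homologous_pair[[sp]]), st)) "shared"
           else paste(sp, st, sep = ":")
    profile_of[paste(sp, st, sep = ":")] <- key
  }
  profiles <- unique(profile_of)

  # Panel slices (contiguous, near-equal) over profiles and shared
  # programs, plus private informative genes for each axis.
  axes <- c(profiles, names(cfg$programs))
  w <- setNames(rep(1, length(axes)), axes)
  if (!is.null(cfg$axis_weights)) {
    known <- intersect(names(cfg$axis_weights), axes)
    w[known] <- cfg$axis_weights[known]
  }
  sizes <- pmax(1L, round(cfg$n_panel_genes * w / sum(w)))
  while (sum(sizes) > cfg$n_panel_genes)
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < cfg$n_panel_genes)
    sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  panel_slices <- split(genes[panel_idx], rep(axes, times = sizes))
  free <- setdiff(seq_len(cfg$n_genes - n_marker), panel_idx)
  informative <- list()
  for (ax in axes) {
    pick <- sample(free, cfg$n_informative)
    informative[[ax]] <- genes[pick]
    free <- setdiff(free, pick)
  }
  axis_genes <- lapply(setNames(axes, axes), function(ax)
    c(panel_slices[[ax]], informative[[ax]]))
  # Per (species:subtype) key, the full up-shifted gene set: the profile's
  # own genes plus the genes of every program the subtype belongs to.
  signal_genes <- lapply(setNames(names(profile_of), names(profile_of)),
                         function(key) {
    st <- sub("^[^:]*:", "", key)
    progs <- names(cfg$programs)[vapply(cfg$programs, function(g)
      st %in% g, logical(1L))]
    unique(unlist(axis_genes[c(profile_of[[key]], progs)]))
  })

  # Log2 mean surface -----------------------------------------------------
  lengths_bp <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                            cfg$gene_length_range[2]))
  names(lengths_bp) <- genes
  b <- rnorm(cfg$n_genes, mean = 3, sd = 1.5)
  # Panel genes model a curated classifier panel: robustly expressed, so
  # their subtype shifts are not flattened by the log transform.
  b[panel_idx] <- rnorm(cfg$n_panel_genes, mean = cfg$panel_log2_mean,
                        sd = cfg$panel_log2_sd)
  # Recentre so expected FPKM of a gene with log2-mean b is ~2^b.
  b <- b + log2(1e9 / sum(2^b * lengths_bp))
  mu_log2 <- matrix(b, cfg$n_genes, n, dimnames = list(genes, meta$sample))

  repressed_genes <- lapply(setNames(names(profile_of), names(profile_of)),
                            function(key) {
    st <- sub("^[^:]*:", "", key)
    ax <- intersect(cfg$repressed[[st]] %||% character(0), axes)
    unique(unlist(axis_genes[ax]))
  })
  for (i in seq_len(n)) {
    key <- paste(meta$species[i], meta$subtype[i], sep = ":")
    mu_log2[signal_genes[[key]], i] <- mu_log2[signal_genes[[key]], i] +
      cfg$effect_size
    rg <- repressed_genes[[key]]
    if (length(rg))
      mu_log2[rg, i] <- mu_log2[rg, i] - cfg$effect_size
  }

  # Species / batch location-scale effects on the log scale --------------
  noise_scale <- rep(1, n)
  sp_names <- names(cfg$subtypes)
  if (length(sp_names) > 1L) for (sp in sp_names[-1L]) {
    gamma <- rnorm(cfg$n_genes, cfg$species_shift, 0.3)
    sel <- meta$species == sp
    mu_log2[, sel] <- mu_log2[, sel] + gamma
    noise_scale[sel] <- noise_scale[sel] * cfg$species_scale
  }
  if (!is.null(cfg$batches)) for (sp in sp_names) {
    bn <- paste0(sp, ".", names(cfg$batches[[sp]]))
    if (length(bn) > 1L) for (bb in bn[-1L]) {
      gamma <- rnorm(cfg$n_genes, cfg$batch_shift, 0.3)
      sel <- meta$batch == bb
      mu_log2[, sel] <- mu_log2[, sel] + gamma
      noise_scale[sel] <- noise_scale[sel] * cfg$batch_scale
    }
  }

  # Biological log-noise, scaled per batch/species (the "scale" effect).
  eps <- matrix(rnorm(cfg$n_genes * n, 0, cfg$bio_sd), cfg$n_genes, n)
  mu_log2 <- mu_log2 + sweep(eps, 2L, noise_scale, "*")

  # Receptor markers override the baseline means --------------------------
  receptor_truth <- NULL
  if (n_marker > 0L) {
    rc <- cfg$receptor
    props <- lapply(seq_len(nrow(meta)), function(i) {
      p <- rc$subgroup_props[[meta$subtype[i]]]
      if (is.null(p)) setNames(rep(0.25, 4L), .subgroups)
      else p[.subgroups] / sum(p[.subgroups])
    })
    subgroup <- vapply(props, function(p)
      sample(.subgroups, 1L, prob = p), character(1L))
    er <- ifelse(grepl("^ER\\+", subgroup), "pos", "neg")
    pr <- ifelse(grepl("PR\\+$", subgroup), "pos", "neg")
    her2 <- ifelse(runif(n) < rc$p_her2, "enriched", "not_enriched")
    fpkm_target <- rbind(
      ifelse(er == "pos", rc$fpkm_pos, rc$fpkm_neg),
      ifelse(pr == "pos", rc$fpkm_pos, rc$fpkm_neg),
      ifelse(her2 == "enriched", rc$her2_enriched_fpkm, rc$her2_not_fpkm))
    jitter <- matrix(rnorm(3L * n, 0, 0.4), 3L, n)
    mu_log2[(cfg$n_genes - 2L):cfg$n_genes, ] <- log2(fpkm_target) + jitter
    meta$subgroup <- subgroup
    meta$ER <- er; meta$PR <- pr; meta$HER2 <- her2
    receptor_truth <- data.frame(sample = meta$sample, subgroup = subgroup,
                                 ER = er, PR = pr, HER2 = her2,
                                 stringsAsFactors = FALSE)
  }

  # Counts: NB around length- and library-scaled means --------------------
  lib <- runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
  mu_counts <- sweep(2^mu_log2 * lengths_bp / 1e9, 2L, lib, "*")
  counts <- matrix(
    rnbinom(length(mu_counts), mu = mu_counts, size = 1 / cfg$nb_dispersion),
    cfg$n_genes, n, dimnames = dimnames(mu_counts))

  truth <- list(
    subtype = setNames(meta$subtype, meta$sample),
    profile = setNames(unname(profile_of[paste(meta$species, meta$subtype,
                                               sep = ":")]), meta$sample),
    informative_genes = signal_genes,
    homologous_pair = cfg$homologous_pair,
    panel_genes = genes[panel_idx],
    receptor_truth = receptor_truth)

  structure(list(counts = counts, gene_lengths = lengths_bp, meta = meta,
                 truth = truth, config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated expression cohort\n")
  cat(sprintf("  %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  for (sp in names(x$config$subtypes)) {
    st <- x$config$subtypes[[sp]]
    cat(sprintf("  %s: %s\n", sp,
                paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  }
  if (!is.null(x$config$homologous_pair))
    cat("  homologous pair:",
        paste(names(x$config$homologous_pair),
              x$config$homologous_pair, sep = ":", collapse = " ~ "), "\n")
  invisible(x)
}

#' Convert raw counts to FPKM
#'
#' FPKM\[g,s\] = counts\[g,s\] * 1e9 / (length\[g\] * total_counts\[s\]).
#'
#' @param counts gene-by-sample count matrix.
#' @param lengths per-gene lengths in bp (recycled by name when named).
#' @return FPKM matrix of the same dimensions.
#' @export
counts_to_fpkm <- function(counts, lengths) {
  .check_matrix(counts, "counts")
  if (!is.null(names(lengths))) {
    .check(all(rownames(counts) %in% names(lengths)),
           "counts_to_fpkm: lengths missing for some genes")
    lengths <- lengths[rownames(counts)]
  }
  .check(length(lengths) == nrow(counts),
         "counts_to_fpkm: one length per gene required")
  .check(all(lengths > 0), "counts_to_fpkm: lengths must be positive")
  totals <- colSums(counts)
  bad <- totals <= 0
  if (any(bad))
    stop("counts_to_fpkm: zero total counts in sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  sweep(counts / lengths, 2L, totals, "/") * 1e9
}

#' Convert FPKM to TPM
#'
#' TPM\[g,s\] = FPKM\[g,s\] / sum_g FPKM\[g,s\] * 1e6; every column of the
#' result sums to 1e6.
#'
#' @param fpkm gene-by-sample FPKM matrix.
#' @return TPM matrix of the same dimensions.
#' @export
fpkm_to_tpm <- function(fpkm) {
  .check_matrix(fpkm, "fpkm")
  cs <- colSums(fpkm)
  bad <- cs <= 0
  if (any(bad))
    stop("fpkm_to_tpm: all-zero column(s): ",
         paste(colnames(fpkm)[bad], collapse = ", "), call. = FALSE)
  sweep(fpkm, 2L, cs, "/") * 1e6
}

#' log2(TPM + 1) expression from a simulated cohort
#'
#' Convenience chain counts -> FPKM -> TPM -> log2(TPM + 1).
#'
#' @param cohort a `sim_cohort`.
#' @return gene-by-sample matrix of log2(TPM + 1) values.
#' @export
cohort_log2tpm <- function(cohort) {
  .check(inherits(cohort, "sim_cohort"), "cohort must be a sim_cohort")
  log2(fpkm_to_tpm(counts_to_fpkm(cohort$counts, cohort$gene_lengths)) + 1)
}
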