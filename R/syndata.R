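#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generator and checks the
#' invariants. Defaults emulate one tissue of the motivating experimental
#' design: three TMT 10-plex runs, each with one pooled-reference channel;
#' six groups (WT/KO/RE genotype x AL/TRF feeding) with n = 4 biological
#' replicates; a planted fraction of clock-dependent proteins of which a
#' sub-fraction is rescued in the RE genotype; feeding effects concentrated
#' in the RE genotype; and 6-timepoint diurnal transcriptomes (ZT0-20,
#' 3 replicates per timepoint per genotype).
#'
#' @param n_proteins number of proteins simulated.
#' @param n_genes number of genes in the transcriptome layer.
#' @param n_per_group biological replicates per (genotype, feeding) group.
#' @param genotypes,feedings group label vocabularies. The second genotype is
#'   treated as the knockout and the third (when present) as the rescue.
#' @param n_plexes,channels_per_plex TMT layout; one channel per plex is the
#'   pooled reference.
#' @param frac_dependent fraction of proteins with a planted knockout effect.
#' @param frac_rescued_given_dependent fraction of dependent proteins whose
#'   rescue genotype is restored to WT level.
#' @param frac_feeding_responsive named vector, per-genotype fraction of
#'   proteins shifted by TRF within that genotype.
#' @param effect_log2 magnitude (log2 units) of planted genotype and feeding
#'   effects; sign is drawn +/-1 with equal probability.
#' @param sigma residual SD in log2 units (within-group noise).
#' @param plex_sd SD of the per-plex batch shift (log2 units).
#' @param frac_flagged fraction of proteins flagged contaminant, decoy or
#'   single-oxidized (split evenly) to exercise filtering.
#' @param frac_secreted baseline fraction of secreted proteins.
#' @param secreted_enrichment odds multiplier for the secreted flag among
#'   dependent proteins.
#' @param frac_rhythmic fraction of genes rhythmic in WT.
#' @param amp_range length-2 interval from which rhythmic amplitudes are drawn.
#' @param frac_rhythm_lost_in_ko fraction of WT-rhythmic genes whose rhythm is
#'   absent in the knockout.
#' @param frac_mean_shift fraction of genes with a WT/KO mesor difference.
#' @param mean_shift_log2 magnitude of the planted mesor difference.
#' @param frac_mapped fraction of proteins with a matching transcriptome gene.
#' @param frac_concordant probability that the gene of a dependent protein
#'   carries an mRNA mean shift (protein/mRNA concordance).
#' @param timepoints ZT sampling times (hours, in `[0, 24)`).
#' @param reps_per_time transcriptome replicates per timepoint per genotype.
#' @param outlier_sample if `TRUE`, one KO-TRF sample is corrupted by a large
#'   uniform per-protein shift so that outlier flagging can be exercised.
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_proteins = 5000,
                       n_genes = 2000,
                       n_per_group = 4,
                       genotypes = c("WT", "KO", "RE"),
                       feedings = c("AL", "TRF"),
                       n_plexes = 3,
                       channels_per_plex = 10,
                       frac_dependent = 0.12,
                       frac_rescued_given_dependent = 0.5,
                       frac_feeding_responsive = c(WT = 0, KO = 0, RE = 0.09),
                       effect_log2 = 1,
                       sigma = 0.25,
                       plex_sd = 0.3,
                       frac_flagged = 0.02,
                       frac_secreted = 0.1,
                       secreted_enrichment = 4,
                       frac_rhythmic = 0.3,
                       amp_range = c(0.5, 2),
                       frac_rhythm_lost_in_ko = 0.8,
                       frac_mean_shift = 0.2,
                       mean_shift_log2 = 1,
                       frac_mapped = 0.8,
                       frac_concordant = 0.55,
                       timepoints = c(0, 4, 8, 12, 16, 20),
                       reps_per_time = 3,
                       outlier_sample = FALSE,
                       seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins), n_genes = as.integer(n_genes),
            n_per_group = as.integer(n_per_group), genotypes = genotypes,
            feedings = feedings, n_plexes = as.integer(n_plexes),
            channels_per_plex = as.integer(channels_per_plex),
            frac_dependent = frac_dependent,
            frac_rescued_given_dependent = frac_rescued_given_dependent,
            frac_feeding_responsive = frac_feeding_responsive,
            effect_log2 = effect_log2, sigma = sigma, plex_sd = plex_sd,
            frac_flagged = frac_flagged, frac_secreted = frac_secreted,
            secreted_enrichment = secreted_enrichment,
            frac_rhythmic = frac_rhythmic, amp_range = amp_range,
            frac_rhythm_lost_in_ko = frac_rhythm_lost_in_ko,
            frac_mean_shift = frac_mean_shift,
            mean_shift_log2 = mean_shift_log2, frac_mapped = frac_mapped,
            frac_concordant = frac_concordant, timepoints = timepoints,
            reps_per_time = as.integer(reps_per_time),
            outlier_sample = isTRUE(outlier_sample), seed = as.integer(seed))
  props <- c(p$frac_dependent, p$frac_rescued_given_dependent,
             p$frac_feeding_responsive, p$frac_flagged, p$frac_secreted,
             p$frac_rhythmic, p$frac_rhythm_lost_in_ko, p$frac_mean_shift,
             p$frac_mapped, p$frac_concordant)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1))
    stop("all proportion parameters must be finite and in [0, 1]")
  num <- c(p$effect_log2, p$sigma, p$plex_sd, p$secreted_enrichment,
           p$mean_shift_log2, p$amp_range)
  if (any(!is.finite(num)))
    stop("non-finite numeric parameter")
  if (p$effect_log2 <= 0) stop("`effect_log2` must be > 0")
  if (p$sigma < 0) stop("`sigma` must be >= 0")
  if (any(p$timepoints < 0) || any(p$timepoints >= 24))
    stop("`timepoints` must lie in [0, 24)")
  if (is.null(names(p$frac_feeding_responsive)))
    stop("`frac_feeding_responsive` must be named by genotype")
  if (!all(names(p$frac_feeding_responsive) %in% p$genotypes))
    stop("`frac_feeding_responsive` names must be genotypes")
  class(p) <- "sim_params"
  p
}

#' Generate a TMT sample design
#'
#' Assigns every (genotype, feeding, replicate) sample to a plex and channel,
#' reserving channel 1 of each plex for the pooled reference. Samples are
#' spread across plexes round-robin after a seeded shuffle, so the assignment
#' is deterministic given the seed.
#'
#' @param params a [sim_params()] object.
#' @param tissue tissue label recorded in the design.
#' @return a `data.frame` design (see [validate_design()]).
#' @export
generate_design <- function(params, tissue = "liver") {
  stopifnot(inherits(params, "sim_params"))
  groups <- expand.grid(feeding = params$feedings, genotype = params$genotypes,
                        stringsAsFactors = FALSE)[, c("genotype", "feeding")]
  n_samples <- nrow(groups) * params$n_per_group
  capacity <- params$n_plexes * (params$channels_per_plex - 1L)
  if (n_samples > capacity)
    stop(sprintf(
      "design capacity exceeded: %d samples but only %d free channels (%d plexes x %d non-reference channels)",
      n_samples, capacity, params$n_plexes, params$channels_per_plex - 1L))
  samples <- data.frame(
    genotype = rep(groups$genotype, each = params$n_per_group),
    feeding = rep(groups$feeding, each = params$n_per_group),
    replicate = rep(seq_len(params$n_per_group), nrow(groups)),
    stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype, samples$feeding,
                            samples$replicate)
  set.seed(params$seed)
  ord <- sample.int(n_samples)
  samples <- samples[ord, , drop = FALSE]
  samples$plex <- sprintf("plex%d", rep_len(seq_len(params$n_plexes),
                                            n_samples))
  # channel 1 of each plex is the reference; fill the rest in order
  ch <- integer(n_samples)
  for (px in unique(samples$plex)) {
    idx <- which(samples$plex == px)
    ch[idx] <- seq_along(idx) + 1L
  }
  samples$channel <- sprintf("ch%02d", ch)
  samples$is_reference <- FALSE
  refs <- data.frame(genotype = "REF", feeding = "REF", replicate = 0L,
                     sample = sprintf("ref_plex%d", seq_len(params$n_plexes)),
                     plex = sprintf("plex%d", seq_len(params$n_plexes)),
                     channel = "ch01", is_reference = TRUE,
                     stringsAsFactors = FALSE)
  out <- rbind(samples, refs)
  out$tissue <- tissue
  out <- out[order(out$plex, out$channel),
             c("sample", "tissue", "genotype", "feeding", "plex", "channel",
               "is_reference", "replicate")]
  rownames(out) <- NULL
  validate_design(out, genotypes = params$genotypes,
                  feedings = params$feedings)
  out
}

# Ground-truth flag draws for the proteome layer; order of draws is fixed so
# results are reproducible from the single seed.
.draw_protein_truth <- function(params) {
  n <- params$n_proteins
  dependent <- stats::runif(n) < params$frac_dependent
  direction <- ifelse(stats::runif(n) < 0.5, 1L, -1L)
  direction[!dependent] <- 0L
  rescued <- dependent &
    (stats::runif(n) < params$frac_rescued_given_dependent)
  feed <- matrix(FALSE, n, length(params$genotypes),
                 dimnames = list(NULL, params$genotypes))
  feed_dir <- matrix(0L, n, length(params$genotypes),
                     dimnames = list(NULL, params$genotypes))
  for (g in params$genotypes) {
    fr <- params$frac_feeding_responsive[g]
    if (is.na(fr)) fr <- 0
    feed[, g] <- stats::runif(n) < fr
    feed_dir[, g] <- ifelse(stats::runif(n) < 0.5, 1L, -1L) * feed[, g]
  }
  # secreted flag with enriched odds among dependent proteins
  base_odds <- params$frac_secreted / (1 - params$frac_secreted)
  dep_odds <- base_odds * params$secreted_enrichment
  p_sec <- ifelse(dependent, dep_odds / (1 + dep_odds),
                  params$frac_secreted)
  secreted <- stats::runif(n) < p_sec
  # filter-exercise flags, split evenly over the three categories
  flag_kind <- rep(0L, n)
  flagged <- stats::runif(n) < params$frac_flagged
  flag_kind[flagged] <- sample.int(3L, sum(flagged), replace = TRUE)
  list(dependent = dependent, direction = direction, rescued = rescued,
       feed = feed, feed_dir = feed_dir, secreted = secreted,
       flag_kind = flag_kind)
}

#' Simulate a multi-plex TMT proteome with planted ground truth
#'
#' Intensities are built on the log2 scale as
#' `base + genotype/feeding effect + plex batch + N(0, sigma)` and then
#' exponentiated; base abundance is drawn `N(20, 2)` log2 units. The pooled
#' reference channel carries the grand mean of all samples' noiseless log2
#' values plus its plex's batch factor (one pool mixed from every sample and
#' aliquoted into each plex), so reference normalization is exactly
#' invertible in the noiseless limit and cancels batch effects.
#' Dependent proteins shift the knockout genotype (and the rescue genotype
#' when not rescued) by `+/- effect_log2` relative to WT; rescued proteins
#' shift only the knockout; feeding-responsive proteins shift TRF vs AL
#' within the flagged genotype.
#'
#' @param design a design from [generate_design()].
#' @param params the [sim_params()] used to build the design.
#' @return a list with elements `matrix` (raw-scale [abundance_matrix()])
#'   and `truth` (a `data.frame` of planted per-protein labels).
#' @export
simulate_proteome <- function(design, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_design(design, params$genotypes, params$feedings)
  n <- params$n_proteins
  set.seed(params$seed + 1L)
  base <- stats::rnorm(n, mean = 20, sd = 2)
  truth <- .draw_protein_truth(params)
  ko <- params$genotypes[2]
  re <- if (length(params$genotypes) >= 3) params$genotypes[3] else NA
  nonref <- design[!design$is_reference, ]
  # noiseless per-sample log2 means (before batch)
  mu <- matrix(base, n, nrow(nonref))
  colnames(mu) <- nonref$sample
  for (j in seq_len(nrow(nonref))) {
    g <- nonref$genotype[j]; f <- nonref$feeding[j]
    eff <- numeric(n)
    if (g == ko) eff <- eff + truth$direction * params$effect_log2
    if (!is.na(re) && g == re)
      eff <- eff + ifelse(truth$rescued, 0, truth$direction) *
        params$effect_log2
    if (f == params$feedings[2] && g %in% colnames(truth$feed))
      eff <- eff + truth$feed_dir[, g] * params$effect_log2
    mu[, j] <- mu[, j] + eff
  }
  plexes <- sort(unique(design$plex))
  batch <- stats::rnorm(length(plexes), 0, params$plex_sd)
  names(batch) <- plexes
  ids <- sprintf("P%05d", seq_len(n))
  all_samples <- design$sample
  vals <- matrix(NA_real_, n, length(all_samples),
                 dimnames = list(ids, all_samples))
  # The pooled reference emulates one pool mixed from every sample of the
  # tissue and aliquoted into each plex: its protein content is the grand
  # mean of the noiseless sample values, and each aliquot picks up its own
  # plex's batch factor (so the ratio to it cancels the batch exactly).
  pool <- rowMeans(mu)
  for (px in plexes) {
    members <- nonref$sample[nonref$plex == px]
    mu_px <- mu[, members, drop = FALSE] + batch[px]
    noise <- matrix(stats::rnorm(n * length(members), 0, params$sigma),
                    n, length(members))
    vals[, members] <- mu_px + noise
    refname <- design$sample[design$is_reference & design$plex == px]
    vals[, refname] <- pool + batch[px]
  }
  if (params$outlier_sample) {
    cand <- nonref$sample[nonref$genotype == ko &
                            nonref$feeding == params$feedings[2]]
    victim <- sort(cand)[1]
    vals[, victim] <- vals[, victim] + stats::runif(n, 2, 5) *
      sign(stats::runif(n) - 0.5)
  }
  gene_ids <- character(n)
  n_mapped <- round(params$frac_mapped * n)
  gene_ids[seq_len(n_mapped)] <- sprintf("G%05d",
                                         seq_len(n_mapped) %% params$n_genes + 1L)
  if (n_mapped < n)
    gene_ids[(n_mapped + 1L):n] <- sprintf("UNMAPPED%05d",
                                           seq.int(n_mapped + 1L, n))
  features <- data.frame(
    protein_id = ids, gene = gene_ids,
    n_peptides = pmax(1L, stats::rpois(n, 6)),
    flag_contaminant = truth$flag_kind == 1L,
    flag_decoy = truth$flag_kind == 2L,
    flag_single_oxidized = truth$flag_kind == 3L,
    secreted = truth$secreted,
    stringsAsFactors = FALSE)
  truth_df <- data.frame(
    protein_id = ids, gene = gene_ids,
    dependent = truth$dependent, direction = truth$direction,
    rescued = truth$rescued, secreted = truth$secreted,
    stringsAsFactors = FALSE)
  for (g in params$genotypes)
    truth_df[[paste0("feeding_responsive_", g)]] <- truth$feed[, g]
  am <- abundance_matrix(2^vals, features, scale = "raw")
  list(matrix = am, truth = truth_df)
}

#' Simulate a diurnal two-genotype transcriptome
#'
#' Rhythmic genes follow `mesor + A * cos(2*pi*(t - phase)/24) + N(0, sigma)`
#' in WT; a configurable subset loses the rhythm in the knockout. Mean-shift
#' genes differ in mesor between WT and KO by `+/- mean_shift_log2`. When a
#' proteome `truth` table is supplied, genes mapped to dependent proteins are
#' given an mRNA mean shift with probability `frac_concordant` so that
#' proteome/transcriptome concordance has a planted value.
#'
#' @param params a [sim_params()] object.
#' @param protein_truth optional `truth` table from [simulate_proteome()],
#'   used to couple mRNA mean shifts to dependent proteins.
#' @return a list with `expression` (long `data.frame`: gene, genotype, zt,
#'   rep, value) and `truth` (per-gene planted labels).
#' @export
simulate_transcriptome <- function(params, protein_truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (length(unique(params$timepoints)) < 4)
    stop("at least 4 distinct timepoints are required to identify a cosinor")
  n <- params$n_genes
  set.seed(params$seed + 2L)
  genes <- sprintf("G%05d", seq_len(n))
  mesor <- stats::rnorm(n, 8, 1.5)
  rhythmic <- stats::runif(n) < params$frac_rhythmic
  amp <- ifelse(rhythmic,
                stats::runif(n, params$amp_range[1], params$amp_range[2]), 0)
  phase <- ifelse(rhythmic, stats::runif(n, 0, 24), NA_real_)
  lost_in_ko <- rhythmic & (stats::runif(n) < params$frac_rhythm_lost_in_ko)
  mean_shift <- stats::runif(n) < params$frac_mean_shift
  if (!is.null(protein_truth)) {
    dep_genes <- unique(protein_truth$gene[protein_truth$dependent &
                                             protein_truth$gene %in% genes])
    hit <- genes %in% dep_genes
    mean_shift[hit] <- stats::runif(sum(hit)) < params$frac_concordant
  }
  shift <- ifelse(mean_shift,
                  ifelse(stats::runif(n) < 0.5, 1, -1) * params$mean_shift_log2,
                  0)
  genotypes <- params$genotypes[1:2]   # transcriptomes are WT vs KO
  grid <- expand.grid(rep = seq_len(params$reps_per_time),
                      zt = params$timepoints, genotype = genotypes,
                      stringsAsFactors = FALSE)
  m <- nrow(grid)
  ko <- genotypes[2]
  vals <- matrix(0, n, m)
  for (j in seq_len(m)) {
    t <- grid$zt[j]
    rhythm_here <- if (grid$genotype[j] == ko) rhythmic & !lost_in_ko
                   else rhythmic
    mu <- mesor +
      ifelse(rhythm_here, amp * cos(2 * pi * (t - ifelse(is.na(phase), 0,
                                                         phase)) / 24), 0) +
      (if (grid$genotype[j] == ko) shift else 0)
    vals[, j] <- mu + stats::rnorm(n, 0, params$sigma)
  }
  expression <- data.frame(
    gene = rep(genes, m),
    genotype = rep(grid$genotype, each = n),
    zt = rep(grid$zt, each = n),
    rep = rep(grid$rep, each = n),
    value = as.vector(vals),
    stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, rhythmic = rhythmic, amplitude = amp,
                      phase = phase, rhythm_lost_in_ko = lost_in_ko,
                      mean_shift = shift, stringsAsFactors = FALSE)
  list(expression = expression, truth = truth)
}
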