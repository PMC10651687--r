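# Shared fixtures: everything is generated in code, no stored data.

# Small simulation for fast end-to-end tests.
small_params <- function(...) {
  args <- list(n_proteins = 200, n_genes = 100, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

# Minimal hand-built design: `groups` is a named list mapping
# "GENOTYPE_FEEDING" to replicate counts; everything goes in one plex with a
# reference channel unless n_plexes > 1 (then samples are split round-robin).
toy_design <- function(groups, n_plexes = 1) {
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    parts <- strsplit(g, "_")[[1]]
    data.frame(genotype = parts[1], feeding = parts[2],
               replicate = seq_len(groups[[g]]),
               sample = sprintf("%s_r%d", g, seq_len(groups[[g]])),
               stringsAsFactors = FALSE)
  }))
  rows$plex <- sprintf("plex%d", rep_len(seq_len(n_plexes), nrow(rows)))
  ch <- integer(nrow(rows))
  for (px in unique(rows$plex)) {
    i <- which(rows$plex == px)
    ch[i] <- seq_along(i) + 1L
  }
  rows$channel <- sprintf("ch%02d", ch)
  rows$is_reference <- FALSE
  refs <- data.frame(genotype = "REF", feeding = "REF", replicate = 0L,
                     sample = sprintf("ref_plex%d", seq_len(n_plexes)),
                     plex = sprintf("plex%d", seq_len(n_plexes)),
                     channel = "ch01", is_reference = TRUE,
                     stringsAsFactors = FALSE)
  out <- rbind(rows, refs)
  out$tissue <- "liver"
  out[c("sample", "tissue", "genotype", "feeding", "plex", "channel",
        "is_reference", "replicate")]
}

# Wrap a numeric matrix as a log2-normalized abundance matrix.
norm_matrix <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  abundance_matrix(values, scale = "log2_normalized")
}

# Simulate, filter and normalize in one go; returns list(am, design, truth).
normalized_sim <- function(params) {
  design <- generate_design(params)
  sim <- simulate_proteome(design, params)
  am <- suppressMessages(filter_features(sim$matrix))
  norm <- reference_normalize(am, design)
  truth <- sim$truth[match(rownames(norm$values), sim$truth$protein_id), ]
  list(am = norm, design = design, truth = truth)
}

# Two-sided power of the pooled t-test at per-test level `cut` -- the
# closed-form noncentral-t oracle used to bound recall expectations.
pooled_t_power <- function(cut, effect, sigma, n) {
  df <- 2 * n - 2
  ncp <- effect / (sigma * sqrt(2 / n))
  crit <- stats::qt(1 - cut / 2, df)
  stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp, lower.tail = FALSE)
}

# samples of one "GENOTYPE_FEEDING" group, via the package-internal resolver
group_samples <- function(design, spec) clockprot:::.group_samples(design, spec)

# O(m^2) Benjamini-Hochberg step-up oracle, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}

# Long-format cosinor observations for two groups with chosen parameters.
cosinor_data <- function(mesor = c(KO = 8, WT = 8), amp = c(KO = 0, WT = 0),
                         phase = c(KO = 0, WT = 0), sigma = 0,
                         timepoints = c(0, 4, 8, 12, 16, 20), reps = 3) {
  grid <- expand.grid(rep = seq_len(reps), zt = timepoints,
                      genotype = names(mesor), stringsAsFactors = FALSE)
  mu <- mesor[grid$genotype] + amp[grid$genotype] *
    cos(2 * pi * (grid$zt - phase[grid$genotype]) / 24)
  grid$value <- mu + stats::rnorm(nrow(grid), 0, sigma)
  grid
}
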