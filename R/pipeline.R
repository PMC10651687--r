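#' Run the full classification pipeline
#'
#' Executes simulate/load -> filter -> normalize -> QC -> differential
#' abundance -> classification (-> rhythmicity -> concordance when expression
#' data are available -> overrepresentation when gene sets are supplied) and
#' writes one TSV per stage plus a single JSON summary of counts,
#' percentages, thresholds and the seed. Rerunning the same configuration
#' produces byte-identical outputs.
#'
#' @param config a list, or path to a JSON file with the same structure.
#'   Recognized elements: `simulate` (list of [sim_params()] overrides;
#'   presence triggers simulation), `abundance`/`design`/`expression` (input
#'   TSV paths used when not simulating), `gmt` (gene-set file),
#'   `secreted_list` (one id per line), `alpha` (default 0.05),
#'   `alpha_relaxed` (0.1), `rescue_mode` (`"dichotomy"`), `k_outlier` (3),
#'   `drop_outliers` (`FALSE`), `window` (c(14, 22)), `bicw_threshold`
#'   (0.4), `reference_group` (`"WT"`), `seed`.
#' @param out output directory (created if needed).
#' @param seed overrides `config$seed` when not `NULL`.
#' @return the summary list, invisibly; all artifacts are on disk under
#'   `out`.
#' @export
run_pipeline <- function(config, out, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(name, default) if (!is.null(config[[name]]))
    config[[name]] else default
  alpha <- cfg("alpha", 0.05)
  alpha_relaxed <- cfg("alpha_relaxed", 0.1)
  rescue_mode <- cfg("rescue_mode", "dichotomy")
  k_outlier <- cfg("k_outlier", 3)
  drop_outliers <- isTRUE(cfg("drop_outliers", FALSE))
  window <- as.numeric(cfg("window", c(14, 22)))
  bicw_threshold <- cfg("bicw_threshold", 0.4)
  reference_group <- cfg("reference_group", "WT")
  if (is.null(seed)) seed <- cfg("seed", 1L)
  seed <- as.integer(seed)

  stage <- function(name, expr) {
    message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  expression <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- seed
      params <- do.call(sim_params, args)
      design <- generate_design(params)
      prot <- simulate_proteome(design, params)
      trans <- simulate_transcriptome(params, protein_truth = prot$truth)
      write_design(design, file.path(out, "design.tsv"))
      write_abundance(prot$matrix, file.path(out, "abundance_raw.tsv"))
      write_expression(trans$expression, file.path(out, "expression.tsv"))
      .write_tsv(prot$truth, file.path(out, "truth_proteome.tsv"))
      .write_tsv(trans$truth, file.path(out, "truth_transcriptome.tsv"))
      list(design = design, am = prot$matrix,
           expression = trans$expression,
           truth = prot$truth)
    })
    design <- sim$design; am <- sim$am
    expression <- sim$expression; truth <- sim$truth
  } else {
    design <- stage("load", read_design(config$design))
    am <- stage("load", read_abundance(config$abundance, design))
    if (!is.null(config$expression))
      expression <- stage("load", read_expression(config$expression))
  }

  n_raw <- nrow(am$values)
  am <- stage("filter", filter_features(am))
  norm <- stage("normalize", reference_normalize(am, design))
  write_abundance(norm, file.path(out, "abundance_norm.tsv"))

  qc <- stage("qc", {
    pc <- abundance_pca(norm)
    flags <- flag_outliers(pc, design, k = k_outlier)
    qcdf <- data.frame(sample = rownames(pc$scores),
                       pc1 = pc$scores[, 1], pc2 = pc$scores[, 2],
                       dist = attr(flags, "distances")[rownames(pc$scores)],
                       outlier = rownames(pc$scores) %in% flags,
                       stringsAsFactors = FALSE)
    .write_tsv(qcdf, file.path(out, "qc_pca.tsv"))
    list(flags = as.character(flags),
         explained = pc$explained[1:min(5, length(pc$explained))])
  })
  exclude <- if (drop_outliers) qc$flags else character(0)

  genos <- unique(design$genotype[!design$is_reference])
  wt <- genos[1]; ko <- genos[2]
  re <- if (length(genos) >= 3) genos[3] else NA
  feeds <- sort(unique(design$feeding[!design$is_reference]))
  al <- feeds[1]

  contrasts <- stage("diff", {
    cts <- list(
      dependence = pairwise_ttest(norm, design,
                                  paste(wt, al, sep = "_"),
                                  paste(ko, al, sep = "_"),
                                  exclude = exclude))
    if (!is.na(re)) {
      cts$re_vs_ko <- pairwise_ttest(norm, design,
                                     paste(re, al, sep = "_"),
                                     paste(ko, al, sep = "_"),
                                     exclude = exclude)
      cts$wt_vs_re <- pairwise_ttest(norm, design,
                                     paste(wt, al, sep = "_"),
                                     paste(re, al, sep = "_"),
                                     exclude = exclude)
    }
    all_ct <- do.call(rbind, cts)
    .write_tsv(all_ct, file.path(out, "contrasts.tsv"))
    cts
  })

  labels <- stage("classify", {
    dep <- call_dependent(contrasts$dependence, alpha = alpha)
    if (!is.na(re))
      dep <- classify_rescue(dep, contrasts$re_vs_ko, contrasts$wt_vs_re,
                             alpha = alpha, mode = rescue_mode)
    feeding <- lapply(genos, function(g)
      call_feeding_responsive(norm, design, g, alpha = alpha,
                              alpha_relaxed = alpha_relaxed,
                              exclude = exclude))
    names(feeding) <- genos
    for (g in genos) {
      dep[[paste0("feeding_responsive_", g)]] <-
        feeding[[g]]$responsive[match(dep$feature_id,
                                      feeding[[g]]$feature_id)]
    }
    .write_tsv(dep, file.path(out, "class_labels.tsv"))
    dep
  })

  rhythm <- NULL; concord <- NULL
  if (!is.null(expression)) {
    rhythm <- stage("rhythm", {
      fits <- rhythm_analysis(expression, reference_group = reference_group,
                              bicw_threshold = bicw_threshold)
      .write_tsv(fits, file.path(out, "rhythm.tsv"))
      fits
    })
    concord <- stage("concord", {
      id_map <- data.frame(protein_id = am$features$protein_id,
                           gene = am$features$gene,
                           stringsAsFactors = FALSE)
      recs <- join_omes(labels, rhythm, id_map, window = window)
      .write_tsv(recs, file.path(out, "concordance.tsv"))
      fr <- concordance_fractions(recs)
      wg <- peak_phase_filter(rhythm, window = window)
      rl <- if (length(intersect(wg, id_map$gene)))
        reverse_lookup(wg, labels$feature_id[labels$dependent], id_map)
      else NULL
      list(fractions = fr, reverse = rl,
           n_unmapped = attr(recs, "n_unmapped"))
    })
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- stage("enrich", {
      sets <- read_gmt(config$gmt)
      res <- ora(labels$feature_id[labels$dependent], sets,
                 universe = labels$feature_id)
      .write_tsv(res, file.path(out, "enrichment.tsv"))
      res
    })
  }

  secreted <- NULL
  sec_ids <- if (!is.null(config$secreted_list))
    readLines(config$secreted_list)
  else if ("secreted" %in% names(am$features))
    am$features$protein_id[am$features$secreted]
  if (!is.null(sec_ids) && length(sec_ids))
    secreted <- stage("secreted", secreted_fraction_test(
      labels$feature_id[labels$dependent],
      intersect(sec_ids, labels$feature_id), labels$feature_id))

  n_det <- nrow(labels)
  summary <- list(
    software = "clockprot",
    version = as.character(utils::packageVersion("clockprot")),
    seed = seed,
    thresholds = list(alpha = alpha, alpha_relaxed = alpha_relaxed,
                      k_outlier = k_outlier,
                      bicw_threshold = bicw_threshold,
                      rescue_mode = rescue_mode, window = window),
    counts = list(
      features_raw = n_raw,
      features_detected = n_det,
      outliers_flagged = length(qc$flags),
      outliers_dropped = length(exclude),
      dependent = sum(labels$dependent),
      dependent_up = sum(labels$direction == "up", na.rm = TRUE),
      dependent_down = sum(labels$direction == "down", na.rm = TRUE)),
    pct_dependent = summarize_percent(sum(labels$dependent), n_det))
  if ("rescue" %in% names(labels)) {
    summary$counts$rescued <- sum(labels$rescue == "rescued")
    summary$counts$nonrescued <- sum(labels$rescue == "nonrescued")
    summary$counts$partial <- sum(labels$rescue == "partial")
  }
  for (g in genos) {
    cn <- paste0("feeding_responsive_", g)
    summary$counts[[cn]] <- sum(labels[[cn]], na.rm = TRUE)
  }
  if (!is.null(concord)) {
    summary$concordance <- concord$fractions
    summary$reverse_lookup <- concord$reverse
  }
  if (!is.null(secreted))
    summary$secreted <- secreted[c("pct_secreted_affected",
                                   "pct_all_affected", "odds_ratio", "p")]
  if (!is.null(enrichment))
    summary$enrichment_significant <- sum(enrichment$significant)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
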