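# Decision rules that turn pairwise contrasts into protein classes:
# clock dependence (WT vs KO under ad libitum feeding), rescue status from
# the rescue-genotype contrasts, feeding responsiveness within genotype,
# cross-tissue overlap, secreted-fraction enrichment and reporting helpers.

#' Call clock-dependent proteins from the WT vs KO contrast
#'
#' A protein is dependent iff `q < alpha` (strict). Direction is the sign of
#' the KO-vs-WT change; with `log2fc = WT - KO` this is `-sign(log2fc)`.
#' Ties at exactly `alpha` are counted as non-significant and logged.
#'
#' @param contrast a [pairwise_ttest()] result for WT vs KO (AL samples).
#' @param alpha significance threshold on q (default 0.05).
#' @return `data.frame`: `feature_id`, `dependent`, `direction`
#'   (`"up"`/`"down"` in KO vs WT, `NA` when not dependent), `q`.
#' @export
call_dependent <- function(contrast, alpha = 0.05) {
  n_tie <- sum(contrast$q == alpha)
  if (n_tie) message(sprintf(
    "call_dependent: %d feature(s) at exactly q = alpha treated as non-significant",
    n_tie))
  dep <- contrast$q < alpha
  data.frame(
    feature_id = contrast$feature_id,
    dependent = dep,
    direction = ifelse(dep, ifelse(contrast$log2fc < 0, "up", "down"),
                       NA_character_),
    q = contrast$q,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify dependent proteins as rescued or nonrescued
#'
#' A dependent protein is rescued when the rescue genotype differs from KO
#' (`q_re_ko < alpha`) but is indistinguishable from WT
#' (`q_wt_re >= alpha`). In the default dichotomy mode everything dependent
#' and not rescued is nonrescued, so rescued + nonrescued partition the
#' dependent set. The three-way mode additionally labels proteins with
#' `q_re_ko < alpha` and `q_wt_re < alpha` as `partial` (moved toward WT but
#' not reaching it).
#'
#' @param dependent a [call_dependent()] result.
#' @param contrast_re_ko [pairwise_ttest()] result, rescue genotype vs KO.
#' @param contrast_wt_re [pairwise_ttest()] result, WT vs rescue genotype.
#' @param alpha threshold on q.
#' @param mode `"dichotomy"` (default) or `"threeway"`.
#' @return `data.frame`: `feature_id`, `dependent`, `direction`, `rescue`
#'   (`rescued` / `nonrescued` / `partial` / `not_applicable`).
#' @export
classify_rescue <- function(dependent, contrast_re_ko, contrast_wt_re,
                            alpha = 0.05, mode = c("dichotomy", "threeway")) {
  mode <- match.arg(mode)
  out <- dependent
  miss <- out$feature_id[out$dependent &
                           (!out$feature_id %in% contrast_re_ko$feature_id |
                              !out$feature_id %in% contrast_wt_re$feature_id)]
  if (length(miss))
    stop("dependent feature(s) missing a rescue contrast: ",
         paste(utils::head(miss, 5), collapse = ", "))
  q_re_ko <- contrast_re_ko$q[match(out$feature_id,
                                    contrast_re_ko$feature_id)]
  q_wt_re <- contrast_wt_re$q[match(out$feature_id,
                                    contrast_wt_re$feature_id)]
  rescue <- rep("not_applicable", nrow(out))
  dep <- out$dependent
  rescued <- dep & q_re_ko < alpha & q_wt_re >= alpha
  rescue[dep] <- "nonrescued"
  rescue[rescued] <- "rescued"
  if (mode == "threeway") {
    partial <- dep & q_re_ko < alpha & q_wt_re < alpha
    rescue[partial] <- "partial"
  }
  out$rescue <- rescue
  out
}

#' Call feeding-responsive proteins within one genotype
#'
#' Responsive iff `q < alpha` for the AL vs TRF contrast within the genotype.
#' A secondary call at a relaxed threshold is reported alongside.
#'
#' @param am log2-normalized [abundance_matrix()].
#' @param design sample design; both feeding arms must be present for the
#'   genotype.
#' @param genotype genotype label.
#' @param alpha primary threshold (default 0.05).
#' @param alpha_relaxed secondary threshold (default 0.1).
#' @param exclude sample ids to drop.
#' @return `data.frame`: `feature_id`, `genotype`, `responsive`,
#'   `responsive_relaxed`, `log2fc` (AL - TRF), `q`.
#' @export
call_feeding_responsive <- function(am, design, genotype, alpha = 0.05,
                                    alpha_relaxed = 0.1,
                                    exclude = character(0)) {
  nonref <- design[!design$is_reference, ]
  feeds <- unique(nonref$feeding[nonref$genotype == genotype])
  if (length(feeds) < 2)
    stop(sprintf("genotype %s lacks one of the feeding arms", genotype))
  feeds <- sort(feeds)  # AL before TRF
  ct <- pairwise_ttest(am, design,
                       list(genotype = genotype, feeding = feeds[1]),
                       list(genotype = genotype, feeding = feeds[2]),
                       exclude = exclude)
  data.frame(feature_id = ct$feature_id, genotype = genotype,
             responsive = ct$q < alpha,
             responsive_relaxed = ct$q < alpha_relaxed,
             log2fc = ct$log2fc, q = ct$q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of dependent proteins across two tissues
#'
#' Restricted to proteins detected in both tissues.
#'
#' @param dep_a,dep_b character vectors of dependent protein ids in each
#'   tissue.
#' @param detected_both ids detected in both tissues.
#' @return list with `both`, `only_a`, `only_b` counts and the shared ids.
#' @export
cross_tissue_overlap <- function(dep_a, dep_b, detected_both) {
  a <- intersect(dep_a, detected_both)
  b <- intersect(dep_b, detected_both)
  shared <- intersect(a, b)
  list(both = length(shared),
       only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)),
       shared_ids = sort(shared))
}

#' Enrichment of affected proteins among the secreted fraction
#'
#' Builds the 2x2 (secreted x affected) table over the detection universe and
#' reports the two-sided Fisher exact p, the conditional-MLE odds ratio, and
#' the affected percentage within the secreted and total pools.
#'
#' @param affected ids of affected (e.g. clock-dependent) proteins.
#' @param secreted ids annotated as secreted; must be a subset of `universe`.
#' @param universe all detected protein ids.
#' @return list: `pct_secreted_affected`, `pct_all_affected`, `odds_ratio`,
#'   `p`, `table`.
#' @export
secreted_fraction_test <- function(affected, secreted, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(secreted, universe)))
    stop("secreted annotation must be a subset of the universe")
  affected <- intersect(affected, universe)
  is_sec <- universe %in% secreted
  is_aff <- universe %in% affected
  tab <- matrix(c(sum(is_sec & is_aff), sum(is_sec & !is_aff),
                  sum(!is_sec & is_aff), sum(!is_sec & !is_aff)),
                2, 2, byrow = TRUE,
                dimnames = list(c("secreted", "other"),
                                c("affected", "unaffected")))
  ft <- stats::fisher.test(tab)
  n_sec <- sum(is_sec)
  list(
    pct_secreted_affected = if (n_sec) summarize_percent(tab[1, 1], n_sec)
                            else NA_real_,
    pct_all_affected = summarize_percent(length(affected), length(universe)),
    odds_ratio = unname(ft$estimate),
    p = ft$p.value,
    table = tab)
}

#' Average abundance of a protein set per sample
#'
#' Arithmetic mean of normalized log2 abundances across the members of a set
#' (e.g. the mitoribosome 28S or 39S subunits), per sample.
#'
#' @param am log2-normalized [abundance_matrix()].
#' @param members protein ids; all must be present.
#' @return named numeric vector, one mean per sample.
#' @export
subunit_set_average <- function(am, members) {
  if (!length(members)) stop("empty subunit set")
  miss <- setdiff(members, rownames(am$values))
  if (length(miss))
    stop("subunit set member(s) not found: ", paste(miss, collapse = ", "))
  colMeans(am$values[members, , drop = FALSE])
}

#' Percentage with half-up rounding
#'
#' `100 * part / whole`, rounded half-up to `decimals` places (the convention
#' used for reported percentages; note base `round()` rounds half to even).
#'
#' @param part,whole counts with `0 <= part <= whole`, `whole > 0`.
#' @param decimals decimal places (default 2).
#' @return the rounded percentage.
#' @export
summarize_percent <- function(part, whole, decimals = 2) {
  if (whole <= 0) stop("`whole` must be > 0")
  if (part < 0 || part > whole) stop("need 0 <= part <= whole")
  x <- 100 * part / whole
  f <- 10^decimals
  floor(x * f + 0.5) / f
}
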