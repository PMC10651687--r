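# Proteome-transcriptome concordance: join protein classifications with
# per-gene rhythm/mean-model fits and summarize which protein changes have a
# transcriptional counterpart.

#' Join dependent proteins with transcriptome fits
#'
#' One record per mappable dependent protein. The protein-to-gene map may be
#' many-to-one; a protein id occurring more than once in the map is resolved
#' to its first gene after sorting (deterministic, logged). Unmapped
#' dependent proteins are counted and reported via the `"n_unmapped"`
#' attribute.
#'
#' The category is the 2x2 cross of the mRNA mean-change and rhythmicity
#' dichotomies: `rhythmic_source` (mean changed, rhythmic mRNA),
#' `transcriptional` (mean changed, nonrhythmic), `nonrhythmic_source`
#' (no mean change, rhythmic) and `post_transcriptional` (no mean change,
#' nonrhythmic mRNA); the four labels partition the records.
#'
#' @param labels a [call_dependent()] (optionally [classify_rescue()]) table.
#' @param fits a [rhythm_analysis()] table.
#' @param id_map `data.frame` with columns `protein_id`, `gene`.
#' @param window phase window passed to the `peaks_in_window` flag.
#' @return `data.frame` of class-annotated records: `protein_id`, `gene`,
#'   `dependent`, `mrna_mean_changed`, `mrna_rhythmic_in_wt`,
#'   `peaks_in_window`, `category`.
#' @export
join_omes <- function(labels, fits, id_map, window = c(14, 22)) {
  stopifnot(all(c("protein_id", "gene") %in% names(id_map)))
  dep <- labels[labels$dependent, , drop = FALSE]
  id_map <- id_map[order(id_map$protein_id, id_map$gene), ]
  dup <- duplicated(id_map$protein_id)
  if (any(dup)) {
    message(sprintf("join_omes: %d duplicate map entries resolved to first gene by sorted protein id",
                    sum(dup)))
    id_map <- id_map[!dup, ]
  }
  gene <- id_map$gene[match(dep$feature_id, id_map$protein_id)]
  has_fit <- gene %in% fits$gene
  n_unmapped <- sum(is.na(gene) | !has_fit)
  keep <- !is.na(gene) & has_fit
  if (!any(keep)) stop("empty join: no dependent protein maps to a fitted gene")
  message(sprintf("join_omes: %d dependent protein(s) joined, %d unmapped",
                  sum(keep), n_unmapped))
  dep <- dep[keep, , drop = FALSE]
  gene <- gene[keep]
  i <- match(gene, fits$gene)
  changed <- fits$mean_model[i] == "distinct"
  rhythmic <- fits$rhythmic_in_reference[i]
  in_window <- rhythmic & !is.na(fits$phase_ref[i]) &
    fits$phase_ref[i] >= window[1] & fits$phase_ref[i] <= window[2]
  category <- ifelse(changed,
                     ifelse(rhythmic, "rhythmic_source", "transcriptional"),
                     ifelse(rhythmic, "nonrhythmic_source",
                            "post_transcriptional"))
  out <- data.frame(protein_id = dep$feature_id, gene = gene,
                    dependent = TRUE, mrna_mean_changed = changed,
                    mrna_rhythmic_in_wt = rhythmic,
                    peaks_in_window = in_window, category = category,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Concordance fractions for joined records
#'
#' Fraction of dependent proteins whose gene shows a mean-level mRNA change,
#' and the rhythmic / nonrhythmic split of their mRNA source, as half-up
#' rounded percentages of the joined records.
#'
#' @param records a [join_omes()] table with >= 1 row.
#' @param decimals decimal places for percentages.
#' @return list: `n`, `pct_mean_changed`, `pct_rhythmic_source`,
#'   `pct_nonrhythmic_source`.
#' @export
concordance_fractions <- function(records, decimals = 2) {
  n <- nrow(records)
  if (!n) stop("no records")
  list(n = n,
       pct_mean_changed = summarize_percent(sum(records$mrna_mean_changed),
                                            n, decimals),
       pct_rhythmic_source = summarize_percent(
         sum(records$mrna_rhythmic_in_wt), n, decimals),
       pct_nonrhythmic_source = summarize_percent(
         sum(!records$mrna_rhythmic_in_wt), n, decimals))
}

#' Fraction of window-rhythmic genes with an altered protein
#'
#' The reverse direction of the concordance question: of the genes rhythmic
#' in the reference group and peaking inside the window, how many have a
#' mapped protein that is clock-dependent? The denominator is window genes
#' with at least one mapped protein.
#'
#' @param window_genes gene ids from [peak_phase_filter()].
#' @param dependent_proteins ids of dependent proteins.
#' @param id_map `data.frame` with columns `protein_id`, `gene`.
#' @param decimals decimal places.
#' @return list: `n_genes` (denominator), `n_altered`, `pct_altered`.
#' @export
reverse_lookup <- function(window_genes, dependent_proteins, id_map,
                           decimals = 2) {
  mapped <- id_map[id_map$gene %in% window_genes, , drop = FALSE]
  genes_with_protein <- unique(mapped$gene)
  if (!length(genes_with_protein))
    stop("no window gene has a mapped protein")
  altered <- unique(mapped$gene[mapped$protein_id %in% dependent_proteins])
  list(n_genes = length(genes_with_protein),
       n_altered = length(altered),
       pct_altered = summarize_percent(length(altered),
                                       length(genes_with_protein), decimals))
}
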