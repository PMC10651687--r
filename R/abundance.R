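#' Construct an abundance matrix
#'
#' The central container of the package: a numeric features x samples grid of
#' reporter intensities (raw scale) or normalized log2 ratios, together with
#' per-feature metadata (gene symbol, peptide count, contaminant / decoy /
#' single-oxidized-peptide flags and an optional secreted flag).
#'
#' @param values numeric matrix, features in rows, samples in columns. Must
#'   have unique, non-missing rownames (feature ids) and colnames (sample ids).
#' @param features data.frame of feature metadata, one row per feature, in the
#'   same order as `values`. Must contain a `protein_id` column matching
#'   `rownames(values)`. Missing flag columns are filled with `FALSE` and a
#'   missing `n_peptides` column with `NA`.
#' @param scale value scale, `"raw"` for reporter intensities or
#'   `"log2_normalized"` after [reference_normalize()].
#' @return an object of class `abund_matrix`: a list with elements `values`,
#'   `features` and `scale`.
#' @export
abundance_matrix <- function(values, features = NULL,
                             scale = c("raw", "log2_normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids in abundance matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in abundance matrix")
  if (is.null(features)) {
    features <- data.frame(protein_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  if (!"protein_id" %in% names(features))
    stop("feature metadata must contain a `protein_id` column")
  if (nrow(features) != nrow(values) ||
      !all(features$protein_id == rownames(values)))
    stop("feature metadata rows must match `values` rownames in order")
  for (fl in c("flag_contaminant", "flag_decoy", "flag_single_oxidized")) {
    if (!fl %in% names(features)) features[[fl]] <- FALSE
    features[[fl]] <- as.logical(features[[fl]])
  }
  if (!"gene" %in% names(features)) features$gene <- features$protein_id
  if (!"n_peptides" %in% names(features)) features$n_peptides <- NA_integer_
  structure(list(values = values, features = features, scale = scale),
            class = "abund_matrix")
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("abund_matrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  nflag <- sum(x$features$flag_contaminant | x$features$flag_decoy |
                 x$features$flag_single_oxidized)
  cat(sprintf("  flagged features (contaminant/decoy/single-oxidized): %d\n",
              nflag))
  invisible(x)
}

#' @export
dim.abund_matrix <- function(x) dim(x$values)

#' Validate a sample design table
#'
#' A design maps each sample to its tissue, genotype, feeding condition, TMT
#' plex and channel, with exactly one pooled-reference channel per plex.
#'
#' @param design data.frame with columns `sample`, `tissue`, `genotype`,
#'   `feeding`, `plex`, `channel`, `is_reference`, `replicate`.
#' @param genotypes,feedings allowed label vocabularies.
#' @return the design, invisibly, after validation.
#' @export
validate_design <- function(design, genotypes = c("WT", "KO", "RE"),
                            feedings = c("AL", "TRF")) {
  need <- c("sample", "tissue", "genotype", "feeding", "plex", "channel",
            "is_reference", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicated sample ids in design")
  key <- paste(design$plex, design$channel)
  if (anyDuplicated(key))
    stop("duplicated (plex, channel) assignment in design")
  refs <- tapply(design$is_reference, design$plex, sum)
  if (any(refs != 1))
    stop("each plex must contain exactly one reference sample; got counts: ",
         paste(refs, collapse = ", "))
  nonref <- design[!design$is_reference, ]
  bad_g <- setdiff(unique(nonref$genotype), genotypes)
  if (length(bad_g))
    stop("unknown genotype label(s): ", paste(bad_g, collapse = ", "))
  bad_f <- setdiff(unique(nonref$feeding), feedings)
  if (length(bad_f))
    stop("unknown feeding label(s): ", paste(bad_f, collapse = ", "))
  invisible(design)
}
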