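#' Remove decoy, contaminant and single-oxidized-peptide features
#'
#' Standard post-search cleanup: rows flagged as decoy, potential contaminant,
#' or identified only by a single oxidized-methionine peptide are dropped.
#' Survivor order is preserved and the operation is idempotent.
#'
#' @param am an [abundance_matrix()].
#' @return the filtered matrix; the number of removed rows is reported via
#'   `message()`.
#' @export
filter_features <- function(am) {
  stopifnot(inherits(am, "abund_matrix"))
  f <- am$features
  drop <- f$flag_contaminant | f$flag_decoy | f$flag_single_oxidized
  drop[is.na(drop)] <- FALSE
  message(sprintf("filter_features: removed %d of %d features", sum(drop),
                  nrow(f)))
  if (all(drop)) warning("filter_features: no features remain")
  keep <- !drop
  abundance_matrix(am$values[keep, , drop = FALSE],
                   f[keep, , drop = FALSE], scale = am$scale)
}

#' Pooled-reference normalization across plexes
#'
#' Converts raw reporter intensities to log2 ratios against the pooled
#' reference channel of the sample's own plex, then centers each sample at
#' zero median. Because every channel of a plex shares the plex's batch
#' factor, the ratio to the in-plex reference cancels multiplicative batch
#' effects exactly. Reference samples are dropped from the output.
#'
#' @param am raw-scale [abundance_matrix()]; all intensities must be > 0.
#' @param design sample design with one reference per plex.
#' @param median_center center each sample at zero median after taking
#'   ratios (default `TRUE`).
#' @return a log2-normalized [abundance_matrix()] without reference columns.
#' @export
reference_normalize <- function(am, design, median_center = TRUE) {
  stopifnot(inherits(am, "abund_matrix"))
  if (am$scale != "raw")
    stop("reference_normalize expects a raw-scale matrix")
  validate_design(design, genotypes = unique(design$genotype),
                  feedings = unique(design$feeding))
  missing_s <- setdiff(design$sample, colnames(am$values))
  if (length(missing_s))
    stop("abundance matrix is missing design sample(s): ",
         paste(missing_s, collapse = ", "))
  bad <- which(am$values[, design$sample, drop = FALSE] <= 0,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive intensity for protein %s in sample %s",
                 rownames(am$values)[bad[1, 1]], design$sample[bad[1, 2]]))
  nonref <- design[!design$is_reference, ]
  refs <- design[design$is_reference, ]
  ref_of_plex <- stats::setNames(refs$sample, refs$plex)
  lg <- log2(am$values)
  out <- matrix(NA_real_, nrow(lg), nrow(nonref),
                dimnames = list(rownames(lg), nonref$sample))
  for (j in seq_len(nrow(nonref))) {
    s <- nonref$sample[j]
    r <- ref_of_plex[[nonref$plex[j]]]
    out[, j] <- lg[, s] - lg[, r]
  }
  if (median_center) {
    med <- apply(out, 2, stats::median)
    out <- sweep(out, 2, med)
  }
  abundance_matrix(out, am$features, scale = "log2_normalized")
}

#' Principal component analysis of samples
#'
#' PCA on centered, unscaled log2 abundances (abundances share units, so
#' per-feature scaling would inflate low-variance proteins). Samples are
#' observations, features are variables.
#'
#' @param am log2-normalized [abundance_matrix()] with at least 2 samples.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `explained` (variance fractions, non-increasing), `rotation`.
#' @export
abundance_pca <- function(am) {
  stopifnot(inherits(am, "abund_matrix"))
  x <- t(am$values)
  if (nrow(x) < 2) stop("PCA requires at least 2 samples")
  if (all(abs(sweep(x, 2, colMeans(x))) < .Machine$double.eps * 100))
    stop("degenerate input: matrix is constant, PCA undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = pc$rotation),
            class = "pca_result")
}

#' Flag outlying samples in PC1/PC2 space
#'
#' A sample is flagged when its Euclidean distance to its (genotype, feeding)
#' group center in the first two principal components exceeds `k` times the
#' median within-group distance, computed over all groups. The center is the
#' componentwise median, so one grossly corrupted sample cannot drag the
#' center and implicate its well-behaved group mates. Flags are reported,
#' never silently applied; exclusion is a separate, explicit step.
#'
#' @param pca a `pca_result` from [abundance_pca()].
#' @param design sample design; only non-reference samples are considered.
#' @param k distance multiplier (default 3).
#' @return character vector of flagged sample ids (possibly empty), with the
#'   per-sample distances attached as attribute `"distances"`.
#' @export
flag_outliers <- function(pca, design, k = 3) {
  stopifnot(inherits(pca, "pca_result"))
  nonref <- design[!design$is_reference, ]
  sc <- pca$scores[, 1:2, drop = FALSE]
  nonref <- nonref[nonref$sample %in% rownames(sc), ]
  grp <- paste(nonref$genotype, nonref$feeding, sep = "_")
  dists <- rep(NA_real_, nrow(nonref))
  names(dists) <- nonref$sample
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 3) {
      warning(sprintf("group %s has fewer than 3 samples; skipped", g))
      next
    }
    pts <- sc[nonref$sample[idx], , drop = FALSE]
    ctr <- apply(pts, 2, stats::median)
    dists[idx] <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  }
  med <- stats::median(dists, na.rm = TRUE)
  flagged <- names(dists)[!is.na(dists) & dists > k * med]
  attr(flagged, "distances") <- dists
  flagged
}
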