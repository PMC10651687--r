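#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up procedure directly: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to the
#' input order. Stable under ties.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

.group_samples <- function(design, spec, feedings = NULL) {
  nonref <- design[!design$is_reference, ]
  if (is.character(spec) && length(spec) == 1) {
    parts <- strsplit(spec, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("group spec must be 'GENOTYPE_FEEDING', got: ", spec)
    spec <- list(genotype = parts[1], feeding = parts[2])
  }
  sel <- nonref$genotype == spec$genotype & nonref$feeding == spec$feeding
  nonref$sample[sel]
}

#' Pairwise differential abundance by two-sample t-test
#'
#' Per feature: pooled-variance Student's t (or Welch's t) on log2 values
#' between two (genotype, feeding) groups, two-sided p, and BH q computed
#' across all features of the contrast. `log2FC` is group A mean minus
#' group B mean.
#'
#' @param am log2-normalized [abundance_matrix()].
#' @param design sample design.
#' @param group_a,group_b group specs, either `"WT_AL"` strings or lists with
#'   `genotype` and `feeding` elements. Groups must be disjoint with >= 2
#'   samples each.
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @param exclude sample ids to drop (e.g. flagged outliers).
#' @return `data.frame` with one row per feature: `feature_id`, `contrast`,
#'   `log2fc`, `t`, `p`, `q`, `n_a`, `n_b`. Features with zero pooled
#'   variance and a nonzero mean difference get `p = 0` with a warning and
#'   `degenerate = TRUE`.
#' @export
pairwise_ttest <- function(am, design, group_a, group_b, welch = FALSE,
                           exclude = character(0)) {
  stopifnot(inherits(am, "abund_matrix"))
  if (am$scale != "log2_normalized")
    stop("pairwise_ttest expects log2-normalized values")
  sa <- setdiff(.group_samples(design, group_a), exclude)
  sb <- setdiff(.group_samples(design, group_b), exclude)
  if (length(intersect(sa, sb))) stop("groups must be disjoint")
  if (length(sa) < 2 || length(sb) < 2)
    stop(sprintf("each group needs >= 2 samples (got %d and %d)",
                 length(sa), length(sb)))
  xa <- am$values[, sa, drop = FALSE]
  xb <- am$values[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  if (welch) {
    va <- ssa / (na - 1); vb <- ssb / (nb - 1)
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- (ssa + ssb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  }
  delta <- ma - mb
  tstat <- delta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se == 0 | !is.finite(se)
  if (any(degen)) {
    warning(sprintf("%d feature(s) with zero pooled variance; p set to 0 (or 1 when means equal)",
                    sum(degen)))
    tstat[degen] <- ifelse(delta[degen] == 0, 0, sign(delta[degen]) * Inf)
    p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  }
  label <- function(g) if (is.character(g)) g else
    paste(g$genotype, g$feeding, sep = "_")
  data.frame(
    feature_id = rownames(am$values),
    contrast = paste(label(group_a), "vs", label(group_b)),
    log2fc = delta, t = tstat, p = p, q = bh_adjust(p),
    n_a = na, n_b = nb, degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way ANOVA with Tukey pairwise comparisons for one feature
#'
#' Type-II sums of squares on the genotype x feeding layout (robust to the
#' mild unbalance caused by excluding an outlier sample), with Tukey-Kramer
#' adjusted pairwise comparisons across all (genotype, feeding) cells.
#'
#' @param values named numeric vector of one feature's log2 abundances; names
#'   are sample ids present in `design`.
#' @param design sample design.
#' @return list of class `anova_result`: `terms` (data.frame with F and p for
#'   genotype, feeding and interaction) and `tukey` (data.frame of pairwise
#'   cell comparisons with mean differences and adjusted p).
#' @export
two_way_anova_tukey <- function(values, design) {
  nonref <- design[!design$is_reference, ]
  nonref <- nonref[nonref$sample %in% names(values), ]
  y <- values[nonref$sample]
  A <- factor(nonref$genotype)
  B <- factor(nonref$feeding)
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("need >= 2 levels per factor")
  tab <- table(A, B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: genotype %s, feeding %s",
                 levels(A)[empty[1]], levels(B)[empty[2]]))
  }
  if (any(tab < 2))
    stop("every (genotype, feeding) cell needs >= 2 replicates")
  df <- data.frame(y = y, A = A, B = B)
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = df))^2)
  rss_ab <- rss(y ~ A + B)
  rss_full <- rss(y ~ A * B)
  ss_a <- rss(y ~ B) - rss_ab
  ss_b <- rss(y ~ A) - rss_ab
  ss_ab <- rss_ab - rss_full
  df_a <- nlevels(A) - 1; df_b <- nlevels(B) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(A) * nlevels(B)
  mse <- rss_full / df_e
  ss <- c(genotype = ss_a, feeding = ss_b, interaction = ss_ab)
  fstat <- (ss / c(df_a, df_b, df_ab)) / mse
  # noiseless input: a term either explains nothing (F = 0) or everything
  tol <- 1e-12 * max(1, sum(y^2))
  if (rss_full <= tol) fstat <- ifelse(ss <= tol, 0, Inf)
  terms <- data.frame(
    term = names(fstat), df = c(df_a, df_b, df_ab),
    sum_sq = c(ss_a, ss_b, ss_ab), F = unname(fstat),
    p = stats::pf(unname(fstat), c(df_a, df_b, df_ab), df_e,
                  lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  cell <- factor(paste(A, B, sep = "_"))
  tk <- stats::TukeyHSD(stats::aov(y ~ cell, data = data.frame(y = y,
                                                               cell = cell)))
  tkdf <- as.data.frame(tk$cell)
  tukey <- data.frame(pair = rownames(tkdf), diff = tkdf$diff,
                      p_adj = tkdf$`p adj`, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, tukey = tukey, mse = mse, df_error = df_e),
            class = "anova_result")
}
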