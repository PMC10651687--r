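# Two-group cosinor model enumeration with BIC-weight selection, in the
# style of differential-rhythmicity tools for diurnal transcriptomes.
#
# Five rhythmic hypotheses, all with group-specific intercepts:
#   1  no rhythm in either group
#   2  rhythmic in group 1 only
#   3  rhythmic in group 2 only
#   4  rhythmic in both, shared cosine coefficients
#   5  rhythmic in both, group-specific coefficients
# By convention the reference group (WT) is group 2, so "models 3, 4, 5"
# reads as rhythmic-in-reference.

.model_matrices <- function(zt, group, g1, g2, period) {
  w <- 2 * pi / period
  c1 <- cos(w * zt); s1 <- sin(w * zt)
  i1 <- as.numeric(group == g1); i2 <- as.numeric(group == g2)
  list(
    cbind(i1 = i1, i2 = i2),
    cbind(i1 = i1, i2 = i2, c_g1 = i1 * c1, s_g1 = i1 * s1),
    cbind(i1 = i1, i2 = i2, c_g2 = i2 * c1, s_g2 = i2 * s1),
    cbind(i1 = i1, i2 = i2, c = c1, s = s1),
    cbind(i1 = i1, i2 = i2, c_g1 = i1 * c1, s_g1 = i1 * s1,
          c_g2 = i2 * c1, s_g2 = i2 * s1))
}

# BIC for a least-squares fit under a Gaussian likelihood. RSS is floored at
# a small fraction of the total sum of squares so that exactly-interpolating
# (noiseless) fits compare by parameter count instead of by log(0).
.bic_ls <- function(rss, n, k, tss) {
  floor_ <- max(1e-300, 1e-16 * tss)
  n * log(max(rss, floor_) / n) + (k + 1) * log(n)
}

.amp_phase <- function(a, b, period) {
  amp <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) * period / (2 * pi)) %% period
  c(amp = amp, phase = phase)
}

#' Fit the five two-group cosinor models to one gene
#'
#' Least-squares fits of the five rhythmicity hypotheses (see Details), BIC
#' per model, BIC weights `softmax(-BIC/2)`, and selection of the
#' maximum-weight model. Amplitude is `sqrt(a^2 + b^2)` and peak phase
#' `atan2(b, a) * period / (2*pi)` (wrapped to `[0, period)`), from the cosine
#' and sine coefficients of the selected model.
#'
#' @param value numeric vector of expression values.
#' @param zt sampling times (hours).
#' @param group group label per observation; exactly two levels.
#' @param reference_group the group mapped to "group 2" (default `"WT"` if
#'   present, otherwise the last level); rhythmic-in-reference means the
#'   selected model is 3, 4 or 5.
#' @param period rhythm period in hours (default 24).
#' @param bicw_threshold minimum BIC weight for a confident call (default
#'   0.4); below it the fit is marked unclassified and excluded from
#'   rhythmic sets.
#' @return list of class `rhythm_fit`: `model` (selected index), `bicw`
#'   (length 5, sums to 1), `confident`, per-group `mesor`, `amplitude`,
#'   `phase` (named by group), `rhythmic_in_reference`, `groups`
#'   (c(group1, group2)).
#' @export
fit_harmonic_models <- function(value, zt, group, reference_group = NULL,
                                period = 24, bicw_threshold = 0.4) {
  if (period <= 0) stop("`period` must be > 0")
  lv <- unique(group)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(reference_group))
    reference_group <- if ("WT" %in% lv) "WT" else lv[2]
  if (!reference_group %in% lv) stop("reference group not present")
  g2 <- reference_group
  g1 <- setdiff(lv, g2)
  for (g in c(g1, g2))
    if (length(unique(zt[group == g])) < 4)
      stop("each group needs >= 4 distinct timepoints for identifiability")
  n <- length(value)
  tss <- sum((value - mean(value))^2)
  mats <- .model_matrices(zt, group, g1, g2, period)
  fits <- lapply(mats, function(X) {
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) stop("rank-deficient cosinor design")
    fit <- stats::lm.fit(X, value)
    list(coef = fit$coefficients, rss = sum(fit$residuals^2), k = ncol(X))
  })
  bic <- vapply(seq_along(fits), function(i)
    .bic_ls(fits[[i]]$rss, n, fits[[i]]$k, tss), numeric(1))
  d <- -0.5 * (bic - min(bic))
  bicw <- exp(d) / sum(exp(d))
  model <- which.max(bicw)
  confident <- bicw[model] >= bicw_threshold
  cf <- fits[[model]]$coef
  mesor <- c(cf[["i1"]], cf[["i2"]])
  names(mesor) <- c(g1, g2)
  ap <- function(a, b) .amp_phase(a, b, period)
  zero <- c(amp = 0, phase = NA_real_)
  pars <- switch(model,
    list(g1 = zero, g2 = zero),
    list(g1 = ap(cf[["c_g1"]], cf[["s_g1"]]), g2 = zero),
    list(g1 = zero, g2 = ap(cf[["c_g2"]], cf[["s_g2"]])),
    {sh <- ap(cf[["c"]], cf[["s"]]); list(g1 = sh, g2 = sh)},
    list(g1 = ap(cf[["c_g1"]], cf[["s_g1"]]),
         g2 = ap(cf[["c_g2"]], cf[["s_g2"]])))
  amplitude <- c(pars$g1[["amp"]], pars$g2[["amp"]])
  phase <- c(pars$g1[["phase"]], pars$g2[["phase"]])
  names(amplitude) <- names(phase) <- c(g1, g2)
  structure(list(model = model, bic = bic, bicw = bicw,
                 confident = confident, mesor = mesor,
                 amplitude = amplitude, phase = phase,
                 rhythmic_in_reference = confident && model %in% 3:5,
                 groups = c(g1, g2), period = period),
            class = "rhythm_fit")
}

#' Compare shared-mean vs group-specific-mean models
#'
#' Keeps the rhythmic structure of the selected rhythmicity model as
#' covariates and asks, by BIC weight, whether the two groups share a mean
#' level. With balanced sampling over the cycle the cosine terms integrate to
#' ~0, so a rhythm cannot masquerade as a mean shift.
#'
#' @inheritParams fit_harmonic_models
#' @param rhythm_fit a `rhythm_fit` for the same gene (used for the rhythm
#'   covariate structure); if `NULL` it is computed.
#' @return list of class `mean_fit`: `model` (`"shared"` or `"distinct"`),
#'   `bicw` (named pair), `mean_diff` (group1 - group2, i.e. the
#'   non-reference minus the reference mean).
#' @export
fit_mean_models <- function(value, zt, group, rhythm_fit = NULL,
                            reference_group = NULL, period = 24) {
  if (is.null(rhythm_fit))
    rhythm_fit <- fit_harmonic_models(value, zt, group,
                                      reference_group = reference_group,
                                      period = period)
  g1 <- rhythm_fit$groups[1]; g2 <- rhythm_fit$groups[2]
  mats <- .model_matrices(zt, group, g1, g2, rhythm_fit$period)
  Xr <- mats[[rhythm_fit$model]]
  rhythm_cols <- setdiff(colnames(Xr), c("i1", "i2"))
  n <- length(value)
  tss <- sum((value - mean(value))^2)
  X_shared <- cbind(intercept = rep(1, n),
                    Xr[, rhythm_cols, drop = FALSE])
  X_distinct <- Xr
  fit1 <- stats::lm.fit(X_shared, value)
  fit2 <- stats::lm.fit(X_distinct, value)
  bic <- c(shared = .bic_ls(sum(fit1$residuals^2), n, ncol(X_shared), tss),
           distinct = .bic_ls(sum(fit2$residuals^2), n, ncol(X_distinct),
                              tss))
  d <- -0.5 * (bic - min(bic))
  bicw <- exp(d) / sum(exp(d))
  model <- names(which.max(bicw))
  diff <- unname(fit2$coefficients[["i1"]] - fit2$coefficients[["i2"]])
  structure(list(model = model, bicw = bicw, mean_diff = diff),
            class = "mean_fit")
}

#' Rhythmicity and mean-model analysis of a long expression table
#'
#' Applies [fit_harmonic_models()] and [fit_mean_models()] to every gene of a
#' long expression table (columns gene, genotype, zt, rep, value).
#'
#' @param expression long expression `data.frame`.
#' @inheritParams fit_harmonic_models
#' @return `data.frame`, one row per gene: selected model, max BIC weight,
#'   `confident`, per-group mesor/amplitude/phase (`_ref` = reference group,
#'   `_alt` = other group), `rhythmic_in_reference`, `mean_model`,
#'   `mean_diff` (alt - ref).
#' @export
rhythm_analysis <- function(expression, reference_group = "WT", period = 24,
                            bicw_threshold = 0.4) {
  genes <- unique(expression$gene)
  rows <- lapply(genes, function(g) {
    d <- expression[expression$gene == g, ]
    rf <- fit_harmonic_models(d$value, d$zt, d$genotype,
                              reference_group = reference_group,
                              period = period,
                              bicw_threshold = bicw_threshold)
    mf <- fit_mean_models(d$value, d$zt, d$genotype, rhythm_fit = rf)
    alt <- rf$groups[1]; ref <- rf$groups[2]
    data.frame(
      gene = g, model = rf$model, bicw = max(rf$bicw),
      confident = rf$confident,
      mesor_ref = rf$mesor[[ref]], mesor_alt = rf$mesor[[alt]],
      amp_ref = rf$amplitude[[ref]], amp_alt = rf$amplitude[[alt]],
      phase_ref = rf$phase[[ref]], phase_alt = rf$phase[[alt]],
      rhythmic_in_reference = rf$rhythmic_in_reference,
      mean_model = mf$model, mean_diff = mf$mean_diff,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select genes peaking inside a phase window
#'
#' Genes rhythmic in the reference group whose reference-group peak phase
#' falls inside the window (both endpoints inclusive); the default window
#' ZT14-ZT22 is the dark phase around a ZT16 harvest.
#'
#' @param fits a [rhythm_analysis()] table.
#' @param window length-2 numeric, phase window in ZT hours.
#' @return character vector of gene ids.
#' @export
peak_phase_filter <- function(fits, window = c(14, 22)) {
  sel <- fits$rhythmic_in_reference &
    !is.na(fits$phase_ref) &
    fits$phase_ref >= window[1] & fits$phase_ref <= window[2]
  fits$gene[sel]
}
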