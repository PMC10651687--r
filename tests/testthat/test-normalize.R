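test_that("filter_features removes exactly the flagged set, idempotently", {
  v <- matrix(2^rnorm(40, 20), 10, 4,
              dimnames = list(sprintf("P%02d", 1:10), paste0("s", 1:4)))
  f <- data.frame(protein_id = rownames(v),
                  flag_contaminant = FALSE, flag_decoy = FALSE,
                  flag_single_oxidized = FALSE)
  f$flag_decoy[c(2, 7)] <- TRUE
  am <- abundance_matrix(v, f)
  out <- suppressMessages(filter_features(am))
  expect_equal(nrow(out$values), 8)
  expect_identical(rownames(out$values), setdiff(rownames(v),
                                                 c("P02", "P07")))

  # identity when nothing is flagged
  f0 <- f; f0$flag_decoy <- FALSE
  am0 <- abundance_matrix(v, f0)
  expect_identical(suppressMessages(filter_features(am0))$values, v)

  # random flags: survivors are the complement (set-difference oracle);
  # filtering twice changes nothing
  set.seed(1)
  for (i in 1:10) {
    fr <- f
    fr$flag_contaminant <- runif(10) < 0.3
    fr$flag_single_oxidized <- runif(10) < 0.2
    amr <- abundance_matrix(v, fr)
    once <- suppressMessages(filter_features(amr))
    flagged <- fr$protein_id[fr$flag_contaminant | fr$flag_decoy |
                               fr$flag_single_oxidized]
    expect_identical(rownames(once$values), setdiff(rownames(v), flagged))
    expect_identical(suppressMessages(filter_features(once))$values,
                     once$values)
  }
})

test_that("reference normalization: ratios, batch cancellation, scaling invariance", {
  d <- toy_design(list(WT_AL = 2, KO_AL = 2), n_plexes = 2)
  samples <- d$sample
  ids <- sprintf("P%02d", 1:6)
  log2v <- matrix(10, 6, length(samples), dimnames = list(ids, samples))
  # plant per-plex batch shifts +/- b on every channel including references
  b <- 0.7
  for (s in samples) {
    px <- d$plex[d$sample == s]
    log2v[, s] <- log2v[, s] + ifelse(px == "plex1", b, -b)
  }
  am <- abundance_matrix(2^log2v, scale = "raw")

  # protein equal to its reference everywhere -> all zeros pre-centering
  out <- reference_normalize(am, d, median_center = FALSE)
  expect_equal(max(abs(out$values)), 0, tolerance = 1e-12)
  expect_identical(out$scale, "log2_normalized")
  expect_false(any(d$sample[d$is_reference] %in% colnames(out$values)))

  # null proteins: between-plex mean difference cancels to < 1e-12
  set.seed(2)
  base <- rnorm(6, 18, 1)
  log2v2 <- matrix(base, 6, length(samples), dimnames = list(ids, samples))
  noise <- matrix(rnorm(length(log2v2), 0, 0.1), nrow(log2v2))
  for (s in samples) {
    px <- d$plex[d$sample == s]
    shift <- ifelse(px == "plex1", b, -b)
    ref <- d$is_reference[d$sample == s]
    log2v2[, s] <- log2v2[, s] + shift + if (ref) 0 else noise[, which(samples == s)]
  }
  am2 <- abundance_matrix(2^log2v2, scale = "raw")
  out2 <- reference_normalize(am2, d, median_center = FALSE)
  nonref <- d[!d$is_reference, ]
  p1 <- rowMeans(out2$values[, nonref$sample[nonref$plex == "plex1"]])
  p2 <- rowMeans(out2$values[, nonref$sample[nonref$plex == "plex2"]])
  noise_means <- sapply(split(seq_len(nrow(nonref)), nonref$plex), function(i)
    rowMeans(noise[, i, drop = FALSE]))
  expect_lt(max(abs((p1 - p2) - (noise_means[, 1] - noise_means[, 2]))),
            1e-12)

  # invariance to per-plex multiplicative rescaling of raw intensities
  am3 <- am2
  scale_fac <- ifelse(d$plex[match(colnames(am3$values), d$sample)] == "plex1",
                      3.7, 0.2)
  am3$values <- sweep(am3$values, 2, scale_fac, `*`)
  out3 <- reference_normalize(am3, d)
  expect_equal(out3$values, reference_normalize(am2, d)$values,
               tolerance = 1e-12)

  # nonpositive intensities are named
  am_bad <- am2
  am_bad$values["P03", samples[2]] <- 0
  expect_error(reference_normalize(am_bad, d), "P03")
})

test_that("noiseless simulated data normalize to the planted effect exactly", {
  p <- small_params(sigma = 0, frac_dependent = 0.04, frac_flagged = 0,
                    frac_rescued_given_dependent = 0,
                    frac_feeding_responsive = c(WT = 0, KO = 0, RE = 0),
                    plex_sd = 1)
  s <- normalized_sim(p)
  wt <- rowMeans(s$am$values[, group_samples(s$design, "WT_AL")])
  ko <- rowMeans(s$am$values[, group_samples(s$design, "KO_AL")])
  dep <- s$truth$dependent
  expect_equal(abs(wt - ko)[dep], rep(p$effect_log2, sum(dep)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA agrees with the eigendecomposition oracle and is orthogonal", {
  set.seed(5)
  v <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("P", 1:5),
                                               paste0("s", 1:4)))
  am <- norm_matrix(v)
  pc <- abundance_pca(am)
  x <- scale(t(v), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))$values
  # centering leaves rank 3; compare the informative components
  expect_equal(pc$explained[1:3], (ev / sum(ev))[1:3], tolerance = 1e-10)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
  expect_equal(colMeans(pc$scores), rep(0, ncol(pc$scores)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(pc$explained[-1] <= pc$explained[-length(pc$explained)]
                  + 1e-12))
  # orthogonality of score columns
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # reconstruction (full rank)
  expect_equal(pc$scores %*% t(pc$rotation), x, tolerance = 1e-8,
               ignore_attr = TRUE)

  # duplicated samples give identical score rows
  v2 <- cbind(v, s5 = v[, "s1"])
  pc2 <- abundance_pca(norm_matrix(v2))
  expect_equal(pc2$scores["s1", ], pc2$scores["s5", ], tolerance = 1e-10)

  expect_error(abundance_pca(norm_matrix(matrix(1, 3, 3,
    dimnames = list(letters[1:3], LETTERS[1:3])))), "constant")

  # strong genotype effect separates groups on PC1
  p <- small_params(effect_log2 = 3, frac_dependent = 0.5, sigma = 0.1)
  s <- normalized_sim(p)
  pc3 <- abundance_pca(s$am)
  nonref <- s$design[!s$design$is_reference, ]
  ko <- pc3$scores[nonref$sample[nonref$genotype == "KO"], 1]
  wt <- pc3$scores[nonref$sample[nonref$genotype == "WT"], 1]
  expect_true(max(ko) < min(wt) || min(ko) > max(wt))
})

test_that("outlier flagging finds the planted corrupted sample", {
  # the rule is a screen: the corrupted sample must always be flagged, with
  # a distance far beyond everything else; occasional mild extra flags are
  # inherent to any scale-free threshold on n = 4 groups and are benign
  # because flags are reported, never silently applied
  for (seed in c(11, 12, 13)) {
    p <- small_params(outlier_sample = TRUE, seed = seed)
    s <- normalized_sim(p)
    pc <- abundance_pca(s$am)
    flags <- flag_outliers(pc, s$design, k = 3)
    nonref <- s$design[!s$design$is_reference, ]
    victim <- sort(nonref$sample[nonref$genotype == "KO" &
                                   nonref$feeding == "TRF"])[1]
    expect_true(victim %in% flags)
    dd <- attr(flags, "distances")
    expect_identical(names(which.max(dd)), victim)
    expect_gt(dd[[victim]], 20 * max(dd[names(dd) != victim]))
    expect_lte(length(setdiff(flags, victim)), 2)
  }

  # homogeneous data: flagging is rare and disappears at large k
  p0 <- small_params(sigma = 0.01, frac_dependent = 0, plex_sd = 0)
  s0 <- normalized_sim(p0)
  expect_lte(length(flag_outliers(abundance_pca(s0$am), s0$design, k = 3)), 3)
  expect_length(flag_outliers(abundance_pca(s0$am), s0$design, k = 10), 0)

  # k = 0 flags every sample off its centroid
  flags0 <- flag_outliers(abundance_pca(s0$am), s0$design, k = 0)
  expect_equal(length(flags0), sum(!s0$design$is_reference))

  # groups smaller than 3 are skipped with a warning
  d_small <- toy_design(list(WT_AL = 2, KO_AL = 4))
  v <- matrix(rnorm(60), 10, 6)
  dimnames(v) <- list(paste0("P", 1:10), d_small$sample[1:6])
  expect_warning(flag_outliers(abundance_pca(norm_matrix(v)),
                               d_small, k = 3), "fewer than 3")
})
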