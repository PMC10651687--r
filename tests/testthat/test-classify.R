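make_contrast <- function(ids, q, log2fc = -1) {
  data.frame(feature_id = ids, contrast = "x vs y", log2fc = log2fc,
             t = 0, p = q, q = q, n_a = 4, n_b = 4,
             stringsAsFactors = FALSE)
}

test_that("dependence call uses strict inequality at alpha", {
  ct <- make_contrast(c("a", "b", "c"), c(0.049, 0.05, 0.051),
                      log2fc = c(-1, 1, 2))
  dep <- suppressMessages(call_dependent(ct, alpha = 0.05))
  expect_equal(dep$dependent, c(TRUE, FALSE, FALSE))
  # direction is the KO-vs-WT sign, i.e. opposite of log2fc = WT - KO
  expect_equal(dep$direction, c("up", NA, NA))
})

test_that("rescue rule follows the full truth table in both modes", {
  lo <- 0.01; hi <- 0.5
  patterns <- expand.grid(dep = c(lo, hi), re_ko = c(lo, hi),
                          wt_re = c(lo, hi))
  ids <- sprintf("f%d", seq_len(nrow(patterns)))
  dep <- call_dependent(make_contrast(ids, patterns$dep))
  ck <- make_contrast(ids, patterns$re_ko)
  cw <- make_contrast(ids, patterns$wt_re)
  # exhaustive oracle over the 8 threshold patterns
  oracle_dich <- ifelse(patterns$dep >= 0.05, "not_applicable",
                        ifelse(patterns$re_ko < 0.05 & patterns$wt_re >= 0.05,
                               "rescued", "nonrescued"))
  got <- classify_rescue(dep, ck, cw)
  expect_equal(got$rescue, oracle_dich)

  three <- classify_rescue(dep, ck, cw, mode = "threeway")
  oracle_three <- oracle_dich
  oracle_three[patterns$dep < 0.05 & patterns$re_ko < 0.05 &
                 patterns$wt_re < 0.05] <- "partial"
  expect_equal(three$rescue, oracle_three)

  # the worked q-triples
  tri <- function(a, b, c, mode = "dichotomy")
    classify_rescue(call_dependent(make_contrast("x", a)),
                    make_contrast("x", b), make_contrast("x", c),
                    mode = mode)$rescue
  expect_equal(tri(0.01, 0.02, 0.50), "rescued")
  expect_equal(tri(0.01, 0.80, 0.01), "nonrescued")
  expect_equal(tri(0.01, 0.02, 0.01), "nonrescued")
  expect_equal(tri(0.01, 0.02, 0.01, mode = "threeway"), "partial")

  # dichotomy partitions the dependent set
  expect_equal(sum(got$rescue == "rescued") + sum(got$rescue == "nonrescued"),
               sum(got$dependent))

  # missing contrast rows are a data error
  expect_error(classify_rescue(dep, ck[-1, ], cw), "missing")
})

test_that("feeding-responsiveness is planted only where simulated", {
  p <- small_params(n_proteins = 1500, frac_dependent = 0,
                    frac_feeding_responsive = c(WT = 0, KO = 0, RE = 0.1),
                    seed = 21)
  s <- normalized_sim(p)
  re <- call_feeding_responsive(s$am, s$design, "RE")
  wt <- call_feeding_responsive(s$am, s$design, "WT")
  planted <- s$truth$feeding_responsive_RE
  # precision: essentially all calls are planted
  called <- re$responsive
  expect_lte(sum(called & !planted) / max(1, sum(called)), 0.05 + 0.03)
  # recall tracks the analytic pooled-t power at the BH-effective cutoff
  recall <- mean(called[planted])
  eff_cut <- 0.05 * sum(called) / nrow(re)
  expect_gt(recall, pooled_t_power(eff_cut, 1, 0.25, 4) - 0.1)
  # relaxed threshold is a superset
  expect_true(all(re$responsive_relaxed[re$responsive]))
  # WT has no planted feeding effects: false-call rate bounded by alpha
  expect_lte(mean(wt$responsive), 0.05)
  # alpha = 0 calls nothing
  expect_equal(sum(call_feeding_responsive(s$am, s$design, "RE",
                                           alpha = 0)$responsive), 0)
  # missing feeding arm
  d_one <- s$design[s$design$feeding != "TRF" | s$design$is_reference, ]
  expect_error(call_feeding_responsive(s$am, d_one, "RE"), "feeding arm")
})

test_that("cross-tissue overlap equals brute-force set intersection", {
  expect_equal(cross_tissue_overlap(c("a", "b"), c("c", "d"),
                                    c("a", "b", "c", "d"))$both, 0)
  same <- cross_tissue_overlap(c("a", "b", "x"), c("a", "b", "x"),
                               c("a", "b"))
  expect_equal(same$both, 2)
  set.seed(8)
  for (i in 1:10) {
    univ <- sprintf("p%02d", 1:40)
    A <- sample(univ, 15); B <- sample(univ, 20); D <- sample(univ, 25)
    got <- cross_tissue_overlap(A, B, D)
    expect_equal(got$both, length(intersect(intersect(A, B), D)))
    expect_equal(got$only_a, length(setdiff(intersect(A, D), B)))
    expect_equal(got$only_b, length(setdiff(intersect(B, D), A)))
  }
})

test_that("secreted-fraction test matches exact-table enumeration", {
  universe <- sprintf("u%04d", 1:1000)
  secreted <- universe[1:100]
  affected <- c(universe[1:20], universe[101:130])  # 20/100 vs 50/1000
  res <- secreted_fraction_test(affected, secreted, universe)
  expect_gt(res$odds_ratio, 1)
  expect_equal(res$pct_secreted_affected, 20)
  expect_equal(res$pct_all_affected, 5)
  # two-sided exact p by enumerating all tables with fixed margins
  m <- 100; n <- 900; k <- 50
  probs <- dhyper(0:50, m, n, k)
  obs <- dhyper(20, m, n, k)
  expect_equal(res$p, sum(probs[probs <= obs * (1 + 1e-7)]),
               tolerance = 1e-10)

  # empty affected set: p = 1
  expect_equal(secreted_fraction_test(character(0), secreted, universe)$p, 1)
  expect_error(secreted_fraction_test("u0001", c(secreted, "zzz"), universe),
               "subset")
  expect_error(secreted_fraction_test("x", "x", character(0)), "universe")
})

test_that("planted secreted enrichment is recovered", {
  ors <- vapply(1:8, function(s) {
    p <- small_params(n_proteins = 3000, secreted_enrichment = 4, seed = s)
    sim <- simulate_proteome(generate_design(p), p)
    tr <- sim$truth
    res <- secreted_fraction_test(tr$protein_id[tr$dependent],
                                  tr$protein_id[tr$secreted],
                                  tr$protein_id)
    res$odds_ratio
  }, numeric(1))
  expect_equal(mean(ors), 4, tolerance = 4 * 2.5 * stats::sd(ors) /
                 sqrt(length(ors)) / 4 + 0.5)
})

test_that("subunit-set averages equal the direct mean", {
  v <- matrix(seq_len(20), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:4)))
  am <- norm_matrix(v)
  expect_equal(subunit_set_average(am, "P2"), v["P2", ])
  v2 <- rbind(A = c(1, -2, 3, 0), B = -c(1, -2, 3, 0))
  colnames(v2) <- paste0("s", 1:4)
  expect_equal(unname(subunit_set_average(norm_matrix(v2), c("A", "B"))),
               rep(0, 4))
  set.seed(2)
  members <- sample(rownames(v), 3)
  expect_equal(subunit_set_average(am, members),
               colMeans(v[members, ]))
  expect_error(subunit_set_average(am, c("P1", "nope")), "nope")
  expect_error(subunit_set_average(am, character(0)), "empty")
})

test_that("summarize_percent uses half-up rounding and bounds", {
  expect_equal(summarize_percent(674, 5613), 12.01)
  expect_equal(summarize_percent(80, 3114), 2.57)
  expect_equal(summarize_percent(0, 17), 0)
  expect_equal(summarize_percent(1, 8, decimals = 1), 12.5)
  expect_equal(summarize_percent(125, 1000, decimals = 1), 12.5)
  # half-up, not banker's: 125/1e5 = 0.125% (exactly representable)
  expect_equal(summarize_percent(125, 1e5), 0.13)   # round() would give 0.12
  expect_error(summarize_percent(5, 0), "whole")
  expect_error(summarize_percent(-1, 10), "part")
  # rounding bound: complements sum to ~100
  set.seed(4)
  for (i in 1:20) {
    w <- sample(3:5000, 1); a <- sample(0:w, 1)
    tot <- summarize_percent(a, w) + summarize_percent(w - a, w)
    expect_lte(abs(tot - 100), 10^(1 - 2))
  }
})
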