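# Pearson correlations across taxon pairs and across shared genes.

test_that("pearson_r matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(1, 3, 2, 5)
  expect_equal(pearson_r(x, y)$r, oracle_pearson(x, y),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10)
    expect_equal(pearson_r(a, b)$r, oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

mk_records <- function(n = 10, seed = 1) {
  set.seed(seed)
  tm <- seq(2, 10, length.out = n)
  peak <- 0.005 * tm + rnorm(n, 0, 0.002)
  mod <- 0.35 + 0.02 * tm + rnorm(n, 0, 0.01)
  stp <- 0.45 - 0.02 * tm + rnorm(n, 0, 0.01)
  neu <- 0.02 + rnorm(n, 0, 0.002)
  wk <- pmax(0.05 - 0.002 * tm + rnorm(n, 0, 0.002), 0.001)
  stpos <- pmax(0.03 - 0.001 * tm + rnorm(n, 0, 0.002), 0.001)
  rel <- 1 - (mod + stp + neu + wk + stpos)
  data.frame(pair_id = sprintf("p%02d", 1:n),
             divergence_time_mya = tm, peak_ks = peak,
             modified_peak_ks = peak,
             prop_strong_purifying = stp,
             prop_moderate_purifying = mod,
             prop_relaxed_purifying = rel, prop_near_neutral = neu,
             prop_weak_positive = wk, prop_strong_positive = stpos)
}

test_that("pair-level associations recover planted signs", {
  res <- pair_level_associations(mk_records(12, seed = 3))
  get_r <- function(x, y) res$r[res$x == x & res$y == y]
  expect_gt(get_r("divergence_time_mya", "peak_ks"), 0)
  expect_gt(get_r("peak_ks", "prop_moderate_purifying"), 0)
  expect_lt(get_r("peak_ks", "prop_strong_purifying"), 0)
  expect_lt(get_r("peak_ks", "prop_positive"), 0)
  # modified peak Ks preserves every sign
  for (y in unique(res$y[res$x == "peak_ks"])) {
    expect_identical(sign(get_r("peak_ks", y)),
                     sign(get_r("modified_peak_ks", y)))
  }
})

test_that("associations are invariant to row order and affine time rescaling", {
  rec <- mk_records(10, seed = 4)
  r1 <- pair_level_associations(rec)
  r2 <- pair_level_associations(rec[sample(nrow(rec)), ])
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  rec2 <- rec
  rec2$divergence_time_mya <- 3.3 * rec2$divergence_time_mya + 1.7
  r3 <- pair_level_associations(rec2)
  expect_equal(r1$r, r3$r, tolerance = 1e-12)
})

test_that("count-valued abundances are normalized to proportions", {
  rec <- mk_records(8, seed = 5)
  cnt <- rec
  prop_cols <- grep("^prop_", names(rec), value = TRUE)
  cnt[prop_cols] <- round(cnt[prop_cols] * 5000)
  r1 <- pair_level_associations(rec)
  r2 <- pair_level_associations(cnt)
  expect_equal(sign(r1$r), sign(r2$r))
})

test_that("constant columns raise a zero-variance warning, not an error", {
  rec <- mk_records(8, seed = 6)
  rec$prop_near_neutral <- 0.02
  rec$prop_strong_positive <- 1 - rowSums(
    rec[c("prop_strong_purifying", "prop_moderate_purifying",
          "prop_relaxed_purifying", "prop_near_neutral",
          "prop_weak_positive")])
  ws <- character(0)
  res <- withCallingHandlers(pair_level_associations(rec),
                             warning = function(w) {
                               ws <<- c(ws, conditionMessage(w))
                               invokeRestart("muffleWarning")
                             })
  expect_true(any(grepl("zero variance", ws)))
  # the degenerate column is skipped, the rest of the panel survives
  expect_false("prop_near_neutral" %in% res$y)
  expect_false(anyNA(res$r))
})

test_that("gene-level screen recovers planted monotone genes", {
  set.seed(8)
  n_pairs <- 20
  tm <- seq(1.7, 10.7, length.out = n_pairs)
  noise <- matrix(runif(71 * n_pairs, 0.05, 1.5), 71, n_pairs,
                  dimnames = list(sprintf("noise%02d", 1:71), NULL))
  up <- t(sapply(1:2, function(i) 0.1 + 0.08 * tm + rnorm(n_pairs, 0, 0.05)))
  dn <- t(sapply(1:6, function(i) 1.2 - 0.08 * tm + rnorm(n_pairs, 0, 0.05)))
  rownames(up) <- sprintf("up%d", 1:2)
  rownames(dn) <- sprintf("dn%d", 1:6)
  ratios <- rbind(noise, up, dn)
  colnames(ratios) <- sprintf("p%02d", 1:n_pairs)
  res <- gene_level_time_correlation(ratios, tm, r_threshold = 0.5)
  planted <- res$per_gene[grepl("^(up|dn)", res$per_gene$gene_id), ]
  expect_true(all(planted$passed))
  expect_identical(sum(planted$sign == "positive"), 2L)
  expect_identical(sum(planted$sign == "negative"), 6L)
  # few noise genes sneak past the threshold
  expect_lte(res$n_pass_positive + res$n_pass_negative - 8, 6)
})

test_that("screen drops unusable ratios and short genes", {
  tm <- c(2, 4, 6, 8)
  ratios <- matrix(c(0, 99, 0.5, 0.6,   # only 2 usable -> skipped
                     0.2, 0.2, 0.2, 0.2), 2, 4, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), NULL))
  res <- suppressMessages(
    gene_level_time_correlation(ratios, tm))
  expect_true(is.na(res$per_gene$r[res$per_gene$gene_id == "gA"]))
  # constant ratios -> correlation undefined -> not passed
  expect_false(isTRUE(res$per_gene$passed[res$per_gene$gene_id == "gB"]))
})
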