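# Scan statistic and permutation test for clustered substitutions.

test_that("substitution positions are reported in gap-stripped coordinates", {
  cds <- paste(rep("ATGGCTAAACCCTTC", 1), collapse = "")
  a <- codon_alignment("g", cds, cds)
  expect_length(substitution_positions(a)$positions, 0L)
  # one mismatch at gap-stripped position 7
  b <- cds
  substr(b, 8, 8) <- "T"
  m <- substitution_positions(codon_alignment("g", cds, b))
  expect_identical(m$positions, 7L)
  # a gap codon before the mismatch shifts the reported coordinate
  ga <- paste0(substr(cds, 1, 3), "---", substr(cds, 4, 15))
  gb <- paste0(substr(b, 1, 3), "---", substr(b, 4, 15))
  m2 <- substitution_positions(codon_alignment("g", ga, gb))
  expect_identical(m2$positions, 7L)
  expect_identical(m2$length, 15L)
})

test_that("codon coordinates collapse within-codon differences", {
  a <- "ATGGCTAAA"
  b <- "ATGGTCAAA" # two diffs inside codon 2
  m <- substitution_positions(codon_alignment("g", a, b),
                              coords = "codon")
  expect_identical(m$positions, 1L)
  expect_identical(m$length, 3L)
})

test_that("the scan statistic is the minimal window over ceil(k/2)+1 hits", {
  m <- substitution_map("g", 300L, c(0L, 1L, 2L))
  expect_identical(cluster_statistic(m), 3L)
  # for k = 3 the window spans all substitutions, so equally spaced
  # end-to-end placement maximizes the statistic; brute-force over every
  # placement in a short sequence
  L <- 21L
  even <- substitution_map("g", L, c(0L, 10L, 20L))
  s_even <- cluster_statistic(even)
  all_stats <- combn(L, 3, function(ix) {
    cluster_statistic(substitution_map("g", L, sort(ix) - 1L))
  })
  expect_identical(s_even, max(all_stats))
  expect_error(cluster_statistic(substitution_map("g", 10L, 3L)),
               "fewer than 2")
})

test_that("tight clusters get small p-values, spread positions do not", {
  tight <- substitution_map("g", 900L, as.integer(0:5))
  r1 <- cluster_test(tight, n_perm = 999, seed = 4)
  expect_lte(r1$p_value, 0.05)
  far <- substitution_map("g", 900L, c(0L, 899L))
  r2 <- cluster_test(far, n_perm = 999, seed = 4)
  expect_gt(r2$p_value, 0.5)
  expect_error(cluster_test(tight, n_perm = 0), "at least 99")
  expect_error(cluster_test(substitution_map("g", 4L, c(0L, 1L, 2L, 3L)),
                            n_perm = 999), NA)
})

test_that("the permutation test is reproducible and seed-sensitive", {
  m <- substitution_map("g", 500L, as.integer(c(3, 9, 40, 240, 241, 300)))
  r1 <- cluster_test(m, n_perm = 199, seed = 10)
  r2 <- cluster_test(m, n_perm = 199, seed = 10)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("p-values are invariant to sequence reversal", {
  set.seed(12)
  for (i in 1:10) {
    L <- 400L
    pos <- sort(sample.int(L, 7L) - 1L)
    m <- substitution_map("g", L, pos)
    mr <- substitution_map("g", L, sort(L - 1L - pos))
    expect_identical(cluster_test(m, 499, seed = i)$p_value,
                     cluster_test(mr, 499, seed = i)$p_value)
  }
})

test_that("clustered genes have higher power than uniform genes", {
  set.seed(21)
  L <- 900L
  k <- 8L
  win <- max(2L, as.integer(0.05 * L))
  p_clu <- vapply(1:60, function(i) {
    start <- sample.int(L - win, 1L)
    pos <- sort(sample(seq(start, start + win - 1L), k)) - 1L
    cluster_test(substitution_map("g", L, pos), 199, seed = i)$p_value
  }, numeric(1))
  p_uni <- vapply(1:60, function(i) {
    pos <- sort(sample.int(L, k) - 1L)
    cluster_test(substitution_map("g", L, pos), 199, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(p_clu <= 0.05), mean(p_uni <= 0.05))
})

test_that("on a shallow cohort where all positive-selection genes are
           clustered, most Ka/Ks > 2 genes test significant", {
  # every gene under strong positive selection, all with their
  # nonsynonymous rate confined to a 5%-of-length window, at a
  # study-like shallow divergence (Ks about 0.02)
  mix <- c(strong_purifying = 0, moderate_purifying = 0,
           relaxed_purifying = 0, near_neutral = 0,
           weak_positive = 0, strong_positive = 1)
  co <- simulate_cohort(250, category_mixture = mix,
                        clustered_fraction = 1,
                        divergence_scale = 0.05, seed = 60)
  alns <- lapply(seq_along(co$seq_a), function(i) {
    codon_alignment(co$truth$gene_id[i], co$seq_a[[i]], co$seq_b[[i]])
  })
  est <- suppressMessages(kaks_table(alns, method = "YN00"))
  kept <- suppressMessages(filter_estimates(est))
  cand <- kept$gene_id[kept$ratio > 2]
  expect_gt(length(cand), 10L)
  names(alns) <- co$truth$gene_id
  pv <- vapply(cand, function(g) {
    m <- substitution_positions(alns[[g]])
    if (length(m$positions) < 2) return(NA_real_)
    cluster_test(m, n_perm = 499, seed = match(g, cand))$p_value
  }, numeric(1))
  expect_gt(mean(pv <= 0.05, na.rm = TRUE), 0.57)
})

test_that("substitution maps round-trip through the TSV reader", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength\tpositions",
               "g1\t100\t3,5,40",
               "g2\t60\t0,59"), tf)
  maps <- read_substitution_maps(tf)
  expect_length(maps, 2L)
  expect_identical(maps[[1]]$positions, c(3L, 5L, 40L))
  expect_identical(maps[[2]]$length, 60L)
})
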