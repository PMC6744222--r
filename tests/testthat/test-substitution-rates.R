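# NG86 and YN00-style Ka/Ks estimation.

test_that("NG86 site counting matches hand-enumerated codons", {
  expect_equal(count_sites_ng86("TTT"), c(S = 1 / 3, N = 8 / 3))
  # ATG: none of the 9 single-nt mutants is synonymous (stops count as
  # nonsynonymous)
  expect_equal(count_sites_ng86("ATG"), c(S = 0, N = 3))
  # additivity over codons
  expect_equal(count_sites_ng86(strrep("TTT", 10))[["S"]], 10 / 3)
  expect_error(count_sites_ng86("TAA"), "stop codon")
})

test_that("site counts always partition 3 sites per codon", {
  ct <- standard_codon_table()
  for (cd in ct$sense) {
    expect_equal(sum(count_sites_ng86(cd)), 3)
  }
})

test_that("NG86 difference counting handles 1- and 2-step codon pairs", {
  expect_equal(count_differences_ng86(list(a = "TTT", b = "TTT")),
               c(Sd = 0, Nd = 0))
  expect_equal(count_differences_ng86(list(a = "TTT", b = "TTC")),
               c(Sd = 1, Nd = 0))
  # TTT -> GTA: average of paths via GTT (1 syn + 1 nonsyn) and via TTA
  # (2 nonsyn)
  expect_equal(count_differences_ng86(list(a = "TTT", b = "GTA")),
               c(Sd = 0.5, Nd = 1.5))
})

test_that("pathway averaging matches the brute-force path enumerator", {
  # spot-check a mixed set here; the exhaustive 61x61 sweep runs in the
  # acceptance suite
  pairs <- list(c("TTT", "GTA"), c("ATG", "TGG"), c("AAA", "CCC"),
                c("TCA", "ACT"), c("CGG", "AGA"), c("GGG", "TTT"))
  for (pr in pairs) {
    oracle <- oracle_pathway_counts(pr[1], pr[2])
    got <- count_differences_ng86(list(a = pr[1], b = pr[2]))
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12,
                 info = paste(pr, collapse = "->"))
  }
})

test_that("NG86 estimate applies the Jukes-Cantor correction", {
  # identical sequences: zero rates, undefined ratio
  cds <- paste(rep("ATGGCTAAA", 10), collapse = "")
  e <- estimate_ng86(codon_alignment("g", cds, cds))
  expect_equal(e$ka, 0)
  expect_equal(e$ks, 0)
  expect_true(is.na(e$ratio))
  # closed form: ps = 0.1 -> Ks = -0.75 log(1 - 0.4/3)
  expect_equal(pogdiv:::jc_correct(0.1, 100)[["d"]],
               -0.75 * log(1 - 0.4 / 3))
  expect_error(pogdiv:::jc_correct(0.8, 100), "saturation")
})

test_that("estimates are invariant under swapping the two sequences", {
  p <- simulate_codon_pair(300, omega = 0.4, t = 0.4, seed = 11)
  a1 <- codon_alignment("g", p$cds_a, p$cds_b)
  a2 <- codon_alignment("g", p$cds_b, p$cds_a)
  for (fn in list(estimate_ng86, estimate_yn00)) {
    e1 <- suppressWarnings(fn(a1))
    e2 <- suppressWarnings(fn(a2))
    expect_equal(e1$ka, e2$ka)
    expect_equal(e1$ks, e2$ks)
    expect_equal(e1$s_sites, e2$s_sites)
  }
})

test_that("kappa estimation responds to transition-only differences and
           falls back without information", {
  # 20 identical codons -> no differences -> default kappa with warning
  cds <- paste(rep("GGTGCTCCTACT", 5), collapse = "")
  expect_warning(k0 <- estimate_kappa(codon_alignment("g", cds, cds)),
                 "no information")
  expect_equal(k0, 2)
  # transition-rich fourfold third positions -> kappa > 1
  a <- paste(rep("GGT", 20), collapse = "")
  b <- paste(c(rep("GGC", 4), "GGA", rep("GGT", 15)), collapse = "")
  k <- estimate_kappa(codon_alignment("g", a, b))
  expect_gt(k, 1)
  # transversion-only differences -> kappa < 1
  b2 <- paste(c(rep("GGA", 5), rep("GGT", 15)), collapse = "")
  expect_lt(estimate_kappa(codon_alignment("g", a, b2)), 1)
})

test_that("kappa is recovered from simulated data", {
  ks <- vapply(1:30, function(i) {
    p <- simulate_codon_pair(1000, omega = 0.3, kappa = 2, t = 0.5,
                             seed = 500 + i)
    suppressWarnings(
      estimate_kappa(codon_alignment("g", p$cds_a, p$cds_b)))
  }, numeric(1))
  expect_gt(mean(ks), 1.6)
  expect_lt(mean(ks), 2.4)
})

test_that("YN00 reduces to NG86 site counts at kappa 1, uniform freqs", {
  p <- simulate_codon_pair(400, omega = 0.5, t = 0.3, seed = 21)
  aln <- codon_alignment("g", p$cds_a, p$cds_b)
  e_ng <- estimate_ng86(aln)
  e_yn <- estimate_yn00(aln, kappa = 1, codon_freqs = "uniform")
  expect_equal(e_yn$s_sites, e_ng$s_sites, tolerance = 1e-9)
  expect_equal(e_yn$n_sites, e_ng$n_sites, tolerance = 1e-9)
})

test_that("site counts conserve 3 sites per ungapped codon (both methods)", {
  p <- simulate_codon_pair(200, omega = 0.8, t = 0.4, seed = 31)
  aln <- codon_alignment("g", p$cds_a, p$cds_b)
  for (e in list(estimate_ng86(aln), suppressWarnings(estimate_yn00(aln)))) {
    expect_equal(e$s_sites + e$n_sites, 3 * e$n_codons, tolerance = 1e-9)
    expect_lte(e$sd, e$s_sites)
    expect_lte(e$nd, e$n_sites)
  }
})

test_that("identical sequences give zero rates under YN00", {
  cds <- paste(rep("ATGGCTAAACCCTTC", 4), collapse = "")
  e <- suppressWarnings(estimate_yn00(codon_alignment("g", cds, cds)))
  expect_equal(e$ka, 0)
  expect_equal(e$ks, 0)
})

test_that("Ks = 0 with Ka > 0 carries the 99 sentinel", {
  # one nonsynonymous difference, no synonymous ones
  a <- paste(rep("ATGGCT", 10), collapse = "")
  b <- sub("^ATGGCT", "ATGACT", a) # GCT(Ala)->ACT(Thr), nonsyn
  e <- estimate_ng86(codon_alignment("g", a, b))
  expect_equal(e$ks, 0)
  expect_gt(e$ka, 0)
  expect_equal(e$ratio, 99)
})

test_that("mean YN00 ratio tracks true omega on simulated pairs", {
  est <- vapply(1:25, function(i) {
    aln <- sim_alignment(800, omega = 0.2, t = 0.4, seed = 900 + i)
    suppressWarnings(estimate_yn00(aln))$ratio
  }, numeric(1))
  expect_lt(abs(mean(est) / 0.2 - 1), 0.15)
})
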