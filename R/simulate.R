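# Codon-model simulator: gene pairs diverged under a continuous-time
# Markov codon model with rates proportional to
# kappa^(transition) x omega^(nonsynonymous) x pi(target codon), stop
# codons unreachable.  Branch lengths are expressed as expected
# substitutions per codon summed over both branches under the neutral
# (omega = 1) normalization, so estimator-recovery targets are
# well-defined.

# Build (and cache) the rate structure for a given kappa and codon
# frequency scheme.  omega enters only through the nonsynonymous part, so
# the same structure serves all omega values.
codon_model <- function(kappa = 2, codon_freqs = "uniform") {
  key <- paste0("model_", kappa, "_",
                if (is.character(codon_freqs)) codon_freqs
                else paste(signif(codon_freqs, 6), collapse = ","))
  if (!is.null(.pogdiv_cache[[key]])) return(.pogdiv_cache[[key]])
  ct <- standard_codon_table()
  n <- length(ct$sense)
  pi <- if (identical(codon_freqs, "uniform")) rep(1 / n, n)
  else {
    stopifnot(is.numeric(codon_freqs), length(codon_freqs) == n)
    codon_freqs / sum(codon_freqs)
  }
  names(pi) <- ct$sense
  nb <- ct$neighbors[ct$neighbors$class != "stop", ]
  nb$w <- ifelse(nb$is_ts, kappa, 1) * pi[nb$to]
  idx <- match(nb$from, ct$sense)
  tidx <- match(nb$to, ct$sense)

  pad <- 9L
  build <- function(sel) {
    Tm <- matrix(0L, n, pad)
    CW <- matrix(Inf, n, pad)
    tot <- numeric(n)
    for (u in seq_len(n)) {
      rows <- which(idx == u & sel)
      if (length(rows) == 0L) next
      w <- nb$w[rows]
      tot[u] <- sum(w)
      Tm[u, seq_along(rows)] <- tidx[rows]
      CW[u, seq_along(rows)] <- cumsum(w)
    }
    list(targets = Tm, cumw = CW, total = tot)
  }
  syn <- build(nb$class == "syn")
  nonsyn <- build(nb$class == "nonsyn")
  mu <- sum(pi * (syn$total + nonsyn$total)) # neutral normalization
  m <- list(sense = ct$sense, pi = pi, kappa = kappa,
            syn = syn, nonsyn = nonsyn, mu = mu)
  .pogdiv_cache[[key]] <- m
  m
}

# Evolve integer codon states along one branch of length tlen (expected
# neutral substitutions per codon).  omega_vec is per-codon.  Returns the
# final states plus realized synonymous/nonsynonymous event counts.
evolve_branch <- function(states, tlen, model, omega_vec) {
  n <- length(states)
  syn_events <- 0L
  nonsyn_events <- 0L
  if (tlen <= 0 || n == 0L) {
    return(list(states = states, syn = 0L, nonsyn = 0L))
  }
  time_left <- rep(tlen, n)
  active <- seq_len(n)
  while (length(active) > 0L) {
    u <- states[active]
    rs <- model$syn$total[u]
    rn <- omega_vec[active] * model$nonsyn$total[u]
    rate <- (rs + rn) / model$mu
    dt <- rep(Inf, length(active))
    pos <- rate > 0
    dt[pos] <- stats::rexp(sum(pos), rate[pos])
    hit <- dt < time_left[active]
    time_left[active] <- time_left[active] - dt
    act <- active[hit]
    if (length(act) > 0L) {
      u <- states[act]
      rs <- model$syn$total[u]
      rn <- omega_vec[act] * model$nonsyn$total[u]
      pick_syn <- stats::runif(length(act)) < rs / (rs + rn)
      for (grp in list(list(sel = pick_syn, part = model$syn),
                       list(sel = !pick_syn, part = model$nonsyn))) {
        ii <- which(grp$sel)
        if (length(ii) == 0L) next
        uu <- states[act[ii]]
        r <- stats::runif(length(ii)) * grp$part$total[uu]
        cw <- grp$part$cumw[uu, , drop = FALSE]
        col <- rowSums(r > cw) + 1L
        states[act[ii]] <- grp$part$targets[cbind(uu, col)]
      }
      syn_events <- syn_events + sum(pick_syn)
      nonsyn_events <- nonsyn_events + sum(!pick_syn)
    }
    active <- active[hit]
  }
  list(states = states, syn = syn_events, nonsyn = nonsyn_events)
}

#' Simulate one diverged codon pair
#'
#' Draws an ancestral sequence from the codon frequencies and evolves two
#' independent branches of length `t/2` under the codon model. `t` is the
#' expected number of substitutions per codon summed over both branches
#' at omega = 1; the realized synonymous/nonsynonymous event counts are
#' returned as ground truth.
#'
#' @param n_codons Gene length in codons.
#' @param omega True dN/dS (>= 0); either a scalar or a per-codon vector
#'   (used for spatially clustered nonsynonymous rates).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param t Expected substitutions per codon over both branches under the
#'   neutral normalization.
#' @param codon_freqs `"uniform"` or a numeric vector of 61 sense-codon
#'   frequencies.
#' @param seed Integer seed; the pair is fully reproducible from it.
#' @return List with `cds_a`, `cds_b` (nucleotide strings, no stops, no
#'   N), and `truth` (list: `omega`, `t`, `kappa`, `n_codons`,
#'   `syn_events`, `nonsyn_events`).
#' @export
#' @examples
#' p <- simulate_codon_pair(100, omega = 0.2, t = 0.3, seed = 1)
#' substr(p$cds_a, 1, 30)
simulate_codon_pair <- function(n_codons, omega, kappa = 2, t = 0.3,
                                codon_freqs = "uniform", seed = 1L) {
  stopifnot(n_codons >= 1, all(omega >= 0), kappa > 0, t >= 0)
  model <- codon_model(kappa, codon_freqs)
  omega_vec <- if (length(omega) == 1L) rep(omega, n_codons)
  else {
    stopifnot(length(omega) == n_codons)
    omega
  }
  with_seed(seed, {
    anc <- sample.int(61L, n_codons, replace = TRUE, prob = model$pi)
    ba <- evolve_branch(anc, t / 2, model, omega_vec)
    bb <- evolve_branch(anc, t / 2, model, omega_vec)
    list(
      cds_a = paste(model$sense[ba$states], collapse = ""),
      cds_b = paste(model$sense[bb$states], collapse = ""),
      truth = list(omega = if (length(omega) == 1L) omega else mean(omega),
                   t = t, kappa = kappa, n_codons = n_codons,
                   syn_events = ba$syn + bb$syn,
                   nonsyn_events = ba$nonsyn + bb$nonsyn)
    )
  })
}

# Default per-category omega sampling ranges, kept away from the category
# boundaries so that estimation noise does not systematically relabel
# genes.
default_omega_ranges <- function() {
  list(strong_purifying   = c(0.01, 0.09),
       moderate_purifying = c(0.12, 0.45),
       relaxed_purifying  = c(0.55, 0.85),
       near_neutral       = c(0.92, 1.08),
       weak_positive      = c(1.20, 1.90),
       strong_positive    = c(2.20, 6.00))
}

# Default category mixture: moderate > strong purifying > relaxed >
# weak positive > near-neutral > strong positive, with the positive and
# neutral shares in the few-percent range reported for allopatric
# transcriptome pairs.
default_category_mixture <- function() {
  c(strong_purifying = 0.26, moderate_purifying = 0.51,
    relaxed_purifying = 0.13, near_neutral = 0.025,
    weak_positive = 0.06, strong_positive = 0.015)
}

#' Simulate a cohort of ortholog pairs
#'
#' Each gene draws a selection category from `category_mixture`, an omega
#' uniform within that category's range, and a diverged codon pair at
#' divergence `divergence_scale`. A fraction `clustered_fraction` of the
#' strong-positive genes concentrate their nonsynonymous rate in a
#' contiguous window of 5% of the gene (local omega scaled so the
#' gene-wide average omega is unchanged), providing positives for the
#' variation-cluster test.
#'
#' @param n_genes Number of gene pairs.
#' @param category_mixture Named vector of six proportions summing to 1.
#' @param omega_ranges Named list of per-category `c(lo, hi)` sampling
#'   ranges.
#' @param divergence_scale Branch-length parameter `t` passed to
#'   [simulate_codon_pair()] (default 0.1, giving a Ks scale near the
#'   upper-middle of the peak-Ks range observed across allopatric
#'   transcriptome pairs).
#' @param clustered_fraction Fraction of strong-positive genes with
#'   clustered nonsynonymous substitutions (default 0.8).
#' @param n_codons Gene length in codons (default 500); alternatively
#'   `len_range = c(lo, hi)` draws per-gene lengths uniformly.
#' @param len_range Optional `c(lo, hi)` codon-length range.
#' @param kappa Transition/transversion ratio (default 2).
#' @param seed Integer root seed.
#' @param dir Optional directory: writes `<prefix>_a.fasta`,
#'   `<prefix>_b.fasta` and `<prefix>_truth.tsv` there.
#' @param prefix File prefix when `dir` is given (default "cohort").
#' @return List with `seq_a`, `seq_b` (named character vectors) and
#'   `truth` (data.frame: `gene_id`, `category`, `omega`, `t`,
#'   `n_codons`, `clustered`, `syn_events`, `nonsyn_events`).
#' @export
simulate_cohort <- function(n_genes,
                            category_mixture = default_category_mixture(),
                            omega_ranges = default_omega_ranges(),
                            divergence_scale = 0.1,
                            clustered_fraction = 0.8,
                            n_codons = 500L, len_range = NULL,
                            kappa = 2, seed = 1L,
                            dir = NULL, prefix = "cohort") {
  stopifnot(abs(sum(category_mixture) - 1) < 1e-8)
  cats <- names(default_category_mixture())
  stopifnot(setequal(names(category_mixture), cats))
  if (n_genes == 0L) {
    out <- list(seq_a = stats::setNames(character(0), character(0)),
                seq_b = stats::setNames(character(0), character(0)),
                truth = data.frame(gene_id = character(0),
                                   category = character(0),
                                   omega = numeric(0), t = numeric(0),
                                   n_codons = integer(0),
                                   clustered = logical(0),
                                   syn_events = integer(0),
                                   nonsyn_events = integer(0)))
    if (!is.null(dir)) write_cohort(out, dir, prefix)
    return(out)
  }
  draws <- with_seed(seed, {
    cat_draw <- sample(cats, n_genes, replace = TRUE,
                       prob = category_mixture[cats])
    omega <- vapply(cat_draw, function(cc) {
      stats::runif(1, omega_ranges[[cc]][1], omega_ranges[[cc]][2])
    }, numeric(1))
    lens <- if (is.null(len_range)) rep(as.integer(n_codons), n_genes)
    else as.integer(round(stats::runif(n_genes, len_range[1],
                                       len_range[2])))
    clustered <- cat_draw == "strong_positive" &
      stats::runif(n_genes) < clustered_fraction
    win_start <- stats::runif(n_genes) # relative window start
    list(cat = cat_draw, omega = omega, lens = lens,
         clustered = clustered, win_start = win_start)
  })
  ids <- sprintf("g%05d", seq_len(n_genes))
  seq_a <- character(n_genes)
  seq_b <- character(n_genes)
  syn_ev <- integer(n_genes)
  nonsyn_ev <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    L <- draws$lens[i]
    om <- draws$omega[i]
    if (draws$clustered[i]) {
      wlen <- max(2L, as.integer(round(0.05 * L)))
      start <- 1L + as.integer(floor(draws$win_start[i] * (L - wlen)))
      ov <- rep(0, L)
      ov[start:(start + wlen - 1L)] <- om * L / wlen
      om <- ov
    }
    sim <- simulate_codon_pair(L, om, kappa = kappa,
                               t = divergence_scale,
                               seed = derive_seed(seed, i))
    seq_a[i] <- sim$cds_a
    seq_b[i] <- sim$cds_b
    syn_ev[i] <- sim$truth$syn_events
    nonsyn_ev[i] <- sim$truth$nonsyn_events
  }
  out <- list(
    seq_a = stats::setNames(seq_a, ids),
    seq_b = stats::setNames(seq_b, ids),
    truth = data.frame(gene_id = ids, category = draws$cat,
                       omega = draws$omega, t = divergence_scale,
                       n_codons = draws$lens,
                       clustered = draws$clustered,
                       syn_events = syn_ev, nonsyn_events = nonsyn_ev,
                       stringsAsFactors = FALSE)
  )
  if (!is.null(dir)) write_cohort(out, dir, prefix)
  out
}

# Linear interpolation between the young-pair and old-pair category
# mixtures: with divergence time the moderate-purifying share grows and
# the strong-purifying and positive shares shrink.
drifted_mixture <- function(time_mya, t_min = 1.69, t_max = 10.67) {
  young <- c(strong_purifying = 0.32, moderate_purifying = 0.42,
             relaxed_purifying = 0.13, near_neutral = 0.02,
             weak_positive = 0.075, strong_positive = 0.035)
  old <- c(strong_purifying = 0.17, moderate_purifying = 0.60,
           relaxed_purifying = 0.13, near_neutral = 0.02,
           weak_positive = 0.05, strong_positive = 0.03)
  a <- (min(max(time_mya, t_min), t_max) - t_min) / (t_max - t_min)
  (1 - a) * young + a * old
}

#' Simulate a panel of taxon pairs spanning a divergence-time range
#'
#' Each taxon pair receives a cohort whose branch length is
#' `calibration x divergence time` and (by default) a category mixture
#' that drifts with time: older pairs carry more moderate-purifying and
#' fewer strong-purifying/positive genes, so peak Ks and the category
#' abundances are recoverably associated with time.
#'
#' @param n_pairs Number of taxon pairs (default 20).
#' @param times_mya Divergence times; default evenly spaced over
#'   1.69-10.67 mya.
#' @param calibration Expected neutral substitutions per codon per mya
#'   (default 0.013).
#' @param n_genes Genes per cohort (default 600).
#' @param n_codons Gene length in codons (default 500).
#' @param kappa Transition/transversion ratio (default 2).
#' @param mixture_drift Logical; `FALSE` freezes the mixture at the
#'   default cohort mixture for null-panel checks.
#' @param clustered_fraction Passed to [simulate_cohort()].
#' @param seed Integer root seed.
#' @return List with `cohorts` (list of [simulate_cohort()] outputs named
#'   by pair id) and `panel` (data.frame of ground truth: `pair_id`,
#'   `divergence_time_mya`, `t`, and the six true mixture proportions as
#'   `mix_<category>`).
#' @export
simulate_pair_panel <- function(n_pairs = 20L,
                                times_mya = seq(1.69, 10.67,
                                                length.out = n_pairs),
                                calibration = 0.013,
                                n_genes = 600L, n_codons = 500L,
                                kappa = 2, mixture_drift = TRUE,
                                clustered_fraction = 0.8,
                                seed = 1L) {
  stopifnot(length(times_mya) == n_pairs, all(times_mya > 0))
  pair_ids <- sprintf("pair%02d", seq_len(n_pairs))
  cohorts <- vector("list", n_pairs)
  names(cohorts) <- pair_ids
  mixes <- matrix(0, n_pairs, 6,
                  dimnames = list(pair_ids,
                                  paste0("mix_", SELECTION_CATEGORIES)))
  for (i in seq_len(n_pairs)) {
    mix <- if (mixture_drift) drifted_mixture(times_mya[i])
    else default_category_mixture()
    mixes[i, ] <- mix[SELECTION_CATEGORIES]
    cohorts[[i]] <- simulate_cohort(
      n_genes, category_mixture = mix,
      divergence_scale = calibration * times_mya[i],
      clustered_fraction = clustered_fraction,
      n_codons = n_codons, kappa = kappa,
      seed = derive_seed(seed, 1000L + i)
    )
  }
  panel <- data.frame(pair_id = pair_ids,
                      divergence_time_mya = times_mya,
                      t = calibration * times_mya,
                      stringsAsFactors = FALSE)
  panel <- cbind(panel, as.data.frame(mixes))
  rownames(panel) <- NULL
  list(cohorts = cohorts, panel = panel)
}
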