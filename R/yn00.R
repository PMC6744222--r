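# YN00-style estimation: transition/transversion bias (kappa) and codon
# frequency bias enter the site and difference counting; omega and the
# counts are updated iteratively until convergence.

#' Estimate the transition/transversion rate ratio (kappa)
#'
#' kappa is estimated from fourfold-degenerate and nondegenerate codon
#' positions (classified identically in both sequences), using the K80
#' multiple-hit correction within each class and pooling the transition
#' and transversion distances weighted by the number of sites in each
#' class.
#'
#' @param aln A [codon_alignment()] object.
#' @param default_kappa Value returned (with a warning) when the alignment
#'   carries no usable information (no differences at degenerate sites, or
#'   saturation).
#' @return Estimated kappa (> 0).
#' @export
estimate_kappa <- function(aln, default_kappa = 2) {
  cods <- strip_gap_codons(aln)
  ct <- standard_codon_table()
  nb <- ct$neighbors
  # number of synonymous alternatives at each codon position, per codon
  syn_by_pos <- tapply(nb$class == "syn",
                       list(nb$from, nb$pos), sum)
  degen_class <- function(codons) {
    m <- syn_by_pos[codons, , drop = FALSE]
    cl <- matrix("other", nrow(m), 3L)
    cl[m == 3L] <- "four"
    cl[m == 0L] <- "zero"
    cl
  }
  ca <- degen_class(cods$a)
  cb <- degen_class(cods$b)
  ba <- matrix(unlist(strsplit(cods$a, "")), ncol = 3L, byrow = TRUE)
  bb <- matrix(unlist(strsplit(cods$b, "")), ncol = 3L, byrow = TRUE)
  is_ts <- (ba == "A" & bb == "G") | (ba == "G" & bb == "A") |
    (ba == "C" & bb == "T") | (ba == "T" & bb == "C")
  differ <- ba != bb

  ts_d <- 0
  tv_d <- 0
  n_tot <- 0
  for (cls in c("four", "zero")) {
    use <- ca == cls & cb == cls
    n <- sum(use)
    if (n == 0L) next
    P <- sum(differ & is_ts & use) / n
    Q <- sum(differ & !is_ts & use) / n
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      warning("saturation at ", cls, "-fold degenerate sites; ",
              "class skipped in kappa estimation")
      next
    }
    d_ts <- -0.5 * log(1 - 2 * P - Q) + 0.25 * log(1 - 2 * Q)
    d_tv <- -0.5 * log(1 - 2 * Q)
    ts_d <- ts_d + n * d_ts
    tv_d <- tv_d + n * d_tv
    n_tot <- n_tot + n
  }
  if (n_tot == 0L || (ts_d == 0 && tv_d == 0)) {
    warning("no information to estimate kappa; using default ",
            default_kappa)
    return(default_kappa)
  }
  if (tv_d == 0) {
    warning("no transversions observed; kappa capped at 99")
    return(99)
  }
  max(2 * ts_d / tv_d, 1e-6)
}

# Position-specific base frequencies from the two sequences (F3x4), a
# single pooled frequency vector (F1x4), or uniform.
codon_position_freqs <- function(cods, scheme = c("F3x4", "F1x4", "uniform")) {
  scheme <- match.arg(scheme)
  f <- matrix(0.25, nrow = 3, ncol = 4, dimnames = list(NULL, .BASES))
  if (scheme == "uniform") return(f)
  b <- matrix(unlist(strsplit(c(cods$a, cods$b), "")),
              ncol = 3L, byrow = TRUE)
  if (scheme == "F1x4") {
    tab <- table(factor(b, levels = .BASES))
    p <- as.numeric(tab) / sum(tab)
    p[p == 0] <- 1e-6
    p <- p / sum(p)
    for (i in 1:3) f[i, ] <- p
    return(f)
  }
  for (i in 1:3) {
    tab <- table(factor(b[, i], levels = .BASES))
    p <- as.numeric(tab) / sum(tab)
    p[p == 0] <- 1e-6
    f[i, ] <- p / sum(p)
  }
  f
}

# Weighted per-codon synonymous site counts: at each position the three
# alternatives are weighted by kappa^(transition) times the frequency of
# the target base at that codon position; stop-codon-creating changes stay
# in the denominator as nonsynonymous, so s_u + n_u = 3 per codon.
yn00_site_vector <- function(kappa, freqs) {
  ct <- standard_codon_table()
  nb <- ct$neighbors
  to_base <- substr(nb$to, nb$pos, nb$pos)
  w <- ifelse(nb$is_ts, kappa, 1) *
    freqs[cbind(nb$pos, match(to_base, .BASES))]
  key <- paste(nb$from, nb$pos)
  tot <- tapply(w, key, sum)
  syn <- tapply(w * (nb$class == "syn"), key, sum)
  frac <- syn / tot
  s <- tapply(frac, sub(" .*", "", names(frac)), sum)
  out <- as.numeric(s[ct$sense])
  names(out) <- ct$sense
  out
}

# Weighted pathway-averaged difference counts for one codon pair under
# current omega/kappa/frequencies.  Paths through stop codons are
# excluded; remaining paths are weighted by the product of their step
# rates.
yn00_pair_diff <- function(c1, c2, kappa, omega, freqs, aa) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffpos <- which(b1 != b2)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k,
                  list(1L),
                  list(1:2, 2:1),
                  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                       c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  is_ts <- function(x, y) {
    (x == "A" && y == "G") || (x == "G" && y == "A") ||
      (x == "C" && y == "T") || (x == "T" && y == "C")
  }
  sd_w <- 0
  nd_w <- 0
  w_tot <- 0
  for (ord in perms) {
    cur <- b1
    w <- 1
    sd_p <- 0
    nd_p <- 0
    ok <- TRUE
    for (p in diffpos[ord]) {
      nxt <- cur
      nxt[p] <- b2[p]
      to <- paste(nxt, collapse = "")
      if (aa[[to]] == "*") {
        ok <- FALSE
        break
      }
      syn <- aa[[to]] == aa[[paste(cur, collapse = "")]]
      w <- w * (if (is_ts(cur[p], b2[p])) kappa else 1) *
        unname(freqs[p, b2[p]]) * (if (syn) 1 else omega)
      if (syn) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (ok && w > 0) {
      sd_w <- sd_w + w * sd_p
      nd_w <- nd_w + w * nd_p
      w_tot <- w_tot + w
    }
  }
  if (w_tot == 0) {
    # all paths blocked or zero-weight: fall back to unweighted NG86 counts
    tabs <- ng86_difference_tables()
    return(c(sd = tabs$SD[c1, c2], nd = tabs$ND[c1, c2]))
  }
  c(sd = sd_w / w_tot, nd = nd_w / w_tot)
}

#' Estimate Ka and Ks by a YN00-style counting method
#'
#' Like NG86 but with synonymous/nonsynonymous site counts weighted by the
#' transition/transversion rate ratio (kappa, estimated from the data by
#' default) and by F3x4 codon-position base frequencies, and with pathway
#' weights for multi-position codon differences that depend on the current
#' omega. Omega and the difference counts are updated iteratively until
#' the change in omega falls below `tol`.
#'
#' @inheritParams estimate_ng86
#' @param kappa Fixed kappa; `NULL` (default) estimates it with
#'   [estimate_kappa()].
#' @param codon_freqs Frequency scheme for the site weights: `"F3x4"`
#'   (default), `"F1x4"` or `"uniform"`.
#' @param tol Convergence tolerance on omega (default 1e-6).
#' @param max_iter Maximum iterations (default 100); non-convergence
#'   raises an error of class `pogdiv_nonconvergence` carrying the last
#'   iterate in its `estimate` field.
#' @return A `kaks_estimate` object with `method = "YN00"`.
#' @export
estimate_yn00 <- function(aln, kappa = NULL,
                          codon_freqs = c("F3x4", "F1x4", "uniform"),
                          tol = 1e-6, max_iter = 100L) {
  codon_freqs <- match.arg(codon_freqs)
  cods <- strip_gap_codons(aln)
  n_codons <- length(cods$a)
  if (n_codons < 1L) stop("no ungapped codons in alignment ", aln$gene_id)
  if (is.null(kappa)) {
    kappa <- suppressWarnings(estimate_kappa(aln))
  }
  ct <- standard_codon_table()
  freqs <- codon_position_freqs(cods, codon_freqs)
  svec <- yn00_site_vector(kappa, freqs)
  S <- (sum(svec[cods$a]) + sum(svec[cods$b])) / 2
  N <- 3 * n_codons - S
  if (S <= 0) stop("no synonymous sites; Ks undefined")

  differ <- cods$a != cods$b
  if (!any(differ)) {
    return(kaks_estimate(aln$gene_id, "YN00", ka = 0, ks = 0,
                         se_ka = 0, se_ks = 0, s_sites = S, n_sites = N,
                         sd = 0, nd = 0, kappa = kappa,
                         n_codons = n_codons))
  }
  pairs <- paste(cods$a[differ], cods$b[differ])
  pair_counts <- table(pairs)
  upairs <- strsplit(names(pair_counts), " ")

  omega <- 1
  est <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Sd <- 0
    Nd <- 0
    for (i in seq_along(upairs)) {
      d <- yn00_pair_diff(upairs[[i]][1], upairs[[i]][2],
                          kappa, omega, freqs, ct$aa)
      Sd <- Sd + d[["sd"]] * pair_counts[[i]]
      Nd <- Nd + d[["nd"]] * pair_counts[[i]]
    }
    ks <- jc_correct(Sd / S, S)
    ka <- jc_correct(Nd / N, N)
    est <- kaks_estimate(aln$gene_id, "YN00", ka = ka[["d"]], ks = ks[["d"]],
                         se_ka = ka[["se"]], se_ks = ks[["se"]],
                         s_sites = S, n_sites = N, sd = Sd, nd = Nd,
                         kappa = kappa, n_codons = n_codons)
    omega_new <- if (est$ks > 0) est$ka / est$ks else omega
    if (abs(omega_new - omega) < tol) {
      converged <- TRUE
      omega <- omega_new
      break
    }
    omega <- omega_new
  }
  if (!converged) {
    cond <- structure(
      class = c("pogdiv_nonconvergence", "error", "condition"),
      list(message = paste0("YN00 iteration did not converge for gene ",
                            aln$gene_id, " (last omega = ",
                            signif(omega, 6), ")"),
           call = sys.call(-1), estimate = est)
    )
    stop(cond)
  }
  est
}

#' Estimate substitution rates for one codon alignment
#'
#' Thin dispatcher over [estimate_ng86()] and [estimate_yn00()].
#'
#' @inheritParams estimate_ng86
#' @param method `"YN00"` (default) or `"NG86"`.
#' @param ... Passed to the chosen estimator.
#' @return A `kaks_estimate` object.
#' @export
kaks <- function(aln, method = c("YN00", "NG86"), ...) {
  method <- match.arg(method)
  switch(method,
         YN00 = estimate_yn00(aln, ...),
         NG86 = estimate_ng86(aln))
}
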