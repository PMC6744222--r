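# Nei-Gojobori (1986) counting: equal-weight site counting, pathway
# averaging for codons differing at more than one position, and the
# Jukes-Cantor correction for multiple hits.

#' Count synonymous and nonsynonymous sites (NG86)
#'
#' Each codon position contributes (number of synonymous single-nucleotide
#' changes at that position)/3 synonymous sites; changes that create a
#' stop codon are counted as nonsynonymous, so S + N = 3 x (number of
#' codons) exactly.
#'
#' @param cds In-frame coding sequence (string) or a vector of codons;
#'   must contain no stop codons.
#' @return Named numeric vector with elements `S` and `N`.
#' @export
#' @examples
#' count_sites_ng86("TTT") # S = 1/3, N = 8/3
count_sites_ng86 <- function(cds) {
  ct <- standard_codon_table()
  codons <- if (length(cds) == 1L && nchar(cds[1]) > 3L) {
    split_codons(toupper(cds))
  } else {
    toupper(cds)
  }
  if (length(codons) == 0L) return(c(S = 0, N = 0))
  s <- ct$s_sites[codons]
  if (anyNA(s)) {
    bad <- codons[is.na(s)]
    if (any(bad %in% .STOPS)) {
      stop("stop codon in input: ", paste(unique(bad), collapse = ", "))
    }
    stop("unrecognized codon(s): ", paste(unique(bad), collapse = ", "))
  }
  S <- sum(s)
  c(S = S, N = 3 * length(codons) - S)
}

#' Count synonymous and nonsynonymous differences (NG86)
#'
#' Codon pairs differing at k positions are resolved by averaging the
#' synonymous/nonsynonymous step counts over all k! orderings of
#' single-nucleotide steps, excluding orderings that pass through a stop
#' codon.
#'
#' @param aln A [codon_alignment()] object, or a list with codon vectors
#'   `a` and `b` of equal length (gap columns already removed).
#' @return Named numeric vector with elements `Sd` and `Nd`.
#' @export
#' @examples
#' count_differences_ng86(list(a = "TTT", b = "TTC")) # Sd = 1, Nd = 0
count_differences_ng86 <- function(aln) {
  if (inherits(aln, "codon_alignment")) {
    aln <- strip_gap_codons(aln)
  }
  a <- toupper(aln$a)
  b <- toupper(aln$b)
  if (length(a) == 1L && nchar(a[1]) > 3L) a <- split_codons(a)
  if (length(b) == 1L && nchar(b[1]) > 3L) b <- split_codons(b)
  stopifnot(length(a) == length(b))
  diff <- a != b
  if (!any(diff)) return(c(Sd = 0, Nd = 0))
  tabs <- ng86_difference_tables()
  c(Sd = sum(tabs$SD[cbind(a[diff], b[diff])]),
    Nd = sum(tabs$ND[cbind(a[diff], b[diff])]))
}

# Jukes-Cantor correction of a proportion of differences, with its
# delta-method variance given the (possibly fractional) number of sites.
jc_correct <- function(p, sites) {
  if (p >= 0.75) {
    stop("proportion of differences (", signif(p, 4),
         ") at or beyond saturation; distance undefined")
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  v <- if (sites > 0) p * (1 - p) / sites * 9 / (3 - 4 * p)^2 else NA_real_
  c(d = d, se = sqrt(v))
}

# Assemble a substitution-rate estimate object shared by both methods.
kaks_estimate <- function(gene_id, method, ka, ks, se_ka, se_ks,
                          s_sites, n_sites, sd, nd, kappa, n_codons) {
  ratio <- if (ks > 0) ka / ks
  else if (ka > 0) RATIO_SENTINEL
  else NA_real_
  structure(
    list(gene_id = gene_id, method = method, ka = ka, ks = ks,
         ratio = ratio, se_ka = se_ka, se_ks = se_ks,
         s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
         kappa = kappa, n_codons = n_codons),
    class = "kaks_estimate"
  )
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("%s substitution-rate estimate for %s (%d codons)\n",
              x$method, x$gene_id, x$n_codons))
  cat(sprintf("  Ka = %.4f (SE %.4f)   Ks = %.4f (SE %.4f)\n",
              x$ka, x$se_ka, x$ks, x$se_ks))
  rat <- if (is.na(x$ratio)) "undefined (Ka = Ks = 0)"
  else if (x$ratio == RATIO_SENTINEL) "99 (Ks = 0)"
  else sprintf("%.4f", x$ratio)
  cat("  Ka/Ks =", rat, "\n")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f  kappa = %.2f\n",
              x$s_sites, x$n_sites, x$sd, x$nd, x$kappa))
  invisible(x)
}

#' @export
as.data.frame.kaks_estimate <- function(x, ...) {
  data.frame(gene_id = x$gene_id, method = x$method, ka = x$ka, ks = x$ks,
             ratio = x$ratio, se_ka = x$se_ka, se_ks = x$se_ks,
             s_sites = x$s_sites, n_sites = x$n_sites, sd = x$sd,
             nd = x$nd, kappa = x$kappa, n_codons = x$n_codons,
             stringsAsFactors = FALSE)
}

#' Estimate Ka and Ks by the Nei-Gojobori (1986) method
#'
#' Site counts are averaged over the two sequences, the proportions of
#' synonymous and nonsynonymous differences are corrected for multiple
#' hits with the Jukes-Cantor formula, and standard errors come from the
#' delta method on the corrected proportions.
#'
#' @param aln A [codon_alignment()] object.
#' @return A `kaks_estimate` object (fields `ka`, `ks`, `ratio`, `se_ka`,
#'   `se_ks`, `s_sites`, `n_sites`, `sd`, `nd`, `kappa`, `n_codons`).
#'   When Ks = 0 and Ka > 0 the ratio carries the conventional sentinel
#'   value 99; when both are 0 it is `NA`. Both cases are removed by
#'   [filter_estimates()] downstream.
#' @export
estimate_ng86 <- function(aln) {
  cods <- strip_gap_codons(aln)
  n_codons <- length(cods$a)
  if (n_codons < 1L) stop("no ungapped codons in alignment ", aln$gene_id)
  sa <- count_sites_ng86(cods$a)
  sb <- count_sites_ng86(cods$b)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  d <- count_differences_ng86(cods)
  if (S <= 0) stop("no synonymous sites; Ks undefined")
  ps <- d[["Sd"]] / S
  pn <- d[["Nd"]] / N
  ks <- jc_correct(ps, S)
  ka <- jc_correct(pn, N)
  kaks_estimate(aln$gene_id, "NG86", ka = ka[["d"]], ks = ks[["d"]],
                se_ka = ka[["se"]], se_ks = ks[["se"]],
                s_sites = S, n_sites = N, sd = d[["Sd"]], nd = d[["Nd"]],
                kappa = 1, n_codons = n_codons)
}
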