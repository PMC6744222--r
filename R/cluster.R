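# Variation-cluster test: are the substitutions of a gene more tightly
# aggregated along the sequence than uniform placement would produce?
# The statistic is the minimal window length containing ceiling(k/2) + 1
# consecutive substitution positions (a scan statistic); significance
# comes from a uniform permutation null with an add-one correction.

#' Positions at which an aligned pair differs
#'
#' Gap columns are removed first, so positions are 0-based coordinates in
#' the gap-stripped alignment.
#'
#' @param aln A [codon_alignment()] object.
#' @param coords `"nucleotide"` (default) or `"codon"`: report each
#'   differing nucleotide position, or the set of codon indices containing
#'   at least one difference.
#' @return An object of class `substitution_map`: list with `gene_id`,
#'   `length` (gap-stripped length in the chosen coordinate unit) and
#'   `positions` (sorted, 0-based).
#' @export
substitution_positions <- function(aln,
                                   coords = c("nucleotide", "codon")) {
  coords <- match.arg(coords)
  cods <- strip_gap_codons(aln, drop_ambiguous = FALSE)
  a <- strsplit(paste(cods$a, collapse = ""), "")[[1]]
  b <- strsplit(paste(cods$b, collapse = ""), "")[[1]]
  pos <- which(a != b) - 1L
  len <- length(a)
  if (coords == "codon") {
    pos <- sort(unique(pos %/% 3L))
    len <- len %/% 3L
  }
  substitution_map(aln$gene_id, len, pos)
}

#' Construct a substitution map
#'
#' @param gene_id Gene label.
#' @param length Gap-stripped sequence length.
#' @param positions Strictly increasing integer positions in
#'   `[0, length)`.
#' @return An object of class `substitution_map`.
#' @export
substitution_map <- function(gene_id, length, positions) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (length(positions) > 0 &&
      (min(positions) < 0L || max(positions) >= length)) {
    stop("positions must lie in [0, length)")
  }
  structure(list(gene_id = gene_id, length = as.integer(length),
                 positions = positions),
            class = "substitution_map")
}

#' Minimal-window clustering statistic
#'
#' The length (in sites) of the shortest window containing
#' `ceiling(k/2) + 1` consecutive substitution positions, where k is the
#' number of substitutions. Smaller values indicate tighter clustering.
#'
#' @param m A [substitution_map()] (or a `codon_alignment`, converted via
#'   [substitution_positions()]).
#' @return The scan statistic (integer window length).
#' @export
cluster_statistic <- function(m) {
  if (inherits(m, "codon_alignment")) m <- substitution_positions(m)
  k <- length(m$positions)
  if (k < 2L) stop("clustering statistic undefined for fewer than 2 ",
                   "substitutions (k = ", k, ")")
  scan_window_stat(m$positions, k)
}

scan_window_stat <- function(pos, k) {
  w <- as.integer(ceiling(k / 2)) + 1L
  i <- seq_len(k - w + 1L)
  min(pos[i + w - 1L] - pos[i] + 1L)
}

#' Permutation test for clustered substitutions
#'
#' Compares the observed scan statistic with its distribution under
#' uniform placement of the same number of substitutions: in each
#' permutation k positions are drawn uniformly without replacement from
#' `[0, length)`. The p-value uses the add-one correction
#' `(1 + #{permutation statistic <= observed}) / (1 + n_perm)`.
#'
#' @inheritParams cluster_statistic
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @return An object of class `cluster_test_result`: list with `gene_id`,
#'   `k`, `length`, `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
cluster_test <- function(m, n_perm = 999L, seed = 1L) {
  if (inherits(m, "codon_alignment")) m <- substitution_positions(m)
  k <- length(m$positions)
  if (k < 2L) stop("cluster test requires at least 2 substitutions")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (m$length < k) stop("sequence length smaller than substitution count")
  obs <- scan_window_stat(m$positions, k)
  perm_le <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sort.int(sample.int(m$length, k) - 1L)
      if (scan_window_stat(p, k) <= obs) hits <- hits + 1L
    }
    hits
  })
  structure(
    list(gene_id = m$gene_id, k = k, length = m$length,
         statistic = obs, p_value = (1 + perm_le) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("Variation-cluster permutation test:", x$gene_id, "\n")
  cat(sprintf("  k = %d substitutions in %d sites\n", x$k, x$length))
  cat(sprintf("  minimal-window statistic = %d, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Read precomputed substitution maps from a TSV file
#'
#' One gene per line: `gene_id`, `length`, comma-separated positions.
#'
#' @param path Path to a tab-separated file with columns `gene_id`,
#'   `length`, `positions`.
#' @return List of [substitution_map()] objects.
#' @export
read_substitution_maps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    pos <- as.integer(strsplit(as.character(df$positions[i]), ",")[[1]])
    substitution_map(df$gene_id[i], df$length[i], sort(pos))
  })
}
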