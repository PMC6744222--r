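# Independent oracles used to cross-check the package implementations.

# Brute-force pathway enumerator for codon difference counting: builds
# every complete single-step path between two codons by depth-first
# search, discards paths visiting a stop codon, and averages the per-path
# synonymous/nonsynonymous step counts with equal weight.  Deliberately a
# different construction from the package's permutation loop.
oracle_pathway_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  paths <- list()
  walk <- function(cur, sd, nd) {
    diffpos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diffpos) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in diffpos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      if (gc[[nxt]] == "*") next
      if (gc[[nxt]] == gc[[cur]]) walk(nxt, sd + 1, nd)
      else walk(nxt, sd, nd + 1)
    }
  }
  walk(c1, 0, 0)
  if (length(paths) == 0L) return(NULL)
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# Textbook sum-based Pearson correlation (independent of stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small no-indel alignment straight from a simulated pair.
sim_alignment <- function(n_codons, omega, t, kappa = 2, seed = 1) {
  p <- simulate_codon_pair(n_codons, omega, kappa = kappa, t = t,
                           seed = seed)
  codon_alignment("sim", p$cds_a, p$cds_b)
}
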