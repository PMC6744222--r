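# Genetic-code machinery shared by the counting methods and the simulator.
# All tables are built once per session and cached.

.pogdiv_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' Standard codon table with degeneracy information
#'
#' Returns the standard nuclear genetic code (NCBI table 1) augmented with
#' the per-codon structures the Ka/Ks estimators need: the list of all nine
#' single-nucleotide mutant codons per sense codon, their
#' transition/transversion status and synonymous/nonsynonymous/stop class,
#' and the NG86 synonymous site count per codon (mutations that create a
#' stop codon are counted as nonsynonymous, so synonymous and nonsynonymous
#' sites always sum to 3 per codon).
#'
#' @return A list with elements `codons` (64 codons), `aa` (named amino-acid
#'   vector, `*` for stops), `sense` (61 sense codons), `neighbors` (a
#'   data.frame of all single-nucleotide changes from sense codons with
#'   columns `from`, `pos`, `to`, `is_ts`, `class`), and `s_sites` (named
#'   NG86 synonymous site count per sense codon).
#' @export
#' @examples
#' ct <- standard_codon_table()
#' ct$s_sites[["TTT"]] # 1/3: only TTT->TTC is synonymous
standard_codon_table <- function() {
  if (!is.null(.pogdiv_cache$codon_table)) {
    return(.pogdiv_cache$codon_table)
  }
  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stopifnot(length(sense) == 61L)

  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }

  nb <- vector("list", length(sense))
  for (i in seq_along(sense)) {
    cd <- sense[i]
    ch <- strsplit(cd, "")[[1]]
    rows <- list()
    for (p in 1:3) {
      for (b in setdiff(.BASES, ch[p])) {
        mut <- ch
        mut[p] <- b
        to <- paste(mut, collapse = "")
        cls <- if (aa[[to]] == "*") "stop"
        else if (aa[[to]] == aa[[cd]]) "syn" else "nonsyn"
        rows[[length(rows) + 1L]] <- data.frame(
          from = cd, pos = p, to = to,
          is_ts = is_transition(ch[p], b), class = cls,
          stringsAsFactors = FALSE
        )
      }
    }
    nb[[i]] <- do.call(rbind, rows)
  }
  neighbors <- do.call(rbind, nb)

  # NG86 sites: each position contributes (#synonymous alternatives)/3
  syn_per_codon <- tapply(neighbors$class == "syn", neighbors$from, sum)
  s_sites <- as.numeric(syn_per_codon[sense]) / 3
  names(s_sites) <- sense

  ct <- list(codons = codons, aa = aa, sense = sense,
             neighbors = neighbors, s_sites = s_sites)
  .pogdiv_cache$codon_table <- ct
  ct
}

# Pathway-averaged NG86 difference tables over all 61 x 61 sense-codon
# pairs.  For codons differing at k positions all k! single-step orderings
# are enumerated; orderings passing through a stop codon are discarded and
# the synonymous/nonsynonymous step counts of the remaining paths are
# averaged with equal weight.  (Every sense-codon pair has at least one
# stop-free path under the standard code; this is asserted at build time.)
ng86_difference_tables <- function() {
  if (!is.null(.pogdiv_cache$ng86_diff)) {
    return(.pogdiv_cache$ng86_diff)
  }
  ct <- standard_codon_table()
  n <- length(ct$sense)
  SD <- matrix(0, n, n, dimnames = list(ct$sense, ct$sense))
  ND <- matrix(0, n, n, dimnames = list(ct$sense, ct$sense))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in seq_len(n)) {
    ci <- strsplit(ct$sense[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(ct$sense[j], "")[[1]]
      diffpos <- which(ci != cj)
      k <- length(diffpos)
      if (k == 1L) {
        syn <- ct$aa[[ct$sense[i]]] == ct$aa[[ct$sense[j]]]
        SD[i, j] <- as.numeric(syn)
        ND[i, j] <- as.numeric(!syn)
        next
      }
      perms <- if (k == 2L) perms2 else perms3
      sd_tot <- 0
      nd_tot <- 0
      n_valid <- 0L
      for (ord in perms) {
        cur <- ci
        sd_p <- 0
        nd_p <- 0
        ok <- TRUE
        for (p in diffpos[ord]) {
          nxt <- cur
          nxt[p] <- cj[p]
          to <- paste(nxt, collapse = "")
          if (ct$aa[[to]] == "*") {
            ok <- FALSE
            break
          }
          if (ct$aa[[to]] == ct$aa[[paste(cur, collapse = "")]]) {
            sd_p <- sd_p + 1
          } else {
            nd_p <- nd_p + 1
          }
          cur <- nxt
        }
        if (ok) {
          sd_tot <- sd_tot + sd_p
          nd_tot <- nd_tot + nd_p
          n_valid <- n_valid + 1L
        }
      }
      stopifnot(n_valid > 0L)
      SD[i, j] <- sd_tot / n_valid
      ND[i, j] <- nd_tot / n_valid
    }
  }
  .pogdiv_cache$ng86_diff <- list(SD = SD, ND = ND)
  .pogdiv_cache$ng86_diff
}

# Split a nucleotide string into codons; error if not a multiple of 3.
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate a vector of codons under the standard code ("X" for codons
# containing non-ACGT characters).
translate_codons <- function(codons) {
  ct <- standard_codon_table()
  aa <- ct$aa[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}
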