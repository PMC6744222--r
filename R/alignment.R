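# Codon-aware pairwise alignment: the two coding sequences are translated,
# the proteins are aligned globally with affine gap penalties and a fixed
# substitution matrix (BLOSUM62), and the protein alignment is threaded
# back onto the codons, so gaps only ever occur in whole-codon units.

#' Construct a codon alignment object
#'
#' @param gene_id Identifier for the gene pair.
#' @param aligned_a,aligned_b Gap-threaded nucleotide strings of equal
#'   length; gaps (`-`) must occur in whole-codon units.
#' @return An object of class `codon_alignment` with fields `gene_id`,
#'   `aligned_a`, `aligned_b` and `n_codons_ungapped` (number of columns
#'   in which neither sequence is gapped).
#' @export
codon_alignment <- function(gene_id, aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length")
  }
  if (nchar(aligned_a) %% 3L != 0L) {
    stop("alignment length must be a multiple of 3")
  }
  ca <- split_codons(toupper(aligned_a))
  cb <- split_codons(toupper(aligned_b))
  gap_ok <- function(cd) cd == "---" | !grepl("-", cd)
  if (!all(gap_ok(ca)) || !all(gap_ok(cb))) {
    stop("gaps must occur in whole-codon units")
  }
  structure(
    list(gene_id = gene_id, aligned_a = toupper(aligned_a),
         aligned_b = toupper(aligned_b),
         n_codons_ungapped = sum(ca != "---" & cb != "---")),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", x$gene_id, "\n")
  cat("  columns:", nchar(x$aligned_a) / 3L,
      "codons;", x$n_codons_ungapped, "ungapped\n")
  invisible(x)
}

# Drop gap columns (and optionally codon columns containing N) pairwise;
# returns a list of two equal-length codon vectors.
strip_gap_codons <- function(aln, drop_ambiguous = TRUE) {
  ca <- split_codons(aln$aligned_a)
  cb <- split_codons(aln$aligned_b)
  keep <- ca != "---" & cb != "---"
  if (drop_ambiguous) {
    keep <- keep & !grepl("N", ca) & !grepl("N", cb)
  }
  list(a = ca[keep], b = cb[keep])
}

#' Align an ortholog pair codon-by-codon
#'
#' Translates both coding sequences, aligns the proteins globally (affine
#' gap penalties, BLOSUM62) and threads the alignment back onto the
#' codons. Gaps are therefore always whole codons and the reading frame is
#' preserved.
#'
#' @param pair An ortholog pair as returned by [find_single_copy_pairs()],
#'   or any list with fields `gene_id`, `seq_a`, `seq_b` holding in-frame
#'   CDS without internal stop codons.
#' @param gap_open,gap_extend Affine gap penalties for the protein-level
#'   alignment (defaults 10 and 0.5, the classic BLOSUM62 setting).
#' @return A [codon_alignment()] object.
#' @export
#' @examples
#' p <- list(gene_id = "g1", seq_a = "ATGAAAAAA", seq_b = "ATGAAA")
#' align_codons(p)
align_codons <- function(pair, gap_open = 10, gap_extend = 0.5) {
  sa <- toupper(pair$seq_a)
  sb <- toupper(pair$seq_b)
  ca <- split_codons(sa)
  cb <- split_codons(sb)
  pa <- paste(translate_codons(ca), collapse = "")
  pb <- paste(translate_codons(cb), collapse = "")
  if (nchar(pa) == 0L || nchar(pb) == 0L) {
    stop("zero-length translation for gene ", pair$gene_id)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  apat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  asub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  thread <- function(prot_gapped, codons) {
    out <- character(length(prot_gapped))
    k <- 0L
    for (i in seq_along(prot_gapped)) {
      if (prot_gapped[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    stopifnot(k == length(codons))
    paste(out, collapse = "")
  }
  codon_alignment(pair$gene_id, thread(apat, ca), thread(asub, cb))
}
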