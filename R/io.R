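# File formats: FASTA in/out, TSV tables for every stage, and a
# PHYLIP-like paired-alignment writer compatible with PAML's sequential
# input layout (for external cross-validation against yn00).

#' Read a FASTA file into a transcript set
#'
#' Wrapped or unwrapped FASTA, case-insensitive; sequence ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @param taxon_id Taxon label for the resulting set (default: file name
#'   without extension).
#' @return A [transcript_set()].
#' @export
read_transcripts <- function(path, taxon_id = NULL) {
  if (!file.exists(path)) stop("FASTA input not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA input: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  transcript_set(taxon_id %||% sub("\\.[^.]*$", "", basename(path)), seqs)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

# Write a cohort (simulate_cohort output) as two FASTA files + truth TSV.
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(cohort$seq_a, file.path(dir, paste0(prefix, "_a.fasta")))
  write_fasta(cohort$seq_b, file.path(dir, paste0(prefix, "_b.fasta")))
  write_tsv(cohort$truth, file.path(dir, paste0(prefix, "_truth.tsv")))
  invisible(dir)
}

# Deterministic TSV writer: header, tab-separated, no quoting, no row
# names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an ortholog pair table as TSV
#'
#' One row per pair: `gene_id`, `id_a`, `id_b`, `score`, `cds_len_a`,
#' `cds_len_b`, sorted by `gene_id`.
#'
#' @param pairs List of ortholog pairs from [find_single_copy_pairs()]
#'   or [pair_by_id()].
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(gene_id = p$gene_id, id_a = p$id_a, id_b = p$id_b,
               score = p$similarity_score,
               cds_len_a = nchar(p$seq_a), cds_len_b = nchar(p$seq_b),
               stringsAsFactors = FALSE)
  }))
  write_tsv(df[order(df$gene_id), , drop = FALSE], path)
}

#' Write a codon alignment as paired FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @param names Sequence names (default derived from the gene id).
#' @export
write_alignment_fasta <- function(aln, path,
                                  names = paste0(aln$gene_id,
                                                 c("_a", "_b"))) {
  write_fasta(stats::setNames(c(aln$aligned_a, aln$aligned_b), names),
              path)
}

#' Write an aligned pair in PAML sequential format
#'
#' Two-sequence sequential PHYLIP-like layout accepted by yn00: a header
#' line with the number of sequences and alignment length, then each name
#' on its own line followed by the aligned sequence.
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @param names Sequence names (default `c("seq_a", "seq_b")`).
#' @export
write_paml_pair <- function(aln, path, names = c("seq_a", "seq_b")) {
  writeLines(c(sprintf(" 2 %d", nchar(aln$aligned_a)),
               names[1], aln$aligned_a,
               names[2], aln$aligned_b),
             path)
  invisible(path)
}

#' Read a taxon-pair record table
#'
#' TSV with one row per taxon pair: `pair_id`, `divergence_time_mya`,
#' `peak_ks`, `modified_peak_ks`, and six `prop_<category>` columns
#' (matching the layout of per-pair supplementary tables in this kind of
#' study).
#'
#' @param path TSV path.
#' @return Data.frame suitable for [pair_level_associations()].
#' @export
read_pair_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "divergence_time_mya", "peak_ks")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("pair record table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"modified_peak_ks" %in% names(df)) {
    df$modified_peak_ks <- df$peak_ks
  }
  if (any(df$divergence_time_mya <= 0)) {
    stop("divergence times must be positive (mya)")
  }
  df
}

# Profile -> one TaxonPairRecord row.
profile_record <- function(profile, divergence_time_mya = NA_real_) {
  props <- as.list(profile$category_props)
  names(props) <- paste0("prop_", names(profile$category_props))
  cbind(data.frame(pair_id = profile$pair_id,
                   divergence_time_mya = divergence_time_mya,
                   n_genes_raw = profile$n_genes_raw,
                   n_genes_filtered = profile$n_genes_filtered,
                   peak_ks = profile$peak_ks,
                   modified_peak_ks = profile$modified_peak_ks,
                   prop_purifying_lt_0.9 = profile$prop_purifying,
                   stringsAsFactors = FALSE),
        as.data.frame(props))
}

#' Tabulate substitution-rate estimates for many alignments
#'
#' @param alns List of [codon_alignment()] objects.
#' @param method `"NG86"`, `"YN00"`, or both.
#' @param ... Passed to the estimators.
#' @return Data.frame with one row per alignment and method; genes whose
#'   estimation fails (saturation, non-convergence) are dropped with a
#'   message naming the gene.
#' @export
kaks_table <- function(alns, method = "YN00", ...) {
  rows <- list()
  for (aln in alns) {
    for (m in method) {
      est <- tryCatch(suppressWarnings(kaks(aln, method = m, ...)),
                      error = function(e) {
                        message("kaks_table: dropped gene ", aln$gene_id,
                                " (", m, "): ", conditionMessage(e))
                        NULL
                      })
      if (!is.null(est)) rows[[length(rows) + 1L]] <- as.data.frame(est)
    }
  }
  if (length(rows) == 0L) stop("no estimable genes")
  df <- do.call(rbind, rows)
  df[order(df$gene_id, df$method), , drop = FALSE]
}
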