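# Ortholog pairing: quality filtering, longest-ORF CDS extraction, and
# reciprocal-best-hit pairing of two transcript sets.

#' Construct a transcript set
#'
#' @param taxon_id Taxon label.
#' @param records Named character vector of nucleotide sequences over
#'   {A,C,G,T,N}; names are the sequence ids and must be unique.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(taxon_id, records) {
  records <- toupper(unlist(records))
  if (length(records) > 0) {
    if (is.null(names(records)) || anyDuplicated(names(records))) {
      stop("records must carry unique names (sequence ids)")
    }
    if (any(nchar(records) == 0L)) stop("sequences must be non-empty")
    check_dna(records, "transcript")
  }
  structure(list(taxon_id = taxon_id, records = records),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("Transcript set:", x$taxon_id, "-", length(x$records),
      "sequences\n")
  invisible(x)
}

#' Remove short and stop-rich sequences from a transcript set
#'
#' Mirrors the standard pre-orthology quality filter: sequences shorter
#' than `min_len` nucleotides or with more than `max_stop_frac` stop
#' codons (evaluated over the frame-0 codons of the given orientation)
#' are dropped. Input order is preserved.
#'
#' @param ts A [transcript_set()].
#' @param min_len Minimum sequence length in nucleotides (default 30).
#' @param max_stop_frac Maximum tolerated fraction of stop codons in
#'   frame 0 (default 0.20).
#' @return A filtered [transcript_set()]; a warning is emitted if nothing
#'   survives.
#' @export
filter_sequences <- function(ts, min_len = 30L, max_stop_frac = 0.20) {
  stopifnot(min_len >= 3L, max_stop_frac >= 0, max_stop_frac <= 1)
  recs <- ts$records
  if (length(recs) == 0L) return(ts)
  stop_frac <- vapply(recs, function(s) {
    nc <- floor(nchar(s) / 3)
    if (nc == 0L) return(1)
    cods <- substring(s, seq(1L, by = 3L, length.out = nc),
                      seq(3L, by = 3L, length.out = nc))
    mean(cods %in% .STOPS)
  }, numeric(1))
  keep <- nchar(recs) >= min_len & stop_frac <= max_stop_frac
  if (!any(keep)) {
    warning("no sequences passed the length/stop-codon filter for taxon ",
            ts$taxon_id)
  }
  transcript_set(ts$taxon_id, recs[keep])
}

#' Extract the coding sequence of a transcript
#'
#' Returns the longest open reading frame (ATG to the codon before the
#' next in-frame stop, or to the frame end when no stop follows) over all
#' six reading frames (three forward, three on the reverse complement).
#' When no ATG-anchored frame exists anywhere, the longest stop-free codon
#' run is returned instead. Codons containing ambiguous bases (N) never
#' start or extend an ORF.
#'
#' @param transcript Nucleotide string (length >= 3).
#' @param min_cds_len Minimum acceptable ORF length in nucleotides;
#'   shorter results yield `NA` with a warning so the gene can be dropped
#'   upstream.
#' @return In-frame CDS string (length a multiple of 3, no internal
#'   stop), or `NA_character_` when no acceptable ORF exists.
#' @export
#' @examples
#' extract_cds("ATGAAATGA") # "ATGAAA"
extract_cds <- function(transcript, min_cds_len = 30L) {
  s <- toupper(transcript)
  if (nchar(s) < 3L) stop("transcript shorter than one codon")
  check_dna(s, "transcript")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  frames <- c(lapply(0:2, function(o) substring(s, o + 1L)),
              lapply(0:2, function(o) substring(rc, o + 1L)))

  runs_of <- function(fr) {
    nc <- floor(nchar(fr) / 3)
    if (nc == 0L) return(NULL)
    cods <- substring(fr, seq(1L, by = 3L, length.out = nc),
                      seq(3L, by = 3L, length.out = nc))
    valid <- !(cods %in% .STOPS) & !grepl("[^ACGT]", cods)
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    lapply(idx, function(i) cods[starts[i]:ends[i]])
  }

  best_orf <- NULL
  best_run <- NULL
  for (fr in frames) {
    for (run in runs_of(fr)) {
      if (is.null(best_run) || length(run) > length(best_run)) {
        best_run <- run
      }
      atg <- which(run == "ATG")
      if (length(atg) > 0) {
        orf <- run[atg[1]:length(run)]
        if (is.null(best_orf) || length(orf) > length(best_orf)) {
          best_orf <- orf
        }
      }
    }
  }
  pick <- best_orf %||% best_run
  if (is.null(pick) || length(pick) * 3L < min_cds_len) {
    warning("no open reading frame of length >= ", min_cds_len,
            " nt; transcript dropped")
    return(NA_character_)
  }
  paste(pick, collapse = "")
}

# Local-alignment similarity scores of every sequence in `a` against every
# sequence in `b` (blastn-like scoring), used by the RBH pairing.
similarity_matrix <- function(a, b, match = 2L, mismatch = -3L,
                              gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  sa <- Biostrings::DNAStringSet(a)
  out <- matrix(NA_real_, length(a), length(b),
                dimnames = list(names(a), names(b)))
  for (j in seq_along(b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      sa, Biostrings::DNAString(b[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  out
}

#' Find single-copy ortholog pairs by reciprocal best hit
#'
#' All-against-all local alignment scores are computed between the two
#' (already filtered) transcript sets; a pair (x, y) is returned when y is
#' the best-scoring hit of x, x is the best-scoring hit of y, and the
#' score reaches `min_score`. Ties are broken lexicographically by
#' sequence id, so the result is deterministic, and each id appears in at
#' most one pair.
#'
#' @param ts_a,ts_b Two [transcript_set()] objects (CDS or transcripts).
#' @param min_score Minimum similarity score for a pair to be reported.
#' @param scores Optional precomputed similarity matrix (rows = ids of
#'   `ts_a`, columns = ids of `ts_b`); mainly for tests.
#' @return A list of ortholog pairs, each a list with fields `gene_id`
#'   (the id from `ts_a`), `id_a`, `id_b`, `seq_a`, `seq_b`,
#'   `similarity_score`; empty list when nothing pairs.
#' @export
find_single_copy_pairs <- function(ts_a, ts_b, min_score = 0,
                                   scores = NULL) {
  a <- ts_a$records
  b <- ts_b$records
  if (length(a) == 0L || length(b) == 0L) return(list())
  # lexicographic order makes the argmax tie-break deterministic
  a <- a[order(names(a))]
  b <- b[order(names(b))]
  if (is.null(scores)) {
    scores <- similarity_matrix(a, b)
  } else {
    scores <- scores[names(a), names(b), drop = FALSE]
  }
  best_in_b <- apply(scores, 1L, which.max)
  best_in_a <- apply(scores, 2L, which.max)
  pairs <- list()
  for (i in seq_along(a)) {
    j <- best_in_b[[i]]
    if (best_in_a[[j]] == i && scores[i, j] >= min_score) {
      pairs[[length(pairs) + 1L]] <- list(
        gene_id = names(a)[i], id_a = names(a)[i], id_b = names(b)[j],
        seq_a = unname(a[[i]]), seq_b = unname(b[[j]]),
        similarity_score = unname(scores[i, j])
      )
    }
  }
  pairs
}

#' Turn a paired id match into ortholog pairs without re-scoring
#'
#' For inputs where orthology is already known (simulated cohorts, curated
#' CDS sets with matching ids) this pairs sequences by shared id.
#'
#' @inheritParams find_single_copy_pairs
#' @return As [find_single_copy_pairs()]; `similarity_score` is `NA`.
#' @export
pair_by_id <- function(ts_a, ts_b) {
  ids <- sort(intersect(names(ts_a$records), names(ts_b$records)))
  lapply(ids, function(id) {
    list(gene_id = id, id_a = id, id_b = id,
         seq_a = unname(ts_a$records[[id]]),
         seq_b = unname(ts_b$records[[id]]),
         similarity_score = NA_real_)
  })
}
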