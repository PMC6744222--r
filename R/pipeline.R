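# End-to-end drivers tying the stages together: one taxon pair from two
# FASTA files (or in-memory sets) to a selection profile plus cluster
# tests, and a panel of pairs to the cross-pair association table.

#' Configuration for a pipeline run
#'
#' Collects every tunable of the per-pair pipeline with the documented
#' defaults; unknown names are rejected.
#'
#' @param ... Overrides of: `min_len` (30), `max_stop_frac` (0.20),
#'   `pairing` ("rbh" or "by_id"), `min_score` (0), `cds` ("longest_orf"
#'   or "as_is"), `min_cds_len` (30), `gap_open` (10), `gap_extend`
#'   (0.5), `method` ("YN00" or "NG86"), `bin_width` (0.01),
#'   `cluster_ratio_threshold` (2), `n_perm` (999), `seed` (1),
#'   `out_dir` (NULL: nothing written).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(min_len = 30L, max_stop_frac = 0.20,
              pairing = "rbh", min_score = 0,
              cds = "longest_orf", min_cds_len = 30L,
              gap_open = 10, gap_extend = 0.5,
              method = "YN00", bin_width = 0.01,
              cluster_ratio_threshold = 2, n_perm = 999L,
              seed = 1L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  for (f in c("min_len", "min_cds_len", "n_perm", "seed")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  stopifnot(cfg$min_len >= 3, cfg$max_stop_frac >= 0,
            cfg$max_stop_frac <= 1, cfg$bin_width > 0,
            cfg$n_perm >= 99, cfg$pairing %in% c("rbh", "by_id"),
            cfg$cds %in% c("longest_orf", "as_is"),
            cfg$method %in% c("YN00", "NG86"))
  structure(cfg, class = "run_config")
}

#' Serialize and restore a run configuration
#'
#' Configurations round-trip losslessly through JSON so a run can be
#' reproduced from its recorded config.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_config()` returns a validated [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(run_config, vals)
}

#' Run the full per-pair pipeline
#'
#' Filtering, ortholog pairing, CDS extraction, codon alignment, Ka/Ks
#' estimation, Ks-0/sentinel filtering, selection profiling, and the
#' variation-cluster test on every gene whose Ka/Ks exceeds the
#' configured threshold.
#'
#' @param fasta_a,fasta_b FASTA file paths or [transcript_set()] objects
#'   (or named character vectors) for the two taxa.
#' @param pair_id Taxon-pair label.
#' @param config A [run_config()].
#' @return List with `profile` (a `selection_profile`), `estimates`
#'   (per-gene data.frame), `cluster_tests` (data.frame for candidate
#'   positive-selection genes), `alignments`, and `log` (counts at every
#'   stage plus seed and config). When `config$out_dir` is set, the
#'   estimate, profile, histogram and cluster TSVs are written there.
#' @export
run_pair <- function(fasta_a, fasta_b, pair_id = "pair",
                     config = run_config()) {
  as_set <- function(x, label) {
    if (inherits(x, "transcript_set")) return(x)
    if (is.character(x) && length(x) == 1L && is.null(names(x))) {
      return(read_transcripts(x, taxon_id = label))
    }
    transcript_set(label, x)
  }
  ts_a <- as_set(fasta_a, paste0(pair_id, "_a"))
  ts_b <- as_set(fasta_b, paste0(pair_id, "_b"))
  log <- list(pair_id = pair_id, seed = config$seed,
              config = unclass(config),
              n_input = c(a = length(ts_a$records),
                          b = length(ts_b$records)))

  ts_a <- filter_sequences(ts_a, config$min_len, config$max_stop_frac)
  ts_b <- filter_sequences(ts_b, config$min_len, config$max_stop_frac)
  log$n_filtered <- c(a = length(ts_a$records),
                      b = length(ts_b$records))

  pairs <- if (config$pairing == "rbh") {
    find_single_copy_pairs(ts_a, ts_b, min_score = config$min_score)
  } else {
    pair_by_id(ts_a, ts_b)
  }
  log$n_pairs <- length(pairs)
  if (length(pairs) == 0L) stop("no ortholog pairs found for ", pair_id)

  if (config$cds == "longest_orf") {
    pairs <- lapply(pairs, function(p) {
      p$seq_a <- suppressWarnings(extract_cds(p$seq_a, config$min_cds_len))
      p$seq_b <- suppressWarnings(extract_cds(p$seq_b, config$min_cds_len))
      p
    })
    dropped <- vapply(pairs, function(p) {
      is.na(p$seq_a) || is.na(p$seq_b)
    }, logical(1))
    if (any(dropped)) {
      message("run_pair: dropped ", sum(dropped),
              " pairs without an acceptable ORF")
    }
    pairs <- pairs[!dropped]
  }
  log$n_cds <- length(pairs)
  if (length(pairs) == 0L) stop("no pairs with usable CDS for ", pair_id)

  alns <- lapply(pairs, align_codons,
                 gap_open = config$gap_open,
                 gap_extend = config$gap_extend)
  estimates <- kaks_table(alns, method = config$method)
  log$n_estimated <- nrow(estimates)

  profile <- build_profile(estimates, pair_id = pair_id,
                           bin_width = config$bin_width)
  log$n_profiled <- profile$n_genes_filtered

  kept <- suppressMessages(filter_estimates(estimates))
  cand <- kept$gene_id[kept$ratio > config$cluster_ratio_threshold]
  names(alns) <- vapply(alns, `[[`, "", "gene_id")
  ct_rows <- list()
  for (g in cand) {
    res <- tryCatch({
      m <- substitution_positions(alns[[g]])
      cluster_test(m, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, match(g, cand)))
    }, error = function(e) {
      message("run_pair: cluster test skipped for gene ", g, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene_id = res$gene_id, k = res$k, length = res$length,
        statistic = res$statistic, p_value = res$p_value,
        n_perm = res$n_perm, seed = res$seed, stringsAsFactors = FALSE)
    }
  }
  cluster_tests <- if (length(ct_rows) > 0) do.call(rbind, ct_rows)
  else data.frame(gene_id = character(0), k = integer(0),
                  length = integer(0), statistic = numeric(0),
                  p_value = numeric(0), n_perm = integer(0),
                  seed = integer(0))
  log$n_cluster_tested <- nrow(cluster_tests)

  out <- list(profile = profile, estimates = estimates,
              cluster_tests = cluster_tests, alignments = alns,
              log = log)
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_tsv(estimates, file.path(d, paste0(pair_id, "_kaks.tsv")))
    write_tsv(profile_record(profile),
              file.path(d, paste0(pair_id, "_profile.tsv")))
    h <- profile$histogram
    write_tsv(data.frame(bin_lo = h$edges[-length(h$edges)],
                         bin_hi = h$edges[-1], count = h$counts,
                         proportion = h$counts / h$total),
              file.path(d, paste0(pair_id, "_ks_histogram.tsv")))
    write_tsv(cluster_tests,
              file.path(d, paste0(pair_id, "_cluster_tests.tsv")))
  }
  out
}

#' Run the cross-pair association stage
#'
#' Assembles taxon-pair records from per-pair profiles and a divergence
#' time table, and computes the pair-level association panel; optionally
#' also the gene-level time-correlation screen.
#'
#' @param profiles List of `selection_profile` objects (or a prebuilt
#'   record data.frame from [read_pair_records()]).
#' @param times Named numeric vector of divergence times (mya) keyed by
#'   pair id; ignored when `profiles` is already a record table. Pairs
#'   without a time are skipped with a warning.
#' @param shared_ratios Optional genes x pairs Ka/Ks matrix for
#'   [gene_level_time_correlation()].
#' @param r_threshold Threshold for the gene-level screen (default 0.5).
#' @param out_dir Optional output directory for TSVs.
#' @return List with `records`, `associations`, and (when
#'   `shared_ratios` is given) `gene_screen`.
#' @export
run_panel <- function(profiles, times = NULL, shared_ratios = NULL,
                      r_threshold = 0.5, out_dir = NULL) {
  if (is.data.frame(profiles)) {
    records <- profiles
  } else {
    rows <- list()
    for (pr in profiles) {
      tm <- if (pr$pair_id %in% names(times)) times[[pr$pair_id]]
      else NA_real_
      if (is.na(tm)) {
        warning("no divergence time for pair ", pr$pair_id,
                "; pair skipped")
        next
      }
      if (tm <= 0) stop("divergence time for ", pr$pair_id,
                        " must be positive (mya)")
      rows[[length(rows) + 1L]] <- profile_record(pr, tm)
    }
    records <- do.call(rbind, rows)
  }
  if (is.null(records) || nrow(records) < 3L) {
    stop("need at least 3 taxon pairs with divergence times")
  }
  records <- records[order(records$pair_id), , drop = FALSE]
  associations <- pair_level_associations(records)
  out <- list(records = records, associations = associations)
  if (!is.null(shared_ratios)) {
    tms <- records$divergence_time_mya[
      match(colnames(shared_ratios), records$pair_id)]
    out$gene_screen <- gene_level_time_correlation(
      shared_ratios[, !is.na(tms), drop = FALSE],
      tms[!is.na(tms)], r_threshold = r_threshold)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(records, file.path(out_dir, "pair_records.tsv"))
    write_tsv(associations, file.path(out_dir, "associations.tsv"))
    if (!is.null(out$gene_screen)) {
      write_tsv(out$gene_screen$per_gene,
                file.path(out_dir, "gene_screen.tsv"))
    }
  }
  out
}
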