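# Cross-pair and cross-gene correlation analyses: divergence time vs.
# peak Ks, peak Ks vs. category abundances, and the per-gene screen for
# Ka/Ks ratios that track divergence time across taxon pairs.

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r` (sample Pearson correlation), `p` (two-sided
#'   p-value from the t distribution with n - 2 df) and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cross-pair association panel
#'
#' Computes Pearson r and p for the standard panel: divergence time vs.
#' peak Ks; peak Ks vs. each selection-category abundance and vs. the
#' pooled positive-selection abundance (weak + strong positive); and
#' divergence time vs. the moderate- and strong-purifying abundances.
#' Every peak-Ks association is also computed with the tie-merged
#' (modified) peak Ks.
#'
#' @param records Data.frame with one row per taxon pair and columns
#'   `pair_id`, `divergence_time_mya`, `peak_ks`, `modified_peak_ks`, and
#'   the six `prop_<category>` columns (proportions; counts are
#'   normalized to proportions first).
#' @return Data.frame with columns `x`, `y`, `n`, `r`, `p`.
#' @export
pair_level_associations <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 3L) stop("need at least 3 taxon pairs")
  prop_cols <- paste0("prop_", SELECTION_CATEGORIES)
  missing_cols <- setdiff(c("divergence_time_mya", "peak_ks",
                            "modified_peak_ks", prop_cols),
                          names(records))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  props <- records[prop_cols]
  if (any(rowSums(props) > 1 + 1e-6)) {
    props <- props / rowSums(props) # counts supplied; normalize
  }
  vars <- c(list(divergence_time_mya = records$divergence_time_mya,
                 peak_ks = records$peak_ks,
                 modified_peak_ks = records$modified_peak_ks),
            as.list(props),
            list(prop_positive = props$prop_weak_positive +
                   props$prop_strong_positive))
  panel <- rbind(
    c("divergence_time_mya", "peak_ks"),
    c("divergence_time_mya", "modified_peak_ks"),
    do.call(rbind, lapply(c(prop_cols, "prop_positive"), function(v) {
      rbind(c("peak_ks", v), c("modified_peak_ks", v))
    })),
    c("divergence_time_mya", "prop_moderate_purifying"),
    c("divergence_time_mya", "prop_strong_purifying")
  )
  out <- lapply(seq_len(nrow(panel)), function(i) {
    res <- tryCatch(pearson_r(vars[[panel[i, 1]]], vars[[panel[i, 2]]]),
                    error = function(e) {
                      warning("association ", panel[i, 1], " ~ ",
                              panel[i, 2], " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(x = panel[i, 1], y = panel[i, 2], n = res$n,
               r = res$r, p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-level correlation of Ka/Ks with divergence time
#'
#' For genes shared by most taxon pairs, correlates each gene's Ka/Ks
#' ratio with divergence time across pairs and summarizes how many genes
#' exceed a threshold |r|, split by sign. Ratios of 0 and the sentinel 99
#' are treated as missing; genes with fewer than 3 usable pairs are
#' skipped (pairwise deletion).
#'
#' @param ratios Numeric matrix of Ka/Ks values, genes in rows (rownames
#'   = gene ids), taxon pairs in columns; `NA` for missing.
#' @param times Divergence times (mya), one per column of `ratios`.
#' @param r_threshold Threshold on |r| (default 0.5).
#' @param ratio_cap Optional upper bound; ratios >= `ratio_cap` are also
#'   treated as missing (the screen's "< 0.5 only" variant).
#' @return List with `per_gene` (data.frame `gene_id`, `n`, `r`, `sign`,
#'   `passed`), `n_pass_positive`, `n_pass_negative`, `n_skipped`.
#' @export
gene_level_time_correlation <- function(ratios, times, r_threshold = 0.5,
                                        ratio_cap = NULL) {
  stopifnot(is.matrix(ratios), length(times) == ncol(ratios))
  ratios[ratios == 0 | ratios == RATIO_SENTINEL] <- NA
  if (!is.null(ratio_cap)) ratios[ratios >= ratio_cap] <- NA
  rows <- lapply(seq_len(nrow(ratios)), function(i) {
    y <- ratios[i, ]
    use <- !is.na(y)
    if (sum(use) < 3L) {
      return(data.frame(gene_id = rownames(ratios)[i], n = sum(use),
                        r = NA_real_, sign = NA_character_,
                        passed = NA, stringsAsFactors = FALSE))
    }
    r <- tryCatch(pearson_r(times[use], y[use])$r,
                  error = function(e) NA_real_)
    data.frame(gene_id = rownames(ratios)[i], n = sum(use), r = r,
               sign = if (is.na(r)) NA_character_
               else if (r > 0) "positive" else "negative",
               passed = !is.na(r) && abs(r) > r_threshold,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  skipped <- sum(is.na(per_gene$passed))
  if (skipped > 0) {
    message("gene_level_time_correlation: skipped ", skipped,
            " genes with < 3 usable pairs or constant ratios")
  }
  list(per_gene = per_gene,
       n_pass_positive = sum(per_gene$passed & per_gene$sign == "positive",
                             na.rm = TRUE),
       n_pass_negative = sum(per_gene$passed & per_gene$sign == "negative",
                             na.rm = TRUE),
       n_skipped = skipped)
}
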