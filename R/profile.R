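# Per-taxon-pair selection profile: Ks histogram, peak Ks (plain and
# tie-merged), and six Ka/Ks selection-pressure categories.

SELECTION_CATEGORIES <- c("strong_purifying", "moderate_purifying",
                          "relaxed_purifying", "near_neutral",
                          "weak_positive", "strong_positive")

#' Remove undefined-rate genes before profiling
#'
#' Drops estimates with Ks = 0 and estimates whose Ka/Ks carries the
#' sentinel 99 (Ks = 0, Ka > 0) or is undefined (Ka = Ks = 0), the
#' standard pre-analysis filter for yn00-style output.
#'
#' @param estimates A data.frame of per-gene estimates with columns `ks`
#'   and `ratio` (as produced by [kaks_table()]), or a list of
#'   `kaks_estimate` objects.
#' @return The retained rows/elements, with a message reporting how many
#'   were removed.
#' @export
filter_estimates <- function(estimates) {
  df <- as_estimates_df(estimates)
  keep <- df$ks > 0 & !is.na(df$ratio) & df$ratio != RATIO_SENTINEL
  n_rm <- sum(!keep)
  if (n_rm > 0) {
    message("filter_estimates: removed ", n_rm, " of ", nrow(df),
            " genes (Ks = 0 or undefined/sentinel Ka/Ks)")
  }
  if (is.data.frame(estimates)) estimates[keep, , drop = FALSE]
  else estimates[keep]
}

as_estimates_df <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  do.call(rbind, lapply(estimates, as.data.frame))
}

#' Histogram of Ks values in fixed-width bins
#'
#' Bins are half-open `[lo, hi)` starting at 0; the paper-standard width
#' is 0.01. The last bin is the one containing the largest observed Ks.
#'
#' @param estimates Filtered estimates (data.frame/list as in
#'   [filter_estimates()]) or a bare numeric vector of Ks values.
#' @param bin_width Bin width (default 0.01).
#' @return An object of class `ks_histogram` with fields `bin_width`,
#'   `edges`, `counts`, `total`.
#' @export
ks_histogram <- function(estimates, bin_width = 0.01) {
  ks <- if (is.numeric(estimates)) estimates else as_estimates_df(estimates)$ks
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0L) stop("no Ks values to bin")
  if (any(ks < 0)) stop("negative Ks values")
  bin <- floor(ks / bin_width) + 1L
  n_bins <- max(bin)
  counts <- tabulate(bin, nbins = n_bins)
  structure(
    list(bin_width = bin_width,
         edges = seq(0, by = bin_width, length.out = n_bins + 1L),
         counts = counts, total = length(ks)),
    class = "ks_histogram"
  )
}

#' @export
print.ks_histogram <- function(x, ...) {
  cat("Ks histogram:", x$total, "genes in", length(x$counts),
      "bins of width", x$bin_width, "\n")
  cat("  peak Ks:", peak_ks(x), " modified peak Ks:",
      suppressWarnings(modified_peak_ks(x)), "\n")
  invisible(x)
}

#' Ks value at peak frequency
#'
#' The midpoint of the modal bin of the Ks histogram. Ties between
#' equal-count bins are broken toward the lower bin, with a warning.
#'
#' @param h A [ks_histogram()].
#' @return The midpoint of the modal bin.
#' @export
peak_ks <- function(h) {
  stopifnot(inherits(h, "ks_histogram"), h$total >= 1L)
  m <- which.max(h$counts)
  if (sum(h$counts == h$counts[m]) > 1L) {
    warning("tied modal bins; using the lowest")
  }
  (h$edges[m] + h$edges[m + 1L]) / 2
}

#' Modified peak Ks (adjacent near-tie rule)
#'
#' When the modal bin and an immediately adjacent bin have frequencies
#' differing by less than 10% of their combined frequency, the shared
#' boundary of the two bins is returned instead of the modal midpoint
#' (e.g. adjacent bins holding 21% and 19% of genes yield the boundary,
#' since 2% < 10% of 40%). If both neighbors qualify, the one closer in
#' frequency to the modal bin is used. Otherwise this equals
#' [peak_ks()].
#'
#' @inheritParams peak_ks
#' @return A Ks value.
#' @export
modified_peak_ks <- function(h) {
  stopifnot(inherits(h, "ks_histogram"), h$total >= 1L)
  m <- which.max(h$counts)
  cand <- c(m - 1L, m + 1L)
  cand <- cand[cand >= 1L & cand <= length(h$counts)]
  if (length(cand) > 0) {
    gap <- abs(h$counts[m] - h$counts[cand])
    ok <- gap < 0.10 * (h$counts[m] + h$counts[cand]) &
      (h$counts[m] + h$counts[cand]) > 0
    cand <- cand[ok]
    gap <- gap[ok]
    if (length(cand) > 0) {
      nb <- cand[which.min(gap)]
      # shared boundary between modal bin and its qualifying neighbor
      return(h$edges[max(m, nb)])
    }
  }
  suppressWarnings(peak_ks(h))
}

#' Classify Ka/Ks ratios into selection-pressure categories
#'
#' Category bounds: strong purifying < 0.1 <= moderate purifying < 0.5 <=
#' relaxed purifying < 0.9 <= near neutral <= 1.1 < weak positive <= 2 <
#' strong positive. The purifying bins are lower-closed/upper-open, the
#' near-neutral bin is closed, so every defined ratio maps to exactly one
#' category.
#'
#' @param ratio Numeric vector of defined, non-negative Ka/Ks ratios
#'   (filter with [filter_estimates()] first; `NA` or sentinel values are
#'   an error).
#' @return Factor with levels `strong_purifying`, `moderate_purifying`,
#'   `relaxed_purifying`, `near_neutral`, `weak_positive`,
#'   `strong_positive`.
#' @export
#' @examples
#' classify_selection(c(0.05, 0.3, 0.7, 1.0, 1.5, 2.5))
classify_selection <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio == RATIO_SENTINEL)) {
    stop("undefined or sentinel Ka/Ks ratios must be filtered out first")
  }
  if (any(ratio < 0)) stop("negative Ka/Ks ratio")
  out <- character(length(ratio))
  out[ratio < 0.1] <- "strong_purifying"
  out[ratio >= 0.1 & ratio < 0.5] <- "moderate_purifying"
  out[ratio >= 0.5 & ratio < 0.9] <- "relaxed_purifying"
  out[ratio >= 0.9 & ratio <= 1.1] <- "near_neutral"
  out[ratio > 1.1 & ratio <= 2] <- "weak_positive"
  out[ratio > 2] <- "strong_positive"
  factor(out, levels = SELECTION_CATEGORIES)
}

#' Build the selection profile of one taxon pair
#'
#' Applies the Ks = 0 / sentinel filter, bins Ks, extracts the plain and
#' tie-merged peak-Ks values, and tabulates the six selection categories.
#'
#' @param estimates Per-gene estimates (data.frame or list of
#'   `kaks_estimate`), unfiltered.
#' @param pair_id Taxon-pair label.
#' @param bin_width Ks bin width (default 0.01).
#' @return An object of class `selection_profile` with fields `pair_id`,
#'   `n_genes_raw`, `n_genes_filtered`, `histogram`, `peak_ks`,
#'   `modified_peak_ks`, `category_counts`, `category_props`,
#'   `prop_purifying` (Ka/Ks < 0.9) and `rank_order` (categories sorted
#'   by decreasing abundance).
#' @export
build_profile <- function(estimates, pair_id = "pair", bin_width = 0.01) {
  df_raw <- as_estimates_df(estimates)
  df <- suppressMessages(filter_estimates(df_raw))
  if (nrow(df) < 1L) stop("no genes left after filtering for ", pair_id)
  h <- ks_histogram(df$ks, bin_width = bin_width)
  cats <- classify_selection(df$ratio)
  counts <- table(cats)
  props <- as.numeric(counts) / nrow(df)
  names(props) <- names(counts)
  structure(
    list(pair_id = pair_id,
         n_genes_raw = nrow(df_raw),
         n_genes_filtered = nrow(df),
         histogram = h,
         peak_ks = suppressWarnings(peak_ks(h)),
         modified_peak_ks = modified_peak_ks(h),
         category_counts = as.integer(counts) |>
           stats::setNames(names(counts)),
         category_props = props,
         prop_purifying = mean(df$ratio < 0.9),
         rank_order = names(sort(counts, decreasing = TRUE))),
    class = "selection_profile"
  )
}

#' @export
print.selection_profile <- function(x, ...) {
  cat("Selection profile:", x$pair_id, "\n")
  cat(sprintf("  genes: %d raw, %d after Ks/sentinel filter\n",
              x$n_genes_raw, x$n_genes_filtered))
  cat(sprintf("  peak Ks: %.4g (modified: %.4g)\n",
              x$peak_ks, x$modified_peak_ks))
  cat(sprintf("  purifying (Ka/Ks < 0.9): %.1f%%\n",
              100 * x$prop_purifying))
  tab <- data.frame(count = x$category_counts,
                    proportion = round(x$category_props, 4))
  print(tab)
  invisible(x)
}
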