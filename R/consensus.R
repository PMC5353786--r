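#' Read a per-sample CpG methylation profile
#'
#' Parses a tab-separated CpG count profile with columns
#' `chrom`, `pos`, `strand`, `total_reads`, `meth_reads` (no header), the
#' per-CpG output of a bisulfite methylation caller consumed as a table.
#' Positions are 0-based.
#'
#' @param path Path to the TSV file.
#' @param sample_id Identifier attached to every row of the result.
#' @param total_aligned_reads Total number of aligned reads for this sample;
#'   its reciprocal is the sample's weight when profiles are combined.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `strand`,
#'   `total_reads`, `meth_reads`, carrying `total_aligned_reads` in the
#'   `totals` attribute-free convention: return also has column
#'   `total_aligned_reads` repeated per row for tidy joins.
#' @export
read_cpg_profile <- function(path, sample_id, total_aligned_reads) {
  assert_count(total_aligned_reads, "total_aligned_reads")
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "total_reads", "meth_reads"),
    col_types = "cicii",
    progress = FALSE
  )
  bad <- which(x$meth_reads > x$total_reads | x$meth_reads < 0 | x$total_reads < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid methylation counts (meth_reads > total_reads) at line(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  srt <- order(x$chrom, x$pos)
  if (is.unsorted(srt)) {
    warn(sprintf("profile `%s` was not position-sorted; sorting", sample_id))
    x <- x[srt, ]
  }
  mutate(x,
    sample_id = as.character(sample_id),
    total_aligned_reads = as.integer(total_aligned_reads),
    .before = 1
  )
}

#' Drop CpG sites with insufficient read coverage
#'
#' Removes sites observed by fewer than `min_reads` aligned reads, applied per
#' sample independently, before any cross-sample combination.
#'
#' @param profile Tibble of per-sample CpG counts (long format, one row per
#'   sample x site) with at least a `total_reads` column.
#' @param min_reads Minimum reads for a site to be retained (default 5).
#' @return The filtered tibble.
#' @export
filter_low_coverage <- function(profile, min_reads = 5) {
  assert_count(min_reads, "min_reads")
  filter(profile, .data$total_reads >= min_reads)
}

#' Combine per-sample CpG profiles into a class consensus
#'
#' Computes, at every CpG site, the weighted combined read count
#' \deqn{R(k) = \sum_i w_i r_{ik} / \sum_i w_i} with sample weight
#' \eqn{w_i = 1 / \mathrm{total\ aligned\ reads}_i}, and the analogous
#' combined methylated read count \eqn{MR(k)}; the consensus methylation level
#' is \eqn{MR(k)/R(k)}. The weight normaliser runs over the samples that
#' contribute a (coverage-filtered) measurement at that site, so sites missing
#' in some samples are not deflated.
#'
#' @param profiles Long tibble with columns `sample_id`, `chrom`, `pos`,
#'   `total_reads`, `meth_reads`, and either a `total_aligned_reads` column or
#'   a separate `totals` lookup.
#' @param totals Optional tibble `sample_id`, `total_aligned_reads`; used when
#'   `profiles` lacks the column.
#' @return A tibble `chrom`, `pos`, `R`, `MR`, `meth`, `n_samples`, sorted by
#'   position.
#' @export
combine_profiles <- function(profiles, totals = NULL) {
  if (!"total_aligned_reads" %in% names(profiles)) {
    if (is.null(totals)) {
      abort("supply `total_aligned_reads` in `profiles` or via `totals`")
    }
    profiles <- left_join(profiles, totals, by = "sample_id")
  }
  if (nrow(profiles) == 0) {
    return(tibble(
      chrom = character(), pos = integer(),
      R = double(), MR = double(), meth = double(), n_samples = integer()
    ))
  }
  if (any(is.na(profiles$total_aligned_reads) | profiles$total_aligned_reads <= 0)) {
    abort("every sample needs total_aligned_reads > 0 (weight undefined otherwise)")
  }
  profiles %>%
    mutate(w = 1 / .data$total_aligned_reads) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      R = sum(.data$w * .data$total_reads) / sum(.data$w),
      MR = sum(.data$w * .data$meth_reads) / sum(.data$w),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(meth = .data$MR / .data$R) %>%
    select("chrom", "pos", "R", "MR", "meth", "n_samples") %>%
    arrange(.data$chrom, .data$pos)
}
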