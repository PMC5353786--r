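#' Segment a consensus methylation profile into regions
#'
#' Connects runs of adjacent assayed CpGs that share a methylation state into
#' regions: hypomethylated runs (consensus methylation below `meth_cutoff`)
#' are candidate active regulatory elements; hypermethylated runs (methylation
#' at or above the cutoff) are candidate highly methylated regions. A run is
#' broken where the gap between consecutive assayed CpGs exceeds `max_gap_bp`,
#' and only maximal runs with at least `n_cpg_cutoff` member CpGs are
#' reported. A site exactly at the cutoff counts as hypermethylated.
#'
#' Region coordinates are 0-based half-open and span the first member CpG to
#' the last member CpG plus the dinucleotide (`end = last CpG + 2`).
#'
#' @param profile Consensus profile tibble (`chrom`, `pos`, `meth`), sorted by
#'   position; the output of [combine_profiles()].
#' @param state `"hypo"` (methylation < cutoff) or `"hyper"` (>= cutoff).
#' @param meth_cutoff Methylation cutoff separating the two states
#'   (default 0.5).
#' @param n_cpg_cutoff Minimum CpGs per region (default 3).
#' @param max_gap_bp Maximum distance between consecutive member CpGs
#'   (default 500).
#' @return Tibble `chrom`, `start`, `end`, `n_cpg`, `mean_meth`, `state`.
#' @export
segment_profile <- function(profile, state = c("hypo", "hyper"),
                            meth_cutoff = 0.5, n_cpg_cutoff = 3,
                            max_gap_bp = 500) {
  state <- match.arg(state)
  assert_count(n_cpg_cutoff, "n_cpg_cutoff")
  assert_count(max_gap_bp, "max_gap_bp")
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpg = integer(), mean_meth = double(), state = character()
  )
  if (nrow(profile) == 0) return(empty)
  profile <- arrange(profile, .data$chrom, .data$pos)
  keep <- if (state == "hypo") profile$meth < meth_cutoff else profile$meth >= meth_cutoff
  x <- profile[keep, , drop = FALSE]
  if (nrow(x) == 0) return(empty)
  # Run ids increment at chromosome changes, at gaps beyond max_gap_bp, and
  # wherever an assayed CpG of the opposite state sits between two same-state
  # CpGs (maximality over consecutive assayed sites, not genomic distance).
  pos_all <- profile$pos
  chrom_all <- profile$chrom
  idx <- which(keep)
  new_run <- c(TRUE, diff(idx) > 1L |
    chrom_all[idx[-1]] != chrom_all[idx[-length(idx)]] |
    (pos_all[idx[-1]] - pos_all[idx[-length(idx)]]) > max_gap_bp)
  run <- cumsum(new_run)
  x %>%
    mutate(run = run) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(
      start = as.integer(min(.data$pos)),
      end = as.integer(max(.data$pos) + 2L),
      n_cpg = dplyr::n(),
      mean_meth = mean(.data$meth),
      .groups = "drop"
    ) %>%
    filter(.data$n_cpg >= n_cpg_cutoff) %>%
    mutate(state = if (state == "hypo") "hypo" else "hyper") %>%
    select("chrom", "start", "end", "n_cpg", "mean_meth", "state") %>%
    arrange(.data$chrom, .data$start)
}

#' @rdname segment_profile
#' @param ... Passed to [segment_profile()].
#' @export
segment_hypo <- function(profile, ...) segment_profile(profile, "hypo", ...)

#' @rdname segment_profile
#' @export
segment_himr <- function(profile, ...) segment_profile(profile, "hyper", ...)
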