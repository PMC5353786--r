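# Spatial statistics on region maps: nearest-neighbour distance
# distributions, label-shuffle backgrounds, and clustering of lost elements.

# Edge-to-edge nearest-neighbour distance within one sorted region set.
# Overlapping regions get distance 0; regions alone on a chromosome get NA.
nn_within <- function(regions) {
  if (nrow(regions) == 0) return(numeric())
  d <- rep(NA_real_, nrow(regions))
  ord <- order(regions$chrom, regions$start, regions$end)
  x <- regions[ord, ]
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    if (length(i) < 2) next
    s <- x$start[i]
    e <- x$end[i]
    gap_prev <- c(Inf, pmax(0, s[-1] - cummax(e)[-length(e)]))
    gap_next <- c(pmax(0, s[-1] - e[-length(e)]), Inf)
    # gap to the next region uses this region's own end, to the previous the
    # running max end (an earlier long region can be the nearest neighbour)
    d[ord[i]] <- pmin(gap_prev, gap_next)
  }
  d
}

#' Nearest within-class neighbour distances
#'
#' For each region, the edge-to-edge distance (bp) to the nearest other
#' region of the same set on the same chromosome; overlap counts as 0.
#' Regions alone on their chromosome are excluded with a log note.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @return Numeric vector of distances (one per retained region); empty with
#'   a warning when fewer than two regions are supplied.
#' @export
within_class_distances <- function(regions) {
  if (nrow(regions) < 2) {
    warn("fewer than two regions; no within-class distances")
    return(numeric())
  }
  d <- nn_within(regions)
  if (anyNA(d)) inform("regions alone on a chromosome excluded from distances")
  d[!is.na(d)]
}

#' Nearest cross-class neighbour distances
#'
#' For each region of `from`, the edge-to-edge distance to the nearest region
#' of `to` on the same chromosome (0 when they overlap). `from` regions on a
#' chromosome with no `to` region are excluded.
#'
#' @param from,to Region tibbles.
#' @return Numeric vector of distances.
#' @export
cross_class_distances <- function(from, to) {
  if (nrow(from) == 0 || nrow(to) == 0) {
    warn("empty region set; no cross-class distances")
    return(numeric())
  }
  d <- rep(NA_real_, nrow(from))
  for (ch in intersect(unique(from$chrom), unique(to$chrom))) {
    i <- which(from$chrom == ch)
    j <- which(to$chrom == ch)
    for (k in i) {
      gaps <- pmax(to$start[j] - from$end[k], from$start[k] - to$end[j])
      d[k] <- max(0, min(gaps))
    }
  }
  d[!is.na(d)]
}

#' Label-shuffle background for a distance statistic
#'
#' Shuffles class labels uniformly at random over the fixed region
#' coordinates (class sizes preserved), recomputes the within-class distance
#' distribution of the target class for each permutation, and compares the
#' observed distribution against the pooled permutation distances with a
#' one-sided Wilcoxon rank-sum test. The per-permutation mean ECDF (the
#' averaged background distribution) is also returned.
#'
#' @param labeled_regions Region tibble with a `class` label column (e.g. a
#'   [classify_regions()] map).
#' @param target_class Class whose within-class distances are tested.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param alternative Direction of the rank-sum test: `"less"` (observed
#'   distances shorter than background, the within-class clustering
#'   direction) or `"greater"`.
#' @return Object of class `spatial_test`: list with `distances`,
#'   `background_pooled`, `background_ecdf` (tibble `distance`, `mean_ecdf`),
#'   `statistic`, `p_value`, `n_perm`, `seed`, `alternative`.
#' @export
shuffle_label_background <- function(labeled_regions, target_class,
                                     n_perm = 1000, seed = 1,
                                     alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  assert_count(n_perm, "n_perm")
  # exchangeability: key the RNG stream on sorted coordinates, not input order
  labeled_regions <- arrange(labeled_regions, .data$chrom, .data$start, .data$end)
  observed <- within_class_distances(
    filter(labeled_regions, .data$class == target_class)
  )
  labels <- labeled_regions$class
  eval_grid <- sort(unique(observed))
  pooled <- vector("list", n_perm)
  ecdf_sum <- numeric(length(eval_grid))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample(labels)
      dp <- nn_within(labeled_regions[perm == target_class, , drop = FALSE])
      dp <- dp[!is.na(dp)]
      pooled[[p]] <- dp
      if (length(dp) > 0 && length(eval_grid) > 0) {
        ecdf_sum <- ecdf_sum + ecdf(dp)(eval_grid)
      }
    }
  })
  pooled <- unlist(pooled)
  test <- suppressWarnings(
    wilcox.test(observed, pooled, alternative = alternative, exact = FALSE)
  )
  structure(
    list(
      distances = observed,
      background_pooled = pooled,
      background_ecdf = tibble(
        distance = eval_grid,
        mean_ecdf = if (n_perm > 0) ecdf_sum / n_perm else numeric()
      ),
      statistic = unname(test$statistic),
      p_value = test$p.value,
      n_perm = n_perm,
      seed = seed,
      alternative = alternative
    ),
    class = "spatial_test"
  )
}

#' Clusters of lost elements
#'
#' Selects the lost regions whose nearest within-class neighbour lies closer
#' than `max_gap` bp and groups them into single-linkage clusters at that gap.
#'
#' @param lost Lost-region tibble.
#' @param max_gap Gap threshold in bp (default 10000).
#' @return The selected regions with a `cluster` id column.
#' @export
cluster_lost_dres <- function(lost, max_gap = 10000) {
  if (nrow(lost) == 0) {
    return(mutate(lost, cluster = integer(0)))
  }
  d <- nn_within(lost)
  sel <- !is.na(d) & d < max_gap
  x <- lost[sel, , drop = FALSE]
  if (nrow(x) == 0) return(mutate(x, cluster = integer(0)))
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  new_cluster <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
    (x$start[-1] - cummax(x$end)[-nrow(x)]) >= max_gap)
  mutate(x, cluster = cumsum(new_cluster))
}
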