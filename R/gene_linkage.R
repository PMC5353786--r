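#' Assign each region to the gene with the closest TSS
#'
#' Distance is 0 when a TSS falls inside the region's half-open interval,
#' otherwise the distance from the nearer region edge to the TSS. Ties are
#' broken deterministically by the lexicographically smaller gene id. Regions
#' on a chromosome without any TSS are returned unassigned (`NA` gene) with a
#' log note.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @return `regions` with `gene_id` and `tss_distance` columns appended.
#' @export
assign_nearest_tss <- function(regions, genes) {
  check_intervals(regions, "regions")
  n <- nrow(regions)
  gene_id <- rep(NA_character_, n)
  tss_distance <- rep(NA_integer_, n)
  gsplit <- split(genes[order(genes$tss, genes$gene_id), ], genes$chrom[order(genes$tss, genes$gene_id)])
  no_tss <- FALSE
  for (i in seq_len(n)) {
    g <- gsplit[[regions$chrom[i]]]
    if (is.null(g) || nrow(g) == 0) {
      no_tss <- TRUE
      next
    }
    s <- regions$start[i]
    e <- regions$end[i]
    d <- ifelse(g$tss >= s & g$tss < e, 0L,
      ifelse(g$tss < s, s - g$tss, g$tss - (e - 1L))
    )
    dmin <- min(d)
    cand <- g$gene_id[d == dmin]
    gene_id[i] <- min(cand)
    tss_distance[i] <- as.integer(dmin)
  }
  if (no_tss) inform("some regions lie on chromosomes without any TSS; left unassigned")
  mutate(regions, gene_id = gene_id, tss_distance = tss_distance)
}

#' Per-gene expression fold change with a low-expression filter
#'
#' Genes whose mean expression is below `min_expr` in either class are marked
#' excluded (unreliable measurements); for the rest the fold change is the
#' ratio of the case-class mean to the control-class mean.
#'
#' @param expr Tibble with `gene_id`, `mean_case`, `mean_control`
#'   (non-negative).
#' @param min_expr Exclusion threshold on either class mean (default 0.1).
#' @return Tibble `gene_id`, `mean_case`, `mean_control`, `fold_change`
#'   (`NA` when excluded), `excluded`.
#' @export
compute_fold_change <- function(expr, min_expr = 0.1) {
  if (any(expr$mean_case < 0 | expr$mean_control < 0)) {
    abort("expression means must be non-negative")
  }
  expr %>%
    mutate(
      excluded = .data$mean_case < min_expr | .data$mean_control < min_expr,
      fold_change = ifelse(.data$excluded, NA_real_, .data$mean_case / .data$mean_control)
    ) %>%
    select("gene_id", "mean_case", "mean_control", "fold_change", "excluded")
}

#' Select the top percentile of differentially expressed genes
#'
#' Ranks the expression-filtered gene universe by fold change (descending for
#' `direction = "up"`, ascending for `"down"`) and returns the top
#' `top_percent` percent; the count is `ceiling(top_percent / 100 * n)`. Ties
#' are resolved deterministically by gene id, so shuffled input yields the
#' same set.
#'
#' @param fold_changes Output of [compute_fold_change()].
#' @param top_percent Percentile in (0, 100].
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
rank_de_genes <- function(fold_changes, top_percent, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(top_percent) || top_percent <= 0 || top_percent > 100) {
    abort("`top_percent` must lie in (0, 100]")
  }
  x <- filter(fold_changes, !.data$excluded)
  if (nrow(x) == 0) return(character())
  ord <- if (direction == "up") {
    order(-x$fold_change, x$gene_id)
  } else {
    order(x$fold_change, x$gene_id)
  }
  n_top <- ceiling(top_percent / 100 * nrow(x))
  x$gene_id[ord][seq_len(n_top)]
}

#' Enrichment of a region class near a gene set, against the shared baseline
#'
#' Computes `fract(R, G)`, the fraction of the tested regions (among those
#' assigned to expression-measured genes) whose nearest gene lies in the gene
#' set, the same fraction `fract(S, G)` for the shared-element baseline, their
#' ratio as the enrichment, and one-sided binomial tail probabilities for
#' enrichment and depletion with the baseline fraction as success probability.
#'
#' @param dre_assign Assigned tested regions ([assign_nearest_tss()] output).
#' @param sre_assign Assigned shared-element baseline regions.
#' @param gene_set Character vector of gene ids (e.g. from [rank_de_genes()]).
#' @param measured_genes Gene ids with reliable expression; regions assigned
#'   outside this universe are dropped from both numerator and denominator.
#' @return An object of class `dre_enrichment` (also a one-row tibble) with
#'   `n_R`, `k_R`, `fract_R_G`, `n_S`, `k_S`, `fract_S_G`, `enrichment`,
#'   `p_enrich`, `p_deplete`, `direction`, `p_value`.
#' @export
dre_gene_enrichment <- function(dre_assign, sre_assign, gene_set, measured_genes) {
  in_univ <- function(x) filter(x, !is.na(.data$gene_id), .data$gene_id %in% measured_genes)
  r <- in_univ(dre_assign)
  s <- in_univ(sre_assign)
  n_R <- nrow(r)
  k_R <- sum(r$gene_id %in% gene_set)
  n_S <- nrow(s)
  k_S <- sum(s$gene_id %in% gene_set)
  fract_R_G <- if (n_R > 0) k_R / n_R else NaN
  fract_S_G <- if (n_S > 0) k_S / n_S else NaN
  if (is.finite(fract_S_G) && fract_S_G == 0) {
    enrichment <- if (k_R > 0) Inf else NaN
    p_enrich <- if (k_R > 0) 0 else 1
    p_deplete <- 1
  } else {
    enrichment <- fract_R_G / fract_S_G
    p_enrich <- pbinom(k_R - 1, n_R, fract_S_G, lower.tail = FALSE)
    p_deplete <- pbinom(k_R, n_R, fract_S_G)
  }
  direction <- if (is.nan(enrichment) || enrichment >= 1) "enrichment" else "depletion"
  out <- tibble(
    n_R = n_R, k_R = k_R, fract_R_G = fract_R_G,
    n_S = n_S, k_S = k_S, fract_S_G = fract_S_G,
    enrichment = enrichment,
    p_enrich = p_enrich, p_deplete = p_deplete,
    direction = direction,
    p_value = ifelse(direction == "enrichment", p_enrich, p_deplete)
  )
  class(out) <- c("dre_enrichment", class(out))
  out
}

#' Genes carrying multiple lost elements and no gained elements
#'
#' Identifies genes whose locus harbours at least `min_count` lost elements
#' and zero gained elements -- the pattern reported for genes whose regulation
#' is dismantled during carcinogenesis (e.g. DNA methyltransferases).
#'
#' @param lost_assign Assigned lost regions.
#' @param gained_assign Assigned gained regions.
#' @param min_count Minimum lost elements per gene (default 2).
#' @return Tibble `gene_id`, `n_lost`, `n_gained`.
#' @export
find_multi_lost_genes <- function(lost_assign, gained_assign, min_count = 2) {
  if (nrow(lost_assign) == 0) {
    return(tibble(gene_id = character(), n_lost = integer(), n_gained = integer()))
  }
  lost_counts <- lost_assign %>%
    filter(!is.na(.data$gene_id)) %>%
    dplyr::count(.data$gene_id, name = "n_lost")
  gained_counts <- gained_assign %>%
    filter(!is.na(.data$gene_id)) %>%
    dplyr::count(.data$gene_id, name = "n_gained")
  lost_counts %>%
    left_join(gained_counts, by = "gene_id") %>%
    mutate(n_gained = dplyr::coalesce(.data$n_gained, 0L)) %>%
    filter(.data$n_lost >= min_count, .data$n_gained == 0L) %>%
    arrange(.data$gene_id)
}
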