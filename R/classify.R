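#' Contrast case and control region maps into gained/lost/shared/hiMR classes
#'
#' A case (cancer-class) hypomethylated region that overlaps no control
#' hypomethylated region is a gained element; a control hypomethylated region
#' with no case overlap is lost; overlapping case/control hypomethylated
#' regions are merged (union coordinates, transitively across chains) into a
#' single shared element. Highly methylated regions in both classes (hiMRs)
#' are the interval intersections of the case and control hypermethylated
#' maps; when consensus profiles are supplied, the minimum-CpG requirement is
#' re-checked on each intersection.
#'
#' @param case_hypo,control_hypo,case_hyper,control_hyper Region tibbles from
#'   [segment_profile()].
#' @param min_overlap_bp Minimum overlap (bp) for two regions to be treated as
#'   the same element (default 1: any overlap).
#' @param case_profile,control_profile Optional consensus profiles used to
#'   re-count CpGs inside hiMR intersections.
#' @param n_cpg_cutoff Minimum CpGs for a hiMR intersection when profiles are
#'   supplied (default 3).
#' @return A region class map: tibble `chrom`, `start`, `end`, `n_cpg`,
#'   `mean_meth`, `class` (gained/lost/shared/himr), `provenance`, of S3 class
#'   `dre_classmap`.
#' @export
classify_regions <- function(case_hypo, control_hypo, case_hyper, control_hyper,
                             min_overlap_bp = 1,
                             case_profile = NULL, control_profile = NULL,
                             n_cpg_cutoff = 3) {
  as_reg <- function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(tibble(
        chrom = character(), start = integer(), end = integer(),
        n_cpg = integer(), mean_meth = double()
      ))
    }
    select(x, "chrom", "start", "end", "n_cpg", "mean_meth")
  }
  ca <- as_reg(case_hypo)
  co <- as_reg(control_hypo)

  prs <- overlap_pairs(ca, co, min_overlap_bp)
  shared <- shared_components(ca, co, prs)
  gained <- ca[setdiff(seq_len(nrow(ca)), unique(prs$a_idx)), , drop = FALSE]
  lost <- co[setdiff(seq_len(nrow(co)), unique(prs$b_idx)), , drop = FALSE]

  himr <- intersect_himr(
    as_reg(case_hyper), as_reg(control_hyper), min_overlap_bp,
    case_profile, control_profile, n_cpg_cutoff
  )

  out <- bind_rows(
    mutate(gained, class = "gained", provenance = "case"),
    mutate(lost, class = "lost", provenance = "control"),
    shared,
    himr
  ) %>%
    arrange(.data$chrom, .data$start, .data$class)
  class(out) <- c("dre_classmap", class(out))
  out
}

# Merge transitive chains of overlapping case/control hypo regions into
# union-coordinate shared elements via union-find over the bipartite graph.
shared_components <- function(ca, co, prs) {
  if (nrow(prs) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_cpg = integer(), mean_meth = double(),
      class = character(), provenance = character()
    ))
  }
  na <- nrow(ca)
  parent <- seq_len(na + nrow(co))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(prs))) {
    i <- find(prs$a_idx[r])
    j <- find(na + prs$b_idx[r])
    if (i != j) parent[j] <- i
  }
  members <- tibble(
    node = c(unique(prs$a_idx), na + unique(prs$b_idx))
  )
  members$root <- vapply(members$node, find, integer(1))
  all_reg <- bind_rows(
    mutate(ca, side = "case"),
    mutate(co, side = "control")
  )
  members %>%
    mutate(
      chrom = all_reg$chrom[.data$node],
      start = all_reg$start[.data$node],
      end = all_reg$end[.data$node],
      n_cpg = all_reg$n_cpg[.data$node],
      mean_meth = all_reg$mean_meth[.data$node],
      side = all_reg$side[.data$node]
    ) %>%
    group_by(.data$root) %>%
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_cpg = sum(.data$n_cpg),
      mean_meth = sum(.data$mean_meth * .data$n_cpg) / sum(.data$n_cpg),
      provenance = paste0("case+control(", dplyr::n(), ")"),
      .groups = "drop"
    ) %>%
    mutate(class = "shared") %>%
    select("chrom", "start", "end", "n_cpg", "mean_meth", "class", "provenance")
}

intersect_himr <- function(ca_hyper, co_hyper, min_overlap_bp,
                           case_profile, control_profile, n_cpg_cutoff) {
  prs <- overlap_pairs(ca_hyper, co_hyper, min_overlap_bp)
  if (nrow(prs) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_cpg = integer(), mean_meth = double(),
      class = character(), provenance = character()
    ))
  }
  him <- tibble(
    chrom = ca_hyper$chrom[prs$a_idx],
    start = pmax(ca_hyper$start[prs$a_idx], co_hyper$start[prs$b_idx]),
    end = pmin(ca_hyper$end[prs$a_idx], co_hyper$end[prs$b_idx]),
    mean_meth = (ca_hyper$mean_meth[prs$a_idx] + co_hyper$mean_meth[prs$b_idx]) / 2
  )
  if (!is.null(case_profile) && !is.null(control_profile)) {
    pos_in <- function(profile, chrom, start, end) {
      sum(profile$chrom == chrom & profile$pos >= start & profile$pos < end)
    }
    him$n_cpg <- vapply(seq_len(nrow(him)), function(i) {
      min(
        pos_in(case_profile, him$chrom[i], him$start[i], him$end[i]),
        pos_in(control_profile, him$chrom[i], him$start[i], him$end[i])
      )
    }, integer(1))
    him <- filter(him, .data$n_cpg >= n_cpg_cutoff)
  } else {
    him$n_cpg <- NA_integer_
  }
  him %>%
    mutate(class = "himr", provenance = "case*control") %>%
    select("chrom", "start", "end", "n_cpg", "mean_meth", "class", "provenance") %>%
    arrange(.data$chrom, .data$start)
}

#' Annotate regions with their genomic category
#'
#' Assigns each region to `promoter`, `exonic`, `intronic` or `intergenic`
#' with precedence promoter > exonic > intronic > intergenic. The promoter
#' window is strand-aware: `promoter_upstream` bp 5' of the TSS through
#' `promoter_downstream` bp 3' of it.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genes Gene annotation tibble with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss` (0-based TSS position).
#' @param exons Optional exon tibble (`chrom`, `start`, `end`); without it no
#'   region is called exonic.
#' @param promoter_upstream,promoter_downstream Promoter window half-widths in
#'   bp (defaults 1000 / 500).
#' @param chrom_sizes Optional named vector of chromosome lengths; regions
#'   beyond bounds raise an error.
#' @return `regions` with a `genomic_category` column appended.
#' @export
annotate_genomic_category <- function(regions, genes, exons = NULL,
                                      promoter_upstream = 1000,
                                      promoter_downstream = 500,
                                      chrom_sizes = NULL) {
  check_intervals(regions, "regions")
  if (!is.null(chrom_sizes) && nrow(regions) > 0) {
    lim <- unname(chrom_sizes[regions$chrom])
    if (any(is.na(lim)) || any(regions$start < 0) || any(regions$end > lim)) {
      abort("regions fall outside the supplied chromosome bounds")
    }
  }
  if (nrow(regions) == 0) {
    return(mutate(regions, genomic_category = character(0)))
  }
  promoters <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+",
      genes$tss - promoter_upstream,
      genes$tss - promoter_downstream + 1L
    ),
    end = ifelse(genes$strand == "+",
      genes$tss + promoter_downstream,
      genes$tss + promoter_upstream + 1L
    )
  ) %>% mutate(start = pmax(.data$start, 0L))
  bodies <- select(genes, "chrom", "start", "end")
  cat <- rep("intergenic", nrow(regions))
  if (nrow(bodies) > 0) {
    cat[unique(overlap_pairs(regions, bodies)$a_idx)] <- "intronic"
  }
  if (!is.null(exons) && nrow(exons) > 0) {
    cat[unique(overlap_pairs(regions, exons)$a_idx)] <- "exonic"
  }
  if (nrow(promoters) > 0) {
    cat[unique(overlap_pairs(regions, promoters)$a_idx)] <- "promoter"
  }
  mutate(regions, genomic_category = cat)
}

#' Fraction of region base pairs covered by a repeat track
#'
#' @param regions Region tibble; optionally grouped via `by`.
#' @param track Repeat interval tibble (`chrom`, `start`, `end`).
#' @param by Optional column name in `regions` to stratify the summary by
#'   (e.g. `"class"`).
#' @return One-row-per-group tibble with `region_bp`, `repeat_bp`, `fraction`.
#' @export
repeat_fraction <- function(regions, track, by = NULL) {
  check_intervals(regions, "regions")
  cov <- if (nrow(regions) > 0) covered_bp(regions, track) else integer()
  x <- mutate(regions, .cov = cov, .len = .data$end - .data$start)
  if (!is.null(by)) x <- group_by(x, .data[[by]])
  summarise(x,
    region_bp = sum(.data$.len),
    repeat_bp = sum(.data$.cov),
    fraction = sum(.data$.cov) / sum(.data$.len),
    .groups = "drop"
  )
}

#' Fraction of regions overlapping any CpG island
#'
#' @param regions Region tibble.
#' @param cgi_track CpG-island interval tibble.
#' @param by Optional stratification column (e.g. `"genomic_category"`).
#' @return Tibble with `n_regions`, `n_overlapping`, `fraction` per group;
#'   `NaN` fraction (with a warning) for an empty region set.
#' @export
cgi_overlap_fraction <- function(regions, cgi_track, by = NULL) {
  check_intervals(regions, "regions")
  if (nrow(regions) == 0) {
    warn("no regions supplied; CGI overlap fraction undefined")
    return(tibble(n_regions = 0L, n_overlapping = 0L, fraction = NaN))
  }
  hit <- logical(nrow(regions))
  hit[unique(overlap_pairs(regions, cgi_track)$a_idx)] <- TRUE
  x <- mutate(regions, .hit = hit)
  if (!is.null(by)) x <- group_by(x, .data[[by]])
  summarise(x,
    n_regions = dplyr::n(),
    n_overlapping = sum(.data$.hit),
    fraction = mean(.data$.hit),
    .groups = "drop"
  )
}
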