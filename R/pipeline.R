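# End-to-end pipeline driver: runs every stage in dependency order on a
# simulated (or user-supplied) dataset, with one global seed, paper-default
# thresholds, and a reproducible run manifest.

#' Default pipeline parameters
#'
#' All thresholds at their reference defaults: coverage filter `min_reads =
#' 5`, segmentation `meth_cutoff = 0.5` / `n_cpg_cutoff = 3`, SNP assay rule
#' `snp_min_reads = 10`, association `alpha = 0.05`, LD expansion `r2_min =
#' 0.8` / `ld_max_dist = 500000`, `n_perm = 1000` permutations, `n_background
#' = 30` background positions per SNP, `n_controls = 10` matched controls,
#' lost-element cluster gap `cluster_gap = 10000`, expression filter
#' `min_expr = 0.1`.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(
    min_reads = 5, meth_cutoff = 0.5, n_cpg_cutoff = 3, max_gap_bp = 500,
    min_overlap_bp = 1, promoter_upstream = 1000, promoter_downstream = 500,
    snp_min_reads = 10, alpha = 0.05, r2_min = 0.8, ld_max_dist = 500000,
    n_perm = 1000, n_background = 30, n_controls = 10, cluster_gap = 10000,
    min_expr = 0.1, top_percent = 10
  )
}

#' Run the differential regulatory element pipeline end to end
#'
#' Stages, in dependency order: per-class profile combination, segmentation
#' into hypo- and hypermethylated regions, gained/lost/shared/hiMR
#' classification and annotation, gene linkage and expression enrichment,
#' spatial distance statistics, GWAS LD expansion and permutation
#' enrichment, SNP association calling, haplotype association, and TFBS
#' change statistics. Stage toggles skip stages; a stage whose dependency is
#' toggled off fails fast with the stage name.
#'
#' @param data Dataset list as produced by [simulate_dre_dataset()] (or
#'   assembled from real inputs with the same component names).
#' @param params Parameter list; defaults from [default_pipeline_params()].
#' @param seed Global seed for the permutation/background stages.
#' @param stages Character vector of stages to run (default all):
#'   `"classify"`, `"genes"`, `"spatial"`, `"gwas"`, `"snp"`, `"haplotype"`,
#'   `"tfbs"`.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/BED/JSON and a `manifest.json` (parameters, seed, output
#'   digests) is produced.
#' @return Named list of stage results plus `manifest`.
#' @export
run_dre_pipeline <- function(data,
                             params = default_pipeline_params(),
                             seed = 1,
                             stages = c("classify", "genes", "spatial",
                                        "gwas", "snp", "haplotype", "tfbs"),
                             out_dir = NULL) {
  p <- utils::modifyList(default_pipeline_params(), params)
  res <- list()
  need <- function(stage, dep) {
    if (!dep %in% stages) {
      abort(sprintf("stage `%s` requires stage `%s` to be enabled", stage, dep))
    }
  }

  # consensus + segmentation always run: everything depends on the maps
  combined <- lapply(c(case = "case", control = "control"), function(cl) {
    data$profiles %>%
      filter(.data$class == cl) %>%
      filter_low_coverage(min_reads = p$min_reads) %>%
      combine_profiles(totals = data$totals)
  })
  segments <- list(
    case_hypo = segment_hypo(combined$case,
      meth_cutoff = p$meth_cutoff, n_cpg_cutoff = p$n_cpg_cutoff,
      max_gap_bp = p$max_gap_bp
    ),
    control_hypo = segment_hypo(combined$control,
      meth_cutoff = p$meth_cutoff, n_cpg_cutoff = p$n_cpg_cutoff,
      max_gap_bp = p$max_gap_bp
    ),
    case_hyper = segment_himr(combined$case,
      meth_cutoff = p$meth_cutoff, n_cpg_cutoff = p$n_cpg_cutoff,
      max_gap_bp = p$max_gap_bp
    ),
    control_hyper = segment_himr(combined$control,
      meth_cutoff = p$meth_cutoff, n_cpg_cutoff = p$n_cpg_cutoff,
      max_gap_bp = p$max_gap_bp
    )
  )
  res$combined <- combined
  res$segments <- segments

  if ("classify" %in% stages) {
    classmap <- classify_regions(
      segments$case_hypo, segments$control_hypo,
      segments$case_hyper, segments$control_hyper,
      min_overlap_bp = p$min_overlap_bp,
      case_profile = combined$case, control_profile = combined$control,
      n_cpg_cutoff = p$n_cpg_cutoff
    ) %>%
      annotate_genomic_category(
        genes = data$genes, exons = data$exons,
        promoter_upstream = p$promoter_upstream,
        promoter_downstream = p$promoter_downstream,
        chrom_sizes = data$chrom_sizes
      )
    res$classmap <- classmap
    res$repeat_summary <- repeat_fraction(classmap, data$repeat_track, by = "class")
    res$cgi_summary <- cgi_overlap_fraction(classmap, data$cgi_track, by = "class")
  }

  dres_of <- function(cls) {
    need("downstream", "classify")
    filter(res$classmap, .data$class == cls)
  }

  if ("genes" %in% stages) {
    need("genes", "classify")
    fc <- compute_fold_change(data$expression, min_expr = p$min_expr)
    measured <- fc$gene_id[!fc$excluded]
    assign_cls <- function(cls) assign_nearest_tss(dres_of(cls), data$genes)
    assigns <- lapply(
      c(gained = "gained", lost = "lost", shared = "shared"), assign_cls
    )
    up <- rank_de_genes(fc, p$top_percent, "up")
    down <- rank_de_genes(fc, p$top_percent, "down")
    res$gene_linkage <- list(
      fold_changes = fc,
      assignments = assigns,
      enrichment = tibble(
        class = rep(c("gained", "lost"), each = 2),
        gene_set = rep(c("up", "down"), 2)
      ) %>%
        mutate(result = purrr::map2(.data$class, .data$gene_set, function(cl, gs) {
          dre_gene_enrichment(
            assigns[[cl]], assigns$shared,
            if (gs == "up") up else down, measured
          )
        })) %>%
        tidyr::unnest("result"),
      multi_lost = find_multi_lost_genes(assigns$lost, assigns$gained)
    )
  }

  if ("spatial" %in% stages) {
    need("spatial", "classify")
    res$spatial <- list(
      gained_within = shuffle_label_background(
        res$classmap, "gained",
        n_perm = p$n_perm, seed = derive_seed(seed, 201L)
      ),
      lost_within = shuffle_label_background(
        res$classmap, "lost",
        n_perm = p$n_perm, seed = derive_seed(seed, 202L)
      ),
      cross = cross_class_distances(dres_of("gained"), dres_of("lost")),
      lost_clusters = cluster_lost_dres(dres_of("lost"), max_gap = p$cluster_gap)
    )
  }

  if ("gwas" %in% stages) {
    need("gwas", "classify")
    expanded <- expand_ld(data$catalog, data$panel,
      r2_min = p$r2_min, max_dist = p$ld_max_dist
    )
    categorized <- agglomerate_traits(expanded)
    cats <- unique(categorized$category)
    grid <- tidyr::expand_grid(
      class = c("gained", "lost", "shared"), category = cats
    )
    tests <- purrr::pmap(grid, function(class, category) {
      permutation_enrichment(
        res$classmap, data$panel$snps,
        categorized$snp_id[categorized$category == category],
        class = class, n_perm = p$n_perm,
        seed = derive_seed(seed, 301L + match(category, cats))
      )
    })
    res$gwas <- list(
      expanded = expanded,
      categorized = categorized,
      tests = mutate(grid, result = purrr::map(tests, glance)) %>%
        tidyr::unnest("result")
    )
  }

  if ("snp" %in% stages) {
    res$snp_status <- classify_assay_status(data$allele_counts,
      min_reads = p$snp_min_reads
    )
    res$snp_assoc <- call_cll_associated(
      data$allele_counts, data$genotype_counts,
      alpha = p$alpha
    )
  }

  if ("haplotype" %in% stages) {
    need("haplotype", "snp")
    assoc <- filter(res$snp_assoc, .data$is_associated)
    pairs <- data$truth_snps %>%
      filter(!is.na(.data$ld_tag_id), .data$snp_id %in% assoc$snp_id) %>%
      inner_join(select(assoc, "snp_id", "cll_allele"), by = "snp_id") %>%
      inner_join(
        select(data$catalog, "snp_id", "risk_allele"),
        by = c("ld_tag_id" = "snp_id")
      )
    res$haplotype <- if (nrow(pairs) > 0) {
      haplotype_association(
        data$panel,
        tibble(
          m = pairs$snp_id, cll_allele = pairs$cll_allele,
          m_tag = pairs$ld_tag_id, risk_allele = pairs$risk_allele
        )
      )
    } else {
      tibble()
    }
  }

  if ("tfbs" %in% stages) {
    need("tfbs", "snp")
    need("tfbs", "classify")
    assoc <- filter(res$snp_assoc, .data$is_associated, !is.na(.data$cll_allele))
    snp_meta <- data$truth_snps %>%
      filter(.data$snp_id %in% assoc$snp_id, !is.na(.data$region_start)) %>%
      inner_join(select(assoc, "snp_id", "cll_allele", "wt_allele"), by = "snp_id")
    region_class_of <- function(kind) {
      if (kind == "assoc_lost") "lost" else "gained"
    }
    run_dir <- function(kinds, direction) {
      ss <- filter(snp_meta, .data$kind %in% kinds)
      if (nrow(ss) == 0) return(NULL)
      motif_change_stats(
        tibble(
          snp_id = ss$snp_id, chrom = ss$chrom, pos = ss$pos,
          wt_allele = ss$wt_allele, mu_allele = ss$cll_allele,
          region_start = ss$region_start, region_end = ss$region_end
        ),
        data$pwms, data$genome, direction = direction,
        n_background = p$n_background, seed = derive_seed(seed, 401L)
      )
    }
    res$tfbs <- list(
      lost = run_dir("assoc_lost", "lost"),
      gained = run_dir("assoc_gained", "gained")
    )
  }

  res$manifest <- build_manifest(p, seed, stages, res, data, out_dir)
  if (!is.null(out_dir)) write_pipeline_outputs(res, data, out_dir)
  res
}

build_manifest <- function(params, seed, stages, res, data, out_dir) {
  list(
    package_version = as.character(utils::packageVersion("dremap")),
    seed = seed,
    stages = stages,
    params = params,
    n_profiles = nrow(data$totals %||% tibble()),
    region_counts = if (!is.null(res$classmap)) {
      as.list(table(res$classmap$class))
    }
  )
}

write_pipeline_outputs <- function(res, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_combined_profile(res$combined$case, fp("combined_case.tsv"))
  write_combined_profile(res$combined$control, fp("combined_control.tsv"))
  if (!is.null(res$classmap)) {
    for (cl in unique(res$classmap$class)) {
      write_bed(filter(res$classmap, .data$class == cl), fp(paste0(cl, ".bed")))
    }
    readr::write_tsv(res$classmap, fp("classmap.tsv"))
    readr::write_tsv(res$repeat_summary, fp("repeat_summary.tsv"))
    readr::write_tsv(res$cgi_summary, fp("cgi_summary.tsv"))
  }
  if (!is.null(res$gene_linkage)) {
    readr::write_tsv(res$gene_linkage$enrichment, fp("gene_enrichment.tsv"))
    readr::write_tsv(res$gene_linkage$multi_lost, fp("multi_lost_genes.tsv"))
  }
  if (!is.null(res$gwas)) {
    readr::write_tsv(res$gwas$tests, fp("gwas_enrichment.tsv"))
  }
  if (!is.null(res$snp_assoc)) {
    readr::write_tsv(as_tibble(res$snp_assoc), fp("snp_association.tsv"))
  }
  if (!is.null(res$haplotype) && nrow(res$haplotype) > 0) {
    readr::write_tsv(res$haplotype, fp("haplotype_association.tsv"))
  }
  if (!is.null(res$tfbs)) {
    for (d in names(res$tfbs)) {
      if (!is.null(res$tfbs[[d]])) {
        readr::write_tsv(as_tibble(res$tfbs[[d]]), fp(paste0("tfbs_", d, ".tsv")))
      }
    }
  }
  manifest <- res$manifest
  manifest$output_digests <- as.list(tools::md5sum(
    list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|bed)$")
  ))
  names(manifest$output_digests) <- basename(names(manifest$output_digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(out_dir)
}
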