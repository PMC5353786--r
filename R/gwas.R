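# GWAS catalog analysis: LD expansion of tag SNPs over phased haplotype
# panels, keyword trait agglomeration, and permutation enrichment of trait
# SNPs in region classes.

#' Squared allelic correlation between two panel SNPs
#'
#' Computes r-squared from phased haplotypes:
#' \deqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))}
#' where frequencies are taken over the panel chromosomes.
#'
#' @param panel A phased haplotype panel (see [generate_haplotype_panel()]):
#'   list with an integer 0/1 matrix `haplotypes` (chromosomes x SNPs, column
#'   names = SNP ids) and a `snps` tibble.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in `[0, 1]`; `NA` with a warning for a monomorphic SNP.
#' @export
compute_r2 <- function(panel, snp_a, snp_b) {
  H <- panel$haplotypes
  if (!all(c(snp_a, snp_b) %in% colnames(H))) {
    abort("both SNPs must be present in the panel")
  }
  a <- H[, snp_a]
  b <- H[, snp_b]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    warn("monomorphic SNP: r-squared undefined")
    return(NA_real_)
  }
  pab <- mean(a == 1 & b == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Expand GWAS tag SNPs through linkage disequilibrium
#'
#' A panel SNP joins a trait when it is in tight LD (`r2 > r2_min` and
#' distance `< max_dist` bp) with any tag SNP of that trait in at least one
#' of the supplied panels. Tag SNPs themselves are always members of their
#' trait set; tags absent from every panel keep only themselves (logged).
#'
#' @param catalog GWAS catalog tibble: `snp_id`, `chrom`, `pos`, `trait`,
#'   `risk_allele`.
#' @param panels A single panel or list of panels.
#' @param r2_min LD threshold (default 0.8, strict `>`).
#' @param max_dist Maximum tag-partner distance in bp (default 500000,
#'   strict `<`).
#' @return Tibble `trait`, `snp_id`, `chrom`, `pos`, `tag_snp`, `r2`, `panel`
#'   (provenance; `"tag"` for the tag itself), one row per (trait, SNP,
#'   best-provenance).
#' @export
expand_ld <- function(catalog, panels, r2_min = 0.8, max_dist = 500000) {
  if (!is.null(panels$haplotypes)) panels <- list(panels)
  if (nrow(catalog) == 0) {
    return(tibble(
      trait = character(), snp_id = character(), chrom = character(),
      pos = integer(), tag_snp = character(), r2 = double(), panel = character()
    ))
  }
  tags <- distinct(catalog, .data$trait, .data$snp_id, .data$chrom, .data$pos)
  rows <- list(
    tibble(
      trait = tags$trait, snp_id = tags$snp_id, chrom = tags$chrom,
      pos = tags$pos, tag_snp = tags$snp_id, r2 = 1, panel = "tag"
    )
  )
  missing_tags <- character()
  for (t in seq_len(nrow(tags))) {
    found <- FALSE
    for (pi in seq_along(panels)) {
      pan <- panels[[pi]]
      if (!tags$snp_id[t] %in% colnames(pan$haplotypes)) next
      found <- TRUE
      cand <- pan$snps %>%
        filter(
          .data$chrom == tags$chrom[t],
          abs(.data$pos - tags$pos[t]) < max_dist,
          .data$snp_id != tags$snp_id[t]
        )
      if (nrow(cand) == 0) next
      r2 <- vapply(
        cand$snp_id,
        function(s) suppressWarnings(compute_r2(pan, tags$snp_id[t], s)),
        double(1)
      )
      keep <- !is.na(r2) & r2 > r2_min
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- tibble(
          trait = tags$trait[t],
          snp_id = cand$snp_id[keep],
          chrom = cand$chrom[keep],
          pos = cand$pos[keep],
          tag_snp = tags$snp_id[t],
          r2 = unname(r2[keep]),
          panel = names(panels)[pi] %||% paste0("panel", pi)
        )
      }
    }
    if (!found) missing_tags <- c(missing_tags, tags$snp_id[t])
  }
  if (length(missing_tags) > 0) {
    inform(sprintf(
      "%d tag SNP(s) absent from all panels kept as singletons",
      length(unique(missing_tags))
    ))
  }
  bind_rows(rows) %>%
    arrange(.data$trait, .data$snp_id, dplyr::desc(.data$r2)) %>%
    distinct(.data$trait, .data$snp_id, .keep_all = TRUE)
}

#' Default trait agglomeration keyword rules
#'
#' Regular expressions (case-insensitive) defining the agglomerated trait
#' categories, applied with precedence CLL > lymphoma > cancer; everything
#' else is the irrelevant baseline.
#'
#' @return Named list of regex character vectors.
#' @export
default_trait_rules <- function() {
  list(
    CLL = c("chronic lymphocytic leuk", "\\bCLL\\b"),
    lymphoma = c("lymphoma"),
    cancer = c(
      "cancer", "carcinoma", "melanoma", "leuk[ae]mia", "tumou?r",
      "myeloma", "glioma", "sarcoma", "neoplas"
    )
  )
}

#' Agglomerate GWAS traits into broad categories
#'
#' Maps each trait string to one of `CLL`, `lymphoma`, `cancer` or
#' `irrelevant` by keyword matching with precedence CLL > lymphoma > cancer >
#' irrelevant (so lymphoma excludes CLL-matched traits). Precedence is also
#' enforced at the SNP level so category SNP sets are disjoint.
#'
#' @param trait_snps Tibble with at least `trait` and `snp_id` (e.g. an
#'   [expand_ld()] result or the raw catalog).
#' @param rules Keyword rules as from [default_trait_rules()].
#' @return `trait_snps` with a `category` column, category-disjoint by SNP.
#' @export
agglomerate_traits <- function(trait_snps, rules = default_trait_rules()) {
  cat_of_trait <- function(trait) {
    for (nm in names(rules)) {
      if (any(vapply(rules[[nm]], function(rx) {
        grepl(rx, trait, ignore.case = TRUE, perl = TRUE)
      }, logical(1)))) {
        return(nm)
      }
    }
    "irrelevant"
  }
  lev <- c(names(rules), "irrelevant")
  x <- trait_snps %>%
    mutate(category = vapply(.data$trait, cat_of_trait, character(1)))
  # SNP-level precedence: a SNP under several categories keeps the strongest
  x %>%
    mutate(.ord = match(.data$category, lev)) %>%
    group_by(.data$snp_id) %>%
    mutate(category = lev[min(.data$.ord)]) %>%
    ungroup() %>%
    select(-".ord")
}

# SNP membership in half-open regions; returns region row index or NA.
snp_region_index <- function(snps, regions) {
  idx <- rep(NA_integer_, nrow(snps))
  if (nrow(regions) == 0 || nrow(snps) == 0) return(idx)
  pts <- tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1L)
  prs <- overlap_pairs(pts, regions)
  idx[prs$a_idx] <- prs$b_idx
  idx
}

#' Permutation test of trait-SNP enrichment in a region class
#'
#' Counts the trait-associated SNPs falling in the tested class and compares
#' against the counts obtained after shuffling class labels among all regions
#' (class sizes fixed, coordinates fixed). Reports the raw exceedance
#' probability and the add-one-corrected permutation p-value, plus the SNP
#' density per 1,000 panel SNPs in the class.
#'
#' @param classmap Region tibble with a `class` column.
#' @param panel_snps All panel SNPs: tibble `snp_id`, `chrom`, `pos`.
#' @param trait_snps SNP ids of the tested trait/category.
#' @param class Tested class label (default `"gained"`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `gwas_permutation`: list with `observed`,
#'   `density_per_1000`, `n_class_snps`, `p_value` (add-one), `p_raw`,
#'   `perm_counts`, `n_perm`, `seed`, `class`.
#' @export
permutation_enrichment <- function(classmap, panel_snps, trait_snps,
                                   class = "gained", n_perm = 1000, seed = 1) {
  assert_count(n_perm, "n_perm")
  classmap <- arrange(classmap, .data$chrom, .data$start, .data$end)
  ridx <- snp_region_index(panel_snps, classmap)
  in_region <- !is.na(ridx)
  is_trait <- panel_snps$snp_id %in% trait_snps
  # per-region SNP tallies make each permutation a label-indexed sum
  n_reg <- nrow(classmap)
  trait_per_region <- tabulate(ridx[in_region & is_trait], nbins = n_reg)
  panel_per_region <- tabulate(ridx[in_region], nbins = n_reg)
  lab <- classmap$class
  target <- lab == class
  observed <- sum(trait_per_region[target])
  n_class_snps <- sum(panel_per_region[target])
  perm_counts <- integer(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm_target <- sample(target)
      perm_counts[p] <- sum(trait_per_region[perm_target])
    }
  })
  if (n_class_snps == 0) {
    warn("no panel SNPs in the tested class; density undefined")
  }
  structure(
    list(
      observed = observed,
      density_per_1000 = if (n_class_snps > 0) 1000 * observed / n_class_snps else NaN,
      n_class_snps = n_class_snps,
      p_value = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
      p_raw = mean(perm_counts >= observed),
      perm_counts = perm_counts,
      n_perm = n_perm,
      seed = seed,
      class = class
    ),
    class = "gwas_permutation"
  )
}
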