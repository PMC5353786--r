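# broom-style tidiers for the package's result objects.

#' Tidy a gene-set enrichment result
#'
#' @param x A `dre_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble of the enrichment quantities.
#' @export
tidy.dre_enrichment <- function(x, ...) {
  as_tibble(unclass(x)[c(
    "n_R", "k_R", "fract_R_G", "n_S", "k_S", "fract_S_G",
    "enrichment", "p_enrich", "p_deplete", "direction", "p_value"
  )])
}

#' @rdname tidy.dre_enrichment
#' @export
glance.dre_enrichment <- function(x, ...) {
  tibble(enrichment = x$enrichment, p_value = x$p_value, direction = x$direction)
}

#' Tidy a GWAS permutation enrichment test
#'
#' @param x A `gwas_permutation` object.
#' @param ... Unused.
#' @return Tibble of the permutation counts (one row per permutation).
#' @export
tidy.gwas_permutation <- function(x, ...) {
  tibble(permutation = seq_along(x$perm_counts), count = x$perm_counts)
}

#' @rdname tidy.gwas_permutation
#' @export
glance.gwas_permutation <- function(x, ...) {
  tibble(
    observed = x$observed,
    density_per_1000 = x$density_per_1000,
    n_class_snps = x$n_class_snps,
    p_value = x$p_value,
    p_raw = x$p_raw,
    n_perm = x$n_perm
  )
}

#' Tidy a spatial distance test
#'
#' @param x A `spatial_test` object.
#' @param ... Unused.
#' @return Tibble of observed and pooled background distances (long format
#'   with a `source` column).
#' @export
tidy.spatial_test <- function(x, ...) {
  bind_rows(
    tibble(source = "observed", distance = x$distances),
    tibble(source = "background", distance = x$background_pooled)
  )
}

#' @rdname tidy.spatial_test
#' @export
glance.spatial_test <- function(x, ...) {
  tibble(
    n = length(x$distances),
    median_observed = stats::median(x$distances),
    median_background = stats::median(x$background_pooled),
    statistic = x$statistic,
    p_value = x$p_value,
    alternative = x$alternative,
    n_perm = x$n_perm
  )
}

#' @export
print.spatial_test <- function(x, ...) {
  cat(sprintf(
    "Spatial distance test (%s): n = %d, rank-sum p = %.3g (%d permutations)\n",
    x$alternative, length(x$distances), x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @export
print.gwas_permutation <- function(x, ...) {
  cat(sprintf(
    "GWAS permutation enrichment [%s]: observed %d trait SNPs (%.2f per 1,000 class SNPs), p = %.3g (%d permutations)\n",
    x$class, x$observed, x$density_per_1000, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "PWM %s: width %d, consensus %s, hit threshold p <= %g\n",
    x$motif_id, x$width, x$consensus, x$p_threshold
  ))
  invisible(x)
}
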