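# Haplotype association between a cancer-associated allele and a GWAS risk
# allele: 2x2 chromosome-count table, odds ratio, Fisher's exact test.

#' Build the 2x2 haplotype contingency table
#'
#' Over all phased panel chromosomes, counts `D11` (cancer-associated allele
#' at the tested SNP and risk allele at the tag SNP), `D12`, `D21`, `D22`,
#' where the "2" stratum pools all non-focal alleles at either SNP.
#'
#' @param panel Phased haplotype panel (list with `haplotypes` 0/1 matrix and
#'   `snps` tibble carrying `snp_id`, `ref`, `alt`).
#' @param m Tested SNP id.
#' @param cll_allele Cancer-associated allele (base) at `m`.
#' @param m_tag GWAS tag SNP id.
#' @param risk_allele Risk allele (base) at `m_tag`.
#' @return Object of class `haplotype_table`: list with the 2x2 integer
#'   matrix `D` and the identifying metadata.
#' @export
build_contingency <- function(panel, m, cll_allele, m_tag, risk_allele) {
  H <- panel$haplotypes
  for (s in c(m, m_tag)) {
    if (!s %in% colnames(H)) abort(sprintf("SNP %s missing from panel", s))
    if (anyNA(H[, s])) abort(sprintf("SNP %s has missing/unphased genotypes", s))
  }
  allele_is <- function(snp, allele) {
    info <- panel$snps[panel$snps$snp_id == snp, ]
    if (allele == info$ref) {
      H[, snp] == 0L
    } else if (allele == info$alt) {
      H[, snp] == 1L
    } else {
      abort(sprintf("allele %s not observed at SNP %s", allele, snp))
    }
  }
  a <- allele_is(m, cll_allele)
  b <- allele_is(m_tag, risk_allele)
  D <- matrix(
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      c("cll_allele", "other_m"),
      c("risk_allele", "other_tag")
    )
  )
  structure(
    list(D = D, m = m, cll_allele = cll_allele, m_tag = m_tag,
         risk_allele = risk_allele, n_chromosomes = nrow(H)),
    class = "haplotype_table"
  )
}

as_d_matrix <- function(table) {
  if (inherits(table, "haplotype_table")) return(table$D)
  if (is.matrix(table) && all(dim(table) == c(2, 2))) return(table)
  abort("expected a haplotype_table or a 2x2 matrix")
}

#' Haplotype odds ratio
#'
#' \deqn{OR = D_{11} D_{22} / (D_{12} D_{21})}, with an infinite sentinel
#' when the denominator is 0 but the numerator is positive, and `NaN` when
#' both products are 0.
#'
#' @param table A `haplotype_table` or plain 2x2 matrix
#'   (`rbind(c(D11, D12), c(D21, D22))`).
#' @return The odds ratio.
#' @export
odds_ratio <- function(table) {
  D <- as_d_matrix(table)
  num <- as.double(D[1, 1]) * D[2, 2]
  den <- as.double(D[1, 2]) * D[2, 1]
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Fisher's exact test on a haplotype table
#'
#' Two-sided p-value by the point-probability method (sum of the
#' probabilities of all tables, at the observed margins, no more probable
#' than the observed one); one-sided alternatives are also available.
#'
#' @param table A `haplotype_table` or 2x2 matrix.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
fisher_exact_p <- function(table, alternative = "two.sided") {
  D <- as_d_matrix(table)
  fisher.test(D, alternative = alternative)$p.value
}

#' Test haplotype association for a list of SNP pairs
#'
#' @param panel Phased haplotype panel.
#' @param pairs Tibble `m`, `cll_allele`, `m_tag`, `risk_allele`.
#' @return Tibble with the table counts, `odds_ratio`, two-sided `p_value`
#'   and one-sided `p_greater`, one row per pair.
#' @export
haplotype_association <- function(panel, pairs) {
  purrr::pmap_dfr(pairs, function(m, cll_allele, m_tag, risk_allele, ...) {
    tab <- build_contingency(panel, m, cll_allele, m_tag, risk_allele)
    tibble(
      m = m, cll_allele = cll_allele, m_tag = m_tag, risk_allele = risk_allele,
      D11 = tab$D[1, 1], D12 = tab$D[1, 2],
      D21 = tab$D[2, 1], D22 = tab$D[2, 2],
      odds_ratio = odds_ratio(tab),
      p_value = fisher_exact_p(tab),
      p_greater = fisher_exact_p(tab, "greater")
    )
  })
}
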