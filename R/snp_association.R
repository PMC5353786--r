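# Cancer-associated SNP calling from pooled read counts: assay-status
# classification and the exact binomial allele/genotype comparison.

#' Classify SNP assay status from read evidence
#'
#' SNPs polymorphic in the read pool are `assayed_polymorphic`; monomorphic
#' positions are `non_assayed` when covered by fewer than `min_reads` reads
#' overall and `non_mutated` otherwise.
#'
#' @param allele_counts Long tibble `snp_id`, `class` (`"case"`/`"control"`),
#'   `allele`, `count` of pooled read-level allele occurrences.
#' @param min_reads Read threshold for the non-assayed rule (default 10).
#' @return Tibble `snp_id`, `total_reads`, `n_alleles`, `status`.
#' @export
classify_assay_status <- function(allele_counts, min_reads = 10) {
  allele_counts %>%
    group_by(.data$snp_id) %>%
    summarise(
      total_reads = sum(.data$count),
      n_alleles = dplyr::n_distinct(.data$allele[.data$count > 0]),
      .groups = "drop"
    ) %>%
    mutate(status = case_when(
      .data$n_alleles >= 2 ~ "assayed_polymorphic",
      .data$total_reads < min_reads ~ "non_assayed",
      TRUE ~ "non_mutated"
    ))
}

#' Strict upper-tail binomial probability for an allele count
#'
#' The probability \eqn{\Pr(X > n_{k,c})} of observing strictly more than the
#' case-class occurrence count of an allele under a binomial with the
#' case-class total as trial count and the control-class allele frequency as
#' success probability:
#' \deqn{\Pr(X > n_{k,c}) = 1 - \sum_{i=0}^{n_{k,c}} \binom{n_c}{i}
#'   p_{k,n}^{\,i} (1 - p_{k,n})^{n_c - i}.}
#'
#' @param n_kc Observed allele count in the case class (vectorised).
#' @param n_c Total allele occurrences in the case class.
#' @param p_kn Allele frequency in the control class.
#' @return Tail probability in `[0, 1]`.
#' @export
allele_tail_probability <- function(n_kc, n_c, p_kn) {
  if (any(p_kn < 0 | p_kn > 1)) abort("`p_kn` must lie in [0, 1]")
  if (any(n_kc < 0 | n_kc > n_c)) abort("need 0 <= n_kc <= n_c")
  pbinom(n_kc, n_c, p_kn, lower.tail = FALSE)
}

#' Call cancer-associated SNPs and their alleles
#'
#' For each assayed polymorphic SNP, computes the strict upper-tail binomial
#' probability of every allele's case-class count given its control-class
#' frequency, and likewise for every diploid genotype state over samples. The
#' minimum of these tail probabilities measures the genotypic difference
#' between classes; SNPs with minimum below `alpha` are flagged associated,
#' and the allele with the largest positive case-minus-control frequency
#' excess is the cancer-associated (MU) allele; the remaining major allele is
#' reported as WT.
#'
#' Alleles or states with control frequency 0 make the tail 0 (trivial
#' association from any case observation); such SNPs carry a
#' `zero_control_freq` flag so callers can require a minimum control depth.
#' No multiple-testing correction is applied by default, matching the raw
#' 0.05 rule; `adjust = TRUE` appends a Benjamini-Hochberg column.
#'
#' @param allele_counts Long tibble `snp_id`, `class`, `allele`, `count`
#'   (pooled read counts).
#' @param genotype_counts Optional long tibble `snp_id`, `class`, `genotype`,
#'   `count` of diploid genotype states across samples.
#' @param alpha Association threshold on the minimum tail probability
#'   (default 0.05).
#' @param adjust Add a BH-adjusted column (default FALSE).
#' @return Tibble of class `snp_association`: `snp_id`, `status`,
#'   `p_allele`, `p_genotype`, `min_p`, `is_associated`, `cll_allele`,
#'   `wt_allele`, `zero_control_freq`.
#' @export
call_cll_associated <- function(allele_counts, genotype_counts = NULL,
                                alpha = 0.05, adjust = FALSE) {
  status <- classify_assay_status(allele_counts)
  snps <- status$snp_id[status$status == "assayed_polymorphic"]
  res <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    ac <- filter(allele_counts, .data$snp_id == s)
    wide <- ac %>%
      group_by(.data$allele) %>%
      summarise(
        case = sum(.data$count[.data$class == "case"]),
        control = sum(.data$count[.data$class == "control"]),
        .groups = "drop"
      )
    n_c <- sum(wide$case)
    n_n <- sum(wide$control)
    if (n_n == 0) abort(sprintf("SNP %s has no control reads", s))
    if (n_c == 0) abort(sprintf("SNP %s has no case reads", s))
    p_kn <- wide$control / n_n
    p_all <- allele_tail_probability(wide$case, n_c, p_kn)
    p_geno <- NA_real_
    if (!is.null(genotype_counts)) {
      gc <- filter(genotype_counts, .data$snp_id == s)
      if (nrow(gc) > 0) {
        gw <- gc %>%
          group_by(.data$genotype) %>%
          summarise(
            case = sum(.data$count[.data$class == "case"]),
            control = sum(.data$count[.data$class == "control"]),
            .groups = "drop"
          )
        m_c <- sum(gw$case)
        m_n <- sum(gw$control)
        if (m_c > 0 && m_n > 0) {
          p_geno <- min(allele_tail_probability(gw$case, m_c, gw$control / m_n))
        }
      }
    }
    min_p <- min(c(p_all, p_geno), na.rm = TRUE)
    excess <- wide$case / n_c - p_kn
    cll_allele <- NA_character_
    wt_allele <- NA_character_
    if (max(excess) > 0) {
      cand <- which(excess == max(excess))
      cll_allele <- min(wide$allele[cand])
      others <- wide[wide$allele != cll_allele, ]
      wt_allele <- others$allele[which.max(others$control)]
    }
    res[[i]] <- tibble(
      snp_id = s,
      p_allele = min(p_all),
      p_genotype = p_geno,
      min_p = min_p,
      is_associated = min_p < alpha & !is.na(cll_allele),
      cll_allele = ifelse(min_p < alpha, cll_allele, NA_character_),
      wt_allele = ifelse(min_p < alpha, wt_allele, NA_character_),
      zero_control_freq = any(p_kn == 0 & wide$case > 0)
    )
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      snp_id = character(), p_allele = double(), p_genotype = double(),
      min_p = double(), is_associated = logical(), cll_allele = character(),
      wt_allele = character(), zero_control_freq = logical()
    )
  }
  out <- left_join(select(status, "snp_id", "status"), out, by = "snp_id")
  if (adjust && nrow(out) > 0) {
    out$p_adjusted <- p.adjust(out$min_p, method = "BH")
  }
  class(out) <- c("snp_association", class(out))
  out
}
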