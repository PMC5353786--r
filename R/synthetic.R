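# Seeded synthetic-data generator. Produces every input the pipeline
# consumes -- genome, annotation, tracks, per-sample CpG counts, SNP read
# counts, phased haplotype panel, GWAS catalog, PWMs, expression table --
# with planted ground truth manifests sufficient to score recovery.

#' Configuration for the synthetic dataset
#'
#' Defaults mirror the study design this package models: 32 cancer-class
#' versus 10 control-class samples, mean CpG coverage of 30 reads, planted
#' regions at methylation 0.05 (active/hypomethylated) versus 0.9
#' (inactive/background), and at least three CpGs per region.
#'
#' @param seed Integer master seed; all generators derive sub-seeds from it.
#' @param n_chromosomes,chrom_length_bp Genome shape (defaults 2 x 1 Mb).
#' @param n_genes Genes in the annotation (default 200).
#' @param n_cpg Background CpG sites beyond the planted regions
#'   (default 4000).
#' @param n_case_samples,n_control_samples Class sizes (defaults 32 / 10).
#' @param mean_coverage Mean reads per CpG (default 30).
#' @param meth_low,meth_high Methylation levels of hypomethylated and
#'   background/hypermethylated CpGs (defaults 0.05 / 0.9).
#' @param planted_regions Tibble of planted regions (`chrom`, `start`, `end`,
#'   `truth_class`, `n_cpg`); `NULL` for the deterministic default layout.
#' @param planted_snps Tibble of planted SNPs; `NULL` for the default set.
#' @param snp_depth_per_sample Mean reads overlapping a SNP per sample
#'   (default 30, matching the CpG coverage).
#' @param n_haplotypes Chromosomes in the phased panel (default 1000).
#' @param n_traits Catalog traits (default 8).
#' @param n_pwms Motifs in the PWM set (default 5).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 2,
                             chrom_length_bp = 1000000,
                             n_genes = 200,
                             n_cpg = 4000,
                             n_case_samples = 32,
                             n_control_samples = 10,
                             mean_coverage = 30,
                             meth_low = 0.05,
                             meth_high = 0.9,
                             planted_regions = NULL,
                             planted_snps = NULL,
                             snp_depth_per_sample = 30,
                             n_haplotypes = 1000,
                             n_traits = 8,
                             n_pwms = 5) {
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(chrom_length_bp, "chrom_length_bp")
  assert_count(n_genes, "n_genes", min = 0)
  assert_count(n_cpg, "n_cpg", min = 0)
  assert_count(n_case_samples, "n_case_samples")
  assert_count(n_control_samples, "n_control_samples")
  if (mean_coverage <= 0) abort("`mean_coverage` must be positive")
  assert_fraction(meth_low, "meth_low")
  assert_fraction(meth_high, "meth_high")
  if (!(meth_low < 0.5 && meth_high >= 0.5)) {
    abort("need meth_low < 0.5 <= meth_high")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    n_genes = n_genes, n_cpg = n_cpg,
    n_case_samples = n_case_samples, n_control_samples = n_control_samples,
    mean_coverage = mean_coverage,
    meth_low = meth_low, meth_high = meth_high,
    snp_depth_per_sample = snp_depth_per_sample,
    n_haplotypes = n_haplotypes, n_traits = n_traits, n_pwms = n_pwms
  )
  cfg$planted_regions <- planted_regions %||% default_planted_regions(cfg)
  pr <- cfg$planted_regions
  if (!"region_id" %in% names(pr)) pr$region_id <- sprintf("pr%02d", seq_len(nrow(pr)))
  if (!"cpg_spacing" %in% names(pr)) pr$cpg_spacing <- 25L
  if (!"companion" %in% names(pr)) pr$companion <- TRUE
  cfg$planted_regions <- pr
  cfg$planted_snps <- planted_snps %||% default_planted_snps(cfg)
  check_intervals(cfg$planted_regions, "planted_regions")
  if (any(cfg$planted_regions$n_cpg < 3)) {
    abort("planted regions need n_cpg >= 3")
  }
  if (any(cfg$planted_regions$end > chrom_length_bp)) {
    abort("planted regions overflow chromosome length")
  }
  ovl <- overlap_pairs(cfg$planted_regions, cfg$planted_regions)
  if (any(ovl$a_idx != ovl$b_idx)) {
    abort("planted regions must not overlap each other")
  }
  structure(cfg, class = "synthetic_config")
}

# Deterministic default layout: regions cycle through the four truth classes
# along the chromosomes; CpGs are spaced 25 bp, regions 8 kb apart.
default_planted_regions <- function(cfg) {
  classes <- rep(c("gained", "lost", "shared", "himr"), length.out = 40)
  n_cpg <- rep(c(8L, 10L, 12L, 15L), length.out = 40)
  spacing <- 25L
  gap <- 8000L
  chrom <- character(40)
  start <- integer(40)
  cur_chrom <- 1L
  cur_pos <- 10000L
  for (i in seq_len(40)) {
    span <- (n_cpg[i] - 1L) * spacing + 2L
    if (cur_pos + span + gap > cfg$chrom_length_bp) {
      cur_chrom <- cur_chrom + 1L
      cur_pos <- 10000L
      if (cur_chrom > cfg$n_chromosomes) abort("planted regions overflow the genome")
    }
    chrom[i] <- paste0("chr", cur_chrom)
    start[i] <- cur_pos
    cur_pos <- cur_pos + span + gap
  }
  base <- tibble(
    chrom = chrom, start = start,
    end = start + (n_cpg - 1L) * spacing + 2L,
    truth_class = classes, n_cpg = n_cpg, cpg_spacing = spacing,
    companion = TRUE
  )
  # a tight cluster of three lost elements sharing one gene locus (the
  # multiple-lost-elements-per-gene pattern), 1.5 kb apart
  clus_start <- cur_pos + integer(3)
  for (i in 1:3) {
    clus_start[i] <- cur_pos
    cur_pos <- cur_pos + (8L - 1L) * spacing + 2L + 1500L
  }
  cluster <- tibble(
    chrom = paste0("chr", cur_chrom), start = clus_start,
    end = clus_start + (8L - 1L) * spacing + 2L,
    truth_class = "lost", n_cpg = 8L, cpg_spacing = spacing,
    companion = FALSE
  )
  out <- bind_rows(base, cluster)
  mutate(out, region_id = sprintf("pr%02d", seq_len(nrow(out))), .before = 1)
}

# Default planted SNPs: associated SNPs inside lost regions (motif-destroying)
# and gained regions (motif-creating), null SNPs, and monomorphic positions
# exercising the non-assayed (<10 reads) and non-mutated rules. One LD tag sits
# 600 kb from its partner to exercise the distance rule.
default_planted_snps <- function(cfg) {
  reg <- cfg$planted_regions
  lost <- utils::head(reg[reg$truth_class == "lost" & reg$companion, ], 6)
  gained <- utils::head(reg[reg$truth_class == "gained" & reg$companion, ], 6)
  shared <- utils::head(reg[reg$truth_class == "shared" & reg$companion, ], 4)
  mid <- function(r) as.integer((r$start + r$end) %/% 2L + 7L)  # off the CpG grid
  snp <- function(id, r, kind, case_f, control_f, tag = NA_character_,
                  r2 = NA_real_, tag_pos = NA_integer_) {
    tibble(
      snp_id = id, chrom = r$chrom, pos = mid(r),
      region_id = r$region_id, region_start = r$start, region_end = r$end,
      kind = kind, case_alt_freq = case_f, control_alt_freq = control_f,
      ld_tag_id = tag, ld_r2_target = r2, ld_tag_pos = tag_pos
    )
  }
  rows <- list()
  for (i in seq_len(nrow(lost))) {
    r <- lost[i, ]
    tag <- if (i <= 3) paste0("tag_L", i) else NA_character_
    tag_pos <- if (i <= 3) mid(r) + 12000L else NA_integer_
    rows[[length(rows) + 1L]] <- snp(
      paste0("snpL", i), r, "assoc_lost", 0.8, 0.2,
      tag, ifelse(i <= 3, 0.95, NA_real_), tag_pos
    )
  }
  for (i in seq_len(nrow(gained))) {
    r <- gained[i, ]
    tag <- if (i <= 3) paste0("tag_G", i) else NA_character_
    # tag 1 is placed 600 kb away: beyond the LD expansion distance rule
    tag_pos <- if (i == 1) {
      mid(r) + 600000L
    } else if (i <= 3) mid(r) + 12000L else NA_integer_
    rows[[length(rows) + 1L]] <- snp(
      paste0("snpG", i), r, "assoc_gained", 0.8, 0.2,
      tag, ifelse(i <= 3, 0.95, NA_real_), tag_pos
    )
  }
  for (i in seq_len(nrow(shared))) {
    rows[[length(rows) + 1L]] <- snp(
      paste0("snpN", i), shared[i, ], "null", 0.5, 0.5
    )
  }
  base <- tibble(
    snp_id = paste0("snpM", 1:6),
    chrom = rep(reg$chrom[1], 6),
    pos = as.integer(5000 + (0:5) * 311),
    region_id = NA_character_,
    region_start = NA_integer_, region_end = NA_integer_,
    kind = rep(c("mono_low", "mono_high"), each = 3),
    case_alt_freq = 0, control_alt_freq = 0,
    ld_tag_id = NA_character_, ld_r2_target = NA_real_,
    ld_tag_pos = NA_integer_
  )
  out <- bind_rows(c(rows, list(base)))
  mutate(out, ld_tag_pos = pmin(.data$ld_tag_pos, 2147483000L))
}

inject_seq <- function(seq, pos0, s) {
  paste0(substr(seq, 1, pos0), s, substr(seq, pos0 + nchar(s) + 1L, nchar(seq)))
}

#' Generate the genome fixture: sequence, genes, repeat and CGI tracks
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named character vector), `genes`, `exons`,
#'   `repeat_track`, `cgi_track`, `chrom_sizes`.
#' @export
generate_genome_fixture <- function(config) {
  cfg <- config
  L <- cfg$chrom_length_bp
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  with_seed(derive_seed(cfg$seed, 101L), {
    genome <- setNames(vapply(chroms, function(ch) {
      paste(sample(DNA, L, replace = TRUE, prob = c(0.275, 0.225, 0.225, 0.275)),
        collapse = ""
      )
    }, character(1)), chroms)
    if (cfg$n_genes > 0) {
      # the first genes are companions: one per planted region, TSS placed
      # 1.5 kb upstream so the region falls in the gene body (nearest-TSS
      # linkage then recovers the planted region-gene coupling)
      reg <- cfg$planted_regions
      comp <- reg[reg$companion %||% rep(TRUE, nrow(reg)), , drop = FALSE]
      clus <- reg[!(reg$companion %||% rep(TRUE, nrow(reg))), , drop = FALSE]
      n_comp <- min(cfg$n_genes, nrow(comp))
      has_clus_gene <- nrow(clus) > 0 && cfg$n_genes > n_comp
      n_rand <- cfg$n_genes - n_comp - as.integer(has_clus_gene)
      g_chrom <- c(
        comp$chrom[seq_len(n_comp)],
        if (has_clus_gene) clus$chrom[1],
        sample(chroms, n_rand, replace = TRUE)
      )
      g_start <- c(
        pmax(0L, comp$start[seq_len(n_comp)] - 1500L),
        if (has_clus_gene) max(0L, clus$start[1] - 1500L),
        as.integer(runif(n_rand, 2000, L - 12000))
      )
      g_len <- c(
        rep(4000L, n_comp),
        # the cluster gene's locus spans all clustered elements
        if (has_clus_gene) as.integer(max(clus$end) - clus$start[1] + 2500L),
        as.integer(runif(n_rand, 2000, 8000))
      )
      strand <- c(
        rep("+", n_comp + as.integer(has_clus_gene)),
        sample(c("+", "-"), n_rand, replace = TRUE)
      )
      genes <- tibble(
        gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
        chrom = g_chrom, start = g_start, end = g_start + g_len,
        strand = strand,
        tss = ifelse(strand == "+", g_start, g_start + g_len - 1L)
      )
      exons <- bind_rows(lapply(seq_len(cfg$n_genes), function(i) {
        e1 <- genes$start[i]
        tibble(
          gene_id = genes$gene_id[i], chrom = genes$chrom[i],
          start = c(e1, e1 + as.integer(g_len[i] * 0.6)),
          end = c(e1 + 200L, e1 + as.integer(g_len[i] * 0.6) + 250L)
        )
      }))
    } else {
      genes <- tibble(
        gene_id = character(), chrom = character(), start = integer(),
        end = integer(), strand = character(), tss = integer()
      )
      exons <- tibble(
        gene_id = character(), chrom = character(),
        start = integer(), end = integer()
      )
    }
    rep_track <- bind_rows(lapply(chroms, function(ch) {
      n_rep <- as.integer(L / 10000)
      st <- sort(sample.int(L - 900L, n_rep))
      tibble(chrom = ch, start = st, end = st + as.integer(runif(n_rep, 200, 800)))
    })) %>% merge_intervals()
    cgi <- bind_rows(lapply(chroms, function(ch) {
      n_cgi <- as.integer(L / 40000)
      st <- sort(sample.int(L - 1000L, n_cgi))
      tibble(chrom = ch, start = st, end = st + as.integer(runif(n_cgi, 300, 800)))
    })) %>% merge_intervals()
  })
  list(
    genome = genome, genes = genes, exons = exons,
    repeat_track = rep_track, cgi_track = cgi,
    chrom_sizes = setNames(rep(L, length(chroms)), chroms)
  )
}

# Planted CpG site table: per-region evenly spaced sites plus background
# sites scattered outside planted regions. `true_meth_*` columns give the
# planted per-class methylation levels.
planted_cpg_sites <- function(cfg) {
  reg <- cfg$planted_regions
  reg_sites <- bind_rows(lapply(seq_len(nrow(reg)), function(i) {
    pos <- reg$start[i] + (seq_len(reg$n_cpg[i]) - 1L) * reg$cpg_spacing[i]
    tibble(chrom = reg$chrom[i], pos = pos, truth_class = reg$truth_class[i])
  }))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  bg <- with_seed(derive_seed(cfg$seed, 102L), {
    bind_rows(lapply(chroms, function(ch) {
      n_bg <- as.integer(ceiling(cfg$n_cpg / cfg$n_chromosomes))
      tibble(
        chrom = ch,
        pos = sort(sample.int(cfg$chrom_length_bp - 2L, n_bg)),
        truth_class = "background"
      )
    }))
  })
  # background CpGs inside planted regions would blur the planted signal
  hit <- snp_region_index(bg, reg)
  bg <- bg[is.na(hit), , drop = FALSE]
  sites <- bind_rows(reg_sites, bg) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$pos)
  sites %>% mutate(
    true_meth_case = case_when(
      .data$truth_class == "gained" ~ cfg$meth_low,
      .data$truth_class == "lost" ~ cfg$meth_high,
      .data$truth_class == "shared" ~ cfg$meth_low,
      TRUE ~ cfg$meth_high
    ),
    true_meth_control = case_when(
      .data$truth_class == "gained" ~ cfg$meth_high,
      .data$truth_class == "lost" ~ cfg$meth_low,
      .data$truth_class == "shared" ~ cfg$meth_low,
      TRUE ~ cfg$meth_high
    )
  )
}

#' Generate per-sample CpG methylation count profiles
#'
#' Per sample and CpG, total reads are Poisson around the sample's coverage
#' (truncated at one read) and methylated reads are binomial with success
#' probability set by the planted region class: gained regions are
#' hypomethylated in the cancer class only, lost regions in the control class
#' only, shared regions in both, and hiMR regions plus all background CpGs
#' are highly methylated in both.
#'
#' @param config A [synthetic_config()].
#' @return List with `profiles` (long tibble `sample_id`, `class`, `chrom`,
#'   `pos`, `strand`, `total_reads`, `meth_reads`), `totals` (`sample_id`,
#'   `class`, `total_aligned_reads`), `truth_regions`, `truth_sites`.
#' @export
generate_methylation_samples <- function(config) {
  cfg <- config
  if (cfg$mean_coverage <= 0) abort("coverage must be positive")
  sites <- planted_cpg_sites(cfg)
  samples <- tibble(
    sample_id = c(
      sprintf("cll%02d", seq_len(cfg$n_case_samples)),
      sprintf("nbc%02d", seq_len(cfg$n_control_samples))
    ),
    class = rep(c("case", "control"), c(cfg$n_case_samples, cfg$n_control_samples))
  )
  n_sites <- nrow(sites)
  profs <- vector("list", nrow(samples))
  with_seed(derive_seed(cfg$seed, 103L), {
    depth_factor <- runif(nrow(samples), 0.8, 1.25)
    for (i in seq_len(nrow(samples))) {
      r <- rpois(n_sites, cfg$mean_coverage * depth_factor[i])
      r[r == 0] <- 1L
      p <- if (samples$class[i] == "case") sites$true_meth_case else sites$true_meth_control
      mr <- rbinom(n_sites, r, p)
      profs[[i]] <- tibble(
        sample_id = samples$sample_id[i], class = samples$class[i],
        chrom = sites$chrom, pos = sites$pos, strand = "+",
        total_reads = as.integer(r), meth_reads = as.integer(mr)
      )
    }
  })
  profiles <- bind_rows(profs)
  totals <- profiles %>%
    group_by(.data$sample_id, .data$class) %>%
    summarise(total_aligned_reads = sum(.data$total_reads), .groups = "drop")
  list(
    profiles = profiles, totals = totals,
    truth_regions = cfg$planted_regions, truth_sites = sites
  )
}

#' Generate the PWM set and plant motif sites into the genome
#'
#' Builds `n_pwms` high-information motifs (width 8-12), writes exact
#' consensus sites into selected planted regions, and arranges the planted
#' associated SNPs so that at lost-region SNPs the WT allele completes a
#' consensus site destroyed by the MU allele, and at gained-region SNPs the
#' MU allele creates a consensus the WT lacks.
#'
#' @param config A [synthetic_config()].
#' @param fixture Genome fixture from [generate_genome_fixture()].
#' @return List with `pwms` (list of [new_pwm()]), `genome` (updated
#'   sequences), `manifest` (planted site table: `motif_id`, `chrom`, `pos`,
#'   `region_id`, `kind`, `snp_id`, `wt_allele`, `mu_allele`).
#' @export
generate_pwm_set <- function(config, fixture) {
  cfg <- config
  genome <- fixture$genome
  # widths 8-9: at the 1e-4 hit threshold these high-information motifs admit
  # only exact-consensus windows, so a planted single-base substitution
  # always creates or destroys the site
  widths <- rep(c(8L, 9L), length.out = cfg$n_pwms)
  pwms <- with_seed(derive_seed(cfg$seed, 104L), {
    lapply(seq_len(cfg$n_pwms), function(i) {
      w <- widths[i]
      cons <- sample(1:4, w, replace = TRUE)
      prob <- matrix(0.03, nrow = 4, ncol = w)
      prob[cbind(cons, seq_len(w))] <- 0.91
      new_pwm(sprintf("motif%02d", i), prob)
    })
  })
  reg <- cfg$planted_regions
  snps <- cfg$planted_snps
  manifest <- list()
  # pure consensus sites in a few gained/lost regions (between CpGs)
  host <- reg[reg$truth_class %in% c("gained", "lost"), ]
  for (i in seq_len(min(nrow(host), 2 * cfg$n_pwms))) {
    p <- pwms[[(i - 1L) %% cfg$n_pwms + 1L]]
    pos <- host$start[i] + 11L  # inside the region, off the SNP midpoint
    genome[[host$chrom[i]]] <- inject_seq(genome[[host$chrom[i]]], pos, p$consensus)
    manifest[[length(manifest) + 1L]] <- tibble(
      motif_id = p$motif_id, chrom = host$chrom[i], pos = pos,
      region_id = host$region_id[i], kind = "consensus_site",
      snp_id = NA_character_, wt_allele = NA_character_, mu_allele = NA_character_
    )
  }
  # allele-coupled sites at the associated SNPs
  assoc <- snps[snps$kind %in% c("assoc_lost", "assoc_gained"), ]
  for (i in seq_len(nrow(assoc))) {
    p <- pwms[[(i - 1L) %% cfg$n_pwms + 1L]]
    w <- p$width
    off <- w %/% 2L          # SNP sits at this offset within the site
    site_start <- assoc$pos[i] - off
    cons_codes <- match(strsplit(p$consensus, "")[[1]], DNA)
    cons_base <- DNA[cons_codes[off + 1L]]
    worst_base <- DNA[which.min(p$prob[, off + 1L])]
    if (assoc$kind[i] == "assoc_lost") {
      # WT completes the consensus; MU destroys it
      genome[[assoc$chrom[i]]] <- inject_seq(genome[[assoc$chrom[i]]], site_start, p$consensus)
      wt <- cons_base
      mu <- worst_base
    } else {
      # site has a mismatch at the SNP; MU restores the consensus
      broken <- p$consensus
      substr(broken, off + 1L, off + 1L) <- worst_base
      genome[[assoc$chrom[i]]] <- inject_seq(genome[[assoc$chrom[i]]], site_start, broken)
      wt <- worst_base
      mu <- cons_base
    }
    manifest[[length(manifest) + 1L]] <- tibble(
      motif_id = p$motif_id, chrom = assoc$chrom[i], pos = assoc$pos[i],
      region_id = assoc$region_id[i],
      kind = ifelse(assoc$kind[i] == "assoc_lost", "destroy_snp", "create_snp"),
      snp_id = assoc$snp_id[i], wt_allele = wt, mu_allele = mu
    )
  }
  list(pwms = pwms, genome = genome, manifest = bind_rows(manifest))
}

# WT/MU alleles per planted SNP, honouring motif-coupled alleles and falling
# back to the genome base (WT) plus a transversion (MU).
planted_snp_alleles <- function(cfg, genome, pwm_manifest) {
  snps <- cfg$planted_snps
  wt <- character(nrow(snps))
  mu <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    m <- pwm_manifest[!is.na(pwm_manifest$snp_id) &
      pwm_manifest$snp_id == snps$snp_id[i], ]
    if (nrow(m) == 1) {
      wt[i] <- m$wt_allele
      mu[i] <- m$mu_allele
    } else {
      base <- toupper(substr(genome[[snps$chrom[i]]], snps$pos[i] + 1L, snps$pos[i] + 1L))
      wt[i] <- base
      mu[i] <- chartr("ACGT", "TGCA", base)
    }
  }
  mutate(snps, ref_allele = wt, alt_allele = mu)
}

#' Generate per-class SNP read counts and genotype-state counts
#'
#' Pooled allele occurrence counts per class follow the planted class
#' allele frequencies; diploid genotype states are drawn per sample under
#' Hardy-Weinberg at the class frequency. Monomorphic positions with fewer
#' than 10 overlapping reads (non-assayed) and with 25 reads (non-mutated)
#' are included to exercise the assay-status rules.
#'
#' @param config A [synthetic_config()].
#' @param truth_snps Planted SNPs with `ref_allele`/`alt_allele` (from the
#'   full simulation; defaults to genome-free alleles when omitted).
#' @return List with `allele_counts`, `genotype_counts`, `truth_snps`.
#' @export
generate_snp_reads <- function(config, truth_snps = NULL) {
  cfg <- config
  snps <- truth_snps %||% mutate(cfg$planted_snps, ref_allele = "A", alt_allele = "T")
  ac <- vector("list", nrow(snps))
  gc <- vector("list", nrow(snps))
  with_seed(derive_seed(cfg$seed, 105L), {
    for (i in seq_len(nrow(snps))) {
      s <- snps[i, ]
      if (s$kind == "mono_low") {
        reads <- c(case = 5L, control = 3L)  # 8 total: below the 10-read rule
      } else if (s$kind == "mono_high") {
        reads <- c(case = 17L, control = 8L)  # 25 total
      } else {
        reads <- c(
          case = max(1L, rpois(1, cfg$snp_depth_per_sample * cfg$n_case_samples)),
          control = max(1L, rpois(1, cfg$snp_depth_per_sample * cfg$n_control_samples))
        )
      }
      freqs <- c(case = s$case_alt_freq, control = s$control_alt_freq)
      ac[[i]] <- bind_rows(lapply(c("case", "control"), function(cl) {
        alt_n <- rbinom(1, reads[[cl]], freqs[[cl]])
        tibble(
          snp_id = s$snp_id, class = cl,
          allele = c(s$ref_allele, s$alt_allele),
          count = c(reads[[cl]] - alt_n, alt_n)
        )
      }))
      n_smp <- c(case = cfg$n_case_samples, control = cfg$n_control_samples)
      gc[[i]] <- bind_rows(lapply(c("case", "control"), function(cl) {
        alt_copies <- rbinom(n_smp[[cl]], 2, freqs[[cl]])
        tibble(
          snp_id = s$snp_id, class = cl,
          genotype = c("hom_ref", "het", "hom_alt"),
          count = c(sum(alt_copies == 0), sum(alt_copies == 1), sum(alt_copies == 2))
        )
      }))
    }
  })
  list(
    allele_counts = bind_rows(ac),
    genotype_counts = bind_rows(gc),
    truth_snps = snps
  )
}

#' Generate the phased haplotype panel
#'
#' Columns hold planted SNPs and their LD tag SNPs; each tagged pair is
#' constructed so the empirical r-squared approaches its `ld_r2_target`
#' (equal allele frequencies, correlation-mixture copying). Untagged SNPs are
#' independent draws. Allele coding: 0 = ref/WT, 1 = alt/MU.
#'
#' @param config A [synthetic_config()].
#' @param truth_snps Planted SNP table with alleles.
#' @return Panel: list with `haplotypes` (0/1 matrix, one row per
#'   chromosome), `snps` tibble (`snp_id`, `chrom`, `pos`, `ref`, `alt`),
#'   and `ld_pairs` manifest. Warns when a target r-squared is unattainable.
#' @export
generate_haplotype_panel <- function(config, truth_snps = NULL) {
  cfg <- config
  snps <- truth_snps %||% mutate(cfg$planted_snps, ref_allele = "A", alt_allele = "T")
  snps <- filter(snps, !.data$kind %in% c("mono_low", "mono_high"))
  n <- cfg$n_haplotypes
  cols <- list()
  info <- list()
  pairs <- list()
  with_seed(derive_seed(cfg$seed, 106L), {
    # independent background panel SNPs scattered over the genome: the
    # density denominator and the irrelevant-trait universe
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    n_bg <- 60L
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    bg_pos <- as.integer(runif(n_bg, 1000, cfg$chrom_length_bp - 1000))
    for (b in seq_len(n_bg)) {
      id <- sprintf("bg%03d", b)
      cols[[id]] <- rbinom(n, 1, 0.3)
      info[[length(info) + 1L]] <- tibble(
        snp_id = id, chrom = bg_chrom[b], pos = bg_pos[b], ref = "A", alt = "G"
      )
    }
    for (i in seq_len(nrow(snps))) {
      s <- snps[i, ]
      # panel frequency: pooled across classes (reference-panel analogue)
      p <- min(max((s$case_alt_freq + s$control_alt_freq) / 2, 0.05), 0.95)
      x <- rbinom(n, 1, p)
      cols[[s$snp_id]] <- x
      info[[length(info) + 1L]] <- tibble(
        snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
        ref = s$ref_allele, alt = s$alt_allele
      )
      if (!is.na(s$ld_tag_id)) {
        r <- sqrt(s$ld_r2_target)
        y <- ifelse(
          x == 1,
          rbinom(n, 1, p + r * (1 - p)),
          rbinom(n, 1, p * (1 - r))
        )
        cols[[s$ld_tag_id]] <- y
        # tag risk allele: the alt (coded-1) allele travels with the MU allele
        info[[length(info) + 1L]] <- tibble(
          snp_id = s$ld_tag_id, chrom = s$chrom, pos = s$ld_tag_pos,
          ref = "C", alt = "G"
        )
        emp <- suppressWarnings(stats::cor(x, y)^2)
        if (is.na(emp) || abs(emp - s$ld_r2_target) > 0.1) {
          warn(sprintf(
            "pair %s-%s: empirical r2 %.3f misses target %.2f (best effort)",
            s$snp_id, s$ld_tag_id, emp, s$ld_r2_target
          ))
        }
        pairs[[length(pairs) + 1L]] <- tibble(
          snp_id = s$snp_id, tag_id = s$ld_tag_id,
          target_r2 = s$ld_r2_target, empirical_r2 = emp,
          distance = abs(s$ld_tag_pos - s$pos)
        )
      }
    }
  })
  H <- do.call(cbind, cols)
  rownames(H) <- sprintf("h%04d", seq_len(n))
  list(
    haplotypes = H,
    snps = bind_rows(info),
    ld_pairs = if (length(pairs)) bind_rows(pairs) else tibble(
      snp_id = character(), tag_id = character(), target_r2 = double(),
      empirical_r2 = double(), distance = integer()
    )
  )
}

#' Generate a GWAS catalog fixture
#'
#' Trait strings cover the agglomeration categories (CLL, lymphoma, cancer,
#' irrelevant); tag SNPs are panel columns, risk alleles are their alt
#' alleles. One trait carries fewer than five SNPs (the small-trait case).
#'
#' @param config A [synthetic_config()].
#' @param panel Haplotype panel (for tag SNP ids/positions).
#' @return Catalog tibble `snp_id`, `chrom`, `pos`, `trait`, `risk_allele`.
#' @export
generate_gwas_catalog <- function(config, panel) {
  tag_ids <- grep("^tag_", colnames(panel$haplotypes), value = TRUE)
  tags <- panel$snps[panel$snps$snp_id %in% tag_ids, ]
  trait_names <- c(
    "Chronic lymphocytic leukemia",
    "Hodgkin's lymphoma",
    "Breast cancer",
    "Height", "Body mass index", "Type 2 diabetes",
    "Crohn's disease", "Asthma"
  )[seq_len(min(config$n_traits, 8))]
  if (nrow(tags) == 0) {
    return(tibble(
      snp_id = character(), chrom = character(), pos = integer(),
      trait = character(), risk_allele = character()
    ))
  }
  # lost-region tags -> the CLL trait, gained-region tags -> lymphoma
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    trait <- if (grepl("^tag_L", tags$snp_id[i])) {
      trait_names[1]
    } else {
      trait_names[min(2, length(trait_names))]
    }
    rows[[i]] <- tibble(
      snp_id = tags$snp_id[i], chrom = tags$chrom[i], pos = tags$pos[i],
      trait = trait, risk_allele = tags$alt[i]
    )
  }
  extra <- panel$snps[grepl("^bg", panel$snps$snp_id), ]
  irrelevant <- trait_names[trait_names %in% c("Height", "Body mass index", "Type 2 diabetes", "Asthma")]
  # a small trait (three SNPs), a broad-cancer trait, and the irrelevant
  # baseline traits
  small_trait <- if (length(trait_names) >= 7) trait_names[7] else "Crohn's disease"
  cancer_trait <- if (length(trait_names) >= 3) trait_names[3] else "Breast cancer"
  for (i in seq_len(nrow(extra))) {
    trait <- if (i <= 3) {
      small_trait
    } else if (i <= 6) {
      cancer_trait
    } else {
      irrelevant[(i - 7L) %% max(1L, length(irrelevant)) + 1L]
    }
    rows[[length(rows) + 1L]] <- tibble(
      snp_id = extra$snp_id[i], chrom = extra$chrom[i], pos = extra$pos[i],
      trait = trait, risk_allele = extra$alt[i]
    )
  }
  bind_rows(rows)
}

#' Generate the per-gene expression table
#'
#' Genes whose TSS lies near a planted gained region get elevated cancer
#' class expression; near lost regions, depressed; other genes draw fold
#' changes around one. A handful of genes fall below the low-expression
#' filter in both classes.
#'
#' @param config A [synthetic_config()].
#' @param genes Gene annotation tibble.
#' @return Tibble `gene_id`, `mean_case`, `mean_control`, `truth` label.
#' @export
generate_expression_table <- function(config, genes) {
  cfg <- config
  if (nrow(genes) == 0) {
    return(tibble(
      gene_id = character(), mean_case = double(), mean_control = double(),
      truth = character()
    ))
  }
  reg <- cfg$planted_regions
  # label each gene by its nearest planted region (within 5 kb of the TSS):
  # genes beside gained regions go up in the cancer class, beside lost ones
  # down; everything else is neutral
  truth <- vapply(seq_len(nrow(genes)), function(i) {
    on_chrom <- reg[reg$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(on_chrom) == 0) return("neutral")
    tss <- genes$tss[i]
    d <- pmax(0L, pmax(on_chrom$start - tss, tss - on_chrom$end + 1L))
    j <- which.min(d)
    if (d[j] > 5000L) return("neutral")
    switch(on_chrom$truth_class[j],
      gained = "up", lost = "down", shared = "shared_host", "neutral"
    )
  }, character(1))
  # some genes hosting shared elements are also differentially expressed
  # (regulation changes for reasons other than local element gain/loss), so
  # the shared-element baseline fraction is non-degenerate
  shared_host <- which(truth == "shared_host")
  u <- with_seed(derive_seed(cfg$seed, 108L), runif(length(shared_host)))
  truth[shared_host] <- "neutral"
  truth[shared_host[u < 0.15]] <- "up"
  truth[shared_host[u >= 0.15 & u < 0.3]] <- "down"
  near_gained <- which(truth == "up")
  near_lost <- which(truth == "down")
  with_seed(derive_seed(cfg$seed, 107L), {
    base <- exp(rnorm(nrow(genes), log(5), 0.8))
    fc <- exp(rnorm(nrow(genes), 0, 0.15))
    fc[near_gained] <- exp(rnorm(length(near_gained), log(3), 0.2))
    fc[near_lost] <- exp(rnorm(length(near_lost), log(1 / 3), 0.2))
  })
  low_idx <- utils::head(order(base), 5)  # 5 weakest genes fall below filter
  mean_control <- base
  mean_case <- base * fc
  mean_control[low_idx] <- 0.05
  mean_case[low_idx] <- 0.05
  truth[low_idx] <- "low_expressed"
  tibble(
    gene_id = genes$gene_id,
    mean_case = mean_case, mean_control = mean_control, truth = truth
  )
}

#' Simulate the full synthetic dataset
#'
#' Orchestrates every generator under one master seed: genome and annotation,
#' PWM planting (which edits the genome and fixes the WT/MU alleles of the
#' associated SNPs), methylation samples, SNP read counts, haplotype panel,
#' GWAS catalog and expression table, each with its ground-truth manifest.
#'
#' @param config A [synthetic_config()] (or a seed to build one).
#' @return Named list with all fixture components.
#' @export
simulate_dre_dataset <- function(config = synthetic_config()) {
  if (is.numeric(config)) config <- synthetic_config(seed = config)
  fixture <- generate_genome_fixture(config)
  pw <- generate_pwm_set(config, fixture)
  fixture$genome <- pw$genome
  truth_snps <- planted_snp_alleles(config, pw$genome, pw$manifest)
  meth <- generate_methylation_samples(config)
  reads <- generate_snp_reads(config, truth_snps)
  panel <- generate_haplotype_panel(config, truth_snps)
  catalog <- generate_gwas_catalog(config, panel)
  expression <- generate_expression_table(config, fixture$genes)
  list(
    config = config,
    genome = fixture$genome,
    genes = fixture$genes,
    exons = fixture$exons,
    repeat_track = fixture$repeat_track,
    cgi_track = fixture$cgi_track,
    chrom_sizes = fixture$chrom_sizes,
    pwms = pw$pwms,
    pwm_manifest = pw$manifest,
    profiles = meth$profiles,
    totals = meth$totals,
    truth_regions = meth$truth_regions,
    truth_sites = meth$truth_sites,
    allele_counts = reads$allele_counts,
    genotype_counts = reads$genotype_counts,
    truth_snps = truth_snps,
    panel = panel,
    catalog = catalog,
    expression = expression
  )
}
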