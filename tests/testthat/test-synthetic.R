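small_cfg <- function(seed = 3, ...) {
  args <- list(
    seed = seed, n_cpg = 300, n_genes = 30, n_haplotypes = 400,
    n_case_samples = 4, n_control_samples = 3
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

test_that("configuration validation rejects degenerate settings", {
  expect_error(synthetic_config(mean_coverage = 0), "positive")
  expect_error(synthetic_config(n_case_samples = 0), "integer")
  expect_error(synthetic_config(meth_low = 0.7), "meth_low < 0.5")
  # planted regions beyond the chromosome end are a configuration error
  bad <- tibble::tibble(
    chrom = "chr1", start = 999000L, end = 1002000L,
    truth_class = "gained", n_cpg = 10L
  )
  expect_error(synthetic_config(planted_regions = bad), "overflow")
  over <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 1100L), end = c(1300L, 1400L),
    truth_class = c("gained", "lost"), n_cpg = c(10L, 10L)
  )
  expect_error(synthetic_config(planted_regions = over), "overlap")
})

test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_dre_dataset(small_cfg(5))
  b <- simulate_dre_dataset(small_cfg(5))
  expect_identical(a$genome, b$genome)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$allele_counts, b$allele_counts)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$expression, b$expression)
  c <- simulate_dre_dataset(small_cfg(6))
  expect_false(identical(a$profiles, c$profiles))
})

test_that("the genome fixture respects bounds and the empty-gene case", {
  fx <- generate_genome_fixture(small_cfg(4, n_genes = 10))
  expect_equal(nrow(fx$genes), 10L)
  expect_true(all(fx$genes$tss >= 0 & fx$genes$tss < 1e6))
  expect_true(all(nchar(fx$genome) == 1e6))
  # tracks are merged (disjoint) and in bounds
  for (track in list(fx$repeat_track, fx$cgi_track)) {
    expect_true(all(track$start >= 0 & track$end <= 1e6))
    by_chrom <- split(track, track$chrom)
    for (p in by_chrom) {
      expect_true(all(diff(p$start) > 0))
      expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
    }
  }
  fx0 <- generate_genome_fixture(small_cfg(4, n_genes = 0))
  expect_equal(nrow(fx0$genes), 0L)
  expect_equal(nrow(fx0$exons), 0L)
})

test_that("planted methylation levels shape the sampled counts", {
  cfg <- small_cfg(8)
  meth <- generate_methylation_samples(cfg)
  sites <- meth$truth_sites
  prof <- meth$profiles
  # background CpGs concentrate near meth_high in both classes
  bg_pos <- sites$pos[sites$truth_class == "background"][1:1000]
  bg <- prof[prof$pos %in% bg_pos & prof$chrom == "chr1", ]
  frac <- sum(bg$meth_reads) / sum(bg$total_reads)
  expect_gte(frac, 0.88)
  expect_lte(frac, 0.92)
  # a shared region is hypomethylated in both classes
  shared <- cfg$planted_regions[cfg$planted_regions$truth_class == "shared", ][1, ]
  sh <- prof[prof$chrom == shared$chrom & prof$pos >= shared$start &
    prof$pos < shared$end, ]
  for (cl in c("case", "control")) {
    f <- sum(sh$meth_reads[sh$class == cl]) / sum(sh$total_reads[sh$class == cl])
    expect_lt(abs(f - cfg$meth_low), 0.05)
  }
  # gained regions separate the classes
  gained <- cfg$planted_regions[cfg$planted_regions$truth_class == "gained", ][1, ]
  g <- prof[prof$chrom == gained$chrom & prof$pos >= gained$start &
    prof$pos < gained$end, ]
  f_case <- sum(g$meth_reads[g$class == "case"]) / sum(g$total_reads[g$class == "case"])
  f_ctrl <- sum(g$meth_reads[g$class == "control"]) / sum(g$total_reads[g$class == "control"])
  expect_lt(f_case, 0.2)
  expect_gt(f_ctrl, 0.8)
  expect_true(all(prof$total_reads >= 1))
})

test_that("haplotype panel honours the target r-squared and independence", {
  cfg <- small_cfg(9, n_haplotypes = 2000)
  ds <- simulate_dre_dataset(cfg)
  pairs <- ds$panel$ld_pairs
  expect_gt(nrow(pairs), 0)
  expect_true(all(abs(pairs$empirical_r2 - pairs$target_r2) <= 0.1))
  # background SNPs are mutually independent
  H <- ds$panel$haplotypes
  bg <- grep("^bg", colnames(H), value = TRUE)[1:10]
  for (i in 2:10) {
    r2 <- suppressWarnings(compute_r2(ds$panel, bg[1], bg[i]))
    expect_lt(r2, 0.05)
  }
})

test_that("a perfect-LD pair gives identical haplotype columns", {
  snps <- tibble::tibble(
    snp_id = "s1", chrom = "chr1", pos = 1000L,
    region_id = NA_character_, region_start = NA_integer_,
    region_end = NA_integer_, kind = "assoc_lost",
    case_alt_freq = 0.5, control_alt_freq = 0.5,
    ld_tag_id = "t1", ld_r2_target = 1.0, ld_tag_pos = 5000L,
    ref_allele = "A", alt_allele = "G"
  )
  pan <- generate_haplotype_panel(small_cfg(10), snps)
  expect_equal(pan$haplotypes[, "s1"], pan$haplotypes[, "t1"])
})

test_that("the panel round-trips losslessly through the VCF dialect", {
  ds <- simulate_dre_dataset(small_cfg(11))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_hap_panel(ds$panel, path)
  back <- read_hap_panel(path)
  expect_equal(
    unname(back$haplotypes[, colnames(ds$panel$haplotypes)]),
    unname(ds$panel$haplotypes)
  )
  expect_equal(
    dplyr::arrange(back$snps, snp_id),
    dplyr::arrange(ds$panel$snps, snp_id)
  )
})

test_that("catalog traits cover the agglomeration categories", {
  ds <- default_dataset()
  cats <- agglomerate_traits(ds$catalog)
  expect_setequal(
    unique(cats$category),
    c("CLL", "lymphoma", "cancer", "irrelevant")
  )
  # the small-trait case: a trait with fewer than five SNPs exists
  sizes <- table(ds$catalog$trait)
  expect_true(any(sizes < 5))
  # empty catalog passes through downstream enrichment without failure
  empty <- ds$catalog[0, ]
  expanded <- expand_ld(empty, ds$panel)
  expect_equal(nrow(expanded), 0L)
  test0 <- permutation_enrichment(
    run_cached_pipeline()$classmap, ds$panel$snps, character(),
    n_perm = 10, seed = 1
  )
  expect_equal(test0$observed, 0L)
})

test_that("PWM set is normalised and its planted sites are live", {
  ds <- default_dataset()
  for (p in ds$pwms) {
    expect_true(all(abs(colSums(p$prob) - 1) < 1e-9))
    expect_gte(p$width, 6)
    expect_lte(p$width, 15)
  }
  man <- ds$pwm_manifest
  cons <- man[man$kind == "consensus_site", ]
  for (i in seq_len(min(nrow(cons), 5))) {
    p <- ds$pwms[[match(cons$motif_id[i], vapply(ds$pwms, function(x) x$motif_id, ""))]]
    seq <- dremap:::extract_seq(
      ds$genome, cons$chrom[i], cons$pos[i], cons$pos[i] + p$width
    )
    expect_equal(seq, p$consensus)
    hits <- scan_sequence(p, seq)
    expect_true(any(hits$offset == 0 & hits$strand == "+"))
  }
  # destroy-SNPs: WT sequence hits, MU does not
  destroy <- man[man$kind == "destroy_snp", ][1, ]
  p <- ds$pwms[[match(destroy$motif_id, vapply(ds$pwms, function(x) x$motif_id, ""))]]
  w0 <- destroy$pos - p$width + 1L
  wt_seq <- dremap:::extract_seq(ds$genome, destroy$chrom, w0, destroy$pos + p$width)
  center <- destroy$pos - w0
  mu_seq <- wt_seq
  substr(mu_seq, center + 1L, center + 1L) <- destroy$mu_allele
  expect_gt(nrow(scan_sequence(p, wt_seq)), 0)
  expect_equal(nrow(scan_sequence(p, mu_seq)), 0L)
})

test_that("expression table exercises the filter and planted fold changes", {
  ds <- default_dataset()
  ex <- ds$expression
  expect_true(any(ex$mean_case < 0.1 & ex$mean_control < 0.1))
  fc <- compute_fold_change(ex)
  expect_true(all(fc$excluded[ex$truth == "low_expressed"]))
  up <- ex$truth == "up"
  expect_gt(median(ex$mean_case[up] / ex$mean_control[up]), 1)
  down <- ex$truth == "down"
  expect_lt(median(ex$mean_case[down] / ex$mean_control[down]), 1)
})

test_that("equal class means give fold change one", {
  expr <- tibble::tibble(gene_id = "g", mean_case = 2.5, mean_control = 2.5)
  expect_equal(compute_fold_change(expr)$fold_change, 1)
})
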