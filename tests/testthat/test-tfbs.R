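test_that("PWM construction validates its inputs", {
  expect_error(new_pwm("x", matrix(0.3, 4, 8)), "sum to 1")
  expect_error(new_pwm("x", matrix(0.25, 4, 3)), "width")
  expect_error(new_pwm("x", matrix(0.25, 3, 8)), "4 rows")
  p <- sharp_pwm("ACGTACGT")
  expect_equal(p$consensus, "ACGTACGT")
  expect_true(all(abs(colSums(p$prob) - 1) < 1e-9))
})

test_that("a planted consensus site is hit at the planted offset", {
  withr::local_seed(91)
  p <- sharp_pwm("ACGTTCCA")
  seq <- paste0(random_dna(40), "ACGTTCCA", random_dna(40))
  hits <- scan_sequence(p, seq)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))
})

test_that("sequences shorter than the motif give no hits", {
  p <- sharp_pwm("ACGTTCCA")
  expect_equal(nrow(scan_sequence(p, "ACGT")), 0L)
})

test_that("windows containing N are skipped", {
  p <- sharp_pwm("ACGTTCCA")
  seq <- paste0("ACGTNCCA", "ACGTTCCA")
  hits <- scan_sequence(p, seq)
  expect_true(all(hits$offset == 8))
})

test_that("hit sets equal exhaustive all-window rescoring", {
  withr::local_seed(92)
  pwms <- list(sharp_pwm("ACGTTCCA", "a"), sharp_pwm("GGATCCGAT", "b"))
  for (rep in 1:5) {
    seq <- paste0(
      random_dna(300), "ACGTTCCA", random_dna(200), "GGATCCGAT",
      random_dna(300)
    )
    for (p in pwms) {
      got <- scan_sequence(p, seq)
      want <- oracle_scan(p, seq)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reverse-complementing the sequence mirrors the hit set", {
  withr::local_seed(93)
  p <- sharp_pwm("ACGTTCCA")
  seq <- paste0(random_dna(100), "ACGTTCCA", random_dna(100), "TGGAACGT")
  rc <- dremap:::revcomp(seq)
  fwd <- scan_sequence(p, seq)
  rev_ <- scan_sequence(p, rc)
  L <- nchar(seq)
  w <- p$width
  mirrored <- tibble::tibble(
    offset = L - w - rev_$offset,
    strand = ifelse(rev_$strand == "+", "-", "+")
  )
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(fwd$offset, mirrored$offset)
  expect_equal(fwd$strand, mirrored$strand)
})

test_that("matched controls respect length and tolerance constraints", {
  withr::local_seed(94)
  genome <- list(chr1 = random_dna(30000), chr2 = random_dna(30000))
  track <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 9000L), end = c(3000L, 12000L)
  )
  region <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2600L)
  ctl <- sample_matched_controls(region, genome, track,
    n = 8, gc_tol = 0.06, repeat_tol = 0.3, seed = 4
  )
  expect_equal(nrow(ctl), 8L)
  expect_true(all(ctl$end - ctl$start == 600L))
  target_gc <- dremap:::gc_content(dremap:::extract_seq(genome, "chr1", 2000, 2600))
  # post-hoc verification of both constraints on recomputation
  for (i in seq_len(nrow(ctl))) {
    sq <- dremap:::extract_seq(genome, ctl$chrom[i], ctl$start[i], ctl$end[i])
    expect_lte(abs(dremap:::gc_content(sq) - target_gc), 0.06)
    expect_equal(sq, ctl$seq[i])
  }
  # saturated tolerances accept anything; a starved budget warns
  expect_silent(
    sample_matched_controls(region, genome, track,
      n = 3, gc_tol = 1, repeat_tol = 1, seed = 4
    )
  )
  expect_warning(
    few <- sample_matched_controls(region, genome, track,
      n = 5, gc_tol = 0.0001, repeat_tol = 0.0001, seed = 4, max_attempts = 50
    ),
    "budget"
  )
  expect_lt(nrow(few), 5L)
})

test_that("identical sequence sets give unit density ratios", {
  withr::local_seed(95)
  pwms <- list(sharp_pwm("ACGTTCCA", "a"), sharp_pwm("GGATCCGAT", "b"))
  seqs <- c(
    paste0(random_dna(100), "ACGTTCCA", random_dna(100)),
    random_dna(300)
  )
  enr <- tfbs_enrichment(seqs, seqs, pwms)
  expect_equal(enr$enrichment[enr$motif_id == "a"], 1)
  # motif absent from controls but present in regions: infinite sentinel
  enr2 <- tfbs_enrichment(seqs, c(random_dna(300), random_dna(300)), pwms)
  expect_equal(enr2$enrichment[enr2$motif_id == "a"], Inf)
  expect_true(is.nan(enr2$enrichment[enr2$motif_id == "b"]))
})

test_that("background positions carry the WT base and respect exhaustion", {
  genome <- list(chr1 = paste0(
    strrep("C", 50), "A", strrep("C", 20), "A", strrep("C", 20), "A",
    strrep("C", 50)
  ))
  # three A positions at 50, 71, 92; the SNP sits at 71
  pos <- sample_background_positions(genome, "chr1", 0L, 143L, 71L, "A",
    N = 30, seed = 1
  )
  expect_setequal(pos, c(50L, 92L))
  expect_false(71L %in% pos)
  expect_warning(
    none <- sample_background_positions(genome, "chr1", 0L, 49L, 10L, "G",
      N = 5, seed = 1
    ),
    "no background"
  )
  expect_length(none, 0)
  # subsampling is seeded and capped at N
  big <- sample_background_positions(genome, "chr1", 0L, 143L, 200L, "C",
    N = 10, seed = 3
  )
  expect_length(big, 10)
  expect_equal(
    big,
    sample_background_positions(genome, "chr1", 0L, 143L, 200L, "C",
      N = 10, seed = 3
    )
  )
})

test_that("an MU allele equal to WT changes no motif", {
  withr::local_seed(96)
  genome <- list(chr1 = random_dna(5000))
  pwms <- list(sharp_pwm("ACGTTCCA", "a"), sharp_pwm("GGATCCGAT", "b"))
  snps <- tibble::tibble(
    snp_id = paste0("s", 1:5), chrom = "chr1",
    pos = c(500L, 1500L, 2500L, 3500L, 4500L),
    wt_allele = "A", mu_allele = "A",
    region_start = c(400L, 1400L, 2400L, 3400L, 4400L),
    region_end = c(700L, 1700L, 2700L, 3700L, 4700L)
  )
  st <- motif_change_stats(snps, pwms, genome, seed = 2)
  expect_true(all(st$n_wt_not_mu == 0))
  expect_true(all(st$n_mu_not_wt == 0))
})

test_that("planted destroy-SNPs lose the motif completely", {
  p <- sharp_pwm("ACGTTCCA", "a")
  genome <- list(chr1 = paste0(
    strrep("C", 100), "ACGTTCCA", strrep("C", 100)
  ))
  snps <- tibble::tibble(
    snp_id = "s1", chrom = "chr1", pos = 104L,  # the second T of the site
    wt_allele = "T", mu_allele = "G",
    region_start = 50L, region_end = 160L
  )
  st <- motif_change_stats(snps, list(p), genome, direction = "lost", seed = 5)
  expect_equal(st$n_wt, 1L)
  expect_equal(st$fract_lost, 1)
  expect_equal(st$fraction, 1)
})

test_that("change counts equal a brute-force WT/MU rescan diff", {
  withr::local_seed(97)
  pwms <- lapply(1:5, function(i) {
    sharp_pwm(random_dna(sample(8:9, 1)), paste0("m", i))
  })
  genome <- list(chr1 = random_dna(20000))
  # seed motif sites near some SNP positions so counts are non-trivial
  pos <- sort(sample(seq(200L, 19000L, by = 900L), 20))
  for (i in seq_along(pos)) {
    if (i %% 2 == 0) {
      p <- pwms[[(i %% 5) + 1]]
      genome$chr1 <- dremap:::inject_seq(
        genome$chr1, pos[i] - p$width %/% 2L, p$consensus
      )
    }
  }
  base_of <- function(pp) substr(genome$chr1, pp + 1L, pp + 1L)
  snps <- tibble::tibble(
    snp_id = paste0("s", seq_along(pos)), chrom = "chr1", pos = pos,
    wt_allele = vapply(pos, base_of, character(1)),
    mu_allele = sample(c("A", "C", "G", "T"), 20, replace = TRUE),
    region_start = pos - 150L, region_end = pos + 150L
  )
  got <- motif_change_stats(snps, pwms, genome, seed = 6)

  # oracle: scan the full WT and MU neighbourhoods and diff the hit sets
  maxw <- max(vapply(pwms, function(p) p$width, integer(1)))
  want <- lapply(pwms, function(p) c(n_wt = 0, n_wt_not_mu = 0, n_mu = 0, n_mu_not_wt = 0))
  names(want) <- vapply(pwms, function(p) p$motif_id, character(1))
  for (i in seq_along(pos)) {
    w0 <- pos[i] - (maxw - 1L)
    wt_seq <- dremap:::extract_seq(genome, "chr1", w0, pos[i] + maxw)
    substr(wt_seq, maxw, maxw) <- snps$wt_allele[i]
    mu_seq <- wt_seq
    substr(mu_seq, maxw, maxw) <- snps$mu_allele[i]
    for (p in pwms) {
      key <- function(h) paste(h$offset, h$strand)
      cover <- function(h) h[h$offset <= maxw - 1 & h$offset + p$width > maxw - 1, ]
      hw <- key(cover(oracle_scan(p, wt_seq)))
      hm <- key(cover(oracle_scan(p, mu_seq)))
      want[[p$motif_id]] <- want[[p$motif_id]] + c(
        length(hw), length(setdiff(hw, hm)),
        length(hm), length(setdiff(hm, hw))
      )
    }
  }
  for (p in pwms) {
    row <- got[got$motif_id == p$motif_id, ]
    expect_equal(row$n_wt, unname(want[[p$motif_id]][1]))
    expect_equal(row$n_wt_not_mu, unname(want[[p$motif_id]][2]))
    expect_equal(row$n_mu, unname(want[[p$motif_id]][3]))
    expect_equal(row$n_mu_not_wt, unname(want[[p$motif_id]][4]))
  }
})

test_that("loss under one labelling equals gain under the swapped labelling", {
  withr::local_seed(98)
  genome <- list(chr1 = random_dna(10000))
  p <- sharp_pwm("ACGTTCCA", "a")
  genome$chr1 <- dremap:::inject_seq(genome$chr1, 496L, p$consensus)
  snps <- tibble::tibble(
    snp_id = "s", chrom = "chr1", pos = 500L,
    wt_allele = substr(genome$chr1, 501L, 501L),
    mu_allele = "G",
    region_start = 400L, region_end = 700L
  )
  swapped <- dplyr::mutate(snps,
    wt_allele = .data$mu_allele, mu_allele = snps$wt_allele
  )
  a <- motif_change_stats(snps, list(p), genome, seed = 9)
  b <- motif_change_stats(swapped, list(p), genome, seed = 9)
  expect_equal(a$n_wt_not_mu, b$n_mu_not_wt)
  expect_equal(a$n_mu_not_wt, b$n_wt_not_mu)
})
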