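mk_regions <- function(starts, ends, chrom = "chr1", n_cpg = 5, meth = 0.2) {
  tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    n_cpg = as.integer(n_cpg), mean_meth = meth,
    state = "hypo"
  )
}
empty_reg <- mk_regions(integer(), integer())

test_that("identical case and control maps yield only shared regions", {
  m <- mk_regions(c(100, 1000), c(300, 1400))
  cm <- classify_regions(m, m, empty_reg, empty_reg)
  expect_equal(sort(unique(cm$class)), "shared")
  expect_equal(nrow(cm), 2L)
  expect_equal(cm$start, m$start)
  expect_equal(cm$end, m$end)
})

test_that("disjoint maps classify as gained and lost", {
  ca <- mk_regions(c(100, 1000), c(300, 1200))
  co <- mk_regions(c(5000, 9000), c(5300, 9100))
  cm <- classify_regions(ca, co, empty_reg, empty_reg)
  expect_equal(sum(cm$class == "gained"), 2L)
  expect_equal(sum(cm$class == "lost"), 2L)
  expect_equal(sum(cm$class == "shared"), 0L)
})

test_that("shared regions take union coordinates and merge chains", {
  ca <- mk_regions(c(100, 400), c(250, 600))
  co <- mk_regions(200, 450)  # overlaps both case regions: one chain
  cm <- classify_regions(ca, co, empty_reg, empty_reg)
  shared <- cm[cm$class == "shared", ]
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$start, 100L)
  expect_equal(shared$end, 600L)
  expect_equal(nrow(cm[cm$class == "gained", ]), 0L)
})

test_that("classification is antisymmetric under case/control swap", {
  withr::local_seed(31)
  ca <- mk_regions(sort(sample.int(50000, 20)) * 10, integer(20))
  ca$end <- ca$start + sample(50:400, 20, replace = TRUE)
  co <- mk_regions(sort(sample.int(50000, 15)) * 10, integer(15))
  co$end <- co$start + sample(50:400, 15, replace = TRUE)
  a <- classify_regions(ca, co, empty_reg, empty_reg)
  b <- classify_regions(co, ca, empty_reg, empty_reg)
  pick <- function(x, cl) x[x$class == cl, c("chrom", "start", "end")]
  expect_equal(pick(a, "gained"), pick(b, "lost"))
  expect_equal(pick(a, "lost"), pick(b, "gained"))
  expect_equal(pick(a, "shared"), pick(b, "shared"))
})

test_that("no region is dropped silently (provenance conservation)", {
  withr::local_seed(32)
  ca <- mk_regions(sort(sample.int(30000, 12)) * 10, integer(12))
  ca$end <- ca$start + 200L
  co <- mk_regions(sort(sample.int(30000, 9)) * 10, integer(9))
  co$end <- co$start + 200L
  cm <- classify_regions(ca, co, empty_reg, empty_reg)
  n_shared_members <- sum(as.integer(
    sub("case\\+control\\((\\d+)\\)", "\\1", cm$provenance[cm$class == "shared"])
  ))
  expect_equal(
    sum(cm$class == "gained") + sum(cm$class == "lost") + n_shared_members,
    nrow(ca) + nrow(co)
  )
})

test_that("hiMRs are hyper-map intersections with CpG recheck", {
  ca_hyp <- tibble::tibble(
    chrom = "chr1", start = 100L, end = 1000L, n_cpg = 10L,
    mean_meth = 0.9, state = "hyper"
  )
  co_hyp <- tibble::tibble(
    chrom = "chr1", start = 500L, end = 1500L, n_cpg = 10L,
    mean_meth = 0.95, state = "hyper"
  )
  cm <- classify_regions(empty_reg, empty_reg, ca_hyp, co_hyp)
  him <- cm[cm$class == "himr", ]
  expect_equal(him$start, 500L)
  expect_equal(him$end, 1000L)

  # with profiles supplied, intersections with too few assayed CpGs drop out
  prof <- tibble::tibble(chrom = "chr1", pos = c(510L, 600L), meth = 0.9)
  cm2 <- classify_regions(empty_reg, empty_reg, ca_hyp, co_hyp,
    case_profile = prof, control_profile = prof, n_cpg_cutoff = 3
  )
  expect_equal(sum(cm2$class == "himr"), 0L)
})

test_that("genomic categories follow the promoter > exonic > intronic precedence", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 20000L,
    strand = "+", tss = 10000L
  )
  exons <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10200L)
  cat_of <- function(start, end) {
    annotate_genomic_category(
      tibble::tibble(chrom = "chr1", start = start, end = end),
      genes, exons
    )$genomic_category
  }
  expect_equal(cat_of(9900L, 10050L), "promoter")   # contains the TSS
  expect_equal(cat_of(10050L, 10150L), "promoter")  # exon inside promoter window
  expect_equal(cat_of(11000L, 11500L), "intronic")  # gene body, no exon
  expect_equal(cat_of(120000L, 121000L), "intergenic")
  # downstream-but-within-window stays promoter; outside it, exonic wins
  expect_equal(cat_of(10600L, 10700L), "intronic")
  genes_minus <- dplyr::mutate(genes, strand = "-", tss = end - 1L)
  got <- annotate_genomic_category(
    tibble::tibble(chrom = "chr1", start = 20500L, end = 20600L),
    genes_minus, exons
  )$genomic_category
  expect_equal(got, "promoter")  # upstream of a minus-strand TSS
})

test_that("regions beyond chromosome bounds are rejected", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 0L, end = 100L,
    strand = "+", tss = 0L
  )
  expect_error(
    annotate_genomic_category(
      tibble::tibble(chrom = "chr1", start = 900L, end = 1200L),
      genes,
      chrom_sizes = c(chr1 = 1000L)
    ),
    "bounds"
  )
})

test_that("repeat fraction matches the per-base painting oracle", {
  expect_equal(
    repeat_fraction(
      tibble::tibble(chrom = "chr1", start = 100L, end = 200L),
      tibble::tibble(chrom = "chr1", start = 0L, end = 500L)
    )$fraction,
    1
  )
  expect_equal(
    repeat_fraction(
      tibble::tibble(chrom = "chr1", start = 100L, end = 200L),
      tibble::tibble(chrom = character(), start = integer(), end = integer())
    )$fraction,
    0
  )
  withr::local_seed(33)
  regs <- tibble::tibble(
    chrom = "chr1", start = sample.int(9000, 30) * 10L
  ) |> dplyr::mutate(end = start + sample(20:900, 30, replace = TRUE))
  track <- tibble::tibble(
    chrom = "chr1", start = sort(sample.int(95000, 60))
  ) |> dplyr::mutate(end = start + sample(10:400, 60, replace = TRUE))
  got <- repeat_fraction(regs, track)
  per_base <- oracle_covered_bp(regs, track)
  expect_equal(got$fraction, sum(per_base) / sum(regs$end - regs$start),
    tolerance = 1e-9
  )
})

test_that("CGI overlap fraction counts touching regions", {
  regs <- tibble::tibble(
    chrom = "chr1", start = (1:10) * 1000L, end = (1:10) * 1000L + 100L
  )
  cgi <- tibble::tibble(chrom = "chr1", start = (1:4) * 1000L + 50L,
                        end = (1:4) * 1000L + 60L)
  expect_equal(cgi_overlap_fraction(regs, cgi)$fraction, 0.4)
  expect_equal(cgi_overlap_fraction(regs, regs)$fraction, 1)
  expect_warning(
    out <- cgi_overlap_fraction(regs[0, ], cgi),
    "undefined"
  )
  expect_true(is.nan(out$fraction))
})

test_that("planted region classes are recovered on the synthetic fixture", {
  ds <- default_dataset()
  combined <- lapply(c(case = "case", control = "control"), function(cl) {
    ds$profiles |>
      dplyr::filter(class == cl) |>
      filter_low_coverage() |>
      combine_profiles(totals = ds$totals)
  })
  cm <- classify_regions(
    segment_hypo(combined$case), segment_hypo(combined$control),
    segment_himr(combined$case), segment_himr(combined$control),
    case_profile = combined$case, control_profile = combined$control
  )
  truth <- ds$truth_regions[
    ds$truth_regions$truth_class %in% c("gained", "lost", "shared"),
  ]
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- cm[cm$class == truth$truth_class[i] & cm$chrom == truth$chrom[i], ]
    ov <- pmin(cand$end, truth$end[i]) - pmax(cand$start, truth$start[i])
    any(ov >= 0.5 * (truth$end[i] - truth$start[i]) &
      ov >= 0.5 * (cand$end - cand$start))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
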