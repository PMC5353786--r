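test_that("nearest-TSS assignment handles containment, ties and distance", {
  genes <- tibble::tibble(
    gene_id = c("gB", "gA", "gC"),
    chrom = "chr1", tss = c(100L, 100L, 5000L)
  )
  regions <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  got <- assign_nearest_tss(regions, genes)
  expect_equal(got$tss_distance, 0L)
  expect_equal(got$gene_id, "gA")  # tie at distance 0 broken by gene id

  far <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
  got2 <- assign_nearest_tss(far, genes)
  expect_equal(got2$gene_id, "gA")
  expect_equal(got2$tss_distance, 100L)  # 200 - 100, not 5000 - 299
})

test_that("nearest-TSS assignment matches an all-pairs scan", {
  withr::local_seed(41)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:80),
    chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
    tss = sample.int(1e6, 80)
  )
  regions <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
    start = sample.int(1e6, 300)
  ) |> dplyr::mutate(end = start + sample(50:2000, 300, replace = TRUE))
  got <- assign_nearest_tss(regions, genes)
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    d <- ifelse(
      g$tss >= regions$start[i] & g$tss < regions$end[i], 0L,
      ifelse(g$tss < regions$start[i], regions$start[i] - g$tss,
        g$tss - regions$end[i] + 1L
      )
    )
    expect_equal(got$tss_distance[i], min(d))
    expect_equal(got$gene_id[i], min(g$gene_id[d == min(d)]))
  }
})

test_that("regions on a chromosome without TSS stay unassigned", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10L)
  regions <- tibble::tibble(chrom = "chr9", start = 0L, end = 10L)
  expect_message(got <- assign_nearest_tss(regions, genes), "without")
  expect_true(is.na(got$gene_id))
})

test_that("fold change applies the low-expression filter in either class", {
  expr <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    mean_case = c(2.0, 0.05, 1.0, 0.5),
    mean_control = c(1.0, 5.0, 1.0, 0.05)
  )
  fc <- compute_fold_change(expr)
  expect_equal(fc$fold_change[fc$gene_id == "a"], 2.0)
  expect_equal(fc$fold_change[fc$gene_id == "c"], 1.0)
  expect_true(fc$excluded[fc$gene_id == "b"])  # low in case
  expect_true(fc$excluded[fc$gene_id == "d"])  # low in control
  expect_error(compute_fold_change(dplyr::mutate(expr, mean_case = -1)), "negative")
})

test_that("top-percentile gene ranking is order-invariant and complete", {
  withr::local_seed(42)
  fc <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    mean_case = 1, mean_control = 1,
    fold_change = c(seq(5, 1, length.out = 99), 5),  # a tie at the top
    excluded = FALSE
  )
  up10 <- rank_de_genes(fc, 10, "up")
  expect_length(up10, 10)
  expect_true(all(c("g001", "g100") %in% up10))  # tied top genes both ranked
  expect_setequal(rank_de_genes(fc, 100, "up"), fc$gene_id)
  shuffled <- fc[sample.int(100), ]
  expect_equal(rank_de_genes(shuffled, 10, "up"), up10)
  down5 <- rank_de_genes(fc, 5, "down")
  expect_length(down5, 5)
  expect_true(all(fc$fold_change[match(down5, fc$gene_id)] <= sort(fc$fold_change)[5]))
  expect_error(rank_de_genes(fc, 0, "up"), "0, 100")
  expect_error(rank_de_genes(fc, 150, "up"), "0, 100")
})

test_that("enrichment of the shared set against itself is exactly one", {
  withr::local_seed(43)
  assign <- tibble::tibble(
    chrom = "chr1", start = 1:50, end = 2:51,
    gene_id = sample(sprintf("g%02d", 1:20), 50, replace = TRUE)
  )
  res <- dre_gene_enrichment(assign, assign, c("g01", "g05", "g10"),
    measured_genes = sprintf("g%02d", 1:20)
  )
  expect_equal(res$enrichment, 1)
})

test_that("depletion tail has the closed binomial form", {
  # zero of 50 regions linked at baseline 0.2: depletion tail = 0.8^50
  r <- tibble::tibble(chrom = "chr1", start = 1:50, end = 2:51, gene_id = "gx")
  s <- tibble::tibble(
    chrom = "chr1", start = 1:100, end = 2:101,
    gene_id = rep(c("gy", "gz", "gy", "gw", "gv"), 20)
  )
  res <- dre_gene_enrichment(r, s, "gy", c("gx", "gy", "gz", "gw", "gv"))
  expect_equal(res$fract_S_G, 0.4)
  expect_equal(res$p_deplete, 0.6^50)
  expect_equal(res$direction, "depletion")
})

test_that("binomial tails agree with the survival-function oracle", {
  withr::local_seed(44)
  for (i in 1:100) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(
      pbinom(k - 1, n, p, lower.tail = FALSE),  # P(X >= k), enrichment tail
      oracle_tail(k - 1, n, p),
      tolerance = 1e-12
    )
  }
})

test_that("zero baseline fraction yields the infinite-enrichment sentinel", {
  r <- tibble::tibble(chrom = "chr1", start = 1:5, end = 2:6, gene_id = "gx")
  s <- tibble::tibble(chrom = "chr1", start = 1:5, end = 2:6, gene_id = "gy")
  res <- dre_gene_enrichment(r, s, "gx", c("gx", "gy"))
  expect_equal(res$enrichment, Inf)
  expect_equal(res$p_enrich, 0)
  res0 <- dre_gene_enrichment(s, s, "gx", c("gx", "gy"))
  expect_true(is.nan(res0$enrichment))
  expect_equal(res0$p_enrich, 1)
})

test_that("planted gained-near-upregulated structure is detected", {
  ds <- default_dataset()
  res <- run_cached_pipeline()
  enr <- res$gene_linkage$enrichment
  g_up <- enr[enr$class == "gained" & enr$gene_set == "up", ]
  expect_gt(g_up$enrichment, 1)
  expect_lt(g_up$p_value, 0.01)
  l_down <- enr[enr$class == "lost" & enr$gene_set == "down", ]
  expect_gt(l_down$k_R / l_down$n_R, 0.5)
})

test_that("multi-lost genes require >= 2 lost and zero gained elements", {
  lost <- tibble::tibble(
    chrom = "chr1", start = 1:6, end = 2:7,
    gene_id = c("a", "a", "a", "b", "b", "c")
  )
  gained <- tibble::tibble(chrom = "chr1", start = 10L, end = 11L, gene_id = "b")
  got <- find_multi_lost_genes(lost, gained)
  expect_equal(got$gene_id, "a")
  expect_equal(got$n_lost, 3L)
  # gene with >= 2 lost but also a gained element is excluded
  expect_false("b" %in% got$gene_id)
  empty <- find_multi_lost_genes(lost[0, ], gained)
  expect_equal(nrow(empty), 0L)
})

test_that("tidiers expose the enrichment result", {
  r <- tibble::tibble(chrom = "chr1", start = 1:5, end = 2:6, gene_id = "gx")
  s <- tibble::tibble(
    chrom = "chr1", start = 1:10, end = 2:11,
    gene_id = rep(c("gx", "gy"), 5)
  )
  res <- dre_gene_enrichment(r, s, "gx", c("gx", "gy"))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$enrichment, 2)
  expect_named(glance(res), c("enrichment", "p_value", "direction"))
})
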