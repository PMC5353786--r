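# Interval arithmetic on tibbles with `chrom`, `start`, `end` columns.
# All coordinates are 0-based, half-open [start, end). These helpers back the
# region classification, annotation and track-overlap computations; each is
# checked against a per-base brute-force oracle in the test suite.

check_intervals <- function(x, name = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("`%s` must have columns chrom, start, end", name))
  }
  if (nrow(x) > 0 && any(x$end <= x$start)) {
    abort(sprintf("`%s` has intervals with end <= start", name))
  }
  invisible(x)
}

# All overlapping pairs between interval sets `a` and `b` with overlap width
# >= min_overlap_bp. Returns a tibble with row indices into a and b.
overlap_pairs <- function(a, b, min_overlap_bp = 1) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_idx = integer(), b_idx = integer(), overlap_bp = integer()))
  }
  out <- vector("list", 0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    bo <- bi[order(b$start[bi])]
    bs <- b$start[bo]
    be <- b$end[bo]
    cummax_end <- cummax(be)
    for (i in ai) {
      # first candidate: earliest b whose running max end exceeds a's start
      j0 <- findInterval(a$start[i], cummax_end) + 1L
      if (j0 > length(bo)) next
      js <- j0:length(bo)
      js <- js[bs[js] < a$end[i]]
      if (length(js) == 0) next
      ov <- pmin(be[js], a$end[i]) - pmax(bs[js], a$start[i])
      keep <- ov >= min_overlap_bp
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble(
          a_idx = i, b_idx = bo[js[keep]], overlap_bp = as.integer(ov[keep])
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(a_idx = integer(), b_idx = integer(), overlap_bp = integer()))
  }
  bind_rows(out)
}

# Union-merge possibly-overlapping intervals (strict overlap; bookended
# intervals stay separate).
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  parts <- split(x, x$chrom)
  out <- lapply(parts, function(p) {
    s <- p$start
    e <- p$end
    grp <- cumsum(c(TRUE, s[-1] >= cummax(e)[-length(e)]))
    tibble(
      chrom = p$chrom[1],
      start = as.integer(tapply(s, grp, min)),
      end = as.integer(tapply(e, grp, max))
    )
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# Per-interval total base pairs of `a` covered by track `b` (b merged first).
covered_bp <- function(a, b) {
  check_intervals(a, "a")
  if (nrow(a) == 0) return(integer())
  bm <- merge_intervals(b)
  res <- integer(nrow(a))
  prs <- overlap_pairs(a, bm)
  if (nrow(prs) > 0) {
    agg <- prs %>%
      group_by(.data$a_idx) %>%
      summarise(bp = sum(.data$overlap_bp), .groups = "drop")
    res[agg$a_idx] <- agg$bp
  }
  res
}
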