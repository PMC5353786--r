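# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately written as a different algorithm from the implementation it
# checks (naive loops, exhaustive enumeration, log-space summation).

# One shared default synthetic dataset per test session (expensive to build).
.fixture_cache <- new.env(parent = emptyenv())
default_dataset <- function(seed = 1) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_dre_dataset(synthetic_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# One shared full pipeline run on the default dataset (permutations trimmed).
run_cached_pipeline <- function(seed = 1) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_dre_pipeline(
      default_dataset(seed),
      params = list(n_perm = 200), seed = seed
    )
  }
  .fixture_cache[[key]]
}

# Naive per-site weighted-mean combination (direct translation of the
# formula, looping over sites and samples).
oracle_combine <- function(profiles) {
  keys <- unique(profiles[c("chrom", "pos")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- profiles[profiles$chrom == keys$chrom[i] & profiles$pos == keys$pos[i], ]
    w <- 1 / rows$total_aligned_reads
    R <- sum(w * rows$total_reads) / sum(w)
    MR <- sum(w * rows$meth_reads) / sum(w)
    data.frame(
      chrom = keys$chrom[i], pos = keys$pos[i],
      R = R, MR = MR, meth = MR / R, n_samples = nrow(rows)
    )
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$pos), ]
}

# Brute-force maximal-run enumerator: starting from every CpG, extends a
# window while the state predicate and gap rule hold, and keeps windows that
# cannot be extended on either side.
oracle_segment <- function(profile, state, meth_cutoff = 0.5,
                           n_cpg_cutoff = 3, max_gap_bp = 500) {
  profile <- profile[order(profile$chrom, profile$pos), ]
  pred <- if (state == "hypo") {
    profile$meth < meth_cutoff
  } else {
    profile$meth >= meth_cutoff
  }
  res <- list()
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    pos <- profile$pos[idx]
    ok <- pred[idx]
    n <- length(idx)
    for (i in seq_len(n)) {
      if (!ok[i]) next
      j <- i
      while (j < n && ok[j + 1] && (pos[j + 1] - pos[j]) <= max_gap_bp) j <- j + 1
      left_ext <- i > 1 && ok[i - 1] && (pos[i] - pos[i - 1]) <= max_gap_bp
      if (left_ext) next
      if (j - i + 1 < n_cpg_cutoff) next
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = pos[i], end = as.integer(pos[j] + 2L),
        n_cpg = as.integer(j - i + 1)
      )
    }
  }
  if (length(res) == 0) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(), n_cpg = integer()
    ))
  }
  out <- unique(do.call(rbind, res))
  out[order(out$chrom, out$start), ]
}

random_profile <- function(n, chrom = "chr1", max_pos_step = 800) {
  pos <- cumsum(sample.int(max_pos_step, n, replace = TRUE))
  tibble::tibble(chrom = chrom, pos = pos, meth = round(runif(n), 3))
}

# Log-space explicit summation of the strict binomial upper tail.
oracle_tail <- function(n_kc, n_c, p) {
  if (p == 0) return(0)
  if (p == 1) return(if (n_kc < n_c) 1 else 0)
  i <- seq.int(n_kc + 1, n_c)
  if (length(i) == 0 || n_kc >= n_c) return(0)
  sum(exp(lchoose(n_c, i) + i * log(p) + (n_c - i) * log1p(-p)))
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher p-value:
# sum of the probabilities of all tables with the observed margins whose
# probability does not exceed the observed one (point-probability method).
oracle_fisher2 <- function(D) {
  m <- D[1, 1] + D[1, 2]
  n <- D[2, 1] + D[2, 2]
  k <- D[1, 1] + D[2, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(D[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Per-base interval coverage: paints bases into a logical vector.
oracle_covered_bp <- function(a, b, genome_len = 100000) {
  vapply(seq_len(nrow(a)), function(i) {
    paint <- logical(genome_len)
    for (j in seq_len(nrow(b))) {
      if (b$chrom[j] == a$chrom[i]) {
        paint[(b$start[j] + 1):b$end[j]] <- TRUE
      }
    }
    sum(paint[(a$start[i] + 1):a$end[i]])
  }, numeric(1))
}

# All-pairs nearest-neighbour distances (edge-to-edge, same chromosome).
oracle_nn_within <- function(regions) {
  n <- nrow(regions)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j || regions$chrom[i] != regions$chrom[j]) next
      gap <- max(
        regions$start[j] - regions$end[i],
        regions$start[i] - regions$end[j]
      )
      best <- min(best, max(0, gap))
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# All-window PWM rescoring from the probability matrix (recomputes the
# discretized scores independently of scan_sequence's vectorised path).
oracle_scan <- function(pwm, sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- pwm$width
  hits <- list()
  score_of <- function(seq_bases) {
    idx <- match(seq_bases, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_integer_)
    sum(pwm$score_int[cbind(idx, seq_len(w))])
  }
  for (off in 0:(length(bases) - w)) {
    win <- bases[(off + 1):(off + w)]
    s_plus <- score_of(win)
    if (!is.na(s_plus) && s_plus >= pwm$threshold_int) {
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+")
    }
    s_minus <- score_of(rev(unname(comp[win])))
    if (!is.na(s_minus) && s_minus >= pwm$threshold_int) {
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), ]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# High-information PWM around a consensus string (0.91 consensus base).
sharp_pwm <- function(consensus, id = "m1", p_threshold = 1e-4) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  prob <- matrix(0.03, 4, length(codes))
  prob[cbind(codes, seq_along(codes))] <- 0.91
  new_pwm(id, prob, p_threshold = p_threshold)
}

# Simple labelled-region fixture for spatial/permutation null tests.
random_labeled_regions <- function(n, labels = c("gained", "lost", "shared", "himr"),
                                   chrom_len = 1e6) {
  st <- sort(sample.int(chrom_len, n))
  tibble::tibble(
    chrom = "chr1", start = st, end = st + sample(100:500, n, replace = TRUE),
    class = sample(rep(labels, length.out = n))
  )
}
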