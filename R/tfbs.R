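# PWM motif scanning and motif gain/loss statistics at allele substitutions.
#
# Scores are additive log-odds over a column-stochastic probability matrix
# with pseudocount, discretized to an integer lattice so the null score
# distribution (and hence the p-value threshold) is computed exactly by
# convolution over positions under the background model.

DNA <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], DNA)
  x
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

gc_content <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  mean(s %in% c("G", "C"))
}

#' Construct a position weight matrix scanner
#'
#' Builds the log-odds matrix from per-position nucleotide probabilities with
#' a pseudocount, discretizes the scores, and calibrates the hit threshold so
#' that a background-model window exceeds it with probability at most
#' `p_threshold`. The null score distribution is exact: a dynamic-programming
#' convolution of the discretized per-position score distributions under the
#' background nucleotide frequencies.
#'
#' @param motif_id Motif identifier.
#' @param prob 4 x width matrix of probabilities (rows A, C, G, T); columns
#'   must each sum to 1.
#' @param bg Background nucleotide frequencies (default uniform).
#' @param pseudocount Added to every cell before normalisation (default 0.01).
#' @param p_threshold Background tail probability defining a hit
#'   (default 1e-4).
#' @param granularity Number of lattice steps across the score range of the
#'   whole matrix (default 1000).
#' @return Object of class `pwm`.
#' @export
new_pwm <- function(motif_id, prob, bg = rep(0.25, 4), pseudocount = 0.01,
                    p_threshold = 1e-4, granularity = 1000) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 4) abort("`prob` must have 4 rows (A, C, G, T)")
  w <- ncol(prob)
  if (w < 4) abort("motif width must be at least 4")
  if (any(abs(colSums(prob) - 1) > 1e-6)) abort("PWM columns must sum to 1")
  if (abs(sum(bg) - 1) > 1e-6) abort("background frequencies must sum to 1")
  p2 <- sweep(prob + pseudocount, 2, colSums(prob + pseudocount), "/")
  lo <- log2(p2 / bg)
  delta <- (max(lo) - min(lo)) / granularity
  if (delta == 0) delta <- 1e-9
  score_int <- round(lo / delta)
  storage.mode(score_int) <- "integer"
  # exact null distribution of the integer window score by convolution
  lo_int <- apply(score_int, 2, min)
  hi_int <- apply(score_int, 2, max)
  off <- sum(lo_int)
  dist <- 1
  for (j in seq_len(w)) {
    col_support <- score_int[, j] - lo_int[j]
    col_dist <- numeric(hi_int[j] - lo_int[j] + 1L)
    for (a in 1:4) {
      col_dist[col_support[a] + 1L] <- col_dist[col_support[a] + 1L] + bg[a]
    }
    dist <- convolve_pmf(dist, col_dist)
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p_threshold)
  threshold_int <- if (length(ok) == 0) {
    as.integer(off + length(dist))  # unreachable: no window can be a hit
  } else {
    as.integer(off + ok[1] - 1L)
  }
  structure(
    list(
      motif_id = motif_id, width = w, prob = prob, bg = bg,
      pseudocount = pseudocount, log_odds = lo, delta = delta,
      score_int = score_int, threshold_int = threshold_int,
      p_threshold = p_threshold,
      consensus = paste(DNA[apply(prob, 2, which.max)], collapse = "")
    ),
    class = "pwm"
  )
}

# discrete convolution of two probability mass vectors (support offsets 0..)
convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    if (b[i] > 0) {
      idx <- seq_along(a) + i - 1L
      out[idx] <- out[idx] + a * b[i]
    }
  }
  out
}

#' Scan a sequence for motif hits on both strands
#'
#' Reports every window whose discretized log-odds score reaches the
#' calibrated threshold, on either strand. Windows containing `N` are
#' skipped. Offsets are 0-based positions of the window's leftmost base on
#' the forward strand.
#'
#' @param pwm A [new_pwm()] object.
#' @param sequence Character scalar over A/C/G/T/N.
#' @param seq_id Identifier attached to the hits.
#' @return Tibble `seq_id`, `offset`, `strand`, `motif_id`, `score`
#'   (log-odds), `score_int`.
#' @export
scan_sequence <- function(pwm, sequence, seq_id = "seq") {
  empty <- tibble(
    seq_id = character(), offset = integer(), strand = character(),
    motif_id = character(), score = double(), score_int = integer()
  )
  code <- encode_dna(sequence)
  w <- pwm$width
  nwin <- length(code) - w + 1L
  if (nwin < 1) return(empty)
  scan_matrix <- function(M, M_real) {
    s <- rep(0L, nwin)
    r <- rep(0, nwin)
    bad <- rep(FALSE, nwin)
    for (j in seq_len(w)) {
      cj <- code[j:(j + nwin - 1L)]
      bad <- bad | is.na(cj)
      cj[is.na(cj)] <- 1L
      s <- s + M[cbind(cj, j)]
      r <- r + M_real[cbind(cj, j)]
    }
    list(s = ifelse(bad, NA_integer_, s), r = r)
  }
  fwd <- scan_matrix(pwm$score_int, pwm$log_odds)
  rc_int <- pwm$score_int[4:1, w:1, drop = FALSE]
  rc_real <- pwm$log_odds[4:1, w:1, drop = FALSE]
  rev_ <- scan_matrix(rc_int, rc_real)
  collect <- function(sc, strand) {
    hit <- !is.na(sc$s) & sc$s >= pwm$threshold_int
    if (!any(hit)) return(empty)
    tibble(
      seq_id = seq_id, offset = which(hit) - 1L, strand = strand,
      motif_id = pwm$motif_id, score = sc$r[hit], score_int = sc$s[hit]
    )
  }
  bind_rows(collect(fwd, "+"), collect(rev_, "-")) %>%
    arrange(.data$offset, .data$strand)
}

#' Scan a set of sequences with a set of motifs
#'
#' @param pwms List of [new_pwm()] objects.
#' @param sequences Named character vector of sequences.
#' @return Combined hit tibble.
#' @export
scan_sequences <- function(pwms, sequences) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  bind_rows(lapply(pwms, function(p) {
    bind_rows(lapply(seq_along(sequences), function(i) {
      scan_sequence(p, sequences[[i]], ids[i])
    }))
  }))
}

extract_seq <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

#' Sample control sequences matched on GC content and repeat density
#'
#' Rejection-samples same-length windows from the genome until `n` windows
#' match the region's GC content within `gc_tol` and its repeat fraction
#' within `repeat_tol`, under a bounded attempt budget (fewer controls are
#' returned with a warning when the budget is exhausted).
#'
#' @param region One-row region tibble (`chrom`, `start`, `end`).
#' @param genome Named character vector (or list) of chromosome sequences.
#' @param repeat_track Repeat interval tibble.
#' @param n Number of control sequences (default 10).
#' @param gc_tol,repeat_tol Matching tolerances (defaults 0.05).
#' @param seed Integer seed.
#' @param max_attempts Attempt budget (default `1000 * n`).
#' @return Tibble `chrom`, `start`, `end`, `gc`, `repeat_frac`, `seq`.
#' @export
sample_matched_controls <- function(region, genome, repeat_track, n = 10,
                                    gc_tol = 0.05, repeat_tol = 0.05,
                                    seed = 1, max_attempts = 1000 * n) {
  len <- region$end - region$start
  target_gc <- gc_content(extract_seq(genome, region$chrom, region$start, region$end))
  target_rep <- covered_bp(region, repeat_track) / len
  chroms <- names(genome)
  chrom_len <- vapply(genome, nchar, integer(1))
  ok_chroms <- chroms[chrom_len >= len]
  if (length(ok_chroms) == 0) abort("no chromosome long enough for controls")
  out <- list()
  with_seed(seed, {
    attempts <- 0
    while (length(out) < n && attempts < max_attempts) {
      attempts <- attempts + 1
      ch <- sample(ok_chroms, 1, prob = chrom_len[ok_chroms] - len + 1)
      st <- sample.int(chrom_len[[ch]] - len + 1L, 1) - 1L
      win <- tibble(chrom = ch, start = st, end = st + len)
      sq <- extract_seq(genome, ch, st, st + len)
      gc <- gc_content(sq)
      rp <- covered_bp(win, repeat_track) / len
      if (abs(gc - target_gc) <= gc_tol && abs(rp - target_rep) <= repeat_tol) {
        out[[length(out) + 1L]] <- mutate(win, gc = gc, repeat_frac = rp, seq = sq)
      }
    }
  })
  if (length(out) < n) {
    warn(sprintf("matched-control budget exhausted: %d/%d controls", length(out), n))
  }
  if (length(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      gc = double(), repeat_frac = double(), seq = character()
    ))
  }
  bind_rows(out)
}

#' Motif density enrichment in regions versus matched controls
#'
#' @param region_seqs Character vector of region sequences.
#' @param control_seqs Character vector of control sequences.
#' @param pwms List of [new_pwm()] objects.
#' @return Tibble per motif with hit counts, densities (hits/kb) and their
#'   ratio (`Inf` sentinel when controls have zero hits but regions do not).
#' @export
tfbs_enrichment <- function(region_seqs, control_seqs, pwms) {
  kb <- function(seqs) sum(nchar(seqs)) / 1000
  region_kb <- kb(region_seqs)
  control_kb <- kb(control_seqs)
  bind_rows(lapply(pwms, function(p) {
    rh <- nrow(scan_sequences(list(p), region_seqs))
    chh <- nrow(scan_sequences(list(p), control_seqs))
    rd <- rh / region_kb
    cd <- chh / control_kb
    tibble(
      motif_id = p$motif_id, region_hits = rh, control_hits = chh,
      region_kb = region_kb, control_kb = control_kb,
      region_density = rd, control_density = cd,
      enrichment = if (cd == 0) {
        if (rd == 0) NaN else Inf
      } else {
        rd / cd
      }
    )
  }))
}

#' Sample background positions carrying the WT allele
#'
#' Within the host region of a SNP, draws up to `N` positions whose reference
#' base equals the SNP's WT allele (excluding the SNP position itself); each
#' serves as a pseudo-substitution site for the background motif-change
#' statistics. When fewer than `N` candidates exist all are used.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,region_start,region_end Host region coordinates.
#' @param snp_pos SNP position (0-based, excluded).
#' @param wt_allele WT base to match.
#' @param N Number of background positions (default 30).
#' @param seed Integer seed.
#' @return Sorted integer vector of genomic positions (possibly empty).
#' @export
sample_background_positions <- function(genome, chrom, region_start, region_end,
                                        snp_pos, wt_allele, N = 30, seed = 1) {
  seqs <- strsplit(toupper(extract_seq(genome, chrom, region_start, region_end)), "")[[1]]
  cand <- region_start + which(seqs == toupper(wt_allele)) - 1L
  cand <- cand[cand != snp_pos]
  if (length(cand) == 0) {
    warn("no background positions carry the WT allele in the host region")
    return(integer())
  }
  if (length(cand) <= N) return(sort(cand))
  sort(with_seed(seed, sample(cand, N)))
}

# Hits (per motif) overlapping a substituted base, for WT and MU local
# sequences built with maxw-1 flanking bases on each side.
allele_local_hits <- function(pwms, genome, chrom, pos, wt, mu, key) {
  maxw <- max(vapply(pwms, function(p) p$width, integer(1)))
  chrom_len <- nchar(genome[[chrom]])
  wstart <- max(0L, pos - (maxw - 1L))
  wend <- min(chrom_len, pos + maxw)
  center <- pos - wstart
  wt_seq <- extract_seq(genome, chrom, wstart, wend)
  base_here <- toupper(substr(wt_seq, center + 1L, center + 1L))
  if (base_here != toupper(wt)) {
    wt_seq <- paste0(
      substr(wt_seq, 1, center), toupper(wt),
      substr(wt_seq, center + 2L, nchar(wt_seq))
    )
  }
  mu_seq <- paste0(
    substr(wt_seq, 1, center), toupper(mu),
    substr(wt_seq, center + 2L, nchar(wt_seq))
  )
  over <- function(hits, w) {
    filter(hits, .data$offset <= center, .data$offset + w > center)
  }
  per_motif <- lapply(pwms, function(p) {
    wt_hits <- over(scan_sequence(p, wt_seq, key), p$width)
    mu_hits <- over(scan_sequence(p, mu_seq, key), p$width)
    hit_key <- function(h) paste(h$seq_id, h$offset, h$strand, sep = ":")
    list(wt = hit_key(wt_hits), mu = hit_key(mu_hits))
  })
  names(per_motif) <- vapply(pwms, function(p) p$motif_id, character(1))
  per_motif
}

count_changes <- function(hit_list, pwms) {
  bind_rows(lapply(pwms, function(p) {
    wt <- unlist(lapply(hit_list, function(h) h[[p$motif_id]]$wt))
    mu <- unlist(lapply(hit_list, function(h) h[[p$motif_id]]$mu))
    tibble(
      motif_id = p$motif_id,
      n_wt = length(wt),
      n_wt_not_mu = length(setdiff(wt, mu)),
      n_mu = length(mu),
      n_mu_not_wt = length(setdiff(mu, wt))
    )
  }))
}

#' Motif gain/loss statistics at cancer-associated substitutions
#'
#' For every SNP, builds the WT and MU local sequences (motif-width minus one
#' flanking bases each side of the substituted position), counts per motif
#' the hits overlapping the substituted base in the WT and MU alleles, and
#' aggregates over SNPs:
#' \deqn{Fract(lost|t) = N(t|WT, not\ MU) / N(t|WT)}
#' \deqn{Fract(gained|t) = N(t|MU, not\ WT) / N(t|MU)}
#' The same procedure at background positions (same host regions, matched WT
#' base, pooled across SNPs) yields the background fraction `p_t`, and the
#' significance is the strict upper-tail binomial probability of the observed
#' changed-hit count with trial count `N(t|WT)` (loss) or `N(t|MU)` (gain)
#' and success probability `p_t`.
#'
#' @param snps Tibble `snp_id`, `chrom`, `pos`, `wt_allele`, `mu_allele`,
#'   `region_start`, `region_end` (host region).
#' @param pwms List of [new_pwm()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param direction `"both"` (default), `"lost"` or `"gained"`: which
#'   canonical `fraction` / `p_value` / `enrichment` columns to emit (all
#'   underlying counts are always returned).
#' @param n_background Background positions per SNP (default 30).
#' @param seed Integer seed for background sampling.
#' @return Tibble of class `tfbs_change`, one row per motif.
#' @export
motif_change_stats <- function(snps, pwms, genome,
                               direction = c("both", "lost", "gained"),
                               n_background = 30, seed = 1) {
  direction <- match.arg(direction)
  obs_hits <- lapply(seq_len(nrow(snps)), function(i) {
    allele_local_hits(
      pwms, genome, snps$chrom[i], snps$pos[i],
      snps$wt_allele[i], snps$mu_allele[i], snps$snp_id[i]
    )
  })
  obs <- count_changes(obs_hits, pwms)
  bg_hits <- list()
  n_bg_positions <- 0L
  for (i in seq_len(nrow(snps))) {
    bg_pos <- suppressWarnings(sample_background_positions(
      genome, snps$chrom[i], snps$region_start[i], snps$region_end[i],
      snps$pos[i], snps$wt_allele[i], N = n_background,
      seed = derive_seed(seed, i)
    ))
    n_bg_positions <- n_bg_positions + length(bg_pos)
    for (bp in bg_pos) {
      bg_hits[[length(bg_hits) + 1L]] <- allele_local_hits(
        pwms, genome, snps$chrom[i], bp,
        snps$wt_allele[i], snps$mu_allele[i],
        paste0(snps$snp_id[i], "@", bp)
      )
    }
  }
  bg <- count_changes(bg_hits, pwms) %>%
    rename(
      bg_n_wt = "n_wt", bg_n_wt_not_mu = "n_wt_not_mu",
      bg_n_mu = "n_mu", bg_n_mu_not_wt = "n_mu_not_wt"
    )
  out <- inner_join(obs, bg, by = "motif_id") %>%
    mutate(
      fract_lost = ifelse(.data$n_wt > 0, .data$n_wt_not_mu / .data$n_wt, NA_real_),
      fract_gained = ifelse(.data$n_mu > 0, .data$n_mu_not_wt / .data$n_mu, NA_real_),
      # background fraction defaults to 0 when no background hit exists at
      # all for the motif (no evidence of background change)
      bg_fract_lost = ifelse(.data$bg_n_wt > 0, .data$bg_n_wt_not_mu / .data$bg_n_wt, 0),
      bg_fract_gained = ifelse(.data$bg_n_mu > 0, .data$bg_n_mu_not_wt / .data$bg_n_mu, 0),
      p_lost = ifelse(
        .data$n_wt > 0,
        pbinom(.data$n_wt_not_mu, .data$n_wt, .data$bg_fract_lost,
          lower.tail = FALSE),
        NA_real_
      ),
      p_gained = ifelse(
        .data$n_mu > 0,
        pbinom(.data$n_mu_not_wt, .data$n_mu, .data$bg_fract_gained,
          lower.tail = FALSE),
        NA_real_
      ),
      enrichment_lost = .data$fract_lost / .data$bg_fract_lost,
      enrichment_gained = .data$fract_gained / .data$bg_fract_gained,
      n_bg_positions = n_bg_positions
    )
  if (direction == "lost") {
    out <- mutate(out,
      fraction = .data$fract_lost, p_value = .data$p_lost,
      enrichment = .data$enrichment_lost
    )
  } else if (direction == "gained") {
    out <- mutate(out,
      fraction = .data$fract_gained, p_value = .data$p_gained,
      enrichment = .data$enrichment_gained
    )
  }
  class(out) <- c("tfbs_change", class(out))
  out
}
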