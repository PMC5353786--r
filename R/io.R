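# Readers/writers for the external text formats: BED regions, TSV profiles,
# FASTA genomes (via seqinr), a VCF-like phased panel (read back via vcfR),
# and a MEME-like motif exchange format (minimal hand-rolled dialect: no
# installed R package parses MEME text).

#' Write regions as BED
#'
#' Columns: chrom, start, end, name (the state/class), score
#' (`round(1000 * mean_meth)`). 0-based half-open, BED convention.
#'
#' @param regions Region tibble with `state` or `class` and `mean_meth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  col <- function(nm) if (nm %in% names(regions)) regions[[nm]] else NULL
  name <- col("class") %||% col("state") %||% rep(".", nrow(regions))
  score <- if ("mean_meth" %in% names(regions)) {
    ifelse(is.na(regions$mean_meth), 0L, as.integer(round(1000 * regions$mean_meth)))
  } else {
    rep(0L, nrow(regions))
  }
  readr::write_tsv(
    tibble(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      name = name, score = score
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a BED file into a region tibble
#'
#' @param path BED path (3+ columns, no header).
#' @return Tibble `chrom`, `start`, `end` (+ `name`, `score` when present).
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score")[seq_len(min(5, ncol(x)))]
  as_tibble(x[seq_len(min(5, ncol(x)))])
}

#' Write/read a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path FASTA path.
#' @return `path` invisibly; `read_genome_fasta()` returns the named vector.
#' @export
write_genome_fasta <- function(genome, path) {
  seqinr::write.fasta(
    sequences = lapply(genome, function(s) strsplit(s, "")[[1]]),
    names = names(genome), file.out = path
  )
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' Write a phased haplotype panel as a VCF-like file
#'
#' Minimal VCFv4.2 body with phased GT columns, two haplotype rows per
#' nominal sample column; readable by standard VCF parsers.
#'
#' @param panel Panel list (`haplotypes`, `snps`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hap_panel <- function(panel, path) {
  H <- panel$haplotypes
  n_hap <- nrow(H)
  if (n_hap %% 2 != 0) abort("panel must hold an even number of haplotypes")
  n_ind <- n_hap / 2
  ids <- sprintf("ind%04d", seq_len(n_ind))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(panel$snps)), function(i) {
    s <- panel$snps[i, ]
    gt <- paste(H[seq(1, n_hap, 2), s$snp_id], H[seq(2, n_hap, 2), s$snp_id],
      sep = "|"
    )
    paste(c(s$chrom, s$pos + 1L, s$snp_id, s$ref, s$alt, ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phased panel from a VCF file
#'
#' @param path VCF path.
#' @return Panel list (`haplotypes`, `snps`).
#' @export
read_hap_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  split_gt <- function(col) {
    parts <- strsplit(gt[, col], "|", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad)) abort("panel contains unphased or missing genotypes")
    as.integer(unlist(parts))
  }
  H <- vapply(colnames(gt), split_gt, integer(2 * nrow(gt)))
  # rows of H alternate hap1/hap2 per variant block; reshape to chrom x snp
  n_ind <- ncol(gt)
  n_snp <- nrow(gt)
  out <- matrix(0L, nrow = 2 * n_ind, ncol = n_snp)
  for (j in seq_len(n_ind)) {
    m <- matrix(H[, j], nrow = 2)  # 2 x n_snp for individual j
    out[2 * j - 1L, ] <- m[1, ]
    out[2 * j, ] <- m[2, ]
  }
  colnames(out) <- rownames(gt)
  rownames(out) <- sprintf("h%04d", seq_len(2 * n_ind))
  list(
    haplotypes = out,
    snps = tibble(
      snp_id = rownames(gt), chrom = fix$CHROM,
      pos = as.integer(fix$POS) - 1L, ref = fix$REF, alt = fix$ALT
    )
  )
}

#' Write/read motifs in a MEME-like text format
#'
#' @param pwms List of [new_pwm()] objects.
#' @param path Output path.
#' @return `path` invisibly; the reader returns a list of [new_pwm()]
#'   objects rebuilt with the stored probabilities.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (p in pwms) {
    lines <- c(
      lines,
      paste("MOTIF", p$motif_id),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
        p$width
      ),
      apply(p$prob, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @param ... Passed to [new_pwm()] (threshold settings).
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(i) {
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- lines[i + 1L]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
    rows <- lines[(i + 2L):(i + 1L + w)]
    prob <- unname(t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4))))
    new_pwm(id, t(prob), ...)
  })
}

#' Write a combined consensus profile as TSV
#'
#' @param profile [combine_profiles()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combined_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}
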