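# Shared fixture builders: everything is generated in code at test time.

# Build a genotype_matrix from a character matrix of "a/b" genotype strings
# ("./." = missing), one row per site.
toy_gm <- function(gt, ref, alt, chrom = NULL, pos = NULL,
                   samples = NULL, panels = list()) {
  gt <- as.matrix(gt)
  S <- nrow(gt); N <- ncol(gt)
  if (is.null(chrom)) chrom <- rep("chr01", S)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(N))
  a1 <- suppressWarnings(matrix(as.integer(sub("/.*", "", gt)), S, N))
  a2 <- suppressWarnings(matrix(as.integer(sub(".*/", "", gt)), S, N))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_matrix(chrom, pos, ref, alt, a1, a2, samples, panels)
}

# Minimal VCF text on disk; body rows are list(c(chrom, pos, ref, alt, gt...)).
write_toy_vcf <- function(rows, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(rows, function(r) {
    paste(c(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".", "GT",
            r[-(1:4)]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Brute-force nucleotide diversity: explicit enumeration of all haplotype
# pairs, the independent oracle for the allele-count shortcut.
brute_force_pi <- function(haps, L_bar) {
  n <- nrow(haps)
  k_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k_sum <- k_sum + sum(haps[i, ] != haps[j, ])
    }
  }
  (1 / L_bar) * (n / (n - 1)) * (k_sum / (n * (n - 1) / 2))
}

# Single-locus pedigree enumeration: genotype-class distribution of a
# g-times-backcrossed hybrid, propagating exact gamete probabilities.
pedigree_class_freqs <- function(g) {
  v <- c(AA = 0, Aa = 1, aa = 0)  # F1 is heterozygous
  for (i in seq_len(g)) {
    p_donor_gamete <- v[["aa"]] + v[["Aa"]] / 2
    v <- c(AA = 1 - p_donor_gamete, Aa = p_donor_gamete, aa = 0)
  }
  v
}

# Expand smoothed segments back to per-site classes (for idempotence checks).
segments_to_classes <- function(track) {
  out <- character(length(track$pos))
  for (k in seq_len(nrow(track$smoothed))) {
    seg <- track$smoothed[k, ]
    out[track$pos >= seg$start & track$pos <= seg$end] <- seg$class
  }
  out
}

table1_counts <- c(N_AA = 434253, N_Aa = 460070, N_aa = 20760)
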