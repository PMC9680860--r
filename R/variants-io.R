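#' Read a panel configuration
#'
#' Panel assignments map sample ids to panel roles. Accepted forms: a
#' two-column TSV (`sample_id<TAB>panel`, no header or a `sample_id\tpanel`
#' header), a YAML file (`panel: [ids]` mapping), or an in-memory named list
#' `list(panelName = c(ids...))`.
#'
#' @param x Path to a TSV/YAML file, or a named list of sample-id vectors.
#' @return Named list of [sample_panel()] objects.
#' @export
read_panel_config <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    return(mapply(sample_panel, names(x), x, SIMPLIFY = FALSE))
  }
  stopifnot(is.character(x), length(x) == 1L, file.exists(x))
  if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML panel configs requires the 'yaml' package")
    cfg <- yaml::read_yaml(x)
    return(mapply(sample_panel, names(cfg), cfg, SIMPLIFY = FALSE))
  }
  tab <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("panel TSV must have two columns: sample_id, panel")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  split_ids <- split(as.character(tab[[1]]), as.character(tab[[2]]))
  mapply(sample_panel, names(split_ids), split_ids, SIMPLIFY = FALSE)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or bgzipped) via \pkg{vcfR} and attaches
#' panel assignments. All records are retained; genotypes are parsed as
#' unphased allele pairs (phase separators `|` and `/` are equivalent) and
#' missing calls are preserved as `NA`.
#'
#' @param path VCF file path.
#' @param panel_config Panel mapping accepted by [read_panel_config()], or
#'   `NULL` for no panels.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, panel_config = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(samples)) stop("VCF has no sample columns: ", path)
  panels <- if (is.null(panel_config)) list() else read_panel_config(panel_config)
  for (p in panels) {
    bad <- setdiff(p$sample_ids, samples)
    if (length(bad))
      stop("panel '", p$name, "' names sample(s) absent from VCF header: ",
           paste(bad, collapse = ", "))
  }
  parsed <- parse_gt_pairs(gt)
  genotype_matrix(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
    a1 = parsed$a1, a2 = parsed$a2,
    samples = samples, panels = panels
  )
}

# "0/1", "1|0", "./.", ".", NA -> unordered integer pairs
parse_gt_pairs <- function(gt) {
  dm <- dim(gt)
  gt <- as.character(gt)
  gt[is.na(gt)] <- "."
  first <- sub("^([^/|]+)[/|].*$", "\\1", gt)
  second <- sub("^[^/|]+[/|]([^/|:]+).*$", "\\1", gt)
  second[!grepl("[/|]", gt)] <- "."   # haploid or missing call -> missing
  first[!grepl("[/|]", gt)] <- "."
  a1 <- suppressWarnings(as.integer(first))
  a2 <- suppressWarnings(as.integer(second))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  list(a1 = matrix(a1, dm[1], dm[2]), a2 = matrix(a2, dm[1], dm[2]))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal plain-text VCF with GT-only genotype columns; the
#' round-trip `read_vcf(write_vcf(gm))` preserves chrom/pos/alleles and
#' unphased genotypes exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. simulation provenance).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, extra_header = character()) {
  gt_chr <- matrix(".", n_sites(gm), length(gm$samples))
  ok <- !is.na(gm$a1)
  gt_chr[ok] <- paste0(gm$a1[ok], "/", gm$a2[ok])
  gt_chr[!ok] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
                apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Restrict to biallelic SNPs with complete genotypes
#'
#' Keeps only sites with exactly one single-nucleotide ALT allele, a
#' single-nucleotide REF, and no missing genotype among `sample_subset`.
#' Multiallelic records are never split. Site order is preserved and the
#' operation is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param sample_subset Sample ids whose completeness is required; defaults
#'   to all samples.
#' @return The filtered [genotype_matrix()].
#' @export
filter_biallelic_complete <- function(gm, sample_subset = gm$samples) {
  if (length(sample_subset) == 0L) stop("sample_subset must be non-empty")
  cols <- sample_cols(gm, sample_subset)
  keep <- is_biallelic_snp(gm) &
    rowSums(is.na(gm$a1[, cols, drop = FALSE])) == 0L
  subset_sites(gm, keep)
}

#' Export an IUPAC-coded SNP alignment
#'
#' Concatenates per-site genotypes into one aligned sequence per sample:
#' homozygotes become the base itself, heterozygotes the two-base IUPAC
#' ambiguity code (R, Y, S, W, K, M). This is the standard encoding used to
#' feed concatenated SNPs to phylogenetic-network software. The matrix must
#' contain only biallelic SNPs with no missing genotype (run
#' [filter_biallelic_complete()] first).
#'
#' @param gm A [genotype_matrix()] of biallelic, complete SNPs.
#' @param path Optional FASTA output path; if `NULL`, no file is written.
#' @param chroms Optional chromosome subset (e.g. to exclude unanchored
#'   contigs); default uses all sites.
#' @return Named character vector of sequences (one per sample), invisibly
#'   if `path` is given.
#' @export
export_iupac_fasta <- function(gm, path = NULL, chroms = NULL) {
  if (!is.null(chroms)) gm <- subset_sites(gm, gm$chrom %in% chroms)
  if (!all(is_biallelic_snp(gm)))
    stop("alignment export supports only biallelic single-nucleotide sites")
  if (anyNA(gm$a1))
    stop("alignment export requires complete genotypes; filter first")
  b1 <- vapply(seq_along(gm$samples),
               function(j) allele_base(gm, gm$a1[, j]), character(n_sites(gm)))
  b2 <- vapply(seq_along(gm$samples),
               function(j) allele_base(gm, gm$a2[, j]), character(n_sites(gm)))
  if (n_sites(gm) == 1L) { b1 <- rbind(b1); b2 <- rbind(b2) }
  code <- matrix(iupac_code(b1, b2), nrow = n_sites(gm))
  seqs <- apply(code, 2, paste, collapse = "")
  names(seqs) <- gm$samples
  if (!is.null(path)) {
    write_fasta(seqs, path)
    return(invisible(seqs))
  }
  seqs
}

IUPAC2 <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

iupac_code <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  hom <- b1 == b2
  out <- b1
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  out[!hom] <- IUPAC2[key[!hom]]
  if (anyNA(out)) stop("unrecognized allele pair in IUPAC encoding")
  out
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Export the IUPAC alignment in NEXUS format
#'
#' Same encoding as [export_iupac_fasta()], wrapped in a minimal NEXUS DATA
#' block for network/phylogeny software that prefers NEXUS input.
#'
#' @inheritParams export_iupac_fasta
#' @param path NEXUS output path.
#' @return `path`, invisibly.
#' @export
export_iupac_nexus <- function(gm, path, chroms = NULL) {
  seqs <- export_iupac_fasta(gm, path = NULL, chroms = chroms)
  nchar1 <- if (length(seqs)) nchar(seqs[[1]]) else 0L
  lines <- c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs), nchar1),
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("    %s %s", names(seqs), unname(seqs)),
    "  ;", "END;"
  )
  writeLines(lines, path)
  invisible(path)
}
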