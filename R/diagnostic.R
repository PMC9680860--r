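#' Find species-discriminatory (diagnostic) SNPs
#'
#' A diagnostic site is fixed for opposite alleles in the two parental
#' panels: every panel-A sample homozygous for one allele and every panel-B
#' sample homozygous for the other. The focal individual's genotype at such
#' sites reveals its ancestry dosage. Fixation is judged on genotype calls
#' (all samples homozygous), matching a small-panel design; set
#' `min_freq < 1` to switch to an allele-frequency threshold for larger
#' panels (a site then qualifies when the A-panel frequency of one allele
#' and the B-panel frequency of the other are both `>= min_freq`, still
#' requiring different majority alleles and, for the allele assignment,
#' within-panel fixation is no longer guaranteed so the majority allele is
#' recorded).
#'
#' @param gm A [genotype_matrix()] pre-filtered to biallelic SNPs with no
#'   missing genotype across both panels and the focal sample
#'   ([filter_biallelic_complete()]).
#' @param panelA,panelB The two parental panels (no shared sample ids).
#' @param min_freq Fixation threshold in (0.5, 1]; default 1 = strict
#'   fixation on genotype calls.
#' @return A `data.frame` of class `diagnostic_sites` with columns `chrom`,
#'   `pos`, `allele_A` (parent-A-specific base) and `allele_a`
#'   (parent-B-specific base), sorted in matrix site order.
#' @export
find_discriminatory_sites <- function(gm, panelA, panelB, min_freq = 1) {
  panelA <- get_panel(gm, panelA); panelB <- get_panel(gm, panelB)
  shared <- intersect(panelA$sample_ids, panelB$sample_ids)
  if (length(shared))
    stop("panels share sample id(s): ", paste(shared, collapse = ", "))
  if (min_freq <= 0.5 || min_freq > 1)
    stop("min_freq must be in (0.5, 1]")
  colsA <- sample_cols(gm, panelA$sample_ids)
  colsB <- sample_cols(gm, panelB$sample_ids)
  bi <- is_biallelic_snp(gm)
  complete <- rowSums(is.na(gm$a1[, c(colsA, colsB), drop = FALSE])) == 0L
  eligible <- bi & complete

  freq_alt <- function(cols) {
    (rowSums(gm$a1[, cols, drop = FALSE] == 1L) +
     rowSums(gm$a2[, cols, drop = FALSE] == 1L)) / (2L * length(cols))
  }
  pA <- freq_alt(colsA); pB <- freq_alt(colsB)
  if (min_freq >= 1) {
    keep <- eligible & ((pA == 0 & pB == 1) | (pA == 1 & pB == 0))
    a_idx <- ifelse(pA == 1, 1L, 0L)       # A-specific allele index
  } else {
    majA <- pA >= 0.5; majB <- pB >= 0.5   # TRUE = ALT majority
    fixA <- pmax(pA, 1 - pA) >= min_freq
    fixB <- pmax(pB, 1 - pB) >= min_freq
    keep <- eligible & fixA & fixB & (majA != majB)
    a_idx <- ifelse(majA, 1L, 0L)
  }
  keep[is.na(keep)] <- FALSE
  out <- data.frame(
    chrom = gm$chrom[keep], pos = gm$pos[keep],
    allele_A = allele_base(subset_sites(gm, keep), a_idx[keep]),
    allele_a = allele_base(subset_sites(gm, keep), 1L - a_idx[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "panelA") <- panelA$name
  attr(out, "panelB") <- panelB$name
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

#' Classify the focal individual at diagnostic sites
#'
#' Labels each diagnostic site by the focal genotype: `AA` (homozygous for
#' the parent-A-specific allele), `Aa` (heterozygous), `aa` (homozygous for
#' the parent-B-specific allele). A genotype carrying an allele that is
#' neither diagnostic allele is put in a separate `other` bucket and
#' excluded from the three-class counts rather than forced into them.
#'
#' @param siteset A [find_discriminatory_sites()] result (or a data.frame
#'   with `chrom`, `pos`, `allele_A`, `allele_a`).
#' @param gm The [genotype_matrix()] holding the focal sample.
#' @param focal Focal sample id.
#' @param anchored_chroms Optional character vector naming the anchored
#'   chromosomes; sites on other sequences are aggregated under an
#'   `unanchored` scope in the class table. `NULL` treats every sequence as
#'   its own scope.
#' @return List of class `focal_classification`: `classes` (per-site
#'   data.frame `chrom`, `pos`, `class`, in site order) and `table` (the
#'   per-scope [genotype_class_table()]).
#' @export
classify_focal_genotypes <- function(siteset, gm, focal,
                                     anchored_chroms = NULL) {
  stopifnot(all(c("chrom", "pos", "allele_A", "allele_a") %in% names(siteset)))
  col <- sample_cols(gm, focal)
  idx <- match(paste(siteset$chrom, siteset$pos),
               paste(gm$chrom, gm$pos))
  if (anyNA(idx))
    stop("diagnostic site(s) absent from the genotype matrix")
  a1 <- gm$a1[idx, col]; a2 <- gm$a2[idx, col]
  if (anyNA(a1))
    stop("missing focal genotype at ", sum(is.na(a1)),
         " diagnostic site(s); pre-filter the matrix for completeness")
  b1 <- allele_base_at(gm, idx, a1)
  b2 <- allele_base_at(gm, idx, a2)
  A <- siteset$allele_A; a <- siteset$allele_a
  cls <- rep("other", length(idx))
  cls[b1 == A & b2 == A] <- "AA"
  cls[b1 == a & b2 == a] <- "aa"
  cls[(b1 == A & b2 == a) | (b1 == a & b2 == A)] <- "Aa"
  classes <- data.frame(chrom = siteset$chrom, pos = siteset$pos,
                        class = factor(cls, levels = c("AA", "Aa", "aa", "other")),
                        stringsAsFactors = FALSE)
  structure(
    list(classes = classes,
         table = genotype_class_table(classes, anchored_chroms)),
    class = "focal_classification"
  )
}

# base of allele index at arbitrary matrix rows
allele_base_at <- function(gm, rows, idx) {
  first_alt <- sub(",.*$", "", gm$alt[rows])
  out <- ifelse(idx == 0L, gm$ref[rows],
                ifelse(idx == 1L, first_alt, NA_character_))
  hi <- which(!is.na(idx) & idx >= 2L)
  if (length(hi)) {
    alts <- strsplit(gm$alt[rows[hi]], ",", fixed = TRUE)
    out[hi] <- mapply(function(al, i) al[i], alts, idx[hi])  # allele k = ALT k
  }
  out
}

#' Tabulate genotype classes per scope
#'
#' Counts `N_AA`, `N_Aa`, `N_aa` (and `N_other`) per chromosome, optionally
#' for an aggregated `unanchored` scope, and genome-wide (`All`). Fractions
#' are over the three diagnostic classes; the `All` row equals the sum of
#' all per-scope rows.
#'
#' @param classes Per-site class data.frame (`chrom`, `pos`, `class`).
#' @param anchored_chroms Optional anchored-chromosome names; see
#'   [classify_focal_genotypes()].
#' @return A `data.frame` of class `genotype_class_table`.
#' @export
genotype_class_table <- function(classes, anchored_chroms = NULL) {
  scope <- as.character(classes$chrom)
  if (!is.null(anchored_chroms))
    scope[!scope %in% anchored_chroms] <- "unanchored"
  scope_levels <- unique(scope)
  if ("unanchored" %in% scope_levels)  # keep the aggregate row last
    scope_levels <- c(setdiff(scope_levels, "unanchored"), "unanchored")
  tab <- table(factor(scope, levels = scope_levels), classes$class)
  tab <- rbind(tab, All = colSums(tab))
  out <- data.frame(
    scope = rownames(tab),
    N_AA = as.integer(tab[, "AA"]), N_Aa = as.integer(tab[, "Aa"]),
    N_aa = as.integer(tab[, "aa"]), N_other = as.integer(tab[, "other"]),
    stringsAsFactors = FALSE
  )
  tot <- out$N_AA + out$N_Aa + out$N_aa
  out$frac_AA <- ifelse(tot > 0, out$N_AA / tot, NA_real_)
  out$frac_Aa <- ifelse(tot > 0, out$N_Aa / tot, NA_real_)
  out$frac_aa <- ifelse(tot > 0, out$N_aa / tot, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("genotype_class_table", "data.frame")
  out
}

#' Per-chromosome heterozygosity summary
#'
#' Rate of heterozygous (`Aa`) calls among the three diagnostic classes for
#' each chromosome. A chromosome with no classified site gets `NA`, not 0.
#'
#' @param classes Per-site class data.frame (from
#'   [classify_focal_genotypes()]`$classes`).
#' @return `data.frame` with `chrom`, `n_sites` (three-class total) and
#'   `het_rate`, in chromosome order of appearance.
#' @export
per_chromosome_summary <- function(classes) {
  chroms <- unique(as.character(classes$chrom))
  rows <- lapply(chroms, function(ch) {
    cl <- classes$class[classes$chrom == ch]
    n3 <- sum(cl %in% c("AA", "Aa", "aa"))
    data.frame(chrom = ch, n_sites = n3,
               het_rate = if (n3 > 0) sum(cl == "Aa") / n3 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract the genome-wide class counts
#'
#' Convenience accessor returning `c(N_AA, N_Aa, N_aa)` from a
#' classification, the input shape expected by the backcross-likelihood
#' stage.
#'
#' @param x A `focal_classification` or `genotype_class_table`.
#' @return Named integer vector `c(N_AA=, N_Aa=, N_aa=)`.
#' @export
class_counts <- function(x) {
  tab <- if (inherits(x, "focal_classification")) x$table else x
  all_row <- tab[tab$scope == "All", ]
  c(N_AA = all_row$N_AA, N_Aa = all_row$N_Aa, N_aa = all_row$N_aa)
}
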