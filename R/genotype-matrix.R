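#' Define a sample panel
#'
#' A panel groups the samples of one population/species role: the two
#' parental species panels, the focal (putative hybrid) individual, or an
#' outgroup. Diversity and diagnostic-site stages require diploid panels.
#'
#' @param name Panel label, e.g. `"parentA"`, `"parentB"`, `"focal"`.
#' @param sample_ids Character vector of sample identifiers (non-empty,
#'   unique).
#' @param ploidy Integer ploidy; all analysis stages assume 2.
#' @return An object of class `sample_panel`.
#' @export
sample_panel <- function(name, sample_ids, ploidy = 2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 0L)
    stop("panel '", name, "': sample_ids must be non-empty")
  if (anyDuplicated(sample_ids))
    stop("panel '", name, "': duplicated sample ids")
  structure(
    list(name = name, sample_ids = sample_ids, ploidy = as.integer(ploidy)),
    class = "sample_panel"
  )
}

#' @export
print.sample_panel <- function(x, ...) {
  cat("<sample_panel> ", x$name, ": ", length(x$sample_ids),
      " sample(s), ploidy ", x$ploidy, "\n", sep = "")
  invisible(x)
}

#' Construct a genotype matrix
#'
#' The central container of the pipeline: unphased diploid genotype calls at
#' `S` variant sites for `N` samples, plus panel assignments. Genotypes are
#' stored as two allele-index matrices (`0` = REF, `1` = first ALT, ...),
#' with the pair sorted so that `a1 <= a2` (phase is never used) and `NA`
#' marking missing calls.
#'
#' @param chrom Character vector of sequence names, length `S`.
#' @param pos Integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref Character vector of REF alleles.
#' @param alt Character vector of ALT alleles (comma-joined if multiallelic).
#' @param a1,a2 Integer `S x N` matrices of allele indices (`NA` = missing).
#' @param samples Character vector of `N` sample ids.
#' @param panels Named list of [sample_panel()] objects; every panel sample
#'   must be present in `samples`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, a1, a2, samples,
                            panels = list()) {
  S <- length(chrom)
  N <- length(samples)
  pos <- as.integer(pos)
  a1 <- matrix(as.integer(a1), nrow = S, ncol = N)
  a2 <- matrix(as.integer(a2), nrow = S, ncol = N)
  stopifnot(
    length(pos) == S, length(ref) == S, length(alt) == S,
    nrow(a1) == S, ncol(a1) == N, nrow(a2) == S, ncol(a2) == N
  )
  if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  ord_ok <- tapply(pos, factor(chrom, levels = unique(chrom)),
                   function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok)))
    stop("site positions must be strictly increasing within each chromosome")
  # enforce unordered representation
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  colnames(a1) <- colnames(a2) <- samples
  if (length(panels)) {
    panels <- check_panels(panels, samples)
  }
  structure(
    list(chrom = as.character(chrom), pos = pos, ref = as.character(ref),
         alt = as.character(alt), a1 = a1, a2 = a2,
         samples = as.character(samples), panels = panels),
    class = "genotype_matrix"
  )
}

check_panels <- function(panels, samples) {
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- vapply(panels, `[[`, "", "name")
  all_ids <- unlist(lapply(panels, `[[`, "sample_ids"))
  if (anyDuplicated(all_ids))
    stop("sample id(s) assigned to more than one panel: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  missing_ids <- setdiff(all_ids, samples)
  if (length(missing_ids))
    stop("panel sample id(s) not present among samples: ",
         paste(missing_ids, collapse = ", "))
  panels
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_sites(x), " sites x ", length(x$samples),
      " samples (", length(unique(x$chrom)), " sequence(s))\n", sep = "")
  if (length(x$panels))
    cat("  panels:",
        paste(sprintf("%s[%d]", names(x$panels),
                      vapply(x$panels, function(p) length(p$sample_ids), 0L)),
              collapse = " "), "\n")
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer site count.
#' @export
n_sites <- function(gm) length(gm$chrom)

#' Resolve a panel by name
#'
#' @param gm A [genotype_matrix()].
#' @param panel A `sample_panel`, a panel name present in `gm$panels`, or a
#'   character vector of sample ids.
#' @return A `sample_panel`.
#' @export
get_panel <- function(gm, panel) {
  if (inherits(panel, "sample_panel")) return(panel)
  if (is.character(panel) && length(panel) == 1L && panel %in% names(gm$panels))
    return(gm$panels[[panel]])
  if (is.character(panel) && all(panel %in% gm$samples))
    return(sample_panel("adhoc", panel))
  stop("unknown panel: ", paste(panel, collapse = ", "))
}

subset_sites <- function(gm, keep) {
  genotype_matrix(gm$chrom[keep], gm$pos[keep], gm$ref[keep], gm$alt[keep],
                  gm$a1[keep, , drop = FALSE], gm$a2[keep, , drop = FALSE],
                  gm$samples, gm$panels)
}

sample_cols <- function(gm, sample_ids) {
  idx <- match(sample_ids, gm$samples)
  if (anyNA(idx))
    stop("sample id(s) not in matrix: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  idx
}

is_biallelic_snp <- function(gm) {
  nchar(gm$ref) == 1L & nchar(gm$alt) == 1L & gm$alt != "." & gm$ref != "."
}

# Map allele indices to bases; valid rows only (biallelic handled fast,
# higher indices resolved through the ALT list).
allele_base <- function(gm, idx) {
  out <- rep(NA_character_, length(idx))
  out[!is.na(idx) & idx == 0L] <- gm$ref[!is.na(idx) & idx == 0L]
  one <- !is.na(idx) & idx == 1L
  if (any(one)) {
    first_alt <- sub(",.*$", "", gm$alt)
    out[one] <- first_alt[one]
  }
  hi <- !is.na(idx) & idx >= 2L
  if (any(hi)) {
    alts <- strsplit(gm$alt[hi], ",", fixed = TRUE)
    out[hi] <- mapply(function(a, i) a[i], alts, idx[hi])  # allele k = ALT k
  }
  out
}
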