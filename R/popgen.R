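#' Nucleotide diversity of a panel
#'
#' Per-site pairwise nucleotide diversity among the `n = 2 x (diploid
#' individuals)` chromosomes of a panel,
#' \deqn{\hat\theta_\pi = \frac{1}{\bar L}\,\frac{n}{n-1}\,
#'   \frac{\sum_{i<j} k_{ij}}{n(n-1)/2},}
#' where \eqn{k_{ij}} is the number of nucleotide differences between
#' haplotype sequences i and j and \eqn{\bar L} is the average number of
#' mapped (callable) sites per panel sample. The pairwise sum is computed
#' per site from allele counts — for a biallelic site with minor-allele
#' count `c` among `n` alleles, the contribution is `c * (n - c)` — so the
#' estimator is phase-free and identical to explicit haplotype-pair
#' enumeration.
#'
#' `L_bar` depends on upstream coverage masks the pipeline does not see, so
#' it is always an explicit input, never inferred from the SNP set.
#'
#' @param gm A [genotype_matrix()] pre-filtered to biallelic SNPs with no
#'   missing genotype within the panel (see [filter_biallelic_complete()]).
#' @param panel Panel name, `sample_panel`, or sample-id vector (>= 2
#'   diploid samples).
#' @param L_bar Average number of mapped sites per sample (> 0).
#' @return List of class `diversity_result`: `theta_pi`, `n_chromosomes`,
#'   `L_bar`, `n_snps_used`.
#' @export
nucleotide_diversity <- function(gm, panel, L_bar) {
  if (!is.numeric(L_bar) || length(L_bar) != 1L || L_bar <= 0)
    stop("L_bar must be a positive number")
  panel <- get_panel(gm, panel)
  if (length(panel$sample_ids) < 2L)
    stop("nucleotide diversity requires a panel of >= 2 samples")
  cols <- sample_cols(gm, panel$sample_ids)
  a1 <- gm$a1[, cols, drop = FALSE]
  a2 <- gm$a2[, cols, drop = FALSE]
  if (anyNA(a1))
    stop("panel has missing genotypes; run filter_biallelic_complete() first")
  n <- 2L * length(cols)
  alt_count <- rowSums(a1 == 1L) + rowSums(a2 == 1L)
  k_sum <- sum(alt_count * (n - alt_count))   # sum over i<j of k_ij
  theta <- (1 / L_bar) * (n / (n - 1)) * (k_sum / (n * (n - 1) / 2))
  structure(
    list(theta_pi = theta, n_chromosomes = n, L_bar = L_bar,
         n_snps_used = n_sites(gm)),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result> theta_pi =", format(x$theta_pi, digits = 6),
      " (n =", x$n_chromosomes, "chromosomes, L_bar =", x$L_bar,
      ",", x$n_snps_used, "SNPs)\n")
  invisible(x)
}

#' Genome-averaged Wright's FST between two panels
#'
#' Per biallelic site, \eqn{F_{ST} = (H_T - H_S)/H_T} with
#' \eqn{H_S} the unweighted mean of the within-panel expected
#' heterozygosities \eqn{2p(1-p)} and \eqn{H_T = 2\bar p(1-\bar p)} at the
#' pooled frequency \eqn{\bar p = (p_A+p_B)/2} (equal panel weights).
#' Monomorphic sites (\eqn{H_T = 0}) are skipped. The genome average is by
#' default the arithmetic mean of per-site ratios; `average =
#' "ratio_of_means"` instead divides the mean of \eqn{H_T - H_S} by the
#' mean of \eqn{H_T} (a common alternative, useful as a sensitivity check).
#'
#' Allele frequencies are plain allele counts over `2 x panel size`
#' chromosomes, with no small-sample correction.
#'
#' @param gm A [genotype_matrix()] pre-filtered to biallelic SNPs with no
#'   missing genotype in either panel.
#' @param panelA,panelB Panels of >= 2 samples each.
#' @param average `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return List of class `fst_result`: `fst_mean`, `n_sites`, `average`.
#' @export
pairwise_fst <- function(gm, panelA, panelB,
                         average = c("mean_of_ratios", "ratio_of_means")) {
  average <- match.arg(average)
  panelA <- get_panel(gm, panelA); panelB <- get_panel(gm, panelB)
  if (length(panelA$sample_ids) < 2L || length(panelB$sample_ids) < 2L)
    stop("FST requires >= 2 samples in each panel")
  ps <- lapply(list(panelA, panelB), function(p) {
    cols <- sample_cols(gm, p$sample_ids)
    a1 <- gm$a1[, cols, drop = FALSE]; a2 <- gm$a2[, cols, drop = FALSE]
    if (anyNA(a1))
      stop("panel '", p$name, "' has missing genotypes; filter first")
    (rowSums(a1 == 1L) + rowSums(a2 == 1L)) / (2L * length(cols))
  })
  pA <- ps[[1]]; pB <- ps[[2]]
  hS <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
  pbar <- (pA + pB) / 2
  hT <- 2 * pbar * (1 - pbar)
  ok <- hT > 0
  if (!any(ok))
    stop("FST undefined: no site is polymorphic in the pooled panels")
  fst_mean <- switch(average,
    mean_of_ratios = mean((hT[ok] - hS[ok]) / hT[ok]),
    ratio_of_means = (mean(hT[ok]) - mean(hS[ok])) / mean(hT[ok])
  )
  structure(
    list(fst_mean = fst_mean, n_sites = sum(ok), average = average),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> mean FST =", format(x$fst_mean, digits = 4),
      "over", x$n_sites, "sites (", x$average, ")\n")
  invisible(x)
}
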