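pA <- c("a1", "a2", "a3"); pB <- c("b1", "b2", "b3")
seven <- c(pA, "foc", pB)

# 6-site toy: 3 fixed-opposite, 1 shared-fixed, 1 polymorphic in A,
# 1 polymorphic in B
toy_seven <- function() {
  toy_gm(rbind(
    c("0/0", "0/0", "0/0", "0/1", "1/1", "1/1", "1/1"),  # diagnostic
    c("1/1", "1/1", "1/1", "0/1", "0/0", "0/0", "0/0"),  # diagnostic (A=ALT)
    c("0/0", "0/0", "0/0", "0/0", "1/1", "1/1", "1/1"),  # diagnostic
    c("1/1", "1/1", "1/1", "1/1", "1/1", "1/1", "1/1"),  # shared-fixed
    c("0/0", "0/1", "0/0", "0/0", "1/1", "1/1", "1/1"),  # polymorphic in A
    c("0/0", "0/0", "0/0", "0/0", "1/1", "0/1", "1/1")   # polymorphic in B
  ),
  ref = c("C", "G", "A", "T", "C", "A"),
  alt = c("T", "A", "G", "C", "T", "G"),
  samples = seven,
  panels = list(parentA = sample_panel("parentA", pA),
                parentB = sample_panel("parentB", pB),
                focal = sample_panel("focal", "foc")))
}

test_that("discriminatory-site finder keeps exactly the fixed-opposite sites", {
  gm <- toy_seven()
  d <- find_discriminatory_sites(gm, "parentA", "parentB")
  expect_equal(nrow(d), 3L)
  expect_equal(d$pos, c(100L, 200L, 300L))
  expect_equal(d$allele_A, c("C", "A", "A"))
  expect_equal(d$allele_a, c("T", "G", "G"))
  expect_error(
    find_discriminatory_sites(gm, sample_panel("x", c("a1", "b1")),
                              "parentB"),
    "share")
})

test_that("swapping the parental panels swaps AA and aa classes", {
  gm <- toy_seven()
  d1 <- find_discriminatory_sites(gm, "parentA", "parentB")
  d2 <- find_discriminatory_sites(gm, "parentB", "parentA")
  expect_equal(d2$allele_A, d1$allele_a)
  expect_equal(d2$allele_a, d1$allele_A)
  c1 <- classify_focal_genotypes(d1, gm, "foc")$classes$class
  c2 <- classify_focal_genotypes(d2, gm, "foc")$classes$class
  map <- c(AA = "aa", Aa = "Aa", aa = "AA", other = "other")
  expect_equal(as.character(c2), unname(map[as.character(c1)]))
})

test_that("focal classification labels AA/Aa/aa and buckets third alleles", {
  gm <- toy_seven()
  d <- find_discriminatory_sites(gm, "parentA", "parentB")
  cls <- classify_focal_genotypes(d, gm, "foc")
  expect_equal(as.character(cls$classes$class), c("Aa", "Aa", "AA"))
  expect_equal(unname(class_counts(cls)), c(1L, 2L, 0L))

  # a focal genotype carrying a non-diagnostic allele goes to "other"
  gm2 <- toy_gm(rbind(c("0/0", "0/0", "0/0", "1/2", "1/1", "1/1", "1/1")),
                ref = "C", alt = "T,G", samples = seven,
                panels = gm$panels)
  d2 <- data.frame(chrom = "chr01", pos = 100L, allele_A = "C",
                   allele_a = "T", stringsAsFactors = FALSE)
  cls2 <- classify_focal_genotypes(d2, gm2, "foc")
  expect_equal(as.character(cls2$classes$class), "other")
  expect_equal(cls2$table$N_other[cls2$table$scope == "All"], 1L)

  # missing focal genotype is a data error
  gm3 <- toy_gm(rbind(c("0/0", "0/0", "0/0", "./.", "1/1", "1/1", "1/1")),
                ref = "C", alt = "T", samples = seven, panels = gm$panels)
  expect_error(classify_focal_genotypes(d2, gm3, "foc"), "missing focal")
})

test_that("class-table fractions sum to one and All equals the scope sum", {
  classes <- data.frame(
    chrom = c(rep("chr01", 4), rep("chr02", 3), rep("ctg0007", 2)),
    pos = c((1:4) * 10L, (1:3) * 10L, (1:2) * 10L),
    class = factor(c("Aa", "Aa", "AA", "Aa", "AA", "aa", "AA", "Aa", "AA"),
                   levels = c("AA", "Aa", "aa", "other")),
    stringsAsFactors = FALSE)
  tab <- genotype_class_table(classes,
                              anchored_chroms = c("chr01", "chr02"))
  expect_setequal(tab$scope, c("chr01", "chr02", "unanchored", "All"))
  sums <- rowSums(tab[, c("frac_AA", "frac_Aa", "frac_aa")])
  expect_true(all(abs(sums - 1) < 1e-12))
  per_scope <- tab[tab$scope != "All", c("N_AA", "N_Aa", "N_aa")]
  expect_equal(colSums(per_scope),
               unlist(tab[tab$scope == "All", c("N_AA", "N_Aa", "N_aa")]))
})

test_that("per-chromosome heterozygosity matches hand computation", {
  classes <- data.frame(
    chrom = c(rep("chr01", 4), rep("chr02", 4)),
    pos = rep((1:4) * 10L, 2),
    class = factor(c("Aa", "Aa", "AA", "Aa", "aa", "AA", "AA", "Aa"),
                   levels = c("AA", "Aa", "aa", "other")))
  s <- per_chromosome_summary(classes)
  expect_equal(s$het_rate, c(0.75, 0.25))
  # all-AA chromosome has rate 0, not NA
  s2 <- per_chromosome_summary(data.frame(
    chrom = "chr03", pos = 10L,
    class = factor("AA", levels = c("AA", "Aa", "aa", "other"))))
  expect_equal(s2$het_rate, 0)
  # a chromosome whose sites were all bucketed as "other" is undefined
  s3 <- per_chromosome_summary(data.frame(
    chrom = "chr04", pos = 10L,
    class = factor("other", levels = c("AA", "Aa", "aa", "other"))))
  expect_true(is.na(s3$het_rate))
})

test_that("finder recovers the simulated truth exactly and BC1F1 fractions follow the pedigree", {
  cfg <- sim_config(n_chromosomes = 5, sites_per_chromosome = 2000,
                    fixed_diff_fraction = 0.5,
                    within_pop_het_fraction = 0.3,
                    error_rate = 0, seed = 31)
  sim <- simulate_hybrid_dataset(cfg, "BC1F1")
  gm <- filter_biallelic_complete(sim$matrix)
  d <- find_discriminatory_sites(gm, "parentA", "parentB")
  expect_equal(d$pos, sim$truth$diagnostic_sites$pos)
  expect_equal(d$chrom, sim$truth$diagnostic_sites$chrom)
  expect_equal(d$allele_A, sim$truth$diagnostic_sites$allele_A)

  cls <- classify_focal_genotypes(d, gm, "focal")
  counts <- class_counts(cls)
  n <- sum(counts)
  # sites are linked: the heterozygous fraction fluctuates at the level of
  # ancestry blocks (~2 per chromosome), so the band scales with the
  # chromosome count, not the site count
  expect_lt(abs(counts[["N_Aa"]] / n - 0.5),
            3 * sqrt(0.25 / cfg$n_chromosomes))
  expect_equal(counts[["N_aa"]], 0L)
})

test_that("frequency-threshold mode admits nearly fixed sites in larger panels", {
  pa <- sprintf("a%d", 1:10); pb <- sprintf("b%d", 1:10)
  gt <- rbind(c(rep("0/0", 9), "0/1", rep("1/1", 10)))
  gm <- toy_gm(gt, ref = "C", alt = "T", samples = c(pa, pb))
  strict <- find_discriminatory_sites(gm, pa, pb)
  relaxed <- find_discriminatory_sites(gm, pa, pb, min_freq = 0.95)
  expect_equal(nrow(strict), 0L)
  expect_equal(nrow(relaxed), 1L)
  expect_equal(relaxed$allele_A, "C")
})
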