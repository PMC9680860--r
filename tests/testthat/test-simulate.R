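test_that("config validation rejects inconsistent fractions", {
  expect_error(sim_config(fixed_diff_fraction = 0.7,
                          within_pop_het_fraction = 0.5), "fractions")
  expect_error(sim_config(map_length = -1), "map_length")
  expect_error(sim_config(error_rate = 1), "error_rate")
})

test_that("simulation is deterministic: same seed, byte-identical VCF", {
  cfg <- sim_config(n_chromosomes = 2, sites_per_chromosome = 150, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulated_vcf(simulate_hybrid_dataset(cfg, "BC1F1"), d1)
  write_simulated_vcf(simulate_hybrid_dataset(cfg, "BC1F1"), d2)
  expect_identical(readLines(file.path(d1, "sim.vcf")),
                   readLines(file.path(d2, "sim.vcf")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  # different seed, different data
  cfg2 <- sim_config(n_chromosomes = 2, sites_per_chromosome = 150, seed = 6)
  d3 <- tempfile()
  write_simulated_vcf(simulate_hybrid_dataset(cfg2, "BC1F1"), d3)
  expect_false(identical(readLines(file.path(d1, "sim.vcf")),
                         readLines(file.path(d3, "sim.vcf"))))
})

test_that("site-role fractions control what the diagnostic finder can recover", {
  # all fixed-opposite: every site is recovered
  cfg <- sim_config(n_chromosomes = 1, sites_per_chromosome = 100,
                    fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                    error_rate = 0, seed = 2)
  sim <- simulate_hybrid_dataset(cfg, "BC1F1")
  d <- find_discriminatory_sites(sim$matrix, "parentA", "parentB")
  expect_equal(nrow(d), 100L)
  # all within-population polymorphism: nothing is diagnostic
  cfg0 <- sim_config(n_chromosomes = 1, sites_per_chromosome = 100,
                     fixed_diff_fraction = 0, within_pop_het_fraction = 1,
                     error_rate = 0, seed = 2)
  sim0 <- simulate_hybrid_dataset(cfg0, "BC1F1")
  d0 <- find_discriminatory_sites(sim0$matrix, "parentA", "parentB")
  expect_equal(nrow(d0), 0L)
})

test_that("meiosis follows the Haldane model", {
  cfg <- sim_config(n_chromosomes = 1, sites_per_chromosome = 50,
                    map_length = 0, seed = 3)
  set.seed(3)
  sites <- hyborigin:::simulate_sites(cfg)
  ind <- hyborigin:::draw_individual(sites, "A", cfg)
  # map length 0: the gamete is one parental haplotype, unrecombined
  g <- meiosis(ind, cfg)
  expect_length(g[[1]]$breaks, 0L)
  expect_true(identical(g[[1]]$alleles, ind$haps[[1]]$alleles[1, ]) ||
              identical(g[[1]]$alleles, ind$haps[[1]]$alleles[2, ]))
  # crossover counts are Poisson(map_length): moment check at L = 2
  cfg2 <- sim_config(n_chromosomes = 1, sites_per_chromosome = 10,
                     map_length = 2, seed = 3)
  set.seed(31)
  sites2 <- hyborigin:::simulate_sites(cfg2)
  ind2 <- hyborigin:::draw_individual(sites2, "A", cfg2)
  nx <- replicate(10000, length(meiosis(ind2, cfg2)[[1]]$breaks))
  expect_lt(abs(mean(nx) - 2), 3 * sqrt(2 / 10000))
  # F1 gamete at 1 Morgan: mean ancestry blocks ~ breakpoints + 1 ~ 2
  cfg3 <- sim_config(n_chromosomes = 1, sites_per_chromosome = 200,
                     fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                     map_length = 1, seed = 3)
  set.seed(7)
  sites3 <- hyborigin:::simulate_sites(cfg3)
  f1 <- hyborigin:::cross(hyborigin:::draw_individual(sites3, "B", cfg3),
                          hyborigin:::draw_individual(sites3, "A", cfg3),
                          cfg3)
  blocks <- replicate(2000, length(rle(meiosis(f1, cfg3)[[1]]$anc)$lengths))
  expect_lt(abs(mean(blocks) - 2), 3 * sqrt(1 / 2000) + 0.02)
})

test_that("pedigrees produce the expected heterozygosity and organelle lineage", {
  # F1 with no error: heterozygous at every diagnostic site
  cfgF1 <- sim_config(n_chromosomes = 2, sites_per_chromosome = 300,
                      fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                      error_rate = 0, seed = 13)
  simF1 <- simulate_hybrid_dataset(cfgF1, "F1")
  expect_true(all(simF1$truth$classes$class == "Aa"))
  expect_equal(simF1$truth$generation, 0L)
  # BC1F1: heterozygous fraction 1/2 within binomial noise; no aa class
  cfg1 <- sim_config(n_chromosomes = 10, sites_per_chromosome = 1000,
                     fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                     error_rate = 0, seed = 13)
  sim1 <- simulate_hybrid_dataset(cfg1, "BC1F1")
  het <- mean(sim1$truth$classes$class == "Aa")
  # sites within a chromosome are linked; noise is dominated by the ~2
  # independent ancestry blocks per chromosome, not by site count
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10) )
  expect_equal(sum(sim1$truth$classes$class == "aa"), 0L)
  # organelle follows the maternal line
  expect_equal(sim1$truth$organelle, "B")
  simA <- simulate_hybrid_dataset(cfg1, "BC1F1", mother_species = "A")
  expect_equal(simA$truth$organelle, "A")
  expect_error(hyborigin:::parse_pedigree("BCxF1"), "pedigree")
  expect_equal(hyborigin:::parse_pedigree("BC3F1"), 3L)
})

test_that("genotype error mechanisms behave as documented", {
  cfg <- sim_config(n_chromosomes = 10, sites_per_chromosome = 3000,
                    fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                    error_rate = 0, seed = 23)
  sim <- simulate_hybrid_dataset(cfg, "BC1F1")
  classify <- function(gm) {
    d <- sim$truth$diagnostic_sites
    class_counts(classify_focal_genotypes(d, gm, "focal"))
  }
  # rate 0 leaves the matrix untouched
  expect_identical(apply_genotype_error(sim$matrix, "focal", 0), sim$matrix)
  # rate 1, uniform: class fractions converge to 1/3 each
  set.seed(1)
  g1 <- apply_genotype_error(sim$matrix, "focal", 1)
  fr <- classify(g1) / 30000
  expect_true(all(abs(fr - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 30000)))
  # uniform replacement maps rate e to an aa-class mass of ~ e/3
  set.seed(2)
  g2 <- apply_genotype_error(sim$matrix, "focal", 0.06)
  fr2 <- classify(g2) / 30000
  expect_lt(abs(fr2[["N_aa"]] - 0.02), 3 * sqrt(0.02 * 0.98 / 30000))
  # aa_flip mode realizes the model p_error exactly (rate = aa mass)
  set.seed(3)
  g3 <- apply_genotype_error(sim$matrix, "focal", 0.05, mode = "aa_flip",
                             diag_sites = sim$truth$diagnostic_sites)
  fr3 <- classify(g3) / 30000
  expect_lt(abs(fr3[["N_aa"]] - 0.05), 3 * sqrt(0.05 * 0.95 / 30000))
})

test_that("uniform-error class fractions match the adjusted BC1F1 expectation", {
  # for g = 1 the mapping p_error = rate/3 is exact in expectation
  cfg <- sim_config(n_chromosomes = 10, sites_per_chromosome = 3000,
                    fixed_diff_fraction = 1, within_pop_het_fraction = 0,
                    error_rate = 0.06, seed = 29)
  sim <- simulate_hybrid_dataset(cfg, "BC1F1")
  gm <- filter_biallelic_complete(sim$matrix)
  d <- find_discriminatory_sites(gm, "parentA", "parentB")
  cls <- class_counts(classify_focal_genotypes(d, gm, "focal"))
  n <- sum(cls)
  q <- expected_frequencies(1, 0.06 / 3)
  # AA/Aa split is linked within chromosomes (block noise ~ 10 chromosomes);
  # the aa mass is independent per site
  expect_lt(abs(cls[["N_Aa"]] / n - q[["q_Aa"]]), 3 * sqrt(0.25 / 10))
  expect_lt(abs(cls[["N_aa"]] / n - q[["q_aa"]]),
            3 * sqrt(q[["q_aa"]] / n))
})

test_that("simulated VCF bundle reloads through the standard readers", {
  cfg <- sim_config(n_chromosomes = 2, sites_per_chromosome = 120, seed = 37)
  sim <- simulate_hybrid_dataset(cfg, "BC2F1")
  dir <- tempfile()
  paths <- write_simulated_vcf(sim, dir)
  expect_true(all(file.exists(paths)))
  gm <- read_vcf(paths[["vcf"]], paths[["panels"]])
  expect_equal(length(gm$samples), cfg$n_panel_a + cfg$n_panel_b + 1L)
  expect_identical(unname(gm$a1), unname(sim$matrix$a1))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$generation, 2L)
  expect_equal(truth$seed, 37L)
  # the truth sidecar's diagnostic list equals the finder's output
  d <- find_discriminatory_sites(filter_biallelic_complete(gm),
                                 "parentA", "parentB")
  expect_equal(d$pos, truth$diagnostic_sites$pos)
  expect_equal(d$allele_A, truth$diagnostic_sites$allele_A)
  # header records provenance
  hdr <- readLines(paths[["vcf"]], n = 10)
  expect_true(any(grepl("##simulation_seed=37", hdr)))
  expect_true(any(grepl("##simulation_pedigree=BC2F1", hdr)))
})
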