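#' Configuration for the hybrid-pedigree simulator
#'
#' Defines two diverged diploid species populations (A = the recurrent
#' backcross parent, B = the donor), a marker landscape, and the pedigree
#' machinery: each chromosome carries `sites_per_chromosome` evenly spaced
#' SNPs; a fraction `fixed_diff_fraction` of sites is fixed for opposite
#' alleles between the species (the true diagnostic sites), a fraction
#' `within_pop_het_fraction` is polymorphic within one species (alternate
#' allele frequency drawn uniform(0.1, 0.9)), and the remainder is
#' monomorphic. Meiosis follows the Haldane model: crossover count per
#' chromosome is Poisson with mean `map_length` Morgans, breakpoints
#' uniform on the genetic map, no interference. Genotype error replaces a
#' focal call with probability `error_rate`.
#'
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param sites_per_chromosome SNPs per chromosome (default 2000).
#' @param map_length Genetic map length per chromosome in Morgans
#'   (default 1).
#' @param fixed_diff_fraction Proportion of sites fixed-opposite between
#'   species (default 0.6).
#' @param within_pop_het_fraction Proportion of sites polymorphic within
#'   one species (default 0.3); together with `fixed_diff_fraction` must
#'   not exceed 1.
#' @param n_panel_a,n_panel_b Diploid individuals per parental panel
#'   (default 3 and 3, the typical resequencing-panel size).
#' @param error_rate Per-site focal genotype error probability
#'   (default 0.02).
#' @param error_mode `"uniform"` (replacement by a uniformly random
#'   genotype among the three classes at the site; maps simulator error
#'   rate e to model `p_error` of about e/3) or `"aa_flip"` (the genotype
#'   becomes homozygous for the donor allele with probability e, so model
#'   `p_error` = e exactly).
#' @param seed Integer seed recorded in all outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10L, sites_per_chromosome = 2000L,
                       map_length = 1, fixed_diff_fraction = 0.6,
                       within_pop_het_fraction = 0.3,
                       n_panel_a = 3L, n_panel_b = 3L,
                       error_rate = 0.02,
                       error_mode = c("uniform", "aa_flip"),
                       seed = 1L) {
  error_mode <- match.arg(error_mode)
  if (fixed_diff_fraction < 0 || within_pop_het_fraction < 0 ||
      fixed_diff_fraction + within_pop_het_fraction > 1)
    stop("site-role fractions must be non-negative and sum to <= 1")
  if (map_length < 0) stop("map_length must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  stopifnot(n_chromosomes >= 1, sites_per_chromosome >= 1,
            n_panel_a >= 1, n_panel_b >= 1)
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         sites_per_chromosome = as.integer(sites_per_chromosome),
         map_length = map_length,
         fixed_diff_fraction = fixed_diff_fraction,
         within_pop_het_fraction = within_pop_het_fraction,
         n_panel_a = as.integer(n_panel_a), n_panel_b = as.integer(n_panel_b),
         error_rate = error_rate, error_mode = error_mode,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

BASES <- c("A", "C", "G", "T")

# Site landscape: roles get exact (rounded) counts, then shuffled positions.
simulate_sites <- function(config) {
  S <- config$sites_per_chromosome
  C <- config$n_chromosomes
  total <- S * C
  n_fixed <- round(config$fixed_diff_fraction * total)
  n_poly <- round(config$within_pop_het_fraction * total)
  n_poly <- min(n_poly, total - n_fixed)
  role <- sample(rep(c("fixed", "poly", "mono"),
                     c(n_fixed, n_poly, total - n_fixed - n_poly)))
  ref <- sample(BASES, total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
  freqA <- numeric(total); freqB <- numeric(total)
  fx <- role == "fixed"
  a_has_alt <- stats::runif(sum(fx)) < 0.5   # randomize fixation direction
  freqA[fx] <- as.numeric(a_has_alt)
  freqB[fx] <- as.numeric(!a_has_alt)
  pl <- role == "poly"
  in_a <- stats::runif(sum(pl)) < 0.5
  pf <- stats::runif(sum(pl), 0.1, 0.9)
  freqA[pl][in_a] <- pf[in_a]
  freqB[pl][!in_a] <- pf[!in_a]
  data.frame(
    chrom = rep(sprintf("chr%02d", seq_len(C)), each = S),
    pos = rep(1000L * seq_len(S), times = C),
    ref = ref, alt = unname(alt), role = role,
    freqA = freqA, freqB = freqB,
    stringsAsFactors = FALSE
  )
}

# Joint haplotype draw for a whole panel: (2 x n_ind) x sites matrix.
# With ascertain = TRUE, sites labelled polymorphic within this species are
# redrawn until the panel actually carries both alleles — the usual
# ascertainment of a SNP panel, and what makes the truth record exact.
draw_panel_haplotypes <- function(sites, species, n_ind, config,
                                  ascertain = TRUE) {
  freq <- if (species == "A") sites$freqA else sites$freqB
  n_h <- 2L * n_ind
  H <- matrix(stats::rbinom(n_h * nrow(sites), 1L, rep(freq, each = n_h)),
              nrow = n_h)
  if (ascertain) {
    own <- which(sites$role == "poly" & freq > 0)
    while (length(own)) {
      cs <- colSums(H[, own, drop = FALSE])
      own <- own[cs == 0L | cs == n_h]
      if (!length(own)) break
      H[, own] <- matrix(
        stats::rbinom(n_h * length(own), 1L, rep(freq[own], each = n_h)),
        nrow = n_h)
    }
  }
  H
}

haplotypes_to_individuals <- function(H, species, config) {
  S <- config$sites_per_chromosome
  anc_code <- if (species == "A") 1L else 2L
  lapply(seq_len(nrow(H) %/% 2L), function(i) {
    haps <- lapply(seq_len(config$n_chromosomes), function(ci) {
      cols <- ((ci - 1L) * S + 1L):(ci * S)
      list(alleles = H[c(2L * i - 1L, 2L * i), cols, drop = FALSE],
           anc = matrix(anc_code, 2L, S))
    })
    list(species = species, organelle = species, haps = haps)
  })
}

# A single pure-species diploid (unascertained draw) — used for pedigree
# founders and recurrent backcross parents.
draw_individual <- function(sites, species, config) {
  S <- config$sites_per_chromosome
  freq <- if (species == "A") sites$freqA else sites$freqB
  haps <- lapply(seq_len(config$n_chromosomes), function(ci) {
    f <- freq[((ci - 1L) * S + 1L):(ci * S)]
    alleles <- matrix(stats::rbinom(2L * S, 1L, rep(f, each = 2L)),
                      nrow = 2L)
    list(alleles = alleles,
         anc = matrix(if (species == "A") 1L else 2L, 2L, S))
  })
  list(species = species, organelle = species, haps = haps)
}

#' Simulate the two parental panels
#'
#' Draws `n_panel_a` species-A and `n_panel_b` species-B diploid
#' individuals from the configured site landscape, together with the truth
#' record of the simulated fixed-difference (diagnostic) sites.
#'
#' @param config A [sim_config()].
#' @param sites Optional pre-built site table (internal reuse); by default
#'   a fresh landscape is drawn from the current RNG state.
#' Sites labelled polymorphic within a species are drawn conditioned on the
#' panel actually carrying both alleles (SNP-panel ascertainment), so the
#' truth record's site roles describe the realized panels exactly and no
#' chance-fixed polymorphic site masquerades as a diagnostic site.
#'
#' @return List: `panelA`, `panelB` (lists of individuals), `sites` (site
#'   table) and `truth_diagnostic` (data.frame `chrom`, `pos`, `allele_A`,
#'   `allele_a` of the true fixed-opposite sites).
#' @export
simulate_parental_panels <- function(config, sites = NULL) {
  if (is.null(sites)) sites <- simulate_sites(config)
  panelA <- haplotypes_to_individuals(
    draw_panel_haplotypes(sites, "A", config$n_panel_a, config), "A", config)
  panelB <- haplotypes_to_individuals(
    draw_panel_haplotypes(sites, "B", config$n_panel_b, config), "B", config)
  fx <- sites$role == "fixed"
  truth <- data.frame(
    chrom = sites$chrom[fx], pos = sites$pos[fx],
    allele_A = ifelse(sites$freqA[fx] == 1, sites$alt[fx], sites$ref[fx]),
    allele_a = ifelse(sites$freqB[fx] == 1, sites$alt[fx], sites$ref[fx]),
    stringsAsFactors = FALSE
  )
  list(panelA = panelA, panelB = panelB, sites = sites,
       truth_diagnostic = truth)
}

#' One meiosis of a simulated individual (Haldane model)
#'
#' Draws a gamete for each chromosome: crossover count ~
#' Poisson(`map_length`), breakpoints uniform on the genetic map (sites are
#' evenly spaced on the map), the gamete alternating between the parent's
#' two haplotypes, starting haplotype chosen with probability 1/2. Allele
#' and ancestry labels travel together.
#'
#' @param ind A simulated individual.
#' @param config The [sim_config()] (supplies `map_length` and sizes).
#' @return List per chromosome: `alleles`, `anc` (site vectors) and
#'   `breaks` (crossover positions on (0,1) of the map).
#' @export
meiosis <- function(ind, config) {
  S <- config$sites_per_chromosome
  sitef <- (seq_len(S) - 0.5) / S
  lapply(ind$haps, function(h) {
    n_x <- stats::rpois(1L, config$map_length)
    br <- sort(stats::runif(n_x))
    start <- sample(1:2, 1L)
    hap <- (start + findInterval(sitef, br) - 1L) %% 2L + 1L
    ix <- cbind(hap, seq_len(S))
    list(alleles = h$alleles[ix], anc = h$anc[ix], breaks = br)
  })
}

cross <- function(mother, father, config) {
  gm <- meiosis(mother, config)
  gf <- meiosis(father, config)
  haps <- mapply(function(m, f) {
    list(alleles = rbind(m$alleles, f$alleles),
         anc = rbind(m$anc, f$anc))
  }, gm, gf, SIMPLIFY = FALSE)
  list(species = "hybrid", organelle = mother$organelle, haps = haps,
       maternal_breaks = lapply(gm, `[[`, "breaks"),
       paternal_breaks = lapply(gf, `[[`, "breaks"))
}

#' Build a hybrid individual by iterated crossing
#'
#' Expresses the pedigree: an interspecific F1 (mother from
#' `mother_species`, father from the other species), followed by `g`
#' backcrosses in which the hybrid is the mother and a freshly drawn
#' individual of the recurrent species (the F1's father's species) is the
#' father — so the organelle (maternal) lineage is `mother_species`
#' throughout, and each backcross uses a new wild recurrent parent.
#'
#' @param pedigree `"F1"`, `"BC1F1"`, `"BC2F1"`, any `"BC<g>F1"` label, or
#'   a non-negative integer backcross depth `g` (0 = F1).
#' @param config A [sim_config()].
#' @param sites Site table from [simulate_parental_panels()] (or `NULL` to
#'   draw a fresh landscape).
#' @param mother_species Species of the F1's mother, `"A"` or `"B"`
#'   (default `"B"`: the donor species is the female parent, the recurrent
#'   species the pollen donor).
#' @return List: `individual` (the focal hybrid), `generation` `g`,
#'   `organelle`, `breakpoints` (per generation), and `truth` — per-site
#'   donor-allele dosage (`dosage_B` in 0/1/2) with the true genotype class
#'   at every site.
#' @export
make_hybrid <- function(pedigree, config, sites = NULL,
                        mother_species = "B") {
  g <- parse_pedigree(pedigree)
  stopifnot(mother_species %in% c("A", "B"))
  if (is.null(sites)) sites <- simulate_sites(config)
  recurrent <- if (mother_species == "B") "A" else "B"
  mother <- draw_individual(sites, mother_species, config)
  father <- draw_individual(sites, recurrent, config)
  child <- cross(mother, father, config)
  breakpoints <- list(F1 = child$maternal_breaks)
  if (g > 0) for (i in seq_len(g)) {
    father <- draw_individual(sites, recurrent, config)
    child <- cross(child, father, config)
    breakpoints[[sprintf("BC%dF1", i)]] <- child$maternal_breaks
  }
  donor_code <- if (recurrent == "A") 2L else 1L
  dosage <- unlist(lapply(child$haps,
                          function(h) colSums(h$anc == donor_code)))
  truth <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    dosage_B = as.integer(dosage),
    class = c("AA", "Aa", "aa")[dosage + 1L],
    stringsAsFactors = FALSE
  )
  list(individual = child, generation = g, organelle = child$organelle,
       breakpoints = breakpoints, truth = truth)
}

parse_pedigree <- function(pedigree) {
  if (is.numeric(pedigree)) {
    if (pedigree < 0 || pedigree != round(pedigree))
      stop("backcross depth must be a non-negative integer")
    return(as.integer(pedigree))
  }
  if (identical(pedigree, "F1")) return(0L)
  m <- regmatches(pedigree, regexec("^BC([0-9]+)F1$", pedigree))[[1]]
  if (length(m) == 2L) return(as.integer(m[2]))
  stop("unknown pedigree label: ", pedigree)
}

#' Apply genotype error to samples of a matrix
#'
#' With probability `rate`, independently per site and sample, the call is
#' replaced. In `"uniform"` mode the replacement is drawn uniformly from
#' the three genotypes the site's two alleles allow (hom-REF, het,
#' hom-ALT), so only two-thirds of replacements change the class
#' effectively observed. In `"aa_flip"` mode the call is set to homozygous
#' for the donor-specific allele, which requires `diag_sites` and only
#' touches diagnostic sites; this maps the rate onto the model's `p_error`
#' one-to-one. Truth records are never modified.
#'
#' @param gm A [genotype_matrix()] of biallelic sites.
#' @param samples Sample ids to perturb.
#' @param rate Error probability in `[0, 1]`.
#' @param mode `"uniform"` or `"aa_flip"`.
#' @param diag_sites Diagnostic-site table (needed for `"aa_flip"`).
#' @return The perturbed matrix.
#' @export
apply_genotype_error <- function(gm, samples, rate,
                                 mode = c("uniform", "aa_flip"),
                                 diag_sites = NULL) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(gm)
  cols <- sample_cols(gm, samples)
  S <- n_sites(gm)
  for (j in cols) {
    if (mode == "uniform") {
      hit <- which(stats::runif(S) < rate & !is.na(gm$a1[, j]))
      if (!length(hit)) next
      gcls <- sample(0:2, length(hit), replace = TRUE)  # 0/0, 0/1, 1/1
      gm$a1[hit, j] <- ifelse(gcls == 2L, 1L, 0L)
      gm$a2[hit, j] <- ifelse(gcls == 0L, 0L, 1L)
    } else {
      if (is.null(diag_sites))
        stop("aa_flip mode needs the diagnostic-site table")
      rows_all <- match(paste(diag_sites$chrom, diag_sites$pos),
                        paste(gm$chrom, gm$pos))
      ok <- !is.na(rows_all)
      rows <- rows_all[ok]
      allele_a <- diag_sites$allele_a[ok]
      sel <- stats::runif(length(rows)) < rate
      hit <- rows[sel]
      if (!length(hit)) next
      # homozygous for the donor allele (allele_a)
      first_alt <- sub(",.*$", "", gm$alt[hit])
      aa_idx <- ifelse(allele_a[sel] == first_alt, 1L, 0L)
      gm$a1[hit, j] <- aa_idx
      gm$a2[hit, j] <- aa_idx
    }
  }
  gm
}

#' Simulate a complete hybrid dataset
#'
#' Top-level generator: seeds the RNG from `config$seed`, draws the site
#' landscape and parental panels, builds the focal hybrid through the
#' requested pedigree, assembles everything into a [genotype_matrix()]
#' (panels `parentA`, `parentB`, `focal`), and applies genotype error to
#' the focal sample. Identical configs yield byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param pedigree Pedigree label or backcross depth (see [make_hybrid()]).
#' @param mother_species Female parent of the initial cross (default
#'   `"B"`).
#' @return List of class `hybrid_sim`: `matrix` (the genotype matrix),
#'   `sites`, `truth` (generation, organelle, true diagnostic sites, true
#'   per-site classes and donor dosage, breakpoints), `individuals`, and
#'   `config`.
#' @export
simulate_hybrid_dataset <- function(config = sim_config(),
                                    pedigree = "BC1F1",
                                    mother_species = "B") {
  set.seed(config$seed)
  pan <- simulate_parental_panels(config)
  hyb <- make_hybrid(pedigree, config, sites = pan$sites,
                     mother_species = mother_species)
  inds <- c(pan$panelA, pan$panelB, list(hyb$individual))
  ids <- c(sprintf("A%d", seq_len(config$n_panel_a)),
           sprintf("B%d", seq_len(config$n_panel_b)), "focal")
  gm <- individuals_to_matrix(inds, ids, pan$sites, config)
  gm <- apply_genotype_error(gm, "focal", config$error_rate,
                             mode = config$error_mode,
                             diag_sites = pan$truth_diagnostic)
  fx <- pan$sites$role == "fixed"
  structure(
    list(matrix = gm, sites = pan$sites,
         truth = list(
           generation = hyb$generation, organelle = hyb$organelle,
           diagnostic_sites = pan$truth_diagnostic,
           classes = hyb$truth[fx, c("chrom", "pos", "class")],
           dosage = hyb$truth,
           breakpoints = hyb$breakpoints),
         individuals = list(panelA = pan$panelA, panelB = pan$panelB,
                            focal = hyb$individual),
         config = config),
    class = "hybrid_sim"
  )
}

individuals_to_matrix <- function(inds, ids, sites, config) {
  nI <- length(inds)
  total <- nrow(sites)
  a1 <- matrix(NA_integer_, total, nI)
  a2 <- matrix(NA_integer_, total, nI)
  for (k in seq_len(nI)) {
    al <- lapply(inds[[k]]$haps, `[[`, "alleles")
    h1 <- unlist(lapply(al, function(m) m[1, ]))
    h2 <- unlist(lapply(al, function(m) m[2, ]))
    a1[, k] <- pmin(h1, h2)
    a2[, k] <- pmax(h1, h2)
  }
  panels <- list(
    parentA = sample_panel("parentA", ids[seq_len(config$n_panel_a)]),
    parentB = sample_panel("parentB",
                           ids[config$n_panel_a + seq_len(config$n_panel_b)]),
    focal = sample_panel("focal", "focal")
  )
  genotype_matrix(sites$chrom, sites$pos, sites$ref, sites$alt,
                  a1, a2, ids, panels)
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cat("<hybrid_sim> pedigree g =", x$truth$generation,
      " organelle =", x$truth$organelle, "\n  ")
  print(x$matrix)
  cat("  true diagnostic sites:", nrow(x$truth$diagnostic_sites), "\n")
  invisible(x)
}

#' Phased haplotype matrix of a simulated panel
#'
#' Returns the simulated haplotypes (phases known) as a `(2 x individuals)
#' x sites` 0/1 allele matrix — the substrate for brute-force pairwise
#' difference oracles.
#'
#' @param sim A `hybrid_sim`.
#' @param panel `"panelA"`, `"panelB"` or `"focal"`.
#' @return Integer matrix, one row per haplotype.
#' @export
panel_haplotypes <- function(sim, panel = c("panelA", "panelB", "focal")) {
  panel <- match.arg(panel)
  inds <- if (panel == "focal") list(sim$individuals$focal)
          else sim$individuals[[panel]]
  do.call(rbind, lapply(inds, function(ind) {
    al <- lapply(ind$haps, `[[`, "alleles")
    rbind(unlist(lapply(al, function(m) m[1, ])),
          unlist(lapply(al, function(m) m[2, ])))
  }))
}

#' True ancestry-block counts per chromosome
#'
#' Number of runs of the true genotype class along the diagnostic sites of
#' each chromosome — the oracle for segment counting at window = 1,
#' error = 0.
#'
#' @param sim A `hybrid_sim`.
#' @return `data.frame` with `chrom` and `n_blocks`.
#' @export
true_block_counts <- function(sim) {
  cls <- sim$truth$classes
  chroms <- unique(cls$chrom)
  data.frame(
    chrom = chroms,
    n_blocks = vapply(chroms, function(ch) {
      length(rle(cls$class[cls$chrom == ch])$lengths)
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the VCF (v4.2, with seed/config/pedigree provenance in the
#' header), the panel-assignment TSV, and a JSON truth sidecar (generation,
#' organelle lineage, true diagnostic sites, per-chromosome donor-dosage,
#' crossover breakpoints).
#'
#' @param sim A `hybrid_sim`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulated_vcf <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  hdr <- c(
    sprintf("##simulation_seed=%d", cfg$seed),
    sprintf("##simulation_pedigree=%s",
            if (sim$truth$generation == 0) "F1"
            else sprintf("BC%dF1", sim$truth$generation)),
    sprintf("##simulation_config=%s",
            paste(sprintf("%s=%s", names(unclass(cfg)),
                          vapply(unclass(cfg), format, "")), collapse = ";"))
  )
  vcf <- file.path(dir, "sim.vcf")
  write_vcf(sim$matrix, vcf, extra_header = hdr)
  panels_tsv <- file.path(dir, "panels.tsv")
  pan <- do.call(rbind, lapply(sim$matrix$panels, function(p) {
    data.frame(sample_id = p$sample_ids, panel = p$name,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(pan, panels_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = cfg$seed, generation = sim$truth$generation,
         organelle = sim$truth$organelle,
         diagnostic_sites = sim$truth$diagnostic_sites,
         classes = sim$truth$classes,
         block_counts = true_block_counts(sim),
         breakpoints = sim$truth$breakpoints),
    truth_json, auto_unbox = TRUE, digits = NA)
  invisible(c(vcf = vcf, panels = panels_tsv, truth = truth_json))
}
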