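test_that("config validation rejects bad rates, masks and coordinates", {
  expect_error(sim_config(omega_pbr = -1), "non-negative")
  expect_error(sim_config(err_sub = 1.5), "rates")
  expect_error(sim_config(n_codons = 5), "n_codons")
  expect_error(sim_config(n_codons = 20, pbr_mask = c(1, 25)), "pbr_mask")
  expect_error(sim_config(pop_coords = matrix(0, 9, 2)), "distinct")
})

test_that("allele pool: PBR amino-acid diversity exceeds non-PBR under
           diversifying omegas", {
  cfg <- sim_config(seed = 1, n_alleles_global = 20)
  alleles <- simulate_allele_pool(cfg)
  expect_equal(length(unique(alleles)), 20)
  aln <- codon_alignment(alleles)
  mask <- pbr_mask("sim", cfg$n_codons, cfg$pbr_mask)
  m <- attr(site_diversity(aln, mask), "partition_means")
  expect_gt(m[["PBR"]], m[["non-PBR"]])
})

test_that("allele pool: frozen omegas reproduce the ancestor; stops never
           occur", {
  cfg0 <- sim_config(seed = 3, omega_pbr = 0, omega_nonpbr = 0,
                     n_alleles_global = 5)
  frozen <- simulate_allele_pool(cfg0)
  expect_true(all(frozen == attr(frozen, "ancestor")))
  for (s in c(2, 11, 29)) {
    al <- simulate_allele_pool(sim_config(seed = s, n_alleles_global = 8))
    aa <- vapply(al, function(x) {
      paste(Biostrings::GENETIC_CODE[substring(x, seq(1, nchar(x), 3),
                                               seq(3, nchar(x), 3))],
            collapse = "")
    }, "")
    expect_false(any(grepl("*", aa, fixed = TRUE)))
  }
})

test_that("error-free reads are exact template copies and demultiplex to
           their true pool", {
  sim <- small_sim(seed = 2, err_sub = 0, err_homopolymer = 0,
                   chimera_rate = 0)
  ins <- substr(sim$reads$reads, 26, 1000)
  expect_true(all(ins == sim$reads$templates[sim$reads$truth$origin]))
  dmx <- demultiplex(sim$reads$reads, sim$reads$pools)
  got <- rep(names(dmx$pools), vapply(dmx$pools, length, 0L))
  names(got) <- unlist(lapply(dmx$pools, names), use.names = FALSE)
  expect_equal(unname(got[sim$reads$truth$read_id]), sim$reads$truth$pop)
})

test_that("chimera counts are binomial at the configured rate", {
  cfg <- sim_config(seed = 5, n_pops = 2, depth_per_pool = 1000,
                    n_alleles_global = 6, chimera_rate = 0.05)
  sim <- simulate_pool_reads(cfg, simulate_allele_pool(cfg))
  n_chim <- sum(sim$truth$is_chimera)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(n_chim, ci[1]); expect_lte(n_chim, ci[2])
})

test_that("read simulation is byte-deterministic and conserves depth", {
  a <- small_sim(seed = 9)
  b <- small_sim(seed = 9)
  expect_identical(a$reads$reads, b$reads$reads)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$reads$reads, f1); write_fasta(b$reads$reads, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  expect_equal(length(a$reads$reads),
               a$cfg$depth_per_pool * a$cfg$n_pops)
  # truth completeness: every read id resolves in the truth table
  expect_setequal(names(a$reads$reads), a$reads$truth$read_id)
})

test_that("AFLP genotypes are binary and the realized IBD slope is
           recovered from sampled individuals", {
  cfg <- sim_config(seed = 4, ibd_slope_target = 2e-3, n_aflp_loci = 500)
  sim <- simulate_aflp(cfg)
  expect_true(all(sim$genotypes %in% 0:1))
  fst <- dominant_fst(sim$genotypes, sim$pop_assign)
  lt <- lower.tri(fst)
  est <- coef(lm(fst[lt] ~ unclass(sim$geo)[lt]))[[2]]
  realized <- sim$truth$realized_ibd_slope
  expect_lt(abs(est - realized) / realized, 0.25)
})

test_that("flat-geography AFLP shows no isolation by distance", {
  hits <- 0L
  for (s in 1:30) {
    cfg <- sim_config(seed = s, ibd_slope_target = 0, n_aflp_loci = 120)
    sim <- simulate_aflp(cfg)
    fst <- dominant_fst(sim$genotypes, sim$pop_assign)
    p <- mantel_test(fst, sim$geo, n_perm = 199, seed = s)$P
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits, 3L)   # ~binomial(30, 0.05); 90%+ non-significant
})

test_that("community generator couples pathogen richness to the
           covariate as programmed", {
  covar <- rnorm(9)
  strong <- simulate_communities(sim_config(seed = 1, assoc_effect = 3),
                                 covar)
  r <- cor(strong$truth$pathogen_richness, covar)
  expect_gt(r, 0.7)
  none <- simulate_communities(sim_config(seed = 1, pathogen_fraction = 0),
                               covar)
  expect_true(all(none$truth$pathogen_richness == 0))
  expect_false(any(none$records$taxon %in% austin_pathogens()))
})
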