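test_that("DIVAA diversity matches its analytic values", {
  # conserved column / 50-50 column / uniform-20 column
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  aln <- aln_from_aa(list(rep("A", 20),
                          rep(c("A", "S"), 10),
                          aas))
  mask <- pbr_mask("toy", 3, 1)
  sd <- site_diversity(aln, mask)
  expect_equal(sd$D, c(0.05, 0.1, 1.0))
  expect_equal(sd$D_rescaled[1], 0)
  expect_equal(sd$D_rescaled[3], 1)
  expect_equal(sd$polymorphic, c(FALSE, TRUE, TRUE))
})

test_that("DIVAA is bounded and increases toward a uniform column", {
  # nested distributions approaching uniformity over 4 residues
  mk <- function(freqs) aln_from_aa(list(rep(c("A", "S", "G", "V"), freqs)))
  mask <- pbr_mask("toy", 1, 1)
  steps <- list(c(17, 1, 1, 1), c(14, 2, 2, 2), c(11, 3, 3, 3),
                c(8, 4, 4, 4), c(5, 5, 5, 5))
  D <- vapply(steps, function(f) site_diversity(mk(f), mask)$D, 0)
  expect_true(all(diff(D) > 0))
  expect_true(all(D >= 0.05 & D <= 1))
})

test_that("gap codons are excluded from column frequencies", {
  aln <- codon_alignment(c(a = "GCTGCT", b = "GCT---", c = "GCTTCT"))
  sd <- site_diversity(aln, pbr_mask("toy", 2, 1))
  expect_equal(sd$D[1], 0.05)        # three Ala
  expect_equal(sd$D[2], 0.1)         # Ala/Ser over the two non-gap rows
})

test_that("percent polymorphic counts distinct amino acids per codon", {
  # 4 sequences, 12 codons, exactly 3 polymorphic (hand enumeration)
  cols <- c(lapply(1:9, function(i) rep("A", 4)),
            list(c("A", "A", "S", "A"), c("G", "V", "G", "G"),
                 c("L", "L", "L", "F")))
  aln <- aln_from_aa(cols)
  mask <- pbr_mask("toy", 12, c(10, 11, 12))
  pct <- percent_polymorphic(aln, mask)
  expect_equal(pct[["pct_all"]], 25)
  expect_equal(pct[["pct_pbr"]], 100)
  expect_equal(pct[["pct_nonpbr"]], 0)
  # synonymous difference is not amino-acid polymorphism
  syn <- codon_alignment(c(a = "CTTAAA", b = "CTCAAA"))
  expect_equal(percent_polymorphic(syn, pbr_mask("t", 2, 1))[["pct_all"]], 0)
})

test_that("Welch test matches direct arithmetic and yields fractional df", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  got <- welch_t_test(x, y)
  # textbook Welch-Satterthwaite computed longhand
  se2 <- var(x) / 3 + var(y) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 6)^2 / 5)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_gt(abs(got$df - round(got$df)), 1e-6)   # non-integer df
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Nei-Gojobori single-codon cases match hand computation", {
  id <- nei_gojobori_pair("TTTAAA", "TTTAAA")
  expect_equal(id$dN, 0); expect_equal(id$dS, 0)

  # TTT (Phe) vs TTA (Leu): 1 nonsynonymous difference; potential
  # synonymous sites: TTT has 1/3 (TTC), TTA has 2/3 (TTG syn at pos 3;
  # CTA syn at pos 1), averaged = 1/2
  r <- nei_gojobori_pair("TTT", "TTA")
  expect_equal(r$Nd, 1); expect_equal(r$Sd, 0)
  expect_equal(r$s_sites, (1 / 3 + 2 / 3) / 2)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, -0.75 * log(1 - (4 / 3) * r$pN))

  # two-difference pair conserves the difference count across pathways
  r2 <- nei_gojobori_pair("TTT", "GTA")
  expect_equal(r2$Nd + r2$Sd, 2)
})

test_that("pathways through stop codons are excluded", {
  # TGT (Cys) -> TAC (Tyr): path via TAT is fine, path via TGC->..., the
  # order (pos2 first) passes TAT(Tyr), order (pos3 first) passes TGC
  # (Cys, synonymous step); neither hits a stop: both counted.
  r <- nei_gojobori_pair("TGT", "TAC")
  expect_equal(r$Nd + r$Sd, 2)
  # TGG (Trp) -> TAA would involve stops, but TAA is not a sense codon;
  # use TCA (Ser) -> TGG (Trp): path via TGA (stop) must be excluded,
  # leaving only the pathway through TCG
  o <- oracle_pair_counts("TCA", "TGG")
  m <- nei_gojobori_pair("TCA", "TGG")
  expect_equal(m$Nd, o[["Nd"]], tolerance = 1e-12)
  expect_equal(m$Sd, o[["Sd"]], tolerance = 1e-12)
})

test_that("codon-bootstrap Z-test recovers the selective regime of the
           simulator", {
  cfg <- sim_config(seed = 2, n_alleles_global = 12, n_codons = 30,
                    omega_pbr = 8, omega_nonpbr = 0.15)
  aln <- codon_alignment(simulate_allele_pool(cfg))
  mask <- pbr_mask("sim", cfg$n_codons, cfg$pbr_mask)
  pbr <- z_test_selection(aln, mask, "PBR", n_boot = 300, seed = 1)
  non <- z_test_selection(aln, mask, "non-PBR", n_boot = 300, seed = 1)
  expect_lt(pbr$P, 0.05)
  expect_gt(non$P, 0.05)
  expect_gt(pbr$dN, pbr$dS)
})

test_that("Z-test degenerates gracefully on identical sequences and
           refuses tiny partitions", {
  aln <- codon_alignment(c(a = "GCTGCTGCTGCT", b = "GCTGCTGCTGCT",
                           c = "GCTGCTGCTGCT"))
  mask <- pbr_mask("toy", 4, 1:2)
  res <- z_test_selection(aln, mask, "all", n_boot = 100, seed = 1)
  expect_equal(res$Z, 0); expect_equal(res$P, 1)
  expect_error(z_test_selection(aln, mask, "PBR", n_boot = 100),
               "fewer than 3")
})

test_that("per-population polymorphism uses population-restricted
           variant subsets", {
  aln <- aln_from_aa(list(c("A", "A", "S"), c("G", "G", "G"),
                          c("L", "F", "L")))
  rownames(aln) <- c("V1", "V2", "V3")
  pm <- rbind(P1 = c(V1 = 1, V2 = 1, V3 = 0),
              P2 = c(V1 = 1, V2 = 1, V3 = 1),
              P3 = c(V1 = 0, V2 = 0, V3 = 1))
  mask <- pbr_mask("toy", 3, 1)
  by_pop <- percent_polymorphic_by_pop(aln, mask, pm)
  # P1 sees V1,V2: codon3 L vs F polymorphic only
  expect_equal(by_pop$pct_all, c(100 / 3, 200 / 3, 0))
  expect_equal(by_pop$n_variants, c(2L, 3L, 1L))
})
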