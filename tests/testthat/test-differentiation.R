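test_that("presence-profile Euclidean distances match hand values", {
  pm <- rbind(P1 = c(1, 0, 1), P2 = c(1, 1, 1), P3 = c(1, 0, 1),
              P4 = c(0, 1, 0))
  d <- euclidean_presence(pm)
  expect_equal(d["P1", "P2"], 1)
  expect_equal(d["P1", "P3"], 0)
  expect_equal(d["P1", "P4"], sqrt(3))
  expect_true(all(abs(d - t(d)) < 1e-15))
  two <- rbind(P1 = c(1, 0), P2 = c(0, 1))
  expect_error(euclidean_presence(two), ">= 3")
  expect_equal(unname(as.matrix(dist(two))[1, 2]), sqrt(2))
})

test_that("0/1 standardization hits both endpoints and is idempotent", {
  m <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m[lower.tri(m)] <- c(2, 5, 8); m <- m + t(m)
  d <- dist_matrix(m, kind = "raw")
  s <- standardize01(d)
  off <- sort(s[lower.tri(s)])
  expect_equal(off, c(0, 0.5, 1))
  expect_equal(unclass(standardize01(s)), unclass(s))
  flat <- dist_matrix(matrix(1, 3, 3) - diag(3), kind = "raw")
  expect_error(standardize01(flat), "degenerate")
})

geo4 <- function() {
  coords <- c(0, 1, 3, 7)
  dist_matrix(abs(outer(coords, coords, "-")),
              labels = paste0("P", 1:4), kind = "geographic")
}

test_that("Mantel test: perfect correlation, exact 4-population null", {
  g <- geo4()
  res <- mantel_test(g, g, n_perm = 999, seed = 1)
  expect_equal(res$R, 1)
  expect_equal(res$slope, 1); expect_equal(res$r2, 1)
  # exhaustive-relabelling oracle: P = 1/24 for self-correlation of a
  # line with all-distinct distances
  exact <- exact_mantel_p(unclass(g), unclass(g))
  expect_equal(exact, 1 / 24)
  big <- mantel_test(g, g, n_perm = 10000, seed = 3)
  expect_lt(abs(big$P - exact), 0.01)
})

test_that("Mantel test rejects mismatched labels and degenerate input", {
  g <- geo4()
  h <- g; rownames(h) <- colnames(h) <- paste0("Q", 1:4)
  expect_error(mantel_test(g, h), "identical labels")
  flat <- dist_matrix(matrix(1, 4, 4) - diag(4),
                      labels = paste0("P", 1:4))
  expect_error(mantel_test(flat, g), "zero variance")
})

test_that("partial Mantel: control-free limit and full-explanation limit", {
  set.seed(42)
  n <- 8
  mk <- function() {
    m <- matrix(0, n, n); m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    dist_matrix(m + t(m), labels = paste0("P", 1:n))
  }
  a <- mk(); b <- mk(); ctrl <- mk()
  plain <- mantel_test(a, b, n_perm = 199, seed = 1)$R
  partial <- partial_mantel_test(a, b, ctrl, n_perm = 199, seed = 1)$R
  expect_lt(abs(plain - partial), 0.05 + abs(plain) * 0.5)
  self <- partial_mantel_test(a, b, a, n_perm = 199, seed = 1)
  expect_lt(abs(self$R), 1e-10)
  expect_error(partial_mantel_test(a, a, a, n_perm = 199), "collinear")
})

test_that("masked pairs are excluded from statistic and permutations", {
  set.seed(7)
  n <- 9
  m <- matrix(0, n, n); m[lower.tri(m)] <- runif(36)
  d <- dist_matrix(m + t(m), labels = paste0("P", 1:n))
  g <- dist_matrix(as.matrix(dist(cbind(runif(n), runif(n)))),
                   labels = paste0("P", 1:n), kind = "geographic")
  masked <- drop_pairs(d, c("P1-P4", "P2-P4", "P3-P4"))
  expect_equal(sum(is.na(masked[lower.tri(masked)])), 3)
  res <- mantel_test(masked, g, n_perm = 199, seed = 1)
  expect_equal(res$n_pairs, 33)
  expect_identical(drop_pairs(d, character(0)), d)
  all_pairs <- apply(combn(paste0("P", 1:n), 2), 2, paste, collapse = "-")
  expect_error(drop_pairs(d, all_pairs), "fewer than 3")
  expect_error(drop_pairs(d, "P1-XX"), "unknown")
})

test_that("dominant Fst matches hand-computed ratio of averages", {
  # two populations of 4; three loci with band frequencies
  # pop1: 1.00, 0.75, 0.00 ; pop2: 1.00, 0.00, 1.00
  g <- rbind(
    matrix(c(1, 1, 1, 1,  1, 1, 1, 0,  0, 0, 0, 0), 4),
    matrix(c(1, 1, 1, 1,  0, 0, 0, 0,  1, 1, 1, 1), 4))
  pops <- rep(c("x", "y"), each = 4)
  fst <- dominant_fst(g, pops)
  q1 <- sqrt(1 - c(1, 0.75, 0)); q2 <- sqrt(1 - c(1, 0, 1))
  num <- (q1 - q2)^2 / 4; qb <- (q1 + q2) / 2; den <- qb * (1 - qb)
  keep <- den > 0
  expect_equal(fst["x", "y"], sum(num[keep]) / sum(den[keep]))
  # identical band frequencies give zero; 0-vs-1 fixation gives 1
  same <- dominant_fst(rbind(g[1:4, ], g[1:4, ]), pops)
  expect_equal(same["x", "y"], 0)
  fix <- dominant_fst(matrix(rep(c(0, 1), each = 4), ncol = 1), pops)
  expect_equal(fix["x", "y"], 1)
  expect_error(dominant_fst(matrix(1, 8, 2), pops), "undefined")
})

test_that("neutral slope envelope is deterministic and its verdict
           brackets correctly", {
  sim <- simulate_aflp(sim_config(seed = 3, n_aflp_loci = 120))
  e1 <- neutral_slope_envelope(sim$genotypes, sim$pop_assign, sim$geo,
                               subset_size = 40, n_subsets = 10, seed = 5)
  e2 <- neutral_slope_envelope(sim$genotypes, sim$pop_assign, sim$geo,
                               subset_size = 40, n_subsets = 10, seed = 5)
  expect_identical(e1$slopes, e2$slopes)
  expect_lte(e1$min_r2, e1$max_r2)
  mid <- (e1$min_slope + e1$max_slope) / 2
  expect_true(envelope_verdict(e1, slope = mid)$within_slope)
  expect_false(envelope_verdict(e1, slope = e1$max_slope * 10 + 1)$within_slope)
  expect_error(neutral_slope_envelope(sim$genotypes, sim$pop_assign,
                                      sim$geo, subset_size = 1e6),
               "exceeds")
})

test_that("Mantel R agrees with vegan on unmasked matrices", {
  set.seed(11)
  n <- 7
  mk <- function() {
    m <- matrix(0, n, n); m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    dist_matrix(m + t(m), labels = paste0("P", 1:n))
  }
  a <- mk(); b <- mk()
  ours <- mantel_test(a, b, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(unclass(a)), as.dist(unclass(b)),
                       permutations = 999)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
})
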