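#' Simulate dominant neutral markers with isolation by distance
#'
#' Generates an individuals x loci 0/1 band matrix for dominant
#' (AFLP-style) neutral markers whose population allele frequencies drift
#' along geography, so that pairwise differentiation (Fst) increases with
#' distance at approximately `cfg$ibd_slope_target` per km. Per-locus
#' recessive-allele frequencies receive a spatially autocorrelated
#' deviation (Gaussian field with exponential covariance, range 50 km)
#' whose scale is solved from the target slope; individuals are then
#' sampled under Hardy-Weinberg equilibrium, a band being present unless
#' the individual is homozygous recessive.
#'
#' The realized slope reported in the truth is computed from the true
#' (infinite-sample) allele frequencies: pairwise multilocus Fst from the
#' truth frequencies regressed on geographic distance.
#'
#' @param cfg a [sim_config()] object (uses `n_pops`, `pool_size`,
#'   `n_aflp_loci`, `ibd_slope_target`, `pop_coords`).
#' @return list of class `sim_aflp`: `genotypes` (individuals x loci 0/1
#'   matrix), `pop_assign` (factor), `coords` (n_pops x 2 km), `geo`
#'   (geographic [dist_matrix()]), `truth` (list with `q` true
#'   recessive-frequency matrix pops x loci and `realized_ibd_slope`).
#' @examples
#' sim <- simulate_aflp(sim_config(seed = 1, n_aflp_loci = 50))
#' dim(sim$genotypes)
#' @export
simulate_aflp <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pops < 3L) stop("need at least 3 populations", call. = FALSE)
  if (cfg$n_aflp_loci < 10L)
    stop("n_aflp_loci < 10: slope estimation unstable", call. = FALSE)

  with_seed(sub_seed(cfg$seed, 5L), {
    pops <- sprintf("P%d", seq_len(cfg$n_pops))
    coords <- cfg$pop_coords
    if (is.null(coords)) {
      coords <- cbind(stats::runif(cfg$n_pops, 0, 100),
                      stats::runif(cfg$n_pops, 0, 100))
    }
    rownames(coords) <- pops
    D <- as.matrix(stats::dist(coords))

    # Spatial field scale from the target slope: for d << range,
    # E[(q_i - q_j)^2]/4 ~ s^2 d / (2 range), and Fst divides that by
    # ~E[q(1-q)] = 0.2, so slope ~ s^2 / (0.4 range).
    range_km <- 50
    s <- sqrt(max(cfg$ibd_slope_target, 0) * range_km * 0.4)
    q <- matrix(0, cfg$n_pops, cfg$n_aflp_loci,
                dimnames = list(pops, sprintf("L%04d", seq_len(cfg$n_aflp_loci))))
    q0 <- stats::runif(cfg$n_aflp_loci, 0.15, 0.85)
    if (s > 0) {
      K <- s^2 * exp(-D / range_km)
      L <- chol(K + diag(1e-10, cfg$n_pops))
      Z <- crossprod(L, matrix(stats::rnorm(cfg$n_pops * cfg$n_aflp_loci),
                               cfg$n_pops))
      q[] <- pmin(pmax(sweep(Z, 2, q0, `+`), 0.02), 0.98)
    } else {
      q <- matrix(rep(q0, each = cfg$n_pops), cfg$n_pops,
                  dimnames = dimnames(q))
    }

    # Individuals: dominant band unless homozygous recessive (HWE).
    n_ind <- cfg$n_pops * cfg$pool_size
    pop_assign <- factor(rep(pops, each = cfg$pool_size), levels = pops)
    p_band <- 1 - q[as.integer(pop_assign), , drop = FALSE]^2
    genotypes <- matrix(
      as.integer(stats::runif(length(p_band)) < p_band),
      n_ind, cfg$n_aflp_loci,
      dimnames = list(sprintf("%s_i%02d", pop_assign,
                              sequence(rep(cfg$pool_size, cfg$n_pops))),
                      colnames(q)))

    geo <- dist_matrix(D, kind = "geographic")
    fst_true <- fst_from_q(q)
    realized <- ibd_slope(fst_true, D)

    structure(list(genotypes = genotypes, pop_assign = pop_assign,
                   coords = coords, geo = geo,
                   truth = list(q = q, realized_ibd_slope = realized)),
              class = "sim_aflp")
  })
}

# Multilocus pairwise Fst from a pops x loci recessive-frequency matrix
# (ratio of averages; between-population variance of q over
# q-bar(1-q-bar), so a 0-vs-1 fixation gives a per-locus Fst of 1).
fst_from_q <- function(q) {
  pops <- rownames(q)
  n <- nrow(q)
  fst <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- (q[i, ] - q[j, ])^2 / 4
    qb <- (q[i, ] + q[j, ]) / 2
    den <- qb * (1 - qb)
    keep <- den > 0
    fst[i, j] <- fst[j, i] <-
      if (any(keep)) max(0, sum(num[keep]) / sum(den[keep])) else 0
  }
  fst
}

# Least-squares slope of the off-diagonal of y on the off-diagonal of x.
ibd_slope <- function(y, x) {
  lt <- lower.tri(x)
  stats::coef(stats::lm(y[lt] ~ x[lt]))[[2]]
}
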