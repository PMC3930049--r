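#' Labelled population distance matrix
#'
#' Symmetric nonnegative matrix with zero diagonal and population
#' labels. Off-diagonal cells may be `NA` to mark masked pairs (see
#' [drop_pairs()]); all statistics skip masked cells and permutation
#' nulls keep the mask on fixed cell positions.
#'
#' @param values square numeric matrix.
#' @param labels population labels (default: rownames of `values`).
#' @param kind one of `"raw"`, `"standardized"`, `"fst"`,
#'   `"geographic"`.
#' @return matrix of class `dist_matrix` with attribute `kind`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        kind = c("raw", "standardized", "fst",
                                 "geographic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("P%d", seq_len(nrow(values)))
  offd <- values[row(values) != col(values)]
  if (any(!is.na(offd) & offd < 0))
    stop("distances must be nonnegative", call. = FALSE)
  if (any(abs(values - t(values)) > 1e-12, na.rm = TRUE))
    stop("distance matrix must be symmetric", call. = FALSE)
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d populations", attr(x, "kind"),
              nrow(x)))
  n_mask <- sum(is.na(x[lower.tri(x)]))
  if (n_mask) cat(sprintf(" (%d masked pairs)", n_mask))
  cat("\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Euclidean distances between population presence-absence profiles
#'
#' @param presence binary populations x variants matrix.
#' @return a raw [dist_matrix()].
#' @export
euclidean_presence <- function(presence) {
  if (nrow(presence) < 3L) stop("need >= 3 populations", call. = FALSE)
  dist_matrix(as.matrix(stats::dist(presence)), kind = "raw")
}

#' Standardize a distance matrix to the 0/1 scale
#'
#' Maps each off-diagonal cell by `(d - d_min) / (d_max - d_min)` using
#' the off-diagonal minimum and maximum, so the smallest distance is
#' exactly 0 and the largest exactly 1; idempotent on already
#' standardized input.
#'
#' @param d a [dist_matrix()].
#' @return a standardized `dist_matrix`.
#' @export
standardize01 <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  offd <- d[row(d) != col(d)]
  rng <- range(offd, na.rm = TRUE)
  if (diff(rng) == 0)
    stop("degenerate matrix: all off-diagonal distances equal",
         call. = FALSE)
  out <- (d - rng[1L]) / diff(rng)
  diag(out) <- 0
  dist_matrix(unclass(out), labels = rownames(d), kind = "standardized")
}

# Lower-triangle index pairs of an n x n matrix.
lt_pairs <- function(n) {
  iu <- rep(seq_len(n), times = seq_len(n) - 1L)
  ju <- unlist(lapply(seq_len(n)[-1L], function(i) seq_len(i - 1L)),
               use.names = FALSE)
  cbind(i = unlist(lapply(seq_len(n)[-1L], function(i) rep(i, i - 1L))),
        j = ju)
}

# Least-squares fit summary of y ~ x (vectors).
ls_fit <- function(x, y) {
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  r2 <- stats::cor(x, y)^2
  c(slope = b, intercept = a, r2 = r2)
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation over the `n(n-1)/2` population pairs, with a
#' permutation null obtained by simultaneous row/column relabelling of
#' the first matrix. The one-tailed p-value uses the add-one convention
#' `(number of permuted R >= observed + 1) / (n_perm + 1)`. Masked
#' (`NA`) pairs are excluded from the statistic, and permutations are
#' evaluated over the same fixed cell positions. A least-squares fit of
#' `b ~ a` (slope, intercept, R-squared) is reported alongside, as used
#' for isolation-by-distance regressions.
#'
#' @param a,b [dist_matrix()] objects with identical labels in identical
#'   order (`a` is permuted).
#' @param n_perm number of permutations (default 1000, minimum 99).
#' @param seed optional RNG seed.
#' @param alternative `"greater"` (default; positive association) or
#'   `"two.sided"`.
#' @return list of class `mantel_result`: `R`, `P`, `n_perm`, `slope`,
#'   `intercept`, `r2`, `n_pairs`, `partial`, `control_used`.
#' @export
mantel_test <- function(a, b, n_perm = 1000L, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_same_labels(a, b)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  n <- nrow(a)
  lt <- lt_pairs(n)
  av <- a[lt]; bv <- b[lt]
  keep <- !is.na(av) & !is.na(bv)
  if (sum(keep) < 3L) stop("fewer than 3 usable pairs", call. = FALSE)
  if (stats::sd(av[keep]) == 0 || stats::sd(bv[keep]) == 0)
    stop("zero variance in off-diagonal distances", call. = FALSE)
  R <- stats::cor(av[keep], bv[keep])
  fit <- ls_fit(av[keep], bv[keep])
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      apv <- a[cbind(p[lt[, 1L]], p[lt[, 2L]])][keep]
      # relabelling can move a masked cell into view; drop it pairwise
      ok <- !is.na(apv)
      if (sum(ok) < 3L || stats::sd(apv[ok]) == 0) return(NA_real_)
      stats::cor(apv[ok], bv[keep][ok])
    }, numeric(1L))
  })
  P <- perm_pvalue(R, perm_R, alternative)
  structure(list(R = R, P = P, n_perm = n_perm,
                 slope = fit[["slope"]], intercept = fit[["intercept"]],
                 r2 = fit[["r2"]], n_pairs = sum(keep),
                 partial = FALSE, control_used = NA_character_,
                 alternative = alternative),
            class = "mantel_result")
}

perm_pvalue <- function(obs, perm, alternative) {
  perm <- perm[!is.na(perm)]
  if (alternative == "greater") {
    (sum(perm >= obs) + 1) / (length(perm) + 1)
  } else {
    (sum(abs(perm) >= abs(obs)) + 1) / (length(perm) + 1)
  }
}

check_same_labels <- function(...) {
  labs <- lapply(list(...), rownames)
  if (!all(vapply(labs[-1L], identical, TRUE, labs[[1L]])))
    stop("matrices must carry identical labels in identical order",
         call. = FALSE)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel test: R = %.3f, P = %.4g (%d permutations, %s)\n",
              if (x$partial) "Partial " else "", x$R, x$P, x$n_perm,
              x$alternative))
  if (x$partial) cat(sprintf("  controlling: %s\n", x$control_used))
  cat(sprintf("  IBD fit: slope = %.4g, intercept = %.4g, R2 = %.3f over %d pairs\n",
              x$slope, x$intercept, x$r2, x$n_pairs))
  invisible(x)
}

#' Partial Mantel test
#'
#' First-order partial correlation of `a` and `b` given `control`,
#' computed from the three pairwise matrix correlations; significance by
#' permuting matrix `a` and recomputing the partial statistic (add-one
#' p-value). A residual-based variant (`method = "residual"`: correlate
#' the residuals of `a` and `b` on `control`) is available.
#'
#' @inheritParams mantel_test
#' @param control the [dist_matrix()] held constant.
#' @param method `"first_order"` (default) or `"residual"`.
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(a, b, control, n_perm = 1000L, seed = NULL,
                                alternative = c("greater", "two.sided"),
                                method = c("first_order", "residual")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  check_same_labels(a, b, control)
  n <- nrow(a)
  lt <- lt_pairs(n)
  av <- a[lt]; bv <- b[lt]; cv <- control[lt]
  keep <- !is.na(av) & !is.na(bv) & !is.na(cv)
  if (sum(keep) < 4L) stop("fewer than 4 usable pairs", call. = FALSE)
  bv <- bv[keep]; cv <- cv[keep]
  stat <- function(avk, bvk = bv, cvk = cv) {
    if (method == "first_order") {
      r_ab <- stats::cor(avk, bvk); r_ac <- stats::cor(avk, cvk)
      r_bc <- stats::cor(bvk, cvk)
      if (abs(r_bc) >= 1 - 1e-12)
        stop("control matrix is collinear with b; partial undefined",
             call. = FALSE)
      if (abs(r_ac) >= 1 - 1e-12) return(0)  # a fully explained by control
      (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
    } else {
      ra <- stats::resid(stats::lm(avk ~ cvk))
      rb <- stats::resid(stats::lm(bvk ~ cvk))
      stats::cor(ra, rb)
    }
  }
  avk <- av[keep]
  if (stats::sd(avk) == 0 || stats::sd(bv) == 0)
    stop("zero variance in off-diagonal distances", call. = FALSE)
  R <- stat(avk)
  fit <- ls_fit(avk, bv)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      apv <- a[cbind(p[lt[, 1L]], p[lt[, 2L]])][keep]
      ok <- !is.na(apv)
      if (sum(ok) < 4L || stats::sd(apv[ok]) == 0) return(NA_real_)
      stat(apv[ok], bv[ok], cv[ok])
    }, numeric(1L))
  })
  P <- perm_pvalue(R, perm_R, alternative)
  structure(list(R = R, P = P, n_perm = n_perm,
                 slope = fit[["slope"]], intercept = fit[["intercept"]],
                 r2 = fit[["r2"]], n_pairs = sum(keep),
                 partial = TRUE, control_used = attr(control, "kind"),
                 alternative = alternative),
            class = "mantel_result")
}

#' Mask outlier population pairs in a distance matrix
#'
#' Sets the listed off-diagonal cells to `NA`. Downstream Mantel and
#' regression statistics are computed over the unmasked cells only, and
#' permutation nulls are re-evaluated over the same masked positions.
#'
#' @param d a [dist_matrix()].
#' @param pairs pairs to mask: a character vector like
#'   `c("P1-P4", "P2-P4")`, or a two-column matrix/data.frame of labels.
#' @return the masked `dist_matrix`.
#' @export
drop_pairs <- function(d, pairs) {
  stopifnot(inherits(d, "dist_matrix"))
  if (length(pairs) == 0L) return(d)
  if (is.character(pairs)) {
    pairs <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  labs <- rownames(d)
  if (!all(pairs %in% labs))
    stop("unknown population labels in pairs: ",
         paste(setdiff(as.vector(pairs), labs), collapse = ", "),
         call. = FALSE)
  for (k in seq_len(nrow(pairs))) {
    d[pairs[k, 1L], pairs[k, 2L]] <- NA
    d[pairs[k, 2L], pairs[k, 1L]] <- NA
  }
  if (sum(!is.na(d[lower.tri(d)])) < 3L)
    stop("masking leaves fewer than 3 usable pairs", call. = FALSE)
  d
}

#' Pairwise multilocus Fst from dominant (band presence) genotypes
#'
#' Assuming Hardy-Weinberg equilibrium, the recessive (band-absence)
#' allele frequency per locus and population is `q = sqrt(1 - f)` with
#' `f` the band frequency among individuals. The per-locus pairwise Fst
#' is the between-population variance of `q` over `q_bar (1 - q_bar)`,
#' and the multilocus value the ratio of averages across loci; negative
#' estimates are truncated at 0.
#'
#' @param genotypes individuals x loci 0/1 matrix.
#' @param pop_assign factor of population labels per individual.
#' @param loci_subset optional column names/indices restricting the loci.
#' @return an `fst` [dist_matrix()].
#' @export
dominant_fst <- function(genotypes, pop_assign, loci_subset = NULL) {
  pop_assign <- as.factor(pop_assign)
  if (nlevels(pop_assign) < 2L || any(table(pop_assign) < 2L))
    stop("need >= 2 populations with >= 2 individuals each", call. = FALSE)
  g <- if (is.null(loci_subset)) genotypes
       else genotypes[, loci_subset, drop = FALSE]
  f <- rowsum(g, pop_assign) / as.integer(table(pop_assign))
  if (all(f == 1))
    stop("band frequency 1 everywhere: Fst undefined", call. = FALSE)
  q <- sqrt(pmax(1 - f, 0))
  dist_matrix(fst_from_q(q), kind = "fst")
}

#' Neutral envelope of isolation-by-distance slopes
#'
#' Draws `n_subsets` seeded random subsets of `subset_size` loci from
#' dominant neutral genotypes, computes the pairwise multilocus Fst
#' matrix of each subset, regresses it on geographic distance, and
#' records the distribution of regression slopes and R-squared values.
#' Degenerate draws (zero Fst variance) are discarded, logged and
#' redrawn. Use [envelope_verdict()] to check whether an observed MHC
#' slope or R-squared lies inside the envelope.
#'
#' @param genotypes,pop_assign as in [dominant_fst()].
#' @param geo geographic [dist_matrix()] (labels matching the
#'   populations).
#' @param subset_size loci per draw.
#' @param n_subsets number of draws (default 100, minimum 10).
#' @param seed optional RNG seed.
#' @return list of class `slope_envelope`: `slopes`, `r2s`, `min_r2`,
#'   `max_r2`, `min_slope`, `max_slope`, `subset_size`, `n_subsets`,
#'   `n_degenerate`.
#' @export
neutral_slope_envelope <- function(genotypes, pop_assign, geo, subset_size,
                                   n_subsets = 100L, seed = NULL) {
  if (subset_size > ncol(genotypes))
    stop("subset_size exceeds locus count", call. = FALSE)
  if (n_subsets < 10L) stop("n_subsets must be >= 10", call. = FALSE)
  pop_assign <- as.factor(pop_assign)
  lt <- lower.tri(geo)
  gv <- geo[lt]
  with_seed(seed, {
    slopes <- r2s <- numeric(n_subsets)
    n_degenerate <- 0L
    k <- 1L
    while (k <= n_subsets) {
      loci <- sample.int(ncol(genotypes), subset_size)
      fst <- dominant_fst(genotypes, pop_assign, loci)
      fv <- fst[lt]
      if (stats::sd(fv) == 0) { n_degenerate <- n_degenerate + 1L; next }
      fit <- ls_fit(gv, fv)
      slopes[k] <- fit[["slope"]]; r2s[k] <- fit[["r2"]]
      k <- k + 1L
    }
    structure(list(slopes = slopes, r2s = r2s,
                   min_slope = min(slopes), max_slope = max(slopes),
                   min_r2 = min(r2s), max_r2 = max(r2s),
                   subset_size = subset_size, n_subsets = n_subsets,
                   n_degenerate = n_degenerate),
              class = "slope_envelope")
  })
}

#' @export
print.slope_envelope <- function(x, ...) {
  cat(sprintf("Neutral IBD slope envelope (%d subsets of %d loci)\n",
              x$n_subsets, x$subset_size))
  cat(sprintf("  slopes: [%.4g, %.4g]   R2: [%.3f, %.3f]\n",
              x$min_slope, x$max_slope, x$min_r2, x$max_r2))
  invisible(x)
}

#' Is an observed slope or R-squared inside the neutral envelope?
#'
#' @param envelope a [neutral_slope_envelope()] result.
#' @param slope,r2 observed values to compare (either or both).
#' @return list: `within_slope`, `within_r2` (NA when not supplied).
#' @export
envelope_verdict <- function(envelope, slope = NULL, r2 = NULL) {
  stopifnot(inherits(envelope, "slope_envelope"))
  list(
    within_slope = if (is.null(slope)) NA else
      slope >= envelope$min_slope & slope <= envelope$max_slope,
    within_r2 = if (is.null(r2)) NA else
      r2 >= envelope$min_r2 & r2 <= envelope$max_r2)
}
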