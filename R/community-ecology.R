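#' Filter classified 16S records and build the community table
#'
#' Removes records whose read length is below `min_len` or whose
#' taxon-assignment bootstrap is below `min_bootstrap` (strictly below:
#' a bootstrap of exactly the threshold is kept), keeping per-rule
#' counters, then aggregates the survivors into a taxa x populations
#' count matrix. "Unclassified X" taxa are distinct units keyed by their
#' lowest assigned rank. The default length threshold is 200 bp; 250 bp
#' (the expected amplicon size) is available by argument.
#'
#' @param records data.frame with columns `taxon`, `population`,
#'   `count` (optional; default 1 per row), `bootstrap` (in `[0,1]`),
#'   `length` (bases).
#' @param min_len minimum read length (default 200).
#' @param min_bootstrap minimum assignment bootstrap (default 0.5).
#' @return list of class `community_table`: `counts` (taxa x populations
#'   integer matrix), `pathogen_flag` (named logical, all `FALSE` until
#'   [flag_pathogens()]), `n_input`, `n_removed_length`,
#'   `n_removed_bootstrap`, `n_retained`.
#' @export
filter_records <- function(records, min_len = 200L, min_bootstrap = 0.5) {
  stopifnot(all(c("taxon", "population", "bootstrap", "length") %in%
                  names(records)))
  if (is.null(records$count)) records$count <- 1L
  fail_len <- records$length < min_len
  fail_boot <- !fail_len & records$bootstrap < min_bootstrap
  keep <- !fail_len & !fail_boot
  kept <- records[keep, , drop = FALSE]
  if (!nrow(kept)) {
    warning("all records removed by the QC filters")
    counts <- matrix(0L, 0L, 0L)
  } else {
    counts <- as.matrix(stats::xtabs(count ~ taxon + population,
                                     data = kept))
    counts <- counts[order(rownames(counts)), , drop = FALSE]
    storage.mode(counts) <- "integer"
  }
  structure(list(counts = counts,
                 pathogen_flag = stats::setNames(
                   rep(FALSE, nrow(counts)), rownames(counts)),
                 n_input = nrow(records),
                 n_removed_length = sum(fail_len),
                 n_removed_bootstrap = sum(fail_boot),
                 n_retained = nrow(kept)),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d taxa x %d populations (%d flagged pathogenic)\n",
              nrow(x$counts), ncol(x$counts), sum(x$pathogen_flag)))
  cat(sprintf("  records: %d in, %d removed (length %d, bootstrap %d), %d kept\n",
              x$n_input, x$n_removed_length + x$n_removed_bootstrap,
              x$n_removed_length, x$n_removed_bootstrap, x$n_retained))
  invisible(x)
}

#' Flag pathogenic taxa in a community table
#'
#' Case-insensitive exact name matching against a pathogen list; the
#' default list is the seven-taxon fish-pathogen set of
#' [austin_pathogens()].
#'
#' @param tab a [filter_records()] community table.
#' @param pathogen_list character vector of taxon names.
#' @return the table with `pathogen_flag` updated.
#' @export
flag_pathogens <- function(tab, pathogen_list = austin_pathogens()) {
  stopifnot(inherits(tab, "community_table"))
  if (!length(pathogen_list)) {
    warning("empty pathogen list: no taxa flagged")
    tab$pathogen_flag[] <- FALSE
    return(tab)
  }
  tab$pathogen_flag <- stats::setNames(
    tolower(rownames(tab$counts)) %in% tolower(pathogen_list),
    rownames(tab$counts))
  tab
}

#' Per-population species richness
#'
#' Number of taxa with nonzero count per population, within the
#' requested partition of the community.
#'
#' @param tab a [flag_pathogens()] community table.
#' @param partition `"all"`, `"pathogen"` or `"nonpathogen"`.
#' @return named integer vector, one count per population.
#' @export
richness <- function(tab, partition = c("all", "pathogen", "nonpathogen")) {
  partition <- match.arg(partition)
  stopifnot(inherits(tab, "community_table"))
  rows <- switch(partition, all = rep(TRUE, nrow(tab$counts)),
                 pathogen = tab$pathogen_flag,
                 nonpathogen = !tab$pathogen_flag)
  m <- tab$counts[rows, , drop = FALSE]
  stats::setNames(as.integer(colSums(m > 0L)), colnames(tab$counts))
}

#' Bray-Curtis (or other) dissimilarities between population communities
#'
#' Convenience wrapper building a sample dissimilarity matrix from a
#' community table partition via [vegan::vegdist()].
#'
#' @param tab a community table.
#' @param partition as in [richness()].
#' @param method dissimilarity index (default `"bray"`).
#' @return a raw [dist_matrix()] over populations.
#' @export
community_dissimilarity <- function(tab, partition = "all",
                                    method = "bray") {
  rows <- switch(partition, all = rep(TRUE, nrow(tab$counts)),
                 pathogen = tab$pathogen_flag,
                 nonpathogen = !tab$pathogen_flag)
  m <- t(tab$counts[rows, , drop = FALSE])
  keep <- rowSums(m) > 0
  dist_matrix(as.matrix(vegan::vegdist(m[keep, , drop = FALSE],
                                       method = method)),
              kind = "raw")
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Distance-based permutational multivariate analysis of variance
#' (ADONIS-style) with a single grouping factor. The total sum of
#' squares is `sum(d^2)/N` over all sample pairs, the within-group part
#' the analogous sum within groups, and
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))`. Significance is
#' obtained by permuting the group labels (add-one p-value).
#'
#' @param dissim a [dist_matrix()] over samples.
#' @param groups factor of group labels, one per sample.
#' @param n_perm permutations (default 999).
#' @param seed optional RNG seed.
#' @return list of class `permanova_result`: `pseudo_F`, `P`, `n_perm`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`.
#' @export
permanova <- function(dissim, groups, n_perm = 999L, seed = NULL) {
  groups <- as.factor(groups)
  N <- nrow(dissim)
  stopifnot(length(groups) == N)
  a <- nlevels(droplevels(groups))
  if (a < 2L) stop("need >= 2 groups", call. = FALSE)
  if (N - a < 1L)
    stop("within-group degrees of freedom are zero", call. = FALSE)
  d2 <- unclass(dissim)^2
  ss_total <- sum(d2[lower.tri(d2)]) / N
  ss_within_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L)
        s <- s + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  ssw <- ss_within_of(groups)
  ssb <- ss_total - ssw
  f_of <- function(ssw) ((ss_total - ssw) / (a - 1L)) / (ssw / (N - a))
  F_obs <- f_of(ssw)
  perm_F <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      f_of(ss_within_of(groups[sample.int(N)]))
    }, numeric(1L))
  })
  P <- (sum(perm_F >= F_obs) + 1) / (n_perm + 1)
  structure(list(pseudo_F = F_obs, P = P, n_perm = n_perm,
                 df_between = a - 1L, df_within = N - a,
                 ss_between = ssb, ss_within = ssw),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.3f, P = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$P, x$n_perm))
  invisible(x)
}
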