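# Nei-Gojobori (1986) pathway-counting estimation of synonymous and
# nonsynonymous substitution rates, with Jukes-Cantor correction.

# Cache of per-codon-pair pathway counts; filled lazily.
.ng_cache <- new.env(parent = emptyenv())

# Fraction of synonymous one-step changes per position, summed over the
# codon: potential synonymous sites s = sum_pos (n_syn / 3). Changes to
# stop codons count as nonsynonymous in the denominator of 3.
codon_syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  tab <- codon_table()
  aa <- tab[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      cand <- codon
      substr(cand, pos, pos) <- b
      if (!cand %in% STOP_CODONS && tab[[cand]] == aa) s <- s + 1 / 3
    }
  }
  .ng_cache[[key]] <- s
  s
}

# Pathway-averaged observed synonymous/nonsynonymous differences between
# two codons: enumerate all orderings of the differing positions,
# exclude pathways passing through stop codons (fall back to all
# pathways if every one is blocked), and average the per-step counts.
codon_pair_diffs <- function(a, b) {
  key <- paste0(a, "_", b)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  tab <- codon_table()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  res <- if (k == 0L) c(Nd = 0, Sd = 0) else {
    perms <- all_permutations(pos)
    path_counts <- matrix(NA_real_, nrow(perms), 2L)
    blocked <- logical(nrow(perms))
    for (w in seq_len(nrow(perms))) {
      cur <- a; sd <- 0; nd <- 0
      for (p in perms[w, ]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (nxt %in% STOP_CODONS) { blocked[w] <- TRUE; break }
        if (tab[[nxt]] == tab[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked[w]) path_counts[w, ] <- c(nd, sd)
    }
    use <- !blocked
    if (!any(use)) {        # all pathways pass through a stop: count anyway
      for (w in seq_len(nrow(perms))) {
        cur <- a; sd <- 0; nd <- 0
        for (p in perms[w, ]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(b, p, p)
          if (!nxt %in% STOP_CODONS && tab[[nxt]] == tab[[cur]])
            sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        path_counts[w, ] <- c(nd, sd)
      }
      use <- rep(TRUE, nrow(perms))
    }
    c(Nd = mean(path_counts[use, 1L]), Sd = mean(path_counts[use, 2L]))
  }
  .ng_cache[[key]] <- res
  res
}

all_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_permutations(v[-i])))
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`; returns `NA` (saturation) when
#' `p >= 3/4`.
#'
#' @param p proportion of differences per site.
#' @return corrected distance.
#' @export
jukes_cantor <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Nei-Gojobori synonymous/nonsynonymous rates for one sequence pair
#'
#' Pathway-counting method: potential synonymous sites per codon are the
#' per-position fractions of synonymous one-step changes (averaged
#' between the two sequences), observed differences are averaged over
#' all minimal mutational pathways between differing codons (pathways
#' through stop codons excluded), and proportions are Jukes-Cantor
#' corrected. Codons where either sequence has a gap are skipped.
#'
#' @param a,b in-frame DNA strings of equal length (no stop codons).
#' @return list: `Nd`, `Sd`, `n_sites`, `s_sites`, `pN`, `pS`, `dN`,
#'   `dS`, `saturated` (logical; correction undefined at p >= 3/4).
#' @examples
#' nei_gojobori_pair("TTT", "TTA")
#' @export
nei_gojobori_pair <- function(a, b) {
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3L == 0L)
  ca <- split_codons(toupper(a)); cb <- split_codons(toupper(b))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (any(c(ca, cb) %in% STOP_CODONS))
    stop("stop codons in input sequences", call. = FALSE)
  Nd <- 0; Sd <- 0; s_sites <- 0
  for (i in seq_along(ca)) {
    s_sites <- s_sites + (codon_syn_sites(ca[i]) + codon_syn_sites(cb[i])) / 2
    d <- codon_pair_diffs(ca[i], cb[i])
    Nd <- Nd + d[["Nd"]]; Sd <- Sd + d[["Sd"]]
  }
  n_sites <- 3 * length(ca) - s_sites
  pN <- if (n_sites > 0) Nd / n_sites else 0
  pS <- if (s_sites > 0) Sd / s_sites else 0
  list(Nd = Nd, Sd = Sd, n_sites = n_sites, s_sites = s_sites,
       pN = pN, pS = pS, dN = jukes_cantor(pN), dS = jukes_cantor(pS),
       saturated = (pN >= 0.75) || (pS >= 0.75))
}

# Per-pair, per-codon component arrays over a codon alignment subset:
# lists of pairs x codons matrices (Nd, Sd, n_sites, s_sites).
ng_components <- function(aln, codons) {
  n <- nrow(aln)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs); nc <- length(codons)
  Nd <- Sd <- ns <- ss <- matrix(0, np, nc)
  for (k in seq_len(np)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    for (c0 in seq_len(nc)) {
      ca <- toupper(aln[i, codons[c0]]); cb <- toupper(aln[j, codons[c0]])
      if (grepl("-", ca, fixed = TRUE) || grepl("-", cb, fixed = TRUE)) {
        ns[k, c0] <- NA; next
      }
      sa <- codon_syn_sites(ca); sb <- codon_syn_sites(cb)
      ss[k, c0] <- (sa + sb) / 2
      ns[k, c0] <- 3 - ss[k, c0]
      d <- codon_pair_diffs(ca, cb)
      Nd[k, c0] <- d[["Nd"]]; Sd[k, c0] <- d[["Sd"]]
    }
  }
  list(Nd = Nd, Sd = Sd, n_sites = ns, s_sites = ss)
}

# Mean pairwise dN and dS from component matrices and codon weights.
ng_mean_rates <- function(cmp, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(cmp$Nd))
  wN <- function(m) as.numeric(m %*% w)
  ok <- !is.na(cmp$n_sites)
  NdW <- as.numeric(ifelse(ok, cmp$Nd, 0) %*% w)
  SdW <- as.numeric(ifelse(ok, cmp$Sd, 0) %*% w)
  nsW <- as.numeric(ifelse(ok, cmp$n_sites, 0) %*% w)
  ssW <- as.numeric(ifelse(ok, cmp$s_sites, 0) %*% w)
  pN <- ifelse(nsW > 0, NdW / nsW, 0)
  pS <- ifelse(ssW > 0, SdW / ssW, 0)
  c(dN = mean(jukes_cantor(pN), na.rm = TRUE),
    dS = mean(jukes_cantor(pS), na.rm = TRUE))
}

#' Codon-bootstrap Z-test of positive selection
#'
#' Estimates mean pairwise Nei-Gojobori `dN` and `dS` over the codons of
#' one partition (PBR, non-PBR or all), and tests the one-tailed null
#' `dN = dS` against positive selection (`dN > dS`) with
#' `Z = (dN - dS) / SE`, the standard error taken from a seeded codon
#' bootstrap (`n_boot` resamples of the partition codons); P is the
#' upper normal tail.
#'
#' @param aln a [codon_alignment()] of retained variants.
#' @param mask a [pbr_mask()].
#' @param partition `"all"`, `"PBR"` or `"non-PBR"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @return data.frame row: partition, n_codons, dN, dS, ratio, Z, P.
#' @export
z_test_selection <- function(aln, mask,
                             partition = c("all", "PBR", "non-PBR"),
                             n_boot = 1000L, seed = NULL) {
  partition <- match.arg(partition)
  stopifnot(inherits(aln, "codon_alignment"), nrow(aln) >= 2L)
  codons <- switch(partition, all = seq_len(mask$n_codons),
                   PBR = mask$pbr_codons, `non-PBR` = mask$nonpbr_codons)
  if (length(codons) < 3L)
    stop("partition has fewer than 3 codons; bootstrap degenerate",
         call. = FALSE)
  cmp <- ng_components(aln, codons)
  obs <- ng_mean_rates(cmp)
  dN <- obs[["dN"]]; dS <- obs[["dS"]]
  delta <- dN - dS
  if (!is.finite(delta) || (dN == 0 && dS == 0)) {
    z <- 0; p <- 1; se <- 0
  } else {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        w <- tabulate(sample.int(length(codons), replace = TRUE),
                      nbins = length(codons))
        r <- ng_mean_rates(cmp, w)
        r[["dN"]] - r[["dS"]]
      }, numeric(1L))
    })
    se <- stats::sd(boot, na.rm = TRUE)
    if (!is.finite(se) || se == 0) { z <- 0; p <- 1 }
    else { z <- delta / se; p <- stats::pnorm(z, lower.tail = FALSE) }
  }
  data.frame(partition = partition, n_codons = length(codons),
             dN = dN, dS = dS,
             ratio = if (is.finite(dS) && dS > 0) dN / dS else NA_real_,
             Z = z, P = p, stringsAsFactors = FALSE)
}

#' Selection summary over all codon partitions
#'
#' Tabulates the codon-bootstrap Z-test for the non-PBR, PBR and full
#' codon sets of one locus, mirroring the usual per-locus selection
#' table of pooled MHC surveys.
#'
#' @inheritParams z_test_selection
#' @return data.frame with one row per partition.
#' @export
selection_table <- function(aln, mask, n_boot = 1000L, seed = NULL) {
  parts <- c("non-PBR", "PBR", "all")
  out <- do.call(rbind, lapply(seq_along(parts), function(i) {
    z_test_selection(aln, mask, parts[i], n_boot = n_boot,
                     seed = if (is.null(seed)) NULL else seed + i)
  }))
  out$locus <- mask$locus
  out[, c("locus", setdiff(names(out), "locus"))]
}
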