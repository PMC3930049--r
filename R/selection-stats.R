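#' In-frame codon alignment
#'
#' Builds a codon alignment from equal-length, in-frame, possibly gapped
#' DNA sequences (as produced by [screen_frameshift()]). Stored as a
#' character matrix of codon triplets, sequences x codons. Codons
#' containing any gap character are treated as missing at translation.
#'
#' @param seqs named character vector; equal lengths, multiples of 3.
#' @return character matrix of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  n <- unique(nchar(seqs))
  if (length(n) != 1L || n %% 3L != 0L)
    stop("sequences must share one length divisible by 3", call. = FALSE)
  m <- t(vapply(seqs, split_codons, character(n / 3L)))
  if (n / 3L == 1L) m <- matrix(m, ncol = 1L, dimnames = list(names(seqs)))
  class(m) <- c("codon_alignment", class(m))
  m
}

# Amino-acid matrix of a codon alignment; gap/ambiguous codons are NA.
translate_alignment <- function(aln) {
  aa <- matrix(translate_codon(toupper(aln)), nrow(aln), ncol(aln),
               dimnames = dimnames(aln))
  aa[grepl("-", aln, fixed = TRUE)] <- NA_character_
  aa[aa == "X"] <- NA_character_
  aa
}

#' Peptide-binding-region codon mask
#'
#' @param locus locus label (e.g. `"DAB1"`).
#' @param n_codons total codons in the alignment.
#' @param pbr_codons 1-based PBR codon indices; defaults to
#'   [default_pbr_codons()].
#' @return list of class `pbr_mask` with `locus`, `n_codons`,
#'   `pbr_codons`, `nonpbr_codons`.
#' @export
pbr_mask <- function(locus, n_codons, pbr_codons = NULL) {
  if (is.null(pbr_codons)) pbr_codons <- default_pbr_codons(n_codons)
  pbr_codons <- sort(unique(as.integer(pbr_codons)))
  if (any(pbr_codons < 1L | pbr_codons > n_codons))
    stop("pbr_codons must lie in 1..n_codons", call. = FALSE)
  structure(list(locus = locus, n_codons = as.integer(n_codons),
                 pbr_codons = pbr_codons,
                 nonpbr_codons = setdiff(seq_len(n_codons), pbr_codons)),
            class = "pbr_mask")
}

#' @export
print.pbr_mask <- function(x, ...) {
  cat(sprintf("PBR mask %s: %d PBR + %d non-PBR = %d codons\n", x$locus,
              length(x$pbr_codons), length(x$nonpbr_codons), x$n_codons))
  invisible(x)
}

#' Per-codon amino-acid diversity (DIVAA)
#'
#' For each codon column the diversity is the inverse participation
#' ratio of the observed amino-acid frequencies scaled by the alphabet
#' size: `D = 1 / (20 * sum(p_i^2))`, ranging from 0.05 (conserved) to 1
#' (all twenty residues equally frequent). Gap codons are excluded from
#' the frequencies. `D_rescaled = (D - 0.05) / 0.95` maps the statistic
#' onto `[0, 1]`. Entirely-gap columns are flagged `NA` and excluded
#' from partition means.
#'
#' @param aln a [codon_alignment()] (>= 2 sequences).
#' @param mask a [pbr_mask()] for the alignment.
#' @return data.frame of class `site_diversity` with columns `codon`,
#'   `partition`, `D`, `D_rescaled`, `polymorphic`, plus attribute
#'   `partition_means`.
#' @examples
#' aln <- codon_alignment(c(a = "GCTGCT", b = "GCTTCT"))
#' site_diversity(aln, pbr_mask("toy", 2, 1))
#' @export
site_diversity <- function(aln, mask) {
  stopifnot(inherits(aln, "codon_alignment"), nrow(aln) >= 2L,
            inherits(mask, "pbr_mask"), ncol(aln) == mask$n_codons)
  aa <- translate_alignment(aln)
  D <- apply(aa, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    p <- as.numeric(table(col)) / length(col)
    1 / (20 * sum(p^2))
  })
  poly <- apply(aa, 2L, function(col) length(unique(col[!is.na(col)])) > 1L)
  part <- ifelse(seq_len(ncol(aln)) %in% mask$pbr_codons, "PBR", "non-PBR")
  out <- data.frame(codon = seq_len(ncol(aln)), partition = part,
                    D = D, D_rescaled = (D - 0.05) / 0.95,
                    polymorphic = poly, stringsAsFactors = FALSE)
  attr(out, "partition_means") <- c(
    PBR = mean(D[part == "PBR"], na.rm = TRUE),
    `non-PBR` = mean(D[part == "non-PBR"], na.rm = TRUE),
    all = mean(D, na.rm = TRUE))
  class(out) <- c("site_diversity", class(out))
  out
}

#' Percentage of polymorphic codons by partition
#'
#' A codon is polymorphic iff at least two distinct amino acids occur
#' among the selected sequences. Percentages are reported over the PBR,
#' non-PBR and all codons. `which_seqs` restricts the computation to a
#' subset of sequences (e.g. the variants present in one population).
#'
#' @param aln a [codon_alignment()].
#' @param mask a [pbr_mask()].
#' @param which_seqs optional row names or indices selecting sequences.
#' @return named numeric vector: `pct_pbr`, `pct_nonpbr`, `pct_all`.
#' @export
percent_polymorphic <- function(aln, mask, which_seqs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(mask, "pbr_mask"))
  sub <- if (is.null(which_seqs)) aln else aln[which_seqs, , drop = FALSE]
  if (nrow(sub) < 2L) {
    warning("fewer than 2 sequences selected; reporting zero polymorphism")
    return(c(pct_pbr = 0, pct_nonpbr = 0, pct_all = 0))
  }
  aa <- translate_alignment(sub)
  poly <- apply(aa, 2L, function(col) length(unique(col[!is.na(col)])) > 1L)
  c(pct_pbr = 100 * mean(poly[mask$pbr_codons]),
    pct_nonpbr = 100 * mean(poly[mask$nonpbr_codons]),
    pct_all = 100 * mean(poly))
}

#' Per-population percent polymorphism from a presence matrix
#'
#' Restricts the retained-variant alignment to the variants present in
#' each population and reports the percentage of polymorphic codons per
#' partition, the per-population quantity used by the association tests.
#'
#' @param aln retained-variant [codon_alignment()].
#' @param mask a [pbr_mask()].
#' @param presence binary populations x variants matrix
#'   ([build_presence_matrix()]).
#' @return data.frame: population, n_variants, pct_pbr, pct_nonpbr,
#'   pct_all.
#' @export
percent_polymorphic_by_pop <- function(aln, mask, presence) {
  vars <- intersect(colnames(presence), rownames(aln))
  res <- lapply(rownames(presence), function(p) {
    present <- vars[presence[p, vars] > 0]
    pct <- if (length(present) >= 2L)
      percent_polymorphic(aln, mask, present)
    else c(pct_pbr = 0, pct_nonpbr = 0, pct_all = 0)
    data.frame(population = p, n_variants = length(present),
               pct_pbr = pct[["pct_pbr"]], pct_nonpbr = pct[["pct_nonpbr"]],
               pct_all = pct[["pct_all"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' returning the statistic, Satterthwaite (fractional) degrees of
#' freedom and p-value.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
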