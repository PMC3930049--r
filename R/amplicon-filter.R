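#' Assign multiplexed reads to population pools by tag and primer
#'
#' A read is assigned to the unique pool whose 5-base tag matches the
#' read start exactly and whose forward or reverse primer matches
#' immediately downstream within `max_primer_mismatch` mismatches. Tag
#' and primer are stripped; reads matching the reverse primer are
#' reverse-complemented into forward orientation. Tags tolerate no
#' mismatches (5-bp tags have no safe mismatch margin), primers default
#' to one.
#'
#' @param reads named character vector of reads (e.g. from
#'   [read_fasta()]).
#' @param pools data.frame with columns `pop_id`, `tag`, `fwd_primer`,
#'   `rev_primer`.
#' @param max_primer_mismatch maximum primer mismatches (default 1).
#' @return list: `pools` (named list of per-pool named insert vectors),
#'   `n_assigned`, `n_unassigned`, `unassigned_ids`.
#' @export
demultiplex <- function(reads, pools, max_primer_mismatch = 1L) {
  if (nrow(pools) == 0L) stop("empty pool table", call. = FALSE)
  if (anyDuplicated(pools$tag))
    stop("duplicate tags in pool table", call. = FALSE)
  if (any(nchar(pools$tag) != 5L))
    stop("tags must be exactly 5 bases", call. = FALSE)

  out <- stats::setNames(vector("list", nrow(pools)), pools$pop_id)
  assigned <- rep(FALSE, length(reads))
  tag_of <- substr(reads, 1L, 5L)
  for (p in seq_len(nrow(pools))) {
    hit <- which(tag_of == pools$tag[p] & !assigned)
    if (!length(hit)) { out[[p]] <- character(0); next }
    rest <- substring(reads[hit], 6L)
    fl <- nchar(pools$fwd_primer[p]); rl <- nchar(pools$rev_primer[p])
    fwd_ok <- nchar(rest) >= fl &
      hamming(substr(rest, 1L, fl), pools$fwd_primer[p]) <= max_primer_mismatch
    rev_ok <- !fwd_ok & nchar(rest) >= rl &
      hamming(substr(rest, 1L, rl), pools$rev_primer[p]) <= max_primer_mismatch
    ins <- character(length(hit))
    ins[fwd_ok] <- substring(rest[fwd_ok], fl + 1L)
    if (any(rev_ok)) ins[rev_ok] <- revcomp(substring(rest[rev_ok], rl + 1L))
    keep <- fwd_ok | rev_ok
    out[[p]] <- stats::setNames(ins[keep], names(reads)[hit][keep])
    assigned[hit[keep]] <- TRUE
  }
  if (!any(assigned) && length(reads))
    warning("no reads could be assigned to any pool")
  list(pools = out, n_assigned = sum(assigned),
       n_unassigned = sum(!assigned),
       unassigned_ids = names(reads)[!assigned])
}

#' Truncate reads to a common length
#'
#' Reads longer than `L` are cut to their first `L` bases; reads shorter
#' than `L` are discarded and counted, so every surviving read has equal
#' length and exact string identity defines a variant downstream.
#'
#' @param reads named character vector (or per-pool list of such).
#' @param L truncation length in bases (default 220).
#' @return list: `reads` (same shape as input), `n_discarded`.
#' @export
truncate_reads <- function(reads, L = 220L) {
  stopifnot(L > 0L)
  trunc1 <- function(x) {
    keep <- nchar(x) >= L
    list(reads = substr(x[keep], 1L, L), n = sum(!keep))
  }
  if (is.list(reads)) {
    res <- lapply(reads, trunc1)
    list(reads = lapply(res, `[[`, "reads"),
         n_discarded = sum(vapply(res, `[[`, 0L, "n")))
  } else {
    r <- trunc1(reads)
    list(reads = r$reads, n_discarded = r$n)
  }
}

#' Collapse per-pool reads into unique variants with per-pool counts
#'
#' Exact string identity (any single base or indel difference separates
#' variants) defines a variant. Variants receive deterministic ids
#' ordered by total count (descending) then sequence (lexicographic).
#'
#' @param pool_reads named list: population -> character vector of
#'   equal-length reads.
#' @return object of class `variant_table`: data.frame `records`
#'   (variant_id, sequence, total, status, reason) plus integer `counts`
#'   matrix (variants x populations).
#' @export
collapse_variants <- function(pool_reads) {
  pops <- names(pool_reads)
  seqs <- sort(unique(unlist(pool_reads, use.names = FALSE)))
  counts <- vapply(pool_reads, function(r) {
    tab <- table(factor(r, levels = seqs))
    as.integer(tab)
  }, integer(length(seqs)))
  if (length(seqs) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- pops
  total <- rowSums(counts)
  ord <- order(-total, seqs)
  seqs <- seqs[ord]; counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("V%04d", seq_along(seqs))
  rownames(counts) <- ids
  records <- data.frame(
    variant_id = ids, sequence = seqs, total = as.integer(total[ord]),
    status = "retained", reason = "none", stringsAsFactors = FALSE)
  structure(list(records = records, counts = counts),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  ret <- sum(x$records$status == "retained")
  cat(sprintf("Variant table: %d variants x %d populations (%d retained)\n",
              nrow(x$records), ncol(x$counts), ret))
  if (any(x$records$status == "removed")) {
    print(table(reason = x$records$reason[x$records$status == "removed"]))
  }
  invisible(x)
}

#' Remove count-based artifact variants (singletons, single-population)
#'
#' Implements the stepwise abundance rules distinguishing true variants
#' (TV) from artifactual variants (AV): a variant is removed with reason
#' `"singleton"` if it appears only once, and with reason
#' `"single_population"` if it occurs in fewer than two populations; the
#' first matching rule is recorded. Under the default `"global"` scope a
#' singleton is a variant with total count <= 1 across all pools (so one
#' read in each of two pools is retained); `"per_pool"` additionally
#' requires a count >= 2 in at least one pool.
#'
#' @param vt a [collapse_variants()] table.
#' @param singleton_scope `"global"` (default) or `"per_pool"`.
#' @return the updated `variant_table`.
#' @export
filter_artifacts <- function(vt, singleton_scope = c("global", "per_pool")) {
  singleton_scope <- match.arg(singleton_scope)
  stopifnot(inherits(vt, "variant_table"))
  live <- vt$records$status == "retained"
  singleton <- if (singleton_scope == "global") vt$records$total <= 1L
    else apply(vt$counts, 1L, max) <= 1L
  n_pops_present <- rowSums(vt$counts > 0L)
  rm_singleton <- live & singleton
  rm_single_pop <- live & !singleton & n_pops_present < 2L
  vt$records$status[rm_singleton | rm_single_pop] <- "removed"
  vt$records$reason[rm_singleton] <- "singleton"
  vt$records$reason[rm_single_pop] <- "single_population"
  vt
}

#' Screen variants for frameshift indels against a reference exon
#'
#' Globally aligns each retained variant to the in-frame reference exon
#' (reference fully aligned, variant flanks trimmed to the exon bounds,
#' removing partial intron-like sequence), then removes any variant whose
#' alignment contains an indel run of length not divisible by three
#' (reason `"frameshift"`). Variants scoring below
#' `min_score_frac * nchar(reference)` are removed as `"unalignable"`.
#' Survivors are returned as a reference-anchored in-frame codon
#' alignment; codons overlapping a (3k) deletion appear as gap codons,
#' and in-frame insertions relative to the reference are trimmed out of
#' the projection.
#'
#' Because the trimming removes flanking non-exonic sequence, distinct
#' truncated read variants can become identical within the exon (e.g.
#' variants differing only by a flank indel). Such duplicates are merged
#' into the highest-count representative -- their counts are added to it
#' and they are removed with reason `"duplicate_after_trim"` -- so
#' retained true variants are unique exon sequences.
#'
#' Alignment scoring: match +1, mismatch -1, a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param vt a `variant_table`.
#' @param reference in-frame reference exon DNA string (no stop codons).
#' @param gap_open,gap_extend gap penalties (defaults 4 and 1).
#' @param min_score_frac unalignable floor as a fraction of the maximum
#'   attainable score (default 0.5).
#' @return list: `variants` (updated table), `alignment` (a
#'   [codon_alignment()] of retained variants).
#' @export
screen_frameshift <- function(vt, reference, gap_open = 4, gap_extend = 1,
                              min_score_frac = 0.5) {
  stopifnot(inherits(vt, "variant_table"))
  reference <- toupper(reference)
  if (nchar(reference) %% 3L != 0L)
    stop("reference must be in frame", call. = FALSE)
  if (any(translate_codon(split_codons(reference)) == "*"))
    stop("reference contains stop codons", call. = FALSE)

  live <- which(vt$records$status == "retained")
  aligned <- rep(NA_character_, nrow(vt$records))
  vt$records$exon_sequence <- NA_character_
  if (length(live)) {
    subs <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(vt$records$sequence[live]),
      Biostrings::DNAString(reference),
      substitutionMatrix = subs, type = "local-global",
      gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
    scores <- Biostrings::score(aln)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    floor_score <- min_score_frac * nchar(reference)
    for (k in seq_along(live)) {
      i <- live[k]
      if (scores[k] < floor_score) {
        vt$records$status[i] <- "removed"
        vt$records$reason[i] <- "unalignable"
        next
      }
      runs <- indel_run_lengths(pat[k], sub[k])
      if (any(runs %% 3L != 0L)) {
        vt$records$status[i] <- "removed"
        vt$records$reason[i] <- "frameshift"
        next
      }
      pc <- strsplit(pat[k], "")[[1]]
      sc <- strsplit(sub[k], "")[[1]]
      aligned[i] <- paste(pc[sc != "-"], collapse = "")
    }
    vt$records$exon_sequence <- aligned
    # merge variants identical within the exon after flank trimming
    surv <- which(vt$records$status == "retained")
    if (length(surv) > 1L) {
      grp <- split(surv, aligned[surv])
      for (g in grp) {
        if (length(g) > 1L) {
          rep_i <- g[1L]            # records are count-ordered
          dup <- g[-1L]
          vt$counts[rep_i, ] <- vt$counts[rep_i, ] +
            colSums(vt$counts[dup, , drop = FALSE])
          vt$records$total[rep_i] <- sum(vt$counts[rep_i, ])
          vt$records$status[dup] <- "removed"
          vt$records$reason[dup] <- "duplicate_after_trim"
        }
      }
    }
  }
  keep <- vt$records$status == "retained"
  alignment <- if (any(keep)) {
    codon_alignment(stats::setNames(aligned[keep],
                                    vt$records$variant_id[keep]))
  } else NULL
  list(variants = vt, alignment = alignment)
}

# Lengths of all gap runs in either aligned string.
indel_run_lengths <- function(pattern, subject) {
  runs <- function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    r$lengths[r$values]
  }
  c(runs(pattern), runs(subject))
}

#' Build the presence-absence matrix of retained variants
#'
#' @param vt a `variant_table` after filtering.
#' @return binary integer matrix, populations x retained variants.
#' @export
build_presence_matrix <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- vt$records$status == "retained"
  if (!any(keep))
    stop("no retained variants; review filtering parameters", call. = FALSE)
  m <- t(vt$counts[keep, , drop = FALSE] > 0L) * 1L
  colnames(m) <- vt$records$variant_id[keep]
  m
}

#' Run the full amplicon filtering chain
#'
#' Demultiplex, truncate, collapse, abundance-filter and frameshift-screen
#' multiplexed amplicon reads in the published order, returning the
#' variant table, presence-absence matrix, codon alignment and per-stage
#' counters.
#'
#' @param reads named character vector of multiplexed reads.
#' @param pools pool specification (`pop_id`, `tag`, `fwd_primer`,
#'   `rev_primer`).
#' @param reference in-frame reference exon sequence.
#' @param truncate_len truncation length (default 220).
#' @param max_primer_mismatch passed to [demultiplex()].
#' @param singleton_scope passed to [filter_artifacts()].
#' @param min_score_frac passed to [screen_frameshift()].
#' @return list of class `amplicon_filter`: `variants`, `presence`,
#'   `alignment`, `counters`.
#' @examples
#' cfg <- sim_config(seed = 1, n_pops = 3, depth_per_pool = 60,
#'                   n_alleles_global = 4)
#' sim <- simulate_pool_reads(cfg, simulate_allele_pool(cfg))
#' ref <- substr(sim$templates[[1]], 21, 20 + 3 * cfg$n_codons)
#' res <- filter_amplicons(sim$reads, sim$pools, ref)
#' res$counters$n_retained
#' @export
filter_amplicons <- function(reads, pools, reference, truncate_len = 220L,
                             max_primer_mismatch = 1L,
                             singleton_scope = "global",
                             min_score_frac = 0.5) {
  dmx <- demultiplex(reads, pools, max_primer_mismatch)
  trc <- truncate_reads(dmx$pools, truncate_len)
  vt <- collapse_variants(trc$reads)
  n0 <- nrow(vt$records)
  vt <- filter_artifacts(vt, singleton_scope)
  scr <- screen_frameshift(vt, reference, min_score_frac = min_score_frac)
  vt <- scr$variants
  counters <- list(
    n_reads = length(reads), n_assigned = dmx$n_assigned,
    n_unassigned = dmx$n_unassigned, n_short_discarded = trc$n_discarded,
    n_variants = n0,
    n_removed = table(factor(vt$records$reason[vt$records$status == "removed"],
                             levels = c("singleton", "single_population",
                                        "frameshift", "unalignable",
                                        "duplicate_after_trim"))),
    n_retained = sum(vt$records$status == "retained"))
  structure(list(variants = vt,
                 presence = build_presence_matrix(vt),
                 alignment = scr$alignment, counters = counters),
            class = "amplicon_filter")
}

#' @export
print.amplicon_filter <- function(x, ...) {
  cat("Amplicon filtering result\n")
  cat(sprintf("  reads: %d (%d assigned, %d unassigned, %d short)\n",
              x$counters$n_reads, x$counters$n_assigned,
              x$counters$n_unassigned, x$counters$n_short_discarded))
  cat(sprintf("  variants: %d -> %d retained\n", x$counters$n_variants,
              x$counters$n_retained))
  rm <- x$counters$n_removed
  cat("  removed: ", paste(sprintf("%s=%d", names(rm), rm), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
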