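# Read-level simulation of the pooled, tagged 454-style amplicon design.
# Amplicon geometry: each allele's sequencing template ("insert") is a
# fixed 5' flank, the coding exon, and a 3' flank padded to AMPLICON_LEN,
# mimicking a partially intronic amplicon longer than the exon itself.
AMPLICON_LEN <- 276L
FLANK5_LEN <- 20L
PRIMER_LEN <- 20L
TAG_LEN <- 5L

#' Simulate multiplexed pooled amplicon reads with known ground truth
#'
#' Emits one tagged read set per population pool. Each read is
#' `tag + forward primer + insert`, where the insert derives from one
#' allele template (or, for chimeric reads, the 5' part of one template
#' joined to the 3' part of another at a uniform breakpoint) and then
#' receives one-base homopolymer indels at rate `cfg$err_homopolymer` per
#' run (length >= 2) and substitution errors at `cfg$err_sub` per base.
#' Every read is attributable to exactly one allele or one artifact
#' record in the returned truth table.
#'
#' @param cfg a [sim_config()] object.
#' @param alleles global allele pool from [simulate_allele_pool()].
#' @param pool_counts alleles x populations copy-count matrix as produced
#'   by [draw_pool_alleles()]; drawn internally when `NULL`.
#' @param tag_map optional data.frame with columns `pop_id`, `tag`
#'   (unique 5-base tags); generated when `NULL`.
#' @return list of class `sim_reads` with elements `reads` (named
#'   character vector), `truth` (data.frame: read_id, pop, origin,
#'   is_chimera, chimera_parents, n_indel, n_sub, clean), `pools`
#'   (pop_id, tag, fwd_primer, rev_primer), `templates` (insert per
#'   allele), `pool_counts`.
#' @examples
#' cfg <- sim_config(seed = 1, n_pops = 3, depth_per_pool = 50,
#'                   n_alleles_global = 4)
#' sim <- simulate_pool_reads(cfg, simulate_allele_pool(cfg))
#' length(sim$reads)
#' @export
simulate_pool_reads <- function(cfg, alleles, pool_counts = NULL,
                                tag_map = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(pool_counts)) pool_counts <- draw_pool_alleles(cfg, alleles)
  stopifnot(nrow(pool_counts) == length(alleles))
  if (any(colSums(pool_counts) == 0))
    stop("every pool needs at least one allele copy", call. = FALSE)

  design <- with_seed(sub_seed(cfg$seed, 3L), {
    flank5 <- random_dna(FLANK5_LEN)
    pad <- AMPLICON_LEN - FLANK5_LEN - 3L * cfg$n_codons
    if (pad < 0L) pad <- 0L
    flank3 <- random_dna(pad)
    fwd <- random_dna(PRIMER_LEN)
    rev <- random_dna(PRIMER_LEN)
    tags <- make_tags(cfg$n_pops)
    list(flank5 = flank5, flank3 = flank3, fwd = fwd, rev = rev,
         tags = tags)
  })
  pops <- colnames(pool_counts)
  if (is.null(tag_map)) {
    tag_map <- data.frame(pop_id = pops, tag = design$tags,
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tag_map$tag) || any(nchar(tag_map$tag) != TAG_LEN))
    stop("tags must be unique 5-base strings", call. = FALSE)
  pools <- data.frame(pop_id = tag_map$pop_id, tag = tag_map$tag,
                      fwd_primer = design$fwd, rev_primer = design$rev,
                      stringsAsFactors = FALSE)

  templates <- paste0(design$flank5, alleles, design$flank3)
  names(templates) <- names(alleles)
  tmpl_chars <- lapply(templates, function(s) strsplit(s, "")[[1]])
  tmpl_rle <- lapply(tmpl_chars, rle)

  if (cfg$depth_per_pool == 0L) {
    warning("depth_per_pool is 0; emitting an empty read set")
    truth <- data.frame(read_id = character(), pop = character(),
                        origin = character(), is_chimera = logical(),
                        chimera_parents = character(), n_indel = integer(),
                        n_sub = integer(), clean = logical(),
                        stringsAsFactors = FALSE)
    return(structure(list(reads = character(), truth = truth, pools = pools,
                          templates = templates, pool_counts = pool_counts),
                     class = "sim_reads"))
  }

  out <- with_seed(sub_seed(cfg$seed, 4L), {
    all_reads <- vector("list", length(pops))
    all_truth <- vector("list", length(pops))
    for (p in seq_along(pops)) {
      w <- pool_counts[, p]
      n <- cfg$depth_per_pool
      src <- sample.int(length(w), n, replace = TRUE, prob = w / sum(w))
      chim <- stats::runif(n) < cfg$chimera_rate & sum(w > 0) >= 2L
      reads <- character(n)
      origin <- names(templates)[src]
      parents <- rep(NA_character_, n)
      n_ind <- integer(n)
      n_sub <- integer(n)
      for (r in seq_len(n)) {
        if (chim[r]) {
          others <- which(w > 0 & seq_along(w) != src[r])
          mate <- if (length(others) == 1L) others else
            sample(others, 1L, prob = w[others] / sum(w[others]))
          bp <- sample.int(AMPLICON_LEN - 1L, 1L)
          ins <- c(tmpl_chars[[src[r]]][seq_len(bp)],
                   tmpl_chars[[mate]][(bp + 1L):AMPLICON_LEN])
          rl <- rle(ins)
          origin[r] <- NA_character_
          parents[r] <- paste(names(templates)[c(src[r], mate)],
                              collapse = "+")
        } else {
          ins <- tmpl_chars[[src[r]]]
          rl <- tmpl_rle[[src[r]]]
        }
        hp <- which(rl$lengths >= 2L)
        hit <- hp[stats::runif(length(hp)) < cfg$err_homopolymer]
        if (length(hit)) {
          lens <- rl$lengths
          lens[hit] <- lens[hit] + sample(c(-1L, 1L), length(hit),
                                          replace = TRUE)
          ins <- rep.int(rl$values, lens)
          n_ind[r] <- length(hit)
        }
        ns <- stats::rbinom(1L, length(ins), cfg$err_sub)
        if (ns > 0L) {
          pos <- sample.int(length(ins), ns)
          for (q in pos)
            ins[q] <- sample(setdiff(BASES, ins[q]), 1L)
          n_sub[r] <- ns
        }
        reads[r] <- paste(ins, collapse = "")
      }
      ids <- sprintf("%s_r%04d", pops[p], seq_len(n))
      all_reads[[p]] <- stats::setNames(
        paste0(pools$tag[p], pools$fwd_primer[p], reads), ids)
      all_truth[[p]] <- data.frame(
        read_id = ids, pop = pops[p], origin = origin,
        is_chimera = chim, chimera_parents = parents,
        n_indel = n_ind, n_sub = n_sub,
        clean = !chim & n_ind == 0L & n_sub == 0L,
        stringsAsFactors = FALSE)
    }
    list(reads = do.call(c, all_reads), truth = do.call(rbind, all_truth))
  })

  structure(list(reads = out$reads, truth = out$truth, pools = pools,
                 templates = templates, pool_counts = pool_counts),
            class = "sim_reads")
}

# Deterministic set of distinct 5-base tags (requires active RNG stream).
make_tags <- function(n) {
  tags <- character(0)
  while (length(tags) < n) {
    cand <- paste(sample(BASES, TAG_LEN, replace = TRUE), collapse = "")
    if (!cand %in% tags) tags <- c(tags, cand)
  }
  tags
}

#' Write sequences to a FASTA file
#'
#' Plain, byte-deterministic FASTA writer (one sequence per line) so that
#' identical simulations produce identical files.
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
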