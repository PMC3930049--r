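#' Simulate a global allele pool under site-partitioned selection
#'
#' Generates `cfg$n_alleles_global` unique in-frame coding alleles by
#' seeded codon mutation from a common stop-free ancestor. Each mutation
#' event proposes a uniform single-nucleotide neighbour of a random codon;
#' proposals creating stop codons are always rejected, nonsynonymous
#' proposals are accepted with probability `min(1, omega)` and synonymous
#' ones with probability `min(1, 1/omega)`, where `omega` is
#' `cfg$omega_pbr` inside the PBR mask and `cfg$omega_nonpbr` outside.
#' `omega = 1` is therefore neutral, `omega > 1` enriches amino-acid
#' change relative to silent change, `omega < 1` suppresses it, and
#' `omega = 0` freezes the partition completely (with both partitions at
#' 0 every allele equals the ancestor and uniqueness is not enforced).
#'
#' @param cfg a [sim_config()] object.
#' @return character vector of allele DNA sequences (length
#'   `3 * n_codons`), named `allele_01`, `allele_02`, ...; the ancestor is
#'   attached as attribute `"ancestor"`.
#' @examples
#' alleles <- simulate_allele_pool(sim_config(seed = 1, n_alleles_global = 6))
#' length(alleles)
#' @export
simulate_allele_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  frozen <- cfg$omega_pbr == 0 && cfg$omega_nonpbr == 0

  with_seed(sub_seed(cfg$seed, 1L), {
    sense <- sense_codons()
    ancestor <- sample(sense, cfg$n_codons, replace = TRUE)
    omega_site <- ifelse(seq_len(cfg$n_codons) %in% cfg$pbr_mask,
                         cfg$omega_pbr, cfg$omega_nonpbr)

    alleles <- character(cfg$n_alleles_global)
    for (k in seq_len(cfg$n_alleles_global)) {
      codons <- ancestor
      if (!frozen) {
        budget <- 100L
        repeat {
          n_events <- stats::rpois(1L, cfg$mut_per_codon * cfg$n_codons)
          for (e in seq_len(n_events)) {
            i <- sample.int(cfg$n_codons, 1L)
            codons[i] <- mutate_codon(codons[i], omega_site[i])
          }
          seq_k <- paste(codons, collapse = "")
          if (!seq_k %in% alleles[seq_len(k - 1L)]) break
          budget <- budget - 1L
          if (budget <= 0L)
            stop("could not generate unique alleles within retry budget",
                 call. = FALSE)
        }
      }
      alleles[k] <- paste(codons, collapse = "")
    }
    names(alleles) <- sprintf("allele_%02d", seq_along(alleles))
    attr(alleles, "ancestor") <- paste(ancestor, collapse = "")
    alleles
  })
}

# Propose and (possibly) accept one single-nucleotide change of a codon.
# Returns the new codon, or the old one if the proposal was rejected.
mutate_codon <- function(codon, omega) {
  if (omega == 0) return(codon)
  pos <- sample.int(3L, 1L)
  old_base <- substr(codon, pos, pos)
  new_base <- sample(setdiff(BASES, old_base), 1L)
  cand <- codon
  substr(cand, pos, pos) <- new_base
  if (cand %in% STOP_CODONS) return(codon)
  syn <- identical(unname(codon_table()[cand]), unname(codon_table()[codon]))
  p_accept <- if (syn) min(1, 1 / omega) else min(1, omega)
  if (stats::runif(1L) < p_accept) cand else codon
}

#' Draw the allelic composition of each population pool
#'
#' Each population receives a population-specific allele frequency vector
#' (symmetric Dirichlet across the global pool); `pool_size` individuals
#' then draw up to `alleles_per_individual` alleles each, and the pooled
#' copy counts define the pool's template composition for sequencing.
#'
#' @param cfg a [sim_config()] object.
#' @param alleles global allele pool from [simulate_allele_pool()].
#' @return integer matrix of allele copy counts, alleles x populations,
#'   with population columns `P1..Pn`.
#' @export
draw_pool_alleles <- function(cfg, alleles) {
  stopifnot(inherits(cfg, "sim_config"), length(alleles) >= 1L)
  with_seed(sub_seed(cfg$seed, 2L), {
    n_a <- length(alleles)
    counts <- matrix(0L, nrow = n_a, ncol = cfg$n_pops,
                     dimnames = list(names(alleles),
                                     sprintf("P%d", seq_len(cfg$n_pops))))
    for (p in seq_len(cfg$n_pops)) {
      w <- stats::rgamma(n_a, shape = 1)
      draws <- sample.int(n_a, cfg$pool_size * cfg$alleles_per_individual,
                          replace = TRUE, prob = w / sum(w))
      tab <- tabulate(draws, nbins = n_a)
      counts[, p] <- tab
    }
    counts
  })
}
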