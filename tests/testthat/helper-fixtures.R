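# Small shared fixtures, built in code at test time.

# Compact simulated study: few pools, light depth, fast to filter.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, n_pops = 4, pool_size = 10,
                    depth_per_pool = 150, n_alleles_global = 6,
                    n_codons = 20, ...)
  alleles <- simulate_allele_pool(cfg)
  reads <- simulate_pool_reads(cfg, alleles)
  ref <- substr(reads$templates[[1]], 21, 20 + 3 * cfg$n_codons)
  list(cfg = cfg, alleles = alleles, reads = reads, ref = ref)
}

# Truncated true insert sequences (what a perfect filter would retain).
true_truncated <- function(sim, L = 220) substr(sim$reads$templates, 1, L)

# Codon alignment whose column amino-acid compositions are given
# explicitly: `cols` is a list of amino-acid vectors (one per codon,
# one element per sequence); uses a fixed codon per amino acid.
aln_from_aa <- function(cols) {
  aa2codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  n_seq <- length(cols[[1]])
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(vapply(cols, function(col) aa2codon[[col[i]]], ""), collapse = "")
  }, "")
  codon_alignment(stats::setNames(seqs, sprintf("s%02d", seq_len(n_seq))))
}

# Exhaustive-relabelling Mantel p-value for small n (independent oracle).
exact_mantel_p <- function(a, b) {
  n <- nrow(a)
  perms <- all_perms(seq_len(n))
  lt <- lower.tri(a)
  bv <- b[lt]
  obs <- stats::cor(a[lt], bv)
  rs <- apply(perms, 1, function(p) stats::cor(a[p, p][lt], bv))
  mean(rs >= obs - 1e-12)
}

all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}
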