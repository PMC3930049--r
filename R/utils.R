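# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
codon_table <- function() Biostrings::GENETIC_CODE

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons, fixed order.
sense_codons <- function() {
  all <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
               1L, paste0, collapse = "")
  sort(setdiff(all, STOP_CODONS))
}

translate_codon <- function(codon) {
  aa <- unname(codon_table()[codon])
  aa[is.na(aa)] <- "X"
  aa
}

# Split an in-frame DNA string into codon triplets.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Deterministic sub-stream seed derivation: one global seed, one fixed
# offset per operation, always below 2^31.
sub_seed <- function(seed, k) {
  (as.numeric(seed) + 999331 * as.numeric(k)) %% 2147483647
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length strings (vectorised over x).
hamming <- function(x, y) {
  xm <- matrix(unlist(strsplit(x, "")), ncol = length(x))
  ym <- strsplit(y, "")[[1]]
  colSums(xm != ym)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a
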