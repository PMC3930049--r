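# Independent brute-force oracle for pathway-counting dN/dS on a codon
# pair. Deliberately written from first principles (recursive pathway
# enumeration, explicit per-position site counting, no caching) so it
# shares no code with the package implementation it checks.

oracle_code <- Biostrings::GENETIC_CODE
oracle_stops <- names(oracle_code)[oracle_code == "*"]

# Potential synonymous sites of one codon: at each position, the number
# of the 3 alternative bases giving the same amino acid (changes to stop
# codons count in the denominator but never as synonymous).
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (b in c("A", "C", "G", "T")) {
      if (b == cur) next
      alt <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (!(alt %in% oracle_stops) &&
          oracle_code[[alt]] == oracle_code[[codon]])
        total <- total + 1 / 3
    }
  }
  total
}

# All mutational pathways between two codons by depth-first recursion;
# returns a list of pathways, each a vector of intermediate codons
# (including the endpoint), or NULL when codons are identical.
oracle_pathways <- function(from, to) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(diff_pos)) return(list())
  out <- list()
  recurse <- function(cur, remaining, trail) {
    if (!length(remaining)) { out[[length(out) + 1L]] <<- trail; return() }
    for (p in remaining) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(to, p, p),
                    substr(cur, p + 1, 3))
      recurse(nxt, setdiff(remaining, p), c(trail, nxt))
    }
  }
  recurse(from, diff_pos, character(0))
  out
}

# Pathway-averaged (Nd, Sd) between two codons, excluding pathways that
# pass through a stop codon; if every pathway is blocked, average over
# all of them with stop steps counted as nonsynonymous.
oracle_pair_counts <- function(from, to) {
  paths <- oracle_pathways(from, to)
  if (!length(paths)) return(c(Nd = 0, Sd = 0))
  count_path <- function(path, allow_stops) {
    cur <- from; nd <- 0; sd <- 0
    for (step in path) {
      if (step %in% oracle_stops) {
        if (!allow_stops) return(NULL)
        nd <- nd + 1          # stop intermediates scored nonsynonymous
      } else if (oracle_code[[step]] == oracle_code[[cur]]) {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- step
    }
    c(nd, sd)
  }
  counted <- Filter(Negate(is.null), lapply(paths, count_path, FALSE))
  if (!length(counted)) counted <- lapply(paths, count_path, TRUE)
  m <- do.call(rbind, counted)
  c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# Full oracle over two in-frame sequences.
oracle_ng <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  Nd <- 0; Sd <- 0; s <- 0
  for (i in seq_along(ca)) {
    s <- s + (oracle_syn_sites(ca[i]) + oracle_syn_sites(cb[i])) / 2
    cnt <- oracle_pair_counts(ca[i], cb[i])
    Nd <- Nd + cnt[["Nd"]]; Sd <- Sd + cnt[["Sd"]]
  }
  n <- 3 * length(ca) - s
  list(Nd = Nd, Sd = Sd, n_sites = n, s_sites = s,
       pN = if (n > 0) Nd / n else 0, pS = if (s > 0) Sd / s else 0)
}

# Random sense codon (uses the calling test's RNG stream).
random_sense_codon <- function() {
  repeat {
    c0 <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    if (!(c0 %in% oracle_stops)) return(c0)
  }
}
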