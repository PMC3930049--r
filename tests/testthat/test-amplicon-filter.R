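pools1 <- data.frame(pop_id = c("A", "B"), tag = c("ACGTA", "GGTAC"),
                     fwd_primer = "ACGTACGTAC", rev_primer = "TTGGCCAATT",
                     stringsAsFactors = FALSE)

test_that("demultiplex assigns by exact tag and near-exact primer", {
  insert <- "GATTACAGATTACAGATTACA"
  reads <- c(r1 = paste0("ACGTA", "ACGTACGTAC", insert),   # exact
             r2 = paste0("ACGTA", "TCGTACGTAC", insert),   # 1 mismatch
             r3 = paste0("ACGTA", "TCGTACGTTC", insert),   # 2 mismatches
             r4 = paste0("TTTTT", "ACGTACGTAC", insert),   # unknown tag
             r5 = paste0("GGTAC", "TTGGCCAATT", insert))   # reverse primer
  dmx0 <- demultiplex(reads, pools1, max_primer_mismatch = 0)
  expect_equal(names(dmx0$pools$A), c("r1"))
  dmx1 <- demultiplex(reads, pools1, max_primer_mismatch = 1)
  expect_equal(names(dmx1$pools$A), c("r1", "r2"))
  expect_equal(unname(dmx1$pools$A[["r1"]]), insert)
  expect_true("r3" %in% dmx1$unassigned_ids)
  expect_true("r4" %in% dmx1$unassigned_ids)
  # reverse-primer hit is reverse-complemented into forward orientation
  expect_equal(unname(dmx1$pools$B[["r5"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(insert))))
  expect_error(demultiplex(reads, rbind(pools1, pools1)), "duplicate")
})

test_that("truncation cuts long reads and discards short ones", {
  reads <- c(a = strrep("A", 276), b = strrep("C", 220),
             c = strrep("G", 150))
  tr <- truncate_reads(reads, 220)
  expect_equal(nchar(tr$reads[["a"]]), 220)
  expect_equal(tr$reads[["b"]], strrep("C", 220))
  expect_false("c" %in% names(tr$reads))
  expect_equal(tr$n_discarded, 1L)
})

test_that("variant collapse tallies exact-identity counts per pool", {
  vt <- collapse_variants(list(pop1 = c("AAA", "AAA", "AAA", "AAT"),
                               pop2 = c("AAA", "AAA"),
                               pop3 = character(0)))
  expect_equal(nrow(vt$records), 2)
  expect_equal(vt$records$sequence, c("AAA", "AAT"))  # count-ordered
  expect_equal(unname(vt$counts["V0001", ]), c(3L, 2L, 0L))
  expect_equal(unname(vt$counts["V0002", ]), c(1L, 0L, 0L))
})

test_that("abundance filter matches rule-by-rule enumeration on toy
           variants", {
  # oracle: independent enumeration of the two removal rules over all
  # two-pool count combinations
  combos <- expand.grid(a = 0:4, b = 0:4)
  combos <- combos[combos$a + combos$b > 0, ]
  pool_reads <- list(popA = character(0), popB = character(0))
  # deterministic distinct sequences: index written in base 4 over ACGT
  seqs <- vapply(seq_len(nrow(combos)), function(i) {
    digits <- (i %/% 4^(5:0)) %% 4
    paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
  }, "")
  stopifnot(!anyDuplicated(seqs))
  for (i in seq_len(nrow(combos))) {
    pool_reads$popA <- c(pool_reads$popA, rep(seqs[i], combos$a[i]))
    pool_reads$popB <- c(pool_reads$popB, rep(seqs[i], combos$b[i]))
  }
  vt <- filter_artifacts(collapse_variants(pool_reads))
  for (i in seq_len(nrow(combos))) {
    rec <- vt$records[vt$records$sequence == seqs[i], ]
    tot <- combos$a[i] + combos$b[i]
    npop <- (combos$a[i] > 0) + (combos$b[i] > 0)
    expected <- if (tot <= 1) "singleton"
      else if (npop < 2) "single_population" else "none"
    expect_equal(rec$reason, expected, info = sprintf("counts %d/%d",
                 combos$a[i], combos$b[i]))
  }
})

test_that("per-pool singleton scope is the stricter reading", {
  vt <- collapse_variants(list(p1 = c("AAA", "CCC"), p2 = c("AAA", "CCC"),
                               p3 = c("CCC")))
  g <- filter_artifacts(vt, "global")
  expect_equal(g$records$status[g$records$sequence == "AAA"], "retained")
  p <- filter_artifacts(vt, "per_pool")
  expect_equal(p$records$reason[p$records$sequence == "AAA"], "singleton")
  expect_equal(p$records$status[p$records$sequence == "CCC"], "removed")
})

ref18 <- "ATGGCTGCTAAAGGTCCT"   # 6 codons, no stops

make_vt <- function(...) {
  seqs <- c(...)
  collapse_variants(list(p1 = seqs, p2 = seqs))
}

test_that("frameshift screen keeps 3k indels and removes others", {
  del3 <- paste0(substr(ref18, 1, 6), substr(ref18, 10, 18))   # 3-base del
  del2 <- paste0(substr(ref18, 1, 6), substr(ref18, 9, 18))    # 2-base del
  ins1a <- paste0(substr(ref18, 1, 5), "T", substr(ref18, 6, 18))
  ins1b <- paste0(substr(ins1a, 1, 13), "G", substr(ins1a, 14, 19))
  scr <- screen_frameshift(make_vt(ref18, del3, del2, ins1b), ref18)
  rec <- scr$variants$records
  expect_equal(rec$reason[rec$sequence == del3], "none")
  expect_equal(rec$reason[rec$sequence == del2], "frameshift")
  # two separate 1-base insertions: each run has length 1 (not 3k)
  expect_equal(rec$reason[rec$sequence == ins1b], "frameshift")
  # the 3k deletion appears as a gap codon in the alignment
  aln <- scr$alignment
  v_del <- rec$variant_id[rec$sequence == del3]
  expect_true(any(grepl("-", aln[v_del, ])))
  expect_equal(sum(unlist(strsplit(aln[v_del, ], "")) == "-"), 3)
})

test_that("random garbage is removed as unalignable", {
  junk <- strrep("T", 18)
  scr <- screen_frameshift(make_vt(ref18, junk), ref18,
                           min_score_frac = 0.5)
  rec <- scr$variants$records
  expect_equal(rec$reason[rec$sequence == junk], "unalignable")
})

test_that("flank-trimmed duplicates merge into one exon variant", {
  flank <- "GGGTTT"
  v1 <- paste0(flank, ref18, flank)              # allele with flanks
  v2 <- paste0(flank, ref18, "GGGTT")            # same exon, flank del
  vt <- collapse_variants(list(p1 = rep(c(v1, v2), c(5, 2)),
                               p2 = rep(c(v1, v2), c(4, 2))))
  scr <- screen_frameshift(vt, ref18)
  rec <- scr$variants$records
  expect_equal(rec$reason[rec$sequence == v2], "duplicate_after_trim")
  expect_equal(rec$total[rec$sequence == v1], 13L)  # counts absorbed
  expect_equal(nrow(scr$alignment), 1)
})

test_that("presence matrix is binary with retained variants as columns", {
  vt <- filter_artifacts(collapse_variants(list(
    p1 = c(rep("AAAGGG", 5), "CCCGGG"), p2 = c("AAAGGG", "CCCGGG"))))
  pm <- build_presence_matrix(vt)
  expect_true(all(pm %in% 0:1))
  expect_equal(dim(pm), c(2L, 2L))
  expect_true(all(colSums(pm) >= 2))
  vt$records$status[] <- "removed"
  expect_error(build_presence_matrix(vt), "no retained")
})

test_that("full chain on synthetic error-free reads recovers exactly the
           true truncated variants", {
  sim <- small_sim(seed = 6, err_sub = 0, err_homopolymer = 0,
                   chimera_rate = 0)
  res <- filter_amplicons(sim$reads$reads, sim$reads$pools, sim$ref)
  keep <- res$variants$records$status == "retained"
  in2 <- rowSums(sim$reads$pool_counts > 0) >= 2
  expect_setequal(res$variants$records$sequence[keep],
                  unname(true_truncated(sim)[in2]))
  # read accounting: assigned + unassigned = input
  expect_equal(res$counters$n_assigned + res$counters$n_unassigned,
               res$counters$n_reads)
})

test_that("filtering chain is deterministic", {
  sim <- small_sim(seed = 8)
  r1 <- filter_amplicons(sim$reads$reads, sim$reads$pools, sim$ref)
  r2 <- filter_amplicons(sim$reads$reads, sim$reads$pools, sim$ref)
  expect_identical(r1$variants$records, r2$variants$records)
  expect_identical(r1$presence, r2$presence)
})
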