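#' Run the full simulation-backed analysis pipeline
#'
#' Orchestrates simulate -> filter -> selection statistics -> IBD ->
#' community -> association as one configured, seeded, logged run. Each
#' stage writes its outputs under `outdir` and is checksummed into a run
#' manifest; a failed or disabled stage halts its dependents with a
#' recorded reason. Re-running with an identical configuration
#' reproduces identical checksums for deterministic stages.
#'
#' @param config a configuration list or the path of a YAML file.
#'   Recognised blocks: `seed` (global seed; propagated as per-stage
#'   sub-streams), `outdir`, `stages` (named logical toggles), `sim`
#'   (arguments to [sim_config()]), `filter`
#'   (`truncate`, `max_primer_mismatch`, `singleton_scope`), `selstats`
#'   (`n_boot`), `ibd` (`n_perm`, `drop_pairs`, `envelope_size`,
#'   `envelope_subsets`), `community` (`min_len`, `min_bootstrap`).
#' @return list of class `run_manifest`: per-stage status, output paths
#'   with md5 checksums, and a log of stage counters; also written as
#'   `manifest.json` in `outdir`.
#' @examples
#' \donttest{
#' man <- run_pipeline(list(seed = 1, outdir = tempfile(),
#'                          sim = list(depth_per_pool = 100,
#'                                     n_alleles_global = 6),
#'                          selstats = list(n_boot = 100),
#'                          ibd = list(n_perm = 99, envelope_subsets = 10,
#'                                     envelope_size = 50)))
#' man$stages$filter$status
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% "mhcpop_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  toggles <- config$stages %||% list()
  on_ <- function(s) isTRUE(toggles[[s]] %||% TRUE)

  manifest <- list(seed = seed, outdir = outdir, stages = list())
  state <- new.env(parent = emptyenv())
  log_stage <- function(name, status, outputs = character(0),
                        counters = NULL, reason = NULL) {
    manifest$stages[[name]] <<- list(
      status = status,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(outputs)), basename(outputs))),
      counters = counters, reason = reason)
  }
  tsv <- function(x, name) {
    path <- file.path(outdir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = is.matrix(x))
    path
  }

  ## -- simulate ------------------------------------------------------
  if (on_("simulate")) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    alleles <- simulate_allele_pool(cfg)
    reads <- simulate_pool_reads(cfg, alleles)
    aflp <- simulate_aflp(cfg)
    state$cfg <- cfg; state$reads <- reads; state$aflp <- aflp
    state$alleles <- alleles
    fa <- file.path(outdir, "reads.fasta")
    write_fasta(reads$reads, fa)
    outs <- c(fa,
              tsv(reads$truth, "read_truth.tsv"),
              tsv(reads$pools, "pools.tsv"),
              tsv(aflp$genotypes, "aflp.tsv"),
              tsv(data.frame(population = rownames(aflp$coords),
                             x_km = aflp$coords[, 1L],
                             y_km = aflp$coords[, 2L]), "coords.tsv"))
    log_stage("simulate", "completed", outs,
              counters = list(n_reads = length(reads$reads),
                              realized_ibd_slope =
                                aflp$truth$realized_ibd_slope))
  } else log_stage("simulate", "skipped")

  ## -- filter --------------------------------------------------------
  if (on_("filter")) {
    if (is.null(state$reads))
      log_stage("filter", "dependency_error",
                reason = "stage 'simulate' did not provide reads")
    else {
      fp <- config$filter %||% list()
      ref <- substr(state$reads$templates[[1L]], FLANK5_LEN + 1L,
                    FLANK5_LEN + 3L * state$cfg$n_codons)
      res <- filter_amplicons(
        state$reads$reads, state$reads$pools, ref,
        truncate_len = fp$truncate %||% 220L,
        max_primer_mismatch = fp$max_primer_mismatch %||% 1L,
        singleton_scope = fp$singleton_scope %||% "global",
        min_score_frac = fp$min_score_frac %||% 0.5)
      state$filtered <- res
      keep <- res$variants$records$status == "retained"
      outs <- c(tsv(res$variants$records, "variants.tsv"),
                tsv(res$presence, "presence.tsv"))
      fa <- file.path(outdir, "retained_variants.fasta")
      write_fasta(stats::setNames(res$variants$records$sequence[keep],
                                  res$variants$records$variant_id[keep]), fa)
      log_stage("filter", "completed", c(outs, fa),
                counters = res$counters)
    }
  } else log_stage("filter", "skipped")

  ## -- selstats ------------------------------------------------------
  if (on_("selstats")) {
    if (is.null(state$filtered))
      log_stage("selstats", "dependency_error",
                reason = "stage 'filter' did not provide an alignment")
    else {
      sp <- config$selstats %||% list()
      mask <- pbr_mask("locus1", state$cfg$n_codons, state$cfg$pbr_mask)
      aln <- state$filtered$alignment
      sd_tab <- site_diversity(aln, mask)
      sel <- selection_table(aln, mask, n_boot = sp$n_boot %||% 1000L,
                             seed = sub_seed(seed, 7L))
      poly <- percent_polymorphic_by_pop(aln, mask,
                                         state$filtered$presence)
      state$mask <- mask; state$poly <- poly
      outs <- c(tsv(sd_tab, "site_diversity.tsv"),
                tsv(sel, "selection.tsv"),
                tsv(poly, "poly_by_pop.tsv"))
      log_stage("selstats", "completed", outs,
                counters = list(
                  mean_D_pbr = attr(sd_tab, "partition_means")[["PBR"]],
                  mean_D_nonpbr =
                    attr(sd_tab, "partition_means")[["non-PBR"]]))
    }
  } else log_stage("selstats", "skipped")

  ## -- ibd -----------------------------------------------------------
  if (on_("ibd")) {
    if (is.null(state$filtered) || is.null(state$aflp))
      log_stage("ibd", "dependency_error",
                reason = "needs 'filter' (presence matrix) and 'simulate' (AFLP, geography)")
    else {
      ip <- config$ibd %||% list()
      n_perm <- ip$n_perm %||% 1000L
      geo <- state$aflp$geo
      mhc <- standardize01(euclidean_presence(state$filtered$presence))
      pops_f <- rowsum(state$aflp$genotypes,
                       state$aflp$pop_assign) /
        as.integer(table(state$aflp$pop_assign))
      aflp_d <- standardize01(
        dist_matrix(as.matrix(stats::dist(pops_f)), kind = "raw"))
      if (!is.null(ip$drop_pairs)) {
        mhc <- drop_pairs(mhc, unlist(ip$drop_pairs))
      }
      m_geo <- mantel_test(mhc, geo, n_perm, seed = sub_seed(seed, 8L))
      m_aflp_geo <- mantel_test(aflp_d, geo, n_perm,
                                seed = sub_seed(seed, 9L))
      m_mhc_aflp <- mantel_test(mhc, aflp_d, n_perm,
                                seed = sub_seed(seed, 10L))
      pm <- partial_mantel_test(mhc, geo, aflp_d, n_perm,
                                seed = sub_seed(seed, 11L))
      env <- neutral_slope_envelope(
        state$aflp$genotypes, state$aflp$pop_assign, geo,
        subset_size = ip$envelope_size %||% 200L,
        n_subsets = ip$envelope_subsets %||% 100L,
        seed = sub_seed(seed, 12L))
      verdict <- envelope_verdict(env, slope = m_geo$slope,
                                  r2 = m_geo$r2)
      report <- data.frame(
        test = c("mhc~geo", "aflp~geo", "mhc~aflp", "mhc~geo|aflp"),
        R = c(m_geo$R, m_aflp_geo$R, m_mhc_aflp$R, pm$R),
        P = c(m_geo$P, m_aflp_geo$P, m_mhc_aflp$P, pm$P),
        slope = c(m_geo$slope, m_aflp_geo$slope, m_mhc_aflp$slope,
                  pm$slope),
        r2 = c(m_geo$r2, m_aflp_geo$r2, m_mhc_aflp$r2, pm$r2),
        n_perm = n_perm, stringsAsFactors = FALSE)
      state$ibd <- report
      outs <- c(tsv(report, "mantel.tsv"),
                tsv(data.frame(slope = env$slopes, r2 = env$r2s),
                    "envelope.tsv"))
      jf <- file.path(outdir, "envelope_verdict.json")
      jsonlite::write_json(
        list(min_slope = env$min_slope, max_slope = env$max_slope,
             min_r2 = env$min_r2, max_r2 = env$max_r2,
             mhc_slope = m_geo$slope, mhc_r2 = m_geo$r2,
             within_slope = verdict$within_slope,
             within_r2 = verdict$within_r2),
        jf, auto_unbox = TRUE, digits = NA)
      log_stage("ibd", "completed", c(outs, jf),
                counters = list(mantel_R_mhc_geo = m_geo$R,
                                within_r2 = verdict$within_r2))
    }
  } else log_stage("ibd", "skipped")

  ## -- community -----------------------------------------------------
  if (on_("community")) {
    if (is.null(state$cfg))
      log_stage("community", "dependency_error",
                reason = "stage 'simulate' did not provide a configuration")
    else {
      cp <- config$community %||% list()
      covar <- if (!is.null(state$poly)) {
        stats::setNames(state$poly$pct_pbr, state$poly$population)
      } else stats::setNames(rep(0, state$cfg$n_pops),
                             sprintf("P%d", seq_len(state$cfg$n_pops)))
      comm <- simulate_communities(state$cfg, covar)
      tab <- filter_records(comm$records,
                            min_len = cp$min_len %||% 200L,
                            min_bootstrap = cp$min_bootstrap %||% 0.5)
      tab <- flag_pathogens(tab)
      state$tab <- tab
      rich <- data.frame(
        population = colnames(tab$counts),
        all = richness(tab, "all"),
        nonpathogen = richness(tab, "nonpathogen"),
        pathogen = richness(tab, "pathogen"))
      # one community sample per population: a populations-as-factor
      # PERMANOVA needs within-group replicates, so it is left to
      # permanova() on designs that have them
      outs <- c(tsv(comm$records, "community_records.tsv"),
                tsv(tab$counts, "community_matrix.tsv"),
                tsv(rich, "richness.tsv"))
      log_stage("community", "completed", outs,
                counters = list(n_taxa = nrow(tab$counts),
                                pathogen_richness_range =
                                  range(rich$pathogen)))
    }
  } else log_stage("community", "skipped")

  ## -- assoc ---------------------------------------------------------
  if (on_("assoc")) {
    if (is.null(state$poly) || is.null(state$tab))
      log_stage("assoc", "dependency_error",
                reason = "needs 'selstats' (polymorphism) and 'community' (richness)")
    else {
      grid <- assoc_grid(list(locus1 = state$poly), state$tab)
      outs <- tsv(grid, "assoc.tsv")
      log_stage("assoc", "completed", outs,
                counters = list(n_cells = nrow(grid),
                                n_significant = sum(grid$significant)))
    }
  } else log_stage("assoc", "skipped")

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d) -> %s\n", x$seed, x$outdir))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-9s %s", s, st$status))
    if (!is.null(st$reason)) cat(" [", st$reason, "]", sep = "")
    cat("\n")
  }
  invisible(x)
}
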