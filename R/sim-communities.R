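# Names of the seven pathogen taxa used by default, matching the fish
# pathogen list applied to the emulated survey (Austin & Austin style).
AUSTIN_SEVEN <- c(
  "Carnobacterium/Lactobacillus sp.", "Staphylococcus sp.",
  "Flavobacterium sp.", "unclassified Clostridiales",
  "unclassified Enterobacteriaceae", "unclassified Pseudomonadaceae",
  "unclassified Oxalobacteraceae")

#' Simulate classified 16S community records with a pathogen subset
#'
#' Generates a per-record 16S-style community table (taxon, population,
#' count, assignment bootstrap, read length) for `cfg$n_taxa` taxa of
#' which a `cfg$pathogen_fraction` subset is pathogenic. Pathogen species
#' richness per population follows a latent linear model in the supplied
#' population covariate: `S_i = clamp(round(mu + b z_i + e_i), 0, n_path)`
#' with `z` the standardized covariate, `b = cfg$assoc_effect` and
#' `e ~ N(0,1)`, so `b = 0` gives independence and `b` programs a latent
#' population R-squared of `b^2/(b^2+1)`. Nonpathogen taxa follow an
#' occupancy/abundance model independent of the covariate.
#'
#' When seven or fewer pathogen taxa are requested they are named after
#' the standard fish-pathogen list (see [austin_pathogens()]) so the
#' community filter defaults flag them directly.
#'
#' @param cfg a [sim_config()] object.
#' @param pop_covariate numeric vector, one value per population (e.g.
#'   per-population PBR polymorphism); names are used as population
#'   labels when present.
#' @return list of class `sim_communities`: `records` (data.frame taxon,
#'   population, count, bootstrap, length), `pathogen_taxa`, `truth`
#'   (list: `pathogen_richness` per population, `programmed_assoc_beta`).
#' @examples
#' cfg <- sim_config(seed = 1, assoc_effect = 2)
#' sim <- simulate_communities(cfg, rnorm(9))
#' head(sim$records)
#' @export
simulate_communities <- function(cfg, pop_covariate) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(pop_covariate) != cfg$n_pops)
    stop("pop_covariate needs one value per population", call. = FALSE)
  pops <- names(pop_covariate) %||% sprintf("P%d", seq_len(cfg$n_pops))

  with_seed(sub_seed(cfg$seed, 6L), {
    n_path <- round(cfg$pathogen_fraction * cfg$n_taxa)
    n_path <- min(n_path, cfg$n_taxa)
    path_taxa <- if (n_path == 0L) character(0)
      else if (n_path <= length(AUSTIN_SEVEN)) AUSTIN_SEVEN[seq_len(n_path)]
      else c(AUSTIN_SEVEN, sprintf("Pathogen sp. %02d",
                                   seq_len(n_path - length(AUSTIN_SEVEN))))
    n_free <- cfg$n_taxa - n_path
    free_taxa <- sprintf("Taxon_%03d", seq_len(n_free))

    # Pathogen richness from the latent covariate model.
    z <- if (stats::sd(pop_covariate) > 0) as.numeric(scale(pop_covariate))
         else rep(0, cfg$n_pops)
    latent <- 1.5 + cfg$assoc_effect * z + stats::rnorm(cfg$n_pops)
    S_path <- pmin(pmax(round(latent), 0L), n_path)

    rec <- list()
    for (i in seq_len(cfg$n_pops)) {
      if (n_path > 0L && S_path[i] > 0L) {
        present <- sample(path_taxa, S_path[i])
        rec[[length(rec) + 1L]] <- data.frame(
          taxon = present, population = pops[i],
          count = 1L + stats::rpois(length(present), 2),
          stringsAsFactors = FALSE)
      }
    }

    # Nonpathogens: taxon-specific occupancy, per-population effort.
    occ <- stats::runif(n_free, 0.05, 0.6)
    effort <- stats::runif(cfg$n_pops, 0.2, 1.5)
    for (i in seq_len(cfg$n_pops)) {
      present <- free_taxa[stats::runif(n_free) < occ * effort[i]]
      if (length(present)) {
        rec[[length(rec) + 1L]] <- data.frame(
          taxon = present, population = pops[i],
          count = 1L + stats::rpois(length(present), 2),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rec)
    records$bootstrap <- round(stats::runif(nrow(records), 0.3, 1), 3)
    records$length <- pmax(60L, round(stats::rnorm(nrow(records), 250, 30)))
    records <- records[order(records$population, records$taxon), ]
    rownames(records) <- NULL

    realized <- stats::setNames(S_path, pops)
    structure(list(records = records, pathogen_taxa = path_taxa,
                   truth = list(pathogen_richness = realized,
                                programmed_assoc_beta = cfg$assoc_effect)),
              class = "sim_communities")
  })
}

#' Default fish-pathogen taxon list
#'
#' The seven potentially pathogenic bacterial taxa flagged in the
#' emulated survey following the standard fish-pathogen compilation of
#' Austin & Austin: Carnobacterium/Lactobacillus, Staphylococcus,
#' Flavobacterium, and unclassified Clostridiales, Enterobacteriaceae,
#' Pseudomonadaceae and Oxalobacteraceae.
#'
#' @return character vector of taxon names.
#' @export
austin_pathogens <- function() AUSTIN_SEVEN
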