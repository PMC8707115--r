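#' Packaged cytogenetic record compilation for fungus-farming ants
#'
#' The compiled chromosome counts, karyotype formulas, C-band
#' heterochromatin codes and 1C genome sizes of the Attina (fungus-farming
#' ants) studied cytogenetically to date, one row per published record
#' (61 records over 12 genera, including five newly reported karyotypes).
#'
#' @return A \code{cytogenetic_records} data frame, see [record_schema].
#' @examples
#' summarize_records(attina_records())
#' @export
attina_records <- function() {
  read_attina_records(system.file("extdata", "attina_records.tsv",
                                  package = "attinakaryo", mustWork = TRUE))
}

#' Read a per-chromosome karyomorphometric profile table
#'
#' Profile tables carry one row per chromosome of the karyotype with the
#' across-spread mean and SD of the total length (TL), long arm (L), short
#' arm (S), relative length (RL) and arm ratio (r), plus the morphology
#' class. The packaged tables (see [attina_karyomorph_tables()]) follow
#' this layout.
#'
#' @param path Path to a TSV with columns \code{pair}, \code{homologue},
#'   \code{mean_TL}, \code{sd_TL}, ..., \code{mean_r}, \code{sd_r},
#'   \code{classification}.
#' @return A \code{chromosome_profiles} data frame compatible with
#'   [summarize_karyotype()].
#' @export
read_profile_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("pair", "homologue", "mean_TL", "sd_TL", "mean_L", "sd_L",
            "mean_S", "sd_S", "mean_RL", "sd_RL", "mean_r", "sd_r",
            "classification")
  if (!all(need %in% names(x))) {
    stop("profile table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x$morphology <- x$classification
  x$rank <- seq_len(nrow(x))
  class(x) <- c("chromosome_profiles", class(x))
  x
}

#' Packaged karyomorphometric tables of the newly described karyotypes
#'
#' Per-chromosome measurement summaries (mean +/- SD of TL, L, S, RL and r
#' over >= 10 metaphase spreads) for the four species whose karyotypes were
#' measured in full: Mycocepurus goeldii (2n = 8), Myrmicocrypta sp.
#' (2n = 28), Cyphomyrmex transversus (2n = 42) and Apterostigma madidiense
#' (2n = 24).
#'
#' @return A named list of \code{chromosome_profiles} data frames.
#' @examples
#' kt <- attina_karyomorph_tables()
#' summarize_karyotype(kt[["Mycocepurus goeldii"]])
#' @export
attina_karyomorph_tables <- function() {
  dir <- system.file("extdata", "karyomorphometry", package = "attinakaryo",
                     mustWork = TRUE)
  files <- c("Mycocepurus goeldii" = "table1_mycocepurus_goeldii.tsv",
             "Myrmicocrypta sp." = "table2_myrmicocrypta_sp.tsv",
             "Cyphomyrmex transversus" = "table3_cyphomyrmex_transversus.tsv",
             "Apterostigma madidiense" = "table4_apterostigma_madidiense.tsv")
  lapply(files, function(f) read_profile_table(file.path(dir, f)))
}

#' Packaged approximate chronogram of the fungus-farming ants
#'
#' A synthetic, approximate time-calibrated tree over the taxa of
#' [attina_records()]: the genus-level topology follows the published
#' phylogeny of the subtribe, and node ages are set to the approximate
#' crown ages discussed for the karyotype-stasis clades (~45 Myr
#' Apterostigma, ~25 Cyphomyrmex, ~24.8 Mycetomoellerius, ~19 the costatus
#' group, ~16.8 Trachymyrmex, ~13.7 Atta, ~4.7 Amoimyrmex). It is a fixture
#' for trait mapping, not a reproduced divergence-time estimate.
#'
#' @return An ultrametric \code{phylo} with 51 tips; branch lengths in Myr.
#' @examples
#' tree <- attina_timetree()
#' at <- attach_traits(tree, make_trait_table(attina_records()))
#' @export
attina_timetree <- function() {
  read_timetree(system.file("extdata", "attina_chronogram.nwk",
                            package = "attinakaryo", mustWork = TRUE))
}

#' Reconstruct one idealised metaphase spread from a profile table
#'
#' Builds a single noise-free spread whose arm lengths equal the mean long-
#' and short-arm lengths of a profile table. Useful for pipeline checks:
#' aggregating this spread reproduces the mean lengths (arm ratios are
#' recomputed per chromosome, so they match the printed means only where
#' the mean of per-spread ratios coincides with the ratio of means).
#'
#' @param profiles A \code{chromosome_profiles} data frame.
#' @return A \code{spread_table} with one spread.
#' @export
profile_means_as_spread <- function(profiles) {
  as_spreads(data.frame(
    spread_id = "mean",
    chromosome_index = seq_len(nrow(profiles)),
    long_um = profiles$mean_L,
    short_um = profiles$mean_S))
}
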