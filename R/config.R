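#' Pipeline configuration
#'
#' Bundles every tunable constant of the scoring pipeline. Defaults reproduce
#' the published protocol: 5 A inter-residue contact cutoff, 3 A clash cutoff,
#' exclusion of models with more than 25 clashes, a Maxscore threshold of 0.1
#' separating the strong- and weak-consensus selection regimes, a candidate
#' pool of the top 30 CONSRANK models plus the top 2 models of each of the 15
#' most populated clusters, 10 models submitted, and sequence filtering at
#' 90% identity / 70% coverage.
#'
#' @param contact_cutoff Heavy-atom distance (A) below which two inter-chain
#'   residues are in contact.
#' @param clash_cutoff Heavy-atom distance (A) below which an inter-chain atom
#'   pair counts as a steric clash.
#' @param clash_max Maximum tolerated clash count; models exceeding it are
#'   excluded from the final selection.
#' @param maxscore_threshold Maxscore value at or above which the consensus is
#'   considered strong.
#' @param top_consrank_pool Number of top CONSRANK-ranked models entering the
#'   candidate pool.
#' @param top_clusters Number of most-populated clusters contributing
#'   candidates.
#' @param per_cluster Number of top cluster-local models taken per cluster.
#' @param n_submit Number of models in the final selection.
#' @param seq_identity_min Minimum sequence identity to the target chain.
#' @param coverage_min Minimum target-chain coverage.
#' @param sasa_probe Solvent probe radius (A).
#' @param sasa_points Shrake-Rupley sphere points per atom.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$contact_cutoff
pipeline_config <- function(contact_cutoff = 5.0,
                            clash_cutoff = 3.0,
                            clash_max = 25L,
                            maxscore_threshold = 0.1,
                            top_consrank_pool = 30L,
                            top_clusters = 15L,
                            per_cluster = 2L,
                            n_submit = 10L,
                            seq_identity_min = 0.90,
                            coverage_min = 0.70,
                            sasa_probe = 1.4,
                            sasa_points = 960L) {
  stopifnot(contact_cutoff > 0, clash_cutoff > 0, sasa_probe > 0,
            clash_max >= 0, maxscore_threshold > 0,
            top_consrank_pool >= 1, top_clusters >= 1, per_cluster >= 1,
            n_submit >= 1, sasa_points >= 1)
  if (n_submit > top_consrank_pool + top_clusters * per_cluster)
    stop("n_submit exceeds the maximum candidate pool size")
  structure(list(contact_cutoff = contact_cutoff,
                 clash_cutoff = clash_cutoff,
                 clash_max = as.integer(clash_max),
                 maxscore_threshold = maxscore_threshold,
                 top_consrank_pool = as.integer(top_consrank_pool),
                 top_clusters = as.integer(top_clusters),
                 per_cluster = as.integer(per_cluster),
                 n_submit = as.integer(n_submit),
                 seq_identity_min = seq_identity_min,
                 coverage_min = coverage_min,
                 sasa_probe = sasa_probe,
                 sasa_points = as.integer(sasa_points)),
            class = "pipeline_config")
}
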