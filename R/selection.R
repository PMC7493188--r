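#' Build the candidate pool from the two scoring routes
#'
#' Union (deduplicated) of the top `config$top_consrank_pool` models of the
#' global CONSRANK ranking and the top `config$per_cluster` models of each of
#' the `config$top_clusters` most populated clusters, with interface reports
#' attached. A model reached via both routes occurs once and keeps both
#' provenances.
#'
#' @param ranking A `consrank_ranking` (global).
#' @param cluster_rankings Named list of cluster-local rankings from
#'   [per_cluster_rankings()].
#' @param models Named list of renumbered `decoy_model`s.
#' @param config A [pipeline_config()].
#' @param symmetric Use symmetric contact keys in the interface reports.
#' @return data.frame (model_id, consrank_rank, cluster, cluster_rank,
#'   S_norm, n_contacts, interface_area, n_clashes).
#' @export
build_candidate_pool <- function(ranking, cluster_rankings, models,
                                 config = pipeline_config(),
                                 symmetric = FALSE) {
  stopifnot(nrow(ranking) >= 1)
  top <- utils::head(as.data.frame(ranking), config$top_consrank_pool)
  pool <- data.frame(model_id = top$model_id, consrank_rank = top$rank,
                     cluster = NA_integer_, cluster_rank = NA_integer_,
                     S_norm = top$S_norm, stringsAsFactors = FALSE)
  for (cl in names(cluster_rankings)) {
    crk <- utils::head(as.data.frame(cluster_rankings[[cl]]),
                       config$per_cluster)
    for (r in seq_len(nrow(crk))) {
      id <- crk$model_id[r]
      hit <- match(id, pool$model_id)
      if (!is.na(hit)) {
        if (is.na(pool$cluster[hit])) {
          pool$cluster[hit] <- as.integer(cl)
          pool$cluster_rank[hit] <- crk$rank[r]
        }
      } else {
        pool <- rbind(pool, data.frame(
          model_id = id, consrank_rank = NA_integer_,
          cluster = as.integer(cl), cluster_rank = crk$rank[r],
          S_norm = crk$S_norm[r], stringsAsFactors = FALSE))
      }
    }
  }
  reps <- interface_reports(models[pool$model_id], config,
                            symmetric = symmetric)
  pool <- cbind(pool, reps[match(pool$model_id, reps$model_id),
                           c("n_contacts", "interface_area", "n_clashes")])
  rownames(pool) <- NULL
  pool
}

#' Choose the selection regime from the consensus sharpness
#'
#' A Maxscore at or above the threshold (default 0.1) marks a strong,
#' trustworthy consensus: the whole submission is drawn from the CONSRANK
#' ranking. Below it, the consensus is weak and the selection is diversified
#' across clusters.
#'
#' @param maxscore Normalized score of the top-ranked model, in `(0, 1]`.
#' @param config A [pipeline_config()].
#' @return `"strong-consensus"` or `"weak-consensus"`.
#' @export
#' @examples
#' choose_regime(0.243)  # strong
#' choose_regime(0.071)  # weak
choose_regime <- function(maxscore, config = pipeline_config()) {
  stopifnot(maxscore > 0, maxscore <= 1)
  if (maxscore >= config$maxscore_threshold) "strong-consensus"
  else "weak-consensus"
}

interface_order <- function(df)
  order(-df$n_contacts, -df$interface_area, -df$S_norm, df$model_id)

#' Final selection and interface-based ranking
#'
#' Implements the submission logic: (1) candidates with more than
#' `config$clash_max` clashes are excluded; (2) the regime fixes the quota --
#' strong consensus: all `n_submit` models from CONSRANK-sourced candidates;
#' weak consensus: the top surviving CONSRANK model plus the remainder drawn
#' from distinct clusters in population order (one per cluster before any
#' second picks); (3) models are ordered by contact count, then interface
#' area, then normalized score, all descending -- except that in the weak
#' regime the CONSRANK pick holds position 1.
#'
#' @param pool Candidate data.frame from [build_candidate_pool()].
#' @param regime From [choose_regime()].
#' @param config A [pipeline_config()].
#' @return A `selection_result`: list with `selection` (data.frame
#'   final_rank, model_id, source, consrank_rank, cluster, S_norm,
#'   n_contacts, interface_area, n_clashes), `regime`, `exclusions` (named
#'   vector model_id -> reason).
#' @export
final_rank <- function(pool, regime, config = pipeline_config()) {
  stopifnot(nrow(pool) >= 1)
  clashing <- pool$n_clashes > config$clash_max
  exclusions <- setNames(rep("clashes", sum(clashing)),
                         pool$model_id[clashing])
  ok <- pool[!clashing, , drop = FALSE]
  if (regime == "strong-consensus") {
    cand <- ok[!is.na(ok$consrank_rank), , drop = FALSE]
    cand <- cand[interface_order(cand), , drop = FALSE]
    sel <- utils::head(cand, config$n_submit)
  } else {
    cons <- ok[!is.na(ok$consrank_rank), , drop = FALSE]
    cons_pick <- utils::head(cons[order(cons$consrank_rank), , drop = FALSE],
                             1L)
    chosen <- cons_pick$model_id
    remaining <- config$n_submit - nrow(cons_pick)
    cluster_ids <- sort(unique(ok$cluster[!is.na(ok$cluster)]))
    picks <- ok[0, , drop = FALSE]
    pass <- 1L
    while (remaining > nrow(picks) && pass <= config$per_cluster) {
      for (cl in cluster_ids) {
        if (nrow(picks) >= remaining) break
        cc <- ok[!is.na(ok$cluster) & ok$cluster == cl &
                   !(ok$model_id %in% c(chosen, picks$model_id)), ,
                 drop = FALSE]
        cc <- cc[order(cc$cluster_rank), , drop = FALSE]
        if (nrow(cc)) picks <- rbind(picks, utils::head(cc, 1L))
      }
      pass <- pass + 1L
    }
    picks <- picks[interface_order(picks), , drop = FALSE]
    sel <- rbind(cons_pick, picks)
  }
  if (nrow(sel) < config$n_submit)
    warning(sprintf("only %d of %d requested models survive selection",
                    nrow(sel), config$n_submit))
  source <- ifelse(!is.na(sel$consrank_rank) &
                     (regime == "strong-consensus" | is.na(sel$cluster)),
                   sprintf("consrank:%d", sel$consrank_rank),
                   sprintf("cluster:%d", sel$cluster))
  if (regime == "weak-consensus" && nrow(sel) >= 1 &&
      !is.na(sel$consrank_rank[1]))
    source[1] <- sprintf("consrank:%d", sel$consrank_rank[1])
  selection <- data.frame(final_rank = seq_len(nrow(sel)),
                          model_id = sel$model_id, source = source,
                          consrank_rank = sel$consrank_rank,
                          cluster = sel$cluster, S_norm = sel$S_norm,
                          n_contacts = sel$n_contacts,
                          interface_area = sel$interface_area,
                          n_clashes = sel$n_clashes,
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(selection = selection, regime = regime,
                 exclusions = exclusions),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s, %d models selected, %d excluded\n",
              x$regime, nrow(x$selection), length(x$exclusions)))
  print(x$selection)
  invisible(x)
}

#' Run the full scoring pipeline
#'
#' Reads (or accepts) a decoy ensemble, filters and renumbers it against the
#' target, computes contact maps, the ensemble consensus and CONSRANK
#' ranking, clusters the models by contact Hamming distance
#' (complete linkage, maxclust at t = n/10), ranks within the most populated
#' clusters, builds the candidate pool, and produces the final
#' interface-ranked selection. Deterministic for fixed inputs and
#' configuration.
#'
#' @param x Directory of PDB files, character vector of paths, or a named
#'   list of `decoy_model`s.
#' @param target A [target_spec()] (or path to a FASTA file).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for all intermediate tables
#'   (filter report, ranking, consensus matrix, cluster table, interface
#'   table, selection table, run manifest).
#' @return A `scoring_run`: list with `filter_report`, `models`, `maps`,
#'   `rates`, `ranking`, `maxscore`, `tree`, `clusters`, `cluster_rankings`,
#'   `pool`, `regime`, `result`.
#' @export
run_pipeline <- function(x, target, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(target)) target <- read_target_fasta(target)
  if (is.character(x)) {
    rd <- read_ensemble(x)
    models <- rd$models; failures <- rd$failures
  } else {
    models <- x; failures <- character(0)
  }
  if (length(models) + length(failures) < 2)
    stop("pipeline requires at least 2 models")
  flt <- filter_ensemble(models, target, config = config,
                         prior_failures = failures)
  ren <- renumber_ensemble(flt$models, target, config)
  models <- ren$models
  ## homodimer ensembles use chain-agnostic (symmetric) contact keys
  seqs <- target$sequences
  symmetric <- length(seqs) == 2 && seqs[[1]] == seqs[[2]]
  maps <- lapply(models, compute_contact_map, cutoff = config$contact_cutoff,
                 symmetric = symmetric)
  zero <- vapply(maps, length, 0L) == 0
  report <- flt$report
  if (any(zero) || length(ren$discarded)) {
    disc <- report$discarded
    disc$zero_contacts <- c(disc$zero_contacts, names(models)[zero])
    disc$sequence_mismatch <- c(disc$sequence_mismatch, ren$discarded)
    models <- models[!zero]
    maps <- maps[!zero]
    report <- new_filter_report(report$n_input, names(models), disc)
  }
  if (length(models) < 2) stop("fewer than 2 scorable models remain")
  rates <- conservation_rates(maps)
  ranking <- rank_models(maps, rates)
  dv <- distance_vector(maps)
  tree <- complete_linkage(dv)
  clusters <- flat_clusters_maxclust(tree, default_t(length(maps)))
  cluster_rankings <- per_cluster_rankings(clusters, maps,
                                           config$top_clusters)
  pool <- build_candidate_pool(ranking, cluster_rankings, models, config,
                               symmetric = symmetric)
  regime <- choose_regime(maxscore(ranking), config)
  result <- final_rank(pool, regime, config)
  run <- structure(list(filter_report = report, models = models,
                        maps = maps, rates = rates, ranking = ranking,
                        maxscore = maxscore(ranking), tree = tree,
                        clusters = clusters,
                        cluster_rankings = cluster_rankings, pool = pool,
                        regime = regime, result = result, config = config),
                   class = "scoring_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.scoring_run <- function(x, ...) {
  cat(sprintf("<scoring_run> %d models scored, Maxscore %.3f (%s)\n",
              length(x$maps), x$maxscore, x$regime))
  print(x$result)
  invisible(x)
}

#' Write all pipeline artifacts
#'
#' @param run A `scoring_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_filter_report(run$filter_report, p("filter_report"))
  write_ranking(run$ranking, p("consrank_ranking.tsv"))
  export_consensus_map(run$rates, file = p("consensus"))
  write_cluster_table(run$clusters, p("clusters.tsv"))
  utils::write.table(run$pool, p("interface_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$result$selection, p("selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(package = "consrankr",
         version = as.character(utils::packageVersion("consrankr")),
         r_version = R.version.string,
         n_models = length(run$maps),
         maxscore = run$maxscore, regime = run$regime,
         config = unclass(run$config),
         exclusions = as.list(run$result$exclusions)),
    p("run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
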