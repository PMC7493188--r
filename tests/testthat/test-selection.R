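fake_pool <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(model_id = r$id,
               consrank_rank = r$cr %||% NA_integer_,
               cluster = r$cl %||% NA_integer_,
               cluster_rank = r$clr %||% NA_integer_,
               S_norm = r$s %||% 0.2,
               n_contacts = r$nc, interface_area = r$ar,
               n_clashes = r$clash %||% 0L,
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("regime choice follows the Maxscore threshold with >= boundary", {
  expect_equal(choose_regime(0.243), "strong-consensus")
  expect_equal(choose_regime(0.071), "weak-consensus")
  expect_equal(choose_regime(0.1), "strong-consensus")
  expect_error(choose_regime(0))
})

test_that("interface extent reorders candidates over consensus rank", {
  ## candidate B (CONSRANK 11th, 268 contacts, 4218 A^2) outranks
  ## candidate A (CONSRANK 1st, 170 contacts, 3266 A^2)
  pool <- fake_pool(list(id = "A", cr = 1L, s = 0.243, nc = 170, ar = 3266),
                    list(id = "B", cr = 11L, s = 0.20, nc = 268, ar = 4218))
  cfg <- pipeline_config(n_submit = 2)
  res <- final_rank(pool, "strong-consensus", cfg)
  expect_equal(res$selection$model_id, c("B", "A"))
})

test_that("candidates with more than 25 clashes are excluded", {
  pool <- fake_pool(
    list(id = "ok", cr = 1L, nc = 100, ar = 1000, clash = 25L),
    list(id = "bad", cr = 2L, nc = 300, ar = 5000, clash = 26L),
    list(id = "ok2", cr = 3L, nc = 90, ar = 900, clash = 0L))
  cfg <- pipeline_config(n_submit = 2)
  res <- final_rank(pool, "strong-consensus", cfg)
  expect_false("bad" %in% res$selection$model_id)
  expect_equal(unname(res$exclusions["bad"]), "clashes")
  expect_equal(res$selection$model_id, c("ok", "ok2"))  # 25 is tolerated
})

test_that("final ordering equals an independent stable sort oracle", {
  set.seed(51)
  n <- 40
  pool <- data.frame(model_id = sprintf("m%02d", 1:n),
                     consrank_rank = 1:n, cluster = NA_integer_,
                     cluster_rank = NA_integer_,
                     S_norm = round(runif(n), 2),
                     n_contacts = sample(5:12, n, TRUE),
                     interface_area = round(runif(n, 200, 400), -1),
                     n_clashes = 0L, stringsAsFactors = FALSE)
  res <- final_rank(pool, "strong-consensus", pipeline_config(n_submit = 40))
  oracle <- pool[order(-pool$n_contacts, -pool$interface_area,
                       -pool$S_norm, pool$model_id), "model_id"]
  expect_equal(res$selection$model_id, oracle)
})

test_that("candidate pool unions the two routes with both provenances", {
  set.seed(52)
  ens <- generate_ensemble(synthetic_spec(n_models = 40,
                                          planted_fraction = 0.4,
                                          seed = 52))
  maps <- lapply(ens$models, compute_contact_map, cutoff = 5,
                 symmetric = TRUE)
  rk <- rank_models(maps)
  cs <- flat_clusters_maxclust(complete_linkage(distance_vector(maps)),
                               default_t(40))
  pcr <- per_cluster_rankings(cs, maps, 15)
  cfg <- pipeline_config(top_consrank_pool = 10, per_cluster = 2)
  pool <- build_candidate_pool(rk, pcr, ens$models, cfg, symmetric = TRUE)
  expect_false(any(duplicated(pool$model_id)))
  expect_lte(nrow(pool), 10 + 2 * length(pcr))
  ## every consrank top-10 model present, with rank recorded
  expect_true(all(rk$model_id[1:10] %in% pool$model_id))
  ## dual-provenance models keep both fields
  both <- pool[!is.na(pool$consrank_rank) & !is.na(pool$cluster), ]
  if (nrow(both) > 0)
    expect_true(all(both$model_id %in% rk$model_id[1:10]))
  ## interface metrics attached for every candidate
  expect_true(all(!is.na(pool$n_contacts)))
  expect_true(all(!is.na(pool$interface_area)))
})

test_that("strong consensus draws the whole submission from CONSRANK", {
  ens <- generate_ensemble(synthetic_spec(n_models = 60,
                                          planted_fraction = 0.5,
                                          seed = 53))
  run <- run_pipeline(ens$models, ens$target)
  expect_equal(run$regime, "strong-consensus")
  expect_equal(nrow(run$result$selection), 10)
  expect_true(all(grepl("^consrank:", run$result$selection$source)))
  lab <- ens$truth$label[match(run$result$selection$model_id,
                               ens$truth$model_id)]
  expect_true(all(lab == "near-native"))
})

test_that("weak consensus takes one CONSRANK pick plus distinct clusters", {
  ens <- generate_ensemble(synthetic_spec(n_models = 100,
                                          planted_fraction = 0, seed = 54))
  ## few clusters can survive the maxclust cut at f = 0: a short selection
  ## (with its warning) is the documented behaviour
  run <- suppressWarnings(run_pipeline(ens$models, ens$target))
  expect_equal(run$regime, "weak-consensus")
  sel <- run$result$selection
  expect_equal(sum(grepl("^consrank:", sel$source)), 1)
  expect_equal(sel$source[1], sprintf("consrank:%d", sel$consrank_rank[1]))
  cl_picks <- sel$cluster[grepl("^cluster:", sel$source)]
  expect_equal(length(unique(cl_picks)),
               min(length(cl_picks),
                   length(run$clusters$members)))
})

test_that("the pipeline is deterministic and writes its artifacts", {
  ens <- generate_ensemble(synthetic_spec(n_models = 30,
                                          planted_fraction = 0.5,
                                          seed = 55))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  r1 <- run_pipeline(ens$models, ens$target, out_dir = dir1)
  r2 <- run_pipeline(ens$models, ens$target, out_dir = dir2)
  expect_identical(r1$result$selection, r2$result$selection)
  expect_identical(r1$ranking$model_id, r2$ranking$model_id)
  for (f in c("consrank_ranking.tsv", "clusters.tsv", "selection.tsv",
              "interface_table.tsv", "consensus_matrix.tsv",
              "filter_report.tsv", "run_manifest.json"))
    expect_true(file.exists(file.path(dir1, f)))
  ## byte-identical tables across reruns
  expect_identical(readLines(file.path(dir1, "selection.tsv")),
                   readLines(file.path(dir2, "selection.tsv")))
})

test_that("identical decoys give unit scores and tie-broken selection", {
  ref <- make_reference_dimer(synthetic_spec())
  models <- lapply(sprintf("copy_%02d", 1:12), function(id) {
    m <- ref; m$model_id <- id; m
  })
  names(models) <- sprintf("copy_%02d", 1:12)
  run <- run_pipeline(models, polyA_target(30))
  expect_true(all(run$ranking$S_norm == 1))
  expect_equal(run$maxscore, 1)
  expect_equal(run$regime, "strong-consensus")
  expect_equal(run$result$selection$model_id, sprintf("copy_%02d", 1:10))
})

test_that("pipeline runs identically from files on disk", {
  dir <- withr::local_tempdir()
  ens <- generate_ensemble(synthetic_spec(n_models = 20,
                                          planted_fraction = 0.5,
                                          seed = 56), dir = dir)
  run_mem <- run_pipeline(ens$models, ens$target)
  run_disk <- run_pipeline(dir, file.path(dir, "target.fasta"))
  expect_equal(run_mem$result$selection$model_id,
               run_disk$result$selection$model_id)
  expect_equal(run_mem$maxscore, run_disk$maxscore)
})
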