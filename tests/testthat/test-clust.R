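test_that("distance vector has condensed layout and oracle values", {
  set.seed(31)
  maps <- random_maps(6)
  dv <- distance_vector(maps)
  expect_equal(length(dv), 6 * 5 / 2)
  expect_true(all(dv >= 0))
  D <- as.matrix(dv)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], hamming_distance(maps[[i]], maps[[j]]))
  ## condensed index formula: entry for 0-based (i,j) at i*n - i(i+1)/2 + j-i-1
  n <- 6
  for (i0 in 0:(n - 2)) for (j0 in (i0 + 1):(n - 1)) {
    k <- i0 * n - i0 * (i0 + 1) / 2 + (j0 - i0 - 1) + 1
    expect_equal(dv[k], D[i0 + 1, j0 + 1])
  }
  expect_equal(length(distance_vector(maps[1:2])), 1)
  ident <- lapply(1:3, function(i)
    new_contact_map(c("A:1|B:1"), paste0("m", i)))
  expect_equal(as.numeric(distance_vector(ident)), c(0, 0, 0))
})

test_that("complete linkage matches the naive recomputation oracle", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    ## integer distances: plenty of ties to exercise the tie rule
    D <- matrix(0L, n, n)
    D[upper.tri(D)] <- sample(1:8, n * (n - 1) / 2, replace = TRUE)
    D <- D + t(D)
    dv <- stats::as.dist(D)
    attr(dv, "Labels") <- sprintf("m%03d", 1:n)
    tree <- complete_linkage(dv)
    oracle <- oracle_complete_linkage(D)
    expect_equal(tree$height, oracle$heights)
    expect_equal(replay_partitions(tree), oracle$partitions)
  }
})

test_that("complete linkage agrees with stats::hclust on tie-free input", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 1, 100)
    D <- D + t(D)
    dv <- stats::as.dist(D)
    tree <- complete_linkage(dv)
    ref <- stats::hclust(dv, method = "complete")
    expect_equal(tree$height, ref$height)
    for (k in c(1, 2, min(5, n))) {
      a <- stats::cutree(tree, k)
      b <- stats::cutree(ref, k)
      ## same partition up to label permutation
      expect_equal(length(unique(paste(a, b))), length(unique(a)))
    }
  }
})

test_that("two separated groups merge last", {
  set.seed(34)
  base1 <- sprintf("A:%d|B:%d", 1:20, 1:20)
  base2 <- sprintf("A:%d|B:%d", 31:50, 31:50)
  maps <- c(lapply(1:4, function(i)
    new_contact_map(sample(base1, 15), paste0("g1_", i))),
    lapply(1:4, function(i)
      new_contact_map(sample(base2, 15), paste0("g2_", i))))
  tree <- complete_linkage(distance_vector(maps))
  expect_equal(max(tree$height), tree$height[length(tree$height)])
  cs <- flat_clusters_maxclust(tree, 2)
  groups <- substr(names(cs$labels), 1, 2)
  expect_equal(length(unique(cs$labels[groups == "g1"])), 1)
  expect_equal(length(unique(cs$labels[groups == "g2"])), 1)
  expect_true(all(cs$labels[groups == "g1"] != cs$labels[groups == "g2"]))
})

test_that("maxclust extremes give singletons and one cluster", {
  set.seed(35)
  maps <- random_maps(8, min_m = 4, max_m = 10)
  dv <- distance_vector(maps)
  tree <- complete_linkage(dv)
  if (all(dv > 0)) {
    singles <- flat_clusters_maxclust(tree, 8)
    expect_equal(length(singles$members), 8)
  }
  one <- flat_clusters_maxclust(tree, 1)
  expect_equal(length(one$members), 1)
  expect_equal(one$populations, 8)
})

test_that("cluster sets partition the ensemble with populations sorted", {
  set.seed(36)
  maps <- random_maps(30)
  cs <- flat_clusters_maxclust(complete_linkage(distance_vector(maps)), 5)
  expect_lte(length(cs$members), 5)
  expect_equal(sum(cs$populations), 30)
  expect_equal(sort(unlist(cs$members)),
               sort(vapply(maps, attr, "", "model_id")))
  expect_true(all(diff(cs$populations) <= 0))
  expect_equal(unname(cs$labels[cs$members[[1]]]),
               rep(0L, cs$populations[1]))
})

test_that("clustering is invariant under input permutation", {
  set.seed(37)
  maps <- random_maps(20)
  cs1 <- flat_clusters_maxclust(complete_linkage(distance_vector(maps)), 4)
  perm <- sample(20)
  cs2 <- flat_clusters_maxclust(
    complete_linkage(distance_vector(maps[perm])), 4)
  ids <- names(cs1$labels)
  expect_equal(cs1$labels[ids], cs2$labels[ids])
})

test_that("default_t floors n/10 with a minimum of one", {
  expect_equal(default_t(40), 4L)
  expect_equal(default_t(1916), 191L)
  expect_equal(default_t(9), 1L)
  expect_equal(default_t(2), 1L)
})

test_that("per-cluster rankings equal a local CONSRANK on the subset", {
  set.seed(38)
  maps <- random_maps(24)
  cs <- flat_clusters_maxclust(complete_linkage(distance_vector(maps)), 3)
  pcr <- per_cluster_rankings(cs, maps, top_clusters = 2)
  expect_equal(names(pcr), c("0", "1"))
  ids <- vapply(maps, attr, "", "model_id")
  for (cl in names(pcr)) {
    sub <- maps[match(cs$members[[as.integer(cl) + 1]], ids)]
    if (length(sub) >= 2) {
      oracle <- oracle_consrank(sub)
      got <- as.data.frame(pcr[[cl]])
      for (r in seq_len(nrow(got))) {
        i <- match(got$model_id[r], vapply(sub, attr, "", "model_id"))
        expect_equal(got$S_norm[r], oracle$scores[[i]]$S_norm)
      }
    } else {
      expect_equal(pcr[[cl]]$S_norm, 1)
    }
  }
})

test_that("single-member clusters rank degenerately at score 1", {
  maps <- list(new_contact_map(c("A:1|B:1", "A:2|B:2"), "a"),
               new_contact_map(c("A:1|B:1", "A:2|B:2"), "b"),
               new_contact_map(c("A:9|B:9"), "lone"))
  cs <- flat_clusters_maxclust(complete_linkage(distance_vector(maps)), 2)
  pcr <- per_cluster_rankings(cs, maps, 2)
  lone_cl <- as.character(unname(cs$labels["lone"]))
  expect_equal(pcr[[lone_cl]]$S_norm, 1)
  expect_equal(pcr[[lone_cl]]$M, 1)
})
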