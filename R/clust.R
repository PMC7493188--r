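#' Condensed Hamming distance vector of an ensemble
#'
#' Pairwise contact-map Hamming distances of all n(n-1)/2 model pairs, in
#' condensed upper-triangular row-major order (the entry for pair (i, j),
#' i < j, sits at k = i*n - i(i+1)/2 + (j - i - 1) with 0-based i, j, k).
#' Returned as a base `dist` object so standard tooling applies.
#'
#' @param maps List of `contact_map` objects (n >= 2).
#' @return A `dist` object of integer Hamming distances, labelled by
#'   model id.
#' @export
distance_vector <- function(maps) {
  n <- length(maps)
  stopifnot(n >= 2)
  ## map contacts to a global integer alphabet once, then intersect counts
  sets <- lapply(maps, unclass)
  alphabet <- unique(unlist(sets, use.names = FALSE))
  sets <- lapply(sets, match, table = alphabet)
  sizes <- lengths(sets)
  d <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    si <- sets[[i]]
    for (j in (i + 1):n) {
      shared <- sum(!is.na(match(si, sets[[j]])))
      k <- k + 1L
      d[k] <- sizes[i] + sizes[j] - 2 * shared
    }
  }
  structure(d, Size = n, Labels = vapply(maps, attr, "", "model_id"),
            Diag = FALSE, Upper = FALSE, method = "hamming", class = "dist")
}

#' Complete-linkage agglomerative clustering
#'
#' Bottom-up agglomeration where the distance between two clusters is the
#' maximum pairwise distance between their members (farthest-point
#' criterion). Ties between equally distant merge candidates are broken by
#' the smallest member label (falling back on the member index when the
#' distance object is unlabelled), so the merge tree is deterministic and
#' independent of input order.
#'
#' @param dv A `dist` object (e.g. from [distance_vector()]).
#' @return An object of class `hclust` (merge, height, order, labels), fully
#'   compatible with [stats::cutree()] and plotting.
#' @export
complete_linkage <- function(dv) {
  n <- attr(dv, "Size")
  labels <- attr(dv, "Labels")
  if (is.null(labels)) labels <- sprintf("%09d", seq_len(n))
  D <- as.matrix(dv)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  code <- -seq_len(n)           # hclust encoding: singletons negative
  min_member <- labels
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## deterministic tie-break: smallest member index of either cluster,
    ## then of the other
    a <- idx[cand[, 1]]; b <- idx[cand[, 2]]
    lo <- pmin(min_member[a], min_member[b])
    hi <- pmax(min_member[a], min_member[b])
    pick <- order(lo, hi)[1]
    ia <- a[pick]; ib <- b[pick]
    if (min_member[ib] < min_member[ia]) { tmp <- ia; ia <- ib; ib <- tmp }
    merge[k, ] <- c(code[ia], code[ib])
    height[k] <- dmin
    ## merged cluster kept in slot ia; complete linkage: row-wise max
    D[ia, ] <- pmax(D[ia, ], D[ib, ])
    D[, ia] <- D[ia, ]
    D[ia, ia] <- Inf
    active[ib] <- FALSE
    code[ia] <- k
    min_member[ia] <- min(min_member[ia], min_member[ib])
  }
  structure(list(merge = merge, height = height,
                 order = tree_order(merge, n), labels = labels,
                 method = "complete", call = match.call(),
                 dist.method = attr(dv, "method")),
            class = "hclust")
}

## leaf order for plotting: left-to-right traversal of the merge tree
tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  if (n == 1) return(1L)
  expand(nrow(merge))
}

#' Flat clusters under the maxclust criterion
#'
#' Cuts the merge tree at the smallest height producing no more than `t`
#' flat clusters (merges at equal height are inseparable and are applied
#' together). Clusters are then ranked by population, descending, and
#' numbered consecutively starting from 0; population ties are broken by the
#' smallest contained model id, so numbering does not depend on input order.
#'
#' @param tree An `hclust` object from [complete_linkage()].
#' @param t Maximum number of flat clusters (>= 1).
#' @return A `cluster_set`: list with `t`, `threshold` (cut height),
#'   `labels` (named integer vector model_id -> cluster number),
#'   `members` (list of model-id vectors per cluster, population order),
#'   `populations`.
#' @export
flat_clusters_maxclust <- function(tree, t) {
  stopifnot(t >= 1)
  n <- length(tree$labels)
  h <- cummax(tree$height)       # guard monotonicity for the cut
  ## candidate thresholds: below the first merge, or at each merge height
  cand <- c(-1, unique(h))
  counts <- vapply(cand, function(th) n - sum(h <= th), 0L)
  ok <- which(counts <= t)
  threshold <- cand[ok[1]]
  k_merges <- sum(h <= threshold)
  ## union-find over the first k_merges merges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_code <- integer(max(1, n - 1))   # representative per merge node
  for (k in seq_len(k_merges)) {
    reps <- vapply(tree$merge[k, ], function(cd)
      if (cd < 0) find(-cd) else find(cluster_of_code[cd]), 0L)
    parent[reps[2]] <- reps[1]
    cluster_of_code[k] <- reps[1]
  }
  raw <- vapply(seq_len(n), find, 0L)
  ## number by population desc, ties by smallest contained model id (a
  ## permutation-invariant rule)
  reps <- unique(raw)
  pops <- vapply(reps, function(r) sum(raw == r), 0L)
  first <- vapply(reps, function(r) min(tree$labels[raw == r]), "")
  ord <- order(-pops, first)
  renum <- setNames(seq_along(reps) - 1L, reps[ord])
  labels <- setNames(renum[as.character(raw)], tree$labels)
  members <- lapply(seq_along(reps) - 1L, function(cl)
    tree$labels[labels == cl])
  structure(list(t = as.integer(t), threshold = threshold,
                 labels = labels, members = members,
                 populations = lengths(members)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (t = %d, cut at %g)\n",
              length(x$members), x$t, x$threshold))
  cat("  populations:", paste(x$populations, collapse = " "), "\n")
  invisible(x)
}

#' Default maximum cluster count
#'
#' One tenth of the ensemble size (floored), with a minimum of one, making
#' the clustering granularity independent of ensemble size.
#'
#' @param n Ensemble size (>= 2).
#' @return Positive integer.
#' @export
#' @examples
#' default_t(1916)  # 191
default_t <- function(n) {
  stopifnot(n >= 2)
  max(1L, as.integer(floor(n / 10)))
}

#' Cluster-local CONSRANK rankings
#'
#' For each of the `top_clusters` most populated clusters, conservation rates
#' and the CONSRANK ranking are recomputed within the cluster only (the
#' cluster's own size is the consensus n). A single-member cluster yields the
#' degenerate ranking with normalized score 1.
#'
#' @param clusterset A `cluster_set`.
#' @param maps The ensemble contact maps (superset of the cluster set).
#' @param top_clusters How many clusters, in population order, to rank.
#' @return Named list (cluster number as name) of `consrank_ranking`s.
#' @export
per_cluster_rankings <- function(clusterset, maps, top_clusters = 15L) {
  ids <- vapply(maps, attr, "", "model_id")
  stopifnot(all(names(clusterset$labels) %in% ids))
  ncl <- min(top_clusters, length(clusterset$members))
  out <- list()
  for (cl in seq_len(ncl) - 1L) {
    mids <- clusterset$members[[cl + 1L]]
    sub <- maps[match(mids, ids)]
    if (length(sub) == 1) {
      df <- data.frame(rank = 1L, model_id = mids,
                       S_norm = 1, S = as.numeric(length(sub[[1]])),
                       M = length(sub[[1]]), stringsAsFactors = FALSE)
      rk <- structure(df, maxscore = 1,
                      class = c("consrank_ranking", "data.frame"))
    } else {
      rk <- rank_models(sub, conservation_rates(sub))
    }
    out[[as.character(cl)]] <- rk
  }
  out
}

#' Write a cluster assignment table
#'
#' Columns: model_id, cluster, population.
#'
#' @param clusterset A `cluster_set`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusterset, path) {
  df <- data.frame(model_id = names(clusterset$labels),
                   cluster = unname(clusterset$labels))
  df$population <- clusterset$populations[df$cluster + 1L]
  df <- df[order(df$cluster, df$model_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
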