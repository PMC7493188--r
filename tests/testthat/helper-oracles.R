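## Independent oracles, deliberately written with different algorithms/data
## structures than the package internals.

## brute-force contact map: loop over all residue pairs, min over the full
## atom-pair distance matrix
oracle_contact_map <- function(model, cutoff, symmetric = FALSE) {
  at <- model$atoms
  if (!is.null(at$scored)) at <- at[at$scored, , drop = FALSE]
  res <- unique(at[, c("chain", "resno")])
  keys <- character(0)
  for (i in seq_len(nrow(res) - 1)) for (j in (i + 1):nrow(res)) {
    if (res$chain[i] == res$chain[j]) next
    a <- at[at$chain == res$chain[i] & at$resno == res$resno[i],
            c("x", "y", "z")]
    b <- at[at$chain == res$chain[j] & at$resno == res$resno[j],
            c("x", "y", "z")]
    dmin <- Inf
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt(sum((a[p, ] - b[q, ])^2)))
    if (dmin < cutoff) {
      keys <- c(keys, if (symmetric)
        paste0(min(res$resno[i], res$resno[j]), "~",
               max(res$resno[i], res$resno[j]))
      else {
        k1 <- paste0(res$chain[i], ":", res$resno[i])
        k2 <- paste0(res$chain[j], ":", res$resno[j])
        paste(sort(c(k1, k2))[1], sort(c(k1, k2))[2], sep = "|")
      })
    }
  }
  sort(unique(keys))
}

## brute-force inter-chain atom-pair count below cutoff
oracle_clash_count <- function(model, cutoff) {
  at <- model$atoms
  n <- 0L
  for (p in seq_len(nrow(at) - 1)) for (q in (p + 1):nrow(at)) {
    if (at$chain[p] == at$chain[q]) next
    d <- sqrt((at$x[p] - at$x[q])^2 + (at$y[p] - at$y[q])^2 +
              (at$z[p] - at$z[q])^2)
    if (d < cutoff) n <- n + 1L
  }
  n
}

## tally-based conservation rates and per-model scores
oracle_consrank <- function(maps) {
  n <- length(maps)
  all_contacts <- unique(unlist(lapply(maps, as.character)))
  rate <- vapply(all_contacts, function(ct)
    sum(vapply(maps, function(m) ct %in% as.character(m), TRUE)) / n, 0)
  scores <- lapply(maps, function(m) {
    keys <- as.character(m)
    S <- sum(rate[keys])
    list(S = S, M = length(keys), S_norm = S / length(keys))
  })
  list(rate = rate, scores = scores)
}

## from-scratch complete-linkage agglomeration: at every step inter-cluster
## distances are recomputed as the max over original member distances; ties
## broken by smallest member index. Records the merge height and the full
## partition after each merge (canonicalized).
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      d <- max(D[clusters[[a]], clusters[[b]]])
      cand <- c(d, min(min(clusters[[a]]), min(clusters[[b]])),
                max(min(clusters[[a]]), min(clusters[[b]])))
      if (is.null(best) ||
          cand[1] < best$key[1] ||
          (cand[1] == best$key[1] && (cand[2] < best$key[2] ||
            (cand[2] == best$key[2] && cand[3] < best$key[3])))) {
        best <- list(key = cand, a = a, b = b)
      }
    }
    heights <- c(heights, best$key[1])
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- c(clusters[-c(best$a, best$b)], list(merged))
    partitions[[length(partitions) + 1]] <-
      sort(vapply(clusters, function(cl) paste(sort(cl), collapse = ","), ""))
  }
  list(heights = heights, partitions = partitions)
}

## replay the package merge tree into the same canonical partition strings
replay_partitions <- function(tree) {
  n <- nrow(tree$merge) + 1
  node_members <- vector("list", n - 1)
  members_of <- function(code)
    if (code < 0) -code else node_members[[code]]
  clusters <- lapply(seq_len(n), identity)
  partitions <- list()
  for (k in seq_len(n - 1)) {
    m1 <- members_of(tree$merge[k, 1]); m2 <- members_of(tree$merge[k, 2])
    node_members[[k]] <- sort(c(m1, m2))
    keys <- vapply(clusters, function(cl) paste(sort(cl), collapse = ","), "")
    drop <- keys %in% c(paste(sort(m1), collapse = ","),
                        paste(sort(m2), collapse = ","))
    clusters <- c(clusters[!drop], list(node_members[[k]]))
    partitions[[k]] <-
      sort(vapply(clusters, function(cl) paste(sort(cl), collapse = ","), ""))
  }
  partitions
}

## exact accessible area of sphere 1 (radius r1, at origin) occluded by
## sphere 2 (radius r2, centre distance d): spherical-cap closed form
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- r1 - x
  4 * pi * r1^2 - 2 * pi * r1 * h
}

## random contact maps over a synthetic contact alphabet
random_maps <- function(n_maps, alphabet_size = 60, min_m = 1, max_m = 15,
                        ids = sprintf("m%03d", seq_len(n_maps))) {
  alphabet <- sprintf("A:%d|B:%d",
                      rep(1:10, each = alphabet_size / 10),
                      rep(seq_len(alphabet_size / 10), 10))
  lapply(seq_len(n_maps), function(i)
    new_contact_map(sample(alphabet, sample(min_m:max_m, 1)), ids[i]))
}

spearman <- function(x, y) suppressWarnings(cor(x, y, method = "spearman"))
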