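## Contact maps are stored as sorted character vectors of canonical keys:
##   asymmetric key : "A:12|B:34"  (sides ordered lexicographically)
##   symmetric  key : "12~34"      (residue indices, lower first) -- used for
##                                  homo-oligomers so a pose and its
##                                  chain-relabelled mirror map identically.

contact_keys <- function(chain1, res1, chain2, res2, symmetric = FALSE) {
  if (symmetric) {
    lo <- pmin(res1, res2); hi <- pmax(res1, res2)
    sprintf("%d~%d", lo, hi)
  } else {
    a <- sprintf("%s:%d", chain1, res1)
    b <- sprintf("%s:%d", chain2, res2)
    swap <- a > b
    ifelse(swap, paste(b, a, sep = "|"), paste(a, b, sep = "|"))
  }
}

parse_contact_keys <- function(keys) {
  if (length(keys) == 0)
    return(data.frame(chain1 = character(0), res1 = integer(0),
                      chain2 = character(0), res2 = integer(0)))
  if (grepl("~", keys[1], fixed = TRUE)) {
    parts <- do.call(rbind, strsplit(keys, "~", fixed = TRUE))
    data.frame(chain1 = "*", res1 = as.integer(parts[, 1]),
               chain2 = "*", res2 = as.integer(parts[, 2]),
               stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "[|:]"))
    data.frame(chain1 = parts[, 1], res1 = as.integer(parts[, 2]),
               chain2 = parts[, 3], res2 = as.integer(parts[, 4]),
               stringsAsFactors = FALSE)
  }
}

#' Construct a contact map from contact keys
#'
#' Keys are canonical strings, either `"A:12|B:34"` (chain:residue pairs,
#' lexicographically ordered) or `"12~34"` (chain-agnostic symmetric keys
#' for homo-oligomers). Duplicates are removed; the sorted unique key set is
#' the contact set and its length is the contact count M.
#'
#' @param keys Character vector of contact keys.
#' @param model_id Model identifier stored in attribute `"model_id"`.
#' @return Object of class `contact_map`.
#' @export
new_contact_map <- function(keys, model_id = NA_character_) {
  structure(sort(unique(keys)), model_id = model_id, class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: M = %d contacts\n",
              attr(x, "model_id"), length(x)))
  invisible(x)
}

## All atom-index pairs (i from xyz1, j from xyz2) with distance < cutoff.
## Exact: a bounding-box prefilter discards atoms that cannot be within
## cutoff of the other group, then distances are evaluated in vectorized
## blocks. Returns a 3-column matrix (i, j, dist).
close_pairs <- function(xyz1, xyz2, cutoff, block = 2e6) {
  n1 <- nrow(xyz1); n2 <- nrow(xyz2)
  empty <- cbind(i = integer(0), j = integer(0), d = numeric(0))
  if (n1 == 0 || n2 == 0) return(empty)
  lo2 <- apply(xyz2, 2, min) - cutoff; hi2 <- apply(xyz2, 2, max) + cutoff
  keep1 <- which(xyz1[, 1] >= lo2[1] & xyz1[, 1] <= hi2[1] &
                 xyz1[, 2] >= lo2[2] & xyz1[, 2] <= hi2[2] &
                 xyz1[, 3] >= lo2[3] & xyz1[, 3] <= hi2[3])
  if (!length(keep1)) return(empty)
  lo1 <- apply(xyz1[keep1, , drop = FALSE], 2, min) - cutoff
  hi1 <- apply(xyz1[keep1, , drop = FALSE], 2, max) + cutoff
  keep2 <- which(xyz2[, 1] >= lo1[1] & xyz2[, 1] <= hi1[1] &
                 xyz2[, 2] >= lo1[2] & xyz2[, 2] <= hi1[2] &
                 xyz2[, 3] >= lo1[3] & xyz2[, 3] <= hi1[3])
  if (!length(keep2)) return(empty)
  a <- xyz1[keep1, , drop = FALSE]; b <- xyz2[keep2, , drop = FALSE]
  cut2 <- cutoff^2
  rows_per_chunk <- max(1L, floor(block / length(keep2)))
  out <- list()
  for (s in seq(1L, length(keep1), by = rows_per_chunk)) {
    e <- min(s + rows_per_chunk - 1L, length(keep1))
    ach <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ach^2), rowSums(b^2), "+") - 2 * tcrossprod(ach, b)
    hit <- which(d2 < cut2, arr.ind = TRUE)
    if (nrow(hit))
      out[[length(out) + 1L]] <-
        cbind(i = keep1[s:e][hit[, 1]], j = keep2[hit[, 2]],
              d = sqrt(pmax(d2[hit], 0)))
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

scored_atoms <- function(model) {
  at <- model$atoms
  if (!is.null(at$scored)) at <- at[at$scored, , drop = FALSE]
  at
}

#' Compute the inter-residue contact map of a model
#'
#' Two residues on different chains are in contact if any pair of their heavy
#' atoms is closer than `cutoff` (strict `<`; default 5 A). By default all
#' inter-chain residue pairs are considered; `chain_groups` restricts the
#' computation to contacts across a designated bipartition of the chains.
#'
#' For homo-oligomers (`symmetric = TRUE`) contacts are keyed by the unordered
#' pair of residue indices only, so a pose and its chain-relabelled mirror
#' produce identical maps.
#'
#' @param model A `decoy_model` (renumbered for ensemble use).
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param chain_groups Optional list of two character vectors of chain labels.
#' @param symmetric Use symmetric (chain-agnostic) contact keys.
#' @return A `contact_map`: sorted character vector of contact keys with the
#'   model id in attribute `"model_id"`; its length is the contact count M.
#' @export
#' @examples
#' m <- make_reference_dimer(synthetic_spec())
#' compute_contact_map(m, 5)
compute_contact_map <- function(model, cutoff = 5.0, chain_groups = NULL,
                                symmetric = FALSE) {
  stopifnot(cutoff > 0)
  at <- scored_atoms(model)
  chains <- unique(at$chain)
  if (is.null(chain_groups)) {
    if (length(model$chains) < 2) stop("model has fewer than 2 chains")
    pairs <- utils::combn(chains, 2, simplify = FALSE)
  } else {
    stopifnot(length(chain_groups) == 2)
    missing <- setdiff(unlist(chain_groups), model$chains)
    if (length(missing))
      stop("chain_groups names chains absent from model: ",
           paste(missing, collapse = ","))
    pairs <- list()
    for (c1 in intersect(chain_groups[[1]], chains))
      for (c2 in intersect(chain_groups[[2]], chains))
        pairs[[length(pairs) + 1L]] <- c(c1, c2)
  }
  keys <- character(0)
  for (pr in pairs) {
    a1 <- at[at$chain == pr[1], , drop = FALSE]
    a2 <- at[at$chain == pr[2], , drop = FALSE]
    cp <- close_pairs(as.matrix(a1[, c("x", "y", "z")]),
                      as.matrix(a2[, c("x", "y", "z")]), cutoff)
    if (nrow(cp) == 0) next
    keys <- c(keys, contact_keys(pr[1], a1$resno[cp[, "i"]],
                                 pr[2], a2$resno[cp[, "j"]],
                                 symmetric = symmetric))
  }
  new_contact_map(keys, model$model_id)
}

#' Contact table with minimum inter-residue distances
#'
#' Per-contact detail used for export: residue identities on both sides and
#' the minimum heavy-atom distance.
#'
#' @inheritParams compute_contact_map
#' @return data.frame: chain1, resno1, resname1, chain2, resno2, resname2,
#'   min_dist.
#' @export
contact_table <- function(model, cutoff = 5.0, chain_groups = NULL) {
  at <- scored_atoms(model)
  chains <- unique(at$chain)
  rows <- list()
  for (pr in utils::combn(chains, 2, simplify = FALSE)) {
    a1 <- at[at$chain == pr[1], , drop = FALSE]
    a2 <- at[at$chain == pr[2], , drop = FALSE]
    cp <- close_pairs(as.matrix(a1[, c("x", "y", "z")]),
                      as.matrix(a2[, c("x", "y", "z")]), cutoff)
    if (nrow(cp) == 0) next
    df <- data.frame(chain1 = pr[1], resno1 = a1$resno[cp[, "i"]],
                     resname1 = a1$resid[cp[, "i"]],
                     chain2 = pr[2], resno2 = a2$resno[cp[, "j"]],
                     resname2 = a2$resid[cp[, "j"]],
                     min_dist = cp[, "d"], stringsAsFactors = FALSE)
    agg <- stats::aggregate(min_dist ~ chain1 + resno1 + resname1 +
                              chain2 + resno2 + resname2, df, min)
    rows[[length(rows) + 1L]] <- agg
  }
  if (!length(rows))
    return(data.frame(chain1 = character(0), resno1 = integer(0),
                      resname1 = character(0), chain2 = character(0),
                      resno2 = integer(0), resname2 = character(0),
                      min_dist = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$chain1, out$resno1, out$chain2, out$resno2), , drop = FALSE]
}

#' Hamming distance between two contact maps
#'
#' The absolute number of differing contacts: the size of the symmetric
#' difference of the two contact sets.
#'
#' @param x,y `contact_map` objects built on consistently renumbered models.
#' @return Non-negative integer.
#' @export
#' @examples
#' x <- new_contact_map(c("A:1|B:1", "A:2|B:2"))
#' y <- new_contact_map(c("A:1|B:1", "A:3|B:3"))
#' hamming_distance(x, y)  # 2
hamming_distance <- function(x, y) {
  length(x) + length(y) - 2L * sum(!is.na(match(unclass(x), unclass(y))))
}

#' Count inter-chain steric clashes
#'
#' Number of inter-chain heavy-atom pairs at distance below `cutoff`
#' (strict `<`; default 3 A). Counts atom pairs, not residue pairs.
#'
#' @param model A `decoy_model`.
#' @param cutoff Clash distance cutoff in Angstrom.
#' @param chain_groups Optional bipartition of the chains (as in
#'   [compute_contact_map()]); default: all inter-chain pairs.
#' @return Non-negative integer.
#' @export
count_clashes <- function(model, cutoff = 3.0, chain_groups = NULL) {
  stopifnot(cutoff > 0)
  at <- model$atoms
  chains <- unique(at$chain)
  if (is.null(chain_groups)) pairs <- utils::combn(chains, 2, simplify = FALSE)
  else {
    pairs <- list()
    for (c1 in intersect(chain_groups[[1]], chains))
      for (c2 in intersect(chain_groups[[2]], chains))
        pairs[[length(pairs) + 1L]] <- c(c1, c2)
  }
  n <- 0L
  for (pr in pairs) {
    cp <- close_pairs(
      as.matrix(at[at$chain == pr[1], c("x", "y", "z")]),
      as.matrix(at[at$chain == pr[2], c("x", "y", "z")]), cutoff)
    n <- n + nrow(cp)
  }
  n
}

#' Write a per-model contact table
#'
#' @param model A `decoy_model`.
#' @param path Output TSV file.
#' @param cutoff Contact cutoff (A).
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(model, path, cutoff = 5.0) {
  utils::write.table(contact_table(model, cutoff), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
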