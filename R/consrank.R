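#' Contact conservation rates over an ensemble
#'
#' For every inter-residue contact observed in at least one model, the
#' conservation rate CR is the fraction of ensemble models containing it
#' (so 1/n <= CR <= 1).
#'
#' @param maps List of `contact_map` objects on consistently renumbered
#'   models (n >= 2).
#' @return A `conservation_map`: named numeric vector contact key -> rate,
#'   with ensemble size in attribute `"n"`.
#' @export
#' @examples
#' maps <- list(new_contact_map(c("A:1|B:1", "A:2|B:2"), "m1"),
#'              new_contact_map(c("A:1|B:1"), "m2"))
#' conservation_rates(maps)
conservation_rates <- function(maps) {
  n <- length(maps)
  if (n < 2) stop("consensus undefined: need at least 2 contact maps")
  counts <- table(unlist(lapply(maps, unclass), use.names = FALSE))
  rate <- as.numeric(counts) / n
  structure(setNames(rate, names(counts)), n = n, class = "conservation_map")
}

#' @export
print.conservation_map <- function(x, ...) {
  cat(sprintf("<conservation_map> %d contacts over n = %d models\n",
              length(x), attr(x, "n")))
  invisible(x)
}

#' CONSRANK score of a model
#'
#' Raw score S = sum of the conservation rates of the model's M contacts;
#' normalized score = S / M. Contacts absent from the rates table (possible
#' when scoring an external model against a fixed ensemble) contribute 0 to
#' S but still count in M.
#'
#' @param map A `contact_map`.
#' @param rates A `conservation_map` from [conservation_rates()].
#' @return list(S, M, S_norm).
#' @export
consrank_score <- function(map, rates) {
  M <- length(map)
  if (M == 0) stop("model has zero contacts (should have been filtered)")
  r <- unname(rates)[match(unclass(map), names(rates))]
  r[is.na(r)] <- 0
  S <- sum(r)
  list(S = S, M = M, S_norm = S / M)
}

#' Rank an ensemble by normalized CONSRANK score
#'
#' Models are ordered by normalized score, descending. Ties are broken by
#' contact count M descending (richer interface preferred), then model id
#' ascending, so the order is total and input-order invariant. The head
#' score (normalized score of the top model) is the Maxscore, a proxy for
#' the sharpness of the ensemble consensus.
#'
#' @param maps List of `contact_map` objects.
#' @param rates A `conservation_map`; computed from `maps` if missing.
#' @return A `consrank_ranking`: data.frame (rank, model_id, S_norm, S, M)
#'   with the Maxscore in attribute `"maxscore"`.
#' @export
rank_models <- function(maps, rates = NULL) {
  if (is.null(rates)) rates <- conservation_rates(maps)
  ids <- vapply(maps, attr, "", "model_id")
  sc <- lapply(maps, consrank_score, rates = rates)
  df <- data.frame(model_id = ids,
                   S_norm = vapply(sc, `[[`, 0, "S_norm"),
                   S = vapply(sc, `[[`, 0, "S"),
                   M = vapply(sc, `[[`, 0L, "M"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$S_norm, -df$M, df$model_id), , drop = FALSE]
  df <- data.frame(rank = seq_len(nrow(df)), df, row.names = NULL)
  structure(df, maxscore = df$S_norm[1], class = c("consrank_ranking",
                                                   "data.frame"))
}

#' Maxscore of a ranking
#' @param ranking A `consrank_ranking`.
#' @return The normalized score of the top-ranked model.
#' @export
maxscore <- function(ranking) attr(ranking, "maxscore")

#' Contacts conserved above a threshold
#'
#' @param rates A `conservation_map`.
#' @param threshold Conservation rate threshold in `[0, 1]`; strict `>`
#'   ("above").
#' @return data.frame (contact, rate) sorted by rate descending (ties by
#'   contact key).
#' @export
conserved_contacts_above <- function(rates, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- unname(rates) > threshold
  df <- data.frame(contact = names(rates)[keep],
                   rate = unname(rates)[keep], stringsAsFactors = FALSE)
  df[order(-df$rate, df$contact), , drop = FALSE]
}

#' Export the consensus contact map
#'
#' Materializes the sparse conservation rates as a dense residue-by-residue
#' matrix (rows = first partner positions, columns = second partner
#' positions; symmetric square matrix for chain-agnostic homo-oligomer keys)
#' plus a contact table. Models listed in `annotate` get a logical column in
#' the table flagging their own contacts.
#'
#' @param rates A `conservation_map`.
#' @param annotate Optional character vector of model ids to overlay.
#' @param maps The ensemble contact maps (required when `annotate` is used).
#' @param file Optional output stem; writes `<file>_matrix.tsv` and
#'   `<file>_contacts.tsv`.
#' @return list(matrix, table), invisibly when `file` is given.
#' @export
export_consensus_map <- function(rates, annotate = NULL, maps = NULL,
                                 file = NULL) {
  keys <- names(rates)
  parsed <- parse_contact_keys(keys)
  tab <- data.frame(parsed, rate = unname(rates), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rate, keys), , drop = FALSE]
  symmetric <- length(keys) > 0 && grepl("~", keys[1], fixed = TRUE)
  if (symmetric) {
    L <- max(parsed$res1, parsed$res2)
    mat <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
    mat[cbind(parsed$res1, parsed$res2)] <- unname(rates)
    mat[cbind(parsed$res2, parsed$res1)] <- unname(rates)
  } else {
    rlab <- sort(unique(sprintf("%s:%d", parsed$chain1, parsed$res1)))
    clab <- sort(unique(sprintf("%s:%d", parsed$chain2, parsed$res2)))
    mat <- matrix(0, length(rlab), length(clab),
                  dimnames = list(rlab, clab))
    mat[cbind(sprintf("%s:%d", parsed$chain1, parsed$res1),
              sprintf("%s:%d", parsed$chain2, parsed$res2))] <- unname(rates)
  }
  if (!is.null(annotate)) {
    if (is.null(maps)) stop("annotate requires the ensemble maps")
    ids <- vapply(maps, attr, "", "model_id")
    missing <- setdiff(annotate, ids)
    if (length(missing))
      stop("annotated model(s) not in ensemble: ",
           paste(missing, collapse = ","))
    for (id in annotate) {
      mk <- unclass(maps[[match(id, ids)]])
      tab[[paste0("in_", id)]] <-
        paste_key(tab) %in% mk
    }
  }
  out <- list(matrix = mat, table = tab)
  if (!is.null(file)) {
    utils::write.table(mat, paste0(file, "_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(tab, paste0(file, "_contacts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

paste_key <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  if (tab$chain1[1] == "*") sprintf("%d~%d", tab$res1, tab$res2)
  else sprintf("%s:%d|%s:%d", tab$chain1, tab$res1, tab$chain2, tab$res2)
}

#' Write a ranking as tab-separated text
#'
#' Columns: rank, model_id, S_norm, S, M.
#'
#' @param ranking A `consrank_ranking`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
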