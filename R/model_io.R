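#' @importFrom stats setNames
NULL

## One-letter translation is delegated to bio3d::aa321 (unknown -> "X").

#' Target specification
#'
#' Reference amino-acid sequence per chain of the target complex, used for
#' sequence filtering, chain assignment, and consistent renumbering of decoy
#' ensembles.
#'
#' @param sequences Named character vector of one-letter amino-acid sequences;
#'   names are canonical chain labels (e.g. `c(A = "MKV...", B = "GSH...")`).
#' @param roles Optional named character vector giving a role per chain
#'   (e.g. receptor/ligand); defaults to `"subunit"` for every chain.
#'
#' @return Object of class `target_spec`.
#' @export
#' @examples
#' target_spec(c(A = "ACDEFGHIK", B = "ACDEFGHIK"))
target_spec <- function(sequences, roles = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be a named character vector (names = chain labels)")
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("target sequences must be non-empty")
  bad <- grepl(sprintf("[^%s]", "ACDEFGHIKLMNPQRSTVWYX"), sequences)
  if (any(bad))
    stop("target sequences may contain only the 20 standard residues and X")
  if (is.null(roles)) roles <- setNames(rep("subunit", length(sequences)),
                                        names(sequences))
  structure(list(sequences = sequences, roles = roles), class = "target_spec")
}

#' Read a target specification from a FASTA file
#'
#' One record per chain; record ids are taken as chain labels (first word of
#' the header, last character if longer than one letter is not assumed --
#' the full first word is used).
#'
#' @param path FASTA file.
#' @return A [target_spec()].
#' @export
read_target_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readAAStringSet(path)
  labels <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  target_spec(setNames(as.character(ss), labels))
}

#' Write a target specification as FASTA
#' @param target A [target_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(target, path) {
  lines <- unlist(lapply(names(target$sequences), function(ch)
    c(paste0(">", ch), target$sequences[[ch]])))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a decoy model from an atom table
#'
#' Low-level constructor used by the PDB reader and the synthetic generator.
#'
#' @param model_id Identifier (file stem for models read from disk).
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elesy, x, y, z (one row per heavy atom).
#' @return Object of class `decoy_model`.
#' @export
decoy_model <- function(model_id, atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in model ", model_id)
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  if (is.null(atoms$scored)) atoms$scored <- TRUE
  rownames(atoms) <- NULL
  structure(list(model_id = model_id,
                 atoms = atoms,
                 chains = unique(atoms$chain)),
            class = "decoy_model")
}

#' @export
print.decoy_model <- function(x, ...) {
  cat(sprintf("<decoy_model> %s: %d atoms, chains %s\n", x$model_id,
              nrow(x$atoms), paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Read one docking model from a PDB file
#'
#' Parses ATOM records only: HETATM groups, waters and hydrogens are ignored,
#' and alternate locations are resolved to the highest-occupancy conformer
#' (ties: first in file). Chains split into several blocks of the same chain
#' identifier are merged.
#'
#' Unreadable or empty files are not an error: they return a `read_failure`
#' object carrying the reason (`"empty"` or `"unreadable"`), so that ensemble
#' readers can record rather than abort.
#'
#' @param path PDB file (one model per file; MODEL/ENDMDL multi-model files
#'   are not supported).
#' @return A `decoy_model`, or a `read_failure` (list with `model_id` and
#'   `reason`).
#' @export
read_model <- function(path) {
  stopifnot(file.exists(path))
  model_id <- sub("\\.[^.]*$", "", basename(path))
  fail <- function(reason)
    structure(list(model_id = model_id, reason = reason),
              class = "read_failure")
  if (file.size(path) == 0) return(fail("empty"))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(pdb)) return(fail("unreadable"))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  ## drop hydrogens (element symbol, falling back on the atom-name convention)
  elesy <- at$elesy
  elesy[is.na(elesy) | !nzchar(elesy)] <-
    sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[is.na(elesy) | !nzchar(elesy)])
  at <- at[!(toupper(elesy) %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0) return(fail("empty"))
  ## resolve altlocs: highest occupancy, ties first-in-file
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "\r")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, seq_len(nrow(at)))
  keep_rows <- sort(ord[!duplicated(key[ord])])   # restore file order
  at <- at[keep_rows, , drop = FALSE]
  elesy <- at$elesy
  elesy[is.na(elesy) | !nzchar(elesy)] <-
    sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[is.na(elesy) | !nzchar(elesy)])
  decoy_model(model_id,
              data.frame(chain = at$chain, resno = at$resno,
                         insert = ifelse(is.na(at$insert), "", at$insert),
                         resid = at$resid, elety = at$elety,
                         elesy = toupper(elesy),
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE))
}

#' Read a decoy ensemble from a directory or file list
#'
#' @param paths Directory containing `*.pdb` files, or a character vector of
#'   file paths.
#' @return list with `models` (named list of `decoy_model`) and `failures`
#'   (named character vector model_id -> reason).
#' @export
read_ensemble <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.pdb$", full.names = TRUE))
  models <- list()
  failures <- character(0)
  for (p in paths) {
    m <- read_model(p)
    id <- sub("\\.[^.]*$", "", basename(p))
    if (inherits(m, "read_failure")) failures[[id]] <- m$reason
    else models[[id]] <- m
  }
  list(models = models, failures = failures)
}

## residue-level view of a model: one row per residue, in file order
model_residues <- function(model, chain = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resid = at$resid[first],
             stringsAsFactors = FALSE)
}

## one-letter sequence of a chain, in file order
chain_sequence <- function(model, chain) {
  res <- model_residues(model, chain)
  paste(bio3d::aa321(res$resid), collapse = "")
}

## identity substitution matrix over the amino-acid alphabet (incl. X)
aa_identity_matrix <- function() {
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  m <- diag(1, length(ab), length(ab))
  dimnames(m) <- list(ab, ab)
  m
}

.alignment_cache <- new.env(parent = emptyenv())

## End-gap-free global alignment of a model chain against a target sequence.
## Returns identity (matches / aligned columns), coverage (aligned target
## positions / target length) and the model-position -> target-position map.
## Results are memoized: decoys of one ensemble share few distinct sequences.
align_to_target <- function(model_seq, target_seq) {
  key <- paste(model_seq, target_seq, sep = "\r")
  hit <- .alignment_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (model_seq == target_seq) {
    list(identity = 1, coverage = 1,
         map = setNames(seq_len(nchar(target_seq)),
                        seq_len(nchar(target_seq))))
  } else {
    align_to_target_impl(model_seq, target_seq)
  }
  if (length(ls(.alignment_cache)) > 10000) # bound memory on huge runs
    rm(list = ls(.alignment_cache), envir = .alignment_cache)
  assign(key, res, envir = .alignment_cache)
  res
}

align_to_target_impl <- function(model_seq, target_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(model_seq), Biostrings::AAString(target_seq),
    type = "overlap", substitutionMatrix = aa_identity_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  map <- integer(0)    # model position -> target position
  matches <- 0L; cols <- 0L
  for (k in seq_along(pa)) {
    p_gap <- pa[k] == "-"; s_gap <- sa[k] == "-"
    if (!p_gap) pi <- pi + 1L
    if (!s_gap) si <- si + 1L
    if (!p_gap && !s_gap) {
      cols <- cols + 1L
      if (pa[k] == sa[k]) matches <- matches + 1L
      map[[as.character(pi)]] <- si
    }
  }
  list(identity = if (cols) matches / cols else 0,
       coverage = cols / nchar(target_seq),
       map = map)
}

## Align every model chain to every target chain; greedily assign model
## chains to target labels by best identity (ties: file order). Returns NULL
## if some chain has no admissible alignment.
assign_chains <- function(model, target, identity_min, coverage_min) {
  mch <- model$chains
  tch <- names(target$sequences)
  alns <- list()
  score <- matrix(-Inf, length(mch), length(tch), dimnames = list(mch, tch))
  for (i in seq_along(mch)) for (j in seq_along(tch)) {
    a <- align_to_target(chain_sequence(model, mch[i]), target$sequences[[j]])
    alns[[paste(mch[i], tch[j])]] <- a
    if (a$identity >= identity_min && a$coverage >= coverage_min)
      score[i, j] <- a$identity + 1e-9 * a$coverage
  }
  assign <- character(0)
  free_m <- mch; free_t <- tch
  while (length(free_m) && length(free_t)) {
    sub <- score[free_m, free_t, drop = FALSE]
    if (!any(is.finite(sub))) break
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    assign[[free_m[best[1]]]] <- free_t[best[2]]
    free_m <- free_m[-best[1]]; free_t <- free_t[-best[2]]
  }
  if (length(assign) < length(mch)) return(NULL)
  list(assign = assign,
       alignments = setNames(lapply(names(assign), function(mc)
         alns[[paste(mc, assign[[mc]])]]), names(assign)))
}

new_filter_report <- function(n_input, kept_ids, discarded) {
  discarded <- discarded[vapply(discarded, length, 0L) > 0]
  rep <- structure(list(n_input = n_input, n_kept = length(kept_ids),
                        kept = kept_ids, discarded = discarded),
                   class = "filter_report")
  stopifnot(rep$n_input == rep$n_kept + sum(vapply(discarded, length, 0L)))
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d models in, %d kept\n", x$n_input, x$n_kept))
  for (r in names(x$discarded))
    cat(sprintf("  %-18s %d\n", r, length(x$discarded[[r]])))
  invisible(x)
}

#' Filter a decoy ensemble
#'
#' Applies the published discard rules, in order: models with a single chain
#' identifier; models whose chains cannot all be matched to the target
#' sequences (identity below `seq_identity_min` or coverage below
#' `coverage_min`, or no unambiguous chain-to-target assignment); models with
#' zero intermolecular contacts. Read-stage failures (empty/unreadable files)
#' can be folded into the report via `prior_failures`.
#'
#' @param models Named list of `decoy_model` objects.
#' @param target A [target_spec()].
#' @param contact_fn Function `decoy_model -> contact_map`, used for the
#'   zero-contact rule; defaults to [compute_contact_map()] at
#'   `config$contact_cutoff`.
#' @param config A [pipeline_config()].
#' @param prior_failures Named character vector (model id -> reason) of models
#'   that failed at the read stage.
#' @return list with `models` (kept, order preserved, each carrying its chain
#'   assignment in attribute `"chain_assignment"`) and `report`
#'   (a `filter_report`).
#' @export
filter_ensemble <- function(models, target,
                            contact_fn = NULL,
                            config = pipeline_config(),
                            prior_failures = character(0)) {
  if (is.null(contact_fn))
    contact_fn <- function(m) compute_contact_map(m, config$contact_cutoff)
  discarded <- list(empty = character(0), single_chain = character(0),
                    sequence_mismatch = character(0),
                    zero_contacts = character(0), unreadable = character(0))
  for (id in names(prior_failures))
    discarded[[prior_failures[[id]]]] <-
      c(discarded[[prior_failures[[id]]]], id)
  kept <- list()
  for (m in models) {
    id <- m$model_id
    if (nrow(m$atoms) == 0) {
      discarded$empty <- c(discarded$empty, id); next
    }
    if (length(m$chains) < 2) {
      discarded$single_chain <- c(discarded$single_chain, id); next
    }
    asg <- assign_chains(m, target, config$seq_identity_min,
                         config$coverage_min)
    if (is.null(asg)) {
      discarded$sequence_mismatch <- c(discarded$sequence_mismatch, id); next
    }
    if (length(contact_fn(m)) == 0) {
      discarded$zero_contacts <- c(discarded$zero_contacts, id); next
    }
    attr(m, "chain_assignment") <- asg
    kept[[id]] <- m
  }
  report <- new_filter_report(length(models) + length(prior_failures),
                              names(kept), discarded)
  if (length(kept) == 0) stop("no scorable models after filtering")
  list(models = kept, report = report)
}

#' Renumber a filtered ensemble onto the target
#'
#' Each model chain is relabelled with its assigned canonical target chain
#' label and its residues renumbered 1..L of the aligned target sequence
#' (insertion codes are flattened). Residues that do not align to the target
#' keep their coordinates but are excluded from contact consideration
#' (`scored = FALSE`). Atom counts and coordinates are unchanged.
#'
#' @param models Named list of models as returned by [filter_ensemble()]
#'   (carrying `"chain_assignment"` attributes); models without the attribute
#'   are aligned on the fly.
#' @param target A [target_spec()].
#' @param config A [pipeline_config()] (thresholds for on-the-fly alignment).
#' @return list with `models` (renumbered) and `discarded` (ids that failed
#'   on-the-fly assignment, reason sequence_mismatch).
#' @export
renumber_ensemble <- function(models, target, config = pipeline_config()) {
  out <- list()
  dropped <- character(0)
  for (m in models) {
    asg <- attr(m, "chain_assignment")
    if (is.null(asg))
      asg <- assign_chains(m, target, config$seq_identity_min,
                           config$coverage_min)
    if (is.null(asg)) { dropped <- c(dropped, m$model_id); next }
    at <- m$atoms
    new_chain <- at$chain
    new_resno <- at$resno
    scored <- rep(FALSE, nrow(at))
    for (mc in names(asg$assign)) {
      idx <- which(at$chain == mc)
      res <- model_residues(m, mc)
      ## positional (file-order) index of each residue within its chain
      rk <- paste(at$resno[idx], at$insert[idx], sep = "\r")
      pos <- match(rk, paste(res$resno, res$insert, sep = "\r"))
      map <- asg$alignments[[mc]]$map
      tpos <- map[as.character(pos)]
      hit <- !is.na(tpos)
      new_chain[idx] <- asg$assign[[mc]]
      new_resno[idx[hit]] <- tpos[hit]
      scored[idx[hit]] <- TRUE
    }
    at$chain <- new_chain
    at$resno <- new_resno
    at$insert <- ""
    at$scored <- scored
    m2 <- decoy_model(m$model_id, at)
    out[[m$model_id]] <- m2
  }
  list(models = out, discarded = dropped)
}

#' Write a decoy model as a PDB file
#'
#' @param model A `decoy_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000, name4, at$resid, at$chain,
    at$resno %% 10000, substr(paste0(at$insert, " "), 1, 1),
    at$x, at$y, at$z, 1, 0, at$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a filter report
#'
#' @param report A `filter_report`.
#' @param path Output stem; writes `<path>.tsv` and `<path>.json`.
#' @return The two file paths, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  rows <- do.call(rbind, c(list(data.frame(model_id = report$kept,
                                           status = "kept")),
    lapply(names(report$discarded), function(r)
      data.frame(model_id = report$discarded[[r]], status = r))))
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_input = report$n_input, n_kept = report$n_kept,
                            discarded = report$discarded),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, js))
}
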