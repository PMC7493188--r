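backbone_names <- c("N", "CA", "C", "O")

## least-squares (Kabsch) superposition: rotation R and translation t such
## that P %*% R + t best fits Q (rows are corresponding points)
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, t = qc - as.numeric(pc %*% R))
}

rmsd <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

## matched backbone coordinates of model vs native, keyed by
## (chain, resno, atom name); optional chain relabelling of the model
matched_backbone <- function(model, native, chains = NULL,
                             chain_map = NULL) {
  key <- function(at) paste(at$chain, at$resno, at$elety, sep = "\r")
  mat <- function(at) as.matrix(at[, c("x", "y", "z")])
  m_at <- model$atoms[model$atoms$elety %in% backbone_names, , drop = FALSE]
  if (!is.null(chain_map))
    m_at$chain <- unname(chain_map[m_at$chain])
  n_at <- native$atoms[native$atoms$elety %in% backbone_names, , drop = FALSE]
  if (!is.null(chains)) {
    m_at <- m_at[m_at$chain %in% chains, , drop = FALSE]
    n_at <- n_at[n_at$chain %in% chains, , drop = FALSE]
  }
  idx <- match(key(n_at), key(m_at))
  hit <- !is.na(idx)
  if (!any(hit)) stop("no matched backbone atoms between model and native")
  list(model = mat(m_at)[idx[hit], , drop = FALSE],
       native = mat(n_at)[hit, , drop = FALSE],
       native_atoms = n_at[hit, , drop = FALSE])
}

## receptor = chain group with more residues in the native (ties: first)
receptor_ligand_chains <- function(native) {
  sizes <- vapply(native$chains, function(ch)
    nrow(model_residues(native, ch)), 0L)
  rec <- native$chains[which.max(sizes)]
  list(receptor = rec, ligand = setdiff(native$chains, rec))
}

#' Fraction of native contacts reproduced (fnat)
#'
#' `|model contacts  intersect  native contacts| / |native contacts|`, with
#' contacts defined at the 5 A heavy-atom cutoff.
#'
#' @param model_map,native_map `contact_map`s on consistent numbering.
#' @return Fraction in `[0, 1]`.
#' @export
fnat <- function(model_map, native_map) {
  if (length(native_map) == 0) stop("native contact map is empty")
  sum(!is.na(match(unclass(native_map), unclass(model_map)))) /
    length(native_map)
}

#' Ligand RMSD after receptor superposition (L-rms)
#'
#' Backbone atoms of the receptor (the larger chain group of the native) are
#' optimally superposed; the RMSD of the ligand backbone is then reported.
#'
#' @param model,native `decoy_model`s with consistent chain labels and
#'   numbering.
#' @param chain_map Optional named character vector relabelling model chains
#'   before matching (used for homodimer chain-swap assessment).
#' @return RMSD in Angstrom.
#' @export
ligand_rms <- function(model, native, chain_map = NULL) {
  rl <- receptor_ligand_chains(native)
  rec <- matched_backbone(model, native, rl$receptor, chain_map)
  lig <- matched_backbone(model, native, rl$ligand, chain_map)
  fit <- kabsch(rec$model, rec$native)
  moved <- sweep(lig$model %*% fit$R, 2, fit$t, "+")
  rmsd(moved, lig$native)
}

#' Interface RMSD (I-rms)
#'
#' Native interface residues are those with at least one heavy atom within
#' 10 A of any atom of the binding partner. Their backbone atoms in model
#' and native are optimally superposed onto each other and the RMSD of that
#' superposition is reported.
#'
#' @inheritParams ligand_rms
#' @param interface_cutoff Interface definition distance (A), default 10.
#' @return RMSD in Angstrom.
#' @export
interface_rms <- function(model, native, chain_map = NULL,
                          interface_cutoff = 10) {
  at <- native$atoms
  ch <- native$chains
  int_res <- character(0)
  for (pr in utils::combn(ch, 2, simplify = FALSE)) {
    a1 <- at[at$chain == pr[1], , drop = FALSE]
    a2 <- at[at$chain == pr[2], , drop = FALSE]
    cp <- close_pairs(as.matrix(a1[, c("x", "y", "z")]),
                      as.matrix(a2[, c("x", "y", "z")]), interface_cutoff)
    if (nrow(cp) == 0) next
    int_res <- c(int_res,
                 paste(pr[1], a1$resno[cp[, "i"]], sep = "\r"),
                 paste(pr[2], a2$resno[cp[, "j"]], sep = "\r"))
  }
  int_res <- unique(int_res)
  if (!length(int_res)) stop("native interface residue set is empty")
  mb <- matched_backbone(model, native, chain_map = chain_map)
  keep <- paste(mb$native_atoms$chain, mb$native_atoms$resno,
                sep = "\r") %in% int_res
  if (!any(keep)) stop("no matched interface backbone atoms")
  fit <- kabsch(mb$model[keep, , drop = FALSE],
                mb$native[keep, , drop = FALSE])
  moved <- sweep(mb$model[keep, , drop = FALSE] %*% fit$R, 2, fit$t, "+")
  rmsd(moved, mb$native[keep, , drop = FALSE])
}

#' CAPRI quality thresholds
#'
#' The standard joint thresholds on fnat, L-rms and I-rms (Lensink-style
#' criteria). Editable: pass a modified copy to [classify_capri()].
#'
#' @return data.frame (quality, fnat_min, l_rms_max, i_rms_max), best tier
#'   first.
#' @export
capri_thresholds <- function() {
  data.frame(quality = c("high", "medium", "acceptable"),
             fnat_min = c(0.5, 0.3, 0.1),
             l_rms_max = c(1, 5, 10),
             i_rms_max = c(1, 2, 4),
             stringsAsFactors = FALSE)
}

#' Classify model quality from fnat, L-rms and I-rms
#'
#' Tiers are evaluated best-first: a model is `high` if it reproduces at
#' least half of the native contacts and has either L-rms or I-rms within
#' 1 A; `medium` if fnat >= 0.3 with L-rms <= 5 or I-rms <= 2;
#' `acceptable` if fnat >= 0.1 with L-rms <= 10 or I-rms <= 4; otherwise
#' `incorrect`.
#'
#' @param fnat Fraction of native contacts.
#' @param l_rms,i_rms RMSD values (A).
#' @param thresholds Tier table, default [capri_thresholds()].
#' @return One of "high", "medium", "acceptable", "incorrect".
#' @export
classify_capri <- function(fnat, l_rms, i_rms,
                           thresholds = capri_thresholds()) {
  stopifnot(fnat >= 0, fnat <= 1, l_rms >= 0, i_rms >= 0)
  for (k in seq_len(nrow(thresholds))) {
    if (fnat >= thresholds$fnat_min[k] &&
        (l_rms <= thresholds$l_rms_max[k] ||
         i_rms <= thresholds$i_rms_max[k]))
      return(thresholds$quality[k])
  }
  "incorrect"
}

#' Assess one model against the native structure
#'
#' Computes fnat (at the contact cutoff), L-rms and I-rms, and the CAPRI
#' quality class. For homodimers (two chains with identical residue content)
#' both chain assignments are evaluated and the better (lower L-rms) one is
#' used, since decoy chain labels are arbitrary.
#'
#' @param model,native `decoy_model`s on consistent numbering.
#' @param contact_cutoff Contact cutoff for fnat (A).
#' @param thresholds Tier table for [classify_capri()].
#' @return data.frame row (model_id, fnat, L_rms, I_rms, quality).
#' @export
assess_model <- function(model, native, contact_cutoff = 5.0,
                         thresholds = capri_thresholds()) {
  symmetric <- length(native$chains) == 2 &&
    chain_sequence(native, native$chains[1]) ==
    chain_sequence(native, native$chains[2])
  nat_map <- compute_contact_map(native, contact_cutoff,
                                 symmetric = symmetric)
  mod_map <- compute_contact_map(model, contact_cutoff,
                                 symmetric = symmetric)
  f <- fnat(mod_map, nat_map)
  maps <- list(NULL)
  if (symmetric)
    maps <- list(NULL, setNames(rev(native$chains), native$chains))
  l <- Inf; irms <- Inf
  for (cm in maps) {
    l_try <- tryCatch(ligand_rms(model, native, cm), error = function(e) Inf)
    if (l_try < l) {
      l <- l_try
      irms <- interface_rms(model, native, cm)
    }
  }
  data.frame(model_id = model$model_id, fnat = f, L_rms = l, I_rms = irms,
             quality = classify_capri(f, l, irms, thresholds),
             stringsAsFactors = FALSE)
}

#' Assess an ensemble against the native structure
#'
#' @param models Named list of `decoy_model`s.
#' @inheritParams assess_model
#' @param path Optional output TSV.
#' @return data.frame (model_id, fnat, L_rms, I_rms, quality).
#' @export
assess_ensemble <- function(models, native, contact_cutoff = 5.0,
                            thresholds = capri_thresholds(), path = NULL) {
  out <- do.call(rbind, lapply(models, assess_model, native = native,
                               contact_cutoff = contact_cutoff,
                               thresholds = thresholds))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
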