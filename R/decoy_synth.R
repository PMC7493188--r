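#' Specification of a synthetic decoy ensemble
#'
#' Parameters of the generator that emulates a docking scoring set: a mixture
#' of near-native poses (small rigid-body perturbations of a reference
#' dimer), incorrect poses (random orientations touching the receptor), and
#' optionally decoys built on an alternative monomer conformation. Defaults
#' describe the study conditions used throughout the package tests: 100
#' models, 30% near-natives, 0.5 A / 2 degree jitter, 30 residues per chain.
#'
#' @param n_models Ensemble size (>= 2).
#' @param planted_fraction Fraction of near-native poses in `[0, 1]`.
#' @param jitter_translation Per-component standard deviation (A) of the
#'   near-native rigid-body translation.
#' @param jitter_rotation Standard deviation (degrees) of the near-native
#'   rotation angle.
#' @param n_residues_per_chain Residues per chain (>= 5).
#' @param monomer_swap_fraction Fraction of decoys built on an alternative
#'   monomer conformation (distinct fold of chain A), forming their own
#'   contact cluster.
#' @param n_clash_decoys Number of clash-injected decoys (near-native pose
#'   pushed into the receptor until the clash count exceeds 25); used to
#'   exercise the clash-exclusion rule.
#' @param seed RNG seed for the single generator stream.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_models = 100L, planted_fraction = 0.3,
                           jitter_translation = 0.5, jitter_rotation = 2,
                           n_residues_per_chain = 30L,
                           monomer_swap_fraction = 0,
                           n_clash_decoys = 0L, seed = 1L) {
  stopifnot(n_models >= 2, planted_fraction >= 0, planted_fraction <= 1,
            monomer_swap_fraction >= 0, monomer_swap_fraction <= 1,
            planted_fraction + monomer_swap_fraction <= 1,
            n_residues_per_chain >= 5, jitter_translation >= 0,
            jitter_rotation >= 0, n_clash_decoys >= 0)
  structure(list(n_models = as.integer(n_models),
                 planted_fraction = planted_fraction,
                 jitter_translation = jitter_translation,
                 jitter_rotation = jitter_rotation,
                 n_residues_per_chain = as.integer(n_residues_per_chain),
                 monomer_swap_fraction = monomer_swap_fraction,
                 n_clash_decoys = as.integer(n_clash_decoys),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Idealized poly-alanine helix: CA on a standard alpha-helical trace
## (radius 2.3 A, 100 deg/residue, 1.5 A rise), N/C/O/CB placed by simple
## geometric offsets. Heavy-atom-only; adequate for contact/clash/SASA
## exercises.
helix_chain <- function(n_res, chain = "A", radius = 2.3, twist = 100,
                        rise = 1.5) {
  th <- (seq_len(n_res) - 1) * twist * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), (seq_len(n_res) - 1) * rise)
  unit <- function(v) v / sqrt(sum(v^2))
  rows <- list()
  for (i in seq_len(n_res)) {
    tangent <- if (i == 1) unit(ca[2, ] - ca[1, ])
               else if (i == n_res) unit(ca[n_res, ] - ca[n_res - 1, ])
               else unit(ca[i + 1, ] - ca[i - 1, ])
    radial <- unit(c(ca[i, 1], ca[i, 2], 0))
    n_at <- ca[i, ] - 1.46 * tangent
    c_at <- ca[i, ] + 1.52 * tangent
    o_at <- c_at + 1.23 * radial
    cb_at <- ca[i, ] + 1.53 * radial
    rows[[i]] <- data.frame(
      chain = chain, resno = i, insert = "", resid = "ALA",
      elety = c("N", "CA", "C", "O", "CB"),
      elesy = c("N", "C", "C", "O", "C"),
      x = c(n_at[1], ca[i, 1], c_at[1], o_at[1], cb_at[1]),
      y = c(n_at[2], ca[i, 2], c_at[2], o_at[2], cb_at[2]),
      z = c(n_at[3], ca[i, 3], c_at[3], o_at[3], cb_at[3]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## alternative monomer conformation: tighter, faster-twisting helix
## (a distinct fold, so its decoys carry a distinct contact fingerprint)
helix_chain_alt <- function(n_res, chain = "A")
  helix_chain(n_res, chain, radius = 2.6, twist = 120, rise = 1.2)

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

random_rotation <- function() {
  ## uniform rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_atoms <- function(at, R = diag(3), t = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, center) %*% t(R)
  xyz <- sweep(xyz, 2, center + t, "+")
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

#' Build the synthetic reference dimer
#'
#' Two identical idealized poly-alanine helices docked side by side with C2
#' symmetry, separated so that the interface carries at least 10 residue-pair
#' contacts at 5 A and no steric clash at 3 A. Construction is deterministic.
#'
#' @param spec A [synthetic_spec()] (only `n_residues_per_chain` is used).
#' @param alt_monomer Build chain A (and its C2 copy) with the alternative
#'   monomer conformation.
#' @return A `decoy_model` with chains A and B.
#' @export
make_reference_dimer <- function(spec = synthetic_spec(),
                                 alt_monomer = FALSE) {
  n_res <- spec$n_residues_per_chain
  a <- if (alt_monomer) helix_chain_alt(n_res, "A") else helix_chain(n_res, "A")
  ## C2 rotation about the vertical axis at x = d/2: (x,y,z) -> (d-x, -y, z);
  ## take the closest strictly clash-free chain separation (min inter-chain
  ## distance > 3 A) and so the richest contact network the helix geometry
  ## allows
  best <- NULL; best_m <- -1L
  for (d in seq(14, 6, by = -0.1)) {
    b <- a
    b$chain <- "B"
    b$x <- d - a$x; b$y <- -a$y
    m <- decoy_model(if (alt_monomer) "reference_alt" else "reference",
                     rbind(a, b))
    if (min_interchain_distance(m) < 3.02) break
    nc <- length(compute_contact_map(m, 5.0))
    if (nc > best_m) { best <- m; best_m <- nc }
  }
  if (best_m < 10)
    stop("could not construct a clash-free reference interface")
  best
}

chain_atoms <- function(model, chain) model$atoms[model$atoms$chain == chain, ,
                                                  drop = FALSE]

atoms_center <- function(at) colMeans(as.matrix(at[, c("x", "y", "z")]))

## replace the chain-B atoms of `ref` with `b_at`
with_ligand <- function(ref, b_at, model_id) {
  decoy_model(model_id, rbind(chain_atoms(ref, "A"), b_at))
}

near_native_pose <- function(ref, jit_t, jit_r, model_id) {
  b <- chain_atoms(ref, "B")
  ang <- stats::rnorm(1, 0, jit_r * pi / 180)
  axis <- stats::rnorm(3)
  R <- rotation_matrix(axis, ang)
  t <- stats::rnorm(3, 0, jit_t)
  with_ligand(ref, transform_atoms(b, R, t, atoms_center(b)), model_id)
}

## Random orientation of B, slid along a random direction and packed against
## A until it buries a genuine contact patch (incorrect poses from real
## docking programs still have extended interfaces, never a single grazing
## contact), while staying under the clash ceiling; rejection-sampled.
random_pose <- function(ref, model_id, native_keys = NULL, clash_max = 25L,
                        min_contacts = 5L, max_tries = 60L) {
  a <- chain_atoms(ref, "A")
  a_xyz <- as.matrix(a[, c("x", "y", "z")])
  b0 <- chain_atoms(ref, "B")
  for (try in seq_len(max_tries)) {
    R <- random_rotation()
    b <- transform_atoms(b0, R, center = atoms_center(b0))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ## support projection: place B beyond A along u, then walk inwards
    b_xyz <- as.matrix(b[, c("x", "y", "z")])
    shift0 <- max(a_xyz %*% u) - min(b_xyz %*% u)
    s <- shift0 + stats::runif(1, 3.4, 4.6)
    for (step in seq_len(60L)) {
      bs_xyz <- sweep(b_xyz, 2, s * u, "+")
      cp <- close_pairs(a_xyz, bs_xyz, 5.0)
      if (nrow(cp) == 0) {          # drifted apart: walk back in
        bs <- b
        bs$x <- b$x + s * u[1]; bs$y <- b$y + s * u[2]; bs$z <- b$z + s * u[3]
        dmin <- min_interchain_distance(with_ligand(ref, bs, model_id))
        s <- s - (dmin - 4.2)
        next
      }
      n_clash <- sum(cp[, "d"] < 3.0)
      if (n_clash > clash_max) { s <- s + 0.3; next }
      n_res_contacts <- nrow(unique(cbind(a$resno[cp[, "i"]],
                                          b0$resno[cp[, "j"]])))
      if (n_res_contacts < min_contacts) { s <- s - 0.25; next }
      bs <- b
      bs$x <- b$x + s * u[1]; bs$y <- b$y + s * u[2]; bs$z <- b$z + s * u[3]
      cand <- with_ligand(ref, bs, model_id)
      ## an "incorrect" pose must not accidentally reproduce the native
      ## interface (uniform orientations occasionally land near it, twice
      ## as often for a C2 dimer): resample if fnat would reach the
      ## acceptable tier
      if (!is.null(native_keys)) {
        cand_keys <- compute_contact_map(cand, 5.0, symmetric = TRUE)
        f <- sum(!is.na(match(unclass(native_keys), unclass(cand_keys)))) /
          length(native_keys)
        if (f >= 0.1) break   # next orientation
      }
      return(cand)
    }
  }
  stop("rejection sampling failed to place a random decoy")
}

min_interchain_distance <- function(model) {
  at <- model$atoms
  a <- as.matrix(at[at$chain == "A", c("x", "y", "z")])
  b <- as.matrix(at[at$chain == "B", c("x", "y", "z")])
  for (cut in c(6, 12, 25, 50, 200, 1000)) {
    cp <- close_pairs(a, b, cut)
    if (nrow(cp)) return(min(cp[, "d"]))
  }
  Inf
}

clash_pose <- function(ref, model_id, clash_min = 26L) {
  b <- chain_atoms(ref, "B")
  a_cen <- atoms_center(chain_atoms(ref, "A"))
  u <- a_cen - atoms_center(b)
  u <- u / sqrt(sum(u^2))
  for (s in seq(0.2, 6, by = 0.2)) {
    bs <- b
    bs$x <- b$x + s * u[1]; bs$y <- b$y + s * u[2]; bs$z <- b$z + s * u[3]
    cand <- with_ligand(ref, bs, model_id)
    if (count_clashes(cand, 3.0) >= clash_min) return(cand)
  }
  stop("could not inject the requested clash count")
}

#' Generate a synthetic decoy ensemble with ground truth
#'
#' Produces `n_models` decoys of the reference dimer: a planted fraction of
#' near-native poses (jittered reference), optional decoys built on an
#' alternative monomer conformation (near-native around their own reference,
#' so they cluster together), optional clash-injected decoys, and incorrect
#' poses at random orientations packed against the receptor. Random poses
#' bury a genuine contact patch (at least 5 residue contacts, at most 25
#' clashes) -- incorrect poses from real docking programs still carry
#' extended interfaces, and every decoy must survive ensemble filtering --
#' but are rejection-sampled away from the native interface (fraction of
#' native contacts below 0.1), so their ground-truth label "random" always
#' means an incorrect pose in the CAPRI sense. Model identities are shuffled
#' and anonymized.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory: writes one PDB per decoy, the
#'   target FASTA (`target.fasta`) and a ground-truth JSON
#'   (`ground_truth.json`).
#' @return list with `models` (named list of `decoy_model`, shuffled order),
#'   `truth` (data.frame model_id, label), `reference` (`decoy_model`),
#'   `native_contacts` (`contact_map` of the reference, symmetric keys),
#'   `target` ([target_spec()]), and `dir` (or NULL).
#' @export
generate_ensemble <- function(spec = synthetic_spec(), dir = NULL) {
  set.seed(spec$seed)
  ref <- make_reference_dimer(spec)
  n <- spec$n_models
  n_planted <- round(spec$planted_fraction * n)
  n_swap <- round(spec$monomer_swap_fraction * n)
  n_clash <- min(spec$n_clash_decoys, n - n_planted - n_swap)
  n_random <- n - n_planted - n_swap - n_clash
  ref_alt <- if (n_swap > 0) make_reference_dimer(spec, alt_monomer = TRUE)
             else NULL
  native_contacts <- compute_contact_map(ref, 5.0, symmetric = TRUE)
  labels <- c(rep("near-native", n_planted), rep("swapped-monomer", n_swap),
              rep("clash", n_clash), rep("random", n_random))
  models <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("tmp_%04d", i)
    models[[i]] <- switch(labels[i],
      "near-native" = near_native_pose(ref, spec$jitter_translation,
                                       spec$jitter_rotation, id),
      "swapped-monomer" = near_native_pose(ref_alt, spec$jitter_translation,
                                           spec$jitter_rotation, id),
      "clash" = clash_pose(ref, id),
      "random" = random_pose(ref, id, native_contacts))
  }
  ## shuffle and anonymize
  perm <- sample.int(n)
  models <- models[perm]
  labels <- labels[perm]
  ids <- sprintf("model_%04d", seq_len(n))
  for (i in seq_len(n)) models[[i]]$model_id <- ids[i]
  names(models) <- ids
  truth <- data.frame(model_id = ids, label = labels,
                      stringsAsFactors = FALSE)
  seq1 <- strrep("A", spec$n_residues_per_chain)
  target <- target_spec(c(A = seq1, B = seq1))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in ids) write_model_pdb(models[[id]],
                                    file.path(dir, paste0(id, ".pdb")))
    write_target_fasta(target, file.path(dir, "target.fasta"))
    jsonlite::write_json(
      list(labels = setNames(as.list(truth$label), truth$model_id),
           native_contacts = unclass(native_contacts)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(models = models, truth = truth, reference = ref,
       native_contacts = native_contacts, target = target, dir = dir)
}
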