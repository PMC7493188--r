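## Heavy-atom van der Waals radii (A), Bondi set as commonly used for
## protein SASA; unknown elements fall back on the carbon radius.
#' Van der Waals radii used for surface calculations
#'
#' Named vector of heavy-atom radii (A): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, SE 1.90 (Bondi). Unknown elements use the carbon radius with a
#' warning.
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

## deterministic quasi-uniform unit-sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elesy, radii = vdw_radii()) {
  r <- radii[toupper(elesy)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elesy[is.na(r)]),
                                         collapse = ","),
            "; using carbon radius")
    r[is.na(r)] <- radii[["C"]]
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible surface, computed by testing quasi-uniform sphere
#' points on each atom's solvent-expanded sphere against all neighbouring
#' expanded spheres.
#'
#' @param x A `decoy_model`, or an atom data.frame with columns elesy, x, y,
#'   z.
#' @param probe Probe radius (A), default 1.4.
#' @param n_points Sphere points per atom (>= 1), default 960.
#' @param radii Named radius table, default [vdw_radii()].
#' @return Numeric vector of per-atom areas (A^2); `sum()` gives the total.
#' @export
#' @examples
#' one <- data.frame(elesy = "C", x = 0, y = 0, z = 0)
#' sum(sasa(one))            # ~ 4*pi*(1.7 + 1.4)^2
sasa <- function(x, probe = 1.4, n_points = 960L, radii = vdw_radii()) {
  at <- if (inherits(x, "decoy_model")) x$atoms else x
  n <- nrow(at)
  if (n == 0) return(numeric(0))
  r <- atom_radii(at$elesy, radii) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  ## neighbour lists from squared distances (block to bound memory)
  areas <- numeric(n)
  r2 <- r^2
  nb <- close_pairs(xyz, xyz, max(r) * 2 + 1e-9)
  nb <- nb[nb[, "i"] != nb[, "j"], , drop = FALSE]
  ## tight neighbour criterion: spheres intersect
  keep <- nb[, "d"] < (r[nb[, "i"]] + r[nb[, "j"]])
  nb <- nb[keep, , drop = FALSE]
  nb_list <- split(nb[, "j"], factor(nb[, "i"], levels = seq_len(n)))
  nb_dist <- split(nb[, "d"], factor(nb[, "i"], levels = seq_len(n)))
  for (i in seq_len(n)) {
    js <- nb_list[[i]]
    if (!length(js)) { areas[i] <- 4 * pi * r2[i]; next }
    js <- js[order(nb_dist[[i]])]        # nearest first: fastest burial
    ## a point u (unit sphere) of atom i is inside neighbour j's expanded
    ## sphere iff  u . v_ij >= (r_i^2 + D^2 - r_j^2) / (2 r_i), with
    ## v_ij = xyz_j - xyz_i and D = |v_ij|: a half-space test
    v <- xyz[js, , drop = FALSE] -
      matrix(xyz[i, ], length(js), 3, byrow = TRUE)
    D2 <- rowSums(v^2)
    thr <- (r2[i] + D2 - r2[js]) / (2 * r[i])
    alive <- pts
    for (s in seq(1L, length(js), by = 8L)) {
      e <- min(s + 7L, length(js))
      proj <- alive %*% t(v[s:e, , drop = FALSE])
      buried <- proj >= rep(thr[s:e], each = nrow(alive))
      keep <- .rowSums(buried, nrow(alive), e - s + 1L) == 0L
      alive <- alive[keep, , drop = FALSE]
      if (nrow(alive) == 0L) break
    }
    areas[i] <- 4 * pi * r2[i] * nrow(alive) / n_points
  }
  areas
}

default_partition <- function(model) {
  ch <- model$chains
  if (length(ch) < 2) stop("interface requires at least 2 chains")
  list(ch[1], ch[-1])
}

#' Buried-surface interface area
#'
#' Solvent-accessible surface buried upon complex formation, reported as the
#' mean of the two partners' buried surfaces:
#' `(SASA(group1) + SASA(group2) - SASA(complex)) / 2`. Set
#' `convention = "sum"` for the total buried surface (twice the mean).
#'
#' @param model A `decoy_model`.
#' @param partition List of two character vectors of chain labels splitting
#'   the chains into the two binding partners; default: first chain vs the
#'   rest.
#' @param convention `"mean"` (default) or `"sum"`.
#' @param probe,n_points,radii Passed to [sasa()].
#' @return Interface area in A^2.
#' @export
interface_area <- function(model, partition = NULL, convention = c("mean", "sum"),
                           probe = 1.4, n_points = 960L, radii = vdw_radii()) {
  convention <- match.arg(convention)
  if (is.null(partition)) partition <- default_partition(model)
  stopifnot(length(partition) == 2)
  if (!length(partition[[1]]) || !length(partition[[2]]))
    stop("both partition groups must be non-empty")
  at <- model$atoms
  g1 <- at[at$chain %in% partition[[1]], , drop = FALSE]
  g2 <- at[at$chain %in% partition[[2]], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2)) stop("a partition group has no atoms")
  a1 <- sum(sasa(g1, probe, n_points, radii))
  a2 <- sum(sasa(g2, probe, n_points, radii))
  ac <- sum(sasa(at, probe, n_points, radii))
  buried <- a1 + a2 - ac
  if (convention == "mean") buried / 2 else buried
}

#' Interface report for one model
#'
#' Bundles the three interface descriptors driving the final ranking:
#' intermolecular residue-contact count, buried interface area, and
#' inter-chain clash count.
#'
#' @param model A renumbered `decoy_model`.
#' @param config A [pipeline_config()].
#' @param partition Chain bipartition for the area (default: first chain vs
#'   rest).
#' @param symmetric Use symmetric contact keys (homo-oligomer ensembles).
#' @return data.frame row (model_id, n_contacts, interface_area, n_clashes).
#' @export
interface_report <- function(model, config = pipeline_config(),
                             partition = NULL, symmetric = FALSE) {
  cm <- compute_contact_map(model, config$contact_cutoff,
                            symmetric = symmetric)
  data.frame(model_id = model$model_id,
             n_contacts = length(cm),
             interface_area = interface_area(model, partition,
                                             probe = config$sasa_probe,
                                             n_points = config$sasa_points),
             n_clashes = count_clashes(model, config$clash_cutoff),
             stringsAsFactors = FALSE)
}

#' Interface reports for a set of models
#'
#' @param models Named list of `decoy_model`s.
#' @inheritParams interface_report
#' @return data.frame, one row per model.
#' @export
interface_reports <- function(models, config = pipeline_config(),
                              partition = NULL, symmetric = FALSE) {
  do.call(rbind, lapply(models, interface_report, config = config,
                        partition = partition, symmetric = symmetric))
}
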