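## In-code fixtures: toy models and PDB files built at test time.

toy_atoms <- function(chain, resno, x, y, z, elety = "CA", elesy = "C",
                      resid = "ALA") {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

## two-chain model with one atom per residue at given coordinates
toy_dimer <- function(xyz_a, xyz_b, id = "toy") {
  a <- toy_atoms("A", seq_len(nrow(xyz_a)), xyz_a[, 1], xyz_a[, 2],
                 xyz_a[, 3])
  b <- toy_atoms("B", seq_len(nrow(xyz_b)), xyz_b[, 1], xyz_b[, 2],
                 xyz_b[, 3])
  decoy_model(id, rbind(a, b))
}

## random two-chain blob for property tests
random_toy_dimer <- function(n_res = 8, spread = 6, id = "toy") {
  toy_dimer(matrix(runif(n_res * 3, 0, spread), ncol = 3),
            matrix(runif(n_res * 3, 0, spread) + 2, ncol = 3), id)
}

## write PDB lines for a simple CA-trace model
write_toy_pdb <- function(path, chains, resnos, xyz, occ = NULL,
                          alt = NULL, resid = "ALA") {
  n <- length(chains)
  if (is.null(occ)) occ <- rep(1, n)
  if (is.null(alt)) alt <- rep(" ", n)
  lines <- sprintf(
    "ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), alt, resid, chains, resnos, xyz[, 1], xyz[, 2], xyz[, 3],
    occ, 0)
  writeLines(c(lines, "END"), path)
  path
}

## sequence helper for poly-alanine targets
polyA_target <- function(L, chains = c("A", "B"))
  target_spec(setNames(rep(strrep("A", L), length(chains)), chains))

rigid_transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  at <- model$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  decoy_model(model$model_id, at)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
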