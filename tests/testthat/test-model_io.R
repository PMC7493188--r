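test_that("well-formed two-chain PDB files parse into models", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, chains = c("A", "A", "B"), resnos = c(1, 2, 1),
                xyz = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  m <- read_model(p)
  expect_s3_class(m, "decoy_model")
  expect_equal(sort(m$chains), c("A", "B"))
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$resno[m$atoms$chain == "A"], c(1, 2))
})

test_that("zero-byte and unparseable files are recorded, not raised", {
  p <- withr::local_tempfile(fileext = ".pdb")
  file.create(p)
  m <- read_model(p)
  expect_s3_class(m, "read_failure")
  expect_equal(m$reason, "empty")

  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK no atoms here", p2)
  m2 <- read_model(p2)
  expect_s3_class(m2, "read_failure")
  expect_true(m2$reason %in% c("empty", "unreadable"))
})

test_that("split chain blocks merge into one chain", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, chains = c("A", "B", "A"), resnos = c(1, 1, 2),
                xyz = rbind(c(0, 0, 0), c(0, 4, 0), c(3, 0, 0)))
  m <- read_model(p)
  expect_equal(length(m$chains), 2)   # oracle: distinct chain ids
  expect_equal(sum(m$atoms$chain == "A"), 2)
})

test_that("alternate locations resolve to highest occupancy, ties first", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, chains = rep("A", 3), resnos = c(1, 1, 2),
                xyz = rbind(c(0, 0, 0), c(9, 9, 9), c(3, 0, 0)),
                occ = c(0.4, 0.6, 1), alt = c("A", "B", " "))
  m <- read_model(p)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 9)  # occupancy 0.6 wins

  ## tie: first conformer in file wins
  write_toy_pdb(p, chains = rep("A", 2), resnos = c(1, 1),
                xyz = rbind(c(1, 0, 0), c(2, 0, 0)),
                occ = c(0.5, 0.5), alt = c("A", "B"))
  m2 <- read_model(p)
  expect_equal(m2$atoms$x, 1)
})

test_that("hydrogens and waters are ignored", {
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       1.000   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       2.000   0.000   0.000  1.00  0.00           O",
    "ATOM      4  CA  ALA B   1       0.000   3.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, p)
  m <- read_model(p)
  expect_equal(nrow(m$atoms), 2)
  expect_true(all(m$atoms$elesy == "C"))
})

test_that("filter_ensemble applies the discard rules and reconciles counts", {
  L <- 30
  tgt <- polyA_target(L)
  good <- function(id) {
    ref <- make_reference_dimer(synthetic_spec(n_residues_per_chain = L))
    ref$model_id <- id
    ref
  }
  single <- decoy_model("single", toy_atoms("A", 1:3, c(0, 3, 6), 0, 0))
  far_a <- toy_atoms("A", seq_len(L), seq_len(L) * 3, 0, 0)
  far_b <- toy_atoms("B", seq_len(L), seq_len(L) * 3, 500, 0)
  far <- decoy_model("nocontact", rbind(far_a, far_b))
  mism_b <- far_b
  mism_b$y <- 4
  mism_b$resid <- rep(c("GLY", "VAL", "LYS", "TRP"), length.out = L)
  mismatch <- decoy_model("mismatch", rbind(far_a, mism_b))

  models <- list(g1 = good("g1"), single = single, mismatch = mismatch,
                 nocontact = far, g2 = good("g2"))
  flt <- filter_ensemble(models, tgt,
                         prior_failures = c(bad1 = "empty",
                                            bad2 = "unreadable"))
  rep <- flt$report
  expect_equal(rep$n_input, 7)
  expect_equal(rep$n_kept, 2)
  expect_equal(names(flt$models), c("g1", "g2"))   # order preserved
  expect_equal(rep$discarded$single_chain, "single")
  expect_equal(rep$discarded$sequence_mismatch, "mismatch")
  expect_equal(rep$discarded$zero_contacts, "nocontact")
  expect_equal(rep$n_input,
               rep$n_kept + sum(lengths(rep$discarded)))

  ## idempotence: filtering the kept models removes nothing
  flt2 <- filter_ensemble(flt$models, tgt)
  expect_equal(names(flt2$models), names(flt$models))
  expect_equal(flt2$report$n_kept, flt2$report$n_input)
})

test_that("identity below 90% is discarded even at full coverage", {
  L <- 20
  tgt <- polyA_target(L)
  base_a <- toy_atoms("A", seq_len(L), seq_len(L) * 3, 0, 0)
  good_b <- toy_atoms("B", seq_len(L), seq_len(L) * 3, 4, 0)
  ## chain B at 85% identity (3 of 20 residues differ), full coverage
  b_res <- rep("ALA", L); b_res[1:3] <- "GLY"
  b85 <- good_b; b85$resid <- b_res
  m85 <- decoy_model("m85", rbind(base_a, b85))
  good <- decoy_model("good", rbind(base_a, good_b))
  flt <- filter_ensemble(list(m85 = m85, good = good), tgt)
  expect_equal(flt$report$discarded$sequence_mismatch, "m85")
  expect_equal(names(flt$models), "good")
})

test_that("renumbering shifts offset models onto the target frame", {
  L <- 10
  tgt <- polyA_target(L)
  a <- toy_atoms("A", seq_len(L) + 10, seq_len(L) * 3, 0, 0)   # +10 offset
  b <- toy_atoms("B", seq_len(L) + 100, seq_len(L) * 3, 4, 0)  # +100 offset
  m <- decoy_model("off", rbind(a, b))
  ren <- renumber_ensemble(list(off = m), tgt)
  m2 <- ren$models$off
  expect_equal(m2$atoms$resno[m2$atoms$chain == "A"], seq_len(L))
  expect_equal(m2$atoms$resno[m2$atoms$chain == "B"], seq_len(L))
  ## coordinates and atom counts untouched
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms[, c("x", "y", "z")], m$atoms[, c("x", "y", "z")])
})

test_that("partial-coverage chains renumber onto aligned target positions", {
  L <- 20
  tgt <- target_spec(c(A = paste(bio3d::aa321(sample(bio3d::aa.table$aa3[1:20],
                                                     L, replace = TRUE)),
                                 collapse = ""),
                       B = strrep("A", L)))
  ## model chain A covers target positions 4..20 (17/20 = 85% coverage)
  sub <- substr(tgt$sequences[["A"]], 4, 20)
  res3 <- vapply(strsplit(sub, "")[[1]], function(a)
    bio3d::aa123(a), "")
  a <- toy_atoms("A", seq_len(nchar(sub)), seq_len(nchar(sub)) * 3, 0, 0,
                 resid = res3)
  b <- toy_atoms("B", seq_len(L), seq_len(L) * 3, 4, 0)
  m <- decoy_model("part", rbind(a, b))
  ren <- renumber_ensemble(list(part = m), tgt)
  got <- ren$models$part$atoms
  expect_equal(got$resno[got$chain == "A"], 4:20)
})

test_that("models round-trip through PDB write and read", {
  ref <- make_reference_dimer(synthetic_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(ref, p)
  back <- read_model(p)
  expect_equal(nrow(back$atoms), nrow(ref$atoms))
  expect_equal(back$atoms$chain, ref$atoms$chain)
  expect_equal(back$atoms$resno, ref$atoms$resno)
  expect_equal(back$atoms$x, ref$atoms$x, tolerance = 1e-3)
})
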