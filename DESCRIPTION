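Package: consrankr
Title: Consensus Contact Ranking and Selection of Protein-Protein Docking Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores ensembles of protein-protein docking models ("decoys") by
    the conservation of their inter-residue contacts across the ensemble
    (CONSRANK consensus scoring), clusters models by contact-fingerprint
    Hamming distance with complete-linkage agglomeration (Clust-CONSRANK),
    characterizes interfaces (contact counts, buried solvent-accessible
    surface area, steric clashes), and combines these into a selection
    pipeline that adapts to the sharpness of the ensemble consensus. Includes
    CAPRI-style model quality assessment (fnat, ligand RMSD, interface RMSD)
    and a synthetic decoy-ensemble generator with known ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
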