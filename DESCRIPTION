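Package: sitedepth
Title: Atom Depth Profiling and Structural Classification of Missense
    Mutation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes exposed-volume atom depth indices on protein
    structures by voxelizing the protein body (with solvent-inaccessible
    cavities filled) and integrating the free volume of a reference
    sphere around each heavy atom.  Summarizes each residue by the depth
    of its C-alpha atom and the mean depth of its side-chain atoms,
    classifies missense mutation sites into inner-layer, outer-layer and
    intermediate topological clusters from side-chain position and
    orientation, and prioritizes substitutions of bulky outward-pointing
    residues by smaller ones (wild-type/mutant volume ratio) as
    candidates for mutation-induced surface pockets.  Includes PDB
    input/output with depth-annotated B-factor columns, pLDDT-based
    filtering of predicted models, deterministic synthetic structure
    generators with analytic ground truth, aggregate cluster reporting,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
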