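Package: fragdiff
Title: Fragment-Based Dual Conditional Diffusion for Pocket-Conditioned 3D
    Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage conditional denoising-diffusion framework for
    structure-based drug design. Starting from a reaction-informed seed
    fragment inside a protein pocket, a first E(3)-equivariant diffusion
    stage grows the molecular scaffold that fixes the global topology and
    binding pose, and a second stage decorates the scaffold with R-groups
    using virtual-atom padding. Chemical bonds are reconstructed from the
    generated point cloud by an edge-focused iterative graph refiner with a
    deterministic covalent-radius fallback. Includes BRICS-style
    fragmentation with Rule-of-Three filtering, reaction-template
    scaffold/R-group slicing, an evaluation battery (QED, synthetic
    accessibility, Tanimoto diversity, heteroatom ratio, geometric
    distributions and KL divergence), a synthetic fixture generator, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
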