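Package: ooplasm
Title: Cortical Microtubule Cytoskeletons, Cytoplasmic Flows and mRNA
    Transport in the Drosophila Oocyte
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic and continuum models of the non-centrosomal
    microtubule cytoskeleton of the stage 9 Drosophila oocyte, and of the
    intracellular transport it drives.  Microtubules are grown as persistent
    random walks from cortical seeding points drawn by inverse-transform
    sampling of arclength nucleation densities; realizations are
    coarse-grained into motor-velocity fields that force an incompressible
    Stokes solver for slow cytoplasmic streaming and advect bound cargo in a
    two-species reaction-advection-diffusion model of oskar and bicoid mRNA
    localisation.  A companion straight-rod continuum model supports
    fixed-point analysis of the cytoskeletal topology, (epsilon, kP) phase
    diagrams and the saddle-node bifurcation between wild-type and par-1
    hypomorph architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
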