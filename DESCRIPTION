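Package: zfescape
Title: Experiment-Driven Energetics of Zebrafish C-Start Escape Swims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline quantifying the kinematics and mechanical
    energetics of zebrafish eleutheroembryo C-start escape swims. From
    high-speed silhouette movies (synthetic or recorded) it isolates pure
    body movement by an iterative momentum-based Procrustes procedure,
    tracks a 300-segment midline and its curvature, reconstructs a
    three-dimensional body from transverse cross-sections by entropic
    optimal-transport (Sinkhorn) barycenter interpolation, and drives a
    penalized incompressible Navier-Stokes solver two-way coupled to the
    rigid-body equations of motion. Downstream it computes instantaneous
    mechanical power, total work, cost of transport, Reynolds number,
    vorticity and Q-criterion wake fields, and orchestrates viscosity-sweep
    and frequency-rescaling in-silico experiments summarised by ordinary
    least-squares regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    igraph,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
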