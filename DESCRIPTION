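Package: minisitus
Title: Multi-Resolution Density Map Fitting and Volume Algebra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conventions and tools for multi-resolution structural modelling:
    reading and writing volumetric density maps (Situs ASCII and an MRC/CCP4
    binary subset) and atomic structures (PDB); conversion between atomic
    models, density maps and hexagonal close-packed bead models via kernel
    convolution; a calculus of resolution conventions (crystallographic,
    Rayleigh point, Situs 2-sigma, EMAN) derived from Airy-disk matching;
    cross-correlation scoring with optional Laplacian contour filtering and
    FFT-accelerated exhaustive rigid-body search; vector-quantization feature
    points and unequal-size point-cloud matching; simultaneous multi-fragment
    off-lattice Powell refinement; cyclic, dihedral and helical symmetry
    generation with a symmetry-constrained refinement loop; and voxel-wise
    volume algebra with 2D projections. Includes a synthetic-fixture
    generator and a command-line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
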