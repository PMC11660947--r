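Package: crossalps
Title: Crossing-Fibre-Aware DTI-ALPS Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computation of the diffusion-tensor-imaging analysis along the
    perivascular space (DTI-ALPS) index with an explicit treatment of the
    bias introduced by crossing fibres. Provides log-linear diffusion tensor
    fitting, eigen-analysis, fractional anisotropy and diffusion-encoded
    colour maps, flagging of crossing-fibre voxels by the middle-to-lowest
    eigenvalue ratio, conventional and crossing-adjusted ALPS indices, an
    analytic crossing-fibre bias model, synthetic diffusion-weighted
    phantom and cohort generators with Rician noise, and paired
    nonparametric comparisons of conventional versus adjusted indices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'tensor-core.R'
    'crossing.R'
    'alps.R'
    'bias-model.R'
    'phantom.R'
    'cohort.R'
    'crossalps-package.R'
    'stats.R'
    'io.R'
    'pipeline.R'
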