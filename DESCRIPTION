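Package: spacergeom
Title: Geometry of Remodeled Promoter Spacer DNA in Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural measurements for protein-induced promoter DNA
    remodeling, of the kind produced by MerR-family transcription factors
    bound to suboptimal 19-20 bp spacers: standard base reference frames,
    Watson-Crick pair detection (including broken central pairs), CEHS
    base-pair step and helical parameters, total spacer twist and
    under-twist relative to ideal B-form DNA, centroid-partition kink
    angles, spacer end-to-end lengths, transcription-bubble sizes,
    Kabsch superposition and rigid-body domain motion, and
    Shrake-Rupley solvent-accessible and buried interface areas.
    Includes a deterministic B-DNA duplex generator driven by per-step
    parameter schedules (with controllable kinks, global unwinding and
    opened base pairs) that emits machine-readable ground truth, so the
    whole measurement chain is testable without coordinate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
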