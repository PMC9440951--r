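Package: ieegcurate
Title: Curate Clinical Intracranial EEG Recordings into BIDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organizing clinical intraoperative and long-term
    intracranial EEG (ECoG and SEEG) into the Brain Imaging Data Structure
    (BIDS). Provides a reader/writer for a Micromed-style TRC binary dialect,
    pseudo-anonymization of patient headers with a restricted identifier
    registry, a parser for an in-file annotation grammar (electrode formats,
    channel status marks, paired event segments, task declarations),
    geometric classification of electrode contacts as resected, edge or
    cavity from 2D photo-plane polygons or 3D resection masks, BIDS entity
    naming for intraoperative situations and long-term monitoring runs,
    sidecar and BrainVision Core Data Format export, a structural dataset
    validator, and a fully synthetic demonstration study generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
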