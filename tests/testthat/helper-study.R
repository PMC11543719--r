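# The original field survey's sample-by-element workbook is distributed only
# as journal supplementary material (no public accession) and is not bundled.
# If a user exports it to the canonical CSV pair below, the study-data checks
# run against it; otherwise the property-based and synthetic suites stand on
# their own.
study_panel_path <- function() {
  file.path(system.file("extdata", package = "mosscreen"), "study_panel.csv")
}
study_mdl_path <- function() {
  file.path(system.file("extdata", package = "mosscreen"), "study_mdl.csv")
}
study_data_available <- function() {
  file.exists(study_panel_path()) && file.exists(study_mdl_path())
}
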