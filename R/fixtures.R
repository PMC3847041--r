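# Genotype fixture registry. The published per-genotype summary statistics
# are transcribed once into inst/extdata/paper_params.yaml and serve as
# ground-truth parameters for the synthetic generators.

.fixture_env <- new.env(parent = emptyenv())

#' Genotype fixture registry
#'
#' Returns the full registry of published per-genotype parameters (acceptor
#' bleach FRET ratios, ratiometric drop fractions, assembly rates, junction
#' presence fractions, disassembly time constants and lags, spheroid roundness
#' trajectories, and the calcium dose-response calibration).
#'
#' @return nested list as stored in `extdata/paper_params.yaml`.
#' @export
fixture_registry <- function() {
  if (is.null(.fixture_env$reg)) {
    path <- system.file("extdata", "paper_params.yaml", package = "adherens",
                        mustWork = TRUE)
    .fixture_env$reg <- yaml::read_yaml(path)
  }
  .fixture_env$reg
}

#' Fixture parameters for one genotype and assay
#'
#' @param genotype one of "WT", "W2A", "R14E", "V81D_V174D", "EC5".
#' @param assay one of "bleach_fret", "ratiometric", "assembly", "lifetime",
#'   "disassembly", "spheroid".
#' @return list of published parameters for that assay.
#' @export
fixture_params <- function(genotype, assay) {
  reg <- fixture_registry()$genotypes
  g <- reg[[genotype]] %||% stop("unknown genotype: ", genotype)
  g[[assay]] %||% stop("no '", assay, "' fixture for genotype ", genotype)
}

#' Calcium to spheroid roundness plateau map
#'
#' Declared monotone logistic mapping external calcium concentration (mM) to
#' the spheroid roundness plateau, calibrated once against the published
#' wild-type 20-h dose series.
#'
#' @param ca_mM external calcium concentration(s), mM.
#' @return roundness plateau value(s).
#' @export
ca_roundness_map <- function(ca_mM) {
  p <- fixture_registry()$ca_dose$logistic
  p$lo + (p$hi - p$lo) / (1 + exp(-(ca_mM - p$c50) / p$scale))
}
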