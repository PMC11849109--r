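# Shared documentation topics for the S4 classes whose constructors carry
# the main documentation.

#' AcquisitionSchedule: label-duration/PLD timing grid
#' @name AcquisitionSchedule
#' @seealso \code{\link{acquisitionSchedule}}
NULL

#' KineticConstants: fixed parameters of the kinetic model
#' @name KineticConstants
#' @seealso \code{\link{kineticConstants}}
NULL

#' OximetryConstants: susceptibility-oximetry constants
#' @name OximetryConstants
#' @seealso \code{\link{oximetryConstants}}
NULL

#' RespiratoryTrace: sampled exhaled-oxygen trace
#' @name RespiratoryTrace
#' @seealso \code{\link{respiratoryTrace}}
NULL

#' VeinTerritoryAtlas: vein to parcellation-label mapping
#' @name VeinTerritoryAtlas
#' @seealso \code{\link{veinTerritoryAtlas}}
NULL

#' PhantomSpec: phantom geometry and noise specification
#' @name PhantomSpec
#' @seealso \code{\link{phantomSpec}}
NULL
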