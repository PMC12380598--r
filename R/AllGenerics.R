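#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))

#' @export
setGeneric("mrdValues", function(x, timepoint) standardGeneric("mrdValues"))

#' @export
setGeneric("responseLabels", function(x, timepoint) standardGeneric("responseLabels"))

#' @export
setGeneric("dichotomize", function(x, scheme) standardGeneric("dichotomize"))

#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @export
setGeneric("chromArms", function(x) standardGeneric("chromArms"))

#' @export
setGeneric("annotatedGenes", function(x, expressed.only = FALSE) standardGeneric("annotatedGenes"))

#' @export
setGeneric("blacklistRegions", function(x) standardGeneric("blacklistRegions"))
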