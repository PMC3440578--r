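## Generics for accessors shared across the S4 containers.

#' @rdname accessors
#' @export
setGeneric("channelWidth", function(object) standardGeneric("channelWidth"))

#' @rdname accessors
#' @export
setGeneric("decayCounts", function(object) standardGeneric("decayCounts"))

#' @rdname accessors
#' @export
setGeneric("irfCounts", function(object) standardGeneric("irfCounts"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("background", function(object) standardGeneric("background"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))

#' @rdname accessors
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))

#' @rdname accessors
#' @export
setGeneric("thetas", function(object) standardGeneric("thetas"))

#' @rdname accessors
#' @export
setGeneric("r0", function(object) standardGeneric("r0"))

#' @rdname accessors
#' @export
setGeneric("rTotal", function(object) standardGeneric("rTotal"))

#' @rdname accessors
#' @export
setGeneric("gFactor", function(object) standardGeneric("gFactor"))

#' @rdname accessors
#' @export
setGeneric("tauGrid", function(object) standardGeneric("tauGrid"))

#' @rdname accessors
#' @export
setGeneric("densityWeights", function(object) standardGeneric("densityWeights"))

#' @rdname accessors
#' @export
setGeneric("chi2Reduced", function(object) standardGeneric("chi2Reduced"))

#' @rdname accessors
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("fieldAxis", function(object) standardGeneric("fieldAxis"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("frequencyGHz", function(object) standardGeneric("frequencyGHz"))

#' @rdname accessors
#' @export
setGeneric("powers", function(object) standardGeneric("powers"))

#' @rdname accessors
#' @export
setGeneric("pHalf", function(object) standardGeneric("pHalf"))

#' @rdname accessors
#' @export
setGeneric("meltingPoint", function(object) standardGeneric("meltingPoint"))

#' @rdname accessors
#' @export
setGeneric("vantHoffEnthalpy",
           function(object) standardGeneric("vantHoffEnthalpy"))
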