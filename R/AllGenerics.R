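#' @name scrselect-generics
#' @title Common accessors
#' @description Small accessor generics shared across the package's classes.
#' @param x an object.
#' @return integer or numeric scalars/vectors as appropriate.
NULL

#' @rdname scrselect-generics
#' @export
setGeneric("nTraps", function(x) standardGeneric("nTraps"))

#' @rdname scrselect-generics
#' @export
setGeneric("nOccasions", function(x) standardGeneric("nOccasions"))

#' @rdname scrselect-generics
#' @export
setGeneric("nAugmented", function(x) standardGeneric("nAugmented"))

#' @rdname scrselect-generics
#' @export
setGeneric("nObserved", function(x) standardGeneric("nObserved"))

#' @rdname scrselect-generics
#' @export
setGeneric("spaceArea", function(x) standardGeneric("spaceArea"))

#' @rdname scrselect-generics
#' @export
setGeneric("trapCoords", function(x) standardGeneric("trapCoords"))

#' @rdname scrselect-generics
#' @export
setGeneric("knownLinks", function(x) standardGeneric("knownLinks"))

#' Evaluate the log-density of a fitted tuning density
#'
#' @param object a [TuningDensity-class].
#' @param x numeric vector or matrix (rows = points) on the transformed scale.
#' @return numeric vector of log-densities.
#' @export
setGeneric("logDensity", function(object, x) standardGeneric("logDensity"))

#' @rdname scrselect-generics
#' @export
setGeneric("populationSizeDraws", function(x) standardGeneric("populationSizeDraws"))

#' @rdname scrselect-generics
#' @export
setGeneric("criterionValue", function(x) standardGeneric("criterionValue"))
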