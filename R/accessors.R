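## Accessor generics: slot access stays behind these.

#' Normalized radii of a profile
#' @param x a [RadialProfile-class].
#' @return numeric vector of normalized radii.
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @rdname radii
#' @export
setMethod("radii", "RadialProfile", function(x) x@r)

#' Field values of a profile or map
#' @param x a [RadialProfile-class] or [ScalarMap-class].
#' @return numeric vector or matrix of field values.
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "RadialProfile", function(x) x@values)

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "ScalarMap", function(x) x@values)

#' Unit label
#' @param x a [RadialProfile-class] or [ScalarMap-class].
#' @return character unit label.
#' @export
setGeneric("valueUnits", function(x) standardGeneric("valueUnits"))

#' @rdname valueUnits
#' @export
setMethod("valueUnits", "RadialProfile", function(x) x@units)

#' @rdname valueUnits
#' @export
setMethod("valueUnits", "ScalarMap", function(x) x@units)

#' Inclusion mask of a map
#' @param x a [ScalarMap-class].
#' @return logical matrix, or `NULL` when the map has no mask.
#' @export
setGeneric("inclusionMask", function(x) standardGeneric("inclusionMask"))

#' @rdname inclusionMask
#' @export
setMethod("inclusionMask", "ScalarMap", function(x)
    if (length(x@mask)) x@mask else NULL)

#' Fitted alpha of a recovery result
#' @param x a [RecoveryResult-class].
#' @return fitted alpha (dimensionless).
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname alphaHat
#' @export
setMethod("alphaHat", "RecoveryResult", function(x) x@alphaHat)

#' Fitted peak SSn of a recovery result
#' @param x a [RecoveryResult-class].
#' @return peak SSn at the fitted alpha.
#' @export
setGeneric("ssnPeakHat", function(x) standardGeneric("ssnPeakHat"))

#' @rdname ssnPeakHat
#' @export
setMethod("ssnPeakHat", "RecoveryResult", function(x) x@ssnPeakHat)
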