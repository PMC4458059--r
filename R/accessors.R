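#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("sMatrix", function(x) standardGeneric("sMatrix"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("fluxBounds", function(x) standardGeneric("fluxBounds"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("knockouts", function(x) standardGeneric("knockouts"))

#' @rdname accessors
#' @export
setGeneric("isCoupled", function(x) standardGeneric("isCoupled"))

#' @rdname accessors
#' @export
setGeneric("designTrace", function(x) standardGeneric("designTrace"))

#' @rdname accessors
#' @export
setGeneric("profileSteps", function(x) standardGeneric("profileSteps"))

#' Accessors for tyroflux S4 objects
#'
#' Small read-only accessors: `reactionIds`/`metaboliteIds`/`sMatrix`/
#' `objectiveReaction`/`fluxBounds` for [MetabolicModel-class] objects,
#' `fluxes`/`solutionStatus` for [FluxSolution-class], `knockouts`/
#' `isCoupled`/`designTrace` for [DesignResult-class], and `profileSteps`
#' for [ThermoProfile-class].
#'
#' @param x the object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@rxns$id)

#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@mets$id)

#' @rdname accessors
#' @export
setMethod("sMatrix", "MetabolicModel", function(x) x@S)

#' @rdname accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objective_id)

#' @rdname accessors
#' @export
setMethod("fluxBounds", "MetabolicModel", function(x) {
  data.frame(id = x@rxns$id, lower_bound = x@rxns$lower_bound,
             upper_bound = x@rxns$upper_bound, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("knockouts", "DesignResult", function(x) x@knockouts)

#' @rdname accessors
#' @export
setMethod("isCoupled", "DesignResult", function(x) x@coupled)

#' @rdname accessors
#' @export
setMethod("designTrace", "DesignResult", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("profileSteps", "ThermoProfile", function(x) x@steps)
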