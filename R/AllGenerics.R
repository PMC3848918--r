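#' Accessors for fitted objects and containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @return The corresponding component: \code{modelId} and friends return
#'   scalars, \code{estimates} a named numeric vector, \code{fittedCurve}
#'   a two-column data.frame, \code{measurements} / \code{experiments} /
#'   \code{projects} lists of the child objects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("fitRMSE", function(object) standardGeneric("fitRMSE"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("fittedCurve", function(object) standardGeneric("fittedCurve"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("experiments", function(object) standardGeneric("experiments"))

#' @rdname accessors
#' @export
setGeneric("projects", function(object) standardGeneric("projects"))

#' @rdname accessors
#' @export
setMethod("modelId", "GrowthFit", function(object) object@modelId)

#' @rdname accessors
#' @export
setMethod("modelId", "ModelDefinition", function(object) object@modelId)

#' @rdname accessors
#' @export
setMethod("estimates", "GrowthFit", function(object) object@estimates)

#' @rdname accessors
#' @export
setMethod("fitRMSE", "GrowthFit", function(object) object@rmse)

#' @rdname accessors
#' @export
setMethod("isConverged", "GrowthFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("fittedCurve", "GrowthFit", function(object)
    data.frame(time = object@fittedTimes, value = object@fittedValues))

#' @rdname accessors
#' @export
setMethod("measurements", "Experiment", function(object) object@measurements)

#' @rdname accessors
#' @export
setMethod("experiments", "Project", function(object) object@experiments)

#' @rdname accessors
#' @export
setMethod("projects", "GrowthRepository", function(object) object@projects)

#' Convert a Measurement to a data.frame
#'
#' @param x a \linkS4class{Measurement}.
#' @param ... unused.
#' @return data.frame with columns \code{time}, \code{value} and, when
#'   present, \code{extra} and \code{annotation}.
#' @export
as.data.frame.Measurement <- function(x, ...) {
    df <- data.frame(time = x@time, value = x@value)
    if (length(x@extra)) df$extra <- x@extra
    if (length(x@annotation)) df$annotation <- x@annotation
    df
}

setMethod("show", "Measurement", function(object) {
    cat(sprintf("Measurement '%s' (%s): %d points, t in [%g, %g]\n",
                object@measurementId, object@name, length(object@time),
                if (length(object@time)) min(object@time) else NA,
                if (length(object@time)) max(object@time) else NA))
    if (length(object@extra)) cat("  carries a third numeric dimension\n")
    if (length(object@annotation)) cat("  carries row annotations\n")
})

setMethod("show", "Experiment", function(object) {
    cat(sprintf("Experiment '%s' (%s): %d measurement(s), %d fit(s)\n",
                object@experimentId, object@name,
                length(object@measurements), length(object@fits)))
})

setMethod("show", "Project", function(object) {
    cat(sprintf("Project '%s' (%s): %d experiment(s)\n",
                object@projectId, object@name, length(object@experiments)))
})

setMethod("show", "GrowthRepository", function(object) {
    cat(sprintf("GrowthRepository: %d project(s)%s\n",
                length(object@projects),
                if (nzchar(object@root))
                    sprintf(" [root: %s]", object@root) else ""))
})

setMethod("show", "GrowthFit", function(object) {
    cat(sprintf("GrowthFit: model '%s' on %d points\n",
                object@modelId, object@nPoints))
    est <- object@estimates
    for (nm in names(est))
        cat(sprintf("  %-12s %.6g\n", nm, est[[nm]]))
    cat(sprintf("  RMSE %.6g | converged: %s | starts: %d\n",
                object@rmse, object@converged, object@nStartsUsed))
})

setMethod("show", "LogLinearFit", function(object) {
    cat(sprintf(
        "LogLinearFit: slope %.6g (1/time), intercept %.6g, R^2 %.4f, n=%d, window [%g, %g]\n",
        object@slope, object@intercept, object@rSquared, object@nPoints,
        object@window[1], object@window[2]))
})

setMethod("show", "ModelDefinition", function(object) {
    cat(sprintf("ModelDefinition '%s' (%s)%s\n", object@modelId,
                object@displayName, if (object@odeModel) " [ODE]" else ""))
    cat("  ", object@equationText, "\n", sep = "")
    cat(sprintf("  parameters: %s\n",
                paste(object@parameters$name, collapse = ", ")))
})

setMethod("show", "ModelRegistry", function(object) {
    cat(sprintf("ModelRegistry with %d model(s): %s\n",
                length(object@models),
                paste(names(object@models), collapse = ", ")))
})
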