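#' @import methods
NULL

setClassUnion("functionORNULL", c("function", "NULL"))

.checkId <- function(id, what) {
    if (length(id) != 1L || is.na(id) || !nzchar(id))
        return(sprintf("%s must be a single non-empty string", what))
    if (!grepl("^[A-Za-z0-9._-]+$", id))
        return(sprintf("%s '%s' may only contain [A-Za-z0-9._-]", what, id))
    NULL
}

#' Measurement: one annotated growth time series
#'
#' The bottom layer of the data hierarchy: an ordered series of
#' \code{(time, value)} observations, optionally carrying a third numeric
#' dimension (\code{extra}) and a free-text \code{annotation} per row.
#' Only \code{time} and \code{value} take part in model fitting; the third
#' dimension and the annotation are inert payload that is stored and
#' round-tripped verbatim.
#'
#' @slot measurementId single identifier string.
#' @slot name display name.
#' @slot time strictly increasing numeric times (arbitrary units).
#' @slot value finite numeric signal (e.g. optical density, radius, weight).
#' @slot extra optional third numeric dimension; length 0 or \code{length(time)}.
#' @slot annotation optional per-row text; length 0 or \code{length(time)}.
#'
#' @exportClass Measurement
setClass("Measurement",
    representation(
        measurementId = "character",
        name = "character",
        time = "numeric",
        value = "numeric",
        extra = "numeric",
        annotation = "character"
    ),
    prototype(extra = numeric(0), annotation = character(0))
)

setValidity("Measurement", function(object) {
    msg <- character(0)
    idp <- .checkId(object@measurementId, "measurementId")
    if (!is.null(idp)) msg <- c(msg, idp)
    n <- length(object@time)
    if (length(object@value) != n)
        msg <- c(msg, "time and value must have equal length")
    if (n > 1L && any(diff(object@time) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@time)) || any(!is.finite(object@value)))
        msg <- c(msg, "times and values must all be finite")
    if (length(object@extra) != 0L && length(object@extra) != n)
        msg <- c(msg, "extra must be empty or match the number of rows")
    if (length(object@annotation) != 0L && length(object@annotation) != n)
        msg <- c(msg, "annotation must be empty or match the number of rows")
    if (length(msg)) msg else TRUE
})

#' Experiment: a folder of measurements with attached fit results
#'
#' @slot experimentId single identifier string.
#' @slot name display name.
#' @slot measurements list of \linkS4class{Measurement}, ids unique.
#' @slot fits list of attached results; each element is a list with
#'   components \code{measurements} (character vector of measurement ids),
#'   \code{modelId} and \code{fit} (a \linkS4class{GrowthFit}).
#'
#' @exportClass Experiment
setClass("Experiment",
    representation(
        experimentId = "character",
        name = "character",
        measurements = "list",
        fits = "list"
    ),
    prototype(measurements = list(), fits = list())
)

setValidity("Experiment", function(object) {
    msg <- character(0)
    idp <- .checkId(object@experimentId, "experimentId")
    if (!is.null(idp)) msg <- c(msg, idp)
    ids <- vapply(object@measurements, function(m) m@measurementId, "")
    if (anyDuplicated(ids))
        msg <- c(msg, "measurement ids must be unique within an experiment")
    if (length(msg)) msg else TRUE
})

#' Project: top-level container of experiments
#'
#' @slot projectId single identifier string.
#' @slot name display name.
#' @slot description free text.
#' @slot experiments list of \linkS4class{Experiment}, ids unique.
#'
#' @exportClass Project
setClass("Project",
    representation(
        projectId = "character",
        name = "character",
        description = "character",
        experiments = "list"
    ),
    prototype(description = "", experiments = list())
)

setValidity("Project", function(object) {
    msg <- character(0)
    idp <- .checkId(object@projectId, "projectId")
    if (!is.null(idp)) msg <- c(msg, idp)
    ids <- vapply(object@experiments, function(e) e@experimentId, "")
    if (anyDuplicated(ids))
        msg <- c(msg, "experiment ids must be unique within a project")
    if (length(msg)) msg else TRUE
})

#' GrowthRepository: hierarchical store of projects
#'
#' Plain-file replacement for a database backend: projects contain
#' experiments which contain measurements plus attached fits.  Persisted
#' as a diffable directory tree of CSV and JSON files by
#' \code{\link{saveRepository}}.
#'
#' @slot projects list of \linkS4class{Project}, ids unique.
#' @slot root directory the repository was loaded from ("" if in-memory).
#'
#' @exportClass GrowthRepository
setClass("GrowthRepository",
    representation(projects = "list", root = "character"),
    prototype(projects = list(), root = "")
)

setValidity("GrowthRepository", function(object) {
    ids <- vapply(object@projects, function(p) p@projectId, "")
    if (anyDuplicated(ids)) "project ids must be unique" else TRUE
})

#' GrowthFit: result of fitting one model to one or more time series
#'
#' @slot modelId identifier of the fitted model.
#' @slot estimates named numeric vector of parameter estimates, each within
#'   its search range.
#' @slot rmse root mean square error of the fitted curve against the
#'   observations (denominator \code{n}, no degrees-of-freedom correction).
#' @slot nPoints number of observations used.
#' @slot converged whether the winning optimizer start reported success.
#' @slot nStartsUsed number of multi-start launches performed.
#' @slot fittedTimes,fittedValues simulated curve on the observation times
#'   (concatenated across datasets for pooled fits).
#'
#' @exportClass GrowthFit
setClass("GrowthFit",
    representation(
        modelId = "character",
        estimates = "numeric",
        rmse = "numeric",
        nPoints = "integer",
        converged = "logical",
        nStartsUsed = "integer",
        fittedTimes = "numeric",
        fittedValues = "numeric"
    )
)

setValidity("GrowthFit", function(object) {
    msg <- character(0)
    if (is.null(names(object@estimates)) && length(object@estimates))
        msg <- c(msg, "estimates must be named")
    if (length(object@rmse) != 1L || object@rmse < 0)
        msg <- c(msg, "rmse must be a single value >= 0")
    if (length(object@fittedTimes) != length(object@fittedValues))
        msg <- c(msg, "fitted curve times and values must align")
    if (length(msg)) msg else TRUE
})

#' LogLinearFit: manual regression of log-signal on time
#'
#' Ordinary least squares of \code{ln(value)} on \code{time} restricted to a
#' window; the slope is the specific growth rate on the natural-log scale.
#'
#' @slot slope specific growth rate (1/time).
#' @slot intercept intercept on the ln scale.
#' @slot window numeric \code{c(tStart, tEnd)}.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot nPoints points inside the window.
#'
#' @exportClass LogLinearFit
setClass("LogLinearFit",
    representation(
        slope = "numeric",
        intercept = "numeric",
        window = "numeric",
        rSquared = "numeric",
        nPoints = "integer"
    )
)

#' ModelDefinition: one entry of the model registry
#'
#' The in-process plugin contract: every model exposes parameter metadata
#' plus a simulate function, and optionally its own estimate function
#' (models without one fall back to the generic box-constrained
#' least-squares estimator).
#'
#' @slot modelId unique identifier within a registry.
#' @slot displayName human-readable name.
#' @slot equationText human-readable equation.
#' @slot parameters data.frame of parameter specs with columns
#'   \code{name, lower, upper, init, guess} (see \code{\link{parameterSpec}}).
#' @slot simulateFn \code{function(params, times)} returning one simulated
#'   value per requested time; \code{params} is a named numeric vector.
#' @slot estimateFn optional \code{function(data, specs, options)} returning
#'   a \linkS4class{GrowthFit}; \code{NULL} selects the generic estimator.
#' @slot paramCheck optional \code{function(params)} returning a character
#'   vector of violated invariants (empty when valid).
#' @slot odeModel whether simulation integrates an ODE (affects contract
#'   probing and documentation only; dispatch is identical).
#'
#' @exportClass ModelDefinition
setClass("ModelDefinition",
    representation(
        modelId = "character",
        displayName = "character",
        equationText = "character",
        parameters = "data.frame",
        simulateFn = "function",
        estimateFn = "functionORNULL",
        paramCheck = "functionORNULL",
        odeModel = "logical"
    ),
    prototype(estimateFn = NULL, paramCheck = NULL, odeModel = FALSE)
)

setValidity("ModelDefinition", function(object) {
    msg <- character(0)
    idp <- .checkId(object@modelId, "modelId")
    if (!is.null(idp)) msg <- c(msg, idp)
    p <- object@parameters
    need <- c("name", "lower", "upper", "init", "guess")
    if (!all(need %in% names(p)))
        msg <- c(msg, sprintf("parameters must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        if (nrow(p) == 0L) msg <- c(msg, "parameters must be nonempty")
        if (any(p$lower >= p$upper))
            msg <- c(msg, "each parameter must have lower < upper")
        bad <- !is.na(p$guess) & (p$guess < p$lower | p$guess > p$upper)
        if (any(bad))
            msg <- c(msg, sprintf("guess outside [lower, upper] for: %s",
                                  paste(p$name[bad], collapse = ", ")))
        if (anyDuplicated(p$name))
            msg <- c(msg, "parameter names must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' ModelRegistry: ordered collection of model definitions
#'
#' @slot models named list of \linkS4class{ModelDefinition}, in
#'   registration order.
#'
#' @exportClass ModelRegistry
setClass("ModelRegistry",
    representation(models = "list"),
    prototype(models = list())
)

setValidity("ModelRegistry", function(object) {
    ids <- vapply(object@models, function(m) m@modelId, "")
    if (anyDuplicated(ids)) "model ids must be unique" else TRUE
})
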