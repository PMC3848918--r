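#' Describe one model parameter and its search range
#'
#' Builds a one-row parameter-spec data.frame; rbind several to describe a
#' model.  The search range acts as a box constraint during estimation;
#' parameters flagged as initial conditions take their default start value
#' from the first data point rather than from \code{guess}.
#'
#' @param name parameter identifier.
#' @param lower,upper search range (lower < upper).
#' @param init is this parameter an initial condition of the curve?
#' @param guess optional default start value inside \code{[lower, upper]}.
#' @return data.frame with columns \code{name, lower, upper, init, guess}.
#' @examples
#' rbind(parameterSpec("A", 0.1, 10, guess = 1),
#'       parameterSpec("muMax", 0.01, 5))
#' @export
parameterSpec <- function(name, lower, upper, init = FALSE, guess = NA_real_) {
    stopifnot(is.character(name), length(name) == 1L,
              is.numeric(lower), is.numeric(upper), lower < upper)
    if (!is.na(guess) && (guess < lower || guess > upper))
        stop(sprintf("guess for '%s' outside [%g, %g]", name, lower, upper))
    data.frame(name = name, lower = as.numeric(lower),
               upper = as.numeric(upper), init = isTRUE(init),
               guess = as.numeric(guess), stringsAsFactors = FALSE)
}

#' Create a model definition for the registry
#'
#' @param modelId unique identifier.
#' @param displayName human-readable name.
#' @param equationText human-readable equation.
#' @param parameters parameter-spec data.frame (see \code{\link{parameterSpec}}).
#' @param simulateFn \code{function(params, times)} -> numeric values.
#' @param estimateFn optional custom estimator; \code{NULL} uses the generic
#'   box-constrained least-squares estimator.
#' @param paramCheck optional invariant checker returning violation messages.
#' @param odeModel whether simulation integrates an ODE.
#' @return a \linkS4class{ModelDefinition}.
#' @export
modelDefinition <- function(modelId, displayName, equationText, parameters,
                            simulateFn, estimateFn = NULL, paramCheck = NULL,
                            odeModel = FALSE) {
    new("ModelDefinition", modelId = modelId, displayName = displayName,
        equationText = equationText, parameters = parameters,
        simulateFn = simulateFn, estimateFn = estimateFn,
        paramCheck = paramCheck, odeModel = odeModel)
}

#' Create an empty model registry
#'
#' @return a \linkS4class{ModelRegistry} with no models.
#' @export
ModelRegistry <- function() new("ModelRegistry")

#' Register a model definition
#'
#' @param registry a \linkS4class{ModelRegistry}.
#' @param definition a \linkS4class{ModelDefinition}.
#' @return the updated registry (registries are immutable values; the input
#'   is not modified in place).
#' @export
registerModel <- function(registry, definition) {
    stopifnot(is(registry, "ModelRegistry"), is(definition, "ModelDefinition"))
    validObject(definition)
    id <- definition@modelId
    if (id %in% names(registry@models))
        stop(sprintf("model id '%s' is already registered", id))
    registry@models[[id]] <- definition
    validObject(registry)
    registry
}

#' Retrieve a model definition by id
#'
#' @param registry a \linkS4class{ModelRegistry}.
#' @param modelId identifier to look up.
#' @return the \linkS4class{ModelDefinition}.
#' @export
getModel <- function(registry, modelId) {
    stopifnot(is(registry, "ModelRegistry"))
    if (!modelId %in% names(registry@models))
        stop(sprintf("unknown model id '%s'; available: %s", modelId,
                     paste(names(registry@models), collapse = ", ")))
    registry@models[[modelId]]
}

#' List registered models
#'
#' @param registry a \linkS4class{ModelRegistry}.
#' @return data.frame in registration order with columns \code{modelId},
#'   \code{displayName}, \code{equationText}, \code{ode} and a list-column
#'   \code{parameters} holding each model's parameter-spec data.frame
#'   (default ranges and initial-condition flags included).
#' @export
listModels <- function(registry) {
    stopifnot(is(registry, "ModelRegistry"))
    ms <- registry@models
    out <- data.frame(
        modelId = vapply(ms, function(m) m@modelId, ""),
        displayName = vapply(ms, function(m) m@displayName, ""),
        equationText = vapply(ms, function(m) m@equationText, ""),
        ode = vapply(ms, function(m) m@odeModel, NA),
        stringsAsFactors = FALSE, row.names = NULL
    )
    out$parameters <- I(unname(lapply(ms, function(m) m@parameters)))
    out
}

## ---- parameter validation helpers -----------------------------------------

.needParams <- function(params, wanted) {
    miss <- setdiff(wanted, names(params))
    if (length(miss))
        return(sprintf("missing parameter(s): %s", paste(miss, collapse = ", ")))
    bad <- wanted[!is.finite(unlist(params[wanted]))]
    if (length(bad))
        return(sprintf("non-finite parameter(s): %s", paste(bad, collapse = ", ")))
    NULL
}

.checks <- list(
    sigmoid3 = function(p) {
        v <- .needParams(p, c("A", "muMax", "lambda"))
        if (!is.null(v)) return(v)
        c(if (p[["A"]] <= 0) "A must be > 0",
          if (p[["muMax"]] <= 0) "muMax must be > 0")
    },
    richards = function(p) {
        v <- .needParams(p, c("A", "muMax", "lambda", "v"))
        if (!is.null(v)) return(v)
        c(if (p[["A"]] <= 0) "A must be > 0",
          if (p[["muMax"]] <= 0) "muMax must be > 0",
          if (p[["v"]] <= 0) "v must be > 0")
    },
    baranyi = function(p) {
        v <- .needParams(p, c("y0", "yMax", "muMax", "vRate", "h0", "mCurv"))
        if (!is.null(v)) return(v)
        c(if (p[["yMax"]] <= p[["y0"]]) "yMax must be > y0",
          if (p[["muMax"]] <= 0) "muMax must be > 0",
          if (p[["vRate"]] <= 0) "vRate must be > 0",
          if (p[["h0"]] < 0) "h0 must be >= 0",
          if (p[["mCurv"]] <= 0) "mCurv must be > 0")
    },
    h3 = function(p) {
        v <- .needParams(p, c("M", "delta", "gamma", "theta", "P0", "t0"))
        if (!is.null(v)) return(v)
        c(if (p[["P0"]] <= 0) "P0 must be > 0",
          if (p[["M"]] <= p[["P0"]]) "M must be > P0",
          if (p[["gamma"]] <= 0) "gamma must be > 0",
          if (p[["theta"]] < 0) "theta must be >= 0",
          if (p[["delta"]] < 0) "delta must be >= 0")
    },
    lcf = function(p) {
        v <- .needParams(p, c("alpha", "delta", "lambdaDepth", "r0"))
        if (!is.null(v)) return(v)
        c(if (p[["alpha"]] <= 0) "alpha must be > 0",
          if (p[["delta"]] <= 0) "delta must be > 0",
          if (p[["lambdaDepth"]] <= 0) "lambdaDepth must be > 0",
          if (p[["r0"]] <= 0) "r0 must be > 0")
    },
    expDecay = function(p) {
        v <- .needParams(p, c("y0", "k", "offset"))
        if (!is.null(v)) return(v)
        if (p[["k"]] <= 0) "k must be > 0"
    }
)

## ---- built-in registry -----------------------------------------------------

#' Load default parameter search ranges from a YAML metadata file
#'
#' @param path YAML file; defaults to the ranges shipped with the package.
#' @param modelId optional single model to extract.
#' @return a named list of parameter-spec data.frames, or one data.frame
#'   when \code{modelId} is given.
#' @export
defaultRanges <- function(path = system.file("extdata", "model_ranges.yaml",
                                             package = "GrowthCurveFit"),
                          modelId = NULL) {
    cfg <- yaml::read_yaml(path)
    specs <- lapply(cfg, function(m) {
        do.call(rbind, lapply(names(m$parameters), function(nm) {
            p <- m$parameters[[nm]]
            parameterSpec(nm, p$lower, p$upper,
                          init = isTRUE(p$init),
                          guess = if (is.null(p$guess)) NA_real_ else p$guess)
        }))
    })
    if (!is.null(modelId)) {
        if (!modelId %in% names(specs))
            stop(sprintf("no ranges for model '%s' in %s", modelId, path))
        return(specs[[modelId]])
    }
    specs
}

.asParams <- function(params) {
    p <- unlist(params)
    if (is.null(names(p)) || any(!nzchar(names(p))))
        stop("params must be a fully named numeric vector or list")
    p
}

#' Registry preloaded with the built-in model catalogue
#'
#' Built-ins: \code{gompertz}, \code{logistic}, \code{richards},
#' \code{baranyi} (printed 1/muMax adjustment), \code{baranyi_classic}
#' (1/v adjustment), \code{h3}, \code{lcf}, \code{poly1}, \code{poly2},
#' \code{exp_decay}.  Default search ranges come from the packaged
#' \code{model_ranges.yaml}.
#'
#' @return a \linkS4class{ModelRegistry}.
#' @examples
#' names(defaultRegistry()@models)
#' @export
defaultRegistry <- function() {
    rg <- defaultRanges()
    reg <- ModelRegistry()
    add <- function(reg, id, nm, eq, fn, check, ode = FALSE)
        registerModel(reg, modelDefinition(id, nm, eq, rg[[id]], fn,
                                           paramCheck = check, odeModel = ode))
    reg <- add(reg, "gompertz", "Gompertz (modified)",
        "y(t) = A*exp(-exp((muMax*e/A)*(lambda - t) + 1))",
        function(params, times) {
            p <- .asParams(params)
            gompertzValue(times, p[["A"]], p[["muMax"]], p[["lambda"]])
        }, .checks$sigmoid3)
    reg <- add(reg, "logistic", "Logistic",
        "y(t) = A / (1 + exp(4*muMax*(lambda - t)/A + 2))",
        function(params, times) {
            p <- .asParams(params)
            logisticValue(times, p[["A"]], p[["muMax"]], p[["lambda"]])
        }, .checks$sigmoid3)
    reg <- add(reg, "richards", "Richards",
        "y(t) = A*(1 + v*exp(1+v)*exp((muMax/A)*(1+v)^(1+1/v)*(lambda - t)))^(-1/v)",
        function(params, times) {
            p <- .asParams(params)
            richardsValue(times, p[["A"]], p[["muMax"]], p[["lambda"]], p[["v"]])
        }, .checks$richards)
    reg <- add(reg, "baranyi", "Baranyi (1/muMax adjustment)",
        "y(t) = y0 + muMax*A(t) - (1/m)*ln(1 + (exp(m*muMax*A(t)) - 1)/exp(m*(yMax - y0))), A(t) = t + ln(e^-vt + e^-h0 - e^(-vt-h0))/muMax",
        function(params, times) {
            p <- .asParams(params)
            baranyiValue(times, p[["y0"]], p[["yMax"]], p[["muMax"]],
                         p[["vRate"]], p[["h0"]], p[["mCurv"]], "muMax")
        }, .checks$baranyi)
    reg <- add(reg, "baranyi_classic", "Baranyi (classic 1/v adjustment)",
        "as 'baranyi' with A(t) = t + ln(e^-vt + e^-h0 - e^(-vt-h0))/v",
        function(params, times) {
            p <- .asParams(params)
            baranyiValue(times, p[["y0"]], p[["yMax"]], p[["muMax"]],
                         p[["vRate"]], p[["h0"]], p[["mCurv"]], "vRate")
        }, .checks$baranyi)
    reg <- add(reg, "h3", "Hyperbolastic type III",
        "P(t) = M - alpha*exp(-delta*t^gamma - arcsinh(theta*t)), alpha = (M - P0)*exp(delta*t0^gamma + arcsinh(theta*t0))",
        function(params, times) {
            p <- .asParams(params)
            h3Value(times, p[["M"]], p[["delta"]], p[["gamma"]],
                    p[["theta"]], p[["P0"]], p[["t0"]])
        }, .checks$h3)
    reg <- add(reg, "lcf", "Live Cell Fraction (spheroid radius ODE)",
        "dr/dt = r/3 * ((alpha + delta)*3*lambda/(3*lambda + r) - delta)",
        function(params, times) {
            p <- .asParams(params)
            lcfSimulate(times, p[["alpha"]], p[["delta"]],
                        p[["lambdaDepth"]], p[["r0"]])
        }, .checks$lcf, ode = TRUE)
    ## polynomial models are linear in their parameters, so their contract
    ## estimator solves the normal equations exactly (QR) instead of running
    ## the iterative optimizer; bounds, pins or log scale fall back to it
    addPoly <- function(reg, id, nm, eq, degree, check) {
        def <- modelDefinition(id, nm, eq, rg[[id]],
            function(params, times) {
                p <- .asParams(params)
                polynomialValue(times, p[paste0("c", 0:degree)])
            }, paramCheck = check)
        def@estimateFn <- function(data, specs, options)
            .linearPolyFit(def, degree, data, specs, options)
        registerModel(reg, def)
    }
    reg <- addPoly(reg, "poly1", "First-order polynomial",
                   "y(t) = c0 + c1*t", 1L,
                   function(p) .needParams(p, c("c0", "c1")))
    reg <- addPoly(reg, "poly2", "Second-order polynomial",
                   "y(t) = c0 + c1*t + c2*t^2", 2L,
                   function(p) .needParams(p, c("c0", "c1", "c2")))
    reg <- add(reg, "exp_decay", "Exponential decay",
        "y(t) = offset + (y0 - offset)*exp(-k*t)",
        function(params, times) {
            p <- .asParams(params)
            expDecayValue(times, p[["y0"]], p[["k"]], p[["offset"]])
        }, .checks$expDecay)
    reg
}

#' Simulate a registered model on a time grid
#'
#' Dispatches through the registry to the model's simulate function after
#' validating the parameters against the model's invariants.
#'
#' @param registry a \linkS4class{ModelRegistry}.
#' @param modelId registered model id.
#' @param params named numeric vector or list of parameter values.
#' @param times numeric times (strictly increasing for ODE models).
#' @return data.frame with columns \code{time} and \code{value}, aligned
#'   1:1 with \code{times}; deterministic given identical inputs.
#' @examples
#' reg <- defaultRegistry()
#' simulateModel(reg, "gompertz",
#'               c(A = 1, muMax = 0.2, lambda = 5), seq(0, 48, 2))
#' @export
simulateModel <- function(registry, modelId, params, times) {
    def <- getModel(registry, modelId)
    p <- .asParams(params)
    if (!is.null(def@paramCheck)) {
        viol <- def@paramCheck(p)
        if (length(viol))
            stop(sprintf("invalid parameters for model '%s': %s", modelId,
                         paste(viol, collapse = "; ")))
    }
    vals <- def@simulateFn(p, times)
    if (length(vals) != length(times))
        stop(sprintf("model '%s' returned %d values for %d times",
                     modelId, length(vals), length(times)))
    data.frame(time = times, value = as.numeric(vals))
}

#' Check a model definition against the plugin contract
#'
#' Exercises the simulate function on a probe grid at the model's default
#' guesses (falling back to range midpoints) and, when the definition
#' carries its own estimator, runs it on self-simulated data.  Returns a
#' report rather than raising errors, so broken plugins can be diagnosed.
#'
#' Clauses checked: simulation returns finite values; output length agrees
#' with the number of requested times; repeated simulation is identical
#' (determinism); estimates stay within their declared ranges.
#'
#' @param definition a \linkS4class{ModelDefinition}.
#' @param times probe grid (default \code{seq(0, 24, length.out = 25)}).
#' @return data.frame with columns \code{clause}, \code{pass}, \code{detail}.
#' @export
validateContract <- function(definition, times = seq(0, 24, length.out = 25)) {
    stopifnot(is(definition, "ModelDefinition"))
    spec <- definition@parameters
    probe <- ifelse(is.na(spec$guess), (spec$lower + spec$upper) / 2, spec$guess)
    names(probe) <- spec$name
    rep0 <- function(clause, pass, detail = "")
        data.frame(clause = clause, pass = pass, detail = detail,
                   stringsAsFactors = FALSE)
    out <- data.frame(clause = character(0), pass = logical(0),
                      detail = character(0), stringsAsFactors = FALSE)
    vals <- try(definition@simulateFn(probe, times), silent = TRUE)
    if (inherits(vals, "try-error")) {
        out <- rbind(out, rep0("simulate_runs", FALSE,
                               attr(vals, "condition")$message))
        return(out)
    }
    out <- rbind(out, rep0("simulate_runs", TRUE))
    out <- rbind(out, rep0("finite_outputs", all(is.finite(vals)),
                           if (all(is.finite(vals))) "" else
                               "non-finite simulated values"))
    lenOK <- length(vals) == length(times)
    out <- rbind(out, rep0("length_agreement", lenOK,
                           if (lenOK) "" else
                               sprintf("%d values for %d times",
                                       length(vals), length(times))))
    vals2 <- try(definition@simulateFn(probe, times), silent = TRUE)
    det <- !inherits(vals2, "try-error") && identical(vals, vals2)
    out <- rbind(out, rep0("deterministic", det))
    if (!is.null(definition@estimateFn) && lenOK && all(is.finite(vals))) {
        data <- data.frame(time = times, value = vals)
        fit <- try(definition@estimateFn(data, spec,
                                         fitOptions(nStarts = 3, seed = 1)),
                   silent = TRUE)
        if (inherits(fit, "try-error")) {
            out <- rbind(out, rep0("estimate_runs", FALSE,
                                   attr(fit, "condition")$message))
        } else {
            out <- rbind(out, rep0("estimate_runs", TRUE))
            est <- estimates(fit)
            inb <- all(est[spec$name] >= spec$lower - 1e-12 &
                       est[spec$name] <= spec$upper + 1e-12)
            out <- rbind(out, rep0("estimates_within_bounds", inb))
        }
    }
    rownames(out) <- NULL
    out
}
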