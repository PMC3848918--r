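## Bounded multi-start nonlinear least squares: the "parameter estimation"
## half of the model contract, shared by every model that does not bring its
## own estimator.

#' Root mean square error
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (obs_i - pred_i)^2}}
#' The denominator is \code{n}, not \code{n - p}: RMSE serves as a baseline
#' for comparison across models with different parameter counts, so no
#' degrees-of-freedom correction is applied.
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @return single nonnegative number in signal units.
#' @export
rmse <- function(observed, predicted) {
    if (length(observed) == 0L || length(observed) != length(predicted))
        stop("observed and predicted must have equal nonzero length")
    sqrt(mean((observed - predicted)^2))
}

#' Fitting options
#'
#' @param nStarts number of multi-start launches (first start uses the
#'   default guesses, the rest a Latin-hypercube sample of the search box).
#' @param seed RNG seed controlling the start sample; identical inputs and
#'   seed give identical fits.
#' @param scale \code{"raw"} minimizes residuals on the signal scale;
#'   \code{"log"} on the natural-log scale (requires positive data).
#'   Reported RMSE is always on the raw scale.
#' @param ftol optimizer cost tolerance.
#' @param maxIter iteration cap per start.
#' @param pin named numeric vector/list of parameters to hold fixed at the
#'   given values (e.g. an initial condition read off the data).
#' @return list of class \code{"fitOptions"}.
#' @export
fitOptions <- function(nStarts = 20L, seed = 1L, scale = c("raw", "log"),
                       ftol = 1e-10, maxIter = 1000L, pin = list()) {
    scale <- match.arg(scale)
    stopifnot(nStarts >= 1L, is.finite(seed))
    structure(list(nStarts = as.integer(nStarts), seed = as.integer(seed),
                   scale = scale, ftol = ftol, maxIter = as.integer(maxIter),
                   pin = unlist(pin)),
              class = "fitOptions")
}

#' Read fit configuration (options and parameter ranges) from YAML or JSON
#'
#' Accepted top-level keys: \code{options} (any \code{\link{fitOptions}}
#' argument) and \code{ranges} (per-model parameter blocks in the same
#' schema as the packaged \code{model_ranges.yaml}).
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return list with elements \code{options} (a \code{fitOptions} object or
#'   \code{NULL}) and \code{ranges} (named list of spec data.frames).
#' @export
readFitConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    opts <- NULL
    if (!is.null(cfg$options))
        opts <- do.call(fitOptions, cfg$options)
    ranges <- list()
    if (!is.null(cfg$ranges))
        ranges <- lapply(cfg$ranges, function(m) {
            blk <- if (!is.null(m$parameters)) m$parameters else m
            do.call(rbind, lapply(names(blk), function(nm) {
                p <- blk[[nm]]
                parameterSpec(nm, p$lower, p$upper, init = isTRUE(p$init),
                              guess = if (is.null(p$guess)) NA_real_ else p$guess)
            }))
        })
    list(options = opts, ranges = ranges)
}

.asSeries <- function(data) {
    if (is(data, "Measurement"))
        return(data.frame(time = data@time, value = data@value))
    df <- as.data.frame(data)
    if (!all(c("time", "value") %in% names(df)))
        stop("data must be a Measurement or a data.frame with columns time, value")
    if (any(!is.finite(df$time)) || any(!is.finite(df$value)))
        stop("non-finite values in data are rejected, never silently dropped")
    df[c("time", "value")]
}

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Core driver: pooled box-constrained least squares over >= 1 series.
.fitCore <- function(def, seriesList, specs, options) {
    spec <- specs
    validObject(modelDefinition(def@modelId, def@displayName,
                                def@equationText, spec, def@simulateFn))
    n <- sum(vapply(seriesList, nrow, 0L))
    obs <- unlist(lapply(seriesList, `[[`, "value"))
    if (stats::sd(obs) == 0)
        stop("degenerate data: constant values carry no curve information")
    if (options$scale == "log" && any(obs <= 0))
        stop("log-scale fitting requires strictly positive values")

    pin <- options$pin
    if (length(pin)) {
        unknown <- setdiff(names(pin), spec$name)
        if (length(unknown))
            stop("pinned parameters not in spec: ",
                 paste(unknown, collapse = ", "))
        row <- match(names(pin), spec$name)
        out <- pin < spec$lower[row] | pin > spec$upper[row]
        if (any(out))
            stop("pinned value outside search range for: ",
                 paste(names(pin)[out], collapse = ", "))
    }
    free <- spec[!spec$name %in% names(pin), , drop = FALSE]
    nFree <- nrow(free)
    if (n < nFree)
        stop(sprintf("degenerate data: %d points cannot identify %d free parameters",
                     n, nFree))

    ## parameters bounded away from zero whose range spans at least a decade
    ## (rates, scale factors) are searched and optimized on the log scale:
    ## log-uniform starts cover the decades evenly and log-space steps follow
    ## curved parameter valleys (e.g. rate-coefficient/exponent trade-offs)
    logp <- free$lower > 0 & free$upper / free$lower >= 10
    toOpt <- function(x) { x[logp] <- log(x[logp]); x }
    fromOpt <- function(x) { x[logp] <- exp(x[logp]); x }
    optLower <- toOpt(free$lower)
    optUpper <- toOpt(free$upper)

    ## default start: configured guess, else the midpoint of the search box
    ## in optimization space (geometric mean for log-scale parameters);
    ## initial-condition parameters start at the first observed value
    guess <- fromOpt((optLower + optUpper) / 2)
    guess[!is.na(free$guess)] <- free$guess[!is.na(free$guess)]
    firstVal <- seriesList[[1]]$value[1]
    ic <- free$init & firstVal >= free$lower & firstVal <= free$upper
    guess[ic] <- firstVal
    names(guess) <- free$name

    fullParams <- function(theta) {
        p <- c(theta, pin)
        p[spec$name]
    }
    residOne <- function(p, s) {
        pred <- def@simulateFn(p, s$time)
        if (options$scale == "log") log(s$value) - log(pmax(pred, 1e-300))
        else s$value - pred
    }
    residFun <- function(thetaOpt) {
        p <- fullParams(fromOpt(thetaOpt))
        r <- try(unlist(lapply(seriesList, function(s) residOne(p, s))),
                 silent = TRUE)
        if (inherits(r, "try-error") || length(r) != n || any(!is.finite(r)))
            rep(1e8, n)
        else r
    }

    nStarts <- options$nStarts
    starts <- matrix(rep(toOpt(guess), each = nStarts), nrow = nStarts,
                     dimnames = list(NULL, free$name))
    if (nStarts > 1L) {
        L <- .withSeed(options$seed, lhs::randomLHS(nStarts - 1L, nFree))
        starts[-1L, ] <- sweep(sweep(L, 2, optUpper - optLower, "*"),
                               2, optLower, "+")
    }

    best <- NULL
    ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol,
                                       ptol = min(options$ftol, 1e-12),
                                       maxiter = options$maxIter)
    for (i in seq_len(nStarts)) {
        fit <- try(minpack.lm::nls.lm(par = starts[i, ], lower = optLower,
                                      upper = optUpper, fn = residFun,
                                      control = ctrl),
                   silent = TRUE)
        if (inherits(fit, "try-error")) next
        theta <- pmin(pmax(unlist(fit$par), optLower), optUpper)
        cost <- sum(residFun(theta)^2)
        ok <- fit$info %in% c(1L, 2L, 3L, 4L, 6L, 7L)
        if (is.null(best) || cost < best$cost) {
            best <- list(theta = theta, cost = cost, ok = ok)
        }
    }
    if (is.null(best))
        stop("estimation failed: no optimizer start produced a result")

    ## polish the winner at machine-level tolerances with a wider
    ## finite-difference step (the default sqrt(eps) step limits the
    ## jacobian, and hence linear fits, to ~1e-9 of the OLS optimum)
    pol <- try(minpack.lm::nls.lm(par = best$theta, lower = optLower,
                                  upper = optUpper, fn = residFun,
                                  control = minpack.lm::nls.lm.control(
                                      ftol = 1e-15, ptol = 1e-15,
                                      epsfcn = 1e-8, maxiter = 200)),
               silent = TRUE)
    if (!inherits(pol, "try-error")) {
        theta <- pmin(pmax(unlist(pol$par), optLower), optUpper)
        cost <- sum(residFun(theta)^2)
        if (cost <= best$cost * (1 + 1e-10) + 1e-300) best$theta <- theta
    }

    thetaFull <- fullParams(pmin(pmax(fromOpt(best$theta), free$lower),
                                 free$upper))
    fittedT <- unlist(lapply(seriesList, `[[`, "time"))
    fittedV <- unlist(lapply(seriesList,
                             function(s) def@simulateFn(thetaFull, s$time)))
    new("GrowthFit", modelId = def@modelId, estimates = thetaFull,
        rmse = rmse(obs, fittedV), nPoints = as.integer(n),
        converged = best$ok, nStartsUsed = as.integer(nStarts),
        fittedTimes = as.numeric(fittedT), fittedValues = as.numeric(fittedV))
}

.resolveSpecs <- function(def, specs) {
    if (is.null(specs)) def@parameters else specs
}

## exact QR least squares for polynomial models; defers to the generic
## box-constrained estimator whenever the closed form cannot honour the
## requested constraints (pins, log scale, active bounds, rank deficiency)
.linearPolyFit <- function(def, degree, data, specs, options) {
    s <- .asSeries(data)
    coefNames <- paste0("c", 0:degree)
    generic <- function() .fitCore(def, list(s), specs, options)
    if (options$scale != "raw" || length(options$pin) ||
        !setequal(specs$name, coefNames))
        return(generic())
    if (stats::sd(s$value) == 0)
        stop("degenerate data: constant values carry no curve information")
    if (nrow(s) < length(coefNames))
        stop(sprintf("degenerate data: %d points cannot identify %d free parameters",
                     nrow(s), length(coefNames)))
    X <- outer(s$time, 0:degree, "^")
    beta <- try(qr.coef(qr(X), s$value), silent = TRUE)
    if (inherits(beta, "try-error") || any(is.na(beta))) return(generic())
    names(beta) <- coefNames
    row <- match(coefNames, specs$name)
    if (any(beta < specs$lower[row]) || any(beta > specs$upper[row]))
        return(generic())
    est <- beta[specs$name]
    fitted <- as.numeric(X %*% beta)
    new("GrowthFit", modelId = def@modelId, estimates = est,
        rmse = rmse(s$value, fitted), nPoints = nrow(s),
        converged = TRUE, nStartsUsed = 1L,
        fittedTimes = s$time, fittedValues = fitted)
}

#' Fit a registered model to one time series
#'
#' Minimizes the sum of squared residuals between the data and the model
#' curve over the box defined by the parameter specs, using
#' Levenberg-Marquardt with box constraints (\code{minpack.lm::nls.lm})
#' from a Latin-hypercube multi-start.  All starts in the budget are run
#' and the lowest-cost solution wins (ties broken by start order); the
#' result is flagged non-converged when the winning start did not report
#' optimizer success.
#'
#' Models registered with their own \code{estimateFn} are dispatched to it
#' instead, fulfilling the plugin contract.
#'
#' @param modelId registered model id.
#' @param data a \linkS4class{Measurement} or data.frame with columns
#'   \code{time} and \code{value}.
#' @param specs parameter-spec data.frame; defaults to the model's
#'   registered ranges.
#' @param options a \code{\link{fitOptions}} object.
#' @param registry model registry (default built-ins).
#' @return a \linkS4class{GrowthFit}.  Its \code{rmse} always equals
#'   \code{rmse(observed, fittedCurve(fit)$value)} on the raw signal scale.
#' @examples
#' tm <- seq(0, 48, 0.5)
#' dat <- data.frame(time = tm,
#'                   value = gompertzValue(tm, A = 1, muMax = 0.2, lambda = 5))
#' fit <- fitModel("gompertz", dat, options = fitOptions(nStarts = 5))
#' estimates(fit)
#' @export
fitModel <- function(modelId, data, specs = NULL, options = fitOptions(),
                     registry = defaultRegistry()) {
    def <- getModel(registry, modelId)
    specs <- .resolveSpecs(def, specs)
    if (!is.null(def@estimateFn))
        return(def@estimateFn(.asSeries(data), specs, options))
    .fitCore(def, list(.asSeries(data)), specs, options)
}

#' Fit one parameter vector to several replicate series simultaneously
#'
#' Pooled least squares: a single parameter vector minimizes the summed
#' squared residuals over the concatenation of all datasets' points, so
#' replicates are weighted by their point counts.  Useful for finding an
#' average model over replicates of the same experimental condition.
#' With a single dataset this is identical to \code{\link{fitModel}}.
#'
#' @param modelId registered model id.
#' @param datasets list of \linkS4class{Measurement}s or data.frames.
#' @inheritParams fitModel
#' @return a \linkS4class{GrowthFit}; \code{rmse} is computed over the
#'   pooled residuals and the fitted curve is the concatenation over
#'   datasets.
#' @export
fitAggregate <- function(modelId, datasets, specs = NULL,
                         options = fitOptions(), registry = defaultRegistry()) {
    if (!is.list(datasets) || length(datasets) == 0L ||
        (is.data.frame(datasets)))
        stop("datasets must be a nonempty list of series")
    def <- getModel(registry, modelId)
    .fitCore(def, lapply(datasets, .asSeries), .resolveSpecs(def, specs),
             options)
}

#' Manual regression: linear fit of log-signal within a time window
#'
#' The traditional manual estimate of the specific growth rate: ordinary
#' least squares of \code{ln(value)} on \code{time}, restricted to a
#' user-chosen window covering the exponential phase.
#'
#' @param data a \linkS4class{Measurement} or data.frame (time, value).
#' @param window numeric \code{c(tStart, tEnd)}, inclusive.
#' @return a \linkS4class{LogLinearFit}; the slope is the specific growth
#'   rate on the natural-log scale.
#' @export
manualLogRegression <- function(data, window) {
    s <- .asSeries(data)
    stopifnot(length(window) == 2L, window[1] <= window[2])
    keep <- s$time >= window[1] & s$time <= window[2]
    sub <- s[keep, , drop = FALSE]
    if (nrow(sub) < 2L)
        stop("need at least 2 points inside the window")
    bad <- sub$value <= 0
    if (any(bad))
        stop("nonpositive values inside the window at t = ",
             paste(signif(sub$time[bad], 6), collapse = ", "),
             "; log scale requires positive signal")
    fit <- stats::lm(log(value) ~ time, data = sub)
    co <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((log(sub$value) - mean(log(sub$value)))^2)
    r2 <- if (tss <= .Machine$double.eps * max(1, rss)) 1 else
        max(0, min(1, 1 - rss / tss))
    new("LogLinearFit", slope = unname(co[["time"]]),
        intercept = unname(co[["(Intercept)"]]),
        window = as.numeric(window), rSquared = r2,
        nPoints = nrow(sub))
}

#' Fit several candidate models to the same series and rank them by RMSE
#'
#' Each candidate is fitted via \code{\link{fitModel}} with the same
#' options (hence the same seed, making the table invariant to candidate
#' order).  Converged fits are ranked first by ascending RMSE;
#' non-converged fits follow, also by RMSE; candidates whose fit raised an
#' error are retained last with the message recorded.
#'
#' @param data a \linkS4class{Measurement} or data.frame (time, value).
#' @param candidates character vector of model ids, or a list whose
#'   elements are model ids or \code{list(modelId =, specs =)} pairs.
#' @inheritParams fitModel
#' @return data.frame with columns \code{modelId}, \code{rmse},
#'   \code{converged}, \code{nPoints}, \code{error} and a list-column
#'   \code{estimates}; the full \linkS4class{GrowthFit} objects are in
#'   \code{attr(, "fits")} keyed by model id.
#' @export
compareModels <- function(data, candidates, options = fitOptions(),
                          registry = defaultRegistry()) {
    if (length(candidates) == 0L) stop("need at least one candidate model")
    if (is.character(candidates)) candidates <- as.list(candidates)
    rows <- list(); fits <- list()
    for (cand in candidates) {
        if (is.character(cand)) cand <- list(modelId = cand, specs = NULL)
        id <- cand$modelId
        res <- try(fitModel(id, data, specs = cand$specs, options = options,
                            registry = registry), silent = TRUE)
        if (inherits(res, "try-error")) {
            rows[[id]] <- data.frame(modelId = id, rmse = NA_real_,
                                     converged = FALSE, nPoints = NA_integer_,
                                     error = attr(res, "condition")$message,
                                     stringsAsFactors = FALSE)
            rows[[id]]$estimates <- I(list(NULL))
        } else {
            fits[[id]] <- res
            rows[[id]] <- data.frame(modelId = id, rmse = fitRMSE(res),
                                     converged = isConverged(res),
                                     nPoints = res@nPoints, error = "",
                                     stringsAsFactors = FALSE)
            rows[[id]]$estimates <- I(list(estimates(res)))
        }
    }
    tbl <- do.call(rbind, rows)
    failed <- !is.na(tbl$rmse)
    ord <- order(!failed, !tbl$converged, tbl$rmse, seq_len(nrow(tbl)))
    tbl <- tbl[ord, , drop = FALSE]
    rownames(tbl) <- NULL
    attr(tbl, "fits") <- fits
    tbl
}
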