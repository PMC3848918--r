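## Seeded synthetic-data generator: noisy growth curves with known ground
## truth for every built-in model.  All test and example inputs are produced
## here; no external dataset is required.

#' Describe a synthetic dataset to generate
#'
#' @param modelId registered model id for the ground truth.
#' @param truth named numeric vector of true parameter values.
#' @param tStart,tStop,tStep regular time grid specification (tStep > 0).
#' @param noise \code{"none"}, \code{"additive_gaussian"} (value + N(0,
#'   sigma^2)) or \code{"multiplicative_lognormal"} (value * exp(N(0,
#'   sigma^2)), positivity-preserving for log-scale fitting).
#' @param sigma noise scale (>= 0).
#' @param nReplicates number of replicate series (>= 1), each with
#'   independent noise draws.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class \code{"generationSpec"}.
#' @export
generationSpec <- function(modelId, truth, tStart, tStop, tStep,
                           noise = c("none", "additive_gaussian",
                                     "multiplicative_lognormal"),
                           sigma = 0, nReplicates = 1L, seed = 1L) {
    noise <- match.arg(noise)
    if (tStep <= 0) stop("tStep must be > 0")
    if (sigma < 0) stop("sigma must be >= 0")
    if (nReplicates < 1L) stop("nReplicates must be >= 1")
    structure(list(modelId = modelId, truth = unlist(truth),
                   tStart = tStart, tStop = tStop, tStep = tStep,
                   noise = noise, sigma = sigma,
                   nReplicates = as.integer(nReplicates),
                   seed = as.integer(seed)),
              class = "generationSpec")
}

#' Generate noisy replicate curves with known ground truth
#'
#' Simulates the true curve on the grid, then applies the configured noise
#' to the values (never to the times) independently per replicate.  Each
#' replicate draws from its own RNG substream whose seed is derived
#' deterministically from the spec seed, so regeneration is exact.
#'
#' @param spec a \code{\link{generationSpec}}.
#' @param registry model registry (default built-ins).
#' @return list with \code{measurements} (list of
#'   \linkS4class{Measurement}s named \code{<modelId>_rep<k>}) and
#'   \code{manifest} (truth, grid, noise, seed and per-replicate seeds).
#' @export
generateCurve <- function(spec, registry = defaultRegistry()) {
    stopifnot(inherits(spec, "generationSpec"))
    times <- seq(spec$tStart, spec$tStop, by = spec$tStep)
    truthCurve <- simulateModel(registry, spec$modelId, spec$truth, times)
    repSeeds <- .withSeed(spec$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     spec$nReplicates))
    meas <- vector("list", spec$nReplicates)
    for (k in seq_len(spec$nReplicates)) {
        vals <- truthCurve$value
        if (spec$noise == "additive_gaussian")
            vals <- .withSeed(repSeeds[k],
                              vals + stats::rnorm(length(vals), 0, spec$sigma))
        else if (spec$noise == "multiplicative_lognormal")
            vals <- .withSeed(repSeeds[k],
                              vals * exp(stats::rnorm(length(vals), 0, spec$sigma)))
        meas[[k]] <- Measurement(sprintf("%s_rep%d", spec$modelId, k),
                                 times, vals)
    }
    list(measurements = meas,
         manifest = list(modelId = spec$modelId,
                         truth = as.list(spec$truth),
                         grid = list(tStart = spec$tStart, tStop = spec$tStop,
                                     tStep = spec$tStep),
                         noise = spec$noise, sigma = spec$sigma,
                         nReplicates = spec$nReplicates, seed = spec$seed,
                         replicateSeeds = repSeeds))
}

## study conditions for the default benchmark suite, one per dynamic model
.suiteSpecs <- function(seed) {
    mk <- function(id, truth, t0, t1, dt, sigma)
        generationSpec(id, truth, t0, t1, dt, noise = "additive_gaussian",
                       sigma = sigma, nReplicates = 1L,
                       seed = (seed * 131L + which(.suiteIds == id)) %%
                           .Machine$integer.max)
    list(
        mk("gompertz", c(A = 1, muMax = 0.2, lambda = 5), 0, 48, 0.5, 0.02),
        mk("logistic", c(A = 1, muMax = 0.25, lambda = 4), 0, 48, 0.5, 0.02),
        mk("richards", c(A = 1, muMax = 0.3, lambda = 2, v = 0.5),
           0, 48, 0.5, 0.02),
        mk("baranyi", c(y0 = 0, yMax = 9, muMax = 0.8, vRate = 0.5,
                        h0 = 2, mCurv = 1), 0, 24, 0.25, 0.05),
        mk("baranyi_classic", c(y0 = 0, yMax = 9, muMax = 0.8, vRate = 0.5,
                                h0 = 2, mCurv = 1), 0, 24, 0.25, 0.05),
        mk("h3", c(M = 7.547, delta = 5.103e-9, gamma = 4.630, theta = 0.004,
                   P0 = 0.05, t0 = 0), 0, 60, 1, 0.05),
        mk("lcf", c(alpha = 0.2, delta = 0.05, lambdaDepth = 1, r0 = 0.5),
           0, 40, 1, 0.02),
        mk("exp_decay", c(y0 = 2, k = 0.3, offset = 0.2), 0, 20, 0.5, 0.02)
    )
}

.suiteIds <- c("gompertz", "logistic", "richards", "baranyi",
               "baranyi_classic", "h3", "lcf", "exp_decay")

#' Write the default benchmark suite to disk
#'
#' One noisy CSV per built-in dynamic model (8 files) plus a JSON manifest
#' recording ground truth, grids, noise levels and seeds.  Regenerating
#' with the same seed reproduces the files byte for byte.
#'
#' @param root destination directory (created if absent).
#' @param seed master seed from which each dataset's seed is derived.
#' @param registry model registry (default built-ins).
#' @return data.frame manifest with columns \code{modelId}, \code{file}
#'   and \code{sigma}; the JSON manifest is at \code{root/manifest.json}.
#' @export
makeBenchmarkSuite <- function(root, seed = 1L, registry = defaultRegistry()) {
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    specs <- .suiteSpecs(as.integer(seed))
    entries <- lapply(specs, function(sp) {
        gen <- generateCurve(sp, registry)
        file <- paste0(sp$modelId, ".csv")
        exportMeasurementCSV(gen$measurements[[1]], file.path(root, file))
        c(gen$manifest, list(file = file))
    })
    .writeJSON(list(seed = as.integer(seed), datasets = entries),
               file.path(root, "manifest.json"))
    data.frame(modelId = vapply(entries, `[[`, "", "modelId"),
               file = vapply(entries, `[[`, "", "file"),
               sigma = vapply(entries, `[[`, 0, "sigma"),
               stringsAsFactors = FALSE)
}
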