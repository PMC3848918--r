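## Hierarchical plain-file data store: projects > experiments > measurements,
## with CSV as the measurement interchange format and JSON for metadata and
## attached fit results.  Diffable, serverless replacement for a database.

#' Construct a Measurement
#'
#' @param measurementId identifier ([A-Za-z0-9._-]).
#' @param name display name (defaults to the id).
#' @param time,value numeric vectors; rows are sorted by time on input.
#' @param extra optional third numeric dimension (stored, never modeled).
#' @param annotation optional per-row free text (stored, never modeled).
#' @return a \linkS4class{Measurement}.
#' @export
Measurement <- function(measurementId, time, value, name = measurementId,
                        extra = NULL, annotation = NULL) {
    ord <- order(time)
    if (anyDuplicated(time))
        stop("duplicate time points within a measurement; replicates belong in separate measurements")
    new("Measurement", measurementId = measurementId, name = name,
        time = as.numeric(time)[ord], value = as.numeric(value)[ord],
        extra = if (is.null(extra)) numeric(0) else as.numeric(extra)[ord],
        annotation = if (is.null(annotation)) character(0)
                     else as.character(annotation)[ord])
}

#' Construct an Experiment
#'
#' @param experimentId identifier.
#' @param name display name.
#' @param measurements list of \linkS4class{Measurement}s.
#' @return an \linkS4class{Experiment}.
#' @export
Experiment <- function(experimentId, name = experimentId,
                       measurements = list()) {
    new("Experiment", experimentId = experimentId, name = name,
        measurements = measurements, fits = list())
}

#' Construct a Project
#'
#' @param projectId identifier.
#' @param name display name.
#' @param description free text.
#' @param experiments list of \linkS4class{Experiment}s.
#' @return a \linkS4class{Project}.
#' @export
Project <- function(projectId, name = projectId, description = "",
                    experiments = list()) {
    new("Project", projectId = projectId, name = name,
        description = description, experiments = experiments)
}

#' Construct an in-memory repository
#'
#' @param projects list of \linkS4class{Project}s.
#' @return a \linkS4class{GrowthRepository}.
#' @export
GrowthRepository <- function(projects = list()) {
    new("GrowthRepository", projects = projects, root = "")
}

#' Attach a fit result to an experiment
#'
#' @param experiment an \linkS4class{Experiment}.
#' @param measurementIds ids of the measurement(s) the fit used.
#' @param fit a \linkS4class{GrowthFit}.
#' @return the updated experiment.
#' @export
attachFit <- function(experiment, measurementIds, fit) {
    stopifnot(is(experiment, "Experiment"), is(fit, "GrowthFit"))
    have <- vapply(experiment@measurements, function(m) m@measurementId, "")
    miss <- setdiff(measurementIds, have)
    if (length(miss))
        stop("unknown measurement id(s): ", paste(miss, collapse = ", "))
    experiment@fits[[length(experiment@fits) + 1L]] <-
        list(measurements = as.character(measurementIds),
             modelId = modelId(fit), fit = fit)
    experiment
}

## canonical float formatting: shortest round-trip representation
.fmtNum <- function(x) {
    vapply(x, function(v) {
        s <- sprintf("%.15g", v)
        if (as.numeric(s) == v) s else sprintf("%.17g", v)
    }, "")
}

.splitLine <- function(line, delim) strsplit(line, delim, fixed = TRUE)[[1]]

.detectDelim <- function(lines) {
    for (d in c(",", ";", "\t")) {
        counts <- vapply(lines, function(l) length(.splitLine(l, d)), 0L)
        if (all(counts >= 2L)) return(d)
    }
    stop("could not detect a delimiter (tried ',', ';', tab) giving >= 2 columns on every row")
}

.numOrNA <- function(x) suppressWarnings(as.numeric(x))

#' Import a measurement from a delimited text file
#'
#' Layout: first column time, second column value, optional third numeric
#' column as the extra dimension, optional trailing text as a row
#' annotation.  The delimiter is auto-detected among comma, semicolon and
#' tab; a single header line is auto-detected (non-numeric first two
#' fields) and skipped.  Rows are sorted by ascending time with value
#' pairing preserved; the decimal separator is ".".
#'
#' @param path file to read.
#' @param measurementId id for the new measurement (default: file stem).
#' @param name display name (default: the id).
#' @return a \linkS4class{Measurement}.
#' @export
importMeasurementCSV <- function(path, measurementId = NULL, name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(measurementId))
        measurementId <- sub("\\.[^.]*$", "", basename(path))
    if (is.null(name)) name <- measurementId
    lines <- readLines(path, warn = FALSE)
    blank <- !nzchar(trimws(lines))
    lineNo <- which(!blank)
    lines <- lines[!blank]
    if (length(lines) == 0L) stop("empty file: ", path)
    delim <- .detectDelim(lines)
    rows <- lapply(lines, .splitLine, delim = delim)
    first <- trimws(rows[[1]])
    hasHeader <- is.na(.numOrNA(first[1])) || is.na(.numOrNA(first[2]))
    if (hasHeader) { rows <- rows[-1]; lineNo <- lineNo[-1] }
    if (length(rows) == 0L) stop("no data rows in ", path)
    tm <- vl <- ex <- rep(NA_real_, length(rows))
    an <- rep(NA_character_, length(rows))
    for (i in seq_along(rows)) {
        f <- trimws(rows[[i]])
        if (length(f) < 2L)
            stop(sprintf("line %d: expected at least 2 columns", lineNo[i]))
        tm[i] <- .numOrNA(f[1]); vl[i] <- .numOrNA(f[2])
        if (is.na(tm[i]) || is.na(vl[i]))
            stop(sprintf("line %d: could not parse time/value from '%s'",
                         lineNo[i], lines[if (hasHeader) i + 1L else i]))
        if (length(f) >= 3L && nzchar(f[3])) {
            third <- .numOrNA(f[3])
            if (!is.na(third)) ex[i] <- third
            else an[i] <- f[3]
        }
        if (length(f) >= 4L && nzchar(f[4]))
            an[i] <- if (is.na(an[i])) f[4] else paste(an[i], f[4], sep = " ")
    }
    Measurement(measurementId, tm, vl, name = name,
                extra = if (all(is.na(ex))) NULL else ex,
                annotation = if (all(is.na(an))) NULL
                             else ifelse(is.na(an), "", an))
}

#' Write a measurement to CSV
#'
#' Inverse of \code{\link{importMeasurementCSV}}: comma-delimited with a
#' header line, numeric fields in shortest round-trip formatting so that
#' import(export(m)) reproduces the numbers exactly.
#'
#' @param measurement a \linkS4class{Measurement}.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
exportMeasurementCSV <- function(measurement, path) {
    m <- measurement
    cols <- list(time = .fmtNum(m@time), value = .fmtNum(m@value))
    if (length(m@extra)) cols$extra <- .fmtNum(m@extra)
    if (length(m@annotation)) cols$annotation <- m@annotation
    header <- paste(names(cols), collapse = ",")
    body <- do.call(paste, c(cols, sep = ","))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Export an experiment's fit results for one model as CSV
#'
#' One row per attached fit of the given model: the measurement id(s) the
#' fit used, each parameter estimate in declared order, the RMSE, the
#' convergence flag and the number of points.  Numeric fields use shortest
#' round-trip formatting so re-import reproduces them to full precision.
#'
#' @param experiment an \linkS4class{Experiment}.
#' @param modelId model whose fits to export.
#' @param path destination file.
#' @param registry used only to name the parameter columns when the
#'   experiment holds no fits for this model.
#' @return number of data rows written.
#' @export
exportResultsCSV <- function(experiment, modelId, path,
                             registry = defaultRegistry()) {
    hits <- Filter(function(f) f$modelId == modelId, experiment@fits)
    paramNames <- if (length(hits)) names(estimates(hits[[1]]$fit))
    else if (modelId %in% names(registry@models))
        getModel(registry, modelId)@parameters$name
    else character(0)
    header <- paste(c("measurement", paramNames, "rmse", "converged",
                      "n_points"), collapse = ",")
    lines <- vapply(hits, function(f) {
        est <- estimates(f$fit)
        paste(c(paste(f$measurements, collapse = ";"),
                .fmtNum(unname(est[paramNames])),
                .fmtNum(fitRMSE(f$fit)),
                tolower(as.character(isConverged(f$fit))),
                f$fit@nPoints), collapse = ",")
    }, "")
    con <- file(path, open = "wt")
    ok <- try(writeLines(c(header, lines), con), silent = TRUE)
    close(con)
    if (inherits(ok, "try-error")) stop("could not write ", path)
    length(hits)
}

.fitToList <- function(entry) {
    f <- entry$fit
    list(measurements = as.list(entry$measurements), modelId = entry$modelId,
         estimates = as.list(f@estimates), rmse = f@rmse,
         nPoints = f@nPoints, converged = f@converged,
         nStartsUsed = f@nStartsUsed, fittedTimes = f@fittedTimes,
         fittedValues = f@fittedValues)
}

.fitFromList <- function(x) {
    est <- unlist(x$estimates)
    list(measurements = unlist(x$measurements), modelId = x$modelId,
         fit = new("GrowthFit", modelId = x$modelId, estimates = est,
                   rmse = as.numeric(x$rmse), nPoints = as.integer(x$nPoints),
                   converged = as.logical(x$converged),
                   nStartsUsed = as.integer(x$nStartsUsed),
                   fittedTimes = as.numeric(unlist(x$fittedTimes)),
                   fittedValues = as.numeric(unlist(x$fittedValues))))
}

## I(17): 17 significant digits, the shortest count that round-trips doubles
.writeJSON <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")

#' Persist a repository as a directory tree
#'
#' Layout: \code{root/repository.json} lists projects; each project gets
#' \code{projects/<id>/project.json}; each experiment
#' \code{experiments/<id>/experiment.json} plus one CSV per measurement
#' under \code{measurements/}.  Fit results are embedded in the experiment
#' JSON at full numeric precision.  \code{load(save(x))} reproduces every
#' stored field and ordering.
#'
#' @param repository a \linkS4class{GrowthRepository}.
#' @param root destination directory (created if absent).
#' @return the root, invisibly.
#' @export
saveRepository <- function(repository, root) {
    stopifnot(is(repository, "GrowthRepository"))
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    .writeJSON(list(projects = lapply(repository@projects,
                                      function(p) p@projectId)),
               file.path(root, "repository.json"))
    for (p in repository@projects) {
        pdir <- file.path(root, "projects", p@projectId)
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        .writeJSON(list(projectId = p@projectId, name = p@name,
                        description = p@description,
                        experiments = lapply(p@experiments,
                                             function(e) e@experimentId)),
                   file.path(pdir, "project.json"))
        for (e in p@experiments) {
            edir <- file.path(pdir, "experiments", e@experimentId)
            mdir <- file.path(edir, "measurements")
            dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
            minfo <- lapply(e@measurements, function(m) {
                file <- paste0(m@measurementId, ".csv")
                exportMeasurementCSV(m, file.path(mdir, file))
                list(measurementId = m@measurementId, name = m@name,
                     file = file)
            })
            .writeJSON(list(experimentId = e@experimentId, name = e@name,
                            measurements = minfo,
                            fits = lapply(e@fits, .fitToList)),
                       file.path(edir, "experiment.json"))
        }
    }
    invisible(root)
}

.readJSON <- function(path) {
    if (!file.exists(path)) stop("missing repository file: ", path)
    out <- try(jsonlite::read_json(path), silent = TRUE)
    if (inherits(out, "try-error"))
        stop("corrupt repository file: ", path)
    out
}

#' Load a repository saved by \code{\link{saveRepository}}
#'
#' @param root directory written by \code{\link{saveRepository}}.
#' @return a \linkS4class{GrowthRepository} with \code{root} recorded.
#' @export
loadRepository <- function(root) {
    meta <- .readJSON(file.path(root, "repository.json"))
    projects <- lapply(meta$projects, function(pid) {
        pdir <- file.path(root, "projects", pid)
        pj <- .readJSON(file.path(pdir, "project.json"))
        exps <- lapply(pj$experiments, function(eid) {
            edir <- file.path(pdir, "experiments", eid)
            ej <- .readJSON(file.path(edir, "experiment.json"))
            meas <- lapply(ej$measurements, function(mi) {
                mpath <- file.path(edir, "measurements", mi$file)
                if (!file.exists(mpath))
                    stop("missing measurement file: ", mpath)
                importMeasurementCSV(mpath, measurementId = mi$measurementId,
                                     name = mi$name)
            })
            e <- Experiment(ej$experimentId, name = ej$name,
                            measurements = meas)
            e@fits <- lapply(ej$fits, .fitFromList)
            e
        })
        Project(pj$projectId, name = pj$name,
                description = if (is.null(pj$description)) "" else pj$description,
                experiments = exps)
    })
    repo <- GrowthRepository(projects)
    repo@root <- root
    repo
}
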