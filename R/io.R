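## One CSV dialect everywhere: long format with header
## time_min,series,value,units,normalization  (UTF-8, "." decimal).

.TC_HEADER <- c("time_min", "series", "value", "units", "normalization")

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write a time course to CSV
#'
#' Deterministic output: fixed column order, rows sorted by series then
#' time, floats at 12 significant digits. Writing the same time course
#' twice yields byte-identical files.
#'
#' @param tc a `dox_timecourse`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "dox_timecourse"))
  long <- as.data.frame(tc)
  lines <- paste(.TC_HEADER, collapse = ",")
  if (nrow(long))
    lines <- c(lines, paste(.fmt_num(long$time_min), long$series,
                            .fmt_num(long$value), long$units,
                            long$normalization, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a time course from CSV
#'
#' Strict parser for the package's CSV dialect; malformed rows are rejected
#' with their line number, rows may appear in any order (canonical sort is
#' applied), and the per-series grid must be strictly monotone after
#' sorting with every series on the same grid.
#'
#' @param path input file.
#' @return a `dox_timecourse`.
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !identical(strsplit(lines[1], ",")[[1]], .TC_HEADER))
    stop("line 1: malformed header (expected ",
         paste(.TC_HEADER, collapse = ","), ")")
  if (length(lines) == 1)
    return(dox_timecourse(numeric(0), data.frame()))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5)
      stop("line ", i + 1, ": expected 5 fields, got ", length(p))
    tv <- suppressWarnings(as.numeric(p[c(1, 3)]))
    if (anyNA(tv) || !all(is.finite(tv)))
      stop("line ", i + 1, ": non-numeric time or value")
    if (tv[1] < 0)
      stop("line ", i + 1, ": negative time")
  }
  df <- data.frame(time_min = as.numeric(vapply(parts, `[[`, "", 1)),
                   series = vapply(parts, `[[`, "", 2),
                   value = as.numeric(vapply(parts, `[[`, "", 3)),
                   units = vapply(parts, `[[`, "", 4),
                   normalization = vapply(parts, `[[`, "", 5))
  df <- df[order(df$series, df$time_min), , drop = FALSE]
  series <- unique(df$series)
  grid <- sort(unique(df$time_min))
  vals <- list(); units <- c(); norm <- c()
  for (s in series) {
    d <- df[df$series == s, , drop = FALSE]
    if (anyDuplicated(d$time_min))
      stop("series `", s, "`: duplicated time point (grid not strictly monotone)")
    if (!identical(d$time_min, grid))
      stop("series `", s, "` is not on the common time grid")
    vals[[s]] <- d$value
    units <- c(units, d$units[1]); norm <- c(norm, d$normalization[1])
  }
  dox_timecourse(grid, as.data.frame(vals, check.names = FALSE),
                 kind = "observable", units = units, normalization = norm)
}

#' Write a synthetic dataset to a directory
#'
#' One CSV per observable (replicates as `<name>:repK` series) plus a
#' sidecar `generating_parameters.json` recording the scenario, noise
#' settings and the exact generating parameter values for recovery tests.
#'
#' @param ds a `dox_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in names(ds$replicates)) {
    m <- ds$replicates[[j]]
    cols <- c(list(ds$mean[[j]]), lapply(seq_len(ncol(m)), function(k) m[, k]))
    names(cols) <- c(j, paste0(j, ":", colnames(m)))
    tc <- dox_timecourse(ds$t_grid, as.data.frame(cols, check.names = FALSE),
                         kind = "observable", units = "assay",
                         normalization = "raw")
    write_timecourse(tc, file.path(dir, paste0(j, ".csv")))
  }
  meta <- list(scenario = unclass(ds$scenario),
               noise = unclass(ds$noise),
               t_grid = ds$t_grid,
               generating_parameters = as.list(ds$truth),
               clipped = ds$clipped)
  jsonlite::write_json(meta, file.path(dir, "generating_parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `dox_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "generating_parameters.json"),
                              simplifyVector = TRUE)
  sc_fields <- meta$scenario
  if (!is.null(sc_fields$interventions) && !length(sc_fields$interventions))
    sc_fields$interventions <- list()
  scenario <- do.call(dox_scenario, c(sc_fields, list(strict = FALSE)))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  reps <- list(); means <- list()
  for (f in files) {
    tc <- read_timecourse(f)
    nm <- sub("\\.csv$", "", basename(f))
    repcols <- grep(":rep", names(tc$values), value = TRUE)
    reps[[nm]] <- as.matrix(tc$values[repcols])
    colnames(reps[[nm]]) <- sub(".*:", "", repcols)
    means[[nm]] <- tc$values[[nm]]
  }
  structure(list(scenario = scenario, t_grid = meta$t_grid,
                 replicates = reps, mean = means, clean = NULL,
                 truth = unlist(meta$generating_parameters),
                 noise = do.call(dox_noise, as.list(meta$noise)),
                 clipped = meta$clipped),
            class = "dox_dataset")
}

#' Write a run manifest
#'
#' Records command, arguments, seed, package version and the md5 of every
#' artifact file, so a run can be checked for byte-level reproducibility.
#' The manifest itself carries a timestamp and is not part of the
#' reproducible artifact set.
#'
#' @param path manifest path.
#' @param command subcommand name.
#' @param args named list of arguments.
#' @param seed integer seed (or NULL).
#' @param artifacts character vector of artifact files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args = list(), seed = NULL,
                           artifacts = character()) {
  hashes <- if (length(artifacts)) as.list(tools::md5sum(artifacts)) else
    list()
  m <- list(command = command, arguments = args, seed = seed,
            artifacts = hashes,
            tool_version = as.character(utils::packageVersion("doxcycle")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
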