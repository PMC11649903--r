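#' Time course of an observed species fraction
#'
#' A single chase trace: signal (dimensionless fraction or anisotropy
#' amplitude) versus time at one fixed nucleophile concentration.
#'
#' @param times Sampling times, min; strictly increasing.
#' @param signal Observed signal at each time; finite.
#' @param nu Nucleophile concentration during the chase, mM.
#' @param observable One of `"mono_band"`, `"anisotropy"`,
#'   `"modified_fraction"`.
#' @param label Free-text label.
#' @param replicate Replicate identifier.
#' @return A data frame of class `time_course` with columns `time_min`,
#'   `signal` and attributes `nu_mM`, `observable`, `label`, `replicate`.
#' @export
time_course <- function(times, signal, nu = 0,
                        observable = c("mono_band", "anisotropy",
                                       "modified_fraction"),
                        label = "", replicate = 1L) {
  observable <- match.arg(observable)
  if (!is.numeric(times) || !is.numeric(signal))
    stop("times and signal must be numeric")
  if (length(times) != length(signal))
    stop("times and signal must have equal length")
  if (length(times) < 1L) stop("empty time course")
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1L]
    stop(sprintf("times must be strictly increasing (violation at row %d)",
                 i + 1L))
  }
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0)
    stop("nu must be a non-negative scalar (mM)")
  structure(data.frame(time_min = times, signal = signal),
            nu_mM = nu, observable = observable, label = label,
            replicate = replicate,
            class = c("time_course", "data.frame"))
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course '%s' (%s, nu = %g mM, replicate %s, %d points)\n",
              attr(x, "label"), attr(x, "observable"), attr(x, "nu_mM"),
              as.character(attr(x, "replicate")), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Nucleophile concentration of a time course
#' @param course A [time_course].
#' @return Scalar mM.
#' @export
nu_of <- function(course) {
  stopifnot(inherits(course, "time_course"))
  attr(course, "nu_mM")
}

#' A set of paired chase time courses fitted jointly
#'
#' Groups time courses recorded at different nucleophile concentrations
#' for a global fit in which the kinetic parameters are shared while
#' each course keeps its own fixed `nu`.
#'
#' @param ... [time_course] objects, or a single list of them.
#' @param shared Character vector naming the parameters shared across
#'   courses (informational; the global fit always shares its free
#'   parameters). Defaults to all four.
#' @return An object of class `chase_design`.
#' @export
chase_design <- function(..., shared = c("E2L0", "k1", "k2", "k3")) {
  courses <- list(...)
  if (length(courses) == 1L && is.list(courses[[1L]]) &&
      !inherits(courses[[1L]], "time_course"))
    courses <- courses[[1L]]
  if (length(courses) == 0L) stop("a chase design needs at least one course")
  ok <- vapply(courses, inherits, logical(1L), what = "time_course")
  if (!all(ok)) stop("all elements must be time_course objects")
  bad <- setdiff(shared, c("E2L0", "k1", "k2", "k3"))
  if (length(bad)) stop("unknown shared parameter: ", bad[1L])
  structure(list(courses = courses, shared = shared),
            class = "chase_design")
}

#' @export
print.chase_design <- function(x, ...) {
  cat(sprintf("Chase design: %d course(s), shared = {%s}\n",
              length(x$courses), paste(x$shared, collapse = ", ")))
  for (co in x$courses)
    cat(sprintf("  nu = %6g mM  n = %3d  '%s'\n",
                nu_of(co), nrow(co), attr(co, "label")))
  invisible(x)
}

#' @export
length.chase_design <- function(x) length(x$courses)

# ---- CSV interface -------------------------------------------------------

.tc_cols <- c("time_min", "signal", "nu_mM", "observable", "label",
              "replicate")

#' Read chase time courses from CSV
#'
#' The schema is `time_min, signal, nu_mM, observable, label, replicate`
#' (header required, comma separated, '.' decimal, UTF-8). Rows are
#' grouped into one [time_course] per unique
#' (`label`, `nu_mM`, `observable`, `replicate`) combination.
#'
#' @param path Path to a CSV file.
#' @return A list of [time_course] objects.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(.tc_cols, names(df))
  if (length(missing_cols))
    stop("malformed time-course CSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty time-course CSV")
  for (col in c("time_min", "signal", "nu_mM")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data row %d",
                   col, bad[1L]))
    df[[col]] <- as.numeric(df[[col]])
  }
  key <- interaction(df$label, df$nu_mM, df$observable, df$replicate,
                     drop = TRUE)
  df$.row <- seq_len(nrow(df)) + 1L            # header is line 1
  lapply(split(df, key), function(g) {
    if (any(diff(g$time_min) <= 0)) {
      i <- which(diff(g$time_min) <= 0)[1L]
      stop(sprintf(
        "non-monotone times for course '%s' (nu = %g) at file row %d",
        g$label[1L], g$nu_mM[1L], g$.row[i + 1L]))
    }
    time_course(g$time_min, g$signal, nu = g$nu_mM[1L],
                observable = g$observable[1L], label = g$label[1L],
                replicate = g$replicate[1L])
  })
}

#' Write time courses to CSV
#'
#' Inverse of [read_timecourse_csv()]; writing then reading returns the
#' same courses.
#'
#' @param courses A [time_course], a list of them, or a [chase_design].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(courses, path) {
  if (inherits(courses, "chase_design")) courses <- courses$courses
  if (inherits(courses, "time_course")) courses <- list(courses)
  rows <- lapply(courses, function(co) {
    data.frame(time_min = co$time_min, signal = co$signal,
               nu_mM = nu_of(co), observable = attr(co, "observable"),
               label = attr(co, "label"),
               replicate = attr(co, "replicate"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
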