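#' Quantified band intensities for one gel lane
#'
#' @param lane_id Identifier.
#' @param intensities Named non-negative numeric vector; recognised band
#'   roles are `loaded`, `apo`, `unmodified`, `modified_total`,
#'   `background`.
#' @param treatment One of `"none"`, `"NaOH"`, `"no_ATP"`.
#' @param time_min Optional sampling time for time-course assembly.
#' @param condition Optional condition tag.
#' @return An object of class `lane_quant`.
#' @export
lane_quant <- function(lane_id, intensities,
                       treatment = c("none", "NaOH", "no_ATP"),
                       time_min = NA_real_, condition = "") {
  treatment <- match.arg(treatment)
  roles <- c("loaded", "apo", "unmodified", "modified_total", "background")
  if (is.null(names(intensities)) || any(!nzchar(names(intensities))))
    stop("intensities must be a fully named vector")
  bad <- setdiff(names(intensities), roles)
  if (length(bad)) stop("unknown band role: ", bad[1L])
  if (anyDuplicated(names(intensities)))
    stop("band roles must be unique per lane")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  structure(list(lane_id = lane_id, intensities = intensities,
                 treatment = treatment, time_min = time_min,
                 condition = condition),
            class = "lane_quant")
}

#' @export
print.lane_quant <- function(x, ...) {
  cat(sprintf("Lane '%s' (%s%s)\n", x$lane_id, x$treatment,
              if (is.finite(x$time_min))
                sprintf(", t = %g min", x$time_min) else ""))
  print(x$intensities)
  invisible(x)
}

.get_band <- function(lane, role) {
  if (!role %in% names(lane$intensities))
    stop(sprintf("lane '%s' lacks the '%s' band", lane$lane_id, role))
  unname(lane$intensities[[role]])
}

#' Fraction of E2 in the loaded (thioester) state
#'
#' `loaded / (loaded + apo)` for one lane; the discharge-assay
#' quantification that feeds the kinetic fits. Invariant under uniform
#' rescaling of the lane intensities.
#'
#' @param lane A [lane_quant] carrying `loaded` and `apo` bands.
#' @return Fraction in \[0, 1\].
#' @export
fraction_loaded <- function(lane) {
  stopifnot(inherits(lane, "lane_quant"))
  loaded <- .get_band(lane, "loaded")
  apo <- .get_band(lane, "apo")
  total <- loaded + apo
  if (total <= 0)
    stop(sprintf("lane '%s': loaded + apo intensity is zero", lane$lane_id))
  loaded / total
}

#' Background-corrected modified fraction of a substrate lane
#'
#' Subtracts a background intensity (an impurity band or the signal of a
#' no-ATP control) from the modified signal, clamping at zero from
#' below, then computes `modified / (modified + unmodified)`. Clamping
#' is reported via a warning and recorded in the `"clamped"` attribute.
#'
#' @param lane A [lane_quant] with `unmodified` and `modified_total`
#'   bands.
#' @param background Scalar background intensity, or a [lane_quant]
#'   (e.g. the no-ATP lane) whose `modified_total` band is used; lanes
#'   carrying their own `background` band use it when `background` is
#'   omitted.
#' @return Fraction in \[0, 1\] with attribute `clamped` (logical).
#' @export
fraction_modified <- function(lane, background = NULL) {
  stopifnot(inherits(lane, "lane_quant"))
  modified <- .get_band(lane, "modified_total")
  unmodified <- .get_band(lane, "unmodified")
  bg <- if (is.null(background)) {
    if ("background" %in% names(lane$intensities))
      .get_band(lane, "background") else 0
  } else if (inherits(background, "lane_quant")) {
    .get_band(background, "modified_total")
  } else {
    stopifnot(is.numeric(background), length(background) == 1L,
              background >= 0)
    background
  }
  corrected <- modified - bg
  clamped <- bg > 0 && corrected <= 0
  if (clamped) {
    warning(sprintf(
      "lane '%s': background (%g) consumes the modified signal (%g); clamped to 0",
      lane$lane_id, bg, modified))
    corrected <- 0
  }
  total <- corrected + unmodified
  frac <- if (total <= 0) 0 else corrected / total
  structure(min(frac, 1), clamped = clamped)
}

#' NaOH-resistant / NaOH-sensitive partition of the modified fraction
#'
#' Alkaline treatment hydrolyzes ubiquitin oxyesters (Ser/Thr linkages)
#' but leaves isopeptide (Lys) linkages intact. The NaOH-resistant
#' proportion of modification is the background-corrected modified
#' fraction with NaOH divided by the one without; the sensitive
#' proportion is its complement. Small noise excursions above 1 are
#' capped (with a warning).
#'
#' @param mod_with_naoh Modified fraction after NaOH treatment, in
#'   \[0, 1\] (vectorized).
#' @param mod_without Modified fraction without treatment, in (0, 1\]
#'   (vectorized).
#' @return Data frame with columns `resistant` and `sensitive`
#'   (proportions of total modification; they sum to 1 exactly) and
#'   attribute `capped` (logical vector).
#' @examples
#' naoh_partition(0.3, 0.6) # half isopeptide, half oxyester
#' @export
naoh_partition <- function(mod_with_naoh, mod_without) {
  stopifnot(is.numeric(mod_with_naoh), is.numeric(mod_without),
            length(mod_with_naoh) == length(mod_without))
  if (any(!is.finite(mod_with_naoh)) || any(!is.finite(mod_without)))
    stop("fractions must be finite")
  if (any(mod_with_naoh < 0) || any(mod_with_naoh > 1) ||
      any(mod_without < 0) || any(mod_without > 1))
    stop("fractions must lie in [0, 1]")
  if (any(mod_without == 0))
    stop("mod_without = 0: NaOH partition undefined without modification")
  resistant <- mod_with_naoh / mod_without
  capped <- resistant > 1
  if (any(capped)) {
    warning(sprintf(
      "%d ratio(s) exceeded 1 (noise: NaOH fraction above untreated); capped",
      sum(capped)))
    resistant[capped] <- 1
  }
  structure(data.frame(resistant = resistant, sensitive = 1 - resistant),
            capped = capped)
}

#' Split a modified-fraction time course into NaOH-resistant and
#' -sensitive components
#'
#' Time-course form of [naoh_partition()]: the resistant component is
#' `resistant_fraction * total` and the sensitive one is the difference
#' between the total and the resistant component.
#'
#' @param total Total modified fraction over time.
#' @param resistant_fraction Scalar or vector resistant proportion(s)
#'   from [naoh_partition()].
#' @return Data frame with `resistant` and `sensitive` columns summing
#'   to `total`.
#' @export
naoh_split_timecourse <- function(total, resistant_fraction) {
  stopifnot(is.numeric(total), is.numeric(resistant_fraction))
  resistant <- resistant_fraction * total
  data.frame(resistant = resistant, sensitive = total - resistant)
}

#' Read a lane-quantification CSV
#'
#' Schema: `lane_id, role, intensity, treatment, time_min, condition`
#' (long format, one band per row; header required).
#'
#' @param path CSV path.
#' @return List of [lane_quant] objects, ordered by time then lane id.
#' @export
read_lane_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("lane_id", "role", "intensity", "treatment", "time_min",
            "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed lane CSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lanes <- lapply(split(df, df$lane_id), function(g) {
    lane_quant(g$lane_id[1L],
               stats::setNames(as.numeric(g$intensity), g$role),
               treatment = g$treatment[1L],
               time_min = as.numeric(g$time_min[1L]),
               condition = g$condition[1L])
  })
  ord <- order(vapply(lanes, function(l) l$time_min, numeric(1L)),
               vapply(lanes, function(l) as.character(l$lane_id),
                      character(1L)))
  lanes[ord]
}

#' Convert quantified lanes into a modified-fraction time course
#'
#' Applies [fraction_modified()] per lane (using a no-ATP lane of the
#' same condition as background when present) and assembles a
#' [time_course] of the modified fraction, ready for the exponential
#' fits.
#'
#' @param lanes List of [lane_quant] objects with finite `time_min`.
#' @param treatment Which treatment arm to assemble (`"none"` or
#'   `"NaOH"`).
#' @param label Label for the resulting course.
#' @return A [time_course] with observable `"modified_fraction"`.
#' @export
lanes_to_timecourse <- function(lanes, treatment = "none", label = "") {
  stopifnot(is.list(lanes), length(lanes) > 0L)
  no_atp <- Filter(function(l) l$treatment == "no_ATP", lanes)
  bg <- if (length(no_atp)) no_atp[[1L]] else NULL
  sel <- Filter(function(l) l$treatment == treatment &&
                  is.finite(l$time_min), lanes)
  if (!length(sel))
    stop("no lanes with treatment '", treatment, "' and a time_min")
  tm <- vapply(sel, function(l) l$time_min, numeric(1L))
  ord <- order(tm)
  fr <- vapply(sel[ord], function(l)
    as.numeric(fraction_modified(l, background = bg)), numeric(1L))
  time_course(tm[ord], fr, nu = 0, observable = "modified_fraction",
              label = label)
}
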