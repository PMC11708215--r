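#' Live egg-chamber growth trace
#'
#' Midsection-area (and optionally oocyte-fraction) measurements of one
#' chamber over an imaging session, indexed by elapsed time since the
#' first frame. Alignment to a standard growth curve assigns the chamber
#' an absolute age.
#'
#' @param chamber_id Identifier.
#' @param elapsed_h Strictly increasing elapsed times in hours (first
#'   sample usually 0).
#' @param area_um2 Midsection areas, um^2, all > 0.
#' @param oocyte_fraction Optional oocyte fractions (NA where unmeasured).
#' @return An `egg_chamber_trace`.
#' @export
egg_chamber_trace <- function(chamber_id, elapsed_h, area_um2,
                              oocyte_fraction = NULL) {
  stopifnot(length(elapsed_h) == length(area_um2))
  if (is.unsorted(elapsed_h, strictly = TRUE))
    stop("`elapsed_h` must be strictly increasing")
  if (any(area_um2 <= 0, na.rm = TRUE)) stop("areas must be > 0")
  if (is.null(oocyte_fraction)) oocyte_fraction <- rep(NA_real_, length(elapsed_h))
  structure(list(chamber_id = chamber_id,
                 samples = data.frame(elapsed_h = elapsed_h,
                                      area_um2 = area_um2,
                                      oocyte_fraction = oocyte_fraction),
                 t0 = NA_real_, aligned_by = NA_character_),
            class = "egg_chamber_trace")
}

#' Align a live trace to a standard growth curve
#'
#' Sets the chamber's initial age `t0` by inverting the curve at the first
#' sample's value; subsequent samples keep their actual acquisition
#' offsets, so the absolute age of sample i is `t0 + elapsed_h[i]`. With
#' `by = "auto"`, vitellogenic chambers (first oocyte fraction >= 0.30,
#' i.e. stage 8 or later) align by oocyte percent - size alone is
#' unreliable once growth is yolk-limited - and earlier chambers by area.
#'
#' @param trace An [egg_chamber_trace()].
#' @param curve A [growth_curve()] matching the alignment quantity.
#' @param by `"area"`, `"oocyte_percent"`, or `"auto"` (needs the curve of
#'   the matching kind; see `curve_oocyte`).
#' @param curve_oocyte Oocyte-percent curve used when `by = "auto"`
#'   selects it.
#' @return The trace with `t0`, `aligned_by`, and an `age_h` column.
#' @export
align_trace <- function(trace, curve, by = c("area", "oocyte_percent", "auto"),
                        curve_oocyte = NULL) {
  stopifnot(inherits(trace, "egg_chamber_trace"), inherits(curve, "growth_curve"))
  by <- match.arg(by)
  s <- trace$samples
  if (by == "auto") {
    oo1 <- s$oocyte_fraction[1L]
    by <- if (is.finite(oo1) && oo1 >= 0.30) "oocyte_percent" else "area"
    if (by == "oocyte_percent" && !is.null(curve_oocyte)) curve <- curve_oocyte
  }
  if (by == "area") {
    if (curve$kind != "area") stop("curve kind must be 'area' for area alignment")
    v1 <- s$area_um2[1L]
  } else {
    if (curve$kind != "oocyte_percent")
      stop("curve kind must be 'oocyte_percent' for oocyte alignment")
    v1 <- s$oocyte_fraction[1L]
    if (!is.finite(v1)) stop("first sample lacks an oocyte fraction")
  }
  if (!is.finite(v1) || v1 <= 0) stop("missing alignment quantity in first sample")
  trace$t0 <- invert_time(curve, v1)
  trace$aligned_by <- by
  trace$samples$age_h <- trace$t0 + s$elapsed_h
  trace
}

#' Observed size as a fraction of curve expectation
#'
#' For an aligned trace, `observed_area / predict(curve, t0 + elapsed)`
#' per sample: 1 means the chamber tracks the standard curve, below 1 it
#' grows more slowly than fixed-sample expectation.
#'
#' @param trace An aligned [egg_chamber_trace()] (see [align_trace()]).
#' @param curve The area [growth_curve()].
#' @return Data frame with `elapsed_h`, `age_h`, `observed_um2`,
#'   `expected_um2`, `fraction_of_expected`.
#' @export
percent_of_expected <- function(trace, curve) {
  stopifnot(inherits(trace, "egg_chamber_trace"))
  if (!is.finite(trace$t0)) stop("trace is not aligned; call align_trace() first")
  s <- trace$samples
  expected <- predict(curve, trace$t0 + s$elapsed_h)
  data.frame(elapsed_h = s$elapsed_h,
             age_h = trace$t0 + s$elapsed_h,
             observed_um2 = s$area_um2,
             expected_um2 = expected,
             fraction_of_expected = s$area_um2 / expected)
}

#' Cohort mean fraction of expected size at chosen elapsed times
#'
#' Averages [percent_of_expected()] across traces at the requested elapsed
#' times; a trace contributes where it has a sample at (or, with
#' `interpolate = TRUE`, spanning) that elapsed time. Interpolation is
#' linear in log area, consistent with exponential growth.
#'
#' @param traces List of aligned traces.
#' @param curve The area [growth_curve()].
#' @param at_elapsed_h Elapsed times to evaluate, hours.
#' @param interpolate Interpolate between samples (default TRUE).
#' @return Data frame `elapsed_h`, `mean_fraction`, `n_traces`.
#' @export
cohort_percent_of_expected <- function(traces, curve, at_elapsed_h,
                                       interpolate = TRUE) {
  per_trace <- lapply(traces, function(tr) {
    p <- percent_of_expected(tr, curve)
    vapply(at_elapsed_h, function(e) {
      if (e %in% p$elapsed_h) return(p$fraction_of_expected[p$elapsed_h == e][1L])
      if (!interpolate || e < min(p$elapsed_h) || e > max(p$elapsed_h))
        return(NA_real_)
      lf <- stats::approx(p$elapsed_h, log(p$fraction_of_expected), xout = e)$y
      exp(lf)
    }, numeric(1L))
  })
  m <- do.call(rbind, per_trace)
  data.frame(elapsed_h = at_elapsed_h,
             mean_fraction = colMeans(m, na.rm = TRUE),
             n_traces = colSums(!is.na(m)))
}

#' Write / read growth traces as CSV
#'
#' Long format with columns `chamber_id`, `elapsed_h`, `area_um2`,
#' `oocyte_fraction`.
#'
#' @param traces List of [egg_chamber_trace()] objects.
#' @param path CSV path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns
#'   a list of traces.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    cbind(chamber_id = tr$chamber_id, tr$samples[c("elapsed_h", "area_um2",
                                                   "oocyte_fraction")])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$chamber_id), function(d)
    egg_chamber_trace(d$chamber_id[1L], d$elapsed_h, d$area_um2,
                      d$oocyte_fraction))
}
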