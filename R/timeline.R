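#' Egg production rate per ovariole
#'
#' `EPR = E / O`: eggs laid per female per day divided by ovarioles per
#' female gives the egg output of a single ovariole per day. Because an
#' ovariole is an assembly line, this is also the rate at which chambers
#' move through it at steady state.
#'
#' @param mean_eggs_per_day Mean eggs laid per female per 24 h (E).
#' @param mean_ovarioles Mean ovarioles per female (O); must be > 0.
#' @return Eggs per ovariole per day, at full precision (round only for
#'   display).
#' @examples
#' compute_epr(51.5, 35.63)  # ~1.445, displays as 1.45
#' @export
compute_epr <- function(mean_eggs_per_day, mean_ovarioles) {
  stopifnot(is.numeric(mean_eggs_per_day), is.numeric(mean_ovarioles))
  if (mean_ovarioles <= 0) stop("`mean_ovarioles` must be > 0")
  if (mean_eggs_per_day < 0) stop("`mean_eggs_per_day` must be >= 0")
  mean_eggs_per_day / mean_ovarioles
}

#' Total duration of egg-chamber progression (stages 2-14)
#'
#' At steady state an ovariole holds `EO` chambers and emits `EPR` eggs per
#' day, so a chamber takes `G = EO / EPR` days - returned in hours - to
#' traverse the ovariole (stage 2 through stage 14).
#'
#' @param mean_chambers_per_ovariole Mean egg chambers per ovariole (EO).
#' @param epr Egg production rate per ovariole per day; must be > 0.
#' @return Total duration G in hours.
#' @examples
#' epr <- compute_epr(51.5, 35.63)
#' compute_total_duration(5.2, epr)  # ~86.3 h, displays as 86 h
#' @export
compute_total_duration <- function(mean_chambers_per_ovariole, epr) {
  if (!is.numeric(epr) || epr <= 0) stop("`epr` must be > 0")
  if (mean_chambers_per_ovariole <= 0)
    stop("`mean_chambers_per_ovariole` must be > 0")
  mean_chambers_per_ovariole / epr * 24
}

#' Stage domain of the developmental timeline
#'
#' Stages 2 through 14; the germarium and stage 1 are excluded because the
#' timeline covers progression from stage 2 to egg laying.
#' @return Integer vector 2:14.
#' @export
timeline_stages <- function() 2:14

#' Empirical stage frequencies from a fixed-sample survey
#'
#' The fraction of fixed chambers found in each stage. Under steady-state
#' progression, a stage's frequency is proportional to the time a chamber
#' spends in it, which is what [stage_durations()] exploits.
#'
#' @param stages Integer vector of per-chamber stage calls (each in 2..14),
#'   or a `fixed_survey` (see [simulate_survey()]) whose chamber table is
#'   used.
#' @return Named numeric vector over stages 2..14 summing to 1; stages not
#'   observed get 0.
#' @export
stage_frequencies <- function(stages) {
  if (inherits(stages, "fixed_survey")) stages <- stages$chambers$stage
  stages <- as.integer(stages)
  if (length(stages) == 0L) stop("empty survey: no staged chambers")
  if (any(!stages %in% timeline_stages()))
    stop("stage calls must lie in 2..14")
  tab <- tabulate(stages, nbins = 14L)[timeline_stages()]
  f <- tab / sum(tab)
  names(f) <- as.character(timeline_stages())
  f
}

#' Per-stage durations and cumulative schedule
#'
#' Allocates the total duration G across stages proportionally to their
#' observed frequencies: `Gs = f_s * G`. The cumulative schedule places the
#' start of stage 2 at 0 h.
#'
#' @param frequencies Named numeric vector over stages 2..14 (names are the
#'   stage numbers) summing to 1 within 1e-9.
#' @param total_duration_G Total duration G in hours (see
#'   [compute_total_duration()]).
#' @return A `stage_timeline`: list with `frequencies`, `total_duration`,
#'   and a data frame `schedule` with columns `stage`, `frequency`,
#'   `duration_h`, `start_h`, `midpoint_h`.
#' @examples
#' f <- rep(1 / 13, 13); names(f) <- 2:14
#' stage_durations(f, 86.34)
#' @export
stage_durations <- function(frequencies, total_duration_G) {
  stages <- timeline_stages()
  if (is.null(names(frequencies)) ||
      !identical(sort(as.integer(names(frequencies))), stages))
    stop("`frequencies` must be named by stages 2..14")
  frequencies <- frequencies[as.character(stages)]
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(frequencies)), ")")
  if (total_duration_G <= 0) stop("`total_duration_G` must be > 0")
  dur <- unname(frequencies) * total_duration_G
  start <- cumsum(c(0, dur[-length(dur)]))
  schedule <- data.frame(stage = stages,
                         frequency = unname(frequencies),
                         duration_h = dur,
                         start_h = start,
                         midpoint_h = start + dur / 2)
  structure(list(frequencies = frequencies,
                 total_duration = total_duration_G,
                 schedule = schedule),
            class = "stage_timeline")
}

#' @export
print.stage_timeline <- function(x, ...) {
  cat(sprintf("<stage_timeline>  stages 2-14, G = %.4g h\n", x$total_duration))
  print(transform(x$schedule,
                  frequency = round(frequency, 4),
                  duration_h = round(duration_h, 2),
                  start_h = round(start_h, 2),
                  midpoint_h = round(midpoint_h, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Representative (midpoint) age of a stage
#'
#' The age at the middle of a stage's occupancy window: cumulative start
#' plus half the stage duration. Used when a single age must stand for all
#' chambers of a stage (e.g. when sampling areas per stage).
#'
#' @param timeline A `stage_timeline` from [stage_durations()].
#' @param stage Stage number(s) in 2..14.
#' @return Midpoint age(s) in hours.
#' @export
stage_midpoint_age <- function(timeline, stage) {
  stopifnot(inherits(timeline, "stage_timeline"))
  i <- match(as.integer(stage), timeline$schedule$stage)
  if (anyNA(i)) stop("stage out of range 2..14")
  timeline$schedule$midpoint_h[i]
}

#' One-line developmental-timeline report with display rounding
#'
#' All quantities are carried at full precision internally; rounding to two
#' decimals (and G to the nearest hour) happens only here, at the
#' formatting layer. Rounding earlier is not reproducible: `0.077 * 86.34`
#' gives 6.65 h, but rounding G to 86 h first gives 6.62 h.
#'
#' @param mean_eggs_per_day,mean_ovarioles,mean_chambers_per_ovariole
#'   Survey means E, O, EO.
#' @param frequencies Stage frequencies as in [stage_durations()].
#' @return A list with full-precision `epr`, `G_hours`, `timeline`, and a
#'   `display` character summary using the conventional rounding.
#' @export
timeline_report <- function(mean_eggs_per_day, mean_ovarioles,
                            mean_chambers_per_ovariole, frequencies) {
  epr <- compute_epr(mean_eggs_per_day, mean_ovarioles)
  G <- compute_total_duration(mean_chambers_per_ovariole, epr)
  tl <- stage_durations(frequencies, G)
  display <- sprintf("EPR = %.2f eggs/ovariole/day; G = %.0f h; %s",
                     epr, G,
                     paste(sprintf("Gs%d = %.2f h", tl$schedule$stage,
                                   tl$schedule$duration_h),
                           collapse = "; "))
  list(epr = epr, G_hours = G, timeline = tl, display = display)
}
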