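## Fixed-sample survey generator. Emulates the observational structure of a
## dissection survey: per-female ovariole and 24-h egg counts, per-ovariole
## chamber stage calls drawn from a stage-frequency distribution, and
## per-chamber midsection areas sampled from the standard growth curve at
## the stage's midpoint age with multiplicative lognormal noise.

# run `fn()` under a temporary RNG state seeded with `seed`
.eval_with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

#' Default stage-frequency distribution (stages 2-14)
#'
#' A plausible steady-state frequency distribution over stages 2-14 used by
#' the survey generator. Stage 8 is fixed at 0.077 (so that, with the
#' default survey means, its inferred duration is ~6.65 h); the remaining
#' mass falls off from the longer early/mid stages toward the brief late
#' stages and sums to 1 exactly.
#'
#' @return Named numeric vector over stages 2..14 summing to 1.
#' @export
default_stage_frequencies <- function() {
  f <- c(0.120, 0.110, 0.100, 0.095, 0.090, 0.085, 0.077,
         0.080, 0.090, 0.035, 0.040, 0.038, 0.040)
  names(f) <- as.character(timeline_stages())
  f
}

#' Parameters of the fixed-sample survey generator
#'
#' Defaults are the observed colony means: 35.63 ovarioles and 51.5 eggs
#' laid per day per female, 5.2 egg chambers per ovariole, and the standard
#' area curve 273 * exp(0.06 t) um^2.
#'
#' @param n_females Number of females to simulate.
#' @param mean_ovarioles Mean ovarioles per female (O).
#' @param mean_chambers_per_ovariole Mean egg chambers per ovariole (EO).
#' @param mean_eggs_per_day Mean eggs laid per female per 24 h (E).
#' @param stage_frequencies Named frequencies over stages 2..14 summing to
#'   1 within 1e-9.
#' @param area_curve [growth_curve()] for midsection area (um^2 vs hours).
#' @param oocyte_curve [growth_curve()] for oocyte percent; applied to
#'   vitellogenic chambers (stages 8-11), others get `NA`.
#' @param area_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on areas and oocyte fractions (>= 0).
#' @param seed Integer seed; identical seeds give identical surveys.
#' @return A `survey_params` list.
#' @export
survey_params <- function(n_females = 16L,
                          mean_ovarioles = 35.63,
                          mean_chambers_per_ovariole = 5.2,
                          mean_eggs_per_day = 51.5,
                          stage_frequencies = default_stage_frequencies(),
                          area_curve = growth_curve(273, 0.06, "area"),
                          oocyte_curve = growth_curve(0.318, 0.07, "oocyte_percent"),
                          area_noise_cv = 0.1,
                          seed = NULL) {
  if (n_females < 1L) stop("`n_females` must be >= 1")
  if (mean_ovarioles <= 0 || mean_chambers_per_ovariole <= 0 ||
      mean_eggs_per_day < 0)
    stop("generative means must be positive")
  if (area_noise_cv < 0) stop("`area_noise_cv` must be >= 0")
  if (any(stage_frequencies < 0) || abs(sum(stage_frequencies) - 1) > 1e-9)
    stop("`stage_frequencies` must be >= 0 and sum to 1")
  if (is.null(names(stage_frequencies)) ||
      !identical(sort(as.integer(names(stage_frequencies))), timeline_stages()))
    stop("`stage_frequencies` must be named by stages 2..14")
  structure(list(n_females = as.integer(n_females),
                 mean_ovarioles = mean_ovarioles,
                 mean_chambers_per_ovariole = mean_chambers_per_ovariole,
                 mean_eggs_per_day = mean_eggs_per_day,
                 stage_frequencies = stage_frequencies[as.character(timeline_stages())],
                 area_curve = area_curve, oocyte_curve = oocyte_curve,
                 area_noise_cv = area_noise_cv, seed = seed),
            class = "survey_params")
}

# lognormal multipliers with mean 1 and the requested CV
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a fixed-sample oogenesis survey
#'
#' Draws per-female ovariole and egg counts (Poisson around the generative
#' means), per-ovariole chamber stage calls (multinomial on the stage
#' frequencies), and per-chamber midsection areas: the area curve evaluated
#' at the chamber's stage-midpoint age, times lognormal noise with the
#' requested CV. Vitellogenic chambers (stages 8-11) also get an oocyte
#' fraction from the oocyte-percent curve. Ground-truth stage and age are
#' recorded per chamber.
#'
#' @param params A [survey_params()].
#' @return A `fixed_survey`: list of data frames `females` (female_id,
#'   ovariole_count, eggs_24h), `chambers` (chamber_id, female_id,
#'   ovariole_id, stage, age_h, midsection_area_um2, oocyte_fraction), plus
#'   the generative `timeline` used for ages.
#' @export
simulate_survey <- function(params) {
  stopifnot(inherits(params, "survey_params"))
  .eval_with_seed(params$seed, function() {
    epr <- compute_epr(params$mean_eggs_per_day, params$mean_ovarioles)
    G <- compute_total_duration(params$mean_chambers_per_ovariole, epr)
    tl <- stage_durations(params$stage_frequencies, G)

    nf <- params$n_females
    females <- data.frame(
      female_id = seq_len(nf),
      ovariole_count = stats::rpois(nf, params$mean_ovarioles),
      eggs_24h = stats::rpois(nf, params$mean_eggs_per_day))

    ovariole_rows <- data.frame(
      female_id = rep(females$female_id, females$ovariole_count))
    ovariole_rows$ovariole_id <- seq_len(nrow(ovariole_rows))
    n_ch <- stats::rpois(nrow(ovariole_rows), params$mean_chambers_per_ovariole)

    stages <- sample(timeline_stages(), size = sum(n_ch), replace = TRUE,
                     prob = params$stage_frequencies)
    age <- stage_midpoint_age(tl, stages)
    area <- predict(params$area_curve, age) *
      .lognormal_noise(length(age), params$area_noise_cv)
    oo <- rep(NA_real_, length(age))
    vit <- stages >= 8L & stages <= 11L
    if (any(vit)) {
      # the oocyte-percent curve runs on its own clock, anchored where its
      # amplitude (0.318) matches the 30%-at-stage-8-completion benchmark:
      # t_oo = 0 at the end of stage 8
      sched <- tl$schedule
      t_anchor <- sched$start_h[sched$stage == 9L]
      oo[vit] <- pmin(1, predict(params$oocyte_curve, age[vit] - t_anchor) *
                        .lognormal_noise(sum(vit), params$area_noise_cv))
    }
    chambers <- data.frame(
      chamber_id = seq_along(stages),
      female_id = rep(ovariole_rows$female_id, n_ch),
      ovariole_id = rep(ovariole_rows$ovariole_id, n_ch),
      stage = stages,
      age_h = age,
      midsection_area_um2 = area,
      oocyte_fraction = oo)
    structure(list(females = females, chambers = chambers, timeline = tl),
              class = "fixed_survey")
  })
}

#' @export
print.fixed_survey <- function(x, ...) {
  cat(sprintf("<fixed_survey>  %d females, %d chambers (stages %s)\n",
              nrow(x$females), nrow(x$chambers),
              paste(range(x$chambers$stage), collapse = "-")))
  invisible(x)
}

#' Write / read a fixed survey as CSV files
#'
#' Writes `females.csv` and `chambers.csv` (documented headers matching the
#' `fixed_survey` columns) into `dir`.
#'
#' @param survey A `fixed_survey`.
#' @param dir Directory (created if missing).
#' @return `write_survey` returns `dir` invisibly; `read_survey` returns a
#'   `fixed_survey` (without the generative timeline).
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "fixed_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(survey$females, file.path(dir, "females.csv"), row.names = FALSE)
  utils::write.csv(survey$chambers, file.path(dir, "chambers.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  females <- utils::read.csv(file.path(dir, "females.csv"))
  chambers <- utils::read.csv(file.path(dir, "chambers.csv"))
  structure(list(females = females, chambers = chambers, timeline = NULL),
            class = "fixed_survey")
}
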