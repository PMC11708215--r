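## Follicle-cell rotation tracks. Egg chambers rotate about their
## anterior-posterior (x) axis; a tracked cell near the mid-focal plane
## moves on a circle of radius r in the (y, z) plane, and the imaging
## plane records its (x, y) projection: y(t) = y_mid + r * sin(phi(t)).
## The angular-displacement estimator arctan((y - y_mid)/r) recovers the
## rotation in the small-angle regime, which is where tracks are simulated
## by default (phases centred on zero).

#' Simulate tracked follicle cells on a rotating egg chamber
#'
#' @param omega Angular rate in degrees/hour.
#' @param r Chamber radius at the mid-focal plane, um.
#' @param duration,dt Track length and sampling interval, hours.
#' @param speed_noise_sd Positional jitter expressed as a speed noise in
#'   um/minute; each sampled position gets Gaussian jitter with
#'   sd = `speed_noise_sd * dt_minutes` um.
#' @param n_cells Number of tracked cells.
#' @param y_mid Midline y coordinate, um.
#' @param seed Integer seed.
#' @return A `cell_track_set`: list with `tracks` (data frame cell_id, t_h,
#'   x_um, y_um), `geometry` (list `y_mid`, `r`), and the generative
#'   parameters.
#' @export
simulate_rotation_track <- function(omega, r, duration = 1, dt = 1 / 6,
                                    speed_noise_sd = 0, n_cells = 5L,
                                    y_mid = 0, seed = NULL) {
  if (r <= 0) stop("`r` must be > 0")
  if (dt <= 0 || duration < dt) stop("need duration >= dt > 0")
  .eval_with_seed(seed, function() {
    times <- seq(0, duration, by = dt)
    omega_rad <- omega * pi / 180
    # phases centred on zero so tracks stay in the small-angle regime
    phase0 <- -omega_rad * duration / 2 +
      seq(-0.05, 0.05, length.out = max(n_cells, 2L))[seq_len(n_cells)]
    jitter_sd <- speed_noise_sd * dt * 60
    tracks <- do.call(rbind, lapply(seq_len(n_cells), function(ci) {
      phi <- phase0[ci] + omega_rad * times
      x <- rep(10 * ci, length(times))        # cells spread along the AP axis
      y <- y_mid + r * sin(phi)
      if (jitter_sd > 0) {
        x <- x + stats::rnorm(length(times), sd = jitter_sd)
        y <- y + stats::rnorm(length(times), sd = jitter_sd)
      }
      data.frame(cell_id = ci, t_h = times, x_um = x, y_um = y)
    }))
    structure(list(tracks = tracks, geometry = list(y_mid = y_mid, r = r),
                   omega = omega, duration = duration, dt = dt),
              class = "cell_track_set")
  })
}

#' @export
print.cell_track_set <- function(x, ...) {
  cat(sprintf("<cell_track_set>  %d cells, %d samples each, r = %g um\n",
              length(unique(x$tracks$cell_id)),
              sum(x$tracks$cell_id == x$tracks$cell_id[1L]), x$geometry$r))
  invisible(x)
}

#' Write / read cell tracks as CSV plus geometry JSON
#'
#' @param track_set A `cell_track_set`.
#' @param csv_path Track table path (columns cell_id, t_h, x_um, y_um).
#' @param json_path Geometry path (`y_mid`, `r`).
#' @return `write_tracks` returns `csv_path` invisibly; `read_tracks`
#'   returns a `cell_track_set`.
#' @export
write_tracks <- function(track_set, csv_path, json_path) {
  stopifnot(inherits(track_set, "cell_track_set"))
  utils::write.csv(track_set$tracks, csv_path, row.names = FALSE)
  jsonlite::write_json(track_set$geometry, json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(csv_path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(csv_path, json_path) {
  tracks <- utils::read.csv(csv_path)
  geometry <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(tracks = tracks, geometry = geometry),
            class = "cell_track_set")
}
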