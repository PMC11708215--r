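#' Angular displacement of a tracked follicle cell
#'
#' `theta = arctan((y - y_mid) / r) * 180 / pi` degrees: the projection
#' approximation mapping a cell's in-plane y position to its angle around
#' the chamber's rotation (anterior-posterior) axis. Valid away from the
#' chamber edge; see [angular_velocity()] for the flagging rule.
#'
#' @param y Cell y coordinate(s), um.
#' @param y_mid Midline y coordinate along the rotation-axis projection, um.
#' @param r Chamber radius at the mid-focal plane, um; must be > 0.
#' @return Angle(s) in degrees, in (-90, 90).
#' @examples
#' angular_displacement(0, 0, 10)   # 0
#' angular_displacement(10, 0, 10)  # 45
#' @export
angular_displacement <- function(y, y_mid, r) {
  if (!is.numeric(r) || any(r <= 0)) stop("`r` must be > 0")
  atan((y - y_mid) / r) * 180 / pi
}

#' Angular velocity from a cell track
#'
#' Per-interval `delta theta / delta t` from [angular_displacement()] and
#' their arithmetic mean. Samples with `|y - y_mid| > 0.9 r`, where the
#' projection approximation degrades, are flagged in the returned interval
#' table.
#'
#' @param track Data frame with columns `t_h` and `y_um` (a single cell),
#'   or a `cell_track_set` (all cells pooled per cell, means averaged).
#' @param y_mid,r Chamber geometry, um (taken from the track set when
#'   given).
#' @return A list with `mean_deg_per_h`, `per_interval` (data frame:
#'   cell_id, t_h, dtheta_deg, dt_h, omega_deg_per_h), and `n_flagged`
#'   samples outside the trusted band.
#' @export
angular_velocity <- function(track, y_mid = NULL, r = NULL) {
  df <- .as_track_df(track, y_mid, r)
  y_mid <- attr(df, "y_mid"); r <- attr(df, "r")
  per <- do.call(rbind, lapply(split(df, df$cell_id), function(d) {
    if (nrow(d) < 2L) stop("angular velocity needs >= 2 samples per cell")
    if (is.unsorted(d$t_h, strictly = TRUE) && is.unsorted(rev(d$t_h), strictly = TRUE))
      stop("sample times must be strictly monotone")
    th <- angular_displacement(d$y_um, y_mid, r)
    data.frame(cell_id = d$cell_id[-1L],
               t_h = d$t_h[-1L],
               dtheta_deg = diff(th),
               dt_h = diff(d$t_h),
               omega_deg_per_h = diff(th) / diff(d$t_h))
  }))
  flagged <- abs(df$y_um - y_mid) > 0.9 * r
  list(mean_deg_per_h = mean(per$omega_deg_per_h),
       per_interval = per, n_flagged = sum(flagged))
}

#' Mean in-plane speed of a cell track
#'
#' Mean of Euclidean step length over step duration across consecutive
#' samples, converted to um/minute.
#'
#' @inheritParams angular_velocity
#' @return Mean speed in um/minute (scalar; track sets are pooled over
#'   cells).
#' @export
mean_speed <- function(track) {
  df <- .as_track_df(track, y_mid = 0, r = 1)
  speeds <- unlist(lapply(split(df, df$cell_id), function(d) {
    if (nrow(d) < 2L) stop("mean speed needs >= 2 samples per cell")
    step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    step / (diff(d$t_h) * 60)
  }))
  mean(speeds)
}

# normalize track input: data frame (single cell) or cell_track_set
.as_track_df <- function(track, y_mid, r) {
  if (inherits(track, "cell_track_set")) {
    df <- track$tracks
    if (is.null(y_mid)) y_mid <- track$geometry$y_mid
    if (is.null(r)) r <- track$geometry$r
  } else {
    df <- as.data.frame(track)
    if (!"cell_id" %in% names(df)) df$cell_id <- 1L
  }
  need <- c("cell_id", "t_h", "y_um")
  if (!all(need %in% names(df)))
    stop("track needs columns ", paste(need, collapse = ", "))
  if (!"x_um" %in% names(df)) df$x_um <- 0
  if (is.null(y_mid) || is.null(r)) stop("chamber geometry (y_mid, r) required")
  structure(df, y_mid = y_mid, r = r)
}
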