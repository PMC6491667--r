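#' Collapse a trajectory into cell visits
#'
#' Events mark every coded occurrence; a visit is a maximal run of
#' consecutive events in the same grid cell, and is the unit for transition
#' counting. Collapsing conserves both time and events exactly: visit
#' durations sum to the trajectory's total duration, visit event counts sum
#' to the trajectory's event count.
#'
#' @param traj An `ssg_trajectory` coded on the space's dimensions.
#' @param space An [make_state_space()] space.
#' @return An `ssg_visits` tibble with one row per visit — columns `cell`,
#'   `x`, `y`, `x_label`, `y_label`, `start`, `duration`, `n_events` — and
#'   attributes `space`, `trajectory_id`, `offset`.
#' @export
to_visits <- function(traj, space) {
  stopifnot(inherits(traj, "ssg_trajectory"), inherits(space, "ssg_space"))
  ec <- event_cells(traj, space)
  dur <- event_durations(traj)
  run <- cumsum(c(1L, as.integer(diff(ec$cell) != 0L)))
  first <- !duplicated(run)
  vis <- tibble::tibble(
    cell = ec$cell[first],
    x = ec$x[first],
    y = ec$y[first],
    x_label = space$x$categories[ec$x[first]],
    y_label = space$y$categories[ec$y[first]],
    start = traj$events$onset[first],
    duration = as.numeric(tapply(dur, run, sum)),
    n_events = as.integer(tabulate(run))
  )
  structure(vis, class = c("ssg_visits", class(vis)),
            space = space, trajectory_id = traj$id, offset = traj$offset)
}

visit_space <- function(vs) attr(vs, "space", exact = TRUE)

#' Cell-to-cell transitions of a visit sequence
#'
#' A transition is the movement from one visit's cell to the next visit's
#' (necessarily different) cell; a sequence of `k` visits therefore has
#' `k - 1` transitions.
#'
#' @param vs An `ssg_visits` sequence from [to_visits()].
#' @return A tibble with one row per transition: `from`, `to` (linear cell
#'   indices) and `from_label`, `to_label`.
#' @export
transitions <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  k <- nrow(vs)
  if (k < 2) {
    return(tibble::tibble(from = integer(), to = integer(),
                          from_label = character(), to_label = character()))
  }
  tibble::tibble(
    from = vs$cell[-k], to = vs$cell[-1],
    from_label = paste0(vs$x_label[-k], "/", vs$y_label[-k]),
    to_label = paste0(vs$x_label[-1], "/", vs$y_label[-1])
  )
}

#' Extract a time window of a trajectory
#'
#' Windows are half-open `[t0, t1)`, so adjacent windows partition time with
#' no instant counted twice. Every event overlapping the window is kept; the
#' first kept event's onset is clipped to `t0` and the offset to
#' `min(offset, t1)`, because the system occupies a state at every instant —
#' the sliced trajectory's total duration equals the overlap length with no
#' gaps. Slicing is idempotent and composes: a narrower slice of a wider
#' slice equals the narrow slice directly.
#'
#' @param traj An `ssg_trajectory`.
#' @param t0,t1 Window bounds in seconds, `t0 < t1`. The window must overlap
#'   the observation span.
#' @return An `ssg_trajectory` restricted to the window (id suffixed with
#'   the window).
#' @export
slice_trajectory <- function(traj, t0, t1) {
  stopifnot(inherits(traj, "ssg_trajectory"))
  if (!(is.numeric(t0) && is.numeric(t1)) || t0 >= t1) {
    stop("need numeric window bounds with t0 < t1", call. = FALSE)
  }
  start <- traj$events$onset[1]
  if (t1 <= start || t0 >= traj$offset) {
    stop("window [", t0, ", ", t1, ") outside observation [", start, ", ",
         traj$offset, ")", call. = FALSE)
  }
  onset <- traj$events$onset
  ends <- c(onset[-1], traj$offset)
  keep <- onset < t1 & ends > t0
  ev <- traj$events[keep, , drop = FALSE]
  ev$onset[1] <- max(ev$onset[1], t0)
  off <- min(traj$offset, t1)
  trajectory(ev, off, traj$codebook, id = traj$id)
}
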