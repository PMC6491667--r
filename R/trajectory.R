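#' Construct a timed categorical trajectory
#'
#' A trajectory is one observation session: a sequence of coded events at
#' strictly increasing onsets plus a terminal offset marking the end of
#' observation. Each event carries one category per codebook dimension. An
#' event lasts until the next event's onset (the last event until the
#' offset), so the stream is exhaustive: the system occupies exactly one
#' joint state at every instant of the session.
#'
#' @param events A data frame with an `onset` column (seconds, strictly
#'   increasing) and one column per codebook dimension holding category
#'   labels.
#' @param offset End of observation in seconds; must exceed the last onset.
#' @param codebook A [codebook()] whose dimensions match the event columns.
#' @param id Trajectory identifier (any string).
#' @return An object of class `ssg_trajectory`: a list with fields `id`,
#'   `events` (tibble), `offset`, `codebook`.
#' @seealso [validate_trajectory()] for a non-throwing violation report,
#'   [read_trj()] and [read_long()] to build trajectories from files.
#' @export
trajectory <- function(events, offset, codebook, id = "trajectory") {
  events <- tibble::as_tibble(events)
  viol <- trajectory_violations(events, offset, codebook, id = id)
  err <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(err) > 0) {
    stop("invalid trajectory '", id, "':\n  ",
         paste(err$message, collapse = "\n  "), call. = FALSE)
  }
  for (d in names(codebook)) {
    events[[d]] <- as.character(events[[d]])
  }
  structure(
    list(id = id, events = events, offset = as.numeric(offset),
         codebook = codebook),
    class = "ssg_trajectory"
  )
}

# Shared invariant checker used by the constructor (errors) and by
# validate_trajectory() (report). Returns a tibble(severity, row, dimension,
# message); severity is "error" or "warning".
trajectory_violations <- function(events, offset, codebook, id = "trajectory") {
  v <- list()
  add <- function(severity, message, row = NA_integer_, dimension = NA_character_) {
    v[[length(v) + 1]] <<- tibble::tibble(
      severity = severity, row = row, dimension = dimension, message = message
    )
  }

  if (!is.data.frame(events) || !"onset" %in% names(events)) {
    add("error", "events must be a data frame with an 'onset' column")
    return(dplyr::bind_rows(v))
  }
  onset <- suppressWarnings(as.numeric(events$onset))
  if (nrow(events) < 1) {
    add("error", "trajectory must contain at least one event")
  }
  if (anyNA(onset)) {
    bad <- which(is.na(onset))[1]
    add("error", paste0("row ", bad, ": onset is not a number"), row = bad)
  } else {
    if (any(onset < 0)) {
      bad <- which(onset < 0)[1]
      add("error", paste0("row ", bad, ": negative onset ", onset[bad]),
          row = bad)
    }
    if (nrow(events) >= 2) {
      nonInc <- which(diff(onset) <= 0)
      for (k in nonInc) {
        add("error",
            paste0("row ", k + 1, ": onset ", onset[k + 1],
                   " does not increase past previous onset ", onset[k]),
            row = k + 1L)
      }
    }
    off <- suppressWarnings(as.numeric(offset))
    if (length(off) != 1 || is.na(off)) {
      add("error", "offset must be a single number")
    } else if (nrow(events) >= 1 && off <= onset[nrow(events)]) {
      add("error", paste0("offset ", off, " must exceed the last onset ",
                          onset[nrow(events)]))
    } else if (nrow(events) >= 1) {
      # durations implied by consecutive onsets + offset
      dur <- diff(c(onset, off))
      sub <- which(dur < 1)
      for (k in sub) {
        add("warning",
            paste0("row ", k, ": event duration ", signif(dur[k], 4),
                   " s is below the recommended 1 s minimum time unit"),
            row = as.integer(k))
      }
    }
  }

  for (d in names(codebook)) {
    if (!d %in% names(events)) {
      add("error", paste0("missing dimension column '", d, "'"), dimension = d)
      next
    }
    vals <- as.character(events[[d]])
    missing_val <- which(is.na(vals) | !nzchar(vals))
    for (k in missing_val) {
      add("error", paste0("row ", k, ": missing value for dimension '", d,
                          "' (interaction stream must be exhaustive)"),
          row = as.integer(k), dimension = d)
    }
    unknown <- which(!is.na(vals) & nzchar(vals) & !vals %in% codebook[[d]])
    for (k in unknown) {
      add("error", paste0("row ", k, ": category '", vals[k],
                          "' is not in dimension '", d, "'"),
          row = as.integer(k), dimension = d)
    }
  }

  if (length(v) == 0) {
    tibble::tibble(severity = character(), row = integer(),
                   dimension = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Report invariant violations of a trajectory
#'
#' Unlike the [trajectory()] constructor, this never throws: it returns a
#' tibble of violations, one row each, with columns `severity`, `row`,
#' `dimension`, `message`. An empty tibble means the trajectory is valid.
#' Sub-second event durations yield a `"warning"` row (time units below 1 s
#' are discouraged for coded interaction data but not rejected); everything
#' else is an `"error"` row.
#'
#' @param traj An `ssg_trajectory`, or a list with fields `events`, `offset`,
#'   `codebook` not yet validated.
#' @return A tibble of violations (zero rows when valid).
#' @export
validate_trajectory <- function(traj) {
  trajectory_violations(traj$events, traj$offset, traj$codebook,
                        id = traj$id %||% "trajectory")
}

#' Event durations of a trajectory
#'
#' Each event lasts from its onset to the next event's onset; the final event
#' lasts until the trajectory offset. Durations therefore sum exactly to
#' `offset - first onset`.
#'
#' @param traj An `ssg_trajectory`.
#' @return Numeric vector of durations in seconds, one per event.
#' @export
event_durations <- function(traj) {
  diff(c(traj$events$onset, traj$offset))
}

#' Total observed duration of a trajectory
#'
#' @param traj An `ssg_trajectory`.
#' @return `offset - first onset`, in seconds.
#' @export
total_duration <- function(traj) {
  traj$offset - traj$events$onset[1]
}

#' Number of events in a trajectory
#' @param traj An `ssg_trajectory`.
#' @return Integer event count.
#' @export
n_events <- function(traj) nrow(traj$events)

#' @export
print.ssg_trajectory <- function(x, ...) {
  cat("<ssg_trajectory> '", x$id, "': ", nrow(x$events), " events over ",
      format(total_duration(x)), " s (",
      paste(names(x$codebook), collapse = " x "), ")\n", sep = "")
  print(utils::head(x$events, 5))
  if (nrow(x$events) > 5) cat("# ... with", nrow(x$events) - 5, "more events\n")
  invisible(x)
}

#' Bundle trajectories sharing one codebook
#'
#' @param trajectories List of `ssg_trajectory` objects over an identical
#'   codebook.
#' @return An `ssg_collection`: the list, with unique trajectory ids enforced.
#' @export
trajectory_collection <- function(trajectories) {
  if (length(trajectories) < 1) {
    stop("collection needs at least one trajectory", call. = FALSE)
  }
  cb <- trajectories[[1]]$codebook
  for (t in trajectories) {
    if (!inherits(t, "ssg_trajectory")) {
      stop("all elements must be ssg_trajectory objects", call. = FALSE)
    }
    if (!identical(unclass(t$codebook), unclass(cb))) {
      stop("all trajectories in a collection must share one codebook",
           call. = FALSE)
    }
  }
  ids <- vapply(trajectories, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated trajectory ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(trajectories) <- ids
  structure(trajectories, class = "ssg_collection")
}

#' @export
print.ssg_collection <- function(x, ...) {
  cat("<ssg_collection> ", length(x), " trajectories: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
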