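#' Per-cell content measures of a visit sequence
#'
#' For every cell of the state space (visited or not) this tallies the
#' classic SSG content measures: number of events, number of visits, total
#' duration, mean duration per visit, and standardized versions — the
#' proportion of all events, the proportion of total time, and events per
#' minute of observation. Cells with the highest visits, total duration or
#' mean duration per visit are the first-pass attractor candidates (see
#' [top_cells()]).
#'
#' @param vs An `ssg_visits` sequence from [to_visits()].
#' @return A tibble with one row per cell of the space: `cell`, `x`, `y`,
#'   `x_label`, `y_label`, `events`, `visits`, `total_duration`,
#'   `mean_duration_per_visit` (`NA` for unvisited cells),
#'   `event_proportion`, `duration_proportion`, `events_per_minute`.
#' @export
cell_stats <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  cells <- all_cells(space)
  n <- space$n_cells
  ev <- dur <- visits <- numeric(n)
  for (i in seq_len(nrow(vs))) {
    ci <- vs$cell[i]
    ev[ci] <- ev[ci] + vs$n_events[i]
    dur[ci] <- dur[ci] + vs$duration[i]
    visits[ci] <- visits[ci] + 1
  }
  tot_ev <- sum(ev)
  tot_dur <- sum(dur)
  cells$events <- as.integer(ev)
  cells$visits <- as.integer(visits)
  cells$total_duration <- dur
  cells$mean_duration_per_visit <- ifelse(visits > 0, dur / pmax(visits, 1),
                                          NA_real_)
  cells$event_proportion <- ev / tot_ev
  cells$duration_proportion <- dur / tot_dur
  cells$events_per_minute <- ev / (tot_dur / 60)
  cells
}

#' Aggregate content measures over a grid region
#'
#' A region is a set of cells — typically one full column (a speaker) or one
#' full row (a behavior code). Region-level visits are maximal runs of
#' consecutive visits inside the region, so e.g. a speaker keeping the floor
#' across several of their own cells counts as one region visit. When the
#' region is a single full row or column, the standard deviation of the
#' percentage time shares across all sibling rows/columns is also returned
#' — the usual check of how evenly the conversational floor is shared.
#'
#' @param vs An `ssg_visits` sequence.
#' @param x,y Select the region by axis category label (or index): `x =
#'   "C"` takes speaker C's full column, `y = "Relat"` a full row; give both
#'   for a single cell.
#' @param cells Alternatively, an explicit integer vector of linear cell
#'   indices.
#' @return A one-row tibble: `region`, `n_cells_region`, `events`, `visits`,
#'   `total_duration`, `event_proportion`, `duration_proportion`,
#'   `duration_pct`, and `sibling_sd_pct` (`NA` unless the region is a full
#'   row or column).
#' @export
region_stats <- function(vs, x = NULL, y = NULL, cells = NULL) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  reg <- resolve_region(space, x = x, y = y, cells = cells)
  st <- cell_stats(vs)
  in_reg <- st$cell %in% reg$cells
  inside <- vs$cell %in% reg$cells
  # region visits: maximal runs of consecutive inside visits
  r_visits <- if (nrow(vs) == 0) 0L else {
    sum(inside & !c(FALSE, inside[-length(inside)]))
  }
  tot_dur <- sum(vs$duration)
  out <- tibble::tibble(
    region = reg$label,
    n_cells_region = length(reg$cells),
    events = sum(st$events[in_reg]),
    visits = as.integer(r_visits),
    total_duration = sum(st$total_duration[in_reg]),
    event_proportion = sum(st$event_proportion[in_reg]),
    duration_proportion = sum(st$duration_proportion[in_reg]),
    duration_pct = 100 * sum(st$duration_proportion[in_reg]),
    sibling_sd_pct = NA_real_
  )
  # SD across sibling rows/columns of percentage time shares
  if (!is.null(reg$margin)) {
    ax <- if (reg$margin == "x") st$x else st$y
    shares <- vapply(seq_len(max(ax)), function(i) {
      100 * sum(st$duration_proportion[ax == i])
    }, numeric(1))
    out$sibling_sd_pct <- stats::sd(shares)
  }
  out
}

# Region selector shared by region_stats() and return_stats(): by axis
# label/index or explicit cell set.
resolve_region <- function(space, x = NULL, y = NULL, cells = NULL) {
  if (!is.null(cells)) {
    cells <- as.integer(cells)
    if (length(cells) == 0) stop("region is empty", call. = FALSE)
    if (any(cells < 1 | cells > space$n_cells)) {
      stop("region contains unknown cells", call. = FALSE)
    }
    return(list(cells = unique(cells),
                label = paste0("cells{", length(unique(cells)), "}"),
                margin = NULL))
  }
  axis_index <- function(val, axis, axis_name) {
    if (is.character(val)) {
      i <- match(val, axis$categories)
      if (is.na(i)) {
        stop("unknown ", axis_name, " category '", val, "'", call. = FALSE)
      }
      i
    } else {
      i <- as.integer(val)
      if (i < 1 || i > length(axis$categories)) {
        stop(axis_name, " index ", i, " out of range", call. = FALSE)
      }
      i
    }
  }
  grid <- all_cells(space)
  if (!is.null(x) && !is.null(y)) {
    xi <- axis_index(x, space$x, "x")
    yi <- axis_index(y, space$y, "y")
    list(cells = cell_index(space, xi, yi),
         label = cell_label(space, xi, yi), margin = NULL)
  } else if (!is.null(x)) {
    xi <- axis_index(x, space$x, "x")
    list(cells = grid$cell[grid$x == xi],
         label = paste0(space$x$name, "=", space$x$categories[xi]),
         margin = "x")
  } else if (!is.null(y)) {
    yi <- axis_index(y, space$y, "y")
    list(cells = grid$cell[grid$y == yi],
         label = paste0(space$y$name, "=", space$y$categories[yi]),
         margin = "y")
  } else {
    stop("specify a region via x=, y= or cells=", call. = FALSE)
  }
}

# Inverted, cell-count-corrected sum of squared proportions; shared core.
dispersion_from_props <- function(p, n_cells) {
  if (n_cells < 2) stop("dispersion needs at least 2 cells", call. = FALSE)
  1 - (n_cells * sum(p^2) - 1) / (n_cells - 1)
}

#' Dispersion of a visit sequence over its state space
#'
#' Dispersion is the inverted sum of squared proportional durations across
#' all cells, corrected for the number of cells:
#' `1 - (n * sum(p_i^2) - 1) / (n - 1)` with `n` the number of cells of the
#' defined state space and `p_i` each cell's share of total duration. It is
#' 0 when all time is spent in a single cell (maximally rigid interaction)
#' and 1 when time is spread evenly over all cells (maximally flexible).
#'
#' @param vs An `ssg_visits` sequence.
#' @return A number in `[0, 1]`.
#' @export
dispersion <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  st <- cell_stats(vs)
  dispersion_from_props(st$duration_proportion, space$n_cells)
}

# Shannon entropy in nats over a tally vector; zero tallies drop out
# (0 * log 0 := 0).
shannon <- function(counts) {
  q <- counts[counts > 0]
  q <- q / sum(q)
  -sum(q * log(q))
}

#' Shannon entropies of a visit sequence
#'
#' Entropy measures the predictability of the trajectory's organization.
#' Three variants are standard: over per-cell visit proportions
#' (`visit_entropy`), over per-cell duration proportions
#' (`duration_entropy`), and over the proportions of distinct ordered
#' `(from, to)` cell transition types (`transition_entropy`). All use the
#' Shannon form `-sum(q * log(q))` with the natural logarithm, so units are
#' nats; zero-probability cells contribute nothing. Low values indicate a
#' highly organized, repetitive pattern; the maximum `log(k)` is reached
#' when the `k` occupied cells (or transition types) are used uniformly.
#'
#' @param vs An `ssg_visits` sequence (for `transition_entropy`, with at
#'   least two visits).
#' @return Entropy in nats (non-negative).
#' @export
visit_entropy <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  shannon(tabulate(vs$cell, nbins = visit_space(vs)$n_cells))
}

#' @rdname visit_entropy
#' @export
duration_entropy <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  st <- cell_stats(vs)
  shannon(st$total_duration)
}

#' @rdname visit_entropy
#' @export
transition_entropy <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  tr <- transitions(vs)
  if (nrow(tr) == 0) {
    stop("no transitions: the sequence has a single visit", call. = FALSE)
  }
  shannon(as.numeric(table(paste(tr$from, tr$to))))
}

#' Whole-grid structure measures
#'
#' Bundles the structure measures of a single trajectory's visit sequence:
#' event/visit/transition counts, cell range (number of distinct cells
#' visited at least once), dispersion, and the visit, transition and
#' duration entropies. Transitions number `visits - 1`, since the first
#' visit is not a transition. `transition_entropy` is `NA` for a
#' single-visit sequence.
#'
#' @param vs An `ssg_visits` sequence.
#' @return A one-row tibble: `n_events`, `n_visits`, `n_transitions`,
#'   `cell_range`, `n_unvisited`, `dispersion`, `visit_entropy`,
#'   `transition_entropy`, `duration_entropy`.
#' @export
grid_measures <- function(vs) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  cr <- length(unique(vs$cell))
  tibble::tibble(
    n_events = sum(vs$n_events),
    n_visits = nrow(vs),
    n_transitions = nrow(vs) - 1L,
    cell_range = as.integer(cr),
    n_unvisited = as.integer(space$n_cells - cr),
    dispersion = dispersion(vs),
    visit_entropy = visit_entropy(vs),
    transition_entropy = if (nrow(vs) >= 2) transition_entropy(vs) else NA_real_,
    duration_entropy = duration_entropy(vs)
  )
}

#' Pooled grid measures over a collection of trajectories
#'
#' Pools tallies (visits, durations, transition types) over all
#' trajectories before forming proportions, so proportions reflect summed
#' time and counts. No transition is ever counted across trajectory
#' boundaries: pooled `n_transitions` is the sum of each trajectory's
#' `visits - 1`. Per-trajectory measures are returned alongside for
#' between-team comparison.
#'
#' @param collection An `ssg_collection` (or list of trajectories).
#' @param space A shared [make_state_space()] space.
#' @return A list with `pooled` (one-row tibble as [grid_measures()]) and
#'   `per_trajectory` (tibble, one row per trajectory, first column
#'   `trajectory_id`).
#' @export
pooled_measures <- function(collection, space) {
  if (inherits(collection, "ssg_trajectory")) {
    collection <- trajectory_collection(list(collection))
  }
  vss <- lapply(collection, to_visits, space = space)
  per <- dplyr::bind_rows(lapply(names(vss), function(id) {
    dplyr::bind_cols(tibble::tibble(trajectory_id = id),
                     grid_measures(vss[[id]]))
  }))

  n <- space$n_cells
  visit_tally <- dur_tally <- numeric(n)
  ev_total <- 0
  trans_tally <- list()
  for (vs in vss) {
    visit_tally <- visit_tally + tabulate(vs$cell, nbins = n)
    for (i in seq_len(nrow(vs))) {
      dur_tally[vs$cell[i]] <- dur_tally[vs$cell[i]] + vs$duration[i]
    }
    ev_total <- ev_total + sum(vs$n_events)
    tr <- transitions(vs)
    trans_tally[[length(trans_tally) + 1]] <- paste(tr$from, tr$to)
  }
  trans_types <- unlist(trans_tally)
  n_visits <- sum(visit_tally)
  cr <- sum(visit_tally > 0)
  pooled <- tibble::tibble(
    n_events = ev_total,
    n_visits = as.integer(n_visits),
    n_transitions = as.integer(sum(vapply(vss, nrow, integer(1)) - 1L)),
    cell_range = as.integer(cr),
    n_unvisited = as.integer(n - cr),
    dispersion = dispersion_from_props(dur_tally / sum(dur_tally), n),
    visit_entropy = shannon(visit_tally),
    transition_entropy = if (length(trans_types) > 0) {
      shannon(as.numeric(table(trans_types)))
    } else NA_real_,
    duration_entropy = shannon(dur_tally)
  )
  list(pooled = pooled, per_trajectory = per)
}
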