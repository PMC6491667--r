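#' Return-time statistics for a cell or region
#'
#' The pull of an attractor shows in how quickly the system comes back
#' after leaving it. Each excursion runs from the moment the trajectory
#' leaves the region to the moment it next re-enters; its return time is
#' the elapsed time outside, and its return visits the number of discrete
#' visits to other cells in between. Short mean return times (and few
#' return visits) indicate a strong attractor. A trailing excursion that
#' never re-enters before the observation ends is censored: it is counted
#' but excluded from the means.
#'
#' @param vs An `ssg_visits` sequence.
#' @inheritParams region_stats
#' @return A list of class `ssg_return_stats`: `region`, `n_excursions`
#'   (all exits, censored included), `n_censored`, `mean_return_time`,
#'   `mean_return_visits` (both `NA` when no completed excursion exists),
#'   and `excursions`, a tibble with one row per excursion (`exit_time`,
#'   `reentry_time` (`NA` if censored), `return_time`, `visits_outside`,
#'   `censored`).
#' @export
return_stats <- function(vs, x = NULL, y = NULL, cells = NULL) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  reg <- resolve_region(space, x = x, y = y, cells = cells)
  inside <- vs$cell %in% reg$cells
  if (!any(inside)) {
    stop("region not visited: ", reg$label, call. = FALSE)
  }
  ends <- vs$start + vs$duration
  exc <- list()
  i <- 1L
  n <- nrow(vs)
  while (i <= n) {
    if (inside[i]) {
      # find the exit, if any
      j <- i
      while (j <= n && inside[j]) j <- j + 1L
      if (j > n) break
      exit_time <- ends[j - 1L]          # leaving the region
      k <- j
      while (k <= n && !inside[k]) k <- k + 1L
      if (k <= n) {
        exc[[length(exc) + 1]] <- tibble::tibble(
          exit_time = exit_time, reentry_time = vs$start[k],
          return_time = vs$start[k] - exit_time,
          visits_outside = as.integer(k - j), censored = FALSE
        )
        i <- k
      } else {
        exc[[length(exc) + 1]] <- tibble::tibble(
          exit_time = exit_time, reentry_time = NA_real_,
          return_time = NA_real_,
          visits_outside = as.integer(n - j + 1L), censored = TRUE
        )
        i <- n + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  excursions <- if (length(exc)) dplyr::bind_rows(exc) else {
    tibble::tibble(exit_time = numeric(), reentry_time = numeric(),
                   return_time = numeric(), visits_outside = integer(),
                   censored = logical())
  }
  done <- excursions[!excursions$censored, , drop = FALSE]
  structure(list(
    region = reg$label,
    n_excursions = nrow(excursions),
    n_censored = sum(excursions$censored),
    mean_return_time = if (nrow(done)) mean(done$return_time) else NA_real_,
    mean_return_visits = if (nrow(done)) mean(done$visits_outside) else NA_real_,
    excursions = excursions
  ), class = "ssg_return_stats")
}

#' @export
print.ssg_return_stats <- function(x, ...) {
  cat("<ssg_return_stats> region ", x$region, ": ", x$n_excursions,
      " excursion(s), ", x$n_censored, " censored\n", sep = "")
  cat("  mean return time:  ", format(x$mean_return_time), " s\n", sep = "")
  cat("  mean return visits:", format(x$mean_return_visits), "\n")
  invisible(x)
}

#' Rank cells as first-pass attractor candidates
#'
#' Attractor candidates are the cells with the most visits, the longest
#' total duration, or the longest mean duration per visit. Only visited
#' cells are ranked; ties are broken by total duration, then event count,
#' then cell index, so the ranking is deterministic.
#'
#' @param stats A [cell_stats()] tibble.
#' @param by Ranking criterion: `"visits"`, `"total_duration"` or
#'   `"mean_duration_per_visit"`.
#' @param k Number of cells to return (capped at the number of visited
#'   cells).
#' @return The top `k` rows of `stats`, ranked.
#' @export
top_cells <- function(stats, by = c("visits", "total_duration",
                                    "mean_duration_per_visit"), k = 3) {
  by <- match.arg(by)
  stopifnot(k >= 1)
  st <- stats[stats$visits > 0, , drop = FALSE]
  ord <- order(-st[[by]], -st$total_duration, -st$events, st$cell)
  utils::head(st[ord, , drop = FALSE], k)
}

#' Identify attractor cells by winnowing
#'
#' Winnowing iteratively deletes the cell(s) with the lowest total duration
#' and, after each deletion, scores the heterogeneity of the surviving
#' cells: with expected duration `E = (remaining total)/(remaining count)`
#' for every remaining cell, heterogeneity is the chi-square-like sum
#' `sum((observed - E)^2 / E)`. Screening stops when fewer than two cells
#' would remain. A large proportional jump in heterogeneity marks the
#' screen at which the surviving cells separate from the rest; the last
#' screen whose proportional increase over the previous screen is at least
#' `stop_ratio` is selected, and its surviving cells are the attractor
#' candidates. The full screen log is always returned so any alternative
#' stopping rule can be applied post hoc. Cells tied on minimal duration
#' are removed together, making the procedure permutation-invariant.
#'
#' @param vs An `ssg_visits` sequence with at least one visited cell.
#' @param stop_ratio Minimal proportional heterogeneity increase (default
#'   0.5) for a screen to be selectable.
#' @return A list of class `ssg_winnow`: `screens` (tibble with `screen`,
#'   `n_remaining`, `heterogeneity`, `prop_change`, `removed` — list-column
#'   of cell labels removed entering that screen), `selected_screen`, and
#'   `attractor_cells` (tibble of surviving cells with durations).
#' @export
winnow <- function(vs, stop_ratio = 0.5) {
  stopifnot(inherits(vs, "ssg_visits"))
  space <- visit_space(vs)
  st <- cell_stats(vs)
  st <- st[st$visits > 0, , drop = FALSE]
  label <- paste0(st$x_label, "/", st$y_label)
  dur <- st$total_duration
  names(dur) <- label

  het <- function(d) {
    e <- sum(d) / length(d)
    sum((d - e)^2 / e)
  }

  screens <- list()
  remaining <- dur
  screen <- 0L
  removed <- character(0)
  repeat {
    screens[[screen + 1L]] <- tibble::tibble(
      screen = screen,
      n_remaining = length(remaining),
      heterogeneity = het(remaining),
      removed = list(removed)
    )
    # next removal: all cells tied at the minimal duration
    lo <- min(remaining)
    drop_idx <- which(remaining <= lo + 1e-12)
    if (length(remaining) - length(drop_idx) < 2) break
    removed <- names(remaining)[drop_idx]
    remaining <- remaining[-drop_idx]
    screen <- screen + 1L
  }
  log <- dplyr::bind_rows(screens)
  h <- log$heterogeneity
  prop_change <- c(NA_real_, vapply(seq_along(h)[-1], function(k) {
    if (h[k - 1] > 0) (h[k] - h[k - 1]) / h[k - 1]
    else if (h[k] > 0) Inf else 0
  }, numeric(1)))
  log$prop_change <- prop_change
  sel_candidates <- which(!is.na(prop_change) & prop_change >= stop_ratio) - 1L
  selected <- if (length(sel_candidates)) max(sel_candidates) else 0L

  # surviving cells at the selected screen: replay removals
  surviving <- dur
  if (selected > 0) {
    for (k in seq_len(selected) + 1L) {
      surviving <- surviving[!names(surviving) %in% log$removed[[k]]]
    }
  }
  surv_idx <- match(names(surviving), label)
  structure(list(
    screens = log[, c("screen", "n_remaining", "heterogeneity",
                      "prop_change", "removed")],
    selected_screen = selected,
    attractor_cells = tibble::tibble(
      cell = st$cell[surv_idx],
      x = st$x[surv_idx], y = st$y[surv_idx],
      x_label = st$x_label[surv_idx], y_label = st$y_label[surv_idx],
      total_duration = unname(surviving)
    )
  ), class = "ssg_winnow")
}

#' @export
print.ssg_winnow <- function(x, ...) {
  cat("<ssg_winnow> ", nrow(x$screens), " screen(s); selected screen ",
      x$selected_screen, "\n", sep = "")
  cat("attractor cells: ",
      paste(paste0(x$attractor_cells$x_label, "/", x$attractor_cells$y_label),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
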