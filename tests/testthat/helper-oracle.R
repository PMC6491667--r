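# Independent brute-force oracles. Everything here works directly on raw
# event tables with plain loops, deliberately sharing no code with the
# package's vectorized implementations.

# run-length collapse of an event cell-id vector -> list of runs
oracle_runs <- function(cells) {
  runs <- list()
  cur <- cells[1]
  len <- 1L
  start_i <- 1L
  if (length(cells) >= 2) {
    for (i in 2:length(cells)) {
      if (cells[i] == cur) {
        len <- len + 1L
      } else {
        runs[[length(runs) + 1]] <- list(cell = cur, n = len, first = start_i)
        cur <- cells[i]
        len <- 1L
        start_i <- i
      }
    }
  }
  runs[[length(runs) + 1]] <- list(cell = cur, n = len, first = start_i)
  runs
}

# per-event cell key "xi,yi" for a trajectory over a space
oracle_event_keys <- function(traj, space) {
  xs <- traj$events[[space$x$name]]
  ys <- traj$events[[space$y$name]]
  keys <- character(nrow(traj$events))
  for (i in seq_along(keys)) {
    xi <- which(space$x$categories == xs[i])
    yi <- which(space$y$categories == ys[i])
    keys[i] <- paste0(xi, ",", yi)
  }
  keys
}

oracle_event_durs <- function(traj) {
  on <- traj$events$onset
  d <- numeric(length(on))
  for (i in seq_along(on)) {
    d[i] <- (if (i < length(on)) on[i + 1] else traj$offset) - on[i]
  }
  d
}

# event-loop tally of per-cell stats; returns a named list of environments
oracle_cell_tally <- function(traj, space) {
  keys <- oracle_event_keys(traj, space)
  durs <- oracle_event_durs(traj)
  ev <- list(); du <- list(); vi <- list()
  prev_key <- ""
  for (i in seq_along(keys)) {
    k <- keys[i]
    ev[[k]] <- (if (is.null(ev[[k]])) 0 else ev[[k]]) + 1
    du[[k]] <- (if (is.null(du[[k]])) 0 else du[[k]]) + durs[i]
    if (k != prev_key) {
      vi[[k]] <- (if (is.null(vi[[k]])) 0 else vi[[k]]) + 1
    }
    prev_key <- k
  }
  list(events = ev, duration = du, visits = vi)
}

oracle_dispersion <- function(durations, n_cells) {
  tot <- 0
  for (d in durations) tot <- tot + d
  s <- 0
  for (d in durations) s <- s + (d / tot)^2
  1 - (n_cells * s - 1) / (n_cells - 1)
}

oracle_entropy <- function(weights) {
  tot <- 0
  for (w in weights) tot <- tot + w
  h <- 0
  for (w in weights) {
    if (w > 0) h <- h - (w / tot) * log(w / tot)
  }
  h
}

# full structure-measure recomputation from raw events
oracle_grid_measures <- function(traj, space) {
  keys <- oracle_event_keys(traj, space)
  durs <- oracle_event_durs(traj)
  runs <- oracle_runs(keys)
  tal <- oracle_cell_tally(traj, space)
  visit_counts <- unlist(tal$visits)
  dur_by_cell <- unlist(tal$duration)
  all_dur <- c(dur_by_cell, rep(0, space$n_cells - length(dur_by_cell)))
  trans <- character(0)
  if (length(runs) >= 2) {
    for (i in 1:(length(runs) - 1)) {
      trans <- c(trans, paste(runs[[i]]$cell, runs[[i + 1]]$cell, sep = "->"))
    }
  }
  list(
    n_events = length(keys),
    n_visits = length(runs),
    n_transitions = length(runs) - 1,
    cell_range = length(visit_counts),
    dispersion = oracle_dispersion(all_dur, space$n_cells),
    visit_entropy = oracle_entropy(visit_counts),
    duration_entropy = oracle_entropy(dur_by_cell),
    transition_entropy = if (length(trans) > 0) {
      oracle_entropy(as.numeric(table(trans)))
    } else NA_real_
  )
}

# excursion scanner over a visit table (cell, start, duration)
oracle_return <- function(cells, starts, durations, region) {
  inside <- cells %in% region
  n <- length(cells)
  completed_times <- numeric(0)
  completed_visits <- numeric(0)
  censored <- 0L
  i <- 1L
  while (i <= n) {
    if (inside[i] && i < n && !inside[i + 1]) {
      exit_t <- starts[i] + durations[i]
      j <- i + 1L
      outside <- 0L
      while (j <= n && !inside[j]) {
        outside <- outside + 1L
        j <- j + 1L
      }
      if (j <= n) {
        completed_times <- c(completed_times, starts[j] - exit_t)
        completed_visits <- c(completed_visits, outside)
        i <- j
      } else {
        censored <- censored + 1L
        i <- n + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  list(
    n_excursions = length(completed_times) + censored,
    n_censored = censored,
    mean_return_time = if (length(completed_times)) mean(completed_times) else NA_real_,
    mean_return_visits = if (length(completed_visits)) mean(completed_visits) else NA_real_
  )
}

# step-by-step winnowing replay over a named duration vector
oracle_winnow <- function(durations, stop_ratio = 0.5) {
  het <- function(d) {
    e <- mean(d)
    s <- 0
    for (x in d) s <- s + (x - e)^2 / e
    s
  }
  d <- durations
  hets <- het(d)
  sets <- list(names(d))
  repeat {
    lo <- min(d)
    drop <- which(d <= lo + 1e-12)
    if (length(d) - length(drop) < 2) break
    d <- d[-drop]
    hets <- c(hets, het(d))
    sets[[length(sets) + 1]] <- names(d)
  }
  selected <- 0L
  for (k in seq_along(hets)[-1]) {
    prev <- hets[k - 1]
    change <- if (prev > 0) (hets[k] - prev) / prev else if (hets[k] > 0) Inf else 0
    if (!is.na(change) && change >= stop_ratio) selected <- k - 1L
  }
  list(heterogeneity = hets, n_screens = length(hets),
       selected = selected, attractors = sets[[selected + 1]])
}

# stationary duration shares of a semi-Markov chain: embedded stationary
# vector weighted by dwell means (closed form via eigen decomposition)
oracle_stationary_duration <- function(P, dwell_means) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  w <- pi_embed * dwell_means
  w / sum(w)
}
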