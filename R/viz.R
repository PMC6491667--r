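#' Plot a state space grid with a duration-scaled trajectory
#'
#' Draws the classic SSG figure: the grid of all cells, one node per event
#' placed at a seeded-random jitter inside its cell, node area growing with
#' event duration (above a minimum visibility radius), arrows connecting
#' consecutive events in order, and the first event ringed in red. An
#' optional off-scale padding row and column can be drawn in gray, mimicking
#' common SSG software displays; padding is purely visual and never enters
#' any measure. Axis categories follow codebook order unless an explicit
#' reordering is passed — rearranging categories can make a trajectory much
#' easier to read.
#'
#' The returned object separates the *plot specification* (pure data: node
#' positions, radii, arrows) from rendering, so a figure can be reproduced
#' exactly, serialized with [write_plot_spec()], or manually adjusted via
#' `node_offsets` before rendering.
#'
#' @param traj An `ssg_trajectory`.
#' @param space An [make_state_space()] space.
#' @param window Optional `c(t0, t1)` half-open time window to display.
#' @param jitter_seed Integer seed for within-cell node placement.
#' @param order_x,order_y Optional permutations (category label vectors) to
#'   reorder an axis for display.
#' @param node_offsets Optional data frame `(order, dx, dy)` of manual node
#'   nudges in cell units, applied after jitter and clamped to the cell.
#' @param show_padding Draw the gray off-scale padding row/column.
#' @param r_min,r_max Node radius floor and cap, in cell units.
#' @param file Optional output path (`.png` or `.svg`); rendered via
#'   ggplot2.
#' @return An `ssg_plot`: list with `spec` (tibble of nodes), `arrows`,
#'   `space`, `jitter_seed`, `window`, and `plot` (the ggplot object).
#' @export
plot_grid <- function(traj, space, window = NULL, jitter_seed = 1L,
                      order_x = NULL, order_y = NULL, node_offsets = NULL,
                      show_padding = FALSE, r_min = 0.06, r_max = 0.38,
                      file = NULL) {
  stopifnot(inherits(traj, "ssg_trajectory"), inherits(space, "ssg_space"))
  if (!is.null(window)) {
    traj <- slice_trajectory(traj, window[1], window[2])
  }
  ec <- event_cells(traj, space)
  dur <- event_durations(traj)
  n <- nrow(ec)

  xcats <- order_x %||% space$x$categories
  ycats <- order_y %||% space$y$categories
  if (!setequal(xcats, space$x$categories) ||
      !setequal(ycats, space$y$categories)) {
    stop("order_x/order_y must be permutations of the axis categories",
         call. = FALSE)
  }
  px <- match(space$x$categories, xcats)[ec$x]  # display positions
  py <- match(space$y$categories, ycats)[ec$y]

  # area affine in duration above the visibility floor: strictly increasing
  radius <- sqrt(r_min^2 + (r_max^2 - r_min^2) * dur / max(dur))

  # seeded jitter, clamped so node circles stay inside their cell
  # one (dx, dy) draw per node, interleaved so node k's placement does not
  # depend on how many later nodes the window contains (stable across
  # cumulative movie frames)
  jit <- withr::with_seed(as.integer(jitter_seed), {
    u <- stats::runif(2 * n, -1, 1)
    m <- pmax(pmin(0.5 - radius - 0.02, 0.45), 0)
    tibble::tibble(dx = u[seq(1, 2 * n, 2)] * m,
                   dy = u[seq(2, 2 * n, 2)] * m)
  })
  nodes <- tibble::tibble(
    order = seq_len(n),
    cell = ec$cell, x = ec$x, y = ec$y,
    x_label = space$x$categories[ec$x],
    y_label = space$y$categories[ec$y],
    duration = dur, radius = radius,
    cx = px + jit$dx, cy = py + jit$dy,
    first = seq_len(n) == 1L
  )
  if (!is.null(node_offsets)) {
    i <- match(node_offsets$order, nodes$order)
    nodes$cx[i] <- nodes$cx[i] + node_offsets$dx
    nodes$cy[i] <- nodes$cy[i] + node_offsets$dy
    # clamp back into the cell, honoring the node radius
    m <- 0.5 - nodes$radius[i] - 0.02
    nodes$cx[i] <- pmin(pmax(nodes$cx[i], px[i] - m), px[i] + m)
    nodes$cy[i] <- pmin(pmax(nodes$cy[i], py[i] - m), py[i] + m)
  }
  arrows <- if (n >= 2) {
    tibble::tibble(from = seq_len(n - 1), to = seq_len(n - 1) + 1L,
                   x0 = nodes$cx[-n], y0 = nodes$cy[-n],
                   x1 = nodes$cx[-1], y1 = nodes$cy[-1])
  } else {
    tibble::tibble(from = integer(), to = integer(), x0 = numeric(),
                   y0 = numeric(), x1 = numeric(), y1 = numeric())
  }

  p <- render_ssg(nodes, arrows, xcats, ycats, space, show_padding)
  out <- structure(list(spec = nodes, arrows = arrows, space = space,
                        jitter_seed = as.integer(jitter_seed),
                        window = window, plot = p),
                   class = "ssg_plot")
  if (!is.null(file)) save_ssg_plot(out, file)
  out
}

# ggplot2 rendering of a node/arrow spec; padding row/column drawn gray and
# off-scale, never part of the state space.
render_ssg <- function(nodes, arrows, xcats, ycats, space, show_padding) {
  nx <- length(xcats)
  ny <- length(ycats)
  lo <- if (show_padding) 0 else 0.5
  grid_lines <- tibble::tibble(
    x = c(rep(lo, ny + 1), seq(0.5, nx + 0.5, 1)),
    xend = c(rep(nx + 0.5, ny + 1), seq(0.5, nx + 0.5, 1)),
    y = c(seq(0.5, ny + 0.5, 1), rep(lo, nx + 1)),
    yend = c(seq(0.5, ny + 0.5, 1), rep(ny + 0.5, nx + 1))
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = grid_lines,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey70", linewidth = 0.3
    )
  if (show_padding) {
    pad <- tibble::tibble(xmin = c(0, 0), xmax = c(0.5, nx + 0.5),
                          ymin = c(0, 0), ymax = c(ny + 0.5, 0.5))
    p <- p + ggplot2::geom_rect(
      data = pad,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = "grey85", color = "grey70", linewidth = 0.3
    )
  }
  if (nrow(arrows) > 0) {
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                             type = "closed"),
      color = "grey30", linewidth = 0.3
    )
  }
  circle <- function(cx, cy, r, k = 48) {
    th <- seq(0, 2 * pi, length.out = k + 1)
    tibble::tibble(px = cx + r * cos(th), py = cy + r * sin(th))
  }
  discs <- dplyr::bind_rows(lapply(seq_len(nrow(nodes)), function(i) {
    d <- circle(nodes$cx[i], nodes$cy[i], nodes$radius[i])
    d$id <- i
    d$first <- nodes$first[i]
    d
  }))
  if (nrow(discs) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = discs,
      ggplot2::aes(x = .data$px, y = .data$py, group = .data$id,
                   color = .data$first),
      fill = "steelblue", alpha = 0.6, linewidth = 0.6
    ) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                             `TRUE` = "red"),
                                  guide = "none")
  }
  p +
    ggplot2::scale_x_continuous(breaks = seq_len(nx), labels = xcats,
                                limits = c(lo, nx + 0.5),
                                expand = c(0.01, 0.01)) +
    ggplot2::scale_y_continuous(breaks = seq_len(ny), labels = ycats,
                                limits = c(lo, ny + 0.5),
                                expand = c(0.01, 0.01)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = space$x$name, y = space$y$name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @export
print.ssg_plot <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Save a rendered SSG plot to PNG or SVG
#'
#' @param p An `ssg_plot` from [plot_grid()].
#' @param file Output path ending in `.png` or `.svg`.
#' @param width,height,dpi Device size in inches and resolution.
#' @return `file`, invisibly.
#' @export
save_ssg_plot <- function(p, file, width = 6, height = 6, dpi = 120) {
  stopifnot(inherits(p, "ssg_plot"))
  if (grepl("\\.svg$", file, ignore.case = TRUE)) {
    dev <- grDevices::svg
  } else {
    dev <- NULL  # ggsave infers from the extension
  }
  ggplot2::ggsave(file, plot = p$plot, width = width, height = height,
                  dpi = dpi, device = dev)
  invisible(file)
}

#' Serialize / read a plot specification as JSON
#'
#' The node table (positions, radii, order) round-trips through JSON so
#' node placement can be adjusted by hand and re-rendered.
#'
#' @param p An `ssg_plot`.
#' @param path JSON output path.
#' @return `path` invisibly; `read_plot_spec()` returns the node tibble.
#' @export
write_plot_spec <- function(p, path) {
  stopifnot(inherits(p, "ssg_plot"))
  jsonlite::write_json(
    list(jitter_seed = p$jitter_seed,
         window = p$window,
         nodes = p$spec,
         arrows = p$arrows),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_plot_spec
#' @export
read_plot_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(raw$nodes)
}

#' Render cumulative trajectory frames ("movie" export)
#'
#' Writes one image per step: frame `k` shows the window
#' `[start, start + k*step)`, so the grid fills in cumulatively and the
#' final frame equals the full-trajectory plot. Assemble the frames into a
#' video externally if desired.
#'
#' @param traj An `ssg_trajectory`.
#' @param space An [make_state_space()] space.
#' @param step Frame step in seconds (> 0).
#' @param dir Output directory (created if needed).
#' @param jitter_seed Seed shared by all frames so nodes do not move
#'   between frames.
#' @param format `"png"` or `"svg"`.
#' @param ... Passed to [plot_grid()].
#' @return A tibble with one row per frame: `frame`, `t1`, `file`, and a
#'   list-column `spec` of node tables.
#' @export
render_frames <- function(traj, space, step, dir, jitter_seed = 1L,
                          format = c("png", "svg"), ...) {
  stopifnot(inherits(traj, "ssg_trajectory"))
  format <- match.arg(format)
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  start <- traj$events$onset[1]
  total <- traj$offset - start
  n_frames <- ceiling(total / step)
  rows <- lapply(seq_len(n_frames), function(k) {
    t1 <- min(start + k * step, traj$offset)
    file <- file.path(dir, sprintf("frame_%04d.%s", k, format))
    # final frame closes at the offset so the full trajectory is shown
    win <- c(start, if (k == n_frames) traj$offset + 1e-9 else t1)
    p <- plot_grid(traj, space, window = win, jitter_seed = jitter_seed,
                   file = file, ...)
    tibble::tibble(frame = k, t1 = t1, file = file, spec = list(p$spec))
  })
  dplyr::bind_rows(rows)
}
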