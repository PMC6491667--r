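#' Build a two-dimensional state space from a codebook
#'
#' The state space is the Cartesian product of two coded dimensions, drawn
#' as a grid: one axis per dimension, one cell per joint category pair. Axis
#' category order equals codebook order (reordering is a plotting option
#' only, see [plot_grid()]). The space does not have to be square — e.g.
#' 5 speakers by 7 behavior codes gives 35 cells.
#'
#' @param codebook A [codebook()].
#' @param x_dim,y_dim Names of the codebook dimensions to place on the x and
#'   y axis.
#' @return An `ssg_space`: list with `x`, `y` (each `list(name, categories)`)
#'   and `n_cells`.
#' @examples
#' cb <- codebook(speaker = LETTERS[1:5], behavior = letters[1:7])
#' make_state_space(cb, "speaker", "behavior")$n_cells  # 35
#' @export
make_state_space <- function(codebook, x_dim, y_dim) {
  stopifnot(inherits(codebook, "ssg_codebook"))
  check_dimension(codebook, x_dim)
  check_dimension(codebook, y_dim)
  if (identical(x_dim, y_dim)) {
    stop("x and y must be different dimensions", call. = FALSE)
  }
  n <- length(codebook[[x_dim]]) * length(codebook[[y_dim]])
  if (n < 2) {
    stop("state space must have at least 2 cells (got ", n, "); ",
         "grid measures such as dispersion are undefined on a 1-cell space",
         call. = FALSE)
  }
  structure(
    list(
      x = list(name = x_dim, categories = codebook[[x_dim]]),
      y = list(name = y_dim, categories = codebook[[y_dim]]),
      n_cells = n
    ),
    class = "ssg_space"
  )
}

#' @export
print.ssg_space <- function(x, ...) {
  cat("<ssg_space> ", x$x$name, " (", length(x$x$categories), ") x ",
      x$y$name, " (", length(x$y$categories), ") = ", x$n_cells, " cells\n",
      sep = "")
  invisible(x)
}

# Linear 1-based cell index from 1-based axis indices (column-major in x).
cell_index <- function(space, xi, yi) {
  (yi - 1L) * length(space$x$categories) + xi
}

cell_label <- function(space, xi, yi) {
  paste0(space$x$categories[xi], "/", space$y$categories[yi])
}

# All cells of the space as a tibble (x, y indices and labels, linear cell).
all_cells <- function(space) {
  nx <- length(space$x$categories)
  ny <- length(space$y$categories)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  tibble::tibble(
    cell = cell_index(space, g$x, g$y),
    x = as.integer(g$x), y = as.integer(g$y),
    x_label = space$x$categories[g$x],
    y_label = space$y$categories[g$y]
  )[order(cell_index(space, g$x, g$y)), ]
}

# Map a trajectory's events to axis and cell indices over a space.
event_cells <- function(traj, space) {
  xi <- match(traj$events[[space$x$name]], space$x$categories)
  yi <- match(traj$events[[space$y$name]], space$y$categories)
  if (anyNA(xi) || anyNA(yi)) {
    bad <- which(is.na(xi) | is.na(yi))[1]
    stop("event ", bad, " uses a category outside the state space",
         call. = FALSE)
  }
  tibble::tibble(x = as.integer(xi), y = as.integer(yi),
                 cell = cell_index(space, xi, yi))
}
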