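#' Read a GridWare-style .trj trajectory file
#'
#' The `.trj` dialect is UTF-8, tab-separated: a header line
#' `Onset<TAB><dim1><TAB><dim2>...`, then one line per event (onset in
#' decimal seconds plus one category label per dimension), and a final
#' terminal line whose onset is the end of observation. Category cells on
#' the terminal line, if present, are ignored (exported files vary on
#' whether they repeat the last state). Lines starting with `#` are skipped.
#'
#' @param path Path to the file.
#' @param codebook [codebook()] whose dimension names match the header.
#' @param id Trajectory id; defaults to the file name without extension.
#' @return An `ssg_trajectory`.
#' @export
read_trj <- function(path, codebook, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 3) {
    stop("'", path, "': need a header, at least one event row and a ",
         "terminal row", call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (tolower(header[1]) != "onset") {
    stop("'", path, "': first header column must be 'Onset', got '",
         header[1], "'", call. = FALSE)
  }
  dims <- header[-1]
  missing_dims <- setdiff(names(codebook), dims)
  if (length(missing_dims) > 0) {
    stop("'", path, "': header lacks codebook dimension(s): ",
         paste(missing_dims, collapse = ", "), call. = FALSE)
  }

  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(body)
  onset <- vapply(body, function(f) suppressWarnings(as.numeric(f[1])),
                  numeric(1))
  if (anyNA(onset)) {
    bad <- which(is.na(onset))[1]
    stop("'", path, "': row ", bad, ": onset '", body[[bad]][1],
         "' is not a number", call. = FALSE)
  }
  # terminal row: its onset is the observation offset; categories ignored
  offset <- onset[n]
  ev <- tibble::tibble(onset = onset[-n])
  for (j in seq_along(dims)) {
    vals <- vapply(body[-n], function(f) {
      if (length(f) >= j + 1) f[[j + 1]] else NA_character_
    }, character(1))
    ev[[dims[j]]] <- vals
  }
  ev <- ev[, c("onset", names(codebook))]
  trajectory(ev, offset, codebook,
             id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a trajectory as a GridWare-style .trj file
#'
#' Onsets are written with three decimals (millisecond precision); the
#' terminal line repeats no category labels. `read_trj(write_trj(t))`
#' reproduces `t` exactly whenever onsets lie on the millisecond grid, which
#' holds for all trajectories generated by this package.
#'
#' @param traj An `ssg_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trj <- function(traj, path) {
  stopifnot(inherits(traj, "ssg_trajectory"))
  dims <- names(traj$codebook)
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  header <- paste(c("Onset", dims), collapse = "\t")
  rows <- vapply(seq_len(nrow(traj$events)), function(i) {
    paste(c(fmt(traj$events$onset[i]),
            vapply(dims, function(d) traj$events[[d]][i], character(1))),
          collapse = "\t")
  }, character(1))
  terminal <- fmt(traj$offset)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows, terminal), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a long-format table of one or more trajectories
#'
#' The long format is a CSV or TSV with header
#' `trajectory_id,onset,<dim1>,<dim2>,...`. Rows are grouped by
#' `trajectory_id` and sorted by onset within id, so shuffled input is
#' accepted. The end of each trajectory comes either from an optional
#' terminal row per id with empty category cells, or from a uniform
#' `offset` argument applied to every trajectory.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file (delimiter inferred
#'   from the extension; `delim` overrides).
#' @param codebook [codebook()] matching the category columns.
#' @param offset Optional uniform terminal offset (seconds) used for
#'   trajectories without a terminal row.
#' @param delim Optional field delimiter.
#' @return An `ssg_collection`.
#' @export
read_long <- function(path, codebook, offset = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("trajectory_id", "onset", names(codebook))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("'", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$onset <- suppressWarnings(as.numeric(tab$onset))
  if (anyNA(tab$onset)) {
    stop("'", path, "': non-numeric onset in row ",
         which(is.na(tab$onset))[1], call. = FALSE)
  }

  trajs <- lapply(split(tab, factor(tab$trajectory_id,
                                    levels = unique(tab$trajectory_id))),
                  function(g) {
    g <- g[order(g$onset), , drop = FALSE]
    if (anyDuplicated(g$onset)) {
      dup <- g$onset[duplicated(g$onset)][1]
      stop("duplicated (trajectory_id, onset) pair: ('",
           g$trajectory_id[1], "', ", dup, ")", call. = FALSE)
    }
    # terminal row: all category cells empty
    cats <- g[, names(codebook), drop = FALSE]
    is_term <- apply(cats, 1, function(r) all(is.na(r) | !nzchar(trimws(r))))
    off <- offset
    if (nrow(g) >= 1 && is_term[nrow(g)]) {
      off <- g$onset[nrow(g)]
      g <- g[-nrow(g), , drop = FALSE]
      is_term <- is_term[-length(is_term)]
    }
    if (any(is_term)) {
      stop("trajectory '", g$trajectory_id[1], "': row ", which(is_term)[1],
           " has empty category cells but is not terminal", call. = FALSE)
    }
    if (is.null(off)) {
      stop("trajectory '", g$trajectory_id[1], "' has no terminal row and ",
           "no uniform offset was given", call. = FALSE)
    }
    trajectory(g[, c("onset", names(codebook))], off, codebook,
               id = g$trajectory_id[1])
  })
  trajectory_collection(unname(trajs))
}

#' Write a collection (or single trajectory) as a long-format CSV/TSV
#'
#' Emits a terminal row per trajectory (empty category cells at the offset)
#' so the file is self-contained.
#'
#' @param x An `ssg_collection` or single `ssg_trajectory`.
#' @param path Output path (`.tsv`/`.txt` writes tabs, otherwise commas).
#' @return `path`, invisibly.
#' @export
write_long <- function(x, path) {
  if (inherits(x, "ssg_trajectory")) x <- trajectory_collection(list(x))
  stopifnot(inherits(x, "ssg_collection"))
  cb <- x[[1]]$codebook
  rows <- lapply(x, function(t) {
    ev <- t$events
    ev$trajectory_id <- t$id
    term <- ev[1, , drop = FALSE]
    term$onset <- t$offset
    for (d in names(cb)) term[[d]] <- ""
    dplyr::bind_rows(ev, term)[, c("trajectory_id", "onset", names(cb))]
  })
  out <- dplyr::bind_rows(rows)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read every .trj file in a directory as a collection
#'
#' @param dir Directory containing `.trj` files.
#' @param codebook Shared [codebook()].
#' @return An `ssg_collection`, ordered by file name.
#' @export
read_trj_dir <- function(dir, codebook) {
  files <- sort(list.files(dir, pattern = "\\.trj$", full.names = TRUE))
  if (length(files) == 0) stop("no .trj files in ", dir, call. = FALSE)
  trajectory_collection(lapply(files, read_trj, codebook = codebook))
}
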