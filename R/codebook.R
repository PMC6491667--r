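#' Define a codebook of categorical coding dimensions
#'
#' A codebook declares the dimensions of an observational coding scheme and,
#' for each dimension, its ordered list of mutually exclusive and exhaustive
#' category labels. Category order is meaningful: it fixes the axis order when
#' a state space is built from the codebook.
#'
#' @param ... Named character vectors, one per dimension. The name is the
#'   dimension name; the vector holds its ordered category labels.
#' @return An object of class `ssg_codebook`: a named list of character
#'   vectors.
#' @examples
#' cb <- codebook(
#'   talk   = c("support", "idea expression", "neutral statement",
#'              "idea blocking", "criticism"),
#'   energy = c("high negativity", "low negativity", "neutral",
#'              "low positivity", "high positivity")
#' )
#' @export
codebook <- function(...) {
  dims <- list(...)
  if (length(dims) == 0) {
    stop("a codebook needs at least one dimension", call. = FALSE)
  }
  nm <- names(dims)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every dimension must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("dimension names must be unique", call. = FALSE)
  }
  for (d in nm) {
    cats <- dims[[d]]
    if (!is.character(cats) || length(cats) == 0) {
      stop("dimension '", d, "' must be a non-empty character vector",
           call. = FALSE)
    }
    if (any(!nzchar(cats))) {
      stop("dimension '", d, "' has an empty category label", call. = FALSE)
    }
    if (anyDuplicated(cats)) {
      stop("dimension '", d, "' has duplicated category labels", call. = FALSE)
    }
  }
  structure(dims, class = "ssg_codebook")
}

#' Read a codebook from a YAML or JSON file
#'
#' The file maps dimension names to ordered category arrays, e.g.
#' ```yaml
#' speaker: [A, B, C, D, E]
#' behavior: [KnowEx, ProbSolve, Struct, TakeAction, Relat, CMB, Other]
#' ```
#' Array order fixes axis order in downstream grids.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [codebook()] object.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) {
    stop("codebook file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) {
    stop("codebook file must map dimension names to category arrays",
         call. = FALSE)
  }
  raw <- lapply(raw, as.character)
  do.call(codebook, raw)
}

#' Write a codebook to YAML or JSON
#'
#' @param cb A [codebook()] object.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "ssg_codebook"))
  x <- lapply(unclass(cb), as.character)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.ssg_codebook <- function(x, ...) {
  cat("<ssg_codebook> ", length(x), " dimension(s)\n", sep = "")
  for (d in names(x)) {
    cat("  ", d, ": ", paste(x[[d]], collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

dimension_names <- function(cb) names(cb)

check_dimension <- function(cb, name) {
  if (!name %in% names(cb)) {
    stop("unknown dimension '", name, "'; codebook has: ",
         paste(names(cb), collapse = ", "), call. = FALSE)
  }
  invisible(name)
}
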