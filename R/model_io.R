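# Model files are plain-text JSON.  Doubles are stored as strings with 17
# significant digits, which round-trips IEEE-754 doubles bit-for-bit.

.fmt_dbl <- function(x) {
  s <- sprintf("%.17g", x)
  s[is.na(x)] <- "NA"
  s
}

.encode_node <- function(x) {
  if (is.null(x)) {
    list(t = "null")
  } else if (is.list(x)) {
    out <- list(t = "list", items = lapply(unname(x), .encode_node))
    if (!is.null(names(x))) out$names <- as.list(names(x))
    cls <- class(x)
    if (!identical(cls, "list")) out$class <- as.list(cls)
    out
  } else {
    t <- if (is.double(x)) {
      "dbl"
    } else if (is.integer(x)) {
      "int"
    } else if (is.character(x)) {
      "chr"
    } else if (is.logical(x)) {
      "lgl"
    } else {
      stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
    }
    out <- list(t = t,
                v = as.list(if (t == "dbl") .fmt_dbl(x) else
                              as.character(x)))
    if (!is.null(dim(x))) out$dim <- as.list(dim(x))
    if (!is.null(dimnames(x))) {
      out$dimnames <- lapply(dimnames(x), function(e) {
        if (is.null(e)) NA else as.list(e)
      })
    }
    if (is.null(dim(x)) && !is.null(names(x))) out$vnames <- as.list(names(x))
    out
  }
}

.decode_node <- function(node) {
  t <- node$t
  if (t == "null") return(NULL)
  if (t == "list") {
    out <- lapply(node$items, .decode_node)
    if (!is.null(node$names)) names(out) <- as.character(unlist(node$names))
    if (!is.null(node$class)) class(out) <- unlist(node$class)
    return(out)
  }
  v <- as.character(unlist(node$v))
  x <- switch(t,
    dbl = {
      y <- suppressWarnings(as.numeric(v))
      y[v == "NA"] <- NA_real_
      y
    },
    int = as.integer(v),
    chr = v,
    lgl = as.logical(v),
    stop("unknown node type: ", t, call. = FALSE))
  if (!is.null(node$dim)) dim(x) <- unlist(node$dim)
  if (!is.null(node$dimnames)) {
    dimnames(x) <- lapply(node$dimnames, function(e) {
      if (length(e) == 1 && is.logical(unlist(e)[1]) && is.na(unlist(e)[1])) {
        NULL
      } else {
        as.character(unlist(e))
      }
    })
  }
  if (!is.null(node$vnames)) names(x) <- unlist(node$vnames)
  x
}

#' Save a fitted trajectory model to file
#'
#' Writes a self-describing, versioned plain-text (JSON) archive.  All
#' numeric posterior quantities are stored at full precision, so
#' `read_traj_model(write_traj_model(m, path))` reproduces every field
#' bit-for-bit.
#'
#' @param model A `traj_model` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traj_model <- function(model, path) {
  stopifnot(inherits(model, "traj_model"))
  tree <- list(format = "trajvi-model", version = 1L,
               payload = .encode_node(unclass(model)))
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a fitted trajectory model from file
#'
#' @param path Path to a file written by [write_traj_model()].
#' @return A `traj_model` object.
#' @export
read_traj_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e) {
                     stop("cannot parse model file '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (is.null(tree$format) || !identical(tree$format, "trajvi-model")) {
    stop("not a trajvi model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(tree$version), 1L)) {
    stop("unsupported model file version: ", tree$version, call. = FALSE)
  }
  model <- .decode_node(tree$payload)
  class(model) <- "traj_model"
  class(model$prior) <- "traj_prior"
  model
}
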