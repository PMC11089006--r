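# Plain-text dialect: UTF-8, tab-delimited payload plus a JSON sidecar
# `<path>.json` carrying tr_seconds, structure tags, coordinates and (for
# label files) the palette. Grayordinate indexing is documented 0-based in
# sidecars and converted to R's 1-based indexing on read.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, space, extra = list()) {
  meta <- c(list(
    indexing = "0-based",
    n_gray = space$n_gray,
    structure = space$structure,
    coords = unname(apply(space$coords, 1L, function(r) as.numeric(r), simplify = FALSE))
  ), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) abort(paste0("Missing JSON sidecar: ", sp))
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

space_from_sidecar <- function(meta) {
  coords <- matrix(unlist(meta$coords), ncol = 3L, byrow = TRUE)
  gray_space(coords, meta$structure)
}

read_plain_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    abort(sprintf("Row %d has %d fields; expected %d.", bad, widths[bad], widths[1L]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    abort(sprintf("Non-numeric cell in row %d.",
                  ceiling(which(is.na(vals))[1L] / widths[1L])))
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

write_plain_matrix <- function(m, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = "\t")),
             con)
}

#' Read a dense time series
#'
#' @param path File path. For `dialect = "plaintext"` a tab-delimited matrix
#'   (one frame per row) with a `<path>.json` sidecar; for
#'   `dialect = "cifti2"` a CIFTI-2 `.dtseries.nii`.
#' @param dialect One of `"plaintext"`, `"cifti2"`.
#' @return A [dense_timeseries()].
#' @export
read_dense <- function(path, dialect = c("plaintext", "cifti2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "cifti2") return(read_cifti_dense(path))
  meta <- read_sidecar(path)
  if (is.null(meta$tr_seconds)) {
    abort("Sidecar is missing required field 'tr_seconds'.")
  }
  vals <- read_plain_matrix(path)
  dense_timeseries(vals, space_from_sidecar(meta), meta$tr_seconds)
}

#' Write a dense time series
#'
#' @param ts A [dense_timeseries()].
#' @param path Output file path.
#' @param dialect One of `"plaintext"`, `"cifti2"`.
#' @return `path`, invisibly.
#' @export
write_dense <- function(ts, path, dialect = c("plaintext", "cifti2")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "dense_timeseries"))
  if (dialect == "cifti2") return(write_cifti_dense(ts, path))
  write_plain_matrix(ts$values, path)
  write_sidecar(path, ts$space, list(tr_seconds = ts$tr_seconds, kind = "dtseries"))
  invisible(path)
}

#' Read a label map (single or multi-column dialect)
#'
#' Single-column integer files yield a [label_map()]; multi-column binary
#' files (one column per palette network) yield an [overlap_map()].
#'
#' @param path File path.
#' @param dialect One of `"plaintext"`, `"cifti2"`.
#' @return A [label_map()] or [overlap_map()].
#' @export
read_labels <- function(path, dialect = c("plaintext", "cifti2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "cifti2") return(read_cifti_labels(path))
  meta <- read_sidecar(path)
  if (is.null(meta$palette)) abort("Sidecar is missing required field 'palette'.")
  m <- read_plain_matrix(path)
  space <- space_from_sidecar(meta)
  if (ncol(m) == 1L) {
    lab <- as.integer(m[, 1L])
    if (any(lab < 0L | lab > length(meta$palette))) {
      abort(sprintf("Label outside palette range 0..%d found.", length(meta$palette)))
    }
    label_map(lab, space, meta$palette)
  } else {
    if (ncol(m) != length(meta$palette)) {
      abort("Multi-column label file width must equal palette length.")
    }
    overlap_map(t(m), space, meta$palette)
  }
}

#' Write a label map or overlap map
#'
#' @param x A [label_map()] or [overlap_map()].
#' @param path Output file path.
#' @param dialect One of `"plaintext"`, `"cifti2"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path, dialect = c("plaintext", "cifti2")) {
  dialect <- match.arg(dialect)
  if (dialect == "cifti2") return(write_cifti_labels(x, path))
  if (inherits(x, "label_map")) {
    write_plain_matrix(matrix(x$labels, ncol = 1L), path)
    kind <- "dlabel"
  } else if (inherits(x, "overlap_map")) {
    write_plain_matrix(t(x$membership), path)
    kind <- "dlabel_multi"
  } else {
    abort("`x` must be a label_map or overlap_map.")
  }
  write_sidecar(path, x$space, list(palette = x$palette, kind = kind))
  invisible(path)
}

#' Read / write a scalar map in the plain-text dialect
#'
#' @param path File path.
#' @return A [scalar_map()].
#' @export
read_scalar <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  meta <- read_sidecar(path)
  m <- read_plain_matrix(path)
  scalar_map(m[, 1L], space_from_sidecar(meta),
             name = if (!is.null(meta$name)) meta$name else "map")
}

#' @rdname read_scalar
#' @param x A [scalar_map()].
#' @export
write_scalar <- function(x, path) {
  stopifnot(inherits(x, "scalar_map"))
  write_plain_matrix(matrix(x$values, ncol = 1L), path)
  write_sidecar(path, x$space, list(name = x$name, kind = "dscalar"))
  invisible(path)
}
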