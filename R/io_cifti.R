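# Minimal CIFTI-2 I/O: a CIFTI-2 file is a NIfTI-2 container (540-byte
# header, little-endian) whose payload matrix lives in dims 6-7 and whose
# mapping metadata is an XML header extension with ecode 32. Only the three
# dense map types used here (dtseries / dscalar / dlabel) are supported, with
# surface-style brain models. Grayordinate coordinates (which standard CIFTI
# does not carry for surfaces) are stored in the Matrix MetaData so that
# spaces survive a roundtrip.

CIFTI_ECODE <- 32L

struct_to_cifti <- c(LEFT_CORTEX = "CIFTI_STRUCTURE_CORTEX_LEFT",
                     RIGHT_CORTEX = "CIFTI_STRUCTURE_CORTEX_RIGHT",
                     SUBCORTEX = "CIFTI_STRUCTURE_OTHER")

cifti_to_struct <- function(x) {
  switch(x,
         CIFTI_STRUCTURE_CORTEX_LEFT = "LEFT_CORTEX",
         CIFTI_STRUCTURE_CORTEX_RIGHT = "RIGHT_CORTEX",
         "SUBCORTEX")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# --- writer ------------------------------------------------------------

brain_model_xml <- function(space) {
  runs <- rle(space$structure)
  off <- 0L
  out <- character(length(runs$lengths))
  counters <- c(LEFT_CORTEX = 0L, RIGHT_CORTEX = 0L, SUBCORTEX = 0L)
  for (i in seq_along(runs$lengths)) {
    n <- runs$lengths[i]
    tag <- runs$values[i]
    verts <- seq.int(counters[[tag]], length.out = n)
    counters[[tag]] <- counters[[tag]] + n
    out[i] <- paste0(
      '<BrainModel IndexOffset="', off, '" IndexCount="', n,
      '" ModelType="CIFTI_MODEL_TYPE_SURFACE" BrainStructure="',
      struct_to_cifti[[tag]], '" SurfaceNumberOfVertices="',
      sum(space$structure == tag), '">',
      "<VertexIndices>", paste(verts, collapse = " "), "</VertexIndices>",
      "</BrainModel>")
    off <- off + n
  }
  paste0(out, collapse = "")
}

space_metadata_xml <- function(space) {
  coords_json <- jsonlite::toJSON(space$coords, digits = NA)
  paste0("<MetaData><MD><Name>precisionmap_coords</Name><Value>",
         xml_escape(as.character(coords_json)),
         "</Value></MD></MetaData>")
}

cifti_xml <- function(kind, space, n_rows, tr_seconds = NULL,
                      palette = NULL, map_names = NULL) {
  dim0 <- switch(kind,
    dtseries = paste0(
      '<MatrixIndicesMap AppliesToMatrixDimension="0" ',
      'IndicesMapToDataType="CIFTI_INDEX_TYPE_SERIES" NumberOfSeriesPoints="',
      n_rows, '" SeriesExponent="0" SeriesStart="0" SeriesStep="',
      format(tr_seconds, digits = 17), '" SeriesUnit="SECOND" />'),
    dscalar = paste0(
      '<MatrixIndicesMap AppliesToMatrixDimension="0" ',
      'IndicesMapToDataType="CIFTI_INDEX_TYPE_SCALARS">',
      paste0("<NamedMap><MapName>", xml_escape(map_names),
             "</MapName></NamedMap>", collapse = ""),
      "</MatrixIndicesMap>"),
    dlabel = paste0(
      '<MatrixIndicesMap AppliesToMatrixDimension="0" ',
      'IndicesMapToDataType="CIFTI_INDEX_TYPE_LABELS">',
      paste0(vapply(seq_len(n_rows), function(r) {
        paste0("<NamedMap><MapName>", xml_escape(map_names[r]),
               "</MapName><LabelTable>",
               '<Label Key="0" Red="1" Green="1" Blue="1" Alpha="0">???</Label>',
               paste0('<Label Key="', seq_along(palette),
                      '" Red="0.5" Green="0.5" Blue="0.5" Alpha="1">',
                      xml_escape(palette), "</Label>", collapse = ""),
               "</LabelTable></NamedMap>")
      }, character(1L)), collapse = ""),
      "</MatrixIndicesMap>"))
  paste0('<CIFTI Version="2.0"><Matrix>',
         space_metadata_xml(space),
         dim0,
         '<MatrixIndicesMap AppliesToMatrixDimension="1" ',
         'IndicesMapToDataType="CIFTI_INDEX_TYPE_BRAIN_MODELS">',
         brain_model_xml(space),
         "</MatrixIndicesMap></Matrix></CIFTI>")
}

write_nifti2_cifti <- function(path, data_matrix, xml, intent_code, intent_name) {
  n_rows <- nrow(data_matrix)
  n_cols <- ncol(data_matrix)
  xml_raw <- charToRaw(xml)
  esize <- 8L + length(xml_raw)
  pad <- (16L - esize %% 16L) %% 16L
  esize <- esize + pad
  vox_offset <- 540L + 4L + esize

  con <- file(path, open = "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_i64 <- function(x) for (v in x) {
    # 64-bit little-endian from doubles (all values here < 2^31)
    w_i32(v %% 2^32); w_i32(v %/% 2^32)
  }
  w_f64 <- function(x) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  w_raw0 <- function(n) writeBin(raw(n), con)

  w_i32(540L)                                   # sizeof_hdr
  writeBin(c(charToRaw("n+2"), as.raw(c(0, 13, 10, 26, 10))), con)  # magic
  w_i16(16L); w_i16(32L)                        # datatype float32, bitpix
  w_i64(c(6, 1, 1, 1, 1, n_rows, n_cols, 1))    # dim
  w_f64(c(0, 0, 0))                             # intent_p1..3
  w_f64(rep(1, 8))                              # pixdim
  w_i64(vox_offset)                             # vox_offset
  w_f64(c(1, 0, 0, 0, 0, 0))                    # scl_slope..toffset
  w_i64(c(0, 0))                                # slice_start, slice_end
  w_raw0(80L); w_raw0(24L)                      # descrip, aux_file
  w_i32(0L); w_i32(0L)                          # qform_code, sform_code
  w_f64(rep(0, 6))                              # quatern/qoffset
  w_f64(rep(0, 12))                             # srow
  w_i32(0L); w_i32(0L); w_i32(intent_code)      # slice_code, xyzt, intent
  nm <- charToRaw(intent_name)
  writeBin(c(nm, raw(16L - length(nm))), con)   # intent_name
  w_raw0(1L + 15L)                              # dim_info + unused
  writeBin(as.raw(c(1, 0, 0, 0)), con)          # extension flag
  w_i32(esize); w_i32(CIFTI_ECODE)
  writeBin(c(xml_raw, raw(pad)), con)
  # data: row index (time/map) varies fastest on disk
  writeBin(as.numeric(data_matrix), con, size = 4L, endian = "little")
  invisible(path)
}

read_nifti2_cifti <- function(path) {
  raw_all <- readBin(path, what = "raw", n = file.info(path)$size)
  r_i32 <- function(off) readBin(raw_all[(off + 1):(off + 4)], "integer",
                                 size = 4L, endian = "little")
  r_i16 <- function(off) readBin(raw_all[(off + 1):(off + 2)], "integer",
                                 size = 2L, endian = "little")
  r_i64 <- function(off, n = 1L) {
    sapply(seq_len(n) - 1L, function(k) {
      lo <- r_i32(off + 8L * k); hi <- r_i32(off + 8L * k + 4L)
      (lo %% 2^32) + hi * 2^32
    })
  }
  if (r_i32(0L) != 540L) abort("Not a NIfTI-2 / CIFTI-2 file (bad sizeof_hdr).")
  if (rawToChar(raw_all[5:7]) != "n+2") abort("Bad NIfTI-2 magic string.")
  datatype <- r_i16(12L)
  dims <- r_i64(16L, 8L)
  n_rows <- dims[6L]; n_cols <- dims[7L]
  vox_offset <- r_i64(168L)
  # walk extensions
  if (raw_all[541L] != as.raw(1L)) abort("CIFTI-2 file has no header extension.")
  off <- 544L
  xml <- NULL
  while (off + 8L <= vox_offset) {
    esize <- r_i32(off); ecode <- r_i32(off + 4L)
    if (ecode == CIFTI_ECODE) {
      payload <- raw_all[(off + 9L):(off + esize)]
      payload <- payload[payload != as.raw(0L)]
      xml <- rawToChar(payload)
      break
    }
    off <- off + esize
  }
  if (is.null(xml)) abort("No CIFTI XML extension (ecode 32) found.")
  nvals <- n_rows * n_cols
  if (datatype == 16L) {
    vals <- readBin(raw_all[(vox_offset + 1L):length(raw_all)], "numeric",
                    n = nvals, size = 4L, endian = "little")
  } else if (datatype == 64L) {
    vals <- readBin(raw_all[(vox_offset + 1L):length(raw_all)], "numeric",
                    n = nvals, size = 8L, endian = "little")
  } else {
    abort(sprintf("Unsupported CIFTI data type code %d.", datatype))
  }
  list(values = matrix(vals, nrow = n_rows, ncol = n_cols), xml = xml)
}

parse_cifti_xml <- function(xml, n_cols) {
  doc <- xml2::read_xml(xml)
  mims <- xml2::xml_find_all(doc, ".//MatrixIndicesMap")
  get_mim <- function(dim) {
    hit <- mims[vapply(mims, function(m) {
      dims <- xml2::xml_attr(m, "AppliesToMatrixDimension")
      dim %in% trimws(strsplit(dims, ",")[[1L]])
    }, logical(1L))]
    if (length(hit) == 0L) abort(paste0("CIFTI XML lacks a map for dimension ", dim, "."))
    hit[[1L]]
  }
  bm_map <- get_mim("1")
  models <- xml2::xml_find_all(bm_map, ".//BrainModel")
  if (length(models) == 0L) {
    abort("CIFTI XML brain-model map contains no BrainModel elements (missing structure metadata).")
  }
  structure_tags <- character(n_cols)
  for (m in models) {
    off <- as.integer(xml2::xml_attr(m, "IndexOffset"))
    cnt <- as.integer(xml2::xml_attr(m, "IndexCount"))
    bs <- xml2::xml_attr(m, "BrainStructure")
    structure_tags[(off + 1L):(off + cnt)] <- cifti_to_struct(bs)
  }
  # coordinates from our metadata, if present
  mds <- xml2::xml_find_all(doc, ".//Matrix/MetaData/MD")
  coords <- NULL
  for (md in mds) {
    if (xml2::xml_text(xml2::xml_find_first(md, "./Name")) == "precisionmap_coords") {
      coords <- jsonlite::fromJSON(xml2::xml_text(xml2::xml_find_first(md, "./Value")))
    }
  }
  if (is.null(coords)) {
    warn("CIFTI file carries no grayordinate coordinates; using placeholder line geometry.")
    coords <- cbind(seq_len(n_cols), 0, 0)
  }
  row_map <- get_mim("0")
  kind <- xml2::xml_attr(row_map, "IndicesMapToDataType")
  tr <- NULL
  palette <- NULL
  map_names <- NULL
  if (kind == "CIFTI_INDEX_TYPE_SERIES") {
    tr <- as.numeric(xml2::xml_attr(row_map, "SeriesStep"))
    if (is.na(tr)) abort("CIFTI series map is missing required field 'SeriesStep' (TR).")
    unit <- xml2::xml_attr(row_map, "SeriesUnit")
    if (!is.na(unit) && unit == "MSEC") tr <- tr / 1000
  } else {
    nmaps <- xml2::xml_find_all(row_map, ".//NamedMap")
    map_names <- vapply(nmaps, function(nm)
      xml2::xml_text(xml2::xml_find_first(nm, "./MapName")), character(1L))
    if (kind == "CIFTI_INDEX_TYPE_LABELS" && length(nmaps) > 0L) {
      labs <- xml2::xml_find_all(nmaps[[1L]], ".//Label")
      keys <- as.integer(xml2::xml_attr(labs, "Key"))
      names_ <- xml2::xml_text(labs)
      ord <- order(keys)
      palette <- names_[ord][keys[ord] > 0L]
    }
  }
  list(kind = kind, structure = structure_tags, coords = coords,
       tr_seconds = tr, palette = palette, map_names = map_names)
}

# --- dialect entry points ---------------------------------------------

read_cifti_dense <- function(path) {
  f <- read_nifti2_cifti(path)
  meta <- parse_cifti_xml(f$xml, ncol(f$values))
  if (meta$kind != "CIFTI_INDEX_TYPE_SERIES") {
    abort("Expected a dtseries (SERIES row map) CIFTI file.")
  }
  dense_timeseries(f$values, gray_space(meta$coords, meta$structure),
                   meta$tr_seconds)
}

write_cifti_dense <- function(ts, path) {
  xml <- cifti_xml("dtseries", ts$space, nrow(ts$values),
                   tr_seconds = ts$tr_seconds)
  write_nifti2_cifti(path, ts$values, xml, 3002L, "ConnDenseSeries")
}

read_cifti_labels <- function(path) {
  f <- read_nifti2_cifti(path)
  meta <- parse_cifti_xml(f$xml, ncol(f$values))
  if (meta$kind != "CIFTI_INDEX_TYPE_LABELS") {
    abort("Expected a dlabel (LABELS row map) CIFTI file.")
  }
  space <- gray_space(meta$coords, meta$structure)
  if (any(f$values < 0 | f$values > length(meta$palette))) {
    abort(sprintf("Label outside palette range 0..%d found.", length(meta$palette)))
  }
  if (nrow(f$values) == 1L) {
    label_map(as.integer(f$values[1L, ]), space, meta$palette)
  } else {
    overlap_map(f$values, space, meta$palette)
  }
}

write_cifti_labels <- function(x, path) {
  if (inherits(x, "label_map")) {
    data <- matrix(as.numeric(x$labels), nrow = 1L)
    nm <- "labels"
  } else if (inherits(x, "overlap_map")) {
    data <- matrix(as.numeric(x$membership), nrow = nrow(x$membership))
    nm <- x$palette
  } else {
    abort("`x` must be a label_map or overlap_map.")
  }
  xml <- cifti_xml("dlabel", x$space, nrow(data), palette = x$palette,
                   map_names = nm)
  write_nifti2_cifti(path, data, xml, 3007L, "ConnDenseLabel")
}

#' Read / write a scalar map as CIFTI-2 dscalar
#'
#' @param path File path to a `.dscalar.nii`.
#' @return A [scalar_map()].
#' @export
read_cifti_scalar <- function(path) {
  f <- read_nifti2_cifti(path)
  meta <- parse_cifti_xml(f$xml, ncol(f$values))
  if (meta$kind != "CIFTI_INDEX_TYPE_SCALARS") {
    abort("Expected a dscalar (SCALARS row map) CIFTI file.")
  }
  scalar_map(f$values[1L, ], gray_space(meta$coords, meta$structure),
             name = meta$map_names[1L])
}

#' @rdname read_cifti_scalar
#' @param x A [scalar_map()].
#' @export
write_cifti_scalar <- function(x, path) {
  xml <- cifti_xml("dscalar", x$space, 1L, map_names = x$name)
  write_nifti2_cifti(path, matrix(x$values, nrow = 1L), xml,
                     3006L, "ConnDenseScalar")
}
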