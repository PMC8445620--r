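# Minimal GIFTI-1 XML codec. Covers the array intents the toolkit touches:
# POINTSET + TRIANGLE (surfaces), NONE/SHAPE/TIME_SERIES (per-vertex scalars)
# and LABEL (per-vertex integer codes with a label table). Encodings:
# ASCII, Base64Binary and GZipBase64Binary, little- or big-endian.
# Triangle indices are 0-based on disk (GIFTI convention) and 1-based in R.

gifti_type_info <- list(
  NIFTI_TYPE_UINT8   = list(what = "integer", size = 1L, signed = FALSE),
  NIFTI_TYPE_INT32   = list(what = "integer", size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT32 = list(what = "double",  size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT64 = list(what = "double",  size = 8L, signed = TRUE))

decode_gifti_data <- function(node) {
  at <- xml2::xml_attrs(node)
  dtype <- at[["DataType"]]
  info <- gifti_type_info[[dtype]]
  if (is.null(info)) stop("unsupported GIFTI DataType: ", dtype)
  ndim <- as.integer(at[["Dimensionality"]])
  dims <- vapply(seq_len(ndim) - 1L,
                 function(i) as.integer(at[[paste0("Dim", i)]]), integer(1))
  n <- prod(dims)
  enc <- at[["Encoding"]]
  data_node <- xml2::xml_find_first(node, './*[local-name()="Data"]')
  txt <- xml2::xml_text(data_node)
  if (enc == "ASCII") {
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    endian <- if (identical(at[["Endian"]], "BigEndian")) "big" else "little"
    vals <- readBin(raw, what = info$what, n = n, size = info$size,
                    signed = info$signed, endian = endian)
  } else stop("unsupported GIFTI Encoding: ", enc)
  if (length(vals) != n)
    stop("GIFTI data array length ", length(vals), " != expected ", n)
  order <- at[["ArrayIndexingOrder"]]
  if (length(dims) == 2L) {
    vals <- matrix(vals, nrow = dims[1], ncol = dims[2],
                   byrow = !identical(order, "ColumnMajorOrder"))
  }
  list(values = vals, intent = at[["Intent"]], dims = dims)
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, '//*[local-name()="DataArray"]')
  if (length(nodes) == 0) stop("no DataArray elements in '", path, "'")
  arrays <- lapply(nodes, decode_gifti_data)
  # label table, if present
  lab_nodes <- xml2::xml_find_all(doc, '//*[local-name()="Label"]')
  labels <- NULL
  if (length(lab_nodes) > 0) {
    labels <- data.frame(
      key = as.integer(xml2::xml_attr(lab_nodes, "Key")),
      name = xml2::xml_text(lab_nodes),
      stringsAsFactors = FALSE)
  }
  list(arrays = arrays, labels = labels)
}

encode_base64_array <- function(values, dtype) {
  info <- gifti_type_info[[dtype]]
  raw <- writeBin(
    if (info$what == "integer") as.integer(values) else as.numeric(values),
    raw(), size = info$size, endian = "little")
  jsonlite::base64_enc(raw)
}

gifti_data_array <- function(values, intent, dtype) {
  if (is.matrix(values)) {
    dims <- dim(values)
    flat <- as.vector(t(values))  # RowMajorOrder on disk
    dim_attrs <- sprintf(' Dimensionality="2" Dim0="%d" Dim1="%d"',
                         dims[1], dims[2])
  } else {
    flat <- as.vector(values)
    dim_attrs <- sprintf(' Dimensionality="1" Dim0="%d"', length(values))
  }
  paste0(
    '<DataArray Intent="', intent, '" DataType="', dtype,
    '" ArrayIndexingOrder="RowMajorOrder"', dim_attrs,
    ' Encoding="Base64Binary" Endian="LittleEndian"',
    ' ExternalFileName="" ExternalFileOffset="">\n<Data>',
    encode_base64_array(flat, dtype), "</Data>\n</DataArray>")
}

write_gifti_file <- function(path, arrays, label_table = NULL) {
  lt <- ""
  if (!is.null(label_table)) {
    lt <- paste0("<LabelTable>\n",
                 paste0('<Label Key="', label_table$key, '"><![CDATA[',
                        label_table$name, ']]></Label>', collapse = "\n"),
                 "\n</LabelTable>\n")
  }
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="',
                length(arrays), '">\n', lt,
                paste(arrays, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

is_gifti_path <- function(path) grepl("\\.gii(\\.gz)?$", path)

read_gifti_surface <- function(path) {
  g <- read_gifti_arrays(path)
  intents <- vapply(g$arrays, `[[`, "", "intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1L || length(it) != 1L)
    stop("'", path, "' is not a surface GIFTI (needs one pointset and one ",
         "triangle array)")
  triangle_mesh(g$arrays[[ip]]$values, g$arrays[[it]]$values + 1L)
}

write_gifti_surface <- function(mesh, path) {
  arrays <- c(
    gifti_data_array(mesh$vertices, "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT32"),
    gifti_data_array(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32"))
  write_gifti_file(path, arrays)
}

read_gifti_vertex_data <- function(path) {
  g <- read_gifti_arrays(path)
  ar <- g$arrays[[1]]
  vals <- ar$values
  if (identical(ar$intent, "NIFTI_INTENT_LABEL")) storage.mode(vals) <- "integer"
  attr(vals, "labels") <- g$labels
  vals
}

write_gifti_vertex_data <- function(values, path, label = is.integer(values),
                                    label_table = NULL) {
  if (label) {
    if (is.null(label_table)) {
      keys <- sort(unique(as.integer(values)))
      label_table <- data.frame(key = keys, name = paste0("label_", keys))
    }
    arrays <- gifti_data_array(as.integer(values), "NIFTI_INTENT_LABEL",
                               "NIFTI_TYPE_INT32")
    write_gifti_file(path, arrays, label_table = label_table)
  } else {
    arrays <- gifti_data_array(as.numeric(values), "NIFTI_INTENT_NONE",
                               "NIFTI_TYPE_FLOAT32")
    write_gifti_file(path, arrays)
  }
}
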