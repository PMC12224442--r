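## Readers/writers: ASCII-encoded GIFTI functional/label files for surface
## maps, TSV for tables. Kept deliberately minimal; vertex tables and meshes
## travel as TSV.

#' Write a surface data file (GIFTI, ASCII encoding)
#'
#' One data array per column of \code{values}. Functional maps use the
#' float32 type; label maps (\code{intent = "label"}) are written as int32
#' with a label table built from the unique values.
#'
#' @param values numeric vector or vertex-by-map matrix.
#' @param path output file path (conventionally \code{.func.gii} or
#'   \code{.label.gii}).
#' @param intent \code{"func"} or \code{"label"}.
#' @return The path, invisibly.
#' @export
writeGifti <- function(values, path, intent = c("func", "label")) {
  intent <- match.arg(intent)
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(values)))
  if (intent == "label") {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (v in sort(unique(as.integer(values)))) {
      lab <- xml2::xml_add_child(lt, "Label", Key = as.character(v))
      xml2::xml_text(lab) <- paste0("segment_", v)
    }
  }
  for (j in seq_len(ncol(values))) {
    da <- xml2::xml_add_child(
      doc, "DataArray",
      Intent = if (intent == "label") "NIFTI_INTENT_LABEL" else "NIFTI_INTENT_NONE",
      DataType = if (intent == "label") "NIFTI_TYPE_INT32" else "NIFTI_TYPE_FLOAT32",
      ArrayIndexingOrder = "RowMajorOrder",
      Dimensionality = "1", Dim0 = as.character(nrow(values)),
      Encoding = "ASCII", Endian = "LittleEndian")
    dn <- xml2::xml_add_child(da, "Data")
    xml2::xml_text(dn) <- paste(format(values[, j], digits = 9, trim = TRUE),
                                collapse = " ")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a surface data file written by \code{\link{writeGifti}}
#'
#' @param path GIFTI file path (ASCII encoding).
#' @return Numeric matrix, one column per data array.
#' @export
readGifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0) stopUser("no data arrays in %s", path)
  cols <- lapply(arrays, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stopUser("only ASCII-encoded GIFTI is supported (got %s)", enc)
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  })
  do.call(cbind, cols)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
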