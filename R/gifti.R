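# Minimal GIFTI overlay IO (.func.gii / .label.gii) for exchanging
# per-vertex maps with surface-neuroimaging tools. ASCII-encoded
# DataArrays only; surfaces themselves live in the cohort container.

#' Write a per-vertex map as a GIFTI functional overlay
#'
#' @param values numeric per-vertex field.
#' @param path output path (conventionally `.func.gii`).
#' @export
writeGiftiFunc <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = "NIFTI_INTENT_NONE", DataType = "NIFTI_TYPE_FLOAT32",
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(values)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "",
    ExternalFileOffset = "")
  xml2::xml_add_child(da, "Data",
                      paste(format(values, digits = 9, trim = TRUE,
                                   scientific = FALSE),
                            collapse = " "))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI functional or label overlay
#'
#' @param path a `.func.gii` / `.label.gii` file with ASCII encoding.
#' @return numeric (or integer for label intents) per-vertex values of
#'   the first DataArray.
#' @export
readGiftiFunc <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  if (is.na(xml2::xml_attr(da, "Encoding")) ||
      xml2::xml_attr(da, "Encoding") != "ASCII") {
    stop("only ASCII-encoded GIFTI DataArrays are supported")
  }
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  if (grepl("LABEL", xml2::xml_attr(da, "Intent")) ||
      xml2::xml_attr(da, "DataType") == "NIFTI_TYPE_INT32") {
    vals <- as.integer(vals)
  }
  vals
}

#' Write an integer label map as a GIFTI label overlay
#'
#' @param labels integer per-vertex labels (`NA` written as 0).
#' @param path output path (conventionally `.label.gii`).
#' @param names optional label names for the label table.
#' @export
writeGiftiLabel <- function(labels, path, names = NULL) {
  labels[is.na(labels)] <- 0L
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  keys <- sort(unique(as.integer(labels)))
  for (k in keys) {
    lbl <- xml2::xml_add_child(lt, "Label", Key = as.character(k))
    xml2::xml_text(lbl) <- if (!is.null(names) && k > 0 &&
                               k <= length(names)) names[k]
      else paste0("label_", k)
  }
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = "NIFTI_INTENT_LABEL", DataType = "NIFTI_TYPE_INT32",
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(labels)), Encoding = "ASCII",
    Endian = "LittleEndian")
  xml2::xml_add_child(da, "Data", paste(as.integer(labels),
                                        collapse = " "))
  xml2::write_xml(doc, path)
  invisible(path)
}
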