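## CSV dialect everywhere: comma, header row, UTF-8, '.' decimal.

.requireColumns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
}

.numericColumn <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "")
  if (length(bad))
    stop("non-numeric value in column '", col, "' of '", path,
         "' at row ", bad[1])
  out
}

#' Read a segments table
#'
#' @param path CSV with columns \code{id}, \code{length_um},
#'   \code{diameter_um}; optional \code{depth_um}, \code{is_feeder}. Unknown
#'   extra columns are preserved with a message.
#' @return data.frame ready for [buildNetwork()].
#' @examples
#' seg <- readSegmentsTable(system.file("extdata", "example_segments.csv",
#'                                      package = "capnet"))
#' edges <- readEdgesTable(system.file("extdata", "example_edges.csv",
#'                                     package = "capnet"))
#' classifySegments(buildNetwork(seg, edges))
#' @export
readSegmentsTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .requireColumns(df, c("id", "length_um", "diameter_um"), "segments", path)
  df$id <- as.character(df$id)
  for (col in intersect(c("length_um", "diameter_um", "depth_um"), names(df)))
    df[[col]] <- .numericColumn(df, col, path)
  extra <- setdiff(names(df), c("id", "length_um", "diameter_um", "depth_um",
                                "is_feeder"))
  if (length(extra))
    message("segments table: preserving unknown column(s) ",
            paste(extra, collapse = ", "))
  df
}

#' Read a junction (edges) table
#'
#' @param path CSV with columns \code{junction_id}, \code{kind},
#'   \code{parent_id}, \code{daughter1_id}, \code{daughter2_id} (or the
#'   \code{major_id}/\code{minor1_id}/\code{minor2_id} synonyms).
#' @return data.frame ready for [buildNetwork()].
#' @export
readEdgesTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  ok <- all(c("parent_id", "daughter1_id", "daughter2_id") %in% names(df)) ||
    all(c("major_id", "minor1_id", "minor2_id") %in% names(df))
  if (!all(c("junction_id", "kind") %in% names(df)) || !ok)
    .requireColumns(df, c("junction_id", "kind", "parent_id", "daughter1_id",
                          "daughter2_id"), "edges", path)
  df
}

#' Write segments and edges CSVs for a network
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeNetworkTables <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  segPath <- file.path(dir, "segments.csv")
  edgePath <- file.path(dir, "edges.csv")
  utils::write.csv(net@segments, segPath, row.names = FALSE)
  jn <- net@junctions
  names(jn)[names(jn) == "major_id"] <- "parent_id"
  names(jn)[names(jn) == "minor1_id"] <- "daughter1_id"
  names(jn)[names(jn) == "minor2_id"] <- "daughter2_id"
  utils::write.csv(jn, edgePath, row.names = FALSE)
  invisible(c(segments = segPath, edges = edgePath))
}

#' Write and read velocity traces
#'
#' The CSV holds time in seconds in the first column (\code{time_s}) and one
#' column of mm/s samples per segment, headed by the segment id. The
#' sampling rate is recovered from the time column on read.
#'
#' @param traces named list of \linkS4class{VelocityTrace} (equal rates and
#'   lengths).
#' @param path CSV path.
#' @return \code{writeVelocityTraces} invisibly returns \code{path};
#'   \code{readVelocityTraces} returns a named list of
#'   \linkS4class{VelocityTrace}.
#' @export
writeVelocityTraces <- function(traces, path) {
  rate <- traces[[1]]@rate
  n <- length(traces[[1]]@samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rate)
  for (id in names(traces)) df[[id]] <- traces[[id]]@samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVelocityTraces
#' @export
readVelocityTraces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .requireColumns(df, "time_s", "traces", path)
  dt <- diff(df$time_s)
  rate <- round(1 / stats::median(dt))
  ids <- setdiff(names(df), "time_s")
  stats::setNames(lapply(ids, function(id) VelocityTrace(df[[id]], rate)), ids)
}

#' Write and read an OCTA depth stack as multi-page TIFF
#'
#' Pages are ordered by increasing depth; intensities are min-max scaled to
#' [0, 1] for 32-bit float TIFF storage and the original range plus depth
#' labels are kept in a JSON sidecar so the round trip is exact.
#'
#' @param stack a \linkS4class{DepthStack}.
#' @param path TIFF path; the sidecar is written at \code{<path>.json}.
#' @return \code{writeDepthStack} invisibly returns \code{path};
#'   \code{readDepthStack} returns a \linkS4class{DepthStack}.
#' @export
writeDepthStack <- function(stack, path) {
  lo <- min(vapply(stack@slabs, min, numeric(1)))
  hi <- max(vapply(stack@slabs, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(stack@slabs, function(s) (s - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(depth_labels_um = stack@depthLabels,
         slab_thickness_um = stack@slabThickness,
         intensity_min = lo, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDepthStack
#' @export
readDepthStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  slabs <- lapply(pages, function(p) p * meta$intensity_scale + meta$intensity_min)
  DepthStack(slabs, meta$depth_labels_um, meta$slab_thickness_um)
}

#' Write and read ROI masks as a label-image TIFF
#'
#' Masks are merged into one integer label image (0 = background, i = i-th
#' vessel) stored as 16-bit TIFF with the id order in a JSON sidecar.
#'
#' @param masks named list of logical matrices (disjoint ROIs).
#' @param path TIFF path.
#' @return \code{writeMaskLabels} invisibly returns \code{path};
#'   \code{readMaskLabels} returns the named list of logical masks.
#' @export
writeMaskLabels <- function(masks, path) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(ids = names(masks)), paste0(path, ".json"),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeMaskLabels
#' @export
readMaskLabels <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- round(tiff::readTIFF(path) * 65535)
  ids <- meta$ids
  stats::setNames(lapply(seq_along(ids), function(i) lab == i), ids)
}

#' Import per-vessel records from an exported analysis workbook
#'
#' Imports a spreadsheet of per-vessel network and flow variables using an
#' explicit column mapping (the workbook schema is user-defined). XLSX files
#' are read through the readxl package when it is installed; otherwise
#' export the sheet as CSV and point this function at the CSV.
#'
#' @param path XLSX or CSV file.
#' @param columnMap named list/character vector mapping record fields
#'   (\code{vessel_id}, \code{feeder_distance_um}, \code{depth_um},
#'   \code{branch_order}, \code{je_upstream}, \code{je_downstream},
#'   \code{v_ave}, \code{v_min}, \code{v_max}, \code{pulsatility}) to source
#'   column names. \code{vessel_id} is required; unmapped fields become
#'   \code{NA} columns.
#' @param sheet sheet name or index for XLSX input.
#' @return records data.frame suitable for [networkFlowTable()].
#' @export
importVesselRecords <- function(path, columnMap, sheet = 1) {
  columnMap <- unlist(columnMap)
  if (!"vessel_id" %in% names(columnMap))
    stop("columnMap must map the required field 'vessel_id'")
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package; ",
           "export the sheet as CSV instead")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  miss <- setdiff(unname(columnMap), names(df))
  if (length(miss))
    stop("mapped source column(s) absent from '", path, "': ",
         paste(miss, collapse = ", "))
  fields <- c("vessel_id", "feeder_distance_um", "depth_um", "branch_order",
              "je_upstream", "je_downstream", "v_ave", "v_min", "v_max",
              "pulsatility")
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (f in fields) {
    if (f %in% names(columnMap)) {
      x <- df[[columnMap[[f]]]]
      out[[f]] <- if (f == "vessel_id") as.character(x)
                  else suppressWarnings(as.numeric(x))
    } else {
      out[[f]] <- if (f == "vessel_id") NA_character_ else NA_real_
    }
  }
  nblank <- sum(!stats::complete.cases(out[, intersect(names(columnMap),
                                                       fields)]))
  if (nblank)
    message(nblank, " row(s) have blank mapped cells; correlations use ",
            "complete-case deletion per pair")
  out
}
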