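# File formats: TIFF/PNG images, 8-bit label TIFFs with the {0,1,2}
# code contract, CSV tables, JSON run configurations.

#' Read a grayscale DIC image
#'
#' Accepts TIFF or PNG. Multi-channel images are rejected unless all
#' channels are identical (grayscale stored as RGB).
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um physical pixel size to attach.
#' @return A [dic_image()].
#' @export
read_dic_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read_raster(path)
  dic_image(x, pixel_size_um)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(x)) == 3) {
    ch <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
    if (!all(vapply(ch[-1], function(c1) isTRUE(all.equal(c1, ch[[1]])), logical(1))))
      stop("non-grayscale image: channels differ")
    x <- ch[[1]]
  }
  x
}

#' Write a DIC image as 16-bit grayscale TIFF
#'
#' @param image a [dic_image()] (intensities clipped into `[0,1]`).
#' @param path output path.
#' @export
write_dic_image <- function(image, path) {
  stopifnot(inherits(image, "dic_image"))
  tiff::writeTIFF(clip01(image$intensity), path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write three-class label maps as 8-bit TIFF
#'
#' Label maps carry the fixed code contract 0 background, 1 cell, 2 pit,
#' stored as raw 8-bit values. Reading validates the codes and names any
#' offender.
#'
#' @param labels integer matrix with codes in `{0, 1, 2}`.
#' @param path file path.
#' @return `read_labels` returns the integer label matrix.
#' @export
write_labels <- function(labels, path) {
  bad <- setdiff(unique(as.vector(labels)), 0:2)
  if (length(bad)) stop("label map contains invalid code(s): ",
                        paste(sort(bad), collapse = ", "))
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read_raster(path)
  m <- round(x * 255)
  bad <- setdiff(unique(as.vector(m)), 0:2)
  if (length(bad)) stop("label TIFF contains invalid code(s): ",
                        paste(sort(bad), collapse = ", "))
  storage.mode(m) <- "integer"
  m
}

#' Write an instance label map as 16-bit TIFF
#' @param instances integer matrix of instance labels (0 = background).
#' @param path file path.
#' @export
write_instances <- function(instances, path) {
  if (max(instances) > 65535) stop("more than 65535 instances")
  tiff::writeTIFF(instances / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read an object table as CSV
#'
#' One row per cell; the `pit_areas_um2` list-column is serialised as a
#' semicolon-joined string. Column set and order are fixed.
#'
#' @param table an `object_table`.
#' @param path CSV path.
#' @return `read_object_table` returns the table (list-column restored).
#' @export
write_object_table <- function(table, path) {
  flat <- as.data.frame(table)
  flat$pit_areas_um2 <- vapply(table$pit_areas_um2, function(a)
    paste(format(a, trim = TRUE, digits = 10), collapse = ";"), character(1))
  flat$pit_areas_um2[flat$pit_count == 0] <- ""
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  raw <- as.character(flat$pit_areas_um2)
  raw[is.na(raw)] <- ""
  flat$pit_areas_um2 <- I(lapply(strsplit(raw, ";"), function(s) {
    s <- s[nzchar(s)]
    if (length(s) == 0) numeric(0) else as.numeric(s)
  }))
  class(flat) <- c("object_table", "data.frame")
  flat
}

#' Read paired manual/automated %PIT measurements from CSV
#'
#' Required columns: `sample_id`, `manual_percent_pit`,
#' `automated_percent_pit`; missing values are rejected.
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_pairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "manual_percent_pit", "automated_percent_pit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df[need])) stop("paired measurements contain missing values")
  if (nrow(df) < 2) stop("at least 2 pairs are required")
  df[need]
}

#' Write sample results as CSV
#'
#' One row per sample with the fixed column set of a `sample_result`.
#'
#' @param results a `sample_result` or list of them; names become sample
#'   ids.
#' @param path CSV path.
#' @export
write_sample_results <- function(results, path) {
  if (inherits(results, "sample_result")) results <- list(sample = results)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(sample_id = nm,
               n_cells_counted = r$n_cells_counted,
               n_pitted = r$n_pitted,
               percent_pit = r$percent_pit,
               sufficient_count = r$sufficient_count,
               mean_pits_per_pitted_cell = r$mean_pits_per_pitted_cell,
               max_pits_in_one_cell = r$max_pits_in_one_cell,
               mean_pit_size_percent_of_cell = r$mean_pit_size_percent_of_cell,
               excluded_size = as.integer(r$exclusions["excluded_size"]),
               excluded_edge = as.integer(r$exclusions["excluded_edge"]),
               excluded_solidity = as.integer(r$exclusions["excluded_solidity"]),
               spleen_status = r$spleen_status)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a scene's ground truth to a directory
#'
#' Emits the rendered image (16-bit TIFF), the truth label map (8-bit
#' TIFF), the truth statistics (CSV) and the scene configuration (JSON).
#'
#' @param scene an `rbc_scene`.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- render_dic(scene)
  p1 <- file.path(dir, paste0(name, "_dic.tif"))
  p2 <- file.path(dir, paste0(name, "_truth.tif"))
  p3 <- file.path(dir, paste0(name, "_truth_stats.csv"))
  p4 <- file.path(dir, paste0(name, "_config.json"))
  write_dic_image(img, p1)
  write_labels(scene$truth_label_map, p2)
  write.csv(as.data.frame(scene_truth_stats(scene)), p3, row.names = FALSE)
  jsonlite::write_json(unclass(scene$config), p4, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4))
}
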