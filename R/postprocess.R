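# Macro-style object analysis: label map -> filtered per-cell table.
#
# Mirrors the classical ImageJ treatment of a three-channel segmentation:
# split the channels, fill holes in the cell mask, separate adjoining
# cells with a distance-transform watershed, measure every instance,
# then flag cells failing the size / edge / solidity gates.

#' Post-processing configuration
#'
#' @param min_cell_area_um2,max_cell_area_um2 RBC size gate in square
#'   micrometres. Defaults 20-80 um2 bracket a 6-8 um-diameter disk
#'   (~28-50 um2) generously.
#' @param min_solidity minimum solidity (area / convex area) for
#'   inclusion, in (0, 1]. Low-solidity objects are typically platelet
#'   aggregates or cells with attached debris.
#' @param min_pit_area_px minimum connected-component area (pixels) for
#'   a pit to be counted.
#' @param watershed_h merge depth for distance-map peak suppression:
#'   peaks whose dynamic is below `watershed_h` do not seed their own
#'   instance.
#' @param connectivity pixel connectivity for components, 4 or 8.
#' @return A `postprocess_config` object. Cells touching the image edge
#'   are always excluded (fixed policy).
#' @export
postprocess_config <- function(min_cell_area_um2 = 20, max_cell_area_um2 = 80,
                               min_solidity = 0.90, min_pit_area_px = 8,
                               watershed_h = 2, connectivity = 8) {
  if (min_cell_area_um2 >= max_cell_area_um2)
    stop("min_cell_area_um2 must be smaller than max_cell_area_um2")
  if (min_solidity <= 0 || min_solidity > 1)
    stop("min_solidity must lie in (0, 1]")
  if (min_pit_area_px < 1) stop("min_pit_area_px must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(min_cell_area_um2 = min_cell_area_um2,
                 max_cell_area_um2 = max_cell_area_um2,
                 min_solidity = min_solidity,
                 min_pit_area_px = as.integer(min_pit_area_px),
                 watershed_h = watershed_h,
                 edge_policy = TRUE,
                 connectivity = as.integer(connectivity)),
            class = "postprocess_config")
}

#' Split a three-class label map into cell and pit masks
#'
#' Pits are part of their cell: the cell mask is the union of codes 1
#' and 2, the pit mask is code 2 alone.
#'
#' @param labels integer matrix with codes 0 background, 1 cell, 2 pit.
#' @return List of logical matrices `cell_mask`, `pit_mask`.
#' @export
split_channels <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), 0:2)
  if (length(bad))
    stop("label map contains unknown code(s): ", paste(sort(bad), collapse = ", "))
  list(cell_mask = labels >= 1, pit_mask = labels == 2)
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the image border become
#' foreground; border-connected background is untouched.
#'
#' @param cell_mask logical or 0/1 matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(cell_mask) {
  m <- matrix(as.numeric(cell_mask != 0), nrow(cell_mask), ncol(cell_mask))
  as.matrix(EBImage::fillHull(m)) != 0
}

#' Separate adjoining cells with a distance-transform watershed
#'
#' Computes the Euclidean distance transform of the foreground,
#' suppresses peaks shallower than `watershed_h`, and floods the
#' inverted distance map from the surviving peaks, restricted to the
#' mask. Instance labels are renumbered deterministically by centroid
#' (row, then column).
#'
#' @param cell_mask logical matrix.
#' @param config a [postprocess_config()].
#' @return Integer matrix of instance labels (0 = background).
#' @export
separate_cells <- function(cell_mask, config = postprocess_config()) {
  m <- matrix(as.numeric(cell_mask != 0), nrow(cell_mask), ncol(cell_mask))
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = config$watershed_h, ext = 1)
  w <- matrix(as.integer(w), nrow(m), ncol(m))
  relabel_by_centroid(w)
}

relabel_by_centroid <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  idx <- which(lab > 0)
  ri <- ((idx - 1L) %% nrow(lab)) + 1L
  ci <- ((idx - 1L) %/% nrow(lab)) + 1L
  g <- match(lab[idx], ids)
  cy <- tapply(ri, g, mean); cx <- tapply(ci, g, mean)
  ord <- order(cy, cx)
  remap <- integer(length(ids)); remap[ord] <- seq_along(ord)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- remap[g]
  out
}

# solidity: pixel-count area over pixel count of the filled convex hull
# of pixel centres (half-plane test on the hull polygon)
hull_pixel_count <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(n)
  pts <- cbind(cols, rows)            # (x, y)
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 3) return(n)         # collinear pixels
  # orient counter-clockwise (y down: positive signed area = clockwise on
  # screen, but only consistency matters)
  sa <- sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] - hp[c(2:nrow(hp), 1), 1] * hp[, 2])
  if (sa < 0) hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  gr <- rep(r0:r1, times = c1 - c0 + 1)
  gc <- rep(c0:c1, each = r1 - r0 + 1)
  inside <- rep(TRUE, length(gr))
  tol <- 1e-9
  for (k in seq_len(nrow(hp))) {
    k2 <- if (k == nrow(hp)) 1L else k + 1L
    ex <- hp[k2, 1] - hp[k, 1]; ey <- hp[k2, 2] - hp[k, 2]
    cross <- ex * (gr - hp[k, 2]) - ey * (gc - hp[k, 1])
    inside <- inside & (cross >= -tol)
  }
  sum(inside)
}

#' Measure cell instances and their pits
#'
#' Per instance: area (pixels, converted to um2 via the squared pixel
#' size), solidity (pixel area / convex-hull pixel area), centroid
#' (0-based row/col), an edge flag (any pixel on the image border), and
#' the pits: connected components of `pit_mask` within the instance with
#' at least `min_pit_area_px` pixels.
#'
#' @param cell_labels integer instance label matrix
#'   (from [separate_cells()]).
#' @param pit_mask logical matrix, same geometry.
#' @param pixel_size_um physical pixel size.
#' @param config a [postprocess_config()].
#' @return An `object_table`: data frame with one row per instance,
#'   ordered by centroid (row, then column), columns `cell_id`,
#'   `area_um2`, `area_px`, `solidity`, `centroid_row`, `centroid_col`,
#'   `touches_edge`, `pit_count`, `pit_area_sum_um2` and list-column
#'   `pit_areas_um2`. Rows are unfiltered; see [apply_filters()].
#' @export
measure_cells <- function(cell_labels, pit_mask, pixel_size_um,
                          config = postprocess_config()) {
  if (!identical(dim(cell_labels), dim(pit_mask))) stop("geometry mismatch")
  h <- nrow(cell_labels); w <- ncol(cell_labels)
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  px2 <- pixel_size_um^2
  rows <- lapply(ids, function(id) {
    idx <- which(cell_labels == id)
    ri <- ((idx - 1L) %% h) + 1L
    ci <- ((idx - 1L) %/% h) + 1L
    area_px <- length(idx)
    hull_px <- hull_pixel_count(ri, ci)
    sol <- min(1, area_px / hull_px)
    # pits inside this instance (bounding-box local labelling)
    r0 <- min(ri); r1 <- max(ri); c0 <- min(ci); c1 <- max(ci)
    sub_cells <- cell_labels[r0:r1, c0:c1, drop = FALSE]
    sub_pits <- pit_mask[r0:r1, c0:c1, drop = FALSE] & (sub_cells == id)
    pit_areas_px <- integer(0)
    if (any(sub_pits)) {
      pl <- label_components(sub_pits, config$connectivity)
      sizes <- tabulate(pl[pl > 0])
      pit_areas_px <- sizes[sizes >= config$min_pit_area_px]
    }
    data.frame(cell_id = NA_integer_,
               area_um2 = area_px * px2,
               area_px = area_px,
               solidity = sol,
               centroid_row = mean(ri) - 1,
               centroid_col = mean(ci) - 1,
               touches_edge = any(ri == 1L | ri == h | ci == 1L | ci == w),
               pit_count = length(pit_areas_px),
               pit_area_sum_um2 = sum(pit_areas_px) * px2,
               pit_areas_um2 = I(list(pit_areas_px * px2)))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else empty_object_table()
  if (nrow(tab)) {
    ord <- order(tab$centroid_row, tab$centroid_col)
    tab <- tab[ord, , drop = FALSE]
    tab$cell_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  attr(tab, "pixel_size_um") <- pixel_size_um
  attr(tab, "config") <- config
  class(tab) <- c("object_table", "data.frame")
  tab
}

empty_object_table <- function() {
  data.frame(cell_id = integer(0), area_um2 = numeric(0), area_px = integer(0),
             solidity = numeric(0), centroid_row = numeric(0),
             centroid_col = numeric(0), touches_edge = logical(0),
             pit_count = integer(0), pit_area_sum_um2 = numeric(0),
             pit_areas_um2 = I(list()))
}

#' Flag cells failing the inclusion gates
#'
#' Assigns each record a status with precedence size, then edge, then
#' solidity (the first failing gate is recorded); no record is deleted.
#'
#' @param table an `object_table` from [measure_cells()].
#' @param config a [postprocess_config()].
#' @return The table with a `status` column
#'   (`included` / `excluded_size` / `excluded_edge` /
#'   `excluded_solidity`).
#' @export
apply_filters <- function(table, config = postprocess_config()) {
  status <- rep("included", nrow(table))
  bad_size <- table$area_um2 < config$min_cell_area_um2 |
    table$area_um2 > config$max_cell_area_um2
  bad_edge <- table$touches_edge & config$edge_policy
  bad_sol <- table$solidity < config$min_solidity
  status[bad_sol] <- "excluded_solidity"
  status[bad_edge] <- "excluded_edge"
  status[bad_size] <- "excluded_size"
  table$status <- status
  table
}

#' Full macro analysis of a label map
#'
#' Runs [split_channels()], [fill_holes()], [separate_cells()],
#' [measure_cells()] and [apply_filters()] in sequence. Pit pixels are
#' merged into the cell mask before hole filling so pits never read as
#' holes.
#'
#' @param labels integer label matrix with codes 0/1/2.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param config a [postprocess_config()].
#' @return A filtered `object_table`.
#' @export
analyze_labels <- function(labels, pixel_size_um,
                           config = postprocess_config()) {
  ch <- split_channels(labels)
  cm <- fill_holes(ch$cell_mask)
  inst <- separate_cells(cm, config)
  tab <- measure_cells(inst, ch$pit_mask, pixel_size_um, config)
  apply_filters(tab, config)
}

#' @export
print.object_table <- function(x, ...) {
  cat(sprintf("object_table: %d instance(s)\n", nrow(x)))
  if ("status" %in% names(x) && nrow(x)) print(table(x$status))
  NextMethod()
}
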