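# Macro stages: channel split, hole filling, watershed, measurement, gates.

test_that("channel split follows the pit-is-part-of-cell rule", {
  empty <- matrix(0L, 10, 10)
  ch <- split_channels(empty)
  expect_false(any(ch$cell_mask)); expect_false(any(ch$pit_mask))

  m <- matrix(0L, 12, 12); m[4:9, 4:9] <- 1L; m[6:7, 6:7] <- 2L
  ch <- split_channels(m)
  expect_true(all(ch$cell_mask[4:9, 4:9]))
  expect_identical(sum(ch$pit_mask), 4L)

  set.seed(2)
  r <- matrix(sample(0:2, 100, TRUE), 10, 10)
  ch <- split_channels(r)
  for (i in 1:10) for (j in 1:10) {
    expect_identical(ch$cell_mask[i, j], r[i, j] >= 1L)
    expect_identical(ch$pit_mask[i, j], r[i, j] == 2L)
  }
  m[1, 1] <- 7L
  expect_error(split_channels(m), "unknown code")
})

test_that("hole filling matches a border flood-fill oracle", {
  disk <- disk_mask(21, 21, 11, 11, 7)
  expect_identical(fill_holes(disk), disk)
  annulus <- disk & !disk_mask(21, 21, 11, 11, 4)
  expect_identical(fill_holes(annulus), disk)

  set.seed(4)
  blobs <- matrix(runif(40 * 40) < 0.45, 40, 40)
  filled <- fill_holes(blobs)
  # oracle: label background 4-connected; components containing a border
  # pixel stay background, everything else is foreground
  bg_lab <- bfs_label(!blobs, connectivity = 4)
  border_ids <- unique(c(bg_lab[1, ], bg_lab[40, ], bg_lab[, 1], bg_lab[, 40]))
  oracle <- !(bg_lab %in% setdiff(border_ids, 0L) & !blobs)
  oracle <- matrix(oracle, 40, 40)
  expect_identical(filled, oracle)
})

test_that("watershed separation agrees with a two-seed region-growing oracle", {
  mask <- disk_mask(60, 100, 30, 30, 20) | disk_mask(60, 100, 30, 70, 20)
  inst <- separate_cells(mask, postprocess_config())
  ids <- setdiff(unique(as.vector(inst)), 0L)
  expect_length(ids, 2)
  one_disk <- sum(disk_mask(60, 100, 30, 30, 20))
  areas <- vapply(ids, function(i) sum(inst == i), numeric(1))
  expect_true(all(abs(areas - one_disk) / one_disk <= 0.05))
  # oracle: every foreground pixel joins the nearer of the two seeds
  idx <- which(mask)
  ri <- ((idx - 1) %% 60) + 1; ci <- ((idx - 1) %/% 60) + 1
  d1 <- (ri - 30)^2 + (ci - 30)^2; d2 <- (ri - 30)^2 + (ci - 70)^2
  oracle <- ifelse(d1 <= d2, 1L, 2L)
  got <- inst[idx]
  # match labels by majority overlap, then require near-total agreement
  map <- vapply(1:2, function(k) {
    as.integer(names(which.max(table(oracle[got == k]))))
  }, integer(1))
  expect_gte(mean(map[got] == oracle), 0.97)
})

test_that("a single blob is never split and the peak bound holds", {
  disk <- disk_mask(50, 50, 25, 25, 15)
  inst <- separate_cells(disk, postprocess_config())
  expect_identical(sort(unique(as.vector(inst))), c(0L, 1L))

  set.seed(6)
  blob <- disk_mask(60, 60, 25, 25, 13) | disk_mask(60, 60, 38, 36, 11)
  inst <- separate_cells(blob, postprocess_config())
  # instances never exceed the number of (plateau-merged) distance maxima
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(blob), 60, 60)))
  is_max <- blob
  for (o in pitcount:::neighbour_offsets(8))
    is_max <- is_max & (d >= pitcount:::shift_mat(d, o[1], o[2]))
  n_peaks <- max(bfs_label(is_max & blob, 8))
  expect_lte(max(inst), n_peaks)
  # conservation: every foreground pixel gets exactly one label
  expect_identical(sum(inst > 0), sum(blob))
})

test_that("pit counting inside instances respects the minimum area", {
  lab <- matrix(0L, 40, 40); lab[disk_mask(40, 40, 20, 20, 15)] <- 1L
  pits <- matrix(FALSE, 40, 40)
  pits[19:20, 14:15] <- TRUE        # 4 px
  pits[24:26, 24] <- TRUE           # 3 px
  tab <- measure_cells(lab, pits, 0.1, postprocess_config(min_pit_area_px = 1))
  expect_identical(tab$pit_count, 2L)
  expect_equal(tab$pit_area_sum_um2, 7 * 0.01)
  tab4 <- measure_cells(lab, pits, 0.1, postprocess_config(min_pit_area_px = 4))
  expect_identical(tab4$pit_count, 1L)
  expect_error(measure_cells(lab, matrix(FALSE, 4, 4), 0.1), "mismatch")
})

test_that("solidity matches a brute-force convex-hull oracle", {
  # plus-shaped instance: clearly non-convex
  plus <- matrix(FALSE, 30, 30)
  plus[13:18, 6:25] <- TRUE
  plus[6:25, 13:18] <- TRUE
  lab <- matrix(0L, 30, 30); lab[plus] <- 1L
  tab <- measure_cells(lab, matrix(FALSE, 30, 30), 0.1, postprocess_config())
  expect_lt(tab$solidity, 0.9)
  # oracle: a pixel centre is inside the hull iff adding it leaves the
  # hull vertex set unchanged
  idx <- which(plus)
  pr <- ((idx - 1) %% 30) + 1; pc <- ((idx - 1) %/% 30) + 1
  pts <- cbind(pc, pr)
  hull_vertices <- sort(paste(pts[chull(pts), 1], pts[chull(pts), 2]))
  inside <- 0L
  for (i in 1:30) for (j in 1:30) {
    cand <- rbind(pts, c(j, i))
    if (identical(sort(paste(cand[chull(cand), 1], cand[chull(cand), 2])),
                  hull_vertices)) inside <- inside + 1L
  }
  expect_equal(tab$solidity, sum(plus) / inside, tolerance = 1e-9)
  expect_lte(tab$solidity, 1 + 1e-9)
})

test_that("edge contact and centroid ordering are recorded", {
  lab2 <- matrix(0L, 30, 30)
  lab2[15:20, 1] <- 1L                     # strip on the left border
  tab <- measure_cells(lab2, matrix(FALSE, 30, 30), 0.1, postprocess_config())
  expect_true(tab$touches_edge[1])
  # ordering: two disks, the upper-left one must come first
  lab3 <- matrix(0L, 40, 40)
  lab3[disk_mask(40, 40, 30, 30, 6)] <- 1L
  lab3[disk_mask(40, 40, 10, 10, 6)] <- 2L
  tab3 <- measure_cells(lab3, matrix(FALSE, 40, 40), 0.1, postprocess_config())
  expect_identical(tab3$cell_id, 1:2)
  expect_lt(tab3$centroid_row[1], tab3$centroid_row[2])
})

test_that("filters assign statuses with size > edge > solidity precedence", {
  mk_row <- function(area, edge, sol) data.frame(
    cell_id = 1L, area_um2 = area, area_px = 100L, solidity = sol,
    centroid_row = 1, centroid_col = 1, touches_edge = edge, pit_count = 0L,
    pit_area_sum_um2 = 0, pit_areas_um2 = I(list(numeric(0))))
  cfg <- postprocess_config()
  tab <- rbind(mk_row(120, FALSE, 0.99),  # WBC-sized
               mk_row(40, TRUE, 0.99),    # edge
               mk_row(40, FALSE, 0.5),    # aggregate-like solidity
               mk_row(40, TRUE, 0.5),     # edge + solidity -> edge
               mk_row(120, TRUE, 0.5),    # everything -> size
               mk_row(40, FALSE, 0.99))   # clean
  out <- apply_filters(tab, cfg)
  expect_identical(out$status, c("excluded_size", "excluded_edge",
                                 "excluded_solidity", "excluded_edge",
                                 "excluded_size", "included"))
  empty <- apply_filters(tab[0, ], cfg)
  expect_identical(nrow(empty), 0L)
})

test_that("a fused-disk aggregate is excluded by solidity, a disk is not", {
  # L-shaped chain of fused small disks, the shape of a platelet aggregate
  fused <- disk_mask(50, 60, 15, 15, 8) | disk_mask(50, 60, 15, 29, 8) |
    disk_mask(50, 60, 15, 43, 8) | disk_mask(50, 60, 29, 15, 8)
  lab <- matrix(0L, 50, 60); lab[fused] <- 1L
  tab <- apply_filters(measure_cells(lab, matrix(FALSE, 50, 60), 0.2,
                                     postprocess_config()),
                       postprocess_config())
  expect_identical(tab$status, "excluded_solidity")
  disk <- matrix(0L, 40, 60); disk[disk_mask(40, 60, 20, 30, 12)] <- 1L
  tab2 <- apply_filters(measure_cells(disk, matrix(FALSE, 40, 60), 0.3,
                                      postprocess_config()),
                        postprocess_config())
  expect_identical(tab2$status, "included")
})

test_that("tightening any gate never adds included cells", {
  sc <- sample_scene(toy_clean_config(41, n_cells = 9))
  tab <- analyze_labels(sc$truth_label_map, 0.1)
  n_inc <- function(cfg) sum(apply_filters(tab, cfg)$status == "included")
  base <- postprocess_config()
  for (s in c(0.5, 0.9, 0.95, 0.99, 1)) {
    tighter <- postprocess_config(min_solidity = s)
    expect_lte(n_inc(tighter), n_inc(postprocess_config(min_solidity = max(0.01, s - 0.2))))
  }
  wide <- postprocess_config(min_cell_area_um2 = 10, max_cell_area_um2 = 100)
  narrow <- postprocess_config(min_cell_area_um2 = 30, max_cell_area_um2 = 45)
  expect_lte(n_inc(narrow), n_inc(wide))
})

test_that("truth label maps pass through the macro unchanged", {
  for (seed in c(51, 52)) {
    sc <- sample_scene(toy_clean_config(seed, n_cells = 8))
    tab <- analyze_labels(sc$truth_label_map, 0.1)
    expect_identical(nrow(tab), 8L)
    expect_true(all(tab$status == "included"))
    expect_identical(sort(tab$pit_count),
                     sort(unname(sc$per_cell_pit_counts)))
    st <- scene_truth_stats(sc)
    expect_equal(pit_count_percent(tab, 8)$percent_pit, st$percent_pit)
  }
})
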