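# Scene generator: placement, pit assignment, truth consistency, rendering.

test_that("degenerate scene configurations behave as stated", {
  sc0 <- sample_scene(toy_scene_config(1, n_cells = 0))
  expect_length(sc0$objects, 0)
  expect_true(all(sc0$truth_label_map == 0L))
  expect_true(is.na(scene_truth_stats(sc0)$percent_pit))

  scp0 <- sample_scene(toy_scene_config(2, n_cells = 6, pitted_fraction = 0))
  expect_true(all(scp0$per_cell_pit_counts == 0L))
  expect_identical(scene_truth_stats(scp0)$percent_pit, 0)
})

test_that("pitted-cell count follows the binomial draw", {
  # coarse pixel size so 1000 cells fit a desk-scale image; one pit per
  # pitted cell keeps crater placement feasible in the small cells
  cfg <- scene_config(image_height_px = 700, image_width_px = 700,
                      pixel_size_um = 0.5, n_cells = 1000,
                      pitted_fraction = 0.3, pits_per_pitted_cell_mean = 1,
                      seed = 42)
  sc <- sample_scene(cfg)
  n_pitted <- sum(sc$per_cell_pit_counts >= 1)
  # central 99.7% interval of Binomial(1000, 0.3): 300 +/- 44
  expect_gte(n_pitted, 256)
  expect_lte(n_pitted, 344)
})

test_that("identical config and seed reproduce scene and render bit-identically", {
  cfg <- toy_scene_config(7)
  s1 <- sample_scene(cfg); s2 <- sample_scene(cfg)
  expect_identical(s1$truth_label_map, s2$truth_label_map)
  expect_identical(s1$per_cell_pit_counts, s2$per_cell_pit_counts)
  expect_identical(render_dic(s1)$intensity, render_dic(s2)$intensity)
})

test_that("truth label map is consistent with object and pit masks", {
  sc <- sample_scene(toy_scene_config(13, n_cells = 7))
  truth <- sc$truth_label_map
  # rebuild the map from the object list
  rebuilt <- matrix(0L, nrow(truth), ncol(truth))
  for (o in sc$objects) rebuilt[o$mask] <- 1L
  for (o in sc$objects) for (pm in o$pits) rebuilt[pm] <- 2L
  expect_identical(truth, rebuilt)
  # regroup pit pixels of the map by containing cell: counts must match
  pit_lab <- pitcount:::label_components(truth == 2L, 8)
  for (o in sc$objects) {
    ids <- setdiff(unique(pit_lab[o$mask]), 0L)
    expect_identical(length(ids), length(o$pits))
    # and pit pixels lie strictly inside the parent mask
    for (pm in o$pits) expect_true(all(pm %in% o$mask))
  }
})

test_that("raising pitted_fraction never removes pitted cells (shared stream)", {
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8), function(pf) {
    sc <- sample_scene(toy_scene_config(3, n_cells = 8, pitted_fraction = pf))
    sum(sc$per_cell_pit_counts >= 1)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("an overfull scene fails with an informative density error", {
  cfg <- scene_config(image_height_px = 120, image_width_px = 120,
                      pixel_size_um = 0.1, n_cells = 40, seed = 1)
  expect_error(sample_scene(cfg), "coverage")
})

test_that("rendering an empty scene gives a flat half-intensity image", {
  sc <- sample_scene(toy_clean_config(4, n_cells = 0))
  img <- render_dic(sc)
  expect_equal(img$intensity, matrix(0.5, 380, 380), tolerance = 1e-12)
  # defocus blur of a constant image stays constant
  sc2 <- sample_scene(toy_scene_config(4, n_cells = 0, noise_sigma = 0))
  expect_equal(max(abs(render_dic(sc2)$intensity - 0.5)), 0, tolerance = 1e-10)
})

test_that("shear-axis rendering is antisymmetric for a centred cell", {
  # hand-built scene: one RBC exactly centred in an odd-sized image,
  # shear along +x, no blur, no noise
  cfg <- scene_config(image_height_px = 201, image_width_px = 201,
                      pixel_size_um = 0.1, n_cells = 1, pitted_fraction = 0,
                      defocus_sigma_px = 0, noise_sigma = 0,
                      shear_angle_deg = 0, seed = 1)
  centre <- 101; r <- 35
  obj <- list(id = "rbc_001", class = "rbc",
              params = list(cy = centre, cx = centre, r_px = r),
              mask = pitcount:::disk_indices(centre, centre, r, 201, 201),
              pits = list(), pit_params = list())
  truth <- matrix(0L, 201, 201); truth[obj$mask] <- 1L
  scene <- structure(list(objects = list(obj), truth_label_map = truth,
                          per_cell_pit_counts = c(rbc_001 = 0L), config = cfg),
                     class = "rbc_scene")
  dev <- colSums(render_dic(scene)$intensity - 0.5)
  for (d in 1:(r + 2)) expect_equal(dev[centre + d], -dev[centre - d], tolerance = 1e-9)
})

test_that("truth statistics equal an independent recount of the object list", {
  sc <- sample_scene(toy_scene_config(17, n_cells = 9))
  st <- scene_truth_stats(sc)
  # brute-force recount
  rbcs <- Filter(function(o) o$class == "rbc", sc$objects)
  counts <- vapply(rbcs, function(o) length(o$pits), integer(1))
  expect_identical(st$n_rbc, length(rbcs))
  expect_identical(st$n_pitted, sum(counts >= 1))
  expect_equal(st$percent_pit, 100 * sum(counts >= 1) / length(rbcs))
  expect_equal(st$mean_pits_per_pitted_cell, mean(counts[counts >= 1]))
  expect_equal(st$max_pits_in_one_cell, max(counts))
  fracs <- unlist(lapply(rbcs, function(o)
    vapply(o$pits, function(p) 100 * length(p) / length(o$mask), numeric(1))))
  expect_equal(st$mean_pit_size_percent_of_cell, mean(fracs))
})

test_that("hand-assembled two-cell scene yields the stated arithmetic", {
  cfg <- toy_clean_config(1, n_cells = 2)
  mk_obj <- function(id, cy, cx, r, npits) {
    mask <- pitcount:::disk_indices(cy, cx, r, 380, 380)
    pits <- if (npits > 0) lapply(seq_len(npits), function(k)
      pitcount:::disk_indices(cy, cx - 10 + 8 * k, 2.5, 380, 380)) else list()
    list(id = id, class = "rbc", params = list(cy = cy, cx = cx, r_px = r),
         mask = mask, pits = pits, pit_params = list())
  }
  objs <- list(mk_obj("rbc_001", 80, 80, 30, 0), mk_obj("rbc_002", 200, 200, 30, 2))
  truth <- matrix(0L, 380, 380)
  for (o in objs) truth[o$mask] <- 1L
  for (o in objs) for (pm in o$pits) truth[pm] <- 2L
  scene <- structure(list(objects = objs, truth_label_map = truth,
                          per_cell_pit_counts = c(rbc_001 = 0L, rbc_002 = 2L),
                          config = cfg), class = "rbc_scene")
  st <- scene_truth_stats(scene)
  expect_equal(st$percent_pit, 50)
  expect_equal(st$mean_pits_per_pitted_cell, 2)
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(pitted_fraction = 1.2), "pitted_fraction")
  expect_error(scene_config(pit_radius_um_range = c(0.4, 0.2)), "pit_radius")
  expect_error(scene_config(artefact_rates = list(wbc = -1)), "rates")
  expect_error(scene_config(artefact_rates = list(nonsense = 1)), "unknown")
  expect_error(scene_config(pits_per_pitted_cell_mean = 0.5), "pits_per_pitted")
})
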