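# Shared fixtures, built in code and memoised for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small, fast scene for unit tests (0.1 um/px keeps cells ~60 px across)
toy_scene_config <- function(seed, n_cells = 8, pitted_fraction = 0.5, ...) {
  scene_config(image_height_px = 380, image_width_px = 380, pixel_size_um = 0.1,
               n_cells = n_cells, pitted_fraction = pitted_fraction,
               touching_fraction = 0, seed = seed, ...)
}

# noiseless, blur-free variant for exact checks
toy_clean_config <- function(seed, n_cells = 8, ...) {
  toy_scene_config(seed, n_cells, defocus_sigma_px = 0, noise_sigma = 0, ...)
}

# classifier trained on a single noiseless, blur-free scene (background
# exactly uniform 0.5)
toy_clean_classifier <- function() {
  fixture("toy_clean_classifier", function() {
    scene <- sample_scene(toy_clean_config(31))
    img <- render_dic(scene)
    clf <- pit_classifier(img, scene$truth_label_map, n_trees = 30,
                          pixel_cap = 3000, seed = 5)
    list(scene = scene, img = img, clf = clf)
  })
}

toy_classifier <- function() {
  fixture("toy_classifier", function() {
    scenes <- lapply(21:22, function(s) sample_scene(toy_scene_config(s)))
    pit_classifier(lapply(scenes, render_dic),
                   lapply(scenes, `[[`, "truth_label_map"),
                   n_trees = 30, pixel_cap = 3000, seed = 5)
  })
}

# study conditions of the end-to-end recovery experiment: 50-cell scenes,
# default pitted fraction / noise / defocus, 0.1 um/px
recovery_scene_config <- function(seed) {
  scene_config(image_height_px = 800, image_width_px = 800, pixel_size_um = 0.1,
               n_cells = 50, pitted_fraction = 0.3, seed = seed)
}

# trained classifier + held-out predictions for the recovery experiment
# (built once; reused by the segmentation-quality and recovery tests)
recovery_fixture <- function() {
  fixture("recovery", function() {
    train <- lapply(1:6, function(s) sample_scene(recovery_scene_config(s)))
    clf <- pit_classifier(lapply(train, render_dic),
                          lapply(train, `[[`, "truth_label_map"), seed = 11)
    held_out <- lapply(101:106, function(s) {
      scene <- sample_scene(recovery_scene_config(s))
      list(scene = scene, prediction = predict(clf, render_dic(scene)))
    })
    list(classifier = clf, held_out = held_out)
  })
}

# binary disk mask (matrix builder used by postprocess fixtures)
disk_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# independent connected-component labeller (breadth-first flood fill),
# used as an oracle against the package's labelling-based measurements
bfs_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1) %% h) + 1; pc <- ((p - 1) %/% h) + 1
      for (k in seq_len(nrow(offs))) {
        nr <- pr + offs[k, 1]; nc <- pc + offs[k, 2]
        if (nr >= 1 && nr <= h && nc >= 1 && nc <= w) {
          q <- (nc - 1) * h + nr
          if (mask[q] && lab[q] == 0) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}
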