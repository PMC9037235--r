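# Synthetic DIC erythrocyte scenes with exhaustive ground truth.
#
# A scene is a set of non-overlapping objects (biconcave RBCs, a
# configurable fraction of them pitted, plus optional confounders:
# platelets adjoining cells, fused platelet aggregates, white blood
# cells, wrinkled cells, debris). The renderer turns the scene's height
# map into a DIC-like relief image: intensity = 0.5 + gain x directional
# derivative of height along the shear axis, followed by defocus blur
# and additive noise.

# Evans-Fung biconcave thickness coefficients (normalised to cell radius).
.BICONCAVE <- c(C0 = 0.207, C1 = 2.003, C2 = -1.123)
# Intensity gain per (um height / px) of shear-axis slope; fixed so that a
# default RBC rim spans roughly 0.3 intensity units.
.DIC_GAIN <- 0.5

#' Scene configuration for the synthetic DIC simulator
#'
#' Defines the study conditions under which synthetic scenes are drawn.
#' All geometry is physical (micrometres) and converted to pixels through
#' `pixel_size_um`.
#'
#' @param image_height_px,image_width_px image size in pixels (>= 16).
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#'   The default 0.065 um/px corresponds to a x100/1.46 oil objective with
#'   a typical sCMOS camera.
#' @param n_cells number of red blood cells to place (>= 0).
#' @param pitted_fraction probability in `[0,1]` that a cell bears pits.
#' @param pits_per_pitted_cell_mean mean number of pits on a pitted cell
#'   (>= 1); a pitted cell receives `1 + Poisson(mean - 1)` pits.
#' @param cell_radius_um_range range (min, max) of RBC radii in um.
#' @param pit_radius_um_range range (min, max) of pit crater radii in um.
#'   The default (0.2, 0.4) um yields pits covering roughly 0.2-0.8% of
#'   the parent cell's area, the size class seen in clinical material.
#' @param artefact_rates named list of expected counts per scene for the
#'   confounder classes `platelet_on_cell`, `platelet_aggregate`, `wbc`,
#'   `wrinkled_cell`, `debris` (Poisson-distributed; defaults all 0 so
#'   that confounders are opt-in).
#' @param touching_fraction fraction of cells placed tangent to an
#'   already-placed cell (masks adjacent but non-overlapping), to
#'   exercise watershed separation.
#' @param defocus_sigma_px isotropic Gaussian blur applied to the
#'   rendered image, in pixels (>= 0).
#' @param noise_sigma standard deviation of additive zero-mean Gaussian
#'   intensity noise (>= 0).
#' @param shear_angle_deg DIC shear direction, degrees from the +x
#'   (column) axis, y pointing down.
#' @param seed integer RNG seed; identical `(config, seed)` reproduce
#'   scenes, renders and statistics bit-identically.
#'
#' @return A validated `scene_config` object (a named list).
#' @seealso [sample_scene()], [render_dic()]
#' @export
scene_config <- function(image_height_px = 1200, image_width_px = 1200,
                         pixel_size_um = 0.065,
                         n_cells = 50, pitted_fraction = 0.3,
                         pits_per_pitted_cell_mean = 1.5,
                         cell_radius_um_range = c(3.0, 4.0),
                         pit_radius_um_range = c(0.2, 0.4),
                         artefact_rates = list(),
                         touching_fraction = 0.1,
                         defocus_sigma_px = 1, noise_sigma = 0.02,
                         shear_angle_deg = 45, seed = 1L) {
  rates <- list(platelet_on_cell = 0, platelet_aggregate = 0, wbc = 0,
                wrinkled_cell = 0, debris = 0)
  if (length(artefact_rates)) {
    bad <- setdiff(names(artefact_rates), names(rates))
    if (length(bad)) stop("unknown artefact class(es): ", paste(bad, collapse = ", "))
    rates[names(artefact_rates)] <- artefact_rates
  }
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              pixel_size_um = pixel_size_um,
              n_cells = as.integer(n_cells),
              pitted_fraction = pitted_fraction,
              pits_per_pitted_cell_mean = pits_per_pitted_cell_mean,
              cell_radius_um_range = as.numeric(cell_radius_um_range),
              pit_radius_um_range = as.numeric(pit_radius_um_range),
              artefact_rates = rates,
              touching_fraction = touching_fraction,
              defocus_sigma_px = defocus_sigma_px,
              noise_sigma = noise_sigma,
              shear_angle_deg = shear_angle_deg,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$image_height_px >= 16, cfg$image_width_px >= 16,
            cfg$pixel_size_um > 0, cfg$n_cells >= 0)
  if (cfg$pitted_fraction < 0 || cfg$pitted_fraction > 1)
    stop("pitted_fraction must lie in [0,1]")
  if (cfg$pits_per_pitted_cell_mean < 1)
    stop("pits_per_pitted_cell_mean must be >= 1")
  for (nm in c("cell_radius_um_range", "pit_radius_um_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2])
      stop(nm, " must be (min, max) with 0 < min <= max")
  }
  if (any(unlist(cfg$artefact_rates) < 0)) stop("artefact rates must be >= 0")
  if (cfg$touching_fraction < 0 || cfg$touching_fraction > 1)
    stop("touching_fraction must lie in [0,1]")
  stopifnot(cfg$defocus_sigma_px >= 0, cfg$noise_sigma >= 0)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("DIC scene configuration\n")
  cat(sprintf("  image: %d x %d px at %.3f um/px\n", x$image_height_px,
              x$image_width_px, x$pixel_size_um))
  cat(sprintf("  cells: %d (pitted fraction %.2f, %.2f pits/pitted cell)\n",
              x$n_cells, x$pitted_fraction, x$pits_per_pitted_cell_mean))
  ar <- unlist(x$artefact_rates)
  if (any(ar > 0))
    cat("  artefact rates:", paste(names(ar)[ar > 0], ar[ar > 0],
                                   sep = "=", collapse = ", "), "\n")
  cat(sprintf("  defocus %.1f px, noise sd %.3f, shear %.0f deg, seed %d\n",
              x$defocus_sigma_px, x$noise_sigma, x$shear_angle_deg, x$seed))
  invisible(x)
}

# pixel indices of a disk of radius r (px) centred at (cy, cx), clipped to
# the image; returns linear indices into an h x w matrix
disk_indices <- function(cy, cx, r, h, w) {
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - cy)^2, (cc - cx)^2, `+`)
  inside <- d2 <= r^2
  (rep(cc, each = length(rr))[inside] - 1L) * h + rep(rr, times = length(cc))[inside]
}

# can a disk at (cy,cx,r) be placed given placed objects (data.frame with
# cy,cx,extent)? `gap` is the minimum centre-distance slack in px;
# `ignore` exempts one partner (for tangent placements)
placement_ok <- function(cy, cx, r, placed, gap, h, w, margin = 2, ignore = 0L) {
  if (cy - r < margin + 1 || cy + r > h - margin ||
      cx - r < margin + 1 || cx + r > w - margin) return(FALSE)
  if (!nrow(placed)) return(TRUE)
  keep <- seq_len(nrow(placed)) != ignore
  if (!any(keep)) return(TRUE)
  d <- sqrt((placed$cy[keep] - cy)^2 + (placed$cx[keep] - cx)^2)
  all(d >= placed$extent[keep] + r + gap)
}

#' Draw a ground-truth scene from a scene configuration
#'
#' Places `n_cells` biconcave RBCs without mask overlap (except the
#' configured tangent fraction), assigns pits (`1 + Poisson(mean - 1)`
#' per pitted cell, craters strictly inside the cell rim), adds
#' confounder objects at their Poisson rates, and populates the
#' three-class truth label map (0 background, 1 cell, 2 pit; pit
#' overrides cell overrides background).
#'
#' @param config a [scene_config()].
#' @return An `rbc_scene`: list with `objects` (id, class, pixel mask,
#'   pit masks, render parameters), `truth_label_map` (integer matrix),
#'   `per_cell_pit_counts` (named integer vector over RBC ids), and the
#'   generating `config`.
#' @export
sample_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  set.seed(config$seed)
  h <- config$image_height_px; w <- config$image_width_px
  ps <- config$pixel_size_um
  n <- config$n_cells

  # primary draws come first so that the pitted-cell assignment sees the
  # same random stream irrespective of later placement randomness
  r_cell <- runif(n, config$cell_radius_um_range[1], config$cell_radius_um_range[2]) / ps
  u_pit <- runif(n)
  pitted <- u_pit < config$pitted_fraction
  k_all <- 1L + rpois(n, config$pits_per_pitted_cell_mean - 1)
  k_pits <- ifelse(pitted, k_all, 0L)

  placed <- data.frame(cy = numeric(0), cx = numeric(0), extent = numeric(0))
  objects <- list()
  add_placed <- function(cy, cx, extent) {
    placed[nrow(placed) + 1L, ] <<- list(cy, cx, extent)
  }
  density_error <- function(what, i) {
    cov <- sum(pi * placed$extent^2) / (h * w)
    stop(sprintf(paste0("failed to place %s %d after bounded retries; ",
                        "achieved %d objects at ~%.0f%% area coverage - ",
                        "reduce n_cells/artefact rates or enlarge the image"),
                 what, i, nrow(placed), 100 * cov))
  }

  n_touch <- if (n > 1) as.integer(floor(config$touching_fraction * n)) else 0L
  touch_set <- if (n_touch > 0) (n - n_touch + 1L):n else integer(0)

  place_tangent <- function(r, partners) {
    # tangent to a random already-placed partner; centre distance padded by
    # >= 0.5 px so pixel masks stay disjoint while remaining adjacent
    for (attempt in 1:200) {
      j <- if (length(partners) == 1) partners else sample(partners, 1)
      ang <- runif(1, 0, 2 * pi)
      for (delta in c(0.5, 1, 1.5, 2)) {
        d <- placed$extent[j] + r + delta
        cy <- placed$cy[j] + d * sin(ang); cx <- placed$cx[j] + d * cos(ang)
        if (placement_ok(cy, cx, r, placed, gap = 2, h, w, ignore = j))
          return(c(cy, cx))
      }
    }
    NULL
  }
  place_free <- function(r, tries = 600) {
    for (attempt in seq_len(tries)) {
      cy <- runif(1, r + 3, h - r - 2); cx <- runif(1, r + 3, w - r - 2)
      if (placement_ok(cy, cx, r, placed, gap = 3, h, w)) return(c(cy, cx))
    }
    NULL
  }

  for (i in seq_len(n)) {
    r <- r_cell[i]
    pos <- if (i %in% touch_set && nrow(placed) > 0)
      place_tangent(r, seq_len(nrow(placed))) else place_free(r)
    if (is.null(pos)) density_error("cell", i)
    add_placed(pos[1], pos[2], r)
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("rbc_%03d", i), class = "rbc",
      params = list(cy = pos[1], cx = pos[2], r_px = r),
      mask = disk_indices(pos[1], pos[2], r, h, w), pits = list(),
      pit_params = list())
  }

  # confounders, Poisson counts at the configured rates
  rates <- config$artefact_rates
  n_art <- list(platelet_on_cell = rpois(1, rates$platelet_on_cell),
                platelet_aggregate = rpois(1, rates$platelet_aggregate),
                wbc = rpois(1, rates$wbc),
                wrinkled_cell = rpois(1, rates$wrinkled_cell),
                debris = rpois(1, rates$debris))
  rbc_rows <- seq_len(n)

  for (i in seq_len(n_art$platelet_on_cell)) {
    r <- runif(1, 0.6, 1.1) / ps
    pos <- if (n > 0) place_tangent(r, rbc_rows) else place_free(r)
    if (is.null(pos)) density_error("platelet_on_cell", i)
    add_placed(pos[1], pos[2], r)
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("plt_%03d", i), class = "platelet",
      params = list(cy = pos[1], cx = pos[2], r_px = r),
      mask = disk_indices(pos[1], pos[2], r, h, w), pits = list(), pit_params = list())
  }
  for (i in seq_len(n_art$platelet_aggregate)) {
    m <- sample(2:4, 1)
    rs <- runif(m, 0.6, 1.0) / ps
    ext <- sum(rs[1] + 1.6 * max(rs))   # coarse cluster extent bound
    pos <- place_free(ext)
    if (is.null(pos)) density_error("platelet_aggregate", i)
    members <- data.frame(cy = pos[1], cx = pos[2], r = rs[1])
    for (k in seq_len(m - 1)) {
      b <- sample(nrow(members), 1); ang <- runif(1, 0, 2 * pi)
      d <- 0.8 * (members$r[b] + rs[k + 1])      # overlapping: fused cluster
      members[nrow(members) + 1L, ] <- list(members$cy[b] + d * sin(ang),
                                            members$cx[b] + d * cos(ang), rs[k + 1])
    }
    add_placed(pos[1], pos[2], ext)
    mask <- sort(unique(unlist(lapply(seq_len(nrow(members)), function(k)
      disk_indices(members$cy[k], members$cx[k], members$r[k], h, w)))))
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("agg_%03d", i), class = "platelet_aggregate",
      params = list(members = members), mask = mask, pits = list(), pit_params = list())
  }
  for (i in seq_len(n_art$wbc)) {
    r <- runif(1, 4.6, 6.0) / ps
    pos <- place_free(r)
    if (is.null(pos)) density_error("wbc", i)
    add_placed(pos[1], pos[2], r)
    nb <- 8
    bumps <- data.frame(dy = runif(nb, -0.6, 0.6) * r, dx = runif(nb, -0.6, 0.6) * r,
                        sd = runif(nb, 0.10, 0.22) * r, amp = runif(nb, 0.15, 0.40))
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("wbc_%03d", i), class = "wbc",
      params = list(cy = pos[1], cx = pos[2], r_px = r, bumps = bumps),
      mask = disk_indices(pos[1], pos[2], r, h, w), pits = list(), pit_params = list())
  }
  for (i in seq_len(n_art$wrinkled_cell)) {
    r <- runif(1, config$cell_radius_um_range[1], config$cell_radius_um_range[2]) / ps
    pos <- place_free(r)
    if (is.null(pos)) density_error("wrinkled_cell", i)
    add_placed(pos[1], pos[2], r)
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("wrk_%03d", i), class = "wrinkled_rbc",
      params = list(cy = pos[1], cx = pos[2], r_px = r,
                    n_ridges = sample(5:8, 1), phase = runif(1, 0, 2 * pi),
                    ridge_amp = 0.30),
      mask = disk_indices(pos[1], pos[2], r, h, w), pits = list(), pit_params = list())
  }
  for (i in seq_len(n_art$debris)) {
    r <- max(1.2, runif(1, 0.15, 0.35) / ps)
    pos <- if (n > 0) place_tangent(r, rbc_rows) else place_free(r)
    if (is.null(pos)) density_error("debris", i)
    add_placed(pos[1], pos[2], r)
    objects[[length(objects) + 1L]] <- list(
      id = sprintf("deb_%03d", i), class = "debris",
      params = list(cy = pos[1], cx = pos[2], r_px = r),
      mask = disk_indices(pos[1], pos[2], r, h, w), pits = list(), pit_params = list())
  }

  # pits: hemispherical craters strictly inside the parent rim, pairwise
  # separated so each pit is its own connected component
  rmin_pit <- config$pit_radius_um_range[1] / ps
  rmax_pit <- config$pit_radius_um_range[2] / ps
  for (i in seq_len(n)) {
    k <- k_pits[i]
    if (k == 0) next
    obj <- objects[[i]]
    centres <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    for (p in seq_len(k)) {
      ok <- FALSE
      for (attempt in 1:150) {
        rp <- runif(1, rmin_pit, rmax_pit)
        rho_max <- obj$params$r_px - rp - 2
        if (rho_max <= 0) next
        rho <- sqrt(runif(1)) * rho_max; ang <- runif(1, 0, 2 * pi)
        cy <- obj$params$cy + rho * sin(ang); cx <- obj$params$cx + rho * cos(ang)
        if (nrow(centres) == 0 ||
            all(sqrt((centres$cy - cy)^2 + (centres$cx - cx)^2) >= centres$r + rp + 3)) {
          centres[nrow(centres) + 1L, ] <- list(cy, cx, rp); ok <- TRUE; break
        }
      }
      if (!ok) stop(sprintf("failed to place pit %d/%d in cell %s: cell too crowded",
                            p, k, obj$id))
    }
    obj$pit_params <- lapply(seq_len(nrow(centres)), function(p)
      list(cy = centres$cy[p], cx = centres$cx[p], r_px = centres$r[p]))
    obj$pits <- lapply(obj$pit_params, function(pp)
      disk_indices(pp$cy, pp$cx, pp$r_px, h, w))
    objects[[i]] <- obj
  }

  truth <- matrix(0L, h, w)
  for (obj in objects) truth[obj$mask] <- 1L
  for (obj in objects) for (pm in obj$pits) truth[pm] <- 2L

  counts <- vapply(objects[seq_len(n)], function(o) length(o$pits), integer(1))
  names(counts) <- vapply(objects[seq_len(n)], `[[`, character(1), "id")

  structure(list(objects = objects, truth_label_map = truth,
                 per_cell_pit_counts = counts, config = config),
            class = "rbc_scene")
}

#' @export
print.rbc_scene <- function(x, ...) {
  cls <- vapply(x$objects, `[[`, character(1), "class")
  cat(sprintf("rbc_scene: %d x %d px, %d objects\n",
              nrow(x$truth_label_map), ncol(x$truth_label_map), length(x$objects)))
  if (length(cls)) print(table(cls))
  n_rbc <- sum(cls == "rbc")
  if (n_rbc)
    cat(sprintf("  pitted RBCs: %d / %d\n", sum(x$per_cell_pit_counts >= 1), n_rbc))
  invisible(x)
}

# object-specific height contributions, in micrometres
height_profile <- function(obj, h, w, ps) {
  add <- function(hmap, cy, cx, r, f) {
    r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
    c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
    rr <- r0:r1; cc <- c0:c1
    dy <- outer(rr - cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cx)
    d <- sqrt(dy^2 + dx^2)
    prof <- f(d, dy, dx)
    prof[d > r] <- 0
    hmap[rr, cc] <- pmax(hmap[rr, cc], prof)
    hmap
  }
  biconcave <- function(d, r) {
    rho2 <- pmin(1, (d / r)^2)
    (r * ps) * sqrt(pmax(0, 1 - rho2)) *
      (.BICONCAVE[1] + .BICONCAVE[2] * rho2 + .BICONCAVE[3] * rho2^2) / 2
  }
  function(hmap) {
    p <- obj$params
    switch(obj$class,
      rbc = add(hmap, p$cy, p$cx, p$r_px, function(d, dy, dx) biconcave(d, p$r_px)),
      wrinkled_rbc = add(hmap, p$cy, p$cx, p$r_px, function(d, dy, dx) {
        rho <- pmin(1, d / p$r_px)
        theta <- atan2(dy, dx)
        biconcave(d, p$r_px) +
          p$ridge_amp * sin(p$n_ridges * theta + p$phase) *
            2 * rho * sqrt(pmax(0, 1 - rho^2))
      }),
      platelet = add(hmap, p$cy, p$cx, p$r_px, function(d, dy, dx)
        0.9 * sqrt(pmax(0, 1 - (d / p$r_px)^2))),
      platelet_aggregate = {
        for (k in seq_len(nrow(p$members))) {
          mk <- p$members[k, ]
          hmap <- add(hmap, mk$cy, mk$cx, mk$r, function(d, dy, dx)
            0.9 * sqrt(pmax(0, 1 - (d / mk$r)^2)))
        }
        hmap
      },
      wbc = add(hmap, p$cy, p$cx, p$r_px, function(d, dy, dx) {
        base <- 2.2 * sqrt(pmax(0, 1 - (d / p$r_px)^2))^0.7
        for (k in seq_len(nrow(p$bumps))) {
          b <- p$bumps[k, ]
          base <- base + b$amp * exp(-((dy - b$dy)^2 + (dx - b$dx)^2) / (2 * b$sd^2))
        }
        base
      }),
      debris = add(hmap, p$cy, p$cx, p$r_px, function(d, dy, dx)
        0.6 * sqrt(pmax(0, 1 - (d / p$r_px)^2))),
      stop("unknown object class: ", obj$class))
  }
}

#' Render a scene as a DIC-like intensity image
#'
#' Builds a physical height map (biconcave RBC profiles, hemispherical
#' pit craters subtracted, distinct profiles per confounder class) and
#' renders `intensity = 0.5 + gain x d(height)/d(shear axis)` with the
#' gain fixed so cell rims span about 0.3 intensity units, then applies
#' isotropic defocus blur and additive Gaussian noise, clipping to
#' `[0, 1]`.
#'
#' @param scene an `rbc_scene` from [sample_scene()].
#' @param config scene configuration; defaults to the one stored in the
#'   scene (must share its geometry).
#' @return A [dic_image()] (intensity matrix in `[0,1]` plus pixel size).
#' @export
render_dic <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "rbc_scene"))
  h <- config$image_height_px; w <- config$image_width_px
  if (!identical(dim(scene$truth_label_map), c(h, w)))
    stop("scene and config geometry differ")
  ps <- config$pixel_size_um
  hmap <- matrix(0, h, w)
  for (obj in scene$objects) hmap <- height_profile(obj, h, w, ps)(hmap)
  # crater subtraction: sharp-rimmed hemispherical depressions
  for (obj in scene$objects) {
    for (pp in obj$pit_params) {
      idx <- disk_indices(pp$cy, pp$cx, pp$r_px, h, w)
      if (!length(idx)) next
      ri <- ((idx - 1L) %% h) + 1L; ci <- ((idx - 1L) %/% h) + 1L
      d2 <- (ri - pp$cy)^2 + (ci - pp$cx)^2
      depth <- 2.0 * sqrt(pmax(0, pp$r_px^2 - d2)) * ps
      hmap[idx] <- hmap[idx] - depth
    }
  }
  a <- config$shear_angle_deg * pi / 180
  dcol <- (hmap[, c(2:w, w)] - hmap[, c(1, 1:(w - 1))]) / 2
  drow <- (hmap[c(2:h, h), ] - hmap[c(1, 1:(h - 1)), ]) / 2
  img <- 0.5 + .DIC_GAIN * (cos(a) * dcol + sin(a) * drow)
  if (config$defocus_sigma_px > 0) img <- gaussian_blur(img, config$defocus_sigma_px)
  if (config$noise_sigma > 0) {
    set.seed(derive_seed(config$seed, 1L))
    img <- img + rnorm(length(img), 0, config$noise_sigma)
  }
  dic_image(clip01(img), ps)
}

#' Construct a DIC image object
#'
#' @param intensity 2-D numeric matrix, nominal range `[0,1]`, finite,
#'   at least 16 px on each side.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return A `dic_image` (list with `intensity` and `pixel_size_um`).
#' @export
dic_image <- function(intensity, pixel_size_um) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) < 16 || ncol(intensity) < 16)
    stop("image must be at least 16 x 16 px")
  if (!all(is.finite(intensity))) stop("image intensities must be finite")
  stopifnot(pixel_size_um > 0)
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um),
            class = "dic_image")
}

#' @export
print.dic_image <- function(x, ...) {
  cat(sprintf("dic_image: %d x %d px at %.3f um/px, intensity [%.3f, %.3f]\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Ground-truth summary statistics of a scene
#'
#' Computes, over RBC-class objects only, the true %PIT (share of RBCs
#' bearing at least one pit), mean pits per pitted cell, the maximum pit
#' count in one cell, and the mean pit size as a percentage of the parent
#' cell's area. Ratios with empty denominators are returned as `NA`
#' (explicit "undefined" marker).
#'
#' @param scene an `rbc_scene`.
#' @return Named list: `n_rbc`, `n_pitted`, `percent_pit`,
#'   `mean_pits_per_pitted_cell`, `max_pits_in_one_cell`,
#'   `mean_pit_size_percent_of_cell`.
#' @export
scene_truth_stats <- function(scene) {
  stopifnot(inherits(scene, "rbc_scene"))
  rbcs <- Filter(function(o) o$class == "rbc", scene$objects)
  n_rbc <- length(rbcs)
  counts <- vapply(rbcs, function(o) length(o$pits), integer(1))
  n_pitted <- sum(counts >= 1)
  pit_frac <- unlist(lapply(rbcs, function(o) {
    if (!length(o$pits)) return(numeric(0))
    100 * vapply(o$pits, length, integer(1)) / length(o$mask)
  }))
  list(n_rbc = n_rbc,
       n_pitted = n_pitted,
       percent_pit = if (n_rbc > 0) 100 * n_pitted / n_rbc else NA_real_,
       mean_pits_per_pitted_cell = if (n_pitted > 0) mean(counts[counts >= 1]) else NA_real_,
       max_pits_in_one_cell = if (n_rbc > 0) max(counts) else NA_real_,
       mean_pit_size_percent_of_cell = if (length(pit_frac)) mean(pit_frac) else NA_real_)
}
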