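# Multi-scale filter-bank features for pixel classification.

#' Feature-bank configuration
#'
#' The pixel classifier sees, per pixel, one plane per (feature kind,
#' smoothing scale) pair: Gaussian-smoothed intensity, gradient
#' magnitude, Laplacian, the two Hessian eigenvalues, and local variance,
#' each computed on the image smoothed at every requested scale.
#'
#' @param scales_px Gaussian smoothing scales in pixels (>= 1 scale).
#' @param intensity,gradient,laplacian,hessian,variance logical flags
#'   enabling each feature kind; at least two kinds must stay enabled.
#' @return A `feature_config` object.
#' @export
feature_config <- function(scales_px = c(1, 2, 4, 8), intensity = TRUE,
                           gradient = TRUE, laplacian = TRUE,
                           hessian = TRUE, variance = TRUE) {
  kinds <- c(intensity = intensity, gradient = gradient, laplacian = laplacian,
             hessian = hessian, variance = variance)
  if (length(scales_px) < 1) stop("at least one scale is required")
  if (any(scales_px <= 0)) stop("scales must be positive")
  if (sum(kinds) < 2) stop("at least two feature kinds must be enabled")
  structure(list(scales_px = as.numeric(scales_px), kinds = kinds),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("feature_config: scales {", paste(x$scales_px, collapse = ", "), "} x kinds {",
      paste(names(x$kinds)[x$kinds], collapse = ", "), "}\n")
  invisible(x)
}

# central differences with replicated borders
diff_col <- function(x) (x[, c(2:ncol(x), ncol(x))] - x[, c(1, 1:(ncol(x) - 1))]) / 2
diff_row <- function(x) (x[c(2:nrow(x), nrow(x)), ] - x[c(1, 1:(nrow(x) - 1)), ]) / 2

#' Per-pixel feature stack of a DIC image
#'
#' Planes are ordered scale-major: for each scale (ascending as given),
#' the enabled kinds in the fixed order intensity, gradient, laplacian,
#' hessian (2 planes: larger then smaller eigenvalue), variance. The
#' plane list for scales `{s1}` is therefore a prefix of the list for
#' `{s1, s2}`. Boundaries are handled reflectively.
#'
#' @param image a [dic_image()] or numeric matrix.
#' @param config a [feature_config()].
#' @return Numeric array `height x width x n_planes` with plane names in
#'   `dimnames`.
#' @export
compute_features <- function(image, config = feature_config()) {
  x <- if (inherits(image, "dic_image")) image$intensity else as.matrix(image)
  if (!all(is.finite(x))) stop("image must be finite")
  stopifnot(inherits(config, "feature_config"))
  if (max(config$scales_px) > min(dim(x)) / 2)
    stop("largest scale exceeds half the image size")
  kinds <- config$kinds
  planes <- list()
  for (s in config$scales_px) {
    g <- gaussian_blur(x, s)
    tag <- function(kind) sprintf("%s_s%g", kind, s)
    if (kinds["intensity"]) planes[[tag("intensity")]] <- g
    need_d2 <- kinds["laplacian"] || kinds["hessian"]
    if (kinds["gradient"] || need_d2) {
      gx <- diff_col(g); gy <- diff_row(g)
      if (kinds["gradient"]) planes[[tag("gradient")]] <- sqrt(gx^2 + gy^2)
      if (need_d2) {
        gxx <- diff_col(gx); gyy <- diff_row(gy); gxy <- diff_row(gx)
        if (kinds["laplacian"]) planes[[tag("laplacian")]] <- gxx + gyy
        if (kinds["hessian"]) {
          disc <- sqrt(pmax(0, (gxx - gyy)^2 + 4 * gxy^2))
          planes[[tag("hessian1")]] <- (gxx + gyy + disc) / 2
          planes[[tag("hessian2")]] <- (gxx + gyy - disc) / 2
        }
      }
    }
    if (kinds["variance"])
      planes[[tag("variance")]] <- pmax(0, gaussian_blur(x^2, s) - g^2)
  }
  out <- array(unlist(planes, use.names = FALSE),
               dim = c(nrow(x), ncol(x), length(planes)),
               dimnames = list(NULL, NULL, names(planes)))
  out
}
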