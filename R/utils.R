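# Internal numerical helpers shared across modules.

#' Clip values into an interval
#' @noRd
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Reflectively pad a matrix by `k` pixels on every side
#' @noRd
pad_reflect <- function(x, k) {
  if (k <= 0) return(x)
  h <- nrow(x); w <- ncol(x)
  stopifnot(k < h, k < w)
  ri <- c(rev(seq_len(k) + 1L), seq_len(h), h - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(w), w - seq_len(k))
  x[ri, ci, drop = FALSE]
}

#' Isotropic Gaussian smoothing with reflective boundary handling.
#'
#' Separable Gaussian implemented through EBImage's FFT convolution on a
#' reflectively padded copy, so that boundary pixels see a mirrored image
#' rather than a circular wrap.
#' @noRd
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-k:k)^2) / (2 * sigma^2))
  g <- g / sum(g)
  kern <- outer(g, g)
  xp <- pad_reflect(x, k)
  y <- EBImage::filter2(xp, kern, boundary = "circular")
  y <- as.matrix(y)
  y[(k + 1):(k + nrow(x)), (k + 1):(k + ncol(x)), drop = FALSE]
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(x, dr, dc, fill = 0) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  rlo <- max(1, 1 + dr); rhi <- min(h, h + dr)
  clo <- max(1, 1 + dc); chi <- min(w, w + dc)
  if (rlo > rhi || clo > chi) return(out)
  out[rlo:rhi, clo:chi] <- x[(rlo:rhi) - dr, (clo:chi) - dc]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

#' Connected-component labelling on a binary mask.
#'
#' Label propagation: every foreground pixel starts with its own linear
#' index and repeatedly takes the maximum over its (4- or 8-) neighbours
#' until a fixed point; components then get compact ids 1..k, ordered by
#' their smallest linear index (deterministic raster order).
#' @noRd
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(0L, h, w))
  lab <- matrix(0, h, w)
  lab[mask] <- which(mask)
  offs <- neighbour_offsets(connectivity)
  repeat {
    new <- lab
    for (o in offs) new <- pmax(new, shift_mat(lab, o[1], o[2]))
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[mask]
  first <- tapply(which(mask), ids, min)
  ord <- order(first)                   # raster order of first pixel
  remap <- integer(max(ids))
  remap[as.numeric(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, h, w)
  out[mask] <- remap[ids]
  out
}

# Derive a secondary RNG seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
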