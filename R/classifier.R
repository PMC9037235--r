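# Trainable background / cell / pit pixel classifier.
#
# A classical stand-in for a pretrained-CNN feature extractor: a
# multi-scale filter bank feeds a random forest, which is all the rest of
# the pipeline needs from the segmentation stage - a per-pixel posterior
# over {background, cell, pit}.

.PIT_CLASSES <- c("background", "cell", "pit")

# cell pixels within chebyshev distance 2 of a background pixel
rim_band <- function(labels) {
  bg <- labels == 0L
  near_bg <- bg
  for (o in neighbour_offsets(8)) {
    near_bg <- near_bg | shift_mat(bg, o[1], o[2], fill = TRUE)
  }
  near2 <- near_bg
  for (o in neighbour_offsets(8)) {
    near2 <- near2 | shift_mat(near_bg, o[1], o[2], fill = TRUE)
  }
  (labels == 1L) & near2
}

as_image_list <- function(x) {
  if (inherits(x, "dic_image")) list(x) else x
}
as_label_list <- function(x) {
  if (is.matrix(x)) list(x) else x
}

#' Fit a background/cell/pit pixel classifier
#'
#' Trains a random forest on multi-scale filter-bank features
#' ([compute_features()]) of one or more images with matching
#' three-class truth label maps (codes 0 background, 1 cell, 2 pit). To
#' tame class imbalance, at most `pixel_cap` pixels per class per image
#' are sampled (stratified, seeded). Out-of-bag per-class accuracy is
#' recorded in the fitted object as a training-quality diagnostic.
#'
#' @param images a [dic_image()] or list of them.
#' @param labels an integer label matrix or list of them, geometry
#'   matching `images`; all three classes must be present across the set.
#' @param features a [feature_config()].
#' @param n_trees number of trees in the forest.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param pixel_cap maximum training pixels per class per image.
#' @param seed RNG seed; identical data + seed reproduce the fit exactly.
#' @return A `pit_classifier` object with `print`, `summary` and
#'   [predict.pit_classifier()] methods.
#' @export
pit_classifier <- function(images, labels, features = feature_config(),
                           n_trees = 80, max_depth = 24,
                           pixel_cap = 10000, seed = 1L) {
  images <- as_image_list(images); labels <- as_label_list(labels)
  if (length(images) < 1) stop("at least one training image is required")
  if (length(images) != length(labels))
    stop("images and labels must have equal length")
  for (i in seq_along(images)) {
    li <- labels[[i]]
    if (!identical(dim(images[[i]]$intensity), dim(li)))
      stop("image/label geometry mismatch at position ", i)
    bad <- setdiff(unique(as.vector(li)), 0:2)
    if (length(bad)) stop("label map ", i, " contains invalid code(s): ",
                          paste(bad, collapse = ", "))
  }
  present <- sort(unique(unlist(lapply(labels, function(l) unique(as.vector(l))))))
  missing <- setdiff(0:2, present)
  if (length(missing))
    stop("class ", paste(.PIT_CLASSES[missing + 1], collapse = ", "),
         " absent from training labels")

  set.seed(seed)
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    fs <- compute_features(images[[i]], features)
    np <- dim(fs)[3]
    fm <- matrix(fs, ncol = np, dimnames = list(NULL, dimnames(fs)[[3]]))
    lv <- as.vector(labels[[i]])
    # cell-class hard negatives: the rim band (cell pixels close to
    # background) carries the steep relief most confusable with pit
    # crater rims, so half the cell cap is reserved for it
    rim <- rim_band(labels[[i]])
    for (cls in 0:2) {
      idx <- which(lv == cls)
      if (!length(idx)) next
      if (length(idx) > pixel_cap) {
        if (cls == 1L) {
          band <- idx[rim[idx]]
          other <- idx[!rim[idx]]
          n_band <- min(length(band), floor(pixel_cap / 2))
          take_band <- if (length(band) > n_band) sample(band, n_band) else band
          take_rest <- sample(other, min(length(other), pixel_cap - length(take_band)))
          idx <- c(take_band, take_rest)
        } else {
          idx <- sample(idx, pixel_cap)
        }
      }
      xs[[length(xs) + 1L]] <- fm[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep.int(cls, length(idx))
    }
  }
  X <- do.call(rbind, xs)
  y <- factor(.PIT_CLASSES[unlist(ys) + 1L], levels = .PIT_CLASSES)

  forest <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                           max.depth = if (max_depth > 0) max_depth else NULL,
                           probability = TRUE, seed = seed, num.threads = 1)
  # out-of-bag per-class accuracy
  oob <- forest$predictions
  ok <- stats::complete.cases(oob)
  pred_cls <- .PIT_CLASSES[max.col(oob[ok, , drop = FALSE], ties.method = "first")]
  acc <- tapply(pred_cls == as.character(y)[ok], as.character(y)[ok], mean)

  structure(list(forest = forest, features = features,
                 classes = .PIT_CLASSES,
                 n_trees = n_trees, max_depth = max_depth,
                 pixel_cap = pixel_cap, seed = as.integer(seed),
                 fitted = TRUE,
                 training = list(n_images = length(images),
                                 n_sampled = table(y),
                                 oob_class_accuracy = acc)),
            class = "pit_classifier")
}

#' @export
print.pit_classifier <- function(x, ...) {
  cat("pit_classifier: random forest on a multi-scale filter bank\n")
  cat(sprintf("  classes: %s (fixed order)\n", paste(x$classes, collapse = " < ")))
  cat(sprintf("  %d trees, max depth %s, seed %d, %d training image(s)\n",
              x$n_trees, if (x$max_depth > 0) x$max_depth else "unlimited",
              x$seed, x$training$n_images))
  invisible(x)
}

#' @export
summary.pit_classifier <- function(object, ...) {
  print(object)
  print(object$features)
  cat("  training pixels per class:\n")
  print(object$training$n_sampled)
  cat("  out-of-bag per-class accuracy:\n")
  print(round(object$training$oob_class_accuracy, 4))
  invisible(object)
}

#' Pixel-classify a DIC image
#'
#' Applies the fitted forest to every pixel's feature vector and takes
#' the posterior argmax; ties break towards the fixed class order
#' background < cell < pit.
#'
#' @param object a fitted [pit_classifier()].
#' @param image a [dic_image()] or numeric matrix.
#' @param posteriors if `TRUE`, attach the per-class posterior array
#'   (`height x width x 3`, rows summing to 1) as attribute
#'   `"posteriors"`.
#' @param ... unused.
#' @return Integer label matrix with codes 0 background, 1 cell, 2 pit.
#' @export
predict.pit_classifier <- function(object, image, posteriors = FALSE, ...) {
  if (!isTRUE(object$fitted)) stop("classifier is not fitted")
  fs <- compute_features(image, object$features)
  np <- dim(fs)[3]
  fm <- matrix(fs, ncol = np, dimnames = list(NULL, dimnames(fs)[[3]]))
  pr <- stats::predict(object$forest, data = fm, num.threads = 1)$predictions
  pr <- pr[, object$classes, drop = FALSE]
  lab <- max.col(pr, ties.method = "first") - 1L
  out <- matrix(as.integer(lab), nrow = dim(fs)[1], ncol = dim(fs)[2])
  if (posteriors) {
    attr(out, "posteriors") <- array(pr, dim = c(dim(fs)[1], dim(fs)[2], 3),
                                     dimnames = list(NULL, NULL, object$classes))
  }
  out
}

#' Save / load a fitted pixel classifier
#'
#' The model is serialised to a single file embedding the feature
#' configuration, class order, seed and training metadata.
#'
#' @param object a `pit_classifier`.
#' @param path file path.
#' @return `load_classifier` returns the `pit_classifier`.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "pit_classifier"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "pit_classifier"))
    stop("file does not contain a pit_classifier")
  object
}

#' Compare a predicted label map with truth
#'
#' @param predicted,truth integer label matrices with codes 0/1/2 and
#'   identical geometry.
#' @return List with `iou` (per-class intersection-over-union; an empty
#'   union counts as 1), `accuracy`, and the 3x3 `confusion` table
#'   (rows = truth, columns = prediction; row sums equal truth class
#'   counts).
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth))) stop("geometry mismatch")
  p <- factor(as.vector(predicted), levels = 0:2)
  t_ <- factor(as.vector(truth), levels = 0:2)
  conf <- table(truth = t_, predicted = p)
  iou <- vapply(1:3, function(k) {
    inter <- conf[k, k]
    uni <- sum(conf[k, ]) + sum(conf[, k]) - inter
    if (uni == 0) 1 else as.numeric(inter) / as.numeric(uni)
  }, numeric(1))
  names(iou) <- .PIT_CLASSES
  list(iou = iou,
       accuracy = sum(diag(conf)) / sum(conf),
       confusion = conf)
}
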