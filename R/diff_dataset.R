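# Dataset machinery for image-based differentiability prediction: tile
# early-culture bright-field fields into patches, label them from a
# co-registered tight-junction (ZO-1) fluorescence mask, augment, and run a
# pluggable classifier through leakage-safe k-fold cross-validation.

# Evaluate expr with a private, restorable RNG stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Tile a field image into fixed-size patches
#'
#' Top-left-anchored grid; partial tiles at the right/bottom margins are
#' dropped (a 1608 px field tiled at 224 px yields a 7 x 7 grid with 40 px
#' margins discarded).
#'
#' @param field `H x W` numeric matrix.
#' @param tile_size patch side in px (default 224).
#' @param stride grid step in px (default `tile_size`: non-overlapping).
#' @return A `tile_set`: list with `images` (list of `tile_size^2`
#'   matrices) and `info` (data frame `tile_id, origin_row, origin_col`,
#'   0-based origins).
#' @export
tile_field <- function(field, tile_size = 224, stride = tile_size) {
  stopifnot(is.matrix(field))
  h <- nrow(field); w <- ncol(field)
  if (tile_size > min(h, w)) stop("field smaller than one tile")
  if (stride < 1) stop("stride must be >= 1")
  r0 <- seq(0L, h - tile_size, by = stride)
  c0 <- seq(0L, w - tile_size, by = stride)
  grid <- expand.grid(origin_col = c0, origin_row = r0)[, 2:1]
  images <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$origin_row[i]; cc <- grid$origin_col[i]
    field[(r + 1L):(r + tile_size), (cc + 1L):(cc + tile_size)]
  })
  info <- data.frame(tile_id = seq_len(nrow(grid)) - 1L,
                     origin_row = grid$origin_row,
                     origin_col = grid$origin_col)
  structure(list(images = images, info = info, tile_size = tile_size),
            class = "tile_set")
}

#' Label tiles from a co-registered fluorescence mask
#'
#' A tile is labeled 0 ("differentiable tissue") when at least
#' `positive_fraction` of the mask pixels under its footprint are positive
#' (ZO-1 present), else 1 ("non-differentiable tissue").
#'
#' @param tiles a `tile_set` from [tile_field()].
#' @param zo1_mask `H x W` logical (or 0/1) matrix, same size as the field
#'   the tiles came from.
#' @param positive_fraction coverage needed for label 0 (default 0.5,
#'   majority coverage).
#' @return The `tile_set` with `label` and `source_id` columns added to
#'   `info` (each original tile is its own source).
#' @export
label_tiles <- function(tiles, zo1_mask, positive_fraction = 0.5) {
  stopifnot(inherits(tiles, "tile_set"))
  m <- zo1_mask != 0
  ts <- tiles$tile_size
  needed <- max(tiles$info$origin_row) + ts
  if (nrow(m) < needed || ncol(m) < max(tiles$info$origin_col) + ts)
    stop("mask smaller than the tiled field")
  cov <- vapply(seq_len(nrow(tiles$info)), function(i) {
    r <- tiles$info$origin_row[i]; cc <- tiles$info$origin_col[i]
    mean(m[(r + 1L):(r + ts), (cc + 1L):(cc + ts)])
  }, numeric(1))
  tiles$info$label <- ifelse(cov >= positive_fraction, 0L, 1L)
  tiles$info$coverage <- cov
  tiles$info$source_id <- tiles$info$tile_id
  tiles$info$provenance <- "orig"
  tiles
}

.rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

.apply_op <- function(img, op, noise_sigma, lo, hi) {
  switch(op,
    identity = img,
    hflip = img[, ncol(img):1L, drop = FALSE],
    rot90 = .rot90cw(img),
    rot180 = .rot90cw(.rot90cw(img)),
    rot270 = .rot90cw(.rot90cw(.rot90cw(img))),
    gaussian_noise = ,
    noise = {
      out <- img + stats::rnorm(length(img), sd = noise_sigma)
      pmin(pmax(out, lo), hi)
    },
    blur = {
      # 3x3 binomial smoothing as an optional alternative perturbation
      k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
      p <- rbind(img[1L, ], img, img[nrow(img), ])
      p <- cbind(p[, 1L], p, p[, ncol(p)])
      out <- img
      out[] <- 0
      for (dr in -1:1) for (dc in -1:1)
        out <- out + k[dr + 2L, dc + 2L] *
          p[(2L + dr):(nrow(img) + 1L + dr), (2L + dc):(ncol(img) + 1L + dc)]
      out
    },
    stop("unknown augmentation op: ", op))
}

#' Augment labeled tiles
#'
#' Expands the tile set by geometric operations (horizontal flip, rotations
#' by 90/180/270 degrees) and additive Gaussian noise. Geometric ops
#' preserve the label and the patch shape; noise is zero-mean, clipped to
#' the set's intensity range, and deterministic under `seed`. Provenance
#' tags record the source tile and the op applied, so downstream fold
#' assignment can keep all variants of one source together.
#'
#' @param tiles a labeled `tile_set` from [label_tiles()] (or any tile set
#'   whose `info` has `label` and `source_id`).
#' @param ops character vector drawn from `identity`, `hflip`, `rot90`,
#'   `rot180`, `rot270`, `noise` (alias `gaussian_noise`), `blur`.
#' @param noise_sigma SD of the additive noise; default 1% of the set's
#'   dynamic range.
#' @param seed RNG seed for the noise op.
#' @return A `tile_set` with one tile per (source, op), provenance-tagged.
#' @export
augment_tiles <- function(tiles,
                          ops = c("identity", "hflip", "rot90", "rot180",
                                  "rot270", "noise"),
                          noise_sigma = NULL, seed = 1) {
  stopifnot(inherits(tiles, "tile_set"))
  known <- c("identity", "hflip", "rot90", "rot180", "rot270",
             "noise", "gaussian_noise", "blur")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  rng <- range(unlist(lapply(tiles$images, range)))
  if (is.null(noise_sigma)) noise_sigma <- 0.01 * max(rng[2L] - rng[1L], 1)
  n <- nrow(tiles$info)
  images <- vector("list", n * length(ops))
  info <- vector("list", length(ops))
  .with_seed(seed, {
    k <- 0L
    for (oi in seq_along(ops)) {
      op <- ops[oi]
      for (i in seq_len(n)) {
        k <- k + 1L
        images[[k]] <- .apply_op(tiles$images[[i]], op, noise_sigma,
                                 rng[1L], rng[2L])
      }
      inf <- tiles$info
      inf$provenance <- paste0(inf$provenance, "+", op)
      info[[oi]] <- inf
    }
  })
  info <- do.call(rbind, info)
  info$tile_id <- seq_len(nrow(info)) - 1L
  rownames(info) <- NULL
  structure(list(images = images, info = info, tile_size = tiles$tile_size),
            class = "tile_set")
}

#' Assign tiles to cross-validation folds without augmentation leakage
#'
#' Source tiles (not augmented variants) are shuffled under `seed` and
#' dealt round-robin into `k` folds, so all augmented variants of one
#' source share a fold and source counts per fold differ by at most one.
#' With `stratify = TRUE` the deal is done within each label class, keeping
#' the class mix of every fold as close to the overall prevalence as the
#' counts allow.
#'
#' @param tiles a `tile_set` whose `info` has `source_id` (and `label` when
#'   stratifying).
#' @param k fold count (default 5).
#' @param seed RNG seed for the shuffle.
#' @param stratify balance class labels across folds (default `FALSE`).
#' @return A `fold_split`: list with `k`, `assignments` (integer fold index
#'   1..k per tile, in `info` row order), `seed`.
#' @export
make_folds <- function(tiles, k = 5, seed = 1, stratify = FALSE) {
  stopifnot(inherits(tiles, "tile_set"))
  if (k < 2) stop("k must be at least 2")
  src <- unique(tiles$info$source_id)
  if (length(src) < k) stop("fewer source tiles than folds")
  if (stratify) {
    lab_of_src <- tapply(tiles$info$label, tiles$info$source_id, `[`, 1L)
    perm <- .with_seed(seed, {
      unlist(lapply(split(src, lab_of_src[as.character(src)]), sample),
             use.names = FALSE)
    })
  } else {
    perm <- .with_seed(seed, sample(src))
  }
  fold_of_src <- stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  assignments <- unname(fold_of_src[as.character(tiles$info$source_id)])
  structure(list(k = as.integer(k), assignments = as.integer(assignments),
                 seed = seed),
            class = "fold_split")
}

#' Run k-fold cross-validation with a pluggable classifier
#'
#' For each fold, the classifier is fit on the other `k - 1` folds and
#' evaluated on the held-out fold; per-fold accuracies, their mean and SD,
#' and an aggregate 2 x 2 confusion matrix over all validation predictions
#' are reported.
#'
#' @param classifier list with `fit(images, labels) -> model` and
#'   `predict(model, images) -> labels in {0, 1}`.
#' @param tiles a labeled `tile_set`.
#' @param folds a `fold_split` from [make_folds()].
#' @return A `cv_result`: list with `per_fold_accuracy` (percent),
#'   `mean_accuracy`, `sd_accuracy`, `confusion` (rows = true 0/1, cols =
#'   predicted 0/1), `n_validation`.
#' @export
cross_validate <- function(classifier, tiles, folds) {
  stopifnot(inherits(tiles, "tile_set"), inherits(folds, "fold_split"))
  stopifnot(is.function(classifier$fit), is.function(classifier$predict))
  labels <- tiles$info$label
  acc <- numeric(folds$k)
  confusion <- matrix(0L, 2L, 2L,
                      dimnames = list(true = c("0", "1"),
                                      predicted = c("0", "1")))
  for (f in seq_len(folds$k)) {
    val <- folds$assignments == f
    train_labels <- labels[!val]
    if (length(unique(train_labels)) < 2L)
      warning("fold ", f, ": a class is absent from the training split")
    model <- classifier$fit(tiles$images[!val], train_labels)
    pred <- classifier$predict(model, tiles$images[val])
    truth <- labels[val]
    acc[f] <- 100 * mean(pred == truth)
    for (i in seq_along(truth))
      confusion[truth[i] + 1L, pred[i] + 1L] <-
        confusion[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), confusion = confusion,
                 n_validation = sum(confusion)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean accuracy %.2f%% (sd %.2f) over %d folds\n",
              x$mean_accuracy, x$sd_accuracy, length(x$per_fold_accuracy)))
  print(x$confusion)
  invisible(x)
}

#' Threshold-on-mean-intensity reference classifier
#'
#' Fits the midpoint between the two class means of per-tile mean intensity
#' and predicts by thresholding; a deliberately simple reference model for
#' exercising the cross-validation harness on synthetic textures (the CNNs
#' used on real bright-field data plug into the same `fit`/`predict`
#' interface).
#'
#' @return A classifier list usable with [cross_validate()].
#' @export
classifier_mean_intensity <- function() {
  list(
    fit = function(images, labels) {
      mi <- vapply(images, mean, numeric(1))
      m0 <- mean(mi[labels == 0L]); m1 <- mean(mi[labels == 1L])
      if (is.nan(m0)) m0 <- m1; if (is.nan(m1)) m1 <- m0
      list(threshold = (m0 + m1) / 2, zero_is_high = m0 >= m1)
    },
    predict = function(model, images) {
      mi <- vapply(images, mean, numeric(1))
      high <- mi >= model$threshold
      as.integer(if (model$zero_is_high) !high else high)
    })
}

#' Majority-class dummy classifier
#'
#' Always predicts the most frequent training label; its cross-validation
#' accuracy equals the class prevalence, a useful chance-level baseline.
#'
#' @return A classifier list usable with [cross_validate()].
#' @export
classifier_majority <- function() {
  list(
    fit = function(images, labels) {
      tab <- table(factor(labels, levels = c(0L, 1L)))
      list(label = as.integer(names(tab)[which.max(tab)]))
    },
    predict = function(model, images) rep(model$label, length(images)))
}
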