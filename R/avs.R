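# The full artificial visual system: a trained Gaussian mixture over LMDN
# index vectors, a calibrated label-to-direction map, and an argmax
# population read-out of global motion direction.

#' Train the unsupervised artificial visual system
#'
#' Fits the 8-component Gaussian mixture to the identity index vectors of
#' the local motion detection layer (by default the complete ideal set of
#' all `H * W * 8` neurons), then calibrates which mixture component stands
#' for which motion direction.  The result is a ready-to-use model:
#' [predict()] on a frame pair returns the detected global motion
#' direction.
#'
#' @param grid Retina dimensions `c(H, W)` (default `c(32, 32)`).
#' @param data Optional training set: a list with an `N x 16` matrix
#'   `vectors` and (optionally) integer truth tags `direction`, as returned
#'   by [ideal_index_vectors()].  When `NULL`, the complete ideal set for
#'   `grid` is enumerated and used.
#' @param seed Optional integer seed; fixes the whole training run.
#' @param lmdn An [lmdn_config()] used both for encoding and, later, by
#'   [predict.avs()].
#' @param n_init,max_iter,tol,reg_eps Passed to [gmm_em()].
#' @return An object of class `"avs"`: the fitted `gmm` ([gmm_em()]
#'   object), the `label_map` (see [calibrate_labels()]), `lmdn_config`,
#'   `grid`, `norm_const`, per-component training `counts`, and training
#'   `purity` when truth tags were available.
#' @examples
#' model <- avs(grid = c(8, 8), seed = 1, n_init = 5)
#' model
#' @export
avs <- function(grid = c(32, 32), data = NULL, seed = NULL,
                lmdn = lmdn_config(), n_init = 10, max_iter = 100,
                tol = 1e-3, reg_eps = 1e-6) {
  grid <- as.integer(grid)
  norm_const <- lmdn$a + max(grid) - 1
  if (is.null(data)) {
    data <- ideal_index_vectors(grid[1L], grid[2L], a = lmdn$a,
                                norm_const = norm_const)
  }
  X <- data$vectors
  fit <- gmm_em(X, K = 8, seed = seed, max_iter = max_iter, tol = tol,
                n_init = n_init, reg_eps = reg_eps)
  label_map <- calibrate_labels(fit)
  labels <- predict(fit, X)
  counts <- tabulate(labels + 1L, nbins = 8L)
  purity <- if (!is.null(data$direction)) {
    .cluster_purity(labels, data$direction)
  } else NA_real_
  structure(list(gmm = fit, label_map = label_map, lmdn_config = lmdn,
                 grid = grid, norm_const = norm_const,
                 counts = counts, purity = purity, n_train = nrow(X),
                 seed = seed, call = match.call()),
            class = "avs")
}

#' Calibrate mixture labels to motion directions
#'
#' The identity encoding reserves dimensions `2d` and `2d + 1` (0-based)
#' for direction `d`, so the direction a trained component represents can
#' be read off deterministically from its mean vector: the dimension pair
#' carrying the mass identifies `d`.  This replaces any visual inspection
#' of an embedding with an automatic rule.  The map is only returned when
#' it is a bijection over the 8 labels; a non-bijective assignment signals
#' an impure clustering and raises an error carrying the per-component
#' report.
#'
#' @param gmm A fitted [gmm_em()] model with `K = 8` on 16-dimensional
#'   vectors.
#' @return A data frame of class `"label_direction_map"` with columns
#'   `label` (0..7, the component index), `direction` (0..7) and `angle`
#'   (degrees).
#' @export
calibrate_labels <- function(gmm) {
  if (gmm$K != 8L || gmm$dim != 16L) {
    stop("calibration expects an 8-component mixture on 16-dim vectors",
         call. = FALSE)
  }
  direction <- integer(8)
  for (k in 1:8) {
    direction[k] <- (which.max(abs(gmm$means[k, ])) - 1L) %/% 2L
  }
  if (anyDuplicated(direction)) {
    tab <- paste(sprintf("label %d -> direction %d", 0:7, direction),
                 collapse = "; ")
    stop("label calibration failed (non-bijective map, clustering impure): ",
         tab, call. = FALSE)
  }
  structure(data.frame(label = 0:7, direction = direction,
                       angle = 45 * direction,
                       name = .dir_names[direction + 1L]),
            class = c("label_direction_map", "data.frame"))
}

#' Detect the global motion direction of a frame pair
#'
#' Runs the local motion detection layer, encodes every activated neuron's
#' normalized index vector, hard-assigns each vector to a mixture
#' component, translates component labels to directions through the
#' calibrated map, and reads out the global motion direction as the
#' direction with the most activated neurons (ties broken toward the
#' lowest direction index).  When no neuron is activated the direction is
#' `NA`.
#'
#' @param object A trained [avs()] model.
#' @param pair A [frame_pair()] matching the model's grid.
#' @param ... Unused.
#' @return An object of class `"avs_detection"`: list with
#'   `global_direction` (0..7 or `NA`), `angle`, `per_direction_counts`
#'   (via the mixture labels), `per_label_counts`, `lmdn_counts` (the raw
#'   truth-tag counts from the activation map, for diagnostics) and
#'   `n_activated`.
#' @examples
#' model <- avs(grid = c(16, 16), seed = 1, n_init = 5)
#' set.seed(2)
#' m <- random_object_mask(16, 16, 16, direction = 0)
#' det <- predict(model, make_frame_pair(m, direction = 0))
#' det$global_direction
#' @export
predict.avs <- function(object, pair, ...) {
  stopifnot(inherits(pair, "frame_pair"))
  if (!identical(grid_shape(pair), object$grid)) {
    stop("frame shape does not match the model's retina grid",
         call. = FALSE)
  }
  act <- lmdn_layer(pair, object$lmdn_config)
  on <- which(act$bits == 1L, arr.ind = TRUE)
  n_act <- nrow(on)
  if (n_act == 0L) {
    det <- list(global_direction = NA_integer_, angle = NA_real_,
                per_direction_counts = integer(8),
                per_label_counts = integer(8),
                lmdn_counts = act$counts, n_activated = 0L)
    return(structure(det, class = "avs_detection"))
  }
  vec <- .index_vectors(row = on[, 1L] - 1L, col = on[, 2L] - 1L,
                        d = on[, 3L] - 1L,
                        a = object$lmdn_config$a,
                        norm_const = object$norm_const)
  labels <- predict(object$gmm, vec)
  per_label <- tabulate(labels + 1L, nbins = 8L)
  dir_of_label <- object$label_map$direction[match(0:7,
                                                   object$label_map$label)]
  per_dir <- integer(8)
  for (l in 0:7) {
    per_dir[dir_of_label[l + 1L] + 1L] <- per_label[l + 1L]
  }
  gd <- which.max(per_dir) - 1L   # lowest index wins ties
  structure(list(global_direction = gd, angle = 45 * gd,
                 per_direction_counts = per_dir,
                 per_label_counts = per_label,
                 lmdn_counts = act$counts, n_activated = n_act),
            class = "avs_detection")
}

#' @export
print.avs_detection <- function(x, ...) {
  if (is.na(x$global_direction)) {
    cat("no neuron activated: global motion direction undetermined\n")
  } else {
    cat(sprintf("global motion direction: %d (%g degrees, %s)\n",
                x$global_direction, x$angle,
                .dir_names[x$global_direction + 1L]))
  }
  cat("activated neurons per direction (0..7):", x$per_direction_counts,
      "\n")
  invisible(x)
}

#' @export
print.avs <- function(x, ...) {
  cat(sprintf("unsupervised AVS: %d x %d retina, %d LMDNs\n",
              x$grid[1L], x$grid[2L], prod(x$grid) * 8L))
  cat(sprintf("GMM trained on %d index vectors, log-likelihood %.2f (%d update(s)%s)\n",
              x$n_train, x$gmm$loglik, x$gmm$n_iter,
              if (x$gmm$converged) ", converged" else ""))
  cat("component sizes:", x$counts, "\n")
  if (!is.na(x$purity)) cat(sprintf("training purity: %.4f\n", x$purity))
  invisible(x)
}

#' @export
summary.avs <- function(object, ...) {
  structure(list(model = object), class = "summary.avs")
}

#' @export
print.summary.avs <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nlabel -> direction calibration:\n")
  print.data.frame(m$label_map, row.names = FALSE)
  cat("\nmixing weights:", format(m$gmm$weights, digits = 4), "\n")
  cat("log-likelihood trace:",
      format(m$gmm$loglik_trace, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.avs <- function(object, ...) coef(object$gmm)

#' @export
logLik.avs <- function(object, ...) logLik(object$gmm)

#' Diagnostic plot of a trained AVS
#'
#' `which = "means"` draws the component mean vectors as an 8 x 16 image:
#' a clean training run shows exactly one bright dimension pair per
#' component, each pair in a different position.  `which = "counts"` draws
#' the per-component training counts, which are all equal (`H * W`) for a
#' direction-pure fit on the full ideal set.
#'
#' @param x A trained [avs()] model.
#' @param which `"means"` or `"counts"`.
#' @param ... Passed on to the underlying base graphics call.
#' @return Invisibly, `x`.
#' @export
plot.avs <- function(x, which = c("means", "counts"), ...) {
  which <- match.arg(which)
  if (which == "means") {
    m <- abs(x$gmm$means)
    graphics::image(x = 1:16, y = 1:8, z = t(m[8:1, ]),
                    xlab = "index-vector dimension", ylab = "component",
                    yaxt = "n", main = "component means", ...)
    graphics::axis(2, at = 1:8, labels = 7:0)
  } else {
    graphics::barplot(x$counts, names.arg = 0:7,
                      xlab = "component label",
                      ylab = "training vectors assigned",
                      main = "cluster sizes", ...)
  }
  invisible(x)
}

#' Simulate motion stimuli at the model's retina
#'
#' Draws `nsim` random moving-object frame pairs matching the model's grid:
#' a random 4-connected object of `size` pixels with a uniform random
#' colour on a uniform random background, translated one pixel in a random
#' (or given) direction, with optional static pixel noise.  The generated
#' direction of each pair is attached as attribute `"direction"`.
#'
#' @param object A trained [avs()] model.
#' @param nsim Number of stimuli.
#' @param seed Optional seed.
#' @param size Object size in pixels (default 64).
#' @param direction Direction index in `0..7`, or `NULL` to draw uniformly.
#' @param noise Static-noise pixel fraction in `[0, 1]`.
#' @param color_mode Passed to [make_frame_pair()].
#' @param ... Unused.
#' @return A list of [frame_pair()] objects, each with attribute
#'   `"direction"`.
#' @export
simulate.avs <- function(object, nsim = 1, seed = NULL, size = 64,
                         direction = NULL, noise = 0,
                         color_mode = "rgb", ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    d <- if (is.null(direction)) sample(0:7, 1L) else as.integer(direction)
    mask <- random_object_mask(size, object$grid[1L], object$grid[2L], d)
    fp <- make_frame_pair(mask, d, color_mode = color_mode)
    if (noise > 0) fp <- add_static_noise(fp, noise)
    attr(fp, "direction") <- d
    out[[i]] <- fp
  }
  out
}
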