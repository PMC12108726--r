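# Evaluation utilities: cluster diagnostics, subsample retraining, and the
# object-size x noise-level accuracy grid.

# fraction of points whose cluster's majority direction matches their own
.cluster_purity <- function(labels, truth) {
  n <- length(labels)
  ok <- 0L
  for (l in unique(labels)) {
    in_l <- truth[labels == l]
    ok <- ok + sum(in_l == .majority(in_l))
  }
  ok / n
}

.majority <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Cluster diagnostics against truth direction tags
#'
#' Reports how the mixture partitions a tagged training set: per-component
#' member counts, the clustering purity (fraction of points whose
#' component's majority direction is their own; 1 means direction-perfect),
#' whether the label-to-direction calibration is bijective, and how many EM
#' updates the fit used.
#'
#' @param object A trained [avs()] model or a fitted [gmm_em()] model.
#' @param data Training set with `vectors` and `direction` (as from
#'   [ideal_index_vectors()]).  May be omitted for an `avs` model trained
#'   on the full ideal set, in which case the set is re-enumerated.
#' @return A list of class `"cluster_report"` with `per_label_counts`,
#'   `purity`, `label_map_ok` and `n_iter`.
#' @export
cluster_report <- function(object, data = NULL) {
  gmm <- if (inherits(object, "avs")) object$gmm else object
  if (is.null(data)) {
    if (!inherits(object, "avs")) {
      stop("data is required for a bare mixture fit", call. = FALSE)
    }
    data <- ideal_index_vectors(object$grid[1L], object$grid[2L],
                                a = object$lmdn_config$a,
                                norm_const = object$norm_const)
  }
  labels <- predict(gmm, data$vectors)
  map_ok <- !inherits(try(calibrate_labels(gmm), silent = TRUE),
                      "try-error")
  structure(list(per_label_counts = tabulate(labels + 1L, nbins = gmm$K),
                 purity = .cluster_purity(labels, data$direction),
                 label_map_ok = map_ok,
                 n_iter = gmm$n_iter),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("per-label counts:", x$per_label_counts, "\n")
  cat(sprintf("purity %.4f; calibration %s; %d EM update(s)\n",
              x$purity, if (x$label_map_ok) "bijective" else "FAILED",
              x$n_iter))
  invisible(x)
}

#' Retrain on a random subsample of the ideal set
#'
#' Draws `fraction` of the complete ideal index-vector set uniformly
#' without replacement, trains a fresh model on it, and reports cluster
#' purity together with the (possibly permuted) label-to-direction map:
#' with less data the clusters stay direction-pure, but which component
#' ends up standing for which angle is arbitrary, so calibration must be
#' redone after every training run.
#'
#' @param fraction Fraction of the ideal set to keep, in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param grid Retina dimensions (default `c(32, 32)`).
#' @param ... Passed to [avs()].
#' @return A list with `report` (a [cluster_report()]), `label_map` and
#'   the trained `model`.
#' @export
subsample_experiment <- function(fraction, seed = NULL, grid = c(32, 32),
                                 ...) {
  full <- ideal_index_vectors(grid[1L], grid[2L])
  n <- nrow(full$vectors)
  m <- floor(fraction * n)
  if (m < 8L) stop("subsample too small: need at least 8 vectors",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  keep <- sample.int(n, m)
  sub <- list(vectors = full$vectors[keep, , drop = FALSE],
              direction = full$direction[keep])
  model <- avs(grid = grid, data = sub, ...)
  list(report = cluster_report(model, sub),
       label_map = model$label_map,
       model = model)
}

#' Accuracy over an object-size by noise-level grid
#'
#' For every combination of object size and static-noise fraction,
#' generates `trials_per_cell` independent stimuli balanced over the eight
#' directions (uniformly coloured random objects, one-pixel motion, static
#' pixel noise), runs the detector, and records the fraction of trials
#' whose detected global direction equals the generated one.
#'
#' @param model A trained [avs()] model.
#' @param sizes Object sizes in pixels (rows of the grid).
#' @param noise_levels Noise pixel fractions (columns of the grid).
#' @param trials_per_cell Trials per cell (default 800, i.e. 100 per
#'   direction).
#' @param seed Optional integer seed for the whole grid.
#' @param color_mode Passed to [make_frame_pair()].
#' @return A numeric `length(sizes) x length(noise_levels)` matrix of
#'   class `"accuracy_grid"` with accuracies in `[0, 1]`; attributes
#'   `trials_per_cell` and `seed`.
#' @examples
#' model <- avs(grid = c(16, 16), seed = 1, n_init = 5)
#' accuracy_grid(model, sizes = c(4, 16), noise_levels = c(0, 0.1),
#'               trials_per_cell = 16, seed = 2)
#' @export
accuracy_grid <- function(model, sizes = c(1, 2, 4, 8, 16, 32, 64, 128,
                                           256, 512),
                          noise_levels = c(0, 0.01, 0.05, 0.10),
                          trials_per_cell = 800, seed = NULL,
                          color_mode = "rgb") {
  stopifnot(inherits(model, "avs"), trials_per_cell >= 1)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(NA_real_, length(sizes), length(noise_levels),
                dimnames = list(size = sizes,
                                noise = sprintf("%g%%", 100 * noise_levels)))
  directions <- rep(0:7, length.out = trials_per_cell)
  for (i in seq_along(sizes)) {
    for (j in seq_along(noise_levels)) {
      correct <- 0L
      for (t in seq_len(trials_per_cell)) {
        d <- directions[t]
        mask <- random_object_mask(sizes[i], model$grid[1L],
                                   model$grid[2L], d)
        fp <- make_frame_pair(mask, d, color_mode = color_mode)
        if (noise_levels[j] > 0) fp <- add_static_noise(fp, noise_levels[j])
        det <- predict(model, fp)
        if (!is.na(det$global_direction) && det$global_direction == d) {
          correct <- correct + 1L
        }
      }
      acc[i, j] <- correct / trials_per_cell
    }
  }
  structure(acc, class = c("accuracy_grid", "matrix"),
            trials_per_cell = trials_per_cell, seed = seed)
}

#' @export
print.accuracy_grid <- function(x, ...) {
  cat(sprintf("detection accuracy (%d trials per cell)\n",
              attr(x, "trials_per_cell")))
  m <- matrix(sprintf("%.2f%%", 100 * unclass(x)), nrow(x), ncol(x),
              dimnames = dimnames(x))
  print(m, quote = FALSE)
  invisible(x)
}
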