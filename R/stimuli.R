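# Synthetic motion stimuli: frame pairs holding a uniformly coloured object
# translated by one pixel on a uniformly coloured background, optionally
# corrupted by static pixel noise.  Frames are numeric arrays with channel
# values in [0, 255]: an H x W matrix (grayscale) or an H x W x 3 array (rgb).

#' Construct a two-frame motion stimulus
#'
#' A frame pair is the sole stimulus input of the model: the scene at time
#' \eqn{t} and the scene one frame step later.  Both frames must share the
#' same shape and colour mode, and channel values must lie in `[0, 255]`.
#'
#' @param frame_t,frame_t1 Numeric `H x W` matrices (grayscale) or
#'   `H x W x 3` arrays (rgb); same shape for both.
#' @param color_mode `"grayscale"` or `"rgb"`.  Inferred from the array
#'   dimensions when missing.
#' @return An object of class `"frame_pair"`: a list with elements
#'   `frame_t`, `frame_t1` and `color_mode`.
#' @examples
#' f <- matrix(0, 4, 4)
#' g <- f; g[2, 3] <- 255
#' fp <- frame_pair(f, g)
#' dim(fp$frame_t)
#' @export
frame_pair <- function(frame_t, frame_t1, color_mode = NULL) {
  if (is.matrix(frame_t)) frame_t <- array(frame_t, c(dim(frame_t), 1L))
  if (is.matrix(frame_t1)) frame_t1 <- array(frame_t1, c(dim(frame_t1), 1L))
  if (!is.array(frame_t) || !is.array(frame_t1) ||
      length(dim(frame_t)) != 3L || length(dim(frame_t1)) != 3L) {
    stop("frames must be H x W matrices or H x W x 3 arrays", call. = FALSE)
  }
  if (!identical(dim(frame_t), dim(frame_t1))) {
    stop("frame_t and frame_t1 must have identical shape", call. = FALSE)
  }
  nchan <- dim(frame_t)[3L]
  if (!nchan %in% c(1L, 3L)) {
    stop("frames must have 1 (grayscale) or 3 (rgb) channels", call. = FALSE)
  }
  if (is.null(color_mode)) {
    color_mode <- if (nchan == 3L) "rgb" else "grayscale"
  }
  color_mode <- match.arg(color_mode, c("grayscale", "rgb"))
  if ((color_mode == "rgb") != (nchan == 3L)) {
    stop("color_mode does not match the number of channels", call. = FALSE)
  }
  rng <- range(frame_t, frame_t1)
  if (rng[1L] < 0 || rng[2L] > 255) {
    stop("pixel channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(frame_t = frame_t, frame_t1 = frame_t1,
                 color_mode = color_mode),
            class = "frame_pair")
}

#' @export
print.frame_pair <- function(x, ...) {
  d <- dim(x$frame_t)
  ndiff <- sum(apply(x$frame_t != x$frame_t1, c(1, 2), any))
  cat(sprintf("frame pair: %d x %d %s, %d pixel(s) differ between frames\n",
              d[1L], d[2L], x$color_mode, ndiff))
  invisible(x)
}

# grid dimensions (H, W) of a frame pair
grid_shape <- function(pair) dim(pair$frame_t)[1:2]

#' Grow a random 4-connected object mask
#'
#' Object shapes are random blobs grown by randomized breadth-first
#' accretion from a random seed cell, so edges face all directions.  The
#' blob is constrained to the region of the grid where both the object and
#' its one-pixel translate along `direction` fit entirely inside the frame,
#' which keeps the motion in-frame.
#'
#' @param n_pixels Number of cells in the object (positive integer).
#' @param grid_h,grid_w Grid dimensions.
#' @param direction Motion direction index in `0..7` the mask must admit.
#' @return An object of class `"object_mask"`: a list with `cells` (an
#'   `n_pixels x 2` matrix of 1-based `(row, col)` positions) and
#'   `n_pixels`.
#' @examples
#' set.seed(1)
#' m <- random_object_mask(64, 32, 32, direction = 0)
#' m$n_pixels
#' @export
random_object_mask <- function(n_pixels, grid_h, grid_w, direction) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 1L) stop("n_pixels must be positive", call. = FALSE)
  if (n_pixels > (grid_h - 2L) * (grid_w - 2L)) {
    stop(sprintf("object of %d pixels does not fit a %d x %d grid",
                 n_pixels, grid_h, grid_w), call. = FALSE)
  }
  off <- .dir_offsets[as.integer(direction) + 1L, ]
  # rows/cols where both the cell and its translate are in-grid
  r_lo <- max(1L, 1L - off[1L]); r_hi <- min(grid_h, grid_h - off[1L])
  c_lo <- max(1L, 1L - off[2L]); c_hi <- min(grid_w, grid_w - off[2L])
  nr <- r_hi - r_lo + 1L; nc <- c_hi - c_lo + 1L
  if (n_pixels > nr * nc) {
    stop("object too large for the admissible placement region", call. = FALSE)
  }
  in_blob <- matrix(FALSE, nr, nc)
  seed_cell <- c(sample.int(nr, 1L), sample.int(nc, 1L))
  in_blob[seed_cell[1L], seed_cell[2L]] <- TRUE
  frontier <- matrix(integer(0), ncol = 2L)
  nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  push_neighbours <- function(cell, frontier) {
    for (k in 1:4) {
      p <- cell + nb[k, ]
      if (p[1L] >= 1L && p[1L] <= nr && p[2L] >= 1L && p[2L] <= nc &&
          !in_blob[p[1L], p[2L]]) {
        frontier <- rbind(frontier, p)
      }
    }
    frontier
  }
  frontier <- push_neighbours(seed_cell, frontier)
  n_have <- 1L
  while (n_have < n_pixels) {
    # frontier may contain duplicates; drop already-absorbed entries lazily
    i <- sample.int(nrow(frontier), 1L)
    cell <- frontier[i, ]
    frontier <- frontier[-i, , drop = FALSE]
    if (in_blob[cell[1L], cell[2L]]) next
    in_blob[cell[1L], cell[2L]] <- TRUE
    n_have <- n_have + 1L
    frontier <- push_neighbours(cell, frontier)
  }
  idx <- which(in_blob, arr.ind = TRUE)
  cells <- cbind(row = idx[, 1L] + r_lo - 1L, col = idx[, 2L] + c_lo - 1L)
  structure(list(cells = cells, n_pixels = n_pixels,
                 grid = c(grid_h, grid_w)),
            class = "object_mask")
}

#' Render a moving-object frame pair
#'
#' Draws one uniform colour for the background and one for the object
#' (redrawn until the two differ in at least one channel), paints the object
#' at its mask cells in the first frame, and at the cells translated one
#' pixel along `direction` in the second frame.  Everything else is
#' background in both frames: only the object moves.
#'
#' @param mask An [random_object_mask()] result valid for `direction`.
#' @param direction Motion direction index in `0..7`.
#' @param color_mode `"rgb"` (default; 24-bit colours drawn uniformly) or
#'   `"grayscale"` (one intensity in `0..255`).
#' @return A [frame_pair()].
#' @examples
#' set.seed(7)
#' m <- random_object_mask(8, 16, 16, direction = 2)
#' fp <- make_frame_pair(m, direction = 2)
#' @export
make_frame_pair <- function(mask, direction,
                            color_mode = c("rgb", "grayscale")) {
  color_mode <- match.arg(color_mode)
  h <- mask$grid[1L]; w <- mask$grid[2L]
  off <- .dir_offsets[as.integer(direction) + 1L, ]
  cells1 <- cbind(mask$cells[, 1L] + off[1L], mask$cells[, 2L] + off[2L])
  if (any(cells1 < 1L) || any(cells1[, 1L] > h) || any(cells1[, 2L] > w)) {
    stop("mask does not admit one-pixel motion along this direction",
         call. = FALSE)
  }
  nchan <- if (color_mode == "rgb") 3L else 1L
  bg <- sample(0:255, nchan, replace = TRUE)
  repeat {
    obj <- sample(0:255, nchan, replace = TRUE)
    if (any(obj != bg)) break
  }
  frame_t <- array(rep(bg, each = h * w), c(h, w, nchan))
  frame_t1 <- frame_t
  for (ch in seq_len(nchan)) {
    frame_t[cbind(mask$cells, ch)] <- obj[ch]
    frame_t1[cbind(cells1, ch)] <- obj[ch]
  }
  footprint <- unique(rbind(mask$cells, cells1))
  structure(list(frame_t = frame_t, frame_t1 = frame_t1,
                 color_mode = color_mode, object_cells = footprint),
            class = "frame_pair")
}

#' Corrupt a frame pair with static pixel noise
#'
#' Picks `round(fraction * H * W)` distinct pixel positions uniformly at
#' random and overwrites BOTH frames at each position with one independently
#' drawn random colour.  The noise is identical in the two frames, so noise
#' pixels do not move: they mask signal rather than create motion.
#'
#' Noise pixels are scene features independent of the moving object, so for
#' pairs produced by [make_frame_pair()] the positions are drawn outside the
#' object's pre- and post-motion footprint (carried by the pair as
#' `object_cells`).  This keeps the set of positions at which the two frames
#' differ -- the motion signal -- unchanged by noising.  For hand-built
#' pairs with no recorded footprint, positions are drawn over the whole
#' grid; pass `exclude` to control this directly.
#'
#' @param pair A [frame_pair()].
#' @param fraction Fraction of pixels to corrupt, in `[0, 1]`.
#' @param exclude Optional `m x 2` matrix of `(row, col)` positions never
#'   noised; defaults to the pair's recorded object footprint.
#' @return The corrupted [frame_pair()].
#' @export
add_static_noise <- function(pair, fraction,
                             exclude = pair$object_cells) {
  stopifnot(inherits(pair, "frame_pair"))
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  hw <- grid_shape(pair)
  n <- round(fraction * hw[1L] * hw[2L])
  if (n == 0L) return(pair)
  allowed <- seq_len(hw[1L] * hw[2L])
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    allowed <- setdiff(allowed,
                       (exclude[, 2L] - 1L) * hw[1L] + exclude[, 1L])
  }
  if (n > length(allowed)) {
    stop("noise fraction too large for the non-object area", call. = FALSE)
  }
  pos <- allowed[sample.int(length(allowed), n)]  # distinct positions
  rows <- ((pos - 1L) %% hw[1L]) + 1L
  cols <- ((pos - 1L) %/% hw[1L]) + 1L
  nchan <- dim(pair$frame_t)[3L]
  colors <- matrix(sample(0:255, n * nchan, replace = TRUE), n, nchan)
  for (ch in seq_len(nchan)) {
    pair$frame_t[cbind(rows, cols, ch)] <- colors[, ch]
    pair$frame_t1[cbind(rows, cols, ch)] <- colors[, ch]
  }
  pair
}

#' Enumerate the ideal index-vector training set
#'
#' The unsupervised layer is trained on the identity outputs of every local
#' motion detection neuron in the retina: one 16-dimensional normalized
#' index vector per (row, column, direction) triple, i.e. `H * W * 8`
#' vectors.  For a 32 x 32 retina this is the complete 8192-neuron set.
#'
#' @param grid_h,grid_w Retina dimensions (default 32 x 32).
#' @param a Index offset constant added to both coordinates so no index is
#'   zero (default 16).
#' @param norm_const Normalization divisor; defaults to
#'   `a + max(grid_h, grid_w) - 1`, which maps the largest index to exactly 1.
#' @return A list of class `"lmdn_training_set"` with `vectors` (an
#'   `N x 16` numeric matrix), and integer truth tags `direction` (`0..7`),
#'   `row` and `col` (0-based grid coordinates).
#' @examples
#' ts <- ideal_index_vectors(32, 32)
#' nrow(ts$vectors)   # 8192
#' @export
ideal_index_vectors <- function(grid_h = 32, grid_w = 32, a = 16,
                                norm_const = NULL) {
  stopifnot(grid_h >= 1, grid_w >= 1)
  if (is.null(norm_const)) norm_const <- a + max(grid_h, grid_w) - 1
  grid <- expand.grid(d = 0:7, col = 0:(grid_w - 1L), row = 0:(grid_h - 1L))
  n <- nrow(grid)
  vectors <- matrix(0, n, 16L)
  ix <- cbind(seq_len(n), 2L * grid$d + 1L)
  iy <- cbind(seq_len(n), 2L * grid$d + 2L)
  vectors[ix] <- (a + grid$row) / norm_const
  vectors[iy] <- (a + grid$col) / norm_const
  structure(list(vectors = vectors,
                 direction = as.integer(grid$d),
                 row = as.integer(grid$row),
                 col = as.integer(grid$col),
                 a = a, norm_const = norm_const,
                 grid = c(grid_h, grid_w)),
            class = "lmdn_training_set")
}

#' @export
print.lmdn_training_set <- function(x, ...) {
  cat(sprintf(paste0("ideal LMDN training set: %d vectors ",
                     "(%d x %d retina, 8 directions), a = %g, ",
                     "normalization = %g\n"),
              nrow(x$vectors), x$grid[1L], x$grid[2L], x$a, x$norm_const))
  invisible(x)
}
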