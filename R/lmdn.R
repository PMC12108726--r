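# Local motion detection neuron (LMDN) layer.
#
# Each retinal position hosts eight neurons, one per motion direction.  A
# neuron mimics four retinal cell types: photoreceptors pass pixel values
# through, a bipolar cell (BC) fires when the pixel changed between the two
# frames, a horizontal cell (HC) fires when the pixel at time t differs
# from its direction-offset neighbour at time t + 1, and the ganglion cell
# (GC) combines the two as BC AND NOT HC.  A neuron therefore fires only
# when its pixel changed AND its own content reappeared one pixel away
# along the preferred direction -- one-pixel motion in that direction.

#' Configuration of the local motion detection layer
#'
#' @param threshold_L Luminance-difference threshold `L`: two values are
#'   "different" when they differ by more than `L`.  Default 0, i.e. any
#'   nonzero change counts, appropriate for noiseless uniform-colour
#'   stimuli; raise it for graded real images.
#' @param a Index offset constant of the identity encoding (default 16).
#' @param synapse_omega,synapse_theta,synapse_k Sigmoid synapse weight,
#'   threshold and steepness used by the soft ganglion stage
#'   (`omega = 1`, `theta = 0.5`, `k = 10`); the excitatory regime requires
#'   `0 < theta <= omega`.
#' @param gc_threshold Cutoff applied to the soft ganglion product to yield
#'   a binary activation; must lie strictly in `(0, 1)`.
#' @param color_rule `"any_channel"`: a pixel differs when any RGB channel
#'   differs by more than `L` (the most sensitive reading of per-channel
#'   colour processing).  `"luminance"`: compare the channel mean.
#' @return A list of class `"lmdn_config"`.
#' @export
lmdn_config <- function(threshold_L = 0, a = 16,
                        synapse_omega = 1, synapse_theta = 0.5,
                        synapse_k = 10, gc_threshold = 0.5,
                        color_rule = c("any_channel", "luminance")) {
  color_rule <- match.arg(color_rule)
  if (threshold_L < 0) stop("threshold_L must be >= 0", call. = FALSE)
  if (a < 1) stop("offset constant a must be >= 1", call. = FALSE)
  if (gc_threshold <= 0 || gc_threshold >= 1) {
    stop("gc_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (!(synapse_theta > 0 && synapse_theta <= synapse_omega)) {
    stop("excitatory synapse requires 0 < theta <= omega", call. = FALSE)
  }
  structure(list(threshold_L = threshold_L, a = a,
                 synapse_omega = synapse_omega,
                 synapse_theta = synapse_theta,
                 synapse_k = synapse_k, gc_threshold = gc_threshold,
                 color_rule = color_rule),
            class = "lmdn_config")
}

# per-pixel "differs" predicate between two channel vectors
.pixel_differs <- function(x, y, config) {
  if (config$color_rule == "luminance" && length(x) > 1L) {
    abs(mean(x) - mean(y)) > config$threshold_L
  } else {
    any(abs(x - y) > config$threshold_L)
  }
}

#' Bipolar cell response at one position
#'
#' Fires (returns 1) when the pixel value at `pos` changed between the two
#' frames by more than the threshold `L`, i.e. when there is a temporal
#' change at that position.
#'
#' @param pair A [frame_pair()].
#' @param pos 1-based `(row, col)` position.
#' @param config An [lmdn_config()].
#' @return 0 or 1.
#' @export
bc_response <- function(pair, pos, config = lmdn_config()) {
  hw <- grid_shape(pair)
  if (pos[1L] < 1L || pos[1L] > hw[1L] || pos[2L] < 1L || pos[2L] > hw[2L]) {
    stop("position outside the grid", call. = FALSE)
  }
  as.integer(.pixel_differs(pair$frame_t[pos[1L], pos[2L], ],
                            pair$frame_t1[pos[1L], pos[2L], ], config))
}

#' Horizontal cell response at one position for one direction
#'
#' Compares the pixel at `pos` in the first frame against its neighbour one
#' step along the direction offset in the second frame.  Fires (returns 1)
#' when they differ by more than `L`, i.e. when the content at `pos` did
#' NOT reappear at the offset position.  When the offset position falls
#' outside the grid the cell fires, so border neurons cannot signal motion
#' pointing off the image.
#'
#' @inheritParams bc_response
#' @param direction Direction index in `0..7`.
#' @return 0 or 1.
#' @export
hc_response <- function(pair, pos, direction, config = lmdn_config()) {
  hw <- grid_shape(pair)
  if (pos[1L] < 1L || pos[1L] > hw[1L] || pos[2L] < 1L || pos[2L] > hw[2L]) {
    stop("position outside the grid", call. = FALSE)
  }
  off <- .dir_offsets[as.integer(direction) + 1L, ]
  p1 <- c(pos[1L] + off[1L], pos[2L] + off[2L])
  if (p1[1L] < 1L || p1[1L] > hw[1L] || p1[2L] < 1L || p1[2L] > hw[2L]) {
    return(1L)
  }
  as.integer(.pixel_differs(pair$frame_t[pos[1L], pos[2L], ],
                            pair$frame_t1[p1[1L], p1[2L], ], config))
}

#' Sigmoid synapse
#'
#' The synaptic transfer function `1 / (1 + exp(-k * (omega * x - theta)))`.
#' With `omega > 0` it is strictly increasing in the input and crosses 0.5
#' at `x = theta / omega`.
#'
#' @param x Input signal in `[0, 1]` (vectorized).
#' @param omega Synaptic weight.
#' @param theta Synaptic threshold.
#' @param k Steepness (must be positive).
#' @return Values in `(0, 1)`.
#' @export
synapse <- function(x, omega = 1, theta = 0.5, k = 10) {
  if (k <= 0) stop("steepness k must be positive", call. = FALSE)
  1 / (1 + exp(-k * (omega * x - theta)))
}

#' Ganglion cell output
#'
#' Combines the excitatory bipolar input and the inhibitory horizontal
#' input.  In `"hard"` mode this is the logical product `bc AND NOT hc` --
#' the neuron fires only for excitation without inhibition.  In `"soft"`
#' mode each input passes through a sigmoid [synapse()] and the neuron
#' fires when `synapse(bc) * (1 - synapse(hc))` exceeds `gc_threshold`;
#' with the default synapse parameters this reproduces the hard truth table
#' exactly.
#'
#' @param bc,hc Binary inputs (vectorized).
#' @param config An [lmdn_config()].
#' @param mode `"hard"` (reference semantics) or `"soft"`.
#' @return 0/1 integer vector.
#' @export
gc_output <- function(bc, hc, config = lmdn_config(),
                      mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (mode == "hard") {
    as.integer(bc == 1L & hc == 0L)
  } else {
    s_exc <- synapse(bc, config$synapse_omega, config$synapse_theta,
                     config$synapse_k)
    s_inh <- synapse(hc, config$synapse_omega, config$synapse_theta,
                     config$synapse_k)
    as.integer(s_exc * (1 - s_inh) > config$gc_threshold)
  }
}

# Align frame values with their direction-offset neighbours: returns an
# H x W matrix m with m[i, j] = x[i + drow, j + dcol] for one channel,
# NA where the neighbour is off-grid.
.shift_channel <- function(x, drow, dcol) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(NA_real_, h, w)
  r_src <- max(1L, 1L + drow):min(h, h + drow)
  c_src <- max(1L, 1L + dcol):min(w, w + dcol)
  out[r_src - drow, c_src - dcol] <- x[r_src, c_src]
  out
}

#' Evaluate the whole local motion detection layer
#'
#' Runs all `H * W * 8` neurons on a frame pair and returns the binary
#' activation map: for every pixel and direction, the ganglion output of
#' the bipolar (temporal change) and horizontal (direction-offset
#' comparison) responses.  Vectorized over the grid; bit-equivalent to
#' evaluating [bc_response()], [hc_response()] and [gc_output()] per
#' neuron.
#'
#' @param pair A [frame_pair()].
#' @param config An [lmdn_config()].
#' @param mode Ganglion mode, `"hard"` or `"soft"` (see [gc_output()]).
#' @return An object of class `"activation_map"`: list with `bits`
#'   (`H x W x 8` 0/1 array, slice `d + 1` for direction `d`) and `counts`
#'   (activated neurons per direction).
#' @export
lmdn_layer <- function(pair, config = lmdn_config(),
                       mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "frame_pair"))
  if (!identical(dim(pair$frame_t), dim(pair$frame_t1))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  A <- pair$frame_t; B <- pair$frame_t1
  hw <- grid_shape(pair); nchan <- dim(A)[3L]
  L <- config$threshold_L
  lum <- config$color_rule == "luminance" && nchan > 1L
  diff_mat <- function(x, y) {   # H x W logical "differs" per pixel
    if (lum) {
      abs(apply(x, c(1, 2), mean) - apply(y, c(1, 2), mean)) > L
    } else {
      m <- abs(x[, , 1L] - y[, , 1L]) > L
      if (nchan > 1L) for (ch in 2:nchan) {
        m <- m | (abs(x[, , ch] - y[, , ch]) > L)
      }
      m
    }
  }
  bc <- diff_mat(A, B)
  bits <- array(0L, c(hw, 8L))
  for (d in 0:7) {
    off <- .dir_offsets[d + 1L, ]
    Bs <- array(NA_real_, dim(B))
    for (ch in seq_len(nchan)) {
      Bs[, , ch] <- .shift_channel(B[, , ch], off[1L], off[2L])
    }
    if (lum) {
      hc <- abs(apply(A, c(1, 2), mean) - apply(Bs, c(1, 2), mean)) > L
    } else {
      hc <- abs(A[, , 1L] - Bs[, , 1L]) > L
      if (nchan > 1L) for (ch in 2:nchan) {
        hc <- hc | (abs(A[, , ch] - Bs[, , ch]) > L)
      }
    }
    hc[is.na(hc)] <- TRUE          # off-grid neighbour inhibits
    bits[, , d + 1L] <- matrix(
      gc_output(as.integer(bc), as.integer(hc), config, mode), hw[1L], hw[2L])
  }
  structure(list(bits = bits,
                 counts = as.integer(apply(bits, 3L, sum))),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("LMDN activation map", paste(dim(x$bits)[1:2], collapse = " x "),
      "pixels\n")
  cat("activated per direction (0..7):", x$counts, "\n")
  invisible(x)
}

#' Identity encoding of an activated neuron
#'
#' An activated neuron reports who it is through an 8 x 2 index matrix:
#' row `d + 1` (its preferred direction) holds `(a + row, a + col)` while
#' every other row is zero, so the position indices can never be zero and
#' the active row identifies the direction.
#'
#' @param row,col 0-based grid coordinates of the neuron.
#' @param d Direction index in `0..7`.
#' @param a Offset constant (default 16).
#' @return An 8 x 2 numeric matrix.
#' @examples
#' encode_index(0, 0, 0)        # row 1 is (16, 16)
#' encode_index(31, 31, 5)[6, ] # (47, 47)
#' @export
encode_index <- function(row, col, d, a = 16) {
  stopifnot(row >= 0, col >= 0, d >= 0, d <= 7)
  m <- matrix(0, 8L, 2L)
  m[d + 1L, ] <- c(a + row, a + col)
  m
}

#' Normalize and flatten an index matrix
#'
#' Row-major flattening of the 8 x 2 index matrix into a 16-vector (the
#' pair for direction `d` lands at dimensions `2d` and `2d + 1`, 0-based),
#' divided by `norm_const` so all entries lie in `[0, 1]`.
#'
#' @param m An 8 x 2 index matrix from [encode_index()].
#' @param norm_const Positive normalization divisor, at least the largest
#'   possible index so the output is within `[0, 1]`.
#' @return A numeric vector of length 16.
#' @export
normalize_flatten <- function(m, norm_const) {
  if (norm_const <= 0) stop("norm_const must be positive", call. = FALSE)
  if (max(m) > norm_const) {
    stop("norm_const smaller than the largest index", call. = FALSE)
  }
  as.vector(t(m)) / norm_const
}

# fast path: normalized 16-vectors for many (row, col, d) triples at once
.index_vectors <- function(row, col, d, a, norm_const) {
  n <- length(d)
  v <- matrix(0, n, 16L)
  v[cbind(seq_len(n), 2L * d + 1L)] <- (a + row) / norm_const
  v[cbind(seq_len(n), 2L * d + 2L)] <- (a + col) / norm_const
  v
}
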