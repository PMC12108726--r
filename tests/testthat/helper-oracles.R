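# Independent oracles used across the suite.  These re-derive expected
# results by the most literal route available (double loops, dense linear
# algebra, breadth-first search) and deliberately share no code with the
# package internals.

# direction -> (row, col) offset of one pixel of motion; d = 0 rightward,
# counterclockwise in 45-degree steps, rows increasing downward
oracle_offsets <- rbind(
  c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
  c(0, -1), c(1, -1), c(1, 0), c(1, 1))

# literal per-neuron evaluation of the four-cell logic: bipolar change
# detection, horizontal offset comparison (off-grid inhibits), ganglion
# AND-NOT.  Returns an H x W x 8 0/1 array.
oracle_lmdn <- function(pair, L = 0) {
  A <- pair$frame_t; B <- pair$frame_t1
  h <- dim(A)[1]; w <- dim(A)[2]
  out <- array(0L, c(h, w, 8))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    bc <- as.integer(any(abs(A[i, j, ] - B[i, j, ]) > L))
    for (d in 0:7) {
      p <- c(i, j) + oracle_offsets[d + 1, ]
      hc <- if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) 1L else {
        as.integer(any(abs(A[i, j, ] - B[p[1], p[2], ]) > L))
      }
      out[i, j, d + 1] <- bc * (1L - hc)
    }
  }
  out
}

# dense quadratic-form multivariate normal log-density
oracle_logpdf <- function(x, mu, sigma) {
  d <- length(mu)
  q <- as.numeric(t(x - mu) %*% solve(sigma) %*% (x - mu))
  -0.5 * (d * log(2 * pi) + log(det(sigma)) + q)
}

# 4-connectivity of a set of (row, col) cells, checked by BFS
oracle_connected <- function(cells) {
  n <- nrow(cells)
  if (n == 1) return(TRUE)
  key <- paste(cells[, 1], cells[, 2])
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (k in 1:4) {
      nb <- cells[cur, ] + rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[k, ]
      m <- match(paste(nb[1], nb[2]), key)
      if (!is.na(m) && !seen[m]) {
        seen[m] <- TRUE
        queue <- c(queue, m)
      }
    }
  }
  all(seen)
}

# random frame pair with independent uniform pixels (no motion structure)
random_pair <- function(h, w, nchan = 3) {
  frame_pair(array(sample(0:255, h * w * nchan, TRUE), c(h, w, nchan)),
             array(sample(0:255, h * w * nchan, TRUE), c(h, w, nchan)))
}

# a small trained model reused by several test files (cheap: 8 x 8 retina)
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(avs(grid = c(8, 8), seed = 421,
                                     n_init = 5))
    }
    cache
  }
})
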