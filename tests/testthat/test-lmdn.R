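test_that("the sigmoid synapse matches direct arithmetic", {
  # midpoint: x = theta / omega
  expect_equal(synapse(0.5, omega = 1, theta = 0.5, k = 10), 0.5)
  expect_equal(synapse(0.25, omega = 2, theta = 0.5, k = 3), 0.5)
  # frozen values of 1 / (1 + exp(-10 * (x - 0.5)))
  expect_equal(synapse(1, 1, 0.5, 10), 0.9933071490757153, tolerance = 1e-12)
  expect_equal(synapse(0, 1, 0.5, 10), 0.0066928509242848554,
               tolerance = 1e-12)
  # strictly increasing in x for positive weight
  xs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(synapse(xs)) > 0))
  expect_error(synapse(0.5, k = 0), "positive")
})

test_that("the ganglion stage is excitation AND NOT inhibition, in both modes", {
  cfg <- lmdn_config()
  truth <- data.frame(bc = c(0, 0, 1, 1), hc = c(0, 1, 0, 1),
                      out = c(0, 0, 1, 0))
  for (i in 1:4) {
    expect_equal(gc_output(truth$bc[i], truth$hc[i], cfg, "hard"),
                 truth$out[i])
    expect_equal(gc_output(truth$bc[i], truth$hc[i], cfg, "soft"),
                 truth$out[i])
  }
})

test_that("bipolar cells fire on temporal change only", {
  cfg <- lmdn_config()
  same <- frame_pair(matrix(7, 4, 4), matrix(7, 4, 4))
  expect_equal(bc_response(same, c(2, 2), cfg), 0)
  jump <- frame_pair(matrix(0, 4, 4),
                     {m <- matrix(0, 4, 4); m[2, 2] <- 255; m})
  expect_equal(bc_response(jump, c(2, 2), cfg), 1)
  expect_equal(bc_response(jump, c(1, 1), cfg), 0)
  # any_channel rule: a single-channel change suffices
  a <- array(100, c(3, 3, 3)); b <- a; b[2, 2, 2] <- 101
  rgb <- frame_pair(a, b)
  expect_equal(bc_response(rgb, c(2, 2), cfg), 1)
  # below-threshold change is ignored
  expect_equal(bc_response(rgb, c(2, 2), lmdn_config(threshold_L = 2)), 0)
  expect_error(bc_response(same, c(5, 1), cfg), "outside")
})

test_that("horizontal cells compare against the direction-offset neighbour", {
  cfg <- lmdn_config()
  flat <- frame_pair(matrix(42, 4, 4), matrix(42, 4, 4))
  expect_equal(hc_response(flat, c(2, 2), 0, cfg), 0)
  # off-grid neighbour inhibits: right edge, rightward offset
  expect_equal(hc_response(flat, c(2, 4), 0, cfg), 1)
  expect_equal(hc_response(flat, c(1, 2), 2, cfg), 1)   # top edge, upward
  # constructed 3x3: object pixel at (2,2) moves right, its colour occupies
  # (2,3) in the second frame, so the rightward HC stays silent
  f1 <- matrix(0, 3, 3); f1[2, 2] <- 200
  f2 <- matrix(0, 3, 3); f2[2, 3] <- 200
  mv <- frame_pair(f1, f2)
  expect_equal(hc_response(mv, c(2, 2), 0, cfg), 0)
  expect_equal(hc_response(mv, c(2, 2), 4, cfg), 1)     # leftward differs
})

test_that("the layer agrees bit-for-bit with the literal per-neuron oracle", {
  set.seed(515)
  for (trial in 1:200) {
    pair <- random_pair(8, 8, nchan = if (trial %% 2) 3 else 1)
    act <- lmdn_layer(pair)
    expect_identical(unname(act$bits), unname(oracle_lmdn(pair)))
    expect_equal(act$counts, as.integer(apply(act$bits, 3, sum)))
  }
})

test_that("soft-mode layer equals hard-mode layer under default synapses", {
  set.seed(52)
  for (trial in 1:20) {
    pair <- random_pair(8, 8)
    expect_identical(lmdn_layer(pair, mode = "soft")$bits,
                     lmdn_layer(pair, mode = "hard")$bits)
  }
})

test_that("whole-field translation maximizes the true direction's count", {
  set.seed(77)
  for (d in 0:7) {
    off <- oracle_offsets[d + 1, ]
    big <- matrix(sample(0:255, 12 * 12, TRUE), 12, 12)
    h <- 10; w <- 10
    # crop so frame_t1 is frame_t shifted by the direction offset
    f_t <- big[2:(1 + h), 2:(1 + w)]
    f_t1 <- big[(2 - off[1]):(1 + h - off[1]), (2 - off[2]):(1 + w - off[2])]
    act <- lmdn_layer(frame_pair(f_t, f_t1))
    expect_equal(which.max(act$counts) - 1, d)
    expect_true(all(act$counts[d + 1] > act$counts[-(d + 1)]))
  }
})

test_that("identical frames silence the whole layer", {
  f <- matrix(sample(0:255, 36, TRUE), 6, 6)
  act <- lmdn_layer(frame_pair(f, f))
  expect_equal(sum(act$bits), 0)
  expect_equal(act$counts, integer(8))
})

test_that("index encoding reserves one row per direction", {
  m <- encode_index(0, 0, 0, a = 16)
  expect_equal(m[1, ], c(16, 16))
  expect_equal(sum(m != 0), 2)
  m2 <- encode_index(31, 31, 5, a = 16)
  expect_equal(m2[6, ], c(47, 47))
  expect_equal(rowSums(m2 != 0), c(0, 0, 0, 0, 0, 2, 0, 0))
})

test_that("normalize_flatten is row-major and scales into [0, 1]", {
  m <- encode_index(0, 0, 0, a = 16)
  v <- normalize_flatten(m, 47)
  expect_equal(v[1:2], rep(16 / 47, 2))
  expect_equal(v[3:16], rep(0, 14))
  v7 <- normalize_flatten(encode_index(31, 31, 7, a = 16), 47)
  expect_equal(v7[15:16], c(1, 1))
  expect_error(normalize_flatten(m, -1), "positive")
  expect_error(normalize_flatten(m, 10), "largest index")
})

test_that("the encoding is injective over a grid", {
  ts <- ideal_index_vectors(6, 5, a = 3)
  expect_equal(nrow(unique(ts$vectors)), nrow(ts$vectors))
})

test_that("config constraints are enforced", {
  expect_error(lmdn_config(threshold_L = -1))
  expect_error(lmdn_config(a = 0))
  expect_error(lmdn_config(gc_threshold = 1))
  expect_error(lmdn_config(synapse_theta = 2, synapse_omega = 1))
})
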