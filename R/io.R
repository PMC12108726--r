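# File interfaces: PNG frame pairs and JSON model bundles.

#' Write / read a frame pair as two PNG files
#'
#' Channel values in `[0, 255]` are stored as 8-bit PNG, so integer-valued
#' frames round-trip exactly.  On reading, the colour mode is inferred
#' from the channel count; 16-bit input is rescaled to `[0, 255]`.
#'
#' @param pair A [frame_pair()].
#' @param path_t,path_t1 File paths for the two frames.
#' @return `write_frame_pair()` returns the paths invisibly;
#'   `read_frame_pair()` returns a [frame_pair()].
#' @export
write_frame_pair <- function(pair, path_t, path_t1) {
  stopifnot(inherits(pair, "frame_pair"))
  squeeze <- function(a) if (dim(a)[3L] == 1L) a[, , 1L] else a
  png::writePNG(squeeze(pair$frame_t) / 255, path_t)
  png::writePNG(squeeze(pair$frame_t1) / 255, path_t1)
  invisible(c(path_t, path_t1))
}

#' @rdname write_frame_pair
#' @export
read_frame_pair <- function(path_t, path_t1) {
  load1 <- function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
      img <- img[, , 1:3]               # drop alpha
    }
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    round(img * 255)
  }
  a <- load1(path_t); b <- load1(path_t1)
  if (!identical(dim(a), dim(b))) {
    stop("frame files have mismatched shapes", call. = FALSE)
  }
  frame_pair(a, b)
}

.avs_format_version <- 1L

#' Save / load a trained AVS model as JSON
#'
#' Serializes every parameter of the model -- mixture weights, means,
#' covariances, regularization, the label-to-direction map, the local
#' layer configuration, grid shape and seed -- to a single JSON file with
#' full numeric precision, and restores it losslessly.
#'
#' @param model A trained [avs()] model.
#' @param path File path.
#' @return `read_avs()` returns the restored `"avs"` object.
#' @export
save_avs <- function(model, path) {
  stopifnot(inherits(model, "avs"))
  bundle <- list(
    format = "avsmotion-model", version = .avs_format_version,
    grid = model$grid, norm_const = model$norm_const,
    lmdn_config = unclass(model$lmdn_config),
    gmm = list(K = model$gmm$K, dim = model$gmm$dim,
               weights = model$gmm$weights,
               means = model$gmm$means,
               covariances = model$gmm$covariances,
               reg_eps = model$gmm$reg_eps,
               loglik = model$gmm$loglik,
               loglik_trace = model$gmm$loglik_trace,
               n_iter = model$gmm$n_iter,
               converged = model$gmm$converged,
               n_obs = model$gmm$n_obs,
               n_init = model$gmm$n_init,
               restart = model$gmm$restart),
    label_map = unclass(model$label_map)[c("label", "direction", "angle")],
    counts = model$counts, purity = model$purity,
    n_train = model$n_train, seed = model$seed)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_avs
#' @export
read_avs <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("format", "version", "grid", "norm_const", "lmdn_config",
                "gmm", "label_map")
  missing <- setdiff(required, names(b))
  if (length(missing)) {
    stop("model file incomplete, missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(b$format, "avsmotion-model")) {
    stop("not an avsmotion model file", call. = FALSE)
  }
  if (b$version != .avs_format_version) {
    stop(sprintf("model format version %s not supported (expected %d)",
                 b$version, .avs_format_version), call. = FALSE)
  }
  if (b$gmm$K != 8L) {
    stop("invalid model: K must be 8 (one component per direction)",
         call. = FALSE)
  }
  covs <- b$gmm$covariances
  if (!is.array(covs) || length(dim(covs)) != 3L) {
    covs <- array(unlist(covs), c(b$gmm$dim, b$gmm$dim, b$gmm$K))
  }
  gmm <- structure(list(weights = b$gmm$weights,
                        means = matrix(unlist(b$gmm$means), b$gmm$K,
                                       b$gmm$dim),
                        covariances = covs,
                        reg_eps = b$gmm$reg_eps, K = b$gmm$K,
                        dim = b$gmm$dim, n_obs = b$gmm$n_obs,
                        loglik = b$gmm$loglik,
                        loglik_trace = b$gmm$loglik_trace,
                        n_iter = b$gmm$n_iter,
                        converged = b$gmm$converged,
                        n_init = b$gmm$n_init, restart = b$gmm$restart,
                        seed = b$seed),
                   class = "gmm_em")
  cfg <- b$lmdn_config
  lmdn <- lmdn_config(threshold_L = cfg$threshold_L, a = cfg$a,
                      synapse_omega = cfg$synapse_omega,
                      synapse_theta = cfg$synapse_theta,
                      synapse_k = cfg$synapse_k,
                      gc_threshold = cfg$gc_threshold,
                      color_rule = cfg$color_rule)
  lm <- as.data.frame(b$label_map)
  lm$name <- .dir_names[lm$direction + 1L]
  structure(list(gmm = gmm,
                 label_map = structure(lm,
                   class = c("label_direction_map", "data.frame")),
                 lmdn_config = lmdn,
                 grid = as.integer(b$grid), norm_const = b$norm_const,
                 counts = b$counts, purity = b$purity,
                 n_train = b$n_train, seed = b$seed,
                 call = NULL),
            class = "avs")
}
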