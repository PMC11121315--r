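#' Configuration of the contact classifier
#'
#' Defaults follow the published training recipe: six leaky-ReLU hidden
#' layers, binary cross-entropy loss, Adam with learning rate 1e-4,
#' mini-batches of 256, 400 epochs, Xavier-uniform initialization and
#' per-element gradient clipping to \[-1, 1\]. Hidden widths taper
#' 512-256-128-64-32-16 from the 192-dimensional input to the scalar output.
#' Structure-derived (40-dim) inputs are first passed through a static
#' (frozen, non-trainable) fully connected 40->192 projection so the same
#' network serves both feature sets.
#'
#' @param hidden_sizes integer vector of exactly 6 hidden-layer widths.
#' @param leaky_slope negative slope of the leaky-ReLU activation.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs.
#' @param grad_clip length-2 clipping range applied elementwise to gradients.
#' @param seed integer seed governing initialization and batch shuffling.
#' @param input_projection `"auto"` (static 40->192 projection iff the input
#'   has 40 columns), `"none"`, or `"static_40_to_192"`.
#' @param projection_trainable if `TRUE` the projection layer is optimized
#'   like any other layer instead of being frozen.
#' @return A `contact_net_config` list.
#' @export
contact_net_config <- function(hidden_sizes = c(512L, 256L, 128L, 64L, 32L, 16L),
                               leaky_slope = 0.01,
                               learning_rate = 1e-4,
                               batch_size = 256L,
                               epochs = 400L,
                               grad_clip = c(-1, 1),
                               seed = 1L,
                               input_projection = c("auto", "none", "static_40_to_192"),
                               projection_trainable = FALSE) {
  input_projection <- match.arg(input_projection)
  if (length(hidden_sizes) != 6L)
    stop("contact_net_config: exactly 6 hidden layers expected, got ",
         length(hidden_sizes))
  if (any(hidden_sizes <= 0)) stop("contact_net_config: non-positive layer width")
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L,
            length(grad_clip) == 2L, grad_clip[1] < grad_clip[2])
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 leaky_slope = leaky_slope,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 grad_clip = as.numeric(grad_clip),
                 seed = as.integer(seed),
                 input_projection = input_projection,
                 projection_trainable = isTRUE(projection_trainable)),
            class = "contact_net_config")
}

# Xavier (Glorot) uniform draw: U(+-sqrt(6 / (fan_in + fan_out)))
xavier_uniform <- function(fan_in, fan_out) {
  bound <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

# build layer list (weights Xavier-uniform, biases zero) for given input dim
init_layers <- function(config, input_dim) {
  use_proj <- identical(config$input_projection, "static_40_to_192")
  dims_in <- if (use_proj) c(input_dim, 192L) else input_dim
  dims <- c(dims_in, config$hidden_sizes, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = xavier_uniform(dims[l], dims[l + 1L]),
      b = rep(0, dims[l + 1L]),
      trainable = !(use_proj && l == 1L && !config$projection_trainable),
      activation = if (use_proj && l == 1L) "linear"
                   else if (l == length(layers)) "sigmoid" else "leaky_relu")
  }
  layers
}

leaky_relu <- function(z, slope) ifelse(z > 0, z, slope * z)

forward_net <- function(layers, X, slope, keep = FALSE) {
  acts <- if (keep) vector("list", length(layers) + 1L) else NULL
  A <- X
  if (keep) acts[[1L]] <- A
  for (l in seq_along(layers)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    A <- switch(layers[[l]]$activation,
                linear = Z,
                leaky_relu = leaky_relu(Z, slope),
                sigmoid = 1 / (1 + exp(-Z)))
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the feed-forward contact classifier
#'
#' Trains the binary contact classifier on a feature matrix (one row per
#' candidate residue pair). A min-max scaler is fitted on the training
#' features (unless a pre-fitted one is supplied) and stored with the model,
#' so [predict.contact_net()] takes raw, unscaled features. Training is
#' fully deterministic given `config$seed`: initialization, the per-epoch
#' mini-batch shuffles and hence the final weights are reproducible bitwise.
#' Class imbalance is left as-is (no re-weighting or resampling).
#'
#' @param X numeric feature matrix, 40 (structure-derived) or 192
#'   (raw-coordinate) columns; or a `pair_feature_set`.
#' @param y logical or 0/1 labels (taken from `X$labels` when `X` is a
#'   `pair_feature_set`).
#' @param config a [contact_net_config()].
#' @param scaler optional pre-fitted [fit_scaler()] parameters.
#' @param verbose print the loss every few epochs.
#' @return An object of class `contact_net` with elements `layers`
#'   (weights), `scaler`, `config`, `feature_kind`, `loss_trace`
#'   (per-epoch mean BCE), `grad_range` (elementwise gradient extrema after
#'   clipping) and `fitted_scores`.
#' @export
contact_net <- function(X, y = NULL, config = contact_net_config(),
                        scaler = NULL, verbose = FALSE) {
  feature_kind <- NULL
  if (inherits(X, "pair_feature_set")) {
    if (is.null(y)) y <- X$labels
    feature_kind <- X$feature_kind
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("contact_net: X rows and y length differ")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("contact_net: y must be binary")
  if (length(unique(y)) < 2L)
    warning("contact_net: degenerate single-class labels; training proceeds")
  if (is.null(feature_kind))
    feature_kind <- if (ncol(X) == 40L) "SDF" else "CF"
  if (identical(config$input_projection, "auto"))
    config$input_projection <- if (ncol(X) == 40L) "static_40_to_192" else "none"

  if (is.null(scaler)) scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  layers <- init_layers(config, ncol(Xs))
  st <- adam_state(layers)
  n <- nrow(Xs)
  loss_trace <- numeric(config$epochs)
  grad_lo <- Inf; grad_hi <- -Inf
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      res <- net_step(layers, st, Xs[idx, , drop = FALSE], y[idx], config)
      layers <- res$layers; st <- res$st
      ep_loss <- ep_loss + res$loss * length(idx)
      grad_lo <- min(grad_lo, res$gmin); grad_hi <- max(grad_hi, res$gmax)
    }
    loss_trace[epoch] <- ep_loss / n
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  BCE %.5f", epoch, loss_trace[epoch]))
  }
  model <- structure(list(layers = layers, scaler = scaler, config = config,
                          feature_kind = feature_kind,
                          input_dim = ncol(Xs),
                          loss_trace = loss_trace,
                          grad_range = c(grad_lo, grad_hi),
                          n_train = n, base_rate = mean(y)),
                     class = "contact_net")
  model$fitted_scores <- as.numeric(forward_net(layers, Xs, config$leaky_slope))
  model
}

# one mini-batch: forward, BCE backward, elementwise clip, Adam update
net_step <- function(layers, st, Xb, yb, config) {
  slope <- config$leaky_slope
  fw <- forward_net(layers, Xb, slope, keep = TRUE)
  p <- as.numeric(fw$out)
  loss <- bce_loss(p, yb)
  nl <- length(layers)
  m <- nrow(Xb)
  # dL/dz at the sigmoid output
  delta <- matrix((p - yb) / m, ncol = 1L)
  gmin <- Inf; gmax <- -Inf
  grads <- vector("list", nl)
  for (l in nl:1L) {
    A_prev <- fw$acts[[l]]
    gW <- crossprod(A_prev, delta)
    gb <- colSums(delta)
    if (layers[[l]]$trainable) {
      gW <- pmin(pmax(gW, config$grad_clip[1]), config$grad_clip[2])
      gb <- pmin(pmax(gb, config$grad_clip[1]), config$grad_clip[2])
      gmin <- min(gmin, gW, gb); gmax <- max(gmax, gW, gb)
      grads[[l]] <- list(W = gW, b = gb)
    }
    if (l > 1L) {
      dA <- delta %*% t(layers[[l]]$W)
      act <- layers[[l - 1L]]$activation
      A <- fw$acts[[l]] # post-activation output of layer l-1
      delta <- switch(act,
                      linear = dA,
                      leaky_relu = dA * ifelse(A > 0, 1, slope),
                      sigmoid = dA * A * (1 - A))
    }
  }
  st$t <- st$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- config$learning_rate * sqrt(1 - b2^st$t) / (1 - b1^st$t)
  for (l in seq_len(nl)) {
    if (is.null(grads[[l]])) next
    st$mW[[l]] <- b1 * st$mW[[l]] + (1 - b1) * grads[[l]]$W
    st$vW[[l]] <- b2 * st$vW[[l]] + (1 - b2) * grads[[l]]$W^2
    st$mb[[l]] <- b1 * st$mb[[l]] + (1 - b1) * grads[[l]]$b
    st$vb[[l]] <- b2 * st$vb[[l]] + (1 - b2) * grads[[l]]$b^2
    layers[[l]]$W <- layers[[l]]$W - lr_t * st$mW[[l]] / (sqrt(st$vW[[l]]) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr_t * st$mb[[l]] / (sqrt(st$vb[[l]]) + eps)
  }
  list(layers = layers, st = st, loss = loss, gmin = gmin, gmax = gmax)
}

adam_state <- function(layers) {
  zW <- lapply(layers, function(l) l$W * 0)
  zb <- lapply(layers, function(l) l$b * 0)
  list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0L)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Predict contact scores
#'
#' Applies the model's stored min-max scaler and returns the sigmoid output
#' per row, a score in (0, 1). Scores are deterministic and row-order
#' equivariant.
#'
#' @param object a fitted [contact_net()].
#' @param newdata raw (unscaled) feature matrix or `pair_feature_set` with
#'   the model's expected number of columns.
#' @param ... unused.
#' @return Numeric score vector.
#' @export
predict.contact_net <- function(object, newdata, ...) {
  if (inherits(newdata, "pair_feature_set")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$scaler$min))
    stop("predict.contact_net: input has ", ncol(newdata),
         " columns but the model (feature_kind ", object$feature_kind,
         ") expects ", length(object$scaler$min))
  Xs <- apply_scaler(newdata, object$scaler)
  as.numeric(forward_net(object$layers, Xs, object$config$leaky_slope))
}

#' @export
print.contact_net <- function(x, ...) {
  dims <- vapply(x$layers, function(l) ncol(l$W), integer(1L))
  cat(sprintf("<contact_net> %s classifier: %d -> %s\n", x$feature_kind,
              nrow(x$layers[[1L]]$W), paste(dims, collapse = " -> ")))
  cat(sprintf("  trained %d epochs on %d pairs (base rate %.4f); final BCE %.5f\n",
              x$config$epochs, x$n_train, x$base_rate,
              if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA))
  invisible(x)
}

#' @export
summary.contact_net <- function(object, ...) {
  cat("Feed-forward inter-helical contact classifier\n")
  print(object)
  frozen <- !vapply(object$layers, `[[`, logical(1L), "trainable")
  if (any(frozen))
    cat(sprintf("  layer %s is a static (frozen) input projection\n",
                paste(which(frozen), collapse = ",")))
  cat(sprintf("  Adam lr %.2g, batch %d, leaky-ReLU slope %.2g, seed %d\n",
              object$config$learning_rate, object$config$batch_size,
              object$config$leaky_slope, object$config$seed))
  cat(sprintf("  clipped gradient extrema: [%.4f, %.4f]\n",
              object$grad_range[1], object$grad_range[2]))
  invisible(object)
}

#' @export
coef.contact_net <- function(object, ...) {
  lapply(object$layers, function(l) list(W = l$W, b = l$b))
}

#' @export
fitted.contact_net <- function(object, ...) object$fitted_scores

#' @export
plot.contact_net <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "training BCE",
       main = sprintf("%s contact classifier", x$feature_kind), ...)
  invisible(x)
}

#' Save / load a fitted contact classifier
#'
#' The archive is a single JSON file holding the configuration, the scaler,
#' and every weight encoded at 17 significant digits, so a loaded model
#' reproduces the original's predictions exactly.
#'
#' @param model a fitted [contact_net()].
#' @param path file path for the JSON archive.
#' @return `path` invisibly ([save_contact_net()]); a `contact_net`
#'   ([load_contact_net()]).
#' @export
save_contact_net <- function(model, path) {
  enc <- function(v) sprintf("%.17g", as.numeric(v))
  obj <- list(
    format = "tmhc_contact_net", version = 1L,
    feature_kind = model$feature_kind,
    input_dim = model$input_dim,
    n_train = model$n_train, base_rate = model$base_rate,
    config = unclass(model$config),
    scaler = list(min = enc(model$scaler$min), max = enc(model$scaler$max),
                  fitted_on = model$scaler$fitted_on),
    grad_range = enc(model$grad_range),
    loss_trace = enc(model$loss_trace),
    layers = lapply(model$layers, function(l)
      list(dim = dim(l$W), W = enc(l$W), b = enc(l$b),
           trainable = l$trainable, activation = l$activation)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname save_contact_net
#' @export
load_contact_net <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("load_contact_net: cannot parse '",
                                           path, "': ", conditionMessage(e)))
  if (!identical(obj$format, "tmhc_contact_net"))
    stop("load_contact_net: not a contact_net archive: ", path)
  if (!identical(as.integer(obj$version), 1L))
    stop("load_contact_net: unsupported archive version ", obj$version)
  dec <- as.numeric
  cfg <- obj$config
  config <- contact_net_config(hidden_sizes = cfg$hidden_sizes,
                               leaky_slope = cfg$leaky_slope,
                               learning_rate = cfg$learning_rate,
                               batch_size = cfg$batch_size,
                               epochs = cfg$epochs,
                               grad_clip = cfg$grad_clip,
                               seed = cfg$seed,
                               input_projection = cfg$input_projection,
                               projection_trainable = cfg$projection_trainable)
  layers <- lapply(seq_len(nrow_list(obj$layers)), function(k) {
    l <- pick_row(obj$layers, k)
    list(W = matrix(dec(l$W), l$dim[1L], l$dim[2L]),
         b = dec(l$b), trainable = l$trainable, activation = l$activation)
  })
  scaler <- structure(list(min = dec(obj$scaler$min), max = dec(obj$scaler$max),
                           fitted_on = obj$scaler$fitted_on),
                      class = "feature_scaler")
  structure(list(layers = layers, scaler = scaler, config = config,
                 feature_kind = obj$feature_kind,
                 input_dim = as.integer(obj$input_dim),
                 loss_trace = dec(obj$loss_trace),
                 grad_range = dec(obj$grad_range),
                 n_train = as.integer(obj$n_train),
                 base_rate = as.numeric(obj$base_rate),
                 fitted_scores = NULL),
            class = "contact_net")
}

# jsonlite may return the layer list as a data.frame or a list
nrow_list <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, k) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) col[[k]] else col[k])
  else x[[k]]
}
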