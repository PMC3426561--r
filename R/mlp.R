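#' Training configuration for Levenberg-Marquardt learning
#'
#' Defaults follow the classic feed-forward toolbox settings: damping
#' mu starts at 1e-3, is multiplied by 10 after a rejected step and by 0.1
#' after an accepted one, and training halts if mu exceeds 1e10.  Early
#' stopping watches the validation MSE: an epoch "fails" when the validation
#' error does not strictly decrease below the best seen so far, and training
#' stops after `max_fail` consecutive failures (default 6), returning the
#' weights from the best-validation epoch.
#'
#' @param max_epochs maximum number of LM epochs.
#' @param max_fail consecutive validation failures tolerated (>= 1).
#' @param mu_init,mu_increase,mu_decrease,mu_max LM damping schedule.
#' @param goal_mse stop when the training MSE reaches this goal.
#' @param init weight initialization: `"nguyen-widrow"` or `"uniform"`.
#' @return a list of class `training_config`.
#' @export
training_config <- function(max_epochs = 1000L, max_fail = 6L,
                            mu_init = 1e-3, mu_increase = 10,
                            mu_decrease = 0.1, mu_max = 1e10,
                            goal_mse = 0,
                            init = c("nguyen-widrow", "uniform")) {
  init <- match.arg(init)
  stopifnot(max_fail >= 1L, mu_init > 0, mu_increase > 1,
            mu_decrease > 0, mu_decrease < 1, max_epochs >= 1L)
  structure(list(max_epochs = as.integer(max_epochs),
                 max_fail = as.integer(max_fail),
                 mu_init = mu_init, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, mu_max = mu_max,
                 goal_mse = goal_mse, init = init),
            class = "training_config")
}

#' Initialize a multilayer perceptron
#'
#' Layer sizes run input -> hidden(s) -> single output; all units use the
#' hyperbolic tangent.  Input scaling is fitted on the training inputs:
#' each feature's (min, max) maps linearly to `[-1, 1]`; a constant feature
#' degenerates to the identity map with a warning.  Hidden weights use the
#' seeded Nguyen-Widrow scheme (random unit directions scaled by
#' `0.7 * q^(1/p)`, biases spread across the input range), which spreads the
#' tanh active regions over the scaled input cube; `"uniform"` draws all
#' weights from U(-0.5, 0.5).
#'
#' @param layer_sizes integer vector, e.g. `c(20, 40, 1)`; 1 or 2 hidden
#'   layers; final size must be 1.
#' @param training_inputs numeric matrix used to fit the input scaling.
#' @param seed integer seed; the same seed reproduces the weights exactly.
#' @param init `"nguyen-widrow"` or `"uniform"`.
#' @return an object of class `mlp_model`.
#' @export
init_model <- function(layer_sizes, training_inputs, seed = 1L,
                       init = c("nguyen-widrow", "uniform")) {
  init <- match.arg(init)
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 3L, length(layer_sizes) <= 4L,
            layer_sizes[length(layer_sizes)] == 1L, all(layer_sizes >= 1L),
            is.matrix(training_inputs),
            ncol(training_inputs) == layer_sizes[1],
            nrow(training_inputs) >= 2L)
  fmin <- apply(training_inputs, 2, min)
  fmax <- apply(training_inputs, 2, max)
  constant <- fmax - fmin <= 0
  if (any(constant)) {
    warning("constant feature(s) ", paste(which(constant), collapse = ", "),
            "; scaling degenerates to identity for them")
    # (min, max) = (-1, 1) makes the affine map the identity
    fmin[constant] <- -1
    fmax[constant] <- 1
  }
  n_layers <- length(layer_sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  withr::with_seed(seed, {
    for (l in seq_len(n_layers)) {
      p <- layer_sizes[l]
      q <- layer_sizes[l + 1L]
      if (init == "nguyen-widrow" && l < n_layers) {
        w <- matrix(stats::runif(p * q, -1, 1), nrow = p)
        norms <- sqrt(colSums(w^2))
        beta <- 0.7 * q^(1 / p)
        w <- sweep(w, 2, beta / pmax(norms, 1e-12), `*`)
        b <- beta * seq(-1, 1, length.out = q) *
          sign(stats::runif(q, -1, 1))
        weights[[l]] <- w
        biases[[l]] <- b
      } else {
        weights[[l]] <- matrix(stats::runif(p * q, -0.5, 0.5), nrow = p)
        biases[[l]] <- stats::runif(q, -0.5, 0.5)
      }
    }
  })
  structure(list(layer_sizes = layer_sizes,
                 weights = weights, biases = biases,
                 scaling = list(min = unname(fmin), max = unname(fmax)),
                 activation = "tanh",
                 feature_names = colnames(training_inputs),
                 seed = as.integer(seed),
                 provenance = list(init = init)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> topology ", paste(x$layer_sizes, collapse = "x"),
      ", tanh units, ", n_params(x), " parameters\n", sep = "")
  invisible(x)
}

scale_inputs <- function(model, x) {
  rng <- model$scaling$max - model$scaling$min
  sweep(sweep(x, 2, model$scaling$min), 2, rng / 2, `/`) - 1
}

n_params <- function(model) {
  sum(vapply(model$weights, length, integer(1))) +
    sum(vapply(model$biases, length, integer(1)))
}

as_input_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$layer_sizes[1]) {
    stop("input has ", ncol(x), " features; model expects ",
         model$layer_sizes[1])
  }
  x
}

# Forward pass keeping per-layer activations (for the Jacobian).
forward_full <- function(model, x) {
  x <- as_input_matrix(model, x)
  a <- scale_inputs(model, x)
  activations <- list(a)
  for (l in seq_along(model$weights)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], `+`)
    a <- tanh(z)
    activations[[l + 1L]] <- a
  }
  activations
}

#' Forward pass of an MLP
#'
#' Scales the raw features to `[-1, 1]` using the fitted training-range map,
#' then propagates through the tanh layers.  A pure function of (model, x);
#' outputs are bounded in (-1, 1).
#'
#' @param model an `mlp_model`.
#' @param x a feature vector or matrix (rows = examples) on the raw scale.
#' @return numeric vector of outputs, one per row.
#' @export
forward <- function(model, x) {
  acts <- forward_full(model, x)
  as.numeric(acts[[length(acts)]])
}

# Flatten / unflatten parameters: per layer, as.vector(W) then b.
get_params <- function(model) {
  unlist(lapply(seq_along(model$weights), function(l) {
    c(as.vector(model$weights[[l]]), model$biases[[l]])
  }))
}

set_params <- function(model, theta) {
  pos <- 0L
  for (l in seq_along(model$weights)) {
    nw <- length(model$weights[[l]])
    nb <- length(model$biases[[l]])
    model$weights[[l]][] <- theta[pos + seq_len(nw)]
    model$biases[[l]] <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  model
}

# Jacobian of network outputs w.r.t. all parameters (n x n_params),
# computed by reverse-mode sweep vectorized over examples.
output_jacobian <- function(model, x) {
  acts <- forward_full(model, x)
  L <- length(model$weights)
  n <- nrow(acts[[1]])
  # delta[[l]]: d y / d z_l  (n x size_l)
  delta <- vector("list", L)
  delta[[L]] <- 1 - acts[[L + 1L]]^2
  if (L > 1L) {
    for (l in (L - 1L):1L) {
      delta[[l]] <- (delta[[l + 1L]] %*% t(model$weights[[l + 1L]])) *
        (1 - acts[[l + 1L]]^2)
    }
  }
  blocks <- vector("list", 2L * L)
  for (l in seq_len(L)) {
    a_prev <- acts[[l]]
    p <- ncol(a_prev)
    q <- ncol(delta[[l]])
    # d y / d W_l[j, k] = a_prev[, j] * delta[, k]; column-major order of W
    jac_w <- a_prev[, rep(seq_len(p), times = q), drop = FALSE] *
      delta[[l]][, rep(seq_len(q), each = p), drop = FALSE]
    blocks[[2L * l - 1L]] <- jac_w
    blocks[[2L * l]] <- delta[[l]]
  }
  do.call(cbind, blocks)
}

mse_of <- function(model, x, y) mean((y - forward(model, x))^2)

#' One Levenberg-Marquardt proposal
#'
#' For residuals `e = y - out` and output Jacobian `J`, proposes
#' `delta = (J'J + mu I)^(-1) J'e` and returns the candidate model together
#' with its training MSE.  Small `mu` approaches the Gauss-Newton step,
#' large `mu` a short gradient step; the accept/reject schedule lives in
#' [train_mlp()].
#'
#' @param model an `mlp_model`.
#' @param x,y training inputs (raw scale) and +-1 targets.
#' @param mu damping parameter (> 0).
#' @return list with `model` (candidate) and `mse` (its training MSE).
#' @export
lm_step <- function(model, x, y, mu) {
  stopifnot(mu > 0, length(y) == nrow(as_input_matrix(model, x)))
  e <- y - forward(model, x)
  J <- output_jacobian(model, x)
  A <- crossprod(J)
  diag(A) <- diag(A) + mu
  delta <- tryCatch(solve(A, crossprod(J, e)),
                    error = function(err) NULL)
  if (is.null(delta)) return(list(model = model, mse = Inf, singular = TRUE))
  cand <- set_params(model, get_params(model) + as.numeric(delta))
  list(model = cand, mse = mse_of(cand, x, y), singular = FALSE)
}

# Pure early-stopping scan: given the per-epoch validation MSE sequence,
# return the epoch training would stop at and the best epoch.  An epoch
# fails when it does not strictly decrease below the running best; the
# counter resets on strict improvement.
early_stop_scan <- function(val_mse, max_fail) {
  best <- Inf
  best_epoch <- 0L
  fails <- 0L
  for (i in seq_along(val_mse)) {
    if (val_mse[i] < best) {
      best <- val_mse[i]
      best_epoch <- i
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= max_fail) {
        return(list(stop_epoch = i, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(val_mse), best_epoch = best_epoch)
}

#' Train an MLP by Levenberg-Marquardt with early stopping
#'
#' Each epoch proposes an LM step; if the training MSE does not strictly
#' decrease the damping `mu` is multiplied by `mu_increase` and the step
#' retried, and after an accepted step `mu` is multiplied by `mu_decrease`.
#' Training stops when (a) the validation MSE has failed to strictly improve
#' for `max_fail` consecutive epochs, (b) `max_epochs` is reached, (c) the
#' training MSE reaches `goal_mse`, or (d) `mu` exceeds `mu_max`.  The
#' returned model carries the weights of the epoch with minimum validation
#' MSE.  Deterministic: no randomness beyond the model's initialization.
#'
#' @param model an initialized `mlp_model`.
#' @param train_x,train_y training inputs (raw scale) and +-1 targets.
#' @param val_x,val_y validation inputs and targets (mandatory, non-empty).
#' @param config a [training_config()].
#' @return list with `model` (best-validation weights) and `trace` (class
#'   `training_trace`: per-epoch `train_mse`, `val_mse`, `stop_reason`,
#'   `best_epoch`).
#' @export
train_mlp <- function(model, train_x, train_y, val_x, val_y,
                      config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (is.null(val_x) || NROW(val_x) == 0L) {
    stop("validation set is mandatory and must be non-empty")
  }
  train_x <- as_input_matrix(model, train_x)
  val_x <- as_input_matrix(model, val_x)
  stopifnot(nrow(train_x) == length(train_y), nrow(val_x) == length(val_y))

  mu <- config$mu_init
  current_mse <- mse_of(model, train_x, train_y)
  best_val <- mse_of(model, val_x, val_y)  # epoch-0 baseline
  best_model <- model
  best_epoch <- 0L
  fails <- 0L
  train_trace <- numeric(0)
  val_trace <- numeric(0)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    # inner mu loop: escalate damping until the step reduces training MSE
    repeat {
      step <- lm_step(model, train_x, train_y, mu)
      if (!step$singular && step$mse < current_mse) {
        model <- step$model
        current_mse <- step$mse
        mu <- max(mu * config$mu_decrease, 1e-20)
        break
      }
      mu <- mu * config$mu_increase
      if (mu > config$mu_max) break
    }
    if (mu > config$mu_max) {
      stop_reason <- "mu_max"
      break
    }
    val_mse <- mse_of(model, val_x, val_y)
    train_trace <- c(train_trace, current_mse)
    val_trace <- c(val_trace, val_mse)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_model <- model
      best_epoch <- epoch
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= config$max_fail) {
        stop_reason <- "max_fail"
        break
      }
    }
    if (current_mse <= config$goal_mse) {
      stop_reason <- "goal"
      break
    }
  }
  trace <- structure(list(train_mse = train_trace, val_mse = val_trace,
                          stop_reason = stop_reason,
                          best_epoch = best_epoch,
                          best_val_mse = best_val),
                     class = "training_trace")
  best_model$provenance$trained <- TRUE
  best_model$provenance$stop_reason <- stop_reason
  best_model$provenance$best_epoch <- best_epoch
  list(model = best_model, trace = trace)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a model to a JSON file
#'
#' The file is self-describing: format version, layer sizes, weights,
#' biases, input scaling, activation, seed, and provenance, plus a weight
#' checksum verified on load.
#'
#' @param model an `mlp_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  theta <- get_params(model)
  # parameters stored as %.17g strings so the text round-trip is exact to
  # the last bit
  payload <- list(
    format = "vironet-mlp",
    version = MODEL_FORMAT_VERSION,
    layer_sizes = as.list(model$layer_sizes),
    params = as.list(sprintf("%.17g", theta)),  # column-major per layer: W, b
    scaling_min = as.list(sprintf("%.17g", model$scaling$min)),
    scaling_max = as.list(sprintf("%.17g", model$scaling$max)),
    activation = model$activation,
    feature_names = model$feature_names,
    seed = model$seed,
    provenance = model$provenance,
    checksum = sum(theta^2))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path path to a model JSON file.
#' @return an `mlp_model`; errors on version mismatch or a corrupted file.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "vironet-mlp") ||
      !identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop("not a vironet model file or version mismatch: ", path)
  }
  layer_sizes <- as.integer(unlist(payload$layer_sizes))
  n_layers <- length(layer_sizes) - 1L
  skeleton <- structure(list(
    layer_sizes = layer_sizes,
    weights = lapply(seq_len(n_layers), function(l) {
      matrix(0, layer_sizes[l], layer_sizes[l + 1L])
    }),
    biases = lapply(seq_len(n_layers), function(l) {
      numeric(layer_sizes[l + 1L])
    }),
    scaling = list(min = as.numeric(unlist(payload$scaling_min)),
                   max = as.numeric(unlist(payload$scaling_max))),
    activation = payload$activation,
    feature_names = payload$feature_names,
    seed = payload$seed,
    provenance = as.list(payload$provenance)),
    class = "mlp_model")
  theta <- as.numeric(unlist(payload$params))
  if (length(theta) != n_params(skeleton)) {
    stop("parameter count mismatch in ", path, ": expected ",
         n_params(skeleton), ", found ", length(theta))
  }
  if (length(skeleton$scaling$min) != layer_sizes[1]) {
    stop("input scaling length mismatch in ", path)
  }
  model <- set_params(skeleton, theta)
  if (abs(sum(theta^2) - payload$checksum) >
      1e-8 * max(1, abs(payload$checksum))) {
    stop("checksum mismatch: model file appears corrupted: ", path)
  }
  model
}
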