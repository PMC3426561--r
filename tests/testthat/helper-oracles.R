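# Independent oracles used across the test files.  Each deliberately avoids
# the code path it checks: plain loops, finite differences, grid scans, and
# dynamic-programming alignment written from the textbook definitions.

# Needleman-Wunsch global alignment score with match 1, mismatch 0, and a
# linear gap penalty; also reports matches and alignment length of one
# optimal traceback.
nw_align <- function(a, b, gap = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -gap * (0:m)
  S[, 1] <- -gap * (0:n)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                             S[i, j + 1] - gap,
                             S[i + 1, j] - gap)
    }
  }
  # traceback (diagonal preferred) for matches / alignment length
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(S[i + 1, j + 1] - (S[i, j] + (A[i] == B[j]))) < 1e-9) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(S[i + 1, j + 1] - (S[i, j + 1] - gap)) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  list(score = S[n + 1, m + 1], matches = matches, length = len,
       identity = matches / len)
}

# Forward pass re-implemented as explicit per-example loops.
oracle_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- 2 * (x[i, ] - model$scaling$min) /
      (model$scaling$max - model$scaling$min) - 1
    for (l in seq_along(model$weights)) {
      a <- tanh(as.numeric(t(model$weights[[l]]) %*% a) + model$biases[[l]])
    }
    out[i] <- a
  }
  out
}

# Central finite-difference Jacobian of network outputs w.r.t. parameters.
fd_jacobian <- function(model, x, h = 1e-6) {
  theta <- vironet:::get_params(model)
  n <- NROW(if (is.null(dim(x))) t(x) else x)
  J <- matrix(0, n, length(theta))
  for (p in seq_along(theta)) {
    up <- theta; up[p] <- up[p] + h
    dn <- theta; dn[p] <- dn[p] - h
    J[, p] <- (forward(vironet:::set_params(model, up), x) -
                 forward(vironet:::set_params(model, dn), x)) / (2 * h)
  }
  J
}

# Zero crossing of net_charge located by a fixed-resolution pH grid scan.
grid_scan_pi <- function(residues, table = pka_table(), step = 5e-4) {
  grid <- seq(0, 14, by = step)
  charge <- net_charge(residues, grid, table)
  i <- max(which(charge > 0))
  (grid[i] + grid[i + 1]) / 2
}

# Random cleaned protein sequence.
random_sequence <- function(len) {
  paste(sample(AA_CODES, len, replace = TRUE), collapse = "")
}

# Small constant-output model: a 1-1-1 tanh net whose output is
# tanh(bias) regardless of input (all weights zero), with identity scaling.
constant_model <- function(value) {
  m <- init_model(c(1L, 1L, 1L), matrix(c(-1, 1), ncol = 1), seed = 1L)
  m$weights <- lapply(m$weights, function(w) w * 0)
  m$biases <- list(0, atanh(value))
  m
}

# Fast training configuration for test-scale problems.
test_config <- function(max_epochs = 40L, ...) {
  training_config(max_epochs = max_epochs, ...)
}
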