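# Minimal feed-forward network engine: rectifier activations, inverted
# dropout, softmax cross-entropy head, Adam updates, full backprop with
# gradients exposed at the input so the step-trace-person hierarchy can be
# fine-tuned end to end.

mlp_init <- function(input_dim, hidden, n_class, seed = 1) {
  widths <- c(input_dim, hidden, n_class)
  withr::with_seed(as.integer(seed), {
    layers <- lapply(seq_len(length(widths) - 1), function(l) {
      fan_in <- widths[l]
      list(W = matrix(stats::rnorm(fan_in * widths[l + 1], 0,
                                   sqrt(2 / fan_in)),
                      fan_in, widths[l + 1]),
           b = numeric(widths[l + 1]))
    })
    structure(list(layers = layers, widths = widths), class = "fg_mlp")
  })
}

# Forward pass. Hidden layers: ReLU (+ inverted dropout when training).
# Final layer: linear logits -> row-wise softmax. Dropout masks are drawn
# from the current RNG so callers control determinism.
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  X <- as.matrix(X)
  L <- length(net$layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    if (l < L) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
        A <- A * m / (1 - dropout)
        masks[[l]] <- m
      }
      acts[[l + 1]] <- A
    } else {
      acts[[l + 1]] <- Z      # logits
    }
  }
  logits <- acts[[L + 1]]
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, acts = acts, masks = masks,
       dropout = if (training) dropout else 0)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy of one-hot labels `y` (integer class indices).
cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# Backward pass. Gradient at the logits can come from two sources that are
# summed: `grad_logits` (e.g. (P - Y)/n from a cross-entropy loss) and
# `grad_probs` (an upstream gradient on the softmax outputs, mapped through
# the softmax Jacobian). Returns per-layer gradients plus the gradient with
# respect to the input matrix.
mlp_backward <- function(net, fwd, grad_logits = NULL, grad_probs = NULL) {
  L <- length(net$layers)
  P <- fwd$probs
  G <- matrix(0, nrow(P), ncol(P))
  if (!is.null(grad_logits)) G <- G + grad_logits
  if (!is.null(grad_probs)) {
    # dL/dz = P * (g - rowSums(g * P)) for softmax rows
    G <- G + P * (grad_probs - rowSums(grad_probs * P))
  }
  grads <- vector("list", L)
  delta <- G
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(net$layers[[l]]$W)
      if (fwd$dropout > 0 && !is.null(fwd$masks[[l - 1]])) {
        delta <- delta * fwd$masks[[l - 1]] / (1 - fwd$dropout)
      }
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  dX <- delta %*% t(net$layers[[1]]$W)
  # note: when L == 1 the loop above never multiplies by ReLU masks at the
  # input, which is correct (inputs are not activations)
  list(grads = grads, dX = dX)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t)
    vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

# Train a single network with cross-entropy, 20% dropout by default, and
# early stopping on a validation split of the training portion. `y` holds
# integer class indices (1-based). Deterministic under `seed`.
mlp_train <- function(net, X, y, epochs = 150, lr = 1e-3, dropout = 0.2,
                      val_frac = 0.1, patience = 25, seed = 1,
                      verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  withr::with_seed(as.integer(seed), {
    n_val <- base::floor(val_frac * n)
    # a validation split below a handful of samples gives a selection
    # signal noisier than useful: train on everything, full epoch budget
    use_val <- n_val >= 5
    if (use_val) {
      idx <- sample.int(n)
      val <- idx[seq_len(n_val)]
      tra <- idx[-seq_len(n_val)]
    } else {
      tra <- seq_len(n)
      val <- seq_len(n)
    }
    state <- adam_init(net)
    best <- list(net = net, loss = Inf, epoch = 0)
    for (e in seq_len(epochs)) {
      fwd <- mlp_forward(net, X[tra, , drop = FALSE], dropout = dropout,
                         training = TRUE)
      Y <- matrix(0, length(tra), ncol(fwd$probs))
      Y[cbind(seq_along(tra), y[tra])] <- 1
      bwd <- mlp_backward(net, fwd,
                          grad_logits = (fwd$probs - Y) / length(tra))
      upd <- adam_step(net, bwd$grads, state, t = e, lr = lr)
      net <- upd$net
      state <- upd$state
      vloss <- cross_entropy(
        mlp_forward(net, X[val, , drop = FALSE])$probs, y[val])
      if (vloss < best$loss - 1e-6) {
        best <- list(net = net, loss = vloss, epoch = e)
      } else if (use_val && e - best$epoch >= patience) break
      if (verbose && e %% 20 == 0) {
        message(sprintf("epoch %d val loss %.4f", e, vloss))
      }
    }
    best$net
  })
}
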