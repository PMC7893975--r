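#' Hyperparameters of the hierarchical attentive network
#'
#' Defaults follow the reported best setting: 50-dimensional herb
#' embeddings, a 128-unit first projection inside the second attention
#' layer, a 50-unit hidden layer before the sigmoid output, L2 factor
#' 2e-4, Adam with learning rate 1e-3, 30 epochs at batch size 1.
#'
#' @param d_h herb embedding dimension.
#' @param d_a projection dimension of the second attention layer.
#' @param d_m hidden units of the output perceptron.
#' @param lambda L2 regularization factor (>= 0).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size samples per gradient step (default 1; larger values
#'   average gradients over the batch).
#' @param squared_l2 if `TRUE` the regularizer is `lambda * ||w||^2`
#'   instead of the default unsquared norm `lambda * ||w||`.
#' @param attend_original if `TRUE` (default) the prescription feature
#'   vector is the attention-weighted sum of the original embeddings; if
#'   `FALSE` the first-layer updated representations are summed instead.
#' @return list of class `hann_hyper`.
#' @export
hann_hyper <- function(d_h = 50L, d_a = 128L, d_m = 50L,
                       lambda = 2e-4, lr = 1e-3, epochs = 30L,
                       batch_size = 1L, squared_l2 = FALSE,
                       attend_original = TRUE) {
  stopifnot(d_h >= 1L, d_a >= 1L, d_m >= 1L, lambda >= 0, lr >= 0,
            epochs >= 1L, batch_size >= 1L)
  structure(list(d_h = as.integer(d_h), d_a = as.integer(d_a),
                 d_m = as.integer(d_m), lambda = lambda, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 squared_l2 = isTRUE(squared_l2),
                 attend_original = isTRUE(attend_original)),
            class = "hann_hyper")
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters
#'
#' The embedding table is drawn uniform(-0.1, 0.1); the five weight
#' matrices use Glorot-uniform initialization. Deterministic given the
#' seed.
#'
#' @param n_herbs vocabulary size N (rows of the embedding table).
#' @param hyper a [hann_hyper()].
#' @param seed integer seed.
#' @return list of class `hann_params` with `H` (N x d_h), `W1`
#'   (d_h x d_h), `W2` (d_a x d_h), `W3` (1 x d_a), `W4` (d_m x d_h),
#'   `W5` (1 x d_m) and `hyper`.
#' @export
hann_init <- function(n_herbs, hyper = hann_hyper(), seed = 1L) {
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  hann_init_stream(n_herbs, hyper)
}

# draws from the current RNG stream (no seeding); used by the trainer so
# that initialization and epoch shuffling share one seeded stream
hann_init_stream <- function(n_herbs, hyper) {
  stopifnot(n_herbs >= 1L)
  params <- list(
    H  = matrix(stats::runif(n_herbs * hyper$d_h, -0.1, 0.1),
                n_herbs, hyper$d_h),
    W1 = glorot(hyper$d_h, hyper$d_h),
    W2 = glorot(hyper$d_a, hyper$d_h),
    W3 = glorot(1L, hyper$d_a),
    W4 = glorot(hyper$d_m, hyper$d_h),
    W5 = glorot(1L, hyper$d_m),
    hyper = hyper)
  class(params) <- "hann_params"
  params
}

#' @export
print.hann_params <- function(x, ...) {
  cat("<hann_params> N=", nrow(x$H), " d_h=", x$hyper$d_h,
      " d_a=", x$hyper$d_a, " d_m=", x$hyper$d_m, "\n", sep = "")
  invisible(x)
}

# Row-wise softmax with max subtraction; x is a matrix (rows are logit
# vectors) or a plain vector.
softmax_rows <- function(x) {
  if (is.null(dim(x))) {
    e <- exp(x - max(x))
    return(e / sum(e))
  }
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Embedding lookup for a prescription
#'
#' @param ids integer herb ids (1-based rows of `params$H`).
#' @param params a [hann_init()] parameter set.
#' @return k x d_h matrix stacking the herbs' embedding rows in
#'   prescription order.
#' @export
hann_embed <- function(ids, params) {
  ids <- as.integer(ids)
  if (any(ids < 1L | ids > nrow(params$H))) {
    bad <- ids[ids < 1L | ids > nrow(params$H)]
    stop("herb id out of vocabulary: ", paste(bad, collapse = ", "))
  }
  params$H[ids, , drop = FALSE]
}

#' First attention layer: herb-herb correlation
#'
#' Computes `beta = softmax(Hmat W1 Hmat^T)` row-wise, so each herb gets a
#' probability distribution over all herbs of the prescription, and the
#' correlation-enriched representations `Hbar = beta Hmat`.
#'
#' @param Hmat k x d_h stacked embeddings.
#' @param W1 d_h x d_h weight matrix.
#' @return list with `beta` (k x k, rows sum to 1) and `Hbar` (k x d_h).
#' @export
first_attention <- function(Hmat, W1) {
  S <- Hmat %*% W1 %*% t(Hmat)
  if (any(!is.finite(S))) stop("non-finite attention logits")
  beta <- softmax_rows(S)
  list(beta = beta, Hbar = beta %*% Hmat)
}

#' Second attention layer: herb-to-efficacy contribution
#'
#' Computes `alpha = softmax(W3 tanh(W2 Hbar^T))` over the k herb
#' positions, and the prescription feature vector `M = alpha Hmat` — the
#' weighted sum of the original embeddings (set `attend_original = FALSE`
#' in the hyperparameters to sum the updated representations `Hbar`
#' instead).
#'
#' @param Hmat k x d_h original embeddings.
#' @param Hbar k x d_h updated representations from [first_attention()].
#' @param W2 d_a x d_h weight matrix.
#' @param W3 1 x d_a weight matrix.
#' @param attend_original sum original embeddings (default) or `Hbar`.
#' @return list with `alpha` (length k, sums to 1) and `M` (length d_h).
#' @export
second_attention <- function(Hmat, Hbar, W2, W3, attend_original = TRUE) {
  Z <- W2 %*% t(Hbar)            # d_a x k
  if (any(!is.finite(Z))) stop("non-finite attention logits")
  Tm <- tanh(Z)
  u <- as.vector(W3 %*% Tm)      # length k
  alpha <- softmax_rows(u)
  src <- if (attend_original) Hmat else Hbar
  M <- as.vector(alpha %*% src)  # length d_h
  list(alpha = alpha, M = M)
}

#' Output layer: efficacy probability
#'
#' `p = sigmoid(W5 ReLU(W4 M))`.
#'
#' @param M length-d_h prescription feature vector.
#' @param W4 d_m x d_h weight matrix.
#' @param W5 1 x d_m weight matrix.
#' @return probability in (0, 1).
#' @export
output_probability <- function(M, W4, W5) {
  v <- as.vector(W4 %*% M)
  r <- pmax(v, 0)
  z <- sum(W5 * r)
  p <- 1 / (1 + exp(-z))
  # keep the probability strictly inside (0, 1) despite saturation
  min(max(p, 1e-12), 1 - 1e-12)
}

#' Full forward pass
#'
#' @param ids integer herb ids of one prescription.
#' @param params a [hann_init()] parameter set.
#' @return list of class `hann_trace` with `Hmat`, `beta`, `Hbar`,
#'   `alpha`, `M`, `p`.
#' @export
hann_forward <- function(ids, params) {
  Hmat <- hann_embed(ids, params)
  a1 <- first_attention(Hmat, params$W1)
  a2 <- second_attention(Hmat, a1$Hbar, params$W2, params$W3,
                         attend_original = params$hyper$attend_original)
  p <- output_probability(a2$M, params$W4, params$W5)
  structure(list(Hmat = Hmat, beta = a1$beta, Hbar = a1$Hbar,
                 alpha = a2$alpha, M = a2$M, p = p),
            class = "hann_trace")
}

param_norm <- function(params) {
  sqrt(sum(params$H^2) + sum(params$W1^2) + sum(params$W2^2) +
         sum(params$W3^2) + sum(params$W4^2) + sum(params$W5^2))
}

#' Regularized cross-entropy loss for one prescription
#'
#' `L = -[y log p + (1 - y) log(1 - p)] + lambda * ||w||_2`, where `w`
#' concatenates all entries of the embedding table and the five weight
#' matrices. The regularizer is the unsquared L2 norm by default
#' (`squared_l2 = TRUE` in the hyperparameters switches to the squared
#' form).
#'
#' @param p predicted probability in (0, 1).
#' @param y label, 0 or 1.
#' @param params a [hann_init()] parameter set.
#' @return non-negative loss value.
#' @export
hann_loss <- function(p, y, params) {
  if (!(length(y) == 1L && y %in% c(0, 1))) stop("label y must be 0 or 1")
  p <- min(max(p, 1e-12), 1 - 1e-12)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  nrm <- param_norm(params)
  reg <- if (params$hyper$squared_l2) params$hyper$lambda * nrm^2
         else params$hyper$lambda * nrm
  ce + reg
}

#' Loss and analytic gradients for one prescription
#'
#' Backpropagates the regularized cross-entropy through the output layer,
#' both attention layers and the embedding lookup. Used by the trainer
#' and verifiable against finite differences.
#'
#' @param ids integer herb ids of one prescription.
#' @param y label, 0 or 1.
#' @param params a [hann_init()] parameter set.
#' @return list with `loss`, `p`, `trace` and `grads` (matrices `H`,
#'   `W1`..`W5` shaped like the parameters).
#' @export
hann_gradients <- function(ids, y, params) {
  hyper <- params$hyper
  tr <- hann_forward(ids, params)
  k <- length(ids)
  E <- tr$Hmat
  beta <- tr$beta
  Hbar <- tr$Hbar
  alpha <- tr$alpha

  # recompute intermediates not kept in the trace
  Z <- params$W2 %*% t(Hbar)     # d_a x k
  Tm <- tanh(Z)
  v <- as.vector(params$W4 %*% tr$M)
  r <- pmax(v, 0)

  p <- tr$p
  dz <- p - y                    # d L_ce / d logit

  gW5 <- matrix(dz * r, 1L)
  dr <- dz * as.vector(params$W5)
  dv <- dr * (v > 0)
  gW4 <- outer(dv, tr$M)
  dM <- as.vector(crossprod(params$W4, dv))   # length d_h

  src <- if (hyper$attend_original) E else Hbar
  dalpha <- as.vector(src %*% dM)             # length k
  dsrc_fromM <- outer(alpha, dM)              # k x d_h

  # softmax over positions
  du <- alpha * (dalpha - sum(alpha * dalpha))
  gW3 <- matrix(as.vector(Tm %*% du), 1L)     # 1 x d_a
  dT <- outer(as.vector(params$W3), du)       # d_a x k
  dZ <- dT * (1 - Tm^2)
  gW2 <- dZ %*% Hbar                          # d_a x d_h
  dHbar <- t(crossprod(params$W2, dZ))        # k x d_h
  if (!hyper$attend_original) dHbar <- dHbar + dsrc_fromM

  # Hbar = beta E
  dbeta <- dHbar %*% t(E)                     # k x k
  dE <- crossprod(beta, dHbar)                # k x d_h

  # row-wise softmax of S = E W1 E^T
  dS <- beta * (dbeta - rowSums(beta * dbeta))
  gW1 <- crossprod(E, dS) %*% E               # d_h x d_h
  dE <- dE + dS %*% E %*% t(params$W1) + crossprod(dS, E %*% params$W1)
  if (hyper$attend_original) dE <- dE + dsrc_fromM

  # scatter embedding gradient and add the regularizer term
  nrm <- param_norm(params)
  reg_scale <- if (hyper$squared_l2) 2 * hyper$lambda
               else if (nrm > 0) hyper$lambda / nrm else 0
  gH <- reg_scale * params$H
  gH[ids, ] <- gH[ids, ] + dE

  grads <- list(H = gH,
                W1 = gW1 + reg_scale * params$W1,
                W2 = gW2 + reg_scale * params$W2,
                W3 = gW3 + reg_scale * params$W3,
                W4 = gW4 + reg_scale * params$W4,
                W5 = gW5 + reg_scale * params$W5)
  list(loss = hann_loss(p, y, params), p = p, trace = tr, grads = grads)
}

adam_state <- function(params) {
  blocks <- c("H", "W1", "W2", "W3", "W4", "W5")
  st <- lapply(blocks, function(b) {
    list(m = params[[b]] * 0, v = params[[b]] * 0)
  })
  names(st) <- blocks
  st
}

adam_update <- function(params, grads, state, t, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (b in names(state)) {
    g <- grads[[b]]
    state[[b]]$m <- beta1 * state[[b]]$m + (1 - beta1) * g
    state[[b]]$v <- beta2 * state[[b]]$v + (1 - beta2) * g^2
    mhat <- state[[b]]$m / (1 - beta1^t)
    vhat <- state[[b]]$v / (1 - beta2^t)
    params[[b]] <- params[[b]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Coerce the accepted dataset shapes to a list of integer id vectors plus
# labels. `dataset` is either build_balanced_dataset() output (needs a
# vocabulary) or a list(ids = ..., labels = ...).
dataset_ids <- function(dataset, vocabulary = NULL) {
  if (!is.null(dataset$ids)) {
    return(list(ids = lapply(dataset$ids, as.integer),
                labels = as.integer(dataset$labels)))
  }
  if (is.null(vocabulary)) {
    stop("a vocabulary is required to index prescriptions")
  }
  ids <- lapply(dataset$prescriptions, function(p) herb_id(vocabulary, p$herbs))
  list(ids = ids, labels = as.integer(dataset$labels))
}

#' Train the hierarchical attentive network
#'
#' Adam on the regularized cross-entropy, one prescription per step by
#' default (batch size 1), with the sample order reshuffled each epoch.
#' Bit-identical results for a given seed.
#'
#' @param dataset either the output of [build_balanced_dataset()] (then
#'   `vocabulary` is required) or a list with `ids` (list of integer
#'   vectors) and `labels` (0/1).
#' @param vocabulary a [herb_vocabulary()] sized to the corpus; ignored
#'   when `dataset` already carries ids.
#' @param hyper a [hann_hyper()].
#' @param seed integer seed for initialization and epoch shuffling.
#' @param params_init optional pre-built [hann_init()] parameters
#'   (initialization is then skipped and the seed only drives shuffling).
#' @return list with `params` (trained), `loss_history` (mean loss per
#'   epoch) and `hyper`.
#' @export
hann_train <- function(dataset, vocabulary = NULL, hyper = hann_hyper(),
                       seed = 1L, params_init = NULL) {
  ds <- dataset_ids(dataset, vocabulary)
  n <- length(ds$ids)
  if (n == 0L) stop("empty training dataset")
  if (length(unique(ds$labels)) < 2L) {
    warning("training labels are all one class; training is degenerate")
  }
  n_herbs <- if (!is.null(vocabulary)) length(vocabulary$names)
             else max(unlist(ds$ids))
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  params <- if (is.null(params_init)) {
    # drawn from the seeded stream; epoch shuffles continue from it
    hann_init_stream(n_herbs, hyper)
  } else {
    stopifnot(nrow(params_init$H) >= n_herbs)
    params_init
  }
  params$hyper <- hyper
  state <- adam_state(params)
  t <- 0L
  loss_history <- numeric(hyper$epochs)
  bs <- hyper$batch_size
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + bs - 1L, n)]
      acc <- NULL
      for (j in batch) {
        g <- hann_gradients(ds$ids[[j]], ds$labels[[j]], params)
        losses[j] <- g$loss
        if (is.null(acc)) acc <- g$grads
        else for (b in names(acc)) acc[[b]] <- acc[[b]] + g$grads[[b]]
      }
      if (length(batch) > 1L) {
        for (b in names(acc)) acc[[b]] <- acc[[b]] / length(batch)
      }
      t <- t + 1L
      if (hyper$lr > 0) {
        upd <- adam_update(params, acc, state, t, hyper$lr)
        params <- upd$params
        state <- upd$state
      }
      i <- i + bs
    }
    loss_history[epoch] <- mean(losses)
  }
  list(params = params, loss_history = loss_history, hyper = hyper)
}

#' Second-layer attention weights of a prescription
#'
#' The per-herb probabilities expressing each herb's contribution to the
#' prescription's efficacy under the trained model; they sum to 1.
#'
#' @param p a [prescription()] or an integer id vector.
#' @param params trained [hann_init()] parameters.
#' @param vocabulary required when `p` is a prescription.
#' @return numeric vector of length k, named by herb when names are
#'   available.
#' @export
attention_weights <- function(p, params, vocabulary = NULL) {
  if (inherits(p, "prescription")) {
    if (is.null(vocabulary)) stop("a vocabulary is required")
    ids <- herb_id(vocabulary, p$herbs)
    w <- hann_forward(ids, params)$alpha
    names(w) <- p$herbs
    w
  } else {
    hann_forward(as.integer(p), params)$alpha
  }
}

#' Predicted efficacy probability
#'
#' @inheritParams attention_weights
#' @return probability in (0, 1).
#' @export
hann_predict <- function(p, params, vocabulary = NULL) {
  if (inherits(p, "prescription")) {
    if (is.null(vocabulary)) stop("a vocabulary is required")
    ids <- herb_id(vocabulary, p$herbs)
  } else {
    ids <- as.integer(p)
  }
  hann_forward(ids, params)$p
}
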