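# Independent straight-line oracle for the forward pass: plain scalar
# loops, no shared code with the package implementation.
oracle_forward <- function(ids, params) {
  k <- length(ids)
  dh <- ncol(params$H)
  da <- nrow(params$W2)
  dm <- nrow(params$W4)
  E <- matrix(0, k, dh)
  for (i in seq_len(k)) for (j in seq_len(dh)) E[i, j] <- params$H[ids[i], j]

  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    s <- 0
    for (a in seq_len(dh)) for (b in seq_len(dh)) {
      s <- s + E[i, a] * params$W1[a, b] * E[j, b]
    }
    S[i, j] <- s
  }
  beta <- matrix(0, k, k)
  for (i in seq_len(k)) {
    m <- max(S[i, ])
    ex <- exp(S[i, ] - m)
    beta[i, ] <- ex / sum(ex)
  }
  Hbar <- matrix(0, k, dh)
  for (i in seq_len(k)) for (j in seq_len(dh)) {
    s <- 0
    for (l in seq_len(k)) s <- s + beta[i, l] * E[l, j]
    Hbar[i, j] <- s
  }
  u <- numeric(k)
  for (i in seq_len(k)) {
    s <- 0
    for (a in seq_len(da)) {
      z <- 0
      for (j in seq_len(dh)) z <- z + params$W2[a, j] * Hbar[i, j]
      s <- s + params$W3[1, a] * tanh(z)
    }
    u[i] <- s
  }
  ex <- exp(u - max(u))
  alpha <- ex / sum(ex)
  M <- numeric(dh)
  for (j in seq_len(dh)) {
    s <- 0
    for (i in seq_len(k)) s <- s + alpha[i] * E[i, j]
    M[j] <- s
  }
  v <- numeric(dm)
  for (m in seq_len(dm)) {
    s <- 0
    for (j in seq_len(dh)) s <- s + params$W4[m, j] * M[j]
    v[m] <- s
  }
  z <- 0
  for (m in seq_len(dm)) z <- z + params$W5[1, m] * max(v[m], 0)
  p <- 1 / (1 + exp(-z))
  list(beta = beta, Hbar = Hbar, alpha = alpha, M = M, p = p)
}

# Independent brute-force oracle for frequent K-itemsets: enumerate every
# K-subset of the transaction universe and count containment directly.
oracle_k_itemsets <- function(transactions, K, min_sup) {
  tx <- lapply(transactions, function(t) unique(as.character(t)))
  universe <- sort(unique(unlist(tx)))
  min_sup_eff <- max(min_sup, 1)
  if (length(universe) < K) {
    return(data.frame(key = character(), support = integer()))
  }
  subs <- utils::combn(universe, K, simplify = FALSE)
  rows <- lapply(subs, function(s) {
    sup <- sum(vapply(tx, function(t) all(s %in% t), logical(1)))
    if (sup >= min_sup_eff) {
      data.frame(key = paste(s, collapse = "|"), support = sup,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(key = character(), support = integer())
  else out[order(out$key), , drop = FALSE]
}

itemsets_as_keys <- function(result) {
  df <- data.frame(
    key = vapply(result$itemsets$itemset,
                 function(s) paste(s, collapse = "|"), character(1)),
    support = result$itemsets$support, stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}

# Small random parameter set for forward/gradient tests.
random_params <- function(n_herbs, d_h, d_a, d_m, lambda = 0,
                          squared_l2 = FALSE) {
  hy <- hann_hyper(d_h = d_h, d_a = d_a, d_m = d_m, lambda = lambda,
                   squared_l2 = squared_l2)
  params <- list(H = matrix(rnorm(n_herbs * d_h, sd = 0.5), n_herbs, d_h),
                 W1 = matrix(rnorm(d_h * d_h, sd = 0.5), d_h, d_h),
                 W2 = matrix(rnorm(d_a * d_h, sd = 0.5), d_a, d_h),
                 W3 = matrix(rnorm(d_a, sd = 0.5), 1, d_a),
                 W4 = matrix(rnorm(d_m * d_h, sd = 0.5), d_m, d_h),
                 W5 = matrix(rnorm(d_m, sd = 0.5), 1, d_m),
                 hyper = hy)
  class(params) <- "hann_params"
  params
}

# Random transaction sets for miner property tests.
random_transactions <- function(n_items, n_tx, max_len) {
  items <- letters[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i) {
    sample(items, sample.int(max_len, 1))
  })
}

tiny_corpus <- function() {
  prescription_corpus(list(
    prescription("p1", c("a", "b", "c"), "eff1"),
    prescription("p2", c("a", "b"), "eff1"),
    prescription("p3", c("c", "d"), "eff2"),
    prescription("p4", c("d", "e"), character()),
    prescription("p5", c("b", "d", "e"), "eff2"),
    prescription("p6", c("a", "e"), character())
  ))
}
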