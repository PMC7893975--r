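test_that("embedding lookup extracts rows in prescription order and checks bounds", {
  set.seed(1)
  params <- random_params(6, 4, 5, 4)
  ids <- c(3L, 1L, 5L)
  E <- hann_embed(ids, params)
  expect_equal(E, params$H[ids, ])
  expect_equal(hann_embed(2L, params), params$H[2L, , drop = FALSE])
  perm <- c(2L, 3L, 1L)
  expect_equal(hann_embed(ids[perm], params), E[perm, ])
  expect_error(hann_embed(9L, params), "out of vocabulary")
})

test_that("attention layers reduce to closed forms in degenerate cases", {
  set.seed(2)
  params <- random_params(5, 4, 6, 3)
  E <- hann_embed(c(2L, 4L, 5L), params)

  # k = 1: softmax of a single logit
  a1 <- first_attention(E[1, , drop = FALSE], params$W1)
  expect_equal(a1$beta, matrix(1), tolerance = 1e-12)
  expect_equal(a1$Hbar, E[1, , drop = FALSE])
  a2 <- second_attention(E[1, , drop = FALSE], a1$Hbar, params$W2, params$W3)
  expect_equal(a2$alpha, 1)
  expect_equal(a2$M, as.vector(E[1, ]))

  # zero weights: uniform attention, column means
  z1 <- first_attention(E, matrix(0, 4, 4))
  expect_true(all(abs(z1$beta - 1 / 3) < 1e-12))
  expect_equal(z1$Hbar[1, ], colMeans(E))
  z2 <- second_attention(E, z1$Hbar, params$W2, matrix(0, 1, 6))
  expect_equal(z2$alpha, rep(1 / 3, 3))
  expect_equal(z2$M, colMeans(E))

  # zero W4 gives sigmoid(0) = 0.5; non-positive W5 caps p at 0.5
  expect_equal(output_probability(rnorm(4), matrix(0, 3, 4), params$W5), 0.5)
  expect_lte(output_probability(rnorm(4), matrix(rnorm(12), 3, 4),
                                matrix(-abs(rnorm(3)), 1, 3)), 0.5)
})

test_that("forward pass matches the straight-line oracle on random instances", {
  set.seed(3)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    dh <- sample(2:8, 1)
    params <- random_params(8, dh, sample(2:8, 1), sample(2:8, 1))
    ids <- sample.int(8, k)
    got <- hann_forward(ids, params)
    want <- oracle_forward(ids, params)
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$Hbar, want$Hbar, tolerance = 1e-10)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-10)
    expect_equal(got$M, want$M, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("loss reproduces closed-form values and validates labels", {
  params0 <- random_params(3, 2, 2, 2, lambda = 0)
  expect_equal(hann_loss(0.5, 1L, params0), log(2), tolerance = 1e-12)
  expect_lt(hann_loss(1 - 1e-12, 1L, params0), 1e-10)

  # lambda = 1, single non-zero weight of 3: L = ln 2 + 3
  params1 <- random_params(3, 2, 2, 2, lambda = 1)
  for (b in c("H", "W1", "W2", "W3", "W4", "W5")) params1[[b]][] <- 0
  params1$W4[1, 1] <- 3
  expect_equal(hann_loss(0.5, 1L, params1), log(2) + 3, tolerance = 1e-12)
  # squared form: L = ln 2 + lambda * 9
  params1$hyper$squared_l2 <- TRUE
  expect_equal(hann_loss(0.5, 1L, params1), log(2) + 9, tolerance = 1e-12)

  expect_error(hann_loss(0.5, 2, params0), "0 or 1")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(4)
  for (case in 1:3) {
    params <- random_params(6, 4, 5, 4,
                            lambda = c(0, 0.01, 0.01)[case],
                            squared_l2 = case == 3)
    ids <- sample.int(6, 3)
    y <- sample(0:1, 1)
    g <- hann_gradients(ids, y, params)
    eps <- 1e-5
    for (b in c("H", "W1", "W2", "W3", "W4", "W5")) {
      n_entries <- length(params[[b]])
      probe <- if (n_entries > 30) sample.int(n_entries, 30) else seq_len(n_entries)
      for (i in probe) {
        up <- params; up[[b]][i] <- up[[b]][i] + eps
        dn <- params; dn[[b]][i] <- dn[[b]][i] - eps
        fd <- (hann_loss(hann_forward(ids, up)$p, y, up) -
                 hann_loss(hann_forward(ids, dn)$p, y, dn)) / (2 * eps)
        bp <- g$grads[[b]][i]
        rel <- abs(fd - bp) / max(1e-8, abs(fd) + abs(bp))
        expect_lt(rel, 1e-4)
      }
    }
  }
})

test_that("attention is permutation-equivariant and the probability invariant", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    params <- random_params(10, 5, 6, 4)
    ids <- sample.int(10, k)
    perm <- sample.int(k)
    tr <- hann_forward(ids, params)
    tp <- hann_forward(ids[perm], params)
    expect_equal(tp$alpha, tr$alpha[perm], tolerance = 1e-12)
    expect_equal(tp$beta, tr$beta[perm, perm], tolerance = 1e-12)
    expect_equal(tp$p, tr$p, tolerance = 1e-12)
    expect_equal(sum(tr$alpha), 1, tolerance = 1e-6)
    expect_equal(unname(rowSums(tr$beta)), rep(1, k), tolerance = 1e-6)
    expect_true(all(tr$alpha >= 0) && all(tr$beta >= 0))
  }
})

test_that("training is seed-deterministic, inert at lr 0, and learns separable data", {
  st <- simulate_study(sim_config(seed = 31L, noise_rate = 0,
                                  n_pos_per_efficacy = 15L,
                                  n_neg_per_efficacy = 15L))
  ds <- build_balanced_dataset(st$corpus, "efficacy_1", seed = 2L)
  hy <- hann_hyper(d_h = 10L, d_a = 12L, d_m = 10L, epochs = 5L)

  f1 <- hann_train(ds, st$corpus$vocabulary, hyper = hy, seed = 11L)
  f2 <- hann_train(ds, st$corpus$vocabulary, hyper = hy, seed = 11L)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params$H, f2$params$H)

  hy0 <- hann_hyper(d_h = 10L, d_a = 12L, d_m = 10L, epochs = 3L, lr = 0)
  init <- hann_init(length(st$corpus$vocabulary$names), hy0, seed = 11L)
  f0 <- hann_train(ds, st$corpus$vocabulary, hyper = hy0, seed = 11L,
                   params_init = init)
  expect_identical(f0$params$H, init$H)
  expect_equal(diff(range(f0$loss_history)), 0, tolerance = 1e-12)

  expect_lt(f1$loss_history[5], f1$loss_history[1])
})

test_that("degenerate one-class training warns", {
  ds <- list(ids = list(c(1L, 2L), c(2L, 3L)), labels = c(1L, 1L))
  hy <- hann_hyper(d_h = 3L, d_a = 3L, d_m = 3L, epochs = 1L)
  expect_warning(hann_train(ds, hyper = hy, seed = 1L), "one class")
})

test_that("attention weights sum to one and follow herb reordering", {
  set.seed(6)
  params <- random_params(8, 4, 5, 4)
  v <- herb_vocabulary(letters[1:8])
  p <- prescription("x", c("c", "f", "a", "h"))
  w <- attention_weights(p, params, v)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_named(w, p$herbs)
  p2 <- prescription("x2", rev(p$herbs))
  expect_equal(unname(attention_weights(p2, params, v)), unname(rev(w)),
               tolerance = 1e-12)
  expect_equal(unname(attention_weights(prescription("s", p$herbs[1]),
                                        params, v)), 1)
})
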