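test_that("the loss equals the elementwise summation oracle", {
  d <- random_dataset(5, 2, density = 0.4, seed = 3)
  model <- random_model(5, 2, 3, seed = 10)
  for (pen in c(0, 0.7)) {
    expect_equal(rescal_loss(d, model, penalty = pen),
                 oracle_rescal_loss(d$adjacency, model$E, model$M, pen),
                 tolerance = 1e-10)
  }
})

test_that("the zero model's loss is the tensor's nonzero count", {
  d <- random_dataset(6, 3, density = 0.3, seed = 2)
  zero <- list(E = matrix(0, 6, 2),
               M = replicate(3, matrix(0, 2, 2), simplify = FALSE))
  expect_equal(rescal_loss(d, zero, penalty = 0),
               sum(vapply(d$adjacency, sum, numeric(1))))
})

test_that("a realizable tensor has zero loss and zero gradient at the truth", {
  rz <- realizable_dataset(n = 8, m = 2, d_true = 3, seed = 6)
  truth <- list(E = rz$E0, M = rz$M0)
  expect_equal(rescal_loss(rz$dataset, truth, penalty = 0), 0, tolerance = 1e-18)
  g <- rescal_gradients(rz$dataset, truth, penalty = 0)
  expect_lt(max(abs(g$grad_E)), 1e-10)
  expect_lt(max(abs(unlist(g$grad_M))), 1e-10)
})

test_that("analytic gradients match central finite differences", {
  fd_check <- function(d, model, pen, h = 1e-6) {
    g <- rescal_gradients(d, model, pen)
    num_g <- function(get, set) {
      x <- get(model)
      vapply(seq_along(x), function(q) {
        mp <- model; mm <- model
        xp <- x; xm <- x
        xp[q] <- xp[q] + h; xm[q] <- xm[q] - h
        mp <- set(mp, xp); mm <- set(mm, xm)
        (rescal_loss(d, mp, pen) - rescal_loss(d, mm, pen)) / (2 * h)
      }, numeric(1))
    }
    gE_num <- num_g(function(m) m$E, function(m, x) { m$E[] <- x; m })
    expect_equal(as.vector(g$grad_E), gE_num,
                 tolerance = 1e-5)
    for (k in seq_along(model$M)) {
      gM_num <- num_g(function(m) m$M[[k]],
                      function(m, x) { m$M[[k]][] <- x; m })
      expect_equal(as.vector(g$grad_M[[k]]), gM_num, tolerance = 1e-5)
    }
  }
  d <- random_dataset(5, 2, density = 0.4, seed = 11)
  fd_check(d, random_model(5, 2, 3, seed = 12), pen = 0.05)
  d2 <- random_dataset(7, 1, density = 0.3, seed = 13)
  fd_check(d2, random_model(7, 1, 2, seed = 14), pen = 0)
})

test_that("with a zero tensor only the penalty term drives grad_E", {
  n <- 6; m <- 2; dd <- 3
  d <- random_dataset(n, m, density = 0.3, seed = 4)
  for (k in seq_len(m)) d$adjacency[[k]][] <- 0
  model <- random_model(n, m, dd, seed = 5)
  pen <- 0.4
  g <- rescal_gradients(d, model, pen)
  g0 <- rescal_gradients(d, model, 0)
  expect_equal(unname(g$grad_E - g0$grad_E), 2 * pen * model$E,
               tolerance = 1e-12)
  for (k in seq_len(m)) {
    expect_equal(unname(g$grad_M[[k]] - g0$grad_M[[k]]), 2 * pen * model$M[[k]],
                 tolerance = 1e-12)
  }
})

test_that("the descent engine stops after `patience` worse-than-best losses", {
  # stubbed loss sequence: state is just an index into a fixed trace
  run_stub <- function(losses, patience, consecutive = FALSE) {
    ddicold:::descend(
      state = 1L,
      step_fn = function(s) s + 1L,
      loss_fn = function(s) losses[s],
      max_iter = length(losses) - 1L,
      patience = patience, consecutive = consecutive)
  }
  # monotone increasing after the start: stops exactly 3 iterations past best
  res <- run_stub(c(5, 6, 7, 8, 9, 10, 11), patience = 3)
  expect_equal(res$stopped_at, 3L)
  expect_equal(res$best_iter, 0L)
  expect_identical(res$state, 1L)  # best-loss iterate, not the last
  expect_equal(res$loss_trace, c(5, 6, 7, 8))

  # cumulative counting: worse iterations need not be consecutive
  res2 <- run_stub(c(5, 6, 4, 7, 3, 8, 2, 9), patience = 3)
  expect_equal(res2$stopped_at, 5L)  # worse at iterations 1, 3, 5
  expect_equal(res2$best_iter, 4L)
  expect_identical(res2$state, 5L)

  # consecutive variant resets the counter on every improvement
  res3 <- run_stub(c(5, 6, 7, 4, 8, 9, 10, 11), patience = 3, consecutive = TRUE)
  expect_equal(res3$stopped_at, 6L)
  expect_equal(res3$best_iter, 3L)

  # equal-to-best losses neither improve nor count as worse
  res4 <- run_stub(c(5, 5, 5, 5), patience = 1)
  expect_equal(res4$stopped_at, 3L)
  expect_equal(res4$best_iter, 0L)
})

test_that("training a noiseless realizable instance drives the loss near zero", {
  rz <- realizable_dataset(n = 12, m = 2, d_true = 3, seed = 21)
  cfg <- rescal_config(dim = 3, learning_rate = 0.01, penalty = 0,
                       max_iter = 800, seed = 1)
  fit <- fit_rescal(rz$dataset, cfg)
  expect_lt(min(fit$loss_trace), 0.01 * fit$loss_trace[1])
  expect_true(all(is.finite(fit$loss_trace)))
  # the reported best is the running minimum of the trace
  expect_equal(min(fit$loss_trace), fit$loss_trace[fit$best_iter + 1L])
})

test_that("training is deterministic given config and seed", {
  d <- random_dataset(10, 2, density = 0.3, seed = 8)
  cfg <- rescal_config(dim = 4, learning_rate = 0.005, penalty = 0.01,
                       max_iter = 60, seed = 99)
  f1 <- fit_rescal(d, cfg)
  f2 <- fit_rescal(d, cfg)
  expect_identical(f1$E, f2$E)
  expect_identical(f1$M, f2$M)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("a divergent learning rate raises a helpful error", {
  d <- random_dataset(10, 2, density = 0.3, seed = 8)
  # patience is raised so early stopping does not mask the blow-up
  cfg <- rescal_config(dim = 4, learning_rate = 10, max_iter = 200,
                       patience = 50, seed = 1)
  expect_error(fit_rescal(d, cfg), "smaller learning rate")
})

test_that("relabeling drugs permutes embedding rows and keeps the trace", {
  d <- random_dataset(9, 2, density = 0.3, seed = 15)
  perm <- c(3, 1, 2, 9, 5, 4, 8, 6, 7)
  dp <- d
  dp$drug_ids <- d$drug_ids[perm]
  dp$adjacency <- lapply(d$adjacency, function(A) A[perm, perm])
  init <- random_model(9, 2, 3, seed = 16)
  init_p <- list(E = init$E[perm, , drop = FALSE], M = init$M)
  cfg <- rescal_config(dim = 3, learning_rate = 0.005, max_iter = 40, seed = 1)
  f <- fit_rescal(d, cfg, init = init)
  fp <- fit_rescal(dp, cfg, init = init_p)
  expect_equal(f$loss_trace, fp$loss_trace, tolerance = 1e-12)
  expect_equal(unname(fp$E), unname(f$E[perm, , drop = FALSE]), tolerance = 1e-10)
})

test_that("svd embedding reconstructs exact low-rank symmetric matrices", {
  withr::local_seed(31)
  G <- matrix(rnorm(12), 6, 2)
  A <- G %*% t(G)  # symmetric PSD, rank 2
  d <- structure(list(drug_ids = sprintf("d%d", 1:6), type_ids = "T",
                      adjacency = list(T = A), attributes = NULL,
                      attribute_ids = NULL), class = "ddi_dataset")
  fit <- svd_embed(d, dim = 2)
  expect_lt(max(abs(fit$E %*% t(fit$E) - A)), 1e-8)

  # full dimension: reconstruction matches the eigendecomposition bound
  db <- random_dataset(7, 1, density = 0.4, seed = 32)
  full <- svd_embed(db, dim = 7)
  eg <- eigen(db$adjacency[[1]], symmetric = TRUE)
  best <- sum((db$adjacency[[1]] -
                 eg$vectors %*% diag(abs(eg$values)) %*% t(eg$vectors))^2)
  got <- sum((db$adjacency[[1]] - full$E %*% t(full$E))^2)
  expect_equal(got, best, tolerance = 1e-8)

  expect_error(svd_embed(db, dim = 0), "dim")
  expect_error(svd_embed(db, dim = 8), "dim")
  expect_error(svd_embed(random_dataset(5, 2, seed = 1), dim = 2), "single-type")
})

test_that("grid search returns the best-scoring configuration", {
  sim <- simulate_ddi(n = 40, p = 20, m = 2, d_true = 3, noise_sd = 0, seed = 41)
  split <- make_folds(40, 5, seed = 2)[[1]]

  # single-point grid: returned verbatim
  one <- grid_search_rescal(sim$dataset, split, dims = 6, rates = 0.005,
                            penalties = 0.01, max_iter = 100, seed = 1)
  expect_equal(one$learning_rate, 0.005)
  expect_equal(nrow(attr(one, "grid")), 1)

  # a known-good config against a divergent rate: divergent point excluded
  best <- grid_search_rescal(sim$dataset, split, dims = 6,
                             rates = c(0.005, 10), penalties = 0.01,
                             max_iter = 100, seed = 1)
  expect_equal(best$learning_rate, 0.005)
  grid <- attr(best, "grid")
  # the blown-up point either diverged outright or stalled at its
  # initialization; either way it scores clearly below the good point
  bad <- grid$s1_aupr[grid$learning_rate == 10]
  good <- grid$s1_aupr[grid$learning_rate == 0.005]
  expect_true(is.na(bad) || bad < good)
})
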