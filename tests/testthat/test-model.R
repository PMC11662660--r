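test_that("bin placement follows the half-open, clamped convention", {
  expect_equal(which(bin_events(0, B = 20L) == 1), 1L)
  expect_equal(which(bin_events(14, B = 20L) == 1), 20L)  # right-closed last
  expect_equal(which(bin_events(7, B = 20L) == 1), 11L)   # floor(7/0.7) = 10
  expect_equal(which(bin_events(-3, B = 20L) == 1), 1L)   # clamped
  expect_equal(which(bin_events(99, B = 20L) == 1), 20L)
  h <- bin_events(c(0.1, 0.1, 13.9), B = 20L)
  expect_equal(sum(h), 1)
  expect_error(bin_events(numeric(0)), "empty")
})

test_that("mean log intensity is the histogram expectation", {
  point <- c(1, rep(0, 19))
  expect_equal(mean_log_intensity(point), 0.35)
  expect_equal(mean_log_intensity(rep(1 / 20, 20)), 7)
  ends <- c(0.5, rep(0, 18), 0.5)
  expect_equal(mean_log_intensity(ends), 7)
})

test_that("closed-form ridge solves the regularized objective", {
  set.seed(31)
  # n = 1, lambda = 0: an exact interpolation exists
  cf1 <- ridge_closed_form(rdirichlet_rows(1, 4), rdirichlet_rows(1, 20), 0)
  expect_lt(cf1$fit_meta$final_loss, 1e-20)

  # lambda -> infinity: W -> 0 and b -> column mean of Y
  X <- rdirichlet_rows(16, 4); Y <- rdirichlet_rows(16, 20)
  cf_inf <- ridge_closed_form(X, Y, 1e12)
  expect_lt(max(abs(cf_inf$W)), 1e-9)
  expect_equal(cf_inf$b, colMeans(Y), tolerance = 1e-6)

  # random instance: an independent numerical minimizer cannot beat it,
  # and the gradient vanishes at the closed-form solution
  lam <- 0.05
  cf <- ridge_closed_form(X, Y, lam)
  obj <- function(theta) {
    W <- matrix(theta[1:80], 20, 4); b <- theta[81:100]
    sum((X %*% t(W) + rep(1, 16) %o% b - Y)^2) + lam * sum(W^2)
  }
  grad <- function(theta) {
    W <- matrix(theta[1:80], 20, 4); b <- theta[81:100]
    R <- X %*% t(W) + rep(1, 16) %o% b - Y
    c(as.vector(2 * (t(R) %*% X) + 2 * lam * W), 2 * colSums(R))
  }
  opt <- optim(rep(0, 100), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(cf$fit_meta$final_loss, opt$value + 1e-8)
  theta_cf <- c(as.vector(cf$W), cf$b)
  expect_lt(max(abs(grad(theta_cf))), 1e-8)
})

test_that("gradient descent reaches the closed-form optimum", {
  set.seed(32)
  for (i in 1:5) {
    X <- rdirichlet_rows(16, 4); Y <- rdirichlet_rows(16, 20)
    lam <- 10^runif(1, -2, 1)
    cf <- ridge_closed_form(X, Y, lam)
    gd <- fit_affine_gd(X, Y, lam, max_iters = 3e5, tol = 1e-15)
    expect_lt(max(abs(cf$W - gd$W)), 1e-5)
    expect_lt(max(abs(cf$b - gd$b)), 1e-5)
    expect_lt(gd$fit_meta$final_loss, cf$fit_meta$final_loss + 1e-8)
  }
  # zero initialization makes the fit fully deterministic
  X <- rdirichlet_rows(8, 4); Y <- rdirichlet_rows(8, 20)
  expect_identical(fit_affine_gd(X, Y, 0.1), fit_affine_gd(X, Y, 0.1))
  # divergence is reported, not silent
  expect_error(fit_affine_gd(X, Y, 0.1, lr = 10), "learning rate")
})

test_that("constant targets are fit by the offset alone", {
  set.seed(33)
  X <- rdirichlet_rows(10, 4)
  y0 <- as.numeric(rdirichlet_rows(1, 20))
  Y <- matrix(y0, 10, 20, byrow = TRUE)
  # with any lambda > 0 the unique optimum is W = 0, b = y0
  gd <- fit_affine_gd(X, Y, 0.1, max_iters = 3e5, tol = 1e-15)
  expect_lt(max(abs(gd$W)), 1e-5)
  expect_lt(max(abs(gd$b - y0)), 1e-5)
})

test_that("predicted histograms are clipped, renormalized distributions", {
  h <- as.numeric(rdirichlet_rows(1, 20))
  const <- sortscape:::new_affine_model(matrix(0, 20, 4), h, 0, "manual",
                                        list(final_loss = 0))
  x <- as.numeric(rdirichlet_rows(1, 4))
  expect_equal(predict_histogram(const, x), h)

  # single-benchmark interpolation at lambda = 0
  X1 <- rdirichlet_rows(1, 4); Y1 <- rdirichlet_rows(1, 20)
  cf <- ridge_closed_form(X1, Y1, 0)
  expect_equal(predict_histogram(cf, as.numeric(X1)), as.numeric(Y1),
               tolerance = 1e-9)

  # a negative raw entry is clipped and the vector re-sums to 1
  neg <- sortscape:::new_affine_model(matrix(0, 3, 2),
                                      c(-0.2, 0.6, 0.6), 0, "manual",
                                      list(final_loss = 0))
  p <- predict_histogram(neg, c(0.5, 0.5))
  expect_equal(p, c(0, 0.5, 0.5))

  degenerate <- sortscape:::new_affine_model(matrix(0, 3, 2),
                                             c(-1, -1, 1e-9), 0, "manual",
                                             list(final_loss = 0))
  expect_error(predict_histogram(degenerate, c(0.5, 0.5)), "degenerate")

  set.seed(34)
  model <- ridge_closed_form(rdirichlet_rows(16, 4), rdirichlet_rows(16, 20),
                             0.1)
  P <- predict_histogram(model, rdirichlet_rows(30, 4))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 30), tolerance = 1e-9)
})

test_that("LOO-CV matches a brute-force refit loop", {
  set.seed(35)
  X <- rdirichlet_rows(16, 4); Y <- rdirichlet_rows(16, 20)
  rownames(X) <- rownames(Y) <- paste0("v", 1:16)
  lam <- 0.1
  res <- loo_cv(X, Y, lambda_grid = lam)

  brute <- vapply(1:16, function(i) {
    A <- cbind(X[-i, ], 1)
    M <- crossprod(A) + lam * diag(c(1, 1, 1, 1, 0))
    theta <- solve(M, crossprod(A, Y[-i, ]))
    raw <- as.numeric(c(X[i, ], 1) %*% theta)
    raw[raw < 0] <- 0
    mean((raw / sum(raw) - Y[i, ])^2)
  }, numeric(1L))
  expect_lt(max(abs(res$table$mse - brute)), 1e-10)

  # duplicate benchmarks are predicted exactly at lambda = 0
  X2 <- rdirichlet_rows(1, 4)[c(1, 1), ]
  Y2 <- rdirichlet_rows(1, 20)[c(1, 1), ]
  res2 <- loo_cv(X2, Y2, lambda_grid = 0)
  expect_lt(max(res2$table$mse), 1e-20)

  # huge lambda cannot beat the variance baseline
  res_inf <- loo_cv(X, Y, lambda_grid = 1e10)
  baseline <- mean(vapply(1:16, function(i) {
    mean((colMeans(Y[-i, ]) - Y[i, ])^2)
  }, numeric(1L)))
  expect_gte(mean(res_inf$table$mse), baseline - 1e-6)
})

test_that("predict_all summarizes replicates into activity and confidence", {
  d <- design_library(toy_orf(5L, seed = 36L))
  set.seed(36)
  counts1 <- purrr::map_dfr(paste0("F", 1:4), function(f) {
    counts_template(d, replicate = 1L, fraction = f) |>
      dplyr::mutate(count = rpois(dplyr::n(), 50))
  })
  counts <- dplyr::bind_rows(
    counts1,
    dplyr::mutate(counts1, replicate = 2L),
    dplyr::mutate(counts1, replicate = 3L))
  fd <- fraction_distributions(aggregate_to_aa(counts))
  ids <- setdiff(unique(fd$variant_id), "WT")[1:6]
  Y <- rdirichlet_rows(6, 20)
  rownames(Y) <- ids

  est <- predict_all(fd, Y, lambda = 0.1, method = "closed_form")
  # identical replicates: zero confidence sd everywhere
  expect_true(all(abs(est$confidence_sd) < 1e-12))
  expect_equal(est$activity, est$mean_rep1, tolerance = 1e-12)
  expect_true(all(est$activity >= 0 & est$activity <= 14))

  # permuting variant rows leaves per-variant estimates unchanged
  fd_perm <- fd[sample(nrow(fd)), ]
  est_perm <- predict_all(fd_perm, Y, lambda = 0.1, method = "closed_form")
  est_perm <- est_perm[match(est$variant_id, est_perm$variant_id), ]
  expect_equal(est$activity, est_perm$activity, tolerance = 1e-12)

  # a missing benchmark is a hard error naming the variant
  rownames(Y)[1] <- "GHOST1X"
  expect_error(predict_all(fd, Y, lambda = 0.1), "GHOST1X")
})

test_that("tidy and glance expose the affine model coefficients", {
  set.seed(37)
  m <- ridge_closed_form(rdirichlet_rows(8, 4), rdirichlet_rows(8, 20), 0.2)
  td <- tidy(m)
  expect_identical(nrow(td), 20L * 5L)
  expect_setequal(unique(td$term), c(paste0("F", 1:4), "(offset)"))
  gl <- glance(m)
  expect_identical(gl$n_bins, 20L)
  expect_identical(gl$n_fractions, 4L)
  expect_true(gl$converged)
})
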