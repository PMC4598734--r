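test_that("the Gaussian component is parameterised by FWHM and area", {
  x <- seq(-10, 10, by = 0.001)
  y <- gaussian_fwhm(x, 0, 2, 5)
  # half maximum is reached at +-w/2
  expect_equal(gaussian_fwhm(1, 0, 2, 5), max(y) / 2, tolerance = 1e-9)
  # numeric integral equals the area parameter
  expect_equal(sum(y) * 0.001, 5, tolerance = 1e-6)
})

test_that("mobilogram construction validates its axis and intensities", {
  expect_error(mobilogram(1:5, rep(1, 5)), ">= 8")
  expect_error(mobilogram(c(1:7, 7), rep(1, 8)), "strictly increasing")
  expect_error(mobilogram(1:8, c(rep(1, 7), -1)), ">= 0")
  m <- mobilogram(1:8, rep(1, 8), channel = "test")
  expect_s3_class(m, "mobilogram")
})

test_that("noiseless Gaussians are recovered essentially exactly", {
  x <- seq(0, 12, by = 0.05)
  truth <- data.frame(x_c = 5.0, w = 1.2, A = 100)
  sim <- make_mobilogram(truth, k_im = 3, axis = x)
  fit <- fit_mobilogram(sim$mobilogram, 1)
  expect_true(fit$converged)
  expect_equal(fit$components$x_c, 5.0, tolerance = 1e-6)
  expect_equal(fit$components$w, 1.2, tolerance = 1e-6)
  expect_equal(fit$components$A, 100, tolerance = 1e-6)
  expect_equal(fit$k_im, 3, tolerance = 1e-6)
  # the stored fitted curve is the model evaluated at the data points
  expect_equal(fit$fitted,
               3 + gaussian_fwhm(x, fit$components$x_c, fit$components$w,
                                 fit$components$A),
               tolerance = 1e-9)
})

test_that("fitted optimum matches a dense grid-search oracle", {
  x <- seq(0, 10, by = 0.1)
  sim <- make_mobilogram(data.frame(x_c = 4.3, w = 1.5, A = 80), k_im = 1,
                         noise_sd = 0.5, axis = x, seed = 7)
  fit <- fit_mobilogram(sim$mobilogram, 1)
  oracle <- oracle_grid_fit_1g(x, sim$mobilogram$intensity,
                               xc_grid = seq(4.0, 4.6, by = 0.02),
                               w_grid = seq(1.2, 1.8, by = 0.02),
                               A_grid = seq(70, 90, by = 0.5),
                               k_grid = seq(0.5, 1.5, by = 0.1))
  expect_lte(fit$rss, oracle$rss + 1e-9)
  expect_equal(fit$components$x_c, oracle$par[["xc"]], tolerance = 0.02 / 4)
  expect_equal(fit$components$w, oracle$par[["w"]], tolerance = 0.04 / 1.5)
})

test_that("two overlapping components resolve with correct areas and centres", {
  x <- seq(0, 14, by = 0.04)
  truth <- data.frame(x_c = c(4, 6.5), w = c(1.0, 1.1), A = c(200, 100))
  h1 <- gaussian_fwhm(4, 4, 1, 200)
  set.seed(42)
  ratios <- dts <- numeric(25)
  for (i in 1:25) {
    sim <- make_mobilogram(truth, k_im = 2, noise_sd = 0.01 * h1, axis = x,
                           seed = 1000 + i)
    fit <- fit_mobilogram(sim$mobilogram, 2)
    expect_true(fit$converged)
    ratios[i] <- fit$components$A[1] / fit$components$A[2]
    dts[i] <- diff(fit$components$x_c)
  }
  expect_equal(mean(ratios), 2, tolerance = 0.025)
  expect_equal(mean(dts), 2.5, tolerance = 0.02)
})

test_that("scale equivariance: doubling intensities doubles areas and baseline only", {
  x <- seq(0, 12, by = 0.05)
  sim <- make_mobilogram(data.frame(x_c = c(4, 8), w = c(1, 1.2), A = c(50, 30)),
                         k_im = 2, noise_sd = 0.2, axis = x, seed = 3)
  f1 <- fit_mobilogram(sim$mobilogram, 2)
  m2 <- mobilogram(x, 2 * sim$mobilogram$intensity)
  f2 <- fit_mobilogram(m2, 2)
  expect_equal(f2$components$A, 2 * f1$components$A, tolerance = 1e-4)
  expect_equal(f2$k_im, 2 * f1$k_im, tolerance = 1e-3)
  expect_equal(f2$components$x_c, f1$components$x_c, tolerance = 1e-5)
  expect_equal(f2$components$w, f1$components$w, tolerance = 1e-5)
})

test_that("area conservation: components plus baseline reproduce the curve integral", {
  x <- seq(0, 20, by = 0.02)
  sim <- make_mobilogram(data.frame(x_c = c(6, 9, 13), w = c(1, 1.4, 1.1),
                                    A = c(120, 60, 20)),
                         k_im = 1.5, noise_sd = 0.3, axis = x, seed = 11)
  fit <- fit_mobilogram(sim$mobilogram, 3)
  span <- diff(range(x))
  model_int <- sum(fit$components$A) + fit$k_im * span
  curve_int <- sum(fit$fitted[-1] + fit$fitted[-length(x)]) / 2 * 0.02
  expect_equal(model_int, curve_int, tolerance = 2e-3)
})

test_that("data support and convergence contracts are honoured", {
  x <- seq(0, 5, by = 0.5)  # 11 points
  m <- mobilogram(x, gaussian_fwhm(x, 2.5, 1, 10))
  expect_error(fit_mobilogram(m, 2), "insufficient data support")
  # non-convergence is reported, never silent
  x2 <- seq(0, 12, by = 0.05)
  sim <- make_mobilogram(data.frame(x_c = c(5, 5.4), w = c(1, 1), A = c(50, 40)),
                         k_im = 0, noise_sd = 1, axis = x2, seed = 1)
  fit <- fit_mobilogram(sim$mobilogram, 2, max_iter = 1L)
  expect_false(fit$converged)
})

test_that("AICc selects the generating number of components at high SNR", {
  x <- seq(2, 30, by = 0.05)
  hits <- 0L
  cases <- expand.grid(rep = 1:5, n = 1:3)
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]
    comp <- data.frame(x_c = seq(8, 22, length.out = n), w = 1.0,
                       A = seq(100, 60, length.out = n))
    h <- max(gaussian_fwhm(comp$x_c[1], comp$x_c[1], 1, comp$A[1]))
    sim <- make_mobilogram(comp, k_im = 1, noise_sd = h / 50, axis = x,
                           seed = 300 + i)
    fit <- fit_mobilogram(sim$mobilogram)
    if (fit$n_components == n) hits <- hits + 1L
  }
  expect_gte(hits / nrow(cases), 0.9)
})

test_that("relative contributions normalise areas and match numeric integration", {
  x <- seq(0, 20, by = 0.01)
  sim <- make_mobilogram(data.frame(x_c = c(5, 10), w = c(1, 1.2), A = c(200, 100)),
                         axis = x)
  fit <- fit_mobilogram(sim$mobilogram, 2, labels = c("D", "M"))
  fr <- relative_contributions(fit)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(unname(fr["D"]), 2 / 3, tolerance = 1e-6)
  # trapezoid-integration oracle per component
  set.seed(8)
  A3 <- runif(3, 10, 200)
  sim3 <- make_mobilogram(data.frame(x_c = c(4, 9, 15), w = c(1, 1.3, 0.9), A = A3),
                          axis = x)
  fit3 <- fit_mobilogram(sim3$mobilogram, 3)
  fr3 <- relative_contributions(fit3)
  ints <- vapply(1:3, function(j) {
    yj <- gaussian_fwhm(x, fit3$components$x_c[j], fit3$components$w[j],
                        fit3$components$A[j])
    sum((yj[-1] + yj[-length(x)]) / 2) * 0.01
  }, 0)
  expect_equal(unname(fr3), ints / sum(ints), tolerance = 1e-6)
})

test_that("line-width comparison runs an unpaired two-tailed t-test", {
  x <- seq(0, 12, by = 0.05)
  mkfits <- function(ws, label) lapply(ws, function(w) {
    sim <- make_mobilogram(data.frame(x_c = 5, w = w, A = 100, label = label),
                           axis = x)
    fit_mobilogram(sim$mobilogram, 1, labels = label)
  })
  A <- mkfits(c(1.0, 1.1, 0.9), "D")
  B <- mkfits(c(2.0, 2.1, 1.9), "D")
  res <- peak_width_stats(A, B, "D")
  oracle <- oracle_t_test(res$widths_A, res$widths_B)
  expect_equal(res$t, oracle$t, tolerance = 1e-9)
  expect_equal(res$p, oracle$p, tolerance = 1e-9)
  expect_lt(res$p, 0.01)
  expect_lt(res$mean_A, res$mean_B)
  same <- peak_width_stats(A, A, "D")
  expect_equal(same$t, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_error(peak_width_stats(A, B, "Tr"), "group A")
})
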