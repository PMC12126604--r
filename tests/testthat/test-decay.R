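test_that("acquisition grid has the documented two-phase structure", {
  g <- mant_timegrid(5, 90, 10, 390)
  expect_length(g, 49)
  expect_identical(g[1], 0)
  expect_true(all(diff(g) > 0))
  expect_equal(sum(g == 90), 1)  # no duplicate at the phase junction
  expect_equal(mant_timegrid(1, 1, 1, 2), c(0, 1, 2))
  expect_error(mant_timegrid(5, 90, 10, 90), "invalid")
  expect_error(mant_timegrid(0, 90, 10, 390), "invalid")
  expect_error(mant_timegrid(5, 90, -1, 390), "invalid")
})

test_that("trace normalisation subtracts background and anchors frame 0 at 1", {
  times <- seq(0, 40, by = 5)
  n <- length(times)
  roi <- matrix(110, n, 3)
  tr <- normalise_trace(roi, rep(10, n), times)
  expect_equal(tr$normalised, rep(1, n))

  roi2 <- roi
  roi2[3, ] <- 60
  tr2 <- normalise_trace(roi2, rep(10, n), times)
  expect_equal(tr2$normalised[3], 0.5)  # (60 - 10) / (110 - 10)
  expect_equal(tr2$normalised[1], 1)

  expect_error(normalise_trace(matrix(10, n, 3), rep(10, n), times),
               "degenerate")
  expect_error(normalise_trace(roi, rep(10, n - 1), times), "shape")
  expect_error(normalise_trace(roi[, 1:2], rep(10, n), times), "shape")
})

test_that("normalisation is idempotent on an already-normalised trace", {
  times <- mant_timegrid()
  y <- decay_model(times, c(P1 = 0.4, T1 = 3, P2 = 0.5, T2 = 120))
  roi <- matrix(rep(y, 3), ncol = 3)
  tr <- normalise_trace(roi, rep(0, length(times)), times)
  expect_equal(tr$normalised, y)
})

test_that("noiseless double-exponential traces are recovered to solver precision", {
  set.seed(42)
  grid <- mant_timegrid()
  for (i in 1:15) {
    truth <- c(P1 = runif(1, 0.05, 0.95), T1 = runif(1, 0.5, 10),
               P2 = runif(1, 0.05, 0.95), T2 = runif(1, 20, 500))
    tr <- decay_trace(grid, decay_model(grid, truth))
    fit <- fit_decay(tr)
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) - truth[c("P1", "T1", "P2", "T2")])), 1e-6)
    expect_equal(fit$srx_pct, 100 * coef(fit)[["P2"]])
    expect_equal(fit$drx_pct + fit$srx_pct,
                 100 * sum(coef(fit)[c("P1", "P2")]))
  }
})

test_that("a noiseless single-exponential trace yields a near-zero second amplitude", {
  grid <- mant_timegrid()
  y <- 1 - 0.6 * (1 - exp(-grid / 3))
  fit <- fit_decay(decay_trace(grid, y))
  expect_lt(abs(coef(fit)[["P2"]]), 1e-3)
  expect_equal(coef(fit)[["P1"]], 0.6, tolerance = 1e-3)
})

test_that("component labelling is invariant to swapping the starting values", {
  grid <- mant_timegrid()
  truth <- c(P1 = 0.3, T1 = 4, P2 = 0.6, T2 = 180)
  tr <- decay_trace(grid, decay_model(grid, truth))
  f1 <- fit_decay(tr, init = c(P1 = 0.5, T1 = 2, P2 = 0.5, T2 = 150))
  f2 <- fit_decay(tr, init = c(P1 = 0.5, T1 = 150, P2 = 0.5, T2 = 2))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_lte(coef(f1)[["T1"]], coef(f1)[["T2"]])
})

test_that("fitting demands at least 8 frames and a valid trace", {
  short <- decay_trace(c(0, 5, 10, 15, 20, 25, 30),
                       rep(c(1, 0.9), length.out = 7))
  expect_error(fit_decay(short), "insufficient")
  expect_error(fit_decay(list(times = 1:10)), "decay_trace")
  tr <- decay_trace(mant_timegrid(),
                    decay_model(mant_timegrid(),
                                c(P1 = 0.5, T1 = 2, P2 = 0.5, T2 = 150)))
  expect_error(fit_decay(tr, init = c(P1 = 0.5, T1 = -1, P2 = 0.5, T2 = 150)),
               "bounds")
})

test_that("decay_fit methods are mutually consistent", {
  grid <- mant_timegrid()
  truth <- c(P1 = 0.45, T1 = 2.5, P2 = 0.5, T2 = 140)
  sim <- simulate_traces(data.frame(fibre_id = "x", P1 = truth[["P1"]],
                                    T1 = truth[["T1"]], P2 = truth[["P2"]],
                                    T2 = truth[["T2"]]),
                         grid = grid, sigma = 0.01, seed = 5)
  fit <- fit_decay(sim$traces$x)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit) + fitted(fit), sim$traces$x$normalised)
  expect_equal(sum(residuals(fit)^2), fit$rss)
  expect_equal(predict(fit, 0), 1)
  s <- summary(fit)
  expect_equal(s$sigma, sqrt(fit$rss / (length(grid) - 4)))
  resim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(resim, 2)
  expect_s3_class(resim[[1]], "decay_trace")
  expect_output(print(fit), "SRX")
})

test_that("SRX clustering uses inclusive low/high boundaries", {
  expect_identical(srx_class(35), "low")
  expect_identical(srx_class(65), "high")
  expect_identical(srx_class(50), "mid")
  expect_identical(srx_class(c(0, 35.0001, 64.9999, 100)),
                   c("low", "mid", "mid", "high"))
  # monotone step function
  grid <- seq(0, 100, by = 0.5)
  cl <- factor(srx_class(grid), levels = c("low", "mid", "high"))
  expect_true(all(diff(as.integer(cl)) >= 0))
  expect_error(srx_class(50, low_cut = 70, high_cut = 60), "invalid")
  expect_error(srx_class(NaN), "finite")
})

test_that("ANOVA with Tukey HSD matches its classical identities", {
  out <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(out$p, 1)

  # two groups: one-way ANOVA p equals the equal-variance t-test p (F = t^2)
  set.seed(7)
  x <- rnorm(8); y <- rnorm(9, mean = 0.5)
  out2 <- anova_tukey(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(out2$p, tt$p.value, tolerance = 1e-12)
  expect_equal(out2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(out2$pairwise_tukey$diff, mean(y) - mean(x), tolerance = 1e-12)

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "insufficient")
  expect_error(anova_tukey(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA rejection rate is calibrated under the null", {
  set.seed(11)
  reject <- replicate(400, {
    g <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
    anova_tukey(g)$p < 0.05
  })
  rate <- mean(reject)
  half <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("trace CSV round-trips through read_traces/write_traces", {
  dir <- withr::local_tempdir()
  sim <- simulate_traces(data.frame(fibre_id = c("a", "b"),
                                    P1 = c(0.5, 0.3), T1 = c(2, 3),
                                    P2 = c(0.4, 0.6), T2 = c(100, 200)),
                         sigma = 0.01, seed = 2)
  path <- file.path(dir, "traces.csv")
  write_traces(sim$traces, path)
  back <- read_traces(path)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$normalised, sim$traces$a$normalised, tolerance = 1e-9)
})
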