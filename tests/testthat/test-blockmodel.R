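test_that("training-design arithmetic matches the default workflow", {
  d <- training_design(grid_n = 40, reps = 10, block_size = 5)
  expect_equal(d$combinations, 64000)
  expect_equal(d$block_centers, 512)
  expect_equal(d$records_per_block, 1250)
  expect_error(training_design(grid_n = 41), "divisible")
})

test_that("a minimal training grid has the right shape and conserves counts", {
  co <- builtin_coarsening("D", 4, 4)
  cfg <- sample_config(4, 4, num_loci = 2)
  pf <- im_params(tau = 1, theta_1 = 4, rho = 2)
  tr <- build_training_grid(grid_n = 5, reps = 1, params_fixed = pf,
                            cfg = cfg, coarsening = co, seed = 3,
                            block_size = 5)
  expect_equal(nrow(tr$counts), 125)   # one block
  expect_equal(nrow(tr$table), 125)
  expect_true(all(diff(tr$axes$tau) > 0))
  # axis endpoints span the configured range
  expect_equal(range(tr$axes$M12), c(0.01, 10))
  # record sums equal the segregating-site totals of their datasets: the
  # record at row r was simulated with the stored parameters and seed
  seeds <- imsfs:::make_seeds(3, 125)
  for (r in c(1, 60, 125)) {
    p <- im_params(tau = tr$table$tau[r], M12 = tr$table$M12[r],
                   M21 = tr$table$M21[r], theta_1 = 4, rho = 2)
    S <- simulate_jsfs(p, cfg, seeds[r])
    expect_equal(sum(tr$counts[r, ]), sum(S))
  }
  expect_error(build_training_grid(grid_n = 7, reps = 1, params_fixed = pf,
                                   cfg = cfg, coarsening = co, seed = 3),
               "divisible")
})

test_that("Poisson regression recovers known coefficients from exact draws", {
  # counts generated exactly from log E[y] = b1 + b2*u1 + b3*u2 + b4*u3 on a
  # block-like design; fitted slopes should match within 3 SE ~ 95% of runs
  ax <- seq(-0.4, 0.4, length.out = 5)
  X <- as.matrix(expand.grid(u1 = ax, u2 = ax, u3 = ax))
  X <- X[rep(seq_len(nrow(X)), 10), ]  # 1250 records
  beta <- c(2, 0.8, -0.5, 0.3)
  eta <- cbind(1, X) %*% beta
  set.seed(88)
  hits <- 0
  nfit <- 200
  for (f in seq_len(nfit)) {
    y <- rpois(nrow(X), exp(eta))
    fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = poisson()))
    se <- sqrt(diag(chol2inv(fit$qr$qr[1:4, 1:4])))
    if (all(abs(fit$coefficients - beta) <= 3 * se)) hits <- hits + 1
  }
  expect_gte(hits / nfit, 0.95)
})

test_that("block fitting flags degenerate classes and predicts by hand", {
  co <- builtin_coarsening("D", 4, 4)
  cfg <- sample_config(4, 4, num_loci = 2)
  pf <- im_params(tau = 1, theta_1 = 1e-9, rho = 0)  # essentially no mutations
  tr <- build_training_grid(grid_n = 5, reps = 1, params_fixed = pf,
                            cfg = cfg, coarsening = co, seed = 5)
  m <- fit_block_models(tr, 5)
  expect_true(all(m$degenerate))
  expect_equal(unname(predict_expected(m, c(1, 1, 1))), rep(m$eps, 7))
  obs0 <- manual_summary(rep(0, 7), co)
  expect_error(im_estimate(obs0, m, "J1"), "degenerate")
  # hand-set coefficients reproduce d = exp(beta . covariates)
  m2 <- tiny_model()
  b <- 3
  lphi <- m2$centers_log[b, ] + c(0.1, -0.2, 0.05)
  d <- predict_expected(m2, exp(lphi))
  dd <- exp(m2$coef[, 1, b] + m2$coef[, 2, b] * 0.1 +
            m2$coef[, 3, b] * (-0.2) + m2$coef[, 4, b] * 0.05)
  dd[m2$degenerate[, b]] <- m2$eps
  expect_equal(unname(d), unname(pmax(dd, m2$eps)), tolerance = 1e-12)
})

test_that("boundary modes agree at block centers and between equal blocks", {
  m <- tiny_model()
  for (b in c(1, 4, 8)) {
    phi <- exp(m$centers_log[b, ])
    expect_equal(predict_expected(m, phi, "hard"),
                 predict_expected(m, phi, "mixture"), tolerance = 1e-12)
  }
  # two adjacent blocks encoding the same regression surface (coefficients
  # re-centred onto block 2's frame): mixture == hard at the boundary
  m3 <- m
  shift <- m3$centers_log[2, ] - m3$centers_log[1, ]
  m3$coef[, 1, 2] <- m3$coef[, 1, 1] + m3$coef[, 2:4, 1] %*% shift
  m3$coef[, 2:4, 2] <- m3$coef[, 2:4, 1]
  m3$degenerate[, 2] <- m3$degenerate[, 1]
  edge <- m3$edges_axis[[1]][2]  # boundary between tau-blocks 1 and 2
  phi <- exp(c(edge - 0.01, m3$centers_log[1, 2], m3$centers_log[1, 3]))
  expect_equal(predict_expected(m3, phi, "hard"),
               predict_expected(m3, phi, "mixture"), tolerance = 1e-10)
  # out-of-range parameters are refused
  expect_error(predict_expected(m, c(100, 1, 1)), "outside")
})

test_that("composite log-likelihood arithmetic", {
  # K = 2 hand computation
  F <- c(1, 2); d <- c(1.0, 2.0)
  expect_equal(composite_loglik(F, d),
               (1 * log(1) - 1 - lgamma(2)) + (2 * log(2) - 2 - lgamma(3)))
  # F = 0: -sum(d)
  expect_equal(composite_loglik(c(0, 0, 0), c(0.5, 1, 2)), -3.5)
  # F = d maximizes over d (Poisson MLE property)
  F <- c(3, 7, 1)
  best <- composite_loglik(F, F)
  set.seed(10)
  for (r in 1:50) {
    pert <- F * exp(rnorm(3, 0, 0.3))
    expect_lte(composite_loglik(F, pert), best)
  }
  expect_error(composite_loglik(c(1, 2), c(1, 2, 3)), "length")
  expect_error(composite_loglik(c(1, 2), c(1, 0)), "positive")
})

test_that("J1 equals a brute-force argmax over all block centers", {
  m <- tiny_model()
  co <- builtin_coarsening("Dcheck", 6, 6)
  cfg <- sample_config(6, 6, 3)
  for (s in 1:5) {
    obs <- simulate_summary(im_params(tau = 0.3 * s, M12 = 0.5, M21 = 2,
                                      theta_1 = 5, rho = 5), cfg, co, 100 + s)
    fit <- im_estimate(obs, m, "J1")
    # independent route: composite loglik via predict_expected at each center
    ll <- vapply(seq_len(m$nb^3), function(b)
      composite_loglik(as.numeric(obs),
                       predict_expected(m, exp(m$centers_log[b, ]))),
      numeric(1))
    expect_equal(unname(coef(fit)), unname(exp(m$centers_log[which.max(ll), ])),
                 tolerance = 1e-9)
    expect_equal(fit$loglik, max(ll), tolerance = 1e-9)
  }
})

test_that("J2 collapses to the dominant center and interpolates otherwise", {
  m <- tiny_model()
  co <- builtin_coarsening("Dcheck", 6, 6)
  cfg <- sample_config(6, 6, 3)
  obs <- simulate_summary(im_params(tau = 0.5, M12 = 1, M21 = 1,
                                    theta_1 = 5, rho = 5), cfg, co, 7)
  ll <- imsfs:::center_logliks(m, as.numeric(obs))
  b <- which.max(ll)
  fit <- im_estimate(obs, m, "J2")
  w <- exp(ll - max(ll)); w <- w / sum(w)
  expect_equal(unname(coef(fit)),
               unname(exp(as.vector(t(m$centers_log) %*% w))),
               tolerance = 1e-9)
  if (max(ll) - sort(ll, decreasing = TRUE)[2] > 50) {
    expect_equal(unname(coef(fit)), unname(exp(m$centers_log[b, ])),
                 tolerance = 1e-3)
  }
})

test_that("J3 never does worse than J1 on seeded datasets", {
  m <- tiny_model()
  co <- builtin_coarsening("Dcheck", 6, 6)
  cfg <- sample_config(6, 6, 3)
  seeds <- imsfs:::make_seeds(2024, 20)
  for (s in seeds) {
    obs <- simulate_summary(im_params(tau = 0.4, M12 = 2, M21 = 0.5,
                                      theta_1 = 5, rho = 5), cfg, co, s)
    f1 <- im_estimate(obs, m, "J1")
    f3 <- im_estimate(obs, m, "J3")
    expect_gte(f3$loglik, f1$loglik - 1e-6)
  }
})

test_that("J4 crosses blocks and reports a finite optimum", {
  m <- tiny_model()
  co <- builtin_coarsening("Dcheck", 6, 6)
  cfg <- sample_config(6, 6, 3)
  obs <- simulate_summary(im_params(tau = 0.4, M12 = 2, M21 = 0.5,
                                    theta_1 = 5, rho = 5), cfg, co, 31)
  f4 <- im_estimate(obs, m, "J4")
  expect_true(is.finite(f4$loglik))
  f3 <- im_estimate(obs, m, "J3")
  expect_gte(f4$loglik, f3$loglik - 0.5)  # same surface up to boundary blending
  lo <- c(m$ranges$tau[1], m$ranges$M12[1], m$ranges$M21[1])
  hi <- c(m$ranges$tau[2], m$ranges$M12[2], m$ranges$M21[2])
  expect_true(all(coef(f4) >= lo & coef(f4) <= hi))
})

test_that("estimation refuses a summary from a mismatching configuration", {
  m <- tiny_model()
  co10 <- builtin_coarsening("Dcheck", 10, 10)
  cfg10 <- sample_config(10, 10, 3)
  obs <- simulate_summary(im_params(tau = 1, theta_1 = 5, rho = 5),
                          cfg10, co10, 2)
  expect_error(im_estimate(obs, m, "J1"), "mismatch")
  coW <- builtin_coarsening("W", 6, 6)
  obsW <- simulate_summary(im_params(tau = 1, theta_1 = 5, rho = 5),
                           sample_config(6, 6, 3), coW, 2)
  expect_error(im_estimate(obsW, m, "J1"), "coarsening")
})

test_that("a reloaded model gives bit-identical predictions", {
  m <- tiny_model()
  tmp <- tempfile(fileext = ".rds")
  write_blockmodel(m, tmp)
  m2 <- read_blockmodel(tmp)
  for (phi in list(c(0.1, 0.5, 2), c(1, 1, 1), c(5, 0.02, 9))) {
    expect_identical(predict_expected(m2, phi), predict_expected(m, phi))
    expect_identical(predict_expected(m2, phi, "mixture"),
                     predict_expected(m, phi, "mixture"))
  }
  expect_error(suppressWarnings(read_blockmodel(tempfile())),
               "cannot open|supported")
})

test_that("confidence regions: threshold, membership, degenerate cases", {
  m <- tiny_model()
  co <- builtin_coarsening("Dcheck", 6, 6)
  cfg <- sample_config(6, 6, 3)
  obs <- simulate_summary(im_params(tau = 0.3, M12 = 1, M21 = 1,
                                    theta_1 = 5, rho = 5), cfg, co, 55)
  reg <- confidence_region(obs, m, df = 2, level = 0.95, n_eval = 25)
  expect_equal(reg$threshold, qchisq(0.95, 2) / 2, tolerance = 1e-12)
  # the region always contains the point(s) at the surface maximum
  best <- reg$grid[which.max(reg$grid$loglik), ]
  expect_true(reg$contains(best$tau, best$M))
  # df = 3 region contains the J1/J3 point estimates
  reg3 <- confidence_region(obs, m, df = 3, level = 0.95, n_eval = 8)
  f1 <- im_estimate(obs, m, "J1")
  f3 <- im_estimate(obs, m, "J3")
  expect_true(reg3$contains(coef(f1)[1], coef(f1)[2], coef(f1)[3]))
  expect_true(reg3$contains(coef(f3)[1], coef(f3)[2], coef(f3)[3]))
  # a flat surface puts the whole grid inside the region
  mflat <- m
  mflat$coef[, 2:4, ] <- 0
  mflat$coef[, 1, ] <- rep(m$coef[, 1, 1], m$nb^3)
  mflat$degenerate[] <- FALSE
  regf <- confidence_region(obs, mflat, df = 2, level = 0.95, n_eval = 10)
  expect_true(all(regf$maxll - regf$grid$loglik <= regf$threshold + 1e-9))
})
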