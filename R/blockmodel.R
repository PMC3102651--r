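# Composite-likelihood estimation: simulate summary statistics on a
# log-spaced (tau, M12, M21) grid, partition the grid into blocks, and fit,
# per block and per summary class, a log-linear Poisson regression of the
# expected class count on the log parameters.  The fitted surrogate then
# yields a Poisson composite likelihood for any observed summary vector,
# maximized by one of four strategies (J1-J4).

#' Arithmetic of a training design
#'
#' @param grid_n grid values per parameter axis.
#' @param reps coalescent simulations per grid point.
#' @param block_size grid points per block edge.
#' @return List with `combinations` (grid points), `records` (simulated
#'   summary vectors), `blocks`, `block_centers` and `records_per_block`.
#' @examples
#' training_design()  # the full-scale default: 64000 combinations
#' @export
training_design <- function(grid_n = 40, reps = 10, block_size = 5) {
  if (grid_n %% block_size != 0)
    stop("grid_n (", grid_n, ") is not divisible by the block size (",
         block_size, ")")
  nb <- grid_n %/% block_size
  list(combinations = grid_n^3, records = grid_n^3 * reps, blocks = nb^3,
       block_centers = nb^3, records_per_block = block_size^3 * reps)
}

log_axis <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

#' Simulate the training table for the composite-likelihood fit
#'
#' For every combination of `grid_n` log-spaced values of each of `tau`,
#' `M12`, `M21`, simulates `reps` independent datasets of `cfg$num_loci`
#' loci and stores their coarsened JSFS summary vectors.
#'
#' @param ranges named list `tau`, `M12`, `M21`, each `c(lo, hi)` with
#'   `lo > 0` (defaults 0.01..10 for all three).
#' @param grid_n grid values per axis (must be divisible by `block_size`).
#' @param reps simulated datasets per grid point.
#' @param params_fixed [im_params()] carrying `theta_*` and `rho` (its
#'   `tau`/`M12`/`M21` are ignored).
#' @param cfg [sample_config()] of the data that will be analysed: training
#'   and observed data must share `n1`, `n2`, `num_loci` and the nuisance
#'   parameters so that class counts are on the same scale.
#' @param coarsening an `im_coarsening` for `(cfg$n1, cfg$n2)`.
#' @param seed integer run seed (split into one stream per record).
#' @param block_size used only to validate `grid_n` up front.
#' @return An `im_training` object.
#' @export
build_training_grid <- function(ranges = list(tau = c(0.01, 10),
                                              M12 = c(0.01, 10),
                                              M21 = c(0.01, 10)),
                                grid_n, reps, params_fixed, cfg, coarsening,
                                seed, block_size = 5) {
  stopifnot(inherits(params_fixed, "im_params"),
            inherits(cfg, "im_sample_config"),
            inherits(coarsening, "im_coarsening"))
  if (grid_n %% block_size != 0)
    stop("grid_n (", grid_n, ") is not divisible by the block size (",
         block_size, ")")
  for (nm in c("tau", "M12", "M21")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] <= 0 || r[2] <= r[1])
      stop("range for '", nm, "' must be c(lo, hi) with 0 < lo < hi")
  }
  if (coarsening$n1 != cfg$n1 || coarsening$n2 != cfg$n2)
    stop("coarsening sample sizes do not match the configuration")
  axes <- lapply(ranges, function(r) log_axis(r[1], r[2], grid_n))
  nodes <- expand.grid(x = seq_len(grid_n), y = seq_len(grid_n),
                       z = seq_len(grid_n), KEEP.OUT.ATTRS = FALSE)
  nrec <- nrow(nodes) * reps
  seeds <- make_seeds(seed, nrec)
  idx <- attr(coarsening, "index")
  K <- length(coarsening$classes)
  class_cells <- lapply(seq_len(K), function(k) which(idx == k))
  counts <- matrix(0, nrec, K)
  tab <- data.frame(x = rep(nodes$x, each = reps),
                    y = rep(nodes$y, each = reps),
                    z = rep(nodes$z, each = reps),
                    rep = rep(seq_len(reps), nrow(nodes)))
  tab$tau <- axes$tau[tab$x]
  tab$M12 <- axes$M12[tab$y]
  tab$M21 <- axes$M21[tab$z]
  for (r in seq_len(nrec)) {
    S <- cpp_sim_jsfs(cfg$n1, cfg$n2, params_fixed$theta_1,
                      params_fixed$theta_2, params_fixed$theta_A,
                      tab$tau[r], tab$M12[r], tab$M21[r], params_fixed$rho,
                      cfg$num_loci, as.double(seeds[r]))
    counts[r, ] <- vapply(class_cells, function(ii) sum(S[ii]), numeric(1))
  }
  colnames(counts) <- labels(coarsening)
  structure(list(table = tab, counts = counts, axes = axes, ranges = ranges,
                 grid_n = grid_n, reps = reps, block_size = block_size,
                 fingerprint = model_fingerprint(params_fixed, cfg,
                                                 coarsening, ranges, grid_n,
                                                 reps, block_size, seed)),
            class = "im_training")
}

model_fingerprint <- function(params_fixed, cfg, coarsening, ranges, grid_n,
                              reps, block_size, seed) {
  list(n1 = cfg$n1, n2 = cfg$n2, num_loci = cfg$num_loci,
       theta_1 = params_fixed$theta_1, theta_2 = params_fixed$theta_2,
       theta_A = params_fixed$theta_A, rho = params_fixed$rho,
       coarsening = coarsening$name, ranges = ranges, grid_n = grid_n,
       reps = reps, block_size = block_size, seed = seed)
}

#' @export
print.im_training <- function(x, ...) {
  cat(sprintf("Training table: %d^3 grid x %d replicates = %d records (%d classes)\n",
              x$grid_n, x$reps, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

block_id <- function(a, b, c, nb) a + nb * (b - 1L + nb * (c - 1L))

#' Fit the per-block log-linear Poisson regressions
#'
#' Partitions the training grid into `(grid_n/block_size)^3` blocks of
#' `block_size` grid values per axis and fits, for each block and summary
#' class, a Poisson regression with log link of the simulated class count on
#' the centred log parameter values (intercept + three slopes), by
#' iteratively reweighted least squares.  Classes with all-zero counts in a
#' block are flagged degenerate and predicted at a small constant
#' expectation; non-converging fits fall back to the intercept-only model
#' and are flagged.
#'
#' @param training an `im_training` from [build_training_grid()].
#' @param block_size grid points per block edge (default 5, so the default
#'   40-point axes give 8 x 8 x 8 blocks fitted on 5^3 x reps records each).
#' @param eps expected count assigned to degenerate classes.
#' @return An `im_blockmodel`.
#' @seealso [im_train()] for the one-call wrapper, [predict_expected()],
#'   [im_estimate()].
#' @export
fit_block_models <- function(training, block_size = 5, eps = 1e-10) {
  stopifnot(inherits(training, "im_training"))
  grid_n <- training$grid_n
  if (grid_n %% block_size != 0)
    stop("grid_n (", grid_n, ") is not divisible by the block size (",
         block_size, ")")
  nb <- grid_n %/% block_size
  K <- ncol(training$counts)
  laxes <- lapply(training$axes, log)
  # per-axis block membership of each grid index and log centers/edges
  axblock <- ceiling(seq_len(grid_n) / block_size)
  centers_ax <- lapply(laxes, function(lv)
    vapply(seq_len(nb), function(m) mean(lv[axblock == m]), numeric(1)))
  edges_ax <- lapply(laxes, function(lv) {
    inner <- vapply(seq_len(nb - 1), function(m)
      (lv[m * block_size] + lv[m * block_size + 1]) / 2, numeric(1))
    c(lv[1], inner, lv[grid_n])
  })
  tab <- training$table
  rec_block <- block_id(axblock[tab$x], axblock[tab$y], axblock[tab$z], nb)
  nblocks <- nb^3
  coefs <- array(0, dim = c(K, 4, nblocks))
  degenerate <- matrix(FALSE, K, nblocks)
  nonconv <- matrix(FALSE, K, nblocks)
  centers_log <- matrix(0, nblocks, 3)
  for (c3 in seq_len(nb)) for (c2 in seq_len(nb)) for (c1 in seq_len(nb)) {
    b <- block_id(c1, c2, c3, nb)
    ctr <- c(centers_ax[[1]][c1], centers_ax[[2]][c2], centers_ax[[3]][c3])
    centers_log[b, ] <- ctr
    rows <- which(rec_block == b)
    X <- cbind(1, log(tab$tau[rows]) - ctr[1],
               log(tab$M12[rows]) - ctr[2],
               log(tab$M21[rows]) - ctr[3])
    for (k in seq_len(K)) {
      y <- training$counts[rows, k]
      if (all(y == 0)) {
        degenerate[k, b] <- TRUE
        coefs[k, , b] <- c(log(eps), 0, 0, 0)
        next
      }
      fit <- tryCatch(
        suppressWarnings(glm.fit(X, y, family = poisson())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
        nonconv[k, b] <- TRUE
        coefs[k, , b] <- c(log(mean(y)), 0, 0, 0)
      } else {
        coefs[k, , b] <- fit$coefficients
      }
    }
  }
  structure(list(coef = coefs, degenerate = degenerate, nonconverged = nonconv,
                 centers_log = centers_log, centers_axis = centers_ax,
                 edges_axis = edges_ax, axes = training$axes,
                 ranges = training$ranges, grid_n = grid_n,
                 block_size = block_size, nb = nb, K = K,
                 labels = colnames(training$counts), eps = eps,
                 log_step = (log(training$ranges$tau[2]) -
                             log(training$ranges$tau[1])) / (grid_n - 1),
                 fingerprint = training$fingerprint,
                 version = "imsfs-blockmodel-1"),
            class = "im_blockmodel")
}

#' Simulate a training grid and fit the block regressions in one call
#'
#' @inheritParams build_training_grid
#' @inheritParams fit_block_models
#' @return An `im_blockmodel`.
#' @export
im_train <- function(ranges = list(tau = c(0.01, 10), M12 = c(0.01, 10),
                                   M21 = c(0.01, 10)),
                     grid_n = 40, reps = 10, params_fixed, cfg, coarsening,
                     seed, block_size = 5, eps = 1e-10) {
  tr <- build_training_grid(ranges, grid_n, reps, params_fixed, cfg,
                            coarsening, seed, block_size)
  fit_block_models(tr, block_size, eps)
}

#' @export
print.im_blockmodel <- function(x, ...) {
  cat(sprintf("Block-wise Poisson surrogate: %d^3 grid, %d x %d x %d blocks, %d classes ('%s')\n",
              x$grid_n, x$nb, x$nb, x$nb, x$K, x$fingerprint$coarsening))
  cat(sprintf("  trained for n1 = %d, n2 = %d, %d loci, theta_1 = %g, rho = %g\n",
              x$fingerprint$n1, x$fingerprint$n2, x$fingerprint$num_loci,
              x$fingerprint$theta_1, x$fingerprint$rho))
  ndeg <- sum(x$degenerate)
  if (ndeg) cat(sprintf("  %d degenerate (all-zero) class fits\n", ndeg))
  invisible(x)
}

# parameter values of exactly 0 are pulled to 1e-3 * the axis lower bound
# before the log transform
replace_zero <- function(phi, ranges) {
  lo <- c(ranges$tau[1], ranges$M12[1], ranges$M21[1])
  ifelse(phi == 0, 1e-3 * lo, phi)
}

phi_block <- function(model, lphi) {
  c1 <- findInterval(lphi[1], model$edges_axis[[1]], all.inside = TRUE)
  c2 <- findInterval(lphi[2], model$edges_axis[[2]], all.inside = TRUE)
  c3 <- findInterval(lphi[3], model$edges_axis[[3]], all.inside = TRUE)
  c(c1, c2, c3)
}

predict_block <- function(model, b, lphi) {
  cov <- c(1, lphi - model$centers_log[b, ])
  d <- exp(as.vector(model$coef[, , b] %*% cov))
  d[model$degenerate[, b]] <- model$eps
  pmax(d, model$eps)
}

#' Expected summary vector under the fitted block model
#'
#' @param model an `im_blockmodel`.
#' @param phi numeric `c(tau, M12, M21)` within the trained ranges (zeros
#'   are replaced by `1e-3` times the axis lower bound).
#' @param boundary_mode `"hard"` uses the enclosing block's regression;
#'   `"mixture"` blends, within half a grid step of a block boundary, the
#'   predictions of the adjacent blocks with weights linear in log-parameter
#'   distance (the cross-block mode used by strategy J4).
#' @return Numeric vector of positive expected class counts.
#' @export
predict_expected <- function(model, phi, boundary_mode = c("hard", "mixture")) {
  stopifnot(inherits(model, "im_blockmodel"))
  boundary_mode <- match.arg(boundary_mode)
  phi <- replace_zero(as.numeric(phi), model$ranges)
  lo <- c(model$ranges$tau[1], model$ranges$M12[1], model$ranges$M21[1])
  hi <- c(model$ranges$tau[2], model$ranges$M12[2], model$ranges$M21[2])
  if (any(phi < lo * (1 - 1e-9)) || any(phi > hi * (1 + 1e-9)))
    stop("phi = (", paste(signif(phi, 4), collapse = ", "),
         ") is outside the trained parameter ranges")
  lphi <- log(phi)
  blk <- phi_block(model, lphi)
  if (boundary_mode == "hard")
    return(predict_block(model, block_id(blk[1], blk[2], blk[3], model$nb),
                         lphi))
  # mixture: per axis, a (block, weight) pair list; combined multiplicatively
  h <- model$log_step
  axw <- vector("list", 3)
  for (a in 1:3) {
    m <- blk[a]
    edges <- model$edges_axis[[a]]
    w <- list(c(m, 1))
    if (m > 1 && lphi[a] - edges[m] < h / 2) {
      wN <- 0.5 - (lphi[a] - edges[m]) / h
      w <- list(c(m, 1 - wN), c(m - 1, wN))
    } else if (m < model$nb && edges[m + 1] - lphi[a] < h / 2) {
      wN <- 0.5 - (edges[m + 1] - lphi[a]) / h
      w <- list(c(m, 1 - wN), c(m + 1, wN))
    }
    axw[[a]] <- w
  }
  d <- numeric(model$K)
  for (w1 in axw[[1]]) for (w2 in axw[[2]]) for (w3 in axw[[3]]) {
    wt <- w1[2] * w2[2] * w3[2]
    if (wt > 0)
      d <- d + wt * predict_block(model, block_id(w1[1], w2[1], w3[1],
                                                  model$nb), lphi)
  }
  d
}

#' @export
predict.im_blockmodel <- function(object, newdata,
                                  boundary_mode = c("hard", "mixture"), ...) {
  boundary_mode <- match.arg(boundary_mode)
  newdata <- as.matrix(newdata)
  t(apply(newdata, 1, function(p) predict_expected(object, p, boundary_mode)))
}

#' Poisson composite log-likelihood
#'
#' `sum_k F_k * log(d_k) - d_k - log Gamma(F_k + 1)` for observed class
#' counts `F` and expected counts `d`.
#'
#' @param observed numeric vector of observed class counts.
#' @param expected numeric vector of positive expected counts, same length.
#' @return The composite log-likelihood (a scalar).
#' @export
composite_loglik <- function(observed, expected) {
  F <- as.numeric(observed); d <- as.numeric(expected)
  if (length(F) != length(d))
    stop("observed and expected vectors have different lengths")
  if (any(d <= 0)) stop("expected counts must be positive")
  sum(ifelse(F > 0, F * log(d), 0) - d - lgamma(F + 1))
}

center_logliks <- function(model, F) {
  nb <- model$nb
  vapply(seq_len(nb^3), function(b) {
    d <- exp(model$coef[, 1, b])
    d[model$degenerate[, b]] <- model$eps
    composite_loglik(F, pmax(d, model$eps))
  }, numeric(1))
}

# bounded simplex optimization of the composite loglik on the log scale via
# a logistic reparametrization of the box [blo, bhi]
optimize_box <- function(F, blo, bhi, start_l, objective_d,
                         maxit = 500, reltol = 1e-6) {
  u0 <- qlogis(pmin(pmax((start_l - blo) / (bhi - blo), 1e-6), 1 - 1e-6))
  fn <- function(u) {
    lphi <- blo + (bhi - blo) * plogis(u)
    -composite_loglik(F, objective_d(lphi))
  }
  res <- tryCatch(optim(u0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol)),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  lphi <- blo + (bhi - blo) * plogis(res$par)
  list(lphi = lphi, loglik = -res$value, converged = res$convergence == 0)
}

#' Estimate IM parameters with the composite-likelihood strategies
#'
#' Given an observed summary vector and a fitted block model, locates the
#' parameter combination maximizing the Poisson composite likelihood:
#'
#' * `J1`: the best of the block centers.
#' * `J2`: the likelihood-weighted mean of the block centers (weights
#'   proportional to the center likelihoods, averaged on the log-parameter
#'   scale, reported on the natural scale).
#' * `J3`: a bounded within-block optimization started at every block
#'   center; the best result over all blocks.
#' * `J4`: optimizations started at every center that may cross block
#'   boundaries, using the mixture predictions of [predict_expected()] near
#'   boundaries.
#'
#' @param observed an `im_summary` produced with the same coarsening and
#'   sampling configuration as the training grid (checked against the model
#'   fingerprint).
#' @param model an `im_blockmodel`.
#' @param strategy one of `"J1"`, `"J2"`, `"J3"`, `"J4"`.
#' @return An `im_fit` with the estimates on the natural scale, the
#'   composite log-likelihood at the estimate, the strategy tag and
#'   diagnostics.
#' @export
im_estimate <- function(observed, model, strategy = c("J2", "J1", "J3", "J4")) {
  stopifnot(inherits(model, "im_blockmodel"))
  strategy <- match.arg(strategy)
  check_fingerprint(observed, model)
  F <- as.numeric(observed)
  if (length(F) != model$K)
    stop("observed summary has ", length(F), " classes; model expects ",
         model$K)
  if (all(model$degenerate))
    stop("degenerate model: every class in every block was flagged")
  ll <- center_logliks(model, F)
  nb <- model$nb
  ctr <- model$centers_log
  ord <- order(-ll, ctr[, 1], ctr[, 2], ctr[, 3])
  b1 <- ord[1]
  diagnostics <- list(block = b1, converged = TRUE)
  if (strategy == "J1") {
    est_l <- ctr[b1, ]
    best_ll <- ll[b1]
  } else if (strategy == "J2") {
    w <- exp(ll - max(ll))
    w <- w / sum(w)
    est_l <- as.vector(t(ctr) %*% w)
    best_ll <- composite_loglik(F, predict_expected(model, exp(est_l)))
  } else {
    best <- NULL
    conv <- logical(0)
    for (c3 in seq_len(nb)) for (c2 in seq_len(nb)) for (c1 in seq_len(nb)) {
      b <- block_id(c1, c2, c3, nb)
      if (strategy == "J3") {
        blo <- c(model$edges_axis[[1]][c1], model$edges_axis[[2]][c2],
                 model$edges_axis[[3]][c3])
        bhi <- c(model$edges_axis[[1]][c1 + 1], model$edges_axis[[2]][c2 + 1],
                 model$edges_axis[[3]][c3 + 1])
        obj <- function(lphi) predict_block(model, b, lphi)
      } else {
        blo <- log(c(model$ranges$tau[1], model$ranges$M12[1],
                     model$ranges$M21[1]))
        bhi <- log(c(model$ranges$tau[2], model$ranges$M12[2],
                     model$ranges$M21[2]))
        obj <- function(lphi) predict_expected(model, exp(lphi), "mixture")
      }
      res <- optimize_box(F, blo, bhi, ctr[b, ], obj)
      if (is.null(res)) next
      conv <- c(conv, res$converged)
      if (is.null(best) || res$loglik > best$loglik) {
        best <- res
        diagnostics$block <- b
      }
    }
    if (is.null(best)) stop("all within-block optimizations failed")
    est_l <- best$lphi
    best_ll <- best$loglik
    diagnostics$converged <- all(conv)
  }
  est <- exp(est_l)
  names(est) <- c("tau", "M12", "M21")
  new_im_fit(estimate = est, loglik = best_ll, strategy = strategy,
             diagnostics = diagnostics, observed = F,
             expected = predict_expected(model, est,
                                         if (strategy == "J4") "mixture"
                                         else "hard"),
             fingerprint = model$fingerprint)
}

check_fingerprint <- function(observed, model) {
  fp <- model$fingerprint
  mism <- character(0)
  co <- attr(observed, "coarsening")
  if (!is.null(co) && !identical(co, fp$coarsening))
    mism <- c(mism, sprintf("coarsening: data '%s' vs model '%s'", co,
                            fp$coarsening))
  for (nm in c("n1", "n2")) {
    v <- attr(observed, nm)
    if (!is.null(v) && v != fp[[nm]])
      mism <- c(mism, sprintf("%s: data %d vs model %d", nm, v, fp[[nm]]))
  }
  cfgat <- attr(observed, "config")
  if (!is.null(cfgat)) {
    for (nm in c("num_loci", "theta_1", "rho")) {
      if (!is.null(cfgat[[nm]]) && !isTRUE(all.equal(cfgat[[nm]], fp[[nm]])))
        mism <- c(mism, sprintf("%s: data %g vs model %g", nm,
                                cfgat[[nm]], fp[[nm]]))
    }
  }
  if (length(mism))
    stop("summary/model configuration mismatch:\n  ",
         paste(mism, collapse = "\n  "))
  invisible(TRUE)
}

#' Chi-square confidence region from the composite likelihood
#'
#' The region is the set of parameter combinations whose composite
#' log-likelihood is within `qchisq(level, df)/2` of the maximum (for
#' `df = 2` and `level = 0.95` the threshold is 2.99).  With `df = 2` the
#' parameter space is profiled to symmetric migration (`M12 = M21`), the
#' two free parameters being the divergence time and the common migration
#' rate; `df = 3` keeps all three parameters free.
#'
#' @param observed an `im_summary` matching the model.
#' @param model an `im_blockmodel`.
#' @param df 2 (symmetric migration profile) or 3.
#' @param level confidence level in (0, 1).
#' @param n_eval optional evaluation-grid resolution per axis (log-spaced
#'   over the trained ranges).  The default `NULL` evaluates on the block
#'   *centers* — the same lattice whose likelihood values drive strategies
#'   J1/J2, where the regression predictions have the smallest variance, so
#'   the reference maximum is not inflated by surrogate noise at
#'   off-center points.
#' @return An `im_region`: list with the threshold, the evaluation grid with
#'   its log-likelihoods, the grid maximum, and `contains(tau, M12,
#'   M21 = M12)`, a membership function.
#' @export
confidence_region <- function(observed, model, df = 2, level = 0.95,
                              n_eval = NULL) {
  stopifnot(inherits(model, "im_blockmodel"), df %in% c(2, 3),
            level > 0, level < 1)
  check_fingerprint(observed, model)
  F <- as.numeric(observed)
  threshold <- qchisq(level, df) / 2
  r <- model$ranges
  llphi <- function(phi) composite_loglik(F, predict_expected(model, phi))
  if (df == 2) {
    Mlo <- max(r$M12[1], r$M21[1]); Mhi <- min(r$M12[2], r$M21[2])
    if (is.null(n_eval)) {
      taus <- exp(model$centers_axis[[1]])
      Ms <- exp(model$centers_axis[[2]])
      Ms <- Ms[Ms >= Mlo & Ms <= Mhi]
    } else {
      taus <- log_axis(r$tau[1], r$tau[2], n_eval)
      Ms <- log_axis(Mlo, Mhi, n_eval)
    }
    grid <- expand.grid(tau = taus, M = Ms, KEEP.OUT.ATTRS = FALSE)
    grid$loglik <- vapply(seq_len(nrow(grid)), function(g)
      llphi(c(grid$tau[g], grid$M[g], grid$M[g])), numeric(1))
  } else {
    if (is.null(n_eval)) {
      taus <- exp(model$centers_axis[[1]])
      M12s <- exp(model$centers_axis[[2]])
      M21s <- exp(model$centers_axis[[3]])
    } else {
      taus <- log_axis(r$tau[1], r$tau[2], n_eval)
      M12s <- log_axis(r$M12[1], r$M12[2], n_eval)
      M21s <- log_axis(r$M21[1], r$M21[2], n_eval)
    }
    grid <- expand.grid(tau = taus, M12 = M12s, M21 = M21s,
                        KEEP.OUT.ATTRS = FALSE)
    grid$loglik <- vapply(seq_len(nrow(grid)), function(g)
      llphi(c(grid$tau[g], grid$M12[g], grid$M21[g])), numeric(1))
  }
  maxll <- max(grid$loglik)
  contains <- function(tau, M12, M21 = M12) {
    maxll - llphi(c(tau, M12, M21)) <= threshold + 1e-9
  }
  structure(list(df = df, level = level, threshold = threshold, grid = grid,
                 maxll = maxll, contains = contains),
            class = "im_region")
}

#' @export
print.im_region <- function(x, ...) {
  cat(sprintf("%.0f%% composite-likelihood confidence region (df = %d, threshold %.3f)\n",
              100 * x$level, x$df, x$threshold))
  inr <- x$maxll - x$grid$loglik <= x$threshold
  cat(sprintf("  %d of %d evaluation-grid points inside\n", sum(inr),
              nrow(x$grid)))
  invisible(x)
}
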