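# Power-analysis machinery: relative error, relative RMSE, Factor 2,
# scripted simulation designs and chi-square-region coverage.

#' Relative error of an estimate
#'
#' `(estimated - simulated) / simulated`; undefined (an error) when the
#' simulated value is zero.
#'
#' @param estimated,simulated numeric vectors (recycled pairwise).
#' @return Numeric vector of relative errors.
#' @examples
#' relative_error(0.2, 0.1)   #  1
#' relative_error(0.05, 0.1)  # -0.5
#' @export
relative_error <- function(estimated, simulated) {
  if (any(simulated == 0))
    stop("relative error is undefined for a simulated value of 0")
  (estimated - simulated) / simulated
}

#' Relative root-mean-square error
#'
#' Square root of the average squared relative error over datasets.
#'
#' @inheritParams relative_error
#' @return A scalar.
#' @examples
#' rmse_rel(c(2, 0.5), c(1, 1))  # sqrt(1.25/2)
#' @export
rmse_rel <- function(estimated, simulated) {
  if (length(estimated) == 0) stop("no estimates supplied")
  sqrt(mean(relative_error(estimated, simulated)^2))
}

#' Factor-2 proportion
#'
#' Fraction of estimates that are at least half and at most twice the
#' simulated value (boundaries inclusive).
#'
#' @inheritParams relative_error
#' @return A proportion in `[0, 1]`.
#' @examples
#' factor2(c(0.5, 2.1, 1), c(1, 1, 1))  # 2/3
#' @export
factor2 <- function(estimated, simulated) {
  if (length(estimated) == 0) stop("no estimates supplied")
  mean(estimated >= simulated / 2 & estimated <= 2 * simulated)
}

#' Randomized power-study design
#'
#' Draws independent parameter combinations: `tau`, `M12`, `M21` uniform on
#' a range (default `[0.01, 9]`, redrawing until `M12 != M21`), and the
#' common `theta` and per-locus `rho` uniform on `[5, 20]`.  Uniform on the
#' natural scale by default; `scale = "log"` switches to log-uniform draws.
#'
#' @param n_datasets number of parameter combinations.
#' @param seed integer seed.
#' @param tau_range,M_range,theta_range,rho_range numeric `c(lo, hi)`.
#' @param scale `"natural"` or `"log"`.
#' @return A list of design cells `list(params = im_params, n_datasets = 1)`.
#' @export
randomized_design <- function(n_datasets, seed,
                              tau_range = c(0.01, 9), M_range = c(0.01, 9),
                              theta_range = c(5, 20), rho_range = c(5, 20),
                              scale = c("natural", "log")) {
  scale <- match.arg(scale)
  draw <- function(u, r) {
    if (scale == "log") exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
    else r[1] + u * (r[2] - r[1])
  }
  seeds <- make_seeds(seed, 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seeds)
  lapply(seq_len(n_datasets), function(i) {
    tau <- draw(runif(1), tau_range)
    M12 <- draw(runif(1), M_range)
    M21 <- draw(runif(1), M_range)
    while (M12 == M21) M21 <- draw(runif(1), M_range)
    th <- draw(runif(1), theta_range)
    rho <- draw(runif(1), rho_range)
    list(params = im_params(tau = tau, M12 = M12, M21 = M21, theta_1 = th,
                            rho = rho),
         n_datasets = 1L)
  })
}

#' Fixed-divergence power-study design
#'
#' The factorial panel with a recent divergence time: `tau = 0.1`,
#' symmetric migration `M12 = M21` in `M_values`, `theta` in `theta_values`,
#' `rho` in `rho_values`, each cell replicated `n_per_cell` times.
#'
#' @param M_values,theta_values,rho_values factor levels.
#' @param tau the fixed divergence time.
#' @param n_per_cell datasets per cell.
#' @return A list of design cells `list(params, n_datasets)`.
#' @export
fixed_tau_design <- function(M_values = c(0.5, 2), theta_values = c(5, 10),
                             rho_values = c(5, 10, 20), tau = 0.1,
                             n_per_cell = 20) {
  cells <- expand.grid(M = M_values, theta = theta_values, rho = rho_values,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    list(params = im_params(tau = tau, M12 = cells$M[i], M21 = cells$M[i],
                            theta_1 = cells$theta[i], rho = cells$rho[i]),
         n_datasets = as.integer(n_per_cell)))
}

#' Run a simulation power study
#'
#' For each design cell, simulates `n_datasets` datasets at the cell's
#' parameters, applies every estimator, and tabulates the distribution of
#' relative errors, the relative RMSE and the Factor-2 proportion for each
#' of `tau`, `M12`, `M21`.  An estimator that errors on a dataset is
#' recorded as missing and excluded from the aggregates, with a count.
#'
#' Each estimator is a function `f(data)` returning `c(tau, M12, M21)`,
#' where `data` is a list with elements `jsfs` (the pooled [jsfs()]),
#' `params` (the true [im_params()] - for oracle estimators), `cfg` and
#' `seed`.
#'
#' @param design list of cells `list(params, n_datasets)`
#'   ([randomized_design()], [fixed_tau_design()]).
#' @param cfg a [sample_config()].
#' @param estimators named list of estimator functions.
#' @param seed integer seed.
#' @return An `im_power` object: `$estimates` (long data frame of all runs)
#'   and `$cells` (aggregated power table).
#' @export
run_power_study <- function(design, cfg, estimators, seed) {
  stopifnot(inherits(cfg, "im_sample_config"), length(estimators) > 0,
            !is.null(names(estimators)))
  rows <- list()
  total <- sum(vapply(design, function(cl) cl$n_datasets, integer(1)))
  seeds <- make_seeds(seed, total)
  s <- 0L
  for (ci in seq_along(design)) {
    cell <- design[[ci]]
    p <- cell$params
    for (d in seq_len(cell$n_datasets)) {
      s <- s + 1L
      sfs <- simulate_jsfs(p, cfg, seeds[s])
      data <- list(jsfs = sfs, params = p, cfg = cfg, seed = seeds[s])
      for (en in names(estimators)) {
        est <- tryCatch(estimators[[en]](data), error = function(e) {
          warning("estimator '", en, "' failed on cell ", ci, " dataset ", d,
                  ": ", conditionMessage(e), call. = FALSE)
          c(NA_real_, NA_real_, NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          cell = ci, dataset = d, estimator = en,
          tau_sim = p$tau, M12_sim = p$M12, M21_sim = p$M21,
          theta = p$theta_1, rho = p$rho,
          tau_est = est[[1]], M12_est = est[[2]], M21_est = est[[3]])
      }
    }
  }
  estimates <- do.call(rbind, rows)
  cells <- power_table(estimates)
  structure(list(estimates = estimates, cells = cells, design = design,
                 cfg = cfg, seed = seed),
            class = "im_power")
}

power_table <- function(estimates) {
  out <- list()
  for (en in unique(estimates$estimator)) {
    for (ci in unique(estimates$cell)) {
      sub <- estimates[estimates$estimator == en & estimates$cell == ci, ]
      for (par in c("tau", "M12", "M21")) {
        sim <- sub[[paste0(par, "_sim")]]
        est <- sub[[paste0(par, "_est")]]
        ok <- !is.na(est) & sim > 0
        re <- if (any(ok)) relative_error(est[ok], sim[ok]) else numeric(0)
        q <- if (length(re)) quantile(re, c(0, .25, .5, .75, 1), names = FALSE)
             else rep(NA_real_, 5)
        out[[length(out) + 1L]] <- data.frame(
          cell = ci, estimator = en, parameter = par,
          n = sum(ok), n_failed = sum(is.na(est)),
          mean_est = if (any(ok)) mean(est[ok]) else NA_real_,
          re_min = q[1], re_q25 = q[2], re_median = q[3], re_q75 = q[4],
          re_max = q[5],
          re_mean = if (length(re)) mean(re) else NA_real_,
          rmse = if (length(re)) sqrt(mean(re^2)) else NA_real_,
          factor2 = if (any(ok)) factor2(est[ok], sim[ok]) else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.im_power <- function(x, ...) {
  cat(sprintf("Power study: %d design cells, estimators: %s\n",
              length(x$design),
              paste(unique(x$cells$estimator), collapse = ", ")))
  print(x$cells, digits = 3)
  invisible(x)
}

#' Write a power report as TSV
#'
#' One row per design cell x estimator x parameter; the raw per-dataset
#' estimates can be written alongside for external re-analysis.
#'
#' @param power an `im_power`.
#' @param path output path for the aggregated table.
#' @param raw_path optional path for the raw estimates.
#' @return `path`, invisibly.
#' @export
write_power_tsv <- function(power, path, raw_path = NULL) {
  stopifnot(inherits(power, "im_power"))
  write.table(power$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(raw_path))
    write.table(power$estimates, raw_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read externally produced estimates
#'
#' Ingests a TSV of `(dataset, tau_est, M12_est, M21_est)` produced by some
#' other estimation program, for comparison in a power table without
#' running that program.
#'
#' @param path TSV path with columns `dataset`, `tau_est`, `M12_est`,
#'   `M21_est`.
#' @return A data frame.
#' @export
read_external_estimates <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  need <- c("dataset", "tau_est", "M12_est", "M21_est")
  if (!all(need %in% names(d)))
    stop("external estimates file must have columns: ",
         paste(need, collapse = ", "))
  d
}

#' Coverage of chi-square confidence regions
#'
#' Simulates `n_datasets` datasets at a truth with symmetric migration,
#' builds the composite-likelihood confidence region for each, and reports
#' the fraction of regions containing the true `(tau, M)`.
#'
#' @param truth an [im_params()] with `M12 == M21`.
#' @param n_datasets number of simulated datasets.
#' @param cfg a [sample_config()] matching the model fingerprint.
#' @param model an `im_blockmodel` trained at the truth's nuisance
#'   parameters, or a function `f(observed)` returning a membership
#'   function `g(tau, M12, M21 = M12)` (for other region methods).
#' @param seed integer seed.
#' @param df,level,n_eval passed to [confidence_region()] when `model` is a
#'   block model.
#' @return List with `coverage`, the per-dataset logical vector `inside`,
#'   and `n`.
#' @export
run_coverage_study <- function(truth, n_datasets, cfg, model, seed, df = 2,
                               level = 0.95, n_eval = NULL) {
  stopifnot(inherits(truth, "im_params"))
  if (truth$M12 != truth$M21)
    stop("the coverage design profiles symmetric migration: need M12 == M21")
  co <- NULL
  if (inherits(model, "im_blockmodel"))
    co <- builtin_coarsening(model$fingerprint$coarsening, cfg$n1, cfg$n2)
  seeds <- make_seeds(seed, n_datasets)
  inside <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    if (inherits(model, "im_blockmodel")) {
      obs <- simulate_summary(truth, cfg, co, seeds[d])
      reg <- confidence_region(obs, model, df = df, level = level,
                               n_eval = n_eval)
      inside[d] <- reg$contains(truth$tau, truth$M12)
    } else {
      sfs <- simulate_jsfs(truth, cfg, seeds[d])
      member <- model(sfs)
      inside[d] <- member(truth$tau, truth$M12)
    }
  }
  list(coverage = mean(inside), inside = inside, n = n_datasets)
}
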