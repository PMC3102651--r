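# The classed result of any of the package's estimators (composite J1-J4 or
# the genealogy-averaged ML route).

new_im_fit <- function(estimate, loglik, strategy, diagnostics = list(),
                       observed = NULL, expected = NULL, fingerprint = NULL) {
  names(estimate) <- c("tau", "M12", "M21")
  structure(list(estimate = estimate, loglik = loglik, strategy = strategy,
                 diagnostics = diagnostics, observed = observed,
                 expected = expected, fingerprint = fingerprint),
            class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf("IM parameter estimate (strategy %s)\n", x$strategy))
  print(signif(x$estimate, 4))
  cat(sprintf("log-likelihood at estimate: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.im_fit <- function(object, ...) object$estimate

#' @export
logLik.im_fit <- function(object, ...) {
  structure(object$loglik, df = 3, class = "logLik")
}

#' @export
summary.im_fit <- function(object, ...) {
  structure(object, class = c("summary.im_fit", "im_fit"))
}

#' @export
print.summary.im_fit <- function(x, ...) {
  print.im_fit(x)
  if (!is.null(x$observed) && !is.null(x$expected)) {
    cat("\nObserved vs expected class counts at the estimate:\n")
    tab <- data.frame(observed = x$observed,
                      expected = signif(x$expected, 4),
                      pearson = signif((x$observed - x$expected) /
                                         sqrt(x$expected), 3))
    print(tab)
  }
  if (isFALSE(x$diagnostics$converged))
    cat("\nwarning: at least one block optimization did not converge\n")
  invisible(x)
}

#' @export
residuals.im_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$observed) || is.null(object$expected))
    stop("this fit carries no observed/expected class counts")
  r <- object$observed - object$expected
  if (type == "pearson") r <- r / sqrt(object$expected)
  r
}

#' Simulate datasets at a fitted parameter combination
#'
#' Uses the sampling configuration and nuisance parameters recorded in the
#' fit's model fingerprint together with the estimated `(tau, M12, M21)`.
#'
#' @param object an `im_fit` from [im_estimate()].
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `im_dataset` objects.
#' @export
simulate.im_fit <- function(object, nsim = 1, seed = 1, ...) {
  fp <- object$fingerprint
  if (is.null(fp))
    stop("this fit carries no model fingerprint to simulate from")
  p <- im_params(tau = object$estimate[["tau"]],
                 M12 = object$estimate[["M12"]],
                 M21 = object$estimate[["M21"]],
                 theta_1 = fp$theta_1, theta_2 = fp$theta_2,
                 theta_A = fp$theta_A, rho = fp$rho)
  cfg <- sample_config(fp$n1, fp$n2, fp$num_loci)
  seeds <- make_seeds(seed, nsim)
  lapply(seeds, function(s) simulate_dataset(p, cfg, s))
}

#' Profile view of a likelihood surface
#'
#' Draws the log-likelihood of an [grid_loglik()] surface against one
#' parameter axis, maximizing over the others.
#'
#' @param x an `im_surface`.
#' @param parameter which axis to profile.
#' @param ... passed to [plot()].
#' @export
plot.im_surface <- function(x, parameter = c("tau", "M12", "M21"), ...) {
  parameter <- match.arg(parameter)
  d <- as.data.frame(x)
  prof <- tapply(d$loglik, d[[parameter]], max)
  plot(as.numeric(names(prof)), prof, log = "x", type = "b",
       xlab = parameter, ylab = "profile log-likelihood", ...)
  invisible(x)
}
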