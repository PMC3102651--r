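#' Per-class total branch lengths of a genealogy spectrum
#'
#' Sums the branch-length spectrum `L[i, j]` of one simulated genealogy over
#' the cells of each coarsening class.  Mutations landing in class `k` of
#' the summary vector are Poisson with mean `(theta_1/2)` times the class
#' length.
#'
#' @param spectrum an `(n1+1) x (n2+1)` branch-length matrix
#'   ([sample_genealogy_spectra()]).
#' @param coarsening an `im_coarsening` with matching dimensions.
#' @return Named numeric vector of per-class lengths (units of `2*N_1`
#'   generations).
#' @export
class_lengths <- function(spectrum, coarsening) {
  stopifnot(inherits(coarsening, "im_coarsening"))
  if (nrow(spectrum) != coarsening$n1 + 1 || ncol(spectrum) != coarsening$n2 + 1)
    stop("spectrum dimensions do not match the coarsening")
  idx <- attr(coarsening, "index")
  K <- length(coarsening$classes)
  out <- vapply(seq_len(K), function(k) sum(spectrum[which(idx == k)]),
                numeric(1))
  names(out) <- labels(coarsening)
  out
}

# class-length matrix (one row per spectrum) via a dense membership matrix
class_length_matrix <- function(spectra, coarsening) {
  idx <- attr(coarsening, "index")
  K <- length(coarsening$classes)
  ncell <- length(idx)
  M <- matrix(0, ncell, K)
  ok <- !is.na(idx)
  M[cbind(which(ok), idx[ok])] <- 1
  Lmat <- matrix(unlist(spectra, use.names = FALSE), nrow = length(spectra),
                 byrow = TRUE)
  CL <- Lmat %*% M
  colnames(CL) <- labels(coarsening)
  CL
}

#' Genealogy-averaged likelihood of one locus summary
#'
#' Approximates the likelihood of the observed class counts of one locus by
#' Monte-Carlo averaging over simulated genealogies: conditional on a
#' genealogy the class counts are independent Poisson with means
#' `(theta_1/2)` times the per-class branch lengths, and the locus
#' likelihood is the average over the supplied genealogy pool of the product
#' of the Poisson probabilities.
#'
#' @param observed an `im_summary` for one locus.
#' @param spectra list of branch-length spectra ([sample_genealogy_spectra()]).
#' @param theta_1 scaled mutation rate per locus.
#' @param coarsening the `im_coarsening` that produced `observed`.
#' @param log return the log-likelihood instead of the likelihood.
#' @return The (log-)likelihood; the natural-scale value lies in `[0, 1]`.
#' @export
locus_likelihood <- function(observed, spectra, theta_1, coarsening,
                             log = FALSE) {
  stopifnot(inherits(coarsening, "im_coarsening"))
  if (length(observed) != length(coarsening$classes))
    stop("observed summary length does not match the coarsening")
  if (length(spectra) < 1) stop("need at least one genealogy spectrum")
  CL <- class_length_matrix(spectra, coarsening)
  ll <- locus_loglik_pool(as.numeric(observed), CL, theta_1)
  if (log) ll else exp(ll)
}

# log of the genealogy-averaged likelihood for one locus given the pooled
# class-length matrix (spectra x classes); exact -Inf when every genealogy
# gives probability zero
locus_loglik_pool <- function(F, CL, theta_1) {
  lambda <- 0.5 * theta_1 * CL
  ll_m <- rowSums(dpois(matrix(F, nrow(CL), length(F), byrow = TRUE),
                        lambda, log = TRUE))
  logmeanexp(ll_m)
}

# all loci at once: ll[m, l] = sum_k F[l,k]*log(lambda[m,k]) - lambda[m,k]
# - lgamma(F[l,k]+1); log(0) is floored at -745 (exp underflows to 0) so that
# 0 * log(0) contributes 0 and positive counts on zero-length classes are
# crushed to numerical impossibility
loci_logliks_pool <- function(Fmat, CL, theta_1) {
  lambda <- 0.5 * theta_1 * CL
  lg <- log(lambda)
  zero <- lg < -745
  lg[zero] <- -745
  ll <- lg %*% t(Fmat) - rowSums(lambda)
  if (any(zero))  # positive count in a zero-length class: probability 0
    ll[(lambda == 0) %*% t(Fmat > 0) > 0] <- -Inf
  const <- rowSums(lgamma(Fmat + 1))
  vapply(seq_len(ncol(ll)), function(l) logmeanexp(ll[, l]),
         numeric(1)) - const
}

#' Log-likelihood surface of the IM parameters over a grid
#'
#' Evaluates the genealogy-averaged log-likelihood of a multi-locus dataset
#' (one summary vector per locus) at every node of a grid over
#' `(tau, M12, M21)`.  At each node a pool of `I` genealogies is simulated
#' once and shared across loci (loci are exchangeable: identical sample
#' sizes and nuisance parameters); the per-locus log-likelihoods are
#' accumulated in log space, so impossible configurations yield `-Inf`
#' rather than `NaN`.
#'
#' @param summaries list of per-locus `im_summary` vectors (same coarsening).
#' @param params_fixed an [im_params()] carrying the nuisance parameters
#'   (`theta_*`, `rho`); its `tau`, `M12`, `M21` are ignored.
#' @param grid list with numeric axes `tau`, `M12`, `M21` (values > 0).
#' @param I genealogies per grid node (default 10000; tests use far fewer).
#' @param coarsening the `im_coarsening` that produced the summaries.
#' @param seed integer seed (one sub-seed per grid node).
#' @return An `im_surface`: a data frame with columns `tau`, `M12`, `M21`,
#'   `loglik` and attributes `grid`, `coarsening`, `I`.
#' @export
grid_loglik <- function(summaries, params_fixed, grid, I = 10000, coarsening,
                        seed) {
  stopifnot(inherits(params_fixed, "im_params"),
            inherits(coarsening, "im_coarsening"))
  if (I < 1) stop("'I' must be >= 1")
  if (!all(c("tau", "M12", "M21") %in% names(grid)))
    stop("'grid' must have axes tau, M12, M21")
  Fmat <- do.call(rbind, lapply(summaries, as.numeric))
  if (ncol(Fmat) != length(coarsening$classes))
    stop("summary length does not match the coarsening")
  nodes <- expand.grid(tau = grid$tau, M12 = grid$M12, M21 = grid$M21,
                       KEEP.OUT.ATTRS = FALSE)
  cfg <- sample_config(coarsening$n1, coarsening$n2, num_loci = 1)
  seeds <- make_seeds(seed, nrow(nodes))
  ll <- numeric(nrow(nodes))
  for (g in seq_len(nrow(nodes))) {
    p <- im_params(tau = nodes$tau[g], M12 = nodes$M12[g], M21 = nodes$M21[g],
                   theta_1 = params_fixed$theta_1,
                   theta_2 = params_fixed$theta_2,
                   theta_A = params_fixed$theta_A, rho = params_fixed$rho)
    spectra <- sample_genealogy_spectra(p, cfg, I, seeds[g])
    CL <- class_length_matrix(spectra, coarsening)
    ll[g] <- sum(loci_logliks_pool(Fmat, CL, params_fixed$theta_1))
  }
  nodes$loglik <- ll
  structure(nodes, grid = grid, coarsening = coarsening$name, I = I,
            class = c("im_surface", "data.frame"))
}

#' Maximize a log-likelihood surface by local regression
#'
#' Fits a local polynomial smoother (tricube weights, `stats::loess`) to the
#' log-likelihood over log-parameter coordinates and returns the maximizer
#' of the smoothed surface on a 10x-per-axis refinement of the original
#' grid.  Ties are broken towards the smallest `(tau, M12, M21)` in
#' lexicographic order on the log scale.
#'
#' @param surface an `im_surface` from [grid_loglik()] with at least two
#'   distinct finite values.
#' @param smoother list with elements `span` (nearest-neighbour fraction,
#'   default 0.3) and `degree` (local polynomial degree, default 2).
#' @return An `im_fit` with the smoothed-maximum parameter estimates.
#' @export
maximize_surface <- function(surface, smoother = list(span = 0.3, degree = 2)) {
  stopifnot(inherits(surface, "im_surface"))
  span <- if (is.null(smoother$span)) 0.3 else smoother$span
  degree <- if (is.null(smoother$degree)) 2 else smoother$degree
  d <- as.data.frame(surface)[, c("tau", "M12", "M21", "loglik")]
  d <- d[is.finite(d$loglik), , drop = FALSE]
  if (nrow(d) < 2 || length(unique(d$loglik)) < 2)
    stop("flat surface: cannot locate a maximum")
  ld <- data.frame(ltau = log(d$tau), lM12 = log(d$M12), lM21 = log(d$M21),
                   loglik = d$loglik)
  # loess needs enough neighbours for a local quadratic in 3 covariates
  minspan <- min(1, 12 / nrow(ld))
  span <- max(span, minspan)
  fit <- suppressWarnings(
    loess(loglik ~ ltau + lM12 + lM21, data = ld, span = span,
          degree = degree, surface = "direct", normalize = FALSE))
  refine <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1) return(u)
    exp(seq(log(min(u)), log(max(u)), length.out = 10 * length(u)))
  }
  newgrid <- expand.grid(tau = refine(d$tau), M12 = refine(d$M12),
                         M21 = refine(d$M21), KEEP.OUT.ATTRS = FALSE)
  pred <- suppressWarnings(
    predict(fit, newdata = data.frame(ltau = log(newgrid$tau),
                                      lM12 = log(newgrid$M12),
                                      lM21 = log(newgrid$M21))))
  ord <- order(-pred, log(newgrid$tau), log(newgrid$M12), log(newgrid$M21))
  best <- ord[1]
  est_l <- log(c(newgrid$tau[best], newgrid$M12[best], newgrid$M21[best]))
  best_val <- pred[best]
  # polish continuously on the smoothed surface within the grid box
  lo <- log(c(min(d$tau), min(d$M12), min(d$M21)))
  hi <- log(c(max(d$tau), max(d$M12), max(d$M21)))
  pol <- tryCatch(
    suppressWarnings(
      optim(pmin(pmax(est_l, lo), hi),
            function(u) -predict(fit, newdata = data.frame(ltau = u[1],
                                                           lM12 = u[2],
                                                           lM21 = u[3])),
            method = "L-BFGS-B", lower = lo, upper = hi)),
    error = function(e) NULL)
  if (!is.null(pol) && -pol$value >= best_val) {
    est_l <- pol$par
    best_val <- -pol$value
  }
  est <- exp(est_l)
  names(est) <- c("tau", "M12", "M21")
  new_im_fit(estimate = est, loglik = best_val,
             strategy = paste0("ML-", attr(surface, "coarsening")),
             diagnostics = list(smoother = list(span = span, degree = degree),
                                grid_max = max(d$loglik),
                                polished = !is.null(pol)))
}

#' Genealogy-averaged maximum-likelihood estimation, end to end
#'
#' Convenience wrapper: summarizes each locus of a dataset with the chosen
#' coarsening, evaluates the likelihood surface over the grid and maximizes
#' it by local regression.
#'
#' @inheritParams grid_loglik
#' @param dataset an `im_dataset`.
#' @param smoother passed to [maximize_surface()].
#' @return An `im_fit`.
#' @export
im_mle <- function(dataset, params_fixed, grid, I = 10000, coarsening, seed,
                   smoother = list(span = 0.3, degree = 2)) {
  stopifnot(inherits(dataset, "im_dataset"))
  summaries <- lapply(seq_along(dataset$loci), function(k) {
    one <- structure(list(loci = dataset$loci[k]), class = "im_dataset")
    summarize_jsfs(jsfs_from_haplotypes(one, coarsening$n1, coarsening$n2),
                   coarsening)
  })
  surf <- grid_loglik(summaries, params_fixed, grid, I, coarsening, seed)
  maximize_surface(surf, smoother)
}

#' Export a likelihood surface as TSV
#'
#' @param surface an `im_surface`.
#' @param path output path; columns `tau`, `M12`, `M21`, `loglik`.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  stopifnot(inherits(surface, "im_surface"))
  write.table(as.data.frame(surface), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
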