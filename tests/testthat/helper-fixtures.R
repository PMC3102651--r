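# Shared fixtures: everything is generated in code at test time.

quick_params <- function(tau = 0.5, M12 = 1, M21 = 1, theta = 5, rho = 0)
  im_params(tau = tau, M12 = M12, M21 = M21, theta_1 = theta, rho = rho)

# a small random JSFS with the corner cells empty
random_jsfs <- function(n1, n2, lambda = 3) {
  m <- matrix(rpois((n1 + 1) * (n2 + 1), lambda), n1 + 1, n2 + 1)
  m[1, 1] <- 0L
  m[n1 + 1, n2 + 1] <- 0L
  jsfs(m, n1, n2)
}

# an im_summary with given counts for a coarsening (bypassing simulation)
manual_summary <- function(counts, coarsening) {
  structure(as.numeric(counts), names = labels(coarsening),
            coarsening = coarsening$name, n1 = coarsening$n1,
            n2 = coarsening$n2, class = "im_summary")
}

# independent naive Poisson-product likelihood (explicit formula, no dpois)
naive_locus_likelihood <- function(obs, spectra, theta_1, coarsening) {
  vals <- vapply(spectra, function(sp) {
    lam <- 0.5 * theta_1 * class_lengths(sp, coarsening)
    prod(exp(-lam) * lam^obs / factorial(obs))
  }, numeric(1))
  mean(vals)
}

# tiny trained block model shared across tests (built once per test run)
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- builtin_coarsening("Dcheck", 6, 6)
      cfg <- sample_config(6, 6, num_loci = 3)
      pf <- im_params(tau = 1, theta_1 = 5, rho = 5)
      cache <<- im_train(grid_n = 10, reps = 2, params_fixed = pf, cfg = cfg,
                         coarsening = co, seed = 99, block_size = 5)
    }
    cache
  }
})
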