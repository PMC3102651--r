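#' Parameters of the isolation-migration model
#'
#' Container for the scaled parameters of the neutral two-population
#' isolation-migration (IM) model.  An ancestral population of scaled
#' mutation rate `theta_A` splits `tau` time units ago (in units of `2*N_1`
#' generations) into two populations with rates `theta_1`, `theta_2` that
#' exchange migrants at scaled rates `M12` and `M21`.
#'
#' Scalings: `theta = 4*N*mu*L` per locus of length `L` bp, `rho = 4*N_1*c*L`
#' per locus, `M12 = 4*N_2*m_12` where `m_12` is the fraction of population 2
#' replaced each generation by migrants from population 1 (so `M12` is the
#' rate at which population 2 *receives* genes from population 1, forward in
#' time; backwards in time a lineage sampled in population 2 jumps into
#' population 1).  Symmetrically `M21 = 4*N_1*m_21`.
#'
#' @param tau divergence time in units of `2*N_1` generations (>= 0).
#' @param M12 scaled migration rate into population 2 from population 1.
#' @param M21 scaled migration rate into population 1 from population 2.
#' @param theta_1,theta_2,theta_A scaled mutation rates per locus for the two
#'   extant populations and the ancestral population.  `theta_1` must be
#'   positive; the others default to `theta_1`.
#' @param rho scaled intra-locus recombination rate per locus.
#'
#' @return An object of class `im_params`.
#' @examples
#' im_params(tau = 0.1, M12 = 0.5, M21 = 0.5, theta_1 = 5, rho = 10)
#' @export
im_params <- function(tau, M12 = 0, M21 = 0, theta_1, theta_2 = theta_1,
                      theta_A = theta_1, rho = 0) {
  p <- list(theta_A = theta_A, theta_1 = theta_1, theta_2 = theta_2,
            tau = tau, M12 = M12, M21 = M21, rho = rho)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", nm, "' must be a single non-missing number")
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")")
  }
  if (p$theta_1 <= 0) stop("parameter 'theta_1' must be positive")
  structure(p, class = "im_params")
}

#' @export
print.im_params <- function(x, ...) {
  cat("Isolation-migration model parameters\n")
  cat(sprintf("  divergence time tau = %g (2*N_1 generations)\n", x$tau))
  cat(sprintf("  migration M12 = %g, M21 = %g\n", x$M12, x$M21))
  cat(sprintf("  theta (A, 1, 2) = (%g, %g, %g) per locus\n",
              x$theta_A, x$theta_1, x$theta_2))
  cat(sprintf("  recombination rho = %g per locus\n", x$rho))
  invisible(x)
}

#' Sampling configuration
#'
#' Describes how the data were (or are to be) sampled: haploid sample sizes
#' in each population and the number and length of independently evolving
#' loci.
#'
#' @param n1,n2 haploid sample sizes in populations 1 and 2 (each >= 2,
#'   `n1 + n2 <= 64`).
#' @param num_loci number of independent loci (>= 0; zero gives empty
#'   datasets).
#' @param locus_length locus length in base pairs.  Only used to interpret
#'   per-base-pair rates; all scaled rates in [im_params()] are per locus.
#' @return An object of class `im_sample_config`.
#' @examples
#' sample_config(10, 10, num_loci = 7)
#' @export
sample_config <- function(n1, n2, num_loci = 7, locus_length = 1000) {
  for (nm in c("n1", "n2", "num_loci", "locus_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v))
      stop("'", nm, "' must be a single integer")
  }
  if (n1 < 2 || n2 < 2) stop("sample sizes n1 and n2 must each be >= 2")
  if (n1 + n2 > 64) stop("total sample size n1 + n2 must be at most 64")
  if (num_loci < 0) stop("'num_loci' must be >= 0")
  if (locus_length < 1) stop("'locus_length' must be >= 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 num_loci = as.integer(num_loci),
                 locus_length = as.integer(locus_length)),
            class = "im_sample_config")
}

#' @export
print.im_sample_config <- function(x, ...) {
  cat(sprintf("Sampling: n1 = %d, n2 = %d haploid sequences; %d locus/loci of %d bp\n",
              x$n1, x$n2, x$num_loci, x$locus_length))
  invisible(x)
}
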