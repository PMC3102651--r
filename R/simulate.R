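#' Simulate a multi-locus dataset under the isolation-migration model
#'
#' Draws `cfg$num_loci` independent loci from the IM coalescent with
#' intra-locus recombination and infinite-sites mutation, using the
#' package's built-in ancestral-recombination-graph simulator.  Each locus is
#' returned as a 0/1 haplotype matrix (rows = sampled sequences, the first
#' `n1` rows from population 1; 1 = derived allele) together with the
#' positions of its segregating sites on the unit interval.
#'
#' Columns fixed for the derived allele in the pooled sample never occur
#' (such sites are unobservable under the polarized infinite-sites
#' convention); columns where the derived allele is fixed in one population
#' and absent in the other (fixed differences) do occur.
#'
#' @param params an [im_params()] object.
#' @param cfg a [sample_config()] object.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `im_dataset`: a list with elements `loci` (a
#'   list of `list(positions, haplotypes)`), `n1`, `n2`, `params`, `cfg`,
#'   `seed`.
#' @seealso [jsfs_from_haplotypes()], [simulate_jsfs()], [write_ms()]
#' @examples
#' d <- simulate_dataset(im_params(tau = 0.5, theta_1 = 5), sample_config(4, 4, 2), seed = 1)
#' sapply(d$loci, function(l) ncol(l$haplotypes))
#' @export
simulate_dataset <- function(params, cfg, seed) {
  stopifnot(inherits(params, "im_params"), inherits(cfg, "im_sample_config"))
  raw <- cpp_sim_loci(cfg$n1, cfg$n2, params$theta_1, params$theta_2,
                      params$theta_A, params$tau, params$M12, params$M21,
                      params$rho, cfg$num_loci, as.double(seed),
                      want_haplotypes = TRUE, want_spectrum = FALSE)
  loci <- lapply(raw, function(l)
    list(positions = l$positions, haplotypes = l$haplotypes))
  structure(list(loci = loci, n1 = cfg$n1, n2 = cfg$n2, params = params,
                 cfg = cfg, seed = seed),
            class = "im_dataset")
}

#' @export
print.im_dataset <- function(x, ...) {
  S <- vapply(x$loci, function(l) ncol(l$haplotypes), integer(1))
  cat(sprintf("IM dataset: %d locus/loci, %s sequences, %d segregating sites\n",
              length(x$loci),
              if (is.null(x$n1)) "?" else paste0(x$n1, "+", x$n2),
              sum(S)))
  invisible(x)
}

#' Simulate a pooled joint site-frequency spectrum
#'
#' Fast path used by the composite-likelihood training step: simulates the
#' ancestral recombination graph of each locus, then draws the count of each
#' JSFS cell `(i, j)` directly as Poisson with mean `(theta_1/2) * L[i, j]`,
#' where `L[i, j]` is the span-weighted length of branches subtending `i`
#' population-1 and `j` population-2 tips.  The result is distributed
#' identically to tallying the haplotype matrices of [simulate_dataset()],
#' but skips all per-mutation bookkeeping.
#'
#' @inheritParams simulate_dataset
#' @return A [jsfs()] object pooled over all loci.
#' @examples
#' simulate_jsfs(im_params(tau = 1, theta_1 = 5), sample_config(4, 4, 3), seed = 7)
#' @export
simulate_jsfs <- function(params, cfg, seed) {
  stopifnot(inherits(params, "im_params"), inherits(cfg, "im_sample_config"))
  counts <- cpp_sim_jsfs(cfg$n1, cfg$n2, params$theta_1, params$theta_2,
                         params$theta_A, params$tau, params$M12, params$M21,
                         params$rho, cfg$num_loci, as.double(seed))
  jsfs(counts, cfg$n1, cfg$n2)
}

#' Simulate a summarized dataset
#'
#' Simulates one dataset, pools the JSFS over all loci and reduces it to the
#' class totals of a coarsening.
#'
#' @inheritParams simulate_dataset
#' @param coarsening an `im_coarsening` matching `cfg$n1`, `cfg$n2`.
#' @return An `im_summary` vector (class counts, in coarsening order).
#' @examples
#' co <- builtin_coarsening("W", 4, 4)
#' simulate_summary(im_params(tau = 1, theta_1 = 5), sample_config(4, 4, 3), co, seed = 7)
#' @export
simulate_summary <- function(params, cfg, coarsening, seed) {
  stopifnot(inherits(coarsening, "im_coarsening"))
  if (coarsening$n1 != cfg$n1 || coarsening$n2 != cfg$n2)
    stop("coarsening was built for (n1, n2) = (", coarsening$n1, ", ",
         coarsening$n2, ") but the sampling configuration has (",
         cfg$n1, ", ", cfg$n2, ")")
  s <- summarize_jsfs(simulate_jsfs(params, cfg, seed), coarsening)
  attr(s, "config") <- list(num_loci = cfg$num_loci,
                            theta_1 = params$theta_1, rho = params$rho)
  s
}

#' Sample genealogy branch-length spectra
#'
#' Simulates `count` independent ancestral recombination graphs of a single
#' locus and returns, for each, the matrix `L` with `L[i+1, j+1]` the total
#' branch length (span-weighted over the marginal trees of the locus)
#' subtending exactly `i` population-1 tips and `j` population-2 tips.
#' Lengths are in units of `2*N_1` generations, so the number of mutations
#' falling in JSFS cell `(i, j)` is Poisson with mean `(theta_1/2)*L[i, j]`.
#' Without recombination (`rho = 0`) the spectrum is the branch
#' classification of the single marginal tree with span weight 1.
#'
#' @inheritParams simulate_dataset
#' @param count number of independent genealogies (>= 1).
#' @return A list of `count` numeric `(n1+1) x (n2+1)` matrices.
#' @examples
#' sp <- sample_genealogy_spectra(im_params(tau = 1, theta_1 = 5),
#'                                sample_config(3, 3, 1), count = 2, seed = 1)
#' sum(sp[[1]])  # total span-weighted ARG length
#' @export
sample_genealogy_spectra <- function(params, cfg, count, seed) {
  stopifnot(inherits(params, "im_params"), inherits(cfg, "im_sample_config"))
  if (!is.numeric(count) || count < 1) stop("'count' must be >= 1")
  raw <- cpp_sim_loci(cfg$n1, cfg$n2, params$theta_1, params$theta_2,
                      params$theta_A, params$tau, params$M12, params$M21,
                      params$rho, as.integer(count), as.double(seed),
                      want_haplotypes = FALSE, want_spectrum = TRUE)
  lapply(raw, `[[`, "spectrum")
}
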