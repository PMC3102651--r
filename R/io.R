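# Interchange formats: Hudson's ms text dialect, the JSFS TSV, summary
# vectors and block-model files.

#' Parse ms-format coalescent output
#'
#' Reads the plain-text dialect of Hudson's ms: an optional command/seed
#' header, then one replicate per `//` delimiter with a `segsites:` line, an
#' optional `positions:` line, and one 0/1 row per sampled sequence.  Each
#' replicate becomes one locus; row order is preserved (the first `n1` rows
#' are population 1 by this package's convention).
#'
#' @param path file path, or `text` a character vector of lines.
#' @param text optional character vector (overrides `path`).
#' @return An `im_dataset` (without sampling metadata).
#' @export
parse_ms_output <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  starts <- grep("^//", lines)
  loci <- list()
  for (b in seq_along(starts)) {
    at <- starts[b] + 1L
    end <- if (b < length(starts)) starts[b + 1] - 1L else length(lines)
    if (at > end || !grepl("^segsites:", lines[at]))
      stop("line ", at, ": expected 'segsites:' after '//'")
    S <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", lines[at])))
    if (is.na(S) || S < 0) stop("line ", at, ": bad segsites count")
    at <- at + 1L
    positions <- numeric(0)
    if (S > 0) {
      if (at > end || !grepl("^positions:", lines[at]))
        stop("line ", at, ": expected 'positions:' line")
      positions <- as.numeric(strsplit(trimws(sub("^positions:\\s*",
                                                  "", lines[at])),
                                       "\\s+")[[1]])
      if (length(positions) != S)
        stop("line ", at, ": ", length(positions),
             " positions for ", S, " segregating sites")
      at <- at + 1L
    }
    rows <- lines[seq.int(at, end)]
    rows <- rows[nzchar(trimws(rows))]
    if (S == 0) {
      haps <- matrix(integer(0), nrow = max(length(rows), 0), ncol = 0)
    } else {
      if (length(rows) == 0) stop("line ", at, ": replicate has no haplotype rows")
      bad <- which(nchar(rows) != S | grepl("[^01]", rows))
      if (length(bad))
        stop("line ", at + bad[1] - 1L,
             ": haplotype row is not a 0/1 string of length ", S)
      haps <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    }
    loci[[b]] <- list(positions = positions, haplotypes = haps)
  }
  nrows <- unique(vapply(loci, function(l) nrow(l$haplotypes), integer(1)))
  nrows <- nrows[nrows > 0]
  if (length(nrows) > 1)
    stop("inconsistent number of haplotype rows across replicates: ",
         paste(nrows, collapse = ", "))
  structure(list(loci = loci, n1 = NULL, n2 = NULL), class = "im_dataset")
}

#' Write a dataset in ms format
#'
#' @param dataset an `im_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(dataset, path) {
  stopifnot(inherits(dataset, "im_dataset"))
  nsam <- if (length(dataset$loci))
    nrow(dataset$loci[[1]]$haplotypes) else 0L
  out <- c(sprintf("ms %d %d", nsam, length(dataset$loci)), "imsfs", "")
  for (l in dataset$loci) {
    S <- ncol(l$haplotypes)
    out <- c(out, "//", paste0("segsites: ", S))
    if (S > 0) {
      out <- c(out,
               paste0("positions: ",
                      paste(sprintf("%.5f", l$positions), collapse = " ")),
               apply(l$haplotypes, 1, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write the JSFS TSV format
#'
#' Two header lines `#n1=<int>` and `#n2=<int>` followed by `(n1+1)` rows of
#' `(n2+1)` tab-separated integer counts.
#'
#' @param path file path.
#' @return `read_jsfs`: a [jsfs()] object.
#' @export
read_jsfs <- function(path) {
  lines <- readLines(path)
  gethdr <- function(key) {
    hit <- grep(paste0("^#", key, "="), lines)
    if (length(hit) != 1)
      stop("JSFS file is missing the '#", key, "=' header")
    v <- suppressWarnings(as.integer(sub(paste0("^#", key, "="), "",
                                         lines[hit])))
    if (is.na(v)) stop("bad '#", key, "=' header")
    v
  }
  n1 <- gethdr("n1"); n2 <- gethdr("n2")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n1 + 1)
    stop("expected ", n1 + 1, " count rows, found ", length(body))
  counts <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (ncol(counts) != n2 + 1)
    stop("expected ", n2 + 1, " columns per row")
  if (any(is.na(counts) | counts < 0))
    stop("JSFS counts must be non-negative integers")
  jsfs(counts, n1, n2)
}

#' @rdname read_jsfs
#' @param x a [jsfs()] object.
#' @export
write_jsfs <- function(x, path) {
  stopifnot(inherits(x, "jsfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#n1=", attr(x, "n1")), paste0("#n2=", attr(x, "n2"))),
             con)
  write.table(unclass(x), con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write summary vectors as TSV
#'
#' Header lines carry the coarsening name, sample sizes and (optionally)
#' the dataset configuration used for fingerprint checks; the body has one
#' `label<TAB>count` row per class.
#'
#' @param path file path.
#' @return `read_summary_tsv`: an `im_summary`.
#' @export
read_summary_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- function(key, required = TRUE, num = TRUE) {
    hit <- grep(paste0("^#", key, "="), lines)
    if (length(hit) == 0) {
      if (required) stop("summary file is missing the '#", key, "=' header")
      return(NULL)
    }
    v <- sub(paste0("^#", key, "="), "", lines[hit[1]])
    if (num) as.numeric(v) else v
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t")
  counts <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(counts) <- vapply(parts, `[`, character(1), 1)
  s <- structure(counts, coarsening = hdr("coarsening", num = FALSE),
                 n1 = as.integer(hdr("n1")), n2 = as.integer(hdr("n2")),
                 class = "im_summary")
  cfgat <- list(num_loci = hdr("num_loci", required = FALSE),
                theta_1 = hdr("theta_1", required = FALSE),
                rho = hdr("rho", required = FALSE))
  if (!all(vapply(cfgat, is.null, logical(1))))
    attr(s, "config") <- cfgat
  s
}

#' @rdname read_summary_tsv
#' @param s an `im_summary`.
#' @export
write_summary_tsv <- function(s, path) {
  stopifnot(inherits(s, "im_summary"))
  out <- c(paste0("#coarsening=", attr(s, "coarsening")),
           paste0("#n1=", attr(s, "n1")), paste0("#n2=", attr(s, "n2")))
  cfgat <- attr(s, "config")
  for (nm in names(cfgat))
    if (!is.null(cfgat[[nm]]))
      out <- c(out, paste0("#", nm, "=", cfgat[[nm]]))
  out <- c(out, paste0(names(unclass(s)), "\t", as.numeric(s)))
  writeLines(out, path)
  invisible(path)
}

#' Save and restore a fitted block model
#'
#' Serialization uses R's versioned RDS format; the fingerprint (sample
#' sizes, locus count, nuisance parameters, coarsening, ranges, seed)
#' travels with the coefficients, and a reloaded model gives bit-identical
#' predictions.
#'
#' @param model an `im_blockmodel`.
#' @param path file path.
#' @return `path` / the restored model.
#' @export
write_blockmodel <- function(model, path) {
  stopifnot(inherits(model, "im_blockmodel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_blockmodel
#' @export
read_blockmodel <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "im_blockmodel") ||
      !identical(model$version, "imsfs-blockmodel-1"))
    stop("'", path, "' is not a supported block-model file")
  model
}

#' Write parameter estimates as TSV
#'
#' @param fits an `im_fit` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimates_tsv <- function(fits, path) {
  if (inherits(fits, "im_fit")) fits <- list(fits)
  rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(dataset = i, strategy = f$strategy,
               tau_est = f$estimate[["tau"]], M12_est = f$estimate[["M12"]],
               M21_est = f$estimate[["M21"]], loglik = f$loglik)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
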