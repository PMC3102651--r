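#' Joint site-frequency spectrum
#'
#' An `(n1+1) x (n2+1)` matrix of non-negative integer counts where entry
#' `[i+1, j+1]` is the number of polymorphic sites whose derived allele is
#' carried by `i` sequences in the population-1 sample and `j` sequences in
#' the population-2 sample.  Under the polarized infinite-sites convention
#' the corner cells `(0, 0)` and `(n1, n2)` are unobservable and must be
#' zero.
#'
#' @param counts integer matrix of dimensions `(n1+1) x (n2+1)`.
#' @param n1,n2 haploid sample sizes.
#' @return An object of class `jsfs` (an integer matrix with attributes
#'   `n1`, `n2`).
#' @examples
#' m <- matrix(0L, 4, 4); m[2, 3] <- 5L
#' jsfs(m, 3, 3)
#' @export
jsfs <- function(counts, n1, n2) {
  counts <- as.matrix(counts)
  if (nrow(counts) != n1 + 1 || ncol(counts) != n2 + 1)
    stop("'counts' must be a (n1+1) x (n2+1) matrix")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("JSFS counts must be non-negative integers")
  if (counts[1, 1] != 0 || counts[n1 + 1, n2 + 1] != 0)
    stop("JSFS cells (0,0) and (n1,n2) must be zero under polarized infinite sites")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(i = 0:n1, j = 0:n2)
  structure(counts, n1 = as.integer(n1), n2 = as.integer(n2),
            class = c("jsfs", "matrix", "array"))
}

#' @export
print.jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS (n1 = %d, n2 = %d), %d segregating sites\n",
              attr(x, "n1"), attr(x, "n2"), sum(x)))
  print(unclass(structure(x, n1 = NULL, n2 = NULL)))
  invisible(x)
}

#' Tally a haplotype dataset into a joint site-frequency spectrum
#'
#' Each segregating column with derived-allele count `i` among the first
#' `n1` rows and `j` among the remaining `n2` rows increments cell `(i, j)`;
#' columns mapping to the unobservable corners `(0, 0)` and `(n1, n2)` are
#' dropped.  Loci are pooled.
#'
#' @param dataset an `im_dataset` ([simulate_dataset()], [parse_ms_output()]).
#' @param n1,n2 haploid sample sizes (each locus matrix must have `n1 + n2`
#'   rows).
#' @return A [jsfs()] object.
#' @export
jsfs_from_haplotypes <- function(dataset, n1, n2) {
  stopifnot(inherits(dataset, "im_dataset"))
  counts <- matrix(0L, n1 + 1, n2 + 1)
  for (k in seq_along(dataset$loci)) {
    h <- dataset$loci[[k]]$haplotypes
    if (nrow(h) != n1 + n2)
      stop("locus ", k, " has ", nrow(h), " rows but n1 + n2 = ", n1 + n2)
    if (ncol(h) == 0) next
    i <- colSums(h[seq_len(n1), , drop = FALSE])
    j <- colSums(h[n1 + seq_len(n2), , drop = FALSE])
    keep <- !((i == 0 & j == 0) | (i == n1 & j == n2))
    for (s in which(keep))
      counts[i[s] + 1L, j[s] + 1L] <- counts[i[s] + 1L, j[s] + 1L] + 1L
  }
  jsfs(counts, n1, n2)
}

# ---- coarsenings -----------------------------------------------------------

cells_rect <- function(i0, i1, j0, j1) {
  if (i1 < i0 || j1 < j0) return(matrix(integer(0), 0, 2))
  as.matrix(expand.grid(i = i0:i1, j = j0:j1, KEEP.OUT.ATTRS = FALSE))
}

cells_union <- function(...) {
  m <- do.call(rbind, list(...))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Construct a validated coarsening
#'
#' A coarsening is an ordered partition of the eligible JSFS cells (all
#' `(i, j)` except the unobservable corners `(0,0)` and `(n1,n2)`) into
#' labelled classes.  Construction fails (never warns) if the classes
#' overlap, leave a gap, or touch an excluded corner.
#'
#' @param name short name of the coarsening.
#' @param n1,n2 sample sizes the partition applies to.
#' @param classes list of `list(label = , cells = )` where `cells` is a
#'   two-column integer matrix of `(i, j)` pairs.
#' @return An object of class `im_coarsening` with an `index` attribute (an
#'   `(n1+1) x (n2+1)` integer matrix mapping each cell to its class, `NA`
#'   for the two excluded corners).
#' @seealso [builtin_coarsening()], [load_coarsening()]
#' @export
new_coarsening <- function(name, n1, n2, classes) {
  idx <- matrix(NA_integer_, n1 + 1, n2 + 1)
  for (k in seq_along(classes)) {
    cls <- classes[[k]]
    cells <- cls$cells
    if (nrow(cells) == 0)
      stop("class '", cls$label, "' is empty")
    if (any(cells[, 1] < 0 | cells[, 1] > n1 | cells[, 2] < 0 | cells[, 2] > n2))
      stop("class '", cls$label, "' contains cells outside the JSFS")
    lin <- cells[, 1] + 1L + (n1 + 1L) * cells[, 2]
    if (anyDuplicated(lin))
      stop("class '", cls$label, "' lists a cell twice")
    hit <- !is.na(idx[lin])
    if (any(hit)) {
      c1 <- cells[which(hit)[1], ]
      stop("overlap: cell (", c1[1], ",", c1[2], ") belongs to classes '",
           classes[[idx[lin[which(hit)[1]]]]]$label, "' and '", cls$label, "'")
    }
    corner <- (cells[, 1] == 0 & cells[, 2] == 0) |
      (cells[, 1] == n1 & cells[, 2] == n2)
    if (any(corner))
      stop("class '", cls$label,
           "' contains an excluded corner cell ((0,0) or (n1,n2))")
    idx[lin] <- k
  }
  miss <- which(is.na(idx))
  miss <- setdiff(miss, c(1L, (n1 + 1L) * (n2 + 1L)))
  if (length(miss)) {
    i <- (miss[1] - 1L) %% (n1 + 1L)
    j <- (miss[1] - 1L) %/% (n1 + 1L)
    stop("gap: cell (", i, ",", j, ") is not covered by any class")
  }
  structure(list(name = name, n1 = as.integer(n1), n2 = as.integer(n2),
                 classes = classes),
            index = idx, class = "im_coarsening")
}

#' @export
print.im_coarsening <- function(x, ...) {
  cat(sprintf("Coarsening '%s' for (n1, n2) = (%d, %d): %d classes\n",
              x$name, x$n1, x$n2, length(x$classes)))
  for (k in seq_along(x$classes))
    cat(sprintf("  %2d %-12s %3d cells\n", k, x$classes[[k]]$label,
                nrow(x$classes[[k]]$cells)))
  invisible(x)
}

#' @export
labels.im_coarsening <- function(object, ...)
  vapply(object$classes, `[[`, character(1), "label")

# the two 23-class layouts share the private/fixed structure (frequency bins
# {1}, {2}, {3..n-1}) and differ only in the shared-polymorphism 3 x 3 bins;
# class 6 is always the shared low-by-low class
coarsen23 <- function(name, n1, n2, sbins1, sbins2) {
  priv1 <- function(lab, a, b) list(label = lab, cells = cells_rect(a, b, 0, 0))
  priv2 <- function(lab, a, b) list(label = lab, cells = cells_rect(0, 0, a, b))
  f1 <- function(lab, a, b) list(label = lab, cells = cells_rect(a, b, n2, n2))
  f2 <- function(lab, a, b) list(label = lab, cells = cells_rect(n1, n1, a, b))
  sh <- function(a, b) cells_rect(sbins1[[a]][1], sbins1[[a]][2],
                                  sbins2[[b]][1], sbins2[[b]][2])
  shlab <- function(k, a, b)
    paste0(name, k, "_sh.", names(sbins1)[a], "x", names(sbins2)[b])
  classes <- list(
    priv1(paste0(name, "1_p1.s1"), 1, 1),
    priv2(paste0(name, "2_p2.s1"), 1, 1),
    list(label = paste0(name, "3_fix1"), cells = cells_rect(n1, n1, 0, 0)),
    list(label = paste0(name, "4_fix2"), cells = cells_rect(0, 0, n2, n2)),
    priv1(paste0(name, "5_p1.s2"), 2, 2),
    list(label = shlab(6, 1, 1), cells = sh(1, 1)),
    priv2(paste0(name, "7_p2.s2"), 2, 2),
    priv1(paste0(name, "8_p1.hi"), 3, n1 - 1),
    priv2(paste0(name, "9_p2.hi"), 3, n2 - 1),
    f1(paste0(name, "10_f2p1.s1"), 1, 1),
    f1(paste0(name, "11_f2p1.s2"), 2, 2),
    f1(paste0(name, "12_f2p1.hi"), 3, n1 - 1),
    f2(paste0(name, "13_f1p2.s1"), 1, 1),
    f2(paste0(name, "14_f1p2.s2"), 2, 2),
    f2(paste0(name, "15_f1p2.hi"), 3, n2 - 1)
  )
  rest <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 2), c(2, 3),
               c(3, 1), c(3, 2), c(3, 3))
  for (r in seq_along(rest)) {
    a <- rest[[r]][1]; b <- rest[[r]][2]
    classes[[15 + r]] <- list(label = shlab(15 + r, a, b), cells = sh(a, b))
  }
  new_coarsening(name, n1, n2, classes)
}

#' Built-in JSFS coarsenings
#'
#' The six partitions of the joint site-frequency spectrum used by the
#' estimators in this package, in increasing order of refinement:
#'
#' * `W` (4 classes): private polymorphisms of population 1 (`W1`) and
#'   population 2 (`W2`), fixed differences (`W3`), shared polymorphisms
#'   (`W4`).
#' * `D` (7): `W` with each private class split by whether the derived
#'   allele is absent or fixed in the other population, and the two fixed
#'   difference cells separated; `W1 = D1 + D6`, `W2 = D2 + D7`,
#'   `W3 = D3 + D4`, `W4 = D5`.
#' * `Dprime` (12): `D` with the shared class split to isolate shared
#'   singletons and doubletons (asymmetric nesting).
#' * `Dsecond` (12): `D` with the shared class split into six symmetric
#'   low-frequency bins.
#' * `Dstar` (23): privates and fixed-in-the-other-population classes split
#'   by frequency bins {1}, {2}, {3..n-1}; shared polymorphisms split 3 x 3
#'   on the same bins.  Class 6 holds sites that are singletons in both
#'   populations.
#' * `Dcheck` (23): as `Dstar` but the shared 3 x 3 split uses bins
#'   low = {1,2}, mid = {3..n-3}, high = {n-2, n-1}, adding classes of
#'   shared polymorphism at nearly fixed frequencies.  Class 6 (`Dcheck6`)
#'   holds sites that are singletons or doubletons in both populations.
#'
#' The exact bin boundaries beyond the constraints above are package
#' defaults; alternative partitions can be supplied via
#' [load_coarsening()].
#'
#' @param name one of `"W"`, `"D"`, `"Dprime"`, `"Dsecond"`, `"Dstar"`,
#'   `"Dcheck"`.
#' @param n1,n2 sample sizes; minimums are 2 for `W`/`D`, 4 for
#'   `Dprime`/`Dsecond`, 6 for `Dstar`/`Dcheck` (so that every frequency bin
#'   is non-empty).
#' @return An `im_coarsening`.
#' @examples
#' builtin_coarsening("W", 10, 10)
#' @export
builtin_coarsening <- function(name = c("W", "D", "Dprime", "Dsecond",
                                        "Dstar", "Dcheck"), n1, n2) {
  name <- match.arg(name)
  need <- c(W = 2, D = 2, Dprime = 4, Dsecond = 4, Dstar = 6, Dcheck = 6)[[name]]
  if (n1 < need || n2 < need)
    stop("coarsening '", name, "' requires n1, n2 >= ", need,
         " (got ", n1, ", ", n2, ")")
  switch(name,
    W = new_coarsening("W", n1, n2, list(
      list(label = "W1_private1", cells = cells_union(
        cells_rect(1, n1 - 1, 0, 0), cells_rect(1, n1 - 1, n2, n2))),
      list(label = "W2_private2", cells = cells_union(
        cells_rect(0, 0, 1, n2 - 1), cells_rect(n1, n1, 1, n2 - 1))),
      list(label = "W3_fixed", cells = cells_union(
        cells_rect(n1, n1, 0, 0), cells_rect(0, 0, n2, n2))),
      list(label = "W4_shared", cells = cells_rect(1, n1 - 1, 1, n2 - 1)))),
    D = new_coarsening("D", n1, n2, list(
      list(label = "D1", cells = cells_rect(1, n1 - 1, 0, 0)),
      list(label = "D2", cells = cells_rect(0, 0, 1, n2 - 1)),
      list(label = "D3", cells = cells_rect(n1, n1, 0, 0)),
      list(label = "D4", cells = cells_rect(0, 0, n2, n2)),
      list(label = "D5", cells = cells_rect(1, n1 - 1, 1, n2 - 1)),
      list(label = "D6", cells = cells_rect(1, n1 - 1, n2, n2)),
      list(label = "D7", cells = cells_rect(n1, n1, 1, n2 - 1)))),
    Dprime = new_coarsening("Dprime", n1, n2, list(
      list(label = "Dp1", cells = cells_rect(1, n1 - 1, 0, 0)),
      list(label = "Dp2", cells = cells_rect(0, 0, 1, n2 - 1)),
      list(label = "Dp3", cells = cells_rect(n1, n1, 0, 0)),
      list(label = "Dp4", cells = cells_rect(0, 0, n2, n2)),
      list(label = "Dp5_sh11", cells = cells_rect(1, 1, 1, 1)),
      list(label = "Dp6_sh1j", cells = cells_rect(1, 1, 2, n2 - 1)),
      list(label = "Dp7_shi1", cells = cells_rect(2, n1 - 1, 1, 1)),
      list(label = "Dp8_sh2j", cells = cells_rect(2, 2, 2, n2 - 1)),
      list(label = "Dp9_shi2", cells = cells_rect(3, n1 - 1, 2, 2)),
      list(label = "Dp10_shrest", cells = cells_rect(3, n1 - 1, 3, n2 - 1)),
      list(label = "Dp11", cells = cells_rect(1, n1 - 1, n2, n2)),
      list(label = "Dp12", cells = cells_rect(n1, n1, 1, n2 - 1)))),
    Dsecond = new_coarsening("Dsecond", n1, n2, list(
      list(label = "Ds1", cells = cells_rect(1, n1 - 1, 0, 0)),
      list(label = "Ds2", cells = cells_rect(0, 0, 1, n2 - 1)),
      list(label = "Ds3", cells = cells_rect(n1, n1, 0, 0)),
      list(label = "Ds4", cells = cells_rect(0, 0, n2, n2)),
      list(label = "Ds5_shlowlow", cells = cells_rect(1, 2, 1, 2)),
      list(label = "Ds6_sh1hi", cells = cells_rect(1, 1, 3, n2 - 1)),
      list(label = "Ds7_sh2hi", cells = cells_rect(2, 2, 3, n2 - 1)),
      list(label = "Ds8_shhi1", cells = cells_rect(3, n1 - 1, 1, 1)),
      list(label = "Ds9_shhi2", cells = cells_rect(3, n1 - 1, 2, 2)),
      list(label = "Ds10_shhihi", cells = cells_rect(3, n1 - 1, 3, n2 - 1)),
      list(label = "Ds11", cells = cells_rect(1, n1 - 1, n2, n2)),
      list(label = "Ds12", cells = cells_rect(n1, n1, 1, n2 - 1)))),
    Dstar = coarsen23("Dstar", n1, n2,
      sbins1 = list(s1 = c(1, 1), s2 = c(2, 2), hi = c(3, n1 - 1)),
      sbins2 = list(s1 = c(1, 1), s2 = c(2, 2), hi = c(3, n2 - 1))),
    Dcheck = coarsen23("Dcheck", n1, n2,
      sbins1 = list(low = c(1, 2), mid = c(3, n1 - 3), high = c(n1 - 2, n1 - 1)),
      sbins2 = list(low = c(1, 2), mid = c(3, n2 - 3), high = c(n2 - 2, n2 - 1)))
  )
}

#' Reduce a JSFS to the class totals of a coarsening
#'
#' @param x a [jsfs()] object.
#' @param coarsening an `im_coarsening` with matching `n1`, `n2`.
#' @return An `im_summary`: a named numeric vector of class counts in
#'   coarsening order, with attributes `coarsening`, `n1`, `n2`.
#' @examples
#' co <- builtin_coarsening("W", 3, 3)
#' m <- matrix(0L, 4, 4); m[2, 1] <- 4L
#' summarize_jsfs(jsfs(m, 3, 3), co)
#' @export
summarize_jsfs <- function(x, coarsening) {
  stopifnot(inherits(x, "jsfs"), inherits(coarsening, "im_coarsening"))
  if (attr(x, "n1") != coarsening$n1 || attr(x, "n2") != coarsening$n2)
    stop("JSFS dimensions (", attr(x, "n1"), ", ", attr(x, "n2"),
         ") do not match the coarsening (", coarsening$n1, ", ",
         coarsening$n2, ")")
  idx <- attr(coarsening, "index")
  K <- length(coarsening$classes)
  counts <- vapply(seq_len(K), function(k) sum(x[which(idx == k)]), numeric(1))
  names(counts) <- labels(coarsening)
  structure(counts, coarsening = coarsening$name, n1 = coarsening$n1,
            n2 = coarsening$n2, class = "im_summary")
}

#' @export
print.im_summary <- function(x, ...) {
  cat(sprintf("JSFS summary '%s' (n1 = %d, n2 = %d), total %g sites\n",
              attr(x, "coarsening"), attr(x, "n1"), attr(x, "n2"), sum(x)))
  v <- as.numeric(x); names(v) <- names(unclass(x))
  print(v)
  invisible(x)
}

# ---- coarsening spec files -------------------------------------------------

parse_bound <- function(tok, n1, n2) {
  tok <- gsub(" ", "", tok)
  m <- regmatches(tok, regexec("^(n1|n2|-?[0-9]+)([+-][0-9]+)?$", tok))[[1]]
  if (length(m) == 0) stop("cannot parse bound '", tok, "'")
  base <- switch(m[2], n1 = n1, n2 = n2, as.integer(m[2]))
  off <- if (m[3] == "") 0L else as.integer(m[3])
  base + off
}

parse_rule <- function(line, n1, n2) {
  lo <- c(i = 0L, j = 0L); hi <- c(i = n1, j = n2)
  for (pred in strsplit(line, ";", fixed = TRUE)[[1]]) {
    pred <- trimws(pred)
    if (pred == "") next
    m <- regmatches(pred, regexec("^([ij])\\s+in\\s+(\\S+)\\.\\.(\\S+)$", pred))[[1]]
    if (length(m) == 0) stop("unknown predicate '", pred, "'")
    lo[m[2]] <- parse_bound(m[3], n1, n2)
    hi[m[2]] <- parse_bound(m[4], n1, n2)
  }
  cells_rect(lo["i"], hi["i"], lo["j"], hi["j"])
}

#' Read a coarsening from a partition-spec file
#'
#' The format is line-oriented plain text.  Header lines `coarsening:`,
#' `n1:`, `n2:` are followed by one `class: <label>` line per class, each
#' followed by one or more rule lines.  A rule line is a `;`-separated list
#' of predicates `i in a..b` / `j in a..b`; bounds may be integers or the
#' keywords `n1`, `n2` with an optional `+k`/`-k` offset (e.g. `n1-1`).  An
#' omitted axis spans its full range.  The class is the union of its rule
#' rectangles.  The partition is validated on load: overlapping classes,
#' uncovered cells, or unknown predicates are errors, never warnings.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return An `im_coarsening`.
#' @examples
#' lines <- c("coarsening: halves", "n1: 3", "n2: 3",
#'            "class: left",  "i in 0..1",
#'            "class: right", "i in 2..3")
#' load_coarsening(text = lines)
#' @export
load_coarsening <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  hdr <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) != 1) stop("spec needs exactly one '", key, ":' line")
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  name <- hdr("coarsening")
  n1 <- as.integer(hdr("n1")); n2 <- as.integer(hdr("n2"))
  if (is.na(n1) || is.na(n2)) stop("n1/n2 headers must be integers")
  body <- lines[!grepl("^(coarsening|n1|n2):", lines)]
  classes <- list(); cur <- NULL
  for (ln in body) {
    if (grepl("^class:", ln)) {
      if (!is.null(cur)) classes[[length(classes) + 1L]] <- cur
      cur <- list(label = trimws(sub("^class:", "", ln)),
                  cells = matrix(integer(0), 0, 2))
    } else {
      if (is.null(cur)) stop("rule line before any 'class:' line: '", ln, "'")
      cur$cells <- rbind(cur$cells, parse_rule(ln, n1, n2))
    }
  }
  if (!is.null(cur)) classes[[length(classes) + 1L]] <- cur
  if (length(classes) == 0) stop("spec defines no classes")
  new_coarsening(name, n1, n2, classes)
}

#' Write a coarsening as a partition-spec file
#'
#' Emits one rule rectangle per cell, which is verbose but round-trips any
#' partition exactly through [load_coarsening()].
#'
#' @param coarsening an `im_coarsening`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coarsening <- function(coarsening, path) {
  stopifnot(inherits(coarsening, "im_coarsening"))
  out <- c(paste0("coarsening: ", coarsening$name),
           paste0("n1: ", coarsening$n1), paste0("n2: ", coarsening$n2))
  for (cls in coarsening$classes) {
    out <- c(out, paste0("class: ", cls$label),
             sprintf("i in %d..%d ; j in %d..%d",
                     cls$cells[, 1], cls$cells[, 1],
                     cls$cells[, 2], cls$cells[, 2]))
  }
  writeLines(out, path)
  invisible(path)
}

# TRUE if two coarsenings induce the same partition (same classes as cell
# sets, in the same order), regardless of labels
same_partition <- function(a, b) {
  if (a$n1 != b$n1 || a$n2 != b$n2) return(FALSE)
  if (length(a$classes) != length(b$classes)) return(FALSE)
  ia <- attr(a, "index"); ib <- attr(b, "index")
  identical(ia, ib)
}
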