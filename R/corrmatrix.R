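new_corr_matrix <- function(values, bin_length, labels, convergence,
                            origin_ap = 0) {
  structure(values, class = "corr_matrix", bin_length = bin_length,
            labels = labels, convergence = convergence, origin_ap = origin_ap)
}

#' @export
print.corr_matrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("<corr_matrix> ", nrow(x), " x ", ncol(x), " bins of ",
      signif(attr(x, "bin_length"), 4), " μm (",
      paste(lab, collapse = " vs "), "), ",
      sum(is.na(x)), " undefined entries\n", sep = "")
  invisible(x)
}

#' Self cross-correlation matrix of a slab series
#'
#' Registers every unordered pair of transverse sections and scores the
#' registered pair, giving the n x n axial self-correlation matrix in which
#' segmentally repeated structure appears as periodic high-correlation bands
#' and the 3D nodes as one conspicuous band per segment. Only the upper
#' triangle is computed; the matrix is mirrored, which enforces the symmetry
#' the readout assumes. The diagonal is 1 by definition. Pairs whose score is
#' undefined (insufficient overlap or zero variance) carry `NA`, never abort
#' the matrix.
#'
#' @param slabs a [slab_series()].
#' @param opts a [reg_options()].
#' @param embryo label recorded on the matrix axes.
#' @return A `corr_matrix`: an n x n numeric matrix with attributes
#'   `bin_length` (μm), `labels`, `origin_ap` and `convergence` (logical
#'   matrix of optimiser convergence flags).
#' @export
self_correlation_matrix <- function(slabs, opts = reg_options(),
                                    embryo = "self") {
  stopifnot(inherits(slabs, "slab_series"))
  n <- length(slabs)
  vals <- matrix(NA_real_, n, n)
  conv <- matrix(TRUE, n, n)
  diag(vals) <- 1
  for (i in seq_len(n - 1L)) {
    fixed <- slabs$sections[[i]]
    for (j in seq.int(i + 1L, n)) {
      sc <- pair_score(fixed, slabs$sections[[j]], opts, slabs$pitch)
      vals[i, j] <- vals[j, i] <- sc$score
      conv[i, j] <- conv[j, i] <- sc$converged
    }
  }
  new_corr_matrix(vals, slabs$bin_length, c(embryo, embryo), conv,
                  slabs$origin_ap)
}

#' Cross-correlation matrix between two slab series
#'
#' Rectangular inter-embryo counterpart of [self_correlation_matrix()]: entry
#' (i, j) scores section i of `slabs_a` against section j of `slabs_b` after
#' rigid registration. No symmetry or unit diagonal is implied.
#'
#' @param slabs_a,slabs_b [slab_series()] objects sharing the same bin length.
#' @param opts a [reg_options()].
#' @param labels length-2 character vector naming the two embryos.
#' @return A `corr_matrix` of dimension `length(slabs_a) x length(slabs_b)`.
#' @export
cross_correlation_matrix <- function(slabs_a, slabs_b, opts = reg_options(),
                                     labels = c("a", "b")) {
  stopifnot(inherits(slabs_a, "slab_series"), inherits(slabs_b, "slab_series"))
  if (!isTRUE(all.equal(slabs_a$bin_length, slabs_b$bin_length))) {
    abort("bin lengths differ between the two series")
  }
  na <- length(slabs_a); nb <- length(slabs_b)
  vals <- matrix(NA_real_, na, nb)
  conv <- matrix(TRUE, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sc <- pair_score(slabs_a$sections[[i]], slabs_b$sections[[j]], opts,
                       slabs_a$pitch)
      vals[i, j] <- sc$score
      conv[i, j] <- sc$converged
    }
  }
  new_corr_matrix(vals, slabs_a$bin_length, labels, conv, slabs_a$origin_ap)
}

pair_score <- function(fixed, moving, opts, pitch) {
  res <- tryCatch({
    tr <- register_rigid(fixed, moving, opts, pitch)
    list(score = correlation_score(fixed, moving, tr, pitch,
                                   opts$min_overlap_fraction),
         converged = isTRUE(attr(tr, "converged")))
  }, error = function(e) list(score = NA_real_, converged = FALSE))
  res
}

#' Tidy a correlation matrix into long form
#'
#' @param x a `corr_matrix`.
#' @param ... unused.
#' @return A tibble with one row per matrix entry: `bin_a`, `bin_b`,
#'   `position_a`, `position_b` (bin-centre AP positions, μm), `score`,
#'   `converged`.
#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  bl <- attr(x, "bin_length")
  o <- attr(x, "origin_ap")
  idx <- expand.grid(bin_a = seq_len(nrow(x)), bin_b = seq_len(ncol(x)))
  tibble::tibble(
    bin_a = idx$bin_a, bin_b = idx$bin_b,
    position_a = o + (idx$bin_a - 0.5) * bl,
    position_b = o + (idx$bin_b - 0.5) * bl,
    score = as.vector(unclass(x)[cbind(idx$bin_a, idx$bin_b)]),
    converged = as.vector(attr(x, "convergence")[cbind(idx$bin_a, idx$bin_b)])
  )
}

#' Write a correlation matrix as CSV plus JSON sidecar
#' @param matrix a `corr_matrix`.
#' @param path output CSV path (bin-by-bin scores); metadata in `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_corr_matrix <- function(matrix, path) {
  utils::write.csv(unclass(matrix)[, , drop = FALSE], path, row.names = FALSE)
  jsonlite::write_json(
    list(bin_length = attr(matrix, "bin_length"),
         labels = attr(matrix, "labels"),
         origin_ap = attr(matrix, "origin_ap")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a correlation matrix written by [write_corr_matrix()]
#' @param path CSV path with `<path>.json` sidecar.
#' @return A `corr_matrix`.
#' @export
read_corr_matrix <- function(path) {
  vals <- as.matrix(utils::read.csv(path))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_corr_matrix(vals, meta$bin_length, meta$labels,
                  matrix(TRUE, nrow(vals), ncol(vals)), meta$origin_ap)
}
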