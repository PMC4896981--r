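intensities_of <- function(x) {
  if (inherits(x, "planar_image")) x$pixels
  else if (inherits(x, "volume_image")) x$voxels
  else if (is.numeric(x)) x
  else stop("expected a planar_image, volume_image or numeric array")
}

check_same_shape <- function(A, B) {
  a <- intensities_of(A); b <- intensities_of(B)
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(da, db))
    stop("images must have identical shape (", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), ")")
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Mean squared intensity difference
#'
#' \eqn{MSQ(A,B) = \frac{1}{N}\sum_i (A_i - B_i)^2} over the N pixels of the
#' two same-shaped images.  Symmetric, zero iff the images are identical.
#'
#' @param A,B Images ([planar_image], [volume_image]) or numeric arrays of
#'   identical shape.
#' @return Non-negative scalar.
#' @export
msq <- function(A, B) {
  v <- check_same_shape(A, B)
  mean((v$a - v$b)^2)
}

#' Normalized cross-correlation of two images
#'
#' Pearson correlation of the intensity vectors; in \[-1, 1\].
#'
#' @inheritParams msq
#' @return Scalar in \[-1, 1\].
#' @export
ncc <- function(A, B) {
  v <- check_same_shape(A, B)
  sa <- stats::sd(v$a); sb <- stats::sd(v$b)
  if (sa == 0 || sb == 0)
    stop("ncc: undefined for an image with zero intensity variance")
  stats::cor(v$a, v$b)
}

#' Rescale a correlation value to the \[-1, 0\] similarity convention
#'
#' Maps NCC in \[-1, 1\] to \eqn{s = -(1 + NCC)/2}: identical images give -1,
#' perfectly anticorrelated images give 0; lower means more similar.  This
#' is the edge-similarity convention of the graph-based alignment workflow.
#'
#' @param ncc_value Scalar in \[-1, 1\].
#' @return Scalar in \[-1, 0\].
#' @export
rescale_cc <- function(ncc_value) {
  if (!is.numeric(ncc_value) || any(ncc_value < -1 - 1e-12) ||
      any(ncc_value > 1 + 1e-12))
    stop("rescale_cc: input must lie in [-1, 1]")
  -(1 + pmin(pmax(ncc_value, -1), 1)) / 2
}

#' Mutual information of two images
#'
#' Mutual information in nats from a joint histogram with `bins` x `bins`
#' cells on per-image min-max-normalized intensities.
#'
#' @inheritParams msq
#' @param bins Number of histogram bins per image (default 32).
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(A, B, bins = 32L) {
  v <- check_same_shape(A, B)
  bins <- as.integer(bins)
  bin_index <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) return(NULL)
    pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  }
  bi <- bin_index(v$a); bj <- bin_index(v$b)
  if (is.null(bi) || is.null(bj)) {
    warning("mutual_information: constant image, MI = 0")
    return(0)
  }
  joint <- tabulate((bi - 1L) * bins + bj, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)          # [bj, bi]
  px <- colSums(pm); py <- rowSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(py, px)[nz]))
}

#' Metric value in the minimization convention
#'
#' The scalar the registration engine minimizes: MSQ directly, NCC via
#' [rescale_cc()], MI negated.
#' @param fixed,warped Images of identical shape.
#' @param metric `"NCC"`, `"MSQ"` or `"MI"`.
#' @param bins MI histogram bins.
#' @return Scalar (lower = more similar).
#' @export
metric_value <- function(fixed, warped, metric = c("NCC", "MSQ", "MI"),
                         bins = 32L) {
  metric <- match.arg(metric)
  switch(metric,
         MSQ = msq(fixed, warped),
         NCC = {
           v <- check_same_shape(fixed, warped)
           if (stats::sd(v$a) == 0 || stats::sd(v$b) == 0) 0
           else rescale_cc(stats::cor(v$a, v$b))
         },
         MI = -mutual_information(fixed, warped, bins = bins))
}
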