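# 2D fingerprint similarity calculation model.
#
# Two layered count fingerprints are compared by (i) an exact-match prefix
# filter on the first `exact_depth` layers, then (ii) a weighted sum over
# layers of Soergel distance times Hamming distance.  Scores range from 0
# (identity) upward; fingerprints are similar when the prefix matches and
# the total score is at or below the threshold.

#' Similarity model parameters
#'
#' @param exact_depth number of leading layers that must match exactly
#'   (default 3: layers 0, 1, 2 — the root layer counts as the first).
#' @param threshold inclusive upper bound on the total weighted score for
#'   two fingerprints to count as similar (default 3.5).
#' @param n_layers total number of fingerprint layers (default 6).
#' @return an object of class `similarity_params`.
#' @export
#' @examples
#' similarity_params()
similarity_params <- function(exact_depth = 3L, threshold = 3.5,
                              n_layers = .n_layers_default) {
  exact_depth <- as.integer(exact_depth)
  n_layers <- as.integer(n_layers)
  stopifnot(exact_depth >= 0, exact_depth <= n_layers, threshold >= 0,
            n_layers >= 1)
  structure(list(exact_depth = exact_depth, threshold = threshold,
                 n_layers = n_layers),
            class = "similarity_params")
}

#' @export
print.similarity_params <- function(x, ...) {
  cat(sprintf(
    "<similarity_params: exact_depth=%d threshold=%g n_layers=%d>\n",
    x$exact_depth, x$threshold, x$n_layers))
  invisible(x)
}

#' Layer weighting coefficient
#'
#' Weight of fingerprint level `lambda` (1-based: level 1 is the root
#' layer) out of `n_layers` levels:
#' `(2/n_layers) * (lambda/exp(lambda-1) + (n_layers-1)/(2*lambda))`.
#' Strictly decreasing in `lambda` for the default six levels, so inner
#' layers dominate the score.
#'
#' @param lambda level index, `1 <= lambda <= n_layers`.
#' @param n_layers total number of levels (default 6).
#' @return the weight (positive real).
#' @export
#' @examples
#' layer_weight(1)  # 7/6
layer_weight <- function(lambda, n_layers = .n_layers_default) {
  if (any(lambda < 1)) stop("lambda must be >= 1")
  if (any(lambda > n_layers)) stop("lambda must be <= n_layers")
  (2 / n_layers) * (lambda / exp(lambda - 1) + (n_layers - 1) / (2 * lambda))
}

#' Soergel distance between two count-vector layers
#'
#' `1 - sum(a*b) / sum(a^2 + b^2 - a*b)` over the full alphabet width;
#' the complement of the count (generalized) Tanimoto coefficient.  Lies in
#' `[0, 1]`: 0 for equal vectors, 1 for disjoint support.
#'
#' @param row_a,row_b nonnegative integer vectors of equal width, not both
#'   all-zero (the PAD column guarantees this for fingerprint rows).
#' @return the distance.
#' @export
soergel_layer <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) {
    stop("layer width mismatch: ", length(row_a), " vs ", length(row_b))
  }
  num <- sum(row_a * row_b)
  den <- sum(row_a^2 + row_b^2 - row_a * row_b)
  if (den == 0) return(0)   # both all-zero: identical by convention
  1 - num / den
}

#' Hamming distance between two count-vector layers
#'
#' Sum of absolute per-type count differences.
#'
#' @param row_a,row_b integer vectors of equal width.
#' @return a nonnegative integer.
#' @export
hamming_layer <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) {
    stop("layer width mismatch: ", length(row_a), " vs ", length(row_b))
  }
  sum(abs(row_a - row_b))
}

#' Total weighted similarity score between two fingerprints
#'
#' `sum_j weight(j+1) * soergel_j * hamming_j` over layers `j = 0..n-1`,
#' plus the exact-match prefix verdict on the first `exact_depth` layers.
#'
#' @param fp_a,fp_b `fingerprint` matrices over the same alphabet with the
#'   same number of layers.
#' @param params a [similarity_params()] object.
#' @return a list of class `similarity_score` with elements `total`,
#'   `per_layer_soergel`, `per_layer_hamming`, `weights`, `exact_prefix_ok`.
#' @export
total_distance <- function(fp_a, fp_b, params = similarity_params()) {
  if (nrow(fp_a) != nrow(fp_b)) {
    stop("fingerprint layer count mismatch: ", nrow(fp_a), " vs ", nrow(fp_b))
  }
  if (ncol(fp_a) != ncol(fp_b)) {
    stop("fingerprint alphabet width mismatch")
  }
  n <- nrow(fp_a)
  dj <- numeric(n)
  dh <- integer(n)
  for (j in seq_len(n)) {
    dj[j] <- soergel_layer(fp_a[j, ], fp_b[j, ])
    dh[j] <- hamming_layer(fp_a[j, ], fp_b[j, ])
  }
  w <- layer_weight(seq_len(n), n_layers = n)
  ed <- min(params$exact_depth, n)
  ok <- ed == 0 || all(dh[seq_len(ed)] == 0L)
  structure(list(
    total = sum(w * dj * dh),
    per_layer_soergel = dj,
    per_layer_hamming = dh,
    weights = w,
    exact_prefix_ok = ok
  ), class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score total=%.4f exact_prefix_ok=%s>\n",
              x$total, x$exact_prefix_ok))
  invisible(x)
}

#' Are two fingerprints similar?
#'
#' TRUE iff the exact-match prefix holds and the total weighted score is at
#' or below the threshold (inclusive).
#'
#' @inheritParams total_distance
#' @return logical.
#' @export
is_similar <- function(fp_a, fp_b, params = similarity_params()) {
  s <- total_distance(fp_a, fp_b, params)
  s$exact_prefix_ok && s$total <= params$threshold
}
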