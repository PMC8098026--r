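# Interaction prediction head: pairwise drug x protein interaction map,
# CNN aggregation, sigmoid decoder and binary cross-entropy loss.

#' Pairwise sub-structure interaction map
#'
#' Cell (j, i) scores the interaction between drug sub-structure j and protein
#' sub-structure i.  Under the default dot product the map is the matrix
#' product `Ed %*% t(Ep)`; `sum` and `average` are the scalar reductions
#' `sum(a) + sum(b)` and `mean(a + b)` of the embedding pair.
#'
#' @param Ed Drug embeddings, Theta_d x dim.
#' @param Ep Protein embeddings, Theta_p x dim.
#' @param fn One of `"dot"` (default), `"sum"`, `"average"`.
#' @return Theta_d x Theta_p numeric matrix.
#' @export
interaction_map <- function(Ed, Ep, fn = c("dot", "sum", "average")) {
  fn <- match.arg(fn)
  if (ncol(Ed) != ncol(Ep)) stop("drug and protein embeddings must share the latent dimension")
  switch(fn,
         dot = Ed %*% t(Ep),
         sum = outer(rowSums(Ed), rowSums(Ep), `+`),
         average = outer(rowSums(Ed), rowSums(Ep), `+`) / ncol(Ed))
}

#' Aggregate an interaction map with the CNN layer
#'
#' One 2-D convolution (stride 1, valid padding) with ReLU activation; the
#' default head uses three 3x3 filters, so the output has shape
#' `(Theta_d - 2, Theta_p - 2, 3)`.
#'
#' @param I Interaction map matrix.
#' @param kernels k x k x n_filters array of filters.
#' @param bias Numeric vector, one bias per filter.
#' @return 3-D array of activated feature maps.
#' @export
aggregate_interaction <- function(I, kernels, bias) {
  if (any(!is.finite(I))) stop("non-finite values in interaction map")
  conv_relu_forward(I, kernels, bias)$out
}

#' Decode aggregated features to an interaction probability
#'
#' @param O Numeric array (flattened column-major).
#' @param weights Weight vector matching `length(O)`.
#' @param bias Scalar bias.
#' @return Probability strictly inside (0, 1).
#' @export
predict_probability <- function(O, weights, bias) {
  x <- as.numeric(O)
  if (length(x) != length(weights)) {
    stop(sprintf("decoder expects %d inputs, got %d", length(weights), length(x)))
  }
  stats::plogis(sum(weights * x) + bias)
}

#' Binary cross-entropy loss
#'
#' The mean over the batch of `-(y log p + (1 - y) log(1 - p))`; probabilities
#' at exactly 0 or 1 are clamped to `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @return Scalar loss.
#' @export
bce_loss <- function(p, y) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  eps <- 1e-7
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clamped away from {0,1} before taking logs")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
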