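#' Focal loss
#'
#' Cross-entropy variant that down-weights well-classified pixels by
#' `(1 - p_t)^gamma`, which keeps the rare fiber-bundle class from being
#' swamped by the abundant background class. With the class-balance weight
#' enabled, `alpha_t` is `alpha` for positive pixels and `1 - alpha` for
#' negatives (the original focal-loss convention); with `gamma = 0` and
#' the weighting disabled the loss reduces exactly to plain cross-entropy.
#'
#' Probabilities are clamped to `[eps, 1 - eps]` before the logarithm so a
#' confidently wrong pixel yields a large finite value rather than `Inf`.
#'
#' @param p predicted fiber-class probabilities in `[0, 1]` (any shape).
#' @param y targets in `{0, 1}`, same shape as `p`.
#' @param alpha class-balance weight in (0, 1); default 0.25.
#' @param gamma focusing exponent, `>= 0`; default 2.
#' @param alpha_weighting apply the `alpha_t` class weight (default `TRUE`).
#' @param eps probability clamp before the log.
#' @return Mean focal loss over all elements (non-negative scalar).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2,
                       alpha_weighting = TRUE, eps = 1e-7) {
  stopifnot(length(p) == length(y))
  if (any(p < 0 | p > 1)) {
    abort("probabilities must lie in [0, 1]", class = "ft_validation_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort("targets must be 0/1", class = "ft_validation_error")
  }
  if (alpha <= 0 || alpha >= 1 || gamma < 0) {
    abort("need alpha in (0,1) and gamma >= 0", class = "ft_validation_error")
  }
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  at <- if (alpha_weighting) ifelse(y == 1, alpha, 1 - alpha) else 1
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' SimCLR-style contrastive loss (NT-Xent)
#'
#' Operates on the embeddings of `2N` augmented views, arranged so that
#' rows `(1, 2), (3, 4), ...` are the two views of the same patch. For an
#' ordered positive pair `(i, j)` the per-pair term is
#' `-log( exp(sim(f_i, f_j)/tau) / sum_{k != i} exp(sim(f_i, f_k)/tau) )`
#' with `sim` the cosine similarity, and the loss is the mean over all
#' `2N` ordered pairs. Cosine similarity makes the loss invariant to a
#' positive rescaling of any embedding.
#'
#' @param embeddings numeric matrix, `2N x d`, `2N >= 4`; no zero rows.
#' @param tau temperature parameter (default 0.5).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(embeddings, tau = 0.5) {
  embeddings <- as.matrix(embeddings)
  m <- nrow(embeddings)
  if (m < 4 || m %% 2 != 0) {
    abort("contrastive batch needs 2N >= 4 embeddings (pairs in consecutive rows)",
          class = "ft_validation_error")
  }
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm < 1e-12)) {
    abort("zero-norm embedding: cosine similarity undefined",
          class = "ft_validation_error")
  }
  u <- embeddings / nrm
  s <- u %*% t(u) / tau
  diag(s) <- -Inf
  partner <- ifelse(seq_len(m) %% 2 == 1, seq_len(m) + 1L, seq_len(m) - 1L)
  mx <- apply(s, 1, max)
  lse <- mx + log(rowSums(exp(s - mx)))
  mean(-(s[cbind(seq_len(m), partner)] - lse))
}
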