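# Decoupled contrastive objective: an intra-view term contrasting the
# online and target branches of each view, and an inter-view term
# contrasting decoder-projected embeddings against the destination view's
# target branch. Both are temperature-scaled softmax cross-entropies in
# which the AFNE weights modulate each negative's contribution to the
# normalizer. Gradients flow only through the first (online/projected)
# argument; the target branch is a constant.

#' Row-normalized similarity matrix
#'
#' `P[i, j] = exp(s(gamma_i, delta_j) / tau) / sum_l exp(s(gamma_i,
#' delta_l) / tau)` with cosine similarity `s`; every row sums to 1.
#'
#' @param gamma,delta numeric matrices with matching dimensions (B x d).
#' @param tau temperature, > 0 (default 0.5).
#' @param normalized are the inputs already row-L2-normalized?
#' @return A row-stochastic B x B matrix.
#' @export
rho <- function(gamma, delta, tau = 0.5, normalized = FALSE) {
  if (tau <= 0) stop("tau must be > 0")
  stopifnot(all(dim(gamma) == dim(delta)))
  if (!normalized) {
    gamma <- l2_normalize(gamma)$out
    delta <- l2_normalize(delta)$out
  }
  s <- tcrossprod(gamma, delta) / tau
  e <- exp(s - apply(s, 1L, max))      # row-wise shift for stability
  e / rowSums(e)
}

# Core weighted cross-entropy on normalized embeddings.
# loss = -(1/B) sum_i log[ exp(s_ii/tau) / sum_j Lambda_ij exp(s_ij/tau) ]
# with Lambda_ii = 1. Returns the loss and its gradient w.r.t. the
# normalized gamma (delta is a constant).
.wce_core <- function(Lambda, gamma_hat, delta_hat, tau, want_grad = FALSE) {
  B <- nrow(gamma_hat)
  s <- tcrossprod(gamma_hat, delta_hat) / tau
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  diag(Lambda) <- 1
  denom <- rowSums(Lambda * e)
  loss <- -mean(diag(s) - (log(denom) + m))
  if (!want_grad) return(list(loss = loss))
  P <- (Lambda * e) / denom
  dS <- -(diag(B) - P) / (B * tau)
  list(loss = loss, d_gamma_hat = dS %*% delta_hat)
}

#' Weighted contrastive cross-entropy
#'
#' Realizes the pseudo-target objective: one-hot positives on the
#' diagonal against a normalizer in which each negative pair's
#' exponential similarity is scaled by its adaptive weight. With all
#' weights 1 this is the standard temperature-normalized contrastive
#' (InfoNCE) loss; with flagged weights 0 it equals InfoNCE with those
#' pairs deleted from the normalizer (the hard-elimination limit).
#'
#' @param target a [pseudo_target()] (its `Lambda` attribute is used) or
#'   a plain B x B weight matrix.
#' @param gamma online / projected embeddings (B x d); the differentiated
#'   argument.
#' @param delta target-branch embeddings (B x d); a constant.
#' @param tau temperature (default 0.5).
#' @param normalized are the inputs already row-L2-normalized?
#' @return Scalar loss (mean over anchors).
#' @export
weighted_cross_entropy <- function(target, gamma, delta, tau = 0.5,
                                   normalized = FALSE) {
  Lambda <- attr(target, "Lambda") %||% unclass(target)
  stopifnot(all(dim(gamma) == dim(delta)),
            nrow(Lambda) == nrow(gamma), tau > 0)
  if (!normalized) {
    gamma <- l2_normalize(gamma)$out
    delta <- l2_normalize(delta)$out
  }
  .wce_core(Lambda, gamma, delta, tau)$loss
}

#' Intra-view contrastive loss
#'
#' Sum over views of the weighted cross-entropy between the view's online
#' and target embeddings under its pseudo-target.
#'
#' @param views list, one element per view, each a list with `f_a`,
#'   `f_b`, and `target` (a [pseudo_target()] or weight matrix).
#' @param tau temperature.
#' @return Scalar loss.
#' @export
intra_loss <- function(views, tau = 0.5) {
  sum(vapply(views, function(v)
    weighted_cross_entropy(v$target, v$f_a, v$f_b, tau), numeric(1)))
}

#' Inter-view contrastive loss
#'
#' Sum over ordered view pairs (v -> k), v != k, of the weighted
#' cross-entropy between the projected embedding Q(v -> k) and view k's
#' target embedding, under view k's pseudo-target.
#'
#' @param pairs list, one element per ordered pair, each a list with `q`
#'   (projected embedding), `f_b` (destination view target embedding) and
#'   `target` (destination view pseudo-target).
#' @param tau temperature.
#' @return Scalar loss; 0 for a single view (empty sum).
#' @export
inter_loss <- function(pairs, tau = 0.5) {
  if (length(pairs) == 0L) return(0)
  sum(vapply(pairs, function(p)
    weighted_cross_entropy(p$target, p$q, p$f_b, tau), numeric(1)))
}

#' Total decoupled contrastive loss
#'
#' @param intra,inter the two loss components.
#' @return List with `intra`, `inter`, `total = intra + inter`.
#' @export
total_loss <- function(intra, inter) {
  list(intra = intra, inter = inter, total = intra + inter)
}
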