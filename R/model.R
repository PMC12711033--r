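# View-specific Siamese encoders (online + EMA target) and cross-view
# decoders. The target branch is never optimized: it only moves through
# the exponential-moving-average update, and its outputs are treated as
# constants (stop-gradient) by every loss.

#' Create an online/target encoder pair for one view
#'
#' Both encoders share the four-layer fully connected architecture (three
#' hidden layers with batch normalization and ReLU, affine output); the
#' target starts as an exact copy of the online encoder and is
#' subsequently updated only by [ema_update()].
#'
#' @param input_dim number of input features of the view.
#' @param hidden_dims widths of the three hidden layers.
#' @param embed_dim embedding dimensionality.
#' @param xi EMA momentum in `[0, 1)`; larger means a slower target.
#' @return An `encoder_pair` (lists `online`, `target`, scalar `xi`).
#' @export
encoder_pair <- function(input_dim, hidden_dims = c(1024L, 512L, 256L),
                         embed_dim = 128L, xi = 0.99) {
  if (xi < 0 || xi >= 1) stop("xi must lie in [0, 1)")
  online <- nn_encoder(input_dim, hidden_dims, embed_dim)
  structure(list(online = online, target = online, xi = xi,
                 input_dim = input_dim, embed_dim = embed_dim),
            class = "encoder_pair")
}

#' Encode a mini-batch through both branches
#'
#' @param pair an [encoder_pair()].
#' @param x numeric matrix, batch rows by `input_dim` columns.
#' @param training use batch statistics in normalization layers (and
#'   update running statistics)? Feature extraction uses `FALSE`.
#' @return List with `f_a` (online embedding), `f_b` (target embedding,
#'   gradient-isolated by construction), forward caches for backprop, and
#'   the updated `pair`.
#' @export
encode <- function(pair, x, training = TRUE) {
  if (ncol(x) != pair$input_dim)
    stop("input has ", ncol(x), " columns, encoder expects ", pair$input_dim)
  fa <- nn_forward(pair$online, x, training = training)
  fb <- nn_forward(pair$target, x, training = training)
  pair$online <- fa$net
  pair$target <- fb$net
  list(f_a = fa$out, f_b = fb$out, cache_a = fa$cache, pair = pair)
}

#' Exponential moving average update of the target encoder
#'
#' `theta_b <- xi * theta_b + (1 - xi) * theta_a`, applied exactly once
#' per optimization step to every trainable tensor. Normalization running
#' statistics are maintained by the target's own forward passes.
#'
#' @param pair an [encoder_pair()].
#' @return The pair with an updated target branch.
#' @export
ema_update <- function(pair) {
  if (pair$xi < 0 || pair$xi >= 1) stop("xi must lie in [0, 1)")
  pa <- nn_params(pair$online)
  pb <- nn_params(pair$target)
  for (key in names(pa))
    pb[[key]] <- pair$xi * pb[[key]] + (1 - pair$xi) * pa[[key]]
  pair$target <- nn_set_params(pair$target, pb)
  pair
}

#' Create the full set of cross-view decoders
#'
#' One two-layer MLP per ordered view pair (v -> k), v != k, mapping
#' view v's embedding space into view k's.
#'
#' @param embed_dims integer vector of per-view embedding dims.
#' @param hidden_mult hidden width as a multiple of the target embed dim.
#' @return Named list of decoders keyed `"v->k"` (1-based view indices).
#' @export
decoder_set <- function(embed_dims, hidden_mult = 4L) {
  V <- length(embed_dims)
  out <- list()
  for (v in seq_len(V)) for (k in seq_len(V)) {
    if (v == k) next
    out[[paste0(v, "->", k)]] <-
      nn_decoder(embed_dims[v], embed_dims[k],
                 hidden = hidden_mult * embed_dims[k])
  }
  out
}

#' Project an embedding into another view's space
#'
#' @param decoders a [decoder_set()].
#' @param e embedding matrix (batch x embed_dim of view `from`).
#' @param from,to 1-based view indices, `from != to`.
#' @param training training-mode forward (kept for interface symmetry;
#'   decoders carry no normalization layers).
#' @return List with `q` (batch x embed_dim of view `to`), the forward
#'   cache, and the decoder key used.
#' @export
decode_cross_view <- function(decoders, e, from, to, training = TRUE) {
  if (from == to) stop("no self-decoder: from == to == ", from)
  key <- paste0(from, "->", to)
  dec <- decoders[[key]]
  if (is.null(dec)) stop("no decoder for view pair ", key)
  fwd <- nn_forward(dec, e, training = training)
  list(q = fwd$out, cache = fwd$cache, key = key)
}

#' Recover a missing view's representation from an observed view
#'
#' For a sample whose view `k` is unobserved, the target-branch embedding
#' of the lowest-index observed view `v` is pushed through the decoder
#' p(v -> k). The result is used wherever view k's embeddings are needed
#' and is treated as a constant (no gradient flows back through the
#' recovery path).
#'
#' @param decoders a [decoder_set()].
#' @param f_b_observed target embedding rows of the donor view.
#' @param from donor (observed) view index, `to` the missing view index.
#' @param to missing view index.
#' @return Matrix of recovered embeddings (rows match `f_b_observed`).
#' @export
recover_missing <- function(decoders, f_b_observed, from, to) {
  decode_cross_view(decoders, f_b_observed, from, to, training = FALSE)$q
}

# Lowest-index observed view per sample; errors if a sample has none.
donor_view <- function(obs_matrix) {
  # obs_matrix: samples x views logical
  don <- apply(obs_matrix, 1L, function(r) which(r)[1L])
  if (anyNA(don)) stop("sample(s) with no observed view")
  as.integer(don)
}
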