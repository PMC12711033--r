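# Adaptive false negative elimination (AFNE). Within a mini-batch,
# randomly drawn negatives that actually share the anchor's latent cluster
# (false negatives) are screened by relative similarity - an anchor's
# negative is suspicious when its similarity to the anchor nearly matches
# the anchor-positive similarity - and, instead of being discarded, are
# down-weighted adaptively in the contrastive normalizer.

#' Batch similarity profile from target-branch embeddings
#'
#' Computes the full pairwise cosine similarity matrix `S` among the
#' target embeddings of a batch, and the anchor-positive similarity
#' `s_pos[i]` between each sample's target embedding and its positive
#' counterpart: the same sample's online-branch embedding, taken as a
#' constant (stop-gradient).
#'
#' @param f_b target-branch embedding matrix (B x d), B >= 2.
#' @param f_a_hat online-branch embedding matrix of the same batch,
#'   used only to form the positive similarities (no gradient flows
#'   through this profile).
#' @param normalized are the inputs already row-L2-normalized?
#' @return A `similarity_profile`: list with `S` (B x B, diagonal 1) and
#'   `s_pos` (length B).
#' @export
similarity_profile <- function(f_b, f_a_hat, normalized = FALSE) {
  B <- nrow(f_b)
  if (B < 2L) stop("a batch of ", B, " has no negatives; need B >= 2")
  if (!normalized) {
    f_b <- l2_normalize(f_b)$out
    f_a_hat <- l2_normalize(f_a_hat)$out
  }
  S <- tcrossprod(f_b)
  s_pos <- rowSums(f_b * f_a_hat)
  structure(list(S = S, s_pos = s_pos, B = B), class = "similarity_profile")
}

#' Screen candidate false negatives by relative similarity
#'
#' Per anchor `i`, the relative similarity of negative `j` is
#' `R[i, j] = |s_pos[i] - S[i, j]|`. The candidate set is
#' `{ j != i : 0 < R[i, j] < t and R[i, j] among the k smallest of row i }`
#' - the threshold gives dynamic adjustment, the top-k cap bounds how many
#' candidates an anchor may flag. Exact ties on R are broken by ascending
#' sample index; `R == 0` exactly is excluded as unreliable.
#'
#' @param profile a [similarity_profile()].
#' @param t threshold on the relative similarity (default 0.7).
#' @param k maximum candidates per anchor (default 3).
#' @return A `fn_screen`: list with `R` (B x B), `fn_sets` (list of
#'   integer vectors), and the `t`, `k` used.
#' @export
screen_false_negatives <- function(profile, t = 0.7, k = 3L) {
  stopifnot(t > 0, k >= 1L)
  B <- profile$B
  R <- abs(outer(profile$s_pos, rep(1, B)) - profile$S)
  fn_sets <- vector("list", B)
  for (i in seq_len(B)) {
    r <- R[i, ]
    cand <- setdiff(which(r > 0 & r < t), i)
    if (length(cand) > k) {
      ord <- order(r[cand], cand)     # ties -> ascending sample index
      cand <- sort(cand[ord[seq_len(k)]])
    }
    fn_sets[[i]] <- cand
  }
  structure(list(R = R, fn_sets = fn_sets, t = t, k = as.integer(k)),
            class = "fn_screen")
}

#' Adaptive weights for screened candidates
#'
#' For a flagged candidate `m` of anchor `i`,
#' `alpha[i, m] = 1 - exp(S[i, m]) / sum_{j != i} exp(S[i, j])`
#' (plain exponentials, no temperature): the more similar a candidate is
#' to its anchor, the likelier it is a genuine false negative and the
#' smaller its weight. Unflagged negatives and the diagonal keep weight 1.
#'
#' @param profile a [similarity_profile()].
#' @param screen the matching [screen_false_negatives()] output.
#' @return A B x B weight matrix `Lambda` with unit diagonal.
#' @export
adaptive_weights <- function(profile, screen) {
  B <- profile$B
  E <- exp(profile$S)
  denom <- rowSums(E) - diag(E)        # sum over j != i
  Lambda <- matrix(1, B, B)
  for (i in seq_len(B)) {
    m <- screen$fn_sets[[i]]
    if (length(m)) Lambda[i, m] <- 1 - E[i, m] / denom[i]
  }
  Lambda
}

#' Pseudo-target matrix
#'
#' Elementwise product of the adaptive weights with the temperature-scaled
#' exponential similarity structure: off-diagonal entries are
#' `Lambda[i, j] * exp(S[i, j] / tau)`, the diagonal is
#' `exp(s_pos[i] / tau)`. Consumed by the contrastive losses as the
#' per-pair weighting of the normalizer.
#'
#' @param profile a [similarity_profile()].
#' @param Lambda weight matrix from [adaptive_weights()].
#' @param tau contrastive temperature (default 0.5).
#' @return A B x B matrix of class `pseudo_target` with attribute
#'   `"Lambda"`.
#' @export
pseudo_target <- function(profile, Lambda, tau = 0.5) {
  stopifnot(tau > 0)
  S_exp <- exp(profile$S / tau)
  diag(S_exp) <- exp(profile$s_pos / tau)
  T_mat <- Lambda * S_exp
  attr(T_mat, "Lambda") <- Lambda
  class(T_mat) <- c("pseudo_target", class(T_mat))
  T_mat
}

# One-call helper: profile -> screen -> weights -> target.
afne_batch <- function(f_b_hat, f_a_hat, t = 0.7, k = 3L, tau = 0.5,
                       mode = c("adaptive", "none", "eliminate")) {
  mode <- match.arg(mode)
  prof <- similarity_profile(f_b_hat, f_a_hat, normalized = TRUE)
  if (mode == "none") {
    Lambda <- matrix(1, prof$B, prof$B)
    screen <- NULL
  } else {
    screen <- screen_false_negatives(prof, t = t, k = k)
    if (mode == "eliminate") {
      Lambda <- matrix(1, prof$B, prof$B)
      for (i in seq_len(prof$B)) {
        m <- screen$fn_sets[[i]]
        if (length(m)) Lambda[i, m] <- 0
      }
    } else {
      Lambda <- adaptive_weights(prof, screen)
    }
  }
  list(profile = prof, screen = screen, Lambda = Lambda,
       n_candidates = if (is.null(screen)) 0L
                      else sum(lengths(screen$fn_sets)))
}
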