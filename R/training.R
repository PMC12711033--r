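# Training loop: mini-batch optimization of the online encoders and
# cross-view decoders by Adam under a linear learning-rate warmup, EMA
# updates of the target encoders, AFNE screening per view per batch, and
# final feature extraction in evaluation mode.

#' Training configuration
#'
#' Defaults follow the reference experimental protocol: 200 epochs, batch
#' size 256, 20 warmup epochs, temperature 0.5, screening threshold 0.7,
#' top-k 3. Architecture and optimizer settings are exposed because they
#' are not fixed by the protocol.
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size (>= 2).
#' @param warmup_epochs epochs of linear learning-rate ramp.
#' @param tau contrastive temperature.
#' @param fn_threshold relative-similarity screening threshold `t`.
#' @param top_k per-anchor cap on screened false-negative candidates.
#' @param xi EMA momentum of the target encoders.
#' @param base_lr Adam learning rate after warmup.
#' @param runs independent training runs; the run whose extracted
#'   features score the highest silhouette is kept.
#' @param seed integer seed; all stage seeds are derived from it.
#' @param hidden_dims encoder hidden-layer widths (three hidden layers).
#' @param embed_dim embedding dimensionality.
#' @param decoder_hidden_mult decoder hidden width as a multiple of the
#'   destination embedding dim.
#' @param target_mode `"soft_target"` (default) uses the row-normalized
#'   pseudo-target matrix as a soft target distribution for the
#'   cross-entropy — the pseudo-label rectification that pulls likely
#'   same-cluster pairs together; `"weighted_normalizer"` instead treats
#'   the adaptive weights as per-pair scalings of the contrastive
#'   normalizer (one-hot positives; its zero-weight limit is hard false
#'   negative elimination).
#' @param fn_mode `"adaptive"` (AFNE, default), `"none"` (no
#'   rectification), or `"eliminate"` (hard FNE: flagged pairs dropped).
#' @param use_decoder route the inter-view loss through cross-view
#'   decoders (`FALSE` reproduces the no-decoder ablation).
#' @param use_intra,use_inter include the respective loss terms.
#' @param shared_encoder replace the target encoder by the (gradient
#'   isolated) online encoder, removing the momentum update.
#' @param k_candidates candidate cluster numbers used when scoring runs.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L,
                         warmup_epochs = 20L, tau = 0.5,
                         fn_threshold = 0.7, top_k = 3L, xi = 0.99,
                         base_lr = 3e-4, runs = 5L, seed = 1L,
                         hidden_dims = c(1024L, 512L, 256L),
                         embed_dim = 128L, decoder_hidden_mult = 4L,
                         target_mode = c("soft_target", "weighted_normalizer"),
                         fn_mode = c("adaptive", "none", "eliminate"),
                         use_decoder = TRUE, use_intra = TRUE,
                         use_inter = TRUE, shared_encoder = FALSE,
                         k_candidates = 3:5) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              warmup_epochs = as.integer(warmup_epochs), tau = tau,
              fn_threshold = fn_threshold, top_k = as.integer(top_k),
              xi = xi, base_lr = base_lr, runs = as.integer(runs),
              seed = as.integer(seed), hidden_dims = as.integer(hidden_dims),
              embed_dim = as.integer(embed_dim),
              decoder_hidden_mult = as.integer(decoder_hidden_mult),
              target_mode = match.arg(target_mode),
              fn_mode = match.arg(fn_mode),
              use_decoder = isTRUE(use_decoder),
              use_intra = isTRUE(use_intra), use_inter = isTRUE(use_inter),
              shared_encoder = isTRUE(shared_encoder),
              k_candidates = as.integer(k_candidates))
  stopifnot(cfg$epochs >= 0L, cfg$batch_size >= 2L,
            cfg$warmup_epochs <= max(cfg$epochs, cfg$warmup_epochs),
            cfg$tau > 0, cfg$fn_threshold > 0, cfg$top_k >= 1L,
            cfg$xi >= 0, cfg$xi < 1, cfg$base_lr > 0, cfg$runs >= 1L,
            length(cfg$hidden_dims) == 3L, cfg$embed_dim >= 1L)
  class(cfg) <- "train_config"
  cfg
}

#' Linear learning-rate warmup schedule
#'
#' Ramps linearly from `base_lr / 100` at epoch 0 to `base_lr` at epoch
#' `warmup_epochs`, constant thereafter.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return The learning rate for that epoch.
#' @export
warmup_lr <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  frac <- if (cfg$warmup_epochs <= 0L) 1 else min(epoch / cfg$warmup_epochs, 1)
  cfg$base_lr * (0.01 + 0.99 * frac)
}

# Initialize the full model state for a dataset. Caller controls the RNG.
init_model <- function(ds, cfg) {
  V <- length(ds$views)
  pairs <- lapply(ds$views, function(v)
    encoder_pair(ncol(v$values), cfg$hidden_dims, cfg$embed_dim, cfg$xi))
  decoders <- if (V > 1L)
    decoder_set(rep(cfg$embed_dim, V), cfg$decoder_hidden_mult) else list()
  opt <- list(
    enc = lapply(pairs, function(p) adam_init(nn_params(p$online))),
    dec = lapply(decoders, function(d) adam_init(nn_params(d))))
  structure(list(pairs = pairs, decoders = decoders, opt = opt, cfg = cfg,
                 view_names = names(ds$views), epoch = 0L, step = 0L,
                 history = data.frame()),
            class = "dcmc_model")
}

#' @export
print.dcmc_model <- function(x, ...) {
  cat(sprintf("<dcmc_model> %d views, embed_dim %d, %d epochs trained\n",
              length(x$pairs), x$cfg$embed_dim, x$epoch))
  invisible(x)
}

# Soft-target variant of the weighted cross-entropy: the row-normalized
# pseudo-target is used as a target distribution against rho(gamma, delta).
.wce_soft <- function(T_mat, gamma_hat, delta_hat, tau, want_grad = FALSE) {
  B <- nrow(gamma_hat)
  Tn <- T_mat / rowSums(T_mat)
  s <- tcrossprod(gamma_hat, delta_hat) / tau
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  P <- e / rowSums(e)
  loss <- -sum(Tn * (s - (log(rowSums(e)) + m))) / B
  if (!want_grad) return(list(loss = loss))
  dS <- (P - Tn) / (B * tau)
  list(loss = loss, d_gamma_hat = dS %*% delta_hat)
}

# One optimization step on one mini-batch. Returns the updated model and
# the loss components.
train_step <- function(model, Xs, obs, lr) {
  cfg <- model$cfg
  V <- length(model$pairs)
  B <- nrow(obs)
  d <- cfg$embed_dim

  f_a <- f_b <- f_a_hat <- f_b_hat <- norm_a <- vector("list", V)
  cache_a <- obs_idx <- vector("list", V)

  for (v in seq_len(V)) {
    oi <- which(obs[, v])
    enc <- encode(model$pairs[[v]], Xs[[v]][oi, , drop = FALSE],
                  training = TRUE)
    model$pairs[[v]] <- enc$pair
    fa <- fb <- matrix(0, B, d)
    fa[oi, ] <- enc$f_a
    fb[oi, ] <- if (cfg$shared_encoder) enc$f_a else enc$f_b
    f_a[[v]] <- fa; f_b[[v]] <- fb
    cache_a[[v]] <- enc$cache_a
    obs_idx[[v]] <- oi
  }

  # Missing-view recovery: lowest-index observed view donates its target
  # embedding through the decoder; the result is a constant for gradients.
  if (V > 1L && any(!obs)) {
    don <- donor_view(obs)
    for (v in seq_len(V)) {
      mi <- which(!obs[, v])
      for (d0 in unique(don[mi])) {
        rows <- mi[don[mi] == d0]
        q <- recover_missing(model$decoders,
                             f_b[[d0]][rows, , drop = FALSE], d0, v)
        f_a[[v]][rows, ] <- q
        f_b[[v]][rows, ] <- q
      }
    }
  }

  for (v in seq_len(V)) {
    na <- l2_normalize(f_a[[v]])
    f_a_hat[[v]] <- na$out; norm_a[[v]] <- na$norm
    f_b_hat[[v]] <- l2_normalize(f_b[[v]])$out
  }

  # AFNE screening per view (target-branch embeddings, within view).
  af <- lapply(seq_len(V), function(v)
    afne_batch(f_b_hat[[v]], f_a_hat[[v]], t = cfg$fn_threshold,
               k = cfg$top_k, tau = cfg$tau, mode = cfg$fn_mode))
  n_fn <- sum(vapply(af, `[[`, 0L, "n_candidates"))

  wce <- function(v_target, gamma_hat, delta_hat, grad) {
    if (cfg$target_mode == "soft_target") {
      T_mat <- pseudo_target(af[[v_target]]$profile, af[[v_target]]$Lambda,
                             cfg$tau)
      .wce_soft(unclass(T_mat), gamma_hat, delta_hat, cfg$tau, grad)
    } else {
      .wce_core(af[[v_target]]$Lambda, gamma_hat, delta_hat, cfg$tau, grad)
    }
  }

  dFa_hat <- lapply(seq_len(V), function(v) matrix(0, B, d))
  dFa_raw <- lapply(seq_len(V), function(v) matrix(0, B, d))
  dec_grads <- list()
  intra <- inter <- 0

  if (cfg$use_intra) {
    for (v in seq_len(V)) {
      core <- wce(v, f_a_hat[[v]], f_b_hat[[v]], grad = TRUE)
      intra <- intra + core$loss
      dFa_hat[[v]] <- dFa_hat[[v]] + core$d_gamma_hat
    }
  }

  if (cfg$use_inter && V > 1L) {
    for (v in seq_len(V)) for (k in seq_len(V)) {
      if (v == k) next
      if (cfg$use_decoder) {
        dc <- decode_cross_view(model$decoders, f_a[[v]], v, k,
                                training = TRUE)
        qn <- l2_normalize(dc$q)
        core <- wce(k, qn$out, f_b_hat[[k]], grad = TRUE)
        inter <- inter + core$loss
        dq <- l2_normalize_backward(core$d_gamma_hat, qn$out, qn$norm)
        bk <- nn_backward(model$decoders[[dc$key]], dc$cache, dq)
        g <- nn_flat_grads(model$decoders[[dc$key]], bk$grads)
        if (is.null(dec_grads[[dc$key]])) {
          dec_grads[[dc$key]] <- g
        } else {
          for (nm in names(g))
            dec_grads[[dc$key]][[nm]] <- dec_grads[[dc$key]][[nm]] + g[[nm]]
        }
        dFa_raw[[v]] <- dFa_raw[[v]] + bk$dx
      } else {
        core <- wce(k, f_a_hat[[v]], f_b_hat[[k]], grad = TRUE)
        inter <- inter + core$loss
        dFa_hat[[v]] <- dFa_hat[[v]] + core$d_gamma_hat
      }
    }
  }

  # Backprop into the online encoders; recovered rows are constants, so
  # only observed rows carry gradient.
  for (v in seq_len(V)) {
    dRaw <- dFa_raw[[v]] +
      l2_normalize_backward(dFa_hat[[v]], f_a_hat[[v]], norm_a[[v]])
    oi <- obs_idx[[v]]
    bk <- nn_backward(model$pairs[[v]]$online, cache_a[[v]],
                      dRaw[oi, , drop = FALSE])
    flat <- nn_flat_grads(model$pairs[[v]]$online, bk$grads)
    params <- nn_params(model$pairs[[v]]$online)
    upd <- adam_step(params, flat, model$opt$enc[[v]], lr)
    model$opt$enc[[v]] <- upd$state
    model$pairs[[v]]$online <- nn_set_params(model$pairs[[v]]$online,
                                             upd$params)
  }
  for (key in names(dec_grads)) {
    params <- nn_params(model$decoders[[key]])
    upd <- adam_step(params, dec_grads[[key]], model$opt$dec[[key]], lr)
    model$opt$dec[[key]] <- upd$state
    model$decoders[[key]] <- nn_set_params(model$decoders[[key]],
                                           upd$params)
  }

  if (!cfg$shared_encoder)
    for (v in seq_len(V))
      model$pairs[[v]] <- ema_update(model$pairs[[v]])

  model$step <- model$step + 1L
  list(model = model, intra = intra, inter = inter,
       total = intra + inter, n_fn = n_fn)
}

#' Run one training epoch
#'
#' Shuffles the samples, splits them into mini-batches (a trailing batch
#' with fewer than 2 samples is dropped), and performs one optimization
#' step per batch: encode all views, recover missing views, screen false
#' negatives, assemble adaptive weights, evaluate the intra- and
#' inter-view losses, update the online encoders and decoders by Adam,
#' then apply the EMA update. Consumes the current RNG stream (callers
#' seed once per fit for reproducibility).
#'
#' @param model a `dcmc_model` from `init_model`/[dcmc_fit()].
#' @param ds the preprocessed `multi_omics` dataset.
#' @return The updated model with one row appended to `model$history`.
#' @export
train_epoch <- function(model, ds) {
  cfg <- model$cfg
  n <- length(ds$sample_ids)
  lr <- warmup_lr(model$epoch, cfg)
  perm <- sample.int(n)
  starts <- seq(1L, n, by = cfg$batch_size)
  obs_all <- vapply(ds$views, `[[`, logical(n), "observed")
  tot <- c(intra = 0, inter = 0, total = 0)
  n_fn <- 0L; n_batches <- 0L
  for (s in starts) {
    idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
    if (length(idx) < 2L) next
    Xs <- lapply(ds$views, function(v) v$values[idx, , drop = FALSE])
    step <- train_step(model, Xs, obs_all[idx, , drop = FALSE], lr)
    model <- step$model
    tot <- tot + c(step$intra, step$inter, step$total)
    n_fn <- n_fn + step$n_fn
    n_batches <- n_batches + 1L
  }
  model$epoch <- model$epoch + 1L
  model$history <- rbind(model$history, data.frame(
    epoch = model$epoch, lr = lr,
    intra = tot[["intra"]] / n_batches,
    inter = tot[["inter"]] / n_batches,
    total = tot[["total"]] / n_batches,
    n_fn_candidates = n_fn))
  model
}

# Expand a single-view dataset to two views by Gaussian augmentation so
# contrastive pairs exist across "views".
expand_single_view <- function(ds, seed) {
  if (length(ds$views) > 1L) return(ds)
  aug <- gaussian_augment(ds$views[[1L]], seed = derive_seed(seed, "augment"))
  ds$views[[aug$name]] <- aug
  ds
}

#' Fit the decoupled contrastive multi-view model
#'
#' Trains `cfg$runs` independent models under derived seeds and keeps the
#' one whose extracted features achieve the highest silhouette width over
#' `cfg$k_candidates` K-means clusterings. A single-view dataset is first
#' expanded to two views by range-scaled Gaussian augmentation.
#'
#' @param ds a preprocessed `multi_omics` dataset (>= 2 samples).
#' @param cfg a [train_config()].
#' @return The selected `dcmc_model` (with `$run_scores` attached when
#'   `runs > 1`).
#' @export
dcmc_fit <- function(ds, cfg = train_config()) {
  stopifnot(inherits(ds, "multi_omics"))
  if (length(ds$views) == 0L) stop("dataset has no views")
  if (length(ds$sample_ids) < 2L) stop("need at least 2 samples")
  ds <- expand_single_view(ds, cfg$seed)

  one_run <- function(run_seed) {
    with_seed(derive_seed(run_seed, "init"), {
      model <- init_model(ds, cfg)
      for (e in seq_len(cfg$epochs)) model <- train_epoch(model, ds)
      model
    })
  }

  if (cfg$runs == 1L) return(one_run(cfg$seed))

  best <- NULL; best_score <- -Inf; scores <- numeric(cfg$runs)
  for (r in seq_len(cfg$runs)) {
    model <- one_run(derive_seed(cfg$seed, paste0("run", r)))
    feats <- extract_features(model, ds)
    scores[r] <- max(vapply(cfg$k_candidates, function(k) {
      if (k > nrow(feats)) return(-Inf)
      lab <- kmeans_assign(feats, k, seed = derive_seed(cfg$seed, "runsel"))
      silhouette_width(feats, lab)
    }, numeric(1)))
    if (scores[r] > best_score) { best <- model; best_score <- scores[r] }
  }
  best$run_scores <- scores
  best
}

#' Extract per-sample features from a trained model
#'
#' Evaluation-mode full-data pass: each view's target-encoder embedding
#' (online encoder when `shared_encoder`) is computed for observed
#' samples; an unobserved view's block is recovered through the decoder
#' from the lowest-index observed view. Blocks are concatenated across
#' views.
#'
#' @param model a trained `dcmc_model`.
#' @param ds the dataset it was trained on (or a compatible one).
#' @return Numeric matrix, N x (V * embed_dim), rownames = sample IDs.
#' @export
extract_features <- function(model, ds) {
  ds <- expand_single_view(ds, model$cfg$seed)
  V <- length(model$pairs)
  stopifnot(length(ds$views) == V)
  n <- length(ds$sample_ids)
  d <- model$cfg$embed_dim
  obs <- vapply(ds$views, `[[`, logical(n), "observed")
  blocks <- vector("list", V)
  for (v in seq_len(V)) {
    net <- if (model$cfg$shared_encoder) model$pairs[[v]]$online
           else model$pairs[[v]]$target
    fb <- matrix(0, n, d)
    oi <- which(obs[, v])
    fb[oi, ] <- nn_forward(net, ds$views[[v]]$values[oi, , drop = FALSE],
                           training = FALSE)$out
    blocks[[v]] <- fb
  }
  if (V > 1L && any(!obs)) {
    don <- donor_view(obs)
    for (v in seq_len(V)) {
      mi <- which(!obs[, v])
      for (d0 in unique(don[mi])) {
        rows <- mi[don[mi] == d0]
        blocks[[v]][rows, ] <- recover_missing(
          model$decoders, blocks[[d0]][rows, , drop = FALSE], d0, v)
      }
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- ds$sample_ids
  out
}
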