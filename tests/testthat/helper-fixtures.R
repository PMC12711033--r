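# Shared fixtures: everything is generated in code at test time.

# A small multi-view dataset with known clusters, preprocessed and ready
# for training (values are synthetic Gaussians, so no log transform).
toy_dataset <- function(n = 120L, k = 3L, dims = c(30L, 25L, 20L),
                        separation = 8, seed = 2L, missing_rate = 0) {
  spec <- synthetic_spec(n_samples = n, n_clusters = k, view_dims = dims,
                         separation = separation,
                         missing_rate = missing_rate, seed = seed)
  sim <- generate_multiview(spec)
  list(spec = spec, sim = sim,
       ds = preprocess_dataset(sim$dataset, count_like = FALSE,
                               n_top = max(dims)))
}

# Desk-scale training configuration: sized so a 50-epoch fit on n = 400
# takes ~30 s on one core while the EMA window stays a small fraction of
# the total optimizer steps.
desk_config <- function(seed, epochs = 50L, runs = 1L, ...) {
  train_config(epochs = epochs, batch_size = 128L, warmup_epochs = 5L,
               runs = runs, seed = seed, base_lr = 1e-3, xi = 0.9,
               hidden_dims = c(256L, 128L, 64L), embed_dim = 32L, ...)
}

# Tiny config for fast structural tests.
tiny_config <- function(seed, epochs = 3L, ...) {
  train_config(epochs = epochs, batch_size = 64L, warmup_epochs = 1L,
               runs = 1L, seed = seed, base_lr = 1e-3, xi = 0.9,
               hidden_dims = c(16L, 12L, 8L), embed_dim = 4L, ...)
}

# Random L2-normalized embedding batch.
random_unit_rows <- function(B, d) {
  x <- matrix(rnorm(B * d), B, d)
  x / sqrt(rowSums(x^2))
}

# Write a small view matrix to a temp TSV and return the path.
write_temp_view <- function(values, ids, feats, sep = "\t",
                            ext = ".tsv") {
  path <- tempfile(fileext = ext)
  df <- data.frame(sample_id = ids, values, check.names = FALSE)
  colnames(df) <- c("sample_id", feats)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force oracles ------------------------------------

# Plain InfoNCE (one-hot targets, full normalizer), coded independently
# of the package: explicit per-anchor loops.
oracle_infonce <- function(gamma, delta, tau, drop = NULL) {
  gamma <- gamma / sqrt(rowSums(gamma^2))
  delta <- delta / sqrt(rowSums(delta^2))
  B <- nrow(gamma)
  total <- 0
  for (i in seq_len(B)) {
    num <- exp(sum(gamma[i, ] * delta[i, ]) / tau)
    den <- 0
    for (j in seq_len(B)) {
      if (!is.null(drop) && j %in% drop[[i]] && j != i) next
      den <- den + exp(sum(gamma[i, ] * delta[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / B
}

# Brute-force per-anchor false-negative screening.
oracle_screen <- function(S, s_pos, t, k) {
  B <- nrow(S)
  sets <- vector("list", B)
  for (i in seq_len(B)) {
    cand <- integer(0)
    for (j in seq_len(B)) {
      if (j == i) next
      r <- abs(s_pos[i] - S[i, j])
      if (r > 0 && r < t) cand <- c(cand, j)
    }
    if (length(cand) > k) {
      r <- abs(s_pos[i] - S[i, cand])
      cand <- cand[order(r, cand)][seq_len(k)]
    }
    sets[[i]] <- sort(cand)
  }
  sets
}

# Brute-force adaptive weights from the screening sets.
oracle_weights <- function(S, sets) {
  B <- nrow(S)
  L <- matrix(1, B, B)
  for (i in seq_len(B)) {
    den <- 0
    for (j in seq_len(B)) if (j != i) den <- den + exp(S[i, j])
    for (m in sets[[i]]) L[i, m] <- 1 - exp(S[i, m]) / den
  }
  L
}

# Two-group log-rank chi-square by explicit O-E tabulation over event
# times.
oracle_logrank2 <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1L]
  U <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Brute-force external metrics on small labelings.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  den <- (s11 + s10) * (s11 + s01) + (s01 + s00) * (s10 + s00)
  tot <- choose(n, 2)
  (tot * s11 - (s11 + s10) * (s11 + s01)) /
    (tot * (s11 + s10 + s11 + s01) / 2 - (s11 + s10) * (s11 + s01))
}

oracle_acc <- function(labels, truth) {
  ul <- unique(labels); ut <- unique(truth)
  k <- max(length(ul), length(ut))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  ut_pad <- c(ut, rep(NA, k - length(ut)))
  for (p in perms(seq_len(k))) {
    hit <- 0
    for (ci in seq_along(ul)) {
      tc <- ut_pad[p[ci]]
      if (!is.na(tc)) hit <- hit + sum(labels == ul[ci] & truth == tc)
    }
    best <- max(best, hit)
  }
  best / length(labels)
}

oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
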