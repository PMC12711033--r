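test_that("similarity_profile matches an explicit per-pair cosine loop", {
  set.seed(8)
  B <- 8; d <- 5
  fb <- matrix(rnorm(B * d), B, d)
  fa <- matrix(rnorm(B * d), B, d)
  prof <- similarity_profile(fb, fa)
  fbn <- fb / sqrt(rowSums(fb^2))
  fan <- fa / sqrt(rowSums(fa^2))
  for (i in 1:B) {
    for (j in 1:B)
      expect_equal(prof$S[i, j], sum(fbn[i, ] * fbn[j, ]), tolerance = 1e-12)
    expect_equal(prof$s_pos[i], sum(fbn[i, ] * fan[i, ]), tolerance = 1e-12)
  }
  expect_true(all(abs(prof$S) <= 1 + 1e-12))
  expect_lt(max(abs(prof$S - t(prof$S))), 1e-6)
  # degenerate geometry
  u <- matrix(rep(c(1, 0), each = 1), 1)
  same <- rbind(c(1, 0), c(1, 0))
  expect_equal(similarity_profile(same, same)$S[1, 2], 1)
  orth <- rbind(c(1, 0), c(0, 1))
  expect_equal(similarity_profile(orth, orth)$S[1, 2], 0)
  expect_error(similarity_profile(orth[1, , drop = FALSE],
                                  orth[1, , drop = FALSE]), "B >= 2")
})

test_that("relative-similarity screening applies threshold and top-k jointly", {
  # hand example: s_pos = 0.9, negative sims (0.85, 0.3, -0.2)
  S <- diag(4)
  S[1, 2:4] <- S[2:4, 1] <- c(0.85, 0.3, -0.2)
  prof <- structure(list(S = S, s_pos = c(0.9, 0.9, 0.9, 0.9), B = 4L),
                    class = "similarity_profile")
  # R row 1 = (0.05, 0.6, 1.1): threshold 0.7 keeps {2, 3}
  scr <- screen_false_negatives(prof, t = 0.7, k = 3)
  expect_equal(scr$fn_sets[[1]], c(2L, 3L))
  expect_equal(scr$R[1, 2:4], c(0.05, 0.6, 1.1))
  # top-1 of the same row keeps only the closest
  scr1 <- screen_false_negatives(prof, t = 0.7, k = 1)
  expect_equal(scr1$fn_sets[[1]], 2L)
  # all R >= t excludes everything
  scr0 <- screen_false_negatives(prof, t = 0.04, k = 3)
  expect_equal(scr0$fn_sets[[1]], integer(0))
  # R exactly 0 is excluded (strict inequality)
  S2 <- diag(3); S2[1, 2] <- S2[2, 1] <- 0.9; S2[1, 3] <- S2[3, 1] <- 0.5
  prof2 <- structure(list(S = S2, s_pos = c(0.9, 0.9, 0.9), B = 3L),
                     class = "similarity_profile")
  expect_equal(screen_false_negatives(prof2, 0.7, 3)$fn_sets[[1]], 3L)
})

test_that("adaptive weights follow the relative-abundance formula", {
  # B = 2: the single negative flagged -> alpha = 1 - e^s / e^s = 0
  S <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  prof <- structure(list(S = S, s_pos = c(0.5, 0.5), B = 2L),
                    class = "similarity_profile")
  scr <- screen_false_negatives(prof, t = 0.7, k = 3)
  expect_equal(scr$fn_sets[[1]], 2L)
  L <- adaptive_weights(prof, scr)
  expect_equal(L[1, 2], 0)
  expect_equal(diag(L), c(1, 1))
  # B = 3, both negatives equally similar, one flagged -> alpha = 0.5
  S3 <- diag(3); S3[1, 2] <- S3[2, 1] <- 0.6; S3[1, 3] <- S3[3, 1] <- 0.6
  prof3 <- structure(list(S = S3, s_pos = c(0.65, 0, 0), B = 3L),
                     class = "similarity_profile")
  scr3 <- screen_false_negatives(prof3, t = 0.2, k = 1)
  expect_equal(scr3$fn_sets[[1]], 2L)   # tie on R broken by lower index
  L3 <- adaptive_weights(prof3, scr3)
  expect_equal(L3[1, 2], 0.5)
  expect_equal(L3[1, 3], 1)   # outside the set keeps full weight
})

test_that("weights decrease strictly as a flagged candidate's similarity rises", {
  base <- diag(4)
  base[1, 2:4] <- base[2:4, 1] <- c(0.5, 0.2, 0.1)
  alphas <- vapply(seq(0.3, 0.9, by = 0.1), function(s) {
    S <- base; S[1, 2] <- S[2, 1] <- s
    prof <- structure(list(S = S, s_pos = rep(s + 0.05, 4), B = 4L),
                      class = "similarity_profile")
    scr <- structure(list(R = abs(outer(prof$s_pos, rep(1, 4)) - S),
                          fn_sets = list(2L, integer(0), integer(0),
                                         integer(0)), t = 1, k = 1L),
                     class = "fn_screen")
    adaptive_weights(prof, scr)[1, 2]
  }, numeric(1))
  expect_true(all(diff(alphas) < 0))
  expect_true(all(alphas > 0 & alphas < 1))
})

test_that("pseudo-target is the elementwise product of weights and similarities", {
  set.seed(9)
  B <- 6
  fb <- random_unit_rows(B, 4)
  fa <- random_unit_rows(B, 4)
  prof <- similarity_profile(fb, fa, normalized = TRUE)
  scr <- screen_false_negatives(prof, 0.7, 3)
  L <- adaptive_weights(prof, scr)
  T_mat <- pseudo_target(prof, L, tau = 0.5)
  for (i in 1:B) for (j in 1:B) {
    want <- if (i == j) exp(prof$s_pos[i] / 0.5)
            else L[i, j] * exp(prof$S[i, j] / 0.5)
    expect_equal(unclass(T_mat)[i, j], want, tolerance = 1e-12)
  }
  # Lambda = 1 -> plain exponential similarities (unrectified target)
  L1 <- matrix(1, B, B)
  T1 <- pseudo_target(prof, L1, 0.5)
  off <- row(T1) != col(T1)
  expect_equal(unclass(T1)[off], exp(prof$S / 0.5)[off], tolerance = 1e-12)
  # zero weight eliminates the pair entirely
  L0 <- L1; L0[1, 2] <- 0
  expect_equal(unclass(pseudo_target(prof, L0, 0.5))[1, 2], 0)
})

test_that("self-pairs are never screened or down-weighted", {
  set.seed(10)
  for (rep in 1:20) {
    B <- sample(2:12, 1)
    prof <- similarity_profile(random_unit_rows(B, 6),
                               random_unit_rows(B, 6), normalized = TRUE)
    scr <- screen_false_negatives(prof, 0.7, 3)
    for (i in 1:B) expect_false(i %in% scr$fn_sets[[i]])
    L <- adaptive_weights(prof, scr)
    expect_equal(diag(L), rep(1, B))
  }
})
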