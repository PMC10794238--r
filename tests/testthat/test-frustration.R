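test_that("sampled frustration agrees with exhaustive enumeration", {
  em <- mj_energy_model()
  toy <- make_toy_structure(20, seed = 3)
  set.seed(31)
  seq <- sample(AA, 20, replace = TRUE)
  w <- tabulate(match(seq, AA), 20) / 20   # native composition

  positions <- unique(c(toy$cmap$contacts$i, toy$cmap$contacts$j))
  for (pos in positions) {
    nb <- c(toy$cmap$contacts$j[toy$cmap$contacts$i == pos],
            toy$cmap$contacts$i[toy$cmap$contacts$j == pos])
    # closed-form mean and sd over the composition distribution
    cand <- vapply(AA, function(a) sum(em$table[a, seq[nb]]), 0)
    mu <- sum(w * cand)
    sdv <- sqrt(sum(w * (cand - mu)^2))
    EN <- sum(em$table[seq[pos], seq[nb]])
    exact <- (mu - EN) / sdv
    # Monte-Carlo standard error of the Z-score estimated from 200
    # replicate estimates drawn from the exact candidate distribution
    mc_se <- local({
      set.seed(1000 + pos)
      reps <- vapply(1:200, function(b) {
        eu <- sample(cand, 1000, replace = TRUE, prob = w)
        (mean(eu) - EN) / sqrt(mean((eu - mean(eu))^2))
      }, 0)
      sd(reps)
    })
    Fi <- frustration_index(seq, pos, toy$cmap, em, n_decoys = 1000,
                            seed = 100 + pos)
    expect_lt(abs(as.numeric(Fi) - exact), 3 * mc_se)
    # deterministic given seed
    Fi2 <- frustration_index(seq, pos, toy$cmap, em, n_decoys = 1000,
                             seed = 100 + pos)
    expect_identical(as.numeric(Fi), as.numeric(Fi2))
  }
})

test_that("degenerate and contact-free positions raise errors", {
  em <- diag_energy_model(0)   # all energies 0 -> zero variance
  cm <- cmap_from_pairs(rbind(c(1, 3), c(1, 4)), 4)
  expect_error(frustration_index("AAAA", 1, cm, em, seed = 1),
               "degenerate-decoy")
  expect_error(frustration_index("AAAA", 2, cm, mj_energy_model(),
                                 seed = 1), "no-contact")
})

test_that("frustration is invariant to a uniform energy-table shift", {
  em <- mj_energy_model()
  em_shift <- em
  em_shift$table <- em$table + 3.7
  toy <- make_toy_structure(16, seed = 5)
  set.seed(12)
  seq <- sample(AA, 16, replace = TRUE)
  pos <- toy$cmap$contacts$i[1]
  f1 <- frustration_index(seq, pos, toy$cmap, em, seed = 9)
  f2 <- frustration_index(seq, pos, toy$cmap, em_shift, seed = 9)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-12)
})

test_that("ensemble profiles average per position and respect duplication", {
  em <- mj_energy_model()
  toy <- make_toy_structure(14, seed = 7)
  set.seed(4)
  seqs <- matrix(sample(AA, 10 * 14, replace = TRUE), 10, 14)
  prof <- ensemble_frustration_profile(seqs, toy$cmap, em,
                                       n_decoys = 200, seed = 2)
  # oracle: recompute each sequence (stream restarted per sequence) and
  # average
  oracle <- local({
    ct <- table(factor(c(toy$cmap$contacts$i, toy$cmap$contacts$j),
                       levels = 1:14))
    positions <- which(as.integer(ct) > 0)
    Fm <- matrix(NA_real_, 10, length(positions))
    for (r in 1:10) {
      set.seed(2)
      for (k in seq_along(positions))
        Fm[r, k] <- as.numeric(frustration_index(
          seqs[r, ], positions[k], toy$cmap, em, 200, seed = NULL))
    }
    colMeans(Fm)
  })
  expect_equal(prof$F, oracle)

  # single sequence equals its own profile; duplication leaves it unchanged
  p1 <- ensemble_frustration_profile(seqs[1, , drop = FALSE], toy$cmap,
                                     em, n_decoys = 200, seed = 5)
  p2 <- ensemble_frustration_profile(seqs[c(1, 1, 1), ], toy$cmap, em,
                                     n_decoys = 200, seed = 5)
  expect_identical(p1$F, p2$F)
  expect_equal(p1$n, rep(1L, length(p1$n)))
})

test_that("frustration deltas classify by sign above the threshold", {
  mk <- function(F) structure(data.frame(position = 1:3, F = F, n = 5L),
                              class = c("frustration_profile",
                                        "data.frame"))
  d0 <- frustration_delta(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_length(d0$less_frustrated, 0L)
  expect_length(d0$more_frustrated, 0L)
  d <- frustration_delta(mk(c(0, 0, 0)), mk(c(0.8, -0.9, 0.1)))
  expect_equal(d$less_frustrated, 1L)
  expect_equal(d$more_frustrated, 2L)
  expect_error(frustration_delta(mk(1:3),
                                 structure(data.frame(position = 2:4,
                                                      F = 1:3, n = 1L),
                                           class = c("frustration_profile",
                                                     "data.frame"))),
               "alignment error")
})

test_that("profile correlation matches the textbook formula", {
  mk <- function(F) structure(data.frame(position = seq_along(F), F = F,
                                         n = 1L),
                              class = c("frustration_profile",
                                        "data.frame"))
  x <- c(0.3, -1.2, 0.8, 2.0, -0.5)
  expect_equal(profile_correlation(mk(x), mk(x))$r, 1)
  expect_equal(profile_correlation(mk(x), mk(-x))$r, -1)
  y <- c(1.1, 0.2, -0.4, 1.5, 0.3)
  naive_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc <- profile_correlation(mk(x), mk(y))
  expect_equal(pc$r, naive_r)
  expect_equal(pc$p_value, cor.test(x, y)$p.value)
  expect_error(profile_correlation(mk(rep(1, 5)), mk(y)),
               "undefined-correlation")
})
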