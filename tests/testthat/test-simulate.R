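test_that("make_default_pwms: determinism, separation, sharpness limit", {
  p1 <- make_default_pwms(C = 2, m = 8, sharpness = 4, seed = 7)
  p2 <- make_default_pwms(C = 2, m = 8, sharpness = 4, seed = 7)
  expect_identical(p1, p2)
  for (p in p1) expect_equal(rowSums(p$probs), rep(1, 8), tolerance = 1e-9)

  # pairwise consensus Hamming distance >= m/2
  cons <- vapply(make_default_pwms(4, m = 8, seed = 3), pwm_consensus, "")
  for (a in 1:3) for (b in (a + 1):4) {
    d <- sum(strsplit(cons[a], "")[[1]] != strsplit(cons[b], "")[[1]])
    expect_gte(d, 4)
  }

  # high-sharpness limit approaches one-hot rows
  sharp <- make_default_pwms(1, m = 6, sharpness = 30, seed = 1)[[1]]
  expect_equal(max(sharp$probs), 1, tolerance = 1e-9)
  expect_gte(pwm_information(sharp), 2 - 1e-6)
})

test_that("information content grows monotonically with sharpness", {
  ic <- vapply(c(0, 0.5, 1, 2, 4, 8), function(s) {
    pwm_information(make_default_pwms(1, m = 8, sharpness = s, seed = 2)[[1]])
  }, numeric(1))
  expect_true(all(diff(ic) > 0))
  expect_equal(ic[1], 0, tolerance = 1e-12)   # sharpness 0 = uniform
})

test_that("simulate_dataset embeds consensus motifs exactly where labelled", {
  pwms <- make_default_pwms(C = 3, m = 6, sharpness = 30, seed = 5)
  sim <- simulate_dataset(sim_config(n = 60, length = 50, pwms = pwms,
                                     prevalence = 0.4, seed = 5))
  cons <- vapply(pwms, pwm_consensus, "")
  y <- sim$labels$values
  for (i in seq_len(60)) {
    for (cl in which(y[i, ] == 1)) {
      expect_true(grepl(cons[cl], sim$sequences[i], fixed = TRUE),
                  label = sprintf("consensus of class %d in sequence %d", cl, i))
    }
  }
  # bitwise determinism
  sim2 <- simulate_dataset(sim_config(n = 60, length = 50, pwms = pwms,
                                      prevalence = 0.4, seed = 5))
  expect_identical(sim2$sequences, sim$sequences)
  expect_identical(sim2$labels$values, sim$labels$values)
})

test_that("per-class prevalence sits inside a 99% binomial interval", {
  pwms <- make_default_pwms(C = 3, m = 8, sharpness = 6, seed = 9)
  sim <- simulate_dataset(sim_config(n = 5000, length = 100, pwms = pwms,
                                     prevalence = 0.3, seed = 9))
  ci <- qbinom(c(0.005, 0.995), 5000, 0.3) / 5000
  frac <- colMeans(sim$labels$values)
  expect_true(all(frac >= ci[1] & frac <= ci[2]))
})

test_that("background composition tracks the configured distribution", {
  pwms <- make_default_pwms(C = 1, m = 4, sharpness = 8, seed = 4)
  bg <- c(0.4, 0.1, 0.1, 0.4)
  sim <- simulate_dataset(sim_config(n = 200, length = 60, pwms = pwms,
                                     prevalence = 0.05, background = bg, seed = 4))
  counts <- table(factor(unlist(strsplit(paste(sim$sequences, collapse = ""), "")),
                         levels = c("A", "C", "G", "T")))
  obs <- as.numeric(counts) / sum(counts)
  expect_equal(obs, bg, tolerance = 0.03)   # motifs perturb composition slightly
})

test_that("impossible placements error with guidance; revcomp flag flips instances", {
  pwms <- make_default_pwms(C = 1, m = 8, sharpness = 30, seed = 2)
  cfg <- sim_config(n = 20, length = 17, pwms = pwms, prevalence = 0.9,
                    embed_per_positive = 3, seed = 2)
  expect_error(simulate_dataset(cfg), "increase the sequence length")

  cons <- pwm_consensus(pwms[[1]])
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", cons), "")[[1]]), collapse = "")
  simr <- simulate_dataset(sim_config(n = 120, length = 40, pwms = pwms,
                                      prevalence = 0.6, revcomp = TRUE, seed = 3))
  pos <- simr$sequences[simr$labels$values[, 1] == 1]
  fwd_hit <- grepl(cons, pos, fixed = TRUE)
  rc_hit <- grepl(rc, pos, fixed = TRUE)
  expect_true(all(fwd_hit | rc_hit))
  expect_true(any(fwd_hit) && any(rc_hit))
})

test_that("as_cac_dataset encodes and splits consistently", {
  ds <- tiny_dataset(n = 25, L = 15, seed = 6)
  expect_identical(dim(ds$x), c(15L, 4L, 25L))
  expect_true(all(apply(ds$x, 3, rowSums) == 1))
  expect_length(ds$split$train_idx, floor(0.75 * 25 + 0.5))
  # labels exactly match the recorded simulation
  expect_identical(sort(c(ds$split$train_idx, ds$split$val_idx)), 1:25)
})

test_that("seed is mandatory and configs validate", {
  pwms <- make_default_pwms(C = 1, m = 4, seed = 1)
  expect_error(sim_config(n = 10, length = 20, pwms = pwms), "seed")
  expect_error(sim_config(n = 10, length = 3, pwms = pwms, seed = 1), "longest motif")
  expect_error(sim_config(n = 10, length = 20, pwms = pwms, prevalence = 1.2, seed = 1),
               "prevalence")
  expect_error(pwm(matrix(0.3, 4, 4)), "summing to 1")
})
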