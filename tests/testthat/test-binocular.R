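test_that("RMI matches its normalized-difference definition", {
  w <- c(0, 1)
  equal <- rmi(tensor_with_auc(2), tensor_with_auc(2), w)
  expect_equal(equal$rmi, 0)
  r <- rmi(tensor_with_auc(3), tensor_with_auc(1), w)
  expect_equal(r$rmi, 0.5) # (3 - 1) / (3 + 1)
  expect_equal(r$auc_both, 3)
  expect_equal(r$auc_contra, 1)
  # both AUCs zero -> undefined
  zero <- rmi(tensor_with_auc(0), tensor_with_auc(0), w)
  expect_true(is.na(zero$rmi))
})

test_that("RMI is antisymmetric and scale-invariant", {
  set.seed(22)
  a <- as_tensor(matrix(abs(rnorm(40, 1)), 10, 4))
  b <- as_tensor(matrix(abs(rnorm(40, 0.6)), 10, 4))
  w <- c(0, 1)
  expect_equal(rmi(a, b, w)$rmi, -rmi(b, a, w)$rmi)
  a5 <- a * 5; attr(a5, "time") <- attr(a, "time")
  b5 <- b * 5; attr(b5, "time") <- attr(b, "time")
  expect_equal(rmi(a5, b5, w)$rmi, rmi(a, b, w)$rmi, tolerance = 1e-12)
})

test_that("summation class separates linear from supralinear responses", {
  set.seed(23)
  base <- abs(rnorm(10, 1, 0.05))
  mk <- function(scale, jitter = 0.01) {
    as_tensor(replicate(6, scale * base + rnorm(10, 0, jitter)))
  }
  w <- c(0, 1)
  lin <- summation_class(mk(2, 0), mk(1, 0), mk(1, 0), w, seed = 1)
  expect_equal(lin$class, "LINEAR")
  supra <- summation_class(mk(3), mk(1), mk(1), w, seed = 1)
  expect_equal(supra$class, "SUPRALINEAR")
  sub <- summation_class(mk(1), mk(1), mk(1), w, seed = 1)
  expect_equal(sub$class, "SUBLINEAR")
})

test_that("covariance SNR matches hand-built cases and the closed form", {
  # identical trials: zero noise -> capped
  m <- cbind(1:5, 1:5, 1:5)
  r <- snr_covariance(m)
  expect_true(r$clamped)
  expect_equal(r$snr, Inf)
  expect_equal(r$v_noise, 0)
  # iid noise: signal variance ~ 0, SNR ~ 0
  set.seed(24)
  vals <- replicate(30, snr_covariance(matrix(rnorm(200), 50, 4))$snr)
  expect_lt(median(vals), 0.15)
  # 2 trials of [1,2,3] + noise: SNR ~ Var([1,2,3]) / sigma^2
  sigma <- 0.05
  est <- replicate(200, {
    m2 <- cbind(1:3, 1:3) + matrix(rnorm(6, 0, sigma), 3, 2)
    snr_covariance(m2)$v_signal
  })
  expect_equal(mean(est), var(1:3), tolerance = 0.05)
  expect_error(snr_covariance(matrix(1:5, 5, 1)), ">= 2 trials")
})

test_that("SNR improvement reports the summation landmark flags", {
  mk_res <- function(snr) {
    structure(list(v_signal = 1, v_noise = 1 / snr, snr = snr,
                   n_trials = 5, variant = "COVARIANCE", clamped = FALSE),
              class = "snr_result")
  }
  eq <- snr_improvement(mk_res(2), mk_res(2))
  expect_equal(eq$ratio, 1)
  expect_false(eq$above_sqrt2)
  r <- snr_improvement(mk_res(2.82), mk_res(2))
  expect_equal(r$ratio, 1.41, tolerance = 1e-9)
  expect_false(r$above_sqrt2) # 1.41 < sqrt(2) = 1.4142
  r2 <- snr_improvement(mk_res(2 * sqrt(2)), mk_res(2))
  expect_true(r2$above_sqrt2)
  expect_true(snr_improvement(mk_res(4.2), mk_res(2))$above_2)
  expect_error(snr_improvement(mk_res(0), mk_res(0)), "denominator")
})

test_that("peak-wise SNR equals brute-force window statistics", {
  fr <- 10
  tt <- (0:99) / fr
  tr <- numeric(100)
  tr[tt >= 4 & tt < 5] <- 2                    # peak of mean 2
  tr[tt < 2] <- rep(c(-0.5, 0.5), 10)          # noise window, SD 0.5
  m <- as_tensor(cbind(tr, tr), frame_rate = fr)
  res <- snr_peakwise(m, list(c(4, 5)), c(0, 2))
  expect_equal(res$mu_signal, 2)
  expect_equal(res$sigma_noise, sd(tr[tt < 2])) # 0.5 up to n-1 correction
  expect_equal(res$snr, res$mu_signal / res$sigma_noise)
  # flat dF/F trace -> 0
  flat <- as_tensor(matrix(0, 100, 2), frame_rate = fr)
  expect_equal(snr_peakwise(flat, list(c(4, 5)), c(0, 2))$snr, 0)
  # random tensors against direct recomputation
  set.seed(25)
  rnd <- as_tensor(matrix(rnorm(300), 100, 3), frame_rate = fr)
  out <- snr_peakwise(rnd, list(c(3, 4), c(6, 8)), c(0, 2))
  mu1 <- mean(rowMeans(rnd)[tt >= 3 & tt < 4])
  sg <- sd(rowMeans(rnd)[tt < 2])
  expect_equal(out$snr[1], mu1 / sg)
  expect_error(snr_peakwise(rnd, list(c(1, 3)), c(0, 2)), "overlap")
})

test_that("top-responder selection keeps the requested fraction", {
  v <- c(5, 1, 9, 3, 7)
  expect_equal(sort(top_responders(v, 0.4)), c(3L, 5L))
  expect_equal(top_responders(v, 1), order(v, decreasing = TRUE))
})

test_that("shuffle-null flags planted facilitation but not zeros", {
  set.seed(26)
  tt <- 30; n_tr <- 6; n_b <- 20
  shape <- exp(-((1:tt) - 10)^2 / 20)
  mk_arr <- function(gain) {
    arr <- array(rnorm(tt * n_tr * n_b, 0, 0.05), c(tt, n_tr, n_b))
    for (b in seq_len(n_b)) arr[, , b] <- arr[, , b] + gain * shape
    arr
  }
  time <- (1:tt) / 10
  res <- rmi_significance(mk_arr(1.5), mk_arr(1), time, c(0.5, 2.5),
                          n_shuffles = 300, seed = 1)
  expect_gte(mean(res$facilitated), 0.9)
  # all-zero tensors: nothing can be flagged
  zero <- array(0, c(tt, n_tr, 3))
  res0 <- rmi_significance(zero, zero, time, c(0.5, 2.5),
                           n_shuffles = 50, seed = 1)
  expect_false(any(res0$facilitated))
  expect_error(rmi_significance(mk_arr(1)[, 1, , drop = FALSE],
                                mk_arr(1), time, c(0.5, 2.5)),
               "2 trials")
})
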