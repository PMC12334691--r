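# Small helper: trial tensor set with one known mean trace per bouton.
set_from_means <- function(means, condition = "CONTRA", n_trials = 3) {
  arr <- array(NA_real_, dim = c(ncol(means), n_trials, nrow(means)))
  for (b in seq_len(nrow(means))) {
    arr[, , b] <- matrix(means[b, ], ncol(means), n_trials)
  }
  structure(list(tensors = setNames(list(arr), condition),
                 time = (seq_len(ncol(means)) - 1) / 10, frame_rate = 10,
                 n_boutons = nrow(means), stim_duration_s = 3,
                 excluded = data.frame()),
            class = "trial_tensor_set")
}

test_that("signatures concatenate trial means in a canonical stimulus order", {
  m1 <- rbind(sin(1:20), cos(1:20))
  m2 <- rbind(1:30, 30:1) / 10
  s1 <- set_from_means(m1)
  s2 <- set_from_means(m2)
  # single stimulus: signature is its (smoothed) trial mean
  sig_single <- build_signature(list(flash = s1), "CONTRA",
                                smooth_window = 1L)
  expect_equal(sig_single, m1)
  # two stimuli: lengths add, and input list order does not matter
  sig_ab <- build_signature(list(a = s1, b = s2), "CONTRA")
  sig_ba <- build_signature(list(b = s2, a = s1), "CONTRA")
  expect_equal(dim(sig_ab), c(2, 50))
  expect_identical(sig_ab, sig_ba)
  expect_error(build_signature(list(a = s1), "IPSI"), "missing")
})

test_that("z-normalization uses sample SD and drops constant rows", {
  # row [0, 2]: mean 1, sample SD sqrt(2) -> +/- 0.7071
  z <- znorm(rbind(c(0, 2)))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2))
  # affine-transformed rows normalize identically
  x <- matrix(rnorm(40), 4)
  expect_equal(znorm(5 * x + 2), znorm(x), tolerance = 1e-12)
  expect_equal(unname(rowMeans(znorm(x))), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(znorm(x), 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_warning(zc <- znorm(rbind(x[1, ], rep(3, 10))), "constant")
  expect_equal(nrow(zc), 1)
  expect_equal(attr(zc, "excluded"), 2L)
})

test_that("embedding and clustering separate two synthetic kernels", {
  set.seed(13)
  t_axis <- seq(0, 5, by = 0.1)
  k1 <- exp(-(t_axis - 1)^2 / 0.2)
  k2 <- exp(-(t_axis - 3.5)^2 / 0.4)
  sig <- rbind(
    t(replicate(20, k1 + rnorm(length(t_axis), 0, 0.1))),
    t(replicate(20, k2 + rnorm(length(t_axis), 0, 0.1)))
  )
  truth <- rep(1:2, each = 20)
  for (algo in c("KMEANS", "GMM")) {
    res <- embed_and_cluster(znorm(sig), k = 2, algo = algo, seed = 1)
    tab <- table(res$labels, truth)
    purity <- sum(apply(tab, 2, max)) / sum(tab)
    expect_gte(purity, 0.95)
  }
  # determinism under a fixed seed
  r1 <- embed_and_cluster(znorm(sig), k = 2, seed = 7)
  r2 <- embed_and_cluster(znorm(sig), k = 2, seed = 7)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$embedding, r2$embedding)
  # degenerate cases
  expect_equal(embed_and_cluster(sig, k = 1, seed = 1)$labels,
               rep(1L, nrow(sig)))
  expect_error(embed_and_cluster(sig[1:3, ], k = 5), "fewer signatures")
})

test_that("UMAP embedding path separates the same kernels", {
  skip_if_not_installed("uwot")
  set.seed(14)
  t_axis <- seq(0, 5, by = 0.1)
  k1 <- exp(-(t_axis - 1)^2 / 0.2)
  k2 <- exp(-(t_axis - 3.5)^2 / 0.4)
  sig <- rbind(
    t(replicate(15, k1 + rnorm(length(t_axis), 0, 0.1))),
    t(replicate(15, k2 + rnorm(length(t_axis), 0, 0.1)))
  )
  res <- embed_and_cluster(znorm(sig), k = 2, method = "UMAP", seed = 3)
  tab <- table(res$labels, rep(1:2, each = 15))
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
})

test_that("chirp-driven simulation recovers the five planted RGC types", {
  proto <- make_protocol("CHIRP", conditions = "CONTRA", n_rep = 4,
                         iti_s = 6, seed = 15)
  pupil <- simulate_pupil(proto, seed = 16)
  traces <- simulate_boutons(proto, pupil, axons_per_type = 8, seed = 17)
  set <- process_traces(traces,
                        window_s = c(-2, proto$stim_duration_s + 2))
  sig <- znorm(build_signature(list(chirp = set), "CONTRA"))
  res <- embed_and_cluster(sig, k = 5, seed = 18)
  truth <- traces$meta$type[setdiff(seq_len(nrow(traces$meta)),
                                    attr(sig, "excluded"))]
  tab <- table(res$labels, truth)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.9)
  # each recovered cluster is polarity-pure
  pol <- traces$meta$polarity[setdiff(seq_len(nrow(traces$meta)),
                                      attr(sig, "excluded"))]
  pol_purity <- sum(apply(table(res$labels, pol), 1, max)) /
    length(res$labels)
  expect_gte(pol_purity, 0.95)
})

test_that("peak timing lands in the correct PLR phase", {
  kin <- structure(list(onset_latency_s = 0.51, time_to_peak_s = 1.74,
                        valid = TRUE), class = "plr_kinetics")
  # OFF bouton driven by consensual constriction peaks inside the PLR
  proto <- make_protocol("FLASH", level = 65, conditions = "IPSI",
                         n_rep = 3, seed = 19)
  pupil <- simulate_pupil(proto, noise_sd = 0, physio_noise_sd = 0)
  off <- simulate_boutons(proto, pupil,
                          types = list(rgc_type("OFF", "TRANSIENT",
                                                noise_sd = 1e-12)),
                          axons_per_type = 1, seed = 20)
  set <- process_traces(off)
  timing <- plr_phase_timing(get_tensor(set, "IPSI", 1L), kin)
  expect_gte(timing$peak_time_s, 0.51)
  expect_equal(timing$phase, "CONSTRICTION")
  # a transient ON bouton responds to rebound re-dilation, after the peak
  on <- simulate_boutons(proto, pupil,
                         types = list(rgc_type("ON", "TRANSIENT",
                                               noise_sd = 1e-12)),
                         axons_per_type = 1, seed = 21)
  set_on <- process_traces(on)
  timing_on <- plr_phase_timing(get_tensor(set_on, "IPSI", 1L), kin)
  expect_gt(timing_on$peak_time_s, 1.74)
  expect_equal(timing_on$phase, "REBOUND")
  # flat tensor: no phase label
  flat <- as_tensor(matrix(0.5, 40, 3))
  expect_true(is.na(plr_phase_timing(flat, kin)$phase))
  # timing is invariant to dF/F rescaling
  m <- get_tensor(set, "IPSI", 1L)
  m2 <- m * 4.2
  attr(m2, "time") <- attr(m, "time")
  expect_equal(plr_phase_timing(m2, kin)$peak_time_s, timing$peak_time_s)
})
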