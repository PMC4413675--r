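test_that("attractor connectivity realizes the printed probabilities", {
  spec <- attractor_spec(seed = 3)
  cfg <- build_attractor(spec)
  pools <- attractor_pools(spec)
  i1 <- pools$exc[[1]] + 1

  # within-pool recurrent fraction ~ Binomial(64*63, 0.7) within 3 sigma
  n_pairs <- 64 * 63
  frac <- (sum(cfg$ltp$rec_en[i1, i1])) / n_pairs
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n_pairs))
  expect_false(any(diag(cfg$ltp$rec_en[i1, i1])))
  # recurrent plastic weights are programmed high
  expect_true(all(cfg$ltp$w[i1, i1][cfg$ltp$rec_en[i1, i1]] ==
                    cfg$plasticity$w_max))

  # cross-pool programmable contacts: disjoint exc/inh with the right rates
  j1 <- pools$exc[[2]] + 1
  blk_rec <- cfg$stp$rec_en[i1, j1]
  blk_exc <- cfg$stp$is_exc[i1, j1]
  n_blk <- length(blk_rec)
  expect_lt(abs(mean(blk_rec & blk_exc) - 0.2), 3 * sqrt(0.2 * 0.8 / n_blk))
  expect_lt(abs(mean(blk_rec & !blk_exc) - 0.2), 3 * sqrt(0.2 * 0.8 / n_blk))

  # inhibitory pool -> its excitatory pool, inhibitory synapses
  ci <- pools$inh[[1]] + 1
  blk_ei <- cfg$stp$rec_en[i1, ci]
  expect_lt(abs(mean(blk_ei) - 0.4), 3 * sqrt(0.4 * 0.6 / length(blk_ei)))
  expect_true(all(!cfg$stp$is_exc[i1, ci][blk_ei]))

  # determinism of the sampled pattern
  cfg2 <- build_attractor(spec)
  expect_identical(cfg$ltp$rec_en, cfg2$ltp$rec_en)
  expect_identical(cfg$stp$weight_level, cfg2$stp$weight_level)

  # degenerate case: zero probabilities give an empty network
  empty <- build_attractor(attractor_spec(p_ee_recurrent = 0,
                                          p_ii_recurrent = 0,
                                          p_ee_cross_exc = 0,
                                          p_ee_cross_inh = 0,
                                          p_ei = 0, p_ie = 0))
  expect_equal(sum(empty$ltp$rec_en) + sum(empty$stp$rec_en), 0L)

  expect_error(attractor_spec(exc_pool_size = 80), "budget")
})

test_that("population rate arithmetic and window validation", {
  spk <- data.frame(t = rep(seq(0, 0.499, length.out = 1600)),
                    neuron = rep(0:63, 25))
  expect_equal(mean_rate(spk, 0:63, c(0, 0.5)), 50)
  expect_equal(mean_rate(data.frame(t = numeric(0), neuron = integer(0)),
                         0:9, c(0, 1)), 0)
  expect_error(mean_rate(spk, integer(0), c(0, 1)), "empty")
  expect_error(mean_rate(spk, 0:63, c(1, 1)), "window")

  # a doubled window under stationary Poisson input moves the estimate
  # by less than 3 sigma of the count-based error
  times <- poisson_train(6400, 0, 1, seed = 2)     # pooled over 64 neurons
  spk2 <- data.frame(t = times,
                     neuron = rep_len(0:63, length(times)))
  r1 <- mean_rate(spk2, 0:63, c(0, 0.5))
  r2 <- mean_rate(spk2, 0:63, c(0, 1))
  se <- sqrt(6400 * 0.5) / (64 * 0.5)
  expect_lt(abs(r1 - r2), 3 * se)
})

test_that("classifier wiring: 64 random signed inputs per hidden neuron, full plastic fan-in", {
  spec <- classifier_spec(seed = 2)
  cfg <- build_classifier(spec)
  hid <- spec$hidden + 1
  counts <- rowSums(cfg$stp$bc_en[hid, , drop = FALSE])
  expect_true(all(counts == 64L))
  # signs balanced: Binomial(128*64, 0.5) within 3 sigma
  wired <- cfg$stp$bc_en[hid, ]
  frac_exc <- mean(cfg$stp$is_exc[hid, ][wired])
  expect_lt(abs(frac_exc - 0.5), 3 * sqrt(0.25 / sum(wired)))
  expect_true(all(cfg$stp$weight_level[hid, ][wired] %in% 1:3))

  out <- c(spec$pool_a, spec$pool_b) + 1
  expect_equal(sum(cfg$ltp$rec_en[out, spec$hidden + 1]), 128L * 128L)
  expect_true(all(cfg$ltp$w[out, spec$hidden + 1] ==
                    cfg$plasticity$w_min))
  expect_true(cfg$plasticity$learning_enabled)

  expect_error(classifier_spec(n_hidden = 200, n_output = 128), "256")
})

test_that("an untrained classifier abstains with near-silent output pools", {
  spec <- classifier_spec(n_train_per_class = 0, n_test_per_class = 2)
  cfg <- build_classifier(spec)
  rep <- train_and_test(cfg, spec, test_scenes(), seed = 4)
  tst <- rep$presentations[rep$presentations$phase == "test", ]
  expect_equal(rep$abstentions, nrow(tst))
  expect_true(all(tst$rate_a + tst$rate_b < 1))
})

test_that("config files round-trip through YAML", {
  cfg <- chip_config(neuron_types = list(neuron_params(),
                                         neuron_params(t_ref = 0.004)),
                     demux_factor = 4,
                     plasticity = plasticity_params(theta2 = 0.3),
                     seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_chip_config(cfg, path)
  expect_true(validate_config_file(path))
  back <- read_chip_config(path)
  expect_equal(back$plasticity, cfg$plasticity)
  expect_equal(back$neuron_types, cfg$neuron_types)
  expect_equal(back$demux_factor, cfg$demux_factor)
  expect_equal(back$seed, cfg$seed)
})

test_that("the packaged calibration file reproduces the default operating point", {
  spec_file <- read_attractor_spec()
  spec_code <- attractor_spec()
  for (f in names(formals(attractor_spec)))
    expect_equal(spec_file[[f]], spec_code[[f]], label = f)
  expect_error(read_attractor_spec(
    withr::local_tempfile(lines = "bogus_field: 1", fileext = ".yaml")),
    "unknown field")
})
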