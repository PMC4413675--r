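test_that("pre-spike updates match a literal transcription over all membrane x calcium cases", {
  p <- plasticity_params()
  # both membrane sides crossed with calcium in every region, including
  # the exact threshold boundaries (strict inequalities leave w unchanged)
  vs <- c(0.3, 0.7, p$theta_mem)
  cas <- c(0.05, p$theta1, 0.2, p$theta2, 0.6, p$theta3, 0.95)
  ws <- c(0, 0.05, 0.4, 0.95, 1)
  for (v in vs) for (ca in cas) for (w in ws) {
    expect_identical(pre_spike_update(w, v, ca, p),
                     ref_update_rule(w, v, ca, p))
  }
})

test_that("direct weight-jump instantiations and clipping", {
  p <- plasticity_params()
  expect_equal(pre_spike_update(0.4, v_mem = 0.7, ca = 0.5, p), 0.5)
  expect_equal(pre_spike_update(0.4, v_mem = 0.3, ca = 0.2, p), 0.3)
  expect_equal(pre_spike_update(0.4, v_mem = 0.7, ca = 0.95, p), 0.4)
  expect_equal(pre_spike_update(0.95, v_mem = 0.7, ca = 0.5, p), 1)
  expect_equal(pre_spike_update(0.05, v_mem = 0.3, ca = 0.2, p), 0)
  frozen <- plasticity_params(learning_enabled = FALSE)
  expect_equal(pre_spike_update(0.4, v_mem = 0.7, ca = 0.5, frozen), 0.4)
})

test_that("bistability drift is piecewise linear, saturating, and exactly lazy", {
  p <- plasticity_params()          # theta_w 0.5, drift 0.5/s
  expect_equal(drift_weight(0.6, 0.2, p), 0.7)
  expect_equal(drift_weight(0.4, 0.2, p), 0.3)
  expect_equal(drift_weight(0.5, 5, p), 0.5)       # exactly at threshold
  expect_equal(drift_weight(1, 3, p), 1)
  expect_equal(drift_weight(0.9, 3, p), 1)
  expect_equal(drift_weight(0.1, 3, p), 0)

  # lazy closed form over dt equals many small steps
  w <- c(0.02, 0.3, 0.5, 0.52, 0.97)
  lazy <- drift_weight(w, 0.73, p)
  stepped <- w
  for (i in 1:73) stepped <- drift_weight(stepped, 0.01, p)
  expect_equal(lazy, stepped, tolerance = 1e-12)

  # any start converges to a bound after (w_max - w_min) / drift seconds
  w0 <- seq(0, 1, by = 0.01)
  wT <- drift_weight(w0, (p$w_max - p$w_min) / min(p$c_drift_up,
                                                   p$c_drift_dn), p)
  expect_true(all(wT[w0 != p$theta_w] %in% c(p$w_min, p$w_max)))
})

test_that("efficacy is a thresholded read-out of the internal weight", {
  p <- plasticity_params()
  expect_equal(efficacy(0.7, p), 1)
  expect_equal(efficacy(0.3, p), 0)
  expect_equal(efficacy(p$theta_j, p), p$j_max)   # boundary inclusive
  ps <- plasticity_params(efficacy_form = "sigmoid", sigmoid_slope = 0.05)
  expect_equal(efficacy(ps$theta_j, ps), 0.5)
  expect_true(all(diff(efficacy(seq(0, 1, 0.05), ps)) > 0))
})

test_that("the SET block programs stable states that the drift preserves", {
  p <- plasticity_params()
  syn <- set_weight(ltp_synapse(), high = TRUE, p)
  expect_equal(syn$w, p$w_max)
  expect_equal(drift_weight(syn$w, 7, p), p$w_max)
  expect_equal(set_weight(syn, high = FALSE, p)$w, p$w_min)
})

test_that("any finite event history followed by quiescence ends exactly at a bound", {
  p <- plasticity_params()
  set.seed(42)
  for (rep in 1:20) {
    w <- runif(1)
    for (k in 1:50) {
      w <- pre_spike_update(w, v_mem = runif(1), ca = runif(1), p)
      w <- drift_weight(w, rexp(1, 50), p)
    }
    w <- drift_weight(w, (p$w_max - p$w_min) / min(p$c_drift_up,
                                                   p$c_drift_dn), p)
    expect_true(w %in% c(p$w_min, p$w_max) || w == p$theta_w)
  }
})

test_that("with learning frozen, programmed efficacies are retained through a run", {
  cfg <- single_neuron_cfg(jump_virt = 0.004)
  cfg$plasticity <- plasticity_params(learning_enabled = FALSE)
  cfg$ltp$w[1, 5] <- 1        # programmed high
  cfg$ltp$rec_en[1, 5] <- TRUE
  ev <- events_virt(poisson_train(800, 0, 1, seed = 5), 0, "exc")
  sim <- simulate_chip(cfg, ev, t_end = 1, dt = 1e-4)
  expect_gt(nrow(sim$spikes), 10)                  # the neuron did fire
  expect_equal(sim$config$ltp$w[1, 5], 1)
  expect_equal(sum(sim$config$ltp$w >= 0.5), 1)    # nothing else drifted up
})

test_that("the crossing fraction of a synapse population grows with the up-jump", {
  p0 <- plasticity_params()
  frac_crossed <- function(dw_plus, n = 300, seed = 7) {
    p <- plasticity_params(dw_plus = dw_plus)
    set.seed(seed)
    crossed <- 0L
    for (i in seq_len(n)) {
      w <- p$w_min
      t_pre <- cumsum(rexp(40, 60))      # one Poisson presentation
      t_last <- 0
      for (tt in t_pre) {
        w <- drift_weight(w, tt - t_last, p)
        w <- pre_spike_update(w, v_mem = runif(1), ca = 0.5, p)
        t_last <- tt
      }
      if (w > p$theta_w) crossed <- crossed + 1L
    }
    crossed / n
  }
  fr <- vapply(c(0.02, 0.05, 0.10), frac_crossed, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[3], fr[1])
})
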