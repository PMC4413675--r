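test_that("DPI decay is an exact exponential with the semigroup property", {
  s <- dpi_state(tau = 0.02, i_out = 1)
  expect_equal(dpi_decay(s, 0.02)$i_out, exp(-1), tolerance = 1e-12)
  expect_equal(dpi_decay(s, 0)$i_out, 1)
  two_half <- dpi_decay(dpi_decay(s, 0.007), 0.007)$i_out
  expect_equal(two_half, dpi_decay(s, 0.014)$i_out, tolerance = 1e-14)
  expect_error(dpi_decay(s, -1), "dt")
})

test_that("spikes add charge in proportion to the effective weight", {
  s <- dpi_state(tau = 0.02, jump_scale = 0.5)
  expect_equal(dpi_on_spike(s, 0)$i_out, 0)
  expect_equal(dpi_on_spike(s, 2)$i_out, 1)
  expect_error(dpi_on_spike(s, -1), "effective_weight")
})

test_that("Poisson drive reaches the linear-filter steady state", {
  tau <- 0.02; jump <- 0.7; w <- 0.5; rate <- 400; t_end <- 30
  times <- poisson_train(rate, 0, t_end, seed = 11)
  m <- dpi_mean_current(times, w, tau, jump, t_end)
  expect_equal(m, jump * w * rate * tau, tolerance = 0.05)
})

test_that("DPI response is linear: union of streams equals sum of responses", {
  tau <- 0.05
  a <- poisson_train(100, 0, 2, seed = 1)
  b <- poisson_train(250, 0, 2, seed = 2)
  resp_end <- function(times) {
    s <- dpi_state(tau = tau, jump_scale = 1)
    t_prev <- 0
    for (tt in times) {
      s <- dpi_on_spike(dpi_decay(s, tt - t_prev), 1)
      t_prev <- tt
    }
    dpi_decay(s, 2 - t_prev)$i_out
  }
  expect_equal(resp_end(sort(c(a, b))), resp_end(a) + resp_end(b),
               tolerance = 1e-10)
})

test_that("one fast train time-multiplexes many slow synapses (equal rate x weight)", {
  tau <- 0.02; t_end <- 10
  hi <- seq(0, t_end - 1e-9, by = 1 / 10000)          # one 10 kHz train
  lo <- sort(unlist(lapply(1:100, function(k)        # 100 x 100 Hz trains
    poisson_train(100, 0, t_end, seed = 600 + k))))
  m_hi <- dpi_mean_current(hi, 1, tau, 1, t_end)
  m_lo <- dpi_mean_current(lo, 1, tau, 1, t_end)
  expect_equal(m_hi, 1 * 10000 * tau, tolerance = 0.01)  # closed form
  expect_equal(m_hi / m_lo, 1, tolerance = 0.03)
})

test_that("two-bit weight DAC has four equidistant levels", {
  expect_equal(base_weight(0:3), c(0, 1, 2, 3) / 3)
  expect_equal(base_weight(3, w_unit = 0.6), 0.6)
  expect_error(base_weight(4), "level")
})

test_that("short-term depression samples the EPSC before depressing", {
  syn <- stp_synapse(weight_level = 3)
  p <- std_params(depress_amount = 0.2, std_enabled = TRUE)
  out <- std_on_pre(syn, p)
  expect_equal(out$epsc_weight, 1)         # first pulse of a rested burst
  expect_equal(out$syn$std_x, 0.8)
  expect_error(std_on_pre(stp_synapse(is_excitatory = FALSE), p),
               "inhibitory")
})

test_that("burst depression and silent-gap recovery reproduce the device signature", {
  p <- std_params(depress_amount = 0.2, recovery_tau = 0.05,
                  std_enabled = TRUE)
  syn <- stp_synapse(weight_level = 3)
  burst <- function(syn, n = 5, isi = 0.005) {
    ep <- numeric(n)
    for (i in seq_len(n)) {
      if (i > 1) syn <- std_recover(syn, isi, p)
      out <- std_on_pre(syn, p)
      syn <- out$syn
      ep[i] <- out$epsc_weight
    }
    list(syn = syn, epsc = ep)
  }
  b1 <- burst(syn)
  expect_true(all(diff(b1$epsc) < 0))
  rec <- std_recover(b1$syn, 0.1, p)
  b2 <- burst(rec)
  expect_true(all(diff(b2$epsc) < 0))
  expect_gt(b2$epsc[1], b1$epsc[5])
  # efficacy stays within [0, 1] under heavy stimulation
  s <- stp_synapse(weight_level = 3)
  for (i in 1:50) s <- std_on_pre(s, p)$syn
  expect_gte(s$std_x, 0)
  expect_lte(s$std_x, 1)
})

test_that("recovery follows the first-order closed form", {
  p <- std_params(recovery_tau = 0.05, std_enabled = TRUE)
  syn <- stp_synapse(weight_level = 3, std_x = 0.8)
  expect_equal(std_recover(syn, 0.05, p)$std_x, 1 - 0.2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(std_recover(syn, 0.05, p)$std_x, 0.9264, tolerance = 1e-4)
  expect_equal(std_recover(syn, 0, p)$std_x, 0.8)
  expect_equal(std_recover(syn, 10, p)$std_x, 1, tolerance = 1e-9)
})

test_that("with no depression the programmable synapse is time-invariant", {
  p <- std_params(depress_amount = 0, std_enabled = TRUE)
  syn <- stp_synapse(weight_level = 2)
  for (i in 1:10) {
    out <- std_on_pre(syn, p)
    syn <- out$syn
    expect_equal(out$epsc_weight, base_weight(2))
  }
})

test_that("excitatory and inhibitory branches route to the right integrator", {
  exc <- stp_synapse(weight_level = 2, is_excitatory = TRUE)
  inh <- stp_synapse(weight_level = 2, is_excitatory = FALSE)
  r1 <- stp_route_current(exc, epsc_weight = 0.4)
  expect_equal(r1$target, "AMPA_row_dpi")
  expect_equal(r1$weight, 0.4)
  # the inhibitory branch has no depression circuit: full programmed weight
  r2 <- stp_route_current(inh, epsc_weight = 0.123)
  expect_equal(r2$target, "GABA_row_dpi")
  expect_equal(r2$weight, base_weight(2))
  expect_equal(stp_route_current(stp_synapse(weight_level = 0))$weight, 0)
})

test_that("excitatory input raises and inhibitory input lowers the membrane", {
  cfg <- single_neuron_cfg()
  cfg$dpi$jump_ampa <- 0.01          # subthreshold, no spike/reset
  cfg$dpi$jump_gaba <- 0.01
  cfg$stp$weight_level[1, 1:2] <- 3L
  cfg$stp$is_exc[1, 2] <- FALSE
  run_v <- function(col) {
    ev <- events_dir(0.005, "stp", 0, col)
    sim <- simulate_chip(cfg, ev, t_end = 0.05, dt = 1e-4,
                         record = list(period = 1e-3, v = 0))
    sim$traces$v[, 1]
  }
  base <- simulate_chip(cfg, NULL, t_end = 0.05, dt = 1e-4,
                        record = list(period = 1e-3, v = 0))$traces$v[, 1]
  expect_true(all(run_v(0) >= base))
  expect_gt(max(run_v(0) - base), 0)
  expect_lt(min(run_v(1) - base), 0)
})
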