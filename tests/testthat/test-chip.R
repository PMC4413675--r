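test_that("local configuration events write and read back element latches", {
  cfg <- chip_config()
  ev <- events_cfg_local(0, "stp", 3, 7, "weight_level", 2)
  cfg <- apply_config_event(cfg, ev[1, ])
  expect_equal(cfg$stp$weight_level[4, 8], 2L)
  cfg <- apply_config_event(cfg,
    events_cfg_local(0, "stp", 3, 7, "exc", 0)[1, ])
  expect_false(cfg$stp$is_exc[4, 8])
  cfg <- apply_config_event(cfg,
    events_cfg_local(0, "ltp", 1, 2, "set_hi", 1)[1, ])
  expect_equal(cfg$ltp$w[2, 3], cfg$plasticity$w_max)
  cfg <- apply_config_event(cfg,
    events_cfg_local(0, "ltp", 0, 0, "rec_en", 1)[1, ])
  expect_true(cfg$ltp$rec_en[1, 1])

  expect_error(apply_config_event(cfg,
    list(kind = "CFG_L", a1 = "ltp", a2 = "70000", a3 = "rec_en=1")),
    "address")
  expect_error(apply_config_event(cfg,
    list(kind = "CFG_L", a1 = "stp", a2 = "0", a3 = "bogus=1")),
    "unknown")
})

test_that("global configuration sets the de-multiplexer and neuron types", {
  cfg <- chip_config(neuron_types = list(neuron_params(),
                                         neuron_params(t_ref = 0.004)))
  cfg <- apply_config_event(cfg, events_cfg_global(0, "demux_factor", 2)[1, ])
  expect_equal(cfg$demux_factor, 2L)
  expect_equal(length(active_neurons(cfg)), 128L)
  cfg <- apply_config_event(cfg, events_cfg_global(0, "neuron_type_9", 2)[1, ])
  expect_equal(cfg$neuron_type[10], 2L)
  expect_error(apply_config_event(cfg,
    events_cfg_global(0, "demux_factor", 3)[1, ]), "power of two")
})

test_that("the de-multiplexer trades neuron count for fan-in", {
  cfg <- chip_config()
  expect_equal(length(active_neurons(cfg)), 256L)
  expect_equal(cfg$demux_factor * 512L, 512L)    # default: 512 elements each

  cfg2 <- set_demux(cfg, 2)
  expect_equal(active_neurons(cfg2), seq.int(0L, 254L, by = 2L))
  expect_equal(cfg2$demux_factor * 512L, 1024L)

  cfg256 <- set_demux(cfg, 256)
  expect_equal(active_neurons(cfg256), 0L)
  expect_equal(cfg256$demux_factor * 512L, 131072L)
  expect_error(set_demux(cfg, 6), "power of two")

  # total addressable synapse elements are independent of the factor
  for (f in c(1, 4, 64, 256)) {
    cf <- set_demux(cfg, f)
    expect_equal(length(active_neurons(cf)) * cf$demux_factor * 512L,
                 131072L)
  }
  # row ownership partitions the rows among active neurons
  ro <- row_owner(cfg2)
  expect_true(all(ro %in% active_neurons(cfg2)))
  expect_equal(as.vector(table(ro)), rep(2L, 128L))
})

test_that("routing implements direct, broadcast and recurrent activation", {
  cfg <- chip_config()
  d <- route_event(cfg, events_dir(0, "stp", 1, 1)[1, ])
  expect_equal(d, data.frame(array = "stp", row = 1L, col = 1L))

  cfg$ltp$bc_en[c(3, 10), 6] <- TRUE     # rows 2 and 9, column 5 (0-based)
  b <- route_event(cfg, events_bcast(0, "ltp", 5)[1, ])
  expect_equal(b$row, c(2L, 9L))
  expect_equal(b$col, c(5L, 5L))

  cfg$ltp$rec_en[c(1, 4), 8] <- TRUE     # column 7 fans to rows 0 and 3
  r <- route_event(cfg, events_out(0, 7)[1, ])
  expect_equal(r$row[r$array == "ltp"], c(0L, 3L))
  expect_equal(unique(r$col), 7L)

  v <- route_event(cfg, events_virt(0, 12, "inh")[1, ])
  expect_equal(v$array, "virt_inh")
  expect_equal(v$row, 12L)

  expect_error(route_event(cfg, events_dir(0, "stp", 300, 0)[1, ]),
               "out of range")
})

test_that("a quiescent chip stays silent and unsorted events are rejected", {
  cfg <- chip_config()
  sim <- simulate_chip(cfg, NULL, t_end = 0.1)
  expect_equal(nrow(sim$spikes), 0L)

  bad <- rbind(events_virt(0.02, 0, "exc"), events_virt(0.01, 0, "exc"))
  expect_error(simulate_chip(cfg, bad, t_end = 0.1), "decrease")
})

test_that("simulation is deterministic: identical inputs give identical spikes", {
  cfg <- single_neuron_cfg(jump_virt = 0.004)
  ev <- events_virt(poisson_train(500, 0, 0.5, seed = 3), 0, "exc")
  s1 <- simulate_chip(cfg, ev, t_end = 0.5)
  s2 <- simulate_chip(cfg, ev, t_end = 0.5)
  expect_identical(s1$spikes, s2$spikes)
  expect_gt(nrow(s1$spikes), 0)
})

test_that("Poisson virtual drive matches the equivalent constant current", {
  jv <- 0.0035; rate <- 1000; tau <- 0.02
  cfg <- single_neuron_cfg(jump_virt = jv)
  ev <- events_virt(poisson_train(rate, 0, 2, seed = 7), 0, "exc")
  sim <- simulate_chip(cfg, ev, t_end = 2, dt = 1e-4)
  r_sim <- mean_rate(sim, 0, c(0, 2))
  r_const <- fi_curve(neuron_params(), jv * rate * tau, duration = 2)
  expect_equal(r_sim, r_const, tolerance = 0.1)
})

test_that("row currents superpose: union of streams equals sum of responses", {
  cfg <- chip_config()
  cfg$stp$weight_level[5, 1] <- 3L
  cfg$stp$weight_level[5, 2] <- 2L
  a <- events_dir(poisson_train(150, 0, 0.3, seed = 21), "stp", 4, 0)
  b <- events_dir(poisson_train(150, 0, 0.3, seed = 22), "stp", 4, 1)
  rec <- list(period = 5e-3, rows = 4)
  tr <- function(ev) simulate_chip(cfg, ev, t_end = 0.3, dt = 1e-4,
                                   record = rec)$traces$dpi[, 1, "ampa"]
  expect_equal(tr(bind_events(a, b)), tr(a) + tr(b), tolerance = 1e-10)
})

test_that("every input spike is delivered to its routed targets", {
  cfg <- chip_config()
  cfg$ltp$bc_en[1:10, 3] <- TRUE
  ev <- bind_events(events_bcast(c(0.01, 0.02), "ltp", 2),
                    events_dir(0.03, "stp", 0, 0),
                    events_virt(0.04, 1, "exc"))
  sim <- simulate_chip(cfg, ev, t_end = 0.05)
  expect_equal(sim$counters$n_events_in, 4L)
  expect_equal(sim$counters$n_deliveries, 10L + 10L + 1L + 1L)
})

test_that("the output stream is time-sorted and refractory-consistent", {
  spec <- attractor_spec()
  cfg <- build_attractor(spec)
  pools <- attractor_pools(spec)
  ev <- do.call(bind_events, lapply(pools$exc[[1]], function(r)
    events_virt(poisson_train(100, 0, 0.3, seed = 100 + r), r, "exc")))
  sim <- simulate_chip(cfg, ev, t_end = 0.5)
  expect_true(all(diff(sim$spikes$t) >= 0))
  tref <- vapply(cfg$neuron_types, `[[`, numeric(1), "t_ref")
  for (n in unique(sim$spikes$neuron)) {
    isi <- diff(sim$spikes$t[sim$spikes$neuron == n])
    expect_true(all(isi >= tref[cfg$neuron_type[n + 1]] - 1e-12))
  }
})

test_that("recurrent fan-out arrives one step later and drives the target row", {
  cfg <- single_neuron_cfg(jump_virt = 0.01)
  cfg$ltp$rec_en[2, 1] <- TRUE                 # neuron 0 -> row 1, col 0
  cfg$ltp$w[2, 1] <- 1
  cfg$dpi$jump_nmda <- 0.005
  ev <- events_virt(poisson_train(600, 0, 0.4, seed = 9), 0, "exc")
  sim <- simulate_chip(cfg, ev, t_end = 0.4,
                       record = list(period = 1e-3, rows = 1))
  expect_gt(mean_rate(sim, 0, c(0, 0.4)), 5)
  expect_gt(max(sim$traces$dpi[, 1, "nmda"]), 0)
})
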