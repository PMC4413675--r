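## System-level experiment builders: competing attractor working memories
## and the event-driven two-layer classifier.  Both are expressed purely
## as device configurations plus input event streams and run through
## simulate_chip(); the numeric weight/bias choices bundled in the spec
## constructors are the packaged calibration that puts the default chip
## parameters into the published operating regime.

#' Attractor-network experiment specification
#'
#' Three pools of 64 excitatory neurons and three pools of 10 inhibitory
#' neurons.  Within-pool excitatory (and inhibitory-pool) recurrence is
#' carried by the plastic array with weights programmed to the high state
#' and learning frozen; cross-pool excitation/inhibition between
#' excitatory pools, inhibitory-pool input to its excitatory pool, and
#' excitatory-pool drive of its inhibitory pool are carried by the
#' programmable array.  External stimuli arrive as Poisson trains on the
#' virtual synapses.
#'
#' The `level_*` and `gain_*` fields are the packaged calibration: the
#' two-bit weight levels of the four programmable connection classes and
#' the row-integrator charge scales that put the network in the target
#' regime (driven activity near 50 Hz, self-sustained activity near
#' 15 Hz, collapse after a 200 Hz inhibitory reset).  The self-sustained
#' rate is pinned by threshold-linear feedback from the dedicated
#' inhibitory pool: below the pin the recurrent excitation is
#' supra-threshold and the pool climbs, above it the inhibitory pool
#' ignites and pulls the rate back, so the memory state is a genuine
#' attractor rather than a slowly decaying transient.
#'
#' @param n_exc_pools,exc_pool_size,n_inh_pools,inh_pool_size Pool layout
#'   (defaults 3 x 64 excitatory, 3 x 10 inhibitory; 222 neurons total).
#' @param p_ee_recurrent Within-pool excitatory recurrence probability.
#' @param p_ii_recurrent Within-pool inhibitory-pool recurrence
#'   probability (excitatory synapses on the plastic array).
#' @param p_ee_cross_exc,p_ee_cross_inh Between-pool excitatory /
#'   inhibitory connection probabilities (programmable array).
#' @param p_ei Inhibitory-pool to excitatory-pool connection probability.
#' @param p_ie Excitatory-pool to inhibitory-pool connection probability.
#' @param v_in External stimulus rate (Hz) per neuron.
#' @param stim_dur Stimulus duration (s).
#' @param reset_rate Rate (Hz) of the inhibitory-pool reset stimulus.
#' @param level_cross_exc,level_cross_inh,level_ei,level_ie Two-bit weight
#'   levels of the four programmable connection classes.
#' @param gain_nmda,gain_ampa,gain_gaba,gain_virt Row-integrator charge
#'   scales (per-spike jump per unit weight).
#' @param ahp_b Adaptation increment of the excitatory neurons
#'   (optional; the packaged calibration does not rely on adaptation).
#' @param ahp_tau Adaptation decay time constant (s) of the excitatory
#'   neurons.
#' @param inh_leak Leak conductance of the inhibitory neuron type.  Set
#'   high enough that the inhibitory pools' own recurrent excitation
#'   cannot self-sustain them (they must fire only while driven).
#' @param nmda_gate,nmda_gate_threshold Optional NMDA voltage gate of
#'   the excitatory neurons (the recurrent row current reaches the soma
#'   only while the membrane exceeds the gate threshold); off in the
#'   packaged calibration.
#' @param seed Integer seed controlling the sampled connectivity.
#' @return An object of class `attractor_spec`.
#' @export
attractor_spec <- function(n_exc_pools = 3, exc_pool_size = 64,
                           n_inh_pools = 3, inh_pool_size = 10,
                           p_ee_recurrent = 0.7, p_ii_recurrent = 0.4,
                           p_ee_cross_exc = 0.2, p_ee_cross_inh = 0.2,
                           p_ei = 0.4, p_ie = 0.7,
                           v_in = 100, stim_dur = 0.5, reset_rate = 200,
                           level_cross_exc = 1, level_cross_inh = 3,
                           level_ei = 3, level_ie = 2,
                           gain_nmda = 0.00125, gain_ampa = 0.0125,
                           gain_gaba = 0.020, gain_virt = 0.072,
                           ahp_b = 0, ahp_tau = 0.1, inh_leak = 0.15,
                           nmda_gate = FALSE, nmda_gate_threshold = 0.55,
                           seed = 1) {
  probs <- c(p_ee_recurrent, p_ii_recurrent, p_ee_cross_exc,
             p_ee_cross_inh, p_ei, p_ie)
  if (any(probs < 0 | probs > 1))
    stop("attractor_spec: connection probabilities must be in [0, 1]")
  n_tot <- n_exc_pools * exc_pool_size + n_inh_pools * inh_pool_size
  if (n_tot > N_NEURONS)
    stop("attractor_spec: ", n_tot, " neurons exceed the 256-neuron budget")
  s <- as.list(environment())
  s$n_total <- n_tot
  class(s) <- "attractor_spec"
  s
}

#' Pool membership of the attractor network
#'
#' @param spec An [attractor_spec()].
#' @return A list with `exc` and `inh`, each a list of 0-based neuron
#'   address vectors, one per pool.
#' @export
attractor_pools <- function(spec) {
  ne <- spec$exc_pool_size; ni <- spec$inh_pool_size
  exc <- lapply(seq_len(spec$n_exc_pools) - 1L,
                function(i) seq.int(i * ne, (i + 1L) * ne - 1L))
  off <- spec$n_exc_pools * ne
  inh <- lapply(seq_len(spec$n_inh_pools) - 1L,
                function(i) seq.int(off + i * ni, off + (i + 1L) * ni - 1L))
  list(exc = exc, inh = inh)
}

## Bernoulli(p) block mask, optionally removing the diagonal
bern_block <- function(nr, nc, p, no_diag = FALSE) {
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  if (no_diag) diag(m) <- FALSE
  m
}

#' Build the attractor-network device configuration
#'
#' Samples the Bernoulli connectivity (seeded, hence reproducible dot
#' patterns), programs the plastic within-pool recurrence to the high
#' bistable state with learning frozen, sets the programmable-array
#' latches and weight levels for the four cross-connection classes, and
#' returns the complete configuration.  Between-pool excitatory and
#' inhibitory contacts share one programmable element per (row, column)
#' pair, so they are drawn disjointly with the correct marginal
#' probabilities.
#'
#' @param spec An [attractor_spec()].
#' @return A [chip_config()].
#' @export
build_attractor <- function(spec) {
  stopifnot(inherits(spec, "attractor_spec"))
  pools <- attractor_pools(spec)
  exc_type <- neuron_params(ahp_b = spec$ahp_b, ahp_tau = spec$ahp_tau,
                            nmda_gate_enabled = spec$nmda_gate,
                            nmda_gate_threshold = spec$nmda_gate_threshold)
  inh_type <- neuron_params(tau_mem = 0.010, t_ref = 0.001,
                            leak_conductance = spec$inh_leak)
  cfg <- chip_config(
    neuron_types = list(exc_type, inh_type),
    neuron_type = {
      ty <- rep(1L, N_NEURONS)
      ty[unlist(pools$inh) + 1L] <- 2L
      ty
    },
    plasticity = plasticity_params(learning_enabled = FALSE),
    std = std_params(std_enabled = FALSE),
    dpi = list(tau_nmda = 0.1, tau_ampa = 0.02, tau_gaba = 0.02,
               tau_virt = 0.02,
               jump_nmda = spec$gain_nmda, jump_ampa = spec$gain_ampa,
               jump_gaba = spec$gain_gaba, jump_virt = spec$gain_virt),
    virtual_w = list(exc = 1, inh = 1),
    seed = spec$seed)
  wmax <- cfg$plasticity$w_max
  with_seed(spec$seed, {
    ## within-pool recurrence on the plastic array (programmed, frozen)
    for (po in pools$exc) {
      i1 <- po + 1L
      m <- bern_block(length(po), length(po), spec$p_ee_recurrent,
                      no_diag = TRUE)
      cfg$ltp$rec_en[i1, i1] <- cfg$ltp$rec_en[i1, i1] | m
      cfg$ltp$w[i1, i1][m] <- wmax
    }
    for (po in pools$inh) {
      i1 <- po + 1L
      m <- bern_block(length(po), length(po), spec$p_ii_recurrent,
                      no_diag = TRUE)
      cfg$ltp$rec_en[i1, i1] <- cfg$ltp$rec_en[i1, i1] | m
      cfg$ltp$w[i1, i1][m] <- wmax
    }
    ## cross-pool excitation/inhibition between excitatory pools (STP);
    ## one element per pair, so draw the two classes disjointly
    for (i in seq_len(spec$n_exc_pools)) {
      for (j in seq_len(spec$n_exc_pools)) {
        if (i == j) next
        ri <- pools$exc[[i]] + 1L; cj <- pools$exc[[j]] + 1L
        u <- matrix(stats::runif(length(ri) * length(cj)),
                    length(ri), length(cj))
        me <- u < spec$p_ee_cross_exc
        mi <- u >= spec$p_ee_cross_exc &
          u < spec$p_ee_cross_exc + spec$p_ee_cross_inh
        cfg$stp$rec_en[ri, cj] <- me | mi
        lv <- cfg$stp$weight_level[ri, cj]
        lv[me] <- spec$level_cross_exc; lv[mi] <- spec$level_cross_inh
        cfg$stp$weight_level[ri, cj] <- lv
        ex <- cfg$stp$is_exc[ri, cj]; ex[mi] <- FALSE
        cfg$stp$is_exc[ri, cj] <- ex
      }
    }
    ## inhibitory pool -> its excitatory pool (STP inhibitory)
    for (i in seq_len(spec$n_inh_pools)) {
      ri <- pools$exc[[i]] + 1L; cj <- pools$inh[[i]] + 1L
      m <- bern_block(length(ri), length(cj), spec$p_ei)
      cfg$stp$rec_en[ri, cj] <- cfg$stp$rec_en[ri, cj] | m
      lv <- cfg$stp$weight_level[ri, cj]; lv[m] <- spec$level_ei
      cfg$stp$weight_level[ri, cj] <- lv
      ex <- cfg$stp$is_exc[ri, cj]; ex[m] <- FALSE
      cfg$stp$is_exc[ri, cj] <- ex
    }
    ## excitatory pool -> its inhibitory pool (STP excitatory)
    for (i in seq_len(spec$n_exc_pools)) {
      if (i > spec$n_inh_pools) break
      ri <- pools$inh[[i]] + 1L; cj <- pools$exc[[i]] + 1L
      m <- bern_block(length(ri), length(cj), spec$p_ie)
      cfg$stp$rec_en[ri, cj] <- cfg$stp$rec_en[ri, cj] | m
      lv <- cfg$stp$weight_level[ri, cj]; lv[m] <- spec$level_ie
      cfg$stp$weight_level[ri, cj] <- lv
    }
  })
  cfg
}

## Poisson trains on the virtual excitatory synapses of a set of rows,
## drawn from one seeded stream (one train per row).
pool_poisson_events <- function(rows, rate, t0, t1, seed,
                                type = "exc") {
  if (rate <= 0 || t1 <= t0) return(empty_events())
  with_seed(seed, {
    n <- stats::rpois(length(rows), rate * (t1 - t0))
    tt <- stats::runif(sum(n), t0, t1)
    rr <- rep.int(rows, n)
    o <- order(tt)
    events_virt(tt[o], rr[o], type)
  })
}

#' Run the attractor working-memory protocol
#'
#' Protocol: drive excitatory pool 1 with per-neuron Poisson trains
#' (`v_in`, `stim_dur`) through the virtual synapses; leave the network
#' unstimulated so the pool self-sustains; drive pool 2 to switch the
#' active memory; at t = 3 s drive all inhibitory pools at `reset_rate`
#' to reset every attractor; observe the quiescent network.  Rates are
#' reported per pool over the named protocol windows.
#'
#' @param cfg A configuration from [build_attractor()].
#' @param spec The matching [attractor_spec()].
#' @param dt Integration step (s).
#' @param seed Seed for the stimulus Poisson trains (defaults to the
#'   spec's connectivity seed).
#' @return An object of class `rate_report`: a list with `rates` (a
#'   data.frame of pool x window mean rates in Hz), `windows`, `spikes`,
#'   and `persistence` (duration, in s, for which the pool-1 rate stayed
#'   above 10x the mean rate of the other excitatory pools after stimulus
#'   removal, assessed in 250 ms bins).
#' @export
run_attractor <- function(cfg, spec, dt = 1e-4, seed = spec$seed) {
  stopifnot(inherits(spec, "attractor_spec"))
  pools <- attractor_pools(spec)
  t_stim2 <- 2.5
  t_reset <- 3.0
  t_end <- 4.0
  ev <- bind_events(
    pool_poisson_events(pools$exc[[1]], spec$v_in, 0, spec$stim_dur,
                        seed = seed + 101L),
    pool_poisson_events(pools$exc[[2]], spec$v_in, t_stim2,
                        t_stim2 + spec$stim_dur, seed = seed + 202L),
    do.call(bind_events, lapply(seq_along(pools$inh), function(i)
      pool_poisson_events(pools$inh[[i]], spec$reset_rate, t_reset,
                          t_reset + spec$stim_dur,
                          seed = seed + 300L + i)))
  )
  sim <- simulate_chip(cfg, ev, t_end = t_end, dt = dt)
  windows <- list(driven = c(0, spec$stim_dur),
                  sustained = c(spec$stim_dur, spec$stim_dur + 1),
                  persist = c(spec$stim_dur + 1, t_stim2),
                  switch_driven = c(t_stim2, t_stim2 + spec$stim_dur),
                  post_reset = c(t_reset + spec$stim_dur, t_end))
  pool_sets <- c(stats::setNames(pools$exc,
                                 paste0("exc", seq_along(pools$exc))),
                 stats::setNames(pools$inh,
                                 paste0("inh", seq_along(pools$inh))))
  rates <- do.call(rbind, lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    data.frame(window = wn, pool = names(pool_sets), t0 = w[1], t1 = w[2],
               rate = vapply(pool_sets, function(ns)
                 mean_rate(sim$spikes, ns, w), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  ## persistence of the pool-1 memory after stimulus removal (250 ms bins)
  bins <- seq(spec$stim_dur, t_stim2, by = 0.25)
  others <- unlist(pools$exc[-1])
  persist <- 0
  for (b in seq_len(length(bins) - 1)) {
    w <- c(bins[b], bins[b + 1])
    r1 <- mean_rate(sim$spikes, pools$exc[[1]], w)
    ro <- mean_rate(sim$spikes, others, w)
    if (r1 > 10 * max(ro, 0.1)) persist <- persist + diff(w) else break
  }
  out <- list(rates = rates, windows = windows, spikes = sim$spikes,
              persistence = persist, counters = sim$counters)
  class(out) <- "rate_report"
  out
}

#' @export
print.rate_report <- function(x, ...) {
  cat("<rate_report>\n")
  wide <- stats::reshape(x$rates[, c("window", "pool", "rate")],
                         idvar = "pool", timevar = "window",
                         direction = "wide")
  names(wide) <- sub("^rate\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  if (!is.null(x$persistence))
    cat(sprintf("  pool-1 memory persistence after stimulus: %.2f s\n",
                x$persistence))
  invisible(x)
}

#' Mean population firing rate in a window
#'
#' Spike count of the addressed neurons inside `[t0, t1)`, divided by the
#' population size and the window length.
#'
#' @param spikes A spike data.frame (`t`, `neuron`) or a
#'   [simulate_chip()] result.
#' @param neuron_set 0-based neuron addresses (non-empty).
#' @param window Numeric `c(t0, t1)` with `t1 > t0`.
#' @return Mean rate in Hz.
#' @export
mean_rate <- function(spikes, neuron_set, window) {
  if (inherits(spikes, "sim_result")) spikes <- spikes$spikes
  if (length(neuron_set) == 0) stop("mean_rate: empty neuron set")
  if (diff(window) <= 0) stop("mean_rate: zero-length window")
  n <- sum(spikes$t >= window[1] & spikes$t < window[2] &
             spikes$neuron %in% neuron_set)
  n / (length(neuron_set) * diff(window))
}

#' Classifier experiment specification
#'
#' A two-layer feed-forward network on the chip: 128 hidden neurons each
#' receive broadcast events from 64 randomly selected input pixels with
#' random sign and random two-bit weight (the programmable array); the
#' 128 output neurons (two class pools of 64) receive all 128 hidden
#' neurons through plastic synapses in recurrent mode, with on-line
#' learning enabled.  During training an external Poisson teacher drives
#' the class-matching output pool through the virtual synapses; during
#' testing the teacher is off and the decision is the arg-max of the two
#' pool rates.
#'
#' @param n_hidden,n_output Layer sizes (both 128; outputs are two pools
#'   of `n_output / 2`).
#' @param inputs_per_hidden Number of distinct input columns per hidden
#'   neuron (64).
#' @param teacher_rate Teacher Poisson rate (Hz) per output neuron.
#' @param n_train_per_class,n_test_per_class Presentation counts.
#' @param gain_nmda,gain_ampa,gain_gaba,gain_virt Row-integrator charge
#'   scales (the packaged calibration).
#' @param ca_jump Calcium increment per output spike.  With the default
#'   calcium time constant this places the depression window over
#'   roughly 10-35 Hz and the potentiation window over 10-90 Hz of
#'   output rate, so a wrongly responding pool (tens of Hz, membrane
#'   mostly low) is pruned while a silent pool is protected by
#'   stop-learning.
#' @param dw_plus,dw_minus Plasticity jump amplitudes used for the
#'   output-layer synapses.  Small relative to the weight range, so
#'   potentiation needs several coincident pre-spikes per presentation
#'   and the calcium-gated depression can prune wrongly potentiated
#'   synapses across presentations.
#' @param seed Integer seed for the random input wiring.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_hidden = 128, n_output = 128,
                            inputs_per_hidden = 64,
                            teacher_rate = 250,
                            n_train_per_class = 20,
                            n_test_per_class = 10,
                            gain_nmda = 0.0012, gain_ampa = 0.012,
                            gain_gaba = 0.012, gain_virt = 0.015,
                            ca_jump = 0.05,
                            dw_plus = 0.05, dw_minus = 0.05,
                            seed = 1) {
  if (n_hidden + n_output > N_NEURONS)
    stop("classifier_spec: hidden + output layers exceed 256 neurons")
  if (inputs_per_hidden > N_NEURONS)
    stop("classifier_spec: inputs_per_hidden cannot exceed 256 columns")
  if (n_output %% 2 != 0)
    stop("classifier_spec: n_output must split into two pools")
  s <- as.list(environment())
  s$hidden <- seq.int(0L, n_hidden - 1L)
  s$pool_a <- seq.int(n_hidden, n_hidden + n_output / 2 - 1L)
  s$pool_b <- seq.int(n_hidden + n_output / 2, n_hidden + n_output - 1L)
  class(s) <- "classifier_spec"
  s
}

#' Build the classifier device configuration
#'
#' Wires, per hidden neuron, `inputs_per_hidden` distinct random input
#' columns on the programmable array (broadcast mode) with random
#' excitatory/inhibitory sign (probability 1/2) and random nonzero weight
#' level; wires every hidden neuron to every output neuron through the
#' plastic array in recurrent mode with all weights initialized at the
#' low state and learning enabled.
#'
#' @param spec A [classifier_spec()].
#' @return A [chip_config()].
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  cfg <- chip_config(
    neuron_types = list(neuron_params()),
    plasticity = plasticity_params(learning_enabled = TRUE,
                                   ca_jump = spec$ca_jump,
                                   dw_plus = spec$dw_plus,
                                   dw_minus = spec$dw_minus),
    std = std_params(std_enabled = FALSE),
    dpi = list(tau_nmda = 0.1, tau_ampa = 0.02, tau_gaba = 0.02,
               tau_virt = 0.02,
               jump_nmda = spec$gain_nmda, jump_ampa = spec$gain_ampa,
               jump_gaba = spec$gain_gaba, jump_virt = spec$gain_virt),
    virtual_w = list(exc = 1, inh = 1),
    seed = spec$seed)
  with_seed(spec$seed, {
    for (r in spec$hidden) {
      cols <- sample.int(N_NEURONS, spec$inputs_per_hidden) # 1-based
      sign_exc <- stats::runif(spec$inputs_per_hidden) < 0.5
      lvl <- sample(1:3, spec$inputs_per_hidden, replace = TRUE)
      cfg$stp$bc_en[r + 1L, cols] <- TRUE
      cfg$stp$is_exc[r + 1L, cols] <- sign_exc
      cfg$stp$weight_level[r + 1L, cols] <- lvl
    }
  })
  out_rows <- c(spec$pool_a, spec$pool_b) + 1L
  hid_cols <- spec$hidden + 1L
  cfg$ltp$rec_en[out_rows, hid_cols] <- TRUE
  cfg$ltp$w[out_rows, hid_cols] <- cfg$plasticity$w_min
  cfg
}

#' Train and test the on-chip classifier
#'
#' Alternates presentations of the two scene classes.  During training
#' the teacher Poisson signal drives the class-matching output pool
#' through the virtual excitatory synapses, steering the stop-learning
#' plasticity of the hidden-to-output synapses; during testing no teacher
#' is given and each presentation is classified by the arg-max of the two
#' output-pool mean rates (equal rates, including both silent, count as
#' an abstention).
#'
#' @param cfg A configuration from [build_classifier()].
#' @param spec The matching [classifier_spec()].
#' @param scenes List of two [dvs_scene()] objects (class 1, class 2)
#'   with identical presentation/gap timing.
#' @param dt Integration step (s).
#' @param seed Seed stream for scene jitter and teacher trains.
#' @return An object of class `classifier_report`: per-presentation pool
#'   rates and decisions, test accuracy, abstention count, training-phase
#'   taught/untaught pool rates, the best single output neuron's test
#'   accuracy (optimal threshold rule), the fraction of high-state
#'   plastic weights per pool, and the trained configuration.
#' @export
train_and_test <- function(cfg, spec, scenes, dt = 1e-4, seed = spec$seed) {
  stopifnot(inherits(spec, "classifier_spec"), length(scenes) == 2)
  pres_s <- scenes[[1]]$presentation_s
  gap_s <- scenes[[1]]$saccade_gap_s
  if (!isTRUE(all.equal(pres_s, scenes[[2]]$presentation_s)) ||
      !isTRUE(all.equal(gap_s, scenes[[2]]$saccade_gap_s)))
    stop("train_and_test: the two scenes must share presentation timing")
  slot <- pres_s + gap_s
  classes <- c(rep(c(1L, 2L), spec$n_train_per_class),
               rep(c(1L, 2L), spec$n_test_per_class))
  phase <- rep(c("train", "test"),
               c(2 * spec$n_train_per_class, 2 * spec$n_test_per_class))
  n_pres <- length(classes)
  t0s <- (seq_len(n_pres) - 1) * slot
  ev <- vector("list", 2 * n_pres)
  pool_of <- list(spec$pool_a, spec$pool_b)
  for (j in seq_len(n_pres)) {
    cl <- classes[j]
    ev[[2 * j - 1]] <- synth_dvs(scenes[[cl]], t0 = t0s[j],
                                 seed = seed + 1000L + j)
    if (phase[j] == "train")
      ev[[2 * j]] <- pool_poisson_events(pool_of[[cl]], spec$teacher_rate,
                                         t0s[j], t0s[j] + pres_s,
                                         seed = seed + 5000L + j)
  }
  events <- do.call(bind_events, ev)
  t_end <- n_pres * slot
  sim <- simulate_chip(cfg, events, t_end = t_end, dt = dt)
  spk <- sim$spikes
  rate_in <- function(ns, w) mean_rate(spk, ns, w)
  pres <- data.frame(phase = phase, class = classes, t0 = t0s,
                     t1 = t0s + pres_s)
  pres$rate_a <- mapply(function(a, b) rate_in(spec$pool_a, c(a, b)),
                        pres$t0, pres$t1)
  pres$rate_b <- mapply(function(a, b) rate_in(spec$pool_b, c(a, b)),
                        pres$t0, pres$t1)
  pres$decision <- ifelse(pres$rate_a > pres$rate_b, 1L,
                          ifelse(pres$rate_b > pres$rate_a, 2L, NA))
  pres$correct <- pres$decision == pres$class
  test <- pres[pres$phase == "test", ]
  accuracy <- sum(test$correct, na.rm = TRUE) / nrow(test)  # abstention = wrong
  ## training-phase rates of taught vs untaught pools
  tr <- pres[pres$phase == "train", ]
  taught <- mean(ifelse(tr$class == 1L, tr$rate_a, tr$rate_b))
  untaught <- mean(ifelse(tr$class == 1L, tr$rate_b, tr$rate_a))
  ## best single output neuron on the test presentations (optimal
  ## threshold, both polarities) -- the boosting comparison
  out_neurons <- c(spec$pool_a, spec$pool_b)
  win_len <- pres_s
  n_rates <- vapply(out_neurons, function(nn) {
    vapply(seq_len(nrow(test)), function(i)
      sum(spk$neuron == nn & spk$t >= test$t0[i] & spk$t < test$t1[i]) /
        win_len, numeric(1))
  }, numeric(nrow(test)))
  best_single <- 0
  truth_a <- test$class == 1L
  for (k in seq_len(ncol(n_rates))) {
    r <- n_rates[, k]
    for (thr in unique(r)) {
      acc1 <- mean((r >= thr) == truth_a)
      best_single <- max(best_single, acc1, 1 - acc1)
    }
  }
  wmat <- sim$config$ltp$w
  thw <- cfg$plasticity$theta_w
  frac_high <- function(rows) mean(wmat[rows + 1L, spec$hidden + 1L] >= thw)
  out <- list(presentations = pres, accuracy = accuracy,
              n_test = nrow(test), abstentions = sum(is.na(test$decision)),
              train_rate_taught = taught, train_rate_untaught = untaught,
              best_single_neuron_accuracy = best_single,
              frac_high_a = frac_high(spec$pool_a),
              frac_high_b = frac_high(spec$pool_b),
              config = sim$config, counters = sim$counters)
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  cat(sprintf("  test accuracy: %.1f%% (%d presentations, %d abstentions)\n",
              100 * x$accuracy, x$n_test, x$abstentions))
  cat(sprintf("  training pool rates: taught %.1f Hz, untaught %.1f Hz\n",
              x$train_rate_taught, x$train_rate_untaught))
  cat(sprintf("  best single output neuron: %.1f%%\n",
              100 * x$best_single_neuron_accuracy))
  cat(sprintf("  high-state plastic weights: pool A %.2f, pool B %.2f\n",
              x$frac_high_a, x$frac_high_b))
  invisible(x)
}
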