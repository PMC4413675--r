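## Clock-driven master loop.  Within each time step the ordering is fixed
## and documented: (1) configuration events, (2) recurrent fan-out of the
## previous step's output spikes (one-step axonal delay, avoiding
## same-step causal loops), (3) external spike deliveries (LTP array, then
## STP array, then virtual synapses), (4) exponential decays of all row
## integrators and calcium traces, (5) neuron integration and spike
## detection, with simultaneous output spikes ordered by neuron index (the
## software stand-in for the output arbiter).  Plasticity jumps are
## evaluated at delivery time against the post-synaptic membrane/calcium
## from the end of the previous step, i.e. before the EPSC of the same
## pre-spike; the bistability drift and short-term depression recovery are
## applied lazily in closed form, which equals per-step application
## exactly.

#' Run the device simulation
#'
#' Clock-driven simulation of the full chip for a time-sorted input event
#' stream.  Deterministic: the same `(cfg, events, t_end, dt)` always
#' yields an identical output spike stream.
#'
#' @param cfg A [chip_config()].
#' @param events Input event data.frame (see [read_events()] for the
#'   format), or `NULL` for none.  Must be time-sorted with all times
#'   `<= t_end`.
#' @param t_end Simulated duration (s).
#' @param dt Integration step (s); default 0.1 ms.
#' @param record Optional trace specification: a list with `period`
#'   (sampling period, s) and any of `v`, `ca` (0-based neuron
#'   addresses), `rows` (0-based row addresses whose five row-integrator
#'   currents are sampled) and `w` (two-column matrix of 0-based
#'   `(row, col)` plastic-synapse addresses).
#'
#' @return An object of class `sim_result`: a list with `spikes`
#'   (data.frame `t`, `neuron`, time-sorted, ties in neuron order),
#'   `traces` (sampled state, or `NULL`), `counters` (input events,
#'   synapse deliveries, output spikes), `config` (the configuration with
#'   final plastic weights and depression states written back), `state`
#'   (final neuron state vectors), `t_end` and `dt`.
#' @export
simulate_chip <- function(cfg, events = NULL, t_end, dt = 1e-4,
                          record = NULL) {
  stopifnot(inherits(cfg, "chip_config"))
  if (dt <= 0) stop("simulate_chip: dt must be > 0")
  if (t_end <= 0) stop("simulate_chip: t_end must be > 0")
  if (is.null(events)) events <- empty_events()
  validate_events(events, "simulate_chip")
  n_ev <- nrow(events)
  if (n_ev > 0 && max(events$t_us) * 1e-6 > t_end + 1e-12)
    stop("simulate_chip: event times exceed t_end")
  n_steps <- as.integer(ceiling(round(t_end / dt, 6)))
  N <- N_NEURONS

  ## --- static per-neuron parameter vectors -------------------------------
  types <- cfg$neuron_types
  tix <- cfg$neuron_type
  pv <- function(f) vapply(types, `[[`, numeric(1), f)[tix]
  tau_m <- pv("tau_mem"); tref <- pv("t_ref")
  gl <- pv("leak_conductance") * cfg$mismatch
  rest <- pv("rest_level"); dT <- pv("exp_slope")
  vT <- pv("exp_threshold"); vpeak <- pv("peak_level")
  vreset <- pv("reset_level"); ahp_b <- pv("ahp_b"); ahp_tau <- pv("ahp_tau")
  nmda_thr <- pv("nmda_gate_threshold")
  nmda_en <- vapply(types, `[[`, logical(1), "nmda_gate_enabled")[tix]
  any_nmda_gate <- any(nmda_en)
  cm <- tau_m * gl
  sthr <- ifelse(dT > 0, vpeak, vT)
  has_exp <- dT > 0
  dahp <- exp(-dt / ahp_tau)

  pl <- cfg$plasticity
  th_mem <- pl$theta_mem; th1 <- pl$theta1; th2 <- pl$theta2; th3 <- pl$theta3
  dwp <- pl$dw_plus; dwm <- pl$dw_minus
  thw <- pl$theta_w; cdu <- pl$c_drift_up; cdd <- pl$c_drift_dn
  wmin <- pl$w_min; wmax <- pl$w_max
  jmax <- pl$j_max; thj <- pl$theta_j
  hard_eff <- pl$efficacy_form == "hard"
  sslope <- pl$sigmoid_slope
  learn_on <- pl$learning_enabled
  ca_jump <- pl$ca_jump
  dca <- exp(-dt / pl$ca_tau)

  dpi <- cfg$dpi
  dnm <- exp(-dt / dpi$tau_nmda); dam <- exp(-dt / dpi$tau_ampa)
  dga <- exp(-dt / dpi$tau_gaba); dvi <- exp(-dt / dpi$tau_virt)
  jn <- dpi$jump_nmda; ja <- dpi$jump_ampa
  jg <- dpi$jump_gaba; jv <- dpi$jump_virt
  vw_exc <- cfg$virtual_w$exc; vw_inh <- cfg$virtual_w$inh

  std_on <- cfg$std$std_enabled
  d_dep <- cfg$std$depress_amount
  rtau <- cfg$std$recovery_tau

  ## --- mutable device state ---------------------------------------------
  lw <- cfg$ltp$w
  col_t <- numeric(N)                      # last drift time per LTP column
  stp_lvl <- cfg$stp$weight_level
  stp_exc <- cfg$stp$is_exc
  wE <- (stp_lvl / 3) * cfg$w_unit * stp_exc          # excitatory weights
  wI <- (stp_lvl / 3) * cfg$w_unit * (!stp_exc)       # inhibitory weights
  std_x <- cfg$stp$std_x
  std_t <- matrix(0, N, N)
  ltp_rec <- cfg$ltp$rec_en; ltp_bc <- cfg$ltp$bc_en
  stp_rec <- cfg$stp$rec_en; stp_bc <- cfg$stp$bc_en
  ltp_rec_rows <- lapply(seq_len(N), function(c) which(ltp_rec[, c]))
  ltp_bc_rows <- lapply(seq_len(N), function(c) which(ltp_bc[, c]))
  stp_rec_rows <- lapply(seq_len(N), function(c) which(stp_rec[, c]))
  stp_bc_rows <- lapply(seq_len(N), function(c) which(stp_bc[, c]))

  f_demux <- cfg$demux_factor
  owner1 <- ((seq_len(N) - 1L) %/% f_demux) * f_demux + 1L
  act <- logical(N); act[seq.int(1L, N, by = f_demux)] <- TRUE
  uo1 <- seq.int(1L, N, by = f_demux)

  v <- rest; i_ahp <- numeric(N); ca <- numeric(N); ref_until <- rep(-Inf, N)
  i_nmda <- numeric(N); i_ampa <- numeric(N); i_gaba <- numeric(N)
  i_ve <- numeric(N); i_vi <- numeric(N)

  n_deliv <- 0L

  ## --- parse events ------------------------------------------------------
  if (n_ev > 0) {
    ev_step <- pmax(1L, pmin(n_steps,
                             as.integer(floor(events$t_us * 1e-6 / dt)) + 1L))
    ev_code <- match(events$kind, EVENT_KINDS)  # DIR BCAST VIRT CFG_L CFG_G OUT
    ev_arr <- integer(n_ev); ev_x <- integer(n_ev); ev_y <- integer(n_ev)
    sel <- ev_code %in% c(1L, 2L)
    if (any(sel)) {
      arr <- match(events$a1[sel], c("ltp", "stp"))
      if (anyNA(arr))
        stop("simulate_chip: unknown array in event record ",
             which(sel)[which(is.na(arr))[1]])
      ev_arr[sel] <- arr
    }
    dsel <- ev_code == 1L
    if (any(dsel)) {
      r <- as.integer(events$a2[dsel]); c <- as.integer(events$a3[dsel])
      if (anyNA(r) || anyNA(c) || any(r < 0 | r >= N | c < 0 | c >= N))
        stop("simulate_chip: direct event address out of range")
      ev_x[dsel] <- r + 1L; ev_y[dsel] <- c + 1L
    }
    bsel <- ev_code == 2L
    if (any(bsel)) {
      c <- as.integer(events$a2[bsel])
      if (anyNA(c) || any(c < 0 | c >= N))
        stop("simulate_chip: broadcast column out of range")
      ev_y[bsel] <- c + 1L
    }
    vsel <- ev_code == 3L
    if (any(vsel)) {
      r <- as.integer(events$a1[vsel])
      ty <- match(events$a2[vsel], c("exc", "inh"))
      if (anyNA(r) || any(r < 0 | r >= N) || anyNA(ty))
        stop("simulate_chip: bad virtual-synapse event")
      ev_x[vsel] <- r + 1L; ev_y[vsel] <- ty
    }
    osel <- ev_code == 6L
    if (any(osel)) {
      k <- as.integer(events$a1[osel])
      if (anyNA(k) || any(k < 0 | k >= N))
        stop("simulate_chip: OUT neuron out of range")
      ev_x[osel] <- k + 1L
    }
  }

  ## --- recording ---------------------------------------------------------
  rec_on <- !is.null(record)
  if (rec_on) {
    rp <- max(1L, as.integer(round((record$period %||% dt) / dt)))
    rv <- as.integer(record$v %||% integer(0)) + 1L
    rca <- as.integer(record$ca %||% integer(0)) + 1L
    rrows <- as.integer(record$rows %||% integer(0)) + 1L
    rw <- record$w
    if (!is.null(rw)) rw <- cbind(as.integer(rw[, 1]), as.integer(rw[, 2]))
    n_samp <- n_steps %/% rp
    tr_time <- numeric(n_samp)
    tr_v <- matrix(NA_real_, n_samp, length(rv))
    tr_ca <- matrix(NA_real_, n_samp, length(rca))
    tr_dpi <- if (length(rrows))
      array(NA_real_, c(n_samp, length(rrows), 5),
            dimnames = list(NULL, NULL,
                            c("nmda", "ampa", "gaba", "virt_exc",
                              "virt_inh")))
    else NULL
    tr_w <- if (!is.null(rw)) matrix(NA_real_, n_samp, nrow(rw)) else NULL
    samp_i <- 0L
  }

  spk_t <- vector("list", 4096L); spk_n <- vector("list", 4096L)
  spk_chunks <- 0L
  prev_spk <- integer(0)                  # 1-based neuron indices
  ev_ptr <- 1L

  ## local delivery helpers (operate on enclosing state via <<-) ----------
  deliver_ltp <- function(rows1, c1, t) {
    dtd <- t - col_t[c1]
    if (dtd > 0) {
      colw <- lw[, c1]
      up <- colw > thw; dn <- colw < thw
      colw[up] <- pmin(colw[up] + cdu * dtd, wmax)
      colw[dn] <- pmax(colw[dn] - cdd * dtd, wmin)
      lw[, c1] <<- colw
      col_t[c1] <<- t
    }
    wcol <- lw[rows1, c1]
    if (learn_on) {
      post <- owner1[rows1]
      vp <- v[post]; cp <- ca[post]
      up <- vp > th_mem & cp > th1 & cp < th3
      dn <- vp < th_mem & cp > th1 & cp < th2
      if (any(up) || any(dn)) {
        wcol <- pmin(pmax(wcol + dwp * up - dwm * dn, wmin), wmax)
        lw[rows1, c1] <<- wcol
      }
    }
    eff <- if (hard_eff) jmax * (wcol >= thj)
           else jmax * stats::plogis((wcol - thj) / sslope)
    i_nmda[rows1] <<- i_nmda[rows1] + jn * eff
    n_deliv <<- n_deliv + length(rows1)
  }

  deliver_stp <- function(rows1, c1, t) {
    idx <- rows1 + (c1 - 1L) * N
    if (std_on) {
      exc_i <- stp_exc[idx]
      if (any(exc_i)) {
        ie <- idx[exc_i]
        sx <- 1 + (std_x[ie] - 1) * exp(-(t - std_t[ie]) / rtau)
        i_ampa[rows1[exc_i]] <<- i_ampa[rows1[exc_i]] + ja * wE[ie] * sx
        std_x[ie] <<- pmax(sx - d_dep, 0)
        std_t[ie] <<- t
      }
      if (any(!exc_i)) {
        ii <- idx[!exc_i]
        i_gaba[rows1[!exc_i]] <<- i_gaba[rows1[!exc_i]] + jg * wI[ii]
      }
    } else {
      i_ampa[rows1] <<- i_ampa[rows1] + ja * wE[idx]
      i_gaba[rows1] <<- i_gaba[rows1] + jg * wI[idx]
    }
    n_deliv <<- n_deliv + length(rows1)
  }

  apply_cfg_local <- function(i) {
    arr <- events$a1[i]
    addr <- as.integer(events$a2[i])
    if (is.na(addr) || addr < 0 || addr >= N * N)
      stop("simulate_chip: config address out of range at event ", i)
    r <- addr %/% N + 1L; c <- addr %% N + 1L
    kv <- parse_local_payload(events$a3[i])
    on_bit <- kv$value %in% c("1", "TRUE", "true")
    if (arr == "stp") {
      switch(kv$field,
        weight_level = stp_lvl[r, c] <<- as.integer(kv$value),
        exc = stp_exc[r, c] <<- on_bit,
        bc_en = {
          stp_bc[r, c] <<- on_bit
          stp_bc_rows[[c]] <<- which(stp_bc[, c])
        },
        rec_en = {
          stp_rec[r, c] <<- on_bit
          stp_rec_rows[[c]] <<- which(stp_rec[, c])
        },
        mon_en = invisible(NULL),
        stop("simulate_chip: unknown STP latch '", kv$field, "'"))
      wE[r, c] <<- (stp_lvl[r, c] / 3) * cfg$w_unit * stp_exc[r, c]
      wI[r, c] <<- (stp_lvl[r, c] / 3) * cfg$w_unit * !stp_exc[r, c]
    } else if (arr == "ltp") {
      switch(kv$field,
        bc_en = {
          ltp_bc[r, c] <<- on_bit
          ltp_bc_rows[[c]] <<- which(ltp_bc[, c])
        },
        rec_en = {
          ltp_rec[r, c] <<- on_bit
          ltp_rec_rows[[c]] <<- which(ltp_rec[, c])
        },
        mon_en = invisible(NULL),
        set_hi = if (on_bit) lw[r, c] <<- wmax,
        set_low = if (on_bit) lw[r, c] <<- wmin,
        stop("simulate_chip: unknown LTP latch '", kv$field, "'"))
    } else stop("simulate_chip: unknown array in config event ", i)
  }

  ## --- main loop ---------------------------------------------------------
  for (step in seq_len(n_steps)) {
    t <- (step - 1L) * dt

    ## (1) configuration events, (3') collect this step's drive events
    ii <- integer(0)
    if (n_ev > 0 && ev_ptr <= n_ev && ev_step[ev_ptr] <= step) {
      first <- ev_ptr
      while (ev_ptr <= n_ev && ev_step[ev_ptr] <= step) ev_ptr <- ev_ptr + 1L
      ii <- first:(ev_ptr - 1L)
      cfg_i <- ii[ev_code[ii] >= 4L & ev_code[ii] <= 5L]
      for (i in cfg_i) {
        if (ev_code[i] == 5L) {
          kv <- parse_local_payload(events$a1[i])
          if (kv$field == "demux_factor") {
            f_demux <- as.integer(kv$value); check_demux(f_demux)
            owner1 <- ((seq_len(N) - 1L) %/% f_demux) * f_demux + 1L
            act <- logical(N); act[seq.int(1L, N, by = f_demux)] <- TRUE
            uo1 <- seq.int(1L, N, by = f_demux)
          } else if (grepl("^neuron_type_[0-9]+$", kv$field)) {
            stop("simulate_chip: neuron type changes are not supported ",
                 "at run time; set them in chip_config()")
          } else stop("simulate_chip: unknown global register '",
                      kv$field, "'")
        } else apply_cfg_local(i)
      }
      ii <- ii[ev_code[ii] < 4L | ev_code[ii] == 6L]
    }

    ## (2) recurrent fan-out of previous step's spikes
    if (length(prev_spk)) {
      for (k1 in prev_spk) {
        rows1 <- ltp_rec_rows[[k1]]
        if (length(rows1)) deliver_ltp(rows1, k1, t)
        rows1 <- stp_rec_rows[[k1]]
        if (length(rows1)) deliver_stp(rows1, k1, t)
      }
      prev_spk <- integer(0)
    }

    ## (3) external deliveries: LTP, then STP, then virtual
    if (length(ii)) {
      for (i in ii) {
        code <- ev_code[i]
        if (code == 1L) {                      # direct
          if (ev_arr[i] == 1L) deliver_ltp(ev_x[i], ev_y[i], t)
          else deliver_stp(ev_x[i], ev_y[i], t)
        } else if (code == 2L) {               # broadcast
          if (ev_arr[i] == 1L) {
            rows1 <- ltp_bc_rows[[ev_y[i]]]
            if (length(rows1)) deliver_ltp(rows1, ev_y[i], t)
          } else {
            rows1 <- stp_bc_rows[[ev_y[i]]]
            if (length(rows1)) deliver_stp(rows1, ev_y[i], t)
          }
        } else if (code == 3L) {               # virtual synapse
          if (ev_y[i] == 1L)
            i_ve[ev_x[i]] <- i_ve[ev_x[i]] + jv * vw_exc
          else
            i_vi[ev_x[i]] <- i_vi[ev_x[i]] + jv * vw_inh
          n_deliv <- n_deliv + 1L
        } else {                               # OUT: recurrent source
          k1 <- ev_x[i]
          rows1 <- ltp_rec_rows[[k1]]
          if (length(rows1)) deliver_ltp(rows1, k1, t)
          rows1 <- stp_rec_rows[[k1]]
          if (length(rows1)) deliver_stp(rows1, k1, t)
        }
      }
    }

    ## (4) decays
    i_nmda <- i_nmda * dnm; i_ampa <- i_ampa * dam; i_gaba <- i_gaba * dga
    i_ve <- i_ve * dvi; i_vi <- i_vi * dvi
    ca <- ca * dca
    i_ahp <- i_ahp * dahp

    ## (5) neuron integration
    if (f_demux == 1L) {
      e_n <- i_ampa + i_ve; n_n <- i_nmda; g_n <- i_gaba + i_vi
    } else {
      e_n <- numeric(N); n_n <- numeric(N); g_n <- numeric(N)
      e_n[uo1] <- rowsum(i_ampa + i_ve, owner1, reorder = FALSE)
      n_n[uo1] <- rowsum(i_nmda, owner1, reorder = FALSE)
      g_n[uo1] <- rowsum(i_gaba + i_vi, owner1, reorder = FALSE)
    }
    if (any_nmda_gate)
      n_n <- n_n * ifelse(nmda_en, v > nmda_thr, TRUE)
    i_syn <- n_n + e_n - g_n
    ed <- numeric(N)
    if (any(has_exp))
      ed[has_exp] <- gl[has_exp] * dT[has_exp] *
        exp(pmin((v[has_exp] - vT[has_exp]) / dT[has_exp], EXP_ARG_MAX))
    dv <- (-gl * (v - rest) + ed - i_ahp + i_syn) / cm
    in_ref <- t < ref_until
    v <- v + dv * dt
    v[in_ref] <- vreset[in_ref]
    v[!act] <- rest[!act]
    spk <- act & !in_ref & v >= sthr
    if (any(spk)) {
      ks <- which(spk)
      v[ks] <- vreset[ks]
      i_ahp[ks] <- i_ahp[ks] + ahp_b[ks]
      ca[ks] <- ca[ks] + ca_jump
      ref_until[ks] <- t + tref[ks]
      spk_chunks <- spk_chunks + 1L
      if (spk_chunks > length(spk_t)) {
        length(spk_t) <- 2L * spk_chunks
        length(spk_n) <- 2L * spk_chunks
      }
      spk_t[[spk_chunks]] <- rep.int(t, length(ks))
      spk_n[[spk_chunks]] <- ks - 1L
      prev_spk <- ks
    }

    if (rec_on && step %% rp == 0L) {
      samp_i <- samp_i + 1L
      tr_time[samp_i] <- step * dt
      if (length(rv)) tr_v[samp_i, ] <- v[rv]
      if (length(rca)) tr_ca[samp_i, ] <- ca[rca]
      if (!is.null(tr_dpi)) {
        tr_dpi[samp_i, , 1] <- i_nmda[rrows]
        tr_dpi[samp_i, , 2] <- i_ampa[rrows]
        tr_dpi[samp_i, , 3] <- i_gaba[rrows]
        tr_dpi[samp_i, , 4] <- i_ve[rrows]
        tr_dpi[samp_i, , 5] <- i_vi[rrows]
      }
      if (!is.null(tr_w)) {
        tt <- step * dt
        wq <- lw[rw + 1L]            # matrix index (row, col), 1-based
        dtd <- tt - col_t[rw[, 2] + 1L]
        up <- wq > thw; dn <- wq < thw
        wq[up] <- pmin(wq[up] + cdu * dtd[up], wmax)
        wq[dn] <- pmax(wq[dn] - cdd * dtd[dn], wmin)
        tr_w[samp_i, ] <- wq
      }
    }

    if (step %% 1024L == 0L && any(!is.finite(v)))
      stop("simulate_chip: non-finite membrane state at t = ", t,
           " (neurons ", paste(which(!is.finite(v)) - 1L, collapse = ", "),
           "); reduce dt or input weights")
  }

  ## finalize lazy state
  for (c1 in seq_len(N)) {
    dtd <- t_end - col_t[c1]
    if (dtd > 0) {
      colw <- lw[, c1]
      up <- colw > thw; dn <- colw < thw
      colw[up] <- pmin(colw[up] + cdu * dtd, wmax)
      colw[dn] <- pmax(colw[dn] - cdd * dtd, wmin)
      lw[, c1] <- colw
    }
  }
  if (std_on) std_x <- 1 + (std_x - 1) * exp(-(t_end - std_t) / rtau)

  cfg$ltp$w <- lw
  cfg$stp$weight_level <- stp_lvl
  cfg$stp$is_exc <- stp_exc
  cfg$stp$std_x <- std_x
  cfg$stp$rec_en <- stp_rec; cfg$stp$bc_en <- stp_bc
  cfg$ltp$rec_en <- ltp_rec; cfg$ltp$bc_en <- ltp_bc
  cfg$demux_factor <- f_demux

  if (spk_chunks > 0L) {
    spikes <- data.frame(t = unlist(spk_t[seq_len(spk_chunks)]),
                         neuron = unlist(spk_n[seq_len(spk_chunks)]))
  } else {
    spikes <- data.frame(t = numeric(0), neuron = integer(0))
  }

  traces <- NULL
  if (rec_on) {
    keep <- seq_len(samp_i)
    traces <- list(time = tr_time[keep],
                   v = tr_v[keep, , drop = FALSE],
                   ca = tr_ca[keep, , drop = FALSE],
                   dpi = if (!is.null(tr_dpi)) tr_dpi[keep, , , drop = FALSE],
                   w = if (!is.null(tr_w)) tr_w[keep, , drop = FALSE])
  }

  res <- list(spikes = spikes, traces = traces,
              counters = list(n_events_in = n_ev,
                              n_deliveries = n_deliv,
                              n_output_spikes = nrow(spikes)),
              config = cfg,
              state = list(v = v, i_ahp = i_ahp, ca = ca,
                           ref_until = ref_until),
              t_end = t_end, dt = dt)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  cat(sprintf("  %g s simulated at dt = %g s\n", x$t_end, x$dt))
  cat(sprintf("  %d input events, %d synapse deliveries, %d output spikes from %d neurons\n",
              x$counters$n_events_in, x$counters$n_deliveries,
              x$counters$n_output_spikes,
              length(unique(x$spikes$neuron))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert output spikes to an event stream
#'
#' @param sim A [simulate_chip()] result.
#' @return An event data.frame of `OUT` records.
#' @export
spikes_as_events <- function(sim) {
  if (nrow(sim$spikes) == 0) return(empty_events())
  events_out(sim$spikes$t, sim$spikes$neuron)
}
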