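## Device-level model: the 256-neuron row, the two 256x256 synapse arrays,
## the per-row virtual synapses, the synapse de-multiplexer, address-event
## routing and the clock-driven master loop.  All synapse/neuron addresses
## in the public interface are 0-based, matching the address-event
## convention; R matrices inside are 1-based.

N_NEURONS <- 256L

#' Full device configuration
#'
#' Holds the complete programmable state of the simulated device: the
#' long-term-plasticity (LTP) array (bistable weights + latches), the
#' short-term-plasticity (STP) array (2-bit weights, excitatory/inhibitory
#' and activation latches), the per-row virtual-synapse weights, the
#' synapse de-multiplexer factor, per-neuron type assignments (at most 4
#' parameter sets, mirroring the two leak x two refractory latch options),
#' and all module parameter sets.
#'
#' @param neuron_types List of up to 4 [neuron_params()] sets.
#' @param neuron_type Integer vector of length 256 assigning each neuron a
#'   type (1-based index into `neuron_types`).
#' @param plasticity A [plasticity_params()].
#' @param std An [std_params()].
#' @param dpi Named list of row-integrator constants: `tau_nmda`,
#'   `tau_ampa`, `tau_gaba`, `tau_virt` (s) and the per-spike charge
#'   scales `jump_nmda`, `jump_ampa`, `jump_gaba`, `jump_virt`.
#' @param virtual_w Named list with the fixed virtual-synapse weights
#'   `exc` and `inh`.
#' @param w_unit Full-scale weight of the STP two-bit DAC.
#' @param demux_factor Synapse de-multiplexer factor, a power of two in
#'   `1..256`; with factor `F`, neuron `k*F` owns synapse rows
#'   `[k*F, (k+1)*F)` and the other neurons are disconnected.
#' @param mismatch_cv Coefficient of variation of optional log-normal
#'   per-neuron parameter jitter emulating device mismatch (applied to
#'   the leak conductance; `0` disables it).
#' @param seed Integer seed (used only by the mismatch jitter).
#'
#' @return An object of class `chip_config`.
#' @seealso [set_demux()], [apply_config_event()], [simulate_chip()]
#' @export
chip_config <- function(neuron_types = list(neuron_params()),
                        neuron_type = rep(1L, N_NEURONS),
                        plasticity = plasticity_params(),
                        std = std_params(),
                        dpi = list(tau_nmda = 0.1, tau_ampa = 0.02,
                                   tau_gaba = 0.02, tau_virt = 0.02,
                                   jump_nmda = 1, jump_ampa = 1,
                                   jump_gaba = 1, jump_virt = 1),
                        virtual_w = list(exc = 1, inh = 1),
                        w_unit = 1,
                        demux_factor = 1L,
                        mismatch_cv = 0,
                        seed = 1L) {
  if (length(neuron_types) < 1 || length(neuron_types) > 4)
    stop("chip_config: between 1 and 4 neuron types are expressible")
  for (nt in neuron_types) validate_neuron_params(nt)
  if (length(neuron_type) != N_NEURONS ||
      any(!neuron_type %in% seq_along(neuron_types)))
    stop("chip_config: neuron_type must index neuron_types for all 256 ",
         "neurons")
  validate_plasticity_params(plasticity)
  need <- c("tau_nmda", "tau_ampa", "tau_gaba", "tau_virt",
            "jump_nmda", "jump_ampa", "jump_gaba", "jump_virt")
  if (!all(need %in% names(dpi)))
    stop("chip_config: dpi must name ", paste(need, collapse = ", "))
  if (any(unlist(dpi[paste0("tau_", c("nmda", "ampa", "gaba", "virt"))]) <= 0))
    stop("chip_config: DPI time constants must be > 0")
  check_demux(demux_factor)
  lg <- function() matrix(FALSE, N_NEURONS, N_NEURONS)
  mismatch <- rep(1, N_NEURONS)
  if (mismatch_cv > 0) {
    sdlog <- sqrt(log(1 + mismatch_cv^2))
    mismatch <- with_seed(seed,
      stats::rlnorm(N_NEURONS, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  cfg <- list(
    n_neurons = N_NEURONS,
    ltp = list(w = matrix(plasticity$w_min, N_NEURONS, N_NEURONS),
               rec_en = lg(), bc_en = lg(), mon_en = lg()),
    stp = list(weight_level = matrix(0L, N_NEURONS, N_NEURONS),
               is_exc = matrix(TRUE, N_NEURONS, N_NEURONS),
               rec_en = lg(), bc_en = lg(), mon_en = lg(),
               std_x = matrix(1, N_NEURONS, N_NEURONS)),
    virtual_w = virtual_w,
    w_unit = w_unit,
    demux_factor = as.integer(demux_factor),
    neuron_types = neuron_types,
    neuron_type = as.integer(neuron_type),
    plasticity = plasticity,
    std = std,
    dpi = dpi,
    mismatch = mismatch,
    seed = as.integer(seed)
  )
  class(cfg) <- "chip_config"
  cfg
}

check_demux <- function(f) {
  ok <- f %in% 2^(0:8)
  if (!ok)
    stop("demux factor must be a power of two in 1..256 (got ", f, ")",
         call. = FALSE)
  invisible(f)
}

#' @export
print.chip_config <- function(x, ...) {
  f <- x$demux_factor
  cat("<chip_config>\n")
  cat(sprintf("  256 neurons (%d type%s), demux factor %d -> %d active neuron%s, %d synapse elements each\n",
              length(x$neuron_types),
              if (length(x$neuron_types) > 1) "s" else "", f,
              N_NEURONS %/% f, if (f == 1) "s" else "", f * 512L))
  cat(sprintf("  LTP array: %d recurrent, %d broadcast-enabled, %d at high state\n",
              sum(x$ltp$rec_en), sum(x$ltp$bc_en),
              sum(x$ltp$w >= x$plasticity$theta_w)))
  cat(sprintf("  STP array: %d recurrent, %d broadcast-enabled, %d nonzero weights (%d inhibitory)\n",
              sum(x$stp$rec_en), sum(x$stp$bc_en),
              sum(x$stp$weight_level > 0), sum(!x$stp$is_exc)))
  cat(sprintf("  learning %s, STD %s, seed %d\n",
              if (x$plasticity$learning_enabled) "enabled" else "frozen",
              if (x$std$std_enabled) "enabled" else "disabled", x$seed))
  invisible(x)
}

#' Set the synapse de-multiplexer factor
#'
#' With factor `F` only neurons `0, F, 2F, ...` remain connected; each
#' active neuron owns the `F` consecutive synapse rows starting at its own
#' index (so `F * 512` synapse elements across the two arrays).  Inactive
#' neurons receive no current and never spike.
#'
#' @param cfg A [chip_config()].
#' @param f Power of two in `1..256`.
#' @return The updated configuration.
#' @export
set_demux <- function(cfg, f) {
  check_demux(f)
  cfg$demux_factor <- as.integer(f)
  cfg
}

#' Active neurons and row ownership under the de-multiplexer
#'
#' @param cfg A [chip_config()].
#' @return `active_neurons()`: 0-based addresses of connected neurons.
#'   `row_owner()`: for each synapse row (0-based order), the 0-based
#'   address of the neuron that integrates it.
#' @export
active_neurons <- function(cfg) {
  seq.int(0L, N_NEURONS - 1L, by = cfg$demux_factor)
}

#' @rdname active_neurons
#' @export
row_owner <- function(cfg) {
  f <- cfg$demux_factor
  ((seq_len(N_NEURONS) - 1L) %/% f) * f
}

parse_local_payload <- function(payload) {
  kv <- strsplit(payload, "=", fixed = TRUE)[[1]]
  if (length(kv) != 2)
    stop("apply_config_event: malformed local payload '", payload, "'",
         call. = FALSE)
  list(field = kv[1], value = kv[2])
}

#' Apply a configuration address-event
#'
#' Local configuration events (`CFG_L`) write one addressed element's
#' latches: `weight_level`, `exc`, `bc_en`, `rec_en`, `mon_en` and, for
#' the plastic array, `set_hi`/`set_low` (the SET block forcing the
#' bistable weight to its high/low state).  Global configuration events
#' (`CFG_G`) write peripheral registers: `demux_factor=<F>` and
#' `neuron_type_<i>=<k>`.  Out-of-range addresses and unknown payloads
#' are rejected.
#'
#' @param cfg A [chip_config()].
#' @param ev A single event (one-row data.frame or list with `kind`,
#'   `a1`, `a2`, `a3`).
#' @return The updated configuration.
#' @export
apply_config_event <- function(cfg, ev) {
  kind <- as.character(ev$kind)
  if (kind == "CFG_G") {
    kv <- parse_local_payload(as.character(ev$a1))
    if (kv$field == "demux_factor") {
      cfg <- set_demux(cfg, as.integer(kv$value))
    } else if (grepl("^neuron_type_[0-9]+$", kv$field)) {
      i <- as.integer(sub("^neuron_type_", "", kv$field))
      k <- as.integer(kv$value)
      if (i < 0 || i >= N_NEURONS)
        stop("apply_config_event: neuron address out of range: ", i)
      if (!k %in% seq_along(cfg$neuron_types))
        stop("apply_config_event: unknown neuron type ", k)
      cfg$neuron_type[i + 1L] <- k
    } else {
      stop("apply_config_event: unknown global register '", kv$field, "'")
    }
    return(cfg)
  }
  if (kind != "CFG_L")
    stop("apply_config_event: not a configuration event (kind ", kind, ")")
  array <- as.character(ev$a1)
  if (!array %in% c("ltp", "stp"))
    stop("apply_config_event: unknown array '", array, "'")
  addr <- as.integer(ev$a2)
  if (is.na(addr) || addr < 0 || addr >= N_NEURONS * N_NEURONS)
    stop("apply_config_event: address out of range: ", ev$a2)
  r <- addr %/% N_NEURONS + 1L
  c <- addr %% N_NEURONS + 1L
  kv <- parse_local_payload(as.character(ev$a3))
  val <- kv$value
  on_bit <- function(v) v %in% c("1", "TRUE", "true")
  if (array == "stp") {
    switch(kv$field,
      weight_level = {
        lvl <- as.integer(val)
        if (!lvl %in% 0:3)
          stop("apply_config_event: weight_level must be in {0,1,2,3}")
        cfg$stp$weight_level[r, c] <- lvl
      },
      exc = cfg$stp$is_exc[r, c] <- on_bit(val),
      bc_en = cfg$stp$bc_en[r, c] <- on_bit(val),
      rec_en = cfg$stp$rec_en[r, c] <- on_bit(val),
      mon_en = cfg$stp$mon_en[r, c] <- on_bit(val),
      stop("apply_config_event: unknown STP latch '", kv$field, "'")
    )
  } else {
    switch(kv$field,
      bc_en = cfg$ltp$bc_en[r, c] <- on_bit(val),
      rec_en = cfg$ltp$rec_en[r, c] <- on_bit(val),
      mon_en = cfg$ltp$mon_en[r, c] <- on_bit(val),
      set_hi = if (on_bit(val)) cfg$ltp$w[r, c] <- cfg$plasticity$w_max,
      set_low = if (on_bit(val)) cfg$ltp$w[r, c] <- cfg$plasticity$w_min,
      stop("apply_config_event: unknown LTP latch '", kv$field, "'")
    )
  }
  cfg
}

#' Route a spike address-event to its synapse targets
#'
#' Implements the three activation modes: a *direct* event stimulates
#' exactly the addressed element; a *broadcast* event stimulates every
#' synapse of the addressed column whose broadcast latch is set; a
#' *recurrent* source (an on-chip neuron spike, kind `OUT`) stimulates
#' every synapse of its own column whose recurrent latch is set, in both
#' arrays; a *virtual* event targets the addressed row's virtual
#' integrator.  Targets are returned in ascending row order (LTP array
#' before STP for recurrent sources), which is the deterministic stand-in
#' for the hardware arbiter.
#'
#' @param cfg A [chip_config()].
#' @param ev A single spike event (kind `DIR`, `BCAST`, `VIRT` or `OUT`).
#' @return A data.frame with columns `array` (`"ltp"`, `"stp"`,
#'   `"virt_exc"` or `"virt_inh"`), `row` and `col` (0-based; `col` is
#'   `NA` for virtual targets).
#' @export
route_event <- function(cfg, ev) {
  kind <- as.character(ev$kind)
  tgt <- function(array, row, col)
    data.frame(array = array, row = as.integer(row), col = as.integer(col),
               stringsAsFactors = FALSE)
  if (kind == "DIR") {
    array <- as.character(ev$a1)
    r <- as.integer(ev$a2); c <- as.integer(ev$a3)
    if (!array %in% c("ltp", "stp"))
      stop("route_event: unknown array '", array, "'")
    if (is.na(r) || is.na(c) || r < 0 || r >= N_NEURONS ||
        c < 0 || c >= N_NEURONS)
      stop("route_event: address out of range (", ev$a2, ",", ev$a3, ")")
    return(tgt(array, r, c))
  }
  if (kind == "BCAST") {
    array <- as.character(ev$a1)
    c <- as.integer(ev$a2)
    if (!array %in% c("ltp", "stp"))
      stop("route_event: unknown array '", array, "'")
    if (is.na(c) || c < 0 || c >= N_NEURONS)
      stop("route_event: column out of range: ", ev$a2)
    bc <- if (array == "ltp") cfg$ltp$bc_en else cfg$stp$bc_en
    rows <- which(bc[, c + 1L]) - 1L
    return(tgt(rep(array, length(rows)), rows, rep(c, length(rows))))
  }
  if (kind == "OUT") {
    k <- as.integer(ev$a1)
    if (is.na(k) || k < 0 || k >= N_NEURONS)
      stop("route_event: neuron out of range: ", ev$a1)
    rl <- which(cfg$ltp$rec_en[, k + 1L]) - 1L
    rs <- which(cfg$stp$rec_en[, k + 1L]) - 1L
    return(rbind(tgt(rep("ltp", length(rl)), rl, rep(k, length(rl))),
                 tgt(rep("stp", length(rs)), rs, rep(k, length(rs)))))
  }
  if (kind == "VIRT") {
    r <- as.integer(ev$a1)
    type <- as.character(ev$a2)
    if (is.na(r) || r < 0 || r >= N_NEURONS)
      stop("route_event: row out of range: ", ev$a1)
    if (!type %in% c("exc", "inh"))
      stop("route_event: virtual branch must be 'exc' or 'inh'")
    return(tgt(paste0("virt_", type), r, NA_integer_))
  }
  stop("route_event: not a spike event (kind ", kind, ")")
}
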