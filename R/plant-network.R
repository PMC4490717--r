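# Synthetic cultured-network plant: a doubly-stochastic Poisson population
# with a saturating blue-light dose-response, steep yellow-light suppression,
# multiplicative within-trial adaptation, a two-state aperiodic bursting
# envelope, slow log-normal excitability drift, and drug-condition modifiers.

#' Drug-condition modifiers for the network plant
#'
#' Synaptic-blockade conditions are applied as parameter modifiers: CNQX
#' (AMPAR blockade) scales spontaneous rate by 0.258 (-74.2%), AP5 (NMDAR
#' blockade) by 0.334 (-66.6%), and bicuculline (GABA-A blockade) by 4.57
#' (+357%) while capping the achievable driven rate at 5.1 Hz/unit.
#'
#' @param name One of `"none"`, `"CNQX"`, `"AP5"`, `"bicuculline"`.
#' @param spont_multiplier Override the default spontaneous-rate multiplier.
#' @param dose_max_override Override the saturated driven rate, Hz/unit
#'   (`NA` keeps the plant's own value).
#' @param burst_gain_multiplier Override the burst-amplitude multiplier.
#' @return An object of class `oc_drug_condition`.
#' @export
drug_condition <- function(name = c("none", "CNQX", "AP5", "bicuculline"),
                           spont_multiplier = NULL,
                           dose_max_override = NULL,
                           burst_gain_multiplier = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    none        = list(sm = 1,     dm = NA_real_, bm = 1),
    CNQX        = list(sm = 0.258, dm = NA_real_, bm = 0.1),
    AP5         = list(sm = 0.334, dm = NA_real_, bm = 0.3),
    bicuculline = list(sm = 4.57,  dm = 5.1,      bm = 2.5))
  structure(list(name = name,
                 spont_multiplier = spont_multiplier %||% defaults$sm,
                 dose_max_override = dose_max_override %||% defaults$dm,
                 burst_gain_multiplier = burst_gain_multiplier %||%
                   defaults$bm),
            class = "oc_drug_condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# time-averaged blue power (mW/mm^2) commanded by the pulse-train mapping
# at a given U_C: freq * width * peak power.
uc_mean_power <- function(U_C, power_coeff = 13.2) {
  (10 * U_C + 10) * (5 * U_C / 1000) * (power_coeff * U_C)
}

#' Parameters of the synthetic cultured-network plant
#'
#' The plant emits spikes from `n_units` units as an inhomogeneous Poisson
#' process with per-unit intensity
#' `lambda_i = (spont * env + g_i * E * D(b) * a) * S(y) * x`,
#' where `b` and `y` are low-pass-filtered blue/yellow power densities
#' (opsin kinetics), `D` is a Hill dose-response on the mean-power scale
#' calibrated so the population rate saturates at `dose_max` (12.5 Hz/unit)
#' at the drive equivalent of `U_C = dose_half`-scaled commands (saturation
#' near U_C = 0.47), `E = max(dose_max - spont_rate, 0)` scales the evoked
#' component, `S` is a monotone suppression reaching
#' `suppress_floor/spont_rate` at the yellow drive equivalent of
#' `U_H = 0.15`, `a` is a shared multiplicative adaptation state, `env` is a
#' two-state aperiodic bursting envelope with unit mean, `g_i` are static
#' log-normal unit gains with unit mean, and `x` is a slow log-normal
#' excitability process (within-trial Ornstein-Uhlenbeck drift times a
#' per-instance preparation factor).
#'
#' @param n_units Number of recorded units. Default 30.
#' @param spont_rate Spontaneous population rate, Hz/unit. Default 1.5.
#' @param dose_half `U_C` equivalent at half-maximal blue drive (Hill
#'   half-point on the commanded mean-power scale). Default 0.15.
#' @param dose_max Saturated driven population rate, Hz/unit. Default 12.5.
#' @param suppress_floor Fully suppressed rate, Hz/unit. Default 0.04.
#' @param suppress_half `U_H` equivalent at half suppression. Default 0.03.
#' @param hill_drive,hill_suppress Hill exponents of the drive and
#'   suppression curves. Defaults 2 and 3.
#' @param adapt_tau Adaptation recovery time constant, s. Default 60.
#' @param adapt_depth Fraction of drive lost at full adaptation, in
#'   `[0, 1)`. Default 0.3.
#' @param adapt_rate Adaptation onset rate at full drive, 1/s. Default 1/40.
#' @param burst_rate Burst rate, bursts/min. Default 8.
#' @param burst_gain Within-burst rate multiplier. Default 6.
#' @param burst_duration Mean burst duration, s. Default 0.2.
#' @param unit_gain_spread Coefficient of variation of the static per-unit
#'   gains. Default 0.5.
#' @param excit_sd Standard deviation (log scale) of the within-trial
#'   excitability drift. Default 0.15.
#' @param excit_tau Time constant of the excitability drift, s. Default 30.
#' @param instance_sd Standard deviation (log scale) of the per-instance
#'   preparation excitability factor drawn at plant creation. Default 0.1.
#' @param opsin_tau_blue,opsin_tau_yellow Opsin response time constants, s.
#'   Defaults 0.08 and 0.03.
#' @param net_tau Network recruitment/response time constant, s: the
#'   population rate follows changes in optical drive with this first-order
#'   lag (synaptic integration and recurrent recruitment). Default 0.15.
#' @param suppress_fade_tau Time constant (s of time-under-yellow-light) of
#'   the slow loss of suppression efficacy (chloride accumulation / pump
#'   desensitization). Default 7200 (negligible within 60-s trials).
#' @param yellow_max_power Yellow power density at `U_H = 1`, mW·mm^-2
#'   (used to place the suppression half-point). Default 10.8.
#' @param drug An `oc_drug_condition`. Default none.
#' @return An object of class `oc_network_params`.
#' @export
network_plant_params <- function(n_units = 30L, spont_rate = 1.5,
                                 dose_half = 0.15, dose_max = 12.5,
                                 suppress_floor = 0.04, suppress_half = 0.03,
                                 hill_drive = 2, hill_suppress = 3,
                                 adapt_tau = 60, adapt_depth = 0.3,
                                 adapt_rate = 1 / 40,
                                 burst_rate = 8, burst_gain = 6,
                                 burst_duration = 0.2,
                                 unit_gain_spread = 0.5,
                                 excit_sd = 0.15, excit_tau = 30,
                                 instance_sd = 0.1,
                                 opsin_tau_blue = 0.08,
                                 opsin_tau_yellow = 0.03,
                                 net_tau = 0.15,
                                 suppress_fade_tau = 7200,
                                 yellow_max_power = 10.8,
                                 drug = drug_condition("none")) {
  if (n_units < 1L) stop("`n_units` must be at least 1", call. = FALSE)
  if (adapt_depth < 0 || adapt_depth >= 1)
    stop("`adapt_depth` must lie in [0, 1)", call. = FALSE)
  p <- list(n_units = as.integer(n_units), spont_rate = spont_rate,
            dose_half = dose_half, dose_max = dose_max,
            suppress_floor = suppress_floor, suppress_half = suppress_half,
            hill_drive = hill_drive, hill_suppress = hill_suppress,
            adapt_tau = adapt_tau, adapt_depth = adapt_depth,
            adapt_rate = adapt_rate,
            burst_rate = burst_rate, burst_gain = burst_gain,
            burst_duration = burst_duration,
            unit_gain_spread = unit_gain_spread,
            excit_sd = excit_sd, excit_tau = excit_tau,
            instance_sd = instance_sd,
            opsin_tau_blue = opsin_tau_blue,
            opsin_tau_yellow = opsin_tau_yellow,
            net_tau = net_tau,
            suppress_fade_tau = suppress_fade_tau,
            yellow_max_power = yellow_max_power,
            drug = drug)
  if (any(unlist(p[c("spont_rate", "dose_max", "suppress_floor",
                     "burst_rate", "burst_gain")]) < 0))
    stop("rates and gains must be non-negative", call. = FALSE)
  structure(p, class = "oc_network_params")
}

#' Apply a drug condition to network-plant parameters
#'
#' Returns a modified copy of the parameters: spontaneous rate and burst
#' amplitude are scaled by the condition's multipliers and the saturated
#' driven rate is capped where the condition specifies one. The input is
#' left untouched.
#'
#' @param params An `oc_network_params`.
#' @param drug An `oc_drug_condition` or a condition name.
#' @return A new `oc_network_params`.
#' @export
apply_drug <- function(params, drug) {
  if (is.character(drug)) drug <- drug_condition(drug)
  if (!inherits(drug, "oc_drug_condition"))
    stop("`drug` must be an oc_drug_condition or a condition name",
         call. = FALSE)
  params$spont_rate <- params$spont_rate * drug$spont_multiplier
  params$burst_gain <- 1 + (params$burst_gain - 1) * drug$burst_gain_multiplier
  if (!is.na(drug$dose_max_override))
    params$dose_max <- min(params$dose_max, drug$dose_max_override)
  params$drug <- drug
  params
}

#' Create a synthetic cultured-network plant
#'
#' @param params An `oc_network_params`.
#' @return An object of class `oc_plant` (type `"network"`). Use
#'   [plant_init()] to draw its random state and [network_step()] to
#'   advance it.
#' @export
network_plant <- function(params = network_plant_params()) {
  structure(list(type = "network", params = params), class = "oc_plant")
}

#' Create a deterministic static-gain test plant
#'
#' A noise-free plant whose population rate is `g * U_C` exactly; the
#' engine drives it directly with the excitatory control variable. Used for
#' verifying the zero-steady-state-error property of integral action.
#'
#' @param g Static gain, Hz/unit per unit `U_C`. Must be positive.
#' @param n_units Nominal unit count. Default 1.
#' @return An object of class `oc_plant` (type `"static"`).
#' @export
static_gain_plant <- function(g, n_units = 1L) {
  if (g <= 0) stop("`g` must be positive", call. = FALSE)
  structure(list(type = "static", params = list(g = g,
                                                n_units = as.integer(n_units))),
            class = "oc_plant")
}

#' Initialize the random state of a plant
#'
#' Draws the plant's random structure (per-unit gains, preparation
#' excitability factor, initial burst state) using the current RNG stream.
#' Identical RNG state yields an identical plant.
#'
#' @param plant An `oc_plant`.
#' @param dt Simulation step, seconds, at which the state will be advanced.
#' @return An environment holding the mutable plant state.
#' @export
plant_init <- function(plant, dt = 0.001) {
  p <- plant$params
  st <- new.env(parent = emptyenv())
  st$dt <- dt
  st$t <- 0
  if (plant$type == "network") {
    cv <- p$unit_gain_spread
    sdlog <- sqrt(log(1 + cv^2))
    st$gains <- stats::rlnorm(p$n_units, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    st$instance <- stats::rlnorm(1, -p$instance_sd^2 / 2, p$instance_sd)
    st$z <- stats::rnorm(1, 0, p$excit_sd)   # OU log-excitability
    st$a <- 1                                 # shared adaptation state
    st$b <- 0; st$y <- 0                      # filtered light power
    st$yellow_exposure <- 0
    st$in_burst <- FALSE
    st$t_switch <- if (p$burst_rate > 0)
      stats::rexp(1, p$burst_rate / 60) else Inf
    # envelope baseline keeping the time-averaged envelope at 1
    duty <- min(0.5, (p$burst_rate / 60) * p$burst_duration)
    st$env_base <- max(0, (1 - p$burst_gain * duty) / (1 - duty))
    # lagged network response components (spontaneous and evoked)
    st$c_spont <- p$spont_rate
    st$c_evoked <- 0
    # precomputed constants
    st$K_drive <- uc_mean_power(p$dose_half)
    st$K_supp <- p$yellow_max_power * p$suppress_half
    st$ev_scale <- max(p$dose_max - p$spont_rate, 0)
    st$floor_frac <- if (p$spont_rate > 0)
      min(1, p$suppress_floor / p$spont_rate) else 0
    st$excit_steps <- max(1L, as.integer(round(0.01 / dt)))
    st$rho <- exp(-(st$excit_steps * dt) / p$excit_tau)
    st$k <- 0L
  } else if (plant$type == "tcu") {
    st$instance <- stats::rlnorm(1, -p$instance_sd^2 / 2, p$instance_sd)
    st$z <- stats::rnorm(1, 0, p$excit_sd)
    st$a <- 1
    st$b <- 0
    st$in_burst <- FALSE
    st$t_switch <- if (p$burst_rate > 0) stats::rexp(1, p$burst_rate) else Inf
    duty <- min(0.5, p$burst_rate * p$burst_duration)
    st$env_base <- max(0, (1 - p$burst_gain * duty) / (1 - duty))
    st$t_last_spike <- -Inf
    st$excit_steps <- max(1L, as.integer(round(0.01 / dt)))
    st$rho <- exp(-(st$excit_steps * dt) / p$excit_tau)
    st$k <- 0L
  }
  st
}

#' Advance the network plant by one simulation step
#'
#' @param state Plant state environment from [plant_init()] (mutated in
#'   place).
#' @param params The plant's `oc_network_params`.
#' @param blue_power Blue (465 nm) power density this step, mW·mm^-2.
#' @param yellow_power Yellow (590 nm) power density this step, mW·mm^-2.
#' @param dt Step length, seconds.
#' @return Integer vector of per-unit spike counts for this step.
#' @export
network_step <- function(state, params, blue_power, yellow_power, dt) {
  if (blue_power < 0 || yellow_power < 0)
    stop("light powers must be non-negative", call. = FALSE)
  p <- params
  st <- state
  # opsin kinetics: first-order response to delivered light
  st$b <- st$b + (blue_power - st$b) * dt / p$opsin_tau_blue
  st$y <- st$y + (yellow_power - st$y) * dt / p$opsin_tau_yellow
  # aperiodic bursting envelope (two-state, exponential dwell times)
  st$t <- st$t + dt
  if (st$t >= st$t_switch) {
    if (st$in_burst) {
      st$in_burst <- FALSE
      st$t_switch <- st$t + if (p$burst_rate > 0)
        stats::rexp(1, p$burst_rate / 60) else Inf
    } else {
      st$in_burst <- TRUE
      st$t_switch <- st$t + stats::rexp(1, 1 / p$burst_duration)
    }
  }
  env <- if (st$in_burst) p$burst_gain else st$env_base
  # slow excitability drift, updated on a coarser tick
  st$k <- st$k + 1L
  if (st$k %% st$excit_steps == 0L) {
    st$z <- st$z * st$rho +
      sqrt(1 - st$rho^2) * stats::rnorm(1, 0, p$excit_sd)
  }
  excit <- st$instance * exp(st$z - p$excit_sd^2 / 2)
  # saturating blue dose-response (Hill on the mean-power scale)
  hb <- if (st$b > 0)
    st$b^p$hill_drive / (st$b^p$hill_drive + st$K_drive^p$hill_drive) else 0
  # yellow suppression with slow efficacy fade under sustained light
  if (st$y > 1e-3) st$yellow_exposure <- st$yellow_exposure + dt
  fade <- exp(-st$yellow_exposure / p$suppress_fade_tau)
  ys <- st$y * fade
  S <- st$floor_frac + (1 - st$floor_frac) /
    (1 + (ys / st$K_supp)^p$hill_suppress)
  # shared multiplicative adaptation driven by the normalized blue drive
  floor_a <- 1 - p$adapt_depth
  st$a <- st$a + dt * ((1 - st$a) / p$adapt_tau -
                         p$adapt_rate * hb * (st$a - floor_a))
  st$a <- min(max(st$a, floor_a), 1)
  # the population follows drive changes with a network recruitment lag
  target_spont <- p$spont_rate * env * S * excit
  target_evoked <- st$ev_scale * hb * st$a * S * excit
  st$c_spont <- st$c_spont + (target_spont - st$c_spont) * dt / p$net_tau
  st$c_evoked <- st$c_evoked + (target_evoked - st$c_evoked) * dt / p$net_tau
  lam <- st$c_spont + st$gains * st$c_evoked
  stats::rpois(p$n_units, pmax(lam, 0) * dt)
}
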