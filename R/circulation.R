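## ---------------------------------------------------------------------------
## Closed-loop 0D circulation: time-varying-elastance left ventricle, passive
## left atrium, diode valves with instantaneous switching, systemic arterial
## windkessel, constant-pressure pulmonary-venous source and a lumped venous
## reservoir closing the loop.  Internal units: Pa, mL, s.
## ---------------------------------------------------------------------------

#' Parameters of the 0D circulation surrogate
#'
#' Defaults are calibrated so a two-beat physiological (PH) run reproduces
#' resting left-heart biomarkers: stroke volume ~83 mL, ejection fraction
#' ~54%, peak LV pressure ~125 mmHg, peak aortic flow ~560 mL/s, peak
#' pulmonary-vein inflow ~270 mL/s and systemic arterial pressure
#' ~103/80 mmHg.
#'
#' @param T_hb heartbeat period, s.
#' @param E_max,E_min maximal/minimal LV elastance, Pa/mL.
#' @param V0_LV LV unstressed volume, mL.
#' @param act_m1,act_m2,act_tau1,act_tau2 double-Hill activation shape
#'   exponents and time constants (tau in fractions of `T_hb`).
#' @param E_LA constant (passive) left-atrial elastance, Pa/mL.
#' @param V0_LA LA unstressed volume, mL.
#' @param R_mv,R_ao open mitral / aortic valve resistances, Pa s/mL.
#' @param R_closed closed-valve resistance, Pa s/mL (ideal diode limit).
#' @param R_pul pulmonary venous inflow resistance, Pa s/mL.
#' @param p_pv constant pulmonary-venous pressure, Pa (default 10 mmHg).
#' @param R_sys,C_art systemic windkessel resistance (Pa s/mL) and
#'   compliance (mL/Pa).
#' @param p_ven systemic venous pressure, Pa.
#' @param annulus_area aortic annulus section, mm^2.
#' @param leak_area regurgitant orifice area, mm^2 (0 = competent valve).
#' @param leak_coef conductance per orifice area, mL/(s Pa mm^2); the linear
#'   leak law `G = leak_coef * leak_area` is used instead of a Bernoulli
#'   orifice for robustness, calibrated against the coronary-flow reduction.
#' @param sys_scale,dia_scale scaling of the effective arterial pressure in
#'   systole/diastole (1 in the physiological scenario; the aortic
#'   regurgitation scenario raises systole and lowers diastole by 20%).
#' @param beats number of heartbeats to simulate (default 2).
#' @param dt time step, s (default 1e-3).
#' @return object of class `circulation_params`.
#' @export
circulation_params <- function(T_hb = 0.8,
                               E_max = 237.98, E_min = 7.4279,
                               V0_LV = 10,
                               act_m1 = 1.9, act_m2 = 21.9,
                               act_tau1 = 0.27, act_tau2 = 0.45,
                               E_LA = 35.241, V0_LA = 10,
                               R_mv = 0.38761, R_ao = 9.0845,
                               R_closed = 1e9,
                               R_pul = 1.9775, p_pv = mmHg_to_Pa(10),
                               R_sys = 112.48, C_art = 0.019271,
                               p_ven = mmHg_to_Pa(4),
                               annulus_area = 490,
                               leak_area = 0,
                               leak_coef = 6.5e-5,
                               sys_scale = 1, dia_scale = 1,
                               beats = 2, dt = 1e-3) {
  p <- as.list(environment())
  stopifnot(T_hb > 0, E_max > E_min, E_min > 0, E_LA > 0,
            R_mv > 0, R_ao > 0, R_closed >= R_ao, R_closed >= R_mv,
            R_pul > 0, R_sys > 0, C_art > 0, dt > 0, beats >= 1,
            leak_area >= 0, leak_coef >= 0, annulus_area > 0)
  structure(p, class = "circulation_params")
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("0D circulation parameters\n")
  cat(sprintf("  T_hb %.2f s, E_max %.0f Pa/mL, E_min %.1f Pa/mL\n",
              x$T_hb, x$E_max, x$E_min))
  cat(sprintf("  windkessel R %.0f Pa s/mL, C %.4f mL/Pa; p_pv %.1f mmHg\n",
              x$R_sys, x$C_art, Pa_to_mmHg(x$p_pv)))
  if (x$leak_area > 0) {
    cat(sprintf("  aortic leak: %.1f mm^2 (%.1f%% of annulus)\n",
                x$leak_area, 100 * x$leak_area / x$annulus_area))
  }
  invisible(x)
}

# Normalised double-Hill activation on [0, T), continuous and periodic,
# scaled to max 1.  Vectorised in t.
.activation <- function(t, params) {
  tau1 <- params$act_tau1 * params$T_hb
  tau2 <- params$act_tau2 * params$T_hb
  tt <- t %% params$T_hb
  raw <- function(s) {
    h1 <- (s / tau1)^params$act_m1
    (h1 / (1 + h1)) * (1 / (1 + (s / tau2)^params$act_m2))
  }
  key <- paste(params$T_hb, params$act_m1, params$act_m2,
               params$act_tau1, params$act_tau2)
  if (is.null(.act_cache$key) || .act_cache$key != key) {
    .act_cache$key <- key
    .act_cache$max <- max(raw(seq(0, params$T_hb, length.out = 4097)))
  }
  raw(tt) / .act_cache$max
}
.act_cache <- new.env(parent = emptyenv())

#' Time-varying left-ventricular elastance
#'
#' Periodic double-Hill elastance `E(t) = E_min + (E_max - E_min) e(t)`
#' with `e` the normalised activation; pressure follows as
#' `p_LV = E(t) (V_LV - V0)`.
#'
#' @param t time, s (vectorised).
#' @param params a `circulation_params`.
#' @return elastance, Pa/mL.
#' @export
elastance <- function(t, params) {
  stopifnot(all(t >= 0))
  params$E_min + (params$E_max - params$E_min) * .activation(t, params)
}

# Smooth systole/diastole arterial-pressure scaling for the AR scenario,
# blended by the LV activation (1 in PH where both scales are 1).
.arterial_scale <- function(t, params) {
  if (params$sys_scale == 1 && params$dia_scale == 1) {
    return(rep(1, length(t)))
  }
  e <- .activation(t, params)
  params$dia_scale + (params$sys_scale - params$dia_scale) * e
}

#' Initial circulation state
#'
#' Starts at end-diastole (onset of ventricular activation) with nominal
#' resting volumes and diastolic arterial pressure.
#'
#' @param params a `circulation_params`.
#' @return list of state variables (`time`, `V_LA`, `V_LV`, `p_ar`,
#'   `V_res`), all finite.
#' @export
initial_circulation_state <- function(params) {
  list(time = 0, V_LA = 60, V_LV = 150,
       p_ar = mmHg_to_Pa(80), V_res = 500)
}

#' Advance the 0D circulation by one time step
#'
#' Semi-implicit Euler step: chamber pressures are evaluated from current
#' volumes via the elastances, valve states switch instantaneously with the
#' sign of the transvalvular pressure difference, then volumes and the
#' windkessel pressure advance by flow balance.  The total coronary outflow
#' is withdrawn from the arterial compartment.
#'
#' @param state current state (see [initial_circulation_state()]).
#' @param dt time step, s.
#' @param params a `circulation_params`.
#' @param coronary_sink total coronary outflow, mL/s (default 0).
#' @return new state, with derived pressures, flows and valve flags attached.
#' @export
step_circulation <- function(state, dt, params, coronary_sink = 0) {
  stopifnot(dt > 0, all(vapply(state[c("V_LA", "V_LV", "p_ar")],
                               is.finite, logical(1))))
  t <- state$time
  E_lv <- elastance(t, params)
  p_LV <- E_lv * (state$V_LV - params$V0_LV)
  p_LA <- params$E_LA * (state$V_LA - params$V0_LA)
  s_ar <- .arterial_scale(t, params)
  p_ar_eff <- s_ar * state$p_ar

  mv_open <- p_LA > p_LV
  ao_open <- p_LV > p_ar_eff
  Q_mv <- (p_LA - p_LV) / if (mv_open) params$R_mv else params$R_closed
  Q_leak <- 0
  if (ao_open) {
    Q_ao <- (p_LV - p_ar_eff) / params$R_ao
  } else {
    Q_ao <- (p_LV - p_ar_eff) / params$R_closed
    if (params$leak_area > 0) {
      Q_leak <- params$leak_coef * params$leak_area * (p_LV - p_ar_eff)
    }
  }
  Q_av <- Q_ao + Q_leak                      # net transvalvular aortic flow
  Q_pv <- (params$p_pv - p_LA) / params$R_pul
  Q_sys <- (state$p_ar - params$p_ven) / params$R_sys

  V_LA <- state$V_LA + dt * (Q_pv - Q_mv)
  V_LV <- state$V_LV + dt * (Q_mv - Q_av)
  p_ar <- state$p_ar + dt * (Q_av - Q_sys - coronary_sink) / params$C_art
  V_res <- state$V_res + dt * (Q_sys - Q_pv)
  if (V_LA <= 0 || V_LV <= 0) {
    stop(sprintf("negative chamber volume at t = %.4f s (V_LA = %.2f, V_LV = %.2f)",
                 t + dt, V_LA, V_LV))
  }
  list(time = t + dt, V_LA = V_LA, V_LV = V_LV, p_ar = p_ar, V_res = V_res,
       p_LV = p_LV, p_LA = p_LA, p_ar_eff = p_ar_eff,
       Q_mv = Q_mv, Q_ao = Q_ao, Q_leak = Q_leak, Q_av = Q_av,
       Q_pv = Q_pv, Q_sys = Q_sys,
       mv_open = mv_open, ao_open = ao_open)
}

#' Run the standalone 0D circulation
#'
#' @param params a `circulation_params`.
#' @param coronary_sink scalar, vector (one per step) or function of time
#'   giving the total coronary outflow, mL/s.
#' @return a `data.frame` of uniformly sampled transients (class
#'   `circulation_transients`): time, volumes, pressures (Pa and mmHg
#'   columns for convenience), flows and valve flags.
#' @export
run_circulation <- function(params, coronary_sink = 0) {
  nsteps <- as.integer(round(params$beats * params$T_hb / params$dt))
  sink_at <- if (is.function(coronary_sink)) {
    coronary_sink
  } else {
    v <- rep_len(coronary_sink, nsteps)
    function(t, i) v[i]
  }
  st <- initial_circulation_state(params)
  out <- matrix(NA_real_, nsteps, 15L)
  colnames(out) <- c("time_s", "V_LA_mL", "V_LV_mL", "p_LV_Pa", "p_LA_Pa",
                     "p_ar_Pa", "p_ar_eff_Pa", "Q_mv_mL_s", "Q_ao_mL_s",
                     "Q_leak_mL_s", "Q_av_mL_s", "Q_pv_mL_s", "Q_sys_mL_s",
                     "mv_open", "ao_open")
  for (i in seq_len(nsteps)) {
    st <- step_circulation(st, params$dt, params, sink_at(st$time, i))
    out[i, ] <- c(st$time, st$V_LA, st$V_LV, st$p_LV, st$p_LA, st$p_ar,
                  st$p_ar_eff, st$Q_mv, st$Q_ao, st$Q_leak, st$Q_av,
                  st$Q_pv, st$Q_sys, st$mv_open, st$ao_open)
  }
  df <- as.data.frame(out)
  df$p_LV_mmHg <- Pa_to_mmHg(df$p_LV_Pa)
  df$p_ar_mmHg <- Pa_to_mmHg(df$p_ar_eff_Pa)
  attr(df, "params") <- params
  class(df) <- c("circulation_transients", class(df))
  df
}

#' Derive the aortic-regurgitation (AR) parameter set
#'
#' Opens a regurgitant orifice in the closed aortic valve sized as a
#' fraction of the aortic annulus section (the leak conductance is linear in
#' the orifice area) and rescales the effective systemic arterial pressure
#' by `systolic_scale` in systole and `diastolic_scale` in diastole with a
#' smooth activation-weighted blend.
#'
#' @param params a `circulation_params` (physiological).
#' @param orifice_fraction regurgitant orifice area as a fraction of the
#'   annulus section (paper scenario: 0.045); 0 returns `params` unchanged.
#' @param systolic_scale,diastolic_scale pressure scalings (defaults 1.2 and
#'   0.8: +/-20%).
#' @return a modified `circulation_params`.
#' @export
apply_ar_scenario <- function(params, orifice_fraction = 0.045,
                              systolic_scale = 1.2, diastolic_scale = 0.8) {
  stopifnot(orifice_fraction >= 0, orifice_fraction < 1)
  if (orifice_fraction == 0) return(params)
  params$leak_area <- orifice_fraction * params$annulus_area
  params$sys_scale <- systolic_scale
  params$dia_scale <- diastolic_scale
  params
}

#' Extract left-heart biomarkers from circulation transients
#'
#' All quantities are computed over one reported beat (by default the last
#' simulated one, matching the convention of discarding the first transient
#' cycle).
#'
#' @param transients a `circulation_transients` (or any data.frame with the
#'   same columns).
#' @param params the `circulation_params` used (defaults to the attribute
#'   stored on the transients).
#' @param beat which beat to report (default: last complete one).
#' @return named list: `SV_mL`, `EDV_mL`, `EF_pct`, `p_LV_max_mmHg`,
#'   `Q_ao_max_mL_s`, `Q_pv_max_mL_s`, `p_ar_sys_mmHg`, `p_ar_dia_mmHg`,
#'   `regurgitant_volume_mL` (diastolic backflow through the leak).
#' @export
extract_biomarkers <- function(transients, params = attr(transients, "params"),
                               beat = NULL) {
  stopifnot(!is.null(params))
  T_hb <- params$T_hb
  if (is.null(beat)) beat <- floor(max(transients$time_s) / T_hb + 1e-9)
  stopifnot(beat >= 1, max(transients$time_s) >= beat * T_hb - params$dt / 2)
  sel <- transients$time_s > (beat - 1) * T_hb + params$dt / 2 &
         transients$time_s <= beat * T_hb + params$dt / 2
  tr <- transients[sel, , drop = FALSE]
  SV <- max(tr$V_LV_mL) - min(tr$V_LV_mL)
  EDV <- max(tr$V_LV_mL)
  leak_in <- -pmin(tr$Q_av_mL_s, 0)
  list(
    SV_mL = SV,
    EDV_mL = EDV,
    EF_pct = if (EDV > 0) SV / EDV * 100 else 0,
    p_LV_max_mmHg = Pa_to_mmHg(max(tr$p_LV_Pa)),
    Q_ao_max_mL_s = max(tr$Q_av_mL_s),
    Q_pv_max_mL_s = max(tr$Q_pv_mL_s),
    p_ar_sys_mmHg = Pa_to_mmHg(max(tr$p_ar_eff_Pa)),
    p_ar_dia_mmHg = Pa_to_mmHg(min(tr$p_ar_eff_Pa)),
    regurgitant_volume_mL = sum(leak_in) * params$dt
  )
}
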