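## ---------------------------------------------------------------------------
## Reduced epicardial coronary network: each terminal branch connects the
## aortic-root pressure to the mean arteriolar (compartment-1) pressure of
## its perfusion territory through an epicardial resistance, a systolic
## ostial obstruction resistance (active while the aortic valve is open,
## emulating leaflet obstruction of the ostia), and the interface
## conductance alpha_j of the reduced outlet coupling condition.
## ---------------------------------------------------------------------------

#' Build a reduced epicardial coronary network
#'
#' One branch per perfusion territory.  The interface conductances `alpha_j`
#' scale with territory volume (a larger territory is fed by a larger
#' vessel), and the series resistances are split between a distributed
#' epicardial part and the lumped interface part `1/alpha_j`.
#'
#' @param regions a `perfusion_regions`.
#' @param side character vector of feeding-artery tags (`"LCA"`/`"RCA"`),
#'   one per territory (e.g. from [coronary_seeds()]).
#' @param R_total_parallel target total (parallel) network resistance in
#'   diastole, Pa s/mL; per-branch resistances are `R_total_parallel *
#'   V_total / V_j`.
#' @param alpha_share fraction of each branch resistance assigned to the
#'   interface conductance (`1/alpha_j`), the rest to the epicardial
#'   resistance.
#' @param R_ostium_factor systolic ostial obstruction resistance as a
#'   multiple of the branch diastolic resistance; calibrated so systolic
#'   flow is roughly a third of the diastolic peak.
#' @return object of class `coronary_network`: data.frame `branches` with
#'   columns `region`, `side`, `alpha` (mL/(s Pa)), `R_epi`, `R_ostium`
#'   (Pa s/mL).
#' @export
coronary_network <- function(regions, side = NULL,
                             R_total_parallel = 3820,
                             alpha_share = 0.25,
                             R_ostium_factor = 1.2) {
  J <- nrow(regions$seeds)
  if (is.null(side)) side <- rep("LCA", J)
  stopifnot(length(side) == J, all(side %in% c("LCA", "RCA")),
            R_total_parallel > 0, alpha_share > 0, alpha_share < 1,
            R_ostium_factor >= 0)
  Vj <- regions$region_volumes
  Rj <- R_total_parallel * sum(Vj) / Vj
  branches <- data.frame(
    region = seq_len(J),
    side = side,
    alpha = 1 / (alpha_share * Rj),
    R_epi = (1 - alpha_share) * Rj,
    R_ostium = R_ostium_factor * Rj)
  structure(list(branches = branches), class = "coronary_network")
}

#' @export
print.coronary_network <- function(x, ...) {
  cat(sprintf("Coronary network: %d branches (%d LCA, %d RCA)\n",
              nrow(x$branches), sum(x$branches$side == "LCA"),
              sum(x$branches$side == "RCA")))
  invisible(x)
}

#' Flux through one coronary branch
#'
#' `Q_j = (p_root - p1_mean) / (R_epi + R_ostium [valve open] + 1/alpha_j)`,
#' positive into the myocardium.  The ostial resistance is only active while
#' the aortic valve is open, which (together with the systolic rise of the
#' coronary-bed pressure) produces the diastolic-dominant flow pattern.
#'
#' @param p_root aortic-root pressure, Pa.
#' @param p1_region_mean mean compartment-1 pressure of the branch's
#'   territory, Pa.
#' @param branch one row of `coronary_network$branches`.
#' @param aortic_valve_open logical.
#' @return flux, mL/s.
#' @export
branch_flux <- function(p_root, p1_region_mean, branch, aortic_valve_open) {
  stopifnot(is.finite(p_root), is.finite(p1_region_mean))
  R <- branch$R_epi + branch$R_ostium * as.numeric(aortic_valve_open) +
    1 / branch$alpha
  if (any(R <= 0)) stop("non-positive total branch resistance")
  (p_root - p1_region_mean) / R
}

# Vector of effective branch resistances for a valve state.
.branch_resistances <- function(network, aortic_valve_open) {
  b <- network$branches
  R <- b$R_epi + b$R_ostium * as.numeric(aortic_valve_open) + 1 / b$alpha
  if (any(R <= 0)) stop("non-positive total branch resistance")
  R
}

#' Per-branch fluxes and LCA/RCA totals
#'
#' @param network a `coronary_network`.
#' @param p_root aortic-root pressure, Pa.
#' @param region_means mean compartment-1 pressure per territory, Pa
#'   (length J, indexed by region).
#' @param aortic_valve_open logical.
#' @return list: `Q` (per-branch fluxes, mL/s), `LCA`, `RCA`, `total`.
#' @export
total_flows <- function(network, p_root, region_means, aortic_valve_open) {
  b <- network$branches
  stopifnot(length(region_means) == nrow(b))
  R <- .branch_resistances(network, aortic_valve_open)
  Q <- (p_root - region_means[b$region]) / R
  list(Q = Q,
       LCA = sum(Q[b$side == "LCA"]),
       RCA = sum(Q[b$side == "RCA"]),
       total = sum(Q))
}
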