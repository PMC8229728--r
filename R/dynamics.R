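# Mass-action kinetics of the reader/writer post-translational-modification
# system in a shared cytoplasm, with a death threshold on the reader signal.
#
# Per allele i of the incompatibility locus:
#   dR_i/dt = alpha * [nucleus i present] - delta_R * R_i
#   dU_i/dt = beta - k_write * R_i * U_i - delta_T * U_i
#   dS/dt   = sum_i k_read * R_i * U_i - delta_S * S
# R_i is the allele-i reader/writer protein, U_i the unmodified cognate
# target (targets are produced constitutively in every cell; writing moves
# them to the modified pool; reading detects unmodified target and emits
# signal without consuming it), S the integrated death signal. The cell
# dies when S first reaches the threshold theta.

#' Kinetic parameters of the reader/writer system
#'
#' Rates are in arbitrary concentration/time units; only their ratios
#' matter for the qualitative outcomes. The shipped defaults fix the reader
#' (signal-generating) activity at five times the writing activity and set
#' the death threshold `theta` by calibration: the geometric mean of the
#' peak signals of the canonical fertilization (no cytoplasmic mixing) and
#' heterokaryon-fusion (full mixing) scenarios, so the threshold separates
#' the two by construction (see [death_margin()]).
#'
#' @param alpha Reader/writer expression rate per present nucleus
#'   (conc/time).
#' @param delta_R Reader/writer decay rate (1/time).
#' @param beta Constitutive target production rate per allele (conc/time).
#' @param delta_T Target decay rate (1/time).
#' @param k_write Writing (modification) rate constant (1/(conc x time)).
#' @param k_read Reading (signal generation) rate constant
#'   (1/(conc x time)); default five times `k_write`.
#' @param delta_S Signal decay rate (1/time).
#' @param theta Death threshold on the signal (conc); `NULL` (default)
#'   calibrates it with [calibrate_death_threshold()].
#' @return An object of class `rw_params`.
#' @export
rw_params <- function(alpha = 1, delta_R = 0.1, beta = 1, delta_T = 0.05,
                      k_write = 0.2, k_read = 5 * k_write, delta_S = 0.5,
                      theta = NULL) {
  p <- list(alpha = alpha, delta_R = delta_R, beta = beta,
            delta_T = delta_T, k_write = k_write, k_read = k_read,
            delta_S = delta_S, theta = NA_real_)
  rates <- unlist(p[setdiff(names(p), "theta")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  class(p) <- "rw_params"
  if (is.null(theta)) {
    default <- missing(alpha) && missing(delta_R) && missing(beta) &&
      missing(delta_T) && missing(k_write) && missing(k_read) &&
      missing(delta_S)
    if (default && !is.null(.si_cache$default_theta)) {
      theta <- .si_cache$default_theta
    } else {
      theta <- calibrate_death_threshold(p)
      if (default) .si_cache$default_theta <- theta
    }
  }
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be positive")
  p$theta <- theta
  p
}

.si_cache <- new.env(parent = emptyenv())

#' @export
print.rw_params <- function(x, ...) {
  cat("<rw_params>\n")
  for (f in names(x))
    cat(sprintf("  %-8s %g\n", f, x[[f]]))
  invisible(x)
}

#' Cytoplasm state
#'
#' Concentrations in one (possibly fused) cell: per-allele reader/writer
#' `R`, per-allele unmodified target `U`, death signal `S`, viability flag
#' and time. The allele universe is fixed by the names of `R`/`U`.
#'
#' @param R,U Named numeric vectors (same allele names, non-negative).
#' @param S Signal level (non-negative scalar).
#' @param alive Logical.
#' @param t Time.
#' @return An object of class `cytoplasm_state`.
#' @export
cytoplasm_state <- function(R, U, S = 0, alive = TRUE, t = 0) {
  if (is.null(names(R)) || !identical(names(R), names(U)))
    stop("'R' and 'U' must be named numeric vectors over the same alleles")
  if (any(R < 0) || any(U < 0) || S < 0)
    stop("concentrations must be non-negative")
  structure(list(R = R, U = U, S = S, alive = alive, t = t),
            class = "cytoplasm_state")
}

#' @export
print.cytoplasm_state <- function(x, ...) {
  cat("<cytoplasm_state> t =", x$t,
      if (x$alive) "(alive)" else "(dead)", "\n")
  m <- rbind(R = x$R, U = x$U)
  print(round(m, 4))
  cat("  S =", format(x$S, digits = 6), "\n")
  invisible(x)
}

#' Resident steady state of a cell
#'
#' Closed-form equilibrium of the kinetics for a cell whose nuclei carry
#' the given alleles: present alleles have `R* = alpha/delta_R` and
#' `U* = beta/(k_write R* + delta_T)` (targets mostly written); absent
#' alleles have `R* = 0` and `U* = beta/delta_T` (their cognate targets
#' accumulate unmodified, invisible to the resident readers). The resident
#' signal `S* = sum_present k_read R* U* / delta_S` is positive but, under
#' the shipped defaults, sub-threshold for homo- and heterokaryons.
#'
#' @param present_alleles Character vector of alleles whose nuclei are in
#'   the cell (non-empty subset of `all_alleles`).
#' @param all_alleles Character vector, the allele universe to track.
#' @param params An [rw_params()].
#' @return A [cytoplasm_state()] at equilibrium (t = 0).
#' @export
steady_state <- function(present_alleles, all_alleles, params) {
  present_alleles <- unique(as.character(present_alleles))
  all_alleles <- unique(as.character(all_alleles))
  if (length(present_alleles) == 0)
    stop("'present_alleles' must be non-empty")
  if (!all(present_alleles %in% all_alleles))
    stop("'present_alleles' must be a subset of 'all_alleles'")
  pres <- all_alleles %in% present_alleles
  R <- ifelse(pres, params$alpha / params$delta_R, 0)
  U <- params$beta / (params$k_write * R + params$delta_T)
  S <- if (params$delta_S > 0)
    sum(params$k_read * R[pres] * U[pres]) / params$delta_S
  else 0
  names(R) <- names(U) <- all_alleles
  cytoplasm_state(R = R, U = U, S = S)
}

#' Mix two cytoplasms
#'
#' Volume-weighted linear blend of two cytoplasm states, modelling
#' anastomosis: every concentration in the fusion cell is
#' `phi * s1 + (1 - phi) * s2`. Time restarts at 0 and the fusion cell
#' starts alive.
#'
#' @param s1,s2 [cytoplasm_state()] objects over the same allele universe,
#'   both alive.
#' @param phi Volume fraction contributed by `s1`, in \[0, 1\]; 0.5 models
#'   equal volumes.
#' @return A [cytoplasm_state()].
#' @export
mix_states <- function(s1, s2, phi = 0.5) {
  if (!identical(names(s1$R), names(s2$R)))
    stop("states must share the same allele universe")
  if (!s1$alive || !s2$alive) stop("cannot mix with a dead cell")
  if (length(phi) != 1 || is.na(phi) || phi < 0 || phi > 1)
    stop("'phi' must lie in [0, 1]")
  cytoplasm_state(R = phi * s1$R + (1 - phi) * s2$R,
                  U = phi * s1$U + (1 - phi) * s2$U,
                  S = phi * s1$S + (1 - phi) * s2$S,
                  alive = TRUE, t = 0)
}

rw_rhs <- function(t, y, parms) {
  n <- parms$n
  R <- y[seq_len(n)]
  U <- y[n + seq_len(n)]
  S <- y[2 * n + 1]
  p <- parms$p
  dR <- p$alpha * parms$pres - p$delta_R * R
  dU <- p$beta - p$k_write * R * U - p$delta_T * U
  dS <- sum(p$k_read * R * U) - p$delta_S * S
  list(c(dR, dU, dS))
}

#' Integrate the reader/writer kinetics
#'
#' Fixed-step 4th-order Runge-Kutta integration of the mass-action system
#' from an initial cytoplasm state, with the given set of nuclei present
#' (expressing their reader/writer). The first time step at which the
#' signal reaches `theta` is localized by linear interpolation within the
#' step and recorded as the death time; the state is frozen from the
#' crossing onward (death is absorbing).
#'
#' @param state Initial [cytoplasm_state()].
#' @param present_nuclei Character vector of alleles whose nuclei are
#'   present in the cell.
#' @param params An [rw_params()].
#' @param t_max Integration horizon (time units).
#' @param dt Step size.
#' @return An object of class `rw_trajectory`: list with `times`, `states`
#'   (data.frame with columns `t`, `R_<allele>`, `U_<allele>`, `S`,
#'   `alive`), `death_time` (`NA` if the cell survives), `peak_signal`,
#'   `peak_time`, `present`, `params`.
#' @export
integrate_rw <- function(state, present_nuclei, params, t_max = 200,
                         dt = 0.01) {
  if (dt <= 0 || t_max < dt) stop("need dt > 0 and t_max >= dt")
  alleles <- names(state$R)
  present_nuclei <- unique(as.character(present_nuclei))
  if (!all(present_nuclei %in% alleles))
    stop("present nuclei must belong to the state's allele universe")
  n <- length(alleles)
  y0 <- c(state$R, state$U, S = state$S)
  times <- seq(0, t_max, by = dt)
  out <- deSolve::ode(y = y0, times = times, func = rw_rhs,
                      parms = list(n = n, p = params,
                                   pres = as.numeric(alleles %in%
                                                       present_nuclei)),
                      method = "rk4")
  out <- unclass(out)
  if (min(out[, -1]) < -1e-9)
    stop("integration produced negative concentrations; reduce 'dt'")
  out[, -1][out[, -1] < 0] <- 0
  S <- out[, 2 * n + 2]
  cross <- which(S >= params$theta)[1]
  death_time <- NA_real_
  alive <- rep(TRUE, length(times))
  if (!is.na(cross)) {
    if (cross == 1L) {
      death_time <- 0
      frozen <- out[1L, -1]
    } else {
      f <- (params$theta - S[cross - 1L]) / (S[cross] - S[cross - 1L])
      death_time <- times[cross - 1L] + f * dt
      frozen <- out[cross - 1L, -1] + f * (out[cross, -1] -
                                             out[cross - 1L, -1])
    }
    out[cross:length(times), -1] <- rep(frozen, each = length(times) -
                                          cross + 1L)
    alive[cross:length(times)] <- FALSE
    S <- out[, 2 * n + 2]
  }
  states <- as.data.frame(out)
  names(states) <- c("t", paste0("R_", alleles), paste0("U_", alleles), "S")
  states$alive <- alive
  ipk <- which.max(S)
  structure(list(times = times, states = states, death_time = death_time,
                 peak_signal = S[ipk], peak_time = times[ipk],
                 present = present_nuclei, params = params),
            class = "rw_trajectory")
}

#' @export
print.rw_trajectory <- function(x, ...) {
  cat("<rw_trajectory> nuclei {", paste(x$present, collapse = ","),
      "}, t in [0, ", max(x$times), "]\n", sep = "")
  cat(sprintf("  peak signal %.4g at t = %.3g (theta = %.4g)\n",
              x$peak_signal, x$peak_time, x$params$theta))
  if (is.na(x$death_time)) cat("  cell survives\n")
  else cat(sprintf("  cell death at t = %.4g\n", x$death_time))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj An `rw_trajectory`.
#' @return A [cytoplasm_state()].
#' @export
final_state <- function(traj) {
  last <- traj$states[nrow(traj$states), ]
  alleles <- sub("^R_", "", grep("^R_", names(last), value = TRUE))
  R <- as.numeric(last[paste0("R_", alleles)])
  U <- as.numeric(last[paste0("U_", alleles)])
  names(R) <- names(U) <- alleles
  cytoplasm_state(R = R, U = U, S = last$S, alive = last$alive,
                  t = last$t)
}

#' Simulate fusion of two mycelia with cytoplasmic mixing
#'
#' Both partners start at their resident steady states over the union
#' allele universe; anastomosis blends the cytoplasms with volume fraction
#' `phi` and the fused cell is integrated with the union of nuclei present.
#' When the partners' allele sets differ, each side's accumulated
#' unmodified targets meet the other side's reader at high concentration
#' and the signal spikes; identical karyotypes stay at the resident
#' steady state and never die.
#'
#' @param karyotype1,karyotype2 Character vectors of alleles carried by
#'   each partner (1-3 each).
#' @param params An [rw_params()].
#' @param phi Volume fraction of partner 1.
#' @param t_max,dt Integration controls, as in [integrate_rw()].
#' @return An `rw_trajectory`.
#' @export
simulate_heterokaryon_fusion <- function(karyotype1, karyotype2,
                                         params = rw_params(), phi = 0.5,
                                         t_max = 200, dt = 0.01) {
  universe <- sort(unique(c(karyotype1, karyotype2)))
  s1 <- steady_state(karyotype1, universe, params)
  s2 <- steady_state(karyotype2, universe, params)
  s0 <- mix_states(s1, s2, phi)
  integrate_rw(s0, universe, params, t_max = t_max, dt = dt)
}

#' Simulate fertilization by a migrating nucleus
#'
#' Nuclear migration brings a nucleus but essentially no cytoplasm: the
#' resident cell keeps its steady-state cytoplasm and the incoming
#' nucleus switches on expression of its reader/writer from zero. Because
#' the incoming writer accumulates gradually, it modifies its cognate
#' targets as they appear and the reader signal stays below threshold
#' under the shipped defaults -- mating succeeds where cytoplasmic mixing
#' would kill the cell.
#'
#' @param resident_alleles Character vector, alleles of the resident
#'   nuclei.
#' @param incoming_allele Single allele label, not already resident.
#' @param params An [rw_params()].
#' @param t_max,dt Integration controls.
#' @return An `rw_trajectory`.
#' @export
simulate_fertilization <- function(resident_alleles, incoming_allele,
                                   params = rw_params(), t_max = 200,
                                   dt = 0.01) {
  if (length(incoming_allele) != 1)
    stop("exactly one incoming allele")
  if (incoming_allele %in% resident_alleles)
    stop("incoming allele is already resident; nothing to fertilize")
  universe <- sort(unique(c(resident_alleles, incoming_allele)))
  s0 <- steady_state(resident_alleles, universe, params)
  integrate_rw(s0, universe, params, t_max = t_max, dt = dt)
}

# Free-running signal peaks (threshold suppressed) of the two canonical
# scenarios used for calibration.
canonical_peaks <- function(params, t_max = 200, dt = 0.01) {
  free <- params
  free$theta <- Inf
  fert <- simulate_fertilization("A", "B", free, t_max = t_max, dt = dt)
  fus <- simulate_heterokaryon_fusion(c("A", "B"), c("A", "C"), free,
                                      t_max = t_max, dt = dt)
  c(fertilization = fert$peak_signal, fusion = fus$peak_signal)
}

#' Calibrate the death threshold
#'
#' Runs the canonical fertilization (A fertilized by B, no mixing) and
#' heterokaryon fusion (AB x AC, full mixing) scenarios with the threshold
#' suppressed and returns the geometric mean of the two signal peaks.
#' Placing `theta` there guarantees the qualitative contrast --
#' fertilization survives, fusion dies -- whenever the peaks differ.
#'
#' @param params An [rw_params()] (its `theta` is ignored).
#' @param t_max,dt Integration controls.
#' @return Numeric threshold.
#' @export
calibrate_death_threshold <- function(params, t_max = 200, dt = 0.01) {
  pk <- canonical_peaks(params, t_max = t_max, dt = dt)
  sqrt(pk[["fertilization"]] * pk[["fusion"]])
}

#' Signal peaks of the canonical scenarios versus the threshold
#'
#' Calibration report: free-running peak signal of the canonical
#' fertilization and heterokaryon-fusion scenarios together with the
#' configured threshold. Under the shipped defaults the strict ordering
#' `fertilization_peak < theta < fusion_peak` holds; for other parameter
#' sets a broken ordering is reported, not raised as an error.
#'
#' @param params An [rw_params()].
#' @param t_max,dt Integration controls.
#' @return List with `fertilization_peak`, `fusion_peak`, `theta`,
#'   `ordering_ok`.
#' @export
death_margin <- function(params = rw_params(), t_max = 200, dt = 0.01) {
  pk <- canonical_peaks(params, t_max = t_max, dt = dt)
  list(fertilization_peak = pk[["fertilization"]],
       fusion_peak = pk[["fusion"]],
       theta = params$theta,
       ordering_ok = pk[["fertilization"]] < params$theta &&
         params$theta < pk[["fusion"]])
}
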