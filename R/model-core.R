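#' @title Forward model of the activation-gated crossbridge cycle
#'
#' @description
#' The model collapses the crossbridge cycle into three pools:
#'
#' * `N` - non-cycling crossbridges (detached, thin filament not yet
#'   permissive);
#' * `D` - the attached, non-force A-M.ADP.Pi state;
#' * `F` - the force-bearing pool AM*.ADP.Pi + AM*.ADP, with Pi release
#'   treated as a rapid equilibrium with constant `K2`, so the pool is
#'   partitioned as `[AM*.ADP.Pi]/[AM*.ADP] = [Pi]/K2`.
#'
#' Transitions: the Ca2+-dependent activation gate opens `N -> D` at rate
#' `g(Ca)`; the Pi isomerization exchanges `D <-> F` with forward rate `k1`
#' and effective reverse rate `k_minus1 * [Pi]/(K2 + [Pi])` (only the
#' Pi-bound fraction of the force pool can re-isomerize); a slow recycling
#' rate `g_off` returns `D` and `F` to `N`. With a fast, saturated gate and
#' slow recycling, the slowest relaxation eigenvalue reduces to the
#' closed-form observed rate `k1 + k_minus1 [Pi]/(K2 + [Pi])`.
#'
#' @name model_core
NULL

# free Ca2+ in uM from pCa (pCa is -log10 of molar free Ca2+)
pca_to_ca_uM <- function(pCa) 10^(-pCa) * 1e6

# gate opening rate, s^-1
gate_rate <- function(params, pCa) {
  ca <- pca_to_ca_uM(pCa)
  params$g_act_max * ca^params$h_act /
    (params$ca50_act^params$h_act + ca^params$h_act)
}

# Pi-bound fraction of the force pool under rapid-equilibrium release
pi_bound_fraction <- function(params, pi_mM) pi_mM / (params$K2 + pi_mM)

# generator matrix A for dx/dt = A x over states (N, D, F)
rate_matrix <- function(params, pCa, pi_mM) {
  g <- gate_rate(params, pCa)
  kr <- params$k_minus1 * pi_bound_fraction(params, pi_mM)
  k1 <- params$k1
  goff <- params$g_off
  matrix(c(-g,           goff,        goff,
            g, -(k1 + goff),           kr,
            0,            k1, -(kr + goff)),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("N", "D", "F"), c("N", "D", "F")))
}

#' Closed-form observed relaxation rate as a function of added Pi
#'
#' Evaluates `k1 + k_minus1 * pi_mM / (K2 + pi_mM)`: the observed rate
#' constant of force redevelopment when Pi release is a rapid equilibrium
#' and activation is not rate-limiting. It equals `k1` at zero added Pi,
#' increases strictly with Pi, and saturates below `k1 + k_minus1`.
#'
#' @param params A [scheme_params()] object.
#' @param pi_mM Added phosphate concentration(s), mM; must be >= 0.
#' @return Rate constant(s), s^-1 (vectorized over `pi_mM`).
#' @export
#' @examples
#' p <- group_scheme_params("perfused")
#' relaxation_rate(p, c(0, 5, 10, 20, 30))
relaxation_rate <- function(params, pi_mM) {
  stopifnot(inherits(params, "scheme_params"))
  if (any(!is.finite(pi_mM)) || any(pi_mM < 0))
    stop("relaxation_rate: pi_mM must be finite and >= 0", call. = FALSE)
  params$k1 + params$k_minus1 * pi_mM / (params$K2 + pi_mM)
}

#' Steady-state occupancy and force
#'
#' Solves the null space of the three-pool generator at the given Ca2+ and
#' Pi, then partitions the force pool into AM*.ADP.Pi and AM*.ADP by the
#' rapid-equilibrium Pi-bound fraction. Force is `f_scale` times the
#' force-pool occupancy.
#'
#' @param params A [scheme_params()] object.
#' @param pCa -log10 of molar free Ca2+.
#' @param pi_mM Added phosphate, mM.
#' @return A list of class `state_distribution` with `occupancy` (named
#'   fractions over non_cycling, A_M_ADP_Pi, AMstar_ADP_Pi, AMstar_ADP,
#'   summing to 1) and `force` (mN/mm^2).
#' @export
steady_state <- function(params, pCa, pi_mM = 0) {
  stopifnot(inherits(params, "scheme_params"))
  if (pi_mM < 0) stop("steady_state: pi_mM must be >= 0", call. = FALSE)
  A <- rate_matrix(params, pCa, pi_mM)
  if (all(abs(A) < 1e-12))
    stop("steady_state: degenerate rate matrix (all rates zero)", call. = FALSE)
  # replace one balance equation with the conservation constraint
  M <- rbind(A[1:2, ], rep(1, 3))
  x <- tryCatch(solve(M, c(0, 0, 1)),
                error = function(e) stop("steady_state: singular rate matrix",
                                         call. = FALSE))
  x <- pmax(x, 0)
  x <- x / sum(x)
  phi <- pi_bound_fraction(params, pi_mM)
  occ <- c(non_cycling  = x[["N"]],
           A_M_ADP_Pi   = x[["D"]],
           AMstar_ADP_Pi = x[["F"]] * phi,
           AMstar_ADP   = x[["F"]] * (1 - phi))
  structure(list(occupancy = occ,
                 force = params$f_scale * x[["F"]]),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("Steady-state crossbridge distribution\n")
  print(round(x$occupancy, 4))
  cat(sprintf("force: %.3f mN/mm^2\n", x$force))
  invisible(x)
}

#' Slowest relaxation eigenvalue of the model
#'
#' Magnitude of the slowest nonzero eigenvalue of the generator matrix at
#' the given condition: the rate at which a perturbed distribution relaxes
#' to steady state, and the model-internal oracle for
#' [relaxation_rate()]. With the gate fast and saturated (high Ca2+) and
#' recycling slow, it agrees with the closed form within a few percent.
#'
#' @inheritParams steady_state
#' @return Rate constant, s^-1.
#' @export
eigen_rate <- function(params, pCa = 4.5, pi_mM = 0) {
  stopifnot(inherits(params, "scheme_params"))
  A <- rate_matrix(params, pCa, pi_mM)
  ev <- eigen(A, only.values = TRUE)$values
  ev <- Re(ev)
  nz <- abs(ev) > 1e-9 * max(1, max(abs(ev)))
  if (!any(nz))
    stop("eigen_rate: no nonzero eigenvalue (degenerate model)", call. = FALSE)
  min(abs(ev[nz]))
}

#' Experimental protocol descriptor
#'
#' @param kind `"CA_JUMP"` (photolytic Ca2+ release from caged calcium),
#'   `"ATP_JUMP"` (photolytic ATP release in Ca2+-rigor) or
#'   `"LENGTH_RELEASE"` (force redevelopment after a rapid 5 percent
#'   release; the release itself is not modelled, traces start at the
#'   post-release force minimum).
#' @param pCa Post-stimulus -log10 molar free Ca2+ (in `[4, 9]`).
#' @param pi_mM Added phosphate, mM.
#' @param duration Record length, s.
#' @param rate_hz Sampling rate, samples/s (instrument default 1000 Hz).
#' @return An object of class `protocol`.
#' @export
protocol <- function(kind = c("CA_JUMP", "ATP_JUMP", "LENGTH_RELEASE"),
                     pCa = 4.5, pi_mM = 0, duration = 0.5, rate_hz = 1000) {
  kind <- match.arg(kind)
  if (!is.finite(pCa) || pCa < 4 || pCa > 9)
    stop("protocol: pCa must be in [4, 9]", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("protocol: duration must be > 0", call. = FALSE)
  if (!is.finite(rate_hz) || rate_hz <= 0)
    stop("protocol: rate_hz must be > 0", call. = FALSE)
  if (pi_mM < 0) stop("protocol: pi_mM must be >= 0", call. = FALSE)
  structure(list(kind = kind, pCa = pCa, pi_mM = pi_mM,
                 duration = duration, rate_hz = rate_hz),
            class = "protocol")
}

#' Simulate a force transient under a protocol
#'
#' Integrates the three-pool ODE with a stiff-safe solver
#' ([deSolve::lsoda()], absolute tolerance 1e-9 on occupancies) and returns
#' the sampled force trace.
#'
#' Initial conditions by protocol: `CA_JUMP` and `LENGTH_RELEASE` start with
#' all crossbridges non-cycling (a rapid release detaches essentially all
#' crossbridges, and caged-Ca2+ fibers start relaxed); `ATP_JUMP` starts
#' from a Ca2+-rigor distribution, represented as force-bearing occupancy
#' scaled so that initial (rigor) force is `rigor_frac` of the steady
#' active force, with the gate open. On ATP photolysis a fraction
#' `detach_frac` of the rigor bridges binds ATP and detaches rapidly (rate
#' `k_detach`) into the attached non-force pool before re-entering the
#' cycle; the net early detachment produces the characteristic small,
#' brief dip in force before force development.
#'
#' @param params A [scheme_params()] object.
#' @param protocol A [protocol()] object.
#' @param rigor_frac For `ATP_JUMP`, initial rigor force as a fraction of
#'   the steady active force. Default 1/3 (measured rigor force was about
#'   one third of the total force developed after ATP release).
#' @param detach_frac Fraction of rigor bridges that transiently detach on
#'   ATP binding (ATP_JUMP only).
#' @param k_detach Rate of ATP-induced rigor detachment, s^-1 (fast
#'   relative to cycling; sets the dip duration of a few ms).
#' @return A [force_trace()] with protocol metadata.
#' @export
simulate_transient <- function(params, protocol, rigor_frac = 1/3,
                               detach_frac = 0.3, k_detach = 300) {
  stopifnot(inherits(params, "scheme_params"), inherits(protocol, "protocol"))
  A <- rate_matrix(params, protocol$pCa, protocol$pi_mM)
  # 4th state R: rigor bridges detaching at k_detach into D (ATP_JUMP only;
  # R is force-bearing, so force tracks F + R)
  A4 <- rbind(cbind(A, c(0, k_detach, 0)), c(0, 0, 0, -k_detach))
  dimnames(A4) <- rep(list(c("N", "D", "F", "R")), 2)
  x0 <- switch(protocol$kind,
    CA_JUMP = , LENGTH_RELEASE = c(N = 1, D = 0, F = 0, R = 0),
    ATP_JUMP = {
      ss <- steady_state(params, protocol$pCa, protocol$pi_mM)
      f0 <- rigor_frac * (ss$occupancy[["AMstar_ADP_Pi"]] +
                          ss$occupancy[["AMstar_ADP"]])
      c(N = 1 - f0, D = 0, F = (1 - detach_frac) * f0,
        R = detach_frac * f0)
    })
  times <- seq(0, protocol$duration, by = 1 / protocol$rate_hz)
  rhs <- function(t, x, p) list(as.vector(A4 %*% x))
  sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-9)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol)))
    stop("simulate_transient: integration failure (non-finite state)",
         call. = FALSE)
  occ <- sol[, c("N", "D", "F", "R"), drop = FALSE]
  if (any(abs(rowSums(occ) - 1) > 1e-6))
    stop("simulate_transient: occupancy conservation violated", call. = FALSE)
  force <- params$f_scale * (occ[, "F"] + occ[, "R"])
  tr <- force_trace(time_s = sol[, "time"], force = force,
                    protocol_kind = protocol$kind, pCa = protocol$pCa,
                    pi_mM = protocol$pi_mM, rate_hz = protocol$rate_hz)
  ss_force <- steady_state(params, protocol$pCa, protocol$pi_mM)$force
  if (ss_force > 1e-6 &&
      abs(force[length(force)] - ss_force) > 0.01 * ss_force)
    warning("simulate_transient: terminal force not within 1% of steady state; ",
            "consider a longer duration")
  tr
}

#' Sampled force-time record with protocol metadata
#'
#' A thin data-frame wrapper: columns `time_s` and `force_mN_per_mm2`, with
#' protocol metadata (`protocol_kind`, `pCa`, `pi_mM`, `adp_mM`, `rate_hz`,
#' `group`, `fiber_id`) stored as attributes and preserved by the
#' plain-text serialization ([write_force_trace()]).
#'
#' @param time_s Sample times, s.
#' @param force Force, mN/mm^2.
#' @param protocol_kind,pCa,pi_mM,adp_mM,rate_hz,group,fiber_id Metadata.
#' @return A data frame of class `force_trace`.
#' @export
force_trace <- function(time_s, force, protocol_kind = NA_character_,
                        pCa = NA_real_, pi_mM = NA_real_, adp_mM = NA_real_,
                        rate_hz = NA_real_, group = NA_character_,
                        fiber_id = NA_character_) {
  if (length(time_s) != length(force))
    stop("force_trace: time_s and force must have equal length", call. = FALSE)
  df <- data.frame(time_s = as.numeric(time_s),
                   force_mN_per_mm2 = as.numeric(force))
  structure(df,
            class = c("force_trace", "data.frame"),
            protocol_kind = protocol_kind, pCa = pCa, pi_mM = pi_mM,
            adp_mM = adp_mM, rate_hz = rate_hz, group = group,
            fiber_id = fiber_id)
}

trace_meta <- function(trace) {
  nms <- c("protocol_kind", "pCa", "pi_mM", "adp_mM", "rate_hz", "group",
           "fiber_id")
  stats::setNames(lapply(nms, function(n) attr(trace, n)), nms)
}

#' @export
print.force_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf("Force trace: %d samples, %.3g s, %s\n",
              nrow(x), max(x$time_s) - min(x$time_s),
              if (is.na(m$protocol_kind)) "protocol unknown" else m$protocol_kind))
  cat(sprintf("  pCa %.3g, Pi %.3g mM, %s Hz; force %.3g -> %.3g mN/mm^2\n",
              m$pCa, m$pi_mM, format(m$rate_hz),
              x$force_mN_per_mm2[1], x$force_mN_per_mm2[nrow(x)]))
  invisible(x)
}
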