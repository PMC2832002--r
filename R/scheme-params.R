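#' Rate constants for the activation-gated crossbridge scheme
#'
#' Bundles the kinetic constants of the forward model: the Pi isomerization
#' between the attached non-force A-M.ADP.Pi state and the force-bearing
#' AM*.ADP.Pi state (forward `k1`, reverse `k_minus1`, both s^-1), the
#' rapid-equilibrium Pi release constant `K2` (mM), the Ca2+-dependent
#' activation gate that moves non-cycling crossbridges into the cycling
#' pool, a recycling (detachment) rate back to the non-cycling pool, and a
#' force scale converting force-bearing occupancy to mN/mm^2.
#'
#' The gate opening rate is a phenomenological Hill function of free Ca2+,
#' `g_act_max * ca^h_act / (ca50_act^h_act + ca^h_act)`, chosen so that the
#' gate is fast and saturated at activating Ca2+ (pCa 4.5) and effectively
#' closed at relaxing Ca2+ (pCa 8-9); it is not asserted as the physical
#' mechanism of thin-filament activation. The default maximal opening rate
#' (500 s^-1) keeps the gate more than an order of magnitude faster than
#' the cycling rates, so that simulated activation transients are
#' mono-exponential to within a few percent; a slower gate adds a visible
#' sigmoidal lag that biases single-exponential fits.
#'
#' @param k1 Forward Pi-isomerization rate, s^-1.
#' @param k_minus1 Reverse Pi-isomerization rate, s^-1.
#' @param K2 Pi-release equilibrium constant, mM.
#' @param g_act_max Maximal gate opening rate, s^-1.
#' @param ca50_act Free Ca2+ (uM) for half-maximal gate opening.
#' @param h_act Gate Hill exponent.
#' @param g_off Gate closing / crossbridge recycling rate, s^-1. Kept slow
#'   relative to the cycling rates so that detachment perturbs the observed
#'   relaxation rate by less than 5 percent.
#' @param f_scale Force per unit occupancy of the force-bearing states,
#'   mN/mm^2.
#' @return An object of class `scheme_params`.
#' @seealso [group_scheme_params()] for the published group parameter sets,
#'   [relaxation_rate()], [steady_state()], [simulate_transient()].
#' @export
#' @examples
#' p <- scheme_params(k1 = 26.6, k_minus1 = 42.3, K2 = 39.4)
#' relaxation_rate(p, pi_mM = c(0, 5, 30))
scheme_params <- function(k1, k_minus1, K2,
                          g_act_max = 500, ca50_act = 3, h_act = 2,
                          g_off = 0.5, f_scale = 50) {
  p <- list(k1 = k1, k_minus1 = k_minus1, K2 = K2,
            g_act_max = g_act_max, ca50_act = ca50_act, h_act = h_act,
            g_off = g_off, f_scale = f_scale)
  validate_scheme_params(p)
  structure(p, class = "scheme_params")
}

validate_scheme_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("k1", "k_minus1", "K2", "g_act_max", "ca50_act", "h_act",
               "g_off", "f_scale")) {
    if (!num1(p[[nm]])) {
      stop(sprintf("scheme_params: '%s' must be a single finite number", nm),
           call. = FALSE)
    }
  }
  if (p$k1 < 0 || p$k_minus1 < 0 || p$g_act_max < 0 || p$g_off < 0)
    stop("scheme_params: all rates must be >= 0", call. = FALSE)
  if (p$K2 <= 0) stop("scheme_params: K2 must be > 0", call. = FALSE)
  if (p$ca50_act <= 0) stop("scheme_params: ca50_act must be > 0", call. = FALSE)
  if (p$h_act <= 0) stop("scheme_params: h_act must be > 0", call. = FALSE)
  if (p$f_scale <= 0) stop("scheme_params: f_scale must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.scheme_params <- function(x, ...) {
  cat("Crossbridge scheme parameters\n")
  cat(sprintf("  Pi isomerization: k1 = %.3g s^-1, k-1 = %.3g s^-1\n",
              x$k1, x$k_minus1))
  cat(sprintf("  Pi release:       K2 = %.3g mM (rapid equilibrium)\n", x$K2))
  cat(sprintf("  Activation gate:  g_max = %.3g s^-1, Ca50 = %.3g uM, h = %.3g, g_off = %.3g s^-1\n",
              x$g_act_max, x$ca50_act, x$h_act, x$g_off))
  cat(sprintf("  Force scale:      %.3g mN/mm^2 per unit occupancy\n", x$f_scale))
  invisible(x)
}

# Published group values (mean +/- SEM) for the three surgery groups, used
# as synthetic-cohort defaults and to calibrate f_scale per group.
.group_registry <- list(
  perfused = list(
    k1 = 26.6, k1_se = 0.8, k_minus1 = 42.3, k_minus1_se = 3.1,
    K2 = 39.4, K2_se = 4.6,
    fmax = 50.1, fmax_se = 2.5, ec50 = 3.32, ec50_se = 0.13,
    k_act = 22.0, k_act_se = 1.2,
    n_pca = 7, n_pi = 7, n_act = 11,
    tnt_p1 = 0.221, tnt_p2 = 0.776,
    tni_rel = 1.0, mybpc_rel = 1.0
  ),
  ischemic = list(
    k1 = 18.9, k1_se = 0.8, k_minus1 = 30.7, k_minus1_se = 1.7,
    K2 = 24.5, K2_se = 3.2,
    fmax = 36.1, fmax_se = 2.4, ec50 = 3.61, ec50_se = 0.11,
    k_act = 15.4, k_act_se = 1.1,
    n_pca = 8, n_pi = 10, n_act = 10,
    tnt_p1 = 0.396, tnt_p2 = 0.603,
    tni_rel = 0.659, mybpc_rel = 0.636
  ),
  reperfused = list(
    k1 = 20.4, k1_se = 0.6, k_minus1 = 37.4, k_minus1_se = 2.9,
    K2 = 29.4, K2_se = 3.3,
    fmax = 41.3, fmax_se = 5.2, ec50 = 3.57, ec50_se = 0.12,
    k_act = 19.3, k_act_se = 1.6,
    n_pca = 5, n_pi = 7, n_act = 9,
    tnt_p1 = NA_real_, tnt_p2 = NA_real_,
    tni_rel = NA_real_, mybpc_rel = NA_real_
  )
)

#' Published parameter sets for the three surgery groups
#'
#' Returns a [scheme_params()] object carrying the group's fitted Scheme-1
#' constants (k1, k-1, K2). The force scale is calibrated numerically so the
#' model's steady-state force at pCa 4.5 and zero added Pi equals the
#' group's maximal Ca2+-activated force per cross-sectional area.
#'
#' @param group One of `"perfused"`, `"ischemic"`, `"reperfused"`.
#' @param ... Overrides passed on to [scheme_params()] (e.g. `g_off`).
#' @return A `scheme_params` object.
#' @export
#' @examples
#' p <- group_scheme_params("ischemic")
#' steady_state(p, pCa = 4.5, pi_mM = 0)$force  # = 36.1 mN/mm^2
group_scheme_params <- function(group = c("perfused", "ischemic", "reperfused"),
                                ...) {
  group <- match.arg(group)
  g <- .group_registry[[group]]
  p <- scheme_params(k1 = g$k1, k_minus1 = g$k_minus1, K2 = g$K2,
                     f_scale = 1, ...)
  # occupancy of the force pool at saturating Ca2+, zero Pi
  occ <- steady_state(p, pCa = 4.5, pi_mM = 0)$force  # f_scale = 1
  p$f_scale <- g$fmax / occ
  p
}

#' Printed group summary values used as synthetic-data truth
#'
#' The registry of published group means, SEMs and sample sizes (Scheme-1
#' constants, Hill parameters, activation rate constants, phosphoform and
#' phospho/total truth ratios) that parameterize the synthetic-cohort
#' generators.
#'
#' @param group One of `"perfused"`, `"ischemic"`, `"reperfused"`.
#' @return A named list of printed values for the group.
#' @export
group_truth <- function(group = c("perfused", "ischemic", "reperfused")) {
  .group_registry[[match.arg(group)]]
}

#' Calibrate k1 to a target observed activation rate
#'
#' Adjusts the forward isomerization rate `k1` so that the model's slowest
#' relaxation eigenvalue under the given condition equals a target rate
#' constant, e.g. the measured rate of force development after photolytic
#' Ca2+ release. Used to generate photolysis cohorts whose fitted
#' exponential rates are centred on a measured group value.
#'
#' @param params A [scheme_params()] object.
#' @param target_rate Target observed rate constant, s^-1.
#' @param pCa,pi_mM Condition at which the eigenvalue is matched.
#' @return `params` with `k1` replaced by the calibrated value.
#' @export
calibrate_activation <- function(params, target_rate, pCa = 4.5, pi_mM = 0) {
  stopifnot(inherits(params, "scheme_params"))
  if (!is.finite(target_rate) || target_rate <= 0)
    stop("calibrate_activation: target_rate must be > 0", call. = FALSE)
  f <- function(k1) {
    p <- params; p$k1 <- k1
    eigen_rate(p, pCa = pCa, pi_mM = pi_mM) - target_rate
  }
  lo <- 1e-3
  hi <- max(2 * target_rate, 10)
  # widen until bracketed (eigen_rate is increasing in k1)
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibrate_activation: target rate not attainable by varying k1",
         call. = FALSE)
  k1 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  params$k1 <- k1
  params
}
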