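#' Hill fit of the force-pCa relation
#'
#' Least-squares fit of `F = fmax * ca^n / (ec50^n + ca^n)` to force versus
#' free Ca2+, giving the maximal force (Fmax), the Ca2+ for half-maximal
#' force (EC50) and the Hill coefficient. At `ca = ec50` the fitted curve
#' equals `fmax / 2` identically.
#'
#' @param ca_uM Free Ca2+, uM; alternatively a data frame with columns
#'   `ca_uM` and `force` as the single argument.
#' @param force Force, mN/mm^2 (or any consistent unit).
#' @return Object of class `hill_fit`: `fmax`, `ec50`, `n_hill`, standard
#'   errors (`fmax_se`, `ec50_se`, `n_hill_se`), `n_points`, `r2`.
#' @export
#' @examples
#' ca <- 10^seq(-2, 1.5, length.out = 10)
#' f <- 50.1 * ca^2 / (3.32^2 + ca^2)
#' fit_hill(ca, f)
fit_hill <- function(ca_uM, force = NULL) {
  if (is.data.frame(ca_uM)) {
    df <- ca_uM
    if (!all(c("ca_uM", "force") %in% names(df)))
      stop("fit_hill: data frame needs columns 'ca_uM' and 'force'",
           call. = FALSE)
    ca_uM <- df$ca_uM; force <- df$force
  }
  if (length(ca_uM) != length(force) || length(ca_uM) < 4)
    stop("fit_hill: need at least 4 (ca, force) points", call. = FALSE)
  if (any(ca_uM <= 0)) stop("fit_hill: ca_uM must be > 0", call. = FALSE)
  if (max(ca_uM) / min(ca_uM) < 10)
    stop("fit_hill: Ca2+ values must span at least one decade", call. = FALSE)
  fmax0 <- max(force)
  if (fmax0 <= 0 || diff(range(force)) < 1e-8 * max(1, abs(fmax0)))
    stop("fit_hill: not identifiable (forces do not vary)", call. = FALSE)
  if (min(force) > 0.8 * fmax0)
    stop("fit_hill: not identifiable (all forces near maximum)", call. = FALSE)

  ec500 <- ca_uM[which.min(abs(force - fmax0 / 2))]
  dat <- data.frame(ca = ca_uM, f = force)
  fit <- minpack.lm::nlsLM(
    f ~ fmax * ca^n / (ec50^n + ca^n), data = dat,
    start = list(fmax = fmax0, ec50 = ec500, n = 2),
    lower = c(1e-9, 1e-9, 0.1), upper = c(Inf, Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((force - mean(force))^2)
  structure(list(fmax = unname(cf[["fmax"]]), ec50 = unname(cf[["ec50"]]),
                 n_hill = unname(cf[["n"]]),
                 fmax_se = unname(se[["fmax"]]), ec50_se = unname(se[["ec50"]]),
                 n_hill_se = unname(se[["n"]]),
                 n_points = length(force), r2 = r2),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill force-pCa fit\n")
  cat(sprintf("  Fmax = %.4g (SE %.3g), EC50 = %.4g uM (SE %.3g), nH = %.3g (SE %.3g)\n",
              x$fmax, x$fmax_se, x$ec50, x$ec50_se, x$n_hill, x$n_hill_se))
  cat(sprintf("  n = %d points, R^2 = %.4f\n", x$n_points, x$r2))
  invisible(x)
}

#' Fit the phosphate dependence of the force-redevelopment rate
#'
#' Least-squares fit of the Scheme-1 relation `kF = k1 + k_minus1 * Pi /
#' (K2 + Pi)`: `k1` is the observed rate at zero added Pi, `k1 + k_minus1`
#' the saturating rate, and `K2` the Pi at which the saturating term is
#' half-maximal.
#'
#' K2 is only identifiable when saturation is detectable within the tested
#' Pi range; a fitted K2 greater than `identify_factor` times the largest
#' tested Pi is flagged `identified = FALSE` (the hyperbola is then
#' indistinguishable from a line over the data).
#'
#' @param pi_mM Added Pi, mM; alternatively a data frame with columns
#'   `pi_mM` and `kf` as the single argument.
#' @param kf Observed rate of force redevelopment, s^-1.
#' @param identify_factor Identifiability threshold on `K2 / max(pi_mM)`.
#' @return Object of class `pi_fit`: `k1`, `k_minus1`, `K2`, standard
#'   errors, `n_points`, `r2`, `identified`.
#' @export
#' @examples
#' p <- group_scheme_params("perfused")
#' pi <- c(0, 5, 10, 20, 30)
#' fit_pi_dependence(pi, relaxation_rate(p, pi))
fit_pi_dependence <- function(pi_mM, kf = NULL, identify_factor = 5) {
  if (is.data.frame(pi_mM)) {
    df <- pi_mM
    if (!all(c("pi_mM", "kf") %in% names(df)))
      stop("fit_pi_dependence: data frame needs columns 'pi_mM' and 'kf'",
           call. = FALSE)
    pi_mM <- df$pi_mM; kf <- df$kf
  }
  if (length(pi_mM) != length(kf))
    stop("fit_pi_dependence: pi_mM and kf must have equal length", call. = FALSE)
  if (any(pi_mM < 0)) stop("fit_pi_dependence: pi_mM must be >= 0", call. = FALSE)
  if (length(unique(pi_mM)) < 3)
    stop("fit_pi_dependence: not identifiable (need >= 3 distinct Pi levels)",
         call. = FALSE)
  if (diff(range(kf)) < 1e-10 * max(1, max(abs(kf))))
    stop("fit_pi_dependence: degenerate (all kF equal)", call. = FALSE)

  # starts: k1 from the zero-Pi points (or smallest Pi), k-1 from the span
  k10 <- if (any(pi_mM == 0)) mean(kf[pi_mM == 0]) else kf[which.min(pi_mM)]
  km10 <- max(kf[which.max(pi_mM)] - k10, 1)
  K20 <- stats::median(pi_mM[pi_mM > 0])
  dat <- data.frame(pi = pi_mM, kf = kf)
  fit <- minpack.lm::nlsLM(
    kf ~ k1 + km1 * pi / (K2 + pi), data = dat,
    start = list(k1 = k10, km1 = km10, K2 = K20),
    lower = c(1e-6, 1e-6, 1e-6), upper = c(500, 500, 500),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((kf - mean(kf))^2)
  structure(list(k1 = unname(cf[["k1"]]), k_minus1 = unname(cf[["km1"]]),
                 K2 = unname(cf[["K2"]]),
                 k1_se = unname(se[["k1"]]), k_minus1_se = unname(se[["km1"]]),
                 K2_se = unname(se[["K2"]]),
                 n_points = length(kf), r2 = r2,
                 identified = unname(cf[["K2"]]) <= identify_factor * max(pi_mM)),
            class = "pi_fit")
}

#' @export
print.pi_fit <- function(x, ...) {
  cat("Scheme-1 Pi-dependence fit: kF = k1 + k-1 [Pi]/(K2 + [Pi])\n")
  cat(sprintf("  k1  = %.4g s^-1 (SE %.3g)\n", x$k1, x$k1_se))
  cat(sprintf("  k-1 = %.4g s^-1 (SE %.3g)\n", x$k_minus1, x$k_minus1_se))
  cat(sprintf("  K2  = %.4g mM  (SE %.3g)%s\n", x$K2, x$K2_se,
              if (x$identified) "" else "  [K2 not identified within tested Pi range]"))
  cat(sprintf("  n = %d points, R^2 = %.4f\n", x$n_points, x$r2))
  invisible(x)
}

#' Fiber stiffness from length-release quadruplets
#'
#' Ordinary least-squares line through (length change, force change)
#' points from consecutive small releases; the slope is reported as the
#' fiber stiffness (mN/mm^2 per mm).
#'
#' @param delta_length_mm Length changes, mm.
#' @param delta_force Force changes, mN/mm^2.
#' @return Object of class `stiffness_fit`: `slope`, `intercept`, `r2`,
#'   `slope_se`, `n_points`.
#' @export
fit_stiffness <- function(delta_length_mm, delta_force) {
  if (length(delta_length_mm) != length(delta_force))
    stop("fit_stiffness: inputs must have equal length", call. = FALSE)
  if (length(unique(delta_length_mm)) < 2)
    stop("fit_stiffness: need at least 2 distinct release amplitudes",
         call. = FALSE)
  fit <- stats::lm(delta_force ~ delta_length_mm)
  cf <- stats::coef(fit)
  # suppress the "essentially perfect fit" note on noiseless lines
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(delta_force) > 0) sm$r.squared else 1
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_se = sm$coefficients[2, "Std. Error"],
                 r2 = r2, n_points = length(delta_force)),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("Stiffness fit: slope = %.4g mN/mm^2/mm (SE %.3g), intercept = %.3g, R^2 = %.4f, n = %d\n",
              x$slope, x$slope_se, x$intercept, x$r2, x$n_points))
  invisible(x)
}

#' Force retained relative to a zero-Pi reference, in percent
#'
#' @param f_at_pi Force in the presence of added Pi.
#' @param f_at_zero Reference force at zero added Pi (> 0).
#' @return `100 * f_at_pi / f_at_zero` (vectorized).
#' @export
#' @examples
#' relative_force(26.0, 41.3)  # 63%: a 37% reduction by 5 mM Pi
relative_force <- function(f_at_pi, f_at_zero) {
  if (any(!is.finite(f_at_zero)) || any(f_at_zero <= 0))
    stop("relative_force: reference force must be > 0", call. = FALSE)
  100 * f_at_pi / f_at_zero
}

#' Fiber cross-sectional area from two diameters
#'
#' Fibers are assumed elliptical in cross-section; the area from the two
#' measured diameters is `pi * d1 * d2 / 4`, converted from um^2 to mm^2.
#'
#' @param d_major_um,d_minor_um Fiber diameters, um.
#' @return Cross-sectional area, mm^2.
#' @export
fiber_csa <- function(d_major_um, d_minor_um) {
  if (any(d_major_um <= 0) || any(d_minor_um <= 0))
    stop("fiber_csa: diameters must be > 0", call. = FALSE)
  pi * d_major_um * d_minor_um / 4 * 1e-6
}

#' Per-fiber or pooled Hill fits over a measurement table
#'
#' @param table Data frame with columns `fiber_id`, `ca_uM`, `force` (and
#'   optionally `group`).
#' @param by `"fiber"` fits each fiber separately and summarizes the
#'   fitted parameters across fibers; `"group"` fits one curve to the
#'   mean force at each Ca2+ level.
#' @return For `by = "fiber"`, a list with `fits` (per fiber) and
#'   `summary` (data frame of mean, sem, n per parameter); for
#'   `by = "group"`, a single [fit_hill()] result.
#' @export
fit_hill_cohort <- function(table, by = c("fiber", "group")) {
  by <- match.arg(by)
  need_cols(table, c("fiber_id", "ca_uM", "force"), "fit_hill_cohort")
  if (by == "group") {
    agg <- stats::aggregate(force ~ ca_uM, data = table, FUN = mean)
    return(fit_hill(agg$ca_uM, agg$force))
  }
  fits <- lapply(split(table, table$fiber_id),
                 function(d) fit_hill(d$ca_uM, d$force))
  pars <- c("fmax", "ec50", "n_hill")
  summ <- do.call(rbind, lapply(pars, function(p) {
    v <- vapply(fits, `[[`, numeric(1), p)
    data.frame(parameter = p, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  list(fits = fits, summary = summ)
}

#' Per-fiber or pooled Scheme-1 Pi-dependence fits over a measurement table
#'
#' `by = "group"` fits the group-mean kF curve (mean across fibers at each
#' Pi level); this is the recommended mode for recovering K2, which is
#' poorly identified by single-fiber five-point curves.
#'
#' @param table Data frame with columns `fiber_id`, `pi_mM`, `kf`.
#' @param by `"fiber"` or `"group"` (see [fit_hill_cohort()]).
#' @return As [fit_hill_cohort()], with parameters `k1`, `k_minus1`, `K2`.
#' @export
fit_pi_cohort <- function(table, by = c("fiber", "group")) {
  by <- match.arg(by)
  need_cols(table, c("fiber_id", "pi_mM", "kf"), "fit_pi_cohort")
  if (by == "group") {
    agg <- stats::aggregate(kf ~ pi_mM, data = table, FUN = mean)
    return(fit_pi_dependence(agg$pi_mM, agg$kf))
  }
  fits <- lapply(split(table, table$fiber_id),
                 function(d) fit_pi_dependence(d$pi_mM, d$kf))
  pars <- c("k1", "k_minus1", "K2")
  summ <- do.call(rbind, lapply(pars, function(p) {
    v <- vapply(fits, `[[`, numeric(1), p)
    data.frame(parameter = p, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  list(fits = fits, summary = summ)
}

need_cols <- function(df, cols, where) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
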