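# Seeded synthetic cohorts with the statistical structure the fitters
# assume: Hill force-pCa surfaces per fiber, Scheme-1 kF-vs-Pi points,
# ODE-simulated photolysis / length-release transients, stiffness
# quadruplets and densitometry signal tables. Defaults are the published
# group values carried by group_truth().

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for a synthetic fiber cohort
#'
#' Collects the generating truth for one surgery group: Scheme-1
#' parameters, Hill force-pCa truth, the activation rate constant used to
#' calibrate photolysis transients, noise magnitudes, measurement grids,
#' densitometry truth ratios and the seed. All defaults are the published
#' group values ([group_truth()]); noise defaults are calibrations chosen
#' so that synthetic group SEMs approximate the printed SEMs (about
#' 2 s^-1 per kF point, 3 percent multiplicative force noise, 2 percent
#' trace noise).
#'
#' @param group `"perfused"`, `"ischemic"` or `"reperfused"`.
#' @param n_fibers Number of fibers per cohort (default: the group's
#'   published n for the Pi-dependence experiment).
#' @param params [scheme_params()] truth (default [group_scheme_params()]).
#' @param fmax,ec50,n_hill Hill truth (defaults: published group values;
#'   Hill coefficient 2).
#' @param k_act Observed activation rate constant (s^-1) to which
#'   caged-Ca2+ transients are calibrated.
#' @param rate_cv Between-fiber coefficient of variation of the activation
#'   rate (default: published SEM * sqrt(n) / k_act).
#' @param kf_noise_sd Additive SD per kF point, s^-1.
#' @param pca_noise Fractional (multiplicative) SD per force point.
#' @param trace_noise Fractional SD of trace noise relative to steady force.
#' @param pca_grid pCa levels for force-pCa tables.
#' @param pi_grid Added-Pi levels, mM (must include 0 for kF experiments).
#' @param dens_noise Log-normal SD of densitometry signals.
#' @param n_samples Number of densitometry samples.
#' @param seed Integer seed; identical configs generate identical output.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(group = c("perfused", "ischemic", "reperfused"),
                          n_fibers = NULL, params = NULL,
                          fmax = NULL, ec50 = NULL, n_hill = 2,
                          k_act = NULL, rate_cv = NULL,
                          kf_noise_sd = 2, pca_noise = 0.03,
                          trace_noise = 0.02,
                          pca_grid = c(8.0, 6.5, 6.2, 6.0, 5.8, 5.6, 5.4,
                                       5.0, 4.5, 4.0),
                          pi_grid = c(0, 5, 10, 20, 30),
                          dens_noise = 0.15, n_samples = NULL,
                          seed = 1L) {
  group <- match.arg(group)
  g <- group_truth(group)
  if (is.null(params)) params <- group_scheme_params(group)
  if (is.null(n_fibers)) n_fibers <- g$n_pi
  if (is.null(fmax)) fmax <- g$fmax
  if (is.null(ec50)) ec50 <- g$ec50
  if (is.null(k_act)) k_act <- g$k_act
  if (is.null(rate_cv)) rate_cv <- g$k_act_se * sqrt(g$n_act) / g$k_act
  if (is.null(n_samples)) n_samples <- 5L
  stopifnot(inherits(params, "scheme_params"))
  if (n_fibers < 1) stop("cohort_config: n_fibers must be >= 1", call. = FALSE)
  if (kf_noise_sd < 0 || pca_noise < 0 || trace_noise < 0 || dens_noise < 0)
    stop("cohort_config: noise magnitudes must be >= 0", call. = FALSE)
  if (!length(pca_grid) || !length(pi_grid))
    stop("cohort_config: measurement grids must be non-empty", call. = FALSE)
  structure(list(group = group, n_fibers = as.integer(n_fibers),
                 params = params, fmax = fmax, ec50 = ec50, n_hill = n_hill,
                 k_act = k_act, rate_cv = rate_cv,
                 kf_noise_sd = kf_noise_sd, pca_noise = pca_noise,
                 trace_noise = trace_noise,
                 pca_grid = pca_grid, pi_grid = pi_grid,
                 dens_noise = dens_noise, n_samples = as.integer(n_samples),
                 truth = g, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: %s, %d fibers, seed %d\n",
              x$group, x$n_fibers, x$seed))
  cat(sprintf("  truth: k1 %.3g, k-1 %.3g, K2 %.3g; Fmax %.3g, EC50 %.3g, nH %.3g; k_act %.3g\n",
              x$params$k1, x$params$k_minus1, x$params$K2,
              x$fmax, x$ec50, x$n_hill, x$k_act))
  cat(sprintf("  noise: kF sd %.3g s^-1, pCa force %.3g, trace %.3g, densitometry %.3g\n",
              x$kf_noise_sd, x$pca_noise, x$trace_noise, x$dens_noise))
  invisible(x)
}

#' Generate a per-fiber force-pCa measurement table
#'
#' Hill-law forces on the configured pCa grid with multiplicative Gaussian
#' noise, one block of rows per fiber.
#'
#' @param cfg A [cohort_config()].
#' @return Data frame with columns `fiber_id`, `group`, `pCa`, `ca_uM`,
#'   `force`.
#' @export
generate_force_pca_table <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    ca <- pca_to_ca_uM(cfg$pca_grid)
    f_true <- cfg$fmax * ca^cfg$n_hill / (cfg$ec50^cfg$n_hill + ca^cfg$n_hill)
    do.call(rbind, lapply(seq_len(cfg$n_fibers), function(i) {
      f <- f_true * (1 + stats::rnorm(length(ca), 0, cfg$pca_noise))
      data.frame(fiber_id = sprintf("%s_f%02d", cfg$group, i),
                 group = cfg$group, pCa = cfg$pca_grid, ca_uM = ca,
                 force = f)
    }))
  })
}

#' Generate a per-fiber kF-versus-Pi measurement table
#'
#' Per fiber, the observed rate of force redevelopment at each Pi level is
#' the Scheme-1 relation [relaxation_rate()] plus additive Gaussian noise.
#'
#' @param cfg A [cohort_config()]; `pi_grid` must include 0.
#' @return Data frame with columns `fiber_id`, `group`, `pi_mM`, `kf`.
#' @export
generate_kf_vs_pi <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!any(cfg$pi_grid == 0))
    stop("generate_kf_vs_pi: pi_grid must include 0", call. = FALSE)
  with_seed(cfg$seed, {
    kf_true <- relaxation_rate(cfg$params, cfg$pi_grid)
    do.call(rbind, lapply(seq_len(cfg$n_fibers), function(i) {
      data.frame(fiber_id = sprintf("%s_f%02d", cfg$group, i),
                 group = cfg$group, pi_mM = cfg$pi_grid,
                 kf = kf_true + stats::rnorm(length(kf_true), 0,
                                             cfg$kf_noise_sd))
    }))
  })
}

#' Generate a cohort of simulated force transients
#'
#' Simulates [simulate_transient()] per fiber and adds additive Gaussian
#' trace noise (fractional SD times the steady active force). For
#' `CA_JUMP`, per-fiber kinetics are calibrated ([calibrate_activation()])
#' so that each fiber's slowest relaxation eigenvalue equals a per-fiber
#' activation rate drawn around the group's `k_act` with coefficient of
#' variation `rate_cv`; noiseless cohorts (`trace_noise = 0`,
#' `rate_cv = 0`) reproduce the deterministic model trace. `ATP_JUMP`
#' traces start at the rigor force and show the early dip.
#'
#' @param cfg A [cohort_config()].
#' @param protocol_kind `"CA_JUMP"`, `"ATP_JUMP"` or `"LENGTH_RELEASE"`.
#' @param n_traces Number of traces (default: the group's published n for
#'   the caged-Ca2+ experiment).
#' @param duration,rate_hz Record length (s) and sampling rate (Hz).
#' @return List of [force_trace()] objects.
#' @export
generate_transients <- function(cfg, protocol_kind = "CA_JUMP",
                                n_traces = NULL, duration = 0.5,
                                rate_hz = 1000) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(n_traces)) n_traces <- cfg$truth$n_act
  with_seed(cfg$seed + 211L, {
    lapply(seq_len(n_traces), function(i) {
      p <- cfg$params
      if (protocol_kind == "CA_JUMP" && is.finite(cfg$k_act)) {
        target <- cfg$k_act * max(1 + stats::rnorm(1, 0, cfg$rate_cv), 0.2)
        p <- calibrate_activation(p, target)
      }
      prot <- protocol(protocol_kind, pCa = 4.5, pi_mM = 0,
                       duration = duration, rate_hz = rate_hz)
      tr <- simulate_transient(p, prot)
      ss <- steady_state(p, prot$pCa, prot$pi_mM)$force
      noisy <- tr$force_mN_per_mm2 +
        stats::rnorm(nrow(tr), 0, cfg$trace_noise * ss)
      force_trace(tr$time_s, noisy, protocol_kind = protocol_kind,
                  pCa = prot$pCa, pi_mM = prot$pi_mM, rate_hz = rate_hz,
                  group = cfg$group,
                  fiber_id = sprintf("%s_t%02d", cfg$group, i))
    })
  })
}

#' Generate stiffness release quadruplets
#'
#' Force responses to the four standard consecutive length releases
#' (0.05, 0.1, 0.15, 0.2 percent of fiber length), linear in the length
#' change with additive noise.
#'
#' @param cfg A [cohort_config()].
#' @param stiffness True slope, mN/mm^2/mm.
#' @param fiber_length_mm Fiber segment length, mm.
#' @param noise_sd Additive SD on each force response, mN/mm^2. The
#'   release force changes are themselves well below 1 mN/mm^2, so the
#'   default reflects force-transducer resolution rather than
#'   between-fiber scatter.
#' @return Data frame with `fiber_id`, `group`, `release_pct`,
#'   `delta_length_mm`, `delta_force`.
#' @export
generate_stiffness_quadruplets <- function(cfg, stiffness = 465.8,
                                           fiber_length_mm = 1.0,
                                           noise_sd = 0.02) {
  stopifnot(inherits(cfg, "cohort_config"))
  rel <- c(0.05, 0.1, 0.15, 0.2) / 100
  with_seed(cfg$seed + 433L, {
    do.call(rbind, lapply(seq_len(cfg$n_fibers), function(i) {
      dl <- rel * fiber_length_mm
      data.frame(fiber_id = sprintf("%s_s%02d", cfg$group, i),
                 group = cfg$group, release_pct = rel * 100,
                 delta_length_mm = dl,
                 delta_force = stiffness * dl +
                   stats::rnorm(length(dl), 0, noise_sd))
    }))
  })
}

#' Generate densitometry signal tables
#'
#' Log-normal signal noise around the configured truth ratios.
#' `assay = "tnt"` gives phosphoform pairs (P1 mono-, P2 diphosphorylated)
#' around the group's truth proportions; `"tni"` and `"mybpc"` give
#' phospho/total pairs whose true ratio is the group's relative level
#' times a common baseline.
#'
#' @param cfg A [cohort_config()].
#' @param assay `"tnt"`, `"tni"` or `"mybpc"`.
#' @param base_ratio Baseline phospho/total ratio of the reference group.
#' @return Data frame: for `"tnt"`, columns `sample_id`, `group`, `P1`,
#'   `P2`; otherwise `sample_id`, `group`, `phospho`, `total`.
#' @export
generate_densitometry <- function(cfg, assay = c("tnt", "tni", "mybpc"),
                                  base_ratio = 0.5) {
  stopifnot(inherits(cfg, "cohort_config"))
  assay <- match.arg(assay)
  g <- cfg$truth
  with_seed(cfg$seed + 877L, {
    n <- cfg$n_samples
    ids <- sprintf("%s_d%02d", cfg$group, seq_len(n))
    lnoise <- function(m) m * exp(stats::rnorm(n, 0, cfg$dens_noise))
    if (assay == "tnt") {
      if (!is.finite(g$tnt_p1))
        stop("generate_densitometry: no TnT phosphoform truth for this group",
             call. = FALSE)
      pr <- c(g$tnt_p1, g$tnt_p2) / (g$tnt_p1 + g$tnt_p2)
      tot <- lnoise(1000)
      data.frame(sample_id = ids, group = cfg$group,
                 P1 = tot * pr[1] * exp(stats::rnorm(n, 0, cfg$dens_noise)),
                 P2 = tot * pr[2] * exp(stats::rnorm(n, 0, cfg$dens_noise)))
    } else {
      rel <- if (assay == "tni") g$tni_rel else g$mybpc_rel
      if (!is.finite(rel))
        stop("generate_densitometry: no truth ratio for this group/assay",
             call. = FALSE)
      total <- lnoise(1000)
      data.frame(sample_id = ids, group = cfg$group,
                 phospho = total * base_ratio * rel *
                   exp(stats::rnorm(n, 0, cfg$dens_noise)),
                 total = total)
    }
  })
}

#' Parameter-recovery experiment over replicate synthetic cohorts
#'
#' For each replicate and each cohort configuration: generate a kF-vs-Pi
#' table and fit the group-mean curve with [fit_pi_dependence()]
#' (recovering k1, k-1, K2), and generate a force-pCa table and fit each
#' fiber with [fit_hill()], recording the group-mean EC50 and Fmax. Each
#' replicate uses a distinct derived seed; failures and non-identified K2
#' fits are recorded per replicate, not fatal.
#'
#' @param cfgs A [cohort_config()], a list of them, or a character vector
#'   of group names.
#' @param n_reps Number of replicate cohorts per group.
#' @param seed Integer master seed for the replicate seeds.
#' @return Object of class `recovery_report`: a data frame with columns
#'   `rep`, `group`, `parameter`, `truth`, `estimate`, `identified`.
#' @seealso [summarize_recovery()]
#' @export
recovery_experiment <- function(cfgs, n_reps = 20, seed = 1L) {
  if (inherits(cfgs, "cohort_config")) cfgs <- list(cfgs)
  if (is.character(cfgs)) cfgs <- lapply(cfgs, cohort_config)
  if (n_reps < 1) stop("recovery_experiment: n_reps must be >= 1",
                       call. = FALSE)
  rows <- list()
  for (gi in seq_along(cfgs)) {
    cfg <- cfgs[[gi]]
    truth <- c(k1 = cfg$params$k1, k_minus1 = cfg$params$k_minus1,
               K2 = cfg$params$K2, ec50 = cfg$ec50, fmax = cfg$fmax)
    for (r in seq_len(n_reps)) {
      sub <- (seed + 7919L * r + 104729L * gi) %% .Machine$integer.max
      c_kf <- cfg; c_kf$seed <- sub
      c_pca <- cfg; c_pca$seed <- sub + 1L
      est <- c(k1 = NA_real_, k_minus1 = NA_real_, K2 = NA_real_,
               ec50 = NA_real_, fmax = NA_real_)
      ident <- c(k1 = FALSE, k_minus1 = FALSE, K2 = FALSE,
                 ec50 = FALSE, fmax = FALSE)
      tryCatch({
        pf <- fit_pi_cohort(generate_kf_vs_pi(c_kf), by = "group")
        est[c("k1", "k_minus1", "K2")] <- c(pf$k1, pf$k_minus1, pf$K2)
        ident[c("k1", "k_minus1")] <- TRUE
        ident["K2"] <- pf$identified
      }, error = function(e) NULL)
      tryCatch({
        hf <- fit_hill_cohort(generate_force_pca_table(c_pca), by = "fiber")
        s <- hf$summary
        est["ec50"] <- s$mean[s$parameter == "ec50"]
        est["fmax"] <- s$mean[s$parameter == "fmax"]
        ident[c("ec50", "fmax")] <- TRUE
      }, error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, group = cfg$group, parameter = names(est),
        truth = unname(truth[names(est)]), estimate = unname(est),
        identified = unname(ident[names(est)]))
    }
  }
  structure(do.call(rbind, rows), class = c("recovery_report", "data.frame"))
}

#' Summarize a recovery report
#'
#' Mean, median, bias (mean - truth) and RMSE of the recovered estimates
#' per group and parameter, over identified replicates. The median is the
#' recommended consensus for the saturation constant K2, whose sampling
#' distribution over five-point Pi curves is strongly right-skewed.
#'
#' @param report A `recovery_report` from [recovery_experiment()].
#' @return Data frame with columns `group`, `parameter`, `truth`, `mean`,
#'   `median`, `bias`, `rmse`, `n_identified`, `n_reps`.
#' @export
summarize_recovery <- function(report) {
  stopifnot(inherits(report, "recovery_report"))
  parts <- split(report, list(report$group, report$parameter), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- d$identified & is.finite(d$estimate)
    e <- d$estimate[ok]
    data.frame(group = d$group[1], parameter = d$parameter[1],
               truth = d$truth[1],
               mean = if (length(e)) mean(e) else NA_real_,
               median = if (length(e)) stats::median(e) else NA_real_,
               bias = if (length(e)) mean(e) - d$truth[1] else NA_real_,
               rmse = if (length(e)) sqrt(mean((e - d$truth[1])^2)) else NA_real_,
               n_identified = sum(ok), n_reps = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$group, out$parameter), ]
}
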