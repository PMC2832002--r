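# Plain-text readers/writers and the pipeline driver. Traces are
# two-column tab-separated text (time_s, force_mN_per_mm2) with a '#
# key: value' header block carrying the protocol metadata; measurement
# tables are CSV/TSV with unit-bearing column names.

#' Write a force trace to delimited text
#'
#' @param trace A [force_trace()].
#' @param path Output file path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(trace, path, overwrite = FALSE) {
  stopifnot(inherits(trace, "force_trace"))
  if (file.exists(path) && !overwrite)
    stop("write_force_trace: '", path, "' exists (set overwrite = TRUE)",
         call. = FALSE)
  m <- trace_meta(trace)
  hdr <- vapply(names(m), function(k) {
    v <- m[[k]]
    sprintf("# %s: %s", k, if (is.na(v)) "NA" else format(v, digits = 15))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\tforce_mN_per_mm2", con)
  utils::write.table(as.data.frame(trace)[, c("time_s", "force_mN_per_mm2")],
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a force trace from delimited text
#'
#' Parses the header block and samples, restores metadata, and checks that
#' sampling is uniform within 1 percent of the declared rate (warning and
#' optional resampling otherwise).
#'
#' @param path File written by [write_force_trace()] (or conforming).
#' @param resample If sampling is non-uniform, linearly resample onto a
#'   uniform grid at the declared rate instead of only warning.
#' @return A [force_trace()].
#' @export
read_force_trace <- function(path, resample = FALSE) {
  if (!file.exists(path))
    stop("read_force_trace: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  if (!length(body))
    stop("read_force_trace: no data lines in ", path, call. = FALSE)
  col_line <- strsplit(body[1], "\t")[[1]]
  if (!all(c("time_s", "force_mN_per_mm2") %in% col_line))
    stop("read_force_trace: line ", hdr_idx[length(hdr_idx)] + 1,
         ": expected columns 'time_s' and 'force_mN_per_mm2'", call. = FALSE)
  df <- utils::read.table(text = body[-1], sep = "\t",
                          col.names = col_line)
  num <- function(k) {
    v <- meta[[k]]
    if (is.null(v) || v == "NA") NA_real_ else as.numeric(v)
  }
  chr <- function(k) {
    v <- meta[[k]]
    if (is.null(v) || v == "NA") NA_character_ else v
  }
  rate <- num("rate_hz")
  dt <- diff(df$time_s)
  if (length(dt) > 1) {
    target <- if (is.finite(rate)) 1 / rate else stats::median(dt)
    if (any(abs(dt - target) > 0.01 * target)) {
      if (resample) {
        tt <- seq(min(df$time_s), max(df$time_s), by = target)
        df <- data.frame(time_s = tt,
                         force_mN_per_mm2 = stats::approx(df$time_s,
                           df$force_mN_per_mm2, tt)$y)
      } else {
        warning("read_force_trace: non-uniform sampling in ", path,
                " (use resample = TRUE to regrid)")
      }
    }
  }
  force_trace(df$time_s, df$force_mN_per_mm2,
              protocol_kind = chr("protocol_kind"), pCa = num("pCa"),
              pi_mM = num("pi_mM"), adp_mM = num("adp_mM"),
              rate_hz = rate, group = chr("group"),
              fiber_id = chr("fiber_id"))
}

#' Read and validate a measurement table
#'
#' Reads a CSV or TSV (by file extension), checks required columns,
#' coerces declared numeric columns with a row-level error report, warns
#' on duplicated fiber/condition combinations, and preserves unknown
#' columns.
#'
#' @param path CSV/TSV file.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers (default: the
#'   required columns that look like measurements).
#' @return A validated data frame.
#' @export
read_measurements <- function(path, required = character(),
                              numeric_cols = intersect(required,
                                c("pCa", "ca_uM", "pi_mM", "adp_mM", "force",
                                  "kf", "delta_length_mm", "delta_force",
                                  "phospho", "total", "P1", "P2"))) {
  if (!file.exists(path))
    stop("read_measurements: no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("read_measurements: cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(df) || !ncol(df))
    stop("read_measurements: ", path, " is empty", call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("read_measurements: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("read_measurements: non-numeric values in column '", cc,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    df[[cc]] <- v
  }
  if (all(c("fiber_id", "condition") %in% names(df))) {
    key <- paste(df$fiber_id, df$condition)
    if (anyDuplicated(key))
      warning("read_measurements: duplicated fiber_id + condition rows in ",
              path)
  }
  df
}

#' Run the simulate-fit-summarize pipeline
#'
#' Generates synthetic cohorts for the configured groups, fits the Hill
#' force-pCa relation (per fiber) and the Scheme-1 Pi dependence (group
#' curve), performs Bonferroni-adjusted pairwise group comparisons of the
#' recovered EC50s, and writes tables (TSV), results (JSON) and a run
#' manifest recording the seed, configuration and package versions.
#'
#' @param config A list (or path to a YAML file, requires the `yaml`
#'   package) with elements `groups` (character), `seed` (integer),
#'   `out_dir`, and optional `n_fibers`, `overwrite`, `base_alpha`.
#' @return Invisibly, a list with `results`, `manifest` and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("run_pipeline: reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    if (!file.exists(config))
      stop("run_pipeline: no such config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$groups) || is.null(config$seed) || is.null(config$out_dir))
    stop("run_pipeline: config needs 'groups', 'seed' and 'out_dir'",
         call. = FALSE)
  groups <- match.arg(config$groups, c("perfused", "ischemic", "reperfused"),
                      several.ok = TRUE)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  overwrite <- isTRUE(config$overwrite)
  alpha <- if (is.null(config$base_alpha)) 0.05 else config$base_alpha
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  out_path <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p) && !overwrite)
      stop("run_pipeline: '", p, "' exists (set overwrite: true)",
           call. = FALSE)
    p
  }
  results <- list()
  ec50_by_group <- list()
  stage <- "simulate"
  manifest <- list(seed = seed, groups = groups, config = config,
                   package = as.character(utils::packageVersion("fiberkin")),
                   r_version = R.version.string,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  on.exit({
    if (stage != "done") manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    cfg <- cohort_config(g, seed = seed + 101L * gi,
                         n_fibers = config$n_fibers)
    stage <- paste0("simulate:", g)
    pca_tab <- generate_force_pca_table(cfg)
    kf_tab <- generate_kf_vs_pi(cfg)
    utils::write.table(pca_tab, out_path(sprintf("force_pca_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(kf_tab, out_path(sprintf("kf_vs_pi_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stage <- paste0("fit:", g)
    hf <- fit_hill_cohort(pca_tab, by = "fiber")
    pf <- fit_pi_cohort(kf_tab, by = "group")
    ec50_by_group[[g]] <- vapply(hf$fits, `[[`, numeric(1), "ec50")
    results[[g]] <- list(
      hill = hf$summary,
      scheme = list(k1 = pf$k1, k_minus1 = pf$k_minus1, K2 = pf$K2,
                    identified = pf$identified, r2 = pf$r2))
  }
  stage <- "stats"
  if (length(groups) >= 2) {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    m <- length(prs)
    results$comparisons <- lapply(prs, function(pr) {
      cr <- compare_groups(ec50_by_group[[pr[1]]], ec50_by_group[[pr[2]]],
                           m_comparisons = m, base_alpha = alpha,
                           labels = pr)
      list(groups = pr, p_value = cr$p_value,
           adjusted_alpha = cr$adjusted_alpha,
           significant = cr$significant)
    })
  }
  stage <- "write"
  res_path <- out_path("results.json")
  jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  stage <- "done"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  invisible(list(results = results, manifest = manifest,
                 out_dir = out_dir, results_path = res_path))
}
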