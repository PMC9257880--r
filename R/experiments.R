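#' Configuration of a batch replication experiment
#'
#' Describes a battery of stochastic walking trials over the Cartesian
#' product of gait speeds, noise amplitudes and reset modes, with a fixed
#' number of replicate trials per cell and deterministic per-cell seeds
#' derived from `base_seed`.
#'
#' @param id short experiment label (used in file names).
#' @param walker a [walker_params()] object.
#' @param speeds gait speeds (must be present in `params`).
#' @param xis noise amplitudes.
#' @param modes reset modes, subset of `c("resetting", "flip")`.
#' @param replicates trials per cell.
#' @param base_seed base seed; each cell/replicate gets a distinct derived
#'   seed.
#' @param dt integrator time step, s.
#' @param n_steps steps per trial (1300 = 650 strides).
#' @param discard,keep analysis window (strides).
#' @param params calibration table: data frame with columns `v`, `A1`,
#'   `A2`, `delta` (and optionally `phi0`), as returned by
#'   [gait_presets()] or [optimal_param_table()] (rename `v_target` to `v`).
#' @param outdir optional output directory for CSV files.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(id, walker = walker_params(),
                              speeds = 0.4, xis = 1,
                              modes = c("resetting", "flip"),
                              replicates = 10L, base_seed = 1L, dt = 1e-5,
                              n_steps = 1300L, discard = 150L, keep = 500L,
                              params = gait_presets(), outdir = NULL) {
  stopifnot(replicates >= 1L, all(modes %in% c("resetting", "flip")))
  miss <- setdiff(speeds, params$v)
  if (length(miss))
    stop("no calibration row for speed(s) ", paste(miss, collapse = ", "),
         "; run optimize_for_speed() or extend 'params'")
  structure(list(id = id, walker = walker, speeds = speeds, xis = xis,
                 modes = modes, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), dt = dt,
                 n_steps = as.integer(n_steps), discard = as.integer(discard),
                 keep = as.integer(keep), params = params, outdir = outdir),
            class = "experiment_config")
}

#' Deterministic per-cell seed
#'
#' Polynomial string hash of the cell labels folded into the base seed;
#' result lies in `[0, 2^31)`.
#'
#' @param base base seed.
#' @param mode,v,xi,replicate cell coordinates.
#' @return A non-negative integer-valued double.
#' @export
derive_seed <- function(base, mode, v, xi, replicate) {
  key <- paste(mode, format(v, digits = 12), format(xi, digits = 12),
               replicate, sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  (h + base * 2654435) %% 2147483647
}

#' Run a batch replication experiment
#'
#' For every cell `(mode, v, xi)` of the configuration, runs `replicates`
#' seeded trials from the noiseless limit cycle of that speed's parameter
#' set, extracts the analysis window and computes the DFA exponent.  `phi0`
#' is calibrated once per speed at the experiment's time step (unless
#' supplied in `config$params`).
#'
#' @param config an [experiment_config()] object.
#' @param verbose print per-cell progress?
#' @return A list of class `"experiment_result"`: `trials` (one row per
#'   trial: mode, v, xi, replicate, seed, fell, alpha, sd_stride,
#'   mean_stride, speed), `summary` (from [aggregate_alpha()]), `config`.
#'   If `config$outdir` is set, per-trial stride CSVs and the two tables
#'   are also written there.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  w <- config$walker
  # per-speed setup: cpg in both modes + limit-cycle initial state
  setups <- list()
  for (v in config$speeds) {
    row <- config$params[match(v, config$params$v), ]
    flip <- cpg_params(A1 = row$A1, A2 = row$A2, delta = row$delta,
                       mode = "flip")
    phi0 <- if (!is.null(row$phi0) && is.finite(row$phi0)) row$phi0 else
      as.numeric(calibrate_phi0(w, flip, dt = config$dt))
    flip$phi0 <- phi0
    cyc <- find_limit_cycle(w, flip, dt = config$dt)
    setups[[as.character(v)]] <- list(
      flip = cyc$cpg,
      resetting = cpg_params(A1 = row$A1, A2 = row$A2, delta = row$delta,
                             phi0 = cyc$cpg$phi0, mode = "resetting"),
      cycle = cyc)
  }

  rows <- list()
  for (mode in config$modes) for (v in config$speeds)
    for (xi in config$xis) for (rep in seq_len(config$replicates)) {
      su <- setups[[as.character(v)]]
      cpg <- su[[mode]]
      seed <- derive_seed(config$base_seed, mode, v, xi, rep)
      tr <- run_trial(w, cpg, noise_spec(xi, seed), n_steps = config$n_steps,
                      dt = config$dt, initial = su$cycle$state,
                      phi_init = su$cycle$phi)
      ok <- !tr$fell &&
        length(tr$stride_intervals) >= config$discard + config$keep
      rec <- data.frame(mode = mode, v = v, xi = xi, replicate = rep,
                        seed = seed, fell = tr$fell,
                        strides = length(tr$stride_intervals),
                        alpha = NA_real_, sd_stride = NA_real_,
                        mean_stride = NA_real_, speed = NA_real_)
      if (ok) {
        x <- analysis_window(tr, config$discard, config$keep)
        rec$alpha <- dfa(x)$alpha
        rec$sd_stride <- stats::sd(x)
        rec$mean_stride <- mean(x)
        rec$speed <- gait_speed(tr, config$discard, config$keep)
      }
      if (!is.null(config$outdir)) {
        dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
        fn <- file.path(config$outdir, sprintf(
          "%s_%s_v%s_xi%s_r%02d.csv", config$id, mode,
          format(v), format(xi), rep))
        write_stride_csv(tr, fn)
      }
      rows[[length(rows) + 1L]] <- rec
      if (verbose)
        message(sprintf("%s v=%g xi=%g rep %d: %s alpha=%.3f", mode, v, xi,
                        rep, if (tr$fell) "FELL" else "ok",
                        if (ok) rec$alpha else NA))
    }
  trials <- do.call(rbind, rows)
  out <- structure(list(trials = trials, summary = aggregate_alpha(trials),
                        config = config),
                   class = "experiment_result")
  if (!is.null(config$outdir)) {
    utils::write.csv(trials, file.path(config$outdir,
                                       paste0(config$id, "_trials.csv")),
                     row.names = FALSE)
    utils::write.csv(out$summary,
                     file.path(config$outdir,
                               paste0(config$id, "_summary.csv")),
                     row.names = FALSE)
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment", x$config$id, "-", nrow(x$trials), "trials\n")
  print(x$summary)
  invisible(x)
}

#' Aggregate per-trial scaling exponents by cell
#'
#' @param trials the per-trial data frame from [run_experiment()] (columns
#'   `mode`, `v`, `xi`, `alpha`, `fell`, optionally `sd_stride`).
#' @return A data frame with one row per `(mode, v, xi)` cell: replicate
#'   count `n`, completed count, falls, `alpha_mean`, `alpha_sd` (`NA`
#'   for a single completed replicate), `sd_stride_mean`.
#' @export
aggregate_alpha <- function(trials) {
  key <- interaction(trials$mode, trials$v, trials$xi, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    a <- d$alpha[is.finite(d$alpha)]
    data.frame(mode = d$mode[1L], v = d$v[1L], xi = d$xi[1L],
               n = nrow(d), completed = length(a), falls = sum(d$fell),
               alpha_mean = if (length(a)) mean(a) else NA_real_,
               alpha_sd = if (length(a) > 1L) stats::sd(a) else NA_real_,
               sd_stride_mean = if ("sd_stride" %in% names(d))
                 mean(d$sd_stride[is.finite(d$sd_stride)]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mode, out$v, out$xi), ]
}

#' Write a stride-interval series as annotated CSV
#'
#' One `stride_interval` column preceded by `# key=value` metadata lines
#' recording the generating parameters and seed.
#'
#' @param x a `walk_trial` object or numeric series.
#' @param path output file.
#' @param meta named list of extra metadata.
#' @return `path`, invisibly.
#' @export
write_stride_csv <- function(x, path, meta = list()) {
  if (inherits(x, "walk_trial")) {
    meta <- c(list(mode = x$cpg$mode, omega = x$cpg$omega, A1 = x$cpg$A1,
                   A2 = x$cpg$A2, delta = x$cpg$delta, phi0 = x$cpg$phi0,
                   xi = x$noise$xi, seed = x$noise$seed, dt = x$dt,
                   fell = x$fell), meta)
    x <- x$stride_intervals
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 17)), con)
  writeLines("stride_interval", con)
  writeLines(format(as.numeric(x), digits = 17), con)
  invisible(path)
}

#' Read a stride-interval CSV written by [write_stride_csv()]
#'
#' @param path input file.
#' @return Numeric vector with the metadata in attribute `"meta"`.
#' @export
read_stride_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!is_meta]
  x <- as.numeric(body[-1L]) # drop header
  attr(x, "meta") <- meta
  x
}
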