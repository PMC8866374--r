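# Calcium transient kinetics.
#
# Metrics follow the half-amplitude conventions used for single-cell calcium
# transients: with the trace normalised to g = (f - F0)/A,
#   CD50   = time the signal spends at or above g = 0.5,
#   T50on  = transient onset (last 5 % up-crossing before the peak) to the
#            0.5 up-crossing,
#   T50off = peak to the 0.5 down-crossing,
#   tau    = decay constant of an exponential fitted from the peak onward.
# All times are milliseconds; 83 fps acquisition gives dt = 1000/83 ms.

#' Synthetic transient model
#'
#' Product-of-exponentials transient
#' `g(t) = (1 - exp(-t/tau_r)) * exp(-t/tau_d)` for `t >= 0`, normalised to
#' peak 1, scaled to amplitude `A` over baseline `F0`, starting at `t0`.
#'
#' @param t0 Onset time (ms).
#' @param tau_r Rise constant (ms, > 0).
#' @param tau_d Decay constant (ms, > `tau_r` so the transient is peaked).
#' @param A Amplitude (peak minus baseline, > 0).
#' @param F0 Baseline fluorescence.
#' @return A `transient_model` list.
#' @export
transient_model <- function(t0 = 200, tau_r = 100, tau_d = 500,
                            A = 1, F0 = 0.2) {
  if (tau_r <= 0 || tau_d <= 0) stop("time constants must be positive",
                                     call. = FALSE)
  if (tau_d <= tau_r) stop("tau_d must exceed tau_r (peaked transient)",
                           call. = FALSE)
  structure(list(t0 = t0, tau_r = tau_r, tau_d = tau_d, A = A, F0 = F0),
            class = "transient_model")
}

# closed-form model curve at arbitrary times
#' @noRd
transient_curve <- function(model, t_ms) {
  tt <- t_ms - model$t0
  g <- ifelse(tt >= 0,
              (1 - exp(-tt / model$tau_r)) * exp(-tt / model$tau_d), 0)
  t_peak <- model$tau_r * log((model$tau_r + model$tau_d) / model$tau_r)
  g_max <- (1 - exp(-t_peak / model$tau_r)) * exp(-t_peak / model$tau_d)
  model$F0 + model$A * g / g_max
}

#' Ground-truth kinetics of a transient model (fine-grid oracle)
#'
#' Evaluates the noiseless closed-form transient on a fine grid and measures
#' the kinetics by linear-interpolated threshold crossings, giving
#' quantisation-free reference values for estimator validation. `tau_ms` in
#' the truth record is the model's asymptotic decay constant `tau_d`.
#'
#' @param model A [transient_model()].
#' @param duration_ms Trace duration covered (ms).
#' @param step_ms Oracle grid step (default: 1/83000 s, i.e. 1000x finer
#'   than 83 fps sampling).
#' @return One-row tibble: `F0`, `amplitude`, `CD50_ms`, `T50on_ms`,
#'   `T50off_ms`, `tau_ms`, `t_peak_ms`.
#' @export
transient_truth <- function(model, duration_ms = 4000,
                            step_ms = (1000 / 83) / 1000) {
  t <- seq(0, duration_ms, by = step_ms)
  tt <- t - model$t0
  t_peak_rel <- model$tau_r * log((model$tau_r + model$tau_d) / model$tau_r)
  g_max <- (1 - exp(-t_peak_rel / model$tau_r)) *
    exp(-t_peak_rel / model$tau_d)
  g <- ifelse(tt >= 0,
              (1 - exp(-tt / model$tau_r)) * exp(-tt / model$tau_d), 0) / g_max
  t_peak <- model$t0 + t_peak_rel
  cr <- crossing_times(t, g, 0.5)
  on5 <- crossing_times(t, g, 0.05)
  up50 <- cr$up[cr$up <= t_peak][1]
  down50 <- rev(cr$down[cr$down >= t_peak])[1]
  onset <- rev(on5$up[on5$up <= t_peak])[1]
  tibble::tibble(
    F0 = model$F0, amplitude = model$A,
    CD50_ms = down50 - up50,
    T50on_ms = up50 - onset,
    T50off_ms = down50 - t_peak,
    tau_ms = model$tau_d,
    t_peak_ms = t_peak
  )
}

# all linear-interpolated threshold crossings of a sampled curve
#' @noRd
crossing_times <- function(t, g, level) {
  dg <- g - level
  s <- dg[-length(dg)] * dg[-1]
  idx <- which(s < 0 | (dg[-length(dg)] == 0 & dg[-1] != 0))
  if (!length(idx)) return(list(up = numeric(0), down = numeric(0)))
  frac <- dg[idx] / (dg[idx] - dg[idx + 1])
  tc <- t[idx] + frac * (t[idx + 1] - t[idx])
  up <- tc[dg[idx + 1] > dg[idx]]
  down <- tc[dg[idx + 1] < dg[idx]]
  list(up = up, down = down)
}

#' Generate a sampled synthetic calcium trace with recorded truth
#'
#' @param model A [transient_model()].
#' @param fps Sampling rate in frames per second (acquisitions in the
#'   emulated protocol run at 83 fps).
#' @param duration_ms Trace duration (must cover the transient).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed for the noise (required when `noise_sd > 0`).
#' @return A list with `trace` (a [calcium_trace()]) and `truth` (the
#'   [transient_truth()] record of the noiseless model).
#' @export
make_transient <- function(model, fps = 83, duration_ms = 4000,
                           noise_sd = 0, seed = NULL) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  dt <- 1000 / fps
  t <- seq(0, duration_ms, by = dt)
  f <- transient_curve(model, t)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("supply a seed when adding noise", call. = FALSE)
    f <- f + withr::with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  list(trace = calcium_trace(t, f),
       truth = transient_truth(model, duration_ms, step_ms = dt / 1000))
}

#' Calcium transient kinetics from a single-transient trace
#'
#' Estimates baseline, amplitude and the half-amplitude kinetics of the one
#' dominant transient in a uniformly sampled trace. The baseline is the mean
#' of pre-peak samples lying below `baseline_frac` of the peak prominence;
#' all threshold crossings are located by linear interpolation between
#' samples; the decay constant comes from a least-squares fit of
#' `F0 + A' exp(-(t - t_peak)/tau)` from the peak to the end of the trace
#' (baseline held fixed, start value `tau = T50off / ln 2`).
#'
#' @param trace A [calcium_trace()] (or data frame with `t_ms`, `f`).
#' @param onset_frac Normalised level defining transient onset (default
#'   0.05: last 5 % up-crossing before the peak).
#' @param baseline_frac Fraction of prominence below which pre-peak samples
#'   count as baseline (default 0.10).
#' @return One-row tibble of class `calcium_kinetics`: `F0`, `amplitude`,
#'   `CD50_ms`, `T50on_ms`, `T50off_ms`, `tau_ms`, `fit_rmse`, `flags`.
#'   `tau_ms` is `NA` when the decay fit does not converge.
#' @export
transient_metrics <- function(trace, onset_frac = 0.05,
                              baseline_frac = 0.10) {
  t <- trace$t_ms; f <- trace$f
  rng <- max(f) - min(f)
  if (rng <= 0) stop("no transient found: constant trace", call. = FALSE)
  peaks <- which(f == max(f))
  flags <- character(0)
  if (length(peaks) > 1) {
    warning("multiple equal peaks: upstroke references the first, ",
            "decay the last")
    flags <- c(flags, "multiple_peaks")
  }
  ip <- peaks[1]                 # upstroke reference
  ip_dn <- peaks[length(peaks)]  # decay reference (end of any plateau)
  prom <- max(f) - min(f)
  if (prom < 0.5 * rng) stop("no dominant transient found", call. = FALSE)

  pre <- seq_len(ip - 1)
  base_idx <- pre[f[pre] < min(f) + baseline_frac * prom]
  if (!length(base_idx)) {
    base_idx <- pre[which.min(f[pre])]
    flags <- c(flags, "short_baseline")
  }
  F0 <- mean(f[base_idx])
  A <- f[ip] - F0
  if (A <= 0) stop("no transient found: peak does not exceed baseline",
                   call. = FALSE)
  g <- (f - F0) / A
  t_peak <- t[ip]

  t_peak_dn <- t[ip_dn]
  cr50 <- crossing_times(t, g, 0.5)
  cr_on <- crossing_times(t, g, onset_frac)
  up50 <- cr50$up[cr50$up <= t_peak][1]
  down50 <- rev(cr50$down[cr50$down >= t_peak_dn])[1]
  onset <- rev(cr_on$up[cr_on$up <= t_peak])[1]
  if (is.na(up50) || is.na(down50)) {
    stop("transient never crosses half amplitude on both flanks",
         call. = FALSE)
  }

  # exponential decay fit from the peak onward, baseline fixed
  dec <- ip_dn:length(t)
  tau0 <- max((down50 - t_peak_dn) / log(2), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Ap * exp(-(x - x0) / tau),
      data = list(y = f[dec] - F0, x = t[dec], x0 = t_peak_dn),
      start = list(Ap = A, tau = tau0),
      lower = c(Ap = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- NA_real_; rmse <- NA_real_
    flags <- c(flags, "tau_fit_failed")
  } else {
    tau <- stats::coef(fit)[["tau"]]
    rmse <- sqrt(mean(stats::resid(fit)^2))
  }

  out <- tibble::tibble(
    F0 = F0, amplitude = A,
    CD50_ms = down50 - up50,
    T50on_ms = up50 - onset,
    T50off_ms = down50 - t_peak_dn,
    tau_ms = tau, fit_rmse = rmse,
    flags = paste(flags, collapse = ";")
  )
  class(out) <- c("calcium_kinetics", class(out))
  out
}

#' Tune a transient model so the fine-grid oracle hits a target metric
#'
#' Bisects one model parameter (`tau_d` for duration-type targets, `tau_r`
#' for upstroke-type) until the [transient_truth()] value of `metric`
#' matches `target_ms`. Used to build benchmark transients whose ground
#' truth equals a prescribed kinetic value.
#'
#' @param metric `"CD50_ms"`, `"T50on_ms"` or `"T50off_ms"`.
#' @param target_ms Target value in ms.
#' @param vary Which constant to solve for (`"tau_d"` or `"tau_r"`).
#' @param tau_r,tau_d Value of the constant held fixed (and start point).
#' @param t0,A,F0 Remaining model parameters.
#' @param interval Search interval for the varied constant (ms).
#' @param duration_ms Trace duration used by the oracle.
#' @param tol Absolute tolerance on the metric (ms).
#' @return The tuned [transient_model()].
#' @export
tune_transient <- function(metric, target_ms, vary = c("tau_d", "tau_r"),
                           tau_r = 100, tau_d = 500, t0 = 200, A = 1,
                           F0 = 0.2, interval = NULL, duration_ms = 6000,
                           tol = 0.01) {
  vary <- match.arg(vary)
  if (is.null(interval)) {
    interval <- if (vary == "tau_d") c(tau_r * 1.01, 5e4) else c(0.1, tau_d * 0.99)
  }
  objective <- function(x) {
    m <- if (vary == "tau_d") {
      transient_model(t0, tau_r, x, A, F0)
    } else {
      transient_model(t0, x, tau_d, A, F0)
    }
    # cover slow decays: extend the window and coarsen the oracle grid as
    # needed (crossing interpolation keeps errors far below `tol`)
    dur <- max(duration_ms, t0 + 12 * max(m$tau_d, m$tau_r))
    val <- transient_truth(m, dur, step_ms = max((1000 / 83) / 1000,
                                                 dur / 4e5))[[metric]]
    if (is.na(val)) return(1e6)   # metric unreachable: treat as too large
    val - target_ms
  }
  root <- stats::uniroot(objective, interval, tol = tol)$root
  if (vary == "tau_d") transient_model(t0, tau_r, root, A, F0)
  else transient_model(t0, root, tau_d, A, F0)
}
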