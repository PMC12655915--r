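# Synthetic electronic-nose data generator.
#
# Emulates the standardized 3-phase aroma digitization protocol (ambient
# reference sampling, aroma exposure, sensor recovery plus a post-recovery
# buffer) on a 32-channel chemiresistive array, with class-conditional VOC
# response kinetics and a relative-humidity confounder that distorts the
# channels non-linearly and can be spuriously correlated with the class
# label in training data.

#' Sampling-protocol description
#'
#' Durations of the three protocol phases plus the post-recovery buffer.
#' At the defaults (30 s ambient, 30 s exposure, 50 s recovery, 60 s
#' buffer, 1 Hz) a recording has 170 timesteps.
#'
#' @param ambient_s ambient reference phase duration, seconds.
#' @param exposure_s aroma exposure phase duration, seconds.
#' @param recovery_s sensor recovery phase duration, seconds.
#' @param buffer_s post-recovery buffer retained after truncation, seconds.
#' @param rate_hz sampling rate, Hz.
#' @return A \code{ProtocolSpec} record (validated list).
#' @examples
#' protocolSpec()          # 170 timesteps at the defaults
#' @export
protocolSpec <- function(ambient_s = 30, exposure_s = 30, recovery_s = 50,
                         buffer_s = 60, rate_hz = 1) {
  p <- list(ambient_s = ambient_s, exposure_s = exposure_s,
            recovery_s = recovery_s, buffer_s = buffer_s, rate_hz = rate_hz)
  if (any(unlist(p[1:4]) <= 0) || rate_hz <= 0)
    stop("all protocol durations and the sampling rate must be positive")
  structure(p, class = "ProtocolSpec")
}

#' Total number of timesteps of a protocol
#' @param protocol a [protocolSpec()] record.
#' @return Integer timestep count.
#' @export
nTimesteps <- function(protocol) {
  as.integer(round((protocol$ambient_s + protocol$exposure_s +
                    protocol$recovery_s + protocol$buffer_s) *
                   protocol$rate_hz))
}

# phase-end sample indices (ambient, exposure, recovery)
protocol_phases <- function(protocol) {
  r <- protocol$rate_hz
  as.integer(round(cumsum(c(protocol$ambient_s, protocol$exposure_s,
                            protocol$recovery_s)) * r))
}

#' @export
print.ProtocolSpec <- function(x, ...) {
  cat(sprintf("ProtocolSpec: %gs ambient / %gs exposure / %gs recovery + %gs buffer @ %g Hz (%d timesteps)\n",
              x$ambient_s, x$exposure_s, x$recovery_s, x$buffer_s, x$rate_hz,
              nTimesteps(x)))
  invisible(x)
}

#' Simulation configuration for the synthetic e-nose
#'
#' Defines the sensor array and the confounding model. Channel responses
#' follow first-order adsorption/desorption kinetics with class-dependent
#' amplitudes (\code{sensitivity_matrix}); humidity enters each channel
#' affinely in the humidity excess over ambient, with per-channel
#' multiplicative gains \code{gamma} and additive offsets \code{beta}. The
#' per-sample humidity peak level is drawn from class-conditional
#' distributions whose separation is set by \code{rho}, creating the
#' spurious class-humidity association a naive classifier exploits.
#'
#' Default patterns for \code{sensitivity_matrix}, \code{gamma} and
#' \code{beta} are smooth deterministic functions of the channel index, so
#' the default configuration is a fixed, reproducible study condition.
#'
#' @param n_channels number of sensor channels.
#' @param n_classes number of aroma classes.
#' @param sensitivity_matrix n_channels x n_classes response amplitudes;
#'   \code{NULL} for the default pattern.
#' @param tau_adsorb,tau_desorb VOC adsorption/desorption time constants,
#'   seconds.
#' @param tau_humidity_desorb humidity desorption time constant, seconds;
#'   slower than the VOC constant because water desorbs sluggishly
#'   (hysteresis).
#' @param humidity_tau_cv coefficient of variation of the per-sample
#'   log-normal multiplier applied to the humidity rise and decay time
#'   constants (breath-flow / pump variability); multipliers are clipped
#'   to [0.3, 3].
#' @param humidity_ambient reference ambient relative humidity (fraction).
#' @param humidity_ambient_sd across-sample standard deviation of the
#'   per-recording ambient humidity (day-to-day / session variability);
#'   draws are clipped to [0.1, 0.7].
#' @param humidity_breath length-2 range of breath-like peak humidity
#'   levels used for unshifted draws.
#' @param humidity_shifted length-2 range of peak humidity levels for the
#'   range-shifted generalization split; must be disjoint from
#'   \code{humidity_breath}.
#' @param gamma per-channel multiplicative humidity gains; \code{NULL} for
#'   the default pattern (scale 0.4).
#' @param beta per-channel additive humidity offsets; \code{NULL} for the
#'   default pattern (scale 1.0).
#' @param rho class-humidity correlation in [-1, 1] for unshifted draws.
#' @param noise_sd Gaussian measurement-noise standard deviation.
#' @param drift_sd per-step standard deviation of the slow random-walk
#'   baseline drift.
#' @param amplitude_cv coefficient of variation of the per-sample response
#'   gain, emulating inter-individual/physiological variability of the VOC
#'   signal strength.
#' @param sensitivity_jitter_sd standard deviation of the per-sample,
#'   per-channel multiplicative jitter on the effective sensitivity
#'   pattern (sensor-state / session variability); blurs the VOC
#'   scentprint so the spurious humidity shortcut is genuinely tempting.
#' @param seed default RNG seed used by [simulateDataset()].
#' @return A \code{SimConfig} record (validated list).
#' @export
simConfig <- function(n_channels = 32, n_classes = 2,
                      sensitivity_matrix = NULL,
                      tau_adsorb = 8, tau_desorb = 20,
                      tau_humidity_desorb = 40,
                      humidity_tau_cv = 0.4,
                      humidity_ambient = 0.4,
                      humidity_ambient_sd = 0.15,
                      humidity_breath = c(0.85, 0.99),
                      humidity_shifted = c(0.55, 0.70),
                      gamma = NULL, beta = NULL, rho = 0.6,
                      noise_sd = 0.01, drift_sd = 0.002,
                      amplitude_cv = 0.2, sensitivity_jitter_sd = 0.5,
                      seed = 1L) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (n_classes < 1) stop("n_classes must be >= 1")
  if (tau_adsorb <= 0 || tau_desorb <= 0 || tau_humidity_desorb <= 0)
    stop("kinetic time constants must be positive")
  if (any(c(humidity_ambient, humidity_breath, humidity_shifted) < 0) ||
      any(c(humidity_ambient, humidity_breath, humidity_shifted) > 1))
    stop("humidity levels must lie in [0, 1]")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (noise_sd < 0 || drift_sd < 0) stop("noise scales must be nonnegative")
  if (amplitude_cv < 0) stop("amplitude_cv must be nonnegative")
  if (humidity_ambient_sd < 0) stop("humidity_ambient_sd must be nonnegative")
  if (sensitivity_jitter_sd < 0) stop("sensitivity_jitter_sd must be nonnegative")
  if (humidity_tau_cv < 0) stop("humidity_tau_cv must be nonnegative")
  i <- seq_len(n_channels) - 1
  if (is.null(sensitivity_matrix)) {
    sensitivity_matrix <- sapply(seq_len(n_classes) - 1, function(cl)
      0.035 * (1 + 0.30 * sin(2 * pi * i / n_channels + 2 * pi * cl / n_classes)))
    sensitivity_matrix <- matrix(sensitivity_matrix, n_channels, n_classes)
  }
  if (!all(dim(sensitivity_matrix) == c(n_channels, n_classes)))
    stop("sensitivity_matrix must be n_channels x n_classes")
  if (is.null(gamma))
    gamma <- 0.4 * (0.5 + 0.5 * sin(2 * pi * 3 * i / n_channels + 1))
  if (is.null(beta))
    beta <- 1.0 * (0.5 + 0.5 * cos(2 * pi * 5 * i / n_channels + 2))
  if (length(gamma) != n_channels || length(beta) != n_channels)
    stop("gamma and beta must have one entry per channel")
  structure(list(n_channels = n_channels, n_classes = n_classes,
                 sensitivity_matrix = sensitivity_matrix,
                 tau_adsorb = tau_adsorb, tau_desorb = tau_desorb,
                 tau_humidity_desorb = tau_humidity_desorb,
                 humidity_tau_cv = humidity_tau_cv,
                 humidity_ambient = humidity_ambient,
                 humidity_ambient_sd = humidity_ambient_sd,
                 humidity_breath = humidity_breath,
                 humidity_shifted = humidity_shifted,
                 gamma = gamma, beta = beta, rho = rho,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 amplitude_cv = amplitude_cv,
                 sensitivity_jitter_sd = sensitivity_jitter_sd,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d channels, %d classes | tau_ads %gs, tau_des %gs, tau_h_des %gs\n",
              x$n_channels, x$n_classes, x$tau_adsorb, x$tau_desorb,
              x$tau_humidity_desorb))
  cat(sprintf("  humidity: ambient %.2f, breath [%.2f, %.2f], shifted [%.2f, %.2f], rho %.2f\n",
              x$humidity_ambient, x$humidity_breath[1], x$humidity_breath[2],
              x$humidity_shifted[1], x$humidity_shifted[2], x$rho))
  invisible(x)
}

# first-order rise during exposure, exponential decay after, per unit forcing
kinetic_profile <- function(protocol, tau_rise, tau_fall) {
  t_total <- nTimesteps(protocol)
  ph <- protocol_phases(protocol)
  tvec <- seq_len(t_total) / protocol$rate_hz
  t_amb <- ph[1] / protocol$rate_hz
  t_exp <- ph[2] / protocol$rate_hz
  k <- numeric(t_total)
  rising <- tvec > t_amb & tvec <= t_exp
  k[rising] <- 1 - exp(-(tvec[rising] - t_amb) / tau_rise)
  peak <- 1 - exp(-(t_exp - t_amb) / tau_rise)
  falling <- tvec > t_exp
  k[falling] <- peak * exp(-(tvec[falling] - t_exp) / tau_fall)
  k
}

#' Simulate a humidity trace
#'
#' The trace sits at the ambient humidity during the reference phase, rises
#' with first-order kinetics toward \code{level} during exposure, and decays
#' back toward ambient during recovery and buffer with the (slow) humidity
#' desorption constant. Gaussian noise of scale \code{noise_sd} is added and
#' the result is clipped to [0, 1].
#'
#' @param protocol a [protocolSpec()].
#' @param cfg a [simConfig()].
#' @param level peak humidity level approached during exposure (fraction).
#' @param seed optional RNG seed; \code{NULL} continues the current RNG
#'   stream.
#' @param ambient starting (ambient) humidity of this recording; defaults
#'   to the configuration's reference ambient level.
#' @param tau_mult per-sample multiplier on the humidity rise/decay time
#'   constants (flow variability); 1 for the nominal kinetics.
#' @return Numeric length-T humidity trace.
#' @export
makeHumidityTrace <- function(protocol, cfg, level, seed = NULL,
                              ambient = cfg$humidity_ambient,
                              tau_mult = 1) {
  if (level < 0 || level > 1) stop("level must lie in [0, 1]")
  if (cfg$tau_adsorb <= 0 || cfg$tau_humidity_desorb <= 0 || tau_mult <= 0)
    stop("kinetic time constants must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- kinetic_profile(protocol, tau_mult * cfg$tau_adsorb,
                       tau_mult * cfg$tau_humidity_desorb)
  h <- ambient + (level - ambient) * k
  if (cfg$noise_sd > 0)
    h <- h + stats::rnorm(length(h), 0, cfg$noise_sd)
  pmin(pmax(h, 0), 1)
}

#' Simulate a clean (humidity-free) sensor response
#'
#' Each channel sits at a unit baseline (plus slow random-walk drift)
#' during the ambient phase, rises by its class sensitivity with the VOC
#' adsorption constant during exposure, and decays with the desorption
#' constant afterwards. Channel-wise Gaussian noise is added.
#'
#' @inheritParams makeHumidityTrace
#' @param label class label in \code{1..n_classes}.
#' @return T x n_channels response matrix.
#' @export
makeCleanResponse <- function(protocol, cfg, label, seed = NULL,
                              gain = 1) {
  if (label < 1 || label > cfg$n_classes)
    stop("label must lie in 1..n_classes")
  if (!is.null(seed)) set.seed(seed)
  t_total <- nTimesteps(protocol)
  k <- kinetic_profile(protocol, cfg$tau_adsorb, cfg$tau_desorb)
  sens <- cfg$sensitivity_matrix[, label]
  if (cfg$sensitivity_jitter_sd > 0)
    sens <- sens * pmax(1 + cfg$sensitivity_jitter_sd *
                          stats::rnorm(cfg$n_channels), 0)
  signal <- gain * outer(k, sens)
  resp <- 1 + signal
  if (cfg$drift_sd > 0) {
    drift <- apply(matrix(stats::rnorm(t_total * cfg$n_channels, 0, cfg$drift_sd),
                          t_total, cfg$n_channels), 2, cumsum)
    resp <- resp + drift
  }
  if (cfg$noise_sd > 0)
    resp <- resp + matrix(stats::rnorm(t_total * cfg$n_channels, 0, cfg$noise_sd),
                          t_total, cfg$n_channels)
  resp
}

#' Apply the humidity confounding model to a clean response
#'
#' Affine per-channel coupling in the humidity excess over ambient:
#' \code{X[t, i] = clean[t, i] * (1 + gamma[i] * h(t)) + beta[i] * h(t)}
#' where \code{h(t)} is the humidity trace minus the ambient level. With
#' \code{gamma = beta = 0} the clean response is returned unchanged.
#'
#' @param clean T x n_channels clean response matrix.
#' @param humidity length-T humidity trace (fraction).
#' @param cfg a [simConfig()].
#' @return T x n_channels confounded response matrix.
#' @export
applyConfounding <- function(clean, humidity, cfg) {
  if (nrow(clean) != length(humidity))
    stop("clean response and humidity trace must have the same length")
  if (ncol(clean) != cfg$n_channels)
    stop("clean response must have n_channels columns")
  htil <- humidity - cfg$humidity_ambient
  clean * (1 + outer(htil, cfg$gamma)) + outer(htil, cfg$beta)
}

# standardized numeric score of the class label under the class prior
label_score <- function(labels, class_probs) {
  k <- length(class_probs)
  mu <- sum(seq_len(k) * class_probs)
  v <- sum((seq_len(k) - mu)^2 * class_probs)
  if (v <= 0) return(numeric(length(labels)))
  (labels - mu) / sqrt(v)
}

#' Simulate a dataset of confounded e-nose recordings
#'
#' Draws class labels from \code{class_probs}, then a per-sample peak
#' humidity level whose association with the label depends on \code{shift}:
#' \describe{
#'   \item{none}{level drawn from class-conditional Gaussians centred in
#'     the breath range, with label correlation \code{rho} (training
#'     condition).}
#'   \item{decorrelated}{same marginal level distribution, independent of
#'     the label.}
#'   \item{range_shift}{level drawn uniformly from the disjoint shifted
#'     range, independent of the label (generalization test split).}
#' }
#' Each recording is a clean class response passed through the humidity
#' confounding model.
#'
#' @inheritParams makeHumidityTrace
#' @param n number of samples (must be at least \code{n_classes}).
#' @param class_probs class prior; defaults to uniform.
#' @param shift humidity sampling regime, see Details.
#' @param seed RNG seed; defaults to \code{cfg$seed}.
#' @return List of [SensorRecording-class] objects with a
#'   \code{"sim_meta"} attribute (data.frame of label, level, shift).
#' @examples
#' recs <- simulateDataset(protocolSpec(), simConfig(), n = 4, seed = 7)
#' attr(recs, "sim_meta")
#' @export
simulateDataset <- function(protocol, cfg, n,
                            class_probs = NULL,
                            shift = c("none", "decorrelated", "range_shift"),
                            seed = cfg$seed) {
  shift <- match.arg(shift)
  if (is.null(class_probs)) class_probs <- rep(1 / cfg$n_classes, cfg$n_classes)
  if (length(class_probs) != cfg$n_classes)
    stop("class_probs must have one entry per class")
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (n < cfg$n_classes) stop("n must be at least n_classes")
  set.seed(seed)
  labels <- sample.int(cfg$n_classes, n, replace = TRUE, prob = class_probs)
  mid <- mean(cfg$humidity_breath)
  sigma <- diff(range(cfg$humidity_breath)) / 4
  eps <- stats::rnorm(n)
  levels <- switch(shift,
    none = {
      s <- label_score(labels, class_probs)
      mid + sigma * (cfg$rho * s + sqrt(1 - cfg$rho^2) * eps)
    },
    decorrelated = mid + sigma * eps,
    range_shift = stats::runif(n, cfg$humidity_shifted[1], cfg$humidity_shifted[2]))
  if (shift != "range_shift")
    levels <- pmin(pmax(levels, cfg$humidity_breath[1]), cfg$humidity_breath[2])
  gains <- pmax(1 + cfg$amplitude_cv * stats::rnorm(n), 0.2)
  ambients <- pmin(pmax(cfg$humidity_ambient +
                          cfg$humidity_ambient_sd * stats::rnorm(n),
                        0.1), 0.7)
  tau_mults <- pmin(pmax(exp(cfg$humidity_tau_cv * stats::rnorm(n) -
                               cfg$humidity_tau_cv^2 / 2), 0.3), 3)
  ph <- protocol_phases(protocol)
  recs <- vector("list", n)
  for (s in seq_len(n)) {
    h <- makeHumidityTrace(protocol, cfg, levels[s], ambient = ambients[s],
                           tau_mult = tau_mults[s])
    clean <- makeCleanResponse(protocol, cfg, labels[s], gain = gains[s])
    x <- applyConfounding(clean, h, cfg)
    recs[[s]] <- SensorRecording(response = x, humidity = h,
                                 label = labels[s], phases = ph,
                                 rate_hz = protocol$rate_hz,
                                 meta = list(level = levels[s],
                                             ambient = ambients[s],
                                             shift = shift))
  }
  attr(recs, "sim_meta") <- data.frame(label = labels, level = levels,
                                       shift = shift, seed = seed)
  recs
}
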