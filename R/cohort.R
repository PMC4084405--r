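# truncated-normal draw by rejection (floors are far in the tail, so cheap)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' A virtual animal
#'
#' Hidden per-animal parameters of the synthetic population: the strength of
#' the hyperpolarizing (`h`, mV) and depolarizing (`d`, mV) components of the
#' direct C2-to-VSI synapse measured in Hi-Di saline, the motor-pattern and
#' behavioral baselines, the excitatory drive available to the episode, the
#' distal-zone excitability, and the spike-propagation category implied by
#' `h`.
#'
#' @param id Animal identifier.
#' @param h,d Synaptic amplitudes, mV (`h >= 0`, `d >= 0`).
#' @param baseline Intact VSI bursts per swim episode (expected).
#' @param flexion_baseline Intact body flexions per swim (expected).
#' @param drive Episode drive reservoir scale (dimensionless).
#' @param distal_gain Distal spike-initiation-zone excitability multiplier.
#' @param category Propagation category, or `NA` to derive it from `h`.
#' @return Object of class `virtual_animal`.
#' @export
virtual_animal <- function(id = 1L, h = 2.9, d = 0.8, baseline = 6,
                           flexion_baseline = 6, drive = 1,
                           distal_gain = 1, category = NA_character_) {
  stopifnot(h >= 0, d >= 0, drive > 0, distal_gain > 0)
  structure(list(id = id, h = h, d = d, baseline = baseline,
                 flexion_baseline = flexion_baseline, drive = drive,
                 distal_gain = distal_gain, category = category),
            class = "virtual_animal")
}

#' Cohort configuration
#'
#' Distributional defaults of the synthetic population. The synaptic
#' amplitudes follow the measured Hi-Di population: hyperpolarizations
#' 2.9 +/- 1.3 mV and depolarizations 0.8 +/- 0.36 mV (mean +/- SD), drawn
#' independently and truncated at a small positive floor. Intact swim
#' episodes average six VSI bursts / body flexions. The propagation-category
#' thresholds on `h` reproduce the observed 24.6 / 68.1 / 7.2 percent
#' antidromic / mixed / orthodromic split (the thresholds are the matching
#' quantiles of the `h` distribution).
#'
#' @param n_animals Cohort size (>= 2).
#' @param h_mean,h_sd,h_floor Hyperpolarization distribution, mV.
#' @param d_mean,d_sd,d_floor Depolarization distribution, mV.
#' @param baseline_mean,baseline_sd Intact burst-count distribution.
#' @param flexion_mean,flexion_sd Intact flexion-count distribution.
#' @param episode_sd Episode-to-episode count noise (SD).
#' @param drive_cv Animal-to-animal CV of the episode drive reservoir.
#' @param distal_sdlog Log-SD of the distal excitability multiplier.
#' @param ortho_max,anti_min Category thresholds on `h`, mV.
#' @param coef Lesion-loss mapping coefficients
#'   (see [lesion_mapping_defaults()]).
#' @param surgery_effect Fixed post-surgery flexion decrement (both arms).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 34,
                          h_mean = 2.9, h_sd = 1.3, h_floor = 0.2,
                          d_mean = 0.8, d_sd = 0.36, d_floor = 0.1,
                          baseline_mean = 6, baseline_sd = 1.0,
                          flexion_mean = 6.0, flexion_sd = 1.26,
                          episode_sd = 0.45,
                          drive_cv = 0.05,
                          distal_sdlog = 0.07,
                          ortho_max = NULL, anti_min = NULL,
                          coef = lesion_mapping_defaults(),
                          surgery_effect = 0.5) {
  stopifnot(n_animals >= 2, h_sd > 0, d_sd > 0)
  # quantile-matched category thresholds: 7.2 % orthodromic-only (low h),
  # 24.6 % antidromic-only (high h)
  if (is.null(ortho_max)) ortho_max <- stats::qnorm(0.072, h_mean, h_sd)
  if (is.null(anti_min)) anti_min <- stats::qnorm(1 - 0.246, h_mean, h_sd)
  structure(list(n_animals = n_animals, h_mean = h_mean, h_sd = h_sd,
                 h_floor = h_floor, d_mean = d_mean, d_sd = d_sd,
                 d_floor = d_floor, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, flexion_mean = flexion_mean,
                 flexion_sd = flexion_sd, episode_sd = episode_sd,
                 drive_cv = drive_cv, distal_sdlog = distal_sdlog,
                 ortho_max = ortho_max, anti_min = anti_min,
                 coef = coef, surgery_effect = surgery_effect),
            class = "cohort_config")
}

#' Generate a virtual-animal cohort
#'
#' Pure function of `(config, seed)`: the same seed reproduces the same
#' cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of [virtual_animal()] objects with class `virtual_cohort`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_animals
  h <- rtnorm(n, config$h_mean, config$h_sd, lower = config$h_floor)
  d <- rtnorm(n, config$d_mean, config$d_sd, lower = config$d_floor)
  baseline <- pmin(8, pmax(4, round(stats::rnorm(n, config$baseline_mean,
                                                 config$baseline_sd))))
  flex <- pmin(10, pmax(2, round(stats::rnorm(n, config$flexion_mean,
                                              config$flexion_sd))))
  drive <- rtnorm(n, 1, config$drive_cv, lower = 0.7, upper = 1.3)
  dg <- stats::rlnorm(n, 0, config$distal_sdlog)
  cat_h <- ifelse(h < config$ortho_max, "orthodromic-only",
                  ifelse(h > config$anti_min, "antidromic-only", "mixed"))
  animals <- lapply(seq_len(n), function(i)
    virtual_animal(id = i, h = h[i], d = d[i], baseline = baseline[i],
                   flexion_baseline = flex[i], drive = drive[i],
                   distal_gain = dg[i], category = cat_h[i]))
  structure(animals, class = "virtual_cohort", config = config, seed = seed)
}

#' @export
as.data.frame.virtual_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(a)
    data.frame(id = a$id, h = a$h, d = a$d, baseline = a$baseline,
               flexion_baseline = a$flexion_baseline, drive = a$drive,
               distal_gain = a$distal_gain, category = a$category,
               stringsAsFactors = FALSE)))
}

#' @export
print.virtual_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Virtual cohort: %d animals; h %.2f +/- %.2f mV (CoV %.2f), d %.2f +/- %.2f mV\n",
              nrow(df), mean(df$h), stats::sd(df$h), coef_variation(df$h),
              mean(df$d), stats::sd(df$d)))
  print(table(df$category))
  invisible(x)
}

#' Default lesion-susceptibility mapping coefficients
#'
#' Expected loss of VSI bursts (or body flexions) after PdN6 disconnection,
#' as a function of the hidden hyperpolarization amplitude `h`:
#' `loss = clip(alpha + beta * h + gamma * epsilon, 0, n)` with standard
#' normal `epsilon`. The values are the output of
#' [calibrate_population_model()] at its default targets and seed; rerunning
#' the calibration reproduces them.
#'
#' @return Named numeric vector `c(alpha, beta, gamma)`.
#' @export
lesion_mapping_defaults <- function() {
  c(alpha = -2.3, beta = 1.2, gamma = 1.0)
}

#' Expected-loss draw of the lesion mapping
#'
#' @param h Hyperpolarization amplitude, mV.
#' @param n_max Cap (the pre-lesion count).
#' @param coef Mapping coefficients.
#' @return One stochastic loss draw (continuous, in `[0, n_max]`).
#' @export
lesion_loss <- function(h, n_max, coef = lesion_mapping_defaults()) {
  raw <- coef[["alpha"]] + coef[["beta"]] * h +
    coef[["gamma"]] * stats::rnorm(length(h))
  pmin(pmax(raw, 0), n_max)
}

#' Draw a behavioral flexion count for one animal
#'
#' Intact pre-surgery swims draw around the animal's flexion baseline
#' (population mean 6, CoV about 0.21 by construction). Post-surgery counts
#' lose a fixed small surgery decrement (both arms); lesioned animals
#' additionally lose the `h`-dependent mapping amount. A swim that would be
#' left with fewer than three flexions usually collapses entirely -- a body
#' retraction without a flexion, scored as 0 (swim failure).
#'
#' @param animal A [virtual_animal()].
#' @param lesioned Was PdN6 cut (vs sham)?
#' @param post_surgery Is this a post-surgery observation?
#' @param config A [cohort_config()] (mapping coefficients, noise, surgery
#'   effect).
#' @return Integer flexion count (>= 0; 0 encodes swim failure).
#' @export
generate_behavior <- function(animal, lesioned = FALSE, post_surgery = lesioned,
                              config = cohort_config()) {
  stopifnot(inherits(animal, "virtual_animal"))
  base <- animal$flexion_baseline + stats::rnorm(1, 0, config$episode_sd)
  if (post_surgery) base <- base - config$surgery_effect
  loss <- if (lesioned) lesion_loss(animal$h, n_max = 10, coef = config$coef) else 0
  left <- base - loss
  if (lesioned && left < 3) {
    # complete disruption: retraction without flexion in most such swims
    return(stats::rbinom(1L, 1L, 0.25))
  }
  max(0L, min(10L, as.integer(round(left))))
}

#' Draw a motor-pattern burst count for one animal (count-level generator)
#'
#' The count-level counterpart of simulating a full episode: intact episodes
#' draw around the animal's burst baseline; lesioned episodes subtract the
#' shared `h`-dependent mapping loss (floored at one burst -- even strongly
#' inhibited preparations retain an initial proximal burst).
#'
#' @inheritParams generate_behavior
#' @return Integer burst count.
#' @export
generate_motor_count <- function(animal, lesioned = FALSE,
                                 config = cohort_config()) {
  stopifnot(inherits(animal, "virtual_animal"))
  base <- animal$baseline + stats::rnorm(1, 0, config$episode_sd)
  loss <- if (lesioned) lesion_loss(animal$h, n_max = 10, coef = config$coef) else 0
  cnt <- as.integer(round(base - loss))
  max(if (lesioned) 1L else 2L, min(10L, cnt))
}

# shared kinetics kernels of the Hi-Di PSP generator, cached per dt
.psp_kernel_cache <- new.env(parent = emptyenv())

.psp_kernels <- function(dt = 0.5, duration = 14, stim_onset = 2,
                         stim_dur = 4, rate = 10) {
  key <- paste(dt, duration, stim_onset, stim_dur, rate, sep = "|")
  hit <- .psp_kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- as.integer(duration * 1000 / dt)
  tt <- (seq_len(n) - 1L) * dt            # ms
  v_pre <- rep(-50, n)
  spike_starts <- seq(stim_onset * 1000, (stim_onset + stim_dur) * 1000 - 1,
                      by = 1000 / rate)
  for (s0 in spike_starts) {
    idx <- which(tt >= s0 & tt < s0 + 2)  # 2 ms spike width
    v_pre[idx] <- 30
  }
  k <- synapse_kinetics(components = list(c(1 / 3, 150), c(1 / 3, 700),
                                          c(1 / 3, 1300)))
  s_inf <- steady_state_activation(v_pre, k)
  S <- clamp_activation_core(s_inf, c(150, 700, 1300), dt)
  K_d <- S[1L, ] / max(S[1L, ])
  slow <- 0.5 * (S[2L, ] + S[3L, ])
  K_h <- slow / max(slow)
  res <- list(K_d = K_d, K_h = K_h, dt = dt, n = n,
              stim_onset = stim_onset, stim_dur = stim_dur,
              duration = duration)
  .psp_kernel_cache[[key]] <- res
  res
}

#' Generate a Hi-Di isolated biphasic PSP trace
#'
#' Builds the VSI membrane response to the standard C2 stimulation (10 Hz,
#' 4 s) in Hi-Di saline from the dual-time-constant release kinetics: a fast
#' depolarising lobe scaled so that the measured depolarization equals the
#' animal's `d`, and a slow (700/1300 ms) hyperpolarising lobe scaled so the
#' measured peak-to-trough hyperpolarization equals `h`, plus white noise.
#' Amplitudes scale linearly with `(d, h)` by construction.
#'
#' @param animal A [virtual_animal()] (uses `h` and `d`).
#' @param noise_sd Gaussian noise SD, mV.
#' @param seed Integer seed.
#' @param dt Sample interval, ms.
#' @param baseline Resting potential, mV.
#' @return List with `trace` (data frame `time`, `VSI`), `dt`, `stim_onset`,
#'   `stim_dur`, `baseline_window`, `search_window`, `animal`.
#' @export
generate_hi_di_psp_trace <- function(animal, noise_sd = 0.05, seed = 1,
                                     dt = 0.5, baseline = -50) {
  stopifnot(inherits(animal, "virtual_animal"), noise_sd >= 0)
  kr <- .psp_kernels(dt)
  bw <- c(0.5, kr$stim_onset - 0.2)
  sw <- c(kr$stim_onset, kr$duration - 2)
  compose <- function(a, b) baseline + a * kr$K_d - b * kr$K_h
  meas <- function(a, b) {
    m <- measure_psp(compose(a, b), dt, bw, sw)
    c(dep = m$depolarization, hyp = m$hyperpolarization)
  }
  d <- animal$d; h <- animal$h
  a <- 0; b <- 0
  if (d > 0 || h > 0) {
    # both measured amplitudes are monotone in their own scale, so nested
    # root-finding with an expanding bracket recovers the exact scales even
    # when the opposite lobe dominates the raw trace
    expand_root <- function(f, hi0) {
      hi <- hi0
      for (i in 1:30) {
        if (f(hi) >= 0) return(stats::uniroot(f, c(0, hi), tol = 1e-3)$root)
        hi <- hi * 2
      }
      stop("generate_hi_di_psp_trace(): cannot reach the target amplitudes (d = ",
           d, ", h = ", h, ")")
    }
    if (h == 0) {
      a <- expand_root(function(x) meas(x, 0)["dep"] - d, max(d, 1))
    } else if (d == 0) {
      b <- expand_root(function(x) meas(0, x)["hyp"] - h, max(h, 1))
    } else {
      a_for <- function(bb) expand_root(function(x) meas(x, bb)["dep"] - d,
                                        max(d, 1))
      b <- expand_root(function(x) meas(a_for(x), x)["hyp"] - h, max(h, 1))
      a <- a_for(b)
    }
  }
  set.seed(as.integer(seed))
  v <- compose(a, b) + stats::rnorm(kr$n, 0, noise_sd)
  list(trace = data.frame(time = (seq_len(kr$n) - 1L) * dt / 1000, VSI = v),
       dt = dt, stim_onset = kr$stim_onset, stim_dur = kr$stim_dur,
       baseline_window = bw, search_window = sw, animal = animal)
}

#' Generate a dual-site (soma + nerve) classifier fixture
#'
#' Builds an episode with a known propagation ground truth: `n_bursts` VSI
#' bursts recorded at the soma, each paired with nerve impulses offset by the
#' conduction delay in the direction dictated by the category. The mixed
#' category switches from orthodromic to antidromic mid-episode, as spike
#' initiation typically shifts distally over the course of a swim.
#'
#' @param category `"antidromic-only"`, `"mixed"`, or `"orthodromic-only"`.
#' @param n_bursts Number of bursts.
#' @param delay Conduction delay, ms (> 0).
#' @param noise_sd Timing jitter SD, ms.
#' @param seed Integer seed.
#' @param spikes_per_burst Spikes per burst.
#' @return An `episode_recording` (events only, no traces).
#' @export
generate_dual_site_fixture <- function(category = c("antidromic-only", "mixed",
                                                    "orthodromic-only"),
                                       n_bursts = 5, delay = 25, noise_sd = 0,
                                       seed = 1, spikes_per_burst = 8) {
  category <- match.arg(category)
  if (delay <= 0) stop("generate_dual_site_fixture(): delay must be > 0")
  stopifnot(n_bursts >= 1, spikes_per_burst >= 2)
  set.seed(as.integer(seed))
  soma <- numeric(0); nerve <- numeric(0); origin <- character(0)
  burst_dir <- switch(category,
    "antidromic-only" = rep("antidromic", n_bursts),
    "orthodromic-only" = rep("orthodromic", n_bursts),
    "mixed" = c(rep("orthodromic", ceiling(n_bursts / 2)),
                rep("antidromic", n_bursts - ceiling(n_bursts / 2))))
  for (k in seq_len(n_bursts)) {
    t0 <- 3 + (k - 1) * 6
    st <- t0 + (seq_len(spikes_per_burst) - 1L) * 0.08
    jitter <- stats::rnorm(spikes_per_burst, 0, noise_sd) / 1000
    off <- if (burst_dir[k] == "antidromic") -delay / 1000 else delay / 1000
    soma <- c(soma, st)
    nerve <- c(nerve, st + off + jitter)
    origin <- c(origin, rep(if (burst_dir[k] == "antidromic") "distal"
                            else "proximal", spikes_per_burst))
  }
  o <- order(soma)
  structure(list(
    dt = NA_real_, duration = max(soma) + 3,
    channels = NULL,
    spike_times = list(VSI_soma = soma[o]),
    soma_events = data.frame(time = soma[o], origin = origin[o],
                             stringsAsFactors = FALSE),
    nerve_impulse_times = sort(nerve),
    nerve_kind = "triphasic",
    epsp_events = data.frame(time = numeric(0), amplitude = numeric(0)),
    stim_window = c(0, 1),
    condition = list(pdn6_intact = TRUE, hi_di = FALSE, clamp_mode = "off",
                     stim = "fixture", category = category),
    animal = NULL, seed = seed),
    class = "episode_recording")
}
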