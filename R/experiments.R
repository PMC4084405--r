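# Scripted in-silico reproductions of the figure-level experiments.

#' Describe an experiment run
#'
#' A light container bundling the cohort configuration, arm size, and seed
#' that every `run_*()` experiment consumes. Each experiment supplies its own
#' conventional arm size (the N of the corresponding study) when `n` is
#' `NULL`.
#'
#' @param name Experiment name.
#' @param config A [cohort_config()].
#' @param n Animals (or pairs / preparations) per arm; `NULL` = experiment
#'   default.
#' @param seed Integer seed; every experiment is a pure function of
#'   `(spec)`.
#' @param circuit_config Circuit parameters for the episode-level
#'   experiments ([cpg_defaults()]).
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(name = "experiment", config = cohort_config(),
                            n = NULL, seed = 1,
                            circuit_config = cpg_defaults()) {
  stopifnot(inherits(config, "cohort_config"), is.null(n) || n >= 2)
  structure(list(name = name, config = config, n = n, seed = seed,
                 circuit_config = circuit_config),
            class = "experiment_spec")
}

.cohort_result <- function(name, rows, summary) {
  structure(list(name = name, rows = rows, summary = summary),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort result:", x$name, "-", nrow(x$rows), "rows\n")
  str(x$summary, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Behavioral lesion experiment: paired cut vs sham cohorts
#'
#' Nerve-cut animals are blindly paired with sham-operated ones; each animal
#' swims at three pre-surgery timepoints and one post-surgery timepoint.
#' Reports per-timepoint mean flexion counts and CoV for both arms, and the
#' Levene-median test of post-surgery variance (cut vs sham).
#'
#' @param spec An [experiment_spec()]; default arm size 11 pairs.
#' @return A `cohort_result` with per-swim rows and a summary list.
#' @export
run_behavior_lesion <- function(spec = experiment_spec("behavior_lesion")) {
  n <- if (is.null(spec$n)) 11L else spec$n
  cfg <- spec$config
  cfg$n_animals <- 2L * n
  cohort <- generate_cohort(cfg, seed = spec$seed)
  set.seed(spec$seed + 7919L)
  arms <- rep(c("cut", "sham"), each = n)
  rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    a <- cohort[[i]]
    arm <- arms[i]
    pre <- vapply(1:3, function(k)
      generate_behavior(a, lesioned = FALSE, post_surgery = FALSE,
                        config = cfg), integer(1))
    post <- generate_behavior(a, lesioned = (arm == "cut"),
                              post_surgery = TRUE, config = cfg)
    data.frame(id = a$id, arm = arm, h = a$h, timepoint = c(1:3, 4L),
               phase = c(rep("pre", 3), "post"),
               flexions = c(pre, post))
  }))
  by_tp <- function(arm, tp) rows$flexions[rows$arm == arm & rows$timepoint == tp]
  tp_stats <- do.call(rbind, lapply(1:4, function(tp) {
    data.frame(timepoint = tp,
               mean_cut = mean(by_tp("cut", tp)),
               mean_sham = mean(by_tp("sham", tp)),
               cov_cut = coef_variation(by_tp("cut", tp)),
               cov_sham = coef_variation(by_tp("sham", tp)))
  }))
  lev <- levene_median_test(by_tp("cut", 4L), by_tp("sham", 4L))
  .cohort_result("behavior_lesion", rows, list(
    timepoints = tp_stats,
    cov_cut_pre = coef_variation(rows$flexions[rows$arm == "cut" &
                                                 rows$phase == "pre"]),
    cov_cut_post = tp_stats$cov_cut[4L],
    cov_sham_post = tp_stats$cov_sham[4L],
    levene_post = lev))
}

#' Motor-pattern lesion experiment: four episodes, block before the last
#'
#' Each preparation produces the swim motor pattern four times; the nerve is
#' blocked between episodes 3 and 4. Reports per-episode burst counts, the
#' pre/post coefficient of variation, per-animal percent changes, the paired
#' episode-1 vs episode-3 stability test, and the Levene variance test.
#'
#' @param spec An [experiment_spec()]; default 34 preparations.
#' @return A `cohort_result`.
#' @export
run_motor_lesion <- function(spec = experiment_spec("motor_lesion")) {
  n <- if (is.null(spec$n)) 34L else spec$n
  cfg <- spec$config
  cfg$n_animals <- n
  cohort <- generate_cohort(cfg, seed = spec$seed)
  set.seed(spec$seed + 104729L)
  rows <- do.call(rbind, lapply(cohort, function(a) {
    eps <- c(vapply(1:3, function(k)
      generate_motor_count(a, lesioned = FALSE, config = cfg), integer(1)),
      generate_motor_count(a, lesioned = TRUE, config = cfg))
    data.frame(id = a$id, h = a$h, episode = 1:4,
               blocked = c(FALSE, FALSE, FALSE, TRUE), bursts = eps)
  }))
  ep <- function(k) rows$bursts[rows$episode == k]
  pc <- percent_change(ep(3), ep(4))
  .cohort_result("motor_lesion", rows, list(
    mean_pre = mean(ep(3)), mean_post = mean(ep(4)),
    cov_pre = coef_variation(ep(3)), cov_post = coef_variation(ep(4)),
    percent_change = pc, mean_percent_change = mean(pc),
    stability_t_1v3 = paired_t_test(ep(1), ep(3)),
    levene = levene_median_test(ep(3), ep(4))))
}

#' Correlation suite: hidden PSP amplitudes vs lesion susceptibility
#'
#' Per animal: a Hi-Di PSP trace is generated and measured to obtain the
#' observed depolarization/hyperpolarization amplitudes, and the motor
#' pattern is counted before and after disconnection. Reports the
#' regressions of the lesioned burst count and the percent change on the
#' measured amplitudes, the intact-condition null (no correlation of the
#' intact count with hyperpolarization), and the Fig 5C-style null of the
#' intact count against the C2 firing produced by the standard stimulus.
#'
#' @param spec An [experiment_spec()]; default 50 animals.
#' @param noise_sd PSP trace noise, mV RMS.
#' @return A `cohort_result`.
#' @export
run_correlation_suite <- function(spec = experiment_spec("correlation_suite"),
                                  noise_sd = 0.05) {
  n <- if (is.null(spec$n)) 50L else spec$n
  cfg <- spec$config
  cfg$n_animals <- n
  cohort <- generate_cohort(cfg, seed = spec$seed)
  set.seed(spec$seed + 15485863L)
  rows <- do.call(rbind, lapply(cohort, function(a) {
    tr <- generate_hi_di_psp_trace(a, noise_sd = noise_sd,
                                   seed = spec$seed * 1000L + a$id)
    m <- measure_psp(tr$trace$VSI, tr$dt,
                     baseline_window = tr$baseline_window,
                     search_window = tr$search_window)
    pre <- generate_motor_count(a, lesioned = FALSE, config = cfg)
    post <- generate_motor_count(a, lesioned = TRUE, config = cfg)
    # C2 spike count under the standard 10 Hz / 4 s train: set by the
    # stimulus and the cell's excitability, not by the hidden amplitudes
    c2_spikes <- max(1L, round(40 * a$drive + stats::rnorm(1, 0, 2)))
    data.frame(id = a$id, h = a$h, d = a$d,
               meas_h = m$hyperpolarization, meas_d = m$depolarization,
               pre = pre, post = post,
               pc = percent_change(pre, post), c2_spikes = c2_spikes)
  }))
  .cohort_result("correlation_suite", rows, list(
    pc_vs_hyp = linear_regression(rows$meas_h, rows$pc),
    post_vs_hyp = linear_regression(rows$meas_h, rows$post),
    pc_vs_dep = linear_regression(rows$meas_d, rows$pc),
    intact_vs_hyp = linear_regression(rows$meas_h, rows$pre),
    intact_vs_c2 = linear_regression(rows$c2_spikes, rows$pre),
    dep_vs_hyp = linear_regression(rows$meas_h, rows$meas_d)))
}

#' Propagation census: classify dual-site recordings across a cohort
#'
#' Builds one dual-site fixture per animal according to its propagation
#' category, classifies every episode with [match_and_classify()], and
#' reports the category percentages together with each category's mean
#' lesioned percent change (orthodromic-only animals are least impaired,
#' antidromic-only most).
#'
#' @param spec An [experiment_spec()]; default 69 animals.
#' @param delay PdN6 conduction delay of the fixtures, ms.
#' @return A `cohort_result`.
#' @export
run_propagation_census <- function(
    spec = experiment_spec("propagation_census"), delay = 25) {
  n <- if (is.null(spec$n)) 69L else spec$n
  cfg <- spec$config
  cfg$n_animals <- n
  cohort <- generate_cohort(cfg, seed = spec$seed)
  set.seed(spec$seed + 32452843L)
  rows <- do.call(rbind, lapply(cohort, function(a) {
    fx <- generate_dual_site_fixture(a$category, n_bursts = 5, delay = delay,
                                     noise_sd = 0, seed = spec$seed + a$id)
    lab <- classify_episode_propagation(fx, window = 2 * delay)
    pre <- generate_motor_count(a, lesioned = FALSE, config = cfg)
    post <- generate_motor_count(a, lesioned = TRUE, config = cfg)
    data.frame(id = a$id, h = a$h, true_category = a$category,
               classified = lab$animal,
               pre = pre, post = post, pc = percent_change(pre, post))
  }))
  shares <- table(rows$classified) / nrow(rows) * 100
  pc_by_cat <- tapply(rows$pc, rows$classified, mean)
  # categories can be very rare at this N; the omnibus test needs n >= 2
  grp <- Filter(function(g) length(g) >= 2L, split(rows$pc, rows$classified))
  anova_res <- if (length(grp) >= 2L) one_way_anova(grp) else
    list(F = NA_real_, p.value = NA_real_,
         note = "fewer than two categories with n >= 2")
  .cohort_result("propagation_census", rows, list(
    category_percent = shares,
    classification_accuracy = mean(rows$classified == rows$true_category),
    mean_pc_by_category = pc_by_cat,
    anova = anova_res))
}

#' Dynamic-clamp suite: artificial synapse on intact and lesioned circuits
#'
#' Episode-level experiment on the circuit model: per animal and condition
#' pair, the swim motor pattern is simulated with the dynamic clamp off and
#' on (same seed), and the paired burst counts are compared. Four arms:
#' intact + addition, intact + subtraction, lesioned + addition, lesioned +
#' subtraction. Addition uses the standard 1000 nS synapse; subtraction
#' scales the conductance with the animal's own hyperpolarization amplitude
#' (counteracting the synapse it actually has).
#'
#' @param spec An [experiment_spec()]; default arm sizes 18/9/20/19
#'   (intact-add / intact-subtract / lesioned-add / lesioned-subtract).
#' @param arm_n Named integer vector overriding the four arm sizes.
#' @param g_add Added conductance, nS.
#' @param g_sub_per_mv Subtracted conductance per mV of measured
#'   hyperpolarization, nS.
#' @param duration Episode length, s.
#' @return A `cohort_result`.
#' @export
run_dynclamp_suite <- function(spec = experiment_spec("dynclamp_suite"),
                               arm_n = c(intact_add = 18L,
                                         intact_subtract = 9L,
                                         lesioned_add = 20L,
                                         lesioned_subtract = 19L),
                               g_add = 1000, g_sub_per_mv = 200,
                               duration = 80) {
  cfg <- spec$config
  cfg$n_animals <- sum(arm_n)
  cohort <- generate_cohort(cfg, seed = spec$seed)
  arms <- rep(names(arm_n), arm_n)
  rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    a <- cohort[[i]]
    arm <- arms[i]
    lesioned <- grepl("^lesioned", arm)
    mode <- if (grepl("add$", arm)) "add" else "subtract"
    g <- if (mode == "add") g_add else g_sub_per_mv * a$h
    circ <- build_circuit(a, spec$circuit_config)
    if (lesioned) circ <- apply_lesion(circ)
    clamped <- attach_dynamic_clamp(circ, synapse_kinetics(g_syn = g),
                                    mode = mode)
    sd_ep <- spec$seed * 100L + i
    off <- simulate_episode(circ, stim_swim(), duration = duration,
                            seed = sd_ep)
    on <- simulate_episode(clamped, stim_swim(), duration = duration,
                           seed = sd_ep)
    prop_on <- classify_episode_propagation(on)
    lb <- prop_on$spikes$label
    matched <- lb != "unmatched"
    data.frame(id = a$id, arm = arm, h = a$h, g = g,
               bursts_off = count_vsi_bursts(off),
               bursts_on = count_vsi_bursts(on),
               frac_antidromic_on = if (any(matched))
                 mean(lb[matched] == "antidromic") else NA_real_)
  }))
  arm_summary <- lapply(split(rows, rows$arm), function(d) {
    tt <- tryCatch(paired_t_test(d$bursts_off, d$bursts_on),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_,
                                            note = conditionMessage(e)))
    list(n = nrow(d),
         mean_off = mean(d$bursts_off), mean_on = mean(d$bursts_on),
         mean_diff = mean(d$bursts_on - d$bursts_off),
         mean_pc = mean(percent_change(pmax(d$bursts_off, 1), d$bursts_on)),
         paired_t = tt)
  })
  .cohort_result("dynclamp_suite", rows, list(
    arms = arm_summary,
    intact_add_frac_antidromic =
      mean(rows$frac_antidromic_on[rows$arm == "intact_add"], na.rm = TRUE)))
}
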