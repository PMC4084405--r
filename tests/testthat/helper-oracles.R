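# Independent brute-force oracles used by the acceptance suite. Each is a
# deliberately naive re-derivation from first principles, kept free of any
# package internals.

# Gap-partition burst oracle: walk the sorted train, split wherever the gap
# to the previous spike is >= max_isi, keep groups with >= min_spikes.
oracle_bursts <- function(times, stim_window = NULL, max_isi = 1,
                          min_spikes = 2L) {
  if (!is.null(stim_window))
    times <- times[times < stim_window[1] | times > stim_window[2]]
  groups <- list()
  cur <- c()
  for (t in times) {
    if (length(cur) == 0L || t - cur[length(cur)] < max_isi) {
      cur <- c(cur, t)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- t
    }
  }
  if (length(cur)) groups[[length(groups) + 1L]] <- cur
  groups <- Filter(function(g) length(g) >= min_spikes, groups)
  data.frame(start = vapply(groups, min, 0),
             end = vapply(groups, max, 0),
             n_spikes = vapply(groups, length, 0L))
}

# Textbook Brown-Forsythe statistic: one-way ANOVA F on |x - median(group)|.
oracle_levene <- function(a, b) {
  za <- abs(a - median(a)); zb <- abs(b - median(b))
  z <- c(za, zb); n <- length(z); k <- 2L
  zm <- mean(z)
  ssb <- length(za) * (mean(za) - zm)^2 + length(zb) * (mean(zb) - zm)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f,
       p.value = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Textbook OLS: closed-form slope/intercept, R^2 from sums of squares,
# p from the t distribution of the slope.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  yhat <- b0 + b1 * x
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  se_b1 <- sqrt(sse / (n - 2) / sxx)
  tval <- b1 / se_b1
  list(slope = b1, intercept = b0, r.squared = 1 - sse / sst,
       p.value = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Textbook paired t: t = mean(d) / (sd(d)/sqrt(n)).
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p.value = 2 * pt(abs(tval), n - 1, lower.tail = FALSE),
       df = n - 1)
}

# Textbook one-way ANOVA from between/within sums of squares.
oracle_anova <- function(groups) {
  y <- unlist(groups); n <- length(y); k <- length(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p.value = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Burst count of one simulated episode.
episode_bursts <- function(h, seed, lesion = FALSE, clamp = "off",
                           g = 1000, d = 0.8, config = cpg_defaults()) {
  circ <- build_circuit(virtual_animal(h = h, d = d), config)
  if (lesion) circ <- apply_lesion(circ)
  if (clamp != "off")
    circ <- attach_dynamic_clamp(circ, synapse_kinetics(g_syn = g),
                                 mode = clamp)
  rec <- simulate_episode(circ, stim_swim(), duration = 80, seed = seed)
  count_vsi_bursts(rec)
}
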