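# Independent oracles and fixture builders used across the suite.

# Brute-force product-limit estimator: direct loop over distinct event
# times, independent of the survival package.
km_oracle <- function(time, event) {
  ord <- order(time, -event)  # events precede censorings at tied times
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Hand-computed log-rank statistic from 2xk contingency tables.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  grp <- rep(c(1, 2), c(length(time_a), length(time_b)))
  ev_times <- sort(unique(time[event == 1]))
  o_a <- e_a <- v_a <- 0
  for (t in ev_times) {
    n1 <- sum(time >= t & grp == 1); n2 <- sum(time >= t & grp == 2)
    d1 <- sum(time == t & event == 1 & grp == 1)
    d2 <- sum(time == t & event == 1 & grp == 2)
    n <- n1 + n2; d <- d1 + d2
    o_a <- o_a + d1
    e_a <- e_a + d * n1 / n
    if (n > 1) v_a <- v_a + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v_a
}

# Quick builder for an exchange record with a fixed percent value.
make_record <- function(start, end, percent, id = sprintf("p%d_%d", start, end)) {
  structure(list(timepoints = 60,
                 percent = percent, sd = 1,
                 median_residue = stats::median(c(start, end)),
                 start_res = start, end_res = end, peptide_id = id),
            class = "exchange_record")
}

# Synthetic Gaussian mixture envelope on an m/z grid.
mixture_envelope <- function(means, sds, areas, n = 400, pad = 4) {
  lo <- min(means - pad * sds); hi <- max(means + pad * sds)
  mz <- seq(lo, hi, length.out = n)
  intensity <- Reduce(`+`, lapply(seq_along(means), function(i) {
    areas[i] / (sds[i] * sqrt(2 * pi)) *
      exp(-(mz - means[i])^2 / (2 * sds[i]^2))
  }))
  list(mz = mz, intensity = intensity)
}
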