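# Shared fixtures: canonical generating parameters and an independent
# grid-profiling oracle for the peak temperature.

std_params <- function(t_star = 50) {
  list(F0 = 100, F_star = 1000, t_star = t_star, s_L = 8, s_R = 12, w = 5)
}

# Independent brute-force oracle: profile t* on a fine grid, refitting the
# other four parameters (F0, amplitude, widths) at every grid point with
# its own objective code. Restricted to a window around the empirical peak;
# for unimodal profiles the SSE profile is worse outside it.
profile_tstar_oracle <- function(profile, step = 0.1, halfwidth = 15, w = 5) {
  tt <- rep(profile$temperatures, each = nrow(profile$fluorescence))
  ff <- as.vector(profile$fluorescence)
  means <- colMeans(profile$fluorescence)
  center <- profile$temperatures[which.max(means)]
  grid <- seq(max(min(tt), center - halfwidth),
              min(max(tt), center + halfwidth), by = step)
  obj <- function(p, ts) {
    F0 <- p[1]; Fs <- F0 + exp(p[2]); sL <- exp(p[3]); sR <- exp(p[4])
    s <- sL + (sR - sL) / (1 + exp(-(tt - ts) / w))
    r <- ff - (F0 + (Fs - F0) * exp(-((tt - ts) / s)^2))
    sum(r * r)
  }
  fresh <- c(min(means), log(max(max(means) - min(means), 1e-6)),
             log(10), log(10))
  th <- fresh
  best_sse <- Inf
  best_ts <- NA_real_
  for (ts in grid) {
    # both a data-driven start and the neighbouring point's solution, so a
    # poor fit at one grid point cannot poison the rest of the profile
    o1 <- stats::optim(fresh, obj, ts = ts, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    o2 <- stats::optim(th, obj, ts = ts, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    opt <- if (o1$value < o2$value) o1 else o2
    th <- opt$par
    if (opt$value < best_sse) { best_sse <- opt$value; best_ts <- ts }
  }
  best_ts
}
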