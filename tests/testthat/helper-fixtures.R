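# Shared fixture builders for the test suite.

default_cfg <- function(bm = 0.46) respiro_config(body_mass = bm)

# linear oxygen decline with a given true MO2, 2 s sampling, 15 min
linear_o2_trace <- function(mo2_true, cfg, duration_s = 900, sampling = 2,
                            noise_sd = 0, start = 100) {
  t <- seq(0, duration_s, by = sampling)
  slope <- mo2_true * cfg$body_mass * 100 /
    (cfg$do_max * cfg$chamber_volume * 3600)
  do <- start - slope * t
  if (noise_sd > 0) do <- do + rnorm(length(t), 0, noise_sd)
  data.frame(time_s = t, do_percent = do)
}

# minimal sentinel data frame with explicit hour-of-day and constant metrics
flat_sentinel <- function(n_fish = 2, hr = 70, days = 2, epoch_min = 60) {
  epochs <- seq(0, days * 24 * 60 - epoch_min, by = epoch_min) * 60
  ts <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC") + epochs
  treatment <- rep(c("steady", "unsteady"), each = length(ts) / 2)
  do.call(rbind, lapply(seq_len(n_fish), function(f) {
    data.frame(fish_id = paste0("f", f), timestamp = ts,
               treatment = treatment, hr_bpm = hr)
  }))
}
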