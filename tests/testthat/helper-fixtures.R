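# Shared fixtures. All tests log to a scratch file so preprocessing messages
# do not clutter test output.
set_log_file(file.path(tempdir(), "biofilmmech-tests.log"))

# the log-spaced ramp grid used by the torque generator
ramp_grid <- function(n = 72, range = c(0.1, 300)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# noiseless bilinear indentation fixture built directly (not via the
# generator), for tests that need an oracle independent of generator code
bilinear_curve <- function(k_film = 0.5, k_sub = 100, delta_c = 50e-6,
                           h = 200e-6, d_max = 320e-6, n = 321) {
  d <- seq(0, d_max, length.out = n)
  f <- ifelse(d < delta_c, 0,
              ifelse(d < delta_c + h, k_film * (d - delta_c),
                     k_film * h + k_sub * (d - delta_c - h)))
  force_displacement_curve(d, f)
}
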