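# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) assign(name, builder(), fixture_env)
  get(name, fixture_env)
}

# reduced-size conditions for unit tests: 89-orientation powder
unit_cond <- function(s_ch = 0.1, ...) {
  simulation_conditions(s_ch = s_ch, ...,
                        powder = powder_orientations("zcw", 89))
}

unit_rf <- function() gaussian_rf_distribution(sigma = 0.1, n_nodes = 11)

# 32-point databases on s in [0, 0.15]; t1 subsets serve shorter data
unit_ideal_db <- function() fx("unit_ideal_db", function()
  build_database(seq(0, 0.15, by = 0.005), unit_cond(0),
                 delta_rf_distribution(), 32))

unit_inhom_db <- function() fx("unit_inhom_db", function()
  build_database(seq(0, 0.15, by = 0.005), unit_cond(0), unit_rf(), 32))

# full study conditions: default powder (233), default Gaussian RF profile
study_cond <- function(s_ch = 0.1) simulation_conditions(s_ch = s_ch)

study_ideal_db <- function() fx("study_ideal_db", function()
  build_database(seq(0, 0.35, by = 0.005), study_cond(0),
                 delta_rf_distribution(), 32))

study_inhom_db <- function() fx("study_inhom_db", function()
  build_database(seq(0, 0.35, by = 0.005), study_cond(0),
                 gaussian_rf_distribution(), 32))

# restrict a modulation-like numeric vector to the first k points as data
as_data <- function(db, amplitude, k = length(db$t1)) {
  dipolar_modulation(db$t1[seq_len(k)], amplitude[seq_len(k)] /
                       amplitude[1])
}

# first zero-crossing time of a modulation (linear interpolation)
first_zero <- function(mod) {
  a <- mod$amplitude
  i <- which(a[-1] * a[-length(a)] < 0)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- mod$t1[i]; t1 <- mod$t1[i + 1]
  t0 + (0 - a[i]) * (t1 - t0) / (a[i + 1] - a[i])
}

# fit the fixed-axis rotation closed form a + (1-a) cos(2 pi f t) and
# return the rms residual together with the fitted parameters
fit_rotation_power <- function(t, s) {
  nfft <- 8192L
  x <- c(s - mean(s), rep(0, nfft - length(s)))
  spec <- Mod(fft(x))[2:(nfft %/% 2)]
  f0 <- ((1:(nfft %/% 2 - 1)) / (nfft * (t[2] - t[1])))[which.max(spec)]
  obj <- function(p) sum((p[1] + (1 - p[1]) * cos(2 * pi * p[2] * t) - s)^2)
  o <- optim(c(mean(s), f0), obj, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 1000))
  list(pedestal = o$par[1], freq = o$par[2],
       rms = sqrt(o$value / length(s)))
}
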