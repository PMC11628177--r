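# Waveform generation, encoding spectra and duration planning.

test_that("generated waveforms are self-refocusing, amplitude-limited and hit the requested anisotropy", {
  for (ord in 0:2) for (bd in c(-0.5, 0, 0.5, 1)) {
    wf <- generate_waveform(ord, 0.010, bd, g_max = 0.5)
    expect_lte(max(abs(wf$samples)), 0.5 + 1e-12)
    sp <- compute_spectrum(wf)
    q <- sp$q_time
    expect_lt(sqrt(sum(q[nrow(q), ]^2)) / max(sqrt(rowSums(q^2))), 1e-9)
    expect_lt(abs(sp$b_delta - bd), 0.02)
    # Parseval: frequency-integrated trace equals the time-domain integral
    expect_lt(abs(sp$b - sp$b_time) / sp$b, 1e-6)
  }
})

test_that("spectral weight shifts to higher frequency with modulation order", {
  wc <- vapply(0:2, function(ord)
    compute_spectrum(generate_waveform(ord, 0.010, 0))$omega_cent, numeric(1))
  expect_true(all(diff(wc) > 0))
  # linear encoding too
  wc1 <- vapply(0:2, function(ord)
    compute_spectrum(generate_waveform(ord, 0.010, 1))$omega_cent, numeric(1))
  expect_true(all(diff(wc1) > 0))
})

test_that("centroid frequency of a windowed pure tone matches the analytic oracle", {
  tau <- 0.010
  n <- 800L
  gamma <- 26.75e7
  t <- seq(0, tau, length.out = n)
  # independent oracle: analytic Fourier transform of q(t) = sin(2 pi f t)
  # on [0, tau], centroid by quadrature on a fine grid
  oracle_cent <- function(f) {
    a <- 2 * pi * f
    om <- seq(0, 60 * a, length.out = 400000)
    Q <- (a - a * cos(a * tau) * exp(1i * om * tau) +
            1i * om * sin(a * tau) * exp(1i * om * tau)) / (a^2 - om^2)
    Q[!is.finite(Q)] <- 0
    p <- Mod(Q)^2
    sum(om * p) / sum(p) / (2 * pi)
  }
  for (f in c(100, 1000)) {
    g <- cbind(0, 0, cos(2 * pi * f * t) / gamma)  # q = sin/(2 pi f), refocused
    wf <- structure(list(samples = g, dt = t[2] - t[1], duration = tau,
                         g_max = max(abs(g)), order = 0L,
                         b_delta_nominal = 1, gamma = gamma),
                    class = "mmd_waveform")
    sp <- compute_spectrum(wf, zero_fill_factor = 8)
    expect_lt(abs(sp$omega_cent / (2 * pi) - oracle_cent(f)),
              0.03 * f)
  }
  # with more cycles in the window the relative centroid offset shrinks
  offset <- function(f) {
    g <- cbind(0, 0, cos(2 * pi * f * t) / gamma)
    wf <- structure(list(samples = g, dt = t[2] - t[1], duration = tau,
                         g_max = max(abs(g)), order = 0L,
                         b_delta_nominal = 1, gamma = gamma),
                    class = "mmd_waveform")
    sp <- compute_spectrum(wf, zero_fill_factor = 8)
    abs(sp$omega_cent / (2 * pi) - f) / f
  }
  expect_lt(offset(1000), 0.2 * offset(100))
})

test_that("b grows with the cube of duration and the centroid scales inversely", {
  for (ord in c(0L, 1L)) {
    s1 <- compute_spectrum(generate_waveform(ord, 0.008, 0.5))
    s2 <- compute_spectrum(generate_waveform(ord, 0.016, 0.5))
    expect_lt(abs(s2$b / s1$b - 8) / 8, 0.01)
    expect_lt(abs(s1$omega_cent / s2$omega_cent - 2) / 2, 0.01)
  }
})

test_that("duration planner reproduces the published protocol durations", {
  tab <- efficiency_table()
  expect_true(all(diff(tab$C) < 0))
  expect_equal(plan_duration(2.602e9, 0, tab), 0.018)
  expect_equal(plan_duration(2.069e9, 1, tab), 0.021)
  expect_equal(plan_duration(0.228e9, 0, tab), 0.008)
  expect_error(plan_duration(1e9, 5, tab), "missing")
})

test_that("waveform generation rejects invalid requests", {
  expect_error(generate_waveform(3, 0.01, 0), "order")
  expect_error(generate_waveform(0, 0.01, 1.2), "b_delta")
  expect_error(generate_waveform(0, -0.01, 0), "duration")
  expect_error(generate_waveform(0, 0.01, 0, n_samples = 4L), "coarsely")
})

test_that("non-refocused gradient traces are rejected with a diagnostic", {
  t <- seq(0, 0.01, length.out = 100)
  g <- cbind(0, 0, rep(1e-3, 100))          # never returns q to zero
  wf <- structure(list(samples = g, dt = t[2] - t[1], duration = 0.01,
                       g_max = 1e-3, order = 0L, b_delta_nominal = 1,
                       gamma = 26.75e7), class = "mmd_waveform")
  expect_error(compute_spectrum(wf), "self-refocusing")
})

test_that("rotation preserves b and b_delta and steers the principal axis", {
  wf <- generate_waveform(0, 0.010, 1)
  sp <- compute_spectrum(wf)
  expect_identical(rotate_waveform(wf, c(0, 0, 1))$samples, wf$samples)
  for (dir in list(c(1, 0, 0), c(1, 1, 0) / sqrt(2), c(1, 2, 3) / sqrt(14))) {
    spr <- compute_spectrum(rotate_waveform(wf, dir))
    expect_lt(abs(spr$b - sp$b) / sp$b, 1e-6)
    expect_lt(abs(spr$b_delta - sp$b_delta), 1e-6)
    ev <- eigen(spr$b_tensor, symmetric = TRUE)
    v1 <- ev$vectors[, which.max(ev$values)]
    expect_lt(acos(min(abs(sum(v1 * dir)), 1)), 1e-3)
  }
})

test_that("spectrum eigenvalue convention matches the anisotropy definition", {
  sp0 <- compute_spectrum(generate_waveform(0, 0.01, 1))
  expect_equal(summarize_spectrum(sp0)$b_delta, 1, tolerance = 1e-6)
  spp <- compute_spectrum(generate_waveform(0, 0.01, -0.5))
  expect_equal(summarize_spectrum(spp)$b_delta, -0.5, tolerance = 1e-6)
  sps <- compute_spectrum(generate_waveform(0, 0.01, 0))
  expect_lt(abs(summarize_spectrum(sps)$b_delta), 0.01)
})

test_that("waveform text round trip preserves the trace and metadata", {
  wf <- generate_waveform(1, 0.012, 0.5)
  path <- tempfile(fileext = ".txt")
  write_waveform(wf, path)
  wf2 <- read_waveform(path)
  expect_equal(wf2$samples, wf$samples, tolerance = 1e-10)
  expect_equal(wf2$order, wf$order)
  expect_equal(wf2$dt, wf$dt, tolerance = 1e-12)
  sp <- compute_spectrum(wf)
  sp2 <- compute_spectrum(wf2)
  expect_lt(abs(sp$b - sp2$b) / sp$b, 1e-9)
})
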