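# exact Boltzmann sampler for a two-level system (the WHAM oracle)
two_level_samples <- function(g0, g1, e1, temps, n_per_T, seed) {
  set.seed(seed)
  do.call(rbind, lapply(temps, function(Tv) {
    p1 <- g1 * exp(-e1 / Tv) / (g0 + g1 * exp(-e1 / Tv))
    E <- ifelse(runif(n_per_T) < p1, e1, 0)
    data.frame(mcs = seq_along(E), temperature = Tv, E = E, Q = 0,
               knotted = NA)
  }))
}

schottky_cv <- function(Tv, ratio, e1) {
  p <- ratio * exp(-e1 / Tv) / (1 + ratio * exp(-e1 / Tv))
  e1^2 * p * (1 - p) / Tv^2
}

test_that("single-temperature WHAM reproduces the direct sample mean", {
  set.seed(41)
  E <- round(rnorm(4000, -10, 2), 1)
  s <- data.frame(mcs = seq_along(E), temperature = 0.8, E = E, Q = 0,
                  knotted = NA)
  dos <- wham_fit(s, 0.8, nc = 1)
  u <- thermo_curves(dos, 0.8)$U
  expect_equal(u, mean(E), tolerance = dos$e_binwidth)
})

test_that("WHAM recovers the degeneracy ratio of a two-level system", {
  g0 <- 4; g1 <- 12; e1 <- 1.5
  temps <- c(0.4, 0.7, 1.1, 1.8)
  s <- two_level_samples(g0, g1, e1, temps, 4000, seed = 2)
  dos <- wham_fit(s, temps, nc = 1)
  ratio <- exp(dos$log_g[dos$E > 0.5] - dos$log_g[dos$E < 0.5])
  # bootstrap SE of the recovered ratio over resampled data sets
  set.seed(3)
  boots <- vapply(1:50, function(b) {
    sb <- s[sample.int(nrow(s), replace = TRUE), ]
    sb <- do.call(rbind, lapply(split(sb, sb$temperature), function(d) {
      d$mcs <- seq_len(nrow(d)); d
    }))
    db <- suppressWarnings(wham_fit(sb, temps, nc = 1))
    if (length(db$E) < 2) return(NA_real_)
    exp(db$log_g[db$E > 0.5] - db$log_g[db$E < 0.5])
  }, numeric(1))
  se <- sd(boots, na.rm = TRUE)
  expect_lt(abs(ratio - g1 / g0), 3 * se + 1e-9)
})

test_that("thermo curves match the closed-form Schottky heat capacity", {
  g0 <- 4; g1 <- 12; e1 <- 1.5
  temps <- c(0.4, 0.7, 1.1, 1.8)
  dos <- wham_fit(two_level_samples(g0, g1, e1, temps, 4000, 2), temps,
                  nc = 1)
  ratio <- exp(dos$log_g[dos$E > 0.5] - dos$log_g[dos$E < 0.5])
  tg <- seq(0.25, 3, length.out = 400)
  tc <- thermo_curves(dos, tg)
  expect_lt(max(abs(tc$CV - schottky_cv(tg, ratio, e1))), 1e-6)
  # limits: U -> ground state as T -> 0, density-weighted mean as T -> inf
  expect_equal(thermo_curves(dos, 0.01)$U, 0, tolerance = 1e-8)
  expect_equal(thermo_curves(dos, 1e6)$U, e1 * ratio / (1 + ratio),
               tolerance = 1e-3)
})

test_that("melting temperature and FWHM come from the peak geometry", {
  # synthetic Gaussian CV: FWHM = 2 sqrt(2 ln 2) sigma to grid resolution
  tg <- seq(0.2, 2, length.out = 1000)
  sigma <- 0.13; tc <- 0.9
  cv <- exp(-(tg - tc)^2 / (2 * sigma^2))
  mw <- melting_and_width(tg, cv)
  expect_equal(mw$Tm, tc, tolerance = diff(tg)[1])
  expect_equal(mw$FWHM, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 2 * diff(tg)[1])
  expect_equal(mw$ratio, mw$FWHM / mw$Tm)
  # Schottky curve: maximiser matches a dense analytic scan
  an <- schottky_cv(tg, 3, 1.5)
  mw2 <- melting_and_width(tg, an)
  expect_equal(mw2$Tm, tg[which.max(an)])
  # peak on the boundary is an error
  expect_error(melting_and_width(seq(1.2, 2, length.out = 50),
                                 schottky_cv(seq(1.2, 2, length.out = 50),
                                             3, 1.5)), "boundary")
})

test_that("WHAM curves agree with direct per-temperature averages on a run", {
  p <- go_params()
  topo <- make_toy_topology("compact_globule", 15)
  temps <- temperature_ladder(0.3, 2, 6)
  run <- quick_run(topo, p, temps, total = 4e5, seed = 17,
                   sample_period = 2e3)
  dos <- wham_fit(run)
  wc <- thermo_curves(dos, temps)
  direct <- thermo_direct(run$samples)
  expect_lt(max(abs(wc$U - direct$U) / pmax(direct$U_se, 1e-3)), 3)
  # U(T) is non-decreasing and pk-style weights stay normalized
  tg <- seq(min(temps), max(temps), length.out = 200)
  curves <- thermo_curves(dos, tg)
  expect_true(all(diff(curves$U) > -1e-9))
  # estimates are stable when the energy bin width is halved
  dos2 <- wham_fit(run, e_binwidth = dos$e_binwidth / 2)
  wc2 <- thermo_curves(dos2, temps)
  expect_lt(max(abs(wc2$U - wc$U) / pmax(direct$U_se, 1e-3)), 3)
})

test_that("non-overlapping ladders are rejected and sparse overlap warns", {
  s <- rbind(
    data.frame(mcs = 1:500, temperature = 0.2,
               E = round(rnorm(500, -30, 0.5), 2), Q = 0, knotted = NA),
    data.frame(mcs = 1:500, temperature = 5,
               E = round(rnorm(500, -1, 0.5), 2), Q = 0, knotted = NA))
  expect_error(wham_fit(s, c(0.2, 5), nc = 1), "overlap")
})

test_that("knotting profiles are probabilities with NA for empty bins", {
  p <- go_params(w = 0.5)
  topo <- make_knotted_topology(35)
  # the sharp folding transition needs the ladder densified around Tm (and
  # its bottom not too deep in the frozen regime) for the energy histograms
  # of adjacent replicas to overlap
  run <- quick_run(topo, p, temperature_ladder(0.15, 0.8, 10, tm_hint = 0.27),
                   total = 3e5, seed = 19, sample_period = 1e3,
                   record_knots = TRUE)
  dos <- wham_fit(run)
  tg <- seq(0.1, 0.8, length.out = 100)
  prof <- knotting_profiles(dos, tg)
  expect_true(all(prof$pk_T$pk >= -1e-12 & prof$pk_T$pk <= 1 + 1e-12))
  expect_true(all(is.na(prof$pk_Q$pk) |
                  (prof$pk_Q$pk >= -1e-12 & prof$pk_Q$pk <= 1 + 1e-12)))
  # all-knotted flags force pk identically 1
  s1 <- run$samples; s1$knotted <- 1
  dos1 <- wham_fit(s1, temperatures = run$config$temperatures, nc = 21)
  prof1 <- knotting_profiles(dos1, tg)
  expect_true(all(abs(prof1$pk_T$pk - 1) < 1e-9))
  expect_true(all(abs(prof1$pk_Q$pk[!is.na(prof1$pk_Q$pk)] - 1) < 1e-9))
})

test_that("equilibration check passes identical runs and fails a truncated one", {
  p <- go_params()
  topo <- make_toy_topology("compact_globule", 15)
  temps <- temperature_ladder(0.3, 2, 5)
  base <- quick_run(topo, p, temps, total = 2e5, seed = 23,
                    sample_period = 2e3)
  same <- check_equilibration(list(base, base, base, base))
  expect_true(same$pass)
  expect_equal(same$max_dev_U, 0)
  expect_equal(same$max_dev_CV, 0)
  # a denatured-start run given almost no relaxation on a knotted system
  # disagrees with a native-start run at low temperature
  pk <- go_params(w = 0.5)
  kt <- make_knotted_topology(35)
  tempk <- temperature_ladder(0.1, 0.8, 5)
  den <- generate_denatured(kt, pk, t_hot = 4, budget_mcs = 2e4, seed = 29)
  nat <- quick_run(kt, pk, tempk, total = 2e5, seed = 24,
                   sample_period = 2e3, record_knots = FALSE)
  trunc <- quick_run(kt, pk, tempk, total = 2e5, seed = 25, ltyp = TRUE,
                     start = "denatured", den = den, sample_period = 2e3,
                     record_knots = FALSE,
                     relax_override = 0.01 * relaxation_budget(2e5))
  bad <- check_equilibration(list(nat, trunc))
  expect_false(bad$pass)
  # mismatched ladders are refused
  other <- quick_run(topo, p, temps + 0.01, total = 5e4, seed = 26)
  expect_error(check_equilibration(list(base, other)), "mismatch")
})
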