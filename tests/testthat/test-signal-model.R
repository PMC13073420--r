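test_that("steady-state factor matches its closed form and limits", {
  # frozen from a direct scalar evaluation of sin(a)(1-E1)/(1-cos(a)E1)
  expect_equal(steady_state_factor(828, tr = 80, flip_angle = 50),
               0.1694257185, tolerance = 1e-9)
  # TR >> T1 saturates: E1 -> 0, factor -> sin(alpha)
  expect_equal(steady_state_factor(828, tr = 1e9, flip_angle = 90), 1.0)
  expect_equal(steady_state_factor(1e-6, tr = 80, flip_angle = 50),
               sin(50 * pi / 180))
  # strictly decreasing in t1
  t1s <- seq(100, 2000, by = 100)
  expect_true(all(diff(steady_state_factor(t1s, 80, 50)) < 0))
  expect_error(steady_state_factor(-1, 80, 50), "positive")
  expect_error(steady_state_factor(828, 0, 50), "positive")
  expect_error(steady_state_factor(828, 80, 95), "flip_angle")
})

test_that("T2* decay factor behaves as an exponential", {
  expect_equal(t2star_decay(0, 20), 1.0)
  expect_equal(t2star_decay(2.46, 20), 0.8842636626, tolerance = 1e-9)
  expect_equal(t2star_decay(20, 20), exp(-1))
  expect_error(t2star_decay(2.46, 0), "positive")
  expect_error(t2star_decay(-1, 20), "non-negative")
})

test_that("forward dual-echo model reproduces the scalar oracle", {
  p <- default_params
  # pure water: no fat-water cancellation, ratio set by T2* alone
  w_only <- forward_dual_echo(tissue_composition(80, 0, 25), p)
  a <- steady_state_factor(p$t1_water, p$tr, p$flip_angle)
  expect_equal(w_only$si_ip, 80 * a * exp(-p$te_ip / 25))
  expect_equal(w_only$si_op / w_only$si_ip,
               exp(-p$te_op / 25) / exp(-p$te_ip / 25))
  # equal weighted magnetizations cancel in opposed phase
  pe <- acquisition_params(t1_water = 500, t1_fat = 500)
  cancel <- forward_dual_echo(tissue_composition(50, 50, 25), pe)
  expect_equal(cancel$si_op, 0)
  # frozen oracle values for a 10% fat mixture
  sig <- forward_dual_echo(tissue_composition(90, 10, 25), p)
  expect_equal(sig$si_ip, 16.5598441026, tolerance = 1e-9)
  expect_equal(sig$si_op, 11.6375439617, tolerance = 1e-9)
  orc <- forward_oracle(w = 57, f = 13, t2_star = 18)
  sig2 <- forward_dual_echo(tissue_composition(57, 13, 18), p)
  expect_equal(c(sig2$si_ip, sig2$si_op), unname(orc), tolerance = 1e-12)
})

test_that("T2* estimation recovers a noise-free exponential exactly", {
  tes <- c(2.46, 3.69, 4.92, 6.15, 7.38)
  s <- 100 * exp(-tes / 20)
  expect_equal(estimate_t2star(tes, s, echoes = "in_phase"), 20,
               tolerance = 1e-12)
  expect_equal(estimate_t2star(tes, s, echoes = "all"), 20,
               tolerance = 1e-12)
  expect_error(estimate_t2star(tes, rep(5, 5)), "no decay")
  expect_error(estimate_t2star(tes, c(-1, 1, 1, 1, 1), echoes = "all"),
               "positive")
  expect_error(estimate_t2star(tes[1:2], s[1:2], echoes = "in_phase"),
               "at least 2")
})

test_that("T2* estimation is nearly unbiased under 1% multiplicative noise", {
  tes <- c(2.46, 3.69, 4.92, 6.15, 7.38)
  clean <- 100 * exp(-tes / 20)
  set.seed(42)
  est <- replicate(1000, {
    estimate_t2star(tes, clean * (1 + rnorm(5, 0, 0.01)))
  })
  expect_lt(abs(mean(est) - 20) / 20, 0.02)
})

test_that("corrected fat fraction inverts the forward model exactly", {
  p <- default_params
  for (ff in c(0.02, 0.05, 0.10, 0.20)) {
    sig <- forward_dual_echo(tissue_composition(100 * (1 - ff), 100 * ff, 30),
                             p)
    est <- fat_fraction_corrected(sig$si_ip, sig$si_op, 30, p)
    expect_equal(est$ff, ff, tolerance = 1e-9)
    expect_false(est$out_of_range)
  }
})

test_that("round-trip identity holds across FF, T2* and flip-angle sweeps", {
  ffs <- seq(0, 0.45, by = 0.05)
  for (t2 in c(5, 12, 25, 40, 60)) {
    for (flip in c(5, 20, 50, 75, 90)) {
      p <- acquisition_params(flip_angle = flip)
      # phase-sensitive signals invert exactly over the whole sweep
      sig <- forward_dual_echo(
        tissue_composition(100 * (1 - ffs), 100 * ffs, t2), p,
        magnitude = FALSE)
      est <- fat_fraction_corrected(sig$si_ip, sig$si_op, t2, p)
      expect_equal(est$ff, ffs, tolerance = 1e-9)
      # magnitude signals invert exactly in their water-dominant regime,
      # i.e. below the T1-weighted sign-loss bound a / (a + b)
      a <- steady_state_factor(p$t1_water, p$tr, flip)
      b <- steady_state_factor(p$t1_fat, p$tr, flip)
      ok <- ffs < a / (a + b) - 0.01
      mag <- forward_dual_echo(
        tissue_composition(100 * (1 - ffs[ok]), 100 * ffs[ok], t2), p)
      est_m <- fat_fraction_corrected(mag$si_ip, mag$si_op, t2, p)
      expect_equal(est_m$ff, ffs[ok], tolerance = 1e-9)
    }
  }
})

test_that("magnitude reconstruction mirrors fat-dominant mixtures while
           phase-sensitive reconstruction does not", {
  p <- default_params  # a/(a+b) ~ 0.359 at the default flip angle
  ff <- 0.45
  mag <- forward_dual_echo(tissue_composition(55, 45, 25), p)
  est <- fat_fraction_corrected(mag$si_ip, mag$si_op, 25, p)
  expect_gt(abs(est$ff - ff), 0.01)
  signed <- forward_dual_echo(tissue_composition(55, 45, 25), p,
                              magnitude = FALSE)
  expect_lt(signed$si_op, 0)
  expect_equal(fat_fraction_corrected(signed$si_ip, signed$si_op, 25, p)$ff,
               ff, tolerance = 1e-9)
})

test_that("estimated fat fraction increases strictly with fat content", {
  p <- default_params
  fats <- seq(1, 45, by = 2)
  sig <- forward_dual_echo(tissue_composition(rep(100, length(fats)),
                                              fats, 25), p)
  est <- fat_fraction_corrected(sig$si_ip, sig$si_op, 25, p)
  expect_true(all(diff(est$ff) > 0))
})

test_that("with equal T1s and no T2* decay the formula reduces to the naive
           dual-echo estimate", {
  pe <- acquisition_params(t1_water = 700, t1_fat = 700)
  si_ip <- 100; si_op <- 70
  est <- fat_fraction_corrected(si_ip, si_op, t2_star = 1e12, params = pe)
  expect_equal(est$ff, (si_ip - si_op) / (2 * si_ip), tolerance = 1e-9)
})

test_that("perfect opposed-phase cancellation gives FF = a / (a + b)", {
  p <- default_params
  a <- steady_state_factor(p$t1_water, p$tr, p$flip_angle)
  b <- steady_state_factor(p$t1_fat, p$tr, p$flip_angle)
  est <- fat_fraction_corrected(si_ip = 10, si_op = 0, t2_star = 25,
                                params = p)
  expect_equal(est$ff, a / (a + b), tolerance = 1e-12)
})

test_that("the decay-factor pairing is the unique one closing the round trip", {
  # swapping e_x and e_y (te_ip <-> te_op in the correction only) must break
  # the inversion
  p <- default_params
  ff <- 0.10
  sig <- forward_dual_echo(tissue_composition(90, 10, 20), p)
  e_x_swap <- exp(-p$te_op / 20)  # wrong: opposed-phase TE on si_ip's factor
  e_y_swap <- exp(-p$te_ip / 20)
  a <- steady_state_factor(p$t1_water, p$tr, p$flip_angle)
  b <- steady_state_factor(p$t1_fat, p$tr, p$flip_angle)
  ff_swapped <- a * (sig$si_ip * e_y_swap - sig$si_op * e_x_swap) /
    (sig$si_ip * e_y_swap * (a + b) + sig$si_op * e_x_swap * (b - a))
  expect_gt(abs(ff_swapped - ff), 1e-3)
  expect_equal(fat_fraction_corrected(sig$si_ip, sig$si_op, 20, p)$ff, ff,
               tolerance = 1e-9)
})

test_that("degenerate and invalid signal inputs are rejected or flagged", {
  p <- default_params
  expect_error(fat_fraction_corrected(0, 1, 25, p), "si_ip")
  # noisy opposed-phase signal exceeding in-phase: negative raw FF, flagged
  est <- fat_fraction_corrected(si_ip = 10, si_op = 12, t2_star = 1e12,
                                params = acquisition_params(t1_water = 700,
                                                            t1_fat = 700))
  expect_true(est$out_of_range)
  expect_equal(est$ff, 0)
  expect_lt(est$ff_raw, 0)
})
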