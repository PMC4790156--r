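test_that("double-well sampler reproduces the Boltzmann well populations", {
  # symmetric wells: half the samples in each well, within 3 binomial SE
  sym <- double_well_spec(delta_U = 0, well_width = 0.4, barrier_height = 8)
  s <- sample_double_well(sym, 1e5, seed = 21)
  p_A <- mean(s$label == "A")
  expect_lt(abs(p_A - 0.5), 3 * sqrt(0.25 / 1e5))

  # delta_U = 2 kT, deep wells: N_B/N_A -> exp(-2), quadrature oracle
  spec <- double_well_spec(delta_U = 2, well_width = 0.35, barrier_height = 12)
  mass_A <- dw_quadrature_mass(spec, spec$well_A[1], spec$well_A[2])
  mass_B <- dw_quadrature_mass(spec, spec$well_B[1], spec$well_B[2])
  expect_equal(mass_B / mass_A, exp(-2), tolerance = 1e-8)
  s2 <- sample_double_well(spec, 2e5, seed = 22)
  ratio <- sum(s2$label == "B") / sum(s2$label == "A")
  se <- exp(-2) * sqrt(1 / (2e5 * mass_B) + 1 / (2e5 * mass_A))
  expect_lt(abs(ratio - exp(-2)), 3 * se)

  expect_error(sample_double_well(spec, 0), "positive")
  expect_error(double_well_spec(delta_U = 2, barrier_height = 1), "barrier")
})

test_that("double-well energies are stored exactly and samples labeled", {
  spec <- double_well_spec()
  s <- sample_double_well(spec, 5000, seed = 23)
  expect_identical(s$energies, double_well_energy(spec, s$x))
  expect_true(all(s$label[s$x < spec$well_A[2]] == "A"))
  expect_true(all(s$label[s$x >= spec$well_B[1]] == "B"))
  # determinism given (spec, n, seed)
  expect_identical(s$x, sample_double_well(spec, 5000, seed = 23)$x)
})

test_that("uniform discretization of the double well fails ISWD at -delta_U", {
  spec <- double_well_spec(delta_U = 2, well_width = 0.35, barrier_height = 12)
  s <- sample_double_well(spec, 2e5, seed = 24)
  for (cells in c(20, 100, 400)) {
    dw <- double_well_iswd(s, n_cells = cells)
    expect_equal(dw$ddF, -2, tolerance = 0.05)
    expect_equal(dw$dF_conf, 0, tolerance = 1e-12)  # equal-width wells
  }
})

test_that("factorized sampler reproduces exact marginals", {
  # flat energies: uniform bins
  flat <- torsion_system(matrix(0, 1, 12))
  s <- sample_torsion_system(flat, 3e4, seed = 31)
  occ <- tabulate(s$bins[, 1], 12) / 3e4
  expect_true(all(abs(occ - 1 / 12) < 3 * sqrt((1 / 12) / 3e4)))

  # two independent torsions: joint frequencies ~ product of exact marginals
  sys <- small_rugged_system(seed = 32)
  sys2 <- torsion_system(sys$site_energies[1:2, , drop = FALSE])
  s2 <- sample_torsion_system(sys2, 5e4, seed = 33)
  marg <- apply(sys2$site_energies, 1, function(e) {
    w <- exp(-(e - min(e))); w / sum(w)
  })
  joint_hat <- table(factor(s2$bins[, 1], levels = 1:12),
                     factor(s2$bins[, 2], levels = 1:12)) / 5e4
  joint <- outer(marg[, 1], marg[, 2])
  se <- sqrt(joint * (1 - joint) / 5e4)
  expect_true(all(abs(joint_hat - joint) < 3.9 * se + 1e-12))

  expect_error(
    sample_torsion_system(small_rugged_system(coupled = TRUE), 10,
                          sampler = "exact_factorized"),
    "factorized")
})

test_that("MCMC sampler matches brute-force enumeration on a coupled system", {
  sys <- small_rugged_system(seed = 34, coupled = TRUE)
  enum <- enumerate_microstates(sys)
  s <- sample_torsion_system(sys, 4000, seed = 35, sampler = "mcmc")
  for (d in 1:3) {
    exact <- vapply(1:12, function(b) sum(enum$p[enum$bins[, d] == b]),
                    numeric(1))
    emp <- tabulate(s$bins[, d], 12) / 4000
    # thinned Metropolis samples retain some autocorrelation; allow a
    # generous multiple of the iid standard error
    expect_true(all(abs(emp - exact) < 6 * sqrt(exact * (1 - exact) / 4000) + 0.01))
  }
  # energies recomputable from stored angles, exactly
  expect_equal(system_energy(sys, angles = s$trajectory$angles),
               s$trajectory$energies)
  expect_identical(s$bins, sample_torsion_system(sys, 4000, seed = 35,
                                                 sampler = "mcmc")$bins)
})

test_that("exact macrostate weights: closed cases and sampling cross-check", {
  flat <- torsion_system(matrix(0, 2, 360))
  expect_equal(exact_macrostate_weight(flat, macrostate_selector(1, -180, -162)),
               18 / 360)
  expect_equal(exact_macrostate_weight(flat, macrostate_selector(2, -180, 180)),
               1.0)

  sys <- small_rugged_system(seed = 36)
  sel <- macrostate_selector(2, -90, -60)
  w <- exact_macrostate_weight(sys, sel)
  s <- sample_torsion_system(sys, 4e4, seed = 37)
  a <- s$trajectory$angles[, 2]
  emp <- mean(a >= -90 & a < -60)
  expect_lt(abs(emp - w), 3 * sqrt(w * (1 - w) / 4e4))

  # coupled systems are enumerated; same answer as summing the enumeration
  sysc <- small_rugged_system(seed = 36, coupled = TRUE)
  enum <- enumerate_microstates(sysc)
  centers <- bin_centers(sysc)
  direct <- sum(enum$p[centers[enum$bins[, 2]] >= -90 &
                         centers[enum$bins[, 2]] < -60])
  expect_equal(exact_macrostate_weight(sysc, sel), direct, tolerance = 1e-12)
  expect_error(enumerate_microstates(sysc, cap = 100), "cap exceeded")
})

test_that("exact entropy report closes against direct microstate entropy", {
  # flat system: uniform conformer weights, D_KL = 0, S_conf = ln N_conf
  flat <- torsion_system(matrix(0, 2, 12))
  sel <- macrostate_selector(1, -180, 180)
  def <- conformer_definition(1:2, name = "pair")
  rep_flat <- exact_entropy_report(flat, sel, def)
  expect_equal(rep_flat$d_kl, 0, tolerance = 1e-12)
  expect_equal(rep_flat$s_conf, log(rep_flat$n_conf), tolerance = 1e-12)

  # single conformer spanning the macrostate: S_conf = 0, S_total = <S_intra>
  one <- exact_entropy_report(flat, macrostate_selector(1, -180, -60),
                              conformer_definition(1L, name = "t1"))
  expect_equal(one$n_conf, 1L)
  expect_equal(one$s_conf, 0)
  expect_equal(one$s_total, one$mean_s_intra)

  # rugged coupled system: grouped decomposition equals the direct sum
  sys <- small_rugged_system(seed = 38, coupled = TRUE)
  rep_r <- exact_entropy_report(sys, macrostate_selector(1, -60, 60),
                                conformer_definition(1:3, name = "all"))
  expect_equal(rep_r$s_total, rep_r$s_total_direct, tolerance = 1e-10)
  expect_equal(rep_r$s_conf, rep_r$s_boltz - rep_r$d_kl, tolerance = 1e-12)
  expect_gte(rep_r$d_kl, 0)
  expect_equal(sum(rep_r$conformer_weights), 1, tolerance = 1e-12)
})

test_that("empirical macrostate frequencies converge on the exact weights", {
  sys <- small_rugged_system(seed = 39)
  s <- sample_torsion_system(sys, 5e4, seed = 40)
  mset <- build_macrostates(s$trajectory, order_params = 1L, window_width = 30)
  for (k in which(mset$selectors$observed)) {
    w <- exact_macrostate_weight(
      sys, macrostate_selector(1, mset$selectors$window_lo[k],
                               mset$selectors$window_hi[k]))
    emp <- mset$selectors$n_snap[k] / 5e4
    expect_lt(abs(emp - w), 3 * sqrt(w * (1 - w) / 5e4) + 1e-9)
  }
})
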