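test_that("count-based free energy estimators evaluate the log ratio", {
  expect_equal(delta_F_snap(100, 100), 0)
  expect_equal(delta_F_snap(1000, 100), log(10), tolerance = 1e-12)
  expect_equal(delta_F_conf(exp(1) * 100, 100), 1, tolerance = 1e-12)
  expect_error(delta_F_snap(0, 10), "empty macrostate")
  expect_error(delta_F_conf(10, 0), "empty macrostate")
  # path consistency: dF(A,C) = dF(A,B) + dF(B,C)
  n <- c(A = 120, B = 46, C = 913)
  expect_equal(unname(delta_F_snap(n["A"], n["C"])),
               unname(delta_F_snap(n["A"], n["B"]) +
                        delta_F_snap(n["B"], n["C"])),
               tolerance = 1e-14)
})

test_that("pairwise ddF table has one row per unordered pair, antisymmetric", {
  traj <- with_seed2(41, dihedral_trajectory(
    matrix(runif(900 * 3, -180, 180), 900, 3)))
  def <- conformer_definition(2:3)
  mset <- build_macrostates(traj, order_params = 1L, window_width = 36)
  tab <- pairwise_ddF(mset, def, traj)
  M <- sum(mset$selectors$observed)
  expect_equal(nrow(tab), M * (M - 1) / 2)
  expect_true(all(tab$i > tab$j))
  expect_equal(tab$ddF, tab$dF_snap - tab$dF_conf)
  # antisymmetry under pair swap: recompute each quantity with roles reversed
  mset2 <- count_conformers_per_macrostate(mset, traj, def)
  n_snap <- mset2$selectors$n_snap
  n_conf <- mset2$conformer_counts[[def$name]]
  for (k in c(1L, 7L, nrow(tab))) {
    expect_equal(delta_F_snap(n_snap[tab$i[k]], n_snap[tab$j[k]]),
                 -tab$dF_snap[k], tolerance = 1e-12)
    expect_equal(delta_F_conf(n_conf[tab$i[k]], n_conf[tab$j[k]]),
                 -tab$dF_conf[k], tolerance = 1e-12)
  }
  expect_error(pairwise_ddF(build_macrostates(
    dihedral_trajectory(matrix(0, 3, 1)), window_width = 360),
    conformer_definition(1L), dihedral_trajectory(matrix(0, 3, 1))),
    "at least 2")
})

test_that("one snapshot per conformer forces ddF = 0 and an identity fit", {
  traj <- iswd_limit_trajectory()
  def <- conformer_definition(1:6, name = "fine")
  mset <- build_macrostates(traj, order_params = 1L, window_width = 120)
  tab <- pairwise_ddF(mset, def, traj)
  expect_true(all(tab$ddF == 0))
  expect_equal(tab$dF_snap, tab$dF_conf)
  fit <- scaling_data(mset, def, traj)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("cpd handles degenerate and shifted inputs correctly", {
  flat <- cpd(rep(0, 10), auc_range = 2)
  expect_equal(flat$auc, 2)            # step to 1 at 0: full range
  expect_equal(flat$x, 0)
  expect_equal(flat$p, 1)
  pm <- cpd(c(-1, 1), auc_range = 2)
  expect_equal(pm$x, 1)                # |.| folds the signs together
  expect_equal(pm$p, 1)
  expect_equal(pm$auc, 1)              # F = 0 on [0,1), 1 on [1,2]
  expect_error(cpd(numeric(0)), "non-empty")
  # stochastic dominance: shifting |values| up never increases the AUC
  v <- with_seed2(42, rexp(200))
  r <- max(v) + 1
  aucs <- vapply(c(0, 0.1, 0.5, 0.9),
                 function(eps) cpd(v + eps, auc_range = r)$auc, numeric(1))
  expect_true(all(diff(aucs) <= 1e-12))
})

test_that("scaling fit flags saturation and degenerate inputs", {
  # sharply peaked 1-torsion system, coarse 1-torsion conformers: the
  # heaviest macrostates saturate N_conf and bend off the identity line
  e <- -3 * exp(-((seq(-179.5, 179.5, by = 1)) + 60)^2 / (2 * 15^2))
  sys <- torsion_system(rbind(e, rep(0, 360)))
  s <- sample_torsion_system(sys, 2e4, seed = 43)
  mset <- build_macrostates(s$trajectory, order_params = 1L, window_width = 18)
  fit <- scaling_data(mset, conformer_definition(1:2, name = "coarse"),
                      s$trajectory)
  expect_lt(fit$slope, 1)
  dev <- fit$points$neg_ln_nconf - fit$points$neg_ln_nsnap
  heaviest <- which.min(fit$points$neg_ln_nsnap)
  expect_gt(dev[heaviest], 0)          # too few conformers for its population
  # fewer than three observed macrostates cannot be fit
  two <- dihedral_trajectory(matrix(c(-90, -90, 90), 3, 1))
  m2 <- build_macrostates(two, window_width = 180)
  expect_error(scaling_data(m2, conformer_definition(1L), two), "at least 3")
})

test_that("convergence trend separates fine from coarse conformers", {
  s <- sample_iswd_trajectory(4e4, seed = 45)
  defs <- list(conformer_definition(1:27, name = "fine"),
               conformer_definition(1:6, name = "coarse"))
  trend <- convergence_trend(s$trajectory, defs, fractions = c(0.1, 0.5, 1.0),
                             order_params = 1L, window_width = 24)
  tab <- trend$table
  expect_equal(nrow(tab), 6L)
  fine_auc <- tab$auc[tab$definition == "fine"]
  coarse_auc <- tab$auc[tab$definition == "coarse"]
  expect_true(all(fine_auc >= coarse_auc))
  expect_equal(unname(trend$classification["fine"]), "shrinking")
  expect_equal(unname(trend$classification["coarse"]), "broadening")
  expect_error(convergence_trend(s$trajectory, defs, fractions = 1.0),
               "at least two")
})

test_that("the ISWD generator realizes its conformer-level model", {
  s <- sample_iswd_trajectory(2e4, seed = 46, n_torsions = 7, n_windows = 6,
                              m1 = 300, lambda = 0.5)
  # window occupancies follow the accessible-conformer ladder m_k / sum(m_k)
  w <- s$m_k / sum(s$m_k)
  occ <- tabulate(s$window, 6) / 2e4
  expect_true(all(abs(occ - w) < 4 * sqrt(w * (1 - w) / 2e4)))
  # the trajectory's window assignment reproduces the generator's
  mset <- build_macrostates(s$trajectory, order_params = 1L, window_width = 60)
  expect_equal(mset$selectors$n_snap, tabulate(s$window, 6))
  # occupied conformers never exceed the accessible count, and deep sampling
  # saturates the small windows exactly at m_k
  mset <- count_conformers_per_macrostate(
    mset, s$trajectory, conformer_definition(1:7, name = "full"))
  nc <- mset$conformer_counts$full
  expect_true(all(nc <= s$m_k))
  expect_equal(nc[6], s$m_k[6])  # ~740 draws over 25 conformers: all hit
})
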