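# Shared fixture builders. Everything is generated in code; no stored data.

# representative angle for torsional state s under the default boundaries
state_angle <- function(s) c(-120, 0, 120)[s + 1L]

# trajectory in the exact-ISWD limit: every snapshot occupies its own
# conformer (all 3^6 state rows distinct), order parameter = torsion 1 with
# 120-degree windows aligned to the arcs
iswd_limit_trajectory <- function(n = 400L, n_tors = 6L) {
  combos <- as.matrix(expand.grid(rep(list(0:2), n_tors)))[seq_len(n), ,
                                                           drop = FALSE]
  dihedral_trajectory(matrix(state_angle(combos), nrow(combos), n_tors),
                      source = "iswd-limit fixture")
}

# two-macrostate fixture with frozen conformer counts {2,2} vs {4,1,1,1,1}
# over torsions {2,3}; chosen so that sum(c*log(c))/n_snap is equal in both
# macrostates, making ddF = -ddS hold exactly and nontrivially (+log(10)/... =
# -log(2) + log(5/2) = 0.22314...)
ddf_dds_fixture <- function() {
  rows_A <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))
  rows_B <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0),
                  c(1, 0), c(2, 0), c(0, 1), c(1, 1))
  states23 <- rbind(rows_A, rows_B)
  t1 <- rep(c(0L, 1L), c(nrow(rows_A), nrow(rows_B)))  # arc 0 = A, arc 1 = B
  angles <- cbind(state_angle(t1),
                  state_angle(states23[, 1]), state_angle(states23[, 2]))
  dihedral_trajectory(angles, source = "ddF/ddS identity fixture")
}

# small rugged 3-torsion system, fully enumerable (G^3 = 1728)
small_rugged_system <- function(seed = 5, coupled = FALSE, grid = 12L) {
  site <- with_seed2(seed, matrix(runif(3 * grid, -2, 2), 3, grid))
  coupling <- NULL
  if (coupled) {
    centers <- -180 + (seq_len(grid) - 0.5) * 360 / grid
    coupling <- 0.8 * (1 - cos(outer(centers, centers, "-") * pi / 180))
  }
  torsion_system(site, coupling)
}

# seed helper local to the tests (keeps the suite deterministic without
# leaking RNG state between tests)
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# exact Boltzmann mass of a double-well region by numerical quadrature,
# independent of the sampler's internal piecewise-constant arithmetic
dw_quadrature_mass <- function(spec, lower, upper) {
  f <- Vectorize(function(x) exp(-double_well_energy(spec, x)))
  stats::integrate(f, lower, upper, rel.tol = 1e-10)$value
}

# system with two equal-weight torsion-1 windows of different internal
# ruggedness: window A flat, window B alternating -log(1.5)/+log(2) so that
# mean exp(-U) = 1. Exact entropy-enthalpy compensation with dU != 0.
perfect_eec_system <- function() {
  G <- 40L  # 9-degree bins; 18-degree windows hold exactly 2 bins
  site1 <- rep(3, G)  # park most of the circle high so the windows dominate
  site1[1:2] <- 0                        # window A: [-180, -162)
  site1[21:22] <- c(-log(1.5), log(2))   # window B: [0, 18)
  site2 <- with_seed2(11, runif(G, -1, 1))
  torsion_system(rbind(site1, site2))
}
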