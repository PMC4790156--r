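#' Sample a trajectory with an exactly invariant statistical weight distribution
#'
#' Constructs snapshots from an explicit conformer-level model in which ISWD
#' holds exactly: every thermally accessible conformer carries the same
#' statistical weight, and the number of accessible conformers per macrostate
#' window sets the window's Boltzmann weight. Macrostates are the
#' `n_windows` equal windows of torsion 1 (the order parameter), with
#' accessible conformer counts `M_k = ceiling(m1 * exp(-lambda * (k - 1)))`,
#' so window weights span `lambda * (n_windows - 1)` kT. Each snapshot draws a
#' conformer uniformly from all accessible conformers, places torsion 1
#' uniformly inside the window, and sets torsions `2..n_torsions` to the
#' conformer's torsional-state arcs (uniform jitter within each arc).
#'
#' Against this ground truth, the full conformer definition (all torsions)
#' satisfies ISWD by construction — its per-window conformer counts track the
#' snapshot counts at every trajectory size — while the order-parameter-only
#' definition collapses each window to a single conformer and exposes the full
#' spread of population free energies, the failure mode of coarse
#' discretizations.
#'
#' @param n number of snapshots.
#' @param seed integer seed; deterministic given `(parameters, n, seed)`.
#' @param n_torsions total torsions including the order parameter; the
#'   conformer space over torsions `2..n_torsions` (`3^(n_torsions - 1)`) must
#'   hold `m1` conformers.
#' @param n_windows windows on torsion 1; the width `360 / n_windows` must
#'   also divide the 120-degree arc width, so windows never straddle a
#'   torsional-state boundary and the construction stays exact (default: 15
#'   windows of 24 degrees).
#' @param m1 accessible conformers in the heaviest window. The default keeps
#'   the accessible conformer space orders of magnitude larger than any
#'   desk-scale trajectory, so the full-resolution definition stays in the
#'   one-snapshot-per-conformer regime at every subset size, as a sufficiently
#'   fine definition should.
#' @param lambda log-weight decrement per window (kT), i.e. the free energy
#'   step between successive macrostates.
#' @return a `sample_set` whose trajectory carries no energies (the model is
#'   specified at conformer, not microstate, resolution), plus `window` (the
#'   generating window index per snapshot) and `m_k` (accessible conformer
#'   counts per window).
#' @export
sample_iswd_trajectory <- function(n, seed = 1L, n_torsions = 27L,
                                   n_windows = 15L, m1 = 2e12, lambda = 0.8) {
  if (360 %% n_windows != 0 || 120 %% (360 / n_windows) != 0) {
    stop("`n_windows` must divide 360 with a width that divides the 120-degree arcs")
  }
  d_conf <- n_torsions - 1L
  m_k <- pmax(1, ceiling(m1 * exp(-lambda * (0:(n_windows - 1L)))))
  if (max(m_k) > 3^d_conf) {
    stop("conformer space 3^", d_conf, " too small for m1 = ", m1)
  }
  total <- sum(m_k)
  upper <- cumsum(m_k)
  width <- 360 / n_windows
  out <- with_seed(seed, {
    conf <- sample.int(total, n, replace = TRUE)  # uniform: equal weights
    window <- findInterval(conf - 1L, upper) + 1L
    j <- conf - c(0L, upper)[window] - 1L         # 0-based index inside window
    # injective, window-dependent placement of conformers on the state grid
    code <- (j + (window - 1L) * 7919) %% 3^d_conf
    states <- matrix(0L, n, d_conf)
    rem <- code
    for (t in seq_len(d_conf)) {
      states[, t] <- as.integer(rem %% 3)
      rem <- rem %/% 3
    }
    ang1 <- -180 + (window - 1L) * width + runif(n) * width
    # arcs [-180,-60) [-60,60) [60,180): jitter keeps the angle in its arc
    ang_rest <- -180 + states * 120 + matrix(runif(n * d_conf) * 120, n, d_conf)
    list(angles = cbind(ang1, ang_rest), window = window)
  })
  prov <- sprintf(
    "iswd_trajectory(D=%d,windows=%d,m1=%g,lambda=%g) n=%d seed=%d",
    n_torsions, n_windows, m1, lambda, n, as.integer(seed))
  angles <- unname(out$angles)
  traj <- dihedral_trajectory(angles, source = prov)
  structure(list(trajectory = traj, window = out$window, m_k = m_k,
                 provenance = prov),
            class = "sample_set")
}
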