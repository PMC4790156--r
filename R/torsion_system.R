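#' Multi-torsion Boltzmann lattice system
#'
#' An exactly solvable stand-in for a flexible molecule: `D` torsions, each
#' discretized into `grid_size` microstate bins with angle values at the bin
#' centers in `(-180, 180]`. The energy of a microstate is the sum of
#' per-torsion site energies plus, optionally, a shared nearest-neighbour
#' coupling term between adjacent torsions. All energies in kT (beta = 1).
#' Without coupling the joint Boltzmann distribution factorizes over torsions,
#' which makes exact marginals, macrostate weights and entropies cheap at any
#' dimension; with coupling, exact results come from full enumeration of the
#' `grid_size^D` microstates (capped).
#'
#' @param site_energies numeric matrix, `n_torsions x grid_size`, kT.
#' @param coupling optional `grid_size x grid_size` matrix; microstate energy
#'   gains `coupling[b_d, b_{d+1}]` for every adjacent torsion pair.
#' @param beta inverse temperature in 1/kT units; fixed at 1 (energies are
#'   already in kT), kept explicit only so the unit convention is visible.
#' @return object of class `torsion_system`.
#' @export
torsion_system <- function(site_energies, coupling = NULL, beta = 1) {
  if (!is.matrix(site_energies) || !is.numeric(site_energies)) {
    stop("`site_energies` must be a numeric matrix (torsions x grid bins)")
  }
  if (any(!is.finite(site_energies))) stop("site energies must be finite")
  G <- ncol(site_energies)
  if (G < 3L) stop("`grid_size` must be at least 3")
  if (!is.null(coupling)) {
    if (!is.matrix(coupling) || any(dim(coupling) != G)) {
      stop("`coupling` must be a grid_size x grid_size matrix")
    }
    if (any(!is.finite(coupling))) stop("coupling energies must be finite")
  }
  if (!identical(beta, 1) && !identical(beta, 1L)) {
    stop("beta is fixed at 1: energies are expressed in kT units")
  }
  structure(
    list(n_torsions = nrow(site_energies), grid_size = G,
         site_energies = site_energies, coupling = coupling, beta = 1),
    class = "torsion_system"
  )
}

#' @export
print.torsion_system <- function(x, ...) {
  cat("<torsion_system> ", x$n_torsions, " torsions x ", x$grid_size,
      " bins", if (!is.null(x$coupling)) ", nearest-neighbour coupled" else
        ", factorized", "\n", sep = "")
  invisible(x)
}

#' Angle values at the microstate bin centers
#' @param system a [torsion_system()].
#' @return numeric vector of `grid_size` angles in `(-180, 180]`.
#' @export
bin_centers <- function(system) {
  G <- system$grid_size
  -180 + (seq_len(G) - 0.5) * 360 / G
}

#' Rugged lipid-like torsion system
#'
#' Default synthetic system emulating the statistical structure of a lipid
#' tail's torsions: each torsion concentrates in three rotameric basins
#' (Gaussian wells centred at -60, +60 and 180 degrees, circular distance,
#' 25-degree width) whose depths are randomized per torsion (uniform on
#' [1, 4] kT, seeded), so macrostate weights vary exponentially. Optional
#' nearest-neighbour coupling `J * (1 - cos(theta_d - theta_{d+1}))`.
#'
#' @param n_torsions number of torsions, default 12.
#' @param grid_size bins per torsion, default 360 (one-degree bins).
#' @param seed integer seed for the randomized basin depths.
#' @param coupling_strength J in kT; 0 (default) gives a factorized system.
#' @return a [torsion_system()].
#' @export
popc_like_system <- function(n_torsions = 12L, grid_size = 360L, seed = 1L,
                             coupling_strength = 0) {
  centers <- bin_centers(list(grid_size = grid_size))
  basins <- c(-60, 60, 180)
  sigma <- 25
  depths <- with_seed(seed, matrix(runif(3 * n_torsions, 1, 4), n_torsions, 3))
  site <- matrix(0, n_torsions, grid_size)
  for (b in 1:3) {
    d <- abs(wrap_angle(centers - basins[b]))
    site <- site - outer(depths[, b], exp(-d^2 / (2 * sigma^2)))
  }
  coupling <- NULL
  if (coupling_strength > 0) {
    coupling <- coupling_strength *
      (1 - cos(outer(centers, centers, "-") * pi / 180))
  }
  torsion_system(site, coupling)
}

#' Potential energy of microstates
#'
#' Exact system energy (kT) of each snapshot, from grid bin indices or from a
#' matrix of angles (mapped to their containing bins).
#'
#' @param system a [torsion_system()].
#' @param bins integer matrix `n x n_torsions` of bin indices, or `NULL` if
#'   `angles` is given.
#' @param angles numeric matrix of angles in degrees.
#' @return numeric vector of energies, kT.
#' @export
system_energy <- function(system, bins = NULL, angles = NULL) {
  if (is.null(bins)) {
    if (is.null(angles)) stop("supply `bins` or `angles`")
    bins <- angles_to_bins(system, angles)
  }
  D <- system$n_torsions
  if (ncol(bins) != D) stop("bin matrix must have one column per torsion")
  e <- numeric(nrow(bins))
  for (d in seq_len(D)) {
    e <- e + system$site_energies[d, bins[, d]]
  }
  if (!is.null(system$coupling) && D > 1L) {
    for (d in seq_len(D - 1L)) {
      e <- e + system$coupling[cbind(bins[, d], bins[, d + 1L])]
    }
  }
  e
}

#' @rdname system_energy
#' @export
angles_to_bins <- function(system, angles) {
  G <- system$grid_size
  idx <- 1L + as.integer(((wrap_angle(as.numeric(angles)) + 180) %% 360) / 360 * G)
  idx[idx > G] <- G
  matrix(idx, nrow(angles), ncol(angles))
}

#' Sample a torsion system
#'
#' Draws Boltzmann-distributed snapshots. `"exact_factorized"` (uncoupled
#' systems only) samples each torsion independently from its exact marginal;
#' `"mcmc"` runs single-site Metropolis on the bin lattice with recorded
#' burn-in and thinning. Bin indices are mapped to angles at the bin centers.
#' Deterministic given `(system, n, seed)`.
#'
#' @param system a [torsion_system()].
#' @param n number of snapshots.
#' @param seed integer seed.
#' @param sampler `"exact_factorized"` or `"mcmc"`.
#' @param burn_in MCMC burn-in in sweeps (one sweep = one Metropolis update per
#'   torsion); default `10 * n_torsions * grid_size`.
#' @param thin MCMC thinning in sweeps between recorded snapshots; default
#'   `n_torsions`.
#' @return object of class `sample_set`: `trajectory` (a
#'   [dihedral_trajectory()] carrying exact per-snapshot energies), `bins`, and
#'   `provenance` (system shape, sampler, seed, burn-in/thinning).
#' @export
sample_torsion_system <- function(system, n, seed = 1L,
                                  sampler = c("exact_factorized", "mcmc"),
                                  burn_in = NULL, thin = NULL) {
  stopifnot(inherits(system, "torsion_system"))
  sampler <- match.arg(sampler)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count")
  }
  n <- as.integer(n)
  D <- system$n_torsions
  G <- system$grid_size
  if (sampler == "exact_factorized") {
    if (!is.null(system$coupling)) {
      stop("exact_factorized sampling requires an uncoupled (factorized) system")
    }
    bins <- with_seed(seed, {
      vapply(seq_len(D), function(d) {
        p <- exp(-(system$site_energies[d, ] - min(system$site_energies[d, ])))
        sample.int(G, n, replace = TRUE, prob = p)
      }, integer(n))
    })
    bins <- matrix(bins, n, D)
    prov <- sprintf("torsion_system(D=%d,G=%d) n=%d seed=%d sampler=exact_factorized",
                    D, G, n, seed)
  } else {
    if (is.null(burn_in)) burn_in <- 10L * D * G
    if (is.null(thin)) thin <- D
    bins <- with_seed(seed, .metropolis_bins(system, n, burn_in, thin))
    prov <- sprintf(
      "torsion_system(D=%d,G=%d) n=%d seed=%d sampler=mcmc burn_in=%d thin=%d",
      D, G, n, seed, as.integer(burn_in), as.integer(thin))
  }
  centers <- bin_centers(system)
  angles <- matrix(centers[bins], n, D)
  traj <- dihedral_trajectory(angles, energies = system_energy(system, bins),
                              source = prov)
  structure(list(trajectory = traj, bins = bins, provenance = prov),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", x$provenance, "\n", sep = "")
  invisible(x)
}

# single-site Metropolis over the bin lattice; one sweep updates every torsion
.metropolis_bins <- function(system, n, burn_in, thin) {
  D <- system$n_torsions
  G <- system$grid_size
  state <- sample.int(G, D, replace = TRUE)
  out <- matrix(0L, n, D)
  site <- system$site_energies
  coupled <- !is.null(system$coupling)
  local_e <- function(state, d, b) {
    e <- site[d, b]
    if (coupled) {
      if (d > 1L) e <- e + system$coupling[state[d - 1L], b]
      if (d < D) e <- e + system$coupling[b, state[d + 1L]]
    }
    e
  }
  n_sweeps <- burn_in + n * thin
  for (sw in seq_len(n_sweeps)) {
    prop <- sample.int(G, D, replace = TRUE)
    acc <- runif(D)
    for (d in seq_len(D)) {
      dE <- local_e(state, d, prop[d]) - local_e(state, d, state[d])
      if (dE <= 0 || acc[d] < exp(-dE)) state[d] <- prop[d]
    }
    if (sw > burn_in && (sw - burn_in) %% thin == 0L) {
      out[(sw - burn_in) %/% thin, ] <- state
    }
  }
  out
}

#' Exact Boltzmann weight of a macrostate
#'
#' Exact probability mass of all microstates whose order-parameter torsion
#' falls in the selector's window. For factorized systems this is the exact
#' single-torsion marginal at any dimension; coupled systems are enumerated in
#' full (subject to `cap`).
#'
#' @param system a [torsion_system()].
#' @param selector a [macrostate_selector()].
#' @param cap maximum number of microstates to enumerate for coupled systems.
#' @return probability in `[0, 1]`.
#' @export
exact_macrostate_weight <- function(system, selector, cap = 1e7) {
  stopifnot(inherits(system, "torsion_system"),
            inherits(selector, "macrostate_selector"))
  centers <- bin_centers(system)
  in_win <- centers >= selector$lo & centers < selector$hi
  if (is.null(system$coupling)) {
    e <- system$site_energies[selector$order_param, ]
    w <- exp(-(e - min(e)))
    sum(w[in_win]) / sum(w)
  } else {
    enum <- enumerate_microstates(system, cap = cap)
    sum(enum$p[in_win[enum$bins[, selector$order_param]]])
  }
}

#' Enumerate all microstates of a small system
#'
#' Full `grid_size^n_torsions` enumeration with exact Boltzmann probabilities;
#' the oracle behind [exact_entropy_report()] and [eec_check()].
#'
#' @param system a [torsion_system()].
#' @param cap maximum number of microstates (error above).
#' @return list: `bins` (integer matrix, microstates x torsions), `energy`
#'   (kT) and `p` (normalized Boltzmann probabilities).
#' @export
enumerate_microstates <- function(system, cap = 1e7) {
  D <- system$n_torsions
  G <- system$grid_size
  M <- G^D
  if (M > cap) {
    stop("enumeration cap exceeded: ", G, "^", D, " microstates > cap = ", cap)
  }
  bins <- as.matrix(expand.grid(rep(list(seq_len(G)), D), KEEP.OUT.ATTRS = FALSE))
  dimnames(bins) <- NULL
  storage.mode(bins) <- "integer"
  e <- system_energy(system, bins)
  w <- exp(-(e - min(e)))
  list(bins = bins, energy = e, p = w / sum(w))
}

#' Exact entropy decomposition of a macrostate
#'
#' By full enumeration: restricts the Boltzmann distribution to the selector's
#' window, groups microstates into conformers, and reports the conformer
#' weights `P_i`, the conformational entropy `S_conf`, its Boltzmann part
#' `S_Boltz = ln N_conf` and KL deviation `D_KL`, the intra-conformer entropies
#' and their average, the total entropy `S_total = S_conf + <S_intra>`
#' (verified against the direct microstate Shannon entropy), and the mean
#' potential energy. All entropies in k, energies in kT.
#'
#' @param system a [torsion_system()].
#' @param selector a [macrostate_selector()].
#' @param conf_def a [conformer_definition()].
#' @param cap enumeration cap.
#' @return object of class `entropy_report`.
#' @export
exact_entropy_report <- function(system, selector, conf_def, cap = 1e7) {
  stopifnot(inherits(conf_def, "conformer_definition"))
  if (max(conf_def$torsion_subset) > system$n_torsions) {
    stop("conformer definition references a torsion absent from the system")
  }
  enum <- enumerate_microstates(system, cap = cap)
  centers <- bin_centers(system)
  member <- centers[enum$bins[, selector$order_param]] >= selector$lo &
    centers[enum$bins[, selector$order_param]] < selector$hi
  weight <- sum(enum$p[member])
  if (weight <= 0) stop("macrostate has zero Boltzmann weight")
  p <- enum$p[member] / weight
  # torsional state of each grid bin, shared across torsions
  bin_state <- assign_torsional_states(matrix(centers, ncol = 1),
                                       conf_def$boundaries)[, 1]
  sub <- conf_def$torsion_subset
  states <- matrix(bin_state[enum$bins[member, sub, drop = FALSE]],
                   ncol = length(sub))
  ids <- as.numeric(states %*% 3^(seq_along(sub) - 1))
  grp <- split(p, ids)
  P <- vapply(grp, sum, numeric(1))
  s_intra <- vapply(grp, function(q) {
    q <- q / sum(q)
    -sum(q * log(q))
  }, numeric(1))
  s_conf <- -sum(P * log(P))
  s_boltz <- log(length(P))
  mean_s_intra <- sum(P * s_intra)
  structure(
    list(selector = selector, weight = weight,
         conformer_weights = P, n_conf = length(P),
         s_conf = s_conf, s_boltz = s_boltz, d_kl = s_boltz - s_conf,
         s_intra = s_intra, mean_s_intra = mean_s_intra,
         s_total = s_conf + mean_s_intra,
         s_total_direct = -sum(p * log(p)),
         mean_u = sum(p * enum$energy[member])),
    class = "entropy_report"
  )
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("<entropy_report> window [", x$selector$lo, ", ", x$selector$hi,
      ") on torsion ", x$selector$order_param, "\n", sep = "")
  cat(sprintf("  weight %.4g | N_conf %d | S_conf %.4f = ln N_conf %.4f - D_KL %.4f\n",
              x$weight, x$n_conf, x$s_conf, x$s_boltz, x$d_kl))
  cat(sprintf("  <S_intra> %.4f | S_total %.4f (direct %.4f) | <U> %.4f kT\n",
              x$mean_s_intra, x$s_total, x$s_total_direct, x$mean_u))
  invisible(x)
}

#' Entropy-enthalpy compensation check
#'
#' For a macrostate pair of an enumerable system, computes exactly (by
#' enumeration) the change of mean potential energy `dU`, of conformational
#' entropy, of Boltzmann entropy, of average intra-conformer entropy and of
#' total entropy, alongside the exact free energy difference
#' `dF = -ln(w_B / w_A)`. The canonical identity `dF = dU - T dS_total` holds
#' to numerical precision by construction. The EEC residual
#' `dU - T d<S_intra> - T (dS_conf - dS_Boltz)` equals `dF - dF_conf`, the
#' error of the conformer-count estimator: it vanishes exactly when the
#' conformer definition realizes ISWD, in which case the enthalpy change is
#' compensated by the intra-conformer entropy change (plus the KL term).
#'
#' @param system a [torsion_system()].
#' @param selA,selB [macrostate_selector()]s for the start and end macrostate.
#' @param conf_def a [conformer_definition()].
#' @param cap enumeration cap.
#' @return object of class `eec_report`: the per-macrostate `entropy_report`s
#'   plus `dU`, `dS_conf`, `dS_boltz`, `dS_intra`, `dS_total`, `dF_exact`,
#'   `dF_conf`, `residual` and `closure` (all kT / k, T = 1).
#' @export
eec_check <- function(system, selA, selB, conf_def, cap = 1e7) {
  repA <- exact_entropy_report(system, selA, conf_def, cap = cap)
  repB <- exact_entropy_report(system, selB, conf_def, cap = cap)
  dU <- repB$mean_u - repA$mean_u
  dS_conf <- repB$s_conf - repA$s_conf
  dS_boltz <- repB$s_boltz - repA$s_boltz
  dS_intra <- repB$mean_s_intra - repA$mean_s_intra
  dS_total <- repB$s_total - repA$s_total
  dF_exact <- -log(repB$weight / repA$weight)
  dF_conf <- -log(repB$n_conf / repA$n_conf)
  structure(
    list(report_A = repA, report_B = repB,
         dU = dU, dS_conf = dS_conf, dS_boltz = dS_boltz,
         dS_intra = dS_intra, dS_total = dS_total,
         dF_exact = dF_exact, dF_conf = dF_conf,
         residual = dU - dS_intra - (dS_conf - dS_boltz),
         closure = dF_exact - (dU - dS_total)),
    class = "eec_report"
  )
}

#' @export
print.eec_report <- function(x, ...) {
  cat("<eec_report> (kT / k units, T = 1)\n")
  cat(sprintf("  dU %+.5f | d<S_intra> %+.5f | dS_conf %+.5f | dS_Boltz %+.5f\n",
              x$dU, x$dS_intra, x$dS_conf, x$dS_boltz))
  cat(sprintf("  dF_exact %+.5f | dF_conf %+.5f | EEC residual %+.3e | closure %+.3e\n",
              x$dF_exact, x$dF_conf, x$residual, x$closure))
  invisible(x)
}
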