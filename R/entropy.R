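#' Conformer statistical weights within a macrostate
#'
#' Normalized occupancies of the occupied conformers among a set of member
#' snapshots: `P_i = (snapshots in conformer i) / (snapshots in macrostate)`.
#'
#' @param ids conformer id vector (from [encode_conformers()]) of the member
#'   snapshots of one macrostate.
#' @return numeric vector of weights over occupied conformers, summing to 1,
#'   named by conformer id.
#' @export
conformer_weights <- function(ids) {
  if (length(ids) == 0L) stop("macrostate is empty: no conformer weights")
  counts <- table(ids)
  w <- as.numeric(counts) / length(ids)
  names(w) <- names(counts)
  w
}

#' Conformational entropy of a weight vector
#'
#' Shannon entropy `-sum(P * ln P)` of the conformer statistical weights within
#' a macrostate, in units of k. Zero for a single conformer; `ln N` for `N`
#' equally weighted conformers. Entropies are computed over occupied conformers
#' only; zero weights contribute nothing via the `p ln p -> 0` limit.
#'
#' @param P numeric weight vector, non-negative, summing to 1 within `1e-9`.
#' @return entropy in k units.
#' @examples
#' conformational_entropy(rep(1 / 8, 8))  # ln 8
#' @export
conformational_entropy <- function(P) {
  P <- .check_weights(P)
  -sum(P * log(P))
}

#' Kullback-Leibler divergence from the uniform distribution
#'
#' `D_KL(P || U) = sum(P * ln(P * N))` over the `N` occupied conformers, in
#' nats. Non-negative, zero iff the weights are uniform, and satisfying the
#' exact decomposition `S_conf = ln N - D_KL`: conformational entropy is the
#' Boltzmann (ideal-gas) entropy of the conformer count minus the KL deviation
#' of the actual weight distribution from uniformity.
#'
#' @inheritParams conformational_entropy
#' @return divergence in nats.
#' @export
kl_to_uniform <- function(P) {
  P <- .check_weights(P)
  sum(P * log(P * length(P)))
}

# validate, drop zero-weight (unoccupied) conformers
.check_weights <- function(P) {
  if (length(P) == 0L) stop("empty weight vector")
  if (any(P < 0)) stop("weights must be non-negative")
  if (abs(sum(P) - 1) > 1e-9) {
    stop("weights must be normalized (sum deviates from 1 by more than 1e-9)")
  }
  P <- P[P > 0]
  if (length(P) == 0L) stop("all weights are zero")
  P
}

#' Entropy decomposition per macrostate from a trajectory
#'
#' For every observed macrostate, computes the conformer weights and the split
#' `S_conf = S_Boltz - k D_KL`, where `S_Boltz = k ln N_conf` is the
#' ideal-gas entropy of the occupied conformer count. The mean potential energy
#' is reported when the trajectory carries energies. Intra-conformer entropies
#' are not estimable from trajectory data (the microstates inside a conformer
#' are not resolved) and are reported as `NA`; see [exact_entropy_report()] for
#' enumerable synthetic systems.
#'
#' @inheritParams pairwise_ddF
#' @param traj the trajectory the macrostates were built from.
#' @return data frame, one row per observed macrostate: `macrostate`, `n_snap`,
#'   `n_conf`, `s_conf`, `s_boltz`, `d_kl`, `mean_u`, `s_intra` (`NA`).
#' @export
macrostate_entropy <- function(mset, conf_def, traj) {
  stopifnot(inherits(mset, "macrostate_set"),
            inherits(traj, "dihedral_trajectory"))
  states <- assign_torsional_states(traj, conf_def$boundaries)
  ids <- encode_conformers(states, conf_def)
  obs <- which(mset$selectors$observed)
  rows <- lapply(obs, function(k) {
    m <- mset$membership[[k]]
    P <- conformer_weights(ids[m])
    s_boltz <- log(length(P))
    s_conf <- conformational_entropy(P)
    data.frame(
      macrostate = k, n_snap = length(m), n_conf = length(P),
      s_conf = s_conf, s_boltz = s_boltz, d_kl = s_boltz - s_conf,
      mean_u = if (is.null(traj$energies)) NA_real_ else mean(traj$energies[m]),
      s_intra = NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Pairwise deviation between conformational and Boltzmann entropy changes
#'
#' For every unordered pair of observed macrostates (same orientation as
#' [pairwise_ddF()]), `ddS = dS_conf - dS_Boltz = -k * dD_KL` in k units:
#' the difference between the observed change of conformational entropy and the
#' ideal-gas change based on conformer counts alone. Under ISWD the KL
#' deviations from uniformity cancel between macrostates and ddS vanishes.
#'
#' @inheritParams macrostate_entropy
#' @return a `pair_delta_table`-style data frame with columns `i`, `j`,
#'   `dS_conf`, `dS_boltz`, `ddS`.
#' @export
pairwise_ddS <- function(mset, conf_def, traj) {
  ent <- macrostate_entropy(mset, conf_def, traj)
  M <- nrow(ent)
  if (M < 2L) stop("need at least 2 observed macrostates for pairwise analysis")
  pr <- .lower_pairs(M)
  out <- data.frame(
    i = ent$macrostate[pr$i], j = ent$macrostate[pr$j],
    dS_conf = ent$s_conf[pr$i] - ent$s_conf[pr$j],
    dS_boltz = ent$s_boltz[pr$i] - ent$s_boltz[pr$j]
  )
  out$ddS <- out$dS_conf - out$dS_boltz
  attr(out, "conf_def_name") <- conf_def$name
  attr(out, "n_macrostates") <- M
  class(out) <- c("pair_delta_table", "data.frame")
  out
}
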