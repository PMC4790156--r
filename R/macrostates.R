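#' Macrostate selector
#'
#' One macrostate: the snapshots whose order-parameter dihedral falls in a
#' half-open window `[lo, hi)` (degrees, canonical circle).
#'
#' @param order_param 1-based torsion index used as order parameter.
#' @param lo,hi window edges in degrees, `lo < hi`.
#' @return object of class `macrostate_selector`.
#' @export
macrostate_selector <- function(order_param, lo, hi) {
  if (!(lo < hi)) stop("window must satisfy lo < hi")
  structure(list(order_param = as.integer(order_param), lo = lo, hi = hi),
            class = "macrostate_selector")
}

#' Build macrostates by windowed projection on order-parameter dihedrals
#'
#' Projects every snapshot onto each order-parameter dihedral and partitions
#' the circle into `360 / window_width` fixed windows anchored at -180 degrees.
#' Windows from the same order parameter are disjoint and cover all snapshots;
#' windows from different order parameters may overlap. Empty windows are
#' retained and flagged unobserved (the free energy of an empty macrostate is
#' undefined, so pairwise analyses use observed macrostates only).
#'
#' @param traj a [dihedral_trajectory()].
#' @param order_params integer vector of 1-based torsion indices; default all.
#' @param window_width window width in degrees; must divide 360. The default,
#'   18 degrees, gives 20 windows per order parameter.
#' @return object of class `macrostate_set`: a `selectors` data frame
#'   (`order_param`, `window_lo`, `window_hi`, `n_snap`, `observed`), a
#'   `membership` list of snapshot index vectors, and the originating window
#'   width.
#' @examples
#' traj <- dihedral_trajectory(matrix(runif(200, -180, 180), 100, 2))
#' mset <- build_macrostates(traj, window_width = 90)
#' mset$selectors
#' @export
build_macrostates <- function(traj, order_params = seq_len(n_torsions(traj)),
                              window_width = 18) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (window_width <= 0 || (360 %% window_width) != 0) {
    stop("`window_width` must divide 360 evenly")
  }
  order_params <- as.integer(order_params)
  if (any(order_params < 1L | order_params > n_torsions(traj))) {
    stop("order-parameter index out of range")
  }
  n_win <- as.integer(360 / window_width)
  edges <- -180 + window_width * (0:n_win)
  selectors <- data.frame(
    order_param = rep(order_params, each = n_win),
    window_lo = rep(edges[-(n_win + 1L)], length(order_params)),
    window_hi = rep(edges[-1L], length(order_params))
  )
  membership <- vector("list", nrow(selectors))
  for (t in seq_along(order_params)) {
    a <- traj$angles[, order_params[t]]
    # +180 then mod 360 sends the canonical representative 180 to window 1,
    # consistent with the half-open [lo, hi) convention under wrap
    win <- as.integer(((a + 180) %% 360) %/% window_width) + 1L
    grouped <- split(seq_along(a), factor(win, levels = seq_len(n_win)))
    membership[(t - 1L) * n_win + seq_len(n_win)] <- grouped
  }
  selectors$n_snap <- vapply(membership, length, integer(1))
  selectors$observed <- selectors$n_snap > 0L
  structure(
    list(selectors = selectors, membership = membership,
         window_width = window_width, n_snapshots = n_snapshots(traj)),
    class = "macrostate_set"
  )
}

#' @export
print.macrostate_set <- function(x, ...) {
  cat("<macrostate_set> ", nrow(x$selectors), " macrostates (",
      sum(x$selectors$observed), " observed), ",
      x$window_width, "-degree windows on ",
      length(unique(x$selectors$order_param)), " order parameter(s)\n", sep = "")
  if (!is.null(x$conformer_counts)) {
    cat("  conformer counts: ", paste(names(x$conformer_counts), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Count occupied conformers within each macrostate
#'
#' Bins the member snapshots of every observed macrostate into conformers
#' (via [encode_conformers()]) and records the number of non-empty bins,
#' `N_conf`, alongside `N_snap`.
#'
#' @param mset a [build_macrostates()] result.
#' @param traj the trajectory the macrostates were built from.
#' @param conf_def a [conformer_definition()].
#' @return `mset` with a `conformer_counts` entry: a named list (by definition
#'   name) of per-macrostate `N_conf` vectors (`NA` for unobserved windows).
#' @export
count_conformers_per_macrostate <- function(mset, traj, conf_def) {
  stopifnot(inherits(mset, "macrostate_set"),
            inherits(traj, "dihedral_trajectory"),
            inherits(conf_def, "conformer_definition"))
  if (max(conf_def$torsion_subset) > n_torsions(traj)) {
    stop("conformer definition references torsion ",
         max(conf_def$torsion_subset), " absent from the trajectory")
  }
  states <- assign_torsional_states(traj, conf_def$boundaries)
  ids <- encode_conformers(states, conf_def)
  n_conf <- rep(NA_integer_, nrow(mset$selectors))
  obs <- which(mset$selectors$observed)
  n_conf[obs] <- vapply(mset$membership[obs],
                        function(m) count_unique(ids[m]), integer(1))
  if (is.null(mset$conformer_counts)) mset$conformer_counts <- list()
  mset$conformer_counts[[conf_def$name]] <- n_conf
  mset
}

#' Nested trajectory subsets
#'
#' Time-ordered prefixes of the snapshot sequence, so that every smaller subset
#' is contained in every larger one (mirroring nested trajectory-set
#' constructions used for convergence analysis).
#'
#' @param traj a [dihedral_trajectory()].
#' @param fractions increasing numeric vector in `(0, 1]`.
#' @return list of `dihedral_trajectory` prefixes, one per fraction.
#' @export
nested_subsets <- function(traj, fractions) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (length(fractions) < 1L || any(fractions <= 0 | fractions > 1)) {
    stop("`fractions` must lie in (0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("`fractions` must be strictly increasing")
  }
  n <- n_snapshots(traj)
  lapply(fractions, function(f) {
    m <- max(1L, floor(f * n))
    dihedral_trajectory(
      traj$angles[seq_len(m), , drop = FALSE],
      torsion_labels = traj$torsion_labels,
      energies = if (!is.null(traj$energies)) traj$energies[seq_len(m)],
      source = sprintf("%s[prefix %d/%d]", traj$source, m, n)
    )
  })
}

#' Macrostate summary table
#'
#' Flat per-macrostate table (one row per window) with snapshot counts and one
#' `N_conf` column per conformer definition counted so far; suitable for
#' writing as TSV.
#'
#' @param mset a `macrostate_set`, after [count_conformers_per_macrostate()].
#' @return data frame.
#' @export
macrostate_table <- function(mset) {
  out <- mset$selectors
  for (nm in names(mset$conformer_counts)) {
    out[[paste0("n_conf_", nm)]] <- mset$conformer_counts[[nm]]
  }
  out
}
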