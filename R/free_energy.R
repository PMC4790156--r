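#' Free energy difference from snapshot counts
#'
#' The population estimator: for macrostates A (start) and B (end) observed
#' `n_A` and `n_B` times in the same trajectory set, `dF = -ln(n_B / n_A)` in
#' kT units. Undefined for an empty macrostate.
#'
#' @param n_snap_A,n_snap_B snapshot counts (>= 1) of the start and end
#'   macrostates.
#' @return free energy difference in kT.
#' @examples
#' delta_F_snap(1000, 100)  # +2.302585 kT
#' @export
delta_F_snap <- function(n_snap_A, n_snap_B) {
  .check_counts(n_snap_A, n_snap_B, "snapshot")
  -log(n_snap_B / n_snap_A)
}

#' Free energy difference from conformer counts
#'
#' The conformer-counting estimator: `dF = -ln(N_conf_B / N_conf_A)` in kT.
#' Exact when the occupied conformers carry an invariant statistical weight
#' distribution (ISWD) across the two macrostates, since then the average
#' conformer weights cancel; its deviation from [delta_F_snap()] is the ISWD
#' diagnostic.
#'
#' @param n_conf_A,n_conf_B occupied-conformer counts (>= 1) of the start and
#'   end macrostates.
#' @return free energy difference in kT.
#' @export
delta_F_conf <- function(n_conf_A, n_conf_B) {
  .check_counts(n_conf_A, n_conf_B, "conformer")
  -log(n_conf_B / n_conf_A)
}

.check_counts <- function(a, b, what) {
  if (any(c(a, b) < 1)) {
    stop("free energy is undefined for an empty macrostate (", what,
         " count of ", if (any(a < 1)) "start" else "end", " state is zero)")
  }
  invisible(NULL)
}

#' Pairwise deviation between snapshot- and conformer-count free energies
#'
#' For every unordered pair (i, j), i > j, of observed macrostates, computes
#' `dF_snap` and `dF_conf` with the lower-indexed macrostate as start state and
#' the higher-indexed one as end state, and their difference
#' `ddF = dF_snap - dF_conf` (kT). Under ISWD, ddF vanishes up to sampling
#' noise; systematic nonzero values indicate conformer weights that vary across
#' configurational space.
#'
#' @param mset a `macrostate_set`; conformer counts for `conf_def` are computed
#'   on demand when `traj` is supplied.
#' @param conf_def a [conformer_definition()].
#' @param traj trajectory (required unless counts were already attached via
#'   [count_conformers_per_macrostate()]).
#' @return a `pair_delta_table` data frame with columns `i`, `j` (global
#'   macrostate indices), `dF_snap`, `dF_conf`, `ddF`; metadata in attributes
#'   `conf_def_name` and `n_macrostates`.
#' @export
pairwise_ddF <- function(mset, conf_def, traj = NULL) {
  counts <- .macrostate_counts(mset, conf_def, traj)
  M <- length(counts$idx)
  if (M < 2L) stop("need at least 2 observed macrostates for pairwise analysis")
  ln_snap <- log(counts$n_snap)
  ln_conf <- log(counts$n_conf)
  pr <- .lower_pairs(M)
  out <- data.frame(
    i = counts$idx[pr$i], j = counts$idx[pr$j],
    dF_snap = ln_snap[pr$j] - ln_snap[pr$i],
    dF_conf = ln_conf[pr$j] - ln_conf[pr$i]
  )
  out$ddF <- out$dF_snap - out$dF_conf
  attr(out, "conf_def_name") <- conf_def$name
  attr(out, "n_macrostates") <- M
  class(out) <- c("pair_delta_table", "data.frame")
  out
}

# all (i, j) with i > j over 1..M, i-major like nested loops i in 2..M, j < i
.lower_pairs <- function(M) {
  i <- rep.int(2:M, 1:(M - 1L))
  j <- sequence(1:(M - 1L))
  list(i = i, j = j)
}

.macrostate_counts <- function(mset, conf_def, traj) {
  stopifnot(inherits(mset, "macrostate_set"))
  nm <- conf_def$name
  if (is.null(mset$conformer_counts[[nm]])) {
    if (is.null(traj)) {
      stop("conformer counts for '", nm,
           "' not present; supply `traj` to compute them")
    }
    mset <- count_conformers_per_macrostate(mset, traj, conf_def)
  }
  obs <- which(mset$selectors$observed)
  list(idx = obs,
       n_snap = mset$selectors$n_snap[obs],
       n_conf = mset$conformer_counts[[nm]][obs])
}

#' Cumulative probability distribution of absolute deviations
#'
#' Empirical CDF of `|values|` together with its area under the curve (AUC)
#' over a fixed abscissa range. A larger AUC means the distribution is more
#' concentrated near zero, i.e. smaller deviations. To compare AUCs across
#' conditions (conformer definitions, trajectory sizes) evaluate all of them
#' over a shared `auc_range`.
#'
#' @param values numeric vector (signs are dropped).
#' @param auc_range upper end of the AUC abscissa `[0, auc_range]`; defaults to
#'   `max(abs(values))`.
#' @return object of class `cpd_curve`: sorted unique abscissae `x`, cumulative
#'   probabilities `p`, the `auc`, `auc_range`, and `n`.
#' @export
cpd <- function(values, auc_range = NULL) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  v <- sort(abs(values))
  x <- unique(v)
  p <- cumsum(tabulate(match(v, x), length(x))) / length(v)
  if (is.null(auc_range)) auc_range <- max(v)
  structure(list(x = x, p = p, n = length(v),
                 auc = .ecdf_auc(x, p, auc_range), auc_range = auc_range),
            class = "cpd_curve")
}

# area under the right-continuous empirical CDF on [0, upper]: on each
# segment between knots the CDF equals the cumulative probability at the
# left knot (exact step integral, i.e. the trapezoid rule on a step function)
.ecdf_auc <- function(x, p, upper) {
  if (upper < 0) stop("AUC range must be non-negative")
  if (upper == 0) return(0)
  keep <- which(x < upper)
  if (length(keep) == 0L) return(0)
  xs <- x[keep]
  ps <- p[keep]
  nxt <- pmin(c(xs[-1L], upper), upper)
  sum(ps * (nxt - xs))
}

#' @export
print.cpd_curve <- function(x, ...) {
  cat("<cpd_curve> n = ", x$n, ", AUC = ", format(x$auc),
      " over [0, ", format(x$auc_range), "]\n", sep = "")
  invisible(x)
}

#' Snapshot-count vs conformer-count scaling diagnostic
#'
#' Per observed macrostate, plots `-ln(N_snap / sum N_snap)` against
#' `-ln(N_conf / sum N_conf)` (both normalized over the macrostates in the set
#' so the axes are comparable) and fits an ordinary least-squares line. Under
#' ISWD the points fall on the identity line (slope 1, r-squared 1); conformer
#' saturation bends the heaviest macrostates below it.
#'
#' @inheritParams pairwise_ddF
#' @return object of class `scaling_fit`: `points` data frame
#'   (`neg_ln_nsnap`, `neg_ln_nconf`), `slope`, `intercept`, `r_squared`.
#' @export
scaling_data <- function(mset, conf_def, traj = NULL) {
  counts <- .macrostate_counts(mset, conf_def, traj)
  if (length(counts$idx) < 3L) stop("need at least 3 observed macrostates to fit")
  x <- -log(counts$n_snap / sum(counts$n_snap))
  y <- -log(counts$n_conf / sum(counts$n_conf))
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    stop("degenerate fit: snapshot counts are constant across macrostates")
  }
  fit <- lm(y ~ x)
  r2 <- if (max(y) - min(y) < .Machine$double.eps^0.5) 1 else cor(x, y)^2
  structure(
    list(points = data.frame(macrostate = counts$idx,
                             neg_ln_nsnap = x, neg_ln_nconf = y),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, conf_def_name = conf_def$name),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> ", x$conf_def_name, ": slope ", format(x$slope),
      ", intercept ", format(x$intercept), ", r^2 ", format(x$r_squared),
      "\n", sep = "")
  invisible(x)
}

#' Convergence trend of the ISWD deviation over nested trajectory subsets
#'
#' The qualitative ISWD diagnostic: for each conformer definition and each
#' nested (time-ordered prefix) subset of the trajectory, computes the |ddF|
#' CPD and its AUC over one shared abscissa range. For a definition with (an
#' approximation of) ISWD the deviations shrink as the trajectory grows, so the
#' AUC is non-decreasing ("shrinking"); for conformers with widely varying
#' statistical weights the deviations grow toward their converged values, so
#' the AUC decreases ("broadening").
#'
#' So that the same quantity is tracked across sizes, the pairwise comparison
#' is restricted to the macrostates already observed in the smallest subset
#' (nesting guarantees they stay observed); macrostates that only appear later
#' would otherwise change the composition of the pair ensemble between sizes
#' and confound the trend.
#'
#' @param traj a [dihedral_trajectory()].
#' @param conf_defs a [conformer_definition()] or list of them.
#' @param fractions increasing subset fractions in `(0, 1]` (at least two).
#' @param order_params,window_width passed to [build_macrostates()].
#' @param auc_range shared AUC range; default `max |ddF|` over all conditions.
#' @return object of class `convergence_trend`: a `table` data frame
#'   (`definition`, `fraction`, `n_snap`, `n_pairs`, `auc`), the shared
#'   `auc_range`, a named `classification` vector
#'   (`"shrinking"`/`"broadening"`/`"mixed"` per definition), and `abs_ddF`, a
#'   list of the raw |ddF| vectors per condition.
#' @export
convergence_trend <- function(traj, conf_defs, fractions,
                              order_params = seq_len(n_torsions(traj)),
                              window_width = 18, auc_range = NULL) {
  if (inherits(conf_defs, "conformer_definition")) conf_defs <- list(conf_defs)
  if (length(fractions) < 2L) {
    stop("need at least two subset fractions to assess a trend")
  }
  subsets <- nested_subsets(traj, fractions)
  defs <- vapply(conf_defs, function(d) d$name, character(1))
  common <- which(build_macrostates(subsets[[1]], order_params,
                                    window_width)$selectors$observed)
  if (length(common) < 2L) {
    stop("fewer than 2 macrostates observed in the smallest subset")
  }
  rows <- list()
  abs_vals <- list()
  for (s in seq_along(subsets)) {
    mset <- build_macrostates(subsets[[s]], order_params, window_width)
    for (d in seq_along(conf_defs)) {
      tab <- pairwise_ddF(mset, conf_defs[[d]], subsets[[s]])
      tab <- tab[tab$i %in% common & tab$j %in% common, ]
      key <- sprintf("%s@%g", defs[d], fractions[s])
      abs_vals[[key]] <- abs(tab$ddF)
      rows[[key]] <- data.frame(
        definition = defs[d], fraction = fractions[s],
        n_snap = n_snapshots(subsets[[s]]), n_pairs = nrow(tab)
      )
    }
  }
  if (is.null(auc_range)) auc_range <- max(unlist(abs_vals))
  table <- do.call(rbind, rows)
  table$auc <- vapply(rownames(table), function(k) {
    cpd(abs_vals[[k]], auc_range = auc_range)$auc
  }, numeric(1))
  rownames(table) <- NULL
  classification <- vapply(defs, function(d) {
    aucs <- table$auc[table$definition == d]
    dd <- diff(aucs)
    # relative tolerance: AUC changes far below the curve scale are ties
    tol <- 1e-6 * max(auc_range, .Machine$double.eps)
    if (all(dd >= -tol)) "shrinking"
    else if (all(dd <= tol)) "broadening"
    else "mixed"
  }, character(1))
  structure(list(table = table, auc_range = auc_range,
                 classification = classification, abs_ddF = abs_vals),
            class = "convergence_trend")
}

#' @export
print.convergence_trend <- function(x, ...) {
  cat("<convergence_trend> AUC over [0, ", format(x$auc_range), "]\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("classification:",
      paste(names(x$classification), x$classification, sep = ": ",
            collapse = "; "), "\n")
  invisible(x)
}
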