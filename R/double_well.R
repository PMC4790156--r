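#' Double-well potential specification
#'
#' A one-dimensional piecewise-constant potential with two wells of equal
#' width separated by a barrier: well A (energy 0) at the low end of the
#' domain, well B (energy `delta_U`) at the high end, and the region between
#' them at `barrier_height`. All energies in kT. This is the minimal
#' counterexample to naive conformer counting: any uniform discretization of x
#' occupies equally many cells in both wells, so the conformer-count free
#' energy is blind to `delta_U` while the population ratio
#' `N_B / N_A -> exp(-delta_U)` in the deep-well limit.
#'
#' @param delta_U energy of well B's bottom above well A's, kT.
#' @param well_width width of each well (equal widths) on the x coordinate.
#' @param barrier_height energy of the inter-well region, kT; must exceed
#'   `max(0, delta_U)`.
#' @param domain closed interval `c(lo, hi)` of the coordinate.
#' @return object of class `double_well_spec` with well intervals `well_A`,
#'   `well_B` attached.
#' @export
double_well_spec <- function(delta_U = 2, well_width = 0.35,
                             barrier_height = 12, domain = c(0, 1)) {
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("`domain` must be an interval c(lo, hi) with lo < hi")
  }
  if (well_width <= 0) stop("`well_width` must be positive")
  if (2 * well_width > diff(domain)) {
    stop("wells must be disjoint sub-intervals of the domain")
  }
  if (barrier_height <= max(0, delta_U)) {
    stop("`barrier_height` must exceed max(0, delta_U)")
  }
  structure(
    list(delta_U = delta_U, well_width = well_width,
         barrier_height = barrier_height, domain = domain,
         well_A = c(domain[1], domain[1] + well_width),
         well_B = c(domain[2] - well_width, domain[2])),
    class = "double_well_spec"
  )
}

#' @export
print.double_well_spec <- function(x, ...) {
  cat("<double_well_spec> delta_U = ", x$delta_U, " kT, well width ",
      x$well_width, ", barrier ", x$barrier_height, " kT on [",
      x$domain[1], ", ", x$domain[2], "]\n", sep = "")
  invisible(x)
}

#' Double-well potential energy
#'
#' @param spec a [double_well_spec()].
#' @param x coordinate values inside the domain.
#' @return potential energy in kT at each `x`.
#' @export
double_well_energy <- function(spec, x) {
  if (any(x < spec$domain[1] | x > spec$domain[2])) {
    stop("`x` outside the potential's domain")
  }
  u <- rep(spec$barrier_height, length(x))
  u[x < spec$well_A[2]] <- 0
  u[x >= spec$well_B[1]] <- spec$delta_U
  u
}

#' Sample the double-well Boltzmann distribution
#'
#' Exact sampling from the density proportional to `exp(-U(x))`: the potential
#' is piecewise constant, so the inverse CDF reduces to choosing a segment with
#' its exact Boltzmann mass and drawing uniformly within it. Deterministic
#' given `(spec, n, seed)`.
#'
#' @param spec a [double_well_spec()].
#' @param n number of samples (>= 1).
#' @param seed integer seed; the sampler neither consumes nor perturbs the
#'   caller's RNG stream.
#' @return object of class `dw_samples`: coordinates `x`, per-sample `label`
#'   (`"A"`, `"B"` or `"barrier"`), `energies` (kT, exactly `U(x)`), the `spec`
#'   and a `provenance` string.
#' @export
sample_double_well <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "double_well_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count")
  }
  n <- as.integer(n)
  lo <- spec$domain[1]; hi <- spec$domain[2]; w <- spec$well_width
  seg_lo <- c(lo, lo + w, hi - w)
  seg_hi <- c(lo + w, hi - w, hi)
  seg_u <- c(0, spec$barrier_height, spec$delta_U)
  mass <- (seg_hi - seg_lo) * exp(-seg_u)
  x <- with_seed(seed, {
    seg <- sample.int(3L, n, replace = TRUE, prob = mass)
    seg_lo[seg] + runif(n) * (seg_hi[seg] - seg_lo[seg])
  })
  label <- c("A", "barrier", "B")[1L + (x >= seg_lo[2]) + (x >= seg_lo[3])]
  structure(
    list(x = x, label = label, energies = double_well_energy(spec, x),
         spec = spec,
         provenance = sprintf("double_well(delta_U=%g) n=%d seed=%d sampler=inverse-cdf",
                              spec$delta_U, n, seed)),
    class = "dw_samples"
  )
}

#' ISWD failure diagnostic on the double well
#'
#' Discretizes the coordinate into `n_cells` uniform cells (the "conformers"),
#' takes the two wells as the macrostate pair and computes the snapshot-count
#' and conformer-count free energies and their deviation. The pair is oriented
#' from the shallow well B into the deep well A, so in the deep-well limit
#' `dF_snap -> -delta_U` while `dF_conf -> 0` (both wells occupy equally many
#' cells), hence `ddF -> -delta_U`: uniform discretization of this system
#' provably violates ISWD no matter how fine the cells.
#'
#' @param samples a [sample_double_well()] result.
#' @param n_cells number of uniform cells across the domain.
#' @return list with `n_A`, `n_B` (snapshot counts), `n_conf_A`, `n_conf_B`
#'   (occupied cells), `dF_snap`, `dF_conf`, `ddF` (kT, B -> A orientation).
#' @export
double_well_iswd <- function(samples, n_cells = 100L) {
  stopifnot(inherits(samples, "dw_samples"))
  if (n_cells < 2) stop("need at least 2 cells")
  dom <- samples$spec$domain
  cell <- pmin(1L + as.integer((samples$x - dom[1]) / diff(dom) * n_cells),
               as.integer(n_cells))
  in_A <- samples$label == "A"
  in_B <- samples$label == "B"
  if (!any(in_A) || !any(in_B)) stop("a well macrostate is empty")
  list(
    n_A = sum(in_A), n_B = sum(in_B),
    n_conf_A = count_unique(cell[in_A]), n_conf_B = count_unique(cell[in_B]),
    dF_snap = delta_F_snap(sum(in_B), sum(in_A)),
    dF_conf = delta_F_conf(count_unique(cell[in_B]), count_unique(cell[in_A])),
    ddF = delta_F_snap(sum(in_B), sum(in_A)) -
      delta_F_conf(count_unique(cell[in_B]), count_unique(cell[in_A]))
  )
}

# run an expression under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
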