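#' Torsional-state boundaries
#'
#' Three cut angles partitioning the circle into three arcs. Each arc is
#' half-open, `[cut_i, cut_{i+1})` with periodic wrap, so every angle belongs
#' to exactly one state and a boundary angle belongs to the arc whose left edge
#' it is. The default cuts `{-180, -60, 60}` trisect the circle into the
#' standard 120-degree rotameric arcs; `shift_boundaries()` produces the
#' +60-degree-shifted alternative set.
#'
#' @param cuts numeric vector of three distinct angles (degrees). Because each
#'   cut is the included left edge of its arc, cuts are canonicalized to
#'   `[-180, 180)` (a cut given as +180 is the same boundary as -180) and
#'   stored in ascending order, which fixes the 0/1/2 state labels.
#' @return object of class `torsion_state_boundaries`.
#' @examples
#' torsion_state_boundaries()                   # arcs [-180,-60) [-60,60) [60,180)
#' shift_boundaries(torsion_state_boundaries(), 60)
#' @export
torsion_state_boundaries <- function(cuts = c(-180, -60, 60)) {
  if (length(cuts) != 3L) stop("exactly three boundary cuts are required")
  cuts <- wrap_angle(cuts)
  cuts[cuts == 180] <- -180
  if (anyDuplicated(cuts)) stop("boundary cuts must be three distinct angles")
  structure(list(cuts = sort(cuts)), class = "torsion_state_boundaries")
}

#' @rdname torsion_state_boundaries
#' @param boundaries a `torsion_state_boundaries` object.
#' @param shift degrees to add to every cut.
#' @export
shift_boundaries <- function(boundaries, shift) {
  torsion_state_boundaries(boundaries$cuts + shift)
}

#' @export
print.torsion_state_boundaries <- function(x, ...) {
  cat("<torsion_state_boundaries> cuts at",
      paste0(format(x$cuts), "°", collapse = ", "), "\n")
  invisible(x)
}

#' Conformer definition
#'
#' A conformer is a joint assignment of torsional states (one of three arcs)
#' over an ordered subset of torsions; two snapshots belong to the same
#' conformer iff they share the torsional state of every selected torsion. A
#' definition over `k` torsions partitions configurational space into `3^k`
#' conformers (never materialized; only occupied ones are ever counted).
#'
#' @param torsion_subset integer vector of 1-based torsion indices (ordered,
#'   non-empty, unique).
#' @param boundaries a [torsion_state_boundaries()] object.
#' @param name identifier used in reports (e.g. `"CONF1"`).
#' @return object of class `conformer_definition`.
#' @export
conformer_definition <- function(torsion_subset,
                                 boundaries = torsion_state_boundaries(),
                                 name = "conformers") {
  torsion_subset <- as.integer(torsion_subset)
  if (length(torsion_subset) == 0L) stop("torsion subset must be non-empty")
  if (any(torsion_subset < 1L)) stop("torsion indices are 1-based")
  if (anyDuplicated(torsion_subset)) stop("torsion subset must not repeat indices")
  if (!inherits(boundaries, "torsion_state_boundaries")) {
    stop("`boundaries` must be a torsion_state_boundaries object")
  }
  structure(
    list(name = name, torsion_subset = torsion_subset, boundaries = boundaries,
         n_states_per_torsion = 3L),
    class = "conformer_definition"
  )
}

#' @export
print.conformer_definition <- function(x, ...) {
  k <- length(x$torsion_subset)
  cat("<conformer_definition> ", x$name, ": ", k, " torsions, 3^", k,
      " conformers\n", sep = "")
  invisible(x)
}

#' Assign torsional states
#'
#' Maps every (snapshot, torsion) angle to a torsional state in `{0, 1, 2}`.
#' The assignment depends only on the wrapped angle and the boundary cuts;
#' state labels follow boundary order.
#'
#' @param traj a [dihedral_trajectory()] or a numeric matrix of angles.
#' @param boundaries a [torsion_state_boundaries()] object.
#' @return integer matrix of states, same shape as the angle matrix.
#' @export
assign_torsional_states <- function(traj, boundaries = torsion_state_boundaries()) {
  a <- if (inherits(traj, "dihedral_trajectory")) traj$angles else
    matrix(wrap_angle(as.numeric(traj)), nrow(traj), ncol(traj))
  if (nrow(a) < 1L) stop("trajectory must be non-empty")
  cuts <- boundaries$cuts
  # rotate so cuts[1] is the origin; half-open arcs make the left edge sticky
  shifted <- (a - cuts[1]) %% 360
  s <- matrix(findInterval(shifted, c(cuts - cuts[1], 360),
                           rightmost.closed = FALSE) - 1L,
              nrow(a), ncol(a))
  storage.mode(s) <- "integer"
  colnames(s) <- colnames(a)
  s
}

#' Encode snapshots as conformer identifiers
#'
#' Encodes the torsional states over the definition's ordered torsion subset
#' into one identifier per snapshot. For subsets of up to 33 torsions the id is
#' the mixed-radix (base-3, least-significant-first) integer
#' `sum(state_j * 3^j)`, exactly representable as a double; for larger subsets
#' (3^k exceeds integer-exact doubles) the id is the packed state string, which
#' is equally sortable and comparable.
#'
#' @param states integer state matrix from [assign_torsional_states()], whose
#'   columns cover the definition's torsion subset.
#' @param conf_def a [conformer_definition()].
#' @return vector of ids (numeric or character), one per snapshot, with
#'   attributes `n_torsions` (subset size) and `encoding`.
#' @examples
#' def <- conformer_definition(1:3)
#' encode_conformers(matrix(c(0L, 1L, 2L), 1), def)  # 0*1 + 1*3 + 2*9 = 21
#' @export
encode_conformers <- function(states, conf_def) {
  subset <- conf_def$torsion_subset
  if (max(subset) > ncol(states)) {
    stop("state matrix does not cover torsion index ", max(subset))
  }
  s <- states[, subset, drop = FALSE]
  k <- length(subset)
  if (k <= 33L) {
    ids <- as.numeric(s %*% 3^(seq_len(k) - 1))
    encoding <- "base3"
  } else {
    ids <- do.call(paste0, as.data.frame(s))
    encoding <- "string"
  }
  attr(ids, "n_torsions") <- k
  attr(ids, "encoding") <- encoding
  ids
}

#' Decode conformer identifiers back to torsional states
#'
#' Inverse of [encode_conformers()]: `decode_conformer_ids(encode_conformers(s,
#' def), k)` recovers the state rows exactly.
#'
#' @param ids id vector from [encode_conformers()].
#' @param n_torsions subset size `k`; taken from the ids' attribute if absent.
#' @return integer state matrix with `k` columns.
#' @export
decode_conformer_ids <- function(ids, n_torsions = attr(ids, "n_torsions")) {
  if (is.null(n_torsions)) stop("`n_torsions` is required to decode")
  k <- as.integer(n_torsions)
  if (is.character(ids)) {
    s <- matrix(as.integer(unlist(strsplit(ids, "", fixed = TRUE))),
                length(ids), k, byrow = TRUE)
  } else {
    s <- matrix(0L, length(ids), k)
    rem <- as.numeric(ids)
    for (j in seq_len(k)) {
      s[, j] <- as.integer(rem %% 3)
      rem <- rem %/% 3
    }
  }
  s
}

#' Count distinct conformer identifiers
#'
#' The number of occupied conformers among a set of snapshots: ids are sorted
#' and runs are counted, so the result is independent of snapshot order and no
#' id space is ever allocated.
#'
#' @param ids id vector from [encode_conformers()] (numeric or character).
#' @return integer count of distinct ids.
#' @examples
#' count_unique(c(5, 5, 7))
#' @export
count_unique <- function(ids) {
  n <- length(ids)
  if (n == 0L) stop("cannot count conformers of an empty snapshot set")
  s <- sort(ids, method = "radix")
  sum(s[-1L] != s[-n]) + 1L
}
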