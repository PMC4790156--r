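#' Read a dihedral-angle table
#'
#' Reads a delimited text file (TSV or CSV, chosen by extension or `sep`) with
#' a header row naming the torsions; an optional `energy` column (any case) is
#' split off as per-snapshot potential energy. Lines starting with `#` are
#' provenance comments and are skipped. Angles are wrapped to `(-180, 180]`.
#' Malformed cells are reported with their line numbers.
#'
#' @param path file path.
#' @param sep field separator; default `\t` unless the file ends in `.csv`.
#' @return a [dihedral_trajectory()].
#' @export
read_dihedral_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  if (ncol(raw) < 1L) stop("missing header naming the torsions in ", path)
  vals <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow(raw), ncol(raw),
                 dimnames = list(NULL, colnames(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    # +1 header line; comment lines before the header would shift this, but
    # tables we write put all comments first, before the header
    n_comment <- length(grep("^#", readLines(path, n = 50L)))
    stop("non-numeric cell(s) in ", path, " at line(s) ",
         paste(unique(bad[, 1] + 1L + n_comment), collapse = ", "),
         " (column ", colnames(vals)[bad[1, 2]], ")")
  }
  is_energy <- tolower(colnames(vals)) == "energy"
  energies <- if (any(is_energy)) vals[, which(is_energy)[1]]
  dihedral_trajectory(vals[, !is_energy, drop = FALSE],
                      energies = energies, source = path)
}

#' Write a dihedral-angle table
#'
#' Writes the trajectory as delimited text with a header row of torsion labels,
#' an `energy` column when energies are present, and `#`-prefixed provenance
#' comment lines. Round-trips through [read_dihedral_table()].
#'
#' @param traj a [dihedral_trajectory()].
#' @param path output path (`.csv` switches to comma separation).
#' @param comments named character vector of extra provenance lines.
#' @return `path`, invisibly.
#' @export
write_dihedral_table <- function(traj, path, comments = character()) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- as.data.frame(traj$angles)
  if (!is.null(traj$energies)) out$energy <- traj$energies
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# source: %s", traj$source),
               sprintf("# %s: %s", names(comments), comments)), con)
  write.table(format(out, digits = 12, trim = TRUE, scientific = FALSE),
              con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract dihedral time series from MD trajectory files
#'
#' Optional adapter around the bio3d reader: loads a PDB topology and (if
#' given) a DCD coordinate trajectory, locates each torsion's four atoms by
#' name or index, and computes the dihedral with [dihedral_angle()]. The core
#' analysis consumes dihedral tables only, so this adapter is never required.
#'
#' @param topology path to a PDB file (also provides coordinates when
#'   `trajectory` is `NULL`, one frame per MODEL).
#' @param trajectory optional path to a DCD file.
#' @param torsions list of atom quadruples, each a character vector of four
#'   atom names or an integer vector of four atom indices.
#' @param labels optional torsion labels.
#' @return a [dihedral_trajectory()].
#' @export
extract_dihedrals_md <- function(topology, trajectory = NULL, torsions,
                                 labels = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("the MD adapter requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(topology, multi = is.null(trajectory))
  xyz <- if (is.null(trajectory)) pdb$xyz else bio3d::read.dcd(trajectory)
  xyz <- matrix(xyz, ncol = length(pdb$atom$elety) * 3L)
  resolve <- function(q) {
    if (is.numeric(q)) return(as.integer(q))
    idx <- match(q, pdb$atom$elety)
    if (anyNA(idx)) stop("atom(s) not found in topology: ",
                         paste(q[is.na(idx)], collapse = ", "))
    idx
  }
  angles <- vapply(torsions, function(q) {
    at <- resolve(q)
    if (length(at) != 4L) stop("each torsion needs exactly four atoms")
    co <- lapply(at, function(a) xyz[, 3L * (a - 1L) + 1:3, drop = FALSE])
    dihedral_angle(co[[1]], co[[2]], co[[3]], co[[4]])
  }, numeric(nrow(xyz)))
  angles <- matrix(angles, nrow(xyz), length(torsions))
  if (is.null(labels)) labels <- paste0("torsion", seq_along(torsions))
  dihedral_trajectory(angles, torsion_labels = labels,
                      source = paste0(topology,
                                      if (!is.null(trajectory)) paste0("+", trajectory)))
}

#' Reference lipid torsion definitions
#'
#' The 43 all-heavy-atom torsions of the POPC lipid (atom quadruples on the
#' standard atom names) used throughout the worked examples, read from the
#' table shipped with the package, plus the standard nested conformer-set
#' memberships over those torsions: `CONF1` uses all 43 torsions, `CONF2` a
#' listed 28-torsion subset, `CONF3` the 22 odd-numbered torsions and `CONF4`
#' the 15-torsion complement of `CONF2`. `CONF5`-`CONF8` reuse the same subsets
#' with the torsional-state boundaries shifted by +60 degrees.
#'
#' @return `popc_torsions()`: data frame with columns `index`, `atom1` ..
#'   `atom4`. `popc_conformer_sets()`: named list of
#'   [conformer_definition()]s `CONF1`-`CONF8`.
#' @export
popc_torsions <- function() {
  read.table(system.file("extdata", "popc_torsions.tsv", package = "confcount"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname popc_torsions
#' @export
popc_conformer_sets <- function() {
  conf2 <- c(2, 3, 5, 6, 8, 9, 11, 12, 14, 15, 17, 18, 20, 21, 23, 24, 26, 27,
             29, 30, 32, 33, 35, 36, 38, 39, 41, 42)
  subsets <- list(
    CONF1 = 1:43,
    CONF2 = conf2,
    CONF3 = seq(1, 43, by = 2),
    CONF4 = setdiff(1:43, conf2)
  )
  b0 <- torsion_state_boundaries()
  b60 <- shift_boundaries(b0, 60)
  defs <- c(
    lapply(names(subsets), function(nm) {
      conformer_definition(subsets[[nm]], b0, name = nm)
    }),
    lapply(seq_along(subsets), function(k) {
      conformer_definition(subsets[[k]], b60, name = paste0("CONF", k + 4L))
    })
  )
  names(defs) <- paste0("CONF", 1:8)
  defs
}
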