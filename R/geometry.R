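#' Read a protein structure from PDB
#'
#' Parses ATOM/HETATM records (via bio3d), keeping the first model and
#' altloc 'A' or blank, with insertion codes preserved. Returns a flat
#' atom table keyed by (chain, residue number, atom name).
#'
#' @param source Path to a PDB file.
#' @return An object of class `"amd_structure"`: a list with `atoms` (a
#'   data frame with `elety`, `resid`, `resno`, `chain`, `insert`, `x`,
#'   `y`, `z`) and `source`.
#' @export
read_pdb <- function(source) {
  pdb <- tryCatch(bio3d::read.pdb(source, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop_amd("format", paste0("cannot parse PDB: ",
                                              conditionMessage(e))))
  a <- pdb$atom
  alt <- a$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  a <- a[keep, , drop = FALSE]
  atoms <- data.frame(elety = a$elety, resid = a$resid, resno = a$resno,
                      chain = a$chain,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) |
          !is.finite(atoms$z))) {
    stop_amd("format", "non-finite coordinates in PDB")
  }
  structure(list(atoms = atoms, source = source), class = "amd_structure")
}

#' @export
print.amd_structure <- function(x, ...) {
  cat(sprintf("Structure from %s: %d atoms, %d residues, chains %s\n",
              x$source, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno,
                                  x$atoms$insert))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# resolve a (chain, resno, atom-name) triple to exactly one atom row
resolve_atom <- function(structure, sel) {
  a <- structure$atoms
  hit <- which(a$chain == sel$chain & a$resno == sel$resno &
                 a$elety == sel$elety &
                 (is.null(sel$insert) | a$insert == (sel$insert %||% "")))
  if (length(hit) != 1L) {
    stop_amd("selection", sprintf(
      "selection (chain %s, residue %s, atom %s) resolved to %d atoms",
      sel$chain, sel$resno, sel$elety, length(hit)))
  }
  hit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atom selections for reaction coordinates
#'
#' `atom_sel` names one atom by chain, residue number and atom name.
#' `distance_rc` pairs two such selections into a distance coordinate
#' (e.g. the ionic-lock Arg(3.50) CZ - Glu(6.30) CD distance, or the
#' Tyr(5.58) OH - Tyr(7.53) OH hydrogen-bond distance). `dihedral_rc`
#' strings four selections into a torsion coordinate.
#'
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @param elety Atom name (PDB convention, e.g. `"CZ"`, `"OH"`).
#' @param insert Insertion code (default any/blank).
#' @return An `"atom_sel"` / `"distance_rc"` / `"dihedral_rc"` object.
#' @export
atom_sel <- function(chain, resno, elety, insert = NULL) {
  structure(list(chain = chain, resno = resno, elety = elety,
                 insert = insert), class = "atom_sel")
}

#' @rdname atom_sel
#' @param a,b `atom_sel` selections.
#' @export
distance_rc <- function(a, b) {
  stopifnot(inherits(a, "atom_sel"), inherits(b, "atom_sel"))
  structure(list(a = a, b = b), class = "distance_rc")
}

#' @rdname atom_sel
#' @param sels A list of four `atom_sel` selections.
#' @param angle_name `"chi1"`, `"chi2"` or a custom label.
#' @export
dihedral_rc <- function(sels, angle_name = "custom") {
  stopifnot(length(sels) == 4L,
            all(vapply(sels, inherits, logical(1), "atom_sel")))
  key <- vapply(sels, function(s)
    paste(s$chain, s$resno, s$elety), character(1))
  if (anyDuplicated(key)) {
    stop_amd("parameter", "dihedral needs four distinct atoms")
  }
  structure(list(sels = sels, angle_name = angle_name),
            class = "dihedral_rc")
}

#' Distance between two selected atoms
#'
#' @param structure An `"amd_structure"` (or one frame of a frame source).
#' @param rc A [distance_rc()].
#' @return Euclidean distance in angstrom.
#' @export
atom_distance <- function(structure, rc) {
  stopifnot(inherits(rc, "distance_rc"))
  i <- resolve_atom(structure, rc$a)
  j <- resolve_atom(structure, rc$b)
  a <- structure$atoms
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking along the 2-3 bond, the angle is
#' positive for a clockwise rotation of the 3-4 bond relative to the 1-2
#' bond; returned in degrees in (-180, 180]. Invariant under rigid
#' rotation and translation; the sign flips under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))  # -90
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0) {
    stop_amd("geometry", "consecutive points coincide")
  }
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop_amd("geometry", "collinear points give an undefined dihedral")
  }
  m <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# dihedral for a dihedral_rc on a structure
structure_dihedral <- function(structure, rc) {
  a <- structure$atoms
  p <- lapply(rc$sels, function(s) {
    i <- resolve_atom(structure, s)
    c(a$x[i], a$y[i], a$z[i])
  })
  dihedral_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
}

#' Tryptophan chi1/chi2 selections (toggle switch)
#'
#' Builds the side-chain dihedral selections for a tryptophan residue
#' using the IUPAC atom definitions: chi1 = N-CA-CB-CG and chi2 =
#' CA-CB-CG-CD1 (the CD1/CD2 branch ambiguity of chi2 is resolved to
#' CD1, the community convention).
#'
#' @param structure An `"amd_structure"`.
#' @param resno Residue number of the tryptophan.
#' @param chain Chain identifier (default the first chain containing
#'   `resno`).
#' @return A list with `chi1` and `chi2` [dihedral_rc()] objects.
#' @export
trp_chi_selections <- function(structure, resno, chain = NULL) {
  a <- structure$atoms
  rows <- a[a$resno == resno &
              (if (is.null(chain)) TRUE else a$chain == chain), ,
            drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_amd("selection", sprintf("residue %s not found", resno))
  }
  ch <- chain %||% rows$chain[1L]
  rows <- rows[rows$chain == ch, , drop = FALSE]
  if (!all(rows$resid == "TRP")) {
    stop_amd("selection", sprintf("residue %s in chain %s is %s, not TRP",
                                  resno, ch, rows$resid[1L]))
  }
  need <- c("N", "CA", "CB", "CG", "CD1")
  missing <- setdiff(need, rows$elety)
  if (length(missing)) {
    stop_amd("selection", paste0("TRP residue lacks atom(s): ",
                                 paste(missing, collapse = ", ")))
  }
  sel <- function(el) atom_sel(ch, resno, el)
  list(chi1 = dihedral_rc(list(sel("N"), sel("CA"), sel("CB"), sel("CG")),
                          "chi1"),
       chi2 = dihedral_rc(list(sel("CA"), sel("CB"), sel("CG"),
                               sel("CD1")), "chi2"))
}

# frame sources --------------------------------------------------------

#' Trajectory frame source for reaction-coordinate extraction
#'
#' The adapter contract for molecular trajectories: a structure template
#' naming the atoms plus an `n_frames x n_atoms x 3` coordinate array
#' (any reader that yields named-atom coordinates — multi-model PDB,
#' bio3d's DCD reader, etc. — can be funnelled through this).
#'
#' @param template An `"amd_structure"` giving atom identities.
#' @param coords Numeric array `n_frames x n_atoms x 3` (defaults to the
#'   template's own coordinates as a single frame).
#' @param delta_v Optional per-frame boost energies.
#' @param dt Time between frames.
#' @return An object of class `"amd_frames"`.
#' @export
frame_source <- function(template, coords = NULL, delta_v = NULL, dt = 1) {
  stopifnot(inherits(template, "amd_structure"))
  if (is.null(coords)) {
    coords <- array(unlist(template$atoms[, c("x", "y", "z")]),
                    dim = c(1L, nrow(template$atoms), 3L))
    coords[1L, , ] <- as.matrix(template$atoms[, c("x", "y", "z")])
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != nrow(template$atoms)
      || dim(coords)[3L] != 3L) {
    stop_amd("input", "coords must be n_frames x n_atoms x 3")
  }
  if (!is.null(delta_v) && length(delta_v) != dim(coords)[1L]) {
    stop_amd("input", "delta_v length must match the number of frames")
  }
  structure(list(template = template, coords = coords, delta_v = delta_v,
                 dt = dt), class = "amd_frames")
}

#' Read a multi-model PDB as a trajectory frame source
#'
#' Each MODEL becomes one frame; atom identities come from the first
#' model.
#'
#' @param source Path to a multi-model PDB file.
#' @param dt Time between frames.
#' @return An [frame_source()] object.
#' @export
read_pdb_frames <- function(source, dt = 1) {
  pdb <- tryCatch(bio3d::read.pdb(source, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop_amd("format", paste0("cannot parse PDB: ",
                                              conditionMessage(e))))
  template <- read_pdb(source)
  xyz <- pdb$xyz
  keep <- is.na(pdb$atom$alt) | pdb$atom$alt == "" | pdb$atom$alt == "A"
  n_frames <- nrow(xyz)
  n_atoms <- sum(keep)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    coords[f, , ] <- m
  }
  frame_source(template, coords, dt = dt)
}

frame_structure <- function(frames, i) {
  s <- frames$template
  s$atoms$x <- frames$coords[i, , 1L]
  s$atoms$y <- frames$coords[i, , 2L]
  s$atoms$z <- frames$coords[i, , 3L]
  s
}

#' Extract a reaction-coordinate series from trajectory frames
#'
#' Evaluates a distance or dihedral coordinate on every `stride`-th frame
#' (frames 0, stride, 2 stride, ... in zero-based numbering). Per-frame
#' boost energies present in the source are carried through to the
#' series for reweighting.
#'
#' @param frames A [frame_source()] or a single `"amd_structure"`.
#' @param rc A [distance_rc()] or [dihedral_rc()].
#' @param stride Keep every `stride`-th frame (default 1).
#' @return An [rc_series()] (angstrom for distances; periodic degrees for
#'   dihedrals).
#' @export
extract_rc_series <- function(frames, rc, stride = 1L) {
  if (inherits(frames, "amd_structure")) {
    frames <- frame_source(frames)
  }
  stopifnot(inherits(frames, "amd_frames"))
  stride <- as.integer(stride)
  if (stride < 1L) stop_amd("parameter", "stride must be >= 1")
  pick <- seq(1L, dim(frames$coords)[1L], by = stride)
  vals <- vapply(pick, function(i) {
    st <- frame_structure(frames, i)
    tryCatch(
      if (inherits(rc, "distance_rc")) atom_distance(st, rc)
      else structure_dihedral(st, rc),
      amd_error = function(e)
        stop_amd("selection", sprintf("frame %d: %s", i - 1L,
                                      conditionMessage(e))))
  }, numeric(1))
  if (inherits(rc, "distance_rc")) {
    rc_series(vals, unit = "angstrom",
              delta_v = frames$delta_v[pick],
              stride = frames$dt * stride)
  } else {
    rc_series(vals, unit = "degrees", periodic = TRUE,
              delta_v = frames$delta_v[pick],
              stride = frames$dt * stride)
  }
}
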