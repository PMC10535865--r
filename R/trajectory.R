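# Multi-frame coordinate container with donor/acceptor annotations.
# Frames share one atom roster; coordinates are an n_atoms x 3 x n_frames
# array in Angstroms.

#' Construct a trajectory
#'
#' @param atoms data.frame describing the constant atom roster, with
#'   columns `serial` (unique integer), `name`, `residue` (label such as
#'   "E875", used for residue-level grouping), `role` (one of
#'   `"donor"`, `"acceptor"`, `"hydrogen"` or `NA`) and `parent`
#'   (for hydrogens: the serial of the donor heavy atom, else `NA`).
#' @param coords numeric array of dimension `c(nrow(atoms), 3, n_frames)`
#'   (Angstroms), or an `n x 3` matrix for a single frame.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords) {
  req <- c("serial", "name", "residue", "role", "parent")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("`atoms` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3 || dim(coords)[1] != nrow(atoms) ||
      dim(coords)[2] != 3) {
    stop("`coords` must be an n_atoms x 3 x n_frames array")
  }
  check_finite(as.numeric(coords), "coords")
  bad <- atoms$role[!is.na(atoms$role)]
  if (!all(bad %in% c("donor", "acceptor", "hydrogen"))) {
    stop("`role` must be donor, acceptor, hydrogen or NA")
  }
  h <- atoms[!is.na(atoms$role) & atoms$role == "hydrogen", ]
  if (any(is.na(h$parent)) || !all(h$parent %in% atoms$serial)) {
    stop("every hydrogen must name its donor heavy atom in `parent`")
  }
  structure(list(atoms = atoms, coords = coords,
                 n_frames = dim(coords)[3]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames\n",
              nrow(x$atoms), x$n_frames))
  invisible(x)
}

#' Frame coordinates
#'
#' @param traj a [trajectory()].
#' @param frame frame index (1-based).
#' @return `n x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 1 || frame > traj$n_frames) stop("frame index out of range")
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Thin wrapper over [bio3d::read.pdb()] (`multi = TRUE`): each MODEL
#' becomes one frame. Donor/acceptor annotations are not present in PDB
#' files; supply them as a data.frame with columns `serial` and `role`
#' (`"donor"`, `"acceptor"`, or `"hydrogen-of:<serial>"`), e.g. from
#' [read_annotation_csv()].
#'
#' @param path PDB file with ATOM/HETATM records.
#' @param annotations optional annotation data.frame.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, annotations = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  n <- nrow(at)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    residue = paste0(at$resid, at$resno),
    role = NA_character_, parent = NA_integer_
  )
  if (!is.null(annotations)) atoms <- apply_annotations(atoms, annotations)
  trajectory(atoms, coords)
}

# merge a serial/role annotation table into an atom roster
apply_annotations <- function(atoms, ann) {
  if (!all(c("serial", "role") %in% names(ann))) {
    stop("annotations need columns `serial` and `role`")
  }
  unknown <- setdiff(ann$serial, atoms$serial)
  if (length(unknown)) {
    stop("annotation serials not in the atom roster: ",
         paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(ann))) {
    j <- match(ann$serial[i], atoms$serial)
    role <- ann$role[i]
    if (grepl("^hydrogen-of:", role)) {
      atoms$role[j] <- "hydrogen"
      atoms$parent[j] <- as.integer(sub("^hydrogen-of:", "", role))
    } else if (role %in% c("donor", "acceptor")) {
      atoms$role[j] <- role
    } else {
      stop("unknown annotation role: ", role)
    }
  }
  h <- atoms[!is.na(atoms$role) & atoms$role == "hydrogen", ]
  if (!all(h$parent %in% atoms$serial)) {
    stop("hydrogen annotation references a serial not in the roster")
  }
  atoms
}
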