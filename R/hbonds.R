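# Geometric hydrogen-bond detection and occupancy bookkeeping.
# A bond is recorded when the donor-acceptor distance is below the
# cut-off (3.5 A) and the donor-hydrogen-acceptor angle exceeds the
# angular cut-off (120 deg) for at least one hydrogen on the donor.

vdist <- function(a, b) sqrt(sum((a - b)^2))

# angle at H between H->D and H->A, degrees
dha_angle <- function(d, h, a) {
  u <- d - h
  v <- a - h
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' Tests every annotated donor against every annotated acceptor (self
#' pairs and acceptors on the donor's own residue are skipped). A pair
#' is bonded when distance(donor, acceptor) < `distance_cutoff` and, for
#' at least one hydrogen attached to the donor, the
#' donor-hydrogen-acceptor angle > `angle_cutoff`. Set
#' `angle_def = "none"` for a distance-only criterion.
#'
#' @param traj a [trajectory()] with donor/hydrogen/acceptor roles.
#' @param frame frame index.
#' @param distance_cutoff donor-acceptor distance cut-off (Angstrom).
#' @param angle_cutoff angle cut-off (degrees), applied to the
#'   donor-hydrogen-acceptor angle.
#' @param angle_def `"dha"` (default) applies the angular criterion;
#'   `"none"` uses the distance criterion alone.
#' @return data.frame with one row per bond: donor/acceptor serials and
#'   residues, donor-acceptor distance `distance_da`,
#'   hydrogen-acceptor distance `distance_ha` and the angle of the best
#'   hydrogen.
#' @export
detect_hbonds <- function(traj, frame = 1, distance_cutoff = 3.5,
                          angle_cutoff = 120,
                          angle_def = c("dha", "none")) {
  stopifnot(inherits(traj, "trajectory"))
  angle_def <- match.arg(angle_def)
  xyz <- frame_coords(traj, frame)
  at <- traj$atoms
  don <- which(!is.na(at$role) & at$role == "donor")
  acc <- which(!is.na(at$role) & at$role == "acceptor")
  hyd <- which(!is.na(at$role) & at$role == "hydrogen")

  out <- list()
  for (d in don) {
    hs <- hyd[at$parent[hyd] == at$serial[d]]
    if (angle_def == "dha" && !length(hs)) {
      stop("donor ", at$serial[d], " has no annotated hydrogen")
    }
    for (a in acc) {
      if (a == d || at$residue[a] == at$residue[d]) next
      dda <- vdist(xyz[d, ], xyz[a, ])
      if (dda >= distance_cutoff) next
      if (angle_def == "none") {
        out[[length(out) + 1L]] <- data.frame(
          donor_serial = at$serial[d], acceptor_serial = at$serial[a],
          donor_residue = at$residue[d], acceptor_residue = at$residue[a],
          distance_da = dda, distance_ha = NA_real_, angle = NA_real_)
        next
      }
      best <- NULL
      for (h in hs) {
        ang <- dha_angle(xyz[d, ], xyz[h, ], xyz[a, ])
        if (ang > angle_cutoff && (is.null(best) || ang > best$angle)) {
          best <- list(angle = ang, dha = vdist(xyz[h, ], xyz[a, ]))
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          donor_serial = at$serial[d], acceptor_serial = at$serial[a],
          donor_residue = at$residue[d], acceptor_residue = at$residue[a],
          distance_da = dda, distance_ha = best$dha, angle = best$angle)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_serial = integer(), acceptor_serial = integer(),
                      donor_residue = character(),
                      acceptor_residue = character(),
                      distance_da = numeric(), distance_ha = numeric(),
                      angle = numeric()))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Atom-pair occupancy is the percentage of frames in which that
#' donor-acceptor pair is bonded (0-100%). With
#' `grouping = "residue"`, atom-pair occupancies are summed per
#' donor-residue/acceptor-residue pair, so a residue donating through
#' two atoms in every frame reports 200% -- the convention under which
#' published per-residue occupancies exceed 100%. Records below
#' `min_occupancy` are suppressed from the default report (set it to 0
#' to keep everything). The mean and SD of the hydrogen-acceptor
#' distance are taken over the bonded frames.
#'
#' @param traj a [trajectory()].
#' @param grouping `"atom"` (donor atom/acceptor atom pairs) or
#'   `"residue"` (summed per residue pair).
#' @param min_occupancy suppression threshold in percent (default 30).
#' @inheritParams detect_hbonds
#' @return data.frame with the pair labels, `occupancy` (%),
#'   `distance_mean` and `distance_sd` (Angstrom), sorted by decreasing
#'   occupancy.
#' @export
hbond_occupancy <- function(traj, grouping = c("atom", "residue"),
                            min_occupancy = 30, distance_cutoff = 3.5,
                            angle_cutoff = 120,
                            angle_def = c("dha", "none")) {
  stopifnot(inherits(traj, "trajectory"))
  grouping <- match.arg(grouping)
  angle_def <- match.arg(angle_def)
  if (traj$n_frames < 1) stop("empty trajectory")

  bonds <- lapply(seq_len(traj$n_frames), function(f) {
    b <- detect_hbonds(traj, f, distance_cutoff, angle_cutoff, angle_def)
    if (nrow(b)) b$frame <- f
    b
  })
  bonds <- do.call(rbind, bonds[vapply(bonds, nrow, integer(1)) > 0])

  empty <- data.frame(donor = character(), acceptor = character(),
                      occupancy = numeric(), distance_mean = numeric(),
                      distance_sd = numeric())
  if (is.null(bonds) || !nrow(bonds)) return(empty)

  key <- paste(bonds$donor_serial, bonds$acceptor_serial, sep = "->")
  dist_val <- if (angle_def == "none") bonds$distance_da else bonds$distance_ha
  per_atom <- do.call(rbind, lapply(split(seq_len(nrow(bonds)), key), function(i) {
    b <- bonds[i, ]
    data.frame(
      donor_serial = b$donor_serial[1], acceptor_serial = b$acceptor_serial[1],
      donor_residue = b$donor_residue[1], acceptor_residue = b$acceptor_residue[1],
      occupancy = 100 * nrow(b) / traj$n_frames,
      distance_mean = mean(dist_val[i]),
      distance_sd = if (length(i) > 1) stats::sd(dist_val[i]) else 0)
  }))

  if (grouping == "atom") {
    out <- data.frame(
      donor = paste0(per_atom$donor_residue, ":", per_atom$donor_serial),
      acceptor = paste0(per_atom$acceptor_residue, ":",
                        per_atom$acceptor_serial),
      occupancy = per_atom$occupancy,
      distance_mean = per_atom$distance_mean,
      distance_sd = per_atom$distance_sd)
  } else {
    rkey <- paste(per_atom$donor_residue, per_atom$acceptor_residue,
                  sep = "->")
    out <- do.call(rbind, lapply(split(seq_len(nrow(per_atom)), rkey),
                                 function(i) {
      p <- per_atom[i, ]
      w <- p$occupancy / sum(p$occupancy)
      data.frame(donor = p$donor_residue[1], acceptor = p$acceptor_residue[1],
                 occupancy = sum(p$occupancy),
                 distance_mean = sum(w * p$distance_mean),
                 distance_sd = sqrt(sum(w * (p$distance_sd^2 +
                                               p$distance_mean^2)) -
                                      sum(w * p$distance_mean)^2))
    }))
  }
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond count per frame
#'
#' Counts bonds in every frame (distance-only criterion by default, the
#' convention used when monitoring bond counts along a simulation) and
#' returns the sample mean and SD.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param cutoff donor-acceptor distance cut-off (Angstrom).
#' @param angle_def `"none"` (default) counts by distance alone;
#'   `"dha"` also applies the angular criterion.
#' @param angle_cutoff angle cut-off when `angle_def = "dha"`.
#' @return list with `mean`, `sd` and the integer vector `counts`.
#' @export
hbond_count_series <- function(traj, cutoff = 3.5,
                               angle_def = c("none", "dha"),
                               angle_cutoff = 120) {
  stopifnot(inherits(traj, "trajectory"))
  angle_def <- match.arg(angle_def)
  if (traj$n_frames < 2) stop("at least 2 frames are required")
  counts <- vapply(seq_len(traj$n_frames), function(f) {
    nrow(detect_hbonds(traj, f, cutoff, angle_cutoff, angle_def))
  }, integer(1))
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
}
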