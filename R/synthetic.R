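# Seeded generators emulating the statistical structure of each assay,
# with machine-readable ground truth attached so round-trip tests need
# no hard-coded numbers. Every generator is a pure function of its
# arguments (seed included).

#' Generate a synthetic THP uptake trace
#'
#' Simulates the uptake assay under the standard protocol (1 uM drug
#' added to 2e6 cells in 2 mL at t = 0, sampled at 1 Hz for 2000 s,
#' detergent step at 1600 s) and adds i.i.d. Gaussian noise to the
#' intensities. The true parameters and the noise-free pool
#' concentrations are attached as ground truth.
#'
#' @param params a [transport_params()] object (the ground truth).
#' @param conditions an [assay_conditions()] object.
#' @param noise_sd Gaussian noise SD in intensity units (the default
#'   0.5 equals 0.5% of the default F0 span of 100).
#' @param seed integer seed.
#' @param t_end,dt trace duration and sampling interval (s).
#' @param permeabilization_time detergent step time (s) or NULL.
#' @param f0_scale net fluorescence span at t = 0.
#' @return a [fluorescence_trace()]; attribute `"truth"` holds the
#'   parameters, conditions and noise-free concentrations.
#' @export
gen_uptake_trace <- function(params = transport_params(),
                             conditions = assay_conditions(),
                             noise_sd = 0.5, seed = 1,
                             t_end = 2000, dt = 1,
                             permeabilization_time = 1600,
                             f0_scale = 100) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  tr <- simulate_uptake(params, conditions,
                        times = seq(0, t_end, by = dt),
                        permeabilization_time = permeabilization_time,
                        f0_scale = f0_scale)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    tr$intensities <- pmax(tr$intensities +
                             stats::rnorm(length(tr$intensities),
                                          sd = noise_sd), 0)
  }
  attr(tr, "truth") <- list(params = params, conditions = conditions,
                            concentrations = attr(tr, "concentrations"),
                            noise_sd = noise_sd, seed = seed)
  tr
}

#' Generate a synthetic dose-response table
#'
#' Hill-model viabilities with replicate Gaussian noise. Default truth
#' mirrors a resistant-line anthracycline response (IC50 4.54 uM over a
#' 0.05-10 uM dose range plus the zero-dose anchor).
#'
#' @param ic50,hill,top,bottom true Hill parameters.
#' @param doses dose vector (must include 0).
#' @param replicates replicates per dose.
#' @param noise_sd Gaussian SD in viability points.
#' @param seed integer seed.
#' @return data.frame with columns `dose`, `replicate`, `viability`;
#'   attribute `"truth"` holds the generating parameters.
#' @export
gen_dose_response <- function(ic50 = 4.54, hill = 1.2, top = 100,
                              bottom = 0,
                              doses = c(0, exp(seq(log(0.05), log(10),
                                                   length.out = 7))),
                              replicates = 3, noise_sd = 5, seed = 1) {
  if (length(unique(doses)) < 4) stop("at least 4 distinct doses")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), dose = doses)
  q <- ifelse(grid$dose == 0, 0, (grid$dose / ic50)^hill)
  v <- bottom + (top - bottom) / (1 + q)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  out <- data.frame(dose = grid$dose, replicate = grid$replicate,
                    viability = v)
  attr(out, "truth") <- list(ic50 = ic50, hill = hill, top = top,
                             bottom = bottom, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate synthetic per-frame MM-GBSA component tables
#'
#' Draws per-frame component energies around the configured means
#' (independent Gaussians per component and frame) for several replica
#' copies. Defaults give the scale of a large polyphenol bound in a
#' polar site: strong van der Waals and electrostatic attraction offset
#' by polar solvation.
#'
#' @param means named vector with `e_vdw`, `e_elect`, `g_polar`,
#'   `g_nonpolar` (kcal/mol).
#' @param sds per-frame SDs in the same order.
#' @param n_frames frames per replica (>= 2).
#' @param n_replicas number of replica copies (>= 1).
#' @param temperature temperature (K) used for the implied
#'   interaction-entropy truth.
#' @param seed integer seed.
#' @return data.frame `replica`/`frame`/components; attribute `"truth"`
#'   holds the configured means and the per-replica -TdS implied by the
#'   drawn E_int series.
#' @export
gen_energy_frames <- function(means = c(e_vdw = -85.5, e_elect = -87.6,
                                        g_polar = 115.2,
                                        g_nonpolar = -14.2),
                              sds = c(e_vdw = 3, e_elect = 5,
                                      g_polar = 6, g_nonpolar = 0.5),
                              n_frames = 1000, n_replicas = 3,
                              temperature = 310, seed = 1) {
  req <- c("e_vdw", "e_elect", "g_polar", "g_nonpolar")
  if (!all(req %in% names(means)) || !all(req %in% names(sds))) {
    stop("`means` and `sds` need components ", paste(req, collapse = ", "))
  }
  if (n_frames < 2) stop("`n_frames` must be >= 2")
  if (n_replicas < 1) stop("`n_replicas` must be >= 1")
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_replicas), function(r) {
    df <- data.frame(replica = paste0("rep", r), frame = seq_len(n_frames))
    for (cm in req) {
      df[[cm]] <- means[[cm]] + stats::rnorm(n_frames, sd = sds[[cm]])
    }
    df
  }))
  ie <- vapply(split(out, out$replica), function(df) {
    interaction_entropy(df$e_vdw + df$e_elect, temperature)
  }, numeric(1))
  attr(out, "truth") <- list(means = means, sds = sds,
                             minus_tds = ie, temperature = temperature,
                             seed = seed)
  out
}

#' Generate a toy trajectory with a planted hydrogen-bond schedule
#'
#' Builds a schematic multi-frame structure in which each scheduled
#' donor-acceptor pair is geometrically bonded (donor-acceptor 2.8 A,
#' donor-H-acceptor angle 170 deg) exactly in the frames listed for it
#' and open (4.5 A) elsewhere, with coordinate jitter of at most
#' `jitter` Angstrom. Pairs are spaced 12 A apart so they never
#' cross-bond. The atom roster is constant across frames.
#'
#' @param pairs list of pairs; each element is a list with
#'   `donor_res` (residue label, e.g. "E875"), `acceptor_res` (e.g.
#'   "PGG") and `bonded_frames` (integer frame indices).
#' @param n_frames number of frames.
#' @param jitter maximum per-atom displacement (Angstrom, < 0.3 to
#'   preserve the planted geometry).
#' @param seed integer seed.
#' @return a [trajectory()]; attribute `"truth"` holds the schedule and
#'   the implied per-pair occupancies.
#' @export
gen_toy_trajectory <- function(pairs, n_frames = 100, jitter = 0.05,
                               seed = 1) {
  if (!length(pairs)) stop("at least one donor-acceptor pair is required")
  if (jitter < 0 || jitter >= 0.3) stop("`jitter` must be in [0, 0.3)")
  for (p in pairs) {
    if (!all(c("donor_res", "acceptor_res", "bonded_frames") %in% names(p))) {
      stop("each pair needs donor_res, acceptor_res and bonded_frames")
    }
    if (length(p$bonded_frames) &&
        (min(p$bonded_frames) < 1 || max(p$bonded_frames) > n_frames)) {
      stop("bonded_frames outside 1..n_frames")
    }
  }
  np <- length(pairs)
  atoms <- do.call(rbind, lapply(seq_len(np), function(i) {
    s0 <- (i - 1L) * 3L
    data.frame(
      serial = s0 + 1:3,
      name = c("D", "H", "A"),
      residue = c(pairs[[i]]$donor_res, pairs[[i]]$donor_res,
                  pairs[[i]]$acceptor_res),
      role = c("donor", "hydrogen", "acceptor"),
      parent = c(NA_integer_, s0 + 1L, NA_integer_)
    )
  }))

  # closed-form positions: D at origin, H 1 A along x; bonded acceptor
  # 2.8 A from D with a 170 deg D-H-A angle, open acceptor at 4.5 A
  a_bonded <- c(2.783, 0.315, 0)
  a_open <- c(4.5, 0, 0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jmax <- jitter / sqrt(3)
  coords <- array(0, c(nrow(atoms), 3, n_frames))
  for (i in seq_len(np)) {
    off <- c(12 * (i - 1), 0, 0)
    r <- (i - 1L) * 3L
    bonded <- seq_len(n_frames) %in% pairs[[i]]$bonded_frames
    for (f in seq_len(n_frames)) {
      coords[r + 1L, , f] <- off
      coords[r + 2L, , f] <- off + c(1, 0, 0)
      a <- if (bonded[f]) a_bonded else a_open
      coords[r + 3L, , f] <- off + a +
        stats::runif(3, -jmax, jmax)
    }
  }
  traj <- trajectory(atoms, coords)
  occ <- vapply(pairs, function(p) {
    100 * length(unique(p$bonded_frames)) / n_frames
  }, numeric(1))
  attr(traj, "truth") <- list(pairs = pairs, occupancy = occ,
                              n_frames = n_frames, seed = seed)
  traj
}

# Save/restore the global RNG state so generators are pure functions of
# their seed without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
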