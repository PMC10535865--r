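# Shared fixtures and independent oracles used across the test files.

default_conditions <- function() assay_conditions()

# Independent steady-state oracle: solves the stationarity equations of
# the pre-permeabilization transport model by root-finding on the
# cytosolic pool (C_e = (1 + k_act/k_plus) C_c from the C_e equation,
# C_n Langmuir in C_c from the C_n equation, closure by mass balance).
steady_state_oracle <- function(params, conditions) {
  rho <- conditions$cell_density
  c_t <- conditions$total_drug
  kd <- params$k_off / params$k_on
  ratio <- 1 + params$k_act / params$k_plus
  g <- function(cc) {
    ratio * cc + cc + params$b_max * cc / (cc + kd) - c_t
  }
  cc <- stats::uniroot(g, c(1e-12, c_t), tol = 1e-12)$root
  c(C_e = ratio * cc, C_c = cc,
    C_n = params$b_max * cc / (cc + kd))
}

# Rotation-grid brute-force RMSD oracle: coarse search over ZYZ Euler
# angles followed by a Nelder-Mead polish, entirely independent of the
# SVD-based superposition.
euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

rmsd_grid_oracle <- function(ref, mob) {
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  obj <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mobc %*% t(r) - refc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  bgrid <- seq(0, pi, length.out = 7)
  best <- c(0, 0, 0)
  bestv <- obj(best)
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < bestv) {
      bestv <- v
      best <- c(a, b, c)
    }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# random rigid motion of a coordinate set
rigid_motion <- function(x, seed = 1) {
  set.seed(seed)
  r <- euler_rot(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                 stats::runif(1, 0, 2 * pi))
  sweep(x %*% t(r), 2, stats::rnorm(3, sd = 5), `+`)
}

# hand-built three-atom donor/hydrogen/acceptor frame for geometric
# hydrogen-bond cases; acceptor position chosen by d(D,A) and the
# D-H-A angle (donor at origin, hydrogen 1 A along +x)
hbond_frame <- function(d_da, angle_dha) {
  theta <- (180 - angle_dha) * pi / 180   # direction of H->A from +x
  # solve |H + t u - D| = d_da with H = (1,0,0), u unit
  u <- c(cos(theta), sin(theta), 0)
  tt <- (-2 * u[1] + sqrt(4 * u[1]^2 + 4 * (d_da^2 - 1))) / 2
  a <- c(1, 0, 0) + tt * u
  atoms <- data.frame(serial = 1:3, name = c("D", "H", "A"),
                      residue = c("E875", "E875", "PGG"),
                      role = c("donor", "hydrogen", "acceptor"),
                      parent = c(NA, 1L, NA))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), a)
  trajectory(atoms, coords)
}
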