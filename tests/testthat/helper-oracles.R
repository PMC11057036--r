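# Independent oracles and small deterministic generators used across tests.

# Direct Coulomb lattice sum over complete cubic shells of periodic images.
# Returns the cumulative energy after each shell (kJ/mol). Converges for
# charge-neutral cells; fixtures are built dipole-free so the shell sums
# approach the tinfoil (Ewald) limit.
direct_coulomb_energy <- function(pos, q, L, nshell = 20) {
  ke <- 138.935458
  n <- nrow(pos)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  dvec <- pos[ij$i, , drop = FALSE] - pos[ij$j, , drop = FALSE]
  qq <- q[ij$i] * q[ij$j]
  same <- ij$i == ij$j
  cum <- numeric(nshell + 1)
  e <- 0
  for (s in 0:nshell) {
    cells <- as.matrix(expand.grid(ix = -s:s, iy = -s:s, iz = -s:s))
    keep <- apply(abs(cells), 1L, max) == s
    cells <- cells[keep, , drop = FALSE] * L
    if (s == 0) {
      d <- sqrt(rowSums(dvec^2))
      e <- e + 0.5 * sum(qq[!same] / d[!same])
    } else {
      for (ci in seq_len(nrow(cells))) {
        d <- sqrt((dvec[, 1] + cells[ci, 1])^2 +
                  (dvec[, 2] + cells[ci, 2])^2 +
                  (dvec[, 3] + cells[ci, 3])^2)
        e <- e + 0.5 * sum(qq / d)
      }
    }
    cum[s + 1] <- e
  }
  ke * cum
}

# Richardson-style tail estimate: average the last few shell sums to damp
# the oscillating quadrupole tail
direct_coulomb_extrapolate <- function(cum, k = 4) {
  mean(utils::tail(cum, k))
}

# dipole-free random charge configuration: pairs of antiparallel +/- dipoles
# (net charge 0, net dipole 0), positions from a deterministic LCG
dipole_free_config <- function(n_dipoles, L, d = 0.08, seed = 1) {
  rng <- local({
    s <- seed
    function() {
      s <<- (s * 48271) %% 2147483647
      s / 2147483647
    }
  })
  pos <- NULL
  q <- numeric(0)
  for (k in seq_len(n_dipoles)) {
    a <- c(rng(), rng(), rng()) * L
    u <- c(rng(), rng(), rng()) * 2 - 1
    u <- u / sqrt(sum(u^2))
    b <- c(rng(), rng(), rng()) * L
    # dipole at a along +u, mirrored dipole at b along -u
    pos <- rbind(pos, a, a + d * u, b, b - d * u)
    q <- c(q, 1, -1, 1, -1)
  }
  list(pos = pos, q = q)
}

# place point charges of a species list at given positions (identity
# orientation) inside an existing system state
place_points <- function(state, pos) {
  state$com <- unname(as.matrix(pos))
  state$quat <- matrix(rep(c(1, 0, 0, 0), nrow(pos)), ncol = 4, byrow = TRUE)
  state
}

# Boltzmann pair-distance density for two particles in a periodic cube,
# restricted to r < L/2 where the shell volume is the full 4 pi r^2
lj_pair_dist_oracle <- function(r, L, epsilon, sigma, T, rc) {
  u <- ifelse(r < rc, 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6), 0)
  w <- r^2 * exp(-u / ecsmc::kBT(T))
  w / stats::integrate(function(x) {
    ux <- ifelse(x < rc, 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6), 0)
    x^2 * exp(-ux / ecsmc::kBT(T))
  }, 0, L / 2, rel.tol = 1e-10)$value
}
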