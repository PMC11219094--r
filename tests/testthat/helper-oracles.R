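# Independent oracles used across the test suite. These deliberately do
# not share code with the package's vectorized engine: plain double
# loops, scalar arithmetic, and textbook formulas only.

# Plain (non-alchemical) energy of one physical endstate of a hybrid:
# atoms of the other endstate's dummies removed, endstate parameters
# used directly, Coulomb (optionally erfc-screened) + LJ over included
# pairs, plus bonds of the matching endstate tags and site restraints.
oracle_endstate_energy <- function(hybrid, positions, endstate = c("old", "new"),
                                   params = energy_params()) {
  endstate <- match.arg(endstate)
  at <- as.data.frame(hybrid$atoms)
  drop_class <- if (endstate == "old") "unique_new" else "unique_old"
  keep <- at$atom_class != drop_class
  qcol <- paste0("charge_", endstate)
  scol <- paste0("sigma_", endstate)
  ecol <- paste0("epsilon_", endstate)
  excl <- hybrid$exclusions
  excl_key <- if (nrow(excl)) paste(excl[, 1], excl[, 2]) else character(0)
  C <- params$coulomb_constant
  e_nb <- 0
  idx <- at$index[keep]
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]
      j <- idx[b]
      if (paste(min(i, j), max(i, j)) %in% excl_key) next
      r <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      if (is.finite(params$cutoff) && r > params$cutoff) next
      scr <- if (params$use_plain_coulomb) 1 else erfc_oracle(params$alpha_pme * r)
      e_nb <- e_nb + C * at[[qcol]][at$index == i] * at[[qcol]][at$index == j] *
        scr / r
      sij <- (at[[scol]][at$index == i] + at[[scol]][at$index == j]) / 2
      eij <- sqrt(at[[ecol]][at$index == i] * at[[ecol]][at$index == j])
      x6 <- (sij / r)^6
      e_nb <- e_nb + 4 * eij * x6 * (x6 - 1)
    }
  }
  tags <- c("shared", endstate)
  e_val <- 0
  v <- as.data.frame(hybrid$valence)
  for (t in seq_len(nrow(v))) {
    if (!(v$endstate_tag[t] %in% tags)) next
    if (v$type[t] != "bond") stop("oracle only handles bonds")
    r <- sqrt(sum((positions[v$i[t], ] - positions[v$j[t], ])^2))
    e_val <- e_val + 0.5 * v$p1[t] * (r - v$p2[t])^2
  }
  e_site <- 0
  s <- hybrid$site_restraints
  if (!is.null(s) && nrow(s)) {
    for (t in seq_len(nrow(s))) {
      d <- positions[s$atom[t], ] - c(s$x0[t], s$y0[t], s$z0[t])
      e_site <- e_site + 0.5 * s$k[t] * sum(d^2)
    }
  }
  e_nb + e_val + e_site
}

erfc_oracle <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

# dummy valence energy of one endstate's unique atoms (tagged bonds only)
oracle_dummy_valence <- function(hybrid, positions, tag) {
  v <- as.data.frame(hybrid$valence)
  e <- 0
  for (t in seq_len(nrow(v))) {
    if (v$endstate_tag[t] != tag) next
    r <- sqrt(sum((positions[v$i[t], ] - positions[v$j[t], ])^2))
    e <- e + 0.5 * v$p1[t] * (r - v$p2[t])^2
  }
  e
}

# Bennett acceptance ratio for two states from forward/reverse work
# values, solved from the implicit equation with uniroot.
oracle_bar <- function(w_f, w_r) {
  M <- log(length(w_f) / length(w_r))
  uniroot(
    function(df) {
      sum(1 / (1 + exp(M + w_f - df))) - sum(1 / (1 + exp(-M + w_r + df)))
    },
    c(-100, 100),
    tol = 1e-14
  )$root
}

# Analytic mean swap acceptance between two 1-D harmonic states with
# spring constants k1, k2 (beta = 1), by 2-D Gauss quadrature:
# E[min(1, exp(-(k1 - k2)(x2^2 - x1^2)/2))] with x1 ~ N(0, 1/k1),
# x2 ~ N(0, 1/k2).
oracle_swap_acceptance <- function(k1, k2, n_grid = 400) {
  gh <- function(k) {
    x <- seq(-8 / sqrt(k), 8 / sqrt(k), length.out = n_grid)
    w <- dnorm(x, 0, 1 / sqrt(k))
    w <- w / sum(w)
    list(x = x, w = w)
  }
  g1 <- gh(k1)
  g2 <- gh(k2)
  acc <- 0
  for (a in seq_len(n_grid)) {
    d <- 0.5 * (k1 - k2) * (g2$x^2 - g1$x[a]^2)
    acc <- acc + g1$w[a] * sum(g2$w * pmin(1, exp(-d)))
  }
  acc
}

# Signed dihedral via an independent vector-algebra route (projection
# onto the plane normal to the central bond).
oracle_dihedral <- function(p1, p2, p3, p4) {
  cx <- function(a, b) {
    c(
      a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  b2 <- p3 - p2
  b2 <- b2 / sqrt(sum(b2^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  v2 <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  ang <- atan2(sum(cx(v1, v2) * b2), sum(v1 * v2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

# Synthetic archives built from exact harmonic sampling (K states of a
# harmonic ladder; replicas pinned to their states). `centers2` gives
# the per-iteration sampling center of state 2, enabling planted
# nonstationarity.
make_harmonic_archive <- function(n_iter, springs = c(1, 4),
                                  centers2 = rep(0, n_iter), seed = 1) {
  set.seed(seed)
  K <- length(springs)
  u_kln <- array(NA_real_, c(K, K, n_iter))
  for (n in seq_len(n_iter)) {
    for (k in seq_len(K)) {
      c_k <- if (k == 2) centers2[n] else 0
      x <- rnorm(1, c_k, 1 / sqrt(springs[k]))
      u_kln[k, , n] <- 0.5 * springs * x^2
    }
  }
  structure(
    list(
      u_kln = u_kln,
      state_trace = matrix(rep(seq_len(K), n_iter), n_iter, K, byrow = TRUE),
      du_dl = matrix(rnorm(n_iter * K), n_iter, K),
      dof_traces = list(),
      dof_categories = character(0),
      acceptance = list(
        attempts = matrix(0L, K, K), accepts = matrix(0L, K, K)
      ),
      meta = list(schema = "alchemforge-archive-1", K = K, seed = seed)
    ),
    class = "simulation_archive"
  )
}

# Fake ddG objects with given kcal/mol value and CI, for verdict tests.
fake_ddg <- function(ddg_kcal, ci_kcal) {
  structure(
    list(
      ddg = kcal_to_kt(ddg_kcal), sigma = kcal_to_kt(diff(ci_kcal)) / 3.92,
      ci95 = kcal_to_kt(ci_kcal),
      ddg_kcal_mol = ddg_kcal,
      sigma_kcal_mol = diff(ci_kcal) / 3.92,
      temperature = 300
    ),
    class = "delta_delta_g"
  )
}

# Small fixture systems reused across files
fixture_chain <- function(wt = "ALA", mut = "THR", phase = "apo", seed = 2,
                          n_residues = 3, site = 2) {
  build_toy_system(
    make_bead_residue_chain(n_residues, site, wt, mut, seed = seed),
    phase = phase
  )
}

random_positions <- function(hybrid, seed, scale = 0.05) {
  set.seed(seed)
  hybrid$positions0 +
    matrix(rnorm(length(hybrid$positions0), sd = scale),
      nrow(hybrid$positions0), 3
    )
}
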