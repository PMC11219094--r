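#' Replica-exchange sampler configuration
#'
#' All quantities are in reduced units: energies in kT at the reference
#' temperature, masses 1, so the thermal velocity scale is 1.
#'
#' @param n_iterations Number of MD + exchange cycles.
#' @param md_steps_per_iteration Langevin steps between exchange blocks.
#' @param timestep Integrator timestep (reduced time).
#' @param friction Langevin friction (1/reduced time).
#' @param seed Integer seed; the whole run is bit-reproducible given the
#'   seed and configuration.
#' @param swap_attempts_per_iteration Number of pair-swap proposals per
#'   exchange block; defaults to K^3 ("many swaps", enough to approximate
#'   an independent permutation draw).
#' @param restraint Optional heavy-atom restraint:
#'   `list(force_constant = , heavy_atoms_only = TRUE)` with the force
#'   constant in kT/nm^2 (see [kcal_per_A2_to_kt_per_nm2()]); atoms are
#'   restrained to the initial conformation.
#' @param record_interval Record every this many iterations.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_iterations = 200, md_steps_per_iteration = 10,
                           timestep = 0.005, friction = 5, seed = 1L,
                           swap_attempts_per_iteration = NULL,
                           restraint = NULL, record_interval = 1L) {
  stopifnot(
    n_iterations >= 1, md_steps_per_iteration >= 0, timestep > 0,
    friction > 0, record_interval >= 1
  )
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      md_steps_per_iteration = as.integer(md_steps_per_iteration),
      timestep = timestep, friction = friction, seed = as.integer(seed),
      swap_attempts_per_iteration = swap_attempts_per_iteration,
      restraint = restraint, record_interval = as.integer(record_interval)
    ),
    class = "sampler_config"
  )
}

#' Convert a restraint force constant from kcal/(mol A^2) to kT/nm^2
#'
#' @param k Force constant in kcal/(mol Angstrom^2).
#' @param temperature Reference temperature (K).
#' @export
kcal_per_A2_to_kt_per_nm2 <- function(k, temperature = 300) {
  k * 100 / kt_kcal(temperature)
}

#' Wrap a hybrid topology as a replica-exchange system
#'
#' Produces the state-indexed reduced-potential/force interface the
#' sampler consumes: state k is the alchemical (and, with `rest_cfg`, the
#' REST-scaled) Hamiltonian at lambda_k. The REST region and interaction
#' classification are fixed from the initial conformation.
#'
#' @param hybrid A `hybrid_topology`.
#' @param protocol A [build_lambda_protocol()].
#' @param params An [energy_params()].
#' @param rest_cfg Optional [rest_config()] (AREST); `NULL` gives AREX.
#' @param dofs Optional named list of degree-of-freedom extractors, each
#'   `list(fn = function(positions) scalar, category = <string>)`.
#' @param restraint Optional heavy-atom restraint spec (see
#'   [sampler_config()]); adds harmonic site terms at `positions0`.
#' @return A `replica_system`.
#' @export
replica_system_from_hybrid <- function(hybrid, protocol,
                                       params = energy_params(),
                                       rest_cfg = NULL, dofs = NULL,
                                       restraint = NULL) {
  if (!is.null(restraint)) {
    at <- hybrid$atoms
    sel <- if (isTRUE(restraint$heavy_atoms_only)) at$is_heavy else TRUE
    extra <- tibble::tibble(
      atom = at$index[sel],
      x0 = hybrid$positions0[at$index[sel], 1],
      y0 = hybrid$positions0[at$index[sel], 2],
      z0 = hybrid$positions0[at$index[sel], 3],
      k = restraint$force_constant
    )
    hybrid$site_restraints <- dplyr::bind_rows(hybrid$site_restraints, extra)
  }
  region <- NULL
  if (!is.null(rest_cfg)) {
    region <- select_rest_region(hybrid$positions0, hybrid, rest_cfg$radius)
  }
  ce <- compile_hybrid_energy(hybrid, params,
    rest_region = region, rest_config = rest_cfg
  )
  lambdas <- protocol$lambdas
  structure(
    list(
      kind = "hybrid", K = protocol$n_states, lambdas = lambdas,
      u = function(x, k) eval_compiled_energy(ce, x, lambdas[k]),
      force = function(x, k) eval_compiled_forces(ce, x, lambdas[k]),
      dudl = function(x, k) {
        du_dlambda_compiled(ce, x, lambdas[k], params$dl)
      },
      dofs = dofs, x0 = hybrid$positions0,
      rest = rest_cfg, rest_region = region, hybrid = hybrid
    ),
    class = c("hybrid_replica_system", "replica_system")
  )
}

#' Relax a configuration by gradient descent
#'
#' Backtracking steepest descent on the reduced potential of one state;
#' used to remove steric clashes from the deterministic initial layouts
#' before Langevin sampling.
#'
#' @param system A `replica_system`.
#' @param state State index whose potential is minimized.
#' @param positions Starting coordinates (defaults to the system's
#'   initial conformation).
#' @param max_iter Iteration cap.
#' @param tol Stop when the maximum force component falls below this.
#' @return The relaxed coordinate matrix.
#' @export
minimize_positions <- function(system, state = 1, positions = system$x0,
                               max_iter = 500, tol = 50) {
  u <- system$u(positions, state)
  step <- 1e-5
  for (it in seq_len(max_iter)) {
    f <- system$force(positions, state)
    fmax <- max(abs(f))
    if (fmax < tol) break
    # cap the displacement so clashes relax without overshooting
    trial_step <- min(step, 0.02 / fmax)
    repeat {
      xn <- positions + trial_step * f
      un <- tryCatch(system$u(xn, state), error = function(e) Inf)
      if (is.finite(un) && un <= u) break
      trial_step <- trial_step / 2
      if (trial_step < 1e-14) {
        return(positions)
      }
    }
    positions <- xn
    u <- un
    step <- trial_step * 2
  }
  positions
}

#' Langevin (BAOAB) propagation under one state's potential
#'
#' @param positions Coordinate matrix.
#' @param system A `replica_system`.
#' @param state State index (1-based).
#' @param md_steps Number of steps.
#' @param config A [sampler_config()].
#' @param velocities Optional velocity matrix (resampled from the
#'   Maxwell-Boltzmann distribution when `NULL`).
#' @return List with `positions` and `velocities`.
#' @export
propagate <- function(positions, system, state, md_steps, config,
                      velocities = NULL) {
  d <- dim(positions)
  if (is.null(velocities)) {
    velocities <- matrix(stats::rnorm(prod(d)), d[1], d[2])
  }
  if (md_steps == 0) {
    return(list(positions = positions, velocities = velocities))
  }
  dt <- config$timestep
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(1 - c1^2) # kT = 1, m = 1
  f <- system$force(positions, state)
  for (s in seq_len(md_steps)) {
    velocities <- velocities + 0.5 * dt * f
    positions <- positions + 0.5 * dt * velocities
    velocities <- c1 * velocities +
      c2 * matrix(stats::rnorm(prod(d)), d[1], d[2])
    positions <- positions + 0.5 * dt * velocities
    f <- system$force(positions, state)
    velocities <- velocities + 0.5 * dt * f
    if (any(!is.finite(f)) || any(!is.finite(positions))) {
      stop(
        "propagation diverged (NaN/Inf) at step ", s,
        "; state ", state, "; max|x| = ",
        format(max(abs(positions[is.finite(positions)]), 0)),
        call. = FALSE
      )
    }
  }
  list(positions = positions, velocities = velocities)
}

#' Log acceptance ratio for exchanging two replicas' state labels
#'
#' Metropolis criterion for swapping the alchemical state labels s_i and
#' s_j of replicas i and j: log R = -(u_si(x_j) + u_sj(x_i) - u_si(x_i)
#' - u_sj(x_j)); the swap is accepted with probability min(1, exp(log
#' R)).
#'
#' @param s_i,s_j Current state indices of the two replicas (1-based).
#' @param u_row_i,u_row_j Reduced potentials of replica i (resp. j)
#'   evaluated at every state (length-K vectors).
#' @return Log acceptance ratio.
#' @export
swap_log_ratio <- function(s_i, s_j, u_row_i, u_row_j) {
  -(u_row_i[s_j] + u_row_j[s_i] - u_row_i[s_i] - u_row_j[s_j])
}

#' Gibbs-sample a new state permutation
#'
#' Attempts `n_attempts` uniformly random pair swaps of state labels,
#' each accepted by [swap_log_ratio()]; with many attempts this
#' approximates an independent draw of the permutation given the current
#' positions, which leaves the extended-ensemble joint distribution
#' invariant.
#'
#' @param state_indices Current permutation (1-based state per replica).
#' @param u_matrix K x K matrix, `u_matrix[k, l]` = reduced potential of
#'   replica k at state l.
#' @param n_attempts Number of proposals (>= 1); default K^3.
#' @return List with `state_indices` (new permutation) and `pair_stats`
#'   (tibble of per-state-pair attempts and accepts).
#' @export
gibbs_permute <- function(state_indices, u_matrix,
                          n_attempts = length(state_indices)^3) {
  K <- length(state_indices)
  if (K == 1) {
    return(list(
      state_indices = state_indices,
      pair_stats = tibble::tibble(
        s_a = integer(0), s_b = integer(0),
        attempts = integer(0), accepts = integer(0)
      )
    ))
  }
  if (n_attempts < 1) stop("n_attempts must be >= 1", call. = FALSE)
  att <- matrix(0L, K, K)
  acc <- matrix(0L, K, K)
  # draw all randomness up front (vectorized)
  a_all <- sample.int(K, n_attempts, replace = TRUE)
  b_all <- sample.int(K - 1, n_attempts, replace = TRUE)
  b_all <- ifelse(b_all >= a_all, b_all + 1L, b_all)
  log_u <- log(stats::runif(n_attempts))
  s <- state_indices
  for (t in seq_len(n_attempts)) {
    a <- a_all[t]
    b <- b_all[t]
    sa <- s[a]
    sb <- s[b]
    lo <- min(sa, sb)
    hi <- max(sa, sb)
    att[lo, hi] <- att[lo, hi] + 1L
    lr <- -(u_matrix[a, sb] + u_matrix[b, sa] -
      u_matrix[a, sa] - u_matrix[b, sb])
    if (log_u[t] < lr) {
      s[a] <- sb
      s[b] <- sa
      acc[lo, hi] <- acc[lo, hi] + 1L
    }
  }
  ix <- which(att > 0, arr.ind = TRUE)
  list(
    state_indices = s,
    pair_stats = tibble::tibble(
      s_a = ix[, 1], s_b = ix[, 2],
      attempts = att[ix], accepts = acc[ix]
    )
  )
}

#' Run AREX/AREST replica exchange
#'
#' Alternates Langevin propagation of the K replicas (each under the
#' Hamiltonian of its current alchemical state) with Gibbs-sampled
#' permutation of the state labels, recording reduced-potential matrices,
#' the replica-to-state trace, dU/dlambda, and any registered
#' degree-of-freedom observables. Deterministic given the seed.
#'
#' @param system A `replica_system` (e.g.
#'   [replica_system_from_hybrid()] or a built toy).
#' @param config A [sampler_config()].
#' @param x0 Optional list of per-replica starting coordinate matrices
#'   (defaults to the system's initial conformation for every replica).
#' @param minimize_start Relax each replica's starting coordinates under
#'   its own state's potential before sampling. Strongly recommended for
#'   hybrid systems: a conformation relaxed at one endstate can leave the
#'   other endstate's dummy atoms clashing, and the replica at that state
#'   would start from an astronomically strained configuration.
#' @return A `simulation_archive`.
#' @export
run_replica_exchange <- function(system, config, x0 = NULL,
                                 minimize_start = FALSE) {
  K <- system$K
  set.seed(config$seed)
  n_att <- config$swap_attempts_per_iteration
  if (is.null(n_att)) n_att <- K^3
  X <- if (is.null(x0)) replicate(K, system$x0, simplify = FALSE) else x0
  if (minimize_start) {
    X <- lapply(seq_len(K), function(k) {
      minimize_positions(system, k, X[[k]])
    })
  }
  V <- lapply(X, function(x) {
    matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  })
  s <- seq_len(K)
  rec_iters <- seq(
    config$record_interval, config$n_iterations,
    by = config$record_interval
  )
  n_rec <- length(rec_iters)
  u_kln <- array(NA_real_, c(K, K, n_rec))
  state_trace <- matrix(NA_integer_, n_rec, K)
  du_dl <- matrix(NA_real_, n_rec, K)
  dof_names <- names(system$dofs)
  dof_traces <- stats::setNames(
    replicate(length(dof_names), matrix(NA_real_, n_rec, K),
      simplify = FALSE
    ),
    dof_names
  )
  att_tot <- matrix(0L, K, K)
  acc_tot <- matrix(0L, K, K)
  r <- 0L
  for (it in seq_len(config$n_iterations)) {
    for (k in seq_len(K)) {
      out <- propagate(
        X[[k]], system, s[k], config$md_steps_per_iteration,
        config, V[[k]]
      )
      X[[k]] <- out$positions
      V[[k]] <- out$velocities
    }
    u_mat <- matrix(0, K, K)
    for (k in seq_len(K)) {
      for (l in seq_len(K)) u_mat[k, l] <- system$u(X[[k]], l)
    }
    if (any(!is.finite(u_mat))) {
      stop("non-finite reduced potential at iteration ", it, call. = FALSE)
    }
    gp <- gibbs_permute(s, u_mat, n_att)
    s <- gp$state_indices
    if (nrow(gp$pair_stats)) {
      ps <- gp$pair_stats
      for (q in seq_len(nrow(ps))) {
        att_tot[ps$s_a[q], ps$s_b[q]] <- att_tot[ps$s_a[q], ps$s_b[q]] +
          ps$attempts[q]
        acc_tot[ps$s_a[q], ps$s_b[q]] <- acc_tot[ps$s_a[q], ps$s_b[q]] +
          ps$accepts[q]
      }
    }
    if (it %in% rec_iters) {
      r <- r + 1L
      u_kln[, , r] <- u_mat
      state_trace[r, ] <- s
      for (k in seq_len(K)) {
        du_dl[r, k] <- system$dudl(X[[k]], s[k])
        for (nm in dof_names) {
          dof_traces[[nm]][r, k] <- system$dofs[[nm]]$fn(X[[k]])
        }
      }
    }
  }
  structure(
    list(
      u_kln = u_kln, state_trace = state_trace, du_dl = du_dl,
      dof_traces = dof_traces,
      dof_categories = vapply(
        system$dofs, function(d) d$category, character(1)
      ),
      acceptance = list(attempts = att_tot, accepts = acc_tot),
      meta = list(
        schema = "alchemforge-archive-1",
        K = K, lambdas = system$lambdas, seed = config$seed,
        n_iterations = config$n_iterations,
        md_steps_per_iteration = config$md_steps_per_iteration,
        timestep = config$timestep, friction = config$friction,
        record_interval = config$record_interval,
        rest = !is.null(system$rest), kind = system$kind
      )
    ),
    class = "simulation_archive"
  )
}

#' @export
print.simulation_archive <- function(x, ...) {
  cat(
    "<simulation_archive> K =", x$meta$K, "states,",
    dim(x$u_kln)[3], "recorded iterations\n"
  )
  if (length(x$dof_traces)) {
    cat("  DOF traces:", paste(names(x$dof_traces), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Empirical replica-mixing statistics
#'
#' Builds the row-stochastic empirical state-transition matrix from the
#' replica-to-state trace, its subdominant eigenvalue (a mixing-time
#' proxy), and a bottleneck flag raised when any adjacent-state exchange
#' rate falls below `floor` or the observed transition graph is
#' disconnected.
#'
#' @param state_trace n x K integer matrix of state indices per recorded
#'   iteration (rows) and replica (columns).
#' @param floor Minimum acceptable adjacent-state transition rate.
#' @return List with `transition_matrix`, `subdominant_eigenvalue`,
#'   `adjacent_rates`, `bottleneck`.
#' @export
mixing_statistics <- function(state_trace, floor = 0.01) {
  if (nrow(state_trace) < 2) {
    stop("need at least 2 recorded iterations", call. = FALSE)
  }
  K <- max(state_trace)
  C <- matrix(0, K, K)
  for (k in seq_len(ncol(state_trace))) {
    from <- state_trace[-nrow(state_trace), k]
    to <- state_trace[-1, k]
    for (t in seq_along(from)) C[from[t], to[t]] <- C[from[t], to[t]] + 1
  }
  rs <- rowSums(C)
  TM <- C / ifelse(rs == 0, 1, rs)
  TM[rs == 0, ] <- 0
  diag(TM)[rs == 0] <- 1
  ev <- sort(abs(eigen(TM, only.values = TRUE)$values), decreasing = TRUE)
  sub <- if (length(ev) > 1) ev[2] else 0
  adj <- if (K > 1) {
    vapply(seq_len(K - 1), function(k) {
      tot <- rs[k] + rs[k + 1]
      if (tot == 0) {
        return(0)
      }
      (C[k, k + 1] + C[k + 1, k]) / tot
    }, numeric(1))
  } else {
    numeric(0)
  }
  # connectivity of the undirected observed-transition graph
  A <- (C + t(C)) > 0
  diag(A) <- TRUE
  reach <- rep(FALSE, K)
  reach[1] <- TRUE
  repeat {
    new <- reach | apply(A[, reach, drop = FALSE], 1, any)
    if (all(new == reach)) break
    reach <- new
  }
  bottleneck <- any(adj < floor) || !all(reach)
  list(
    transition_matrix = TM, subdominant_eigenvalue = sub,
    adjacent_rates = adj, bottleneck = bottleneck
  )
}

#' Serialize / restore a simulation archive
#'
#' JSON container with the logical groups u_kln, state_trace, du_dl,
#' dof/<name>, meta; schema version `alchemforge-archive-1`.
#' [export_archive_csv()] additionally writes one CSV per trace.
#'
#' @param archive A `simulation_archive`.
#' @param path File path (JSON) or directory (CSV export).
#' @return The path, invisibly; `read_archive` returns the archive.
#' @export
write_archive <- function(archive, path) {
  obj <- list(
    schema = "alchemforge-archive-1",
    dims = dim(archive$u_kln),
    u_kln = as.numeric(archive$u_kln),
    state_trace = archive$state_trace,
    du_dl = archive$du_dl,
    dof = archive$dof_traces,
    dof_categories = as.list(archive$dof_categories),
    acceptance = archive$acceptance,
    meta = archive$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "alchemforge-archive-1")) {
    stop("unrecognized archive schema", call. = FALSE)
  }
  dof <- lapply(obj$dof, as.matrix)
  structure(
    list(
      u_kln = array(obj$u_kln, obj$dims),
      state_trace = {
        m <- as.matrix(obj$state_trace)
        storage.mode(m) <- "integer"
        m
      },
      du_dl = as.matrix(obj$du_dl),
      dof_traces = dof,
      dof_categories = unlist(obj$dof_categories),
      acceptance = lapply(obj$acceptance, as.matrix),
      meta = obj$meta
    ),
    class = "simulation_archive"
  )
}

#' @rdname write_archive
#' @export
export_archive_csv <- function(archive, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(archive$state_trace,
    file.path(path, "state_trace.csv"),
    row.names = FALSE
  )
  utils::write.csv(archive$du_dl,
    file.path(path, "du_dl.csv"),
    row.names = FALSE
  )
  for (nm in names(archive$dof_traces)) {
    utils::write.csv(archive$dof_traces[[nm]],
      file.path(path, paste0("dof_", nm, ".csv")),
      row.names = FALSE
    )
  }
  invisible(path)
}
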