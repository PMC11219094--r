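#' Reduced-potential dataset for MBAR
#'
#' Pools samples from all states: `u_kn[k, n]` is the reduced potential
#' of pooled sample n evaluated at state k, and `n_k[k]` counts the
#' samples generated at state k (sum over k equals the number of
#' columns).
#'
#' @param u_kn K x N matrix of reduced potentials.
#' @param n_k Length-K integer vector of per-state sample counts.
#' @param origin_state Optional length-N vector giving the generating
#'   state of each column (used by the state-blocked bootstrap).
#' @param decorrelation_g Optional per-state statistical inefficiencies
#'   recorded for provenance.
#' @return A `reduced_potential_dataset`.
#' @export
reduced_potential_dataset <- function(u_kn, n_k, origin_state = NULL,
                                      decorrelation_g = NULL) {
  u_kn <- as.matrix(u_kn)
  if (sum(n_k) != ncol(u_kn)) {
    stop("sum(n_k) must equal the number of pooled samples", call. = FALSE)
  }
  if (any(!is.finite(u_kn))) stop("u_kn must be finite", call. = FALSE)
  structure(
    list(
      u_kn = u_kn, n_k = as.integer(n_k), origin_state = origin_state,
      decorrelation_g = decorrelation_g
    ),
    class = "reduced_potential_dataset"
  )
}

#' Solve the MBAR self-consistent equations
#'
#' Multistate Bennett acceptance ratio estimate of the per-state reduced
#' free energies f_k (f_1 = 0), by damped self-consistent iteration on
#' the log-sum-exp form of the estimating equations.
#'
#' @param dataset A [reduced_potential_dataset()] (or a bare matrix with
#'   `n_k` supplied).
#' @param n_k Sample counts when `dataset` is a bare matrix.
#' @param tol Max-norm convergence tolerance on f.
#' @param max_iter Iteration cap; non-convergence is an error carrying
#'   the residual.
#' @return Numeric vector f_k of reduced free energies, f_1 = 0.
#' @export
#' @examples
#' # two identical states: delta f is 0
#' u <- matrix(rnorm(200)^2 / 2, nrow = 2, ncol = 100, byrow = TRUE)
#' mbar_solve(reduced_potential_dataset(u, c(50, 50)))
mbar_solve <- function(dataset, n_k = NULL, tol = 1e-10, max_iter = 5000) {
  if (inherits(dataset, "reduced_potential_dataset")) {
    u_kn <- dataset$u_kn
    n_k <- dataset$n_k
  } else {
    u_kn <- as.matrix(dataset)
  }
  stopifnot(tol > 0)
  K <- nrow(u_kn)
  if (K == 1) {
    return(0)
  }
  if (any(n_k <= 0)) {
    stop("every state must contribute samples", call. = FALSE)
  }
  N <- ncol(u_kn)
  logN <- log(n_k)
  f <- numeric(K) # start at zero; Newton acceleration takes it from there
  # one damped self-consistent sweep; returns the updated f
  scf_step <- function(f) {
    a <- logN + f # length K
    # log denominator per sample: logsumexp_l (logN_l + f_l - u_ln)
    m <- apply(a - u_kn, 2, max)
    log_denom <- m + log(colSums(exp(a - u_kn -
      matrix(m, K, N, byrow = TRUE))))
    w <- -u_kn - matrix(log_denom, K, N, byrow = TRUE)
    mw <- apply(w, 1, max)
    f_new <- -(mw + log(rowSums(exp(w - mw))))
    f_new - f_new[1]
  }
  # gradient and Hessian of the MBAR convex objective
  # F(f) = sum_n log sum_l N_l exp(f_l - u_ln) - sum_k N_k f_k
  grad_hess <- function(f) {
    a <- logN + f
    m <- apply(a - u_kn, 2, max)
    log_denom <- m + log(colSums(exp(a - u_kn -
      matrix(m, K, N, byrow = TRUE))))
    W <- exp(f - u_kn - matrix(log_denom, K, N, byrow = TRUE)) # K x N
    NW <- n_k * W
    g <- rowSums(NW) - n_k
    H <- -NW %*% t(NW)
    # diagonal: N_k sum_n W_nk - sum_n (N_k W_nk)^2
    diag(H) <- rowSums(NW) - rowSums(NW^2)
    list(g = g, H = H)
  }
  # SCF warm-up, then Newton with SCF fallback when a step misbehaves.
  # With very large reduced potentials (steric clashes evaluated at
  # foreign states) the attainable precision of f is limited by floating
  # point; iteration is stopped once the residual stalls just above tol.
  delta <- Inf
  best_delta <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    f_scf <- scf_step(f)
    if (it > 5 && it %% 3 == 0) {
      gh <- grad_hess(f_scf)
      step <- tryCatch(
        solve(gh$H[-1, -1, drop = FALSE], gh$g[-1]),
        error = function(e) NULL
      )
      f_new <- f_scf
      if (!is.null(step) && all(is.finite(step))) {
        cand <- f_scf
        cand[-1] <- cand[-1] - step
        # accept the Newton step only if it reduces the gradient norm
        if (sum(grad_hess(cand)$g^2) < sum(gh$g^2)) f_new <- cand
      }
    } else {
      f_new <- f_scf
    }
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      return(f)
    }
    if (delta < best_delta * 0.5) {
      best_delta <- delta
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= 50L && delta < 1e3 * tol) {
      return(f) # stagnated at the floating-point noise floor
    }
    if (!all(is.finite(f)) || max(abs(f)) > 1e8) {
      # a state block with (near-)zero overlap: f runs away; fail fast
      stop("MBAR diverging: a state contributes no overlapping samples",
        call. = FALSE
      )
    }
  }
  stop(sprintf(
    "MBAR failed to converge in %d iterations (residual %.3g)",
    max_iter, delta
  ), call. = FALSE)
}

#' Subsample a series (or sample matrix) at the decorrelation stride
#'
#' Keeps indices 1, 1 + ceil(g), 1 + 2 ceil(g), ... For matrices the
#' columns are taken as samples.
#'
#' @param x Numeric vector or matrix (samples in columns).
#' @param g Statistical inefficiency in samples, >= 1.
#' @return Subsampled vector/matrix (at least 2 samples, else an error).
#' @export
subsample_decorrelated <- function(x, g) {
  stopifnot(g >= 1)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  idx <- seq(1, n, by = ceiling(g))
  if (length(idx) < 2) {
    stop("decorrelation stride leaves fewer than 2 samples", call. = FALSE)
  }
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
}

#' Bootstrap uncertainty of the MBAR free energy difference
#'
#' Resamples pooled columns with replacement within each generating-state
#' block and re-solves MBAR for each replicate. A failed replicate is
#' retried once, then dropped with a warning.
#'
#' @param dataset A (decorrelated) [reduced_potential_dataset()] with
#'   `origin_state` set.
#' @param n_boot Number of bootstrap replicates (200 by default).
#' @param seed Seed for the resampling.
#' @return List with `sigma` (sample sd of the delta-f replicates),
#'   `ci95` (2.5/97.5 percentiles), `replicates`, `n_failed`.
#' @export
bootstrap_delta_g <- function(dataset, n_boot = 200, seed = 1L) {
  stopifnot(!is.null(dataset$origin_state))
  set.seed(seed)
  K <- nrow(dataset$u_kn)
  blocks <- split(seq_len(ncol(dataset$u_kn)), dataset$origin_state)
  reps <- rep(NA_real_, n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(blocks, function(ix) {
      sample(ix, length(ix), replace = TRUE)
    }))
    ds <- reduced_potential_dataset(
      dataset$u_kn[, idx, drop = FALSE], dataset$n_k
    )
    fb <- tryCatch(mbar_solve(ds, max_iter = 500), error = function(e) NULL)
    if (is.null(fb)) {
      fb <- tryCatch(mbar_solve(ds, max_iter = 2000),
        error = function(e) NULL
      )
    }
    if (is.null(fb)) {
      n_failed <- n_failed + 1L
    } else {
      reps[b] <- fb[K]
    }
  }
  if (n_failed > 0) {
    warning(n_failed, " bootstrap replicate(s) dropped after retry")
  }
  reps <- reps[!is.na(reps)]
  list(
    sigma = stats::sd(reps),
    ci95 = unname(stats::quantile(reps, c(0.025, 0.975))),
    replicates = reps, n_failed = n_failed
  )
}

#' Build an MBAR dataset from a simulation archive
#'
#' Pools every recorded (iteration, replica) sample; the generating state
#' of a sample is the state label assigned to the replica at that
#' iteration. Per-state statistical inefficiencies are estimated from
#' the reduced-potential time series at the generating state and used to
#' subsample each state block at its decorrelation stride.
#'
#' @param archive A `simulation_archive`.
#' @param max_iteration Use only recorded iterations up to this index
#'   (prefix analysis); `NULL` uses everything.
#' @param decorrelate Subsample at the per-state statistical
#'   inefficiency.
#' @return A [reduced_potential_dataset()].
#' @export
dataset_from_archive <- function(archive, max_iteration = NULL,
                                 decorrelate = TRUE) {
  u_kln <- archive$u_kln
  st <- archive$state_trace
  n_rec <- dim(u_kln)[3]
  if (!is.null(max_iteration)) {
    n_rec <- min(n_rec, max_iteration)
  }
  K <- dim(u_kln)[1]
  cols <- list()
  origin <- list()
  g_by_state <- rep(NA_real_, K)
  for (l in seq_len(K)) {
    # replica occupying state l at each recorded iteration
    k_l <- apply(st[seq_len(n_rec), , drop = FALSE], 1, function(s) {
      which(s == l)
    })
    # reduced potential series at the generating state
    series <- vapply(seq_len(n_rec), function(n) {
      u_kln[k_l[n], l, n]
    }, numeric(1))
    g <- if (decorrelate && length(series) >= 4 &&
      stats::sd(series) > 0) {
      statistical_inefficiency(series)$g
    } else {
      1
    }
    g_by_state[l] <- g
    keep <- seq(1, n_rec, by = ceiling(g))
    if (length(keep) < 2) keep <- seq_len(min(2, n_rec))
    block <- vapply(keep, function(n) {
      u_kln[k_l[n], , n]
    }, numeric(K))
    cols[[l]] <- block # K x n_keep
    origin[[l]] <- rep(l, length(keep))
  }
  u_kn <- do.call(cbind, cols)
  origin <- unlist(origin)
  reduced_potential_dataset(
    u_kn, tabulate(origin, K),
    origin_state = origin, decorrelation_g = g_by_state
  )
}

#' MBAR free energy estimate with bootstrap uncertainty
#'
#' @param archive_or_dataset A `simulation_archive` or a
#'   [reduced_potential_dataset()].
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param temperature Reference temperature for the kcal/mol conversion.
#' @param ... Passed to [dataset_from_archive()].
#' @return A `free_energy_estimate`: `f_k` (reduced), `delta_g`
#'   (reduced), `delta_g_kcal_mol`, `sigma`/`sigma_kcal_mol`, `ci95`
#'   (reduced), `n_bootstrap`, `n_effective`.
#' @export
estimate_free_energy <- function(archive_or_dataset, n_boot = 200,
                                 seed = 1L, temperature = 300, ...) {
  ds <- if (inherits(archive_or_dataset, "simulation_archive")) {
    dataset_from_archive(archive_or_dataset, ...)
  } else {
    archive_or_dataset
  }
  f <- mbar_solve(ds)
  K <- length(f)
  bt <- if (n_boot > 0 && !is.null(ds$origin_state)) {
    bootstrap_delta_g(ds, n_boot = n_boot, seed = seed)
  } else {
    list(sigma = NA_real_, ci95 = c(NA_real_, NA_real_), replicates = NULL)
  }
  structure(
    list(
      f_k = f, delta_g = f[K],
      delta_g_kcal_mol = kt_to_kcal(f[K], temperature),
      sigma = bt$sigma,
      sigma_kcal_mol = kt_to_kcal(bt$sigma, temperature),
      ci95 = bt$ci95, n_bootstrap = n_boot,
      n_effective = ncol(ds$u_kn),
      decorrelation_g = ds$decorrelation_g,
      temperature = temperature
    ),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf(
    "<free_energy_estimate> delta G = %.4f +/- %.4f kT (%.4f +/- %.4f kcal/mol), n_eff = %d\n",
    x$delta_g, x$sigma, x$delta_g_kcal_mol, x$sigma_kcal_mol, x$n_effective
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.free_energy_estimate <- function(x, ...) {
  tibble::tibble(
    state = seq_along(x$f_k) - 1L,
    f = x$f_k,
    f_kcal_mol = kt_to_kcal(x$f_k, x$temperature)
  )
}

#' @export
glance.free_energy_estimate <- function(x, ...) {
  tibble::tibble(
    delta_g = x$delta_g, sigma = x$sigma,
    ci95_lo = x$ci95[1], ci95_hi = x$ci95[2],
    delta_g_kcal_mol = x$delta_g_kcal_mol,
    sigma_kcal_mol = x$sigma_kcal_mol,
    n_effective = x$n_effective, n_bootstrap = x$n_bootstrap
  )
}

#' Free energy difference as a function of simulation time
#'
#' Recomputes the MBAR estimate on growing prefixes of the archive
#' (decorrelated within each prefix); the final point equals the
#' full-data estimate exactly.
#'
#' @param archive A `simulation_archive`.
#' @param n_points Number of evenly spaced prefixes.
#' @param n_boot Bootstrap replicates per point (0 disables).
#' @param seed Bootstrap seed.
#' @return A `delta_g_series` tibble: `iteration`, `delta_g`, `sigma`.
#' @export
delta_g_time_series <- function(archive, n_points = 10, n_boot = 50,
                                seed = 1L) {
  n_rec <- dim(archive$u_kln)[3]
  if (n_rec < n_points) {
    stop("archive has fewer recorded iterations than n_points",
      call. = FALSE
    )
  }
  ts <- unique(round(seq(n_rec / n_points, n_rec, length.out = n_points)))
  rows <- purrr::map(ts, function(t) {
    est <- estimate_free_energy(
      dataset_from_archive(archive, max_iteration = t),
      n_boot = n_boot, seed = seed
    )
    tibble::tibble(
      iteration = t, delta_g = est$delta_g, sigma = est$sigma
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delta_g_series", class(out))
  out
}

#' Slope of the trailing window of a delta-G time series
#'
#' Ordinary least squares slope of delta G against time over the last
#' fraction (or the last `span` points) of the series, with uncertainty
#' reported as two standard errors of the slope.
#'
#' @param series A [delta_g_time_series()] result (or tibble with
#'   `iteration` and `delta_g`).
#' @param window_fraction Trailing fraction of points to use.
#' @param span Trailing number of points (overrides `window_fraction`).
#' @return List with `slope`, `two_se`, `n` (points in the window).
#' @export
slope_last_window <- function(series, window_fraction = 0.5, span = NULL) {
  n <- nrow(series)
  m <- if (!is.null(span)) span else ceiling(window_fraction * n)
  if (m > n) stop("window longer than series", call. = FALSE)
  if (m < 3) stop("need at least 3 points in the window", call. = FALSE)
  w <- series[(n - m + 1):n, ]
  fit <- stats::lm(delta_g ~ iteration, data = w)
  # perfect fits (exact linear/constant series) are legitimate here
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(sm) > 1 && !is.na(sm[2, 2])) sm[2, 2] else 0
  list(slope = unname(stats::coef(fit)[2]), two_se = 2 * se, n = m)
}

#' Combine two phase estimates into a relative free energy
#'
#' ddG = delta G (phase b) - delta G (phase a), with the uncertainties
#' added in quadrature; the 95% CI uses the normal approximation.
#'
#' @param phase_a,phase_b `free_energy_estimate` objects (e.g. apo and
#'   complex).
#' @return A `delta_delta_g`: `ddg`, `sigma`, `ci95` (reduced units) and
#'   kcal/mol counterparts, plus the two phase estimates.
#' @export
combine_ddg <- function(phase_a, phase_b) {
  if (phase_a$temperature != phase_b$temperature) {
    stop("phase estimates use different reference temperatures",
      call. = FALSE
    )
  }
  ddg <- phase_b$delta_g - phase_a$delta_g
  sigma <- sqrt(phase_a$sigma^2 + phase_b$sigma^2)
  structure(
    list(
      ddg = ddg, sigma = sigma,
      ci95 = ddg + c(-1.96, 1.96) * sigma,
      ddg_kcal_mol = kt_to_kcal(ddg, phase_a$temperature),
      sigma_kcal_mol = kt_to_kcal(sigma, phase_a$temperature),
      phase_estimates = list(a = phase_a, b = phase_b),
      temperature = phase_a$temperature
    ),
    class = "delta_delta_g"
  )
}

#' @export
print.delta_delta_g <- function(x, ...) {
  cat(sprintf(
    "<delta_delta_g> ddG = %.4f +/- %.4f kT (%.4f +/- %.4f kcal/mol)\n",
    x$ddg, x$sigma, x$ddg_kcal_mol, x$sigma_kcal_mol
  ))
  invisible(x)
}

#' @export
glance.delta_delta_g <- function(x, ...) {
  tibble::tibble(
    ddg = x$ddg, sigma = x$sigma,
    ci95_lo = x$ci95[1], ci95_hi = x$ci95[2],
    ddg_kcal_mol = x$ddg_kcal_mol, sigma_kcal_mol = x$sigma_kcal_mol
  )
}
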