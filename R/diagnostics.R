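#' Statistical inefficiency g = 1 + 2 tau of a time series
#'
#' tau is the integrated autocorrelation time, summed with the
#' (1 - t/N) weighting up to (excluding) the first non-positive
#' autocorrelation (initial positive sequence truncation). g is the
#' factor by which correlated samples are less informative than
#' independent ones; g times the sampling interval expresses the same
#' quantity in time units, and a g_time equal to the sampling interval
#' means the samples are completely decorrelated.
#'
#' @param series Numeric vector, length >= 4, non-constant.
#' @param sampling_interval Time per sample (any unit).
#' @return A `statistical_inefficiency` list: `g`, `tau` (samples),
#'   `sampling_interval`, `g_time`.
#' @export
#' @examples
#' statistical_inefficiency(rnorm(1000))$g # about 1
statistical_inefficiency <- function(series, sampling_interval = 1) {
  n <- length(series)
  if (n < 4) stop("series too short (need >= 4)", call. = FALSE)
  if (any(!is.finite(series))) stop("non-finite values", call. = FALSE)
  xc <- series - mean(series)
  s2 <- mean(xc^2)
  if (s2 == 0) stop("constant series: variance undefined", call. = FALSE)
  # autocovariance sums via FFT, unbiased normalization
  m <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(xc, rep(0, m - n)))
  ac_raw <- Re(stats::fft(Mod(fx)^2, inverse = TRUE)) / m
  lags <- 0:(n - 1)
  ac <- ac_raw[1:n] / (n - lags)
  rho <- ac / ac[1]
  tau <- 0
  for (t in seq_len(n - 1)) {
    if (rho[t + 1] <= 0) break
    tau <- tau + (1 - t / n) * rho[t + 1]
  }
  g <- max(1, 1 + 2 * tau)
  structure(
    list(
      g = g, tau = tau, sampling_interval = sampling_interval,
      g_time = g * sampling_interval
    ),
    class = "statistical_inefficiency"
  )
}

#' Pearson correlation with an autocorrelation-aware confidence interval
#'
#' Standard Pearson r between two aligned series; the 95% CI uses the
#' Fisher z transform with an effective sample size n / g_max, where
#' g_max is the larger statistical inefficiency of the two series
#' (correlated samples carry less evidence about r).
#'
#' @param x_series,y_series Equal-length numeric vectors (>= 3 points,
#'   non-constant).
#' @return A `correlation_result`: `pcc`, `ci95`, `n_effective`,
#'   `per_replica_pccs` (NULL here).
#' @export
pcc_with_ci <- function(x_series, y_series) {
  n <- length(x_series)
  if (n != length(y_series) || n < 3) {
    stop("series must be aligned with length >= 3", call. = FALSE)
  }
  if (stats::sd(x_series) == 0 || stats::sd(y_series) == 0) {
    stop("zero variance series", call. = FALSE)
  }
  r <- stats::cor(x_series, y_series)
  g <- 1
  if (n >= 4) {
    g <- max(
      statistical_inefficiency(x_series)$g,
      statistical_inefficiency(y_series)$g
    )
  }
  n_eff <- max(4, n / g)
  rc <- max(-1 + 1e-12, min(1 - 1e-12, r))
  z <- atanh(rc)
  se <- 1 / sqrt(n_eff - 3)
  ci <- tanh(z + c(-1.96, 1.96) * se)
  structure(
    list(
      pcc = r, ci95 = ci, n_effective = floor(n_eff),
      per_replica_pccs = NULL
    ),
    class = "correlation_result"
  )
}

#' Replica-averaged Pearson correlation
#'
#' Computes the per-replica PCC between dU/dlambda and a degree of
#' freedom, combines them by the Fisher-z mean, and back-transforms.
#' Replicas with zero variance in either series are skipped with a
#' warning.
#'
#' @param du_dl_per_replica,dof_per_replica n x K matrices (recorded
#'   iterations x replicas), aligned.
#' @return A `correlation_result` with `per_replica_pccs` retained.
#' @export
replica_averaged_pcc <- function(du_dl_per_replica, dof_per_replica) {
  stopifnot(all(dim(du_dl_per_replica) == dim(dof_per_replica)))
  K <- ncol(du_dl_per_replica)
  rs <- rep(NA_real_, K)
  n_eff <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    x <- du_dl_per_replica[, k]
    y <- dof_per_replica[, k]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("replica ", k, " skipped: zero variance")
      next
    }
    pr <- pcc_with_ci(x, y)
    rs[k] <- pr$pcc
    n_eff[k] <- pr$n_effective
  }
  ok <- !is.na(rs)
  if (!any(ok)) stop("all replicas skipped", call. = FALSE)
  zc <- atanh(pmax(-1 + 1e-12, pmin(1 - 1e-12, rs[ok])))
  zbar <- mean(zc)
  se <- 1 / sqrt(max(1, sum(n_eff[ok] - 3)))
  structure(
    list(
      pcc = tanh(zbar),
      ci95 = tanh(zbar + c(-1.96, 1.96) * se),
      n_effective = floor(sum(n_eff[ok])),
      per_replica_pccs = rs
    ),
    class = "correlation_result"
  )
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention, range (-180, 180] degrees: cis = 0, trans =
#' 180.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("collinear points: dihedral undefined", call. = FALSE)
  }
  b2h <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2h)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Minimum cross-pair distance between two atom groups
#'
#' @param coords n x 3 coordinate matrix.
#' @param group_a,group_b Disjoint, non-empty index sets.
#' @return Minimum Euclidean distance over all cross pairs.
#' @export
min_pair_distance <- function(coords, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  d2 <- outer(group_a, group_b, Vectorize(function(a, b) {
    sum((coords[a, ] - coords[b, ])^2)
  }))
  sqrt(min(d2))
}

#' Count candidates within a radius of a center group
#'
#' Counts candidate atoms whose minimum distance to any center atom is
#' less than or equal to `radius` (boundary inclusive).
#'
#' @param coords n x 3 coordinate matrix.
#' @param center_group,candidate_group Index sets.
#' @param radius Inclusive radius, > 0 (0.5 nm, i.e. 5 Angstrom, is the
#'   conventional shell for neighboring-water counts).
#' @return Integer count.
#' @export
count_within_radius <- function(coords, center_group, candidate_group,
                                radius = 0.5) {
  stopifnot(radius > 0)
  if (length(candidate_group) == 0) {
    return(0L)
  }
  sum(vapply(candidate_group, function(a) {
    min(vapply(center_group, function(c) {
      sqrt(sum((coords[a, ] - coords[c, ])^2))
    }, numeric(1))) <= radius
  }, logical(1)))
}

#' Convergence verdict from a trailing-window slope
#'
#' Converged iff the interval slope +/- two_se intersects
#' \code{[-threshold, threshold]} (a close-to-zero slope within
#' statistical uncertainty).
#'
#' @param slope,two_se Slope of the trailing window and its 2-SE
#'   uncertainty (same units).
#' @param threshold Flatness threshold, > 0 (default 0.1, the
#'   kcal/mol/ns-style criterion expressed in the series' own units).
#' @return Logical flag.
#' @export
convergence_verdict <- function(slope, two_se, threshold = 0.1) {
  stopifnot(threshold > 0)
  (slope - two_se) <= threshold && (slope + two_se) >= -threshold
}

#' Forward/reverse internal-consistency verdict
#'
#' The pair is inconsistent iff the forward ddG is more than `margin`
#' kcal/mol outside the negated 95% CI of the reverse ddG AND the
#' negated reverse ddG is more than `margin` outside the forward 95% CI;
#' otherwise consistent. The discrepancy fwd + rev (which would be 0 for
#' perfectly consistent estimates) is reported.
#'
#' @param fwd,rev `delta_delta_g` objects for the forward and reverse
#'   transformation.
#' @param margin Consistency margin in kcal/mol.
#' @return List with `consistent`, `discrepancy_kcal_mol`.
#' @export
internal_consistency_verdict <- function(fwd, rev, margin = 1) {
  ci_f <- kt_to_kcal(fwd$ci95, fwd$temperature)
  ci_r <- kt_to_kcal(rev$ci95, rev$temperature)
  if (any(!is.finite(c(ci_f, ci_r)))) {
    stop("both estimates must carry 95% CIs", call. = FALSE)
  }
  f <- fwd$ddg_kcal_mol
  r <- rev$ddg_kcal_mol
  neg_ci_r <- sort(-ci_r)
  dist_to <- function(a, ci) max(0, ci[1] - a, a - ci[2])
  inconsistent <- dist_to(f, neg_ci_r) > margin && dist_to(-r, ci_f) > margin
  list(
    consistent = !inconsistent,
    discrepancy_kcal_mol = f + r
  )
}

#' Slow degree-of-freedom report
#'
#' The sampling-problem identification workflow applied to one archive:
#' per DOF category, the maximum |replica-averaged PCC| between
#' dU/dlambda and the category's degrees of freedom (with CI and the
#' arg-max DOF name); the statistical inefficiency of dU/dlambda across
#' replicas; the trailing-slope convergence verdict of the delta-G time
#' series; and the replica-mixing summary.
#'
#' @param archive A `simulation_archive` containing dU/dlambda and DOF
#'   traces.
#' @param catalog Optional tibble with `name`, `category` overriding the
#'   archive's recorded catalog.
#' @param slope_threshold Flatness threshold for the convergence verdict
#'   (units of delta-G per recorded iteration).
#' @param n_points Prefix-grid size for the delta-G time series.
#' @param n_boot Bootstrap replicates per time-series point.
#' @return A `diagnostics_report`.
#' @export
slow_dof_report <- function(archive, catalog = NULL,
                            slope_threshold = 0.1, n_points = 10,
                            n_boot = 50) {
  if (is.null(catalog)) {
    if (!length(archive$dof_traces)) {
      stop("archive has no DOF traces and no catalog given", call. = FALSE)
    }
    catalog <- tibble::tibble(
      name = names(archive$dof_traces),
      category = unname(archive$dof_categories[names(archive$dof_traces)])
    )
  }
  missing <- setdiff(catalog$name, names(archive$dof_traces))
  if (length(missing)) {
    stop(
      "catalog observable(s) missing from archive: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  du <- archive$du_dl
  degenerate <- all(apply(du, 2, stats::sd) < 1e-12)

  per_dof <- purrr::pmap(catalog, function(name, category, ...) {
    if (degenerate) {
      return(tibble::tibble(
        name = name, category = category,
        pcc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_
      ))
    }
    cr <- replica_averaged_pcc(du, archive$dof_traces[[name]])
    tibble::tibble(
      name = name, category = category,
      pcc = cr$pcc, ci_lo = cr$ci95[1], ci_hi = cr$ci95[2]
    )
  }) |> dplyr::bind_rows()

  category_table <- per_dof |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_max(abs(.data$pcc), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(max_abs_pcc_dof = "name") |>
    dplyr::arrange(dplyr::desc(abs(.data$pcc)))

  g_du <- if (degenerate) {
    NA_real_
  } else {
    mean(apply(du, 2, function(x) {
      if (stats::sd(x) < 1e-12) {
        return(NA_real_)
      }
      statistical_inefficiency(x)$g
    }), na.rm = TRUE)
  }

  ts <- delta_g_time_series(archive,
    n_points = min(n_points, dim(archive$u_kln)[3]),
    n_boot = n_boot
  )
  sl <- slope_last_window(ts)
  conv <- convergence_verdict(sl$slope, sl$two_se, slope_threshold)
  mix <- mixing_statistics(archive$state_trace)

  structure(
    list(
      converged = conv, slope = sl$slope, slope_two_se = sl$two_se,
      slope_threshold = slope_threshold,
      mixing = mix, du_dl_g = g_du, degenerate_du_dl = degenerate,
      per_dof = per_dof, category_table = category_table,
      delta_g_series = ts
    ),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  if (x$degenerate_du_dl) {
    cat("  dU/dlambda is degenerate (no alchemical atoms?); PCCs undefined\n")
  } else {
    cat(sprintf("  g(dU/dlambda) = %.2f recorded iterations\n", x$du_dl_g))
  }
  cat(sprintf(
    "  converged: %s (slope %.4g +/- %.4g, threshold %.3g)\n",
    x$converged, x$slope, x$slope_two_se, x$slope_threshold
  ))
  cat(sprintf(
    "  mixing bottleneck: %s (subdominant eigenvalue %.3f)\n",
    x$mixing$bottleneck, x$mixing$subdominant_eigenvalue
  ))
  print(x$category_table)
  invisible(x)
}

#' @export
tidy.diagnostics_report <- function(x, ...) x$category_table

#' @export
glance.diagnostics_report <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, slope = x$slope,
    slope_two_se = x$slope_two_se, du_dl_g = x$du_dl_g,
    degenerate_du_dl = x$degenerate_du_dl,
    mixing_bottleneck = x$mixing$bottleneck,
    subdominant_eigenvalue = x$mixing$subdominant_eigenvalue
  )
}

#' Summarize several diagnostics reports in one table
#'
#' One row per archive, ordered from highest to lowest statistical
#' inefficiency of dU/dlambda (the slowest-converging runs first, as in
#' the slow-DOF category heat map presentation).
#'
#' @param reports Named list of `diagnostics_report` objects.
#' @return A tibble with one row per report.
#' @export
combine_diagnostics <- function(reports) {
  if (is.null(names(reports))) {
    names(reports) <- paste0("archive_", seq_along(reports))
  }
  purrr::imap(reports, function(r, nm) {
    dplyr::bind_cols(tibble::tibble(label = nm), glance(r))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$du_dl_g))
}

#' Write a diagnostics report to disk
#'
#' `report.json` (verdicts and tables) and `category_table.csv`.
#'
#' @param report A `diagnostics_report`.
#' @param path Output directory.
#' @export
write_diagnostics_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      converged = report$converged, slope = report$slope,
      slope_two_se = report$slope_two_se,
      du_dl_g = report$du_dl_g,
      degenerate_du_dl = report$degenerate_du_dl,
      mixing_bottleneck = report$mixing$bottleneck,
      subdominant_eigenvalue = report$mixing$subdominant_eigenvalue,
      category_table = report$category_table,
      per_dof = report$per_dof
    ),
    file.path(path, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(report$category_table,
    file.path(path, "category_table.csv"),
    row.names = FALSE
  )
  invisible(path)
}
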