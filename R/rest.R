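#' REST (solute tempering) configuration
#'
#' Defines the effective-temperature schedule applied to interactions in
#' a region around the mutating residue. The effective inverse
#' temperature interpolates linearly from beta(T0) at lambda = 0 down to
#' beta(Tmax) at lambda = 0.5 and back up to beta(T0) at lambda = 1, so
#' both endstates are exactly unscaled.
#'
#' @param t0 Temperature of the target distribution (K).
#' @param tmax Maximum effective temperature reached at lambda = 0.5 (K).
#' @param radius REST region radius (nm) around the mutating residue.
#' @param inter_exponent Exponent applied to the scale factor for
#'   interactions straddling the region boundary: 0.5 (the REST2
#'   convention, default) scales them by sqrt(alpha), 1.0 scales them by
#'   alpha.
#' @return A `rest_config` list.
#' @export
#' @examples
#' rest_config(tmax = 600)
rest_config <- function(t0 = 300, tmax = 600, radius = 0.5,
                        inter_exponent = 0.5) {
  stopifnot(t0 > 0, tmax >= t0, radius >= 0, inter_exponent %in% c(0.5, 1.0))
  structure(
    list(
      t0 = t0, tmax = tmax, radius = radius,
      inter_exponent = inter_exponent
    ),
    class = "rest_config"
  )
}

#' REST scale factor alpha(lambda)
#'
#' alpha = beta_eff(lambda) / beta(T0) with a triangular inverse-
#' temperature schedule peaking at lambda = 0.5: alpha(0) = alpha(1) = 1
#' and alpha(0.5) = T0 / Tmax.
#'
#' @param lambda Alchemical parameter in \code{[0, 1]}.
#' @param config A [rest_config()].
#' @return Dimensionless scale factor in \code{[T0/Tmax, 1]}.
#' @export
#' @examples
#' rest_scale_factor(0.5, rest_config(t0 = 300, tmax = 600)) # 0.5
rest_scale_factor <- function(lambda, config) {
  .check_lambda(lambda)
  b0 <- 1 / config$t0
  bmax <- 1 / config$tmax
  frac <- 1 - 2 * abs(lambda - 0.5) # 0 at endstates, 1 at midpoint
  beta_eff <- b0 + frac * (bmax - b0)
  beta_eff / b0
}

#' Select the REST region from an initial conformation
#'
#' All atoms of the mutating residue plus every atom within `radius` of
#' any mutating-residue atom, evaluated once on the supplied (initial)
#' conformation. The region is never recomputed during a run.
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param hybrid A `hybrid_topology`.
#' @param radius Region radius (nm).
#' @return Sorted integer vector of atom indices.
#' @export
select_rest_region <- function(positions, hybrid, radius) {
  stopifnot(radius >= 0)
  at <- hybrid$atoms
  mut <- at$index[at$residue_id == hybrid$atom_map$mutating_residue_id]
  if (length(mut) == 0) stop("empty mutating residue", call. = FALSE)
  if (radius == 0) {
    return(sort(mut))
  }
  d2 <- vapply(mut, function(m) {
    rowSums((positions - matrix(positions[m, ],
      nrow(positions), 3,
      byrow = TRUE
    ))^2)
  }, numeric(nrow(positions)))
  near <- which(apply(d2, 1, min) <= radius^2)
  sort(union(mut, at$index[near]))
}

#' Classify an interaction term against the REST region
#'
#' `rest` when all of the term's atoms are in the region, `nonrest` when
#' none are, `inter` otherwise.
#'
#' @param term_atom_indices Integer atom indices of the term.
#' @param rest_region Integer vector from [select_rest_region()].
#' @return One of `"rest"`, `"inter"`, `"nonrest"`.
#' @export
classify_interaction <- function(term_atom_indices, rest_region) {
  ix <- stats::na.omit(term_atom_indices)
  if (length(ix) == 0) stop("empty interaction term", call. = FALSE)
  classify_membership(sum(ix %in% rest_region), length(ix))
}

#' REST-scaled total alchemical energy
#'
#' u_total = alpha u_rest + alpha^p u_inter + u_nonrest with p the
#' configured inter exponent; at lambda in \{0, 1\} alpha = 1 exactly and
#' the result is bit-identical to the unscaled alchemical energy.
#'
#' @inheritParams total_energy
#' @param rest_cfg A [rest_config()].
#' @param rest_region Optional precomputed region; defaults to
#'   [select_rest_region()] on `positions`.
#' @return Energy (kT).
#' @export
scaled_total_energy <- function(positions, hybrid, lambda, rest_cfg,
                                params = energy_params(),
                                rest_region = NULL) {
  if (is.null(rest_region)) {
    rest_region <- select_rest_region(positions, hybrid, rest_cfg$radius)
  }
  ce <- compile_hybrid_energy(hybrid, params,
    rest_region = rest_region, rest_config = rest_cfg
  )
  eval_compiled_energy(ce, positions, lambda)
}
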