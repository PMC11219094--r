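#' Build an atom map between WT and mutant residues
#'
#' Pairs up WT and mutant atoms that will share coordinates in the hybrid
#' system. All backbone atoms (N, H, CA, HA, C, O) plus the beta carbon CB
#' are mapped by label; side-chain atoms with identical labels on both
#' sides are also mapped (so an identity mutation maps everything), with
#' two exceptions: beta hydrogens (labels starting `HB`) are never mapped,
#' and any hydrogen pair whose constrained bond length differs between the
#' endstates is un-mapped (bonds to hydrogen are constrained, so mapping
#' them would tie two different constraint lengths to one coordinate).
#'
#' @param wt_residue_atoms,mut_residue_atoms Tibbles with at least `index`
#'   (atom index in the parent system / template) and `name` columns.
#' @param hydrogen_constraint_lengths A list with elements `old` and `new`,
#'   each a named vector label -> constrained bond length (nm), or a single
#'   named vector applied to both endstates.
#' @param mutating_residue_id Residue id of the mutating residue.
#' @return An `atom_map` object: list with `pairs` (tibble of
#'   `wt_index`, `mut_index`, `name`) and `mutating_residue_id`.
#' @export
build_atom_map <- function(wt_residue_atoms, mut_residue_atoms,
                           hydrogen_constraint_lengths,
                           mutating_residue_id = 1L) {
  wt <- tibble::as_tibble(wt_residue_atoms)
  mut <- tibble::as_tibble(mut_residue_atoms)
  if (anyDuplicated(wt$name) || anyDuplicated(mut$name)) {
    stop("duplicate atom labels within a residue", call. = FALSE)
  }
  hcl <- hydrogen_constraint_lengths
  if (!is.list(hcl)) hcl <- list(old = hcl, new = hcl)

  is_gly <- function(a) !("CB" %in% a$name) && ("HA2" %in% a$name)
  for (side in list(wt, mut)) {
    if (!("CB" %in% side$name) && !is_gly(side)) {
      stop("missing CB on a non-glycine residue", call. = FALSE)
    }
  }

  common <- intersect(wt$name, mut$name)
  common <- setdiff(common, grep("^HB", common, value = TRUE))  # beta hydrogens

  # un-map hydrogens whose constrained bond length changes between endstates
  is_h <- function(nm, side) {
    if ("is_heavy" %in% names(side)) {
      !side$is_heavy[match(nm, side$name)]
    } else {
      startsWith(nm, "H")
    }
  }
  keep <- vapply(common, function(nm) {
    if (!is_h(nm, wt)) return(TRUE)
    lo <- hcl$old[nm]
    ln <- hcl$new[nm]
    if (is.na(lo) || is.na(ln)) return(TRUE)
    isTRUE(all.equal(unname(lo), unname(ln)))
  }, logical(1))
  common <- common[keep]

  pairs <- tibble::tibble(
    name = common,
    wt_index = wt$index[match(common, wt$name)],
    mut_index = mut$index[match(common, mut$name)]
  ) |> dplyr::arrange(.data$wt_index)

  structure(
    list(pairs = pairs, mutating_residue_id = as.integer(mutating_residue_id)),
    class = "atom_map"
  )
}

#' Classify hybrid atoms into alchemical atom classes
#'
#' Unmapped WT atoms become `unique_old`, unmapped mutant atoms
#' `unique_new`; mapped atoms in the mutating residue or in the residues
#' immediately preceding/following it become `core`; all other mapped
#' atoms are `environment`. The partition is exhaustive and disjoint.
#'
#' @param hybrid_atoms Tibble of hybrid atoms with `index`, `residue_id`
#'   and an `origin` column (`"mapped"`, `"wt_only"`, `"mut_only"`).
#' @param atom_map An [build_atom_map()] result (used for the mutating
#'   residue id).
#' @param mutating_residue_id Integer residue id of the mutation site.
#' @param flanking_residue_ids Residue ids treated as core alongside the
#'   mutating residue (defaults to +/- 1 neighbours).
#' @return The input tibble with an `atom_class` column.
#' @export
classify_atoms <- function(hybrid_atoms, atom_map,
                           mutating_residue_id = atom_map$mutating_residue_id,
                           flanking_residue_ids = mutating_residue_id + c(-1L, 1L)) {
  at <- tibble::as_tibble(hybrid_atoms)
  stopifnot(all(c("index", "residue_id", "origin") %in% names(at)))
  core_res <- c(mutating_residue_id, flanking_residue_ids)
  at <- at |>
    dplyr::mutate(atom_class = dplyr::case_when(
      .data$origin == "wt_only" ~ "unique_old",
      .data$origin == "mut_only" ~ "unique_new",
      .data$origin == "mapped" & .data$residue_id %in% core_res ~ "core",
      .data$origin == "mapped" ~ "environment"
    ))
  if (anyNA(at$atom_class)) {
    stop("internal error: atom left unclassified", call. = FALSE)
  }
  at
}

#' Assemble a hybrid topology for a single residue mutation
#'
#' Builds the single hybrid system containing both the WT and mutant
#' residues: mapped atoms share coordinates and carry both endstate
#' nonbonded parameter sets; unmapped atoms become dummy atoms at the
#' opposite endstate (they keep only their valence terms there). All
#' unique_old x unique_new pairs are excluded from nonbonded interactions
#' at every lambda so the two dummy sets can never bias the physical
#' endstates.
#'
#' @param system A bead system as returned by [make_chain_system()]: list
#'   with `atoms`, `bonds`, `positions`.
#' @param mutation_site Residue id of the mutating residue.
#' @param mut_type Three-letter type of the mutant residue.
#' @param seed Integer seed controlling placement of inserted (unique_new)
#'   atom coordinates.
#' @return A `hybrid_topology` object: list with `atoms` (tibble carrying
#'   `charge_old`/`charge_new`, `sigma_old`/`sigma_new`,
#'   `epsilon_old`/`epsilon_new`, `atom_class`), `valence` (tibble of
#'   terms with `endstate_tag`), `atom_map`, `counterion` (NULL until
#'   [apply_counterion_transform()]), `exclusions` (integer matrix) and
#'   `positions0`.
#' @export
build_hybrid_topology <- function(system, mutation_site, mut_type, seed = 1L) {
  atoms <- system$atoms
  bonds <- system$bonds
  pos <- system$positions
  wt_res <- atoms |> dplyr::filter(.data$residue_id == mutation_site)
  if (nrow(wt_res) == 0) stop("mutation site not in system", call. = FALSE)
  wt_type <- wt_res$residue_type[1]

  mut_tpl <- residue_template(mut_type) |>
    dplyr::mutate(index = dplyr::row_number())
  hcl <- list(
    old = hydrogen_constraint_lengths(wt_type),
    new = hydrogen_constraint_lengths(mut_type)
  )
  amap <- build_atom_map(wt_res, mut_tpl, hcl, mutation_site)

  mapped_wt <- amap$pairs$wt_index
  mapped_mut <- amap$pairs$mut_index

  # hybrid atoms: all WT atoms, then inserted mutant-only atoms
  hy <- atoms |>
    dplyr::mutate(
      origin = dplyr::if_else(
        .data$residue_id == mutation_site & !(.data$index %in% mapped_wt),
        "wt_only", "mapped"
      ),
      charge_old = .data$charge,
      sigma_old = .data$sigma,
      epsilon_old = .data$epsilon,
      charge_new = .data$charge,
      sigma_new = .data$sigma,
      epsilon_new = .data$epsilon
    )
  # mapped mutating-residue atoms take mutant endstate parameters by label
  mrow <- match(hy$index, mapped_wt)
  take <- !is.na(mrow) & hy$residue_id == mutation_site
  tpl_idx <- match(amap$pairs$name[mrow[take]], mut_tpl$name)
  hy$charge_new[take] <- mut_tpl$charge[tpl_idx]
  hy$sigma_new[take] <- mut_tpl$sigma[tpl_idx]
  hy$epsilon_new[take] <- mut_tpl$epsilon[tpl_idx]
  # dummy at the new endstate: charges/epsilon off, sigma retained
  off <- hy$origin == "wt_only"
  hy$charge_new[off] <- 0
  hy$epsilon_new[off] <- 0

  new_only <- mut_tpl |> dplyr::filter(!(.data$index %in% mapped_mut))
  n0 <- nrow(hy)
  tpl_to_hybrid <- integer(nrow(mut_tpl))
  tpl_to_hybrid[mapped_mut] <- amap$pairs$wt_index
  if (nrow(new_only) > 0) {
    tpl_to_hybrid[new_only$index] <- n0 + seq_len(nrow(new_only))
    hy <- dplyr::bind_rows(hy, tibble::tibble(
      index = n0 + seq_len(nrow(new_only)),
      name = new_only$name,
      residue_id = mutation_site,
      residue_type = mut_type,
      is_heavy = new_only$is_heavy,
      charge = 0,
      sigma = new_only$sigma,
      epsilon = new_only$epsilon,
      origin = "mut_only",
      charge_old = 0, sigma_old = new_only$sigma, epsilon_old = 0,
      charge_new = new_only$charge,
      sigma_new = new_only$sigma,
      epsilon_new = new_only$epsilon
    ))
  }
  hy <- classify_atoms(hy, amap, mutation_site)

  # valence terms: WT bonds are shared unless they touch a unique_old atom;
  # mutant-template bonds touching a unique_new atom are added as "new".
  uo <- hy$index[hy$atom_class == "unique_old"]
  un <- hy$index[hy$atom_class == "unique_new"]
  val_old <- bonds |>
    dplyr::transmute(
      type = "bond", i = .data$i, j = .data$j,
      k_atom = NA_integer_, l_atom = NA_integer_,
      p1 = .data$k, p2 = .data$r0, p3 = NA_real_,
      endstate_tag = dplyr::if_else(
        .data$i %in% uo | .data$j %in% uo, "old", "shared"
      )
    )
  mut_bonds <- residue_bonds(mut_type)
  mb_i <- tpl_to_hybrid[match(mut_bonds$a, mut_tpl$name)]
  mb_j <- tpl_to_hybrid[match(mut_bonds$b, mut_tpl$name)]
  new_mask <- mb_i %in% un | mb_j %in% un
  val_new <- tibble::tibble(
    type = "bond", i = mb_i[new_mask], j = mb_j[new_mask],
    k_atom = NA_integer_, l_atom = NA_integer_,
    p1 = mut_bonds$k[new_mask], p2 = mut_bonds$r0[new_mask], p3 = NA_real_,
    endstate_tag = "new"
  )
  valence <- dplyr::bind_rows(val_old, val_new)

  # coordinates for inserted atoms: deterministic walk out from the anchor
  pos_h <- rbind(pos, matrix(0, nrow(hy) - nrow(pos), 3))
  if (nrow(new_only) > 0) {
    set.seed(seed)
    placed <- seq_len(n0)
    todo <- hy$index[hy$origin == "mut_only"]
    all_b <- valence
    while (length(todo) > 0) {
      progressed <- FALSE
      for (a in todo) {
        nb <- c(
          all_b$j[all_b$i == a & all_b$j %in% placed],
          all_b$i[all_b$j == a & all_b$i %in% placed]
        )
        if (length(nb) == 0) next
        parent <- nb[1]
        b_row <- all_b[(all_b$i == a & all_b$j == parent) |
          (all_b$j == a & all_b$i == parent), ][1, ]
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos_h[a, ] <- pos_h[parent, ] + b_row$p2 * dir
        placed <- c(placed, a)
        todo <- setdiff(todo, a)
        progressed <- TRUE
      }
      if (!progressed) stop("disconnected unique_new atom", call. = FALSE)
    }
  }

  excl <- build_exclusions(valence, uo, un)
  hybrid <- structure(
    list(
      atoms = hy, valence = valence, atom_map = amap,
      counterion = NULL, exclusions = excl, positions0 = pos_h
    ),
    class = "hybrid_topology"
  )
  validate_hybrid_topology(hybrid, check_neutrality = FALSE)
  hybrid
}

# 1-2 and 1-3 exclusions from bonds, plus all unique_old x unique_new pairs
build_exclusions <- function(valence, unique_old, unique_new) {
  b <- valence[valence$type == "bond", c("i", "j")]
  e12 <- as.matrix(b)
  # 1-3: pairs sharing a bonded neighbour
  nb <- split(c(b$j, b$i), c(b$i, b$j))
  e13 <- do.call(rbind, lapply(nb, function(x) {
    x <- unique(x)
    if (length(x) < 2) return(NULL)
    t(utils::combn(sort(x), 2))
  }))
  uu <- if (length(unique_old) && length(unique_new)) {
    as.matrix(expand.grid(i = unique_old, j = unique_new))
  } else {
    NULL
  }
  e <- rbind(e12, e13, uu)
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  colnames(e) <- c("i", "j")
  storage.mode(e) <- "integer"
  e
}

#' Validate a hybrid topology
#'
#' Checks the atom-class invariants (dummy parameters zeroed, environment
#' atoms unmodified), coverage of unique atoms by endstate valence terms,
#' exclusion of all unique_old x unique_new pairs, and (optionally)
#' endstate charge neutrality to 1e-10 e.
#'
#' @param hybrid A `hybrid_topology`.
#' @param check_neutrality Require equal total charge at both endstates
#'   (use after [apply_counterion_transform()] for charge-changing
#'   mutations).
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_hybrid_topology <- function(hybrid, check_neutrality = TRUE) {
  at <- hybrid$atoms
  stopifnot(all(at$atom_class %in%
    c("unique_old", "unique_new", "core", "environment")))
  uo <- at[at$atom_class == "unique_old", ]
  un <- at[at$atom_class == "unique_new", ]
  env <- at[at$atom_class == "environment", ]
  if (any(uo$charge_new != 0) || any(uo$epsilon_new != 0)) {
    stop("unique_old atoms must have charge_new = 0, epsilon_new = 0")
  }
  if (any(un$charge_old != 0) || any(un$epsilon_old != 0)) {
    stop("unique_new atoms must have charge_old = 0, epsilon_old = 0")
  }
  if (any(env$charge_old != env$charge_new) ||
    any(env$sigma_old != env$sigma_new) ||
    any(env$epsilon_old != env$epsilon_new)) {
    stop("environment atoms must carry identical endstate parameters")
  }
  tagged_atoms <- function(tag) {
    v <- hybrid$valence[hybrid$valence$endstate_tag == tag, ]
    unique(stats::na.omit(c(v$i, v$j, v$k_atom, v$l_atom)))
  }
  if (!all(uo$index %in% tagged_atoms("old"))) {
    stop("a unique_old atom lacks an 'old' valence term")
  }
  if (!all(un$index %in% tagged_atoms("new"))) {
    stop("a unique_new atom lacks a 'new' valence term")
  }
  if (nrow(uo) && nrow(un)) {
    key <- paste(hybrid$exclusions[, 1], hybrid$exclusions[, 2])
    need <- expand.grid(i = uo$index, j = un$index)
    nk <- paste(pmin(need$i, need$j), pmax(need$i, need$j))
    if (!all(nk %in% key)) {
      stop("unique_old x unique_new pair missing from exclusions")
    }
  }
  if (check_neutrality) {
    dq <- abs(sum(at$charge_old) - sum(at$charge_new))
    if (dq > 1e-10) {
      stop(sprintf(
        "endstate total charges differ by %.3g e (counterion transform needed?)",
        dq
      ))
    }
  }
  invisible(TRUE)
}

#' Apply the counterion transform for charge-changing mutations
#'
#' For a mutation changing the residue net charge by dq, one designated
#' water-like particle is co-alchemically transformed into a monovalent
#' ion carrying charge -dq at the mutant endstate (sodium for dq = -1,
#' chloride for dq = +1), keeping the system electrostatically neutral at
#' both endstates. Charge-preserving mutations return the topology
#' unchanged.
#'
#' @param hybrid A `hybrid_topology`.
#' @param water_like_particles Integer atom indices eligible for the
#'   transform; the first is used (the choice policy is configurable by
#'   ordering this vector).
#' @param ion_lj Length-2 numeric, (sigma nm, epsilon kT) of the inserted
#'   ion endstate.
#' @return The transformed `hybrid_topology` with a `counterion` record.
#' @export
apply_counterion_transform <- function(hybrid, water_like_particles,
                                       ion_lj = c(0.25, 0.30)) {
  at <- hybrid$atoms
  dq <- sum(at$charge_new) - sum(at$charge_old)
  if (abs(dq) < 1e-12) {
    hybrid$counterion <- list(water_index = NULL, ion_charge = 0, ion_lj = NULL)
    return(hybrid)
  }
  if (abs(dq) > 1 + 1e-9) {
    stop("unsupported transform: |charge change| > 1 e", call. = FALSE)
  }
  if (length(water_like_particles) == 0) {
    stop("charge-changing mutation but no water-like particle available",
      call. = FALSE
    )
  }
  w <- water_like_particles[1]
  at$charge_new[at$index == w] <- -dq
  at$sigma_new[at$index == w] <- ion_lj[1]
  at$epsilon_new[at$index == w] <- ion_lj[2]
  # the particle is now alchemical: promote from environment to core
  at$atom_class[at$index == w] <- "core"
  hybrid$atoms <- at
  hybrid$counterion <- list(
    water_index = w, ion_charge = -dq, ion_lj = ion_lj
  )
  validate_hybrid_topology(hybrid, check_neutrality = TRUE)
  hybrid
}

#' @export
print.hybrid_topology <- function(x, ...) {
  cls <- table(x$atoms$atom_class)
  cat("<hybrid_topology> ", nrow(x$atoms), " atoms (",
    paste(names(cls), unname(cls), sep = ":", collapse = ", "), ")\n",
    sep = ""
  )
  cat("  valence terms:", nrow(x$valence),
    " exclusions:", nrow(x$exclusions), "\n"
  )
  if (!is.null(x$counterion) && !is.null(x$counterion$water_index)) {
    cat(
      "  counterion: particle", x$counterion$water_index,
      "-> charge", x$counterion$ion_charge, "e at lambda = 1\n"
    )
  }
  invisible(x)
}

#' Serialize / restore a hybrid topology as JSON
#'
#' Versioned JSON schema mirroring the atom and valence tables.
#'
#' @param hybrid A `hybrid_topology`.
#' @param path File path.
#' @return `write_hybrid_json` returns `path` invisibly;
#'   `read_hybrid_json` returns the `hybrid_topology`.
#' @export
write_hybrid_json <- function(hybrid, path) {
  obj <- list(
    schema = "alchemforge-hybrid-1",
    atoms = hybrid$atoms,
    valence = hybrid$valence,
    atom_map = list(
      pairs = hybrid$atom_map$pairs,
      mutating_residue_id = hybrid$atom_map$mutating_residue_id
    ),
    counterion = hybrid$counterion,
    exclusions = as.data.frame(hybrid$exclusions),
    positions0 = hybrid$positions0
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_hybrid_json
#' @export
read_hybrid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "alchemforge-hybrid-1")) {
    stop("unrecognized hybrid topology schema", call. = FALSE)
  }
  amap <- structure(
    list(
      pairs = tibble::as_tibble(obj$atom_map$pairs),
      mutating_residue_id = as.integer(obj$atom_map$mutating_residue_id)
    ),
    class = "atom_map"
  )
  ci <- obj$counterion
  if (!is.null(ci) && length(ci) && !is.null(ci$ion_lj)) {
    ci$ion_lj <- as.numeric(ci$ion_lj)
  }
  structure(
    list(
      atoms = tibble::as_tibble(obj$atoms),
      valence = tibble::as_tibble(obj$valence) |>
        dplyr::mutate(
          k_atom = as.integer(.data$k_atom),
          l_atom = as.integer(.data$l_atom),
          p3 = as.numeric(.data$p3)
        ),
      atom_map = amap,
      counterion = ci,
      exclusions = {
        e <- unname(as.matrix(obj$exclusions))
        storage.mode(e) <- "integer"
        dimnames(e) <- list(NULL, c("i", "j"))
        e
      },
      positions0 = as.matrix(obj$positions0)
    ),
    class = "hybrid_topology"
  )
}
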