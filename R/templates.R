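#' Bead-level residue templates
#'
#' Minimal amino-acid-like templates used by the toy systems: atom names
#' follow PDB conventions (N, H, CA, HA, C, O, CB, ...), charges sum to the
#' residue formal charge, and Lennard-Jones parameters are plausible
#' bead-level values. These are deliberately not force-field parameters;
#' they exist so that hybrid-topology construction, atom mapping, and the
#' alchemical energy machinery can be exercised at desk scale.
#'
#' @section Available types:
#' `ALA`, `GLY`, `SER`, `THR`, `ARG` (+1), `ASP` (-1).
#'
#' @param type Three-letter residue type.
#' @return A tibble with columns `name`, `is_heavy`, `charge`, `sigma`
#'   (nm), `epsilon` (kT).
#' @export
#' @examples
#' residue_template("THR")
residue_template <- function(type) {
  type <- toupper(type)
  tpl <- .residue_templates[[type]]
  if (is.null(tpl)) {
    stop("unknown residue type: ", type, call. = FALSE)
  }
  tpl
}

#' @rdname residue_template
#' @export
residue_types <- function() names(.residue_templates)

# sigma (nm) / epsilon (kT) by bead flavour
.lj <- list(
  C  = c(0.34, 0.35),
  N  = c(0.33, 0.50),
  O  = c(0.30, 0.60),
  H  = c(0.24, 0.08),  # aliphatic hydrogen
  HP = c(0.10, 0.02)   # polar hydrogen (on N or O)
)

.atom_row <- function(name, charge, flavour) {
  p <- .lj[[flavour]]
  tibble::tibble(
    name = name,
    is_heavy = !flavour %in% c("H", "HP"),
    charge = charge,
    sigma = p[1],
    epsilon = p[2]
  )
}

.backbone <- function(with_cb = TRUE) {
  rows <- list(
    .atom_row("N", -0.40, "N"),
    .atom_row("H", 0.25, "HP"),
    .atom_row("CA", 0.10, "C"),
    .atom_row("HA", 0.05, "H"),
    .atom_row("C", 0.50, "C"),
    .atom_row("O", -0.50, "O")
  )
  dplyr::bind_rows(rows)
}

.residue_templates <- local({
  bb <- .backbone()
  side <- list(
    ALA = dplyr::bind_rows(
      .atom_row("CB", -0.09, "C"),
      .atom_row("HB1", 0.03, "H"),
      .atom_row("HB2", 0.03, "H"),
      .atom_row("HB3", 0.03, "H")
    ),
    GLY = .atom_row("HA2", 0.00, "H"),
    SER = dplyr::bind_rows(
      .atom_row("CB", 0.10, "C"),
      .atom_row("HB1", 0.05, "H"),
      .atom_row("HB2", 0.05, "H"),
      .atom_row("OG", -0.60, "O"),
      .atom_row("HG", 0.40, "HP")
    ),
    THR = dplyr::bind_rows(
      .atom_row("CB", 0.15, "C"),
      .atom_row("HB", 0.05, "H"),
      .atom_row("OG1", -0.60, "O"),
      .atom_row("HG1", 0.40, "HP"),
      .atom_row("CG2", -0.15, "C"),
      .atom_row("HG21", 0.05, "H"),
      .atom_row("HG22", 0.05, "H"),
      .atom_row("HG23", 0.05, "H")
    ),
    ARG = dplyr::bind_rows(
      .atom_row("CB", -0.05, "C"),
      .atom_row("HB1", 0.03, "H"),
      .atom_row("HB2", 0.03, "H"),
      .atom_row("CG", -0.02, "C"),
      .atom_row("HG1", 0.03, "H"),
      .atom_row("HG2", 0.03, "H"),
      .atom_row("CD", 0.10, "C"),
      .atom_row("NE", -0.50, "N"),
      .atom_row("HE", 0.35, "HP"),
      .atom_row("CZ", 0.80, "C"),
      .atom_row("NH1", -0.60, "N"),
      .atom_row("HH11", 0.35, "HP"),
      .atom_row("HH12", 0.35, "HP"),
      .atom_row("NH2", -0.60, "N"),
      .atom_row("HH21", 0.35, "HP"),
      .atom_row("HH22", 0.35, "HP")
    ),
    ASP = dplyr::bind_rows(
      .atom_row("CB", -0.10, "C"),
      .atom_row("HB1", 0.05, "H"),
      .atom_row("HB2", 0.05, "H"),
      .atom_row("CG", 0.60, "C"),
      .atom_row("OD1", -0.80, "O"),
      .atom_row("OD2", -0.80, "O")
    )
  )
  lapply(side, function(s) dplyr::bind_rows(bb, s))
})

#' Constrained hydrogen bond lengths by atom label
#'
#' Bonds to hydrogen are treated as constrained; the mapping rule un-maps
#' any hydrogen pair whose constrained bond length differs between
#' endstates. Lengths depend on the parent heavy-atom element: 0.101 nm on
#' nitrogen, 0.109 nm on carbon, 0.096 nm on oxygen.
#'
#' @param type Three-letter residue type.
#' @return Named numeric vector, label -> constrained length (nm), one
#'   entry per hydrogen in the template.
#' @export
hydrogen_constraint_lengths <- function(type) {
  tpl <- residue_template(type)
  h <- tpl$name[!tpl$is_heavy]
  len <- vapply(h, function(nm) {
    if (nm == "H" || grepl("^H[HE]", nm)) 0.101      # on N
    else if (grepl("^HG1$", nm) && type %in% c("SER", "THR")) 0.096  # on O
    else if (nm == "HG" && type == "SER") 0.096
    else 0.109                                        # on C
  }, numeric(1))
  stats::setNames(len, h)
}

#' Within-residue bond list for a template
#'
#' Bead connectivity used to build valence terms and nonbonded exclusions.
#'
#' @param type Three-letter residue type.
#' @return Tibble with columns `a`, `b` (atom labels), `r0` (nm), `k`
#'   (kT/nm^2).
#' @export
residue_bonds <- function(type) {
  type <- toupper(type)
  bb <- list(
    c("N", "H"), c("N", "CA"), c("CA", "HA"), c("CA", "C"), c("C", "O")
  )
  side <- switch(type,
    ALA = list(c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"), c("CB", "HB3")),
    GLY = list(c("CA", "HA2")),
    SER = list(
      c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
      c("CB", "OG"), c("OG", "HG")
    ),
    THR = list(
      c("CA", "CB"), c("CB", "HB"), c("CB", "OG1"), c("OG1", "HG1"),
      c("CB", "CG2"), c("CG2", "HG21"), c("CG2", "HG22"), c("CG2", "HG23")
    ),
    ARG = list(
      c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"), c("CB", "CG"),
      c("CG", "HG1"), c("CG", "HG2"), c("CG", "CD"), c("CD", "NE"),
      c("NE", "HE"), c("NE", "CZ"), c("CZ", "NH1"), c("NH1", "HH11"),
      c("NH1", "HH12"), c("CZ", "NH2"), c("NH2", "HH21"), c("NH2", "HH22")
    ),
    ASP = list(
      c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
      c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")
    ),
    stop("unknown residue type: ", type, call. = FALSE)
  )
  all <- c(bb, side)
  tpl <- residue_template(type)
  hlen <- hydrogen_constraint_lengths(type)
  tibble::tibble(
    a = vapply(all, `[`, character(1), 1),
    b = vapply(all, `[`, character(1), 2)
  ) |>
    dplyr::mutate(
      r0 = dplyr::if_else(.data$b %in% names(hlen),
        unname(hlen[.data$b]), 0.15
      ),
      k = dplyr::if_else(.data$b %in% names(hlen), 5000, 2500)
    )
}
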