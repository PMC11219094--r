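test_that("atom mapping covers backbone plus CB and never beta hydrogens", {
  wt <- residue_template("ALA") |> dplyr::mutate(index = dplyr::row_number())
  mut <- residue_template("THR") |> dplyr::mutate(index = dplyr::row_number())
  hcl <- list(
    old = hydrogen_constraint_lengths("ALA"),
    new = hydrogen_constraint_lengths("THR")
  )
  am <- build_atom_map(wt, mut, hcl)
  expect_setequal(am$pairs$name, c("N", "H", "CA", "HA", "C", "O", "CB"))
  expect_equal(nrow(am$pairs), 7)
  expect_false(any(grepl("^HB", am$pairs$name)))
})

test_that("identity mapping covers everything except beta hydrogens", {
  thr <- residue_template("THR") |> dplyr::mutate(index = dplyr::row_number())
  hcl <- hydrogen_constraint_lengths("THR")
  am <- build_atom_map(thr, thr, hcl)
  expect_setequal(am$pairs$name, setdiff(thr$name, "HB"))
})

test_that("hydrogens with differing constrained bond lengths are un-mapped", {
  # HG1 sits on carbon in ARG (0.109 nm) but on oxygen in THR (0.096 nm)
  arg <- residue_template("ARG") |> dplyr::mutate(index = dplyr::row_number())
  thr <- residue_template("THR") |> dplyr::mutate(index = dplyr::row_number())
  hcl <- list(
    old = hydrogen_constraint_lengths("ARG"),
    new = hydrogen_constraint_lengths("THR")
  )
  am <- build_atom_map(arg, thr, hcl)
  expect_false("HG1" %in% am$pairs$name)
  expect_true("CB" %in% am$pairs$name)
})

test_that("mapping validates residue completeness and label uniqueness", {
  ala <- residue_template("ALA") |> dplyr::mutate(index = dplyr::row_number())
  no_cb <- ala |> dplyr::filter(name != "CB")
  expect_error(
    build_atom_map(ala, no_cb, hydrogen_constraint_lengths("ALA")),
    "CB"
  )
  dup <- dplyr::bind_rows(ala, ala[1, ])
  expect_error(
    build_atom_map(dup, ala, hydrogen_constraint_lengths("ALA")),
    "duplicate"
  )
  # glycine is exempt from the CB requirement
  gly <- residue_template("GLY") |> dplyr::mutate(index = dplyr::row_number())
  expect_silent(build_atom_map(
    ala, gly,
    list(
      old = hydrogen_constraint_lengths("ALA"),
      new = hydrogen_constraint_lengths("GLY")
    )
  ))
})

test_that("ARG->ALA unique atom sets match hand enumeration of templates", {
  h <- fixture_chain("ARG", "ALA")
  at <- h$atoms
  uo <- at$name[at$atom_class == "unique_old"]
  # all ARG side-chain atoms beyond CB, plus the beta hydrogens
  expect_setequal(uo, c(
    "HB1", "HB2", "CG", "HG1", "HG2", "CD", "NE", "HE", "CZ",
    "NH1", "HH11", "HH12", "NH2", "HH21", "HH22"
  ))
  un <- at$name[at$atom_class == "unique_new"]
  expect_setequal(un, c("HB1", "HB2", "HB3")) # ALA beta hydrogens
})

test_that("atom classes partition the atom set and follow flanking rules", {
  for (n_res in c(3, 5)) {
    site <- if (n_res == 3) 2 else 3
    h <- build_toy_system(
      make_bead_residue_chain(n_res, site, "ALA", "THR", seed = 4),
      phase = "apo"
    )
    at <- h$atoms
    expect_equal(sum(table(at$atom_class)), nrow(at))
    core_res <- sort(unique(at$residue_id[at$atom_class == "core"]))
    expect_equal(core_res, (site - 1):(site + 1))
    env_res <- unique(at$residue_id[at$atom_class == "environment"])
    expect_true(all(!env_res %in% (site - 1):(site + 1)))
    if (n_res == 5) {
      # residues 1 and 5 plus the water are environment
      expect_setequal(
        at$residue_id[at$atom_class == "environment"],
        c(rep(1L, 10), rep(5L, 10), max(at$residue_id))
      )
    }
  }
})

test_that("a system with no mutation is classified all-environment", {
  atoms <- tibble::tibble(
    index = 1:3, residue_id = c(1L, 2L, 3L), origin = "mapped"
  )
  am <- structure(
    list(pairs = tibble::tibble(), mutating_residue_id = 99L),
    class = "atom_map"
  )
  out <- classify_atoms(atoms, am)
  expect_true(all(out$atom_class == "environment"))
})

test_that("counterion transform restores endstate charge neutrality", {
  # ARG -> ALA: residue charge +1 -> 0, so dq = -1 and the water becomes
  # a +1 (sodium-like) ion at the mutant endstate
  h <- fixture_chain("ARG", "ALA")
  expect_equal(h$counterion$ion_charge, 1)
  expect_lt(abs(sum(h$atoms$charge_old) - sum(h$atoms$charge_new)), 1e-10)
  # ASP -> ALA: dq = +1, chloride-like ion
  h2 <- fixture_chain("ASP", "ALA")
  expect_equal(h2$counterion$ion_charge, -1)
  expect_lt(abs(sum(h2$atoms$charge_old) - sum(h2$atoms$charge_new)), 1e-10)
  # charge-preserving mutation leaves the topology unchanged
  h3 <- fixture_chain("ALA", "THR")
  expect_null(h3$counterion$water_index)
  # direct-summation oracle on the trio
  trio <- build_toy_system(make_charge_change_trio(1))
  expect_identical(sum(trio$atoms$charge_old), sum(trio$atoms$charge_new))
})

test_that("unsupported counterion transforms raise", {
  trio <- build_toy_system(make_charge_change_trio(1))
  # fabricate |dq| = 2
  bad <- trio
  bad$atoms$charge_new[1] <- -1
  bad$atoms$charge_new[4] <- 0
  bad$atoms$atom_class[4] <- "environment"
  expect_error(
    apply_counterion_transform(bad, 4L),
    "unsupported"
  )
  # dq != 0 with no water available
  bad2 <- trio
  bad2$atoms$charge_new[4] <- 0
  expect_error(
    apply_counterion_transform(bad2, integer(0)),
    "no water"
  )
})

test_that("forward and reverse builds have mirrored atom classes", {
  fwd <- fixture_chain("ALA", "THR")
  rev <- fixture_chain("THR", "ALA")
  expect_setequal(
    fwd$atoms$name[fwd$atoms$atom_class == "unique_old"],
    rev$atoms$name[rev$atoms$atom_class == "unique_new"]
  )
  expect_setequal(
    fwd$atoms$name[fwd$atoms$atom_class == "unique_new"],
    rev$atoms$name[rev$atoms$atom_class == "unique_old"]
  )
})

test_that("unique_old x unique_new pairs are always excluded", {
  for (h in list(fixture_chain("ALA", "THR"), fixture_chain("ARG", "ALA"))) {
    uo <- h$atoms$index[h$atoms$atom_class == "unique_old"]
    un <- h$atoms$index[h$atoms$atom_class == "unique_new"]
    key <- paste(h$exclusions[, 1], h$exclusions[, 2])
    for (i in uo) {
      for (j in un) {
        expect_true(paste(min(i, j), max(i, j)) %in% key)
      }
    }
  }
})

test_that("hybrid topologies round-trip through JSON", {
  h <- fixture_chain("ARG", "ALA")
  path <- withr::local_tempfile(fileext = ".json")
  write_hybrid_json(h, path)
  h2 <- read_hybrid_json(path)
  expect_equal(h2$atoms, h$atoms)
  expect_equal(h2$valence, h$valence)
  expect_equal(h2$exclusions, h$exclusions)
  expect_equal(h2$positions0, h$positions0, tolerance = 1e-12)
  expect_equal(
    h2$atom_map$mutating_residue_id,
    h$atom_map$mutating_residue_id
  )
})

test_that("validation catches violated invariants", {
  h <- fixture_chain("ALA", "THR")
  broken <- h
  broken$atoms$charge_new[broken$atoms$atom_class == "unique_old"][1] <- 0.1
  expect_error(validate_hybrid_topology(broken), "unique_old")
  broken2 <- h
  env_ix <- which(broken2$atoms$atom_class == "environment")[1]
  broken2$atoms$charge_new[env_ix] <- broken2$atoms$charge_new[env_ix] + 1
  expect_error(validate_hybrid_topology(broken2))
})
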