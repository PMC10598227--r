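test_that("the ideal helix reproduces the requested backbone torsions", {
  hel <- make_ideal_helix("AAKLLEAMVA", phi = -57, psi = -47)
  at <- hel$atoms
  xyz <- coords(hel)
  idx <- function(r, n) which(at$resno == r & at$atname == n)
  for (r in 2:9) {
    phi <- dihedral_angle(xyz[idx(r - 1, "C"), ], xyz[idx(r, "N"), ],
                          xyz[idx(r, "CA"), ], xyz[idx(r, "C"), ])
    expect_equal(phi, -57, tolerance = 0.5)
    psi <- dihedral_angle(xyz[idx(r, "N"), ], xyz[idx(r, "CA"), ],
                          xyz[idx(r, "C"), ], xyz[idx(r + 1, "N"), ])
    expect_equal(psi, -47, tolerance = 0.5)
  }
  expect_error(make_ideal_helix("AAA"), "at least 4")
  expect_error(make_ideal_helix("AAXB"), "unknown residue")
  gly <- make_ideal_helix("AAGA")
  expect_false(any(gly$atoms$resno == 3 & gly$atoms$atname == "CB"))
  # methyl-bearing residues carry the HB pseudo-methyl, others do not
  expect_equal(sum(hel$atoms$atname == "HB1"),
               sum(strsplit("AAKLLEAMVA", "")[[1L]] %in%
                     c("A", "V", "L", "I", "T", "M")))
})

test_that("the toy ligand is chiral, and R/S builds are exact mirrors", {
  ligS <- make_toy_ligand("S")
  ligR <- make_toy_ligand("R")
  expect_identical(chirality_sign(ligS$center, ligS$structure), "S_like")
  expect_identical(chirality_sign(ligR$center, ligR$structure), "R_like")
  expect_identical(ligS$structure$atoms$atname, ligR$structure$atoms$atname)
  # mirror the S build through z = 0: exactly the R coordinates
  xyz <- coords(ligS$structure)
  xyz[, 3L] <- -xyz[, 3L]
  expect_equal(xyz, coords(ligR$structure), tolerance = 1e-12)
  expect_equal(covalent_energy(ligS$structure, ligS$topology), 0,
               tolerance = 1e-9)
})

test_that("ligand impropers enforce the requested hand under minimization", {
  lig <- make_toy_ligand("S")
  start <- perturb_structure(lig$structure, 0.4, 77)
  fit <- minimize_structure(start, topology = lig$topology,
                            config = refine_config(max_iterations = 800L))
  expect_identical(chirality_sign(lig$center, fit$structure), "S_like")
  expect_lt(fit$breakdown$covalent, 0.05)
})

test_that("derived restraint classes are the tightest cover of the truth", {
  s_strong <- proton_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)),
                               names = c("HA", "HB2"),
                               resno = c(1L, 3L))
  rs <- derive_restraints(s_strong, cutoff = 5, ligand_chain = "L")
  expect_equal(nrow(rs$distance), 1L)
  expect_identical(rs$distance$intensity, "strong")  # upper 2.8 covers 2.5

  s_vw <- proton_structure(rbind(c(0, 0, 0), c(5.5, 0, 0)),
                           names = c("HA", "HB2"), resno = c(1L, 3L))
  rs2 <- derive_restraints(s_vw, cutoff = 6, ligand_chain = "L")
  expect_identical(rs2$distance$intensity, "very_weak")

  # geminal-range contacts below the universal 1.8 A floor are skipped
  s_close <- proton_structure(rbind(c(0, 0, 0), c(1.7, 0, 0)),
                              names = c("HA", "HB2"), resno = c(1L, 3L))
  expect_equal(nrow(derive_restraints(s_close, cutoff = 5,
                                      ligand_chain = "L")$distance), 0L)
  expect_error(derive_restraints(s_vw, cutoff = 6.5), "6.0")
})

test_that("the fixture truth satisfies every derived restraint exactly", {
  fx <- small_fixture()
  te <- total_energy(fx$truth, fx$restraints, fx$topology)
  expect_equal(te$total, 0, tolerance = 1e-9)
  te_sum <- total_energy(fx$truth, fx$restraints, fx$topology,
                         method = "r6_sum")
  expect_equal(te_sum$noe, 0, tolerance = 1e-9)
})

test_that("fixtures are deterministic and internally consistent", {
  cfg <- fixture_config(sequence = "AEKLLSAMVETIKGA", n_starts = 2L,
                        seed = 11L)
  fx1 <- make_fixture(cfg)
  fx2 <- make_fixture(cfg)
  expect_identical(coords(fx1$truth), coords(fx2$truth))
  expect_identical(fx1$restraints$distance, fx2$restraints$distance)
  expect_identical(coords(fx1$starts[[2L]]), coords(fx2$starts[[2L]]))
  expect_identical(fx1$manifest[["grand_total"]],
                   nrow(fx1$restraints$distance) +
                     nrow(fx1$restraints$dihedral))
})

test_that("raising the derivation cutoff never removes a restraint", {
  fx <- small_fixture()
  lo <- derive_restraints(fx$truth, cutoff = 4.0)
  hi <- derive_restraints(fx$truth, cutoff = 5.5)
  key <- function(d) paste(d$chain_i, d$resno_i, d$atom_i,
                           d$chain_j, d$resno_j, d$atom_j)
  expect_true(all(key(lo$distance) %in% key(hi$distance)))
  expect_gte(nrow(hi$distance), nrow(lo$distance))
})

test_that("widening noise never creates violations of the truth", {
  fx <- small_fixture()
  noisy <- derive_restraints(fx$truth, cutoff = 5, seed = 3L, noise = 0.5)
  rep <- violation_report(nmr_ensemble(list(fx$truth)), noisy)
  expect_equal(rep$distance$r6_average$max, 0)
  expect_equal(rep$distance$r6_sum$max, 0)
})

test_that("the default fixture meets its documented contact richness", {
  fx <- default_fixture()
  expect_gte(fx$manifest[["intermolecular"]], 10L)
  expect_gte(fx$manifest[["hydrogen_bond"]], 2L * 20L)
})

test_that("mirroring a fixture swaps the hand at identical energies", {
  fx <- small_fixture()
  fxm <- mirror_fixture(fx)
  expect_identical(fxm$config$ligand_handedness, "R")
  expect_identical(chirality_sign(fx$chiral_center, fxm$truth), "R_like")
  expect_equal(total_energy(fxm$truth, fxm$restraints, fxm$topology)$total,
               0, tolerance = 1e-9)
})
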