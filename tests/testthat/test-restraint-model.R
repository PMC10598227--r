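test_that("intensity classes carry the fixed bound table", {
  expect_equal(classify_intensity("strong"), c(lower = 1.8, upper = 2.8))
  expect_equal(classify_intensity("medium"), c(lower = 1.8, upper = 3.5))
  expect_equal(classify_intensity("weak"), c(lower = 1.8, upper = 5.0))
  expect_equal(classify_intensity("very_weak"), c(lower = 1.8, upper = 6.0))
  uppers <- vapply(c("strong", "medium", "weak", "very_weak"),
                   function(cl) classify_intensity(cl)[["upper"]],
                   numeric(1L))
  expect_true(all(diff(uppers) > 0))
  expect_error(classify_intensity("huge"), "huge")
  # inverse lookup: tightest class covering a measured distance
  expect_identical(intensity_for_distance(3.3), "medium")  # 3.3 <= 3.5
  expect_identical(intensity_for_distance(3.7), "weak")
  expect_identical(intensity_for_distance(c(2.0, 5.5)),
                   c("strong", "very_weak"))
  expect_error(intensity_for_distance(6.5), "6.0")
})

test_that("the TSV dialect parses published-style rows", {
  set <- parse_distance_table("F71 HE* HM* 4.5", "tsv_table1")
  r <- set$distance
  expect_equal(nrow(r), 1L)
  expect_equal(r$chain_i, "A")
  expect_equal(r$resno_i, 71L)
  expect_equal(r$resname_i, "PHE")
  expect_equal(r$atom_i, "HE*")
  expect_equal(r$chain_j, "L")
  expect_equal(r$atom_j, "HM*")
  expect_equal(c(r$lower, r$upper), c(1.8, 4.5))

  expect_equal(nrow(parse_distance_table("# only comments",
                                         "tsv_table1")$distance), 0L)
  expect_error(parse_distance_table("F71 HE* HM*", "tsv_table1"), "line 1")
  expect_error(parse_distance_table("F71 HE* HM* 1.7", "tsv_table1"),
               "1.8")
  expect_error(parse_distance_table("Z71 HE* HM* 4.5", "tsv_table1"),
               "residue letter")
})

test_that("the packaged intermolecular NOE table has 60 accounted rows", {
  set <- parse_distance_table(
    readLines(noetools_example("bcl2_intermolecular_noe.tsv")),
    "tsv_table1")
  expect_identical(attr(set, "raw_rows"), 60L)
  expect_true(all(set$distance$lower == 1.8))
  acc <- accounting(set, ligand_chain = "L")
  expect_identical(acc[["intermolecular"]], 60L)
  expect_identical(acc[["noe_total"]], 60L)
})

test_that("parse/write round trips are the identity in both dialects", {
  rows <- rbind(
    distance_restraint("A", 71, "HE*", "L", 1, "HM*", lower = 1.8,
                       upper = 4.5, resname_i = "PHE"),
    distance_restraint("A", 74, "HE*", "L", 1, "HK*", lower = 1.8,
                       upper = 6.5, resname_i = "MET"),
    distance_restraint("A", 88, "HA", "L", 1, "HJ*", lower = 1.8,
                       upper = 6.0, resname_i = "ARG"),
    distance_restraint("A", 92, "HG1*", "L", 1, "HL*", lower = 1.8,
                       upper = 3.8, resname_i = "VAL"),
    distance_restraint("A", 112, "HN", "L", 1, "HN*", lower = 1.8,
                       upper = 4.0, resname_i = "PHE"))
  set <- restraint_set(rows)

  tsv <- write_distance_table(set, "tsv_table1")
  back <- parse_distance_table(tsv, "tsv_table1")
  expect_equal(back$distance, set$distance, ignore_attr = TRUE)

  cns <- write_distance_table(set, "cns_tbl")
  back2 <- parse_distance_table(cns, "cns_tbl")
  for (col in c("chain_i", "resno_i", "atom_i", "chain_j", "resno_j",
                "atom_j"))
    expect_equal(back2$distance[[col]], set$distance[[col]])
  expect_equal(back2$distance$lower, set$distance$lower, tolerance = 1e-3)
  expect_equal(back2$distance$upper, set$distance$upper, tolerance = 1e-3)
})

test_that("TALOS records convert with the max(20, 1.5 sd) half-width rule", {
  rec <- data.frame(resno = c(10L, 11L, 12L),
                    phi = c(-65, -65, -60), psi = c(-40, -45, -42),
                    phi_sd = c(8, 20, 5), psi_sd = c(10, 30, 5),
                    usable = c(TRUE, TRUE, FALSE))
  dih <- talos_to_dihedrals(rec, residue_range = c(1L, 100L))
  expect_equal(nrow(dih), 4L)  # two usable records, phi + psi each
  phi10 <- dih[dih$angle_name == "phi" & dih$resno_2 == 10L, ]
  expect_equal(phi10$target, -65)
  expect_equal(phi10$half_width, 20)        # 1.5 * 8 = 12 < 20
  phi11 <- dih[dih$angle_name == "phi" & dih$resno_2 == 11L, ]
  expect_equal(phi11$half_width, 30)        # 1.5 * 20 = 30 > 20
  psi11 <- dih[dih$angle_name == "psi" & dih$resno_3 == 11L, ]
  expect_equal(psi11$half_width, 45)
  expect_true(all(dih$half_width >= 20))
  # phi atoms run C'(i-1), N, CA, C'
  expect_equal(unlist(phi10[paste0("atom_", 1:4)], use.names = FALSE),
               c("C", "N", "CA", "C"))
  expect_equal(phi10$resno_1, 9L)

  # records at the termini lack a flanking atom and are skipped
  term <- talos_to_dihedrals(data.frame(resno = 1L, phi = -60, psi = -45,
                                        phi_sd = 5, psi_sd = 5,
                                        usable = TRUE),
                             residue_range = c(1L, 50L))
  expect_equal(nrow(term), 1L)
  expect_identical(attr(term, "skipped")$angle, "phi")
})

test_that("read_talos parses the whitespace table and validates ranges", {
  txt <- c("# RESID PHI PSI DPHI DPSI CLASS",
           "10  -65.0 -40.0  8.0 10.0 Good",
           "11  -65.0 -45.0 20.0 30.0 Good",
           "12   60.0  40.0  5.0  5.0 Ambig")
  rec <- read_talos(text = txt)
  expect_equal(rec$usable, c(TRUE, TRUE, FALSE))
  expect_equal(rec$phi[1L], -65)
  expect_error(read_talos(text = "10 -190 0 5 5 Good"), "-180")
})

test_that("hydrogen bonds yield exactly paired H/O and N/O restraints", {
  one <- make_hbond_restraints(data.frame(chain_d = "A", resno_d = 5L,
                                          chain_a = "A", resno_a = 1L))
  expect_equal(nrow(one), 2L)
  expect_equal(one$atom_i, c("H", "N"))
  expect_equal(one$atom_j, c("O", "O"))
  expect_equal(one$lower, c(1.7, 2.7))
  expect_equal(one$upper, c(2.5, 3.5))
  expect_true(all(one$origin == "hbond"))

  many <- make_hbond_restraints(data.frame(chain_d = "A",
                                           resno_d = 5:62,
                                           chain_a = "A", resno_a = 1:58))
  expect_equal(nrow(many), 116L)   # 58 bonds -> 2 restraints each

  expect_equal(nrow(make_hbond_restraints(NULL)), 0L)
  expect_error(make_hbond_restraints(
    data.frame(chain_d = "A", resno_d = 5L, chain_a = "A", resno_a = 1L,
               h_atom = "H*")), "wildcard")
})

test_that("categorization follows origin, chain and residue separation", {
  mk <- function(ri, rj, chain_j = "A", origin = "noe") {
    distance_restraint("A", ri, "H", chain_j, rj, "HM*", lower = 1.8,
                       upper = 5, origin = origin)
  }
  expect_identical(as.character(categorize(mk(71, 1, "L"), "L")),
                   "intermolecular")
  expect_identical(as.character(categorize(mk(10, 13), "L")),
                   "medium_range")
  expect_identical(as.character(categorize(mk(10, 10), "L")),
                   "intra_residue")
  expect_identical(as.character(categorize(mk(10, 11), "L")), "sequential")
  expect_identical(as.character(categorize(mk(10, 16), "L")), "long_range")
  hb <- make_hbond_restraints(data.frame(chain_d = "A", resno_d = 5L,
                                         chain_a = "A", resno_a = 1L))
  expect_true(all(categorize(hb, "L") == "hydrogen_bond"))
  lig_lig <- distance_restraint("L", 1, "HM*", "L", 1, "HK*", lower = 1.8,
                                upper = 5)
  expect_error(categorize(lig_lig, "L"), "intra-ligand")
})

test_that("accounting conserves counts on derived restraint sets", {
  fx <- small_fixture()
  acc <- accounting(fx$restraints, ligand_chain = "L")
  expect_identical(acc[["grand_total"]],
                   nrow(fx$restraints$distance) +
                     nrow(fx$restraints$dihedral))
  expect_identical(acc[["inter_residue_total"]],
                   acc[["sequential"]] + acc[["medium_range"]] +
                     acc[["long_range"]])
  expect_identical(acc[["noe_total"]],
                   acc[["inter_residue_total"]] + acc[["intra_residue"]] +
                     acc[["intermolecular"]])
  expect_identical(acc[["grand_total"]],
                   acc[["noe_total"]] + acc[["dihedral_total"]] +
                     acc[["hydrogen_bond"]])
  empty <- accounting(restraint_set(), ligand_chain = "L")
  expect_true(all(empty == 0L))
})

test_that("residue-name mismatches against coordinates warn, not fail", {
  fx <- small_fixture()
  wrong <- restraint_set(distance_restraint("A", 4L, "H", "L", 1L, "HM*",
                                            lower = 1.8, upper = 5,
                                            resname_i = "TRP"))
  expect_warning(check_restraint_residues(wrong, fx$truth), "mismatch")
  ok <- restraint_set(distance_restraint("A", 4L, "H", "L", 1L, "HM*",
                                         lower = 1.8, upper = 5,
                                         resname_i = "LEU"))
  expect_silent(check_restraint_residues(ok, fx$truth))
})
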