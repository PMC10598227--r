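test_that("the violation report is all-zero on the fixture truth", {
  fx <- small_fixture()
  rep <- violation_report(nmr_ensemble(list(fx$truth, fx$truth)),
                          fx$restraints)
  for (m in c("r6_average", "r6_sum")) {
    expect_equal(rep$distance[[m]]$max, 0)
    expect_equal(rep$distance[[m]]$mean, 0)
    expect_equal(rep$distance[[m]]$n_above, 0L)
  }
  expect_equal(rep$dihedral$max, 0)
  expect_equal(nrow(rep$skipped), 0L)
})

test_that("single-restraint violations are counted against the threshold", {
  s <- proton_structure(rbind(c(0, 0, 0), c(3.6, 0, 0)))
  r <- restraint_set(distance_restraint("A", 1, "H1", "A", 1, "H2",
                                        lower = 1.8, upper = 3.3))
  rep <- violation_report(nmr_ensemble(list(s)), r)
  expect_equal(rep$distance$r6_average$max, 0.3, tolerance = 1e-12)
  expect_equal(rep$distance$r6_average$n_above, 1L)
  expect_equal(rep$distance$r6_sum$max, 0.3, tolerance = 1e-12)
})

test_that("the two conventions order upper-bound violations consistently", {
  # r6_sum effective distances never exceed r6_average ones, so against
  # upper bounds the averaged convention flags at least as many cells;
  # the report's counts and extrema must agree with its matrices
  fx <- small_fixture()
  for (seed in c(3L, 9L, 27L)) {
    ens <- nmr_ensemble(lapply(1:3, function(k)
      perturb_structure(fx$truth, 0.5, seed + k)))
    rep <- violation_report(ens, fx$restraints)
    lower_hit <- any(rep$distance$r6_sum$matrix >
                       rep$distance$r6_average$matrix + 1e-9)
    if (!lower_hit) {
      expect_gte(rep$distance$r6_average$n_above,
                 rep$distance$r6_sum$n_above)
      expect_gte(rep$distance$r6_average$max, rep$distance$r6_sum$max)
    }
    for (m in c("r6_average", "r6_sum")) {
      s <- rep$distance[[m]]
      expect_equal(s$max, max(s$matrix))
      expect_identical(s$n_above, sum(s$matrix > s$threshold))
      expect_equal(s$per_model_mean, colMeans(s$matrix))
    }
  }
})

test_that("unresolvable selectors are skipped with a reason, not fatal", {
  fx <- small_fixture()
  odd <- rbind(fx$restraints$distance[1:3, ],
               distance_restraint("A", 2L, "HQ*", "L", 1L, "HM*",
                                  lower = 1.8, upper = 5))
  rep <- violation_report(nmr_ensemble(list(fx$truth)),
                          restraint_set(odd))
  expect_equal(nrow(rep$skipped), 1L)
  expect_match(rep$skipped$reason, "HQ")
  expect_equal(length(rep$distance$restraint_index), 3L)
})

test_that("report serialization round-trips the summary numbers", {
  fx <- small_fixture()
  ens <- nmr_ensemble(lapply(1:2, function(k)
    perturb_structure(fx$truth, 0.3, k)))
  rep <- violation_report(ens, fx$restraints)
  path <- tempfile(fileext = ".tsv")
  write_violation_report(rep, path)
  tab <- read.delim(path)
  expect_equal(tab$max[tab$block == "distance_r6_average"],
               rep$distance$r6_average$max, tolerance = 1e-6)
  expect_equal(nrow(tab), 3L)
})

test_that("region rmsd tables are model-order invariant", {
  fx <- small_fixture()
  models <- lapply(1:4, function(k) perturb_structure(fx$truth, 0.4, k))
  sels <- list(core = atom_selection("A", cbind(4L, 12L)),
               full = atom_selection("A", cbind(1L, 15L)))
  t1 <- region_rmsd_table(nmr_ensemble(models), sels)
  t2 <- region_rmsd_table(nmr_ensemble(rev(models)), sels)
  expect_equal(t1$backbone_rmsd, t2$backbone_rmsd, tolerance = 1e-12)
  expect_equal(t1$heavy_rmsd, t2$heavy_rmsd, tolerance = 1e-12)
  expect_true(all(t1$backbone_rmsd > 0))
  same <- region_rmsd_table(nmr_ensemble(list(fx$truth, fx$truth)), sels)
  expect_equal(same$backbone_rmsd, c(0, 0), tolerance = 1e-12)
  expect_equal(same$heavy_rmsd, c(0, 0), tolerance = 1e-12)
  expect_error(region_rmsd_table(nmr_ensemble(models),
                                 list(atom_selection("A", cbind(1, 5)))),
               "named")
})

test_that("contact sites follow the heavy-atom cutoff convention", {
  fx <- small_fixture()
  lig_sel <- atom_selection("L", cbind(1L, 1L), "all")
  site <- contact_residues(fx$truth, lig_sel, cutoff = 4.5)
  expect_gt(nrow(site), 0L)
  expect_true(all(site$chain == "A"))

  # independent oracle: explicit double loop over heavy atoms
  at <- fx$truth$atoms
  xyz <- coords(fx$truth)
  heavy <- !grepl("^[0-9]*H", at$atname)
  lig <- which(heavy & at$chain == "L")
  prot <- which(heavy & at$chain == "A")
  hits <- unique(at$resno[prot][vapply(prot, function(p)
    any(sqrt(colSums((t(xyz[lig, , drop = FALSE]) - xyz[p, ])^2)) <= 4.5),
    logical(1L))])
  expect_setequal(site$resno, hits)

  wide <- contact_residues(fx$truth, lig_sel, cutoff = 5.5)
  expect_true(all(paste(site$chain, site$resno) %in%
                    paste(wide$chain, wide$resno)))

  far <- fx$truth
  moved <- coords(far)
  moved[at$chain == "L", ] <- moved[at$chain == "L", ] + 100
  expect_equal(nrow(contact_residues(set_coords(far, moved), lig_sel)), 0L)
})

test_that("site overlap computes the jaccard index and unique fraction", {
  mk_site <- function(res) {
    out <- data.frame(chain = rep("A", length(res)), resno = res,
                      resname = rep("ALA", length(res)))
    class(out) <- c("contact_site", "data.frame")
    out
  }
  same <- site_overlap(mk_site(1:5), mk_site(1:5))
  expect_equal(same$jaccard, 1)
  expect_equal(same$fraction_a_unique, 0)
  disj <- site_overlap(mk_site(1:3), mk_site(7:9))
  expect_equal(disj$jaccard, 0)
  expect_equal(disj$fraction_a_unique, 1)
  ab <- site_overlap(mk_site(1:4), mk_site(3:6))
  expect_equal(ab$jaccard, 2 / 6)
  expect_equal(ab$fraction_a_unique, 2 / 4)
  ba <- site_overlap(mk_site(3:6), mk_site(1:4))
  expect_equal(ba$jaccard, ab$jaccard)
  expect_error(site_overlap(mk_site(integer(0L)), mk_site(integer(0L))),
               "empty")
})

test_that("selection strings parse into chain, ranges and atom set", {
  sel <- parse_selection("A:10-31,47-176@backbone")
  expect_equal(sel$chain, "A")
  expect_equal(unname(sel$ranges),
               matrix(c(10L, 47L, 31L, 176L), 2L), ignore_attr = TRUE)
  expect_equal(sel$atoms, "backbone")
  expect_error(atom_selection("A", rbind(c(10, 31), c(20, 40))), "overlap")
  expect_error(parse_selection("10-31"), "CHAIN")
})
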