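test_that("selector expansion is the Cartesian product of the match sets", {
  s <- proton_structure(matrix(rnorm(30), 10L, 3L),
                        names = c("HD11", "HD12", "HD13", "HG11", "HG12",
                                  "HG13", "HG21", "HG22", "HG23", "HZ"))
  lig <- proton_structure(matrix(rnorm(9) + 10, 3L, 3L),
                          names = c("HM1", "HM2", "HM3"), chain = "L")
  both <- nmr_structure(rbind(s$atoms, lig$atoms))
  p1 <- expand_pair(atom_selector("A", 1, "HD1*"),
                    atom_selector("L", 1, "HM1"), both)
  expect_equal(nrow(p1), 3L)
  p2 <- expand_pair(atom_selector("A", 1, "HZ"),
                    atom_selector("L", 1, "HM1"), both)
  expect_equal(nrow(p2), 1L)
  p3 <- expand_pair(atom_selector("A", 1, "HG*"),
                    atom_selector("L", 1, "HM*"), both)
  expect_equal(nrow(p3), 18L)   # 6 x 3
  expect_error(expand_pair(atom_selector("A", 1, "HQ*"),
                           atom_selector("L", 1, "HM*"), both),
               "HQ\\*")
})

test_that("selector invariants reject malformed patterns", {
  expect_error(atom_selector("A", 1, ""), "non-empty")
  expect_error(atom_selector("A", 1, "H*1"), "terminal")
  expect_error(atom_selector("A", 1, "H**"), "one wildcard")
  expect_error(atom_selector("A", 0, "H"), ">= 1")
})

test_that("effective distances follow the two averaging conventions", {
  s <- proton_structure(rbind(c(0, 0, 0), c(3.30, 0, 0)))
  p <- cbind(1L, 2L)
  expect_equal(effective_distance(p, s, "r6_average"), 3.30)
  expect_equal(effective_distance(p, s, "r6_sum"), 3.30)

  # frozen from an independent high-precision evaluation of the formulas
  s2 <- proton_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0)))
  p2 <- cbind(1L, 2:3)
  expect_equal(effective_distance(p2, s2, "r6_average"), 2.2391306,
               tolerance = 1e-6)
  expect_equal(effective_distance(p2, s2, "r6_sum"), 1.9948386,
               tolerance = 1e-6)

  # N identical distances: average is d, sum is d * N^(-1/6)
  d <- 2.7
  sN <- proton_structure(rbind(c(0, 0, 0), c(d, 0, 0), c(-d, 0, 0),
                               c(0, d, 0), c(0, -d, 0)))
  pN <- cbind(1L, 2:5)
  expect_equal(effective_distance(pN, sN, "r6_average"), d)
  expect_equal(effective_distance(pN, sN, "r6_sum"), d * 4^(-1 / 6))

  expect_error(effective_distance(cbind(1L, 1L), s, "r6_average"),
               "coincident")
})

test_that("r6 conventions satisfy their exact relations and bounds", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(1:6, 1L)
    xyz <- rbind(c(0, 0, 0), matrix(rnorm(3 * n, sd = 3), n, 3L))
    d <- sqrt(rowSums(xyz[-1L, , drop = FALSE]^2))
    if (any(d < 1e-3)) next
    s <- proton_structure(xyz)
    p <- cbind(1L, seq_len(n) + 1L)
    avg <- effective_distance(p, s, "r6_average")
    ssum <- effective_distance(p, s, "r6_sum")
    # independent naive re-evaluation by explicit loop
    acc <- 0
    for (k in seq_len(n)) acc <- acc + d[k]^(-6)
    expect_equal(avg, (acc / n)^(-1 / 6), tolerance = 1e-9)
    expect_equal(ssum, acc^(-1 / 6), tolerance = 1e-9)
    # closed-form link and ordering
    expect_equal(avg, n^(1 / 6) * ssum, tolerance = 1e-12)
    expect_true(ssum <= avg + 1e-12)
    expect_true(ssum <= min(d) + 1e-12)
    expect_true(avg <= max(d) + 1e-12)
    # homogeneity under coordinate scaling
    s3 <- proton_structure(xyz * 2.5)
    expect_equal(effective_distance(p, s3, "r6_average"), 2.5 * avg,
                 tolerance = 1e-12)
  }
})

test_that("distance violations measure the excess outside the bounds", {
  s <- proton_structure(rbind(c(0, 0, 0), c(3.5, 0, 0)))
  r_hi <- distance_restraint("A", 1, "H1", "A", 1, "H2", lower = 1.8,
                             upper = 3.3)
  expect_equal(distance_violation(r_hi, s), 0.2)
  r_ok <- distance_restraint("A", 1, "H1", "A", 1, "H2", lower = 1.8,
                             upper = 4.5)
  expect_equal(distance_violation(r_ok, s), 0)
  s_close <- proton_structure(rbind(c(0, 0, 0), c(1.6, 0, 0)))
  expect_equal(distance_violation(r_ok, s_close), 0.2, tolerance = 1e-12)
})

test_that("dihedral angles use the IUPAC sign convention and wrap", {
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                              c(1, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                  c(-1, 1, 0))), 180)
  set.seed(5)
  p <- matrix(rnorm(12), 4L, 3L)
  a <- dihedral_angle(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
  pm <- p
  pm[, 3L] <- -pm[, 3L]  # mirror through z = 0
  expect_equal(dihedral_angle(pm[1L, ], pm[2L, ], pm[3L, ], pm[4L, ]), -a,
               tolerance = 1e-9)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("dihedral violations wrap into (-180, 180]", {
  mk <- function(target, hw) dihedral_restraint("A", rep(1L, 4L),
                                                c("H1", "H2", "H3", "H4"),
                                                target, hw)
  obs_structure <- function(angle) {
    d <- place_for_angle(angle)
    proton_structure(d)
  }
  # build four points realizing a requested torsion about the z axis
  place_for_angle <- function(angle) {
    rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
          c(cos(angle * pi / 180), sin(angle * pi / 180), 1))
  }
  s <- obs_structure(-175)
  expect_equal(dihedral_violation(mk(170, 20), s), 0)      # wrapped diff 15
  s2 <- obs_structure(25)
  expect_equal(dihedral_violation(mk(0, 20), s2), 5, tolerance = 1e-9)
  # full-turn shifts of the observed angle leave the violation unchanged
  expect_equal(wrap_angle(c(385, -335, 25)), c(25, 25, 25))
  expect_equal(wrap_angle(-180), 180)
})

test_that("chirality labels follow the triple-product convention", {
  a <- 1 / sqrt(3)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(-a, -a, -a))
  s <- proton_structure(xyz, names = c("C", "S1", "S2", "S3", "S4"))
  ctr <- chiral_center(atom_selector("A", 1, "C"),
                       lapply(paste0("S", 1:4),
                              function(n) atom_selector("A", 1, n)))
  # triple product (r1-r4).[(r2-r4)x(r3-r4)] = 1 + 3/sqrt(3) > 0
  expect_identical(chirality_sign(ctr, s), "S_like")

  set.seed(8)
  R <- random_rotation()
  s_rot <- transform_structure(s, R, c(3, -2, 7))
  expect_identical(chirality_sign(ctr, s_rot), "S_like")

  xyz_m <- xyz
  xyz_m[, 1L] <- -xyz_m[, 1L]
  expect_identical(chirality_sign(ctr, proton_structure(
    xyz_m, names = c("C", "S1", "S2", "S3", "S4"))), "R_like")

  flat <- proton_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(1, 1, 0), c(-1, -1, 0)),
                           names = c("C", "S1", "S2", "S3", "S4"))
  expect_error(chirality_sign(ctr, flat), "planar")
})

test_that("superposition returns a proper rotation and the least-squares rmsd", {
  fx <- small_fixture()
  s <- fx$truth
  set.seed(21)
  R <- random_rotation()
  moved <- transform_structure(s, R, c(5, -3, 2))
  fit <- superpose(moved, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  noisy <- perturb_structure(s, 0.8, 99)
  f1 <- superpose(noisy, s)
  f2 <- superpose(s, noisy)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-9)
  # rmsd is invariant when either input is rigidly moved
  f3 <- superpose(transform_structure(noisy, random_rotation(), c(1, 2, 3)),
                  s)
  expect_equal(f3$rmsd, f1$rmsd, tolerance = 1e-9)

  # independent oracle: bio3d's Kabsch fit on the same coordinates
  bf <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(coords(s))),
                   mobile = as.numeric(t(coords(noisy)))))
  expect_equal(f1$rmsd,
               sqrt(mean(rowSums((matrix(bf, ncol = 3L, byrow = TRUE) -
                                  coords(s))^2))),
               tolerance = 1e-6)
})

test_that("two-point superposition recovers the hand-derived rmsd", {
  a <- proton_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  b <- proton_structure(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(superpose(a, b)$rmsd, 1.0, tolerance = 1e-9)
})

test_that("superposition errors name the first atom-list disagreement", {
  fx <- small_fixture()
  other <- fx$truth
  other$atoms$atname[5L] <- "XX"
  expect_error(superpose(nmr_structure(other$atoms), fx$truth),
               "disagreement")
})

test_that("mean pairwise rmsd averages independently fitted pairs", {
  fx <- small_fixture()
  s <- fx$truth
  ens_same <- nmr_ensemble(list(s, s, s))
  expect_equal(mean_pairwise_rmsd(ens_same), 0, tolerance = 1e-12)

  m1 <- perturb_structure(s, 0.4, 1)
  m2 <- perturb_structure(s, 0.4, 2)
  m3 <- perturb_structure(s, 0.4, 3)
  sel <- atom_selection("A", cbind(1, 15), "backbone")
  two <- nmr_ensemble(list(m1, m2))
  expect_equal(mean_pairwise_rmsd(two, sel),
               superpose(m1, m2, sel)$rmsd, tolerance = 1e-12)
  a <- superpose(m1, m2, sel)$rmsd
  b <- superpose(m1, m3, sel)$rmsd
  c0 <- superpose(m2, m3, sel)$rmsd
  expect_equal(mean_pairwise_rmsd(nmr_ensemble(list(m1, m2, m3)), sel),
               (a + b + c0) / 3, tolerance = 1e-12)
  expect_error(mean_pairwise_rmsd(nmr_ensemble(list(m1))), "two models")
})
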