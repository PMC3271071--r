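test_that("dihedral_angle handles planar cis, trans and perpendicular cases", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  # hand evaluation of the atan2 cross-product formula:
  # b1=(1,0,0), b2=(0,1,0), b3=(0,0,1); n1=(0,0,1), n2=(1,0,0);
  # x = n1.n2 = 0, y = (n1 x n2).b2hat = +1  ->  +90 degrees
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               90)
})

test_that("dihedral_angle matches an established torsion implementation", {
  set.seed(11)
  for (rep in 1:20) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    ours <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(pts)))
    expect_equal(ours, wrap_angle(ref), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("dihedral_angle symmetry properties hold on random points", {
  set.seed(21)
  for (rep in 1:50) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    ang <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_gt(ang, -180)
    expect_lte(ang, 180)
    # reversing the point order preserves the angle
    expect_equal(dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ]), ang,
                 tolerance = 1e-9)
    # mirroring (z -> -z) negates it (modulo the 180 == -180 identity)
    mir <- pts
    mir[, 3] <- -mir[, 3]
    expect_equal(dihedral_angle(mir[1, ], mir[2, ], mir[3, ], mir[4, ]),
                 wrap_angle(-ang), tolerance = 1e-9)
  }
})

test_that("degenerate dihedral geometry is an error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "phipsi_degenerate_dihedral")
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               class = "phipsi_degenerate_dihedral")
})

test_that("chain torsions follow the boundary rules", {
  one <- build_peptide(c(NA, -60), c(-40, NA))[1, ]
  t1 <- compute_backbone_torsions(one)
  expect_equal(nrow(t1), 1)
  expect_true(is.na(t1$phi) && is.na(t1$psi))

  three <- build_peptide(c(0, -60, -70), c(-40, -45, 0))
  t3 <- compute_backbone_torsions(three)
  expect_true(is.na(t3$phi[1]) && is.na(t3$psi[3]))
  expect_false(anyNA(c(t3$phi[2:3], t3$psi[1:2])))

  # n complete residues -> exactly n-1 defined phi and psi
  n <- 8
  bb <- build_peptide(rep(-57, n), rep(-47, n))
  tt <- compute_backbone_torsions(bb)
  expect_equal(sum(!is.na(tt$phi)), n - 1)
  expect_equal(sum(!is.na(tt$psi)), n - 1)
})

test_that("an ideal helix fragment yields phi ~ -57, psi ~ -47", {
  bb <- build_peptide(rep(-57, 7), rep(-47, 7))
  tt <- compute_backbone_torsions(bb)
  internal <- 2:6
  expect_true(all(abs(tt$phi[internal] - (-57)) < 2))
  expect_true(all(abs(tt$psi[internal] - (-47)) < 2))
})

test_that("incomplete residues propagate undefined angles with a warning", {
  bb <- build_peptide(rep(-57, 5), rep(-47, 5))
  bb$ca_x[3] <- NA
  expect_warning(tt <- compute_backbone_torsions(bb), "missing backbone")
  expect_true(is.na(tt$phi[3]) && is.na(tt$psi[3]))
  # neighbours relying on residue 3 atoms are undefined too
  expect_true(is.na(tt$psi[2]) && is.na(tt$phi[4]))
  expect_false(is.na(tt$phi[2]))
})

test_that("PDB backbones read through the file path give the same torsions", {
  bb <- build_peptide(rep(-60, 6), rep(130, 6), resname = "GLY")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb_fixture(bb, path)
  got <- read_backbone_pdb(path)
  expect_equal(nrow(got), 6)
  expect_true(all(got$complete))
  tt <- compute_backbone_torsions(got)
  expect_equal(tt$phi[2:6], rep(-60, 5), tolerance = 1e-2)
  expect_equal(tt$psi[1:5], rep(130, 5), tolerance = 1e-2)
  expect_equal(tt$aa, rep("G", 6))
})

test_that("normalizer fitting validates its inputs", {
  expect_error(fit_angle_normalizer(rep(-70, 5), rnorm(5)), "variance")
  expect_error(fit_angle_normalizer(-70, c(-40, 10)), "at least two")
  norm <- fit_angle_normalizer(c(-60, -80), c(100, 140))
  expect_equal(norm$mu[["phi"]], -70)
  expect_equal(norm$sigma[["phi"]], sd(c(-60, -80)))
})

test_that("normalization maps mean to 0.5 and +3 sigma to 1", {
  set.seed(5)
  phi <- rnorm(200, -70, 25)
  psi <- rnorm(200, 40, 60)
  norm <- fit_angle_normalizer(phi, psi)
  expect_equal(mean(normalize_angle(phi, "phi", norm)), 0.5)
  expect_equal(normalize_angle(norm$mu[["psi"]], "psi", norm), 0.5)
  expect_equal(
    normalize_angle(norm$mu[["phi"]] + 3 * norm$sigma[["phi"]], "phi", norm),
    1.0)
})

test_that("normalize and denormalize are mutual inverses", {
  norm <- fit_angle_normalizer(c(-100, -40, -70), c(120, 160, 100))
  theta <- seq(-179, 180, by = 7.3)
  expect_equal(denormalize_angle(normalize_angle(theta, "phi", norm),
                                 "phi", norm),
               theta, tolerance = 1e-9)
  # forward direction when no wrap occurs
  v <- seq(0.15, 0.75, by = 0.05)
  expect_equal(normalize_angle(denormalize_angle(v, "psi", norm),
                               "psi", norm),
               v, tolerance = 1e-9)
})

test_that("denormalized values beyond 180 wrap onto the legal circle", {
  norm <- fit_angle_normalizer(c(70, 130), c(0, 1), span = 6)
  # mu_phi = 100, sigma ~ 42.4; v = 1 -> 100 + 3 sigma = 227.3 -> wraps
  v <- normalize_angle(190, "phi", norm)
  expect_equal(denormalize_angle(v, "phi", norm), -170, tolerance = 1e-9)
  expect_true(all(denormalize_angle(runif(100, -2, 3), "phi", norm) > -180))
  expect_true(all(denormalize_angle(runif(100, -2, 3), "phi", norm) <= 180))
})

test_that("angular difference handles wrap-around and both modes", {
  expect_equal(angular_difference(10, 10), 0)
  expect_equal(angular_difference(-175, 175), 10)
  expect_equal(angular_difference(-175, 175, "linear"), 350)
  expect_equal(angular_difference(179, -179), 2)
})

test_that("circular angular difference is a metric on the 1-degree grid", {
  grid <- seq(-179, 180)
  # symmetry, exhaustively on the full grid
  d1 <- outer(grid, grid, angular_difference)
  expect_true(all(d1 == t(d1)))
  expect_true(all(d1 >= 0 & d1 <= 180))
  expect_true(all(diag(d1) == 0))
  # triangle inequality on a coarse full grid plus random 1-degree triples
  coarse <- seq(-180, 170, by = 30)
  for (a in coarse) for (b in coarse) {
    dab <- angular_difference(a, b)
    expect_true(all(dab <= angular_difference(a, grid) +
                      angular_difference(grid, b) + 1e-12))
  }
  set.seed(3)
  for (rep in 1:2000) {
    abc <- sample(grid, 3, replace = TRUE)
    expect_lte(angular_difference(abc[1], abc[3]),
               angular_difference(abc[1], abc[2]) +
                 angular_difference(abc[2], abc[3]) + 1e-12)
  }
})
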