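test_that("signed plane offset matches its construction and the brute-force oracle", {
  site <- toy_site()
  # in-plane probe
  fr0 <- gen_thioester_frame(toy_geometry_spec(offset = 0, angle = 90,
                                               n_decoys = 0))
  expect_equal(signed_plane_offset(fr0, site), 0, tolerance = 1e-9)
  # prescribed positive offset along the oriented normal
  fr3 <- gen_thioester_frame(toy_geometry_spec(offset = 3, angle = 120,
                                               n_decoys = 0))
  expect_equal(signed_plane_offset(fr3, site), 3, tolerance = 1e-9)
  frm <- gen_thioester_frame(toy_geometry_spec(offset = -2.25, angle = 70,
                                               n_decoys = 0))
  expect_equal(signed_plane_offset(frm, site), -2.25, tolerance = 1e-9)
  # 100 seeded random configurations against the explicit oracle
  set.seed(31)
  for (i in 1:100) {
    off <- runif(1, -8, 8); ang <- runif(1, 5, 175)
    fr <- gen_thioester_frame(toy_geometry_spec(offset = off, angle = ang,
                                                n_decoys = 0, seed = i))
    fr <- rigid_transform(fr, seed = 1000 + i)
    xyz <- function(sel) {
      p <- strsplit(sel, ":")[[1]]
      as.numeric(fr[fr$chain == p[1] & fr$resno == as.integer(p[2]) &
                      fr$atom == p[3], c("x", "y", "z")])
    }
    want <- oracle_plane_offset(xyz("A:87:SG"), xyz("B:76:C"),
                                xyz("B:76:O"), xyz("A:94:NE2"),
                                xyz("W:500:O"))
    expect_equal(signed_plane_offset(fr, site), want, tolerance = 1e-10)
  }
})

test_that("plane offset changes sign under reflection of the probe", {
  site <- toy_site()
  fr <- gen_thioester_frame(toy_geometry_spec(offset = 2.4, angle = 100,
                                              n_decoys = 0))
  d1 <- signed_plane_offset(fr, site)
  refl <- fr
  ne_row <- refl$atom == "NE2" & refl$resno == 94
  refl$z[ne_row] <- -refl$z[ne_row]   # plane is z = 0 in the toy build
  expect_equal(signed_plane_offset(refl, site), -d1, tolerance = 1e-9)
  # collinear plane atoms are rejected
  degen <- fr
  degen[degen$atom == "O" & degen$resno == 76, c("x", "y", "z")] <-
    2 * degen[degen$atom == "C" & degen$resno == 76, c("x", "y", "z")]
  expect_error(signed_plane_offset(degen, site), "collinear")
})

test_that("orientation angle reproduces constructions and the law of cosines", {
  site <- toy_site()
  for (ang in c(30, 90, 120, 180)) {
    fr <- gen_thioester_frame(toy_geometry_spec(offset = 1.5, angle = ang,
                                                n_decoys = 0))
    expect_equal(orientation_angle(fr, site), ang, tolerance = 1e-6)
  }
  set.seed(57)
  masses <- c(N = 14.007, C = 12.011)
  for (i in 1:40) {
    fr <- gen_thioester_frame(toy_geometry_spec(
      offset = runif(1, -5, 5), angle = runif(1, 10, 170),
      n_decoys = 0, seed = i))
    fr <- rigid_transform(fr, seed = 2000 + i)
    ring <- fr[fr$resid == "HIS", ]
    m <- masses[ring$elem]
    com <- colSums(as.matrix(ring[, c("x", "y", "z")]) * m) / sum(m)
    ne <- as.numeric(fr[fr$atom == "NE2" & fr$resno == 94,
                        c("x", "y", "z")])
    cc <- as.numeric(fr[fr$atom == "C" & fr$resno == 76,
                        c("x", "y", "z")])
    expect_equal(orientation_angle(fr, site),
                 oracle_angle_lawcos(com, ne, cc), tolerance = 1e-9)
  }
})

test_that("base-catalysis classification applies the offset and angle windows", {
  expect_true(classify_base_catalysis(3.0, 150))
  expect_false(classify_base_catalysis(10, 150))
  expect_false(classify_base_catalysis(3.0, 30))
  flags <- classify_base_catalysis(c(1, -2, 5, 3.4), c(120, 95, 120, 89))
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE))
  # ensemble fraction equals the construction ratio
  site <- toy_site()
  offs <- c(1, 2, 3, 6, 8)
  frames <- lapply(offs, function(o)
    gen_thioester_frame(toy_geometry_spec(offset = o, angle = 130,
                                          n_decoys = 0)))
  rep <- geometry_report(frames, site)
  expect_equal(mean(rep$compatible), 3 / 5)
  expect_equal(rep$offset_A, offs, tolerance = 1e-9)
})

test_that("dihedral angles match constructions and the projection oracle", {
  # eclipsed (cis) and anti (trans) constructions
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 180, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:100) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    # guard against near-collinear degeneracy
    ok <- try(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
              silent = TRUE)
    if (inherits(ok, "try-error")) next
    want <- oracle_dihedral_project(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(ok, want, tolerance = 1e-9)
  }
})

test_that("side-chain chi1/chi2 follow the N-CA-CB-CG / CA-CB-CG-ND1 definition", {
  his <- quick_frame(
    atom = c("N", "CA", "CB", "CG", "ND1"), resid = "HIS", resno = 94L,
    chain = "A", elem = c("N", "C", "C", "C", "N"),
    x = c(0, 1.46, 2.0, 1.45, 2.1),
    y = c(0, 0, 1.3, 2.55, 3.7),
    z = c(0, 0, 0.4, -0.2, 0.5))
  chi <- sidechain_dihedrals(his, "A:94")
  expect_equal(chi[["chi1"]],
               oracle_dihedral_project(c(0, 0, 0), c(1.46, 0, 0),
                                       c(2.0, 1.3, 0.4),
                                       c(1.45, 2.55, -0.2)),
               tolerance = 1e-9)
  expect_equal(chi[["chi2"]],
               oracle_dihedral_project(c(1.46, 0, 0), c(2.0, 1.3, 0.4),
                                       c(1.45, 2.55, -0.2),
                                       c(2.1, 3.7, 0.5)),
               tolerance = 1e-9)
  expect_error(sidechain_dihedrals(his[-5, ], "A:94"), "ND1")
  # values in (-180, 180]
  expect_true(all(chi > -180 & chi <= 180))
})

test_that("hydrogen-bond detection honors the distance and angle criteria", {
  fr <- hbond_frame(da = 2.9)
  hb <- detect_hbonds(fr, donors = "A:1:N", acceptors = "A:2:O")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, "A:1:N")
  expect_equal(hb$acceptor, "A:2:O")
  far <- hbond_frame(da = 3.5)
  expect_equal(nrow(detect_hbonds(far, "A:1:N", "A:2:O")), 0)
  # literal angle mode inverts the angle criterion
  lit <- detect_hbonds(fr, "A:1:N", "A:2:O",
                       contact_criteria(angle_mode = "literal_maximum"))
  expect_equal(nrow(lit), 0)
  # donor without hydrogen warns and is skipped
  noh <- fr[fr$elem != "H", ]
  expect_warning(hb0 <- detect_hbonds(md_frame(noh), "A:1:N", "A:2:O"),
                 "no covalent hydrogen")
  expect_equal(nrow(hb0), 0)
})

test_that("hydrogen-bond detection agrees with the all-pairs brute-force oracle", {
  for (seed in c(3, 17, 29)) {
    fr <- random_polar_frame(seed, n_res = 10, box = 7)
    donors <- paste0("A:", 1:10, ":N")
    acceptors <- paste0("A:", 1:10, ":O")
    hb <- suppressWarnings(detect_hbonds(fr, donors, acceptors))
    idx <- function(sel) vapply(sel, function(s) {
      p <- strsplit(s, ":")[[1]]
      which(fr$chain == p[1] & fr$resno == as.integer(p[2]) &
              fr$atom == p[3])
    }, integer(1))
    want <- oracle_hbonds(fr, idx(donors), idx(acceptors))
    got <- sort(paste(idx(hb$donor), idx(hb$hydrogen), idx(hb$acceptor)))
    expect_identical(got, want)
  }
})

test_that("salt-bridge detection applies the COM cutoff and matches brute force", {
  mk <- function(dx) quick_frame(
    atom = c("NZ", "CD", "OE1", "OE2"),
    resid = c("LYS", "GLU", "GLU", "GLU"),
    resno = c(10L, 20L, 20L, 20L), chain = "A",
    elem = c("N", "C", "O", "O"),
    x = c(0, dx, dx + 0.6, dx + 0.6), y = c(0, 0, 0.8, -0.8), z = 0)
  # COM of the carboxylate sits slightly beyond dx; calibrate to the cutoff
  com_x <- function(dx) {
    m <- c(12.011, 15.999, 15.999)
    sum(c(dx, dx + 0.6, dx + 0.6) * m) / sum(m)
  }
  dx_in <- 4.9 - (com_x(0))
  dx_out <- 5.1 - (com_x(0))
  expect_equal(nrow(detect_salt_bridges(mk(dx_in))), 1)
  expect_equal(detect_salt_bridges(mk(dx_in))$distance, 4.9,
               tolerance = 1e-9)
  expect_equal(nrow(detect_salt_bridges(mk(dx_out))), 0)
  expect_error(detect_salt_bridges(mk(4), cations = list(),
                                   anions = list()), "empty")
  # randomized frames against the brute-force COM scan
  set.seed(23)
  for (rep in 1:5) {
    n <- 6
    atoms <- do.call(rbind, lapply(1:n, function(i) {
      kind <- if (i %% 2 == 0) "LYS" else "GLU"
      base <- runif(3, -6, 6)
      if (kind == "LYS")
        data.frame(atom = "NZ", resid = "LYS", resno = i, chain = "A",
                   elem = "N", x = base[1], y = base[2], z = base[3])
      else
        data.frame(atom = c("CD", "OE1", "OE2"), resid = "GLU",
                   resno = i, chain = "A", elem = c("C", "O", "O"),
                   x = base[1] + c(0, 0.6, 0.6),
                   y = base[2] + c(0, 0.8, -0.8), z = base[3])
    }))
    fr <- md_frame(atoms)
    cg <- charged_groups(fr)
    got <- detect_salt_bridges(fr)
    want <- oracle_salt_bridges(fr, cg$cations, cg$anions)
    expect_identical(sort(paste(got$cation, got$anion)), want)
  }
})

test_that("interaction frequencies count scripted contacts exactly", {
  base <- hbond_frame(da = 2.83)
  always <- gen_fluctuating_ensemble(base, sigma = 0, n_frames = 10,
                                     seed = 2,
                                     contact = list(donor = "A:1:N",
                                                    acceptor = "A:2:O",
                                                    present = rep(TRUE, 10)))
  f1 <- interaction_frequencies(always, data.frame(res1 = "A:1",
                                                   res2 = "A:2"))
  expect_equal(f1$DA, 1)
  never <- gen_fluctuating_ensemble(base, sigma = 0, n_frames = 10,
                                    seed = 2,
                                    contact = list(donor = "A:1:N",
                                                   acceptor = "A:2:O",
                                                   present = rep(FALSE, 10)))
  f0 <- interaction_frequencies(never, data.frame(res1 = "A:1",
                                                  res2 = "A:2"))
  expect_equal(f0$DA, 0)
  sched <- rep(c(TRUE, FALSE), c(3, 7))
  part <- gen_fluctuating_ensemble(base, sigma = 0.05, n_frames = 10,
                                   seed = 2,
                                   contact = list(donor = "A:1:N",
                                                  acceptor = "A:2:O",
                                                  present = sched))
  fp <- interaction_frequencies(part, data.frame(res1 = "A:1",
                                                 res2 = "A:2"))
  expect_equal(fp$DA, 0.3)
  expect_equal(fp$SB, 0)
  expect_error(interaction_frequencies(part,
                                       data.frame(res1 = "A:1",
                                                  res2 = "A:99")),
               "not found")
})

test_that("salt-bridge interaction frequency sees an ion pair in every frame", {
  pairfr <- quick_frame(
    atom = c("NZ", "CD", "OE1", "OE2"),
    resid = c("LYS", "GLU", "GLU", "GLU"),
    resno = c(1L, 2L, 2L, 2L), chain = "A", elem = c("N", "C", "O", "O"),
    x = c(0, 3.5, 4.1, 4.1), y = c(0, 0, 0.8, -0.8), z = 0)
  ens <- gen_fluctuating_ensemble(pairfr, sigma = 0, n_frames = 4, seed = 5)
  fr <- interaction_frequencies(ens, data.frame(res1 = "A:1", res2 = "A:2"))
  expect_equal(fr$SB, 1)
})

test_that("RMSF is zero for rigid ensembles and exact for a two-frame oscillation", {
  base <- gen_thioester_frame(toy_geometry_spec(offset = 2, angle = 120,
                                                n_decoys = 5, seed = 3))
  rigid <- gen_fluctuating_ensemble(base, sigma = 0, n_frames = 4, seed = 1)
  r <- per_residue_rmsf(rigid, superpose = FALSE)
  expect_true(all(r$rmsf < 1e-12))
  # one atom oscillating +-d along x in an otherwise rigid, pre-aligned body
  f1 <- base; f2 <- base
  i <- which(f2$resid == "HOH")
  f2$x[i] <- f2$x[i] + 2 * 0.7
  r2 <- per_residue_rmsf(list(md_frame(f1), md_frame(f2)),
                         superpose = FALSE)
  expect_equal(r2$rmsf[r2$resid == "HOH"], 0.7, tolerance = 1e-12)
  expect_true(all(r2$rmsf[r2$resid != "HOH"] < 1e-12))
})

test_that("RMSF of isotropic Gaussian jitter approaches sigma * sqrt(3)", {
  # rigid anchor triad for superposition + jittered measured atoms
  atoms <- data.frame(
    atom = c("CA", "CA", "CA", "CA", rep("CB", 6)),
    resid = c(rep("GLY", 4), rep("ALA", 6)),
    resno = c(1:4, 11:16), chain = "A", elem = "C",
    x = c(0, 8, 0, 8, runif(6, 2, 6)),
    y = c(0, 0, 8, 8, runif(6, 2, 6)),
    z = c(0, 0, 0, 4, runif(6, 0, 4)))
  base <- md_frame(atoms)
  sig <- c(rep(0, 4), rep(0.5, 6))
  ens <- gen_fluctuating_ensemble(base, sigma = sig, n_frames = 2000,
                                  seed = 11)
  r <- per_residue_rmsf(ens, superpose = TRUE)
  meas <- r$rmsf[r$resno >= 11]
  expect_lt(abs(mean(meas) / (0.5 * sqrt(3)) - 1), 0.05)
  expect_true(all(r$rmsf[r$resno <= 4] < 1e-9))
  expect_error(per_residue_rmsf(ens[1]), "at least 2")
  mismatch <- ens
  mismatch[[2]] <- md_frame(ens[[2]][-1, ])
  expect_error(per_residue_rmsf(mismatch), "does not match")
})

test_that("geometric observables are invariant under rigid-body motion", {
  site <- toy_site()
  fr <- gen_thioester_frame(toy_geometry_spec(offset = 2.7, angle = 115,
                                              n_decoys = 10, seed = 9))
  off0 <- signed_plane_offset(fr, site)
  ang0 <- orientation_angle(fr, site)
  his <- quick_frame(
    atom = c("N", "CA", "CB", "CG", "ND1"), resid = "HIS", resno = 94L,
    chain = "A", elem = c("N", "C", "C", "C", "N"),
    x = c(0, 1.46, 2.0, 1.45, 2.1), y = c(0, 0, 1.3, 2.55, 3.7),
    z = c(0, 0, 0.4, -0.2, 0.5))
  chi0 <- sidechain_dihedrals(his, "A:94")
  for (seed in c(5, 6, 7)) {
    expect_equal(signed_plane_offset(rigid_transform(fr, seed), site),
                 off0, tolerance = 1e-9)
    expect_equal(orientation_angle(rigid_transform(fr, seed), site),
                 ang0, tolerance = 1e-9)
    expect_equal(sidechain_dihedrals(rigid_transform(his, seed), "A:94"),
                 chi0, tolerance = 1e-9)
  }
})
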