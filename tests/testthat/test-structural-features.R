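test_that("isolated and well-separated atoms recover the analytic sphere area", {
  m1 <- toy_model(list(list(res = 0, atom = "CB", el = "C", xyz = c(0, 0, 0))))
  cfg <- sasa_config(probe_radius = 3, vdw_radii = c(C = 1.7))
  s <- shrake_rupley(m1, cfg)
  expect_equal(s, 4 * pi * 4.7^2, tolerance = 0.02)
  m2 <- toy_model(list(
    list(res = 0, atom = "CB", el = "C", xyz = c(0, 0, 0)),
    list(res = 1, atom = "CB", el = "C", xyz = c(25, 0, 0))))
  s2 <- shrake_rupley(m2, cfg)
  expect_equal(s2, rep(4 * pi * 4.7^2, 2), tolerance = 1e-9)
})

test_that("caged-atom SASA agrees with the uniform-grid occupancy oracle", {
  # a central atom surrounded by a two-shell cage (octahedral + cubic shell)
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3))
  atoms <- list(list(res = 0, atom = "CB", el = "C", xyz = c(0, 0, 0)))
  for (k in seq_len(nrow(dirs)))
    atoms[[k + 1]] <- list(res = k, atom = "CB", el = "C",
                           xyz = as.numeric(dirs[k, ]) * 6.5)
  m <- toy_model(atoms)
  cfg <- sasa_config(probe_radius = 3, vdw_radii = c(C = 1.7))
  s <- shrake_rupley(m, cfg)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  rad <- rep(4.7, nrow(xyz))
  for (i in c(1, 2, 8)) {
    expect_equal(s[i], oracle_sasa_atom(i, xyz, rad),
                 tolerance = 0.05)
  }
})

test_that("SASA is conserved in residue sums and monotone under atom addition", {
  g <- build_ideal_structure("ANSTGLKWYVAC", geometry = "globule", seed = 5)
  s <- shrake_rupley(g)
  acc <- accessibility_classes(g, s)
  expect_equal(sum(acc$acc_all), sum(s), tolerance = 1e-6)
  # adding an atom never increases any existing atom's SASA (exact under a
  # fixed sampling frame; the principal-axis frame itself shifts slightly
  # when the coordinate cloud changes)
  cfg_fix <- sasa_config(orientation = "fixed")
  s_fix <- shrake_rupley(g, cfg_fix)
  extra <- g$atoms[1, ]
  extra$x <- extra$x + 3
  g2 <- glycostruct:::new_structure_model(rbind(g$atoms, extra),
                                          g$structure_id, g$chain_id)
  s2 <- shrake_rupley(g2, cfg_fix)
  expect_true(all(s2[seq_along(s_fix)] <= s_fix + 1e-9))
})

test_that("doubling the sphere-point count changes SASA by < 3%", {
  g <- build_ideal_structure("ANSTGLKW", geometry = "helix", seed = 5)
  s1 <- shrake_rupley(g, sasa_config(n_sphere_points = 960))
  s2 <- shrake_rupley(g, sasa_config(n_sphere_points = 1920))
  # per atom, relative to the atom's expanded-sphere area (the resolution
  # of the point sampler); per residue on the summed all-atom channel
  cfg <- sasa_config()
  rad <- glycostruct:::atom_radii(g, cfg) + cfg$probe_radius
  expect_true(all(abs(s2 - s1) / (4 * pi * rad^2) < 0.03))
  a1 <- accessibility_classes(g, s1)$acc_all
  a2 <- accessibility_classes(g, s2)$acc_all
  expect_true(all(abs(a2 - a1) / pmax(a1, 1) < 0.03))
})

test_that("accessibility classes follow the atom partition arithmetic", {
  m <- toy_model(list(
    list(res = 0, atom = "N", el = "N", xyz = c(0, 0, 0)),
    list(res = 0, atom = "CA", el = "C", xyz = c(1.5, 0, 0)),
    list(res = 0, atom = "C", el = "C", xyz = c(2.2, 1.3, 0)),
    list(res = 0, atom = "O", el = "O", xyz = c(1.6, 2.4, 0)),
    list(res = 0, atom = "CB", el = "C", xyz = c(2, -0.8, 1.3))))
  acc <- accessibility_classes(m, c(5, 10, 0, 3, 7))
  expect_equal(acc$acc_all, 25)
  expect_equal(acc$acc_mainchain, 18)
  expect_equal(acc$acc_sidechain, 7)
  expect_equal(acc$acc_nonpolar_sc, 7)
  expect_equal(acc$acc_polar_sc, 0)
  # glycine: no side-chain atoms at all
  mg <- toy_model(list(
    list(res = 0, aa = "G", atom = "N", el = "N", xyz = c(0, 0, 0)),
    list(res = 0, aa = "G", atom = "CA", el = "C", xyz = c(1.5, 0, 0))))
  accg <- accessibility_classes(mg, c(4, 6))
  expect_equal(accg$acc_sidechain, 0)
  expect_equal(accg$acc_nonpolar_sc + accg$acc_polar_sc, 0)
})

test_that("backbone dihedrals recover ideal-helix targets and NA conventions", {
  m <- build_ideal_structure(strrep("A", 20), geometry = "helix", seed = 1)
  d <- backbone_dihedrals(m)
  expect_true(all(abs(d$phi[2:19] - (-57)) < 2))
  expect_true(all(abs(d$psi[2:19] - (-47)) < 2))
  expect_true(is.na(d$phi[1]))
  expect_true(is.na(d$psi[20]))
})

test_that("dihedrals agree with the bio3d torsion oracle", {
  skip_if_not_installed("bio3d")
  m <- build_ideal_structure("ANSTGLKWYV", geometry = "globule", seed = 9)
  d <- backbone_dihedrals(m)
  a <- m$atoms
  get <- function(res, name) {
    k <- which(a$res_idx == res & a$atom == name)[1]
    c(a$x[k], a$y[k], a$z[k])
  }
  for (i in 2:9) {
    ref <- bio3d::torsion.xyz(c(get(i - 2, "C"), get(i - 1, "N"),
                                get(i - 1, "CA"), get(i - 1, "C")), atm.inc = 4)
    expect_equal(d$phi[i], as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("collinear backbone atoms yield missing dihedrals", {
  m <- toy_model(list(
    list(res = 0, atom = "N", xyz = c(0, 0, 0), el = "N"),
    list(res = 0, atom = "CA", xyz = c(1, 0, 0), el = "C"),
    list(res = 0, atom = "C", xyz = c(2, 0, 0), el = "C"),
    list(res = 1, atom = "N", xyz = c(3, 0, 0), el = "N"),
    list(res = 1, atom = "CA", xyz = c(4, 0, 0), el = "C"),
    list(res = 1, atom = "C", xyz = c(5, 0, 0), el = "C")))
  d <- backbone_dihedrals(m)
  expect_true(is.na(d$psi[1]))
  expect_true(is.na(d$phi[2]))
})

test_that("depth index matches the all-pairs oracle and its conventions", {
  g <- build_ideal_structure("ANSTGLKWYV", geometry = "globule", seed = 4)
  s <- shrake_rupley(g)
  dpx_oracle <- oracle_depth(g, s)
  di <- depth_index(g, s)
  a <- g$atoms
  for (r in 0:(g$n_res - 1)) {
    k <- a$res_idx == r
    expect_equal(di$ave_dpx[r + 1], mean(dpx_oracle[k]), tolerance = 1e-9)
    ks <- k & !a$mainchain
    if (any(ks))
      expect_equal(di$sch_ave_dpx[r + 1], mean(dpx_oracle[ks]), tolerance = 1e-9)
  }
  # fully exposed residue: all statistics zero
  iso <- toy_model(list(list(res = 0, atom = "CA", el = "C", xyz = c(0, 0, 0)),
                        list(res = 0, atom = "CB", el = "C", xyz = c(1.5, 0, 0))))
  s_iso <- shrake_rupley(iso)
  expect_true(all(unlist(depth_index(iso, s_iso)) == 0))
  expect_error(depth_index(iso, c(0, 0)), "no surface")
})

test_that("epitope log-odds follows the smoothing-minus-penalty definition", {
  iso <- toy_model(list(list(res = 0, aa = "N", atom = "CA", el = "C",
                             xyz = c(0, 0, 0))))
  prop <- glycostruct:::EPITOPE_PROPENSITY
  expect_equal(epitope_log_odds(iso), unname(prop["N"]))
  two <- toy_model(list(
    list(res = 0, aa = "N", atom = "CA", el = "C", xyz = c(0, 0, 0)),
    list(res = 1, aa = "I", atom = "CA", el = "C", xyz = c(5, 0, 0))))
  e <- epitope_log_odds(two, neighbor_radius = 10, lambda = 0.1)
  expect_equal(e, rep(mean(prop[c("N", "I")]) - 0.1, 2))
  # injected table wins verbatim
  inj <- data.frame(chain = "A", author = c("1", "2"), score = c(-9.6, -11.4))
  expect_equal(epitope_log_odds(two, scores = inj), c(-9.6, -11.4))
})

test_that("residue B-factor is the order-invariant atom mean", {
  m <- toy_model(list(
    list(res = 0, atom = "CA", el = "C", xyz = c(0, 0, 0), b = 10),
    list(res = 0, atom = "CB", el = "C", xyz = c(1.5, 0, 0), b = 20),
    list(res = 1, atom = "CA", el = "C", xyz = c(5, 0, 0), b = 7.5)))
  expect_equal(residue_b_factor(m), c(15, 7.5))
  m2 <- glycostruct:::new_structure_model(m$atoms[c(2, 1, 3), ], "toy", "A")
  expect_equal(residue_b_factor(m2), c(15, 7.5))
})

test_that("structure_features assembles 14 channels and honours injected tables", {
  m <- build_ideal_structure("ANSTG", geometry = "helix", seed = 2)
  sf <- structure_features(m)
  chans <- c("acc_all", "acc_sidechain", "acc_mainchain", "acc_nonpolar_sc",
             "acc_polar_sc", "ss_acc", "phi", "psi", "log_odds", "ave_dpx",
             "sd_dpx", "sch_ave_dpx", "sd_sch_dpx", "b_factor")
  expect_true(all(chans %in% colnames(sf)))
  expect_equal(length(chans), 14L)
  expect_equal(sf$ss_acc, sf$acc_all)   # internal proxy
  expect_true(sf$phi_missing[1] && sf$psi_missing[5])
  expect_equal(sf$phi[1], 0)            # encoded as 0 with the flag set
  # acc_all decomposes into main + side chain
  expect_equal(sf$acc_all, sf$acc_mainchain + sf$acc_sidechain,
               tolerance = 1e-9)

  rsa <- data.frame(chain = "A", author = as.character(1:5), aa3 = "ALA",
                    acc_all = 1:5, acc_sidechain = 6:10,
                    acc_mainchain = 11:15, acc_nonpolar_sc = 16:20,
                    acc_polar_sc = 21:25)
  dssp <- data.frame(chain = "A", author = as.character(1:5), aa = "A",
                     acc = 51:55, phi = c(NA, -60, -58, -61, -59),
                     psi = c(-40, -42, -44, -46, NA))
  sco <- data.frame(chain = "A", author = as.character(1:5),
                    score = seq(-12, -8))
  sf2 <- structure_features(m, dssp = dssp, rsa = rsa, scores = sco)
  expect_equal(sf2$acc_all, 1:5)
  expect_equal(sf2$acc_polar_sc, 21:25)
  expect_equal(sf2$ss_acc, 51:55)
  expect_equal(sf2$phi[2:5], c(-60, -58, -61, -59))
  expect_true(sf2$phi_missing[1])
  expect_equal(sf2$log_odds, seq(-12, -8))
})
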