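test_that("parse_pdb reads standard residues of the requested chain only", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(pdb)
  m <- parse_pdb(pdb, chain = "A")
  expect_s3_class(m, "structure_model")
  expect_equal(m$n_res, 2L)
  expect_equal(m$sequence, "AG")
  expect_equal(m$aa, c("A", "G"))
  # the HETATM water is dropped
  expect_false(any(m$atoms$aa == "X"))
  expect_equal(nrow(m$atoms), 9L)
  # residue indexing is contiguous and order-preserving
  expect_equal(sort(unique(m$atoms$res_idx)), 0:1)
  expect_equal(m$atoms$b[m$atoms$atom == "N" & m$atoms$res_idx == 0], 11)
})

test_that("parse_pdb keeps the highest-occupancy altloc", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(pdb, altloc_ca = TRUE)
  m <- parse_pdb(pdb, chain = "A")
  ca <- m$atoms[m$atoms$atom == "CA" & m$atoms$res_idx == 0, ]
  expect_equal(nrow(ca), 1L)
  # occupancy 0.60 altloc B beats occupancy 0.40 altloc A
  expect_equal(ca$altloc, "B")
  expect_equal(ca$x, 1.458, tolerance = 1e-6)
  expect_equal(ca$occupancy, 0.6)
})

test_that("parse_pdb errors on missing chains and files", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(pdb)
  expect_error(parse_pdb(pdb, chain = "Z"), "chain not found")
  expect_error(parse_pdb(file.path(tempdir(), "nope.pdb"), "A"), "not found")
})

test_that("PDB round-trip preserves residues, sequence, coordinates and B-factors", {
  m0 <- build_ideal_structure("ANSTGLKWYV", geometry = "helix", seed = 3,
                              structure_id = "rt")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m0, pdb)
  m1 <- parse_pdb(pdb, chain = "A")
  expect_equal(m1$n_res, m0$n_res)
  expect_equal(m1$sequence, m0$sequence)
  expect_equal(as.matrix(m1$atoms[, c("x", "y", "z")]),
               as.matrix(m0$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m1$atoms$b, m0$atoms$b, tolerance = 1e-2)
  expect_equal(m1$atoms$res_idx, m0$atoms$res_idx)
})

test_that("read_pssm parses the ASCII layout written by write_pssm", {
  p0 <- synth_pssm("NAT", concentration = 50, seed = 2)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(p0, f)
  p1 <- read_pssm(f)
  expect_s3_class(p1, "pssm_profile")
  expect_equal(p1$length, 3L)
  expect_equal(dim(p1$logodds), c(3L, 20L))
  expect_equal(p1$logodds, p0$logodds, ignore_attr = TRUE)
  expect_equal(rowSums(p1$freqs), rep(1, 3), tolerance = 1e-6)
})

test_that("read_pssm maps one-hot percentage rows to frequency 1", {
  lo <- matrix(0L, 1, 20)
  fr <- matrix(0, 1, 20); fr[1, 1] <- 1
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(glycostruct:::new_pssm_profile(lo, fr, "A"), f)
  p <- read_pssm(f)
  expect_equal(unname(p$freqs[1, "A"]), 1)
  expect_equal(sum(p$freqs[1, ]), 1)
})

test_that("read_pssm rejects malformed rows naming the line", {
  p0 <- synth_pssm("NAT", 10, 1)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(p0, f)
  lines <- readLines(f)
  # drop one column from the second data row
  lines[5] <- sub("\\s+\\S+$", "", sub("(\\s+-?\\d+)(\\s+-?\\d+\\s*)$", "\\1", lines[5]))
  lines[5] <- substr(lines[5], 1, nchar(lines[5]) - 20)
  writeLines(lines, f)
  expect_error(read_pssm(f), "line 5")
})

test_that("read_dssp extracts acc/phi/psi and maps 360.0 to missing", {
  f <- withr::local_tempfile(fileext = ".dssp")
  write_toy_dssp(f, list(
    list(serial = 1, resnum = 1, chain = "A", aa = "A", acc = 120,
         phi = 360.0, psi = -47.0),
    list(serial = 2, resnum = 2, chain = "A", aa = "G", acc = 35,
         phi = -57.0, psi = 360.0)))
  d <- read_dssp(f)
  expect_equal(nrow(d), 2L)
  expect_equal(d$acc, c(120, 35))
  expect_true(is.na(d$phi[1]))
  expect_equal(d$phi[2], -57)
  expect_true(is.na(d$psi[2]))
  expect_equal(d$author, c("1", "2"))
})

test_that("read_dssp errors without a header or data", {
  f <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("not", "a dssp file"), f)
  expect_error(read_dssp(f), "header not found|not a DSSP")
  write_toy_dssp(f, list())
  expect_error(read_dssp(f), "empty data")
})

test_that("read_rsa extracts the five absolute classes and ignores REL", {
  f <- withr::local_tempfile(fileext = ".rsa")
  df <- data.frame(chain = "A", author = "12", aa3 = "ASN",
                   acc_all = 101.25, acc_sidechain = 60.5,
                   acc_mainchain = 40.75, acc_nonpolar_sc = 22.5,
                   acc_polar_sc = 38.0)
  write_rsa(df, f)
  r <- read_rsa(f)
  expect_equal(r$acc_all, 101.25)
  expect_equal(r$acc_sidechain, 60.5)
  expect_equal(r$acc_mainchain, 40.75)
  expect_equal(r$acc_nonpolar_sc, 22.5)
  expect_equal(r$acc_polar_sc, 38.0)
  expect_equal(r$author, "12")
  expect_equal(ncol(r), 8L)  # no relative columns survive
})

test_that("read_rsa errors on truncated lines and missing RES records", {
  f <- withr::local_tempfile(fileext = ".rsa")
  writeLines("RES ASN A  12   101.25", f)
  expect_error(read_rsa(f), "truncated")
  writeLines("# empty", f)
  expect_error(read_rsa(f), "no RES lines")
})

test_that("read_residue_scores reads scores and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t1\t-9.5", "A\t2\t-11.4", "A\t3\t0.25"), f)
  s <- read_residue_scores(f)
  expect_equal(nrow(s), 3L)
  expect_equal(s$score, c(-9.5, -11.4, 0.25))  # negative log-odds accepted
  writeLines(c("A\t1\t-9.5", "A\t1\t2.0"), f)
  expect_error(read_residue_scores(f), "duplicate residue")
  writeLines(c("A\t1\tabc"), f)
  expect_error(read_residue_scores(f), "non-numeric")
})
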