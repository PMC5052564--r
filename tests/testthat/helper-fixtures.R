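# Shared fixtures: tiny hand-written structure files and independent
# oracles used across the suite. Everything is generated in code.

# Minimal structure model from an atom spec list:
# list(list(res = 0, author = "1", aa = "A", atom = "CA", el = "C",
#           xyz = c(0,0,0), b = 10), ...)
toy_model <- function(atoms, structure_id = "toy", chain = "A") {
  rows <- lapply(atoms, function(a) data.frame(
    res_idx = as.integer(a$res), author = as.character(a$author %||% (a$res + 1)),
    aa = a$aa %||% "A", atom = a$atom, element = a$el %||% substr(a$atom, 1, 1),
    x = a$xyz[1], y = a$xyz[2], z = a$xyz[3],
    b = a$b %||% 10, occupancy = 1, altloc = "",
    stringsAsFactors = FALSE))
  glycostruct:::new_structure_model(do.call(rbind, rows), structure_id, chain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-written two-residue PDB (ALA then GLY, chain A) exercising the
# fixed-column ATOM format, plus a HETATM water that must be ignored.
write_toy_pdb <- function(path, altloc_ca = FALSE) {
  fmt <- "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, 1, " N", " ", "ALA", "A", 1, 0.0, 0.0, 0.0, 1.00, 11.0, "N"),
    if (altloc_ca) c(
      sprintf(fmt, 2, " CA", "A", "ALA", "A", 1, 1.400, 0.1, 0.0, 0.40, 99.0, "C"),
      sprintf(fmt, 3, " CA", "B", "ALA", "A", 1, 1.458, 0.0, 0.0, 0.60, 12.0, "C"))
    else sprintf(fmt, 2, " CA", " ", "ALA", "A", 1, 1.458, 0.0, 0.0, 1.00, 12.0, "C"),
    sprintf(fmt, 4, " C", " ", "ALA", "A", 1, 2.009, 1.420, 0.0, 1.00, 13.0, "C"),
    sprintf(fmt, 5, " O", " ", "ALA", "A", 1, 1.400, 2.450, 0.0, 1.00, 14.0, "O"),
    sprintf(fmt, 6, " CB", " ", "ALA", "A", 1, 2.000, -0.8, 1.3, 1.00, 15.0, "C"),
    sprintf(fmt, 7, " N", " ", "GLY", "A", 2, 3.300, 1.500, 0.0, 1.00, 16.0, "N"),
    sprintf(fmt, 8, " CA", " ", "GLY", "A", 2, 4.000, 2.700, 0.0, 1.00, 17.0, "C"),
    sprintf(fmt, 9, " C", " ", "GLY", "A", 2, 5.500, 2.500, 0.0, 1.00, 18.0, "C"),
    sprintf(fmt, 10, " O", " ", "GLY", "A", 2, 6.100, 1.450, 0.0, 1.00, 19.0, "O"),
    gsub("^ATOM  ", "HETATM", sprintf(fmt, 11, " O", " ", "HOH", "A", 3,
                                      9.0, 9.0, 9.0, 1.00, 20.0, "O")),
    "END")
  writeLines(lines, path)
  path
}

# Fixed-column DSSP fixture writer (the column layout read_dssp expects).
write_toy_dssp <- function(path, rows) {
  pad <- function(n) strrep(" ", n)
  header <- c("==== Secondary Structure Definition, fixture ====",
              paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC", pad(60), "PHI    PSI"))
  body <- vapply(rows, function(r) {
    ln <- sprintf("%5d%5d%1s%1s %1s", r$serial, r$resnum, " ", r$chain, r$aa)
    ln <- paste0(ln, strrep(" ", 34 - nchar(ln)), sprintf("%4d", r$acc))
    # pad out to column 103 then phi (104-109) and psi (110-115)
    ln <- paste0(ln, strrep(" ", 103 - nchar(ln)),
                 sprintf("%6.1f%6.1f", r$phi, r$psi))
    ln
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Independent SASA oracle for one atom: near-uniform area-weighted
# latitude/longitude grid over the expanded sphere, points tested for
# occupancy against every other atom's expanded sphere.
oracle_sasa_atom <- function(i, xyz, rad, n_theta = 180) {
  ri <- rad[i]
  acc_area <- 0
  total <- 0
  for (t in seq_len(n_theta)) {
    theta <- pi * (t - 0.5) / n_theta
    n_phi <- max(8, round(2 * n_theta * sin(theta)))
    w <- sin(theta)          # area weight of the latitude band
    phis <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
    px <- xyz[i, 1] + ri * sin(theta) * cos(phis)
    py <- xyz[i, 2] + ri * sin(theta) * sin(phis)
    pz <- xyz[i, 3] + ri * cos(theta)
    free <- rep(TRUE, n_phi)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      free <- free & d2 >= rad[j]^2
    }
    acc_area <- acc_area + w * sum(free) / n_phi
    total <- total + w
  }
  4 * pi * ri^2 * acc_area / total
}

# Brute-force structure-window oracle: all atom pairs, strict "<".
oracle_structure_window <- function(model, target, R, include_target = TRUE) {
  a <- model$atoms
  tset <- which(a$res_idx == target)
  members <- integer()
  for (r in unique(a$res_idx)) {
    rows <- which(a$res_idx == r)
    hit <- FALSE
    for (u in tset) for (v in rows) {
      d <- sqrt((a$x[u] - a$x[v])^2 + (a$y[u] - a$y[v])^2 + (a$z[u] - a$z[v])^2)
      if (d < R) { hit <- TRUE; break }
    }
    if (hit) members <- c(members, r)
  }
  members <- sort(members)
  if (!include_target) members <- setdiff(members, target)
  else members <- sort(union(members, target))
  members
}

# Brute-force depth-index oracle (O(n^2) all-pairs distances).
oracle_depth <- function(model, atom_sasa) {
  a <- model$atoms
  exposed <- which(atom_sasa > 0)
  dpx <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (atom_sasa[i] > 0) next
    best <- Inf
    for (j in exposed) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
      if (d < best) best <- d
    }
    dpx[i] <- best
  }
  dpx
}

# Small planted dataset shared by the model-layer tests (kept small; the
# full-scale run lives in the acceptance suite).
small_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synth_spec(n_proteins = 25, seed = 11),
                             plant_rule(seed = 11))
      feats <- do.call(rbind, lapply(names(ds$structures), function(sid)
        encode_sites(ds$structures[[sid]], ds$pssms[[sid]], ds$sites)))
      cache <<- list(ds = ds, feats = feats, fm = feature_matrix(feats))
    }
    cache
  }
})

rigid_motion <- function(model, seed = 99) {
  old <- model
  rot <- with(list(), {
    set.seed(seed)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  shift <- c(12.3, -4.5, 7.9)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rot)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}
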