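# Internal helpers shared across modules.

# Canonical amino-acid column order used by ASCII PSSM files and by all
# per-residue lookup tables in this package.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Modified residues with a conventional parent amino acid; anything else
# nonstandard is skipped with a warning during parsing.
AA_NONSTANDARD <- c(MSE = "M", SEP = "S", TPO = "T", PTR = "Y", SEC = "C",
                    PYL = "K", HYP = "P")

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE), unname(AA_THREE))

#' @keywords internal
#' @noRd
aa_three_to_one <- function(resid) {
  out <- AA_THREE[resid]
  ns <- is.na(out)
  out[ns] <- AA_NONSTANDARD[resid[ns]]
  unname(out)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that global RNG state is never clobbered.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a bounded child seed from a master seed and stream identifiers,
# keeping results independent across (round, fold, step) combinations while
# staying below .Machine$integer.max.
#' @keywords internal
#' @noRd
child_seed <- function(seed, ...) {
  ids <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (v in ids) s <- (s * 69069 + v + 1) %% 2147483587
  as.integer(s) + 1L
}

# Dihedral angle (degrees) defined by four points (rows of a 4x3 matrix).
# Returns NA for degenerate (collinear) configurations.
#' @keywords internal
#' @noRd
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  # IUPAC sign convention: y from the triple product (n1 x n2) . b2
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(cr * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# Place a new atom at bond length r from c3, with angle theta (deg) to
# c2-c3 and dihedral chi (deg) about the c1-c2-c3 axis (NeRF construction).
#' @keywords internal
#' @noRd
place_atom <- function(c1, c2, c3, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  d <- c(r * cos(pi - theta),
         r * sin(pi - theta) * cos(chi),
         r * sin(pi - theta) * sin(chi))
  bc <- c3 - c2
  bc <- bc / sqrt(sum(bc^2))
  ab <- c2 - c1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m2, n)
  c3 + as.vector(rot %*% d)
}

#' @keywords internal
#' @noRd
stop_gs <- function(...) stop(..., call. = FALSE)

# Molecule-intrinsic orthonormal frame (principal axes of the coordinate
# cloud, signs fixed by the third central moment of the projections, third
# axis completing a right-handed system). Rotating or translating the
# molecule rotates this frame with it, which makes point-sampled SASA
# rigid-motion invariant. Degenerate clouds (fewer than 3 atoms, symmetric
# arrangements) fall back to the identity frame.
#' @keywords internal
#' @noRd
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  cen <- colMeans(xyz)
  cc <- sweep(xyz, 2, cen)
  ev <- tryCatch(eigen(crossprod(cc) / nrow(cc), symmetric = TRUE),
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev$values))) return(diag(3))
  e1 <- ev$vectors[, 1]
  e2 <- ev$vectors[, 2]
  s1 <- mean((cc %*% e1)^3)
  s2 <- mean((cc %*% e2)^3)
  if (s1 < 0) e1 <- -e1
  if (s2 < 0) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}
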