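# The 14 per-residue structural feature channels: five absolute
# solvent-accessibility classes, secondary-structure values (ACC, phi, psi),
# epitope log-odds, four depth-index statistics and the mean B-factor.

# NACCESS-style van der Waals radii; hydrogens are stripped at parse time.
DEFAULT_VDW <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)

#' Configuration for Shrake-Rupley solvent-accessible surface area
#'
#' @param probe_radius probe sphere radius in Angstrom. The default of 3.0
#'   (rather than the conventional water probe of 1.4) targets the larger
#'   footprint relevant to glycan accessibility.
#' @param n_sphere_points number of test points per atom, placed on a
#'   deterministic golden-spiral sphere.
#' @param vdw_radii named vector of van der Waals radii (Angstrom) per
#'   element symbol.
#' @param vdw_default fallback radius for elements missing from `vdw_radii`
#'   (applied with a warning).
#' @param orientation `"principal"` orients the test sphere in the
#'   molecule's principal-axis frame, making results invariant under rigid
#'   motion of the input; `"fixed"` keeps the laboratory frame, under which
#'   adding atoms can never increase any SASA value but results depend on
#'   the input orientation at the level of single test points.
#' @return List of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 3.0, n_sphere_points = 960,
                        vdw_radii = DEFAULT_VDW, vdw_default = 1.8,
                        orientation = c("principal", "fixed")) {
  stopifnot(probe_radius > 0, n_sphere_points >= 92)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 vdw_radii = vdw_radii,
                 vdw_default = vdw_default,
                 orientation = match.arg(orientation)),
            class = "sasa_config")
}

# Deterministic golden-spiral points on the unit sphere.
#' @keywords internal
#' @noRd
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' @keywords internal
#' @noRd
atom_radii <- function(model, cfg) {
  r <- cfg$vdw_radii[model$atoms$element]
  miss <- is.na(r)
  if (any(miss)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(model$atoms$element[miss]), collapse = ", "),
            "; using ", cfg$vdw_default, " A", call. = FALSE)
    r[miss] <- cfg$vdw_default
  }
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points are placed on a sphere of radius
#' `r_vdw + probe_radius`; a point is buried if it falls inside any other
#' atom's expanded sphere. SASA is `4 pi (r_vdw + probe)^2` times the
#' accessible point fraction.
#'
#' @param model a `structure_model`.
#' @param cfg a [sasa_config()].
#' @return Numeric vector of per-atom SASA values (Angstrom^2), in atom-table
#'   order.
#' @export
shrake_rupley <- function(model, cfg = sasa_config()) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 0) stop_gs("empty model")
  rad <- atom_radii(model, cfg) + cfg$probe_radius
  # test directions live in the molecule's principal-axis frame so that
  # results are invariant under rigid motion of the input coordinates
  pts <- sphere_points(cfg$n_sphere_points)
  if (is.null(cfg$orientation) || cfg$orientation == "principal")
    pts <- pts %*% t(canonical_frame(xyz))
  .sasa_kernel(xyz, rad, pts)
}

#' Five per-residue absolute accessibility classes
#'
#' Sums per-atom SASA into the five NACCESS-style absolute classes: all
#' atoms, total side chain, main chain, non-polar side chain (side-chain C
#' and S atoms) and polar side chain (side-chain N and O atoms).
#'
#' @param model a `structure_model`.
#' @param atom_sasa per-atom SASA as returned by [shrake_rupley()].
#' @return data.frame with one row per residue and columns `acc_all`,
#'   `acc_sidechain`, `acc_mainchain`, `acc_nonpolar_sc`, `acc_polar_sc`.
#' @export
accessibility_classes <- function(model, atom_sasa) {
  a <- model$atoms
  stopifnot(length(atom_sasa) == nrow(a))
  idx <- factor(a$res_idx, levels = 0:(model$n_res - 1))
  sum_by <- function(mask) {
    as.numeric(tapply(ifelse(mask, atom_sasa, 0), idx, sum, default = 0))
  }
  side <- !a$mainchain
  data.frame(
    acc_all = sum_by(rep(TRUE, nrow(a))),
    acc_sidechain = sum_by(side),
    acc_mainchain = sum_by(a$mainchain),
    acc_nonpolar_sc = sum_by(side & a$element %in% c("C", "S")),
    acc_polar_sc = sum_by(side & a$element %in% c("N", "O")))
}

#' Backbone phi/psi dihedral angles
#'
#' Computes the standard backbone torsions phi (`C[i-1], N[i], CA[i], C[i]`)
#' and psi (`N[i], CA[i], C[i], N[i+1]`). Chain termini and residues with
#' missing backbone atoms yield `NA`.
#'
#' @param model a `structure_model`.
#' @return data.frame with per-residue columns `phi` and `psi` (degrees).
#' @export
backbone_dihedrals <- function(model) {
  a <- model$atoms
  n <- model$n_res
  coord_of <- function(res, name) {
    k <- which(a$res_idx == res & a$atom == name)
    if (!length(k)) return(NULL)
    c(a$x[k[1]], a$y[k[1]], a$z[k[1]])
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n) - 1L) {
    Ni <- coord_of(i, "N"); CAi <- coord_of(i, "CA"); Ci <- coord_of(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 0) {
      Cp <- coord_of(i - 1L, "C")
      if (!is.null(Cp)) phi[i + 1] <- dihedral_angle(rbind(Cp, Ni, CAi, Ci))
    }
    if (i < n - 1) {
      Nn <- coord_of(i + 1L, "N")
      if (!is.null(Nn)) psi[i + 1] <- dihedral_angle(rbind(Ni, CAi, Ci, Nn))
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Residue depth-index statistics
#'
#' The atom depth index (dpx) is 0 for solvent-accessible atoms (SASA > 0)
#' and the Euclidean distance to the nearest accessible atom otherwise.
#' Residue statistics are the mean and standard deviation over all atoms and
#' over side-chain atoms only.
#'
#' @param model a `structure_model`.
#' @param atom_sasa per-atom SASA.
#' @return data.frame with per-residue columns `ave_dpx`, `sd_dpx`,
#'   `sch_ave_dpx`, `sd_sch_dpx`. Standard deviations over a single atom are
#'   0; residues without side-chain atoms get 0 for the side-chain
#'   statistics.
#' @export
depth_index <- function(model, atom_sasa) {
  a <- model$atoms
  stopifnot(length(atom_sasa) == nrow(a))
  exposed <- atom_sasa > 0
  if (!any(exposed)) stop_gs("no surface: structure has no accessible atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dpx <- numeric(nrow(a))
  exy <- xyz[exposed, , drop = FALSE]
  for (i in which(!exposed)) {
    d2 <- (exy[, 1] - xyz[i, 1])^2 + (exy[, 2] - xyz[i, 2])^2 +
      (exy[, 3] - xyz[i, 3])^2
    dpx[i] <- sqrt(min(d2))
  }
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  out <- matrix(0, model$n_res, 4,
                dimnames = list(NULL, c("ave_dpx", "sd_dpx", "sch_ave_dpx", "sd_sch_dpx")))
  for (r in seq_len(model$n_res) - 1L) {
    k <- a$res_idx == r
    out[r + 1, 1] <- mean(dpx[k])
    out[r + 1, 2] <- sd0(dpx[k])
    ks <- k & !a$mainchain
    if (any(ks)) {
      out[r + 1, 3] <- mean(dpx[ks])
      out[r + 1, 4] <- sd0(dpx[ks])
    }
  }
  as.data.frame(out)
}

# Per-residue epitope log-odds propensities used by the internal smoothing
# approximation. Polar, loop-favouring surface residues score positive;
# buried hydrophobics negative. These are package constants, not the trained
# statistics of any external predictor; exact external scores can be
# injected verbatim via read_residue_scores().
EPITOPE_PROPENSITY <- c(A = -0.30, R = 0.40, N = 0.65, D = 0.55, C = -0.60,
                        Q = 0.35, E = 0.45, G = 0.50, H = 0.10, I = -0.70,
                        L = -0.65, K = 0.60, M = -0.45, F = -0.55, P = 0.70,
                        S = 0.40, T = 0.30, W = -0.50, Y = -0.15, V = -0.60)

#' Per-residue epitope log-odds score
#'
#' Internal approximation of a surface-epitope propensity score: the mean
#' residue propensity over spatial neighbours whose CA lies within
#' `neighbor_radius` of the target CA (target included), minus `lambda`
#' times the number of such neighbours excluding the target. Scores from an
#' external predictor can be passed in `scores` to override the internal
#' computation verbatim.
#'
#' @param model a `structure_model`.
#' @param neighbor_radius CA-CA neighbourhood radius in Angstrom.
#' @param lambda contact-number penalty weight.
#' @param scores optional data.frame from [read_residue_scores()].
#' @return Numeric vector of per-residue scores.
#' @export
epitope_log_odds <- function(model, neighbor_radius = 10, lambda = 0.1,
                             scores = NULL) {
  n <- model$n_res
  if (!is.null(scores)) {
    key <- paste(scores$chain, scores$author)
    hit <- match(paste(model$chain_id, model$author), key)
    if (any(is.na(hit)))
      stop_gs("score table does not cover residue ",
              model$author[which(is.na(hit))[1]])
    return(scores$score[hit])
  }
  a <- model$atoms
  ca <- a[a$atom == "CA", , drop = FALSE]
  out <- rep(NA_real_, n)
  prop <- unname(EPITOPE_PROPENSITY[model$aa])
  prop[is.na(prop)] <- mean(EPITOPE_PROPENSITY)
  cax <- rep(NA_real_, n); cay <- rep(NA_real_, n); caz <- rep(NA_real_, n)
  cax[ca$res_idx + 1] <- ca$x
  cay[ca$res_idx + 1] <- ca$y
  caz[ca$res_idx + 1] <- ca$z
  if (any(is.na(cax)))
    warning("residue(s) without CA skipped in epitope_log_odds", call. = FALSE)
  for (r in seq_len(n)) {
    if (is.na(cax[r])) next
    d2 <- (cax - cax[r])^2 + (cay - cay[r])^2 + (caz - caz[r])^2
    nbr <- which(!is.na(d2) & d2 <= neighbor_radius^2)
    out[r] <- mean(prop[nbr]) - lambda * (length(nbr) - 1)
  }
  out
}

#' Mean B-factor per residue
#'
#' @param model a `structure_model`.
#' @return Numeric vector: arithmetic mean of the atom temperature factors
#'   of each residue.
#' @export
residue_b_factor <- function(model) {
  a <- model$atoms
  idx <- factor(a$res_idx, levels = 0:(model$n_res - 1))
  as.numeric(tapply(a$b, idx, mean))
}

#' Assemble the 14 per-residue structural feature channels
#'
#' Computes solvent accessibility (five absolute classes), the
#' secondary-structure channels (`ss_acc`, `phi`, `psi`), the epitope
#' log-odds score, the four depth-index statistics and the mean B-factor.
#' `ss_acc` is proxied by the residue all-atom SASA unless a DSSP table is
#' injected, in which case DSSP `acc`/`phi`/`psi` override the internal
#' values. An injected `.rsa` table overrides the five accessibility
#' classes, and an injected score table overrides `log_odds`.
#'
#' @param model a `structure_model`.
#' @param cfg a [sasa_config()].
#' @param dssp optional data.frame from [read_dssp()].
#' @param rsa optional data.frame from [read_rsa()].
#' @param scores optional data.frame from [read_residue_scores()].
#' @param atom_sasa optional precomputed per-atom SASA (skips recomputation).
#' @return data.frame with one row per residue: the 14 channels `acc_all`,
#'   `acc_sidechain`, `acc_mainchain`, `acc_nonpolar_sc`, `acc_polar_sc`,
#'   `ss_acc`, `phi`, `psi`, `log_odds`, `ave_dpx`, `sd_dpx`, `sch_ave_dpx`,
#'   `sd_sch_dpx`, `b_factor`, plus logical `phi_missing`/`psi_missing`
#'   flags. Missing angles are encoded as 0 with the flag set, and are
#'   excluded from structure-window averaging downstream.
#' @export
structure_features <- function(model, cfg = sasa_config(), dssp = NULL,
                               rsa = NULL, scores = NULL, atom_sasa = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(atom_sasa)) atom_sasa <- shrake_rupley(model, cfg)
  acc <- accessibility_classes(model, atom_sasa)
  dih <- backbone_dihedrals(model)
  dpx <- depth_index(model, atom_sasa)
  out <- cbind(acc,
               ss_acc = acc$acc_all,
               phi = dih$phi,
               psi = dih$psi,
               log_odds = epitope_log_odds(model, scores = scores),
               dpx,
               b_factor = residue_b_factor(model))
  match_key <- function(tab) match(paste(model$chain_id, model$author),
                                   paste(tab$chain, tab$author))
  if (!is.null(rsa)) {
    hit <- match_key(rsa)
    if (any(is.na(hit))) stop_gs(".rsa table does not cover all residues")
    for (cl in c("acc_all", "acc_sidechain", "acc_mainchain",
                 "acc_nonpolar_sc", "acc_polar_sc"))
      out[[cl]] <- rsa[[cl]][hit]
  }
  if (!is.null(dssp)) {
    hit <- match_key(dssp)
    if (any(is.na(hit))) stop_gs("DSSP table does not cover all residues")
    out$ss_acc <- dssp$acc[hit]
    out$phi <- dssp$phi[hit]
    out$psi <- dssp$psi[hit]
  }
  out$phi_missing <- is.na(out$phi)
  out$psi_missing <- is.na(out$psi)
  out$phi[out$phi_missing] <- 0
  out$psi[out$psi_missing] <- 0
  out
}
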