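# Desk-scale synthetic inputs with known structure: idealized 3-D protein
# models, synthetic PSSM profiles, and site labels planted by a known
# sequon-plus-accessibility rule, so the full pipeline can be exercised and
# validated without any external downloads.

# Ideal backbone geometry (Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

#' Build an idealized single-chain structure
#'
#' Backbone N/CA/C/O atoms are placed with standard bond geometry. In
#' `"helix"` mode dihedrals target phi = -57, psi = -47 degrees; in
#' `"extended"` mode phi = -139, psi = 135. In `"globule"` mode residues
#' are packed along a serpentine path on a jittered cubic lattice with a
#' randomly oriented local backbone frame per residue, so that interior
#' residues are solvent-inaccessible. Every non-glycine residue carries a
#' single CB-like pseudo side-chain atom. B-factors are drawn from a seeded
#' gamma distribution.
#'
#' @param sequence one-letter amino-acid string (standard letters).
#' @param geometry `"helix"`, `"extended"` or `"globule"`.
#' @param seed integer seed (B-factors, lattice jitter, local frames).
#' @param structure_id identifier stored in the model.
#' @param chain_id chain identifier.
#' @return A `structure_model`.
#' @export
build_ideal_structure <- function(sequence,
                                  geometry = c("helix", "extended", "globule"),
                                  seed = 1, structure_id = "synth",
                                  chain_id = "A") {
  geometry <- match.arg(geometry)
  aa <- strsplit(sequence, "")[[1]]
  if (!length(aa)) stop_gs("empty sequence")
  if (!all(aa %in% AA_ORDER))
    stop_gs("invalid letters in sequence: ",
            paste(unique(aa[!aa %in% AA_ORDER]), collapse = ""))
  n <- length(aa)
  with_seed(seed, {
    if (geometry == "globule") {
      coords <- globule_backbone(n)
    } else {
      tor <- if (geometry == "helix") c(phi = -57, psi = -47)
             else c(phi = -139, psi = 135)
      coords <- chain_backbone(n, tor["phi"], tor["psi"])
    }
    rows <- list()
    for (i in seq_len(n)) {
      res_b <- stats::rgamma(1, shape = 8, rate = 0.4)
      atoms <- coords[[i]]
      nm <- names(atoms)
      if (aa[i] == "G") {
        nm <- setdiff(nm, "CB")
        atoms <- atoms[nm]
      }
      for (a in nm) {
        el <- substr(a, 1, 1)
        rows[[length(rows) + 1]] <- data.frame(
          res_idx = i - 1L, author = as.character(i), aa = aa[i],
          atom = a, element = el,
          x = atoms[[a]][1], y = atoms[[a]][2], z = atoms[[a]][3],
          b = max(2, res_b + stats::rnorm(1, 0, 1.5)),
          occupancy = 1, altloc = "",
          stringsAsFactors = FALSE)
      }
    }
    new_structure_model(do.call(rbind, rows), structure_id, chain_id)
  })
}

# Sequential NeRF backbone with constant (phi, psi), omega = 180.
#' @keywords internal
#' @noRd
chain_backbone <- function(n, phi, psi) {
  out <- vector("list", n)
  Np <- c(0, 0, 0)
  CAp <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  Cp <- CAp + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Ni <- place_atom(Np, CAp, Cp, BOND_C_N, ANGLE_CA_C_N, psi)
      CAi <- place_atom(CAp, Cp, Ni, BOND_N_CA, ANGLE_C_N_CA, 180)
      Ci <- place_atom(Cp, Ni, CAi, BOND_CA_C, ANGLE_N_CA_C, phi)
      Np <- Ni; CAp <- CAi; Cp <- Ci
    }
    Oi <- place_atom(Np, CAp, Cp, BOND_C_O, ANGLE_CA_C_O, psi + 180)
    CBi <- place_atom(Cp, Np, CAp, BOND_CA_CB, 110.5, 122.5)
    out[[i]] <- list(N = Np, CA = CAp, C = Cp, O = Oi, CB = CBi)
  }
  out
}

# Serpentine walk over a jittered cubic lattice; each residue gets a
# randomly oriented ideal local frame for its N/C/O/CB atoms.
#' @keywords internal
#' @noRd
globule_backbone <- function(n, spacing = 3.8, jitter = 0.35) {
  k <- ceiling(n^(1 / 3))
  cells <- list()
  for (z in seq_len(k)) {
    ys <- if (z %% 2) seq_len(k) else rev(seq_len(k))
    for (y in ys) {
      xs <- if ((y + z) %% 2) seq_len(k) else rev(seq_len(k))
      for (x in xs) cells[[length(cells) + 1]] <- c(x, y, z)
    }
  }
  local_atoms <- list(N = c(BOND_N_CA, 0, 0),
                      C = c(-0.548, 1.421, 0),
                      O = c(-1.117, 2.385, 0.300),
                      CB = c(0, -0.770, 1.330))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- (cells[[i]] - (k + 1) / 2) * spacing +
      stats::runif(3, -jitter, jitter)
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    at <- lapply(local_atoms, function(v) ca + as.vector(q %*% v))
    out[[i]] <- c(list(CA = ca), at)[c("N", "CA", "C", "O", "CB")]
  }
  out
}

#' Synthesize a PSSM profile for a sequence
#'
#' Per position, frequencies are drawn from a Dirichlet distribution
#' concentrated on the true residue with sharpness `concentration` over a
#' near-uniform base. Log-odds are `round(2 log2(p / 0.05))` clipped to
#' `[-10, 10]` (uniform background of 1/20).
#'
#' @param sequence one-letter amino-acid string.
#' @param concentration Dirichlet sharpness; large values approach one-hot
#'   columns (conservation 1), values near zero approach uniform columns
#'   (conservation 0).
#' @param seed integer seed.
#' @return A `pssm_profile`.
#' @export
synth_pssm <- function(sequence, concentration = 10, seed = 1) {
  stopifnot(concentration > 0)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  with_seed(seed, {
    freqs <- matrix(0, L, 20)
    for (i in seq_len(L)) {
      alpha <- rep(5, 20)
      j <- match(aa[i], AA_ORDER)
      alpha[j] <- alpha[j] + concentration * 20
      g <- stats::rgamma(20, shape = alpha)
      freqs[i, ] <- g / sum(g)
    }
    logodds <- pmin(pmax(round(2 * log2(freqs / 0.05)), -10), 10)
    new_pssm_profile(logodds, freqs, sequence)
  })
}

#' Specification of a synthetic dataset
#'
#' @param n_proteins number of synthetic chains.
#' @param length_range two-element residue-count range.
#' @param frac_globular fraction of chains built as collapsed globules (the
#'   rest split between helices and extended chains); globules provide the
#'   buried/exposed contrast the accessibility rule needs.
#' @param pssm_concentration sharpness passed to [synth_pssm()].
#' @param seed integer master seed.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 200, length_range = c(40, 80),
                       frac_globular = 0.7, pssm_concentration = 10,
                       seed = 7) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] >= 10, length_range[2] >= length_range[1])
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 frac_globular = frac_globular,
                 pssm_concentration = pssm_concentration,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Planted labeling rule
#'
#' A site's planted label is `TRUE` when it satisfies the sequon (if
#' required) and its structure-window-averaged all-atom accessibility
#' exceeds `sasa_threshold`; labels are then flipped independently with
#' probability `noise_rate`.
#'
#' @param glyco_type `"N"` or `"O"`.
#' @param sasa_threshold window-averaged all-atom SASA threshold
#'   (Angstrom^2) above which a site counts as accessible.
#' @param require_sequon require the Asn-X-Ser/Thr sequon (default `TRUE`
#'   for N-linked, ignored for O-linked).
#' @param noise_rate label-flip probability in `[0, 0.5)`.
#' @param seed integer seed for the flips.
#' @return List of class `plant_rule`.
#' @export
plant_rule <- function(glyco_type = "N", sasa_threshold = 36,
                       require_sequon = identical(glyco_type, "N"),
                       noise_rate = 0.05, seed = 7) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5, sasa_threshold >= 0)
  structure(list(glyco_type = glyco_type,
                 sasa_threshold = sasa_threshold,
                 require_sequon = require_sequon,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "plant_rule")
}

# Sample a sequence with elevated N/S/T frequency and plant occasional
# N-X-S/T sequon motifs.
#' @keywords internal
#' @noRd
sample_sequence <- function(L) {
  base <- stats::setNames(rep(0.74 / 16, 20), AA_ORDER)
  base[c("N", "S", "T")] <- c(0.05, 0.09, 0.09)
  base["P"] <- 0.03
  aa <- sample(AA_ORDER, L, replace = TRUE, prob = base)
  n_plant <- stats::rpois(1, 2.5)
  if (n_plant > 0 && L >= 3) {
    starts <- sample(seq_len(L - 2), min(n_plant, L - 2))
    for (s in starts) {
      aa[s] <- "N"
      aa[s + 1] <- sample(setdiff(AA_ORDER, "P"), 1)
      aa[s + 2] <- sample(c("S", "T"), 1)
    }
  }
  paste(aa, collapse = "")
}

#' Generate a fully synthetic labeled dataset
#'
#' For each protein: a sequence with elevated N/S/T content and occasional
#' planted sequons, an idealized structure, and a synthetic PSSM. Candidate
#' sites are extracted with [candidate_sites()] and labeled by the planted
#' rule (sequon if required, AND window-averaged all-atom SASA above the
#' rule threshold), then flipped with the rule's noise rate. Identical
#' `(spec, rule)` inputs reproduce identical outputs.
#'
#' @param spec a [synth_spec()].
#' @param rule a [plant_rule()].
#' @param window a [window_config()] used for the accessibility windows.
#' @param sasa_cfg a [sasa_config()].
#' @return List of class `synth_dataset`: named lists `structures` and
#'   `pssms`, the labeled `sites` data.frame (with the noise-free
#'   `label_clean` and the window accessibility `wacc` retained for
#'   diagnostics), and the generating `spec` and `rule`.
#' @export
generate_dataset <- function(spec = synth_spec(), rule = plant_rule(),
                             window = window_config(),
                             sasa_cfg = sasa_config()) {
  structures <- list()
  pssms <- list()
  sites <- list()
  geoms <- c("helix", "extended")
  for (i in seq_len(spec$n_proteins)) {
    sid <- sprintf("syn%04d", i)
    si <- child_seed(spec$seed, i, 1)
    L <- with_seed(si, sample(spec$length_range[1]:spec$length_range[2], 1))
    seqc <- with_seed(child_seed(spec$seed, i, 2), sample_sequence(L))
    geom <- with_seed(child_seed(spec$seed, i, 3), {
      if (stats::runif(1) < spec$frac_globular) "globule" else sample(geoms, 1)
    })
    model <- build_ideal_structure(seqc, geometry = geom,
                                   seed = child_seed(spec$seed, i, 4),
                                   structure_id = sid)
    pssm <- synth_pssm(seqc, spec$pssm_concentration,
                       seed = child_seed(spec$seed, i, 5))
    cand <- candidate_sites(model, rule$glyco_type)
    if (nrow(cand)) {
      atom_sasa <- shrake_rupley(model, sasa_cfg)
      acc <- accessibility_classes(model, atom_sasa)
      cand$wacc <- vapply(cand$seq_index, function(t) {
        m <- structure_window(model, t, window$R, window$include_target)
        mean(acc$acc_all[m + 1])
      }, numeric(1))
      clean <- cand$wacc > rule$sasa_threshold
      if (rule$require_sequon && rule$glyco_type == "N")
        clean <- clean & cand$sequon
      flip <- with_seed(child_seed(rule$seed, i),
                        stats::runif(nrow(cand)) < rule$noise_rate)
      lab <- xor(clean, flip)
      cand$label_clean <- ifelse(clean, "positive", "negative")
      cand$label <- ifelse(lab, "positive", "negative")
      sites[[sid]] <- cand
    }
    structures[[sid]] <- model
    pssms[[sid]] <- pssm
  }
  structure(list(structures = structures,
                 pssms = pssms,
                 sites = do.call(rbind, c(sites, list(make.row.names = FALSE))),
                 spec = spec, rule = rule),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  tab <- table(x$sites$label)
  cat(sprintf("<synth_dataset> %d structures, %d candidate sites (%s)\n",
              length(x$structures), nrow(x$sites),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Materializes every structure as a PDB file, every profile as an ASCII
#' PSSM, and the positive labels as an annotation TSV (`structure_id`,
#' `chain`, `author`, `glyco_type`), so the generated fixtures double as
#' tests for the format readers.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_fixture_files <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(ds$structures)) {
    write_structure(ds$structures[[sid]], file.path(dir, paste0(sid, ".pdb")))
    write_pssm(ds$pssms[[sid]], file.path(dir, paste0(sid, ".pssm")))
  }
  pos <- ds$sites[ds$sites$label == "positive", , drop = FALSE]
  utils::write.table(
    pos[, c("structure_id", "chain", "author", "glyco_type")],
    file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
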