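# Per-position sequence-derived features: AAindex scales, physicochemical
# properties, PSSM log-odds columns and the PSSM-based residue-conservation
# score.

.gs_env <- new.env(parent = emptyenv())

# The four AAindex entries behind the feature names used throughout:
#   hydrophobicity = CIDH920105 (normalized average hydrophobicity scales)
#   flexibility    = BHAR880101 (average flexibility indices)
#   polarity       = RADA880108 (mean polarity)
#   beta_turn      = BEGF750103 (conformational parameter of beta-turn)
# Values are taken from the AAindex copy bundled with bio3d.
AAINDEX_IDS <- c(hydrophobicity = "CIDH920105",
                 flexibility = "BHAR880101",
                 polarity = "RADA880108",
                 beta_turn = "BEGF750103")

#' Amino-acid index scales used for window encoding
#'
#' Returns the four AAindex scales (hydrophobicity, flexibility, polarity,
#' beta-turn propensity) as named numeric vectors over the 20 standard amino
#' acids, in the fixed column order `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @return Named list of four numeric vectors of length 20.
#' @export
aaindex_scales <- function() {
  if (is.null(.gs_env$aaindex)) {
    aa.index <- NULL
    utils::data("aa.index", package = "bio3d", envir = environment())
    sc <- lapply(AAINDEX_IDS, function(id) {
      v <- aa.index[[id]]$I[AA_ORDER]
      if (any(is.na(v))) stop_gs("AAindex entry ", id, " is incomplete")
      v
    })
    names(sc) <- names(AAINDEX_IDS)
    .gs_env$aaindex <- sc
  }
  .gs_env$aaindex
}

#' Look up an AAindex scale value for a residue
#'
#' @param scale scale name (`"hydrophobicity"`, `"flexibility"`,
#'   `"polarity"`, `"beta_turn"`) or a named numeric vector of 20 values.
#' @param aa one-letter amino-acid code; `"X"` returns the mean of the 20
#'   values (the neutral-padding convention).
#' @return Numeric scalar (vectorized over `aa`).
#' @export
aaindex_value <- function(scale, aa) {
  if (is.character(scale)) {
    scale <- match.arg(scale, names(AAINDEX_IDS))
    scale <- aaindex_scales()[[scale]]
  }
  stopifnot(length(scale) == 20)
  bad <- !(aa %in% c(AA_ORDER, "X"))
  if (any(bad)) stop_gs("unknown amino-acid letter: ", aa[bad][1])
  out <- unname(scale[aa])
  out[aa == "X"] <- mean(scale)
  out
}

# 14 physicochemical properties per amino acid, transcribed from standard
# reference tables (pK/pI: Lehninger; hydropathy: Kyte-Doolittle; volumes:
# Zamyatnin; ASA: Miller Gly-X-Gly; vdW volumes: Creighton; polarity:
# Zimmerman; helix/strand preferences: Chou-Fasman). pKR is 0 for residues
# without an ionizable side chain.
PHYSCHEM_NAMES <- c("pK1", "pK2", "pKR", "pI", "hydropathy",
                    "pct_occurrence", "pct_buried", "avg_volume", "asa",
                    "vdw_volume", "polarity_rank", "sidechain_polarity",
                    "alpha_helix_pref", "beta_strand_pref")

PHYSCHEM_TABLE <- local({
  m <- rbind(
    #     pK1   pK2    pKR    pI  hyd  occ  bur   vol  asa  vdw  polr  scp  Pa    Pb
    A = c(2.34, 9.69,  0.00,  6.00,  1.8, 8.3, 38, 88.6, 113,  67,  0.00, 0, 1.42, 0.83),
    R = c(2.17, 9.04, 12.48, 10.76, -4.5, 5.7,  0, 173.4, 241, 148, 52.00, 1, 0.98, 0.93),
    N = c(2.02, 8.80,  0.00,  5.41, -3.5, 4.4, 10, 114.1, 158,  96,  3.38, 1, 0.67, 0.89),
    D = c(1.88, 9.60,  3.65,  2.77, -3.5, 5.3, 14.5, 111.1, 151, 91, 49.70, 1, 1.01, 0.54),
    C = c(1.96, 10.28, 8.18,  5.07,  2.5, 1.7, 47, 108.5, 140,  86,  1.48, 1, 0.70, 1.19),
    Q = c(2.17, 9.13,  0.00,  5.65, -3.5, 4.0,  6.3, 143.8, 189, 114, 3.53, 1, 1.11, 1.10),
    E = c(2.19, 9.67,  4.25,  3.22, -3.5, 6.2, 20, 138.4, 183, 109, 49.90, 1, 1.51, 0.37),
    G = c(2.34, 9.60,  0.00,  5.97, -0.4, 7.2, 37, 60.1,  85,  48,  0.00, 0, 0.57, 0.75),
    H = c(1.82, 9.17,  6.00,  7.59, -3.2, 2.2, 19, 153.2, 194, 118, 51.60, 1, 1.00, 0.87),
    I = c(2.36, 9.60,  0.00,  6.02,  4.5, 5.2, 65, 166.7, 182, 124,  0.13, 0, 1.08, 1.60),
    L = c(2.36, 9.60,  0.00,  5.98,  3.8, 9.0, 41, 166.7, 180, 124,  0.13, 0, 1.21, 1.30),
    K = c(2.18, 8.95, 10.53,  9.74, -3.9, 5.7,  4.2, 168.6, 211, 135, 49.50, 1, 1.16, 0.74),
    M = c(2.28, 9.21,  0.00,  5.74,  1.9, 2.4, 50, 162.9, 204, 124,  1.43, 0, 1.45, 1.05),
    F = c(1.83, 9.13,  0.00,  5.48,  2.8, 3.9, 48, 189.9, 218, 135,  0.35, 0, 1.13, 1.38),
    P = c(1.99, 10.60, 0.00,  6.30, -1.6, 5.1, 24, 112.7, 143,  90,  1.58, 0, 0.57, 0.55),
    S = c(2.21, 9.15,  0.00,  5.68, -0.8, 6.9, 24, 89.0, 122,  73,  1.67, 1, 0.77, 0.75),
    T = c(2.09, 9.10,  0.00,  5.60, -0.7, 5.8, 25, 116.1, 146,  93,  1.66, 1, 0.83, 1.19),
    W = c(2.83, 9.39,  0.00,  5.89, -0.9, 1.3, 23, 227.8, 259, 163,  2.10, 0, 1.08, 1.37),
    Y = c(2.20, 9.11, 10.07,  5.66, -1.3, 3.2, 13, 193.6, 229, 141,  1.61, 1, 0.69, 1.47),
    V = c(2.32, 9.62,  0.00,  5.96,  4.2, 6.6, 56, 140.0, 160, 105,  0.13, 0, 1.06, 1.70))
  colnames(m) <- PHYSCHEM_NAMES
  m[AA_ORDER, ]
})

#' Table of the 14 physicochemical amino-acid properties
#'
#' @return 20 x 14 numeric matrix (rows: amino acids in the canonical order;
#'   columns: pK1, pK2, pKR, pI, hydropathy index, percentage occurrence,
#'   percentage buried, average volume, accessible surface area, van der
#'   Waals volume, polarity ranking, side-chain polarity, alpha-helix
#'   preference, beta-strand preference).
#' @export
physchem_table <- function() PHYSCHEM_TABLE

#' Physicochemical property vector for a residue
#'
#' @param aa one-letter amino-acid code; `"X"` returns per-property means.
#' @return Named numeric vector of 14 property values.
#' @export
physchem_vector <- function(aa) {
  stopifnot(length(aa) == 1)
  if (aa == "X") return(colMeans(PHYSCHEM_TABLE))
  if (!aa %in% AA_ORDER) stop_gs("unknown amino-acid letter: ", aa)
  PHYSCHEM_TABLE[aa, ]
}

#' Residue-conservation score from a PSSM column
#'
#' Normalized information content of the frequency column at position `i`:
#' `1 - H_i / log2(20)` with `H_i = -sum_j p_ij log2(p_ij)` (and
#' `0 log 0 = 0`). Equals 0 for a uniform column and 1 for a one-hot column.
#'
#' @param profile a `pssm_profile`.
#' @param i 0-based position (vectorized).
#' @return Numeric in `[0, 1]`.
#' @examples
#' p <- synth_pssm("NAT", concentration = 50, seed = 1)
#' conservation_score(p, 0:2)
#' @export
conservation_score <- function(profile, i) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (any(i < 0 | i >= profile$length))
    stop_gs("position index out of range [0, ", profile$length - 1, "]")
  p <- profile$freqs[i + 1, , drop = FALSE]
  plogp <- p * log2(p)
  plogp[p <= 0] <- 0
  h <- -rowSums(plogp)
  unname(1 - h / log2(20))
}

#' Extract a PSSM log-odds column
#'
#' @param profile a `pssm_profile`.
#' @param i 0-based position.
#' @return The 20 log-odds values at position `i`, named by amino acid in
#'   the canonical order.
#' @export
pssm_column <- function(profile, i) {
  stopifnot(inherits(profile, "pssm_profile"), length(i) == 1)
  if (i < 0 || i >= profile$length)
    stop_gs("position index out of range [0, ", profile$length - 1, "]")
  profile$logodds[i + 1, ]
}
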