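# Encoding of candidate sites as fixed-length named feature vectors: a
# 2N+1-residue sequence window for sequence-derived features and a radius-R
# spatial window whose members' 14 structural channels are averaged.

STRUCT_CHANNELS <- c("acc_all", "acc_sidechain", "acc_mainchain",
                     "acc_nonpolar_sc", "acc_polar_sc", "ss_acc", "phi",
                     "psi", "log_odds", "ave_dpx", "sd_dpx", "sch_ave_dpx",
                     "sd_sch_dpx", "b_factor")

#' Window configuration
#'
#' @param N sequence half-window size in residues; the window holds
#'   `2N + 1` positions with the site at position `P(N+1)` (P8 for the
#'   default `N = 7`).
#' @param R structure-window sphere radius in Angstrom: a residue belongs to
#'   the window of a target when any of its atoms lies strictly within `R`
#'   of any atom of the target.
#' @param include_target whether the target residue is a member of its own
#'   structure window.
#' @return List of class `window_config`.
#' @export
window_config <- function(N = 7, R = 10.0, include_target = TRUE) {
  stopifnot(N >= 0, R > 0)
  structure(list(N = as.integer(N), R = R, include_target = include_target),
            class = "window_config")
}

#' Extract a padded sequence window
#'
#' Substring of length `2N + 1` centered at 0-based position `i`, padded
#' with `"X"` beyond the chain termini.
#'
#' @param sequence one-letter amino-acid string.
#' @param i 0-based site index.
#' @param N half-window size.
#' @return Character string of length `2N + 1`.
#' @export
sequence_window <- function(sequence, i, N = 7) {
  L <- nchar(sequence)
  stopifnot(i >= 0, i < L)
  pos <- (i - N):(i + N)
  ch <- rep("X", length(pos))
  ok <- pos >= 0 & pos < L
  ch[ok] <- strsplit(sequence, "")[[1]][pos[ok] + 1]
  paste(ch, collapse = "")
}

#' Flat index of a PSSM window feature
#'
#' Maps a window position `p` (1-based, 1..2N+1) and an amino-acid column
#' `a` (1..20) to the flat PSSM feature index `(p - 1) * 20 + a`, fixing the
#' meaning of feature names such as `PSSM_P38` (position 2, column 18) and
#' `PSSM_P250` (position 13, column 10).
#'
#' @param p window position, 1..15 for the default window.
#' @param a amino-acid column, 1..20 in the canonical order.
#' @param width window width (positions), default 15.
#' @return Integer flat index in 1..`20 * width`.
#' @export
pssm_flat_index <- function(p, a, width = 15) {
  stopifnot(all(p >= 1), all(p <= width), all(a >= 1), all(a <= 20))
  (p - 1) * 20 + a
}

#' Encode the sequence-derived feature block of a site
#'
#' Concatenates, in fixed order: the flattened PSSM log-odds window
#' (`20 * (2N+1)` features named `PSSM_P1` onward), the four AAindex scales
#' per window position (named `<scale>_P<p>`), the conservation score per
#' window position (`conservation_P<p>`), and the 14 physicochemical values
#' of the central residue (named `<property>_P<N+1>`). Window positions
#' beyond the termini use neutral padding: zero PSSM columns, scale means,
#' and a uniform (zero-conservation) column.
#'
#' @param model a `structure_model` (only its sequence is used).
#' @param pssm a `pssm_profile` of the same length as the sequence.
#' @param i 0-based site index.
#' @param cfg a [window_config()].
#' @return Named numeric vector (length 389 for the default window).
#' @export
encode_sequence_features <- function(model, pssm, i, cfg = window_config()) {
  L <- nchar(model$sequence)
  if (pssm$length != L)
    stop_gs("PSSM length (", pssm$length, ") does not match sequence length (", L, ")")
  stopifnot(i >= 0, i < L)
  N <- cfg$N
  w <- 2 * N + 1
  pos <- (i - N):(i + N)
  inside <- pos >= 0 & pos < L
  win <- sequence_window(model$sequence, i, N)
  win_aa <- strsplit(win, "")[[1]]

  pssm_block <- matrix(0, w, 20)
  pssm_block[inside, ] <- pssm$logodds[pos[inside] + 1, , drop = FALSE]
  pssm_vals <- as.numeric(t(pssm_block))
  names(pssm_vals) <- paste0("PSSM_P", seq_len(20 * w))

  scales <- aaindex_scales()
  aa_vals <- unlist(lapply(names(scales), function(s) {
    v <- aaindex_value(scales[[s]], win_aa)
    stats::setNames(v, paste0(s, "_P", seq_len(w)))
  }))

  cons <- numeric(w)
  cons[inside] <- conservation_score(pssm, pos[inside])
  names(cons) <- paste0("conservation_P", seq_len(w))

  pc <- physchem_vector(win_aa[N + 1])
  names(pc) <- paste0(PHYSCHEM_NAMES, "_P", N + 1)

  c(pssm_vals, aa_vals, cons, pc)
}

#' Residues in the structure window of a target
#'
#' All residues having any atom strictly closer than `R` to any atom of the
#' target residue (minimum over atom pairs; strict `<`).
#'
#' @param model a `structure_model`.
#' @param target 0-based residue index.
#' @param R sphere radius in Angstrom.
#' @param include_target include the target itself (default `TRUE`).
#' @return Sorted integer vector of 0-based residue indices.
#' @export
structure_window <- function(model, target, R = 10.0, include_target = TRUE) {
  a <- model$atoms
  stopifnot(target >= 0, target < model$n_res)
  tk <- a$res_idx == target
  tx <- a$x[tk]; ty <- a$y[tk]; tz <- a$z[tk]
  mind2 <- rep(Inf, model$n_res)
  for (j in seq_along(tx)) {
    d2 <- (a$x - tx[j])^2 + (a$y - ty[j])^2 + (a$z - tz[j])^2
    agg <- tapply(d2, factor(a$res_idx, levels = 0:(model$n_res - 1)), min)
    mind2 <- pmin(mind2, as.numeric(agg))
  }
  members <- which(mind2 < R^2) - 1L
  if (include_target) members <- sort(union(members, target))
  else members <- setdiff(members, target)
  members
}

#' Encode the structure-window-averaged feature block of a site
#'
#' Arithmetic mean of each of the 14 structural channels over the members of
#' the target's structure window. Missing values (undefined phi/psi at
#' termini, residues skipped in the epitope score) are excluded channel-wise;
#' an all-missing channel averages to 0.
#'
#' @param model a `structure_model`.
#' @param struct_feats per-residue table from [structure_features()].
#' @param target 0-based residue index.
#' @param cfg a [window_config()].
#' @return Named numeric vector of the 14 averaged channels.
#' @export
encode_structural_features <- function(model, struct_feats, target,
                                       cfg = window_config()) {
  stopifnot(nrow(struct_feats) == model$n_res)
  members <- structure_window(model, target, cfg$R, cfg$include_target)
  rows <- struct_feats[members + 1, , drop = FALSE]
  rows$phi[rows$phi_missing] <- NA
  rows$psi[rows$psi_missing] <- NA
  out <- vapply(STRUCT_CHANNELS, function(ch) {
    v <- rows[[ch]]
    v <- v[!is.na(v)]
    if (!length(v)) 0 else mean(v)
  }, numeric(1))
  out
}

#' Encode one candidate site as a full named feature vector
#'
#' Concatenation of the sequence block ([encode_sequence_features()]) and
#' the structure-window block ([encode_structural_features()]), with stable
#' global feature naming (403 features for the default configuration).
#'
#' @param model a `structure_model`.
#' @param pssm a `pssm_profile`.
#' @param struct_feats per-residue table from [structure_features()].
#' @param site 0-based residue index of the site.
#' @param cfg a [window_config()].
#' @return Named numeric vector.
#' @export
encode_site <- function(model, pssm, struct_feats, site,
                        cfg = window_config()) {
  c(encode_sequence_features(model, pssm, site, cfg),
    encode_structural_features(model, struct_feats, site, cfg))
}

#' Encode a table of candidate sites into a feature matrix
#'
#' Batch encoder over one structure: computes the structural channels once,
#' then encodes every site in `sites`. The result carries the site identity
#' columns followed by the named features.
#'
#' @param model a `structure_model`.
#' @param pssm a `pssm_profile`.
#' @param sites data.frame of site records (from [candidate_sites()] or
#'   [generate_dataset()]); rows not belonging to `model` are ignored.
#' @param cfg a [window_config()].
#' @param struct_feats optional precomputed [structure_features()] table.
#' @param sasa_cfg a [sasa_config()] used when `struct_feats` is missing.
#' @return data.frame: `structure_id`, `chain`, `seq_index`, `aa`, `label`,
#'   then one column per feature.
#' @export
encode_sites <- function(model, pssm, sites, cfg = window_config(),
                         struct_feats = NULL, sasa_cfg = sasa_config()) {
  sites <- sites[sites$structure_id == model$structure_id &
                   sites$chain == model$chain_id, , drop = FALSE]
  if (nrow(sites) == 0) return(NULL)
  if (is.null(struct_feats)) struct_feats <- structure_features(model, sasa_cfg)
  vecs <- lapply(sites$seq_index, function(i)
    encode_site(model, pssm, struct_feats, i, cfg))
  X <- do.call(rbind, vecs)
  if (anyDuplicated(colnames(X))) stop_gs("duplicated feature names")
  cbind(data.frame(structure_id = sites$structure_id, chain = sites$chain,
                   seq_index = sites$seq_index, aa = sites$aa,
                   label = sites$label, stringsAsFactors = FALSE),
        as.data.frame(X, check.names = FALSE))
}

#' Split a feature-matrix data.frame into X and metadata
#'
#' @param feats data.frame from [encode_sites()] (possibly row-bound over
#'   structures).
#' @return List with numeric matrix `x`, integer labels `y` (`NA` for
#'   unknown) and the metadata data.frame `meta`.
#' @export
feature_matrix <- function(feats) {
  meta_cols <- c("structure_id", "chain", "seq_index", "aa", "label")
  x <- as.matrix(feats[, setdiff(colnames(feats), meta_cols), drop = FALSE])
  y <- ifelse(feats$label == "positive", 1L,
              ifelse(feats$label == "negative", 0L, NA_integer_))
  list(x = x, y = y, meta = feats[, meta_cols, drop = FALSE])
}
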