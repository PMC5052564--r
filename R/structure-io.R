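# Parsing of protein structures and of the per-residue feature files produced
# by the external tools the feature set is defined against (PSI-BLAST ASCII
# PSSMs, DSSP output, NACCESS .rsa tables, plain residue-score tables).

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model from an atom table
#'
#' Internal constructor used by both the PDB parser and the synthetic
#' structure builder. The atom table must hold one row per (retained) atom
#' with columns `res_idx` (0-based residue index), `author` (author residue
#' number plus insertion code, as character), `aa` (one-letter code),
#' `atom` (PDB atom name), `element`, `x`, `y`, `z`, `b`, `occupancy`,
#' `altloc`.
#'
#' @param atoms data.frame of atoms as described above.
#' @param structure_id structure identifier (e.g. a PDB id).
#' @param chain_id single-character chain identifier.
#' @return An object of class `structure_model`: a list with the atom table,
#'   the derived one-letter `sequence`, per-residue `aa` and `author`
#'   vectors, and `n_res`.
#' @keywords internal
new_structure_model <- function(atoms, structure_id, chain_id) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  atoms$mainchain <- atoms$atom %in% MAINCHAIN_ATOMS
  idx <- sort(unique(atoms$res_idx))
  if (!identical(idx, seq_along(idx) - 1L)) {
    remap <- match(atoms$res_idx, idx) - 1L
    atoms$res_idx <- remap
    idx <- seq_along(idx) - 1L
  }
  first <- atoms[!duplicated(atoms$res_idx), , drop = FALSE]
  first <- first[order(first$res_idx), , drop = FALSE]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop_gs("non-finite atom coordinates")
  structure(
    list(structure_id = structure_id,
         chain_id = chain_id,
         atoms = atoms,
         aa = first$aa,
         author = first$author,
         sequence = paste(first$aa, collapse = ""),
         n_res = length(idx)),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d residues, %d atoms\n",
              x$structure_id, x$chain_id, x$n_res, nrow(x$atoms)))
  cat(" sequence:", x$sequence, "\n")
  invisible(x)
}

#' Parse a single chain from a PDB file
#'
#' Reads the first MODEL of a PDB-format file and returns the requested chain
#' as a `structure_model`. Only standard-residue ATOM records are kept
#' (HETATM and waters are excluded, except modified residues with a
#' conventional parent such as MSE, which are mapped to that parent).
#' Hydrogens are stripped. For alternate locations the highest-occupancy
#' altloc is retained, ties broken by lexicographically first altloc id.
#'
#' @param path path to a PDB-format text file.
#' @param chain chain identifier to extract.
#' @param structure_id optional identifier; defaults to the file base name.
#' @return A `structure_model`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' m0 <- build_ideal_structure("ANSTG", geometry = "helix", seed = 1)
#' write_structure(m0, pdb)
#' m <- parse_pdb(pdb, chain = "A")
#' m$sequence
#' @export
parse_pdb <- function(path, chain, structure_id = NULL) {
  if (!file.exists(path)) stop_gs("PDB file not found: ", path)
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!chain %in% unique(at$chain))
    stop_gs("chain not found: '", chain, "' in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  standard <- at$type == "ATOM" & at$resid %in% names(AA_THREE)
  mapped <- at$resid %in% names(AA_NONSTANDARD)
  skipped <- unique(at$resid[!(standard | mapped) & at$resid != "HOH"])
  if (length(skipped))
    warning("skipping nonstandard residues without a parent mapping: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  at <- at[standard | mapped, , drop = FALSE]
  if (nrow(at) == 0) stop_gs("empty chain: no standard residues in chain ", chain)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[^A-Za-z]", "", at$elety[bad]), 1, 1)
  elem <- toupper(elem)
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties to the lexicographically first altloc id
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, at$alt)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)                     # restore file order
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  author <- paste0(at$resno, at$insert)
  res_key <- unique(author)              # first-occurrence (file) order
  res_idx <- match(author, res_key) - 1L
  aa3 <- at$resid
  aa1 <- aa_three_to_one(aa3)
  aa1[is.na(aa1)] <- "X"
  atoms <- data.frame(
    res_idx = res_idx,
    author = paste0(at$resno, at$insert),
    aa = aa1,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = at$alt,
    stringsAsFactors = FALSE)
  new_structure_model(atoms, structure_id, chain)
}

#' Write a structure model as PDB text
#'
#' Serializes a `structure_model` back to a standard PDB file (ATOM records
#' only), allowing round-trip tests and generation of synthetic fixture
#' files.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = as.integer(sub("[A-Za-z]+$", "", a$author)),
    resid = unname(AA_ONE_TO_THREE[a$aa]),
    eleno = seq_len(nrow(a)),
    elety = a$atom,
    chain = rep(model$chain_id, nrow(a)),
    o = a$occupancy,
    b = a$b,
    elesy = a$element)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM layout: a header line listing the 20
#' amino-acid columns twice (log-odds then percentages), followed by one row
#' per residue. Percentages are converted to frequencies and each row is
#' renormalized to sum to one; all-zero rows are renormalized to the uniform
#' distribution.
#'
#' @param path path to the ASCII PSSM file.
#' @return An object of class `pssm_profile`: list with `length`, `sequence`
#'   (query residues), integer matrix `logodds` (L x 20) and numeric matrix
#'   `freqs` (L x 20), columns in the order `A R N D C Q E G H I L K M F P S
#'   T W Y V` (`aa_order`).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop_gs("PSSM file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C\\s+Q\\s+E\\s+G", lines)
  if (!length(hdr)) stop_gs("not an ASCII PSSM: header row of amino-acid columns not found")
  hdr <- hdr[1]
  rows <- list()
  seq_chars <- character()
  for (k in seq(hdr + 1, length(lines))) {
    ln <- lines[k]
    if (!grepl("^\\s*\\d+\\s+[A-Za-z]", ln)) {
      if (length(rows)) break else next
    }
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    # index, residue, 20 log-odds, 20 percentages, then optionally
    # information content and gapless weight
    if (length(tok) < 42)
      stop_gs("malformed PSSM row at line ", k, ": expected 40 numeric columns, found ",
              length(tok) - 2)
    vals <- suppressWarnings(as.numeric(tok[3:42]))
    if (any(is.na(vals)))
      stop_gs("malformed PSSM row at line ", k, ": non-numeric entry")
    seq_chars <- c(seq_chars, toupper(tok[2]))
    rows[[length(rows) + 1]] <- vals
  }
  if (!length(rows)) stop_gs("no PSSM data rows found in ", path)
  m <- do.call(rbind, rows)
  logodds <- m[, 1:20, drop = FALSE]
  freqs <- m[, 21:40, drop = FALSE] / 100
  rs <- rowSums(freqs)
  zero <- rs <= 0
  freqs[zero, ] <- 1 / 20
  freqs[!zero, ] <- freqs[!zero, , drop = FALSE] / rs[!zero]
  new_pssm_profile(logodds, freqs, paste(seq_chars, collapse = ""))
}

#' @keywords internal
#' @noRd
new_pssm_profile <- function(logodds, freqs, sequence = NULL) {
  colnames(logodds) <- AA_ORDER
  colnames(freqs) <- AA_ORDER
  structure(list(length = nrow(logodds),
                 sequence = sequence,
                 logodds = logodds,
                 freqs = freqs,
                 aa_order = paste(AA_ORDER, collapse = "")),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %d positions x 20 columns (%s)\n",
              x$length, x$aa_order))
  invisible(x)
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Counterpart of [read_pssm()]; used to materialize synthetic profiles as
#' files so the reader can be exercised on realistic input.
#'
#' @param profile a `pssm_profile`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", AA_ORDER), collapse = " "), "  ",
                    paste(sprintf("%3s", AA_ORDER), collapse = " ")), con)
  seqc <- if (is.null(profile$sequence)) strrep("X", profile$length) else profile$sequence
  for (i in seq_len(profile$length)) {
    writeLines(paste0(sprintf("%5d %s ", i, substr(seqc, i, i)),
                      paste(sprintf("%3d", profile$logodds[i, ]), collapse = " "), "  ",
                      paste(sprintf("%3d", round(100 * profile$freqs[i, ])), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  invisible(path)
}

#' Read per-residue accessibility, phi and psi from a DSSP output file
#'
#' Extracts the ACC (water-contact solvent accessibility), phi and psi
#' columns of a standard DSSP output file. Angles printed as 360.0 (the DSSP
#' convention for undefined termini) are mapped to `NA`.
#'
#' @param path path to a DSSP output file.
#' @return data.frame with columns `chain`, `author` (residue number plus
#'   insertion code), `aa`, `acc`, `phi`, `psi`; one row per residue.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop_gs("DSSP file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop_gs("not a DSSP file: '  #  RESIDUE' header not found")
  if (hdr[1] >= length(lines)) stop_gs("DSSP file has an empty data section")
  body <- lines[seq(hdr[1] + 1, length(lines))]
  body <- body[nchar(body) >= 115]
  # chain-break records carry '!' in the residue column
  body <- body[substr(body, 14, 14) != "!"]
  if (!length(body)) stop_gs("DSSP file has an empty data section")
  num <- trimws(substr(body, 6, 10))
  ins <- trimws(substr(body, 11, 11))
  parse_angle <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    v[!is.na(v) & abs(v - 360) < 1e-9] <- NA
    v
  }
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    author = paste0(num, ins),
    aa = trimws(substr(body, 14, 14)),
    acc = suppressWarnings(as.numeric(trimws(substr(body, 35, 38)))),
    phi = parse_angle(substr(body, 104, 109)),
    psi = parse_angle(substr(body, 110, 115)),
    stringsAsFactors = FALSE)
}

#' Read absolute accessibilities from a NACCESS .rsa file
#'
#' Extracts the five absolute surface-accessibility classes from the RES
#' lines of a NACCESS .rsa file: all atoms, total side chain, main chain,
#' non-polar side chain and polar side chain. Relative (percentage) columns
#' are ignored.
#'
#' @param path path to a .rsa file.
#' @return data.frame with columns `chain`, `author`, `aa3`, `acc_all`,
#'   `acc_sidechain`, `acc_mainchain`, `acc_nonpolar_sc`, `acc_polar_sc`.
#' @export
read_rsa <- function(path) {
  if (!file.exists(path)) stop_gs(".rsa file not found: ", path)
  lines <- grep("^RES ", readLines(path), value = TRUE)
  if (!length(lines)) stop_gs("no RES lines found in ", path)
  # layout: RES aaa c nnnni then 5 x (ABS, REL); fields are space-separated
  # in practice, so the 10 numeric values are taken as the trailing tokens
  vals <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    if (length(tok) < 13) stop_gs("truncated RES line in ", path)
    v <- suppressWarnings(as.numeric(utils::tail(tok, 10)))
    if (any(is.na(v))) stop_gs("non-numeric accessibility field in ", path)
    v
  })
  m <- do.call(rbind, vals)
  data.frame(
    chain = trimws(substr(lines, 9, 9)),
    author = trimws(substr(lines, 10, 14)),
    aa3 = trimws(substr(lines, 5, 7)),
    acc_all = m[, 1],
    acc_sidechain = m[, 3],
    acc_mainchain = m[, 5],
    acc_nonpolar_sc = m[, 7],
    acc_polar_sc = m[, 9],
    stringsAsFactors = FALSE)
}

#' Write a NACCESS-style .rsa file
#'
#' Counterpart of [read_rsa()] for fixture generation; relative columns are
#' filled with zeros.
#'
#' @param df data.frame as returned by [read_rsa()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_rsa <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(sprintf("RES %3s %s%4s %7.2f%6.1f %7.2f%6.1f %7.2f%6.1f %7.2f%6.1f %7.2f%6.1f",
                       df$aa3[i], df$chain[i], df$author[i],
                       df$acc_all[i], 0, df$acc_sidechain[i], 0,
                       df$acc_mainchain[i], 0, df$acc_nonpolar_sc[i], 0,
                       df$acc_polar_sc[i], 0), con)
  }
  invisible(path)
}

#' Read a plain per-residue score table
#'
#' Reads a whitespace- or tab-delimited table of `chain`, residue number and
#' score (for example per-residue epitope log-odds exported from an external
#' predictor), for verbatim injection into the structural feature channels.
#'
#' @param path path to the table.
#' @return data.frame with columns `chain`, `author`, `score`.
#' @export
read_residue_scores <- function(path) {
  if (!file.exists(path)) stop_gs("score table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop_gs("empty score table: ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(tok) < 3)) stop_gs("score table rows must have 3 columns: chain residue score")
  chain <- vapply(tok, `[`, "", 1)
  author <- vapply(tok, `[`, "", 2)
  score <- suppressWarnings(as.numeric(vapply(tok, `[`, "", 3)))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1]
    stop_gs("non-numeric score on row ", bad, " of ", path)
  }
  key <- paste(chain, author)
  if (anyDuplicated(key))
    stop_gs("duplicate residue in score table: ", key[duplicated(key)][1])
  data.frame(chain = chain, author = author, score = score,
             stringsAsFactors = FALSE)
}
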