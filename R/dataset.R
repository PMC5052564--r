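# Labeled site datasets: candidate extraction, sequon checking, label
# attachment, 1:1 negative under-sampling and the benchmark/independent
# split.

#' Check the N-glycosylation sequon at an asparagine
#'
#' Tests the consensus motif Asn-X-Ser/Thr (X any residue except Pro) at a
#' 0-based asparagine position.
#'
#' @param sequence one-letter amino-acid string.
#' @param i 0-based index of an Asn residue.
#' @return Logical; `FALSE` when the motif is truncated by the C terminus.
#' @export
check_sequon <- function(sequence, i) {
  L <- nchar(sequence)
  stopifnot(i >= 0, i < L)
  if (substr(sequence, i + 1, i + 1) != "N")
    stop_gs("check_sequon requires an Asn at position ", i)
  if (i + 2 >= L) return(FALSE)
  x <- substr(sequence, i + 2, i + 2)
  st <- substr(sequence, i + 3, i + 3)
  x != "P" && st %in% c("S", "T")
}

#' Extract candidate glycosylation sites from a structure
#'
#' N-linked candidates are all asparagines (with the sequon flag recorded as
#' metadata); O-linked candidates are all serines and threonines. Labels are
#' `"unknown"` until [apply_labels()] or a planted rule assigns them.
#'
#' @param model a `structure_model`.
#' @param glyco_type `"N"` or `"O"`.
#' @return data.frame of site records: `structure_id`, `chain`, `seq_index`
#'   (0-based), `author`, `aa`, `glyco_type`, `label`, `sequon`.
#' @export
candidate_sites <- function(model, glyco_type = c("N", "O")) {
  glyco_type <- match.arg(glyco_type)
  aa <- model$aa
  idx <- if (glyco_type == "N") which(aa == "N") else which(aa %in% c("S", "T"))
  sequon <- logical(length(idx))
  if (glyco_type == "N")
    sequon <- vapply(idx - 1L, function(i) check_sequon(model$sequence, i),
                     logical(1))
  data.frame(structure_id = rep(model$structure_id, length(idx)),
             chain = rep(model$chain_id, length(idx)),
             seq_index = idx - 1L,
             author = model$author[idx],
             aa = aa[idx],
             glyco_type = rep(glyco_type, length(idx)),
             label = rep("unknown", length(idx)),
             sequon = sequon,
             stringsAsFactors = FALSE)
}

#' Attach experimental labels to candidate sites
#'
#' Annotated candidates become positive. Remaining candidates in structures
#' that contain at least one positive become negative (the
#' negatives-from-positive-chains convention); candidates in structures
#' without any positive stay `"unknown"` and are excluded from training.
#'
#' @param records candidate-site data.frame from [candidate_sites()].
#' @param annotations data.frame with columns `structure_id`, `chain`,
#'   `author` (author residue number) and `glyco_type`.
#' @return The records with labels filled in. Annotations that do not match
#'   a candidate residue raise an error identifying the offending row.
#' @export
apply_labels <- function(records, annotations) {
  key <- paste(records$structure_id, records$chain, records$author,
               records$glyco_type)
  akey <- paste(annotations$structure_id, annotations$chain,
                annotations$author, annotations$glyco_type)
  hit <- match(akey, key)
  if (any(is.na(hit))) {
    bad <- which(is.na(hit))[1]
    stop_gs("annotation row ", bad, " (", akey[bad],
            ") does not match any candidate N/S/T residue")
  }
  records$label <- "unknown"
  records$label[hit] <- "positive"
  pos_struct <- unique(records$structure_id[records$label == "positive"])
  neg <- records$label != "positive" & records$structure_id %in% pos_struct
  records$label[neg] <- "negative"
  nonseq <- records$label == "positive" & records$glyco_type == "N" &
    !records$sequon
  if (any(nonseq))
    warning(sum(nonseq), " positive N-linked site(s) do not conform to the ",
            "Asn-X-Ser/Thr sequon; kept", call. = FALSE)
  records
}

#' Under-sample negatives to a target positive:negative ratio
#'
#' Keeps all positives and uniformly samples `floor(ratio * n_pos)`
#' negatives without replacement. When fewer negatives exist, all are kept
#' with a warning. `"unknown"` records are dropped.
#'
#' @param records labeled site data.frame.
#' @param ratio negatives per positive (default 1 for a balanced set).
#' @param seed integer seed controlling the sample.
#' @return Balanced data.frame of site records.
#' @export
undersample_negatives <- function(records, ratio = 1.0, seed = 1) {
  pos <- which(records$label == "positive")
  neg <- which(records$label == "negative")
  if (!length(pos)) stop_gs("no positive sites: cannot undersample")
  target <- floor(ratio * length(pos))
  if (length(neg) < target) {
    warning("only ", length(neg), " negatives available for target ", target,
            "; keeping all", call. = FALSE)
    keep <- neg
  } else {
    keep <- with_seed(seed, sort(sample(neg, target)))
  }
  records[sort(c(pos, keep)), , drop = FALSE]
}

#' Split sites into benchmark and independent sets by structure
#'
#' Random partition at the structure level (every site of a chain falls in
#' the same partition) targeting the requested fraction of sites in the
#' independent set: structures are shuffled under the seed and accumulated
#' into the independent partition until its site count reaches the target.
#'
#' @param records labeled site data.frame.
#' @param fraction target fraction of sites in the independent set.
#' @param seed integer seed.
#' @return List of class `dataset_split` with data.frames `benchmark` and
#'   `independent`, plus `seed` and `fraction`.
#' @export
split_dataset <- function(records, fraction = 0.2, seed = 1) {
  ids <- unique(records$structure_id)
  if (length(ids) < 2)
    stop_gs("need at least two structures to split at the structure level")
  target <- fraction * nrow(records)
  ord <- with_seed(seed, sample(ids))
  counts <- table(records$structure_id)[ord]
  csum <- cumsum(as.numeric(counts))
  n_take <- which(csum >= target)[1]
  if (is.na(n_take)) n_take <- length(ord)
  indep_ids <- ord[seq_len(n_take)]
  structure(list(
    benchmark = records[!records$structure_id %in% indep_ids, , drop = FALSE],
    independent = records[records$structure_id %in% indep_ids, , drop = FALSE],
    seed = seed, fraction = fraction),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> benchmark: %d sites / %d structures; independent: %d sites / %d structures\n",
              nrow(x$benchmark), length(unique(x$benchmark$structure_id)),
              nrow(x$independent), length(unique(x$independent$structure_id))))
  invisible(x)
}

#' Optional redundancy-reduction pre-filter
#'
#' Hook for user-supplied sequence clustering (for example CD-HIT output):
#' keeps one representative structure per cluster. Clustering itself is not
#' performed here.
#'
#' @param records site data.frame.
#' @param clusters data.frame with columns `structure_id` and `cluster`.
#' @return Filtered records containing only cluster representatives (the
#'   first structure listed per cluster).
#' @export
filter_redundancy <- function(records, clusters) {
  reps <- clusters$structure_id[!duplicated(clusters$cluster)]
  records[records$structure_id %in% reps |
            !records$structure_id %in% clusters$structure_id, , drop = FALSE]
}
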