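# Cold-split benchmark protocols: novel pair, novel compound, novel protein,
# the hard-pair similarity filter, and entity-level k-fold cross-validation.

# shuffled quota partition of entity ids into named groups
.partition_entities <- function(ids, ratios) {
  ids <- sample(ids)
  n <- length(ids)
  sizes <- floor(ratios / sum(ratios) * n)
  while (sum(sizes) < n) {
    i <- which.max(ratios / sum(ratios) * n - sizes)
    sizes[i] <- sizes[i] + 1L
  }
  if (any(sizes == 0)) {
    rlang::abort(paste0("Infeasible ratios: only ", n, " entities for ",
                        length(ratios), " parts; achievable maxima ",
                        paste(sizes, collapse = "/"), "."),
                 class = "cpinet_contract_error")
  }
  part <- rep(names(ratios), times = sizes)
  stats::setNames(part, ids)
}

.new_split <- function(data, part, protocol, seed, params, dropped = 0L) {
  out <- tibble::tibble(.row = seq_len(nrow(data)), part = part)
  structure(out, protocol = protocol, seed = seed, params = params,
            dropped = dropped, class = c("cpi_split", class(out)))
}

#' @export
print.cpi_split <- function(x, ...) {
  cat("<cpi_split> protocol:", attr(x, "protocol"), " seed:", attr(x, "seed"),
      "\n  parts:", paste(names(table(x$part)), table(x$part),
                          sep = "=", collapse = " "),
      " dropped:", attr(x, "dropped"), "\n")
  invisible(x)
}

# carve a validation set out of the training records (record-level)
.carve_validation <- function(part, val_fraction) {
  tr <- which(part == "train")
  n_val <- floor(length(tr) * val_fraction)
  if (n_val >= 1) part[sample(tr, n_val)] <- "validation"
  part
}

#' Novel-pair split
#'
#' Compounds and proteins are partitioned independently; a record is assigned
#' to test only when both its compound and its protein fall on the test side,
#' to train only when both fall on the train side. Records mixing sides are
#' dropped (the count is recorded). A validation set is carved from the
#' training records at `val_fraction`.
#'
#' @param data Interaction table with `compound_id` and `protein_id` columns.
#' @param test_fraction Fraction of entities assigned to the test side.
#' @param val_fraction Fraction of training records moved to validation
#'   (the 80/20 train:validation convention).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A `cpi_split` tibble (`.row`, `part`) with attributes `protocol`,
#'   `seed`, `params` and `dropped`.
#' @export
split_novel_pair <- function(data, test_fraction = 0.2, val_fraction = 0.2,
                             seed = 1) {
  set.seed(seed)
  cpart <- .partition_entities(unique(data$compound_id),
                               c(train = 1 - test_fraction,
                                 test = test_fraction))
  ppart <- .partition_entities(unique(data$protein_id),
                               c(train = 1 - test_fraction,
                                 test = test_fraction))
  cside <- cpart[data$compound_id]
  pside <- ppart[data$protein_id]
  part <- ifelse(cside == pside, cside, NA_character_)
  dropped <- sum(is.na(part))
  if (dropped > 0) {
    rlang::inform(paste0(dropped,
                         " record(s) straddling the entity partition dropped."))
  }
  part[is.na(part)] <- "dropped"
  part <- .carve_validation(part, val_fraction)
  .new_split(data, part, "novel_pair", seed,
             list(test_fraction = test_fraction,
                  val_fraction = val_fraction), dropped)
}

.split_novel_entity <- function(data, id_col, protocol, test_fraction,
                                val_fraction, seed) {
  set.seed(seed)
  epart <- .partition_entities(unique(data[[id_col]]),
                               c(train = 1 - test_fraction,
                                 test = test_fraction))
  part <- unname(epart[data[[id_col]]])
  part <- .carve_validation(part, val_fraction)
  .new_split(data, part, protocol, seed,
             list(test_fraction = test_fraction, val_fraction = val_fraction))
}

#' Novel-compound split
#'
#' Compounds are partitioned; every record of a compound lands on the same
#' side, so train and test share no compounds (proteins may be shared).
#'
#' @inheritParams split_novel_pair
#' @return A `cpi_split`.
#' @export
split_novel_compound <- function(data, test_fraction = 0.2,
                                 val_fraction = 0.2, seed = 1) {
  .split_novel_entity(data, "compound_id", "novel_compound", test_fraction,
                      val_fraction, seed)
}

#' Novel-protein split
#'
#' Mirror of [split_novel_compound()] with proteins partitioned.
#'
#' @inheritParams split_novel_pair
#' @return A `cpi_split`.
#' @export
split_novel_protein <- function(data, test_fraction = 0.2,
                                val_fraction = 0.2, seed = 1) {
  .split_novel_entity(data, "protein_id", "novel_protein", test_fraction,
                      val_fraction, seed)
}

#' Filter test records by cross-set similarity (novel-hard)
#'
#' Keeps a test record only when its compound's maximum Tanimoto similarity to
#' any training compound and its protein's maximum alignment similarity to any
#' training protein are below `threshold` (mode `"both"`); mode `"either"`
#' keeps records where at least one of the two is below.
#'
#' @param test_records,train_records Interaction tables with `smiles` and
#'   `sequence` columns.
#' @param threshold Similarity cutoff (the hard-split convention is 0.3).
#' @param mode `"both"` (stricter, default) or `"either"`.
#' @param fp_radius,fp_bits Fingerprint settings for the Tanimoto side.
#' @param fixed_len Denominator for the protein similarity.
#' @return The kept rows of `test_records` as a tibble, with attribute
#'   `removed` (count).
#' @export
filter_hard <- function(test_records, train_records, threshold = 0.3,
                        mode = c("both", "either"), fp_radius = 2,
                        fp_bits = 2048, fixed_len = 500) {
  mode <- match.arg(mode)
  if (nrow(test_records) == 0) return(tibble::as_tibble(test_records))
  tr_smi <- unique(train_records$smiles)
  te_smi <- unique(test_records$smiles)
  tr_fp <- lapply(tr_smi, smiles_to_fingerprint, radius = fp_radius,
                  n_bits = fp_bits)
  te_fp <- lapply(te_smi, smiles_to_fingerprint, radius = fp_radius,
                  n_bits = fp_bits)
  max_tani <- vapply(te_fp, function(f)
    max(vapply(tr_fp, tanimoto, numeric(1), b = f)), numeric(1))
  names(max_tani) <- te_smi
  tr_seq <- unique(train_records$sequence)
  te_seq <- unique(test_records$sequence)
  max_psim <- vapply(te_seq, function(s)
    max(vapply(tr_seq, protein_similarity, numeric(1), seq_b = s,
               fixed_len = fixed_len)), numeric(1))
  names(max_psim) <- te_seq
  c_ok <- max_tani[test_records$smiles] < threshold
  p_ok <- max_psim[test_records$sequence] < threshold
  keep <- if (mode == "both") c_ok & p_ok else c_ok | p_ok
  if (!any(keep)) {
    rlang::warn("Hard filter removed every test record.")
  }
  out <- tibble::as_tibble(test_records)[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Entity-level k-fold cross-validation splits
#'
#' Entities (compounds, proteins, or both for the pair protocol) are assigned
#' to `k` folds; fold `f`'s test set honors the protocol's disjointness and
#' rotates so that each entity is tested exactly once. A validation set is
#' carved from each fold's training records.
#'
#' @param data Interaction table.
#' @param k Number of folds (>= 2).
#' @param protocol `"novel_pair"`, `"novel_compound"` or `"novel_protein"`.
#' @param val_fraction Validation fraction of training records per fold.
#' @param seed Integer seed.
#' @return List of `k` `cpi_split` objects.
#' @export
kfold_split <- function(data, k = 5, protocol = c("novel_pair",
                                                  "novel_compound",
                                                  "novel_protein"),
                        val_fraction = 0.2, seed = 1) {
  protocol <- match.arg(protocol)
  if (k < 2) rlang::abort("k must be >= 2.", class = "cpinet_contract_error")
  set.seed(seed)
  fold_of <- function(ids) {
    if (length(ids) < k) {
      rlang::abort(paste0("Fewer entities (", length(ids), ") than folds (",
                          k, ")."), class = "cpinet_contract_error")
    }
    stats::setNames(rep_len(seq_len(k), length(ids)), sample(ids))
  }
  cfold <- if (protocol != "novel_protein") fold_of(unique(data$compound_id))
  pfold <- if (protocol != "novel_compound") fold_of(unique(data$protein_id))
  lapply(seq_len(k), function(f) {
    part <- switch(protocol,
      novel_compound = ifelse(cfold[data$compound_id] == f, "test", "train"),
      novel_protein = ifelse(pfold[data$protein_id] == f, "test", "train"),
      novel_pair = {
        cs <- ifelse(cfold[data$compound_id] == f, "test", "train")
        ps <- ifelse(pfold[data$protein_id] == f, "test", "train")
        ifelse(cs == ps, cs, "dropped")
      })
    part <- unname(part)
    dropped <- sum(part == "dropped")
    part <- .carve_validation(part, val_fraction)
    .new_split(data, part, protocol, seed,
               list(k = k, fold = f, val_fraction = val_fraction), dropped)
  })
}

#' Check a split's disjointness contract
#'
#' Verifies the protocol-specific constraints: train/validation and test
#' share no compounds (novel compound and pair), no proteins (novel protein
#' and pair), and the parts partition the non-dropped records.
#'
#' @param data The interaction table the split was built from.
#' @param split A `cpi_split`.
#' @return `TRUE` invisibly on success; aborts with the violated constraint
#'   otherwise.
#' @export
check_split <- function(data, split) {
  protocol <- attr(split, "protocol")
  stopifnot(nrow(split) == nrow(data))
  tr <- data[split$part %in% c("train", "validation"), , drop = FALSE]
  te <- data[split$part == "test", , drop = FALSE]
  fail <- function(msg) rlang::abort(paste0("Split violates ", protocol, ": ",
                                            msg), class = "cpinet_data_error")
  if (protocol %in% c("novel_pair", "novel_compound")) {
    if (length(intersect(tr$compound_id, te$compound_id)))
      fail("shared compounds between train and test")
  }
  if (protocol %in% c("novel_pair", "novel_protein")) {
    if (length(intersect(tr$protein_id, te$protein_id)))
      fail("shared proteins between train and test")
  }
  if (!all(split$part %in% c("train", "validation", "test", "dropped")))
    fail("unknown part label")
  invisible(TRUE)
}

#' Materialize split parts as data subsets
#'
#' @param data Interaction table.
#' @param split A `cpi_split`.
#' @return Named list of tibbles: `train`, `validation`, `test`.
#' @export
split_parts <- function(data, split) {
  lapply(stats::setNames(nm = c("train", "validation", "test")), function(pp)
    tibble::as_tibble(data)[split$part == pp, , drop = FALSE])
}
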