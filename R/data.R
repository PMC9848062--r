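# Interaction-table I/O, dataset statistics, and the synthetic generator with
# a planted signal.

#' Packaged drug-like molecules
#'
#' Fifty valid drug-like SMILES shipped with the package, used by the
#' synthetic generator and available for tests and examples.
#'
#' @return Tibble with `compound_id` and `smiles`.
#' @export
druglike_smiles <- function() {
  path <- system.file("extdata", "druglike_smiles.csv", package = "cpinet")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read an interaction table
#'
#' Reads a delimited file (comma or tab, chosen by extension or `format`),
#' resolves columns by header or an explicit mapping, validates every record
#' (parseable SMILES, finite affinity) and rejects invalid rows with their
#' line numbers.
#'
#' @param path File path.
#' @param format `"auto"`, `"csv"` or `"tsv"`.
#' @param col_map Optional named character vector mapping the canonical names
#'   (`compound_id`, `smiles`, `protein_id`, `sequence`, `affinity`,
#'   `activity`) to the file's column names.
#' @param sequences_fasta Optional FASTA file of protein sequences joined by
#'   `protein_id`, for tables that carry ids instead of sequences.
#' @param validate Parse-check each SMILES (default `TRUE`).
#' @return Tibble of validated interaction records.
#' @export
read_interactions <- function(path, format = c("auto", "csv", "tsv"),
                              col_map = NULL, sequences_fasta = NULL,
                              validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "cpinet_data_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "tsv" else "csv"
  }
  df <- if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        rlang::abort(paste0("Mapped column '", col_map[[canon]],
                            "' not present."), class = "cpinet_data_error")
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  if (!is.null(sequences_fasta)) {
    seqs <- Biostrings::readAAStringSet(sequences_fasta)
    lk <- stats::setNames(as.character(seqs),
                          sub("\\s.*$", "", names(seqs)))
    df$sequence <- unname(lk[df$protein_id])
  }
  required <- c("smiles", "sequence", "affinity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "cpinet_data_error")
  }
  if (!"compound_id" %in% names(df)) {
    df$compound_id <- paste0("cmpd_", as.integer(factor(df$smiles,
                                                        levels = unique(df$smiles))))
  }
  if (!"protein_id" %in% names(df)) {
    df$protein_id <- paste0("prot_", as.integer(factor(df$sequence,
                                                       levels = unique(df$sequence))))
  }
  df$affinity <- suppressWarnings(as.numeric(df$affinity))
  bad <- !is.finite(df$affinity) | is.na(df$smiles) | is.na(df$sequence)
  if (validate) {
    parse_ok <- vapply(df$smiles, function(s) {
      if (is.na(s)) return(FALSE)
      !inherits(try(.parse_smiles_sdf(s), silent = TRUE), "try-error")
    }, logical(1))
    bad <- bad | !parse_ok
  }
  if (any(bad)) {
    # +1 for the header line
    rlang::inform(paste0("Rejected ", sum(bad), " invalid row(s) at line(s): ",
                         paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  rlang::inform(paste0("Read ", nrow(df), " valid interaction record(s)."))
  tibble::as_tibble(df)
}

#' Write an interaction table
#'
#' @param data Interaction tibble.
#' @param path Destination (`.tsv`/`.tab`/`.txt` writes tab-separated,
#'   anything else comma-separated).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(data, path) {
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' Density of a compound-protein interaction matrix
#'
#' Measured interactions as a percentage of all compound x protein cells,
#' reported to two decimals (round-half-even).
#'
#' @param n_proteins,n_drugs,n_interactions Counts.
#' @return Density percentage.
#' @examples
#' density_percent(442, 68, 30056)    # 100
#' density_percent(229, 2068, 117657) # 24.84
#' @export
density_percent <- function(n_proteins, n_drugs, n_interactions) {
  if (n_proteins < 1 || n_drugs < 1 || n_interactions < 1) {
    rlang::abort("Counts must be positive.", class = "cpinet_contract_error")
  }
  round(100 * n_interactions / (n_proteins * n_drugs), 2)
}

#' Summary statistics of an interaction table
#'
#' @param data Interaction tibble (non-empty).
#' @return One-row tibble: `n_proteins`, `n_drugs`, `n_interactions`,
#'   `density_percent`.
#' @export
dataset_stats <- function(data) {
  if (is.null(data) || nrow(data) == 0) {
    rlang::abort("Empty dataset.", class = "cpinet_data_error")
  }
  tibble::tibble(
    n_proteins = dplyr::n_distinct(data$protein_id),
    n_drugs = dplyr::n_distinct(data$compound_id),
    n_interactions = nrow(data),
    density_percent = density_percent(dplyr::n_distinct(data$protein_id),
                                      dplyr::n_distinct(data$compound_id),
                                      nrow(data)))
}

# deterministic branched-alkane SMILES for compound counts beyond the
# packaged list
.alkane_smiles <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    len <- 4L + (i %% 12L)
    chain <- rep("C", len)
    n_branch <- (i %/% 12L) %% 3L
    pos <- if (n_branch > 0) {
      1L + ((i * 7L + seq_len(n_branch) * 3L) %% (len - 2L))
    } else integer(0)
    for (b in unique(pos)) chain[b] <- "C(C)"
    out[i] <- paste(chain, collapse = "")
  }
  out
}

.random_protein <- function(min_len = 50, max_len = 500) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  len <- sample(min_len:max_len, 1)
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic compound-protein interaction dataset
#'
#' Emulates the structure of public affinity benchmarks: a sparse compound x
#' protein matrix at a requested density, with labels from a planted sparse
#' linear function of the compound fingerprint bits and the protein residue
#' composition plus Gaussian noise. An optional point-mass mode sets a
#' configurable fraction of labels to a constant, mimicking the skew of
#' datasets whose affinity mass concentrates at one value.
#'
#' Compounds are drawn from the packaged drug-like list, extended with
#' generated branched alkanes when more are requested; proteins are random
#' sequences of length 50-500 over the 20-letter alphabet. The planted
#' coefficients are recorded in the `manifest` attribute so noiseless labels
#' are exactly reproducible.
#'
#' @param n_compounds,n_proteins Entity counts (>= 1).
#' @param density Fraction of the matrix observed, in `(0, 1]`.
#' @param label_model `"planted"` or `"point_mass"`.
#' @param noise_sd Gaussian label noise standard deviation.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param point_mass_fraction Fraction of labels pinned to
#'   `point_mass_value` in point-mass mode.
#' @param point_mass_value The constant label (default 5, the pKd at the
#'   common assay ceiling).
#' @param n_signal_bits,n_signal_residues Planted support sizes.
#' @param fp_radius,fp_bits Fingerprint settings used by the planted function.
#' @param activity_threshold Optional: adds a binary `activity` column
#'   (`affinity >= threshold`).
#' @return Interaction tibble with attribute `manifest` (list with the seed,
#'   the planted coefficients and the generator settings).
#' @export
generate_synthetic <- function(n_compounds = 50, n_proteins = 20,
                               density = 0.3,
                               label_model = c("planted", "point_mass"),
                               noise_sd = 0.3, seed = 1,
                               point_mass_fraction = 0.6964,
                               point_mass_value = 5,
                               n_signal_bits = 8, n_signal_residues = 5,
                               fp_radius = 2, fp_bits = 512,
                               activity_threshold = NULL) {
  label_model <- match.arg(label_model)
  if (density <= 0 || density > 1) {
    rlang::abort("density must be in (0, 1].", class = "cpinet_contract_error")
  }
  if (n_compounds < 1 || n_proteins < 1) {
    rlang::abort("Need at least one compound and one protein.",
                 class = "cpinet_contract_error")
  }
  n_cells <- n_compounds * n_proteins
  n_obs <- round(density * n_cells)
  if (n_obs < 1) {
    rlang::abort("density * n_compounds * n_proteins < 1: nothing to sample.",
                 class = "cpinet_contract_error")
  }
  set.seed(seed)
  base <- druglike_smiles()
  if (n_compounds <= nrow(base)) {
    cmpds <- base[seq_len(n_compounds), ]
  } else {
    extra <- .alkane_smiles(n_compounds - nrow(base))
    cmpds <- dplyr::bind_rows(base,
      tibble::tibble(compound_id = paste0("alk_", seq_along(extra)),
                     smiles = extra))
  }
  prots <- tibble::tibble(
    protein_id = paste0("prot_", seq_len(n_proteins)),
    sequence = vapply(seq_len(n_proteins), function(i) .random_protein(),
                      character(1)))

  fps <- vapply(cmpds$smiles, function(s)
    as.numeric(smiles_to_fingerprint(s, radius = fp_radius, n_bits = fp_bits)),
    numeric(fp_bits))
  fps <- t(fps)  # compounds x bits
  varying <- which(apply(fps, 2, function(x) length(unique(x)) > 1))
  if (length(varying) < n_signal_bits) varying <- seq_len(fp_bits)
  sig_bits <- sort(sample(varying, n_signal_bits))
  bit_coef <- stats::runif(n_signal_bits, 0.4, 1.2) *
    sample(c(-1, 1), n_signal_bits, replace = TRUE)
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  sig_res <- sort(sample(aa20, n_signal_residues))
  res_coef <- stats::runif(n_signal_residues, 2, 6) *
    sample(c(-1, 1), n_signal_residues, replace = TRUE)
  res_freq <- vapply(prots$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(sig_res, function(a) mean(ch == a), numeric(1))
  }, numeric(n_signal_residues))
  res_freq <- t(res_freq)  # proteins x residues

  cells <- sample.int(n_cells, n_obs)
  ci <- ((cells - 1L) %% n_compounds) + 1L
  pi_ <- ((cells - 1L) %/% n_compounds) + 1L
  intercept <- 5
  signal <- intercept +
    as.numeric(fps[ci, sig_bits, drop = FALSE] %*% bit_coef) +
    as.numeric(res_freq[pi_, , drop = FALSE] %*% res_coef)
  affinity <- signal + stats::rnorm(n_obs, 0, noise_sd)
  mass_idx <- integer(0)
  if (label_model == "point_mass") {
    mass_idx <- which(stats::runif(n_obs) < point_mass_fraction)
    affinity[mass_idx] <- point_mass_value
  }
  out <- tibble::tibble(
    compound_id = cmpds$compound_id[ci],
    smiles = cmpds$smiles[ci],
    protein_id = prots$protein_id[pi_],
    sequence = prots$sequence[pi_],
    affinity = affinity)
  if (!is.null(activity_threshold)) {
    out$activity <- as.integer(out$affinity >= activity_threshold)
  }
  attr(out, "manifest") <- list(
    seed = seed, n_compounds = n_compounds, n_proteins = n_proteins,
    density = density, label_model = label_model, noise_sd = noise_sd,
    point_mass_fraction = if (label_model == "point_mass") point_mass_fraction,
    point_mass_value = if (label_model == "point_mass") point_mass_value,
    intercept = intercept,
    fp_radius = fp_radius, fp_bits = fp_bits,
    signal_bits = sig_bits, bit_coef = bit_coef,
    signal_residues = sig_res, res_coef = res_coef,
    mass_rows = mass_idx)
  out
}

#' Recompute noiseless planted labels from a generator manifest
#'
#' @param data A [generate_synthetic()] result (or any interaction tibble).
#' @param manifest The generator manifest (defaults to the one attached to
#'   `data`).
#' @return Numeric vector of planted signal values per row.
#' @export
planted_signal <- function(data, manifest = attr(data, "manifest")) {
  if (is.null(manifest)) {
    rlang::abort("No generator manifest available.",
                 class = "cpinet_contract_error")
  }
  fps <- vapply(data$smiles, function(s)
    as.numeric(smiles_to_fingerprint(s, radius = manifest$fp_radius,
                                     n_bits = manifest$fp_bits)),
    numeric(manifest$fp_bits))
  fps <- t(fps)
  freq <- vapply(data$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(manifest$signal_residues, function(a) mean(ch == a), numeric(1))
  }, numeric(length(manifest$signal_residues)))
  manifest$intercept +
    as.numeric(fps[, manifest$signal_bits, drop = FALSE] %*%
                 manifest$bit_coef) +
    as.numeric(t(freq) %*% manifest$res_coef)
}

#' Label histogram fractions
#'
#' @param data Interaction tibble (non-empty).
#' @param bin_edges Strictly increasing break points covering all labels.
#' @return Tibble with `bin_low`, `bin_high`, `fraction` (fractions sum to 1).
#' @export
label_distribution <- function(data, bin_edges) {
  if (nrow(data) == 0) {
    rlang::abort("Empty dataset.", class = "cpinet_data_error")
  }
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    rlang::abort("bin_edges must be strictly increasing with >= 2 values.",
                 class = "cpinet_contract_error")
  }
  x <- data$affinity
  if (any(x < bin_edges[1] | x > bin_edges[length(bin_edges)])) {
    rlang::abort("Labels fall outside the bin range.",
                 class = "cpinet_contract_error")
  }
  cts <- hist(x, breaks = bin_edges, plot = FALSE,
              include.lowest = TRUE, right = FALSE)$counts
  tibble::tibble(bin_low = bin_edges[-length(bin_edges)],
                 bin_high = bin_edges[-1],
                 fraction = cts / length(x))
}
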