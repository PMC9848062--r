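# Protein tokenization and sequence similarity.

#' Amino-acid token vocabulary
#'
#' A stable bijective mapping from one-letter residue codes to integer ids:
#' pad = 0, the 20 canonical residues 1-20 (alphabetical), then the ambiguity
#' codes B, Z, X, the rare residue U, and an explicit "unknown" id for any
#' other character. Embeddings are learned, so any fixed bijection is
#' equivalent; this table is the package's documented choice.
#'
#' @return Named integer vector mapping residue characters to token ids; the
#'   name `"<pad>"` maps to 0 and `"<unk>"` to the unknown id.
#' @export
protein_vocabulary <- function() {
  residues <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y",
                "B","Z","X","U")
  stats::setNames(c(0L, seq_along(residues), length(residues) + 1L),
                  c("<pad>", residues, "<unk>"))
}

.vocab_size <- function() length(protein_vocabulary())

#' Tokenize a protein sequence to a fixed-length id vector
#'
#' Maps each one-letter residue to its vocabulary id, truncates sequences
#' longer than `max_len` from the right and right-pads shorter ones with the
#' pad id 0. Characters outside the vocabulary map to the unknown token; the
#' function is total over text.
#'
#' @param sequence Amino-acid sequence (one-letter codes; case-insensitive).
#' @param max_len Fixed output length (default 500).
#' @return An object of class `protein_tokens`: integer vector of length
#'   `max_len` with attribute `true_length` (number of non-pad positions).
#' @examples
#' tok <- tokenize_protein("ACDG", max_len = 10)
#' attr(tok, "true_length")  # 4
#' @export
tokenize_protein <- function(sequence, max_len = 500) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  vocab <- protein_vocabulary()
  unk <- vocab[["<unk>"]]
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) > max_len) chars <- chars[seq_len(max_len)]
  ids <- unname(vocab[chars])
  ids[is.na(ids)] <- unk
  true_length <- length(ids)
  ids <- c(ids, integer(max_len - true_length))
  structure(as.integer(ids), true_length = as.integer(true_length),
            max_len = as.integer(max_len), class = "protein_tokens")
}

#' Recover the residue string from non-pad token ids
#'
#' Inverse of [tokenize_protein()] over the canonical alphabet: detokenizing
#' the non-pad prefix of a tokenized sequence recovers the input.
#'
#' @param tokens A `protein_tokens` object or plain integer vector.
#' @return Character scalar.
#' @export
detokenize_protein <- function(tokens) {
  vocab <- protein_vocabulary()
  inv <- stats::setNames(names(vocab), vocab)
  n <- attr(tokens, "true_length") %||% sum(tokens != 0)
  if (n == 0) return("")
  ids <- as.integer(tokens)[seq_len(n)]
  sym <- unname(inv[as.character(ids)])
  sym[is.na(sym) | sym == "<unk>"] <- "X"
  paste(sym, collapse = "")
}

#' @export
print.protein_tokens <- function(x, ...) {
  cat("<protein_tokens> length", length(x), "true_length",
      attr(x, "true_length"), "\n")
  invisible(x)
}

#' Alignment-based protein sequence similarity
#'
#' Globally aligns the two sequences (identity scoring: match 1, mismatch 0,
#' linear gap penalty) and returns the number of aligned identical residues
#' divided by a fixed reference length, capped at 1. The fixed denominator
#' matches the fixed-length protein encoding used by the model.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty).
#' @param fixed_len Reference length for the denominator (default 500).
#' @param gap_penalty Linear gap penalty for the alignment (default 0.5).
#' @return Similarity in `[0, 1]`.
#' @examples
#' protein_similarity("ACDEF", "ACDFF", fixed_len = 5)  # 0.8
#' @export
protein_similarity <- function(seq_a, seq_b, fixed_len = 500,
                               gap_penalty = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    rlang::abort("Sequences must be non-empty.", class = "cpinet_contract_error")
  }
  letters26 <- LETTERS
  m <- diag(1, length(letters26))
  dimnames(m) <- list(letters26, letters26)
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = m, gapOpening = 0, gapExtension = gap_penalty)
  min(Biostrings::nmatch(aln) / fixed_len, 1)
}
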