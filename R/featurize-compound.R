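#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Fixed atom-feature layout. One-hot blocks are concatenated in this order;
# the final column is atomic mass scaled by 0.01.
.atom_feature_spec <- list(
  element  = 1:100,                      # one-hot atomic number + "other"
  degree   = 0:6,                        # heavy-atom bond count, clamped
  charge   = c(-2L, -1L, 0L, 1L, 2L),    # formal charge + "other"
  chiral   = c("none", "clockwise", "counterclockwise", "unspecified"),
  n_h      = 0:4,                        # bonded hydrogens + ">=5"
  hybrid   = c("sp", "sp2", "sp3", "sp3d", "sp3d2")
)

.bond_feature_spec <- list(
  type   = c("single", "double", "triple", "aromatic"),
  stereo = c("none", "cis", "trans", "either")
)

#' Dimension of the per-atom feature vector
#' @return Integer scalar.
#' @export
atom_feature_dim <- function() {
  s <- .atom_feature_spec
  (length(s$element) + 1L) + length(s$degree) + (length(s$charge) + 1L) +
    length(s$chiral) + (length(s$n_h) + 1L) + length(s$hybrid) + 1L + 1L
}

#' Dimension of the per-directed-bond feature vector
#' @return Integer scalar.
#' @export
bond_feature_dim <- function() {
  length(.bond_feature_spec$type) + 2L + length(.bond_feature_spec$stereo)
}

.element_data <- local({
  sym <- c("H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P",
           "S","Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu",
           "Zn","Ga","Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc",
           "Ru","Rh","Pd","Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La",
           "Ce","Pr","Nd","Pm","Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu",
           "Hf","Ta","W","Re","Os","Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At",
           "Rn","Fr","Ra","Ac","Th","Pa","U","Np","Pu","Am","Cm","Bk","Cf","Es",
           "Fm","Md")
  mass <- c(1.008,4.003,6.94,9.012,10.81,12.011,14.007,15.999,18.998,20.180,
            22.990,24.305,26.982,28.085,30.974,32.06,35.45,39.948,39.098,40.078,
            44.956,47.867,50.942,51.996,54.938,55.845,58.933,58.693,63.546,65.38,
            69.723,72.630,74.922,78.971,79.904,83.798,85.468,87.62,88.906,91.224,
            92.906,95.95,98,101.07,102.906,106.42,107.868,112.414,114.818,118.710,
            121.760,127.60,126.904,131.293,132.905,137.327,138.905,140.116,
            140.908,144.242,145,150.36,151.964,157.25,158.925,162.500,164.930,
            167.259,168.934,173.045,174.967,178.49,180.948,183.84,186.207,190.23,
            192.217,195.084,196.967,200.592,204.38,207.2,208.980,209,210,222,223,
            226,227,232.038,231.036,238.029,237,244,243,247,247,251,252,257,258)
  list(number = stats::setNames(seq_along(sym), sym),
       mass = stats::setNames(mass, sym))
})

# Smallest standard valence >= bond-order sum, adjusted by formal charge, used
# to infer implicit hydrogen counts on the kekulized heavy-atom graph.
.implicit_h <- function(symbol, bond_order_sum, charge) {
  allowed <- switch(symbol,
    B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
    S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, 0)
  allowed <- allowed + charge
  allowed <- allowed[allowed >= 0]
  v <- allowed[allowed >= bond_order_sum]
  if (length(v) == 0L) return(0L)
  as.integer(min(v) - bond_order_sum)
}

.one_hot <- function(value, levels, other_slot = TRUE) {
  v <- numeric(length(levels) + as.integer(other_slot))
  i <- match(value, levels)
  if (!is.na(i)) v[i] <- 1 else if (other_slot) v[length(v)] <- 1
  v
}

.parse_smiles_sdf <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    abort("SMILES must be a single non-empty string.", class = "cpinet_parse_error")
  }
  out <- suppressWarnings(suppressMessages(
    try(ChemmineOB::convertFormat("SMILES", "SDF", source = smiles),
        silent = TRUE)))
  ok <- !inherits(out, "try-error") && is.character(out) && nzchar(out) &&
    grepl("V2000", out, fixed = TRUE)
  if (!ok) {
    abort(paste0("Unparsable SMILES: '", smiles, "'"),
          class = "cpinet_parse_error")
  }
  # single-atom molecules have an empty bond block, which validSDF flags;
  # atom count is the reliable parse check here
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    textConnection(out))))
  sdf <- sdfset[[1]]
  ab <- try(ChemmineR::atomblock(sdf), silent = TRUE)
  if (inherits(ab, "try-error") || is.null(dim(ab)) || nrow(ab) < 1L) {
    abort(paste0("Unparsable SMILES: '", smiles, "'"),
          class = "cpinet_parse_error")
  }
  sdf
}

# Atom pairs adjacent in any perceived ring; returns list(ring_pairs set,
# aromatic atom indices). Pair keys are "i-j" with i < j.
.ring_info <- function(sdf, n_atoms) {
  ring_pairs <- character(0)
  arom_pairs <- character(0)
  arom_atoms <- integer(0)
  rr <- try(suppressWarnings(ChemmineR::rings(sdf, upper = 20, type = "all",
                                              arom = TRUE)), silent = TRUE)
  if (!inherits(rr, "try-error") && length(rr$RINGS) > 0) {
    for (k in seq_along(rr$RINGS)) {
      idx <- as.integer(sub(".*_", "", rr$RINGS[[k]]))
      m <- length(idx)
      pairs <- vapply(seq_len(m), function(i) {
        a <- idx[i]; b <- idx[if (i == m) 1L else i + 1L]
        paste(min(a, b), max(a, b), sep = "-")
      }, character(1))
      ring_pairs <- union(ring_pairs, pairs)
      if (isTRUE(rr$AROMATIC[[k]])) {
        arom_pairs <- union(arom_pairs, pairs)
        arom_atoms <- union(arom_atoms, idx)
      }
    }
  }
  list(ring_pairs = ring_pairs, arom_pairs = arom_pairs,
       arom_atoms = arom_atoms)
}

# cis/trans classification of a stereo-defined double bond from the 2D layout:
# reference neighbours (lowest atom index) on each side of the a1=a2 axis.
.double_bond_geometry <- function(xy, a1, a2, nb1, nb2) {
  axis <- xy[a2, ] - xy[a1, ]
  side <- function(p, origin) {
    d <- p - origin
    sign(axis[1] * d[2] - axis[2] * d[1])
  }
  s1 <- side(xy[nb1, ], xy[a1, ])
  s2 <- side(xy[nb2, ], xy[a2, ])
  if (s1 == 0 || s2 == 0) return("none")
  if (s1 == s2) "cis" else "trans"
}

#' Convert a SMILES string into a directed molecular graph
#'
#' Parses the molecule with OpenBabel (via ChemmineOB/ChemmineR), keeps heavy
#' atoms only, and expands each chemical bond into two directed bonds. Atom
#' features follow a fixed layout: one-hot atomic number (1-100 plus "other"),
#' one-hot heavy-atom degree (0-6), one-hot formal charge (-2..2 plus other),
#' one-hot chirality tag, one-hot bonded-hydrogen count (0-4 plus ">=5"),
#' one-hot hybridization (sp, sp2, sp3, sp3d, sp3d2), an aromaticity flag and
#' atomic mass scaled by 0.01. Bond features are a bond-type one-hot
#' (single/double/triple/aromatic), a conjugation flag, a ring-membership flag
#' and a stereochemistry one-hot (none/cis/trans/either).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molgraph`: a list with `n_atoms`,
#'   `n_directed_bonds`, `atom_features` (matrix), `bond_features` (matrix),
#'   `src`, `dst`, `rev` (integer vectors indexing directed bonds) and
#'   `incoming` (list mapping each atom to the directed bonds ending there).
#' @examples
#' g <- smiles_to_molgraph("CCO")
#' g$n_atoms            # 3
#' g$n_directed_bonds   # 4
#' @export
smiles_to_molgraph <- function(smiles) {
  sdf <- .parse_smiles_sdf(smiles)
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)
  elements <- sub("_.*$", "", rownames(ab))
  xy <- cbind(ab[, 1], ab[, 2])

  # V2000 fields: column C6 = old-style charge code, C7 = stereo parity
  charge_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n_atoms)
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(n_atoms)
  code_to_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                      `5` = -1L, `6` = -2L, `7` = -3L)
  charges <- unname(code_to_charge[as.character(charge_code)])
  charges[is.na(charges)] <- 0L

  if (!is.null(bb) && is.null(dim(bb)) && length(bb) >= 3) {
    bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  }
  has_bonds <- !is.null(bb) && !is.null(dim(bb)) && nrow(bb) > 0 && ncol(bb) >= 3
  if (has_bonds) {
    b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2])
    order <- as.integer(bb[, 3])
    bstereo_flag <- if (ncol(bb) >= 4) as.integer(bb[, 4]) else integer(nrow(bb))
    n_chem <- nrow(bb)
  } else {
    b1 <- b2 <- order <- bstereo_flag <- integer(0)
    n_chem <- 0L
  }

  ri <- .ring_info(sdf, n_atoms)
  pair_key <- if (n_chem) paste(pmin(b1, b2), pmax(b1, b2), sep = "-") else character(0)
  bond_in_ring <- pair_key %in% ri$ring_pairs
  bond_aromatic <- pair_key %in% ri$arom_pairs
  atom_aromatic <- seq_len(n_atoms) %in% ri$arom_atoms

  degree <- tabulate(c(b1, b2), nbins = n_atoms)
  # per-atom kekulized bond-order sum and multiplicity counts
  bosum <- numeric(n_atoms); n_double <- integer(n_atoms); n_triple <- integer(n_atoms)
  for (j in seq_len(n_chem)) {
    bosum[b1[j]] <- bosum[b1[j]] + order[j]
    bosum[b2[j]] <- bosum[b2[j]] + order[j]
    if (order[j] == 2L) { n_double[b1[j]] <- n_double[b1[j]] + 1L; n_double[b2[j]] <- n_double[b2[j]] + 1L }
    if (order[j] == 3L) { n_triple[b1[j]] <- n_triple[b1[j]] + 1L; n_triple[b2[j]] <- n_triple[b2[j]] + 1L }
  }

  n_h <- vapply(seq_len(n_atoms), function(a) {
    .implicit_h(elements[a], bosum[a], charges[a])
  }, integer(1))

  hybrid <- vapply(seq_len(n_atoms), function(a) {
    if (n_triple[a] > 0L || n_double[a] >= 2L) return("sp")
    if (n_double[a] > 0L || atom_aromatic[a]) return("sp2")
    conn <- degree[a] + n_h[a]
    if (conn >= 6L) "sp3d2" else if (conn == 5L) "sp3d" else "sp3"
  }, character(1))

  chiral_tag <- c("none", "clockwise", "counterclockwise", "unspecified")[
    pmin(parity, 3L) + 1L]

  spec <- .atom_feature_spec
  atom_features <- t(vapply(seq_len(n_atoms), function(a) {
    z <- .element_data$number[elements[a]]
    mass <- .element_data$mass[elements[a]]
    if (is.na(z)) { z <- 0L; mass <- 0 }
    c(.one_hot(z, spec$element),
      .one_hot(min(degree[a], 6L), spec$degree, other_slot = FALSE),
      .one_hot(charges[a], spec$charge),
      .one_hot(chiral_tag[a], spec$chiral, other_slot = FALSE),
      .one_hot(n_h[a], spec$n_h),
      .one_hot(hybrid[a], spec$hybrid, other_slot = FALSE),
      as.numeric(atom_aromatic[a]),
      unname(mass) * 0.01)
  }, numeric(atom_feature_dim())))

  # per-chemical-bond features (shared by both directions)
  neighbours <- lapply(seq_len(n_atoms), function(a)
    c(b2[b1 == a], b1[b2 == a]))
  has_multiple <- n_double > 0L | n_triple > 0L | atom_aromatic
  chem_feat <- matrix(0, nrow = n_chem, ncol = bond_feature_dim())
  for (j in seq_len(n_chem)) {
    type <- if (bond_aromatic[j]) "aromatic" else
      c("single", "double", "triple")[min(order[j], 3L)]
    conj <- if (bond_aromatic[j]) {
      TRUE
    } else if (order[j] >= 2L) {
      # a multiple bond is conjugated when an adjacent atom carries pi density
      any(has_multiple[setdiff(neighbours[[b1[j]]], b2[j])]) ||
        any(has_multiple[setdiff(neighbours[[b2[j]]], b1[j])])
    } else {
      # a single bond is conjugated when it links two pi systems
      has_multiple[b1[j]] && has_multiple[b2[j]]
    }
    stereo <- "none"
    if (order[j] == 2L && !bond_aromatic[j] && !bond_in_ring[j]) {
      if (bstereo_flag[j] == 3L) {
        stereo <- "either"
      } else {
        nb1 <- setdiff(neighbours[[b1[j]]], b2[j])
        nb2 <- setdiff(neighbours[[b2[j]]], b1[j])
        if (length(nb1) && length(nb2)) {
          stereo <- .double_bond_geometry(xy, b1[j], b2[j], min(nb1), min(nb2))
        }
      }
    }
    chem_feat[j, ] <- c(.one_hot(type, .bond_feature_spec$type, other_slot = FALSE),
                        as.numeric(conj), as.numeric(bond_in_ring[j]),
                        .one_hot(stereo, .bond_feature_spec$stereo, other_slot = FALSE))
  }

  n_db <- 2L * n_chem
  src <- dst <- rev_idx <- integer(n_db)
  bond_features <- matrix(0, nrow = n_db, ncol = bond_feature_dim())
  for (j in seq_len(n_chem)) {
    f <- 2L * j - 1L; r <- 2L * j
    src[f] <- b1[j]; dst[f] <- b2[j]
    src[r] <- b2[j]; dst[r] <- b1[j]
    rev_idx[f] <- r; rev_idx[r] <- f
    bond_features[f, ] <- chem_feat[j, ]
    bond_features[r, ] <- chem_feat[j, ]
  }
  incoming <- lapply(seq_len(n_atoms), function(a) which(dst == a))

  structure(list(
    smiles = smiles,
    n_atoms = n_atoms,
    n_directed_bonds = n_db,
    elements = elements,
    atom_features = atom_features,
    bond_features = bond_features,
    src = src, dst = dst, rev = rev_idx,
    incoming = incoming
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      x$n_directed_bonds, " directed bonds\n", sep = "")
  invisible(x)
}

#' Canonical SMILES via the chemistry toolkit
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  .parse_smiles_sdf(smiles) # validates
  out <- ChemmineOB::convertFormat("SMILES", "CAN", source = smiles)
  strsplit(trimws(out), "[\t ]")[[1]][1]
}

#' Morgan (ECFP) fingerprint of a molecule
#'
#' Circular substructure fingerprint: environments up to `radius` bonds around
#' each atom are hashed (OpenBabel's ECFP implementation, 4096 buckets) and
#' folded by bitwise OR to `n_bits`.
#'
#' @param smiles A single SMILES string.
#' @param radius Environment radius in bonds (default 2, i.e. ECFP4).
#' @param n_bits Length of the folded binary vector (default 2048).
#' @return An object of class `morgan_fp`: integer 0/1 vector of length
#'   `n_bits` with attributes `radius` and `n_bits`.
#' @examples
#' fp <- smiles_to_fingerprint("CCO")
#' sum(fp)    # number of set bits
#' @export
smiles_to_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  if (radius < 0 || radius != round(radius)) {
    abort("radius must be a non-negative integer.", class = "cpinet_config_error")
  }
  if (n_bits < 1 || n_bits != round(n_bits)) {
    abort("n_bits must be a positive integer.", class = "cpinet_config_error")
  }
  .parse_smiles_sdf(smiles) # validates; errors on bad input
  fp_name <- paste0("ECFP", 2L * as.integer(radius))
  raw <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::fingerprint_OB(list(m), fp_name)
  })[[1]]
  raw <- as.integer(raw != 0)
  if (n_bits >= length(raw)) {
    bits <- c(raw, integer(n_bits - length(raw)))
  } else {
    bits <- integer(n_bits)
    idx <- ((seq_along(raw) - 1L) %% n_bits) + 1L
    set <- tapply(raw, idx, max)
    bits[as.integer(names(set))] <- as.integer(set)
  }
  structure(as.integer(bits), radius = as.integer(radius),
            n_bits = as.integer(n_bits), class = "morgan_fp")
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat("<morgan_fp> radius", attr(x, "radius"), "length", length(x),
      "set bits", sum(x), "\n")
  invisible(x)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' @param a,b Binary vectors of equal length (e.g. [smiles_to_fingerprint()]
#'   output).
#' @return Similarity in `[0, 1]`: intersection count over union count. Both
#'   all-zero returns 0 with a warning.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Fingerprints must have equal length.", class = "cpinet_config_error")
  }
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  union_n <- sum(a | b)
  if (union_n == 0) {
    warn("Both fingerprints are all-zero; Tanimoto defined as 0.")
    return(0)
  }
  sum(a & b) / union_n
}
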