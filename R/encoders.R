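# Compound and protein encoders: directed bond-level message passing over the
# molecular graph, an MLP over the Morgan fingerprint, and a residual gated
# 1D-convolution stack over protein tokens.

# Message-passing index structure for a molgraph:
#  A[b, c] = 1 iff directed bond c ends where b starts and c is not b's
#  reverse (no immediate backtracking); P[a, b] = 1 iff bond b ends at atom a.
.graph_structure <- function(graph) {
  n_db <- graph$n_directed_bonds
  A <- matrix(0, n_db, n_db)
  if (n_db > 0) {
    for (b in seq_len(n_db)) {
      cands <- graph$incoming[[graph$src[b]]]
      cands <- cands[cands != graph$rev[b]]
      if (length(cands)) A[b, cands] <- 1
    }
  }
  P <- matrix(0, graph$n_atoms, max(n_db, 1L))
  if (n_db > 0) {
    for (a in seq_len(graph$n_atoms)) {
      if (length(graph$incoming[[a]])) P[a, graph$incoming[[a]]] <- 1
    }
  }
  list(A = A, deg = rowSums(A), P = P,
       n_in = pmax(rowSums(P), 1))
}

#' Initialize directed-bond hidden states
#'
#' Every directed bond v->w starts at `ReLU(W_in . concat(x_v, e_vw))` where
#' `x_v` are the source-atom features and `e_vw` the bond features.
#'
#' @param graph A [smiles_to_molgraph()] result.
#' @param params A [cpi_init_params()] parameter list.
#' @return An `mpnn_state`: list with per-bond hidden matrix `h`, the
#'   immutable initial hiddens `h0`, pre-activation `h0_pre` and `step = 0`.
#' @export
init_hidden <- function(graph, params) {
  d_in <- ncol(graph$atom_features) + ncol(graph$bond_features)
  if (nrow(params$atom_in_W) != d_in) {
    rlang::abort("Input projection does not match the feature layout.",
                 class = "cpinet_config_error")
  }
  n_db <- graph$n_directed_bonds
  if (n_db > 0) {
    X <- graph$atom_features[graph$src, , drop = FALSE]
    inp <- cbind(X, graph$bond_features)
    pre <- sweep(inp %*% params$atom_in_W, 2, params$atom_in_b, "+")
  } else {
    inp <- matrix(0, 0, d_in)
    pre <- matrix(0, 0, ncol(params$atom_in_W))
  }
  h0 <- pmax(pre, 0)
  structure(list(h = h0, h0 = h0, h0_pre = pre, step = 0L,
                 n_directed_bonds = n_db),
            class = "mpnn_state")
}

#' One directed message-passing step
#'
#' For each directed bond v->w the incoming message is the sum over
#' neighbouring atoms `k` of `v` (excluding `w`) of the element-wise average
#' of the projected source-atom features, the projected neighbour features and
#' the hidden state of bond k->v; the reverse bond w->v never contributes.
#' The hidden state updates as `ReLU(h0 + W_m . m)`.
#'
#' @param state An `mpnn_state` from [init_hidden()].
#' @param graph The same graph the state was initialized from.
#' @param params Parameter list.
#' @return Updated `mpnn_state` with `step` incremented.
#' @export
message_step <- function(state, graph, params) {
  if (!inherits(state, "mpnn_state") ||
      state$n_directed_bonds != graph$n_directed_bonds) {
    rlang::abort("State does not match the graph.",
                 class = "cpinet_contract_error")
  }
  if (graph$n_directed_bonds == 0L) {
    state$step <- state$step + 1L
    return(state)
  }
  st <- .graph_structure(graph)
  Xp <- sweep(graph$atom_features %*% params$atom_proj_W, 2,
              params$atom_proj_b, "+")
  XpS <- Xp[graph$src, , drop = FALSE]
  M <- (st$deg * XpS + st$A %*% XpS + st$A %*% state$h) / 3
  pre <- state$h0 + sweep(M %*% params$msg_W, 2, params$msg_b, "+")
  state$h <- pmax(pre, 0)
  state$step <- state$step + 1L
  state
}

#' Graph readout to a molecule embedding
#'
#' Averages the hidden states of each atom's incoming directed bonds (zero
#' vector for atoms with none), then averages over atoms. Invariant to atom
#' relabeling; a bond-less molecule reads out as the zero vector.
#'
#' @param state An `mpnn_state`.
#' @param graph The corresponding graph.
#' @return Numeric vector of length `mpnn_hidden` (the graph-view compound
#'   embedding).
#' @export
readout <- function(state, graph) {
  H <- ncol(state$h0)
  if (graph$n_directed_bonds == 0L) return(numeric(max(H, 0L)))
  st <- .graph_structure(graph)
  atomvec <- (st$P %*% state$h) / st$n_in
  colMeans(atomvec)
}

#' Encode a Morgan fingerprint through the compound MLP
#'
#' @param fp A [smiles_to_fingerprint()] result (or plain 0/1 vector matching
#'   the configured `fp_bits`).
#' @param params Parameter list.
#' @return Numeric vector of length `compound_dim` (the fingerprint-view
#'   compound embedding).
#' @export
encode_fingerprint <- function(fp, params) {
  x <- matrix(as.numeric(fp), nrow = 1)
  if (ncol(x) != nrow(params$fp1_W)) {
    rlang::abort("Fingerprint length does not match the first MLP layer.",
                 class = "cpinet_config_error")
  }
  z <- pmax(sweep(x %*% params$fp1_W, 2, params$fp1_b, "+"), 0)
  as.vector(sweep(z %*% params$fp2_W, 2, params$fp2_b, "+"))
}

# internal protein encoder forward; returns output and (optionally) caches
.protein_fwd <- function(tokens, params, cfg, want_cache = FALSE) {
  ids <- as.integer(tokens)
  L <- length(ids)
  true_len <- attr(tokens, "true_length") %||% sum(ids != 0L)
  emb0 <- params$prot_emb[ids + 1L, , drop = FALSE]
  mask <- if (cfg$mask_pad) as.numeric(seq_len(L) <= true_len) else rep(1, L)
  emb0 <- emb0 * mask  # pad rows zeroed so real positions never see pad ids
  idx_stem <- .conv_idx(L, cfg$prot_kernel)
  stem <- .conv1d_fwd(emb0, params$prot_stem_W, params$prot_stem_b, idx_stem)
  s <- stem$Y * mask
  blocks <- vector("list", cfg$prot_blocks)
  for (i in seq_len(cfg$prot_blocks)) {
    cv <- .conv1d_fwd(s, params[[paste0("prot_conv_W_", i)]],
                      params[[paste0("prot_conv_b_", i)]], idx_stem)
    resid <- cbind(s, s) * cfg$prot_lambda
    ln <- .layernorm_fwd(cv$Y + resid, params[[paste0("prot_ln_g_", i)]],
                         params[[paste0("prot_ln_b_", i)]])
    gl <- .glu_fwd(ln$Y)
    s_new <- gl$Y * mask
    if (want_cache) blocks[[i]] <- list(cv = cv, ln = ln, gl = gl, s_in = s)
    s <- s_new
  }
  list(Y = s, cache = if (want_cache)
    list(ids = ids, emb0 = emb0, stem = stem, blocks = blocks, mask = mask))
}

#' Encode tokenized protein through the residual convolution stack
#'
#' An embedding lookup produces the initial per-position representation; a
#' stem convolution maps it to `prot_channels` channels; each residual block
#' applies a same-padding convolution to twice the channel width, adds the
#' block input scaled by `prot_lambda` (duplicated along channels), layer
#' normalization, and a gated linear unit that halves the width back. With
#' `mask_pad = TRUE` pad positions are zeroed after the stem and every block.
#'
#' @param tokens A [tokenize_protein()] result.
#' @param params Parameter list.
#' @return Matrix of `max_len` positions x `prot_channels` channels.
#' @export
encode_protein <- function(tokens, params) {
  cfg <- attr(params, "config")
  if (length(tokens) != cfg$max_len) {
    rlang::abort("Token length does not match the configured max_len.",
                 class = "cpinet_config_error")
  }
  .protein_fwd(tokens, params, cfg)$Y
}
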