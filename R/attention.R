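# Attention modules: compound-view fusion, latent self-attention refinement,
# and the final compound-queries-protein cross-attention.

#' Cross-attention between two token matrices
#'
#' Queries come from `q_tokens`, keys and values from `kv_tokens`, through
#' learned affine projections. Energies are `softmax(QK^T / sqrt(C/d))` per
#' head (or the literal `QK^T * C/d` when `scaling = "literal"`); the output
#' is the energy-weighted value sum passed through the output projection
#' `f_0`. Every energy row sums to one and the output keeps the query token
#' count.
#'
#' @param q_tokens,kv_tokens Token matrices (rows are tokens).
#' @param params List with projections `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @param n_heads Number of attention heads.
#' @param scaling `"sqrt"` or `"literal"`.
#' @return Token matrix with `nrow(q_tokens)` rows; attribute `energy` holds
#'   the per-head attention energy matrices.
#' @export
cross_attention <- function(q_tokens, kv_tokens, params, n_heads = 1,
                            scaling = "sqrt") {
  r <- .attention_fwd(as.matrix(q_tokens), as.matrix(kv_tokens), params,
                      n_heads = n_heads, scaling = scaling)
  structure(r$Y, energy = r$energy)
}

#' Fuse the two compound views by cross-attention
#'
#' Reshapes the 1-D fingerprint-view embedding and the 1-D graph-view
#' embedding into `n_tokens` contiguous tokens each; the fingerprint view
#' provides the queries, the graph view keys and values. The attended output
#' is flattened back to a single 1-D compound representation.
#'
#' @param o_ms Fingerprint-view embedding ([encode_fingerprint()] output).
#' @param o_gs Graph-view embedding ([readout()] output).
#' @param params Parameter list from [cpi_init_params()].
#' @return Numeric vector of length `n_tokens * attn_dim`.
#' @export
fuse_compound <- function(o_ms, o_gs, params) {
  cfg <- attr(params, "config")
  qt <- .to_tokens(as.numeric(o_ms), cfg$n_tokens)
  kv <- .to_tokens(as.numeric(o_gs), cfg$n_tokens)
  out <- .attention_fwd(qt, kv, .attn_params(params, "fuse"),
                        n_heads = cfg$n_heads, scaling = cfg$energy_scaling)
  .from_tokens(out$Y)
}

# internal: latent self-attention stack forward with caches
.latents_fwd <- function(lat, params, cfg, want_cache = FALSE) {
  blocks <- vector("list", cfg$latent_blocks)
  for (j in seq_len(cfg$latent_blocks)) {
    ap <- .attn_params(params, paste0("lat", j))
    at <- .attention_fwd(lat, lat, ap, n_heads = cfg$n_heads,
                         scaling = cfg$energy_scaling)
    x1 <- lat + at$Y
    l1 <- .linear_fwd(x1, params[[paste0("lat", j, "_ff1_W")]],
                      params[[paste0("lat", j, "_ff1_b")]])
    r1 <- .relu_fwd(l1$Y)
    l2 <- .linear_fwd(r1$Y, params[[paste0("lat", j, "_ff2_W")]],
                      params[[paste0("lat", j, "_ff2_b")]])
    out <- x1 + l2$Y
    if (want_cache) blocks[[j]] <- list(at = at, l1 = l1, r1 = r1, l2 = l2)
    lat <- out
  }
  list(Y = lat, cache = if (want_cache) blocks)
}

#' Refine the fused compound representation with latent self-attention
#'
#' Reshapes the fused 1-D compound vector into the latent token grid and
#' applies `latent_blocks` self-attention blocks (queries, keys and values all
#' from the current latents), each followed by a position-wise feed-forward,
#' both with residual connections. Zero blocks is the identity on the grid.
#'
#' @param comp_s Fused compound vector ([fuse_compound()] output).
#' @param params Parameter list.
#' @return Latent token matrix (`n_tokens` x `attn_dim`).
#' @export
refine_latents <- function(comp_s, params) {
  cfg <- attr(params, "config")
  lat <- .to_tokens(as.numeric(comp_s), cfg$n_tokens)
  .latents_fwd(lat, params, cfg)$Y
}

#' Attend compound latents over the protein representation
#'
#' Queries come from the compound latents; keys and values from the protein
#' positions. The attended output is mean-pooled over the query tokens to a
#' single interaction vector.
#'
#' @param latents Latent token matrix ([refine_latents()] output).
#' @param prot_t Protein position-by-channel matrix ([encode_protein()]
#'   output).
#' @param params Parameter list.
#' @return Numeric interaction vector of length `attn_dim`.
#' @export
interact <- function(latents, prot_t, params) {
  cfg <- attr(params, "config")
  out <- .attention_fwd(as.matrix(latents), as.matrix(prot_t),
                        .attn_params(params, "int"),
                        n_heads = cfg$n_heads, scaling = cfg$energy_scaling)
  colMeans(out$Y)
}

#' Regression head mapping the interaction vector to an affinity
#'
#' @param interaction Interaction vector ([interact()] output).
#' @param params Parameter list.
#' @return Scalar predicted affinity.
#' @export
predict_affinity <- function(interaction, params) {
  x <- matrix(as.numeric(interaction), nrow = 1)
  h <- pmax(sweep(x %*% params$head1_W, 2, params$head1_b, "+"), 0)
  as.numeric(h %*% params$head2_W + params$head2_b)
}
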