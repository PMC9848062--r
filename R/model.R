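# End-to-end model: featurized record -> predicted affinity, with the manual
# reverse pass used by the trainer. The op-level functions in encoders.R /
# attention.R expose the same computations piecewise; this file chains them
# with caching so gradients can be propagated to every parameter.

.model_forward <- function(p, cfg, graph, fp, tokens, want_cache = FALSE) {
  H <- cfg$mpnn_hidden
  n_db <- graph$n_directed_bonds

  # --- graph view (directed message passing)
  if (n_db > 0) {
    st <- graph$structure %||% .graph_structure(graph)
    Xp <- sweep(graph$atom_features %*% p$atom_proj_W, 2, p$atom_proj_b, "+")
    XpS <- Xp[graph$src, , drop = FALSE]
    inp <- cbind(graph$atom_features[graph$src, , drop = FALSE],
                 graph$bond_features)
    h0pre <- sweep(inp %*% p$atom_in_W, 2, p$atom_in_b, "+")
    h0 <- pmax(h0pre, 0)
    h <- h0
    steps <- vector("list", cfg$mpnn_depth)
    base <- st$deg * XpS + st$A %*% XpS
    for (t in seq_len(cfg$mpnn_depth)) {
      M <- (base + st$A %*% h) / 3
      pre <- h0 + sweep(M %*% p$msg_W, 2, p$msg_b, "+")
      h <- pmax(pre, 0)
      if (want_cache) steps[[t]] <- list(M = M, pre = pre)
    }
    atomvec <- (st$P %*% h) / st$n_in
    o_g <- colMeans(atomvec)
  } else {
    st <- NULL; inp <- NULL; h0pre <- NULL; steps <- NULL; XpS <- NULL
    o_g <- numeric(H)
  }

  # --- fingerprint view (MLP)
  x_fp <- matrix(as.numeric(fp), nrow = 1)
  z1pre <- sweep(x_fp %*% p$fp1_W, 2, p$fp1_b, "+")
  z1 <- pmax(z1pre, 0)
  o_m <- sweep(z1 %*% p$fp2_W, 2, p$fp2_b, "+")

  # --- compound fusion + latent refinement
  qt <- .to_tokens(as.numeric(o_m), cfg$n_tokens)
  kv <- .to_tokens(o_g, cfg$n_tokens)
  fuse <- .attention_fwd(qt, kv, .attn_params(p, "fuse"),
                         n_heads = cfg$n_heads, scaling = cfg$energy_scaling)
  lats <- .latents_fwd(fuse$Y, p, cfg, want_cache = want_cache)

  # --- protein encoder + final cross-attention
  prot <- .protein_fwd(tokens, p, cfg, want_cache = want_cache)
  int <- .attention_fwd(lats$Y, prot$Y, .attn_params(p, "int"),
                        n_heads = cfg$n_heads, scaling = cfg$energy_scaling)
  ivec <- colMeans(int$Y)

  # --- regression head
  h1pre <- sweep(matrix(ivec, nrow = 1) %*% p$head1_W, 2, p$head1_b, "+")
  h1 <- pmax(h1pre, 0)
  pred <- as.numeric(h1 %*% p$head2_W + p$head2_b)

  cache <- if (want_cache) {
    list(graph = graph, st = st, inp = inp, h0pre = h0pre, XpS = XpS,
         steps = steps, x_fp = x_fp, z1pre = z1pre, z1 = z1,
         fuse = fuse, lats = lats, prot = prot, int = int,
         ivec = ivec, h1pre = h1pre, h1 = h1, n_db = n_db)
  }
  list(pred = pred, cache = cache)
}

.zero_like <- function(p) {
  lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
         else numeric(length(x)))
}

.model_backward <- function(p, cfg, cache, dpred) {
  g <- .zero_like(p)
  n_tokens <- cfg$n_tokens
  C <- cfg$attn_dim

  # head
  dh1 <- dpred * t(p$head2_W)            # 1 x head_hidden
  g$head2_W <- t(cache$h1) * dpred
  g$head2_b <- dpred
  dh1pre <- dh1 * (cache$h1pre > 0)
  g$head1_W <- t(matrix(cache$ivec, nrow = 1)) %*% dh1pre
  g$head1_b <- as.numeric(dh1pre)
  divec <- as.numeric(dh1pre %*% t(p$head1_W))

  # interact (mean pool over query tokens)
  dInt <- matrix(divec / n_tokens, n_tokens, C, byrow = TRUE)
  ib <- .attention_bwd(dInt, cache$int, .attn_params(p, "int"))
  for (nm in names(ib$grads)) g[[paste0("int_", nm)]] <- ib$grads[[nm]]
  dlat <- ib$dQin
  dprot <- ib$dKVin

  # latent self-attention stack (reverse)
  for (j in rev(seq_len(cfg$latent_blocks))) {
    bc <- cache$lats$cache[[j]]
    g2 <- .linear_bwd(dlat, bc$l2, p[[paste0("lat", j, "_ff2_W")]])
    g[[paste0("lat", j, "_ff2_W")]] <- g2$dW
    g[[paste0("lat", j, "_ff2_b")]] <- g2$db
    dr1 <- .relu_bwd(g2$dX, bc$r1)
    g1 <- .linear_bwd(dr1, bc$l1, p[[paste0("lat", j, "_ff1_W")]])
    g[[paste0("lat", j, "_ff1_W")]] <- g1$dW
    g[[paste0("lat", j, "_ff1_b")]] <- g1$db
    dx1 <- dlat + g1$dX
    ab <- .attention_bwd(dx1, bc$at, .attn_params(p, paste0("lat", j)))
    for (nm in names(ab$grads)) g[[paste0("lat", j, "_", nm)]] <- ab$grads[[nm]]
    dlat <- dx1 + ab$dQin + ab$dKVin
  }

  # fusion
  fb <- .attention_bwd(dlat, cache$fuse, .attn_params(p, "fuse"))
  for (nm in names(fb$grads)) g[[paste0("fuse_", nm)]] <- fb$grads[[nm]]
  do_m <- matrix(.from_tokens(fb$dQin), nrow = 1)
  do_g <- .from_tokens(fb$dKVin)

  # fingerprint MLP
  g$fp2_W <- t(cache$z1) %*% do_m
  g$fp2_b <- as.numeric(do_m)
  dz1 <- (do_m %*% t(p$fp2_W)) * (cache$z1pre > 0)
  g$fp1_W <- t(cache$x_fp) %*% dz1
  g$fp1_b <- as.numeric(dz1)

  # graph view
  if (cache$n_db > 0) {
    graph <- cache$graph; st <- cache$st
    n_atoms <- graph$n_atoms
    H <- cfg$mpnn_hidden
    datomvec <- matrix(do_g / n_atoms, n_atoms, H, byrow = TRUE)
    dh <- t(st$P) %*% (datomvec / st$n_in)
    dXpS <- matrix(0, cache$n_db, H)
    dH0 <- matrix(0, cache$n_db, H)
    for (t in rev(seq_len(cfg$mpnn_depth))) {
      sc <- cache$steps[[t]]
      dpre <- dh * (sc$pre > 0)
      dH0 <- dH0 + dpre
      g$msg_W <- g$msg_W + t(sc$M) %*% dpre
      g$msg_b <- g$msg_b + colSums(dpre)
      dM3 <- (dpre %*% t(p$msg_W)) / 3
      dXpS <- dXpS + st$deg * dM3 + t(st$A) %*% dM3
      dh <- t(st$A) %*% dM3
    }
    dH0 <- dH0 + dh
    dh0pre <- dH0 * (cache$h0pre > 0)
    g$atom_in_W <- t(cache$inp) %*% dh0pre
    g$atom_in_b <- colSums(dh0pre)
    rs <- rowsum(dXpS, group = graph$src)
    dXp <- matrix(0, n_atoms, H)
    dXp[as.integer(rownames(rs)), ] <- rs
    g$atom_proj_W <- t(graph$atom_features) %*% dXp
    g$atom_proj_b <- colSums(dXp)
  }

  # protein encoder
  pc <- cache$prot$cache
  ds <- dprot
  for (i in rev(seq_len(cfg$prot_blocks))) {
    bl <- pc$blocks[[i]]
    ds <- ds * pc$mask
    dln_in <- .glu_bwd(ds, bl$gl)
    lb <- .layernorm_bwd(dln_in, bl$ln)
    g[[paste0("prot_ln_g_", i)]] <- lb$dg
    g[[paste0("prot_ln_b_", i)]] <- lb$db
    cb <- .conv1d_bwd(lb$dX, bl$cv, p[[paste0("prot_conv_W_", i)]])
    g[[paste0("prot_conv_W_", i)]] <- cb$dW
    g[[paste0("prot_conv_b_", i)]] <- cb$db
    Cp <- cfg$prot_channels
    dres <- cfg$prot_lambda *
      (lb$dX[, seq_len(Cp), drop = FALSE] +
         lb$dX[, Cp + seq_len(Cp), drop = FALSE])
    ds <- cb$dX + dres
  }
  ds <- ds * pc$mask
  sb <- .conv1d_bwd(ds, pc$stem, p$prot_stem_W)
  g$prot_stem_W <- sb$dW
  g$prot_stem_b <- sb$db
  demb0 <- sb$dX * pc$mask
  rs <- rowsum(demb0, group = pc$ids)
  g$prot_emb[as.integer(rownames(rs)) + 1L, ] <-
    g$prot_emb[as.integer(rownames(rs)) + 1L, , drop = FALSE] + rs

  g
}

.add_grads <- function(a, b, scale = 1) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]] * scale
  a
}

# featurize unique compounds and proteins once; returns lookup lists
.featurize_dataset <- function(data, cfg) {
  smi <- unique(data$smiles)
  graphs <- lapply(smi, function(s) {
    g <- smiles_to_molgraph(s)
    g$structure <- .graph_structure(g)  # cache message-passing indices
    g
  })
  fps <- lapply(smi, smiles_to_fingerprint, radius = cfg$fp_radius,
                n_bits = cfg$fp_bits)
  names(graphs) <- names(fps) <- smi
  seqs <- unique(data$sequence)
  toks <- lapply(seqs, tokenize_protein, max_len = cfg$max_len)
  names(toks) <- seqs
  list(graphs = graphs, fps = fps, tokens = toks)
}

#' Predict affinities for an interaction table
#'
#' Runs the full forward pass (featurize, encode, fuse, attend, regress) on
#' each row of `data`.
#'
#' @param data Data frame with `smiles` and `sequence` columns.
#' @param model A fitted model ([train_cpi()]) or a bare parameter list from
#'   [cpi_init_params()].
#' @return The input as a tibble with a `.pred` column appended.
#' @export
predict_affinity_table <- function(data, model) {
  p <- if (inherits(model, "cpi_fit")) model$params else model
  cfg <- attr(p, "config")
  center <- attr(p, "label_center") %||% 0
  feats <- .featurize_dataset(data, cfg)
  preds <- vapply(seq_len(nrow(data)), function(i) {
    .model_forward(p, cfg, feats$graphs[[data$smiles[i]]],
                   feats$fps[[data$smiles[i]]],
                   feats$tokens[[data$sequence[i]]])$pred
  }, numeric(1))
  out <- tibble::as_tibble(data)
  out$.pred <- preds + center
  out
}

#' Save a model checkpoint
#'
#' Writes a single archive holding all weights plus the configuration that
#' produced them.
#'
#' @param model `cpi_fit` or `cpi_params` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  p <- if (inherits(model, "cpi_fit")) model$params else model
  saveRDS(list(params = unclass(p), config = attr(p, "config"),
               label_center = attr(p, "label_center") %||% 0,
               package_version = as.character(utils::packageVersion("cpinet"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param config Optional [cpi_config()]; when supplied it must equal the
#'   stored configuration — a mismatch is an error, never a silent reshape.
#' @return A `cpi_params` object.
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- readRDS(path)
  stored <- obj$config
  if (!is.null(config) && !identical(unclass(config), unclass(stored))) {
    rlang::abort("Checkpoint configuration does not match the requested one.",
                 class = "cpinet_config_error")
  }
  structure(obj$params, config = stored,
            label_center = obj$label_center %||% 0, class = "cpi_params")
}
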