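# Independent brute-force oracle for directed message passing, written as
# plain loops over atoms and directed bonds straight from the update
# equations, with no shared code or indexing tricks from the implementation.

bf_project <- function(x, W, b) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) out[j] <- sum(x * W[, j]) + b[j]
  out
}

bf_mpnn_readout <- function(graph, params, depth) {
  H <- ncol(params$atom_in_W)
  n_db <- graph$n_directed_bonds
  h0 <- matrix(0, n_db, H)
  for (b in seq_len(n_db)) {
    xe <- c(graph$atom_features[graph$src[b], ], graph$bond_features[b, ])
    h0[b, ] <- pmax(bf_project(xe, params$atom_in_W, params$atom_in_b), 0)
  }
  xp <- matrix(0, graph$n_atoms, H)
  for (a in seq_len(graph$n_atoms)) {
    xp[a, ] <- bf_project(graph$atom_features[a, ], params$atom_proj_W,
                          params$atom_proj_b)
  }
  h <- h0
  for (t in seq_len(depth)) {
    m <- matrix(0, n_db, H)
    for (b in seq_len(n_db)) {
      v <- graph$src[b]
      for (cc in seq_len(n_db)) {
        if (graph$dst[cc] == v && cc != graph$rev[b]) {
          m[b, ] <- m[b, ] + (xp[v, ] + xp[graph$src[cc], ] + h[cc, ]) / 3
        }
      }
    }
    h_new <- matrix(0, n_db, H)
    for (b in seq_len(n_db)) {
      h_new[b, ] <- pmax(h0[b, ] + bf_project(m[b, ], params$msg_W,
                                              params$msg_b), 0)
    }
    h <- h_new
  }
  atomvec <- matrix(0, graph$n_atoms, H)
  for (a in seq_len(graph$n_atoms)) {
    inc <- which(graph$dst == a)
    if (length(inc) > 0) {
      for (b in inc) atomvec[a, ] <- atomvec[a, ] + h[b, ]
      atomvec[a, ] <- atomvec[a, ] / length(inc)
    }
  }
  colMeans(atomvec)
}

# random connected multigraph-free graph with molgraph layout and random
# feature vectors (oracle tests do not need chemically valid molecules)
random_toy_graph <- function(n_atoms, d_atom = 5, d_bond = 3) {
  edges <- list()
  for (a in seq_len(n_atoms)[-1]) {
    edges[[length(edges) + 1L]] <- c(sample(a - 1L, 1), a)  # spanning tree
  }
  if (n_atoms >= 3 && stats::runif(1) < 0.5) {
    extra <- sort(sample(n_atoms, 2))
    if (!any(vapply(edges, function(e) all(sort(e) == extra), logical(1)))) {
      edges[[length(edges) + 1L]] <- extra
    }
  }
  n_chem <- length(edges)
  src <- dst <- rev_idx <- integer(2L * n_chem)
  bond_features <- matrix(0, 2L * n_chem, d_bond)
  for (j in seq_len(n_chem)) {
    f <- 2L * j - 1L; r <- 2L * j
    src[f] <- edges[[j]][1]; dst[f] <- edges[[j]][2]
    src[r] <- edges[[j]][2]; dst[r] <- edges[[j]][1]
    rev_idx[f] <- r; rev_idx[r] <- f
    bf <- stats::rnorm(d_bond)
    bond_features[f, ] <- bf
    bond_features[r, ] <- bf
  }
  structure(list(
    smiles = "<toy>", n_atoms = n_atoms, n_directed_bonds = 2L * n_chem,
    atom_features = matrix(stats::rnorm(n_atoms * d_atom), n_atoms),
    bond_features = bond_features, src = src, dst = dst, rev = rev_idx,
    incoming = lapply(seq_len(n_atoms), function(a) which(dst == a))),
    class = "molgraph")
}

# random parameters shaped for toy graphs
toy_mpnn_params <- function(H = 7, d_atom = 5, d_bond = 3) {
  list(atom_in_W = matrix(stats::rnorm((d_atom + d_bond) * H, sd = 0.5),
                          d_atom + d_bond, H),
       atom_in_b = stats::rnorm(H, sd = 0.2),
       atom_proj_W = matrix(stats::rnorm(d_atom * H, sd = 0.5), d_atom, H),
       atom_proj_b = stats::rnorm(H, sd = 0.2),
       msg_W = matrix(stats::rnorm(H * H, sd = 0.3), H, H),
       msg_b = stats::rnorm(H, sd = 0.2))
}

# run the package's own message-passing path on a toy graph
pkg_mpnn_readout <- function(graph, params, depth) {
  st <- init_hidden(graph, params)
  for (t in seq_len(depth)) st <- message_step(st, graph, params)
  readout(st, graph)
}

# small config used across model-level tests (fast, all paths exercised)
tiny_config <- function(...) {
  defaults <- list(fp_bits = 64, max_len = 30, mpnn_hidden = 12,
                   mpnn_depth = 2, fp_hidden = 24, compound_dim = 12,
                   n_tokens = 3, attn_dim = 8, latent_blocks = 1,
                   prot_embed_dim = 6, prot_channels = 8, prot_kernel = 3,
                   prot_blocks = 2, head_hidden = 8)
  do.call(cpi_config, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function(n = 12, seed = 42) {
  generate_synthetic(n_compounds = 6, n_proteins = 4, density = 0.5,
                     noise_sd = 0.1, seed = seed)
}
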