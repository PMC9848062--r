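test_that("hidden-state initialization is ReLU of the projected features", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 1)
  g <- smiles_to_molgraph("CCO")

  # all-zero input projection gives all-zero hiddens
  p0 <- p
  p0$atom_in_W[] <- 0
  st <- init_hidden(g, p0)
  expect_true(all(st$h == 0))
  expect_equal(st$step, 0L)

  # bond-less molecule: a valid, usable state with zero bond rows
  st1 <- init_hidden(smiles_to_molgraph("C"), p)
  expect_equal(nrow(st1$h), 0)
  expect_length(readout(st1, smiles_to_molgraph("C")), cfg$mpnn_hidden)

  # hand-set rows: hidden equals ReLU of selected concatenated features
  ph <- p
  ph$atom_in_W[] <- 0
  ph$atom_in_b[] <- 0
  ph$atom_in_W[1, 1] <- 1   # first atom-feature column
  ph$atom_in_W[atom_feature_dim() + 1L, 2] <- -1  # first bond-feature column
  st2 <- init_hidden(g, ph)
  expected_1 <- pmax(g$atom_features[g$src, 1], 0)
  expected_2 <- pmax(-g$bond_features[, 1], 0)
  expect_equal(st2$h[, 1], expected_1)
  expect_equal(st2$h[, 2], expected_2)
})

test_that("message step follows the averaged directed update", {
  set.seed(5)
  params <- toy_mpnn_params(H = 4)

  # two-atom molecule: both neighbour sets are empty, m = 0,
  # h1 = ReLU(h0 + W . 0 + b)
  g2 <- random_toy_graph(2)
  st <- init_hidden(g2, params)
  st1 <- message_step(st, g2, params)
  expected <- pmax(st$h0 + matrix(params$msg_b, 2, 4, byrow = TRUE), 0)
  expect_equal(st1$h, expected, tolerance = 1e-12)

  # 3-atom path A-B-C: message into B->C is Average(xB, xA, h_AB) only
  gp <- list(smiles = "<path>", n_atoms = 3L, n_directed_bonds = 4L,
             atom_features = matrix(stats::rnorm(15), 3),
             bond_features = matrix(stats::rnorm(12), 4),
             src = c(1L, 2L, 2L, 3L), dst = c(2L, 1L, 3L, 2L),
             rev = c(2L, 1L, 4L, 3L),
             incoming = list(2L, c(1L, 4L), 3L))
  gp$bond_features[2, ] <- gp$bond_features[1, ]
  gp$bond_features[4, ] <- gp$bond_features[3, ]
  class(gp) <- "molgraph"
  st <- init_hidden(gp, params)
  st1 <- message_step(st, gp, params)
  xp <- function(a) as.numeric(gp$atom_features[a, ] %*% params$atom_proj_W) +
    params$atom_proj_b
  m_bc <- (xp(2) + xp(1) + st$h[1, ]) / 3   # bond 1 is A->B
  expected_bc <- pmax(st$h0[3, ] + as.numeric(m_bc %*% params$msg_W) +
                        params$msg_b, 0)
  expect_equal(st1$h[3, ], expected_bc, tolerance = 1e-12)

  # backtracking exclusion: perturbing h of the reverse bond C->B (bond 4)
  # leaves the message into B->C (bond 3) unchanged
  st_pert <- st
  st_pert$h[4, ] <- st_pert$h[4, ] + 10
  st1_pert <- message_step(st_pert, gp, params)
  expect_equal(st1_pert$h[3, ], st1$h[3, ], tolerance = 1e-12)
  # ...but the message into B->A (bond 2) does change
  expect_false(isTRUE(all.equal(st1_pert$h[2, ], st1$h[2, ])))
})

test_that("readout averages incoming hiddens then atoms", {
  set.seed(6)
  params <- toy_mpnn_params(H = 4)
  g <- random_toy_graph(4)
  st <- init_hidden(g, params)
  # all hidden vectors equal c -> readout = c
  st$h <- matrix(rep(c(1, 2, 3, 4), each = g$n_directed_bonds),
                 g$n_directed_bonds)
  expect_equal(readout(st, g), c(1, 2, 3, 4))
})

test_that("message passing matches the brute-force oracle on random graphs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    g <- random_toy_graph(n)
    params <- toy_mpnn_params(H = 6)
    depth <- sample(1:4, 1)
    expect_equal(pkg_mpnn_readout(g, params, depth),
                 bf_mpnn_readout(g, params, depth), tolerance = 1e-6)
  }
})

test_that("readout is equivariant to atom relabeling", {
  set.seed(12)
  for (rep in 1:10) {
    g <- random_toy_graph(sample(3:6, 1))
    params <- toy_mpnn_params(H = 5)
    perm <- sample(g$n_atoms)
    inv <- order(perm)
    g2 <- g
    g2$atom_features <- g$atom_features[inv, , drop = FALSE]
    g2$src <- perm[g$src]; g2$dst <- perm[g$dst]
    g2$incoming <- lapply(seq_len(g$n_atoms), function(a) which(g2$dst == a))
    expect_equal(pkg_mpnn_readout(g, params, 3),
                 pkg_mpnn_readout(g2, params, 3), tolerance = 1e-6)
  }
})

test_that("backtracking exclusion holds as a zero finite-difference", {
  set.seed(13)
  params <- toy_mpnn_params(H = 4)
  g <- random_toy_graph(4)
  st0 <- init_hidden(g, params)
  base <- message_step(st0, g, params)
  eps <- 1e-4
  for (b in seq_len(g$n_directed_bonds)) {
    st_p <- st0
    st_p$h[g$rev[b], ] <- st_p$h[g$rev[b], ] + eps
    stepped <- message_step(st_p, g, params)
    # the update of bond b never senses its reverse bond's hidden state
    expect_equal(stepped$h[b, ], base$h[b, ], tolerance = 1e-12)
  }
})

test_that("fingerprint encoder is a deterministic feed-forward map", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 3)
  fp <- as.integer(runif(cfg$fp_bits) < 0.2)
  expect_identical(encode_fingerprint(fp, p), encode_fingerprint(fp, p))
  expect_length(encode_fingerprint(fp, p), cfg$compound_dim)
  # zero input through zero biases stays zero
  p0 <- p; p0$fp1_b[] <- 0; p0$fp2_b[] <- 0
  expect_true(all(encode_fingerprint(numeric(cfg$fp_bits), p0) == 0))
  expect_error(encode_fingerprint(numeric(3), p),
               class = "cpinet_config_error")
})

test_that("protein encoder honors GLU, residual scaling and masking", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 4)
  tok <- tokenize_protein("ACDEFGHIKLMNPQRST", max_len = cfg$max_len)
  out <- encode_protein(tok, p)
  expect_equal(dim(out), c(cfg$max_len, cfg$prot_channels))
  expect_true(all(is.finite(out)))

  # zero conv weights and lambda 0: every block output is GLU(LN(bias)),
  # constant across positions
  cfg0 <- tiny_config(prot_lambda = 0, mask_pad = FALSE)
  p0 <- cpi_init_params(cfg0, seed = 4)
  for (i in seq_len(cfg0$prot_blocks)) {
    p0[[paste0("prot_conv_W_", i)]][] <- 0
  }
  out0 <- encode_protein(tok, p0)
  expect_equal(out0, matrix(out0[1, ], nrow(out0), ncol(out0), byrow = TRUE),
               tolerance = 1e-12)

  # GLU halves the channel width
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(ncol(cpinet:::.glu_fwd(x)$Y), 2)
  a <- x[, 1:2]; b <- x[, 3:4]
  expect_equal(cpinet:::.glu_fwd(x)$Y, a * (1 / (1 + exp(-b))))
  expect_error(cpinet:::.glu_fwd(matrix(0, 2, 3)),
               class = "cpinet_config_error")

  # masking: with mask_pad on, altering pad-region token values leaves the
  # representation of real positions unchanged
  tl <- attr(tok, "true_length")
  tok2 <- tok
  tok2[(tl + 1):cfg$max_len] <- 3L
  attr(tok2, "true_length") <- tl
  out2 <- encode_protein(tok2, p)
  expect_equal(out2[seq_len(tl), ], out[seq_len(tl), ], tolerance = 1e-10)
})

test_that("a one-block kernel-1 protein encoder matches scalar arithmetic", {
  cfg <- cpi_config(fp_bits = 16, max_len = 3, mpnn_hidden = 4, mpnn_depth = 1,
                    fp_hidden = 8, compound_dim = 4, n_tokens = 1,
                    attn_dim = 4, latent_blocks = 0, prot_embed_dim = 1,
                    prot_channels = 1, prot_kernel = 1, prot_blocks = 1,
                    head_hidden = 4, mask_pad = FALSE)
  p <- cpi_init_params(cfg, seed = 9)
  p$prot_emb[] <- seq_len(nrow(p$prot_emb)) * 0.1
  p$prot_stem_W[] <- 1; p$prot_stem_b[] <- 0
  p$prot_conv_W_1[] <- c(2, -1)   # 1x1 conv: 1 channel -> 2 channels
  p$prot_conv_b_1[] <- c(0.1, -0.2)
  p$prot_ln_g_1[] <- 1; p$prot_ln_b_1[] <- 0
  tok <- tokenize_protein("AC", max_len = 3)
  out <- encode_protein(tok, p)
  # by hand: emb = 0.1*(id+1); stem = emb; u = (2*s+0.1, -s-0.2) + 0.5*(s, s)
  ids <- as.integer(tok)
  s <- 0.1 * (ids + 1)
  u1 <- 2 * s + 0.1 + 0.5 * s
  u2 <- -s - 0.2 + 0.5 * s
  mu <- (u1 + u2) / 2
  va <- ((u1 - mu)^2 + (u2 - mu)^2) / 2
  a <- (u1 - mu) / sqrt(va + 1e-5)
  b <- (u2 - mu) / sqrt(va + 1e-5)
  expect_equal(as.numeric(out), a * (1 / (1 + exp(-b))), tolerance = 1e-10)
})
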