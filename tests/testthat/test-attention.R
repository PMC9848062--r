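rand_attn_params <- function(d_q, d_kv, C, seed = 1) {
  set.seed(seed)
  list(Wq = matrix(rnorm(d_q * C, sd = 0.5), d_q, C), bq = rnorm(C, sd = 0.1),
       Wk = matrix(rnorm(d_kv * C, sd = 0.5), d_kv, C), bk = rnorm(C, sd = 0.1),
       Wv = matrix(rnorm(d_kv * C, sd = 0.5), d_kv, C), bv = rnorm(C, sd = 0.1),
       Wo = matrix(rnorm(C * C, sd = 0.5), C, C), bo = rnorm(C, sd = 0.1))
}

test_that("attention energies are row-stochastic and degenerate cases hold", {
  set.seed(21)
  ap <- rand_attn_params(3, 4, 6)
  q <- matrix(rnorm(12), 4, 3)
  kv <- matrix(rnorm(20), 5, 4)
  out <- cross_attention(q, kv, ap, n_heads = 2)
  for (E in attr(out, "energy")) {
    expect_equal(rowSums(E), rep(1, nrow(q)), tolerance = 1e-6)
  }
  expect_equal(nrow(out), nrow(q))

  # single key/value token: energy is identically 1, output = f0(fV(kv))
  kv1 <- kv[1, , drop = FALSE]
  out1 <- cross_attention(q, kv1, ap)
  expect_true(all(abs(attr(out1, "energy")[[1]] - 1) < 1e-12))
  v <- sweep(kv1 %*% ap$Wv, 2, ap$bv, "+")
  expected <- sweep(matrix(rep(v, nrow(q)), nrow(q), byrow = TRUE) %*% ap$Wo,
                    2, ap$bo, "+")
  expect_equal(unclass(out1), expected, ignore_attr = TRUE, tolerance = 1e-12)

  # all keys identical: uniform energies, output = f0(mean of V rows)
  kv_same <- kv[rep(2, 5), ]
  out_same <- cross_attention(q, kv_same, ap)
  expect_true(all(abs(attr(out_same, "energy")[[1]] - 1 / 5) < 1e-9))
})

test_that("a 2x2 hand-computed cross-attention matches to 1e-9", {
  # scalar projections: C = 1, one head
  ap <- list(Wq = matrix(2), bq = 0.5, Wk = matrix(1), bk = -0.25,
             Wv = matrix(-1.5), bv = 1, Wo = matrix(0.8), bo = 0.1)
  q <- matrix(c(0.3, -0.7), 2, 1)
  kv <- matrix(c(0.2, 0.9), 2, 1)
  out <- cross_attention(q, kv, ap, n_heads = 1, scaling = "sqrt")
  # hand arithmetic (direct formula, scalar case, scale = 1/sqrt(1) = 1)
  Q <- 2 * q + 0.5; K <- kv - 0.25; V <- -1.5 * kv + 1
  S <- Q %*% t(K)
  E <- exp(S) / rowSums(exp(S))
  expected <- (E %*% V) * 0.8 + 0.1
  expect_equal(unclass(out), expected, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(rowSums(attr(out, "energy")[[1]]), c(1, 1), tolerance = 1e-9)
})

test_that("attention output is equivariant to permuting key/value tokens", {
  set.seed(22)
  ap <- rand_attn_params(4, 4, 8)
  q <- matrix(rnorm(8), 2, 4)
  kv <- matrix(rnorm(24), 6, 4)
  out <- cross_attention(q, kv, ap, n_heads = 2)
  perm <- sample(6)
  out_p <- cross_attention(q, kv[perm, ], ap, n_heads = 2)
  expect_equal(unclass(out), unclass(out_p), ignore_attr = TRUE,
               tolerance = 1e-10)
  E <- attr(out, "energy")[[1]]
  E_p <- attr(out_p, "energy")[[1]]
  expect_equal(E[, perm], E_p, tolerance = 1e-10)
})

test_that("non-finite attention inputs raise numeric errors", {
  ap <- rand_attn_params(2, 2, 4)
  q <- matrix(c(1, NaN), 1, 2)
  expect_error(cross_attention(q, matrix(0, 1, 2), ap),
               class = "cpinet_numeric_error")
})

test_that("compound fusion reshapes, attends and is role-asymmetric", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 7)
  set.seed(30)
  o_ms <- rnorm(cfg$compound_dim)
  o_gs <- rnorm(cfg$mpnn_hidden)
  comp <- fuse_compound(o_ms, o_gs, p)
  expect_length(comp, cfg$n_tokens * cfg$attn_dim)
  expect_true(all(is.finite(comp)))
  # swapping the two views changes the output (queries vs keys/values)
  comp_sw <- fuse_compound(o_gs, o_ms, p)
  expect_false(isTRUE(all.equal(comp, comp_sw)))
  # indivisible vector length is rejected
  expect_error(fuse_compound(rnorm(cfg$compound_dim + 1), o_gs, p),
               class = "cpinet_config_error")
})

test_that("n_tokens = 1 fusion reduces to the single-key case", {
  cfg <- tiny_config(n_tokens = 1, compound_dim = 12, mpnn_hidden = 12)
  p <- cpi_init_params(cfg, seed = 8)
  set.seed(31)
  o_ms <- rnorm(12); o_gs <- rnorm(12)
  comp <- fuse_compound(o_ms, o_gs, p)
  v <- as.numeric(matrix(o_gs, 1) %*% p$fuse_Wv + p$fuse_bv)
  expected <- as.numeric(matrix(v, 1) %*% p$fuse_Wo + p$fuse_bo)
  expect_equal(comp, expected, tolerance = 1e-10)
})

test_that("latent refinement: zero blocks is identity, zero output is residual identity", {
  cfg0 <- tiny_config(latent_blocks = 0)
  p0 <- cpi_init_params(cfg0, seed = 9)
  x <- rnorm(cfg0$n_tokens * cfg0$attn_dim)
  lat <- refine_latents(x, p0)
  expect_equal(lat, matrix(x, cfg0$n_tokens, byrow = TRUE))

  cfg1 <- tiny_config(latent_blocks = 1)
  p1 <- cpi_init_params(cfg1, seed = 9)
  p1$lat1_Wo[] <- 0; p1$lat1_bo[] <- 0
  p1$lat1_ff2_W[] <- 0; p1$lat1_ff2_b[] <- 0
  lat1 <- refine_latents(x, p1)
  expect_equal(lat1, matrix(x, cfg1$n_tokens, byrow = TRUE), tolerance = 1e-12)
})

test_that("one latent block matches hand evaluation on two tokens", {
  cfg <- cpi_config(fp_bits = 16, max_len = 5, mpnn_hidden = 2, mpnn_depth = 1,
                    fp_hidden = 4, compound_dim = 2, n_tokens = 2,
                    attn_dim = 1, latent_blocks = 1, ffn_expansion = 2,
                    prot_embed_dim = 2, prot_channels = 2, prot_kernel = 3,
                    prot_blocks = 1, head_hidden = 2)
  p <- cpi_init_params(cfg, seed = 10)
  p$lat1_Wq[] <- 1; p$lat1_bq[] <- 0
  p$lat1_Wk[] <- 1; p$lat1_bk[] <- 0
  p$lat1_Wv[] <- 2; p$lat1_bv[] <- 0
  p$lat1_Wo[] <- 1; p$lat1_bo[] <- 0
  p$lat1_ff1_W[] <- c(1, -1); p$lat1_ff1_b[] <- 0
  p$lat1_ff2_W[] <- c(0.5, 0.5); p$lat1_ff2_b[] <- 0.25
  x <- c(0.4, -0.2)
  out <- refine_latents(x, p)
  # hand: scalar tokens, attention scale 1
  S <- outer(x, x); E <- exp(S) / rowSums(exp(S))
  a <- as.numeric(E %*% (2 * x))       # attended values through f0 = identity
  x1 <- x + a
  f <- pmax(cbind(x1, -x1), 0)
  x2 <- x1 + as.numeric(f %*% c(0.5, 0.5)) + 0.25
  expect_equal(as.numeric(out), x2, tolerance = 1e-10)
})

test_that("compound-protein interaction pools attended protein values", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 11)
  set.seed(33)
  lat <- matrix(rnorm(cfg$n_tokens * cfg$attn_dim), cfg$n_tokens)
  prot <- matrix(rnorm(cfg$max_len * cfg$prot_channels), cfg$max_len)
  iv <- interact(lat, prot, p)
  expect_length(iv, cfg$attn_dim)

  # identical protein rows: output independent of the attention energies
  prot_same <- prot[rep(3, cfg$max_len), ]
  iv_same <- interact(lat, prot_same, p)
  v <- as.numeric(prot[3, ] %*% p$int_Wv + p$int_bv)
  expected <- as.numeric(v %*% p$int_Wo + p$int_bo)
  expect_equal(iv_same, expected, tolerance = 1e-9)

  # zero latents with zero query bias: energies uniform over positions
  p0 <- p; p0$int_bq[] <- 0
  out_attn <- cross_attention(matrix(0, cfg$n_tokens, cfg$attn_dim), prot,
                              .attn_params <- cpinet:::.attn_params(p0, "int"))
  E <- attr(out_attn, "energy")[[1]]
  expect_true(all(abs(E - 1 / cfg$max_len) < 1e-9))
})

test_that("the regression head is affine-deterministic", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 12)
  iv <- rnorm(cfg$attn_dim)
  expect_identical(predict_affinity(iv, p), predict_affinity(iv, p))
  p0 <- p
  p0$head1_W[] <- 0; p0$head2_W[] <- 0; p0$head2_b <- 1.25
  expect_equal(predict_affinity(iv, p0), 1.25)
})

test_that("the full forward pass is finite and deterministic on the fixture set", {
  cfg <- tiny_config()
  p <- cpi_init_params(cfg, seed = 13)
  smiles <- druglike_smiles()$smiles
  set.seed(40)
  seqs <- replicate(5, paste(sample(c("A", "C", "D", "G", "K", "L", "P"),
                                    25, replace = TRUE), collapse = ""))
  data <- tibble::tibble(smiles = smiles,
                         sequence = rep_len(seqs, length(smiles)),
                         affinity = 0)
  out1 <- predict_affinity_table(data, p)
  out2 <- predict_affinity_table(data, p)
  expect_true(all(is.finite(out1$.pred)))
  expect_identical(out1$.pred, out2$.pred)
  expect_equal(nrow(out1), 50)
})
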