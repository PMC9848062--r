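#' Model configuration
#'
#' Collects every architectural hyperparameter of the affinity model. Defaults
#' are the package's fixed working configuration: message-passing depth 3 with
#' hidden width 300, fingerprint radius 2 over 2048 bits, 6 compound tokens for
#' the cross-attention fusion, a single attention head, two latent
#' self-attention refinement blocks, and a 3-block gated residual convolution
#' protein encoder (128 channels, kernel 7, residual scale 0.5) over
#' fixed-length 500 token inputs. All values are overridable.
#'
#' @param fp_radius,fp_bits Morgan fingerprint radius and folded length.
#' @param max_len Fixed protein token length (longer sequences are truncated).
#' @param mpnn_hidden,mpnn_depth Directed message-passing hidden width and
#'   number of message-passing steps.
#' @param fp_hidden,compound_dim Fingerprint MLP hidden width and output
#'   length (the fingerprint-view embedding size).
#' @param n_tokens Number of tokens each 1-D compound embedding is reshaped
#'   into before attention; must divide `mpnn_hidden` and `compound_dim`.
#' @param n_heads Attention heads (the working default is single-head).
#' @param attn_dim Shared attention embedding dimension C; divisible by
#'   `n_heads`.
#' @param latent_blocks Number of latent self-attention refinement blocks.
#' @param ffn_expansion Width multiplier of the position-wise feed-forward
#'   inside each latent block.
#' @param prot_embed_dim Residue embedding size.
#' @param prot_channels,prot_kernel,prot_blocks Convolutional protein encoder
#'   width, kernel size and residual block count.
#' @param prot_lambda Residual scaling factor applied to the block input.
#' @param mask_pad Zero protein positions beyond the true sequence length
#'   after every block.
#' @param head_hidden Regression head hidden width.
#' @param energy_scaling `"sqrt"` for the conventional scaled dot product
#'   `QK^T / sqrt(C/d)`; `"literal"` multiplies energies by `C/d` instead.
#' @return A list of class `cpi_config`.
#' @export
cpi_config <- function(fp_radius = 2, fp_bits = 2048,
                       max_len = 500,
                       mpnn_hidden = 300, mpnn_depth = 3,
                       fp_hidden = 512, compound_dim = 300,
                       n_tokens = 6, n_heads = 1, attn_dim = 64,
                       latent_blocks = 2, ffn_expansion = 2,
                       prot_embed_dim = 32, prot_channels = 128,
                       prot_kernel = 7, prot_blocks = 3, prot_lambda = 0.5,
                       mask_pad = TRUE,
                       head_hidden = 64,
                       energy_scaling = c("sqrt", "literal")) {
  energy_scaling <- match.arg(energy_scaling)
  cfg <- list(fp_radius = fp_radius, fp_bits = fp_bits, max_len = max_len,
              mpnn_hidden = mpnn_hidden, mpnn_depth = mpnn_depth,
              fp_hidden = fp_hidden, compound_dim = compound_dim,
              n_tokens = n_tokens, n_heads = n_heads, attn_dim = attn_dim,
              latent_blocks = latent_blocks, ffn_expansion = ffn_expansion,
              prot_embed_dim = prot_embed_dim, prot_channels = prot_channels,
              prot_kernel = prot_kernel, prot_blocks = prot_blocks,
              prot_lambda = prot_lambda, mask_pad = mask_pad,
              head_hidden = head_hidden, energy_scaling = energy_scaling)
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in setdiff(names(cfg), c("mask_pad", "energy_scaling"))) {
    if (!ok(cfg[[nm]]) || cfg[[nm]] < 0) {
      rlang::abort(paste0("Invalid config value for ", nm),
                   class = "cpinet_config_error")
    }
  }
  if (cfg$mpnn_depth < 1 || cfg$prot_blocks < 1) {
    rlang::abort("mpnn_depth and prot_blocks must be >= 1.",
                 class = "cpinet_config_error")
  }
  if (cfg$mpnn_hidden %% cfg$n_tokens != 0 ||
      cfg$compound_dim %% cfg$n_tokens != 0) {
    rlang::abort("n_tokens must divide mpnn_hidden and compound_dim.",
                 class = "cpinet_config_error")
  }
  if (cfg$attn_dim %% cfg$n_heads != 0) {
    rlang::abort("attn_dim must be divisible by n_heads.",
                 class = "cpinet_config_error")
  }
  structure(cfg, class = "cpi_config")
}

#' @export
print.cpi_config <- function(x, ...) {
  cat("<cpi_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Initialize model parameters
#'
#' Draws all weights with Glorot-uniform initialization under the given seed;
#' biases and layer-norm offsets start at zero, layer-norm gains at one.
#'
#' @param config A [cpi_config()].
#' @param seed Integer seed controlling the draw.
#' @return Named list of parameter arrays (class `cpi_params`) with the
#'   generating `config` attached as an attribute.
#' @export
cpi_init_params <- function(config = cpi_config(), seed = 1) {
  set.seed(seed)
  d_af <- atom_feature_dim(); d_bf <- bond_feature_dim()
  H <- config$mpnn_hidden; C <- config$attn_dim
  dm <- config$compound_dim %/% config$n_tokens
  dg <- H %/% config$n_tokens
  Cp <- config$prot_channels; k <- config$prot_kernel
  p <- list(
    atom_in_W = .glorot(d_af + d_bf, H), atom_in_b = numeric(H),
    atom_proj_W = .glorot(d_af, H), atom_proj_b = numeric(H),
    msg_W = .glorot(H, H), msg_b = numeric(H),
    fp1_W = .glorot(config$fp_bits, config$fp_hidden),
    fp1_b = numeric(config$fp_hidden),
    fp2_W = .glorot(config$fp_hidden, config$compound_dim),
    fp2_b = numeric(config$compound_dim),
    prot_emb = .glorot(.vocab_size(), config$prot_embed_dim),
    prot_stem_W = .glorot(k * config$prot_embed_dim, Cp),
    prot_stem_b = numeric(Cp)
  )
  for (i in seq_len(config$prot_blocks)) {
    p[[paste0("prot_conv_W_", i)]] <- .glorot(k * Cp, 2L * Cp)
    p[[paste0("prot_conv_b_", i)]] <- numeric(2L * Cp)
    p[[paste0("prot_ln_g_", i)]] <- rep(1, 2L * Cp)
    p[[paste0("prot_ln_b_", i)]] <- numeric(2L * Cp)
  }
  p <- c(p, list(
    fuse_Wq = .glorot(dm, C), fuse_bq = numeric(C),
    fuse_Wk = .glorot(dg, C), fuse_bk = numeric(C),
    fuse_Wv = .glorot(dg, C), fuse_bv = numeric(C),
    fuse_Wo = .glorot(C, C), fuse_bo = numeric(C)))
  for (j in seq_len(config$latent_blocks)) {
    e <- config$ffn_expansion * C
    blk <- list(.glorot(C, C), numeric(C), .glorot(C, C), numeric(C),
                .glorot(C, C), numeric(C), .glorot(C, C), numeric(C),
                .glorot(C, e), numeric(e), .glorot(e, C), numeric(C))
    names(blk) <- paste0("lat", j, "_", c("Wq", "bq", "Wk", "bk", "Wv", "bv",
                                          "Wo", "bo", "ff1_W", "ff1_b",
                                          "ff2_W", "ff2_b"))
    p <- c(p, blk)
  }
  p <- c(p, list(
    int_Wq = .glorot(C, C), int_bq = numeric(C),
    int_Wk = .glorot(Cp, C), int_bk = numeric(C),
    int_Wv = .glorot(Cp, C), int_bv = numeric(C),
    int_Wo = .glorot(C, C), int_bo = numeric(C),
    head1_W = .glorot(C, config$head_hidden),
    head1_b = numeric(config$head_hidden),
    head2_W = .glorot(config$head_hidden, 1L), head2_b = 0))
  structure(p, config = config, class = "cpi_params")
}

.attn_params <- function(p, prefix) {
  list(Wq = p[[paste0(prefix, "_Wq")]], bq = p[[paste0(prefix, "_bq")]],
       Wk = p[[paste0(prefix, "_Wk")]], bk = p[[paste0(prefix, "_bk")]],
       Wv = p[[paste0(prefix, "_Wv")]], bv = p[[paste0(prefix, "_bv")]],
       Wo = p[[paste0(prefix, "_Wo")]], bo = p[[paste0(prefix, "_bo")]])
}
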