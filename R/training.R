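# Label transforms, density-weighted MSE objective, LAMB optimizer and the
# training loop.

#' Convert a dissociation constant to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with `Kd` in nanomolar, so 1e9 nM maps to 0,
#' 1e4 nM to 5 and 1 nM to 9.
#'
#' @param kd_nM Positive dissociation constant(s) in nM.
#' @return pKd value(s).
#' @examples
#' kd_to_pkd(c(1e9, 1e4, 1))  # 0 5 9
#' @export
kd_to_pkd <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0)) {
    rlang::abort("Kd must be positive and finite.",
                 class = "cpinet_domain_error")
  }
  -log10(kd_nM / 1e9)
}

#' Density-based loss weighting rule
#'
#' Squared errors of records whose label falls inside `[low, high]` (closed on
#' both ends) are multiplied by `inside_weight`, all others by
#' `outside_weight`. The Davis preset discounts the high-density mass at
#' pKd 5 by 0.5 and boosts everything else by 5; the KIBA preset applies the
#' same pair over the 11.1-12 high-density interval.
#'
#' @param low,high Interval bounds (closed).
#' @param inside_weight,outside_weight Positive multipliers.
#' @return A `weight_rule` list.
#' @export
weight_rule <- function(low, high, inside_weight, outside_weight) {
  if (low > high || inside_weight <= 0 || outside_weight <= 0) {
    rlang::abort("Need low <= high and positive weights.",
                 class = "cpinet_config_error")
  }
  structure(list(low = low, high = high, inside_weight = inside_weight,
                 outside_weight = outside_weight), class = "weight_rule")
}

#' @rdname weight_rule
#' @export
weight_rule_davis <- function() weight_rule(0, 5, 0.5, 5)

#' @rdname weight_rule
#' @export
weight_rule_kiba <- function() weight_rule(11.1, 12, 0.5, 5)

.rule_weights <- function(target, rule) {
  if (is.null(rule)) return(rep(1, length(target)))
  ifelse(target >= rule$low & target <= rule$high,
         rule$inside_weight, rule$outside_weight)
}

#' Weighted mean squared error
#'
#' Without a rule this is the plain MSE; with a rule each squared error is
#' multiplied by the rule's inside/outside weight for its target value before
#' averaging.
#'
#' @param pred,target Equal-length numeric vectors.
#' @param rule A [weight_rule()] or `NULL`.
#' @return Non-negative scalar loss.
#' @examples
#' weighted_mse(c(5, 5), c(5, 6), weight_rule_davis())  # 2.5
#' @export
weighted_mse <- function(pred, target, rule = NULL) {
  if (length(pred) != length(target) || length(pred) == 0) {
    rlang::abort("pred and target must be non-empty and equal length.",
                 class = "cpinet_contract_error")
  }
  w <- .rule_weights(target, rule)
  mean(w * (pred - target)^2)
}

#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Records per optimizer step.
#' @param learning_rate LAMB base step size.
#' @param weight_decay Decoupled weight decay added to the update.
#' @param lr_decay Optional multiplicative learning-rate decay applied once
#'   per epoch (1 = constant rate).
#' @param seed Seed for shuffling and initialization.
#' @param beta1,beta2,eps Adam-style moment constants.
#' @param trust_min,trust_max Clip bounds on the layer-wise trust ratio. The
#'   default caps the ratio at 1: layers with small weight norms take
#'   proportionally smaller steps but no layer's step is amplified, which
#'   keeps the small output layers of this architecture stable.
#' @param patience Early-stop after this many epochs without validation
#'   improvement.
#' @param weight_rule Optional [weight_rule()] applied to the training loss.
#' @param val_fraction Fraction of records held out for validation when no
#'   explicit validation set is given (the 80/20 convention).
#' @return A `cpi_train_config` list.
#' @export
cpi_train_config <- function(epochs = 100, batch_size = 16,
                             learning_rate = 0.005, weight_decay = 0,
                             lr_decay = 1,
                             seed = 1, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-6, trust_min = 0, trust_max = 1,
                             patience = 30, weight_rule = NULL,
                             val_fraction = 0.2) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            weight_decay >= 0, lr_decay > 0, lr_decay <= 1, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            eps > 0, patience >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_decay = lr_decay, seed = seed, beta1 = beta1, beta2 = beta2, eps = eps,
                 trust_min = trust_min, trust_max = trust_max,
                 patience = patience, weight_rule = weight_rule,
                 val_fraction = val_fraction), class = "cpi_train_config")
}

#' One LAMB optimizer step
#'
#' Layer-wise adaptive moments: per parameter array, bias-corrected Adam
#' moments give the update direction `u`; the trust ratio
#' `r = ||w|| / ||u + wd * w||` rescales the step (degenerate norms fall back
#' to 1), and `w <- w - lr * r * (u + wd * w)`.
#'
#' @param params Named list of parameter arrays.
#' @param grads Gradients with the same structure.
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   (moments at zero, step counter 0).
#' @param config A [cpi_train_config()].
#' @return List with updated `params` and `state`.
#' @export
lamb_step <- function(params, grads, state = NULL, config = cpi_train_config()) {
  if (is.null(state)) {
    state <- list(m = .zero_like(params), v = .zero_like(params), t = 0L)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - config$beta1^state$t
  bc2 <- 1 - config$beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (any(!is.finite(gmat))) {
      rlang::abort(paste0("Non-finite gradient in parameter group '", nm, "'"),
                   class = "cpinet_numeric_error")
    }
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * gmat
    state$v[[nm]] <- config$beta2 * state$v[[nm]] + (1 - config$beta2) * gmat^2
    u <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + config$eps)
    upd <- u + config$weight_decay * params[[nm]]
    wn <- sqrt(sum(params[[nm]]^2))
    un <- sqrt(sum(upd^2))
    r <- if (wn == 0 || un == 0) 1 else wn / un
    r <- min(max(r, config$trust_min), config$trust_max)
    if (r == 0) r <- 1
    params[[nm]] <- params[[nm]] - config$learning_rate * r * upd
  }
  list(params = params, state = state)
}

#' Train the affinity model
#'
#' Full-batch-shuffled minibatch training of the nested cross-attention model
#' with the LAMB optimizer and (optionally) density-weighted MSE. The run is
#' deterministic given the seed. The best-validation parameters are retained
#' and training stops early after `patience` epochs without improvement.
#'
#' @param data Interaction table with columns `smiles`, `sequence`,
#'   `affinity`.
#' @param config Model architecture ([cpi_config()]).
#' @param train_config Optimization settings ([cpi_train_config()]).
#' @param init_params Optional starting parameters (e.g. a loaded checkpoint)
#'   for resuming; defaults to a fresh initialization under the seed.
#' @param validation Optional explicit validation table; otherwise
#'   `val_fraction` of `data` is held out.
#' @param verbose Print per-epoch losses.
#' @return A `cpi_fit`: list with `params`, `config`, `train_config`,
#'   `history` (tibble of per-epoch train/validation loss), `best_epoch` and
#'   `epochs_run`.
#' @export
train_cpi <- function(data, config = cpi_config(),
                      train_config = cpi_train_config(),
                      init_params = NULL, validation = NULL,
                      verbose = FALSE) {
  if (nrow(data) == 0) {
    rlang::abort("Empty training set.", class = "cpinet_contract_error")
  }
  tc <- train_config
  set.seed(tc$seed)
  if (is.null(validation) && tc$val_fraction > 0 &&
      floor(nrow(data) * tc$val_fraction) >= 1) {
    n_val <- floor(nrow(data) * tc$val_fraction)
    vi <- sample(nrow(data), n_val)
    validation <- data[vi, , drop = FALSE]
    data <- data[-vi, , drop = FALSE]
  }
  p <- init_params %||% cpi_init_params(config, seed = tc$seed)
  if (!identical(unclass(attr(p, "config")), unclass(config))) {
    rlang::abort("init_params were built under a different config.",
                 class = "cpinet_config_error")
  }
  all_data <- if (is.null(validation)) data else
    dplyr::bind_rows(data, validation)
  feats <- .featurize_dataset(all_data, config)
  w_train <- .rule_weights(data$affinity, tc$weight_rule)
  # the network starts near zero output; fitting raw affinities would push a
  # large constant through the ReLU stack and can collapse it. Train against
  # centred labels and add the training-label mean back at prediction time.
  center <- mean(data$affinity)

  eval_set <- function(params, set) {
    preds <- vapply(seq_len(nrow(set)), function(i) {
      .model_forward(params, config, feats$graphs[[set$smiles[i]]],
                     feats$fps[[set$smiles[i]]],
                     feats$tokens[[set$sequence[i]]])$pred
    }, numeric(1))
    mean((preds + center - set$affinity)^2)
  }

  state <- NULL
  best <- list(loss = Inf, params = p, epoch = 0L)
  history <- vector("list", tc$epochs)
  stall <- 0L
  n <- nrow(data)
  epochs_run <- 0L
  tc_step <- tc
  for (epoch in seq_len(tc$epochs)) {
    tc_step$learning_rate <- tc$learning_rate * tc$lr_decay^(epoch - 1)
    ord <- sample(n)
    batch_starts <- seq(1L, n, by = tc$batch_size)
    ep_loss <- 0; ep_n <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + tc$batch_size - 1L, n)]
      nb <- length(idx)
      grads <- NULL
      bl <- 0
      for (i in idx) {
        fw <- .model_forward(p, config, feats$graphs[[data$smiles[i]]],
                             feats$fps[[data$smiles[i]]],
                             feats$tokens[[data$sequence[i]]],
                             want_cache = TRUE)
        err <- fw$pred + center - data$affinity[i]
        bl <- bl + w_train[i] * err^2
        gi <- .model_backward(p, config, fw$cache,
                              2 * w_train[i] * err / nb)
        grads <- if (is.null(grads)) gi else .add_grads(grads, gi)
      }
      bl <- bl / nb
      if (!is.finite(bl)) {
        rlang::abort(paste0("Training diverged (non-finite loss) at epoch ",
                            epoch), class = "cpinet_numeric_error")
      }
      step <- lamb_step(p, grads, state, tc_step)
      p <- step$params; state <- step$state
      ep_loss <- ep_loss + bl * nb; ep_n <- ep_n + nb
    }
    train_loss <- ep_loss / ep_n
    val_loss <- if (!is.null(validation)) eval_set(p, validation) else NA_real_
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = train_loss,
                                       val_loss = val_loss)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.5f  val %s\n", epoch, train_loss,
                  ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
    monitor <- if (is.na(val_loss)) train_loss else val_loss
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, params = p, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    epochs_run <- epoch
    if (stall >= tc$patience) break
  }
  attr(best$params, "config") <- config
  attr(best$params, "label_center") <- center
  class(best$params) <- "cpi_params"
  structure(list(params = best$params, config = config, train_config = tc,
                 label_center = center,
                 history = dplyr::bind_rows(history[seq_len(epochs_run)]),
                 best_epoch = best$epoch, best_loss = best$loss,
                 epochs_run = epochs_run),
            class = "cpi_fit")
}

#' @export
print.cpi_fit <- function(x, ...) {
  cat("<cpi_fit> ", x$epochs_run, " epochs; best epoch ", x$best_epoch,
      " (monitored loss ", signif(x$best_loss, 5), ")\n", sep = "")
  invisible(x)
}
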