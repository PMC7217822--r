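# Variational autoencoder for 52-point total-deviation fields.
#
# Architecture (defaults): 52 -> 38 -> 26 -> (mu, log-variance) of an
# 8-dimensional diagonal Gaussian latent; decoder mirrors the encoder
# (8 -> 26 -> 38 -> 52) with a logistic output layer so reconstructions stay
# in [0, 1] on the scaled axis. Hidden activations are rectified linear.
# The network is small enough that plain R matrix algebra (BLAS) trains it
# in seconds; gradients are computed by hand-written reverse mode below and
# checked against finite differences in the test suite.

#' VAE configuration
#'
#' @param input_dim Number of input units; fixed at 52 for 24-2 fields.
#' @param hidden_dims Sizes of the encoder hidden layers; the decoder uses
#'   the reverse. Default `c(38, 26)`.
#' @param latent_dim Dimension of the Gaussian latent space, default 8.
#' @param scale_lo,scale_hi dB bounds of the affine map taking TD values to
#'   [0, 1] before the encoder (defaults -38 and 5, the instrument's
#'   practical dynamic range). Values outside the bounds are clipped with a
#'   warning before scaling.
#' @param kl_weight Weight on the Kullback-Leibler term of the loss,
#'   default 1.
#' @param recon_sigma Observation noise SD of the Gaussian reconstruction
#'   likelihood, on the [0, 1] scale (default 0.07, about 3 dB). The
#'   Gaussian reconstruction term is the sum of squared errors divided by
#'   `2 * recon_sigma^2`, i.e. a Gaussian log-likelihood up to a constant,
#'   which keeps it commensurate with the KL term. Ignored for `"bce"`.
#' @param recon_loss `"bce"` (default: binary cross-entropy between the
#'   scaled input and the logistic output) or `"gaussian"`. Cross-entropy
#'   pairs naturally with the logistic output layer and keeps useful
#'   gradients near the ends of the dynamic range, where the Gaussian loss
#'   saturates; with a Gaussian loss, deep defects (scaled values near 0)
#'   are systematically under-reconstructed.
#' @param epochs,batch_size,learning_rate Optimisation hyperparameters
#'   (Adam), defaults 200 / 64 / 1e-3.
#' @param seed Integer seed governing initialisation, minibatch order and
#'   reparameterisation sampling.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(input_dim = 52, hidden_dims = c(38, 26),
                       latent_dim = 8, scale_lo = -38, scale_hi = 5,
                       kl_weight = 1, recon_sigma = 0.07,
                       recon_loss = c("bce", "gaussian"),
                       epochs = 200, batch_size = 64,
                       learning_rate = 1e-3, seed = 1) {
  recon_loss <- match.arg(recon_loss)
  if (input_dim != 52) stop("`input_dim` is fixed at 52 for 24-2 fields")
  if (latent_dim < 1) stop("`latent_dim` must be >= 1")
  if (scale_lo >= scale_hi) stop("need scale_lo < scale_hi")
  if (kl_weight < 0) stop("`kl_weight` must be nonnegative")
  if (recon_sigma <= 0) stop("`recon_sigma` must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 scale_lo = scale_lo, scale_hi = scale_hi,
                 kl_weight = kl_weight, recon_sigma = recon_sigma,
                 recon_loss = recon_loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "vae_config")
}

#' Scale TD values to the unit interval
#'
#' Affine map `(td - scale_lo) / (scale_hi - scale_lo)`. Values outside the
#' bounds are clipped first (with a warning), so the output always lies in
#' [0, 1].
#'
#' @param td Numeric vector or matrix of TD values, dB.
#' @param config A [vae_config()] supplying the bounds.
#' @return Scaled values with the shape of `td`.
#' @export
scale_td <- function(td, config = vae_config()) {
  n_out <- sum(td < config$scale_lo | td > config$scale_hi)
  if (n_out > 0) {
    warning(n_out, " TD value(s) outside [", config$scale_lo, ", ",
            config$scale_hi, "] dB clipped before scaling")
    # pmin/pmax with the data first so matrix dimensions survive
    td <- pmax(pmin(td, config$scale_hi), config$scale_lo)
  }
  (td - config$scale_lo) / (config$scale_hi - config$scale_lo)
}

#' Map scaled values back to dB
#'
#' Inverse of [scale_td()] on [0, 1].
#'
#' @param u Numeric vector or matrix in [0, 1].
#' @param config A [vae_config()].
#' @return TD values in dB.
#' @export
unscale_td <- function(u, config = vae_config()) {
  u * (config$scale_hi - config$scale_lo) + config$scale_lo
}

# ---- parameter container ---------------------------------------------------

.layer_init <- function(n_in, n_out, gain = 2) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(gain / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

#' Initialise VAE parameters
#'
#' He-style initialisation for the rectified-linear hidden layers and
#' Xavier-style for the linear latent and output layers, driven by the
#' config seed.
#'
#' @param config A [vae_config()].
#' @return An object of class `vae_parameters`: encoder hidden layers,
#'   latent mean/log-variance heads, decoder hidden layers, output layer,
#'   the config, and an (initially empty) training history.
#' @export
vae_init <- function(config = vae_config()) {
  set.seed(config$seed)
  dims_enc <- c(config$input_dim, config$hidden_dims)
  enc <- lapply(seq_along(config$hidden_dims), function(l)
    .layer_init(dims_enc[l], dims_enc[l + 1]))
  d_last <- dims_enc[length(dims_enc)]
  mu_head <- .layer_init(d_last, config$latent_dim, gain = 1)
  lv_head <- .layer_init(d_last, config$latent_dim, gain = 1)
  dims_dec <- c(config$latent_dim, rev(config$hidden_dims))
  dec <- lapply(seq_along(config$hidden_dims), function(l)
    .layer_init(dims_dec[l], dims_dec[l + 1]))
  out <- .layer_init(dims_dec[length(dims_dec)], config$input_dim, gain = 1)
  structure(list(enc = enc, mu = mu_head, lv = lv_head, dec = dec,
                 out = out, config = config, history = numeric(0)),
            class = "vae_parameters")
}

.affine <- function(X, layer) sweep(X %*% layer$W, 2, layer$b, "+")

# forward pass on scaled inputs; keeps intermediates when `cache = TRUE`
.vae_forward <- function(X, params, eps = NULL, cache = FALSE) {
  H <- X
  Hs <- list()
  for (l in seq_along(params$enc)) {
    H <- pmax(.affine(H, params$enc[[l]]), 0)
    if (cache) Hs[[l]] <- H
  }
  MU <- .affine(H, params$mu)
  LV <- .affine(H, params$lv)
  if (is.null(eps)) {
    Z <- MU
  } else {
    Z <- MU + exp(0.5 * LV) * eps
  }
  D <- Z
  Ds <- list()
  for (l in seq_along(params$dec)) {
    D <- pmax(.affine(D, params$dec[[l]]), 0)
    if (cache) Ds[[l]] <- D
  }
  Y <- stats::plogis(.affine(D, params$out))
  if (cache) list(Hs = Hs, MU = MU, LV = LV, Z = Z, Ds = Ds, Y = Y)
  else list(MU = MU, LV = LV, Y = Y)
}

.as_input_matrix <- function(x, config) {
  if (inherits(x, "vf_cohort"))
    x <- do.call(rbind, lapply(x, `[[`, "td"))
  if (inherits(x, "vf_series")) x <- x$td
  if (inherits(x, "visual_field")) x <- matrix(x$td, 1)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), 1)
  if (ncol(x) != config$input_dim)
    stop("input must have ", config$input_dim, " TD values per field")
  x
}

#' Encode fields to their latent posterior
#'
#' Deterministic forward pass through the encoder, returning the mean and
#' log-variance of the diagonal Gaussian posterior for each field.
#'
#' @param x TD input in dB: a [visual_field()], [vf_series()],
#'   [vf_cohort()], a 52-vector or an n x 52 matrix.
#' @param params Trained or initialised [vae_init()] parameters.
#' @return A list of class `latent_code` with matrices `mu` and `log_var`
#'   (one row per field).
#' @export
vae_encode <- function(x, params) {
  X <- scale_td(.as_input_matrix(x, params$config), params$config)
  f <- .vae_forward(X, params)
  structure(list(mu = f$MU, log_var = f$LV), class = "latent_code")
}

#' Kullback-Leibler divergence to the standard normal prior
#'
#' Closed form for a diagonal Gaussian posterior:
#' `0.5 * sum(mu^2 + exp(log_var) - log_var - 1)` per field.
#'
#' @param code A `latent_code` from [vae_encode()], or a list with `mu`
#'   and `log_var` vectors/matrices.
#' @return Nonnegative KL divergence, one value per field.
#' @export
kl_divergence <- function(code) {
  mu <- rbind(code$mu)
  lv <- rbind(code$log_var)
  0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
}

#' Reconstruct fields through the VAE
#'
#' Deterministic reconstruction: the decoder is applied to the posterior
#' mean (no latent sampling), and the logistic output is mapped back to dB.
#' Reconstructions therefore always lie within the scaling bounds.
#'
#' @param x Input fields (same types as [vae_encode()]).
#' @param params [vae_init()] / [vae_train()] parameters.
#' @param sample_latent If `TRUE`, decode from one reparameterised sample
#'   instead of the mean (non-deterministic; off by default).
#' @return Reconstructed TD values in dB, with the container type of the
#'   input (`visual_field`, `vf_series` and `vf_cohort` inputs keep their
#'   times and reliability indices).
#' @export
vae_reconstruct <- function(x, params, sample_latent = FALSE) {
  X <- scale_td(.as_input_matrix(x, params$config), params$config)
  eps <- NULL
  if (sample_latent)
    eps <- matrix(stats::rnorm(nrow(X) * params$config$latent_dim),
                  nrow(X))
  f <- .vae_forward(X, params, eps = eps)
  td <- unscale_td(f$Y, params$config)
  if (inherits(x, "vf_cohort")) {
    i <- 0
    return(vf_cohort(lapply(x, function(s) {
      k <- nrow(s$td)
      s$td <- td[i + seq_len(k), , drop = FALSE]
      i <<- i + k
      s
    })))
  }
  if (inherits(x, "vf_series")) {
    x$td <- td
    return(x)
  }
  if (inherits(x, "visual_field")) {
    x$td <- as.numeric(td)
    return(x)
  }
  if (is.matrix(x)) td else as.numeric(td)
}

#' VAE training objective for a batch of fields
#'
#' Per field: reconstruction term (Gaussian: sum of squared errors on the
#' scaled values divided by `2 * recon_sigma^2`; or binary cross-entropy)
#' with one reparameterised latent sample, plus `kl_weight` times the KL
#' divergence of the posterior from the standard normal prior. Returns the
#' batch mean.
#'
#' @param x Input fields (same types as [vae_encode()]).
#' @param params VAE parameters.
#' @param seed Optional seed for the latent sample; with a fixed seed the
#'   loss is reproducible bit-exactly.
#' @return A single nonnegative number.
#' @export
vae_loss <- function(x, params, seed = NULL) {
  X <- scale_td(.as_input_matrix(x, params$config), params$config)
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(X) * params$config$latent_dim), nrow(X))
  f <- .vae_forward(X, params, eps = eps)
  recon <- .recon_term(X, f$Y, params$config)
  kl <- kl_divergence(list(mu = f$MU, log_var = f$LV))
  mean(recon + params$config$kl_weight * kl)
}

.recon_term <- function(X, Y, config) {
  if (config$recon_loss == "gaussian") {
    rowSums((Y - X)^2) / (2 * config$recon_sigma^2)
  } else {
    Yc <- pmin(pmax(Y, 1e-12), 1 - 1e-12)
    -rowSums(X * log(Yc) + (1 - X) * log(1 - Yc))
  }
}

# gradient of the batch-mean loss wrt all parameters (reverse mode)
.vae_backward <- function(X, params, eps) {
  cfg <- params$config
  f <- .vae_forward(X, params, eps = eps, cache = TRUE)
  n <- nrow(X)
  g <- list(enc = vector("list", length(params$enc)),
            dec = vector("list", length(params$dec)))

  if (cfg$recon_loss == "gaussian") {
    dY <- (f$Y - X) / (cfg$recon_sigma^2 * n)
    dA_out <- dY * f$Y * (1 - f$Y)
  } else {
    # d BCE / d logits simplifies to (Y - X)
    dA_out <- (f$Y - X) / n
  }
  D_last <- if (length(params$dec)) f$Ds[[length(f$Ds)]] else f$Z
  g$out <- list(W = crossprod(D_last, dA_out), b = colSums(dA_out))
  dD <- dA_out %*% t(params$out$W)
  for (l in rev(seq_along(params$dec))) {
    dA <- dD * (f$Ds[[l]] > 0)
    below <- if (l == 1) f$Z else f$Ds[[l - 1]]
    g$dec[[l]] <- list(W = crossprod(below, dA), b = colSums(dA))
    dD <- dA %*% t(params$dec[[l]]$W)
  }
  dZ <- dD
  beta <- cfg$kl_weight / n
  dMU <- dZ + beta * f$MU
  dLV <- dZ * 0.5 * exp(0.5 * f$LV) * eps + 0.5 * beta * (exp(f$LV) - 1)
  H_last <- if (length(params$enc)) f$Hs[[length(f$Hs)]] else X
  g$mu <- list(W = crossprod(H_last, dMU), b = colSums(dMU))
  g$lv <- list(W = crossprod(H_last, dLV), b = colSums(dLV))
  dH <- dMU %*% t(params$mu$W) + dLV %*% t(params$lv$W)
  for (l in rev(seq_along(params$enc))) {
    dA <- dH * (f$Hs[[l]] > 0)
    below <- if (l == 1) X else f$Hs[[l - 1]]
    g$enc[[l]] <- list(W = crossprod(below, dA), b = colSums(dA))
    dH <- dA %*% t(params$enc[[l]]$W)
  }
  g
}

# flatten the nested parameter lists for the optimiser
.param_slots <- function(params) {
  slots <- list()
  for (l in seq_along(params$enc))
    slots[[length(slots) + 1]] <- c("enc", l)
  slots[[length(slots) + 1]] <- "mu"
  slots[[length(slots) + 1]] <- "lv"
  for (l in seq_along(params$dec))
    slots[[length(slots) + 1]] <- c("dec", l)
  slots[[length(slots) + 1]] <- "out"
  slots
}

.get_slot <- function(x, slot) if (length(slot) == 2) x[[slot[1]]][[as.integer(slot[2])]] else x[[slot]]

.set_slot <- function(x, slot, value) {
  if (length(slot) == 2) x[[slot[1]]][[as.integer(slot[2])]] <- value
  else x[[slot]] <- value
  x
}

#' Train the VAE on a cohort of fields
#'
#' Minibatch stochastic optimisation (Adam) of the objective in
#' [vae_loss()], with one reparameterised latent sample per field per step.
#' All randomness (initialisation, shuffling, sampling) is governed by the
#' config seed, so a fixed seed reproduces the training run exactly.
#'
#' @param x Training fields: a [vf_cohort()], [vf_series()] or an n x 52
#'   matrix of TD values (dB). A few hundred fields or more are advisable.
#' @param config A [vae_config()].
#' @param verbose Print the epoch losses every 25 epochs.
#' @return Trained `vae_parameters`; `$history` holds the mean training
#'   loss per epoch.
#' @export
vae_train <- function(x, config = vae_config(), verbose = FALSE) {
  params <- vae_init(config)
  X <- scale_td(.as_input_matrix(x, config), config)
  n <- nrow(X)
  if (n < config$batch_size)
    stop("need at least `batch_size` (", config$batch_size, ") fields")
  slots <- .param_slots(params)
  adam <- lapply(slots, function(s) {
    p <- .get_slot(params, s)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; ek <- 1e-8
  step <- 0
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * config$latent_dim),
                    length(idx))
      f <- .vae_forward(Xb, params, eps = eps)
      loss <- mean(.recon_term(Xb, f$Y, config) +
                     config$kl_weight *
                       kl_divergence(list(mu = f$MU, log_var = f$LV)))
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; lower the learning rate or check the inputs")
      epoch_loss <- epoch_loss + loss * length(idx)
      g <- .vae_backward(Xb, params, eps)
      step <- step + 1
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (k in seq_along(slots)) {
        p <- .get_slot(params, slots[[k]])
        gr <- .get_slot(g, slots[[k]])
        a <- adam[[k]]
        a$mW <- b1 * a$mW + (1 - b1) * gr$W
        a$vW <- b2 * a$vW + (1 - b2) * gr$W^2
        a$mb <- b1 * a$mb + (1 - b1) * gr$b
        a$vb <- b2 * a$vb + (1 - b2) * gr$b^2
        p$W <- p$W - config$learning_rate * corr * a$mW / (sqrt(a$vW) + ek)
        p$b <- p$b - config$learning_rate * corr * a$mb / (sqrt(a$vb) + ek)
        adam[[k]] <- a
        params <- .set_slot(params, slots[[k]], p)
      }
    }
    history[epoch] <- epoch_loss / n
    if (verbose && (epoch %% 25 == 0 || epoch == 1))
      message(sprintf("epoch %4d  loss %.4f", epoch, history[epoch]))
  }
  params$history <- history
  params
}

#' Mean total deviation of the VAE reconstruction
#'
#' `compute_mtd(vae_reconstruct(x, params))`: the mean of the 52
#' reconstructed TD values, the denoised analogue of the mTD.
#'
#' @param x A field, series, cohort, vector or matrix (see [vae_encode()]).
#' @param params Trained VAE parameters.
#' @return mTD of the reconstruction(s), dB.
#' @export
mtd_vae <- function(x, params) {
  r <- vae_reconstruct(x, params)
  if (inherits(r, "vf_cohort"))
    return(unlist(lapply(r, compute_mtd), use.names = FALSE))
  compute_mtd(r)
}

#' Save / load VAE parameters
#'
#' Serialisation round trips restore the parameters bit-exactly, including
#' the config and training history.
#'
#' @param params `vae_parameters`.
#' @param path File path.
#' @return `vae_save` returns `path` invisibly; `vae_load` returns the
#'   parameters.
#' @export
vae_save <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) readRDS(path)

#' @export
print.vae_parameters <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vae_parameters> %d-%s-%d latent, %s loss%s\n",
              cfg$input_dim, paste(cfg$hidden_dims, collapse = "-"),
              cfg$latent_dim, cfg$recon_loss,
              if (length(x$history))
                sprintf(", trained %d epochs (final loss %.3f)",
                        length(x$history), x$history[length(x$history)])
              else " (untrained)"))
  invisible(x)
}
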