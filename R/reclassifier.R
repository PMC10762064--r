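#' Bin-reclassifier configuration
#'
#' The network stacks AA-gapped convolution layers (dilations = the
#' integer-discretized masses of the 21 residue tokens, at most 186 bins)
#' with batch normalization, ReLU, optional dropout and per-layer residual
#' skips, followed by two per-bin sigmoid heads (b- and y-ion series).
#'
#' Presets: `"desk"` (4 layers x 8 filters, batch 64, lr 1e-3) trains in
#' minutes on a single CPU; `"paper"` is the full-scale optimum (16 layers
#' x 20 filters, batch 512, lr 4e-5, dropout 0.3).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... Named overrides of any config field (`n_layers`,
#'   `n_filters`, `batch_size`, `lr`, `dropout`, `gamma`, `alpha`,
#'   `max_epochs`, `patience`, `lr_patience`, `max_mz`, `val_frac`).
#' @return List of class `seqmend_reclass_config`.
#' @export
reclass_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(n_layers = 4L, n_filters = 8L, batch_size = 64L, lr = 3e-3,
              dropout = 0, gamma = 2, alpha = NULL, max_epochs = 5L,
              patience = 2L, lr_patience = 2L, max_mz = 2000L,
              val_frac = 0.15)
  if (preset == "paper")
    cfg[c("n_layers", "n_filters", "batch_size", "lr", "dropout",
          "max_epochs")] <- list(16L, 20L, 512L, 4e-5, 0.3, 30L)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "seqmend_reclass_config")
}

#' Dilation set of the AA-gapped convolution
#'
#' Distinct integer residue masses of the 21 tokens; K/Q (128) and
#' F/M(ox) (147) collide, leaving 18 values with maximum 186 (tryptophan).
#'
#' @return Sorted integer vector.
#' @export
gapped_dilations <- function() sort(unique(as.integer(aa_bins())))

#' Initialize an untrained bin-reclassifier model
#'
#' @param config A [reclass_config()].
#' @return Object of class `seqmend_reclassifier` (untrained; train with
#'   [train_reclassifier()]).
#' @export
init_reclassifier <- function(config = reclass_config()) {
  dil <- gapped_dilations()
  if (config$max_mz < 2L * max(dil))
    stop("max_mz must be at least twice the largest dilation (", 2L * max(dil), ")")
  Fch <- config$n_filters
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    c_in <- if (l == 1L) 4L else Fch
    layers[[l]] <- .gconv_init(c_in, Fch, dil)
  }
  head <- list(W = matrix(stats::rnorm(2L * Fch, sd = sqrt(1 / Fch)), 2L, Fch),
               b = numeric(2L))
  run <- lapply(seq_len(config$n_layers), function(l)
    list(mean = numeric(Fch), var = rep(1, Fch)))
  structure(list(config = config, dil = dil,
                 params = list(layers = layers, head = head),
                 run = run, history = NULL, trained = FALSE),
            class = "seqmend_reclassifier")
}

#' @export
print.seqmend_reclassifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<bin reclassifier: %d AA-gapped conv layers x %d ",
                     "filters, %d bins, %s>\n"),
              cfg$n_layers, cfg$n_filters, cfg$max_mz,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' Apply one AA-gapped convolution layer
#'
#' Functional single-layer entry point (no normalization or activation):
#' output bin `i` aggregates, for every dilation `m`, weighted inputs at
#' bins `i - m`, `i` and `i + m`, zero-padded so the length dimension is
#' preserved.
#'
#' @param x Numeric matrix (channels x bins), `bins >= 2 * max(dilations)`.
#' @param params Layer parameters as produced by the internal initializer:
#'   list with `W0` (c_out x c_in), `Wd` (list per dilation of
#'   c_out x 2 c_in, back-tap columns first) and `b`. If `NULL`, an
#'   all-ones, zero-bias single-output-channel layer is used.
#' @param dilations Integer dilation set (default [gapped_dilations()]).
#' @return Numeric matrix (c_out x bins).
#' @export
gapped_conv_layer <- function(x, params = NULL, dilations = gapped_dilations()) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  B <- ncol(x)
  if (B < 2L * max(dilations))
    stop("need at least ", 2L * max(dilations), " bins")
  C <- nrow(x)
  if (is.null(params))
    params <- list(W0 = matrix(1, 1L, C),
                   Wd = lapply(dilations, function(m) matrix(1, 1L, 2L * C)),
                   b = 0)
  .gconv_forward(x, params, dilations, 1L)
}

# full forward pass; x2: (4 x N*B), sample-fastest column order. Returns
# probabilities and, when training = TRUE, the caches needed for backprop.
.reclass_forward <- function(model, x2, N, training = FALSE,
                             keep_cache = FALSE) {
  cfg <- model$config
  H <- x2
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    par <- model$params$layers[[l]]
    Y <- .gconv_forward(H, par, model$dil, N)
    bn <- .bn_forward(Y, par, training, model$run[[l]])
    if (training) model$run[[l]] <- bn$run
    act <- bn$out
    mask <- act > 0
    act[!mask] <- 0
    drop_mask <- NULL
    if (training && cfg$dropout > 0) {
      drop_mask <- matrix(stats::runif(length(act)) >= cfg$dropout,
                          nrow(act), ncol(act)) / (1 - cfg$dropout)
      act <- act * drop_mask
    }
    skip <- l > 1L  # channel counts match from layer 2 on
    out <- if (skip) act + H else act
    if (keep_cache)
      caches[[l]] <- list(X2 = H, bn = bn, relu_mask = mask,
                          drop_mask = drop_mask, skip = skip)
    H <- out
  }
  logits <- model$params$head$W %*% H + model$params$head$b
  p <- 1 / (1 + exp(-logits))
  list(p = p, H = H, caches = caches, model = model)
}

# backward pass; returns gradient tree matching model$params
.reclass_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  gHead <- list(W = tcrossprod(dlogits, fwd$H), b = rowSums(dlogits))
  dH <- crossprod(model$params$head$W, dlogits)
  gLayers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    cc <- fwd$caches[[l]]
    dact <- dH
    if (!is.null(cc$drop_mask)) dact <- dact * cc$drop_mask
    dact <- dact * cc$relu_mask
    par <- model$params$layers[[l]]
    bnb <- .bn_backward(dact, cc$bn, par)
    cvb <- .gconv_backward(bnb$dX, cc$X2, par, model$dil,
                           ncol(cc$X2) / cfg$max_mz)
    g <- cvb$grad
    g$bn_gamma <- bnb$bn_gamma
    g$bn_beta <- bnb$bn_beta
    gLayers[[l]] <- g
    dH <- cvb$dX2 + if (cc$skip) dH else 0
  }
  list(layers = gLayers, head = gHead)
}

#' Build the 4-channel reclassifier input for one candidate PSM
#'
#' Channels: (1) binned base-peak-normalized experimental intensities,
#' (2) binned predicted intensities for the candidate peptide, (3)/(4)
#' the candidate's binary b-/y-ion bin labels.
#'
#' @param spec A `seqmend_spectrum`.
#' @param candidate Candidate peptide (string or tokens).
#' @param predictor Spectrum predictor function (default the surrogate).
#' @param max_mz Number of 1-Da bins.
#' @return Numeric matrix (4 x max_mz).
#' @export
make_reclass_input <- function(spec, candidate,
                               predictor = get_predictor("surrogate"),
                               max_mz = 2000) {
  s <- base_peak_normalize(spec)
  ions <- predictor(candidate, spec$precursor_charge)
  lab <- label_bins(candidate, max_mz)
  rbind(exp = bin_spectrum(s, max_mz)$bins,
        pred = bin_predicted(ions, max_mz),
        b = lab$b, y = lab$y)
}

#' Predict per-bin b/y ion-series probabilities
#'
#' Deterministic evaluation-mode forward pass (running batch-norm
#' statistics, no dropout); batch-order invariant.
#'
#' @param model A `seqmend_reclassifier`.
#' @param x One input matrix (4 x bins) from [make_reclass_input()], a
#'   list of them, or an array (4 x bins x n).
#' @return For a single input, list with numeric vectors `p_b`, `p_y`;
#'   for a batch, list with matrices (bins x n).
#' @export
predict_bins <- function(model, x) {
  single <- is.matrix(x)
  if (is.list(x)) x <- simplify2array(x)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  B <- model$config$max_mz
  if (dim(x)[1] != 4L || dim(x)[2] != B)
    stop("input must be 4 x ", B, " (x n)")
  N <- dim(x)[3]
  x2 <- .to_sample_fastest(x)
  p <- .reclass_forward(model, x2, N, training = FALSE)$p
  pb <- t(matrix(p[1L, ], N, B))
  py <- t(matrix(p[2L, ], N, B))
  if (single && N == 1L) list(p_b = pb[, 1L], p_y = py[, 1L])
  else list(p_b = pb, p_y = py)
}

#' Per-bin change probabilities
#'
#' Probability that a bin's final label differs from the candidate's
#' initial label: `p` where the initial label is 0 and `1 - p` where it
#' is 1. Flipping an initial label bit flips its change probability.
#'
#' @param p Predicted bin probabilities (vector or matrix).
#' @param initial 0/1 initial labels, same shape.
#' @return Change probabilities, same shape as `p`.
#' @export
change_probs <- function(p, initial) {
  initial * (1 - p) + (1 - initial) * p
}

#' Train the bin reclassifier
#'
#' Adam on binary focal loss summed over the b and y channels, with
#' learning-rate reduction on validation-loss plateau (factor 0.5) and
#' early stopping (best weights restored). True labels come from the
#' ground-truth peptide while the input channels encode the (possibly
#' corrupted) candidate.
#'
#' @param dataset List with `x` (array 4 x bins x n, or list of input
#'   matrices), `yb` and `yy` (bins x n matrices of 0/1 true labels).
#'   Build from simulator output with [build_reclass_dataset()].
#' @param config A [reclass_config()].
#' @param validation Optional dataset of the same shape; if `NULL`, a
#'   `val_frac` tail split of `dataset` is used.
#' @param verbose Print per-epoch losses.
#' @return Trained `seqmend_reclassifier` with a `history` data.frame
#'   (epoch, train_loss, val_loss, lr).
#' @export
train_reclassifier <- function(dataset, config = reclass_config(),
                               validation = NULL, verbose = FALSE) {
  if (is.list(dataset$x) && !is.array(dataset$x))
    dataset$x <- simplify2array(dataset$x)
  n <- dim(dataset$x)[3]
  if (is.null(n) || n < 2L) stop("dataset must hold at least 2 examples")
  if (is.null(validation)) {
    nval <- max(1L, round(config$val_frac * n))
    vidx <- seq.int(n - nval + 1L, n)
    validation <- list(x = dataset$x[, , vidx, drop = FALSE],
                       yb = dataset$yb[, vidx, drop = FALSE],
                       yy = dataset$yy[, vidx, drop = FALSE])
    tidx <- seq_len(n - nval)
    dataset <- list(x = dataset$x[, , tidx, drop = FALSE],
                    yb = dataset$yb[, tidx, drop = FALSE],
                    yy = dataset$yy[, tidx, drop = FALSE])
    n <- length(tidx)
  }
  model <- init_reclassifier(config)
  if (dim(dataset$x)[2] != config$max_mz)
    stop("dataset bin count ", dim(dataset$x)[2],
         " does not match config max_mz ", config$max_mz)
  state <- list(m = .tree_zero(model$params), v = .tree_zero(model$params),
                t = 0L)
  lr <- config$lr
  best <- list(loss = Inf, params = model$params, run = model$run)
  bad_epochs <- 0L; plateau <- 0L
  hist <- NULL
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tr_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
      N <- length(idx)
      x2 <- .to_sample_fastest(dataset$x[, , idx, drop = FALSE])
      targ <- rbind(as.numeric(t(dataset$yb[, idx, drop = FALSE])),
                    as.numeric(t(dataset$yy[, idx, drop = FALSE])))
      fwd <- .reclass_forward(model, x2, N, training = TRUE,
                              keep_cache = TRUE)
      model$run <- fwd$model$run
      loss <- focal_loss(fwd$p, targ, config$gamma, config$alpha)
      tr_loss <- tr_loss + loss * N
      dlogits <- .focal_grad_logits(fwd$p, targ, config$gamma, config$alpha)
      grads <- .reclass_backward(model, fwd, dlogits)
      upd <- .adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    tr_loss <- tr_loss / n
    val_loss <- .reclass_eval_loss(model, validation)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.5f  val %.5f  lr %.2g",
                      epoch, tr_loss, val_loss, lr))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = model$params, run = model$run)
      bad_epochs <- 0L; plateau <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      plateau <- plateau + 1L
      if (plateau >= config$lr_patience) {
        lr <- lr / 2
        plateau <- 0L
      }
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best$params
  model$run <- best$run
  model$history <- hist
  model$trained <- TRUE
  model
}

.reclass_eval_loss <- function(model, ds) {
  N <- dim(ds$x)[3]
  total <- 0
  starts <- seq(1L, N, by = 256L)
  for (s0 in starts) {
    idx <- s0:min(s0 + 255L, N)
    x2 <- .to_sample_fastest(ds$x[, , idx, drop = FALSE])
    targ <- rbind(as.numeric(t(ds$yb[, idx, drop = FALSE])),
                  as.numeric(t(ds$yy[, idx, drop = FALSE])))
    p <- .reclass_forward(model, x2, length(idx), training = FALSE)$p
    total <- total + length(idx) *
      focal_loss(p, targ, model$config$gamma, model$config$alpha)
  }
  total / N
}
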