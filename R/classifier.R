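#' Configuration for the depth classifiers
#'
#' Collects the hyperparameters of both classifiers: the NRMS threshold
#' rule and the attention-based sequence encoder.  `context_k` is the
#' half-width of the bidirectional depth context: classification at depth i
#' may use depths i-k ... i+k (both past and future depths are available;
#' there is no causality constraint).  Track ends are padded with the
#' baseline NRMS value 1.0, representing outside-STN background.
#'
#' The encoder itself is deliberately small (one embedding layer, two
#' attention-pooling heads, width `embed_dim`) so it trains on a CPU in
#' seconds with analytically derived gradients; these sizes are package
#' defaults, not values from any clinical system.
#'
#' @param context_k non-negative integer context half-width (depths per
#'   side; default 5, i.e. 2.5 mm of context each way).
#' @param embed_dim embedding width (default 16).
#' @param n_heads number of attention-pooling heads (default 2).
#' @param tau NRMS threshold of the baseline classifier (default 1.5).
#' @param epochs full-batch training epochs (default 300).
#' @param learning_rate Adam step size (default 0.05).
#' @param seed RNG seed recorded in every trained model.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(context_k = 5L, embed_dim = 16L, n_heads = 2L,
                              tau = 1.5, epochs = 300L, learning_rate = 0.05,
                              seed = 1L) {
  stopifnot(context_k >= 0, embed_dim >= 2, n_heads >= 1, tau > 0,
            epochs >= 1, learning_rate > 0)
  structure(list(context_k = as.integer(context_k),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 tau = tau, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Per-depth STN labels for one trajectory
#'
#' @param trajectory_id channel label.
#' @param depth ordered depths (mm).
#' @param label 0/1 per depth (1 = STN).
#' @param probability optional per-depth probability in `[0, 1]`, consistent
#'   with `label` at the 0.5 cutoff.
#' @return An object of class `depth_labels`.
#' @export
depth_labels <- function(trajectory_id, depth, label, probability = NULL) {
  depth <- as.numeric(depth)
  label <- as.integer(label)
  if (length(depth) != length(label)) stop("depth and label lengths differ")
  if (length(label) == 0L) stop("empty label sequence")
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (!is.null(probability)) {
    probability <- as.numeric(probability)
    if (length(probability) != length(label)) stop("probability length mismatch")
    if (any(probability < 0 | probability > 1)) stop("probabilities must be in [0,1]")
    if (any((probability >= 0.5) != (label == 1L))) {
      stop("probabilities inconsistent with labels at the 0.5 cutoff")
    }
  }
  structure(list(trajectory_id = trajectory_id, depth = depth,
                 label = label, probability = probability),
            class = "depth_labels")
}

#' Threshold baseline classifier
#'
#' Labels a depth STN when its NRMS is at least `tau`.  Serves as the
#' reference against which the sequence encoder is compared, and as the
#' fallback when no trained model is supplied.
#'
#' @param nrms an [nrms_sequence()].
#' @param tau positive threshold (default 1.5).
#' @return A [depth_labels()] object (no probabilities).
#' @export
classify_threshold <- function(nrms, tau = 1.5) {
  stopifnot(inherits(nrms, "nrms_sequence"), tau > 0)
  depth_labels(nrms$trajectory_id, nrms$depth,
               as.integer(nrms$nrms >= tau))
}

# ---- attention encoder internals ------------------------------------------

# fixed sinusoidal positional encoding over window offsets -k..k (L x 4)
positional_encoding <- function(L) {
  rel <- seq_len(L) - (L + 1) / 2
  cbind(sin(rel / 2), cos(rel / 2), sin(rel / 8), cos(rel / 8))
}

# slide a length-L window over each sequence, padding with baseline 1.0
build_windows <- function(seqs, k) {
  L <- 2L * k + 1L
  rows <- lapply(seqs, function(x) {
    n <- length(x)
    padded <- c(rep(1.0, k), x, rep(1.0, k))
    idx <- outer(seq_len(n), 0:(L - 1L), "+")
    matrix(padded[idx], n, L)
  })
  do.call(rbind, rows)
}

init_params <- function(cfg) {
  d <- cfg$embed_dim
  # small deterministic-given-seed init
  list(w_in = rnorm(d, sd = 0.5),
       W_pos = matrix(rnorm(4 * d, sd = 0.2), 4, d),
       b1 = rep(0, d),
       U = lapply(seq_len(cfg$n_heads), function(i) rnorm(d, sd = 0.3)),
       w_out = rnorm((cfg$n_heads + 1L) * d, sd = 0.1),
       b_out = 0)
}

# forward pass over a window matrix X (N x L); returns probabilities and,
# when `keep` is TRUE, the intermediates needed for backprop
encoder_forward <- function(params, X, keep = FALSE) {
  N <- nrow(X)
  L <- ncol(X)
  d <- length(params$w_in)
  nh <- length(params$U)
  cen <- (L + 1L) %/% 2L
  penc <- positional_encoding(L)
  B <- penc %*% params$W_pos + matrix(params$b1, L, d, byrow = TRUE)  # L x d
  # row m of H corresponds to (sample n, window slot j): m = (j-1)*N + n
  Hpre <- outer(as.vector(X), params$w_in) + B[rep(seq_len(L), each = N), ]
  H <- tanh(Hpre)
  A <- vector("list", nh)
  Ctx <- vector("list", nh)
  for (h in seq_len(nh)) {
    s <- matrix(H %*% params$U[[h]], N, L)
    s <- s - apply(s, 1, max)
    a <- exp(s)
    a <- a / rowSums(a)
    C <- matrix(0, N, d)
    for (j in seq_len(L)) C <- C + a[, j] * H[(j - 1L) * N + seq_len(N), , drop = FALSE]
    A[[h]] <- a
    Ctx[[h]] <- C
  }
  Hc <- H[(cen - 1L) * N + seq_len(N), , drop = FALSE]
  feat <- cbind(do.call(cbind, Ctx), Hc)
  logit <- as.numeric(feat %*% params$w_out) + params$b_out
  p <- plogis(logit)
  if (!keep) return(list(p = p))
  list(p = p, H = H, A = A, Ctx = Ctx, Hc = Hc, feat = feat,
       X = X, penc = penc, N = N, L = L, d = d, nh = nh, cen = cen)
}

encoder_backward <- function(params, fw, y) {
  N <- fw$N; L <- fw$L; d <- fw$d; nh <- fw$nh; cen <- fw$cen
  H <- fw$H
  g <- (fw$p - y) / N                       # d loss / d logit
  grads <- list(w_out = as.numeric(crossprod(fw$feat, g)),
                b_out = sum(g))
  dfeat <- outer(g, params$w_out)           # N x (nh+1)d
  dH <- matrix(0, N * L, d)
  idx_c <- (cen - 1L) * N + seq_len(N)
  dH[idx_c, ] <- dH[idx_c, ] + dfeat[, nh * d + seq_len(d), drop = FALSE]
  grads$U <- vector("list", nh)
  for (h in seq_len(nh)) {
    dC <- dfeat[, (h - 1L) * d + seq_len(d), drop = FALSE]  # N x d
    a <- fw$A[[h]]
    da <- matrix(0, N, L)
    for (j in seq_len(L)) {
      Hj <- H[(j - 1L) * N + seq_len(N), , drop = FALSE]
      da[, j] <- rowSums(dC * Hj)
      dH[(j - 1L) * N + seq_len(N), ] <-
        dH[(j - 1L) * N + seq_len(N), ] + a[, j] * dC
    }
    ds <- a * (da - rowSums(a * da))        # softmax Jacobian
    dsv <- as.vector(ds)                    # matches H row ordering
    grads$U[[h]] <- as.numeric(crossprod(H, dsv))
    dH <- dH + outer(dsv, params$U[[h]])
  }
  dHpre <- dH * (1 - H^2)
  grads$w_in <- as.numeric(crossprod(dHpre, as.vector(fw$X)))
  dB <- matrix(0, L, d)
  for (j in seq_len(L)) {
    dB[j, ] <- colSums(dHpre[(j - 1L) * N + seq_len(N), , drop = FALSE])
  }
  grads$W_pos <- crossprod(fw$penc, dB)
  grads$b1 <- colSums(dB)
  grads
}

flatten_params <- function(p) {
  c(p$w_in, as.vector(p$W_pos), p$b1, unlist(p$U), p$w_out, p$b_out)
}

unflatten_params <- function(v, cfg) {
  d <- cfg$embed_dim; nh <- cfg$n_heads
  i <- 0L
  take <- function(n) { out <- v[i + seq_len(n)]; i <<- i + n; out }
  list(w_in = take(d),
       W_pos = matrix(take(4L * d), 4, d),
       b1 = take(d),
       U = lapply(seq_len(nh), function(h) take(d)),
       w_out = take((nh + 1L) * d),
       b_out = take(1L))
}

#' Train the attention-based depth-sequence classifier
#'
#' Trains a small attention encoder on NRMS sequences with per-depth STN
#' labels, minimising unweighted cross-entropy with full-batch Adam.  The
#' run is a pure function of the dataset and the seed in `config`: two runs
#' with the same inputs produce identical models.
#'
#' @param dataset list of training tracks, each a list with elements `nrms`
#'   (an [nrms_sequence()]) and `labels` (a [depth_labels()] of equal
#'   length).
#' @param config a [classifier_config()].
#' @return An object of class `sequence_classifier`: trained parameters,
#'   the config (seed included), the per-epoch loss trace and its running
#'   minimum `best_trace` (non-increasing by construction).
#' @export
train_sequence_classifier <- function(dataset, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(dataset) == 0L) stop("empty training dataset")
  seqs <- lapply(dataset, function(tr) {
    stopifnot(inherits(tr$nrms, "nrms_sequence"), inherits(tr$labels, "depth_labels"))
    if (length(tr$nrms$nrms) != length(tr$labels$label)) {
      stop("nrms and labels lengths differ within a training track")
    }
    tr$nrms$nrms
  })
  y <- unlist(lapply(dataset, function(tr) tr$labels$label))
  if (length(unique(y)) < 2L) {
    stop("training dataset contains a single class; need both STN and non-STN depths")
  }
  X <- build_windows(seqs, config$context_k)

  params <- with_seed(config$seed, init_params(config))
  theta <- flatten_params(params)
  m1 <- numeric(length(theta))
  m2 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(config$epochs)
  for (t in seq_len(config$epochs)) {
    params <- unflatten_params(theta, config)
    fw <- encoder_forward(params, X, keep = TRUE)
    pc <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    if (!is.finite(loss)) {
      stop(sprintf("training diverged: non-finite loss at epoch %d (lr = %g)",
                   t, config$learning_rate))
    }
    trace[t] <- loss
    g <- flatten_params(encoder_backward(params, fw, y))
    m1 <- b1 * m1 + (1 - b1) * g
    m2 <- b2 * m2 + (1 - b2) * g^2
    mh <- m1 / (1 - b1^t)
    vh <- m2 / (1 - b2^t)
    theta <- theta - config$learning_rate * mh / (sqrt(vh) + eps)
  }
  structure(list(params = unflatten_params(theta, config),
                 config = config,
                 loss_trace = trace,
                 best_trace = cummin(trace)),
            class = "sequence_classifier")
}

#' @export
print.sequence_classifier <- function(x, ...) {
  cat(sprintf("sequence_classifier: k = %d, width %d, %d heads; final loss %.4g (seed %d)\n",
              x$config$context_k, x$config$embed_dim, x$config$n_heads,
              x$loss_trace[length(x$loss_trace)], x$config$seed))
  invisible(x)
}

#' Classify an NRMS sequence with a trained encoder
#'
#' Returns one label and probability per depth; the prediction at depth i
#' attends over depths i-k ... i+k, with track ends padded by the baseline
#' value 1.0 so output length always equals input length (a single-depth
#' track is valid).
#'
#' @param model a trained [train_sequence_classifier()] model.
#' @param nrms an [nrms_sequence()].
#' @return A [depth_labels()] with probabilities.
#' @export
classify_sequence <- function(model, nrms) {
  stopifnot(inherits(model, "sequence_classifier"), inherits(nrms, "nrms_sequence"))
  X <- build_windows(list(nrms$nrms), model$config$context_k)
  p <- encoder_forward(model$params, X)$p
  depth_labels(nrms$trajectory_id, nrms$depth,
               as.integer(p >= 0.5), probability = p)
}

#' Accuracy, sensitivity and specificity of depth predictions
#'
#' Pools all depths of the aligned collections into one confusion matrix.
#' Sensitivity is the fraction of true STN depths detected; specificity the
#' analogous fraction for non-STN depths (`NA` when a class is absent).
#'
#' @param predicted a [depth_labels()] or list of them.
#' @param truth matching [depth_labels()] or list, same lengths.
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   2 x 2 `confusion` table (rows = truth, cols = predicted).
#' @export
evaluate_classifier <- function(predicted, truth) {
  as_list <- function(x) if (inherits(x, "depth_labels")) list(x) else x
  predicted <- as_list(predicted)
  truth <- as_list(truth)
  if (length(predicted) != length(truth)) stop("collection lengths differ")
  p <- unlist(lapply(predicted, function(d) d$label))
  y <- unlist(lapply(truth, function(d) d$label))
  if (length(p) != length(y)) stop("total depth counts differ between predictions and truth")
  tp <- sum(p == 1 & y == 1); tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0); fn <- sum(p == 0 & y == 1)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                          dimnames = list(truth = c("0", "1"),
                                          predicted = c("0", "1"))))
}

#' Save / load a trained sequence classifier
#'
#' JSON checkpoint embedding the parameters, the full config and the seed,
#' sufficient to reproduce predictions exactly.
#'
#' @param model a `sequence_classifier`.
#' @param path output `.json` path.
#' @return `path` (write) or the restored model (read).
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "sequence_classifier"))
  obj <- list(config = unclass(model$config),
              theta = flatten_params(model$params),
              loss_trace = model$loss_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, as.list(obj$config))
  structure(list(params = unflatten_params(as.numeric(obj$theta), cfg),
                 config = cfg,
                 loss_trace = as.numeric(obj$loss_trace),
                 best_trace = cummin(as.numeric(obj$loss_trace))),
            class = "sequence_classifier")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
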