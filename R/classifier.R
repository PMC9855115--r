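## Small 1-D convolutional network for FECG segment classification:
## [conv -> ReLU -> max-pool] x 2 -> dense ReLU -> softmax, trained with
## Adam on (weighted) cross-entropy. Implemented with im2col + BLAS matrix
## products; batches are ordered sample-major, position-minor throughout.

#' CNN configuration
#'
#' Two convolution blocks (1-D convolution, ReLU, max-pool) followed by a
#' dense ReLU layer and a softmax output; binary cross-entropy (two
#' classes) or categorical cross-entropy (three classes), Adam optimizer
#' with learning rate 3e-4. Input segments are 1500 samples (3 s at
#' 500 Hz).
#'
#' @param n_classes 2 (normal/arrhythmia) or 3 (+moderate).
#' @param filters Integer pair: filters of the two conv blocks.
#' @param kernel Convolution kernel length, samples.
#' @param stride Stride of the first convolution, samples.
#' @param pool Max-pool width.
#' @param dense Dense layer width.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch Mini-batch size.
#' @param input_len Segment length in samples.
#' @param seed Integer seed for initialization and shuffling.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(n_classes = 2L, filters = c(8L, 16L), kernel = 15L,
                       stride = 1L, pool = 6L, dense = 32L, lr = 3e-4,
                       epochs = 12L, batch = 128L, input_len = 1500L,
                       seed = 1L) {
  stopifnot(n_classes %in% c(2L, 3L), length(filters) == 2L)
  structure(list(n_classes = as.integer(n_classes),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 pool = as.integer(pool), dense = as.integer(dense),
                 lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), input_len = as.integer(input_len),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Assemble a training set from labeled segments
#'
#' In binary mode moderate segments are dropped (they may belong to either
#' class and would blur the decision boundary); ternary mode keeps all
#' three labels. Every segment is z-score normalized (per-segment mean 0,
#' SD 1; constant segments become all zeros) so that electrode-dependent
#' amplitude cannot act as a class cue. Inverse-frequency class weights are
#' attached for the loss.
#'
#' @param set A `segment_set`.
#' @param labels Factor of normal/moderate/arrhythmia labels.
#' @param mode `"binary"` or `"ternary"`.
#' @return List with `X` (matrix), `y` (integer class index), `levels`
#'   (class names) and `class_weights`.
#' @export
build_training_set <- function(set, labels, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "segment_set"),
            length(labels) == nrow(set$samples))
  labels <- as.character(labels)
  if (mode == "binary") {
    keep <- labels != "moderate"
    lv <- c("normal", "arrhythmia")
  } else {
    keep <- rep(TRUE, length(labels))
    lv <- c("normal", "moderate", "arrhythmia")
  }
  X <- zscore_rows(set$samples[keep, , drop = FALSE])
  y <- match(labels[keep], lv)
  counts <- tabulate(y, nbins = length(lv))
  if (any(counts == 0L))
    stop("retained class with zero segments: ",
         paste(lv[counts == 0L], collapse = ","), call. = FALSE)
  w <- sum(counts) / (length(lv) * counts)
  list(X = X, y = y, levels = lv, class_weights = w)
}

#' Z-score normalize matrix rows
#'
#' @param X Numeric matrix.
#' @return Matrix with per-row mean 0 and SD 1 (constant rows become 0).
#' @export
zscore_rows <- function(X) {
  m <- rowMeans(X)
  s <- sqrt(rowMeans((X - m)^2))
  s[s == 0] <- Inf                       # constant rows -> all zeros
  (X - m) / s
}

## ---- layer primitives ------------------------------------------------

im2col1_ <- function(X, K, stride) cpp_im2col_rows(X, K, stride)

im2colC_ <- function(A, n, L, K) cpp_im2col(A, n, L, K)

col2im_add_ <- function(dXcol, n, L, K, C) cpp_col2im(dXcol, n, L, K, C)

pool_fwd_ <- function(A, n, L, p) cpp_pool_fwd(A, n, L, p)

pool_bwd_ <- function(dM, amax, n, L, p) cpp_pool_bwd(dM, amax, n, L, p)

flatten_ <- function(M, n, P) {          # (n*P) x C -> n x (C*P)
  C <- ncol(M)
  out <- matrix(0, n, C * P)
  for (c in seq_len(C))
    out[, ((c - 1L) * P + 1L):(c * P)] <- t(matrix(M[, c], nrow = P))
  out
}

unflatten_ <- function(dF, n, P, C) {
  dM <- matrix(0, n * P, C)
  for (c in seq_len(C))
    dM[, c] <- as.vector(t(dF[, ((c - 1L) * P + 1L):(c * P), drop = FALSE]))
  dM
}

init_params_ <- function(cfg) {
  K <- cfg$kernel; F1 <- cfg$filters[1]; F2 <- cfg$filters[2]
  L1 <- (cfg$input_len - K) %/% cfg$stride + 1L
  P1 <- L1 %/% cfg$pool
  L2 <- P1 - K + 1L
  P2 <- L2 %/% cfg$pool
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)),
                                     nr, nc)
  list(W1 = he(K, F1, K), b1 = numeric(F1),
       W2 = he(K * F1, F2, K * F1), b2 = numeric(F2),
       W3 = he(P2 * F2, cfg$dense, P2 * F2), b3 = numeric(cfg$dense),
       W4 = he(cfg$dense, cfg$n_classes, cfg$dense),
       b4 = numeric(cfg$n_classes))
}

forward_ <- function(par, cfg, X, keep = FALSE) {
  n <- nrow(X)
  K <- cfg$kernel; p <- cfg$pool
  L0 <- cfg$input_len
  Xc1 <- im2col1_(X, K, cfg$stride)
  A1 <- cpp_bias_relu(Xc1 %*% par$W1, par$b1)
  L1 <- (L0 - K) %/% cfg$stride + 1L
  pl1 <- pool_fwd_(A1, n, L1, p)
  Xc2 <- im2colC_(pl1$M, n, pl1$P, K)
  A2 <- cpp_bias_relu(Xc2 %*% par$W2, par$b2)
  L2 <- pl1$P - K + 1L
  pl2 <- pool_fwd_(A2, n, L2, p)
  Fl <- flatten_(pl2$M, n, pl2$P)
  H <- cpp_bias_relu(Fl %*% par$W3, par$b3)
  S <- sweep(H %*% par$W4, 2L, par$b4, `+`)
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  Pr <- E / rowSums(E)
  out <- list(prob = Pr)
  if (keep)
    out <- c(out, list(Xc1 = Xc1, A1 = A1, pl1 = pl1, Xc2 = Xc2, A2 = A2,
                       pl2 = pl2, Fl = Fl, H = H,
                       L1 = L1, L2 = L2, n = n))
  out
}

backward_ <- function(par, cfg, fw, y, w) {
  n <- fw$n
  sw <- w[y]
  dS <- fw$prob
  dS[cbind(seq_len(n), y)] <- dS[cbind(seq_len(n), y)] - 1
  dS <- dS * (sw / sum(sw))
  g <- list()
  g$W4 <- crossprod(fw$H, dS); g$b4 <- colSums(dS)
  dH <- dS %*% t(par$W4)
  dZ3 <- dH * (fw$H > 0)
  g$W3 <- crossprod(fw$Fl, dZ3); g$b3 <- colSums(dZ3)
  dFl <- dZ3 %*% t(par$W3)
  dM2 <- unflatten_(dFl, n, fw$pl2$P, cfg$filters[2])
  dA2 <- pool_bwd_(dM2, fw$pl2$amax, n, fw$L2, cfg$pool)
  dZ2 <- dA2 * (fw$A2 > 0)
  g$W2 <- crossprod(fw$Xc2, dZ2); g$b2 <- colSums(dZ2)
  dXc2 <- dZ2 %*% t(par$W2)
  dM1 <- col2im_add_(dXc2, n, fw$pl1$P, cfg$kernel, cfg$filters[1])
  dA1 <- pool_bwd_(dM1, fw$pl1$amax, n, fw$L1, cfg$pool)
  dZ1 <- dA1 * (fw$A1 > 0)
  g$W1 <- crossprod(fw$Xc1, dZ1); g$b1 <- colSums(dZ1)
  g
}

#' Train the segment CNN
#'
#' Mini-batch Adam on weighted softmax cross-entropy. Deterministic given
#' `config$seed`. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param config A [cnn_config()].
#' @param X Matrix of z-scored segments, `input_len` columns.
#' @param y Integer class indices (1-based).
#' @param levels Class names matching the indices.
#' @param class_weights Per-class loss weights (default: uniform).
#' @return A `cnn_model`: parameters, config, class levels and a per-epoch
#'   `log` data frame (loss, accuracy).
#' @export
train_cnn <- function(config, X, y, levels = NULL, class_weights = NULL) {
  stopifnot(inherits(config, "cnn_config"), is.matrix(X),
            ncol(X) == config$input_len, length(y) == nrow(X))
  if (length(unique(y)) < 2L)
    stop("training targets contain a single class", call. = FALSE)
  if (max(y) > config$n_classes)
    stop("more classes in y than config$n_classes", call. = FALSE)
  if (is.null(class_weights)) class_weights <- rep(1, config$n_classes)
  if (is.null(levels)) levels <- paste0("class", seq_len(config$n_classes))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  par <- init_params_(config)
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0; tot_w <- 0
    for (b0 in seq(1L, n, by = config$batch)) {
      idx <- ord[b0:min(b0 + config$batch - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- forward_(par, config, Xb, keep = TRUE)
      pr <- pmax(fw$prob[cbind(seq_along(yb), yb)], 1e-12)
      wb <- class_weights[yb]
      loss <- -sum(wb * log(pr)) / sum(wb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      tot_loss <- tot_loss + loss * sum(wb)
      tot_w <- tot_w + sum(wb)
      tot_correct <- tot_correct + sum(max.col(fw$prob) == yb)
      g <- backward_(par, config, fw, yb, class_weights)
      step <- step + 1L
      for (nm in names(par)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / tot_w,
                                 accuracy = tot_correct / n))
  }
  structure(list(par = par, config = config, levels = levels,
                 class_weights = class_weights, log = log),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d classes (%s), filters %s, kernel %d\n",
              x$config$n_classes, paste(x$levels, collapse = "/"),
              paste(x$config$filters, collapse = "/"), x$config$kernel))
  if (nrow(x$log))
    cat(sprintf("  final epoch: loss %.4f, accuracy %.3f\n",
                utils::tail(x$log$loss, 1), utils::tail(x$log$accuracy, 1)))
  invisible(x)
}

#' Classify segments with a trained CNN
#'
#' Segments are z-scored exactly as in training. Returns per-class softmax
#' scores (rows sum to 1) and the argmax class.
#'
#' @param model A `cnn_model`.
#' @param segments A `segment_set` or a numeric matrix of raw segments.
#' @param batch Prediction batch size.
#' @return Data frame with `predicted` (factor over the model's levels)
#'   and one `score_<level>` column per class; `subject_id`/`start_ms`
#'   are carried over when a `segment_set` is supplied.
#' @export
predict_cnn <- function(model, segments, batch = 256L) {
  stopifnot(inherits(model, "cnn_model"))
  meta <- NULL
  if (inherits(segments, "segment_set")) {
    meta <- segments$meta
    segments <- segments$samples
  }
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 1L)
  if (ncol(segments) != model$config$input_len)
    stop("segments must have ", model$config$input_len, " samples",
         call. = FALSE)
  X <- zscore_rows(segments)
  n <- nrow(X)
  prob <- matrix(0, n, model$config$n_classes)
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    prob[idx, ] <- forward_(model$par, model$config,
                            X[idx, , drop = FALSE])$prob
  }
  out <- data.frame(predicted = factor(model$levels[max.col(prob)],
                                       levels = model$levels))
  colnames(prob) <- paste0("score_", model$levels)
  out <- cbind(out, as.data.frame(prob))
  if (!is.null(meta))
    out <- cbind(meta[, c("subject_id", "start_ms")], out)
  out
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS of the parameter list next to a JSON copy of
#' the config; the training log goes to CSV.
#'
#' @param model A `cnn_model`.
#' @param base Path prefix; writes `<base>.rds`, `<base>_config.json`,
#'   `<base>_log.csv`.
#' @return Invisibly, `base`.
#' @export
save_cnn <- function(model, base) {
  saveRDS(model, paste0(base, ".rds"))
  jsonlite::write_json(unclass(model$config), paste0(base, "_config.json"),
                       auto_unbox = TRUE)
  utils::write.csv(model$log, paste0(base, "_log.csv"), row.names = FALSE)
  invisible(base)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(base) readRDS(paste0(base, ".rds"))
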