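# Concurrent-speaker count estimation for 5-s windows.
#
# The model follows the x-vector recipe at desk scale: three frame-level
# layers with spliced (time-dilated) context, statistics pooling (per-
# dimension mean and standard deviation over frames), a 128-d linear
# embedding layer, and a 4-class softmax head over the count classes
# C0/C1/C2/C3. Scoring is done either by cosine distance to per-class
# centroid embeddings (the default backend) or directly by the softmax
# head. Everything is plain R matrix algebra; training is Adam on the
# cross-entropy loss, fully seeded.

COUNT_CLASSES <- c("C0", "C1", "C2", "C3")

#' Default configuration of the counting model
#'
#' @param n_mels Mel bands expected from the front end.
#' @param embed_dim Embedding dimension.
#' @param hidden_dim Width of the frame-level layers.
#' @param frame_subsample Keep every k-th frame (2 halves the compute with
#'   little information loss at a 10 ms hop).
#' @param epochs,batch_size,lr,lr_decay Adam training schedule; the
#'   learning rate is multiplied by `lr_decay` after every epoch.
#' @param backend `"centroid"` (cosine distance to class centroids) or
#'   `"softmax"` (argmax of the classification head).
#' @return Named list of configuration values.
#' @export
counter_config <- function(n_mels = 40, embed_dim = 128, hidden_dim = 96,
                           frame_subsample = 2, epochs = 20, batch_size = 16,
                           lr = 1e-3, lr_decay = 0.9, backend = "centroid") {
  list(n_mels = n_mels, embed_dim = embed_dim, hidden_dim = hidden_dim,
       frame_subsample = frame_subsample, epochs = epochs,
       batch_size = batch_size, lr = lr, lr_decay = lr_decay,
       backend = match.arg(backend, c("centroid", "softmax")),
       contexts = list(-2:2, c(-2L, 0L, 2L), c(-3L, 0L, 3L)))
}

# --- network plumbing -------------------------------------------------------

splice_frames <- function(X, offsets) {
  T_ <- nrow(X)
  idx <- lapply(offsets, function(o) pmin(pmax(seq_len(T_) + o, 1L), T_))
  do.call(cbind, lapply(idx, function(i) X[i, , drop = FALSE]))
}

splice_backward <- function(dS, offsets, d, T_) {
  dX <- matrix(0, T_, d)
  for (k in seq_along(offsets)) {
    block <- dS[, ((k - 1) * d + 1):(k * d), drop = FALSE]
    idx <- pmin(pmax(seq_len(T_) + offsets[[k]], 1L), T_)
    acc <- rowsum(block, idx)
    rows <- as.integer(rownames(acc))
    dX[rows, ] <- dX[rows, ] + acc
  }
  dX
}

init_counter_weights <- function(in_dim, config, seed) {
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  h <- config$hidden_dim
  with_seed(seed, {
    list(
      W1 = he(in_dim * 5, h), b1 = numeric(h),
      W2 = he(h * 3, h),      b2 = numeric(h),
      W3 = he(h * 3, h),      b3 = numeric(h),
      W4 = he(2 * h, config$embed_dim), b4 = numeric(config$embed_dim),
      W5 = he(config$embed_dim, 4),     b5 = numeric(4)
    )
  })
}

counter_forward <- function(X, w, config, keep = FALSE) {
  ctx <- config$contexts
  S1 <- splice_frames(X, ctx[[1]])
  A1 <- sweep(S1 %*% w$W1, 2, w$b1, `+`); H1 <- pmax(A1, 0)
  S2 <- splice_frames(H1, ctx[[2]])
  A2 <- sweep(S2 %*% w$W2, 2, w$b2, `+`); H2 <- pmax(A2, 0)
  S3 <- splice_frames(H2, ctx[[3]])
  A3 <- sweep(S3 %*% w$W3, 2, w$b3, `+`); H3 <- pmax(A3, 0)
  mu <- colMeans(H3)
  v <- colMeans(H3^2) - mu^2
  sdv <- sqrt(pmax(v, 0) + 1e-8)
  pooled <- c(mu, sdv)
  A4 <- drop(pooled %*% w$W4) + w$b4
  H4 <- pmax(A4, 0)                        # segment-level embedding
  logits <- drop(H4 %*% w$W5) + w$b5
  out <- list(emb = H4, logits = logits)
  if (keep) {
    out <- c(out, list(X = X, S1 = S1, A1 = A1, H1 = H1, S2 = S2, A2 = A2,
                       H2 = H2, S3 = S3, A3 = A3, H3 = H3, mu = mu,
                       sdv = sdv, pooled = pooled, A4 = A4, H4 = H4))
  }
  out
}

length_normalize <- function(E) {
  E / pmax(sqrt(rowSums(E^2)), 1e-12)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

counter_backward <- function(fw, label, w, config) {
  T_ <- nrow(fw$X)
  h <- config$hidden_dim
  ctx <- config$contexts
  p <- softmax(fw$logits)
  dlogit <- p
  dlogit[label] <- dlogit[label] - 1
  g <- list()
  g$W5 <- outer(fw$H4, dlogit); g$b5 <- dlogit
  dH4 <- drop(w$W5 %*% dlogit) * (fw$A4 > 0)
  g$W4 <- outer(fw$pooled, dH4); g$b4 <- dH4
  dpooled <- drop(w$W4 %*% dH4)
  dmu <- dpooled[seq_len(h)]
  dsd <- dpooled[h + seq_len(h)]
  centred <- sweep(fw$H3, 2, fw$mu)
  dH3 <- matrix(dmu / T_, T_, h, byrow = TRUE) +
    sweep(centred, 2, dsd / (T_ * fw$sdv), `*`)
  dA3 <- dH3 * (fw$A3 > 0)
  g$W3 <- crossprod(fw$S3, dA3); g$b3 <- colSums(dA3)
  dH2 <- splice_backward(dA3 %*% t(w$W3), ctx[[3]], h, T_)
  dA2 <- dH2 * (fw$A2 > 0)
  g$W2 <- crossprod(fw$S2, dA2); g$b2 <- colSums(dA2)
  dH1 <- splice_backward(dA2 %*% t(w$W2), ctx[[2]], h, T_)
  dA1 <- dH1 * (fw$A1 > 0)
  g$W1 <- crossprod(fw$S1, dA1); g$b1 <- colSums(dA1)
  list(grads = g, loss = -log(max(p[label], 1e-12)))
}

# --- feature windows --------------------------------------------------------

#' Assemble per-window model inputs from frame features
#'
#' Cuts a [frame_features()] bundle into consecutive 5-s windows and stacks
#' the per-frame model input (mel filterbanks, normalized pitch, pitch
#' salience, voicing flag) for each.
#'
#' @param feats A [frame_features()] object.
#' @param window_s Window length in seconds (default 5).
#' @param frame_subsample Keep every k-th frame.
#' @return List of `T x (n_mels + 3)` matrices, one per complete window.
#' @export
feature_windows <- function(feats, window_s = 5, frame_subsample = 1) {
  stopifnot(inherits(feats, "frame_features"))
  X <- cbind(feats$fbank, feats$pitch / 300, feats$nacf,
             as.numeric(feats$voiced))
  rel_t <- feats$frame_times - feats$frame_times[1]
  # covered time = frame span plus one frame length; an exactly-5-s clip
  # (498 frames at 25/10 ms) yields one complete window
  covered <- length(rel_t) * feats$hop_s + feats$frame_s
  n_win <- floor(covered / window_s + 1e-6)
  out <- vector("list", max(n_win, 0L))
  for (wdx in seq_len(n_win)) {
    sel <- which(rel_t >= (wdx - 1) * window_s & rel_t < wdx * window_s)
    if (frame_subsample > 1) {
      sel <- sel[seq(1, length(sel), by = frame_subsample)]
    }
    out[[wdx]] <- X[sel, , drop = FALSE]
  }
  out
}

#' Extract the embedding of one 5-s feature window
#'
#' Runs the frame-level layers and statistics pooling and returns the
#' segment-level embedding (the rectified affine layer after pooling).
#' Deterministic given the model weights. The distance backend compares
#' embeddings by cosine, so their scale is irrelevant; centroids are class
#' means of length-normalized training embeddings.
#'
#' @param window A `T x d` feature matrix as produced by
#'   [feature_windows()]; at least 10 frames.
#' @param model A `counter_model`.
#' @return Numeric embedding vector of the configured dimension.
#' @export
extract_embedding <- function(window, model) {
  stopifnot(inherits(model, "counter_model"))
  if (!is.matrix(window) || nrow(window) < 10) {
    stop("window must be a feature matrix with >= 10 frames", call. = FALSE)
  }
  counter_forward(window, model$weights, model$config)$emb
}

# --- training ---------------------------------------------------------------

load_manifest_windows <- function(manifest, split, config, progress = FALSE) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  xs <- list(); ys <- integer(0)
  for (i in seq_len(nrow(rows))) {
    audio <- read_wav(rows$path[i])
    feats <- frame_features(audio, n_mels = config$n_mels)
    wins <- feature_windows(feats, frame_subsample = config$frame_subsample)
    counts <- parse_counts(rows$counts[i])[[1]]
    for (wdx in seq_along(wins)) {
      if (wdx > length(counts) || nrow(wins[[wdx]]) < 10) next
      xs[[length(xs) + 1L]] <- wins[[wdx]]
      ys <- c(ys, as.integer(count_to_class(counts[wdx])))
    }
  }
  list(x = xs, y = ys)
}

#' Train the concurrent-speaker counting model
#'
#' Trains the embedding network with 4-class cross-entropy supervision on
#' the manifest's train split, then freezes per-class centroid embeddings
#' (the mean training embedding of each class) for the distance-scoring
#' backend. Fully seeded: the same corpus, config and seed reproduce the
#' same model. Per-epoch loss and validation accuracy are kept in
#' `$curves`.
#'
#' @param manifest Corpus manifest tibble (or path to a `manifest.csv`)
#'   from [build_corpus()].
#' @param config A [counter_config()].
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `counter_model`: weights, class centroids,
#'   config, seed, and training curves.
#' @export
train_counter <- function(manifest, config = counter_config(), seed = 1) {
  if (is.character(manifest)) {
    manifest <- tibble::as_tibble(utils::read.csv(manifest,
                                                  stringsAsFactors = FALSE))
  }
  train <- load_manifest_windows(manifest, "train", config)
  if (length(unique(train$y)) < 4) {
    stop("training split must contain all four count classes (C0-C3); ",
         "found only {", paste(COUNT_CLASSES[sort(unique(train$y))],
                               collapse = ", "), "}", call. = FALSE)
  }
  has_val <- any(manifest$split == "val")
  val <- if (has_val) load_manifest_windows(manifest, "val", config)

  in_dim <- ncol(train$x[[1]])
  w <- init_counter_weights(in_dim, config, child_seed(seed, "init"))
  mstate <- lapply(w, function(p) p * 0)
  vstate <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(train$x)
  curves <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                           val_accuracy = numeric())

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr * (config$lr_decay %||% 1)^(epoch - 1)
    ord <- with_seed(child_seed(seed, paste0("epoch", epoch)), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      acc <- NULL
      bloss <- 0
      for (i in batch) {
        fw <- counter_forward(train$x[[i]], w, config, keep = TRUE)
        bw <- counter_backward(fw, train$y[i], w, config)
        bloss <- bloss + bw$loss
        acc <- if (is.null(acc)) bw$grads else {
          Map(`+`, acc, bw$grads)
        }
      }
      acc <- lapply(acc, `/`, length(batch))
      step <- step + 1L
      for (nm in names(w)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * acc[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * acc[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      losses <- c(losses, bloss / length(batch))
    }
    val_acc <- NA_real_
    if (has_val && length(val$y)) {
      pred <- vapply(val$x, function(x) {
        which.max(counter_forward(x, w, config)$logits)
      }, integer(1))
      val_acc <- mean(pred == val$y)
    }
    curves <- dplyr::bind_rows(curves, tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_accuracy = val_acc))
  }

  # backend centroids: class means of length-normalized embeddings, the
  # usual preparation for cosine scoring of x-vector-style embeddings
  emb <- length_normalize(t(vapply(train$x, function(x) {
    counter_forward(x, w, config)$emb
  }, numeric(config$embed_dim))))
  centroids <- t(vapply(1:4, function(k) {
    colMeans(emb[train$y == k, , drop = FALSE])
  }, numeric(config$embed_dim)))
  rownames(centroids) <- COUNT_CLASSES

  structure(list(weights = w, centroids = centroids, config = config,
                 seed = seed, curves = curves,
                 feature_hash = digest::digest(config[c("n_mels",
                                                        "frame_subsample")])),
            class = "counter_model")
}

#' @export
print.counter_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<counter_model: %d parameters, %d-d embedding, backend %s>\n",
              np, x$config$embed_dim, x$config$backend))
  invisible(x)
}

# --- scoring and evaluation -------------------------------------------------

#' Score an embedding against the class centroids
#'
#' Computes the cosine distance from the embedding to each class centroid
#' and returns the nearest class; exact ties resolve toward the lower
#' class (the conservative choice for an ambiance measure). With
#' `backend = "softmax"` the classification head is used instead and
#' `embedding` must be a feature window.
#'
#' @param embedding Numeric embedding vector (non-zero norm), or a feature
#'   window matrix when `backend = "softmax"`.
#' @param model A `counter_model`.
#' @param backend Override the model's configured backend.
#' @return Ordered factor of length 1 with levels `C0 < C1 < C2 < C3`.
#' @export
score_count <- function(embedding, model, backend = NULL) {
  stopifnot(inherits(model, "counter_model"))
  backend <- backend %||% model$config$backend
  if (backend == "softmax") {
    lg <- counter_forward(embedding, model$weights, model$config)$logits
    k <- which.max(lg)
  } else {
    if (!is.numeric(embedding) || length(embedding) != ncol(model$centroids)) {
      stop("embedding dimension does not match the model", call. = FALSE)
    }
    nrm <- sqrt(sum(embedding^2))
    if (nrm == 0) stop("zero-norm embedding cannot be scored", call. = FALSE)
    cn <- sqrt(rowSums(model$centroids^2))
    d <- 1 - drop(model$centroids %*% embedding) / (cn * nrm)
    k <- which(d <= min(d) + 1e-12)[1]  # ties -> lower class
  }
  factor(COUNT_CLASSES[k], levels = COUNT_CLASSES, ordered = TRUE)
}

predict_window_class <- function(window, model, backend = NULL) {
  backend <- backend %||% model$config$backend
  if (backend == "softmax") {
    score_count(window, model, backend = "softmax")
  } else {
    score_count(extract_embedding(window, model), model, backend = "centroid")
  }
}

#' Evaluate a counting model on a manifest split
#'
#' Predicts every 5-s window of the split and reports the 4x4 confusion
#' matrix (true class in rows), one-vs-rest sensitivity `TP / (TP + FN)`
#' and specificity `TN / (TN + FP)` per class, and their macro averages.
#' A class absent from the split keeps its row with `NA` sensitivity
#' rather than being dropped.
#'
#' @param model A `counter_model`.
#' @param manifest Corpus manifest tibble or path.
#' @param split Which split to evaluate (default `"test"`).
#' @param backend Optional backend override.
#' @return List with `confusion`, `per_class` (tibble), and
#'   `macro_sensitivity`, `macro_specificity` in percent.
#' @export
evaluate_counter <- function(model, manifest, split = "test", backend = NULL) {
  if (is.character(manifest)) {
    manifest <- tibble::as_tibble(utils::read.csv(manifest,
                                                  stringsAsFactors = FALSE))
  }
  data <- load_manifest_windows(manifest, split, model$config)
  if (!length(data$y)) stop("split '", split, "' is empty", call. = FALSE)
  pred <- vapply(data$x, function(x) {
    as.integer(predict_window_class(x, model, backend))
  }, integer(1))
  classification_report(true = data$y, pred = pred)
}

#' Confusion matrix and one-vs-rest sensitivity/specificity
#'
#' @param true,pred Integer class indices in 1..4 (C0..C3).
#' @return As [evaluate_counter()].
#' @export
classification_report <- function(true, pred) {
  confusion <- matrix(0L, 4, 4, dimnames = list(true = COUNT_CLASSES,
                                                pred = COUNT_CLASSES))
  for (i in seq_along(true)) {
    confusion[true[i], pred[i]] <- confusion[true[i], pred[i]] + 1L
  }
  per <- lapply(1:4, function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- sum(confusion) - tp - fn - fp
    tibble::tibble(
      class = COUNT_CLASSES[k], n = tp + fn,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
  })
  per <- dplyr::bind_rows(per)
  list(confusion = confusion, per_class = per,
       macro_sensitivity = mean(per$sensitivity, na.rm = TRUE),
       macro_specificity = mean(per$specificity, na.rm = TRUE))
}
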