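#' Feature-set definitions for the domain classifiers
#'
#' Maps each model name to the feature-table columns it consumes. The
#' sets mirror the full/anthropometric/biomechanical/neuromuscular/balance
#' decomposition, with the trimmed variants; anthropometric models use one
#' row per subject, the others one row per subject x movement x speed with
#' the movement and speed identity encoded as integer inputs.
#'
#' @param name one of `"full"`, `"anthropometric"`,
#'   `"anthropometric_trimmed"`, `"biomechanical"`,
#'   `"biomechanical_trimmed"`, `"biomechanical_trimmed_normalized"`,
#'   `"neuromuscular"`, `"neuromuscular_entropy"`,
#'   `"neuromuscular_centroid"`, `"balance"`.
#' @return character vector of column names (excluding movement/speed,
#'   which are added by [assemble_feature_set()] where applicable).
#' @export
feature_set_columns <- function(name) {
  sh <- function(stem) paste0("traj_", stem, "_left_shoulder_",
                              c("x", "y", "z"))
  grids <- c("left_lower", "left_upper", "right_lower", "right_upper")
  centroid_cols <- c(paste0("emg_centroid_", rep(grids, each = 2), "_",
                            c("x", "y")),
                     "emg_centroid_global_x", "emg_centroid_global_y")
  entropy_cols <- paste0("emg_entropy_", grids)
  bary <- c("foot_bary_x", "foot_bary_y")
  switch(name,
    anthropometric = c("age", "bmi", "height", "weight", "sex"),
    anthropometric_trimmed = c("age", "bmi", "sex"),
    biomechanical = c(sh("maxamp"), sh("t2max"), sh("sampen"),
                      sh("intravar"), sh("intervar"), bary),
    biomechanical_trimmed = c(sh("maxamp_raw"), sh("t2max"), bary),
    biomechanical_trimmed_normalized = c(sh("maxamp"), sh("t2max"), bary),
    neuromuscular = c(centroid_cols, entropy_cols),
    neuromuscular_entropy = entropy_cols,
    neuromuscular_centroid = centroid_cols,
    balance = c("statok_area", "gfr_ratio"),
    full = c("age", "bmi", "height", "weight", "sex",
             feature_set_columns("biomechanical"),
             "angle_max_shoulder_z", "angle_t2max_shoulder_z",
             centroid_cols, entropy_cols, "statok_area", "gfr_ratio"),
    stop("unknown feature set: ", name))
}

#' Assemble a design matrix for one feature-set model
#'
#' @param table feature table from [build_feature_table()].
#' @param name feature-set name (see [feature_set_columns()]).
#' @return list with `x` (numeric matrix), `y` (0/1 group labels),
#'   `subject_id`, and `columns`.
#' @export
assemble_feature_set <- function(table, name) {
  cols <- feature_set_columns(name)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  anthropometric <- name %in% c("anthropometric", "anthropometric_trimmed")
  tab <- table
  if (anthropometric) {
    tab <- table[!duplicated(table$subject_id), , drop = FALSE]
  } else {
    tab$movement <- as.integer(factor(tab$movement, movement_levels())) - 1L
    tab$speed <- as.integer(factor(tab$speed, speed_levels())) - 1L
    cols <- c(cols, "movement", "speed")
  }
  x <- as.matrix(tab[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x)))     # mean-impute undefined features
    if (anyNA(x[, j])) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  list(x = x, y = as.integer(tab$group), subject_id = tab$subject_id,
       columns = cols)
}

#' Dense-network model specification
#'
#' The standard classifier: `dense(width, sigmoid)` input layer,
#' `dense(128, sigmoid)`, `dropout(0.5)`, `dense(36, sigmoid)`,
#' `dense(1, sigmoid)`.
#'
#' @param input_dim number of input features (>= 1).
#' @param width units of the first (input) dense layer.
#' @return a `model_spec`: list of layer descriptors with an `input_dim`.
#' @export
build_dnn <- function(input_dim, width = 11L) {
  if (input_dim < 1) stop("input_dim must be >= 1")
  structure(list(
    input_dim = as.integer(input_dim),
    layers = list(
      list(kind = "dense", units = as.integer(width), activation = "sigmoid"),
      list(kind = "dense", units = 128L, activation = "sigmoid"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 36L, activation = "sigmoid"),
      list(kind = "dense", units = 1L, activation = "sigmoid"))),
    class = "model_spec")
}

#' 3-D convolutional model specification for raw HD-EMG tensors
#'
#' Three conv-conv-pool-batchnorm blocks (8, 16, 32 filters, kernel
#' 3 x 3 x 20 over rows x columns x time), then flatten,
#' `dense(64)`, dropout, `dense(64)`, dropout, `dense(1)`. Input shape
#' `26 x 10 x 6000 x 1`.
#'
#' @return a `model_spec`.
#' @export
build_cnn <- function() {
  conv <- function(f) list(kind = "conv3d", filters = as.integer(f),
                           kernel = c(3L, 3L, 20L), activation = "relu")
  structure(list(
    input_dim = c(26L, 10L, 6000L, 1L),
    layers = list(
      conv(8), conv(8),
      list(kind = "maxpool3d", pool = c(2L, 2L, 10L)),
      list(kind = "batchnorm"),
      conv(16), conv(16),
      list(kind = "maxpool3d", pool = c(2L, 2L, 10L)),
      list(kind = "batchnorm"),
      conv(32), conv(32),
      list(kind = "maxpool3d", pool = c(2L, 2L, 10L)),
      list(kind = "batchnorm"),
      list(kind = "flatten", units = 384L),
      list(kind = "dense", units = 64L, activation = "relu"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 64L, activation = "relu"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 1L, activation = "sigmoid"))),
    class = "model_spec")
}

#' Trainable-parameter counts of a model specification
#'
#' Dense: `units * (inputs + 1)`. Batchnorm: `4 * channels`. Conv3d:
#' `filters * (kernel_volume * in_channels + 1)`. Dropout, pooling and
#' flatten have none.
#'
#' @param spec a `model_spec`.
#' @return data.frame with `layer`, `kind`, `params`, plus attribute
#'   `"total"`; also accessible as `sum(result$params)`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  conv_like <- length(spec$input_dim) > 1L
  in_units <- if (conv_like) spec$input_dim[length(spec$input_dim)]
              else spec$input_dim
  out <- data.frame(layer = character(0), kind = character(0),
                    params = integer(0))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    p <- switch(ly$kind,
      dense = ly$units * (in_units + 1L),
      conv3d = ly$filters * (prod(ly$kernel) * in_units + 1L),
      batchnorm = 4L * in_units,
      dropout = 0L, maxpool3d = 0L, flatten = 0L,
      stop("unknown layer kind: ", ly$kind))
    if (ly$kind %in% c("dense", "conv3d")) in_units <- ly$units %||% ly$filters
    if (ly$kind == "flatten") in_units <- ly$units
    out <- rbind(out, data.frame(layer = sprintf("%s_%d", ly$kind, i),
                                 kind = ly$kind, params = as.integer(p)))
  }
  attr(out, "total") <- sum(out$params)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-disjoint train/test/validation split
#'
#' Randomly partitions subjects, stratified by group: `val_frac` of the
#' subjects form the validation set; of the remainder, `test_frac_of_rest`
#' form the test set and the rest train. All records of a subject land in
#' exactly one partition, so the three sets never share a subject.
#'
#' @param subjects data.frame with `id` and `group`.
#' @param val_frac validation fraction of all subjects.
#' @param test_frac_of_rest test fraction of the non-validation subjects.
#' @param seed integer seed.
#' @return list with character vectors `train`, `test`, `validation` and
#'   the `seed`.
#' @export
split_subjects <- function(subjects, val_frac = 0.30,
                           test_frac_of_rest = 0.25, seed = 1L) {
  if (min(table(subjects$group)) < 3L)
    stop("need at least 3 subjects per group to stratify")
  set.seed(seed)
  val <- test <- train <- character(0)
  for (g in unique(subjects$group)) {
    ids <- sample(subjects$id[subjects$group == g])
    n <- length(ids)
    n_val <- round(val_frac * n)
    n_test <- round(test_frac_of_rest * (n - n_val))
    val <- c(val, ids[seq_len(n_val)])
    test <- c(test, ids[n_val + seq_len(n_test)])
    train <- c(train, ids[-(seq_len(n_val + n_test))])
  }
  structure(list(train = train, test = test, validation = val, seed = seed),
            class = "split_plan")
}

# ---- dense-network trainer ---------------------------------------------

.act <- function(z, kind) switch(kind, sigmoid = 1 / (1 + exp(-z)),
                                 relu = pmax(z, 0), z)
.act_grad <- function(a, kind) switch(kind, sigmoid = a * (1 - a),
                                      relu = (a > 0) + 0, a * 0 + 1)

#' Train a dense classifier with subject-disjoint data
#'
#' Mini-batch gradient training of the dense layers of a [build_dnn()]
#' specification with the adam optimizer and binary cross-entropy loss
#' (the two-class equivalent of categorical cross-entropy for a one-unit
#' sigmoid output). Inputs are standardized using training-set statistics.
#' Per-epoch accuracies on train, test and validation sets are recorded;
#' the best validation epoch is reported (training curves typically
#' overfit beyond it). Deterministic on CPU for a fixed seed.
#'
#' @param spec a `model_spec` with dense/dropout layers only.
#' @param features numeric matrix (rows = records).
#' @param labels 0/1 vector.
#' @param subject_id per-record subject ids.
#' @param plan a [split_subjects()] plan.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr adam learning rate.
#' @param seed integer seed (weight init, shuffling, dropout).
#' @return a `train_result`: per-epoch accuracy/loss data.frame `history`,
#'   `best_epoch`, `best_validation_accuracy`, final `weights`, `seed`.
#' @export
train_classifier <- function(spec, features, labels, subject_id, plan,
                             epochs = 100L, batch_size = 10L, lr = 1e-3,
                             seed = 1L) {
  if (any(!vapply(spec$layers, function(l)
    l$kind %in% c("dense", "dropout"), logical(1))))
    stop("only dense/dropout layers are trainable; convolutional training is not supported")
  if (nrow(features) != length(labels) || length(labels) != length(subject_id))
    stop("features, labels and subject_id sizes do not agree")
  set.seed(seed)
  part <- function(ids) which(subject_id %in% ids)
  itr <- part(plan$train); ite <- part(plan$test); iva <- part(plan$validation)
  if (!length(itr) || !length(iva)) stop("empty train or validation partition")
  mu <- colMeans(features[itr, , drop = FALSE])
  sg <- apply(features[itr, , drop = FALSE], 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sg, "/")
  y <- as.numeric(labels)

  dense_idx <- which(vapply(spec$layers, function(l) l$kind == "dense",
                            logical(1)))
  dims <- c(spec$input_dim,
            vapply(spec$layers[dense_idx], function(l) l$units, integer(1)))
  L <- length(dense_idx)
  W <- lapply(seq_len(L), function(l) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))        # glorot-uniform
    matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim), dims[l], dims[l + 1])
  })
  b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  acts <- vapply(spec$layers[dense_idx], function(l) l$activation, character(1))
  # dropout rate applied to the output of the preceding dense layer
  drop_after <- numeric(L)
  for (i in seq_along(spec$layers))
    if (spec$layers[[i]]$kind == "dropout") {
      prev <- sum(vapply(spec$layers[seq_len(i - 1)],
                         function(l) l$kind == "dense", logical(1)))
      if (prev >= 1) drop_after[prev] <- spec$layers[[i]]$rate
    }

  forward <- function(X, train = FALSE) {
    A <- list(X)        # post-dropout activations fed to the next layer
    Araw <- list()      # pre-dropout activations (for activation gradients)
    M <- vector("list", L)
    for (l in seq_len(L)) {
      Z <- A[[l]] %*% W[[l]]
      Z <- sweep(Z, 2, b[[l]], "+")
      a <- .act(Z, acts[l])
      Araw[[l]] <- a
      if (train && drop_after[l] > 0) {
        M[[l]] <- matrix(stats::rbinom(length(a), 1, 1 - drop_after[l]),
                         nrow(a), ncol(a)) / (1 - drop_after[l])
        a <- a * M[[l]]
      }
      A[[l + 1]] <- a
    }
    list(A = A, Araw = Araw, M = M)
  }
  predict_prob <- function(idx) drop(forward(X[idx, , drop = FALSE])$A[[L + 1]])
  accuracy <- function(idx) mean((predict_prob(idx) > 0.5) == (y[idx] > 0.5))
  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
  hist_rows <- vector("list", epochs)
  best <- list(acc = -Inf, epoch = NA_integer_, W = W, b = b)
  for (ep in seq_len(epochs)) {
    ord <- sample(itr)
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      fw <- forward(X[bi, , drop = FALSE], train = TRUE)
      A <- fw$A
      p <- A[[L + 1]]
      delta <- (p - y[bi]) / length(bi)      # dL/dz for sigmoid + BCE
      for (l in rev(seq_len(L))) {
        if (l < L) {
          if (!is.null(fw$M[[l]])) delta <- delta * fw$M[[l]]
          delta <- delta * .act_grad(fw$Araw[[l]], acts[l])
        }
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        delta <- delta %*% t(W[[l]])
      }
      step <- step + 1
      c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
      for (l in seq_len(L)) {
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
    ptr <- predict_prob(itr)
    if (any(!is.finite(ptr))) stop("NaN loss encountered; aborting training")
    acc_va <- accuracy(iva)
    hist_rows[[ep]] <- data.frame(
      epoch = ep, loss_train = bce(ptr, y[itr]),
      acc_train = mean((ptr > 0.5) == (y[itr] > 0.5)),
      acc_test = if (length(ite)) accuracy(ite) else NA_real_,
      acc_validation = acc_va)
    if (acc_va > best$acc)
      best <- list(acc = acc_va, epoch = ep, W = W, b = b)
  }
  structure(list(history = do.call(rbind, hist_rows),
                 best_epoch = best$epoch,
                 best_validation_accuracy = best$acc,
                 weights = list(W = best$W, b = best$b),
                 standardization = list(mu = mu, sd = sg),
                 seed = seed),
            class = "train_result")
}
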