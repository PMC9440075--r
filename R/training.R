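#' Multiclass cross-entropy loss
#'
#' Mean over samples of `-sum_i t_i * ln(y_i)` for one-hot targets `t` and
#' predicted class probabilities `y`. Probabilities are floored at `1e-12`
#' so a zero probability at the target class yields a large finite loss
#' rather than infinity.
#'
#' @param probs matrix `(samples, classes)` of probabilities (rows sum to 1).
#' @param targets one-hot matrix of the same shape, or an integer class
#'   vector (1-based) which is expanded internally.
#' @param floor probability floor, default `1e-12`.
#' @return non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(c(0.5, 0.25, 0.25), 1), 1L)  # log(2)
#' @export
cross_entropy <- function(probs, targets, floor = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (!is.matrix(targets)) {
    t_idx <- as.integer(targets)
    stopifnot(all(t_idx >= 1L), all(t_idx <= ncol(probs)))
    targets <- matrix(0, nrow(probs), ncol(probs))
    targets[cbind(seq_len(nrow(probs)), t_idx)] <- 1
  }
  stopifnot(identical(dim(probs), dim(targets)))
  -sum(targets * log(pmax(probs, floor))) / nrow(probs)
}

one_hot <- function(classes, K) {
  out <- matrix(0, length(classes), K)
  out[cbind(seq_along(classes), as.integer(classes))] <- 1
  out
}

#' Create Adam optimizer state
#'
#' The update rule is `w <- w - lr * m / (sqrt(v) + eps)` with moving
#' averages `m = b1 m + (1 - b1) g` and `v = b2 v + (1 - b2) g^2`.
#' By default there is **no** bias correction of `m` and `v` — the update
#' is applied verbatim as published here; set `bias_correction = TRUE` for
#' standard Adam.
#'
#' @param lr learning rate, default 0.001.
#' @param b1,b2 decay rates for `m` and `v`; defaults 0.9 and 0.990.
#' @param eps denominator offset, default 1e-8.
#' @param bias_correction use the standard `m-hat`/`v-hat` correction.
#' @return optimizer state of class `sgt_adam`.
#' @export
adam_state <- function(lr = 0.001, b1 = 0.9, b2 = 0.990, eps = 1e-8,
                       bias_correction = FALSE) {
  structure(list(lr = lr, b1 = b1, b2 = b2, eps = eps,
                 bias_correction = bias_correction,
                 t = 0L, m = list(), v = list()),
            class = "sgt_adam")
}

#' One Adam update over a flat parameter list
#'
#' @param params named list of numeric arrays.
#' @param grads matching named list of gradients.
#' @param state an [adam_state()].
#' @param lr optional learning-rate override for this step (the schedule).
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = state$lr) {
  state$t <- state$t + 1L
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    m <- if (is.null(state$m[[key]])) g * 0 else state$m[[key]]
    v <- if (is.null(state$v[[key]])) g * 0 else state$v[[key]]
    m <- state$b1 * m + (1 - state$b1) * g
    v <- state$b2 * v + (1 - state$b2) * g^2
    state$m[[key]] <- m
    state$v[[key]] <- v
    if (state$bias_correction) {
      m <- m / (1 - state$b1^state$t)
      v <- v / (1 - state$b2^state$t)
    }
    params[[key]] <- params[[key]] - lr * m / (sqrt(v) + state$eps)
  }
  list(params = params, state = state)
}

#' Create SGD-with-momentum optimizer state
#'
#' Classical momentum: `velocity <- mu * velocity - lr * grad`;
#' `params <- params + velocity`.
#'
#' @param lr learning rate, default 0.001.
#' @param momentum momentum coefficient, default 0.9.
#' @return optimizer state of class `sgt_sgdm`.
#' @export
sgdm_state <- function(lr = 0.001, momentum = 0.9) {
  structure(list(lr = lr, momentum = momentum, velocity = list()),
            class = "sgt_sgdm")
}

#' One SGDM update over a flat parameter list
#'
#' @inheritParams adam_step
#' @param state an [sgdm_state()].
#' @return list with updated `params` and `state`.
#' @export
sgdm_step <- function(params, grads, state, lr = state$lr) {
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    vel <- if (is.null(state$velocity[[key]])) g * 0 else state$velocity[[key]]
    vel <- state$momentum * vel - lr * g
    state$velocity[[key]] <- vel
    params[[key]] <- params[[key]] + vel
  }
  list(params = params, state = state)
}

#' Stepped learning-rate schedule
#'
#' The learning rate starts at `initial_lr` and is multiplied by
#' `drop_factor` after every `drop_every` epochs:
#' `lr(epoch) = initial_lr * drop_factor^floor(epoch / drop_every)`
#' with `epoch` counted from 0.
#'
#' @param epoch epoch index, 0-based.
#' @param initial_lr starting rate, default 0.001.
#' @param drop_factor multiplicative drop, default 0.95.
#' @param drop_every epochs between drops, default 10.
#' @return learning rate at `epoch`.
#' @examples
#' lr_at_epoch(0)   # 0.001
#' lr_at_epoch(25)  # 0.001 * 0.95^2
#' @export
lr_at_epoch <- function(epoch, initial_lr = 0.001, drop_factor = 0.95,
                        drop_every = 10L) {
  stopifnot(epoch >= 0)
  initial_lr * drop_factor^floor(epoch / drop_every)
}

# Largest-remainder allocation of `total` units to quotas, ties broken
# toward the larger quota, then lower index.
largest_remainder <- function(quotas, total) {
  base <- floor(quotas)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quotas - base), -quotas, seq_along(quotas))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits each class into train/validation/test at the given ratios using
#' largest-remainder rounding: test quotas are resolved first against a
#' total of `floor(sum(count_c * r_test))` units, then validation against
#' `floor(sum(count_c * r_val))` from what remains, and everything left goes
#' to train. Ties in the remainders go to the larger quota. Membership is
#' shuffled within class by `seed`; subset *sizes* depend only on the counts
#' and ratios.
#'
#' With class counts (209, 305, 474) and ratios 5:2:3 this yields test
#' totals (63, 91, 142) = 296, validation (41, 61, 95) = 197 and train
#' (105, 153, 237) = 495.
#'
#' @param class_counts integer vector of per-class record counts.
#' @param ratios length-3 positive weights for (train, validation, test);
#'   default `c(5, 2, 3)`.
#' @param seed integer seed for the within-class shuffle.
#' @return tibble with columns `class` (1-based index), `index`
#'   (within-class record index) and `subset`
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
stratified_split <- function(class_counts, ratios = c(5, 2, 3), seed = 1L) {
  stopifnot(all(class_counts > 0), all(ratios > 0), length(ratios) == 3L)
  r <- ratios / sum(ratios)
  q_test <- class_counts * r[3L]
  n_test <- largest_remainder(q_test, floor(sum(q_test)))
  q_val <- class_counts * r[2L]
  n_val <- largest_remainder(q_val, floor(sum(q_val)))
  n_train <- class_counts - n_test - n_val
  if (any(n_train < 1L) || any(n_val < 1L) || any(n_test < 1L)) {
    stop("stratified_split: a class is too small for three non-empty subsets")
  }
  set.seed(seed)
  out <- lapply(seq_along(class_counts), function(cl) {
    idx <- sample.int(class_counts[cl])
    subset <- rep("train", class_counts[cl])
    subset[idx[seq_len(n_test[cl])]] <- "test"
    subset[idx[n_test[cl] + seq_len(n_val[cl])]] <- "validation"
    tibble::tibble(class = cl, index = seq_len(class_counts[cl]),
                   subset = subset)
  })
  do.call(rbind, out)
}

# Stack a list of 3D volumes into a (batch, 1, e, e, e) tensor.
stack_volumes <- function(volumes) {
  e <- dim(volumes[[1L]])
  B <- length(volumes)
  X <- array(0, dim = c(B, 1L, e))
  for (b in seq_len(B)) X[b, 1L, , , ] <- volumes[[b]]
  X
}

batch_accuracy <- function(probs, classes) {
  mean(max.col(probs, ties.method = "first") == as.integer(classes))
}

evaluate_network <- function(network, volumes, classes, batch_size = 8L) {
  n <- length(volumes)
  probs <- matrix(NA_real_, n, network$spec$classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- forward_pass(network, stack_volumes(volumes[idx]), mode = "eval")
    probs[idx, ] <- fwd$probs
  }
  list(probs = probs,
       loss = cross_entropy(probs, classes),
       accuracy = batch_accuracy(probs, classes))
}

#' Mini-batch training loop
#'
#' Runs `epochs` epochs of shuffled mini-batches: forward pass, softmax
#' cross-entropy, backward pass, one optimizer step per batch at the
#' scheduled learning rate ([lr_at_epoch()]). Per-epoch data order is
#' reshuffled with a seed derived from `seed` and the epoch index, so runs
#' are reproducible. Training aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param network an [build_network()] object.
#' @param volumes list of 3D arrays (the input cubes, already normalized).
#' @param classes integer class labels (1-based), one per volume.
#' @param epochs number of epochs.
#' @param batch_size mini-batch size, default 8.
#' @param optimizer `"adam"` or `"sgdm"`.
#' @param initial_lr,drop_factor,drop_every learning-rate schedule, see
#'   [lr_at_epoch()].
#' @param seed integer seed for batch shuffling (and dropout masks).
#' @param val_volumes,val_classes optional validation set evaluated at the
#'   end of each epoch.
#' @param verbose print per-epoch progress.
#' @return list with the trained `network` and `history`, a tibble with one
#'   row per epoch (`epoch`, `lr`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`).
#' @export
train_loop <- function(network, volumes, classes, epochs,
                       batch_size = 8L, optimizer = c("adam", "sgdm"),
                       initial_lr = 0.001, drop_factor = 0.95,
                       drop_every = 10L, seed = 1L,
                       val_volumes = NULL, val_classes = NULL,
                       verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  classes <- as.integer(classes)
  K <- network$spec$classes
  stopifnot(length(volumes) == length(classes), all(classes >= 1L),
            all(classes <= K))
  state <- if (optimizer == "adam") adam_state(lr = initial_lr)
           else sgdm_state(lr = initial_lr)
  hist <- vector("list", epochs)
  n <- length(volumes)
  for (ep in seq_len(epochs)) {
    lr <- lr_at_epoch(ep - 1L, initial_lr, drop_factor, drop_every)
    set.seed((seed * 1000L + ep) %% .Machine$integer.max)
    ord <- sample.int(n)
    ep_loss <- 0
    ep_hits <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      X <- stack_volumes(volumes[idx])
      targets <- one_hot(classes[idx], K)
      fwd <- forward_pass(network, X, mode = "train")
      network <- fwd$network
      loss <- cross_entropy(fwd$probs, targets)
      if (!is.finite(loss)) {
        stop("train_loop: non-finite loss at epoch ", ep,
             " (check softmax logits / parameter scale)")
      }
      dlogits <- (fwd$probs - targets) / nrow(targets)
      grads <- backward_pass(network, fwd, dlogits)
      bad <- names(grads)[!vapply(grads, function(g) all(is.finite(g)), TRUE)]
      if (length(bad)) {
        stop("train_loop: non-finite gradient in ", bad[1L],
             " at epoch ", ep)
      }
      params <- get_params(network)
      upd <- if (optimizer == "adam") adam_step(params, grads, state, lr)
             else sgdm_step(params, grads, state, lr)
      state <- upd$state
      network <- set_params(network, upd$params)
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + batch_accuracy(fwd$probs, classes[idx]) * length(idx)
    }
    val_loss <- val_acc <- NA_real_
    if (!is.null(val_volumes) && length(val_volumes)) {
      ev <- evaluate_network(network, val_volumes, val_classes, batch_size)
      val_loss <- ev$loss
      val_acc <- ev$accuracy
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, lr = lr,
      train_loss = ep_loss / n, train_acc = ep_hits / n,
      val_loss = val_loss, val_acc = val_acc
    )
    if (verbose) {
      message(sprintf("epoch %d: lr %.6f loss %.4f acc %.3f", ep, lr,
                      ep_loss / n, ep_hits / n))
    }
  }
  history <- if (epochs > 0) do.call(rbind, hist) else
    tibble::tibble(epoch = integer(), lr = numeric(),
                   train_loss = numeric(), train_acc = numeric(),
                   val_loss = numeric(), val_acc = numeric())
  structure(list(network = network, history = history,
                 optimizer = optimizer, seed = seed),
            class = "sgt_fit")
}

#' @export
print.sgt_fit <- function(x, ...) {
  h <- x$history
  cat("sgt_fit:", nrow(h), "epochs,", x$optimizer, "optimizer\n")
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train loss %.4f, train accuracy %.3f\n",
                last$train_loss, last$train_acc))
  }
  invisible(x)
}

#' @export
tidy.sgt_fit <- function(x, ...) x$history

#' @export
glance.sgt_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble::tibble(epochs = nrow(h), optimizer = x$optimizer,
                 train_loss = last$train_loss, train_acc = last$train_acc,
                 val_loss = last$val_loss, val_acc = last$val_acc)
}
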