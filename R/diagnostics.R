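#' Sample the activation curve and its backward-rule derivative
#'
#' Evaluates the full activation `z(x) = tanh(step1(x))` and the layer's
#' backward-rule derivative `sech^2(Y'(x))` for one channel over a grid.
#' With both exponents at 1 (and gains 0.1 / 1.1) the derivative column is
#' the constant 0.99006 on the negative axis and 0.3592 on the positive
#' axis.
#'
#' @param params an [sgt_params()] object.
#' @param channel channel index to sample, default 1.
#' @param x_grid strictly increasing numeric grid.
#' @return object of class `sgt_curve`: a tibble with columns `x`, `z`,
#'   `deriv`, plus the parameters used as attributes.
#' @export
sample_activation_curve <- function(params, channel = 1L,
                                    x_grid = seq(-3, 3, by = 0.01)) {
  stopifnot(channel >= 1L, channel <= length(params$alpha),
            all(diff(x_grid) > 0), all(is.finite(x_grid)))
  p1 <- sgt_params(alpha = params$alpha[channel], beta = params$beta[channel],
                   a = params$a, b = params$b)
  fwd <- sgt_forward(x_grid, p1)
  deriv <- sech2(sgt_step1_deriv(x_grid, p1))
  out <- tibble::tibble(x = x_grid, z = as.numeric(fwd$Z),
                        deriv = as.numeric(deriv))
  structure(out, channel = channel,
            alpha = params$alpha[channel], beta = params$beta[channel],
            a = params$a, b = params$b,
            class = c("sgt_curve", class(out)))
}

#' @export
autoplot.sgt_curve <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(object$x, 2L),
    value = c(object$z, object$deriv),
    series = rep(c("activation", "backward-rule derivative"),
                 each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "input x", y = NULL, colour = NULL,
      title = sprintf("SGT activation, channel %d (alpha = %.3f, beta = %.3f)",
                      attr(object, "channel"), attr(object, "alpha"),
                      attr(object, "beta"))
    )
}

#' Histograms of tensors entering and leaving activation layers
#'
#' Runs one volume through the network and, for each requested activation
#' layer, histograms the tensor entering the activation (i.e. the
#' batch-normalized features) and the tensor leaving it, pooled over all
#' channels. Bins are 100 equal-width intervals spanning the observed
#' min/max of each tensor.
#'
#' @param network an `sgt_network`.
#' @param volume one 3D array matching the input edge.
#' @param layer_ids indices of activation layers to inspect (default: all).
#' @param bins number of bins, default 100.
#' @param mode forward mode, default `"train"` so batch statistics are used
#'   (a single volume carries no running statistics at initialization).
#' @return tibble with columns `layer`, `side` (`input`/`output`),
#'   `bin_mid`, `count`; one row per bin.
#' @export
layer_histograms <- function(network, volume, layer_ids = NULL, bins = 100L,
                             mode = "train") {
  spec <- network$spec
  act_layers <- which(vapply(spec$layers, function(l) l$kind == "activation", TRUE))
  if (is.null(layer_ids)) layer_ids <- act_layers
  if (!all(layer_ids %in% act_layers)) {
    stop("layer_histograms: layer ids must be activation layers (",
         paste(act_layers, collapse = ", "), ")")
  }
  X <- stack_volumes(list(volume))
  fwd <- forward_pass(network, X, mode = mode)
  # Re-walk the cached activations: the activation input is the cached X of
  # the activation layer itself; the output is recomputed from it.
  rows <- list()
  for (i in layer_ids) {
    nm <- network$activations[[spec$layers[[i]]$slot]]
    sp <- if (nm == "sgt") sgt_params_of(network, i) else NULL
    xin <- fwd$cache[[i]]$X
    xout <- activation_forward(nm, xin, sp)$Z
    for (side in c("input", "output")) {
      v <- as.numeric(if (side == "input") xin else xout)
      rng <- range(v)
      if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
      h <- graphics::hist(v, breaks = seq(rng[1L], rng[2L], length.out = bins + 1L),
                          plot = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = i, side = side, bin_mid = h$mids, count = h$counts
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("sgt_histograms", class(out)))
}

#' @export
autoplot.sgt_histograms <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::facet_grid(layer ~ side, scales = "free") +
    ggplot2::labs(x = "value", y = "count",
                  title = "Activation-layer input/output histograms")
}

#' Per-layer report of the learnable exponents
#'
#' @param network an `sgt_network`.
#' @return tibble with one row per SGT layer: `layer`, `slot`, `n_channels`,
#'   `alpha_min/mean/max`, `beta_min/mean/max`, `n_negative_alpha`,
#'   `n_negative_beta`, and list-columns `alpha`, `beta` with the raw
#'   vectors. Empty (with a warning) if the plan has no SGT layers.
#' @export
alpha_beta_report <- function(network) {
  spec <- network$spec
  idx <- which(vapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    l$kind == "activation" && network$activations[l$slot] == "sgt"
  }, TRUE))
  if (!length(idx)) {
    warning("alpha_beta_report: network has no SGT layers")
    return(tibble::tibble(layer = integer(), slot = integer(),
                          n_channels = integer()))
  }
  rows <- lapply(idx, function(i) {
    p <- network$params[[i]]
    tibble::tibble(
      layer = i, slot = spec$layers[[i]]$slot, n_channels = length(p$alpha),
      alpha_min = min(p$alpha), alpha_mean = mean(p$alpha),
      alpha_max = max(p$alpha),
      beta_min = min(p$beta), beta_mean = mean(p$beta), beta_max = max(p$beta),
      n_negative_alpha = sum(p$alpha < 0), n_negative_beta = sum(p$beta < 0),
      alpha = list(p$alpha), beta = list(p$beta)
    )
  })
  do.call(rbind, rows)
}

#' Correlation of final-layer class weights with sample features
#'
#' Pearson correlation of each class's weight row in the final fully
#' connected layer against each sample's feature vector entering that
#' layer; also the class-by-class self-correlation block. Zero-variance
#' vectors yield `NA` entries.
#'
#' @param fc_weights matrix `(classes, features)` of trained weights.
#' @param sample_activations matrix `(samples, features)`.
#' @param class_labels,sample_labels optional row labels.
#' @return list of class `sgt_correlation` with `cross` (classes x
#'   samples), `weights` (classes x classes) correlation matrices.
#' @export
fc_weight_correlation <- function(fc_weights, sample_activations,
                                  class_labels = rownames(fc_weights),
                                  sample_labels = rownames(sample_activations)) {
  if (ncol(fc_weights) != ncol(sample_activations)) {
    stop("fc_weight_correlation: feature widths differ (",
         ncol(fc_weights), " vs ", ncol(sample_activations), ")")
  }
  safe_cor <- function(a, b) {
    suppressWarnings(out <- stats::cor(a, b))
    out
  }
  cross <- safe_cor(t(fc_weights), t(sample_activations))
  wcor <- safe_cor(t(fc_weights), t(fc_weights))
  if (!is.null(class_labels)) {
    rownames(cross) <- class_labels
    dimnames(wcor) <- list(class_labels, class_labels)
  }
  if (!is.null(sample_labels)) colnames(cross) <- sample_labels
  structure(list(cross = cross, weights = wcor), class = "sgt_correlation")
}

#' @export
print.sgt_correlation <- function(x, ...) {
  cat("FC weight correlations:", nrow(x$cross), "classes x",
      ncol(x$cross), "samples\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Final-layer bias report
#'
#' Returns the bias vector of the last fully connected layer (one entry per
#' class, in label order) together with all pairwise absolute differences.
#'
#' @param network an `sgt_network`.
#' @return list with `bias` (named numeric) and `pairwise` (tibble of
#'   absolute differences).
#' @export
bias_report <- function(network) {
  fc <- which(vapply(network$spec$layers,
                     function(l) l$kind == "fully_connected", TRUE))
  last <- fc[length(fc)]
  b <- network$params[[last]]$b
  names(b) <- network$spec$class_labels
  pairs <- utils::combn(length(b), 2L)
  pairwise <- tibble::tibble(
    class_i = names(b)[pairs[1L, ]], class_j = names(b)[pairs[2L, ]],
    abs_diff = abs(b[pairs[1L, ]] - b[pairs[2L, ]])
  )
  list(bias = b, pairwise = pairwise)
}

#' Export flattened features entering the first fully connected layer
#'
#' Runs each record through the network in eval mode and collects the
#' flattened feature vector entering the first fully connected layer
#' (width 1728 at the reference scale), for use by external embedding
#' tools.
#'
#' @param network an `sgt_network`.
#' @param records list of records with `voxels` and `label`.
#' @param file optional path; when given, features + labels are written as
#'   tab-separated text.
#' @return list with `features` (samples x width matrix) and `labels`.
#' @export
export_fc_features <- function(network, records, file = NULL) {
  if (!length(records)) stop("export_fc_features: empty record subset")
  spec <- network$spec
  fc1 <- which(vapply(spec$layers, function(l) l$kind == "fully_connected",
                      TRUE))[1L]
  feats <- NULL
  for (start in seq(1L, length(records), by = 8L)) {
    idx <- start:min(start + 7L, length(records))
    X <- stack_volumes(lapply(records[idx], `[[`, "voxels"))
    fwd <- forward_pass(network, X, mode = "eval")
    feats <- rbind(feats, fwd$cache[[fc1]]$X)
  }
  labels <- vapply(records, function(r) as.character(r$label), "")
  if (!is.null(file)) {
    utils::write.table(
      data.frame(label = labels, feats, check.names = FALSE),
      file, sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  list(features = feats, labels = labels)
}
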