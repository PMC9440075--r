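#' The diverging 3D CNN architecture
#'
#' Builds the ordered layer list of the diverging network ("divNet"): four
#' convolution blocks whose kernels grow 3 -> 5 -> 7 -> 9 while max pooling
#' (window 2, strides 1, 2, 3, 4) shrinks the volume, each block being
#' convolution -> batch normalization -> activation -> pooling, followed by
#' a fully connected layer as wide as the flattened feature map, 50%
#' dropout, a K-way fully connected layer, softmax and classification. At
#' the reference scale (`edge = 64`, `channels = 64`, `classes = 3`) the
#' spatial chain is 64 -> 63 -> 31 -> 10 -> 3 and the flatten width 1728.
#'
#' @param edge input cube edge length (default 64).
#' @param channels filters per convolution (default 64).
#' @param classes number of output classes (default 3).
#' @param class_labels labels attached to the classification layer.
#' @param dropout dropout rate before the final fully connected layer.
#' @return object of class `sgt_architecture`: a list of layer
#'   descriptions with shape metadata attached.
#' @examples
#' spec <- divnet_spec()
#' length(spec$layers)  # 22
#' @export
divnet_spec <- function(edge = 64L, channels = 64L, classes = 3L,
                        class_labels = c("AD", "CN", "MCI")[seq_len(classes)],
                        dropout = 0.5) {
  stopifnot(edge >= 2L, channels >= 1L, classes >= 2L,
            length(class_labels) == classes)
  kernels <- c(3L, 5L, 7L, 9L)
  pool_strides <- c(1L, 2L, 3L, 4L)
  layers <- list(list(kind = "input", edge = as.integer(edge), channels = 1L,
                      normalization = "zerocenter"))
  for (blk in 1:4) {
    layers <- c(layers, list(
      list(kind = "conv3d", kernel = kernels[blk], filters = as.integer(channels),
           stride = 1L, padding = "same"),
      list(kind = "batchnorm", channels = as.integer(channels)),
      list(kind = "activation", slot = blk, channels = as.integer(channels)),
      list(kind = "maxpool3d", kernel = 2L, stride = pool_strides[blk],
           padding = 0L)
    ))
  }
  spec <- structure(
    list(layers = layers, edge = as.integer(edge),
         channels = as.integer(channels), classes = as.integer(classes),
         class_labels = class_labels),
    class = "sgt_architecture"
  )
  flat <- infer_shapes(spec)$flatten
  spec$layers <- c(spec$layers, list(
    list(kind = "fully_connected", out = flat),
    list(kind = "dropout", rate = dropout),
    list(kind = "fully_connected", out = as.integer(classes)),
    list(kind = "softmax"),
    list(kind = "classification", labels = class_labels)
  ))
  spec
}

#' Shape inference along the architecture
#'
#' Walks the layer list and computes the spatial edge and channel count
#' after every layer, plus the flatten width feeding the first fully
#' connected layer. Pooling output edge is `floor((n - k) / s) + 1`;
#' 'same' convolutions at stride 1 preserve the edge.
#'
#' @param spec an [divnet_spec()] architecture.
#' @return a list with `edges` (per conv/pool stage), `flatten` (features
#'   entering the first fully connected layer) and `table` (a tibble with
#'   one row per layer: kind, spatial edge, channels).
#' @export
infer_shapes <- function(spec) {
  edge <- spec$edge
  ch <- 1L
  rows <- list()
  edges <- integer()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv3d") {
      if (edge + (ly$kernel - 1L) < ly$kernel) stop("conv kernel exceeds padded input")
      edge <- as.integer(floor((edge + (ly$kernel - 1L) - ly$kernel) / ly$stride) + 1L)
      ch <- ly$filters
      edges <- c(edges, edge)
    } else if (ly$kind == "maxpool3d") {
      if (ly$kernel > edge) {
        stop("maxpool kernel ", ly$kernel, " exceeds spatial edge ", edge,
             " at layer ", i)
      }
      edge <- as.integer(floor((edge - ly$kernel) / ly$stride) + 1L)
      edges <- c(edges, edge)
    } else if (ly$kind == "fully_connected") {
      break
    }
    rows[[i]] <- tibble::tibble(layer = i, kind = ly$kind,
                                edge = edge, channels = ch)
  }
  flatten <- as.integer(edge^3 * ch)
  list(edges = edges, flatten = flatten,
       table = do.call(rbind, rows))
}

#' @export
print.sgt_architecture <- function(x, ...) {
  cat("divNet architecture:", length(x$layers), "layers; input edge",
      x$edge, "x", x$edge, "x", x$edge, ";", x$channels, "filters;",
      x$classes, "classes\n")
  invisible(x)
}

#' Per-layer learnable-parameter counts
#'
#' Counts every learnable in the architecture: convolution weights
#' `filters * k^3 * in_channels` plus per-filter bias, batch-norm offset and
#' scale, SGT alpha/beta (2 per channel, 0 for standard activations), and
#' fully connected weights/bias. At the reference scale this reproduces the
#' published counts (1728 / 512,000 / 1,404,928 / 2,985,984 conv weights and
#' 1728^2 = 2,985,984 first-FC weights).
#'
#' @param spec an [divnet_spec()] architecture.
#' @param activation_plan character vector of activation names per slot (see
#'   [activation_plan()]); defaults to all-SGT.
#' @return tibble with one row per layer: `layer`, `kind`, `weights`,
#'   `bias`, `extra` (alpha + beta counts), `total`.
#' @export
count_parameters <- function(spec, activation_plan = rep("sgt", 4L)) {
  in_ch <- 1L
  in_feat <- infer_shapes(spec)$flatten
  rows <- lapply(seq_along(spec$layers), function(i) {
    ly <- spec$layers[[i]]
    w <- b <- e <- 0
    if (ly$kind == "conv3d") {
      w <- ly$filters * ly$kernel^3 * in_ch
      b <- ly$filters
      in_ch <<- ly$filters
    } else if (ly$kind == "batchnorm") {
      b <- 2 * ly$channels                    # offset + scale
    } else if (ly$kind == "activation") {
      if (activation_plan[ly$slot] == "sgt") e <- 2 * ly$channels
    } else if (ly$kind == "fully_connected") {
      w <- ly$out * in_feat
      b <- ly$out
      in_feat <<- ly$out
    }
    tibble::tibble(layer = i, kind = ly$kind, weights = w, bias = b,
                   extra = e, total = w + b + e)
  })
  do.call(rbind, rows)
}

#' Named activation plans for the ablation grid
#'
#' Maps a plan name to the four activation-slot choices: `baseline`
#' (all Leaky-ReLU), `relu`, `tanh`, `leaky_relu`, `swish` (all four slots
#' the named function), `gamma2` (SGT in slots 1-2, ReLU elsewhere),
#' `gamma2_alt` (SGT in slots 1 and 3, ReLU elsewhere) and `gamma4`
#' (all SGT).
#'
#' @param plan plan name, or a character vector of 4 activation names taken
#'   as-is.
#' @return character vector of length 4.
#' @export
activation_plan <- function(plan = "gamma4") {
  known <- c("sgt", "relu", "leaky_relu", "tanh", "swish")
  if (length(plan) == 4L) {
    bad <- setdiff(plan, known)
    if (length(bad)) stop("unknown activation name(s): ", paste(bad, collapse = ", "))
    return(plan)
  }
  switch(plan,
    baseline = ,
    leaky_relu = rep("leaky_relu", 4L),
    relu = rep("relu", 4L),
    tanh = rep("tanh", 4L),
    swish = rep("swish", 4L),
    gamma2 = c("sgt", "sgt", "relu", "relu"),
    gamma2_alt = c("sgt", "relu", "sgt", "relu"),
    gamma4 = rep("sgt", 4L),
    stop("unknown activation plan '", plan, "'")
  )
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Allocate and initialize a network
#'
#' Conv/FC weights use Glorot (uniform) initialization with variance
#' `2 / (fan_in + fan_out)`; SGT exponents alpha, beta are drawn uniformly
#' from (0, 1) per channel; batch-norm starts at offset 0, scale 1 with
#' unit running variance. Deterministic given `seed`.
#'
#' @param spec an [divnet_spec()] architecture.
#' @param plan activation plan name or 4-vector (see [activation_plan()]).
#' @param seed integer RNG seed.
#' @return object of class `sgt_network`.
#' @export
build_network <- function(spec, plan = "gamma4", seed = 1L) {
  acts <- activation_plan(plan)
  set.seed(seed)
  in_ch <- 1L
  in_feat <- infer_shapes(spec)$flatten
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv3d") {
      k <- ly$kernel
      fan_in <- k^3 * in_ch
      fan_out <- k^3 * ly$filters
      params[[i]] <- list(
        W = glorot_uniform(c(k, k, k, in_ch, ly$filters), fan_in, fan_out),
        b = numeric(ly$filters)
      )
      in_ch <- ly$filters
    } else if (ly$kind == "batchnorm") {
      params[[i]] <- list(
        offset = numeric(ly$channels), scale = rep(1, ly$channels),
        running_mean = numeric(ly$channels), running_var = rep(1, ly$channels)
      )
    } else if (ly$kind == "activation" && acts[ly$slot] == "sgt") {
      params[[i]] <- list(alpha = stats::runif(ly$channels),
                          beta = stats::runif(ly$channels))
    } else if (ly$kind == "fully_connected") {
      params[[i]] <- list(
        W = glorot_uniform(c(ly$out, in_feat), in_feat, ly$out),
        b = numeric(ly$out)
      )
      in_feat <- ly$out
    }
  }
  structure(
    list(spec = spec, activations = acts, params = params,
         norm_state = NULL, seed = seed),
    class = "sgt_network"
  )
}

#' @export
print.sgt_network <- function(x, ...) {
  cat("sgt_network:", x$spec$edge, "^3 input,", x$spec$channels,
      "filters, plan [", paste(x$activations, collapse = ", "), "]\n")
  invisible(x)
}

sgt_params_of <- function(network, i) {
  p <- network$params[[i]]
  sgt_params(alpha = p$alpha, beta = p$beta)
}

#' Forward pass through the network
#'
#' Runs a batch through every layer. Softmax probabilities sum to 1 per
#' sample; dropout is active only in `"train"` mode; the returned cache is
#' sufficient for [backward_pass()].
#'
#' @param network an [build_network()] object.
#' @param X input tensor `(batch, 1, edge, edge, edge)`.
#' @param mode `"train"` or `"eval"`.
#' @return list with `probs` (batch x classes matrix), `logits`, `cache`
#'   (per-layer), and the updated `network` (running batch-norm
#'   statistics change in train mode).
#' @export
forward_pass <- function(network, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  spec <- network$spec
  if (length(dim(X)) != 5L || dim(X)[2L] != 1L || !all(dim(X)[3:5] == spec$edge)) {
    stop("forward_pass: input must be (batch, 1, ", spec$edge, ", ",
         spec$edge, ", ", spec$edge, ")")
  }
  cur <- X
  flat <- NULL
  cache <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    p <- network$params[[i]]
    if (ly$kind == "input") {
      # zero-center normalization is applied upstream (see zero_center())
    } else if (ly$kind == "conv3d") {
      cache[[i]] <- list(X = cur)
      cur <- conv3d_same(cur, p$W, p$b, ly$stride)
    } else if (ly$kind == "batchnorm") {
      bn <- batchnorm3d(cur, p$offset, p$scale,
                        state = p[c("running_mean", "running_var")],
                        mode = mode)
      network$params[[i]]$running_mean <- bn$state$running_mean
      network$params[[i]]$running_var <- bn$state$running_var
      cache[[i]] <- bn$cache
      cur <- bn$Y
    } else if (ly$kind == "activation") {
      nm <- network$activations[ly$slot]
      sp <- if (nm == "sgt") sgt_params_of(network, i) else NULL
      act <- activation_forward(nm, cur, sp)
      cache[[i]] <- act$cache
      cur <- act$Z
    } else if (ly$kind == "maxpool3d") {
      mp <- maxpool3d(cur, ly$kernel, ly$stride)
      cache[[i]] <- list(argmax = mp$argmax, dim = dim(cur))
      cur <- mp$Y
    } else if (ly$kind == "fully_connected") {
      if (is.null(flat)) {
        flat <- dim(cur)
        cur <- matrix(cur, nrow = dim(cur)[1L])  # batch-fastest flatten
        cache[[i - 1L]]$flat_from <- flat
      }
      cache[[i]] <- list(X = cur)
      cur <- fully_connected(cur, p$W, p$b)
    } else if (ly$kind == "dropout") {
      dr <- dropout_forward(cur, ly$rate, mode)
      cache[[i]] <- list(mask = dr$mask)
      cur <- dr$Y
    } else if (ly$kind == "softmax") {
      logits <- cur
      cur <- softmax_rows(cur)
      cache[[i]] <- list(probs = cur)
    }
  }
  list(probs = cur, logits = logits, cache = cache, network = network,
       mode = mode)
}

#' Backward pass: gradients for every learnable
#'
#' Given the forward cache (train mode) and the loss gradient with respect
#' to the softmax probabilities' logits (`dlogits`), propagates back through
#' every layer. SGT layers use the layer's own backward rules
#' ([sgt_backward_input()] and [sgt_backward_params()]).
#'
#' @param network the network returned inside [forward_pass()].
#' @param fwd the [forward_pass()] result (must be train mode for dropout).
#' @param dlogits gradient at the logits, `(batch, classes)`.
#' @return named list of gradient arrays, keys `"L<i>.<param>"` matching the
#'   parameter layout.
#' @export
backward_pass <- function(network, fwd, dlogits) {
  spec <- network$spec
  cache <- fwd$cache
  if (is.null(cache)) stop("backward_pass: missing forward cache")
  grads <- list()
  cur <- dlogits
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    p <- network$params[[i]]
    if (ly$kind == "fully_connected") {
      bk <- fully_connected_backward(cache[[i]]$X, p$W, cur)
      grads[[paste0("L", i, ".W")]] <- bk$dW
      grads[[paste0("L", i, ".b")]] <- bk$db
      cur <- bk$dX
    } else if (ly$kind == "dropout") {
      if (!is.null(cache[[i]]$mask)) cur <- cur * cache[[i]]$mask
    } else if (ly$kind == "maxpool3d") {
      if (!is.null(cache[[i]]$flat_from)) {
        cur <- array(cur, dim = cache[[i]]$flat_from)
      }
      cur <- maxpool3d_backward(cur, cache[[i]]$argmax, cache[[i]]$dim)
    } else if (ly$kind == "activation") {
      nm <- network$activations[ly$slot]
      if (nm == "sgt") {
        sp <- sgt_params_of(network, i)
        pg <- sgt_backward_params(cache[[i]], cur, sp)
        grads[[paste0("L", i, ".alpha")]] <- pg$dalpha
        grads[[paste0("L", i, ".beta")]] <- pg$dbeta
        cur <- sgt_backward_input(cache[[i]], cur, sp)
      } else {
        cur <- activation_backward(nm, cache[[i]], cur)
      }
    } else if (ly$kind == "batchnorm") {
      bk <- batchnorm3d_backward(cache[[i]], cur)
      grads[[paste0("L", i, ".offset")]] <- bk$doffset
      grads[[paste0("L", i, ".scale")]] <- bk$dscale
      cur <- bk$dX
    } else if (ly$kind == "conv3d") {
      bk <- conv3d_backward(cache[[i]]$X, p$W, cur, ly$stride)
      grads[[paste0("L", i, ".W")]] <- bk$dW
      grads[[paste0("L", i, ".b")]] <- bk$db
      cur <- bk$dX
    }
  }
  grads
}

# Flat named parameter access, mirrored by the optimizers.
get_params <- function(network) {
  learnable <- c("W", "b", "offset", "scale", "alpha", "beta")
  out <- list()
  for (i in seq_along(network$params)) {
    p <- network$params[[i]]
    for (nm in intersect(names(p), learnable)) {
      out[[paste0("L", i, ".", nm)]] <- p[[nm]]
    }
  }
  out
}

set_params <- function(network, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    i <- as.integer(sub("^L", "", parts[1L]))
    old <- network$params[[i]][[parts[2L]]]
    network$params[[i]][[parts[2L]]] <-
      if (is.null(dim(old))) as.numeric(flat[[key]]) else
        array(flat[[key]], dim = dim(old))
  }
  network
}

#' Save / load a network checkpoint
#'
#' Serializes the full network state (architecture, activation plan, every
#' parameter array, batch-norm running statistics, and any attached
#' normalization state) to a single file; loading restores it bit-exactly.
#'
#' @param network an `sgt_network`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the network.
#' @export
save_checkpoint <- function(network, path) {
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
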