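#' Architecture configuration for the attention U-Net
#'
#' The network is a 2D encoder--decoder. The encoder stacks conv/BN/ReLU
#' blocks at `depth + 1` resolution levels (the last level is the
#' bottleneck), with a 2x2 max pooling between levels; by default 12
#' convolution blocks are distributed as `c(2, 2, 2, 3, 3)` over the five
#' levels, giving 12 conv blocks and 4 pooling stages. The decoder mirrors
#' the resolutions with bilinear upsampling followed by conv blocks, and an
#' attention gate sits in every skip connection. The gating signal is the
#' bottleneck feature map (resampled to each skip's resolution); setting
#' `gate_source = "adjacent_decoder"` instead wires the standard attention
#' U-Net variant where each gate is driven by the adjacent coarser decoder
#' feature.
#'
#' @param in_channels number of input image channels (1--3; one per MRI
#'   sequence).
#' @param out_channels number of output mask channels; the canonical four are
#'   left parotid, right parotid, left tumor, right tumor.
#' @param input_size spatial side length of the (square) model input; must be
#'   divisible by `2^depth`.
#' @param depth number of pooling stages.
#' @param base_filters channel count at the finest level; doubled at each
#'   coarser level.
#' @param encoder_block_allocation integer vector of length `depth + 1`: conv
#'   blocks per encoder level (bottleneck last). Any allocation with every
#'   entry >= 1 is accepted; the default sums to 12.
#' @param gate_source `"bottleneck"` (default) or `"adjacent_decoder"`.
#' @param attention_inter_div divisor mapping skip channels to the gate's
#'   intermediate channel count (default 2).
#' @return an object of class `unet_config`.
#' @export
model_config <- function(in_channels = 3L, out_channels = 4L,
                         input_size = 512L, depth = 4L, base_filters = 64L,
                         encoder_block_allocation = NULL,
                         gate_source = c("bottleneck", "adjacent_decoder"),
                         attention_inter_div = 2L) {
  gate_source <- match.arg(gate_source)
  if (is.null(encoder_block_allocation)) {
    encoder_block_allocation <- if (depth == 4L) c(2L, 2L, 2L, 3L, 3L) else
      rep(1L, depth + 1L)
  }
  in_channels <- as.integer(in_channels)
  depth <- as.integer(depth)
  input_size <- as.integer(input_size)
  if (in_channels < 1L) stop("in_channels must be >= 1")
  if (depth < 1L) stop("depth must be >= 1")
  if (input_size %% 2L^depth != 0L) {
    stop("input_size must be divisible by 2^depth")
  }
  if (length(encoder_block_allocation) != depth + 1L) {
    stop("encoder_block_allocation must have length depth + 1")
  }
  if (any(encoder_block_allocation < 1L)) {
    stop("every encoder level needs at least one conv block")
  }
  structure(list(
    in_channels = in_channels,
    out_channels = as.integer(out_channels),
    input_size = input_size,
    depth = depth,
    base_filters = as.integer(base_filters),
    encoder_block_allocation = as.integer(encoder_block_allocation),
    gate_source = gate_source,
    attention_inter_div = as.integer(attention_inter_div)
  ), class = "unet_config")
}

unet_filters <- function(config) config$base_filters * 2L^(0:config$depth)

init_conv <- function(P, prefix, k, cin, cout, bn = TRUE) {
  fan_in <- k * k * cin
  P[[paste0(prefix, "_W")]] <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                                     c(k, k, cin, cout))
  P[[paste0(prefix, "_b")]] <- numeric(cout)
  if (bn) {
    P[[paste0(prefix, "_g")]] <- rep(1, cout)
    P[[paste0(prefix, "_be")]] <- numeric(cout)
  }
  P
}

init_state <- function(S, prefix, cout) {
  S[[paste0(prefix, "_rm")]] <- numeric(cout)
  S[[paste0(prefix, "_rv")]] <- rep(1, cout)
  S
}

gate_channels_for <- function(config, level) {
  filt <- unet_filters(config)
  if (config$gate_source == "bottleneck") filt[config$depth + 1L] else filt[level + 1L]
}

# Prefix bookkeeping shared by init, forward and backward.
unet_topology <- function(config) {
  depth <- config$depth
  filt <- unet_filters(config)
  alloc <- config$encoder_block_allocation
  enc <- list()
  for (l in seq_len(depth)) {
    cin <- if (l == 1L) config$in_channels else filt[l - 1L]
    enc[[l]] <- lapply(seq_len(alloc[l]), function(k) {
      list(prefix = sprintf("enc%d_b%d", l, k),
           cin = if (k == 1L) cin else filt[l], cout = filt[l])
    })
  }
  bot <- lapply(seq_len(alloc[depth + 1L]), function(k) {
    list(prefix = sprintf("bot_b%d", k),
         cin = if (k == 1L) filt[depth] else filt[depth + 1L],
         cout = filt[depth + 1L])
  })
  dec <- lapply(seq_len(depth), function(l) {
    list(up = list(prefix = sprintf("dec%d_up", l), cin = filt[l + 1L], cout = filt[l]),
         merge = list(prefix = sprintf("dec%d_merge", l), cin = 2L * filt[l], cout = filt[l]),
         gate = list(prefix = sprintf("dec%d_gate", l), skip_ch = filt[l],
                     gate_ch = gate_channels_for(config, l),
                     inter = max(1L, filt[l] %/% config$attention_inter_div)))
  })
  list(enc = enc, bot = bot, dec = dec, filt = filt)
}

#' Build an attention U-Net segmentation model
#'
#' Initializes all parameters (He-normal convolution weights, unit-gain batch
#' norm) under the given seed; two builds with the same configuration and
#' seed are bit-identical.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for parameter initialization.
#' @return an object of class `parotid_unet`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  topo <- unet_topology(config)
  with_local_seed(seed, {
    P <- list(); S <- list()
    for (lvl in topo$enc) for (b in lvl) {
      P <- init_conv(P, b$prefix, 3L, b$cin, b$cout)
      S <- init_state(S, b$prefix, b$cout)
    }
    for (b in topo$bot) {
      P <- init_conv(P, b$prefix, 3L, b$cin, b$cout)
      S <- init_state(S, b$prefix, b$cout)
    }
    for (d in topo$dec) {
      P <- init_conv(P, d$up$prefix, 3L, d$up$cin, d$up$cout)
      S <- init_state(S, d$up$prefix, d$up$cout)
      P <- init_conv(P, d$merge$prefix, 3L, d$merge$cin, d$merge$cout)
      S <- init_state(S, d$merge$prefix, d$merge$cout)
      g <- d$gate
      P <- init_conv(P, paste0(g$prefix, "_x"), 1L, g$skip_ch, g$inter, bn = FALSE)
      P <- init_conv(P, paste0(g$prefix, "_g"), 1L, g$gate_ch, g$inter, bn = FALSE)
      P <- init_conv(P, paste0(g$prefix, "_p"), 1L, g$inter, 1L, bn = FALSE)
      # rename to the gate parameter scheme (_Wx/_bx/_Wg/_bg/_Wp/_bp)
      for (suf in c("x", "g", "p")) {
        P[[paste0(g$prefix, "_W", suf)]] <- P[[paste0(g$prefix, "_", suf, "_W")]]
        P[[paste0(g$prefix, "_b", suf)]] <- P[[paste0(g$prefix, "_", suf, "_b")]]
        P[[paste0(g$prefix, "_", suf, "_W")]] <- NULL
        P[[paste0(g$prefix, "_", suf, "_b")]] <- NULL
      }
    }
    P <- init_conv(P, "out", 1L, topo$filt[1L], config$out_channels, bn = FALSE)
    structure(list(config = config, params = P, state = S, topology = topo),
              class = "parotid_unet")
  })
}

#' Structural summary of a model
#'
#' Counts conv blocks and pooling stages by inspecting the parameter set, for
#' verifying the architecture contract (e.g. 12 encoder conv blocks and 4 max
#' pooling stages in the default configuration).
#'
#' @param model a `parotid_unet`.
#' @return list with `encoder_conv_blocks` (bottleneck included),
#'   `max_pool_stages`, `decoder_conv_blocks`, `attention_gates`, `n_params`.
#' @export
model_summary <- function(model) {
  nm <- names(model$params)
  conv_w <- grep("_W$", nm, value = TRUE)
  list(
    encoder_conv_blocks = sum(grepl("^(enc|bot)", conv_w)),
    max_pool_stages = model$config$depth,
    decoder_conv_blocks = sum(grepl("^dec[0-9]+_(up|merge)_W$", nm)),
    attention_gates = sum(grepl("_gate_Wp$", nm)),
    n_params = sum(vapply(model$params, length, 1L))
  )
}

#' @export
print.parotid_unet <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf(
    paste0("Attention U-Net (%s gating): %dx%dx%d -> %dx%dx%d\n",
           "  encoder: %d conv blocks, %d max-pool stages; decoder: %d conv blocks, %d gates\n",
           "  parameters: %s\n"),
    x$config$gate_source, x$config$input_size, x$config$input_size,
    x$config$in_channels, x$config$input_size, x$config$input_size,
    x$config$out_channels, s$encoder_conv_blocks, s$max_pool_stages,
    s$decoder_conv_blocks, s$attention_gates, format(s$n_params, big.mark = ",")))
  invisible(x)
}

#' Forward pass of the attention U-Net
#'
#' @param model a `parotid_unet`.
#' @param x input tensor, array of dim `(H, W, in_channels, batch)`; a 3D
#'   `(H, W, C)` array is treated as a batch of one.
#' @param train logical; use batch statistics (and update running statistics)
#'   in batch norm. Inference uses the running statistics.
#' @param want_masks return the per-level attention masks.
#' @return list with `y` (sigmoid outputs in (0,1), same spatial dims,
#'   `out_channels` channels), and `masks` (when requested, finest level
#'   first). Internally also the cache/context when `keep = TRUE`.
#' @export
unet_forward <- function(model, x, train = FALSE, want_masks = FALSE,
                         keep = FALSE) {
  config <- model$config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3L] != config$in_channels) {
    stop(sprintf("input has %d channels, model expects %d", d[3L], config$in_channels))
  }
  if (d[1L] %% 2L^config$depth != 0L || d[2L] %% 2L^config$depth != 0L) {
    stop("input spatial dims must be divisible by 2^depth")
  }
  P <- model$params
  topo <- model$topology
  depth <- config$depth
  ctx <- new.env(parent = emptyenv())
  ctx$state <- model$state
  ctx$cache <- list()

  skips <- vector("list", depth)
  pool_idx <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    for (b in topo$enc[[l]]) {
      cur <- conv_block_fwd(P, ctx, b$prefix, cur, train, keep)
    }
    skips[[l]] <- cur
    mp <- maxpool2_fwd_cpp(cur)
    pool_idx[[l]] <- mp$idx
    cur <- mp$y
  }
  for (b in topo$bot) cur <- conv_block_fwd(P, ctx, b$prefix, cur, train, keep)
  bottleneck <- cur

  masks <- vector("list", depth)
  entering <- vector("list", depth)  # decoder input spatial dims per level
  for (l in rev(seq_len(depth))) {
    gate_src <- if (config$gate_source == "bottleneck") bottleneck else cur
    entering[[l]] <- dim(cur)[1:2]
    sk_dim <- dim(skips[[l]])
    up <- resize_bilinear_fwd_cpp(cur, sk_dim[1L], sk_dim[2L])
    if (keep) ctx$cache[[sprintf("dec%d_upresize", l)]] <- dim(cur)[1:2]
    up <- conv_block_fwd(P, ctx, topo$dec[[l]]$up$prefix, up, train, keep)
    gf <- attention_gate_fwd(P, ctx, topo$dec[[l]]$gate$prefix, skips[[l]],
                             gate_src, keep)
    masks[[l]] <- gf$mask
    cur <- conv_block_fwd(P, ctx, topo$dec[[l]]$merge$prefix,
                          concat_channels(gf$gated, up), train, keep)
  }
  logits <- conv2d(cur, P$out_W, P$out_b)
  y <- sigmoid(logits)
  if (keep) {
    ctx$cache$out_in <- cur
    ctx$cache$pool_idx <- pool_idx
    ctx$cache$skip_dims <- lapply(skips, function(s) dim(s))
    ctx$cache$entering <- entering
  }
  res <- list(y = y)
  if (want_masks) res$masks <- masks
  if (keep) res$ctx <- ctx
  res
}

#' Predict on a single (H, W, C) or batched input in inference mode
#'
#' Thin wrapper over [unet_forward()] with batch norm in eval mode.
#'
#' @inheritParams unet_forward
#' @return array of sigmoid outputs.
#' @export
predict_batch <- function(model, x) unet_forward(model, x, train = FALSE)$y

#' Apply an attention gate to a skip/gating feature pair
#'
#' Standalone functional form of the gate used in the skip connections:
#' additive attention with 1x1 projections, ReLU, a single-channel sigmoid
#' mask, and multiplicative gating of the skip features. Exposed for
#' inspection and testing; inside the network the gating signal is the
#' bottleneck feature map resampled to the skip resolution.
#'
#' @param skip_features array `(H, W, C_skip, N)`.
#' @param gate_features array `(H, W, C_gate, N)` on the same spatial grid.
#' @param params named list with elements `Wx`, `bx`, `Wg`, `bg`, `Wp`, `bp`
#'   (1x1 convolution kernels `(1, 1, cin, cout)` and bias vectors).
#' @return list with `gated` (mask times skip) and `mask` (values in (0,1)).
#' @export
attention_gate <- function(skip_features, gate_features, params) {
  if (length(dim(skip_features)) == 3L) dim(skip_features) <- c(dim(skip_features), 1L)
  if (length(dim(gate_features)) == 3L) dim(gate_features) <- c(dim(gate_features), 1L)
  if (!all(dim(skip_features)[c(1L, 2L, 4L)] == dim(gate_features)[c(1L, 2L, 4L)])) {
    stop("skip and gate features must share spatial and batch dims")
  }
  P <- list()
  for (suf in c("Wx", "bx", "Wg", "bg", "Wp", "bp")) {
    P[[paste0("ag_", suf)]] <- params[[suf]]
  }
  ctx <- new.env(parent = emptyenv())
  ctx$cache <- list()
  attention_gate_fwd(P, ctx, "ag", skip_features, gate_features, keep = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, parameters and batch-norm running
#' statistics.
#'
#' @param model a `parotid_unet`.
#' @param path file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(model[c("config", "params", "state")], path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config, seed = 0L)
  model$params <- obj$params
  model$state <- obj$state
  model
}
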