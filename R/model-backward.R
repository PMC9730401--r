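# Reverse-mode pass through the static U-Net graph. `fwd` must come from
# unet_forward(..., keep = TRUE); `dy` is the loss gradient with respect to
# the sigmoid output. Returns the named parameter-gradient list (same names
# as model$params).

unet_backward <- function(model, fwd, dy) {
  config <- model$config
  P <- model$params
  topo <- model$topology
  ctx <- fwd$ctx
  depth <- config$depth
  filt <- topo$filt
  G <- new.env(parent = emptyenv())
  G$g <- list()

  dlogits <- dy * fwd$y * (1 - fwd$y)
  cg <- conv2d_grad(ctx$cache$out_in, P$out_W, dlogits)
  add_grad(G, "out_W", cg$gw)
  add_grad(G, "out_b", cg$gb)
  dcur <- cg$gx

  dskip_extra <- vector("list", depth)
  dbot_gates <- NULL
  for (l in seq_len(depth)) {
    dcat <- conv_block_bwd(P, ctx, topo$dec[[l]]$merge$prefix, dcur, G)
    sp <- split_channels(dcat, filt[l])
    dup <- conv_block_bwd(P, ctx, topo$dec[[l]]$up$prefix, sp$second, G)
    ent <- ctx$cache[[sprintf("dec%d_upresize", l)]]
    denter <- resize_bilinear_bwd_cpp(dup, ent[1L], ent[2L])
    gb <- attention_gate_bwd(P, ctx, topo$dec[[l]]$gate$prefix, sp$first, G)
    dskip_extra[[l]] <- gb$dskip
    # dg arrives on the gate source's native grid (bottleneck or the
    # decoder feature entering this level)
    if (config$gate_source == "bottleneck") {
      dbot_gates <- if (is.null(dbot_gates)) gb$dg else dbot_gates + gb$dg
    } else {
      denter <- denter + gb$dg
    }
    dcur <- denter
  }
  dbot <- if (is.null(dbot_gates)) dcur else dcur + dbot_gates
  for (b in rev(topo$bot)) dbot <- conv_block_bwd(P, ctx, b$prefix, dbot, G)

  ddown <- dbot
  for (l in rev(seq_len(depth))) {
    skd <- ctx$cache$skip_dims[[l]]
    dlev <- maxpool2_bwd_cpp(ctx$cache$pool_idx[[l]], ddown, skd[1L], skd[2L]) +
      dskip_extra[[l]]
    for (b in rev(topo$enc[[l]])) dlev <- conv_block_bwd(P, ctx, b$prefix, dlev, G)
    ddown <- dlev
  }
  list(grads = G$g, dx = ddown)
}
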