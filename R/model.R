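#' Model configuration
#'
#' Configuration of the fusion network: an attention + gated-recurrent-unit
#' message-passing encoder for the complex graph (4 rounds), a graph
#' isomorphism network for the ligand graph (3 layers), an optional
#' single-linear fingerprint branch, and one linear output head mapping the
#' concatenated embedding to a scalar pK.
#'
#' @param complex_dim length of the complex embedding (best ablation: 128)
#' @param ligand_dim length of the ligand embedding (best ablation: 32)
#' @param fp_dim output length of the fingerprint branch
#' @param hidden_complex hidden node-state width of the complex encoder
#' @param hidden_ligand hidden width of the GIN perceptrons
#' @param gnn_layers message-passing rounds over the complex graph
#' @param gin_layers GIN layers over the ligand graph
#' @param dropout dropout probability on node states during training
#' @param attention_heads number of additive-attention heads
#' @param use_fingerprints subset of `c("sifp", "ecif", "cfp")`
#' @param mode `"fusion"`, `"complex_only"` or `"ligand_only"`
#' @return a `ModelConfig` object
#' @export
model_config <- function(complex_dim = 128L, ligand_dim = 32L, fp_dim = 64L,
                         hidden_complex = 16L, hidden_ligand = 32L,
                         gnn_layers = 4L, gin_layers = 3L, dropout = 0.1,
                         attention_heads = 1L,
                         use_fingerprints = character(0),
                         mode = c("fusion", "complex_only", "ligand_only")) {
  mode <- match.arg(mode)
  stopifnot(
    complex_dim >= 1, ligand_dim >= 1, fp_dim >= 1, hidden_complex >= 1,
    hidden_ligand >= 1, gnn_layers >= 1, gin_layers >= 1,
    dropout >= 0, dropout < 1, attention_heads >= 1,
    all(use_fingerprints %in% c("sifp", "ecif", "cfp"))
  )
  structure(
    list(
      complex_dim = as.integer(complex_dim), ligand_dim = as.integer(ligand_dim),
      fp_dim = as.integer(fp_dim), hidden_complex = as.integer(hidden_complex),
      hidden_ligand = as.integer(hidden_ligand),
      gnn_layers = as.integer(gnn_layers), gin_layers = as.integer(gin_layers),
      dropout = dropout, attention_heads = as.integer(attention_heads),
      use_fingerprints = use_fingerprints, mode = mode
    ),
    class = "ModelConfig"
  )
}

#' Ablation variants
#'
#' Returns the configuration with one branch disabled: `complex_only` keeps
#' only the complex-graph embedding, `ligand_only` only the ligand-graph
#' embedding, `fusion` both.
#'
#' @param config a [model_config()]
#' @param mode `"complex_only"`, `"ligand_only"` or `"fusion"`
#' @return modified `ModelConfig`
#' @export
ablation_variant <- function(config, mode) {
  if (!mode %in% c("complex_only", "ligand_only", "fusion")) {
    lgn_stop("unknown ablation mode: %s", mode)
  }
  config$mode <- mode
  config
}

# Width of the fingerprint-branch input for a config.
fp_input_dim <- function(config) {
  dims <- c(sifp = SIFP_LENGTH, ecif = ECIF_LENGTH, cfp = CFP_BITS)
  sum(dims[config$use_fingerprints])
}

#' Length of the fused feature vector
#'
#' Sum of the enabled branch dimensions: the concatenated embedding the
#' output head sees.
#'
#' @param config a [model_config()]
#' @return integer
#' @export
fused_length <- function(config) {
  n <- 0L
  if (config$mode %in% c("fusion", "complex_only")) n <- n + config$complex_dim
  if (config$mode %in% c("fusion", "ligand_only")) n <- n + config$ligand_dim
  if (length(config$use_fingerprints) > 0) n <- n + config$fp_dim
  n
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model weights
#'
#' Uniform Glorot initialization, zero biases, GIN epsilons at 0; seeded and
#' deterministic. The returned model carries the configuration, the
#' featurization version, and an identity label transform (set by
#' [train_model()] to the training-set mean/sd).
#'
#' @param config a [model_config()]
#' @param seed integer seed
#' @return an `lgn_model` object
#' @export
init_model <- function(config, seed = 1L) {
  with_seed(seed, {
    H <- config$hidden_complex
    K <- config$complex_dim
    par <- list()
    if (config$mode %in% c("fusion", "complex_only")) {
      par$W0 <- glorot(COMPLEX_NODE_DIM, H); par$b0 <- numeric(H)
      par$Wm <- glorot(H + COMPLEX_EDGE_DIM, H); par$bm <- numeric(H)
      par$Wa <- glorot(2 * H, H); par$ba <- numeric(H)
      par$va <- glorot(H, config$attention_heads)
      for (nm in c("z", "r", "h")) {
        par[[paste0("W", nm, "g")]] <- glorot(H, H)
        par[[paste0("U", nm, "g")]] <- glorot(H, H)
        par[[paste0("b", nm, "g")]] <- numeric(H)
      }
      par$wg <- glorot(H, 1); par$bg <- 0
      par$Wp <- glorot(H, K); par$bp <- numeric(K)
    }
    if (config$mode %in% c("fusion", "ligand_only")) {
      HL <- config$hidden_ligand
      din <- LIGAND_NODE_DIM
      for (t in seq_len(config$gin_layers)) {
        dout <- if (t == config$gin_layers) config$ligand_dim else HL
        par[[paste0("gin_eps", t)]] <- 0
        par[[paste0("gin_W1_", t)]] <- glorot(din, HL)
        par[[paste0("gin_b1_", t)]] <- numeric(HL)
        par[[paste0("gin_W2_", t)]] <- glorot(HL, dout)
        par[[paste0("gin_b2_", t)]] <- numeric(dout)
        din <- dout
      }
    }
    if (length(config$use_fingerprints) > 0) {
      par$Wf <- glorot(fp_input_dim(config), config$fp_dim)
      par$bf <- numeric(config$fp_dim)
    }
    # zero-initialized head: training starts predicting the label mean
    par$w_out <- matrix(0, fused_length(config), 1)
    par$b_out <- 0
    structure(
      list(
        params = par, config = config,
        featurization = FEATURIZATION_VERSION,
        label_center = 0, label_scale = 1
      ),
      class = "lgn_model"
    )
  })
}

#' @export
print.lgn_model <- function(x, ...) {
  cat(sprintf(
    "<lgn_model: mode %s, fused length %d, %d parameters>\n",
    x$config$mode, fused_length(x$config), n_parameters(x)
  ))
  invisible(x)
}

#' Number of trainable scalars in a model
#' @param model an `lgn_model`
#' @return integer
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# row-wise bias add without sweep()'s aperm overhead
addb <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

# ---- batched forward / backward -------------------------------------------

# Collate featurized samples (list entries with $complex, $ligand, $fp) into
# one block-diagonal batch.
collate_batch <- function(samples) {
  B <- length(samples)
  out <- list(B = B)
  if (!is.null(samples[[1]]$complex)) {
    sizes <- vapply(samples, function(s) s$complex$num_nodes, integer(1))
    offs <- cumsum(c(0L, sizes[-B]))
    out$cx <- do.call(rbind, lapply(samples, function(s) s$complex$node_features))
    ce <- do.call(rbind, Map(function(s, o) s$complex$edges + o, samples, offs))
    storage.mode(ce) <- "integer"
    out$cedge <- ce
    out$cf <- do.call(rbind, lapply(samples, function(s) s$complex$edge_features))
    out$cnode_graph <- rep(seq_len(B), sizes)
    out$cN <- sum(sizes)
  }
  if (!is.null(samples[[1]]$ligand)) {
    sizes <- vapply(samples, function(s) s$ligand$num_nodes, integer(1))
    offs <- cumsum(c(0L, sizes[-B]))
    out$lx <- do.call(rbind, lapply(samples, function(s) s$ligand$node_features))
    le <- do.call(rbind, Map(function(s, o) s$ligand$edges + o, samples, offs))
    storage.mode(le) <- "integer"
    out$ledge <- le
    out$lnode_graph <- rep(seq_len(B), sizes)
    out$lN <- sum(sizes)
  }
  if (!is.null(samples[[1]]$fp)) {
    out$fp <- do.call(rbind, lapply(samples, function(s) s$fp))
  }
  out
}

# Forward pass of the complex encoder on a collated batch. Round caches are
# kept when `keep_cache` so the backward pass avoids recomputation.
forward_complex <- function(par, cfg, batch, training = FALSE,
                            keep_cache = training) {
  src <- batch$cedge[, 1]
  dst <- batch$cedge[, 2]
  N <- batch$cN
  h <- tanh(addb(batch$cx %*% par$W0, par$b0))
  hs_list <- vector("list", cfg$gnn_layers + 1)
  mask_list <- vector("list", cfg$gnn_layers)
  round_list <- vector("list", cfg$gnn_layers)
  hs_list[[1]] <- h
  for (t in seq_len(cfg$gnn_layers)) {
    st <- complex_round(par, cfg, h, src, dst, batch$cf, N)
    h <- st$h
    if (training && cfg$dropout > 0) {
      mask <- matrix(
        stats::rbinom(length(h), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
        nrow(h), ncol(h)
      )
      h <- h * mask
      mask_list[[t]] <- mask
    }
    hs_list[[t + 1]] <- h
    if (keep_cache) round_list[[t]] <- st
  }
  # graph-level readout: softmax attention over nodes (weights sum to 1 per
  # graph), so the embedding scale is independent of graph size
  q <- drop(h %*% par$wg) + par$bg
  a <- softmax_by_group(q, batch$cnode_graph, batch$B)
  P <- tanh(addb(h %*% par$Wp, par$bp))
  emb <- rowsum_mat(a * P, batch$cnode_graph, batch$B)
  list(emb = emb, hs = hs_list, masks = mask_list, rounds = round_list,
       a = a, P = P)
}

# One message-passing round: edge messages conditioned on edge features,
# additive attention over incoming edges, GRU node-state update.
complex_round <- function(par, cfg, h, src, dst, F, N) {
  Min <- cbind(h[src, , drop = FALSE], F)
  M <- relu(addb(Min %*% par$Wm, par$bm))
  Ain <- cbind(h[dst, , drop = FALSE], M)
  U <- tanh(addb(Ain %*% par$Wa, par$ba))
  e <- U %*% par$va
  heads <- ncol(e)
  alpha <- matrix(0, nrow(e), heads)
  for (k in seq_len(heads)) alpha[, k] <- softmax_by_group(e[, k], dst, N)
  am <- if (heads == 1) alpha[, 1] else rowMeans(alpha)
  C <- rowsum_mat(am * M, dst, N)
  z <- sigmoid(addb(C %*% par$Wzg + h %*% par$Uzg, par$bzg))
  r <- sigmoid(addb(C %*% par$Wrg + h %*% par$Urg, par$brg))
  htil <- tanh(addb(C %*% par$Whg + (r * h) %*% par$Uhg, par$bhg))
  hn <- (1 - z) * h + z * htil
  list(h = hn, M = M, Min = Min, Ain = Ain, U = U, alpha = alpha, am = am,
       C = C, z = z, r = r, htil = htil)
}

# Backward through the complex encoder. `fw` is the forward cache; `demb`
# the gradient at the complex embedding (B x K).
backward_complex <- function(par, cfg, batch, fw, demb, grads) {
  src <- batch$cedge[, 1]
  dst <- batch$cedge[, 2]
  N <- batch$cN
  heads <- cfg$attention_heads
  h <- fw$hs[[cfg$gnn_layers + 1]]
  a <- fw$a
  P <- fw$P

  # softmax-attention readout backward
  daP <- demb[batch$cnode_graph, , drop = FALSE]
  da <- rowSums(daP * P)
  dP <- daP * a
  dPpre <- dP * (1 - P^2)
  grads$Wp <- grads$Wp + crossprod(h, dPpre)
  grads$bp <- grads$bp + colSums(dPpre)
  dh <- dPpre %*% t(par$Wp)
  s <- rowsum_vec(a * da, batch$cnode_graph, batch$B)
  dq <- a * (da - s[batch$cnode_graph])
  grads$wg <- grads$wg + crossprod(h, matrix(dq))
  grads$bg <- grads$bg + sum(dq)
  dh <- dh + outer(dq, drop(par$wg))

  for (t in rev(seq_len(cfg$gnn_layers))) {
    if (!is.null(fw$masks[[t]])) dh <- dh * fw$masks[[t]]
    hp <- fw$hs[[t]]
    st <- fw$rounds[[t]]
    if (is.null(st)) st <- complex_round(par, cfg, hp, src, dst, batch$cf, N)
    z <- st$z; r <- st$r; htil <- st$htil
    # GRU backward
    dz <- dh * (htil - hp)
    dhtil <- dh * z
    dhp <- dh * (1 - z)
    dhtilp <- dhtil * (1 - htil^2)
    dC <- dhtilp %*% t(par$Whg)
    drh <- dhtilp %*% t(par$Uhg)
    dr <- drh * hp
    dhp <- dhp + drh * r
    grads$Whg <- grads$Whg + crossprod(st$C, dhtilp)
    grads$Uhg <- grads$Uhg + crossprod(r * hp, dhtilp)
    grads$bhg <- grads$bhg + colSums(dhtilp)
    drp <- dr * r * (1 - r)
    dC <- dC + drp %*% t(par$Wrg)
    dhp <- dhp + drp %*% t(par$Urg)
    grads$Wrg <- grads$Wrg + crossprod(st$C, drp)
    grads$Urg <- grads$Urg + crossprod(hp, drp)
    grads$brg <- grads$brg + colSums(drp)
    dzp <- dz * z * (1 - z)
    dC <- dC + dzp %*% t(par$Wzg)
    dhp <- dhp + dzp %*% t(par$Uzg)
    grads$Wzg <- grads$Wzg + crossprod(st$C, dzp)
    grads$Uzg <- grads$Uzg + crossprod(hp, dzp)
    grads$bzg <- grads$bzg + colSums(dzp)
    # C = rowsum(alpha_mean * M by dst)
    dam_M <- dC[dst, , drop = FALSE]
    dam <- rowSums(dam_M * st$M)
    dM <- dam_M * st$am
    de <- matrix(0, length(dam), heads)
    for (k in seq_len(heads)) {
      a_k <- st$alpha[, k]
      da_k <- dam / heads
      sk <- rowsum_vec(a_k * da_k, dst, N)
      de[, k] <- a_k * (da_k - sk[dst])
    }
    dU <- de %*% t(par$va)
    grads$va <- grads$va + crossprod(st$U, de)
    dUpre <- dU * (1 - st$U^2)
    grads$Wa <- grads$Wa + crossprod(st$Ain, dUpre)
    grads$ba <- grads$ba + colSums(dUpre)
    dAin <- dUpre %*% t(par$Wa)
    H <- cfg$hidden_complex
    dhd <- dAin[, seq_len(H), drop = FALSE]
    dM <- dM + dAin[, H + seq_len(H), drop = FALSE]
    dMpre <- dM * (st$M > 0)
    grads$Wm <- grads$Wm + crossprod(st$Min, dMpre)
    grads$bm <- grads$bm + colSums(dMpre)
    dMin <- dMpre %*% t(par$Wm)
    dhs <- dMin[, seq_len(H), drop = FALSE]
    dhp <- dhp + rowsum_mat(dhd, dst, N) + rowsum_mat(dhs, src, N)
    dh <- dhp
  }
  h0 <- fw$hs[[1]]
  dh0pre <- dh * (1 - h0^2)
  grads$W0 <- grads$W0 + crossprod(batch$cx, dh0pre)
  grads$b0 <- grads$b0 + colSums(dh0pre)
  grads
}

# Forward pass of the GIN ligand encoder; ligand graphs are small, so all
# intermediates are cached.
forward_ligand <- function(par, cfg, batch, training = FALSE) {
  src <- batch$ledge[, 1]
  dst <- batch$ledge[, 2]
  N <- batch$lN
  h <- batch$lx
  layers <- vector("list", cfg$gin_layers)
  for (t in seq_len(cfg$gin_layers)) {
    S <- if (length(src) > 0) {
      rowsum_mat(h[src, , drop = FALSE], dst, N)
    } else {
      matrix(0, N, ncol(h))
    }
    a <- (1 + par[[paste0("gin_eps", t)]]) * h + S
    Z1 <- addb(a %*% par[[paste0("gin_W1_", t)]], par[[paste0("gin_b1_", t)]])
    A1 <- relu(Z1)
    hn <- addb(A1 %*% par[[paste0("gin_W2_", t)]], par[[paste0("gin_b2_", t)]])
    mask <- NULL
    if (training && cfg$dropout > 0 && t < cfg$gin_layers) {
      mask <- matrix(
        stats::rbinom(length(hn), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
        nrow(hn), ncol(hn)
      )
      hn <- hn * mask
    }
    layers[[t]] <- list(h_in = h, a = a, Z1 = Z1, A1 = A1, mask = mask)
    h <- hn
  }
  emb <- rowsum_mat(h, batch$lnode_graph, batch$B)
  list(emb = emb, layers = layers)
}

backward_ligand <- function(par, cfg, batch, fw, demb, grads) {
  src <- batch$ledge[, 1]
  dst <- batch$ledge[, 2]
  N <- batch$lN
  dh <- demb[batch$lnode_graph, , drop = FALSE] # sum-pool backward
  for (t in rev(seq_len(cfg$gin_layers))) {
    ly <- fw$layers[[t]]
    if (!is.null(ly$mask)) dh <- dh * ly$mask
    grads[[paste0("gin_W2_", t)]] <- grads[[paste0("gin_W2_", t)]] +
      crossprod(ly$A1, dh)
    grads[[paste0("gin_b2_", t)]] <- grads[[paste0("gin_b2_", t)]] + colSums(dh)
    dA1 <- dh %*% t(par[[paste0("gin_W2_", t)]])
    dZ1 <- dA1 * (ly$Z1 > 0)
    grads[[paste0("gin_W1_", t)]] <- grads[[paste0("gin_W1_", t)]] +
      crossprod(ly$a, dZ1)
    grads[[paste0("gin_b1_", t)]] <- grads[[paste0("gin_b1_", t)]] + colSums(dZ1)
    da <- dZ1 %*% t(par[[paste0("gin_W1_", t)]])
    eps_nm <- paste0("gin_eps", t)
    grads[[eps_nm]] <- grads[[eps_nm]] + sum(da * ly$h_in)
    dh <- (1 + par[[eps_nm]]) * da
    if (length(src) > 0) {
      dh <- dh + rowsum_mat(da[dst, , drop = FALSE], src, N)
    }
  }
  grads
}

# Full forward pass on a collated batch. Returns predictions in pK units
# plus caches for the backward pass.
forward_model <- function(model, batch, training = FALSE) {
  par <- model$params
  cfg <- model$config
  parts <- list()
  fwc <- fwl <- NULL
  if (cfg$mode %in% c("fusion", "complex_only")) {
    fwc <- forward_complex(par, cfg, batch, training)
    parts$complex <- fwc$emb
  }
  if (cfg$mode %in% c("fusion", "ligand_only")) {
    fwl <- forward_ligand(par, cfg, batch, training)
    parts$ligand <- fwl$emb
  }
  if (length(cfg$use_fingerprints) > 0) {
    if (is.null(batch$fp)) lgn_stop("model expects fingerprints but batch has none")
    parts$fp <- addb(batch$fp %*% par$Wf, par$bf)
  }
  feat <- do.call(cbind, parts)
  out_std <- drop(feat %*% par$w_out) + par$b_out
  preds <- out_std * model$label_scale + model$label_center
  list(preds = preds, feat = feat, fwc = fwc, fwl = fwl)
}

# Backward pass: dpreds is dLoss/dpred (length B). Returns the gradient list.
backward_model <- function(model, batch, fw, dpreds) {
  par <- model$params
  cfg <- model$config
  grads <- lapply(par, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)) * 0)
  dout <- dpreds * model$label_scale
  grads$w_out <- grads$w_out + crossprod(fw$feat, matrix(dout))
  grads$b_out <- grads$b_out + sum(dout)
  dfeat <- outer(dout, drop(par$w_out))
  off <- 0L
  if (cfg$mode %in% c("fusion", "complex_only")) {
    dc <- dfeat[, off + seq_len(cfg$complex_dim), drop = FALSE]
    grads <- backward_complex(par, cfg, batch, fw$fwc, dc, grads)
    off <- off + cfg$complex_dim
  }
  if (cfg$mode %in% c("fusion", "ligand_only")) {
    dl <- dfeat[, off + seq_len(cfg$ligand_dim), drop = FALSE]
    grads <- backward_ligand(par, cfg, batch, fw$fwl, dl, grads)
    off <- off + cfg$ligand_dim
  }
  if (length(cfg$use_fingerprints) > 0) {
    df <- dfeat[, off + seq_len(cfg$fp_dim), drop = FALSE]
    grads$Wf <- grads$Wf + crossprod(batch$fp, df)
    grads$bf <- grads$bf + colSums(df)
  }
  grads
}

#' Predict binding affinity
#'
#' Deterministic forward pass (dropout disabled) over featurized samples.
#'
#' @param object an `lgn_model`
#' @param samples list of featurized samples (see [featurize_dataset()])
#' @param ... unused
#' @return numeric vector of pK predictions
#' @export
predict.lgn_model <- function(object, samples, ...) {
  if (length(samples) == 0) return(numeric(0))
  batch <- collate_batch(samples)
  forward_model(object, batch, training = FALSE)$preds
}

#' Featurize a dataset for the model
#'
#' Builds, per complex, the complex graph, the ligand graph, and the enabled
#' fingerprint vector (count fingerprints enter as `log1p` of the counts;
#' CFP bits enter as 0/1), as the configured mode requires.
#'
#' @param dataset result of [gen_dataset()] or an equivalent list with
#'   `complexes` and `records`
#' @param config a [model_config()]
#' @param contact_cutoff intermolecular cutoff for the complex graph
#' @return list of featurized samples with a `labels` attribute
#' @export
featurize_dataset <- function(dataset, config, contact_cutoff = 5.0) {
  need_c <- config$mode %in% c("fusion", "complex_only")
  need_l <- config$mode %in% c("fusion", "ligand_only")
  fps <- config$use_fingerprints
  samples <- lapply(dataset$complexes, function(cx) {
    s <- list()
    if (need_c) s$complex <- build_complex_graph(cx$pocket, cx$ligand,
                                                 contact_cutoff)
    if (need_l) s$ligand <- build_ligand_graph(cx$ligand)
    if (length(fps) > 0) {
      v <- list()
      if ("sifp" %in% fps) v$sifp <- log1p(compute_sifp(cx$pocket, cx$ligand))
      if ("ecif" %in% fps) v$ecif <- log1p(compute_ecif(cx$pocket, cx$ligand))
      if ("cfp" %in% fps) v$cfp <- as.numeric(compute_cfp(cx$ligand))
      s$fp <- unlist(v, use.names = FALSE)
    }
    s
  })
  attr(samples, "labels") <- dataset$records$label_pk
  attr(samples, "complex_id") <- dataset$records$complex_id
  samples
}

#' Save / load a model checkpoint
#'
#' Weights, full configuration and the featurization version hash in one
#' RDS file; loading refuses a featurization-version mismatch.
#'
#' @param model an `lgn_model`
#' @param path file path
#' @return `path` (write) / the model (read)
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "lgn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "lgn_model")) lgn_stop("%s is not an lgn model checkpoint", path)
  if (!identical(m$featurization, FEATURIZATION_VERSION)) {
    lgn_stop("featurization version mismatch: checkpoint %s, package %s",
             m$featurization, FEATURIZATION_VERSION)
  }
  m
}
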