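#' Encoder hyperparameters
#'
#' Sizes and structure of the token encoder: word-embedding dimension,
#' character-CNN dimensions, the convolution stack (two regular convolutions
#' followed by `blocks` iterations of a shared dilated block), the attention
#' scope, and dropout applied after each block iteration during training.
#' Defaults are sized for desk-scale corpora; all dimensions scale up by
#' configuration.
#'
#' @param d_w Word embedding dimension.
#' @param d_char Character embedding dimension.
#' @param char_width Character convolution window (odd).
#' @param d_char_feat Character feature dimension (max-pooled conv filters).
#' @param filters Convolution filters per layer.
#' @param width Token convolution window (odd).
#' @param dilations Dilation rates of one block.
#' @param blocks Number of iterations of the shared dilated block.
#' @param activation Activation inside the convolution stack (`"relu"`,
#'   `"tanh"`, or `"linear"`).
#' @param dropout Dropout rate on block outputs during training.
#' @param max_doc_len Maximum number of document tokens attended to.
#' @return Object of class `mnp_encoder_config`.
#' @export
encoder_config <- function(d_w = 50L, d_char = 16L, char_width = 3L,
                           d_char_feat = 16L, filters = 64L, width = 3L,
                           dilations = c(1L, 1L, 2L), blocks = 4L,
                           activation = "relu", dropout = 0.2,
                           max_doc_len = 512L) {
  stopifnot(d_w > 0L, d_char > 0L, d_char_feat > 0L, filters > 0L,
            width %% 2L == 1L, char_width %% 2L == 1L,
            length(dilations) >= 1L, all(dilations >= 1L), blocks >= 1L,
            dropout >= 0, dropout < 1, max_doc_len >= 1L)
  structure(list(d_w = as.integer(d_w), d_char = as.integer(d_char),
                 char_width = as.integer(char_width),
                 d_char_feat = as.integer(d_char_feat),
                 filters = as.integer(filters), width = as.integer(width),
                 dilations = as.integer(dilations),
                 blocks = as.integer(blocks), activation = activation,
                 dropout = dropout, max_doc_len = as.integer(max_doc_len)),
            class = "mnp_encoder_config")
}

glorot <- function(fan_in, fan_out, nrow_, ncol_) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

# He-uniform over the whole kernel fan-in: keeps the variance of the ReLU
# convolution stack roughly constant with depth, which matters for a stack
# of 14 layers feeding bounded tanh emissions.
conv_params <- function(prefix, d_in, d_out, width) {
  lim <- sqrt(6 / (d_in * width))
  out <- list()
  for (k in seq_len(width)) {
    out[[paste0(prefix, ".W", k)]] <-
      matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
  }
  out[[paste0(prefix, ".b")]] <- rep(0, d_out)
  out
}

#' Initialize a tagging model
#'
#' Builds the flat parameter list of the full tagger: word/character
#' embeddings, character CNN, the IDCNN stack, the attention layer (for the
#' `"att-idcnn-crf"` variant), the emission projection, and the CRF
#' transition matrix (zero-initialized). Weights use Glorot-uniform
#' initialization under the given seed.
#'
#' @param vocab A [build_vocab()] result (or compatible list).
#' @param types Entity types; the tag set is their BIO expansion.
#' @param config An [encoder_config()].
#' @param variant `"att-idcnn-crf"` (with document attention) or
#'   `"idcnn-crf"` (emissions straight from the convolution stack).
#' @param seed Integer seed for initialization.
#' @param scheme Tagging scheme for [tag_set()].
#' @return Object of class `mnp_model`.
#' @export
new_model <- function(vocab, types, config = encoder_config(),
                      variant = c("att-idcnn-crf", "idcnn-crf"),
                      seed = 1L, scheme = "BIO") {
  variant <- match.arg(variant)
  tags <- tag_set(types, scheme = scheme)
  K <- length(tags)
  d_x <- config$d_w + config$d_char_feat
  Fl <- config$filters
  params <- with_seed(seed, {
    p <- list()
    p$E_word <- {
      lim <- sqrt(3 / config$d_w)
      M <- matrix(stats::runif((length(vocab$words) + 2L) * config$d_w,
                               -lim, lim),
                  length(vocab$words) + 2L, config$d_w)
      M[.PAD, ] <- 0
      M
    }
    p$E_char <- {
      lim <- sqrt(3 / config$d_char)
      M <- matrix(stats::runif((length(vocab$chars) + 2L) * config$d_char,
                               -lim, lim),
                  length(vocab$chars) + 2L, config$d_char)
      M[.PAD, ] <- 0
      M
    }
    p <- c(p, conv_params("char", config$d_char, config$d_char_feat,
                          config$char_width))
    p <- c(p, conv_params("conv0a", d_x, Fl, config$width))
    p <- c(p, conv_params("conv0b", Fl, Fl, config$width))
    for (j in seq_along(config$dilations)) {
      p <- c(p, conv_params(paste0("blk", j), Fl, Fl, config$width))
    }
    if (variant == "att-idcnn-crf") {
      lim <- sqrt(6 / (2 * d_x + 1))
      p$att.ma <- stats::runif(d_x, -lim, lim)
      p$att.mb <- stats::runif(d_x, -lim, lim)
      p$att.Mv <- glorot(2 * Fl, Fl, Fl, 2 * Fl)
      p$att.bv <- rep(0, Fl)
    }
    p$emit.W <- glorot(Fl, K, K, Fl)
    p$emit.b <- rep(0, K)
    p$trans <- matrix(0, K + 2L, K + 2L)
    p
  })
  word_map <- stats::setNames(seq_along(vocab$words) + 2L,
                              tolower(vocab$words))
  char_map <- stats::setNames(seq_along(vocab$chars) + 2L, vocab$chars)
  structure(list(params = params, config = config, variant = variant,
                 types = types, tags = tags, scheme = scheme,
                 word_map = word_map, char_map = char_map),
            class = "mnp_model")
}

#' @export
print.mnp_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<mnp_model> %s: %d tags, vocab %d, %d parameters\n",
              x$variant, length(x$tags), length(x$word_map), n_par))
  invisible(x)
}

# Integer encoding of a document for the model: per-sentence word ids and
# per-token character ids.
encode_doc <- function(model, doc) {
  sent_tokens <- lapply(doc$sentences, function(s) s$tokens$token)
  list(tokens = sent_tokens,
       word_ids = lapply(sent_tokens, function(tk) word_id(model$word_map, tk)),
       char_ids = lapply(sent_tokens, function(tk) {
         lapply(tk, function(t) char_ids(model$char_map, t))
       }),
       lengths = vapply(sent_tokens, length, integer(1)))
}

# Character-CNN features for a flat list of tokens (list of char-id
# vectors). Tokens are laid out consecutively with `h` zero gap rows in
# between so one batched convolution equals per-token zero padding.
# Returns the pooled features plus the cache needed for backprop.
char_features <- function(params, config, char_id_list) {
  h <- (config$char_width - 1L) %/% 2L
  lens <- vapply(char_id_list, length, integer(1))
  n_tok <- length(char_id_list)
  starts <- integer(n_tok)
  pos <- 1L
  for (k in seq_len(n_tok)) {
    starts[k] <- pos
    pos <- pos + lens[k] + h
  }
  total <- pos - 1L
  ids <- rep(NA_integer_, total)
  for (k in seq_len(n_tok)) {
    ids[starts[k]:(starts[k] + lens[k] - 1L)] <- char_id_list[[k]]
  }
  real <- which(!is.na(ids))
  C <- matrix(0, total, config$d_char)
  C[real, ] <- params$E_char[ids[real], , drop = FALSE]
  Ws <- params[paste0("char.W", seq_len(config$char_width))]
  pre <- conv1d(C, Ws, params$char.b, 1L)
  out <- pmax(pre, 0)
  feats <- matrix(0, n_tok, config$d_char_feat)
  amax <- matrix(0L, n_tok, config$d_char_feat)
  for (k in seq_len(n_tok)) {
    rows <- starts[k]:(starts[k] + lens[k] - 1L)
    M <- out[rows, , drop = FALSE]
    j <- max.col(t(M), ties.method = "first")
    amax[k, ] <- rows[j]
    feats[k, ] <- M[cbind(j, seq_len(ncol(M)))]
  }
  list(feats = feats, amax = amax, C = C, pre = pre, out = out,
       ids = ids, real = real)
}

char_features_backward <- function(params, config, cache, d_feats) {
  d_out <- matrix(0, nrow(cache$C), config$d_char_feat)
  for (k in seq_len(nrow(d_feats))) {
    d_out[cbind(cache$amax[k, ], seq_len(ncol(d_feats)))] <-
      d_out[cbind(cache$amax[k, ], seq_len(ncol(d_feats)))] + d_feats[k, ]
  }
  d_pre <- d_out * (cache$pre > 0)
  Ws <- params[paste0("char.W", seq_len(config$char_width))]
  bk <- conv1d_backward(cache$C, Ws, 1L, d_pre)
  g <- list()
  for (k in seq_len(config$char_width)) g[[paste0("char.W", k)]] <- bk$dWs[[k]]
  g$char.b <- bk$db
  dE_char <- matrix(0, nrow(params$E_char), config$d_char)
  agg <- rowsum(bk$dH[cache$real, , drop = FALSE], cache$ids[cache$real])
  dE_char[as.integer(rownames(agg)), ] <- agg
  dE_char[.PAD, ] <- 0
  g$E_char <- dE_char
  g
}

#' Embed tokens as word + character feature vectors
#'
#' Concatenates each token's word vector (case-folded lookup; out-of-
#' vocabulary tokens map to the unknown vector) with its pooled character-
#' convolution features. This is the input representation of the
#' convolution stack.
#'
#' @param tokens Character vector of tokens.
#' @param model An [new_model()] object.
#' @return `length(tokens) x (d_w + d_char_feat)` matrix.
#' @export
embed_tokens <- function(tokens, model) {
  stopifnot(length(tokens) >= 1L)
  wid <- word_id(model$word_map, tokens)
  cf <- char_features(model$params, model$config,
                      lapply(tokens, function(t) char_ids(model$char_map, t)))
  cbind(model$params$E_word[wid, , drop = FALSE], cf$feats)
}

# Batched forward pass over one or more documents. All sentences of all
# documents are laid out in one matrix with `gap` zero rows between them
# (re-zeroed after every convolution), which makes the batched convolution
# exactly equal per-sentence zero padding; the attention layer runs per
# document over that document's token rows. Returns per-document lists of
# per-sentence emission matrices plus the cache for backprop.
forward_batch <- function(model, encs, train = FALSE) {
  cfg <- model$config
  p <- model$params
  n_doc <- length(encs)
  lens <- lapply(encs, function(e) e$lengths)
  doc_ntok <- vapply(lens, sum, integer(1))
  if (any(doc_ntok == 0L)) stop("empty document")
  gap <- max(c(1L, cfg$dilations)) * ((cfg$width - 1L) %/% 2L)
  all_lens <- unlist(lens)
  n_sent <- length(all_lens)
  starts <- integer(n_sent)
  pos <- 1L
  for (s in seq_len(n_sent)) {
    starts[s] <- pos
    pos <- pos + all_lens[s] + gap
  }
  total <- pos - 1L
  real <- unlist(lapply(seq_len(n_sent), function(s) {
    starts[s]:(starts[s] + all_lens[s] - 1L)
  }))
  N <- length(real)
  tok_off <- c(0L, cumsum(doc_ntok)) # token ranges per document
  wid <- unlist(lapply(encs, function(e) unlist(e$word_ids)))
  cf <- char_features(p, cfg,
                      do.call(c, lapply(encs, function(e) {
                        do.call(c, e$char_ids)
                      })))
  Xr <- cbind(p$E_word[wid, , drop = FALSE], cf$feats)
  d_x <- ncol(Xr)
  X <- matrix(0, total, d_x)
  X[real, ] <- Xr

  defs <- idcnn_layers(cfg)
  H <- X
  Hin <- vector("list", length(defs))
  pres <- vector("list", length(defs))
  posts <- vector("list", length(defs))
  masks <- vector("list", length(defs))
  gaprows <- setdiff(seq_len(total), real)
  for (l in seq_along(defs)) {
    def <- defs[[l]]
    Hin[[l]] <- H
    Ws <- p[paste0(def$pname, ".W", seq_len(cfg$width))]
    pre <- conv1d(H, Ws, p[[paste0(def$pname, ".b")]], def$dilation)
    out <- apply_act(pre, cfg$activation)
    if (length(gaprows)) out[gaprows, ] <- 0
    pres[[l]] <- pre
    posts[[l]] <- out # unmasked: activation derivatives are taken on this
    if (train && cfg$dropout > 0 && def$block_end) {
      m <- matrix(stats::rbinom(length(out), 1L, 1 - cfg$dropout),
                  nrow(out), ncol(out)) / (1 - cfg$dropout)
      out <- out * m
      masks[[l]] <- m
    }
    H <- out
  }
  q <- H[real, , drop = FALSE]

  att <- NULL
  if (model$variant == "att-idcnn-crf") {
    att <- vector("list", n_doc)
    V <- matrix(0, N, cfg$filters)
    for (d in seq_len(n_doc)) {
      rows <- (tok_off[d] + 1L):tok_off[d + 1L]
      Xd <- Xr[rows, , drop = FALSE]
      ctx <- seq_len(min(length(rows), cfg$max_doc_len))
      u <- drop(Xd %*% p$att.ma)
      w <- drop(Xd %*% p$att.mb)[ctx]
      Fm <- tanh(outer(u, w, "+"))
      S <- exp(Fm - apply(Fm, 1L, max))
      S <- S / rowSums(S)
      V[rows, ] <- S %*% q[rows[ctx], , drop = FALSE]
      att[[d]] <- list(rows = rows, ctx = ctx, Fm = Fm, S = S)
    }
    Cat <- cbind(V, q)
    P <- tanh(cbind(Cat %*% t(p$att.Mv)) +
                rep(p$att.bv, each = N))
    top <- P
  } else {
    Cat <- NULL
    P <- NULL
    top <- q
  }
  Eout <- tanh(top %*% t(p$emit.W) + rep(p$emit.b, each = N))
  sent_off <- c(0L, cumsum(all_lens))
  k <- 0L
  emissions <- lapply(seq_len(n_doc), function(d) {
    lapply(seq_along(lens[[d]]), function(s) {
      k <<- k + 1L
      Eout[(sent_off[k] + 1L):sent_off[k + 1L], , drop = FALSE]
    })
  })
  list(emissions = emissions,
       cache = list(Xr = Xr, X = X, real = real, gaprows = gaprows,
                    wid = wid, cf = cf, defs = defs, Hin = Hin, pres = pres,
                    posts = posts, masks = masks, q = q, att = att,
                    Cat = Cat, P = P, top = top, Eout = Eout,
                    tok_off = tok_off, N = N))
}

# Backward pass through the full encoder given the gradient of the loss
# w.r.t. the stacked emission rows (documents and sentences in batch
# order). Returns a flat gradient list matching the model parameter names
# (CRF transition gradients are added by the caller).
backward_batch <- function(model, cache, d_E) {
  cfg <- model$config
  p <- model$params
  g <- list()
  d_pre_e <- d_E * (1 - cache$Eout^2)
  g$emit.W <- crossprod(d_pre_e, cache$top)
  g$emit.b <- colSums(d_pre_e)
  d_top <- d_pre_e %*% p$emit.W

  if (model$variant == "att-idcnn-crf") {
    d_pre_p <- d_top * (1 - cache$P^2)
    g$att.Mv <- crossprod(d_pre_p, cache$Cat)
    g$att.bv <- colSums(d_pre_p)
    d_cat <- d_pre_p %*% p$att.Mv
    Fl <- cfg$filters
    d_V <- d_cat[, seq_len(Fl), drop = FALSE]
    d_q <- d_cat[, Fl + seq_len(Fl), drop = FALSE]
    d_Xr_att <- matrix(0, cache$N, length(p$att.ma))
    g$att.ma <- 0
    g$att.mb <- 0
    for (a in cache$att) {
      rows <- a$rows
      ctx_rows <- rows[a$ctx]
      qc <- cache$q[ctx_rows, , drop = FALSE]
      d_Vd <- d_V[rows, , drop = FALSE]
      d_S <- d_Vd %*% t(qc)
      d_q[ctx_rows, ] <- d_q[ctx_rows, ] + crossprod(a$S, d_Vd)
      d_Fm <- a$S * (d_S - rowSums(d_S * a$S))
      d_G <- d_Fm * (1 - a$Fm^2)
      d_u <- rowSums(d_G)
      d_w <- colSums(d_G)
      Xd <- cache$Xr[rows, , drop = FALSE]
      Xc <- cache$Xr[ctx_rows, , drop = FALSE]
      g$att.ma <- g$att.ma + drop(crossprod(Xd, d_u))
      g$att.mb <- g$att.mb + drop(crossprod(Xc, d_w))
      d_Xr_att[rows, ] <- d_Xr_att[rows, ] + outer(d_u, p$att.ma)
      d_Xr_att[ctx_rows, ] <- d_Xr_att[ctx_rows, ] + outer(d_w, p$att.mb)
    }
  } else {
    d_q <- d_top
    d_Xr_att <- 0
  }

  d_H <- matrix(0, nrow(cache$X), cfg$filters)
  d_H[cache$real, ] <- d_q
  for (l in rev(seq_along(cache$defs))) {
    def <- cache$defs[[l]]
    if (!is.null(cache$masks[[l]])) d_H <- d_H * cache$masks[[l]]
    d_pre <- d_H * act_deriv(cache$pres[[l]], cache$posts[[l]],
                             cfg$activation)
    if (length(cache$gaprows)) d_pre[cache$gaprows, ] <- 0
    Ws <- p[paste0(def$pname, ".W", seq_len(cfg$width))]
    bk <- conv1d_backward(cache$Hin[[l]], Ws, def$dilation, d_pre)
    for (k in seq_len(cfg$width)) {
      nm <- paste0(def$pname, ".W", k)
      g[[nm]] <- if (is.null(g[[nm]])) bk$dWs[[k]] else g[[nm]] + bk$dWs[[k]]
    }
    nb <- paste0(def$pname, ".b")
    g[[nb]] <- if (is.null(g[[nb]])) bk$db else g[[nb]] + bk$db
    d_H <- bk$dH
  }
  d_Xr <- d_H[cache$real, , drop = FALSE] + d_Xr_att

  d_w_part <- d_Xr[, seq_len(cfg$d_w), drop = FALSE]
  dEw <- matrix(0, nrow(p$E_word), cfg$d_w)
  agg <- rowsum(d_w_part, cache$wid)
  dEw[as.integer(rownames(agg)), ] <- agg
  dEw[.PAD, ] <- 0
  g$E_word <- dEw

  d_feats <- d_Xr[, cfg$d_w + seq_len(cfg$d_char_feat), drop = FALSE]
  g <- c(g, char_features_backward(p, cfg, cache$cf, d_feats))
  g
}

# Single-document wrappers (the batch of one).
forward_doc <- function(model, enc, train = FALSE) {
  fw <- forward_batch(model, list(enc), train = train)
  list(emissions = fw$emissions[[1L]], cache = fw$cache)
}

backward_doc <- function(model, cache, d_E) {
  backward_batch(model, cache, d_E)
}

# Joint loss and gradients over a batch of documents: summed sentence NLL
# plus the full encoder backward pass.
batch_loss_grad <- function(model, encs, golds, train = FALSE) {
  fw <- forward_batch(model, encs, train = train)
  loss <- 0
  d_E_rows <- vector("list", length(encs))
  d_trans <- 0
  for (d in seq_along(encs)) {
    cp <- crf_params(fw$emissions[[d]], model$params$trans)
    cg <- crf_nll_grad(cp, golds[[d]])
    loss <- loss + cg$loss
    d_E_rows[[d]] <- do.call(rbind, cg$d_emissions)
    d_trans <- d_trans + cg$d_transitions
  }
  g <- backward_batch(model, fw$cache, do.call(rbind, d_E_rows))
  g$trans <- d_trans
  list(loss = loss, grads = g)
}

# Loss (summed sentence NLL) of one document; optionally with gradients.
model_loss <- function(model, enc, gold_paths, train = FALSE) {
  fw <- forward_doc(model, enc, train = train)
  cp <- crf_params(fw$emissions, model$params$trans)
  nll_loss(cp, gold_paths)
}

model_loss_grad <- function(model, enc, gold_paths, train = FALSE) {
  fw <- forward_doc(model, enc, train = train)
  cp <- crf_params(fw$emissions, model$params$trans)
  cg <- crf_nll_grad(cp, gold_paths)
  d_E <- do.call(rbind, cg$d_emissions)
  g <- backward_doc(model, fw$cache, d_E)
  g$trans <- cg$d_transitions
  list(loss = cg$loss, grads = g)
}
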