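# Core numeric operations of the encoder: row-shifted dilated convolutions
# and the document-level attention layer. All functions are pure; training
# state lives in the model object.

# result[i, ] = M[i + k, ], zero-padded outside the matrix.
shift_rows <- function(M, k) {
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  if (k == 0L) return(M)
  a <- abs(k)
  if (a >= n) return(out)
  if (k > 0L) out[seq_len(n - a), ] <- M[(a + 1L):n, , drop = FALSE]
  else out[(a + 1L):n, ] <- M[seq_len(n - a), , drop = FALSE]
  out
}

apply_act <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         tanh = tanh(x),
         linear = x,
         stop("unknown activation: ", activation))
}

act_deriv <- function(pre, post, activation) {
  switch(activation,
         relu = (pre > 0) + 0,
         tanh = 1 - post^2,
         linear = array(1, dim(pre)),
         stop("unknown activation: ", activation))
}

# One dilated 1D convolution along the rows of H (tokens x features).
# Ws is a list of per-tap weight matrices (d_in x d_out), taps at offsets
# (-h..h) * dilation for width = 2h + 1. Zero padding at the edges.
# Row-shifting commutes with right-multiplication, so each tap is one GEMM
# followed by a row-offset accumulation (no shifted copies of H).
conv1d <- function(H, Ws, b, dilation = 1L) {
  w <- length(Ws)
  h <- (w - 1L) %/% 2L
  offs <- ((-h):h) * dilation
  n <- nrow(H)
  out <- matrix(rep(b, each = n), n, length(b))
  for (k in seq_len(w)) {
    o <- offs[k]
    P <- H %*% Ws[[k]]
    if (o == 0L) {
      out <- out + P
    } else if (abs(o) < n) {
      if (o > 0L) {
        r <- seq_len(n - o)
        out[r, ] <- out[r, ] + P[r + o, , drop = FALSE]
      } else {
        r <- seq_len(n + o)
        out[r - o, ] <- out[r - o, ] + P[r, , drop = FALSE]
      }
    }
  }
  out
}

# Gradients of conv1d: returns d_H plus per-tap weight and bias gradients.
conv1d_backward <- function(H, Ws, dilation, d_pre) {
  w <- length(Ws)
  h <- (w - 1L) %/% 2L
  offs <- ((-h):h) * dilation
  n <- nrow(H)
  dWs <- vector("list", w)
  dH <- matrix(0, n, ncol(H))
  for (k in seq_len(w)) {
    o <- offs[k]
    if (o == 0L) {
      dWs[[k]] <- crossprod(H, d_pre)
      dH <- dH + d_pre %*% t(Ws[[k]])
    } else if (abs(o) < n) {
      if (o > 0L) {
        r <- seq_len(n - o) # out[i] reads H[i + o]
        dWs[[k]] <- crossprod(H[r + o, , drop = FALSE],
                              d_pre[r, , drop = FALSE])
        dH[r + o, ] <- dH[r + o, ] +
          d_pre[r, , drop = FALSE] %*% t(Ws[[k]])
      } else {
        r <- seq_len(n + o)
        dWs[[k]] <- crossprod(H[r, , drop = FALSE],
                              d_pre[r - o, , drop = FALSE])
        dH[r, ] <- dH[r, ] +
          d_pre[r - o, , drop = FALSE] %*% t(Ws[[k]])
      }
    } else {
      dWs[[k]] <- matrix(0, ncol(H), ncol(d_pre))
    }
  }
  list(dH = dH, dWs = dWs, db = colSums(d_pre))
}

#' Receptive field of the dilated convolution stack
#'
#' Closed form: each convolution of width `w` and dilation `d` widens the
#' receptive field by `(w - 1) * d` positions, so the stack's field is
#' `1 + sum((w - 1) * d)` over the two initial regular convolutions plus
#' every dilated layer of every block iteration.
#'
#' @param config An [encoder_config()].
#' @return Integer receptive field in tokens.
#' @export
receptive_field <- function(config) {
  per_block <- sum((config$width - 1L) * config$dilations)
  as.integer(1L + 2L * (config$width - 1L) + config$blocks * per_block)
}

#' Document-level attention weights
#'
#' Pairwise alignment scores `f(x_i, x_j) = tanh(m_a . x_i + m_b . x_j)`
#' (a weight vector over the concatenation of the two token vectors),
#' normalized per row with a softmax over the context positions of the
#' document, yielding the row-stochastic attention matrix `S`. With zero
#' weights every alignment score is `tanh(0) = 0` and all rows are uniform.
#'
#' @param X Numeric matrix (`N x d`): one input vector per document token.
#' @param m_a,m_b Numeric weight vectors of length `d` (the two halves of
#'   the alignment map over `[x_i; x_j]`).
#' @param context Integer indices of the positions that may be attended to
#'   (default: all `N`); positions beyond a model's maximum document length
#'   are masked by omission.
#' @return `N x length(context)` row-stochastic matrix.
#' @export
attention_scores <- function(X, m_a, m_b, context = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 1L,
            length(m_a) == ncol(X), length(m_b) == ncol(X))
  if (is.null(context)) context <- seq_len(nrow(X))
  if (length(context) == 0L) stop("attention requires at least one unmasked position")
  u <- drop(X %*% m_a)
  w <- drop(X %*% m_b)[context]
  Fm <- tanh(outer(u, w, "+"))
  S <- exp(Fm - apply(Fm, 1L, max))
  S / rowSums(S)
}

#' Attention context vectors
#'
#' `v_i = sum_j s_ij q_j`: each token's context is the attention-weighted
#' mean of the encoder outputs, so every `v_i` lies in the convex hull of
#' the rows of `Q`.
#'
#' @param S Row-stochastic attention matrix (`N x Nc`).
#' @param Q Encoder outputs over the context positions (`Nc x F`).
#' @param tol Tolerance for the row-stochasticity check.
#' @return `N x F` matrix of context vectors.
#' @export
attention_context <- function(S, Q, tol = 1e-6) {
  stopifnot(is.matrix(S), is.matrix(Q))
  if (ncol(S) != nrow(Q)) stop("attention/context dimension mismatch")
  if (any(S < -tol) || any(abs(rowSums(S) - 1) > tol)) {
    stop("S must be row-stochastic")
  }
  S %*% Q
}

#' Attention layer output
#'
#' `p_i = tanh(M_v [v_i; q_i] + b_v)`: each token's context vector is paired
#' with its own encoder output and projected through a tanh layer, so every
#' entry lies strictly inside (-1, 1).
#'
#' @param V Context vectors (`N x F`).
#' @param Q Encoder outputs (`N x F`).
#' @param M_v Projection matrix (`P x 2F`).
#' @param b_v Bias vector (length `P`).
#' @return `N x P` matrix.
#' @export
attention_output <- function(V, Q, M_v, b_v) {
  stopifnot(nrow(V) == nrow(Q), ncol(M_v) == ncol(V) + ncol(Q),
            length(b_v) == nrow(M_v))
  tanh(sweep(cbind(V, Q) %*% t(M_v), 2L, b_v, "+"))
}

#' Per-token tag scores
#'
#' `e_i = tanh(W_e p_i + b_e)`: a learned affine projection of the attention
#' output to tag-score space followed by tanh. The rows of the result form
#' the emission matrix consumed by the CRF.
#'
#' @param P Attention outputs (`N x P`), or encoder outputs for the variant
#'   without attention.
#' @param W_e Projection matrix (`K x P`), `K` = number of BIO tags.
#' @param b_e Bias vector (length `K`).
#' @return `N x K` matrix of tag scores in (-1, 1).
#' @export
emission_scores <- function(P, W_e, b_e) {
  stopifnot(ncol(W_e) == ncol(P), length(b_e) == nrow(W_e))
  tanh(sweep(P %*% t(W_e), 2L, b_e, "+"))
}

#' Run the iterated dilated convolution stack over one sequence
#'
#' Two regular width-`width` convolutions followed by `blocks` iterations of
#' the shared dilated block (dilations `config$dilations`), all with same
#' padding so sequence length is preserved. No dropout is applied (this is
#' the inference path; training uses the internal document forward pass).
#'
#' @param X Input sequence (`n x d_in`).
#' @param params Flat named parameter list as in a model's `$params`
#'   (entries `conv0a.*`, `conv0b.*`, `blk<j>.*`).
#' @param config An [encoder_config()].
#' @return `n x filters` matrix of per-token features.
#' @export
idcnn_encode <- function(X, params, config) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  if (nrow(X) > config$max_doc_len) {
    stop(sprintf("sequence of %d tokens exceeds the configured maximum of %d",
                 nrow(X), config$max_doc_len))
  }
  H <- X
  for (def in idcnn_layers(config)) {
    Ws <- params[paste0(def$pname, ".W", seq_len(config$width))]
    pre <- conv1d(H, Ws, params[[paste0(def$pname, ".b")]], def$dilation)
    H <- apply_act(pre, config$activation)
  }
  H
}

# Expanded layer sequence: the two initial convolutions, then the dilated
# block repeated `blocks` times with shared parameters per within-block layer.
idcnn_layers <- function(config) {
  defs <- list(list(pname = "conv0a", dilation = 1L, block_end = FALSE),
               list(pname = "conv0b", dilation = 1L, block_end = FALSE))
  for (it in seq_len(config$blocks)) {
    for (j in seq_along(config$dilations)) {
      defs[[length(defs) + 1L]] <-
        list(pname = paste0("blk", j),
             dilation = as.integer(config$dilations[j]),
             block_end = (j == length(config$dilations)))
    }
  }
  defs
}
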