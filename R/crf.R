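# Linear-chain CRF over BIO tag sequences. All math is in log space with
# 64-bit accumulation. Tags are 1..K; the transition matrix carries two extra
# states, START = K+1 and STOP = K+2, so the score of a path y over one
# sentence is
#   R[START, y_1] + sum_i O[i, y_i] + sum_{i>1} R[y_{i-1}, y_i] + R[y_n, STOP]
# and a document's score is the sum over its sentences (transitions never
# cross sentence boundaries).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Shared scalar max across columns: entries within one recursion step span
# a few tens of nats at most, far from the ~700-nat underflow range, so a
# single shift is as stable here as a per-column one and much cheaper.
col_logsumexp <- function(M) {
  m <- max(M)
  if (!is.finite(m)) return(rep(m, ncol(M)))
  m + log(colSums(exp(M - m)))
}

#' Bundle CRF parameters for a document
#'
#' @param emissions A numeric matrix (`n x K`, one sentence) or a list of
#'   such matrices (one per sentence of a document): per-token tag scores
#'   from the encoder.
#' @param transitions `(K+2) x (K+2)` tag-transition score matrix; rows/cols
#'   `K+1` and `K+2` are the START and STOP states.
#' @return Object of class `mnp_crf`.
#' @export
crf_params <- function(emissions, transitions) {
  if (is.matrix(emissions)) emissions <- list(emissions)
  stopifnot(is.list(emissions), length(emissions) >= 1L,
            is.matrix(transitions),
            nrow(transitions) == ncol(transitions))
  K <- ncol(emissions[[1L]])
  stopifnot(nrow(transitions) == K + 2L)
  for (E in emissions) {
    stopifnot(is.matrix(E), ncol(E) == K, nrow(E) >= 1L, all(is.finite(E)))
  }
  structure(list(emissions = emissions, transitions = transitions, K = K,
                 start = K + 1L, stop = K + 2L),
            class = "mnp_crf")
}

check_path <- function(params, y) {
  if (is.numeric(y)) y <- list(as.integer(y))
  stopifnot(length(y) == length(params$emissions))
  for (s in seq_along(y)) {
    if (length(y[[s]]) != nrow(params$emissions[[s]])) {
      stop("label path length does not match emission rows")
    }
    if (any(y[[s]] < 1L | y[[s]] > params$K)) stop("tag index out of range")
  }
  lapply(y, as.integer)
}

#' Score a label path
#'
#' Sum of transition and emission scores of path `y` under `params`,
#' including the START and STOP transitions, summed over the sentences of
#' the document.
#'
#' @param params A [crf_params()] object.
#' @param y Integer vector (single sentence) or list of integer vectors,
#'   tags in `1..K`.
#' @return Numeric scalar score.
#' @export
path_score <- function(params, y) {
  y <- check_path(params, y)
  R <- params$transitions
  total <- 0
  for (s in seq_along(y)) {
    E <- params$emissions[[s]]
    ys <- y[[s]]
    n <- length(ys)
    total <- total + R[params$start, ys[1L]] + R[ys[n], params$stop] +
      sum(E[cbind(seq_len(n), ys)])
    if (n > 1L) total <- total + sum(R[cbind(ys[-n], ys[-1L])])
  }
  total
}

# Forward recursion for one sentence: returns the n x K matrix of log-alpha
# values and log Z.
forward_sentence <- function(E, R, start, stop) {
  n <- nrow(E); K <- ncol(E)
  A <- matrix(0, n, K)
  A[1L, ] <- R[start, seq_len(K)] + E[1L, ]
  Rkk <- R[seq_len(K), seq_len(K), drop = FALSE]
  if (n > 1L) {
    for (t in 2L:n) {
      A[t, ] <- col_logsumexp(A[t - 1L, ] + Rkk) + E[t, ]
    }
  }
  list(alpha = A, logZ = logsumexp(A[n, ] + R[seq_len(K), stop]))
}

backward_sentence <- function(E, R, start, stop) {
  n <- nrow(E); K <- ncol(E)
  B <- matrix(0, n, K)
  B[n, ] <- R[seq_len(K), stop]
  Rkk <- R[seq_len(K), seq_len(K), drop = FALSE]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      # B[t, i] = lse_j( R[i, j] + E[t+1, j] + B[t+1, j] )
      M <- Rkk + rep(E[t + 1L, ] + B[t + 1L, ], each = K)
      B[t, ] <- col_logsumexp(t(M))
    }
  }
  B
}

#' Log-partition function
#'
#' `log` of the sum over all `K^n` label paths of the exponentiated path
#' score, computed exactly by the forward recursion in log space; summed over
#' the sentences of the document. Always at least the maximum path score.
#'
#' @param params A [crf_params()] object.
#' @return Numeric scalar.
#' @export
log_partition <- function(params) {
  R <- params$transitions
  sum(vapply(params$emissions, function(E) {
    forward_sentence(E, R, params$start, params$stop)$logZ
  }, numeric(1)))
}

#' Negative log-likelihood of a gold path
#'
#' `log_partition(params) - path_score(params, gold)`; non-negative, and zero
#' only when the gold path carries all probability mass.
#'
#' @param params A [crf_params()] object.
#' @param gold Gold label path (vector or list of vectors).
#' @return Numeric scalar loss.
#' @export
nll_loss <- function(params, gold) {
  log_partition(params) - path_score(params, gold)
}

#' Negative log-likelihood with analytic gradients
#'
#' Computes the loss of [nll_loss()] together with its exact gradients from
#' the forward-backward marginals: the gradient w.r.t. the emissions is
#' (posterior tag marginals - gold indicators), and the gradient w.r.t. the
#' transition matrix is (expected transition counts - gold transition
#' counts), including the START/STOP rows.
#'
#' @param params A [crf_params()] object.
#' @param gold Gold label path (vector or list of vectors).
#' @return List with `loss`, `d_emissions` (list of `n x K` matrices), and
#'   `d_transitions` (`(K+2) x (K+2)` matrix).
#' @export
crf_nll_grad <- function(params, gold) {
  gold <- check_path(params, gold)
  R <- params$transitions
  K <- params$K
  dR <- matrix(0, K + 2L, K + 2L)
  dE_list <- vector("list", length(params$emissions))
  loss <- 0
  for (s in seq_along(params$emissions)) {
    E <- params$emissions[[s]]
    ys <- gold[[s]]
    n <- nrow(E)
    fw <- forward_sentence(E, R, params$start, params$stop)
    B <- backward_sentence(E, R, params$start, params$stop)
    logZ <- fw$logZ
    A <- fw$alpha
    marg <- exp(A + B - logZ) # n x K posterior tag marginals
    dE <- marg
    dE[cbind(seq_len(n), ys)] <- dE[cbind(seq_len(n), ys)] - 1
    dE_list[[s]] <- dE
    # START / STOP rows
    dR[params$start, seq_len(K)] <- dR[params$start, seq_len(K)] + marg[1L, ]
    dR[params$start, ys[1L]] <- dR[params$start, ys[1L]] - 1
    dR[seq_len(K), params$stop] <- dR[seq_len(K), params$stop] + marg[n, ]
    dR[ys[n], params$stop] <- dR[ys[n], params$stop] - 1
    if (n > 1L) {
      Rkk <- R[seq_len(K), seq_len(K), drop = FALSE]
      for (t in 2L:n) {
        # pairwise posterior P(y_{t-1}=i, y_t=j)
        P <- exp((A[t - 1L, ] - logZ) + Rkk +
                   rep(E[t, ] + B[t, ], each = K))
        dR[seq_len(K), seq_len(K)] <- dR[seq_len(K), seq_len(K)] + P
        dR[ys[t - 1L], ys[t]] <- dR[ys[t - 1L], ys[t]] - 1
      }
    }
    gold_score <- R[params$start, ys[1L]] + R[ys[n], params$stop] +
      sum(E[cbind(seq_len(n), ys)]) +
      if (n > 1L) sum(R[cbind(ys[-n], ys[-1L])]) else 0
    loss <- loss + logZ - gold_score
  }
  list(loss = loss, d_emissions = dE_list, d_transitions = dR)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring label path per sentence; ties are broken
#' toward the lowest tag index at every backtrack step, so all-zero
#' parameters decode to the first tag everywhere.
#'
#' @param params A [crf_params()] object.
#' @return List with `paths` (list of integer vectors, one per sentence) and
#'   `score` (total score over the document, equal to
#'   `path_score(params, paths)`).
#' @export
viterbi_decode <- function(params) {
  R <- params$transitions
  K <- params$K
  paths <- vector("list", length(params$emissions))
  total <- 0
  for (s in seq_along(params$emissions)) {
    E <- params$emissions[[s]]
    n <- nrow(E)
    delta <- R[params$start, seq_len(K)] + E[1L, ]
    back <- matrix(0L, n, K)
    Rkk <- R[seq_len(K), seq_len(K), drop = FALSE]
    if (n > 1L) {
      for (t in 2L:n) {
        M <- delta + Rkk # M[i, j] = delta_i + R[i, j]
        best <- max.col(t(M), ties.method = "first") # first max = lowest index
        back[t, ] <- best
        delta <- M[cbind(best, seq_len(K))] + E[t, ]
      }
    }
    fin <- delta + R[seq_len(K), params$stop]
    y <- integer(n)
    y[n] <- which.max(fin)
    if (n > 1L) {
      for (t in n:2L) y[t - 1L] <- back[t, y[t]]
    }
    paths[[s]] <- y
    total <- total + fin[y[n]]
  }
  list(paths = paths, score = total)
}

#' Brute-force decoding oracle
#'
#' Exhaustively enumerates all `K^n` paths per sentence and returns the
#' argmax under the same tie-break rule as [viterbi_decode()] (among
#' maximum-score paths, the one that is lexicographically smallest read from
#' the last position backwards). Refuses instances with more than `10^6`
#' paths.
#'
#' @param params A [crf_params()] object.
#' @param tol Score tolerance within which paths count as tied.
#' @return List with `paths` and `score`, as [viterbi_decode()].
#' @export
brute_force_decode <- function(params, tol = 1e-9) {
  K <- params$K
  paths <- vector("list", length(params$emissions))
  total <- 0
  for (s in seq_along(params$emissions)) {
    E <- params$emissions[[s]]
    n <- nrow(E)
    if (K^n > 1e6) stop("instance too large for brute-force enumeration")
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    one <- crf_params(E, params$transitions)
    scores <- apply(grid, 1L, function(y) path_score(one, as.integer(y)))
    top <- which(scores >= max(scores) - tol)
    cand <- grid[top, , drop = FALSE]
    ord <- do.call(order, lapply(rev(seq_len(n)), function(j) cand[, j]))
    best <- as.integer(cand[ord[1L], ])
    paths[[s]] <- best
    total <- total + path_score(one, best)
  }
  list(paths = paths, score = total)
}

#' Log-partition by explicit enumeration (test oracle)
#'
#' @param params A [crf_params()] object.
#' @return Numeric scalar, `log` sum over all paths of `exp(path_score)`.
#' @export
brute_force_log_partition <- function(params) {
  K <- params$K
  total <- 0
  for (s in seq_along(params$emissions)) {
    E <- params$emissions[[s]]
    n <- nrow(E)
    if (K^n > 1e6) stop("instance too large for brute-force enumeration")
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    one <- crf_params(E, params$transitions)
    scores <- apply(grid, 1L, function(y) path_score(one, as.integer(y)))
    total <- total + logsumexp(scores)
  }
  total
}

#' Hard BIO-constraint mask for a transition matrix
#'
#' Optionally forbids structurally invalid BIO transitions (an `I-T`
#' following anything other than `B-T`/`I-T`, or opening a sentence) by
#' setting their scores to a large negative penalty. Off by default in
#' training and decoding — malformed decoder output is repaired in
#' [bio_to_spans()] instead — but useful when hard well-formedness is
#' preferred. The penalty is finite so all CRF routines remain applicable.
#'
#' @param transitions `(K+2) x (K+2)` transition matrix.
#' @param tags Tag vector of length `K`, as in a model's `$tags`.
#' @param penalty Score assigned to invalid transitions.
#' @return The masked transition matrix.
#' @export
constrain_transitions <- function(transitions, tags, penalty = -1e4) {
  K <- length(tags)
  stopifnot(nrow(transitions) == K + 2L)
  inside <- startsWith(tags, "I-")
  for (j in which(inside)) {
    tp <- substring(tags[j], 3L)
    ok <- tags %in% paste0(c("B-", "I-"), tp)
    transitions[c(which(!ok), K + 1L), j] <- pmin(
      transitions[c(which(!ok), K + 1L), j], penalty)
  }
  transitions
}
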