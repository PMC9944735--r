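#' Training configuration
#'
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size in documents.
#' @param lr Learning rate (Adam).
#' @param optimizer Optimizer name; only `"adam"` is implemented.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param variant Model variant: `"att-idcnn-crf"` or `"idcnn-crf"`.
#' @param patience Early-stopping patience on dev F (ignored without a dev
#'   set).
#' @param clip Global gradient-norm clip.
#' @return Object of class `mnp_train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 8L, lr = 1e-3,
                         optimizer = "adam", seed = 1L,
                         variant = c("att-idcnn-crf", "idcnn-crf"),
                         patience = 5L, clip = 5) {
  variant <- match.arg(variant)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, patience >= 1L, clip > 0)
  if (optimizer != "adam") stop("unrecognized optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, seed = as.integer(seed),
                 variant = variant, patience = as.integer(patience),
                 clip = clip),
            class = "mnp_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$E_word[.PAD, ] <- 0
  params$E_char[.PAD, ] <- 0
  list(params = params, state = state)
}

clip_grads <- function(grads, clip) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > clip) {
    grads <- lapply(grads, function(g) g * (clip / nrm))
  }
  grads
}

gold_paths <- function(model, doc) {
  lapply(doc$sentences, function(s) {
    tags <- spans_to_bio(s, scheme = model$scheme)
    idx <- match(tags, model$tags)
    if (anyNA(idx)) {
      stop("document contains entity types outside the model's tag set: ",
           paste(unique(tags[is.na(idx)]), collapse = ", "))
    }
    idx
  })
}

#' Train a tagging model
#'
#' Minimizes the mean per-sentence CRF negative log-likelihood by minibatch
#' Adam with global gradient-norm clipping. The run is fully reproducible
#' under `config$seed` (initialization, shuffling, dropout). When a dev set
#' is given, span-level F is computed each epoch and the best-scoring
#' parameters are restored at the end, with early stopping after
#' `config$patience` epochs without improvement. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param train_docs List of [annotated_document()] training documents.
#' @param config A [train_config()].
#' @param enc_config An [encoder_config()].
#' @param types Entity types (default: [mnp_types()]).
#' @param dev_docs Optional dev documents for early stopping.
#' @param pretrained Optional [embedding_table()] of pretrained word vectors
#'   used to initialize known rows of the word embedding matrix.
#' @param quiet Suppress per-epoch progress lines.
#' @return Object of class `mnp_fit`: list with `model`, `log` (one row per
#'   epoch: loss, dev F, seconds) and the configs.
#' @export
train <- function(train_docs, config = train_config(),
                  enc_config = encoder_config(), types = mnp_types(),
                  dev_docs = NULL, pretrained = NULL, quiet = FALSE) {
  stopifnot(length(train_docs) >= 1L)
  vocab <- build_vocab(train_docs)
  model <- new_model(vocab, types, config = enc_config,
                     variant = config$variant, seed = config$seed)
  if (!is.null(pretrained)) {
    stopifnot(pretrained$d == enc_config$d_w)
    hit <- match(names(model$word_map), names(pretrained$map))
    ok <- which(!is.na(hit))
    model$params$E_word[ok + 2L, ] <-
      pretrained$E[pretrained$map[hit[ok]], , drop = FALSE]
  }
  encs <- lapply(train_docs, function(d) encode_doc(model, d))
  golds <- lapply(train_docs, function(d) gold_paths(model, d))
  n_sent <- vapply(golds, length, integer(1))

  opt <- adam_init(model$params)
  log_rows <- vector("list", config$epochs)
  best <- list(f = -Inf, params = model$params, epoch = 0L)
  bad_epochs <- 0L

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(length(train_docs))
      ep_loss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        lg <- batch_loss_grad(model, encs[b], golds[b], train = TRUE)
        b_loss <- lg$loss
        if (!is.finite(b_loss)) {
          stop(sprintf("training diverged (non-finite loss) in epoch %d", ep))
        }
        ns <- sum(n_sent[b])
        acc <- lapply(lg$grads, function(g) g / ns)
        acc <- clip_grads(acc, config$clip)
        st <- adam_step(model$params, acc, opt, config$lr)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + b_loss
      }
      mean_loss <- ep_loss / sum(n_sent)
      dev_f <- NA_real_
      if (!is.null(dev_docs)) {
        pred <- predict_docs(model, dev_docs)
        dev_f <- prf(match_predictions(dev_docs, pred))[["f"]]
        if (dev_f > best$f) {
          best <- list(f = dev_f, params = model$params, epoch = ep)
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      }
      secs <- proc.time()[["elapsed"]] - t0
      log_rows[[ep]] <- data.frame(epoch = ep, loss = mean_loss,
                                   dev_f = dev_f, seconds = secs)
      if (!quiet) {
        message(sprintf("epoch %2d  loss %.4f  dev F %s  %.1fs", ep,
                        mean_loss,
                        if (is.na(dev_f)) "-" else sprintf("%.2f", dev_f),
                        secs))
      }
      if (!is.null(dev_docs) && bad_epochs >= config$patience) break
    }
  })
  if (!is.null(dev_docs) && best$epoch > 0L) model$params <- best$params
  structure(list(model = model, log = do.call(rbind, log_rows),
                 train_config = config, enc_config = enc_config),
            class = "mnp_fit")
}

#' @export
print.mnp_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<mnp_fit> %s, %d epoch(s), final loss %.4f, mean %.1f s/epoch\n",
              x$model$variant, n, x$log$loss[n], mean(x$log$seconds)))
  invisible(x)
}

#' Mean seconds per training epoch
#'
#' The speed metric: average wall-clock training time per epoch. Hardware-
#' dependent; reported alongside accuracy metrics but never used in
#' correctness checks.
#'
#' @param fit An [train()] result.
#' @return Numeric scalar (seconds).
#' @export
epoch_speed <- function(fit) {
  mean(fit$log$seconds)
}

#' Predict entity mentions for documents
#'
#' Runs the encoder (and attention layer, for that variant), decodes the
#' best tag path per sentence with [viterbi_decode()], and converts the tags
#' back to typed character spans with [bio_to_spans()]. The output documents
#' carry the predicted mentions; all offsets satisfy
#' `end - start + 1 == nchar(surface)`.
#'
#' @param model An `mnp_model` (or an `mnp_fit`, whose model is used).
#' @param docs List of [annotated_document()] objects (gold mentions, if
#'   any, are ignored).
#' @return List of [annotated_document()] objects with predicted mentions.
#' @export
predict_docs <- function(model, docs, batch_size = 16L) {
  if (inherits(model, "mnp_fit")) model <- model$model
  if (length(docs) == 0L) return(list())
  out <- vector("list", length(docs))
  for (b in split(seq_along(docs), ceiling(seq_along(docs) / batch_size))) {
    encs <- lapply(docs[b], function(d) encode_doc(model, d))
    fw <- forward_batch(model, encs, train = FALSE)
    for (j in seq_along(b)) {
      d <- docs[[b[j]]]
      dec <- viterbi_decode(crf_params(fw$emissions[[j]],
                                       model$params$trans))
      sents <- lapply(seq_along(d$sentences), function(s) {
        sent <- d$sentences[[s]]
        tags <- model$tags[dec$paths[[s]]]
        rec <- bio_to_spans(tags, sent)
        annotated_sentence(sent$text, rec$mentions, tokens = sent$tokens)
      })
      out[[b[j]]] <- annotated_document(d$doc_id, sents)
    }
  }
  out
}

#' Save a model checkpoint
#'
#' Single versioned JSON file with the variant, tag set, vocabularies,
#' encoder configuration and all parameters embedded.
#'
#' @param model An `mnp_model` or `mnp_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "mnp_fit")) model <- model$model
  obj <- list(format = "mnpner-checkpoint", version = 1L,
              variant = model$variant, types = model$types,
              scheme = model$scheme,
              config = unclass(model$config),
              words = names(model$word_map), chars = names(model$char_map),
              params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return An `mnp_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable checkpoint: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "mnpner-checkpoint")) {
    stop("unreadable checkpoint: not an mnpner checkpoint file")
  }
  cfg <- obj$config
  cfg <- encoder_config(d_w = cfg$d_w, d_char = cfg$d_char,
                        char_width = cfg$char_width,
                        d_char_feat = cfg$d_char_feat, filters = cfg$filters,
                        width = cfg$width, dilations = cfg$dilations,
                        blocks = cfg$blocks, activation = cfg$activation,
                        dropout = cfg$dropout, max_doc_len = cfg$max_doc_len)
  params <- obj$params
  for (nm in names(params)) {
    if (is.list(params[[nm]])) params[[nm]] <- do.call(rbind, params[[nm]])
    if (is.array(params[[nm]]) && length(dim(params[[nm]])) == 2L) {
      params[[nm]] <- matrix(as.numeric(params[[nm]]), nrow(params[[nm]]))
    } else {
      params[[nm]] <- as.numeric(params[[nm]])
    }
  }
  words <- as.character(obj$words)
  chars <- as.character(obj$chars)
  structure(list(params = params, config = cfg, variant = obj$variant,
                 types = as.character(obj$types),
                 tags = tag_set(as.character(obj$types), scheme = obj$scheme),
                 scheme = obj$scheme,
                 word_map = stats::setNames(seq_along(words) + 2L,
                                            tolower(words)),
                 char_map = stats::setNames(seq_along(chars) + 2L, chars)),
            class = "mnp_model")
}
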