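# Fine-tuning and evaluation: masked binary cross-entropy, RMSE, the
# macro-averaged Mann-Whitney ROC-AUC, the fully connected predictor head,
# and the training loop that attaches it to a (pretrained) encoder.

#' Masked binary cross-entropy
#'
#' `-(1/n) * sum over observed entries of [ t log o + (1-t) log(1-o) ]`,
#' where `n` is the number of observed entries.  Unobserved entries never
#' contribute.
#'
#' @param o Predicted probabilities in (0,1) (vector or matrix).
#' @param t Targets, 0/1 wherever observed.
#' @param observed Logical mask, same shape as `o`; default all observed.
#' @return Scalar loss.
#' @export
bce_loss <- function(o, t, observed = NULL) {
  if (length(o) != length(t)) stop("bce_loss: shape mismatch")
  if (is.null(observed)) observed <- rep(TRUE, length(o))
  if (!sum(observed)) stop("bce_loss: no observed entries")
  oo <- o[observed]
  tt <- t[observed]
  if (any(oo <= 0 | oo >= 1)) stop("bce_loss: probabilities must lie in (0,1)")
  -mean(tt * log(oo) + (1 - tt) * log(1 - oo))
}

#' Root mean squared error
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("rmse: length mismatch")
  if (!length(y)) stop("rmse: empty input")
  sqrt(mean((y - yhat)^2))
}

#' ROC-AUC (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' ties counted one half - computed from midranks.  With matrix input the
#' AUC is computed per task over the observed entries and macro-averaged;
#' single-class tasks are skipped with a warning (an error if no task is
#' scorable).
#'
#' @param scores Numeric vector, or `n x T` matrix of per-task scores.
#' @param labels 0/1 labels, same shape.
#' @param observed Optional logical mask for matrix input.
#' @return Scalar AUC in `[0, 1]` (macro average across scorable tasks).
#' @export
roc_auc <- function(scores, labels, observed = NULL) {
  if (is.matrix(scores)) {
    if (is.null(observed)) observed <- !is.na(labels)
    aucs <- rep(NA_real_, ncol(scores))
    for (j in seq_len(ncol(scores))) {
      obs <- observed[, j]
      lab <- labels[obs, j]
      if (length(unique(lab)) < 2L) {
        warning(sprintf("roc_auc: task %d has a single class; skipped", j))
        next
      }
      aucs[j] <- roc_auc(scores[obs, j], lab)
    }
    if (all(is.na(aucs))) stop("roc_auc: every task is single-class")
    return(mean(aucs, na.rm = TRUE))
  }
  if (length(scores) != length(labels)) stop("roc_auc: length mismatch")
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes must be present")
  r <- rank(scores) # midranks: ties count 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- predictor head ---------------------------------------------------------

# Fully connected ReLU stack: widths hidden layers, then a linear task
# output of width n_tasks. Weights Xavier, biases zero.
.init_predictor <- function(d_in, widths, n_tasks) {
  dims <- c(d_in, widths, n_tasks)
  lapply(seq_len(length(dims) - 1L), function(k) {
    list(W = .xavier(dims[k], dims[k + 1L]), b = rep(0, dims[k + 1L]))
  })
}

.pred_fwd <- function(H, layers) {
  caches <- vector("list", length(layers))
  A <- H
  for (k in seq_along(layers)) {
    Z <- A %*% layers[[k]]$W + rep(layers[[k]]$b, each = nrow(A))
    caches[[k]] <- list(input = A, Z = Z)
    A <- if (k < length(layers)) relu(Z) else Z
  }
  list(out = A, caches = caches)
}

.pred_bwd <- function(dout, fwd, layers) {
  grads <- vector("list", length(layers))
  dA <- dout
  for (k in rev(seq_along(layers))) {
    dZ <- if (k < length(layers)) dA * (fwd$caches[[k]]$Z > 0) else dA
    grads[[k]] <- list(W = crossprod(fwd$caches[[k]]$input, dZ),
                       b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[k]]$W)
  }
  list(dH = dA, grads = grads)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- fine-tuning ------------------------------------------------------------

#' Fine-tune an encoder for property prediction
#'
#' Attaches a fully connected predictor head (ReLU between layers, default
#' widths (4096, 512, 64) scaled to the encoder dimension) to a pretrained
#' encoder and trains on the split's training set: masked binary
#' cross-entropy on sigmoid outputs for classification, RMSE for
#' regression (regression targets are standardized on the training set for
#' optimization and predictions mapped back to the original scale).  The
#' epoch with the best validation metric is kept (early stopping with
#' `config$patience`); the returned report is computed on the test set.
#' By default the whole network is updated; set
#' `config$freeze_encoder = TRUE` to train the head only.
#'
#' @param ds A `claps_dataset`.
#' @param split A `claps_split` partitioning it.
#' @param model A `claps_model` (typically from [claps_pretrain()] or
#'   [load_checkpoint()]).
#' @param config A [claps_config()]; fine-tuning keys and `seed` are used.
#' @param verbose Print per-epoch validation metrics.
#' @return List with `model` (encoder), `head` (predictor layers), `best_epoch`,
#'   `report` (a `claps_report` with per-task and macro test metrics), and
#'   `target_scale`.
#' @export
claps_finetune <- function(ds, split, model, config = claps_config(),
                           verbose = FALSE) {
  stopifnot(inherits(ds, "claps_dataset"), inherits(split, "claps_split"),
            inherits(model, "claps_model"))
  if (split$n != length(ds$smiles)) {
    stop("claps_finetune: split does not match dataset size")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  # encode all molecules once; rows the model's vocabulary cannot encode
  # are dropped from every subset with a logged count
  enc <- lapply(ds$smiles, function(s) {
    tryCatch(encode(s, model$vocab, model$config$C), error = function(e) NULL)
  })
  ok <- !vapply(enc, is.null, logical(1))
  if (!any(ok)) stop("claps_finetune: vocabulary mismatch: no encodable molecules")
  if (any(!ok)) {
    message(sprintf("claps_finetune: dropped %d molecules not encodable under the checkpoint vocabulary",
                    sum(!ok)))
  }
  tr <- intersect(split$train, which(ok))
  va <- intersect(split$valid, which(ok))
  te <- intersect(split$test, which(ok))
  if (!length(tr) || !length(va) || !length(te)) {
    stop("claps_finetune: a split subset is empty after encoding")
  }
  classification <- ds$task_type == "classification"
  Y <- ds$labels
  O <- ds$observed
  n_tasks <- ncol(Y)

  # regression targets standardized on train for optimization
  scale_mu <- 0
  scale_sd <- 1
  if (!classification) {
    obs_tr <- Y[tr, , drop = FALSE][O[tr, , drop = FALSE]]
    scale_mu <- mean(obs_tr)
    scale_sd <- stats::sd(obs_tr)
    if (!is.finite(scale_sd) || scale_sd == 0) scale_sd <- 1
  }

  head <- .init_predictor(model$config$d, config$predictor_widths, n_tasks)
  params <- list(enc = model$params, head = head)
  state <- adam_init(params)
  freeze <- isTRUE(config$freeze_encoder)

  # forward a set of rows; returns model outputs (natural scale for
  # regression, probabilities for classification come from sigmoid outside)
  predict_rows <- function(rows, mdl, hd) {
    H <- do.call(rbind, lapply(rows, function(i) {
      .encoder_fwd(mdl, enc[[i]], training = FALSE)$h
    }))
    .pred_fwd(H, hd)$out
  }
  eval_metric <- function(rows, mdl, hd) {
    out <- predict_rows(rows, mdl, hd)
    if (classification) {
      roc_auc(sigmoid(out), Y[rows, , drop = FALSE],
              observed = O[rows, , drop = FALSE])
    } else {
      yhat <- out * scale_sd + scale_mu
      rmse(Y[rows, , drop = FALSE][O[rows, , drop = FALSE]],
           yhat[O[rows, , drop = FALSE]])
    }
  }

  best <- list(metric = if (classification) -Inf else Inf,
               params = params, epoch = 0L)
  stale <- 0L
  lr <- config$lr_finetune
  for (epoch in seq_len(config$epochs_finetune)) {
    ord <- tr[sample.int(length(tr))]
    for (start in seq(1L, length(ord), by = config$batch_finetune)) {
      rows <- ord[start:min(start + config$batch_finetune - 1L, length(ord))]
      fwds <- lapply(rows, function(i) {
        .encoder_fwd(model, enc[[i]], training = !freeze)
      })
      H <- do.call(rbind, lapply(fwds, `[[`, "h"))
      pf <- .pred_fwd(H, head)
      obs <- O[rows, , drop = FALSE]
      nobs <- sum(obs)
      if (!nobs) next
      if (classification) {
        p <- sigmoid(pf$out)
        t <- Y[rows, , drop = FALSE]
        dout <- matrix(0, nrow(p), ncol(p))
        dout[obs] <- (p[obs] - t[obs]) / nobs # d(BCE)/d(logit)
      } else {
        t <- (Y[rows, , drop = FALSE] - scale_mu) / scale_sd
        resid <- matrix(0, nrow(pf$out), ncol(pf$out))
        resid[obs] <- pf$out[obs] - t[obs]
        r <- sqrt(sum(resid^2) / nobs)
        dout <- resid / (nobs * max(r, 1e-8)) # d(RMSE)/d(yhat)
      }
      pb <- .pred_bwd(dout, pf, head)
      hg <- lapply(pb$grads, identity)
      if (freeze) {
        grads <- list(enc = .tree_zeros(model$params), head = hg)
      } else {
        eg <- NULL
        for (k in seq_along(rows)) {
          g <- .encoder_bwd(model, fwds[[k]], pb$dH[k, ])
          eg <- if (is.null(eg)) g else .tree_add(eg, g)
        }
        eg$proj <- .tree_zeros(model$params$proj) # head replaces projection
        grads <- list(enc = eg, head = hg)
      }
      params <- list(enc = model$params, head = head)
      stepped <- adam_step(params, grads, state, lr)
      model$params <- stepped$params$enc
      head <- stepped$params$head
      state <- stepped$state
    }
    m <- eval_metric(va, model, head)
    improved <- if (classification) m > best$metric else m < best$metric
    if (verbose) {
      message(sprintf("epoch %d  valid %s %.4f%s", epoch,
                      if (classification) "ROC-AUC" else "RMSE", m,
                      if (improved) " *" else ""))
    }
    if (improved) {
      best <- list(metric = m, params = list(enc = model$params, head = head),
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params$enc
  head <- best$params$head

  # test-set report
  out_te <- predict_rows(te, model, head)
  if (classification) {
    scores <- sigmoid(out_te)
    per_task <- vapply(seq_len(n_tasks), function(j) {
      obs <- O[te, j]
      lab <- Y[te, j][obs]
      if (length(unique(lab)) < 2L) return(NA_real_)
      roc_auc(scores[obs, j], lab)
    }, numeric(1))
    macro <- mean(per_task, na.rm = TRUE)
    metric_name <- "roc_auc"
  } else {
    yhat <- out_te * scale_sd + scale_mu
    per_task <- vapply(seq_len(n_tasks), function(j) {
      obs <- O[te, j]
      if (!sum(obs)) return(NA_real_)
      rmse(Y[te, j][obs], yhat[obs, j])
    }, numeric(1))
    macro <- mean(per_task, na.rm = TRUE)
    metric_name <- "rmse"
  }
  report <- structure(
    list(metric = metric_name, per_task = per_task, macro = macro,
         task_type = ds$task_type, n_test = length(te),
         best_epoch = best$epoch, valid_metric = best$metric),
    class = "claps_report")
  list(model = model, head = head, best_epoch = best$epoch, report = report,
       target_scale = c(mu = scale_mu, sd = scale_sd))
}

#' @export
print.claps_report <- function(x, ...) {
  cat(sprintf("<claps_report> test %s: macro %.4f over %d task%s (n_test=%d, best epoch %d)\n",
              x$metric, x$macro, length(x$per_task),
              if (length(x$per_task) > 1) "s" else "", x$n_test, x$best_epoch))
  invisible(x)
}

#' Predict properties for new molecules
#'
#' Runs the fine-tuned encoder + head in evaluation mode.  Classification
#' outputs are passed through the sigmoid.  Molecules that cannot be
#' encoded yield `NA` rows (the run continues).
#'
#' @param fit Result of [claps_finetune()] (or a list with `model`, `head`,
#'   `target_scale` and the dataset's task type in `task_type`).
#' @param smiles Character vector of SMILES strings.
#' @param task_type `"classification"` or `"regression"`.
#' @return Numeric matrix, one row per input molecule.
#' @export
claps_predict <- function(fit, smiles,
                          task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  model <- fit$model
  n_tasks <- ncol(fit$head[[length(fit$head)]]$W)
  out <- matrix(NA_real_, length(smiles), n_tasks)
  for (k in seq_along(smiles)) {
    mol <- tryCatch(encode(smiles[k], model$vocab, model$config$C),
                    error = function(e) NULL)
    if (is.null(mol)) next
    h <- .encoder_fwd(model, mol, training = FALSE)$h
    o <- .pred_fwd(matrix(h, 1L), fit$head)$out
    out[k, ] <- if (task_type == "classification") {
      sigmoid(o)
    } else {
      o * fit$target_scale[["sd"]] + fit$target_scale[["mu"]]
    }
  }
  out
}
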