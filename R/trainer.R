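#' Training protocol configuration
#'
#' Canonical values follow the reference protocol: mini-batches of 32,
#' 12,000 iterations, plain stochastic gradient descent on
#' cross-entropy, learning rate 1e-4 stepped down to 1e-5 and 1e-6 at
#' iterations 4,000 and 8,000, 40 independent runs. Every field may be
#' overridden for desk-scale work.
#'
#' @param batch_size Mini-batch size (canonical 32).
#' @param iterations Total weight updates (canonical 12,000); training
#'   halts at the cap even mid-epoch.
#' @param lr_schedule Data frame with columns `iteration`, `rate`:
#'   piecewise-constant learning rate, each breakpoint taking effect at
#'   its iteration. Breakpoints must be strictly increasing and start
#'   at 0.
#' @param runs Number of independent runs (canonical 40).
#' @param proportions Identity-split proportions
#'   train/validation/test (canonical `c(40, 8, 12)`).
#' @param master_seed Master seed from which per-run split, init and
#'   batch-order seeds are derived.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(batch_size = 32L, iterations = 12000L,
                         lr_schedule = data.frame(
                           iteration = c(0L, 4000L, 8000L),
                           rate = c(1e-4, 1e-5, 1e-6)),
                         runs = 40L, proportions = c(40L, 8L, 12L),
                         master_seed = 1L) {
  if (runs < 1) stopf("train_config: runs must be >= 1")
  if (batch_size < 1 || iterations < 1)
    stopf("train_config: batch_size and iterations must be positive")
  if (!all(c("iteration", "rate") %in% names(lr_schedule)))
    stopf("train_config: lr_schedule needs columns `iteration` and `rate`")
  if (lr_schedule$iteration[1] != 0)
    stopf("train_config: lr_schedule must define the rate from iteration 0")
  if (is.unsorted(lr_schedule$iteration, strictly = TRUE))
    stopf("train_config: lr_schedule breakpoints must be strictly increasing")
  if (length(proportions) != 3 || any(proportions < 1))
    stopf("train_config: proportions must be three positive counts")
  structure(list(batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 lr_schedule = lr_schedule, runs = as.integer(runs),
                 proportions = as.integer(proportions),
                 master_seed = as.integer(master_seed)),
            class = "train_config")
}

#' Split identities into train/validation/test sets
#'
#' Uniformly random identity-disjoint partition in the given
#' proportions (canonically 40/8/12 of 60), deterministic per seed.
#'
#' @param ids Character vector of identity labels.
#' @param proportions Three positive counts; `length(ids)` must divide
#'   exactly into them (scaled by a common integer factor).
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` (disjoint identity
#'   vectors) and `seed`.
#' @export
split_identities <- function(ids, proportions = c(40L, 8L, 12L), seed = 0L) {
  n <- length(ids)
  tot <- sum(proportions)
  sizes <- n * proportions / tot
  if (any(abs(sizes - round(sizes)) > 1e-9))
    stopf("split_identities: %d identities cannot be divided in proportions %s",
          n, paste(proportions, collapse = "/"))
  sizes <- as.integer(round(sizes))
  perm <- with_seed(derive_seed(seed, "split"), sample(ids))
  list(train = sort(perm[seq_len(sizes[1])]),
       validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
       seed = as.integer(seed))
}

#' Shuffle samples into mini-batches
#'
#' Samples are shuffled per epoch seed and grouped into batches of
#' `batch_size`; the final batch holds the remainder (`n mod
#' batch_size` samples) and is omitted when the remainder is 0.
#'
#' @param samples Vector of sample indices (or any vector).
#' @param batch_size Batch size.
#' @param seed Epoch seed for the shuffle.
#' @return List of batches (vectors).
#' @export
batch_iterator <- function(samples, batch_size = 32L, seed = 0L) {
  n <- length(samples)
  if (n < 1) stopf("batch_iterator: need at least one sample")
  perm <- with_seed(derive_seed(seed, "batch"), sample(samples, n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) perm[s:min(n, s + batch_size - 1L)])
}

#' Learning rate at an iteration
#'
#' Piecewise-constant lookup in the schedule; a breakpoint takes the
#' new rate at exactly its iteration number.
#'
#' @param iteration Iteration number, `>= 0`.
#' @param schedule Data frame with `iteration`, `rate` columns.
#' @return The learning rate (real).
#' @export
learning_rate_at <- function(iteration, schedule) {
  if (any(iteration < 0)) stopf("learning_rate_at: iteration must be >= 0")
  idx <- findInterval(iteration, schedule$iteration)
  schedule$rate[pmax(idx, 1L)]
}

#' Prepare a database for training: preprocess, augment, extract features
#'
#' Runs every image of the database through the standardization
#' pipeline, expands it into its deterministic augmentation variants,
#' and pushes all variants through the frozen backbone once. Training
#' then operates on the cached feature matrix — valid because the
#' backbone is frozen by construction.
#'
#' @param db A `"face_database"`.
#' @param network An `"expression_net"` (supplies the frozen backbone
#'   and input size).
#' @param prep A [preprocess_config()].
#' @param aug An [augment_config()]; its `input_size` must match the
#'   network.
#' @return Object of class `"prepared_data"`: list with `features`
#'   (N x d matrix), `meta` (data frame: identity, label, centered),
#'   `database` (name) and `identities`.
#' @export
prepare_database <- function(db, network, prep = preprocess_config(),
                             aug = augment_config(input_size =
                                                    network$config$input_size)) {
  if (aug$input_size != network$config$input_size)
    stopf("prepare_database: augment input_size (%d) differs from the network input size (%d)",
          aug$input_size, network$config$input_size)
  nv <- n_variants(aug)
  all_imgs <- vector("list", length(db$images) * nv)
  meta <- vector("list", length(db$images))
  k <- 0L
  for (i in seq_along(db$images)) {
    im <- db$images[[i]]
    pp <- preprocess_image(im$pixels, face_bbox(nrow(im$pixels)), prep)
    vars <- make_variants(pp, aug, background = prep$background)
    vm <- attr(vars, "variants")
    all_imgs[k + seq_len(nv)] <- vars
    meta[[i]] <- data.frame(identity = im$identity, label = im$label,
                            centered = vm$centered, stringsAsFactors = FALSE)
    k <- k + nv
  }
  feats <- backbone_features(network, all_imgs)
  structure(list(features = feats, meta = do.call(rbind, meta),
                 database = db$spec$name, identities = db$identities),
            class = "prepared_data")
}

#' @export
print.prepared_data <- function(x, ...) {
  cat(sprintf("<prepared_data> %s: %d samples (%d identities x 7 labels x %d variants), %d features\n",
              x$database, nrow(x$features), length(x$identities),
              nrow(x$features) / (length(x$identities) * 7),
              ncol(x$features)))
  invisible(x)
}

#' Train the FC head of the classifier (one run)
#'
#' Supervised training of the fully connected head by plain SGD on the
#' cross-entropy loss under the configured mini-batch size, learning
#' rate schedule and iteration cap (training halts at the cap even
#' mid-epoch). The frozen backbone is untouched. The per-iteration loss,
#' the per-epoch training correct rate (on augmented samples as
#' encountered) and the per-epoch validation correct rate are recorded.
#'
#' @param network An `"expression_net"` with a (freshly initialized)
#'   head.
#' @param data A [prepare_database()] result.
#' @param split A [split_identities()] assignment over the data's
#'   identities.
#' @param config A [train_config()].
#' @param run_seed Seed governing batch order and dropout for this run.
#' @return Object of class `"expr_fit"`: the fitted model, with
#'   components `network` (trained state), `split`, `loss`
#'   (per-iteration), `epochs` (data frame: epoch, train_acc, val_acc),
#'   `config`, `run_seed`, `database`.
#' @export
train_run <- function(network, data, split, config = train_config(),
                      run_seed = config$master_seed) {
  meta <- data$meta
  tr <- which(meta$identity %in% split$train)
  va <- which(meta$identity %in% split$validation)
  if (!length(tr)) stopf("train_run: empty training set")
  y_all <- match(meta$label, EXPRESSIONS)
  Xtr <- data$features[tr, , drop = FALSE]; ytr <- y_all[tr]
  Xva <- data$features[va, , drop = FALSE]; yva <- y_all[va]
  state <- network
  # center features on the training-set mean (the frozen-backbone analog
  # of mean-image subtraction); the center travels with the fitted model
  state$center <- colMeans(Xtr)
  losses <- numeric(config$iterations)
  ep_train <- ep_val <- numeric(0)
  it <- 0L; epoch <- 0L
  with_seed(derive_seed(run_seed, "train-loop"), {
    while (it < config$iterations) {
      epoch <- epoch + 1L
      batches <- batch_iterator(seq_along(ytr), config$batch_size,
                                seed = derive_seed(run_seed, "epoch", epoch))
      n_ok <- 0L; n_seen <- 0L
      for (b in batches) {
        if (it >= config$iterations) break
        it <- it + 1L
        lr <- learning_rate_at(it - 1L, config$lr_schedule)
        f <- head_forward(state, Xtr[b, , drop = FALSE], "train")
        nb <- length(b)
        pick <- cbind(seq_len(nb), ytr[b])
        loss <- -mean(log(pmax(f$probs[pick], 1e-300)))
        if (!is.finite(loss))
          stopf("train_run: non-finite loss at iteration %d (lr %.3g, epoch %d)",
                it, lr, epoch)
        losses[it] <- loss
        n_ok <- n_ok + sum(max.col(f$scores, "first") == ytr[b])
        n_seen <- n_seen + nb
        # backpropagation through the head only
        dS <- f$probs
        dS[pick] <- dS[pick] - 1
        dS <- dS / nb
        fc <- state$fc
        dW3 <- crossprod(f$H2r, dS); db3 <- colSums(dS)
        dH2 <- tcrossprod(dS, fc$W3); dH2[f$H2 <= 0] <- 0
        dW2 <- crossprod(f$H1d, dH2); db2 <- colSums(dH2)
        dH1 <- tcrossprod(dH2, fc$W2)
        if (!is.null(f$m1)) dH1 <- dH1 * f$m1
        dH1[f$H1 <= 0] <- 0
        dW1 <- crossprod(f$X, dH1); db1 <- colSums(dH1)
        state$fc <- list(W1 = fc$W1 - lr * dW1, b1 = fc$b1 - lr * db1,
                         W2 = fc$W2 - lr * dW2, b2 = fc$b2 - lr * db2,
                         W3 = fc$W3 - lr * dW3, b3 = fc$b3 - lr * db3)
      }
      ep_train <- c(ep_train, n_ok / n_seen)
      ep_val <- c(ep_val, if (length(va))
        mean(max.col(head_forward(state, Xva, "eval")$scores, "first") == yva)
        else NA_real_)
    }
  })
  structure(list(network = state, split = split,
                 loss = losses[seq_len(it)],
                 epochs = data.frame(epoch = seq_along(ep_train),
                                     train_acc = ep_train, val_acc = ep_val),
                 config = config, run_seed = as.integer(run_seed),
                 database = data$database),
            class = "expr_fit")
}

#' Run the multi-run training experiment on one database
#'
#' Performs `config$runs` independent runs: each draws a fresh random
#' identity split and a fresh FC initialization (seeds derived from the
#' master seed), then trains the head. All run records are retained.
#'
#' @param data A [prepare_database()] result.
#' @param network Template `"expression_net"` (backbone shared across
#'   runs, head re-initialized per run).
#' @param config A [train_config()].
#' @return List of [train_run()] records, class `"expr_fit_list"`.
#' @export
run_experiment <- function(data, network, config = train_config()) {
  fits <- lapply(seq_len(config$runs), function(r) {
    sp <- split_identities(data$identities, config$proportions,
                           seed = derive_seed(config$master_seed, data$database,
                                              "split", r))
    net <- init_fc_weights(network,
                           derive_seed(config$master_seed, data$database,
                                       "init", r))
    train_run(net, data, sp, config,
              run_seed = derive_seed(config$master_seed, data$database,
                                     "run", r))
  })
  structure(fits, class = "expr_fit_list")
}

#' @export
print.expr_fit <- function(x, ...) {
  ne <- nrow(x$epochs)
  cat(sprintf("<expr_fit> %s: %d iterations / %d epochs; final train acc %.3f, val acc %.3f, loss %.4f\n",
              x$database %||% "?", length(x$loss), ne,
              x$epochs$train_acc[ne], x$epochs$val_acc[ne],
              mean(utils::tail(x$loss, 50))))
  invisible(x)
}

#' @export
summary.expr_fit <- function(object, ...) {
  out <- list(database = object$database, iterations = length(object$loss),
              epochs = object$epochs,
              split_sizes = lengths(object$split[c("train", "validation", "test")]),
              final_loss = mean(utils::tail(object$loss, 50)))
  class(out) <- "summary.expr_fit"
  out
}

#' @export
print.summary.expr_fit <- function(x, ...) {
  cat(sprintf("Expression classifier fit (%s)\n", x$database))
  cat(sprintf("  iterations: %d over %d epochs; split %d/%d/%d\n",
              x$iterations, nrow(x$epochs), x$split_sizes[1],
              x$split_sizes[2], x$split_sizes[3]))
  cat(sprintf("  final: train acc %.3f, val acc %.3f, smoothed loss %.4f\n",
              x$epochs$train_acc[nrow(x$epochs)],
              x$epochs$val_acc[nrow(x$epochs)], x$final_loss))
  invisible(x)
}

#' @export
coef.expr_fit <- function(object, ...) object$network$fc

#' Predict expression labels from a fitted classifier
#'
#' @param object An `"expr_fit"`.
#' @param newdata A `"prepared_data"` object (the centered un-augmented
#'   variant of each test image is used), a list of images, a single
#'   image matrix, or a feature matrix.
#' @param type `"label"` (default), `"scores"` or `"probs"`.
#' @param ... Unused.
#' @return Labels, or a matrix of scores/probabilities.
#' @export
predict.expr_fit <- function(object, newdata, type = c("label", "scores", "probs"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "prepared_data")) {
    keep <- newdata$meta$centered
    X <- newdata$features[keep, , drop = FALSE]
  } else X <- feature_rows(object$network, newdata)
  f <- forward(object$network, X, "eval")
  switch(type,
         label = if (is.matrix(f$scores)) EXPRESSIONS[max.col(f$scores, "first")]
                 else EXPRESSIONS[which.max(f$scores)],
         scores = f$scores, probs = f$probs)
}

#' Plot learning curves of a fit
#'
#' Per-iteration loss and per-epoch train/validation correct rates.
#'
#' @param x An `"expr_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.expr_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$loss, type = "l", col = "cyan4", xlab = "iteration",
                 ylab = "cross-entropy loss", main = x$database, ...)
  graphics::plot(x$epochs$epoch, x$epochs$train_acc, type = "b", col = "orange",
                 ylim = c(0, 1), xlab = "epoch", ylab = "correct rate",
                 main = "train (orange) / validation (blue)")
  graphics::lines(x$epochs$epoch, x$epochs$val_acc, type = "b", col = "steelblue")
  graphics::abline(h = 1 / 7, lty = 2)
  invisible(x)
}
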