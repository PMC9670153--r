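#' Classifier architecture configuration
#'
#' The classifier is a frozen convolutional feature extractor followed
#' by a trainable head of three fully connected layers (FC1, FC2, FC3)
#' emitting seven expression scores. The default backbone
#' (`"small-frozen-conv"`) is a stack of three fixed random-filter
#' convolution stages with 2x2 max pooling after each stage (mirroring
#' the pooling placement after CONV1, CONV2 and CONV5 of the canonical
#' five-layer architecture), reducing a `size` x `size` grayscale input
#' to a `(size/8)^2 * 32` feature vector. A pre-trained `"alexnet-conv"`
#' stack can be plugged in from a local weights file; it is never
#' downloaded.
#'
#' @param backbone `"small-frozen-conv"` (default) or `"alexnet-conv"`.
#' @param input_size Input side in pixels; must be divisible by 8 for
#'   the small backbone (canonical 224, desk scale 64).
#' @param fc_sizes Widths `(n1, n2, 7)` of the FC layers; the final
#'   layer must have exactly 7 units (canonical `c(4096, 4096, 7)`,
#'   desk scale `c(128, 128, 7)`).
#' @param dropout Proportion of units dropped before FC1 and FC2 at
#'   each weight update, in `[0, 1)` (default 0.1).
#' @param backbone_seed Seed for the frozen random filters.
#' @param init_seed Seed for the FC initialization.
#' @param weights_file Local weights file for `"alexnet-conv"` (JSON:
#'   list of stages with `filters` (K x F, row-major over kernel taps)
#'   and `pool` flags).
#' @return Object of class `"net_config"`.
#' @export
net_config <- function(backbone = c("small-frozen-conv", "alexnet-conv"),
                       input_size = 64L, fc_sizes = c(128L, 128L, 7L),
                       dropout = 0.1, backbone_seed = 1L, init_seed = 1L,
                       weights_file = NULL) {
  backbone <- match.arg(backbone)
  if (length(fc_sizes) != 3 || fc_sizes[3] != 7)
    stopf("net_config: fc_sizes must be (n1, n2, 7); the final layer has exactly 7 units")
  if (dropout < 0 || dropout >= 1)
    stopf("net_config: dropout must lie in [0, 1)")
  if (backbone == "small-frozen-conv" && input_size %% 8 != 0)
    stopf("net_config: input_size must be divisible by 8 for the small backbone")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout,
                 backbone_seed = as.integer(backbone_seed),
                 init_seed = as.integer(init_seed),
                 weights_file = weights_file),
            class = "net_config")
}

# --- convolution machinery -------------------------------------------
# Batch activations are held as an N x (H*W*C) matrix, element
# (n, (c-1)*H*W + (x-1)*H + y). Convolution is im2col + one BLAS
# matmul; indices are precomputed per stage at build time.

make_im2col_index <- function(H, W, C, k) {
  r <- (k - 1L) %/% 2L
  HW <- H * W
  pos <- expand.grid(y = seq_len(H), x = seq_len(W))   # y fastest = layout order
  taps <- expand.grid(dy = -r:r, dx = -r:r, c = seq_len(C))
  idx <- matrix(HW * C + 1L, nrow = HW, ncol = nrow(taps))  # pad cell
  for (j in seq_len(nrow(taps))) {
    yy <- pos$y + taps$dy[j]; xx <- pos$x + taps$dx[j]
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    idx[ok, j] <- (taps$c[j] - 1L) * HW + (xx[ok] - 1L) * H + yy[ok]
  }
  idx
}

make_pool_index <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  q <- expand.grid(y = seq_len(H2), x = seq_len(W2))
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
    (2L * (q$x - 1L) + o[2]) * H + (2L * (q$y - 1L) + o[1]) + 1L
  })
}

conv_stage <- function(H, W, Cin, Cout, k, seed) {
  K <- k * k * Cin
  Wf <- with_seed(seed, matrix(stats::rnorm(K * Cout, 0, sqrt(2 / K)), K, Cout))
  list(H = H, Wd = W, Cin = Cin, Cout = Cout, k = k, W = Wf,
       idx = make_im2col_index(H, W, Cin, k), pool = make_pool_index(H, W))
}

stage_forward <- function(stage, A) {
  N <- nrow(A); H <- stage$H; W_ <- stage$Wd; HW <- H * W_
  Ap <- cbind(A, 0)                                   # zero-pad cell
  M <- Ap[, as.vector(stage$idx), drop = FALSE]       # N x (HW*K)
  dim(M) <- c(N * HW, ncol(stage$idx))
  Z <- M %*% stage$W                                  # (N*HW) x F
  Z[Z < 0] <- 0                                       # ReLU
  p <- stage$pool
  gather <- function(pidx) {
    rows <- rep((pidx - 1L) * N, each = N) + seq_len(N)
    Z[rows, , drop = FALSE]
  }
  P <- pmax(gather(p[[1]]), gather(p[[2]]), gather(p[[3]]), gather(p[[4]]))
  dim(P) <- c(N, (HW %/% 4L) * stage$Cout)
  P
}

build_small_backbone <- function(input_size, seed) {
  s1 <- conv_stage(input_size, input_size, 1L, 8L, 5L, derive_seed(seed, "conv", 1))
  s2 <- conv_stage(input_size %/% 2L, input_size %/% 2L, 8L, 16L, 3L,
                   derive_seed(seed, "conv", 2))
  s3 <- conv_stage(input_size %/% 4L, input_size %/% 4L, 16L, 32L, 3L,
                   derive_seed(seed, "conv", 3))
  list(stages = list(s1, s2, s3), input_size = input_size,
       n_features = (input_size %/% 8L)^2 * 32L)
}

build_alexnet_backbone <- function(input_size, weights_file) {
  if (is.null(weights_file))
    stopf(paste("net_config: the alexnet-conv backbone requires a local",
                "weights file (`weights_file`); pre-trained weights are",
                "never downloaded"))
  if (!file.exists(weights_file))
    stopf("net_config: weights file '%s' not found", weights_file)
  doc <- yaml::read_yaml(weights_file)
  H <- input_size
  stages <- lapply(doc$stages, function(st) {
    Cin <- st$cin; Cout <- st$cout; k <- st$k
    Wf <- matrix(as.numeric(unlist(st$filters)), k * k * Cin, Cout)
    s <- list(H = H, Wd = H, Cin = Cin, Cout = Cout, k = k, W = Wf,
              idx = make_im2col_index(H, H, Cin, k), pool = make_pool_index(H, H))
    H <<- H %/% 2L
    s
  })
  Cl <- utils::tail(doc$stages, 1)[[1]]$cout
  list(stages = stages, input_size = input_size, n_features = H * H * Cl)
}

backbone_checksum <- function(state) {
  sum(vapply(state$backbone$stages, function(s) sum(s$W), numeric(1)))
}

#' Build the expression classifier
#'
#' Assembles the frozen backbone (deterministic from the backbone seed)
#' and initializes the trainable FC head with [init_fc_weights()]. The
#' backbone parameters are never altered by training.
#'
#' @param config A [net_config()].
#' @return Object of class `"expression_net"`: list with `config`,
#'   `backbone`, `fc` (weight matrices `W1, b1, W2, b2, W3, b3`) and
#'   `n_features`.
#' @export
build_network <- function(config = net_config()) {
  backbone <- switch(config$backbone,
    "small-frozen-conv" = build_small_backbone(config$input_size,
                                               config$backbone_seed),
    "alexnet-conv" = build_alexnet_backbone(config$input_size,
                                            config$weights_file))
  state <- structure(list(config = config, backbone = backbone,
                          n_features = backbone$n_features, fc = NULL),
                     class = "expression_net")
  init_fc_weights(state, config$init_seed)
}

#' Initialize the fully connected head
#'
#' Weights are drawn from a zero-mean normal with fan-in-scaled
#' standard deviation `sqrt(2 / fan_in)` (the He scheme for rectified
#' units); all biases start at 0. Deterministic per seed.
#'
#' @param state An `"expression_net"`.
#' @param seed Integer seed.
#' @return The network with a freshly initialized head.
#' @export
init_fc_weights <- function(state, seed = state$config$init_seed) {
  d <- state$n_features; n <- state$config$fc_sizes
  state$fc <- with_seed(derive_seed(seed, "fc-init"), list(
    W1 = matrix(stats::rnorm(d * n[1], 0, sqrt(2 / d)), d, n[1]),
    b1 = numeric(n[1]),
    W2 = matrix(stats::rnorm(n[1] * n[2], 0, sqrt(2 / n[1])), n[1], n[2]),
    b2 = numeric(n[2]),
    W3 = matrix(stats::rnorm(n[2] * 7, 0, sqrt(2 / n[2])), n[2], 7),
    b3 = numeric(7)
  ))
  state
}

#' Extract frozen backbone features
#'
#' Runs images through the frozen convolution stack. Pixels are scaled
#' by 1/255 on entry so activations are of order one.
#'
#' @param state An `"expression_net"`.
#' @param images A single H x W matrix or a list of them.
#' @param batch Number of images per BLAS pass.
#' @return N x n_features numeric matrix.
#' @export
backbone_features <- function(state, images, batch = 64L) {
  if (is.matrix(images)) images <- list(images)
  sz <- state$backbone$input_size
  for (im in images[1])
    if (nrow(im) != sz || ncol(im) != sz)
      stopf("backbone_features: image is %d x %d but the network input size is %d",
            nrow(im), ncol(im), sz)
  N <- length(images)
  out <- matrix(0, N, state$n_features)
  for (start in seq(1L, N, by = batch)) {
    idx <- start:min(N, start + batch - 1L)
    A <- t(vapply(images[idx], function(im) {
      if (nrow(im) != sz || ncol(im) != sz)
        stopf("backbone_features: image is %d x %d but the network input size is %d",
              nrow(im), ncol(im), sz)
      as.numeric(im) / 255
    }, numeric(sz * sz)))
    for (stg in state$backbone$stages) A <- stage_forward(stg, A)
    out[idx, ] <- A
  }
  out
}

# Head forward pass on a feature matrix X (N x d). If the state carries
# a feature center (set by train_run from its training samples, the
# analog of mean-image subtraction), it is subtracted first. In train
# mode, inverted dropout (keep probability 1 - p) is applied to the
# inputs of FC1 and FC2, drawing masks from the current RNG stream.
# Returns the intermediates needed for backpropagation.
head_forward <- function(state, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!is.null(state$center)) X <- sweep(X, 2, state$center)
  fc <- state$fc
  p <- state$config$dropout
  if (mode == "train" && p > 0) {
    m0 <- matrix(stats::rbinom(length(X), 1, 1 - p), nrow(X)) / (1 - p)
    X <- X * m0
  } else m0 <- NULL
  H1 <- sweep(X %*% fc$W1, 2, fc$b1, "+")
  H1r <- pmax(H1, 0)
  H1d <- H1r
  if (mode == "train" && p > 0) {
    m1 <- matrix(stats::rbinom(length(H1r), 1, 1 - p), nrow(H1r)) / (1 - p)
    H1d <- H1r * m1
  } else m1 <- NULL
  H2 <- sweep(H1d %*% fc$W2, 2, fc$b2, "+")
  H2r <- pmax(H2, 0)
  S <- sweep(H2r %*% fc$W3, 2, fc$b3, "+")
  Sm <- S - apply(S, 1, max)
  E <- exp(Sm)
  P <- E / rowSums(E)
  list(X = X, H1 = H1, H1d = H1d, H2 = H2, H2r = H2r, scores = S, probs = P,
       m0 = m0, m1 = m1)
}

#' Forward pass of the classifier
#'
#' Computes the seven raw FC3 scores and their softmax probabilities
#' for one image (or precomputed feature vector). Dropout is active
#' only in `"train"` mode; in `"eval"` mode the forward pass is a pure
#' function of (state, image).
#'
#' @param state An `"expression_net"` .
#' @param image H x W matrix matching the input size, or a numeric
#'   vector/matrix of backbone features.
#' @param mode `"eval"` (default) or `"train"`.
#' @return List with `scores` (7 named reals, pre-softmax) and `probs`
#'   (7 named reals summing to 1).
#' @export
forward <- function(state, image, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- feature_rows(state, image)
  f <- head_forward(state, X, mode)
  if (nrow(X) == 1) {
    list(scores = stats::setNames(drop(f$scores), EXPRESSIONS),
         probs = stats::setNames(drop(f$probs), EXPRESSIONS))
  } else {
    colnames(f$scores) <- colnames(f$probs) <- EXPRESSIONS
    list(scores = f$scores, probs = f$probs)
  }
}

feature_rows <- function(state, image) {
  if (is.list(image) || (is.matrix(image) && nrow(image) == ncol(image) &&
                         nrow(image) == state$backbone$input_size)) {
    backbone_features(state, image)
  } else if (is.matrix(image) && ncol(image) == state$n_features) {
    image
  } else if (is.numeric(image) && length(image) == state$n_features) {
    matrix(image, 1)
  } else {
    stopf("forward: input size mismatch (expected a %d x %d image or %d features)",
          state$backbone$input_size, state$backbone$input_size, state$n_features)
  }
}

#' Predict the expression label
#'
#' Argmax readout of the raw FC3 scores; ties break toward the first
#' label in the fixed [EXPRESSIONS] order.
#'
#' @param state An `"expression_net"`.
#' @param image Image or feature input as in [forward()].
#' @return An expression label (character).
#' @export
predict_label <- function(state, image) {
  sc <- forward(state, image, "eval")$scores
  if (is.matrix(sc)) EXPRESSIONS[apply(sc, 1, which.max)]
  else EXPRESSIONS[which.max(sc)]
}

#' @export
print.expression_net <- function(x, ...) {
  n <- x$config$fc_sizes
  cat(sprintf("<expression_net> %s backbone (%dpx -> %d features), FC %d/%d/%d, dropout %.2g\n",
              x$config$backbone, x$config$input_size, x$n_features,
              n[1], n[2], n[3], x$config$dropout))
  invisible(x)
}
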