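#' @include AllClasses.R graph.R
NULL

#' Classifier configuration
#'
#' Architecture and training settings for the compact convolutional
#' classifier: four conv blocks (3x3 kernels, stride 1, batch normalization,
#' ReLU) with a 2x2 stride-2 max pool after blocks 1-3, then two fully
#' connected layers and a softmax over two classes.  Defaults: 128 px input,
#' channel widths 8/16/32/64, hidden FC width 64, Adam with learning rate
#' 1e-3, batch size 16, 20 epochs, 90/10 stratified split.
#'
#' @param inputSize square input side in pixels; must be divisible by 8
#'   (three stride-2 pools).
#' @param channels integer vector of 4 conv channel widths.
#' @param fcSizes integer vector of 2 fully connected widths; the second is
#'   the class count and must be 2.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param trainFraction train split fraction in (0, 1).
#' @param rngSeed seed for initialization, splitting and shuffling.
#' @return a validated config list.
#' @export
cnnConfig <- function(inputSize = 128L, channels = c(8L, 16L, 32L, 64L),
                      fcSizes = c(64L, 2L), learningRate = 1e-3,
                      batchSize = 16L, epochs = 20L, trainFraction = 0.9,
                      rngSeed = 1L) {
  if (inputSize %% 8 != 0)
    stop("inputSize must be divisible by 8 (three stride-2 pools)")
  if (length(channels) != 4) stop("exactly 4 conv blocks are required")
  if (length(fcSizes) != 2 || fcSizes[2] != 2)
    stop("two fully connected layers with a final width of 2 are required")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  list(inputSize = as.integer(inputSize), channels = as.integer(channels),
       fcSizes = as.integer(fcSizes), learningRate = learningRate,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       trainFraction = trainFraction, rngSeed = as.integer(rngSeed))
}

#' Build the classifier with seeded He-initialized weights
#'
#' @param cfg a [cnnConfig()] list.
#' @param classes the two class labels (negative, positive).
#' @return a [CNNModel-class].
#' @export
buildModel <- function(cfg = cnnConfig(), classes = c("CTRL", "HOA")) {
  cin <- c(1L, cfg$channels[1:3])
  flat <- as.integer((cfg$inputSize / 8)^2 * cfg$channels[4])
  params <- withSeed(cfg$rngSeed, {
    p <- list()
    for (l in 1:4) {
      p[[paste0("convW", l)]] <- array(
        rnorm(9 * cin[l] * cfg$channels[l]) * sqrt(2 / (9 * cin[l])),
        dim = c(3, 3, cin[l], cfg$channels[l]))
      p[[paste0("bnGamma", l)]] <- rep(1, cfg$channels[l])
      p[[paste0("bnBeta", l)]] <- rep(0, cfg$channels[l])
    }
    p$fcW1 <- matrix(rnorm(cfg$fcSizes[1] * flat) * sqrt(2 / flat),
                     cfg$fcSizes[1], flat)
    p$fcB1 <- rep(0, cfg$fcSizes[1])
    p$fcW2 <- matrix(rnorm(2 * cfg$fcSizes[1]) * sqrt(2 / cfg$fcSizes[1]),
                     2, cfg$fcSizes[1])
    p$fcB2 <- rep(0, 2)
    p
  })
  state <- list()
  for (l in 1:4) {
    state[[paste0("bnMean", l)]] <- rep(0, cfg$channels[l])
    state[[paste0("bnVar", l)]] <- rep(1, cfg$channels[l])
  }
  new("CNNModel", config = cfg, params = params, state = state,
      classes = classes)
}

#' Trainable parameter count
#'
#' Total number of trainable weights: conv kernels, batch-norm scale/shift,
#' and fully connected weights and biases (running statistics excluded).
#'
#' @param model a [CNNModel-class].
#' @return integer parameter count.
#' @export
nParameters <- function(model) {
  stopifnot(is(model, "CNNModel"))
  sum(vapply(model@params, length, integer(1)))
}

#' Spatial size of the feature map entering the fully connected layers
#' @param model a [CNNModel-class].
#' @return integer vector (height, width, channels).
#' @export
featureMapDim <- function(model) {
  s <- model@config$inputSize / 8
  c(s, s, model@config$channels[4])
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# per-channel batch statistics of an (H, W, C, B) array
bnForward <- function(x, gamma, beta, runMean, runVar, train) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- runMean; v <- runVar
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- aperm(array(y, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = y, xhat = xhat, invstd = invstd, mu = mu, v = v)
}

bnBackward <- function(gy, cache, gamma) {
  d <- dim(gy)
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
  n <- nrow(gym)
  gbeta <- colSums(gym)
  ggamma <- colSums(gym * cache$xhat)
  t1 <- sweep(gym, 2, gbeta / n)
  t2 <- sweep(cache$xhat, 2, ggamma / n, `*`)
  gxm <- sweep(t1 - t2, 2, gamma * cache$invstd, `*`)
  gx <- aperm(array(gxm, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# forward pass; returns softmax probabilities (2 x B) and caches when
# train = TRUE
cnnForward <- function(model, x, train = FALSE) {
  p <- model@params; st <- model@state
  caches <- list()
  for (l in 1:4) {
    xin <- x
    x <- conv3x3_fwd_cpp(x, p[[paste0("convW", l)]])
    bn <- bnForward(x, p[[paste0("bnGamma", l)]], p[[paste0("bnBeta", l)]],
                    st[[paste0("bnMean", l)]], st[[paste0("bnVar", l)]],
                    train)
    relu <- bn$y > 0
    a <- bn$y * relu
    if (l <= 3) {
      pool <- maxpool2_fwd_cpp(a)
      caches[[l]] <- list(xin = xin, conv = x, bn = bn, relu = relu,
                          poolIdx = pool$idx, poolInDim = dim(a))
      x <- pool$y
    } else {
      caches[[l]] <- list(xin = xin, conv = x, bn = bn, relu = relu)
      x <- a
    }
  }
  d <- dim(x)
  B <- d[4]
  xf <- matrix(x, ncol = B)
  h1 <- p$fcW1 %*% xf + p$fcB1
  r1 <- h1 > 0
  a1 <- h1 * r1
  logits <- p$fcW2 %*% a1 + p$fcB2
  mx <- apply(logits, 2, max)
  ez <- exp(sweep(logits, 2, mx))
  probs <- sweep(ez, 2, colSums(ez), `/`)
  list(probs = probs, caches = caches, xf = xf, r1 = r1, a1 = a1,
       featDim = d)
}

# one training step on a minibatch; returns loss, gradients and batch stats
cnnBackward <- function(model, fwd, yOneHot) {
  p <- model@params
  B <- ncol(yOneHot)
  loss <- -mean(colSums(yOneHot * log(pmax(fwd$probs, 1e-12))))
  g <- list()
  dlogits <- (fwd$probs - yOneHot) / B
  g$fcW2 <- dlogits %*% t(fwd$a1)
  g$fcB2 <- rowSums(dlogits)
  da1 <- (t(p$fcW2) %*% dlogits) * fwd$r1
  g$fcW1 <- da1 %*% t(fwd$xf)
  g$fcB1 <- rowSums(da1)
  dx <- array(t(p$fcW1) %*% da1, dim = fwd$featDim)
  bnStats <- list()
  for (l in 4:1) {
    cache <- fwd$caches[[l]]
    if (l <= 3)
      dx <- maxpool2_bwd_cpp(dx, cache$poolIdx, cache$poolInDim)
    dx <- dx * cache$relu
    bb <- bnBackward(dx, cache$bn, p[[paste0("bnGamma", l)]])
    g[[paste0("bnGamma", l)]] <- bb$ggamma
    g[[paste0("bnBeta", l)]] <- bb$gbeta
    cb <- conv3x3_bwd_cpp(cache$xin, p[[paste0("convW", l)]], bb$gx)
    g[[paste0("convW", l)]] <- cb$gW
    if (l > 1) dx <- cb$gx
    bnStats[[paste0("bnMean", l)]] <- cache$bn$mu
    bnStats[[paste0("bnVar", l)]] <- cache$bn$v
  }
  list(loss = loss, grads = g, bnStats = bnStats)
}

# stack a list of SliceImage (or matrices) into an (S, S, 1, N) array,
# bilinearly resizing when needed
stackImages <- function(images, inputSize) {
  n <- length(images)
  x <- array(0, dim = c(inputSize, inputSize, 1, n))
  for (i in seq_len(n)) {
    m <- if (is(images[[i]], "SliceImage")) images[[i]]@pixels
         else images[[i]]
    if (!all(dim(m) == inputSize))
      m <- EBImage::resize(m, w = inputSize, h = inputSize)
    x[, , 1, i] <- m
  }
  x
}

#' Stratified train/test split
#'
#' Splits a labeled image set preserving class balance exactly, deterministic
#' under `seed`; train and test are disjoint and cover the dataset.
#'
#' @param labels factor of class labels.
#' @param trainFraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return list of integer index vectors `train` and `test`.
#' @export
splitData <- function(labels, trainFraction = 0.9, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < 10))
    stop("each class needs at least 10 items to split")
  withSeed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      nTrain <- round(length(idx) * trainFraction)
      train <- c(train, sort(sample(idx, nTrain)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy with Adam; shuffling and initialization
#' are seeded, so the loss trace is reproducible on a given BLAS backend.
#' Aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param model a [CNNModel-class] from [buildModel()].
#' @param images list of [SliceImage-class] (or matrices) for training.
#' @param labels factor of class labels aligned with `images`; levels must
#'   match `model@classes`.
#' @param verbose print a per-epoch loss line.
#' @return list with `model` (trained [CNNModel-class]), `lossTrace`
#'   (per-epoch mean loss) and `trainAccuracy`.
#' @export
trainModel <- function(model, images, labels, verbose = FALSE) {
  stopifnot(is(model, "CNNModel"), length(images) == length(labels))
  cfg <- model@config
  labels <- factor(labels, levels = model@classes)
  x <- stackImages(images, cfg$inputSize)
  yIdx <- as.integer(labels)
  n <- length(images)
  p <- model@params
  adamM <- lapply(p, function(w) w * 0)   # zeroed copies keep shapes/classes
  adamV <- adamM
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tAdam <- 0
  lossTrace <- numeric(0)
  st <- model@state
  if (cfg$epochs > 0) {
    withSeed(cfg$rngSeed + 1L, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(n)
        batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
        epLoss <- 0
        for (b in batches) {
          xb <- x[, , , b, drop = FALSE]
          yb <- matrix(0, 2, length(b))
          yb[cbind(yIdx[b], seq_along(b))] <- 1
          model@params <- p; model@state <- st
          fwd <- cnnForward(model, xb, train = TRUE)
          bwd <- cnnBackward(model, fwd, yb)
          if (!is.finite(bwd$loss))
            stop("training diverged (non-finite loss) at epoch ", ep)
          epLoss <- epLoss + bwd$loss * length(b)
          tAdam <- tAdam + 1
          for (nm in names(p)) {
            gw <- bwd$grads[[nm]]
            adamM[[nm]] <- beta1 * adamM[[nm]] + (1 - beta1) * gw
            adamV[[nm]] <- beta2 * adamV[[nm]] + (1 - beta2) * gw^2
            mhat <- adamM[[nm]] / (1 - beta1^tAdam)
            vhat <- adamV[[nm]] / (1 - beta2^tAdam)
            p[[nm]] <- p[[nm]] - cfg$learningRate * mhat / (sqrt(vhat) + eps)
          }
          for (l in 1:4) {
            for (s in c("bnMean", "bnVar")) {
              nm <- paste0(s, l)
              st[[nm]] <- (1 - BN_MOMENTUM) * st[[nm]] +
                BN_MOMENTUM * bwd$bnStats[[nm]]
            }
          }
        }
        lossTrace <- c(lossTrace, epLoss / n)
        if (verbose)
          message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs,
                          epLoss / n))
      }
    })
  }
  model@params <- p
  model@state <- st
  pred <- predictProbs(model, x)
  trainAcc <- mean(apply(pred, 2, which.max) == yIdx)
  list(model = model, lossTrace = lossTrace, trainAccuracy = trainAcc)
}

# softmax probabilities (2 x N) in inference mode, batched
predictProbs <- function(model, x, batchSize = 32L) {
  n <- dim(x)[4]
  probs <- matrix(0, 2, n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    probs[, idx] <- cnnForward(model, x[, , , idx, drop = FALSE],
                               train = FALSE)$probs
  }
  probs
}

#' Evaluate the classifier on a labeled test set
#'
#' Confusion counts at the argmax decision (the second class label is the
#' positive class), ROC curve by sweeping the softmax score threshold, and
#' AUC by the trapezoidal rule.  With a single-class test set the ROC and
#' AUC are undefined (NA, with a warning).
#'
#' @param model a trained [CNNModel-class].
#' @param images list of test [SliceImage-class] (or matrices).
#' @param labels factor of test labels.
#' @param arm label recorded in the report.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, images, labels, arm = "raw_images") {
  stopifnot(length(images) == length(labels), length(images) > 0)
  labels <- factor(labels, levels = model@classes)
  x <- stackImages(images, model@config$inputSize)
  probs <- predictProbs(model, x)
  scores <- probs[2, ]
  isPos <- labels == model@classes[2]
  pred <- apply(probs, 2, which.max) == 2
  tp <- sum(pred & isPos); fp <- sum(pred & !isPos)
  tn <- sum(!pred & !isPos); fn <- sum(!pred & isPos)
  roc <- rocCurve(scores, isPos)
  new("EvalReport", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn),
      accuracy = (tp + tn) / length(labels), roc = roc$points,
      auc = roc$auc, arm = arm)
}

# ROC by exhaustive threshold sweep + trapezoidal AUC
rocCurve <- function(scores, isPos) {
  nP <- sum(isPos); nN <- sum(!isPos)
  if (nP == 0 || nN == 0) {
    warning("ROC undefined for a single-class test set")
    return(list(points = data.frame(fpr = numeric(0), tpr = numeric(0),
                                    threshold = numeric(0)),
                auc = NA_real_))
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(th, function(t) sum(scores >= t & !isPos) / nN, numeric(1))
  tpr <- vapply(th, function(t) sum(scores >= t & isPos) / nP, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = th),
       auc = auc)
}

#' Run the two-arm classification experiment
#'
#' Arm 1 trains and tests on raw slices; arm 2 on binary renderings of the
#' networks extracted from the same slices ([extractNetwork()] then
#' [renderNetwork()]).  Both arms share the identical stratified split and
#' configuration (including seeds), so the only difference is the input
#' encoding.
#'
#' @param cohort a labeled cohort as returned by [makeCohort()] (elements
#'   `images`, `labels`).
#' @param extractParams extraction settings for the network arm (see
#'   [extractionParams()]).
#' @param cfg a [cnnConfig()].
#' @param verbose print per-epoch losses.
#' @return list with [EvalReport-class] elements `raw` and `networks`, plus
#'   `rawTrain` and `networksTrain` (training traces).
#' @export
runTwoArmExperiment <- function(cohort, extractParams = extractionParams(),
                                cfg = cnnConfig(), verbose = FALSE) {
  labels <- cohort$labels
  split <- splitData(labels, cfg$trainFraction, cfg$rngSeed)
  classes <- levels(labels)
  runArm <- function(images, arm) {
    model <- buildModel(cfg, classes)
    fit <- trainModel(model, images[split$train], labels[split$train],
                      verbose = verbose)
    rep <- evaluateModel(fit$model, images[split$test], labels[split$test],
                         arm = arm)
    list(report = rep, fit = fit)
  }
  raw <- runArm(cohort$images, "raw_images")
  netImgs <- lapply(cohort$images, function(im)
    renderNetwork(extractNetwork(im, extractParams)))
  net <- runArm(netImgs, "extracted_networks")
  list(raw = raw$report, networks = net$report,
       rawTrain = raw$fit[c("lossTrace", "trainAccuracy")],
       networksTrain = net$fit[c("lossTrace", "trainAccuracy")])
}
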