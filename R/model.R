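# Model configuration, construction, training and replica-averaged
# clamped prediction.

#' Model configuration for the %PPB regression network
#'
#' Four architecture variants share a conv -> pool -> fully-connected spine
#' with batch normalization after every convolutional and fully connected
#' layer; they differ only in the convolution kind and whether
#' rotation/translation augmentation is applied:
#' \itemize{
#'   \item \code{"baseline"}: ordinary convolution, no augmentation;
#'   \item \code{"cyclicconv"}: circular convolution, no augmentation;
#'   \item \code{"augmented"}: ordinary convolution + augmentation;
#'   \item \code{"cyclicconv_augmented"}: circular convolution + augmentation.
#' }
#'
#' @param variant Architecture variant (above).
#' @param D Number of input descriptors (rows of the feature map).
#' @param L Feature-map length (default 15).
#' @param convLayers list of \code{list(kernel, channels)}; kernels must be odd.
#' @param pooling \code{"max"} (global max over the occupied span) or
#'   \code{"flatten"} (only valid without conv layers; used for linear probes).
#' @param fcLayers Hidden fully-connected widths (a final scalar output layer
#'   is always appended).
#' @param batchNorm Batch normalization after every conv and hidden fc layer.
#' @param activation \code{"relu"} or \code{"identity"}.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); \code{Inf} disables early stopping.
#' @param batchSize Minibatch size.
#' @param valFraction Fraction of peptides held out for validation-based
#'   early stopping (0 disables; train loss is then monitored).
#' @param replicasPerEpoch For augmented variants: number of replicas drawn
#'   per peptide per epoch (\code{NULL} = the full replica set every epoch).
#' @param seed Integer seed controlling initialization, validation split,
#'   shuffling and replica subsampling.
#' @param bnMomentum Running-statistics momentum for batch normalization.
#' @return Validated configuration list.
#' @export
ppbModelConfig <- function(variant = c("augmented", "baseline", "cyclicconv",
                                       "cyclicconv_augmented"),
                           D = 3L, L = 15L,
                           convLayers = list(list(kernel = 3L, channels = 32L),
                                             list(kernel = 3L, channels = 64L)),
                           pooling = c("max", "flatten"),
                           fcLayers = c(64L, 16L),
                           batchNorm = TRUE,
                           activation = c("relu", "identity"),
                           lr = 1e-3, epochs = 300L, patience = 30L,
                           batchSize = 128L, valFraction = 0.1,
                           replicasPerEpoch = NULL,
                           seed = 1L, bnMomentum = 0.1) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  activation <- match.arg(activation)
  if (D < 1L) stop("configuration error: D must be >= 1")
  if (L < 1L) stop("configuration error: L must be >= 1")
  for (spec in convLayers) {
    if (!all(c("kernel", "channels") %in% names(spec)))
      stop("configuration error: each conv layer needs 'kernel' and 'channels'")
    if (spec$kernel %% 2L != 1L)
      stop("configuration error: kernel size must be odd, got ", spec$kernel)
    if (spec$channels < 1L)
      stop("configuration error: channels must be >= 1")
  }
  if (pooling == "flatten" && length(convLayers) > 0L)
    stop("configuration error: 'flatten' pooling requires an empty conv stack")
  if (any(fcLayers < 1L))
    stop("configuration error: fc widths must be >= 1")
  list(variant = variant,
       convKind = if (variant %in% c("cyclicconv", "cyclicconv_augmented"))
         "cyclic" else "ordinary",
       augment = variant %in% c("augmented", "cyclicconv_augmented"),
       D = as.integer(D), L = as.integer(L),
       convLayers = lapply(convLayers, function(s)
         list(kernel = as.integer(s$kernel), channels = as.integer(s$channels))),
       pooling = pooling, fcLayers = as.integer(fcLayers),
       batchNorm = isTRUE(batchNorm), activation = activation,
       lr = lr, epochs = as.integer(epochs), patience = patience,
       batchSize = as.integer(batchSize), valFraction = valFraction,
       replicasPerEpoch = replicasPerEpoch,
       seed = as.integer(seed), bnMomentum = bnMomentum)
}

#' Build an untrained model from a configuration
#'
#' Allocates and seeds all network parameters (He-scaled normal weights),
#' validating layer shape consistency at build time.
#'
#' @param config Configuration from \code{\link{ppbModelConfig}}.
#' @return An untrained \linkS4class{PPBModel}.
#' @export
buildPPBModel <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  params <- list(conv = list(), fc = list())
  Cin <- cfg$D
  for (l in seq_along(cfg$convLayers)) {
    spec <- cfg$convLayers[[l]]
    fanin <- Cin * spec$kernel
    ly <- list(
      W = matrix(stats::rnorm(spec$channels * fanin, 0, sqrt(2 / fanin)),
                 spec$channels, fanin),
      b = numeric(spec$channels)
    )
    if (cfg$batchNorm)
      ly <- c(ly, list(gamma = rep(1, spec$channels),
                       beta = numeric(spec$channels),
                       rmean = numeric(spec$channels),
                       rvar = rep(1, spec$channels)))
    params$conv[[l]] <- ly
    Cin <- spec$channels
  }
  params$labelNorm <- list(mu = 0, sd = 1)
  fin <- if (cfg$pooling == "flatten") cfg$D * cfg$L else Cin
  widths <- c(cfg$fcLayers, 1L)
  for (m in seq_along(widths)) {
    w <- widths[m]
    ly <- list(
      W = matrix(stats::rnorm(w * fin, 0, sqrt(2 / fin)), w, fin),
      b = numeric(w)
    )
    if (cfg$batchNorm && m < length(widths))
      ly <- c(ly, list(gamma = rep(1, w), beta = numeric(w),
                       rmean = numeric(w), rvar = rep(1, w)))
    params$fc[[m]] <- ly
    fin <- w
  }
  new("PPBModel", config = cfg, params = params,
      history = data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0)),
      standardization = list(), descriptors = character(0))
}

#' Train a %PPB regression model
#'
#' Minimizes squared error on the clamped %PPB labels with Adam. For
#' augmented variants every rotation/translation replica of each training
#' peptide enters the epoch (optionally a random per-epoch subsample via
#' \code{replicasPerEpoch}); minibatches are homogeneous in span length so
#' that convolutions and batch-norm statistics are well defined. A fraction
#' of peptides is held out for validation-based early stopping; the
#' checkpoint with the best validation loss is returned. Fully seeded:
#' identical data + configuration reproduce the identical history.
#'
#' @param maps list of \linkS4class{PPBFeatureMap}, one per training peptide
#'   (rotation-0 maps from \code{\link{buildFeatureMap}}).
#' @param labels Clamped %PPB vector aligned with \code{maps}.
#' @param config Configuration from \code{\link{ppbModelConfig}}.
#' @return A trained \linkS4class{PPBModel} with per-epoch history.
#' @export
trainPPBModel <- function(maps, labels, config) {
  cfg <- config
  stopifnot(length(maps) == length(labels))
  if (any(labels < 50 | labels > 95))
    stop("labels must be clamped %PPB in [50, 95]; apply clampPPB() first")
  model <- buildPPBModel(cfg)
  params <- model@params
  # the network regresses z-scored labels (the raw 50-95 scale would need
  # tens of thousands of optimizer steps just to move the output bias);
  # predictions are mapped back to %PPB units by predictPPB
  yMu <- mean(labels)
  ySd <- stats::sd(labels)
  if (!is.finite(ySd) || ySd == 0) ySd <- 1
  params$labelNorm <- list(mu = yMu, sd = ySd)
  yNorm <- (labels - yMu) / ySd
  npep <- length(maps)
  blocks <- lapply(maps, .spanBlock)
  ns <- vapply(maps, function(m) m@n, integer(1))
  L <- cfg$L

  set.seed(cfg$seed)
  nval <- floor(cfg$valFraction * npep)
  valIdx <- if (nval >= 2L) sort(sample.int(npep, nval)) else integer(0)
  trIdx <- setdiff(seq_len(npep), valIdx)

  # replica inventory per training peptide: rotations weighted by the number
  # of translations, mirroring the full n x (L - n + 1) replica set
  replicaRots <- lapply(trIdx, function(i) {
    n <- ns[i]
    if (cfg$augment) rep(0:(n - 1L), each = L - n + 1L) else 0L
  })

  state <- .adamInit(params)
  tstep <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  wait <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    # assemble this epoch's (peptide, rotation) sample list
    pid <- integer(0); rot <- integer(0)
    for (a in seq_along(trIdx)) {
      rr <- replicaRots[[a]]
      if (!is.null(cfg$replicasPerEpoch) && cfg$augment &&
          length(rr) > cfg$replicasPerEpoch)
        rr <- rr[sample.int(length(rr), cfg$replicasPerEpoch)]
      pid <- c(pid, rep(trIdx[a], length(rr)))
      rot <- c(rot, rr)
    }
    perm <- sample.int(length(pid))
    pid <- pid[perm]; rot <- rot[perm]

    epochLoss <- 0; epochN <- 0L
    for (n in sort(unique(ns[pid]))) {
      gsel <- which(ns[pid] == n)
      nb <- ceiling(length(gsel) / cfg$batchSize)
      bounds <- pmin(seq_len(nb) * cfg$batchSize, length(gsel))
      # merge a singleton tail into the previous batch so no sample is lost
      if (nb > 1L && bounds[nb] - bounds[nb - 1L] < 2L) {
        bounds <- bounds[-(nb - 1L)]
        nb <- nb - 1L
      }
      lo <- c(1L, utils::head(bounds, -1L) + 1L)
      for (bi in seq_len(nb)) {
        sel <- gsel[lo[bi]:bounds[bi]]
        B <- length(sel)
        X3 <- array(0, c(cfg$D, n, B))
        for (s in seq_len(B)) {
          i <- pid[sel[s]]; r <- rot[sel[s]]
          ridx <- ((seq_len(n) - 1L + r) %% n) + 1L
          X3[, , s] <- blocks[[i]][, ridx, drop = FALSE]
        }
        y <- yNorm[pid[sel]]
        fw <- .netForward(params, cfg, X3, training = TRUE)
        resid <- fw$yhat - y
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch,
               " (span ", n, ", batch ", bi, ", peptides ",
               paste(unique(pid[sel]), collapse = ","), ")")
        params <- .applyStatsUpdates(params, fw$statsUpdates)
        bw <- .netBackward(params, cfg, fw$cache, 2 * resid / B,
                           training = TRUE)
        tstep <- tstep + 1L
        up <- .adamStep(params, bw$grads, state, cfg$lr, tstep)
        params <- up$params; state <- up$state
        epochLoss <- epochLoss + loss * B
        epochN <- epochN + B
      }
    }
    trainLoss <- epochLoss / max(epochN, 1L) * ySd^2

    monIdx <- if (length(valIdx)) valIdx else trIdx
    preds <- .forwardMaps(params, cfg, blocks[monIdx], ns[monIdx])
    valLoss <- mean((preds - yNorm[monIdx])^2) * ySd^2
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = trainLoss,
                                val_loss = valLoss)
    if (valLoss < best$loss - 1e-12) {
      best <- list(loss = valLoss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (is.finite(cfg$patience) && wait >= cfg$patience) break
    }
  }
  new("PPBModel", config = cfg, params = best$params,
      history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
      standardization = model@standardization,
      descriptors = model@descriptors)
}

# Eval-mode forward over a list of span blocks (possibly mixed n).
.forwardMaps <- function(params, cfg, blocks, ns) {
  out <- numeric(length(blocks))
  for (n in unique(ns)) {
    sel <- which(ns == n)
    X3 <- array(0, c(nrow(blocks[[sel[1]]]), n, length(sel)))
    for (s in seq_along(sel)) X3[, , s] <- blocks[[sel[s]]]
    out[sel] <- .netForward(params, cfg, X3, training = FALSE)$yhat
  }
  out
}

#' Predict clamped %PPB with replica averaging
#'
#' For each peptide: with augmentation, every rotation/translation replica of
#' its feature map is forwarded in evaluation mode and the replica mean is
#' taken as the raw prediction; without augmentation a single forward pass is
#' used. The raw prediction is then clamped to [50, 95]. Because the full
#' replica multiset is invariant to the ring rotation in which the peptide is
#' presented, the augmented prediction is exactly rotation invariant.
#'
#' @param model A trained \linkS4class{PPBModel}.
#' @param maps A \linkS4class{PPBFeatureMap} or list of them (one per peptide).
#' @param augment Replica-average (defaults to the variant's setting).
#' @return data.frame with columns \code{peptide_id}, \code{y_hat_raw},
#'   \code{y_hat}, \code{n_replicas}; attribute \code{"replicas"} holds the
#'   per-peptide replica prediction vectors.
#' @export
predictPPB <- function(model, maps, augment = NULL) {
  if (is(maps, "PPBFeatureMap")) maps <- list(maps)
  cfg <- model@config
  if (is.null(augment)) augment <- cfg$augment
  for (m in maps)
    if (nrow(m@values) != cfg$D || ncol(m@values) != cfg$L)
      stop("shape mismatch: map is ", nrow(m@values), " x ", ncol(m@values),
           " but the model expects ", cfg$D, " x ", cfg$L)
  blocks <- list(); ns <- integer(0); owner <- integer(0)
  for (i in seq_along(maps)) {
    reps <- if (augment) augmentFeatureMap(maps[[i]]) else list(maps[[i]])
    for (rp in reps) {
      blocks[[length(blocks) + 1L]] <- .spanBlock(rp)
      ns <- c(ns, rp@n)
      owner <- c(owner, i)
    }
  }
  vals <- .forwardMaps(model@params, cfg, blocks, ns)
  ln <- model@params$labelNorm
  if (!is.null(ln)) vals <- vals * ln$sd + ln$mu
  fowner <- factor(owner, levels = seq_along(maps))
  raw <- as.numeric(tapply(vals, fowner, mean))
  reps <- split(vals, fowner)
  out <- data.frame(
    peptide_id = vapply(maps, function(m) m@peptideId, character(1)),
    y_hat_raw = raw,
    y_hat = pmin(95, pmax(50, raw)),
    n_replicas = as.integer(table(fowner))
  )
  attr(out, "replicas") <- unname(reps)
  out
}

#' Depthwise circular convolution of a feature map
#'
#' Convolves each descriptor row of the occupied span with its own
#' length-k kernel, wrapping indices circularly within the span (the left
#' neighbour of the first substructure is the last one, and vice versa, as
#' in a ring). Positions outside the span remain zero; the output span
#' equals the input span.
#'
#' @param map A \linkS4class{PPBFeatureMap}.
#' @param kernels Numeric D x k matrix of per-row kernels, or a single
#'   length-k vector applied to every row; k must be odd and at most the
#'   span length.
#' @return A \linkS4class{PPBFeatureMap} of the same shape.
#' @examples
#' m <- buildFeatureMap(matrix(1:3, 1), "p")
#' mapValues(cyclicConv1d(m, c(0, 1, 0)))  # identity kernel
#' @export
cyclicConv1d <- function(map, kernels) {
  stopifnot(is(map, "PPBFeatureMap"))
  D <- nrow(map@values)
  if (is.vector(kernels)) kernels <- matrix(kernels, D, length(kernels),
                                            byrow = TRUE)
  stopifnot(nrow(kernels) == D)
  k <- ncol(kernels)
  if (k %% 2L != 1L) stop("kernel size must be odd")
  n <- map@n
  if (k > n) stop("kernel larger than ring: kernel size ", k,
                  " exceeds span ", n)
  block <- .spanBlock(map)
  idx <- .convIndex(n, k, "cyclic")
  out <- matrix(0, D, n)
  for (t in seq_len(k))
    out <- out + kernels[, t] * block[, idx[t, ], drop = FALSE]
  vals <- matrix(0, D, ncol(map@values))
  vals[, (map@start + 1L):(map@start + n)] <- out
  rownames(vals) <- rownames(map@values)
  new("PPBFeatureMap", values = vals, start = map@start, n = n,
      peptideId = map@peptideId, rotation = map@rotation,
      translation = map@translation)
}
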