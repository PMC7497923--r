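# The cycle-consistent dual-network objective and its optimization:
# both networks are updated jointly from the combined loss
#   L = sum over both directions of
#       lambda_cont * L_cont(warped moving, fixed)
#     + lambda_reg  * L_reg(field)
#     + lambda_cyc  * L_cyc(moving)
# with L_cyc the L1 error of reconstructing the moving image by warping
# the deformed image with the opposite network's field predicted from
# the (deformed, original) pair.

# First-difference smoothness penalty as a tape op: the mean squared
# forward difference per difference term (averaged over voxels, the 3
# displacement components and the 3 axes), so that a lambda = 1
# regularizer sits on the same per-term scale as the content and cycle
# means.
ag_gradpen <- function(f, nvox) {
  u <- f$value
  d <- dim(u)
  nterm <- 9 * nvox
  diffs <- list()
  val <- 0
  if (d[1] >= 2) {
    diffs$x <- u[2:d[1], , , , drop = FALSE] - u[1:(d[1] - 1), , , , drop = FALSE]
    val <- val + sum(diffs$x^2) / nterm
  }
  if (d[2] >= 2) {
    diffs$y <- u[, 2:d[2], , , drop = FALSE] - u[, 1:(d[2] - 1), , , drop = FALSE]
    val <- val + sum(diffs$y^2) / nterm
  }
  if (d[3] >= 2) {
    diffs$z <- u[, , 2:d[3], , drop = FALSE] - u[, , 1:(d[3] - 1), , drop = FALSE]
    val <- val + sum(diffs$z^2) / nterm
  }
  ag_op(val, list(f), function(g) {
    gu <- array(0, d)
    s <- 2 * g / nterm
    if (!is.null(diffs$x)) {
      gu[2:d[1], , , ] <- gu[2:d[1], , , ] + s * diffs$x
      gu[1:(d[1] - 1), , , ] <- gu[1:(d[1] - 1), , , ] - s * diffs$x
    }
    if (!is.null(diffs$y)) {
      gu[, 2:d[2], , ] <- gu[, 2:d[2], , ] + s * diffs$y
      gu[, 1:(d[2] - 1), , ] <- gu[, 1:(d[2] - 1), , ] - s * diffs$y
    }
    if (!is.null(diffs$z)) {
      gu[, , 2:d[3], ] <- gu[, , 2:d[3], ] + s * diffs$z
      gu[, , 1:(d[3] - 1), ] <- gu[, , 1:(d[3] - 1), ] - s * diffs$z
    }
    list(gu)
  })
}

.term_names <- c("cont_b2a", "reg_b2a", "cyc_b2a",
                 "cont_a2b", "reg_a2b", "cyc_a2b")

# Build the full two-direction loss graph for one (a, b) pair.
# pnAB / pnBA: named lists of parameter nodes (or constants).
# descA / descB: precomputed MIND descriptor arrays of a and b.
.pair_loss_graph <- function(pnAB, pnBA, cfg, adata, bdata, mindCfg,
                             w, descA, descB, regType = "magnitude") {
  aN <- ag_const(adata)
  bN <- ag_const(bdata)
  nvox <- prod(dim(adata))
  zero <- ag_const(0)
  one_dir <- function(pnFwd, pnBwd, movN, fixN, fixDesc) {
    fld <- .net_forward(pnFwd, cfg, movN, fixN)
    warped <- ag_warp(movN, fld)
    cont <- if (w@lambdaCont > 0)
      ag_content_loss(warped, fixDesc, mindCfg) else zero
    reg <- if (w@lambdaReg > 0) {
      if (regType == "magnitude") ag_sumsq(fld, nvox)
      else ag_gradpen(fld, nvox)
    } else zero
    cyc <- if (w@lambdaCyc > 0) {
      fldBack <- .net_forward(pnBwd, cfg, warped, movN)
      ag_meanabs(ag_warp(warped, fldBack), movN)
    } else zero
    list(cont = cont, reg = reg, cyc = cyc)
  }
  d1 <- one_dir(pnBA, pnAB, bN, aN, descA)  # B moving toward A
  d2 <- one_dir(pnAB, pnBA, aN, bN, descB)  # A moving toward B
  terms <- list(d1$cont, d1$reg, d1$cyc, d2$cont, d2$reg, d2$cyc)
  weights <- c(w@lambdaCont, w@lambdaReg, w@lambdaCyc,
               w@lambdaCont, w@lambdaReg, w@lambdaCyc)
  total <- ag_wsum(terms, weights)
  list(total = total, terms = terms, weights = weights)
}

.case_ab <- function(case) {
  if (is(case, "PhantomCase")) return(list(a = case@volA, b = case@volB))
  if (is.list(case) && !is.null(case$a) && !is.null(case$b)) return(case)
  stop("each case must be a PhantomCase or a list(a = Volume, b = Volume)")
}

#' Cycle-reconstruction loss
#'
#' Warps the moving image by the forward network's field, predicts the
#' return field from the (deformed, original) pair with the backward
#' network, warps the deformed image back, and reports the mean
#' absolute reconstruction error against the original moving image.
#' Zero for identity (zero-field) networks.
#'
#' @param moving,fixed normalized [Volume-class] objects of the
#'   networks' input size.
#' @param netFwd network deforming `moving` toward `fixed`.
#' @param netBwd network deforming back.
#' @return A non-negative scalar.
#' @export
cycleLoss <- function(moving, fixed, netFwd, netBwd) {
  stopifnot(is(netFwd, "RegistrationNetwork"), is(netBwd, "RegistrationNetwork"))
  if (!identical(dim(moving@data), dim(fixed@data)))
    stop("cycleLoss: volume sizes differ")
  f1 <- predictField(netFwd, moving, fixed)
  warped <- warpVolume(moving, f1)
  f2 <- predictField(netBwd, warped, moving)
  recon <- warpVolume(warped, f2)
  mean(abs(recon@data - moving@data))
}

#' Total cycle-consistent training loss with per-term breakdown
#'
#' Evaluates the weighted two-direction objective for one volume pair
#' under the current networks: content, regularization and cycle terms
#' for B moving toward A and for A moving toward B.
#'
#' @param a,b normalized [Volume-class] objects (e.g. CT-like and
#'   MR-like) of the networks' input size.
#' @param state a [TrainState-class].
#' @param weights a [LossWeights-class].
#' @param mindCfg a [MindConfig-class].
#' @param regType `"gradient"` (default) or `"magnitude"` field
#'   regularization; see [trainRegistration()].
#' @return A list with `total` and named `terms` (length 6).
#' @export
totalLoss <- function(a, b, state, weights = LossWeights(),
                      mindCfg = mindConfig(), regType = "gradient") {
  stopifnot(is(state, "TrainState"))
  if (!identical(dim(a@data), dim(b@data)))
    stop("totalLoss: volume sizes differ")
  cfg <- state@netAB@config
  .check_net_input(cfg, a, "a")
  .check_net_input(cfg, b, "b")
  descA <- ag_value(ag_mind(ag_const(a@data), mindCfg))
  descB <- ag_value(ag_mind(ag_const(b@data), mindCfg))
  g <- .pair_loss_graph(lapply(state@netAB@params, ag_const),
                        lapply(state@netBA@params, ag_const),
                        cfg, a@data, b@data, mindCfg, weights,
                        descA, descB, regType)
  terms <- setNames(vapply(g$terms, ag_value, 0), .term_names)
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad))
    stop("non-finite loss term(s): ", paste(bad, collapse = ", "))
  list(total = ag_value(g$total), terms = terms)
}

.adam_new <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

.adam_step <- function(params, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, st = st)
}

#' Train the cycle-consistent registration networks
#'
#' Joint Adam optimization of both networks on the combined loss, one
#' volume pair per step, fully unsupervised (masks and landmarks are
#' never seen). Deterministic given `seed` under single-threaded
#' execution.
#'
#' @param cases list of training pairs: [PhantomCase-class] objects or
#'   `list(a = Volume, b = Volume)`, preprocessed to a common size and
#'   normalized to `[-1, 1]`.
#' @param netCfg a [NetworkConfig-class] shared by both networks.
#' @param weights a [LossWeights-class] (defaults: content 5,
#'   regularization 1, cycle 1).
#' @param mindCfg a [MindConfig-class].
#' @param epochs passes over `cases` (0 returns the initial state).
#' @param lr,beta1,beta2 Adam hyperparameters (defaults 2e-3, 0.5,
#'   0.999).
#' @param seed integer seed for initialization and case ordering.
#' @param regType field regularization used in the objective:
#'   `"gradient"` (default; first differences of the displacement,
#'   penalizing non-smoothness) or `"magnitude"` (squared displacement
#'   norm, a zero-deformation prior that suppresses any recovery of a
#'   real deformation; see the methods vignette).
#' @param shuffle shuffle case order each epoch (seeded).
#' @param state optional [TrainState-class] to resume from.
#' @param checkpointDir if non-NULL, networks are checkpointed there
#'   after each epoch.
#' @param verbose print per-epoch mean losses.
#' @return A [TrainState-class] with the trained networks and the
#'   per-step loss history.
#' @export
trainRegistration <- function(cases, netCfg, weights = LossWeights(),
                              mindCfg = mindConfig(), epochs = 10L,
                              lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                              seed = 1L, regType = c("magnitude", "gradient"),
                              shuffle = TRUE, state = NULL,
                              checkpointDir = NULL, verbose = FALSE) {
  regType <- match.arg(regType)
  epochs <- as.integer(epochs)
  seed <- as.integer(seed)
  if (length(cases) < 1L) stop("need at least one training pair")
  pairs <- lapply(cases, .case_ab)
  for (p in pairs) {
    .check_net_input(netCfg, p$a, "a")
    .check_net_input(netCfg, p$b, "b")
  }
  if (is.null(state)) {
    netAB <- buildNetwork(netCfg, seed)
    netBA <- buildNetwork(netCfg, seed + 1L)
    params <- c(setNames(netAB@params, paste0("AB.", names(netAB@params))),
                setNames(netBA@params, paste0("BA.", names(netBA@params))))
    opt <- .adam_new(params)
    epoch0 <- 0L
    history <- data.frame()
  } else {
    stopifnot(is(state, "TrainState"))
    netAB <- state@netAB
    netBA <- state@netBA
    params <- c(setNames(netAB@params, paste0("AB.", names(netAB@params))),
                setNames(netBA@params, paste0("BA.", names(netBA@params))))
    opt <- if (length(state@optState)) state@optState else .adam_new(params)
    epoch0 <- state@epoch
    history <- state@lossHistory
  }
  mk_state <- function() {
    abn <- names(netAB@params)
    ban <- names(netBA@params)
    new("TrainState",
        netAB = new("RegistrationNetwork", config = netCfg,
                    params = setNames(params[paste0("AB.", abn)], abn)),
        netBA = new("RegistrationNetwork", config = netCfg,
                    params = setNames(params[paste0("BA.", ban)], ban)),
        optState = opt, epoch = epoch0, lossHistory = history)
  }
  if (epochs < 1L) return(mk_state())
  set.seed(seed + 104729L)  # ordering substream, distinct from init
  # fixed-image descriptors are constant across steps: compute once
  descs <- lapply(pairs, function(p) list(
    a = ag_value(ag_mind(ag_const(p$a@data), mindCfg)),
    b = ag_value(ag_mind(ag_const(p$b@data), mindCfg))))
  rows <- vector("list", epochs * length(pairs))
  ri <- 0L
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(length(pairs)) else seq_along(pairs)
    for (ci in ord) {
      p <- pairs[[ci]]
      ag_tape_begin()
      pnAll <- lapply(params, ag_param)
      pnAB <- setNames(pnAll[paste0("AB.", names(netAB@params))],
                       names(netAB@params))
      pnBA <- setNames(pnAll[paste0("BA.", names(netBA@params))],
                       names(netBA@params))
      g <- .pair_loss_graph(pnAB, pnBA, netCfg, p$a@data, p$b@data,
                            mindCfg, weights, descs[[ci]]$a, descs[[ci]]$b,
                            regType)
      terms <- setNames(vapply(g$terms, ag_value, 0), .term_names)
      total <- ag_value(g$total)
      if (!is.finite(total)) {
        ag_tape_clear()
        warning(sprintf(
          "training diverged (non-finite loss) at epoch %d; returning last finite state",
          epoch0 + ep))
        epoch0 <- epoch0 + ep - 1L
        history <- do.call(rbind, c(list(history), rows[seq_len(ri)]))
        st <- mk_state()
        if (!is.null(checkpointDir)) saveTrainState(st,
          file.path(checkpointDir, "state_diverged.rds"))
        return(st)
      }
      ag_backward(g$total)
      grads <- lapply(pnAll, function(n) n$grad)
      ag_tape_clear()
      upd <- .adam_step(params, grads, opt, lr, beta1, beta2)
      params <- upd$params
      opt <- upd$st
      ri <- ri + 1L
      rows[[ri]] <- data.frame(epoch = epoch0 + ep, case = ci,
                               t(terms), total = total)
    }
    if (verbose) {
      recent <- do.call(rbind, rows[(ri - length(pairs) + 1L):ri])
      message(sprintf("epoch %d: total %.5f", epoch0 + ep,
                      mean(recent$total)))
    }
    if (!is.null(checkpointDir)) {
      epoch0_tmp <- epoch0 + ep
      st <- mk_state()
      st@epoch <- epoch0_tmp
      saveTrainState(st, file.path(checkpointDir,
                                   sprintf("state_epoch%04d.rds", epoch0_tmp)))
    }
  }
  epoch0 <- epoch0 + epochs
  history <- do.call(rbind, c(list(history), rows[seq_len(ri)]))
  mk_state()
}

#' Save / load a full training state
#'
#' @param state a [TrainState-class].
#' @param path file path.
#' @return `loadTrainState` returns the restored [TrainState-class].
#' @export
saveTrainState <- function(state, path) {
  stopifnot(is(state, "TrainState"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname saveTrainState
#' @export
loadTrainState <- function(path) {
  if (!file.exists(path)) stop("train state not found: ", path)
  readRDS(path)
}
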