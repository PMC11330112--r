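# The deep polygenic risk network: a sparse partial-connection layer mapping
# encoded SNPs to genes, one bidirectional LSTM per chromosome over the
# gene sequence (genes in genomic order), and a sigmoid head over the
# concatenated hidden states plus covariates, trained with class-weighted
# binary cross-entropy, L2 on the recurrent weights, dropout on the BiLSTM
# outputs, Adam, and early stopping.
#
# The network is implemented directly with dense linear algebra batched over
# samples; the partial layer's sparsity is enforced structurally by masking
# both the weights and their gradients, so connections outside the
# SNP-to-gene map are exactly zero at every step of training.

#' Model configuration
#'
#' @param lstm_hidden_per_direction Hidden units per LSTM direction
#'   (default 4).
#' @param dropout_rate Dropout on the BiLSTM outputs during training.
#' @param l2_coefficient L2 penalty on the LSTM input/recurrent weight
#'   matrices.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param val_fraction Fraction of the training data held out (stratified)
#'   for early stopping.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param variant `"full"` (two-dim encoding + partial layer),
#'   `"no_partial_layer"` (encoded SNPs fed directly as the sequence), or
#'   `"additive_encoding"` (additive one-dim encoding + partial layer).
#' @param covariate_dim Number of covariates concatenated before the head.
#' @param gene_activation `"none"` (default; the gene feature is the plain
#'   weighted aggregate of its SNP features) or `"tanh"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(lstm_hidden_per_direction = 4L,
                         dropout_rate = 0.2, l2_coefficient = 1e-4,
                         learning_rate = 1e-3, max_epochs = 50L,
                         batch_size = 128L, early_stop_patience = 5L,
                         val_fraction = 0.1, seed = 1L,
                         variant = c("full", "no_partial_layer",
                                     "additive_encoding"),
                         covariate_dim = 0L,
                         gene_activation = c("none", "tanh")) {
  variant <- match.arg(variant)
  gene_activation <- match.arg(gene_activation)
  stopifnot(lstm_hidden_per_direction >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            l2_coefficient >= 0, learning_rate > 0, max_epochs >= 1,
            batch_size >= 1, early_stop_patience >= 0,
            val_fraction > 0, val_fraction < 1, covariate_dim >= 0)
  structure(list(lstm_hidden_per_direction = as.integer(lstm_hidden_per_direction),
                 dropout_rate = dropout_rate, l2_coefficient = l2_coefficient,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 variant = variant, covariate_dim = as.integer(covariate_dim),
                 gene_activation = gene_activation),
            class = "model_config")
}

#' Class weights for imbalanced case/control training
#'
#' `w0 = n / (2 (n - n_positive))` for controls and
#' `w1 = n / (2 n_positive)` for cases; balanced classes give (1, 1) and the
#' weighted loss reduces to plain binary cross-entropy.
#'
#' @param n_samples Total sample count.
#' @param n_positive Number of cases; must satisfy `0 < n_positive <
#'   n_samples`.
#' @return Named numeric vector `c(w0, w1)`.
#' @export
class_weights <- function(n_samples, n_positive) {
  if (n_positive <= 0 || n_positive >= n_samples) {
    stop("degenerate cohort: need 0 < n_positive < n_samples")
  }
  c(w0 = n_samples / (2 * (n_samples - n_positive)),
    w1 = n_samples / (2 * n_positive))
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `-w1 y log(p) - w0 (1 - y) log(1 - p)`, with
#' predictions clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param w0,w1 Control/case class weights (default 1: plain BCE).
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(p, y, w0 = 1, w1 = 1) {
  if (length(p) != length(y)) stop("length mismatch between p and y")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-w1 * y * log(p) - w0 * (1 - y) * log(1 - p))
}

#' Build an untrained risk model
#'
#' Wires the network defined by a connectivity map: per chromosome, a masked
#' partial-connection weight matrix (one column per gene, rows for each
#' connected SNP's encoded dimensions) and a BiLSTM over the gene sequence in
#' genomic order; a single sigmoid head reads the concatenation of every
#' chromosome's hidden states plus covariates. The `no_partial_layer`
#' variant skips the gene aggregation and feeds encoded SNPs (one per step)
#' to the BiLSTMs. Head weights start at zero, so an untrained model scores
#' every sample 0.5.
#'
#' @param conn A [build_connectivity()] map.
#' @param cfg A [model_config()].
#' @return An object of class `risk_model`.
#' @export
build_risk_model <- function(conn, cfg) {
  stopifnot(inherits(conn, "connectivity_map"), inherits(cfg, "model_config"))
  if (length(conn$chromosomes) == 0) stop("empty connectivity map")
  set.seed(cfg$seed)
  d_enc <- if (cfg$variant == "additive_encoding") 1L else 2L
  h <- cfg$lstm_hidden_per_direction
  use_partial <- cfg$variant != "no_partial_layer"
  partial <- list()
  masks <- list()
  lstm <- list()
  layout <- list()
  offset <- 0L
  for (key in names(conn$chromosomes)) {
    ch <- conn$chromosomes[[key]]
    m_c <- length(ch$snp_ids)
    if (use_partial) {
      l_c <- nrow(ch$genes)
      mask <- ch$incidence[rep(seq_len(m_c), each = d_enc), , drop = FALSE]
      w <- matrix(0, nrow = d_enc * m_c, ncol = l_c)
      sd_col <- 1 / sqrt(pmax(1, colSums(mask)))
      w[mask] <- stats::rnorm(sum(mask)) *
        rep(sd_col, times = colSums(mask))
      partial[[key]] <- w
      masks[[key]] <- mask
      d_seq <- 1L
    } else {
      l_c <- m_c
      d_seq <- d_enc
    }
    lstm[[key]] <- list(fwd = .init_lstm(d_seq, h),
                        bwd = .init_lstm(d_seq, h))
    layout[[key]] <- list(m = m_c, steps = l_c, d_seq = d_seq,
                          offset = offset, width = 2L * h * l_c)
    offset <- offset + 2L * h * l_c
  }
  d_total <- offset + cfg$covariate_dim
  structure(list(
    connectivity = conn, cfg = cfg, snp_ids = conn$snp_ids,
    d_enc = d_enc, layout = layout,
    params = list(partial = partial, lstm = lstm,
                  head = list(W = matrix(0, nrow = d_total, ncol = 1), b = 0)),
    masks = masks, cov_center = NULL, cov_scale = NULL, trained = FALSE
  ), class = "risk_model")
}

.init_lstm <- function(d, h) {
  k <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  list(Wx = matrix(stats::runif(d * 4 * h, -k, k), nrow = d),
       Wh = matrix(stats::runif(h * 4 * h, -k, k), nrow = h),
       b = b)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model (", x$cfg$variant, "): ", length(x$snp_ids), " SNPs, ",
      sum(vapply(x$layout, `[[`, 0L, "steps")), " sequence steps over ",
      length(x$layout), " chromosome(s), ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# split an encoded array into per-chromosome flattened matrices
# [n x d_enc * m_c] with columns grouped per SNP (dim-major within SNP)
.split_encoded <- function(model, X) {
  stopifnot(inherits(X, "encoded_genotypes"))
  ids <- attr(X, "snp_ids")
  if (!identical(ids, model$snp_ids)) {
    stop("encoded SNP order does not match the model's SNP order")
  }
  want_mode <- if (model$d_enc == 1L) "additive" else "two_dim"
  if (!identical(attr(X, "mode"), want_mode)) {
    stop("encoding mode '", attr(X, "mode"), "' does not match the model (",
         want_mode, ")")
  }
  n <- dim(X)[1]
  d <- model$d_enc
  out <- list()
  col0 <- 0L
  for (key in names(model$layout)) {
    m_c <- model$layout[[key]]$m
    xs <- unclass(X)[, col0 + seq_len(m_c), , drop = FALSE]
    flat <- matrix(0, nrow = n, ncol = d * m_c)
    for (dd in seq_len(d)) {
      flat[, seq(dd, d * m_c, by = d)] <- xs[, , dd]
    }
    out[[key]] <- flat
    col0 <- col0 + m_c
  }
  out
}

# one LSTM direction over sequence G [n x d*L]; returns H [n x h*L]
# (step-major) and a cache for backprop
.lstm_forward <- function(G, d, L, par, h) {
  n <- nrow(G)
  H <- matrix(0, n, h * L)
  cache <- vector("list", L)
  h_prev <- matrix(0, n, h)
  c_prev <- matrix(0, n, h)
  for (t in seq_len(L)) {
    x_t <- G[, (t - 1L) * d + seq_len(d), drop = FALSE]
    pre <- x_t %*% par$Wx + h_prev %*% par$Wh +
      matrix(par$b, n, 4 * h, byrow = TRUE)
    i_g <- .sigmoid(pre[, seq_len(h), drop = FALSE])
    f_g <- .sigmoid(pre[, h + seq_len(h), drop = FALSE])
    o_g <- .sigmoid(pre[, 2 * h + seq_len(h), drop = FALSE])
    g_g <- tanh(pre[, 3 * h + seq_len(h), drop = FALSE])
    c_t <- f_g * c_prev + i_g * g_g
    tc <- tanh(c_t)
    h_t <- o_g * tc
    H[, (t - 1L) * h + seq_len(h)] <- h_t
    cache[[t]] <- list(x = x_t, h_prev = h_prev, c_prev = c_prev,
                       i = i_g, f = f_g, o = o_g, g = g_g, tc = tc)
    h_prev <- h_t
    c_prev <- c_t
  }
  list(H = H, cache = cache)
}

# backprop through one LSTM direction; dH is [n x h*L] step-major
.lstm_backward <- function(dH, cache, par, d, L, h) {
  n <- nrow(dH)
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(length(par$b))
  dG <- matrix(0, n, d * L)
  dh_next <- matrix(0, n, h)
  dc_next <- matrix(0, n, h)
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    dh <- dH[, (t - 1L) * h + seq_len(h), drop = FALSE] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dpre <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, dpre)
    dWh <- dWh + crossprod(cc$h_prev, dpre)
    db <- db + colSums(dpre)
    dG[, (t - 1L) * d + seq_len(d)] <- dpre %*% t(par$Wx)
    dh_next <- dpre %*% t(par$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dG = dG)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# column index that reverses step order while keeping within-step dims
.rev_step_index <- function(d, L) {
  as.vector(vapply(rev(seq_len(L)),
                   function(t) (t - 1L) * d + seq_len(d), integer(d)))
}

# full forward pass; Xc = .split_encoded output, Z covariates already scaled
# returns score + (optionally) all caches needed for backprop
.model_forward <- function(model, Xc, cov = NULL, keep_cache = FALSE,
                           dropout_mask = NULL) {
  h <- model$cfg$lstm_hidden_per_direction
  n <- nrow(Xc[[1]])
  blocks <- list()
  caches <- list()
  for (key in names(model$layout)) {
    lay <- model$layout[[key]]
    d <- lay$d_seq
    L <- lay$steps
    if (model$cfg$variant != "no_partial_layer") {
      raw <- Xc[[key]] %*% model$params$partial[[key]]
      G <- if (model$cfg$gene_activation == "tanh") tanh(raw) else raw
    } else {
      raw <- NULL
      G <- Xc[[key]]
    }
    fwd <- .lstm_forward(G, d, L, model$params$lstm[[key]]$fwd, h)
    Grev <- G[, .rev_step_index(d, L), drop = FALSE]
    bwd <- .lstm_forward(Grev, d, L, model$params$lstm[[key]]$bwd, h)
    # assemble per-step [fwd_t, bwd_t] (bwd step t sits at reversed position)
    block <- matrix(0, n, 2 * h * L)
    for (t in seq_len(L)) {
      block[, (t - 1L) * 2 * h + seq_len(h)] <-
        fwd$H[, (t - 1L) * h + seq_len(h)]
      block[, (t - 1L) * 2 * h + h + seq_len(h)] <-
        bwd$H[, (L - t) * h + seq_len(h)]
    }
    blocks[[key]] <- block
    if (keep_cache) caches[[key]] <- list(fwd = fwd, bwd = bwd, G = G, raw = raw)
  }
  Z <- do.call(cbind, unname(blocks))
  if (!is.null(dropout_mask)) Z <- Z * dropout_mask
  if (!is.null(cov)) Z <- cbind(Z, cov)
  z_lin <- as.numeric(Z %*% model$params$head$W + model$params$head$b)
  p <- .sigmoid(z_lin)
  if (keep_cache) {
    list(p = p, Z = Z, caches = caches)
  } else {
    p
  }
}

# gradients of the batch loss wrt every parameter
.model_backward <- function(model, fw, Xc, y, wts, dropout_mask = NULL) {
  cfg <- model$cfg
  h <- cfg$lstm_hidden_per_direction
  n <- length(y)
  p <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
  wvec <- ifelse(y == 1, wts["w1"], wts["w0"])
  dz <- matrix(wvec * (p - y) / n, ncol = 1)
  grads <- list(partial = list(), lstm = list(),
                head = list(W = crossprod(fw$Z, dz), b = sum(dz)))
  dZ <- dz %*% t(model$params$head$W[, 1, drop = FALSE])
  use_partial <- cfg$variant != "no_partial_layer"
  hid_width <- sum(vapply(model$layout, `[[`, 0L, "width"))
  dZh <- dZ[, seq_len(hid_width), drop = FALSE]
  if (!is.null(dropout_mask)) dZh <- dZh * dropout_mask
  for (key in names(model$layout)) {
    lay <- model$layout[[key]]
    d <- lay$d_seq
    L <- lay$steps
    block <- dZh[, lay$offset + seq_len(lay$width), drop = FALSE]
    dHf <- matrix(0, n, h * L)
    dHb_rev <- matrix(0, n, h * L)
    for (t in seq_len(L)) {
      dHf[, (t - 1L) * h + seq_len(h)] <-
        block[, (t - 1L) * 2 * h + seq_len(h)]
      dHb_rev[, (L - t) * h + seq_len(h)] <-
        block[, (t - 1L) * 2 * h + h + seq_len(h)]
    }
    cache <- fw$caches[[key]]
    par <- model$params$lstm[[key]]
    bf <- .lstm_backward(dHf, cache$fwd$cache, par$fwd, d, L, h)
    bb <- .lstm_backward(dHb_rev, cache$bwd$cache, par$bwd, d, L, h)
    # un-reverse the backward direction's input gradient
    idx <- .rev_step_index(d, L)
    dG <- bf$dG
    dG[, idx] <- dG[, idx] + bb$dG
    l2 <- cfg$l2_coefficient
    grads$lstm[[key]] <- list(
      fwd = list(Wx = bf$dWx + 2 * l2 * par$fwd$Wx,
                 Wh = bf$dWh + 2 * l2 * par$fwd$Wh, b = bf$db),
      bwd = list(Wx = bb$dWx + 2 * l2 * par$bwd$Wx,
                 Wh = bb$dWh + 2 * l2 * par$bwd$Wh, b = bb$db)
    )
    if (use_partial) {
      if (cfg$gene_activation == "tanh") dG <- dG * (1 - cache$G^2)
      dP <- crossprod(Xc[[key]], dG)
      dP[!model$masks[[key]]] <- 0  # sparsity: no gradient off the map
      grads$partial[[key]] <- dP
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = c("matrix", "numeric", "array"))
}

# walk params/grads/state in lockstep
.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_leaf <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(s) && identical(sort(names(s)), c("m", "v"))) {
      return(step_leaf(p, g, s))
    }
    for (k in names(p)) {
      res <- walk(p[[k]], g[[k]], s[[k]])
      p[[k]] <- res$p
      s[[k]] <- res$s
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

# ---- training --------------------------------------------------------------

#' Train a risk model
#'
#' Minimizes class-weighted binary cross-entropy plus an L2 penalty on the
#' LSTM weights with Adam, inverted dropout on the BiLSTM outputs, and early
#' stopping on a stratified internal validation split (best-epoch weights
#' are restored). Class weights are computed once from the full `y` passed
#' in. Fully deterministic given the config seed.
#'
#' @param model An untrained (or trained) [build_risk_model()].
#' @param X [encode_genotypes()] output matching the model's SNP order and
#'   encoding mode.
#' @param y Binary labels.
#' @param covariates Optional numeric matrix `[n x covariate_dim]`;
#'   standardized internally (center/scale stored on the model).
#' @return List with the trained `model` and a `report` (per-epoch
#'   train/validation weighted loss, chosen epoch, class weights, seed).
#' @export
train_risk_model <- function(model, X, y, covariates = NULL) {
  cfg <- model$cfg
  y <- as.integer(y)
  n <- length(y)
  stopifnot(dim(X)[1] == n)
  if (length(unique(y)) < 2) stop("training needs both classes present")
  wts <- class_weights(n, sum(y))
  if (cfg$covariate_dim > 0) {
    if (is.null(covariates) || ncol(covariates) != cfg$covariate_dim) {
      stop("expected ", cfg$covariate_dim, " covariate column(s)")
    }
    model$cov_center <- colMeans(covariates)
    model$cov_scale <- apply(covariates, 2, stats::sd)
    model$cov_scale[model$cov_scale == 0] <- 1
    cov <- scale(covariates, model$cov_center, model$cov_scale)
  } else {
    cov <- NULL
    if (!is.null(covariates)) stop("model was built with covariate_dim = 0")
  }
  Xc <- .split_encoded(model, X)
  set.seed(cfg$seed)
  val_idx <- stratified_holdout(y, cfg$val_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  sub_rows <- function(lst, idx) lapply(lst, function(m) m[idx, , drop = FALSE])
  Xc_val <- sub_rows(Xc, val_idx)
  cov_val <- if (!is.null(cov)) cov[val_idx, , drop = FALSE]
  hid_width <- sum(vapply(model$layout, `[[`, 0L, "width"))
  state <- .adam_init(model$params)
  step <- 0L
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(tr_idx)
    batch_losses <- numeric(0)
    for (b0 in seq(1, length(perm), by = cfg$batch_size)) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, length(perm))]
      Xb <- sub_rows(Xc, idx)
      covb <- if (!is.null(cov)) cov[idx, , drop = FALSE]
      dm <- if (cfg$dropout_rate > 0) {
        matrix((stats::runif(length(idx) * hid_width) > cfg$dropout_rate) /
                 (1 - cfg$dropout_rate), nrow = length(idx))
      }
      fw <- .model_forward(model, Xb, covb, keep_cache = TRUE,
                           dropout_mask = dm)
      loss <- weighted_bce(fw$p, y[idx], wts["w0"], wts["w1"])
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate too high?)")
      }
      batch_losses <- c(batch_losses, loss)
      grads <- .model_backward(model, fw, Xb, y[idx], wts, dropout_mask = dm)
      step <- step + 1L
      res <- .adam_step(model$params, grads, state, cfg$learning_rate, step)
      model$params <- res$p
      state <- res$s
    }
    p_val <- .model_forward(model, Xc_val, cov_val)
    val_loss <- weighted_bce(p_val, y[val_idx], wts["w0"], wts["w1"])
    hist_train <- c(hist_train, mean(batch_losses))
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  report <- list(
    loss = data.frame(epoch = seq_along(hist_train), train = hist_train,
                      validation = hist_val),
    chosen_epoch = best$epoch, class_weights = wts, seed = cfg$seed
  )
  list(model = model, report = report)
}

#' Deep polygenic risk scores
#'
#' Deterministic forward pass (dropout disabled); scores lie strictly in
#' (0, 1) and are row-independent, so batching and sample order do not
#' change them.
#'
#' @param model A trained `risk_model`.
#' @param X [encode_genotypes()] output in the model's SNP order and mode.
#' @param covariates Covariate matrix when the model was trained with
#'   covariates.
#' @return Numeric score vector, one per sample.
#' @export
predict_scores <- function(model, X, covariates = NULL) {
  cfg <- model$cfg
  if (cfg$covariate_dim > 0) {
    if (is.null(covariates) || ncol(covariates) != cfg$covariate_dim) {
      stop("expected ", cfg$covariate_dim, " covariate column(s)")
    }
    cov <- scale(covariates, model$cov_center, model$cov_scale)
  } else {
    cov <- NULL
  }
  Xc <- .split_encoded(model, X)
  p <- .model_forward(model, Xc, cov)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

# ---- checkpointing ---------------------------------------------------------

.connectivity_hash <- function(conn) {
  edges <- as.data.frame(conn)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.table(edges, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Save / load a risk model checkpoint
#'
#' The checkpoint stores the parameters, config and a hash of the
#' connectivity edge list; loading verifies the hash so a model cannot
#' silently score through mismatched wiring.
#'
#' @param model A `risk_model`.
#' @param path Checkpoint path (RDS).
#' @return `path` invisibly for save; the model for load.
#' @export
save_risk_model <- function(model, path) {
  obj <- list(model = model, hash = .connectivity_hash(model$connectivity))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$hash, .connectivity_hash(obj$model$connectivity))) {
    stop("checkpoint connectivity hash mismatch")
  }
  obj$model
}
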