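#' Network and training configuration for the point-set segmenter
#'
#' The segmenter is a miniature hierarchical point-set network: two
#' set-abstraction levels (farthest point sampling -> fixed-radius
#' grouping -> shared per-point feature map -> channel-wise max pool)
#' followed by two feature-propagation levels (inverse-distance-weighted
#' 3-NN interpolation back to the finer level, concatenation with the
#' skip features, per-point feature map) and a linear 2-class head.
#' Input features per point are the elevation above the chunk's 5th
#' z-percentile plus RGB when colors are present; grouping uses local
#' coordinate offsets. Sized to train on a CPU in minutes.
#'
#' @param m1,m2 centers kept by set-abstraction levels 1 and 2.
#' @param r1,r2 grouping radii in meters.
#' @param k group size (points per neighborhood).
#' @param w1,w2 feature widths of the two encoder levels.
#' @param f2,f1 feature widths of the two decoder levels.
#' @return An object of class `seg_net_config`.
#' @export
seg_net_config <- function(m1 = 512, m2 = 128, r1 = 0.25, r2 = 0.75, k = 16,
                           w1 = 32, w2 = 64, f2 = 64, f1 = 32) {
  if (any(c(r1, r2) <= 0)) stop("radii must be > 0", call. = FALSE)
  if (any(c(m1, m2, k, w1, w2, f2, f1) < 1)) stop("sizes must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "seg_net_config")
}

#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param block_m edge of the square spatial blocks a cloud is chunked
#'   into before encoding.
#' @param max_points maximum points per chunk; larger blocks are
#'   partitioned deterministically.
#' @rdname seg_net_config
#' @export
seg_train_config <- function(epochs = 25, lr = 0.01, block_m = 2.0,
                             max_points = 4096) {
  structure(as.list(environment()), class = "seg_train_config")
}

relu <- function(x) (x > 0) * x

# ---- chunking ---------------------------------------------------------------

chunk_features <- function(cloud, idx) {
  z <- cloud$points[idx, 3]
  zrel <- z - stats::quantile(z, 0.05, names = FALSE)
  if (!is.null(cloud$colors)) cbind(zrel, cloud$colors[idx, , drop = FALSE])
  else cbind(zrel)
}

make_chunks <- function(cloud, block_m, max_points) {
  p <- cloud$points
  bx <- floor((p[, 1] - min(p[, 1])) / block_m)
  by <- floor((p[, 2] - min(p[, 2])) / block_m)
  groups <- split(seq_len(nrow(p)), paste(bx, by))
  out <- list()
  for (g in groups) {
    # canonical within-block order (by coordinates) so chunking, and hence
    # prediction, does not depend on input point order
    g <- g[order(p[g, 1], p[g, 2], p[g, 3])]
    nparts <- ceiling(length(g) / max_points)
    parts <- split(g, rep_len(seq_len(nparts), length(g)))
    out <- c(out, unname(parts))
  }
  out
}

chunk_geometry <- function(pts, feats, cfg) {
  n <- nrow(pts)
  m1 <- min(cfg$m1, n); k1 <- min(cfg$k, n)
  c1 <- fps_cpp(pts, m1, 1L)
  g1 <- ball_query_cpp(pts, pts[c1, , drop = FALSE], cfg$r1, k1)
  m2 <- min(cfg$m2, m1); k2 <- min(cfg$k, m1)
  pts1 <- pts[c1, , drop = FALSE]
  c2 <- fps_cpp(pts1, m2, 1L)
  g2 <- ball_query_cpp(pts1, pts1[c2, , drop = FALSE], cfg$r2, k2)
  pts2 <- pts1[c2, , drop = FALSE]
  iw <- function(src, q) {
    nn <- knn_query_cpp(src, q, 3L)
    w <- 1 / (nn$dist^2 + 1e-8)
    list(idx = nn$idx, w = w / rowSums(w))
  }
  gidx1 <- as.vector(t(g1$idx))
  gidx2 <- as.vector(t(g2$idx))
  list(n = n, feats = feats,
       m1 = m1, k1 = k1, gidx1 = gidx1,
       local1 = pts[gidx1, , drop = FALSE] -
         pts1[rep(seq_len(m1), each = k1), , drop = FALSE],
       m2 = m2, k2 = k2, gidx2 = gidx2,
       local2 = pts1[gidx2, , drop = FALSE] -
         pts2[rep(seq_len(m2), each = k2), , drop = FALSE],
       fp2 = iw(pts2, pts1), fp1 = iw(pts1, pts))
}

# ---- primitive forward/backward ops ----------------------------------------

pool_max <- function(H, m, k) {
  cc <- ncol(H)
  sel <- seq(1L, m * k, by = k)
  out <- H[sel, , drop = FALSE]
  arg <- matrix(1L, m, cc)
  if (k > 1) for (s in 2:k) {
    cand <- H[sel + (s - 1L), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = out, arg = arg)
}

pool_max_back <- function(dOut, arg, m, k, cc) {
  dH <- matrix(0, m * k, cc)
  rows <- (seq_len(m) - 1L) * k
  dH[cbind(as.vector(rows + arg), rep(seq_len(cc), each = m))] <- as.vector(dOut)
  dH
}

interp_fwd <- function(Fsrc, fp) {
  fp$w[, 1] * Fsrc[fp$idx[, 1], , drop = FALSE] +
    fp$w[, 2] * Fsrc[fp$idx[, 2], , drop = FALSE] +
    fp$w[, 3] * Fsrc[fp$idx[, 3], , drop = FALSE]
}

interp_back <- function(dOut, fp, m_src) {
  dF <- matrix(0, m_src, ncol(dOut))
  for (j in 1:3) {
    r <- rowsum(dOut * fp$w[, j], fp$idx[, j])
    ii <- as.integer(rownames(r))
    dF[ii, ] <- dF[ii, , drop = FALSE] + r
  }
  dF
}

init_params <- function(cfg, d0, seed) {
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  list(
    W1a = he(3 + d0, cfg$w1), b1a = rep(0, cfg$w1),
    W1b = he(cfg$w1, cfg$w1), b1b = rep(0, cfg$w1),
    W2a = he(3 + cfg$w1, cfg$w2), b2a = rep(0, cfg$w2),
    W2b = he(cfg$w2, cfg$w2), b2b = rep(0, cfg$w2),
    Wf2 = he(cfg$w2 + cfg$w1, cfg$f2), bf2 = rep(0, cfg$f2),
    Wf1 = he(cfg$f2 + d0, cfg$f1), bf1 = rep(0, cfg$f1),
    Wh = he(cfg$f1, 2), bh = rep(0, 2)
  )
}

net_forward <- function(par, g) {
  addb <- function(X, b) X + rep(b, each = nrow(X))
  A1 <- cbind(g$local1, g$feats[g$gidx1, , drop = FALSE])
  H1a <- relu(addb(A1 %*% par$W1a, par$b1a))
  H1b <- relu(addb(H1a %*% par$W1b, par$b1b))
  p1 <- pool_max(H1b, g$m1, g$k1)
  A2 <- cbind(g$local2, p1$out[g$gidx2, , drop = FALSE])
  H2a <- relu(addb(A2 %*% par$W2a, par$b2a))
  H2b <- relu(addb(H2a %*% par$W2b, par$b2b))
  p2 <- pool_max(H2b, g$m2, g$k2)
  G2 <- interp_fwd(p2$out, g$fp2)
  C2 <- cbind(G2, p1$out)
  P2 <- relu(addb(C2 %*% par$Wf2, par$bf2))
  G1 <- interp_fwd(P2, g$fp1)
  C1 <- cbind(G1, g$feats)
  P1 <- relu(addb(C1 %*% par$Wf1, par$bf1))
  logits <- addb(P1 %*% par$Wh, par$bh)
  list(A1 = A1, H1a = H1a, H1b = H1b, p1 = p1, A2 = A2, H2a = H2a,
       H2b = H2b, p2 = p2, C2 = C2, P2 = P2, C1 = C1, P1 = P1,
       logits = logits)
}

softmax2 <- function(logits) {
  mx <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mx); e2 <- exp(logits[, 2] - mx)
  cbind(e1, e2) / (e1 + e2)
}

net_backward <- function(par, g, fw, labels, class_w) {
  prob <- softmax2(fw$logits)
  wv <- class_w[labels + 1L]
  sw <- sum(wv)
  onehot <- cbind(labels == 0L, labels == 1L)
  dlogits <- (prob - onehot) * (wv / sw)
  gr <- list()
  gr$Wh <- crossprod(fw$P1, dlogits); gr$bh <- colSums(dlogits)
  dP1 <- tcrossprod(dlogits, par$Wh) * (fw$P1 > 0)
  gr$Wf1 <- crossprod(fw$C1, dP1); gr$bf1 <- colSums(dP1)
  dC1 <- tcrossprod(dP1, par$Wf1)
  dG1 <- dC1[, seq_len(ncol(fw$P2)), drop = FALSE]
  dP2 <- interp_back(dG1, g$fp1, g$m1) * (fw$P2 > 0)
  gr$Wf2 <- crossprod(fw$C2, dP2); gr$bf2 <- colSums(dP2)
  dC2 <- tcrossprod(dP2, par$Wf2)
  c2 <- ncol(fw$p2$out)
  dG2 <- dC2[, seq_len(c2), drop = FALSE]
  dF1 <- dC2[, c2 + seq_len(ncol(fw$p1$out)), drop = FALSE]   # skip branch
  dF2 <- interp_back(dG2, g$fp2, g$m2)
  # SA level 2 backward
  dH2b <- pool_max_back(dF2, fw$p2$arg, g$m2, g$k2, ncol(dF2)) * (fw$H2b > 0)
  gr$W2b <- crossprod(fw$H2a, dH2b); gr$b2b <- colSums(dH2b)
  dH2a <- tcrossprod(dH2b, par$W2b) * (fw$H2a > 0)
  gr$W2a <- crossprod(fw$A2, dH2a); gr$b2a <- colSums(dH2a)
  dA2 <- tcrossprod(dH2a, par$W2a)
  dF1g <- dA2[, 3 + seq_len(ncol(fw$p1$out)), drop = FALSE]
  r <- rowsum(dF1g, g$gidx2)
  ii <- as.integer(rownames(r))
  dF1[ii, ] <- dF1[ii, , drop = FALSE] + r
  # SA level 1 backward
  dH1b <- pool_max_back(dF1, fw$p1$arg, g$m1, g$k1, ncol(dF1)) * (fw$H1b > 0)
  gr$W1b <- crossprod(fw$H1a, dH1b); gr$b1b <- colSums(dH1b)
  dH1a <- tcrossprod(dH1b, par$W1b) * (fw$H1a > 0)
  gr$W1a <- crossprod(fw$A1, dH1a); gr$b1a <- colSums(dH1a)
  loss <- -sum(wv * log(pmax(prob[cbind(seq_len(g$n), labels + 1L)], 1e-12))) / sw
  list(grads = gr, loss = loss)
}

adam_step <- function(par, gr, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(gr)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# ---- public API -------------------------------------------------------------

#' Train the point-set segmentation network
#'
#' Trains the miniature hierarchical network on one or more labeled
#' clouds. Clouds are chunked into spatial blocks, per-chunk grouping
#' geometry is precomputed once, and the network is optimized with Adam
#' on a class-frequency-weighted cross-entropy (ground returns usually
#' outnumber canopy returns). Reproducible for a fixed seed and thread
#' count.
#'
#' @param labeled_clouds a [point_cloud()] or list of them, all labeled.
#' @param net_cfg a [seg_net_config()].
#' @param train_cfg a [seg_train_config()].
#' @param seed integer seed for weight init and chunk shuffling.
#' @return A `seg_model` with fitted parameters and `loss_trace`, the
#'   mean weighted cross-entropy per epoch.
#' @export
train_segmenter <- function(labeled_clouds, net_cfg = seg_net_config(),
                            train_cfg = seg_train_config(), seed = 1L) {
  if (inherits(labeled_clouds, "point_cloud")) labeled_clouds <- list(labeled_clouds)
  if (length(labeled_clouds) == 0) stop("need at least one labeled cloud", call. = FALSE)
  all_labels <- unlist(lapply(labeled_clouds, `[[`, "labels"))
  if (is.null(all_labels)) stop("training clouds must carry labels", call. = FALSE)
  if (length(unique(all_labels)) < 2)
    stop("training data contain a single class; need both ground and canopy",
         call. = FALSE)
  has_col <- vapply(labeled_clouds, function(cl) !is.null(cl$colors), logical(1))
  if (!all(has_col == has_col[1]))
    stop("all training clouds must agree on presence of colors", call. = FALSE)

  chunks <- list()
  for (cl in labeled_clouds) {
    for (idx in make_chunks(cl, train_cfg$block_m, train_cfg$max_points)) {
      g <- chunk_geometry(cl$points[idx, , drop = FALSE],
                          chunk_features(cl, idx), net_cfg)
      g$labels <- cl$labels[idx]
      chunks[[length(chunks) + 1L]] <- g
    }
  }
  freq <- tabulate(all_labels + 1L, 2) / length(all_labels)
  class_w <- (1 / pmax(freq, 1e-6)); class_w <- class_w / sum(class_w) * 2

  d0 <- ncol(chunks[[1]]$feats)
  par <- init_params(net_cfg, d0, as.integer(seed))
  state <- list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0))
  trace <- numeric(train_cfg$epochs)
  t <- 0L
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample.int(length(chunks))
    losses <- numeric(length(chunks))
    for (ci in seq_along(ord)) {
      g <- chunks[[ord[ci]]]
      fw <- net_forward(par, g)
      bk <- net_backward(par, g, fw, g$labels, class_w)
      t <- t + 1L
      upd <- adam_step(par, bk$grads, state, train_cfg$lr, t)
      par <- upd$par; state <- upd$state
      losses[ci] <- bk$loss
    }
    trace[ep] <- mean(losses)
  }
  structure(list(params = par, net_cfg = net_cfg, train_cfg = train_cfg,
                 n_features = d0, class_weights = class_w,
                 seed = as.integer(seed), loss_trace = trace),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("Point-set segmentation model: %d input features, final loss %.4f after %d epochs\n",
              x$n_features, utils::tail(x$loss_trace, 1), length(x$loss_trace)))
  invisible(x)
}

#' Predict ground/canopy labels with a trained segmenter
#'
#' Chunks the cloud exactly as during training, runs the network forward
#' and assigns each point the class with the larger softmax probability;
#' an exact tie at 0.5 goes to ground (the conservative choice for
#' downstream height statistics).
#'
#' @param model a `seg_model` from [train_segmenter()].
#' @param cloud a [point_cloud()] with the same feature set (colors
#'   present/absent) as the training clouds.
#' @return Integer labels (0 = ground, 1 = canopy), one per point.
#' @export
predict_labels <- function(model, cloud) {
  stopifnot(inherits(model, "seg_model"), inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n == 0) return(integer(0))
  d0 <- if (is.null(cloud$colors)) 1L else 4L
  if (d0 != model$n_features)
    stop("cloud feature set does not match the trained model", call. = FALSE)
  labels <- integer(n)
  for (idx in make_chunks(cloud, model$train_cfg$block_m,
                          model$train_cfg$max_points)) {
    g <- chunk_geometry(cloud$points[idx, , drop = FALSE],
                        chunk_features(cloud, idx), model$net_cfg)
    fw <- net_forward(model$params, g)
    prob <- softmax2(fw$logits)
    labels[idx] <- as.integer(prob[, 2] > 0.5)   # ties -> ground
  }
  labels
}
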