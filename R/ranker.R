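#' Ranker network specification
#'
#' Early-fusion MLP over the 68 user-night features: two hidden layers (128
#' units, ReLU, batch normalization, dropout 0.2) followed by a 64-unit
#' shared layer and two heads -- a relevance head that scores candidate
#' items (the shared representation concatenated with a learned 8-dimension
#' item embedding, through one 32-unit ReLU layer; a purely linear head
#' would make the pairwise margin independent of the user features) and a
#' scalar regression head for next-day fatigue.
#'
#' @param input_dim Feature width (default 68).
#' @param hidden Hidden widths (default `c(128, 128)`).
#' @param shared Shared layer width (default 64).
#' @param emb_dim Item embedding width (default 8).
#' @param head_hidden Relevance-head hidden width (default 32).
#' @param dropout Dropout rate, training only (default 0.2).
#' @param batchnorm Use batch normalization (default TRUE).
#' @return A `sleeprec_network_spec` list.
#' @export
network_spec <- function(input_dim = 68, hidden = c(128, 128), shared = 64,
                         emb_dim = 8, head_hidden = 32, dropout = 0.2,
                         batchnorm = TRUE) {
  structure(list(input_dim = input_dim, hidden = hidden, shared = shared,
                 emb_dim = emb_dim, head_hidden = head_hidden,
                 dropout = dropout, batchnorm = batchnorm),
            class = "sleeprec_network_spec")
}

#' Ranker training configuration
#'
#' AdamW with decoupled weight decay, the combined BPR + lambda x Huber
#' objective, early stopping on the validation combined loss.
#'
#' @param lr Learning rate (default 3e-4).
#' @param weight_decay Decoupled weight decay (default 1e-2).
#' @param batch_size Pairs per batch (default 256).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param lambda Huber weight in the combined loss (default 0.1).
#' @param delta Huber transition point, rating-scale units (default 1).
#' @param seeds Seeds for repeated runs (default `c(0, 1, 2)`).
#' @return A `sleeprec_train_config` list.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 1e-2, batch_size = 256,
                         max_epochs = 100, patience = 10, lambda = 0.1,
                         delta = 1, seeds = c(0L, 1L, 2L)) {
  if (lambda < 0) abort("train_config: lambda must be >= 0")
  if (lr <= 0) abort("train_config: lr must be > 0")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, lambda = lambda, delta = delta,
                 seeds = as.integer(seeds)),
            class = "sleeprec_train_config")
}

#' Bayesian Personalized Ranking loss
#'
#' `-mean(log sigmoid(pos - neg))`: strictly decreasing in the score margin,
#' `log(2)` at zero margin, tending to 0 as the margin grows.
#'
#' @param pos_scores,neg_scores Equal-length numeric vectors of paired
#'   positive/negative item scores.
#' @return Non-negative scalar.
#' @export
bpr_loss <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || length(pos_scores) != length(neg_scores))
    abort("bpr_loss: need equal-length, non-empty score vectors")
  m <- pos_scores - neg_scores
  # -log sigmoid(m) = log(1 + exp(-m)), computed stably
  mean(log1p(exp(-abs(m))) + pmax(-m, 0))
}

#' Huber regression loss
#'
#' Mean over the batch of the residual penalty: quadratic (`r^2/2`) within
#' `± delta`, linear (`delta * (|r| - delta/2)`) beyond.
#'
#' @param pred,target Numeric vectors.
#' @param delta Transition point (> 0, default 1).
#' @return Non-negative scalar.
#' @export
huber_loss <- function(pred, target, delta = 1) {
  if (delta <= 0) abort("huber_loss: delta must be > 0")
  r <- abs(pred - target)
  mean(ifelse(r <= delta, 0.5 * r^2, delta * (r - delta / 2)))
}

#' Combined ranking + regression objective
#'
#' `L = L_BPR + lambda * L_Huber`.
#'
#' @param bpr,huber Component losses.
#' @param lambda Huber weight (>= 0).
#' @return Scalar.
#' @export
combined_loss <- function(bpr, huber, lambda = 0.1) {
  if (lambda < 0) abort("combined_loss: lambda must be >= 0")
  bpr + lambda * huber
}

# --- parameter initialization -------------------------------------------

ranker_init <- function(spec, n_items, seed = 0L) {
  withr::with_seed(seed, {
    he <- function(fan_in, fan_out)
      matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
    dims <- c(spec$input_dim, spec$hidden)
    par <- list()
    for (l in seq_along(spec$hidden)) {
      par[[paste0("W", l)]] <- he(dims[l], dims[l + 1])
      par[[paste0("b", l)]] <- rep(0, dims[l + 1])
      if (spec$batchnorm) {
        par[[paste0("gamma", l)]] <- rep(1, dims[l + 1])
        par[[paste0("beta", l)]] <- rep(0, dims[l + 1])
      }
    }
    par$W3 <- he(tail(dims, 1), spec$shared)
    par$b3 <- rep(0, spec$shared)
    par$E <- matrix(rnorm(n_items * spec$emb_dim, 0, 0.1), n_items, spec$emb_dim)
    par$Wh1 <- he(spec$shared + spec$emb_dim, spec$head_hidden)
    par$bh1 <- rep(0, spec$head_hidden)
    par$Wh2 <- he(spec$head_hidden, 1)
    par$bh2 <- 0
    par$Wf <- he(spec$shared, 1)
    par$bf <- 0
    par
  })
}

bn_forward <- function(z, gamma, beta, eps = 1e-5) {
  mu <- colMeans(z)
  v <- colMeans(sweep(z, 2, mu)^2)
  std <- sqrt(v + eps)
  xhat <- sweep(sweep(z, 2, mu), 2, std, "/")
  list(y = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, std = std, mu = mu, v = v)
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat; std <- cache$std
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  mdy <- colMeans(dy)
  mdyx <- colMeans(dy * xhat)
  dz <- sweep(sweep(sweep(dy, 2, mdy) - sweep(xhat, 2, mdyx, "*"),
                    2, gamma, "*"), 2, std, "/")
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

bn_eval <- function(z, gamma, beta, rmu, rvar, eps = 1e-5) {
  xhat <- sweep(sweep(z, 2, rmu), 2, sqrt(rvar + eps), "/")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

# forward through trunk (input -> shared H); training mode uses batch stats
# and the supplied dropout masks, eval mode running stats and no dropout
trunk_forward <- function(par, spec, x, training = FALSE, masks = NULL,
                          running = NULL) {
  a <- x
  cache <- list(a0 = x)
  for (l in seq_along(spec$hidden)) {
    z <- sweep(a %*% par[[paste0("W", l)]], 2, par[[paste0("b", l)]], "+")
    if (spec$batchnorm) {
      if (training) {
        bn <- bn_forward(z, par[[paste0("gamma", l)]], par[[paste0("beta", l)]])
        cache[[paste0("bn", l)]] <- bn
        y <- bn$y
      } else {
        y <- bn_eval(z, par[[paste0("gamma", l)]], par[[paste0("beta", l)]],
                     running[[paste0("mu", l)]], running[[paste0("var", l)]])
      }
    } else y <- z
    r <- y * (y > 0)
    if (training && spec$dropout > 0) {
      r <- r * masks[[l]] / (1 - spec$dropout)
    }
    cache[[paste0("z", l)]] <- z
    cache[[paste0("relu", l)]] <- y > 0
    cache[[paste0("a", l)]] <- r
    a <- r
  }
  z3 <- sweep(a %*% par$W3, 2, par$b3, "+")
  h <- z3 * (z3 > 0)
  cache$z3 <- z3
  cache$h <- h
  cache
}

# relevance head: score for shared rows H paired with item embedding rows E
head_forward <- function(par, h, e) {
  cc <- cbind(h, e)
  z <- sweep(cc %*% par$Wh1, 2, par$bh1, "+")
  a <- z * (z > 0)
  s <- as.numeric(a %*% par$Wh2 + par$bh2)
  list(s = s, cc = cc, relu = z > 0, a = a)
}

# backward through relevance head; returns grads + dH and dE rows
head_backward <- function(par, cache, ds) {
  da <- ds %*% t(par$Wh2)  # ds is B x 1
  dWh2 <- t(cache$a) %*% ds
  dbh2 <- sum(ds)
  dz <- da * cache$relu
  dWh1 <- t(cache$cc) %*% dz
  dbh1 <- colSums(dz)
  dcc <- dz %*% t(par$Wh1)
  list(dWh1 = dWh1, dbh1 = dbh1, dWh2 = dWh2, dbh2 = dbh2, dcc = dcc)
}

# combined loss + gradients for one batch of BPR pairs with fatigue targets.
# batch: list(x [B x d], pos, neg (item indices), fatigue [B])
ranker_loss_grad <- function(par, spec, batch, lambda = 0.1, delta = 1,
                             masks = NULL, training = TRUE, running = NULL,
                             want_grad = TRUE) {
  B <- nrow(batch$x)
  cache <- trunk_forward(par, spec, batch$x, training = training,
                         masks = masks, running = running)
  h <- cache$h
  hp <- head_forward(par, h, par$E[batch$pos, , drop = FALSE])
  hn <- head_forward(par, h, par$E[batch$neg, , drop = FALSE])
  f <- as.numeric(h %*% par$Wf + par$bf)
  m <- hp$s - hn$s
  l_bpr <- mean(log1p(exp(-abs(m))) + pmax(-m, 0))
  l_hub <- huber_loss(f, batch$fatigue, delta)
  loss <- combined_loss(l_bpr, l_hub, lambda)
  if (!want_grad)
    return(list(loss = loss, bpr = l_bpr, huber = l_hub))
  g <- lapply(par, function(p) if (is.matrix(p)) p * 0 else p * 0)
  # BPR: d/dm of -log sigmoid(m) = -sigmoid(-m)
  dm <- matrix(-1 / (1 + exp(m)) / B, ncol = 1)
  bp <- head_backward(par, hp, dm)
  bn_ <- head_backward(par, hn, -dm)
  g$Wh1 <- bp$dWh1 + bn_$dWh1; g$bh1 <- bp$dbh1 + bn_$dbh1
  g$Wh2 <- bp$dWh2 + bn_$dWh2; g$bh2 <- bp$dbh2 + bn_$dbh2
  ns <- spec$shared
  dh <- bp$dcc[, seq_len(ns), drop = FALSE] + bn_$dcc[, seq_len(ns), drop = FALSE]
  dep <- bp$dcc[, -seq_len(ns), drop = FALSE]
  den <- bn_$dcc[, -seq_len(ns), drop = FALSE]
  for (i in seq_len(B)) {
    g$E[batch$pos[i], ] <- g$E[batch$pos[i], ] + dep[i, ]
    g$E[batch$neg[i], ] <- g$E[batch$neg[i], ] + den[i, ]
  }
  # Huber head
  r <- f - batch$fatigue
  df <- matrix(lambda * clip(r, -delta, delta) / B, ncol = 1)
  g$Wf <- t(h) %*% df
  g$bf <- sum(df)
  dh <- dh + df %*% t(par$Wf)
  # shared layer
  dz3 <- dh * (cache$z3 > 0)
  a_last <- cache[[paste0("a", length(spec$hidden))]]
  g$W3 <- t(a_last) %*% dz3
  g$b3 <- colSums(dz3)
  da <- dz3 %*% t(par$W3)
  for (l in rev(seq_along(spec$hidden))) {
    if (training && spec$dropout > 0)
      da <- da * masks[[l]] / (1 - spec$dropout)
    dy <- da * cache[[paste0("relu", l)]]
    if (spec$batchnorm) {
      bb <- bn_backward(dy, cache[[paste0("bn", l)]], par[[paste0("gamma", l)]])
      g[[paste0("gamma", l)]] <- bb$dgamma
      g[[paste0("beta", l)]] <- bb$dbeta
      dz <- bb$dz
    } else dz <- dy
    a_prev <- cache[[paste0("a", l - 1)]] %||% cache$a0
    if (l == 1) a_prev <- cache$a0
    g[[paste0("W", l)]] <- t(a_prev) %*% dz
    g[[paste0("b", l)]] <- colSums(dz)
    da <- dz %*% t(par[[paste0("W", l)]])
  }
  list(loss = loss, bpr = l_bpr, huber = l_hub, grads = g, cache = cache)
}

adamw_step <- function(par, grads, state, lr, wd, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W1", "W2", "W3", "Wh1", "Wh2", "Wf", "E")
  for (nm in names(par)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (nm %in% decayed) upd <- upd + wd * par[[nm]]
    par[[nm]] <- par[[nm]] - lr * upd
  }
  list(par = par, state = state)
}

#' Build BPR training pairs from aggregated ratings
#'
#' For each user-night feature row, positives are catalog items the user
#' rated at least `pos_threshold` and negatives are sampled uniformly from
#' items rated at most `neg_threshold` or never rated. Users without a
#' positive item are skipped with a warning. The fatigue target is the
#' user-night's next-day fatigue z-score (schema column
#' `fatigue_index_lag1`-free: taken from the raw nights table by the
#' caller); here it is passed in as `fatigue`.
#'
#' @param feature_matrix Tibble from [build_feature_matrix()].
#' @param ratings Aggregated long ratings.
#' @param catalog Item catalog.
#' @param fatigue Numeric vector aligned with `feature_matrix` rows
#'   (next-day fatigue z-scores).
#' @param pairs_per_night Sampled pairs per user-night (default 2).
#' @param pos_threshold,neg_threshold Relevance cuts (default 4 / 2).
#' @param seed Sampling seed.
#' @return List: `x` (matrix), `pos`, `neg` (item indices into the
#'   catalog), `fatigue`, `user_id` per pair.
#' @export
build_pairs <- function(feature_matrix, ratings, catalog, fatigue,
                        pairs_per_night = 2, pos_threshold = 4,
                        neg_threshold = 2, seed = 0L) {
  items <- sort(catalog$item_id)
  x <- as.matrix(feature_matrix[feature_schema()])
  withr::with_seed(seed, {
    rows <- list(); k <- 0
    skipped <- character(0)
    by_user <- split(seq_len(nrow(feature_matrix)), feature_matrix$user_id)
    for (u in names(by_user)) {
      ru <- ratings[ratings$user_id == u, ]
      pos <- ru$item_id[ru$rating >= pos_threshold]
      negpool <- union(ru$item_id[ru$rating <= neg_threshold],
                       setdiff(items, ru$item_id))
      if (!length(pos) || !length(negpool)) {
        skipped <- c(skipped, u)
        next
      }
      for (i in by_user[[u]]) {
        for (j in seq_len(pairs_per_night)) {
          k <- k + 1
          rows[[k]] <- c(i, match(sample(pos, 1), items),
                         match(sample(negpool, 1), items))
        }
      }
    }
    if (length(skipped))
      warn(sprintf("build_pairs: no positive items for user(s): %s",
                   paste(skipped, collapse = ", ")))
    if (!k) abort("build_pairs: no training pairs could be formed")
    mat <- do.call(rbind, rows)
    list(x = x[mat[, 1], , drop = FALSE], pos = mat[, 2], neg = mat[, 3],
         fatigue = fatigue[mat[, 1]],
         user_id = feature_matrix$user_id[mat[, 1]],
         items = items)
  })
}

#' Train the hybrid MLP ranker
#'
#' Mini-batch AdamW on the combined BPR + Huber objective with early
#' stopping on the validation combined loss. Deterministic for a fixed
#' seed. Batch-norm running statistics are tracked for inference.
#'
#' @param train,val Pair sets from [build_pairs()].
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return A `sleeprec_ranker`: parameters, running statistics, history
#'   tibble, `best_epoch`, `items`, `spec`, `config`, `seed`.
#' @export
train_ranker <- function(train, val, spec = network_spec(),
                         config = train_config(), seed = 0L,
                         verbose = FALSE) {
  n_items <- length(train$items)
  par <- ranker_init(spec, n_items, seed)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  running <- list()
  for (l in seq_along(spec$hidden)) {
    running[[paste0("mu", l)]] <- rep(0, spec$hidden[l])
    running[[paste0("var", l)]] <- rep(1, spec$hidden[l])
  }
  momentum <- 0.9
  n <- nrow(train$x)
  best <- list(loss = Inf, par = par, running = running, epoch = 0L)
  hist <- list()
  t_step <- 0
  withr::with_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      tr_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        if (length(idx) < 2) next
        batch <- list(x = train$x[idx, , drop = FALSE],
                      pos = train$pos[idx], neg = train$neg[idx],
                      fatigue = train$fatigue[idx])
        masks <- NULL
        if (spec$dropout > 0)
          masks <- lapply(spec$hidden, function(w)
            matrix(runif(length(idx) * w) > spec$dropout, length(idx), w))
        out <- ranker_loss_grad(par, spec, batch, config$lambda, config$delta,
                                masks = masks, training = TRUE)
        if (spec$batchnorm) {
          for (l in seq_along(spec$hidden)) {
            bn <- out$cache[[paste0("bn", l)]]
            running[[paste0("mu", l)]] <- momentum * running[[paste0("mu", l)]] +
              (1 - momentum) * bn$mu
            running[[paste0("var", l)]] <- momentum * running[[paste0("var", l)]] +
              (1 - momentum) * bn$v
          }
        }
        t_step <- t_step + 1
        st <- adamw_step(par, out$grads, state, config$lr,
                         config$weight_decay, t_step)
        par <- st$par; state <- st$state
        tr_loss <- tr_loss + out$loss * length(idx)
      }
      tr_loss <- tr_loss / n
      vl <- ranker_evaluate_loss(par, spec, val, config, running)
      hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                      val_loss = vl$loss, val_bpr = vl$bpr,
                                      val_huber = vl$huber)
      if (verbose)
        message(sprintf("epoch %3d train %.4f val %.4f (bpr %.4f)",
                        epoch, tr_loss, vl$loss, vl$bpr))
      if (vl$loss < best$loss - 1e-6) {
        best <- list(loss = vl$loss, par = par, running = running,
                     epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) break
    }
  })
  structure(list(par = best$par, running = best$running,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, val_loss = best$loss,
                 items = train$items, spec = spec, config = config,
                 seed = seed),
            class = "sleeprec_ranker")
}

# validation losses in eval mode (no dropout, running statistics)
ranker_evaluate_loss <- function(par, spec, pairs, config, running) {
  out <- ranker_loss_grad(par, spec,
                          list(x = pairs$x, pos = pairs$pos, neg = pairs$neg,
                               fatigue = pairs$fatigue),
                          config$lambda, config$delta, training = FALSE,
                          running = running, want_grad = FALSE)
  out
}

#' @export
print.sleeprec_ranker <- function(x, ...) {
  cat(sprintf("<sleeprec_ranker> %d epochs (best %d), val loss %.4f, %d items\n",
              nrow(x$history), x$best_epoch, x$val_loss, length(x$items)))
  invisible(x)
}

#' Score catalog items with a trained ranker
#'
#' Inference mode (running batch-norm statistics, no dropout): returns the
#' relevance-head score of every item for every feature row. Two passes on
#' identical input give identical scores.
#'
#' @param model A `sleeprec_ranker`.
#' @param x Feature matrix (rows = user-nights or user means).
#' @param items Item ids to score (default all the model knows).
#' @return Matrix `nrow(x)` x `length(items)` of scores.
#' @export
score_items <- function(model, x, items = model$items) {
  x <- as.matrix(x)
  cache <- trunk_forward(model$par, model$spec, x, training = FALSE,
                         running = model$running)
  h <- cache$h
  idx <- match(items, model$items)
  if (anyNA(idx)) abort("score_items: unknown item id(s)")
  sapply(idx, function(i) {
    e <- matrix(model$par$E[i, ], nrow(x), model$spec$emb_dim, byrow = TRUE)
    head_forward(model$par, h, e)$s
  })
}

#' Fuse MLP and PFRA score vectors
#'
#' Min-max normalizes each score vector over the items, then returns
#' `alpha * pfra + (1 - alpha) * mlp`. A constant vector carries no ranking
#' information and is normalized to 0.5 with a warning.
#'
#' @param mlp_scores,pfra_scores Named or positional numeric vectors over
#'   the same items.
#' @param alpha Fusion weight on the PFRA side, in `[0, 1]` (default 0.5).
#' @return Numeric vector of fused scores.
#' @export
fuse_scores <- function(mlp_scores, pfra_scores, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) abort("fuse_scores: alpha must be in [0,1]")
  if (length(mlp_scores) != length(pfra_scores))
    abort("fuse_scores: score sets must cover the same items")
  mm <- function(s) {
    rng <- range(s)
    if (diff(rng) == 0) {
      warn("fuse_scores: constant score vector normalized to 0.5")
      return(rep(0.5, length(s)))
    }
    (s - rng[1]) / diff(rng)
  }
  alpha * mm(pfra_scores) + (1 - alpha) * mm(mlp_scores)
}
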