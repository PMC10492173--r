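#' Tokenize forum text for the screening models
#'
#' Lowercases, maps every run of digits (including decimals) to the single
#' number-class token `<num>`, and strips punctuation. Slashes split tokens,
#' so `"LH/FSH 2.2"` tokenizes as `lh`, `fsh`, `<num>`.
#'
#' @param text Character scalar (or vector; vectors are tokenized per element
#'   and returned as a list).
#' @return Character vector of tokens, or a list of such vectors.
#' @export
preprocess <- function(text) {
  if (length(text) > 1) return(lapply(text, preprocess))
  x <- tolower(as.character(text))
  if (!length(x) || is.na(x) || !nzchar(x)) return(character(0))
  x <- gsub("[0-9]+(\\.[0-9]+)?", " <num> ", x)
  x <- gsub("[^a-z<>]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Fit co-occurrence word embeddings
#'
#' A weighted least-squares fit to the log word-word co-occurrence matrix
#' (symmetric context window, counts weighted by 1/distance, loss weight
#' `min(1, (x/x_max)^alpha)`), optimized full-batch with Adam. The returned
#' embedding for a token is the sum of its word and context vectors.
#'
#' @param corpus List of token sequences from [preprocess()].
#' @param d Embedding dimension (>= 2).
#' @param window Symmetric context window width.
#' @param iters Number of full-batch Adam iterations.
#' @param seed Integer seed (initialization).
#' @param x_max,alpha Co-occurrence weighting parameters.
#' @param lr Adam step size.
#' @return An `embedding_table`: list with `vocab` (token -> row index) and
#'   `vectors` (matrix, one row per token).
#' @export
train_embeddings <- function(corpus, d = 50, window = 5, iters = 80,
                             seed = 1L, x_max = 100, alpha = 0.75, lr = 0.05) {
  stopifnot(d >= 2, length(corpus) >= 1)
  vocab <- unique(unlist(corpus))
  if (length(vocab) < 2) stop("vocabulary must contain at least 2 tokens",
                              call. = FALSE)
  V <- length(vocab)
  idx <- stats::setNames(seq_len(V), vocab)
  # accumulate co-occurrence triplets
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (doc in corpus) {
    n <- length(doc)
    if (n < 2) next
    w <- idx[doc]
    for (off in seq_len(min(window, n - 1))) {
      a <- w[seq_len(n - off)]
      b <- w[seq_len(n - off) + off]
      ii <- c(ii, a, b); jj <- c(jj, b, a)
      xx <- c(xx, rep(1 / off, 2 * (n - off)))
    }
  }
  if (!length(ii)) stop("no co-occurring token pairs in corpus", call. = FALSE)
  key <- (ii - 1) * V + jj
  agg <- rowsum(xx, key)
  key_u <- as.numeric(rownames(agg))
  x <- as.numeric(agg)
  i <- ((key_u - 1) %/% V) + 1
  j <- ((key_u - 1) %% V) + 1
  fx <- pmin(1, (x / x_max)^alpha)
  lx <- log(x)

  set.seed(seed)
  W <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
  C <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
  bw <- numeric(V); bc <- numeric(V)
  adam <- make_adam(list(W = W, C = C, bw = bw, bc = bc), lr = lr)
  for (it in seq_len(iters)) {
    P <- adam$params
    pred <- rowSums(P$W[i, , drop = FALSE] * P$C[j, , drop = FALSE]) +
      P$bw[i] + P$bc[j]
    err <- fx * (pred - lx)
    gW <- rowsum_mat(err * P$C[j, , drop = FALSE], i, V)
    gC <- rowsum_mat(err * P$W[i, , drop = FALSE], j, V)
    gbw <- rowsum_vec(err, i, V)
    gbc <- rowsum_vec(err, j, V)
    adam <- adam_step(adam, list(W = gW, C = gC, bw = gbw, bc = gbc))
  }
  P <- adam$params
  structure(list(vocab = idx, vectors = P$W + P$C, d = d),
            class = "embedding_table")
}

# scatter-add of matrix rows / vector entries into V bins
rowsum_mat <- function(m, bins, V) {
  out <- matrix(0, V, ncol(m))
  r <- rowsum(m, bins)
  out[as.integer(rownames(r)), ] <- r
  out
}
rowsum_vec <- function(v, bins, V) {
  out <- numeric(V)
  r <- rowsum(v, bins)
  out[as.integer(rownames(r))] <- r
  out
}

make_adam <- function(params, lr = 1e-3, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  zero <- lapply(params, function(p) p * 0)
  list(params = params, m = zero, v = zero, t = 0,
       lr = lr, b1 = b1, b2 = b2, eps = eps)
}

adam_step <- function(st, grads) {
  st$t <- st$t + 1
  for (nm in names(st$params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$b1 * st$m[[nm]] + (1 - st$b1) * g
    st$v[[nm]] <- st$b2 * st$v[[nm]] + (1 - st$b2) * g^2
    mh <- st$m[[nm]] / (1 - st$b1^st$t)
    vh <- st$v[[nm]] / (1 - st$b2^st$t)
    st$params[[nm]] <- st$params[[nm]] - st$lr * mh / (sqrt(vh) + st$eps)
  }
  st
}

embed_tokens <- function(emb, tokens, min_len) {
  known <- emb$vocab[tokens]
  known <- known[!is.na(known)]
  X <- if (length(known)) emb$vectors[known, , drop = FALSE] else
    matrix(0, 0, emb$d)
  if (nrow(X) < min_len) X <- rbind(X, matrix(0, min_len - nrow(X), emb$d))
  X
}

cnn_forward <- function(model, X) {
  feats <- numeric(0)
  cache <- list()
  for (k in seq_along(model$widths)) {
    w <- model$widths[k]
    L <- nrow(X) - w + 1
    Xw <- do.call(cbind, lapply(seq_len(w), function(o) X[o:(o + L - 1), , drop = FALSE]))
    S <- Xw %*% model$W[[k]] + matrix(model$b[[k]], L, length(model$b[[k]]), byrow = TRUE)
    R <- pmax(S, 0)
    tstar <- max.col(t(R), ties.method = "first")
    f <- R[cbind(tstar, seq_along(tstar))]
    cache[[k]] <- list(Xw = Xw, S = S, tstar = tstar)
    feats <- c(feats, f)
  }
  z <- sum(feats * model$v) + model$c
  list(p = 1 / (1 + exp(-z)), feats = feats, cache = cache)
}

cnn_backward <- function(model, fw, y) {
  dz <- fw$p - y
  grads <- list(v = dz * fw$feats, c = dz, W = list(), b = list())
  df <- dz * model$v
  off <- 0
  for (k in seq_along(model$widths)) {
    nf <- ncol(model$W[[k]])
    gk <- df[off + seq_len(nf)]
    cc <- fw$cache[[k]]
    act <- cc$S[cbind(cc$tstar, seq_len(nf))] > 0
    gk <- gk * act
    rows <- cc$Xw[cc$tstar, , drop = FALSE]
    # dW[, k] = g_k * Xw[tstar_k, ]; `rows * gk` scales row k by g_k
    grads$W[[k]] <- t(rows * gk)
    grads$b[[k]] <- gk
    off <- off + nf
  }
  grads
}

#' Train the convolutional post screen
#'
#' A small text classifier in the mold used for short-document screening:
#' frozen embedding lookup, parallel one-dimensional convolutions of widths
#' 2-5 with ReLU, global max pooling, and a dense sigmoid output trained
#' with binary cross-entropy and Adam. A held-out fraction is reserved for
#' evaluation and early stopping.
#'
#' @param labeled Data frame with columns `text` (or a list column `tokens`)
#'   and `label` (logical or 0/1).
#' @param embeddings An `embedding_table`.
#' @param hyper List of hyperparameters: `widths`, `n_filters`, `epochs`,
#'   `lr`, `holdout`, `patience`, `threshold`.
#' @param seed Integer seed.
#' @return A fitted `screen_cnn` model.
#' @export
train_screen <- function(labeled, embeddings,
                         hyper = list(), seed = 1L) {
  h <- utils::modifyList(list(widths = c(2L, 3L, 4L, 5L), n_filters = 32L,
                              epochs = 40L, lr = 2e-3, holdout = 0.25,
                              patience = 6L, threshold = 0.5), hyper)
  y <- as.integer(labeled$label)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  toks <- if (!is.null(labeled$tokens)) labeled$tokens else
    lapply(labeled$text, preprocess)
  set.seed(seed)
  n <- length(y)
  # stratified held-out split
  ho <- unlist(lapply(split(seq_len(n), y), function(ix) {
    k <- max(1, round(length(ix) * h$holdout))
    sample(ix, k)
  }))
  tr <- setdiff(seq_len(n), ho)
  d <- embeddings$d
  maxw <- max(h$widths)
  Xs <- lapply(toks, function(t) embed_tokens(embeddings, t, maxw))

  model <- list(widths = h$widths,
                W = lapply(h$widths, function(w)
                  matrix(stats::rnorm(w * d * h$n_filters, sd = sqrt(2 / (w * d))),
                         w * d, h$n_filters)),
                b = lapply(h$widths, function(w) numeric(h$n_filters)),
                v = stats::rnorm(length(h$widths) * h$n_filters, sd = 0.05),
                c = 0, threshold = h$threshold)
  nw <- length(h$widths)
  flat <- function(m) {
    p <- c(list(v = m$v, c = m$c),
           stats::setNames(m$W, paste0("W", seq_len(nw))),
           stats::setNames(m$b, paste0("b", seq_len(nw))))
    p
  }
  unflat <- function(p, m) {
    m$v <- p$v; m$c <- p$c
    m$W <- unname(p[paste0("W", seq_len(nw))])
    m$b <- unname(p[paste0("b", seq_len(nw))])
    m
  }
  adam <- make_adam(flat(model), lr = h$lr)
  best <- list(loss = Inf, params = adam$params, stall = 0)
  batch <- 16L
  for (ep in seq_len(h$epochs)) {
    ord <- sample(tr)
    for (start in seq(1, length(ord), by = batch)) {
      ix <- ord[start:min(start + batch - 1, length(ord))]
      model <- unflat(adam$params, model)
      acc <- NULL
      for (s in ix) {
        fw <- cnn_forward(model, Xs[[s]])
        g <- cnn_backward(model, fw, y[s])
        gf <- c(list(v = g$v, c = g$c),
                stats::setNames(g$W, paste0("W", seq_len(nw))),
                stats::setNames(g$b, paste0("b", seq_len(nw))))
        acc <- if (is.null(acc)) gf else mapply(`+`, acc, gf, SIMPLIFY = FALSE)
      }
      acc <- lapply(acc, function(g) g / length(ix))
      adam <- adam_step(adam, acc)
    }
    model <- unflat(adam$params, model)
    ho_loss <- mean(vapply(ho, function(s) {
      p <- cnn_forward(model, Xs[[s]])$p
      p <- min(max(p, 1e-12), 1 - 1e-12)
      -(y[s] * log(p) + (1 - y[s]) * log(1 - p))
    }, numeric(1)))
    if (ho_loss < best$loss - 1e-5) {
      best <- list(loss = ho_loss, params = adam$params, stall = 0)
    } else {
      best$stall <- best$stall + 1
      if (best$stall >= h$patience) break
    }
  }
  model <- unflat(best$params, model)
  model$embeddings <- embeddings
  model$holdout <- data.frame(label = y[ho])
  model$holdout_tokens <- toks[ho]
  structure(model, class = "screen_cnn")
}

#' Keyword-rule baseline screen
#'
#' Flags a post when any catalog synonym occurs and the post contains a
#' number token. Transparent, training-free stand-in for the convolutional
#' screen; downstream stages accept either.
#'
#' @param catalog A `lab_catalog`.
#' @param threshold Decision threshold (kept for interface parity).
#' @return A `screen_rule` model.
#' @export
rule_screen <- function(catalog = lab_catalog(), threshold = 0.5) {
  syn_tokens <- unique(unlist(lapply(catalog, function(t)
    unlist(lapply(t$synonyms, preprocess)))))
  syn_tokens <- setdiff(syn_tokens, "<num>")
  structure(list(tokens = syn_tokens, threshold = threshold),
            class = "screen_rule")
}

screen_prob <- function(model, tokens) UseMethod("screen_prob")

#' @export
screen_prob.screen_cnn <- function(model, tokens) {
  X <- embed_tokens(model$embeddings, tokens, max(model$widths))
  cnn_forward(model, X)$p
}

#' @export
screen_prob.screen_rule <- function(model, tokens) {
  hit <- any(tokens %in% model$tokens) && "<num>" %in% tokens
  if (hit) 0.99 else 0.01
}

#' Score posts with a screening model
#'
#' @param model A `screen_cnn` or `screen_rule`.
#' @param posts Post data frame (`id`, `title`, `selftext`).
#' @return Data frame `id`, `probability`, `flag` in input order; `flag` is
#'   `probability >= threshold`.
#' @export
screen <- function(model, posts) {
  if (!nrow(posts)) {
    return(data.frame(id = character(0), probability = numeric(0),
                      flag = logical(0), stringsAsFactors = FALSE))
  }
  probs <- vapply(seq_len(nrow(posts)), function(i) {
    toks <- preprocess(paste(posts$title[i], posts$selftext[i]))
    screen_prob(model, toks)
  }, numeric(1))
  data.frame(id = posts$id, probability = probs,
             flag = probs >= model$threshold, stringsAsFactors = FALSE)
}

#' Evaluate a screening model on labeled posts
#'
#' @param model A fitted screen model.
#' @param labeled Data frame with `text` (or `tokens`) and `label`. When
#'   omitted for a `screen_cnn`, the model's own held-out split is used.
#' @return List with `accuracy` and the confusion counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
evaluate_screen <- function(model, labeled = NULL) {
  if (is.null(labeled)) {
    if (!inherits(model, "screen_cnn")) {
      stop("a labeled evaluation set is required", call. = FALSE)
    }
    toks <- model$holdout_tokens
    y <- model$holdout$label
  } else {
    toks <- if (!is.null(labeled$tokens)) labeled$tokens else
      lapply(labeled$text, preprocess)
    y <- as.integer(labeled$label)
  }
  if (!length(y)) stop("evaluation set is empty", call. = FALSE)
  p <- vapply(toks, function(t) screen_prob(model, t), numeric(1))
  flag <- p >= model$threshold
  tp <- sum(flag & y == 1); fp <- sum(flag & y == 0)
  tn <- sum(!flag & y == 0); fn <- sum(!flag & y == 1)
  list(accuracy = (tp + tn) / length(y), tp = tp, fp = fp, tn = tn, fn = fn)
}
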