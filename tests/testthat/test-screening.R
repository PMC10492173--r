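test_that("tokenizer lowercases, classes numbers, and splits on slashes", {
  expect_identical(preprocess("My FSH was 5.5!"), c("my", "fsh", "was", "<num>"))
  expect_identical(preprocess(""), character(0))
  expect_identical(preprocess("LH/FSH 2.2"), c("lh", "fsh", "<num>"))
  # digits inside words are also number-classed, by the documented rule
  expect_identical(preprocess("a1c 5.7%"), c("a", "<num>", "c", "<num>"))
})

test_that("embeddings reflect co-occurrence structure", {
  corpus <- c(replicate(40, c("alpha", "beta"), simplify = FALSE),
              replicate(40, c("gamma", "delta"), simplify = FALSE))
  emb <- train_embeddings(corpus, d = 8, iters = 120, seed = 5)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  va <- emb$vectors[emb$vocab[["alpha"]], ]
  vb <- emb$vectors[emb$vocab[["beta"]], ]
  vc <- emb$vectors[emb$vocab[["gamma"]], ]
  expect_gt(cosine(va, vb), cosine(va, vc))

  # degenerate single-document corpus still yields finite vectors
  one <- train_embeddings(list(c("x", "y", "x")), d = 2, iters = 20, seed = 1)
  expect_true(all(is.finite(one$vectors)))

  # determinism
  e1 <- train_embeddings(corpus, d = 8, iters = 30, seed = 9)
  e2 <- train_embeddings(corpus, d = 8, iters = 30, seed = 9)
  expect_identical(e1$vectors, e2$vectors)

  expect_error(train_embeddings(list(c("solo", "solo")), d = 4),
               "vocabulary")
})

test_that("the convolutional screen separates result posts from noise", {
  corp <- mini_corpus(n_posts = 200, seed = 101)
  toks <- lapply(paste(corp$posts$title, corp$posts$selftext), preprocess)
  emb <- train_embeddings(toks, d = 16, iters = 40, seed = 2)
  y <- as.integer(corpus_labels(corp))
  labeled <- data.frame(label = y)
  labeled$tokens <- toks

  model <- train_screen(labeled, emb, hyper = list(n_filters = 8L), seed = 4)
  ev <- evaluate_screen(model)
  expect_gte(ev$accuracy, 0.95)
  # accuracy identity recomputed from the confusion counts
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / (ev$tp + ev$tn + ev$fp + ev$fn))
  # comfortably above the majority-class baseline
  base <- max(mean(model$holdout$label), 1 - mean(model$holdout$label))
  expect_gte(ev$accuracy, base + 0.2)

  # label symmetry: flipping all labels flips the mapping, not the skill
  flipped <- labeled
  flipped$label <- 1L - flipped$label
  mf <- train_screen(flipped, emb, hyper = list(n_filters = 8L), seed = 4)
  expect_gte(evaluate_screen(mf)$accuracy, 0.95)

  # determinism of training and prediction
  m2 <- train_screen(labeled, emb, hyper = list(n_filters = 8L), seed = 4)
  expect_identical(screen(model, corp$posts), screen(m2, corp$posts))

  # training points are memorized
  scr <- screen(model, corp$posts)
  truthy <- corpus_labels(corp)
  expect_true(all(scr$flag[truthy]))

  expect_error(train_screen(data.frame(label = rep(1L, 5),
                                       text = rep("fsh 5", 5)), emb),
               "both classes")
})

test_that("screening output is ordered, probabilistic, and threshold-monotone", {
  corp <- mini_corpus(n_posts = 80, seed = 55)
  model <- rule_screen()
  expect_identical(nrow(screen(model, corp$posts[0, ])), 0L)
  scr <- screen(model, corp$posts)
  expect_identical(scr$id, corp$posts$id)
  expect_true(all(scr$probability >= 0 & scr$probability <= 1))
  strict <- model
  strict$threshold <- 0.999
  scr2 <- screen(strict, corp$posts)
  expect_true(all(scr$flag | !scr2$flag))  # raising threshold never adds flags
})

test_that("the keyword-rule baseline screens the default corpus accurately", {
  corp <- mini_corpus(n_posts = 150, seed = 77)
  labels <- corpus_labels(corp)
  ev <- evaluate_screen(rule_screen(), data.frame(
    text = paste(corp$posts$title, corp$posts$selftext),
    label = as.integer(labels), stringsAsFactors = FALSE))
  expect_gte(ev$accuracy, 0.95)
  expect_error(evaluate_screen(rule_screen(), data.frame(text = character(0),
                                                         label = integer(0))),
               "empty")
})
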