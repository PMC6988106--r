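# Potential-learning networks: similarity primitives, gradients, balanced
# sampling and optimization behaviour.

test_that("label similarity follows the product rule", {
  expect_equal(label_similarity(1, 1), 1)
  expect_equal(label_similarity(1, 0), 0)
  expect_equal(label_similarity(0, 1), 0)
  expect_equal(label_similarity(0, 0), 1)
  expect_equal(label_similarity(0.5, 0.5), 0.5)
  expect_equal(label_similarity(0.3, 0.8), 0.3 * 0.8 + 0.7 * 0.2)
  expect_error(label_similarity(1.2, 0), "\\[0, 1\\]")
})

test_that("feature similarity obeys its algebraic identities", {
  withr::with_seed(8, {
    f <- round(stats::runif(16))
    expect_equal(similarity_features(f, f), rep(1, 16))       # agreement
    expect_equal(similarity_features(f, 1 - f), rep(0, 16))   # disagreement
    expect_equal(similarity_features(rep(0.5, 4), rep(0.5, 4)), rep(0.5, 4))
    a <- stats::runif(16); b <- stats::runif(16)
    expect_equal(similarity_features(a, b), similarity_features(b, a))
    # complement invariance
    expect_equal(similarity_features(1 - a, 1 - b), similarity_features(a, b))
    expect_true(all(similarity_features(a, b) >= 0 &
                    similarity_features(a, b) <= 1))
  })
  expect_error(similarity_features(c(0.1, 0.2), 0.5), "dimensions")
})

test_that("analytic gradients match numerical differentiation", {
  mcfg <- msp_config(dims = c(3, 3, 5), n_scales = 2, base_spacing_mm = 1,
                     shift_R_mm = 0)
  arch <- net_config(channels = c(2, 3), d_feat = 4, hidden = 3)
  nvox <- prod(mcfg$dims)
  B <- 4
  eps <- 1e-5
  withr::with_seed(42, {
    th <- init_t_net(mcfg, arch, seed = 99)
    X <- lapply(1:2, function(s) matrix(stats::rnorm(B * nvox), B, nvox))
    y <- c(0, 1, 1, 0)
    loss_t <- function(p) {
      th2 <- th; th2$params <- p
      mean((atrialscar:::t_net_forward(X, th2)$pred - y)^2)
    }
    fw <- atrialscar:::t_net_forward(X, th)
    gr <- unlist(atrialscar:::t_net_backward(2 * (fw$pred - y) / B,
                                             fw$cache, th))
    flat <- unlist(th$params)
    idx <- sample(length(flat), 40)
    num <- vapply(idx, function(i) {
      p1 <- flat; p1[i] <- p1[i] + eps
      p2 <- flat; p2[i] <- p2[i] - eps
      (loss_t(utils::relist(p1, th$params)) -
         loss_t(utils::relist(p2, th$params))) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gr[idx])), 1e-7)

    thn <- init_n_net(mcfg, arch, seed = 7)
    Xi <- lapply(1:2, function(s) matrix(stats::rnorm(B * nvox), B, nvox))
    Xj <- lapply(1:2, function(s) matrix(stats::rnorm(B * nvox), B, nvox))
    dn <- stats::runif(B)
    yn <- c(1, 0, 1, 1)
    loss_n <- function(p) {
      t2 <- thn; t2$params <- p
      mean((atrialscar:::n_net_forward(Xi, Xj, dn, t2)$pred - yn)^2)
    }
    fwn <- atrialscar:::n_net_forward(Xi, Xj, dn, thn)
    grn <- unlist(atrialscar:::n_net_backward(2 * (fwn$pred - yn) / B,
                                              fwn$cache, thn))
    flatn <- unlist(thn$params)
    idx <- sample(length(flatn), 40)
    numn <- vapply(idx, function(i) {
      p1 <- flatn; p1[i] <- p1[i] + eps
      p2 <- flatn; p2[i] <- p2[i] - eps
      (loss_n(utils::relist(p1, thn$params)) -
         loss_n(utils::relist(p2, thn$params))) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(numn - grn[idx])), 1e-7)
    expect_gt(max(abs(grn)), 0)
  })
})

test_that("a zeroed output layer predicts exactly 0.5 and is deterministic", {
  mcfg <- tiny_msp_config()
  th <- init_t_net(mcfg, tiny_arch(), seed = 1)
  th$params$head$W2[] <- 0
  th$params$head$b2 <- 0
  th$trained <- TRUE
  withr::with_seed(2, {
    X <- list(matrix(stats::rnorm(3 * prod(mcfg$dims)), 3))
  })
  expect_equal(t_net_predict(X, th), rep(0.5, 3))
  expect_identical(t_net_predict(X, th), t_net_predict(X, th))
  expect_error(t_net_predict(list(matrix(0, 1, 10)), th), "dimensions")
})

test_that("pairwise predictions are symmetric and bounded", {
  mcfg <- tiny_msp_config()
  thn <- init_n_net(mcfg, tiny_arch(), seed = 3)
  thn$trained <- TRUE
  nvox <- prod(mcfg$dims)
  withr::with_seed(4, {
    Xi <- list(matrix(stats::rnorm(100 * nvox), 100))
    Xj <- list(matrix(stats::rnorm(100 * nvox), 100))
    dd <- stats::runif(100, 0, 5)
  })
  a <- n_net_predict(Xi, Xj, dd, thn)
  b <- n_net_predict(Xj, Xi, dd, thn)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(n_net_predict(Xi, Xj, -dd, thn), ">= 0")
  # identical patches give identical features regardless of parameters
  s1 <- n_net_predict(Xi, Xi, dd, thn)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("balanced sampling matches the equal-count rule", {
  sp <- sphere_mask(8)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  n <- nrow(mesh$vertices)
  labels <- integer(n)
  labels[1:40] <- 1L
  ts <- make_training_set(mesh, labels, seed = 5)
  n_pos <- length(ts$scar) + length(ts$boundary)
  expect_equal(length(ts$scar), 40L)
  expect_equal(length(ts$background), n_pos)
  expect_equal(length(ts$nodes), 2 * n_pos)
  expect_setequal(ts$labels, c(0L, 1L))
  # boundary nodes are background nodes adjacent to scar
  ed <- mesh$edges
  adj_scar <- unique(c(ed[labels[ed[, 1]] == 1L, 2],
                       ed[labels[ed[, 2]] == 1L, 1]))
  expect_setequal(ts$boundary, setdiff(adj_scar, which(labels == 1L)))
  # reproducibility and degenerate cases
  expect_identical(ts$nodes, make_training_set(mesh, labels, seed = 5)$nodes)
  expect_error(make_training_set(mesh, integer(n)), "no scar")
  expect_error(make_training_set(mesh, rep(1L, n)), "no background")
})

test_that("zero learning rate leaves parameters untouched", {
  mcfg <- tiny_msp_config()
  d <- separable_patches(40, mcfg, seed = 6)
  th <- init_t_net(mcfg, tiny_arch(), seed = 8)
  before <- th$params
  th2 <- train_t_net(d, th, train_config(epochs = 2, lr = 0,
                                         weight_decay = 0, seed = 1))
  expect_equal(th2$params, before, tolerance = 0)
  expect_true(th2$trained)
})

test_that("a single sample is memorized", {
  mcfg <- tiny_msp_config()
  d <- separable_patches(1, mcfg, seed = 7)
  d$y <- 1
  th <- init_t_net(mcfg, tiny_arch(), seed = 9)
  th <- train_t_net(d, th, train_config(epochs = 200, batch_size = 1,
                                        lr = 0.05, weight_decay = 0,
                                        lr_step = 10000L, seed = 2))
  expect_lt(utils::tail(th$loss, 1), 1e-3)
})

test_that("training separates bright from dark patches", {
  mcfg <- tiny_msp_config()
  train <- separable_patches(2000, mcfg, sep = 5, seed = 10)
  th <- init_t_net(mcfg, tiny_arch(), seed = 11)
  th <- train_t_net(train, th, train_config(epochs = 3, seed = 3))
  test <- separable_patches(400, mcfg, sep = 5, seed = 12)
  pred <- t_net_predict(test$X, th)
  expect_gte(mean((pred > 0.5) == (test$y == 1)), 0.95)
  # epoch-averaged loss decreases in >= 90% of epochs
  expect_gte(mean(diff(th$loss) < 0), 0.9)
})

test_that("pairwise training reaches high same-class discrimination", {
  mcfg <- tiny_msp_config()
  nvox <- prod(mcfg$dims)
  make_pairs <- function(n, seed) {
    withr::with_seed(seed, {
      ci <- rbinom(n, 1, 0.5)
      cj <- rbinom(n, 1, 0.5)
      list(Xi = list(matrix(stats::rnorm(n * nvox, 5 * ci), n)),
           Xj = list(matrix(stats::rnorm(n * nvox, 5 * cj), n)),
           d = stats::runif(n, 0.5, 2),
           y = as.numeric(ci == cj))
    })
  }
  thn <- init_n_net(mcfg, tiny_arch(), seed = 13)
  thn <- train_n_net(make_pairs(1500, 14), thn,
                     train_config(epochs = 8, lr = 0.02, seed = 4))
  te <- make_pairs(400, 15)
  pred <- n_net_predict(te$Xi, te$Xj, te$d, thn)
  # threshold-free check: AUC >= 0.9
  pos <- pred[te$y == 1]; neg <- pred[te$y == 0]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gte(auc, 0.9)
})
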