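# squash, lengths, margin loss ---------------------------------------------

test_that("squash maps norms into [0, 1) monotonically", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  expect_equal(sqrt(sum(squash(v)^2)), 0.5)
  expect_equal(sqrt(sum(squash(10 * v)^2)), 100 / 101)
  set.seed(1)
  norms <- sort(runif(50, 0, 20))
  out <- vapply(norms, function(n) sqrt(sum(squash(n * v)^2)), numeric(1))
  expect_true(all(out >= 0 & out < 1))
  expect_true(all(diff(out) > 0))     # norm-monotone
  # direction preserved
  s <- rnorm(4)
  expect_equal(squash(s) / sqrt(sum(squash(s)^2)), s / sqrt(sum(s^2)))
})

test_that("class lengths are Euclidean norms with argmax prediction", {
  expect_equal(class_lengths(matrix(0, 16, 3)), c(0, 0, 0))
  m <- matrix(0, 16, 3); m[1:2, 2] <- c(0.6, 0.8)
  expect_equal(class_lengths(m), c(0, 1, 0))
  set.seed(2)
  r <- matrix(rnorm(48), 16, 3)
  loop <- sapply(1:3, function(j) {
    acc <- 0
    for (d in 1:16) acc <- acc + r[d, j]^2
    sqrt(acc)
  })
  expect_equal(class_lengths(r), loop, tolerance = 1e-12)
})

test_that("margin loss matches closed-form hinge arithmetic", {
  expect_equal(margin_loss(c(0.9, 0.1, 0.1), 1), 0)
  expect_equal(margin_loss(c(0, 0, 0), 1), 0.81)
  expect_equal(margin_loss(c(0, 1, 1), 1), 0.81 + 2 * 0.5 * 0.9^2)
  # zero iff true length >= m+ and all others <= m-
  expect_gt(margin_loss(c(0.89, 0.1, 0.1), 1), 0)
  expect_gt(margin_loss(c(0.9, 0.11, 0.1), 1), 0)
  # batch averaging
  L <- rbind(c(0, 0, 0), c(0.9, 0.1, 0.1))
  expect_equal(margin_loss(L, c(1, 1)), 0.405)
  expect_error(margin_loss(c(0.5, 0.5, 0.5), 4), "out of range")
  expect_error(margin_loss(c(1.5, 0, 0), 1), "lengths")
})

# attention ------------------------------------------------------------------

test_that("se_weight matches a hand-computed pool-affine-sigmoid chain", {
  # 2-channel toy with hand-set weights
  x <- array(0, c(2, 2, 2))
  x[1, , ] <- matrix(c(1, 2, 3, 4), 2)    # pooled mean 2.5
  x[2, , ] <- matrix(c(0, 0, 2, 2), 2)    # pooled mean 1
  W1 <- matrix(c(1, -1), 1, 2)            # bottleneck to 1 unit
  b1 <- 0.5
  W2 <- matrix(c(2, -1), 2, 1)
  b2 <- c(0, 0.25)
  h <- max(0, 1 * 2.5 + (-1) * 1 + 0.5)   # = 2
  expected <- 1 / (1 + exp(-c(2 * h + 0, -1 * h + 0.25)))
  expect_equal(se_weight(x, W1, b1, W2, b2), expected)
  # permutation invariance of the spatial pool
  set.seed(3)
  y <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  ys <- y
  perm <- sample(16)
  for (ch in 1:2) ys[ch, , ] <- matrix(as.vector(y[ch, , ])[perm], 4)
  expect_equal(se_weight(y, W1, b1, W2, b2), se_weight(ys, W1, b1, W2, b2))
  # strictly inside (0, 1)
  z <- se_weight(y, W1, b1, W2, b2)
  expect_true(all(z > 0 & z < 1))
})

test_that("selective fusion is a per-channel two-way softmax", {
  set.seed(4)
  U <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  # identical descriptors: both weights exactly one half
  f <- selective_fuse(U, 2 * U, c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$att_spe, rep(0.5, 3))
  expect_equal(f$V[1:3, , ], 0.5 * U)
  expect_equal(f$V[4:6, , ], 0.5 * 2 * U)
  # closed-form softmax: a gap of ln 3 gives weight 3/4
  f2 <- selective_fuse(U, U, c(log(3), 0, -log(3)), c(0, 0, 0))
  expect_equal(f2$att_spe, c(0.75, 0.5, 0.25))
  expect_equal(f2$att_spe + f2$att_spa, rep(1, 3), tolerance = 1e-12)
  expect_error(selective_fuse(U, U[1:2, , , drop = FALSE], 1:3, 1:2),
               "identical shape")
})

# routing --------------------------------------------------------------------

test_that("dynamic routing agrees with a straight-loop oracle", {
  set.seed(5)
  for (case in 1:5) {
    nc <- sample(2:8, 1); K <- sample(2:3, 1); dd <- sample(c(4, 8, 16), 1)
    uh <- array(rnorm(nc * K * dd, sd = 0.8), c(nc, K, dd))
    got <- dynamic_routing(uh, iters = 3)
    ref <- oracle_routing(uh, iters = 3)
    expect_equal(got$v, ref$v, tolerance = 1e-6)
    expect_equal(got$coupling, ref$coupling, tolerance = 1e-6)
    # every coupling row (per input capsule) sums to 1 at every iteration
    for (cm in got$coupling_iters)
      expect_equal(colSums(cm), rep(1, nc), tolerance = 1e-6)
  }
})

test_that("routing limit cases follow the update equations", {
  # a single input capsule, one iteration: uniform coupling over the K
  # output capsules gives v_j = squash(u_hat_j / K)
  uh <- array(rnorm(1 * 2 * 4), c(1, 2, 4))
  got <- dynamic_routing(uh, iters = 1)
  for (j in 1:2) expect_equal(got$v[, j], squash(uh[1, j, ] / 2),
                              tolerance = 1e-6)
  expect_error(dynamic_routing(array(NA_real_, c(2, 2, 4))), "non-finite")
  expect_error(dynamic_routing(array(0, c(2, 2, 4)), iters = 0),
               "at least one")
})

# network structure -----------------------------------------------------------

test_that("the spectral branch reproduces the published depth trace", {
  m <- dbsa_model("DBSACaps", seed = 1)
  tr <- branch_trace(m)
  expect_equal(tr$spectral_depths, c(150, 72, 33, 1))
  expect_equal(tr$spatial_collapse_depth, 1)
  # incompatible band counts are rejected naming the offending layer
  expect_error(dbsa_model("SpectralCaps", bands = 100), "3DConv_3")
  expect_error(dbsa_model("SpatialCaps", bands = 149), "150 bands")
})

test_that("parameter counts decompose by module as designed", {
  m <- dbsa_model("DBSACaps", seed = 1)
  expect_identical(count_parameters(m), 7135312)
  tab <- parameter_table(m)
  mod <- sub("\\..*$", "", tab$name)
  by_mod <- tapply(tab$n, mod, sum)
  expect_equal(unname(by_mod["spectral"] + by_mod["spatial"]), 420160)
  expect_equal(unname(by_mod["se"]), 4368)
  expect_equal(unname(by_mod["caps"]), 4720128 + 1990656)
  # dropping attention removes exactly the two SE blocks
  expect_equal(count_parameters(dbsa_model("DBCaps", seed = 1)),
               7135312 - 4368)
  expect_error(dbsa_model("DBXCaps"), "DBSACaps")
})

test_that("primary capsules form a squashed 64x81 grid", {
  m <- dbsa_model("DBSACaps", input_size = 64, seed = 2)
  info <- dbsacaps:::net_info(m$ptr)
  expect_equal(info$grid, 9)            # floor((64-6)/7)+1
  expect_equal(info$ncaps, 5184)        # 64 types x 81 positions
  ps <- tiny_patch_set(1, size = 64, seed = 9)
  u <- primary_capsules(m, ps[1])
  expect_equal(dim(u), c(8, 5184, 1))
  norms <- sqrt(colSums(u[, , 1]^2))
  expect_true(all(norms < 1))
})

test_that("attention weights normalize and match the reference chain", {
  m <- dbsa_model("DBSACaps", input_size = 16, seed = 3)
  ps <- tiny_patch_set(1, size = 16, seed = 5)
  det <- forward_detail(m, ps[1:2])
  expect_equal(det$att_spe + det$att_spa,
               matrix(1, 128, 2), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(det$att_spe > 0 & det$att_spe < 1))
  # recompute one sample's attention in R from the extracted SE weights
  U_spe <- array(det$U_spe[, 1:256], c(128, 16, 16))
  U_spa <- array(det$U_spa[, 1:256], c(128, 16, 16))
  z1 <- se_weight(U_spe, get_param(m, "se.spectral.fc1.weight"),
                  get_param(m, "se.spectral.fc1.bias"),
                  get_param(m, "se.spectral.fc2.weight"),
                  get_param(m, "se.spectral.fc2.bias"))
  z2 <- se_weight(U_spa, get_param(m, "se.spatial.fc1.weight"),
                  get_param(m, "se.spatial.fc1.bias"),
                  get_param(m, "se.spatial.fc2.weight"),
                  get_param(m, "se.spatial.fc2.bias"))
  fus <- selective_fuse(U_spe, U_spa, z1, z2)
  expect_equal(fus$att_spe, det$att_spe[, 1], tolerance = 1e-4)
  expect_equal(as.vector(fus$V), as.vector(det$V[, 1:256]),
               tolerance = 1e-4)
})

test_that("the spectral branch has zero spatial receptive field", {
  m <- dbsa_model("SpectralCaps", input_size = 13, seed = 4)
  set.seed(6)
  x1 <- array(runif(150 * 13 * 13), c(150, 13, 13, 1))
  x2 <- x1
  x2[, 5, 9, 1] <- runif(150)
  u1 <- spectral_branch(m, x1)
  u2 <- spectral_branch(m, x2)
  changed <- apply(abs(u1 - u2) > 1e-7, c(2, 3), any)
  expect_true(changed[5, 9])
  expect_equal(sum(changed), 1L)
})

test_that("forward passes are deterministic, per-sample and in range", {
  m <- dbsa_model("DBSACaps", input_size = 16, seed = 5)
  ps <- tiny_patch_set(2, size = 16, seed = 7)
  x <- ps$data
  dup <- x[, , , c(1, 1, 3, 5), drop = FALSE]
  s <- predict(m, dup, type = "scores")
  expect_equal(dim(s), c(4, 3))
  expect_true(all(s >= 0 & s < 1))
  expect_equal(s[1, ], s[2, ], tolerance = 1e-6)      # duplicated sample
  perm <- predict(m, x[, , , c(3, 1, 5), drop = FALSE], type = "scores")
  expect_equal(perm[2, ], s[1, ], tolerance = 1e-6)   # order invariance
  # shape errors name the failing stage
  expect_error(predict(m, array(0, c(150, 8, 8, 1))), "input stage")
})

test_that("affine-head variants emit probabilities, not capsule lengths", {
  m <- dbsa_model("DBNet", input_size = 16, seed = 6)
  ps <- tiny_patch_set(1, size = 16, seed = 8)
  s <- predict(m, ps, type = "scores")
  expect_equal(rowSums(s), rep(1, 3), tolerance = 1e-5)
  cls <- predict(m, ps, type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), c("background", "healthy", "soft_rot"))
})

test_that("hand-derived gradients agree with finite differences", {
  m <- dbsa_model("DBSACaps", input_size = 13, seed = 11)
  set.seed(12)
  x <- array(runif(150 * 13 * 13 * 2), c(150, 13, 13, 2))
  y <- c(0L, 2L)
  lg <- dbsacaps:::net_loss_grad(m$ptr, x, y, 2L, TRUE)
  w <- coef(m)
  g <- lg$grad
  idx <- order(-abs(g))[seq(1, 40, by = 5)]
  eps <- 2e-3
  for (i in idx) {
    w2 <- w; w2[i] <- w[i] + eps
    dbsacaps:::net_set_params(m$ptr, w2)
    lp <- dbsacaps:::net_loss_only(m$ptr, x, y, 2L, TRUE)
    w2[i] <- w[i] - eps
    dbsacaps:::net_set_params(m$ptr, w2)
    lm <- dbsacaps:::net_loss_only(m$ptr, x, y, 2L, TRUE)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(1e-3, abs(fd) + abs(g[i])), 0.05)
  }
})

test_that("checkpoints restore identical predictions", {
  m <- dbsa_model("SpatialCaps", input_size = 13, seed = 13)
  ps <- tiny_patch_set(1, size = 13, seed = 14)
  s1 <- predict(m, ps, type = "scores")
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, ps, type = "scores"), s1, tolerance = 1e-7)
  expect_equal(count_parameters(m2), count_parameters(m))
})
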