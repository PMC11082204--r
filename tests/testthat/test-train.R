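test_that("metric identities hold on random confusion matrices", {
  set.seed(21)
  for (i in 1:20) {
    cls <- c("background", "healthy", "soft_rot")
    cm <- matrix(rpois(9, 20), 3, dimnames = list(cls, cls))
    r <- metrics_report(cm)
    expect_equal(r$oa, sum(diag(cm)) / sum(cm))
    expect_equal(r$aa, mean(diag(cm) / rowSums(cm)))
    expect_equal(r$macro_f1, mean(r$per_class$f1))
    expect_equal(r$macro_recall, r$aa)
    expect_true(all(unlist(r[c("oa", "aa", "macro_precision",
                               "macro_recall", "macro_f1")]) >= 0))
    expect_true(all(unlist(r[c("oa", "aa", "macro_f1")]) <= 1))
    expect_equal(unname(rowSums(r$confusion)), unname(r$per_class$support))
  }
})

test_that("the worked confusion example reproduces hand arithmetic", {
  cm <- matrix(c(50, 0, 0,
                 0, 40, 10,
                 0, 5, 45), 3, byrow = TRUE,
               dimnames = list(c("background", "healthy", "soft_rot"),
                               c("background", "healthy", "soft_rot")))
  r <- metrics_report(cm)
  expect_equal(r$oa, 135 / 150)
  expect_equal(r$aa, (1 + 0.8 + 0.9) / 3)
  sr <- r$per_class[r$per_class$class == "soft_rot", ]
  expect_equal(sr$precision, 45 / 55)
  expect_equal(sr$recall, 0.90)
  expect_equal(sr$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9))
  expect_equal(round(sr$f1, 4), 0.8571)
  # perfect diagonal: everything 1
  perfect <- metrics_report(diag(c(5, 5, 5)))
  expect_equal(perfect$oa, 1)
  expect_equal(perfect$aa, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  # zero-division flagged, not propagated
  degenerate <- metrics_report(matrix(c(5, 0, 0, 5, 0, 0, 0, 0, 0), 3))
  expect_true(degenerate$zero_division)
  expect_false(anyNA(unlist(degenerate$per_class[, 2:4])))
})

test_that("training batches, history and seeding behave arithmetically", {
  ps <- tiny_patch_set(6, size = 13, seed = 31)   # 18 patches
  train <- ps[1:16]
  cfg <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 16,
                      seed = 5, microbatch = 4)
  m1 <- fit(dbsa_model("DBNet", input_size = 13, seed = 5), train,
            config = cfg)
  expect_equal(nrow(m1$history), 1)                # one epoch recorded
  expect_true(is.finite(m1$history$loss))
  expect_true(m1$trained)
  # identical seeds and config: identical epoch-1 loss
  m2 <- fit(dbsa_model("DBNet", input_size = 13, seed = 5), train,
            config = cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  # a different init seed changes the loss
  m3 <- fit(dbsa_model("DBNet", input_size = 13, seed = 6), train,
            config = cfg)
  expect_false(identical(m1$history$loss, m3$history$loss))
  expect_error(fit(dbsa_model("DBNet", input_size = 13, seed = 5),
                   ps[0], config = cfg), "empty")
})

test_that("validation tracking keeps the best epoch and can stop early", {
  tr <- tiny_patch_set(4, size = 13, seed = 41)
  va <- tiny_patch_set(2, size = 13, seed = 42, split = "val")
  cfg <- train_config(learning_rate = 5e-4, epochs = 3, batch_size = 8,
                      seed = 7, microbatch = 4)
  m <- fit(dbsa_model("DBNet", input_size = 13, seed = 7), tr, va, cfg)
  expect_equal(nrow(m$history), 3)
  expect_true(all(is.finite(m$history$val_oa)))
  # early stop: target reached on some epoch ends the loop there
  cfg2 <- cfg
  cfg2$stop_at_val_oa <- 0
  m2 <- fit(dbsa_model("DBNet", input_size = 13, seed = 7), tr, va, cfg2)
  expect_equal(nrow(m2$history), 1)
})

test_that("evaluation is deterministic and order-invariant", {
  ps <- tiny_patch_set(3, size = 13, seed = 51)
  m <- dbsa_model("SpatialCaps", input_size = 13, seed = 8)
  r1 <- evaluate(m, ps)
  r2 <- evaluate(m, ps)
  expect_equal(r1$confusion, r2$confusion)
  perm <- sample(length(ps))
  r3 <- evaluate(m, ps[perm])
  expect_equal(r1$confusion, r3$confusion)
  expect_equal(r1$n, length(ps))
})

test_that("the ablation harness reports per-variant rows and survives failures", {
  tr <- tiny_patch_set(2, size = 13, seed = 61)
  te <- tiny_patch_set(2, size = 13, seed = 62, split = "test")
  cfg <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 8,
                      seed = 9, microbatch = 4)
  # DBSACapsWithRec3 cannot build at an odd spatial size: row marked failed
  tmp <- withr::local_tempdir()
  tab <- run_ablation(c("DBNet", "SpatialCaps", "DBSACapsWithRec3"),
                      tr, NULL, te, cfg, out_dir = tmp)
  expect_equal(nrow(tab), 3)
  expect_false(any(tab$failed[1:2]))
  expect_true(tab$failed[tab$variant == "DBSACapsWithRec3"])
  expect_true(all(is.finite(tab$oa[1:2])))
  expect_true(all(tab$parameters[1:2] > 0))
  expect_true(file.exists(file.path(tmp, "ablation.csv")))
  expect_true(file.exists(file.path(tmp, "ablation.json")))
  expect_error(run_ablation("NoSuchNet", tr, NULL, te, cfg), "unknown")
  # same config twice: identical parameter-count column
  tab2 <- run_ablation(c("DBNet", "SpatialCaps"), tr, NULL, te, cfg)
  expect_identical(tab$parameters[1:2], tab2$parameters)
})
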