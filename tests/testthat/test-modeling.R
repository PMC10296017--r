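test_that("feature sets list exactly the documented columns", {
  expect_setequal(feature_set_columns("anthropometric_trimmed"),
                  c("age", "bmi", "sex"))
  expect_setequal(feature_set_columns("anthropometric"),
                  c("age", "bmi", "height", "weight", "sex"))
  expect_setequal(feature_set_columns("balance"),
                  c("statok_area", "gfr_ratio"))
  expect_length(feature_set_columns("neuromuscular"), 14L)
  expect_error(feature_set_columns("does_not_exist"), "unknown")
})

test_that("assemble_feature_set encodes factors and shapes correctly", {
  tab <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                    group = rep(0:1, each = 2), sex = 0L,
                    age = c(30, 30, 40, 40), bmi = 24, height = 170,
                    weight = 70,
                    movement = rep(c("back_extension", "back_flexion"), 2),
                    speed = "preferred",
                    statok_area = c(1, 2, 3, NA), gfr_ratio = 1.1)
  fs <- assemble_feature_set(tab, "balance")
  expect_equal(ncol(fs$x), 4L)       # + movement, speed codes
  expect_equal(nrow(fs$x), 4L)
  expect_true(all(fs$x[, "movement"] %in% c(0, 1)))
  expect_false(anyNA(fs$x))          # NA mean-imputed
  an <- assemble_feature_set(tab, "anthropometric_trimmed")
  expect_equal(nrow(an$x), 2L)       # one row per subject
  expect_equal(an$y, c(0L, 1L))
  expect_error(assemble_feature_set(tab[, -10], "balance"), "missing")
})

test_that("the dense classifier specification matches its blueprint", {
  spec <- build_dnn(68)
  expect_length(spec$layers, 5L)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c("dense", "dense", "dropout", "dense", "dense"))
  expect_equal(spec$layers[[3]]$rate, 0.5)
  expect_equal(spec$layers[[5]]$units, 1L)
  expect_error(build_dnn(0), ">= 1")
})

test_that("parameter counting reproduces dense/conv/batchnorm arithmetic", {
  # dense(1) on a single input: weight + bias
  p <- count_parameters(build_dnn(1, width = 1))
  expect_equal(p$params[1], 2L)
  full <- count_parameters(build_dnn(68))
  expect_equal(full$params[full$kind == "dense"], c(759L, 1536L, 4644L, 37L))
  cnn <- count_parameters(build_cnn())
  expect_equal(cnn$params[cnn$kind == "conv3d"],
               c(1448L, 11528L, 23056L, 46096L, 92192L, 184352L))
  expect_equal(cnn$params[cnn$kind == "batchnorm"], c(32L, 64L, 128L))
  expect_equal(cnn$params[cnn$kind == "dense"], c(24640L, 4160L, 65L))
})

test_that("subject splits are stratified, disjoint and reproducible", {
  subjects <- data.frame(id = sprintf("S%02d", 1:100),
                         group = rep(0:1, each = 50))
  plan <- split_subjects(subjects, seed = 13)
  expect_length(plan$validation, 30L)
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_length(intersect(plan$train, plan$validation), 0L)
  expect_length(intersect(plan$test, plan$validation), 0L)
  expect_setequal(c(plan$train, plan$test, plan$validation), subjects$id)
  expect_identical(plan, split_subjects(subjects, seed = 13))
  expect_error(split_subjects(data.frame(id = c("a", "b", "c"),
                                         group = c(0, 0, 1))),
               "stratify")
})

test_that("training separates separable data and not shuffled labels", {
  set.seed(31)
  n_sub <- 80
  subj <- data.frame(id = sprintf("P%03d", 1:n_sub),
                     group = rep(0:1, each = n_sub / 2))
  x <- cbind(rnorm(n_sub, 2 * subj$group), rnorm(n_sub), rnorm(n_sub))
  plan <- split_subjects(subj, seed = 3)
  spec <- build_dnn(3)
  tr <- train_classifier(spec, x, subj$group, subj$id, plan,
                         epochs = 120, seed = 7)
  expect_gte(tr$best_validation_accuracy, 0.8)
  expect_true(all(tr$history$acc_validation >= 0 &
                  tr$history$acc_validation <= 1))
  # label shuffling destroys the signal
  set.seed(5); ysh <- sample(subj$group)
  tr_sh <- train_classifier(spec, x, ysh, subj$id, plan,
                            epochs = 40, seed = 7)
  expect_lt(tail(tr_sh$history$acc_validation, 1), 0.8)
  # fixed seed reproduces the accuracy trace
  tr2 <- train_classifier(spec, x, subj$group, subj$id, plan,
                          epochs = 120, seed = 7)
  expect_identical(tr$history, tr2$history)
  # convolutional specs are not trainable here
  expect_error(train_classifier(build_cnn(), x, subj$group, subj$id, plan),
               "not supported")
})
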