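test_that("critical correlations match an independent t-CDF inversion", {
  # oracle: solve pt(r sqrt((n-2)/(1-r^2)), n-2) = 1 - alpha/2 for r
  oracle <- function(n, alpha) {
    uniroot(function(r)
      2 * (1 - pt(r * sqrt((n - 2) / (1 - r^2)), n - 2)) - alpha,
      c(1e-9, 1 - 1e-9), tol = 1e-14)$root
  }
  for (n in c(10, 46, 200)) for (a in c(0.05, 0.01, 0.005, 0.001)) {
    expect_equal(critical_correlation(n, a), oracle(n, a),
                 tolerance = 1e-10)
  }
  # decreasing in n, increasing as alpha shrinks, vanishing as n grows
  expect_lt(critical_correlation(100, 0.05), critical_correlation(20, 0.05))
  expect_gt(critical_correlation(46, 0.001), critical_correlation(46, 0.05))
  expect_lt(critical_correlation(1e6, 0.05), 0.005)
  expect_error(critical_correlation(2, 0.05), ">= 3")
})

test_that("the factor-count ensemble recovers planted dimensionality", {
  set.seed(61)
  lam <- matrix(0, 8, 2)
  lam[1:4, 1] <- 0.85; lam[5:8, 2] <- 0.85
  f <- matrix(rnorm(500 * 2), 500, 2)
  x <- f %*% t(lam) + matrix(rnorm(500 * 8, 0, 0.4), 500, 8)
  nf <- n_factors_ensemble(x, seed = 2)
  expect_equal(as.integer(nf), 2L)
  # independent noise: the parallel-analysis vote stays at the null; the
  # rounded-mean ensemble is inflated only by the liberal Kaiser vote
  noise <- matrix(rnorm(500 * 8), 500, 8)
  nn <- n_factors_ensemble(noise, seed = 2)
  expect_lte(attr(nn, "counts")[["parallel"]], 1L)
  expect_lte(as.integer(nn), 2L)
  # determinism
  expect_equal(n_factors_ensemble(x, seed = 2), n_factors_ensemble(x, seed = 2))
  expect_error(n_factors_ensemble(x[, c(1, 1)], seed = 1), "singular")
})

test_that("ML extraction recovers a planted loading structure", {
  set.seed(62)
  p <- 10
  lam <- matrix(0, p, 2)
  lam[1:5, 1] <- c(0.9, 0.8, 0.7, 0.75, 0.85)
  lam[6:10, 2] <- c(0.85, 0.7, 0.8, 0.9, 0.75)
  psi <- 1 - rowSums(lam^2)
  n <- 2000
  f <- matrix(rnorm(n * 2), n, 2)
  x <- f %*% t(lam) + matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi))
  fit <- fit_fa_ml(x, 2)
  # a factor solution is identified only up to an orthogonal rotation;
  # align with the planted frame by orthogonal procrustes before comparing
  sv <- svd(crossprod(fit$loadings, lam))
  L <- fit$loadings %*% (sv$u %*% t(sv$v))
  expect_lt(max(abs(L - lam)), 0.05)
  expect_true(all(fit$uniquenesses >= 0 & fit$uniquenesses <= 1))
  expect_error(fit_fa_ml(x, 0), ">= 1")
})

test_that("varimax rotation preserves the common-variance structure", {
  set.seed(63)
  L <- matrix(rnorm(24), 8, 3)
  R <- varimax_rotate(L)
  expect_equal(R %*% t(R), L %*% t(L), tolerance = 1e-10)
  expect_identical(varimax_rotate(L[, 1, drop = FALSE]),
                   L[, 1, drop = FALSE])
  vc <- function(M) sum(apply(M^2, 2, var))
  expect_gte(vc(R), vc(L) - 1e-10)
  # a perfectly simple structure is a fixed point up to sign/order
  S <- matrix(0, 6, 2); S[1:3, 1] <- 0.9; S[4:6, 2] <- 0.8
  RS <- varimax_rotate(S)
  expect_equal(abs(RS %*% t(RS)), abs(S %*% t(S)), tolerance = 1e-8)
})

test_that("FA input assembles the 13 variables with the right axis rules", {
  cols <- c("age", "group", "sex", "bmi", "max_rom", "time_to_max_rom",
            "traj_entropy", "traj_intervar", "traj_intravar",
            "emg_entropy_l_low", "emg_entropy_r_low", "emg_centroid_y",
            "gfr_fa")
  set.seed(64)
  tab <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                     movement = movement_levels(), speed = speed_levels(),
                     stringsAsFactors = FALSE)
  tab$group <- as.integer(tab$subject_id %in% sprintf("S%02d", 5:8))
  tab$sex <- 0L; tab$age <- 30; tab$bmi <- 24
  for (ax in c("x", "y", "z")) {
    tab[[paste0("traj_maxamp_left_shoulder_", ax)]] <- runif(nrow(tab))
    tab[[paste0("traj_t2max_left_shoulder_", ax)]] <- runif(nrow(tab))
    tab[[paste0("traj_sampen_left_shoulder_", ax)]] <- runif(nrow(tab))
    tab[[paste0("traj_intervar_left_shoulder_", ax)]] <- runif(nrow(tab))
    tab[[paste0("traj_intravar_left_shoulder_", ax)]] <- runif(nrow(tab))
  }
  tab$angle_max_shoulder_z <- runif(nrow(tab))
  tab$angle_t2max_shoulder_z <- runif(nrow(tab))
  tab$emg_entropy_left_lower <- runif(nrow(tab))
  tab$emg_entropy_right_lower <- runif(nrow(tab))
  tab$emg_centroid_global_y <- runif(nrow(tab))
  tab$gfr_fa <- runif(nrow(tab), -0.2, 0.2)

  inp <- fa_input(tab, "back_extension", "preferred")
  expect_setequal(names(inp), cols)
  expect_equal(attr(inp, "axis"), "y")
  expect_equal(attr(fa_input(tab, "back_flexion", "preferred"), "axis"), "z")
  expect_equal(attr(fa_input(tab, "lat_flex_left", "maximum"), "axis"), "z")
  # rotations use the max-angle pair
  rotin <- fa_input(tab, "rot_left", "preferred")
  sub <- tab[tab$movement == "rot_left" & tab$speed == "preferred", ]
  expect_equal(rotin$max_rom, sub$angle_max_shoulder_z)
  # axis override implements the z -> y -> x fallback
  expect_equal(attr(fa_input(tab, "back_flexion", "preferred", axis = "y"),
                    "axis"), "y")
  # missing values are mean-imputed and counted
  tab$gfr_fa[1] <- NA
  inp2 <- fa_input(tab, "back_extension", "preferred")
  expect_false(anyNA(inp2))
  expect_gte(attr(inp2, "n_imputed"), 0L)
})

test_that("the group component is flagged by the critical threshold", {
  crit <- critical_table(46)
  res <- structure(list(
    n_factors = 2L,
    loadings = matrix(c(crit[[1]], 0.9, -0.5, 0.05,
                        0.01, 0.1, 0.2, 0.8),
                      4, 2, dimnames = list(c("group", "a", "b", "c"),
                                            c("F1", "F2"))),
    signif = matrix(c("*", "++", "++", "", "", "", "", "++"), 4, 2,
                    dimnames = list(c("group", "a", "b", "c"),
                                    c("F1", "F2"))),
    critical = crit, n = 46), class = "fa_result")
  g <- find_group_component(res)
  expect_equal(g$component, 1L)
  # a loading exactly at the threshold counts as significant
  expect_true(g$significant)
  expect_setequal(g$co_loadings$variable, c("a", "b"))
  # below threshold: not significant
  res$loadings["group", 1] <- 0.20
  expect_false(find_group_component(res)$significant)
})
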