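rates_row <- function(network_id, group, compartment, vals) {
  tibble::tibble(network_id = network_id, group = group,
                 compartment = compartment,
                 condition = names(vals), rate_hz = as.numeric(vals))
}

test_that("features are the four percent changes, with missing propagation", {
  r <- rates_row("n1", "control", "single",
                 c(baseline1 = 2, NMDA_gly = 1, D_AP5 = 1.5,
                   baseline2 = 2, AMPA = 4, CNQX = 1))
  f <- build_features(r)
  expect_equal(f$f1, -50)
  expect_equal(f$f2, 50)
  expect_equal(f$f3, 100)
  expect_equal(f$f4, -75)

  r2 <- rates_row("n2", "control", "single",
                  c(baseline1 = 2, NMDA_gly = 1, D_AP5 = 1.5,
                    baseline2 = NA, AMPA = 4, CNQX = 1))
  f2 <- build_features(r2)
  expect_true(is.na(f2$f3))
  expect_equal(f2$f1, -50)
  expect_equal(f2$f2, 50)
  expect_equal(f2$f4, -75)
})

test_that("tripartite layouts give 12 features in fixed compartment order", {
  rows <- dplyr::bind_rows(lapply(c("proximal", "distal1", "distal2"),
    function(cp) rates_row("n1", "control", cp,
                           c(baseline1 = 2, NMDA_gly = 3, D_AP5 = 1,
                             baseline2 = 2, AMPA = 4, CNQX = 1))))
  f <- build_features(rows)
  expect_equal(names(f),
               c("network_id", "group",
                 paste(rep(c("proximal", "distal1", "distal2"), each = 4),
                       c("f1", "f2", "f3", "f4"), sep = "_")))
})

test_that("mean padding fills with the pooled column mean", {
  feats <- tibble::tibble(network_id = c("a", "b", "c"),
                          group = c("control", "control", "treated"),
                          f1 = c(1, NA, 3), f2 = c(2, 4, 6))
  out <- impute_standardize(feats)
  expect_equal(nrow(out$imputation), 1)
  expect_equal(out$imputation$value, 2)
  expect_equal(out$imputation$column, "f1")
  # filled matrix column was [1,2,3]; standardized with population SD sqrt(2/3)
  expect_equal(out$standardized$f1,
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(out$standardized$f1[3], 4), 1.2247)

  complete <- impute_standardize(dplyr::mutate(feats, f1 = c(1, 2, 3)))
  expect_equal(nrow(complete$imputation), 0)
  expect_equal(complete$standardized$f1, out$standardized$f1)
})

test_that("standardized columns have mean 0 and population SD 1; constants flagged", {
  set.seed(3)
  feats <- tibble::tibble(network_id = as.character(1:40),
                          group = rep(c("control", "treated"), 20),
                          f1 = rnorm(40), f2 = runif(40) * 100,
                          f3 = c(NA, rnorm(39)), f4 = rep(7, 40))
  out <- impute_standardize(feats)
  for (cl in c("f1", "f2", "f3")) {
    z <- out$standardized[[cl]]
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  }
  expect_equal(out$constant_columns, "f4")
  expect_equal(out$standardized$f4, rep(0, 40))
  expect_error(impute_standardize(dplyr::mutate(feats, f1 = NA_real_)),
               "no observed values")
})

test_that("PCA: variance fractions, rotation invariance, eigen oracle", {
  set.seed(4)
  line <- tibble::tibble(network_id = as.character(1:20),
                         group = rep(c("control", "treated"), 10),
                         f1 = seq(-2, 2, length.out = 20),
                         f2 = 2 * seq(-2, 2, length.out = 20))
  emb <- pca_embed(line, n_components = 2)
  expect_equal(emb$explained_variance[1], 1)

  x <- matrix(rnorm(200 * 4), 200)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  as_feats <- function(m) {
    dplyr::bind_cols(tibble::tibble(network_id = as.character(seq_len(nrow(m))),
                                    group = "control"),
                     tibble::as_tibble(as.data.frame(m)))
  }
  e1 <- pca_embed(as_feats(x), 3)
  e2 <- pca_embed(as_feats(x %*% q), 3)
  expect_equal(e1$explained_variance, e2$explained_variance, tolerance = 1e-9)

  # correlated Gaussian cloud: PC1 fraction matches the eigendecomposition
  n <- 500; rho <- 0.9
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  feats <- tibble::tibble(network_id = as.character(1:n), group = "control",
                          f1 = z1, f2 = z2)
  std <- impute_standardize(feats)$standardized
  emb <- pca_embed(std, 2)
  zc <- scale(as.matrix(std[, c("f1", "f2")]), scale = FALSE)
  ev <- eigen(crossprod(zc) / n, symmetric = TRUE)$values
  expect_lt(abs(emb$explained_variance[1] - ev[1] / sum(ev)), 1e-9)

  expect_error(pca_embed(line[1:1, ], 2), "fewer rows")
})

test_that("PCA sign convention is deterministic", {
  set.seed(5)
  x <- matrix(rnorm(60), 20)
  feats <- dplyr::bind_cols(tibble::tibble(network_id = as.character(1:20),
                                           group = "g"),
                            tibble::as_tibble(as.data.frame(x)))
  e <- pca_embed(feats, 3)
  for (j in 1:3) {
    l <- e$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

square <- function(ox, oy) {
  rbind(c(ox, oy), c(ox + 1, oy), c(ox + 1, oy + 1), c(ox, oy + 1))
}

test_that("overlap: closed forms, symmetry, rigid-motion invariance", {
  set.seed(6)
  a <- matrix(rnorm(30), ncol = 2)
  expect_equal(overlap_percentage(a, a)$overlap_percent, 100)

  b <- a + 100
  expect_equal(overlap_percentage(a, b)$overlap_percent, 0)

  s1 <- square(0, 0); s2 <- square(0.5, 0)
  ov <- overlap_percentage(s1, s2)
  expect_equal(ov$intersection_area,
               oracle_rect_overlap(c(0, 1), c(0, 1), c(0.5, 1.5), c(0, 1)))
  expect_lt(abs(ov$overlap_percent - 50), 1e-9)

  ab <- overlap_percentage(a, b)$overlap_percent
  ba <- overlap_percentage(b, a)$overlap_percent
  expect_identical(ab, ba)
  c2 <- a + matrix(rep(c(0.3, -0.2), each = 15), ncol = 2)
  expect_identical(overlap_percentage(a, c2)$overlap_percent,
                   overlap_percentage(c2, a)$overlap_percent)

  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(3, -5)
  moved <- function(p) sweep(p %*% rot, 2, shift, "+")
  expect_equal(overlap_percentage(moved(a), moved(c2))$overlap_percent,
               overlap_percentage(a, c2)$overlap_percent, tolerance = 1e-9)
})

test_that("degenerate geometry is flagged, not scored", {
  coll <- cbind(1:5, 2 * (1:5))
  set.seed(7)
  ok <- matrix(rnorm(20), ncol = 2)
  res <- overlap_percentage(coll, ok)
  expect_true(res$degenerate)
  expect_true(is.na(res$overlap_percent))
  expect_true(overlap_percentage(ok[1:2, ], ok)$degenerate)
})

test_that("fingerprint pipeline separates what the generator separates", {
  null_spec <- pharm_sim_spec(n_per_group = 20,
                              treated_factors = c(NMDA_gly = 1.8, D_AP5 = 0.5,
                                                  AMPA = 2.0, CNQX = 0.3),
                              seed = 41)
  fp <- run_fingerprint(simulate_pharm_experiment(null_spec)$rates)
  expect_false(fp$overlap$degenerate)
  expect_gte(fp$overlap$overlap_percent, 60)

  # duplicate of one cohort in both groups: exact 100%
  sim <- simulate_pharm_experiment(pharm_sim_spec(n_per_group = 10, seed = 42))
  both <- dplyr::bind_rows(
    dplyr::mutate(sim$rates, group = "control",
                  network_id = paste0("c_", network_id)),
    dplyr::mutate(sim$rates, group = "treated",
                  network_id = paste0("t_", network_id)))
  fp2 <- run_fingerprint(both)
  expect_equal(fp2$overlap$overlap_percent, 100)

  one_group <- dplyr::filter(sim$rates, group == "control")
  expect_error(run_fingerprint(one_group), "both groups")
})

test_that("identical inputs give bit-identical fingerprint reports", {
  sim <- simulate_pharm_experiment(pharm_sim_spec(n_per_group = 8, seed = 43))
  f1 <- run_fingerprint(sim$rates)
  f2 <- run_fingerprint(sim$rates)
  expect_identical(f1$embedding$scores, f2$embedding$scores)
  expect_identical(f1$overlap$overlap_percent, f2$overlap$overlap_percent)
})
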