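test_that("normalized Laplacian matches hand-computed small cases", {
  expect_equal(bare(normalized_laplacian(matrix(1, 2, 2))),
               rbind(c(0.5, -0.5), c(-0.5, 0.5)), ignore_attr = TRUE)
  expect_equal(bare(normalized_laplacian(diag(4))),
               matrix(0, 4, 4), ignore_attr = TRUE)

  # two-entity kernel with off-diagonal e^-2:
  # L diagonal = e^-2 / (1 + e^-2) = 0.11920292202211755
  K <- rbind(c(1, exp(-2)), c(exp(-2), 1))
  L <- bare(normalized_laplacian(K))
  expect_equal(diag(L), rep(0.11920292202211755, 2), tolerance = 1e-12)
  expect_equal(L[1, 2], -0.11920292202211755, tolerance = 1e-12)

  expect_error(normalized_laplacian(matrix(1:6, 2, 3)), "square")
  expect_error(normalized_laplacian(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("Laplacian spectrum lies in [0, 2] and sqrt-degrees are annihilated", {
  for (seed in 1:5) {
    net <- random_bipartite(15, 8, 0.25, seed = seed)
    K <- gip_similarity(net, "microbe")
    L <- normalized_laplacian(K)
    ev <- eigen(unclass(L), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
    v <- sqrt(attr(L, "degree_diagonal"))
    expect_lt(max(abs(unclass(L) %*% v)), 1e-8 * sqrt(sum(v^2)))
    expect_equal(bare(L), ref_laplacian(bare(K)), tolerance = 1e-12)
  }
})

test_that("eta = 0 recovers the label matrix exactly", {
  K <- random_pd_kernel(5, seed = 2)
  L <- normalized_laplacian(K)
  A <- withr::with_seed(3, matrix(rbinom(15, 1, 0.4), 5, 3))
  expect_equal(unname(optimal_classifier(K, L, A, eta = 0)), A * 1,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("closed form equals (I + eta L)^(-1) A on invertible kernels", {
  for (seed in 1:6) {
    K <- random_pd_kernel(5, seed = seed)
    L <- normalized_laplacian(K)
    A <- withr::with_seed(seed + 100, matrix(rbinom(10, 1, 0.5), 5, 2))
    for (eta in c(0.3, 1, 4)) {
      F_pkg <- optimal_classifier(K, L, A, eta)
      F_id <- solve(diag(5) + eta * unclass(L), A)
      expect_equal(unname(F_pkg), unname(F_id), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("closed form minimizes the trace-form regularized cost", {
  # J(F) = ||A - F||_F^2 + eta tr(F' L F); compare against a generic
  # numeric minimizer started away from the solution
  K <- random_pd_kernel(4, seed = 11)
  L <- unclass(normalized_laplacian(K))
  A <- withr::with_seed(12, matrix(rbinom(8, 1, 0.5), 4, 2))
  eta <- 1
  J <- function(f) {
    F_ <- matrix(f, 4, 2)
    sum((A - F_)^2) + eta * sum(diag(t(F_) %*% L %*% F_))
  }
  gJ <- function(f) {
    F_ <- matrix(f, 4, 2)
    as.vector(2 * (F_ - A) + 2 * eta * L %*% F_)
  }
  opt <- stats::optim(rep(0, 8), J, gJ, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  F_pkg <- optimal_classifier(K, normalized_laplacian(K), A, eta)
  expect_equal(as.vector(F_pkg), opt$par, tolerance = 1e-6)
  expect_lte(J(as.vector(F_pkg)), opt$value + 1e-8)
})

test_that("singular kernels fall back to the pseudo-inverse solution", {
  # duplicated 0/1 profiles make K exactly singular; in the model the
  # label matrix is the profile matrix itself, so identical kernel rows
  # always carry identical labels
  P <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 0))
  K <- gip_kernel(P)
  L <- normalized_laplacian(K)
  expect_warning(F_pkg <- optimal_classifier(K, L, P, eta = 1),
                 class = "lrls_singular_fallback")
  expect_true(attr(F_pkg, "fallback"))
  # the pseudo-inverse solution coincides with the well-posed identity form
  F_id <- solve(diag(4) + unclass(L), P)
  expect_equal(unname(F_pkg), unname(F_id), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fusion is a convex combination with the declared orientation", {
  Y <- toy_Y()
  expect_equal(combine_classifiers(Y, t(Y), lw = 0.5), Y * 1,
               ignore_attr = TRUE)
  FM <- matrix(1:6, 2, 3)
  FD <- matrix(7:12, 3, 2)
  expect_equal(combine_classifiers(FM, FD, lw = 1), FM * 1)
  expect_equal(combine_classifiers(FM, FD, lw = 0), t(FD) * 1)
  expect_error(combine_classifiers(FM, t(FD)), "incompatible")
})

test_that("full pipeline matches an independent reference implementation", {
  # 2x2 toy: known pairs must outscore unknown pairs, values must match
  net <- as_mda_network(toy_Y())
  fit <- lrlshmda(net)
  expect_equal(unname(fit$scores), ref_predict(toy_Y()), tolerance = 1e-10)
  expect_gt(min(fit$scores[net$Y == 1]), max(fit$scores[net$Y == 0]))

  # and on a larger random instance with non-default parameters
  net2 <- planted_block_network(14, 7, 2, 0.6, 0.05, seed = 21)
  p <- lrls_params(eta_m = 0.7, eta_d = 2, lw = 0.3)
  fit2 <- lrlshmda(net2, p)
  expect_equal(unname(fit2$scores),
               unname(ref_predict(net2$Y, eta_m = 0.7, eta_d = 2, lw = 0.3)),
               tolerance = 1e-8)
})

test_that("eta = 0 on both sides returns the adjacency as scores", {
  net <- planted_block_network(10, 5, 2, 0.6, 0.1, seed = 8)
  fit <- lrlshmda(net, lrls_params(eta_m = 0, eta_d = 0))
  expect_equal(unname(fit$scores), unname(net$Y) * 1, tolerance = 1e-8)
})

test_that("pipeline is equivariant under label permutation", {
  net <- planted_block_network(12, 6, 2, 0.7, 0.05, seed = 13)
  fit <- lrlshmda(net)
  pm <- withr::with_seed(1, sample(net$nm))
  pd <- withr::with_seed(2, sample(net$nd))
  net_p <- as_mda_network(net$Y[pm, pd])
  fit_p <- lrlshmda(net_p)
  expect_equal(unname(fit_p$scores), unname(fit$scores[pm, pd]),
               tolerance = 1e-10)
})

test_that("duplicate input rows do not change the scores", {
  df <- tibble::tibble(microbe = c("m1", "m2", "m1", "m3"),
                       disease = c("d1", "d2", "d2", "d1"))
  fit1 <- lrlshmda(build_adjacency(df))
  fit2 <- lrlshmda(build_adjacency(dplyr::bind_rows(df, df[c(1, 1, 3), ])))
  expect_equal(fit1$scores, fit2$scores)
})

test_that("tidy/glance expose scores and configuration", {
  net <- as_mda_network(toy_Y())
  fit <- lrlshmda(net)
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_true(all(td$known[1:2]))          # sorted descending by score
  expect_equal(nrow(tidy(fit, known = FALSE)), 2L)
  g <- glance(fit)
  expect_equal(g$lw, 0.5)
  expect_equal(g$n_known, 2L)
})

test_that("candidate ranking excludes known pairs and flags ties", {
  net <- as_mda_network(rbind(c(0, 1), c(1, 0), c(0, 0)))
  fit <- lrlshmda(net)
  fit$scores[, 1] <- c(0.9, 0.1, 0.5)   # m2 is the known pair in d1
  ranked <- rank_candidates(fit, "d1", top_k = 2)
  expect_equal(ranked$microbe, c("m1", "m3"))
  expect_equal(ranked$score, c(0.9, 0.5))

  # top_k beyond the candidate count returns everything
  expect_equal(nrow(rank_candidates(fit, "d1", top_k = 50)), 2L)

  # ties flagged, broken by index order
  fit$scores[, 2] <- c(0.4, 0.7, 0.7)
  r2 <- rank_candidates(fit, "d2", top_k = 3)
  expect_equal(r2$microbe, c("m2", "m3"))
  expect_true(all(r2$tied))

  expect_error(rank_candidates(fit, "d3"), "unknown disease")
  net2 <- as_mda_network(matrix(c(1, 0), 2, 1,
                                dimnames = list(c("m1", "m2"), "asthma")))
  expect_error(rank_candidates(lrlshmda(net2), "astma"), "did you mean")
})
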