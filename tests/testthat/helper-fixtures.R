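# Small fixtures and independent straight-line reference implementations
# used as oracles. These deliberately use naive double loops and the
# algebraic identity (I + eta L)^(-1) A, i.e. a different computation path
# from the package internals.

toy_Y <- function() {
  rbind(c(1L, 0L), c(0L, 1L))
}

# naive element-by-element GIP kernel
ref_gip <- function(P, gamma_prime = 1) {
  n <- nrow(P)
  g <- gamma_prime / mean(vapply(seq_len(n),
                                 function(i) sum(P[i, ]^2), 0))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-g * sum((P[i, ] - P[j, ])^2))
    }
  }
  K
}

ref_laplacian <- function(K) {
  D <- diag(rowSums(K))
  Dm <- diag(1 / sqrt(rowSums(K)))
  Dm %*% (D - K) %*% Dm
}

# full pipeline via the (I + eta L)^(-1) identity
ref_predict <- function(Y, eta_m = 1, eta_d = 1, lw = 0.5) {
  SM <- ref_gip(Y)
  SD <- ref_gip(t(Y))
  LM <- ref_laplacian(SM)
  LD <- ref_laplacian(SD)
  FM <- solve(diag(nrow(Y)) + eta_m * LM, Y)       # nm x nd
  FD <- solve(diag(ncol(Y)) + eta_d * LD, t(Y))    # nd x nm
  lw * FM + (1 - lw) * t(FD)
}

# all-pairs concordance count with ties worth 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# a random kernel-like symmetric positive definite matrix with unit
# diagonal (Gaussian kernel of generic continuous points is PD and,
# with distinct points, invertible)
random_pd_kernel <- function(n, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 3), n, 3)
    K <- exp(-as.matrix(dist(X))^2)
    diag(K) <- 1
    K
  })
}

write_toy_edges <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      microbe = c("m1", "m2", "m1", "m3", "m2"),
      disease = c("d1", "d2", "d2", "d1", "d1")
    )
  }
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# strip class/attrs so matrices compare on values alone
bare <- function(M) {
  M <- unclass(M)
  attributes(M) <- list(dim = dim(M))
  M
}
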