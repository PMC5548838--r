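#' Symmetric normalized graph Laplacian of a similarity matrix
#'
#' `L = D^(-1/2) (D - K) D^(-1/2) = I - D^(-1/2) K D^(-1/2)` with
#' `D = diag(rowSums(K))`. For a kernel with unit diagonal every row sum is
#' strictly positive, so L is always defined; its spectrum lies in `[0, 2]`
#' and the sqrt-degree vector spans its null space component for each
#' connected block.
#'
#' @param K A symmetric similarity matrix with strictly positive row sums
#'   (e.g. a [gip_kernel()]).
#' @return A symmetric matrix of class `graph_laplacian` with attribute
#'   `degree_diagonal` (the diagonal of D).
#' @export
normalized_laplacian <- function(K) {
  K <- unclass(K)
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("K must be a square matrix", call. = FALSE)
  }
  if (max(abs(K - t(K))) > 1e-8) {
    stop("K must be symmetric", call. = FALSE)
  }
  d <- rowSums(K)
  if (any(d <= 0)) stop("K must have strictly positive row sums", call. = FALSE)
  s <- 1 / sqrt(d)
  L <- diag(nrow(K)) - s * sweep(K, 2L, s, "*")
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(K)
  structure(L, degree_diagonal = d,
            class = c("graph_laplacian", "matrix", "array"))
}

#' Model parameters for the Laplacian-regularized least-squares model
#'
#' @param eta_m,eta_d Nonnegative trade-off weights between the data-fit
#'   term and the Laplacian smoothness penalty in microbe and disease
#'   space. Default 1.
#' @param lw Fusion weight in `[0, 1]` mixing the microbe-space and
#'   disease-space classifiers; 0.5 (default) is the plain mean.
#' @param gamma_prime_m,gamma_prime_d Raw GIP kernel bandwidths, default 1.
#' @return A validated list of class `lrls_params`.
#' @export
lrls_params <- function(eta_m = 1, eta_d = 1, lw = 0.5,
                        gamma_prime_m = 1, gamma_prime_d = 1) {
  stopifnot(is.numeric(eta_m), eta_m >= 0, is.numeric(eta_d), eta_d >= 0,
            is.numeric(lw), lw >= 0, lw <= 1,
            gamma_prime_m > 0, gamma_prime_d > 0)
  structure(list(eta_m = eta_m, eta_d = eta_d, lw = lw,
                 gamma_prime_m = gamma_prime_m,
                 gamma_prime_d = gamma_prime_d),
            class = "lrls_params")
}

#' Closed-form optimal classifier in one space
#'
#' Solves the Laplacian-regularized least-squares problem
#' `min_F ||A_side - F||_F^2 + eta * tr(F' L F)` whose closed form is
#' `F = K (K + eta L K)^(-1) A_side`. The system is solved with a linear
#' solve; if it is numerically singular (reciprocal condition number below
#' `1e-12` — which happens exactly when two entities share identical
#' interaction profiles) an SVD pseudo-inverse is used instead (relative
#' singular value cutoff `1e-10`) and a warning of class
#' `lrls_singular_fallback` is raised. The fallback coincides with the
#' always-well-posed equivalent form `(I + eta L)^(-1) A_side`.
#'
#' @param K Similarity kernel (n x n).
#' @param L Its normalized Laplacian.
#' @param A_side Label matrix oriented for this space (n rows).
#' @param eta Nonnegative regularization weight.
#' @return The n x ncol(A_side) classifier matrix, with attribute
#'   `fallback` (TRUE if the pseudo-inverse path was taken).
#' @export
optimal_classifier <- function(K, L, A_side, eta) {
  K <- unclass(K); L <- unclass(L); A_side <- as.matrix(A_side)
  storage.mode(A_side) <- "double"
  stopifnot(nrow(K) == ncol(K), nrow(L) == nrow(K), nrow(A_side) == nrow(K),
            is.numeric(eta), eta >= 0)
  M <- K + eta * L %*% K
  rc <- tryCatch(rcond(M), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-12) {
    F_hat <- K %*% solve(M, A_side)
    fallback <- FALSE
  } else {
    warning(structure(class = c("lrls_singular_fallback", "warning",
                                "condition"),
                      list(message = paste0(
                        "classifier system numerically singular (rcond ",
                        format(rc, digits = 3),
                        "); using pseudo-inverse solution"),
                        call = sys.call())))
    F_hat <- K %*% (pseudo_inverse(M) %*% A_side)
    fallback <- TRUE
  }
  dimnames(F_hat) <- list(rownames(K), colnames(A_side))
  attr(F_hat, "fallback") <- fallback
  F_hat
}

# Moore-Penrose pseudo-inverse via SVD; tol is relative to the largest
# singular value.
pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Fuse the microbe- and disease-space classifiers
#'
#' `F* = lw * FM + (1 - lw) * FD'`, where `FM` is the microbe-space
#' classifier already oriented microbes x diseases and `FD` the
#' disease-space classifier oriented diseases x microbes. With `lw = 0.5`
#' this is the plain mean of the two scores for every pair.
#'
#' @param FM Microbe-space classifier, nm x nd.
#' @param FD Disease-space classifier, nd x nm.
#' @param lw Fusion weight in `[0, 1]`.
#' @return The nm x nd fused score matrix.
#' @export
combine_classifiers <- function(FM, FD, lw = 0.5) {
  stopifnot(lw >= 0, lw <= 1)
  if (!all(dim(FM) == rev(dim(FD)))) {
    stop("incompatible classifier shapes: FM is ", nrow(FM), "x", ncol(FM),
         ", FD is ", nrow(FD), "x", ncol(FD), call. = FALSE)
  }
  lw * FM + (1 - lw) * t(FD)
}

#' Fit the Laplacian-regularized least-squares association model
#'
#' Runs the full pipeline on a bipartite association network: interaction
#' profiles on both sides, GIP kernel similarities SM (microbes) and SD
#' (diseases), their normalized Laplacians, the closed-form classifiers in
#' each space, and the weighted fusion into one score matrix over every
#' microbe-disease pair. Deterministic for fixed input and parameters.
#'
#' @param network An `mda_network`.
#' @param params An [lrls_params()] object.
#' @return An object of class `lrls_fit` with elements `scores` (nm x nd
#'   matrix aligned with the network indexes), `network`, `params`, and
#'   `n_fallback` (how many of the two linear systems needed the
#'   pseudo-inverse path).
#' @examples
#' net <- as_mda_network(rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1)))
#' fit <- lrlshmda(net)
#' tidy(fit)
#' @export
lrlshmda <- function(network, params = lrls_params()) {
  stopifnot(inherits(network, "mda_network"), inherits(params, "lrls_params"))
  n_fallback <- 0L
  h <- function(w) {
    if (inherits(w, "lrls_singular_fallback")) {
      n_fallback <<- n_fallback + 1L
      invokeRestart("muffleWarning")
    }
  }
  Y <- network$Y
  scores <- withCallingHandlers({
    PM <- interaction_profiles(network, "microbe")
    PD <- interaction_profiles(network, "disease")
    SM <- gip_kernel(PM, gip_bandwidth(PM, params$gamma_prime_m))
    SD <- gip_kernel(PD, gip_bandwidth(PD, params$gamma_prime_d))
    LM <- normalized_laplacian(SM)
    LD <- normalized_laplacian(SD)
    # adjacency as consumed by the classifiers: A = Y' (diseases x microbes)
    A <- t(Y)
    FM <- optimal_classifier(SM, LM, t(A), params$eta_m)  # nm x nd
    FD <- optimal_classifier(SD, LD, A, params$eta_d)     # nd x nm
    combine_classifiers(FM, FD, params$lw)
  }, warning = h)
  attr(scores, "fallback") <- NULL
  structure(list(scores = scores, network = network, params = params,
                 n_fallback = n_fallback),
            class = "lrls_fit")
}

#' @export
print.lrls_fit <- function(x, ...) {
  cat("LapRLS microbe-disease association fit\n",
      "  pairs scored: ", x$network$nm, " microbes x ", x$network$nd,
      " diseases\n",
      "  parameters:   eta_m = ", x$params$eta_m,
      ", eta_d = ", x$params$eta_d, ", lw = ", x$params$lw, "\n",
      sep = "")
  invisible(x)
}

#' Tidy per-pair scores of a fit
#'
#' @param x An `lrls_fit`.
#' @param known Include pairs already known in the training network?
#'   Default TRUE; candidate-only listings set this FALSE.
#' @param ... Unused.
#' @return A tibble with columns `microbe`, `disease`, `score`, `known`,
#'   sorted by descending score.
#' @method tidy lrls_fit
#' @export
tidy.lrls_fit <- function(x, known = TRUE, ...) {
  net <- x$network
  out <- tibble::tibble(
    microbe = rep(net$microbe_index, times = net$nd),
    disease = rep(net$disease_index, each = net$nm),
    score = as.vector(x$scores),
    known = as.vector(net$Y) == 1L
  )
  if (!known) out <- dplyr::filter(out, !.data$known)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' @method glance lrls_fit
#' @export
glance.lrls_fit <- function(x, ...) {
  tibble::tibble(
    nm = x$network$nm, nd = x$network$nd,
    n_known = sum(x$network$Y),
    eta_m = x$params$eta_m, eta_d = x$params$eta_d, lw = x$params$lw,
    n_fallback = x$n_fallback
  )
}

#' Rank candidate microbes for one disease
#'
#' Returns the microbes *not* already associated with the disease, ordered
#' by decreasing predicted score. Ties are broken by microbe index order
#' and flagged in the output.
#'
#' @param fit An `lrls_fit`.
#' @param disease Disease name (must be in the network's disease index; an
#'   unknown name raises an error listing near matches).
#' @param top_k How many candidates to return; truncated to the number
#'   available. Default 10.
#' @return A tibble with columns `rank`, `microbe`, `score`, `tied`
#'   (TRUE when the score equals another candidate's score).
#' @export
rank_candidates <- function(fit, disease, top_k = 10) {
  stopifnot(inherits(fit, "lrls_fit"))
  net <- fit$network
  j <- match(disease, net$disease_index)
  if (is.na(j)) {
    near <- agrep(disease, net$disease_index, max.distance = 0.3,
                  ignore.case = TRUE, value = TRUE)
    stop("unknown disease: '", disease, "'",
         if (length(near) > 0L)
           paste0("; did you mean: ", paste(near, collapse = ", "), "?"),
         call. = FALSE)
  }
  candidate <- net$Y[, j] == 0L
  scores <- fit$scores[candidate, j]
  ord <- order(-scores, seq_along(scores))
  scores <- scores[ord]
  out <- tibble::tibble(
    rank = seq_along(scores),
    microbe = net$microbe_index[candidate][ord],
    score = unname(scores),
    tied = duplicated(scores) | duplicated(scores, fromLast = TRUE)
  )
  utils::head(out, top_k)
}
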