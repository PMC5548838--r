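#' Interaction profiles of one side of the network
#'
#' The interaction profile IP(x) of a microbe is its row of the adjacency
#' matrix Y (its 0/1 association vector over all diseases); for a disease
#' it is the column of Y, returned as a row.
#'
#' @param network An `mda_network`.
#' @param side `"microbe"` or `"disease"`.
#' @return An integer 0/1 matrix, one profile per row, with entity names as
#'   rownames and attribute `side`.
#' @export
interaction_profiles <- function(network, side = c("microbe", "disease")) {
  side <- match.arg(side)
  stopifnot(inherits(network, "mda_network"))
  P <- if (side == "microbe") network$Y else t(network$Y)
  attr(P, "side") <- side
  P
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The effective bandwidth gamma is the raw bandwidth gamma' normalized by
#' the mean squared profile norm, `gamma = gamma' / mean(||IP_i||^2)`. For
#' 0/1 profiles `||IP_i||^2` is the degree of entity i, so the denominator
#' is the mean number of known associations per entity.
#'
#' @param profiles A 0/1 profile matrix from [interaction_profiles()].
#' @param gamma_prime Raw bandwidth, positive; default 1.
#' @return A list of class `gip_bandwidth` with elements `gamma` and
#'   `gamma_prime`.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  stopifnot(is.numeric(gamma_prime), length(gamma_prime) == 1L,
            gamma_prime > 0)
  mean_sq_norm <- mean(rowSums(profiles^2))
  if (mean_sq_norm == 0) {
    stop("bandwidth undefined: every interaction profile is zero",
         call. = FALSE)
  }
  structure(list(gamma = gamma_prime / mean_sq_norm,
                 gamma_prime = gamma_prime),
            class = "gip_bandwidth")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `K[i, j] = exp(-gamma * ||IP_i - IP_j||^2)`: entities whose association
#' vectors are close in squared Euclidean (for 0/1 profiles, Hamming)
#' distance are similar. Individual all-zero profiles are allowed (their
#' distances remain defined); only an all-zero profile *set* makes the
#' bandwidth undefined.
#'
#' @param profiles A 0/1 profile matrix from [interaction_profiles()].
#' @param bandwidth A `gip_bandwidth`, default computed from `profiles`
#'   with `gamma_prime = 1`.
#' @return A symmetric matrix of class `gip_kernel` with unit diagonal,
#'   entity names on both dimnames, and attributes `side` and `bandwidth`.
#' @examples
#' net <- as_mda_network(rbind(c(1, 0), c(0, 1)))
#' gip_kernel(interaction_profiles(net, "microbe"))
#' @export
gip_kernel <- function(profiles, bandwidth = gip_bandwidth(profiles)) {
  stopifnot(inherits(bandwidth, "gip_bandwidth"),
            is.finite(bandwidth$gamma), bandwidth$gamma > 0)
  P <- profiles
  storage.mode(P) <- "double"
  sq <- rowSums(P^2)
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2<a,b>, clipped against rounding
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  K <- exp(-bandwidth$gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  structure(K, side = attr(profiles, "side"), bandwidth = bandwidth,
            class = c("gip_kernel", "matrix", "array"))
}

#' One-call GIP similarity for a network side
#'
#' @inheritParams interaction_profiles
#' @param gamma_prime Raw bandwidth, default 1.
#' @return A `gip_kernel` matrix (nm x nm for microbes, nd x nd for
#'   diseases).
#' @export
gip_similarity <- function(network, side = c("microbe", "disease"),
                           gamma_prime = 1) {
  P <- interaction_profiles(network, side)
  gip_kernel(P, gip_bandwidth(P, gamma_prime))
}

#' Export a kernel (or any named square matrix) as dense TSV
#'
#' @param K A matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_kernel <- function(K, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(K)), rownames = "name")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
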