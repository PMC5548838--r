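#' Random bipartite association network
#'
#' Independent Bernoulli(density) edges between `nm` microbes and `nd`
#' diseases, mimicking the size and sparsity of a curated genus-level
#' microbe-disease catalogue (the defaults reproduce a 292 x 39 network
#' with about 483 associations). Every row and column is guaranteed at
#' least one edge: empty lines are repaired by adding one uniformly placed
#' edge each, for at most 100 rounds.
#'
#' @param nm,nd Numbers of microbes and diseases (>= 2).
#' @param density Expected fraction of 1s, in (0, 1).
#' @param seed Integer seed; identical arguments give bit-identical
#'   networks.
#' @return An `mda_network` with attribute `fixture_spec` recording the
#'   generating parameters.
#' @examples
#' net <- random_bipartite(20, 8, density = 0.1, seed = 1)
#' network_summary(net)
#' @export
random_bipartite <- function(nm = 292, nd = 39, density = 483 / (292 * 39),
                             seed = 1) {
  stopifnot(nm >= 2, nd >= 2, density > 0, density < 1)
  Y <- withr::with_seed(as.integer(seed), {
    Y <- matrix(stats::rbinom(nm * nd, 1L, density), nm, nd)
    repair_empty_lines(Y)
  })
  net <- as_mda_network(Y)
  attr(net, "fixture_spec") <- list(nm = nm, nd = nd, density = density,
                                    n_blocks = 1L, seed = as.integer(seed))
  net
}

#' Planted co-cluster bipartite network
#'
#' Microbes and diseases are partitioned into `n_blocks` co-clusters;
#' pairs inside the same co-cluster connect with probability `p_in`,
#' across co-clusters with `p_out`. This plants the structure the model
#' exploits: entities sharing a block share many associations, so their
#' interaction-profile similarity is high. With `p_in = p_out` the result
#' is indistinguishable from [random_bipartite()].
#'
#' @inheritParams random_bipartite
#' @param n_blocks Number of co-clusters, `<= min(nm, nd)`.
#' @param p_in,p_out Within/between-block edge probabilities,
#'   `0 <= p_out <= p_in <= 1`. The defaults (8 co-clusters, p_in = 0.35,
#'   p_out = 0.004) give an expected density of about 0.047 -- the sparsity
#'   of real genus-level catalogues -- while keeping the expected
#'   within-block degree near 2, the minimum at which entities share
#'   associations often enough for interaction-profile similarity to carry
#'   signal.
#' @return An `mda_network` with attributes `microbe_block`,
#'   `disease_block` (integer block labels) and `fixture_spec`.
#' @export
planted_block_network <- function(nm = 292, nd = 39, n_blocks = 8,
                                  p_in = 0.35, p_out = 0.004, seed = 1) {
  stopifnot(nm >= 2, nd >= 2, n_blocks >= 1, n_blocks <= min(nm, nd),
            p_out >= 0, p_in >= p_out, p_in <= 1, p_in > 0)
  res <- withr::with_seed(as.integer(seed), {
    mb <- sort(rep_len(seq_len(n_blocks), nm))
    db <- sort(rep_len(seq_len(n_blocks), nd))
    P <- matrix(p_out, nm, nd)
    P[outer(mb, db, "==")] <- p_in
    Y <- matrix(stats::rbinom(nm * nd, 1L, as.vector(P)), nm, nd)
    list(Y = repair_empty_lines(Y), mb = mb, db = db)
  })
  net <- as_mda_network(res$Y)
  attr(net, "microbe_block") <- res$mb
  attr(net, "disease_block") <- res$db
  attr(net, "fixture_spec") <- list(nm = nm, nd = nd, n_blocks = n_blocks,
                                    p_in = p_in, p_out = p_out,
                                    seed = as.integer(seed))
  net
}

# add one uniform edge to every empty row/column; cap the repair loop so
# pathologically sparse requests fail loudly instead of spinning
repair_empty_lines <- function(Y, max_rounds = 100L) {
  for (round in seq_len(max_rounds)) {
    er <- which(rowSums(Y) == 0L)
    ec <- which(colSums(Y) == 0L)
    if (length(er) == 0L && length(ec) == 0L) return(Y)
    for (i in er) Y[i, sample.int(ncol(Y), 1L)] <- 1L
    for (j in ec) Y[sample.int(nrow(Y), 1L), j] <- 1L
  }
  if (any(rowSums(Y) == 0L) || any(colSums(Y) == 0L)) {
    stop("could not repair empty rows/columns within ", max_rounds,
         " rounds; density too low for the requested size", call. = FALSE)
  }
  Y
}
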