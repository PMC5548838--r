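#' Read a microbe-disease association table
#'
#' Reads a delimited text file (TSV by default, CSV auto-detected from the
#' extension or forced via `delim`) listing one known microbe-disease
#' association per row, and returns it as a validated association tibble.
#'
#' Names are normalized by stripping surrounding whitespace and collapsing
#' internal runs of whitespace; matching is otherwise exact and
#' case-preserving. Rows with a blank microbe or disease name are skipped
#' with a warning that lists their row numbers.
#'
#' @param file Path to a delimited text file with a header row.
#' @param microbe_col,disease_col Names of the columns holding the microbe
#'   and disease labels.
#' @param delim Field delimiter. `NULL` (default) picks `","` for `.csv`
#'   files and `"\t"` otherwise.
#' @return A tibble of class `mda_associations` with columns `microbe` and
#'   `disease`, one row per input row (in input order, skipped rows
#'   removed), and attributes `n_raw` (rows read), `n_distinct` (distinct
#'   pairs) and `n_skipped`.
#' @seealso [association_table()] for in-memory data frames,
#'   [build_adjacency()] for the 0/1 network.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("microbe\tdisease", "Pseudomonas\tasthma",
#'              "Lactobacillus\tasthma"), tf)
#' read_associations(tf)
#' @export
read_associations <- function(file, microbe_col = "microbe",
                              disease_col = "disease", delim = NULL) {
  if (!file.exists(file)) {
    stop("association file not found: ", file, call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(file, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, trim_ws = FALSE)
  if (nrow(df) == 0L) {
    stop("empty association table: ", file, call. = FALSE)
  }
  association_table(df, microbe_col = microbe_col, disease_col = disease_col)
}

#' Build an association table from a data frame
#'
#' Validates and normalizes an in-memory data frame of microbe-disease
#' pairs. This is the entry point [read_associations()] delegates to.
#'
#' @param df A data frame with at least the two mapped columns.
#' @param microbe_col,disease_col Column names for microbe and disease
#'   labels.
#' @return A tibble of class `mda_associations`; see [read_associations()].
#' @export
association_table <- function(df, microbe_col = "microbe",
                              disease_col = "disease") {
  missing_cols <- setdiff(c(microbe_col, disease_col), names(df))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in association table: ",
         paste(missing_cols, collapse = ", "),
         " (available: ", paste(names(df), collapse = ", "), ")",
         call. = FALSE)
  }
  n_raw <- nrow(df)
  if (n_raw == 0L) stop("empty association table", call. = FALSE)

  microbe <- normalize_name(as.character(df[[microbe_col]]))
  disease <- normalize_name(as.character(df[[disease_col]]))
  blank <- !nzchar(microbe) | !nzchar(disease) | is.na(microbe) | is.na(disease)
  if (any(blank)) {
    warning(sum(blank), " row(s) with a blank microbe or disease name ",
            "skipped (rows ", paste(which(blank), collapse = ", "), ")",
            call. = FALSE)
  }
  out <- tibble::tibble(microbe = microbe[!blank], disease = disease[!blank])
  if (nrow(out) == 0L) {
    stop("no usable rows: every row had a blank name", call. = FALSE)
  }
  structure(out,
            n_raw = n_raw,
            n_distinct = nrow(dplyr::distinct(out, .data$microbe, .data$disease)),
            n_skipped = sum(blank),
            class = c("mda_associations", class(out)))
}

# strip surrounding whitespace, collapse internal runs
normalize_name <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

#' @export
print.mda_associations <- function(x, ...) {
  cat("Microbe-disease association table: ",
      attr(x, "n_raw"), " raw rows, ",
      attr(x, "n_distinct"), " distinct pairs",
      if (attr(x, "n_skipped") > 0L)
        paste0(" (", attr(x, "n_skipped"), " skipped)"),
      "\n", sep = "")
  NextMethod()
}

#' Build the bipartite 0/1 adjacency network
#'
#' Turns an association table into the nm x nd adjacency matrix Y consumed
#' by the model: `Y[i, j] = 1` iff microbe i is known to be associated with
#' disease j. Duplicate rows collapse to a single edge, so `sum(Y)` equals
#' the number of distinct pairs.
#'
#' @param assoc An `mda_associations` tibble (or any data frame with
#'   `microbe` and `disease` columns).
#' @param ordering How to order the microbe/disease indexes: first
#'   appearance in the table (default) or lexicographic. Rankings are
#'   invariant to this choice; it only fixes row/column order.
#' @return An object of class `mda_network`: a list with the 0/1 matrix
#'   `Y` (named rows = microbes, columns = diseases), `microbe_index`,
#'   `disease_index`, dimensions `nm`, `nd`, the provenance counts
#'   `n_raw`/`n_distinct`, and the `ordering` used.
#' @examples
#' assoc <- tibble::tibble(microbe = c("m1", "m2"), disease = c("d1", "d2"))
#' build_adjacency(assoc)$Y
#' @export
build_adjacency <- function(assoc, ordering = c("first", "lexicographic")) {
  ordering <- match.arg(ordering)
  if (!all(c("microbe", "disease") %in% names(assoc))) {
    assoc <- association_table(assoc)
  }
  pairs <- dplyr::distinct(tibble::as_tibble(assoc)[c("microbe", "disease")])
  if (nrow(pairs) == 0L) stop("association table has no pairs", call. = FALSE)

  microbe_index <- unique(pairs$microbe)
  disease_index <- unique(pairs$disease)
  if (ordering == "lexicographic") {
    microbe_index <- sort(microbe_index)
    disease_index <- sort(disease_index)
  }
  Y <- matrix(0L, length(microbe_index), length(disease_index),
              dimnames = list(microbe_index, disease_index))
  Y[cbind(match(pairs$microbe, microbe_index),
          match(pairs$disease, disease_index))] <- 1L

  n_raw <- attr(assoc, "n_raw")
  structure(list(
    Y = Y,
    microbe_index = microbe_index,
    disease_index = disease_index,
    nm = length(microbe_index),
    nd = length(disease_index),
    n_raw = if (is.null(n_raw)) nrow(assoc) else n_raw,
    n_distinct = nrow(pairs),
    ordering = ordering
  ), class = "mda_network")
}

#' Wrap an existing 0/1 matrix as an association network
#'
#' @param Y A 0/1 matrix, rows = microbes, columns = diseases. Dimnames are
#'   used as indexes when present; default labels `m1..` / `d1..` otherwise.
#' @return An `mda_network`.
#' @export
as_mda_network <- function(Y) {
  Y <- as.matrix(Y)
  stopifnot(all(Y %in% c(0, 1)))
  storage.mode(Y) <- "integer"
  if (is.null(rownames(Y))) rownames(Y) <- paste0("m", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("d", seq_len(ncol(Y)))
  structure(list(
    Y = Y, microbe_index = rownames(Y), disease_index = colnames(Y),
    nm = nrow(Y), nd = ncol(Y), n_raw = sum(Y), n_distinct = sum(Y),
    ordering = "first"
  ), class = "mda_network")
}

#' @export
print.mda_network <- function(x, ...) {
  cat("Bipartite microbe-disease network\n",
      "  microbes:     ", x$nm, "\n",
      "  diseases:     ", x$nd, "\n",
      "  associations: ", sum(x$Y), " (density ",
      signif(mean(x$Y), 3), ")\n", sep = "")
  invisible(x)
}

#' @method as_tibble mda_network
#' @export
as_tibble.mda_network <- function(x, ...) {
  idx <- which(x$Y == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(microbe = x$microbe_index[idx[, 1L]],
                 disease = x$disease_index[idx[, 2L]])
}

#' Summarize a network
#'
#' @param network An `mda_network`.
#' @return A one-row tibble with `nm`, `nd`, `n_associations`, `density`,
#'   and summary statistics of the per-microbe and per-disease degree
#'   distributions.
#' @seealso [node_degrees()] for the full degree distributions.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "mda_network"))
  md <- rowSums(network$Y)
  dd <- colSums(network$Y)
  tibble::tibble(
    nm = network$nm, nd = network$nd,
    n_associations = sum(network$Y),
    density = mean(network$Y),
    microbe_degree_mean = mean(md), microbe_degree_max = max(md),
    disease_degree_mean = mean(dd), disease_degree_max = max(dd)
  )
}

#' Per-entity degrees of a network
#'
#' @param network An `mda_network`.
#' @return A tibble with columns `side` ("microbe"/"disease"), `name`,
#'   `degree`.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "mda_network"))
  dplyr::bind_rows(
    tibble::tibble(side = "microbe", name = network$microbe_index,
                   degree = unname(rowSums(network$Y))),
    tibble::tibble(side = "disease", name = network$disease_index,
                   degree = unname(colSums(network$Y)))
  )
}

#' Write a network as an edge list or dense matrix
#'
#' `write_edge_list()` writes a two-column `microbe<TAB>disease` TSV in the
#' same dialect [read_associations()] reads (round-trip safe).
#' `write_adjacency()` writes the dense 0/1 matrix with row and column
#' headers.
#'
#' @param network An `mda_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "mda_network"))
  readr::write_tsv(as_tibble.mda_network(network), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_adjacency <- function(network, path) {
  stopifnot(inherits(network, "mda_network"))
  df <- tibble::as_tibble(as.data.frame(network$Y), rownames = "microbe")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
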