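## Network-parameter panel on the simple undirected graph: degrees and
## <k>, average path length L, clustering coefficient C, density ND and
## degree centralization NC.  Implementations are sparse-matrix based so
## that corpora-scale networks (N of a few thousand) stay fast; an
## independent brute-force oracle lives in the test suite.

#' Degree statistics
#'
#' Degrees count distinct incident edges; multiplicities are ignored.
#'
#' @param network A `syntactic_network`.
#' @return List with `k` (named degree vector), `k_mean` (`<k>` = sum of
#'   degrees / N = 2M/N) and `k_max`.
#' @export
degree_stats <- function(network) {
  if (network$N == 0) stop_validation("empty network")
  k <- degree_vector(network)
  names(k) <- network$vertices
  list(k = k, k_mean = sum(k) / network$N, k_max = max(k))
}

#' Average path length
#'
#' Geodesic distances by breadth-first search from every vertex.  `L` is
#' the mean distance over unordered vertex pairs.  On disconnected
#' networks the default averages over reachable pairs only (the convention
#' of standard network tools, keeping `L` finite); `mode = "all_pairs"`
#' follows the textbook formula dividing by N(N-1)/2 and errors when any
#' pair is unreachable; `mode = "largest_component"` restricts to the
#' largest connected component.
#'
#' @param network A `syntactic_network` with at least 2 vertices.
#' @param mode `"reachable"` (default), `"all_pairs"` or
#'   `"largest_component"`.
#' @param keep_distances Also return the full distance matrix (`Inf` for
#'   unreachable pairs); only sensible for small networks.
#' @return List with `L`, `reachable_pairs`, `unreachable_pairs`,
#'   `component_count`, `largest_component_fraction` and (optionally)
#'   `distances`.
#' @export
average_path_length <- function(network,
                                mode = c("reachable", "all_pairs",
                                         "largest_component"),
                                keep_distances = FALSE) {
  mode <- match.arg(mode)
  if (network$N < 2) stop_validation("need at least 2 vertices")
  if (network$M == 0) stop_validation("network has no edges")
  n <- network$N
  st <- bfs_all_stats(n, network$edges$i, network$edges$j)
  reach_ordered <- st$reach_ordered
  reachable_pairs <- reach_ordered / 2
  all_pairs <- n * (n - 1) / 2
  unreachable_pairs <- all_pairs - reachable_pairs
  comp_sizes <- tabulate(st$comp + 1L, nbins = st$ncomp)
  L <- switch(mode,
    reachable = st$dist_sum / reach_ordered,
    all_pairs = {
      if (unreachable_pairs > 0)
        stop_validation(
          "network is disconnected: %d unreachable pair(s) give infinite distance under all_pairs mode",
          unreachable_pairs)
      st$dist_sum / (2 * all_pairs)
    },
    largest_component = {
      big <- which.max(comp_sizes) - 1L
      keep <- which(st$comp == big)
      sel <- network$edges$i %in% keep     # both endpoints share a component
      relab <- match(seq_len(n), keep)
      st2 <- bfs_all_stats(length(keep),
                           relab[network$edges$i[sel]],
                           relab[network$edges$j[sel]])
      st2$dist_sum / st2$reach_ordered
    })
  out <- list(L = L,
              reachable_pairs = reachable_pairs,
              unreachable_pairs = unreachable_pairs,
              component_count = st$ncomp,
              largest_component_fraction = max(comp_sizes) / n)
  if (keep_distances)
    out$distances <- bfs_dist_matrix(n, network$edges$i, network$edges$j)
  out
}

#' Geodesic distance between two named vertices
#'
#' @param network A `syntactic_network`.
#' @param from,to Vertex labels (word types).
#' @return Edge count of the shortest path (`Inf` if unreachable).
#' @export
geodesic_distance <- function(network, from, to) {
  i <- match(from, network$vertices)
  j <- match(to, network$vertices)
  if (is.na(i) || is.na(j))
    stop_validation("vertex not in network: %s",
                    paste(c(from, to)[is.na(c(i, j))], collapse = ", "))
  if (i == j) return(0)
  adj <- adjacency_list(network)
  dist <- rep(Inf, network$N)
  dist[i] <- 0
  frontier <- i
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- d
    if (is.finite(dist[j])) return(dist[j])
    frontier <- nxt
  }
  dist[j]
}

adjacency_list <- function(network) {
  ii <- c(network$edges$i, network$edges$j)
  jj <- c(network$edges$j, network$edges$i)
  split(jj, factor(ii, levels = seq_len(network$N)))
}

#' Clustering coefficients
#'
#' Local coefficient `C_i = 2 E_i / (k_i (k_i - 1))`, where `E_i` counts
#' edges among the neighbors of `i`; vertices of degree < 2 contribute
#' `C_i = 0`.  The network coefficient `C` is the unweighted mean of `C_i`
#' over all N vertices.
#'
#' @param network A `syntactic_network`.
#' @return List with `C_i` (named vector), `E_i` (named vector) and `C`.
#' @export
clustering <- function(network) {
  if (network$N == 0) stop_validation("empty network")
  A <- adjacency_matrix(network)
  k <- degree_vector(network)
  ## (A %*% A)_{ij} counts common neighbors of i and j; masking by A and
  ## summing rows counts each neighbor-neighbor edge twice.
  E2 <- Matrix::rowSums((A %*% A) * A)
  E_i <- E2 / 2
  denom <- k * (k - 1)
  C_i <- ifelse(denom > 0, 2 * E_i / denom, 0)
  names(C_i) <- names(E_i) <- network$vertices
  list(C_i = C_i, E_i = E_i, C = mean(C_i))
}

#' Network density and degree centralization
#'
#' Density `ND = M / (N(N-1)/2)` is the realized fraction of possible
#' edges.  Degree centralization `NC` measures the dominance of the
#' highest-degree vertex: the exact form is
#' `(N/(N-1)) * (k_max/(N-1) - ND)`; the approximate form `k_max/N - ND`
#' is also provided.
#'
#' @param network A `syntactic_network` with N >= 2.
#' @param form `"exact"` (default) or `"approximate"`.
#' @return List with `ND`, `NC` and `form_used`.
#' @export
density_centralization <- function(network, form = c("exact", "approximate")) {
  form <- match.arg(form)
  n <- network$N
  if (n < 2) stop_validation("need at least 2 vertices")
  nd <- network$M / (n * (n - 1) / 2)
  k_max <- max(degree_vector(network))
  nc <- switch(form,
    exact = (n / (n - 1)) * (k_max / (n - 1) - nd),
    approximate = k_max / n - nd)
  list(ND = nd, NC = nc, form_used = form)
}

#' Assemble one row of the per-corpus metric panel
#'
#' Combines all panel statistics into one row mirroring the standard
#' report layout: the power-law exponent of the cumulative degree
#' distribution and its fit R2, then `<k>`, `C`, `L`, `ND`, `NC`, plus
#' provenance columns (label, modality, level, N, M, token count).
#' Values are kept in double precision; rounding (half-to-even, 3
#' decimals) happens only at serialization time in [write_metrics_table()].
#'
#' @param network A `syntactic_network`.
#' @param meta A [corpus_meta()]; may carry `NA` fields.
#' @param fit A power-law fit from [fit_power_law()], or `NULL` to leave
#'   the fit columns `NA`.
#' @param token_count Token count of the source treebank (`NA` if unknown).
#' @param l_mode Path-length mode, see [average_path_length()].
#' @param nc_form Centralization form, see [density_centralization()].
#' @return A one-row data.frame.
#' @export
compute_metrics_row <- function(network, meta = corpus_meta(), fit = NULL,
                                token_count = NA_integer_,
                                l_mode = "reachable", nc_form = "exact") {
  ds <- degree_stats(network)
  cl <- clustering(network)
  pl <- average_path_length(network, mode = l_mode)
  dc <- density_centralization(network, form = nc_form)
  data.frame(
    label = meta$label, modality = meta$modality, level = meta$level,
    N = network$N, M = network$M, tokens = as.integer(token_count),
    gamma_prime = if (is.null(fit)) NA_real_ else fit$gamma_prime,
    fit_R2 = if (is.null(fit)) NA_real_ else fit$R2,
    k_mean = ds$k_mean, C = cl$C, L = pl$L, ND = dc$ND, NC = dc$NC,
    stringsAsFactors = FALSE)
}

#' Write a metrics table as TSV, rounded for reporting
#'
#' Numeric panel columns are rounded half-to-even to `digits` decimals.
#'
#' @param rows A data.frame of metric rows ([compute_metrics_row()]).
#' @param path Output TSV path.
#' @param digits Decimals for the panel columns (default 3).
#' @export
write_metrics_table <- function(rows, path, digits = 3) {
  out <- rows
  for (col in c("gamma_prime", "fit_R2", "k_mean", "C", "L", "ND", "NC"))
    if (col %in% names(out)) out[[col]] <- round(out[[col]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table (TSV) into the panel schema
#'
#' @param path TSV with at least the columns `label`, `modality`, `level`
#'   and the panel columns `gamma_prime`, `fit_R2`, `k_mean`, `C`, `L`,
#'   `ND`, `NC`.
#' @return A data.frame.
#' @export
read_metrics_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(level = "character"))
  needed <- c("label", "modality", "level",
              "gamma_prime", "k_mean", "C", "L", "ND", "NC")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop_validation("metrics table lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
  tab
}
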