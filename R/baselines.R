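## Matched random-graph null model and the small-world decision rule.
## The null is the uniform G(N, M) graph: it matches the two moments the
## observed panel reports (vertex and edge counts), and its clustering and
## path length have the familiar closed-form limits C ~ <k>/N and
## L ~ ln N / ln <k>.

#' Uniform G(N, M) random graph
#'
#' Draws a simple undirected graph with exactly `N` labeled vertices and
#' `M` distinct edges, uniformly over all such graphs, reproducibly per
#' seed.  Vertices are labeled `v1..vN`.
#'
#' @param N Vertex count.
#' @param M Edge count, `0 <= M <= N(N-1)/2`.
#' @param seed RNG seed (caller's RNG state is restored).
#' @return A `syntactic_network`.
#' @export
generate_gnm <- function(N, M, seed = NULL) {
  max_m <- N * (N - 1) / 2
  if (M < 0 || M > max_m)
    stop_validation("M = %d out of range 0..%d for N = %d", M, max_m, N)
  idx <- with_seed(seed, sample.int(max_m, M))
  ## map linear pair index (lexicographic by i, then j) back to (i, j)
  cumstart <- c(0, cumsum((N - 1):1))      # pairs before row i = cumstart[i]
  i <- findInterval(idx - 1, cumstart, rightmost.closed = FALSE)
  j <- i + (idx - cumstart[i])
  ord <- order(i, j)
  edges <- data.frame(i = i[ord], j = j[ord], weight = 1L)
  new_syntactic_network(paste0("v", seq_len(N)), edges)
}

#' Ensemble summaries of matched random graphs
#'
#' Generates `reps` G(N, M) graphs and summarizes their clustering
#' coefficient and average path length with the same conventions as the
#' observed panel ([clustering()], [average_path_length()]), alongside the
#' closed-form expectations `C = <k>/N` and `L = ln N / ln <k>`.
#'
#' @param N,M Matched vertex and edge counts.
#' @param reps Ensemble size (default 30).
#' @param seed Base seed (default 0); replicate r uses `seed + r`.
#' @param metrics Which metrics to compute, subset of `c("L", "C")`.
#' @param l_mode Path-length mode for the replicates.
#' @return A `random_ensemble` list with per-metric mean/sd, the closed
#'   forms, the replicate values, and the generation parameters.
#' @export
ensemble_metrics <- function(N, M, reps = 30, seed = 0,
                             metrics = c("L", "C"), l_mode = "reachable") {
  stopifnot(reps >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  Ls <- Cs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    g <- generate_gnm(N, M, seed = seed + r)
    if ("C" %in% metrics) Cs[r] <- clustering(g)$C
    if ("L" %in% metrics) Ls[r] <- average_path_length(g, mode = l_mode)$L
  }
  k_mean <- 2 * M / N
  structure(list(
    model = "gnm", N = N, M = M, reps = reps, seed = seed,
    L_mean = mean(Ls), L_sd = if (reps > 1) sd(Ls) else 0,
    C_mean = mean(Cs), C_sd = if (reps > 1) sd(Cs) else 0,
    sd_degenerate = reps == 1,
    L_closed_form = log(N) / log(k_mean),
    C_closed_form = k_mean / N,
    L_values = Ls, C_values = Cs), class = "random_ensemble")
}

#' Small-world assessment against a matched random ensemble
#'
#' A network is deemed small-world when its clustering coefficient is far
#' above the matched random ensemble (`C_obs / C_mean >= tau_C`) while its
#' average path length is not above it (`L_obs / L_mean <= tau_L`).  The
#' default thresholds (5 and 1.2) are conservative relative to typical
#' corpus networks, whose C-ratios run an order of magnitude higher.
#'
#' @param obs A one-row metrics data.frame ([compute_metrics_row()]) with
#'   columns `N`, `M`, `C`, `L`.
#' @param ens A `random_ensemble` matched on `N` and `M`.
#' @param tau_C Clustering ratio threshold (default 5).
#' @param tau_L Path-length ratio threshold (default 1.2).
#' @return List with `c_ratio`, `l_ratio`, `is_small_world`, thresholds.
#' @export
assess_small_world <- function(obs, ens, tau_C = 5, tau_L = 1.2) {
  stopifnot(inherits(ens, "random_ensemble"))
  if (obs$N != ens$N || obs$M != ens$M)
    stop_validation("ensemble (N=%d, M=%d) does not match network (N=%d, M=%d)",
                    ens$N, ens$M, obs$N, obs$M)
  c_ratio <- obs$C / ens$C_mean
  l_ratio <- obs$L / ens$L_mean
  list(c_ratio = c_ratio, l_ratio = l_ratio,
       is_small_world = isTRUE(c_ratio >= tau_C && l_ratio <= tau_L),
       tau_C = tau_C, tau_L = tau_L)
}
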