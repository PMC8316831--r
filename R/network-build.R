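## Undirected word-type syntactic network.  Vertices are word types (NFC-
## normalized surface forms, or form/POS pairs in the off-default keying
## mode); edges are unordered type pairs with a multiplicity count.  All
## metrics treat the network as a simple graph; multiplicities survive only
## for Pajek export and diagnostics.

new_syntactic_network <- function(vertices, edges, build_log = list()) {
  stopifnot(all(edges$i >= 1), all(edges$j >= 1),
            all(edges$i <= length(vertices)), all(edges$j <= length(vertices)),
            all(edges$i < edges$j))
  structure(
    list(vertices = vertices, edges = edges,
         N = length(vertices), M = nrow(edges), build_log = build_log),
    class = "syntactic_network")
}

#' @export
print.syntactic_network <- function(x, ...) {
  cat(sprintf("<syntactic_network> N = %d vertices, M = %d edges\n",
              x$N, x$M))
  invisible(x)
}

#' Build the word-type syntactic network of a treebank
#'
#' Every dependency row whose governor order is >= 1 and whose two
#' endpoints are both non-punctuation contributes the unordered word-type
#' pair (dependent form, governor form).  Repeated pairs are merged with
#' their multiplicity counted; pairs whose two forms coincide (a type
#' depending on itself, e.g. reduplication) are dropped; root rows
#' contribute the dependent as a vertex but no edge, and the fictitious
#' root is never a vertex.  The result is the merged simple graph over the
#' whole treebank.
#'
#' @param tb A [treebank()].
#' @param key `"form"` (default: vertices are word forms) or `"form_pos"`
#'   (vertices are form/POS pairs, joined by `"/"`).
#' @param drop_punct Drop punctuation tokens (default `TRUE`; corpora in
#'   the intended use are already punctuation-free, so this is a no-op
#'   there).
#' @return A `syntactic_network` with a `build_log` listing dropped
#'   self-loop rows, dropped punctuation rows and multi-root sentences.
#' @export
build_network <- function(tb, key = c("form", "form_pos"),
                          drop_punct = TRUE) {
  key <- match.arg(key)
  tk <- tb$tokens
  if (nrow(tk) == 0) stop_validation("empty treebank")
  if (drop_punct && all(tk$is_punct)) stop_validation("no edges: all tokens are punctuation")

  keyed <- if (key == "form") tk$form else paste(tk$form, tk$pos, sep = "/")
  starts <- sentence_starts(tb)
  base <- starts[match(tk$sentence_id, tk$sentence_id[starts])]
  gov_idx <- ifelse(tk$governor_order == 0, NA_integer_,
                    base + tk$governor_order - 1L)

  usable <- if (drop_punct) !tk$is_punct else rep(TRUE, nrow(tk))
  dep_key <- keyed[usable]
  gidx <- gov_idx[usable]
  has_gov <- !is.na(gidx)
  gov_punct <- rep(FALSE, length(gidx))
  gov_punct[has_gov] <- tk$is_punct[gidx[has_gov]]
  gov_ok <- has_gov & !(drop_punct & gov_punct)
  n_punct_dropped <- sum(tk$is_punct) + sum(has_gov & !gov_ok)

  ## vertex set: every usable token's type, in order of first appearance
  vertices <- unique(dep_key)
  vid <- match(dep_key, vertices)
  gov_key <- rep(NA_character_, length(gidx))
  gov_key[gov_ok] <- keyed[gidx[gov_ok]]
  gvid <- match(gov_key, vertices)

  a <- vid[gov_ok]
  b <- gvid[gov_ok]
  self_loop <- a == b
  n_self <- sum(self_loop)
  a2 <- pmin(a[!self_loop], b[!self_loop])
  b2 <- pmax(a[!self_loop], b[!self_loop])
  if (length(a2)) {
    pair_key <- paste(a2, b2)
    first <- !duplicated(pair_key)
    agg <- table(factor(pair_key, levels = pair_key[first]))
    edges <- data.frame(i = a2[first], j = b2[first],
                        weight = as.integer(agg))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]  # canonical order
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), weight = integer(0))
  }

  root_counts <- tapply(tk$governor_order == 0, tk$sentence_id, sum)
  log <- list(self_loops_dropped = n_self,
              punct_rows_dropped = as.integer(n_punct_dropped),
              multi_root_sentences = sum(root_counts > 1),
              rootless_sentences = sum(root_counts == 0))
  new_syntactic_network(vertices, edges, build_log = log)
}

#' Highest-degree vertices
#'
#' Vertices ranked by degree (distinct incident edges) descending, ties
#' broken lexicographically by word type.  The degree share is the vertex
#' degree divided by the degree sum `2M`.
#'
#' @param network A `syntactic_network`.
#' @param n Number of hubs to return; if `n > N` all vertices are returned
#'   with a warning.
#' @return A data.frame with columns `word`, `degree`, `share`.
#' @export
top_hubs <- function(network, n = 5L) {
  if (network$N == 0) stop_validation("empty network")
  if (n < 1) stop_validation("n must be >= 1")
  if (n > network$N) {
    warn_syntnet("n = %d exceeds N = %d; returning all vertices",
                 n, network$N)
    n <- network$N
  }
  k <- degree_vector(network)
  ord <- order(-k, network$vertices, method = "radix")
  total <- sum(k)
  idx <- ord[seq_len(n)]
  data.frame(word = network$vertices[idx], degree = k[idx],
             share = if (total > 0) k[idx] / total else rep(NA_real_, n),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Integer degree vector (distinct incident edges; multiplicity ignored).
degree_vector <- function(network) {
  tabulate(c(network$edges$i, network$edges$j), nbins = network$N)
}

## Sparse symmetric 0/1 adjacency matrix.
adjacency_matrix <- function(network) {
  Matrix::sparseMatrix(
    i = c(network$edges$i, network$edges$j),
    j = c(network$edges$j, network$edges$i),
    x = 1, dims = c(network$N, network$N))
}
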