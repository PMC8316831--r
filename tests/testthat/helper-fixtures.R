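# Fixture builders used across the suite.  Everything is constructed in
# code; the only files on disk are the two tiny bundled corpora.

toy_path <- function(ext = "tsv") {
  system.file("extdata", paste0("table2_toy.", ext), package = "syntnet")
}

toy_treebank <- function() {
  read_dependency_table(toy_path())
}

toy_network <- function() {
  build_network(toy_treebank())
}

table4_path <- function() {
  system.file("extdata", "table4_metrics.tsv", package = "syntnet")
}

# Treebank from a compact sentence spec: each sentence is a data.frame
# with columns form, gov (0 = root), and optionally pos.
mk_treebank <- function(..., meta = corpus_meta()) {
  sents <- list(...)
  rows <- lapply(seq_along(sents), function(s) {
    sp <- sents[[s]]
    n <- nrow(sp)
    data.frame(
      sentence_id = paste0("s", s), order = seq_len(n), form = sp$form,
      pos = if ("pos" %in% names(sp)) sp$pos else "x",
      governor_order = sp$gov,
      relation = ifelse(sp$gov == 0, "HED", "DEP"),
      is_punct = if ("pos" %in% names(sp)) sp$pos %in% PUNCT_TAGS else FALSE,
      stringsAsFactors = FALSE)
  })
  treebank(do.call(rbind, rows), meta = meta, validate = FALSE)
}

# Network directly from an edge list over vertex labels: one two-token
# sentence per edge instance (governor = edges_to, dependent =
# edges_from); `weight` repeats an edge to raise its multiplicity.
mk_network <- function(edges_from, edges_to, weight = 1L) {
  stopifnot(length(edges_from) == length(edges_to))
  sents <- list()
  for (e in seq_along(edges_from)) {
    for (r in seq_len(if (length(weight) > 1) weight[e] else weight)) {
      sents[[length(sents) + 1L]] <-
        data.frame(form = c(edges_to[e], edges_from[e]), gov = c(0L, 1L))
    }
  }
  build_network(do.call(mk_treebank, sents))
}

# Absolute-tolerance comparison against a printed (rounded) value:
# `digits` is the precision of the printed number; the band is a padded
# half-ulp, so an exact recomputation of the unrounded quantity passes.
expect_near <- function(actual, printed, digits, pad = 1.2) {
  expect_lt(abs(actual - printed), pad * 0.5 * 10^(-digits))
}

level_code_test <- function(level) {
  suppressWarnings(ifelse(level == "native", 5, as.numeric(level)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Canonical per-edge labels (in edge order) for set comparisons.
key_pairs <- function(net) {
  e <- net$edges
  paste(pmin(net$vertices[e$i], net$vertices[e$j]),
        pmax(net$vertices[e$i], net$vertices[e$j]))
}

# Random Erdos-Renyi-style adjacency as a syntactic_network, for
# property tests (edge probability p, labels v1..vn).
random_small_network <- function(n, p) {
  a <- matrix(runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  idx <- which(a, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- cbind(1L, 2L)  # ensure at least one edge
  sents <- lapply(seq_len(nrow(idx)), function(e)
    data.frame(form = paste0("v", c(idx[e, 2], idx[e, 1])), gov = c(0L, 1L)))
  # include isolated vertices as single-token sentences
  present <- unique(as.vector(idx))
  for (v in setdiff(seq_len(n), present))
    sents[[length(sents) + 1L]] <- data.frame(form = paste0("v", v), gov = 0L)
  build_network(do.call(mk_treebank, sents))
}
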