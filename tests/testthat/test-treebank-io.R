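test_that("the bundled tabular fixture parses to 2 sentences / 8 tokens", {
  tb <- toy_treebank()
  expect_s3_class(tb, "treebank")
  expect_equal(n_sentences(tb), 2L)
  expect_equal(n_tokens(tb), 8L)
  expect_equal(tb$tokens$form[tb$tokens$sentence_id == "s2"],
               c("Ta", "Zai", "Xuexiao", "Kan", "Shu"))
  expect_equal(sum(tb$tokens$governor_order == 0), 2L)  # one root per sentence
})

test_that("tabular dialect errors are precise", {
  bad_cols <- tempfile(fileext = ".tsv")
  writeLines(c("s1\t1\tA\tx\t2\tB\tDEP", "s1\t2\tB\tx\t0\t_"), bad_cols)
  expect_error(read_dependency_table(bad_cols), "line 2.*7 columns",
               class = "syntnet_validation_error")

  empty <- tempfile(fileext = ".tsv")
  writeLines("# only a comment", empty)
  expect_error(read_dependency_table(empty), "no sentences",
               class = "syntnet_validation_error")

  # corrupted governor: s2 row 3 points at order 9
  lines <- readLines(toy_path())
  lines <- sub("^s2\t3\tXuexiao\tn\t2", "s2\t3\tXuexiao\tn\t9", lines)
  bad_gov <- tempfile(fileext = ".tsv")
  writeLines(lines, bad_gov)
  expect_error(read_dependency_table(bad_gov), "s2",
               class = "syntnet_validation_error")
})

test_that("governor-form mismatches are reported, not repaired", {
  lines <- readLines(toy_path())
  lines <- sub("s1\t1\tTa\tr\t2\tKan", "s1\t1\tTa\tr\t2\tWRONG", lines)
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  expect_warning(tb <- read_dependency_table(p), "mismatch")
  # the stored annotation still follows governor_order
  expect_equal(tb$tokens$governor_order[1], 2L)
})

test_that("HED/root labeling is enforced on the dialect, tolerated in CoNLL-U", {
  lines <- readLines(toy_path())
  lines <- sub("s1\t2\tKan\tv\t0\t_\tHED", "s1\t2\tKan\tv\t0\t_\troot", lines)
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  expect_error(read_dependency_table(p), "HED",
               class = "syntnet_validation_error")

  cl <- readLines(toy_path("conllu"))
  cl <- sub("2\tKan\t_\tv\t_\t_\t0\tHED", "2\tKan\t_\tv\t_\t_\t0\troot", cl)
  p2 <- tempfile(fileext = ".conllu")
  writeLines(cl, p2)
  expect_warning(tb <- read_conllu(p2), "root")
  expect_equal(tb$tokens$relation[2], "root")
})

test_that("CoNLL-U rendering equals the tabular fixture field-wise", {
  a <- toy_treebank()
  b <- read_conllu(toy_path("conllu"))
  cols <- c("order", "form", "pos", "governor_order", "relation")
  expect_equal(a$tokens[, cols], b$tokens[, cols])
})

test_that("CoNLL-U parse errors and tolerances", {
  p <- tempfile(fileext = ".conllu")
  writeLines(c("1\tA\t_\tx\t_\t_\tZ\tDEP\t_\t_"), p)
  expect_error(read_conllu(p), "HEAD", class = "syntnet_validation_error")

  writeLines(character(0), p)
  expect_error(read_conllu(p), "no sentences",
               class = "syntnet_validation_error")

  # two roots in one sentence: accepted with a warning
  writeLines(c("1\tA\t_\tx\t_\t_\t0\tHED\t_\t_",
               "2\tB\t_\tx\t_\t_\t0\tHED\t_\t_"), p)
  expect_warning(tb <- read_conllu(p), "multiple roots")
  expect_equal(n_tokens(tb), 2L)

  # multiword-token and empty-node lines are skipped
  writeLines(c("1-2\tAB\t_\t_\t_\t_\t_\t_\t_\t_",
               "1\tA\t_\tx\t_\t_\t2\tDEP\t_\t_",
               "1.1\tE\t_\t_\t_\t_\t_\t_\t_\t_",
               "2\tB\t_\tx\t_\t_\t0\tHED\t_\t_"), p)
  expect_silent(tb <- read_conllu(p))
  expect_equal(n_tokens(tb), 2L)
})

test_that("round trips are lossless, plain and gzipped", {
  tb <- toy_treebank()
  cols <- c("order", "form", "pos", "governor_order", "relation")
  for (ext in c(".tsv", ".tsv.gz")) {
    p <- tempfile(fileext = ext)
    write_dependency_table(tb, p)
    # silence also asserts the governor-form column was emitted correctly
    expect_silent(back <- read_dependency_table(p))
    expect_equal(back$tokens[, cols], tb$tokens[, cols])
  }
  p <- tempfile(fileext = ".conllu")
  write_conllu(tb, p)
  expect_equal(read_conllu(p)$tokens[, cols], tb$tokens[, cols])
})

test_that("Pajek export has the documented shape and survives a round trip", {
  net <- toy_network()
  p <- tempfile(fileext = ".net")
  write_pajek(net, p)
  lines <- readLines(p)
  expect_equal(lines[1], "*Vertices 5")
  edge_lines <- lines[(which(lines == "*Edges") + 1):length(lines)]
  expect_length(edge_lines, 4L)
  # the Ta-Kan edge carries multiplicity 2
  i_ta <- match("Ta", net$vertices); i_kan <- match("Kan", net$vertices)
  expect_true(sprintf("%d %d 2", min(i_ta, i_kan), max(i_ta, i_kan)) %in%
                edge_lines)
  back <- read_pajek(p)
  expect_equal(back$vertices, net$vertices)
  expect_equal(back$edges, net$edges)

  single <- mk_network("A", "B")
  p2 <- tempfile(fileext = ".net")
  write_pajek(single, p2)
  l2 <- readLines(p2)
  expect_equal(l2[1], "*Vertices 2")
  expect_equal(l2[length(l2)], "1 2 1")

  expect_error(write_pajek(build_network(mk_treebank(
    data.frame(form = "A", gov = 0L))), p2), NA)  # vertex-only net allowed
})
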