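test_that("variability counts residue types above the frequency floor", {
  expect_equal(column_variability("AAAA"), 1)
  expect_equal(column_variability("ACDE"), 4)
  rare <- paste0(strrep("A", 99), "C")
  expect_equal(column_variability(rare, min_freq = 0.02), 1)
  expect_equal(column_variability(rare, min_freq = 0.01), 2)
  # gaps excluded by default, countable on request
  expect_equal(column_variability("AA--"), 1)
  expect_equal(column_variability("AA--", include_gaps = TRUE), 2)
  v <- column_variability("----")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "undefined"))
  # pluggable definition
  expect_equal(column_variability("AACC", fun = function(p) sum(p^2)), 0.5)
})

test_that("entropy matches closed forms on the 0-100 scale", {
  expect_equal(column_entropy("ACDEFGHIKLMNPQRSTVWY"), 100,
               tolerance = 1e-12)
  expect_equal(column_entropy("AAAA"), 0)
  expect_equal(column_entropy(strrep("AC", 50)), 100 * log(2) / log(20),
               tolerance = 1e-12)
  # gaps and X are not counted
  expect_equal(column_entropy("AAXX--"), 0)
  e <- column_entropy("----")
  expect_true(is.na(e) && attr(e, "undefined"))
})

test_that("entropy and variability are frequency properties of the column", {
  set.seed(11)
  for (k in c(2, 7, 20)) {
    col <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][1:k],
                        200, replace = TRUE), collapse = "")
    perm <- paste(sample(strsplit(col, "")[[1]]), collapse = "")
    doubled <- paste0(col, col)
    expect_equal(column_entropy(perm), column_entropy(col))
    expect_equal(column_variability(perm), column_variability(col))
    expect_equal(column_entropy(doubled), column_entropy(col))
    expect_equal(column_variability(doubled), column_variability(col))
    expect_lte(column_variability(col),
               length(unique(strsplit(col, "")[[1]])))
    expect_lte(column_variability(col), 20)
    expect_true(column_entropy(col) >= 0 && column_entropy(col) <= 100)
  }
})

test_that("kolmogorov score is a deterministic bzip2 byte ratio", {
  const <- strrep("A", 10000)
  set.seed(5)
  rand <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       10000, replace = TRUE), collapse = "")
  expect_lt(column_kolmogorov(const), column_kolmogorov(rand))
  expect_identical(column_kolmogorov(rand), column_kolmogorov(rand))
  expect_equal(column_kolmogorov(rand) * nchar(rand),
               column_kolmogorov(rand, mode = "bytes"))
  expect_gt(column_kolmogorov(const), 0)
  expect_error(column_kolmogorov(""), "empty")
  expect_error(column_kolmogorov("ACD", level = 5), "level 9")
})

test_that("complexity_track scores every position and flags all-gap ones", {
  aln <- synth_msa(length = 5, n_seqs = 40, profile = c(1, 20), seed = 2)
  tr <- complexity_track(aln)
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$position, 1:5)
  expect_true(all(tr$flag == "ok"))

  gapped <- foldsignal:::new_msa(c("a", "b"), c("A-C", "A-C"))
  tr2 <- complexity_track(gapped)
  expect_equal(tr2$flag, c("ok", "allgap", "ok"))
  expect_true(is.na(tr2$ent[2]))
  expect_equal(tr2$var[2], 0)
  expect_false(is.na(tr2$kol[2])) # byte string still compressible
})

test_that("a conserved column scores below a uniform column in ENT and KOL", {
  aln <- synth_msa(length = 2, n_seqs = 500, profile = c(1, 20), seed = 9)
  tr <- complexity_track(aln)
  expect_lt(tr$ent[1], tr$ent[2])
  expect_lt(tr$kol[1], tr$kol[2])
})

test_that("permuting sequence order leaves ENT and VAR unchanged", {
  aln <- synth_msa(length = 6, n_seqs = 80, profile = c(3, 20), seed = 4)
  set.seed(1)
  perm <- sample(aln$n_seqs)
  shuffled <- foldsignal:::new_msa(aln$ids[perm], aln$rows[perm])
  t1 <- complexity_track(aln)
  t2 <- complexity_track(shuffled)
  expect_equal(t2$ent, t1$ent)
  expect_equal(t2$var, t1$var)
})

test_that("complexity TSV round-trips with '.' for undefined values", {
  gapped <- foldsignal:::new_msa(c("a", "b"), c("A-C", "A-C"))
  tr <- complexity_track(gapped)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_complexity_tsv(tr, tf)
  expect_match(readLines(tf)[3], "\\.")
  back <- read_complexity_tsv(tf)
  expect_equal(back$kol, tr$kol, tolerance = 1e-9)
  expect_true(is.na(back$ent[2]))
})
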