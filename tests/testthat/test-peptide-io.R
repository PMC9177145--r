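test_that("line-format peptide lists are read, validated and deduplicated", {
  f <- write_tmp_lines(c("GADGVGKSA", "GADGVGKSAL"))
  ps <- read_peptide_list(f, allotype = "C*08:02")
  expect_s3_class(ps, "peptide_set")
  expect_length(ps, 2L)
  expect_setequal(nchar(ps$peptides), c(9L, 10L))

  # duplicates collapse to one entry; case is normalised
  f2 <- write_tmp_lines(c("gadgvgksa", "GADGVGKSA", "GADGVGKSA"))
  expect_length(read_peptide_list(f2), 1L)

  # empty file warns and returns an empty set
  f3 <- write_tmp_lines(character(0))
  expect_warning(ps3 <- read_peptide_list(f3), "empty")
  expect_length(ps3, 0L)
})

test_that("invalid sequences raise a validation error naming the line", {
  f <- write_tmp_lines(c("GADGVGKSA", "GADGVGXSA", "GADGVGKSV"))
  expect_error(read_peptide_list(f), "line 2")
  expect_error(read_peptide_list(write_tmp_lines("SHORT")), "line 1")
  # drop mode removes them with a logged count instead
  expect_message(ps <- read_peptide_list(f, on_invalid = "drop"), "1 invalid")
  expect_length(ps, 2L)
  expect_error(read_peptide_list(tempfile("nope")), "cannot read")
})

test_that("csv peptide lists split by allotype and keep per-peptide sources", {
  f <- write_tmp_lines(c("allotype,peptide,source",
                         "C*08:02,GADGVGKSA,study1",
                         "C*08:02,AADGVGKSA,study2",
                         "C*05:01,GADGVGKSL,study1"), ext = ".csv")
  out <- read_peptide_list(f)
  expect_named(out, c("C*05:01", "C*08:02"))
  expect_length(out[["C*08:02"]], 2L)
  expect_identical(out[["C*08:02"]]$allotype$group, "C1")
  expect_identical(out[["C*05:01"]]$allotype$group, "C2")
})

test_that("merging is a set union: idempotent, commutative, allotype-checked", {
  al <- allotype_record("C*08:02", "S", "N")
  a <- peptide_set(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"), al, source = "s1")
  b <- peptide_set(c("CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"), al, source = "s2")
  m <- merge_peptide_sets(a, b)
  expect_length(m, 4L)
  expect_identical(merge_peptide_sets(b, a)$peptides, m$peptides)
  expect_identical(merge_peptide_sets(a, a)$peptides, a$peptides)
  expect_identical(merge_peptide_sets(a)$peptides, a$peptides)
  # shared sequences accumulate both source labels
  expect_identical(m$sources[m$peptides == "CCCCCCCCC"], "s1;s2")
  b2 <- peptide_set("EEEEEEEEE", allotype_record("C*05:01", "N", "K"))
  expect_error(merge_peptide_sets(a, b2), "different allotypes")
})

test_that("disjoint merges add sizes and re-merging is idempotent", {
  al <- allotype_record("C*08:02", "S", "N")
  x <- peptide_set(random_peptides(10, seed = 11), al)
  y <- peptide_set(setdiff(random_peptides(20, seed = 12), x$peptides), al)
  m1 <- merge_peptide_sets(x, y)
  expect_length(m1, length(x) + length(y))
  expect_identical(merge_peptide_sets(m1, m1)$peptides, m1$peptides)
})

test_that("unique/shared partition is disjoint and complete", {
  al8 <- allotype_record("C*08:02", "S", "N")
  al5 <- allotype_record("C*05:01", "N", "K")
  a <- peptide_set(c("AAAAAAAAA", "CCCCCCCCC", "SSSSSSSSS"), al8)
  b <- peptide_set(c("DDDDDDDDD", "SSSSSSSSS"), al5)
  p <- partition_unique_shared(a, b, length = 9L)
  expect_setequal(p$unique_a, c("AAAAAAAAA", "CCCCCCCCC"))
  expect_setequal(p$unique_b, "DDDDDDDDD")
  expect_setequal(p$shared, "SSSSSSSSS")

  # identical sets: both uniques empty
  p2 <- partition_unique_shared(a, peptide_set(a$peptides, al5), length = 9L)
  expect_length(p2$unique_a, 0L)
  expect_setequal(p2$shared, a$peptides)

  # brute-force completeness on random disjoint sets
  x <- unique(random_peptides(50, seed = 21))
  y <- setdiff(unique(random_peptides(70, seed = 22)), x)
  px <- partition_unique_shared(peptide_set(x, al8), peptide_set(y, al5), 9L)
  expect_length(px$shared, 0L)
  expect_identical(length(px$unique_a) + length(px$unique_b) + 2L * length(px$shared),
                   length(x) + length(y))
  expect_error(partition_unique_shared(a, b, length = 10L), "no 10-mer")
})

test_that("peptide sets round-trip through provenance CSV", {
  al <- allotype_record("C*08:02", "S", "N")
  ps <- peptide_set(c("AAAAAAAAA", "CCCCCCCCC"), al, source = "study1")
  f <- tempfile(fileext = ".csv")
  write_peptide_csv(ps, f)
  back <- read_peptide_list(f)
  expect_identical(back$peptides, ps$peptides)
  expect_identical(back$sources, ps$sources)
})
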