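test_that("negative-control MOTUs are deleted outright", {
  t <- toy_motu_table()
  t2 <- remove_control_motus(t)
  expect_equal(nrow(t2$counts), 4)
  expect_false("m4" %in% t2$motus$motu_id)
  # no flags -> identity
  t$motus$in_negative_control[] <- FALSE
  expect_equal(remove_control_motus(t)$motus$motu_id, t$motus$motu_id)
  # all flagged -> empty table with a warning
  t$motus$in_negative_control[] <- TRUE
  expect_warning(t3 <- remove_control_motus(t), "empty")
  expect_equal(nrow(t3$counts), 0)
})

test_that("similarity filter is strict-below-threshold with whitelisting", {
  t <- toy_motu_table()
  t$motus$best_similarity <- c(0.95, 0.96, 0.97, 1.0, 0.94)
  t$motus$whitelist <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  t2 <- filter_similarity(t, 0.96)
  # 0.95 removed, 0.96 exactly retained, whitelisted 0.94 retained
  expect_setequal(t2$motus$motu_id, c("m2", "m3", "m4", "m5"))
})

test_that("reporting-level assignment resolves species/genus/subfamily", {
  t <- remove_control_motus(toy_motu_table())
  t2 <- assign_reporting_level(t)
  a <- setNames(t2$motus$assigned_name, t2$motus$motu_id)
  r <- setNames(t2$motus$assigned_rank, t2$motus$motu_id)
  expect_equal(a[["m1"]], "Alces alces")
  expect_equal(r[["m1"]], "species")
  expect_equal(a[["m2"]], "Canis")
  expect_equal(r[["m2"]], "genus")
  expect_equal(a[["m3"]], "Arvicolinae")
  expect_equal(r[["m3"]], "subfamily")
  # candidates spanning two subfamilies are removed with a warning
  t$motus$candidates[1] <- "Myodes gapperi;Alces alces"
  expect_warning(t3 <- assign_reporting_level(t), "unassignable")
  expect_false("m1" %in% t3$motus$motu_id)
})

test_that("tag-jump filter zeroes sub-threshold cells per taxon and library", {
  # one taxon, one library of 3 samples, 10,000 reads total
  motus <- data.frame(motu_id = "m1", candidates = "Alces alces",
                      best_similarity = 0.99,
                      in_negative_control = FALSE, whitelist = FALSE,
                      stringsAsFactors = FALSE)
  counts <- matrix(c(9975L, 5L, 20L), 1, 3,
                   dimnames = list("m1", c("s1", "s2", "s3")))
  t <- motu_table(motus, counts, c(s1 = "L1", s2 = "L1", s3 = "L1"))
  t <- assign_reporting_level(t)
  t2 <- filter_tag_jumps(t, 0.001)
  # 5/10000 = 0.0005 < 0.001 -> zeroed; 20/10000 = 0.002 -> retained
  expect_equal(unname(t2$counts[1, ]), c(9975L, 0L, 20L))

  # single-sample library: frequency 1, always retained
  t1 <- motu_table(motus, matrix(3L, 1, 1, dimnames = list("m1", "q1")),
                   c(q1 = "LX"))
  t1 <- assign_reporting_level(t1)
  expect_equal(filter_tag_jumps(t1)$counts[1, 1], 3L)
})

test_that("tag-jump totals are a single snapshot, not recomputed iteratively", {
  # two cells just above/below threshold relative to the ORIGINAL total;
  # if totals were recomputed after the first removal the 12-read cell
  # (12/9992 > 0.001) would still pass, but a naive iterative scheme
  # could cascade; rule is one pass against the input totals
  motus <- data.frame(motu_id = "m1", candidates = "Alces alces",
                      best_similarity = 0.99,
                      in_negative_control = FALSE, whitelist = FALSE,
                      stringsAsFactors = FALSE)
  counts <- matrix(c(9980L, 8L, 12L), 1, 3,
                   dimnames = list("m1", c("s1", "s2", "s3")))
  t <- assign_reporting_level(
    motu_table(motus, counts, c(s1 = "L1", s2 = "L1", s3 = "L1")))
  t2 <- filter_tag_jumps(t, 0.001)
  expect_equal(unname(t2$counts[1, ]), c(9980L, 0L, 12L))
  # idempotence on its own output
  expect_equal(filter_tag_jumps(t2, 0.001)$counts, t2$counts)
})

test_that("binarisation pools congeneric MOTUs and uses volume as effort", {
  t <- toy_motu_table()
  t <- remove_control_motus(t)
  t <- assign_reporting_level(t)
  m <- to_detection_matrix(t, toy_samples())
  expect_true(all(m$y %in% 0:1))
  # counts (100,0,40,7) -> detections (1,0,1,1) for Alces alces
  expect_equal(unname(m$y["Alces alces", c("a1", "a2", "b1", "b2")]),
               c(1L, 0L, 1L, 1L))
  expect_equal(unname(m$effort[c("a1", "a2", "b1", "b2")]),
               c(30, 60, 80, 30))
  # sample missing from metadata -> error
  expect_error(to_detection_matrix(t, toy_samples(ids = c("a1", "a2", "b1"),
                                                  volume = c(30, 60, 80))),
               "absent")
})

test_that("congeneric MOTUs with counts 0 and 3 still yield a detection", {
  motus <- data.frame(motu_id = c("m1", "m2"),
                      candidates = c("Canis lupus;Canis latrans",
                                     "Canis lupus;Canis familiaris"),
                      best_similarity = 0.99, in_negative_control = FALSE,
                      whitelist = FALSE, stringsAsFactors = FALSE)
  counts <- matrix(c(0L, 3L), 2, 1, dimnames = list(c("m1", "m2"), "a1"))
  t <- assign_reporting_level(motu_table(motus, counts, c(a1 = "L1")))
  m <- to_detection_matrix(t, toy_samples(ids = "a1", volume = 30))
  expect_equal(unname(m$y["Canis", "a1"]), 1L)
})

test_that("the full filter chain is idempotent and non-increasing", {
  for (seed in 1:6) {
    t <- random_motu_table(seed = seed)
    t1 <- suppressWarnings(remove_control_motus(t))
    if (nrow(t1$counts) == 0) next
    t1 <- suppressWarnings(filter_similarity(t1, 0.96))
    if (nrow(t1$counts) == 0) next
    t1 <- suppressWarnings(assign_reporting_level(t1))
    if (nrow(t1$counts) == 0) next
    t2 <- filter_tag_jumps(t1, 0.001)
    # each filter never increases reads or MOTU count
    expect_lte(sum(t2$counts), sum(t$counts))
    expect_lte(nrow(t2$counts), nrow(t$counts))
    # applying the chain to its own output changes nothing
    t3 <- filter_tag_jumps(
      suppressWarnings(assign_reporting_level(
        filter_similarity(remove_control_motus(t2), 0.96))), 0.001)
    expect_equal(t3$counts, t2$counts)
    expect_equal(t3$motus$assigned_name, t2$motus$assigned_name)
  }
})

test_that("binarisation is invariant to scaling all counts", {
  t <- random_motu_table(seed = 11)
  t <- suppressWarnings(assign_reporting_level(
    filter_similarity(remove_control_motus(t), 0.96)))
  samples <- toy_samples(ids = colnames(t$counts),
                         volume = rep(30, ncol(t$counts)))
  m1 <- to_detection_matrix(filter_tag_jumps(t), samples)
  t$counts <- t$counts * 7L
  m2 <- to_detection_matrix(filter_tag_jumps(t), samples)
  expect_identical(m1$y, m2$y)
})

test_that("read retention reproduces printed percentages", {
  expect_equal(read_retention(12757213, 6310334), 49.5)
  expect_equal(read_retention(7641854, 4308349), 56.4)
  expect_error(read_retention(100, 200), "retained")
})

test_that("MOTU tables round-trip from disk", {
  t <- toy_motu_table()
  counts_path <- withr::local_tempfile(fileext = ".tsv")
  libs_path <- withr::local_tempfile(fileext = ".tsv")
  d <- cbind(t$motus, as.data.frame(t$counts))
  write.table(d, counts_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = names(t$library_of_sample),
                         library = unname(t$library_of_sample)),
              libs_path, sep = "\t", row.names = FALSE, quote = FALSE)
  t2 <- read_motu_table(counts_path, libs_path)
  expect_equal(t2$counts, t$counts)
  expect_equal(t2$motus$candidates, t$motus$candidates)
  expect_equal(t2$library_of_sample, t$library_of_sample)
})
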