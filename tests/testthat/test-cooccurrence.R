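y_nacl <- c(10, 9, 9, 5, 4, 3)

test_that("co-occurrence statistic reproduces the published presence/copy patterns", {
  expect_equal(round_half_away(pearson_cooccurrence(c(1, 1, 1, 0, 0, 0), y_nacl)), 0.97)
  expect_equal(round_half_away(pearson_cooccurrence(c(1, 1, 1, 1, 0, 0), y_nacl)), 0.81)
  expect_equal(round_half_away(pearson_cooccurrence(c(1, 1, 2, 0, 0, 0), y_nacl)), 0.84)
})

test_that("statistic edge cases: perfect correlation, zero variance, validation", {
  expect_identical(pearson_cooccurrence(y_nacl, y_nacl), 1)
  expect_true(is.na(pearson_cooccurrence(c(1, 1, 1, 1, 1, 1), y_nacl)))
  expect_error(pearson_cooccurrence(c(1, 0), c(1, 2)), "at least 3")
  expect_error(pearson_cooccurrence(c(1, 0, 1), c(1, 2)), "length mismatch")
  expect_error(pearson_cooccurrence(c(1, 0, 1), c(2, 2, 2)), "constant")
})

test_that("statistic agrees with stats::cor and is invariant to y rescaling and genome permutation", {
  set.seed(7)
  for (i in 1:50) {
    x <- sample(0:3, 6, replace = TRUE)
    if (var(x) == 0) next
    v <- pearson_cooccurrence(x, y_nacl)
    expect_equal(v, cor(x, y_nacl))
    expect_true(v >= -1 && v <= 1)
    # affine rescaling of the phenotype
    expect_equal(pearson_cooccurrence(x, 3.7 * y_nacl + 11), v)
    # permuting genomes together with y
    p <- sample(6)
    expect_equal(pearson_cooccurrence(x[p], y_nacl[p]), v)
  }
})

test_that("rounding is half-away-from-zero at two decimals", {
  expect_identical(round_half_away(c(0.975, -0.975, 0.8146, -0.8146, 0.845)),
                   c(0.98, -0.98, 0.81, -0.81, 0.85))
})

test_that("pattern enumeration is exhaustive, uniquely explains 0.97/0.81, and is antisymmetric", {
  tab <- enumerate_patterns(y_nacl, max_count = 1)
  expect_identical(nrow(tab), 63L)
  expect_false(anyDuplicated(tab$pattern) > 0)
  defined <- tab[!is.na(tab$value), ]
  expect_identical(defined$pattern[which.max(defined$value)], "1,1,1,0,0,0")
  expect_identical(defined$pattern[defined$value_2dp == 0.97], "1,1,1,0,0,0")
  expect_identical(defined$pattern[defined$value_2dp == 0.81], "1,1,1,1,0,0")
  # complement antisymmetry for every binary pattern
  pat <- do.call(rbind, lapply(strsplit(tab$pattern, ","), as.numeric))
  comp <- apply(1 - pat, 1, paste, collapse = ",")
  keep <- comp %in% tab$pattern
  expect_equal(tab$value[match(comp[keep], tab$pattern)], -tab$value[keep])
})

test_that("no binary pattern reaches 0.84, but copy-count patterns do", {
  bin <- enumerate_patterns(y_nacl, max_count = 1)
  expect_false(any(bin$value_2dp == 0.84, na.rm = TRUE))
  cnt <- enumerate_patterns(y_nacl, max_count = 2)
  expect_true("1,1,2,0,0,0" %in% cnt$pattern[which(cnt$value_2dp == 0.84)])
})

test_that("enumeration guards and the 3-point closed form hold", {
  expect_error(enumerate_patterns(rep(1, 9)), "length")
  expect_error(enumerate_patterns(y_nacl, max_count = 5), "max_count")
  tab <- enumerate_patterns(c(1, 2, 3), max_count = 1)
  expect_equal(tab$value[tab$pattern == "0,0,1"], sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(tab$value[tab$pattern == "1,0,0"], -sqrt(3) / 2, tolerance = 1e-12)
})

test_that("screen keeps strict exceedances, sidelines core rows, and orders like the published table", {
  m <- rbind(fam_a = c(1, 1, 1, 0, 0, 0),
             fam_b = c(1, 1, 1, 1, 0, 0),
             fam_c = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  scr <- screen_cooccurrence(m, y_nacl, threshold = 0.8)
  expect_identical(scr$pass$cluster_id, c("fam_a", "fam_b"))
  expect_identical(scr$pass$value_2dp, c(0.97, 0.81))
  expect_identical(scr$undefined$cluster_id, "fam_c")
  # strict threshold: a family exactly at the cutoff must not pass
  at <- pearson_cooccurrence(c(1, 1, 1, 1, 0, 0), y_nacl)
  expect_identical(nrow(screen_cooccurrence(m, y_nacl, threshold = at)$pass), 1L)
  # high cutoff and empty input
  expect_identical(nrow(screen_cooccurrence(m, y_nacl, threshold = 0.999)$pass), 0L)
  empty <- m[0, , drop = FALSE]
  expect_identical(nrow(screen_cooccurrence(empty, y_nacl)$pass), 0L)
  expect_error(screen_cooccurrence(m, y_nacl, threshold = 1.2), "threshold")
})

test_that("screen modes: binarization collapses copy number; absolute screening admits negatives", {
  m <- rbind(dup = c(1, 1, 2, 0, 0, 0), anti = c(0, 0, 0, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  counts <- screen_cooccurrence(m, y_nacl, mode = "counts")
  expect_identical(counts$pass$cluster_id, "dup")
  expect_identical(counts$pass$value_2dp, 0.84)
  binary <- screen_cooccurrence(m, y_nacl, mode = "binary")
  expect_identical(binary$pass$value_2dp, 0.97)   # (1,1,2,...) binarized
  absneg <- screen_cooccurrence(m, y_nacl, absolute = TRUE)
  expect_identical(absneg$pass$cluster_id, c("dup", "anti"))
  expect_identical(absneg$pass$value_2dp[2], -0.97)
})

test_that("screen value agrees with the enumeration oracle on every row", {
  set.seed(21)
  m <- matrix(sample(0:2, 60, replace = TRUE), nrow = 10,
              dimnames = list(paste0("Cluster_", 1:10), paste0("s", 1:6)))
  m[rowSums(m) == 0, 1] <- 1L
  tab <- enumerate_patterns(y_nacl, max_count = 2)
  lookup <- setNames(tab$value, tab$pattern)
  scr <- screen_cooccurrence(m, y_nacl, threshold = 0.8)
  for (i in seq_len(nrow(m))) {
    key <- paste(m[i, ], collapse = ",")
    expect_equal(scr$all$value[i], unname(lookup[key]))
  }
})

test_that("annotation join defaults to hypothetical protein and warns on unknown ids", {
  res <- data.frame(cluster_id = c("Cluster_1", "Cluster_2"),
                    stringsAsFactors = FALSE)
  out <- join_annotations(res)
  expect_identical(out$annotation, rep("hypothetical protein", 2))
  out <- join_annotations(res, c(Cluster_1 = "TauD/TfdA family dioxygenase"))
  expect_identical(out$annotation,
                   c("TauD/TfdA family dioxygenase", "hypothetical protein"))
  expect_warning(join_annotations(res, c(Cluster_9 = "x")), "unknown")
  # data-frame form, order preserved
  ann <- data.frame(cluster_id = "Cluster_2", annotation = "BCCT family transporter")
  expect_identical(join_annotations(res, ann)$annotation[2],
                   "BCCT family transporter")
})
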