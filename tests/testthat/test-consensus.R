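# convenience: a retained run over a character universe from minority sets
fake_run <- function(minorities, universe, label = "fake",
                     divergent = FALSE, k2 = FALSE) {
  majority <- setdiff(universe, unlist(minorities))
  part <- c(list(majority), lapply(minorities, as.character))
  rk <- data.frame(k = 2:3, rk = c(2, 1))
  attr(rk, "selected_k") <- 2L
  attr(rk, "divergent") <- divergent
  class(rk) <- c("rk_curve", "data.frame")
  scdrisk:::new_clustering_run(
    dataset_tag = "T", metric = list(metric = "fake"),
    linkage = list(criterion = "fake"), partition = part, rk = rk,
    universe = universe, label = label)
}

test_that("partitions_equal is label-invariant and an equivalence", {
  p <- list(c("a", "b"), c("c"))
  expect_true(partitions_equal(p, list(c("c"), c("b", "a"))))
  expect_false(partitions_equal(p, list(c("a"), c("b", "c"))))
  expect_true(partitions_equal(p, p))                       # reflexive
  expect_error(partitions_equal(p, list(c("a", "b"), c("d"))),
               "same universe")
  # symmetry and transitivity on random partitions
  set.seed(3)
  universe <- letters[1:8]
  rand_part <- function() unname(split(universe, sample(1:3, 8, TRUE)))
  for (i in 1:15) {
    p1 <- rand_part(); p2 <- rand_part(); p3 <- rand_part()
    expect_equal(partitions_equal(p1, p2), partitions_equal(p2, p1))
    if (partitions_equal(p1, p2) && partitions_equal(p2, p3))
      expect_true(partitions_equal(p1, p3))
  }
})

test_that("the default grid produces 24 runs and groups coincident ones", {
  catL <- catalog_subset(feature_catalog(), "L")
  spec <- default_risk_scenario(catL, n_total = 40, risk_fraction = 0.1,
                                seed = 77)
  norm <- minmax_normalize(generate_cohort(spec, catL)$cohort)
  runs <- run_grid(norm)
  expect_length(runs, 24L)
  labs <- vapply(runs, `[[`, character(1L), "label")
  expect_false(anyDuplicated(labs) > 0)
  # squared Euclidean is a monotone transform of Euclidean, so single
  # linkage produces the identical partition
  by_label <- setNames(runs, labs)
  expect_true(partitions_equal(by_label[["euclidean/single"]]$partition,
                               by_label[["squared-euclidean/single"]]$partition))
})

test_that("exclusion rules mirror the published decisions", {
  universe <- as.character(1:711)
  runs <- list(
    fake_run(list(as.character(1:332)), universe, "minority-332"),
    fake_run(list(as.character(1:78)), universe, "minority-78"),
    fake_run(list(as.character(1:37)), universe, "minority-37"),
    fake_run(list(as.character(1:5)), universe, "divergent-run",
             divergent = TRUE))
  out <- apply_exclusions(runs, max_minority_fraction = 0.10)
  expect_equal(vapply(out, `[[`, character(1L), "status"),
               c("excluded", "excluded", "retained", "excluded"))
  expect_equal(vapply(out, `[[`, character(1L), "exclusion_reason"),
               c("minority-too-large", "minority-too-large", "none",
                 "rk-divergent"))
})

test_that("different_subjects unions minorities and grows monotonically", {
  universe <- as.character(1:702)
  r1 <- fake_run(list(c("701", "702")), universe)
  expect_equal(different_subjects(list(r1)), c("701", "702"))
  r2 <- fake_run(list(c("10", "701")), universe)
  d1 <- different_subjects(list(r1))
  d12 <- different_subjects(list(r1, r2))
  expect_true(all(d1 %in% d12))
  expect_setequal(d12, c("10", "701", "702"))
})

test_that("consolidation unifies, errors on overlap, or unions on request", {
  universe <- as.character(1:100)
  r1 <- fake_run(list(c("1", "2"), c("5")), universe, "r1")
  r2 <- fake_run(list(c("1", "2"), c("7", "8")), universe, "r2")
  res <- consolidate(list(r1, r2))
  expect_length(res$final_clusters, 3L)   # {1,2} unified, {5}, {7,8}
  expect_equal(length(res$others) + length(res$different_subjects), 100L)
  expect_setequal(res$different_subjects, c("1", "2", "5", "7", "8"))
  # single retained run: its minorities pass through
  res1 <- consolidate(list(r1))
  expect_equal(res1$final_clusters, list(`1` = c("1", "2"), `2` = "5"))

  r3 <- fake_run(list(c("2", "3")), universe, "r3")  # overlaps {1,2}
  expect_error(consolidate(list(r1, r3)), "unresolved-overlap")
  resu <- consolidate(list(r1, r3), overlap_policy = "union")
  expect_true(any(vapply(resu$final_clusters, function(cl)
    setequal(cl, c("1", "2", "3")), logical(1L))))
  # a directive resolves the same overlap explicitly
  resd <- consolidate(list(r1, r3),
                      merge_map = list(c("1", "2", "3")))
  expect_true(any(vapply(resd$final_clusters, function(cl)
    setequal(cl, c("1", "2", "3")), logical(1L))))
})

test_that("provenance and pattern classes track contributing runs", {
  universe <- as.character(1:50)
  r1 <- fake_run(list(c("1", "2")), universe, "r1")
  r2 <- fake_run(list(c("1", "2")), universe, "r2")
  r3 <- fake_run(list(c("9")), universe, "r3")
  res <- consolidate(list(r1, r2, r3))
  expect_length(res$pattern_classes, 2L)  # r1 == r2, r3 distinct
  cl12 <- which(vapply(res$final_clusters, function(cl)
    setequal(cl, c("1", "2")), logical(1L)))
  expect_setequal(res$provenance[[cl12]], c("r1", "r2"))
})

test_that("fixture patterns reproduce the published bookkeeping", {
  runsL <- reported_runs("L")
  runsLE <- reported_runs("LE")
  expect_length(runsL, 4L)
  expect_length(runsLE, 7L)
  expect_equal(length(different_subjects(runsL)), 37L)
  expect_equal(length(different_subjects(runsLE)), 33L)

  resL <- consolidate_reported("L")
  resLE <- consolidate_reported("LE")
  expect_length(resL$final_clusters, 9L)    # 10 including Others
  expect_length(resLE$final_clusters, 10L)  # 11 including Others
  expect_true(any(vapply(resLE$final_clusters, function(cl)
    setequal(cl, c("249", "331", "375", "548")), logical(1L))))
  ov <- cross_dataset_overlap(resL, resLE)
  expect_equal(ov, c("79", "120", "121", "249", "379", "381", "548"))
})

test_that("consolidation of the fixtures equals the published proposals", {
  for (ds in c("L", "LE")) {
    res <- consolidate_reported(ds)
    pub <- reported_final_proposal(ds)
    got <- unname(lapply(res$final_clusters, scdrisk:::sort_ids))
    want <- unname(lapply(pub$final_clusters, scdrisk:::sort_ids))
    # same clusters as sets, regardless of order
    key <- function(x) paste(x, collapse = ",")
    expect_setequal(vapply(got, key, character(1L)),
                    vapply(want, key, character(1L)))
  }
})
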