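test_that("fold change normalises compound wells to the in-plate DMSO mean", {
  lay <- small_layout(80)
  read <- make_plate_read(lay, "P01", "coculture", neg = rep(200, 8),
                          pos = rep(2000, 8), compound_value = 260)
  fc <- fold_change_plate(read, lay)
  expect_equal(nrow(fc), 80)
  expect_true(all(fc$fc == 1.3))
  # compound wells equal to the DMSO mean give fc = 1
  read1 <- make_plate_read(lay, "P01", "coculture", neg = rep(200, 8),
                           compound_value = 200)
  expect_true(all(fold_change_plate(read1, lay)$fc == 1))
})

test_that("fold change is invariant under plate-level gain", {
  lay <- small_layout(80)
  set.seed(404)
  read <- make_plate_read(lay, "P01", "coculture",
                          neg = runif(8, 150, 250), pos = runif(8, 1500, 2500))
  read$rlu[read$well %in% plate_wells()[13:20]] <- runif(8, 100, 500)
  fc1 <- fold_change_plate(read, lay)
  read3 <- dplyr::mutate(read, rlu = rlu * 3)
  fc3 <- fold_change_plate(read3, lay)
  expect_equal(fc3$fc, fc1$fc)
  # scaling only the compound wells scales fc by the same factor
  readc <- read
  cmp_wells <- plate_layout(lay, "P01", "coculture")
  cmp_wells <- cmp_wells$well[cmp_wells$role == "compound"]
  readc$rlu[readc$well %in% cmp_wells] <-
    readc$rlu[readc$well %in% cmp_wells] * 2
  expect_equal(fold_change_plate(readc, lay)$fc, fc1$fc * 2)
})

test_that("empty wells are skipped and never produce records", {
  lay <- build_screen_layout(sprintf("C%04d", 1:85))
  read <- make_plate_read(lay, "P02", "coculture", neg = rep(100, 8))
  fc <- fold_change_plate(read, lay)
  expect_equal(nrow(fc), 5)
  expect_false(any(is.na(fc$compound_id)))
})

test_that("replicate aggregation is the arithmetic mean with n recorded", {
  recs <- tibble::tibble(compound_id = c("a", "a", "b"),
                         replicate_id = c(1, 2, 1),
                         fc = c(1.4, 1.6, 2.02))
  agg <- aggregate_replicates(recs)
  expect_equal(agg$mean_fc[agg$compound_id == "a"], 1.5)
  expect_equal(agg$n_replicates[agg$compound_id == "a"], 2)
  expect_equal(agg$mean_fc[agg$compound_id == "b"], 2.02)
  expect_equal(agg$n_replicates[agg$compound_id == "b"], 1)
  expect_error(aggregate_replicates(recs[0, ]), "no fold-change")
})

make_records <- function(ids, fcs_by_rep, condition) {
  dplyr::bind_rows(lapply(seq_along(fcs_by_rep), function(r) {
    tibble::tibble(compound_id = ids, condition = condition,
                   replicate_id = r, fc = fcs_by_rep[[r]])
  }))
}

test_that("hit statuses follow the dual-replicate and counter-screen rules", {
  ids <- c("both_high", "one_day", "toxic", "low", "exact", "single")
  co <- make_records(ids[1:5], list(c(2.0, 1.4, 2.0, 1.4, 1.3),
                                    c(2.1, 1.2, 2.1, 0.84, 1.3)),
                     "coculture")
  co <- dplyr::bind_rows(co, tibble::tibble(
    compound_id = "single", condition = "coculture", replicate_id = 1,
    fc = 1.5))
  ta <- make_records(ids, list(rep(1, 6), c(1, 1, 1.5, 1, 1, 1)),
                     "target_alone")
  ht <- call_hits(co, ta, threshold = 1.3)
  status <- setNames(ht$status, ht$compound_id)
  expect_equal(status[["both_high"]], "hit")
  expect_equal(status[["one_day"]], "non_hit")    # 1.4 then 1.2
  expect_equal(status[["toxic"]], "excluded_toxic") # co-culture 2.0/2.1
  expect_equal(status[["low"]], "non_hit")        # 1.4 then 0.84
  expect_equal(status[["exact"]], "hit")          # inclusive threshold
  expect_equal(status[["single"]], "single_replicate_hit")
})

test_that("raising the threshold never converts a non-hit into a hit", {
  set.seed(405)
  for (i in 1:50) {
    ids <- sprintf("c%02d", 1:30)
    co <- make_records(ids, list(rlnorm(30, 0, 0.3), rlnorm(30, 0, 0.3)),
                       "coculture")
    ta <- make_records(ids, list(rlnorm(30, 0, 0.2), rlnorm(30, 0, 0.2)),
                       "target_alone")
    t1 <- runif(1, 1.1, 1.5)
    t2 <- t1 + runif(1, 0.05, 0.5)
    h1 <- call_hits(co, ta, threshold = t1)
    h2 <- call_hits(co, ta, threshold = t2)
    hits1 <- h1$compound_id[h1$status == "hit"]
    hits2 <- h2$compound_id[h2$status == "hit"]
    expect_true(all(hits2 %in% hits1))
    # exclusion dominance at either threshold
    for (h in list(h1, h2)) {
      thr <- attr(h, "threshold")
      tox <- vapply(h$target_alone_fcs, function(v) any(v >= thr), logical(1))
      expect_true(all(h$status[tox] == "excluded_toxic"))
    }
  }
})

test_that("ranking is by descending mean fc with lexicographic ties", {
  co <- make_records(c("zeta", "alpha", "mid"),
                     list(c(1.40, 1.40, 1.60), c(1.40, 1.40, 1.60)),
                     "coculture")
  ta <- make_records(c("zeta", "alpha", "mid"), list(rep(1, 3), rep(1, 3)),
                     "target_alone")
  ht <- call_hits(co, ta)
  expect_equal(ht$compound_id, c("mid", "alpha", "zeta"))
  expect_identical(rank_hits(ht)$compound_id, ht$compound_id)
})

test_that("a compound present in one condition only is flagged, not dropped", {
  co <- make_records(c("a", "b"), list(c(1.5, 1.5), c(1.5, 1.5)), "coculture")
  ta <- make_records("a", list(1, 1), "target_alone")
  expect_warning(ht <- call_hits(co, ta), "one condition only")
  expect_equal(ht$condition_coverage[ht$compound_id == "b"],
               "coculture_only")
  expect_equal(ht$status[ht$compound_id == "b"], "hit")
})

test_that("candidate selection applies external curation flags", {
  co <- make_records(c("a", "b", "c"), list(rep(1.5, 3), rep(1.6, 3)),
                     "coculture")
  ta <- make_records(c("a", "b", "c"), list(rep(1, 3), rep(1, 3)),
                     "target_alone")
  ht <- call_hits(co, ta)
  expect_equal(nrow(select_candidates(ht)), 3)
  ann <- tibble::tibble(compound_id = c("a", "b", "c"),
                        deprioritize = c(TRUE, TRUE, TRUE))
  expect_equal(nrow(select_candidates(ht, ann)), 0)
  part <- tibble::tibble(compound_id = "a", deprioritize = TRUE)
  expect_warning(sel <- select_candidates(ht, part), "not flagged")
  expect_equal(sort(sel$compound_id), c("b", "c"))
})

test_that("fixture reconstruction reproduces the published hit list", {
  fix <- table1_fixture()
  expect_equal(nrow(fix), 14)
  expect_equal(sum(fix$candidate), 8)
  rec <- fixture_fold_change_records(fix)
  ht <- call_hits(rec$coculture, rec$target_alone, threshold = 1.3)
  expect_equal(nrow(screen_hits(ht)), 14)
  expect_equal(sum(ht$status == "single_replicate_hit"), 1)
  expect_equal(ht$compound_id[1], "colistin_sulfate_salt")
  expect_equal(ht$mean_fc[1:2], c(2.02, 1.85))
  # tied 1.40 pair is ordered lexicographically
  tied <- ht$compound_id[ht$mean_fc == 1.40]
  expect_equal(tied, sort(tied))
})
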