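test_that("shared/unique/retained/contribution match the worked dyad", {
  tab <- demo_dyad_table()
  dyad <- demo_dyad()
  su <- shared_unique_t1(dyad, tab)
  expect_setequal(su$shared, c("B", "C"))
  expect_setequal(su$unique, "D")
  expect_equal(su$pct_shared_t1, 100 * 2 / 3, tolerance = 1e-9)

  ret <- retention_t1_to_t2(dyad, su$shared, tab)
  expect_identical(ret$transferred, "C")
  expect_equal(ret$pct_retained, 50)

  expect_equal(contribution_to_t2(dyad, ret$transferred, tab), 50)
})

test_that("boundary dyads give 0, 100, or missing - never 0/0 = 0", {
  ids <- c("A", "B", "C")
  m <- cbind(M = c(1L, 1L, 1L), T1 = c(1L, 1L, 0L), T2 = c(1L, 1L, 1L),
             M2 = c(1L, 0L, 0L), T1b = c(0L, 1L, 1L), T2b = c(1L, 0L, 0L))
  rownames(m) <- ids
  tab <- asv_table(m)

  # T1 subset of mother: no unique ASVs, 100% shared
  d1 <- list(mother = "M", t1 = "T1", t2 = "T2")
  su1 <- shared_unique_t1(d1, tab)
  expect_identical(su1$unique, character(0))
  expect_equal(su1$pct_shared_t1, 100)
  expect_equal(retention_t1_to_t2(d1, su1$shared, tab)$pct_retained, 100)

  # disjoint mother and T1: 0% shared; empty shared set -> retention missing
  d2 <- list(mother = "M2", t1 = "T1b", t2 = "T2b")
  su2 <- shared_unique_t1(d2, tab)
  expect_equal(su2$pct_shared_t1, 0)
  expect_true(is.na(retention_t1_to_t2(d2, su2$shared, tab)$pct_retained))

  # transferred set empty -> contribution 0 (T2 still has ASVs)
  expect_equal(contribution_to_t2(d2, character(0), tab), 0)
})

test_that("cohort records equal the brute-force oracle on 200 random dyads", {
  set.seed(77)
  n_asv <- 40
  ids <- sprintf("A%03d", 1:n_asv)
  cols <- list(); meta <- list()
  for (i in 1:200) {
    did <- sprintf("R%03d", i)
    cols[[paste0(did, "M")]] <- rbinom(n_asv, 1, 0.4) * rpois(n_asv, 4)
    cols[[paste0(did, "T1")]] <- rbinom(n_asv, 1, 0.3) * rpois(n_asv, 4)
    cols[[paste0(did, "T2")]] <- rbinom(n_asv, 1, 0.3) * rpois(n_asv, 4)
    meta[[did]] <- metadata_for(did, if (i %% 2) "GDM" else "control")
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  tab <- asv_table(m)
  md <- do.call(rbind, meta)
  dy <- build_dyads(md, tab)
  recs <- cohort_transmission(dy, tab, complete_pairs_only = TRUE)$records

  expect_identical(nrow(recs), 200L)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    o <- oracle_transmission(m[, paste0(r$dyad_id, "M")],
                             m[, paste0(r$dyad_id, "T1")],
                             m[, paste0(r$dyad_id, "T2")], ids)
    expect_identical(r$n_t1, o$n_t1)
    expect_identical(r$n_shared_t1, o$n_shared)
    expect_identical(r$n_unique_t1, o$n_unique)
    expect_identical(r$n_transferred, o$n_transferred)
    expect_identical(r$n_t2, o$n_t2)
    expect_equal(r$pct_shared_t1, o$pct_shared, tolerance = 1e-12)
    expect_equal(r$pct_retained, o$pct_retained, tolerance = 1e-12)
    expect_equal(r$pct_contribution_t2, o$pct_contribution, tolerance = 1e-12)
  }
  # conservation and range invariants on every record
  expect_true(all(recs$n_shared_t1 + recs$n_unique_t1 == recs$n_t1))
  pct <- unlist(recs[, c("pct_shared_t1", "pct_retained",
                         "pct_contribution_t2")])
  expect_true(all(is.na(pct) | (pct >= 0 & pct <= 100)))
})

test_that("complete-pair and vaginal-delivery filters restrict the cohort", {
  md <- rbind(metadata_for(c("D1", "D2"), c("GDM", "GDM")),
              metadata_for("D3", "control", with_t2 = FALSE))
  md$delivery_mode[md$dyad_id == "D2"] <- "caesarean"
  m <- matrix(1L, 4, nrow(md), dimnames = list(paste0("A", 1:4), md$sample_id))
  tab <- asv_table(m)
  dy <- build_dyads(md, tab)
  all_rec <- cohort_transmission(dy, tab, complete_pairs_only = FALSE)
  expect_identical(nrow(all_rec$records), 3L)
  expect_true(is.na(all_rec$records$pct_retained[
    all_rec$records$dyad_id == "D3"]))
  vag <- cohort_transmission(dy, tab, complete_pairs_only = TRUE,
                             vaginal_only = TRUE)
  expect_identical(vag$records$dyad_id, "D1")
  expect_error(cohort_transmission(dy[0, ], tab), "no eligible")
})

test_that("marker bookkeeping counts markers among shared and transferred sets", {
  tab <- demo_dyad_table()
  md <- data.frame(sample_id = c("M1", "T1a", "T2a"), dyad_id = "D1",
                   group = "GDM", role = c("mother", "infant", "infant"),
                   timepoint = c("antenatal", "T1", "T2"),
                   delivery_mode = "vaginal")
  dy <- build_dyads(md, tab)
  tr <- cohort_transmission(dy, tab, markers = c("C", "E"))
  expect_identical(tr$records$n_marker_shared_t1, 1L)     # C in shared {B,C}
  expect_identical(tr$records$n_marker_transferred_t2, 1L)

  freq <- marker_sharing_frequency(dy, c("B", "E"), tab)
  expect_identical(freq$asv_id, c("B", "E"))
  expect_identical(freq$n_dyads_shared, c(1L, 0L))        # E still reported
  expect_true(all(freq$n_dyads_shared <= nrow(dy)))
})
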