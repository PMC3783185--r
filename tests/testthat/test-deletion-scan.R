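ref <- smn2IntronReference()

test_that("the three overlapping-deletion scans delineate nested cores", {
  c20 <- inferCoreRegion(fig2DeletionScan(), partial_as = "retained", ref = ref)
  expect_equal(nrow(c20), 1L)
  expect_equal(c(c20$start, c20$end, c20$length_nt), c(282L, 300L, 19L))

  c10 <- inferCoreRegion(fig3aDeletionScan(), partial_as = "abrogated",
                         ref = ref)
  expect_equal(c(c10$start, c10$end, c10$length_nt), c(286L, 300L, 15L))

  c5 <- inferCoreRegion(fig3bDeletionScan(), ref = ref)
  expect_equal(c(c5$start, c5$end, c5$length_nt), c(289L, 295L, 7L))
  expect_equal(c5$motif, "AGCAGAC")

  # nesting: each finer scan sharpens, never contradicts, the coarser one
  expect_true(c10$start >= c20$start && c10$end <= c20$end)
  expect_true(c5$start >= c10$start && c5$end <= c10$end)
})

test_that("the partial-call policy changes only how 'lesser extent' rows count", {
  rec <- fig3aDeletionScan()
  lenient <- inferCoreRegion(rec, partial_as = "retained")
  strict <- inferCoreRegion(rec, partial_as = "abrogated")
  # resolving the partial window as abrogating extends the core rightwards
  expect_equal(lenient$end, 295L)
  expect_equal(strict$end, 300L)
  expect_equal(lenient$start, strict$start)
})

test_that("core inference agrees with the position-wise oracle on random scans", {
  set.seed(7)
  for (rep in 1:40) {
    nWin <- sample(4:14, 1)
    starts <- sort(sample(1:480, nWin))
    width <- sample(3:25, 1)
    rec <- perturbationRecords(
      sprintf("Δ%d-%d", starts, starts + width - 1L),
      sample(c("retained", "partial", "abrogated"), nWin, replace = TRUE))
    for (policy in c("retained", "abrogated")) {
      got <- suppressWarnings(inferCoreRegion(rec, partial_as = policy))
      want <- oracleCore(rec, partial_as = policy)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("adding a retained deletion can only shrink or preserve the core", {
  set.seed(11)
  base <- perturbationRecords(
    sprintf("Δ%d-%d", c(10, 20, 30), c(24, 34, 44)),
    c("abrogated", "abrogated", "abrogated"))
  core0 <- inferCoreRegion(base)
  pos0 <- unlist(lapply(seq_len(nrow(core0)), function(k)
    intervalPositions(core0$start[k], core0$end[k])))
  for (s in seq(5, 40, by = 4)) {
    extra <- perturbationRecords(sprintf("Δ%d-%d", s, s + 9L), "retained")
    core1 <- suppressWarnings(inferCoreRegion(rbind(base, extra)))
    pos1 <- unlist(lapply(seq_len(nrow(core1)), function(k)
      intervalPositions(core1$start[k], core1$end[k])))
    expect_true(all(pos1 %in% pos0))
  }
})

test_that("uncovered positions are never claimed and empty scans warn", {
  rec <- perturbationRecords(c("Δ10-19", "Δ40-49"),
                             c("abrogated", "abrogated"))
  core <- inferCoreRegion(rec)
  # the gap 20..39 is untested, so two disjoint cores are reported
  expect_equal(core$start, c(10L, 40L))
  expect_equal(core$end, c(19L, 49L))

  allRet <- perturbationRecords(c("Δ10-19", "Δ15-24"), rep("retained", 2))
  expect_warning(empty <- inferCoreRegion(allRet), "empty core")
  expect_equal(nrow(empty), 0L)
})

test_that("the point-substitution scan maps the 6-nt LS-1 motif", {
  core <- pointScanCore(fig4PointScan(), ref = ref)
  expect_equal(c(core$start, core$end, core$length_nt), c(290L, 295L, 6L))
  expect_equal(core$motif, "GCAGAC")
  # the identical upstream copy exists but is not the mapped element
  expect_equal(coreMotif(ref, 282, 287), core$motif)

  allRet <- perturbationRecords(c("290A", "291A"), rep("retained", 2))
  expect_equal(nrow(pointScanCore(allRet)), 0L)

  expect_error(pointScanCore(fig3bDeletionScan()), "substitution")
  expect_error(inferCoreRegion(fig4PointScan()), "deletion")
})

test_that("planted cores are recovered exactly from noise-free simulated scans", {
  # exact recovery needs exculpatory evidence flush against the core: some
  # window must end at core_start - 1 and another begin at core_end + 1, as
  # in the published scan designs
  set.seed(3)
  for (rep in 1:15) {
    offs <- sample(2:6, 1)
    width <- sample((offs + 1):12, 1)
    starts <- seq(20L, 180L, by = offs)
    ends <- starts + width - 1L
    j <- sample(which(ends < 150L), 1)
    mCand <- which(starts >= ends[j] + 2L)
    m <- mCand[sample(length(mCand), 1)]
    core <- c(ends[j] + 1L, starts[m] - 1L)
    params <- scanSimParams(core, data.frame(start = starts, end = ends),
                            flip_prob = 0, seed = rep)
    got <- inferCoreRegion(simulateScan(params))
    expect_equal(nrow(got), 1L)
    expect_equal(c(got$start, got$end), core)
  }
})

test_that("recovered cores always bracket the covered planted positions", {
  # without boundary alignment the recovered interval may overshoot by less
  # than a window width, but never undershoots the covered planted core
  set.seed(8)
  for (rep in 1:15) {
    offs <- sample(2:6, 1)
    width <- sample((offs + 1):12, 1)
    starts <- seq(20L, 180L, by = offs)
    core <- sort(sample(60:140, 2))
    params <- scanSimParams(core,
                            data.frame(start = starts,
                                       end = starts + width - 1L),
                            flip_prob = 0, seed = rep)
    got <- inferCoreRegion(simulateScan(params))
    expect_equal(nrow(got), 1L)
    expect_lte(got$start, core[1])
    expect_gte(got$end, core[2])
    expect_lt(got$start - (core[1] - width + 1L), width)
    expect_lte(got$end, core[2] + width - 1L)
  }
})

test_that("scan tables round-trip through TSV and match the shipped fixtures", {
  tmp <- tempfile(fileext = ".tsv")
  writeScanTsv(fig3bDeletionScan(), tmp)
  back <- readScanTsv(tmp)
  expect_equal(back$variant_label, fig3bDeletionScan()$variant_label)
  expect_equal(back$call, fig3bDeletionScan()$call)

  shipped <- readScanTsv(system.file("extdata", "scan_20nt.tsv",
                                     package = "ldiscan"))
  core <- inferCoreRegion(shipped, partial_as = "retained")
  expect_equal(c(core$start, core$end), c(282L, 300L))
})
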