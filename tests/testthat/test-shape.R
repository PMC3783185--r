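ref <- smn2IntronReference()

test_that("reactivity arithmetic: subtract, clamp, normalize per primer", {
  lane <- LaneProfile("p", 1:5, c(10, 2, 6, 0, 3), c(2, 2, 8, 0, 3))
  prof <- computeReactivity(lane)
  d <- profileData(prof)
  expect_equal(d$raw, c(8, 0, 0, 0, 0))        # negative differences clamp to 0
  expect_equal(d$normalized, c(1, 0, 0, 0, 0)) # max-normalized
  expect_error(LaneProfile("p", 1:2, c(-1, 2), c(0, 0)), "nonnegative")
  expect_error(LaneProfile("p", c(2, 1), c(1, 2), c(0, 0)), "increasing")

  null <- LaneProfile("p", 1:3, c(5, 5, 5), c(5, 5, 5))
  expect_warning(p0 <- computeReactivity(null), "degenerate")
  expect_equal(profileData(p0)$normalized, c(0, 0, 0))
})

test_that("normalization is scale-invariant", {
  set.seed(5)
  i1 <- runif(30, 0, 50); i0 <- runif(30, 0, 10)
  a <- computeReactivity(LaneProfile("p", 1:30, i1, i0))
  b <- computeReactivity(LaneProfile("p", 1:30, 7.3 * i1, 7.3 * i0))
  expect_equal(profileData(a)$normalized, profileData(b)$normalized)
})

test_that("classification uses the 0.3/0.5 thresholds with moderate ties at 0.5", {
  prof <- ReactivityProfile(data.frame(
    position = 1:6, raw = 1,
    normalized = c(0.51, 0.5, 0.3, 0.29, 0, 1)))
  cl <- profileData(classifyReactivity(prof))$class
  expect_equal(cl, c("high", "moderate", "moderate", "low", "low", "high"))
  # idempotence
  expect_equal(profileData(classifyReactivity(classifyReactivity(prof))),
               profileData(classifyReactivity(prof)))
})

test_that("protected counts partition the residue set", {
  istl1 <- istl1Residues(ref)
  classes <- rep("low", 16)
  classes[match(c(3L, 293L), istl1)] <- "moderate"
  prof <- profileFromClasses(istl1, classes)
  expect_equal(countProtected(prof, istl1), 14L)
  d <- profileData(prof)
  nonLow <- sum(d$class != "low")
  expect_equal(countProtected(prof, istl1) + nonLow, length(istl1))

  expect_equal(countProtected(profileFromClasses(1:5, rep("low", 5)), 1:5), 5L)
  expect_equal(countProtected(profileFromClasses(1:5, rep("high", 5)), 1:5), 0L)
  expect_error(countProtected(prof, c(3L, 999L)), "999")
  # falloff positions carry no structural signal and are not counted
  expect_equal(countProtected(flagFalloff(prof, 4L), istl1), 13L)
})

test_that("falloff detection flags control-lane stops above the window median", {
  flat <- LaneProfile("p", 1:20, rep(10, 20), rep(5, 20))
  expect_length(detectFalloff(flat, 3), 0L)
  expect_length(detectFalloff(flat, Inf), 0L)

  dm <- rep(5, 20); dm[c(12, 13)] <- 60   # stops in the control lane too
  stopped <- LaneProfile("p", 1:20, rep(10, 20), dm)
  expect_equal(detectFalloff(stopped, 3), c(12L, 13L))
})

test_that("primer merging keeps the nearest-window-center value", {
  a <- profileFromClasses(1:10, rep("low", 10), "pA")
  b <- profileFromClasses(11:20, rep("high", 10), "pB")
  m <- mergePrimers(list(a, b))
  expect_equal(profilePositions(m), 1:20)            # disjoint: concatenation

  # overlap 8..13 with conflicting classes: centers at 5.5 (pA) and 15.5 (pB)
  b2 <- profileFromClasses(8:20, rep("high", 13), "pB")
  a2 <- profileFromClasses(1:13, rep("low", 13), "pA")
  m2 <- mergePrimers(list(a2, b2))
  d <- profileData(m2)
  expect_equal(d$primer_id[d$position == 9], "pA")   # nearer pA's center
  expect_equal(d$primer_id[d$position == 12], "pB")
  expect_true(length(attr(m2, "conflicts")) > 0)
  expect_error(mergePrimers(list()), "no profiles")
})

test_that("ten simulated primers tile the 467-nt substrate without gaps", {
  wt <- wtStructureModel(ref)
  wins <- primerWindows(modelSpan(wt), 10L)
  expect_equal(nrow(wins), 10L)
  p0 <- probeSimParams(noise_cv = 0)
  profs <- lapply(seq_len(nrow(wins)), function(k)
    simulateProfile(wt, p0, c(wins$start[k], wins$end[k]), wins$primer_id[k]))
  merged <- mergePrimers(profs)
  expect_equal(profilePositions(merged), modelPositions(wt))
})

test_that("differential profiles reproduce the strand-protection patterns", {
  p0 <- probeSimParams(noise_cv = 0)
  wt <- wtStructureModel(ref)
  m4 <- istl1M4StructureModel(ref)

  # strengthened stem: the extended 5' strand becomes protected
  a <- simulateProfile(wt, p0, primer5pWindow(), "p5")
  b <- simulateProfile(m4, p0, primer5pWindow(), "p5")
  d <- differentialProfile(a, b, 0.15)
  expect_equal(d$position[d$call == "protected"],
               c(-1L, 1L, 2L, 3L, 11L, 12L, 13L, 14L))

  # invading ASO releases the 3' strand: exposure except the damped 291C
  pov <- probeSimParams(noise_cv = 0, p_mod_override = asoD291Override())
  c1 <- simulateProfile(m4, p0, primerMidWindow(), "p17")
  c2 <- simulateProfile(m4AsoDModel(ref), pov, primerMidWindow(), "p17")
  d2 <- differentialProfile(c1, c2, 0.15)
  expect_equal(d2$position[d2$call == "exposed"],
               setdiff(286:299, 291L))

  same <- differentialProfile(a, a, 0.15)
  expect_true(all(same$call == "unchanged"))
  expect_error(differentialProfile(a, c1), "aligned")
})

test_that("structure concordance scores paired-low / unpaired-reactive", {
  istl1 <- istl1Residues(ref)
  classes <- rep("low", 16); classes[match(c(3L, 293L), istl1)] <- "moderate"
  prof <- profileFromClasses(istl1, classes)
  istl1Model <- StructureModel(list(ISTL1 = buildWtIstl1(ref)),
                               c(3L, 297L))
  expect_equal(structureConcordance(prof, istl1Model), 14 / 16)

  # a noise-free profile from probabilities that classify like their truth
  # is perfectly concordant with its generating model
  pSharp <- probeSimParams(p_mod_unpaired = 0.6, p_mod_terminal = 0.1,
                           p_mod_paired = 0.02, noise_cv = 0)
  wt <- wtStructureModel(ref)
  expect_equal(structureConcordance(simulateProfile(wt, pSharp), wt), 1)

  # shuffling classes degrades concordance to the marginal expectation
  set.seed(21)
  full <- simulateProfile(wt, pSharp)
  d <- profileData(full)
  paired <- isPaired(wt, d$position)
  pLow <- mean(d$class == "low")
  expected <- mean(paired) * pLow + mean(!paired) * (1 - pLow)
  shuffled <- vapply(1:200, function(i) {
    d2 <- d; d2$class <- sample(d2$class)
    structureConcordance(ReactivityProfile(d2), wt)
  }, numeric(1))
  expect_lt(abs(mean(shuffled) - expected), 0.02)
})

test_that("true-model concordance beats an ISTL1-less model at default noise", {
  wt <- wtStructureModel(ref)
  noIstl1 <- StructureModel(modelHelices(wt)[
    setdiff(names(modelHelices(wt)), "ISTL1")], modelSpan(wt))
  prof <- simulateProfile(wt, probeSimParams(noise_cv = 0.2, seed = 17))
  expect_gt(structureConcordance(prof, wt),
            structureConcordance(prof, noIstl1))
})

test_that("lane and profile tables round-trip through TSV and export", {
  lane <- simulateLanes(
    simulateTruthReactivity(wtStructureModel(ref), probeSimParams(seed = 2)),
    probeSimParams(seed = 2), "p1", c(1, 60))
  tmp <- tempfile(fileext = ".tsv")
  writeLaneTsv(lane, tmp)
  back <- readLaneTsv(tmp)[["p1"]]
  expect_equal(back@positions, lane@positions)
  expect_equal(back@intensity_1m7, lane@intensity_1m7)

  prof <- flagFalloff(classifyReactivity(computeReactivity(lane)), 30L)
  tmp2 <- tempfile(fileext = ".tsv")
  writeProfileTsv(prof, tmp2)
  expect_equal(profileData(readProfileTsv(tmp2)), profileData(prof))

  tmp3 <- tempfile(fileext = ".shape")
  writeShapeExport(prof, tmp3)
  exp <- read.delim(tmp3, header = FALSE)
  expect_equal(exp$V2[exp$V1 == 30], -999)
})
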