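ref <- smn2IntronReference()

test_that("the wild-type internal stem pairs 3-10 with 297-290", {
  wt <- buildWtIstl1(ref)
  expect_equal(helixLength(wt), 8L)
  p <- helixPairs(wt)
  expect_equal(p$i[1], 3L);  expect_equal(p$j[1], 297L)   # outermost
  expect_equal(p$i[8], 10L); expect_equal(p$j[8], 290L)   # innermost
  expect_equal(length(unique(c(p$i, p$j))), 16L)
  # all wild-type pairs are Watson-Crick: wobble setting is irrelevant
  expect_equal(helixPairs(buildWtIstl1(ref, wcRule)), p)
  # a reference breaking the anchor pair is rejected with the failing pair
  broken <- mutantSeq(applyVariant(ref, parseVariantLabel("290C")))
  expect_error(buildWtIstl1(broken), "10:290")
})

test_that("helix validity enforces contiguity and strand order", {
  expect_error(Helix("bad", c(3L, 5L), c(297L, 296L)), "contiguous")
  expect_error(Helix("bad", c(300L), c(10L)), "i < j")
  expect_silent(Helix("empty", integer(), integer()))
  expect_equal(helixLength(Helix("empty", integer(), integer())), 0L)
})

test_that("helix extension under point mutations follows base-pair logic", {
  wt <- buildWtIstl1(ref)
  gain <- function(v, rule = basePairRule()) {
    helixLength(extendHelix(ref, wt, parseVariantLabel(v), rule)) -
      helixLength(wt)
  }
  expect_equal(gain("289G"), 1L)       # new 11C:289G pair
  expect_equal(gain("288U"), 0L)       # 11:289 mismatch blocks contiguity
  expect_equal(gain("286G"), 0L)
  expect_equal(gain("288U/289G"), 3L)  # 11:289, 12:288, 13:287
  expect_equal(gain("298A", wcRule), 1L)  # distal 2U:298A
  m4 <- extendHelix(ref, wt, istl1M4Variant(), wcRule)
  expect_gte(helixLength(m4), 13L)
  # idempotence: re-extending a maximal helix changes nothing
  again <- extendHelix(ref, m4, istl1M4Variant(), wcRule)
  expect_equal(helixPairs(again), helixPairs(m4))
  # every reported pair re-validates against the mutated reference
  mut <- mutantSeq(applyVariant(ref, istl1M4Variant()))
  expect_length(validateHelix(m4, mut, wcRule), 0L)
  # deleting an anchored position is a structural error
  expect_error(extendHelix(ref, wt, parseVariantLabel("Δ290-294")),
               "deletes anchored")
})

test_that("loop geometry is measured between the innermost pair's strands", {
  wt <- buildWtIstl1(ref)
  expect_equal(loopLength(wt), 279L)
  expect_equal(loopLength(Helix("tiny", 5L, 7L)), 1L)  # minimal enclosure
  ext <- extendHelix(ref, wt, parseVariantLabel("289G"))
  expect_equal(loopLength(ext), 277L)                  # innermost now 11:289
  expect_error(loopLength(Helix("empty", integer(), integer())), "empty")
})

test_that("the duplex scan finds the internal stem as the top hit", {
  hits <- findLdiDuplexes(ref, c(-2, 14), c(282, 300), min_bp = 6,
                          rule = wcRule)
  top <- hits[[1]]
  expect_equal(helixLength(top), 8L)
  expect_equal(pairSetKey(helixPairs(top)),
               pairSetKey(helixPairs(buildWtIstl1(ref))))
  # the identical upstream GCAGAC copy shows up as a weaker 6-bp candidate
  expect_equal(helixLength(hits[[2]]), 6L)
  expect_equal(helixPairs(hits[[2]])$j[1], 287L)

  expect_length(findLdiDuplexes(IntronSeq("AAAAAAAACCCCCCCC"), c(1, 8),
                                c(9, 16), 3), 0L)
  expect_error(findLdiDuplexes(ref, c(1, 20), c(15, 40), 6), "disjoint")
  expect_error(findLdiDuplexes(ref, c(1, 8), c(20, 30), 2), "min_bp")
})

test_that("duplex scanning is strand-swap symmetric and matches brute force", {
  set.seed(13)
  for (rep in 1:12) {
    n1 <- sample(20:50, 1); n2 <- sample(20:50, 1)
    s <- IntronSeq(paste0(randomRnaString(n1), randomRnaString(n2)), 1L)
    q <- c(1, n1); r <- c(n1 + 1, n1 + n2)
    for (rule in list(wcRule, basePairRule(TRUE))) {
      a <- findLdiDuplexes(s, q, r, 4, rule)
      b <- findLdiDuplexes(s, r, q, 4, rule)
      keyA <- sort(vapply(a, function(h) pairSetKey(helixPairs(h)), ""))
      keyB <- sort(vapply(b, function(h) pairSetKey(helixPairs(h)), ""))
      expect_equal(keyA, keyB)
      want <- sort(vapply(oracleDuplexes(s, q, r, 4, rule), pairSetKey, ""))
      expect_equal(keyA, want)
    }
  }
})

test_that("the forms-check honours deletion context, not sequence identity alone", {
  model <- wtStructureModel(ref)
  forms <- function(label) istl1Forms(ref, parseVariantLabel(label), model)
  wt <- forms("WT")
  expect_true(wt$forms)
  expect_equal(helixLength(wt$duplex), 8L)
  # deleting LS-1 leaves the identical upstream GCAGAC, but that copy is
  # held inside the intact ISTL2 strand and cannot substitute
  expect_false(forms("Δ290-295")$forms)
  expect_true(283 %in% forms("Δ290-295")$masked)
  # deleting the upstream copy instead dissolves ISTL2 and shifts LS-1 in
  expect_true(forms("Δ282-287")$forms)
  # compensatory pair logic
  expect_false(forms("8C")$forms)
  expect_false(forms("292G")$forms)   # Watson-Crick only: no 8U:292G rescue
  expect_true(forms("8C/292G")$forms)
  expect_false(forms("Δ286-295")$forms)
  # a large upstream deletion merely shifts the element; the duplex persists
  expect_true(forms("Δ93-281")$forms)
})

test_that("structures round-trip through multi-bracket dot-bracket and CT", {
  model <- wtStructureModel(ref)
  lines <- writeDotBracket(model, ref)
  back <- readDotBracket(lines)
  expect_equal(sort(pairedPositions(back)), sort(pairedPositions(model)))

  tmp <- tempfile(fileext = ".ct")
  writeCt(model, ref, tmp)
  ct <- readCt(tmp)
  expect_equal(seqString(ct$ref), seqString(ref))
  expect_equal(sort(pairedPositions(ct$model)), sort(pairedPositions(model)))

  # a model with no helices still round-trips
  bare <- StructureModel(list(), modelSpan(model))
  expect_equal(length(modelHelices(readDotBracket(
    writeDotBracket(bare, ref)))), 0L)
})

test_that("structure models refuse positions claimed by two helices", {
  expect_error(StructureModel(list(
    A = helixFromAnchor("A", 3L, 297L, 8L),
    B = helixFromAnchor("B", 8L, 320L, 4L)), c(-23L, 444L)),
    "two helices")
})
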