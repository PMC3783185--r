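## ---------------------------------------------------------------------------
## Helix modeling: pair tables, extension under variants, and bounded
## long-distance duplex scanning by complementarity.
## ---------------------------------------------------------------------------

#' Canonical base-pairing rule
#'
#' AU/UA and GC/CG always pair; GU/UG pairs iff `allow_wobble`. Pair classes
#' are ranked GC > AU > GU for tie-breaking between equally long duplexes.
#'
#' @param allow_wobble logical; default TRUE (the probed intron structure
#'   contains a wobble pair), but helix-extension analyses of ISTL1 are
#'   insensitive to it and the effect-rule engine uses Watson-Crick only.
#' @return an object of class `BasePairRule`.
#' @examples
#' canBasePair("G", "U", basePairRule(TRUE))   # TRUE
#' canBasePair("G", "U", basePairRule(FALSE))  # FALSE
#' @export
basePairRule <- function(allow_wobble = TRUE) {
  structure(list(allow_wobble = isTRUE(allow_wobble)), class = "BasePairRule")
}

#' @rdname basePairRule
#' @param a,b character vectors of residues.
#' @param rule a `BasePairRule`.
#' @export
canBasePair <- function(a, b, rule = basePairRule()) {
  key <- paste0(a, b)
  wc <- key %in% c("AU", "UA", "GC", "CG")
  if (rule$allow_wobble) wc | key %in% c("GU", "UG") else wc
}

#' @rdname basePairRule
#' @export
pairStrength <- function(a, b) {
  key <- paste0(a, b)
  out <- integer(length(key))
  out[key %in% c("GC", "CG")] <- 3L
  out[key %in% c("AU", "UA")] <- 2L
  out[key %in% c("GU", "UG")] <- 1L
  out
}

## ---------------------------------------------------------------------------
## Helix class
## ---------------------------------------------------------------------------

#' Helix: a contiguous antiparallel stem as an ordered pair table
#'
#' Pairs `(i, j)` are stored 5'-to-3' along the `i` strand; consecutive pairs
#' step `i` forward and `j` backward by one position (zero skipped), so the
#' helix is contiguous by construction. Bulged or interrupted stems are
#' represented as separate helices.
#'
#' @slot name helix name (e.g. "ISTL1").
#' @slot i,j integer vectors of paired positions (`i < j` pairwise).
#' @exportClass Helix
setClass("Helix",
  representation(name = "character", i = "integer", j = "integer"))

setValidity("Helix", function(object) {
  i <- object@i; j <- object@j
  msg <- character()
  if (length(i) != length(j)) return("i and j differ in length")
  if (length(i)) {
    if (any(i == 0L) || any(j == 0L)) msg <- c(msg, "position 0 is invalid")
    li <- linIndex(i); lj <- linIndex(j)
    if (any(li >= lj)) msg <- c(msg, "every pair must satisfy i < j")
    if (length(i) > 1L) {
      if (!all(diff(li) == 1L)) msg <- c(msg, "i strand not contiguous")
      if (!all(diff(lj) == -1L)) msg <- c(msg, "j strand not contiguous")
    }
    if (max(li) >= min(lj)) msg <- c(msg, "strands overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a helix from explicit strands or an anchor
#'
#' `Helix(name, i, j)` takes matched position vectors; `helixFromAnchor()`
#' builds `n` pairs starting from the outermost pair `(i5, j3)` stepping
#' inward.
#'
#' @param name helix name.
#' @param i,j paired positions, 5' strand ascending / 3' strand descending.
#' @return a [Helix-class].
#' @examples
#' istl1 <- helixFromAnchor("ISTL1", 3, 297, 8)
#' helixLength(istl1)  # 8
#' loopLength(istl1)   # 279
#' @export
Helix <- function(name, i, j) {
  new("Helix", name = name, i = as.integer(i), j = as.integer(j))
}

#' @rdname Helix
#' @param i5,j3 outermost pair positions.
#' @param n number of pairs.
#' @export
helixFromAnchor <- function(name, i5, j3, n) {
  Helix(name,
        posFromLin(linIndex(i5) + seq_len(n) - 1L),
        posFromLin(linIndex(j3) - seq_len(n) + 1L))
}

setMethod("show", "Helix", function(object) {
  n <- length(object@i)
  if (!n) { cat(sprintf("Helix '%s': empty\n", object@name)); return(invisible()) }
  cat(sprintf("Helix '%s': %d bp, %d..%d : %d..%d\n", object@name, n,
              object@i[1L], object@i[n], object@j[1L], object@j[n]))
})

#' Helix geometry accessors
#'
#' `helixLength()` is the number of pairs; `loopLength()` the number of
#' residues enclosed between the strands of the innermost pair `(i*, j*)`,
#' i.e. `j* - i* - 1` on the gapless coordinate line; `helixPairs()` the pair
#' table; `helixStrand5()`/`helixStrand3()` the strand position vectors.
#'
#' @param h a [Helix-class].
#' @return integers / data.frame as described.
#' @export
helixLength <- function(h) length(h@i)

#' @rdname helixLength
#' @export
loopLength <- function(h) {
  n <- length(h@i)
  if (!n) stop("empty helix has no enclosed loop")
  linIndex(h@j[n]) - linIndex(h@i[n]) - 1L
}

#' @rdname helixLength
#' @export
helixPairs <- function(h) data.frame(i = h@i, j = h@j)

#' @rdname helixLength
#' @export
helixStrand5 <- function(h) h@i

#' @rdname helixLength
#' @export
helixStrand3 <- function(h) sort(h@j)

#' @rdname helixLength
#' @export
helixName <- function(h) h@name

#' Re-validate a helix against a (possibly mutated) sequence
#'
#' @param h a [Helix-class].
#' @param seq an [IntronSeq-class] covering the helix positions.
#' @param rule a [basePairRule()].
#' @return character vector of failure descriptions; empty when every pair is
#'   canonical.
#' @export
validateHelix <- function(h, seq, rule = basePairRule()) {
  if (!helixLength(h)) return(character())
  pos <- c(h@i, h@j)
  out <- tryCatch(residueAt(seq, pos), error = function(e) NULL)
  if (is.null(out))
    return(sprintf("helix '%s' positions outside reference span", h@name))
  a <- out[seq_along(h@i)]
  b <- out[length(h@i) + seq_along(h@j)]
  bad <- !canBasePair(a, b, rule)
  sprintf("pair %d:%d is %s:%s", h@i[bad], h@j[bad], a[bad], b[bad])
}

## ---------------------------------------------------------------------------
## The wild-type ISTL1 helix and its extension under variants
## ---------------------------------------------------------------------------

#' Build the wild-type ISTL1 helix
#'
#' ISTL1 pairs intron positions 3-10 with 297-290 (innermost pair 10:290,
#' outermost 3:297): 8 pairs, 16 residues, all Watson-Crick, locking the 10C
#' residue against 290G across a 279-nt enclosed loop.
#'
#' @param ref reference covering intron positions 1-14 and 282-300.
#' @param rule a [basePairRule()]; the wild-type helix is all Watson-Crick so
#'   the result is identical under either wobble setting.
#' @return a [Helix-class] named "ISTL1".
#' @export
buildWtIstl1 <- function(ref = smn2IntronReference(), rule = basePairRule()) {
  h <- helixFromAnchor("ISTL1", 3L, 297L, 8L)
  bad <- validateHelix(h, ref, rule)
  if (length(bad))
    stop("reference inconsistent with the ISTL1 anchor: ",
         paste(bad, collapse = "; "))
  h
}

nextPos <- function(p) posFromLin(linIndex(p) + 1L)
prevPos <- function(p) posFromLin(linIndex(p) - 1L)

canPairAt <- function(seq, i, j, rule) {
  ok <- tryCatch(residueAt(seq, c(i, j)), error = function(e) NULL)
  !is.null(ok) && canBasePair(ok[1L], ok[2L], rule)
}

#' Extend a helix maximally under a variant
#'
#' Applies the variant, lifts the anchor pairs into mutant coordinates, and
#' greedily adds one pair at a time at both ends - loop-proximal (i+1 with
#' j-1 beyond the innermost pair) and distal (i-1 with j+1 beyond the
#' outermost pair) - while the residues are canonical under `rule`. The
#' result is the maximal contiguous helix containing the anchor, in mutant
#' coordinates. Extending an already-maximal helix is a no-op.
#'
#' @param ref wild-type reference.
#' @param h anchor [Helix-class] in wild-type coordinates.
#' @param v a [Variant-class] (or NULL for the wild type). A variant that
#'   deletes an anchored position is a structural error.
#' @param rule a [basePairRule()].
#' @return a [Helix-class].
#' @examples
#' ref <- smn2IntronReference()
#' wt <- buildWtIstl1(ref)
#' helixLength(extendHelix(ref, wt, parseVariantLabel("289G")))  # 9
#' @export
extendHelix <- function(ref, h, v = NULL, rule = basePairRule()) {
  if (is.null(v)) v <- new("Variant", label = "WT", edits = emptyEdits())
  ms <- applyVariant(ref, v)
  seq <- mutantSeq(ms)
  i <- liftPosition(ms, h@i)
  j <- liftPosition(ms, h@j)
  if (anyNA(i) || anyNA(j))
    stop("variant '", variantLabel(v), "' deletes anchored position(s) of ",
         "helix '", h@name, "'")
  hm <- Helix(h@name, i, j)
  bad <- validateHelix(hm, seq, rule)
  if (length(bad))
    stop("anchor helix '", h@name, "' invalid on variant '", variantLabel(v),
         "': ", paste(bad, collapse = "; "))
  n <- length(i)
  # loop-proximal growth
  ni <- nextPos(i[n]); nj <- prevPos(j[n])
  while (linIndex(nj) - linIndex(ni) >= 2L && canPairAt(seq, ni, nj, rule)) {
    i <- c(i, ni); j <- c(j, nj)
    ni <- nextPos(ni); nj <- prevPos(nj)
  }
  # distal growth
  pi <- prevPos(i[1L]); pj <- nextPos(j[1L])
  while (canPairAt(seq, pi, pj, rule)) {
    i <- c(pi, i); j <- c(pj, j)
    pi <- prevPos(pi); pj <- nextPos(pj)
  }
  Helix(h@name, i, j)
}

## ---------------------------------------------------------------------------
## Bounded long-distance duplex scan
## ---------------------------------------------------------------------------

# Maximal contiguous antiparallel duplex runs between two residue vectors.
# smask: logical over the search residues; TRUE positions may not pair.
.duplexRuns <- function(qres, qpos, sres, spos, min_bp, rule, smask = NULL) {
  nq <- length(qres); ns <- length(sres)
  if (!nq || !ns) return(list())
  M <- outer(qres, sres, function(a, b) canBasePair(a, b, rule))
  if (!is.null(smask) && any(smask)) M[, smask] <- FALSE
  runs <- list()
  # a duplex pairs q[x + k] with s[y - k]; substituting z = x + y this is a
  # constant-z anti-diagonal of M
  for (z in 2L:(nq + ns)) {
    xs <- max(1L, z - ns):min(nq, z - 1L)
    vals <- M[cbind(xs, z - xs)]
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_bp)) {
      x0 <- xs[starts[k]]; len <- r$lengths[k]
      xi <- x0 + seq_len(len) - 1L
      yi <- z - xi
      runs <- c(runs, list(list(i = qpos[xi], j = spos[yi],
        strength = sum(pairStrength(qres[xi], sres[yi])))))
    }
  }
  runs
}

#' Enumerate candidate long-distance duplexes between two regions
#'
#' Exhaustively scans for maximal contiguous antiparallel duplexes between a
#' query and a disjoint search region, returning all with at least `min_bp`
#' canonical pairs, sorted by (pair count, summed pair-strength rank)
#' descending with a deterministic tie-break on (query start, search start).
#' This is a bounded complementarity scanner, not a free-energy folder.
#'
#' @param ref an [IntronSeq-class] covering both regions.
#' @param query,search inclusive intervals `c(start, end)`; must be disjoint.
#' @param min_bp minimum pairs per reported duplex (>= 3).
#' @param rule a [basePairRule()].
#' @return list of [Helix-class] objects (possibly empty).
#' @examples
#' hits <- findLdiDuplexes(smn2IntronReference(), c(-2, 14), c(282, 300), 6)
#' helixLength(hits[[1]])  # 8 (the ISTL1 duplex)
#' @export
findLdiDuplexes <- function(ref, query, search, min_bp = 3L,
                            rule = basePairRule()) {
  if (min_bp < 3L) stop("min_bp must be >= 3")
  if (!validInterval(query[1L], query[2L]) ||
      !validInterval(search[1L], search[2L]))
    stop("invalid region interval")
  swapped <- linIndex(query[1L]) > linIndex(search[1L])
  if (swapped) { tmp <- query; query <- search; search <- tmp }
  if (linIndex(query[2L]) >= linIndex(search[1L]))
    stop("query and search regions must be disjoint")
  qpos <- intervalPositions(query[1L], query[2L])
  spos <- intervalPositions(search[1L], search[2L])
  qres <- residueAt(ref, qpos)
  sres <- residueAt(ref, spos)
  runs <- .duplexRuns(qres, qpos, sres, spos, min_bp, rule)
  if (!length(runs)) return(list())
  ord <- order(-vapply(runs, function(r) length(r$i), 1L),
               -vapply(runs, function(r) r$strength, 1L),
               vapply(runs, function(r) linIndex(r$i[1L]), 1L),
               vapply(runs, function(r) linIndex(min(r$j)), 1L))
  lapply(runs[ord], function(r) Helix("duplex", r$i, r$j))
}

## ---------------------------------------------------------------------------
## Structure models
## ---------------------------------------------------------------------------

#' StructureModel: a set of coexisting helices over a substrate
#'
#' Holds named helices (internal stems formed by long-distance interactions
#' and local terminal stem-loops). Helices may cross (pseudoknot-free nesting
#' is not required: internal stems coexist with hairpins), but no position
#' may belong to two helices.
#'
#' @slot helices named list of [Helix-class] objects.
#' @slot span integer `c(first, last)` positions of the substrate.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(helices = "list", span = "integer"))

setValidity("StructureModel", function(object) {
  msg <- character()
  if (!all(vapply(object@helices, is, logical(1L), "Helix")))
    return("helices must be Helix objects")
  pos <- unlist(lapply(object@helices, function(h) c(h@i, h@j)))
  if (anyDuplicated(pos))
    msg <- c(msg, "a position appears in two helices")
  if (length(object@span) != 2L)
    msg <- c(msg, "span must be c(first, last)")
  if (length(msg)) msg else TRUE
})

#' @rdname StructureModel-class
#' @param helices named list of [Helix-class] objects.
#' @param span substrate extent `c(first, last)` in intron coordinates.
#' @export
StructureModel <- function(helices, span) {
  if (is.null(names(helices)))
    names(helices) <- vapply(helices, helixName, "")
  new("StructureModel", helices = helices, span = as.integer(span))
}

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel over %d..%d with %d helices: %s\n",
              object@span[1L], object@span[2L], length(object@helices),
              paste(names(object@helices), collapse = ", ")))
})

#' Structure-model accessors
#'
#' @param model a [StructureModel-class].
#' @param name helix name.
#' @param pos positions to query.
#' @return as described per function.
#' @export
modelHelices <- function(model) model@helices

#' @rdname modelHelices
#' @export
modelHelix <- function(model, name) {
  if (!name %in% names(model@helices)) stop("no helix named '", name, "'")
  model@helices[[name]]
}

#' @rdname modelHelices
#' @export
modelSpan <- function(model) model@span

#' @rdname modelHelices
#' @export
pairedPositions <- function(model) {
  sort(unique(unlist(lapply(model@helices, function(h) c(h@i, h@j)))))
}

#' @rdname modelHelices
#' @export
isPaired <- function(model, pos) pos %in% pairedPositions(model)

#' @rdname modelHelices
#' @export
modelPositions <- function(model) {
  intervalPositions(model@span[1L], model@span[2L])
}

#' Positions simulated / treated as helix-terminal
#'
#' A helix's outermost-pair residues fray more readily than interior ones, as
#' do wobble-paired residues; these get the intermediate modification
#' propensity in the probe simulator and are tolerated as moderately reactive
#' in concordance scoring. The innermost (loop-closing) pair is held by its
#' enclosed loop and is treated as interior.
#'
#' @param model a [StructureModel-class].
#' @param ref reference sequence for wobble detection.
#' @return sorted integer positions.
#' @export
terminalPositions <- function(model, ref) {
  out <- integer()
  for (h in model@helices) {
    n <- helixLength(h)
    if (!n) next
    out <- c(out, h@i[1L], h@j[1L])  # outermost pair
    res_i <- residueAt(ref, h@i); res_j <- residueAt(ref, h@j)
    wob <- paste0(res_i, res_j) %in% c("GU", "UG")
    out <- c(out, h@i[wob], h@j[wob])
  }
  sort(unique(out))
}

## ---------------------------------------------------------------------------
## The packaged wild-type / mutant structure models
## ---------------------------------------------------------------------------

#' Packaged structure models of the probing substrate
#'
#' `wtStructureModel()` returns the wild-type model: ISTL1 (3-10 : 297-290),
#' ISTL2 (51-57 : 289-283), ISTL3 (59-65 : 281-275) and the TSL3 hairpin
#' (17-25 : 41-33, containing the 19U:39G wobble). `istl1M4StructureModel()`
#' returns the model for the quadruple 286G/288U/289G/298A mutant, in which
#' ISTL1 extends across the exon-intron junction and the destabilized ISTL2
#' and TSL3 are dissolved (ISTL3 is retained). Pair tables are in the
#' coordinates of the unchanged-length substrate (the mutant carries
#' substitutions only).
#'
#' @param ref the reference sequence.
#' @param rule a [basePairRule()]; the mutant model uses wobble pairing for
#'   its extended stem.
#' @return a [StructureModel-class].
#' @export
wtStructureModel <- function(ref = smn2IntronReference()) {
  span <- c(seqPositions(ref)[1L], seqPositions(ref)[length(ref)])
  StructureModel(list(
    ISTL1 = buildWtIstl1(ref),
    ISTL2 = helixFromAnchor("ISTL2", 51L, 289L, 7L),
    ISTL3 = helixFromAnchor("ISTL3", 59L, 281L, 7L),
    TSL3  = helixFromAnchor("TSL3", 17L, 41L, 9L)
  ), span)
}

#' @rdname wtStructureModel
#' @export
istl1M4Variant <- function() parseVariantLabel("286G/288U/289G/298A")

#' @rdname wtStructureModel
#' @export
istl1M4StructureModel <- function(ref = smn2IntronReference(),
                                  rule = basePairRule(TRUE)) {
  span <- c(seqPositions(ref)[1L], seqPositions(ref)[length(ref)])
  ext <- extendHelix(ref, buildWtIstl1(ref), istl1M4Variant(), rule)
  StructureModel(list(ISTL1 = ext,
                      ISTL3 = helixFromAnchor("ISTL3", 59L, 281L, 7L)), span)
}

## ---------------------------------------------------------------------------
## "Does ISTL1 form?" - the rule engine's structural predicate
## ---------------------------------------------------------------------------

#' Test whether the 10C-anchored long-distance duplex can form in a variant
#'
#' Applies the variant, then scans for a contiguous Watson-Crick duplex of at
#' least `min_bp` pairs that pairs intron position 10 (lifted into mutant
#' coordinates), between the intron 5' end (wild-type -4..14) and the
#' scanned downstream neighbourhood (wild-type 261..320, lifted). Search
#' positions that remain base-paired inside other intact helices of `model`
#' (e.g. the ISTL2 strand holding the upstream GCAGAC copy) are unavailable
#' for pairing: sequence identity alone does not substitute for the
#' structural context.
#'
#' @param ref wild-type reference.
#' @param variant a [Variant-class].
#' @param model the wild-type [StructureModel-class] supplying the competing
#'   helices (its ISTL1 entry, if present, is ignored).
#' @param min_bp minimum duplex length; default 6.
#' @param rule pairing rule for competing-helix validation (wobble allowed by
#'   default); the duplex scan itself is Watson-Crick only.
#' @return list with `forms` (logical), `duplex` (best qualifying
#'   [Helix-class] in mutant coordinates, or NULL) and `masked` (positions
#'   withheld from pairing).
#' @export
istl1Forms <- function(ref, variant, model = wtStructureModel(ref),
                       min_bp = 6L, rule = basePairRule(TRUE)) {
  ms <- applyVariant(ref, variant)
  seq <- mutantSeq(ms)
  ten <- liftPosition(ms, 10L)
  if (is.na(ten))
    return(list(forms = FALSE, duplex = NULL, masked = integer()))
  qpos <- liftPosition(ms, intervalPositions(-4L, 14L))
  spos <- liftPosition(ms, intervalPositions(261L, 320L))
  qpos <- qpos[!is.na(qpos)]; spos <- spos[!is.na(spos)]
  if (!length(spos))
    return(list(forms = FALSE, duplex = NULL, masked = integer()))
  # positions held inside other helices that survive the variant intact
  masked <- integer()
  for (h in model@helices) {
    if (identical(helixName(h), "ISTL1")) next
    li <- liftPosition(ms, h@i); lj <- liftPosition(ms, h@j)
    if (anyNA(li) || anyNA(lj)) next
    hm <- Helix(helixName(h), li, lj)
    if (!length(validateHelix(hm, seq, rule))) masked <- c(masked, li, lj)
  }
  wc <- basePairRule(allow_wobble = FALSE)
  qres <- residueAt(seq, qpos)
  sres <- residueAt(seq, spos)
  runs <- .duplexRuns(qres, qpos, sres, spos, min_bp, wc,
                      smask = spos %in% masked)
  runs <- Filter(function(r) ten %in% r$i, runs)
  if (!length(runs))
    return(list(forms = FALSE, duplex = NULL, masked = sort(masked)))
  best <- runs[[order(-vapply(runs, function(r) length(r$i), 1L),
                      -vapply(runs, function(r) r$strength, 1L))[1L]]]
  list(forms = TRUE, duplex = Helix("ISTL1", best$i, best$j),
       masked = sort(masked))
}

## ---------------------------------------------------------------------------
## CT and multi-bracket dot-bracket I/O
## ---------------------------------------------------------------------------

.bracketAlphabets <- rbind(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

helicesCross <- function(a, b) {
  # two helices cross if one's pairs straddle the other's
  ra <- range(linIndex(c(a@i, a@j))); rb <- range(linIndex(c(b@i, b@j)))
  innerA <- linIndex(c(a@i[length(a@i)], a@j[length(a@j)]))
  innerB <- linIndex(c(b@i[length(b@i)], b@j[length(b@j)]))
  straddles <- function(r, inner) xor(inner[1L] > r[1L] && inner[1L] < r[2L],
                                      inner[2L] > r[1L] && inner[2L] < r[2L])
  straddles(ra, innerB) || straddles(rb, innerA)
}

#' Write / read a structure as multi-bracket dot-bracket
#'
#' Crossing helices (long-distance stems over local hairpins) are emitted
#' with successive bracket alphabets `()`, `[]`, `{}`, `<>` so the notation
#' stays unambiguous.
#'
#' @param model a [StructureModel-class].
#' @param ref the sequence (defines length and coordinates).
#' @param path optional file; when NULL the lines are returned.
#' @return `writeDotBracket()` returns the lines invisibly (or visibly when
#'   `path` is NULL); `readDotBracket()` returns a `StructureModel`.
#' @export
writeDotBracket <- function(model, ref, path = NULL) {
  n <- length(ref)
  db <- rep(".", n)
  layer <- integer(length(model@helices))
  hs <- model@helices
  for (k in seq_along(hs)) {
    used <- 1L
    repeat {
      clash <- any(vapply(seq_len(k - 1L), function(m)
        layer[m] == used && helicesCross(hs[[k]], hs[[m]]), logical(1L)))
      if (!clash) break
      used <- used + 1L
      if (used > nrow(.bracketAlphabets))
        stop("more crossing layers than bracket alphabets")
    }
    layer[k] <- used
    db[posToIdx(ref, hs[[k]]@i)] <- .bracketAlphabets[used, 1L]
    db[posToIdx(ref, hs[[k]]@j)] <- .bracketAlphabets[used, 2L]
  }
  lines <- c(sprintf(">structure offset=%d", seqOrigin(ref)),
             seqString(ref), paste(db, collapse = ""))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' @rdname writeDotBracket
#' @param x path or character vector of dot-bracket lines.
#' @export
readDotBracket <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  off <- as.integer(sub(".*offset=(-?[0-9]+).*", "\\1", lines[1L]))
  ref <- IntronSeq(lines[2L], origin = off)
  db <- strsplit(lines[3L], "")[[1L]]
  pos <- seqPositions(ref)
  pairs <- NULL
  for (a in seq_len(nrow(.bracketAlphabets))) {
    stack <- integer()
    for (k in seq_along(db)) {
      if (db[k] == .bracketAlphabets[a, 1L]) stack <- c(stack, k)
      else if (db[k] == .bracketAlphabets[a, 2L]) {
        if (!length(stack)) stop("unbalanced brackets")
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced brackets")
  }
  if (is.null(pairs))
    return(StructureModel(list(), c(pos[1L], pos[length(pos)])))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  # group into contiguous helices
  helices <- list(); cur <- pairs[1L, , drop = FALSE]
  flush <- function(cur, helices) {
    h <- Helix(sprintf("H%d", length(helices) + 1L),
               pos[cur[, 1L]], pos[cur[, 2L]])
    c(helices, setNames(list(h), helixName(h)))
  }
  for (k in seq_len(nrow(pairs))[-1L]) {
    if (pairs[k, 1L] == cur[nrow(cur), 1L] + 1L &&
        pairs[k, 2L] == cur[nrow(cur), 2L] - 1L) {
      cur <- rbind(cur, pairs[k, ])
    } else {
      helices <- flush(cur, helices)
      cur <- pairs[k, , drop = FALSE]
    }
  }
  helices <- flush(cur, helices)
  StructureModel(helices, c(pos[1L], pos[length(pos)]))
}

#' Write / read a structure in CT format
#'
#' Standard 6-column connectivity table; the header records the coordinate
#' offset so intron numbering round-trips.
#'
#' @param model a [StructureModel-class].
#' @param ref the sequence.
#' @param path file path.
#' @return `readCt()` returns `list(ref =, model =)`.
#' @export
writeCt <- function(model, ref, path) {
  n <- length(ref)
  res <- strsplit(seqString(ref), "")[[1L]]
  pairIdx <- integer(n)
  for (h in model@helices) {
    ii <- posToIdx(ref, h@i); jj <- posToIdx(ref, h@j)
    pairIdx[ii] <- jj; pairIdx[jj] <- ii
  }
  lines <- c(sprintf("%d offset=%d", n, seqOrigin(ref)),
             sprintf("%d %s %d %d %d %d", seq_len(n), res,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     pairIdx, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCt
#' @export
readCt <- function(path) {
  lines <- readLines(path)
  off <- as.integer(sub(".*offset=(-?[0-9]+).*", "\\1", lines[1L]))
  fields <- strsplit(trimws(lines[-1L]), "\\s+")
  res <- vapply(fields, `[`, "", 2L)
  pairIdx <- as.integer(vapply(fields, `[`, "", 5L))
  ref <- IntronSeq(paste(res, collapse = ""), origin = off)
  pos <- seqPositions(ref)
  open <- which(pairIdx > seq_along(pairIdx))
  helices <- list()
  if (length(open)) {
    cur <- rbind(c(open[1L], pairIdx[open[1L]]))
    for (k in open[-1L]) {
      if (k == cur[nrow(cur), 1L] + 1L && pairIdx[k] == cur[nrow(cur), 2L] - 1L)
        cur <- rbind(cur, c(k, pairIdx[k]))
      else {
        h <- Helix(sprintf("H%d", length(helices) + 1L),
                   pos[cur[, 1L]], pos[cur[, 2L]])
        helices <- c(helices, setNames(list(h), helixName(h)))
        cur <- rbind(c(k, pairIdx[k]))
      }
    }
    h <- Helix(sprintf("H%d", length(helices) + 1L),
               pos[cur[, 1L]], pos[cur[, 2L]])
    helices <- c(helices, setNames(list(h), helixName(h)))
  }
  list(ref = ref, model = StructureModel(helices, c(pos[1L], pos[length(pos)])))
}

#' JSON helix report
#'
#' @param helices list of [Helix-class] objects.
#' @param path output path.
#' @export
writeHelixReport <- function(helices, path) {
  rep <- lapply(helices, function(h) list(
    name = helixName(h), length_bp = helixLength(h),
    loop_length = if (helixLength(h)) loopLength(h) else NA_integer_,
    pairs = helixPairs(h)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
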