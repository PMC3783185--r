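# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's internal algorithms: the
# core-mapping oracle tests the membership predicate position by position and
# the duplex oracle enumerates every (offset, offset, length) triple.

wcRule <- basePairRule(allow_wobble = FALSE)

# position-by-position core membership oracle (deletion scans, positive
# coordinates only, which is all the scans use)
oracleCore <- function(records, partial_as = "retained") {
  iv <- do.call(rbind, lapply(records$variant, function(v) variantEdits(v)))
  call <- ifelse(records$call == "partial", partial_as, records$call)
  lo <- min(iv$start); hi <- max(iv$end)
  core <- logical(hi - lo + 1L)
  for (p in lo:hi) {
    covering <- which(iv$start <= p & p <= iv$end)
    core[p - lo + 1L] <- length(covering) > 0L &&
      all(call[covering] == "abrogated")
  }
  pos <- (lo:hi)[core]
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  grp <- cumsum(c(1L, diff(pos) != 1L))
  do.call(rbind, lapply(split(pos, grp), function(g)
    data.frame(start = min(g), end = max(g))))
}

# exhaustive O(n^2 * L) antiparallel duplex enumeration returning maximal runs
oracleDuplexes <- function(ref, query, search, min_bp, rule) {
  qpos <- intervalPositions(query[1], query[2])
  spos <- intervalPositions(search[1], search[2])
  qres <- residueAt(ref, qpos)
  sres <- residueAt(ref, spos)
  hits <- list()
  for (x in seq_along(qpos)) {
    for (y in seq_along(spos)) {
      # pair (x, y) starts a run only if (x-1, y+1) does not pair
      prev_ok <- x > 1L && y < length(spos) &&
        canBasePair(qres[x - 1L], sres[y + 1L], rule)
      if (prev_ok || !canBasePair(qres[x], sres[y], rule)) next
      len <- 0L
      while (x + len <= length(qpos) && y - len >= 1L &&
             canBasePair(qres[x + len], sres[y - len], rule)) len <- len + 1L
      if (len >= min_bp)
        hits <- c(hits, list(data.frame(i = qpos[x + 0:(len - 1L)],
                                        j = spos[y - 0:(len - 1L)])))
    }
  }
  hits
}

pairSetKey <- function(pairs) {
  paste(sprintf("%d:%d", pairs$i, pairs$j), collapse = ",")
}

randomRnaString <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

istl1Residues <- function(ref = smn2IntronReference()) {
  h <- buildWtIstl1(ref)
  c(helixStrand5(h), helixStrand3(h))
}

# a ReactivityProfile built directly from classes (bypasses lane arithmetic)
profileFromClasses <- function(positions, classes, primer = "manual") {
  norm <- c(low = 0.1, moderate = 0.4, high = 0.9)[classes]
  classifyReactivity(ReactivityProfile(data.frame(
    position = positions, raw = norm, normalized = unname(norm),
    primer_id = primer, stringsAsFactors = FALSE)))
}
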