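## ---------------------------------------------------------------------------
## Deletion / point-substitution scan core mapping.
##
## A perturbation-phenotype scan records, per variant, whether the inhibitory
## ASO response was retained, partially retained, or abrogated.  The core of
## the long-distance interaction is the set of positions for which the
## evidence is unanimous: every tested deletion covering the position
## abrogated the response.
## ---------------------------------------------------------------------------

.calls <- c("retained", "partial", "abrogated")

#' Build a perturbation-scan record table
#'
#' @param labels character vector of variant labels (parsed with
#'   [parseVariantLabel()]).
#' @param calls character vector of phenotype calls, one of
#'   `"retained"`, `"partial"`, `"abrogated"`.
#' @param figure optional provenance strings.
#' @return a data.frame with columns `variant_label`, `call`, `figure` and a
#'   list-column `variant` of parsed [Variant-class] objects.
#' @examples
#' perturbationRecords(c("Δ281-300", "Δ301-320"), c("abrogated", "retained"))
#' @export
perturbationRecords <- function(labels, calls, figure = NA_character_) {
  if (length(labels) != length(calls)) stop("labels and calls differ in length")
  calls <- match.arg(calls, .calls, several.ok = TRUE)
  vars <- lapply(labels, parseVariantLabel)
  df <- data.frame(variant_label = vapply(vars, variantLabel, ""),
                   call = calls, figure = figure, stringsAsFactors = FALSE)
  df$variant <- vars
  df
}

resolvePartial <- function(calls, partial_as) {
  partial_as <- match.arg(partial_as, c("retained", "abrogated"))
  ifelse(calls == "partial", partial_as, calls)
}

recordIntervals <- function(records) {
  do.call(rbind, lapply(records$variant, function(v) {
    e <- variantEdits(v)
    if (nrow(e) != 1L || e$kind != "deletion")
      stop("deletion-scan records must carry exactly one deletion each ('",
           variantLabel(v), "')")
    data.frame(start = e$start, end = e$end)
  }))
}

runsToIntervals <- function(pos) {
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  lin <- sort(linIndex(pos))
  brk <- c(0L, which(diff(lin) != 1L), length(lin))
  do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
    data.frame(start = posFromLin(lin[brk[k] + 1L]),
               end = posFromLin(lin[brk[k + 1L]]))
  }))
}

coreTable <- function(intervals, ref = NULL) {
  if (!nrow(intervals))
    return(data.frame(start = integer(), end = integer(),
                      length_nt = integer(), motif = character()))
  intervals$length_nt <- spanLength(intervals$start, intervals$end)
  intervals$motif <- if (is.null(ref)) NA_character_ else
    vapply(seq_len(nrow(intervals)),
           function(k) segmentAt(ref, intervals$start[k], intervals$end[k]), "")
  intervals
}

#' Infer the core region of a long-distance interaction from a deletion scan
#'
#' A position belongs to the core iff (a) at least one tested deletion covers
#' it and (b) every tested deletion covering it abrogated the response, after
#' resolving `partial` calls via `partial_as`. Maximal runs of core positions
#' are returned as inclusive intervals; positions never covered by any tested
#' deletion are excluded (no evidence, no claim).
#'
#' @param records a table from [perturbationRecords()]; all variants must be
#'   single-interval deletions.
#' @param partial_as how to resolve `"partial"` calls: `"retained"`
#'   (conservative default) or `"abrogated"`.
#' @param ref optional [IntronSeq-class]; when given, the wild-type motif over
#'   each core interval is reported.
#' @return data.frame with columns `start`, `end`, `length_nt`, `motif`; zero
#'   rows (with a warning) when no deletion abrogates.
#' @examples
#' rec <- perturbationRecords(
#'   c("Δ287-291", "Δ290-294", "Δ293-297", "Δ284-288", "Δ296-300"),
#'   c("abrogated", "abrogated", "abrogated", "retained", "retained"))
#' inferCoreRegion(rec, ref = smn2IntronReference())
#' @export
inferCoreRegion <- function(records, partial_as = "retained", ref = NULL) {
  if (!nrow(records)) stop("no records")
  iv <- recordIntervals(records)
  call <- resolvePartial(records$call, partial_as)
  if (!any(call == "abrogated")) {
    warning("no abrogating deletion after policy resolution; empty core")
    return(coreTable(data.frame(start = integer(), end = integer()), ref))
  }
  pos <- sort(unique(unlist(lapply(seq_len(nrow(iv)), function(k)
    intervalPositions(iv$start[k], iv$end[k])))))
  inCore <- vapply(pos, function(p) {
    covering <- linIndex(iv$start) <= linIndex(p) &
                linIndex(p) <= linIndex(iv$end)
    all(call[covering] == "abrogated")
  }, logical(1L))
  coreTable(runsToIntervals(pos[inCore]), ref)
}

#' Infer the core motif from a point-substitution scan
#'
#' Over a contiguous scanned window, the core is the maximal run of positions
#' at which every tested substitution abrogated the response; positions with
#' any retained call, and untested positions, are excluded.
#'
#' @param records a table from [perturbationRecords()]; all variants must be
#'   single substitutions. Mixed deletion/substitution input is an error.
#' @param partial_as policy for `"partial"` calls, as in [inferCoreRegion()].
#' @param ref optional reference for motif reporting.
#' @return data.frame as in [inferCoreRegion()] (zero rows if nothing
#'   abrogates).
#' @export
pointScanCore <- function(records, partial_as = "retained", ref = NULL) {
  if (!nrow(records)) stop("no records")
  ok <- vapply(records$variant, isSubstitutionVariant, logical(1L))
  if (!all(ok))
    stop("point-scan records must all be substitution variants; offending: ",
         paste(records$variant_label[!ok], collapse = ", "))
  pos <- vapply(records$variant, function(v) variantEdits(v)$start[1L],
                integer(1L))
  call <- resolvePartial(records$call, partial_as)
  tested <- sort(unique(pos))
  abro <- vapply(tested, function(p) all(call[pos == p] == "abrogated"),
                 logical(1L))
  coreTable(runsToIntervals(tested[abro]), ref)
}

#' Extract the wild-type motif over an interval
#'
#' @param ref an [IntronSeq-class].
#' @param start,end inclusive interval (must lie within the reference span).
#' @return character scalar.
#' @examples
#' coreMotif(smn2IntronReference(), 290, 295)  # "GCAGAC"
#' @export
coreMotif <- function(ref, start, end) {
  if (!validInterval(start, end)) stop("invalid interval")
  segmentAt(ref, start, end)
}

## -- TSV / JSON interfaces ---------------------------------------------------

#' Read a perturbation-scan table from TSV
#'
#' Expected columns: `variant_label`, `call` (retained|partial|abrogated) and
#' optionally `figure`.
#'
#' @param path TSV file path.
#' @return a record table as from [perturbationRecords()].
#' @export
readScanTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_label", "call")
  if (!all(need %in% names(df)))
    stop("scan TSV must have columns: ", paste(need, collapse = ", "))
  perturbationRecords(df$variant_label, df$call,
                      if ("figure" %in% names(df)) df$figure else NA_character_)
}

#' @rdname readScanTsv
#' @param records a record table.
#' @export
writeScanTsv <- function(records, path) {
  write.table(records[, c("variant_label", "call", "figure")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a core-region report as JSON
#'
#' @param core a core table from [inferCoreRegion()] or [pointScanCore()].
#' @param path output path.
#' @param policy the partial-call policy used (recorded for reproducibility).
#' @export
writeCoreReport <- function(core, path, policy = "retained") {
  jsonlite::write_json(list(policy = policy, cores = core), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
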