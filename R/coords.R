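#' @import methods
#' @importFrom stats median setNames cor rlnorm runif
#' @importFrom utils read.delim write.table head tail
NULL

## ---------------------------------------------------------------------------
## Intron coordinate arithmetic.
##
## Positions are signed integers on a number line with no zero: +1 is the
## first intronic nucleotide, -1 the last exonic one.  linIndex() maps that
## line onto contiguous integers so that spans and offsets can be computed
## with ordinary arithmetic.
## ---------------------------------------------------------------------------

#' Map signed intron positions to a contiguous integer line
#'
#' Intron coordinates have no position 0: positive values count from the first
#' intronic nucleotide, negative values count back from the exon-intron
#' junction (-1 is the last exonic residue). `linIndex()` collapses the gap at
#' zero so spans can be computed by subtraction; `posFromLin()` is its inverse.
#'
#' @param pos integer vector of signed intron positions (no zeros).
#' @param lin integer vector on the contiguous line.
#' @return `linIndex()` returns integers; `posFromLin()` returns positions.
#' @examples
#' linIndex(c(-2, -1, 1, 2))   # -1 0 1 2
#' spanLength(-2, 14)          # 16 residues, junction crossed, no position 0
#' @export
linIndex <- function(pos) {
  pos <- as.integer(pos)
  if (any(pos == 0L, na.rm = TRUE))
    stop("intron position 0 is invalid (coordinates skip zero)")
  ifelse(pos > 0L, pos, pos + 1L)
}

#' @rdname linIndex
#' @export
posFromLin <- function(lin) {
  lin <- as.integer(lin)
  ifelse(lin >= 1L, lin, lin - 1L)
}

#' @rdname linIndex
#' @param start,end interval bounds (inclusive at both ends).
#' @export
spanLength <- function(start, end) {
  linIndex(end) - linIndex(start) + 1L
}

#' Enumerate the positions of an inclusive interval
#'
#' @param start,end inclusive interval bounds in intron coordinates.
#' @return integer vector of positions, zero skipped.
#' @export
intervalPositions <- function(start, end) {
  if (spanLength(start, end) < 1L) stop("empty interval: start must be <= end")
  posFromLin(seq.int(linIndex(start), linIndex(end)))
}

validInterval <- function(start, end) {
  is.numeric(start) && is.numeric(end) && length(start) == 1L &&
    length(end) == 1L && start != 0 && end != 0 &&
    linIndex(start) <= linIndex(end)
}

## ---------------------------------------------------------------------------
## IntronSeq: an RNA segment anchored in intron coordinates
## ---------------------------------------------------------------------------

#' IntronSeq: a reference RNA segment anchored in intron coordinates
#'
#' Wraps a [Biostrings::RNAString] together with the intron position of its
#' first residue, so that any residue can be addressed by its signed intron
#' coordinate. DNA input is transcribed (T to U) and upper-cased on ingest.
#'
#' @slot residues an `RNAString`.
#' @slot origin integer; intron position of the first residue (never 0).
#' @exportClass IntronSeq
setClass("IntronSeq",
  representation(residues = "RNAString", origin = "integer"))

setValidity("IntronSeq", function(object) {
  msg <- character()
  if (length(object@origin) != 1L || is.na(object@origin) || object@origin == 0L)
    msg <- c(msg, "origin must be a single non-zero integer")
  if (length(object@residues) == 0L)
    msg <- c(msg, "empty sequence")
  if (grepl("[^ACGU]", as.character(object@residues)))
    msg <- c(msg, "residues must be over {A,C,G,U} with no gaps")
  if (length(msg)) msg else TRUE
})

#' Construct an IntronSeq
#'
#' @param x a character string or `RNAString`/`DNAString`; mixed case and DNA
#'   alphabet are accepted and normalized to uppercase RNA.
#' @param origin intron position of the first residue of `x`.
#' @return an [IntronSeq-class] object.
#' @examples
#' s <- IntronSeq("gtaagt", origin = 1)
#' residueAt(s, 2)  # "U"
#' @export
IntronSeq <- function(x, origin = 1L) {
  if (is(x, "XString")) x <- as.character(x)
  x <- toupper(gsub("[[:space:]]", "", x))
  x <- chartr("T", "U", x)
  new("IntronSeq", residues = Biostrings::RNAString(x),
      origin = as.integer(origin))
}

#' @describeIn IntronSeq number of residues.
#' @param object,x an `IntronSeq`.
#' @export
setMethod("length", "IntronSeq", function(x) length(x@residues))

setMethod("show", "IntronSeq", function(object) {
  pos <- seqPositions(object)
  cat(sprintf("IntronSeq of %d residues spanning positions %d..%d\n",
              length(object), pos[1L], pos[length(pos)]))
  cat(" ", as.character(Biostrings::subseq(object@residues, 1,
        min(60L, length(object)))),
      if (length(object) > 60L) "..." else "", "\n", sep = "")
})

#' Accessors for IntronSeq
#'
#' `seqOrigin()` gives the intron position of the first residue,
#' `seqPositions()` the coordinate of every residue, `residueAt()` the
#' residue(s) at given positions and `segmentAt()` the string over an
#' inclusive interval.
#'
#' @param x an [IntronSeq-class].
#' @param pos integer vector of intron positions.
#' @param start,end inclusive interval bounds.
#' @return characters / integers as described.
#' @export
seqOrigin <- function(x) x@origin

#' @rdname seqOrigin
#' @export
seqPositions <- function(x) {
  posFromLin(linIndex(x@origin) + seq_len(length(x)) - 1L)
}

#' @rdname seqOrigin
#' @export
seqString <- function(x) as.character(x@residues)

posToIdx <- function(x, pos) {
  idx <- linIndex(pos) - linIndex(x@origin) + 1L
  bad <- idx < 1L | idx > length(x)
  if (any(bad))
    stop("position(s) outside reference span: ",
         paste(pos[bad], collapse = ", "))
  idx
}

#' @rdname seqOrigin
#' @export
residueAt <- function(x, pos) {
  strsplit(seqString(x), "")[[1L]][posToIdx(x, pos)]
}

#' @rdname seqOrigin
#' @export
segmentAt <- function(x, start, end) {
  if (!validInterval(start, end)) stop("invalid interval")
  paste(residueAt(x, intervalPositions(start, end)), collapse = "")
}

#' @rdname seqOrigin
#' @export
subSeq <- function(x, start, end) {
  IntronSeq(segmentAt(x, start, end), origin = start)
}

## ---------------------------------------------------------------------------
## Variants: named deletions / substitutions
## ---------------------------------------------------------------------------

#' Variant: a named set of deletions and substitutions
#'
#' @slot label the variant name, e.g. `"289G"` or `"Δ281-300"`.
#' @slot edits a data.frame with columns `kind` ("deletion"/"substitution"),
#'   `start`, `end` (inclusive, equal for substitutions) and `base`
#'   (replacement residue, NA for deletions).
#' @exportClass Variant
setClass("Variant", representation(label = "character", edits = "data.frame"))

setValidity("Variant", function(object) {
  e <- object@edits
  msg <- character()
  need <- c("kind", "start", "end", "base")
  if (!all(need %in% names(e))) return("edits must have kind/start/end/base")
  if (nrow(e)) {
    if (!all(e$kind %in% c("deletion", "substitution")))
      msg <- c(msg, "kind must be deletion or substitution")
    if (any(e$start == 0L | e$end == 0L))
      msg <- c(msg, "position 0 is invalid")
    if (any(linIndex(e$start) > linIndex(e$end)))
      msg <- c(msg, "start must be <= end")
    sub <- e$kind == "substitution"
    if (any(sub & (is.na(e$base) | !e$base %in% c("A", "C", "G", "U"))))
      msg <- c(msg, "substitution base must be one of A,C,G,U")
    if (any(sub & e$start != e$end))
      msg <- c(msg, "substitutions are single-position")
    covered <- unlist(lapply(seq_len(nrow(e)), function(i)
      intervalPositions(e$start[i], e$end[i])))
    if (anyDuplicated(covered))
      msg <- c(msg, "edits overlap")
  }
  if (length(msg)) msg else TRUE
})

emptyEdits <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             base = character(), stringsAsFactors = FALSE)
}

setMethod("show", "Variant", function(object) {
  cat(sprintf("Variant '%s' with %d edit(s)\n", object@label,
              nrow(object@edits)))
})

#' @rdname parseVariantLabel
#' @param label variant name.
#' @param edits optional pre-built edits data.frame (then `label` is only a
#'   name and is not parsed).
#' @export
Variant <- function(label, edits = NULL) {
  if (is.null(edits)) return(parseVariantLabel(label))
  new("Variant", label = label, edits = edits)
}

#' Parse the field's mutant nomenclature into a structured variant
#'
#' Deletions are written `Δ<start>-<end>` (en dash or hyphen; a "d" or
#' "del" prefix is also accepted) and remove the inclusive interval.
#' Substitutions are slash-separated `<pos><base>` tokens: `"289G"` replaces
#' the residue at intron position 289 with G. `"WT"` denotes no edits.
#'
#' @param label character scalar.
#' @return a [Variant-class].
#' @examples
#' parseVariantLabel("Δ281-300")
#' parseVariantLabel("286G/288U/289G/298A")
#' @export
parseVariantLabel <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label))
    stop("malformed variant label: empty")
  lab <- trimws(label)
  if (toupper(lab) %in% c("WT", "WILD-TYPE", "WILDTYPE"))
    return(new("Variant", label = lab, edits = emptyEdits()))
  norm <- gsub("–|—", "-", lab)
  delRe <- "^(?:Δ|[Dd](?:el)?)\\s*([0-9]+)\\s*-\\s*([0-9]+)$"
  if (grepl(delRe, norm)) {
    m <- regmatches(norm, regexec(delRe, norm))[[1L]]
    start <- as.integer(m[2L]); end <- as.integer(m[3L])
    if (start == 0L || end == 0L)
      stop("malformed token '", lab, "': position 0 is invalid")
    edits <- data.frame(kind = "deletion", start = start, end = end,
                        base = NA_character_, stringsAsFactors = FALSE)
    return(new("Variant", label = lab, edits = edits))
  }
  toks <- strsplit(norm, "/", fixed = TRUE)[[1L]]
  subRe <- "^(-?[0-9]+)([A-Za-z])$"
  edits <- lapply(toks, function(tk) {
    tk <- trimws(tk)
    if (!grepl(subRe, tk)) stop("malformed token '", tk, "' in '", lab, "'")
    m <- regmatches(tk, regexec(subRe, tk))[[1L]]
    p <- as.integer(m[2L]); b <- toupper(chartr("Tt", "Uu", m[3L]))
    if (p == 0L) stop("malformed token '", tk, "': position 0 is invalid")
    if (!b %in% c("A", "C", "G", "U"))
      stop("malformed token '", tk, "': base must be A, C, G or U")
    data.frame(kind = "substitution", start = p, end = p, base = b,
               stringsAsFactors = FALSE)
  })
  new("Variant", label = lab, edits = do.call(rbind, edits))
}

#' @rdname parseVariantLabel
#' @param v a `Variant`.
#' @export
variantLabel <- function(v) v@label

#' @rdname parseVariantLabel
#' @export
variantEdits <- function(v) v@edits

#' @rdname parseVariantLabel
#' @export
isDeletionVariant <- function(v) {
  nrow(v@edits) > 0L && all(v@edits$kind == "deletion")
}

#' @rdname parseVariantLabel
#' @export
isSubstitutionVariant <- function(v) {
  nrow(v@edits) > 0L && all(v@edits$kind == "substitution")
}

## ---------------------------------------------------------------------------
## Applying a variant: mutant sequence + coordinate lift
## ---------------------------------------------------------------------------

#' MutatedSeq: a mutant sequence plus its coordinate lift table
#'
#' Result of [applyVariant()]. The lift table maps every wild-type position of
#' the reference to the corresponding position in the mutant numbering, or NA
#' where the residue was deleted. Mutant positions are renumbered contiguously
#' from the (unchanged) origin.
#'
#' @slot seq the mutant [IntronSeq-class].
#' @slot lift data.frame with columns `wt_pos`, `mut_pos` (NA = deleted).
#' @slot variant the applied [Variant-class].
#' @exportClass MutatedSeq
setClass("MutatedSeq",
  representation(seq = "IntronSeq", lift = "data.frame", variant = "Variant"))

setMethod("show", "MutatedSeq", function(object) {
  cat(sprintf("MutatedSeq: variant '%s', %d -> %d residues\n",
              object@variant@label, nrow(object@lift), length(object@seq)))
})

#' Apply a variant to a reference sequence
#'
#' Deletions excise their inclusive interval; substitutions replace in place.
#' A coordinate lift table (wild-type position to mutant position, NA where
#' deleted) is returned alongside the edited sequence.
#'
#' @param ref an [IntronSeq-class].
#' @param v a [Variant-class]; all edits must fall inside the reference span.
#' @return a [MutatedSeq-class].
#' @examples
#' ref <- IntronSeq("GUAAGU", origin = 1)
#' ms <- applyVariant(ref, parseVariantLabel("3G"))
#' seqString(mutantSeq(ms))
#' @export
applyVariant <- function(ref, v) {
  stopifnot(is(ref, "IntronSeq"), is(v, "Variant"))
  wt_pos <- seqPositions(ref)
  res <- strsplit(seqString(ref), "")[[1L]]
  keep <- rep(TRUE, length(res))
  e <- v@edits
  for (i in seq_len(nrow(e))) {
    idx <- posToIdx(ref, intervalPositions(e$start[i], e$end[i]))
    if (e$kind[i] == "deletion") keep[idx] <- FALSE else res[idx] <- e$base[i]
  }
  mut <- res[keep]
  if (!length(mut)) stop("variant deletes the entire reference")
  mut_lin <- linIndex(ref@origin) + seq_len(length(mut)) - 1L
  mut_pos <- rep(NA_integer_, length(res))
  mut_pos[keep] <- posFromLin(mut_lin)
  new("MutatedSeq",
      seq = IntronSeq(paste(mut, collapse = ""), origin = ref@origin),
      lift = data.frame(wt_pos = wt_pos, mut_pos = mut_pos),
      variant = v)
}

#' @rdname applyVariant
#' @param ms a `MutatedSeq`.
#' @export
mutantSeq <- function(ms) ms@seq

#' @rdname applyVariant
#' @export
liftTable <- function(ms) ms@lift

#' Lift wild-type positions into mutant coordinates
#'
#' @param ms a [MutatedSeq-class].
#' @param pos wild-type positions.
#' @return integer vector of mutant positions (NA where deleted).
#' @export
liftPosition <- function(ms, pos) {
  ms@lift$mut_pos[match(pos, ms@lift$wt_pos)]
}

## ---------------------------------------------------------------------------
## FASTA I/O with an offset-carrying header convention
## ---------------------------------------------------------------------------

#' Read / write IntronSeq objects as FASTA
#'
#' The header convention is `>name offset=<origin>`, recording where residue 1
#' of the record sits in intron coordinates (negative = exonic).
#'
#' @param path file path.
#' @param x a named list of [IntronSeq-class] objects (for writing).
#' @return `readIntronFasta()` returns a named list of `IntronSeq`.
#' @export
readIntronFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    off <- 1L
    m <- regexec("offset=(-?[0-9]+)", hdr)[[1L]]
    if (m[1L] != -1L)
      off <- as.integer(regmatches(hdr, regexec("offset=(-?[0-9]+)", hdr))[[1L]][2L])
    IntronSeq(as.character(set[[i]]), origin = off)
  })
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname readIntronFasta
#' @export
writeIntronFasta <- function(x, path) {
  if (is(x, "IntronSeq")) x <- list(seq = x)
  lines <- unlist(lapply(names(x), function(nm) {
    c(sprintf(">%s offset=%d", nm, seqOrigin(x[[nm]])),
      seqString(x[[nm]]))
  }))
  writeLines(lines, path)
  invisible(path)
}
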