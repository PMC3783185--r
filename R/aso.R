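## ---------------------------------------------------------------------------
## Antisense oligonucleotide mapping and splicing-effect rules.
##
## An ASO is identified by its annealing interval in intron coordinates.
## Effect calls are direction-only (stimulatory / inhibitory / neutral),
## derived from which structural elements the ASO sequesters and whether the
## 10C-anchored long-distance duplex can still form in the minigene variant.
## ---------------------------------------------------------------------------

#' Build an ASO record table
#'
#' The field convention "ASO <start>-<end>" names the first and last intron
#' positions of the target site; `length_nt` is the target span.
#'
#' @param name ASO names.
#' @param start,end inclusive target intervals (intron coordinates; negative
#'   = exonic).
#' @return data.frame with columns `name`, `start`, `end`, `length_nt`.
#' @examples
#' asoRecords("ASO 283-297", 283, 297)
#' @export
asoRecords <- function(name, start, end) {
  ok <- mapply(validInterval, start, end)
  if (!all(ok)) stop("invalid ASO interval(s): ",
                     paste(name[!ok], collapse = ", "))
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             length_nt = spanLength(start, end), stringsAsFactors = FALSE)
}

#' Parse "ASO <start>-<end>" style names into records
#'
#' @param names character vector like `"ASO 283-297"`.
#' @export
parseAsoNames <- function(names) {
  m <- regmatches(names, regexec("(-?[0-9]+)\\s*[-–]\\s*(-?[0-9]+)\\s*$",
                                 names))
  bad <- vapply(m, function(x) length(x) == 0L, logical(1L))
  if (any(bad)) stop("cannot parse ASO name(s): ",
                     paste(names[bad], collapse = ", "))
  asoRecords(names,
             vapply(m, function(x) as.integer(x[2L]), 1L),
             vapply(m, function(x) as.integer(x[3L]), 1L))
}

#' The named ASOs used throughout the intron 7 work
#'
#' F14 covers the first 14 intronic residues (1-14, sequestering 10C), L14
#' the last 14 residues of ISS-N1 (11-24, leaving 10C free), Anti-N1 the
#' 20-mer ISS-N1 ASO (10-29), ASO-M the 23-mer against the mutated ISTL1 3'
#' strand (275-297), ASO-D the 23-mer against the ISTL1 5' strand across the
#' junction (-9..14), and "ASO 276-290" / "ASO 283-297" the microwalk ASOs.
#' "ASO-N2" is the 23-mer fully covering ISS-N2 (275-297).
#'
#' @return an ASO record table.
#' @export
knownAsos <- function() {
  rbind(
    asoRecords("F14", 1L, 14L),
    asoRecords("L14", 11L, 24L),
    asoRecords("Anti-N1", 10L, 29L),
    asoRecords("ASO 276-290", 276L, 290L),
    asoRecords("ASO 283-297", 283L, 297L),
    asoRecords("ASO-M", 275L, 297L),
    asoRecords("ASO-D", -9L, 14L),
    asoRecords("ASO-N2", 275L, 297L)
  )
}

asoByName <- function(name) {
  tab <- knownAsos()
  hit <- tab[tab$name == name, , drop = FALSE]
  if (nrow(hit)) hit else parseAsoNames(name)
}

asoCovers <- function(aso, pos) {
  linIndex(aso$start) <= linIndex(pos) & linIndex(pos) <= linIndex(aso$end)
}

intervalOverlapFraction <- function(aso, positions) {
  mean(vapply(positions, function(p) asoCovers(aso, p), logical(1L)))
}

#' Which structural elements does an ASO sequester?
#'
#' For every helix of the model, reports the fraction of each strand covered
#' by the ASO target and whether the opposite strand is thereby released
#' (its pairing partner fully covered). `tenC_free` records whether intron
#' position 10 lies outside the ASO target.
#'
#' @param aso a one-row ASO record (or a name resolvable by [knownAsos()]).
#' @param model a [StructureModel-class].
#' @param ref reference sequence (bounds checking).
#' @return data.frame, one row per helix, with coverage fractions and
#'   release flags; `tenC_free` is attached as an attribute and column.
#' @export
sequestration <- function(aso, model = wtStructureModel(ref),
                          ref = smn2IntronReference()) {
  if (is.character(aso)) aso <- asoByName(aso)
  pos <- seqPositions(ref)
  if (linIndex(aso$start) < linIndex(pos[1L]) ||
      linIndex(aso$end) > linIndex(pos[length(pos)]))
    stop("ASO target outside reference span")
  rows <- lapply(model@helices, function(h) {
    f5 <- intervalOverlapFraction(aso, helixStrand5(h))
    f3 <- intervalOverlapFraction(aso, helixStrand3(h))
    data.frame(element = helixName(h),
               frac_strand5 = f5, frac_strand3 = f3,
               overlapped = f5 > 0 | f3 > 0,
               strand5_released = f3 == 1,  # partner strand fully covered
               strand3_released = f5 == 1)
  })
  out <- do.call(rbind, rows)
  out$tenC_free <- !asoCovers(aso, 10L)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Effect rules
## ---------------------------------------------------------------------------

overlapsInterval <- function(aso, iv) {
  linIndex(aso$start) <= linIndex(iv[2L]) &&
    linIndex(aso$end) >= linIndex(iv[1L])
}

#' Predict the splicing-effect direction of an ASO on a minigene variant
#'
#' Ordered mechanistic rules; the first match fires:
#' \describe{
#'   \item{R1}{ASO covers intron position 10 and overlaps ISS-N1: the
#'     inhibitory 10C is sequestered along with the silencer - stimulatory.}
#'   \item{R2}{ASO overlaps ISS-N1 but leaves position 10 free, and the
#'     10C-anchored duplex (>= `min_bp` Watson-Crick pairs pairing position
#'     10, see [istl1Forms()]) forms in the variant - inhibitory.}
#'   \item{R3}{ASO overlaps ISS-N1, position 10 free, duplex cannot form -
#'     stimulatory.}
#'   \item{R4}{ASO covers at least `release_frac` of the 3' strand of one of
#'     the internal stems (the strands whose union is ISS-N2) - stimulatory.}
#'   \item{R5}{otherwise - neutral.}
#' }
#' Only the response direction is predicted; baseline splicing levels of the
#' variant itself are not.
#'
#' @param variant a [Variant-class] (or label).
#' @param aso a one-row ASO record or a known ASO name.
#' @param ref wild-type reference.
#' @param model wild-type [StructureModel-class].
#' @param min_bp duplex threshold for "ISTL1 forms"; default 6.
#' @param release_frac strand-coverage threshold for R4; default 0.8.
#' @return list with `call` ("stimulatory"/"inhibitory"/"neutral"),
#'   `fired_rules` (character), and `istl1` (the [istl1Forms()] result).
#' @examples
#' predictEffect("WT", "L14")$call   # "inhibitory"
#' predictEffect("WT", "F14")$call   # "stimulatory"
#' @export
predictEffect <- function(variant, aso, ref = smn2IntronReference(),
                          model = wtStructureModel(ref), min_bp = 6L,
                          release_frac = 0.8) {
  if (is.character(variant)) variant <- parseVariantLabel(variant)
  if (is.character(aso)) aso <- asoByName(aso)
  forms <- istl1Forms(ref, variant, model, min_bp = min_bp)
  covers10 <- asoCovers(aso, 10L)
  onIssN1 <- overlapsInterval(aso, issN1())
  if (covers10 && onIssN1)
    return(list(call = "stimulatory", fired_rules = "R1", istl1 = forms))
  if (onIssN1 && !covers10) {
    if (forms$forms)
      return(list(call = "inhibitory", fired_rules = "R2", istl1 = forms))
    return(list(call = "stimulatory", fired_rules = "R3", istl1 = forms))
  }
  istls <- intersect(names(model@helices), c("ISTL1", "ISTL2", "ISTL3"))
  fr3 <- vapply(istls, function(nm)
    intervalOverlapFraction(aso, helixStrand3(model@helices[[nm]])),
    numeric(1L))
  if (length(fr3) && any(fr3 >= release_frac))
    return(list(call = "stimulatory",
                fired_rules = c("R4", paste0("R4:", istls[fr3 >= release_frac])),
                istl1 = forms))
  list(call = "neutral", fired_rules = "R5", istl1 = forms)
}

#' Run an antisense walk over a set of ASOs
#'
#' Applies [sequestration()] and [predictEffect()] (against the wild type by
#' default) to each ASO and annotates coverage of the ISS-N2 region (intron
#' 275-297).
#'
#' @param asos an ASO record table ([asoRecords()]); may be empty.
#' @param ref reference sequence.
#' @param model wild-type structure model.
#' @param variant minigene variant the walk is performed on; default WT.
#' @return data.frame with one row per ASO: name, target, length, effect
#'   call, fired rule, fraction of ISS-N2 covered, and whether the ASO fully
#'   covers ISS-N2 (with the covering length).
#' @export
asoWalk <- function(asos, ref = smn2IntronReference(),
                    model = wtStructureModel(ref), variant = "WT") {
  if (!nrow(asos))
    return(data.frame(name = character(), start = integer(), end = integer(),
                      length_nt = integer(), call = character(),
                      fired_rule = character(), issN2_coverage = numeric(),
                      covers_issN2 = logical()))
  n2pos <- intervalPositions(issN2()[1L], issN2()[2L])
  rows <- lapply(seq_len(nrow(asos)), function(k) {
    aso <- asos[k, , drop = FALSE]
    eff <- predictEffect(variant, aso, ref, model)
    cov <- mean(vapply(n2pos, function(p) asoCovers(aso, p), logical(1L)))
    data.frame(aso[, c("name", "start", "end", "length_nt")],
               call = eff$call, fired_rule = eff$fired_rules[1L],
               issN2_coverage = cov, covers_issN2 = cov == 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "issN2") <- issN2()
  out
}

#' @rdname asoWalk
#' @param walk a walk table.
#' @param path output path.
#' @export
writeWalkReport <- function(walk, path) {
  jsonlite::write_json(list(issN2 = issN2(), walk = walk), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---------------------------------------------------------------------------
## The transcribed (variant, ASO) response table and concordance harness
## ---------------------------------------------------------------------------

#' Transcribed minigene/ASO splicing responses
#'
#' The (variant, ASO) response directions transcribed from the deletion
#' scans, the point-substitution scan and the compensatory-mutation series:
#' `observed` is "stimulatory" when the ASO promoted exon 7 inclusion in
#' that variant, "inhibitory" when it promoted skipping. Rows the source
#' reports as partial ("to a lesser extent" / suppressed-but-not-reversed)
#' carry `clear = FALSE` and are excluded from the concordance harness.
#'
#' @return data.frame with columns `variant_label`, `aso`, `observed`,
#'   `clear`, `figure`.
#' @export
paperSplicingResponses <- function() {
  del20 <- fig2DeletionScan()
  del10 <- fig3aDeletionScan()
  del5 <- fig3bDeletionScan()
  pts <- fig4PointScan()
  fromScan <- function(rec, figure) {
    data.frame(variant_label = rec$variant_label, aso = "L14",
               observed = ifelse(rec$call == "abrogated", "stimulatory",
                          ifelse(rec$call == "retained", "inhibitory", NA)),
               clear = rec$call != "partial", figure = figure,
               stringsAsFactors = FALSE)
  }
  l14 <- rbind(fromScan(del20, "20-nt scan"), fromScan(del10, "10-nt scan"),
               fromScan(del5, "5-nt scan"), fromScan(pts, "point scan"))
  extra <- data.frame(
    variant_label = c("WT", "Δ93-281", "Δ330-412", "Δ290-295", "Δ282-287",
                      "8C", "10G", "290C", "292G", "8C/292G", "10G/290C"),
    aso = "L14",
    observed = c("inhibitory", "inhibitory", "inhibitory", "stimulatory",
                 "inhibitory", "stimulatory", "stimulatory", "stimulatory",
                 "stimulatory", "inhibitory", "inhibitory"),
    clear = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              FALSE),  # 10G/290C: suppression only, not a clear reversal
    figure = c("WT", rep("large deletions", 2), rep("motif swap", 2),
               rep("compensatory series", 6)),
    stringsAsFactors = FALSE)
  f14 <- data.frame(
    variant_label = c("WT", del20$variant_label, del10$variant_label,
                      "288U/289G", "286G/288U/289G/298A"),
    aso = "F14", observed = "stimulatory", clear = TRUE,
    figure = "F14 response", stringsAsFactors = FALSE)
  out <- rbind(l14, extra, f14)
  rownames(out) <- NULL
  out
}

#' Concordance of predicted vs observed ASO responses
#'
#' Runs [predictEffect()] for every clear row of
#' [paperSplicingResponses()] (or a user table of the same shape) and
#' tabulates agreement. Partial rows are listed but not scored.
#'
#' @param responses a response table; defaults to the transcribed one.
#' @param ref,model reference and wild-type model.
#' @return list with `results` (per-row data.frame including `predicted` and
#'   `match`), `n_clear`, `n_match`, and `excluded` (the partial rows).
#' @export
responseConcordance <- function(responses = paperSplicingResponses(),
                                ref = smn2IntronReference(),
                                model = wtStructureModel(ref)) {
  clear <- responses[responses$clear, , drop = FALSE]
  pred <- vapply(seq_len(nrow(clear)), function(k)
    predictEffect(clear$variant_label[k], clear$aso[k], ref, model)$call, "")
  res <- cbind(clear, predicted = pred,
               match = pred == clear$observed)
  list(results = res, n_clear = nrow(res), n_match = sum(res$match),
       excluded = responses[!responses$clear, , drop = FALSE])
}

#' Read / write ASO definition tables
#'
#' TSV columns `name`, `start`, `end`; JSON as a records array.
#'
#' @param path file path.
#' @export
readAsoTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  asoRecords(df$name, df$start, df$end)
}

#' @rdname readAsoTsv
#' @param asos an ASO record table.
#' @export
writeAsoTsv <- function(asos, path) {
  write.table(asos[, c("name", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
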