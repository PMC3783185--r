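## ---------------------------------------------------------------------------
## SHAPE (1M7) reactivity quantification from primer-extension lanes.
##
## raw = max(0, 1M7 - DMSO) per position; normalized per extension primer to
## the most reactive position; classes low / moderate / high at 0.3 / 0.5.
## ---------------------------------------------------------------------------

#' LaneProfile: per-position band intensities for one extension primer
#'
#' @slot primer_id primer identifier.
#' @slot positions strictly increasing intron positions.
#' @slot intensity_1m7,intensity_dmso nonnegative intensities (arbitrary
#'   units), one per position.
#' @exportClass LaneProfile
setClass("LaneProfile",
  representation(primer_id = "character", positions = "integer",
                 intensity_1m7 = "numeric", intensity_dmso = "numeric"))

setValidity("LaneProfile", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (length(object@intensity_1m7) != n || length(object@intensity_dmso) != n)
    msg <- c(msg, "intensity vectors must match positions in length")
  if (any(object@positions == 0L)) msg <- c(msg, "position 0 is invalid")
  if (n > 1L && any(diff(linIndex(object@positions)) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(object@intensity_1m7 < 0) || any(object@intensity_dmso < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @rdname LaneProfile-class
#' @param primer_id primer identifier.
#' @param positions intron positions (strictly increasing).
#' @param intensity_1m7,intensity_dmso nonnegative intensities.
#' @export
LaneProfile <- function(primer_id, positions, intensity_1m7, intensity_dmso) {
  new("LaneProfile", primer_id = as.character(primer_id),
      positions = as.integer(positions),
      intensity_1m7 = as.numeric(intensity_1m7),
      intensity_dmso = as.numeric(intensity_dmso))
}

setMethod("show", "LaneProfile", function(object) {
  cat(sprintf("LaneProfile '%s': %d positions (%d..%d)\n", object@primer_id,
              length(object@positions), min(object@positions),
              max(object@positions)))
})

#' ReactivityProfile: normalized, classified per-position reactivities
#'
#' Backing table columns: `position`, `raw`, `normalized`, `class`
#' (low/moderate/high or NA before classification), `falloff` (logical),
#' `primer_id`.
#'
#' @slot data the backing data.frame.
#' @exportClass ReactivityProfile
setClass("ReactivityProfile", representation(data = "data.frame"))

setValidity("ReactivityProfile", function(object) {
  need <- c("position", "raw", "normalized", "class", "falloff", "primer_id")
  if (!all(need %in% names(object@data)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(object@data)), collapse = ", ")))
  cl <- object@data$class
  if (!all(is.na(cl) | cl %in% c("low", "moderate", "high")))
    return("class must be low/moderate/high or NA")
  if (any(object@data$normalized < 0 | object@data$normalized > 1, na.rm = TRUE))
    return("normalized must lie in [0,1]")
  TRUE
})

setMethod("show", "ReactivityProfile", function(object) {
  d <- object@data
  cat(sprintf("ReactivityProfile: %d positions, %d classified, %d falloff\n",
              nrow(d), sum(!is.na(d$class)), sum(d$falloff)))
})

#' @rdname ReactivityProfile-class
#' @param data a data.frame with the backing columns (missing ones are
#'   initialized).
#' @export
ReactivityProfile <- function(data) {
  if (!"class" %in% names(data)) data$class <- NA_character_
  if (!"falloff" %in% names(data)) data$falloff <- FALSE
  if (!"primer_id" %in% names(data)) data$primer_id <- NA_character_
  rownames(data) <- NULL
  new("ReactivityProfile", data = data)
}

#' @rdname ReactivityProfile-class
#' @param profile a `ReactivityProfile`.
#' @export
profileData <- function(profile) profile@data

#' @rdname ReactivityProfile-class
#' @export
profilePositions <- function(profile) profile@data$position

#' Compute raw and normalized reactivity from one primer's lanes
#'
#' Per position, `raw = max(0, intensity_1m7 - intensity_dmso)` (negative
#' differences are clamped: negative reactivity is physically meaningless);
#' `normalized = raw / max(raw)` over the primer's positions, so the most
#' reactive position gets 1. An all-zero lane yields all-zero normalized
#' values and a degenerate-profile warning.
#'
#' @param lane a [LaneProfile-class].
#' @return an unclassified [ReactivityProfile-class].
#' @export
computeReactivity <- function(lane) {
  stopifnot(is(lane, "LaneProfile"))
  raw <- pmax(0, lane@intensity_1m7 - lane@intensity_dmso)
  mx <- max(raw)
  if (mx <= 0) {
    warning("degenerate profile for primer '", lane@primer_id,
            "': no positive reactivity")
    normalized <- rep(0, length(raw))
  } else normalized <- raw / mx
  ReactivityProfile(data.frame(
    position = lane@positions, raw = raw, normalized = normalized,
    class = NA_character_, falloff = FALSE, primer_id = lane@primer_id,
    stringsAsFactors = FALSE))
}

#' Classify normalized reactivities
#'
#' high iff normalized > 0.5; moderate iff 0.3 <= normalized <= 0.5
#' (both bounds inclusive, so a tie at 0.5 is moderate); low otherwise.
#' Idempotent.
#'
#' @param profile a [ReactivityProfile-class] with normalized values.
#' @return the profile with `class` filled in.
#' @export
classifyReactivity <- function(profile) {
  d <- profile@data
  d$class <- ifelse(d$normalized > 0.5, "high",
             ifelse(d$normalized >= 0.3, "moderate", "low"))
  ReactivityProfile(d)
}

#' Count protected residues in a profile
#'
#' Counts the residues of `residues` whose reactivity class is `low`.
#' Positions flagged as reverse-transcriptase falloffs carry no usable
#' structural signal and are excluded from the count.
#'
#' @param profile a classified [ReactivityProfile-class].
#' @param residues intron positions; all must be present in the profile.
#' @return integer count.
#' @export
countProtected <- function(profile, residues) {
  d <- profile@data
  miss <- setdiff(residues, d$position)
  if (length(miss))
    stop("positions absent from profile: ", paste(miss, collapse = ", "))
  sel <- d[d$position %in% residues & !d$falloff, , drop = FALSE]
  sum(sel$class == "low", na.rm = TRUE)
}

#' Flag reverse-transcriptase falloff positions
#'
#' A falloff is a premature RTase stop present in the no-reagent control as
#' well as the modified lane; it confounds reactivity at its position.
#' Positions whose DMSO-lane intensity exceeds `threshold` times the median
#' DMSO intensity of the primer window are flagged.
#'
#' @param lane a [LaneProfile-class].
#' @param threshold multiple of the window median; `Inf` flags nothing.
#' @return integer vector of flagged positions.
#' @export
detectFalloff <- function(lane, threshold = 3) {
  med <- median(lane@intensity_dmso)
  if (!is.finite(threshold) || med <= 0) {
    if (is.finite(threshold) && med <= 0) med <- 0
    else return(integer())
  }
  lane@positions[lane@intensity_dmso > threshold * med]
}

#' @rdname detectFalloff
#' @param profile a [ReactivityProfile-class].
#' @param positions positions to mark; their class becomes NA (unreliable).
#' @export
flagFalloff <- function(profile, positions) {
  d <- profile@data
  hit <- d$position %in% positions
  d$falloff[hit] <- TRUE
  d$class[hit] <- NA_character_
  ReactivityProfile(d)
}

#' Merge per-primer profiles into one substrate-wide profile
#'
#' Normalization is per primer, so merged values are comparable class-wise
#' only. At positions covered by several primers the value from the primer
#' whose window center is nearest wins; conflicts between discarded and kept
#' classes are recorded in the `conflicts` attribute.
#'
#' @param profiles list of [ReactivityProfile-class] objects.
#' @return a [ReactivityProfile-class] covering the union of positions, with
#'   per-position provenance in `primer_id`.
#' @export
mergePrimers <- function(profiles) {
  if (!length(profiles)) stop("no profiles to merge")
  all <- do.call(rbind, lapply(profiles, profileData))
  centers <- vapply(profiles, function(p) {
    pos <- linIndex(p@data$position); (min(pos) + max(pos)) / 2
  }, numeric(1L))
  names(centers) <- vapply(profiles, function(p) p@data$primer_id[1L], "")
  all$dist <- abs(linIndex(all$position) - centers[all$primer_id])
  ord <- order(linIndex(all$position), all$dist)
  all <- all[ord, , drop = FALSE]
  dup <- duplicated(all$position)
  conflicts <- character()
  if (any(dup)) {
    for (p in unique(all$position[dup])) {
      cls <- unique(all$class[all$position == p])
      cls <- cls[!is.na(cls)]
      if (length(cls) > 1L)
        conflicts <- c(conflicts, sprintf(
          "position %d: classes %s; kept nearest-center primer", p,
          paste(cls, collapse = "/")))
    }
  }
  out <- all[!dup, setdiff(names(all), "dist"), drop = FALSE]
  res <- ReactivityProfile(out)
  attr(res, "conflicts") <- conflicts
  res
}

#' Differential SHAPE profile between two conditions
#'
#' Per position, `delta = alt_normalized - ref_normalized`; the three-way
#' call is `protected` when `delta <= -delta_margin`, `exposed` when
#' `delta >= delta_margin`, `unchanged` otherwise. Positions flagged as
#' falloff in either profile are called NA.
#'
#' @param ref_profile,alt_profile classified [ReactivityProfile-class]
#'   objects over identical positions.
#' @param delta_margin normalized-units margin; default 0.15.
#' @return data.frame with columns `position`, `delta`, `call`.
#' @export
differentialProfile <- function(ref_profile, alt_profile, delta_margin = 0.15) {
  a <- profileData(ref_profile); b <- profileData(alt_profile)
  if (!identical(a$position, b$position))
    stop("profiles are not position-aligned")
  delta <- b$normalized - a$normalized
  call <- ifelse(delta <= -delta_margin, "protected",
          ifelse(delta >= delta_margin, "exposed", "unchanged"))
  call[a$falloff | b$falloff] <- NA_character_
  data.frame(position = a$position, delta = delta, call = call,
             stringsAsFactors = FALSE)
}

#' Concordance between a reactivity profile and a structure model
#'
#' Fraction of evaluable positions whose reactivity class is consistent with
#' the model: base-paired positions should be `low`; unpaired positions
#' should be `moderate` or `high`. Falloff-flagged and unclassified
#' positions are not evaluable.
#'
#' @param profile a classified [ReactivityProfile-class].
#' @param model a [StructureModel-class].
#' @return a number in `[0, 1]` (NA when nothing is evaluable).
#' @export
structureConcordance <- function(profile, model) {
  d <- profileData(profile)
  eval <- d[!d$falloff & !is.na(d$class), , drop = FALSE]
  eval <- eval[eval$position %in% modelPositions(model), , drop = FALSE]
  if (!nrow(eval)) return(NA_real_)
  paired <- isPaired(model, eval$position)
  ok <- ifelse(paired, eval$class == "low",
               eval$class %in% c("moderate", "high"))
  mean(ok)
}

## -- TSV / export interfaces -------------------------------------------------

#' Read primer-extension lanes from TSV
#'
#' Expected columns: `position`, `primer_id`, `intensity_1m7`,
#' `intensity_dmso`. One [LaneProfile-class] is returned per primer.
#'
#' @param path TSV file path.
#' @return named list of [LaneProfile-class].
#' @export
readLaneTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "primer_id", "intensity_1m7", "intensity_dmso")
  if (!all(need %in% names(df)))
    stop("lane TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$primer_id), function(g) {
    g <- g[order(linIndex(g$position)), , drop = FALSE]
    LaneProfile(g$primer_id[1L], g$position, g$intensity_1m7, g$intensity_dmso)
  })
  out
}

#' @rdname readLaneTsv
#' @param lanes list of [LaneProfile-class].
#' @export
writeLaneTsv <- function(lanes, path) {
  if (is(lanes, "LaneProfile")) lanes <- list(lanes)
  df <- do.call(rbind, lapply(lanes, function(l)
    data.frame(position = l@positions, primer_id = l@primer_id,
               intensity_1m7 = l@intensity_1m7,
               intensity_dmso = l@intensity_dmso)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reactivity profile as TSV
#'
#' @param profile a [ReactivityProfile-class].
#' @param path output path.
#' @export
writeProfileTsv <- function(profile, path) {
  write.table(profileData(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path) {
  ReactivityProfile(read.delim(path, stringsAsFactors = FALSE))
}

#' Export reactivities in the two-column convention of structure-drawing tools
#'
#' Writes `position<TAB>reactivity` with -999 for no-data (falloff or
#' unmeasured) positions.
#'
#' @param profile a [ReactivityProfile-class].
#' @param path output path.
#' @export
writeShapeExport <- function(profile, path) {
  d <- profileData(profile)
  val <- ifelse(d$falloff, -999, d$normalized)
  write.table(data.frame(position = d$position, reactivity = val), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
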