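## ---------------------------------------------------------------------------
## Synthetic-data generation: primer-extension lane intensities from a
## ground-truth structure, and perturbation-scan phenotype tables from a
## planted core.  Everything is seeded and bit-reproducible.
## ---------------------------------------------------------------------------

#' Parameters for the chemical-probing simulator
#'
#' Modification propensities: interior base-paired residues `p_mod_paired`,
#' helix-terminal (outermost-pair) and wobble residues `p_mod_terminal`,
#' unpaired residues `p_mod_unpaired`
#' (`0 <= paired < terminal < unpaired <= 1`). Lane intensities are
#' `amplitude * p + dmso_background` (modified lane) and `dmso_background`
#' (control lane), each multiplied by independent lognormal noise with
#' coefficient of variation `noise_cv`. `falloff_sites` is a data.frame
#' `(position, stop_fraction)`: reverse-transcriptase stops that add
#' `stop_fraction * amplitude` to both lanes. `p_mod_override` is a named
#' numeric vector of per-position propensities that replace the structural
#' assignment (used to emulate residue-specific damping such as low-reactive
#' cytosines).
#'
#' @param p_mod_unpaired,p_mod_terminal,p_mod_paired modification
#'   propensities.
#' @param dmso_background mean control-lane stop intensity (arbitrary units).
#' @param noise_cv multiplicative lognormal coefficient of variation.
#' @param falloff_sites data.frame with columns `position`, `stop_fraction`.
#' @param seed integer RNG seed.
#' @param amplitude signal scale of a fully modified position.
#' @param p_mod_override named numeric vector (names = positions).
#' @return an object of class `ProbeSimParams`.
#' @export
probeSimParams <- function(p_mod_unpaired = 0.6, p_mod_terminal = 0.35,
                           p_mod_paired = 0.05, dmso_background = 10,
                           noise_cv = 0.2,
                           falloff_sites = data.frame(position = integer(),
                                                      stop_fraction = numeric()),
                           seed = 1L, amplitude = 100,
                           p_mod_override = numeric()) {
  stopifnot(p_mod_paired >= 0, p_mod_paired < p_mod_terminal,
            p_mod_terminal < p_mod_unpaired, p_mod_unpaired <= 1,
            noise_cv >= 0, dmso_background >= 0, amplitude > 0)
  structure(list(p_mod_unpaired = p_mod_unpaired,
                 p_mod_terminal = p_mod_terminal,
                 p_mod_paired = p_mod_paired,
                 dmso_background = dmso_background, noise_cv = noise_cv,
                 falloff_sites = falloff_sites, seed = as.integer(seed),
                 amplitude = amplitude, p_mod_override = p_mod_override),
            class = "ProbeSimParams")
}

#' Ground-truth modification probabilities from a structure model
#'
#' Deterministic given model and parameters: interior paired positions get
#' `p_mod_paired`, helix-terminal and wobble positions `p_mod_terminal`,
#' unpaired positions `p_mod_unpaired`; per-position overrides are applied
#' last.
#'
#' @param model a [StructureModel-class].
#' @param params a [probeSimParams()].
#' @param ref reference sequence (wobble detection).
#' @return data.frame with columns `position`, `p_mod`.
#' @export
simulateTruthReactivity <- function(model, params = probeSimParams(),
                                    ref = smn2IntronReference()) {
  pos <- modelPositions(model)
  p <- rep(params$p_mod_unpaired, length(pos))
  p[pos %in% pairedPositions(model)] <- params$p_mod_paired
  p[pos %in% terminalPositions(model, ref)] <- params$p_mod_terminal
  if (length(params$p_mod_override)) {
    ov <- params$p_mod_override
    hit <- match(as.integer(names(ov)), pos)
    p[hit[!is.na(hit)]] <- ov[!is.na(hit)]
  }
  data.frame(position = pos, p_mod = p)
}

lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate primer-extension lanes from ground-truth reactivities
#'
#' The modified-lane stop intensity is proportional to the modification
#' probability plus the control background; the control lane is background
#' only; both lanes share the falloff stops; multiplicative lognormal noise
#' is applied per lane. Reproducible under `params$seed`.
#'
#' @param truth data.frame from [simulateTruthReactivity()].
#' @param params a [probeSimParams()].
#' @param primer_id lane label.
#' @param window optional `c(first, last)` restriction to a primer's
#'   informative window.
#' @return a [LaneProfile-class] carrying both lanes.
#' @export
simulateLanes <- function(truth, params = probeSimParams(),
                          primer_id = "sim", window = NULL) {
  t <- truth
  if (!is.null(window)) {
    keep <- linIndex(t$position) >= linIndex(window[1L]) &
            linIndex(t$position) <= linIndex(window[2L])
    t <- t[keep, , drop = FALSE]
  }
  if (!nrow(t)) stop("empty truth window")
  set.seed(params$seed)
  n <- nrow(t)
  base1 <- params$amplitude * t$p_mod + params$dmso_background
  base0 <- rep(params$dmso_background, n)
  fs <- params$falloff_sites
  if (nrow(fs)) {
    hit <- match(fs$position, t$position)
    ok <- !is.na(hit)
    base1[hit[ok]] <- base1[hit[ok]] + fs$stop_fraction[ok] * params$amplitude
    base0[hit[ok]] <- base0[hit[ok]] + fs$stop_fraction[ok] * params$amplitude
  }
  LaneProfile(primer_id, t$position,
              base1 * lognoise(n, params$noise_cv),
              base0 * lognoise(n, params$noise_cv))
}

#' One-call simulated reactivity profile
#'
#' Convenience wrapper: truth, lanes, reactivity, falloff flagging and
#' classification in one step.
#'
#' @param model ground-truth [StructureModel-class].
#' @param params a [probeSimParams()].
#' @param window primer window `c(first, last)` (NULL = whole substrate).
#' @param primer_id lane label.
#' @param falloff_threshold threshold for [detectFalloff()].
#' @param ref reference sequence.
#' @return a classified [ReactivityProfile-class].
#' @export
simulateProfile <- function(model, params = probeSimParams(), window = NULL,
                            primer_id = "sim", falloff_threshold = 3,
                            ref = smn2IntronReference()) {
  truth <- simulateTruthReactivity(model, params, ref)
  lane <- simulateLanes(truth, params, primer_id, window)
  prof <- classifyReactivity(computeReactivity(lane))
  flagFalloff(prof, detectFalloff(lane, falloff_threshold))
}

#' Parameters for the perturbation-scan simulator
#'
#' @param true_core planted core interval `c(start, end)`.
#' @param windows data.frame of deletion windows (`start`, `end`) tiling the
#'   scanned region.
#' @param flip_prob probability a call is recorded wrongly (in `[0, 0.5)`).
#' @param seed integer RNG seed.
#' @return an object of class `ScanSimParams`.
#' @export
scanSimParams <- function(true_core, windows, flip_prob = 0, seed = 1L) {
  stopifnot(validInterval(true_core[1L], true_core[2L]),
            is.data.frame(windows), nrow(windows) >= 1L,
            flip_prob >= 0, flip_prob < 0.5)
  structure(list(true_core = as.integer(true_core), windows = windows,
                 flip_prob = flip_prob, seed = as.integer(seed)),
            class = "ScanSimParams")
}

#' Simulate a deletion-scan phenotype table from a planted core
#'
#' A window's true call is `abrogated` iff it removes at least one core
#' position (window and core intervals intersect); calls are then flipped
#' independently with probability `flip_prob`. Seeded and reproducible.
#'
#' @param params a [scanSimParams()].
#' @return a record table as from [perturbationRecords()].
#' @export
simulateScan <- function(params) {
  w <- params$windows
  core <- params$true_core
  hit <- linIndex(w$start) <= linIndex(core[2L]) &
         linIndex(w$end) >= linIndex(core[1L])
  call <- ifelse(hit, "abrogated", "retained")
  set.seed(params$seed)
  flip <- runif(nrow(w)) < params$flip_prob
  call[flip] <- ifelse(call[flip] == "abrogated", "retained", "abrogated")
  perturbationRecords(sprintf("Δ%d-%d", w$start, w$end), call, "simulated")
}

## ---------------------------------------------------------------------------
## Packaged probing scenarios (models + primer windows)
## ---------------------------------------------------------------------------

#' Packaged probing scenarios
#'
#' `m4AsoDModel()` is the quadruple-mutant model with the strengthened ISTL1
#' dissolved by the 5'-strand-invading ASO (its 3' strand released); only
#' ISTL3 persists. `primer5pWindow()` / `primerMidWindow()` are the
#' informative windows of the extension primers reading the intron 5' end
#' (positions -20..60) and the middle portion (240..299; residues within a
#' primer's annealing footprint are not resolved, so the window stops short
#' of it). `asoD291Override()` is the per-position damping emulating the
#' low-reactive cytosine at 291 seen when the released strand is probed.
#'
#' @param ref reference sequence.
#' @return models, windows and override vectors as described.
#' @export
m4AsoDModel <- function(ref = smn2IntronReference()) {
  span <- c(seqPositions(ref)[1L], seqPositions(ref)[length(ref)])
  StructureModel(list(ISTL3 = helixFromAnchor("ISTL3", 59L, 281L, 7L)), span)
}

#' @rdname m4AsoDModel
#' @export
primer5pWindow <- function() c(-20L, 60L)

#' @rdname m4AsoDModel
#' @export
primerMidWindow <- function() c(240L, 299L)

#' @rdname m4AsoDModel
#' @export
asoD291Override <- function(p = probeSimParams()) {
  setNames(p$p_mod_paired * 2, "291")
}

#' Tile a substrate with simulated extension-primer windows
#'
#' @param span substrate extent `c(first, last)`.
#' @param n number of primers.
#' @return data.frame of overlapping windows covering the span.
#' @export
primerWindows <- function(span, n = 10L) {
  lin <- linIndex(span)
  total <- lin[2L] - lin[1L] + 1L
  width <- ceiling(total / n) + 5L
  starts <- floor(seq(lin[1L], lin[2L] - width + 1L, length.out = n))
  data.frame(primer_id = sprintf("primer%02d", seq_len(n)),
             start = posFromLin(as.integer(starts)),
             end = posFromLin(as.integer(pmin(starts + width - 1L, lin[2L]))))
}
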