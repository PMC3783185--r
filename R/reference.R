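## ---------------------------------------------------------------------------
## Synthetic reconstruction of the SMN2 exon 7 (3' end) / intron 7 substrate.
##
## No deposited accession exists for the probed construct, so the package
## carries a 467-nt synthetic reference: the last 23 exonic residues plus the
## 444-nt intron 7.  Positions that the analyses depend on are fixed by the
## published residue calls and pairing relationships (see the methods
## vignette); every other stretch is seeded filler and is labelled synthetic.
## ---------------------------------------------------------------------------

.ref_segments <- list(
  # exon 7 3' end, positions -23..-1; -1 is the last exonic residue (A)
  exon23   = "GCUCACAUUCCUUAAAUUAAGGA",
  # intron 1-24: 5' splice site + ISS-N1 (positions 10-24); 10C is the
  # long-distance partner of 290G
  i001_024 = "GUAAGUCUGCCAGCAUUAUGAAAG",
  # 25: loop-closing U of TSL3
  i025     = "U",
  # 26-32: TSL3 terminal loop (synthetic filler)
  i026_032 = "AAUACAU",
  # 33-41: TSL3 3' strand, pairs 17-25 antiparallel (19U:39G is a wobble)
  i033_041 = "ACUUUCGUA",
  # 42-50: synthetic filler
  i042_050 = "ACAAAUCAA",
  # 51-57: ISTL2 5' strand, pairs the 283-289 3' strand
  i051_057 = "UUGUCUG",
  # 58: synthetic filler
  i058     = "A",
  # 59-65: ISTL3 5' strand, pairs the 275-281 3' strand
  i059_065 = "GUAACAU",
  # 66-260: Modules 1 and 2 territory (synthetic filler, seeded)
  i066_260 = paste0(
    "AAAAUGGCGGGAUUCUUGAAGCACAAAAUACAUGGAGGUCCUAGAAUCUACCGCGUCACAGAAUA",
    "CCAAUCAUUGCAAAUAAAUACUUUUAGUUAACGGAACAGUUACUUAACAUUUCCCCGACUAUAUA",
    "GUAUUGUUUCUCAUGAAAACAUGGAUAACGACUGUAUUUCAAUAGAAUACUUAACGGAAUAGAAU"),
  # 261-274: synthetic filler upstream of ISS-N2
  i261_274 = "UCAUUCAUACUAAC",
  # 275-281: ISTL3 3' strand (synthetic; 275 opens ISS-N2)
  i275_281 = "AUGUUAC",
  # 282-300: printed region: the upstream GCAGAC copy (282-287), 288A,
  # LS-1 = GCAGAC (290-295, 3' strand of ISTL1 with 296U/297U), then the
  # U-rich tract immediately downstream of LS-1
  i282_300 = "GCAGACAAGCAGACUUUUU",
  # 301-330: synthetic filler continuing the A/U-rich stretch
  i301_330 = "AUUUCAUAACCUUAUUUACCAAUCUACUAU",
  # 331-444: Module 3 territory (synthetic filler, seeded)
  i331_444 = paste0(
    "AUGGCGGAAUUACUUCUAAUGAAACCGCGUAUCUAGGAUAUUUGUACAUAGUCCUUAAAGCUAC",
    "UAACUUGAGCGGUAGUCCUUAUAAAUAUCAUCAUUCGACCGCGGAAAACA")
)

#' The packaged synthetic SMN2 exon 7 / intron 7 reference
#'
#' Returns the 467-residue probing substrate: the last 23 exonic residues of
#' exon 7 (positions -23..-1) followed by the 444-nt intron 7 (positions
#' 1..444). Residues that the published analyses determine - the 5' splice
#' site region, ISS-N1 (10-24), the TSL3 stem, the ISTL2/ISTL3 strands, the
#' 282-300 stretch containing LS-1 (GCAGAC, 290-295) and its identical
#' upstream copy (282-287), and the downstream U-rich tract - are fixed;
#' everything else is synthetic filler, so the object is a reconstruction
#' suitable for method development and simulation, not a genomic sequence.
#'
#' @return an [IntronSeq-class] with origin -23.
#' @examples
#' ref <- smn2IntronReference()
#' segmentAt(ref, 290, 295)  # LS-1
#' @export
smn2IntronReference <- function() {
  IntronSeq(paste(unlist(.ref_segments), collapse = ""), origin = -23L)
}

#' Printed sub-segments of the reference
#'
#' Convenience accessors mirroring how the sequence is presented: the exon 7
#' 3' end with the first 104 intronic residues, the first 40 intronic
#' residues, and the 285-300 stretch.
#'
#' @param ref reference sequence; defaults to [smn2IntronReference()].
#' @return an [IntronSeq-class].
#' @export
refSegment5p <- function(ref = smn2IntronReference()) subSeq(ref, -23, 104)

#' @rdname refSegment5p
#' @export
refSegmentIntronStart <- function(ref = smn2IntronReference()) subSeq(ref, 1, 40)

#' @rdname refSegment5p
#' @export
refSegmentLs1 <- function(ref = smn2IntronReference()) subSeq(ref, 285, 300)

#' Landmark intervals of the intron 7 silencer architecture
#'
#' `issN1()` returns the 15-nt intronic splicing silencer N1 (positions
#' 10-24); `issN2()` the 23-nt silencer N2 (275-297), i.e. the adjacent 3'
#' strands of ISTL1/2/3; `ls1()` the 6-nt LS-1 motif (290-295).
#'
#' @return integer vector `c(start, end)`.
#' @export
issN1 <- function() c(10L, 24L)

#' @rdname issN1
#' @export
issN2 <- function() c(275L, 297L)

#' @rdname issN1
#' @export
ls1 <- function() c(290L, 295L)
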