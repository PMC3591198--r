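# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and Biostrings lookups) so they can arbitrate.

# brute-force size of the per-base union of 1-based closed intervals
bf_union_bp <- function(starts, ends) {
  bases <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
  length(unique(bases))
}

# hand-written standard genetic code, independent of Biostrings
oracle_codon_table <- local({
  txt <- c(
    "TTT=F", "TTC=F", "TTA=L", "TTG=L", "CTT=L", "CTC=L", "CTA=L", "CTG=L",
    "ATT=I", "ATC=I", "ATA=I", "ATG=M", "GTT=V", "GTC=V", "GTA=V", "GTG=V",
    "TCT=S", "TCC=S", "TCA=S", "TCG=S", "CCT=P", "CCC=P", "CCA=P", "CCG=P",
    "ACT=T", "ACC=T", "ACA=T", "ACG=T", "GCT=A", "GCC=A", "GCA=A", "GCG=A",
    "TAT=Y", "TAC=Y", "TAA=*", "TAG=*", "CAT=H", "CAC=H", "CAA=Q", "CAG=Q",
    "AAT=N", "AAC=N", "AAA=K", "AAG=K", "GAT=D", "GAC=D", "GAA=E", "GAG=E",
    "TGT=C", "TGC=C", "TGA=*", "TGG=W", "CGT=R", "CGC=R", "CGA=R", "CGG=R",
    "AGT=S", "AGC=S", "AGA=R", "AGG=R", "GGT=G", "GGC=G", "GGA=G", "GGG=G")
  parts <- strsplit(txt, "=", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
})

oracle_effect <- function(ref_codon, alt_codon) {
  a <- oracle_codon_table[[ref_codon]]
  b <- oracle_codon_table[[alt_codon]]
  if (a == b) "synonymous"
  else if (b == "*") "nonsense"
  else if (a == "*") "stoploss"
  else "missense"
}

# rule-text cosegregation decision for a fully genotyped family
oracle_coseg <- function(geno, affected, sex, mode) {
  carries <- geno %in% c("het", "hom", "hemi")
  ok <- switch(mode,
    AD = all(carries[affected]) && !any(carries[!affected]),
    AR = all(geno[affected] == "hom") && !any(geno[!affected] == "hom"),
    XL = {
      male <- sex == "M"
      all(geno[affected & male] %in% c("hemi", "hom")) &&
        !any(carries[!affected & male]) &&
        all(geno[affected & !male] == "hom") &&
        !any(geno[!affected & !male] == "hom")
    })
  if (ok) "yes" else "no"
}

# sort-and-pick median, avoiding stats::median
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# brute-force homopolymer scan: positions lying in or adjoining a run >= k
oracle_repeat_positions <- function(seq_chr, k) {
  b <- strsplit(seq_chr, "")[[1L]]
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flagged <- rep(FALSE, length(b))
  for (i in which(r$lengths >= k)) {
    lo <- max(1L, starts[i] - 1L)
    hi <- min(length(b), ends[i] + 1L)
    flagged[lo:hi] <- TRUE
  }
  flagged
}
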