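#' Build a DNA duplex topology
#'
#' Constructs the pairing and numbering bookkeeping for a blunt-ended
#' Watson-Crick duplex. The sense strand is numbered 1..n (5' to 3'); the
#' complementary strand continues n+1..2n along its own 5' to 3' direction,
#' so that sense residue i pairs with complement residue 2n+1-i
#' (antiparallel). This is the numbering convention used for the 15-mer
#' TFF1-ERE duplex (residues 1-30).
#'
#' @param sense DNA sequence of the sense strand, 5' to 3' (string over
#'   A/C/G/T, case-insensitive).
#' @return An object of class `duplex_topology`: a list with elements
#'   `sense`, `complement` (both 5' to 3'), `n` (number of pairs),
#'   `pairs` (data.frame `sense_res`, `comp_res`, `pair`), and
#'   `residues` (data.frame `resno`, `base`, `strand`, `pair`).
#' @examples
#' top <- build_duplex("AGGTCACGGTGGCCA")
#' top$complement   # "TGGCCACCGTGACCT"
#' @export
build_duplex <- function(sense) {
  if (!is.character(sense) || length(sense) != 1 || nchar(sense) == 0) {
    stop("`sense` must be a single non-empty DNA string")
  }
  sense <- toupper(sense)
  if (grepl("[^ACGT]", sense)) {
    stop("`sense` contains non-ACGT characters: ",
         gsub("[ACGT]", "", sense))
  }
  comp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  n <- nchar(sense)
  sense_b <- strsplit(sense, "")[[1]]
  comp_b <- strsplit(comp, "")[[1]]
  pairs <- data.frame(pair = seq_len(n),
                      sense_res = seq_len(n),
                      comp_res = 2L * n + 1L - seq_len(n))
  residues <- rbind(
    data.frame(resno = seq_len(n), base = sense_b, strand = "sense",
               pair = seq_len(n)),
    data.frame(resno = n + seq_len(n), base = comp_b, strand = "comp",
               pair = n + 1L - seq_len(n))   # comp residue n+k pairs pair n+1-k
  )
  structure(list(sense = sense, complement = comp, n = n,
                 pairs = pairs, residues = residues),
            class = "duplex_topology")
}

#' @export
print.duplex_topology <- function(x, ...) {
  cat("DNA duplex topology:", x$n, "base pairs\n")
  cat("  sense      5'-", x$sense, "-3'  (residues 1-", x$n, ")\n", sep = "")
  cat("  complement 5'-", x$complement, "-3'  (residues ", x$n + 1, "-",
      2 * x$n, ")\n", sep = "")
  invisible(x)
}

#' Look up base identity by residue number
#' @param topology a `duplex_topology`
#' @param resno residue number(s) in 1..2n
#' @return character vector of bases
#' @keywords internal
residue_base <- function(topology, resno) {
  topology$residues$base[match(resno, topology$residues$resno)]
}

#' Count observable imino protons of a duplex
#'
#' Each Watson-Crick pair contributes exactly one imino proton: thymine H3
#' for an A:T (or T:A) pair, guanine H1 for a G:C (or C:G) pair. Terminal
#' pairs exchange too fast with water to be observed and can be excluded.
#' For the TFF1-ERE 15-mer this yields 3 thymine H3 and 10 guanine H1
#' protons from the 13 non-terminal pairs.
#'
#' @param topology a `duplex_topology`
#' @param exclude_terminal drop the first and last pair (default TRUE)
#' @return named integer vector `c(thymine_H3, guanine_H1)`
#' @export
count_imino_protons <- function(topology, exclude_terminal = TRUE) {
  stopifnot(inherits(topology, "duplex_topology"))
  idx <- seq_len(topology$n)
  if (exclude_terminal && topology$n > 2) idx <- idx[-c(1, topology$n)]
  sense_b <- strsplit(topology$sense, "")[[1]][idx]
  at <- sum(sense_b %in% c("A", "T"))
  gc <- sum(sense_b %in% c("G", "C"))
  c(thymine_H3 = at, guanine_H1 = gc)
}

#' The TFF1-ERE duplex sequence
#'
#' The naturally occurring estrogen response element of the TFF1 gene
#' promoter used throughout the examples: 5'-AGGTCACGGTGGCCA paired with
#' 5'-TGGCCACCGTGACCT, residues numbered 1-30.
#' @return a `duplex_topology` of the 15-mer
#' @export
tff1_duplex <- function() build_duplex("AGGTCACGGTGGCCA")

#' Describe the bis-intercalator ligand topology
#'
#' Returns the internal topology of the bis-intercalating ligand: two
#' planar tricyclic phenazine ring systems (units A and B), each with
#' aromatic protons H2/H3/H4 and H6/H7/H8 and a C9 methyl, joined by a
#' carboxamide-aminoalkyl linker whose two gamma-amino nitrogens (NG1,
#' NG2) are protonated (+1 each) at pH 7.
#'
#' @return list with `atoms` (data.frame of names/elements/idealized
#'   coordinates), `bonds`, `rings`, `units` (atom names per ring system),
#'   `linker`, and `charged` (protonated nitrogens).
#' @export
ligand_topology <- function() .ligand_template()
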