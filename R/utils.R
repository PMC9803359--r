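# Signed position conventions for splice-site windows. There is no position 0:
# negative positions are exonic for donors and intronic for acceptors.
#' Signed positions covered by a splice-site window
#'
#' Donor (5'SS) windows cover -3..-1 (exonic) and +1..+5 (intronic);
#' acceptor (3'SS) windows cover -5..-1 (intronic) and +1..+2 (exonic).
#'
#' @param site_kind `"five_prime"` or `"three_prime"`.
#' @return Integer vector of signed positions (no zero).
#' @export
window_positions <- function(site_kind = c("five_prime", "three_prime")) {
  site_kind <- match.arg(site_kind)
  if (site_kind == "five_prime") c(-3:-1, 1:5) else c(-5:-1, 1:2)
}

# Convert DNA-alphabet strings to the RNA alphabet used for reporting.
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Comparisons are alphabet-insensitive internally: normalise to RNA.
norm_seq <- function(x) to_rna(x)

# Extract the base at a signed window position from window sequences.
# `positions` is the signed position vector of the window layout.
base_at <- function(seq, position, positions) {
  idx <- match(position, positions)
  if (is.na(idx)) {
    stop("position ", position, " is not covered by this window layout",
         call. = FALSE)
  }
  substr(norm_seq(seq), idx, idx)
}

# Substring of window sequences covering a contiguous signed position range.
window_slice <- function(seq, from, to, positions) {
  i <- match(from, positions)
  j <- match(to, positions)
  if (is.na(i) || is.na(j)) {
    stop("positions ", from, "..", to, " not covered by this window layout",
         call. = FALSE)
  }
  substr(norm_seq(seq), i, j)
}

# Reverse complement for plain character vectors (DNA or RNA in, DNA out).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(chartr("Uu", "Tt", x))
  ))
}

iupac_match <- function(base, code) {
  sets <- list(
    A = "A", C = "C", G = "G", U = "U",
    R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
    K = c("G", "U"), M = c("A", "C"),
    B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "U")
  )
  base %in% sets[[code]]
}
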