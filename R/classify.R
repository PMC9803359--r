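# Discrete U5/U6 interaction classes for 5' splice sites.
#
# The U5 class is the edit distance of the exonic -2..-1 positions from the
# consensus AG contacted by U5 snRNA loop 1 (0..2). The U6 class is the edit
# distance of the intronic +3..+5 positions from the consensus RAG contacted
# by the U6 snRNA ACAGA box, with the degenerate R matching A or G at zero
# cost (0..3). N at a classed position counts as one edit.

check_five_prime <- function(windows) {
  if (is.data.frame(windows)) {
    if (any(windows$site_kind != "five_prime")) {
      stop("U5/U6 classification applies to five_prime windows only",
           call. = FALSE)
    }
    norm_seq(windows$seq)
  } else {
    s <- norm_seq(windows)
    if (any(nchar(s) != 8)) {
      stop("5'SS windows must be 8 nt (-3..-1, +1..+5)", call. = FALSE)
    }
    s
  }
}

char_matrix <- function(seqs) do.call(rbind, strsplit(seqs, ""))

#' U5 and U6 splice-site classes
#'
#' @param windows 5'SS window tibble (from [extract_windows()]) or character
#'   vector of 8-nt windows covering -3..+5.
#' @return Integer vector of edit distances: 0..2 for `u5_class()` (distance
#'   of -2..-1 from "AG"), 0..3 for `u6_class()` (distance of +3..+5 from
#'   "RAG", R = A or G).
#' @export
u5_class <- function(windows) {
  s <- check_five_prime(windows)
  m <- char_matrix(s)
  # layout -3,-2,-1,+1..+5 -> columns 2:3 are -2..-1
  (m[, 2] != "A") + (m[, 3] != "G")
}

#' @rdname u5_class
#' @export
u6_class <- function(windows) {
  s <- check_five_prime(windows)
  m <- char_matrix(s)
  # columns 6:8 are +3..+5
  (!m[, 6] %in% c("A", "G")) + (m[, 7] != "A") + (m[, 8] != "G")
}

#' Major 5'SS class membership
#'
#' `is_gurag()` tests whether the intron starts GURAG (+1..+5 match
#' G,U,\[AG\],A,G): the U6-favoured class. `is_aggu()` tests AG//GU
#' (-2..-1 == "AG" and +1..+2 == "GU"): the U5-favoured class. The classes
#' overlap: an AG//GURAG donor satisfies both.
#'
#' @inheritParams u5_class
#' @return Logical vector.
#' @export
is_gurag <- function(windows) {
  m <- char_matrix(check_five_prime(windows))
  m[, 4] == "G" & m[, 5] == "U" & m[, 6] %in% c("A", "G") &
    m[, 7] == "A" & m[, 8] == "G"
}

#' @rdname is_gurag
#' @export
is_aggu <- function(windows) {
  m <- char_matrix(check_five_prime(windows))
  m[, 2] == "A" & m[, 3] == "G" & m[, 4] == "G" & m[, 5] == "U"
}

#' Base at the +4 position of a donor window
#'
#' @inheritParams u5_class
#' @return Character vector of single bases.
#' @export
plus4_base <- function(windows) {
  char_matrix(check_five_prime(windows))[, 7]
}

#' Categorise the base switch between a lost and a gained alternative donor
#'
#' For a pair of alternative 5'SSs oriented lost (reduced usage) to gained
#' (increased usage), records the bases at one signed position and assigns
#' the coarsest matching IUPAC group label. At +4 the labels are `"same"`,
#' `"A>U"`, `"A>B"` (B = C, G or U), `"S>U"` (S = C or G), `"B>A"`, and
#' `"other"`; at +5 and -1 the labels `"G>H"` and `"H>G"` (H = A, C or U)
#' are used instead.
#'
#' @param lost_windows,gained_windows 5'SS windows (tibble or character).
#' @param position Signed position, one of -1, +4 (default), +5.
#' @return Tibble with columns `position`, `from_base`, `to_base`,
#'   `group_label`.
#' @export
switch_category <- function(lost_windows, gained_windows, position = 4) {
  layout <- window_positions("five_prime")
  if (!position %in% layout) {
    stop("position ", position, " is not in the 5'SS window", call. = FALSE)
  }
  from <- base_at(check_five_prime(lost_windows), position, layout)
  to <- base_at(check_five_prime(gained_windows), position, layout)
  label <- rep("other", length(from))
  if (position == 4) {
    label[from == "A" & to == "U"] <- "A>U"
    label[from == "A" & to %in% c("C", "G")] <- "A>B"
    label[from %in% c("C", "G") & to == "U"] <- "S>U"
    label[from %in% c("C", "G", "U") & to == "A"] <- "B>A"
  } else {
    label[from == "G" & to %in% c("A", "C", "U")] <- "G>H"
    label[from %in% c("A", "C", "U") & to == "G"] <- "H>G"
  }
  label[from == to] <- "same"
  tibble(position = position, from_base = from, to_base = to,
         group_label = label)
}

#' Predict the major class of a donor window
#'
#' Assigns each 5'SS to the U5-favoured (`"aggu"`) or U6-favoured
#' (`"gurag"`) major class. Windows matching exactly one of the
#' [is_aggu()] / [is_gurag()] motifs take that class; ambiguous windows
#' (both motifs, as in AG//GURAG, or neither) are resolved by comparing the
#' U5 and U6 consensus distances, with ties going to the U5 side (the exact
#' AG//GU core is the shorter motif, so a tie carries no U6-side evidence).
#'
#' @inheritParams u5_class
#' @return Character vector, `"aggu"` or `"gurag"`.
#' @export
predict_major_class <- function(windows) {
  aggu <- is_aggu(windows)
  gurag <- is_gurag(windows)
  d5 <- u5_class(windows)
  d6 <- u6_class(windows)
  ifelse(aggu & !gurag, "aggu",
         ifelse(gurag & !aggu, "gurag",
                ifelse(d6 < d5, "gurag", "aggu")))
}

#' Annotate a site table with U5/U6 classes and major-class flags
#'
#' Adds the columns `u5_class`, `u6_class`, `is_gurag`, `is_aggu`, and
#' `plus4` to a 5'SS window tibble.
#'
#' @param windows 5'SS window tibble.
#' @return The annotated tibble.
#' @export
classify_sites <- function(windows) {
  windows |>
    mutate(
      u5_class = u5_class(windows),
      u6_class = u6_class(windows),
      is_gurag = is_gurag(windows),
      is_aggu = is_aggu(windows),
      plus4 = plus4_base(windows)
    )
}
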