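#' @title IMGT unique numbering positions
#'
#' @description
#' Positions of the IMGT unique numbering scheme for immunoglobulin variable
#' domains. A position is an integer in 1--128 plus an optional insertion
#' index; insertions are only legal at positions 111 and 112 and encode the
#' extra residues of long CDR3 loops. The total order of positions runs
#' ... 110 < 111 < 111.1 < 111.2 < ... < 112.2 < 112.1 < 112 < 113 ...:
#' insertion indices ascend away from 111 and descend into 112.
#'
#' `imgt_position()` builds a vectorized position table (a data.frame with
#' columns `number` and `insertion`); `imgt_key()` maps positions to numeric
#' sort keys realizing the total order; `imgt_format()`/`imgt_parse()`
#' convert to and from strings such as `"111.2"`.
#'
#' @param number integer vector, 1--128.
#' @param insertion integer vector of insertion indices (NA for none);
#'   permitted only with numbers 111 and 112, and capped at 13.
#' @return `imgt_position()`: a data.frame of class `imgt_position`.
#' @examples
#' p <- imgt_position(c(111, 111, 112), c(NA, 2, 1))
#' imgt_format(p)
#' order(imgt_key(p))
#' @export
imgt_position <- function(number, insertion = NA_integer_) {
  if (length(number) == 0L) {
    return(structure(data.frame(number = integer(0), insertion = integer(0)),
                     class = c("imgt_position", "data.frame")))
  }
  n <- max(length(number), length(insertion))
  number <- as.integer(rep_len(number, n))
  insertion <- as.integer(rep_len(insertion, n))
  if (any(is.na(number)) || any(number < 1L | number > 128L)) {
    stop_ab("IMGT position number must be in 1..128", "ablineage_domain_error")
  }
  bad <- !is.na(insertion) & !(number %in% c(111L, 112L))
  if (any(bad)) {
    stop_ab("insertion indices are only permitted at positions 111 and 112",
            "ablineage_domain_error")
  }
  if (any(!is.na(insertion) & (insertion < 1L | insertion > 13L))) {
    stop_ab("insertion index must be in 1..13", "ablineage_domain_error")
  }
  structure(data.frame(number = number, insertion = insertion),
            class = c("imgt_position", "data.frame"))
}

#' @rdname imgt_position
#' @param pos an `imgt_position` table.
#' @export
imgt_key <- function(pos) {
  k <- as.numeric(pos$number)
  ins <- pos$insertion
  has <- !is.na(ins)
  # 111.x ascends from 111, 112.x descends into 112
  k[has & pos$number == 111L] <- 111 + ins[has & pos$number == 111L] / 100
  k[has & pos$number == 112L] <- 112 - ins[has & pos$number == 112L] / 100
  k
}

#' @rdname imgt_position
#' @export
imgt_format <- function(pos) {
  ifelse(is.na(pos$insertion), as.character(pos$number),
         paste0(pos$number, ".", pos$insertion))
}

#' @rdname imgt_position
#' @param text character vector like `"40"` or `"111.2"`.
#' @export
imgt_parse <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+)(?:\\.([0-9]+))?$", text))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop_ab(sprintf("malformed IMGT position: '%s'", text[bad][1]),
            "ablineage_parse_error")
  }
  number <- vapply(m, function(g) as.integer(g[2]), integer(1))
  insertion <- vapply(m, function(g) {
    if (is.na(g[3]) || g[3] == "") NA_integer_ else as.integer(g[3])
  }, integer(1))
  imgt_position(number, insertion)
}

# IMGT region boundaries (same for heavy and light chains):
# FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117
# (including 111.x/112.x insertions), FR4 118-128.
#' IMGT region of a position
#'
#' @param pos an `imgt_position` table (or integer vector of plain numbers).
#' @return character vector of region labels (FR1, CDR1, FR2, CDR2, FR3,
#'   CDR3, FR4).
#' @export
imgt_region <- function(pos) {
  if (!inherits(pos, "imgt_position")) pos <- imgt_position(pos)
  n <- pos$number
  out <- character(length(n))
  out[n >= 1 & n <= 26] <- "FR1"
  out[n >= 27 & n <= 38] <- "CDR1"
  out[n >= 39 & n <= 55] <- "FR2"
  out[n >= 56 & n <= 65] <- "CDR2"
  out[n >= 66 & n <= 104] <- "FR3"
  out[n >= 105 & n <= 117] <- "CDR3"
  out[n >= 118 & n <= 128] <- "FR4"
  out
}

#' Number a CDR3 loop of given length
#'
#' Assigns IMGT positions to a CDR3 of `length_aa` residues. The canonical
#' 13-residue loop occupies 105--117. Longer loops gain insertion positions
#' between 111 and 112, added alternately starting on the 112 side
#' (112.1 first, then 111.1, then 112.2, ...), so a 19-residue loop carries
#' 111.1--111.3 and 112.3--112.1. Shorter loops lose apex positions starting
#' on the 112 side (112 first, then 111, then 113, 110, ...).
#'
#' With insertion indices capped at 13 per side the longest representable
#' loop is 39 residues.
#'
#' @param length_aa integer, 1--39.
#' @return an `imgt_position` table of `length_aa` rows in increasing IMGT
#'   order.
#' @examples
#' imgt_format(number_cdr3(19))
#' @export
number_cdr3 <- function(length_aa) {
  if (!is.numeric(length_aa) || length(length_aa) != 1L ||
      is.na(length_aa) || length_aa < 1 || length_aa > 39) {
    stop_ab("CDR3 length must be a single integer in 1..39",
            "ablineage_domain_error")
  }
  L <- as.integer(length_aa)
  extra <- L - 13L
  if (extra >= 0L) {
    n111 <- extra %/% 2L          # insertions ascending after 111
    n112 <- extra - n111          # insertions descending before 112 (>=)
    number <- c(105:111,
                rep(111L, n111), rep(112L, n112),
                112:117)
    insertion <- c(rep(NA_integer_, 7),
                   seq_len(n111),
                   rev(seq_len(n112)),
                   rep(NA_integer_, 6))
    imgt_position(number, insertion)
  } else {
    # removal order: 112, 111, 113, 110, 114, 109, ...
    highs <- 112:117
    lows <- 111:105
    removal <- as.integer(rbind(highs, lows[seq_along(highs)]))
    removal <- c(removal, 105L)[seq_len(12L)]
    keep <- setdiff(105:117, removal[seq_len(-extra)])
    imgt_position(keep)
  }
}

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

#' Amino-acid substitutions in lineage nomenclature
#'
#' A substitution names the ancestral residue, an IMGT position, the chain,
#' and the replacement residue, written e.g. `"N40_H_T"` (asparagine 40 of
#' the heavy chain replaced by threonine) or `"D111.3_H_E"` for a CDR3
#' insertion position. `parse_substitution()` and `format_substitution()`
#' are mutually inverse on canonical strings.
#'
#' @param text substitution string matching
#'   `<AA><number>[.<ins>]_(H|L)_<AA>`.
#' @return `parse_substitution()`: a list of class `substitution` with
#'   fields `from_aa`, `position` (an `imgt_position`), `chain`, `to_aa`.
#' @examples
#' s <- parse_substitution("D111.3_H_E")
#' format_substitution(s)
#' @export
parse_substitution <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^([A-Z])([0-9]+(?:\\.[0-9]+)?)_([HL])_([A-Z])$", text))[[1]]
  if (length(m) == 0L) {
    stop_ab(sprintf("malformed substitution string: '%s'", text),
            "ablineage_parse_error")
  }
  from_aa <- m[2]; to_aa <- m[5]
  if (!(from_aa %in% AA_LETTERS) || !(to_aa %in% AA_LETTERS)) {
    stop_ab(sprintf("unknown amino-acid letter in '%s'", text),
            "ablineage_parse_error")
  }
  if (from_aa == to_aa) {
    stop_ab(sprintf("'%s' is a no-op substitution (identical residues)", text),
            "ablineage_parse_error")
  }
  substitution(from_aa, imgt_parse(m[3]), m[4], to_aa)
}

#' @rdname parse_substitution
#' @param from_aa,to_aa single amino-acid letters, distinct.
#' @param position an `imgt_position` of one row.
#' @param chain `"H"` or `"L"`.
#' @export
substitution <- function(from_aa, position, chain, to_aa) {
  if (!inherits(position, "imgt_position")) position <- imgt_parse(as.character(position))
  stopifnot(nrow(position) == 1L, chain %in% c("H", "L"))
  if (identical(from_aa, to_aa)) {
    stop_ab("substitution must change the residue", "ablineage_domain_error")
  }
  structure(list(from_aa = from_aa, position = position,
                 chain = chain, to_aa = to_aa),
            class = "substitution")
}

#' @rdname parse_substitution
#' @param s a `substitution`.
#' @export
format_substitution <- function(s) {
  stopifnot(inherits(s, "substitution"))
  paste0(s$from_aa, imgt_format(s$position), "_", s$chain, "_", s$to_aa)
}

#' @export
print.substitution <- function(x, ...) {
  cat("<substitution>", format_substitution(x), "\n")
  invisible(x)
}

#' @export
format.substitution <- function(x, ...) format_substitution(x)

# canonical ordering of a list of substitutions: heavy first, then by
# IMGT position order
order_substitutions <- function(subs) {
  if (length(subs) == 0L) return(subs)
  chain <- vapply(subs, `[[`, character(1), "chain")
  key <- vapply(subs, function(s) imgt_key(s$position), numeric(1))
  subs[order(match(chain, c("H", "L")), key)]
}
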