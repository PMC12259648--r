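# Internal helpers shared across modules.

stop_ab <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ablineage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_ab <- function(msg, class) {
  warning(structure(
    class = c(class, "ablineage_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG state so generators are pure functions of seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) grepl("^[ACGT]*$", x)

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# codon -> amino acid (single letter; "*" for stop) using the standard code
codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# translate an in-frame DNA string; incomplete trailing codon is dropped
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(codon_to_aa(codons), collapse = "")
}

split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Round half away from zero
#'
#' Rounding used for reported fold changes and table values; unlike base
#' \code{round()} (banker's rounding), halves move away from zero so e.g.
#' 19.5 rounds to 20.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample size-1-safe
sample1 <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]
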