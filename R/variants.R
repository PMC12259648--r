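# Reversion-variant panel enumeration and site-directed mutagenesis primer
# design in the overlapping complementary-primer style.

#' A variant specification
#'
#' @param substitutions list of `substitution`s (at most one per position).
#' @param background `"mature"` or `"UCA"` template the substitutions apply to.
#' @param full_set optional list of all lineage substitutions; a variant whose
#'   set equals it is named `"UCA"`.
#' @return object of class `variant_spec` with a deterministic `name`.
#' @export
variant_spec <- function(substitutions, background = "mature",
                         full_set = NULL) {
  stopifnot(background %in% c("mature", "UCA"))
  substitutions <- order_substitutions(substitutions)
  keys <- vapply(substitutions, function(s)
    paste0(imgt_format(s$position), s$chain), character(1))
  if (anyDuplicated(keys)) {
    stop_ab("variant carries two substitutions at one position",
            "ablineage_usage_error")
  }
  labels <- vapply(substitutions, format_substitution, character(1))
  name <- if (length(labels) == 0L) {
    "parental"
  } else if (!is.null(full_set) &&
             setequal(labels, vapply(full_set, format_substitution,
                                     character(1)))) {
    "UCA"
  } else {
    paste(labels, collapse = ", ")
  }
  structure(list(name = name, background = background,
                 substitutions = substitutions),
            class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s (%s background)\n", x$name, x$background))
  invisible(x)
}

as_sub <- function(x) if (inherits(x, "substitution")) x else parse_substitution(x)

#' Enumerate the reversion / allele-swap variant panel
#'
#' Reproduces the experimental design graph used to dissect the 212579
#' lineage: starting from the parental (mature) antibody, heavy-chain
#' reversions are explored as singles and as cumulative combinations (in
#' IMGT position order), the light-chain reversions move as one block, the
#' block is additionally combined with each of the first two heavy singles,
#' the full reversion set defines the UCA, and germline allele-swap
#' substitutions are explored as singles plus their combination. With the
#' six lineage substitutions and the two allele swaps this yields the
#' 13-member study panel.
#'
#' @param heavy_subs heavy-chain reversion substitutions (list of
#'   `substitution` or strings), e.g. `c("T40_H_N","I53_H_V","H113_H_Y")`.
#' @param light_subs light-chain reversion substitutions (moved as a block).
#' @param allele_swaps allele-swap substitutions, e.g.
#'   `c("E38_H_S","G62_H_S")`.
#' @return list of `variant_spec`s; deterministic and independent of input
#'   ordering.
#' @export
enumerate_panel <- function(heavy_subs = list(), light_subs = list(),
                            allele_swaps = list()) {
  heavy <- order_substitutions(lapply(heavy_subs, as_sub))
  light <- order_substitutions(lapply(light_subs, as_sub))
  swaps <- order_substitutions(lapply(allele_swaps, as_sub))
  full <- c(heavy, light)
  sets <- list(list())
  add <- function(sets, subs) c(sets, list(subs))
  for (h in heavy) sets <- add(sets, list(h))
  if (length(heavy) >= 2L) {
    for (k in 2:length(heavy)) sets <- add(sets, heavy[seq_len(k)])
  }
  if (length(light) > 0L) {
    sets <- add(sets, light)
    for (h in heavy[seq_len(min(2L, length(heavy)))]) {
      sets <- add(sets, c(list(h), light))
    }
    if (length(heavy) > 0L) sets <- add(sets, full)
  }
  for (s in swaps) sets <- add(sets, list(s))
  if (length(swaps) >= 2L) sets <- add(sets, swaps)
  specs <- lapply(sets, variant_spec, background = "mature", full_set = full)
  specs[!duplicated(vapply(specs, `[[`, character(1), "name"))]
}

# ranked codon preference per amino acid; the first entries for N, S, V, Y,
# A and G follow the codons used in the published 212579 mutagenesis primers
CODON_PREFERENCE <- list(
  A = c("GCA", "GCC", "GCT", "GCG"),
  C = c("TGC", "TGT"),
  D = c("GAC", "GAT"),
  E = c("GAG", "GAA"),
  F = c("TTC", "TTT"),
  G = c("GGG", "GGC", "GGA", "GGT"),
  H = c("CAC", "CAT"),
  I = c("ATC", "ATT", "ATA"),
  K = c("AAG", "AAA"),
  L = c("CTG", "CTC", "TTG", "CTT", "TTA", "CTA"),
  M = "ATG",
  N = c("AAC", "AAT"),
  P = c("CCC", "CCT", "CCA", "CCG"),
  Q = c("CAG", "CAA"),
  R = c("AGA", "CGG", "AGG", "CGC", "CGA", "CGT"),
  S = c("TCG", "TCT", "AGC", "TCC", "AGT", "TCA"),
  T = c("ACC", "ACA", "ACT", "ACG"),
  V = c("GTC", "GTG", "GTT", "GTA"),
  W = "TGG",
  Y = c("TAC", "TAT"))

# minimal-edit codon for `aa` starting from `from_codon`; ties broken by the
# fixed preference table
choose_codon <- function(aa, from_codon) {
  cands <- CODON_PREFERENCE[[aa]]
  if (is.null(cands)) {
    stop_ab(sprintf("no codon table entry for residue '%s'", aa),
            "ablineage_domain_error")
  }
  d <- vapply(cands, function(c) {
    sum(strsplit(c, "")[[1]] != strsplit(from_codon, "")[[1]])
  }, integer(1))
  cands[which(d == min(d))[1L]]  # cands is preference-ordered
}

#' Apply amino-acid substitutions to a nucleotide gene
#'
#' Each targeted codon is replaced by a codon of the new residue chosen by
#' the codon policy: minimal nucleotide edit from the template codon, ties
#' broken by a fixed preference table (seeded with the codons of the
#' published 212579 mutagenesis primers). Only targeted codons change.
#'
#' @param gene_nt in-frame DNA gene whose codon `i` encodes residue `i` of
#'   `numbered`.
#' @param numbered the `numbered_domain` of the gene's translation.
#' @param subs list of `substitution`s (or strings).
#' @return the mutated DNA string.
#' @export
apply_substitutions <- function(gene_nt, numbered, subs) {
  subs <- lapply(subs, as_sub)
  codons <- split_codons(gene_nt)
  if (length(codons) < nrow(numbered)) {
    stop_ab("gene shorter than its numbered domain", "ablineage_usage_error")
  }
  for (s in subs) {
    row <- which(numbered$position == imgt_format(s$position))
    if (length(row) != 1L || attr(numbered, "chain") != s$chain) {
      stop_ab(sprintf("position %s_%s_ absent from the numbered domain",
                      imgt_format(s$position), s$chain),
              "ablineage_usage_error")
    }
    if (numbered$aa[row] != s$from_aa) {
      stop_ab(sprintf(
        "gene encodes %s at position %s, substitution expects %s",
        numbered$aa[row], imgt_format(s$position), s$from_aa),
        "ablineage_consistency_error")
    }
    codons[row] <- choose_codon(s$to_aa, codons[row])
  }
  paste(codons, collapse = "")
}

#' Overlapping complementary mutagenesis primer pair
#'
#' @param forward,reverse primer DNA strings, both written 5' to 3'.
#' @param target a `substitution` (or string).
#' @param overlap_len length of the mutual reverse-complement overlap.
#' @param mutant_codon the codon introduced by the pair (optional).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, target, overlap_len,
                        mutant_codon = NULL) {
  target <- as_sub(target)
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!is_dna(forward) || !is_dna(reverse)) {
    stop_ab("primers must be plain DNA", "ablineage_format_error")
  }
  structure(list(forward = forward, reverse = reverse, target = target,
                 overlap_len = as.integer(overlap_len),
                 mutant_codon = mutant_codon),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s overlap %d nt\n  fwd %s\n  rev %s\n",
              format_substitution(x$target), x$overlap_len, x$forward,
              x$reverse))
  invisible(x)
}

#' Design an overlapping complementary mutagenesis primer pair
#'
#' The forward primer spans `flank` codom-flanking nucleotides on each side
#' of the mutated codon; the reverse primer is the reverse complement of the
#' same window shifted 3'-ward by `rev_offset` nucleotides (printed pairs of
#' this style differ in register by a few bases), giving an overlap of
#' `2*flank + 3 - rev_offset`.
#'
#' @param template_nt in-frame gene to mutate.
#' @param numbered `numbered_domain` of the template translation.
#' @param sub the target `substitution` (or string).
#' @param flank nucleotides flanking the codon on each side (default 14).
#' @param rev_offset register shift of the reverse window, 0--3 (default 1).
#' @return a `primer_pair`.
#' @export
design_primers <- function(template_nt, numbered, sub, flank = 14L,
                           rev_offset = 1L) {
  sub <- as_sub(sub)
  stopifnot(rev_offset >= 0L, rev_offset <= 3L)
  mutant <- apply_substitutions(template_nt, numbered, list(sub))
  row <- which(numbered$position == imgt_format(sub$position))
  c0 <- 3L * (row - 1L)  # 0-based codon start
  fstart <- c0 - flank; fend <- c0 + 3L + flank          # half-open, 0-based
  rstart <- fstart + rev_offset; rend <- fend + rev_offset
  if (fstart < 0L || rend > nchar(mutant)) {
    stop_ab("codon too close to the template end for the requested flank",
            "ablineage_design_error")
  }
  fwd <- substr(mutant, fstart + 1L, fend)
  rev <- revcomp(substr(mutant, rstart + 1L, rend))
  primer_pair(fwd, rev, sub, overlap_len = 2L * flank + 3L - rev_offset,
              mutant_codon = substr(mutant, c0 + 1L, c0 + 3L))
}

# longest exact ungapped run between two strings (any relative offset)
best_overlap_run <- function(x, y) {
  run <- longest_exact_run(strsplit(x, "")[[1]], strsplit(y, "")[[1]])
  if (is.null(run)) list(len = 0L, x_off = 0L, y_off = 0L)
  else list(len = run$len, x_off = run$win_off, y_off = run$germ_off)
}

# simple GC-based melting-temperature estimate (informational)
primer_tm <- function(p) {
  n <- nchar(p)
  gc <- sum(strsplit(p, "")[[1]] %in% c("G", "C"))
  if (n < 14) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}

#' Validate a mutagenesis primer pair
#'
#' Runs four checks: (a) mutual complementarity -- the reverse complement of
#' the reverse primer must share a contiguous exact overlap of at least
#' `min_overlap` nt with the forward primer; (b) template match (only when a
#' template is supplied) -- each primer must match the template except
#' within the intended codon, whose change must translate as the target
#' substitution; (c) intended codon -- a codon of the target residue must be
#' present in the overlap (the pair's declared mutant codon when available);
#' (d) an informational melting-temperature estimate per primer.
#'
#' @param pair a `primer_pair`.
#' @param template_nt optional in-frame template gene for check (b).
#' @param min_overlap minimum acceptable overlap for check (a).
#' @return list of class `primer_validation`: `checks` (data.frame of
#'   check/pass/detail), `overlap_len`, `mutant_codon_found`, `tm_forward`,
#'   `tm_reverse`, `pass`.
#' @export
validate_primer_pair <- function(pair, template_nt = NULL, min_overlap = 15L) {
  stopifnot(inherits(pair, "primer_pair"))
  rc <- revcomp(pair$reverse)
  run <- best_overlap_run(pair$forward, rc)
  overlap <- substr(pair$forward, run$x_off + 1L, run$x_off + run$len)
  pass_a <- run$len >= min_overlap
  detail_a <- sprintf("exact complementary overlap %d nt", run$len)

  # (c) intended codon within the overlap
  to_codons <- CODON_PREFERENCE[[pair$target$to_aa]]
  if (!is.null(pair$mutant_codon)) {
    to_codons <- unique(c(pair$mutant_codon, to_codons))
  }
  found <- to_codons[vapply(to_codons, grepl, logical(1), x = overlap,
                            fixed = TRUE)]
  mutant_codon_found <- if (length(found)) found[1L] else NA_character_
  pass_c <- length(found) > 0L
  detail_c <- if (pass_c) {
    sprintf("codon %s (%s) present in overlap", mutant_codon_found,
            pair$target$to_aa)
  } else {
    sprintf("no codon of %s found in overlap", pair$target$to_aa)
  }

  # (b) against the template: mismatches confined to one codon, translating
  # as the target substitution
  pass_b <- NA; detail_b <- "no template supplied"
  if (!is.null(template_nt)) {
    template_nt <- toupper(template_nt)
    check_primer <- function(p) {
      pc <- strsplit(p, "")[[1]]
      tc <- strsplit(template_nt, "")[[1]]
      np <- length(pc); nt <- length(tc)
      if (np > nt) return(NULL)
      best <- NULL
      for (off in 0:(nt - np)) {
        mm <- which(pc != tc[off + seq_len(np)])
        if (is.null(best) || length(mm) < length(best$mm)) {
          best <- list(off = off, mm = mm)
        }
      }
      best
    }
    res_f <- check_primer(pair$forward)
    res_r <- check_primer(rc)
    codon_ok <- function(res, primer) {
      if (is.null(res)) return(FALSE)
      tpos <- res$off + res$mm  # 1-based template coords
      if (length(tpos) == 0L) return(FALSE)  # no edit: wrong primer/template
      codon_idx <- unique((tpos - 1L) %/% 3L)
      if (length(codon_idx) != 1L) return(FALSE)
      k <- codon_idx
      tcodon <- substr(template_nt, 3L * k + 1L, 3L * k + 3L)
      pcodon <- substr(primer, 3L * k - res$off + 1L, 3L * k - res$off + 3L)
      if (3L * k < res$off || 3L * k + 3L > res$off + nchar(primer)) {
        return(FALSE)
      }
      identical(codon_to_aa(tcodon), pair$target$from_aa) &&
        identical(codon_to_aa(pcodon), pair$target$to_aa)
    }
    ok_f <- codon_ok(res_f, pair$forward)
    ok_r <- codon_ok(res_r, rc)
    pass_b <- ok_f && ok_r
    detail_b <- sprintf(
      "forward: %s (%d mismatches); reverse: %s (%d mismatches)",
      if (ok_f) "ok" else "fail", length(res_f$mm),
      if (ok_r) "ok" else "fail", length(res_r$mm))
  }

  checks <- data.frame(
    check = c("complementarity", "template_match", "intended_codon"),
    pass = c(pass_a, pass_b, pass_c),
    detail = c(detail_a, detail_b, detail_c),
    stringsAsFactors = FALSE)
  structure(list(checks = checks,
                 overlap_len = run$len,
                 mutant_codon_found = mutant_codon_found,
                 tm_forward = primer_tm(pair$forward),
                 tm_reverse = primer_tm(pair$reverse),
                 pass = isTRUE(pass_a) && isTRUE(pass_c) &&
                   (is.na(pass_b) || isTRUE(pass_b))),
            class = "primer_validation")
}

#' @export
print.primer_validation <- function(x, ...) {
  cat(sprintf("<primer_validation> overall %s\n",
              if (x$pass) "PASS" else "FAIL"))
  print(x$checks)
  cat(sprintf("  Tm(fwd) %.1f C, Tm(rev) %.1f C\n", x$tm_forward, x$tm_reverse))
  invisible(x)
}

#' Published mutagenesis primer pairs for the 212579 variant panel
#'
#' Reads the packaged table of primer pairs used to construct the 212579
#' reversion and allele-swap variants (forward and reverse separated; the
#' pair boundaries follow the published layout, reconstructed from mutual
#' complementarity where the layout is ambiguous).
#'
#' @return data.frame with columns `substitution`, `forward`, `reverse`.
#' @export
primer_table_212579 <- function() {
  utils::read.csv(system.file("extdata", "primers_212579.csv",
                              package = "ablineage"),
                  stringsAsFactors = FALSE)
}
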