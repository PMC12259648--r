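#' Immunoglobulin germline allele
#'
#' One V, D, or J allele of an immunoglobulin locus. V alleles carry an
#' IMGT-gapped sequence (gap character `.`) whose codons align one-to-one
#' with IMGT positions 1--104; removing the gaps recovers the plain
#' nucleotide sequence. J alleles may carry an `fr4` annotation: the 0-based
#' nucleotide offset within the ungapped sequence at which the FR4 region
#' (IMGT position 118) begins.
#'
#' @param name allele designation, e.g. `"IGHV3-48*03"` (gene `*` allele).
#' @param locus one of `"IGH"`, `"IGK"`, `"IGL"`.
#' @param segment one of `"V"`, `"D"`, `"J"`.
#' @param seq_nt DNA string over A/C/G/T. If missing it is derived from
#'   `gapped_seq_nt`.
#' @param gapped_seq_nt DNA-with-gaps string; `.` and `-` both accepted as
#'   gap characters and normalized to `.`. Required for V alleles.
#' @param fr4 for J alleles, 0-based offset of the FR4 start (optional).
#' @return an object of class `germline_allele`.
#' @export
germline_allele <- function(name, locus, segment, seq_nt = NULL,
                            gapped_seq_nt = NULL, fr4 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!locus %in% c("IGH", "IGK", "IGL")) {
    stop_ab(sprintf("unknown locus '%s' for allele %s", locus, name),
            "ablineage_format_error")
  }
  if (!segment %in% c("V", "D", "J")) {
    stop_ab(sprintf("unknown segment '%s' for allele %s", segment, name),
            "ablineage_format_error")
  }
  if (!grepl("^[^*]+\\*[0-9]+$", name)) {
    stop_ab(sprintf("allele name '%s' does not parse as <gene>*<allele>", name),
            "ablineage_format_error")
  }
  if (!is.null(gapped_seq_nt)) {
    gapped_seq_nt <- toupper(gsub("-", ".", gapped_seq_nt))
    if (!grepl("^[ACGT.]*$", gapped_seq_nt)) {
      stop_ab(sprintf("allele %s: non-DNA characters in gapped sequence", name),
              "ablineage_format_error")
    }
    degapped <- gsub(".", "", gapped_seq_nt, fixed = TRUE)
    if (is.null(seq_nt)) seq_nt <- degapped
    if (!identical(seq_nt, degapped)) {
      stop_ab(sprintf("allele %s: seq_nt does not match degapped sequence", name),
              "ablineage_format_error")
    }
  }
  seq_nt <- toupper(seq_nt)
  if (!is_dna(seq_nt)) {
    stop_ab(sprintf("allele %s: non-DNA characters in sequence", name),
            "ablineage_format_error")
  }
  if (segment == "V") {
    if (is.null(gapped_seq_nt)) {
      stop_ab(sprintf("V allele %s requires an IMGT-gapped sequence", name),
              "ablineage_format_error")
    }
    if (nchar(gapped_seq_nt) %% 3L != 0L) {
      stop_ab(sprintf(
        "V allele %s: gapped length %d is not a multiple of 3",
        name, nchar(gapped_seq_nt)), "ablineage_format_error")
    }
    if (nchar(gapped_seq_nt) / 3L > 104L) {
      stop_ab(sprintf("V allele %s: gapped sequence exceeds IMGT codon 104", name),
              "ablineage_format_error")
    }
  }
  structure(list(name = name, locus = locus, segment = segment,
                 seq_nt = seq_nt, gapped_seq_nt = gapped_seq_nt,
                 fr4 = if (!is.null(fr4)) as.integer(fr4) else NULL),
            class = "germline_allele")
}

#' @export
print.germline_allele <- function(x, ...) {
  cat(sprintf("<germline_allele> %s [%s %s] %d nt\n",
              x$name, x$locus, x$segment, nchar(x$seq_nt)))
  invisible(x)
}

allele_gene <- function(allele) sub("\\*[0-9]+$", "", allele$name)

# codon table of a gapped V allele: IMGT position, codon ("..." for gaps)
v_gapped_codons <- function(allele) {
  stopifnot(allele$segment == "V")
  split_codons(allele$gapped_seq_nt)
}

#' Read a germline allele set from FASTA
#'
#' Headers follow the convention `>NAME|LOCUS|SEGMENT[|key=value...]`;
#' the only key currently used is `fr4` on J alleles (0-based FR4 start
#' offset). V records must carry IMGT-gapped sequences (dots or dashes).
#'
#' @param path FASTA file path.
#' @return a named list of `germline_allele` objects, class `germline_set`.
#' @export
read_germline_set <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  alleles <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    header <- names(recs)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_ab(sprintf("header '%s' does not follow NAME|LOCUS|SEGMENT", header),
              "ablineage_format_error")
    }
    kv <- list()
    if (length(fields) > 3L) {
      for (f in fields[-(1:3)]) {
        p <- strsplit(f, "=", fixed = TRUE)[[1]]
        if (length(p) == 2L) kv[[p[1]]] <- p[2]
      }
    }
    seqchr <- toupper(as.character(recs[[i]]))
    gapped <- if (grepl("[.-]", seqchr)) seqchr else NULL
    if (fields[3] == "V" && is.null(gapped)) gapped <- seqchr
    alleles[[i]] <- germline_allele(
      name = fields[1], locus = fields[2], segment = fields[3],
      seq_nt = if (is.null(gapped)) seqchr else NULL,
      gapped_seq_nt = gapped,
      fr4 = kv$fr4)
  }
  nm <- vapply(alleles, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_ab(sprintf("duplicate allele name '%s'", nm[duplicated(nm)][1]),
            "ablineage_format_error")
  }
  names(alleles) <- nm
  structure(alleles, class = "germline_set")
}

#' Write a germline allele set to FASTA
#'
#' Inverse of [read_germline_set()].
#'
#' @param set a `germline_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_set <- function(set, path) {
  lines <- unlist(lapply(set, function(a) {
    header <- paste0(">", a$name, "|", a$locus, "|", a$segment,
                     if (!is.null(a$fr4)) paste0("|fr4=", a$fr4) else "")
    seqchr <- if (!is.null(a$gapped_seq_nt)) a$gapped_seq_nt else a$seq_nt
    c(header, seqchr)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("<germline_set> %d alleles\n", length(x)))
  for (a in x) cat(sprintf("  %-16s %s %s %4d nt\n", a$name, a$locus,
                           a$segment, nchar(a$seq_nt)))
  invisible(x)
}

# subset by locus/segment
filter_set <- function(set, locus = NULL, segment = NULL) {
  keep <- vapply(set, function(a) {
    (is.null(locus) || a$locus %in% locus) &&
      (is.null(segment) || a$segment %in% segment)
  }, logical(1))
  structure(set[keep], class = "germline_set")
}

#' Variable-domain sequence under IMGT numbering
#'
#' Constructor for the numbered-domain container: every residue is bound to
#' an IMGT position, its underlying codon, and its region label.
#'
#' @param chain `"H"` or `"L"`.
#' @param position an `imgt_position` table (strictly increasing).
#' @param aa amino-acid letters, one per position.
#' @param codon DNA codons, one per position.
#' @return a data.frame of class `numbered_domain` with columns
#'   `position` (formatted label), `number`, `insertion`, `aa`, `codon`,
#'   `region`, and a `chain` attribute.
#' @export
numbered_domain <- function(chain, position, aa, codon) {
  stopifnot(chain %in% c("H", "L"), inherits(position, "imgt_position"))
  k <- imgt_key(position)
  if (any(diff(k) <= 0)) {
    stop_ab("IMGT positions must be strictly increasing", "ablineage_domain_error")
  }
  out <- data.frame(position = imgt_format(position),
                    number = position$number,
                    insertion = position$insertion,
                    aa = aa, codon = codon,
                    region = imgt_region(position),
                    stringsAsFactors = FALSE)
  structure(out, class = c("numbered_domain", "data.frame"), chain = chain)
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain> chain %s, %d residues (%s)\n",
              attr(x, "chain"), nrow(x), paste(unique(x$region), collapse = " ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Propagate IMGT numbering onto a V-encoded region
#'
#' Each codon of `seq_nt` inherits the IMGT position of the germline codon it
#' aligns to, walking the IMGT-gapped germline codon by codon from position 1
#' (gap-free, 5'-anchored alignment; this clonotype carries no indels).
#' Positions gapped in the germline are absent from the output. Misalignment
#' consistent with an indel (mismatch fraction above `max_mismatch_frac`) is
#' an explicit error, never silently repaired.
#'
#' @param seq_nt rearranged nucleotide sequence, 5' end at germline codon 1.
#' @param v_allele a V `germline_allele` with gapped sequence.
#' @param chain `"H"` or `"L"`.
#' @param max_mismatch_frac mismatch tolerance before the alignment is
#'   declared indel-like (default 0.2).
#' @return a `numbered_domain` covering positions 1 through the end of the
#'   V-encoded region (or of `seq_nt` if shorter).
#' @export
number_v_domain <- function(seq_nt, v_allele, chain,
                            max_mismatch_frac = 0.2) {
  stopifnot(inherits(v_allele, "germline_allele"), v_allele$segment == "V")
  seq_nt <- toupper(seq_nt)
  if (!is_dna(seq_nt)) {
    stop_ab("sequence contains non-DNA characters", "ablineage_format_error")
  }
  gcodons <- v_gapped_codons(v_allele)
  is_gap <- grepl(".", gcodons, fixed = TRUE)
  if (any(is_gap & gcodons != "...")) {
    stop_ab(sprintf("V allele %s: partially gapped codon", v_allele$name),
            "ablineage_format_error")
  }
  n_codons <- min(sum(!is_gap), nchar(seq_nt) %/% 3L)
  pos_numbers <- which(!is_gap)[seq_len(n_codons)]
  codons <- split_codons(seq_nt)[seq_len(n_codons)]
  germ <- gcodons[!is_gap][seq_len(n_codons)]
  mm <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, codons, germ))
  if (mm / (3L * n_codons) > max_mismatch_frac) {
    stop_ab(sprintf(
      "sequence does not align to %s without indels (mismatch fraction %.2f)",
      v_allele$name, mm / (3L * n_codons)), "ablineage_indel_error")
  }
  numbered_domain(chain, imgt_position(pos_numbers),
                  aa = codon_to_aa(codons), codon = codons)
}

#' Compare two gapped V alleles residue by residue
#'
#' Translates both IMGT-gapped sequences codon-wise and reports every IMGT
#' position at which the encoded residues differ, with region labels.
#' Comparing an allele with itself returns zero rows.
#'
#' @param a,b V `germline_allele` objects of the same gene.
#' @return data.frame with columns `position`, `aa_a`, `aa_b`, `region`.
#' @export
compare_alleles <- function(a, b) {
  stopifnot(inherits(a, "germline_allele"), inherits(b, "germline_allele"))
  if (a$segment != "V" || b$segment != "V") {
    stop_ab("compare_alleles requires two V alleles", "ablineage_usage_error")
  }
  if (a$locus != b$locus) {
    stop_ab("cannot compare alleles of different loci", "ablineage_usage_error")
  }
  if (allele_gene(a) != allele_gene(b)) {
    stop_ab("cannot compare alleles of different genes", "ablineage_usage_error")
  }
  ca <- v_gapped_codons(a); cb <- v_gapped_codons(b)
  n <- min(length(ca), length(cb))
  ca <- ca[seq_len(n)]; cb <- cb[seq_len(n)]
  gap_a <- ca == "..."; gap_b <- cb == "..."
  if (any(gap_a != gap_b)) {
    warn_ab("alleles have different gap architectures; shared positions compared",
            "ablineage_gap_warning")
  }
  both <- !gap_a & !gap_b
  aa_a <- codon_to_aa(ca[both]); aa_b <- codon_to_aa(cb[both])
  pos <- which(both)[aa_a != aa_b]
  data.frame(position = pos,
             aa_a = aa_a[aa_a != aa_b],
             aa_b = aa_b[aa_a != aa_b],
             region = imgt_region(imgt_position(pos)),
             stringsAsFactors = FALSE)
}
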