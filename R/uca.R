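#' A rearranged antibody variable-domain sequence
#'
#' @param id sequence identifier.
#' @param chain `"H"` or `"L"`.
#' @param seq_nt in-frame DNA from the V-region 5' end through the end of J.
#'   Sanity floor: at least 250 nt (heavy) / 230 nt (light); must translate
#'   without stop codons.
#' @return an object of class `rearrangement`.
#' @export
rearrangement <- function(id, chain, seq_nt) {
  stopifnot(chain %in% c("H", "L"))
  seq_nt <- toupper(seq_nt)
  if (!is_dna(seq_nt)) {
    stop_ab(sprintf("rearrangement %s: non-DNA characters", id),
            "ablineage_format_error")
  }
  floor_nt <- if (chain == "H") 250L else 230L
  if (nchar(seq_nt) < floor_nt) {
    stop_ab(sprintf("rearrangement %s: %d nt is below the %d nt sanity floor",
                    id, nchar(seq_nt), floor_nt), "ablineage_format_error")
  }
  if (grepl("*", translate_nt(seq_nt), fixed = TRUE)) {
    stop_ab(sprintf("rearrangement %s: stop codon in reading frame", id),
            "ablineage_format_error")
  }
  structure(list(id = id, chain = chain, seq_nt = seq_nt),
            class = "rearrangement")
}

#' @export
print.rearrangement <- function(x, ...) {
  cat(sprintf("<rearrangement> %s chain %s, %d nt\n", x$id, x$chain,
              nchar(x$seq_nt)))
  invisible(x)
}

# internal: ungapped alignment record; 0-based half-open intervals
segment_alignment <- function(allele_name, segment, read_start, read_end,
                              germline_start, germline_end,
                              mismatch_positions = integer(0),
                              co_optimal = character(0)) {
  stopifnot(read_end > read_start, germline_end > germline_start,
            read_end - read_start == germline_end - germline_start)
  structure(list(allele_name = allele_name, segment = segment,
                 read_start = as.integer(read_start),
                 read_end = as.integer(read_end),
                 germline_start = as.integer(germline_start),
                 germline_end = as.integer(germline_end),
                 mismatch_positions = as.integer(mismatch_positions),
                 co_optimal = co_optimal),
            class = "segment_alignment")
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat(sprintf("<segment_alignment> %s [%d,%d) <- germline [%d,%d), %d mismatches\n",
              x$allele_name, x$read_start, x$read_end, x$germline_start,
              x$germline_end, length(x$mismatch_positions)))
  invisible(x)
}

# score an ungapped overlap: matches - 4*mismatches (IgBLAST-like penalty);
# returns list(score, mismatch read coords 0-based relative to read_off)
score_overlap <- function(read_chars, germ_chars, read_off, germ_off, len) {
  a <- read_chars[read_off + seq_len(len)]
  b <- germ_chars[germ_off + seq_len(len)]
  mm <- which(a != b)
  list(score = (len - length(mm)) - 4L * length(mm),
       mismatches = read_off + mm - 1L)
}

#' Assign the V germline allele of a rearrangement
#'
#' Gap-free alignment anchored at the read 5' end; the germline 3' end may be
#' trimmed (exonuclease trimming during rearrangement). The allele maximizing
#' the match score (matches minus 4 per mismatch, over its best trim) is
#' selected; co-optimal alleles are reported as ties and the
#' lexicographically smallest name is used. Assignment fails if the best
#' alignment still mismatches more than `max_mismatch_frac` of its overlap.
#'
#' @param r a `rearrangement`.
#' @param alleles a `germline_set` (non-V/other-locus members are ignored).
#' @param max_mismatch_frac rejection threshold on mismatch fraction.
#' @param max_trim maximum germline 3' trimming considered.
#' @return a `segment_alignment`.
#' @export
align_v <- function(r, alleles, max_mismatch_frac = 0.2, max_trim = 30L) {
  locus <- if (r$chain == "H") "IGH" else c("IGK", "IGL")
  cand <- filter_set(alleles, locus = locus, segment = "V")
  if (length(cand) == 0L) {
    stop_ab("no V alleles of matching locus", "ablineage_usage_error")
  }
  read_chars <- strsplit(r$seq_nt, "")[[1]]
  best <- NULL
  scores <- numeric(0)
  for (a in cand) {
    germ_chars <- strsplit(a$seq_nt, "")[[1]]
    U <- length(germ_chars)
    best_a <- NULL
    for (t in 0:min(max_trim, U - 30L)) {
      len <- min(U - t, length(read_chars))
      sc <- score_overlap(read_chars, germ_chars, 0L, 0L, len)
      if (is.null(best_a) || sc$score > best_a$score) {
        best_a <- c(sc, list(trim = t, len = len))
      }
    }
    scores[a$name] <- best_a$score
    if (is.null(best) || best_a$score > best$score ||
        (best_a$score == best$score && a$name < best$allele)) {
      best <- c(best_a, list(allele = a$name))
    }
  }
  co <- names(scores)[scores == max(scores)]
  frac <- length(best$mismatches) / best$len
  if (frac > max_mismatch_frac) {
    stop_ab(sprintf("no V assignment: best allele %s mismatches %.2f of overlap",
                    best$allele, frac), "ablineage_no_assignment_error")
  }
  segment_alignment(best$allele, "V", 0L, best$len, 0L, best$len,
                    best$mismatches, co_optimal = sort(co))
}

#' Assign the J germline allele of a rearrangement
#'
#' As [align_v()] but anchored at the read 3' end (the rearrangement ends at
#' the J 3' end), allowing 5' trimming of the germline J.
#'
#' @inheritParams align_v
#' @param max_trim maximum germline 5' trimming considered.
#' @return a `segment_alignment` whose `germline_start` equals the inferred
#'   5' trim.
#' @export
align_j <- function(r, alleles, max_mismatch_frac = 0.2, max_trim = 15L) {
  locus <- if (r$chain == "H") "IGH" else c("IGK", "IGL")
  cand <- filter_set(alleles, locus = locus, segment = "J")
  if (length(cand) == 0L) {
    stop_ab("no J alleles of matching locus", "ablineage_usage_error")
  }
  read_chars <- strsplit(r$seq_nt, "")[[1]]
  n <- length(read_chars)
  best <- NULL
  scores <- numeric(0)
  for (a in cand) {
    germ_chars <- strsplit(a$seq_nt, "")[[1]]
    Jlen <- length(germ_chars)
    best_a <- NULL
    for (t in 0:min(max_trim, Jlen - 12L)) {
      len <- Jlen - t
      if (len > n) next
      sc <- score_overlap(read_chars, germ_chars, n - len, t, len)
      if (is.null(best_a) || sc$score > best_a$score) {
        best_a <- c(sc, list(trim = t, len = len))
      }
    }
    if (is.null(best_a)) next
    scores[a$name] <- best_a$score
    if (is.null(best) || best_a$score > best$score ||
        (best_a$score == best$score && a$name < best$allele)) {
      best <- c(best_a, list(allele = a$name))
    }
  }
  if (is.null(best)) {
    stop_ab("no J allele could be aligned", "ablineage_no_assignment_error")
  }
  co <- names(scores)[scores == max(scores)]
  frac <- length(best$mismatches) / best$len
  if (frac > max_mismatch_frac) {
    stop_ab(sprintf("no J assignment: best allele %s mismatches %.2f of overlap",
                    best$allele, frac), "ablineage_no_assignment_error")
  }
  segment_alignment(best$allele, "J", n - best$len, n,
                    best$trim, best$trim + best$len,
                    best$mismatches, co_optimal = sort(co))
}

# longest exact common run between window and germline D; returns
# list(len, win_off, germ_off) with leftmost-in-window, then smallest
# germline offset tie-break; NULL if no common base
longest_exact_run <- function(win_chars, d_chars) {
  nw <- length(win_chars); nd <- length(d_chars)
  if (nw == 0L || nd == 0L) return(NULL)
  best <- list(len = 0L, win_off = 0L, germ_off = 0L)
  # DP over diagonal runs
  prev <- integer(nd)
  for (i in seq_len(nw)) {
    cur <- integer(nd)
    for (j in seq_len(nd)) {
      if (win_chars[i] == d_chars[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        len <- cur[j]
        if (len > best$len) {
          best <- list(len = len, win_off = i - len, germ_off = j - len)
        }
      }
    }
    prev <- cur
  }
  if (best$len == 0L) NULL else best
}

#' Search the junction window for D gene matches
#'
#' Exact-substring search of all heavy-chain D alleles against the window
#' between the V 3' end and the J 5' start. The longest exact run wins; all
#' alleles achieving the maximal run length (>= `min_len`) are returned as
#' co-optimal candidates. An empty list (no run of at least `min_len`) is a
#' legitimate outcome, as for light chains.
#'
#' @param r a `rearrangement` (heavy chain).
#' @param v_aln,j_aln `segment_alignment`s from [align_v()]/[align_j()].
#' @param alleles a `germline_set`.
#' @param min_len minimum exact run length to call a D gene (default 5).
#' @return list of `segment_alignment`s, one per co-optimal D allele,
#'   ordered by allele name.
#' @export
find_d <- function(r, v_aln, j_aln, alleles, min_len = 5L) {
  if (r$chain != "H") {
    stop_ab("D search applies to heavy chains only", "ablineage_usage_error")
  }
  if (j_aln$read_start <= v_aln$read_end) {
    stop_ab("junction window is empty", "ablineage_usage_error")
  }
  cand <- filter_set(alleles, locus = "IGH", segment = "D")
  win <- substr(r$seq_nt, v_aln$read_end + 1L, j_aln$read_start)
  win_chars <- strsplit(win, "")[[1]]
  runs <- list()
  for (a in cand) {
    run <- longest_exact_run(win_chars, strsplit(a$seq_nt, "")[[1]])
    if (!is.null(run) && run$len >= min_len) runs[[a$name]] <- run
  }
  if (length(runs) == 0L) return(list())
  lens <- vapply(runs, `[[`, integer(1), "len")
  winners <- sort(names(runs)[lens == max(lens)])
  lapply(winners, function(nm) {
    run <- runs[[nm]]
    segment_alignment(nm, "D",
                      v_aln$read_end + run$win_off,
                      v_aln$read_end + run$win_off + run$len,
                      run$germ_off, run$germ_off + run$len)
  })
}

#' Classify every base of a rearrangement as templated or non-templated
#'
#' Bases inside a segment alignment are labeled with that segment (V, D, J);
#' all remaining bases are non-templated (N). Overlapping claims are resolved
#' by the precedence V > J > D with a warning.
#'
#' @param r a `rearrangement`.
#' @param v_aln,j_aln alignments from [align_v()]/[align_j()].
#' @param d_alns list of D alignments from [find_d()] (may be empty; the
#'   first candidate provides the labels, all are recorded as ties).
#' @return an object of class `junction_annotation`: fields `labels`
#'   (character vector over the read, values V/D/J/N), `d_candidates`,
#'   `v`, `d`, `j`.
#' @export
classify_bases <- function(r, v_aln, d_alns = list(), j_aln) {
  n <- nchar(r$seq_nt)
  labels <- rep("N", n)
  claim <- function(labels, aln, code) {
    idx <- (aln$read_start + 1L):aln$read_end
    if (any(labels[idx] != "N")) {
      warn_ab(sprintf("segment %s overlaps a previous claim; precedence V > J > D applied",
                      code), "ablineage_overlap_warning")
    }
    labels[idx] <- ifelse(labels[idx] == "N", code, labels[idx])
    labels
  }
  # lowest precedence first; later claims do not overwrite earlier ones,
  # so apply V, then J, then D
  labels <- claim(labels, v_aln, "V")
  labels <- claim(labels, j_aln, "J")
  d <- NULL
  if (length(d_alns) > 0L) {
    d <- d_alns[[1L]]
    labels <- claim(labels, d, "D")
  }
  structure(list(labels = labels,
                 d_candidates = vapply(d_alns, `[[`, character(1), "allele_name"),
                 v = v_aln, d = d, j = j_aln),
            class = "junction_annotation")
}

#' @export
print.junction_annotation <- function(x, ...) {
  cat(sprintf("<junction_annotation> %s", paste0(rle(x$labels)$values,
                                                 rle(x$labels)$lengths,
                                                 collapse = " ")), "\n")
  invisible(x)
}

# full-domain IMGT numbering of a rearrangement given its V and J assignment
number_full_domain <- function(seq_nt, chain, v_allele, j_allele, j_aln) {
  U <- nchar(v_allele$seq_nt)
  if (is.null(j_allele$fr4)) {
    stop_ab(sprintf("J allele %s lacks an fr4 annotation", j_allele$name),
            "ablineage_usage_error")
  }
  fr4_read_start <- j_aln$read_start + (j_allele$fr4 - j_aln$germline_start)
  cdr3_nt <- fr4_read_start - U
  if (cdr3_nt %% 3L != 0L || cdr3_nt < 3L) {
    stop_ab(sprintf("CDR3 of %d nt is not a positive codon multiple", cdr3_nt),
            "ablineage_domain_error")
  }
  L <- cdr3_nt %/% 3L
  gcodons <- v_gapped_codons(v_allele)
  v_positions <- which(gcodons != "...")
  cdr3_pos <- number_cdr3(L)
  n_fr4 <- (nchar(seq_nt) - fr4_read_start) %/% 3L
  pos <- imgt_position(
    c(v_positions, cdr3_pos$number, 117L + seq_len(n_fr4)),
    c(rep(NA_integer_, length(v_positions)), cdr3_pos$insertion,
      rep(NA_integer_, n_fr4)))
  codons <- split_codons(substr(seq_nt, 1L, fr4_read_start + 3L * n_fr4))
  stopifnot(length(codons) == nrow(pos))
  numbered_domain(chain, pos, aa = codon_to_aa(codons), codon = codons)
}

#' Build the most-likely unmutated common ancestor of a rearrangement
#'
#' Under the assumption that non-templated junction bases carry no mutation,
#' the UCA is obtained by reverting every templated base to its germline
#' state and copying N-labeled bases from the observed read. Substitutions
#' (UCA residue, IMGT position, mature residue) are the translated
#' differences between the mature domain and the UCA.
#'
#' @param r a `rearrangement`.
#' @param annotation a `junction_annotation` from [classify_bases()].
#' @param alleles the `germline_set` holding the assigned alleles.
#' @return an object of class `uca_result`: `uca_nt`, `uca_domain` and
#'   `mature_domain` (`numbered_domain`s), `substitutions` (list of
#'   `substitution`), `codon_coverage` (templated-base count per CDR3
#'   position), plus the segment calls.
#' @export
build_uca <- function(r, annotation, alleles) {
  read_chars <- strsplit(r$seq_nt, "")[[1]]
  uca_chars <- read_chars
  revert <- function(uca_chars, aln, germ_nt) {
    germ_chars <- strsplit(germ_nt, "")[[1]]
    idx <- (aln$read_start + 1L):aln$read_end
    uca_chars[idx] <- germ_chars[aln$germline_start + seq_along(idx)]
    uca_chars
  }
  v_allele <- alleles[[annotation$v$allele_name]]
  j_allele <- alleles[[annotation$j$allele_name]]
  uca_chars <- revert(uca_chars, annotation$v, v_allele$seq_nt)
  uca_chars <- revert(uca_chars, annotation$j, j_allele$seq_nt)
  if (!is.null(annotation$d)) {
    d_allele <- alleles[[annotation$d$allele_name]]
    uca_chars <- revert(uca_chars, annotation$d, d_allele$seq_nt)
  }
  # N-labeled bases must be untouched
  stopifnot(all(uca_chars[annotation$labels == "N"] ==
                  read_chars[annotation$labels == "N"]))
  uca_nt <- paste(uca_chars, collapse = "")
  mature_dom <- number_full_domain(r$seq_nt, r$chain, v_allele, j_allele,
                                   annotation$j)
  uca_dom <- number_full_domain(uca_nt, r$chain, v_allele, j_allele,
                                annotation$j)
  diff <- which(mature_dom$aa != uca_dom$aa)
  subs <- lapply(diff, function(i) {
    substitution(uca_dom$aa[i],
                 imgt_position(uca_dom$number[i], uca_dom$insertion[i]),
                 r$chain, mature_dom$aa[i])
  })
  U <- nchar(v_allele$seq_nt)
  cdr3 <- uca_dom[uca_dom$region == "CDR3", , drop = FALSE]
  cov <- codon_template_coverage(annotation,
                                 imgt_position(cdr3$number, cdr3$insertion),
                                 cdr3_start = U)
  structure(list(id = r$id, chain = r$chain,
                 uca_nt = uca_nt,
                 uca_domain = uca_dom, mature_domain = mature_dom,
                 substitutions = order_substitutions(subs),
                 codon_coverage = cov,
                 v_call = annotation$v$allele_name,
                 d_call = annotation$d_candidates,
                 j_call = annotation$j$allele_name,
                 cdr3_length = nrow(cdr3)),
            class = "uca_result")
}

#' @export
print.uca_result <- function(x, ...) {
  cat(sprintf("<uca_result> %s chain %s: V=%s D=%s J=%s, CDR3 %d aa\n",
              x$id, x$chain, x$v_call,
              if (length(x$d_call)) paste(x$d_call, collapse = "/") else "-",
              x$j_call, x$cdr3_length))
  if (length(x$substitutions) == 0L) {
    cat("  no substitutions relative to the UCA\n")
  } else {
    cat("  substitutions:",
        paste(vapply(x$substitutions, format_substitution, character(1)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count germline-templated bases per CDR3 codon
#'
#' Residues with count 0 are encoded entirely by non-templated junction
#' bases ("not encoded by any base" of the germline genes).
#'
#' @param annotation a `junction_annotation`.
#' @param cdr3_positions an `imgt_position` table for the CDR3 loop.
#' @param cdr3_start 0-based read offset of the first CDR3 base.
#' @return named integer vector (position label -> count in 0..3).
#' @export
codon_template_coverage <- function(annotation, cdr3_positions, cdr3_start) {
  L <- nrow(cdr3_positions)
  counts <- vapply(seq_len(L) - 1L, function(i) {
    idx <- cdr3_start + 3L * i + (1:3)
    sum(annotation$labels[idx] %in% c("V", "D", "J"))
  }, integer(1))
  names(counts) <- imgt_format(cdr3_positions)
  counts
}

#' One-call UCA inference
#'
#' Runs V/J assignment, D search, junction base classification and UCA
#' construction on one rearrangement.
#'
#' @param r a `rearrangement`.
#' @param alleles a `germline_set`.
#' @param min_d_len minimum exact D run (heavy chains), see [find_d()].
#' @return a `uca_result`.
#' @export
infer_uca <- function(r, alleles, min_d_len = 5L) {
  v_aln <- align_v(r, alleles)
  j_aln <- align_j(r, alleles)
  d_alns <- if (r$chain == "H" && j_aln$read_start > v_aln$read_end) {
    find_d(r, v_aln, j_aln, alleles, min_len = min_d_len)
  } else list()
  ann <- classify_bases(r, v_aln, d_alns, j_aln)
  build_uca(r, ann, alleles)
}
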