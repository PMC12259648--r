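test_that("the full lineage input enumerates the 13-member study panel", {
  panel <- enumerate_panel(HEAVY_REVERSIONS, LIGHT_REVERSIONS, ALLELE_SWAPS)
  expect_length(panel, 13L)
  names_got <- vapply(panel, `[[`, character(1), "name")
  expect_setequal(names_got, c(
    "parental", "UCA",
    "T40_H_N", "I53_H_V", "H113_H_Y",
    "T40_H_N, I53_H_V", "T40_H_N, I53_H_V, H113_H_Y",
    "I29_L_V, T40_L_A, V108_L_G",
    "I53_H_V, I29_L_V, T40_L_A, V108_L_G",
    "T40_H_N, I29_L_V, T40_L_A, V108_L_G",
    "E38_H_S", "G62_H_S", "E38_H_S, G62_H_S"))
})

test_that("panel enumeration handles degenerate inputs and ignores input order", {
  expect_equal(vapply(enumerate_panel(), `[[`, character(1), "name"),
               "parental")
  # heavy singles only: parental, 3 singles, cumulative pair and triple
  p <- enumerate_panel(HEAVY_REVERSIONS)
  expect_equal(vapply(p, `[[`, character(1), "name"),
               c("parental", "T40_H_N", "I53_H_V", "H113_H_Y",
                 "T40_H_N, I53_H_V", "UCA"))
  shuffled <- enumerate_panel(rev(HEAVY_REVERSIONS), rev(LIGHT_REVERSIONS),
                              rev(ALLELE_SWAPS))
  straight <- enumerate_panel(HEAVY_REVERSIONS, LIGHT_REVERSIONS, ALLELE_SWAPS)
  expect_equal(vapply(shuffled, `[[`, character(1), "name"),
               vapply(straight, `[[`, character(1), "name"))
})

test_that("two substitutions at one position are rejected in a variant", {
  expect_error(variant_spec(lapply(c("T40_H_N", "T40_H_A"), parse_substitution)),
               class = "ablineage_usage_error")
})

test_that("codon edits are minimal with table-seeded tie-breaks (ACC + T40N -> AAC)", {
  # miniature gene: positions 37-41 encoding Y-E-M-T-W (the residue-40
  # context of the published forward primer)
  pos <- imgt_position(37:41)
  codons <- c("TAC", "GAG", "ATG", "ACC", "TGG")
  dom <- numbered_domain("H", pos, aa = c("Y", "E", "M", "T", "W"),
                         codon = codons)
  gene <- paste(codons, collapse = "")
  out <- apply_substitutions(gene, dom, list("T40_H_N"))
  expect_equal(substr(out, 10, 12), "AAC")  # 1-nt edit beats AAT's tie rank
  expect_equal(substr(out, 1, 9), substr(gene, 1, 9))
  expect_equal(substr(out, 13, 15), substr(gene, 13, 15))
})

test_that("an empty substitution set is the identity and edits are bounded by 3 per site", {
  expect_equal(apply_substitutions(fixture_gene, fixture_numbered, list()),
               fixture_gene)
  subs <- list("E38_H_S", "G62_H_S")
  out <- apply_substitutions(fixture_gene, fixture_numbered, subs)
  nd <- sum(strsplit(out, "")[[1]] != strsplit(fixture_gene, "")[[1]])
  expect_lte(nd, 3L * length(subs))
  expect_gt(nd, 0L)
})

test_that("applying then reverting a substitution restores the original codon", {
  out <- apply_substitutions(fixture_gene, fixture_numbered, list("E38_H_S"))
  dom2 <- number_v_domain(out, fixture_set[["SIMHV3-48*03"]],
                          "H", max_mismatch_frac = 1)
  back <- apply_substitutions(out, dom2, list("S38_H_E"))
  expect_equal(back, fixture_gene)
})

test_that("a substitution whose source residue mismatches the gene is a consistency error", {
  expect_error(apply_substitutions(fixture_gene, fixture_numbered,
                                   list("W38_H_S")),
               class = "ablineage_consistency_error")
  expect_error(apply_substitutions(fixture_gene, fixture_numbered,
                                   list("E3_L_S")),
               class = "ablineage_usage_error")
})

test_that("designed primer pairs validate against their own template", {
  for (sub in c("E38_H_S", "G62_H_S", "T12_H_P")) {
    sub_obj <- tryCatch(parse_substitution(sub), error = function(e) NULL)
    if (is.null(sub_obj)) next
    row <- which(fixture_numbered$position == imgt_format(sub_obj$position))
    if (fixture_numbered$aa[row] != sub_obj$from_aa) next
    pair <- design_primers(fixture_gene, fixture_numbered, sub)
    v <- validate_primer_pair(pair, template_nt = fixture_gene)
    expect_true(v$pass, info = sub)
    expect_true(all(v$checks$pass))
    expect_gte(v$overlap_len, 28L)
  }
})

test_that("primer design is fuzz-closed over random positions and residues", {
  set.seed(42)
  rows <- sample(15:90, 8)
  for (row in rows) {
    cur <- fixture_numbered$aa[row]
    to <- sample(setdiff(c("A", "G", "S", "P", "K"), cur), 1)
    sub <- substitution(cur, imgt_position(fixture_numbered$number[row]),
                        "H", to)
    pair <- design_primers(fixture_gene, fixture_numbered, sub,
                           rev_offset = sample(0:3, 1))
    v <- validate_primer_pair(pair, template_nt = fixture_gene)
    expect_true(v$pass)
    expect_true(all(v$checks$pass))
  }
})

test_that("a scrambled forward primer fails complementarity", {
  pair <- design_primers(fixture_gene, fixture_numbered, "E38_H_S")
  chars <- strsplit(pair$forward, "")[[1]]
  chars[c(3, 9, 15, 21, 27)] <- c("T", "T", "A", "A", "T")
  bad <- primer_pair(paste(chars, collapse = ""), pair$reverse,
                     pair$target, pair$overlap_len)
  v <- validate_primer_pair(bad)
  expect_false(v$checks$pass[v$checks$check == "complementarity"])
})

test_that("validation against an unrelated template fails the template-match check", {
  pair <- design_primers(fixture_gene, fixture_numbered, "E38_H_S")
  unrelated <- fixture_set[["SIMKV3-20*01"]]$seq_nt
  v <- validate_primer_pair(pair, template_nt = unrelated)
  expect_false(v$checks$pass[v$checks$check == "template_match"])
})

test_that("a codon too close to the template end is a design error", {
  first_aa <- fixture_numbered$aa[1]
  sub <- substitution(first_aa, imgt_position(1), "H",
                      setdiff(c("G", "A"), first_aa)[1])
  expect_error(design_primers(fixture_gene, fixture_numbered, sub,
                              flank = 14),
               class = "ablineage_design_error")
})

test_that("every published 212579 primer pair passes complementarity and intended-codon checks", {
  pt <- primer_table_212579()
  expect_equal(nrow(pt), 7L)
  for (i in seq_len(nrow(pt))) {
    for (s in strsplit(pt$substitution[i], "+", fixed = TRUE)[[1]]) {
      pair <- primer_pair(pt$forward[i], pt$reverse[i], s, overlap_len = 15)
      v <- validate_primer_pair(pair)
      expect_true(v$checks$pass[v$checks$check == "complementarity"], info = s)
      expect_true(v$checks$pass[v$checks$check == "intended_codon"], info = s)
    }
  }
})

test_that("the T40_H_N pair overlaps 30 nt with mutant codon AAC (hand reverse-complement)", {
  pt <- primer_table_212579()
  row <- pt[pt$substitution == "T40_H_N", ]
  expect_equal(revcomp(row$reverse), "GCTCCTACGAGATGAACTGGGTTAGACAGGCG")
  expect_equal(substr(revcomp(row$reverse), 1, 30), row$forward)
  v <- validate_primer_pair(primer_pair(row$forward, row$reverse,
                                        "T40_H_N", overlap_len = 15))
  expect_equal(v$overlap_len, 30L)
  expect_equal(v$mutant_codon_found, "AAC")
})

test_that("the E38_H_S pair overlaps 31 nt with mutant codon TCG on the mature background", {
  pt <- primer_table_212579()
  row <- pt[pt$substitution == "E38_H_S", ]
  rc <- revcomp(row$reverse)
  expect_equal(nchar(rc), 31L)
  expect_equal(rc, substr(row$forward, 1, 31))
  v <- validate_primer_pair(primer_pair(row$forward, row$reverse,
                                        "E38_H_S", overlap_len = 15))
  expect_equal(v$overlap_len, 31L)
  expect_equal(v$mutant_codon_found, "TCG")
  # flanking codons read ...Y-S-M-T..., the threonine-40 (mature) context
  expect_true(grepl("TACTCGATGACC", row$forward, fixed = TRUE))
  expect_equal(translate_codons_for_test("TACTCGATGACC"), "YSMT")
})
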