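# Shared fixtures, built once per test run.

fixture_set <- make_fixture_germline_set(seed = 1)

# the six lineage reversions and the two allele swaps of the 212579 panel
HEAVY_REVERSIONS <- c("T40_H_N", "I53_H_V", "H113_H_Y")
LIGHT_REVERSIONS <- c("I29_L_V", "T40_L_A", "V108_L_G")
ALLELE_SWAPS <- c("E38_H_S", "G62_H_S")

# published Table-3 hydrodynamic radii at 25 C by heavy-residue-40 identity
RH25_N40 <- c(6.28, 6.11, 6.32, 6.03, 6.07)
RH25_T40 <- c(6.52, 6.67, 6.20, 6.53, 6.49, 6.46, 6.37)

# brute-force exact two-sided Mann-Whitney p over all labelings (oracle,
# independent of the package's rank-sum recursion)
mw_bruteforce_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(length(pool), na), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

fixture_set_for <- function(study) study$germline

# independent translation helper (Biostrings, not the package's own path)
translate_codons_for_test <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

# a small in-frame synthetic gene with its numbered domain, for primer and
# substitution tests: the fixture heavy V *03 sequence numbered onto itself
fixture_gene <- fixture_set[["SIMHV3-48*03"]]$seq_nt
fixture_numbered <- number_v_domain(fixture_gene, fixture_set[["SIMHV3-48*03"]], "H")
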