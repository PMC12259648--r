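# Synthetic inputs for every pipeline stage: fixture germline sets, V(D)J
# rearrangement simulation with recorded ground truth, and instrument-trace
# suites. All generators are pure functions of their seed.

NONSTOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

random_codons <- function(n) sample1(NONSTOP_CODONS, n, replace = TRUE)
random_nt <- function(n) paste(sample1(DNA_BASES, n, replace = TRUE),
                               collapse = "")

# build a gapped 104-codon V sequence with fixed conserved residues
build_v_gapped <- function(gap_codons, fixed = list()) {
  codons <- random_codons(104L)
  codons[c(23L, 104L)] <- "TGC"  # 1st/2nd-CYS
  codons[41L] <- "TGG"           # conserved W41
  for (p in names(fixed)) codons[as.integer(p)] <- fixed[[p]]
  codons[gap_codons] <- "..."
  paste(codons, collapse = "")
}

set_codon <- function(gapped, pos, codon) {
  substr(gapped, 3L * (pos - 1L) + 1L, 3L * pos) <- codon
  gapped
}

#' Generate the fixture germline allele set
#'
#' Emits a synthetic heavy-chain V gene of four alleles whose differences
#' mirror the allelic structure of IGHV3-48 (the *03-like allele differs
#' from the *01-like allele at CDR positions 38 and 62; the *02-like allele
#' differs at framework position 96; the fourth allele differs only
#' synonymously), plus heavy D and J alleles, and kappa light-chain V and J
#' alleles. J alleles carry `fr4` annotations (FR4 start offsets). The
#' synthetic light J encodes most of the light CDR3, so that light-chain
#' junctions can leave as few as two bases untemplated. Deterministic for a
#' seed; different seeds change the sequences but not the architecture.
#'
#' @param seed RNG seed (default 1).
#' @param path optional FASTA path to write the set to.
#' @return a `germline_set`.
#' @export
make_fixture_germline_set <- function(seed = 1L, path = NULL) {
  set <- with_seed(seed, {
    hv_base <- build_v_gapped(
      gap_codons = c(10L, 32L, 33L, 60L, 61L, 73L),
      fixed = list(`38` = "AGC",   # S38 (*01-like)
                   `50` = "CTG",
                   `62` = "AGC",   # S62
                   `96` = "AAT"))  # N96
    hv01 <- hv_base
    hv02 <- set_codon(hv_base, 96L, "GAT")                    # D96
    hv03 <- set_codon(set_codon(hv_base, 38L, "GAG"), 62L, "GGC")  # E38 G62
    hv04 <- set_codon(hv_base, 50L, "CTC")                    # synonymous
    kv_base <- build_v_gapped(gap_codons = c(10L, 32L, 33L),
                              fixed = list(`45` = "CTG"))
    kv01 <- kv_base
    kv02 <- set_codon(kv_base, 45L, "CCG")  # P45
    d1 <- random_nt(28L)
    d2 <- random_nt(30L)
    d3 <- random_nt(21L)
    # heavy J: 27 nt CDR3 head (9 non-stop codons in junction register,
    # as for the long CDR3 contribution of IGHJ6) + FR4 of 11 codons
    # starting with the conserved W118
    hj6 <- paste0(paste(random_codons(9L), collapse = ""),
                  "TGG", paste(random_codons(10L), collapse = ""))
    hj4 <- paste0(paste(random_codons(3L), collapse = ""),
                  "TGG", paste(random_codons(10L), collapse = ""))
    # light J: long 25 nt CDR3 head (1 nt + 8 codons) + 10-codon FR4 (F118)
    kj5 <- paste0(random_nt(1L), paste(random_codons(8L), collapse = ""),
                  "TTC", paste(random_codons(9L), collapse = ""))
    alleles <- list(
      germline_allele("SIMHV3-48*01", "IGH", "V", gapped_seq_nt = hv01),
      germline_allele("SIMHV3-48*02", "IGH", "V", gapped_seq_nt = hv02),
      germline_allele("SIMHV3-48*03", "IGH", "V", gapped_seq_nt = hv03),
      germline_allele("SIMHV3-48*04", "IGH", "V", gapped_seq_nt = hv04),
      germline_allele("SIMKV3-20*01", "IGK", "V", gapped_seq_nt = kv01),
      germline_allele("SIMKV3-20*02", "IGK", "V", gapped_seq_nt = kv02),
      germline_allele("SIMD3-10*01", "IGH", "D", seq_nt = d1),
      germline_allele("SIMD3-16*02", "IGH", "D", seq_nt = d2),
      germline_allele("SIMD2-8*01", "IGH", "D", seq_nt = d3),
      germline_allele("SIMJ6*02", "IGH", "J", seq_nt = hj6, fr4 = 27L),
      germline_allele("SIMJ4*02", "IGH", "J", seq_nt = hj4, fr4 = 9L),
      germline_allele("SIMKJ5*01", "IGK", "J", seq_nt = kj5, fr4 = 25L))
    names(alleles) <- vapply(alleles, `[[`, character(1), "name")
    structure(alleles, class = "germline_set")
  })
  if (!is.null(path)) write_germline_set(set, path)
  set
}

#' Scenario configuration for the synthetic generators
#'
#' Collects every tunable of the rearrangement simulator and the instrument
#' suite; serializes losslessly through YAML.
#'
#' @param seed master RNG seed.
#' @param chain `"H"` or `"L"`.
#' @param cdr3_length CDR3 length to construct (default 19 heavy, 9 light,
#'   the lengths of the 212579 junctions).
#' @param shm_rate per-base somatic hypermutation probability in `[0, 1]`.
#' @param trim_prob geometric parameter for V-3'/J-5' exonuclease trimming.
#' @param trim_cap maximum trimming, nt.
#' @param d_trim_cap maximum D-end trimming, nt (heavy).
#' @param v_allele,d_allele,j_allele allele names (NULL = sample).
#' @param planted list of planted coding mutations, each
#'   `list(position = "40", to_aa = "T")` at a fully templated codon.
#' @param ka,kd,rmax,conc_nM,t_assoc,t_dissoc,spr_noise_sd SPR design
#'   (defaults: the study's 0 and 1.875--60 nM twofold series, 120 s
#'   association, 1360 s dissociation).
#' @param tm_C,dH_kJ,melt_noise,melt_replicates melt-curve design
#'   (25--95 C at 1 C/min).
#' @param rh_nm,taylor_temps_C,taylor_noise,taylor_replicates Taylor
#'   dispersion design (triplicates at 25 C and 37 C).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, chain = "H",
                            cdr3_length = if (chain == "H") 19L else 9L,
                            shm_rate = 0.02,
                            trim_prob = 0.4, trim_cap = 12L,
                            d_trim_cap = 4L,
                            v_allele = NULL, d_allele = NULL, j_allele = NULL,
                            planted = NULL,
                            ka = 4.4e5, kd = 1.4e-4, rmax = 100,
                            conc_nM = c(0, 1.875, 3.75, 7.5, 15, 30, 60),
                            t_assoc = 120, t_dissoc = 1360,
                            spr_noise_sd = 0.5,
                            tm_C = 67.8, dH_kJ = 400, melt_noise = 0.002,
                            melt_replicates = 3L,
                            rh_nm = 6.52, taylor_temps_C = c(25, 37),
                            taylor_noise = 0.002, taylor_replicates = 3L) {
  stopifnot(shm_rate >= 0, shm_rate <= 1, chain %in% c("H", "L"))
  cfg <- as.list(environment())
  structure(cfg, class = "scenario_config")
}

#' @rdname scenario_config
#' @param config a `scenario_config`.
#' @param path YAML file path.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nulls <- setdiff(names(formals(scenario_config)), names(cfg))
  cfg[nulls] <- list(NULL)
  structure(cfg[names(formals(scenario_config))], class = "scenario_config")
}

rgeom_capped <- function(p, cap) min(stats::rgeom(1L, p), cap)

#' Simulate one V(D)J rearrangement with recorded ground truth
#'
#' Builds V (3'-trimmed) + N1 + D (both ends trimmed) + N2 + J (5'-trimmed)
#' for heavy chains, or V + N + J for light chains, with the junction sized
#' so that the CDR3 has the configured length and the reading frame is
#' preserved. Somatic point mutations are applied per base at the
#' configured rate (optionally with pinned coding mutations at given IMGT
#' positions) and recorded with their templated-or-N status. Junctions whose
#' frame would contain a stop codon are resampled up to a retry cap.
#'
#' @param config a `scenario_config`.
#' @param alleles a `germline_set` (default: the fixture set for
#'   `config$seed`).
#' @param max_retry junction resampling cap (default 50).
#' @return list with elements `rearrangement` (a [rearrangement()]) and
#'   `truth` (class `rearrangement_truth`): allele names, trim lengths, N
#'   strings, per-base origin `labels`, the unmutated sequence, and the
#'   mutation table (`read_pos` 0-based, `from`, `to`, `templated`).
#' @export
simulate_rearrangement <- function(config, alleles = NULL, max_retry = 50L) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(alleles)) alleles <- make_fixture_germline_set(config$seed)
  with_seed(config$seed, {
    for (attempt in seq_len(max_retry)) {
      out <- try_simulate_once(config, alleles)
      if (!is.null(out)) return(out)
    }
    stop_ab(sprintf("no stop-free junction found in %d attempts", max_retry),
            "ablineage_simulation_error")
  })
}

# one junction draw; NULL if the draw produces a stop codon
try_simulate_once <- function(config, alleles) {
  chain <- config$chain
  locus <- if (chain == "H") "IGH" else "IGK"
  pick <- function(name, segment) {
    if (!is.null(name)) return(alleles[[name]])
    cand <- filter_set(alleles, locus = locus, segment = segment)
    cand[[sample.int(length(cand), 1L)]]
  }
  v <- pick(config$v_allele, "V")
  j <- pick(config$j_allele, "J")
  U <- nchar(v$seq_nt)
  L <- config$cdr3_length
  tv <- rgeom_capped(config$trim_prob, config$trim_cap)
  tj <- rgeom_capped(config$trim_prob, min(config$trim_cap, j$fr4))
  fill_len <- 3L * L + tv + tj - j$fr4
  if (fill_len < 0L) return(NULL)
  if (chain == "H") {
    d <- pick(config$d_allele, "D")
    td5 <- rgeom_capped(config$trim_prob, config$d_trim_cap)
    td3 <- rgeom_capped(config$trim_prob, config$d_trim_cap)
    d_seq <- substr(d$seq_nt, td5 + 1L, nchar(d$seq_nt) - td3)
    if (nchar(d_seq) > fill_len) return(NULL)
    n1 <- sample.int(fill_len - nchar(d_seq) + 1L, 1L) - 1L
    n2 <- fill_len - nchar(d_seq) - n1
    n1_seq <- if (n1 > 0L) random_nt(n1) else ""
    n2_seq <- if (n2 > 0L) random_nt(n2) else ""
    fill <- paste0(n1_seq, d_seq, n2_seq)
    labels <- c(rep("V", U - tv), rep("N", n1), rep("D", nchar(d_seq)),
                rep("N", n2), rep("J", nchar(j$seq_nt) - tj))
  } else {
    d <- NULL; td5 <- td3 <- NA_integer_
    n1_seq <- if (fill_len > 0L) random_nt(fill_len) else ""
    n2_seq <- ""
    fill <- n1_seq
    labels <- c(rep("V", U - tv), rep("N", fill_len),
                rep("J", nchar(j$seq_nt) - tj))
  }
  unmutated <- paste0(substr(v$seq_nt, 1L, U - tv), fill,
                      substr(j$seq_nt, tj + 1L, nchar(j$seq_nt)))
  if (grepl("*", translate_nt(unmutated), fixed = TRUE)) return(NULL)
  j_read_start <- nchar(unmutated) - (nchar(j$seq_nt) - tj)
  j_aln <- segment_alignment(j$name, "J", j_read_start, nchar(unmutated),
                             tj, nchar(j$seq_nt))
  dom <- number_full_domain(unmutated, chain, v, j, j_aln)

  chars <- strsplit(unmutated, "")[[1]]
  mut <- data.frame(read_pos = integer(0), from = character(0),
                    to = character(0), templated = logical(0),
                    stringsAsFactors = FALSE)
  # pinned coding mutations at templated codons
  for (p in config$planted) {
    row <- which(dom$position == as.character(p$position))
    if (length(row) != 1L) {
      stop_ab(sprintf("planted position %s absent from domain", p$position),
              "ablineage_usage_error")
    }
    idx <- 3L * (row - 1L) + (1:3)
    if (!all(labels[idx] %in% c("V", "D", "J"))) {
      stop_ab(sprintf("planted position %s is not fully templated", p$position),
              "ablineage_usage_error")
    }
    new_codon <- choose_codon(p$to_aa, dom$codon[row])
    changed <- which(strsplit(new_codon, "")[[1]] != chars[idx])
    for (ci in changed) {
      mut <- rbind(mut, data.frame(
        read_pos = idx[ci] - 1L, from = chars[idx[ci]],
        to = substr(new_codon, ci, ci), templated = TRUE))
      chars[idx[ci]] <- substr(new_codon, ci, ci)
    }
  }
  # uniform per-base SHM elsewhere
  if (config$shm_rate > 0) {
    hit <- which(stats::runif(length(chars)) < config$shm_rate)
    hit <- setdiff(hit, mut$read_pos + 1L)
    for (i in hit) {
      to <- sample1(setdiff(DNA_BASES, chars[i]), 1L)
      mut <- rbind(mut, data.frame(
        read_pos = i - 1L, from = chars[i], to = to,
        templated = labels[i] %in% c("V", "D", "J")))
      chars[i] <- to
    }
  }
  emitted <- paste(chars, collapse = "")
  if (grepl("*", translate_nt(emitted), fixed = TRUE)) return(NULL)
  r <- tryCatch(rearrangement(paste0("sim_", config$seed), chain, emitted),
                error = function(e) NULL)
  if (is.null(r)) return(NULL)
  truth <- structure(list(
    chain = chain, v_call = v$name,
    d_call = if (!is.null(d)) d$name else NA_character_,
    j_call = j$name,
    v_trim = tv, d_trim_5 = td5, d_trim_3 = td3, j_trim = tj,
    n1 = n1_seq, n2 = n2_seq,
    labels = labels, unmutated = unmutated,
    mutations = mut[order(mut$read_pos), , drop = FALSE],
    cdr3_length = L, j_read_start = j_read_start),
    class = "rearrangement_truth")
  list(rearrangement = r, truth = truth)
}

#' Reconstruct the emitted sequence from simulator ground truth
#'
#' Invariant check: reassembling the trimmed segments, N additions and
#' recorded mutations must reproduce the emitted read exactly.
#'
#' @param truth a `rearrangement_truth`.
#' @param alleles the `germline_set` used for simulation.
#' @return the reconstructed DNA string.
#' @export
reconstruct_truth <- function(truth, alleles) {
  v <- alleles[[truth$v_call]]
  j <- alleles[[truth$j_call]]
  U <- nchar(v$seq_nt)
  d_seq <- if (!is.na(truth$d_call)) {
    d <- alleles[[truth$d_call]]
    substr(d$seq_nt, truth$d_trim_5 + 1L, nchar(d$seq_nt) - truth$d_trim_3)
  } else ""
  s <- paste0(substr(v$seq_nt, 1L, U - truth$v_trim),
              truth$n1, d_seq, truth$n2,
              substr(j$seq_nt, truth$j_trim + 1L, nchar(j$seq_nt)))
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(truth$mutations))) {
    m <- truth$mutations[i, ]
    stopifnot(chars[m$read_pos + 1L] == m$from)
    chars[m$read_pos + 1L] <- m$to
  }
  paste(chars, collapse = "")
}

#' Substitutions a UCA inference should report for a simulated read
#'
#' From the ground truth: non-templated bases are assumed unmutated, so the
#' truth-implied UCA keeps N-region mutations and reverts templated ones;
#' the expected substitution set is the translated difference between that
#' UCA and the emitted read.
#'
#' @param truth a `rearrangement_truth`.
#' @param sim the list returned by [simulate_rearrangement()] (for the
#'   emitted read), or the emitted DNA string.
#' @param alleles the `germline_set` used.
#' @return character vector of substitution strings, canonically ordered.
#' @export
expected_substitutions <- function(truth, sim, alleles) {
  emitted <- if (is.character(sim)) sim else sim$rearrangement$seq_nt
  chars <- strsplit(truth$unmutated, "")[[1]]
  for (i in seq_len(nrow(truth$mutations))) {
    m <- truth$mutations[i, ]
    if (!m$templated) chars[m$read_pos + 1L] <- m$to
  }
  uca <- paste(chars, collapse = "")
  v <- alleles[[truth$v_call]]; j <- alleles[[truth$j_call]]
  j_aln <- segment_alignment(j$name, "J", truth$j_read_start, nchar(emitted),
                             truth$j_trim, nchar(j$seq_nt))
  dom_uca <- number_full_domain(uca, truth$chain, v, j, j_aln)
  dom_mat <- number_full_domain(emitted, truth$chain, v, j, j_aln)
  diff <- which(dom_uca$aa != dom_mat$aa)
  subs <- lapply(diff, function(i) substitution(
    dom_uca$aa[i], imgt_position(dom_uca$number[i], dom_uca$insertion[i]),
    truth$chain, dom_mat$aa[i]))
  vapply(order_substitutions(subs), format_substitution, character(1))
}

#' Simulate the full instrument-trace suite
#'
#' Generates the SPR concentration series (blank plus twofold dilutions),
#' replicate melt curves, and replicate taylorgrams at both run
#' temperatures, per the scenario configuration; optionally writes CSVs, a
#' ground-truth JSON, and the scenario YAML to a directory.
#'
#' @param config a `scenario_config`.
#' @param dir optional output directory.
#' @return list with `sensorgrams`, `melt_curves`, `taylorgrams` (named by
#'   temperature and replicate), and `truth` (the generating parameters).
#' @export
simulate_instrument_suite <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  sensorgrams <- simulate_sensorgram(
    config$ka, config$kd, config$rmax, conc = config$conc_nM * 1e-9,
    t_assoc = config$t_assoc, t_dissoc = config$t_dissoc,
    noise_sd = config$spr_noise_sd, seed = config$seed + 1L)
  melt_curves <- lapply(seq_len(config$melt_replicates), function(i) {
    simulate_melt_curve(config$tm_C, config$dH_kJ, noise = config$melt_noise,
                        seed = config$seed + 10L + i, replicate = i)
  })
  taylorgrams <- list()
  k <- 0L
  for (temp in config$taylor_temps_C) {
    for (i in seq_len(config$taylor_replicates)) {
      k <- k + 1L
      taylorgrams[[sprintf("T%g_rep%d", temp, i)]] <- simulate_taylorgram(
        config$rh_nm, temperature_C = temp, noise = config$taylor_noise,
        seed = config$seed + 100L + k)
    }
  }
  truth <- list(ka = config$ka, kd = config$kd, rmax = config$rmax,
                KD = config$kd / config$ka, tm_C = config$tm_C,
                rh_nm = config$rh_nm)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sensorgram_csv(sensorgrams, file.path(dir, "sensorgrams.csv"))
    melt_rows <- do.call(rbind, lapply(melt_curves, function(m) {
      cbind(as.data.frame(m), replicate = attr(m, "replicate"))
    }))
    utils::write.csv(melt_rows, file.path(dir, "melt_curves.csv"),
                     row.names = FALSE)
    taylor_rows <- do.call(rbind, lapply(names(taylorgrams), function(nm) {
      tg <- taylorgrams[[nm]]
      cbind(tg$data, run = nm, temperature_C = tg$temperature_C,
            viscosity = tg$viscosity, rc = tg$rc)
    }))
    utils::write.csv(taylor_rows, file.path(dir, "taylorgrams.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_scenario_config(config, file.path(dir, "scenario.yaml"))
  }
  list(sensorgrams = sensorgrams, melt_curves = melt_curves,
       taylorgrams = taylorgrams, truth = truth)
}

#' Simulate a rearrangement with planted interior coding mutations
#'
#' Two-pass wrapper around [simulate_rearrangement()]: the junction is drawn
#' first without mutations, then `n_mut` coding mutations are planted at
#' "recoverable" templated positions -- codons fully inside the V or J
#' blocks, further from any segment boundary than the aligners' maximum
#' trim reach (`margin` nt), and away
#' from allele-distinguishing positions -- and the identical junction is
#' re-emitted with the mutations applied. Mutations at segment edges or
#' inside the D (whose assignment relies on exact runs) are deliberately
#' not planted: their germline origin is not identifiable from the
#' rearrangement alone.
#'
#' @param seed RNG seed (junction and position draws).
#' @param chain `"H"` or `"L"`.
#' @param n_mut number of coding mutations to plant.
#' @param alleles a `germline_set` (default: fixture set for seed 1).
#' @param margin minimum distance (nt) from any label-block boundary
#'   (default 31, one beyond the V aligner's trimming cap, so boundary
#'   re-trimming can never absorb a planted codon).
#' @param trim_prob geometric trimming parameter, see [scenario_config()].
#' @return list with `sim` (as [simulate_rearrangement()]), `planted`
#'   (the planted list), and `expected` (substitution strings the
#'   inference should report).
#' @export
simulate_planted_rearrangement <- function(seed, chain = "H", n_mut = 3L,
                                           alleles = NULL, margin = 31L,
                                           trim_prob = 0.4) {
  if (is.null(alleles)) alleles <- make_fixture_germline_set(1L)
  cfg <- scenario_config(seed = seed, chain = chain, shm_rate = 0,
                         trim_prob = trim_prob)
  sim0 <- simulate_rearrangement(cfg, alleles)
  truth <- sim0$truth
  v <- alleles[[truth$v_call]]; j <- alleles[[truth$j_call]]
  j_aln <- segment_alignment(j$name, "J", truth$j_read_start,
                             nchar(truth$unmutated), truth$j_trim,
                             nchar(j$seq_nt))
  dom <- number_full_domain(truth$unmutated, chain, v, j, j_aln)
  labels <- truth$labels
  n <- length(labels)
  boundaries <- which(labels[-1] != labels[-n])  # read index of block ends
  dist_to_boundary <- function(i) {
    if (length(boundaries) == 0L) return(Inf)
    min(abs(i - boundaries), abs(i - boundaries - 1L))
  }
  distinguishing <- if (chain == "H") c(38L, 50L, 62L, 96L) else 45L
  ok_rows <- vapply(seq_len(nrow(dom)), function(k) {
    idx <- 3L * (k - 1L) + (1:3)
    all(labels[idx] %in% c("V", "J")) &&
      min(vapply(idx, dist_to_boundary, numeric(1))) >= margin &&
      !(is.na(dom$insertion[k]) && dom$number[k] %in% distinguishing)
  }, logical(1))
  planted <- with_seed(seed + 1000003L, {
    rows <- sample1(which(ok_rows), min(n_mut, sum(ok_rows)))
    lapply(rows, function(k) list(
      position = dom$position[k],
      to_aa = sample1(setdiff(AA_LETTERS, dom$aa[k]), 1L)))
  })
  cfg$planted <- planted
  sim <- simulate_rearrangement(cfg, alleles)
  list(sim = sim, planted = planted,
       expected = expected_substitutions(sim$truth, sim, alleles))
}
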