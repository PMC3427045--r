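test_that("global alignment handles identical and length-mismatched pairs", {
  same <- needleman_wunsch("MKVL", "MKVL")
  expect_equal(same$identity_pct, 100)
  expect_false(grepl("-", same$aligned_a, fixed = TRUE))

  gapped <- needleman_wunsch("MK", "M")
  expect_equal(gapped$aligned_a, "MK")
  expect_equal(gapped$aligned_b, "M-")
})

test_that("codon threading maps residue columns to codon pairs", {
  guide <- needleman_wunsch("MK", "MK")
  ca <- thread_codons(guide, "ATGAAA", "ATGAAG")
  expect_equal(ca$codon_a, c("ATG", "AAA"))
  expect_equal(ca$codon_b, c("ATG", "AAG"))

  # a guide gap column drops that codon
  guide2 <- needleman_wunsch("MKV", "MV")
  expect_equal(guide2$aligned_b, "M-V")
  ca2 <- thread_codons(guide2, "ATGAAAGTT", "ATGGTA")
  expect_equal(nrow(ca2), 2L)
  expect_equal(ca2$codon_a, c("ATG", "GTT"))

  # trailing stops are tolerated; ambiguity is dropped with a message
  expect_silent(ca3 <- thread_codons(guide, "ATGAAATAA", "ATGAAG"))
  expect_equal(nrow(ca3), 2L)
  expect_message(ca4 <- thread_codons(guide, "ATGAAN", "ATGAAG"), "dropped")
  expect_equal(nrow(ca4), 1L)

  expect_error(thread_codons(guide, "ATGCCC", "ATGAAG"),
               "translation mismatch")
})

test_that("NG86 reproduces hand-enumerated site and difference counts", {
  # identical pair: no differences, undefined ratio
  same <- ng86(codon_frame("ATGAAA", "ATGAAA"))
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_equal(same$Ks, 0)
  expect_equal(same$Ka, 0)
  expect_equal(same$selection, "undefined")

  # GGA->GGC is synonymous (all GGN encode Gly)
  gly <- ng86(data.frame(codon_a = "GGA", codon_b = "GGC"))
  expect_equal(gly$Sd, 1)
  expect_equal(gly$Nd, 0)

  # TTT vs TTA, hand enumeration: S(TTT) = 1/3 (only pos 3 has the
  # synonymous TTC; TTA pos 2 changes hit two stops, leaving 0/1),
  # S(TTA) = 1/3 + 1/3; averaged S = 0.5, N = 2.5, one nonsyn diff
  phe <- ng86(data.frame(codon_a = "TTT", codon_b = "TTA"))
  expect_equal(phe$S, 0.5)
  expect_equal(phe$N, 2.5)
  expect_equal(phe$Sd, 0)
  expect_equal(phe$Nd, 1)

  expect_error(ng86(data.frame(codon_a = character(0),
                               codon_b = character(0))), "empty")
})

test_that("per-codon site counts match an independent enumeration oracle", {
  set.seed(808)
  codons <- sample(names(Biostrings::GENETIC_CODE)
                   [Biostrings::GENETIC_CODE != "*"], 25)
  for (cod in codons) {
    expect_equal(ccchfamily:::syn_sites(cod), oracle_syn_sites(cod),
                 info = cod)
  }
})

test_that("NG86 is symmetric and conserves S + N = 3 x codons", {
  set.seed(809)
  for (rep in 1:10) {
    g <- gen_cds_pairs(1L, n_codons = 40L, omega = 0.5,
                       expected_sub_per_codon = 0.3, seed = 900 + rep)
    cf <- codon_frame(g$records$seq[1], g$records$seq[2])
    fwd <- ng86(cf)
    rev <- ng86(data.frame(codon_a = cf$codon_b, codon_b = cf$codon_a))
    expect_equal(fwd$S + fwd$N, 3 * nrow(cf))
    for (field in c("S", "N", "Sd", "Nd", "Ks", "Ka", "ratio")) {
      expect_equal(fwd[[field]], rev[[field]], info = field)
    }
    expect_true(fwd$Sd <= fwd$S && fwd$Nd <= fwd$N)
  }
})

test_that("a single synonymous difference matches the closed-form Ks", {
  # 10 identical Leu codons plus GGA/GGG: Sd = 1, Ks = JC(1/S)
  cf <- rbind(codon_frame(strrep("CTG", 10), strrep("CTG", 10)),
              data.frame(codon_a = "GGA", codon_b = "GGG"))
  res <- ng86(cf)
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$Ks, -3 / 4 * log(1 - 4 * (1 / res$S) / 3))
  expect_equal(res$Ka, 0)
})

test_that("saturated proportions are flagged undefined, not NaN", {
  sat <- ng86(data.frame(codon_a = "GGA", codon_b = "GGC"))
  expect_true(is.na(sat$Ks))  # pS = 1 >= 3/4
  expect_equal(sat$selection, "undefined")
})

test_that("selection calls follow the 0.5 threshold convention", {
  expect_equal(classify_selection(0.2797), "purifying")
  expect_equal(classify_selection(0.6247), "relaxed_or_positive")
  expect_equal(classify_selection(0.5), "relaxed_or_positive")
  expect_equal(classify_selection(NA_real_), "undefined")
  expect_equal(classify_selection(0.7, threshold = 1.0), "purifying")
})

test_that("omega = 0 simulations yield Ka = 0 through the full workflow", {
  g <- gen_cds_pairs(2L, n_codons = 60L, omega = 0,
                     expected_sub_per_codon = 0.3, seed = 17L)
  expect_true(all(g$truth$nonsyn_events == 0L))
  for (k in 1:2) {
    res <- kaks_pair(g$records$seq[2 * k - 1], g$records$seq[2 * k])
    expect_equal(res$Ka, 0)
    expect_gt(res$Ks, 0)
  }
})
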