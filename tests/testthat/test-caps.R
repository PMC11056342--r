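avai <- restriction_enzyme("AvaI", "CYCGRG", 1)

test_that("enzyme definitions are validated", {
  expect_error(restriction_enzyme("X", "CYCGQG", 1), "IUPAC")
  expect_error(restriction_enzyme("X", "CYCGRG", 7), "cut_offset")
  tab <- read_enzyme_table()
  expect_true("AvaI" %in% tab$name)
  expect_equal(tab$recognition[tab$name == "AvaI"], "CYCGRG")
})

test_that("degenerate recognition sites are found on the top strand", {
  expect_equal(find_recognition_sites("AACCCGGGTT", avai), 3)
  expect_equal(find_recognition_sites("CTCGAG", avai), 1)
  expect_equal(length(find_recognition_sites("AAAATTTT", avai)), 0)
  expect_equal(find_recognition_sites("aaCCCGGGtt", avai), 3)  # case folded
  expect_error(find_recognition_sites("ACGTN", avai), "non-ACGT")
})

test_that("non-palindromic patterns are matched on both strands", {
  bsai <- restriction_enzyme("BsaI", "GGTCTC", 1)
  # GAGACC is the reverse complement of GGTCTC
  expect_equal(find_recognition_sites("AAGAGACCAA", bsai), 3)
  expect_equal(find_recognition_sites("AAGGTCTCAA", bsai), 3)
})

test_that("site finding agrees with a brute-force IUPAC matcher", {
  tab <- read_enzyme_table()
  set.seed(8)
  for (rep in 1:4) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
    for (i in seq_len(nrow(tab))) {
      enz <- restriction_enzyme(tab$name[i], tab$recognition[i],
                                tab$cut_offset[i])
      expect_equal(find_recognition_sites(seq, enz),
                   oracle_find_sites(seq, enz$recognition),
                   info = paste(tab$name[i], "rep", rep))
    }
  }
})

test_that("digestion reproduces the 1118-bp CAPS fixture geometry", {
  pair <- simulate_amplicon_pair(1118, avai, site_start = 418, seed = 1)
  expect_equal(digest(pair$ref_amplicon, avai), c(418L, 700L))
  expect_equal(digest(pair$alt_amplicon, avai), 1118L)
})

test_that("digestion conserves total length and handles multiple sites", {
  # two planted sites -> three fragments summing to the length
  pair <- simulate_amplicon_pair(600, avai, site_start = 100, seed = 4)
  s <- pair$ref_amplicon
  with_two <- paste0(substr(s, 1, 299), "CTCGGG", substr(s, 306, 600))
  sites <- find_recognition_sites(with_two, avai)
  expect_equal(sites, c(100, 300))
  fr <- digest(with_two, avai)
  expect_equal(length(fr), 3)
  expect_equal(sum(fr), 600)

  # property: fragment lengths always sum to the amplicon length
  tab <- read_enzyme_table()
  set.seed(15)
  for (rep in 1:40) {
    n <- sample(200:1200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    i <- sample(nrow(tab), 1)
    enz <- restriction_enzyme(tab$name[i], tab$recognition[i],
                              tab$cut_offset[i])
    fr <- digest(seq, enz)
    expect_equal(sum(fr), n)
    expect_true(all(fr >= 1))
  }
})

test_that("re-digesting a reconstructed junction yields no extra fragments", {
  set.seed(23)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                 collapse = "")
    fr <- digest(seq, avai)
    if (length(fr) < 2) next
    ends <- cumsum(fr)
    starts <- c(1, head(ends, -1) + 1)
    for (k in seq_len(length(fr) - 1)) {
      junction <- substr(seq, starts[k], ends[k + 1])
      expect_lte(length(digest(junction, avai)), length(fr))
    }
  }
})

test_that("CAPS assay verdicts follow gel resolvability", {
  pair <- simulate_amplicon_pair(1118, avai, site_start = 418, seed = 1)
  assay <- evaluate_caps_assay(pair$ref_amplicon, pair$alt_amplicon, avai)
  expect_true(assay$diagnostic)
  expect_equal(assay$fragments_ref, c(700L, 418L))
  expect_equal(assay$fragments_alt, 1118L)

  same <- evaluate_caps_assay(pair$ref_amplicon, pair$ref_amplicon, avai)
  expect_false(same$diagnostic)

  # a second site shifting one band by less than the resolvable difference
  # (and creating a sub-resolution fragment) is not diagnostic
  s <- pair$ref_amplicon
  shifted <- paste0(substr(s, 1, 423), "CCCGGG", substr(s, 430, 1118))
  expect_equal(find_recognition_sites(shifted, avai), c(418, 424))
  # bands: ref [418, 700] vs alt [418, 6, 694]; the 6-bp fragment is
  # invisible and the 6-bp band shift is below a 20-bp gel resolution
  assay2 <- evaluate_caps_assay(pair$ref_amplicon, shifted, avai,
                                min_resolvable_diff = 20)
  expect_false(assay2$diagnostic)
  # but a fine gel would resolve the extra band
  assay3 <- evaluate_caps_assay(pair$ref_amplicon, shifted, avai,
                                min_resolvable_diff = 5)
  expect_true(assay3$diagnostic)
})

test_that("enzyme proposal ranks diagnostic enzymes overlapping the SNP", {
  pair <- simulate_amplicon_pair(500, avai, site_start = 200, seed = 6)
  hits <- propose_enzymes(pair$ref_amplicon, pair$alt_amplicon,
                          snp_position = 202)
  expect_true("AvaI" %in% hits$name)
  expect_true(all(hits$margin > 0))

  # a SNP outside every recognition window proposes nothing
  none <- propose_enzymes(pair$ref_amplicon, pair$ref_amplicon,
                          snp_position = 10)
  expect_equal(nrow(none), 0)

  expect_error(propose_enzymes(pair$ref_amplicon, pair$alt_amplicon, 202,
                               enzyme_table = data.frame()), "empty")
})

test_that("InDel markers are judged by product-length difference", {
  a <- strrep("ACGT", 50)            # 200 bp
  b <- paste0(a, strrep("AC", 15))   # 230 bp
  c30 <- paste0(a, strrep("A", 10))  # 210 bp
  expect_true(evaluate_indel_marker(a, b, 20)$diagnostic)
  expect_false(evaluate_indel_marker(a, a, 20)$diagnostic)
  expect_false(evaluate_indel_marker(a, c30, 20)$diagnostic)
  expect_equal(evaluate_indel_marker(a, b)$size_diff, 30)
})
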