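# Hand-built single-site panels: 2 donors, 3 references, 1 query.
mini_panel <- data.frame(
  id = c("d1", "d2", "r1", "r2", "r3", "q"),
  species = c("Ae. longissima", "Ae. sharonensis", "T. dicoccoides",
              "T. durum", "T. aestivum", "line"),
  group = c("DONOR_CANDIDATE", "DONOR_CANDIDATE", "POLYPLOID_REFERENCE",
            "POLYPLOID_REFERENCE", "POLYPLOID_REFERENCE", "QUERY"),
  stringsAsFactors = FALSE)

one_site <- function(calls) {
  genotype_matrix(data.frame(chrom = "6B", pos = 100, ref = "A", alt = "G"),
                  matrix(as.integer(calls), 1, 6,
                         dimnames = list(NULL, mini_panel$id)))
}

test_that("site classification applies the diagnostic rules", {
  # donors fixed alt, references ref, query alt -> donor-diagnostic + shared
  cl <- classify_sites(one_site(c(2, 2, 0, 0, 0, 2)), mini_panel)
  expect_equal(as.character(cl$category), "DONOR_DIAGNOSTIC")
  expect_true(cl$query_carries_donor_allele)

  # monomorphic -> uninformative
  cl <- classify_sites(one_site(c(0, 0, 0, 0, 0, 0)), mini_panel)
  expect_equal(as.character(cl$category), "UNINFORMATIVE")
  expect_false(cl$query_carries_donor_allele)

  # alt present in a reference -> shared wheat, even if donors are fixed
  cl <- classify_sites(one_site(c(2, 2, 2, 0, 0, 2)), mini_panel)
  expect_equal(as.character(cl$category), "SHARED_WHEAT")

  # query-private alt, donors not fixed -> query-rare
  cl <- classify_sites(one_site(c(2, 0, 0, 0, 0, 2)), mini_panel)
  expect_equal(as.character(cl$category), "QUERY_RARE")

  # donor-fixed alt the query does not carry stays donor-diagnostic
  cl <- classify_sites(one_site(c(2, 2, 0, 0, 0, 0)), mini_panel)
  expect_equal(as.character(cl$category), "DONOR_DIAGNOSTIC")
  expect_false(cl$query_carries_donor_allele)
})

test_that("het policy controls allele-presence tests", {
  g <- one_site(c(2, 1, 0, 0, 0, 1))
  cl_het <- classify_sites(g, mini_panel)
  expect_equal(as.character(cl_het$category), "DONOR_DIAGNOSTIC")
  expect_true(cl_het$query_carries_donor_allele)

  # hom-only policy: the het donor no longer carries (donor condition
  # fails) and the het query does not either -> uninformative
  cl_hom <- classify_sites(g, mini_panel,
                           classification_policy(het_carries = FALSE))
  expect_equal(as.character(cl_hom$category), "UNINFORMATIVE")
  expect_false(cl_hom$query_carries_donor_allele)
})

test_that("missing-data tolerance gates the donor-diagnostic call", {
  g <- one_site(c(2, NA, 0, 0, 0, 2))
  strict <- classify_sites(g, mini_panel)
  expect_equal(as.character(strict$category), "QUERY_RARE")
  expect_equal(strict$n_missing, 1L)

  tolerant <- classify_sites(g, mini_panel,
                             classification_policy(max_missing_frac = 0.5))
  expect_equal(as.character(tolerant$category), "DONOR_DIAGNOSTIC")

  expect_error(classification_policy(max_missing_frac = 1.5), "\\[0, 1\\]")
})

test_that("classification on clean simulated panels matches generator truth", {
  sim <- simulate_species_panel(panel_sim_config(n_sites = 1500, seed = 21))
  cl <- classify_sites(sim$geno, sim$panel)
  expect_identical(as.character(cl$category), sim$truth$category)
  # category partition: every site exactly one category
  expect_equal(sum(table(cl$category)), nrow(cl))
})

test_that("detect_segment reproduces the worked breakpoint bracket", {
  cl <- worked_breakpoint_sites()
  call <- detect_segment(cl)
  expect_equal(call$breakpoint_lo, 687016683)
  expect_equal(call$breakpoint_hi, 688295787)
  expect_equal(call$segment_end, 687016683)
  expect_equal(round(call$segment_end / 1e6, 2), 687.02)
})

test_that("detect_segment handles absence of a qualifying run", {
  expect_null(detect_segment(make_classified(
    pos = c(1e6, 2e6, 3e6),
    category = rep("SHARED_WHEAT", 3))))
  # too few supporting SNPs for min_support
  expect_null(detect_segment(make_classified(
    pos = seq(1e6, 10e6, by = 1e6),
    category = rep("DONOR_DIAGNOSTIC", 10))))
})

test_that("raising min_window_fraction never lengthens the segment", {
  sim <- simulate_species_panel(panel_sim_config(n_sites = 3000, seed = 31,
                                                 segment_interval = c(50e6, 400e6)))
  cl <- classify_sites(sim$geno, sim$panel)
  spans <- vapply(c(0.2, 0.5, 0.8, 1.0), function(f) {
    call <- detect_segment(cl, detection_params(min_window_fraction = f))
    if (is.null(call)) 0 else call$segment_end - call$segment_start
  }, numeric(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("detect_segment matches the exhaustive oracle on small site lists", {
  params <- detection_params(min_support = 5, window_bp = 5e5,
                             min_window_fraction = 0.5, max_gap_bp = 1e6)
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(40:200, 1)
    pos <- sort(sample.int(8e6, n))
    category <- sample(c("DONOR_DIAGNOSTIC", "SHARED_WHEAT", "UNINFORMATIVE"),
                       n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    cl <- make_classified(pos, category)
    got <- detect_segment(cl, params)
    want <- oracle_segment_search(cl, params)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$segment_start, want$start, info = paste("seed", seed))
      expect_equal(got$segment_end, want$end, info = paste("seed", seed))
      expect_equal(got$n_support, want$n_support, info = paste("seed", seed))
    }
  }
})

test_that("breakpoint_hi falls back to the chromosome-end sentinel", {
  cl <- make_classified(pos = seq(1e6, 30e6, by = 1e6),
                        category = rep("DONOR_DIAGNOSTIC", 30))
  call <- detect_segment(cl, chrom_length = 50e6)
  expect_equal(call$breakpoint_hi, 50e6)
  call2 <- detect_segment(cl)
  expect_equal(call2$breakpoint_hi, Inf)
})

test_that("restrict_to_region uses inclusive ends and preserves order", {
  g <- genotype_matrix(
    data.frame(chrom = "6B", pos = c(5, 10, 15, 20), ref = "A", alt = "G"),
    matrix(0L, 4, 2, dimnames = list(NULL, c("x", "y"))))
  expect_equal(restrict_to_region(g, "6B", 1, 10)$sites$pos, c(5, 10))
  expect_equal(restrict_to_region(g, "6B", 10, 15)$sites$pos, c(10, 15))
  # identity on a full-chromosome region
  expect_equal(restrict_to_region(g, "6B", 1, 100)$sites, g$sites)
  # brute-force filter agreement
  expect_equal(restrict_to_region(g, "6B", 7, 16)$sites$pos,
               g$sites$pos[g$sites$pos >= 7 & g$sites$pos <= 16])
  expect_error(restrict_to_region(g, "1A", 1, 10), "unknown chromosome")
  expect_error(restrict_to_region(g, "6B", 10, 5), "start_bp")
})
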