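test_that("Stakman infection types parse to numeric classes and R/S", {
  ph <- classify_phenotype(c("0;", ";1-", "3+", "3-4", ";", "4", "2+"))
  expect_equal(ph$numeric_class, c(0L, 1L, 3L, 4L, 0L, 4L, 2L))
  expect_equal(ph$binary, c("R", "R", "S", "S", "R", "S", "R"))
})

test_that("the resistance threshold is configurable", {
  expect_equal(classify_phenotype("2", threshold = 2)$binary, "R")
  expect_equal(classify_phenotype("2", threshold = 1)$binary, "S")
})

test_that("unparseable infection types are an error, never silent S", {
  expect_error(classify_phenotype("X?"), "unparseable")
  expect_error(classify_phenotype("5"), "unparseable")
  expect_error(classify_phenotype(""), "nonempty")
  expect_error(classify_phenotype("+"), "unparseable")  # modifier only
})

test_that("segregation chi-square equals the textbook statistic", {
  # frozen values computed with the sum((O-E)^2/E) oracle
  cases <- list(list(obs = c(91, 45), chi2 = 4.745098),
                list(obs = c(79, 38), chi2 = 3.490028),
                list(obs = c(132, 56), chi2 = 2.297872),
                list(obs = c(130, 57), chi2 = 2.996435),
                list(obs = c(75, 25), chi2 = 0))
  for (cs in cases) {
    got <- chi2_segregation(cs$obs[1], cs$obs[2], c(3, 1))
    expect_equal(got$chi2, oracle_chi2(cs$obs, c(3, 1)), tolerance = 1e-12)
    expect_equal(got$chi2, cs$chi2, tolerance = 1e-6)
    expect_equal(got$df, 1)
    expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # property over a grid of integer inputs and a non-3:1 ratio
  for (n_r in c(1, 10, 50)) {
    for (n_s in c(1, 7, 33)) {
      got <- chi2_segregation(n_r, n_s, c(15, 1))
      expect_equal(got$chi2, oracle_chi2(c(n_r, n_s), c(15, 1)),
                   tolerance = 1e-12)
    }
  }
  expect_error(chi2_segregation(0, 0), "at least one")
  expect_error(chi2_segregation(10, 5, c(3, 0)), "positive")
})

test_that("progeny tests resolve gene genotypes", {
  expect_equal(resolve_gene_genotype(rep("R", 25)), "RR")
  expect_equal(resolve_gene_genotype(rep("S", 25)), "rr")
  expect_equal(resolve_gene_genotype(c(rep("R", 18), rep("S", 7))), "Rr")
  expect_warning(g <- resolve_gene_genotype(rep("R", 5)), "min_family_size")
  expect_equal(g, "UNKNOWN")
  expect_error(resolve_gene_genotype(c("R", "weird")), "'R' or 'S'")
})

test_that("recombinant counting equals exhaustive minimization, all 9 combos", {
  for (m in c("A", "H", "B")) {
    for (g in c("RR", "Rr", "rr")) {
      expect_equal(count_recombinant_gametes(m, g),
                   oracle_min_recombinants(m, g),
                   info = paste(m, g))
    }
  }
  expect_equal(count_recombinant_gametes("A", "Rr"), 1)
  expect_equal(count_recombinant_gametes("H", "Rr"), 0)
  expect_true(is.na(count_recombinant_gametes(NA, "Rr")))
  expect_true(is.na(count_recombinant_gametes("A", "UNKNOWN")))
})

test_that("map distances round half away from zero at 2 decimals", {
  expect_equal(map_distance(18, 3892), 0.46)
  expect_equal(map_distance(11, 372), 2.96)
  expect_equal(map_distance(1, 376), 0.27)
  expect_equal(map_distance(0, 376), 0)
  expect_equal(map_distance(1, 80000), 0)     # rounds below resolution
  expect_equal(map_distance(5, 4000), 0.13)   # 0.125 rounds away from zero
  expect_error(map_distance(1, 0), "> 0")
  expect_error(map_distance(10, 5), "exceed")
})

test_that("genetic map reproduces forced-recombinant truth and groups", {
  cfg <- pop_sim_config(n_plants = 188,
                        loci = c("mk165", "gene", "mk97F"),
                        r = c(0, 0.0027),
                        forced_recombinants = c(0, 1), seed = 3)
  sim <- simulate_mapping_population(cfg)
  gm <- build_genetic_map(sim$population, cfg$loci)
  expect_equal(gm$intervals$n_recombinant, c(0L, 1L))
  expect_equal(gm$intervals$n_gametes, c(376L, 376L))
  expect_equal(gm$intervals$cM, c(0, 0.27))
  expect_equal(gm$map$pos_cM, c(0, 0, 0.27))
  expect_equal(gm$map$group, c(1L, 1L, 2L))  # completely linked pair
})

test_that("interval counts equal generator truth on a seeded population", {
  cfg <- pop_sim_config(n_plants = 188,
                        loci = c("m1", "gene", "m2", "m3"),
                        r = c(0.005, 0.01, 0.02), seed = 77)
  sim <- simulate_mapping_population(cfg)
  gm <- build_genetic_map(sim$population, cfg$loci)
  expect_equal(gm$intervals$n_recombinant,
               as.integer(sim$truth$interval_recombinants))
})

test_that("map positions are invariant to plant order and anchored ordering", {
  cfg <- pop_sim_config(n_plants = 150, loci = c("a", "gene", "b"),
                        r = c(0.02, 0.05), seed = 9)
  sim <- simulate_mapping_population(cfg)
  gm1 <- build_genetic_map(sim$population, cfg$loci)
  set.seed(1)
  shuffled <- sim$population[sample.int(nrow(sim$population)), ]
  gm2 <- build_genetic_map(shuffled, cfg$loci)
  expect_equal(gm1$map, gm2$map)
  # anchor ordering overrides the supplied order
  gm3 <- build_genetic_map(sim$population, c("b", "a", "gene"),
                           anchor = c(a = 1e6, gene = 2e6, b = 3e6))
  expect_equal(gm3$map$locus, c("a", "gene", "b"))
  expect_equal(gm3$intervals$n_recombinant, gm1$intervals$n_recombinant)
})

test_that("degenerate map inputs error clearly", {
  pop <- data.frame(id = "p1", m1 = "A", m2 = NA)
  expect_error(build_genetic_map(pop, c("m1", "m2")), "all missing")
  expect_error(build_genetic_map(pop, c("m1", "nope")), "absent from population")
  expect_error(build_genetic_map(pop[0, ], c("m1", "m2")), "empty")
})

test_that("recombination-fraction recovery is unbiased at small r", {
  # 20 seeded replicates at r = 0.01, n = 2000 gametes; the mean estimate
  # must sit within 2 binomial SEs of a single estimate from the truth
  r <- 0.01
  ests <- vapply(1:20, function(s) {
    sim <- simulate_mapping_population(
      pop_sim_config(n_plants = 1000, loci = c("m", "gene"), r = r,
                     seed = 1000 + s))
    gm <- build_genetic_map(sim$population, c("m", "gene"))
    100 * gm$intervals$n_recombinant / gm$intervals$n_gametes
  }, numeric(1))
  se <- 100 * sqrt(r * (1 - r) / 2000)
  expect_lt(abs(mean(ests) - 100 * r), 2 * se)
})

test_that("marker-panel validation reports amplification percentages", {
  markers <- c(m1 = "1118", m2 = "+")
  mk_group <- function(group, n, n_amp) {
    data.frame(accession = sprintf("%s_%03d", group, seq_len(n)),
               group = group,
               m1 = c(rep("1118", n_amp), rep(NA, n - n_amp)),
               m2 = c(rep("-", n_amp), rep(NA, n - n_amp)),
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_group("T. turgidum", 87, 73),
                 mk_group("T. aestivum", 149, 53))
  res <- validate_marker_panel(calls, markers)
  amp <- res$amplification
  expect_equal(amp$pct[amp$group == "T. turgidum" & amp$marker == "m1"], 83.9)
  expect_equal(amp$pct[amp$group == "T. aestivum" & amp$marker == "m1"], 35.6)
  # nobody matches the reference haplotype (m2 differs everywhere)
  expect_equal(length(res$identical_accessions), 0)

  # a planted identical haplotype is found
  calls$m2[1] <- "+"
  res2 <- validate_marker_panel(calls, markers)
  expect_equal(res2$identical_accessions, "T. turgidum_001")

  # all calls missing: 0% amplification, zero identity
  calls$m1 <- NA
  calls$m2 <- NA
  res3 <- validate_marker_panel(calls, markers)
  expect_true(all(res3$amplification$pct == 0))
  expect_equal(length(res3$identical_accessions), 0)
})
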