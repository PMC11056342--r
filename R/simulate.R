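# Seeded generators for every input the pipeline consumes, with ground-truth
# bookkeeping: a multi-species SNP panel whose query carries a contiguous
# donor-derived segment, F2 mapping populations segregating 3:1 for a
# dominant resistance gene, and amplicon pairs for CAPS/InDel assays.
# All generators are pure functions of their config (seed included).

#' Species-panel simulation config
#'
#' Defaults emulate the study design the package targets: four donor
#' accessions (two per donor species), seventeen polyploid references (two
#' tetraploid, fifteen hexaploid), one query line carrying a donor segment
#' spanning positions 1..687,016,683 of a 721-Mb chromosome, and 9,294
#' SNPs of which roughly 85\% are donor-diagnostic (mirroring the reported
#' proportion of species-specific SNPs in such panels).
#'
#' @param n_donor,n_reference accession counts per group.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param n_sites number of SNP sites.
#' @param segment_interval `c(start, end)` of the true donor segment (bp).
#' @param donor_divergence per-site probability the donor lineage carries a
#'   derived (alt) allele fixed among donors.
#' @param background_polymorphism per-site probability of ordinary wheat
#'   polymorphism (alt present in at least one reference).
#' @param missing_rate per-call missingness probability.
#' @param seed RNG seed (mandatory).
#' @return Object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_donor = 4, n_reference = 17, chrom = "6B",
                             chrom_length = 721e6, n_sites = 9294,
                             segment_interval = c(1, 687016683),
                             donor_divergence = 0.85,
                             background_polymorphism = 0.12,
                             missing_rate = 0, seed) {
  if (missing(seed) || !is_count(seed)) stop("a seed is mandatory")
  stopifnot(is_count(n_donor), n_donor >= 1,
            is_count(n_reference), n_reference >= 1,
            is_scalar_number(chrom_length), chrom_length >= 1,
            is_count(n_sites),
            is.numeric(segment_interval), length(segment_interval) == 2)
  check_unit_interval(donor_divergence, "donor_divergence")
  check_unit_interval(background_polymorphism, "background_polymorphism")
  check_unit_interval(missing_rate, "missing_rate")
  if (donor_divergence + background_polymorphism > 1) {
    stop("donor_divergence + background_polymorphism must be <= 1")
  }
  if (segment_interval[1] < 1 || segment_interval[2] > chrom_length ||
      segment_interval[1] > segment_interval[2]) {
    stop("segment_interval must lie within the chromosome")
  }
  structure(list(n_donor = n_donor, n_reference = n_reference,
                 chrom = chrom, chrom_length = chrom_length,
                 n_sites = n_sites, segment_interval = segment_interval,
                 donor_divergence = donor_divergence,
                 background_polymorphism = background_polymorphism,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate a multi-species SNP panel with an introgressed query segment
#'
#' Donor accessions share derived alleles at donor-diagnostic sites,
#' reference accessions never carry them, and the query carries them
#' exactly where the site lies inside `segment_interval`. Shared-wheat
#' polymorphism is sprinkled genome-wide; the remainder of sites split
#' between donor-private rare polymorphisms and monomorphic sites.
#' Ground-truth categories are recomputed from the clean (pre-missingness)
#' genotypes by direct application of the classification rules, so stored
#' truth is self-consistent with the raw data.
#'
#' @param cfg a [panel_sim_config()].
#' @return Object of class `panel_sim`: list with `geno`
#'   ([genotype_matrix()]), `panel` (metadata data.frame), `truth` (list:
#'   `category`, `segment_interval`, `last_supporting`, `next_shared`) and
#'   `config`.
#' @export
simulate_species_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  if (cfg$n_sites == 0) stop("n_sites must be > 0")
  set.seed(cfg$seed)

  donor_species <- rep(c("Ae. longissima", "Ae. sharonensis"),
                       length.out = cfg$n_donor)
  n_tt <- min(2, cfg$n_reference)
  ref_species <- c(rep("T. turgidum", n_tt),
                   rep("T. aestivum", cfg$n_reference - n_tt))
  panel <- data.frame(
    id = c(sprintf("donor_%02d", seq_len(cfg$n_donor)),
           sprintf("ref_%02d", seq_len(cfg$n_reference)),
           "query_line"),
    species = c(donor_species, ref_species, "introgression line"),
    group = c(rep("DONOR_CANDIDATE", cfg$n_donor),
              rep("POLYPLOID_REFERENCE", cfg$n_reference), "QUERY"),
    stringsAsFactors = FALSE)

  n_acc <- nrow(panel)
  pos <- sort(sample.int(cfg$chrom_length, cfg$n_sites))
  bases <- c("A", "C", "G", "T")
  ref_allele <- sample(bases, cfg$n_sites, replace = TRUE)
  alt_allele <- vapply(ref_allele,
                       function(b) sample(setdiff(bases, b), 1), character(1))

  p_rest <- 1 - cfg$donor_divergence - cfg$background_polymorphism
  type <- sample(c("DONOR", "SHARED", "RARE", "MONO"), cfg$n_sites,
                 replace = TRUE,
                 prob = c(cfg$donor_divergence, cfg$background_polymorphism,
                          p_rest / 2, p_rest / 2))
  in_segment <- pos >= cfg$segment_interval[1] & pos <= cfg$segment_interval[2]

  di <- seq_len(cfg$n_donor)
  ri <- cfg$n_donor + seq_len(cfg$n_reference)
  qi <- n_acc
  calls <- matrix(0L, cfg$n_sites, n_acc,
                  dimnames = list(NULL, panel$id))

  is_donor_site <- type == "DONOR"
  calls[is_donor_site, di] <- 2L
  calls[is_donor_site & in_segment, qi] <- 2L

  is_shared <- which(type == "SHARED")
  if (length(is_shared)) {
    carrier <- matrix(runif(length(is_shared) * n_acc) < 0.4,
                      length(is_shared), n_acc)
    gt <- matrix(ifelse(runif(length(is_shared) * n_acc) < 0.7, 2L, 1L),
                 length(is_shared), n_acc)
    block <- ifelse(carrier, gt, 0L)
    no_ref <- rowSums(block[, ri, drop = FALSE] > 0) == 0
    if (any(no_ref)) {
      forced <- ri[sample.int(length(ri), sum(no_ref), replace = TRUE)]
      block[cbind(which(no_ref), forced)] <- 2L
    }
    calls[is_shared, ] <- block
  }

  is_rare <- which(type == "RARE")
  if (length(is_rare)) {
    dcarry <- matrix(runif(length(is_rare) * cfg$n_donor) < 0.4,
                     length(is_rare), cfg$n_donor)
    all_d <- rowSums(dcarry) == cfg$n_donor
    dcarry[all_d, 1] <- FALSE  # donor-private but never fixed in donors
    calls[is_rare, di] <- ifelse(dcarry, 2L, 0L)
    calls[is_rare[in_segment[is_rare]], qi] <- 2L
  }

  # Ground truth by direct rule application on the clean matrix.
  truth_cat <- character(cfg$n_sites)
  for (k in seq_len(cfg$n_sites)) {
    row <- calls[k, ]
    donors_carry_all <- all(row[di] >= 1L)
    refs_carry_any <- any(row[ri] >= 1L)
    q <- row[qi] >= 1L
    truth_cat[k] <- if (donors_carry_all && !refs_carry_any) {
      "DONOR_DIAGNOSTIC"
    } else if (q && !refs_carry_any) {
      "QUERY_RARE"
    } else if (refs_carry_any) {
      "SHARED_WHEAT"
    } else "UNINFORMATIVE"
  }
  supporting <- truth_cat == "DONOR_DIAGNOSTIC" & calls[, qi] >= 1L
  last_supporting <- if (any(supporting)) max(pos[supporting]) else NA_real_
  shared_beyond <- pos[truth_cat == "SHARED_WHEAT" & pos > (last_supporting %||% -Inf)]
  next_shared <- if (!is.na(last_supporting) && length(shared_beyond)) {
    min(shared_beyond)
  } else NA_real_

  if (cfg$missing_rate > 0) {
    calls[matrix(runif(length(calls)) < cfg$missing_rate,
                 nrow(calls), ncol(calls))] <- NA_integer_
  }

  geno <- genotype_matrix(
    data.frame(chrom = cfg$chrom, pos = as.numeric(pos),
               ref = ref_allele, alt = alt_allele, stringsAsFactors = FALSE),
    calls)
  structure(list(geno = geno, panel = panel,
                 truth = list(category = truth_cat,
                              segment_interval = cfg$segment_interval,
                              last_supporting = last_supporting,
                              next_shared = next_shared),
                 config = cfg),
            class = "panel_sim")
}

#' Mapping-population simulation config
#'
#' Defaults emulate an F2 population of 188 plants from a cross between an
#' introgression line and a susceptible parent, in coupling phase, with a
#' dominant resistance gene completely linked to one flanking marker and
#' 0.27 cM from the other.
#'
#' @param n_plants number of F2 plants.
#' @param loci ordered locus names (markers plus the gene).
#' @param r recombination fractions per adjacent interval
#'   (`length(loci) - 1`).
#' @param gene_locus which locus is the dominant resistance gene.
#' @param phenotype_error probability a plant's R/S phenotype is flipped.
#' @param forced_recombinants optional integer vector (per interval) for
#'   the deterministic placement mode used to reconstruct printed worked
#'   examples: all gametes are parental except the stated number of
#'   single-crossover gametes per interval.
#' @param seed RNG seed (mandatory).
#' @return Object of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_plants = 188,
                           loci = c("mk_distal", "gene", "mk_proximal"),
                           r = c(0, 0.0027), gene_locus = "gene",
                           phenotype_error = 0, forced_recombinants = NULL,
                           seed) {
  if (missing(seed) || !is_count(seed)) stop("a seed is mandatory")
  stopifnot(is_count(n_plants), n_plants >= 1, length(loci) >= 1,
            is.numeric(r), length(r) == length(loci) - 1)
  if (length(loci) == 0) stop("locus list must be nonempty")
  if (any(r < 0 | r > 0.5)) stop("recombination fractions must be in [0, 0.5]")
  if (!gene_locus %in% loci) stop("gene_locus must be one of loci")
  check_unit_interval(phenotype_error, "phenotype_error")
  if (!is.null(forced_recombinants)) {
    stopifnot(is.numeric(forced_recombinants),
              length(forced_recombinants) == length(r),
              all(forced_recombinants >= 0))
    if (sum(forced_recombinants) > n_plants) {
      stop("forced recombinants exceed the number of plants")
    }
  }
  structure(list(n_plants = n_plants, loci = loci, r = r,
                 gene_locus = gene_locus, phenotype_error = phenotype_error,
                 forced_recombinants = forced_recombinants,
                 seed = as.integer(seed)),
            class = "pop_sim_config")
}

#' Simulate an F2 mapping population
#'
#' Each plant is the union of two independent gametes; each gamete is an
#' independent crossover realization per interval with probability `r_i`
#' (no interference). Marker genotypes are coded `A`/`H`/`B`; the gene
#' locus is reported both as a resolved genotype (`RR`/`Rr`/`rr`, as a
#' progeny test would establish) and as a Stakman infection-type string
#' consistent with dominant resistance.
#'
#' @param cfg a [pop_sim_config()].
#' @return Object of class `pop_sim`: list with `population` (data.frame:
#'   `id`, one column per locus, `it`, `binary`), `truth` (list:
#'   `interval_recombinants`, `n_gametes`) and `config`.
#' @export
simulate_mapping_population <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  set.seed(cfg$seed)
  n_loci <- length(cfg$loci)
  n_g <- 2L * cfg$n_plants

  if (is.null(cfg$forced_recombinants)) {
    first <- rbinom(n_g, 1, 0.5)
    rec <- matrix(0L, n_g, max(n_loci - 1, 0))
    if (n_loci > 1) {
      for (k in seq_len(n_loci - 1)) rec[, k] <- rbinom(n_g, 1, cfg$r[k])
    }
    alleles <- matrix(0L, n_g, n_loci)
    alleles[, 1] <- first
    if (n_loci > 1) {
      flips <- rec
      if (ncol(flips) > 1) {
        for (k in 2:ncol(flips)) flips[, k] <- flips[, k - 1] + rec[, k]
      }
      for (k in 2:n_loci) alleles[, k] <- (first + flips[, k - 1]) %% 2L
    }
    truth_counts <- if (n_loci > 1) colSums(rec) else integer(0)
  } else {
    # Deterministic placement: gamete 1 all-donor, gamete 2 all-recipient,
    # except the stated single-crossover gametes.
    alleles <- matrix(rep(c(1L, 0L), cfg$n_plants * n_loci),
                      n_g, n_loci)
    cursor <- 1L
    for (k in seq_along(cfg$forced_recombinants)) {
      cnt <- cfg$forced_recombinants[k]
      if (cnt == 0) next
      for (m in seq_len(cnt)) {
        g2 <- 2L * cursor  # second gamete of plant `cursor`
        alleles[g2, ] <- c(rep(0L, k), rep(1L, n_loci - k))
        cursor <- cursor + 1L
      }
    }
    truth_counts <- as.integer(cfg$forced_recombinants)
  }

  g1 <- alleles[seq(1, n_g, by = 2), , drop = FALSE]
  g2 <- alleles[seq(2, n_g, by = 2), , drop = FALSE]
  dose <- g1 + g2
  gene_idx <- match(cfg$gene_locus, cfg$loci)

  population <- data.frame(id = sprintf("plant_%04d", seq_len(cfg$n_plants)),
                           stringsAsFactors = FALSE)
  for (k in seq_len(n_loci)) {
    if (k == gene_idx) {
      population[[cfg$loci[k]]] <- c("rr", "Rr", "RR")[dose[, k] + 1L]
    } else {
      population[[cfg$loci[k]]] <- c("B", "H", "A")[dose[, k] + 1L]
    }
  }
  resistant <- dose[, gene_idx] >= 1L
  if (cfg$phenotype_error > 0) {
    flip <- runif(cfg$n_plants) < cfg$phenotype_error
    resistant <- xor(resistant, flip)
  }
  r_strings <- c("0;", ";1-", "1")
  s_strings <- c("3+", "4", "3-4")
  population$it <- ifelse(
    resistant,
    r_strings[sample.int(3, cfg$n_plants, replace = TRUE)],
    s_strings[sample.int(3, cfg$n_plants, replace = TRUE)])
  population$binary <- ifelse(resistant, "R", "S")

  structure(list(population = population,
                 truth = list(interval_recombinants = truth_counts,
                              n_gametes = n_g),
                 config = cfg),
            class = "pop_sim")
}

# Draw a random ACGT string of a given length.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One concrete expansion of an IUPAC pattern (sampled).
expand_iupac <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    s <- sets[[ch]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

# Bases NOT matched by an IUPAC code.
iupac_complement_set <- function(code) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  setdiff(c("A", "C", "G", "T"), sets[[code]])
}

replace_at <- function(seq, at, replacement) {
  paste0(substr(seq, 1, at - 1), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

#' Simulate an amplicon pair for a CAPS or InDel assay
#'
#' Draws a random background sequence free of incidental recognition sites
#' (rejection sampling, capped at 10,000 attempts), plants one concrete
#' expansion of the recognition site at `site_start` on one allele, and
#' derives the other allele by a single-base change abolishing the site
#' (`destroys_site`/`creates_site`), a deletion (`indel`), or no change
#' (`none`).
#'
#' @param length amplicon length (bp).
#' @param enzyme a [restriction_enzyme()].
#' @param site_start 1-based start of the planted recognition site;
#'   defaults to the amplicon midpoint for `none`/`indel`.
#' @param allele_effect one of `"destroys_site"` (ref carries the site),
#'   `"creates_site"` (alt carries it), `"indel"`, `"none"`.
#' @param indel_size deletion size (bp) for `allele_effect = "indel"`.
#' @param seed RNG seed (mandatory).
#' @return List with `ref_amplicon`, `alt_amplicon`, `site_start`,
#'   `allele_effect`.
#' @examples
#' avai <- restriction_enzyme("AvaI", "CYCGRG", 1)
#' pair <- simulate_amplicon_pair(1118, avai, site_start = 418, seed = 1)
#' digest(pair$ref_amplicon, avai) # 418 700
#' @export
simulate_amplicon_pair <- function(length, enzyme, site_start = NULL,
                                   allele_effect = c("destroys_site",
                                                     "creates_site",
                                                     "indel", "none"),
                                   indel_size = 30, seed) {
  if (missing(seed) || !is_count(seed)) stop("a seed is mandatory")
  allele_effect <- match.arg(allele_effect)
  stopifnot(inherits(enzyme, "restriction_enzyme"),
            is_count(length), length >= nchar(enzyme$recognition))
  site_start <- site_start %||% max(1, floor(length / 2))
  lrec <- nchar(enzyme$recognition)
  if (site_start < 1 || site_start + lrec - 1 > length) {
    stop("impossible geometry: recognition site does not fit at site_start")
  }
  if (allele_effect == "indel" &&
      (indel_size < 1 || site_start + indel_size - 1 > length)) {
    stop("impossible geometry: indel does not fit at site_start")
  }
  set.seed(seed)

  max_attempts <- 10000L
  for (attempt in seq_len(max_attempts)) {
    background <- random_dna(length)
    if (length(find_recognition_sites(background, enzyme)) > 0) next
    if (allele_effect %in% c("none", "indel")) {
      ref <- background
      alt <- if (allele_effect == "none") background else {
        paste0(substr(background, 1, site_start - 1),
               substr(background, site_start + indel_size, length))
      }
      return(list(ref_amplicon = ref, alt_amplicon = alt,
                  site_start = site_start, allele_effect = allele_effect))
    }
    concrete <- expand_iupac(enzyme$recognition)
    with_site <- replace_at(background, site_start, concrete)
    ws_sites <- find_recognition_sites(with_site, enzyme)
    if (!(length(ws_sites) == 1 && ws_sites == site_start)) next
    # abolish the site with one base change inside the recognition window
    codes <- strsplit(enzyme$recognition, "")[[1]]
    without_site <- NULL
    for (p in sample.int(lrec)) {
      for (b in sample(iupac_complement_set(codes[p]))) {
        cand <- replace_at(with_site, site_start + p - 1, b)
        if (length(find_recognition_sites(cand, enzyme)) == 0) {
          without_site <- cand
          break
        }
      }
      if (!is.null(without_site)) break
    }
    if (is.null(without_site)) next
    if (allele_effect == "destroys_site") {
      return(list(ref_amplicon = with_site, alt_amplicon = without_site,
                  site_start = site_start, allele_effect = allele_effect))
    }
    return(list(ref_amplicon = without_site, alt_amplicon = with_site,
                site_start = site_start, allele_effect = allele_effect))
  }
  stop("rejection sampling failed to find a site-free background in ",
       max_attempts, " attempts")
}
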