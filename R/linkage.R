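# Segregation tests, infection-type classification, recombinant-gamete
# counting and genetic-map construction for a dominant resistance locus in
# coupling phase (donor marker allele with the resistance allele).

#' Classify Stakman infection types
#'
#' Parses 0-4 scale strings such as `"0;"`, `";1-"`, `"3+"`, `"3-4"`.
#' Modifiers (`;`, `+`, `-`, `,`) are ignored for the numeric class; range
#' strings take the larger numeral; pure fleck forms (`";"`, `"0;"`) map to
#' class 0. `binary` is `"R"` when `numeric_class <= threshold`.
#'
#' @param it character vector of raw infection-type strings.
#' @param threshold resistance threshold on the 0-4 scale (default 2).
#' @return data.frame with columns `raw`, `numeric_class`, `binary`.
#' @examples
#' classify_phenotype(c("0;", ";1-", "3+", "3-4"))
#' @export
classify_phenotype <- function(it, threshold = 2) {
  stopifnot(is_count(threshold), threshold <= 4)
  it <- as.character(it)
  if (length(it) == 0 || any(is.na(it)) || any(!nzchar(trimws(it)))) {
    stop("infection-type strings must be nonempty")
  }
  x <- gsub("[[:space:]]", "", it)
  ok_chars <- grepl("^[0-4;+,/=-]+$", x)
  has_digit <- grepl("[0-4]", x)
  pure_fleck <- grepl("^[;+-]*;[;+-]*$", x)
  bad_digit <- grepl("[5-9]", gsub("[^0-9]", "", it))
  unparseable <- !ok_chars | bad_digit | (!has_digit & !pure_fleck)
  if (any(unparseable)) {
    stop("unparseable infection type(s): ",
         paste(unique(it[unparseable]), collapse = ", "))
  }
  numeric_class <- integer(length(x))
  for (k in seq_along(x)) {
    digits <- as.integer(strsplit(gsub("[^0-4]", "", x[k]), "")[[1]])
    numeric_class[k] <- if (length(digits)) max(digits) else 0L
  }
  data.frame(raw = it, numeric_class = numeric_class,
             binary = ifelse(numeric_class <= threshold, "R", "S"),
             stringsAsFactors = FALSE)
}

#' Chi-square segregation test
#'
#' Pearson goodness-of-fit test of an observed resistant/susceptible split
#' against an expected ratio (default 3:1), 1 degree of freedom, no
#' continuity correction (the convention matching published segregation
#' chi-squares).
#'
#' @param n_r,n_s observed resistant and susceptible counts.
#' @param ratio expected ratio as a length-2 numeric (resistant first).
#' @return Object of class `segregation_result`: `n_r`, `n_s`, `ratio`,
#'   `expected`, `chi2`, `df`, `p`.
#' @examples
#' chi2_segregation(132, 56) # chi2 = 2.30, p = 0.13
#' @export
chi2_segregation <- function(n_r, n_s, ratio = c(3, 1)) {
  stopifnot(is_count(n_r), is_count(n_s),
            is.numeric(ratio), length(ratio) == 2)
  if (n_r + n_s == 0) stop("need at least one observation")
  if (any(ratio <= 0)) stop("expected counts must be positive")
  obs <- c(n_r, n_s)
  prob <- ratio / sum(ratio)
  ht <- suppressWarnings(stats::chisq.test(obs, p = prob))
  structure(list(n_r = n_r, n_s = n_s, ratio = ratio,
                 expected = unname(ht$expected),
                 chi2 = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = unname(ht$p.value)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> %d R : %d S vs %g:%g  chi2 = %.2f (df = %d), p = %.3g\n",
    x$n_r, x$n_s, x$ratio[1], x$ratio[2],
    round_half_out(x$chi2, 2), x$df, x$p))
  invisible(x)
}

#' Resolve a gene genotype from a progeny test
#'
#' All-resistant families are homozygous resistant (`RR`), all-susceptible
#' homozygous susceptible (`rr`), mixed families heterozygous (`Rr`).
#' Families below `min_family_size` give `UNKNOWN` with a warning: small
#' all-resistant families cannot exclude `Rr` (a 12-plant family leaves
#' under 5\% probability of no susceptible segregant from a heterozygote).
#'
#' @param progeny_phenotypes character vector of `"R"`/`"S"`.
#' @param min_family_size minimum family size for a call (default 12).
#' @return `"RR"`, `"Rr"`, `"rr"` or `"UNKNOWN"`.
#' @export
resolve_gene_genotype <- function(progeny_phenotypes, min_family_size = 12) {
  stopifnot(is_count(min_family_size))
  ph <- as.character(progeny_phenotypes)
  if (!all(ph %in% c("R", "S"))) stop("progeny phenotypes must be 'R' or 'S'")
  if (length(ph) < min_family_size) {
    warning(sprintf("family of %d below min_family_size = %d; returning UNKNOWN",
                    length(ph), min_family_size))
    return("UNKNOWN")
  }
  n_r <- sum(ph == "R")
  if (n_r == length(ph)) "RR" else if (n_r == 0) "rr" else "Rr"
}

# Donor-allele dose per locus code. Marker codes: A homozygous donor,
# H heterozygous, B homozygous recipient. Gene genotypes: RR/Rr/rr in
# coupling (R on the donor chromosome).
locus_dose <- function(code) {
  unname(c(A = 2L, H = 1L, B = 0L, RR = 2L, Rr = 1L, rr = 0L)[as.character(code)])
}

#' Minimal recombinant gametes for a two-locus genotype
#'
#' For an F2 plant from a double heterozygote in coupling phase, the
#' minimum number of recombinant gametes over all gamete-pair assignments
#' consistent with the two-locus genotype equals the absolute difference of
#' donor-allele doses at the two loci; phase-ambiguous double heterozygotes
#' resolve to 0 (at small recombination fractions double-recombinant pairs
#' are negligible).
#'
#' @param marker_code vector of marker codes in `A`/`H`/`B` (`NA` missing).
#' @param gene_genotype vector of gene genotypes in `RR`/`Rr`/`rr`
#'   (`UNKNOWN`/`NA` excluded).
#' @return Integer vector in \{0, 1, 2\}; `NA` where either locus is
#'   missing (the caller tallies exclusions).
#' @examples
#' count_recombinant_gametes("A", "Rr") # 1
#' count_recombinant_gametes("H", "Rr") # 0
#' @export
count_recombinant_gametes <- function(marker_code, gene_genotype) {
  mc <- as.character(marker_code)
  gg <- as.character(gene_genotype)
  if (length(mc) != length(gg)) stop("inputs must have equal length")
  mc[!mc %in% c("A", "H", "B")] <- NA
  gg[!gg %in% c("RR", "Rr", "rr")] <- NA
  abs(locus_dose(mc) - locus_dose(gg))
}

#' Genetic map distance
#'
#' `cM = 100 * n_rec / n_total`, rounded to 2 decimals half away from zero.
#' No mapping function is applied: at the distances involved (well under
#' 10 cM) Haldane/Kosambi corrections are smaller than the rounding error.
#'
#' @param n_recombinant_gametes,n_total_gametes recombinant and total
#'   gamete counts.
#' @return Distance in cM.
#' @examples
#' map_distance(18, 3892) # 0.46
#' @export
map_distance <- function(n_recombinant_gametes, n_total_gametes) {
  stopifnot(is_count(n_recombinant_gametes), is_count(n_total_gametes))
  if (n_total_gametes == 0) stop("n_total_gametes must be > 0")
  if (n_recombinant_gametes > n_total_gametes) {
    stop("recombinant gametes cannot exceed total gametes")
  }
  round_half_out(100 * n_recombinant_gametes / n_total_gametes, 2)
}

#' Build a genetic map from a mapping population
#'
#' Loci (markers plus the resistance gene) are ordered by physical anchor
#' position when `anchor` is given, otherwise taken in the order supplied
#' (the physical reference-genome order replaces multipoint ordering).
#' Adjacent-interval recombinant gametes are counted with the minimal
#' recombinant rule ([count_recombinant_gametes()] generalized: the dose
#' difference between the two locus columns); plants missing either locus
#' are excluded from that interval. Loci joined by zero-recombinant
#' intervals collapse into co-segregation groups.
#'
#' @param population data.frame with one row per plant; locus columns hold
#'   marker codes `A`/`H`/`B` or gene genotypes `RR`/`Rr`/`rr`
#'   (`NA`/`"UNKNOWN"` = missing).
#' @param loci character vector of locus column names.
#' @param anchor optional named numeric vector of physical positions (bp)
#'   used to order `loci`.
#' @return Object of class `genetic_map`: list with `map` (data.frame of
#'   locus, anchor_bp, pos_cM, group) and `intervals` (data.frame of
#'   from/to loci, n_recombinant, n_gametes, n_excluded_plants, cM).
#' @export
build_genetic_map <- function(population, loci, anchor = NULL) {
  stopifnot(is.data.frame(population), length(loci) >= 2)
  if (nrow(population) == 0) stop("population is empty")
  missing_loci <- setdiff(loci, names(population))
  if (length(missing_loci)) {
    stop("locus column(s) absent from population: ",
         paste(missing_loci, collapse = ", "))
  }
  if (!is.null(anchor)) {
    if (!all(loci %in% names(anchor))) {
      stop("anchor positions missing for: ",
           paste(setdiff(loci, names(anchor)), collapse = ", "))
    }
    loci <- loci[order(anchor[loci])]
  }
  doses <- vapply(loci, function(l) {
    v <- as.character(population[[l]])
    v[!v %in% c("A", "H", "B", "RR", "Rr", "rr")] <- NA
    locus_dose(v)
  }, integer(nrow(population)))
  doses <- matrix(doses, nrow = nrow(population),
                  dimnames = list(NULL, loci))
  all_missing <- colSums(!is.na(doses)) == 0
  if (any(all_missing)) {
    stop("locus absent (all missing) from every plant: ",
         paste(loci[all_missing], collapse = ", "))
  }

  n_int <- length(loci) - 1
  intervals <- data.frame(
    from = loci[seq_len(n_int)], to = loci[seq_len(n_int) + 1],
    n_recombinant = integer(n_int), n_gametes = integer(n_int),
    n_excluded_plants = integer(n_int), cM = numeric(n_int),
    stringsAsFactors = FALSE)
  for (k in seq_len(n_int)) {
    d1 <- doses[, k]
    d2 <- doses[, k + 1]
    ok <- !is.na(d1) & !is.na(d2)
    intervals$n_recombinant[k] <- sum(abs(d1[ok] - d2[ok]))
    intervals$n_gametes[k] <- 2L * sum(ok)
    intervals$n_excluded_plants[k] <- sum(!ok)
    intervals$cM[k] <- map_distance(intervals$n_recombinant[k],
                                    intervals$n_gametes[k])
  }
  pos <- c(0, cumsum(intervals$cM))
  group <- cumsum(c(1L, as.integer(intervals$n_recombinant > 0)))
  map <- data.frame(locus = loci,
                    anchor_bp = if (is.null(anchor)) NA_real_
                                else unname(anchor[loci]),
                    pos_cM = pos, group = group, stringsAsFactors = FALSE)
  structure(list(map = map, intervals = intervals), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d loci spanning %.2f cM, %d co-segregation group(s)\n",
              nrow(x$map), max(x$map$pos_cM), max(x$map$group)))
  print(x$map, row.names = FALSE)
  invisible(x)
}

#' Write a genetic map as MapChart-compatible text
#'
#' @param gmap a [build_genetic_map()] result.
#' @param path output path.
#' @param group_name linkage-group header line.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(gmap, path, group_name = "LG1") {
  stopifnot(inherits(gmap, "genetic_map"))
  lines <- c(paste("group", group_name),
             sprintf("%s\t%.2f", gmap$map$locus, gmap$map$pos_cM))
  writeLines(lines, path)
  invisible(path)
}

#' Summarize a diagnostic-marker validation panel
#'
#' Per species group and marker, the percentage of accessions from which a
#' product amplified (non-missing call), to 1 decimal; plus the accessions
#' whose haplotype (all scored markers) is identical to the reference
#' (introgression-line) haplotype.
#'
#' @param calls data.frame with columns `accession`, `group`, then one
#'   column per marker; `NA`/empty = no amplification.
#' @param reference_haplotype named character vector, marker -> expected
#'   allele call of the introgression line.
#' @return Object of class `marker_panel_summary`: list with
#'   `amplification` (data.frame group, marker, n_amplified, n_total, pct)
#'   and `identical_accessions` (character vector).
#' @export
validate_marker_panel <- function(calls, reference_haplotype) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) stop("marker-call table is empty")
  if (!all(c("accession", "group") %in% names(calls))) {
    stop("calls must have 'accession' and 'group' columns")
  }
  markers <- names(reference_haplotype)
  if (is.null(markers) || !all(markers %in% names(calls))) {
    stop("reference_haplotype names must match marker columns")
  }
  amplified <- function(v) !is.na(v) & nzchar(as.character(v))
  groups <- unique(as.character(calls$group))
  amp <- do.call(rbind, lapply(groups, function(gr) {
    sub <- calls[calls$group == gr, , drop = FALSE]
    data.frame(group = gr, marker = markers,
               n_amplified = vapply(markers,
                 function(m) sum(amplified(sub[[m]])), integer(1)),
               n_total = nrow(sub), stringsAsFactors = FALSE)
  }))
  amp$pct <- round_half_out(100 * amp$n_amplified / amp$n_total, 1)
  rownames(amp) <- NULL
  ident <- vapply(seq_len(nrow(calls)), function(i) {
    v <- as.character(unlist(calls[i, markers]))
    all(!is.na(v) & nzchar(v) & v == unname(reference_haplotype))
  }, logical(1))
  structure(list(amplification = amp,
                 identical_accessions = as.character(calls$accession[ident])),
            class = "marker_panel_summary")
}

#' @export
print.marker_panel_summary <- function(x, ...) {
  cat("<marker_panel_summary>\n")
  print(x$amplification, row.names = FALSE)
  cat(sprintf("accessions matching the reference haplotype: %d\n",
              length(x$identical_accessions)))
  invisible(x)
}
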