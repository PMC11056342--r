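# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive and separate from the implementation paths they check.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Sliding-window IUPAC matcher (top strand only).
oracle_iupac_match <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  n <- length(s) - length(p) + 1
  if (n < 1) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (k in seq_along(p)) {
      if (!s[i + k - 1] %in% IUPAC_SETS[[p[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# Both-strand site finder in top-strand coordinates.
oracle_find_sites <- function(seq, recognition) {
  top <- oracle_iupac_match(seq, recognition)
  rc <- oracle_revcomp(recognition)
  if (identical(rc, toupper(recognition))) return(sort(unique(top)))
  sort(unique(c(top, oracle_iupac_match(seq, rc))))
}

# Textbook Pearson goodness-of-fit statistic.
oracle_chi2 <- function(obs, ratio) {
  e <- sum(obs) * ratio / sum(ratio)
  sum((obs - e)^2 / e)
}

# Exhaustive minimal-recombinant count over all gamete-pair assignments.
# Gametes carry (marker allele, gene allele); coupling phase: parental
# gametes are (1,1) and (0,0).
oracle_min_recombinants <- function(marker_code, gene_genotype) {
  gam <- expand.grid(m = 0:1, g = 0:1)
  target_m <- c(A = 2, H = 1, B = 0)[[marker_code]]
  target_g <- c(RR = 2, Rr = 1, rr = 0)[[gene_genotype]]
  best <- Inf
  for (i in seq_len(nrow(gam))) {
    for (j in seq_len(nrow(gam))) {
      if (gam$m[i] + gam$m[j] == target_m && gam$g[i] + gam$g[j] == target_g) {
        rec <- (gam$m[i] != gam$g[i]) + (gam$m[j] != gam$g[j])
        best <- min(best, rec)
      }
    }
  }
  best
}

# Exhaustive segment search over all contiguous runs of density-filtered
# supporting sites, under the same predicates as detect_segment (window
# support filter, gap limit, minimum support; ties to larger support then
# distal start).
oracle_segment_search <- function(classified, params) {
  classified <- classified[order(classified$pos), , drop = FALSE]
  pos <- classified$pos
  supp <- classified$category == "DONOR_DIAGNOSTIC" &
    classified$query_carries_donor_allele
  w <- params$window_bp
  win <- ceiling(pos / w)
  keep <- logical(length(pos))
  for (k in unique(win)) {
    inw <- win == k
    frac <- sum(supp & inw) / sum(inw)
    keep[inw] <- frac >= params$min_window_fraction
  }
  ps <- pos[supp & keep]
  best <- NULL
  n <- length(ps)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < params$min_support) next
      if (j > i && any(diff(ps[i:j]) > params$max_gap_bp)) next
      cand <- list(start = ps[i], end = ps[j], n_support = j - i + 1,
                   span = ps[j] - ps[i])
      if (is.null(best) || cand$span > best$span ||
          (cand$span == best$span && cand$n_support > best$n_support) ||
          (cand$span == best$span && cand$n_support == best$n_support &&
           cand$start > best$start)) {
        best <- cand
      }
    }
  }
  best
}

# Classification rules applied site by site, naively (het carries, complete
# data assumed) -- used to check generator truth bookkeeping.
oracle_classify_clean <- function(calls, donor_idx, ref_idx, query_idx) {
  apply(calls, 1, function(row) {
    donors_all <- all(row[donor_idx] >= 1)
    refs_any <- any(row[ref_idx] >= 1)
    q <- row[query_idx] >= 1
    if (donors_all && !refs_any) "DONOR_DIAGNOSTIC"
    else if (q && !refs_any) "QUERY_RARE"
    else if (refs_any) "SHARED_WHEAT"
    else "UNINFORMATIVE"
  })
}

# Small hand-editable VCF fixture writer.
write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# Classified-site table builder for detect_segment tests.
make_classified <- function(pos, category, query_carries = NULL,
                            chrom = "6B") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             category = factor(category,
                               levels = c("DONOR_DIAGNOSTIC", "QUERY_RARE",
                                          "SHARED_WHEAT", "UNINFORMATIVE")),
             query_carries_donor_allele =
               query_carries %||% (category == "DONOR_DIAGNOSTIC"),
             n_missing = 0L, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The worked breakpoint example: a dense supporting run ending at
# 687,016,683 bp with the next wheat-type SNP at 688,295,787 bp.
worked_breakpoint_sites <- function() {
  run <- round(seq(35000, 687016683, length.out = 800))
  run[length(run)] <- 687016683
  make_classified(
    pos = c(run, 688295787, 695e6, 705e6),
    category = c(rep("DONOR_DIAGNOSTIC", length(run)),
                 rep("SHARED_WHEAT", 3)))
}
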