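# Diagnostic-SNP classification and introgressed-segment detection.
#
# A site is donor-diagnostic when the alternate allele is fixed (present in
# every non-missing donor-candidate accession) and absent from every
# non-missing polyploid reference accession; the query line marks donor
# chromatin wherever it carries such alleles. The translocation breakpoint is
# bracketed between the last supporting SNP and the first shared-wheat SNP
# beyond it.

#' Classification policy
#'
#' @param het_carries should a heterozygous call count as carrying the
#'   alternate allele? Default `TRUE`: RNA-seq of a polyploid makes
#'   homozygous/heterozygous dosage unreliable, so presence of the allele is
#'   the robust signal.
#' @param max_missing_frac maximum tolerated fraction of missing calls in
#'   the donor and reference groups for a site to remain eligible for
#'   `DONOR_DIAGNOSTIC`. Default 0 (complete panels).
#' @return An object of class `classification_policy`.
#' @export
classification_policy <- function(het_carries = TRUE, max_missing_frac = 0) {
  stopifnot(is.logical(het_carries), length(het_carries) == 1L,
            !is.na(het_carries))
  check_unit_interval(max_missing_frac, "max_missing_frac")
  structure(list(het_carries = het_carries,
                 max_missing_frac = max_missing_frac),
            class = "classification_policy")
}

#' Classify SNPs into diagnostic categories
#'
#' Assigns each site exactly one category:
#' * `DONOR_DIAGNOSTIC` — alt present in all non-missing donor candidates,
#'   absent in all non-missing polyploid references, and the missing
#'   fraction within the policy limit in both groups;
#' * `QUERY_RARE` — the query carries the alt allele and no reference
#'   accession does, but the donor condition fails (a rare polymorphism);
#' * `SHARED_WHEAT` — the alt allele is present in at least one reference
#'   accession;
#' * `UNINFORMATIVE` — everything else.
#'
#' @param g a [genotype_matrix()].
#' @param panel data.frame with columns `id`, `species`, `group`
#'   (as from [read_panel_metadata()]); at least one `DONOR_CANDIDATE`, at
#'   least one `POLYPLOID_REFERENCE`, exactly one `QUERY`.
#' @param policy a [classification_policy()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `category` (factor), `query_carries_donor_allele`, `n_missing`.
#' @export
classify_sites <- function(g, panel, policy = classification_policy()) {
  stopifnot(inherits(g, "genotype_matrix"))
  panel <- validate_panel(panel)
  donors <- panel$id[panel$group == "DONOR_CANDIDATE"]
  refs <- panel$id[panel$group == "POLYPLOID_REFERENCE"]
  query <- panel$id[panel$group == "QUERY"]
  if (length(donors) < 1 || length(refs) < 1) {
    stop("classification requires >= 1 DONOR_CANDIDATE and >= 1 POLYPLOID_REFERENCE")
  }
  missing_acc <- setdiff(panel$id, colnames(g$calls))
  if (length(missing_acc)) {
    stop("panel accession(s) absent from genotype matrix: ",
         paste(missing_acc, collapse = ", "))
  }
  calls <- g$calls
  carrier <- if (policy$het_carries) calls >= 1L else calls == 2L

  grp_stats <- function(ids) {
    m <- calls[, ids, drop = FALSE]
    c_m <- carrier[, ids, drop = FALSE]
    n_nonmiss <- rowSums(!is.na(m))
    list(n_nonmiss = n_nonmiss,
         n_carry = rowSums(c_m, na.rm = TRUE),
         miss_frac = 1 - n_nonmiss / length(ids))
  }
  d <- grp_stats(donors)
  r <- grp_stats(refs)
  q_carry <- carrier[, query]
  q_carry[is.na(q_carry)] <- FALSE

  donor_ok <- d$n_nonmiss >= 1 & d$n_carry == d$n_nonmiss &
    d$miss_frac <= policy$max_missing_frac
  ref_absent <- r$n_nonmiss >= 1 & r$n_carry == 0
  ref_absent_ok <- ref_absent & r$miss_frac <= policy$max_missing_frac
  diagnostic <- donor_ok & ref_absent_ok
  shared <- r$n_carry >= 1

  category <- rep("UNINFORMATIVE", nrow(g$sites))
  category[shared] <- "SHARED_WHEAT"
  category[!shared & ref_absent & q_carry & !diagnostic] <- "QUERY_RARE"
  category[diagnostic] <- "DONOR_DIAGNOSTIC"

  out <- cbind(
    g$sites,
    data.frame(category = factor(category, levels = SITE_CATEGORIES),
               query_carries_donor_allele = unname(q_carry),
               n_missing = rowSums(is.na(calls)))
  )
  rownames(out) <- NULL
  out
}

#' Segment-detection parameters
#'
#' Defaults chosen for robustness on panels at realistic SNP densities
#' (about 10 classified SNPs per Mb): a supporting run must hold at least
#' `min_support` query-shared donor-diagnostic SNPs, consecutive supporting
#' SNPs may be at most `max_gap_bp` apart, and every `window_bp`
#' genome-anchored window fully inside the run must have at least
#' `min_window_fraction` of its classified SNPs supporting.
#'
#' @param min_support minimum supporting SNPs in a reported segment.
#' @param window_bp window size in bp for the local density criterion.
#' @param min_window_fraction minimum fraction of classified SNPs in a
#'   window that are query-shared donor-diagnostic.
#' @param max_gap_bp maximum gap between consecutive supporting SNPs.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_support = 20, window_bp = 1e6,
                             min_window_fraction = 0.5, max_gap_bp = 1e7) {
  stopifnot(is_count(min_support), min_support >= 1,
            is_scalar_number(window_bp), window_bp >= 1,
            is_scalar_number(max_gap_bp), max_gap_bp >= 1)
  check_unit_interval(min_window_fraction, "min_window_fraction")
  structure(list(min_support = min_support, window_bp = window_bp,
                 min_window_fraction = min_window_fraction,
                 max_gap_bp = max_gap_bp),
            class = "detection_params")
}

#' Detect the introgressed segment and its breakpoint bracket
#'
#' Candidate supporting SNPs are the query-shared donor-diagnostic sites.
#' The local density criterion is applied first: within each `window_bp`
#' window (tiled from position 1), supporting SNPs are kept only when they
#' make up at least `min_window_fraction` of the window's classified SNPs
#' (so every window contributing support to a reported run passes the
#' fraction test; isolated noisy windows lose their support instead of
#' splitting an otherwise contiguous run). The surviving supporting SNPs
#' are grouped into runs in which consecutive SNPs are at most
#' `max_gap_bp` apart, and the physically longest run with at least
#' `min_support` SNPs is reported. Ties between equal-length runs go to
#' the larger support count, then to the more distal (larger) start.
#'
#' The breakpoint bracket is `[breakpoint_lo, breakpoint_hi]`:
#' `breakpoint_lo` is the last supporting SNP; `breakpoint_hi` is the first
#' SNP beyond the run that evidences recipient chromatin — primarily the
#' first donor-diagnostic SNP at which the query does *not* carry the donor
#' allele (the unambiguous wheat-type signal; shared-wheat polymorphism
#' also occurs inside donor chromatin and so cannot bound the boundary on
#' its own), falling back to the first `SHARED_WHEAT` SNP when no
#' discordant diagnostic site follows, then to the chromosome-end sentinel
#' (`chrom_length`, `Inf` when unknown).
#'
#' @param classified a classification table from [classify_sites()],
#'   restricted to a single chromosome.
#' @param params a [detection_params()].
#' @param chrom_length chromosome length in bp (sentinel for
#'   `breakpoint_hi` when no discordant SNP follows the run); optional.
#' @return An object of class `introgression_call` (list with `chrom`,
#'   `segment_start`, `segment_end`, `breakpoint_lo`, `breakpoint_hi`,
#'   `n_support`, `density_profile`, `params`), or `NULL` when no run
#'   qualifies.
#' @export
detect_segment <- function(classified, params = detection_params(),
                           chrom_length = NULL) {
  stopifnot(is.data.frame(classified),
            all(c("chrom", "pos", "category",
                  "query_carries_donor_allele") %in% names(classified)),
            inherits(params, "detection_params"))
  if (nrow(classified) == 0) return(NULL)
  chroms <- unique(classified$chrom)
  if (length(chroms) != 1) {
    stop("detect_segment works one chromosome at a time; got: ",
         paste(chroms, collapse = ", "))
  }
  classified <- classified[order(classified$pos), , drop = FALSE]
  pos <- classified$pos
  supp <- classified$category == "DONOR_DIAGNOSTIC" &
    classified$query_carries_donor_allele

  # Genome-anchored windows: window k covers ((k-1)*w, k*w].
  w <- params$window_bp
  win <- ceiling(pos / w)
  n_class <- tapply(rep(1L, length(pos)), win, sum)
  n_supp <- tapply(as.integer(supp), win, sum)
  wid <- as.numeric(names(n_class))
  frac <- as.numeric(n_supp) / as.numeric(n_class)
  bad_wins <- wid[frac < params$min_window_fraction]

  # density filter: supporting SNPs in below-threshold windows are dropped
  ps <- pos[supp & !(win %in% bad_wins)]
  best <- NULL
  if (length(ps) >= params$min_support) {
    run_id <- cumsum(c(1, as.integer(diff(ps) > params$max_gap_bp)))
    for (rid in unique(run_id)) {
      psr <- ps[run_id == rid]
      n_sup <- length(psr)
      if (n_sup < params$min_support) next
      span <- psr[n_sup] - psr[1]
      if (is.null(best) || span > best$span ||
          (span == best$span && n_sup > best$n_support) ||
          (span == best$span && n_sup == best$n_support &&
           psr[1] > best$start)) {
        best <- list(start = psr[1], end = psr[n_sup],
                     n_support = n_sup, span = span)
      }
    }
  }
  if (is.null(best)) return(NULL)

  after <- pos > best$end
  discordant <- after & classified$category == "DONOR_DIAGNOSTIC" &
    !classified$query_carries_donor_allele
  shared_after <- after & classified$category == "SHARED_WHEAT"
  sentinel <- if (is.null(chrom_length)) Inf else as.numeric(chrom_length)
  breakpoint_hi <- if (any(discordant)) {
    min(pos[discordant])
  } else if (any(shared_after)) {
    min(pos[shared_after])
  } else sentinel

  profile <- data.frame(window_start = (wid - 1) * w + 1,
                        window_end = wid * w,
                        n_classified = as.integer(n_class),
                        n_supporting = as.integer(n_supp),
                        fraction = frac)
  rownames(profile) <- NULL
  structure(list(chrom = chroms, segment_start = best$start,
                 segment_end = best$end, breakpoint_lo = best$end,
                 breakpoint_hi = breakpoint_hi, n_support = best$n_support,
                 density_profile = profile, params = params),
            class = "introgression_call")
}

#' @export
print.introgression_call <- function(x, ...) {
  cat(sprintf(
    "<introgression_call> %s:%.0f-%.0f (%.2f Mb), %d supporting SNPs\n",
    x$chrom, x$segment_start, x$segment_end,
    round_half_out(x$segment_end / 1e6, 2), x$n_support))
  cat(sprintf("  breakpoint bracket: [%.0f, %s]\n", x$breakpoint_lo,
              if (is.finite(x$breakpoint_hi))
                sprintf("%.0f", x$breakpoint_hi) else "chromosome end"))
  invisible(x)
}

#' Restrict a genotype matrix to a region
#'
#' Keeps sites with `start_bp <= pos <= end_bp` (inclusive ends) on `chrom`,
#' preserving order.
#'
#' @param g a [genotype_matrix()].
#' @param chrom chromosome name (must exist in `g`).
#' @param start_bp,end_bp region bounds, 1-based inclusive.
#' @return A [genotype_matrix()].
#' @export
restrict_to_region <- function(g, chrom, start_bp, end_bp) {
  stopifnot(inherits(g, "genotype_matrix"),
            is_scalar_number(start_bp), is_scalar_number(end_bp))
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  if (!chrom %in% g$sites$chrom) stop("unknown chromosome: ", chrom)
  keep <- g$sites$chrom == chrom & g$sites$pos >= start_bp &
    g$sites$pos <= end_bp
  genotype_matrix(g$sites[keep, , drop = FALSE],
                  g$calls[keep, , drop = FALSE])
}
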