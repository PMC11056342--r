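# In-silico CAPS and InDel marker evaluation: degenerate recognition-site
# scanning (IUPAC), linear digestion of PCR amplicons, and allele
# discrimination with a gel-resolvability threshold.

#' Define a restriction enzyme
#'
#' @param name enzyme name, e.g. `"AvaI"`.
#' @param recognition recognition sequence over the IUPAC alphabet
#'   (AvaI = `"CYCGRG"`).
#' @param cut_offset bases after the recognition start on the top strand at
#'   which the cut falls (AvaI = 1: `C^YCGRG`).
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  if (!nzchar(recognition) ||
      !all(strsplit(recognition, "")[[1]] %in% iupac)) {
    stop("recognition sequence must be over the IUPAC alphabet")
  }
  if (!is_count(cut_offset) || cut_offset > nchar(recognition)) {
    stop("cut_offset must be an integer in [0, length(recognition)]")
  }
  structure(list(name = as.character(name), recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Read a restriction-enzyme table
#'
#' TSV with columns `name`, `recognition`, `cut_offset`. The package ships
#' a small editable table (seeded with AvaI and other common enzymes) at
#' `system.file("extdata", "enzymes.tsv", package = "introscan")`, used
#' when `path` is omitted.
#'
#' @param path TSV path, or `NULL` for the shipped table.
#' @return data.frame with one row per enzyme.
#' @export
read_enzyme_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "enzymes.tsv",
                                package = "introscan")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "recognition", "cut_offset") %in% names(df))) {
    stop("enzyme table must have columns name, recognition, cut_offset")
  }
  # validate every row through the constructor
  for (i in seq_len(nrow(df))) {
    restriction_enzyme(df$name[i], df$recognition[i], df$cut_offset[i])
  }
  df$recognition <- toupper(df$recognition)
  df
}

enzyme_from_row <- function(row) {
  restriction_enzyme(row$name, row$recognition, row$cut_offset)
}

check_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1 || !nzchar(seq)) stop("sequence must be a nonempty string")
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT character(s): ",
         paste(unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]]),
               collapse = ", "))
  }
  seq
}

# IUPAC reverse complement of a recognition pattern.
iupac_revcomp <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

# Internal: site starts with strand information (top-strand coordinates).
recognition_site_table <- function(seq, enzyme) {
  seq <- check_dna(seq)
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enzyme$recognition)
  top <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
  rc <- iupac_revcomp(enzyme$recognition)
  if (identical(rc, enzyme$recognition)) {
    # palindromic under IUPAC: bottom-strand pass is redundant
    return(data.frame(start = top, strand = rep("+", length(top))))
  }
  bottom <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(rc), subj, fixed = FALSE))
  out <- rbind(data.frame(start = top, strand = rep("+", length(top))),
               data.frame(start = bottom, strand = rep("-", length(bottom))))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Find restriction-enzyme recognition sites
#'
#' Matches the IUPAC recognition pattern on the top strand (overlaps
#' allowed). Patterns that are not palindromic under IUPAC are also matched
#' against the reverse complement, with positions reported in top-strand
#' coordinates.
#'
#' @param seq DNA string over A/C/G/T (uppercased internally).
#' @param enzyme a [restriction_enzyme()].
#' @return Sorted vector of 1-based start positions (deduplicated).
#' @examples
#' avai <- restriction_enzyme("AvaI", "CYCGRG", 1)
#' find_recognition_sites("AACCCGGGTT", avai) # 3
#' @export
find_recognition_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sort(unique(recognition_site_table(seq, enzyme)$start))
}

#' Digest a linear amplicon
#'
#' Cuts on the top strand fall after base `site_start + cut_offset - 1`;
#' for bottom-strand (non-palindromic) sites the cut maps to after base
#' `site_start + length(recognition) - cut_offset - 1`. Cuts at identical
#' positions are deduplicated; fragments are returned 5' to 3' and sum to
#' the amplicon length. Zero sites return the intact length.
#'
#' @inheritParams find_recognition_sites
#' @return Integer vector of fragment lengths in 5'->3' order.
#' @export
digest <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  seq <- check_dna(seq)
  len <- nchar(seq)
  sites <- recognition_site_table(seq, enzyme)
  L <- nchar(enzyme$recognition)
  cut_after <- ifelse(sites$strand == "+",
                      sites$start + enzyme$cut_offset - 1,
                      sites$start + L - enzyme$cut_offset - 1)
  cut_after <- sort(unique(cut_after[cut_after >= 1 & cut_after < len]))
  as.integer(diff(c(0, cut_after, len)))
}

# Gel-visible band pattern: fragments below the resolvability threshold are
# too small to see.
visible_fragments <- function(fragments, min_resolvable_diff) {
  sort(fragments[fragments >= min_resolvable_diff])
}

# Two band patterns are distinguishable when the visible fragment counts
# differ or some sorted-pairwise difference reaches the threshold.
fragments_distinguishable <- function(f1, f2, min_resolvable_diff) {
  v1 <- visible_fragments(f1, min_resolvable_diff)
  v2 <- visible_fragments(f2, min_resolvable_diff)
  if (length(v1) != length(v2)) return(TRUE)
  if (length(v1) == 0) return(FALSE)
  any(abs(v1 - v2) >= min_resolvable_diff)
}

#' Evaluate a CAPS assay
#'
#' Digests both allele amplicons and judges whether the banding patterns
#' are distinguishable on a gel: fragments shorter than
#' `min_resolvable_diff` are treated as invisible, and the assay is
#' diagnostic when the visible patterns differ in band count or by at least
#' `min_resolvable_diff` in some band.
#'
#' @param ref_amplicon,alt_amplicon allele amplicon sequences.
#' @param enzyme a [restriction_enzyme()].
#' @param min_resolvable_diff smallest fragment-size difference (bp) an
#'   agarose gel resolves; default 20.
#' @param marker marker name for reporting.
#' @return Object of class `caps_assay`: `marker`, `enzyme`,
#'   `fragments_ref`, `fragments_alt` (sorted decreasing), `diagnostic`,
#'   `min_resolvable_diff`.
#' @export
evaluate_caps_assay <- function(ref_amplicon, alt_amplicon, enzyme,
                                min_resolvable_diff = 20, marker = "assay") {
  stopifnot(inherits(enzyme, "restriction_enzyme"),
            is_scalar_number(min_resolvable_diff), min_resolvable_diff >= 1)
  f_ref <- digest(ref_amplicon, enzyme)
  f_alt <- digest(alt_amplicon, enzyme)
  structure(list(marker = marker, enzyme = enzyme$name,
                 fragments_ref = sort(f_ref, decreasing = TRUE),
                 fragments_alt = sort(f_alt, decreasing = TRUE),
                 diagnostic = fragments_distinguishable(f_ref, f_alt,
                                                        min_resolvable_diff),
                 min_resolvable_diff = min_resolvable_diff),
            class = "caps_assay")
}

#' @export
print.caps_assay <- function(x, ...) {
  cat(sprintf("<caps_assay> %s + %s: ref [%s] vs alt [%s] -> %s\n",
              x$marker, x$enzyme,
              paste(x$fragments_ref, collapse = ", "),
              paste(x$fragments_alt, collapse = ", "),
              if (x$diagnostic) "diagnostic" else "not diagnostic"))
  invisible(x)
}

# Discrimination margin of two band patterns: the best distinguishing
# band's distance to the closest band of the other pattern (0 when the
# visible patterns are identical).
assay_margin <- function(f1, f2, min_resolvable_diff) {
  v1 <- visible_fragments(f1, min_resolvable_diff)
  v2 <- visible_fragments(f2, min_resolvable_diff)
  if (identical(v1, v2)) return(0)
  if (length(v1) == length(v2)) return(max(abs(v1 - v2)))
  nearest <- function(band, other) {
    if (length(other) == 0) band else min(abs(band - other))
  }
  d1 <- vapply(setdiff(v1, v2), nearest, numeric(1), other = v2)
  d2 <- vapply(setdiff(v2, v1), nearest, numeric(1), other = v1)
  max(c(d1, d2, 0))
}

#' Propose CAPS enzymes for a SNP
#'
#' Screens an enzyme table for enzymes whose recognition window overlaps
#' the SNP position with differing site sets between the alleles and whose
#' digestion patterns are diagnostic at the resolvability threshold.
#' Results are ranked by decreasing discrimination margin.
#'
#' @param ref_amplicon,alt_amplicon allele amplicon sequences (differing at
#'   `snp_position`, or more; the overlap test uses `snp_position` only).
#' @param snp_position 1-based position of the targeted SNP.
#' @param enzyme_table data.frame as from [read_enzyme_table()].
#' @param min_resolvable_diff gel resolvability threshold (bp).
#' @return data.frame of candidate enzymes (name, recognition, cut_offset,
#'   margin), ranked; zero rows when no enzyme qualifies.
#' @export
propose_enzymes <- function(ref_amplicon, alt_amplicon, snp_position,
                            enzyme_table = read_enzyme_table(),
                            min_resolvable_diff = 20) {
  stopifnot(is_scalar_number(snp_position), snp_position >= 1)
  if (!is.data.frame(enzyme_table) || nrow(enzyme_table) == 0) {
    stop("enzyme table is empty")
  }
  rows <- lapply(seq_len(nrow(enzyme_table)), function(i) {
    enz <- enzyme_from_row(enzyme_table[i, ])
    len <- nchar(enz$recognition)
    s_ref <- find_recognition_sites(ref_amplicon, enz)
    s_alt <- find_recognition_sites(alt_amplicon, enz)
    differing <- c(setdiff(s_ref, s_alt), setdiff(s_alt, s_ref))
    overlaps <- any(differing <= snp_position &
                    differing + len - 1 >= snp_position)
    if (!overlaps) return(NULL)
    assay <- evaluate_caps_assay(ref_amplicon, alt_amplicon, enz,
                                 min_resolvable_diff)
    if (!assay$diagnostic) return(NULL)
    data.frame(name = enz$name, recognition = enz$recognition,
               cut_offset = enz$cut_offset,
               margin = assay_margin(assay$fragments_ref,
                                     assay$fragments_alt,
                                     min_resolvable_diff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(name = character(), recognition = character(),
                      cut_offset = integer(), margin = numeric()))
  }
  out <- out[order(-out$margin, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate an InDel marker
#'
#' @param ref_amplicon,alt_amplicon allele amplicon sequences.
#' @param min_resolvable_diff smallest length difference (bp) resolvable on
#'   a gel; default 20.
#' @return List with `size_ref`, `size_alt`, `size_diff`, `diagnostic`.
#' @export
evaluate_indel_marker <- function(ref_amplicon, alt_amplicon,
                                  min_resolvable_diff = 20) {
  ref <- check_dna(ref_amplicon)
  alt <- check_dna(alt_amplicon)
  size_diff <- abs(nchar(ref) - nchar(alt))
  list(size_ref = nchar(ref), size_alt = nchar(alt), size_diff = size_diff,
       diagnostic = size_diff >= min_resolvable_diff)
}
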