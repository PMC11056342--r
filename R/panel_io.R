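# Readers and writers for the formats the pipeline touches. No science here:
# heterozygous calls are retained and interpreted by the classifier's policy.

#' Construct a genotype matrix
#'
#' The central container for biallelic SNP calls: an ordered site table plus
#' a site-by-accession matrix of integer genotype codes (0 homozygous
#' reference, 1 heterozygous, 2 homozygous alternate, `NA` missing). Sites
#' are sorted by chromosome then position on construction; coordinates are
#' 1-based inclusive.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (numeric,
#'   >= 1), `ref` and `alt` (single bases in A/C/G/T, `ref != alt`).
#' @param calls integer matrix, `nrow(sites)` rows, one named column per
#'   accession, values in \{0, 1, 2, NA\}.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites` and `calls`.
#' @examples
#' g <- genotype_matrix(
#'   data.frame(chrom = "6B", pos = c(10, 20), ref = "A", alt = "G"),
#'   matrix(c(0L, 2L, 1L, NA), 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' )
#' g
#' @export
genotype_matrix <- function(sites, calls) {
  stopifnot(is.data.frame(sites))
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stop("'sites' must have columns chrom, pos, ref, alt")
  }
  calls <- as.matrix(calls)
  if (nrow(sites) != nrow(calls)) {
    stop("dimension mismatch: ", nrow(sites), " sites but ",
         nrow(calls), " rows of calls")
  }
  if (is.null(colnames(calls)) && ncol(calls) > 0) {
    stop("'calls' must have accession names as column names")
  }
  if (anyDuplicated(colnames(calls))) stop("duplicate accession names")
  if (nrow(sites) > 0) {
    sites$chrom <- as.character(sites$chrom)
    sites$pos <- as.numeric(sites$pos)
    if (any(sites$pos < 1)) stop("positions must be >= 1")
    ok_base <- function(x) is.character(x) | is.factor(x)
    sites$ref <- toupper(as.character(sites$ref))
    sites$alt <- toupper(as.character(sites$alt))
    if (!all(sites$ref %in% c("A", "C", "G", "T")) ||
        !all(sites$alt %in% c("A", "C", "G", "T"))) {
      stop("ref/alt alleles must be single bases in {A, C, G, T}")
    }
    if (any(sites$ref == sites$alt)) stop("ref allele must differ from alt")
    if (anyDuplicated(sites[c("chrom", "pos")])) {
      stop("duplicate (chrom, pos) in site table")
    }
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, req, drop = FALSE]
    calls <- calls[o, , drop = FALSE]
    bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
    if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
    storage.mode(calls) <- "integer"
    rownames(calls) <- NULL
  } else {
    sites <- sites[req]
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d accessions on %s\n",
              nrow(x$sites), ncol(x$calls),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a genotype table (VCF or TSV dialect)
#'
#' VCF input keeps biallelic SNP records only (length-1 REF and ALT);
#' multi-allelic and indel records are skipped and counted (see attribute
#' `n_skipped` and the emitted message). Genotypes are taken from the GT
#' field: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA` (phased
#' separators are accepted). The TSV dialect has header columns
#' `chrom, pos, ref, alt` followed by one column per accession containing
#' codes 0/1/2/NA.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()] (possibly with zero sites, which is not an
#'   error), with attribute `n_skipped` for VCF input.
#' @export
read_genotype_table <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_vcf_genotypes(path) else read_tsv_genotypes(path)
}

read_vcf_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    stop("malformed VCF header at line 1: expected '##fileformat=VCF...', got: ",
         if (length(first)) first else "<empty file>")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) <= 1) {
    stop("VCF has an empty sample list")
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # a single record drops to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  usable <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " non-biallelic-SNP record(s)")
  }
  samples <- colnames(v@gt)[-1]
  if (!any(usable)) {
    g <- genotype_matrix(
      data.frame(chrom = character(), pos = numeric(),
                 ref = character(), alt = character()),
      matrix(integer(), 0, length(samples),
             dimnames = list(NULL, samples))
    )
    attr(g, "n_skipped") <- n_skipped
    return(g)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[usable, , drop = FALSE]
  codes <- gt_string_to_code(gt)
  sites <- data.frame(chrom = fix$CHROM[usable],
                      pos = as.numeric(fix$POS[usable]),
                      ref = ref[usable], alt = alt[usable],
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(sites, codes)
  attr(g, "n_skipped") <- n_skipped
  g
}

# Map GT strings to integer codes; anything containing "." is missing.
gt_string_to_code <- function(gt) {
  dm <- dimnames(gt)
  x <- gsub("|", "/", as.character(gt), fixed = TRUE)
  code <- rep(NA_integer_, length(x))
  code[x %in% "0/0"] <- 0L
  code[x %in% c("0/1", "1/0")] <- 1L
  code[x %in% "1/1"] <- 2L
  matrix(code, nrow(gt), ncol(gt), dimnames = dm)
}

read_tsv_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(df)[seq_len(min(4, ncol(df)))])) {
    stop("malformed genotype TSV header: expected columns ",
         paste(req, collapse = ", "), " at line 1 of ", path)
  }
  acc <- setdiff(names(df), req)
  calls <- as.matrix(df[acc])
  if (length(acc) == 0) stop("genotype TSV has an empty sample list")
  storage.mode(calls) <- "integer"
  colnames(calls) <- acc
  genotype_matrix(df[req], calls)
}

#' Write a genotype matrix to the TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- cbind(g$sites, as.data.frame(g$calls))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF (GT field only)
#'
#' @inheritParams write_genotype_table
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               sprintf("##contig=<ID=%s>", unique(g$sites$chrom))), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(g$calls)), collapse = "\t"), con)
  if (nrow(g$sites) > 0) {
    gt <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L],
                 nrow(g$calls), ncol(g$calls))
    gt[is.na(g$calls)] <- "./."
    body <- paste(g$sites$chrom, sprintf("%.0f", g$sites$pos), ".",
                  g$sites$ref, g$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read panel metadata
#'
#' TSV with columns `id`, `species`, `group`; `group` is parsed
#' case-insensitively against `DONOR_CANDIDATE`, `POLYPLOID_REFERENCE`,
#' `QUERY`. Exactly one accession may be the query.
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `species`, `group` (normalized to
#'   upper case).
#' @export
read_panel_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "species", "group") %in% names(df))) {
    stop("panel metadata must have columns id, species, group")
  }
  validate_panel(df[c("id", "species", "group")])
}

# Shared validation for panel tables (also applied to in-memory panels).
validate_panel <- function(panel) {
  panel$group <- toupper(as.character(panel$group))
  bad <- setdiff(unique(panel$group), PANEL_GROUPS)
  if (length(bad)) {
    stop("unknown panel group(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(panel$id)) {
    stop("duplicate accession id(s): ",
         paste(unique(panel$id[duplicated(panel$id)]), collapse = ", "))
  }
  if (sum(panel$group == "QUERY") != 1) {
    stop("panel must contain exactly one QUERY accession, found ",
         sum(panel$group == "QUERY"))
  }
  rownames(panel) <- NULL
  panel
}

#' Write an introgression call as BED
#'
#' Converts the 1-based inclusive segment interval to BED's 0-based
#' half-open convention. An empty (`NULL`) call yields an empty file.
#'
#' @param call an `introgression_call` from [detect_segment()], or `NULL`.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' \dontrun{
#' write_segment_bed(call, "segment.bed") # chr6B 1..687016683 -> "6B\t0\t687016683"
#' }
#' @export
write_segment_bed <- function(call, path) {
  if (is.null(call)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(inherits(call, "introgression_call"))
  writeLines(sprintf("%s\t%.0f\t%.0f", call$chrom,
                     call$segment_start - 1, call$segment_end), path)
  invisible(path)
}
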