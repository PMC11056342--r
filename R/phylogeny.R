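# Pairwise p-distances from genotype codes and a Saitou-Nei neighbor-joining
# tree to assign the donor lineage. The tree input is a SNP set, so distances
# are genotype mismatch fractions (the standard surrogate when no alignment
# is involved); HET-vs-HOM mismatches count 0.5 by default (allele sharing).

#' Pairwise p-distance matrix from a genotype matrix
#'
#' For accessions i and j, `d(i, j)` is the weighted mismatch fraction over
#' sites called in both: identical codes contribute 0, homozygous-opposite
#' codes 1, and any mismatch involving a heterozygote `het_weight`
#' (default 0.5).
#'
#' @param g a [genotype_matrix()].
#' @param min_overlap minimum number of co-called sites per pair; pairs
#'   below it are an error (unstable distances), default 50.
#' @param het_weight mismatch weight when one call is heterozygous.
#' @return Object of class `p_dist`: list with `taxa`, `d` (symmetric
#'   matrix in `[0, 1]`), `n_shared`.
#' @export
p_distance_matrix <- function(g, min_overlap = 50, het_weight = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"), is_count(min_overlap))
  check_unit_interval(het_weight, "het_weight")
  calls <- g$calls
  n <- ncol(calls)
  if (n < 2) stop("need >= 2 accessions")
  taxa <- colnames(calls)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  n_shared <- matrix(nrow(calls), n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    xi <- calls[, i]
    for (j in (i + 1):n) {
      xj <- calls[, j]
      both <- !is.na(xi) & !is.na(xj)
      ns <- sum(both)
      if (ns == 0) {
        stop(sprintf("accessions '%s' and '%s' share zero called sites",
                     taxa[i], taxa[j]))
      }
      if (ns < min_overlap) {
        stop(sprintf(
          "pair '%s'/'%s' has only %d shared sites (min_overlap = %d)",
          taxa[i], taxa[j], ns, min_overlap))
      }
      a <- xi[both]
      b <- xj[both]
      mism <- a != b
      wt <- ifelse(a == 1L | b == 1L, het_weight, 1)
      dij <- sum(wt[mism]) / ns
      d[i, j] <- d[j, i] <- dij
      n_shared[i, j] <- n_shared[j, i] <- ns
    }
  }
  structure(list(taxa = taxa, d = d, n_shared = n_shared), class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("<p_dist> %d taxa, distances in [%.4g, %.4g]\n",
              length(x$taxa), min(x$d), max(x$d)))
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically toward the lowest-index pair in the current
#' node ordering. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister branch (at the final trifurcation,
#' negatives are clamped only). On an additive distance matrix the tree
#' reproduces all pairwise path lengths.
#'
#' @param d a [p_distance_matrix()] result or a symmetric numeric matrix
#'   with taxon names as dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "p_dist")) {
    taxa <- d$taxa
    m <- d$d
  } else {
    m <- as.matrix(d)
    taxa <- rownames(m)
  }
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  n <- length(taxa)
  if (n < 3) stop("neighbor joining needs >= 3 taxa")
  if (any(is.na(m)) || any(!is.finite(m))) {
    stop("distance matrix contains NA/NaN/Inf")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }

  active <- seq_len(n)          # provisional node ids of current rows
  next_id <- n + 1L             # internal ids n+1, n+2, ...
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  dm <- m

  while (length(active) > 3) {
    sz <- length(active)
    r <- rowSums(dm)
    q <- (sz - 2) * dm - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    dij <- dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (sz - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    edges <- rbind(edges, c(next_id, active[i]), c(next_id, active[j]))
    elen <- c(elen, bi, bj)
    dnew <- (dm[i, ] + dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(sz), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active <- c(active[keep], next_id)
    next_id <- next_id + 1L
  }

  d12 <- dm[1, 2]; d13 <- dm[1, 3]; d23 <- dm[2, 3]
  b <- pmax(c((d12 + d13 - d23) / 2,
              (d12 + d23 - d13) / 2,
              (d13 + d23 - d12) / 2), 0)
  root <- next_id
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                 c(root, active[3]))
  elen <- c(elen, b)

  # Renumber internal nodes in ape convention (root = n + 1, preorder).
  map <- integer(2L * n - 2L)
  map[seq_len(n)] <- seq_len(n)
  counter <- n
  stack <- root
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    counter <- counter + 1L
    map[v] <- counter
    kids <- edges[edges[, 1] == v, 2]
    stack <- c(kids[kids > n], stack)
  }
  phy <- structure(list(edge = cbind(map[edges[, 1]], map[edges[, 2]]),
                        edge.length = elen,
                        tip.label = taxa,
                        Nnode = n - 2L),
                   class = "phylo", order = NULL)
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed with 6 significant digits; leaf names
#' containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output file; `NULL` returns the string only.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(x) {
    if (grepl("[][ ():;,']", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  fmt_len <- function(b) sprintf("%.*g", digits, b)
  serialize <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2]
      sub <- if (child <= n) quote_label(tree$tip.label[child])
             else serialize(child)
      paste0(sub, ":", fmt_len(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  s <- paste0(serialize(root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a distance matrix as square TSV
#'
#' @param d a `p_dist` object or square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- if (inherits(d, "p_dist")) d$d else as.matrix(d)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
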