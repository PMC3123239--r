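## Core data containers: pedigree, genetic map, genotype matrix,
## covariance matrix, model specification.

#' Construct a pedigree
#'
#' Builds a validated, topologically sorted pedigree from parallel vectors of
#' individual, sire and dam identifiers. The unknown-parent code is `"0"` (or
#' `NA`). After construction parents always precede their offspring, which is
#' the order assumed by the tabular relationship-matrix method and by gene
#' dropping.
#'
#' @param id character or coercible; unique individual identifiers.
#' @param sire,dam parent identifiers; `"0"` or `NA` for unknown.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `id`, `sire`, `dam` (parents as `NA` when unknown) in topological order,
#'   plus a logical `founder` column (both parents unknown).
#' @examples
#' ped <- pedigree(c(1, 2, 3), c(0, 0, 1), c(0, 0, 2))
#' @export
pedigree <- function(id, sire = NA, dam = NA) {
  id <- as.character(id)
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  sire[!is.na(sire) & sire == "0"] <- NA
  dam[!is.na(dam) & dam == "0"] <- NA
  if (anyDuplicated(id))
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_par <- setdiff(known, id)
  if (length(missing_par))
    stop("parent id(s) not present as individuals: ",
         paste(missing_par, collapse = ", "))

  ## Kahn-style topological sort; detects cycles (incl. self-ancestry).
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam), NA_integer_, idx[dam])
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ## a record is ready when each known parent has been placed
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (any(!placed)) {
    stuck <- id[!placed][1L]
    stop("pedigree contains a cycle (individual is its own ancestor): ", stuck)
  }
  out <- data.frame(id = id[order_out],
                    sire = sire[order_out],
                    dam = dam[order_out],
                    stringsAsFactors = FALSE)
  out$founder <- is.na(out$sire) & is.na(out$dam)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,", sum(x$founder), "founders\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Construct a genetic map
#'
#' @param marker unique marker names.
#' @param chrom chromosome labels.
#' @param pos_cM map positions in centimorgans from the chromosome start
#'   (Haldane metric assumed downstream).
#' @return An object of class `genetic_map` (a `data.frame`).
#' @export
genetic_map <- function(marker, chrom, pos_cM) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_cM <- as.numeric(pos_cM)
  if (anyDuplicated(marker))
    stop("duplicate marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(pos_cM < 0)) stop("map positions must be non-negative")
  out <- data.frame(marker = marker, chrom = chrom, pos_cM = pos_cM,
                    stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    p <- out$pos_cM[out$chrom == ch]
    if (is.unsorted(p)) stop("map positions decrease within chromosome ", ch)
  }
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Construct a genotype matrix
#'
#' Holds unordered biallelic (or multi-allelic) genotypes as two parallel
#' integer matrices with alleles normalised so `a1 <= a2`; `NA` encodes a
#' missing genotype.
#'
#' @param ids individual labels (rows).
#' @param markers marker labels (columns).
#' @param a1,a2 integer matrices of allele codes (positive integers), `NA`
#'   for missing; both alleles of a genotype must be jointly present or
#'   jointly missing.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(ids, markers, a1, a2) {
  ids <- as.character(ids)
  markers <- as.character(markers)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(ids), length(markers))) ||
      !all(dim(a2) == dim(a1)))
    stop("allele matrix dimensions inconsistent with labels")
  if (anyDuplicated(ids)) stop("duplicate individual ids in genotypes")
  if (anyDuplicated(markers)) stop("duplicate marker names in genotypes")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotype (one allele missing)")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers (0 reserved for missing)")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, markers)
  structure(list(ids = ids, markers = markers, a1 = a1, a2 = a2),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotypes:", length(x$ids), "individuals x", length(x$markers),
      "markers;", sum(is.na(x$a1)), "missing\n")
  invisible(x)
}

#' Construct a covariance / relationship matrix
#'
#' A labelled symmetric matrix over a set of individuals (or random-effect
#' levels), used as the covariance structure of a random term: the numerator
#' relationship matrix `A`, its inverse, a raw or standardized genomic
#' relationship matrix, or any user-supplied structure.
#'
#' @param values numeric symmetric matrix.
#' @param labels level labels, one per row/column.
#' @param kind one of `"A"`, `"A_inverse"`, `"G_raw"`, `"G_std"`, `"user"`.
#' @return An object of class `cov_matrix`.
#' @export
cov_matrix <- function(values, labels = rownames(values),
                       kind = c("user", "A", "A_inverse", "G_raw", "G_std")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in covariance matrix")
  if (nrow(values) != length(labels) || ncol(values) != length(labels))
    stop("matrix dimensions do not match labels")
  if (max(abs(values - t(values))) > 1e-10)
    stop("covariance matrix is not symmetric (tolerance 1e-10)")
  values <- (values + t(values)) / 2
  ## marker-based G may legitimately have a zero diagonal entry (e.g. an
  ## all-heterozygote individual), and A_inverse diagonals are unconstrained
  if (kind %in% c("A", "user") && any(diag(values) <= 0))
    stop("diagonal must be strictly positive for kind ", kind)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind),
            class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat("cov_matrix [", x$kind, "]: ", length(x$labels), " x ",
      length(x$labels), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cov_matrix <- function(x) dim(x$values)

#' @export
as.matrix.cov_matrix <- function(x, ...) x$values
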