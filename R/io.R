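## File input/output: phenotypes, pedigree, genotypes, map, triplet
## covariance matrices, sectioned parameter files, result tables.
##
## All plain-text formats; lines starting with "#" are comments. Missing
## codes: unknown parent "0", missing allele "0", missing phenotype "NA".

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x[!grepl("^\\s*#", x)]
}

.split_ws <- function(lines) strsplit(trimws(lines), "\\s+")

#' Read a pedigree file
#'
#' Whitespace-delimited, three columns: individual, sire, dam; `0` codes an
#' unknown parent. Rows may be in any order; the returned pedigree is
#' topologically sorted (parents before offspring).
#'
#' @param path file path.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- .split_ws(lines)
  bad <- which(lengths(f) != 3L)
  if (length(bad))
    stop("pedigree row ", bad[1L], " does not have 3 columns: ", lines[bad[1L]])
  m <- do.call(rbind, f)
  pedigree(m[, 1], m[, 2], m[, 3])
}

#' Write a pedigree file
#' @param ped a [pedigree].
#' @param path output path.
#' @param header optional comment lines (written prefixed with `#`).
#' @export
write_pedigree <- function(ped, path, header = NULL) {
  s <- ifelse(is.na(ped$sire), "0", ped$sire)
  d <- ifelse(is.na(ped$dam), "0", ped$dam)
  .write_table(cbind(ped$id, s, d), path, header)
}

.write_table <- function(x, path, header = NULL, col_names = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (!is.null(col_names)) writeLines(paste(col_names, collapse = "\t"), con)
  utils::write.table(x, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genetic map file
#'
#' Whitespace-delimited columns: marker name, chromosome, position (cM).
#'
#' @param path file path.
#' @return A [genetic_map].
#' @export
read_map <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- .split_ws(lines)
  bad <- which(lengths(f) != 3L)
  if (length(bad))
    stop("map row ", bad[1L], " does not have 3 columns")
  m <- do.call(rbind, f)
  genetic_map(m[, 1], m[, 2], as.numeric(m[, 3]))
}

#' @rdname read_map
#' @param map a [genetic_map] to write.
#' @param header optional comment lines.
#' @export
write_map <- function(map, path, header = NULL) {
  .write_table(format(as.data.frame(unclass(map)), digits = 12, trim = TRUE),
               path, header)
}

#' Read a genotype file
#'
#' One row per individual: id followed by two allele columns per marker, in
#' map order; `0 0` codes a missing genotype.
#'
#' @param path file path.
#' @param map the [genetic_map] the columns correspond to.
#' @return A [genotypes] object aligned to the map.
#' @export
read_genotypes <- function(path, map) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- .split_ws(lines)
  nmk <- nrow(map)
  bad <- which(lengths(f) != 1L + 2L * nmk)
  if (length(bad))
    stop("genotype row ", bad[1L], " has ", lengths(f)[bad[1L]],
         " columns, expected ", 1L + 2L * nmk, " (id + 2 alleles x ",
         nmk, " markers)")
  m <- do.call(rbind, f)
  ids <- m[, 1]
  al <- matrix(as.integer(m[, -1, drop = FALSE]), nrow = length(ids))
  a1 <- al[, seq(1L, 2L * nmk, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * nmk, by = 2L), drop = FALSE]
  miss <- a1 == 0L | a2 == 0L
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  genotypes(ids, map$marker, a1, a2)
}

#' @rdname read_genotypes
#' @param genos a [genotypes] object to write.
#' @param header optional comment lines.
#' @export
write_genotypes <- function(genos, path, header = NULL) {
  n <- length(genos$markers)
  out <- matrix("0", nrow = length(genos$ids), ncol = 1L + 2L * n)
  out[, 1] <- genos$ids
  a1 <- genos$a1; a2 <- genos$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  out[, seq(2L, 2L * n, by = 2L)] <- as.character(a1)
  out[, seq(3L, 2L * n + 1L, by = 2L)] <- as.character(a2)
  .write_table(out, path, header)
}

#' Read a phenotype/effect table
#'
#' Whitespace- or comma-delimited with a header row; the first column is the
#' individual id; `NA` codes missing values. Columns are kept as character
#' unless fully numeric.
#'
#' @param path file path.
#' @param pedigree optional [pedigree]; if given, every id must resolve.
#' @return A `data.frame`; first column named `id` (character).
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  raw <- .read_lines(path)
  raw <- raw[nzchar(trimws(raw))]
  sep <- if (grepl(",", raw[1])) "," else ""
  df <- utils::read.table(text = raw, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  names(df)[1] <- "id"
  df$id <- as.character(df$id)
  if (!is.null(pedigree)) {
    bad <- setdiff(df$id, pedigree$id)
    if (length(bad))
      stop("phenotype id(s) absent from pedigree: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' @rdname read_phenotypes
#' @param pheno data.frame to write (first column taken as the id).
#' @param header optional comment lines.
#' @export
write_phenotypes <- function(pheno, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(pheno, digits = 12, trim = TRUE), con,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a covariance matrix in sparse triplet format
#'
#' Rows `id_i id_j value` list the lower triangle including every diagonal
#' element; unlisted off-diagonals are zero. The result is symmetrised.
#'
#' @param path file path.
#' @param labels the individual/level labels the matrix must cover.
#' @param kind stored on the result (default `"user"`).
#' @return A [cov_matrix] over `labels` in the given order.
#' @export
read_user_matrix <- function(path, labels, kind = "user") {
  labels <- as.character(labels)
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- .split_ws(lines)
  bad <- which(lengths(f) != 3L)
  if (length(bad)) stop("triplet row ", bad[1L], " does not have 3 columns")
  m <- do.call(rbind, f)
  i <- match(m[, 1], labels)
  j <- match(m[, 2], labels)
  if (anyNA(i) || anyNA(j)) {
    unknown <- unique(c(m[, 1][is.na(i)], m[, 2][is.na(j)]))
    stop("triplet id(s) not in labels: ", paste(unknown, collapse = ", "))
  }
  v <- as.numeric(m[, 3])
  n <- length(labels)
  M <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  for (k in seq_along(v)) {
    a <- i[k]; b <- j[k]
    if (seen[a, b] || seen[b, a]) {
      if (M[a, b] != v[k])
        stop("conflicting duplicate triplet for (", m[k, 1], ", ", m[k, 2], ")")
      next
    }
    M[a, b] <- v[k]; M[b, a] <- v[k]
    seen[a, b] <- TRUE; seen[b, a] <- TRUE
  }
  nodiag <- which(!diag(seen))
  if (length(nodiag))
    stop("diagonal element(s) missing for: ",
         paste(labels[utils::head(nodiag, 5)], collapse = ", "))
  cov_matrix(M, labels, kind = kind)
}

#' Write a covariance matrix as triplets
#'
#' Emits the lower triangle including the diagonal, omitting structural
#' zeros off the diagonal, in the format accepted by [read_user_matrix()].
#'
#' @param cm a [cov_matrix].
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_user_matrix <- function(cm, path, header = NULL) {
  M <- cm$values
  n <- nrow(M)
  idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
  keep <- idx[, 1] == idx[, 2] | M[idx] != 0
  idx <- idx[keep, , drop = FALSE]
  out <- cbind(cm$labels[idx[, 1]], cm$labels[idx[, 2]],
               formatC(M[idx], format = "g", digits = 12))
  .write_table(out, path, header)
}

#' Write a solutions table
#'
#' Tab-separated with header: term, level, estimate, SE.
#' @param fit a fitted [qmm] model.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_solutions <- function(fit, path, header = NULL) {
  co <- coef_table(fit)
  .write_table(format(co, digits = 12, trim = TRUE), path, header,
               col_names = names(co))
}

#' Write a scan profile table
#'
#' Tab-separated with header: chromosome, position/marker, LRT, df, p and
#' any effect-estimate columns.
#' @param profile a `qmm_scan` object (see [scan_qtl()]).
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_profile <- function(profile, path, header = NULL) {
  df <- as.data.frame(profile)
  .write_table(format(df, digits = 12, trim = TRUE), path, header,
               col_names = names(df))
}

## --------------------------------------------------------------------------
## Parameter file
## --------------------------------------------------------------------------

#' Parse a sectioned parameter file
#'
#' The parameter file is a plain-text, sectioned description of one analysis.
#' Recognised section headers (one per line, upper case): `DATA`, `PEDIGREE`,
#' `MARKERS`, `EFFECT`, `QTL`, `TRAIT`. Blank lines separate entries where
#' noted; `#` starts a comment.
#'
#' Sections:
#' \describe{
#'   \item{DATA}{one line: path of the phenotype table (header row, first
#'     column the individual id).}
#'   \item{PEDIGREE}{one line: path of the pedigree file. Optional.}
#'   \item{MARKERS}{one line: genotype-file path and map-file path. Optional.}
#'   \item{EFFECT}{one line per model effect:
#'     `name cross|cov column [covariance file]` where `column` is the 1-based
#'     column index (or name) in the data file. A trailing covariance clause
#'     makes the effect random: `pedigree <pedfile>`, `diagonal`,
#'     `file <tripletfile>`, or `genomic raw|std`. Example:
#'     `u cross 1 pedigree pedigreefile`.}
#'   \item{QTL}{one line per QTL effect:
#'     `name keyword scope [(nest)]` with keyword one of `fix_a`, `fix_d`,
#'     `fix_ad`, `fix_ipat`, `fix_imat`, `ran_a`, `snp_fix`, `snp_ran`; scope
#'     `global` (scan all positions), `pos <chrom> <cM>` (fixed position) or
#'     `snp <marker>`; an optional trailing `(column)` nests the effect within
#'     a cross-classified variable. Consecutive lines with the same scope and
#'     nesting describe the same locus and are merged into one term (so
#'     `qtl_add fix_a global` followed by `qtl_dom fix_ad global` yields one
#'     additive+dominance term); a blank line starts a new locus. A line
#'     `epistasis <partner> <scheme>` immediately after a QTL line attaches an
#'     interaction with a previously declared term (`scheme` one of `aa`,
#'     `ad`, `da`, `dd`, or `user:add*dom,...`).}
#'   \item{TRAIT}{one line: trait column name (or index) followed by the
#'     names of the EFFECT/QTL terms to include. An intercept is always
#'     included.}
#' }
#'
#' @param path parameter-file path.
#' @return A list of class `model_spec` with elements `trait`, `fixed_terms`,
#'   `random_terms`, `qtl_terms` and `files` (paths bound in the DATA /
#'   PEDIGREE / MARKERS / EFFECT sections, resolved relative to the parameter
#'   file's directory).
#' @export
parse_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  dirbase <- dirname(path)
  lines_all <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines_all)
  sections <- c("DATA", "PEDIGREE", "MARKERS", "EFFECT", "QTL", "TRAIT")
  cur <- NULL
  content <- stats::setNames(vector("list", length(sections)), sections)
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt) && is.null(cur)) next
    if (txt %in% sections) { cur <- txt; next }
    if (is.null(cur))
      stop("parameter file line ", ln, ": content before any section header")
    content[[cur]] <- rbind(content[[cur]],
                            data.frame(line = ln, text = txt,
                                       stringsAsFactors = FALSE))
  }
  nonblank <- function(sec) {
    x <- content[[sec]]
    if (is.null(x)) x else x[nzchar(x$text), , drop = FALSE]
  }
  rel <- function(p) if (file.exists(p)) p else file.path(dirbase, p)

  files <- list()
  d <- nonblank("DATA")
  if (is.null(d) || !nrow(d)) stop("parameter file: DATA section is required")
  files$data <- rel(d$text[1])
  p <- nonblank("PEDIGREE")
  if (!is.null(p) && nrow(p)) files$pedigree <- rel(p$text[1])
  m <- nonblank("MARKERS")
  if (!is.null(m) && nrow(m)) {
    tok <- strsplit(m$text[1], "\\s+")[[1]]
    if (length(tok) != 2)
      stop("parameter file line ", m$line[1],
           ": MARKERS needs genotype-file and map-file")
    files$genotypes <- rel(tok[1])
    files$map <- rel(tok[2])
  }

  fixed_terms <- list(); random_terms <- list()
  e <- nonblank("EFFECT")
  if (!is.null(e)) for (k in seq_len(nrow(e))) {
    tok <- strsplit(e$text[k], "\\s+")[[1]]
    if (length(tok) < 3)
      stop("parameter file line ", e$line[k], ": EFFECT needs at least ",
           "'name cross|cov column'")
    nm <- tok[1]; ty <- tok[2]; col <- tok[3]
    if (!ty %in% c("cross", "cov", "mean"))
      stop("parameter file line ", e$line[k], ": unknown effect type '",
           ty, "'")
    if (ty == "mean") next  # intercept is implicit
    if (length(tok) == 3) {
      fixed_terms[[nm]] <- list(name = nm, column = col,
                                type = if (ty == "cross") "cross" else "covariate")
    } else {
      covkw <- tok[4]
      rt <- list(name = nm, column = col, covariance = covkw)
      if (covkw == "pedigree") {
        if (length(tok) >= 5) files$pedigree <- rel(tok[5])
        if (is.null(files$pedigree))
          stop("parameter file line ", e$line[k],
               ": pedigree covariance but no pedigree file given")
      } else if (covkw == "file") {
        if (length(tok) < 5)
          stop("parameter file line ", e$line[k], ": 'file' needs a path")
        rt$path <- rel(tok[5])
      } else if (covkw == "genomic") {
        rt$variant <- if (length(tok) >= 5) tok[5] else "std"
        if (!rt$variant %in% c("raw", "std"))
          stop("parameter file line ", e$line[k],
               ": genomic variant must be raw or std")
      } else if (covkw != "diagonal") {
        stop("parameter file line ", e$line[k], ": unknown covariance ",
             "keyword '", covkw, "'")
      }
      random_terms[[nm]] <- rt
    }
  }

  qtl_terms <- list()
  q <- content[["QTL"]]
  kw_effects <- list(fix_a = c("add"), fix_d = c("dom"),
                     fix_ad = c("add", "dom"),
                     fix_ipat = c("imp_pat"), fix_imat = c("imp_mat"),
                     ran_a = c("add"), snp_fix = c("snp"), snp_ran = c("snp"))
  if (!is.null(q)) {
    prev <- NULL  # open term, merged across consecutive compatible lines
    flush <- function() {
      if (!is.null(prev)) qtl_terms[[prev$name]] <<- prev
      prev <<- NULL
    }
    for (k in seq_len(nrow(q))) {
      txt <- q$text[k]
      if (!nzchar(txt)) { flush(); next }
      tok <- strsplit(txt, "\\s+")[[1]]
      if (tok[1] == "epistasis") {
        if (is.null(prev))
          stop("parameter file line ", q$line[k],
               ": epistasis line without a preceding QTL term")
        if (length(tok) < 3)
          stop("parameter file line ", q$line[k],
               ": epistasis needs 'partner scheme'")
        prev$epistasis <- list(partner = tok[2], scheme = tok[3])
        next
      }
      if (length(tok) < 3)
        stop("parameter file line ", q$line[k],
             ": QTL line needs 'name keyword scope'")
      nm <- tok[1]; kw <- tok[2]
      if (!kw %in% names(kw_effects))
        stop("parameter file line ", q$line[k], ": unknown QTL keyword '",
             kw, "'")
      rest <- tok[-(1:2)]
      nest <- NULL
      if (grepl("^\\(.*\\)$", rest[length(rest)])) {
        nest <- sub("^\\((.*)\\)$", "\\1", rest[length(rest)])
        rest <- rest[-length(rest)]
      }
      scope_kw <- rest[1]
      scope <- switch(scope_kw,
        global = list(kind = "global"),
        pos = {
          if (length(rest) < 3)
            stop("parameter file line ", q$line[k],
                 ": 'pos' needs chromosome and cM")
          list(kind = "position", chrom = rest[2], pos_cM = as.numeric(rest[3]))
        },
        snp = list(kind = "snp",
                   marker = if (length(rest) >= 2) rest[2] else NULL),
        stop("parameter file line ", q$line[k], ": unknown QTL scope '",
             scope_kw, "'"))
      term <- list(name = nm, effects = kw_effects[[kw]],
                   type = if (startsWith(kw, "ran") || kw == "snp_ran")
                     "random" else "fixed",
                   scope = scope, nest = nest)
      same_locus <- !is.null(prev) &&
        identical(prev$scope, term$scope) &&
        identical(prev$nest, term$nest) &&
        identical(prev$type, term$type)
      if (same_locus) {
        prev$effects <- union(prev$effects, term$effects)
      } else {
        flush()
        prev <- term
      }
    }
    flush()
  }
  if (length(qtl_terms) && is.null(files$genotypes))
    stop("parameter file: QTL terms declared but no MARKERS section")

  tr <- nonblank("TRAIT")
  if (is.null(tr) || !nrow(tr))
    stop("parameter file: TRAIT section is required")
  tok <- strsplit(tr$text[1], "\\s+")[[1]]
  trait <- tok[1]
  model_terms <- tok[-1]
  known <- c(names(fixed_terms), names(random_terms), names(qtl_terms))
  bad <- setdiff(model_terms, known)
  if (length(bad))
    stop("parameter file line ", tr$line[1], ": TRAIT references undeclared ",
         "term(s): ", paste(bad, collapse = ", "))
  if (length(model_terms)) {
    fixed_terms <- fixed_terms[intersect(model_terms, names(fixed_terms))]
    random_terms <- random_terms[intersect(model_terms, names(random_terms))]
    qtl_terms <- qtl_terms[intersect(model_terms, names(qtl_terms))]
  }
  for (qt in qtl_terms)
    if (!is.null(qt$epistasis) && !qt$epistasis$partner %in% names(qtl_terms))
      stop("epistasis partner '", qt$epistasis$partner,
           "' is not a declared QTL term")

  structure(list(trait = trait, fixed_terms = fixed_terms,
                 random_terms = random_terms, qtl_terms = qtl_terms,
                 files = files),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec: trait", x$trait, "\n")
  cat("  fixed: ", paste(names(x$fixed_terms), collapse = ", "), "\n")
  cat("  random:", paste(names(x$random_terms), collapse = ", "), "\n")
  cat("  qtl:   ", paste(names(x$qtl_terms), collapse = ", "), "\n")
  invisible(x)
}
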