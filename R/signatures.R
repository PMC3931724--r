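#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Symbols are whitespace-stripped and uppercased; empty/NA entries are
#' removed and duplicates collapsed.  An optional alias table (named character
#' vector, `old -> new`, matched after case normalization) maps non-standard
#' symbols onto their canonical names.  The default alias table is the
#' identity.
#'
#' @param genes character vector of gene symbols.
#' @param alias optional named character vector mapping aliases to symbols.
#' @return character vector of unique, normalized symbols.
#' @export
normalize_symbols <- function(genes, alias = NULL) {
  genes <- toupper(trimws(as.character(genes)))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (!is.null(alias) && length(alias)) {
    names(alias) <- toupper(trimws(names(alias)))
    hit <- genes %in% names(alias)
    genes[hit] <- toupper(trimws(unname(alias[genes[hit]])))
  }
  unique(genes)
}

# case-insensitive lookup of (normalized) gene symbols among feature ids;
# sorted so downstream numerics are invariant to input gene order
match_features <- function(genes, ids) {
  sort(ids[toupper(trimws(ids)) %in% genes])
}

#' Construct a gene signature
#'
#' A named set of gene symbols, e.g. one published list of
#' invasion/motility-associated genes.  Symbols are normalized with
#' [normalize_symbols()] and deduplicated, so membership is counted once per
#' signature downstream.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (non-empty after cleaning).
#' @param source free-text provenance.
#' @param alias optional alias table, see [normalize_symbols()].
#' @return object of class `gene_signature` with fields `name`, `genes`,
#'   `source`.
#' @export
gene_signature <- function(name, genes, source = NA_character_, alias = NULL) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  genes <- normalize_symbols(genes, alias)
  if (length(genes) == 0L)
    stop("gene signature '", name, "' is empty after symbol cleaning")
  structure(list(name = name, genes = genes, source = as.character(source)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Construct a signature collection
#'
#' An ordered list of [gene_signature()] objects together with the derived
#' gene universe (the exact union of all member gene sets).  The universe is
#' the sampling frame for size-matched random collections.
#'
#' @param signatures a list of `gene_signature` objects, or a (optionally
#'   named) list of character vectors.
#' @param alias optional alias table applied when coercing character vectors.
#' @return object of class `signature_collection` with fields `signatures`
#'   and `universe`.
#' @export
signature_collection <- function(signatures, alias = NULL) {
  if (length(signatures) == 0L) stop("empty collection")
  nm <- names(signatures)
  sigs <- lapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (inherits(s, "gene_signature")) return(s)
    name <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else sprintf("signature_%02d", i)
    gene_signature(name, s, alias = alias)
  })
  universe <- sort(unique(unlist(lapply(sigs, `[[`, "genes"), use.names = FALSE)))
  structure(list(signatures = sigs, universe = universe),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  sizes <- vapply(x$signatures, function(s) length(s$genes), integer(1))
  cat("<signature_collection> ", length(x$signatures), " signatures, ",
      length(x$universe), " genes in universe (",
      sum(sizes), " membership slots)\n", sep = "")
  invisible(x)
}

#' @export
length.signature_collection <- function(x) length(x$signatures)

#' Signature sizes of a collection
#' @param collection a `signature_collection`.
#' @return integer vector of member sizes.
#' @export
signature_sizes <- function(collection) {
  stopifnot(inherits(collection, "signature_collection"))
  vapply(collection$signatures, function(s) length(s$genes), integer(1))
}

#' Per-gene multiplicity
#'
#' Number of distinct signatures each universe gene belongs to.  Intra-
#' signature duplicates cannot inflate the count because signatures store
#' deduplicated gene sets.
#'
#' @param collection a `signature_collection`.
#' @return named integer vector over the universe (names sorted).
#' @export
gene_multiplicity <- function(collection) {
  stopifnot(inherits(collection, "signature_collection"))
  all <- unlist(lapply(collection$signatures, `[[`, "genes"), use.names = FALSE)
  tab <- table(all)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(names(out))]
}

#' Read gene sets in GMT format
#'
#' One signature per line, tab-separated: name, description, then gene
#' symbols.  The description field is stored as `source`.
#'
#' @param path file path.
#' @param alias optional alias table, see [normalize_symbols()].
#' @return a `signature_collection`.
#' @export
read_gmt <- function(path, alias = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty collection")
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60))
    gene_signature(f[1], f[-(1:2)], source = f[2], alias = alias)
  })
  signature_collection(sigs)
}

#' Write gene sets in GMT format
#'
#' @param collection a `signature_collection` (or a single `gene_signature`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_signature"))
    collection <- signature_collection(list(collection))
  stopifnot(inherits(collection, "signature_collection"))
  lines <- vapply(collection$signatures, function(s) {
    desc <- if (is.na(s$source)) "na" else s$source
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
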