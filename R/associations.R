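#' Normalize RNA identifiers
#'
#' Gene symbols and miRNA names are treated as opaque, case-sensitive strings
#' after a single normalization pass: surrounding whitespace is trimmed and
#' the "miR"/"MiR" token of miRNA-style names is lowercased so that
#' "hsa-miR-424" and "hsa-mir-424" collapse to one identifier. Optionally the
#' mature-arm suffix ("-5p"/"-3p") is stripped, collapsing arms onto the
#' precursor name; this changes downstream triplet counts and is off by
#' default.
#'
#' @param ids character vector of identifiers.
#' @param collapse_arms logical; strip a trailing "-5p"/"-3p" suffix.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_ids(c(" hsa-miR-424 ", "hsa-mir-424-5p"), collapse_arms = TRUE)
normalize_ids <- function(ids, collapse_arms = FALSE) {
  out <- trimws(as.character(ids))
  out <- gsub("(^|-)miR(-|$)", "\\1mir\\2", out)
  if (collapse_arms) out <- sub("-[35]p$", "", out)
  out
}

#' Construct an association table from a pairs data frame
#'
#' Low-level constructor behind [read_association_file()]: deduplicates the
#' pairs and validates that no identifier is empty.
#'
#' @param pairs two-column data frame (`regulator`, `mirna`).
#' @param kind `"lncRNA-miRNA"` or `"mRNA-miRNA"`.
#' @return an `association_table`.
#' @export
new_association_table <- function(pairs, kind) {
  kind <- match.arg(kind, c("lncRNA-miRNA", "mRNA-miRNA"))
  stopifnot(is.data.frame(pairs), ncol(pairs) == 2L)
  names(pairs) <- c("regulator", "mirna")
  pairs <- unique(pairs[c("regulator", "mirna")])
  if (any(!nzchar(pairs$regulator)) || any(!nzchar(pairs$mirna)))
    psnet_error("association table contains empty identifiers",
                "psnet_parse_error")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, kind = kind), class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> kind: %s, %d unique pairs\n",
              x$kind, nrow(x$pairs)))
  invisible(x)
}

#' Read a two-column association file
#'
#' Reads a tab-separated file of regulator-miRNA pairs (lncRNA-miRNA or
#' mRNA-miRNA), such as exports from miRcode, starBase, miRDB, miRTarBase or
#' TargetScan. Rows are deduplicated; identifiers are normalized with
#' [normalize_ids()]. An optional single header line is auto-detected (a
#' first line whose second field does not look like a miRNA name and whose
#' fields look like column labels) or can be forced.
#'
#' @param path path to a two-column tab-separated text file.
#' @param kind `"lncRNA-miRNA"` or `"mRNA-miRNA"`.
#' @param header `"auto"`, `TRUE` or `FALSE`.
#' @param collapse_arms passed to [normalize_ids()].
#' @return an `association_table`: a list with elements `pairs` (data frame
#'   with columns `regulator`, `mirna`) and `kind`.
#' @export
read_association_file <- function(path, kind = c("lncRNA-miRNA", "mRNA-miRNA"),
                                  header = "auto", collapse_arms = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    psnet_error(sprintf("association file not found: %s", path),
                "psnet_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    psnet_error(sprintf("association file is empty: %s", path),
                "psnet_empty_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    psnet_error(sprintf(
      "malformed association file %s: line %d has %d column(s), expected 2",
      path, which(nf != 2L)[1L], nf[which(nf != 2L)[1L]]),
      "psnet_parse_error")
  mat <- do.call(rbind, fields)
  if (identical(header, "auto")) {
    first <- tolower(mat[1L, ])
    headerish <- grepl("lnc|mrna|mirna|mir_|gene|regulator|target|symbol|id|name",
                       first)
    header <- any(headerish) && !grepl("^hsa-", first[2L])
  }
  if (isTRUE(header)) mat <- mat[-1L, , drop = FALSE]
  if (nrow(mat) == 0L)
    psnet_error(sprintf("association file has a header but no rows: %s", path),
                "psnet_empty_error")
  pairs <- data.frame(regulator = normalize_ids(mat[, 1L], collapse_arms = FALSE),
                      mirna = normalize_ids(mat[, 2L], collapse_arms = collapse_arms),
                      stringsAsFactors = FALSE)
  new_association_table(pairs, kind)
}

pair_keys <- function(tab) paste(tab$pairs$regulator, tab$pairs$mirna, sep = "\r")

#' Intersect association tables
#'
#' Returns the pairs shared by every table, mirroring the construction of a
#' consensus association list from several databases (e.g. keeping
#' lncRNA-miRNA pairs present in both miRcode and starBase, or mRNA-miRNA
#' pairs common to miRDB, miRTarBase and TargetScan).
#'
#' @param tables list of `association_table` objects of the same kind.
#' @return an `association_table` with the set intersection of pairs.
#' @export
intersect_associations <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L)
    psnet_error("need a nonempty list of association tables",
                "psnet_type_error")
  if (!all(vapply(tables, inherits, logical(1), "association_table")))
    psnet_error("all elements must be association_table objects",
                "psnet_type_error")
  kinds <- vapply(tables, function(t) t$kind, character(1))
  if (length(unique(kinds)) != 1L)
    psnet_error(sprintf("cannot intersect tables of mixed kinds: %s",
                        paste(unique(kinds), collapse = ", ")),
                "psnet_type_error")
  keys <- Reduce(intersect, lapply(tables, pair_keys))
  first <- tables[[1L]]
  keep <- first$pairs[pair_keys(first) %in% keys, , drop = FALSE]
  if (nrow(keep) == 0L)
    psnet_warn("association intersection is empty", "psnet_empty_warning")
  new_association_table(keep, kinds[1L])
}

#' Assemble candidate lncRNA-miRNA-mRNA triplets
#'
#' Joins the lncRNA-miRNA and mRNA-miRNA association tables on the shared
#' miRNA and restricts each member to the identifiers actually present
#' (expressed) in the cohort's expression matrices. The triplet count equals,
#' over shared miRNAs z, the sum of (number of expressed lncRNA partners of
#' z) x (number of expressed mRNA partners of z). Triplets in which any two
#' identifiers coincide as strings are dropped.
#'
#' @param lnc_mi `association_table` of kind `"lncRNA-miRNA"`.
#' @param mrna_mi `association_table` of kind `"mRNA-miRNA"`.
#' @param expressed_lnc,expressed_mi,expressed_mrna character vectors of
#'   identifiers present in the cohort; `NULL` means no restriction.
#' @return data frame with columns `lncRNA`, `miRNA`, `mRNA`, one row per
#'   candidate triplet.
#' @export
build_initial_triplets <- function(lnc_mi, mrna_mi,
                                   expressed_lnc = NULL,
                                   expressed_mi = NULL,
                                   expressed_mrna = NULL) {
  stopifnot(inherits(lnc_mi, "association_table"),
            inherits(mrna_mi, "association_table"))
  if (lnc_mi$kind != "lncRNA-miRNA" || mrna_mi$kind != "mRNA-miRNA")
    psnet_error("build_initial_triplets needs one lncRNA-miRNA and one mRNA-miRNA table",
                "psnet_type_error")
  a <- lnc_mi$pairs
  b <- mrna_mi$pairs
  for (nm in c("expressed_lnc", "expressed_mi", "expressed_mrna")) {
    v <- get(nm)
    if (!is.null(v) && length(v) == 0L)
      psnet_warn(sprintf("%s is empty; triplet set may be empty", nm))
  }
  if (!is.null(expressed_lnc)) a <- a[a$regulator %in% expressed_lnc, , drop = FALSE]
  if (!is.null(expressed_mrna)) b <- b[b$regulator %in% expressed_mrna, , drop = FALSE]
  if (!is.null(expressed_mi)) {
    a <- a[a$mirna %in% expressed_mi, , drop = FALSE]
    b <- b[b$mirna %in% expressed_mi, , drop = FALSE]
  }
  out <- merge(a, b, by = "mirna", suffixes = c(".lnc", ".mrna"))
  out <- data.frame(lncRNA = out$regulator.lnc,
                    miRNA = out$mirna,
                    mRNA = out$regulator.mrna,
                    stringsAsFactors = FALSE)
  out <- out[out$lncRNA != out$mRNA & out$lncRNA != out$miRNA &
               out$mRNA != out$miRNA, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$lncRNA, out$miRNA, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a triplet table to TSV
#'
#' @param triplets data frame with columns `lncRNA`, `miRNA`, `mRNA` (extra
#'   columns are preserved).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path) {
  write.table(triplets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply an identifier mapping file
#'
#' Translates identifiers (e.g. Ensembl gene IDs to symbols) using a
#' two-column tab-separated mapping file (`from<TAB>to`). Unmapped
#' identifiers are kept unchanged.
#'
#' @param ids character vector.
#' @param mapping_path path to the two-column mapping file.
#' @return translated character vector.
#' @export
map_ids <- function(ids, mapping_path) {
  map <- read.delim(mapping_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 2L)
    psnet_error("mapping file must have two tab-separated columns",
                "psnet_parse_error")
  lut <- setNames(trimws(map[[2L]]), trimws(map[[1L]]))
  hit <- ids %in% names(lut)
  ids[hit] <- unname(lut[ids[hit]])
  ids
}
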