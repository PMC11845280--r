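# Readers and writers for every tab-separated artifact the workflow touches.
# All readers accept plain or gzip files (a `.gz` suffix triggers transparent
# decompression); all writers emit deterministically sorted output so files
# are diffable across runs. Comment lines start with '#'.

is_gz_path <- function(path) grepl("\\.gz$", path)

open_read <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is_gz_path(path)) gzfile(path, "rt") else file(path, "rt")
}

open_write <- function(path) {
  con <- tryCatch(
    if (is_gz_path(path)) gzfile(path, "wt") else file(path, "wt"),
    error = function(e) stop("cannot write to ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot write to ", path, ": ",
                               conditionMessage(w), call. = FALSE)
  )
  con
}

# Read a TSV into a list of character matrices of fields plus original line
# numbers, skipping blank lines and '#' comments.
read_tsv_fields <- function(path) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = lineno[keep])
}

write_lines_to <- function(lines, path) {
  con <- open_write(path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

parse_numeric_or_stop <- function(x, lineno, path, what) {
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed ", what, " '", x[i], "' at line ", lineno[i],
         " of ", path, call. = FALSE)
  }
  val
}

#' Read a protein-protein interaction network edge list
#'
#' Expects two or three tab-separated columns per line: the two interacting
#' protein identifiers and an optional non-negative weight. Duplicate edges
#' (in either orientation) are collapsed, keeping the first weight seen.
#'
#' @param path Path to a `*_ppin.txt` or `*_ppin.txt.gz` file.
#' @return A protein-level [ppi_network].
#' @export
read_ppin <- function(path) {
  read_edge_list(path, level = "protein")
}

#' Read a domain-domain interaction network edge list
#'
#' Same format as [read_ppin] but node identifiers are domain instances of
#' the form `protein|family|occurrence`.
#'
#' @param path Path to a `*_ddin.txt(.gz)` file.
#' @return A domain-level [ppi_network].
#' @export
read_ddin <- function(path) {
  read_edge_list(path, level = "domain")
}

read_edge_list <- function(path, level) {
  tsv <- read_tsv_fields(path)
  nf <- lengths(tsv$fields)
  if (any(nf < 2L)) {
    i <- which(nf < 2L)[1L]
    stop("expected >= 2 tab-separated columns at line ", tsv$lineno[i],
         " of ", path, call. = FALSE)
  }
  from <- vapply(tsv$fields, `[`, "", 1L)
  to <- vapply(tsv$fields, `[`, "", 2L)
  w3 <- vapply(tsv$fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")
  weight <- parse_numeric_or_stop(w3, tsv$lineno, path, "weight")
  ppi_network(from, to, weight = weight, level = level)
}

#' Write a network edge list
#'
#' Edges are written lexicographically sorted, one `from<TAB>to[<TAB>weight]`
#' row per edge; reading the file back reproduces the same edge set. A `.gz`
#' suffix on `path` gzip-compresses the output.
#'
#' @param net A [ppi_network].
#' @param path Output path; conventionally `<sample>_ppin.txt(.gz)` for
#'   protein-level and `<sample>_ddin.txt(.gz)` for domain-level networks.
#' @return `path`, invisibly.
#' @export
write_ppin <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  if (!identical(net$level, "protein")) {
    stop("write_ppin expects a protein-level network", call. = FALSE)
  }
  write_edge_list(net, path)
}

#' @rdname write_ppin
#' @export
write_ddin <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  if (!identical(net$level, "domain")) {
    stop("write_ddin expects a domain-level network", call. = FALSE)
  }
  write_edge_list(net, path)
}

write_edge_list <- function(net, path) {
  e <- net$edges
  lines <- if (nrow(e)) {
    ifelse(is.na(e$weight),
           paste(e$from, e$to, sep = "\t"),
           paste(e$from, e$to, fmt_num(e$weight), sep = "\t"))
  } else {
    character()
  }
  write_lines_to(lines, path)
}

#' Major-feature table writer/reader
#'
#' The major-feature ("major transcripts") table records, per expressed
#' protein, the gene and the chosen most-abundant feature (gene or
#' transcript) with its abundance: rows are
#' `protein<TAB>gene<TAB>feature<TAB>abundance`.
#'
#' @param major A data.frame with columns `protein`, `gene`, `feature`,
#'   `abundance`.
#' @param path Output path, conventionally `<sample>_major_transcripts.txt(.gz)`.
#' @return `path` (writer) or the data.frame (reader), rows sorted by protein.
#' @export
write_major_transcripts <- function(major, path) {
  stopifnot(is.data.frame(major),
            all(c("protein", "gene", "feature", "abundance") %in% names(major)))
  major <- major[order(major$protein), , drop = FALSE]
  lines <- paste(major$protein, major$gene, major$feature,
                 fmt_num(major$abundance), sep = "\t")
  write_lines_to(lines, path)
}

#' @rdname write_major_transcripts
#' @export
read_major_transcripts <- function(path) {
  tsv <- read_tsv_fields(path)
  nf <- lengths(tsv$fields)
  if (length(nf) && any(nf != 4L)) {
    i <- which(nf != 4L)[1L]
    stop("expected 4 tab-separated columns at line ", tsv$lineno[i],
         " of ", path, call. = FALSE)
  }
  m <- matrix(unlist(tsv$fields), ncol = 4L, byrow = TRUE,
              dimnames = list(NULL, c("protein", "gene", "feature", "abundance")))
  out <- data.frame(
    protein = m[, "protein"], gene = m[, "gene"], feature = m[, "feature"],
    abundance = parse_numeric_or_stop(m[, "abundance"], tsv$lineno, path, "abundance"),
    stringsAsFactors = FALSE
  )
  if (length(nf) == 0L) {
    out <- data.frame(protein = character(), gene = character(),
                      feature = character(), abundance = numeric(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$protein), , drop = FALSE]
}

#' Construct an expression table
#'
#' Holds per-feature abundances (TPM/FPKM scale) at gene or transcript
#' level; transcript-level tables carry the transcript-to-gene map and
#' optionally transcript lengths in nucleotides.
#'
#' @param level `"gene"` or `"transcript"`.
#' @param abundance Named numeric vector of non-negative abundances.
#' @param tx2gene Named character vector mapping transcript -> gene
#'   (required at transcript level, covering every transcript).
#' @param lengths Optional named numeric vector of transcript lengths.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(level = c("gene", "transcript"), abundance,
                             tx2gene = NULL, lengths = NULL) {
  level <- match.arg(level)
  abundance <- unlist(abundance)
  stopifnot(is.numeric(abundance))
  if (length(abundance) && is.null(names(abundance))) {
    stop("abundance must be a named vector", call. = FALSE)
  }
  if (any(is.na(abundance) | abundance < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (level == "transcript") {
    if (is.null(tx2gene) || !all(names(abundance) %in% names(tx2gene))) {
      stop("transcript-level tables need a gene for every transcript",
           call. = FALSE)
    }
  }
  structure(
    list(level = level, abundance = abundance,
         tx2gene = tx2gene, lengths = lengths),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<%s-level expression table: %d features>\n",
              x$level, length(x$abundance)))
  invisible(x)
}

#' Read an expression table
#'
#' Generic tab-separated dialect: gene level expects `gene<TAB>value` rows;
#' transcript level expects `transcript<TAB>gene<TAB>value` with an optional
#' fourth transcript-length column. Values are TPM or FPKM abundances. A
#' first row whose value column is non-numeric is treated as a header and
#' skipped; repeated feature ids have their abundances summed.
#'
#' @param path Path to a plain or gzipped TSV.
#' @param level `"gene"` or `"transcript"`.
#' @param columns Optional named integer vector overriding column positions,
#'   with names among `feature`, `gene`, `value`, `length`.
#' @return An [expression_table].
#' @export
read_expression <- function(path, level = c("gene", "transcript"),
                            columns = NULL) {
  level <- match.arg(level)
  default_cols <- if (level == "gene") {
    c(feature = 1L, value = 2L)
  } else {
    c(feature = 1L, gene = 2L, value = 3L, length = 4L)
  }
  if (!is.null(columns)) {
    default_cols[names(columns)] <- as.integer(columns)
  }
  cols <- default_cols
  tsv <- read_tsv_fields(path)
  need <- if (level == "gene") cols[c("feature", "value")] else cols[c("feature", "gene", "value")]
  nf <- lengths(tsv$fields)
  if (any(nf < max(need))) {
    i <- which(nf < max(need))[1L]
    stop("expected >= ", max(need), " tab-separated columns at line ",
         tsv$lineno[i], " of ", path,
         if (level == "transcript") " (transcript level needs a gene column)" else "",
         call. = FALSE)
  }
  get_col <- function(j) vapply(tsv$fields, function(f) {
    if (length(f) >= j) f[j] else NA_character_
  }, "")
  feature <- get_col(cols[["feature"]])
  value_raw <- get_col(cols[["value"]])
  # Header auto-detection: non-numeric value column in the first row.
  if (length(value_raw) &&
      is.na(suppressWarnings(as.numeric(value_raw[1L])))) {
    drop1 <- function(x) x[-1L]
    feature <- drop1(feature)
    value_raw <- drop1(value_raw)
    tsv$fields <- drop1(tsv$fields)
    tsv$lineno <- drop1(tsv$lineno)
  }
  value <- parse_numeric_or_stop(value_raw, tsv$lineno, path, "abundance")
  if (any(value < 0)) {
    i <- which(value < 0)[1L]
    stop("negative abundance at line ", tsv$lineno[i], " of ", path,
         call. = FALSE)
  }
  get_col2 <- function(j) vapply(tsv$fields, function(f) {
    if (length(f) >= j) f[j] else NA_character_
  }, "")
  if (level == "gene") {
    ab <- tapply_sum(value, feature)
    return(expression_table("gene", ab))
  }
  gene <- get_col2(cols[["gene"]])
  len_raw <- get_col2(cols[["length"]])
  t2g_pairs <- unique(data.frame(tx = feature, gene = gene,
                                 stringsAsFactors = FALSE))
  if (anyDuplicated(t2g_pairs$tx)) {
    dup <- t2g_pairs$tx[duplicated(t2g_pairs$tx)][1L]
    stop("transcript '", dup, "' mapped to more than one gene in ", path,
         call. = FALSE)
  }
  tx2gene <- stats::setNames(t2g_pairs$gene, t2g_pairs$tx)
  ab <- tapply_sum(value, feature)
  lengths <- NULL
  if (any(!is.na(len_raw))) {
    lenv <- parse_numeric_or_stop(len_raw, tsv$lineno, path, "length")
    lp <- unique(data.frame(tx = feature, len = lenv,
                            stringsAsFactors = FALSE))
    lp <- lp[!is.na(lp$len), , drop = FALSE]
    if (any(lp$len <= 0)) {
      stop("transcript lengths must be positive in ", path, call. = FALSE)
    }
    lengths <- stats::setNames(lp$len, lp$tx)
  }
  expression_table("transcript", ab, tx2gene = tx2gene, lengths = lengths)
}

tapply_sum <- function(value, key) {
  if (!length(value)) return(stats::setNames(numeric(), character()))
  s <- rowsum(value, key)
  stats::setNames(as.numeric(s), rownames(s))
}

#' Write an expression table
#'
#' Inverse of [read_expression] (rows sorted by feature id). Transcript
#' tables include the gene column and, when lengths are known, a fourth
#' length column.
#'
#' @param expr An [expression_table].
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  ids <- sort(names(expr$abundance))
  ab <- expr$abundance[ids]
  if (expr$level == "gene") {
    lines <- paste(ids, fmt_num(ab), sep = "\t")
  } else {
    gene <- expr$tx2gene[ids]
    if (is.null(expr$lengths)) {
      lines <- paste(ids, gene, fmt_num(ab), sep = "\t")
    } else {
      len <- expr$lengths[ids]
      lines <- paste(ids, gene, fmt_num(ab), fmt_num(len), sep = "\t")
    }
  }
  write_lines_to(lines, path)
}

#' Construct a protein domain annotation
#'
#' Maps each protein to its gene and its isoforms, each isoform carrying an
#' ordered list of domain family names (possibly empty); exactly one isoform
#' per protein is flagged canonical. The family name `"DUMMY"` is reserved
#' for the artificial domain given to proteins without annotation.
#'
#' @param protein,gene,isoform Character vectors (one row per isoform).
#' @param domains List of character vectors of domain family names.
#' @param canonical Logical vector; exactly one `TRUE` per protein.
#' @return An object of class `domain_annotation` (a data.frame with a
#'   `domains` list-column).
#' @export
domain_annotation <- function(protein, gene, isoform, domains, canonical) {
  stopifnot(length(protein) == length(gene),
            length(protein) == length(isoform),
            length(protein) == length(domains),
            length(protein) == length(canonical))
  domains <- lapply(domains, as.character)
  if (any(vapply(domains, function(d) DUMMY_FAMILY %in% d, TRUE))) {
    stop("domain family name '", DUMMY_FAMILY, "' is reserved", call. = FALSE)
  }
  ann <- data.frame(protein = as.character(protein), gene = as.character(gene),
                    isoform = as.character(isoform),
                    canonical = as.logical(canonical),
                    stringsAsFactors = FALSE)
  ann$domains <- domains
  g_per_p <- tapply(ann$gene, ann$protein, function(g) length(unique(g)))
  if (any(g_per_p > 1L)) {
    stop("protein '", names(g_per_p)[which(g_per_p > 1L)[1L]],
         "' mapped to more than one gene", call. = FALSE)
  }
  if (anyDuplicated(ann$isoform)) {
    stop("duplicate isoform identifiers in annotation", call. = FALSE)
  }
  can_per_p <- tapply(ann$canonical, ann$protein, sum)
  if (any(can_per_p != 1L)) {
    stop("every protein needs exactly one canonical isoform", call. = FALSE)
  }
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Read a protein domain annotation table
#'
#' Rows are
#' `protein<TAB>gene<TAB>isoform<TAB>comma-separated-domains[<TAB>canonical-flag]`;
#' an empty domain field means the isoform has no annotated domains. Without
#' a flag column the first isoform listed per protein is taken as canonical.
#'
#' @param path Path to a plain or gzipped TSV.
#' @return A [domain_annotation].
#' @export
read_domain_annotation <- function(path) {
  tsv <- read_tsv_fields(path)
  nf <- lengths(tsv$fields)
  if (any(nf < 4L)) {
    i <- which(nf < 4L)[1L]
    stop("expected >= 4 tab-separated columns at line ", tsv$lineno[i],
         " of ", path, call. = FALSE)
  }
  protein <- vapply(tsv$fields, `[`, "", 1L)
  gene <- vapply(tsv$fields, `[`, "", 2L)
  isoform <- vapply(tsv$fields, `[`, "", 3L)
  dom_raw <- vapply(tsv$fields, `[`, "", 4L)
  domains <- lapply(dom_raw, function(d) {
    if (is.na(d) || !nzchar(d)) character() else strsplit(d, ",", fixed = TRUE)[[1L]]
  })
  if (any(nf >= 5L)) {
    flag <- vapply(tsv$fields, function(f) if (length(f) >= 5L) f[5L] else "0", "")
    canonical <- flag %in% c("1", "TRUE", "true", "yes")
  } else {
    canonical <- !duplicated(protein)
  }
  domain_annotation(protein, gene, isoform, domains, canonical)
}

#' @rdname read_domain_annotation
#' @param ann A [domain_annotation].
#' @export
write_domain_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "domain_annotation"))
  ord <- order(ann$protein, !ann$canonical, ann$isoform)
  ann <- ann[ord, , drop = FALSE]
  lines <- paste(ann$protein, ann$gene, ann$isoform,
                 vapply(ann$domains, paste, "", collapse = ","),
                 as.integer(ann$canonical), sep = "\t")
  write_lines_to(lines, path)
}

#' Construct a domain-domain interaction library
#'
#' A set of unordered domain-family pairs documented to interact; a family
#' may interact with itself. Pairs are canonically ordered and de-duplicated.
#'
#' @param a,b Character vectors of family names (pairwise).
#' @return An object of class `ddi_library` (a data.frame with columns `a`,
#'   `b`, canonically ordered).
#' @export
ddi_library <- function(a = character(), b = character()) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (any(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))) {
    stop("domain family names must be non-empty", call. = FALSE)
  }
  if (any(grepl("[|\t]", c(a, b)))) {
    stop("domain family names may not contain '|' or tab", call. = FALSE)
  }
  swap <- a > b
  pairs <- data.frame(a = ifelse(swap, b, a), b = ifelse(swap, a, b),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("ddi_library", "data.frame")
  pairs
}

ddi_keys <- function(lib) paste(lib$a, lib$b, sep = "|")

#' Read / write a domain-domain interaction library
#'
#' Rows are `familyA<TAB>familyB`; orientation is irrelevant and duplicates
#' collapse to one canonical pair.
#'
#' @param path Path to a plain or gzipped TSV.
#' @return A [ddi_library] (reader) or `path` (writer).
#' @export
read_ddi_library <- function(path) {
  tsv <- read_tsv_fields(path)
  nf <- lengths(tsv$fields)
  if (any(nf < 2L)) {
    i <- which(nf < 2L)[1L]
    stop("expected 2 tab-separated columns at line ", tsv$lineno[i],
         " of ", path, call. = FALSE)
  }
  ddi_library(vapply(tsv$fields, `[`, "", 1L),
              vapply(tsv$fields, `[`, "", 2L))
}

#' @rdname read_ddi_library
#' @param lib A [ddi_library].
#' @export
write_ddi_library <- function(lib, path) {
  stopifnot(inherits(lib, "ddi_library"))
  write_lines_to(paste(lib$a, lib$b, sep = "\t"), path)
}
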