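## Readers and writers for the plain-text interchange formats the pipeline
## consumes: BED6 (tags, motif sites), BED12 / refFlat (gene models), GMT
## (gene sets), BEDPE (chromatin loops), bedGraph (signal tracks), and TSV
## (GRN edges, TF lists, differential-expression tables).  All on-disk
## coordinates are 0-based half-open (refFlat txStart/txEnd included); in
## memory everything is a 1-based closed GRanges.  Readers reject malformed
## records with the offending line number -- they never skip silently.

read_body_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(body, min_fields, format, path) {
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < min_fields)) {
    i <- which(n < min_fields)[1]
    stop(sprintf("%s: malformed %s record at line %d (%d field(s), need >= %d)",
                 path, format, body$lineno[i], n[i], min_fields))
  }
  fields
}

field_col <- function(fields, j) vapply(fields, `[[`, character(1), j)

as_coord <- function(x, body, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) | v != floor(v) | v < 0)) {
    i <- which(is.na(v) | v != floor(v) | v < 0)[1]
    stop(sprintf("%s: invalid %s coordinate '%s' at line %d",
                 path, what, x[i], body$lineno[i]))
  }
  v
}

#' Read aligned sequencing tags from a BED6 file
#'
#' One interval per mapped read.  The strand column is required because read
#' extension is strand-directed; a `.` strand is an error.
#'
#' @param path path to a tab-delimited BED6 file (`#` comment lines ignored).
#' @param layout optional [genome_layout()]; when supplied, coordinates are
#'   bounds-checked and seqlengths attached.
#' @return A `GRanges`, one range per read, input order preserved, with an
#'   attribute-free length equal to the mapped-read count used for depth
#'   normalization.
#' @export
read_tags_bed <- function(path, layout = NULL) {
  body <- read_body_lines(path)
  if (!length(body$lines)) {
    gr <- GRanges()
    return(if (is.null(layout)) gr else with_layout(gr, layout))
  }
  fields <- split_fields(body, 6L, "BED6", path)
  chrom <- field_col(fields, 1)
  s <- as_coord(field_col(fields, 2), body, path, "start")
  e <- as_coord(field_col(fields, 3), body, path, "end")
  if (any(e <= s)) {
    i <- which(e <= s)[1]
    stop(sprintf("%s: end <= start at line %d", path, body$lineno[i]))
  }
  strand <- field_col(fields, 6)
  if (any(!strand %in% c("+", "-"))) {
    i <- which(!strand %in% c("+", "-"))[1]
    stop(sprintf("%s: missing or invalid strand '%s' at line %d (read extension requires strand)",
                 path, strand[i], body$lineno[i]))
  }
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = strand,
                name = field_col(fields, 4))
  if (!is.null(layout)) {
    check_within_layout(gr, layout, "read")
    gr <- with_layout(gr, layout)
  }
  gr
}

#' Write intervals to a BED6 file
#'
#' @param gr a `GRanges`; `name` and `score` metadata columns are used when
#'   present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  nm <- if (!is.null(gr$name)) gr$name else sprintf("r%d", seq_along(gr))
  sc <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
                   end = end(gr), name = nm, score = sc, strand = st)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Supports two dialects: `"bed12"` (0-based half-open; columns 1-6 used,
#' exon blocks ignored) and `"refflat"` (geneName, transcript, chrom, strand,
#' txStart, txEnd, ...).  Isoforms sharing a `gene_id` on one chromosome and
#' strand are collapsed to their maximal genomic span, so ranking operates at
#' gene level; a `gene_id` recurring on different chromosomes or strands is
#' an error.
#'
#' @param path input file.
#' @param dialect `"bed12"` or `"refflat"`.
#' @param layout optional [genome_layout()] for bounds checking.
#' @return A `GRanges` with metadata columns `gene_id`, `tss`, `tts`
#'   (strand-aware 1-based positions), sorted by coordinate.
#' @export
read_gene_models <- function(path, dialect = c("bed12", "refflat"),
                             layout = NULL) {
  dialect <- match.arg(dialect)
  body <- read_body_lines(path)
  if (!length(body$lines)) {
    gr <- GRanges()
    gr$gene_id <- character(0)
    return(gr)
  }
  if (dialect == "bed12") {
    fields <- split_fields(body, 6L, "BED12", path)
    id <- field_col(fields, 4)
    chrom <- field_col(fields, 1)
    s <- as_coord(field_col(fields, 2), body, path, "start") + 1
    e <- as_coord(field_col(fields, 3), body, path, "end")
    st <- field_col(fields, 6)
  } else {
    fields <- split_fields(body, 6L, "refFlat", path)
    id <- field_col(fields, 1)
    chrom <- field_col(fields, 3)
    st <- field_col(fields, 4)
    ## refFlat txStart is 0-based, txEnd exclusive (UCSC convention)
    s <- as_coord(field_col(fields, 5), body, path, "txStart") + 1
    e <- as_coord(field_col(fields, 6), body, path, "txEnd")
  }
  if (any(e < s)) {
    i <- which(e < s)[1]
    stop(sprintf("%s: end <= start at line %d", path, body$lineno[i]))
  }
  if (any(!st %in% c("+", "-"))) {
    i <- which(!st %in% c("+", "-"))[1]
    stop(sprintf("%s: gene strand must be + or - at line %d", path, body$lineno[i]))
  }
  ## collapse isoforms of one gene to the maximal span
  key <- paste(id, chrom, st, sep = "\r")
  if (anyDuplicated(id[!duplicated(key)]))
    stop(sprintf("%s: gene_id '%s' recurs on different chromosomes or strands",
                 path, id[!duplicated(key)][duplicated(id[!duplicated(key)])][1]))
  smin <- tapply(s, key, min)
  emax <- tapply(e, key, max)
  u <- names(smin)
  parts <- do.call(rbind, strsplit(u, "\r", fixed = TRUE))
  gr <- GRanges(parts[, 2], IRanges(as.numeric(smin), as.numeric(emax)),
                strand = parts[, 3])
  gr$gene_id <- parts[, 1]
  if (!is.null(layout)) {
    check_within_layout(gr, layout, "gene")
    gr <- with_layout(gr, layout)
  }
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  gr$tss <- unname(gene_tss(gr))
  gr$tts <- unname(gene_tts(gr))
  gr
}

#' Write gene models as BED12
#'
#' Each collapsed gene is emitted as a single-block BED12 record.
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param path output path.
#' @export
write_genes_bed12 <- function(genes, path) {
  s0 <- start(genes) - 1
  df <- data.frame(chrom = as.character(seqnames(genes)), start = s0,
                   end = end(genes), name = genes$gene_id, score = 0,
                   strand = as.character(strand(genes)),
                   thickStart = s0, thickEnd = end(genes), rgb = 0,
                   blockCount = 1, blockSizes = width(genes), blockStarts = 0)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is ragged tab-delimited text: set name, description, then one gene id
#' per remaining field.
#'
#' @param path input file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  body <- read_body_lines(path)
  if (!length(body$lines)) return(structure(list(), names = character(0)))
  fields <- split_fields(body, 3L, "GMT", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- field_col(fields, 1)
  if (anyDuplicated(names(sets)))
    stop(sprintf("%s: duplicated gene-set name '%s'", path,
                 names(sets)[duplicated(names(sets))][1]))
  if (any(lengths(sets) == 0)) {
    i <- which(lengths(sets) == 0)[1]
    stop(sprintf("%s: gene set '%s' has no members (line %d)",
                 path, names(sets)[i], body$lineno[i]))
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' @param path BEDPE file (chrom1, start1, end1, chrom2, start2, end2, ...).
#' @param layout optional [genome_layout()].
#' @return A `loop_set`: list with `GRanges` elements `anchor1` and
#'   `anchor2`, pair order normalized by coordinate.
#' @export
read_bedpe <- function(path, layout = NULL) {
  body <- read_body_lines(path)
  if (!length(body$lines))
    return(loop_set(GRanges(), GRanges()))
  fields <- split_fields(body, 6L, "BEDPE", path)
  a1 <- GRanges(field_col(fields, 1),
                IRanges(as_coord(field_col(fields, 2), body, path, "start1") + 1,
                        as_coord(field_col(fields, 3), body, path, "end1")))
  a2 <- GRanges(field_col(fields, 4),
                IRanges(as_coord(field_col(fields, 5), body, path, "start2") + 1,
                        as_coord(field_col(fields, 6), body, path, "end2")))
  if (any(end(a1) < start(a1)) || any(end(a2) < start(a2)))
    stop(sprintf("%s: malformed anchor coordinates", path))
  if (!is.null(layout)) {
    check_within_layout(a1, layout, "loop anchor")
    check_within_layout(a2, layout, "loop anchor")
  }
  loop_set(a1, a2)
}

#' Construct a loop set from two anchor `GRanges`
#'
#' @param anchor1,anchor2 `GRanges` of equal length; each pair is one loop.
#'   Pairs are stored with the lower-coordinate anchor first.
#' @export
loop_set <- function(anchor1, anchor2) {
  if (length(anchor1) != length(anchor2))
    stop("anchor1 and anchor2 must have equal length")
  swap <- as.character(seqnames(anchor1)) > as.character(seqnames(anchor2)) |
    (as.character(seqnames(anchor1)) == as.character(seqnames(anchor2)) &
       start(anchor1) > start(anchor2))
  if (any(swap)) {
    tmp <- anchor1[swap]
    anchor1[swap] <- anchor2[swap]
    anchor2[swap] <- tmp
  }
  structure(list(anchor1 = anchor1, anchor2 = anchor2), class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d loop(s)\n", length(x$anchor1)))
  invisible(x)
}

#' @rdname read_bedpe
#' @param loops a `loop_set`.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(
    c1 = as.character(seqnames(loops$anchor1)), s1 = start(loops$anchor1) - 1,
    e1 = end(loops$anchor1),
    c2 = as.character(seqnames(loops$anchor2)), s2 = start(loops$anchor2) - 1,
    e2 = end(loops$anchor2),
    name = sprintf("loop%d", seq_along(loops$anchor1)), score = 0)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two/three-column GRN edge list
#'
#' @param path TSV with columns source, target and an optional weight;
#'   a header line is detected and skipped.
#' @return data.frame with columns `source`, `target`.
#' @export
read_grn_edges <- function(path) {
  body <- read_body_lines(path)
  if (!length(body$lines)) return(data.frame(source = character(0), target = character(0)))
  fields <- split_fields(body, 2L, "edge-list", path)
  df <- data.frame(source = field_col(fields, 1), target = field_col(fields, 2))
  if (identical(tolower(df$source[1]), "source")) df <- df[-1, , drop = FALSE]
  df
}

#' Read a transcription-factor list (one gene id per line)
#' @param path input file.
#' @return character vector.
#' @export
read_tf_list <- function(path) {
  body <- read_body_lines(path)
  unique(trimws(body$lines))
}

#' Read a differential-expression table
#'
#' Expects a header with columns `gene_id`, `log2fc`, `qvalue` and one or
#' more `fpkm_*` sample columns (or a single `fpkm_max`).
#'
#' @param path TSV file.
#' @return data.frame with an added `fpkm_max` column.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("gene_id", "log2fc", "qvalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  fcols <- grep("^fpkm", names(df), value = TRUE)
  if (!length(fcols)) stop(sprintf("%s: no fpkm_* column", path))
  if (any(df$qvalue < 0 | df$qvalue > 1))
    stop(sprintf("%s: q values must lie in [0,1]", path))
  if (any(as.matrix(df[fcols]) < 0))
    stop(sprintf("%s: FPKM values must be >= 0", path))
  df$fpkm_max <- do.call(pmax, df[fcols])
  df
}
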