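#' Read Visium-style counts and spot positions
#'
#' Reads a MatrixMarket triplet count matrix with its `features.tsv` /
#' `barcodes.tsv` companions plus a tissue-positions table, and returns the
#' aligned in-memory pair: a spots-by-genes sparse count matrix and a
#' [spot_table()]. Both the headered (v2) and headerless (v1) dialects of
#' the positions file are accepted; the dialect is detected from the first
#' row.
#'
#' @param counts_path directory containing `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv`.
#' @param positions_path path to a `tissue_positions` CSV with columns
#'   barcode, in_tissue, array_row, array_col, pxl_row, pxl_col.
#' @return A list with elements `counts` (a `dgCMatrix`, spots in rows,
#'   genes in columns) and `spots` (a `spot_table`), barcodes aligned 1:1.
#'   Spots present in the matrix but absent from the positions table are
#'   dropped with a message.
#' @seealso [write_visium()]
#' @export
read_visium <- function(counts_path, positions_path) {
  mtx <- file.path(counts_path, "matrix.mtx")
  feat <- file.path(counts_path, "features.tsv")
  bc <- file.path(counts_path, "barcodes.tsv")
  for (f in c(mtx, feat, bc, positions_path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  m <- Matrix::readMM(mtx)                       # genes x spots on disk
  features <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  genes <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  barcodes <- readLines(bc)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop("matrix dimensions (", nrow(m), "x", ncol(m),
         ") do not match features/barcodes (", length(genes), "/", length(barcodes), ")")
  }
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  counts <- Matrix::t(m)                         # spots x genes in memory
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(barcodes, genes)

  pos <- read_positions(positions_path)
  if (anyDuplicated(pos$spot_id)) stop("duplicated barcode in positions file")
  key <- paste(pos$array_row, pos$array_col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (array_row, array_col) pair in positions file: (",
         sub(" ", ", ", dup), ")")
  }
  keep <- barcodes %in% pos$spot_id
  if (!any(keep)) {
    stop("no barcode overlap between counts and positions; first offenders: ",
         paste(utils::head(barcodes[!keep], 5), collapse = ", "))
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("dropping ", n_drop, " spot(s) absent from the positions table")
    counts <- counts[keep, , drop = FALSE]
    barcodes <- barcodes[keep]
  }
  pos <- pos[match(barcodes, pos$spot_id), , drop = FALSE]
  rownames(pos) <- NULL
  st <- validate_spot_table(pos)
  list(counts = counts, spots = st)
}

read_positions <- function(path) {
  first <- readLines(path, n = 1)
  headered <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(path, header = headered, stringsAsFactors = FALSE)
  if (ncol(pos) < 6) stop("positions file must have 6 columns, found ", ncol(pos))
  pos <- pos[, 1:6]
  # v1/v2 column order: barcode, in_tissue, array_row, array_col, pxl_row, pxl_col
  names(pos) <- c("spot_id", "in_tissue", "array_row", "array_col", "pxl_row", "pxl_col")
  data.frame(
    spot_id = as.character(pos$spot_id),
    array_row = as.integer(pos$array_row),
    array_col = as.integer(pos$array_col),
    x = as.numeric(pos$pxl_col),
    y = as.numeric(pos$pxl_row),
    in_tissue = as.integer(pos$in_tissue) == 1L,
    stringsAsFactors = FALSE
  )
}

#' Write Visium-style artifacts to a directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, genes in rows),
#' `features.tsv`, `barcodes.tsv` and a headered `tissue_positions.csv`.
#' The pair round-trips bit-exactly through [read_visium()] for counts and
#' integer fields; planar coordinates round-trip at full double precision.
#'
#' @param counts spots-by-genes count matrix (sparse or dense) with
#'   dimnames.
#' @param spots a [spot_table()] matching the matrix rows.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_visium <- function(counts, spots, dir) {
  spots <- validate_spot_table(spots)
  if (nrow(spots) == 0) stop("refusing to write a 0-spot dataset")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry spot and gene dimnames")
  }
  if (!identical(rownames(counts), spots$spot_id)) {
    stop("count matrix rows must match spot table barcodes in order")
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir)
  }

  tm <- methods::as(Matrix::t(counts), "TsparseMatrix")  # genes x spots
  ord <- order(tm@j, tm@i)
  header <- c("%%MatrixMarket matrix coordinate integer general",
              paste(nrow(tm), ncol(tm), length(tm@x)))
  body <- sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L, as.integer(tm@x[ord]))
  writeLines(c(header, body), file.path(dir, "matrix.mtx"))

  genes <- colnames(counts)
  utils::write.table(
    data.frame(genes, genes, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(spots$spot_id, file.path(dir, "barcodes.tsv"))

  pos <- data.frame(
    barcode = spots$spot_id,
    in_tissue = as.integer(spots$in_tissue),
    array_row = spots$array_row,
    array_col = spots$array_col,
    pxl_row_in_fullres = num_full(spots$y),
    pxl_col_in_fullres = num_full(spots$x),
    stringsAsFactors = FALSE)
  utils::write.table(pos, file.path(dir, "tissue_positions.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## full-precision decimal rendering so doubles survive a text round-trip
num_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

#' Read named signature gene sets
#'
#' Accepts either the long two-column form (`name<TAB>gene`, one gene per
#' line) or the wide one-set-per-line form (`name<TAB>gene1<TAB>gene2...`).
#' Gene order is preserved; duplicate genes within a set are dropped with a
#' warning.
#'
#' @param path path to a signature TSV.
#' @return Named list of character vectors (one element per signature).
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("signature file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) stop("each signature line needs a name and at least one gene")
  if (all(nf == 2)) {
    nm <- vapply(fields, `[`, character(1), 1)
    gene <- vapply(fields, `[`, character(1), 2)
    sets <- split(gene, factor(nm, levels = unique(nm)))
    sets <- lapply(sets, as.character)
  } else {
    sets <- stats::setNames(lapply(fields, function(f) f[-1]),
                            vapply(fields, `[`, character(1), 1))
  }
  out <- lapply(names(sets), function(nm) {
    g <- sets[[nm]]
    if (anyDuplicated(g)) {
      warning("signature '", nm, "' contains duplicated genes; deduplicating")
      g <- unique(g)
    }
    if (!length(g)) stop("signature '", nm, "' is empty")
    g
  })
  stats::setNames(out, names(sets))
}

#' Write signature gene sets in the long two-column form
#'
#' @param sigs named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  stopifnot(is.list(sigs), !is.null(names(sigs)))
  df <- data.frame(
    name = rep(names(sigs), lengths(sigs)),
    gene = unlist(sigs, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
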