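#' Construct a multi-species pseudo-bulk expression atlas
#'
#' A pseudo-bulk atlas holds, per species, a cell type x gene matrix of
#' transcripts-per-million (TPM) together with the matching matrix of
#' fractions of cells expressing each gene, plus cell-type metadata
#' (fetal/maternal compartment, cell-type class, cell counts). Genes are
#' species-native identifiers; cross-species unification onto the human
#' catalog happens explicitly via [humanize_atlas()].
#'
#' @param metadata Data frame with columns `species`, `cell_type`,
#'   `compartment` (`"fetal"`/`"maternal"`), `cell_class`, `n_cells` and
#'   optionally `replicate`.
#' @param tpm,frac_expr Named lists (one element per species) of numeric
#'   matrices with cell types as rows and genes as columns. Each TPM row
#'   must sum to 1e6 (relative tolerance 1e-6) and `frac_expr` must lie in
#'   \[0, 1\]; the two matrices of a species must share dimnames.
#' @return An object of class `pseudobulk_atlas`.
#' @export
pseudobulk_atlas <- function(metadata, tpm, frac_expr) {
  atlas <- structure(list(metadata = metadata, tpm = tpm, frac_expr = frac_expr),
                     class = "pseudobulk_atlas")
  validate_atlas(atlas)
}

#' @export
print.pseudobulk_atlas <- function(x, ...) {
  cat(sprintf("pseudobulk_atlas: %d species, %d cell types\n",
              length(x$tpm), nrow(x$metadata)))
  for (sp in names(x$tpm)) {
    cat(sprintf("  %s: %d cell types x %d genes\n", sp,
                nrow(x$tpm[[sp]]), ncol(x$tpm[[sp]])))
  }
  invisible(x)
}

#' Validate a pseudo-bulk atlas
#'
#' Enforces the atlas invariants: unique (species, cell_type) metadata rows,
#' known compartment labels, `n_cells >= 1` for expression-bearing cell
#' types, TPM rows summing to 1e6 within relative tolerance 1e-6, fractions
#' in \[0, 1\], and identical indexing of the TPM and fraction matrices.
#' Cell types with fewer than `min_cells` cells trigger a warning (they are
#' kept; drop upstream if desired).
#'
#' @param atlas A `pseudobulk_atlas`.
#' @param min_cells Warning floor for cells per cell type (default 10).
#' @return The atlas, invisibly. Errors on violation.
#' @export
validate_atlas <- function(atlas, min_cells = 10) {
  md <- atlas$metadata
  need <- c("species", "cell_type", "compartment", "cell_class", "n_cells")
  if (!all(need %in% names(md))) {
    stop("atlas metadata format error: missing column(s) ",
         paste(setdiff(need, names(md)), collapse = ", "))
  }
  key <- paste(md$species, md$cell_type, sep = "\r")
  if (anyDuplicated(key)) stop("atlas integrity error: duplicate (species, cell_type)")
  if (!all(md$compartment %in% c("fetal", "maternal"))) {
    stop("atlas integrity error: compartment must be 'fetal' or 'maternal'")
  }
  if (any(md$n_cells < 1)) stop("atlas integrity error: n_cells must be >= 1")
  if (any(md$n_cells < min_cells)) {
    warning(sum(md$n_cells < min_cells),
            " cell type(s) have fewer than ", min_cells, " cells")
  }
  if (!setequal(names(atlas$tpm), unique(md$species)) ||
      !setequal(names(atlas$frac_expr), unique(md$species))) {
    stop("atlas integrity error: expression matrices must cover exactly the metadata species")
  }
  for (sp in names(atlas$tpm)) {
    tp <- atlas$tpm[[sp]]; fr <- atlas$frac_expr[[sp]]
    if (!identical(dimnames(tp), dimnames(fr))) {
      stop("atlas integrity error: tpm and frac_expr indexing differs for ", sp)
    }
    if (!setequal(rownames(tp), md$cell_type[md$species == sp])) {
      stop("atlas integrity error: cell types of ", sp, " do not match metadata")
    }
    if (any(tp < 0)) stop("atlas integrity error: negative TPM in ", sp)
    rs <- rowSums(tp)
    if (any(abs(rs - 1e6) > 1e-6 * 1e6)) {
      stop("atlas integrity error: TPM rows of ", sp, " do not sum to 1e6")
    }
    if (any(fr < 0 | fr > 1)) {
      stop("atlas integrity error: frac_expr outside [0, 1] in ", sp)
    }
  }
  invisible(atlas)
}

#' Construct a cell-level count matrix
#'
#' @param counts Sparse (or dense) cell x gene matrix of non-negative
#'   integer counts; rownames are cell identifiers, colnames genes.
#' @param cell_meta Data frame with columns `cell_id`, `species`,
#'   `cell_type` and optionally `replicate`, one row per cell, matching
#'   `rownames(counts)`.
#' @return An object of class `cell_level_matrix`.
#' @export
cell_level_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  need <- c("cell_id", "species", "cell_type")
  if (!all(need %in% names(cell_meta))) {
    stop("cell_meta format error: missing column(s) ",
         paste(setdiff(need, names(cell_meta)), collapse = ", "))
  }
  if (!("replicate" %in% names(cell_meta))) cell_meta$replicate <- "rep1"
  if (is.null(rownames(counts))) rownames(counts) <- cell_meta$cell_id
  if (!identical(rownames(counts), as.character(cell_meta$cell_id))) {
    stop("cell_meta integrity error: cell_id must match count matrix rows")
  }
  if (any(counts@x < 0)) stop("counts integrity error: negative counts")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_level_matrix")
}

#' @export
print.cell_level_matrix <- function(x, ...) {
  cat(sprintf("cell_level_matrix: %d cells x %d genes (%d cell types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' Fraction of cells expressing each gene, per cell type
#'
#' For each (cell type, gene), the fraction of that type's cells with a
#' non-zero count. This is the quantity thresholded (at 20% by default
#' elsewhere) to call a gene "on" in a cell type.
#'
#' @param cells A [cell_level_matrix()].
#' @return Numeric matrix, cell types x genes, values in \[0, 1\].
#' @export
fraction_expressing <- function(cells) {
  stopifnot(inherits(cells, "cell_level_matrix"))
  ct <- factor(cells$cell_meta$cell_type)
  if (any(table(ct) < 1)) stop("every cell type needs at least one cell")
  ind <- Matrix::sparseMatrix(i = as.integer(ct), j = seq_along(ct), x = 1,
                              dims = c(nlevels(ct), length(ct)),
                              dimnames = list(levels(ct), NULL))
  nonzero <- cells$counts
  nonzero@x <- rep(1, length(nonzero@x))
  num <- as.matrix(ind %*% nonzero)
  cnt <- table(ct)
  num / as.numeric(cnt[rownames(num)])
}

#' Log-normalized counts per 10,000
#'
#' Per-cell library-size normalization to 10,000 counts followed by a
#' natural-log `log(1 + x)` transform, the common single-cell convention.
#' Used to weight signalling-graph edges after pseudo-bulk averaging.
#'
#' @param cells A [cell_level_matrix()].
#' @param scale Library size target (default 1e4).
#' @return Sparse matrix of the same shape as the counts.
#' @export
lognorm_cp10k <- function(cells, scale = 1e4) {
  stopifnot(inherits(cells, "cell_level_matrix"))
  tot <- Matrix::rowSums(cells$counts)
  if (any(tot <= 0)) stop("cells with zero total counts: ",
                          paste(utils::head(rownames(cells$counts)[tot <= 0]),
                                collapse = ", "))
  out <- Matrix::Diagonal(x = scale / tot) %*% cells$counts
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(cells$counts)
  out
}

#' Pseudo-bulk TPM from cell-level counts
#'
#' Sums counts over the cells of each cell type and rescales each row to
#' 1e6 (transcripts per million over the gene universe of the matrix).
#'
#' @param cells A [cell_level_matrix()].
#' @return Numeric matrix, cell types x genes, rows summing to 1e6.
#' @export
pseudobulk_tpm <- function(cells) {
  agg <- rowsum_by_celltype(cells$counts, cells$cell_meta$cell_type)
  sweep(agg, 1, rowSums(agg), "/") * 1e6
}

#' Per-cell-type mean of log-normalized expression
#'
#' @param cells A [cell_level_matrix()].
#' @return Dense matrix, cell types x genes, of mean [lognorm_cp10k()]
#'   values.
#' @export
mean_lognorm_by_celltype <- function(cells) {
  ln <- lognorm_cp10k(cells)
  agg <- rowsum_by_celltype(ln, cells$cell_meta$cell_type)
  cnt <- table(cells$cell_meta$cell_type)
  agg / as.numeric(cnt[rownames(agg)])
}

rowsum_by_celltype <- function(m, cell_type) {
  ct <- factor(cell_type)
  ind <- Matrix::sparseMatrix(i = as.integer(ct), j = seq_len(length(ct)), x = 1,
                              dims = c(nlevels(ct), length(ct)),
                              dimnames = list(levels(ct), NULL))
  as.matrix(ind %*% m)
}

#' Read / write a pseudo-bulk atlas directory
#'
#' On-disk format: a directory holding `metadata.tsv` (the cell-type
#' metadata table) and one long-format `expression_<species>.tsv` per
#' species with columns `cell_type`, `gene`, `tpm`, `frac_expr`. Values are
#' written with 17 significant digits so that a write/read round-trip is
#' bit-identical.
#'
#' @param path Directory to read from / write to.
#' @return `read_pseudobulk_atlas()` returns a validated
#'   [pseudobulk_atlas()]; `write_pseudobulk_atlas()` returns `path`
#'   invisibly.
#' @export
read_pseudobulk_atlas <- function(path) {
  md_file <- file.path(path, "metadata.tsv")
  if (!file.exists(md_file)) stop("atlas format error: missing ", md_file)
  md <- utils::read.delim(md_file, stringsAsFactors = FALSE)
  tpm <- list(); frac <- list()
  for (sp in unique(md$species)) {
    f <- file.path(path, paste0("expression_", sp, ".tsv"))
    if (!file.exists(f)) stop("atlas format error: missing ", f)
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    need <- c("cell_type", "gene", "tpm", "frac_expr")
    if (!all(need %in% names(tab))) {
      stop("atlas format error in ", f, ": missing column(s) ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    if (anyDuplicated(paste(tab$cell_type, tab$gene, sep = "\r"))) {
      stop("atlas integrity error in ", f, ": duplicate (cell_type, gene) row")
    }
    cts <- unique(tab$cell_type); genes <- unique(tab$gene)
    tp <- matrix(0, length(cts), length(genes), dimnames = list(cts, genes))
    fr <- tp
    i <- cbind(match(tab$cell_type, cts), match(tab$gene, genes))
    tp[i] <- tab$tpm; fr[i] <- tab$frac_expr
    tpm[[sp]] <- tp; frac[[sp]] <- fr
  }
  pseudobulk_atlas(md, tpm, frac)
}

#' @rdname read_pseudobulk_atlas
#' @param atlas A [pseudobulk_atlas()].
#' @export
write_pseudobulk_atlas <- function(atlas, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_tsv(atlas$metadata, file.path(path, "metadata.tsv"))
  for (sp in names(atlas$tpm)) {
    tp <- atlas$tpm[[sp]]
    long <- data.frame(
      cell_type = rep(rownames(tp), times = ncol(tp)),
      gene = rep(colnames(tp), each = nrow(tp)),
      tpm = fmt_num(as.vector(tp)),
      frac_expr = fmt_num(as.vector(atlas$frac_expr[[sp]])),
      stringsAsFactors = FALSE)
    write_tsv(long, file.path(path, paste0("expression_", sp, ".tsv")))
  }
  invisible(path)
}

#' Read / write cell-level counts in MatrixMarket form
#'
#' The directory layout mirrors the common single-cell convention:
#' `matrix.mtx` (cells x genes), `features.tsv` (gene identifiers) and
#' `barcodes.tsv` (per-cell metadata: `cell_id`, `species`, `cell_type`,
#' `replicate`).
#'
#' @param path Directory to read from / write to.
#' @return `read_cell_matrix()` returns a [cell_level_matrix()].
#' @export
read_cell_matrix <- function(path) {
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  genes <- utils::read.delim(file.path(path, "features.tsv"),
                             stringsAsFactors = FALSE)
  meta <- utils::read.delim(file.path(path, "barcodes.tsv"),
                            stringsAsFactors = FALSE)
  dimnames(m) <- list(meta$cell_id, genes$gene)
  cell_level_matrix(m, meta)
}

#' @rdname read_cell_matrix
#' @param cells A [cell_level_matrix()].
#' @export
write_cell_matrix <- function(cells, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$counts, file.path(path, "matrix.mtx"))
  write_tsv(data.frame(gene = colnames(cells$counts)),
            file.path(path, "features.tsv"))
  write_tsv(cells$cell_meta, file.path(path, "barcodes.tsv"))
  invisible(path)
}

# Deterministic TSV writer (fixed eol, no quoting surprises).
write_tsv <- function(df, file) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(file)
}

# Full-precision, locale-independent number formatting.
fmt_num <- function(x) {
  if (is.character(x)) return(x)
  out <- formatC(x, format = "g", digits = 17)
  trimws(out)
}
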