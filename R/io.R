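#' Write a matrix in Matrix-Market format
#'
#' Matrices are stored genes x cells on disk; the orientation is recorded in
#' a header comment line.
#'
#' @param x Numeric matrix (genes x cells).
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_mtx <- function(x, path) {
  m <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  Matrix::writeMM(m, path)
  lines <- readLines(path)
  writeLines(c(lines[1], "% orientation: genes x cells", lines[-1]), path)
  invisible(path)
}

#' Read a Matrix-Market file as a dense matrix
#'
#' @param path `.mtx` path.
#' @return A dense base matrix.
#' @export
read_mtx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(Matrix::readMM(path))
}

#' Load spliced/unspliced count matrices from disk
#'
#' Reads a pair of Matrix-Market matrices plus a two-column TSV of gene and
#' cell identifiers, validating that the shapes agree.
#'
#' @param spliced_path,unspliced_path Matrix-Market files (genes x cells).
#' @param ids_path TSV with columns `kind` (`gene`/`cell`) and `id`.
#' @return List with matrices `spliced`, `unspliced` and vectors `gene_ids`,
#'   `cell_ids`.
#' @export
load_counts <- function(spliced_path, unspliced_path, ids_path) {
  spliced <- read_mtx(spliced_path)
  unspliced <- read_mtx(unspliced_path)
  if (!all(dim(spliced) == dim(unspliced)))
    stop("shape mismatch: spliced is ", nrow(spliced), "x", ncol(spliced),
         " but unspliced is ", nrow(unspliced), "x", ncol(unspliced),
         call. = FALSE)
  ids <- utils::read.delim(ids_path, stringsAsFactors = FALSE)
  if (!all(c("kind", "id") %in% names(ids)))
    stop("malformed ids file (line 1): expected columns 'kind' and 'id'",
         call. = FALSE)
  gene_ids <- ids$id[ids$kind == "gene"]
  cell_ids <- ids$id[ids$kind == "cell"]
  if (length(gene_ids) != nrow(spliced) || length(cell_ids) != ncol(spliced))
    stop("identifier counts (", length(gene_ids), " genes, ",
         length(cell_ids), " cells) do not match the matrix shape",
         call. = FALSE)
  dimnames(spliced) <- dimnames(unspliced) <- list(gene_ids, cell_ids)
  list(spliced = spliced, unspliced = unspliced,
       gene_ids = gene_ids, cell_ids = cell_ids)
}

#' Serialize a simulated dataset to a directory
#'
#' Writes counts as Matrix-Market, latent time and true velocity as TSV,
#' identifiers as TSV, and a `manifest.txt` of `key=value` pairs recording
#' the full configuration (including the seed).
#'
#' @param sim A `velocity_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "velocity_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx(sim$spliced, file.path(dir, "spliced.mtx"))
  write_mtx(sim$unspliced, file.path(dir, "unspliced.mtx"))
  utils::write.table(sim$latent_time, file.path(dir, "latent_time.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(sim$true_velocity, file.path(dir, "true_velocity.tsv"),
                     sep = "\t", quote = FALSE)
  ids <- rbind(data.frame(kind = "gene", id = sim$gene_ids),
               data.frame(kind = "cell", id = sim$cell_ids))
  utils::write.table(ids, file.path(dir, "ids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- sim$params
  manifest <- c(
    paste0("n_genes=", nrow(sim$spliced)),
    paste0("n_cells=", ncol(sim$spliced)),
    paste0("alpha=", p$alpha), paste0("beta=", p$beta),
    paste0("gamma=", p$gamma), paste0("t_switch=", p$t_switch),
    paste0("t_max=", p$t_max),
    paste0("noise_level=", sim$noise$noise_level),
    paste0("sigma_spliced=", sim$noise$sigma_spliced),
    paste0("sigma_unspliced=", sim$noise$sigma_unspliced),
    paste0("seed=", sim$seed)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Export a k-NN graph as an edge list
#'
#' Three-column TSV (`cell_i`, `cell_j`, `weight`) of the non-zero entries
#' of the column-normalized weight matrix.
#'
#' @param graph A `knn_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "knn_graph"))
  W <- methods::as(graph$W, "TsparseMatrix")
  edges <- data.frame(cell_i = W@i + 1L, cell_j = W@j + 1L, weight = W@x)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import a k-NN graph edge list
#'
#' @param path TSV written by [write_graph()].
#' @param n Number of cells.
#' @return A sparse n x n weight matrix.
#' @export
read_graph <- function(path, n) {
  edges <- utils::read.delim(path)
  Matrix::sparseMatrix(i = edges$cell_i, j = edges$cell_j, x = edges$weight,
                       dims = c(n, n))
}
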