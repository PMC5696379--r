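#' Read a gene x sample count matrix
#'
#' Accepts either a 10X-style directory (Matrix Market `matrix.mtx` plus a
#' features/genes TSV and a `barcodes.tsv`) or a plain dense TSV whose first
#' column holds gene ids and whose header row holds sample ids. The MTX
#' triplet is expanded to dense counts with missing entries set to 0.
#'
#' @param path path to the MTX directory or the TSV file
#' @param format `"auto"` (directory => mtx_dir, file => tsv), `"mtx_dir"`
#'   or `"tsv"`
#' @param lengths_path optional TSV (gene id, length_bp) attaching gene
#'   lengths; genes absent from the file get `NA`-free handling by erroring
#' @return a [count_matrix]
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "tsv"),
                        lengths_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx_dir" else "tsv"
  cm <- if (format == "mtx_dir") read_counts_mtx_dir(path) else read_counts_tsv(path)
  if (!is.null(lengths_path)) {
    len <- read_gene_lengths(lengths_path)
    idx <- match(cm$gene_ids, names(len))
    if (anyNA(idx))
      stop("lengths file is missing ", sum(is.na(idx)), " gene ids")
    cm$gene_lengths <- unname(len[idx])
  }
  cm
}

read_counts_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir)
  feat <- Filter(file.exists,
                 file.path(dir, c("features.tsv", "genes.tsv")))
  if (!length(feat)) stop("no features.tsv or genes.tsv in ", dir)
  barc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(barc)) stop("no barcodes.tsv in ", dir)

  header <- readLines(mtx, n = 1)
  if (!grepl("^%%MatrixMarket +matrix +coordinate +(integer|real) +general",
             header))
    stop("malformed MatrixMarket header: ", header)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MTX file: ",
                                         conditionMessage(e)))
  m <- as.matrix(m)
  if (length(m) && any(m != round(m)))
    stop("non-integer entries in MTX counts")

  read_opt <- function(path) {
    if (file.size(path) == 0)
      return(data.frame(V1 = character(0), V2 = character(0)))
    utils::read.delim(path, header = FALSE, colClasses = "character")
  }
  ftab <- read_opt(feat[1])
  btab <- read_opt(barc)
  if (nrow(ftab) != nrow(m))
    stop("features file has ", nrow(ftab), " rows but matrix has ",
         nrow(m), " genes")
  if (nrow(btab) != ncol(m))
    stop("barcodes file has ", nrow(btab), " rows but matrix has ",
         ncol(m), " cells")
  symbols <- if (ncol(ftab) >= 2) ftab[[2]] else ftab[[1]]
  count_matrix(m, gene_ids = ftab[[1]], gene_symbols = symbols,
               sample_ids = btab[[1]])
}

read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (!ncol(tab)) stop("empty count table ", path)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (length(m) && any(m != round(m)))
    stop("non-integer entries in count TSV")
  count_matrix(m, gene_ids = ids, sample_ids = colnames(tab)[-1])
}

#' Write a count_matrix to a 10X-style MTX directory or a dense TSV
#'
#' @param x a [count_matrix]
#' @param path output directory (mtx_dir) or file (tsv)
#' @param format `"mtx_dir"` or `"tsv"`
#' @export
write_counts <- function(x, path, format = c("mtx_dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(x$gene_ids, x$gene_symbols),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(x$sample_ids, file.path(path, "barcodes.tsv"))
    if (!is.null(x$gene_lengths))
      utils::write.table(
        data.frame(x$gene_ids, x$gene_lengths),
        file.path(path, "lengths.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a two-column gene length TSV (id, length_bp)
#'
#' @param path TSV file, no header required (a header line `gene_id` is
#'   tolerated)
#' @return named numeric vector of lengths
#' @export
read_gene_lengths <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           colClasses = c("character", "character"))
  if (nrow(tab) && suppressWarnings(is.na(as.numeric(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]  # header line
  len <- as.numeric(tab[[2]])
  if (any(is.na(len)) || any(len <= 0)) stop("invalid gene lengths in ", path)
  stats::setNames(len, tab[[1]])
}

#' Write records as a UTF-8 TSV with a header row
#'
#' Floating point columns are rendered with 6 significant digits so output
#' files diff cleanly across runs.
#'
#' @param rows a data.frame (possibly with zero rows)
#' @param path output path
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], format = "g", digits = 6))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Read a GMT-style gene set file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file
#' @return a [gene_set_collection]
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", ln)
    nm <- parts[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    sets[[nm]] <- parts[-(1:2)]
  }
  gene_set_collection(sets, provenance = path)
}

#' Write gene sets in GMT format
#'
#' @param x a [gene_set_collection] or [signature_set]
#' @param path output file
#' @param description description field for every line (default ".")
#' @export
write_gene_sets <- function(x, path, description = ".") {
  sets <- x$sets
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Read interaction, ortholog and function tables for the network stage
#'
#' Edges are deduplicated as unordered pairs and self-loops dropped. The
#' ortholog map may be one-to-many. Function tokens must be `ST` (signal
#' transduction) or `TF` (transcription factor activity); a gene may carry
#' both (two rows).
#'
#' @param edges_path TSV with two columns of human gene ids (header optional
#'   as `from`/`to`)
#' @param orthologs_path TSV mouse id -> human id (header optional)
#' @param functions_path TSV human id -> function token
#' @return list with `edges` (data.frame from/to), `orthologs` (data.frame
#'   mouse_id/human_id), `functions` (data.frame human_id/class)
#' @export
read_network_tables <- function(edges_path, orthologs_path, functions_path) {
  read2 <- function(path, nms) {
    tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(tab) < 2) stop("expected >= 2 columns in ", path)
    tab <- tab[, 1:2]
    names(tab) <- nms
    if (nrow(tab) && identical(unname(unlist(tab[1, ])), nms))
      tab <- tab[-1, , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  edges <- read2(edges_path, c("from", "to"))
  edges <- edges[edges$from != edges$to, , drop = FALSE]    # self-loops
  if (nrow(edges)) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(from = a[keep], to = b[keep],
                        stringsAsFactors = FALSE)
  }
  orthologs <- read2(orthologs_path, c("mouse_id", "human_id"))
  functions <- read2(functions_path, c("human_id", "class"))
  bad <- setdiff(unique(functions$class), c("ST", "TF"))
  if (length(bad))
    stop("unknown function token(s): ", paste(bad, collapse = ", "))
  list(edges = edges, orthologs = orthologs, functions = functions)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Unknown keys (at the block or parameter level) are rejected so typos do
#' not silently fall back to defaults. Missing keys take defaults from
#' [default_config()].
#'
#' @param path config file; `.json` parsed as JSON, anything else as YAML
#' @return full configuration list
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON configs")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(), user)
}

merge_config <- function(base, user, path = "") {
  if (is.null(user)) return(base)
  extra <- setdiff(names(user), names(base))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "/"))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
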